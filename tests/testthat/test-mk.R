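test_that("zero-rate likelihood reduces to the uniform root prior", {
  tr <- tree3()
  states <- c(A = "S1", B = "S1", C = "S1")
  for (k in 2:4) {
    m <- mk_model(k, "ER", 1e-12)
    expect_equal(mk_loglik(tr, states, m), -log(k), tolerance = 1e-6)
  }
})

test_that("two-state ER transition probability matches the analytic form", {
  q <- 0.37
  m <- mk_model(2, "ER", q)
  for (t in c(0.1, 1, 5)) {
    P <- phylospat:::mk_prob(m, t)
    expect_equal(P[1, 1], 0.5 + 0.5 * exp(-2 * q * t), tolerance = 1e-12)
    expect_equal(P[1, 2], 0.5 - 0.5 * exp(-2 * q * t), tolerance = 1e-12)
  }
})

test_that("transition matrices are proper stochastic matrices", {
  set.seed(12)
  for (param in c("ER", "SYM", "ARD")) {
    k <- 4
    n_par <- switch(param, ER = 1, SYM = 6, ARD = 12)
    m <- mk_model(k, param, runif(n_par, 0.01, 0.5))
    for (t in c(0.01, 1, 10, 80)) {
      P <- phylospat:::mk_prob(m, t)
      expect_true(all(P >= 0))
      expect_equal(unname(rowSums(P)), rep(1, k), tolerance = 1e-10)
    }
  }
})

test_that("pruning likelihood equals brute-force enumeration on small trees", {
  tr <- tree3()
  Q <- mk_model(2, "ER", 0.3)$Q
  states <- c(A = "S1", B = "S2", C = "S1")
  oracle <- mk_brute(tr, list(A = 1, B = 2, C = 1), Q)
  expect_equal(mk_loglik(tr, states, mk_model(2, "ER", 0.3)),
               log(oracle$lik), tolerance = 1e-10)

  set.seed(77)
  for (rep in 1:8) {
    n_tips <- sample(3:6, 1)
    k <- sample(2:4, 1)
    tr <- sim_yule_tree(n_tips, 1, 500 + rep)
    param <- sample(c("ER", "SYM", "ARD"), 1)
    n_par <- switch(param, ER = 1, SYM = k * (k - 1) / 2, ARD = k * (k - 1))
    m <- mk_model(k, param, runif(n_par, 0.05, 0.8))
    state_idx <- sample(k, n_tips, replace = TRUE)
    states <- setNames(m$state_labels[state_idx], tr$tip.label)
    oracle <- mk_brute(tr, as.list(setNames(state_idx, tr$tip.label)), m$Q)
    expect_equal(mk_loglik(tr, states, m), log(oracle$lik), tolerance = 1e-10)

    marg <- marginal_states(tr, states, m)
    expect_equal(unname(marg$prob), oracle$marginals, tolerance = 1e-10)
    expect_equal(rowSums(marg$prob), rep(1, nrow(marg$prob)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("ambiguity sets sum the likelihood over member states", {
  tr <- tree3()
  m <- mk_model(3, "ER", 0.4)
  states <- c(A = "S1|S2", B = "S3", C = "S1")
  oracle <- mk_brute(tr, list(A = c(1, 2), B = 3, C = 1), m$Q)
  expect_equal(mk_loglik(tr, states, m), log(oracle$lik), tolerance = 1e-10)
})

test_that("likelihood is invariant to tip ordering", {
  tr <- sim_yule_tree(8, 1, 101)
  m <- mk_model(3, "ER", 0.25)
  states <- setNames(m$state_labels[sample(3, 8, replace = TRUE)], tr$tip.label)
  ll1 <- mk_loglik(tr, states, m)
  ll2 <- mk_loglik(tr, states[sample(names(states))], m)
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("marginals at observed tips are certain; uniform data stay modal", {
  tr <- sim_yule_tree(10, 1, 55)
  m <- mk_model(3, "ER", 0.2)
  states <- setNames(rep("S2", 10), tr$tip.label)
  marg <- marginal_states(tr, states, m)
  for (i in 1:10) expect_equal(unname(marg$prob[i, "S2"]), 1)
  expect_true(all(marg$modal_state == "S2"))
})

test_that("ML fitting respects model nesting and boundary cases", {
  tr <- sim_yule_tree(25, 1, 71)
  states <- sim_mk_tip_states(tr, 3, 0.3, seed = 6)
  f_er <- fit_mk(tr, states, "ER")
  f_sym <- fit_mk(tr, states, "SYM")
  f_ard <- fit_mk(tr, states, "ARD")
  expect_gte(f_sym$loglik, f_er$loglik - 1e-4)
  expect_gte(f_ard$loglik, f_sym$loglik - 1e-4)

  same <- setNames(rep("X", 25), tr$tip.label)
  expect_warning(f0 <- fit_mk(tr, same, "ER", state_labels = c("X", "Y")),
                 "lower bound")
  expect_lt(f0$model$rates[1], 1e-6)
})

test_that("ER rate estimates agree with an independent implementation", {
  tr <- sim_yule_tree(40, 1, 88)
  states <- sim_mk_tip_states(tr, 3, 0.4, seed = 14)
  f <- fit_mk(tr, states, "ER")
  ref <- ape::ace(factor(states[tr$tip.label]), tr, type = "discrete",
                  model = "ER")
  expect_equal(unname(f$model$rates[1]), unname(ref$rates[1]),
               tolerance = 0.02)
  # ace reports the likelihood before averaging over the uniform root
  # prior, so the two differ by exactly log(k)
  expect_equal(f$loglik + log(3), ref$loglik, tolerance = 1e-3)
})

test_that("model selection applies the requested criterion", {
  fake <- function(tag, loglik, n_par) {
    structure(list(model = list(parameterization = tag), loglik = loglik,
                   n_par = n_par, aic = 2 * n_par - 2 * loglik),
              class = "mk_fit")
  }
  fits <- list(ER = fake("ER", -10.0, 1), ARD = fake("ARD", -9.9, 12))
  expect_equal(fits$ER$aic, 22.0)
  expect_equal(fits$ARD$aic, 43.8)
  expect_equal(select_model(fits, "aic"), "ER")
  expect_equal(select_model(fits, "loglik"), "ARD")
  expect_equal(select_model(fits["ER"], "aic"), "ER")
})

test_that("a south-east root with late dispersal is recovered as modal", {
  # ~0.5 expected transitions per 80 Myr root-to-tip path: dispersal is
  # rare and late, so the root area should be recoverable
  hits <- 0; reps <- 100
  for (i in seq_len(reps)) {
    tr <- sim_yule_tree(40, 0.05, 9000 + i)
    tr$edge.length <- tr$edge.length * 80 / max(ape::node.depth.edgelength(tr))
    st <- sim_mk_tip_states(tr, 4, 0.002, seed = 9500 + i,
                            state_labels = c("SE", "SW", "NE", "NW"),
                            root_state = "SE")
    if (length(unique(st)) < 2) { hits <- hits + (st[[1]] == "SE"); next }
    f <- fit_mk(tr, st, "ER", state_labels = c("SE", "SW", "NE", "NW"))
    m <- marginal_states(f)
    if (m$modal_state[41] == "SE") hits <- hits + 1
  }
  expect_gte(hits, 80)
})

test_that("ER data lead AIC to prefer ER over ARD in most replicates", {
  wins <- 0
  for (i in 1:10) {
    tr <- sim_yule_tree(30, 1, 3000 + i)
    states <- sim_mk_tip_states(tr, 3, 0.3, seed = 400 + i)
    if (length(unique(states)) < 2) next
    f_er <- fit_mk(tr, states, "ER")
    f_ard <- fit_mk(tr, states, "ARD")
    if (select_model(list(ER = f_er, ARD = f_ard), "aic") == "ER")
      wins <- wins + 1
  }
  expect_gte(wins, 9)
})
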