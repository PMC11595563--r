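test_that("declared collinear pairs achieve their target correlation", {
  sc <- synthetic_scenario(seed = 7, collinear_pairs = list(c(1, 2, 0.95),
                                                            c(3, 4, -0.85)))
  st <- gen_env_stack(sc)
  expect_gte(abs(pearson_r(st$layers[[1]], st$layers[[2]])), 0.9)
  expect_equal(pearson_r(st$layers[[1]], st$layers[[2]]), 0.95,
               tolerance = 0.05)
  expect_equal(pearson_r(st$layers[[3]], st$layers[[4]]), -0.85,
               tolerance = 0.05)
})

test_that("generators are deterministic given the scenario seed", {
  sc <- synthetic_scenario(seed = 3)
  s1 <- gen_env_stack(sc); s2 <- gen_env_stack(sc)
  expect_identical(s1, s2)
  t1 <- sim_yule_tree(10, 0.5, 99); t2 <- sim_yule_tree(10, 0.5, 99)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  tr <- gen_true_suitability(s1, sc$true_coefficients, -1)
  o1 <- sample_presences(tr, 50, 5); o2 <- sample_presences(tr, 50, 5)
  expect_identical(o1, o2)
  m1 <- sim_mk_tip_states(t1, 3, 0.5, 4); m2 <- sim_mk_tip_states(t1, 3, 0.5, 4)
  expect_identical(m1, m2)
})

test_that("degenerate scenarios are rejected with clear messages", {
  expect_error(synthetic_scenario(extent = c(0, 0, 0, 100)), "degenerate")
  expect_error(synthetic_scenario(extent = c(0, 0, 100, 100),
                                  cell_size_km = 50), "100 cells")
  expect_error(synthetic_scenario(true_coefficients = c(bogus = 1)),
               "do not exist")
})

test_that("true suitability is the logistic of the known linear predictor", {
  sc <- synthetic_scenario(seed = 5, n_layers = 2,
                           true_coefficients = c(env1 = 0, env2 = 0))
  st <- gen_env_stack(sc)
  flat <- gen_true_suitability(st, c(env1 = 0), intercept = 0)
  expect_true(all(abs(flat$values - 0.5) < 1e-15))
  nowhere <- gen_true_suitability(st, c(env1 = 0), intercept = -50)
  expect_true(all(nowhere$values < 1e-15))
  # a steep single-layer coefficient approximates a hard threshold map
  steep <- gen_true_suitability(st, c(env1 = 50), intercept = -10)
  hard <- st$layers$env1$values > 10 / 50
  interior <- abs(st$layers$env1$values - 0.2) > 0.05
  expect_true(all((steep$values[interior] > 0.5) == hard[interior]))
  expect_error(gen_true_suitability(st, c(nope = 1)), "unknown layer")
})

test_that("presence sampling follows the suitability surface", {
  tr <- c(0, 0, 10, 10)
  v <- matrix(0, 20, 20); v[7, 13] <- 1
  one <- raster_layer(v, tr)
  occ <- sample_presences(one, 5, seed = 2)
  cc <- cell_centers(one)
  target <- cc[cc$row == 7 & cc$col == 13, ]
  expect_true(all(occ$lon == target$x & occ$lat == target$y))
  expect_error(sample_presences(raster_layer(matrix(0, 20, 20), tr), 5, 1),
               "all-zero")
  # uniform surface: per-quadrant counts within 3 binomial SDs of n/4
  unif <- raster_layer(matrix(1, 40, 40), tr)
  occ <- sample_presences(unif, 1000, seed = 8)
  q <- table(paste(occ$lon > 200, occ$lat > 200))
  expect_equal(length(q), 4L)
  tol <- 3 * sqrt(1000 * 0.25 * 0.75)
  expect_true(all(abs(q - 250) <= tol))
})

test_that("Yule simulation yields binary ultrametric trees with known growth", {
  t3 <- sim_yule_tree(3, 1, 11)
  expect_equal(t3$Nnode, 2L)
  expect_equal(length(t3$tip.label), 3L)
  d <- ape::node.depth.edgelength(t3)[1:3]
  expect_lt(max(d) - min(d), 1e-9)
  # mean lineage count at time t from the root grows like 2*exp(bt)
  reps <- 400
  t_probe <- 2
  counts <- vapply(seq_len(reps), function(i) {
    tr <- sim_yule_tree(150, 1, 1000 + i)
    root_age <- max(ape::node.depth.edgelength(tr))
    if (root_age < t_probe) return(NA_real_)
    lineages_at(tr, root_age - t_probe)
  }, numeric(1))
  counts <- counts[!is.na(counts)]
  expect_gt(length(counts), 350)
  expect_equal(mean(counts), 2 * exp(t_probe), tolerance = 0.1)
})

test_that("Mk tip-state simulation has the right limiting behaviour", {
  tr <- sim_yule_tree(8, 1, 21)
  frozen <- sim_mk_tip_states(tr, 4, 0, seed = 5)
  expect_equal(length(unique(frozen)), 1L)
  # saturated chain: tip states uniform over many replicates
  counts <- integer(3)
  for (i in 1:1000) {
    s <- sim_mk_tip_states(tree3(), 3, 100, seed = i)
    tab <- table(factor(s, levels = paste0("A", 1:3)))
    counts <- counts + as.integer(tab)
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  # a fixed root state is respected at rate 0
  forced <- sim_mk_tip_states(tr, 4, 0, seed = 9, root_state = "A3")
  expect_true(all(forced == "A3"))
})

test_that("scenario inputs serialise to plain-text formats and reload", {
  sc <- synthetic_scenario(seed = 13, n_presences = 30, n_tips = 6)
  dir <- tempfile()
  out <- write_scenario_inputs(sc, dir)
  expect_true(all(file.exists(unlist(out$paths))))
  st <- read_ascii_grid(out$paths$env1)
  expect_equal(st$values, out$stack$layers$env1$values, tolerance = 1e-12)
  occ <- read_occurrences(out$paths$occurrences, geographic = FALSE)
  expect_equal(nrow(occ), 30)
  tree <- read_timetree(out$paths$tree)
  expect_equal(length(tree$tip.label), 6)
})
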