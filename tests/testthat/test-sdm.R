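# a hand-built ensemble whose members are simple deterministic functions of
# the predictor columns, for exact ensemble arithmetic
fake_fit <- function(stack, preds, aucs, thresholds, tsss = NULL) {
  n <- length(preds)
  if (is.null(tsss)) tsss <- rep(0.8, n)
  members <- data.frame(
    algorithm = rep("GLM", n), pa_replicate = 1L, cv_run = seq_len(n),
    auc = aucs, tss = tsss, threshold = thresholds,
    passes_qc = aucs > 0.8 & tsss >= 0.7, ok = TRUE)
  runs <- lapply(preds, function(f) list(predict = f))
  structure(list(members = members, runs = runs, stack = stack,
                 presences = NULL, pa_sets = NULL, settings = list()),
            class = "sdm_ensemble")
}

demo_stack <- function(n = 6) {
  tr <- c(0, 0, 10, 10)
  set.seed(1)
  raster_stack(list(
    raster_layer(matrix(runif(n * n), n, n), tr, "env1"),
    raster_layer(matrix(runif(n * n), n, n), tr, "env2")))
}

test_that("pseudo-absence sets avoid presences and are reproducible", {
  sc <- synthetic_scenario(seed = 4)
  st <- gen_env_stack(sc)
  truth <- gen_true_suitability(st, sc$true_coefficients, -1)
  occ <- sample_presences(truth, 40, 11)
  pa <- gen_pseudo_absences(st, occ, n = 500, n_sets = 3, seed = 9)
  expect_length(pa, 3)
  ref <- st$layers[[1]]
  occ_cells <- paste(point_to_cell(ref, occ$lon, occ$lat)$row,
                     point_to_cell(ref, occ$lon, occ$lat)$col)
  for (s in pa) {
    expect_equal(nrow(s), 500)
    cells <- point_to_cell(ref, s$lon, s$lat)
    expect_false(any(paste(cells$row, cells$col) %in% occ_cells))
  }
  pa2 <- gen_pseudo_absences(st, occ, n = 500, n_sets = 3, seed = 9)
  expect_identical(pa, pa2)
  # infeasible request
  tiny <- raster_stack(list(raster_layer(matrix(1, 15, 15), c(0, 0, 1, 1), "a")))
  many <- data.frame(lon = rep(0.5, 1), lat = 0.5)
  expect_error(gen_pseudo_absences(tiny, many, n = 500), "available")
})

test_that("the model grid always has |algorithms| x |PA| x |CV| runs", {
  sc <- synthetic_scenario(seed = 14, cell_size_km = 50,
                           true_coefficients = c(env1 = 3))
  st <- gen_env_stack(sc)
  truth <- gen_true_suitability(st, c(env1 = 3), -0.5)
  occ <- sample_presences(truth, 30, 2)
  fit <- fit_sdm(st, occ, algorithms = c("GLM", "RF"), cv_runs = 3,
                 seed = 8, n_pa = 100, n_pa_sets = 2,
                 hyper = list(rf_trees = 100))
  expect_equal(nrow(fit$members), 2 * 2 * 3)
  expect_true(all(table(fit$members$algorithm) == 6))
  one <- fit_sdm(st, occ, algorithms = "GLM", cv_runs = 1, seed = 8,
                 n_pa = 100, n_pa_sets = 1)
  expect_equal(nrow(one$members), 1)
})

test_that("committee averaging is the fraction of member votes", {
  st <- demo_stack()
  # member votes: f1 always presence (score 1 >= 0.5); f2 never (0 < 0.5)
  f1 <- function(X) rep(1, nrow(X))
  f2 <- function(X) rep(0, nrow(X))
  fit <- fake_fit(st, list(f1, f1, f2, f2), aucs = rep(0.9, 4),
                  thresholds = rep(0.5, 4))
  ca <- ensemble_ca(fit)
  expect_true(all(ca$values == 0.5))
  unanimous <- fake_fit(st, list(f1, f1), aucs = c(0.9, 0.9),
                        thresholds = c(0.5, 0.5))
  expect_true(all(ensemble_ca(unanimous)$values == 1))
  # single member: CA equals that member's binary map
  solo <- fake_fit(st, list(function(X) as.numeric(X[, "env1"] >= 0.4)),
                   aucs = 0.9, thresholds = 0.5)
  ca1 <- ensemble_ca(solo)
  expect_true(all(ca1$values %in% c(0, 1)))
  expect_equal(as.vector(ca1$values),
               as.numeric(as.vector(st$layers$env1$values) >= 0.4))
})

test_that("weighted mean ensemble applies AUC weights", {
  st <- demo_stack()
  f0 <- function(X) rep(0, nrow(X))
  f1 <- function(X) rep(1, nrow(X))
  fit <- fake_fit(st, list(f0, f1), aucs = c(0.25, 0.75),
                  thresholds = c(0.5, 0.5))
  wm <- ensemble_wm(fit)
  expect_true(all(abs(wm$values - 0.75) < 1e-12))
  # equal weights reduce to the plain mean
  fit_eq <- fake_fit(st, list(f0, f1), aucs = c(0.5, 0.5),
                     thresholds = c(0.5, 0.5))
  expect_true(all(abs(ensemble_wm(fit_eq)$values - 0.5) < 1e-12))
  # identical members return the common map
  g <- function(X) X[, "env1"]
  fit_id <- fake_fit(st, list(g, g, g), aucs = c(0.6, 0.7, 0.8),
                     thresholds = rep(0.5, 3))
  expect_equal(ensemble_wm(fit_id)$values, st$layers$env1$values,
               tolerance = 1e-12)
})

test_that("ensemble evaluation extracts map values at the points", {
  st <- demo_stack()
  cc <- cell_centers(st$layers[[1]])
  pres <- data.frame(lon = cc$x[1:5], lat = cc$y[1:5])
  abs_ <- data.frame(lon = cc$x[20:30], lat = cc$y[20:30])
  v <- matrix(0, 6, 6); v[cbind(cc$row[1:5], cc$col[1:5])] <- 1
  perfect <- raster_layer(v, st$layers[[1]]$transform)
  ev <- evaluate_ensemble(perfect, pres, abs_)
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$tss, 1.0)
  flat <- raster_layer(matrix(0.4, 6, 6), st$layers[[1]]$transform)
  expect_equal(evaluate_ensemble(flat, pres, abs_)$auc, 0.5)
  outside <- data.frame(lon = 1000, lat = 1000)
  expect_error(evaluate_ensemble(flat, pres, outside), "outside")
})

test_that("permutation importance isolates the variables a model uses", {
  sc <- synthetic_scenario(seed = 19, cell_size_km = 50,
                           true_coefficients = c(env1 = 3))
  st <- gen_env_stack(sc)
  truth <- gen_true_suitability(st, c(env1 = 3), 0)
  occ <- sample_presences(truth, 40, 3)
  pa <- gen_pseudo_absences(st, occ, n = 100, n_sets = 1, seed = 2)
  fit <- fit_sdm(st, occ, pa_sets = pa, algorithms = "GLM", cv_runs = 1,
                 seed = 5)
  # swap in a hand-made member that copies env1 and ignores the rest
  fit$runs[[1]]$predict <- function(X) X[, "env1"]
  vi <- variable_importance(fit, n_perm = 3, seed = 7)
  expect_equal(unname(vi["env2"]), 0, tolerance = 1e-12)
  expect_gt(vi["env1"], 0.5)
})

test_that("failed learners are flagged but keep their grid slot", {
  st <- demo_stack()
  cc <- cell_centers(st$layers[[1]])
  occ <- data.frame(lon = cc$x[1:10], lat = cc$y[1:10])
  pa <- list(data.frame(lon = cc$x[11:30], lat = cc$y[11:30]))
  fit <- fit_sdm(st, occ, pa_sets = pa, algorithms = c("GLM", "BOGUS"),
                 cv_runs = 2, seed = 3)
  expect_equal(nrow(fit$members), 4)
  bogus <- fit$members[fit$members$algorithm == "BOGUS", ]
  expect_true(all(!bogus$ok))
  expect_true(all(fit$members$ok[fit$members$algorithm == "GLM"]))
})
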