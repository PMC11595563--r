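combined_mask <- function(stack) {
  m <- stack$layers[[1]]$nodata_mask
  for (l in stack$layers) m <- m | l$nodata_mask
  m
}

#' Generate pseudo-absence point sets
#'
#' Each set draws `n` distinct cells uniformly from the valid study area,
#' excluding any cell that contains a presence record, and places one point
#' at each drawn cell's centre. Sets are independent draws.
#'
#' @param stack a [raster_stack()] defining the study area (a cell is valid
#'   when valid in every layer).
#' @param presences data.frame with `lon`, `lat` columns.
#' @param n points per set (default 500).
#' @param n_sets number of replicate sets (default 3).
#' @param seed RNG seed.
#' @return list of `n_sets` data.frames with columns `lon`, `lat`.
#' @export
gen_pseudo_absences <- function(stack, presences, n = 500, n_sets = 3, seed = 1) {
  ref <- stack$layers[[1]]
  mask <- combined_mask(stack)
  rc <- point_to_cell(ref, presences$lon, presences$lat)
  occupied <- matrix(FALSE, nrow(mask), ncol(mask))
  ok <- !is.na(rc$row)
  occupied[cbind(rc$row[ok], rc$col[ok])] <- TRUE
  available <- which(!mask & !occupied)
  if (length(available) < n)
    stop_ps("only %d cells available for %d pseudo-absences", length(available), n)
  cc <- cell_centers(ref)
  seeds <- derive_seeds(seed, n_sets)
  lapply(seq_len(n_sets), function(s) {
    set.seed(seeds[s])
    idx <- sample(available, n)
    data.frame(lon = cc$x[idx], lat = cc$y[idx])
  })
}

# default learner hyperparameters; gbm_* follow common boosted-model
# defaults for presence/background data (many shallow trees, slow learning)
default_hyper <- function() {
  list(gam_k = 5, gbm_trees = 2500, gbm_depth = 3, gbm_shrinkage = 0.01,
       rf_trees = 500)
}

fit_learner <- function(algorithm, X, y, hyper) {
  df <- data.frame(.y = y, X, check.names = FALSE)
  vars <- colnames(X)
  switch(
    algorithm,
    GLM = {
      m <- stats::glm(stats::reformulate(sprintf("`%s`", vars), ".y"),
                      family = stats::binomial(), data = df)
      function(newX) as.numeric(stats::predict(
        m, newdata = as.data.frame(newX, check.names = FALSE),
        type = "response"))
    },
    GAM = {
      ks <- vapply(vars, function(v) min(hyper$gam_k, length(unique(X[, v])) - 1L),
                   numeric(1))
      terms <- ifelse(ks >= 3, sprintf("s(`%s`, k = %d)", vars, ks),
                      sprintf("`%s`", vars))
      m <- mgcv::gam(stats::as.formula(paste(".y ~", paste(terms, collapse = "+"))),
                     family = stats::binomial(), data = df, method = "REML")
      function(newX) as.numeric(stats::predict(
        m, newdata = as.data.frame(newX, check.names = FALSE),
        type = "response"))
    },
    GBM = {
      m <- xgboost::xgboost(
        data = as.matrix(X), label = y,
        nrounds = hyper$gbm_trees,
        params = list(objective = "binary:logistic",
                      max_depth = hyper$gbm_depth,
                      eta = hyper$gbm_shrinkage,
                      nthread = 1),
        verbose = 0)
      function(newX) as.numeric(stats::predict(m, as.matrix(newX)))
    },
    RF = {
      m <- randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                                      ntree = hyper$rf_trees)
      function(newX) unname(stats::predict(m, newdata = newX,
                                           type = "prob")[, "1"])
    },
    stop_ps("unknown algorithm '%s'", algorithm)
  )
}

#' Fit an ensemble of species distribution models
#'
#' Fits one member model per (algorithm x pseudo-absence set x
#' cross-validation run). For each run the presences and that run's
#' pseudo-absences are split `train_fraction` / rest (stratified); the
#' member is fitted on the training portion and its AUC, max-TSS threshold
#' and TSS are computed on the held-out portion. A member whose learner
#' fails to fit is flagged and excluded from ensembling, never aborting the
#' grid, so the run count is always
#' `length(algorithms) * length(pa_sets) * cv_runs`.
#'
#' @param stack a [raster_stack()] of (already collinearity-filtered)
#'   predictor layers.
#' @param presences data.frame with `lon`, `lat` columns.
#' @param pa_sets list of pseudo-absence data.frames (see
#'   [gen_pseudo_absences()]); generated automatically when `NULL`.
#' @param algorithms subset of `c("GLM", "GAM", "GBM", "RF")`.
#' @param cv_runs number of cross-validation replications (default 10).
#' @param train_fraction fraction used for calibration (default 0.75).
#' @param seed RNG seed controlling pseudo-absences, splits and learners.
#' @param n_pa,n_pa_sets pseudo-absence count and set count used when
#'   `pa_sets` is `NULL` (defaults 500 and 3).
#' @param hyper named list overriding entries of the default learner
#'   hyperparameters: `gam_k` (smooth basis dimension, 5), `gbm_trees`
#'   (2500), `gbm_depth` (3), `gbm_shrinkage` (0.01), `rf_trees` (500).
#' @param qc_auc,qc_tss quality thresholds: a member passes QC when
#'   `auc > qc_auc` and `tss >= qc_tss` (defaults 0.8 and 0.7).
#' @return an object of class `sdm_ensemble` with elements `members`
#'   (data.frame: algorithm, pa_replicate, cv_run, auc, tss, threshold,
#'   passes_qc, ok), `runs` (list of member predictors), `stack`,
#'   `presences`, `pa_sets` and `settings`.
#' @export
fit_sdm <- function(stack, presences, pa_sets = NULL,
                    algorithms = c("GLM", "GAM", "GBM", "RF"),
                    cv_runs = 10, train_fraction = 0.75, seed = 1,
                    n_pa = 500, n_pa_sets = 3, hyper = list(),
                    qc_auc = 0.8, qc_tss = 0.7) {
  if (nrow(presences) < 8) stop_ps("need at least 8 presences")
  hyper <- utils::modifyList(default_hyper(), hyper)
  seeds <- derive_seeds(seed, 3L)
  if (is.null(pa_sets))
    pa_sets <- gen_pseudo_absences(stack, presences, n = n_pa,
                                   n_sets = n_pa_sets, seed = seeds[1])
  if (length(pa_sets) == 0) stop_ps("pa_sets must be non-empty")

  Xp <- extract_values(stack, presences$lon, presences$lat)
  keep_p <- stats::complete.cases(Xp)
  Xp <- Xp[keep_p, , drop = FALSE]
  if (nrow(Xp) < 8) stop_ps("fewer than 8 presences fall on valid cells")

  runs <- list()
  rows <- list()
  run_seeds <- derive_seeds(seeds[2], length(pa_sets) * cv_runs)
  ri <- 0L
  for (pa_i in seq_along(pa_sets)) {
    Xa <- extract_values(stack, pa_sets[[pa_i]]$lon, pa_sets[[pa_i]]$lat)
    Xa <- Xa[stats::complete.cases(Xa), , drop = FALSE]
    for (cv in seq_len(cv_runs)) {
      set.seed(run_seeds[(pa_i - 1L) * cv_runs + cv])
      # one calibration split per (pa, cv), shared by all algorithms
      tr_p <- sample(nrow(Xp), round(train_fraction * nrow(Xp)))
      tr_a <- sample(nrow(Xa), round(train_fraction * nrow(Xa)))
      Xtr <- rbind(Xp[tr_p, , drop = FALSE], Xa[tr_a, , drop = FALSE])
      ytr <- c(rep(1, length(tr_p)), rep(0, length(tr_a)))
      Xte <- rbind(Xp[-tr_p, , drop = FALSE], Xa[-tr_a, , drop = FALSE])
      yte <- c(rep(1, nrow(Xp) - length(tr_p)), rep(0, nrow(Xa) - length(tr_a)))
      for (alg in algorithms) {
        ri <- ri + 1L
        rec <- list(algorithm = alg, pa_replicate = pa_i, cv_run = cv,
                    auc = NA_real_, tss = NA_real_, threshold = NA_real_,
                    passes_qc = FALSE, ok = FALSE, error = NA_character_)
        pred_fun <- tryCatch(
          suppressWarnings(fit_learner(alg, Xtr, ytr, hyper)),
          error = function(e) e)
        if (!inherits(pred_fun, "error")) {
          eval_res <- tryCatch({
            sc <- pred_fun(Xte)
            bt <- best_threshold(sc, yte)
            list(auc = auc_score(sc, yte), tss = bt$tss,
                 threshold = bt$threshold)
          }, error = function(e) e)
          if (!inherits(eval_res, "error")) {
            rec$auc <- eval_res$auc
            rec$tss <- eval_res$tss
            rec$threshold <- eval_res$threshold
            rec$passes_qc <- eval_res$auc > qc_auc && eval_res$tss >= qc_tss
            rec$ok <- TRUE
            runs[[ri]] <- list(predict = pred_fun, algorithm = alg,
                               pa_replicate = pa_i, cv_run = cv)
          } else rec$error <- conditionMessage(eval_res)
        } else rec$error <- conditionMessage(pred_fun)
        if (!rec$ok) runs[ri] <- list(NULL)
        rows[[ri]] <- rec
      }
    }
  }
  members <- do.call(rbind, lapply(rows, function(r)
    data.frame(r[c("algorithm", "pa_replicate", "cv_run", "auc", "tss",
                   "threshold", "passes_qc", "ok")],
               stringsAsFactors = FALSE)))
  structure(
    list(members = members, runs = runs, stack = stack,
         presences = presences[keep_p, , drop = FALSE], pa_sets = pa_sets,
         settings = list(algorithms = algorithms, cv_runs = cv_runs,
                         train_fraction = train_fraction, seed = seed,
                         hyper = hyper, qc_auc = qc_auc, qc_tss = qc_tss)),
    class = "sdm_ensemble"
  )
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  ok <- x$members$ok
  cat(sprintf("<sdm_ensemble> %d member models (%d usable): %s x %d PA sets x %d CV runs\n",
              nrow(x$members), sum(ok),
              paste(x$settings$algorithms, collapse = "/"),
              length(x$pa_sets), x$settings$cv_runs))
  if (any(ok))
    cat(sprintf("  member AUC %.3f +/- %.3f, TSS %.3f +/- %.3f, %d pass QC\n",
                mean(x$members$auc[ok]), stats::sd(x$members$auc[ok]),
                mean(x$members$tss[ok]), stats::sd(x$members$tss[ok]),
                sum(x$members$passes_qc[ok])))
  invisible(x)
}

#' @export
summary.sdm_ensemble <- function(object, ...) {
  m <- object$members[object$members$ok, ]
  out <- do.call(rbind, lapply(split(m, m$algorithm), function(d)
    data.frame(algorithm = d$algorithm[1], n = nrow(d),
               auc_mean = mean(d$auc), auc_sd = stats::sd(d$auc),
               tss_mean = mean(d$tss), tss_sd = stats::sd(d$tss))))
  rownames(out) <- NULL
  out
}

# member scores over all valid grid cells: matrix [valid cells x members]
member_grid_scores <- function(fit, stack) {
  mask <- combined_mask(stack)
  valid <- which(!as.vector(mask))
  X <- sapply(stack$layers, function(l) as.vector(l$values)[valid])
  usable <- which(fit$members$ok)
  if (length(usable) == 0) stop_ps("no usable member models")
  sc <- vapply(usable, function(i) fit$runs[[i]]$predict(X), numeric(length(valid)))
  list(scores = matrix(sc, nrow = length(valid)), valid = valid,
       usable = usable, mask = mask)
}

scores_to_layer <- function(values, valid, stack, name) {
  ref <- stack$layers[[1]]
  v <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  v[valid] <- values
  raster_layer(v, ref$transform, name = name, crs_tag = ref$crs_tag)
}

#' Committee-averaging ensemble map
#'
#' Each usable member votes presence/absence at every cell using its own
#' max-TSS threshold; the CA score is the fraction of members voting
#' presence.
#'
#' @param fit an [fit_sdm()] object.
#' @param stack raster stack to project onto (default: the fitted stack).
#' @param qc_filter restrict to members passing QC (default `FALSE`: all
#'   usable members are mixed).
#' @return a [raster_layer()] with values in `[0, 1]`.
#' @export
ensemble_ca <- function(fit, stack = fit$stack, qc_filter = FALSE) {
  g <- member_grid_scores(fit, stack)
  keep <- if (qc_filter) fit$members$passes_qc[g$usable] else
    rep(TRUE, length(g$usable))
  if (!any(keep)) stop_ps("no members left after QC filtering")
  thr <- fit$members$threshold[g$usable][keep]
  votes <- sweep(g$scores[, keep, drop = FALSE], 2, thr, ">=")
  scores_to_layer(rowMeans(votes), g$valid, stack, "ensemble_ca")
}

#' Weighted-mean ensemble map
#'
#' Per cell, the evaluation-metric-weighted mean of member continuous
#' scores (weights proportional to member AUC by default, TSS optionally).
#'
#' @inheritParams ensemble_ca
#' @param weight_metric `"auc"` (default) or `"tss"`.
#' @return a [raster_layer()] with values in `[0, 1]`.
#' @export
ensemble_wm <- function(fit, stack = fit$stack, weight_metric = c("auc", "tss"),
                        qc_filter = FALSE) {
  weight_metric <- match.arg(weight_metric)
  g <- member_grid_scores(fit, stack)
  keep <- if (qc_filter) fit$members$passes_qc[g$usable] else
    rep(TRUE, length(g$usable))
  if (!any(keep)) stop_ps("no members left after QC filtering")
  w <- fit$members[[weight_metric]][g$usable][keep]
  if (any(w <= 0)) w <- pmax(w, 1e-8)
  wm <- as.vector(g$scores[, keep, drop = FALSE] %*% w) / sum(w)
  scores_to_layer(wm, g$valid, stack, "ensemble_wm")
}

#' Project an ensemble onto a raster stack
#'
#' @param object an [fit_sdm()] object.
#' @param stack raster stack to project onto (default: the fitted stack).
#' @param method `"wm"` (default) or `"ca"`.
#' @param ... passed to [ensemble_wm()] / [ensemble_ca()].
#' @return a [raster_layer()] of ensemble suitability.
#' @export
predict.sdm_ensemble <- function(object, stack = object$stack,
                                 method = c("wm", "ca"), ...) {
  method <- match.arg(method)
  if (method == "wm") ensemble_wm(object, stack, ...)
  else ensemble_ca(object, stack, ...)
}

#' @export
plot.sdm_ensemble <- function(x, method = "wm", ...) {
  plot(predict(x, method = method), ...)
}

#' @export
plot.raster_layer <- function(x, main = x$name, ...) {
  d <- dim(x$values)
  tr <- x$transform
  xs <- tr[1] + (seq_len(d[2]) - 0.5) * tr[3]
  ys <- tr[2] + (seq_len(d[1]) - 0.5) * tr[4]
  graphics::image(xs, ys, t(x$values[d[1]:1, , drop = FALSE]),
                  xlab = "x", ylab = "y", main = main, useRaster = TRUE, ...)
  invisible(x)
}

#' Evaluate an ensemble map against presence and pseudo-absence points
#'
#' Extracts map values at both point sets, then computes AUC and the TSS at
#' the max-TSS threshold.
#'
#' @param map a [raster_layer()] of suitability.
#' @param presences,pa_points data.frames with `lon`, `lat`.
#' @return list with `auc`, `tss`, `threshold`.
#' @export
evaluate_ensemble <- function(map, presences, pa_points) {
  if (nrow(presences) == 0 || nrow(pa_points) == 0)
    stop_ps("both point sets must be non-empty")
  sp <- extract_values(map, presences$lon, presences$lat)
  sa <- extract_values(map, pa_points$lon, pa_points$lat)
  out_idx <- c(which(is.na(sp)), nrow(presences) + which(is.na(sa)))
  if (length(out_idx))
    stop_ps("points outside the grid or on nodata cells at indices: %s",
            paste(out_idx, collapse = ", "))
  sc <- c(sp, sa)
  y <- c(rep(1, length(sp)), rep(0, length(sa)))
  bt <- best_threshold(sc, y)
  list(auc = auc_score(sc, y), tss = bt$tss, threshold = bt$threshold)
}

#' Permutation variable importance
#'
#' For each predictor, a member's predictions on the original point data are
#' compared with predictions after permuting that predictor's column;
#' importance is `1 - |Pearson r|` between the two, averaged over `n_perm`
#' permutations and over usable members. A variable the model ignores
#' scores 0; a variable the model tracks exactly scores near 1.
#'
#' @param fit an [fit_sdm()] object.
#' @param n_perm permutations per variable (default 3).
#' @param seed RNG seed.
#' @return named numeric vector of importance scores in `[0, 1]`.
#' @export
variable_importance <- function(fit, n_perm = 3, seed = 1) {
  usable <- which(fit$members$ok)
  if (length(usable) == 0) stop_ps("no usable member models")
  X <- extract_values(fit$stack, fit$presences$lon, fit$presences$lat)
  for (pa in fit$pa_sets)
    X <- rbind(X, extract_values(fit$stack, pa$lon, pa$lat))
  X <- X[stats::complete.cases(X), , drop = FALSE]
  vars <- colnames(X)
  seeds <- derive_seeds(seed, n_perm)
  imp <- matrix(0, length(vars), length(usable),
                dimnames = list(vars, NULL))
  for (mi in seq_along(usable)) {
    pred <- fit$runs[[usable[mi]]]$predict
    p0 <- pred(X)
    s0 <- stats::sd(p0)
    for (v in vars) {
      acc <- 0
      for (p in seq_len(n_perm)) {
        set.seed(seeds[p])
        Xp <- X
        Xp[, v] <- X[sample(nrow(X)), v]
        p1 <- pred(Xp)
        if (s0 == 0 || stats::sd(p1) == 0) {
          warning("constant predictions: importance set to 0 for ", v)
          r <- 1
        } else r <- stats::cor(p0, p1)
        acc <- acc + (1 - abs(r))
      }
      imp[v, mi] <- acc / n_perm
    }
  }
  rowMeans(imp)
}
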