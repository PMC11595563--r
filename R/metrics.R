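#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, with ties counted one half. Computed from mid-ranks.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (or logical), same length as `scores`.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop_ps("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True Skill Statistic from a confusion table
#'
#' Sensitivity + specificity - 1.
#'
#' @param tp,fp,tn,fn confusion counts.
#' @return TSS in `[-1, 1]`.
#' @export
tss_score <- function(tp, fp, tn, fn) {
  if (tp + fn < 1) stop_ps("no positives: sensitivity undefined")
  if (tn + fp < 1) stop_ps("no negatives: specificity undefined")
  tp / (tp + fn) + tn / (tn + fp) - 1
}

tss_at <- function(scores, labels, threshold) {
  pred <- scores >= threshold
  tss_score(sum(pred & labels == 1), sum(pred & labels == 0),
            sum(!pred & labels == 0), sum(!pred & labels == 1))
}

#' Binarisation threshold maximising TSS
#'
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' scores (the single unique score itself when all scores are equal). A
#' score greater than or equal to the threshold predicts presence. Ties in
#' TSS are broken toward the lower threshold.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return list with `threshold` and `tss`.
#' @export
best_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!any(labels == 1L) || !any(labels == 0L))
    stop_ps("both classes must be present")
  u <- sort(unique(scores))
  cand <- if (length(u) == 1L) u else (u[-length(u)] + u[-1]) / 2
  tss <- vapply(cand, function(th) tss_at(scores, labels, th), numeric(1))
  i <- which.max(tss)  # which.max returns the first (lowest) maximiser
  list(threshold = cand[i], tss = tss[i])
}

#' Exact Fisher-Jenks natural breaks
#'
#' Dynamic program minimising the total within-class sum of squared
#' deviations over all partitions of the sorted values into `k` contiguous
#' classes. Returned breaks are the class maxima of the first k-1 classes;
#' classification uses half-open intervals `(lower, upper]`.
#'
#' @param values numeric vector (>= k distinct values).
#' @param k number of classes (>= 2).
#' @return numeric vector of k-1 ascending break values.
#' @export
jenks_breaks <- function(values, k) {
  stopifnot(k >= 2)
  x <- sort(values[!is.na(values)])
  n <- length(x)
  if (length(unique(x)) < k)
    stop_ps("need at least k distinct values (%d < %d)", length(unique(x)), k)
  # prefix sums give O(1) within-class SSD for any contiguous run
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  ssd <- function(i, j) {  # values x[i..j]
    m <- j - i + 1
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s^2 / m
  }
  # dp[c, j]: minimal total SSD for x[1..j] in c classes
  dp <- matrix(Inf, k, n)
  cut <- matrix(0L, k, n)
  for (j in seq_len(n)) dp[1, j] <- ssd(1, j)
  for (c in 2:k) {
    for (j in c:n) {
      best <- Inf; bi <- 0L
      for (i in c:j) {   # class c is x[i..j]
        v <- dp[c - 1, i - 1] + ssd(i, j)
        if (v < best) { best <- v; bi <- i }
      }
      dp[c, j] <- best; cut[c, j] <- bi
    }
  }
  # backtrack class boundaries
  breaks <- numeric(k - 1)
  j <- n
  for (c in k:2) {
    i <- cut[c, j]
    breaks[c - 1] <- x[i - 1]   # max of the class below
    j <- i - 1L
  }
  breaks
}

#' Assign class labels from ascending breaks
#'
#' Class m contains values in `(breaks[m-1], breaks[m]]`; values at or below
#' the first break are class 1, values above the last break are class
#' `length(breaks) + 1`.
#'
#' @param values numeric vector.
#' @param breaks ascending break values.
#' @return integer classes (NA preserved).
#' @export
classify_values <- function(values, breaks) {
  if (is.unsorted(breaks, strictly = TRUE)) stop_ps("breaks must be strictly ascending")
  cls <- rep(NA_integer_, length(values))
  ok <- !is.na(values)
  # left.open = TRUE gives intervals (breaks[m-1], breaks[m]]
  cls[ok] <- findInterval(values[ok], breaks, left.open = TRUE) + 1L
  cls
}

#' Classify a suitability map into discrete levels
#'
#' Applies Jenks breaks (computed from the map unless supplied) and reports
#' per-class area.
#'
#' @param map a [raster_layer()] of suitability values.
#' @param breaks optional precomputed ascending breaks; if `NULL`, Jenks
#'   breaks with `k` classes are computed from the valid cells.
#' @param k number of classes when computing breaks (default 4; class 1 is
#'   the least suitable).
#' @return object of class `suitability_classification`: `breaks`,
#'   `class_map` ([raster_layer()] of integer classes), `class_areas`
#'   (data.frame: class, n_cells, area_km2, percent).
#' @export
classify_suitability <- function(map, breaks = NULL, k = 4) {
  vals <- map$values[!map$nodata_mask]
  if (is.null(breaks)) breaks <- jenks_breaks(vals, k)
  cls <- matrix(classify_values(as.vector(map$values), breaks),
                nrow(map$values), ncol(map$values))
  cls[map$nodata_mask] <- NA_integer_
  cell_area <- map$transform[3] * map$transform[4]
  n_classes <- length(breaks) + 1L
  counts <- tabulate(cls[!is.na(cls)], nbins = n_classes)
  areas <- data.frame(
    class = seq_len(n_classes),
    n_cells = counts,
    area_km2 = counts * cell_area,
    percent = 100 * counts / sum(counts)
  )
  structure(
    list(breaks = breaks,
         class_map = raster_layer(cls, map$transform, name = "suitability_class",
                                  nodata_mask = map$nodata_mask,
                                  crs_tag = map$crs_tag),
         class_areas = areas),
    class = "suitability_classification"
  )
}

#' @export
print.suitability_classification <- function(x, ...) {
  cat("<suitability_classification> breaks:",
      paste(signif(x$breaks, 4), collapse = ", "), "\n")
  print(x$class_areas, row.names = FALSE)
  invisible(x)
}
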