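#' Build an analysis grid over occurrence points
#'
#' The grid is anchored at the floor of the bounding box to multiples of
#' the cell size; cells are half-open `[x, x + size) x [y, y + size)` so
#' every point falls in exactly one cell.
#'
#' @param points data.frame with `lon` (x) and `lat` (y) in projected /
#'   planar km.
#' @param cell_size_km cell size (default 100).
#' @return object of class `grid_spec`: `origin`, `cell_size_km`, `n_rows`,
#'   `n_cols`.
#' @export
build_grid <- function(points, cell_size_km = 100) {
  if (NROW(points) < 1) stop_ps("need at least one point")
  if (cell_size_km <= 0) stop_ps("cell size must be positive")
  ox <- floor(min(points$lon) / cell_size_km) * cell_size_km
  oy <- floor(min(points$lat) / cell_size_km) * cell_size_km
  n_cols <- floor((max(points$lon) - ox) / cell_size_km) + 1L
  n_rows <- floor((max(points$lat) - oy) / cell_size_km) + 1L
  structure(list(origin = c(ox, oy), cell_size_km = cell_size_km,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g km, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size_km, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Map points to grid cell indices
#'
#' @param grid a [build_grid()] object.
#' @param points data.frame with `lon`, `lat`.
#' @return data.frame with `row`, `col` (row 1 = southernmost).
#' @export
grid_cell_of <- function(grid, points) {
  data.frame(
    row = floor((points$lat - grid$origin[2]) / grid$cell_size_km) + 1L,
    col = floor((points$lon - grid$origin[1]) / grid$cell_size_km) + 1L
  )
}

#' Per-cell species sets and mean divergence times
#'
#' Species present in a cell are the deduplicated species of the records
#' falling in it; the cell's MDT is the mean stem age of that set.
#'
#' @param grid a [build_grid()] object.
#' @param occurrences data.frame with `species`, `lon`, `lat`.
#' @param stem_ages stem-age table ([stem_age_table()]).
#' @return data.frame of occupied cells: `row`, `col`, `cell_x`, `cell_y`
#'   (centres), `n_species`, `species` (comma-joined), `mdt`.
#' @export
cell_mdt <- function(grid, occurrences, stem_ages) {
  miss <- setdiff(unique(occurrences$species), stem_ages$species)
  if (length(miss))
    stop_ps("species missing from stem-age table: %s",
            paste(miss, collapse = ", "))
  rc <- grid_cell_of(grid, occurrences)
  key <- paste(rc$row, rc$col, sep = ":")
  cells <- lapply(split(seq_len(nrow(occurrences)), key), function(ix) {
    sp <- unique(occurrences$species[ix])
    data.frame(row = rc$row[ix[1]], col = rc$col[ix[1]],
               n_species = length(sp),
               species = paste(sp, collapse = ","),
               mdt = mean_divergence_time(sp, stem_ages),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out$cell_x <- grid$origin[1] + (out$col - 0.5) * grid$cell_size_km
  out$cell_y <- grid$origin[2] + (out$row - 0.5) * grid$cell_size_km
  out[order(out$row, out$col),
      c("row", "col", "cell_x", "cell_y", "n_species", "species", "mdt")]
}

#' Classify cell MDTs into Jenks levels
#'
#' @param cells output of [cell_mdt()].
#' @param k number of levels (default 4).
#' @return `cells` with an `mdt_class` column (1 = youngest) and the breaks
#'   as attribute `"breaks"`.
#' @export
classify_mdt <- function(cells, k = 4) {
  breaks <- jenks_breaks(cells$mdt, k)
  cells$mdt_class <- classify_values(cells$mdt, breaks)
  attr(cells, "breaks") <- breaks
  cells
}

#' Attach habitat-suitability values and classes to grid cells
#'
#' A cell's suitability value is the mean of the ensemble suitability map
#' over the raster cells whose centres fall inside the grid cell; its class
#' comes from the global Jenks breaks of the classification.
#'
#' @param cells output of [cell_mdt()].
#' @param grid the [build_grid()] object the cells refer to.
#' @param classification a [classify_suitability()] object (its `class_map`
#'   carries the suitability grid; breaks are reused).
#' @param suitability the continuous suitability [raster_layer()].
#' @return `cells` with `suitability_value` and `suitability_class`; cells
#'   without raster coverage are flagged (`suitability_class` NA) and
#'   reported via attribute `"flagged"`.
#' @export
attach_suitability <- function(cells, grid, classification, suitability) {
  cc <- cell_centers(suitability)
  v <- as.vector(suitability$values)
  v[as.vector(suitability$nodata_mask)] <- NA
  rc <- grid_cell_of(grid, data.frame(lon = cc$x, lat = cc$y))
  key_r <- paste(rc$row, rc$col, sep = ":")
  mean_by_cell <- tapply(v, key_r, mean, na.rm = TRUE)
  key_c <- paste(cells$row, cells$col, sep = ":")
  cells$suitability_value <- as.numeric(mean_by_cell[key_c])
  cells$suitability_value[is.nan(cells$suitability_value)] <- NA
  cells$suitability_class <- classify_values(cells$suitability_value,
                                             classification$breaks)
  flagged <- which(is.na(cells$suitability_value))
  if (length(flagged))
    warning(length(flagged), " occupied cell(s) lack raster coverage and are flagged")
  attr(cells, "flagged") <- flagged
  cells
}

kw_h_stat <- function(values, group) {
  n <- length(values)
  r <- rank(values)
  gs <- split(r, group)
  h <- 12 / (n * (n + 1)) * sum(vapply(gs, function(g) sum(g)^2 / length(g),
                                       numeric(1))) - 3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) h <- h / corr
  h
}

#' Kruskal-Wallis test across groups
#'
#' Tie-corrected H with a chi-square p-value (via [stats::kruskal.test()]),
#' plus an optional exact/Monte-Carlo permutation p-value for small samples.
#'
#' @param groups list of numeric vectors (>= 2 groups, total n >= 3).
#' @param permutation_p `"none"` (default), `"exact"` (full enumeration when
#'   the number of distinct assignments is at most `max_permutations`,
#'   otherwise Monte Carlo) or `"monte-carlo"`.
#' @param max_permutations enumeration/resampling budget (default 1e5).
#' @param seed seed for Monte-Carlo resampling.
#' @return object of class `kw_result`: `H`, `df`, `p_value`,
#'   `group_sizes`, and `p_permutation` when requested.
#' @export
kruskal_wallis <- function(groups, permutation_p = c("none", "exact", "monte-carlo"),
                           max_permutations = 1e5, seed = 1) {
  permutation_p <- match.arg(permutation_p)
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  if (length(groups) < 2) stop_ps("need at least 2 non-empty groups")
  values <- unlist(groups)
  n <- length(values)
  if (n < 3) stop_ps("need total n >= 3")
  group <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  if (length(unique(values)) == 1L) {
    res <- list(H = 0, df = length(groups) - 1L, p_value = 1,
                group_sizes = lengths(groups))
  } else {
    kt <- stats::kruskal.test(values, factor(group))
    res <- list(H = unname(kt$statistic), df = unname(kt$parameter),
                p_value = kt$p.value, group_sizes = lengths(groups))
  }
  if (permutation_p != "none") {
    h_obs <- if (length(unique(values)) == 1L) 0 else kw_h_stat(values, group)
    n_distinct <- exp(lgamma(n + 1) - sum(lgamma(lengths(groups) + 1)))
    if (permutation_p == "exact" && n_distinct <= max_permutations) {
      perms <- all_group_assignments(lengths(groups))
      hs <- apply(perms, 2, function(g) kw_h_stat(values, g))
      res$p_permutation <- mean(hs >= h_obs - 1e-12)
      res$permutation_kind <- "exact"
    } else {
      set.seed(seed)
      hs <- replicate(max_permutations,
                      kw_h_stat(values, sample(group)))
      res$p_permutation <- mean(hs >= h_obs - 1e-12)
      res$permutation_kind <- "monte-carlo"
    }
  }
  structure(res, class = "kw_result")
}

# all distinct assignments of n items to groups with fixed sizes; columns
# are assignments (used by the exact permutation p)
all_group_assignments <- function(sizes) {
  n <- sum(sizes)
  out <- list()
  recurse <- function(avail, gidx, assignment) {
    if (gidx == length(sizes)) {
      assignment[avail] <- gidx
      out[[length(out) + 1L]] <<- assignment
      return(invisible())
    }
    combs <- utils::combn(avail, sizes[gidx])
    for (ci in seq_len(ncol(combs))) {
      a2 <- assignment
      a2[combs[, ci]] <- gidx
      recurse(setdiff(avail, combs[, ci]), gidx + 1L, a2)
    }
  }
  recurse(seq_len(n), 1L, integer(n))
  do.call(cbind, out)
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g (n = %s)\n",
              x$H, x$df, x$p_value, paste(x$group_sizes, collapse = "/")))
  if (!is.null(x$p_permutation))
    cat(sprintf("  permutation p (%s) = %.4g\n", x$permutation_kind,
                x$p_permutation))
  invisible(x)
}

#' Dunn's post hoc pairwise comparisons with Holm adjustment
#'
#' Dunn's z statistics on the pooled ranks (with the standard tie
#' correction), two-sided normal p-values, Holm-adjusted.
#'
#' @param groups list of numeric vectors (the same groups tested with
#'   [kruskal_wallis()]).
#' @param alpha significance level for flagging (default 0.05).
#' @return data.frame: `group_a`, `group_b`, `z`, `p_raw`, `p_adjusted`,
#'   `significant`.
#' @export
pairwise_posthoc <- function(groups, alpha = 0.05) {
  g <- length(groups)
  if (g < 2) stop_ps("need at least 2 groups")
  values <- unlist(groups)
  n <- length(values)
  group <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  r <- rank(values)
  rbar <- tapply(r, group, mean)
  sizes <- lengths(groups)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(g, 2)
  z <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / sizes[a] + 1 / sizes[b]))
    z[i] <- (rbar[a] - rbar[b]) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  padj <- stats::p.adjust(p, method = "holm")
  nms <- names(groups) %||% as.character(seq_len(g))
  data.frame(group_a = nms[pairs[1, ]], group_b = nms[pairs[2, ]],
             z = z, p_raw = p, p_adjusted = padj,
             significant = padj < alpha, stringsAsFactors = FALSE)
}

# signed side of a polyline: interpolate the line's x at the point's y (for
# a mostly north-south line) or y at x (east-west line), extending the end
# segments; returns the coordinate difference
polyline_offset <- function(point, line, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (axis == "x") { s <- line$lat; t <- line$lon; ps <- point[2]; pt <- point[1] }
  else { s <- line$lon; t <- line$lat; ps <- point[1]; pt <- point[2] }
  o <- order(s)
  s <- s[o]; t <- t[o]
  at <- stats::approx(s, t, xout = ps, rule = 2)$y
  pt - at
}

#' Assign a point to one of four quadrant regions
#'
#' Combines the side of a north-south dividing line (west/east) and of an
#' east-west dividing line (north/south) into NE/NW/SE/SW labels. Points
#' exactly on a line are assigned to the east / south side.
#'
#' @param points data.frame with `lon`, `lat`.
#' @param line_we data.frame (`lon`, `lat`) tracing the north-south line
#'   that separates west from east (e.g. the Heihe-Tengchong line).
#' @param line_ns data.frame tracing the east-west line separating north
#'   from south (e.g. the Qinling-Huaihe extension line).
#' @return character vector of `"NE"`, `"NW"`, `"SE"`, `"SW"`.
#' @export
assign_region <- function(points, line_we, line_ns) {
  vapply(seq_len(NROW(points)), function(i) {
    p <- c(points$lon[i], points$lat[i])
    east <- polyline_offset(p, line_we, "x") >= 0
    south <- polyline_offset(p, line_ns, "y") <= 0
    paste0(if (south) "S" else "N", if (east) "E" else "W")
  }, character(1))
}
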