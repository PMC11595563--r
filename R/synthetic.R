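#' Define a synthetic study scenario
#'
#' Bundles every parameter needed to generate a complete synthetic input
#' set — environmental rasters, a true suitability surface, presences, a
#' Yule chronogram and Mk-evolved tip areas — with known ground truth.
#' Geometry is planar km so distances are exact and projection-free.
#'
#' @param seed master seed; all generators derive their streams from it.
#' @param extent numeric `c(x_min, y_min, x_max, y_max)` in km.
#' @param cell_size_km cell size of the environmental grid, km.
#' @param n_layers number of environmental layers (>= 2), named env1..envN.
#' @param collinear_pairs list of `c(i, j, r)` triples: layer j is rebuilt
#'   so that its empirical Pearson correlation with layer i equals r
#'   (|r| >= 0.8 by convention for a deliberately collinear pair).
#' @param true_coefficients named numeric vector, layer name -> coefficient
#'   in the linear predictor of the true suitability surface.
#' @param intercept intercept of the linear predictor.
#' @param trend optional named list, layer name -> `c(dx, dy)`: a linear
#'   spatial trend (per unit of normalised extent) added to that layer's
#'   smooth field, used to anchor suitability in a chosen map corner.
#' @param n_presences number of presence records to sample.
#' @param birth_rate Yule speciation rate, per Myr.
#' @param n_tips number of chronogram tips (>= 3).
#' @param root_age_myr if not `NULL`, the simulated tree is rescaled so its
#'   root age equals this value (Myr).
#' @param mk_rate transition rate of the ER Mk process for tip areas, per Myr.
#' @param n_areas number of areas/states (2..4).
#' @return an object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L,
                               extent = c(0, 0, 1000, 1000),
                               cell_size_km = 20,
                               n_layers = 5L,
                               collinear_pairs = list(),
                               true_coefficients = c(env1 = 2, env2 = -1.5),
                               intercept = -1,
                               trend = NULL,
                               n_presences = 150L,
                               birth_rate = 0.05,
                               n_tips = 40L,
                               root_age_myr = 80,
                               mk_rate = 0.01,
                               n_areas = 4L) {
  if (extent[3] <= extent[1] || extent[4] <= extent[2])
    stop_ps("degenerate extent: x_max/y_max must exceed x_min/y_min")
  if (cell_size_km <= 0) stop_ps("cell_size_km must be positive")
  nc <- floor((extent[3] - extent[1]) / cell_size_km)
  nr <- floor((extent[4] - extent[2]) / cell_size_km)
  if (nr * nc < 100) stop_ps("grid must have at least 100 cells (has %d)", nr * nc)
  if (n_layers < 2) stop_ps("n_layers must be >= 2")
  if (n_tips < 3) stop_ps("n_tips must be >= 3")
  if (birth_rate <= 0) stop_ps("birth_rate must be positive")
  if (!(n_areas %in% 2:4)) stop_ps("n_areas must be in 2..4")
  layer_names <- paste0("env", seq_len(n_layers))
  unknown <- setdiff(names(true_coefficients), layer_names)
  if (length(unknown))
    stop_ps("true_coefficients name layers that do not exist: %s",
            paste(unknown, collapse = ", "))
  for (p in collinear_pairs) {
    if (length(p) != 3 || p[1] < 1 || p[2] < 1 || p[1] > n_layers ||
        p[2] > n_layers || p[1] == p[2])
      stop_ps("collinear pair must be c(i, j, r) with distinct valid layer indices")
  }
  structure(
    list(seed = as.integer(seed), extent = extent, cell_size_km = cell_size_km,
         n_layers = as.integer(n_layers), layer_names = layer_names,
         collinear_pairs = collinear_pairs,
         true_coefficients = true_coefficients, intercept = intercept,
         trend = trend, n_presences = as.integer(n_presences),
         birth_rate = birth_rate, n_tips = as.integer(n_tips),
         root_age_myr = root_age_myr, mk_rate = mk_rate,
         n_areas = as.integer(n_areas), n_rows = nr, n_cols = nc),
    class = "synthetic_scenario"
  )
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("<synthetic_scenario> seed %d, %d x %d cells of %g km, %d layers\n",
              x$seed, x$n_rows, x$n_cols, x$cell_size_km, x$n_layers))
  cat(sprintf("  %d presences, %d tips (Yule rate %g/Myr), %d areas (Mk rate %g/Myr)\n",
              x$n_presences, x$n_tips, x$birth_rate, x$n_areas, x$mk_rate))
  invisible(x)
}

# One smooth spatially autocorrelated field on [0,1]^2 coordinates:
# a mixture of low-frequency cosine waves, standardised to mean 0, sd 1.
smooth_field <- function(nr, nc, n_waves = 8L) {
  xs <- (seq_len(nc) - 0.5) / nc
  ys <- (seq_len(nr) - 0.5) / nr
  f <- matrix(0, nr, nc)
  for (w in seq_len(n_waves)) {
    fx <- stats::runif(1, 0.3, 2.5) * sample(c(-1, 1), 1)
    fy <- stats::runif(1, 0.3, 2.5) * sample(c(-1, 1), 1)
    ph <- stats::runif(1, 0, 2 * pi)
    amp <- stats::rnorm(1)
    f <- f + amp * cos(2 * pi * (outer(ys, xs, function(y, x) fx * x + fy * y)) + ph)
  }
  (f - mean(f)) / stats::sd(f)
}

#' Generate the synthetic environmental raster stack
#'
#' Each layer is a smooth low-frequency field (standardised). For every
#' declared collinear pair `(i, j, r)`, layer j is rebuilt as
#' `r * layer_i + sqrt(1 - r^2) * e`, where `e` is its own field made
#' empirically orthogonal to layer i, so the achieved sample correlation
#' equals the target exactly (up to floating point).
#'
#' @param scenario a [synthetic_scenario()].
#' @return a [raster_stack()] with `scenario$n_layers` layers.
#' @export
gen_env_stack <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  seeds <- derive_seeds(scenario$seed, 2L)
  set.seed(seeds[1])
  nr <- scenario$n_rows; nc <- scenario$n_cols
  tr <- c(scenario$extent[1], scenario$extent[2],
          scenario$cell_size_km, scenario$cell_size_km)
  fields <- lapply(seq_len(scenario$n_layers), function(i) smooth_field(nr, nc))
  # linear trend components anchor suitability in a chosen corner
  if (!is.null(scenario$trend)) {
    xs <- (seq_len(nc) - 0.5) / nc
    ys <- rev((seq_len(nr) - 0.5) / nr)   # row 1 = top (largest y)
    for (nm in names(scenario$trend)) {
      i <- match(nm, scenario$layer_names)
      d <- scenario$trend[[nm]]
      g <- outer(ys, xs, function(y, x) d[1] * x + d[2] * y)
      f <- fields[[i]] + g
      fields[[i]] <- (f - mean(f)) / stats::sd(f)
    }
  }
  for (p in scenario$collinear_pairs) {
    i <- p[1]; j <- p[2]; r <- p[3]
    a <- as.vector(fields[[i]])
    e <- as.vector(fields[[j]])
    e <- stats::residuals(stats::lm(e ~ a))        # empirically orthogonal to a
    e <- (e - mean(e)) / stats::sd(e)
    z <- r * (a - mean(a)) / stats::sd(a) + sqrt(1 - r^2) * e
    fields[[j]] <- matrix((z - mean(z)) / stats::sd(z), nr, nc)
  }
  layers <- mapply(function(f, nm) raster_layer(f, tr, name = nm),
                   fields, scenario$layer_names, SIMPLIFY = FALSE)
  raster_stack(layers)
}

#' True suitability surface from known coefficients
#'
#' Per cell, `logistic(intercept + sum(coef * layer))`; nodata propagates.
#'
#' @param stack a [raster_stack()].
#' @param coefficients named numeric vector (names must be stack layers).
#' @param intercept intercept of the linear predictor.
#' @return a [raster_layer()] with values in (0, 1).
#' @export
gen_true_suitability <- function(stack, coefficients, intercept = 0) {
  unknown <- setdiff(names(coefficients), names(stack$layers))
  if (length(unknown))
    stop_ps("unknown layer name(s): %s", paste(unknown, collapse = ", "))
  ref <- stack$layers[[1]]
  lp <- matrix(intercept, nrow(ref$values), ncol(ref$values))
  mask <- ref$nodata_mask
  for (nm in names(coefficients)) {
    l <- stack$layers[[nm]]
    lp <- lp + coefficients[[nm]] * l$values
    mask <- mask | l$nodata_mask
  }
  v <- logistic(lp)
  v[mask] <- NA_real_
  raster_layer(v, ref$transform, name = "true_suitability",
               nodata_mask = mask, crs_tag = ref$crs_tag)
}

#' Sample presence records from a suitability surface
#'
#' Cells are drawn (with replacement) with probability proportional to
#' suitability; each record is placed at its cell's centre.
#'
#' @param suitability a [raster_layer()] with non-negative values.
#' @param n number of records.
#' @param seed RNG seed.
#' @param species species label(s): recycled to length `n`.
#' @return data.frame with columns `species`, `lon` (x), `lat` (y),
#'   `record_id`.
#' @export
sample_presences <- function(suitability, n, seed, species = "sp") {
  stopifnot(n >= 1)
  w <- suitability$values
  w[suitability$nodata_mask] <- 0
  w[is.na(w)] <- 0
  if (all(w == 0)) stop_ps("all-zero suitability: nothing to sample from")
  if (n_valid_cells(suitability) < n)
    stop_ps("fewer valid cells than requested records")
  cc <- cell_centers(suitability)
  set.seed(seed)
  idx <- sample.int(length(w), n, replace = TRUE, prob = as.vector(w))
  data.frame(
    species = rep_len(species, n),
    lon = cc$x[idx], lat = cc$y[idx],
    record_id = sprintf("rec%04d", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a Yule (pure-birth) chronogram
#'
#' Constructive simulation: starting from two lineages at the root, waiting
#' times between speciation events are exponential with rate
#' `birth_rate * k` (k = current lineage count) and the splitting lineage
#' is chosen uniformly. After the n-th tip appears a final exponential
#' waiting time is added so terminal branches are positive. The tree is
#' ultrametric by construction, tips are labelled sp1..spN.
#'
#' @param n_tips number of tips (>= 3).
#' @param birth_rate speciation rate per Myr.
#' @param seed RNG seed.
#' @return an [ape::phylo] rooted binary ultrametric tree.
#' @export
sim_yule_tree <- function(n_tips, birth_rate, seed) {
  if (n_tips < 3) stop_ps("n_tips must be >= 3")
  if (birth_rate <= 0) stop_ps("birth_rate must be positive")
  set.seed(seed)
  # active lineages carry their birth time; node ids assigned at the end
  birth <- c(0, 0)            # birth time of each active lineage
  parent_split <- c(1L, 1L)   # index of the split event that created it
  split_time <- numeric(0)    # time of each split event
  split_children <- list()    # children (lineage or later split) per event
  split_time[1] <- 0
  split_children[[1]] <- c(-1L, -2L)  # negative = active lineage index
  n_splits <- 1L
  t <- 0
  while (length(birth) < n_tips) {
    k <- length(birth)
    t <- t + stats::rexp(1, rate = birth_rate * k)
    pick <- sample.int(k, 1)
    n_splits <- n_splits + 1L
    split_time[n_splits] <- t
    # the picked lineage ends at this split; two new lineages start
    ev <- parent_split[pick]
    split_children[[ev]][split_children[[ev]] == -pick] <- n_splits
    # renumber: replace lineage `pick` and append one
    birth[pick] <- t
    parent_split[pick] <- n_splits
    birth <- c(birth, t)
    parent_split <- c(parent_split, n_splits)
    split_children[[n_splits]] <- c(-pick, -length(birth))
  }
  t_end <- t + stats::rexp(1, rate = birth_rate * n_tips)

  # assemble ape edge matrix: tips 1..n, internal nodes n+1..2n-1 with the
  # root = n+1 (split event 1); internal node id per split event
  node_id <- n_tips + seq_len(n_splits)
  edge <- matrix(0L, 2L * n_tips - 2L, 2L)
  elen <- numeric(2L * n_tips - 2L)
  ei <- 0L
  for (ev in seq_len(n_splits)) {
    for (ch in split_children[[ev]]) {
      ei <- ei + 1L
      edge[ei, 1] <- node_id[ev]
      if (ch < 0) {         # terminal lineage -> tip
        lin <- -ch
        edge[ei, 2] <- lin
        elen[ei] <- t_end - birth[lin]
      } else {
        edge[ei, 2] <- node_id[ch]
        elen[ei] <- split_time[ch] - split_time[ev]
      }
    }
  }
  tree <- structure(
    list(edge = edge, edge.length = elen,
         tip.label = paste0("sp", seq_len(n_tips)),
         Nnode = n_tips - 1L),
    class = "phylo", order = "cladewise"
  )
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}

#' Simulate tip states under an equal-rates Mk process
#'
#' The root state is uniform over states; along each branch of length t the
#' ER chain's transition probabilities have the closed form
#' `P(stay) = 1/k + (k-1)/k * exp(-k q t)` and
#' `P(move to a given other state) = 1/k - 1/k * exp(-k q t)`,
#' sampled exactly (no event simulation).
#'
#' @param tree an ultrametric [ape::phylo].
#' @param n_states number of states k (>= 2).
#' @param rate ER transition rate q (per Myr, per off-diagonal entry).
#' @param seed RNG seed.
#' @param state_labels optional labels (default `"A1".."Ak"`).
#' @param root_state optional fixed root state (index or label); default the
#'   root state is uniform.
#' @return named character vector: tip label -> state label.
#' @export
sim_mk_tip_states <- function(tree, n_states, rate, seed,
                              state_labels = NULL, root_state = NULL) {
  if (n_states < 2) stop_ps("n_states must be >= 2")
  if (rate < 0) stop_ps("rate must be >= 0")
  if (is.null(state_labels)) state_labels <- paste0("A", seq_len(n_states))
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  state <- integer(n_node)
  root <- n_tip + 1L
  if (is.null(root_state)) {
    state[root] <- sample.int(n_states, 1)
  } else {
    if (is.character(root_state)) root_state <- match(root_state, state_labels)
    if (is.na(root_state) || root_state < 1 || root_state > n_states)
      stop_ps("invalid root_state")
    state[root] <- as.integer(root_state)
  }
  # preorder: ape cladewise edge order guarantees parents precede children
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
    t <- ord$edge.length[e]
    decay <- exp(-n_states * rate * t)
    p_stay <- 1 / n_states + (n_states - 1) / n_states * decay
    if (stats::runif(1) <= p_stay) {
      state[ch] <- state[par]
    } else {
      others <- setdiff(seq_len(n_states), state[par])
      state[ch] <- if (length(others) == 1L) others else sample(others, 1)
    }
  }
  stats::setNames(state_labels[state[seq_len(n_tip)]], tree$tip.label)
}

#' Write all synthetic inputs of a scenario to a directory
#'
#' Emits the environmental layers as ESRI ASCII grids, the true suitability
#' surface, occurrences as CSV, the chronogram as Newick and tip areas as a
#' 2-column TSV.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory (created if missing).
#' @return (invisibly) a list with the generated objects and file paths.
#' @export
write_scenario_inputs <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(scenario$seed, 6L)
  stack <- gen_env_stack(scenario)
  truth <- gen_true_suitability(stack, scenario$true_coefficients,
                                scenario$intercept)
  occ <- sample_presences(truth, scenario$n_presences, seeds[2])
  tree <- sim_yule_tree(scenario$n_tips, scenario$birth_rate, seeds[3])
  if (!is.null(scenario$root_age_myr)) {
    h <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * scenario$root_age_myr / h
  }
  areas <- sim_mk_tip_states(tree, scenario$n_areas, scenario$mk_rate,
                             seeds[4],
                             state_labels = c("SE", "SW", "NE", "NW")[seq_len(scenario$n_areas)])
  paths <- list()
  for (nm in names(stack$layers)) {
    paths[[nm]] <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(stack$layers[[nm]], paths[[nm]])
  }
  paths$truth <- file.path(dir, "true_suitability.asc")
  write_ascii_grid(truth, paths$truth)
  paths$occurrences <- file.path(dir, "occurrences.csv")
  utils::write.csv(occ, paths$occurrences, row.names = FALSE)
  paths$tree <- file.path(dir, "chronogram.nwk")
  ape::write.tree(tree, paths$tree)
  paths$tip_areas <- file.path(dir, "tip_areas.tsv")
  utils::write.table(data.frame(tip = names(areas), area = unname(areas)),
                     paths$tip_areas, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(list(stack = stack, truth = truth, occurrences = occ,
                 tree = tree, tip_areas = areas, paths = paths))
}
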