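test_that("grids anchor at the floored bounding box with half-open cells", {
  single <- build_grid(data.frame(lon = 123, lat = 456), 100)
  expect_equal(c(single$n_rows, single$n_cols), c(1L, 1L))
  rc <- grid_cell_of(single, data.frame(lon = 123, lat = 456))
  expect_equal(c(rc$row, rc$col), c(1L, 1L))

  span <- build_grid(data.frame(lon = c(10, 260), lat = c(5, 155)), 100)
  expect_equal(c(span$n_rows, span$n_cols), c(2L, 3L))

  set.seed(3)
  pts <- data.frame(lon = runif(100, -50, 300), lat = runif(100, -20, 220))
  g <- build_grid(pts, 100)
  rc <- grid_cell_of(g, pts)
  expect_true(all(rc$row >= 1 & rc$row <= g$n_rows))
  expect_true(all(rc$col >= 1 & rc$col <= g$n_cols))
})

test_that("cell MDT deduplicates species and averages their stem ages", {
  tab <- data.frame(species = c("a", "b"), stem_age = c(10, 30))
  occ <- data.frame(species = c("a", "b", "a", "a", "a", "a"),
                    lon = c(50, 50, 50, 50, 50, 50),
                    lat = c(50, 50, 50, 50, 50, 50))
  g <- build_grid(occ, 100)
  cells <- cell_mdt(g, occ, tab)
  expect_equal(nrow(cells), 1)
  expect_equal(cells$mdt, 20)
  expect_equal(cells$n_species, 2)
  expect_error(cell_mdt(g, data.frame(species = "zz", lon = 1, lat = 1), tab),
               "missing")
  # every record lands in exactly one cell; species unions are conserved
  set.seed(8)
  occ2 <- data.frame(species = sample(c("a", "b"), 50, TRUE),
                     lon = runif(50, 0, 500), lat = runif(50, 0, 500))
  g2 <- build_grid(occ2, 100)
  cells2 <- cell_mdt(g2, occ2, tab)
  expect_gte(sum(cells2$n_species), length(unique(occ2$species)))
  expect_lte(sum(cells2$n_species), nrow(occ2))
})

test_that("MDT classification separates planted clusters monotonically", {
  mdts <- c(5, 6, 7, 40, 41, 42, 80, 81, 82, 120, 121, 122)
  cells <- data.frame(row = 1, col = seq_along(mdts), mdt = mdts)
  out <- classify_mdt(cells, k = 4)
  expect_equal(out$mdt_class, rep(1:4, each = 3))
  b <- attr(out, "breaks")
  expect_true(b[1] >= 7 && b[1] < 40)
  expect_true(b[2] >= 42 && b[2] < 80)
  expect_true(b[3] >= 82 && b[3] < 120)
  # monotone in MDT
  expect_true(all(diff(out$mdt_class[order(out$mdt)]) >= 0))
  same <- data.frame(row = 1, col = 1:5, mdt = rep(3, 5))
  expect_error(classify_mdt(same, k = 4), "distinct")
})

test_that("cell suitability is the mean over covered raster cells", {
  suit <- raster_layer(matrix(0.9, 10, 10), c(0, 0, 10, 10))
  cl <- classify_suitability(suit, breaks = c(0.18, 0.45, 0.68))
  occ <- data.frame(species = "a", lon = c(25, 75), lat = c(25, 75))
  tab <- data.frame(species = "a", stem_age = 12)
  g <- build_grid(occ, 100)
  cells <- cell_mdt(g, occ, tab)
  cells <- attach_suitability(cells, g, cl, suit)
  expect_true(all(cells$suitability_value == 0.9))
  expect_true(all(cells$suitability_class == 4))

  # half 0.1 / half 0.9 -> mean 0.5 -> class 3 under the same breaks
  v <- matrix(0.1, 10, 10); v[, 6:10] <- 0.9
  mixed <- raster_layer(v, c(0, 0, 10, 10))
  cells2 <- attach_suitability(cell_mdt(g, occ[1, ], tab), g, cl, mixed)
  expect_equal(cells2$suitability_value, 0.5)
  expect_equal(cells2$suitability_class, 3)
})

test_that("Kruskal-Wallis matches the textbook example and invariances", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(10, 11, 12)), permutation_p = "exact")
  expect_equal(kw$H, 3.8571, tolerance = 1e-4)
  expect_equal(kw$p_permutation, 0.1)
  oracle <- kw_exact_oracle(list(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(kw$H, oracle$H, tolerance = 1e-12)
  expect_equal(oracle$n_assignments, 20)

  same <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)

  # rank-based: invariant under common monotone transforms
  g1 <- list(c(1, 5, 9), c(2, 3, 12), c(4, 6, 7))
  g2 <- lapply(g1, function(v) exp(v / 3))
  expect_equal(kruskal_wallis(g1)$H, kruskal_wallis(g2)$H, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(c(1, 2))), "2 non-empty groups")
})

test_that("Dunn-Holm post hoc reduces to the rank test for two groups", {
  groups <- list(a = c(1, 3, 5, 7), b = c(6, 8, 10, 12))
  ph <- pairwise_posthoc(groups)
  kw <- kruskal_wallis(groups)
  # one comparison: z^2 = H, so the normal p equals the chi-square p
  expect_equal(ph$p_raw, ph$p_adjusted)
  expect_equal(ph$z^2, kw$H, tolerance = 1e-10)
  expect_equal(ph$p_raw, kw$p_value, tolerance = 1e-10)

  g3 <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(30, 40, 50))
  ph3 <- pairwise_posthoc(g3)
  expect_true(all(ph3$p_adjusted >= ph3$p_raw - 1e-15))
  expect_equal(nrow(ph3), 3)
})

test_that("quadrant regions combine the two dividing lines", {
  line_we <- data.frame(lon = c(500, 500), lat = c(-10, 1010))   # N-S line
  line_ns <- data.frame(lon = c(-10, 1010), lat = c(500, 500))   # E-W line
  pts <- data.frame(lon = c(100, 900, 100, 900), lat = c(900, 900, 100, 100))
  expect_equal(assign_region(pts, line_we, line_ns),
               c("NW", "NE", "SW", "SE"))
  # ties go to the east/south side
  on_line <- data.frame(lon = 500, lat = 500)
  expect_equal(assign_region(on_line, line_we, line_ns), "SE")
  # every point gets exactly one label
  set.seed(5)
  rand <- data.frame(lon = runif(50, 0, 1000), lat = runif(50, 0, 1000))
  labs <- assign_region(rand, line_we, line_ns)
  expect_true(all(labs %in% c("NE", "NW", "SE", "SW")))
  # a slanted polyline is invariant to densification
  slant <- data.frame(lon = c(300, 700), lat = c(-10, 1010))
  dense_idx <- seq(0, 1, length.out = 41)
  slant_dense <- data.frame(lon = 300 + 400 * dense_idx,
                            lat = -10 + 1020 * dense_idx)
  expect_equal(assign_region(rand, slant, line_ns),
               assign_region(rand, slant_dense, line_ns))
})
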