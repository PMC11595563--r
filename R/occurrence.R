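#' Great-circle distance between two points (haversine)
#'
#' Haversine formula on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius).
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised).
#' @return distance(s) in km.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop_ps("coordinates out of range: lat in [-90,90], lon in [-180,180]")
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

point_dist_km <- function(lat1, lon1, lat2, lon2, geographic) {
  if (geographic) great_circle_km(lat1, lon1, lat2, lon2)
  else sqrt((lat2 - lat1)^2 + (lon2 - lon1)^2)
}

#' Spatially thin occurrence records
#'
#' Records closer than `radius_km` to an already retained record are treated
#' as replicates and dropped. The scan is greedy in input order (stable and
#' deterministic); pass `seed` to randomise the scan order instead.
#'
#' @param records data.frame with columns `species`, `lat`, `lon` (planar:
#'   `lat` = y km, `lon` = x km).
#' @param radius_km thinning radius; records at distance <= `radius_km` of a
#'   retained record are dropped.
#' @param geographic if `TRUE` distances are haversine km on WGS84-style
#'   coordinates; if `FALSE`, Euclidean on planar km.
#' @param per_species if `TRUE`, thinning is applied within each species
#'   separately; default pools all species.
#' @param seed optional seed to randomise scan order.
#' @return list with data.frames `retained` and `dropped` (the latter with a
#'   `near_record` column naming the retained record it duplicates).
#' @export
thin_occurrences <- function(records, radius_km = 10, geographic = TRUE,
                             per_species = FALSE, seed = NULL) {
  if (NROW(records) < 1) stop_ps("no occurrence records supplied")
  if (per_species) {
    parts <- split(seq_len(nrow(records)), records$species)
    res <- lapply(parts, function(ix)
      thin_occurrences(records[ix, , drop = FALSE], radius_km, geographic,
                       per_species = FALSE, seed = seed))
    return(list(
      retained = do.call(rbind, c(lapply(res, `[[`, "retained"),
                                  make.row.names = FALSE)),
      dropped = do.call(rbind, c(lapply(res, `[[`, "dropped"),
                                 make.row.names = FALSE))
    ))
  }
  ord <- seq_len(nrow(records))
  if (!is.null(seed)) { set.seed(seed); ord <- sample(ord) }
  kept <- integer(0)
  near <- character(0)
  dropped <- integer(0)
  for (i in ord) {
    if (length(kept) == 0L) { kept <- i; next }
    d <- point_dist_km(records$lat[kept], records$lon[kept],
                       records$lat[i], records$lon[i], geographic)
    if (all(d > radius_km)) {
      kept <- c(kept, i)
    } else {
      dropped <- c(dropped, i)
      j <- kept[which.min(d)]
      near <- c(near, if (!is.null(records$record_id)) records$record_id[j]
                      else as.character(j))
    }
  }
  ret <- records[kept, , drop = FALSE]
  drp <- records[dropped, , drop = FALSE]
  if (nrow(drp)) drp$near_record <- near
  rownames(ret) <- NULL; rownames(drp) <- NULL
  list(retained = ret, dropped = drp)
}

#' Filter collinear environmental layers
#'
#' Layers are visited in priority order; a layer is kept only if its
#' absolute Pearson correlation with every already kept layer is at most
#' `threshold`, so the kept set never contains a pair with |r| > threshold.
#'
#' @param stack a [raster_stack()].
#' @param threshold collinearity cutoff on |r| (default 0.8).
#' @param priority `"input-order"` (default), a character vector of layer
#'   names ordered most- to least-preferred, or `"random"` (with `seed`) for
#'   literal random retention.
#' @param seed seed used when `priority = "random"`.
#' @return list with `kept` (layer names), `dropped` (data.frame: dropped
#'   layer, the kept partner it correlated with, and r), and `cor_matrix`.
#' @export
collinearity_filter <- function(stack, threshold = 0.8,
                                priority = "input-order", seed = NULL) {
  nms <- names(stack$layers)
  if (length(nms) < 2) stop_ps("need at least 2 layers")
  ord <- if (identical(priority, "input-order")) {
    nms
  } else if (identical(priority, "random")) {
    if (!is.null(seed)) set.seed(seed)
    sample(nms)
  } else {
    if (!all(nms %in% priority)) stop_ps("priority must order all layer names")
    priority[priority %in% nms]
  }
  k <- length(nms)
  cm <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  diag(cm) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    cm[i, j] <- cm[j, i] <- pearson_r(stack$layers[[i]], stack$layers[[j]])
  kept <- character(0)
  dropped <- data.frame(dropped = character(0), kept_partner = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  for (nm in ord) {
    if (length(kept) == 0L) { kept <- nm; next }
    rs <- cm[nm, kept]
    if (all(abs(rs) <= threshold)) {
      kept <- c(kept, nm)
    } else {
      worst <- which.max(abs(rs))
      dropped <- rbind(dropped, data.frame(
        dropped = nm, kept_partner = kept[worst], r = rs[worst],
        stringsAsFactors = FALSE))
    }
  }
  # keep input order in the result for readability
  kept <- nms[nms %in% kept]
  list(kept = kept, dropped = dropped, cor_matrix = cm)
}

#' Read occurrence records from CSV
#'
#' Expects a header `species,lat,lon[,record_id]` (column order free).
#'
#' @param path CSV file path.
#' @param geographic validate coordinates as lat/lon degrees.
#' @return data.frame of occurrence records.
#' @export
read_occurrences <- function(path, geographic = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lat", "lon")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_ps("missing column(s): %s", paste(miss, collapse = ", "))
  if (any(!nzchar(df$species))) stop_ps("empty species labels")
  if (geographic && (any(abs(df$lat) > 90) || any(abs(df$lon) > 180)))
    stop_ps("coordinates out of range for geographic mode")
  if (is.null(df$record_id)) df$record_id <- sprintf("rec%04d", seq_len(nrow(df)))
  df
}
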