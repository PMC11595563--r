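node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth          # 0 at the deepest tips, root = tree height
}

#' Read a time-calibrated tree
#'
#' Reads Newick or NEXUS, checks the tree is rooted, binary, has unique tip
#' labels and is ultrametric (all tip depths equal within a relative
#' tolerance of the root age).
#'
#' @param path tree file path.
#' @param format `"newick"` or `"nexus"`.
#' @param allow_nonultrametric skip the ultrametricity check.
#' @param tol relative ultrametricity tolerance (default 1e-6 of root age).
#' @return an [ape::phylo] object.
#' @export
read_timetree <- function(path, format = c("newick", "nexus"),
                          allow_nonultrametric = FALSE, tol = 1e-6) {
  format <- match.arg(format)
  tree <- if (format == "newick") ape::read.tree(path) else ape::read.nexus(path)
  if (is.null(tree)) stop_ps("could not parse tree file '%s'", path)
  validate_timetree(tree, allow_nonultrametric = allow_nonultrametric, tol = tol)
  tree
}

#' Validate a chronogram
#'
#' @param tree an [ape::phylo].
#' @param allow_nonultrametric skip the ultrametricity check.
#' @param tol relative ultrametricity tolerance.
#' @return the tree, invisibly; errors describe the violated property.
#' @export
validate_timetree <- function(tree, allow_nonultrametric = FALSE, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop_ps("not a phylo object")
  if (anyDuplicated(tree$tip.label)) stop_ps("duplicate tip labels")
  if (!ape::is.rooted(tree)) stop_ps("tree must be rooted")
  if (is.null(tree$edge.length)) stop_ps("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop_ps("negative branch lengths")
  if (!allow_nonultrametric) {
    depth <- ape::node.depth.edgelength(tree)
    tips <- seq_along(tree$tip.label)
    h <- max(depth[tips])
    if (h <= 0 || max(abs(depth[tips] - h)) > tol * h)
      stop_ps("tree is not ultrametric (max tip-depth spread %.3g vs tolerance %.3g)",
              max(abs(depth[tips] - h)), tol * h)
  }
  invisible(tree)
}

#' Stem age of a tip
#'
#' The age (Myr before present, tips at 0) of the node where the tip's
#' terminal branch attaches — for an ultrametric tree this equals the
#' terminal branch length.
#'
#' @param tree an ultrametric [ape::phylo].
#' @param tip tip label(s).
#' @return numeric stem age(s) in the tree's time units.
#' @export
stem_age <- function(tree, tip) {
  idx <- match(tip, tree$tip.label)
  if (anyNA(idx))
    stop_ps("unknown tip(s): %s", paste(tip[is.na(idx)], collapse = ", "))
  ages <- node_ages(tree)
  parent <- tree$edge[match(idx, tree$edge[, 2]), 1]
  unname(ages[parent])
}

#' Stem age of a clade
#'
#' Age of the parent of the most recent common ancestor of `tip_set`. The
#' set must be monophyletic; the root clade (all tips) has no stem.
#'
#' @param tree an ultrametric [ape::phylo].
#' @param tip_set character vector of tip labels.
#' @return stem age in Myr.
#' @export
clade_stem_age <- function(tree, tip_set) {
  if (length(tip_set) == 0) stop_ps("tip_set must be non-empty")
  idx <- match(tip_set, tree$tip.label)
  if (anyNA(idx))
    stop_ps("unknown tip(s): %s", paste(tip_set[is.na(idx)], collapse = ", "))
  if (length(idx) == length(tree$tip.label))
    stop_ps("root clade: the clade of all tips has no stem")
  mrca <- if (length(idx) == 1L) idx else ape::getMRCA(tree, idx)
  desc <- if (length(idx) == 1L) idx else
    which(seq_along(tree$tip.label) %in% phangorn_descendants(tree, mrca))
  clade_tips <- tree$tip.label[desc]
  extra <- setdiff(clade_tips, tip_set)
  if (length(extra))
    stop_ps("tip_set is not monophyletic; its MRCA also contains: %s",
            paste(extra, collapse = ", "))
  parent <- tree$edge[match(mrca, tree$edge[, 2]), 1]
  if (is.na(parent)) stop_ps("root clade: the clade of all tips has no stem")
  unname(node_ages(tree)[parent])
}

# tip indices descending from an internal node (simple edge-walk; avoids a
# phangorn dependency for one call)
phangorn_descendants <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  todo <- node
  tips <- integer(0)
  while (length(todo)) {
    cur <- todo[1]; todo <- todo[-1]
    ch <- tree$edge[tree$edge[, 1] == cur, 2]
    tips <- c(tips, ch[ch <= n_tip])
    todo <- c(todo, ch[ch > n_tip])
  }
  tips
}

#' Stem-age table for all species on a tree
#'
#' When a species has several collections (tips) on the tree, its stem age
#' is the stem age of the MRCA of its tips (configurable to the first tip).
#'
#' @param tree an ultrametric [ape::phylo].
#' @param species_map optional named character vector tip label -> species;
#'   by default each tip is its own species.
#' @param multi_tip `"mrca"` (default) or `"first"`.
#' @return data.frame with columns `species`, `stem_age`.
#' @export
stem_age_table <- function(tree, species_map = NULL,
                           multi_tip = c("mrca", "first")) {
  multi_tip <- match.arg(multi_tip)
  if (is.null(species_map))
    species_map <- stats::setNames(tree$tip.label, tree$tip.label)
  species <- unique(unname(species_map))
  age <- vapply(species, function(sp) {
    tips <- names(species_map)[species_map == sp]
    if (length(tips) == 1L || multi_tip == "first") stem_age(tree, tips[1])
    else clade_stem_age(tree, tips)
  }, numeric(1))
  data.frame(species = species, stem_age = unname(age),
             stringsAsFactors = FALSE)
}

#' Mean divergence time of a species set
#'
#' Arithmetic mean of the stem ages of the (deduplicated) species.
#'
#' @param species_set character vector of species names.
#' @param table a stem-age table from [stem_age_table()].
#' @return mean stem age, Myr.
#' @export
mean_divergence_time <- function(species_set, table) {
  if (length(species_set) == 0) stop_ps("species_set must be non-empty")
  species_set <- unique(species_set)
  miss <- setdiff(species_set, table$species)
  if (length(miss))
    stop_ps("species missing from stem-age table: %s", paste(miss, collapse = ", "))
  mean(table$stem_age[match(species_set, table$species)])
}

#' Lineage-through-time counts
#'
#' Step function of the number of lineages from the root (age = root age,
#' count 2 for a rooted tree) to the present (age 0, count = tip count).
#'
#' @param tree an ultrametric [ape::phylo].
#' @return data.frame with columns `age` (Myr, descending) and `lineages`
#'   (count on the interval from that age to the next row's age).
#' @export
ltt <- function(tree) {
  validate_timetree(tree)
  ages <- node_ages(tree)
  n_tip <- length(tree$tip.label)
  internal_ages <- sort(ages[(n_tip + 1L):(n_tip + tree$Nnode)],
                        decreasing = TRUE)
  # at the root 2 lineages; each later internal node adds one
  data.frame(age = c(internal_ages, 0),
             lineages = c(seq_along(internal_ages) + 1L, n_tip))
}

#' Number of lineages extant at a given age
#'
#' @param tree an ultrametric [ape::phylo].
#' @param age age in Myr before present (0 = tips).
#' @return integer lineage count crossing that age.
#' @export
lineages_at <- function(tree, age) {
  ages <- node_ages(tree)
  parent_age <- ages[tree$edge[, 1]]
  child_age <- ages[tree$edge[, 2]]
  vapply(age, function(a) sum(parent_age > a & child_age <= a), numeric(1))
}
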