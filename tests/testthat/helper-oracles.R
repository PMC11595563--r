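# Independent brute-force oracles used to validate the package's
# implementations on small inputs. These deliberately share no code with
# the implementation paths they check.

# --- Mk likelihood by enumeration over all internal-node assignments ------

expm_oracle <- function(Q, t) as.matrix(Matrix::expm(Q * t))

# joint probability of one full assignment of states to all nodes
mk_joint_prob <- function(tree, node_states, Q) {
  k <- nrow(Q)
  p <- 1 / k   # uniform root prior
  for (e in seq_len(nrow(tree$edge))) {
    a <- node_states[tree$edge[e, 1]]
    b <- node_states[tree$edge[e, 2]]
    p <- p * expm_oracle(Q, tree$edge.length[e])[a, b]
  }
  p
}

# likelihood by summing over every internal-node state combination;
# tip states may be ambiguity sets (list of allowed state indices)
mk_brute <- function(tree, tip_state_sets, Q) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  k <- nrow(Q)
  total <- 0
  node_marg <- matrix(0, n_tip + n_int, k)
  int_grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n_int)))
  tip_grid <- as.matrix(expand.grid(tip_state_sets))
  for (ti in seq_len(nrow(tip_grid))) {
    for (ii in seq_len(nrow(int_grid))) {
      states <- c(tip_grid[ti, ], int_grid[ii, ])
      p <- mk_joint_prob(tree, states, Q)
      total <- total + p
      for (v in seq_along(states))
        node_marg[v, states[v]] <- node_marg[v, states[v]] + p
    }
  }
  list(lik = total, marginals = node_marg / total)
}

# --- exact Jenks by enumerating all contiguous partitions -----------------

ssd_of <- function(v) sum((v - mean(v))^2)

jenks_brute_ssd <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (ci in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, ci], n)
    tot <- 0
    for (m in seq_len(k))
      tot <- tot + ssd_of(x[(bounds[m] + 1):bounds[m + 1]])
    if (tot < best) best <- tot
  }
  best
}

# total within-class SSD achieved by a set of breaks under (lower, upper]
ssd_of_breaks <- function(values, breaks) {
  cls <- findInterval(values, breaks, left.open = TRUE) + 1L
  sum(vapply(split(values, cls), ssd_of, numeric(1)))
}

# --- AUC by pair counting -------------------------------------------------

auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# --- Kruskal-Wallis H and exact permutation p by direct rank arithmetic ---

kw_h_oracle <- function(values, group) {
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, group, function(g) sum(g)^2 / length(g))) - 3 * (n + 1)
  tie <- table(values)
  c_t <- 1 - sum(tie^3 - tie) / (n^3 - n)
  if (c_t > 0) h / c_t else 0
}

# enumerate every distinct assignment of the pooled values to groups of the
# given sizes (recursive set partitioning, independent of the package)
kw_exact_oracle <- function(groups) {
  values <- unlist(groups)
  sizes <- lengths(groups)
  n <- length(values)
  h_obs <- kw_h_oracle(values, rep(seq_along(sizes), sizes))
  hs <- c()
  recurse <- function(avail, gidx, assignment) {
    if (gidx == length(sizes)) {
      assignment[avail] <- gidx
      hs <<- c(hs, kw_h_oracle(values, assignment))
      return(invisible())
    }
    combs <- utils::combn(avail, sizes[gidx])
    for (ci in seq_len(ncol(combs))) {
      pick <- combs[, ci]
      a2 <- assignment; a2[pick] <- gidx
      recurse(setdiff(avail, pick), gidx + 1L, a2)
    }
  }
  recurse(seq_len(n), 1L, integer(n))
  list(H = h_obs, p = mean(hs >= h_obs - 1e-12), n_assignments = length(hs))
}

# --- tiny tree builders ---------------------------------------------------

tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

random_ultra_tree <- function(n_tips, seed) {
  tr <- sim_yule_tree(max(3, n_tips), 1, seed)
  tr
}
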