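#' Build an Mk rate matrix
#'
#' Constructs the k x k generator Q for a continuous-time Markov chain on
#' discrete states under one of three parameterisations: ER (one rate for
#' every transition), SYM (one rate per unordered state pair) or ARD (one
#' rate per ordered pair). Rows sum to zero.
#'
#' @param k number of states.
#' @param parameterization `"ER"`, `"SYM"` or `"ARD"`.
#' @param rates numeric vector of length 1 (ER), `k(k-1)/2` (SYM) or
#'   `k(k-1)` (ARD); SYM/ARD rates fill the off-diagonal column-by-column
#'   (upper triangle mirrored for SYM).
#' @param state_labels optional state names.
#' @return object of class `mk_model`: `k`, `parameterization`, `rates`,
#'   `Q`, `state_labels`.
#' @export
mk_model <- function(k, parameterization = c("ER", "SYM", "ARD"), rates,
                     state_labels = NULL) {
  parameterization <- match.arg(parameterization)
  k <- as.integer(k)
  n_par <- switch(parameterization, ER = 1L, SYM = (k * (k - 1L)) %/% 2L,
                  ARD = k * (k - 1L))
  if (length(rates) != n_par)
    stop_ps("%s with k=%d needs %d rate(s), got %d", parameterization, k,
            n_par, length(rates))
  if (any(rates < 0)) stop_ps("rates must be non-negative")
  Q <- matrix(0, k, k)
  if (parameterization == "ER") {
    Q[] <- rates[1]
  } else if (parameterization == "SYM") {
    Q[upper.tri(Q)] <- rates
    Q[lower.tri(Q)] <- t(Q)[lower.tri(Q)]
  } else {
    off <- which(row(Q) != col(Q))
    Q[off] <- rates
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  if (is.null(state_labels)) state_labels <- paste0("S", seq_len(k))
  dimnames(Q) <- list(state_labels, state_labels)
  structure(list(k = k, parameterization = parameterization,
                 rates = rates, Q = Q, state_labels = state_labels),
            class = "mk_model")
}

#' @export
print.mk_model <- function(x, ...) {
  cat(sprintf("<mk_model> %s, k = %d, rates: %s\n", x$parameterization, x$k,
              paste(signif(x$rates, 4), collapse = ", ")))
  invisible(x)
}

# factory for P(t) = exp(Qt): ER has a closed form; otherwise the
# eigendecomposition of Q is done once and reused for every branch, with a
# scaling-and-squaring (Matrix::expm) fallback for defective Q
mk_transition_fun <- function(model) {
  k <- model$k
  if (model$parameterization == "ER") {
    q <- model$rates[1]
    return(function(t) {
      decay <- exp(-k * q * t)
      P <- matrix((1 - decay) / k, k, k)
      diag(P) <- 1 / k + (k - 1) / k * decay
      P
    })
  }
  e <- eigen(model$Q)
  usable <- all(abs(Im(e$values)) < 1e-12) &&
    abs(det(Re(e$vectors))) > 1e-10
  if (usable) {
    V <- Re(e$vectors); Vinv <- solve(V); lam <- Re(e$values)
    function(t) {
      P <- V %*% (exp(lam * t) * Vinv)
      P[P < 0] <- 0
      P / rowSums(P)
    }
  } else {
    function(t) {
      P <- as.matrix(Matrix::expm(model$Q * t))
      P[P < 0] <- 0
      P / rowSums(P)
    }
  }
}

mk_prob <- function(model, t) mk_transition_fun(model)(t)

# tip likelihood matrix: rows = tips, cols = states; ambiguity sets put 1 on
# every member state ("SE|SW" style labels)
tip_likelihoods <- function(tree, tip_states, model) {
  n_tip <- length(tree$tip.label)
  L <- matrix(0, n_tip, model$k)
  for (i in seq_len(n_tip)) {
    s <- tip_states[[tree$tip.label[i]]]
    if (is.null(s) || is.na(s))
      stop_ps("tip '%s' has no state", tree$tip.label[i])
    parts <- strsplit(as.character(s), "|", fixed = TRUE)[[1]]
    idx <- match(parts, model$state_labels)
    if (anyNA(idx))
      stop_ps("state label(s) not in model: %s",
              paste(parts[is.na(idx)], collapse = ", "))
    L[i, idx] <- 1
  }
  L
}

# post-order conditional likelihoods (Felsenstein pruning); returns the
# [n_node x k] matrix of partials D and the edge P(t) list
mk_partials <- function(tree, tip_states, model) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  D <- matrix(0, n_node, model$k)
  D[seq_len(n_tip), ] <- tip_likelihoods(tree, tip_states, model)
  po <- ape::reorder.phylo(tree, "postorder")
  pfun <- mk_transition_fun(model)
  Dfull <- D
  Dfull[(n_tip + 1):n_node, ] <- 1
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    Pm <- pfun(po$edge.length[e])
    Dfull[par, ] <- Dfull[par, ] * as.vector(Pm %*% Dfull[ch, ])
  }
  list(D = Dfull, n_tip = n_tip, pfun = pfun)
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' Conditional likelihoods are propagated from the tips to the root with
#' transition probabilities `P(t) = exp(Qt)`; the root combines them under
#' a uniform (default) or stationary state prior.
#'
#' @param tree a rooted [ape::phylo] with branch lengths.
#' @param tip_states named vector tip label -> state label; ambiguity sets
#'   as `"SE|SW"`.
#' @param model an [mk_model()].
#' @param root_prior `"uniform"` (default) or `"stationary"` (uniform for
#'   ER/SYM, whose stationary law is uniform).
#' @return log-likelihood.
#' @export
mk_loglik <- function(tree, tip_states, model, root_prior = "uniform") {
  pr <- mk_partials(tree, tip_states, model)
  root <- pr$n_tip + 1L
  pi0 <- rep(1 / model$k, model$k)
  lik <- sum(pi0 * pr$D[root, ])
  if (lik <= 0) return(-Inf)
  log(lik)
}

#' Maximum-likelihood Mk fit
#'
#' Optimises the transition rate(s) of an ER, SYM or ARD model on a fixed
#' tree by bounded numerical optimisation of the pruning log-likelihood
#' (rates searched on the log scale in `[1e-8, 1e3]` per Myr, several fixed
#' starting points).
#'
#' @param tree a rooted [ape::phylo] with branch lengths.
#' @param tip_states named vector tip label -> state label.
#' @param parameterization `"ER"`, `"SYM"` or `"ARD"`.
#' @param state_labels state space; defaults to the sorted unique observed
#'   states (split on `"|"` for ambiguity sets).
#' @param starts numeric vector of starting rates tried for every parameter.
#' @return object of class `mk_fit`: the fitted `mk_model`, `loglik`,
#'   `n_par`, `aic`, `convergence`, plus the data (`tree`, `tip_states`).
#' @export
fit_mk <- function(tree, tip_states, parameterization = c("ER", "SYM", "ARD"),
                   state_labels = NULL, starts = NULL) {
  parameterization <- match.arg(parameterization)
  if (is.null(state_labels))
    state_labels <- sort(unique(unlist(strsplit(as.character(tip_states), "|",
                                                fixed = TRUE))))
  k <- length(state_labels)
  if (k < 2) stop_ps("need at least 2 states in the state space")
  n_par <- switch(parameterization, ER = 1L, SYM = (k * (k - 1L)) %/% 2L,
                  ARD = k * (k - 1L))
  h <- max(ape::node.depth.edgelength(tree))
  if (is.null(starts)) starts <- c(0.1 / h, 1 / h, 10 / h)
  observed <- unique(unlist(strsplit(as.character(tip_states), "|", fixed = TRUE)))
  boundary <- length(observed) < 2
  if (boundary)
    warning("fewer than 2 distinct observed states: rate MLE is at the lower bound")

  nll <- function(log_rates) {
    m <- mk_model(k, parameterization, exp(log_rates), state_labels)
    v <- -mk_loglik(tree, tip_states, m)
    if (!is.finite(v)) v <- 1e10   # keeps L-BFGS-B inside the finite region
    v
  }
  lb <- log(1e-8); ub <- log(1e3)
  best <- NULL
  for (s in starts) {
    p0 <- rep(log(s), n_par)
    res <- tryCatch(
      stats::optim(p0, nll, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop_ps("optimizer failed to converge from all starts")
  model <- mk_model(k, parameterization, exp(best$par), state_labels)
  ll <- -best$value
  structure(
    list(model = model, loglik = ll, n_par = n_par,
         aic = 2 * n_par - 2 * ll, convergence = best$convergence,
         boundary = boundary, tree = tree, tip_states = tip_states),
    class = "mk_fit"
  )
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("<mk_fit> %s, k = %d, logLik = %.4f, AIC = %.4f\n",
              x$model$parameterization, x$model$k, x$loglik, x$aic))
  cat("  rates:", paste(signif(x$model$rates, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.mk_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_par, class = "logLik")
}

#' @export
coef.mk_fit <- function(object, ...) object$model$rates

#' @export
AIC.mk_fit <- function(object, ..., k = 2) object$aic

#' Marginal ancestral state probabilities
#'
#' Exact per-node marginal posteriors from a combined downward (pruning)
#' and upward pass: for each node, the partial likelihood of the data in
#' its subtree is multiplied by the partial likelihood of everything
#' outside it, under a uniform root prior. Equivalent to brute-force
#' enumeration of all internal-state assignments.
#'
#' @param tree a rooted [ape::phylo] with branch lengths.
#' @param tip_states named vector tip label -> state label.
#' @param model an [mk_model()] (or an [mk_fit()], whose model is used).
#' @return object of class `ancestral_reconstruction`: `prob` (matrix
#'   [nodes x states]; rows sum to 1; tips included), `modal_state` (per
#'   node), `loglik`, `model`.
#' @export
marginal_states <- function(tree, tip_states = NULL, model) {
  if (inherits(tree, "mk_fit")) {
    fit <- tree
    tree <- fit$tree; tip_states <- fit$tip_states; model <- fit$model
  } else if (inherits(model, "mk_fit")) model <- model$model
  pr <- mk_partials(tree, tip_states, model)
  D <- pr$D
  n_tip <- pr$n_tip
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  k <- model$k
  pi0 <- rep(1 / k, k)

  # "above" partials: A[v, s] = P(data outside subtree v | state s at v),
  # weighted by the root prior at the top
  A <- matrix(0, n_node, k)
  A[root, ] <- pi0
  po <- ape::reorder.phylo(tree, "postorder")
  # preorder = reversed postorder edge sequence (parents before children)
  edges <- nrow(po$edge):1
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  pfun <- pr$pfun
  for (e in edges) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    Pm <- pfun(po$edge.length[e])
    sib_edges <- children[[as.character(par)]]
    sib <- tree$edge[sib_edges, 2]
    sib <- sib[sib != ch]
    contrib <- A[par, ]
    for (s in sib) {
      ts <- tree$edge.length[which(tree$edge[, 2] == s)]
      contrib <- contrib * as.vector(pfun(ts) %*% D[s, ])
    }
    A[ch, ] <- as.vector(t(Pm) %*% contrib)
  }
  joint <- A * D
  prob <- joint / rowSums(joint)
  dimnames(prob) <- list(c(tree$tip.label, paste0("node", (n_tip + 1):n_node)),
                         model$state_labels)
  structure(
    list(prob = prob,
         modal_state = model$state_labels[max.col(prob, ties.method = "first")],
         loglik = log(sum(pi0 * D[root, ])), model = model),
    class = "ancestral_reconstruction"
  )
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  n_tip <- sum(!startsWith(rownames(x$prob), "node"))
  cat(sprintf("<ancestral_reconstruction> %d nodes, %d states, logLik = %.4f\n",
              nrow(x$prob), ncol(x$prob), x$loglik))
  root <- n_tip + 1L
  cat("  root: ", paste(sprintf("%s=%.3f", colnames(x$prob), x$prob[root, ]),
                        collapse = " "), "\n")
  invisible(x)
}

#' Select among fitted Mk models
#'
#' @param fits list of [fit_mk()] objects (optionally named).
#' @param criterion `"aic"` (default; lower wins) or `"loglik"` (higher
#'   wins — the raw-likelihood rule some workflows use).
#' @return the name/parameterization tag of the selected fit.
#' @export
select_model <- function(fits, criterion = c("aic", "loglik")) {
  criterion <- match.arg(criterion)
  if (length(fits) < 1) stop_ps("no fits supplied")
  tags <- names(fits) %||% vapply(fits, function(f) f$model$parameterization,
                                  character(1))
  if (is.null(names(fits)))
    tags <- vapply(fits, function(f) f$model$parameterization, character(1))
  score <- vapply(fits, function(f)
    if (criterion == "aic") f$aic else f$loglik, numeric(1))
  tags[if (criterion == "aic") which.min(score) else which.max(score)]
}
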