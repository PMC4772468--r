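#' Canonical birth-death-innovation model forms
#'
#' Four forms make up the canonical model space:
#' \describe{
#'   \item{`L`}{equal birth and deletion, no innovation (`b = d = lambda`,
#'     `i = 0`); one free rate.}
#'   \item{`L_I`}{equal birth, deletion and innovation
#'     (`b = d = i = lambda`); one free rate.}
#'   \item{`BD`}{birth and deletion free, no innovation; two free rates.}
#'   \item{`B_I_D`}{innovation tied to birth (`i = b`), deletion free; two
#'     free rates.}
#' }
#' The extension form `L_indI` (`b = d = lambda`, innovation estimated
#' independently) is available for sensitivity analyses but excluded from
#' the canonical enumeration: reconstructions under independently
#' estimated innovation tend to misplace ancestral presence.
#'
#' @param include_indI Include the `L_indI` extension form.
#' @return Character vector of form names.
#' @export
model_forms <- function(include_indI = FALSE) {
  f <- c("L", "L_I", "BD", "B_I_D")
  if (include_indI) f <- c(f, "L_indI")
  f
}

form_par_names <- function(form) {
  switch(form,
    "L" = "lambda", "L_I" = "lambda",
    "BD" = c("b", "d"), "B_I_D" = c("b", "d"),
    "L_indI" = c("lambda", "i"),
    stop("unknown model form: ", form))
}

form_n_par <- function(form) length(form_par_names(form))

form_has_innovation <- function(form) form %in% c("L_I", "B_I_D", "L_indI")

#' Build a rate specification from free parameters
#'
#' Applies a form's parameter-tying rules to the free parameter vector and
#' returns the full `(b, d, i)` rate triple.  Rates are per gene copy per
#' unit branch length for birth and deletion, and per gene family per unit
#' branch length for innovation.
#'
#' @param form One of [model_forms()].
#' @param params Numeric vector of free parameters, in the order given by
#'   the form (`lambda`; or `b`, `d`; or `lambda`, `i`).
#' @return A `rate_spec`: list with `b`, `d`, `i`, `form`.
#' @examples
#' rate_spec("B_I_D", c(0.2, 0.05))  # i tied to b
#' @export
rate_spec <- function(form, params) {
  if (length(params) != form_n_par(form)) {
    stop("form ", form, " takes ", form_n_par(form), " free parameter(s)")
  }
  if (any(params < 0)) stop("rates must be non-negative")
  r <- switch(form,
    "L"      = list(b = params[1], d = params[1], i = 0),
    "L_I"    = list(b = params[1], d = params[1], i = params[1]),
    "BD"     = list(b = params[1], d = params[2], i = 0),
    "B_I_D"  = list(b = params[1], d = params[2], i = params[1]),
    "L_indI" = list(b = params[1], d = params[1], i = params[2]))
  structure(c(r, list(form = form)), class = "rate_spec")
}

#' Tridiagonal generator of the truncated birth-death-innovation chain
#'
#' States are copy numbers `0..n_max`.  Birth and deletion are
#' copy-proportional: from state `k >= 1` the birth rate is `b * k` and the
#' deletion rate is `d * k`.  Innovation is the `0 -> 1` transition at rate
#' `i` per family; with `i = 0` state 0 is absorbing.  Birth is suppressed
#' at the truncation boundary `n_max`.
#'
#' @param rates A `rate_spec`, or any list with numeric `b`, `d`, `i`.
#' @param n_max Largest copy-number state (>= 1).
#' @return A dense `(n_max + 1) x (n_max + 1)` generator matrix with rows
#'   summing to zero.
#' @examples
#' build_rate_matrix(rate_spec("L", 1), 2)
#' @export
build_rate_matrix <- function(rates, n_max) {
  stopifnot(n_max >= 1)
  b <- rates$b; d <- rates$d; i <- rates$i
  if (any(c(b, d, i) < 0)) stop("rates must be non-negative")
  S <- n_max + 1L
  Q <- matrix(0, S, S, dimnames = list(0:n_max, 0:n_max))
  if (i > 0) { Q[1, 2] <- i }
  k <- seq_len(n_max)               # states 1..n_max, rows 2..S
  up <- k[k < n_max]
  Q[cbind(up + 1L, up + 2L)] <- b * up
  Q[cbind(k + 1L, k)] <- d * k
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probabilities over a branch
#'
#' `P(t) = expm(Q t)` for the truncated generator.  `t = 0` returns the
#' identity exactly.
#'
#' @param Q Generator matrix from [build_rate_matrix()].
#' @param t Branch length (>= 0), in the same time unit as the rates.
#' @return A row-stochastic matrix of transition probabilities.
#' @export
transition_matrix <- function(Q, t) {
  if (!is.finite(t) || t < 0) stop("branch length must be finite and >= 0")
  if (t == 0) return(diag(nrow(Q)))
  P <- as.matrix(Matrix::expm(Q * t))
  P[P < 0] <- 0   # clip tiny negative round-off
  dimnames(P) <- dimnames(Q)
  P
}

#' Root prior over copy-number states
#'
#' Forms without innovation make state 0 absorbing, so a family observed
#' anywhere must have been present in the most recent common ancestor: the
#' prior support excludes state 0.  Forms with innovation allow absence at
#' the root.  The default shape is uniform over the support, the
#' least-informative choice; a point-mass alternative is available.
#'
#' @param form Model form (decides whether state 0 is in the support).
#' @param n_max Largest state.
#' @param mode `"uniform"` or `"point"`.
#' @param point State receiving all mass under `mode = "point"`.
#' @return Numeric vector of length `n_max + 1` summing to 1.
#' @export
root_prior <- function(form, n_max, mode = c("uniform", "point"), point = 1L) {
  mode <- match.arg(mode)
  pi0 <- numeric(n_max + 1)
  if (mode == "point") {
    pi0[point + 1L] <- 1
  } else if (form_has_innovation(form)) {
    pi0[] <- 1 / (n_max + 1)
  } else {
    pi0[-1] <- 1 / n_max
  }
  pi0
}

## Cached traversal structure: internal nodes in postorder with their
## child edges (child node, branch length, class).
tree_traversal <- function(tree, classes) {
  validate_phylogeny(tree)
  if (length(classes) != nrow(tree$edge)) {
    stop("branch class map length must equal the edge count")
  }
  if (is.null(names(classes))) names(classes) <- tree$edge[, 2]
  cls <- classes[as.character(tree$edge[, 2])]
  if (any(is.na(cls))) stop("branch class map does not cover every branch")
  ord <- ape::reorder.phylo(tree, "postorder")
  cls <- classes[as.character(ord$edge[, 2])]
  parents <- unique(ord$edge[, 1])      # postorder: children before parents
  list(tree = tree, ntip = ape::Ntip(tree), root = root_node(tree),
       nnode = ape::Ntip(tree) + tree$Nnode,
       edge = ord$edge, edge.length = ord$edge.length, edge.class = cls,
       internal_postorder = parents)
}

## Transition matrices for every edge, cached over unique (class, length).
edge_transition_matrices <- function(tv, Q_by_class) {
  key <- paste(tv$edge.class, signif(tv$edge.length, 15))
  uk <- !duplicated(key)
  Ps <- setNames(lapply(which(uk), function(e) {
    transition_matrix(Q_by_class[[tv$edge.class[e]]], tv$edge.length[e])
  }), key[uk])
  Ps[key]
}

## Pruning partial likelihoods, vectorized over families.
## tips: array (states, ntip, nfam).  Returns list(partials = array over all
## nodes BEFORE per-node rescaling is undone, logscale = per-family log
## rescale totals, loglik = per-family log-likelihoods under `prior`).
prune_partials <- function(tv, Ps, tips, prior, keep_partials = FALSE) {
  S <- dim(tips)[1]; nf <- dim(tips)[3]
  L <- array(NA_real_, c(S, tv$nnode, nf))
  L[, seq_len(tv$ntip), ] <- tips
  logscale <- numeric(nf)
  scale_of <- matrix(0, tv$nnode, nf)   # per-node log scale applied
  for (nd in tv$internal_postorder) {
    acc <- matrix(1, S, nf)
    es <- which(tv$edge[, 1] == nd)
    for (e in es) {
      child <- tv$edge[e, 2]
      msg <- Ps[[e]] %*% matrix(L[, child, ], S, nf)
      acc <- acc * msg
    }
    cm <- apply(acc, 2, max)
    if (any(cm <= 0)) {
      bad <- cm <= 0
      acc[, bad] <- 0; cm[bad] <- 1
      logscale <- logscale + ifelse(bad, -Inf, 0)
    }
    acc <- sweep(acc, 2, cm, "/")
    logscale <- logscale + log(cm)
    scale_of[nd, ] <- logscale
    L[, nd, ] <- acc
  }
  loglik <- log(as.vector(crossprod(matrix(L[, tv$root, ], S, nf), prior))) +
    logscale
  out <- list(loglik = loglik, logscale = logscale)
  if (keep_partials) {
    out$partials <- L
    out$scale_of <- scale_of
  }
  out
}

## Build per-class generators for a list of rate_specs.
generators_by_class <- function(rates_by_class, n_max) {
  lapply(rates_by_class, build_rate_matrix, n_max = n_max)
}

#' Log-likelihood of one gene family on the tree
#'
#' Felsenstein pruning with per-branch transition matrices chosen by the
#' branch's lineage class; tip likelihood profiles may encode qPCR
#' interval probabilities, sequence-count minimums, or missing data.  The
#' likelihood is the prior-weighted sum of root partial likelihoods.
#'
#' @param tree A `"phylo"` object.
#' @param classes Branch class map (see [assign_clade_class()]).
#' @param rates_by_class Named list: class label -> `rate_spec`.
#' @param profiles Named list: taxon -> `copy_profile` (all the same
#'   length), covering every leaf.
#' @param prior Root prior vector (its support defines which root states
#'   are allowed); defaults to [root_prior()] for the first class's form.
#' @return The log-likelihood (a scalar).
#' @export
family_log_likelihood <- function(tree, classes, rates_by_class, profiles,
                                  prior = NULL) {
  tv <- tree_traversal(tree, classes)
  missing_cls <- setdiff(unique(tv$edge.class), names(rates_by_class))
  if (length(missing_cls)) stop("no rates for class: ", missing_cls[1])
  n_states <- unique(vapply(profiles, length, integer(1)))
  if (length(n_states) != 1L) stop("profiles must share one state space")
  if (!all(tree$tip.label %in% names(profiles))) {
    stop("profiles must cover every leaf")
  }
  n_max <- n_states - 1L
  if (is.null(prior)) {
    prior <- root_prior(rates_by_class[[1]]$form, n_max)
  }
  if (abs(sum(prior) - 1) > 1e-9) stop("root prior must sum to 1")
  tips <- array(0, c(n_states, tv$ntip, 1L))
  for (l in seq_len(tv$ntip)) {
    tips[, l, 1] <- as.numeric(profiles[[tree$tip.label[l]]])
  }
  Qs <- generators_by_class(rates_by_class, n_max)
  Ps <- edge_transition_matrices(tv, Qs)
  prune_partials(tv, Ps, tips, prior)$loglik
}

## Sum of family log-likelihoods for a block (shared rates), vectorized.
block_log_likelihood <- function(tv, table, families, rates_by_class, prior) {
  n_max <- table$n_max
  tips <- table$profiles[, tv$tree$tip.label, families, drop = FALSE]
  Qs <- generators_by_class(rates_by_class, n_max)
  Ps <- edge_transition_matrices(tv, Qs)
  sum(prune_partials(tv, Ps, tips, prior)$loglik)
}
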