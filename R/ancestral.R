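## Inside-outside machinery shared by marginals and event expectations.
## Returns, for one family: tv, per-edge P matrices, inside partials
## (rescaled), outside vectors, and the per-edge "context" (outside of the
## parent times sibling messages) needed for joint parent-child posteriors.
inside_outside <- function(fit, tree, classes, profiles, prior = NULL) {
  if (!fit$lineage_het) classes <- uniform_classes(tree)
  tv <- tree_traversal(tree, classes)
  n_states <- unique(vapply(profiles, length, integer(1)))
  if (length(n_states) != 1L) stop("profiles must share one state space")
  n_max <- n_states - 1L
  if (is.null(prior)) prior <- fit$prior %||% root_prior(fit$form, n_max)
  if (length(prior) != n_states) stop("state-space mismatch with the fit")
  tips <- array(0, c(n_states, tv$ntip, 1L))
  for (l in seq_len(tv$ntip)) {
    tips[, l, 1] <- as.numeric(profiles[[tv$tree$tip.label[l]]])
  }
  Qs <- generators_by_class(fit$rates, n_max)
  missing_cls <- setdiff(unique(tv$edge.class), names(Qs))
  if (length(missing_cls)) stop("no rates for class: ", missing_cls[1])
  Ps <- edge_transition_matrices(tv, Qs)
  ins <- prune_partials(tv, Ps, tips, prior, keep_partials = TRUE)
  L <- ins$partials[, , 1]                      # states x nodes, rescaled
  ## messages up each edge: m_e = P_e %*% L[, child]
  msg <- lapply(seq_len(nrow(tv$edge)), function(e) {
    as.vector(Ps[[e]] %*% L[, tv$edge[e, 2]])
  })
  ## outside pass (preorder = reverse of postorder over internal nodes)
  O <- matrix(NA_real_, n_states, tv$nnode)
  O[, tv$root] <- prior
  ctx <- vector("list", nrow(tv$edge))          # context vector per edge
  for (nd in rev(tv$internal_postorder)) {
    es <- which(tv$edge[, 1] == nd)
    for (e in es) {
      prodsib <- O[, nd]
      for (e2 in setdiff(es, e)) prodsib <- prodsib * msg[[e2]]
      ctx[[e]] <- prodsib
      O[, tv$edge[e, 2]] <- as.vector(crossprod(Ps[[e]], prodsib))
    }
  }
  list(tv = tv, Ps = Ps, inside = L, outside = O, ctx = ctx,
       loglik = ins$loglik, n_max = n_max, Qs = Qs)
}

#' Marginal ancestral copy-number posteriors for one family
#'
#' Computes, by the inside-outside (up-down) algorithm, the marginal
#' posterior distribution over copy-number states at every node of the
#' tree, conditioned on the family's tip profiles under one fitted model.
#' A warning is raised when any node puts more than 1e-4 posterior mass on
#' the truncation boundary state, a sign that `n_max` should be enlarged.
#'
#' @param fit A `bdi_fit` for this family's category.
#' @param tree A `"phylo"` object.
#' @param classes Branch class map (ignored when the fit has no lineage
#'   heterogeneity).
#' @param profiles Named list: taxon -> `copy_profile`.
#' @param prior Optional root prior override.
#' @return An `ancestral_posterior`: matrix (nodes x states, rows sum to
#'   1) with node ids as row names; leaf rows are the tip-profile
#'   posteriors.
#' @export
ancestral_marginals <- function(fit, tree, classes, profiles, prior = NULL) {
  io <- inside_outside(fit, tree, classes, profiles, prior)
  post <- t(io$inside * io$outside)            # nodes x states
  s <- rowSums(post)
  if (any(s <= 0)) stop("data have zero likelihood under this model")
  post <- post / s
  dimnames(post) <- list(seq_len(io$tv$nnode), 0:io$n_max)
  if (max(post[, io$n_max + 1L]) > 1e-4) {
    warning("posterior mass > 1e-4 on the boundary state n_max = ",
            io$n_max, "; consider enlarging the state space")
  }
  structure(post, class = "ancestral_posterior", loglik = io$loglik)
}

#' Maximum a posteriori states
#'
#' @param post An `ancestral_posterior`.
#' @return Integer vector of MAP copy numbers per node.  Ties are broken
#'   toward the smaller state; tied nodes are flagged in the `"ties"`
#'   attribute.
#' @export
map_states <- function(post) {
  states <- as.integer(colnames(post))
  idx <- apply(post, 1, which.max)   # first maximum = smallest state
  tied <- apply(post, 1, function(p) sum(p == max(p)) > 1L)
  structure(setNames(states[idx], rownames(post)), ties = tied)
}

## Van Loan block-matrix integral: M[a,c] = E[count of R-transitions and
## X_t = c | X_0 = a] for generator Q over time t, where R holds the rates
## of the counted transitions.
vanloan_integral <- function(Q, R, t) {
  S <- nrow(Q)
  A <- rbind(cbind(Q, R), cbind(matrix(0, S, S), Q))
  E <- as.matrix(Matrix::expm(A * t))
  M <- E[seq_len(S), S + seq_len(S)]
  M[M < 0] <- 0
  M
}

event_rate_matrix <- function(Q, rates, type) {
  S <- nrow(Q)
  R <- matrix(0, S, S)
  n_max <- S - 1L
  k <- seq_len(n_max)
  switch(type,
    "birth" = {
      up <- k[k < n_max]
      R[cbind(up + 1L, up + 2L)] <- rates$b * up
    },
    "deletion" = {
      R[cbind(k + 1L, k)] <- rates$d * k
    },
    "innovation" = {
      R[1, 2] <- rates$i
    },
    stop("unknown event type: ", type))
  R
}

#' Expected event count on a branch, conditioned on the data
#'
#' The expected number of birth, deletion or innovation events on one
#' branch for one family, averaged over the joint posterior of the
#' branch's endpoint states and, within each endpoint pair, over the
#' conditioned paths of the chain.  The within-pair expectation is exact:
#' it is the matrix integral `int_0^t exp(Qs) R exp(Q(t-s)) ds` (computed
#' by the block matrix-exponential construction), divided by the
#' transition probability — the analytic form of stochastic mapping, so
#' the pipeline stays deterministic.
#'
#' @inheritParams ancestral_marginals
#' @param branch The branch's child node: a tip label or node id.
#' @param type One of `"birth"`, `"deletion"`, `"innovation"`.
#' @return An `event_expectation`: list with `branch`, `type`,
#'   `expectation`.
#' @export
expected_branch_events <- function(fit, tree, classes, profiles, branch,
                                   type = c("birth", "deletion", "innovation"),
                                   prior = NULL) {
  type <- match.arg(type)
  child <- resolve_branch(tree, branch)
  io <- inside_outside(fit, tree, classes, profiles, prior)
  e <- which(io$tv$edge[, 2] == child)
  if (length(e) != 1L) stop("unknown branch: ", branch)
  cls <- io$tv$edge.class[e]
  rates <- fit$rates[[cls]]
  rate_of <- switch(type, birth = rates$b, deletion = rates$d,
                    innovation = rates$i)
  if (type == "innovation" && rates$i == 0) {
    warning("innovation rate is 0 under form ", fit$form,
            "; expected count is 0")
  }
  t_br <- io$tv$edge.length[e]
  if (t_br == 0 || rate_of == 0) {
    return(structure(list(branch = branch, type = type, expectation = 0),
                     class = "event_expectation"))
  }
  Q <- io$Qs[[cls]]
  P <- io$Ps[[e]]
  ## joint posterior over (parent state a, child state c) for this branch
  J <- (io$ctx[[e]] * P) * rep(io$inside[, child], each = nrow(P))
  J <- J / sum(J)
  M <- vanloan_integral(Q, event_rate_matrix(Q, rates, type), t_br)
  ok <- P > 0 & J > 0
  expectation <- sum(J[ok] * M[ok] / P[ok])
  structure(list(branch = branch, type = type, expectation = expectation),
            class = "event_expectation")
}

resolve_branch <- function(tree, branch) {
  if (is.character(branch)) {
    hit <- match(branch, tree$tip.label)
    if (is.na(hit)) stop("unknown branch (tip label): ", branch)
    return(hit)
  }
  as.integer(branch)
}

#' Model-averaged expected event count over a family set
#'
#' Sums a branch's expected event count over families and averages over
#' models with their BIC weights: the model-averaged expectation used,
#' e.g., to ask how many lineage-specific deletions a clade's data imply.
#'
#' @param scores A `model_score_table` from [fit_model_space()].
#' @param table The `gene_family_table` the space was fitted to.
#' @param tree,classes Tree and branch class map.
#' @param families Family ids to sum over (they must share no block only
#'   per model; any set is allowed).
#' @param branch,type As in [expected_branch_events()].
#' @param min_weight Models below this BIC weight are skipped; their
#'   contribution to the average is bounded above by the skipped weight,
#'   so the default `1e-8` is numerically inconsequential.
#' @return The model-averaged expected event count (scalar).
#' @export
model_averaged_events <- function(scores, table, tree, classes, families,
                                  branch, type, min_weight = 1e-8) {
  stopifnot(all(families %in% names(table$category)))
  models <- attr(scores, "models")
  total <- 0
  for (r in seq_len(nrow(scores))) {
    w <- scores$weight[r]
    if (w < min_weight) next
    fits <- model_block_fits(scores, scores$model_id[r])
    m <- models[[which(vapply(models, `[[`, integer(1), "model_id") ==
                         scores$model_id[r])]]
    contrib <- 0
    for (f in families) {
      cat_f <- table$category[[f]]
      bi <- which(vapply(m$blocks, function(b) cat_f %in% b$categories,
                         logical(1)))
      fit <- fits[[bi]]
      if (is.null(fit$rates) || length(fit$rates) == 0L) next
      prof <- profiles_of_family(table, f)
      contrib <- contrib + expected_branch_events(
        fit, tree, classes, prof, branch, type)$expectation
    }
    total <- total + w * contrib
  }
  total
}

#' Extract one family's per-taxon profiles from a table
#'
#' @param table A `gene_family_table`.
#' @param family Family id.
#' @return Named list: taxon -> `copy_profile`.
#' @export
profiles_of_family <- function(table, family) {
  stopifnot(family %in% names(table$category))
  setNames(lapply(table$taxa, function(tx) {
    copy_profile(table$profiles[, tx, family], table$obs_type[tx, family])
  }), table$taxa)
}

#' Sensitivity and specificity of ancestral presence calls
#'
#' Compares presence/absence calls (presence = MAP copy number >= 1)
#' against an external reference, e.g. gene content known from finished Y
#' assemblies.  Used to judge whether a model family reconstructs
#' ancestral gene content plausibly.
#'
#' @param calls Named logical vector (or "present"/"absent" character):
#'   the model's presence calls per node/family key.
#' @param reference Same keys: the reference presence states.
#' @return List with `tp`, `fn`, `tn`, `fp`, `sensitivity`,
#'   `specificity`; a metric whose denominator is empty is `NA` (not
#'   applicable).
#' @export
presence_call_metrics <- function(calls, reference) {
  calls <- as_presence(calls); reference <- as_presence(reference)
  if (is.null(names(calls)) || is.null(names(reference)) ||
      !setequal(names(calls), names(reference))) {
    stop("calls and reference must be named with the same keys")
  }
  reference <- reference[names(calls)]
  tp <- sum(calls & reference); fn <- sum(!calls & reference)
  tn <- sum(!calls & !reference); fp <- sum(calls & !reference)
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Read a presence/absence reference set from a two-column TSV
#'
#' Columns: a key (e.g. node or `family:node`) and a state, `present` or
#' `absent` (or `P`/`A`).
#'
#' @param path Path to the TSV file.
#' @return Named logical vector suitable for [presence_call_metrics()].
#' @export
read_presence_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("presence reference needs two columns")
  as_presence(setNames(df[[2]], df[[1]]))
}

as_presence <- function(x) {
  if (is.character(x)) {
    if (!all(x %in% c("present", "absent", "P", "A"))) {
      stop("presence vectors must be logical or 'present'/'absent'")
    }
    setNames(x %in% c("present", "P"), names(x))
  } else setNames(as.logical(x), names(x))
}
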