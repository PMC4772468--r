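## Independent oracles used across the suite.  These deliberately avoid the
## package's pruning/inside-outside code paths: likelihoods and marginals
## are recomputed by exhaustive enumeration over internal-node states, and
## qPCR interval probabilities by numerical integration of the normal
## density.

## Exhaustive-enumeration likelihood and internal-node marginals for small
## trees (sum over all internal state assignments; tip states integrated
## against their profiles).
brute_tree_posterior <- function(tree, classes, rates_by_class, profiles,
                                 prior) {
  tv <- famflux:::tree_traversal(tree, classes)
  S <- length(prior)
  Qs <- lapply(rates_by_class, build_rate_matrix, n_max = S - 1L)
  Ps <- lapply(seq_len(nrow(tv$edge)), function(e) {
    transition_matrix(Qs[[tv$edge.class[e]]], tv$edge.length[e])
  })
  internal <- setdiff(seq_len(tv$nnode), seq_len(tv$ntip))
  tipw <- sapply(tree$tip.label, function(x) as.numeric(profiles[[x]]))
  grid <- do.call(expand.grid, rep(list(seq_len(S)), length(internal)))
  post <- matrix(0, tv$nnode, S)
  total <- 0
  for (r in seq_len(nrow(grid))) {
    st <- integer(tv$nnode)
    st[internal] <- as.integer(grid[r, ])
    w <- prior[st[tv$root]]
    for (e in seq_len(nrow(tv$edge))) {
      p <- tv$edge[e, 1]; ch <- tv$edge[e, 2]
      w <- w * if (ch <= tv$ntip) {
        sum(Ps[[e]][st[p], ] * tipw[, ch])
      } else {
        Ps[[e]][st[p], st[ch]]
      }
      if (w == 0) break
    }
    if (w > 0) {
      for (v in internal) post[v, st[v]] <- post[v, st[v]] + w
      total <- total + w
    }
  }
  list(loglik = log(total), post = post / total, internal = internal)
}

## qPCR interval weights by numerical integration (no pnorm).
qpcr_weights_integrate <- function(mean, se, n_max) {
  dens <- function(x) exp(-(x - mean)^2 / (2 * se^2)) / (se * sqrt(2 * pi))
  vapply(seq_len(n_max), function(k) {
    lo <- if (k == 1) 0 else k - 0.5
    hi <- if (k == n_max) Inf else k + 0.5
    integrate(dens, lo, hi, rel.tol = 1e-12)$value
  }, numeric(1))
}

## Random small instance generators shared by property tests.
random_small_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = TRUE)
  tr$edge.length <- round(runif(nrow(tr$edge), 0.1, 2), 3)
  tr$tip.label <- paste0("t", seq_len(n_leaves))
  tr
}

random_rates <- function(form = NULL) {
  if (is.null(form)) form <- sample(model_forms(), 1)
  rate_spec(form, runif(famflux:::form_n_par(form), 0.05, 0.9))
}

## Point-mass tip profiles for a tree.
point_profiles <- function(tree, states, n_max) {
  setNames(lapply(states, count_profile, n_max = n_max), tree$tip.label)
}

## Minimal bdi_fit wrapper so ancestral operations can be driven with
## known rates.
manual_fit <- function(form, rates_by_class, prior) {
  structure(list(form = form, lineage_het = length(rates_by_class) > 1L,
                 rates = rates_by_class, prior = prior,
                 class_labels = names(rates_by_class)),
            class = "bdi_fit")
}
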