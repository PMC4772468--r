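#' Copy-number likelihood profile from a qPCR estimate
#'
#' Converts a continuous qPCR copy-number estimate (mean and standard
#' error) into per-state likelihoods over the discrete copy numbers
#' `0..n_max` by the interval-threshold rule: the estimate is treated as
#' Normal(mean, se) and each positive integer k receives the probability
#' mass of its interval, with cut points at (0, 1.5, 2.5, 3.5, ...).  State
#' 0 always has likelihood 0 — an amplifying assay implies at least one
#' copy.  By default the top state absorbs all density above
#' `n_max - 0.5` so total mass stays 1; `strict = TRUE` instead uses the
#' finite interval `(n_max - 0.5, n_max + 0.5]`.
#'
#' @param mean Estimated mean copy number (> 0).
#' @param se Standard error of the estimate (>= 0).  With `se = 0` the
#'   profile is a point mass on the nearest integer >= 1 (ties round half
#'   up).
#' @param n_max Largest copy-number state, at least `ceiling(mean)`.
#'   Under `strict = TRUE` it must also be large enough that less than
#'   0.1% of the density lies beyond `n_max + 0.5`, otherwise truncation
#'   would silently discard likelihood and an error is raised; the
#'   default absorbing top interval holds all mass by construction.
#' @param strict Use the finite top interval instead of extending it to
#'   infinity.
#' @return A `copy_profile`: numeric vector of length `n_max + 1`, names
#'   `"0".."n_max"`, with attribute `obs_type = "qpcr"`.  Profiles are
#'   likelihoods and are deliberately not normalized.
#' @examples
#' qpcr_profile(2.0, 0.5, 4)
#' @export
qpcr_profile <- function(mean, se, n_max, strict = FALSE) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(se), length(se) == 1L, is.finite(se))
  if (mean <= 0) stop("qPCR mean copy number must be positive")
  if (se < 0) stop("standard error must be non-negative")
  if (n_max < 1 || n_max < ceiling(mean)) {
    stop("n_max must be >= ceiling(mean) and >= 1")
  }
  w <- numeric(n_max + 1)
  if (se == 0) {
    k <- max(1L, floor(mean + 0.5))  # ties round half up
    if (k > n_max) stop("point mass beyond n_max")
    w[k + 1] <- 1
  } else {
    if (strict && pnorm(n_max + 0.5, mean, se, lower.tail = FALSE) > 1e-3) {
      stop("n_max too small: > 0.1% of the qPCR density lies beyond n_max + 0.5")
    }
    lower <- c(0, seq_len(n_max - 1) + 0.5)
    upper <- seq_len(n_max) + 0.5
    if (!strict) upper[n_max] <- Inf
    w[-1] <- pnorm(upper, mean, se) - pnorm(lower, mean, se)
  }
  copy_profile(w, "qpcr")
}

#' Copy-number profile from a unique-sequence count
#'
#' A count of distinct sequences is a minimum bound on copy number: all
#' states below the count get likelihood 0, all states at or above it get
#' likelihood 1.  A count of 0 is informationless on states >= 1 and
#' additionally allows state 0 (unlike [missing_profile()] applied to an
#' amplifying assay, the two coincide here).
#'
#' @param n_unique Number of unique sequences observed (0 <= n_unique <=
#'   n_max).
#' @param n_max Largest copy-number state.
#' @return A `copy_profile` with `obs_type = "sequence-count"`.
#' @examples
#' sequence_min_profile(1, 3)  # 0 1 1 1
#' @export
sequence_min_profile <- function(n_unique, n_max) {
  stopifnot(n_max >= 1, n_unique >= 0)
  if (n_unique > n_max) stop("n_unique exceeds n_max")
  w <- as.numeric(0:n_max >= n_unique)
  copy_profile(w, "sequence-count")
}

#' Uninformative profile for missing observations
#'
#' Missing data (a failed assay, an unassayed taxon) contribute likelihood
#' 1 at every state, including 0, so pruning simply integrates over the
#' taxon's state.
#'
#' @param n_max Largest copy-number state (>= 1).
#' @return A `copy_profile` of ones with `obs_type = "missing"`.
#' @export
missing_profile <- function(n_max) {
  stopifnot(n_max >= 1)
  copy_profile(rep(1, n_max + 1), "missing")
}

copy_profile <- function(w, obs_type) {
  stopifnot(all(w >= 0), all(w <= 1), any(w > 0))
  names(w) <- 0:(length(w) - 1L)
  attr(w, "obs_type") <- obs_type
  class(w) <- "copy_profile"
  w
}

#' @export
print.copy_profile <- function(x, ...) {
  cat("<copy_profile> obs_type =", attr(x, "obs_type"), "\n")
  print(unclass(structure(x, obs_type = NULL)), ...)
  invisible(x)
}

#' Rescale a relative quantification to absolute copy number
#'
#' qPCR yields copy number relative to a calibrator sample; multiplying by
#' the calibrator's known copy count (e.g. from a finished Y-chromosome
#' assembly) converts the relative mean and its standard error to the
#' absolute scale.
#'
#' @param rel_mean Relative quantity (> 0).
#' @param rel_se Standard error of the relative quantity (>= 0).
#' @param ref_copies Known copy number of the calibrator (integer >= 1).
#' @return A list with elements `mean` and `se` on the copy-number scale.
#' @export
rescale_relative_quantity <- function(rel_mean, rel_se, ref_copies) {
  if (rel_mean <= 0) stop("relative mean must be positive")
  if (rel_se < 0) stop("relative standard error must be non-negative")
  if (ref_copies < 1 || ref_copies != round(ref_copies)) {
    stop("reference copy number must be a positive integer")
  }
  list(mean = rel_mean * ref_copies, se = rel_se * ref_copies)
}

#' Per-gene coefficients of variation and their sum
#'
#' The summed CV across a gene set is the dispersion summary used to
#' compare copy-number variability between clades.  Uses the sample (n-1)
#' standard deviation, appropriate for the small per-assay sample sizes
#' typical of qPCR panels.
#'
#' @param estimates A named list; each element is the numeric vector of
#'   per-sample mean copy numbers for one gene (length >= 2, all > 0 mean).
#' @return A list with `cv` (named per-gene CVs) and `sum`.
#' @examples
#' summed_cv(list(g1 = c(1, 2, 3), g2 = c(2, 2, 2)))
#' @export
summed_cv <- function(estimates) {
  stopifnot(is.list(estimates), length(estimates) >= 1)
  cvs <- vapply(estimates, function(x) {
    if (length(x) < 2L) stop("each gene needs >= 2 samples")
    m <- mean(x)
    if (m <= 0) stop("non-positive mean copy number")
    sd(x) / m
  }, numeric(1))
  list(cv = cvs, sum = sum(cvs))
}
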