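## Parameter bookkeeping for a block fit: free parameters are log-rates,
## laid out class-by-class in the order of `class_labels`.
block_par_names <- function(form, class_labels) {
  as.vector(outer(form_par_names(form), class_labels,
                  function(p, c) paste(c, p, sep = ":")))
}

rates_from_par <- function(par, form, class_labels) {
  np <- form_n_par(form)
  setNames(lapply(seq_along(class_labels), function(j) {
    rate_spec(form, exp(par[(j - 1) * np + seq_len(np)]))
  }), class_labels)
}

#' Maximum-likelihood fit of one model form to a block of families
#'
#' Maximizes the summed pruning log-likelihood over the block's free
#' rates.  Rates are shared across all families in the block; under
#' lineage heterogeneity each branch class gets its own copy of the form's
#' free parameters (doubling `k` for two classes).  Optimization is on the
#' log-rate scale with a deterministic list of log-spaced multistarts,
#' since tied-parameter likelihood surfaces can be flat.
#'
#' @param table A `gene_family_table` (the block: usually
#'   [subset_families()] of the full table).
#' @param tree A `"phylo"` object.
#' @param classes Branch class map.  Ignored (collapsed to one class) when
#'   `lineage_het = FALSE`.
#' @param form One of [model_forms()].
#' @param lineage_het Fit separate rates per branch class.
#' @param prior_mode Root prior shape, see [root_prior()].
#' @param prior_point Root state given all prior mass under
#'   `prior_mode = "point"`.
#' @param multistarts Number of multistart points (>= 1).
#' @param rate_bounds Log-rate search bounds (rates per unit branch
#'   length).
#' @return A `bdi_fit`: list with `form`, `lineage_het`, `class_labels`,
#'   `rates` (class -> `rate_spec`), `par` (named log-rate MLEs), `logL`,
#'   `k`, `n_families`, `convergence` (per-start optimizer codes),
#'   `prior`.
#' @export
fit_block <- function(table, tree, classes, form, lineage_het = FALSE,
                      prior_mode = "uniform", prior_point = 1L,
                      multistarts = 5, rate_bounds = c(1e-8, 1e3)) {
  fams <- names(table$category)
  if (length(fams) == 0L) stop("empty block: no families to fit")
  if (!lineage_het) classes <- uniform_classes(tree)
  tv <- tree_traversal(tree, classes)
  class_labels <- sort(unique(tv$edge.class))
  if (lineage_het && length(class_labels) < 2L) {
    stop("lineage heterogeneity requires >= 2 branch classes")
  }
  prior <- root_prior(form, table$n_max, mode = prior_mode,
                      point = prior_point)
  np <- form_n_par(form) * length(class_labels)
  negll <- function(par) {
    rb <- rates_from_par(par, form, class_labels)
    v <- -block_log_likelihood(tv, table, fams, rb, prior)
    if (!is.finite(v)) 1e10 else v   # rate regions where the data underflow
  }
  lb <- log(rate_bounds[1]); ub <- log(rate_bounds[2])
  starts <- log(10^seq(-3, 0.5, length.out = max(2, multistarts)))[
    seq_len(max(1, multistarts))]
  best <- NULL; codes <- integer(0)
  if (np == 1L) {
    opt <- optimize(negll, interval = c(lb, ub), tol = 1e-8)
    best <- list(par = opt$minimum, value = opt$objective)
    codes <- 0L
  } else {
    for (s in starts) {
      o <- tryCatch(
        optim(rep(s, np), negll, method = "L-BFGS-B",
              lower = rep(lb, np), upper = rep(ub, np),
              control = list(maxit = 500, factr = 1e7)),
        error = function(e) NULL)
      if (is.null(o)) { codes <- c(codes, 99L); next }
      codes <- c(codes, o$convergence)
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (is.null(best)) stop("optimizer failed to converge from every start")
    if (all(codes != 0L)) {
      warning("no multistart reported clean convergence; best value kept")
    }
  }
  par <- setNames(best$par, block_par_names(form, class_labels))
  structure(list(
    form = form, lineage_het = lineage_het, class_labels = class_labels,
    rates = rates_from_par(best$par, form, class_labels),
    par = par, logL = -best$value, k = np,
    n_families = length(fams), convergence = codes,
    prior_mode = prior_mode, prior = prior,
    rate_bounds = rate_bounds), class = "bdi_fit")
}

#' @export
print.bdi_fit <- function(x, ...) {
  cat("<bdi_fit> form ", x$form,
      if (x$lineage_het) " + lineage heterogeneity", "\n", sep = "")
  cat("  families:", x$n_families, "  logL:", format(x$logL),
      "  k:", x$k, "\n")
  for (cl in x$class_labels) {
    r <- x$rates[[cl]]
    cat(sprintf("  %-10s b=%.5g d=%.5g i=%.5g\n", cl, r$b, r$d, r$i))
  }
  invisible(x)
}

#' Serialize a block fit as JSON
#'
#' Records the form, per-class rates, log-likelihood, parameter count,
#' convergence codes and (optionally) confidence intervals, so a fit can
#' be archived next to the score table it contributed to.
#'
#' @param fit A `bdi_fit`.
#' @param path Output path.
#' @param cis Optional named list of intervals from [profile_ci()].
#' @export
write_fit_json <- function(fit, path, cis = NULL) {
  obj <- list(form = fit$form, lineage_het = fit$lineage_het,
              rates = lapply(fit$rates, function(r) r[c("b", "d", "i")]),
              logL = fit$logL, k = fit$k, n_families = fit$n_families,
              convergence = fit$convergence, prior_mode = fit$prior_mode,
              rate_bounds = fit$rate_bounds)
  if (!is.null(cis)) obj$ci <- cis
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Univariate profile-likelihood confidence interval
#'
#' The interval for one free rate is the set of values whose profile
#' log-likelihood (re-maximizing every other free parameter) is within
#' `qchisq(level, 1) / 2` of the maximum.  The lower bound is clipped at
#' zero.
#'
#' @param fit A `bdi_fit` from [fit_block()].
#' @param table,tree,classes The data and tree the fit used.
#' @param param Name of the free parameter, as in `names(fit$par)` (e.g.
#'   `"all:lambda"` or `"Hominini:b"`).
#' @param level Confidence level, default 0.95.
#' @return Numeric `c(lower, upper)` on the rate scale; `upper` may be
#'   `Inf` when the likelihood does not fall off within the search bounds.
#' @export
profile_ci <- function(fit, table, tree, classes, param, level = 0.95) {
  if (!param %in% names(fit$par)) {
    stop("unknown (or tied) parameter: ", param,
         "; free parameters are: ", paste(names(fit$par), collapse = ", "))
  }
  idx <- match(param, names(fit$par))
  form <- fit$form
  if (!fit$lineage_het) classes <- uniform_classes(tree)
  tv <- tree_traversal(tree, classes)
  fams <- names(table$category)
  np <- length(fit$par)
  negll <- function(par) {
    rb <- rates_from_par(par, form, fit$class_labels)
    v <- -block_log_likelihood(tv, table, fams, rb, fit$prior)
    if (!is.finite(v)) 1e10 else v
  }
  lb <- log(fit$rate_bounds[1]); ub <- log(fit$rate_bounds[2])
  prof <- function(ltheta) {  # profile negative log-likelihood at par[idx]=ltheta
    if (np == 1L) return(negll(ltheta))
    others <- fit$par[-idx]
    f2 <- function(p2) {
      full <- numeric(np); full[idx] <- ltheta; full[-idx] <- p2
      negll(full)
    }
    if (np == 2L) {
      optimize(f2, interval = c(lb, ub), tol = 1e-7)$objective
    } else {
      optim(others, f2, method = "L-BFGS-B", lower = rep(lb, np - 1),
            upper = rep(ub, np - 1))$value
    }
  }
  cut <- qchisq(level, 1) / 2
  nll_max <- -fit$logL
  g <- function(ltheta) prof(ltheta) - nll_max - cut  # > 0 outside the CI
  lmle <- fit$par[idx]
  ## lower side: step down multiplicatively until outside, then root-find
  lo <- NA_real_
  step <- lmle
  found <- FALSE
  for (j in 1:60) {
    step <- step - log(2)
    if (step < lb) break
    if (g(step) > 0) { found <- TRUE; break }
  }
  if (found) {
    lo <- exp(uniroot(g, c(step, lmle), tol = 1e-9)$root)
  } else {
    lo <- 0  # likelihood never falls off before the zero-rate bound
  }
  hi <- NA_real_
  step <- lmle
  found <- FALSE
  for (j in 1:60) {
    step <- step + log(2)
    if (step > ub) break
    if (g(step) > 0) { found <- TRUE; break }
  }
  if (found) {
    hi <- exp(uniroot(g, c(lmle, step), tol = 1e-9)$root)
  } else {
    hi <- Inf
  }
  c(lower = lo, upper = hi)
}
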