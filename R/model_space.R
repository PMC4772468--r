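#' Canonical gene-category partitions
#'
#' The ten ways the four gene categories (autosomal singletons `AutS`,
#' autosomal multicopy `AutM`, Y singletons `YS`, ampliconic `AG`) are
#' grouped into blocks sharing one model of evolution.  These are the ten
#' biologically motivated partitions of the model space, not all fifteen
#' set partitions of four elements; with 8 model variants per block the
#' space totals 6408 models (8 + 4x64 + 4x512 + 4096).
#'
#' @return Named list; each element is a list of character-vector blocks.
#' @export
category_partitions <- function() {
  p <- list(
    list(c("AutS", "AutM", "YS", "AG")),
    list("AutS", c("AutM", "YS", "AG")),
    list(c("AutS", "AutM", "YS"), "AG"),
    list(c("AutS", "AutM"), c("YS", "AG")),
    list(c("AutS", "AutM", "AG"), "YS"),
    list("AutS", "AutM", c("YS", "AG")),
    list(c("AutS", "YS"), "AutM", "AG"),
    list("AutS", "YS", c("AutM", "AG")),
    list(c("AutS", "AutM"), "YS", "AG"),
    list("AutS", "AutM", "YS", "AG"))
  names(p) <- vapply(p, partition_name, character(1))
  p
}

partition_name <- function(blocks) {
  paste(vapply(blocks, paste, character(1), collapse = "+"), collapse = "|")
}

block_key <- function(categories, form, het) {
  paste(paste(categories, collapse = "+"), form, if (het) "het" else "hom",
        sep = "/")
}

#' Enumerate the model space
#'
#' Every model is a choice, for each block of a category partition, of a
#' model form and a lineage-heterogeneity flag.  With the four canonical
#' forms this gives 8 variants per block and 6408 models over the ten
#' partitions.  Enumeration order is deterministic: partitions in their
#' canonical order, then block variants lexicographically (form order as
#' in [model_forms()], homogeneous before heterogeneous, last block
#' varying fastest).
#'
#' @param include_indI Also enumerate the `L_indI` extension form
#'   (excluded by default; see [model_forms()]).
#' @param partitions Optional subset of [category_partitions()] (by name
#'   or as a list) for reduced-scale analyses.
#' @param forms Optional subset of model forms.
#' @param het_options Logical vector of allowed lineage-heterogeneity
#'   flags, default `c(FALSE, TRUE)`.
#' @return A list of `model_spec`s: each a list with `model_id`,
#'   `partition` (name), `blocks` (per block: `categories`, `form`,
#'   `het`), and `k` (total free parameters, assuming two branch classes
#'   under heterogeneity).
#' @examples
#' length(enumerate_model_space())  # 6408
#' @export
enumerate_model_space <- function(include_indI = FALSE, partitions = NULL,
                                  forms = NULL, het_options = c(FALSE, TRUE)) {
  parts <- category_partitions()
  if (!is.null(partitions)) {
    parts <- if (is.character(partitions)) parts[partitions] else partitions
  }
  if (is.null(forms)) forms <- model_forms(include_indI)
  variants <- list()
  for (f in forms) for (h in sort(het_options)) {
    variants[[length(variants) + 1L]] <-
      list(form = f, het = h,
           k = form_n_par(f) * (if (h) 2L else 1L))
  }
  nv <- length(variants)
  out <- vector("list", 0L); id <- 0L
  for (pn in names(parts)) {
    blocks <- parts[[pn]]
    nb <- length(blocks)
    ## indices over variants per block; last block varies fastest
    grid <- as.matrix(do.call(expand.grid, rev(rep(list(seq_len(nv)), nb))))
    grid <- grid[, rev(seq_len(nb)), drop = FALSE]
    chunk <- vector("list", nrow(grid))
    for (r in seq_len(nrow(grid))) {
      id <- id + 1L
      bl <- vector("list", nb)
      k <- 0L
      for (j in seq_len(nb)) {
        v <- variants[[grid[r, j]]]
        bl[[j]] <- list(categories = blocks[[j]], form = v$form, het = v$het)
        k <- k + v$k
      }
      chunk[[r]] <- structure(
        list(model_id = id, partition = pn, blocks = bl, k = k),
        class = "model_spec")
    }
    out <- c(out, chunk)
  }
  out
}

#' Bayesian Information Criterion
#'
#' @param logL Maximized log-likelihood.
#' @param k Number of free parameters (>= 0).
#' @param n Number of observations (>= 1); here, the number of gene
#'   families.
#' @return `k * log(n) - 2 * logL`.
#' @export
bic <- function(logL, k, n) {
  if (n < 1) stop("n must be >= 1")
  if (k < 0) stop("k must be >= 0")
  k * log(n) - 2 * logL
}

#' BIC weights
#'
#' `w_m = exp(-(BIC_m - min BIC)/2)`, normalized to sum to 1: the standard
#' approximation to posterior model probabilities under equal model
#' priors.
#'
#' @param bics Numeric vector of BIC values (at least one finite).
#' @return Numeric vector of weights summing to 1.
#' @export
bic_weights <- function(bics) {
  if (!any(is.finite(bics))) stop("all BIC values are infinite")
  delta <- bics - min(bics, na.rm = TRUE)
  w <- exp(-delta / 2)
  w[!is.finite(bics)] <- 0
  w / sum(w)
}

#' Fit and score the whole model space
#'
#' Fits every enumerated model to the data and scores it by BIC and BIC
#' weight.  A model's log-likelihood is the sum of its block
#' log-likelihoods (blocks share no parameters), so block fits are cached
#' by (category set, form, heterogeneity) and reused across models — the
#' ten partitions reuse only 12 distinct category subsets.
#'
#' @param table A `gene_family_table` covering the categories used by the
#'   partitions (empty categories are permitted with a warning; their
#'   blocks contribute 0 to the log-likelihood and keep their parameter
#'   count).
#' @param tree A `"phylo"` object.
#' @param classes Branch class map (used by heterogeneous models).
#' @param models Model list from [enumerate_model_space()]; defaults to
#'   the full canonical space.
#' @param bic_n `"total"` (default: one shared n, the total number of
#'   families — models are compared on the same data) or `"block"`
#'   (per-block n summed, for sensitivity analysis).
#' @param prior_mode,multistarts Passed to [fit_block()].
#' @return A `model_score_table`: data frame with columns `model_id`,
#'   `partition`, `block_forms`, `het_flags`, `k`, `logL`, `BIC`,
#'   `weight`, `cum_weight`, `rank`, `converged`, ordered by rank
#'   (ties broken by enumeration order).  Attributes: `block_fits` (the
#'   cache of `bdi_fit`s by block key), `models` (the specs), `n` (the n
#'   used for BIC).
#' @export
fit_model_space <- function(table, tree, classes, models = NULL,
                            bic_n = c("total", "block"),
                            prior_mode = "uniform", multistarts = 5) {
  bic_n <- match.arg(bic_n)
  if (is.null(models)) models <- enumerate_model_space()
  present <- unique(table$category)
  used <- unique(unlist(lapply(models, function(m) {
    unlist(lapply(m$blocks, `[[`, "categories"))
  })))
  if (!all(used %in% present)) {
    warning("empty categories in table: ",
            paste(setdiff(used, present), collapse = ", "))
  }
  n_total <- length(table$category)
  cache <- new.env(parent = emptyenv())
  get_fit <- function(b) {
    key <- block_key(b$categories, b$form, b$het)
    if (!is.null(cache[[key]])) return(cache[[key]])
    fams <- table_families(table, b$categories)
    fit <- if (length(fams) == 0L) {
      structure(list(form = b$form, lineage_het = b$het, logL = 0,
                     k = form_n_par(b$form) * (if (b$het) 2L else 1L),
                     n_families = 0L, convergence = 0L,
                     rates = list(), class_labels = character(0)),
                class = "bdi_fit")
    } else {
      fit_block(subset_families(table, fams), tree, classes, b$form,
                lineage_het = b$het, prior_mode = prior_mode,
                multistarts = multistarts)
    }
    cache[[key]] <- fit
    fit
  }
  rows <- lapply(models, function(m) {
    fits <- lapply(m$blocks, get_fit)
    logL <- sum(vapply(fits, `[[`, numeric(1), "logL"))
    conv <- all(vapply(fits, function(f) any(f$convergence == 0L), logical(1)))
    n <- if (bic_n == "total") n_total else {
      sum(vapply(fits, `[[`, numeric(1), "n_families"))
    }
    data.frame(model_id = m$model_id, partition = m$partition,
               block_forms = paste(vapply(m$blocks, `[[`, character(1), "form"),
                                   collapse = ","),
               het_flags = paste(as.integer(vapply(m$blocks, `[[`, logical(1),
                                                   "het")), collapse = ","),
               k = m$k, logL = logL,
               BIC = bic(logL, m$k, max(1L, n)),
               converged = conv, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$weight <- bic_weights(df$BIC)
  ord <- order(df$BIC, df$model_id)
  df <- df[ord, ]
  df$rank <- seq_len(nrow(df))
  df$cum_weight <- cumsum(df$weight)
  rownames(df) <- NULL
  structure(df, class = c("model_score_table", "data.frame"),
            block_fits = as.list(cache), models = models,
            n = if (bic_n == "total") n_total else NA_integer_)
}

#' @export
print.model_score_table <- function(x, ...) {
  cat("<model_score_table> ", nrow(x), " models; top of the ranking:\n",
      sep = "")
  print.data.frame(head(as.data.frame(x)[
    c("rank", "partition", "block_forms", "het_flags", "k", "logL",
      "BIC", "weight", "cum_weight")], 5), digits = 6)
  invisible(x)
}

#' Block fits of one scored model
#'
#' @param scores A `model_score_table`.
#' @param model_id Model id as in the table.
#' @return Named list (block key -> `bdi_fit`) for that model's blocks.
#' @export
model_block_fits <- function(scores, model_id) {
  models <- attr(scores, "models")
  m <- models[[which(vapply(models, `[[`, integer(1), "model_id") == model_id)]]
  fits <- attr(scores, "block_fits")
  keys <- vapply(m$blocks, function(b) block_key(b$categories, b$form, b$het),
                 character(1))
  setNames(fits[keys], keys)
}

#' Write a model score table as TSV
#'
#' @param scores A `model_score_table`.
#' @param path Output path.
#' @export
write_score_table <- function(scores, path) {
  write.table(as.data.frame(scores)[
    c("model_id", "partition", "block_forms", "het_flags", "k", "logL",
      "BIC", "weight", "cum_weight", "converged")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
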