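GENE_CATEGORIES <- c("AutS", "AutM", "YS", "AG")
OBS_TYPES <- c("qpcr", "sequence-count", "missing", "count")

#' Gene-family observation table
#'
#' The container tying together every family's per-taxon copy-number
#' likelihood profile and its gene category.  Categories are the four used
#' throughout: autosomal singletons (`AutS`), autosomal multicopy families
#' (`AutM`), Y-chromosome singletons (`YS`) and ampliconic Y families
#' (`AG`).  Every (family, taxon) pair has a profile; unobserved cells get
#' the uninformative missing profile.
#'
#' @param profiles A named list: family id -> named list of
#'   `copy_profile`s keyed by taxon.  Taxa absent for a family are filled
#'   with [missing_profile()].
#' @param categories Named character vector: family id -> category, one of
#'   `AutS`, `AutM`, `YS`, `AG`.
#' @param taxa Character vector of all taxa (the tree's leaf labels).
#' @param n_max Largest copy-number state shared by all profiles.
#' @return A `gene_family_table`: list with elements `profiles` (3-d array
#'   state x taxon x family), `obs_type` (taxon x family character
#'   matrix), `category`, `taxa`, `n_max`.
#' @export
gene_family_table <- function(profiles, categories, taxa, n_max) {
  fams <- names(profiles)
  stopifnot(length(fams) >= 1L, !anyDuplicated(fams), !anyDuplicated(taxa))
  if (!all(fams %in% names(categories))) stop("every family needs a category")
  categories <- categories[fams]
  if (!all(categories %in% GENE_CATEGORIES)) {
    stop("categories must be one of: ", paste(GENE_CATEGORIES, collapse = ", "))
  }
  arr <- array(NA_real_, dim = c(n_max + 1L, length(taxa), length(fams)),
               dimnames = list(0:n_max, taxa, fams))
  ot <- matrix("missing", length(taxa), length(fams),
               dimnames = list(taxa, fams))
  miss <- missing_profile(n_max)
  for (f in fams) {
    pf <- profiles[[f]]
    extra <- setdiff(names(pf), taxa)
    if (length(extra)) stop("profile taxon not in taxa: ", extra[1])
    for (tx in taxa) {
      p <- pf[[tx]]
      if (is.null(p)) p <- miss
      if (length(p) != n_max + 1L) stop("profile length mismatch with n_max")
      arr[, tx, f] <- as.numeric(p)
      ot[tx, f] <- attr(p, "obs_type") %||% "missing"
    }
  }
  structure(list(profiles = arr, obs_type = ot,
                 category = categories, taxa = taxa, n_max = n_max),
            class = "gene_family_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gene_family_table <- function(x, ...) {
  cat("<gene_family_table> ", length(x$category), " families, ",
      length(x$taxa), " taxa, states 0..", x$n_max, "\n", sep = "")
  print(table(factor(x$category, GENE_CATEGORIES)))
  invisible(x)
}

#' Families of a table, optionally restricted to categories
#'
#' @param table A `gene_family_table`.
#' @param categories Categories to keep; default all.
#' @return Character vector of family ids.
#' @export
table_families <- function(table, categories = GENE_CATEGORIES) {
  names(table$category)[table$category %in% categories]
}

#' Subset a gene-family table
#'
#' @param table A `gene_family_table`.
#' @param families Family ids to keep.
#' @return A `gene_family_table` restricted to `families`.
#' @export
subset_families <- function(table, families) {
  stopifnot(all(families %in% names(table$category)))
  structure(list(profiles = table$profiles[, , families, drop = FALSE],
                 obs_type = table$obs_type[, families, drop = FALSE],
                 category = table$category[families],
                 taxa = table$taxa, n_max = table$n_max),
            class = "gene_family_table")
}

#' Read an observation TSV into a gene-family table
#'
#' Expected columns: `family`, `category`, `taxon`, `obs_type` (one of
#' `qpcr`, `sequence-count`, `missing`), `mean`, `se`, `n_unique`.  Fields
#' irrelevant to a row's `obs_type` may be empty.  Rows are converted with
#' [qpcr_profile()], [sequence_min_profile()] or [missing_profile()];
#' (family, taxon) pairs with no row are treated as missing.
#'
#' @param path Path to the TSV file.
#' @param taxa The tree's leaf labels.
#' @param n_max Largest copy-number state.
#' @param strict Passed to [qpcr_profile()].
#' @return A `gene_family_table`.
#' @export
read_observations <- function(path, taxa, n_max, strict = FALSE) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("family", "category", "taxon", "obs_type")
  if (!all(need %in% names(df))) {
    stop("observation table must have columns: ", paste(need, collapse = ", "))
  }
  observations_to_table(df, taxa, n_max, strict = strict)
}

#' Convert an observation data frame to a gene-family table
#'
#' @param df Data frame with the columns described in
#'   [read_observations()].
#' @inheritParams read_observations
#' @return A `gene_family_table`.
#' @export
observations_to_table <- function(df, taxa, n_max, strict = FALSE) {
  if (!all(df$obs_type %in% OBS_TYPES)) stop("unknown obs_type")
  if (!all(df$taxon %in% taxa)) stop("observation taxon not in tree")
  fams <- unique(df$family)
  cats <- tapply(df$category, df$family, function(x) unique(x))
  if (any(lengths(cats) != 1L)) stop("a family has more than one category")
  categories <- setNames(vapply(cats, identity, character(1))[fams], fams)
  profiles <- lapply(fams, function(f) {
    rows <- df[df$family == f, , drop = FALSE]
    if (anyDuplicated(rows$taxon)) stop("duplicate observation for one (family, taxon)")
    setNames(lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      switch(r$obs_type,
        "qpcr" = qpcr_profile(as.numeric(r$mean), as.numeric(r$se), n_max,
                              strict = strict),
        "sequence-count" = sequence_min_profile(as.integer(r$n_unique), n_max),
        "missing" = missing_profile(n_max),
        "count" = count_profile(as.integer(r$mean), n_max))
    }), rows$taxon)
  })
  names(profiles) <- fams
  gene_family_table(profiles, categories, taxa, n_max)
}

#' Export profiles as a wide TSV for audit
#'
#' One row per (family, taxon), states as columns.
#'
#' @param table A `gene_family_table`.
#' @param path Output path.
#' @export
write_profiles_wide <- function(table, path) {
  fams <- names(table$category)
  rows <- do.call(rbind, lapply(fams, function(f) {
    m <- t(table$profiles[, , f])
    data.frame(family = f, taxon = rownames(m),
               obs_type = table$obs_type[, f], m, check.names = FALSE)
  }))
  names(rows)[-(1:3)] <- paste0("s", 0:table$n_max)
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
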