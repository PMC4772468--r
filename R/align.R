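#' Read an aligned FASTA file
#'
#' Reads a nucleotide alignment and checks that all sequences have equal
#' length and use IUPAC codes (plus `-` for gaps, `?` and `.` tolerated as
#' gap synonyms and normalized to `-`).
#'
#' @param path Path to an aligned FASTA file.
#' @return An `alignment`: character matrix (sequences x columns) with
#'   taxon row names.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- tryCatch(suppressWarnings(ape::read.FASTA(path)),
                   error = function(e) NULL)
  if (is.null(seqs) || length(seqs) == 0L) stop("empty or unreadable FASTA: ", path)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  }
  m <- toupper(as.character(as.matrix(seqs)))
  m[m %in% c("?", ".")] <- "-"
  ok <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
          "B", "D", "H", "V", "N", "-")
  bad <- setdiff(unique(as.vector(m)), ok)
  if (length(bad)) stop("non-IUPAC characters in alignment: ",
                        paste(bad, collapse = " "))
  structure(m, class = c("alignment_matrix", class(m)))
}

#' Number of gap-free alignment columns
#'
#' Counts columns with no gap in any sequence (strict complete deletion,
#' the rule behind "alignment length after excluding positions with
#' gaps"); `lenient = TRUE` instead drops only columns that are gap in
#' every sequence.  Ambiguity codes are never treated as gaps.
#'
#' @param aln An alignment matrix from [read_fasta_alignment()].
#' @param lenient Use the all-gap rule instead of the any-gap rule.
#' @return Integer count of retained columns.
#' @examples
#' \dontrun{
#' aln <- read_fasta_alignment("aln.fasta")
#' c(total = ncol(aln), gapless = gapless_column_count(aln))
#' }
#' @export
gapless_column_count <- function(aln, lenient = FALSE) {
  gap <- aln == "-"
  if (lenient) sum(!apply(gap, 2, all)) else sum(!apply(gap, 2, any))
}
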