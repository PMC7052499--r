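DNA_STATES <- c("A", "C", "G", "T")

#' Coerce sequences to an alignment matrix
#'
#' Alignments are stored as plain uppercase character matrices (rows =
#' sequences, columns = alignment positions, unique rownames). Accepted
#' inputs: such a matrix, a named character vector of equal-length strings, or
#' an `ape::DNAbin` matrix.
#'
#' @param x Sequences in any of the accepted forms.
#' @return Uppercase character matrix with rownames.
#' @export
as_alignment <- function(x) {
  if (inherits(x, "DNAbin")) x <- toupper(as.character(as.matrix(x)))
  if (is.character(x) && is.null(dim(x))) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    chars <- strsplit(toupper(x), "")
    if (length(unique(lengths(chars))) != 1L) {
      stop("sequences must all have the same length")
    }
    x <- do.call(rbind, chars)
    rownames(x) <- names(chars)
  }
  stopifnot(is.matrix(x), is.character(x))
  x[] <- toupper(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("seq", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x))) stop("sequence names must be unique")
  x
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA file (all sequences the same length).
#' @return Alignment character matrix (see [as_alignment()]).
#' @export
read_alignment <- function(path) {
  as_alignment(ape::read.dna(path, format = "fasta", as.character = TRUE,
                             as.matrix = TRUE))
}

#' Write an alignment to FASTA
#'
#' @param a Alignment (see [as_alignment()]).
#' @param path Output file path.
#' @export
write_alignment <- function(a, path) {
  a <- as_alignment(a)
  lines <- character(2L * nrow(a))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(a))
  lines[c(FALSE, TRUE)] <- apply(a, 1, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Remove all alignment columns with gaps or missing data
#'
#' Complete deletion: every column containing a gap (`-`), an `N`, `?`, or any
#' IUPAC ambiguity code in any sequence is removed before analysis, leaving
#' only columns that are unambiguous A/C/G/T across all rows. Column order is
#' preserved and the operation is idempotent.
#'
#' @param a Alignment (see [as_alignment()]).
#' @return The filtered alignment; errors if no column survives.
#' @export
complete_deletion <- function(a) {
  a <- as_alignment(a)
  keep <- apply(a, 2, function(col) all(col %in% DNA_STATES))
  if (!any(keep)) stop("complete deletion removed every column")
  a[, keep, drop = FALSE]
}

#' Empirical base frequencies of an alignment
#'
#' @param a Gap-free alignment.
#' @return Named numeric vector `(A, C, G, T)` of base proportions over all
#'   cells; sums to 1.
#' @export
empirical_frequencies <- function(a) {
  a <- as_alignment(a)
  if (length(a) == 0L) stop("empty alignment")
  if (!all(a %in% DNA_STATES)) {
    stop("alignment contains non-ACGT characters; apply complete_deletion() first")
  }
  counts <- vapply(DNA_STATES, function(s) sum(a == s), numeric(1))
  counts / sum(counts)
}
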