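#' Construct an SSR genotype table
#'
#' The central container for SSR fingerprinting: allele calls (fragment sizes
#' in nucleotides with their relative electropherogram peak heights) across a
#' panel of cultivars and loci. A (cultivar, locus) cell may hold one or more
#' calls; cells listed in `missing` hold none (no amplification) and carry no
#' evidence in downstream key construction. Cells emptied later by peak-height
#' filtering are tracked separately from missing cells.
#'
#' @param calls Data frame with columns `cultivar`, `locus`, `size` (positive
#'   integer, nucleotides), `height` (positive numeric, relative fluorescence
#'   units).
#' @param cultivars,loci Ordered character vectors declaring the panel; default
#'   to the values observed in `calls` (and `missing`).
#' @param missing Data frame with columns `cultivar`, `locus` naming cells with
#'   no call; may be `NULL`.
#' @return An object of class `genotype_table`: list with elements `calls`,
#'   `cultivars`, `loci`, `missing`, `filtered` (calls removed by
#'   [filter_calls()], initially empty) and `threshold` (last filter applied,
#'   `NA` if none).
#' @export
genotype_table <- function(calls, cultivars = NULL, loci = NULL, missing = NULL) {
  stopifnot(is.data.frame(calls))
  need <- c("cultivar", "locus", "size", "height")
  if (!all(need %in% names(calls))) {
    stop("`calls` must have columns ", paste(need, collapse = ", "))
  }
  calls <- as.data.frame(calls)[need]
  calls$cultivar <- as.character(calls$cultivar)
  calls$locus <- as.character(calls$locus)
  if (anyNA(calls$size) || any(calls$size <= 0) ||
      any(calls$size != round(calls$size))) {
    stop("allele sizes must be positive integers")
  }
  calls$size <- as.integer(calls$size)
  if (anyNA(calls$height) || any(calls$height <= 0)) {
    stop("peak heights must be positive")
  }
  if (is.null(missing)) {
    missing <- data.frame(cultivar = character(), locus = character())
  } else {
    missing <- as.data.frame(missing)[c("cultivar", "locus")]
    missing$cultivar <- as.character(missing$cultivar)
    missing$locus <- as.character(missing$locus)
  }
  if (is.null(cultivars)) cultivars <- unique(c(calls$cultivar, missing$cultivar))
  if (is.null(loci)) loci <- unique(c(calls$locus, missing$locus))
  if (!all(calls$cultivar %in% cultivars)) stop("call cultivar outside declared set")
  if (!all(calls$locus %in% loci)) stop("call locus outside declared set")
  if (nrow(missing)) {
    mkey <- paste(missing$cultivar, missing$locus, sep = "\r")
    ckey <- paste(calls$cultivar, calls$locus, sep = "\r")
    if (any(ckey %in% mkey)) stop("a cell declared missing also holds calls")
  }
  structure(
    list(calls = calls, cultivars = cultivars, loci = loci,
         missing = missing,
         filtered = calls[0, , drop = FALSE], threshold = NA_real_),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf(
    "SSR genotype table: %d cultivars x %d loci, %d calls (%d filtered out, %d missing cells)%s\n",
    length(x$cultivars), length(x$loci), nrow(x$calls), nrow(x$filtered),
    nrow(x$missing),
    if (is.na(x$threshold)) "" else sprintf(", peak-height threshold %g", x$threshold)
  ))
  invisible(x)
}

#' Read an SSR genotype table from CSV
#'
#' Expects a header `cultivar,locus,allele_size,peak_height`; missing cells are
#' encoded by absent rows, optionally made explicit in a sidecar CSV with
#' columns `cultivar,locus`. Exact duplicate rows are collapsed with a warning;
#' malformed sizes or non-positive heights abort with the offending row number
#' (header = row 1).
#'
#' @param path Path to the genotype CSV.
#' @param missing_path Optional path to the missing-cell sidecar CSV.
#' @return A [genotype_table()].
#' @export
read_genotype_table <- function(path, missing_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("cultivar", "locus", "allele_size", "peak_height")
  if (!all(need %in% names(df))) {
    stop("genotype CSV must have header ", paste(need, collapse = ","))
  }
  size <- suppressWarnings(as.numeric(df$allele_size))
  bad <- which(is.na(size) | size <= 0 | size != round(size))
  if (length(bad)) {
    stop(sprintf("row %d: allele_size '%s' is not a positive integer",
                 bad[1] + 1L, df$allele_size[bad[1]]))
  }
  height <- suppressWarnings(as.numeric(df$peak_height))
  bad <- which(is.na(height) | height <= 0)
  if (length(bad)) {
    stop(sprintf("row %d: peak_height '%s' is not a positive number",
                 bad[1] + 1L, df$peak_height[bad[1]]))
  }
  calls <- data.frame(cultivar = df$cultivar, locus = df$locus,
                      size = as.integer(size), height = height)
  dup <- duplicated(calls)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate row(s)", sum(dup)))
    calls <- calls[!dup, , drop = FALSE]
  }
  missing <- if (!is.null(missing_path)) {
    utils::read.csv(missing_path, stringsAsFactors = FALSE)
  } else NULL
  genotype_table(calls, missing = missing)
}

#' Filter allele calls by relative peak height
#'
#' Low peaks are unreliable; calls with `height` strictly below the threshold
#' are moved from `calls` to `filtered` (a state distinct from missing: the
#' allele was observed but not trusted). The cultivar and locus panels are
#' unchanged. Filtering is monotone in the threshold and idempotent at a fixed
#' threshold.
#'
#' @param table A [genotype_table()].
#' @param min_peak_height Retain calls with height >= this value (default
#'   14000, the study's electropherogram quality cutoff). Heights exactly equal
#'   to the threshold are kept.
#' @return The filtered `genotype_table`.
#' @export
filter_calls <- function(table, min_peak_height = 14000) {
  stopifnot(inherits(table, "genotype_table"))
  if (length(min_peak_height) != 1L || is.na(min_peak_height) ||
      min_peak_height < 0) {
    stop("`min_peak_height` must be a single non-negative number")
  }
  keep <- table$calls$height >= min_peak_height
  table$filtered <- rbind(table$filtered, table$calls[!keep, , drop = FALSE])
  table$calls <- table$calls[keep, , drop = FALSE]
  table$threshold <- max(min_peak_height, table$threshold, na.rm = TRUE)
  table
}

#' Index alleles by their carrier cultivars
#'
#' Maps every (locus, size) pair to the set of cultivars carrying it. An allele
#' is "repeated" (shared) when its carrier set has two or more members; shared
#' alleles can never discriminate a cultivar on their own, but they can anchor
#' combination keys.
#'
#' @param table A [genotype_table()].
#' @return Data frame with columns `locus`, `size`, `cultivars` (list column of
#'   unique carrier names, sorted), `n_carriers` and `shared`
#'   (`n_carriers >= 2`), ordered by locus then size.
#' @export
shared_allele_index <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  calls <- table$calls
  if (nrow(calls) == 0L) {
    return(data.frame(locus = character(), size = integer(),
                      cultivars = I(list()), n_carriers = integer(),
                      shared = logical()))
  }
  key <- paste(calls$locus, calls$size, sep = "\r")
  carriers <- lapply(split(calls$cultivar, key), function(x) sort(unique(x)))
  parts <- strsplit(names(carriers), "\r", fixed = TRUE)
  idx <- data.frame(
    locus = vapply(parts, `[`, character(1), 1L),
    size = as.integer(vapply(parts, `[`, character(1), 2L))
  )
  idx$cultivars <- I(unname(carriers))
  idx$n_carriers <- lengths(carriers)
  idx$shared <- idx$n_carriers >= 2L
  idx <- idx[order(idx$locus, idx$size), , drop = FALSE]
  rownames(idx) <- NULL
  idx
}

check_bins <- function(bins, what) {
  bins <- lapply(bins, function(b) {
    if (length(b) != 2L || b[1] > b[2]) stop("each ", what, " bin must be c(lower, upper)")
    as.numeric(b)
  })
  if (length(bins) > 1L) {
    for (i in seq_along(bins)) for (j in seq_along(bins)) {
      if (i < j && bins[[i]][1] <= bins[[j]][2] && bins[[j]][1] <= bins[[i]][2]) {
        stop("overlapping ", what, " bins")
      }
    }
  }
  bins
}

bin_percent <- function(x, bins, what) {
  inbin <- vapply(bins, function(b) sum(x >= b[1] & x <= b[2]), integer(1))
  if (sum(inbin) < length(x)) stop(what, " bins do not cover the observed range")
  pct <- round_half_up(100 * inbin / length(x), 0L)
  names(pct) <- vapply(bins, function(b) sprintf("[%g,%g]", b[1], b[2]), character(1))
  pct
}

#' Summarize allele sizes and peak heights into bins
#'
#' @param table A [genotype_table()].
#' @param size_bins,height_bins Lists of closed integer intervals `c(lower,
#'   upper)`; the defaults reproduce the study's reporting bins (sizes below
#'   100 / 100-200 / above 200 nucleotides; heights below 10,000 / 10,000s /
#'   20,000s / 30,000 and above). Bins must not overlap and must jointly cover
#'   every observed value.
#' @return List with integer percentage vectors `size_pct` and `height_pct`
#'   (rounded half-up; they sum to 100 up to rounding), plus `size_range`,
#'   `height_range` and `n_calls`.
#' @export
summarize_alleles <- function(table,
                              size_bins = list(c(0, 99), c(100, 200), c(201, Inf)),
                              height_bins = list(c(0, 9999), c(10000, 19999),
                                                 c(20000, 29999), c(30000, Inf))) {
  stopifnot(inherits(table, "genotype_table"))
  calls <- table$calls
  if (nrow(calls) == 0L) stop("no calls to summarize")
  size_bins <- check_bins(size_bins, "size")
  height_bins <- check_bins(height_bins, "height")
  list(
    size_pct = bin_percent(calls$size, size_bins, "size"),
    height_pct = bin_percent(calls$height, height_bins, "height"),
    size_range = range(calls$size),
    height_range = range(calls$height),
    n_calls = nrow(calls)
  )
}
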