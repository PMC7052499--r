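#' Build a length-ordered karyotype from chromosome measurements
#'
#' Chromosome nomenclature for small walnut chromosomes is purely numeric:
#' chromosomes of one mitotic metaphase are numbered 1..2n from the longest to
#' the shortest measured length (arm ratios are unavailable because the
#' centromeres of chromosomes this small are usually hidden).
#'
#' @param measures A data frame with one row per chromosome of a single
#'   metaphase. Required column `length_um` (positive, micrometres). Optional
#'   columns: `metaphase_id`, `chromosome_id`, `end_signals` (integer 0-2,
#'   number of chromosome ends showing the telomeric (AG3T3)3 signal),
#'   `proximal_5S` (logical, proximal 5S rDNA signal present).
#' @return An object of class `karyotype`: a list with `metaphase_id`,
#'   `lengths` (sorted non-increasing), `numbers` (1..2n in length order),
#'   `order` (permutation mapping input rows to karyotype positions) and the
#'   original `measures`. Ties in length keep their input order (stable sort),
#'   so numbering is deterministic.
#' @examples
#' k <- build_karyotype(data.frame(length_um = c(1.0, 2.5, 1.7)))
#' k$lengths        # 2.5 1.7 1.0
#' chromosome_ratio(k)
#' @export
build_karyotype <- function(measures) {
  if (is.numeric(measures)) measures <- data.frame(length_um = measures)
  stopifnot(is.data.frame(measures))
  if (!"length_um" %in% names(measures)) {
    stop("`measures` must have a `length_um` column")
  }
  len <- measures$length_um
  if (length(len) < 2L) stop("a karyotype needs at least 2 chromosomes")
  if (anyNA(len) || any(len <= 0)) {
    stop("all chromosome lengths must be positive and non-missing")
  }
  if ("end_signals" %in% names(measures)) {
    es <- measures$end_signals
    if (any(!is.na(es) & (es < 0L | es > 2L))) {
      stop("`end_signals` must be between 0 and 2")
    }
  }
  ord <- order(-len)                      # radix order is stable in R
  mid <- if ("metaphase_id" %in% names(measures)) {
    u <- unique(measures$metaphase_id)
    if (length(u) > 1L) stop("measures span more than one metaphase")
    u
  } else NA_character_
  structure(
    list(
      metaphase_id = mid,
      lengths      = len[ord],
      numbers      = seq_along(len),
      order        = ord,
      measures     = measures[ord, , drop = FALSE]
    ),
    class = "karyotype"
  )
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf(
    "Karyotype%s: 2n = %d, lengths %.2f-%.2f um, ratio %.2f\n",
    if (is.na(x$metaphase_id)) "" else paste0(" [", x$metaphase_id, "]"),
    length(x$lengths), max(x$lengths), min(x$lengths), chromosome_ratio(x)
  ))
  invisible(x)
}

# round-half-up (commercial rounding); base round() rounds half to even,
# which would turn e.g. 2.705 into 2.70 instead of 2.71
round_half_up <- function(x, decimals = 2L) {
  p <- 10^decimals
  floor(x * p + 0.5) / p
}

#' Longest/shortest chromosome ratio of a karyotype
#'
#' The karyotype ratio (a coarse asymmetry index for karyotypes whose arm
#' ratios cannot be measured) is the length of the longest chromosome divided
#' by the length of the shortest, rounded half-up.
#'
#' @param k A `karyotype` from [build_karyotype()], or a numeric vector of
#'   lengths.
#' @param decimals Decimal places for half-up rounding (default 2).
#' @return The rounded ratio, always >= 1; exactly 1 iff all lengths are equal.
#' @examples
#' chromosome_ratio(c(2.16, 1.5, 0.97))  # 2.23
#' @export
chromosome_ratio <- function(k, decimals = 2L) {
  lengths <- if (inherits(k, "karyotype")) k$lengths else as.numeric(k)
  if (length(lengths) == 0L) stop("empty karyotype")
  if (any(lengths <= 0)) stop("lengths must be positive")
  round_half_up(max(lengths) / min(lengths), decimals)
}

#' Aggregate karyotype ratios over several metaphases
#'
#' Measurements are taken over multiple metaphase spreads (typically 3); the
#' summary ratio is the arithmetic mean of the per-metaphase ratios.
#'
#' @param karyotypes A list of `karyotype` objects (at least one).
#' @param decimals Decimal places for rounding each per-metaphase ratio.
#' @return A list with `mean_ratio` and the numeric vector `ratios` (named by
#'   metaphase id when available).
#' @export
aggregate_ratios <- function(karyotypes, decimals = 2L) {
  if (inherits(karyotypes, "karyotype")) karyotypes <- list(karyotypes)
  if (length(karyotypes) == 0L) stop("need at least one karyotype")
  ratios <- vapply(karyotypes, chromosome_ratio, numeric(1), decimals = decimals)
  ids <- vapply(karyotypes, function(k) as.character(k$metaphase_id), character(1))
  if (!all(is.na(ids) | ids == "NA")) names(ratios) <- ids
  list(mean_ratio = mean(ratios), ratios = ratios)
}

#' Count chromosomes by telomeric end signals
#'
#' A chromosome is counted as reliably observed only when the telomeric
#' (AG3T3)3 probe lights up both of its ends; chromosomes with fewer than two
#' end signals are flagged as uncounted rather than silently included.
#'
#' @param measures Data frame with an `end_signals` column (integer 0-2).
#' @return List with `count` (rows with both end signals), `flagged` (the rows
#'   with fewer than 2 signals) and `total` rows examined.
#' @export
count_by_end_signals <- function(measures) {
  stopifnot(is.data.frame(measures))
  if (nrow(measures) == 0L) {
    return(list(count = 0L, flagged = measures, total = 0L))
  }
  if (!"end_signals" %in% names(measures)) {
    stop("`measures` must carry an `end_signals` column")
  }
  es <- measures$end_signals
  if (any(!is.na(es) & (es < 0L | es > 2L))) {
    stop("`end_signals` must be between 0 and 2")
  }
  ok <- !is.na(es) & es == 2L
  list(count = sum(ok), flagged = measures[!ok, , drop = FALSE],
       total = nrow(measures))
}

#' Read chromosome measurements and analyse each metaphase
#'
#' Convenience reader for a measurements CSV with columns `metaphase_id`,
#' `chromosome_id`, `length_um` and optionally `end_signals`, `proximal_5S`.
#'
#' @param path Path to the CSV file.
#' @param decimals Rounding for ratios.
#' @return A list with `karyotypes` (one per metaphase), the per-metaphase
#'   `ratios` and their `mean_ratio`.
#' @export
read_karyotype_csv <- function(path, decimals = 2L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("metaphase_id", "length_um") %in% names(df))) {
    stop("CSV must have columns metaphase_id and length_um")
  }
  ks <- lapply(split(df, df$metaphase_id), build_karyotype)
  agg <- aggregate_ratios(ks, decimals = decimals)
  list(karyotypes = ks, ratios = agg$ratios, mean_ratio = agg$mean_ratio)
}
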