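#' Cultivar-exclusive single-locus alleles
#'
#' After peak-height filtering, an allele (locus, size) carried by exactly one
#' cultivar identifies that cultivar on its own. Shared ("repeated") alleles
#' are excluded here but remain available as anchors for combination keys.
#'
#' @param table A peak-height-filtered [genotype_table()].
#' @return Named list, one entry per cultivar of the table (in panel order),
#'   each a data frame with columns `locus`, `size` ordered by locus name then
#'   size; empty for cultivars with no exclusive allele.
#' @export
unique_allele_keys <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  idx <- shared_allele_index(table)
  out <- stats::setNames(
    rep(list(data.frame(locus = character(), size = integer())),
        length(table$cultivars)),
    table$cultivars
  )
  uniq <- idx[idx$n_carriers == 1L, , drop = FALSE]
  for (i in seq_len(nrow(uniq))) {
    cv <- uniq$cultivars[[i]][1]
    out[[cv]] <- rbind(out[[cv]],
                       data.frame(locus = uniq$locus[i], size = uniq$size[i]))
  }
  lapply(out, function(df) {
    df <- df[order(df$locus, df$size), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
}

# alleles carried by `cultivar` (unique locus/size pairs, sorted)
carried_alleles <- function(table, cultivar) {
  df <- table$calls[table$calls$cultivar == cultivar, c("locus", "size")]
  df <- unique(df)
  df <- df[order(df$locus, df$size), , drop = FALSE]
  rownames(df) <- NULL
  df
}

has_allele <- function(table, cultivar, locus, size) {
  any(table$calls$cultivar == cultivar & table$calls$locus == locus &
        table$calls$size == size)
}

cell_missing <- function(table, cultivar, locus) {
  any(table$missing$cultivar == cultivar & table$missing$locus == locus)
}

#' Combination and conjunction keys for cultivars lacking exclusive alleles
#'
#' A cultivar with no exclusive allele can still be discerned by an
#' anchor-plus-exclusion rule: take a shared allele it carries (the anchor)
#' whose other carriers all have single-locus keys of their own; a sample
#' matching the anchor but none of those carriers' exclusive alleles must be
#' this cultivar. When no anchor qualifies, fall back to a greedy minimal set
#' of carried alleles whose joint presence separates the cultivar from every
#' other (a conjunction rule). Absence at a missing cell is never used as
#' evidence against a cultivar. Cultivars separable from no rule (identical
#' non-missing profiles) are reported unresolved, not an error.
#'
#' @param table A peak-height-filtered [genotype_table()].
#' @param partial Output of [unique_allele_keys()] on the same table.
#' @return List with `keys` (named list cultivar -> rule for each cultivar with
#'   an empty `partial` entry that could be resolved) and `unresolved`
#'   (character vector).
#' @export
combination_keys <- function(table, partial) {
  stopifnot(inherits(table, "genotype_table"))
  idx <- shared_allele_index(table)
  need <- names(partial)[vapply(partial, nrow, integer(1)) == 0L]
  keys <- list()
  unresolved <- character()
  for (cv in need) {
    rule <- anchor_rule(table, idx, partial, cv)
    if (is.null(rule)) rule <- greedy_cover_rule(table, cv)
    if (is.null(rule)) unresolved <- c(unresolved, cv) else keys[[cv]] <- rule
  }
  list(keys = keys, unresolved = unresolved)
}

# anchor+exclusion rule: shared allele of cv whose co-carriers all have single
# keys; choose the smallest co-carrier set, tie-break locus name then size.
# The anchor's absence separates cv from non-carriers, so it must sit at a
# locus where no non-carrier has a missing cell (missing is not evidence).
anchor_rule <- function(table, idx, partial, cv) {
  mine <- idx[vapply(idx$cultivars, function(s) cv %in% s, logical(1)) &
                idx$shared, , drop = FALSE]
  if (nrow(mine) == 0L) return(NULL)
  ok <- vapply(seq_len(nrow(mine)), function(i) {
    carriers <- mine$cultivars[[i]]
    co <- setdiff(carriers, cv)
    non <- setdiff(table$cultivars, carriers)
    all(vapply(co, function(d) nrow(partial[[d]]) > 0L, logical(1))) &&
      !any(vapply(non, cell_missing, logical(1), table = table,
                  locus = mine$locus[i]))
  }, logical(1))
  mine <- mine[ok, , drop = FALSE]
  if (nrow(mine) == 0L) return(NULL)
  mine <- mine[order(mine$n_carriers, mine$locus, mine$size), , drop = FALSE]
  co <- setdiff(mine$cultivars[[1]], cv)
  list(type = "combination", cultivar = cv,
       anchor = list(locus = mine$locus[1], size = mine$size[1]),
       excluded = stats::setNames(lapply(co, function(d) partial[[d]]), co))
}

# greedy minimal conjunction: alleles of cv jointly absent-from every other
# cultivar; absence at a missing cell carries no evidence
greedy_cover_rule <- function(table, cv) {
  alleles <- carried_alleles(table, cv)
  others <- setdiff(table$cultivars, cv)
  if (nrow(alleles) == 0L || length(others) == 0L) return(NULL)
  # separates[i, j]: allele i is evidence against cultivar j
  separates <- vapply(others, function(d) {
    vapply(seq_len(nrow(alleles)), function(i) {
      !has_allele(table, d, alleles$locus[i], alleles$size[i]) &&
        !cell_missing(table, d, alleles$locus[i])
    }, logical(1))
  }, logical(nrow(alleles)))
  separates <- matrix(separates, nrow = nrow(alleles),
                      dimnames = list(NULL, others))
  uncovered <- others
  chosen <- integer()
  while (length(uncovered)) {
    gain <- rowSums(separates[, uncovered, drop = FALSE])
    gain[chosen] <- -1L
    if (max(gain) <= 0L) return(NULL)   # some cultivar cannot be separated
    best <- which(gain == max(gain))
    best <- best[order(alleles$locus[best], alleles$size[best])][1]
    chosen <- c(chosen, best)
    uncovered <- uncovered[!separates[best, uncovered]]
  }
  list(type = "conjunction", cultivar = cv,
       alleles = alleles[sort(chosen), , drop = FALSE])
}

#' Build the cultivar identification key
#'
#' Composition of the full keying procedure: peak-height filtering, exclusive
#' single-locus alleles, then anchor-plus-exclusion (or greedy conjunction)
#' rules for the cultivars not yet discerned. "Repeated" (shared) alleles are
#' removed at key-construction time — they cannot serve as single-locus keys —
#' rather than deleted from the table, so they remain available as anchors.
#'
#' @param raw_table A [genotype_table()] (unfiltered).
#' @param min_peak_height Peak-height cutoff passed to [filter_calls()].
#' @return An object of class `identification_key`: list with `keys` (named
#'   list cultivar -> list of rules; single-locus rules have `type = "single"`
#'   and any one matching allele suffices), `unresolved`, `loci_used`,
#'   `threshold`, `panel_loci`, `panel_cultivars`, and `selected` (the allele
#'   records backing the key: one row per single-locus key allele plus the
#'   keyed cultivar's own anchor/conjunction records, with peak heights).
#' @export
build_key <- function(raw_table, min_peak_height = 14000) {
  stopifnot(inherits(raw_table, "genotype_table"))
  table <- filter_calls(raw_table, min_peak_height)
  partial <- unique_allele_keys(table)
  combo <- combination_keys(table, partial)
  keys <- list()
  for (cv in table$cultivars) {
    if (nrow(partial[[cv]]) > 0L) {
      keys[[cv]] <- lapply(seq_len(nrow(partial[[cv]])), function(i) {
        list(type = "single", cultivar = cv,
             locus = partial[[cv]]$locus[i], size = partial[[cv]]$size[i])
      })
    } else if (cv %in% names(combo$keys)) {
      keys[[cv]] <- list(combo$keys[[cv]])
    }
  }
  selected <- key_selected_records(table, keys)
  loci_used <- sort(unique(unlist(lapply(keys, function(rules) {
    unlist(lapply(rules, rule_loci))
  }))))
  structure(
    list(keys = keys, unresolved = combo$unresolved, loci_used = loci_used,
         threshold = min_peak_height, panel_loci = table$loci,
         panel_cultivars = table$cultivars, selected = selected),
    class = "identification_key"
  )
}

rule_loci <- function(rule) {
  switch(rule$type,
    single = rule$locus,
    combination = c(rule$anchor$locus,
                    unlist(lapply(rule$excluded, function(df) df$locus))),
    conjunction = rule$alleles$locus
  )
}

# allele records backing the key: each rule's own-cultivar calls
key_selected_records <- function(table, keys) {
  rows <- list()
  for (cv in names(keys)) for (rule in keys[[cv]]) {
    al <- switch(rule$type,
      single = data.frame(locus = rule$locus, size = rule$size),
      combination = data.frame(locus = rule$anchor$locus, size = rule$anchor$size),
      conjunction = rule$alleles
    )
    for (i in seq_len(nrow(al))) {
      hit <- table$calls[table$calls$cultivar == cv &
                           table$calls$locus == al$locus[i] &
                           table$calls$size == al$size[i], , drop = FALSE]
      rows[[length(rows) + 1L]] <- hit
    }
  }
  out <- unique(do.call(rbind, c(rows, list(table$calls[0, ]))))
  out <- out[order(out$cultivar, out$locus, out$size), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.identification_key <- function(x, ...) {
  cat(sprintf(
    "Identification key: %d/%d cultivars resolved, %d loci used, threshold %g\n",
    length(x$keys), length(x$panel_cultivars), length(x$loci_used), x$threshold))
  for (cv in names(x$keys)) {
    lab <- vapply(x$keys[[cv]], function(r) {
      switch(r$type,
        single = sprintf("%s (%d)", r$locus, r$size),
        combination = sprintf("%s (%d) excluding %s", r$anchor$locus,
                              r$anchor$size,
                              paste(names(r$excluded), collapse = ", ")),
        conjunction = paste(sprintf("%s (%d)", r$alleles$locus, r$alleles$size),
                            collapse = " AND ")
      )
    }, character(1))
    cat(sprintf("  %s: %s\n", cv, paste(lab, collapse = " or ")))
  }
  if (length(x$unresolved)) {
    cat("  unresolved:", paste(x$unresolved, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify a sample against an identification key
#'
#' A cultivar matches when any of its single-locus alleles is present, when a
#' combination rule's anchor is present and none of its excluded cultivars'
#' exclusive alleles are present, or when all alleles of a conjunction rule
#' are present. Peak heights of the sample are not re-filtered here.
#'
#' @param sample_calls Data frame with columns `locus`, `size` (a `height`
#'   column is allowed and ignored), or a [genotype_table()] holding one
#'   cultivar's calls.
#' @param key An [build_key()] result.
#' @return List with `status` (`"match"`, `"ambiguous"` or `"unknown"`),
#'   `cultivar` (the match, or `NA`) and `candidates` (all matching cultivars).
#'   Calls at loci outside the key's panel are ignored with a warning.
#' @export
classify <- function(sample_calls, key) {
  stopifnot(inherits(key, "identification_key"))
  if (inherits(sample_calls, "genotype_table")) sample_calls <- sample_calls$calls
  sample_calls <- as.data.frame(sample_calls)
  if (nrow(sample_calls) > 0L &&
      !all(c("locus", "size") %in% names(sample_calls))) {
    stop("`sample_calls` needs columns locus and size")
  }
  if (nrow(sample_calls) > 0L) {
    alien <- !(sample_calls$locus %in% key$panel_loci)
    if (any(alien)) {
      warning(sprintf("ignoring %d call(s) at loci outside the key's panel: %s",
                      sum(alien),
                      paste(unique(sample_calls$locus[alien]), collapse = ", ")))
      sample_calls <- sample_calls[!alien, , drop = FALSE]
    }
  }
  present <- function(locus, size) {
    any(sample_calls$locus == locus & sample_calls$size == size)
  }
  rule_matches <- function(rule) {
    switch(rule$type,
      single = present(rule$locus, rule$size),
      combination = present(rule$anchor$locus, rule$anchor$size) &&
        !any(vapply(rule$excluded, function(df) {
          any(vapply(seq_len(nrow(df)),
                     function(i) present(df$locus[i], df$size[i]), logical(1)))
        }, logical(1))),
      conjunction = all(vapply(seq_len(nrow(rule$alleles)), function(i) {
        present(rule$alleles$locus[i], rule$alleles$size[i])
      }, logical(1)))
    )
  }
  candidates <- names(key$keys)[vapply(key$keys, function(rules) {
    any(vapply(rules, rule_matches, logical(1)))
  }, logical(1))]
  status <- if (length(candidates) == 1L) "match"
            else if (length(candidates) > 1L) "ambiguous" else "unknown"
  list(status = status,
       cultivar = if (status == "match") candidates else NA_character_,
       candidates = candidates)
}
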