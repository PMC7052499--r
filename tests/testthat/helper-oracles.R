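# Independent brute-force oracles used to check the package's implementations.
# These deliberately share no code with the functions they verify.

# exhaustive log likelihood: enumerate all internal-node state assignments
oracle_loglik <- function(tree, a, model) {
  a <- walnutid::as_alignment(a)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  states <- 1:4
  leaf_state <- function(ch) match(ch, c("A", "C", "G", "T"))
  total <- 0
  for (col in seq_len(ncol(a))) {
    site_lik <- 0
    grid <- as.matrix(expand.grid(rep(list(states), nint)))
    for (g in seq_len(nrow(grid))) {
      st <- integer(ntip + nint)
      st[seq_len(ntip)] <- leaf_state(a[tree$tip.label, col])
      st[ntip + seq_len(nint)] <- grid[g, ]
      p <- unname(model$freqs[st[ntip + 1L]])
      for (e in seq_len(nrow(tree$edge))) {
        P <- walnutid::tn93_probability(model, tree$edge.length[e])
        p <- p * P[st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
      }
      site_lik <- site_lik + p
    }
    total <- total + log(site_lik)
  }
  total
}

# direct double-loop uniqueness scan: cultivar -> exclusive (locus, size) pairs
oracle_unique_alleles <- function(table) {
  calls <- table$calls
  out <- lapply(table$cultivars, function(cv) {
    mine <- unique(calls[calls$cultivar == cv, c("locus", "size")])
    keep <- logical(nrow(mine))
    for (i in seq_len(nrow(mine))) {
      others <- calls[calls$cultivar != cv & calls$locus == mine$locus[i] &
                        calls$size == mine$size[i], ]
      keep[i] <- nrow(others) == 0L
    }
    mine <- mine[keep, , drop = FALSE]
    mine[order(mine$locus, mine$size), , drop = FALSE]
  })
  names(out) <- table$cultivars
  out
}

# does allele set S (rows of data.frame locus/size, all carried by cv)
# separate cv from every other cultivar? Missing cells carry no evidence.
oracle_separates <- function(table, cv, S) {
  for (d in setdiff(table$cultivars, cv)) {
    hit <- FALSE
    for (i in seq_len(nrow(S))) {
      carried <- any(table$calls$cultivar == d &
                       table$calls$locus == S$locus[i] &
                       table$calls$size == S$size[i])
      missing <- any(table$missing$cultivar == d &
                       table$missing$locus == S$locus[i])
      if (!carried && !missing) { hit <- TRUE; break }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

# exhaustive minimum separating subset (size <= max_k) of cv's alleles;
# returns Inf when even the full allele set fails
oracle_min_cover <- function(table, cv, max_k = 3L) {
  al <- unique(table$calls[table$calls$cultivar == cv, c("locus", "size")])
  al <- al[order(al$locus, al$size), , drop = FALSE]
  if (!oracle_separates(table, cv, al)) return(Inf)
  for (k in seq_len(min(max_k, nrow(al)))) {
    for (comb in utils::combn(seq_len(nrow(al)), k, simplify = FALSE)) {
      if (oracle_separates(table, cv, al[comb, , drop = FALSE])) return(k)
    }
  }
  NA_integer_   # separable but only by a subset larger than max_k
}

# exhaustive check for anchor+exclusion resolvability of cv
oracle_anchor_possible <- function(table, cv) {
  uniq <- oracle_unique_alleles(table)
  al <- unique(table$calls[table$calls$cultivar == cv, c("locus", "size")])
  for (i in seq_len(nrow(al))) {
    carriers <- unique(table$calls$cultivar[
      table$calls$locus == al$locus[i] & table$calls$size == al$size[i]])
    co <- setdiff(carriers, cv)
    non <- setdiff(table$cultivars, carriers)
    non_missing_ok <- !any(vapply(non, function(d) {
      any(table$missing$cultivar == d & table$missing$locus == al$locus[i])
    }, logical(1)))
    if (length(co) >= 1L && non_missing_ok &&
        all(vapply(co, function(d) nrow(uniq[[d]]) > 0L, logical(1)))) {
      return(TRUE)
    }
  }
  FALSE
}

# small random genotype table for property tests
random_genotype_table <- function(seed, n_cultivars = 5L, n_loci = 6L,
                                  pool = 3L, p_missing = 0.05) {
  set.seed(seed)
  cultivars <- paste0("cv", seq_len(n_cultivars))
  loci <- paste0("L", seq_len(n_loci))
  base <- sample(seq(100L, 180L, 2L), n_loci)
  rows <- list()
  missing <- list()
  for (cv in cultivars) for (li in seq_len(n_loci)) {
    if (stats::runif(1) < p_missing) {
      missing[[length(missing) + 1L]] <- data.frame(cultivar = cv, locus = loci[li])
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        cultivar = cv, locus = loci[li],
        size = base[li] + 2L * sample.int(pool, 1),
        height = stats::runif(1, 200, 33000)
      )
    }
  }
  walnutid::genotype_table(
    do.call(rbind, rows),
    cultivars = cultivars, loci = loci,
    missing = if (length(missing)) do.call(rbind, missing) else NULL
  )
}

# random unrooted tree with branch lengths, for likelihood/NJ tests
random_tree <- function(n, seed, min_len = 0.02, max_len = 0.3) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  tr
}

# Kimura two-parameter closed-form distance
k2p_distance <- function(P, Q) {
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}
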