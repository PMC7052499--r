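#' Configuration for the SSR genotype-table simulator
#'
#' Defaults emulate the structure of the worked-example dataset: a 9-cultivar
#' x 21-locus panel, one planted cultivar-exclusive allele per cultivar,
#' shared filler alleles everywhere else, and lognormal relative peak heights
#' whose 0.25/99.75 percentiles sit at the observed envelope 201-32,722.
#' Planted alleles draw their heights uniformly from 14,643-32,607 (the
#' observed range of key-worthy peaks), so they always survive the default
#' 14,000 filter.
#'
#' @param n_cultivars,n_loci Panel dimensions.
#' @param allele_pool_per_locus Number of shared filler allele sizes per locus.
#' @param planted_unique_per_cultivar Exclusive alleles planted per cultivar;
#'   must not exceed `allele_pool_per_locus` (or the locus count).
#' @param height_meanlog,height_sdlog Lognormal parameters for filler peak
#'   heights.
#' @param missing_cells Data frame with columns `cultivar`, `locus` (indices
#'   or names) of cells to leave empty; `NULL` for none.
#' @param seed Integer seed; simulation is a pure function of config + seed.
#' @return List of class `genotype_sim_config`.
#' @export
genotype_sim_config <- function(n_cultivars = 9L, n_loci = 21L,
                                allele_pool_per_locus = 4L,
                                planted_unique_per_cultivar = 1L,
                                height_meanlog = (log(201) + log(32722)) / 2,
                                height_sdlog =
                                  (log(32722) - log(201)) / (2 * stats::qnorm(0.9975)),
                                missing_cells = NULL, seed = 1L) {
  stopifnot(n_cultivars >= 1L, n_loci >= 1L, allele_pool_per_locus >= 1L,
            planted_unique_per_cultivar >= 0L)
  if (planted_unique_per_cultivar > allele_pool_per_locus) {
    stop("planted alleles per cultivar exceed the allele pool size")
  }
  if (planted_unique_per_cultivar > n_loci) {
    stop("cannot plant more exclusive alleles than loci")
  }
  structure(list(
    n_cultivars = as.integer(n_cultivars), n_loci = as.integer(n_loci),
    allele_pool_per_locus = as.integer(allele_pool_per_locus),
    planted_unique_per_cultivar = as.integer(planted_unique_per_cultivar),
    height_meanlog = height_meanlog, height_sdlog = height_sdlog,
    missing_cells = missing_cells, seed = as.integer(seed)
  ), class = "genotype_sim_config")
}

#' Simulate an SSR genotype table
#'
#' Every non-missing cell receives one call. Filler alleles at a locus are
#' drawn from a small shared pool and post-adjusted so each used filler size
#' is carried by at least two cultivars (a singleton filler is merged into
#' the locus's most common filler); planted exclusive alleles take sizes
#' outside every filler pool, so they are cultivar-exclusive by construction
#' and their peaks are always above the 14,000 threshold.
#'
#' @param cfg A [genotype_sim_config()].
#' @return A [genotype_table()].
#' @export
simulate_genotype_table <- function(cfg) {
  stopifnot(inherits(cfg, "genotype_sim_config"))
  with_seed(cfg$seed, {
    cultivars <- sprintf("cultivar%02d", seq_len(cfg$n_cultivars))
    loci <- sprintf("locus%02d", seq_len(cfg$n_loci))
    base <- sample(seq(90L, 200L, by = 2L), cfg$n_loci, replace = TRUE)
    pool <- lapply(base, function(b) b + 2L * seq_len(cfg$allele_pool_per_locus))
    missing <- if (is.null(cfg$missing_cells)) {
      data.frame(cultivar = character(), locus = character())
    } else {
      mc <- as.data.frame(cfg$missing_cells)
      data.frame(
        cultivar = if (is.numeric(mc$cultivar)) cultivars[mc$cultivar] else mc$cultivar,
        locus = if (is.numeric(mc$locus)) loci[mc$locus] else mc$locus
      )
    }
    is_missing <- function(cv, lc) {
      any(missing$cultivar == cv & missing$locus == lc)
    }
    # planted exclusive alleles: distinct loci per cultivar (cycled), sizes
    # offset beyond the filler pool so no filler can collide
    planted <- data.frame(cultivar = character(), locus = character(),
                          size = integer())
    if (cfg$planted_unique_per_cultivar > 0L) {
      for (ci in seq_len(cfg$n_cultivars)) {
        lidx <- ((ci - 1L + seq_len(cfg$planted_unique_per_cultivar) - 1L) %%
                   cfg$n_loci) + 1L
        planted <- rbind(planted, data.frame(
          cultivar = cultivars[ci], locus = loci[lidx],
          size = base[lidx] + 2L * (cfg$allele_pool_per_locus + ci)
        ))
      }
    }
    calls <- list()
    for (li in seq_len(cfg$n_loci)) {
      cells <- cultivars[!vapply(cultivars, is_missing, logical(1),
                                 lc = loci[li])]
      pl <- planted[planted$locus == loci[li], , drop = FALSE]
      filler_cvs <- setdiff(cells, pl$cultivar)
      if (length(filler_cvs)) {
        k <- max(1L, min(cfg$allele_pool_per_locus, length(filler_cvs) %/% 2L))
        idx <- sample.int(k, length(filler_cvs), replace = TRUE)
        tab <- table(idx)
        lonely <- as.integer(names(tab)[tab == 1L])
        if (length(lonely) && length(filler_cvs) > 1L) {
          top <- as.integer(names(tab)[which.max(tab)])
          if (top %in% lonely) top <- setdiff(idx, lonely)[1]
          if (is.na(top)) top <- idx[1]
          idx[idx %in% lonely] <- top
        }
        calls[[length(calls) + 1L]] <- data.frame(
          cultivar = filler_cvs, locus = loci[li],
          size = pool[[li]][idx],
          height = stats::rlnorm(length(filler_cvs), cfg$height_meanlog,
                                 cfg$height_sdlog)
        )
      }
      if (nrow(pl)) {
        pl$height <- stats::runif(nrow(pl), 14643, 32607)
        calls[[length(calls) + 1L]] <- pl
      }
    }
    calls <- do.call(rbind, calls)
    calls <- calls[order(calls$cultivar, calls$locus, calls$size), ]
    rownames(calls) <- NULL
    genotype_table(calls, cultivars = cultivars, loci = loci, missing = missing)
  })
}

#' Simulate sequence evolution on a tree under TN93
#'
#' Sites evolve independently: the root state is drawn from the model's
#' stationary frequencies and each branch applies the TN93 transition
#' probabilities for its length. The output is a pure function of the tree,
#' model, site count and seed.
#'
#' @param tree `ape::phylo` with branch lengths (substitutions/site).
#' @param model A [tn93_model()] (its frequency vector must sum to 1, which
#'   the constructor enforces).
#' @param n_sites Number of alignment columns (>= 1).
#' @param seed Integer seed.
#' @return Alignment character matrix with the tree's leaf labels as rownames.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "tn93_model"),
            n_sites >= 1L)
  with_seed(seed, {
    tree <- stats::reorder(tree, "postorder")
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    states <- vector("list", ntip + tree$Nnode)
    states[[root]] <- sample.int(4L, n_sites, replace = TRUE,
                                 prob = model$freqs)
    for (e in rev(seq_len(nrow(tree$edge)))) {   # preorder: parent before child
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      P <- tn93_probability(model, tree$edge.length[e])
      s <- states[[parent]]
      out <- integer(n_sites)
      for (st in 1:4) {
        at <- which(s == st)
        if (length(at)) {
          out[at] <- sample.int(4L, length(at), replace = TRUE, prob = P[st, ])
        }
      }
      states[[child]] <- out
    }
    m <- do.call(rbind, lapply(seq_len(ntip), function(i) DNA_STATES[states[[i]]]))
    rownames(m) <- tree$tip.label
    m
  })
}
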