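# the nine cultivars of the SSR panel, in study order
WALNUT_CULTIVARS <- c("Chuanzao 1", "Chuanzao 2", "Shuangzao", "Shuling",
                      "Shimianju", "Meigupao", "Muzhilinhe", "Maerkang",
                      "Yanyuanzao")

# the 21-locus SSR panel
WALNUT_LOCI <- c("CUJRA123", "CUJRA124", "CUJRA206a", "CUJRB012", "CUJRB103a",
                 "CUJRB218", "CUJRB220", "CUJRB305", "CUJRB307", "CUJRB317",
                 "CUJRC310", "CUJRD204a", "JH2753", "JUG-13", "JSI-15",
                 "JSI-63", "JSI-71", "JSI-73", "JRE-28", "JRE-46", "ZMZ11")

# the reported discriminating allele records (cultivar, locus, size): the 20
# cultivar-exclusive alleles plus the shared ZMZ11:148 anchor on its three
# carriers (Shuling and the two cultivars it must exclude)
WALNUT_KEY_RECORDS <- local({
  rec <- rbind(
    c("Chuanzao 1", "CUJRB307", 116), c("Chuanzao 1", "CUJRA206a", 182),
    c("Chuanzao 2", "JSI-73", 154),
    c("Shuangzao", "CUJRB103a", 123), c("Shuangzao", "CUJRB218", 144),
    c("Shuangzao", "JSI-71", 146), c("Shuangzao", "CUJRA206a", 176),
    c("Shimianju", "ZMZ11", 138),
    c("Meigupao", "CUJRB218", 149), c("Meigupao", "CUJRB103a", 151),
    c("Meigupao", "CUJRA206a", 190),
    c("Muzhilinhe", "CUJRB220", 136), c("Muzhilinhe", "ZMZ11", 147),
    c("Muzhilinhe", "CUJRC310", 156), c("Muzhilinhe", "JSI-73", 166),
    c("Maerkang", "CUJRA124", 154), c("Maerkang", "CUJRB218", 159),
    c("Maerkang", "CUJRA123", 182),
    c("Yanyuanzao", "CUJRA124", 150), c("Yanyuanzao", "CUJRA206a", 192),
    c("Shuling", "ZMZ11", 148),
    c("Chuanzao 1", "ZMZ11", 148), c("Yanyuanzao", "ZMZ11", 148)
  )
  data.frame(cultivar = rec[, 1], locus = rec[, 2],
             size = as.integer(rec[, 3]))
})

# Shuling's six failed loci are not individually reported; fixed here to six
# panel loci that appear in no discriminating record (documented constant)
WALNUT_MISSING_LOCI <- c("CUJRB012", "CUJRB305", "CUJRB317", "CUJRD204a",
                         "JH2753", "JUG-13")

#' Worked-example dataset: nine Sichuan walnut cultivars
#'
#' The packaged worked example: the 9-cultivar x 21-locus SSR genotype table
#' and the four cultivars' extreme chromosome lengths. The discriminating
#' allele records (sizes) and the six missing Shuling cells are the reported
#' values; everything not individually reported is a synthetic reconstruction:
#' each remaining cell carries a per-locus filler allele (size 200 + locus
#' index) shared by every non-keyed cultivar at that locus, at peak height
#' 30,000, so fillers can never discriminate. Peak heights of the
#' discriminating records are spread evenly over the reported selected-record
#' range 14,643-32,607 (only the range was reported), with the extremes
#' assigned to the first and last record.
#'
#' @return List with `genotypes` (a [genotype_table()] holding 183 calls and
#'   6 missing cells), `karyotype_extremes` (data frame of the four FISH-typed
#'   cultivars' longest/shortest chromosome lengths in micrometres) and
#'   `key_records` (the reported discriminating records). Byte-identical
#'   across calls.
#' @examples
#' fx <- walnut_fixture()
#' build_key(fx$genotypes)
#' @export
walnut_fixture <- function() {
  rec <- WALNUT_KEY_RECORDS
  # the 21 selected records (rows 1-21) span the reported height range, with
  # the extremes on the first and last; the two extra anchor carriers (rows
  # 22-23) get a mid-range height
  rec$height <- c(round(seq(14643, 32607, length.out = 21L), 1), 25000, 25000)
  missing <- data.frame(cultivar = "Shuling", locus = WALNUT_MISSING_LOCI)
  filler <- list()
  for (li in seq_along(WALNUT_LOCI)) {
    lc <- WALNUT_LOCI[li]
    open <- setdiff(WALNUT_CULTIVARS, rec$cultivar[rec$locus == lc])
    open <- setdiff(open, missing$cultivar[missing$locus == lc])
    if (length(open)) {
      filler[[length(filler) + 1L]] <- data.frame(
        cultivar = open, locus = lc, size = 200L + li, height = 30000
      )
    }
  }
  calls <- rbind(rec, do.call(rbind, filler))
  calls <- calls[order(match(calls$cultivar, WALNUT_CULTIVARS),
                       match(calls$locus, WALNUT_LOCI), calls$size), ]
  rownames(calls) <- NULL
  karyo <- data.frame(
    cultivar = c("Chuanzao 1", "Muzhilinhe", "Maerkang", "Yanyuanzao"),
    shortest_um = c(0.97, 1.00, 0.98, 0.98),
    longest_um = c(2.16, 2.54, 2.65, 2.13)
  )
  list(
    genotypes = genotype_table(calls, cultivars = WALNUT_CULTIVARS,
                               loci = WALNUT_LOCI, missing = missing),
    karyotype_extremes = karyo,
    key_records = rec
  )
}

#' Synthetic 34-chromosome length set for a fixture cultivar
#'
#' Full per-chromosome lengths were not reported (only the extremes); this
#' helper builds a synthetic descending 34-length series interpolating
#' linearly between a cultivar's reported longest and shortest lengths, for
#' demonstrating [build_karyotype()] end to end. Its ratio equals the ratio of
#' the reported extremes.
#'
#' @param cultivar One of the four FISH-typed cultivars.
#' @param n Number of chromosomes (2n; default 34).
#' @return Numeric vector of lengths, longest first.
#' @export
fixture_karyotype_lengths <- function(cultivar, n = 34L) {
  kx <- walnut_fixture()$karyotype_extremes
  row <- kx[kx$cultivar == cultivar, ]
  if (nrow(row) != 1L) {
    stop("no karyotype extremes for '", cultivar, "'; available: ",
         paste(kx$cultivar, collapse = ", "))
  }
  round(seq(row$longest_um, row$shortest_um, length.out = n), 2)
}

#' Synthetic stand-in for the early-fruiting-gene sequence study
#'
#' The study's 32 early-fruiting-gene sequences live in GenBank and need an
#' external aligner, so this generator builds a synthetic alignment with the
#' same shape for exercising the phylogenetic pipeline offline: 32 sequences
#' labelled with the study's material names and species groups (19 J. regia,
#' 13 J. sigillata), evolved under TN93 on a two-clade tree (random coalescent
#' shape within each species group, long stem between groups), 602 columns of
#' which 40 carry a planted gap or ambiguity so that complete deletion leaves
#' 562. Entirely synthetic: no sequence data are taken from GenBank.
#'
#' @param seed Integer seed.
#' @param n_columns Total alignment width.
#' @param n_dirty_columns Columns given a gap/ambiguity character.
#' @return List with `alignment` (602-column character matrix), `groups`
#'   (named vector leaf -> `"regia"` / `"sigillata"`), `tree` (the true
#'   `phylo`) and `model` (the generating [tn93_model()]).
#' @export
synthetic_early_fruiting_data <- function(seed = 1L, n_columns = 602L,
                                          n_dirty_columns = 40L) {
  regia <- c("Chuanzao1_1", "Chuanzao1_2", "Chuanzao2", "Shuangzao_1",
             "Shuangzao_2", "Shuling", "Zaofeng_1", "Zaofeng_2", "Shimianju",
             "Yanyuanzao_1", "Yanyuanzao_2", "16_1", "16_2", "16_3", "20_1",
             "20_2", "42", "50_1", "50_2")
  sigillata <- c("Muzhilinhe", "Maerkang", "Meigupao", "4", "5", "6", "9_1",
                 "9_2", "10", "32", "45", "46_1", "46_2")
  model <- tn93_model(c(0.30, 0.20, 0.20, 0.30), rate_AG = 4, rate_CT = 6,
                      rate_transversion = 1)
  with_seed(seed, {
    t1 <- ape::rcoal(length(regia), tip.label = sample(regia))
    t2 <- ape::rcoal(length(sigillata), tip.label = sample(sigillata))
    t1$edge.length <- t1$edge.length * 0.02 / max(ape::node.depth.edgelength(t1))
    t2$edge.length <- t2$edge.length * 0.02 / max(ape::node.depth.edgelength(t2))
    nwk <- paste0("(", sub(";$", "", ape::write.tree(t1)), ":0.08,",
                  sub(";$", "", ape::write.tree(t2)), ":0.08);")
    tree <- ape::unroot(ape::read.tree(text = nwk))
    clean <- simulate_alignment(tree, model, n_columns,
                                seed = sample.int(2^30, 1))
    dirty_cols <- sort(sample.int(n_columns, n_dirty_columns))
    marks <- sample(c("-", "N", "R", "?"), n_dirty_columns, replace = TRUE)
    for (k in seq_len(n_dirty_columns)) {
      rows <- sample.int(nrow(clean), sample.int(3L, 1))
      clean[rows, dirty_cols[k]] <- marks[k]
    }
    list(alignment = clean,
         groups = stats::setNames(
           c(rep("regia", length(regia)), rep("sigillata", length(sigillata))),
           c(regia, sigillata))[rownames(clean)],
         tree = tree, model = model)
  })
}
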