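test_that("complete_deletion removes exactly the gap/ambiguity columns", {
  a <- as_alignment(c(r1 = "ACG-T", r2 = "ACTAT", r3 = "ACGCA"))
  cd <- complete_deletion(a)
  expect_equal(ncol(cd), 4L)
  expect_equal(unname(apply(cd, 1, paste, collapse = "")),
               c("ACGT", "ACTT", "ACGA"))
  # gap-free alignment unchanged; idempotent
  b <- as_alignment(c(x = "ACGT", y = "TGCA"))
  expect_equal(complete_deletion(b), b)
  expect_equal(complete_deletion(complete_deletion(a)), cd)
  # ambiguity codes count as missing (columns 2 and 4 drop here)
  expect_equal(ncol(complete_deletion(as_alignment(c(x = "ARGT", y = "ANG?")))), 2L)
  expect_error(complete_deletion(as_alignment(c(x = "-", y = "A"))),
               "every column")
})

test_that("the synthetic early-fruiting stand-in filters 602 to 562 positions", {
  syn <- synthetic_early_fruiting_data(seed = 5)
  expect_equal(dim(syn$alignment), c(32L, 602L))
  expect_equal(ncol(complete_deletion(syn$alignment)), 562L)
  expect_setequal(as.vector(table(syn$groups)), c(13L, 19L))
})

test_that("empirical_frequencies counts base proportions", {
  expect_equal(unname(empirical_frequencies(as_alignment(c(a = "ACGT")))),
               rep(0.25, 4))
  expect_equal(unname(empirical_frequencies(as_alignment(c(a = "AAAC")))),
               c(0.75, 0.25, 0, 0))
  set.seed(1)
  a <- matrix(sample(c("A", "C", "G", "T"), 600, TRUE), 6, 100)
  expect_equal(sum(empirical_frequencies(a)), 1)
  expect_error(empirical_frequencies(as_alignment(c(a = "AC-T"))), "complete_deletion")
})

test_that("tn93_distance is zero on identical pairs and symmetric", {
  f <- c(0.3, 0.2, 0.2, 0.3)
  x <- strsplit("ACGTACGTAC", "")[[1]]
  expect_equal(tn93_distance(x, x, f), 0)
  y <- x; y[2] <- "T"; y[7] <- "A"
  expect_equal(tn93_distance(x, y, f), tn93_distance(y, x, f))
  expect_gte(tn93_distance(x, y, f), 0)
})

test_that("tn93_distance reduces to the Jukes-Cantor closed form", {
  # 120 sites, 12 differences spread equally over all six unordered
  # substitution classes, equal base frequencies: p = 0.1
  x <- rep(c("A", "C", "G", "T"), 30)
  y <- x
  y[c(1, 3)] <- c("G", "A")     # A<->G
  y[c(2, 4)] <- c("T", "C")     # C<->T
  y[c(5, 6)] <- c("C", "A")     # A<->C
  y[c(7, 8)] <- c("T", "G")     # G<->T
  y[c(9, 12)] <- c("T", "A")    # A<->T
  y[c(10, 11)] <- c("G", "C")   # C<->G
  expect_equal(sum(x != y), 12L)
  d <- tn93_distance(x, y, rep(0.25, 4))
  expect_equal(d, -3 / 4 * log(1 - 4 * 0.1 / 3), tolerance = 1e-12)
})

test_that("tn93_distance reduces to the Kimura two-parameter closed form", {
  # equal frequencies with equal A<->G and C<->T transition counts
  x <- rep(c("A", "C", "G", "T"), 50)
  y <- x
  y[c(1, 3, 5, 7)] <- c("G", "A", "G", "A")  # 4 AG transitions
  y[c(2, 4, 6, 8)] <- c("T", "C", "T", "C")  # 4 CT transitions
  y[c(9, 10, 13, 14, 17, 18)] <- c("C", "A", "T", "G", "T", "A")  # 6 tv
  P <- 8 / 200; Q <- 6 / 200
  expect_equal(tn93_distance(x, y, rep(0.25, 4)), k2p_distance(P, Q),
               tolerance = 1e-12)
})

test_that("tn93_distance agrees with an independent implementation", {
  m <- tn93_model(c(0.35, 0.15, 0.2, 0.3), 3, 5, 1)
  tr <- ape::read.tree(text = "(a:0.08,b:0.12,(c:0.05,d:0.3):0.06);")
  a <- simulate_alignment(tr, m, 2000, seed = 42)
  f <- empirical_frequencies(a)
  D <- distance_matrix(a, f)
  Dref <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(a)), model = "TN93"))
  expect_lt(max(abs(D[rownames(Dref), colnames(Dref)] - Dref)), 1e-10)
})

test_that("saturated pairs give non-finite distances, flagged not clamped", {
  x <- rep(c("A", "C"), 30)
  y <- rep(c("C", "A"), 30)   # 100% transversion differences
  expect_true(is.nan(tn93_distance(x, y, rep(0.25, 4))))
  D <- distance_matrix(rbind(x = x, y = y), rep(0.25, 4))
  expect_true(attr(D, "nonfinite"))
  z <- rep(c("G", "T"), 30)
  expect_error(neighbor_joining(rbind(x = x, y = y, z = z) |>
                                  distance_matrix(rep(0.25, 4))),
               "non-finite")
})

test_that("distance_matrix equals the pairwise op and respects permutation", {
  m <- tn93_model(c(0.3, 0.2, 0.2, 0.3), 2, 3, 1)
  tr <- ape::read.tree(text = "(a:0.1,b:0.1,(c:0.1,d:0.1):0.1);")
  a <- simulate_alignment(tr, m, 500, seed = 7)
  f <- empirical_frequencies(a)
  D <- distance_matrix(a, f)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(D[i, j], tn93_distance(a[i, ], a[j, ], f))
  }
  expect_equal(diag(D), setNames(rep(0, 4), rownames(a)))
  perm <- a[c(3, 1, 4, 2), ]
  expect_equal(distance_matrix(perm, f)[rownames(a), rownames(a)],
               D[rownames(a), rownames(a)])
  # two identical rows -> off-diagonal zero
  D2 <- distance_matrix(rbind(p = a[1, ], q = a[1, ]), f)
  expect_equal(D2["p", "q"], 0)
})

test_that("neighbor_joining solves the 3-taxon closed form", {
  D <- matrix(c(0, 0.3, 0.4, 0.3, 0, 0.5, 0.4, 0.5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D, "nj")
  # pendant lengths: a=(.3+.4-.5)/2=.1, b=(.3+.5-.4)/2=.2, c=(.4+.5-.3)/2=.3
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(lens[c("a", "b", "c")], c(a = 0.1, b = 0.2, c = 0.3))
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("neighbor_joining is exact on additive matrices", {
  for (n in 4:5) {
    tr <- random_tree(n, seed = n)
    D <- ape::cophenetic.phylo(tr)
    # BioNJ's reference implementation carries ~1e-8 single-precision noise,
    # so only plain NJ is held to 1e-9
    for (variant in c("nj", "bionj")) {
      est <- neighbor_joining(D, variant)
      expect_lt(max(abs(ape::cophenetic.phylo(est)[rownames(D), colnames(D)] -
                          D)), if (variant == "nj") 1e-9 else 1e-6)
      expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(est)), 0,
                   ignore_attr = TRUE)
    }
  }
})

test_that("an equidistant 4-taxon matrix yields equal pendant branches", {
  D <- matrix(0.4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  tr <- neighbor_joining(D)
  pend <- tr$edge.length[tr$edge[, 2] <= 4]
  expect_equal(pend, rep(0.2, 4))
})

test_that("pruning likelihood matches closed forms on tiny trees", {
  m <- tn93_model(c(0.4, 0.1, 0.2, 0.3), 2, 3, 1)
  two <- ape::read.tree(text = "(a:0,b:0);")
  aln <- as_alignment(c(a = "A", b = "A"))
  expect_equal(tree_log_likelihood(two, aln, m), log(0.4))
  # duplicating every column doubles the log likelihood
  tr <- random_tree(4, seed = 2)
  a <- simulate_alignment(tr, m, 30, seed = 3)
  expect_equal(tree_log_likelihood(tr, cbind(a, a), m),
               2 * tree_log_likelihood(tr, a, m))
  expect_error(tree_log_likelihood(tr, a[c(1, 2, 3), ], m), "match")
})

test_that("pruning equals exhaustive state enumeration (<=5 leaves, <=4 sites)", {
  for (case in list(c(4, 3, 101), c(5, 4, 202), c(3, 2, 303), c(5, 3, 404))) {
    m <- tn93_model(c(0.3, 0.2, 0.25, 0.25), 3, 4, 1)
    tr <- random_tree(case[1], seed = case[3])
    a <- simulate_alignment(tr, m, case[2], seed = case[3] + 1)
    expect_equal(tree_log_likelihood(tr, a, m), oracle_loglik(tr, a, m),
                 tolerance = 1e-9)
  }
})

test_that("likelihood is invariant to leaf order and re-rooting", {
  m <- tn93_model(c(0.3, 0.2, 0.2, 0.3), 2, 2, 1)
  tr <- random_tree(6, seed = 9)
  a <- simulate_alignment(tr, m, 40, seed = 10)
  ll <- tree_log_likelihood(tr, a, m)
  expect_equal(tree_log_likelihood(tr, a[sample(1:6), ], m), ll)
  rerooted <- ape::root(tr, outgroup = tr$tip.label[1], resolve.root = FALSE)
  expect_equal(tree_log_likelihood(rerooted, a, m), ll, tolerance = 1e-9)
})

test_that("pruning agrees with phangorn's likelihood engine", {
  skip_if_not_installed("phangorn")
  m <- tn93_model(c(0.28, 0.22, 0.24, 0.26), 3, 5, 1)
  tr <- random_tree(5, seed = 21)
  a <- simulate_alignment(tr, m, 200, seed = 22)
  dat <- phangorn::phyDat(a, type = "DNA")
  # TN93 in GTR rate order (AC, AG, AT, CG, CT, GT) with beta = 1
  fit <- phangorn::pml(tr, dat, bf = m$freqs, Q = c(1, 3, 1, 1, 5, 1))
  expect_equal(tree_log_likelihood(tr, a, m), fit$logLik, tolerance = 1e-6)
})

test_that("monophyly_check finds two-group bipartitions", {
  cat4 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_true(monophyly_check(cat4, c(a = "x", b = "x", c = "y", d = "y"))$two_groups)
  expect_false(monophyly_check(cat4, c(a = "x", b = "y", c = "x", d = "y"))$two_groups)
  # a single-leaf group splits at its pendant edge
  expect_true(monophyly_check(cat4, c(a = "x", b = "y", c = "y", d = "y"))$two_groups)
  expect_error(monophyly_check(cat4, c(a = "x", b = "y", c = "z", d = "z")),
               "exactly two")
  expect_error(monophyly_check(cat4, c(a = "x", b = "y", c = "y")), "every leaf")
})
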