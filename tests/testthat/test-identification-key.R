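fx <- walnut_fixture()
fx_key <- build_key(fx$genotypes)

test_that("unique_allele_keys finds exactly the cultivar-exclusive alleles", {
  filt <- filter_calls(fx$genotypes)
  uniq <- unique_allele_keys(filt)
  expect_equal(uniq[["Chuanzao 1"]],
               data.frame(locus = c("CUJRA206a", "CUJRB307"),
                          size = c(182L, 116L)))
  expect_equal(nrow(uniq[["Shuling"]]), 0L)

  # two cultivars with identical calls at every locus -> both empty
  calls <- rbind(
    data.frame(cultivar = "a", locus = c("L1", "L2"), size = c(100L, 120L),
               height = 20000),
    data.frame(cultivar = "b", locus = c("L1", "L2"), size = c(100L, 120L),
               height = 20000)
  )
  uniq2 <- unique_allele_keys(genotype_table(calls))
  expect_equal(vapply(uniq2, nrow, integer(1)), c(a = 0L, b = 0L))
})

test_that("unique_allele_keys equals an exhaustive uniqueness scan", {
  for (seed in 1:10) {
    tab <- filter_calls(random_genotype_table(seed), 10000)
    got <- unique_allele_keys(tab)
    want <- oracle_unique_alleles(tab)
    for (cv in tab$cultivars) {
      expect_equal(got[[cv]]$locus, want[[cv]]$locus)
      expect_equal(got[[cv]]$size, want[[cv]]$size)
    }
  }
})

test_that("no allele appears in the single-locus keys of two cultivars", {
  for (seed in 1:5) {
    tab <- filter_calls(random_genotype_table(seed), 8000)
    uniq <- unique_allele_keys(tab)
    all_keys <- do.call(rbind, uniq)
    expect_equal(anyDuplicated(all_keys), 0L)
  }
})

test_that("Shuling gets an anchor key excluding the other ZMZ11:148 carriers", {
  rule <- fx_key$keys[["Shuling"]][[1]]
  expect_equal(rule$type, "combination")
  expect_equal(rule$anchor, list(locus = "ZMZ11", size = 148L))
  expect_equal(sort(names(rule$excluded)), c("Chuanzao 1", "Yanyuanzao"))
  expect_true(all(vapply(rule$excluded, nrow, integer(1)) >= 1L))
})

test_that("cultivars with identical profiles are unresolved, not an error", {
  calls <- rbind(
    data.frame(cultivar = "a", locus = "L1", size = 100L, height = 20000),
    data.frame(cultivar = "b", locus = "L1", size = 100L, height = 20000),
    data.frame(cultivar = "c", locus = "L1", size = 104L, height = 20000)
  )
  key <- build_key(genotype_table(calls))
  expect_setequal(key$unresolved, c("a", "b"))
  expect_true("c" %in% names(key$keys))
})

test_that("greedy conjunction fallback matches the exhaustive cover oracle", {
  # a 2x2 factorial of alleles: every allele is carried by exactly two
  # cultivars, so nobody has an exclusive allele and no anchor can qualify,
  # yet each cultivar's allele *pair* is unique
  calls <- expand.grid(i = 1:2, j = 1:2)
  calls <- do.call(rbind, lapply(seq_len(nrow(calls)), function(r) {
    data.frame(cultivar = paste0("cv", calls$i[r], calls$j[r]),
               locus = c("L1", "L2"),
               size = c(98L + 2L * calls$i[r], 118L + 2L * calls$j[r]),
               height = 20000)
  }))
  tab <- genotype_table(calls)
  partial <- unique_allele_keys(tab)
  expect_true(all(vapply(partial, nrow, integer(1)) == 0L))
  combo <- combination_keys(tab, partial)
  expect_equal(length(combo$unresolved), 0L)
  for (cv in tab$cultivars) {
    rule <- combo$keys[[cv]]
    expect_equal(rule$type, "conjunction")
    expect_equal(nrow(rule$alleles), 2L)
    expect_equal(nrow(rule$alleles), oracle_min_cover(tab, cv))
    expect_true(oracle_separates(tab, cv, rule$alleles))
  }
})

test_that("build_key resolves the worked example exactly as reported", {
  single <- names(fx_key$keys)[vapply(fx_key$keys, function(r) {
    all(vapply(r, function(x) x$type == "single", logical(1)))
  }, logical(1))]
  expect_equal(length(single), 8L)
  expect_false("Shuling" %in% single)
  expect_equal(length(fx_key$loci_used), 11L)
  expect_setequal(fx_key$loci_used,
                  c("CUJRA123", "CUJRA124", "CUJRA206a", "CUJRB103a",
                    "CUJRB218", "CUJRB220", "CUJRB307", "CUJRC310", "JSI-71",
                    "JSI-73", "ZMZ11"))
  expect_equal(length(fx_key$unresolved), 0L)
})

test_that("a single-cultivar table is keyed by any retained allele", {
  tab <- genotype_table(data.frame(cultivar = "only", locus = "L1",
                                   size = 100L, height = 20000))
  key <- build_key(tab)
  expect_equal(names(key$keys), "only")
  expect_equal(key$keys$only[[1]]$type, "single")
})

test_that("planted exclusive alleles always surface in their cultivar's key", {
  for (seed in c(11, 23)) {
    tab <- simulate_genotype_table(genotype_sim_config(seed = seed))
    key <- build_key(tab)
    expect_equal(length(key$unresolved), 0L)
    idx <- shared_allele_index(tab)
    planted <- idx[idx$n_carriers == 1L, ]
    for (i in seq_len(nrow(planted))) {
      cv <- planted$cultivars[[i]][1]
      hit <- any(vapply(key$keys[[cv]], function(r) {
        r$type == "single" && r$locus == planted$locus[i] &&
          r$size == planted$size[i]
      }, logical(1)))
      expect_true(hit)
    }
  }
})

test_that("classify applies single, combination and unknown rules", {
  muzhilinhe <- data.frame(
    locus = c("CUJRB220", "ZMZ11", "CUJRC310", "JSI-73"),
    size = c(136L, 147L, 156L, 166L))
  expect_equal(classify(muzhilinhe, fx_key)$cultivar, "Muzhilinhe")

  empty <- data.frame(locus = character(), size = integer())
  expect_equal(classify(empty, fx_key)$status, "unknown")

  both <- data.frame(locus = c("CUJRB307", "JSI-73"), size = c(116L, 154L))
  res <- classify(both, fx_key)
  expect_equal(res$status, "ambiguous")
  expect_setequal(res$candidates, c("Chuanzao 1", "Chuanzao 2"))

  expect_warning(
    res <- classify(data.frame(locus = c("NOPE", "CUJRB307"),
                               size = c(1L, 116L)), fx_key),
    "outside the key")
  expect_equal(res$cultivar, "Chuanzao 1")
})

test_that("classify round-trips every cultivar of the worked example", {
  for (cv in fx$genotypes$cultivars) {
    own <- fx$genotypes$calls[fx$genotypes$calls$cultivar == cv, ]
    res <- classify(own, fx_key)
    expect_equal(res$status, "match")
    expect_equal(res$cultivar, cv)
  }
})

test_that("keys are stable under permutation of input row order", {
  for (seed in 1:5) {
    tab <- random_genotype_table(seed)
    set.seed(seed + 100)
    perm <- tab$calls[sample.int(nrow(tab$calls)), ]
    tab2 <- genotype_table(perm, cultivars = tab$cultivars, loci = tab$loci,
                           missing = tab$missing)
    k1 <- build_key(tab)
    k2 <- build_key(tab2)
    expect_equal(k1$keys, k2$keys)
    expect_equal(k1$loci_used, k2$loci_used)
  }
})

test_that("missing cells never provide exclusion evidence", {
  # b lacks L2 entirely (missing); a's L2 allele is shared with c, and a's L1
  # allele is shared with b, so a can only be separated from b by L2 absence
  # -- which is not evidence, so a must be unresolved
  calls <- rbind(
    data.frame(cultivar = "a", locus = c("L1", "L2"), size = c(100L, 120L)),
    data.frame(cultivar = "b", locus = "L1", size = 100L),
    data.frame(cultivar = "c", locus = c("L1", "L2"), size = c(102L, 120L))
  )
  calls$height <- 20000
  tab <- genotype_table(calls,
                        missing = data.frame(cultivar = "b", locus = "L2"))
  key <- build_key(tab)
  expect_true("a" %in% key$unresolved)
})
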