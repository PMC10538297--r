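test_that("allele spectra are direct counts with combined multi-copy states", {
  s <- one_locus_pop("p", c(10, 10, 12))
  spec <- allele_spectrum(s, "L1")
  expect_equal(spec$state, c("10", "12"))
  expect_equal(spec$count, c(2L, 1L))
  expect_equal(spec$freq, c(2 / 3, 1 / 3))
  expect_equal(attr(spec, "n"), 3L)

  # multi-copy states count as one combined state
  panel <- panel_def("p", "DYS385", multi_copy = "DYS385")
  m <- matrix(c("11,14", "14,11", "11,15"), ncol = 1,
              dimnames = list(NULL, "DYS385"))
  spec2 <- allele_spectrum(make_sample("q", m, panel), "DYS385")
  expect_equal(spec2$state, c("11,14", "11,15"))
  expect_equal(spec2$count, c(2L, 1L))

  # all-identical locus: a single state at frequency 1
  mono <- one_locus_pop("m", rep(9, 5))
  expect_equal(allele_spectrum(mono, "L1")$freq, 1)
  expect_error(allele_spectrum(mono, "ZZ"), "ZZ")
})

test_that("a singleton among 312 has frequency 0.0032 at 4 decimals", {
  s <- one_locus_pop("p", c(rep(15, 311), 16))
  spec <- allele_spectrum(s, "L1")
  expect_equal(round(min(spec$freq), 4), 0.0032)
})

test_that("diversity formulas match closed forms and brute-force pair counting", {
  # uniform spectrum of k states -> HMP = 1/k asymptotically in counts
  spec_u <- freq_spectrum(stats::setNames(rep(5L, 4), letters[1:4]))
  expect_equal(match_probability(spec_u), 1 / 4)

  # single state -> zero diversity, HMP 1, DC 1/n
  spec_1 <- freq_spectrum(c(a = 7L))
  expect_equal(gene_diversity(spec_1), 0)
  expect_equal(match_probability(spec_1), 1)
  expect_equal(discrimination_capacity(spec_1), 1 / 7)

  # n = 2 distinct states -> maximal corrected diversity 1
  spec_2 <- freq_spectrum(c(a = 1L, b = 1L))
  expect_equal(gene_diversity(spec_2), 1)
  expect_error(gene_diversity(freq_spectrum(c(a = 1L))), "n < 2")

  # random small samples vs brute-force enumeration over haplotype pairs
  for (seed in 1:10) {
    s <- random_str_sample("p", n = sample(5:30, 1), nloci = 3,
                           seed = 100 + seed, range = 9:11)
    spec <- haplotype_spectrum(s)
    counts <- brute_group_counts(s$cells)
    expect_equal(sort(spec$count), sort(counts))
    expect_equal(match_probability(spec), brute_match_probability(counts))
    n <- sum(counts)
    expect_equal(gene_diversity(spec),
                 n * (1 - brute_match_probability(counts)) / (n - 1))
    expect_equal(discrimination_capacity(spec), length(counts) / n)
    expect_equal(n_unique_states(spec), sum(counts == 1))
    # invariants
    expect_gte(match_probability(spec), 1 / n - 1e-12)
    expect_true(abs(discrimination_capacity(spec) * n -
                      round(discrimination_capacity(spec) * n)) < 1e-9)
  }
})

test_that("haplotype spectrum honors panel equality and missing-data rule", {
  panel <- panel_def("p", c("A", "B"))
  cells <- rbind(c("10", "11"), c("10", "11"), c("10", NA))
  colnames(cells) <- panel$loci
  s <- make_sample("x", cells)
  spec <- haplotype_spectrum(s, panel)
  expect_equal(attr(spec, "n"), 2L)      # incomplete haplotype excluded
  expect_equal(nrow(spec), 1L)
  # ...but the incomplete individual still counts at the loci it carries
  expect_equal(attr(allele_spectrum(s, "A"), "n"), 3L)

  one <- make_sample("y", matrix("10", 1, 1, dimnames = list(NULL, "A")))
  spec1 <- haplotype_spectrum(one)
  expect_equal(spec1$count, 1L)
})

test_that("panel report rows equal per-panel statistics and order is kept", {
  s <- random_str_sample("p", 25, 4, seed = 42)
  p1 <- panel_def("one", "L1")
  p12 <- panel_def("two", c("L1", "L2"))
  pall <- panel_def("all", paste0("L", 1:4))
  rep <- panel_report(s, list(p1, p12, pall))
  expect_equal(rep$panel, c("one", "two", "all"))
  # whole-panel row equals whole-sample stats
  st <- diversity_stats(haplotype_spectrum(s))
  expect_equal(rep$hd[3], st$diversity)
  expect_equal(rep$hmp[3], st$match_prob)
  # single-locus panel row equals the per-locus spectrum stats
  st1 <- diversity_stats(allele_spectrum(s, "L1"))
  expect_equal(rep$hd[1], st1$diversity)
  expect_equal(rep$dc[1], st1$disc_capacity)
})

test_that("nested panels give monotone DC/HD/HMP", {
  for (seed in c(3, 17, 29)) {
    s <- random_str_sample("p", 40, 6, seed = seed, range = 9:12)
    panels <- lapply(1:6, function(k)
      panel_def(paste0("k", k), paste0("L", seq_len(k))))
    rep <- panel_report(s, panels)
    expect_true(all(diff(rep$dc) >= -1e-12))
    expect_true(all(diff(rep$hd) >= -1e-12))
    expect_true(all(diff(rep$hmp) <= 1e-12))
  }
})

test_that("InDel loci use the same diversity estimator on two-state spectra", {
  panel <- panel_def("p", "rs1", indel_loci = "rs1")
  m <- matrix(c(rep("I", 18), rep("D", 2)), ncol = 1,
              dimnames = list(NULL, "rs1"))
  s <- make_sample("x", m, panel)
  spec <- allele_spectrum(s, "rs1")
  expect_equal(nrow(spec), 2L)
  expect_equal(gene_diversity(spec), 20 * (1 - 0.9^2 - 0.1^2) / 19)
})
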