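test_that("squared repeat-difference kernel handles microvariants and errors", {
  expect_equal(haplotype_sq_distance(c(L1 = "10"), c(L1 = "10"), "L1"), 0)
  expect_equal(haplotype_sq_distance(c(L1 = "10"), c(L1 = "12"), "L1"), 4)
  expect_equal(haplotype_sq_distance(c(L1 = "10", L2 = "14.1"),
                                     c(L1 = "11", L2 = "14"),
                                     c("L1", "L2")), 1.01)
  expect_error(haplotype_sq_distance(c(L1 = "10,11"), c(L1 = "10"), "L1"),
               "multi-allele")
  expect_error(haplotype_sq_distance(c(L1 = NA), c(L1 = "10"), "L1"),
               "missing")
})

test_that("hand-worked AMOVA toy cases give Rst 1 and Rst -1", {
  a <- one_locus_pop("A", c(10, 10))
  b <- one_locus_pop("B", c(12, 12))
  fixed <- amova_rst(list(a, b), "L1")
  expect_equal(fixed$sigma2_within, 0)
  expect_equal(fixed$rst, 1)
  expect_equal(fixed$distance, 1)

  c1 <- one_locus_pop("A", c(10, 12))
  c2 <- one_locus_pop("B", c(10, 12))
  null <- amova_rst(list(c1, c2), "L1")
  expect_equal(null$ssd_within, 4)
  expect_equal(null$ssd_among, 0, tolerance = 1e-12)
  expect_equal(null$sigma2_within, 2)
  expect_equal(null$sigma2_among, -1)
  expect_equal(null$rst, -1)
  expect_equal(null$distance, 0)
})

test_that("variance components match the brute-force all-pairs oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    sizes <- sample(2:10, sample(2:3, 1), replace = TRUE)
    pops <- lapply(seq_along(sizes), function(p) {
      random_str_sample(paste0("P", p), sizes[p], nloci = 4,
                        seed = seed * 100 + p)
    })
    loci <- paste0("L", 1:4)
    got <- amova_rst(pops, loci)
    want <- brute_amova(lapply(pops, function(s)
      matrix(as.numeric(s$cells), nrow = nrow(s$cells))))
    expect_equal(got$ssd_total, want$ssd_total)
    expect_equal(got$ssd_within, want$ssd_within)
    expect_equal(got$ssd_among, want$ssd_among)
    expect_equal(got$sigma2_among, want$sigma2_among)
    expect_equal(got$sigma2_within, want$sigma2_within)
    expect_equal(got$rst, want$rst)
    # SSD additivity
    expect_equal(got$ssd_among + got$ssd_within, got$ssd_total,
                 tolerance = 1e-9)
  }
})

test_that("Rst is exchangeable under relabelling and population swap", {
  a <- random_str_sample("A", 8, 3, seed = 1)
  b <- random_str_sample("B", 6, 3, seed = 2)
  base <- amova_rst(list(a, b), paste0("L", 1:3))$rst
  swapped <- amova_rst(list(b, a), paste0("L", 1:3))$rst
  expect_equal(swapped, base)
  perm <- a
  idx <- c(3, 1, 2, 4, 8, 7, 5, 6)
  perm$cells <- a$cells[idx, , drop = FALSE]
  perm$ids <- a$ids[idx]
  expect_equal(amova_rst(list(perm, b), paste0("L", 1:3))$rst, base)
})

test_that("amova validates inputs", {
  a <- one_locus_pop("A", c(10, 11))
  tiny <- one_locus_pop("B", 10)
  expect_error(amova_rst(list(a), "L1"), ">= 2")
  expect_error(amova_rst(list(a, tiny), "L1"), "fewer than 2")
  expect_error(amova_rst(list(a, a), character()), "empty locus")
})

test_that("individuals with missing or multi-allele calls are dropped listwise", {
  cells_a <- rbind(c("10", "11"), c("10", "12"), c("10", NA))
  cells_b <- rbind(c("12", "11"), c("12", "12"), c("12,13", "11"))
  colnames(cells_a) <- colnames(cells_b) <- c("L1", "L2")
  a <- make_sample("A", cells_a)
  b <- make_sample("B", cells_b)
  got <- amova_rst(list(a, b), c("L1", "L2"))
  expect_equal(unname(got$n_per_pop), c(2L, 2L))
})

test_that("pairwise Rst matrices are symmetric, clamped and consistent", {
  pops <- lapply(1:3, function(p)
    random_str_sample(paste0("P", p), 8, 3, seed = 40 + p))
  d <- pairwise_rst(pops, paste0("L", 1:3))
  expect_identical(dist_labels(d), c("P1", "P2", "P3"))
  expect_equal(unclass(d), t(unclass(d)), ignore_attr = TRUE)
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0))
  scalar <- amova_rst(pops[1:2], paste0("L", 1:3))$distance
  expect_equal(d["P1", "P2"], scalar, ignore_attr = TRUE)

  same <- lapply(1:3, function(p) {
    s <- one_locus_pop(paste0("Q", p), c(10, 11, 12))
    s
  })
  expect_true(all(pairwise_rst(same, "L1") == 0))
})

test_that("permutation p-value is calibrated, reproducible and one-sided", {
  cfg <- sim_config(n = 12, generations = 60, seed = 21,
                    panel = default_panels()$minimal)
  loci <- rst_loci(cfg$panel)
  null_pair <- simulate_divergent_pair(cfg)
  p_null <- rst_permutation_p(null_pair[[1]], null_pair[[2]], loci,
                              n_perm = 199, seed = 5)
  expect_gte(p_null$p_value, 0.05)

  # identical populations: observed Rst is at the bottom of the null
  twin <- random_str_sample("A", 8, 3, seed = 77)
  twin2 <- twin; twin2$name <- "B"
  p_twin <- rst_permutation_p(twin, twin2, paste0("L", 1:3),
                              n_perm = 199, seed = 3)
  expect_gte(p_twin$p_value, 0.5)

  a <- one_locus_pop("A", rep(10, 10))
  b <- one_locus_pop("B", rep(20, 10))
  p_alt <- rst_permutation_p(a, b, "L1", n_perm = 999, seed = 5)
  expect_equal(p_alt$rst, 1)
  expect_lte(p_alt$p_value, 0.01)

  again <- rst_permutation_p(a, b, "L1", n_perm = 999, seed = 5)
  expect_identical(again$p_value, p_alt$p_value)
  expect_error(rst_permutation_p(a, b, "L1", n_perm = 10), ">= 100")
})
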