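two_pop_geno <- function(n_loci = 40, n_per_pop = 10, seed = 1,
                         fst_sim = 0, na_frac = 0) {
  spec <- population_spec(n_loci = n_loci, n_per_population = n_per_pop,
                          fraction_polymorphic = 1, fraction_indel = 0,
                          fst_sim = fst_sim, seed = seed)
  g <- simulate_genotypes(spec)
  geno <- dosage_to_codes(g$dosage)
  if (na_frac > 0) {
    set.seed(seed + 1)
    geno[sample(length(geno), round(na_frac * length(geno)))] <- NA
  }
  list(geno = geno, populations = g$populations, truth = g)
}

test_that("allele frequencies match the brute-force recount", {
  geno <- matrix(c("CC", "CU", "UU"), 1, 3,
                 dimnames = list("l1", c("a", "b", "c")))
  af <- allele_frequencies(geno, factor(rep("p1", 3)))
  expect_equal(af$p[1, 1], 0.5, ignore_attr = TRUE)
  af0 <- allele_frequencies(matrix("CC", 1, 3), factor(rep("p1", 3)))
  expect_equal(af0$p[1, 1], 0, ignore_attr = TRUE)
  d <- two_pop_geno(seed = 3, na_frac = 0.1)
  af2 <- allele_frequencies(d$geno, d$populations)
  for (pop in levels(d$populations)) {
    cols <- d$populations == pop
    oracle <- apply(d$geno[, cols, drop = FALSE], 1, brute_allele_freq)
    expect_equal(unname(af2$p[, pop]), unname(oracle))
  }
})

test_that("per-locus F_ST matches hand calculation and brute force", {
  expect_equal(fst_locus(c(0.5, 0.5))$fst, 0)
  expect_equal(fst_locus(c(1, 0))$fst, 1)
  # H_T = 0.5, H_S = 0.32 -> 0.36
  expect_equal(fst_locus(c(0.8, 0.2))$fst, 0.36)
  expect_true(is.na(fst_locus(c(0, 0))$fst))
  expect_error(fst_locus(0.5), "two populations")
  set.seed(13)
  for (r in 2:4) {
    p <- matrix(runif(30 * r), 30, r)
    tab <- fst_table(p)
    expect_equal(tab$fst, apply(p, 1, brute_fst))
    expect_true(all(tab$fst >= 0 & tab$fst <= 1, na.rm = TRUE))
  }
})

test_that("small-sample corrected F_ST recovers the simulated truth", {
  for (F in c(0, 0.05)) {
    d <- two_pop_geno(n_loci = 4000, seed = 31, fst_sim = F)
    af <- allele_frequencies(d$geno, d$populations)
    est <- fst_table(af$p, af$n_called, correct = TRUE)
    expect_lt(abs(fst_overall(est$fst, est$h_t, weight = "ht") - F),
              0.01)
  }
})

test_that("individual heterozygosity counts HET fractions and compares populations", {
  geno <- matrix("CU", 5, 2, dimnames = list(NULL, c("a", "b")))
  ih <- individual_heterozygosity(geno, factor(c("x", "y")))
  expect_equal(unname(ih$het), c(1, 1))
  # population with larger expected heterozygosity detected by KS
  spec_hi <- population_spec(n_loci = 600, fraction_polymorphic = 1,
                             freq_range = c(0.4, 0.6), seed = 11)
  spec_lo <- population_spec(n_loci = 600, fraction_polymorphic = 1,
                             freq_range = c(0.02, 0.1), seed = 12)
  hi <- simulate_genotypes(spec_hi); lo <- simulate_genotypes(spec_lo)
  geno2 <- cbind(dosage_to_codes(hi$dosage)[, 1:10],
                 dosage_to_codes(lo$dosage)[, 1:10])
  colnames(geno2) <- sprintf("i%02d", 1:20)
  pops <- factor(rep(c("hi", "lo"), each = 10))
  ih2 <- individual_heterozygosity(geno2, pops)
  expect_gt(ih2$population_means[["hi"]], ih2$population_means[["lo"]])
  expect_lt(ih2$ks$p.value, 0.01)
  # all-missing individual
  geno3 <- geno; geno3[, 1] <- NA
  expect_warning(ih3 <- individual_heterozygosity(geno3,
                                                  factor(c("x", "y"))),
                 "no called")
  expect_true(is.na(ih3$het[[1]]))
})

test_that("HWE chi-square matches closed forms and BH matches the step-up rule", {
  # exact HWE: (25, 50, 25)
  geno_hwe <- matrix(rep(c("CC", "CU", "UU"), c(25, 50, 25)), 1)
  h1 <- hwe_test(geno_hwe, factor(rep("p", 100)))
  expect_equal(h1$chisq, 0)
  expect_equal(h1$p_value, 1)
  # maximal heterozygote deficit: chi-square = n
  geno_fix <- matrix(rep(c("CC", "UU"), c(50, 50)), 1)
  h2 <- hwe_test(geno_fix, factor(rep("p", 100)))
  expect_equal(h2$chisq, 100)
  expect_lt(h2$p_value, 1e-20)
  # monomorphic: p = 1 by convention
  h3 <- hwe_test(matrix("CC", 1, 10), factor(rep("p", 10)))
  expect_equal(h3$p_value, 1)
  # BH adjustment equals the hand step-up on a known example
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(7)
  p <- runif(40)
  expect_equal(p.adjust(p, "BH"), brute_bh(p))
  adj <- sort(p.adjust(p, "BH"))
  expect_true(all(diff(adj) >= 0) && all(adj <= 1))
  # on HWE-simulated data nothing is significant after correction
  d <- two_pop_geno(n_loci = 300, seed = 17)
  hw <- hwe_test(d$geno, d$populations)
  expect_true(all(hw$p_adj >= 0.05, na.rm = TRUE))
})

test_that("panmixia permutation test is reproducible and calibrated", {
  d <- two_pop_geno(n_loci = 60, seed = 19)
  p1 <- permute_panmixia(d$geno, d$populations, n_permutations = 20,
                         seed = 5)
  p2 <- permute_panmixia(d$geno, d$populations, n_permutations = 20,
                         seed = 5)
  expect_identical(p1$perm_mean, p2$perm_mean)
  expect_equal(p1$n_permutations, 20L)
  # null calibration: rank of observed mean uniform across replicates
  ranks <- vapply(1:60, function(i) {
    dd <- two_pop_geno(n_loci = 200, seed = 100 + i)
    permute_panmixia(dd$geno, dd$populations, n_permutations = 200,
                     seed = 500 + i)$rank_observed_mean
  }, 0)
  expect_gt(suppressWarnings(ks.test(ranks, "punif"))$p.value, 0.01)
  # power under real differentiation
  dp <- two_pop_geno(n_loci = 400, seed = 23, fst_sim = 0.05)
  pw <- permute_panmixia(dp$geno, dp$populations, n_permutations = 200,
                         seed = 7)
  expect_gte(pw$rank_observed_mean, 0.99)
  expect_gt(pw$observed_mean, max(pw$perm_mean))
})

test_that("individual-level permutation mode agrees qualitatively", {
  dp <- two_pop_geno(n_loci = 150, seed = 29, fst_sim = 0.1)
  pw <- permute_panmixia(dp$geno, dp$populations, n_permutations = 50,
                         seed = 3, unit = "individual")
  expect_gte(pw$rank_observed_mean, 0.95)
})

test_that("PCA is deterministic, duplicate-safe and subset-consistent", {
  set.seed(41)
  X <- matrix(rnorm(300), 30, 10,
              dimnames = list(sprintf("l%02d", 1:30),
                              sprintf("i%02d", 1:10)))
  X[, 2] <- X[, 1]  # duplicated individual
  pc <- pca_individuals(X)
  expect_equal(pc$scores[1, ], pc$scores[2, ], ignore_attr = TRUE)
  # locus-order invariance up to sign
  pc2 <- pca_individuals(X[sample(nrow(X)), ])
  for (j in 1:3)
    expect_equal(abs(pc2$scores[, j]), abs(pc$scores[, j]),
                 tolerance = 1e-8)
  # population separation at moderate differentiation
  spec <- population_spec(n_loci = 500, fraction_polymorphic = 1,
                          fst_sim = 0.15, seed = 43)
  ds <- simulate_dataset(spec)
  mats <- build_signal_matrices(ds$scans, ds$manifest)
  pcs <- pca_individuals(mats$log_ratio)
  pops <- ds$truth$populations
  # mean silhouette of population labels on the leading components
  sil <- local({
    D <- as.matrix(dist(pcs$scores[, 1:2]))
    vapply(seq_along(pops), function(i) {
      a <- mean(D[i, pops == pops[i] & seq_along(pops) != i])
      b <- mean(D[i, pops != pops[i]])
      (b - a) / max(a, b)
    }, 0)
  })
  expect_gt(mean(sil), 0)
  # subsets partition the polymorphic loci
  fst <- setNames(runif(30)^4, rownames(X))
  top <- top_fst_subset(fst)
  rest <- setdiff(names(fst), top$ids)
  expect_setequal(c(top$ids, rest), names(fst))
  expect_equal(pca_individuals(X, subset = top$ids)$n_loci +
                 pca_individuals(X, subset = rest)$n_loci, 30)
})

test_that("top-F_ST rule takes the mean + 2 sd tail", {
  fst <- setNames(c(rep(0, 99), 0.5), sprintf("l%03d", 1:100))
  top <- top_fst_subset(fst)
  expect_equal(top$ids, "l100")
  expect_equal(top$threshold, mean(fst) + 2 * sd(fst))
  # Gaussian tail: about 2.3% selected
  set.seed(47)
  fstn <- setNames(rnorm(20000, 0.05, 0.01), seq_len(20000))
  frac <- length(top_fst_subset(fstn)$ids) / 20000
  expect_gt(frac, 0.015); expect_lt(frac, 0.032)
})

test_that("paired-locus F_ST correlation and its permutation p behave", {
  set.seed(53)
  a <- runif(100)
  r1 <- paired_fst_correlation(a, a, n_permutations = 200, seed = 1)
  expect_equal(r1$r, 1)
  expect_lt(r1$p_value, 0.01)
  b <- runif(100)
  r2 <- paired_fst_correlation(a, b, n_permutations = 200, seed = 1)
  expect_lt(abs(r2$r), 0.25)
  expect_gt(r2$p_value, 0.05)
  # incomplete pairs dropped
  a2 <- c(a, NA); b2 <- c(b, 0.5)
  expect_equal(paired_fst_correlation(a2, b2, n_permutations = 10,
                                      seed = 1)$n_pairs, 100)
})

test_that("LD screen flags perfect association and respects the joint-call rule", {
  d <- two_pop_geno(n_loci = 6, seed = 59)
  geno <- d$geno
  geno <- rbind(geno, dup = geno[1, ])  # locus as its own pair partner
  rownames(geno)[1] <- "orig"
  ld <- ld_screen(geno, c("orig", "dup", rownames(geno)[2:4]),
                  n_permutations = 200, seed = 3)
  self_pair <- ld[ld$locus_a == "orig" & ld$locus_b == "dup", ]
  expect_lt(self_pair$p_value, 0.02)
  # independent HWE loci: nothing survives correction
  others <- ld[!(ld$locus_a == "orig" & ld$locus_b == "dup"), ]
  expect_true(all(others$p_adj >= 0.05, na.rm = TRUE))
  # sparse pair skipped
  geno2 <- d$geno[1:2, ]
  geno2[1, 1:16] <- NA
  geno2[2, 5:20] <- NA
  ld2 <- ld_screen(geno2, rownames(geno2), n_permutations = 10, seed = 1)
  expect_true(ld2$skipped[1])
})

test_that("Fisher's combined test matches its chi-square form", {
  f1 <- fishers_combined(c(1, 1))
  expect_equal(f1$statistic, 0)
  expect_equal(f1$p_value, 1)
  expect_equal(fishers_combined(0.05)$p_value, 0.05)
  f2 <- fishers_combined(c(0.1, 0.1))
  expect_equal(f2$statistic, -2 * sum(log(c(0.1, 0.1))))
  expect_equal(f2$statistic, 9.21, tolerance = 1e-3)
  expect_equal(f2$p_value,
               pchisq(-2 * sum(log(c(0.1, 0.1))), 4, lower.tail = FALSE))
  expect_equal(f2$p_value, 0.056, tolerance = 1e-2)
  expect_error(fishers_combined(0), "p_values")
})
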