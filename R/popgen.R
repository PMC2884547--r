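geno_dosage <- function(geno) {
  d <- matrix(c(CC = 0L, CU = 1L, UU = 2L)[geno], nrow = nrow(geno),
              dimnames = dimnames(geno))
  d
}

#' Per-locus, per-population mutant allele frequencies
#'
#' Frequency of the mutant ("uncut", U) allele, `p = (2*#UU + #CU) /
#' (2*n_called)`, with per-locus pairwise deletion of missing genotypes.
#'
#' @param geno character matrix of genotype codes CC/CU/UU/NA
#'   (loci x individuals).
#' @param populations factor of population labels per individual.
#' @return list with matrices `p` (loci x populations; NA when no
#'   individual called) and `n_called` (called individuals).
#' @export
allele_frequencies <- function(geno, populations) {
  populations <- as.factor(populations)
  stopifnot(ncol(geno) == length(populations))
  d <- geno_dosage(geno)
  pops <- levels(populations)
  p <- n_called <- matrix(NA_real_, nrow(geno), length(pops),
                          dimnames = list(rownames(geno), pops))
  for (j in seq_along(pops)) {
    cols <- which(populations == pops[j])
    sub <- d[, cols, drop = FALSE]
    nc <- rowSums(!is.na(sub))
    n_called[, j] <- nc
    p[, j] <- ifelse(nc > 0, rowSums(sub, na.rm = TRUE) / (2 * nc),
                     NA_real_)
  }
  list(p = p, n_called = n_called)
}

#' Per-locus F_ST from population allele frequencies
#'
#' Wright's fixation index in its G_ST form: `H_i = 2 p_i (1 - p_i)` per
#' population, `H_S = mean(H_i)`, `H_T = 2 pbar (1 - pbar)` at the
#' (equally weighted) mean frequency, and `F_ST = (H_T - H_S)/H_T`
#' (NA when `H_T = 0`). With `correct = TRUE` and sample sizes supplied,
#' the Nei-Chesser small-sample corrections are applied (`H_S` scaled by
#' `2n/(2n-1)`, `H_T` incremented by `H_S/(2*nbar*r)` with `nbar` the
#' harmonic mean sample size), giving a nearly unbiased estimator used for
#' parameter-recovery validation; the plug-in form is the default.
#'
#' @param p numeric vector of per-population mutant frequencies at one
#'   locus.
#' @param n_called individuals genotyped per population (needed for
#'   `correct = TRUE`).
#' @param correct apply small-sample corrections.
#' @return list: `p`, `h_s`, `h_t`, `fst`.
#' @export
fst_locus <- function(p, n_called = NULL, correct = FALSE) {
  if (length(p) < 2L) stop("F_ST requires at least two populations")
  rec <- fst_table(matrix(p, nrow = 1L),
                   if (is.null(n_called)) NULL else
                     matrix(n_called, nrow = 1L),
                   correct = correct)
  list(p = p, h_s = rec$h_s, h_t = rec$h_t, fst = rec$fst)
}

#' Vectorized per-locus F_ST table
#'
#' @param p_mat loci x populations matrix of mutant allele frequencies.
#' @param n_mat optional matching matrix of called individuals (required
#'   for `correct = TRUE`; also used for the coverage filter).
#' @param correct apply Nei-Chesser small-sample corrections (see
#'   [fst_locus()]).
#' @param n_total total individuals per population; with `n_mat`, loci
#'   with fewer than `min_called_frac` of individuals called in any
#'   population get `fst = NA`.
#' @param min_called_frac minimum called fraction per population.
#' @return data.frame: locus_id, h_s, h_t, fst.
#' @export
fst_table <- function(p_mat, n_mat = NULL, correct = FALSE,
                      n_total = NULL, min_called_frac = 0.5) {
  r <- ncol(p_mat)
  if (r < 2L) stop("F_ST requires at least two populations")
  h_i <- 2 * p_mat * (1 - p_mat)
  if (correct) {
    if (is.null(n_mat)) stop("correct = TRUE requires n_called")
    h_i <- h_i * (2 * n_mat) / pmax(2 * n_mat - 1, 1)
  }
  h_s <- rowMeans(h_i)
  pbar <- rowMeans(p_mat)
  h_t <- 2 * pbar * (1 - pbar)
  if (correct) {
    nbar <- r / rowSums(1 / pmax(n_mat, 1e-9))  # harmonic mean
    h_t <- h_t + h_s / (2 * nbar * r)
  }
  fst <- ifelse(h_t > 0, (h_t - h_s) / h_t, NA_real_)
  if (!is.null(n_mat) && !is.null(n_total)) {
    low <- rowSums(n_mat < min_called_frac * rep(n_total,
                                                 each = nrow(n_mat))) > 0
    fst[low] <- NA_real_
  }
  data.frame(locus_id = if (is.null(rownames(p_mat)))
    seq_len(nrow(p_mat)) else rownames(p_mat),
    h_s = h_s, h_t = h_t, fst = fst, stringsAsFactors = FALSE,
    row.names = NULL)
}

#' Genome-wide summary F_ST
#'
#' @param fst per-locus F_ST values (NAs dropped).
#' @param h_t per-locus total heterozygosities (for `weight = "ht"`).
#' @param weight `"mean"` (simple mean over loci, the default) or `"ht"`
#'   (H_T-weighted ratio of sums, i.e. `sum(h_t - h_s)/sum(h_t)`).
#' @return scalar genome-wide F_ST.
#' @export
fst_overall <- function(fst, h_t = NULL, weight = c("mean", "ht")) {
  weight <- match.arg(weight)
  keep <- is.finite(fst)
  if (weight == "mean") return(mean(fst[keep]))
  stopifnot(!is.null(h_t))
  keep <- keep & is.finite(h_t)
  sum(fst[keep] * h_t[keep]) / sum(h_t[keep])
}

#' Per-individual observed heterozygosity
#'
#' Fraction of heterozygous (CU) calls over non-missing genotypes per
#' individual, with a two-sample Kolmogorov-Smirnov comparison between
#' populations (performed when there are exactly two).
#'
#' @param geno character matrix of genotype codes (loci x individuals);
#'   pass only polymorphic loci for the conventional statistic.
#' @param populations factor of population labels.
#' @return list: `het` (per individual; NA with warning for all-missing
#'   individuals), `population_means`, `ks` (statistic + p, or NULL).
#' @export
individual_heterozygosity <- function(geno, populations) {
  populations <- as.factor(populations)
  called <- colSums(!is.na(geno))
  het <- colSums(geno == "CU", na.rm = TRUE) / called
  if (any(called == 0L)) {
    warning("individual(s) with no called genotypes: heterozygosity NA")
    het[called == 0L] <- NA_real_
  }
  pop_means <- tapply(het, populations, mean, na.rm = TRUE)
  ks <- NULL
  if (nlevels(populations) == 2L) {
    sp <- split(het, populations)
    ks <- ks_safe(sp[[1L]], sp[[2L]])
  }
  list(het = het, population_means = pop_means, ks = ks)
}

#' Hardy-Weinberg equilibrium chi-square tests
#'
#' Per locus and population, a 1-df chi-square comparing observed genotype
#' counts with Hardy-Weinberg expectations from the estimated allele
#' frequency, with Benjamini-Hochberg adjustment over all tests. Tests
#' with any expected count below 1 are flagged low-power; monomorphic
#' samples give p = 1.
#'
#' @param geno character matrix of genotype codes (loci x individuals).
#' @param populations factor of population labels.
#' @return data.frame: locus_id, population, n, p_mutant, chisq, p_value,
#'   p_adj, low_power.
#' @export
hwe_test <- function(geno, populations) {
  populations <- as.factor(populations)
  locus_ids <- rownames(geno)
  if (is.null(locus_ids)) locus_ids <- as.character(seq_len(nrow(geno)))
  out <- lapply(levels(populations), function(pop) {
    sub <- geno[, populations == pop, drop = FALSE]
    nCC <- rowSums(sub == "CC", na.rm = TRUE)
    nCU <- rowSums(sub == "CU", na.rm = TRUE)
    nUU <- rowSums(sub == "UU", na.rm = TRUE)
    n <- nCC + nCU + nUU
    p <- ifelse(n > 0, (2 * nUU + nCU) / (2 * n), NA_real_)
    eCC <- n * (1 - p)^2; eCU <- 2 * n * p * (1 - p); eUU <- n * p^2
    chisq <- rep(0, nrow(sub))
    for (k in 1:3) {
      o <- list(nCC, nCU, nUU)[[k]]; e <- list(eCC, eCU, eUU)[[k]]
      term <- ifelse(e > 0, (o - e)^2 / e, 0)
      chisq <- chisq + term
    }
    chisq[is.na(p)] <- NA_real_
    pval <- ifelse(is.na(chisq), NA_real_,
                   ifelse(p %in% c(0, 1), 1,
                          pchisq(chisq, df = 1, lower.tail = FALSE)))
    data.frame(locus_id = locus_ids, population = pop, n = n,
               p_mutant = p, chisq = chisq, p_value = pval,
               low_power = pmin(eCC, eCU, eUU) < 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

# Deal K mutant allele copies into population pools of sizes `sizes`
# (allele copies), n_perm times: sequential hypergeometric draws, exactly
# the distribution of shuffling the 2n copies and dealing them back.
deal_alleles <- function(K, sizes, n_perm) {
  r <- length(sizes)
  out <- matrix(0, n_perm, r)
  remK <- rep(K, n_perm)
  remN <- sum(sizes)
  for (j in seq_len(r - 1L)) {
    out[, j] <- rhyper(n_perm, remK, remN - remK, sizes[j])
    remK <- remK - out[, j]
    remN <- remN - sizes[j]
  }
  out[, r] <- remK
  out
}

#' Permutation test of panmixia on the F_ST distribution
#'
#' For each permutation and locus, the 2n called allele copies are
#' shuffled across all individuals and dealt back into the populations
#' (implemented by multivariate hypergeometric draws, the exact
#' distribution of that shuffle), and per-locus F_ST is recomputed with
#' the plug-in estimator. The observed genome-wide F_ST distribution is
#' then compared with the permuted ones.
#'
#' @param geno character matrix of genotype codes (loci x individuals).
#' @param populations factor of population labels (>= 2 populations).
#' @param n_permutations number of permutations; default 10000.
#' @param seed RNG seed.
#' @param tail_cutoff F_ST tail threshold for the excess-count summary;
#'   default 0.2.
#' @param unit `"allele"` (shuffle allele copies, the default) or
#'   `"individual"` (permute individuals' population labels), the latter
#'   provided for sensitivity analysis.
#' @return object of class `rsta_permsum`: observed per-locus fst and
#'   summary stats; per-permutation mean/median/sd and tail counts;
#'   `rank_observed_mean` (mid-rank of the observed mean among permuted
#'   means, in \[0, 1\]); `frac_narrower` (fraction of permutations whose
#'   F_ST distribution has smaller sd than observed); `ks_vs_mean_perm`
#'   (KS of observed vs the rank-averaged permuted distribution).
#' @export
permute_panmixia <- function(geno, populations, n_permutations = 10000L,
                             seed = NULL, tail_cutoff = 0.2,
                             unit = c("allele", "individual")) {
  unit <- match.arg(unit)
  populations <- as.factor(populations)
  stopifnot(nlevels(populations) >= 2L)
  af <- allele_frequencies(geno, populations)
  obs <- fst_table(af$p, af$n_called)
  keep <- is.finite(obs$fst)
  obs_fst <- obs$fst[keep]
  L <- sum(keep)
  with_seed(seed, {
    if (unit == "allele") {
      copies <- 2 * af$n_called[keep, , drop = FALSE]
      K <- round(af$p[keep, , drop = FALSE] * copies)
      Ktot <- rowSums(K)
      perm_fst <- matrix(NA_real_, n_permutations, L)
      for (l in seq_len(L)) {
        counts <- deal_alleles(Ktot[l], copies[l, ], n_permutations)
        pm <- sweep(counts, 2L, copies[l, ], "/")
        h_s <- rowMeans(2 * pm * (1 - pm))
        pbar <- rowMeans(pm)
        h_t <- 2 * pbar * (1 - pbar)
        perm_fst[, l] <- ifelse(h_t > 0, (h_t - h_s) / h_t, NA_real_)
      }
    } else {
      perm_fst <- matrix(NA_real_, n_permutations, L)
      for (b in seq_len(n_permutations)) {
        pp <- sample(populations)
        afp <- allele_frequencies(geno[keep, , drop = FALSE], pp)
        perm_fst[b, ] <- fst_table(afp$p, afp$n_called)$fst
      }
    }
    perm_mean <- rowMeans(perm_fst, na.rm = TRUE)
    perm_median <- apply(perm_fst, 1L, stats::median, na.rm = TRUE)
    perm_sd <- apply(perm_fst, 1L, sd, na.rm = TRUE)
    perm_tail <- rowSums(perm_fst > tail_cutoff, na.rm = TRUE)
    obs_mean <- mean(obs_fst)
    rank_obs <- (sum(perm_mean < obs_mean) +
                   0.5 * sum(perm_mean == obs_mean)) / n_permutations
    # rank-averaged permuted distribution (mean of sorted values)
    mean_perm_dist <- colMeans(t(apply(perm_fst, 1L, sort,
                                       na.last = TRUE)), na.rm = TRUE)
    structure(list(
      observed = obs, observed_fst = obs_fst,
      observed_mean = obs_mean, observed_median = stats::median(obs_fst),
      observed_sd = sd(obs_fst),
      observed_tail_count = sum(obs_fst > tail_cutoff),
      n_permutations = n_permutations, tail_cutoff = tail_cutoff,
      perm_mean = perm_mean, perm_median = perm_median,
      perm_sd = perm_sd, perm_tail_count = perm_tail,
      rank_observed_mean = rank_obs,
      frac_narrower = mean(perm_sd < sd(obs_fst)),
      frac_tail_exceeds = mean(perm_tail >= sum(obs_fst > tail_cutoff)),
      ks_vs_mean_perm = ks_safe(obs_fst, mean_perm_dist)),
      class = "rsta_permsum")
  })
}

#' PCA of individuals from the log-ratio matrix
#'
#' Centered covariance PCA with loci as variables and individuals as
#' observations (deterministic up to component sign). Loci with any
#' missing value are dropped. Supports the three conventional locus
#' subsets: all polymorphic loci, polymorphic loci excluding the top-F_ST
#' tail, and the top-F_ST tail alone.
#'
#' @param log_ratio_matrix loci x individuals matrix.
#' @param subset optional character vector of locus ids (rows) to use.
#' @param n_components number of components returned (>= 3 when
#'   available).
#' @return list: `scores` (individuals x components), `var_explained`
#'   (fraction per component), `n_loci`.
#' @export
pca_individuals <- function(log_ratio_matrix, subset = NULL,
                            n_components = 3L) {
  X <- log_ratio_matrix
  if (!is.null(subset)) X <- X[rownames(X) %in% subset, , drop = FALSE]
  X <- X[complete.cases(X), , drop = FALSE]
  stopifnot(nrow(X) >= 1L)
  pc <- prcomp(t(X), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       n_loci = nrow(X))
}

#' Top-F_ST locus subset
#'
#' Loci strictly above the genome-wide `mean + 2 sd` of per-locus F_ST —
#' the conventional tail rule for putatively differentiated loci.
#'
#' @param fst named numeric vector of per-locus F_ST (names = locus ids).
#' @param n_sd number of standard deviations above the mean; default 2.
#' @return list: `ids` (locus ids above the threshold), `threshold`.
#' @export
top_fst_subset <- function(fst, n_sd = 2) {
  keep <- is.finite(fst)
  thr <- mean(fst[keep]) + n_sd * sd(fst[keep])
  list(ids = names(fst)[keep & fst > thr], threshold = thr)
}

#' Correlation of F_ST between paired loci
#'
#' Pearson correlation between the F_ST values of paired loci (e.g. a
#' coding locus and the upstream locus of the same gene), with a
#' pair-label permutation p-value.
#'
#' @param fst_a,fst_b aligned numeric vectors of per-locus F_ST (pair i =
#'   `fst_a[i]`, `fst_b[i]`); incomplete pairs dropped.
#' @param n_permutations permutations for the p-value; default 10000.
#' @param seed RNG seed.
#' @return list: `r`, `p_value`, `n_pairs`.
#' @export
paired_fst_correlation <- function(fst_a, fst_b, n_permutations = 10000L,
                                   seed = NULL) {
  keep <- is.finite(fst_a) & is.finite(fst_b)
  a <- fst_a[keep]; b <- fst_b[keep]
  stopifnot(length(a) >= 3L)
  r <- cor(a, b)
  with_seed(seed, {
    rperm <- vapply(seq_len(n_permutations), function(i)
      cor(a, sample(b)), 0)
    p <- (1 + sum(abs(rperm) >= abs(r))) / (n_permutations + 1)
    list(r = r, p_value = p, n_pairs = length(a))
  })
}

#' Pairwise linkage-disequilibrium screen
#'
#' For each locus pair, a chi-square statistic on the 3x3 genotype
#' contingency table with a p-value from genotype-label permutation
#' (a permutation contingency test, standing in for an exact genotypic LD
#' test), Benjamini-Hochberg adjusted over all pairs. Pairs with fewer
#' than `min_jointly_called` jointly genotyped individuals are skipped.
#'
#' @param geno character matrix of genotype codes (loci x individuals).
#' @param loci locus ids (rows of `geno`) to screen pairwise.
#' @param n_permutations permutations per pair; default 1000.
#' @param seed RNG seed.
#' @param min_jointly_called minimum jointly called individuals; default 5.
#' @return data.frame: locus_a, locus_b, n, chisq, p_value, p_adj,
#'   skipped.
#' @export
ld_screen <- function(geno, loci, n_permutations = 1000L, seed = NULL,
                      min_jointly_called = 5L) {
  stopifnot(all(loci %in% rownames(geno)), length(loci) >= 2L)
  pairs <- utils::combn(loci, 2L)
  code <- c(CC = 1L, CU = 2L, UU = 3L)
  chisq_33 <- function(x, y) {
    tab <- tabulate(x + 3L * (y - 1L), 9L)
    tab <- matrix(tab, 3L)
    rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
    e <- outer(rs, cs) / n
    sum(ifelse(e > 0, (tab - e)^2 / e, 0))
  }
  with_seed(seed, {
    rows <- lapply(seq_len(ncol(pairs)), function(i) {
      la <- pairs[1L, i]; lb <- pairs[2L, i]
      x <- code[geno[la, ]]; y <- code[geno[lb, ]]
      keep <- !is.na(x) & !is.na(y)
      n <- sum(keep)
      if (n < min_jointly_called)
        return(data.frame(locus_a = la, locus_b = lb, n = n,
                          chisq = NA_real_, p_value = NA_real_,
                          skipped = TRUE, stringsAsFactors = FALSE))
      x <- x[keep]; y <- y[keep]
      stat <- chisq_33(x, y)
      perm <- vapply(seq_len(n_permutations), function(b)
        chisq_33(x, sample(y)), 0)
      p <- (1 + sum(perm >= stat)) / (n_permutations + 1)
      data.frame(locus_a = la, locus_b = lb, n = n, chisq = stat,
                 p_value = p, skipped = FALSE, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_adj <- p.adjust(out$p_value, method = "BH")
    out
  })
}

#' Fisher's combined probability test
#'
#' Combines k independent p-values as `X = -2 * sum(log(p))`, chi-square
#' distributed with 2k degrees of freedom under the global null.
#'
#' @param p_values numeric vector of p-values in (0, 1\].
#' @return list: `statistic`, `df`, `p_value`.
#' @export
fishers_combined <- function(p_values) {
  stopifnot(length(p_values) >= 1L, all(p_values > 0),
            all(p_values <= 1))
  X <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(statistic = X, df = df,
       p_value = pchisq(X, df = df, lower.tail = FALSE))
}
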