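logsumexp_rows <- function(m) {
  mx <- m[, 1L]
  k <- ncol(m)
  if (k > 1L) for (j in 2:k) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

kmeanspp_centers <- function(x, k) {
  centers <- numeric(k)
  centers[1L] <- x[sample.int(length(x), 1L)]
  if (k > 1L) {
    dmin <- (x - centers[1L])^2
    for (j in 2:k) {
      centers[j] <- if (sum(dmin) == 0)
        x[sample.int(length(x), 1L)]
      else x[sample.int(length(x), 1L, prob = dmin)]
      dmin <- pmin(dmin, (x - centers[j])^2)
    }
  }
  centers
}

sqdiff <- function(x, mu, n, k) {
  d2 <- (x - rep(mu, each = n))^2
  dim(d2) <- c(n, k)
  d2
}

em_once <- function(x, k, tol, max_iter, vfloor) {
  n <- length(x)
  mu <- kmeanspp_centers(x, k)
  assign0 <- max.col(-sqdiff(x, mu, n, k))
  w <- tabulate(assign0, k) / n
  w <- pmax(w, 1e-6); w <- w / sum(w)
  v <- vapply(seq_len(k), function(j) {
    xi <- x[assign0 == j]
    if (length(xi) > 1L) var(xi) else 0
  }, 0)
  v <- pmax(v, vfloor)
  ll_old <- -Inf; converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E step: log f(x | component) + log weight, all components at once
    d2 <- sqdiff(x, mu, n, k)
    lp <- -0.5 * log(2 * pi) - 0.5 * d2 * rep(1 / v, each = n) -
      rep(0.5 * log(v) - log(w), each = n)
    dim(lp) <- c(n, k)
    lse <- logsumexp_rows(lp)
    ll <- sum(lse)
    resp <- exp(lp - lse)
    nk <- colSums(resp) + 1e-12
    w <- nk / n
    mu <- colSums(resp * x) / nk
    v <- pmax(colSums(resp * sqdiff(x, mu, n, k)) / nk, vfloor)
    # relative convergence on the log-likelihood
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE; break
    }
    ll_old <- ll
  }
  list(loglik = ll, means = mu, variances = v, weights = w,
       resp = resp, converged = converged)
}

#' Univariate Gaussian mixture fit with BIC model selection
#'
#' Expectation-maximization fit of a 1-D Gaussian mixture with
#' component-specific variances (the univariate analogue of
#' unequal-variance spherical components) for each number of components
#' `1..k_max`; the returned model maximizes the Bayesian information
#' criterion. Initialization is k-means++-style with seeded restarts; a
#' small variance floor guards against degenerate point-mass components.
#'
#' @param x numeric values (NAs dropped); with fewer than `2*k_max`
#'   values, `k_max` is reduced.
#' @param k_max maximum number of components; default 4.
#' @param restarts seeded EM restarts per k; default 10.
#' @param seed RNG seed (restart initialization), for determinism.
#' @param tol convergence tolerance on the log-likelihood; default 1e-8.
#' @param max_iter maximum EM iterations per restart.
#' @return object of class `rsta_gmm`: `k` (chosen), `means`, `variances`,
#'   `weights` (sorted by mean), `bic` (per k), `loglik`, `assignments`
#'   (per input value, NA where input was NA), `converged`.
#' @export
fit_gmm_1d <- function(x, k_max = 4L, restarts = 10L, seed = NULL,
                       tol = 1e-8, max_iter = 500L) {
  keep <- is.finite(x)
  xx <- x[keep]
  n <- length(xx)
  if (n < 1L) stop("no finite values to cluster")
  k_max <- max(1L, min(k_max, n %/% 2L, n))
  vx <- if (n > 1L) var(xx) else 0
  vfloor <- max(1e-8, 1e-3 * vx)
  with_seed(seed, {
    fits <- vector("list", k_max)
    bic <- rep(NA_real_, k_max)
    for (k in seq_len(k_max)) {
      best <- NULL
      for (r in seq_len(if (k == 1L) 1L else restarts)) {
        f <- em_once(xx, k, tol, max_iter, vfloor)
        if (is.null(best) || (is.finite(f$loglik) &&
                              f$loglik > best$loglik)) best <- f
      }
      fits[[k]] <- best
      bic[k] <- 2 * best$loglik - (3 * k - 1) * log(n)
    }
    k_hat <- which.max(bic)
    fit <- fits[[k_hat]]
    ord <- order(fit$means)
    assign_kept <- apply(fit$resp[, ord, drop = FALSE], 1L, which.max)
    assignments <- rep(NA_integer_, length(x))
    assignments[keep] <- assign_kept
    structure(list(k = k_hat, means = fit$means[ord],
                   variances = fit$variances[ord],
                   weights = fit$weights[ord],
                   bic = setNames(bic, paste0("k", seq_len(k_max))),
                   loglik = fit$loglik, assignments = assignments,
                   converged = fit$converged),
              class = "rsta_gmm")
  })
}

#' Identify a polymorphic locus from its log-ratio profile
#'
#' A locus is polymorphic when the range of its per-individual log ratios
#' exceeds `range_threshold` AND the mixture model selects more than one
#' cluster. Loci failing either test are monomorphic; the clustering is
#' skipped when the range rule already fails (the conjunction cannot
#' hold). Loci with fewer than 3 unmasked individuals are uncallable.
#'
#' @param log_ratios per-individual averaged log ratios at one locus
#'   (masked individuals excluded beforehand; NAs dropped).
#' @param range_threshold minimum log-ratio range; default 0.7.
#' @param k_max maximum clusters searched; default 4 (letting the
#'   selection consider a fourth helps it settle on three).
#' @param restarts,seed passed to [fit_gmm_1d()].
#' @return list: `callable`, `polymorphic`, `range`, `k` (NA when
#'   clustering was skipped), `fit`.
#' @export
identify_polymorphic <- function(log_ratios, range_threshold = 0.7,
                                 k_max = 4L, restarts = 10L, seed = NULL) {
  xx <- log_ratios[is.finite(log_ratios)]
  if (length(xx) < 3L)
    return(list(callable = FALSE, polymorphic = NA, range = NA_real_,
                k = NA_integer_, fit = NULL))
  rng <- max(xx) - min(xx)
  if (rng <= range_threshold)
    return(list(callable = TRUE, polymorphic = FALSE, range = rng,
                k = NA_integer_, fit = NULL))
  fit <- fit_gmm_1d(log_ratios, k_max = k_max, restarts = restarts,
                    seed = seed)
  list(callable = TRUE, polymorphic = fit$k >= 2L, range = rng,
       k = fit$k, fit = fit)
}

#' Call three-state genotypes from log ratios
#'
#' Fixed-threshold rule on PMT-normalized log ratios: below `lower` is
#' homozygous uncut, above `upper` homozygous cut, between them (bounds
#' included) heterozygous; missing signal gives MISSING. Every finite log
#' ratio receives exactly one call.
#'
#' @param log_ratios numeric vector of per-individual log ratios.
#' @param lower,upper genotype thresholds; defaults -0.6 and -0.1.
#' @return factor with levels HOM_CUT, HET, HOM_UNCUT, MISSING.
#' @export
call_genotypes <- function(log_ratios, lower = -0.6, upper = -0.1) {
  stopifnot(lower < upper)
  call <- ifelse(!is.finite(log_ratios), "MISSING",
                 ifelse(log_ratios < lower, "HOM_UNCUT",
                        ifelse(log_ratios > upper, "HOM_CUT", "HET")))
  factor(call, levels = c("HOM_CUT", "HET", "HOM_UNCUT", "MISSING"))
}

#' Detect an indel locus from Cy5 intensities
#'
#' Deletion alleles abolish binding in the non-digested channel, so indel
#' loci show distinct low (< `low_cutoff`, background range) and normal
#' (> `high_cutoff`) Cy5 clusters. A locus is flagged as an indel when the
#' mixture over raw-scale Cy5 intensities selects two or three clusters
#' AND at least one cluster mean falls below `low_cutoff` AND at least one
#' above `high_cutoff`. Per-individual deletion dosage follows cluster
#' membership: low cluster = 2 deleted alleles, high = 0, intermediate = 1.
#'
#' @param cy5 per-individual mean Cy5 intensities at one locus, on the
#'   original (pre-normalization) intensity scale.
#' @param low_cutoff,high_cutoff intensity cutoffs; defaults 50 and 150.
#' @param k_max maximum clusters; default 3.
#' @param restarts,seed passed to [fit_gmm_1d()].
#' @return list: `is_indel`, `k`, `cluster_means`, `dosage` (0/1/2 per
#'   individual, NA when not an indel locus or signal missing).
#' @export
detect_indels <- function(cy5, low_cutoff = 50, high_cutoff = 150,
                          k_max = 3L, restarts = 10L, seed = NULL) {
  xx <- cy5[is.finite(cy5)]
  dosage <- rep(NA_integer_, length(cy5))
  # an indel locus needs cluster means below low_cutoff AND above
  # high_cutoff, impossible unless values fall on both sides
  if (length(xx) < 3L || min(xx) >= low_cutoff || max(xx) <= high_cutoff)
    return(list(is_indel = FALSE, k = NA_integer_,
                cluster_means = NULL, dosage = dosage))
  fit <- fit_gmm_1d(cy5, k_max = k_max, restarts = restarts, seed = seed)
  is_indel <- fit$k >= 2L && any(fit$means < low_cutoff) &&
    any(fit$means > high_cutoff)
  if (is_indel) {
    # cluster rank -> deletion dosage: lowest cluster = 2 deleted
    # alleles, highest = 0, middle (when present) = 1; means are sorted
    cls <- if (fit$k == 2L) c(2L, 0L) else c(2L, rep(1L, fit$k - 2L), 0L)
    dosage <- cls[fit$assignments]
  }
  list(is_indel = is_indel, k = fit$k, cluster_means = fit$means,
       dosage = dosage)
}

#' Compare genotype calls against truth
#'
#' @param calls vector/matrix of genotype codes.
#' @param truth vector/matrix of true codes, same shape; entries with
#'   missing truth are excluded from concordance.
#' @return list: `confusion` (truth x call table), `concordance`
#'   (fraction of correct calls over non-missing truth entries), `n`.
#' @export
evaluate_calls <- function(calls, truth) {
  calls <- as.character(calls); truth <- as.character(truth)
  stopifnot(length(calls) == length(truth))
  keep <- !is.na(truth) & truth != "MISSING"
  calls <- calls[keep]; truth <- truth[keep]
  lev <- sort(unique(c(calls, truth)))
  confusion <- table(truth = factor(truth, lev), call = factor(calls, lev))
  list(confusion = confusion, concordance = mean(calls == truth),
       n = length(truth))
}

genotype_code <- c(HOM_CUT = "CC", HET = "CU", HOM_UNCUT = "UU",
                   MISSING = NA_character_)

#' Write / read a genotype matrix
#'
#' TSV with loci as rows and individuals as columns, cells in
#' `CC`/`CU`/`UU`/`NA` (cut allele = C, uncut = U), plus a two-column
#' population map (individual, population).
#'
#' @param geno character matrix of genotype codes (loci x individuals).
#' @param populations factor/character of population labels per individual
#'   (in column order).
#' @param path TSV path for the matrix.
#' @param popmap_path TSV path for the population map.
#' @return `write_genotype_matrix()`: `path` invisibly;
#'   `read_genotype_matrix()`: list with `geno` and `populations`.
#' @export
write_genotype_matrix <- function(geno, populations, path,
                                  popmap_path = paste0(path, ".popmap")) {
  stopifnot(ncol(geno) == length(populations))
  df <- data.frame(locus_id = rownames(geno), geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  write.table(data.frame(individual = colnames(geno),
                         population = as.character(populations)),
              popmap_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path,
                                 popmap_path = paste0(path, ".popmap")) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character", na.strings = "NA")
  geno <- as.matrix(df[, -1L, drop = FALSE])
  rownames(geno) <- df$locus_id
  bad <- which(!(geno %in% c("CC", "CU", "UU") | is.na(geno)))
  if (length(bad)) stop("invalid genotype code: ", geno[bad[1L]])
  pm <- read.table(popmap_path, sep = "\t", header = TRUE,
                   colClasses = "character")
  populations <- factor(pm$population[match(colnames(geno),
                                            pm$individual)])
  list(geno = geno, populations = populations)
}

#' Minimal VCF-style export of a genotype matrix
#'
#' Treats the cut allele as REF; CC = 0/0, CU = 0/1, UU = 1/1, NA = ./.
#' Coordinates default to placeholders when the manifest lacks genomic
#' positions (simulated loci).
#'
#' @param geno character matrix of genotype codes (loci x individuals).
#' @param path output path.
#' @param manifest optional tile table supplying CHROM/POS per locus.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(geno, path, manifest = NULL) {
  chrom <- rep(".", nrow(geno)); pos <- rep(1L, nrow(geno))
  if (!is.null(manifest)) {
    m <- match(rownames(geno), manifest$tile_id)
    ok <- !is.na(m) & !is.na(manifest$record_id[m]) &
      !is.na(manifest$site_start[m])
    chrom[ok] <- manifest$record_id[m[ok]]
    pos[ok] <- manifest$site_start[m[ok]] + 1L
  }
  gt <- matrix(c(CC = "0/0", CU = "0/1", UU = "1/1")[geno],
               nrow = nrow(geno))
  gt[is.na(gt)] <- "./."
  lines <- c("##fileformat=VCFv4.2",
             "##source=rsta",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(geno)), collapse = "\t"))
  body <- vapply(seq_len(nrow(geno)), function(i)
    paste(c(chrom[i], pos[i], rownames(geno)[i], "C", "T", ".", ".", ".",
            "GT", gt[i, ]), collapse = "\t"), "")
  writeLines(c(lines, body), path)
  invisible(path)
}
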