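#' Run the full calling pipeline on raw scans
#'
#' Chains the analysis steps applied to a set of per-individual raw scans:
#' PMT normalization, replicate aggregation into per-locus log-ratio and
#' Cy5 matrices, poor-binding masking against the negative controls,
#' polymorphism identification (log-ratio range + mixture clustering),
#' fixed-threshold genotype calling at polymorphic loci, and indel
#' detection on the pre-normalization Cy5 intensities.
#'
#' @param scans_raw named list of raw (un-normalized) scan data.frames,
#'   one per individual.
#' @param manifest tile table identifying tile types (and genomic classes
#'   for the masking report).
#' @param range_threshold minimum log-ratio range for a polymorphic locus.
#' @param k_max maximum mixture components for polymorphism
#'   identification.
#' @param lower,upper genotype-call thresholds on the log ratio.
#' @param low_cutoff,high_cutoff Cy5 intensity cutoffs for indel
#'   detection.
#' @param poor_binding_quantile negative-control quantile for masking.
#' @param restarts EM restarts per mixture fit.
#' @param seed base RNG seed; per-locus fits derive seeds from it.
#' @return list: `log_ratio` and `cy5_raw` matrices, `mask`
#'   (poor-binding result), `poly` (per-locus identification table),
#'   `geno` (genotype-code matrix for loci flagged polymorphic),
#'   `indels` (per-locus flags and deletion-dosage matrix).
#' @export
rsta_pipeline <- function(scans_raw, manifest, range_threshold = 0.7,
                          k_max = 4L, lower = -0.6, upper = -0.1,
                          low_cutoff = 50, high_cutoff = 150,
                          poor_binding_quantile = 0.95, restarts = 10L,
                          seed = 1L) {
  scans <- lapply(scans_raw, apply_pmt_normalization)
  mats <- build_signal_matrices(scans, manifest)
  mats_raw <- build_signal_matrices(scans_raw, manifest)
  # negative-control cy5 pool from the raw scans
  neg_ids <- manifest$tile_id[manifest$tile_type == "negative_control"]
  neg_cy5 <- unlist(lapply(scans_raw, function(s) {
    a <- aggregate_replicates(s)
    a$mean_cy5[a$tile_id %in% neg_ids]
  }), use.names = FALSE)
  classes <- manifest$genomic_class[match(rownames(mats_raw$cy5),
                                          manifest$tile_id)]
  mask <- flag_poor_binding(mats_raw$cy5, neg_cy5,
                            quantile_cut = poor_binding_quantile,
                            classes = classes)
  loci <- rownames(mats$log_ratio)
  unmasked <- !mask$mask[loci]
  poly <- lapply(seq_along(loci), function(i) {
    if (!unmasked[i])
      return(data.frame(locus_id = loci[i], callable = FALSE,
                        polymorphic = NA, range = NA_real_,
                        k = NA_integer_, stringsAsFactors = FALSE))
    r <- identify_polymorphic(mats$log_ratio[i, ],
                              range_threshold = range_threshold,
                              k_max = k_max, restarts = restarts,
                              seed = seed + i)
    data.frame(locus_id = loci[i], callable = r$callable,
               polymorphic = isTRUE(r$polymorphic), range = r$range,
               k = r$k, stringsAsFactors = FALSE)
  })
  poly <- do.call(rbind, poly)
  poly_ids <- poly$locus_id[poly$polymorphic %in% TRUE]
  geno <- NULL
  if (length(poly_ids)) {
    calls <- t(apply(mats$log_ratio[poly_ids, , drop = FALSE], 1L,
                     function(x) as.character(
                       call_genotypes(x, lower, upper))))
    geno <- matrix(genotype_code[calls], nrow = length(poly_ids),
                   dimnames = list(poly_ids, colnames(mats$log_ratio)))
  }
  idx <- which(unmasked)
  indel_fits <- lapply(idx, function(i)
    detect_indels(mats_raw$cy5[i, ], low_cutoff = low_cutoff,
                  high_cutoff = high_cutoff, restarts = restarts,
                  seed = seed + 10000L + i))
  indels <- data.frame(
    locus_id = loci[idx],
    is_indel = vapply(indel_fits, `[[`, TRUE, "is_indel"),
    stringsAsFactors = FALSE)
  dosage <- do.call(rbind, lapply(indel_fits, `[[`, "dosage"))
  dimnames(dosage) <- list(loci[idx], colnames(mats_raw$cy5))
  list(log_ratio = mats$log_ratio, cy5_raw = mats_raw$cy5, mask = mask,
       poly = poly, geno = geno,
       indels = list(flags = indels, dosage = dosage))
}

truth_codes <- function(dosage) {
  matrix(c("CC", "CU", "UU")[dosage + 1L], nrow = nrow(dosage),
         dimnames = dimnames(dosage))
}

#' Evaluate pipeline output against simulation truth
#'
#' Truth is taken at the sample level: a locus counts as polymorphic when
#' more than one genotype is realized among the sampled individuals
#' (population-polymorphic loci that are monomorphic in the sample are
#' undetectable by construction).
#'
#' @param result output of [rsta_pipeline()].
#' @param truth truth list from [simulate_genotypes()] (or the `truth`
#'   element of [simulate_dataset()]).
#' @return list: `concordance` (genotype concordance over point-mutation
#'   loci flagged polymorphic; deletion loci are genotyped from the Cy5
#'   channel instead, since a deletion allele contributes to neither
#'   channel and shifts the log ratio towards the cut-homozygote cluster),
#'   `confusion`, `sensitivity` (fraction of sample-polymorphic, unmasked
#'   loci flagged polymorphic), `false_positive_rate`
#'   (sample-monomorphic loci flagged polymorphic), `indel_sensitivity`,
#'   `indel_false_positive_rate`, `indel_dosage_concordance` (deletion
#'   dosage vs truth at correctly flagged indel loci).
#' @export
evaluate_pipeline <- function(result, truth) {
  tc <- truth_codes(truth$dosage)
  sample_poly <- apply(truth$dosage, 1L, function(d) length(unique(d)) > 1L)
  callable <- result$poly$locus_id[result$poly$callable]
  called_poly <- result$poly$locus_id[result$poly$polymorphic %in% TRUE]
  eligible <- intersect(callable, rownames(tc)[sample_poly])
  sensitivity <- if (length(eligible))
    mean(eligible %in% called_poly) else NA_real_
  mono <- intersect(callable, rownames(tc)[!sample_poly])
  fpr <- if (length(mono)) mean(mono %in% called_poly) else NA_real_
  concordance <- NA_real_; confusion <- NULL
  snp_loci <- rownames(tc)[truth$locus_type != "del"]
  if (!is.null(result$geno) && nrow(result$geno)) {
    ids <- intersect(rownames(result$geno), snp_loci)
    ev <- evaluate_calls(result$geno[ids, , drop = FALSE],
                         tc[ids, , drop = FALSE])
    concordance <- ev$concordance; confusion <- ev$confusion
  }
  # indel truth: deletion loci detectable when both homozygote Cy5
  # classes are realized in the sample
  del <- rownames(tc)[truth$locus_type == "del"]
  detectable <- del[apply(truth$dosage[del, , drop = FALSE], 1L,
                          function(d) any(d == 0L) && any(d == 2L))]
  flagged <- result$indels$flags$locus_id[result$indels$flags$is_indel]
  detectable <- intersect(detectable, result$indels$flags$locus_id)
  indel_sens <- if (length(detectable))
    mean(detectable %in% flagged) else NA_real_
  non_del <- setdiff(result$indels$flags$locus_id, del)
  indel_fpr <- if (length(non_del)) mean(non_del %in% flagged) else NA_real_
  hit_del <- intersect(flagged, del)
  indel_dos <- if (length(hit_del)) {
    est <- result$indels$dosage[hit_del, , drop = FALSE]
    mean(est == truth$dosage[hit_del, , drop = FALSE], na.rm = TRUE)
  } else NA_real_
  list(concordance = concordance, confusion = confusion,
       sensitivity = sensitivity, false_positive_rate = fpr,
       indel_sensitivity = indel_sens,
       indel_false_positive_rate = indel_fpr,
       indel_dosage_concordance = indel_dos)
}
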