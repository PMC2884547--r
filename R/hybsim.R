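#' Population simulation settings
#'
#' Defaults emulate the study design the simulator is meant to stand in
#' for: 2 populations of 10 diploid individuals, 24% of cut-site loci
#' polymorphic in the population, 3% of polymorphic loci carrying a
#' deletion allele instead of a point mutation, among-population
#' differentiation around the observed genome-wide level (0.003), and
#' ancestral mutant-allele frequencies uniform on \[0.05, 0.95\].
#'
#' `fst_sim` is calibrated as the realized among-deme G_ST that the
#' simulated truth table carries: internally the Balding-Nichols Beta
#' variance parameter is `r*F/(r - 1 + F)` for `r` populations, which makes
#' the H_T-weighted Wright F_ST of the true per-population frequencies
#' converge to `fst_sim` (see the methods vignette).
#'
#' @param n_populations number of populations.
#' @param n_per_population diploid individuals per population.
#' @param n_loci number of cut-site loci.
#' @param fraction_polymorphic fraction of loci polymorphic in the
#'   population.
#' @param fraction_indel fraction of polymorphic loci whose mutant allele
#'   is a deletion (DEL) rather than a point mutation (SNP).
#' @param fst_sim target among-population G_ST in \[0, 1).
#' @param freq_range range of the uniform ancestral-frequency distribution.
#' @param seed RNG seed.
#' @return object of class `rsta_popspec`.
#' @export
population_spec <- function(n_populations = 2L, n_per_population = 10L,
                            n_loci = 2000L, fraction_polymorphic = 0.24,
                            fraction_indel = 0.03, fst_sim = 0.003,
                            freq_range = c(0.05, 0.95), seed = 1L) {
  stopifnot(n_populations >= 1L, n_per_population >= 1L, n_loci >= 1L,
            fraction_polymorphic >= 0, fraction_polymorphic <= 1,
            fraction_indel >= 0, fraction_indel <= 1,
            fst_sim >= 0, fst_sim < 1)
  structure(list(n_populations = as.integer(n_populations),
                 n_per_population = as.integer(n_per_population),
                 n_loci = as.integer(n_loci),
                 fraction_polymorphic = fraction_polymorphic,
                 fraction_indel = fraction_indel, fst_sim = fst_sim,
                 freq_range = freq_range, seed = as.integer(seed)),
            class = "rsta_popspec")
}

#' Hybridization model parameters
#'
#' Physics of the two-channel scan. Per tile, a base intensity `I0` (drawn
#' once, uniform over `base_intensity_range`) sets the full-binding
#' fluorescence; each allele contributes half a dose scaled by its binding
#' efficiency; the digested (Cy3) channel additionally attenuates cut
#' alleles by `digestion_efficiency` (the fraction of cut-allele DNA
#' actually digested away); both channels get additive background and
#' multiplicative log-normal replicate noise.
#'
#' Binding loss per mismatch is exponential, `exp(-mismatch_decay * m)`,
#' calibrated so four mismatches lose 80% of signal
#' (`mismatch_decay = log(5)/4`).
#'
#' @param base_intensity_range per-tile full-binding intensity range
#'   (fluorescence units).
#' @param background additive background `b` (units); kept below the
#'   deletion signal cutoff so deletion alleles read as background.
#' @param mismatch_decay per-mismatch exponential decay rate.
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal replicate noise (per channel, per replicate).
#' @param deletion_efficiency residual binding fraction of a deletion
#'   allele (~0: total loss over the tile).
#' @param digestion_efficiency fraction of cut-allele DNA removed from the
#'   digested channel (1 = complete digestion; the default 0.8 reflects
#'   incomplete digestion and is calibrated so the noise-free heterozygote
#'   log ratio sits at the midpoint of the heterozygote calling window
#'   after slide-sum normalization, see vignette).
#' @param positive_factor intensity multiplier for multi-copy positive
#'   control tiles.
#' @param replicate_count in-situ replicate synthesis count per tile.
#' @return object of class `rsta_hybmodel`.
#' @export
hyb_model <- function(base_intensity_range = c(150, 1000), background = 10,
                      mismatch_decay = log(5) / 4, noise_cv = 0.08,
                      deletion_efficiency = 0, digestion_efficiency = 0.8,
                      positive_factor = 10, replicate_count = 3L) {
  stopifnot(background >= 0, min(base_intensity_range) > background,
            mismatch_decay > 0, noise_cv >= 0,
            deletion_efficiency >= 0, deletion_efficiency <= 1,
            digestion_efficiency >= 0, digestion_efficiency <= 1,
            replicate_count >= 1L)
  structure(list(base_intensity_range = base_intensity_range,
                 background = background, mismatch_decay = mismatch_decay,
                 noise_cv = noise_cv,
                 deletion_efficiency = deletion_efficiency,
                 digestion_efficiency = digestion_efficiency,
                 positive_factor = positive_factor,
                 replicate_count = as.integer(replicate_count)),
            class = "rsta_hybmodel")
}

#' Balding-Nichols population allele frequencies
#'
#' Draws one frequency per population from a Beta distribution with mean
#' `p_ancestral` and variance `fst * p_ancestral * (1 - p_ancestral)`.
#' `fst = 0` returns `p_ancestral` exactly; fixed loci (`p_ancestral` 0 or
#' 1) are returned unchanged.
#'
#' @param p_ancestral ancestral allele frequency (scalar or vector, one
#'   per locus).
#' @param fst Balding-Nichols variance parameter in \[0, 1).
#' @param n_populations number of populations.
#' @param seed optional RNG seed.
#' @return matrix of frequencies, `length(p_ancestral)` rows x
#'   `n_populations` columns.
#' @export
draw_allele_frequencies <- function(p_ancestral, fst, n_populations,
                                    seed = NULL) {
  stopifnot(all(p_ancestral >= 0), all(p_ancestral <= 1),
            fst >= 0, fst < 1, n_populations >= 1L)
  L <- length(p_ancestral)
  with_seed(seed, {
    if (fst == 0) {
      mat <- matrix(rep(p_ancestral, n_populations), nrow = L)
    } else {
      scale <- (1 - fst) / fst
      mat <- matrix(NA_real_, L, n_populations)
      for (j in seq_len(n_populations)) {
        mat[, j] <- rbeta(L, p_ancestral * scale,
                          (1 - p_ancestral) * scale)
      }
      fixed <- p_ancestral %in% c(0, 1)
      mat[fixed, ] <- p_ancestral[fixed]
    }
    colnames(mat) <- sprintf("pop%d", seq_len(n_populations))
    mat
  })
}

#' Simulate diploid genotypes for structured populations
#'
#' Within each population, mutant-allele dosages are drawn by binomial
#' (Hardy-Weinberg) sampling from that population's frequency. Monomorphic
#' loci are all-CUT; a `fraction_indel` subset of polymorphic loci carries
#' DEL instead of SNP as the mutant allele.
#'
#' @param spec an [population_spec()] object.
#' @return list with `dosage` (loci x individuals integer matrix of mutant
#'   allele counts 0/1/2), `locus_type` (`"monomorphic"`, `"snp"` or
#'   `"del"` per locus), `freqs` (truth table: loci x populations true
#'   mutant frequencies), `populations` (factor per individual), and
#'   `locus_ids`.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "rsta_popspec"))
  L <- spec$n_loci; r <- spec$n_populations; n <- spec$n_per_population
  locus_ids <- sprintf("locus_%05d", seq_len(L))
  populations <- factor(rep(sprintf("pop%d", seq_len(r)), each = n))
  ind_ids <- sprintf("%s_ind%02d", populations,
                     rep(seq_len(n), times = r))
  with_seed(spec$seed, {
    n_poly <- round(L * spec$fraction_polymorphic)
    poly <- sort(sample.int(L, n_poly))
    locus_type <- rep("monomorphic", L)
    locus_type[poly] <- "snp"
    n_del <- round(n_poly * spec$fraction_indel)
    if (n_del > 0L)
      locus_type[sample(poly, n_del)] <- "del"
    freqs <- matrix(0, L, r,
                    dimnames = list(locus_ids, sprintf("pop%d", seq_len(r))))
    if (n_poly > 0L) {
      p_anc <- runif(n_poly, spec$freq_range[1L], spec$freq_range[2L])
      # Balding-Nichols parameter giving realized among-deme G_ST fst_sim
      v <- if (r > 1L) r * spec$fst_sim / (r - 1 + spec$fst_sim) else 0
      freqs[poly, ] <- draw_allele_frequencies(p_anc, v, r)
    }
    dosage <- matrix(0L, L, r * n, dimnames = list(locus_ids, ind_ids))
    for (j in seq_len(r)) {
      cols <- which(as.integer(populations) == j)
      dosage[poly, cols] <- rbinom(n_poly * n, 2L,
                                   rep(freqs[poly, j], times = n))
    }
    list(dosage = dosage, locus_type = locus_type, freqs = freqs,
         populations = populations, locus_ids = locus_ids)
  })
}

#' Hybridization efficiency under tile/sample mismatches
#'
#' Exponential decay of binding with mismatch count,
#' `exp(-lambda * n_mismatches)`. The default rate `log(5)/4` is calibrated
#' so that four mismatches on a 50-bp tile lose exactly 80% of signal.
#'
#' @param n_mismatches number of mismatching bases (vectorized).
#' @param lambda per-mismatch decay rate.
#' @return binding efficiency fraction in (0, 1\].
#' @export
binding_efficiency <- function(n_mismatches, lambda = log(5) / 4) {
  stopifnot(all(n_mismatches >= 0), lambda > 0)
  exp(-lambda * n_mismatches)
}

#' Draw per-tile base intensities
#'
#' Assigns each manifest tile its full-binding intensity `I0`: uniform
#' over the model range for genome-matching tiles, 0 for negative
#' controls, and `positive_factor` times the draw for multi-copy positive
#' controls.
#'
#' @param manifest tile table.
#' @param model an [hyb_model()] object.
#' @param seed RNG seed.
#' @return `manifest` with an `I0` column appended.
#' @export
draw_tile_intensities <- function(manifest, model, seed = NULL) {
  with_seed(seed, {
    I0 <- runif(nrow(manifest), model$base_intensity_range[1L],
                model$base_intensity_range[2L])
    I0[manifest$tile_type == "negative_control"] <- 0
    pos <- manifest$tile_type == "positive_control"
    I0[pos] <- I0[pos] * model$positive_factor
    manifest$I0 <- I0
    manifest
  })
}

allele_eff <- function(allele, model) {
  eff <- numeric(length(allele))
  eff[allele == "CUT"] <- 1
  eff[allele == "SNP"] <- binding_efficiency(1L, model$mismatch_decay)
  eff[allele == "DEL"] <- model$deletion_efficiency
  eff
}

#' Simulate a two-channel array scan for one individual
#'
#' Renders genotypes into per-tile, per-replicate Cy3 (digested) and Cy5
#' (non-digested) intensities. Per allele, the Cy5 contribution is
#' `I0/2 * eff(allele)`; the Cy3 contribution is the same for uncut
#' alleles (SNP, DEL) while cut alleles are attenuated by the digestion
#' efficiency. Degradation tiles use `binding_efficiency(n_mutations)` in
#' both channels; noncut controls bind fully in both; negative controls
#' read background only. Both channels get additive background and
#' multiplicative log-normal noise, independently per replicate.
#'
#' @param alleles data.frame with columns `tile_id`, `allele1`, `allele2`
#'   (values in `CUT`, `SNP`, `DEL`) for the cut-site tiles of this
#'   individual; control tiles need no entry.
#' @param tiles manifest with `I0` (see [draw_tile_intensities()]).
#' @param model an [hyb_model()] object.
#' @param seed RNG seed.
#' @param individual_id optional id stored as an attribute.
#' @return data.frame (scan) with columns tile_id, replicate, cy3, cy5.
#' @export
simulate_scan <- function(alleles, tiles, model, seed = NULL,
                          individual_id = NA_character_) {
  stopifnot(inherits(model, "rsta_hybmodel"), !is.null(tiles$I0))
  ncut <- sum(tiles$tile_type == "cutsite")
  if (ncut > 0L) {
    miss <- setdiff(tiles$tile_id[tiles$tile_type == "cutsite"],
                    alleles$tile_id)
    if (length(miss))
      stop("no genotype supplied for cut-site tile(s): ",
           paste(head(miss, 3L), collapse = ", "))
  }
  amp3 <- amp5 <- numeric(nrow(tiles))
  type <- tiles$tile_type
  # cut-site tiles: half-dose per allele
  ci <- which(type == "cutsite")
  if (length(ci)) {
    m <- match(tiles$tile_id[ci], alleles$tile_id)
    e1 <- allele_eff(alleles$allele1[m], model)
    e2 <- allele_eff(alleles$allele2[m], model)
    cut1 <- alleles$allele1[m] == "CUT"
    cut2 <- alleles$allele2[m] == "CUT"
    digested <- 1 - model$digestion_efficiency
    amp5[ci] <- tiles$I0[ci] * (e1 + e2) / 2
    amp3[ci] <- tiles$I0[ci] *
      (e1 * ifelse(cut1, digested, 1) + e2 * ifelse(cut2, digested, 1)) / 2
  }
  oi <- which(type %in% c("noncut_control", "positive_control"))
  amp5[oi] <- amp3[oi] <- tiles$I0[oi]
  di <- which(type == "degradation")
  if (length(di)) {
    eff <- binding_efficiency(tiles$n_mutations[di], model$mismatch_decay)
    amp5[di] <- amp3[di] <- tiles$I0[di] * eff
  }
  # negative controls keep amplitude 0 (background only)
  R <- model$replicate_count
  mu3 <- rep(amp3 + model$background, each = R)
  mu5 <- rep(amp5 + model$background, each = R)
  with_seed(seed, {
    if (model$noise_cv > 0) {
      sdlog <- sqrt(log(1 + model$noise_cv^2))
      fac3 <- rlnorm(length(mu3), -sdlog^2 / 2, sdlog)
      fac5 <- rlnorm(length(mu5), -sdlog^2 / 2, sdlog)
    } else {
      fac3 <- fac5 <- 1
    }
    scan <- data.frame(tile_id = rep(tiles$tile_id, each = R),
                       replicate = rep.int(seq_len(R), nrow(tiles)),
                       cy3 = mu3 * fac3, cy5 = mu5 * fac5,
                       stringsAsFactors = FALSE)
    attr(scan, "individual_id") <- individual_id
    scan
  })
}

#' PMT-gain (slide-sum) normalization
#'
#' Rescales the Cy5 channel by a single scalar so the slide-wide channel
#' sums are equal, emulating dynamic PMT gain setting that equalizes the
#' overall slide count ratio. All per-tile log ratios shift by one common
#' constant; on a cut-site-dominated array this offsets the homozygous
#' uncut cluster below zero.
#'
#' @param scan a scan data.frame (tile_id, replicate, cy3, cy5).
#' @return the scan with cy5 rescaled; the applied scalar is stored in
#'   attribute `"pmt_scale"`.
#' @export
apply_pmt_normalization <- function(scan) {
  stopifnot(nrow(scan) > 0L)
  s3 <- sum(scan$cy3); s5 <- sum(scan$cy5)
  if (s3 <= 0 || s5 <= 0)
    stop("cannot normalize: a channel has zero total intensity")
  scale <- s3 / s5
  scan$cy5 <- scan$cy5 * scale
  attr(scan, "pmt_scale") <- scale
  scan
}

#' Write / read a scan table
#'
#' Lossless TSV round trip of per-tile, per-replicate two-channel
#' intensities (column order fixed: tile_id, replicate, cy3, cy5).
#'
#' @param scan scan data.frame.
#' @param path TSV path.
#' @return `write_scan()`: `path` invisibly; `read_scan()`: the scan.
#' @export
write_scan <- function(scan, path) {
  write.table(scan[, c("tile_id", "replicate", "cy3", "cy5")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  scan <- read.table(path, sep = "\t", header = TRUE,
                     colClasses = c("character", "integer", "numeric",
                                    "numeric"))
  if (!identical(names(scan), c("tile_id", "replicate", "cy3", "cy5")))
    stop("scan header mismatch")
  scan
}

# Paper-platform control ratios relative to the cut-site tile count.
control_ratios <- c(noncut = 10523 / 50935, negative = 1036 / 50935,
                    positive = 100 / 50935)

#' Simulate a complete array dataset
#'
#' End-to-end synthetic data: genotypes for all individuals, an array
#' manifest whose control-class sizes mirror the published platform ratios,
#' per-tile intensities, and one two-channel scan per individual (raw and
#' PMT-normalized). Cut-site tiles double as loci (tile_id = locus id);
#' genomic classes are assigned at the platform's coding/upstream/
#' intergenic proportions.
#'
#' @param spec an [population_spec()] object.
#' @param model an [hyb_model()] object.
#' @param n_degradation_bases number of degradation-series base tiles to
#'   add (11 tiles each); 0 by default.
#' @return list with `manifest`, `tiles` (manifest + I0), `scans_raw`,
#'   `scans` (normalized), and `truth` (output of [simulate_genotypes()]).
#' @export
simulate_dataset <- function(spec, model = hyb_model(),
                             n_degradation_bases = 0L) {
  truth <- simulate_genotypes(spec)
  L <- spec$n_loci
  class_probs <- c(coding = 27128, upstream = 9418, intergenic = 14389)
  class_probs <- class_probs / sum(class_probs)
  with_seed(spec$seed + 1L, {
    cut <- data.frame(tile_id = truth$locus_ids, record_id = "sim",
                      start = NA_integer_, end = NA_integer_,
                      tile_type = "cutsite",
                      genomic_class = sample(names(class_probs), L,
                                             replace = TRUE,
                                             prob = class_probs),
                      site_start = NA_integer_, n_mutations = NA_integer_,
                      sequence = NA_character_, stringsAsFactors = FALSE)
    nn <- max(1L, round(L * control_ratios["noncut"]))
    ng <- max(1L, round(L * control_ratios["negative"]))
    np <- max(1L, round(L * control_ratios["positive"]))
    ctrl <- data.frame(
      tile_id = c(sprintf("noncut_%05d", seq_len(nn)),
                  sprintf("neg_%05d", seq_len(ng)),
                  sprintf("pos_%05d", seq_len(np))),
      record_id = NA_character_, start = NA_integer_, end = NA_integer_,
      tile_type = rep(c("noncut_control", "negative_control",
                        "positive_control"), c(nn, ng, np)),
      genomic_class = "not_applicable", site_start = NA_integer_,
      n_mutations = NA_integer_, sequence = NA_character_,
      stringsAsFactors = FALSE)
    manifest <- rbind(cut, ctrl)
    if (n_degradation_bases > 0L) {
      deg <- data.frame(
        tile_id = sprintf("degbase_%04d", seq_len(n_degradation_bases)),
        record_id = NA_character_, start = NA_integer_, end = NA_integer_,
        tile_type = "degradation", genomic_class = "not_applicable",
        site_start = NA_integer_, n_mutations = NA_integer_,
        sequence = NA_character_, stringsAsFactors = FALSE)
      deg <- deg[rep(seq_len(n_degradation_bases), each = 11L), ]
      deg$n_mutations <- rep(0:10, times = n_degradation_bases)
      deg$tile_id <- sprintf("%s_deg%02d", deg$tile_id, deg$n_mutations)
      manifest <- rbind(manifest, deg)
    }
    rownames(manifest) <- NULL
    tiles <- draw_tile_intensities(manifest, model)
    # one degradation series derives from one probe region: all 11
    # members share the base tile's intensity
    di <- which(tiles$tile_type == "degradation")
    if (length(di)) {
      series <- sub("_deg\\d+$", "", tiles$tile_id[di])
      base_I0 <- tiles$I0[di][match(series, series)]
      tiles$I0[di] <- base_I0
    }
    mutant <- ifelse(truth$locus_type == "del", "DEL", "SNP")
    inds <- colnames(truth$dosage)
    scans_raw <- lapply(seq_along(inds), function(i) {
      d <- truth$dosage[, i]
      alleles <- data.frame(
        tile_id = truth$locus_ids,
        allele1 = ifelse(d >= 1L, mutant, "CUT"),
        allele2 = ifelse(d == 2L, mutant, "CUT"),
        stringsAsFactors = FALSE)
      simulate_scan(alleles, tiles, model, individual_id = inds[i])
    })
    names(scans_raw) <- inds
    scans <- lapply(scans_raw, apply_pmt_normalization)
    list(manifest = manifest, tiles = tiles, scans_raw = scans_raw,
         scans = scans, truth = truth, spec = spec, model = model)
  })
}
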