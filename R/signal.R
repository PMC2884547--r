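#' Aggregate replicate tiles into per-locus signal
#'
#' Channel intensities are averaged across the in-situ replicates of each
#' tile, and the log ratio is `log2(mean cy5 / mean cy3)` (averaging before
#' the ratio is robust to single-replicate dropouts). `replicate_cv` is
#' sd/mean of the per-replicate log ratios. Tiles with non-positive channel
#' means are flagged and their log ratio marked missing.
#'
#' @param scan scan data.frame (tile_id, replicate, cy3, cy5).
#' @return data.frame, one row per tile: mean_cy3, mean_cy5, n_replicates,
#'   log_ratio, replicate_cv, flag (`"ok"`, `"nonpositive"` or
#'   `"missing_replicates"`).
#' @export
aggregate_replicates <- function(scan) {
  stopifnot(nrow(scan) > 0L)
  dt <- data.table::as.data.table(scan)
  agg <- dt[, {
    ok <- cy3 > 0 & cy5 > 0
    lr <- log2(cy5[ok] / cy3[ok])
    list(mean_cy3 = mean(cy3), mean_cy5 = mean(cy5),
         n_replicates = .N,
         replicate_cv = if (length(lr) >= 2L && mean(lr) != 0)
           sd(lr) / abs(mean(lr)) else NA_real_)
  }, by = tile_id]
  max_rep <- max(agg$n_replicates)
  agg[, log_ratio := ifelse(mean_cy3 > 0 & mean_cy5 > 0,
                            log2(mean_cy5 / mean_cy3), NA_real_)]
  agg[, flag := ifelse(mean_cy3 <= 0 | mean_cy5 <= 0, "nonpositive",
                       ifelse(n_replicates < max_rep,
                              "missing_replicates", "ok"))]
  out <- as.data.frame(agg)
  out <- out[match(unique(scan$tile_id), out$tile_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build locus-level signal matrices across individuals
#'
#' Aggregates each individual's scan and assembles loci x individuals
#' matrices of log ratios, mean Cy5 and mean Cy3. When a manifest is
#' given, rows are restricted to its cut-site tiles.
#'
#' @param scans named list of scan data.frames (one per individual).
#' @param manifest optional tile table used to select cut-site tiles.
#' @return list with matrices `log_ratio`, `cy5`, `cy3`, `replicate_cv`
#'   (loci x individuals).
#' @export
build_signal_matrices <- function(scans, manifest = NULL) {
  stopifnot(length(scans) >= 1L)
  if (is.null(names(scans)) || anyNA(names(scans)))
    names(scans) <- sprintf("ind%02d", seq_along(scans))
  aggs <- lapply(scans, aggregate_replicates)
  ids <- aggs[[1L]]$tile_id
  if (!is.null(manifest))
    ids <- ids[ids %in% manifest$tile_id[manifest$tile_type == "cutsite"]]
  pull <- function(col) {
    m <- vapply(aggs, function(a) a[[col]][match(ids, a$tile_id)],
                numeric(length(ids)))
    dimnames(m) <- list(ids, names(scans))
    m
  }
  list(log_ratio = pull("log_ratio"), cy5 = pull("mean_cy5"),
       cy3 = pull("mean_cy3"), replicate_cv = pull("replicate_cv"))
}

ks_safe <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) return(list(statistic = NA_real_,
                                            p.value = NA_real_))
  kt <- suppressWarnings(ks.test(x, y))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Array quality-control report
#'
#' Mirrors the platform-validation checks of a two-channel cut-site array:
#' Kolmogorov-Smirnov comparisons between channel and control-class
#' intensity distributions (digested Cy3 should sit below non-digested Cy5
#' on cut-site tiles but not on noncut controls; negative controls below,
#' positive controls above, experimental tiles), squared Pearson
#' correlations of per-tile intensities between arrays, and the
#' replicate-CV distribution per channel. Comparisons whose tile class is
#' absent are omitted with a warning.
#'
#' @param scans named list of scan data.frames.
#' @param manifest tile table identifying tile types.
#' @return list with `ks` (data.frame of KS comparisons), `r2_between_arrays`
#'   (matrix of pairwise squared correlations of per-tile Cy5 means),
#'   `replicate_cv` (summary per channel: median intensity CV and median
#'   log-ratio CV).
#' @export
qc_report <- function(scans, manifest) {
  aggs <- lapply(scans, aggregate_replicates)
  all_agg <- do.call(rbind, aggs)
  type <- manifest$tile_type[match(all_agg$tile_id, manifest$tile_id)]
  pool <- function(tt, col) all_agg[[col]][type %in% tt]
  comparisons <- list(
    cutsite_cy3_vs_cy5 = c("cutsite", "cutsite"),
    negative_vs_cutsite_cy5 = c("negative_control", "cutsite"),
    positive_vs_cutsite_cy5 = c("positive_control", "cutsite"),
    noncut_cy3_vs_cy5 = c("noncut_control", "noncut_control"))
  ks <- lapply(names(comparisons), function(nm) {
    tt <- comparisons[[nm]]
    if (!any(type %in% tt[1L]) || !any(type %in% tt[2L])) {
      warning("tile class absent, omitting comparison: ", nm)
      return(NULL)
    }
    if (nm %in% c("cutsite_cy3_vs_cy5", "noncut_cy3_vs_cy5")) {
      r <- ks_safe(pool(tt[1L], "mean_cy3"), pool(tt[2L], "mean_cy5"))
    } else {
      r <- ks_safe(pool(tt[1L], "mean_cy5"), pool(tt[2L], "mean_cy5"))
    }
    data.frame(comparison = nm, statistic = r$statistic,
               p_value = r$p.value, stringsAsFactors = FALSE)
  })
  ks <- do.call(rbind, ks)
  # inter-array reproducibility on per-tile cy5 means
  ids <- aggs[[1L]]$tile_id
  cy5m <- vapply(aggs, function(a) a$mean_cy5[match(ids, a$tile_id)],
                 numeric(length(ids)))
  r2 <- cor(cy5m, use = "pairwise.complete.obs")^2
  # replicate noise: per-channel intensity CV and log-ratio CV
  cvs <- lapply(scans, function(s) {
    dt <- data.table::as.data.table(s)
    dt[, .(cv3 = sd(cy3) / mean(cy3), cv5 = sd(cy5) / mean(cy5)),
       by = tile_id]
  })
  cvs <- data.table::rbindlist(cvs)
  list(ks = ks, r2_between_arrays = r2,
       replicate_cv = c(
         median_channel_cv = stats::median(c(cvs$cv3, cvs$cv5),
                                           na.rm = TRUE),
         median_log_ratio_cv = stats::median(all_agg$replicate_cv,
                                             na.rm = TRUE)))
}

#' Flag loci with poor binding signal
#'
#' A locus is masked when its across-individual mean Cy5 signal does not
#' exceed the given quantile of the negative-control Cy5 intensities,
#' i.e. its non-digested signal is indistinguishable from background.
#' Masked loci are excluded from polymorphism calling. Per-genomic-class
#' masked fractions are reported when classes are supplied.
#'
#' @param cy5_matrix loci x individuals matrix of mean Cy5 intensities.
#' @param negative_cy5 vector of negative-control Cy5 intensities.
#' @param quantile_cut quantile of the negative controls used as the
#'   threshold; default 0.95.
#' @param classes optional genomic class per locus (for the per-class
#'   masked-fraction report).
#' @return list with `mask` (logical per locus, TRUE = poor binding),
#'   `threshold`, and `class_fractions`.
#' @export
flag_poor_binding <- function(cy5_matrix, negative_cy5,
                              quantile_cut = 0.95, classes = NULL) {
  locus_mean <- rowMeans(cy5_matrix, na.rm = TRUE)
  if (length(negative_cy5) == 0L || all(is.na(negative_cy5))) {
    warning("no negative controls: poor-binding masking disabled")
    mask <- setNames(rep(FALSE, nrow(cy5_matrix)), rownames(cy5_matrix))
    return(list(mask = mask, threshold = NA_real_,
                class_fractions = NULL))
  }
  thr <- quantile(negative_cy5, quantile_cut, na.rm = TRUE, names = FALSE)
  mask <- locus_mean <= thr
  names(mask) <- rownames(cy5_matrix)
  class_fractions <- NULL
  if (!is.null(classes))
    class_fractions <- tapply(mask, classes, mean)
  list(mask = mask, threshold = thr, class_fractions = class_fractions)
}
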