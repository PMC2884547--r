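#' Read a genome FASTA
#'
#' Multi-record scaffold assemblies are supported; sequences are uppercased
#' and record identifiers truncated at the first whitespace.
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase DNA sequences.
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(dss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate record identifiers in ", path)
  seqs
}

#' Read gene/exon annotation from GFF3 or BED
#'
#' Returns regions in 0-based half-open coordinates with `kind` restricted
#' to `gene` and `exon` (other feature types are dropped).
#'
#' @param path path to a GFF3 (`.gff`, `.gff3`) or 6-column BED file. For
#'   BED the name column must contain the feature kind.
#' @return data.frame with columns record_id, start, end, kind, strand.
#' @export
read_annotation <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    gr <- as.data.frame(rtracklayer::import(path))
    ann <- data.frame(
      record_id = as.character(gr$seqnames),
      start = gr$start - 1L,
      end = gr$end,
      kind = as.character(gr$type),
      strand = as.character(gr$strand),
      stringsAsFactors = FALSE)
  } else {
    ann <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(ann) < 6)
      stop("BED annotation must have 6 columns (chrom start end name score strand)")
    ann <- data.frame(record_id = as.character(ann[[1]]),
                      start = as.integer(ann[[2]]),
                      end = as.integer(ann[[3]]),
                      kind = as.character(ann[[4]]),
                      strand = as.character(ann[[6]]),
                      stringsAsFactors = FALSE)
  }
  ann <- ann[ann$kind %in% c("gene", "exon"), , drop = FALSE]
  stopifnot(all(ann$start >= 0), all(ann$start < ann$end))
  rownames(ann) <- NULL
  ann
}

#' Scan a genome record for restriction recognition sites
#'
#' Reports every occurrence of the recognition motif (overlapping
#' occurrences included). Positions containing `N` never match. For
#' non-palindromic motifs set `both_strands = TRUE` to also report
#' minus-strand sites (positions of the reverse-complement motif),
#' deduplicated.
#'
#' @param genome_record DNA sequence (single character string).
#' @param motif recognition motif, default TaqI-alpha `"TCGA"`.
#' @param both_strands scan the reverse complement as well.
#' @return sorted integer vector of 0-based site start positions.
#' @export
scan_recognition_sites <- function(genome_record, motif = "TCGA",
                                   both_strands = FALSE) {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) < 1L)
    stop("motif must be a non-empty DNA string")
  stopifnot(is.character(genome_record), length(genome_record) == 1L,
            nchar(genome_record) >= 1L)
  subject <- Biostrings::DNAString(genome_record)
  hit_starts <- function(m) {
    if (nchar(m) > nchar(genome_record)) return(integer(0))
    IRanges::start(Biostrings::matchPattern(m, subject, fixed = TRUE)) - 1L
  }
  pos <- hit_starts(motif)
  if (both_strands) pos <- union(pos, hit_starts(revcomp(motif)))
  sort(unique(as.integer(pos)))
}

empty_tiles <- function() {
  data.frame(tile_id = character(0), record_id = character(0),
             start = integer(0), end = integer(0),
             tile_type = character(0), genomic_class = character(0),
             site_start = integer(0), n_mutations = integer(0),
             sequence = character(0), stringsAsFactors = FALSE)
}

# Center tiles of length tile_len on motif occurrences for one record,
# dropping edge sites, N-containing windows, and BOTH members of any
# overlapping pair (symmetric drop avoids order dependence).
center_tiles_record <- function(record_id, seq, sites, tile_len, motif_len,
                                prefix) {
  flank <- (tile_len - motif_len) %/% 2L
  reclen <- nchar(seq)
  keep <- sites - flank >= 0L & sites + motif_len + flank <= reclen
  sites <- sites[keep]
  if (!length(sites)) return(empty_tiles())
  start <- sites - flank
  end <- start + tile_len
  # symmetric non-overlap filter (sites are sorted)
  bad <- logical(length(start))
  if (length(start) > 1L) {
    ov <- which(start[-1L] < end[-length(end)])
    bad[unique(c(ov, ov + 1L))] <- TRUE
  }
  start <- start[!bad]; end <- end[!bad]; sites <- sites[!bad]
  if (!length(start)) return(empty_tiles())
  sequence <- substring(seq, start + 1L, end)
  okN <- !grepl("N", sequence, fixed = TRUE)
  data.frame(tile_id = sprintf("%s_%s_%d", prefix, record_id, sites[okN]),
             record_id = record_id, start = start[okN], end = end[okN],
             tile_type = "cutsite", genomic_class = "intergenic",
             site_start = sites[okN], n_mutations = NA_integer_,
             sequence = sequence[okN], stringsAsFactors = FALSE)
}

#' Design cut-site-centered array tiles
#'
#' Constructs tiles of length `tile_len` centered on each recognition site:
#' `(tile_len - nchar(motif))/2` bp flank the motif on each side. Sites too
#' close to a record edge are skipped; when two sites are close enough that
#' their tiles would overlap, BOTH tiles are dropped; windows containing
#' `N` are never tiles.
#'
#' @param genome named character vector of DNA records.
#' @param sites optional named list of 0-based site positions per record;
#'   computed with [scan_recognition_sites()] when `NULL`.
#' @param tile_len tile length in bp (even, > motif length); default 50.
#' @param motif recognition motif; default `"TCGA"`.
#' @return tile table (one row per tile) with 0-based half-open
#'   coordinates; `tile_type = "cutsite"`, `genomic_class` provisional
#'   (`"intergenic"` until [classify_tiles()] is applied).
#' @export
design_cut_site_tiles <- function(genome, sites = NULL, tile_len = 50L,
                                  motif = "TCGA") {
  motif_len <- nchar(motif)
  if (tile_len <= motif_len)
    stop("tile_len must exceed the motif length")
  if ((tile_len - motif_len) %% 2L != 0L)
    stop("tile_len minus motif length must be even (motif centered)")
  if (is.null(sites))
    sites <- lapply(genome, scan_recognition_sites, motif = motif)
  out <- lapply(names(genome), function(rid) {
    s <- sites[[rid]]
    if (is.null(s) || !length(s)) return(empty_tiles())
    center_tiles_record(rid, genome[[rid]], sort(as.integer(s)),
                        as.integer(tile_len), motif_len, "cut")
  })
  out <- do.call(rbind, out)
  out <- out[order(out$record_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify tiles by genomic context
#'
#' A tile's 4-bp recognition site is `coding` if it overlaps any exon, else
#' `upstream` if it lies within `upstream_window` bp 5' of a gene start
#' (strand-aware), else `intergenic`. Precedence: coding > upstream >
#' intergenic. Tiles without a genomic site (negative/positive controls,
#' degradation tiles) are `not_applicable`.
#'
#' @param tiles tile table (from [design_cut_site_tiles()] or friends).
#' @param annotation data.frame from [read_annotation()].
#' @param upstream_window size of the upstream promoter window in bp.
#' @param motif_len recognition-site length (default 4).
#' @return `tiles` with `genomic_class` filled in.
#' @export
classify_tiles <- function(tiles, annotation, upstream_window = 1000L,
                           motif_len = 4L) {
  has_site <- !is.na(tiles$site_start)
  cls <- ifelse(has_site, "intergenic", "not_applicable")
  ex <- annotation[annotation$kind == "exon", , drop = FALSE]
  gn <- annotation[annotation$kind == "gene", , drop = FALSE]
  # strand-aware upstream windows (0-based half-open)
  if (nrow(gn)) {
    up_start <- ifelse(gn$strand == "-", gn$end,
                       pmax(0L, gn$start - upstream_window))
    up_end <- ifelse(gn$strand == "-", gn$end + upstream_window, gn$start)
  }
  for (rid in unique(tiles$record_id[has_site])) {
    idx <- which(tiles$record_id == rid & has_site)
    site <- IRanges::IRanges(start = tiles$site_start[idx] + 1L,
                             width = motif_len)
    exr <- ex[ex$record_id == rid, , drop = FALSE]
    if (nrow(exr)) {
      er <- IRanges::IRanges(start = exr$start + 1L, end = exr$end)
      hit <- IRanges::overlapsAny(site, er)
      cls[idx[hit]] <- "coding"
    }
    gni <- which(gn$record_id == rid)
    if (length(gni)) {
      ur <- IRanges::IRanges(start = up_start[gni] + 1L, end = up_end[gni])
      ur <- ur[IRanges::width(ur) > 0L]
      if (length(ur)) {
        hit <- IRanges::overlapsAny(site, ur)
        cls[idx[hit & cls[idx] != "coding"]] <- "upstream"
      }
    }
  }
  tiles$genomic_class <- cls
  tiles
}

# Count genome locations (record, strand, position) whose ungapped local
# alignment with each query exceeds identity_threshold over the full query
# length. Seed-and-extend: exact k-mer seeds locate candidate diagonals,
# then full-length Hamming identity is computed. The default k = 10 is
# pigeonhole-complete for identity > 0.90 on 50-bp queries (at most 4
# mismatches leave an exact run of >= 10 bases).
count_genome_hits <- function(sequences, genome, identity_threshold = 0.90,
                              seed_k = 10L) {
  w <- unique(nchar(sequences))
  if (length(w) != 1L) stop("all query sequences must have equal length")
  if (seed_k > w) stop("seed_k exceeds query length")
  subjects <- c(as.list(genome), as.list(revcomp(unlist(genome))))
  names(subjects) <- c(paste0(names(genome), "|+"),
                       paste0(names(genome), "|-"))
  subjects <- subjects[nchar(unlist(subjects)) >= w]
  idx <- data.table::rbindlist(lapply(names(subjects), function(sn) {
    s <- subjects[[sn]]
    L <- nchar(s)
    data.table::data.table(
      kmer = substring(s, 1:(L - seed_k + 1L), seed_k:L),
      subj = sn, pos = 1:(L - seed_k + 1L))
  }))
  data.table::setkey(idx, kmer)
  seeds <- data.table::rbindlist(lapply(seq_along(sequences), function(i) {
    data.table::data.table(
      kmer = substring(sequences[i], 1:(w - seed_k + 1L), seed_k:w),
      query = i, offset = 1:(w - seed_k + 1L))
  }))
  cand <- idx[seeds, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  n_hits <- integer(length(sequences))
  if (!nrow(cand)) return(n_hits)
  cand[, astart := pos - offset + 1L]
  cand <- unique(cand[, .(query, subj, astart)])
  cand <- cand[astart >= 1L]
  cand[, slen := nchar(unlist(subjects))[match(subj, names(subjects))]]
  cand <- cand[astart + w - 1L <= slen]
  if (!nrow(cand)) return(n_hits)
  qint <- lapply(sequences, utf8ToInt)
  min_match <- identity_threshold * w
  cand[, window := substring(unlist(subjects)[match(subj, names(subjects))],
                             astart, astart + w - 1L)]
  cand[, matches := mapply(function(win, q)
    sum(utf8ToInt(win) == qint[[q]]), window, query)]
  hits <- cand[matches > min_match, .N, by = query]
  n_hits[hits$query] <- hits$N
  n_hits
}

#' Uniqueness screen for array tiles
#'
#' Excludes tiles with more than one genome location (origin included, both
#' strands) whose ungapped alignment identity over the full tile exceeds
#' `identity_threshold`. This deterministic seed-and-extend screen plays
#' the role a BLASTN cross-reactivity screen plays in array design.
#'
#' @param tiles tile table carrying sequences.
#' @param genome named character vector of DNA records.
#' @param identity_threshold minimum identity fraction counted as a hit
#'   (strict inequality); default 0.90.
#' @param seed_k exact-seed length; the default 10 guarantees no hit above
#'   the default threshold is missed on 50-bp tiles.
#' @return list with `retained` (tiles with exactly one hit), `excluded`
#'   (tiles with >= 2 hits, plus an `n_hits` column), and `n_hits` for all
#'   input tiles.
#' @export
uniqueness_filter <- function(tiles, genome, identity_threshold = 0.90,
                              seed_k = 10L) {
  if (!nrow(tiles))
    return(list(retained = tiles, excluded = tiles, n_hits = integer(0)))
  n_hits <- count_genome_hits(tiles$sequence, genome,
                              identity_threshold, seed_k)
  excluded <- tiles[n_hits >= 2L, , drop = FALSE]
  excluded$n_hits <- n_hits[n_hits >= 2L]
  retained <- tiles[n_hits == 1L, , drop = FALSE]
  rownames(retained) <- rownames(excluded) <- NULL
  list(retained = retained, excluded = excluded, n_hits = n_hits)
}

#' Generate control tiles
#'
#' Three control classes: `noncut` tiles centered on a non-cut motif
#' (default `"TTGA"`) passing the same overlap and uniqueness screens as
#' cut-site tiles; `negative` random tiles with zero genome hits above the
#' identity threshold (background / cross-reactivity controls); `positive`
#' windows of a supplied multi-copy sequence (hybridization-efficiency
#' controls, e.g. ribosomal DNA).
#'
#' @param genome named character vector of DNA records.
#' @param n_noncut,n_negative,n_positive tile counts per class.
#' @param multicopy_sequence DNA string for positive controls (required if
#'   `n_positive > 0`).
#' @param seed RNG seed (sampling of noncut sites and negative sequences).
#' @param tile_len tile length; default 50.
#' @param noncut_motif central motif of noncut controls; default `"TTGA"`.
#' @param identity_threshold uniqueness threshold, as in
#'   [uniqueness_filter()].
#' @param avoid optional tile table whose genome footprint noncut tiles
#'   must not overlap (e.g. the cut-site tiles of the same array).
#' @return tile table of the requested control tiles.
#' @export
generate_control_tiles <- function(genome, n_noncut = 0L, n_negative = 0L,
                                   n_positive = 0L,
                                   multicopy_sequence = NULL, seed = NULL,
                                   tile_len = 50L, noncut_motif = "TTGA",
                                   identity_threshold = 0.90,
                                   avoid = NULL) {
  with_seed(seed, {
    out <- list()
    if (n_noncut > 0L) {
      cand <- do.call(rbind, lapply(names(genome), function(rid) {
        s <- scan_recognition_sites(genome[[rid]], noncut_motif)
        if (!length(s)) return(empty_tiles())
        center_tiles_record(rid, genome[[rid]], s, as.integer(tile_len),
                            nchar(noncut_motif), "noncut")
      }))
      if (!is.null(avoid) && nrow(cand) && nrow(avoid)) {
        drop <- logical(nrow(cand))
        for (rid in unique(cand$record_id)) {
          ci <- which(cand$record_id == rid)
          ai <- which(avoid$record_id == rid)
          if (!length(ai)) next
          ov <- IRanges::overlapsAny(
            IRanges::IRanges(cand$start[ci] + 1L, cand$end[ci]),
            IRanges::IRanges(avoid$start[ai] + 1L, avoid$end[ai]))
          drop[ci[ov]] <- TRUE
        }
        cand <- cand[!drop, , drop = FALSE]
      }
      if (nrow(cand))
        cand <- uniqueness_filter(cand, genome, identity_threshold)$retained
      if (nrow(cand) < n_noncut)
        stop(sprintf("cannot satisfy noncut control count: %d requested, %d available",
                     n_noncut, nrow(cand)))
      cand <- cand[sort(sample.int(nrow(cand), n_noncut)), , drop = FALSE]
      cand$tile_type <- "noncut_control"
      out$noncut <- cand
    }
    if (n_negative > 0L) {
      found <- character(0)
      attempts <- 0L
      while (length(found) < n_negative && attempts < 50L) {
        batch <- vapply(seq_len(max(n_negative, 8L)), function(i)
          paste(sample(c("A", "C", "G", "T"), tile_len, replace = TRUE),
                collapse = ""), "")
        hits <- count_genome_hits(batch, genome, identity_threshold)
        found <- unique(c(found, batch[hits == 0L]))
        attempts <- attempts + 1L
      }
      if (length(found) < n_negative)
        stop(sprintf("cannot satisfy negative control count: %d requested, %d found",
                     n_negative, length(found)))
      found <- found[seq_len(n_negative)]
      neg <- empty_tiles()[rep(1L, 0L), ]
      neg <- data.frame(tile_id = sprintf("neg_%04d", seq_len(n_negative)),
                        record_id = NA_character_, start = NA_integer_,
                        end = NA_integer_, tile_type = "negative_control",
                        genomic_class = "not_applicable",
                        site_start = NA_integer_,
                        n_mutations = NA_integer_, sequence = found,
                        stringsAsFactors = FALSE)
      out$negative <- neg
    }
    if (n_positive > 0L) {
      if (is.null(multicopy_sequence))
        stop("cannot satisfy positive control count: no multicopy sequence supplied")
      L <- nchar(multicopy_sequence)
      if (L < tile_len + n_positive - 1L)
        stop(sprintf("cannot satisfy positive control count: multicopy sequence too short (%d bp)", L))
      starts <- unique(round(seq(1L, L - tile_len + 1L,
                                 length.out = n_positive)))
      starts <- starts[seq_len(n_positive)]
      out$positive <- data.frame(
        tile_id = sprintf("pos_%04d", seq_len(n_positive)),
        record_id = NA_character_, start = NA_integer_, end = NA_integer_,
        tile_type = "positive_control", genomic_class = "not_applicable",
        site_start = NA_integer_, n_mutations = NA_integer_,
        sequence = substring(multicopy_sequence, starts,
                             starts + tile_len - 1L),
        stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    if (is.null(res)) res <- empty_tiles()
    rownames(res) <- NULL
    res
  })
}

#' Generate a mismatch degradation series
#'
#' For each genome-unique base tile, emits the perfect-match tile
#' (`n_mutations = 0`) plus one tile per mutation count `1..max_mutations`.
#' Mutated positions are chosen uniformly without replacement and each
#' substituted base differs from the original, so the Hamming distance of
#' tile *m* from its base is exactly *m*. Used to calibrate hybridization
#' loss per mismatch.
#'
#' @param base_tiles tile table of genome-unique tiles.
#' @param max_mutations maximum number of substitutions; default 10.
#' @param seed RNG seed.
#' @return tile table with `tile_type = "degradation"`; `nrow(base_tiles) *
#'   (max_mutations + 1)` rows.
#' @export
generate_degradation_series <- function(base_tiles, max_mutations = 10L,
                                        seed = NULL) {
  w <- unique(nchar(base_tiles$sequence))
  stopifnot(length(w) == 1L)
  if (max_mutations > w)
    stop("max_mutations exceeds tile length")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(base_tiles)), function(i) {
      bt <- base_tiles[i, ]
      seqs <- character(max_mutations + 1L)
      seqs[1L] <- bt$sequence
      for (m in seq_len(max_mutations)) {
        s <- strsplit(bt$sequence, "")[[1L]]
        pos <- sample.int(w, m)
        for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
        seqs[m + 1L] <- paste(s, collapse = "")
      }
      data.frame(tile_id = sprintf("%s_deg%02d", bt$tile_id,
                                   0:max_mutations),
                 record_id = bt$record_id, start = bt$start, end = bt$end,
                 tile_type = "degradation", genomic_class = "not_applicable",
                 site_start = NA_integer_, n_mutations = 0:max_mutations,
                 sequence = seqs, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
  })
}

manifest_cols <- c("tile_id", "record_id", "start", "end", "tile_type",
                   "genomic_class", "site_start", "n_mutations", "sequence")
tile_types <- c("cutsite", "noncut_control", "negative_control",
                "positive_control", "degradation")
genomic_classes <- c("coding", "upstream", "intergenic", "not_applicable")

#' Write / read a tile manifest
#'
#' Lossless TSV round trip of a tile table (the array platform
#' description). `write_manifest()` can additionally emit a companion FASTA
#' of tile sequences.
#'
#' @param tiles tile table.
#' @param path TSV path.
#' @param fasta optional path for a companion FASTA of tile sequences.
#' @return `write_manifest()`: `path`, invisibly. `read_manifest()`: the
#'   tile table; malformed rows raise an error naming the offending line.
#' @export
write_manifest <- function(tiles, path, fasta = NULL) {
  stopifnot(all(manifest_cols %in% names(tiles)))
  write.table(tiles[, manifest_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  if (!is.null(fasta)) {
    dss <- Biostrings::DNAStringSet(tiles$sequence)
    names(dss) <- tiles$tile_id
    Biostrings::writeXStringSet(dss, fasta)
  }
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  raw <- read.table(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = "character", na.strings = "NA")
  if (!identical(names(raw), manifest_cols))
    stop("manifest header mismatch: expected ",
         paste(manifest_cols, collapse = ", "))
  conv_int <- function(col) {
    x <- suppressWarnings(as.integer(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(x))
    if (length(bad))
      stop(sprintf("malformed manifest row at line %d: non-integer %s",
                   bad[1L] + 1L, col))
    x
  }
  out <- data.frame(tile_id = raw$tile_id, record_id = raw$record_id,
                    start = conv_int("start"), end = conv_int("end"),
                    tile_type = raw$tile_type,
                    genomic_class = raw$genomic_class,
                    site_start = conv_int("site_start"),
                    n_mutations = conv_int("n_mutations"),
                    sequence = raw$sequence, stringsAsFactors = FALSE)
  bad <- which(!out$tile_type %in% tile_types)
  if (length(bad))
    stop(sprintf("malformed manifest row at line %d: unknown tile_type '%s'",
                 bad[1L] + 1L, out$tile_type[bad[1L]]))
  bad <- which(!out$genomic_class %in% genomic_classes)
  if (length(bad))
    stop(sprintf("malformed manifest row at line %d: unknown genomic_class '%s'",
                 bad[1L] + 1L, out$genomic_class[bad[1L]]))
  out
}
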