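test_that("recognition-site scanning finds exact, overlapping, N-free matches", {
  expect_equal(scan_recognition_sites("ATCGAT", "TCGA"), 1L)
  expect_equal(scan_recognition_sites("TCGATCGA", "TCGA"), c(0L, 4L))
  # overlapping occurrences all reported
  expect_equal(scan_recognition_sites("AAAA", "AA"), 0:2)
  # N never matches
  expect_equal(scan_recognition_sites("TCGNTCGA", "TCGA"), 4L)
  expect_error(scan_recognition_sites("ACGT", ""), "motif")
})

test_that("site density on random sequence matches the 1/256 expectation", {
  g <- random_genome(c(chr = 200000L), seed = 101)
  n <- length(scan_recognition_sites(g[[1]], "TCGA"))
  expected <- 200000 / 256
  sd3 <- 3 * sqrt(200000 * (1 / 256) * (255 / 256))
  expect_lt(abs(n - expected), sd3)
})

test_that("palindromic motif scanning is strand-symmetric", {
  for (seed in 1:5) {
    g <- random_genome(c(x = 5000L), seed = seed)
    fwd <- scan_recognition_sites(g[[1]], "TCGA")
    rev_sites <- scan_recognition_sites(revcomp(g[[1]]), "TCGA")
    # site at p on the forward strand maps to L - p - 4 on the reverse
    expect_equal(sort(5000L - rev_sites - 4L), fwd)
  }
})

test_that("tile centering arithmetic places the motif centrally", {
  g <- c(chr = paste0(strrep("A", 100), "TCGA", strrep("G", 100)))
  tiles <- design_cut_site_tiles(g, sites = list(chr = 100L))
  expect_equal(tiles$start, 77L)
  expect_equal(tiles$end, 127L)
  expect_equal(substr(tiles$sequence, 24, 27), "TCGA")
  expect_equal(tiles$sequence, substr(g[[1]], 78, 127))
})

test_that("overlapping tile pairs are both dropped and edge sites skipped", {
  g <- c(chr = random_genome(c(x = 400L), seed = 7)[[1]])
  # sites at 100 and 130: tiles [77,127) and [107,157) overlap -> both out
  tiles <- design_cut_site_tiles(g, sites = list(chr = c(100L, 130L, 300L)))
  expect_equal(tiles$site_start, 300L)
  # site at 10: insufficient left flank
  tiles2 <- design_cut_site_tiles(g, sites = list(chr = c(10L, 200L)))
  expect_equal(tiles2$site_start, 200L)
  expect_error(design_cut_site_tiles(g, sites = list(chr = 100L),
                                     tile_len = 4L), "tile_len")
})

test_that("no two designed tiles share a genome base", {
  g <- random_genome(c(a = 30000L, b = 20000L), seed = 13)
  tiles <- design_cut_site_tiles(g)
  for (rid in unique(tiles$record_id)) {
    tt <- tiles[tiles$record_id == rid, ]
    tt <- tt[order(tt$start), ]
    if (nrow(tt) > 1)
      expect_true(all(tt$start[-1] >= tt$end[-nrow(tt)]))
  }
})

test_that("genomic classification follows coding > upstream > intergenic", {
  g <- c(chr = random_genome(c(x = 20000L), seed = 3)[[1]])
  ann <- data.frame(
    record_id = "chr",
    start = c(5000L, 5100L, 12000L),
    end = c(8000L, 5400L, 14000L),
    kind = c("gene", "exon", "gene"),
    strand = c("+", "+", "-"))
  tiles <- design_cut_site_tiles(
    g, sites = list(chr = c(5200L, 4500L, 14300L, 1000L, 7000L)))
  tiles <- classify_tiles(tiles, ann)
  cls <- setNames(tiles$genomic_class, tiles$site_start)
  expect_equal(unname(cls["5200"]), "coding")      # inside exon
  expect_equal(unname(cls["4500"]), "upstream")    # 500 bp 5' of + gene
  expect_equal(unname(cls["14300"]), "upstream")   # 300 bp 5' of - gene
  expect_equal(unname(cls["1000"]), "intergenic")  # far from genes
  expect_equal(unname(cls["7000"]), "intergenic")  # intron, not exon
  # record with no annotation -> intergenic, not an error
  g2 <- c(other = g[[1]])
  t2 <- classify_tiles(design_cut_site_tiles(g2, sites = list(other = 7000L)),
                       ann)
  expect_equal(t2$genomic_class, "intergenic")
})

test_that("uniqueness filter agrees exactly with the brute-force oracle", {
  base <- random_genome(c(chr1 = 4000L, chr2 = 3000L), seed = 19)
  tiles <- design_cut_site_tiles(base)
  expect_gte(nrow(tiles), 4)
  # plant a 96%-identity copy of tile 1 (2 mismatches) and an 80% copy
  # of tile 2 (10 mismatches) inside chr2
  mutate_seq <- function(s, k, seed) {
    set.seed(seed)
    ch <- strsplit(s, "")[[1]]
    for (p in sample(length(ch), k))
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  near <- mutate_seq(tiles$sequence[1], 2L, 1)
  far <- mutate_seq(tiles$sequence[2], 10L, 2)
  chr2 <- base[["chr2"]]
  substr(chr2, 1001, 1050) <- near
  substr(chr2, 2001, 2050) <- far
  genome <- c(chr1 = base[["chr1"]], chr2 = chr2)
  res <- uniqueness_filter(tiles, genome)
  expect_true(tiles$tile_id[1] %in% res$excluded$tile_id)
  expect_true(tiles$tile_id[2] %in% res$retained$tile_id)
  oracle <- vapply(tiles$sequence, brute_genome_hits, 0L, genome = genome)
  expect_equal(unname(res$n_hits), unname(oracle))
})

test_that("control tiles meet their class definitions and are reproducible", {
  g <- random_genome(c(chr = 60000L), seed = 29)
  rdna <- random_genome(c(r = 300L), seed = 31)[[1]]
  ctrl <- generate_control_tiles(g, n_noncut = 5L, n_negative = 4L,
                                 n_positive = 3L,
                                 multicopy_sequence = rdna, seed = 11)
  nc <- ctrl[ctrl$tile_type == "noncut_control", ]
  expect_equal(nrow(nc), 5L)
  expect_true(all(substr(nc$sequence, 24, 27) == "TTGA"))
  neg <- ctrl[ctrl$tile_type == "negative_control", ]
  expect_equal(nrow(neg), 4L)
  for (s in neg$sequence)
    expect_equal(brute_genome_hits(s, g), 0L)
  pos <- ctrl[ctrl$tile_type == "positive_control", ]
  expect_equal(nrow(pos), 3L)
  expect_true(all(vapply(pos$sequence, grepl, TRUE, x = rdna,
                         fixed = TRUE)))
  # determinism
  ctrl2 <- generate_control_tiles(g, n_noncut = 5L, n_negative = 4L,
                                  n_positive = 3L,
                                  multicopy_sequence = rdna, seed = 11)
  expect_identical(ctrl, ctrl2)
  # unsatisfiable counts name the deficient class
  expect_error(generate_control_tiles(g, n_positive = 3L),
               "positive")
})

test_that("degradation series has exact size and Hamming distances", {
  g <- random_genome(c(chr = 40000L), seed = 37)
  tiles <- design_cut_site_tiles(g)
  tiles <- uniqueness_filter(tiles, g)$retained
  base <- tiles[seq_len(10), ]
  deg <- generate_degradation_series(base, max_mutations = 10L, seed = 5)
  expect_equal(nrow(deg), 10L * 11L)
  for (i in seq_len(nrow(deg))) {
    b <- base$sequence[match(sub("_deg\\d+$", "", deg$tile_id[i]),
                             base$tile_id)]
    expect_equal(brute_hamming(deg$sequence[i], b), deg$n_mutations[i])
  }
  expect_error(generate_degradation_series(base, max_mutations = 51L),
               "tile length")
})

test_that("manifest round trip is lossless and counts are consistent", {
  g <- random_genome(c(chr = 30000L), seed = 41)
  tiles <- design_cut_site_tiles(g)
  path <- withr::local_tempfile(fileext = ".tsv")
  fasta <- withr::local_tempfile(fileext = ".fa")
  write_manifest(tiles, path, fasta = fasta)
  back <- read_manifest(path)
  expect_equal(back, tiles, ignore_attr = TRUE)
  expect_equal(nrow(back), nrow(tiles))
  expect_equal(sum(table(back$genomic_class)),
               sum(back$tile_type == "cutsite"))
  fa <- read_genome_fasta(fasta)
  expect_equal(unname(fa), tiles$sequence)
  # malformed row reported with its line number
  lines <- readLines(path)
  lines[3] <- sub("^(\\S+\t\\S+\t)\\d+", "\\1oops", lines[3])
  writeLines(lines, path)
  expect_error(read_manifest(path), "line 3")
})
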