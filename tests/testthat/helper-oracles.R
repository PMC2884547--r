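# Brute-force oracles, independent of the package implementation.

# Hamming distance by character-wise comparison
brute_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# all-positions, both-strands ungapped alignment hit count
brute_genome_hits <- function(tile, genome, threshold = 0.90) {
  w <- nchar(tile)
  hits <- 0L
  for (rid in names(genome)) {
    for (s in c(genome[[rid]], rsta::revcomp(genome[[rid]]))) {
      L <- nchar(s)
      if (L < w) next
      for (p in 1:(L - w + 1)) {
        idt <- 1 - brute_hamming(substring(s, p, p + w - 1), tile) / w
        if (idt > threshold) hits <- hits + 1L
      }
    }
  }
  hits
}

# allele counting by explicit enumeration
brute_allele_freq <- function(codes) {
  codes <- codes[!is.na(codes)]
  if (!length(codes)) return(NA_real_)
  n_u <- sum(codes == "UU") * 2 + sum(codes == "CU")
  n_u / (2 * length(codes))
}

# F_ST from first principles
brute_fst <- function(p) {
  h_i <- 2 * p * (1 - p)
  h_s <- mean(h_i)
  pbar <- mean(p)
  h_t <- 2 * pbar * (1 - pbar)
  if (h_t == 0) return(NA_real_)
  (h_t - h_s) / h_t
}

# Benjamini-Hochberg step-up by hand
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# genotype matrix from a dosage matrix
dosage_to_codes <- function(dosage) {
  matrix(c("CC", "CU", "UU")[dosage + 1L], nrow = nrow(dosage),
         dimnames = dimnames(dosage))
}

sim_geno_matrix <- function(spec) {
  g <- rsta::simulate_genotypes(spec)
  list(geno = dosage_to_codes(g$dosage), truth = g)
}
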