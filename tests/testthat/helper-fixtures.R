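# Small haplotype fixtures and independent brute-force oracles used across
# the test files.

# Build a two-population HaplotypeMatrix from an alleles matrix.
toy_hm <- function(alleles, positions = NULL, n_pop_a = NULL, chrom = "chr1") {
  alleles <- as.matrix(alleles)
  H <- nrow(alleles)
  if (is.null(positions)) positions <- seq_len(ncol(alleles)) * 100L
  if (is.null(n_pop_a)) n_pop_a <- H %/% 2L
  haplotype_matrix(
    chrom, positions, alleles,
    hap_labels = paste0("h", seq_len(H), "_", rep(1:2, length.out = H)),
    pop_of_hap = c(rep("A", n_pop_a), rep("B", H - n_pop_a)))
}

random_hm <- function(n_hap, n_sites, seed) {
  set.seed(seed)
  repeat {
    a <- matrix(rbinom(n_hap * n_sites, 1L, runif(1, 0.2, 0.8)),
                nrow = n_hap)
    if (all(colSums(a) > 0L & colSums(a) < n_hap)) break
  }
  pos <- sort(sample.int(n_sites * 1000L, n_sites))
  toy_hm(a, positions = pos)
}

# Brute-force EHH: all-pairs shared-segment identity over the k flanking
# SNPs extending from the core (the core allele is shared by construction of
# a carrier set, so k = 0 gives 1), independent of the production kernel.
brute_ehh <- function(hm, core, carriers, direction, k) {
  if (k == 0L) return(1)
  sites <- if (direction == "right") (core + 1L):(core + k)
           else (core - k):(core - 1L)
  n <- length(carriers)
  identical_pairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (all(hm$alleles[carriers[i], sites] == hm$alleles[carriers[j], sites]))
        identical_pairs <- identical_pairs + 1L
    }
  }
  identical_pairs / (n * (n - 1L) / 2L)
}

# Brute-force per-site nucleotide diversity: mean pairwise difference.
brute_site_pi <- function(alleles_col) {
  n <- length(alleles_col)
  diffs <- 0L
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      diffs <- diffs + (alleles_col[i] != alleles_col[j])
  diffs / (n * (n - 1L) / 2L)
}

# A tiny simulated dataset on disk, shared by io/pipeline tests.
small_sim <- function(dir, seed = 11L, chrom_length = 1e5) {
  params <- sweep_sim_params(chrom_length = chrom_length,
                             sweep_pos = chrom_length / 2,
                             sweep_width = chrom_length / 10,
                             snp_density = 2, n_genes = 5L,
                             gene_length = 10000L, seed = seed)
  simulate_dataset(params, dir)
}
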