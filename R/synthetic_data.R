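#' Parameters for the two-population hard-sweep simulator
#'
#' Defaults emulate a small resequencing design: two populations of 4
#' diploids (8 haplotypes) each on a 2-Mb chromosome at ~1 SNP/kb, with a
#' hard sweep in population A - a single haplotype driven to frequency
#' \code{sweep_freq} over a \code{sweep_width} interval around
#' \code{sweep_pos}. Neutral variation is built by Li-Stephens-style founder
#' copying: each simulated haplotype is a mosaic of \code{n_founders} founder
#' haplotypes with a per-site switch probability, which induces the
#' linkage-disequilibrium decay that haplotype statistics require.
#'
#' @param n_hap_a,n_hap_b Haplotypes per population (default 8 = 4 diploids).
#' @param chrom_length Chromosome length in bp (default 2e6).
#' @param n_founders Founder haplotypes in the copying pool (default 10).
#' @param snp_density SNPs per kb (default 1.0).
#' @param recomb_switch_rate Per-site probability of switching founder while
#'   copying (default 0.01).
#' @param sweep_pos Focal position of the sweep (default mid-chromosome).
#' @param sweep_freq Fraction of population-A haplotypes carrying the swept
#'   haplotype (default 0.9).
#' @param sweep_width Width in bp of the interval over which carriers are
#'   identical (default 1e5).
#' @param n_genes,gene_length Gene count and length for the synthetic
#'   annotation (defaults 40 genes of 20 kb).
#' @param n_deg_true Number of sweep-overlapping genes given a true
#'   differential-expression signal (default 2).
#' @param chrom Chromosome name.
#' @param seed RNG seed; fully determines the dataset.
#' @return List of class \code{"SweepSimParams"}.
#' @export
sweep_sim_params <- function(n_hap_a = 8L, n_hap_b = 8L, chrom_length = 2e6,
                             n_founders = 10L, snp_density = 1.0,
                             recomb_switch_rate = 0.01,
                             sweep_pos = chrom_length / 2, sweep_freq = 0.9,
                             sweep_width = 1e5, n_genes = 40L,
                             gene_length = 20000L, n_deg_true = 2L,
                             chrom = "chr1", seed = 1L) {
  p <- list(n_hap_a = as.integer(n_hap_a), n_hap_b = as.integer(n_hap_b),
            chrom_length = as.numeric(chrom_length),
            n_founders = as.integer(n_founders), snp_density = snp_density,
            recomb_switch_rate = recomb_switch_rate,
            sweep_pos = as.numeric(sweep_pos), sweep_freq = sweep_freq,
            sweep_width = as.numeric(sweep_width), n_genes = as.integer(n_genes),
            gene_length = as.integer(gene_length),
            n_deg_true = as.integer(n_deg_true), chrom = chrom,
            seed = as.integer(seed))
  stopifnot(p$sweep_freq >= 0, p$sweep_freq <= 1, p$n_founders >= 2,
            p$sweep_pos - p$sweep_width / 2 >= 0,
            p$sweep_pos + p$sweep_width / 2 <= p$chrom_length,
            p$n_genes * p$gene_length <= p$chrom_length)
  structure(p, class = "SweepSimParams")
}

draw_snp_positions <- function(params) {
  n <- round(params$chrom_length / 1000 * params$snp_density)
  pos <- sort(unique(sample.int(params$chrom_length, n, replace = TRUE)))
  if (length(pos) < 2L) stop("snp_density too low: fewer than 2 SNPs drawn")
  pos
}

draw_founders <- function(params, n_sites) {
  # neutral-like frequency spectrum over founder counts: P(i) proportional 1/i
  k <- params$n_founders
  counts <- sample.int(k - 1L, n_sites, replace = TRUE,
                       prob = 1 / seq_len(k - 1L))
  f <- matrix(0L, nrow = k, ncol = n_sites)
  for (s in seq_len(n_sites)) f[sample.int(k, counts[s]), s] <- 1L
  f
}

mosaic_haplotypes <- function(founders, n_hap, switch_rate) {
  k <- nrow(founders); S <- ncol(founders)
  out <- matrix(0L, nrow = n_hap, ncol = S)
  for (h in seq_len(n_hap)) {
    cur <- sample.int(k, 1L)
    switches <- stats::runif(S) < switch_rate
    path <- integer(S)
    for (s in seq_len(S)) {
      if (switches[s]) cur <- sample.int(k, 1L)
      path[s] <- cur
    }
    out[h, ] <- founders[cbind(path, seq_len(S))]
  }
  out
}

#' Simulate one neutral population by founder copying
#'
#' Uses the current RNG state; \code{\link{simulate_dataset}} seeds it.
#'
#' @param params \code{\link{sweep_sim_params}} object.
#' @param n_hap Number of haplotypes to simulate.
#' @param positions SNP positions (shared across populations); drawn from
#'   \code{params} when NULL.
#' @param founders Founder allele matrix (shared across populations); drawn
#'   when NULL.
#' @return List: \code{alleles} (n_hap x S matrix), \code{positions},
#'   \code{founders}.
#' @export
simulate_neutral_pop <- function(params, n_hap, positions = NULL,
                                 founders = NULL) {
  if (is.null(positions)) positions <- draw_snp_positions(params)
  if (is.null(founders)) founders <- draw_founders(params, length(positions))
  list(alleles = mosaic_haplotypes(founders, n_hap, params$recomb_switch_rate),
       positions = positions, founders = founders)
}

#' Impose a hard sweep on population-A haplotypes
#'
#' Copies one randomly chosen donor haplotype's alleles over the sweep
#' interval onto \code{round(sweep_freq * n_hap)} haplotypes (the carriers,
#' including the donor); sites outside the interval are untouched. This
#' creates extended homozygosity and a within-interval diversity deficit -
#' the exact signal the haplotype and heterozygosity scans detect - with a
#' known truth interval.
#'
#' @param alleles Population-A allele matrix (haplotypes x sites).
#' @param positions 1-based SNP positions.
#' @param sweep_pos,sweep_freq,sweep_width Sweep parameters (see
#'   \code{\link{sweep_sim_params}}).
#' @return List: \code{alleles} (modified matrix) and \code{truth} with
#'   \code{sweep_start}/\code{sweep_end} (1-based inclusive bp),
#'   \code{carriers} (haplotype row indices), \code{donor}.
#' @export
impose_sweep <- function(alleles, positions, sweep_pos, sweep_freq,
                         sweep_width) {
  n <- nrow(alleles)
  lo <- sweep_pos - sweep_width / 2
  hi <- sweep_pos + sweep_width / 2
  truth <- list(sweep_start = lo, sweep_end = hi, carriers = integer(),
                donor = NA_integer_)
  n_car <- round(sweep_freq * n)
  if (n_car == 0L) return(list(alleles = alleles, truth = truth))
  if (n_car < 2L) stop("sweep carrier count < 2; raise sweep_freq or n_hap_a")
  carriers <- sample.int(n, n_car)
  donor <- carriers[1L]
  in_interval <- positions >= lo & positions <= hi
  alleles[carriers, in_interval] <-
    matrix(alleles[donor, in_interval], nrow = n_car, ncol = sum(in_interval),
           byrow = TRUE)
  truth$carriers <- sort(carriers)
  truth$donor <- donor
  list(alleles = alleles, truth = truth)
}

#' Simulate gene annotation and a DEG table with known truth
#'
#' Genes are tiled uniformly along the chromosome. \code{n_deg_true} genes
#' overlapping the sweep interval receive a true differential-expression
#' signal (|log2FC| ~ U(1.6, 3.5), random sign, padj ~ U(1e-8, 0.04)); all
#' other genes are null (log2FC ~ N(0, 0.5), padj ~ U(0.05, 1)), so true-DE
#' genes always pass and null genes always fail the default DEG filter.
#'
#' @param params \code{\link{sweep_sim_params}} object.
#' @param truth Truth list from \code{\link{impose_sweep}}.
#' @return List: \code{genes} (annotation data.frame, 0-based half-open),
#'   \code{degs} (DEG data.frame), \code{true_de} (data.frame of true-DE
#'   gene ids with drawn log2fc).
#' @export
simulate_annotation_and_degs <- function(params, truth) {
  n <- params$n_genes
  gap <- params$chrom_length / n
  start <- as.integer(floor((seq_len(n) - 1L) * gap))
  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(n)),
    chrom = params$chrom, start = start,
    end = start + params$gene_length,
    strand = rep_len(c("+", "-"), n), stringsAsFactors = FALSE)
  # overlap with the truth interval (1-based inclusive) in 0-based half-open
  over <- genes$start < truth$sweep_end & genes$end > truth$sweep_start - 1
  if (!any(over))
    stop("no gene overlaps the sweep interval; increase n_genes or gene_length")
  k <- min(params$n_deg_true, sum(over))
  cand <- which(over)
  de_idx <- sort(cand[sample.int(length(cand), k)])
  lfc <- stats::rnorm(n, 0, 0.5)
  padj <- stats::runif(n, 0.05, 1)
  lfc[de_idx] <- stats::runif(k, 1.6, 3.5) * sample(c(-1, 1), k, replace = TRUE)
  padj[de_idx] <- stats::runif(k, 1e-8, 0.04)
  degs <- data.frame(gene_id = genes$gene_id, log2fc = lfc, padj = padj,
                     stringsAsFactors = FALSE)
  list(genes = genes, degs = degs,
       true_de = data.frame(gene_id = genes$gene_id[de_idx],
                            log2fc = lfc[de_idx], stringsAsFactors = FALSE))
}

write_phased_vcf <- function(hm, path) {
  samples <- unique(sub("_[12]$", "", hm$hap_labels))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=haplosweep-simulator",
    sprintf("##contig=<ID=%s,length=%d>", hm$chrom,
            as.integer(max(hm$positions))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  S <- ncol(hm$alleles)
  gt_cols <- vapply(seq_along(samples), function(i) {
    h1 <- hm$alleles[2L * i - 1L, ]
    h2 <- hm$alleles[2L * i, ]
    paste0(h1, "|", h2)
  }, character(S))
  body <- paste(hm$chrom, hm$positions, ".", "A", "G", ".", "PASS", ".", "GT",
                apply(gt_cols, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate a complete two-population sweep dataset on disk
#'
#' Generates the phased VCF, population map, gene BED, DEG table and truth
#' JSON for one chromosome, cross-consistent and fully determined by
#' \code{params$seed} (identical bytes on rerun). Sites monomorphic across
#' the combined sample after the sweep are removed (they would not appear in
#' a VCF).
#'
#' @param params \code{\link{sweep_sim_params}} object.
#' @param out_dir Output directory (created if needed).
#' @return Invisible list of file paths: \code{vcf}, \code{popmap},
#'   \code{genes}, \code{degs}, \code{truth_json}, plus the in-memory
#'   \code{hm} (HaplotypeMatrix) and \code{truth} list.
#' @export
simulate_dataset <- function(params, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(params$seed)

  base <- simulate_neutral_pop(params, params$n_hap_a)
  popb <- simulate_neutral_pop(params, params$n_hap_b,
                               positions = base$positions,
                               founders = base$founders)
  sw <- impose_sweep(base$alleles, base$positions, params$sweep_pos,
                     params$sweep_freq, params$sweep_width)
  alleles <- rbind(sw$alleles, popb$alleles)
  poly <- colSums(alleles) > 0L & colSums(alleles) < nrow(alleles)
  alleles <- alleles[, poly, drop = FALSE]
  positions <- base$positions[poly]

  n_samp_a <- params$n_hap_a %/% 2L
  n_samp_b <- params$n_hap_b %/% 2L
  samples <- c(sprintf("A%d", seq_len(n_samp_a)), sprintf("B%d", seq_len(n_samp_b)))
  hap_labels <- as.vector(rbind(paste0(samples, "_1"), paste0(samples, "_2")))
  pop_of_hap <- rep(c(rep("A", n_samp_a), rep("B", n_samp_b)), each = 2L)
  hm <- haplotype_matrix(params$chrom, positions, alleles, hap_labels, pop_of_hap)

  ann <- simulate_annotation_and_degs(params, sw$truth)

  paths <- list(vcf = file.path(out_dir, "sim.vcf"),
                popmap = file.path(out_dir, "popmap.tsv"),
                genes = file.path(out_dir, "genes.bed"),
                degs = file.path(out_dir, "degs.tsv"),
                truth_json = file.path(out_dir, "truth.json"))
  write_phased_vcf(hm, paths$vcf)
  utils::write.table(data.frame(sample_id = samples,
                                population = c(rep("A", n_samp_a),
                                               rep("B", n_samp_b))),
                     paths$popmap, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", ann$genes$chrom, ann$genes$start,
                     ann$genes$end, ann$genes$gene_id, ann$genes$strand),
             paths$genes)
  utils::write.table(
    data.frame(gene_id = ann$degs$gene_id,
               log2FC = sprintf("%.6f", ann$degs$log2fc),
               padj = sprintf("%.8g", ann$degs$padj)),
    paths$degs, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(
    sweep_start = sw$truth$sweep_start, sweep_end = sw$truth$sweep_end,
    sweep_carriers = hap_labels[sw$truth$carriers],
    true_de_genes = ann$true_de$gene_id, true_de_log2fc = ann$true_de$log2fc,
    n_snps = length(positions), params = unclass(params))
  jsonlite::write_json(truth, paths$truth_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, list(hm = hm, truth = truth)))
}
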