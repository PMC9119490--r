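test_that("simulated phased VCF round-trips alleles, positions and labels", {
  dir <- withr::local_tempdir()
  sim <- small_sim(dir)
  hms <- read_phased_vcf(sim$vcf, sim$popmap)
  expect_length(hms, 1L)
  hm <- hms[[1L]]
  expect_identical(hm$alleles, sim$hm$alleles)
  expect_identical(hm$positions, sim$hm$positions)
  expect_identical(hm$hap_labels, sim$hm$hap_labels)
  expect_identical(hm$pop_of_hap, sim$hm$pop_of_hap)
  rep <- attr(hms, "load_report")
  expect_equal(rep$retained, ncol(hm$alleles))
  expect_equal(rep$retained + rep$dropped_multiallelic + rep$dropped_unphased +
                 rep$dropped_missing, rep$total)
})

test_that("multiallelic, unphased and missing sites are dropped and counted", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "mixed.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|0",
    "chr1\t200\t.\tA\tG,T\t.\tPASS\t.\tGT\t0|1\t1|2",
    "chr1\t300\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1|0",
    "chr1\t400\t.\tA\tG\t.\tPASS\t.\tGT\t.|1\t0|0",
    "chr1\t500\t.\tA\tG\t.\tPASS\t.\tGT\t1|1\t0|0",
    "chr1\t600\t.\tA\tG\t.\tPASS\t.\tGT\t0|0\t0|1"), vcf)
  pm <- data.frame(sample_id = c("s1", "s2"), population = c("A", "B"))
  hms <- read_phased_vcf(vcf, pm)
  hm <- hms[[1L]]
  expect_equal(dim(hm$alleles), c(4L, 3L))
  expect_equal(hm$positions, c(100L, 500L, 600L))
  # direct transcription of the GT fields at the first retained site
  expect_equal(hm$alleles[, 1L], c(0L, 1L, 1L, 0L))
  rep <- attr(hms, "load_report")
  expect_equal(rep$dropped_multiallelic, 1L)
  expect_equal(rep$dropped_unphased, 1L)
  expect_equal(rep$dropped_missing, 1L)
  expect_equal(rep$total, 6L)
})

test_that("a VCF sample missing from the popmap is an error", {
  dir <- withr::local_tempdir()
  sim <- small_sim(dir)
  pm <- read_popmap(sim$popmap)
  expect_error(read_phased_vcf(sim$vcf, pm[-1L, ]),
               "absent from popmap")
})

test_that("aa_tag polarization flips ALT-ancestral sites and flags unknowns", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "aa.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t100\t.\tA\tG\t.\tPASS\tAA=A\tGT\t0|1\t1|0",
    "chr1\t200\t.\tA\tG\t.\tPASS\tAA=G\tGT\t0|1\t1|0",
    "chr1\t300\t.\tA\tG\t.\tPASS\tAA=C\tGT\t0|1\t1|0"), vcf)
  pm <- data.frame(sample_id = c("s1", "s2"), population = c("A", "B"))
  hm <- read_phased_vcf(vcf, pm, polarization = "aa_tag")[[1L]]
  expect_equal(hm$alleles[, 1L], c(0L, 1L, 1L, 0L))   # AA=REF: unchanged
  expect_equal(hm$alleles[, 2L], c(1L, 0L, 0L, 1L))   # AA=ALT: flipped
  expect_equal(hm$polarized, c(TRUE, TRUE, FALSE))    # AA matches neither
})

test_that("BED and GFF3 annotations normalize to 0-based half-open", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "g.bed")
  writeLines(c("chr1\t100\t200\tgeneX", "chr2\t0\t50\tgeneY"), bed)
  g <- read_annotation(bed)
  expect_equal(g$gene_id, c("geneX", "geneY"))
  expect_equal(g$start[1L], 100L)
  expect_equal(g$end[1L], 200L)

  gff <- file.path(dir, "g.gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=geneX",
               "chr1\tsrc\texon\t101\t150\t.\t+\t.\tID=e1;Parent=geneX"), gff)
  gg <- read_annotation(gff)
  expect_equal(nrow(gg), 1L)            # exon features are not genes
  expect_equal(gg$start, 100L)          # 1-based inclusive -> 0-based half-open
  expect_equal(gg$end, 200L)

  dup <- file.path(dir, "dup.bed")
  writeLines(c("chr1\t100\t200\tgeneX", "chr1\t300\t400\tgeneX"), dup)
  expect_error(read_annotation(dup), "duplicate gene_id")

  bad <- file.path(dir, "bad.bed")
  writeLines(c("chr1\t100\t200\tgeneX", "chr1\t300"), bad)
  expect_error(read_annotation(bad), "line 2")
})

test_that("DEG table parsing enforces numeric columns and padj range", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "degs.tsv")
  writeLines(c("gene_id\tlog2FC\tpadj", "HBB\t-3.382391\t0.02276081"), tsv)
  d <- read_deg_table(tsv)
  expect_equal(d$gene_id, "HBB")
  expect_equal(d$log2fc, -3.382391)
  expect_equal(d$padj, 0.02276081)

  writeLines(c("gene_id\tlog2FC\tpadj", "X\t1.0\t1.2"), tsv)
  expect_error(read_deg_table(tsv), "padj outside")

  writeLines(c("gene_id\tlog2FC\tpadj", "X\tabc\t0.5"), tsv)
  expect_error(read_deg_table(tsv), "non-numeric")

  writeLines("gene_id\tlog2FC\tpadj", tsv)
  expect_equal(nrow(read_deg_table(tsv)), 0L)

  writeLines(c("gene_id\tlfc", "X\t1"), tsv)
  expect_error(read_deg_table(tsv), "missing column")
})

test_that("record writers round-trip and use 1-based inclusive report coords", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "sites.tsv")
  sites <- data.frame(chrom = "chr1", pos = (1:10) * 100L,
                      score = round(rnorm(10), 6))
  write_site_scores(sites, p)
  back <- read_site_scores(p)
  expect_equal(back$pos, sites$pos)
  expect_equal(back$score, sites$score, tolerance = 1e-9)

  expect_error(write_site_scores(sites[c(2, 1, 3:10), ], p), "sorted")

  wp <- file.path(dir, "win.tsv")
  win <- data.frame(chrom = "chr1", start = 0L, end = 10000L, n_snps = 3L,
                    hp = 0.1875)
  write_window_records(win, wp)
  raw <- read.table(wp, header = TRUE, sep = "\t")
  expect_equal(raw$start, 1L)           # report dialect is 1-based inclusive
  expect_equal(raw$end, 10000L)
  expect_equal(read_window_records(wp)$start, 0L)

  write_site_scores(sites[0, ], p)
  expect_equal(nrow(read_site_scores(p)), 0L)
})
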