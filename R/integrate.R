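#' Scan and DEG significance thresholds
#'
#' Defaults mirror a common genome-scan convention: per-test window scores of
#' magnitude at least 1.5 with normal-tail p at most 0.05 (inclusive bounds),
#' ZHp selected on the negative tail only (a heterozygosity deficit), and
#' DEGs at |log2FC| >= 1.5 with adjusted p <= 0.05.
#'
#' @param score_min_abs Minimum |window score| for iHS / XP-EHH (and |ZHp|
#'   magnitude for the ZHp tail).
#' @param p_max Maximum p-value for iHS / XP-EHH windows.
#' @param zhp_select \code{"negative"} (default): keep
#'   \code{zhp <= -score_min_abs}; \code{"two_sided"}: keep
#'   \code{|zhp| >= score_min_abs}.
#' @param deg_lfc_min_abs Minimum |fold change| for DEGs.
#' @param deg_padj_max Maximum adjusted p for DEGs.
#' @param deg_lfc_scale \code{"log2"} (default): the threshold applies to
#'   |log2FC|; \code{"linear"}: it applies to the linear fold change
#'   \code{2^|log2FC|}.
#' @return List of class \code{"ScanThresholds"}.
#' @export
scan_thresholds <- function(score_min_abs = 1.5, p_max = 0.05,
                            zhp_select = c("negative", "two_sided"),
                            deg_lfc_min_abs = 1.5, deg_padj_max = 0.05,
                            deg_lfc_scale = c("log2", "linear")) {
  stopifnot(score_min_abs > 0, p_max > 0, deg_lfc_min_abs > 0, deg_padj_max > 0)
  structure(list(score_min_abs = score_min_abs, p_max = p_max,
                 zhp_select = match.arg(zhp_select),
                 deg_lfc_min_abs = deg_lfc_min_abs,
                 deg_padj_max = deg_padj_max,
                 deg_lfc_scale = match.arg(deg_lfc_scale)),
            class = "ScanThresholds")
}

#' Select significant windows for one test
#'
#' iHS / XP-EHH windows pass when \code{|aggregate| >= score_min_abs} and
#' \code{p <= p_max} (both inclusive). ZHp windows pass on the negative tail,
#' \code{zhp <= -score_min_abs}, by default.
#'
#' @param windows Window-record data.frame from \code{\link{window_scan}}.
#' @param test One of \code{"ihs"}, \code{"xpehh"}, \code{"zhp"}.
#' @param thresholds \code{\link{scan_thresholds}} object.
#' @return The subset of window rows passing the test's filter.
#' @export
significant_windows <- function(windows, test, thresholds = scan_thresholds()) {
  if (!test %in% c("ihs", "xpehh", "zhp"))
    stop("unknown test '", test, "' (use ihs, xpehh or zhp)")
  t <- thresholds
  keep <- if (test == "zhp") {
    if (t$zhp_select == "negative")
      !is.na(windows$zhp) & windows$zhp <= -t$score_min_abs
    else
      !is.na(windows$zhp) & abs(windows$zhp) >= t$score_min_abs
  } else {
    s <- windows[[paste0("agg_", test)]]
    p <- windows[[paste0("p_", test)]]
    !is.na(s) & abs(s) >= t$score_min_abs & !is.na(p) & p <= t$p_max
  }
  windows[keep, , drop = FALSE]
}

#' Map significant windows to genes
#'
#' A gene is selected when it overlaps at least 1 bp of at least one
#' significant window (both in 0-based half-open coordinates, so a boundary
#' touch is not an overlap).
#'
#' @param sig_windows Significant-window data.frame (\code{chrom},
#'   \code{start}, \code{end}).
#' @param genes Annotation data.frame from \code{\link{read_annotation}}.
#' @return Character vector of unique gene ids, sorted.
#' @export
genes_for_windows <- function(sig_windows, genes) {
  if (!nrow(sig_windows) || !nrow(genes)) return(character())
  off <- setdiff(unique(sig_windows$chrom), unique(genes$chrom))
  if (length(off))
    stop("window chromosome(s) absent from annotation: ",
         paste(off, collapse = ", "))
  wg <- GenomicRanges::GRanges(sig_windows$chrom,
          IRanges::IRanges(sig_windows$start + 1L, sig_windows$end))
  gg <- GenomicRanges::GRanges(genes$chrom,
          IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(gg, wg, minoverlap = 1L)
  sort(unique(genes$gene_id[S4Vectors::queryHits(hits)]))
}

#' Filter a DEG table on effect size and adjusted p
#'
#' @param degs data.frame from \code{\link{read_deg_table}}.
#' @param thresholds \code{\link{scan_thresholds}} object.
#' @return Character vector of passing gene ids, sorted.
#' @export
filter_deg <- function(degs, thresholds = scan_thresholds()) {
  t <- thresholds
  lfc_ok <- if (t$deg_lfc_scale == "log2") abs(degs$log2fc) >= t$deg_lfc_min_abs
            else 2^abs(degs$log2fc) >= t$deg_lfc_min_abs
  sort(unique(degs$gene_id[lfc_ok & degs$padj <= t$deg_padj_max]))
}

#' Intersect the four sweep/expression gene sets
#'
#' @param genes_ihs,genes_xpehh,genes_zhp,genes_deg Character vectors of gene
#'   ids (empty allowed).
#' @return List of class \code{"IntegrationResult"}: the four input sets,
#'   \code{common} (the 4-way intersection) and \code{venn_counts}, a named
#'   integer vector over the 15 non-empty membership patterns (names like
#'   \code{"ihs+deg"}), summing to the size of the union.
#' @export
intersect_sets <- function(genes_ihs, genes_xpehh, genes_zhp, genes_deg) {
  sets <- list(ihs = unique(genes_ihs), xpehh = unique(genes_xpehh),
               zhp = unique(genes_zhp), deg = unique(genes_deg))
  all_genes <- sort(unique(unlist(sets, use.names = FALSE)))
  member <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1L,
                                                dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), 4L))
  names(patterns) <- names(sets)
  patterns <- patterns[rowSums(patterns) > 0L, ]
  venn <- integer(nrow(patterns))
  names(venn) <- apply(patterns, 1L, function(p)
    paste(names(sets)[as.logical(p)], collapse = "+"))
  if (length(all_genes)) {
    key <- apply(member, 1L, function(m) paste(names(sets)[m], collapse = "+"))
    tab <- table(key)
    venn[names(tab)] <- as.integer(tab)
  }
  common <- if (length(all_genes)) all_genes[rowSums(member) == 4L] else character()
  structure(list(genes_ihs = sets$ihs, genes_xpehh = sets$xpehh,
                 genes_zhp = sets$zhp, genes_deg = sets$deg,
                 common = common, venn_counts = venn),
            class = "IntegrationResult")
}

#' @export
print.IntegrationResult <- function(x, ...) {
  cat("IntegrationResult: |iHS| =", length(x$genes_ihs),
      " |XP-EHH| =", length(x$genes_xpehh),
      " |ZHp| =", length(x$genes_zhp),
      " |DEG| =", length(x$genes_deg), "\n")
  cat("  common (4-way):", length(x$common), "genes\n")
  invisible(x)
}

gene_test_score <- function(gene, genes, sig_windows, col) {
  g <- genes[genes$gene_id == gene, ]
  sw <- sig_windows[sig_windows$chrom == g$chrom &
                    sig_windows$start < g$end & sig_windows$end > g$start, ]
  s <- sw[[col]]
  s <- s[!is.na(s)]
  if (!length(s)) return(NA_real_)
  s[which.max(abs(s))]
}

#' Build the per-gene report for the common genes
#'
#' One row per common gene: chromosome, the signed max-magnitude XP-EHH and
#' iHS window aggregates and the most extreme ZHp among the gene's
#' overlapping significant windows, plus the DEG effect size and adjusted p.
#' A gene lacking a score for some test (possible when significance came from
#' a window whose other statistic is undefined) carries NA for that column.
#'
#' @param common Character vector of common gene ids.
#' @param genes Annotation data.frame.
#' @param sig List with elements \code{ihs}, \code{xpehh}, \code{zhp}: the
#'   significant-window subsets from \code{\link{significant_windows}}.
#' @param degs DEG data.frame.
#' @return data.frame sorted by gene_id: \code{gene_id}, \code{chrom},
#'   \code{xpehh}, \code{ihs}, \code{zhp}, \code{log2fc}, \code{padj}.
#' @export
build_report <- function(common, genes, sig, degs) {
  common <- sort(common)
  rows <- lapply(common, function(g) {
    ga <- genes[genes$gene_id == g, ]
    d <- degs[degs$gene_id == g, ]
    data.frame(
      gene_id = g,
      chrom = if (nrow(ga)) ga$chrom else NA_character_,
      xpehh = gene_test_score(g, genes, sig$xpehh, "agg_xpehh"),
      ihs = gene_test_score(g, genes, sig$ihs, "agg_ihs"),
      zhp = gene_test_score(g, genes, sig$zhp, "zhp"),
      log2fc = if (nrow(d)) d$log2fc[1L] else NA_real_,
      padj = if (nrow(d)) d$padj[1L] else NA_real_,
      stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(gene_id = character(), chrom = character(),
                      xpehh = numeric(), ihs = numeric(), zhp = numeric(),
                      log2fc = numeric(), padj = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Full integration step: windows + annotation + DEG table -> gene report
#'
#' Thresholds each test's windows, maps them to genes, filters the DEG
#' table, intersects the four sets and builds the per-gene report.
#'
#' @param windows Window-record data.frame from \code{\link{window_scan}}.
#' @param genes Annotation data.frame.
#' @param degs DEG data.frame.
#' @param thresholds \code{\link{scan_thresholds}} object.
#' @return \code{IntegrationResult} with extra elements \code{report}
#'   (the per-gene table) and \code{sig_windows} (per-test subsets).
#' @export
integrate_scan <- function(windows, genes, degs,
                           thresholds = scan_thresholds()) {
  sig <- list(ihs = significant_windows(windows, "ihs", thresholds),
              xpehh = significant_windows(windows, "xpehh", thresholds),
              zhp = significant_windows(windows, "zhp", thresholds))
  res <- intersect_sets(genes_for_windows(sig$ihs, genes),
                        genes_for_windows(sig$xpehh, genes),
                        genes_for_windows(sig$zhp, genes),
                        filter_deg(degs, thresholds))
  res$report <- build_report(res$common, genes, sig, degs)
  res$sig_windows <- sig
  res
}
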