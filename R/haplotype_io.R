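#' Read a sample-to-population map
#'
#' @param path TSV with header columns \code{sample_id} and \code{population}.
#' @return data.frame with columns \code{sample_id}, \code{population}.
#' @export
read_popmap <- function(path) {
  pm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "population")
  miss <- setdiff(need, names(pm))
  if (length(miss)) stop("popmap missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(pm$sample_id)) stop("duplicate sample_id in popmap")
  pm[need]
}

#' Read a phased VCF into haplotype matrices
#'
#' Loads phased, biallelic SNPs from a VCF (v4.x) and returns one
#' \code{\link{haplotype_matrix}} per chromosome. Sites that are
#' multiallelic, carry any unphased genotype ("/" separator) or any missing
#' allele are dropped and counted in the load report. Samples are assigned to
#' populations via the popmap; each diploid sample contributes two haplotype
#' rows \code{<sample>_1} and \code{<sample>_2}.
#'
#' Polarization controls the meaning of the 0/1 allele coding:
#' \describe{
#'   \item{\code{ref_ancestral}}{REF is treated as ancestral (coded 0); the
#'     default, since the study system has no stated ancestral-allele source.}
#'   \item{\code{aa_tag}}{the INFO \code{AA} tag names the ancestral allele;
#'     sites where AA equals ALT are flipped, sites where AA is absent or
#'     matches neither allele are retained but flagged unpolarized (the iHS
#'     scan skips them).}
#'   \item{\code{major_allele}}{the major allele across all retained
#'     haplotypes is coded 0 (ancestral proxy); ties keep REF coding.}
#' }
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param popmap data.frame from \code{\link{read_popmap}}, or a path to one.
#' @param polarization One of \code{"ref_ancestral"}, \code{"aa_tag"},
#'   \code{"major_allele"}.
#' @return Named list of \code{HaplotypeMatrix}, one per chromosome with at
#'   least one retained site, with attribute \code{"load_report"}: a
#'   data.frame per chromosome of \code{total}, \code{retained},
#'   \code{dropped_multiallelic}, \code{dropped_unphased},
#'   \code{dropped_missing}.
#' @export
read_phased_vcf <- function(path, popmap,
                            polarization = c("ref_ancestral", "aa_tag", "major_allele")) {
  polarization <- match.arg(polarization)
  if (is.character(popmap)) popmap <- read_popmap(popmap)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  unknown <- setdiff(samples, popmap$sample_id)
  if (length(unknown))
    stop("sample(s) in VCF absent from popmap: ", paste(unknown, collapse = ", "))
  pop_of_sample <- stats::setNames(popmap$population, popmap$sample_id)[samples]

  chrom <- v@fix[, "CHROM"]
  pos <- as.integer(v@fix[, "POS"])
  ref <- v@fix[, "REF"]
  alt <- v@fix[, "ALT"]
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(pos), dimnames = list(NULL, samples))

  multi <- is.na(alt) | grepl(",", alt, fixed = TRUE)
  unphased <- apply(gt, 1L, function(g) any(grepl("/", g, fixed = TRUE)))
  missing <- apply(gt, 1L, function(g) any(is.na(g) | grepl("\\.", g)))
  # classify each record once, in precedence order multiallelic > unphased > missing
  drop_class <- ifelse(multi, "multiallelic",
                ifelse(unphased & !multi, "unphased",
                ifelse(missing & !multi & !unphased, "missing", "retained")))

  hap_labels <- as.vector(rbind(paste0(samples, "_1"), paste0(samples, "_2")))
  pop_of_hap <- rep(pop_of_sample, each = 2L)

  out <- list()
  report <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    cls <- drop_class[idx]
    keep <- idx[cls == "retained"]
    report[[ch]] <- data.frame(
      chrom = ch, total = length(idx), retained = length(keep),
      dropped_multiallelic = sum(cls == "multiallelic"),
      dropped_unphased = sum(cls == "unphased"),
      dropped_missing = sum(cls == "missing"),
      stringsAsFactors = FALSE)
    if (!length(keep)) {
      warning("chromosome ", ch, ": zero biallelic phased sites; skipped")
      next
    }
    # haplotypes x sites: split "a|b" once per retained record
    am <- matrix(NA_integer_, nrow = 2L * length(samples), ncol = length(keep))
    for (j in seq_along(keep)) {
      parts <- strsplit(gt[keep[j], ], "|", fixed = TRUE)
      am[, j] <- as.integer(unlist(parts, use.names = FALSE))
    }
    pol <- rep(TRUE, length(keep))
    if (polarization == "aa_tag") {
      aa <- vcfR::extract.info(v, element = "AA")[keep]
      flip <- !is.na(aa) & aa == alt[keep]
      ok <- !is.na(aa) & (aa == ref[keep] | aa == alt[keep])
      am[, flip] <- 1L - am[, flip]
      pol <- ok
    } else if (polarization == "major_allele") {
      alt_count <- colSums(am)
      flip <- alt_count > nrow(am) - alt_count     # ALT is major: recode it as 0
      am[, flip] <- 1L - am[, flip]
    }
    out[[ch]] <- haplotype_matrix(ch, pos[keep], am, hap_labels, pop_of_hap,
                                  polarized = pol)
  }
  attr(out, "load_report") <- do.call(rbind, c(report, list(make.row.names = FALSE)))
  out
}

#' Read gene annotation (BED4 or GFF3)
#'
#' BED intervals are already 0-based half-open; GFF3 \code{gene} features are
#' 1-based inclusive and converted on load. All coordinates are stored
#' 0-based half-open internally.
#'
#' @param path Path to a \code{.bed} or \code{.gff}/\code{.gff3} file; the
#'   format is chosen by extension.
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{strand}.
#' @export
read_annotation <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "bed") {
    lines <- readLines(path)
    lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
    if (!length(lines)) {
      warning("annotation has no records")
      return(empty_gene_frame())
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    n <- vapply(fields, length, 0L)
    bad <- which(n < 4L)
    if (length(bad)) stop("malformed BED line ", bad[1L], ": needs >= 4 fields")
    gr <- data.frame(
      gene_id = vapply(fields, `[[`, "", 4L),
      chrom = vapply(fields, `[[`, "", 1L),
      start = as.integer(vapply(fields, `[[`, "", 2L)),
      end = as.integer(vapply(fields, `[[`, "", 3L)),
      strand = vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else "*", ""),
      stringsAsFactors = FALSE)
    if (anyNA(gr$start) || anyNA(gr$end)) {
      bad <- which(is.na(gr$start) | is.na(gr$end))
      stop("malformed BED line ", bad[1L], ": non-numeric coordinates")
    }
  } else if (ext %in% c("gff", "gff3")) {
    g <- rtracklayer::import(path, format = "gff3")
    g <- g[!is.na(g$type) & g$type == "gene"]
    if (!length(g)) {
      warning("GFF3 contains no gene features")
      return(empty_gene_frame())
    }
    ids <- if (!is.null(g$gene_id)) g$gene_id else g$ID
    if (is.null(ids) || anyNA(ids)) stop("GFF3 gene features need an ID or gene_id attribute")
    gr <- data.frame(
      gene_id = as.character(ids),
      chrom = as.character(GenomicRanges::seqnames(g)),
      start = GenomicRanges::start(g) - 1L,   # 1-based inclusive -> 0-based half-open
      end = GenomicRanges::end(g),
      strand = as.character(GenomicRanges::strand(g)),
      stringsAsFactors = FALSE)
  } else {
    stop("unsupported annotation format: .", ext, " (use BED or GFF3)")
  }
  if (any(gr$start >= gr$end)) stop("gene interval with start >= end: ",
                                    gr$gene_id[which(gr$start >= gr$end)[1L]])
  dup <- gr$gene_id[duplicated(gr$gene_id)]
  if (length(dup)) stop("duplicate gene_id in annotation: ",
                        paste(unique(dup), collapse = ", "))
  rownames(gr) <- NULL
  gr
}

empty_gene_frame <- function() {
  data.frame(gene_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), stringsAsFactors = FALSE)
}

#' Read a differential-expression table
#'
#' @param path TSV with a header.
#' @param gene_col,lfc_col,padj_col Column names holding the gene id, log2
#'   fold change and adjusted p-value.
#' @return data.frame with columns \code{gene_id}, \code{log2fc}, \code{padj}.
#' @export
read_deg_table <- function(path, gene_col = "gene_id", lfc_col = "log2FC",
                           padj_col = "padj") {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c(gene_col, lfc_col, padj_col), names(d))
  if (length(miss)) stop("DEG table missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(d))
    return(data.frame(gene_id = character(), log2fc = numeric(), padj = numeric(),
                      stringsAsFactors = FALSE))
  lfc <- suppressWarnings(as.numeric(d[[lfc_col]]))
  padj <- suppressWarnings(as.numeric(d[[padj_col]]))
  bad <- which(is.na(lfc) | is.na(padj))
  if (length(bad)) stop("non-numeric log2FC/padj at row(s): ",
                        paste(bad, collapse = ", "))
  out_of_range <- which(padj < 0 | padj > 1)
  if (length(out_of_range)) stop("padj outside [0,1] at row(s): ",
                                 paste(out_of_range, collapse = ", "))
  data.frame(gene_id = as.character(d[[gene_col]]), log2fc = lfc, padj = padj,
             stringsAsFactors = FALSE)
}

fmt_num <- function(x) {
  out <- ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "f"))
  out
}

#' Write per-site score records to TSV
#'
#' Floats are written with 6 decimals; positions are 1-based as in the VCF.
#' Input must already be sorted by (chrom, pos).
#'
#' @param scores data.frame with at least \code{chrom} and \code{pos}.
#' @param path Output path.
#' @export
write_site_scores <- function(scores, path) {
  if (nrow(scores)) {
    o <- order(scores$chrom, scores$pos)
    if (!identical(o, seq_len(nrow(scores))))
      stop("site scores must be sorted by (chrom, pos) before writing")
  }
  out <- scores
  num <- vapply(out, is.numeric, TRUE) & !(names(out) %in% c("pos"))
  out[num] <- lapply(out[num], fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-window records to TSV
#'
#' Internal window coordinates are 0-based half-open; the report dialect is
#' 1-based inclusive (\code{start+1}, \code{end}). Input must be sorted by
#' (chrom, start).
#'
#' @param windows data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open) plus statistic columns.
#' @param path Output path.
#' @export
write_window_records <- function(windows, path) {
  if (nrow(windows)) {
    o <- order(windows$chrom, windows$start)
    if (!identical(o, seq_len(nrow(windows))))
      stop("window records must be sorted by (chrom, start) before writing")
  }
  out <- windows
  out$start <- out$start + 1L          # report dialect: 1-based inclusive
  num <- vapply(out, is.numeric, TRUE) & !(names(out) %in% c("start", "end", "n_snps"))
  out[num] <- lapply(out[num], fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a TSV written by the writers
#' @param path Path to a TSV written by \code{\link{write_site_scores}}.
#' @return data.frame.
#' @export
read_site_scores <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_site_scores
#' @export
read_window_records <- function(path) {
  w <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(w)) w$start <- w$start - 1L   # back to 0-based half-open
  w
}
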