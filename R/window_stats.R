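#' Tile a chromosome into fixed-size windows
#'
#' Non-overlapping consecutive bins \code{[k*size, (k+1)*size)} in 0-based
#' half-open coordinates; a final partial bin (shorter than \code{size}) is
#' retained and flagged. A step smaller than \code{size} yields overlapping
#' (sliding) windows.
#'
#' @param chrom_length Chromosome length in bp.
#' @param size Window size in bp (default 10000, i.e. 10-kb bins).
#' @param step Distance between window starts (default \code{size}).
#' @return data.frame with \code{start}, \code{end} (0-based half-open) and
#'   \code{partial}.
#' @export
make_windows <- function(chrom_length, size = 10000L, step = size) {
  if (size <= 0 || step <= 0) stop("window size and step must be positive")
  starts <- seq.int(0L, max(0L, chrom_length - 1L), by = step)
  ends <- pmin(starts + size, chrom_length)
  data.frame(start = as.integer(starts), end = as.integer(ends),
             partial = ends - starts < size)
}

window_bounds <- function(positions, windows) {
  # positions 1-based, sorted; windows 0-based half-open: site p is in window
  # [s,e) iff s <= p-1 < e. Returns per-window index ranges (lo, hi] into the
  # site vector, valid for overlapping windows too.
  pos0 <- positions - 1L
  list(lo = findInterval(windows$start - 0.5, pos0),
       hi = findInterval(windows$end - 0.5, pos0))
}

window_sums <- function(positions, values, windows) {
  b <- window_bounds(positions, windows)
  cs <- c(0, cumsum(values))
  list(sum = cs[b$hi + 1L] - cs[b$lo + 1L], n = b$hi - b$lo)
}

#' Pooled heterozygosity (Hp) per window
#'
#' At each SNP the larger and smaller allele counts among the selected
#' haplotypes are the major (nMAJ) and minor (nMIN) counts; per window,
#' \deqn{Hp = 2 \sum nMAJ \sum nMIN / (\sum nMAJ + \sum nMIN)^2.}
#' Sites monomorphic within the selected haplotype set still contribute
#' (nMIN = 0). A tie (equal counts) contributes equally to both sums, which
#' leaves the symmetric formula unaffected. Hp is undefined (NA) for windows
#' with no SNPs.
#'
#' @param hm Haplotype matrix restricted to the haplotypes over which Hp is
#'   pooled (one population by default in the pipeline, or the pooled
#'   sample).
#' @param windows data.frame from \code{\link{make_windows}}.
#' @return data.frame: windows plus \code{n_snps}, \code{sum_maj},
#'   \code{sum_min}, \code{hp}.
#' @export
window_hp <- function(hm, windows) {
  n <- nrow(hm$alleles)
  c1 <- colSums(hm$alleles)
  c0 <- n - c1
  maj <- pmax(c0, c1)
  mnr <- pmin(c0, c1)
  smaj <- window_sums(hm$positions, maj, windows)
  smin <- window_sums(hm$positions, mnr, windows)
  out <- windows
  out$n_snps <- smaj$n
  out$sum_maj <- smaj$sum
  out$sum_min <- smin$sum
  tot <- out$sum_maj + out$sum_min
  out$hp <- ifelse(out$n_snps > 0, 2 * out$sum_maj * out$sum_min / tot^2, NA_real_)
  out
}

#' Z-transform of windowed Hp (ZHp)
#'
#' \code{zhp = (hp - mean(hp)) / sd(hp)} with genome-wide moments over all
#' windows with defined Hp (sample SD, n-1 denominator). Partial terminal
#' windows are excluded from the moment estimation by default but still
#' receive a zhp value. Strongly negative ZHp flags a heterozygosity deficit
#' consistent with a selective sweep.
#'
#' @param hp Numeric vector of per-window Hp (NA for empty windows).
#' @param partial Logical vector flagging partial windows (excluded from
#'   moments when \code{exclude_partial}).
#' @param exclude_partial Exclude partial windows from the moments (default
#'   TRUE).
#' @return List with \code{zhp} (same length as \code{hp}) and
#'   \code{summary}: \code{mu_hp}, \code{sigma_hp}, \code{n_windows_defined},
#'   \code{n_windows_empty}.
#' @export
zhp_transform <- function(hp, partial = rep(FALSE, length(hp)),
                          exclude_partial = TRUE) {
  def <- !is.na(hp)
  basis <- def & (!exclude_partial | !partial)
  if (sum(basis) < 2L) stop("need at least 2 defined Hp windows to Z-transform")
  mu <- mean(hp[basis])
  sigma <- stats::sd(hp[basis])
  if (sigma == 0) stop("zero variance in Hp across windows; ZHp undefined")
  list(zhp = (hp - mu) / sigma,
       summary = list(mu_hp = mu, sigma_hp = sigma,
                      n_windows_defined = sum(def),
                      n_windows_empty = sum(!def)))
}

#' Windowed nucleotide diversity (pi) per bp
#'
#' Per-site unbiased diversity \code{2 * c0 * c1 / (n * (n - 1))} with c0/c1
#' the allele counts among the population's n haplotypes, summed over the
#' window's SNPs and divided by the window span in bp (full window length;
#' partial terminal windows use their actual span) - the convention used by
#' vcftools --window-pi.
#'
#' @param hm Haplotype matrix restricted to one population (n >= 2).
#' @param windows data.frame from \code{\link{make_windows}}.
#' @return Numeric vector of per-window pi per bp.
#' @export
window_pi <- function(hm, windows) {
  n <- nrow(hm$alleles)
  if (n < 2L) stop("nucleotide diversity needs at least 2 haplotypes")
  c1 <- colSums(hm$alleles)
  c0 <- n - c1
  site_pi <- 2 * c0 * c1 / (n * (n - 1))
  window_sums(hm$positions, site_pi, windows)$sum / (windows$end - windows$start)
}

#' Aggregate per-site scores into windows
#'
#' @param pos 1-based site positions, sorted increasing.
#' @param score Per-site scores (NA entries ignored).
#' @param windows data.frame from \code{\link{make_windows}}.
#' @param mode \code{"max_abs"} (default): the signed score of largest
#'   magnitude in the window; \code{"mean"}: the window mean.
#' @return Numeric vector of per-window aggregates, NA where a window holds
#'   no scored site.
#' @export
aggregate_scores <- function(pos, score, windows, mode = c("max_abs", "mean")) {
  mode <- match.arg(mode)
  if (is.unsorted(pos)) stop("site scores must be sorted by position")
  keep <- !is.na(score)
  pos <- pos[keep]; score <- score[keep]
  out <- rep(NA_real_, nrow(windows))
  if (!length(pos)) return(out)
  b <- window_bounds(pos, windows)
  for (w in which(b$hi > b$lo)) {
    s <- score[(b$lo[w] + 1L):b$hi[w]]
    out[w] <- if (mode == "max_abs") s[which.max(abs(s))] else mean(s)
  }
  out
}

#' Full window scan: Hp/ZHp, per-population pi and score aggregation
#'
#' Builds the per-window record table combining pooled heterozygosity of the
#' scanned population, nucleotide diversity of both populations, and
#' window-aggregated iHS / XP-EHH site scores with aggregate p-values.
#'
#' @param hm Two-population haplotype matrix.
#' @param ihs_sites,xpehh_sites Site-score data.frames from
#'   \code{\link{ihs_scan}} / \code{\link{xpehh_scan}} (optional; their
#'   aggregate columns are NA when omitted).
#' @param size,step Window geometry (bp); default non-overlapping 10-kb bins.
#' @param chrom_length Chromosome length (default: last SNP position).
#' @param hp_pop Population whose haplotypes are pooled for Hp (default "A",
#'   the scanned population); \code{"pooled"} uses all haplotypes.
#' @param pop_a,pop_b Population labels for the pi columns.
#' @param agg_mode Aggregation mode for site scores (see
#'   \code{\link{aggregate_scores}}).
#' @param exclude_partial Exclude partial windows from ZHp moments.
#' @return data.frame of window records: \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{partial}, \code{n_snps},
#'   \code{sum_maj}, \code{sum_min}, \code{hp}, \code{zhp}, \code{pi_a},
#'   \code{pi_b}, \code{agg_ihs}, \code{p_ihs}, \code{agg_xpehh},
#'   \code{p_xpehh}; attribute \code{"summary"} holds the genome-scan
#'   moments.
#' @export
window_scan <- function(hm, ihs_sites = NULL, xpehh_sites = NULL,
                        size = 10000L, step = size, chrom_length = NULL,
                        hp_pop = "A", pop_a = "A", pop_b = "B",
                        agg_mode = "max_abs", exclude_partial = TRUE) {
  if (is.null(chrom_length)) chrom_length <- max(hm$positions)
  windows <- make_windows(chrom_length, size = size, step = step)
  hp_hm <- if (identical(hp_pop, "pooled")) hm else subset_population(hm, hp_pop)
  rec <- window_hp(hp_hm, windows)
  zt <- zhp_transform(rec$hp, rec$partial, exclude_partial = exclude_partial)
  rec$zhp <- zt$zhp
  rec$pi_a <- window_pi(subset_population(hm, pop_a), windows)
  rec$pi_b <- window_pi(subset_population(hm, pop_b), windows)
  agg <- function(sites, col) {
    if (is.null(sites)) return(list(s = rep(NA_real_, nrow(windows)),
                                    p = rep(NA_real_, nrow(windows))))
    s <- aggregate_scores(sites$pos, sites[[col]], windows, mode = agg_mode)
    list(s = s, p = ifelse(is.na(s), NA_real_, score_pvalue(s)))
  }
  ai <- agg(ihs_sites, "ihs")
  ax <- agg(xpehh_sites, "xpehh")
  rec$agg_ihs <- ai$s; rec$p_ihs <- ai$p
  rec$agg_xpehh <- ax$s; rec$p_xpehh <- ax$p
  rec <- cbind(chrom = hm$chrom, rec, stringsAsFactors = FALSE)
  attr(rec, "summary") <- zt$summary
  rec
}
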