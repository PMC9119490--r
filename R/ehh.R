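#' Extended haplotype homozygosity curve from a core site
#'
#' EHH at extension step k is the probability that two haplotypes drawn
#' without replacement from the carrier set are identical over all sites from
#' the core out to the k-th flanking SNP (inclusive):
#' \deqn{EHH_k = \sum_h \binom{n_h}{2} / \binom{n}{2}}
#' summed over the distinct extended haplotypes h among the n carriers.
#' Identity is counted over the flanking extension away from the core - the
#' core allele is shared by construction of an allele-class carrier set, and
#' population-level carrier sets (the cross-population case) inherit the same
#' convention - so the curve always starts at 1 at offset 0. It is evaluated
#' at every SNP until it falls below \code{cutoff} (that sub-cutoff point is
#' kept as the final node) or the end of the site set is reached (then
#' \code{truncated = TRUE}).
#'
#' @param hm HaplotypeMatrix or single-population subset.
#' @param core Site index (column) of the core SNP.
#' @param carriers Integer vector of haplotype row indices forming the
#'   allele class (or the whole population for cross-population scans);
#'   at least 2.
#' @param direction \code{"left"} or \code{"right"} of the core.
#' @param cutoff EHH level below which the curve stops (default 0.05).
#' @return List of class \code{"EhhCurve"}: \code{core_index},
#'   \code{direction}, \code{offsets} (bp from core, starting at 0),
#'   \code{ehh_values}, \code{carrier_count}, \code{truncated}.
#' @export
ehh_curve <- function(hm, core, carriers, direction = c("right", "left"),
                      cutoff = 0.05) {
  direction <- match.arg(direction)
  n <- length(carriers)
  if (n < 2L) stop("EHH curve undefined for fewer than 2 carrier haplotypes")
  k <- .ehh_curve_kernel(hm$alleles, hm$positions, as.integer(core),
                         as.integer(carriers), direction == "right", cutoff)
  structure(list(core_index = core, direction = direction,
                 offsets = k$offsets, ehh_values = k$ehh_values,
                 carrier_count = n, truncated = k$truncated),
            class = "EhhCurve")
}

#' Integrated haplotype homozygosity (iHH)
#'
#' Trapezoidal area under the EHH curve against physical distance, summed
#' over the left and right extensions from the core. Each side is truncated
#' at the first node where EHH drops below \code{cutoff}; that node is
#' included as the final integration point. Units are bp x EHH.
#'
#' @param curve_left,curve_right \code{EhhCurve}s for the two directions from
#'   the same core and allele class.
#' @param cutoff EHH cutoff used when the curves were built.
#' @return List with \code{ihh} (numeric) and \code{truncated} (TRUE if
#'   either side reached the end of the site set above the cutoff).
#' @export
integrate_ihh <- function(curve_left, curve_right, cutoff = 0.05) {
  area <- function(cv) {
    keep <- seq_along(cv$ehh_values)
    below <- which(cv$ehh_values < cutoff)
    if (length(below)) keep <- seq_len(below[1L])   # include the sub-cutoff node
    off <- cv$offsets[keep]; e <- cv$ehh_values[keep]
    if (length(off) < 2L) return(0)
    sum(diff(off) * (utils::head(e, -1L) + utils::tail(e, -1L)) / 2)
  }
  list(ihh = area(curve_left) + area(curve_right),
       truncated = isTRUE(curve_left$truncated) || isTRUE(curve_right$truncated))
}

ihh_at_core <- function(hm, core, carriers, cutoff) {
  if (length(carriers) < 2L) return(list(ihh = NA_real_, truncated = FALSE))
  cl <- ehh_curve(hm, core, carriers, "left", cutoff)
  cr <- ehh_curve(hm, core, carriers, "right", cutoff)
  integrate_ihh(cl, cr, cutoff)
}

#' Unstandardized iHS at one core site
#'
#' Computes the integrated haplotype homozygosity separately for the
#' ancestral-allele carriers (allele 0) and derived-allele carriers
#' (allele 1) of the scanned population and returns
#' \code{ihs_unstd = ln(iHH_ancestral / iHH_derived)}. Negative values mean
#' the derived allele sits on unusually long haplotypes, the classic
#' signature of an ongoing sweep on the derived allele.
#'
#' @param hm Single-population haplotype matrix (the scanned population).
#' @param core Core site index.
#' @param cutoff EHH cutoff (default 0.05).
#' @param maf_min Minimum derived-allele frequency distance from 0/1
#'   (default 0.05): cores outside \code{[maf_min, 1 - maf_min]} are skipped.
#' @return One-row data.frame: \code{chrom}, \code{pos}, \code{derived_freq},
#'   \code{ihh_ancestral}, \code{ihh_derived}, \code{ihs_unstd},
#'   \code{truncated}, \code{skip_reason} (NA when scored).
#' @export
site_ihs <- function(hm, core, cutoff = 0.05, maf_min = 0.05) {
  v <- site_ihs_values(hm, core, cutoff, maf_min)
  data.frame(chrom = hm$chrom, pos = hm$positions[core],
             derived_freq = v$freq, ihh_ancestral = v$ia, ihh_derived = v$id,
             ihs_unstd = v$u, truncated = v$trunc, skip_reason = v$skip,
             stringsAsFactors = FALSE)
}

site_ihs_values <- function(hm, core, cutoff, maf_min) {
  out <- list(freq = NA_real_, ia = NA_real_, id = NA_real_, u = NA_real_,
              trunc = FALSE, skip = NA_character_)
  a <- hm$alleles[, core]
  out$freq <- mean(a)
  if (!hm$polarized[core]) { out$skip <- "unpolarized"; return(out) }
  if (out$freq < maf_min || out$freq > 1 - maf_min) {
    out$skip <- "maf"; return(out)
  }
  anc <- which(a == 0L); der <- which(a == 1L)
  if (length(anc) < 2L || length(der) < 2L) { out$skip <- "carriers"; return(out) }
  ra <- ihh_at_core(hm, core, anc, cutoff)
  rd <- ihh_at_core(hm, core, der, cutoff)
  out$ia <- ra$ihh; out$id <- rd$ihh
  out$trunc <- ra$truncated || rd$truncated
  if (ra$ihh == 0 || rd$ihh == 0) { out$skip <- "zero_ihh"; return(out) }
  out$u <- log(ra$ihh / rd$ihh)
  out
}

#' Unstandardized XP-EHH at one core site
#'
#' Integrated haplotype homozygosity is computed over all haplotypes of each
#' population at the core (the established cross-population convention;
#' \code{carrier_mode = "allele_class"} instead restricts each population to
#' its derived-allele carriers). Both curves start at 1 and measure identity
#' over the extension away from the core, so the integral reflects haplotype
#' length rather than the core allele frequency. Positive
#' \code{xpehh_unstd = ln(iHH_A / iHH_B)} means longer haplotypes - a sweep -
#' in population A.
#'
#' @param hm Two-population haplotype matrix.
#' @param core Core site index.
#' @param cutoff EHH cutoff.
#' @param pop_a,pop_b Population labels for the numerator and denominator.
#' @param carrier_mode \code{"population"} (default) or \code{"allele_class"}.
#' @return One-row data.frame: \code{chrom}, \code{pos}, \code{ihh_pop_a},
#'   \code{ihh_pop_b}, \code{xpehh_unstd}, \code{truncated},
#'   \code{skip_reason}.
#' @export
site_xpehh <- function(hm, core, cutoff = 0.05, pop_a = "A", pop_b = "B",
                       carrier_mode = c("population", "allele_class")) {
  carrier_mode <- match.arg(carrier_mode)
  v <- site_xpehh_values(hm, core, cutoff, pop_a, pop_b, carrier_mode)
  data.frame(chrom = hm$chrom, pos = hm$positions[core], ihh_pop_a = v$ia,
             ihh_pop_b = v$ib, xpehh_unstd = v$u, truncated = v$trunc,
             skip_reason = v$skip, stringsAsFactors = FALSE)
}

site_xpehh_values <- function(hm, core, cutoff, pop_a, pop_b, carrier_mode) {
  out <- list(ia = NA_real_, ib = NA_real_, u = NA_real_, trunc = FALSE,
              skip = NA_character_)
  sel <- function(pop) {
    idx <- which(hm$pop_of_hap == pop)
    if (carrier_mode == "allele_class") idx <- idx[hm$alleles[idx, core] == 1L]
    idx
  }
  ca <- sel(pop_a); cb <- sel(pop_b)
  if (length(ca) < 2L || length(cb) < 2L) { out$skip <- "carriers"; return(out) }
  ra <- ihh_at_core(hm, core, ca, cutoff)
  rb <- ihh_at_core(hm, core, cb, cutoff)
  out$ia <- ra$ihh; out$ib <- rb$ihh
  out$trunc <- ra$truncated || rb$truncated
  if (ra$ihh == 0 || rb$ihh == 0) { out$skip <- "zero_ihh"; return(out) }
  out$u <- log(ra$ihh / rb$ihh)
  out
}

#' Standardize raw ln-ratio scores
#'
#' Centers and scales raw scores to z-scores,
#' \code{z = (x - E[x]) / SD[x]} with the sample SD (n-1 denominator).
#' \code{mode = "global"} uses one bin over all scores (the plain form of the
#' statistic); \code{mode = "freq_binned"} (the usual choice for iHS, whose
#' raw ln-ratio depends strongly on derived-allele frequency) estimates the
#' moments within derived-frequency bins. Bins with fewer than
#' \code{min_bin_n} scores are merged with their nearest neighbor until all
#' used bins are large enough.
#'
#' @param x Numeric vector of raw ln-ratio scores (NA allowed, passed
#'   through).
#' @param freq Derived-allele frequencies, required for
#'   \code{mode = "freq_binned"}.
#' @param mode \code{"global"} or \code{"freq_binned"}.
#' @param bin_width Width of the derived-frequency bins (default 0.02).
#' @param min_bin_n Minimum scores per bin before merging (default 20); set
#'   to 1 to disable merging.
#' @return List with \code{z} (standardized scores, same length as \code{x})
#'   and \code{model}: a \code{StandardizationModel} list holding
#'   \code{mode}, \code{bin_edges}, \code{bin_mean}, \code{bin_sd},
#'   \code{bin_n}.
#' @export
standardize_scores <- function(x, freq = NULL,
                               mode = c("global", "freq_binned"),
                               bin_width = 0.02, min_bin_n = 20L) {
  mode <- match.arg(mode)
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("need at least 2 defined scores to standardize")
  if (mode == "global") {
    edges <- c(0, 1)
    bin <- rep(1L, length(x))
  } else {
    if (is.null(freq)) stop("freq_binned standardization needs derived frequencies")
    edges <- seq(0, 1, by = bin_width)
    if (edges[length(edges)] < 1) edges <- c(edges, 1)
    # merge adjacent bins until every occupied bin holds >= min_bin_n scores
    repeat {
      bin <- findInterval(freq, edges, rightmost.closed = TRUE, all.inside = TRUE)
      counts <- tabulate(bin[ok], nbins = length(edges) - 1L)
      used <- which(counts > 0L)
      small <- used[counts[used] < min_bin_n]
      if (!length(small) || length(used) == 1L) break
      b <- small[1L]
      others <- setdiff(used, b)
      nb <- others[which.min(abs(others - b))]
      lo <- min(b, nb); hi <- max(b, nb)
      edges <- edges[-seq.int(lo + 1L, hi)]   # delete interior edges -> one bin
    }
  }
  nb <- length(edges) - 1L
  mu <- sd <- rep(NA_real_, nb)
  z <- rep(NA_real_, length(x))
  for (b in seq_len(nb)) {
    sel <- ok & bin == b
    if (!any(sel)) next
    if (sum(sel) < 2L) stop("fewer than 2 scores in frequency bin ", b)
    mu[b] <- mean(x[sel])
    sd[b] <- stats::sd(x[sel])
    if (sd[b] == 0) stop("zero variance in frequency bin ", b,
                         " [", edges[b], ",", edges[b + 1L], "]")
    z[sel] <- (x[sel] - mu[b]) / sd[b]
  }
  list(z = z,
       model = structure(list(mode = mode, bin_edges = edges, bin_mean = mu,
                              bin_sd = sd,
                              bin_n = tabulate(bin[ok], nbins = nb)),
                         class = "StandardizationModel"))
}

#' Normal-tail p-value for a standardized score
#'
#' @param z Standardized score(s).
#' @param sidedness \code{"two"} (default): \code{P(|Z| >= |z|)} under
#'   N(0,1); \code{"one"}: upper tail \code{P(Z >= z)}.
#' @return p-values in (0, 1].
#' @export
score_pvalue <- function(z, sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  if (sidedness == "two") 2 * stats::pnorm(-abs(z)) else stats::pnorm(z, lower.tail = FALSE)
}

#' Genome-wide iHS scan over one chromosome
#'
#' Runs \code{\link{site_ihs}} at every site of the scanned population,
#' standardizes the raw ln-ratios and attaches normal-tail p-values.
#'
#' @param hm Two-population haplotype matrix.
#' @param pop Population to scan: a population label, or \code{"pooled"}
#'   (default) for the combined two-population panel. With very small
#'   per-population samples (a handful of diploids) a high-frequency swept
#'   allele leaves fewer than 2 ancestral carriers within the swept
#'   population, so per-population iHS is undefined exactly where the signal
#'   is; the combined panel keeps both allele classes populated and mirrors a
#'   jointly phased two-breed SNP set.
#' @param cutoff,maf_min See \code{\link{site_ihs}}.
#' @param std_mode,bin_width,min_bin_n See \code{\link{standardize_scores}};
#'   default frequency-binned.
#' @param sidedness See \code{\link{score_pvalue}}.
#' @return data.frame of per-site records with added \code{ihs} and
#'   \code{pvalue}; attribute \code{"model"} carries the
#'   StandardizationModel.
#' @export
ihs_scan <- function(hm, pop = "pooled", cutoff = 0.05, maf_min = 0.05,
                     std_mode = "freq_binned", bin_width = 0.02,
                     min_bin_n = 20L, sidedness = "two") {
  sub <- if (identical(pop, "pooled")) hm else subset_population(hm, pop)
  S <- ncol(sub$alleles)
  vals <- lapply(seq_len(S), function(s)
    site_ihs_values(sub, s, cutoff, maf_min))
  d <- data.frame(
    chrom = rep(sub$chrom, S), pos = sub$positions,
    derived_freq = vapply(vals, `[[`, 0, "freq"),
    ihh_ancestral = vapply(vals, `[[`, 0, "ia"),
    ihh_derived = vapply(vals, `[[`, 0, "id"),
    ihs_unstd = vapply(vals, `[[`, 0, "u"),
    truncated = vapply(vals, `[[`, TRUE, "trunc"),
    skip_reason = vapply(vals, `[[`, "", "skip"),
    stringsAsFactors = FALSE)
  st <- standardize_scores(d$ihs_unstd, freq = d$derived_freq, mode = std_mode,
                           bin_width = bin_width, min_bin_n = min_bin_n)
  d$ihs <- st$z
  d$pvalue <- ifelse(is.na(d$ihs), NA_real_, score_pvalue(d$ihs, sidedness))
  attr(d, "model") <- st$model
  d
}

#' Genome-wide XP-EHH scan over one chromosome
#'
#' Runs \code{\link{site_xpehh}} at every site, standardizes globally (the
#' cross-population ln-ratio has no strong frequency dependence) and attaches
#' normal-tail p-values.
#'
#' @inheritParams site_xpehh
#' @param std_mode,bin_width,min_bin_n See \code{\link{standardize_scores}}.
#' @param sidedness See \code{\link{score_pvalue}}.
#' @return data.frame of per-site records with added \code{xpehh} and
#'   \code{pvalue}; attribute \code{"model"}.
#' @export
xpehh_scan <- function(hm, cutoff = 0.05, pop_a = "A", pop_b = "B",
                       carrier_mode = "population", std_mode = "global",
                       bin_width = 0.02, min_bin_n = 20L, sidedness = "two") {
  carrier_mode <- match.arg(carrier_mode, c("population", "allele_class"))
  S <- ncol(hm$alleles)
  vals <- lapply(seq_len(S), function(s)
    site_xpehh_values(hm, s, cutoff, pop_a, pop_b, carrier_mode))
  d <- data.frame(
    chrom = rep(hm$chrom, S), pos = hm$positions,
    ihh_pop_a = vapply(vals, `[[`, 0, "ia"),
    ihh_pop_b = vapply(vals, `[[`, 0, "ib"),
    xpehh_unstd = vapply(vals, `[[`, 0, "u"),
    truncated = vapply(vals, `[[`, TRUE, "trunc"),
    skip_reason = vapply(vals, `[[`, "", "skip"),
    stringsAsFactors = FALSE)
  freq <- colMeans(hm$alleles)
  st <- standardize_scores(d$xpehh_unstd, freq = freq, mode = std_mode,
                           bin_width = bin_width, min_bin_n = min_bin_n)
  d$xpehh <- st$z
  d$pvalue <- ifelse(is.na(d$xpehh), NA_real_, score_pvalue(d$xpehh, sidedness))
  attr(d, "model") <- st$model
  d
}
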