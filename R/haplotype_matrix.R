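#' Construct a phased haplotype matrix
#'
#' The central container for haplotype statistics: a binary alleles matrix of
#' H haplotypes (rows) by S sites (columns) on one chromosome, with 1-based
#' physical positions and a two-population label per haplotype. Allele 0 is
#' the reference/ancestral-coded state, allele 1 the alternate/derived-coded
#' state (the coding depends on the polarization mode used at load time).
#'
#' @param chrom Chromosome name (length-1 character).
#' @param positions Integer vector of 1-based physical positions in bp,
#'   strictly increasing, one per site.
#' @param alleles Integer/numeric matrix of 0/1 values, haplotypes x sites.
#'   No missing values are allowed; sites with missing data must be dropped
#'   before construction.
#' @param hap_labels Character vector of haplotype identifiers, typically
#'   \code{"<sample>_1"} / \code{"<sample>_2"} for a diploid sample.
#' @param pop_of_hap Character vector of population labels, one per
#'   haplotype. Exactly two distinct populations must be present, both
#'   non-empty; by convention population \code{"A"} is the population
#'   scanned for sweeps and \code{"B"} the contrast population.
#' @param polarized Optional logical vector, one per site, marking sites
#'   whose ancestral/derived orientation is known. Defaults to all
#'   \code{TRUE}; under AA-tag polarization sites without a usable ancestral
#'   call are retained but flagged \code{FALSE} and skipped by the iHS scan.
#'
#' @return An object of class \code{"HaplotypeMatrix"}: a list with elements
#'   \code{chrom}, \code{positions}, \code{alleles}, \code{hap_labels},
#'   \code{pop_of_hap}, \code{polarized}.
#' @export
haplotype_matrix <- function(chrom, positions, alleles, hap_labels, pop_of_hap,
                             polarized = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  positions <- as.integer(positions)
  if (length(chrom) != 1L || is.na(chrom)) stop("chrom must be a single name")
  if (ncol(alleles) != length(positions))
    stop("alleles has ", ncol(alleles), " sites but positions has ", length(positions))
  if (nrow(alleles) != length(hap_labels) || nrow(alleles) != length(pop_of_hap))
    stop("hap_labels/pop_of_hap length must equal the number of haplotype rows")
  if (anyNA(alleles)) stop("alleles contains missing values; drop incomplete sites at load")
  if (!all(alleles %in% c(0L, 1L))) stop("alleles must be binary 0/1 (biallelic sites only)")
  if (length(positions) > 1L && any(diff(positions) <= 0L))
    stop("positions must be strictly increasing")
  pops <- unique(pop_of_hap)
  if (length(pops) != 2L)
    stop("exactly two populations required, got: ", paste(pops, collapse = ", "))
  if (is.null(polarized)) polarized <- rep(TRUE, length(positions))
  if (length(polarized) != length(positions))
    stop("polarized must have one flag per site")
  structure(
    list(chrom = as.character(chrom), positions = positions, alleles = alleles,
         hap_labels = as.character(hap_labels), pop_of_hap = as.character(pop_of_hap),
         polarized = as.logical(polarized)),
    class = "HaplotypeMatrix")
}

#' @export
print.HaplotypeMatrix <- function(x, ...) {
  tab <- table(x$pop_of_hap)
  cat("HaplotypeMatrix:", x$chrom, "-", nrow(x$alleles), "haplotypes x",
      ncol(x$alleles), "sites\n")
  cat("  positions:", min(x$positions), "-", max(x$positions), "bp\n")
  cat("  populations:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a haplotype matrix to one population
#'
#' Keeps the full site set (including sites monomorphic within the selected
#' population); only haplotype rows are subset. Window-level pooled
#' heterozygosity and nucleotide diversity rely on monomorphic sites staying
#' in place.
#'
#' @param hm A \code{HaplotypeMatrix}.
#' @param pop Population label to keep.
#' @return A list with the same fields as a \code{HaplotypeMatrix} but a
#'   single population; class \code{"HaplotypeSubset"} (one population only,
#'   so the two-population invariant is deliberately not enforced).
#' @export
subset_population <- function(hm, pop) {
  keep <- hm$pop_of_hap == pop
  if (!any(keep)) stop("no haplotypes in population '", pop, "'")
  structure(
    list(chrom = hm$chrom, positions = hm$positions,
         alleles = hm$alleles[keep, , drop = FALSE],
         hap_labels = hm$hap_labels[keep], pop_of_hap = hm$pop_of_hap[keep],
         polarized = hm$polarized),
    class = "HaplotypeSubset")
}

n_haplotypes <- function(hm) nrow(hm$alleles)
n_sites <- function(hm) ncol(hm$alleles)
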