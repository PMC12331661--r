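#' Haldane map function
#'
#' Recombination fraction for a genetic distance under the no-interference
#' (Poisson crossover) model: `r = (1 - exp(-2 d)) / 2` with `d` in Morgans.
#'
#' @param d_cM Genetic distance in centiMorgans (>= 0).
#' @return Recombination fraction in `[0, 0.5)`.
#' @examples
#' haldane(10)  # ~0.0906
#' @export
haldane <- function(d_cM) {
  if (any(d_cM < 0)) stop("distances must be non-negative")
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' Build a genetic map over the QTN loci
#'
#' Converts physical positions to map positions with a constant
#' physical-to-genetic rate, then precomputes the inter-locus recombination
#' fractions used by the gamete simulator: Haldane r between adjacent loci on
#' a chromosome, and 0.5 at every chromosome start (independent assortment,
#' including a random choice of starting haplotype).
#'
#' @param qtn_map A `qtn_map` (positions sorted within chromosome).
#' @param cM_per_Mb Genetic map expansion, centiMorgans per megabase (> 0).
#' @return List of class `genetic_map`: `loci` (data.frame `marker_id`,
#'   `chrom`, `pos_cM`), `r` (length-L recombination vector), `cM_per_Mb`.
#' @export
build_genetic_map <- function(qtn_map, cM_per_Mb = 1.0) {
  if (cM_per_Mb <= 0) stop("cM_per_Mb must be positive")
  validate_qtn_map(qtn_map)
  pos_cM <- qtn_map$pos_bp / 1e6 * cM_per_Mb
  L <- nrow(qtn_map)
  r <- numeric(L)
  r[1] <- 0.5
  if (L > 1) {
    same_chrom <- qtn_map$chrom[-1] == qtn_map$chrom[-L]
    d <- pos_cM[-1] - pos_cM[-L]
    # d < 0 only across chromosome boundaries, where r is 0.5 anyway
    r[-1] <- ifelse(same_chrom, haldane(pmax(d, 0)), 0.5)
  }
  structure(list(loci = data.frame(marker_id = qtn_map$marker_id,
                                   chrom = qtn_map$chrom,
                                   pos_cM = pos_cM,
                                   stringsAsFactors = FALSE),
                 r = r, cM_per_Mb = cM_per_Mb),
            class = "genetic_map")
}

#' Recombination fraction between two mapped loci
#'
#' Haldane r for the map distance between two loci of a genetic map; 0.5 if
#' they sit on different chromosomes.
#'
#' @param gmap A `genetic_map`.
#' @param marker1,marker2 Marker ids.
#' @return Recombination fraction.
#' @export
recomb_fraction <- function(gmap, marker1, marker2) {
  i <- match(marker1, gmap$loci$marker_id)
  j <- match(marker2, gmap$loci$marker_id)
  if (anyNA(c(i, j))) stop("unknown marker id")
  if (gmap$loci$chrom[i] != gmap$loci$chrom[j]) return(0.5)
  haldane(abs(gmap$loci$pos_cM[i] - gmap$loci$pos_cM[j]))
}
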