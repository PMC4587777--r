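#' Genetic maps
#'
#' A `genetic_map` gives, per chromosome, the physical length in bp, the
#' genetic length in cM and a strictly increasing linear bp-cM mapping
#' with cM(0) = 0 and cM(length_bp) = length_cM. The default is a uniform
#' 1 cM/Mb map over 22 autosomes of 50 Mb each — a desk-scale stand-in for
#' the human autosomes that keeps expectations (e.g. the inbreeding
#' coefficient as autozygous genome fraction) analytic.
#'
#' @param chrom chromosome labels.
#' @param length_bp,length_cm physical and genetic lengths per chromosome.
#' @return a data frame of class `genetic_map`.
#' @export
genetic_map <- function(chrom, length_bp, length_cm) {
  if (any(length_bp <= 0) || any(length_cm < 0))
    stop("chromosome lengths must be positive (genetic length may be 0)")
  df <- data.frame(chrom = as.character(chrom), length_bp = as.numeric(length_bp),
                   length_cm = as.numeric(length_cm), stringsAsFactors = FALSE)
  if (anyDuplicated(df$chrom)) stop("duplicated chromosome label")
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' @param n_chrom number of autosomes.
#' @param chrom_length_bp physical length of each autosome in bp.
#' @param cm_per_mb recombination rate in cM per Mb.
#' @rdname genetic_map
#' @export
uniform_genetic_map <- function(n_chrom = 22, chrom_length_bp = 5e7, cm_per_mb = 1) {
  genetic_map(paste0("chr", seq_len(n_chrom)),
              rep(chrom_length_bp, n_chrom),
              rep(chrom_length_bp / 1e6 * cm_per_mb, n_chrom))
}

map_chrom <- function(map, chrom) {
  i <- match(chrom, map$chrom)
  if (is.na(i)) stop("chromosome ", chrom, " not in genetic map")
  list(chrom = chrom, length_bp = map$length_bp[i], length_cm = map$length_cm[i])
}

#' Convert between physical and genetic coordinates
#'
#' Linear within each chromosome; both directions are exact inverses.
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome label (scalar).
#' @param bp,cm positions to convert.
#' @export
bp_to_cm <- function(map, chrom, bp) {
  mc <- map_chrom(map, chrom)
  bp / mc$length_bp * mc$length_cm
}

#' @rdname bp_to_cm
#' @export
cm_to_bp <- function(map, chrom, cm) {
  mc <- map_chrom(map, chrom)
  if (mc$length_cm == 0) stop("chromosome ", chrom, " has zero genetic length")
  cm / mc$length_cm * mc$length_bp
}

#' @export
genome_length <- function(map) sum(map$length_bp)
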