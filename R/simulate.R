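#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator with validated
#' defaults. Defaults emulate a desk-scale genome-wide SNP-array study of
#' two consanguineous families: 22 autosomes of 50 Mb at 1 cM/Mb, one
#' marker per 10 kb, common array variants (minor allele frequency uniform
#' on 0.05-0.5), a 0.002 per-call genotyping error rate and 0.002
#' missingness.
#'
#' @param seed integer seed; recorded in every output header.
#' @param template pedigree template for [build_pedigree()].
#' @param n_chrom,chrom_length_bp,cm_per_mb genome model (see
#'   [uniform_genetic_map()]).
#' @param marker_density markers per bp (default 1e-4 = 1 per 10 kb).
#' @param maf_range range of the uniform minor-allele-frequency sampler.
#' @param error_rate probability a call is flipped to a random wrong call.
#' @param missing_rate probability a call is set missing.
#' @param causal_chrom,causal_pos causal-locus placement (defaults: see
#'   [carrier_condition()]).
#' @param decoys named integer vector of decoy-variant counts per failure
#'   class; see [emit_exome_variants()].
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       template = "two_family_founder",
                       n_chrom = 22, chrom_length_bp = 5e7, cm_per_mb = 1,
                       marker_density = 1e-4,
                       maf_range = c(0.05, 0.5),
                       error_rate = 0.002,
                       missing_rate = 0.002,
                       causal_chrom = NULL, causal_pos = NULL,
                       decoys = NULL) {
  rates <- c(marker_density = marker_density, error_rate = error_rate,
             missing_rate = missing_rate)
  if (any(rates < 0) || any(c(error_rate, missing_rate) > 1))
    stop("rates must lie in [0, 1]")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an increasing pair within (0, 0.5]")
  default_decoys <- c(common = 20L, het = 10L, outside_autozygome = 10L,
                      synonymous = 5L, noncoding = 3L, benign = 6L,
                      non_segregating = 2L, family_private = 3L)
  if (!is.null(decoys)) {
    bad <- setdiff(names(decoys), names(default_decoys))
    if (length(bad)) stop("unknown decoy class: ", bad[1])
    default_decoys[names(decoys)] <- as.integer(decoys)
  }
  structure(list(seed = as.integer(seed), template = template,
                 n_chrom = n_chrom, chrom_length_bp = chrom_length_bp,
                 cm_per_mb = cm_per_mb, marker_density = marker_density,
                 maf_range = maf_range, error_rate = error_rate,
                 missing_rate = missing_rate, causal_chrom = causal_chrom,
                 causal_pos = causal_pos, decoys = default_decoys),
            class = "sim_config")
}

#' Emit SNP-array genotypes from a genome realization
#'
#' Emulates a genome-wide SNP-array experiment: marker positions are drawn
#' per chromosome at the configured density, every founder haplotype
#' receives an allele per marker from the minor-allele-frequency sampler,
#' each individual's call is the allele pair implied by its founder labels,
#' and calls are then independently flipped to a random wrong call with
#' probability `error_rate` and set missing with probability
#' `missing_rate`. Within true autozygous segments, error-free calls are
#' therefore homozygous by construction.
#'
#' @param realization a [drop_genes()] result.
#' @param config a [sim_config()]; density/MAF/error fields are used.
#' @param seed optional seed (otherwise the current RNG state is used).
#' @return a `genotype_matrix`: list with `calls` (individuals x markers
#'   integer matrix; 0 = hom-ref, 1 = het, 2 = hom-alt, `NA` = missing)
#'   and `markers` (data frame: `chrom`, `pos` 1-based, `id`, `ref`,
#'   `alt`).
#' @export
emit_snp_genotypes <- function(realization, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- realization$map
  ids <- names(realization$haplotypes)
  fnd <- founders(realization$pedigree)
  flabs <- as.vector(t(outer(fnd, c(".1", ".2"), paste0)))
  bases <- c("A", "C", "G", "T")

  marker_parts <- list(); call_parts <- list()
  for (j in seq_len(nrow(map))) {
    L <- map$length_bp[j]
    n <- round(L * config$marker_density)
    if (n < 1) {
      warning("marker density yields no markers on ", map$chrom[j],
              "; chromosome skipped")
      next
    }
    pos <- sort(sample.int(L, n))
    maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
    ref <- sample(bases, n, replace = TRUE)
    alt <- bases[(match(ref, bases) - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L]
    # founder-haplotype allele matrix: 1 = alt with probability maf
    A <- matrix(stats::rbinom(length(flabs) * n, 1, rep(maf, each = length(flabs))),
                nrow = length(flabs), dimnames = list(flabs, NULL))
    x <- pos - 0.5  # marker midpoints in 0-based continuous coordinates
    g <- matrix(NA_integer_, nrow = length(ids), ncol = n, dimnames = list(ids, NULL))
    for (id in ids) {
      hp <- realization$haplotypes[[id]][[j]]
      l1 <- match(hp$pat$lab[findInterval(x, hp$pat$bk)], flabs)
      l2 <- match(hp$mat$lab[findInterval(x, hp$mat$bk)], flabs)
      g[id, ] <- A[cbind(l1, seq_len(n))] + A[cbind(l2, seq_len(n))]
    }
    marker_parts[[j]] <- data.frame(
      chrom = map$chrom[j], pos = pos,
      id = sprintf("%s_%d_%s_%s", map$chrom[j], pos, ref, alt),
      ref = ref, alt = alt, stringsAsFactors = FALSE)
    call_parts[[j]] <- g
  }
  markers <- do.call(rbind, marker_parts)
  calls <- do.call(cbind, call_parts)
  if (is.null(markers)) stop("no markers emitted on any chromosome")
  # genotyping error: replace with one of the two wrong states, uniformly
  nc <- length(calls)
  err <- stats::runif(nc) < config$error_rate
  if (any(err))
    calls[err] <- (calls[err] + sample.int(2L, sum(err), replace = TRUE)) %% 3L
  miss <- stats::runif(nc) < config$missing_rate
  calls[miss] <- NA_integer_
  colnames(calls) <- markers$id
  structure(list(calls = calls, markers = markers, seed = config$seed),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d markers (%d chromosome(s))\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$markers$chrom))))
  invisible(x)
}

#' @export
individuals <- function(gm) rownames(gm$calls)

# GT codes used across the VCF/PED writers
GT_STATES <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
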