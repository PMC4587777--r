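#' Gene dropping through a pedigree
#'
#' Assigns each founder two uniquely labelled haplotypes per chromosome and
#' transmits them down the pedigree with recombination. Each transmitted
#' haplotype is a recombinant of the parent's two haplotypes: the crossover
#' count is Poisson with mean `length_cm / 100` and crossover positions are
#' uniform in genetic distance (Haldane model, no interference); the
#' starting haplotype is chosen at random. The result records, for every
#' individual and chromosome, the two haplotypes as founder-labelled
#' segment lists — the ground truth for identity by descent.
#'
#' Haplotypes are stored as a list with components `bk` (segment start
#' positions in bp, first element 0) and `lab` (founder-haplotype labels,
#' `"<founder>.1"` / `"<founder>.2"`); segment i spans `[bk[i], bk[i+1])`,
#' with the chromosome length as final bound, so segments tile each
#' chromosome exactly.
#'
#' @section Ascertainment conditioning:
#' When `condition` is supplied (a list with elements `chrom`, `pos`
#' (1-based bp), `hap` (founder haplotype label), `chain` (data frame of
#' parent/child transmissions) and optionally `avoid_hom` (ids that must
#' not be homozygous for `hap` at the locus)), the meioses named in
#' `chain` are forced to transmit `hap` at the locus: crossovers are
#' simulated as usual and only the starting-haplotype choice is fixed to
#' the one that carries the allele. Individuals in `avoid_hom` are
#' resampled until not homozygous for `hap` at the locus. This reproduces
#' the sampling distribution of families ascertained through an affected
#' (homozygous) child, which is how founder-mutation families come to
#' attention, while leaving recombination unconditioned. Templates built
#' by [build_pedigree()] supply a matching carrier chain; see
#' [carrier_condition()].
#'
#' @param pedigree a [pedigree].
#' @param map a [genetic_map()].
#' @param seed integer seed; if `NULL`, the current RNG state is used.
#' @param condition optional ascertainment condition (see Details).
#' @return an object of class `genome_realization`: list with `haplotypes`
#'   (`[[id]][[chrom]]$pat` / `$mat`), `map`, `pedigree`, `condition`.
#' @export
drop_genes <- function(pedigree, map = uniform_genetic_map(), seed = NULL,
                       condition = NULL) {
  if (!inherits(pedigree, "pedigree")) pedigree <- validate_pedigree(pedigree)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(condition)) {
    need <- c("chrom", "pos", "hap", "chain")
    if (!all(need %in% names(condition)))
      stop("condition must have elements: ", paste(need, collapse = ", "))
    if (!condition$chrom %in% map$chrom)
      stop("condition chromosome ", condition$chrom, " not in genetic map")
  }
  ord <- attr(pedigree, "topo") %||% topo_order(pedigree)
  haps <- vector("list", nrow(pedigree))
  names(haps) <- pedigree$id
  forced <- function(parent, child) {
    !is.null(condition) &&
      any(condition$chain$parent == parent & condition$chain$child == child)
  }
  cond_x0 <- if (is.null(condition)) NULL else condition$pos - 0.5  # locus midpoint, 0-based
  for (id in ord) {
    i <- match(id, pedigree$id)
    fa <- pedigree$father[i]; mo <- pedigree$mother[i]
    repeat {
      if (is.na(fa)) {
        hp <- lapply(seq_len(nrow(map)), function(j) {
          list(pat = list(bk = 0, lab = paste0(id, ".1")),
               mat = list(bk = 0, lab = paste0(id, ".2")))
        })
      } else {
        hp <- lapply(seq_len(nrow(map)), function(j) {
          ch <- map$chrom[j]
          on_cond <- !is.null(condition) && ch == condition$chrom
          list(pat = meiose(haps[[fa]][[j]], map$length_bp[j], map$length_cm[j],
                            force_lab = if (on_cond && forced(fa, id)) condition$hap,
                            force_pos = cond_x0),
               mat = meiose(haps[[mo]][[j]], map$length_bp[j], map$length_cm[j],
                            force_lab = if (on_cond && forced(mo, id)) condition$hap,
                            force_pos = cond_x0))
        })
      }
      names(hp) <- map$chrom
      if (is.null(condition) || !id %in% (condition$avoid_hom %||% character(0)))
        break
      hc <- hp[[condition$chrom]]
      if (!(hap_label_at(hc$pat, cond_x0) == condition$hap &&
            hap_label_at(hc$mat, cond_x0) == condition$hap))
        break
    }
    haps[[id]] <- hp
  }
  structure(list(haplotypes = haps, map = map, pedigree = pedigree,
                 condition = condition),
            class = "genome_realization")
}

hap_label_at <- function(hap, x) hap$lab[findInterval(x, hap$bk)]

# slice [from, to) out of a haplotype's segment list
hap_slice <- function(hap, from, to) {
  i1 <- findInterval(from, hap$bk)
  i2 <- findInterval(to, hap$bk)
  if (i2 > 1 && hap$bk[i2] >= to) i2 <- i2 - 1
  list(bk = c(from, hap$bk[seq_len(i2 - i1) + i1]), lab = hap$lab[i1:i2])
}

# one meiosis: recombine the parent's two haplotypes (Haldane model)
meiose <- function(parent, length_bp, length_cm, force_lab = NULL, force_pos = NULL) {
  nx <- stats::rpois(1, length_cm / 100)
  xo <- if (nx > 0) sort(stats::runif(nx, 0, length_cm)) / length_cm * length_bp
        else numeric(0)
  xo <- xo[xo > 0 & xo < length_bp]
  if (is.null(force_lab)) {
    start <- sample.int(2L, 1L)
  } else {
    h <- if (hap_label_at(parent$pat, force_pos) == force_lab) 1L
         else if (hap_label_at(parent$mat, force_pos) == force_lab) 2L
         else stop("conditioned parent does not carry founder haplotype ",
                   force_lab, " at the causal locus")
    # start-haplotype choice that transmits haplotype h across the crossovers
    # preceding the locus
    start <- ((h - 1L + sum(xo <= force_pos)) %% 2L) + 1L
  }
  src <- list(parent$pat, parent$mat)
  bounds <- c(0, xo, length_bp)
  bk <- numeric(0); lab <- character(0)
  which_h <- start
  for (k in seq_len(length(bounds) - 1)) {
    piece <- hap_slice(src[[which_h]], bounds[k], bounds[k + 1])
    bk <- c(bk, piece$bk); lab <- c(lab, piece$lab)
    which_h <- 3L - which_h
  }
  # compress runs of identical labels
  keep <- c(TRUE, lab[-1] != lab[-length(lab)])
  list(bk = bk[keep], lab = lab[keep])
}

#' Ascertainment condition for a template pedigree
#'
#' Combines the carrier chain attached by [build_pedigree()] with a causal
#' locus to form the `condition` argument of [drop_genes()]. The default
#' locus sits at the midpoint of the penultimate chromosome of the map.
#'
#' @param pedigree a template-built [pedigree].
#' @param map a [genetic_map()].
#' @param chrom,pos causal locus (1-based bp); defaults as described.
#' @export
carrier_condition <- function(pedigree, map = uniform_genetic_map(),
                              chrom = NULL, pos = NULL) {
  carrier <- attr(pedigree, "carrier")
  if (is.null(carrier))
    stop("pedigree has no carrier chain (custom pedigrees are not templated)")
  if (is.null(chrom)) chrom <- map$chrom[max(1L, nrow(map) - 1L)]
  if (is.null(pos)) pos <- floor(map$length_bp[match(chrom, map$chrom)] / 2)
  list(chrom = chrom, pos = pos, hap = carrier$hap, chain = carrier$chain,
       avoid_hom = carrier$avoid_hom)
}

#' True autozygome of a simulated individual
#'
#' Returns the maximal intervals on which the individual's two haplotypes
#' carry the same founder-haplotype label, i.e. the exact identity-by-
#' descent ground truth that ROH calling estimates. Intervals are sorted,
#' non-overlapping, 0-based half-open.
#'
#' @param realization a [drop_genes()] result.
#' @param individual individual id.
#' @return an [interval_set()].
#' @export
true_autozygome <- function(realization, individual) {
  hp <- realization$haplotypes[[individual]]
  if (is.null(hp)) stop("unknown individual id: ", individual)
  map <- realization$map
  out <- lapply(seq_len(nrow(map)), function(j) {
    a <- hp[[j]]$pat; b <- hp[[j]]$mat
    L <- map$length_bp[j]
    bk <- sort(unique(c(a$bk, b$bk)))
    la <- a$lab[findInterval(bk, a$bk)]
    lb <- b$lab[findInterval(bk, b$bk)]
    eq <- la == lb
    if (!any(eq)) return(NULL)
    ends <- c(bk[-1], L)
    data.frame(chrom = map$chrom[j], start = bk[eq], end = ends[eq],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(interval_set())
  interval_set(res$chrom, res$start, res$end)  # merges adjacent runs
}

#' @export
autozygous_fraction <- function(realization, individual) {
  iv_total_length(true_autozygome(realization, individual)) /
    genome_length(realization$map)
}

# intervals where both haplotypes carry exactly the founder label `hap`
autozygome_for_label <- function(realization, individual, hap) {
  full <- true_autozygome(realization, individual)
  hp <- realization$haplotypes[[individual]]
  map <- realization$map
  out <- lapply(seq_len(nrow(map)), function(j) {
    a <- hp[[j]]$pat
    L <- map$length_bp[j]
    keep <- a$lab == hap
    if (!any(keep)) return(NULL)
    ends <- c(a$bk[-1], L)
    data.frame(chrom = map$chrom[j], start = a$bk[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(interval_set())
  iv_intersect(full, interval_set(res$chrom, res$start, res$end))
}

#' @export
print.genome_realization <- function(x, ...) {
  cat(sprintf("genome_realization: %d individuals x %d chromosomes (%s bp genome)\n",
              length(x$haplotypes), nrow(x$map),
              formatC(genome_length(x$map), format = "d", big.mark = ",")))
  invisible(x)
}
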