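#' Call runs of homozygosity for one individual
#'
#' Scans each chromosome of a biallelic genotype matrix for maximal marker
#' runs containing at most `max_het` heterozygous and `max_missing`
#' missing calls, trimmed so that both endpoint markers are homozygous
#' calls. A run is *maximal* when it cannot be extended in either
#' direction (to another homozygous endpoint) without exceeding a
#' tolerance; with a nonzero het tolerance two maximal runs may overlap —
#' both are returned, and [assemble_autozygome()] merges them. Runs are
#' then filtered by spanned length (last minus first marker position,
#' `>= min_length_bp`, or strictly `>` with `strict_length = TRUE`) and
#' marker count. Runs of homozygosity above the conventional 2 Mb length
#' threshold serve as surrogates of autozygosity on SNP-array data.
#'
#' The scanner is deterministic and is tested against an exhaustive
#' sub-interval enumeration oracle.
#'
#' @param matrix a `genotype_matrix` (see [emit_snp_genotypes()] /
#'   [read_genotypes()]).
#' @param individual individual id (a row of the matrix).
#' @param min_length_bp minimum spanned length in bp (default 2,000,000).
#' @param min_markers minimum number of markers in a run (default 50).
#' @param max_het maximum heterozygous calls tolerated per run (default 1,
#'   absorbing array genotyping error).
#' @param max_missing maximum missing calls per run (default 5).
#' @param strict_length if `TRUE`, require spanned length strictly greater
#'   than `min_length_bp`.
#' @return data frame of class `roh_segments`: `individual`, `chrom`,
#'   `start`/`end` (0-based half-open, spanning first to last marker),
#'   `n_markers`, `n_het`, `n_missing`.
#' @export
call_roh <- function(matrix, individual, min_length_bp = 2e6, min_markers = 50,
                     max_het = 1, max_missing = 5, strict_length = FALSE) {
  if (!individual %in% rownames(matrix$calls))
    stop("unknown individual id: ", individual)
  if (min_length_bp < 0 || min_markers < 0 || max_het < 0 || max_missing < 0)
    stop("thresholds must be non-negative")
  mk <- matrix$markers
  out <- lapply(unique(mk$chrom), function(ch) {
    sel <- which(mk$chrom == ch)
    pos <- mk$pos[sel]
    if (is.unsorted(pos, strictly = TRUE))
      stop("marker positions not strictly increasing on ", ch)
    runs <- scan_runs(matrix$calls[individual, sel], max_het, max_missing)
    if (!nrow(runs)) return(NULL)
    span <- pos[runs$j] - pos[runs$i]
    keep <- (if (strict_length) span > min_length_bp else span >= min_length_bp) &
      (runs$j - runs$i + 1) >= min_markers
    runs <- runs[keep, , drop = FALSE]
    if (!nrow(runs)) return(NULL)
    data.frame(individual = individual, chrom = ch,
               start = as.numeric(pos[runs$i]) - 1, end = as.numeric(pos[runs$j]),
               n_markers = runs$j - runs$i + 1L,
               n_het = runs$n_het, n_missing = runs$n_missing,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(individual = character(), chrom = character(),
                      start = numeric(), end = numeric(), n_markers = integer(),
                      n_het = integer(), n_missing = integer(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("roh_segments", "data.frame")
  res
}

# maximal homozygous-endpoint runs within het/missing budgets, vectorized:
# for each homozygous start i, f(i) = furthest homozygous end within budget;
# f is non-decreasing, so keeping the first start attaining each end yields
# exactly the non-contained (maximal) runs
scan_runs <- function(calls, max_het, max_missing) {
  n <- length(calls)
  is_miss <- is.na(calls)
  is_het <- !is_miss & calls == 1L
  is_hom <- !is_miss & !is_het
  hom <- which(is_hom)
  empty <- data.frame(i = integer(), j = integer(), n_het = integer(),
                      n_missing = integer())
  if (!length(hom)) return(empty)
  Ch <- c(0L, cumsum(is_het))
  Cm <- c(0L, cumsum(is_miss))
  # largest j with the budget still satisfied over [i, j]
  j_het <- findInterval(Ch[hom] + max_het, Ch) - 1L
  j_mis <- findInterval(Cm[hom] + max_missing, Cm) - 1L
  j_lim <- pmin(j_het, j_mis, n)
  f <- hom[findInterval(j_lim, hom)]
  keep <- !duplicated(f)
  i <- hom[keep]; j <- f[keep]
  data.frame(i = i, j = j,
             n_het = Ch[j + 1L] - Ch[i],
             n_missing = Cm[j + 1L] - Cm[i])
}

#' Assemble an individual's autozygome from ROH segments
#'
#' Merges overlapping and abutting ROH segments of one individual into a
#' sorted, disjoint interval set per chromosome — the individual's
#' autozygome estimate.
#'
#' @param segments a `roh_segments` data frame from [call_roh()].
#' @param individual required when `segments` is empty.
#' @return an object of class `autozygome`: list with `individual` and
#'   `intervals` (an [interval_set()]).
#' @export
assemble_autozygome <- function(segments, individual = NULL) {
  if (nrow(segments)) {
    ids <- unique(segments$individual)
    if (length(ids) > 1)
      stop("segments from multiple individuals: ", paste(ids, collapse = ", "))
    individual <- ids
  }
  if (is.null(individual))
    stop("individual must be given when the segment list is empty")
  structure(list(individual = individual,
                 intervals = interval_set(segments$chrom, segments$start,
                                          segments$end)),
            class = "autozygome")
}

#' @export
print.autozygome <- function(x, ...) {
  cat(sprintf("autozygome of %s: %d interval(s), %s bp\n", x$individual,
              nrow(x$intervals),
              formatC(iv_total_length(x$intervals), format = "d", big.mark = ",")))
  invisible(x)
}
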