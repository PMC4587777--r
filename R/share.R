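#' Intersect autozygomes across individuals
#'
#' Set-theoretic intersection, per chromosome, of the autozygomes of
#' several (typically all affected) individuals. In a family set
#' segregating a founder mutation, the shared interval that also passes
#' the allele-identity check of [check_haplotype_identity()] is the
#' candidate locus.
#'
#' @param autozygomes list of `autozygome` objects (or interval sets).
#' @return an [interval_set()].
#' @export
intersect_autozygomes <- function(autozygomes) {
  if (!length(autozygomes)) stop("at least one autozygome is required")
  Reduce(iv_intersect, lapply(autozygomes, as_interval_set))
}

#' Check allele-level identity across shared homozygous intervals
#'
#' Overlapping runs of homozygosity may be coincidental; a shared founder
#' haplotype additionally shows the *same* homozygous allele in every
#' individual at (almost) every marker. For each interval this counts the
#' markers at which all individuals have non-missing homozygous calls
#' (*informative*) and, among those, how many carry the identical allele
#' in all individuals. Verdicts: `haplotype_shared` when the mismatch
#' fraction is at most `max_mismatch_fraction` (genotyping-error slack)
#' and at least `min_informative` markers are informative;
#' `uninformative` when fewer (never `haplotype_shared`); otherwise
#' `overlap_only`.
#'
#' Because overlapping autozygomes often extend beyond the truly shared
#' founder segment (each individual's own consanguinity adds private
#' flanks), the verdict is based on the *refined* shared window: the
#' longest stretch of informative markers within the interval whose
#' running mismatch fraction stays within tolerance (longest-subarray
#' search on mismatch indicators). An interval is `haplotype_shared` when
#' that window holds at least `min_informative` informative markers and
#' spans at least `min_length_bp`; the window's coordinates are reported
#' as `shared_start`/`shared_end`.
#'
#' @param intervals an [interval_set()] of candidate shared intervals.
#' @param matrix a `genotype_matrix` containing all `individuals`.
#' @param individuals ids entering the comparison.
#' @param max_mismatch_fraction tolerated fraction of mismatched
#'   informative markers (default 0.02).
#' @param min_informative minimum informative markers (default 25).
#' @param min_length_bp minimum length of a reportable shared window;
#'   candidate intervals shorter than this are dropped up front (default
#'   2e6, consistent with the ROH length threshold).
#' @return data frame of class `shared_haplotype_report`: one row per
#'   interval with marker counts, the whole-interval mismatch fraction,
#'   the refined window and its statistics, and the verdict.
#' @export
check_haplotype_identity <- function(intervals, matrix, individuals,
                                     max_mismatch_fraction = 0.02,
                                     min_informative = 25,
                                     min_length_bp = 2e6) {
  intervals <- as_interval_set(intervals)
  missing_ids <- setdiff(individuals, rownames(matrix$calls))
  if (length(missing_ids))
    stop("individuals not in genotype matrix: ", paste(missing_ids, collapse = ", "))
  intervals <- intervals[intervals$end - intervals$start >= min_length_bp, ,
                         drop = FALSE]
  mk <- matrix$markers
  g <- matrix$calls[individuals, , drop = FALSE]
  rows <- lapply(seq_len(nrow(intervals)), function(r) {
    sel <- mk$chrom == intervals$chrom[r] & mk$pos - 1 >= intervals$start[r] &
      mk$pos - 1 < intervals$end[r]
    sub <- g[, sel, drop = FALSE]
    informative <- colSums(is.na(sub) | sub == 1L) == 0L
    ninf <- sum(informative)
    if (ninf > 0) {
      ident <- colSums(sub[, informative, drop = FALSE] ==
                         rep(sub[1, informative], each = nrow(sub))) == nrow(sub)
      nid <- sum(ident)
    } else ident <- logical(0)
    nid <- sum(ident)
    mism <- ninf - nid
    frac <- if (ninf > 0) mism / ninf else NA_real_
    pos_inf <- mk$pos[sel][informative]
    win <- longest_tolerant_window(!ident, max_mismatch_fraction)
    w_n <- win$j - win$i + 1L
    has_win <- w_n >= 1 && win$j >= win$i
    w_start <- if (has_win) pos_inf[win$i] - 1 else NA_real_
    w_end <- if (has_win) pos_inf[win$j] + 0 else NA_real_
    w_span <- if (has_win) w_end - w_start else 0
    w_mism <- if (has_win) sum(!ident[win$i:win$j]) else NA_integer_
    verdict <- if (ninf < min_informative) "uninformative"
      else if (has_win && w_n >= min_informative && w_span >= min_length_bp)
        "haplotype_shared"
      else "overlap_only"
    data.frame(chrom = intervals$chrom[r], start = intervals$start[r],
               end = intervals$end[r],
               n_individuals = length(individuals), n_informative = ninf,
               n_identical = nid, n_mismatch = mism, mismatch_fraction = frac,
               shared_start = w_start, shared_end = w_end,
               shared_n_informative = if (has_win) w_n else 0L,
               shared_mismatch_fraction = if (has_win) w_mism / w_n else NA_real_,
               verdict = verdict, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_individuals = integer(), n_informative = integer(),
                      n_identical = integer(), n_mismatch = integer(),
                      mismatch_fraction = numeric(), shared_start = numeric(),
                      shared_end = numeric(), shared_n_informative = integer(),
                      shared_mismatch_fraction = numeric(), verdict = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("shared_haplotype_report", "data.frame")
  res
}

# Longest run of markers whose mismatch fraction stays within `tol`:
# the longest window with mean(mismatch) <= tol, i.e. the longest subarray
# of (mismatch - tol) with non-positive sum. O(n log n) prefix-maxima
# binary search. Returns marker indices (i, j); i > j means no window.
longest_tolerant_window <- function(mismatch, tol) {
  n <- length(mismatch)
  if (n == 0) return(list(i = 1L, j = 0L))
  S <- cumsum(as.numeric(mismatch) - tol)  # S[k] = sum over markers 1..k
  S0 <- c(0, S)
  eps <- 1e-9
  # candidate left prefixes: strictly increasing prefix maxima of S0
  cand <- integer(0); best <- -Inf
  for (k in seq_along(S0)) {
    if (S0[k] > best + eps) { cand <- c(cand, k); best <- S0[k] }
  }
  best_i <- 1L; best_j <- 0L; best_len <- 0L
  for (j in seq_len(n)) {
    # smallest candidate prefix k with S0[k] >= S0[j+1] (binary search on
    # the increasing candidate values)
    lo <- 1L; hi <- length(cand); k <- NA_integer_
    target <- S0[j + 1] - eps
    while (lo <= hi) {
      mid <- (lo + hi) %/% 2L
      if (S0[cand[mid]] >= target) { k <- cand[mid]; hi <- mid - 1L }
      else lo <- mid + 1L
    }
    if (!is.na(k) && k <= j) {
      len <- j - k + 1L  # window is markers k..j (prefix index k-1)
      if (len > best_len) { best_len <- len; best_i <- k; best_j <- j }
    }
  }
  list(i = best_i, j = best_j)
}
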