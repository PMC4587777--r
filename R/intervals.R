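#' Genomic interval sets
#'
#' An `interval_set` holds sorted, disjoint genomic intervals in 0-based
#' half-open coordinates (`start` inclusive, `end` exclusive), one row per
#' interval. Overlapping or abutting input intervals are merged on
#' construction, so the disjointness invariant holds after every operation.
#' All user-facing text output (reports, TSV) uses 1-based inclusive
#' coordinates; see [format_region()].
#'
#' @param chrom character vector of chromosome labels.
#' @param start,end numeric vectors of 0-based half-open interval bounds.
#' @return A data frame of class `interval_set` with columns `chrom`,
#'   `start`, `end`.
#' @examples
#' interval_set("chr21", c(0, 100), c(150, 400))  # merged into one row
#' @export
interval_set <- function(chrom = character(), start = numeric(), end = numeric()) {
  if (length(chrom) == 1 && length(start) > 1) chrom <- rep(chrom, length(start))
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start and end must have equal length")
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (any(is.na(df$start)) || any(is.na(df$end)) || any(df$end < df$start))
    stop("intervals must have start <= end and no missing bounds")
  iv_normalize(df)
}

#' @export
as_interval_set <- function(x) {
  if (inherits(x, "interval_set")) return(x)
  if (inherits(x, "autozygome")) return(x$intervals)
  if (is.data.frame(x) && all(c("chrom", "start", "end") %in% names(x)))
    return(interval_set(x$chrom, x$start, x$end))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to interval_set")
}

# merge overlapping/abutting intervals, sort; empty intervals are dropped
iv_normalize <- function(df) {
  df <- df[df$end > df$start, , drop = FALSE]
  if (nrow(df)) {
    parts <- lapply(split(df, df$chrom), function(d) {
      ir <- IRanges::reduce(IRanges::IRanges(start = d$start[order(d$start)] + 1,
                                             end = d$end[order(d$start)]))
      data.frame(chrom = d$chrom[1], start = as.numeric(IRanges::start(ir)) - 1,
                 end = as.numeric(IRanges::end(ir)), stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, parts[order(names(parts))])
  }
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  rownames(df) <- NULL
  class(df) <- c("interval_set", "data.frame")
  df
}

iv_empty <- function() interval_set()

# pairwise set operation dispatched per chromosome through IRanges
iv_binop <- function(a, b, fun, keep = c("union", "intersect")) {
  a <- as_interval_set(a); b <- as_interval_set(b)
  keep <- match.arg(keep)
  chroms <- if (keep == "union") union(a$chrom, b$chrom) else intersect(a$chrom, b$chrom)
  out <- lapply(sort(chroms), function(ch) {
    ir_a <- with(a[a$chrom == ch, ], IRanges::IRanges(start + 1, end))
    ir_b <- with(b[b$chrom == ch, ], IRanges::IRanges(start + 1, end))
    ir <- fun(ir_a, ir_b)
    if (!length(ir)) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(ir) - 1, end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(iv_empty())
  iv_normalize(res)
}

#' Interval-set algebra
#'
#' Union, intersection, difference and total length of [interval_set()]
#' objects. All operations preserve the sorted/disjoint invariant.
#'
#' @param a,b interval sets (or objects coercible via [as_interval_set()]).
#' @return `iv_union`, `iv_intersect`, `iv_setdiff`: an `interval_set`;
#'   `iv_total_length`: total covered bp as a number.
#' @export
iv_union <- function(a, b) {
  a <- as_interval_set(a); b <- as_interval_set(b)
  iv_normalize(rbind(as.data.frame(a), as.data.frame(b)))
}

#' @rdname iv_union
#' @export
iv_intersect <- function(a, b) {
  iv_binop(a, b, IRanges::intersect, keep = "intersect")
}

#' @rdname iv_union
#' @export
iv_setdiff <- function(a, b) {
  a <- as_interval_set(a); b <- as_interval_set(b)
  out <- lapply(unique(a$chrom), function(ch) {
    ir_a <- with(a[a$chrom == ch, ], IRanges::IRanges(start + 1, end))
    bb <- b[b$chrom == ch, , drop = FALSE]
    ir_b <- with(bb, IRanges::IRanges(start + 1, end))
    ir <- IRanges::setdiff(ir_a, ir_b)
    if (!length(ir)) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(ir) - 1, end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(iv_empty())
  iv_normalize(res)
}

#' @rdname iv_union
#' @export
iv_total_length <- function(a) {
  a <- as_interval_set(a)
  sum(a$end - a$start)
}

#' Test 1-based positions for containment in an interval set
#'
#' @param iv an interval set (0-based half-open).
#' @param chrom,pos vectors of chromosome labels and 1-based positions.
#' @return logical vector, one element per query position.
#' @export
iv_contains <- function(iv, chrom, pos) {
  iv <- as_interval_set(iv)
  vapply(seq_along(pos), function(k) {
    rows <- iv$chrom == chrom[k]
    any(rows & iv$start <= pos[k] - 1 & pos[k] - 1 < iv$end)
  }, logical(1))
}

# shrink every interval by `margin` bp on each side (drops emptied intervals)
iv_shrink <- function(iv, margin) {
  iv <- as_interval_set(iv)
  interval_set(iv$chrom, iv$start + margin, pmax(iv$start + margin, iv$end - margin))
}

# sample n positions (1-based) uniformly over the covered bases
iv_sample_pos <- function(iv, n) {
  iv <- as_interval_set(iv)
  len <- iv$end - iv$start
  if (!nrow(iv) || sum(len) <= 0) stop("cannot sample from an empty interval set")
  row <- sample.int(nrow(iv), n, replace = TRUE, prob = len)
  off <- floor(stats::runif(n) * len[row])
  data.frame(chrom = iv$chrom[row], pos = iv$start[row] + off + 1,
             stringsAsFactors = FALSE)
}

#' Coordinate-convention helpers
#'
#' `format_region` renders a 0-based half-open interval in the 1-based
#' inclusive `chr:start-end` style used in reports (with thousands
#' separators); `parse_region` is its inverse. The two conversions are
#' inverse bijections.
#'
#' @param chrom chromosome label(s).
#' @param start,end 0-based half-open bounds.
#' @param x region string(s) like `"chr21:43,809,418-44,828,031"`.
#' @export
format_region <- function(chrom, start, end) {
  sprintf("%s:%s-%s", chrom,
          formatC(start + 1, format = "d", big.mark = ","),
          formatC(end, format = "d", big.mark = ","))
}

#' @rdname format_region
#' @export
parse_region <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) stop("malformed region string: ", x[bad][1])
  chrom <- vapply(m, `[`, character(1), 2)
  s1 <- as.numeric(gsub(",", "", vapply(m, `[`, character(1), 3)))
  e1 <- as.numeric(gsub(",", "", vapply(m, `[`, character(1), 4)))
  data.frame(chrom = chrom, start = s1 - 1, end = e1, stringsAsFactors = FALSE)
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("interval_set: %d interval(s), %s bp total\n", nrow(x),
              formatC(iv_total_length(x), format = "d", big.mark = ",")))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}
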