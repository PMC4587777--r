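# Independent oracles and small fixtures used across the suite.
# Oracles deliberately use brute-force formulations that share no code with
# the implementation they check.

# Exhaustive ROH oracle: enumerate every marker sub-interval [i, j] with
# homozygous endpoints and counts within budget; keep those not strictly
# contained in another valid sub-interval; then apply length/count filters.
roh_oracle <- function(calls, pos, min_length_bp, min_markers, max_het,
                       max_missing) {
  n <- length(calls)
  empty <- data.frame(i = integer(), j = integer())
  if (n == 0) return(empty)
  is_miss <- is.na(calls)
  is_het <- !is_miss & calls == 1L
  is_hom <- !is_miss & !is_het
  Ch <- c(0L, cumsum(is_het)); Cm <- c(0L, cumsum(is_miss))
  nhet <- matrix(Ch[-1], n, n, byrow = TRUE) - matrix(Ch[-(n + 1)], n, n)
  nmis <- matrix(Cm[-1], n, n, byrow = TRUE) - matrix(Cm[-(n + 1)], n, n)
  upper <- outer(seq_len(n), seq_len(n), "<=")
  valid <- upper & outer(is_hom, is_hom, "&") & nhet <= max_het & nmis <= max_missing
  # number of valid supersets (i' <= i, j' >= j), including the cell itself
  if (n == 1) {
    maximal <- valid
  } else {
    cnt <- apply(valid, 2, cumsum)
    cnt <- t(apply(cnt, 1, function(r) rev(cumsum(rev(r)))))
    maximal <- valid & cnt == 1
  }
  idx <- which(maximal, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  i <- idx[, 1]; j <- idx[, 2]
  keep <- (pos[j] - pos[i]) >= min_length_bp & (j - i + 1) >= min_markers
  out <- data.frame(i = i[keep], j = j[keep])
  out[order(out$i), , drop = FALSE]
}

# Per-position interval oracle on a toy chromosome of `L` positions.
iv_to_mask <- function(iv, chrom, L) {
  mask <- rep(FALSE, L)
  sel <- iv$chrom == chrom
  for (r in which(sel)) {
    lo <- max(1, iv$start[r] + 1); hi <- min(L, iv$end[r])
    if (hi >= lo) mask[lo:hi] <- TRUE
  }
  mask
}

mask_to_iv <- function(mask, chrom) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  if (!any(keep)) return(interval_set())
  interval_set(rep(chrom, sum(keep)), starts[keep] - 1, ends[keep])
}

random_interval_set <- function(chroms = c("cA", "cB"), L = 1e4, max_iv = 6) {
  n <- sample.int(max_iv, 1)
  chrom <- sample(chroms, n, replace = TRUE)
  s <- sample.int(L, n) - 1
  e <- pmin(L, s + sample.int(L / 4, n))
  interval_set(chrom, s, e)
}

# Recursive-kinship oracle for the inbreeding coefficient (tabular method,
# independent of the path-counting implementation).
kinship_oracle <- function(ped, a, b, depth = 0) {
  if (depth > 60) stop("kinship recursion too deep")
  ia <- match(a, ped$id); ib <- match(b, ped$id)
  gen <- function(i) {
    if (is.na(ped$father[i])) return(0L)
    1L + max(gen(match(ped$father[i], ped$id)), gen(match(ped$mother[i], ped$id)))
  }
  if (a == b) {
    if (is.na(ped$father[ia])) return(0.5)
    return(0.5 * (1 + kinship_oracle(ped, ped$father[ia], ped$mother[ia], depth + 1)))
  }
  # recurse on the individual from the later generation
  if (gen(ia) < gen(ib)) { tmp <- ia; ia <- ib; ib <- tmp; a <- ped$id[ia]; b <- ped$id[ib] }
  if (is.na(ped$father[ia])) return(0)
  0.5 * (kinship_oracle(ped, ped$father[ia], b, depth + 1) +
         kinship_oracle(ped, ped$mother[ia], b, depth + 1))
}

inbreeding_oracle <- function(ped, id) {
  i <- match(id, ped$id)
  if (is.na(ped$father[i])) return(0)
  kinship_oracle(ped, ped$father[i], ped$mother[i])
}

# Random genotype vector with controllable composition.
random_calls <- function(n, p_het = 0.3, p_miss = 0.1) {
  g <- sample(c(0L, 2L), n, replace = TRUE)
  g[runif(n) < p_het] <- 1L
  g[runif(n) < p_miss] <- NA_integer_
  g
}

# Wrap a call vector in a minimal genotype_matrix for call_roh().
toy_matrix <- function(calls, pos = NULL, chrom = "chr1", id = "IND") {
  if (is.null(pos)) pos <- sort(sample.int(length(calls) * 1000, length(calls)))
  structure(list(
    calls = matrix(calls, nrow = 1, dimnames = list(id, NULL)),
    markers = data.frame(chrom = chrom, pos = pos,
                         id = sprintf("m%d", seq_along(calls)),
                         ref = "A", alt = "G", stringsAsFactors = FALSE)),
    class = "genotype_matrix")
}

# Small genome for fast simulation tests.
small_map <- function(n_chrom = 4, len = 2e7) uniform_genetic_map(n_chrom, len)

# Recovery Jaccard for one true segment: |truth /\ called| / |truth \/ called|
# over the union of called intervals overlapping the segment (the standard
# per-segment ROH evaluation; isolated error clusters may nick a called
# segment without losing coverage).
jaccard_recovered <- function(true_iv_row, called) {
  called <- as_interval_set(called)
  sel <- called$chrom == true_iv_row$chrom & called$end > true_iv_row$start &
    called$start < true_iv_row$end
  if (!any(sel)) return(0)
  b <- interval_set(called$chrom[sel], called$start[sel], called$end[sel])
  a <- interval_set(true_iv_row$chrom, true_iv_row$start, true_iv_row$end)
  iv_total_length(iv_intersect(a, b)) / iv_total_length(iv_union(a, b))
}
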