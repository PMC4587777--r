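#' Variant filter cascade
#'
#' The five ordered filters used to prioritize a homozygous recessive
#' candidate from an annotated exome: population frequency, proband
#' zygosity, autozygome position, coding/splicing consequence, and
#' in-silico predictor consensus. Each filter is a pure predicate on a
#' [variant_table()]; the set surviving all five is therefore invariant
#' under filter order, while per-step survivor counts depend on the order
#' applied. [run_cascade()] applies them in the canonical order, then
#' intersects candidates across families and checks segregation.
#'
#' @name filter_cascade
NULL

#' @param variants a [variant_table()].
#' @param threshold keep variants absent from all `databases` or with
#'   maximum catalogued frequency strictly below `threshold` (default
#'   0.001, i.e. "novel or very low frequency 0.1%"; the stricter 1e-4
#'   reading is available by argument).
#' @param databases database columns to consult (default: all in the
#'   table).
#' @rdname filter_cascade
#' @export
filter_frequency <- function(variants, threshold = 0.001, databases = NULL) {
  if (is.null(databases)) databases <- colnames(variants$freq)
  bad <- setdiff(databases, colnames(variants$freq))
  if (length(bad)) stop("unknown database name: ", paste(bad, collapse = ", "))
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  fq <- variants$freq[, databases, drop = FALSE]
  maxf <- suppressWarnings(apply(fq, 1, max, na.rm = TRUE))
  keep <- !is.finite(maxf) | maxf < threshold
  variants[keep]
}

#' @param proband individual whose zygosity is tested; variants with a
#'   missing proband genotype are removed (tallied via the
#'   `"n_missing_genotype"` attribute of the result).
#' @rdname filter_cascade
#' @export
filter_zygosity <- function(variants, proband) {
  if (!proband %in% colnames(variants$geno))
    stop("proband ", proband, " not genotyped in variant table")
  g <- variants$geno[, proband]
  out <- variants[!is.na(g) & g == GT_STATES[["hom_alt"]]]
  attr(out, "n_missing_genotype") <- sum(is.na(g))
  out
}

#' @param region an [interval_set()]; variants are kept when their 1-based
#'   position falls inside it.
#' @rdname filter_cascade
#' @export
filter_autozygome <- function(variants, region) {
  region <- as_interval_set(region)
  keep <- iv_contains(region, variants$variants$chrom, variants$variants$pos)
  variants[keep]
}

#' @rdname filter_cascade
#' @export
filter_consequence <- function(variants) {
  cls <- variants$variants$consequence
  bad <- setdiff(unique(cls), CONSEQUENCE_CLASSES)
  if (length(bad)) stop("unknown consequence class: ", bad[1])
  variants[cls %in% setdiff(CONSEQUENCE_CLASSES, c("synonymous", "noncoding"))]
}

#' @param min_damaging minimum predictors voting damaging, among those
#'   with a verdict (default 2 of the 3 conventional tools).
#'   Loss-of-function classes (nonsense, frameshift, splicing) bypass the
#'   predictor filter.
#' @rdname filter_cascade
#' @export
filter_predictions <- function(variants, min_damaging = 2) {
  if (min_damaging < 0) stop("min_damaging must be non-negative")
  ndam <- rowSums(variants$pred == "damaging", na.rm = TRUE)
  keep <- ndam >= min_damaging | variants$variants$consequence %in% LOF_CLASSES
  variants[keep]
}

#' Intersect per-family candidate sets
#'
#' Variants are matched on (chrom, pos, ref, alt) exactly; the result is
#' the subset of the first family's table present in every family's
#' surviving set.
#'
#' @param per_family_sets list (length >= 2) of [variant_table()]s.
#' @return a [variant_table()].
#' @export
intersect_candidates <- function(per_family_sets) {
  if (length(per_family_sets) < 2)
    stop("at least two per-family candidate sets are required")
  keyify <- function(vt) with(vt$variants, paste(chrom, pos, ref, alt, sep = ":"))
  keys <- Reduce(intersect, lapply(per_family_sets, keyify))
  first <- per_family_sets[[1]]
  first[keyify(first) %in% keys]
}

#' Segregation check under a homozygous-recessive model
#'
#' A variant segregates when, among members with genotype data, every
#' affected individual is homozygous alternate, every obligate-carrier
#' parent (parent of an affected) is heterozygous, and no unaffected
#' member is homozygous alternate. When the proband is the only genotyped
#' member the check is uninformative.
#'
#' @param variant single-variant [variant_table()] (or an index into
#'   `genotypes`).
#' @param pedigree a [pedigree].
#' @param genotypes named genotype vector (0/1/2/`NA`) covering pedigree
#'   members; defaults to the variant's genotype row.
#' @return list with `status` (`"consistent"`, `"inconsistent"` or
#'   `"uninformative"`) and `detail` (per-member data frame).
#' @export
segregation_check <- function(variant, pedigree, genotypes = NULL) {
  if (is.null(genotypes)) {
    if (length(variant) != 1)
      stop("variant must contain exactly one record")
    genotypes <- variant$geno[1, ]
  }
  ids <- pedigree$id
  g <- genotypes[ids]
  names(g) <- ids
  obligate <- unique(stats::na.omit(c(pedigree$father[pedigree$affected],
                                      pedigree$mother[pedigree$affected])))
  role <- ifelse(pedigree$affected, "affected",
                 ifelse(ids %in% obligate, "obligate_carrier", "unaffected"))
  expected <- ifelse(role == "affected", "hom_alt",
                     ifelse(role == "obligate_carrier", "het", "not_hom_alt"))
  ok <- ifelse(is.na(g), NA,
               ifelse(expected == "hom_alt", g == 2L,
                      ifelse(expected == "het", g == 1L, g != 2L)))
  detail <- data.frame(member = ids, role = role, genotype = g,
                       expected = expected, consistent = ok,
                       stringsAsFactors = FALSE, row.names = NULL)
  with_data <- ids[!is.na(g)]
  status <- if (length(with_data) <= 1 && all(pedigree$affected[match(with_data, ids)]))
    "uninformative"
  else if (all(ok, na.rm = TRUE)) "consistent"
  else "inconsistent"
  list(status = status, detail = detail)
}

#' Run the full prioritization cascade
#'
#' Applies frequency, zygosity, autozygome, consequence and prediction
#' filters in order for each proband, recording survivor counts and the
#' step at which each variant was removed; intersects the per-proband
#' survivor sets across families (when more than one proband); and runs
#' [segregation_check()] on the shared candidates. The final set is the
#' shared candidates not inconsistent with segregation.
#'
#' @param variants a [variant_table()].
#' @param pedigree a [pedigree]; probands default to its affected members
#'   (one per family).
#' @param regions named list of [interval_set()] autozygomes, one per
#'   proband (a single unnamed region is recycled).
#' @param probands proband ids (default `affected_ids(pedigree)`).
#' @param freq_threshold,databases,min_damaging filter parameters.
#' @return object of class `cascade_result`: `steps` (per-proband data
#'   frame of step name and survivor count), `per_family` (surviving ids
#'   per proband), `shared` (ids after cross-family intersection),
#'   `segregation` (status per shared variant), `final` (a
#'   [variant_table()] of the final candidates), `removed` (variant id ->
#'   first removing step, per proband).
#' @export
run_cascade <- function(variants, pedigree, regions, probands = NULL,
                        freq_threshold = 0.001, databases = NULL,
                        min_damaging = 2) {
  if (is.null(probands)) probands <- affected_ids(pedigree)
  if (!length(probands)) stop("no proband given and no affected individual in pedigree")
  if (inherits(regions, "interval_set") || inherits(regions, "autozygome"))
    regions <- stats::setNames(rep(list(as_interval_set(regions)),
                                   length(probands)), probands)
  if (!all(probands %in% names(regions)))
    stop("regions must be a named list covering every proband")

  per_family <- list(); steps_all <- list(); removed_all <- list()
  for (p in probands) {
    vt <- variants
    counts <- c(input = length(vt))
    removed <- stats::setNames(rep(NA_character_, length(variants)),
                               variant_ids(variants))
    note_removed <- function(before, after, step) {
      gone <- setdiff(variant_ids(before), variant_ids(after))
      removed[gone[is.na(removed[gone])]] <<- step
    }
    stepf <- list(
      frequency = function(v) filter_frequency(v, freq_threshold, databases),
      zygosity = function(v) filter_zygosity(v, p),
      autozygome = function(v) filter_autozygome(v, regions[[p]]),
      consequence = filter_consequence,
      predictions = function(v) filter_predictions(v, min_damaging)
    )
    for (s in names(stepf)) {
      nxt <- stepf[[s]](vt)
      note_removed(vt, nxt, s)
      vt <- nxt
      counts[s] <- length(vt)
    }
    per_family[[p]] <- vt
    steps_all[[p]] <- data.frame(proband = p, step = names(counts),
                                 n_survivors = as.integer(counts),
                                 stringsAsFactors = FALSE, row.names = NULL)
    removed_all[[p]] <- removed
  }

  shared <- if (length(probands) >= 2) intersect_candidates(per_family)
            else per_family[[1]]
  seg_status <- vapply(seq_len(length(shared)), function(i)
    segregation_check(shared[i], pedigree)$status, character(1))
  final <- shared[seg_status != "inconsistent"]
  structure(list(
    steps = do.call(rbind, steps_all),
    per_family = lapply(per_family, variant_ids),
    shared = variant_ids(shared),
    segregation = data.frame(id = variant_ids(shared), status = seg_status,
                             stringsAsFactors = FALSE),
    final = final,
    removed = removed_all,
    params = list(probands = probands, freq_threshold = freq_threshold,
                  min_damaging = min_damaging)),
    class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("variant prioritization cascade\n")
  for (p in unique(x$steps$proband)) {
    s <- x$steps[x$steps$proband == p, ]
    cat(sprintf("  %s: %s\n", p,
                paste(sprintf("%s=%d", s$step, s$n_survivors), collapse = " -> ")))
  }
  cat(sprintf("  shared across families: %d; final (segregation-consistent): %d\n",
              length(x$shared), length(x$final)))
  if (length(x$final))
    cat("  final candidates:", paste(variant_ids(x$final), collapse = ", "), "\n")
  invisible(x)
}
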