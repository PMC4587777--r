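#' Annotated exome variant tables
#'
#' A `variant_table` stores annotated biallelic exome variants: a core
#' data frame (`id`, `chrom`, `pos` 1-based, `ref`, `alt`, `gene`,
#' `consequence`) plus three aligned matrices: `freq` (variants x
#' population databases; `NA` = absent from that database), `pred`
#' (variants x in-silico predictors; `"damaging"`, `"benign"` or `NA` =
#' no verdict) and `geno` (variants x pedigree members; 0/1/2/`NA` as in
#' [emit_snp_genotypes()]). Consequence classes: missense, nonsense,
#' frameshift, splicing, inframe_indel, synonymous, noncoding.
#'
#' @name variant_table
NULL

CONSEQUENCE_CLASSES <- c("missense", "nonsense", "frameshift", "splicing",
                         "inframe_indel", "synonymous", "noncoding")
LOF_CLASSES <- c("nonsense", "frameshift", "splicing")
DEFAULT_DATABASES <- c("1000g", "evs", "exac", "inhouse")
DEFAULT_PREDICTORS <- c("polyphen", "sift", "cadd")

#' @param variants core data frame (see above).
#' @param freq,pred,geno aligned annotation matrices.
#' @rdname variant_table
#' @export
variant_table <- function(variants, freq, pred, geno) {
  need <- c("id", "chrom", "pos", "ref", "alt", "gene", "consequence")
  if (!all(need %in% names(variants)))
    stop("variants must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(variants$consequence), CONSEQUENCE_CLASSES)
  if (length(bad)) stop("unknown consequence class: ", bad[1])
  if (any(variants$pos <= 0)) stop("variant positions must be positive")
  n <- nrow(variants)
  for (m in list(freq, pred, geno))
    if (nrow(m) != n) stop("annotation matrices must have one row per variant")
  if (any(freq < 0 | freq > 1, na.rm = TRUE))
    stop("population frequencies must lie in [0, 1]")
  if (!all(pred %in% c("damaging", "benign", NA)))
    stop("predictor verdicts must be 'damaging', 'benign' or NA")
  ord <- order(variants$chrom, variants$pos)
  rownames(variants) <- NULL
  structure(list(variants = variants[ord, , drop = FALSE],
                 freq = freq[ord, , drop = FALSE],
                 pred = pred[ord, , drop = FALSE],
                 geno = geno[ord, , drop = FALSE]),
            class = "variant_table")
}

#' @export
`[.variant_table` <- function(x, i, ...) {
  structure(list(variants = x$variants[i, , drop = FALSE],
                 freq = x$freq[i, , drop = FALSE],
                 pred = x$pred[i, , drop = FALSE],
                 geno = x$geno[i, , drop = FALSE]),
            class = "variant_table")
}

#' @export
length.variant_table <- function(x) nrow(x$variants)

#' @export
variant_ids <- function(x) x$variants$id

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d variants, %d database(s), %d predictor(s), %d genotyped member(s)\n",
              nrow(x$variants), ncol(x$freq), ncol(x$pred), ncol(x$geno)))
  invisible(x)
}

#' Emit an annotated exome variant table with a planted causal variant
#'
#' Builds the exome-sequencing input of a founder-mutation study: one
#' planted causal variant plus decoy variants stratified by the filter
#' they fail. The planted variant sits at the simulation's causal locus,
#' inside a true autozygous segment shared (for the same founder
#' haplotype) by all affected individuals; it is absent from every
#' population database, missense, called damaging by every predictor, and
#' its genotypes follow founder-haplotype carriage in the realization —
#' homozygous alternate in every affected, heterozygous in every
#' obligate-carrier parent.
#'
#' Decoy classes (counts set in [sim_config()]`$decoys`):
#' `common` (population frequency above any plausible rarity threshold),
#' `het` (heterozygous in the probands), `outside_autozygome`,
#' `synonymous` and `noncoding`, `benign` (at most one damaging verdict),
#' `non_segregating` (passes every per-proband filter in all families but
#' an unaffected sibling is homozygous alternate), and `family_private`
#' (per family: passes that family's cascade but is absent in the other
#' family — these reproduce the handful of per-index survivors that
#' disappear at the cross-family intersection).
#'
#' @param realization a conditioned [drop_genes()] result (template
#'   `two_family_founder` for a shared planted variant).
#' @param config a [sim_config()].
#' @param seed optional seed.
#' @return a [variant_table()]; the planted variant has id `"var_causal"`
#'   and gene `"GENE_CAUSAL"`.
#' @export
emit_exome_variants <- function(realization, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ped <- realization$pedigree
  members <- ped$id
  aff <- affected_ids(ped)
  if (!length(aff)) stop("pedigree has no affected individual")
  cond <- realization$condition

  auto_full <- lapply(aff, function(a) true_autozygome(realization, a))
  names(auto_full) <- aff

  if (!is.null(cond)) {
    hap <- cond$hap
    causal <- list(chrom = cond$chrom, pos = cond$pos)
  } else {
    # unconditioned realization: search for a founder haplotype for which
    # every affected is homozygous identical by descent somewhere
    hap <- NULL
    for (lab in as.vector(t(outer(founders(ped), c(".1", ".2"), paste0)))) {
      shared <- Reduce(iv_intersect,
                       lapply(aff, function(a) autozygome_for_label(realization, a, lab)))
      if (nrow(shared) > 0) {
        hap <- lab
        big <- which.max(shared$end - shared$start)
        causal <- list(chrom = shared$chrom[big],
                       pos = floor((shared$start[big] + shared$end[big]) / 2) + 1)
        break
      }
    }
    if (is.null(hap))
      stop("placement failure: no true autozygous interval shared by all ",
           "affected individuals for any founder haplotype; re-run the ",
           "simulation with a different seed")
  }
  shared_label <- Reduce(iv_intersect,
                         lapply(aff, function(a) autozygome_for_label(realization, a, hap)))
  if (!iv_contains(shared_label, causal$chrom, causal$pos))
    stop("placement failure: affected individuals are not all homozygous for ",
         "founder haplotype ", hap, " at the causal locus; re-run the ",
         "simulation with a different seed")

  # carriage-derived genotypes at the causal locus
  x0 <- causal$pos - 0.5
  carriage <- vapply(members, function(id) {
    hp <- realization$haplotypes[[id]][[causal$chrom]]
    sum(hap_label_at(hp$pat, x0) == hap, hap_label_at(hp$mat, x0) == hap)
  }, numeric(1))

  parents_of_aff <- unique(stats::na.omit(c(ped$father[ped$affected],
                                            ped$mother[ped$affected])))
  sibs <- setdiff(ped$id[!ped$affected &
                           paste(ped$father, ped$mother) %in%
                             paste(ped$father[ped$affected], ped$mother[ped$affected])],
                  aff)

  base_geno <- function(aff_gt, parent_gt, sib_gt = 0L) {
    g <- rep(0L, length(members)); names(g) <- members
    g[aff] <- aff_gt; g[parents_of_aff] <- parent_gt; g[sibs] <- sib_gt
    g
  }

  margin <- min(1e5, config$chrom_length_bp / 50)
  shrink_or_keep <- function(iv, m) {
    s <- iv_shrink(iv, m)
    if (nrow(s)) s else iv
  }
  in_region <- shrink_or_keep(shared_label, margin)
  genome_iv <- interval_set(realization$map$chrom,
                            rep(0, nrow(realization$map)),
                            realization$map$length_bp)
  outside <- iv_shrink(iv_setdiff(genome_iv, Reduce(iv_union, auto_full)), 2 * margin)

  fams <- unique(ped$family[ped$affected])
  private_regions <- lapply(fams, function(f) {
    own <- aff[ped$family[match(aff, ped$id)] == f]
    oth <- setdiff(aff, own)
    reg <- Reduce(iv_intersect, auto_full[own])
    for (o in oth) reg <- iv_setdiff(reg, auto_full[[o]])
    shrink_or_keep(reg, margin)
  })
  names(private_regions) <- fams

  bases <- c("A", "C", "G", "T")
  rand_alleles <- function(n) {
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    list(ref = ref, alt = alt)
  }

  rows <- list(); freq <- list(); pred <- list(); geno <- list()
  add <- function(id, chrom, pos, gene, consequence, fq, pv, gt) {
    al <- rand_alleles(1)
    rows[[length(rows) + 1]] <<- data.frame(
      id = id, chrom = chrom, pos = pos, ref = al$ref, alt = al$alt,
      gene = gene, consequence = consequence, stringsAsFactors = FALSE)
    freq[[length(freq) + 1]] <<- fq
    pred[[length(pred) + 1]] <<- pv
    geno[[length(geno) + 1]] <<- gt
  }
  absent <- stats::setNames(rep(NA_real_, length(DEFAULT_DATABASES)), DEFAULT_DATABASES)
  damaging <- stats::setNames(rep("damaging", length(DEFAULT_PREDICTORS)), DEFAULT_PREDICTORS)
  benign3 <- stats::setNames(c("benign", "benign", "damaging"), DEFAULT_PREDICTORS)
  no_verdict <- stats::setNames(rep(NA_character_, length(DEFAULT_PREDICTORS)),
                                DEFAULT_PREDICTORS)

  add("var_causal", causal$chrom, causal$pos, "GENE_CAUSAL", "missense",
      absent, damaging, stats::setNames(as.integer(carriage), members))

  k <- 0
  gene_lab <- function() { k <<- k + 1; sprintf("GENE%03d", k) }
  dk <- config$decoys
  draw_pos <- function(region, n) iv_sample_pos(region, n)

  p <- draw_pos(in_region, dk[["common"]])
  for (i in seq_len(dk[["common"]])) {
    fq <- stats::setNames(stats::runif(length(DEFAULT_DATABASES), 0.01, 0.3),
                          DEFAULT_DATABASES)
    add(sprintf("var_common_%02d", i), p$chrom[i], p$pos[i], gene_lab(),
        "missense", fq, damaging, base_geno(2L, 1L))
  }
  p <- draw_pos(in_region, dk[["het"]])
  for (i in seq_len(dk[["het"]])) {
    fq <- absent
    if (i %% 2 == 0) fq["inhouse"] <- 5e-5  # very rare but catalogued
    add(sprintf("var_het_%02d", i), p$chrom[i], p$pos[i], gene_lab(),
        "missense", fq, damaging, base_geno(1L, sample(0:1, 1)))
  }
  p <- draw_pos(outside, dk[["outside_autozygome"]])
  for (i in seq_len(dk[["outside_autozygome"]]))
    add(sprintf("var_outside_%02d", i), p$chrom[i], p$pos[i], gene_lab(),
        "missense", absent, damaging, base_geno(2L, 1L))
  p <- draw_pos(in_region, dk[["synonymous"]])
  for (i in seq_len(dk[["synonymous"]]))
    add(sprintf("var_syn_%02d", i), p$chrom[i], p$pos[i], gene_lab(),
        "synonymous", absent, no_verdict, base_geno(2L, 1L))
  p <- draw_pos(in_region, dk[["noncoding"]])
  for (i in seq_len(dk[["noncoding"]]))
    add(sprintf("var_nc_%02d", i), p$chrom[i], p$pos[i], gene_lab(),
        "noncoding", absent, no_verdict, base_geno(2L, 1L))
  p <- draw_pos(in_region, dk[["benign"]])
  for (i in seq_len(dk[["benign"]]))
    add(sprintf("var_benign_%02d", i), p$chrom[i], p$pos[i], gene_lab(),
        "missense", absent, benign3, base_geno(2L, 1L))
  if (length(sibs)) {
    p <- draw_pos(in_region, dk[["non_segregating"]])
    for (i in seq_len(dk[["non_segregating"]]))
      add(sprintf("var_nonseg_%02d", i), p$chrom[i], p$pos[i], gene_lab(),
          "missense", absent, damaging, base_geno(2L, 1L, sib_gt = 2L))
  }
  for (f in fams) {
    reg <- private_regions[[f]]
    if (!nrow(reg)) next
    own <- aff[ped$family[match(aff, ped$id)] == f]
    own_par <- unique(stats::na.omit(c(ped$father[match(own, ped$id)],
                                       ped$mother[match(own, ped$id)])))
    p <- draw_pos(reg, dk[["family_private"]])
    for (i in seq_len(dk[["family_private"]])) {
      g <- rep(0L, length(members)); names(g) <- members
      g[own] <- 2L; g[own_par] <- 1L
      add(sprintf("var_priv_%s_%02d", f, i), p$chrom[i], p$pos[i], gene_lab(),
          "missense", absent, damaging, g)
    }
  }

  variants <- do.call(rbind, rows)
  vt <- variant_table(variants,
                      freq = do.call(rbind, freq),
                      pred = do.call(rbind, pred),
                      geno = do.call(rbind, geno))
  # positions must be unique for exact (chrom, pos, ref, alt) matching
  stopifnot(!anyDuplicated(paste(vt$variants$chrom, vt$variants$pos)))
  vt
}
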