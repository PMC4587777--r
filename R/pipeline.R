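#' Pipeline run configuration
#'
#' One object holding every threshold of a mapping run, round-trippable
#' through YAML so each run can write its resolved configuration beside
#' its outputs. Defaults reproduce the package's reference study design:
#' the two-family founder-mutation simulation, ROH calling at >= 2 Mb,
#' allele-identity checking at 2% mismatch, and the rare-homozygous
#' filter cascade.
#'
#' @param seed master seed for the run.
#' @param out_dir output directory for [run_pipeline()].
#' @param sim a [sim_config()] (or list of its arguments).
#' @param roh list of [call_roh()] thresholds.
#' @param share list of [check_haplotype_identity()] thresholds.
#' @param cascade list of [run_cascade()] parameters.
#' @param inputs optional real-mode inputs: a list with paths `genotypes`
#'   (PED/MAP prefix or VCF), `pedigree` (6-column PED) and `variants`
#'   (annotated VCF or TSV). When given, [run_pipeline()] ingests these
#'   instead of simulating.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = "autozygmap_run",
                       sim = list(), roh = list(), share = list(),
                       cascade = list(), inputs = NULL) {
  if (!inherits(sim, "sim_config"))
    sim <- do.call(sim_config, c(list(seed = seed), sim))
  roh_def <- list(min_length_bp = 2e6, min_markers = 50, max_het = 1,
                  max_missing = 5)
  share_def <- list(max_mismatch_fraction = 0.02, min_informative = 25)
  cascade_def <- list(freq_threshold = 0.001, min_damaging = 2)
  merge_in <- function(def, user) { def[names(user)] <- user; def }
  structure(list(seed = as.integer(seed), out_dir = out_dir, sim = sim,
                 roh = merge_in(roh_def, roh),
                 share = merge_in(share_def, share),
                 cascade = merge_in(cascade_def, cascade),
                 inputs = inputs),
            class = "run_config")
}

#' @rdname run_config
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$out_dir <- NULL  # implicit: the directory the file is written into
  x$sim <- unclass(x$sim)
  x$sim$decoys <- as.list(x$sim$decoys)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- yaml::yaml.load_file(path)
  sim_args <- x$sim
  sim_args$decoys <- unlist(sim_args$decoys)
  sim_args$maf_range <- as.numeric(unlist(sim_args$maf_range))
  run_config(seed = x$seed, out_dir = x$out_dir,
             sim = do.call(sim_config, sim_args),
             roh = x$roh, share = x$share, cascade = x$cascade)
}

#' Simulate a complete study
#'
#' Builds the template pedigree, drops genes (with ascertainment
#' conditioning at the causal locus), and emits SNP genotypes, the
#' annotated exome table and the identity-by-descent truth. One seeded
#' generator drives the whole simulation, so equal configurations give
#' identical studies.
#'
#' @param config a [sim_config()].
#' @return list with `pedigree`, `map`, `realization`, `genotypes`
#'   (a `genotype_matrix`), `variants` (a [variant_table()]), `truth`
#'   (causal variant id/locus and per-affected true autozygomes), and
#'   `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  set.seed(config$seed)
  map <- uniform_genetic_map(config$n_chrom, config$chrom_length_bp,
                             config$cm_per_mb)
  ped <- build_pedigree(config$template)
  cond <- if (!is.null(attr(ped, "carrier")))
    carrier_condition(ped, map, config$causal_chrom, config$causal_pos)
  real <- drop_genes(ped, map, condition = cond)
  gm <- emit_snp_genotypes(real, config)
  vt <- emit_exome_variants(real, config)
  aff <- affected_ids(ped)
  truth <- list(
    causal_id = "var_causal",
    causal_chrom = cond$chrom, causal_pos = cond$pos,
    autozygomes = stats::setNames(lapply(aff, function(a)
      true_autozygome(real, a)), aff))
  list(pedigree = ped, map = map, realization = real, genotypes = gm,
       variants = vt, truth = truth, config = config)
}

#' Map a study: ROH, shared haplotype, variant cascade
#'
#' The analysis half of the pipeline, operating on in-memory objects (the
#' file-based front end is [run_pipeline()]): calls ROH for each proband,
#' assembles autozygomes, intersects them across probands, scores
#' allele-level haplotype identity over the shared intervals, and runs
#' the variant-prioritization cascade with per-proband autozygome
#' regions.
#'
#' @param genotypes a `genotype_matrix`.
#' @param variants a [variant_table()].
#' @param pedigree a [pedigree]; probands default to the affected members.
#' @param roh,share,cascade parameter lists as in [run_config()].
#' @return list with `roh` (per-proband segments), `autozygomes`,
#'   `shared_intervals`, `share_report`, `cascade` (a `cascade_result`).
#' @export
map_study <- function(genotypes, variants, pedigree,
                      roh = list(), share = list(), cascade = list(),
                      probands = NULL) {
  cfg <- run_config(roh = roh, share = share, cascade = cascade)
  if (is.null(probands)) probands <- affected_ids(pedigree)
  segs <- lapply(probands, function(p)
    do.call(call_roh, c(list(genotypes, p), cfg$roh)))
  names(segs) <- probands
  autos <- lapply(probands, function(p) assemble_autozygome(segs[[p]], p))
  names(autos) <- probands
  shared <- intersect_autozygomes(autos)
  report <- do.call(check_haplotype_identity,
                    c(list(shared, genotypes, probands), cfg$share))
  regions <- stats::setNames(lapply(autos, as_interval_set), probands)
  casc <- do.call(run_cascade,
                  c(list(variants, pedigree, regions, probands), cfg$cascade))
  list(roh = segs, autozygomes = autos, shared_intervals = shared,
       share_report = report, cascade = casc)
}

#' Run the full file-based pipeline
#'
#' simulate -> ROH -> shared haplotype -> variant cascade, writing every
#' intermediate artifact under `config$out_dir`: simulated inputs
#' (PED/MAP, VCF, pedigree PED, truth BED/TSV), per-proband ROH BED+TSV,
#' the shared-haplotype BED+TSV report, the cascade TSV/JSON summary, the
#' resolved configuration and a run log. Outputs are deterministic:
#' identical configuration and seed give byte-identical trees.
#'
#' @param config a [run_config()].
#' @return (invisibly) the [map_study()] result plus `dir`, `sim`.
#' @export
run_pipeline <- function(config = run_config()) {
  stage <- "setup"
  fail <- function(e) stop("pipeline stage '", stage, "' failed: ",
                           conditionMessage(e), call. = FALSE)
  tryCatch({
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(...) file.path(config$out_dir, ...)

    seed <- config$seed
    if (!is.null(config$inputs)) {
      stage <- "ingest"
      need <- c("genotypes", "pedigree", "variants")
      miss <- setdiff(need, names(config$inputs))
      if (length(miss)) stop("missing input path(s): ", paste(miss, collapse = ", "))
      probe <- unlist(config$inputs[need])
      probe[!grepl("\\.(vcf|ped|tsv)$", probe)] <-
        paste0(probe[!grepl("\\.(vcf|ped|tsv)$", probe)], ".ped")
      absent <- probe[!file.exists(probe)]
      if (length(absent)) stop("input path does not exist: ", absent[1])
      sim <- list(pedigree = read_pedigree(config$inputs$pedigree),
                  genotypes = read_genotypes(config$inputs$genotypes),
                  variants = read_variants(config$inputs$variants),
                  truth = NULL)
    } else {
      stage <- "simulate"
      sim <- simulate_study(config$sim)
    }
    if (!is.null(sim$truth)) {
      write_pedigree(sim$pedigree, out("pedigree.ped"))
      write_ped_map(sim$genotypes, sim$pedigree, out("genotypes"))
      write_vcf(sim$genotypes, out("genotypes.vcf"), seed = seed)
      write_variants_vcf(sim$variants, out("exome.vcf"), seed = seed)
      write_variants_tsv(sim$variants, out("exome.tsv"))
      for (a in names(sim$truth$autozygomes))
        write_bed(sim$truth$autozygomes[[a]],
                  out(sprintf("truth_autozygome_%s.bed", a)),
                  header = sprintf("seed=%d", seed))
      write_tsv(data.frame(causal_id = sim$truth$causal_id,
                           chrom = sim$truth$causal_chrom,
                           pos = sim$truth$causal_pos),
                out("truth_causal_variant.tsv"))
    }

    stage <- "roh"
    res <- map_study(sim$genotypes, sim$variants, sim$pedigree,
                     roh = config$roh, share = config$share,
                     cascade = config$cascade)
    for (p in names(res$roh)) {
      seg <- res$roh[[p]]
      write_bed(as_interval_set(res$autozygomes[[p]]),
                out(sprintf("roh_%s.bed", p)), header = sprintf("seed=%d", seed))
      write_tsv(data.frame(individual = seg$individual, chrom = seg$chrom,
                           start_1based = as.integer(seg$start + 1),
                           end_1based = as.integer(seg$end),
                           n_markers = seg$n_markers, n_het = seg$n_het,
                           n_missing = seg$n_missing),
                out(sprintf("roh_%s.tsv", p)))
    }

    stage <- "share"
    write_bed(res$shared_intervals, out("shared_intervals.bed"),
              header = sprintf("seed=%d", seed))
    rep <- res$share_report
    write_tsv(data.frame(chrom = rep$chrom,
                         start_1based = as.integer(rep$start + 1),
                         end_1based = as.integer(rep$end),
                         region = format_region(rep$chrom, rep$start, rep$end),
                         n_individuals = rep$n_individuals,
                         n_informative = rep$n_informative,
                         mismatch_fraction = rep$mismatch_fraction,
                         verdict = rep$verdict),
              out("shared_haplotypes.tsv"))

    stage <- "filter"
    casc <- res$cascade
    write_tsv(casc$steps, out("cascade_steps.tsv"))
    fin <- casc$final$variants
    write_tsv(cbind(fin,
                    segregation = casc$segregation$status[
                      match(fin$id, casc$segregation$id)]),
              out("final_candidates.tsv"))
    write_json(list(seed = seed,
                    probands = casc$params$probands,
                    steps = casc$steps,
                    shared = casc$shared,
                    final = variant_ids(casc$final),
                    segregation = casc$segregation),
               out("summary.json"))

    stage <- "log"
    write_run_config(config, out("config_resolved.yaml"))
    writeLines(c(sprintf("autozygmap %s",
                         as.character(utils::packageVersion("autozygmap"))),
                 sprintf("seed: %d", seed),
                 sprintf("template: %s", config$sim$template),
                 sprintf("roh: %s", paste(names(config$roh), unlist(config$roh),
                                          sep = "=", collapse = " ")),
                 sprintf("share: %s", paste(names(config$share),
                                            unlist(config$share),
                                            sep = "=", collapse = " ")),
                 sprintf("cascade: %s", paste(names(config$cascade),
                                              unlist(config$cascade),
                                              sep = "=", collapse = " "))),
               out("run.log"))
    invisible(c(res, list(dir = config$out_dir, sim = sim)))
  }, error = fail)
}
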