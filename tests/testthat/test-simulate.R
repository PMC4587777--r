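test_that("error-free emission is homozygous within true autozygous segments", {
  ped <- build_pedigree("first_cousin")
  map <- small_map()
  real <- drop_genes(ped, map, seed = 23)
  cfg <- sim_config(seed = 23, n_chrom = 4, chrom_length_bp = 2e7,
                    error_rate = 0, missing_rate = 0)
  gm <- emit_snp_genotypes(real, cfg, seed = 23)
  auto <- true_autozygome(real, "P1")
  inside <- iv_contains(auto, gm$markers$chrom, gm$markers$pos)
  if (any(inside))
    expect_true(all(gm$calls["P1", inside] %in% c(0L, 2L)))
  expect_false(anyNA(gm$calls))
})

test_that("genotyping error and missingness rates are honoured", {
  ped <- build_pedigree("first_cousin")
  map <- small_map()
  real <- drop_genes(ped, map, seed = 31)
  clean <- emit_snp_genotypes(real, sim_config(error_rate = 0, missing_rate = 0),
                              seed = 7)
  noisy <- emit_snp_genotypes(real, sim_config(error_rate = 0.002,
                                               missing_rate = 0.004), seed = 7)
  # same seed: same markers and founder alleles, so discordance == injected error
  expect_identical(clean$markers, noisy$markers)
  n <- length(clean$calls)
  obs <- !is.na(noisy$calls)
  disc <- mean(noisy$calls[obs] != clean$calls[obs])
  expect_lt(abs(disc - 0.002), 3 * sqrt(0.002 * 0.998 / sum(obs)))
  miss <- mean(is.na(noisy$calls))
  expect_lt(abs(miss - 0.004), 3 * sqrt(0.004 * 0.996 / n))
})

test_that("emission is deterministic given a seed", {
  ped <- build_pedigree("first_cousin")
  real <- drop_genes(ped, small_map(), seed = 1)
  cfg <- sim_config()
  g1 <- emit_snp_genotypes(real, cfg, seed = 42)
  g2 <- emit_snp_genotypes(real, cfg, seed = 42)
  expect_identical(g1, g2)
})

test_that("zero-density emission warns and skips chromosomes", {
  ped <- build_pedigree("first_cousin")
  real <- drop_genes(ped, small_map(1), seed = 2)
  expect_error(
    expect_warning(
      emit_snp_genotypes(real, sim_config(marker_density = 1e-9), seed = 1),
      "skipped"),
    "no markers")
})

test_that("planted variant genotypes follow founder-haplotype carriage", {
  cfg <- sim_config(seed = 99, n_chrom = 6, chrom_length_bp = 2e7)
  sim <- simulate_study(cfg)
  ped <- sim$pedigree
  vt <- sim$variants
  g <- vt$geno[vt$variants$id == "var_causal", ]
  for (a in affected_ids(ped)) expect_identical(unname(g[a]), 2L)
  carriers <- unique(na.omit(c(ped$father[ped$affected], ped$mother[ped$affected])))
  for (p in carriers) expect_identical(unname(g[p]), 1L)
  # planted variant annotations: absent everywhere, missense, all damaging
  i <- which(vt$variants$id == "var_causal")
  expect_true(all(is.na(vt$freq[i, ])))
  expect_identical(vt$variants$consequence[i], "missense")
  expect_true(all(vt$pred[i, ] == "damaging"))
  # planted position lies in every affected's true autozygome
  for (a in affected_ids(ped))
    expect_true(iv_contains(sim$truth$autozygomes[[a]],
                            vt$variants$chrom[i], vt$variants$pos[i]))
})

test_that("decoy classes fail their designated filters by construction", {
  cfg <- sim_config(seed = 12, n_chrom = 6, chrom_length_bp = 2e7)
  sim <- simulate_study(cfg)
  vt <- sim$variants
  ids <- vt$variants$id
  cls <- sub("^var_([a-z]+).*", "\\1", ids)
  aff <- affected_ids(sim$pedigree)

  common <- which(cls == "common")
  expect_true(all(apply(vt$freq[common, , drop = FALSE], 1, max, na.rm = TRUE) > 0.001))
  het <- which(cls == "het")
  expect_true(all(vt$geno[het, aff] == 1L))
  outside <- which(cls == "outside")
  for (a in aff)
    expect_false(any(iv_contains(sim$truth$autozygomes[[a]],
                                 vt$variants$chrom[outside],
                                 vt$variants$pos[outside])))
  ben <- which(cls == "benign")
  expect_true(all(rowSums(vt$pred[ben, , drop = FALSE] == "damaging",
                          na.rm = TRUE) < 2))
  nonseg <- which(cls == "nonseg")
  sibs <- c("F1_S1", "F2_S1")
  expect_true(all(vt$geno[nonseg, sibs] == 2L))
})

test_that("unconditioned realizations without a shared IBD interval fail placement", {
  # two *unrelated* consanguineous families cannot share a founder
  # haplotype: every founder label is private to one family
  ped <- build_pedigree("two_family_founder")
  map <- small_map()
  real <- drop_genes(ped, map, seed = 4)  # unconditioned
  real$pedigree <- ped
  # remove the ancestral bridge: relabel family-2 haplotypes so no label is
  # shared across families, then placement must fail
  for (id in grep("^F2_", ped$id, value = TRUE)) {
    real$haplotypes[[id]] <- lapply(real$haplotypes[[id]], function(ch) {
      lapply(ch, function(h) { h$lab <- paste0("x", h$lab); h })
    })
  }
  expect_error(emit_exome_variants(real, sim_config(seed = 4)),
               "placement failure")
})
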