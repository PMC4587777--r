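toy_fixture <- function() {
  list(variants = read_variants(system.file("extdata", "toy_variants.tsv",
                                            package = "autozygmap")),
       pedigree = read_pedigree(system.file("extdata", "toy_pedigree.ped",
                                            package = "autozygmap")),
       region = read_bed(system.file("extdata", "toy_region.bed",
                                     package = "autozygmap")),
       golden = utils::read.delim(system.file("extdata", "toy_golden_counts.tsv",
                                              package = "autozygmap"),
                                  comment.char = "#"))
}

test_that("individual filters implement their documented predicates", {
  fx <- toy_fixture()
  vt <- fx$variants

  # frequency: absent everywhere kept; 0.5 removed at any sane threshold;
  # threshold 1.0 is vacuous
  expect_true("surv_missense_01" %in% variant_ids(filter_frequency(vt)))
  expect_false("common_01" %in% variant_ids(filter_frequency(vt)))
  expect_identical(length(filter_frequency(vt, threshold = 1)), length(vt))
  # catalogued frequency exactly at the threshold is removed (< is strict)
  at_thr <- vapply(seq_len(length(vt)), function(i)
    isTRUE(suppressWarnings(max(vt$freq[i, ], na.rm = TRUE)) == 0.001),
    logical(1))
  expect_false(any(variant_ids(vt)[at_thr] %in%
                     variant_ids(filter_frequency(vt))))
  # very low catalogued frequency (5e-5) survives both documented thresholds
  expect_true("het_01" %in% variant_ids(filter_frequency(vt)))
  expect_true("het_01" %in% variant_ids(filter_frequency(vt, threshold = 1e-4)))
  expect_error(filter_frequency(vt, databases = "gnomad"), "unknown database")

  # zygosity: het and missing removed, missing tallied
  z <- filter_zygosity(vt, "P1")
  expect_false(any(c("het_01", "missing_01") %in% variant_ids(z)))
  expect_identical(attr(z, "n_missing_genotype"), 1L)
  expect_error(filter_zygosity(vt, "QQ"), "not genotyped")

  # autozygome: printed-endpoint containment, empty region kills everything
  az <- filter_autozygome(vt, fx$region)
  expect_true(all(c("surv_missense_01", "surv_missense_02") %in% variant_ids(az)))
  expect_false(any(grepl("^outside", variant_ids(az))))
  expect_identical(length(filter_autozygome(vt, interval_set())), 0L)

  # consequence: synonymous and noncoding removed
  cq <- filter_consequence(vt)
  expect_false(any(grepl("^(syn|nc)_", variant_ids(cq))))
  expect_true("surv_missense_01" %in% variant_ids(cq))

  # predictions: >= 2 damaging kept, LoF bypass regardless of verdicts
  pr <- filter_predictions(vt)
  expect_false(any(grepl("^benign", variant_ids(pr))))
  expect_true(all(c("surv_frameshift_01", "surv_nonsense_01") %in%
                    variant_ids(pr)))
  expect_true("surv_missense_02" %in% variant_ids(pr))  # 2 of 3 damaging
  pr3 <- filter_predictions(vt, min_damaging = 3)
  expect_false("surv_missense_02" %in% variant_ids(pr3))
  expect_true("surv_frameshift_01" %in% variant_ids(pr3))  # bypass holds
})

test_that("cascade reproduces the hand-derived golden counts on the fixture", {
  fx <- toy_fixture()
  res <- run_cascade(fx$variants, fx$pedigree, fx$region)
  expect_identical(res$steps$n_survivors, fx$golden$n_survivors)
  expect_identical(res$steps$step, fx$golden$step)
  expect_true(all(diff(res$steps$n_survivors) <= 0))
  # segregation: the non-segregating survivor is excluded from the final set
  expect_identical(sort(res$segregation$status),
                   sort(c(rep("consistent", 6), "inconsistent", "uninformative")))
  expect_identical(length(res$final), 7L)
  expect_false("surv_nonseg_01" %in% variant_ids(res$final))
})

test_that("the surviving set is invariant under filter permutation", {
  fx <- toy_fixture()
  filters <- list(
    function(v) filter_frequency(v, 0.001),
    function(v) filter_zygosity(v, "P1"),
    function(v) filter_autozygome(v, fx$region),
    filter_consequence,
    function(v) filter_predictions(v, 2))
  set.seed(13)
  ref <- NULL
  for (perm in 1:8) {
    vt <- fx$variants
    for (f in sample(filters)) vt <- f(vt)
    ids <- sort(variant_ids(vt))
    if (is.null(ref)) ref <- ids else expect_identical(ids, ref)
  }
  expect_identical(ref, sort(run_cascade(fx$variants, fx$pedigree,
                                         fx$region)$shared))
})

test_that("survivor counts are non-increasing on random variant tables", {
  set.seed(99)
  ped <- toy_fixture()$pedigree
  for (rep in 1:10) {
    n <- 40
    variants <- data.frame(
      id = sprintf("v%02d", 1:n), chrom = "chr21",
      pos = sort(sample.int(9e7, n)), ref = "A", alt = "G",
      gene = sprintf("G%02d", 1:n),
      consequence = sample(c("missense", "synonymous", "noncoding", "frameshift"),
                           n, replace = TRUE))
    freq <- matrix(ifelse(runif(2 * n) < 0.5, NA, runif(2 * n, 0, 0.01)),
                   ncol = 2, dimnames = list(NULL, c("dbA", "dbB")))
    pred <- matrix(sample(c("damaging", "benign", NA), 3 * n, replace = TRUE),
                   ncol = 3, dimnames = list(NULL, c("t1", "t2", "t3")))
    geno <- matrix(sample(c(0:2, NA), 4 * n, replace = TRUE), ncol = 4,
                   dimnames = list(NULL, c("FA", "MO", "P1", "S1")))
    vt <- variant_table(variants, freq, pred, geno)
    region <- interval_set("chr21", c(0, 6e7), c(3e7, 8e7))
    res <- run_cascade(vt, ped, region)
    expect_true(all(diff(res$steps$n_survivors) <= 0))
    ids <- res$per_family$P1
    # the final per-proband set satisfies all five predicates at once
    check <- vt[variant_ids(vt) %in% ids]
    if (length(check)) {
      expect_true(all(is.na(check$geno[, "P1"]) == FALSE &
                        check$geno[, "P1"] == 2))
      expect_true(all(check$variants$consequence %in%
                        c("missense", "nonsense", "frameshift", "splicing",
                          "inframe_indel")))
    }
  }
})

test_that("cross-family intersection matches on chrom/pos/ref/alt", {
  fx <- toy_fixture()
  vt <- fx$variants
  a <- vt[1:10]; b <- vt[6:15]
  got <- intersect_candidates(list(a, b))
  expect_identical(variant_ids(got), variant_ids(vt[6:10]))
  expect_identical(length(intersect_candidates(list(vt[1:5], vt[6:10]))), 0L)
  expect_identical(variant_ids(intersect_candidates(list(a, a))),
                   variant_ids(a))
  expect_error(intersect_candidates(list(a)), "at least two")
})

test_that("segregation verdicts cover consistent, inconsistent, uninformative", {
  fx <- toy_fixture()
  ped <- fx$pedigree
  gt <- function(p1, fa, mo, s1) c(FA = fa, MO = mo, P1 = p1, S1 = s1)
  expect_identical(segregation_check(NULL, ped, gt(2L, 1L, 1L, 1L))$status,
                   "consistent")
  expect_identical(segregation_check(NULL, ped, gt(2L, 1L, 1L, 0L))$status,
                   "consistent")
  # unaffected sib homozygous alternate breaks the recessive model
  expect_identical(segregation_check(NULL, ped, gt(2L, 1L, 1L, 2L))$status,
                   "inconsistent")
  # obligate carrier not heterozygous
  expect_identical(segregation_check(NULL, ped, gt(2L, 0L, 1L, 1L))$status,
                   "inconsistent")
  # only the proband genotyped
  expect_identical(segregation_check(NULL, ped,
                                     gt(2L, NA_integer_, NA_integer_,
                                        NA_integer_))$status,
                   "uninformative")
  det <- segregation_check(NULL, ped, gt(2L, 1L, 1L, 2L))$detail
  expect_identical(det$role[det$member == "FA"], "obligate_carrier")
  expect_false(det$consistent[det$member == "S1"])

  # empty input edge: no variants, zero counts all along
  res <- run_cascade(fx$variants[0], ped, fx$region)
  expect_true(all(res$steps$n_survivors == 0L))
  expect_identical(length(res$final), 0L)
})
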