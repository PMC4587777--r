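test_that("an all-homozygous run yields a single first-to-last segment", {
  pos <- seq(10000, by = 10000, length.out = 300)  # spans 2.99 Mb
  gm <- toy_matrix(rep(c(0L, 2L), 150), pos = pos)
  seg <- call_roh(gm, "IND", min_length_bp = 2e6, min_markers = 50, max_het = 0,
                  max_missing = 0)
  expect_identical(nrow(seg), 1L)
  expect_identical(seg$start, pos[1] - 1)
  expect_identical(seg$end, pos[300])
  expect_identical(seg$n_markers, 300L)
  expect_identical(seg$n_het, 0L)
})

test_that("alternating hom/het calls yield no multi-marker segments with zero tolerance", {
  gm <- toy_matrix(rep(c(0L, 1L), 100))
  seg <- call_roh(gm, "IND", min_length_bp = 1, min_markers = 2, max_het = 0,
                  max_missing = 0)
  expect_identical(nrow(seg), 0L)
  # and nothing at the defaults either
  expect_identical(nrow(call_roh(gm, "IND")), 0L)
})

test_that("length threshold boundary is inclusive by default, strict on request", {
  pos <- c(1, 2000001)
  gm <- toy_matrix(c(0L, 0L), pos = pos)
  expect_identical(nrow(call_roh(gm, "IND", min_markers = 2, max_het = 0,
                                 max_missing = 0)), 1L)
  expect_identical(nrow(call_roh(gm, "IND", min_markers = 2, max_het = 0,
                                 max_missing = 0, strict_length = TRUE)), 0L)
})

test_that("caller matches the exhaustive enumeration oracle on random instances", {
  set.seed(909)
  for (rep in seq_len(250)) {
    n <- sample(1:200, 1)
    calls <- random_calls(n, p_het = runif(1, 0.05, 0.5),
                          p_miss = runif(1, 0, 0.2))
    pos <- sort(sample.int(n * 5000, n))
    max_het <- sample(0:3, 1); max_missing <- sample(0:3, 1)
    min_len <- sample(c(0, 1e4, 1e5), 1); min_mark <- sample(c(1, 5, 20), 1)
    gm <- toy_matrix(calls, pos = pos)
    got <- call_roh(gm, "IND", min_length_bp = min_len, min_markers = min_mark,
                    max_het = max_het, max_missing = max_missing)
    want <- roh_oracle(calls, pos, min_len, min_mark, max_het, max_missing)
    expect_equal(got$start, pos[want$i] - 1, info = paste("rep", rep))
    expect_equal(got$end, pos[want$j] + 0, info = paste("rep", rep))
  }
})

test_that("thresholds act monotonically", {
  set.seed(44)
  for (rep in seq_len(20)) {
    calls <- random_calls(150, p_het = 0.1, p_miss = 0.05)
    pos <- sort(sample.int(3e6, 150))
    gm <- toy_matrix(calls, pos = pos)
    base <- call_roh(gm, "IND", min_length_bp = 1e5, min_markers = 5,
                     max_het = 1, max_missing = 2)
    longer <- call_roh(gm, "IND", min_length_bp = 5e5, min_markers = 5,
                       max_het = 1, max_missing = 2)
    # raising the length threshold never adds segments
    expect_true(all(paste(longer$start, longer$end) %in%
                      paste(base$start, base$end)))
    cover <- function(seg) {
      if (!nrow(seg)) 0 else
        iv_total_length(interval_set(seg$chrom, seg$start, seg$end))
    }
    loose <- call_roh(gm, "IND", min_length_bp = 1e5, min_markers = 5,
                      max_het = 2, max_missing = 2)
    expect_gte(cover(loose), cover(base))  # het tolerance only adds coverage
  }
})

test_that("lookup and ordering errors are reported", {
  gm <- toy_matrix(c(0L, 0L, 0L))
  expect_error(call_roh(gm, "nobody"), "unknown individual")
  expect_error(call_roh(gm, "IND", max_het = -1), "non-negative")
  bad <- gm
  bad$markers$pos <- c(5, 2, 9)
  expect_error(call_roh(bad, "IND", min_length_bp = 0, min_markers = 1),
               "not strictly increasing")
})

test_that("assemble_autozygome merges overlapping and abutting segments", {
  empty <- data.frame(individual = character(), chrom = character(),
                      start = numeric(), end = numeric())
  auto0 <- assemble_autozygome(empty, individual = "X")
  expect_identical(nrow(auto0$intervals), 0L)
  expect_error(assemble_autozygome(empty), "individual must be given")

  seg <- data.frame(individual = "A", chrom = "chr1",
                    start = c(0, 100, 500), end = c(100, 300, 600))
  auto <- assemble_autozygome(seg)
  expect_identical(auto$intervals$start, c(0, 500))
  expect_identical(auto$intervals$end, c(300, 600))

  mixed <- seg; mixed$individual <- c("A", "B", "A")
  expect_error(assemble_autozygome(mixed), "multiple individuals")

  # union length matches a per-position oracle on random segment lists
  set.seed(8)
  for (rep in 1:20) {
    iv <- random_interval_set(chroms = "chr1", L = 5000)
    seg <- data.frame(individual = "A", chrom = iv$chrom, start = iv$start,
                      end = iv$end)
    got <- iv_total_length(assemble_autozygome(seg)$intervals)
    expect_equal(got, sum(iv_to_mask(iv, "chr1", 5000)))
  }
})
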