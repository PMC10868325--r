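test_that("primary-alignment counting yields the documented TPM arithmetic", {
  paf <- tempfile()
  writeLines(c(
    "r1\t100\t0\t100\t+\tt1\t200\t0\t100\t100\t100\t60\ttp:A:P",
    "r2\t100\t0\t100\t+\tt1\t200\t0\t100\t100\t100\t60\ttp:A:P",
    "r3\t100\t0\t100\t+\tt2\t300\t0\t100\t100\t100\t60\ttp:A:P"), paf)
  ab <- estimate_abundance(paf)
  expect_equal(ab$transcript_id, c("t1", "t2"))
  expect_equal(ab$tpm, c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  # secondary alignments are ignored entirely
  writeLines(c(readLines(paf), rep(
    "r9\t100\t0\t100\t+\tt2\t300\t0\t100\t100\t100\t0\ttp:A:S", 5)), paf)
  expect_equal(estimate_abundance(paf)$tpm, ab$tpm)
  # records without a tp tag count as primary
  writeLines("r1\t100\t0\t100\t+\tt1\t200\t0\t100\t100\t100\t60", paf)
  expect_equal(estimate_abundance(paf)$tpm, 1e6)
  writeLines("r1\t100\t0\t100\t+\tt1\t200\t0\t100\t100\t100\t0\ttp:A:S", paf)
  expect_error(estimate_abundance(paf), "no primary")
})

test_that("truncation estimation reads trims off target coordinates", {
  paf <- tempfile()
  writeLines("r1\t800\t0\t800\t+\tt1\t1000\t100\t900\t800\t800\t60\ttp:A:P", paf)
  m <- estimate_truncation(paf, bin_width = 10L)
  expect_equal(m$grid, data.frame(bin5 = 10L, bin3 = 10L, prob = 1))
  # '-' strand swaps the ends
  writeLines("r1\t800\t0\t800\t-\tt1\t1000\t50\t900\t800\t800\t60\ttp:A:P", paf)
  m <- estimate_truncation(paf, bin_width = 50L)
  expect_equal(m$grid, data.frame(bin5 = 2L, bin3 = 1L, prob = 1))
  # full-length alignments collapse to the (0,0) bin
  writeLines(c("r1\t1000\t0\t1000\t+\tt1\t1000\t0\t1000\t1000\t1000\t60",
               "r2\t500\t0\t500\t+\tt2\t500\t0\t500\t500\t500\t60"), paf)
  m <- estimate_truncation(paf, bin_width = 10L)
  expect_equal(m$grid, data.frame(bin5 = 0L, bin3 = 0L, prob = 1))
})

test_that("truncation models serialize and round-trip", {
  g <- truncation_model_grid(
    data.frame(bin5 = c(0L, 1L), bin3 = c(0L, 3L), prob = c(0.25, 0.75)), 10L)
  f <- tempfile()
  write_truncation_model(g, f)
  expect_equal(read_truncation_model(f), g)
  ln <- truncation_model_lognormal(3.2, 0.8)
  write_truncation_model(ln, f)
  expect_equal(read_truncation_model(f), ln)
})

test_that("estimators recover fixture truths within sampling bounds", {
  g <- test_genome(n_genes = 20, seed = 51)
  truth_grid <- truncation_model_grid(
    data.frame(bin5 = c(0L, 0L, 1L, 2L), bin3 = c(0L, 2L, 1L, 4L),
               prob = c(0.4, 0.3, 0.2, 0.1)), 10L)
  fx <- make_truth_paf(g$spec, g$annotation, n_alignments = 10000L,
                       trunc_model = truth_grid,
                       dir = file.path(tempdir(), "paf51"))
  # abundance: multinomial 4-sigma bounds per transcript, normalization exact
  est <- estimate_abundance(fx$paf)
  expect_equal(sum(est$tpm), 1e6, tolerance = 1e-6)
  truth <- fx$profile
  est <- est[match(truth$transcript_id, est$transcript_id), ]
  expect_equal(est$tpm, truth$tpm, tolerance = 1e-9)  # encoded exactly
  # truncation: total-variation distance to the truth grid < 0.05
  est_m <- estimate_truncation(fx$paf, bin_width = 10L)
  key <- function(g) paste(g$bin5, g$bin3)
  p <- stats::setNames(truth_grid$grid$prob, key(truth_grid$grid))
  q <- stats::setNames(est_m$grid$prob, key(est_m$grid))
  keys <- union(names(p), names(q))
  tv <- sum(abs(ifelse(is.na(p[keys]), 0, p[keys]) -
                ifelse(is.na(q[keys]), 0, q[keys]))) / 2
  expect_lt(tv, 0.05)
})

test_that("profile + truncation estimates reproduce the fixture length distribution", {
  g <- test_genome(n_genes = 20, seed = 52)
  truth_grid <- truncation_model_grid(
    data.frame(bin5 = c(0L, 1L), bin3 = c(0L, 3L), prob = c(0.6, 0.4)), 10L)
  fx <- make_truth_paf(g$spec, g$annotation, n_alignments = 10000L,
                       trunc_model = truth_grid, secondary_fraction = 0,
                       dir = file.path(tempdir(), "paf52"))
  ab <- estimate_abundance(fx$paf)
  tm <- estimate_truncation(fx$paf, bin_width = 10L)
  mols <- truncate_ends(transcribe(ab, g$annotation, 10000L, seed = 6), tm,
                        seed = 7)
  sim_len <- vapply(mols, molecule_length, numeric(1))
  real_len <- read_paf(fx$paf)$qlen
  ks <- suppressWarnings(stats::ks.test(sim_len, real_len))
  expect_lt(unname(ks$statistic), 0.05)
})
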