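ref <- test_reference()
mols <- random_molecules(60, ref, seed = 11)

test_that("tag instantiates IUPAC patterns and records them", {
  out <- tag_ends(mols[1:10], "ACGT", "", seed = 1)
  expect_true(all(startsWith(unname(realize(out, ref)), "ACGT")))
  expect_true(all(vapply(out, function(m) unname(m$tags["tag5"]), character(1))
                  == "ACGT"))
  expect_identical(tag_ends(mols[1:10], "", "", seed = 1), mols[1:10])
  expect_error(tag_ends(mols[1:2], "ACQT", ""), "IUPAC")
  # ambiguity codes draw uniformly: base frequencies at each of 3 N positions
  many <- random_molecules(6000, ref, seed = 12)
  out <- tag_ends(many, "NNN", "", seed = 2)
  t5 <- vapply(out, function(m) unname(m$tags["tag5"]), character(1))
  expect_true(all(nchar(t5) == 3))
  for (pos in 1:3) {
    cnt <- table(factor(substr(t5, pos, pos), levels = BASES))
    z <- (as.numeric(cnt) - 6000 * 0.25) / sqrt(6000 * 0.25 * 0.75)
    expect_true(all(abs(z) < 4))
  }
})

test_that("polya appends normal-length tails and records the draw", {
  out <- add_polya(mols[1:10], 20, 0, 0, seed = 1)
  expect_true(all(endsWith(unname(realize(out, ref)), strrep("A", 20))))
  expect_true(all(vapply(out, function(m) unname(m$tags["pA"]), character(1))
                  == "20"))
  expect_identical(add_polya(mols[1:10], 0, 0, 0, seed = 1), mols[1:10])
  many <- random_molecules(10000, seed = 13)
  out <- add_polya(many, 50, 10, 0, seed = 3)
  pa <- as.numeric(vapply(out, function(m) unname(m$tags["pA"]), character(1)))
  expect_lt(abs(mean(pa) - 50), 4 * 10 / sqrt(10000) + 0.5)  # + rounding slack
})

test_that("flip is a seeded involution matching the reverse-complement oracle", {
  expect_identical(flip_strand(mols, 0, seed = 1), mols)
  once <- flip_strand(mols, 1, seed = 1)
  oracle <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(unname(realize(mols, ref)))))
  expect_equal(unname(realize(once, ref)), oracle)
  twice <- flip_strand(once, 1, seed = 1)
  expect_identical(lapply(twice, `[[`, "segments"),
                   lapply(mols, `[[`, "segments"))
  # partial flip is deterministic and marks flipped molecules
  half1 <- flip_strand(mols, 0.5, seed = 9)
  half2 <- flip_strand(mols, 0.5, seed = 9)
  expect_identical(half1, half2)
  flipped <- vapply(half1, function(m) "flipped" %in% names(m$tags), logical(1))
  expect_true(any(flipped) && !all(flipped))
})

test_that("truncate trims oriented ends per the string-slice oracle", {
  degen <- truncation_model_grid(data.frame(bin5 = 0L, bin3 = 0L, prob = 1), 1L)
  expect_identical(truncate_ends(mols, degen, seed = 1), mols)

  # forced arithmetic: two segments of length 4 and 3, d3 = 5
  fa <- tempfile(fileext = ".fa"); writeLines(c(">c", "ACGTACGTAC"), fa)
  r2 <- load_reference(fa)
  m <- new_molecule("m", 1L, segments = list(genomic_segment("c", 0, 4, "+"),
                                             genomic_segment("c", 5, 8, "+")))
  d3only <- truncation_model_grid(data.frame(bin5 = 0L, bin3 = 5L, prob = 1), 1L)
  out <- truncate_ends(list(m), d3only, seed = 1)
  expect_length(out[[1]]$segments, 1)
  expect_equal(unname(realize(out, r2)), substr("ACGT", 1, 2))

  model <- truncation_model_grid(
    data.frame(bin5 = c(0L, 2L, 5L), bin3 = c(3L, 0L, 7L),
               prob = c(0.3, 0.4, 0.3)), 1L)
  before <- realize(mols, ref)
  out <- truncate_ends(mols, model, seed = 4)
  expect_lte(length(out), length(mols))
  after <- realize(out, ref)
  for (m in out) {
    d5 <- as.integer(m$tags["trunc5"]); if (is.na(d5)) d5 <- 0L
    d3 <- as.integer(m$tags["trunc3"]); if (is.na(d3)) d3 <- 0L
    orig <- before[[m$id]]
    expect_equal(after[[m$id]],
                 substr(orig, d5 + 1L, nchar(orig) - d3))
  }
  # molecules shorter than the trim are dropped
  short <- new_molecule("s", 1L, segments = list(literal_segment("ACG")))
  big <- truncation_model_grid(data.frame(bin5 = 2L, bin3 = 2L, prob = 1), 1L)
  expect_length(truncate_ends(list(short), big, seed = 1), 0)
})

test_that("filter partitions streams deterministically", {
  tagged <- lapply(seq_along(mols), function(i) {
    m <- mols[[i]]
    if (i %% 3 == 0) m$tags <- c(m$tags, CB = paste0("c", i %% 2))
    m
  })
  res <- filter_molecules(tagged, "tag:CB")
  expect_length(res$pass, sum(seq_along(mols) %% 3 == 0))
  expect_identical(c(res$pass, res$fail)[order(match(
    vapply(c(res$pass, res$fail), `[[`, character(1), "id"),
    vapply(tagged, `[[`, character(1), "id")))], tagged)
  res <- filter_molecules(mols, "len:0-")
  expect_identical(res$pass, mols)
  expect_length(res$fail, 0)
  # tag_equals routes missing keys to fail
  res <- filter_molecules(tagged, "tag:CB=c0")
  expect_true(all(vapply(res$pass, function(m) unname(m$tags["CB"]),
                         character(1)) == "c0"))
  # random predicate: binomial bound + exact reproducibility
  many <- random_molecules(10000, seed = 15)
  r1 <- filter_molecules(many, "rand:0.3", seed = 8)
  r2 <- filter_molecules(many, "rand:0.3", seed = 8)
  expect_identical(r1, r2)
  expect_lt(abs(length(r1$pass) - 3000), 4 * sqrt(10000 * 0.3 * 0.7))
})

test_that("merge conserves counts, depths and realized sequences", {
  a <- random_molecules(20, ref, seed = 16, id_prefix = "a")
  b <- random_molecules(15, ref, seed = 17, id_prefix = "b")
  expect_identical(merge_streams(a), a)
  expect_identical(merge_streams(a, list()), a)
  m <- merge_streams(a, b)
  expect_length(m, 35)
  expect_setequal(unname(realize(m, ref)), unname(c(realize(a, ref), realize(b, ref))))
  # id collisions get per-source prefixes, depth conserved
  coll <- merge_streams(a, a)
  ids <- vapply(coll, `[[`, character(1), "id")
  expect_equal(anyDuplicated(ids), 0L)
  expect_true(all(grepl("^S[12]_", ids)))
  expect_equal(sum(vapply(coll, `[[`, integer(1), "depth")),
               2 * sum(vapply(a, `[[`, integer(1), "depth")))
})

test_that("single-cell barcoding assigns stable per-cell barcodes and fresh UMIs", {
  expect_identical(barcode_cells(mols, c("AAAA"), 4, "", seed = 1), mols)
  cells <- rep(c("cellA", "cellB"), length.out = 40)
  tagged <- lapply(seq_len(40), function(i) {
    new_molecule(paste0("m", i), 1L, c(CB = cells[i]),
                 list(literal_segment("ACGTACGT")))
  })
  wl <- vapply(1:16, function(i) paste(sample(BASES, 16, replace = TRUE),
                                       collapse = ""), character(1))
  out <- barcode_cells(tagged, wl, umi_len = 12, adapter = "CTACAC", seed = 2)
  cb <- vapply(out, function(m) unname(m$tags["cb_seq"]), character(1))
  umi <- vapply(out, function(m) unname(m$tags["umi"]), character(1))
  expect_true(all(tapply(cb, cells, function(x) length(unique(x))) == 1))
  expect_equal(length(unique(cb)), 2)
  expect_true(all(cb %in% wl))
  expect_true(all(nchar(umi) == 12))
  # segment order: adapter, barcode, UMI, then the cDNA
  s <- unname(realize(out[[1]], test_reference()))
  expect_equal(s, paste0("CTACAC", cb[1], umi[1], "ACGTACGT"))
  # duplicate UMIs essentially impossible at 4^12
  big <- lapply(seq_len(1000), function(i)
    new_molecule(paste0("b", i), 1L, c(CB = "cellA"),
                 list(literal_segment("ACGT"))))
  out <- barcode_cells(big, wl, 12, "", seed = 3)
  umis <- vapply(out, function(m) unname(m$tags["umi"]), character(1))
  expect_lt(sum(duplicated(umis)), 3)
  # more cells than whitelist entries
  crowded <- lapply(seq_len(20), function(i)
    new_molecule(paste0("c", i), 1L, c(CB = paste0("cell", i)),
                 list(literal_segment("ACGT"))))
  expect_error(barcode_cells(crowded, wl[1:5], 12, "", seed = 1),
               "exceed whitelist")
})

test_that("core ops conserve molecule count and depth and are chunking-invariant", {
  depth_of <- function(x) sum(vapply(x, `[[`, integer(1), "depth"))
  for (op in list(function(x) tag_ends(x, "NNAC", "TT", seed = 5),
                  function(x) add_polya(x, 30, 5, 0, seed = 5),
                  function(x) flip_strand(x, 0.4, seed = 5))) {
    out <- op(mols)
    expect_length(out, length(mols))
    expect_equal(depth_of(out), depth_of(mols))
    # chunking never changes outcomes
    expect_identical(out, c(op(mols[1:17]), op(mols[18:length(mols)])))
  }
})

test_that("the filter/barcode/merge composition barcodes exactly the CB-tagged molecules", {
  cells <- c("c1", "c2", "c3")
  pool <- lapply(seq_len(60), function(i) {
    tags <- if (i %% 2 == 0) c(CB = cells[1 + i %% 3]) else character(0)
    new_molecule(paste0("m", i), 1L, tags, list(literal_segment(
      paste(sample(BASES, 50, replace = TRUE), collapse = ""))))
  })
  wl <- replicate(8, paste(sample(BASES, 16, replace = TRUE), collapse = ""))
  split <- filter_molecules(pool, "tag:CB")
  done <- merge_streams(barcode_cells(split$pass, wl, 10, "AGGC", seed = 7),
                        split$fail)
  has_cb_seq <- vapply(done, function(m) "cb_seq" %in% names(m$tags), logical(1))
  was_tagged <- vapply(done, function(m) "CB" %in% names(m$tags), logical(1))
  expect_identical(has_cb_seq, was_tagged)
  expect_length(done, 60)
})
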