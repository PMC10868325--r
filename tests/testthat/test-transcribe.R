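test_that("abundance profiles load and normalize to 1e6 (per cell)", {
  f <- tempfile()
  writeLines(c("transcript_id\ttpm", "t1\t500000", "t2\t500000"), f)
  ab <- load_abundance(f)
  expect_equal(ab$tpm, c(5e5, 5e5))
  writeLines(c("transcript_id\ttpm", "t1\t2", "t2\t2"), f)
  expect_warning(ab <- load_abundance(f), "rescaling")
  expect_equal(ab$tpm, c(5e5, 5e5))
  writeLines(c("transcript_id\ttpm\tcell_id", "t1\t3\tc1", "t2\t1\tc1",
               "t1\t5\tc2", "t2\t5\tc2"), f)
  suppressWarnings(ab <- load_abundance(f))
  sums <- tapply(ab$tpm, ab$cell_id, sum)
  expect_equal(as.numeric(sums), c(1e6, 1e6))
  writeLines(c("transcript_id\ttpm", "t1\t-1"), f)
  expect_error(load_abundance(f), "negative")
  writeLines(c("transcript_id\ttpm", "t1\t1", "t1\t2"), f)
  expect_error(load_abundance(f), "duplicate")
})

test_that("transcribe emits exactly n molecules with unique ids and tid tags", {
  g <- test_genome(n_genes = 20, seed = 7)
  tids <- names(g$annotation)
  ab <- data.frame(transcript_id = tids[1], tpm = 1e6,
                   stringsAsFactors = FALSE)
  class(ab) <- c("abundance", "data.frame")
  mols <- transcribe(ab, g$annotation, 5, seed = 1)
  expect_length(mols, 5)
  expect_true(all(vapply(mols, function(m) unname(m$tags["tid"]), character(1))
                  == tids[1]))
  expect_length(transcribe(ab, g$annotation, 0, seed = 1), 0)
  mols <- transcribe(make_abundance(g$spec, tids), g$annotation, 2000, seed = 2)
  ids <- vapply(mols, `[[`, character(1), "id")
  expect_equal(anyDuplicated(ids), 0L)
  expect_length(mols, 2000)
})

test_that("transcript sampling follows the TPM profile (binomial bounds)", {
  g <- test_genome(n_genes = 20, seed = 7)
  ab <- make_abundance(g$spec, names(g$annotation))
  n <- 20000L
  mols <- transcribe(ab, g$annotation, n, seed = 5)
  obs <- table(factor(vapply(mols, function(m) unname(m$tags["tid"]),
                             character(1)), levels = ab$transcript_id))
  p <- ab$tpm / 1e6
  z <- (as.numeric(obs) - n * p) / sqrt(n * p * (1 - p))
  expect_true(all(abs(z) < 4))
})

test_that("unknown transcript ids are skipped with renormalization", {
  g <- test_genome(n_genes = 10, seed = 7)
  tids <- names(g$annotation)
  ab <- data.frame(transcript_id = c(tids[1], "ghost"), tpm = c(5e5, 5e5),
                   stringsAsFactors = FALSE)
  class(ab) <- c("abundance", "data.frame")
  expect_warning(mols <- transcribe(ab, g$annotation, 50, seed = 1),
                 "absent from annotation")
  expect_true(all(vapply(mols, function(m) unname(m$tags["tid"]), character(1))
                  == tids[1]))
})

test_that("per-cell transcription tags molecules with their cell", {
  g <- test_genome(n_genes = 10, seed = 31, n_cells = 3)
  ab <- make_abundance(g$spec, names(g$annotation))
  mols <- transcribe(ab, g$annotation, 300, seed = 4)
  cb <- vapply(mols, function(m) unname(m$tags["CB"]), character(1))
  expect_setequal(unique(cb), paste0("cell", 1:3))
})

test_that("fusion generation is deterministic and respects event structure", {
  g <- test_genome(n_genes = 40, seed = 17)
  ab <- make_abundance(g$spec, names(g$annotation))
  r0 <- generate_fusions(g$annotation, ab, 0, seed = 1, reference = g$ref)
  expect_equal(nrow(r0$events), 0)
  expect_identical(r0$annotation, g$annotation)

  r1 <- generate_fusions(g$annotation, ab, 10, seed = 1, reference = g$ref)
  r2 <- generate_fusions(g$annotation, ab, 10, seed = 1, reference = g$ref)
  expect_identical(r1$events, r2$events)
  expect_equal(nrow(r1$events), 10)
  # 20 distinct genes across events
  gene_of <- function(tid) g$annotation[[tid]]$gene_id
  genes <- c(vapply(r1$events$donor_tid, gene_of, character(1)),
             vapply(r1$events$acceptor_tid, gene_of, character(1)))
  expect_equal(length(unique(genes)), 20)
  expect_true(all(vapply(r1$events$donor_tid, gene_of, character(1)) !=
                  vapply(r1$events$acceptor_tid, gene_of, character(1))))
  # too many events for the gene pool
  expect_error(generate_fusions(g$annotation, ab, 1000, seed = 1,
                                reference = g$ref), "multi-exon genes")
})

test_that("fused chains realize to donor prefix + acceptor suffix", {
  g <- test_genome(n_genes = 40, seed = 17)
  ab <- make_abundance(g$spec, names(g$annotation))
  res <- generate_fusions(g$annotation, ab, 10, seed = 3, reference = g$ref)
  for (i in seq_len(nrow(res$events))) {
    ev <- res$events[i, ]
    d_segs <- transcript_to_segments(g$annotation[[ev$donor_tid]])
    a_segs <- transcript_to_segments(g$annotation[[ev$acceptor_tid]])
    # brute-force reconstruction from the truth file
    expected <- paste0(
      unname(realize(new_molecule("d", 1L,
        segments = d_segs[seq_len(ev$donor_break)]), g$ref)),
      unname(realize(new_molecule("a", 1L,
        segments = a_segs[seq.int(ev$acceptor_break + 1L, length(a_segs))]),
        g$ref)))
    fused <- unname(realize(new_molecule("f", 1L,
      segments = res$annotation[[ev$event_id]]$segments), g$ref))
    expect_equal(fused, expected)
    expect_true(grepl(ev$junction_40mer, fused, fixed = TRUE))
  }
  # abundance augmented, renormalized, fusion tpm = donor tpm fraction
  expect_equal(sum(res$abundance$tpm), 1e6)
  expect_true(all(res$events$event_id %in% res$abundance$transcript_id))
})
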