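# Shared test fixtures: a tiny in-code reference, a randomized molecule
# generator used by round-trip and oracle tests, and an independent
# brute-force PCR lineage simulator that stores full sequences.

BASES <- c("A", "C", "G", "T")

test_reference <- function(lengths = c(ctgA = 500L, ctgB = 300L), seed = 101L) {
  withr_seed <- function(expr) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed); expr
  }
  seqs <- withr_seed(vapply(lengths, function(L)
    paste(sample(BASES, L, replace = TRUE), collapse = ""), character(1)))
  fa <- tempfile(fileext = ".fa")
  writeLines(paste0(">", names(lengths), "\n", seqs), fa)
  load_reference(fa)
}

# Random valid molecules, optionally constrained to a reference's bounds.
random_molecules <- function(n, ref = NULL, seed = 1L, id_prefix = "rm") {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  contigs <- if (is.null(ref)) c(chrX = 10000L) else ref$lengths
  lapply(seq_len(n), function(i) {
    n_seg <- sample(1:4, 1)
    segs <- lapply(seq_len(n_seg), function(j) {
      if (runif(1) < 0.3) {
        literal_segment(paste(sample(BASES, sample(1:30, 1), replace = TRUE),
                              collapse = ""))
      } else {
        ci <- sample(length(contigs), 1)
        L <- contigs[[ci]]
        w <- sample(1:min(80L, L - 1L), 1)
        s <- sample(0:(L - w), 1)
        n_sub <- sample(0:3, 1)
        off <- if (n_sub > 0) sort(sample(0:(w - 1), min(n_sub, w))) else integer(0)
        genomic_segment(names(contigs)[ci], s, s + w,
                        sample(c("+", "-"), 1), off,
                        sample(BASES, length(off), replace = TRUE))
      }
    })
    tags <- character(0)
    if (runif(1) < 0.5) {
      nt <- sample(1:3, 1)
      tags <- stats::setNames(
        replicate(nt, paste(sample(c(BASES, as.character(0:9)), 5,
                                   replace = TRUE), collapse = "")),
        paste0("k", seq_len(nt)))
    }
    new_molecule(paste0(id_prefix, i), sample(1:5, 1), tags, segs)
  })
}

# A small annotated genome for entry/estimation tests: writes FASTA + GTF,
# returns loaded objects plus the paths.
test_genome <- function(n_genes = 20L, seed = 7L, ...) {
  spec <- fixture_spec(seed = seed, n_genes = n_genes, ...)
  dir <- file.path(tempdir(), paste0("tg", seed, "_", n_genes))
  ref <- make_reference(spec, dir)
  list(spec = spec, fasta = ref$fasta, gtf = ref$gtf,
       transcripts = ref$transcripts,
       ref = load_reference(ref$fasta),
       annotation = load_annotation(ref$gtf))
}

# Independent brute-force PCR lineage simulator: every copy is a full
# sequence string; duplication and per-base substitution are applied
# directly to the characters. Returns the final multiset of sequences.
brute_pcr <- function(seqs, cycles, efficiency, error_rate) {
  copies <- as.list(seqs)
  for (cyc in seq_len(cycles)) {
    new_copies <- list()
    for (s in copies) {
      if (runif(1) < efficiency) {
        chars <- strsplit(s, "")[[1]]
        hit <- which(runif(length(chars)) < error_rate)
        for (p in hit) chars[p] <- sample(setdiff(BASES, chars[p]), 1)
        new_copies <- c(new_copies, list(paste(chars, collapse = "")))
      }
    }
    copies <- c(copies, new_copies)
  }
  unlist(copies)
}

# Per-base divergence of each sequence from its same-length ancestor.
seq_divergence <- function(a, b) {
  mapply(function(x, y) {
    cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
    mean(cx != cy)
  }, a, b, USE.NAMES = FALSE)
}

expect_valid_fastq <- function(path) {
  lines <- readLines(path)
  expect_equal(length(lines) %% 4, 0)
  ids <- lines[seq(1, length(lines), 4)]
  expect_true(all(startsWith(ids, "@")))
  expect_false(anyDuplicated(ids) > 0)
  seqs <- lines[seq(2, length(lines), 4)]
  quals <- lines[seq(4, length(lines), 4)]
  expect_true(all(lines[seq(3, length(lines), 4)] == "+"))
  expect_equal(nchar(seqs), nchar(quals))
  invisible(length(ids))
}
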