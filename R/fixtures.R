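#' Synthetic fixture specification
#'
#' Parameters for the deterministic generator of synthetic references,
#' annotations, expression profiles, whitelists and alignments used by the
#' test suite and the packaged pipeline presets. Gene models are placed
#' left to right along uniform-random contigs, never overlapping; each gene
#' carries one transcript (ids `G<g>.T1`) plus, optionally, a second isoform
#' lacking one internal exon (`G<g>.T2`).
#'
#' @param seed generator seed (the whole fixture set is a pure function of
#'   the spec).
#' @param n_contigs number of contigs.
#' @param n_genes total genes, spread round-robin over contigs.
#' @param exons_per_gene integer range `c(min, max)`.
#' @param exon_length,intron_length,intergenic base-pair ranges.
#' @param strand_ratio probability a gene is on '+'.
#' @param second_isoform_prob probability a gene with >= 3 exons gains a
#'   skipped-exon second transcript.
#' @param n_cells number of cells for per-cell profiles (0 = bulk).
#' @param whitelist_size barcodes in the whitelist.
#' @param barcode_length barcode length in bases.
#' @param dirichlet_alpha concentration of the Dirichlet expression profile.
#' @return a list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 1L, n_contigs = 2L, n_genes = 50L,
                         exons_per_gene = c(2L, 8L),
                         exon_length = c(30L, 300L),
                         intron_length = c(30L, 300L),
                         intergenic = c(50L, 400L),
                         strand_ratio = 0.5,
                         second_isoform_prob = 0,
                         n_cells = 0L, whitelist_size = 0L,
                         barcode_length = 16L,
                         dirichlet_alpha = 1) {
  stopifnot(n_contigs >= 1, n_genes >= 0, exons_per_gene[1] >= 1,
            exon_length[1] >= 1, intron_length[1] >= 1, intergenic[1] >= 1)
  structure(as.list(environment()), class = "fixture_spec")
}

rint <- function(n, range) {
  if (range[1] == range[2]) rep(as.integer(range[1]), n)
  else as.integer(sample.int(range[2] - range[1] + 1L, n, replace = TRUE) +
                    range[1] - 1L)
}

#' Generate a synthetic reference genome and annotation
#'
#' Writes a FASTA genome and a GTF annotation that are byte-identical for a
#' given spec (seed included). All invariants of [load_annotation()] hold on
#' the output by construction.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return list with `fasta`, `gtf` paths and `transcripts` (the generating
#'   structures: named list of exon matrices with contig/strand/gene).
#' @export
make_reference <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "reference.fa")
  gtf <- file.path(dir, "annotation.gtf")
  with_preserved_rng({
    set.seed(derive_seed(spec$seed, "fixture-reference"))
    contig_of <- rep(seq_len(spec$n_contigs), length.out = spec$n_genes)
    gtf_lines <- character(0)
    transcripts <- list()
    contig_seqs <- character(spec$n_contigs)
    for (ci in seq_len(spec$n_contigs)) {
      pos <- 0L  # 0-based cursor
      body <- character(0)
      for (g in which(contig_of == ci)) {
        gap <- rint(1L, spec$intergenic)
        n_ex <- rint(1L, spec$exons_per_gene)
        ex_len <- rint(n_ex, spec$exon_length)
        in_len <- if (n_ex > 1L) rint(n_ex - 1L, spec$intron_length) else integer(0)
        strand <- if (stats::runif(1) < spec$strand_ratio) "+" else "-"
        start <- pos + gap
        starts <- integer(n_ex); ends <- integer(n_ex)
        cur <- start
        for (e in seq_len(n_ex)) {
          starts[e] <- cur
          ends[e] <- cur + ex_len[e]
          cur <- ends[e] + if (e < n_ex) in_len[e] else 0L
        }
        pos <- cur
        gid <- paste0("G", g)
        exmat <- cbind(start = starts, end = ends)
        tids <- paste0(gid, ".T1")
        exsets <- list(exmat)
        if (n_ex >= 3L && stats::runif(1) < spec$second_isoform_prob) {
          drop_e <- 1L + sample.int(n_ex - 2L, 1L)
          tids <- c(tids, paste0(gid, ".T2"))
          exsets <- c(exsets, list(exmat[-drop_e, , drop = FALSE]))
        }
        for (k in seq_along(tids)) {
          em <- exsets[[k]]
          transcripts[[tids[k]]] <- list(gene_id = gid,
                                         contig = paste0("ctg", ci),
                                         strand = strand, exons = em)
          gtf_lines <- c(gtf_lines, sprintf(
            "ctg%d\tsynthetic\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
            ci, em[, "start"] + 1L, em[, "end"], strand, gid, tids[k]))
        }
      }
      total <- pos + rint(1L, spec$intergenic)
      contig_seqs[ci] <- paste(sample(.BASES, total, replace = TRUE),
                               collapse = "")
    }
  })
  names(contig_seqs) <- paste0("ctg", seq_len(spec$n_contigs))
  ss <- Biostrings::DNAStringSet(contig_seqs)
  Biostrings::writeXStringSet(ss, fasta, width = 70L)
  write_lines_lf(gtf_lines, gtf)
  list(fasta = fasta, gtf = gtf, transcripts = transcripts)
}

#' Generate a whitelist of distinct random barcodes
#'
#' @param spec a [fixture_spec()] with `whitelist_size > 0`.
#' @param path output file (one barcode per line).
#' @return character vector of barcodes, invisibly.
#' @export
make_whitelist <- function(spec, path) {
  stopifnot(spec$whitelist_size >= 1)
  with_preserved_rng({
    set.seed(derive_seed(spec$seed, "fixture-whitelist"))
    repeat {
      wl <- random_dna(spec$whitelist_size, spec$barcode_length)
      if (!anyDuplicated(wl)) break
    }
  })
  write_lines_lf(wl, path)
  invisible(wl)
}

#' Generate a Dirichlet expression profile over fixture transcripts
#'
#' @param spec a [fixture_spec()]; with `n_cells > 0` an independent profile
#'   is drawn per cell (cell ids `cell1..cellN`).
#' @param transcript_ids transcripts to cover.
#' @param path optional TSV output path.
#' @return an abundance data.frame (TPM sums to 1e6 per cell).
#' @export
make_abundance <- function(spec, transcript_ids, path = NULL) {
  draw <- function() {
    w <- stats::rgamma(length(transcript_ids), shape = spec$dirichlet_alpha)
    w / sum(w) * 1e6
  }
  with_preserved_rng({
    set.seed(derive_seed(spec$seed, "fixture-abundance"))
    if (spec$n_cells > 0L) {
      ab <- do.call(rbind, lapply(seq_len(spec$n_cells), function(ci)
        data.frame(transcript_id = transcript_ids, tpm = draw(),
                   cell_id = paste0("cell", ci), stringsAsFactors = FALSE)))
    } else {
      ab <- data.frame(transcript_id = transcript_ids, tpm = draw(),
                       stringsAsFactors = FALSE)
    }
  })
  ab <- normalize_abundance(ab)
  if (!is.null(path)) write_abundance(ab, path)
  ab
}

#' Synthesize a PAF file with known abundance and truncation truth
#'
#' Samples reads from a known transcript profile and (d5, d3) trims from a
#' known grid, then writes PAF records whose target coordinates encode
#' exactly those truths (plus a fraction of secondary records that counters
#' must ignore). Enables exact parameter-recovery tests for
#' [estimate_abundance()] and [estimate_truncation()].
#'
#' @param spec a [fixture_spec()] (seed source).
#' @param annotation a [load_annotation()] object giving target lengths.
#' @param n_alignments primary records to emit.
#' @param profile abundance data.frame over the annotation (defaults to a
#'   fresh [make_abundance()] draw).
#' @param trunc_model grid [truncation_model] to sample trims from
#'   (defaults to full-length alignments).
#' @param minus_fraction fraction of records written as '-' strand.
#' @param secondary_fraction extra secondary records as a fraction of
#'   `n_alignments`.
#' @param dir output directory.
#' @return list with `paf` path, `profile` (empirical truth abundance:
#'   exactly the counts encoded in the PAF), `sampling_profile` (the
#'   distribution the counts were drawn from), `trunc_model` (truth grid)
#'   and `sampled` (per-read tid and trims).
#' @export
make_truth_paf <- function(spec, annotation, n_alignments = 10000L,
                           profile = NULL, trunc_model = NULL,
                           minus_fraction = 0.2, secondary_fraction = 0.05,
                           dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(profile))
    profile <- make_abundance(spec, names(annotation))
  if (is.null(trunc_model))
    trunc_model <- truncation_model_grid(
      data.frame(bin5 = 0L, bin3 = 0L, prob = 1), 1L)
  tlens <- vapply(annotation, spliced_length, numeric(1))
  with_preserved_rng({
    set.seed(derive_seed(spec$seed, "fixture-paf"))
    tid <- sample(profile$transcript_id, n_alignments, replace = TRUE,
                  prob = profile$tpm)
    d <- sample_truncation(trunc_model, n_alignments)
    tlen <- as.integer(tlens[tid])
    d5 <- pmin(d[, "d5"], pmax(tlen - d[, "d3"] - 1L, 0L))
    d3 <- pmin(d[, "d3"], tlen - d5 - 1L)
    minus <- stats::runif(n_alignments) < minus_fraction
    tstart <- ifelse(minus, d3, d5)
    tend <- tlen - ifelse(minus, d5, d3)
    qlen <- tend - tstart
    lines <- sprintf("read%d\t%d\t0\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t60\ttp:A:P",
                     seq_len(n_alignments), qlen, qlen,
                     ifelse(minus, "-", "+"), tid, tlen, tstart, tend,
                     qlen, qlen)
    n_sec <- as.integer(round(secondary_fraction * n_alignments))
    if (n_sec > 0L) {
      si <- sample.int(n_alignments, n_sec, replace = TRUE)
      other <- sample(names(annotation), n_sec, replace = TRUE)
      olen <- as.integer(tlens[other])
      oend <- pmax(olen %/% 2L, 1L)
      sec <- sprintf("read%d\t%d\t0\t%d\t+\t%s\t%d\t0\t%d\t%d\t%d\t0\ttp:A:S",
                     si, qlen[si], pmin(qlen[si], oend), other, olen, oend,
                     oend, oend)
      lines <- c(lines, sec)
    }
  })
  paf <- file.path(dir, "alignments.paf")
  write_lines_lf(lines, paf)
  counts <- table(tid)
  truth_profile <- normalize_abundance(
    data.frame(transcript_id = names(counts), tpm = as.numeric(counts),
               stringsAsFactors = FALSE))
  truth_profile <- truth_profile[order(truth_profile$transcript_id), ,
                                 drop = FALSE]
  rownames(truth_profile) <- NULL
  list(paf = paf, profile = truth_profile, sampling_profile = profile,
       trunc_model = trunc_model,
       sampled = data.frame(tid = tid, d5 = d5, d3 = d3,
                            stringsAsFactors = FALSE))
}
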