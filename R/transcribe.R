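#' Load a transcript abundance profile
#'
#' Reads a TSV with columns `transcript_id`, `tpm` and optionally `cell_id`.
#' TPM values are normalized so that they sum to 1e6 (per cell when `cell_id`
#' is present); profiles arriving on another scale are rescaled with a
#' warning. Rows with `tpm = 0` are retained but never sampled.
#'
#' @param path TSV file (header required).
#' @return data.frame of class `"abundance"` with columns `transcript_id`,
#'   `tpm` and, when present in the input, `cell_id`.
#' @export
load_abundance <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c("transcript_id", "tpm") %in% names(dt)))
    stop("abundance file must have columns 'transcript_id' and 'tpm'",
         call. = FALSE)
  dt$transcript_id <- as.character(dt$transcript_id)
  dt$tpm <- as.numeric(dt$tpm)
  if (any(is.na(dt$tpm)) || any(dt$tpm < 0))
    stop("abundance contains negative or non-numeric tpm", call. = FALSE)
  has_cell <- "cell_id" %in% names(dt)
  if (has_cell) dt$cell_id <- as.character(dt$cell_id)
  key <- if (has_cell) paste(dt$transcript_id, dt$cell_id, sep = "\r")
         else dt$transcript_id
  if (anyDuplicated(key))
    stop("duplicate (transcript_id, cell_id) pair: ",
         dt$transcript_id[duplicated(key)][1], call. = FALSE)
  normalize_abundance(dt, warn = TRUE)
}

# Rescale tpm to sum to 1e6 (per cell when cell_id is present).
normalize_abundance <- function(dt, warn = FALSE) {
  grp <- if ("cell_id" %in% names(dt)) dt$cell_id else rep("", nrow(dt))
  for (g in unique(grp)) {
    i <- grp == g
    s <- sum(dt$tpm[i])
    if (s <= 0)
      stop("abundance profile sums to zero", if (nzchar(g)) paste0(" for cell '", g, "'"),
           call. = FALSE)
    if (abs(s - 1e6) > 1e-6 * 1e6) {
      if (warn)
        warning(sprintf("tpm sums to %.6g%s; rescaling to 1e6", s,
                        if (nzchar(g)) paste0(" for cell '", g, "'") else ""),
                call. = FALSE)
      dt$tpm[i] <- dt$tpm[i] / s * 1e6
    }
  }
  class(dt) <- c("abundance", "data.frame")
  dt
}

#' Write an abundance profile to TSV
#'
#' @param abundance data.frame with `transcript_id`, `tpm` (+ `cell_id`).
#' @param path output path.
#' @export
write_abundance <- function(abundance, path) {
  utils::write.table(abundance, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Sample molecules from an expression profile (entry module)
#'
#' Emits exactly `n_molecules` molecules; the transcript of each molecule is
#' drawn independently with probability `tpm / 1e6`. With a per-cell profile,
#' a cell is first drawn uniformly and the transcript from that cell's
#' profile; such molecules carry a `CB=<cell_id>` tag. Every molecule has
#' depth 1, a `tid=<transcript_id>` tag, id `M<counter>`, and segments from
#' [transcript_to_segments()].
#'
#' @param abundance an [load_abundance()] profile (ids absent from the
#'   annotation are skipped with a warning and the profile renormalized).
#' @param annotation a [load_annotation()] object.
#' @param n_molecules number of molecules to emit.
#' @param seed global seed.
#' @param id_prefix prefix for molecule ids (default `"M"`).
#' @return list of molecules.
#' @export
transcribe <- function(abundance, annotation, n_molecules, seed = 1L,
                       id_prefix = "M") {
  stopifnot(n_molecules >= 0)
  known <- abundance$transcript_id %in% names(annotation)
  if (!all(known)) {
    missing <- unique(abundance$transcript_id[!known])
    warning(length(missing), " transcript id(s) absent from annotation skipped: ",
            paste(utils::head(missing, 3), collapse = ", "),
            if (length(missing) > 3) ", ..." else "", call. = FALSE)
    abundance <- abundance[known, , drop = FALSE]
    if (!nrow(abundance) || sum(abundance$tpm) <= 0)
      stop("abundance empty after filtering against annotation", call. = FALSE)
    abundance <- normalize_abundance(abundance)
  }
  if (!nrow(abundance)) stop("empty abundance profile", call. = FALSE)
  if (n_molecules == 0) return(list())

  per_cell <- "cell_id" %in% names(abundance)
  with_preserved_rng({
    set.seed(derive_seed(seed, "transcribe"))
    if (per_cell) {
      cells <- sort(unique(abundance$cell_id))
      cell_of <- sample(cells, n_molecules, replace = TRUE)
      tid_of <- character(n_molecules)
      for (cl in cells) {
        i <- which(cell_of == cl)
        if (!length(i)) next
        sub <- abundance[abundance$cell_id == cl, , drop = FALSE]
        tid_of[i] <- sample(sub$transcript_id, length(i), replace = TRUE,
                            prob = sub$tpm)
      }
    } else {
      cell_of <- NULL
      tid_of <- sample(abundance$transcript_id, n_molecules, replace = TRUE,
                       prob = abundance$tpm)
    }
  })
  seg_cache <- new.env(parent = emptyenv())
  out <- vector("list", n_molecules)
  for (i in seq_len(n_molecules)) {
    tid <- tid_of[i]
    segs <- seg_cache[[tid]]
    if (is.null(segs)) {
      segs <- transcript_to_segments(annotation[[tid]])
      seg_cache[[tid]] <- segs
    }
    tags <- c(tid = tid)
    if (per_cell) tags <- c(tags, CB = cell_of[i])
    out[[i]] <- new_molecule(paste0(id_prefix, i), 1L, tags, segs)
  }
  out
}

#' Generate random gene-fusion transcripts
#'
#' Samples `n_events` fusion events. Each event joins two distinct genes
#' (genes are drawn uniformly without replacement across all events, so
#' `2 * n_events` distinct genes are used). A gene is represented by its
#' highest-TPM transcript (ties broken lexicographically); the donor
#' breakpoint is drawn uniformly among the internal exon junctions of that
#' transcript in its 5'->3' orientation, the acceptor breakpoint likewise.
#' The fusion transcript is the donor's oriented exons before its breakpoint
#' followed by the acceptor's oriented exons after its breakpoint. Each event
#' receives an expression of `expression_fraction` times its donor
#' transcript's TPM and the whole profile is renormalized.
#'
#' @param annotation a [load_annotation()] object.
#' @param abundance abundance profile covering the annotation.
#' @param n_events number of fusion events (>= 0).
#' @param seed global seed.
#' @param reference a [load_reference()] object (used to compute the truth
#'   junction 40-mer).
#' @param expression_fraction fraction of the donor TPM assigned to the
#'   fusion (default 1.0).
#' @return list with `events` (truth data.frame: `event_id`, `donor_tid`,
#'   `donor_break`, `acceptor_tid`, `acceptor_break`, `junction_40mer`),
#'   `annotation` (augmented with fusion transcripts `F<i>`), and
#'   `abundance` (augmented and renormalized).
#' @export
generate_fusions <- function(annotation, abundance, n_events, seed = 1L,
                             reference, expression_fraction = 1.0) {
  if (n_events < 0) stop("n_events must be >= 0", call. = FALSE)
  empty_truth <- data.frame(event_id = character(0), donor_tid = character(0),
                            donor_break = integer(0), acceptor_tid = character(0),
                            acceptor_break = integer(0),
                            junction_40mer = character(0),
                            stringsAsFactors = FALSE)
  if (n_events == 0)
    return(list(events = empty_truth, annotation = annotation,
                abundance = abundance))
  if ("cell_id" %in% names(abundance))
    stop("fusion generation expects a bulk (cell-free) abundance profile",
         call. = FALSE)

  # gene -> representative transcript = highest tpm (lexicographic ties)
  tpm_of <- stats::setNames(abundance$tpm, abundance$transcript_id)
  genes <- split(names(annotation),
                 vapply(annotation, `[[`, character(1), "gene_id"))
  rep_tx <- vapply(genes, function(tids) {
    tids <- sort(tids)
    tp <- tpm_of[tids]
    tp[is.na(tp)] <- 0
    tids[which.max(tp)]
  }, character(1))
  multi <- vapply(rep_tx, function(tid) nrow(annotation[[tid]]$exons) >= 2L,
                  logical(1))
  eligible <- names(genes)[multi]
  if (length(eligible) < 2L * n_events)
    stop(sprintf("need >= %d multi-exon genes for %d fusion events, have %d",
                 2L * n_events, n_events, length(eligible)), call. = FALSE)

  with_preserved_rng({
    set.seed(derive_seed(seed, "fusion"))
    chosen <- sample(eligible, 2L * n_events, replace = FALSE)
    donors <- chosen[seq_len(n_events) * 2L - 1L]
    acceptors <- chosen[seq_len(n_events) * 2L]
    events <- vector("list", n_events)
    ann <- annotation
    ab <- as.data.frame(abundance)
    for (i in seq_len(n_events)) {
      d_tid <- rep_tx[[donors[i]]]
      a_tid <- rep_tx[[acceptors[i]]]
      d_segs <- transcript_to_segments(ann[[d_tid]])
      a_segs <- transcript_to_segments(ann[[a_tid]])
      d_break <- sample.int(length(d_segs) - 1L, 1L)
      a_break <- sample.int(length(a_segs) - 1L, 1L)
      f_segs <- c(d_segs[seq_len(d_break)],
                  a_segs[seq.int(a_break + 1L, length(a_segs))])
      fid <- paste0("F", i)
      ann[[fid]] <- structure(
        list(transcript_id = fid,
             gene_id = paste0("FG", i),
             contig = NA_character_, strand = "+",
             exons = NULL, segments = f_segs,
             donor_gene = donors[i], acceptor_gene = acceptors[i]),
        class = "transcript_model")
      prefix_seq <- realize(new_molecule("fd", 1L, segments = d_segs[seq_len(d_break)]),
                            reference)
      suffix_seq <- realize(new_molecule("fa", 1L,
                                         segments = a_segs[seq.int(a_break + 1L, length(a_segs))]),
                            reference)
      k5 <- min(20L, nchar(prefix_seq))
      k3 <- min(20L, nchar(suffix_seq))
      jun <- paste0(substring(prefix_seq, nchar(prefix_seq) - k5 + 1L),
                    substring(suffix_seq, 1L, k3))
      d_tpm <- unname(tpm_of[d_tid])
      if (is.na(d_tpm)) d_tpm <- 0
      ab <- rbind(ab, data.frame(transcript_id = fid,
                                 tpm = expression_fraction * d_tpm,
                                 stringsAsFactors = FALSE))
      events[[i]] <- data.frame(event_id = fid, donor_tid = d_tid,
                                donor_break = d_break, acceptor_tid = a_tid,
                                acceptor_break = a_break, junction_40mer = jun,
                                stringsAsFactors = FALSE)
    }
  })
  truth <- do.call(rbind, events)
  list(events = truth, annotation = ann,
       abundance = normalize_abundance(ab))
}
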