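#' Sequencing error model
#'
#' Per-base substitution/insertion/deletion model for the exit module.
#' Positions are visited left to right; at a visited position the base is
#' deleted with probability `del_rate` (run length ~ geometric(`p_geo`)
#' truncated at `max_indel_len`; positions inside the run are skipped
#' entirely), otherwise substituted with probability `sub_rate` (uniform
#' different base); independently, an insertion of geometric length (uniform
#' bases) is placed before the position with probability `ins_rate`.
#' Qualities are constant per class: `q_match` for retained bases, `q_error`
#' for substituted and inserted bases. A per-position rate-modifier hook
#' (`rate_hook`) is reserved for future homopolymer-aware models.
#'
#' @param sub_rate,ins_rate,del_rate per-base probabilities
#'   (`sub + ins + del < 1`).
#' @param max_indel_len maximum indel length in bases.
#' @param p_geo geometric success parameter for indel lengths
#'   (length = 1 + Geom(p_geo), truncated).
#' @param q_match,q_error mean Phred for match / error bases, in `[2, 41]`.
#' @param rate_hook optional `function(position, n) -> multiplier` applied
#'   to all three rates (default `NULL`, i.e. constant rates).
#' @return object of class `"error_model"`.
#' @export
error_model <- function(sub_rate = 0.03, ins_rate = 0.02, del_rate = 0.02,
                        max_indel_len = 6L, p_geo = 0.5,
                        q_match = 20L, q_error = 7L, rate_hook = NULL) {
  stopifnot(sub_rate >= 0, ins_rate >= 0, del_rate >= 0,
            sub_rate + ins_rate + del_rate <= 1,
            max_indel_len >= 1, p_geo > 0, p_geo <= 1,
            q_match >= 2, q_match <= 41, q_error >= 2, q_error <= 41)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
                 max_indel_len = as.integer(max_indel_len), p_geo = p_geo,
                 q_match = as.integer(q_match), q_error = as.integer(q_error),
                 rate_hook = rate_hook),
            class = "error_model")
}

#' Corrupt a sequence with an error model
#'
#' @param seq non-empty nucleotide string.
#' @param model an [error_model()].
#' @param seed optional seed (draws from the current RNG stream when `NULL`).
#' @return list with `read` (corrupted sequence), `qual` (Phred+33 string of
#'   equal length) and an edit summary: `n` (template length), `visited`
#'   (positions that received draws), `sub_events`, `ins_events`,
#'   `ins_bases`, `del_events`, `del_bases`.
#' @export
corrupt_sequence <- function(seq, model, seed = NULL) {
  n <- nchar(seq)
  stopifnot(n >= 1)
  run <- function() .corrupt_impl(seq, n, model)
  if (is.null(seed)) run() else with_preserved_rng({ set.seed(seed); run() })
}

# The three alternatives to each base, for uniform different-base draws.
.ALT_BASE <- matrix(c("C", "G", "T",
                      "A", "G", "T",
                      "A", "C", "T",
                      "A", "C", "G"), nrow = 3L)

.corrupt_impl <- function(seq, n, model) {
  if (!is.null(model$rate_hook)) mult <- model$rate_hook(seq_len(n), n)
  else mult <- rep(1, n)
  dr <- model$del_rate * mult
  sr <- model$sub_rate * mult
  ir <- model$ins_rate * mult
  chars <- strsplit(seq, "")[[1]]
  qm <- rawToChar(as.raw(33L + model$q_match))
  qe <- rawToChar(as.raw(33L + model$q_error))
  u_del <- stats::runif(n); u_sub <- stats::runif(n); u_ins <- stats::runif(n)
  glen <- pmin(1L + stats::rgeom(n, model$p_geo), model$max_indel_len)

  # deletion runs: a start consumes glen bases; run interiors receive no draws
  cand <- which(u_del < dr)
  del_start <- integer(0)
  deleted <- logical(n)
  last_end <- 0L
  for (s in cand) {
    if (s <= last_end) next
    last_end <- min(s + glen[s] - 1L, n)
    del_start <- c(del_start, s)
    deleted[s:last_end] <- TRUE
  }
  interior <- deleted
  interior[del_start] <- FALSE
  vis <- !interior

  sub_pos <- which(vis & !deleted & u_sub < sr)
  ins_pos <- which(vis & u_ins < ir)

  base_out <- chars
  qual_out <- rep(qm, n)
  base_out[deleted] <- ""
  qual_out[deleted] <- ""
  if (length(sub_pos)) {
    pick <- sample.int(3L, length(sub_pos), replace = TRUE)
    idx <- match(chars[sub_pos], .BASES)
    ok <- !is.na(idx)
    base_out[sub_pos[ok]] <- .ALT_BASE[cbind(pick[ok], idx[ok])]
    if (any(!ok))  # template 'N': any base counts as a substitution
      base_out[sub_pos[!ok]] <- sample(.BASES, sum(!ok), replace = TRUE)
    qual_out[sub_pos] <- qe
  }
  ins_str <- character(n)
  ins_b <- 0L
  if (length(ins_pos)) {
    L <- glen[ins_pos]
    ins_b <- sum(L)
    bs <- sample(.BASES, ins_b, replace = TRUE)
    ins_str[ins_pos] <- vapply(split(bs, rep(seq_along(L), L)),
                               paste, character(1), collapse = "")
  }
  has_ins <- nzchar(ins_str)
  qual_ins <- character(n)
  if (any(has_ins)) qual_ins[has_ins] <- strrep(qe, nchar(ins_str[has_ins]))

  list(read = paste(paste0(ins_str, base_out), collapse = ""),
       qual = paste(paste0(qual_ins, qual_out), collapse = ""),
       n = n, visited = sum(vis), sub_events = length(sub_pos),
       ins_events = length(ins_pos), ins_bases = ins_b,
       del_events = length(del_start), del_bases = sum(deleted))
}

#' Sequence molecules into reads (exit module)
#'
#' Realizes each molecule against the reference and emits `depth`
#' independently corrupted reads per molecule, with ids
#' `<molecule_id>_r<j>`. A sidecar truth TSV links every read to its source:
#' `read_id`, `molecule_id`, `tid`, `cb_seq`, `umi` (empty when the tag is
#' absent), `mol_len`, and the edit counts `sub_events`, `ins_bases`,
#' `del_bases`. The read count is exactly the total depth of the input.
#'
#' @param molecules list of molecules.
#' @param reference a [load_reference()] object.
#' @param model an [error_model()].
#' @param seed global seed.
#' @param fastq output FASTQ (or FASTA) path.
#' @param truth output truth TSV path (`NULL` to skip).
#' @param format `"fastq"` (4-line, Phred+33) or `"fasta"`.
#' @param truth_in_header also append `mol=<id>` to read headers.
#' @return invisible summary list: `n_reads`, `total_bases` (template bases
#'   drawn over all reads), and summed edit counts.
#' @export
sequence_reads <- function(molecules, reference, model = error_model(),
                           seed = 1L, fastq, truth = NULL, format = "fastq",
                           truth_in_header = FALSE) {
  stopifnot(format %in% c("fastq", "fasta"))
  out_con <- file(fastq, open = "wb")
  on.exit(close(out_con), add = TRUE)
  truth_con <- NULL
  if (!is.null(truth)) {
    truth_con <- file(truth, open = "wb")
    on.exit(close(truth_con), add = TRUE)
    writeLines(paste("read_id", "molecule_id", "tid", "cb_seq", "umi",
                     "mol_len", "sub_events", "ins_bases", "del_bases",
                     sep = "\t"), truth_con, sep = "\n")
  }
  totals <- c(n_reads = 0, total_bases = 0, visited = 0, sub_events = 0,
              ins_events = 0, ins_bases = 0, del_events = 0, del_bases = 0)
  tagval <- function(m, key) {
    v <- m$tags[key]
    if (is.na(v)) "" else unname(v)
  }
  for (m in molecules) {
    tpl <- unname(realize(m, reference))
    mlen <- nchar(tpl)
    for (j in seq_len(m$depth)) {
      res <- corrupt_sequence(tpl, model,
                              seed = derive_seed(seed, "sequence", m$id, j))
      rid <- paste0(m$id, "_r", j)
      header_extra <- if (truth_in_header) paste0(" mol=", m$id) else ""
      if (format == "fastq") {
        writeLines(c(paste0("@", rid, header_extra), res$read, "+", res$qual),
                   out_con, sep = "\n")
      } else {
        writeLines(c(paste0(">", rid, header_extra), res$read), out_con,
                   sep = "\n")
      }
      if (!is.null(truth_con)) {
        writeLines(paste(rid, m$id, tagval(m, "tid"), tagval(m, "cb_seq"),
                         tagval(m, "umi"), mlen, res$sub_events, res$ins_bases,
                         res$del_bases, sep = "\t"), truth_con, sep = "\n")
      }
      totals <- totals + c(1, res$n, res$visited, res$sub_events,
                           res$ins_events, res$ins_bases, res$del_events,
                           res$del_bases)
    }
  }
  invisible(as.list(totals))
}
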