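#' Load a reference genome from FASTA
#'
#' Sequences are held in memory, uppercased, and any non-ACGT character is
#' collapsed to `N` (soft-masking and IUPAC ambiguity are irrelevant to
#' simulation; `N` gives deterministic behaviour on ambiguous bases).
#'
#' @param path FASTA file.
#' @return an object of class `"reference"` with fields `seq` (named
#'   character vector) and `lengths`.
#' @export
load_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- gsub("[^ACGT]", "N", seqs)
  structure(list(seq = seqs, lengths = nchar(seqs)), class = "reference")
}

#' Fetch a reference interval
#'
#' @param ref a [load_reference()] object.
#' @param contig contig name.
#' @param start,end 0-based half-open interval.
#' @return exactly `end - start` uppercase bases.
#' @export
fetch_ref <- function(ref, contig, start, end) {
  if (is.na(match(contig, names(ref$seq))))
    stop("unknown contig '", contig, "'", call. = FALSE)
  if (start < 0 || end > ref$lengths[[contig]] || start >= end)
    stop(sprintf("interval [%d,%d) out of bounds on contig '%s' (length %d)",
                 start, end, contig, ref$lengths[[contig]]), call. = FALSE)
  substring(ref$seq[[contig]], start + 1L, end)
}

#' Load transcript models from a GTF annotation
#'
#' Exon features are grouped by `transcript_id`, their 1-based inclusive GTF
#' coordinates converted to 0-based half-open, and exons sorted by genomic
#' start. Transcript features that carry no exons are dropped with a warning.
#' Attribute parsing follows rtracklayer, which tolerates both the
#' `key "value";` GTF spelling and `key=value` (GFF) spelling.
#'
#' @param path GTF file.
#' @return a named list of transcript models (class `"annotation"`). Each
#'   model holds `transcript_id`, `gene_id`, `contig`, `strand`, and `exons`
#'   (two-column integer matrix `start`,`end`, 0-based half-open, ascending).
#' @export
load_annotation <- function(path) {
  if (file.size(path) %in% c(0L, NA_integer_) ||
      !any(nzchar(readLines(path, n = 5L)))) {
    out <- list()
    class(out) <- "annotation"
    return(out)
  }
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) rtracklayer::import(path, format = "gff"))
  type <- as.character(gr$type)
  ex <- gr[type == "exon"]
  if (!length(ex)) {
    out <- list()
    class(out) <- "annotation"
    return(out)
  }
  tid <- as.character(ex$transcript_id)
  if (anyNA(tid) || any(!nzchar(tid))) {
    bad <- which(is.na(tid) | !nzchar(tid))[1]
    stop("exon record ", bad, " lacks a transcript_id attribute", call. = FALSE)
  }
  gid <- as.character(ex$gene_id)
  if (is.null(ex$gene_id)) gid <- rep(NA_character_, length(ex))
  contig <- as.character(GenomicRanges::seqnames(ex))
  strand <- as.character(BiocGenerics::strand(ex))
  start0 <- BiocGenerics::start(ex) - 1L   # GTF 1-based inclusive -> 0-based half-open
  end0 <- BiocGenerics::end(ex)
  ord <- order(tid, start0)
  tid <- tid[ord]; gid <- gid[ord]; contig <- contig[ord]
  strand <- strand[ord]; start0 <- start0[ord]; end0 <- end0[ord]
  idx <- split(seq_along(tid), tid)
  models <- lapply(idx, function(ii) {
    if (length(unique(contig[ii])) != 1L)
      stop("transcript '", tid[ii[1]], "' spans multiple contigs", call. = FALSE)
    exons <- cbind(start = start0[ii], end = end0[ii])
    if (nrow(exons) > 1L && any(exons[-1L, "start"] < exons[-nrow(exons), "end"]))
      stop("transcript '", tid[ii[1]], "' has overlapping exons", call. = FALSE)
    structure(list(transcript_id = tid[ii[1]], gene_id = gid[ii[1]],
                   contig = contig[ii[1]], strand = strand[ii[1]],
                   exons = exons),
              class = "transcript_model")
  })
  # transcripts announced by 'transcript' features but lacking exons
  tf <- gr[type == "transcript"]
  if (length(tf)) {
    declared <- unique(as.character(tf$transcript_id))
    missing <- setdiff(declared, names(models))
    if (length(missing))
      warning(length(missing), " transcript(s) without exons dropped: ",
              paste(utils::head(missing, 3), collapse = ", "),
              if (length(missing) > 3) ", ..." else "", call. = FALSE)
  }
  class(models) <- "annotation"
  models
}

spliced_length <- function(t) {
  if (!is.null(t$segments))
    return(sum(vapply(t$segments, segment_length, numeric(1))))
  sum(t$exons[, "end"] - t$exons[, "start"])
}

#' Convert a transcript model to an oriented segment chain
#'
#' '+' transcripts yield exons in ascending genomic order with strand '+';
#' '-' transcripts yield exons in descending genomic order with strand '-',
#' so that the concatenated oriented sequences read 5'->3' along the mature
#' RNA. Fusion transcripts (which carry a precomputed `segments` chain) are
#' returned as-is.
#'
#' @param t a transcript model from [load_annotation()].
#' @return ordered list of segments, 5'->3'.
#' @export
transcript_to_segments <- function(t) {
  if (!is.null(t$segments)) return(t$segments)
  ex <- t$exons
  rows <- seq_len(nrow(ex))
  if (t$strand == "-") rows <- rev(rows)
  lapply(rows, function(i)
    genomic_segment(t$contig, ex[i, "start"], ex[i, "end"], t$strand))
}

.realize_segment <- function(seg, ref, mol_id, seg_i) {
  if (seg$kind == "literal") return(seg$sequence)
  s <- tryCatch(fetch_ref(ref, seg$contig, seg$start, seg$end),
                error = function(e)
                  stop(sprintf("molecule '%s' segment %d: %s", mol_id, seg_i,
                               conditionMessage(e)), call. = FALSE))
  if (seg$strand == "-") s <- revcomp(s)
  if (length(seg$sub_offset)) {
    for (k in seq_along(seg$sub_offset)) {
      pos <- seg$sub_offset[k] + 1L
      if (substr(s, pos, pos) == "N") {
        warning(sprintf("molecule '%s' segment %d: substitution at offset %d targets 'N'; skipped",
                        mol_id, seg_i, seg$sub_offset[k]), call. = FALSE)
        next
      }
      substr(s, pos, pos) <- seg$sub_base[k]
    }
  }
  s
}

#' Realize molecule sequences against a reference
#'
#' Concatenates, per segment 5'->3': the literal sequence, or the fetched
#' genomic interval (reverse-complemented for '-' strand) with substitutions
#' applied at oriented offsets. The result length always equals
#' [molecule_length()].
#'
#' @param molecules a single molecule or a list of molecules.
#' @param ref a [load_reference()] object.
#' @return character vector of sequences, named by molecule id.
#' @export
realize <- function(molecules, ref) {
  if (inherits(molecules, "molecule")) molecules <- list(molecules)
  out <- vapply(molecules, function(m) {
    paste(vapply(seq_along(m$segments), function(i)
      .realize_segment(m$segments[[i]], ref, m$id, i), character(1)),
      collapse = "")
  }, character(1))
  names(out) <- vapply(molecules, `[[`, character(1), "id")
  out
}
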