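#' Read a PAF alignment file
#'
#' Parses the 12 mandatory PAF columns plus the `tp:A:` type tag. Records
#' lacking the tag are treated as primary.
#'
#' @param path PAF file.
#' @return data.frame with columns `qname`, `qlen`, `qstart`, `qend`,
#'   `strand`, `tname`, `tlen`, `tstart`, `tend`, `nmatch`, `alen`, `mapq`,
#'   `primary` (logical). Coordinates are 0-based half-open on both axes.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty PAF input", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stop("PAF line ", which(nf < 12L)[1], " has fewer than 12 fields",
         call. = FALSE)
  getcol <- function(i) vapply(fields, `[[`, character(1), i)
  df <- data.frame(
    qname = getcol(1), qlen = as.integer(getcol(2)),
    qstart = as.integer(getcol(3)), qend = as.integer(getcol(4)),
    strand = getcol(5), tname = getcol(6), tlen = as.integer(getcol(7)),
    tstart = as.integer(getcol(8)), tend = as.integer(getcol(9)),
    nmatch = as.integer(getcol(10)), alen = as.integer(getcol(11)),
    mapq = as.integer(getcol(12)), stringsAsFactors = FALSE)
  tp <- vapply(fields, function(f) {
    hit <- grep("^tp:A:", f[-seq_len(12)], value = TRUE)
    if (length(hit)) substring(hit[1], 6L) else "P"
  }, character(1))
  df$primary <- tp == "P"
  bad <- df$qstart < 0 | df$qstart >= df$qend | df$qend > df$qlen |
         df$tstart < 0 | df$tstart >= df$tend | df$tend > df$tlen
  if (any(bad))
    stop("PAF line ", which(bad)[1], " has out-of-range coordinates",
         call. = FALSE)
  df
}

#' Estimate a transcript expression profile from alignments
#'
#' Counts primary alignments per target transcript (per (target, cell) when
#' `per_cell`) and converts counts to TPM: `count / sum(count) * 1e6`,
#' normalized per cell. Targets with zero counts are omitted. Multi-mapping
#' is handled by primary-only counting (no EM rescue).
#'
#' @param paf a [read_paf()] data.frame or a PAF file path (long reads
#'   aligned against a transcriptome: targets are transcripts).
#' @param per_cell parse a cell id from each read name and profile per cell.
#' @param cb_extractor function mapping read names to cell ids; the default
#'   takes the substring after the last `"_"`.
#' @return an abundance data.frame (see [load_abundance()]); with `per_cell`,
#'   TPM sums to 1e6 within each cell.
#' @export
estimate_abundance <- function(paf, per_cell = FALSE,
                               cb_extractor = function(x) sub(".*_", "", x)) {
  if (is.character(paf)) paf <- read_paf(paf)
  p <- paf[paf$primary, , drop = FALSE]
  if (!nrow(p)) stop("no primary alignments in PAF input", call. = FALSE)
  if (per_cell) {
    cell <- cb_extractor(p$qname)
    tab <- as.data.frame(table(tname = p$tname, cell_id = cell),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0, , drop = FALSE]
    out <- data.frame(transcript_id = tab$tname, tpm = as.numeric(tab$Freq),
                      cell_id = tab$cell_id, stringsAsFactors = FALSE)
  } else {
    tab <- table(p$tname)
    out <- data.frame(transcript_id = names(tab), tpm = as.numeric(tab),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  normalize_abundance(out)
}

#' Estimate an empirical truncation model from alignments
#'
#' Per primary alignment, the 5' trim is the unaligned target prefix in read
#' orientation (`tstart` for '+', `tlen - tend` for '-') and the 3' trim the
#' complementary suffix. The joint histogram of
#' `(floor(d5/bin), floor(d3/bin))` normalized to probabilities forms a grid
#' [truncation_model]. The model is marginal over targets (not conditioned
#' on transcript length or identity).
#'
#' @param paf a [read_paf()] data.frame or PAF file path (vs transcriptome).
#' @param bin_width histogram bin width in bases.
#' @return a grid `"truncation_model"`.
#' @export
estimate_truncation <- function(paf, bin_width = 10L) {
  if (is.character(paf)) paf <- read_paf(paf)
  p <- paf[paf$primary, , drop = FALSE]
  if (!nrow(p)) stop("no primary alignments in PAF input", call. = FALSE)
  plus <- p$strand == "+"
  d5 <- ifelse(plus, p$tstart, p$tlen - p$tend)
  d3 <- ifelse(plus, p$tlen - p$tend, p$tstart)
  b5 <- d5 %/% bin_width
  b3 <- d3 %/% bin_width
  key <- paste(b5, b3)
  tab <- table(key)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  grid <- data.frame(bin5 = as.integer(vapply(parts, `[[`, character(1), 1)),
                     bin3 = as.integer(vapply(parts, `[[`, character(1), 2)),
                     prob = as.numeric(tab) / nrow(p))
  grid <- grid[order(grid$bin5, grid$bin3), , drop = FALSE]
  rownames(grid) <- NULL
  truncation_model_grid(grid, bin_width)
}
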