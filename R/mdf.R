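#' Molecule Description Format (MDF)
#'
#' MDF is the tabular intermediate format every core module of this simulator
#' consumes and produces. One molecule is a header line followed by one line
#' per segment, 5'->3':
#'
#' ```
#' +<id>\t<depth>\t<k=v;k=v;...>
#' <contig>\t<start>\t<end>\t<strand>\t<subs>      genomic segment
#' =\t<sequence>                                    literal segment
#' ```
#'
#' Coordinates are 0-based half-open (BED convention). `<subs>` is a
#' comma-separated list of `<offset><base>` substitutions whose offsets index
#' the *oriented* segment sequence (after reverse-complementing '-' strand
#' segments); offsets are strictly increasing. Empty tag and substitution
#' fields are written as empty strings, never omitted. Molecule ids contain no
#' whitespace or ';'; '_' is reserved as the lineage separator for ids that
#' modules derive from a parent (e.g. PCR copies `<parent>_p<k>`).
#'
#' @name mdf
NULL

#' Construct a genomic segment
#'
#' @param contig contig name.
#' @param start,end 0-based half-open interval, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @param sub_offset integer offsets of substitutions within the oriented
#'   segment sequence, strictly increasing.
#' @param sub_base replacement bases (one of A,C,G,T), parallel to
#'   `sub_offset`.
#' @return a list of class `"segment"`.
#' @export
genomic_segment <- function(contig, start, end, strand,
                            sub_offset = integer(0), sub_base = character(0)) {
  structure(list(kind = "genomic", contig = as.character(contig),
                 start = as.integer(start), end = as.integer(end),
                 strand = as.character(strand),
                 sub_offset = as.integer(sub_offset),
                 sub_base = as.character(sub_base)),
            class = "segment")
}

#' Construct a literal segment
#'
#' Literal segments carry an explicit sequence (adapters, barcodes, polyA
#' tails) and are written already-final: they admit no substitution list.
#'
#' @param sequence non-empty string over A,C,G,T,N.
#' @return a list of class `"segment"`.
#' @export
literal_segment <- function(sequence) {
  structure(list(kind = "literal", sequence = as.character(sequence)),
            class = "segment")
}

#' Construct a molecule
#'
#' @param id unique molecule id (no whitespace, no ';').
#' @param depth positive integer copy count; the sequencer emits `depth` reads
#'   for the molecule.
#' @param tags named character vector of key=value tags (insertion order is
#'   preserved on serialization).
#' @param segments non-empty list of [genomic_segment()] / [literal_segment()]
#'   objects, ordered 5'->3'.
#' @return a list of class `"molecule"`.
#' @export
new_molecule <- function(id, depth = 1L, tags = character(0), segments) {
  if (length(tags) == 0L) tags <- character(0)
  structure(list(id = as.character(id), depth = as.integer(depth),
                 tags = tags, segments = segments),
            class = "molecule")
}

segment_length <- function(seg) {
  if (seg$kind == "literal") nchar(seg$sequence) else seg$end - seg$start
}

#' Total length of a molecule in bases
#'
#' @param m a molecule.
#' @return sum of segment lengths (genomic `end - start`, literal `nchar`).
#' @export
molecule_length <- function(m) {
  sum(vapply(m$segments, segment_length, numeric(1)))
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule %s> depth=%d len=%d segments=%d tags=%s\n",
              x$id, x$depth, molecule_length(x), length(x$segments),
              if (length(x$tags)) paste0(names(x$tags), "=", x$tags, collapse = ";")
              else "-"))
  invisible(x)
}

validate_segment <- function(seg, where = "") {
  if (seg$kind == "literal") {
    if (!nzchar(seg$sequence))
      stop(where, "literal segment has empty sequence", call. = FALSE)
    if (grepl("[^ACGTN]", seg$sequence))
      stop(where, "literal segment has characters outside {A,C,G,T,N}", call. = FALSE)
    if (length(seg$sub_offset))
      stop(where, "literal segments admit no substitutions", call. = FALSE)
  } else if (seg$kind == "genomic") {
    if (is.na(seg$start) || is.na(seg$end) || seg$start < 0L || seg$start >= seg$end)
      stop(where, "genomic segment requires 0 <= start < end", call. = FALSE)
    if (!seg$strand %in% c("+", "-"))
      stop(where, "strand must be '+' or '-'", call. = FALSE)
    len <- seg$end - seg$start
    off <- seg$sub_offset
    if (length(off) != length(seg$sub_base))
      stop(where, "substitution offsets and bases differ in length", call. = FALSE)
    if (length(off)) {
      if (any(off < 0L) || any(off >= len))
        stop(where, "substitution offset out of segment range", call. = FALSE)
      if (any(diff(off) <= 0L))
        stop(where, "substitution offsets must be strictly increasing", call. = FALSE)
      if (!all(seg$sub_base %in% .BASES))
        stop(where, "substitution base must be one of A,C,G,T", call. = FALSE)
    }
  } else {
    stop(where, "unknown segment kind '", seg$kind, "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a molecule against the MDF invariants
#'
#' Checks id syntax, depth, tag syntax, every segment, and total length.
#'
#' @param m a molecule.
#' @return `TRUE` invisibly; stops with a diagnostic naming the molecule
#'   otherwise.
#' @export
validate_molecule <- function(m) {
  where <- sprintf("molecule '%s': ", m$id %||% "<no id>")
  if (!nzchar(m$id) || grepl("[[:space:];]", m$id))
    stop(where, "id must be non-empty without whitespace or ';'", call. = FALSE)
  if (is.na(m$depth) || m$depth < 1L)
    stop(where, "depth must be a positive integer", call. = FALSE)
  if (length(m$tags)) {
    keys <- names(m$tags)
    if (is.null(keys) || any(!nzchar(keys)))
      stop(where, "tags must be a named character vector", call. = FALSE)
    if (anyDuplicated(keys))
      stop(where, "tag keys must be unique", call. = FALSE)
    if (any(grepl("[=;\t]", keys)) || any(grepl("[=;\t]", m$tags)))
      stop(where, "tag keys/values must not contain '=', ';' or tab", call. = FALSE)
  }
  if (!length(m$segments))
    stop(where, "molecule must have at least one segment", call. = FALSE)
  for (i in seq_along(m$segments))
    validate_segment(m$segments[[i]], sprintf("%ssegment %d: ", where, i))
  if (molecule_length(m) < 1)
    stop(where, "molecule length must be >= 1", call. = FALSE)
  invisible(TRUE)
}

.parse_subs <- function(s, lineno) {
  if (!nzchar(s)) return(list(offset = integer(0), base = character(0)))
  toks <- strsplit(s, ",", fixed = TRUE)[[1]]
  ok <- grepl("^[0-9]+[ACGT]$", toks)
  if (!all(ok))
    stop(sprintf("line %d: malformed substitution token '%s'", lineno,
                 toks[!ok][1]), call. = FALSE)
  n <- nchar(toks)
  list(offset = as.integer(substr(toks, 1L, n - 1L)),
       base = substr(toks, n, n))
}

.parse_tags <- function(s, lineno) {
  if (!nzchar(s)) return(character(0))
  toks <- strsplit(s, ";", fixed = TRUE)[[1]]
  eq <- regexpr("=", toks, fixed = TRUE)
  if (any(eq < 1L))
    stop(sprintf("line %d: malformed tag token '%s'", lineno, toks[eq < 1L][1]),
         call. = FALSE)
  keys <- substr(toks, 1L, eq - 1L)
  vals <- substr(toks, eq + 1L, nchar(toks))
  stats::setNames(vals, keys)
}

#' Parse MDF text into molecules
#'
#' @param lines character vector of MDF lines (no trailing newlines).
#' @param line_offset added to reported line numbers in diagnostics (used by
#'   the chunked reader).
#' @param validate validate every parsed molecule (default `TRUE`).
#' @return list of molecules in file order.
#' @seealso [read_mdf()], [mdf_reader()] for file input, [write_mdf()].
#' @export
parse_mdf <- function(lines, line_offset = 0L, validate = TRUE) {
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  is_header <- startsWith(lines, "+")
  if (!is_header[1L])
    stop(sprintf("line %d: expected molecule header starting with '+'",
                 line_offset + 1L), call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header_at <- which(is_header)
  bounds <- c(header_at, length(lines) + 1L)
  out <- vector("list", length(header_at))
  for (k in seq_along(header_at)) {
    i <- header_at[k]
    lineno <- line_offset + i
    h <- fields[[i]]
    id <- substring(h[1L], 2L)
    if (length(h) < 2L || !nzchar(id))
      stop(sprintf("line %d: malformed header line", lineno), call. = FALSE)
    depth <- suppressWarnings(as.integer(h[2L]))
    if (is.na(depth) || depth < 1L)
      stop(sprintf("line %d: non-positive or non-integer depth '%s'", lineno,
                   h[2L]), call. = FALSE)
    tags <- .parse_tags(if (length(h) >= 3L) h[3L] else "", lineno)
    seg_idx <- if (bounds[k] + 1L <= bounds[k + 1L] - 1L)
      seq.int(bounds[k] + 1L, bounds[k + 1L] - 1L) else integer(0)
    if (!length(seg_idx))
      stop(sprintf("line %d: molecule '%s' has no segments", lineno, id),
           call. = FALSE)
    segs <- vector("list", length(seg_idx))
    for (j in seq_along(seg_idx)) {
      f <- fields[[seg_idx[j]]]
      sl <- line_offset + seg_idx[j]
      if (f[1L] == "=") {
        if (length(f) < 2L)
          stop(sprintf("line %d: literal segment without sequence", sl),
               call. = FALSE)
        segs[[j]] <- literal_segment(f[2L])
      } else if (length(f) >= 4L) {
        start <- suppressWarnings(as.integer(f[2L]))
        end <- suppressWarnings(as.integer(f[3L]))
        if (is.na(start) || is.na(end))
          stop(sprintf("line %d: non-integer genomic coordinates", sl),
               call. = FALSE)
        subs <- .parse_subs(if (length(f) >= 5L) f[5L] else "", sl)
        segs[[j]] <- genomic_segment(f[1L], start, end, f[4L],
                                     subs$offset, subs$base)
      } else {
        stop(sprintf("line %d: unknown segment kind or missing fields", sl),
             call. = FALSE)
      }
    }
    m <- new_molecule(id, depth, tags, segs)
    if (validate) {
      tryCatch(validate_molecule(m), error = function(e)
        stop(sprintf("line %d: %s", lineno, conditionMessage(e)), call. = FALSE))
    }
    out[[k]] <- m
  }
  out
}

#' Read an entire MDF file
#'
#' @param path file path, or `"-"` for standard input.
#' @param validate validate molecules while parsing.
#' @return list of molecules. Duplicate molecule ids raise a validation
#'   error.
#' @export
read_mdf <- function(path, validate = TRUE) {
  lines <- if (identical(path, "-")) readLines(file("stdin")) else readLines(path)
  mols <- parse_mdf(lines, validate = validate)
  ids <- vapply(mols, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate molecule id in MDF stream: '",
         ids[duplicated(ids)][1], "'", call. = FALSE)
  mols
}

#' Chunked MDF reader with bounded memory
#'
#' Opens an MDF file and yields molecules incrementally: each `$read(n)` call
#' parses at most `n` molecules, holding only the current chunk (plus one
#' partial record) in memory, so arbitrarily long streams can be traversed
#' under a fixed memory ceiling.
#'
#' @param path MDF file path.
#' @param chunk_lines lines fetched from disk per refill.
#' @return an environment with `read(n)` (returns up to `n` molecules, or an
#'   empty list at end of stream) and `close()`.
#' @export
mdf_reader <- function(path, chunk_lines = 4096L) {
  con <- file(path, open = "r")
  env <- new.env(parent = emptyenv())
  env$buf <- character(0)
  env$lineno <- 0L
  env$eof <- FALSE
  env$seen <- new.env(parent = emptyenv())
  env$con <- con

  refill <- function() {
    got <- readLines(con, n = chunk_lines)
    if (!length(got)) env$eof <- TRUE else env$buf <- c(env$buf, got)
    invisible(length(got))
  }

  env$read <- function(n = 1000L) {
    # ensure the buffer holds at least n+1 headers or the rest of the file
    repeat {
      headers <- which(startsWith(env$buf, "+"))
      if (length(headers) > n || env$eof) break
      if (refill() == 0L) break
    }
    headers <- which(startsWith(env$buf, "+"))
    if (!length(headers)) return(list())
    if (length(headers) > n) {
      cut <- headers[n + 1L] - 1L
    } else if (env$eof) {
      cut <- length(env$buf)
    } else {
      cut <- length(env$buf)  # unreachable in practice
    }
    take <- env$buf[seq_len(cut)]
    env$buf <- env$buf[-seq_len(cut)]
    off <- env$lineno
    env$lineno <- env$lineno + cut
    mols <- parse_mdf(take, line_offset = off)
    for (m in mols) {
      if (!is.null(env$seen[[m$id]]))
        stop("duplicate molecule id in MDF stream: '", m$id, "'", call. = FALSE)
      env$seen[[m$id]] <- TRUE
    }
    mols
  }
  env$close <- function() close(con)
  env
}

.format_segment <- function(seg) {
  if (seg$kind == "literal") {
    paste0("=\t", seg$sequence)
  } else {
    subs <- if (length(seg$sub_offset))
      paste0(seg$sub_offset, seg$sub_base, collapse = ",") else ""
    paste(seg$contig, seg$start, seg$end, seg$strand, subs, sep = "\t")
  }
}

#' Serialize molecules to MDF
#'
#' Canonical serialization: fixed field order, tab separators, tags in
#' insertion order, empty fields written as empty strings. The output
#' re-parses to an equal value ([parse_mdf()] is its inverse).
#'
#' @param molecules list of molecules (each must satisfy the invariants;
#'   violations refuse to serialize, naming the molecule).
#' @param path output file path, connection, or `NULL` to return the lines.
#' @return if `path` is `NULL`, the character vector of lines; otherwise the
#'   byte count written, invisibly.
#' @export
write_mdf <- function(molecules, path = NULL) {
  lines <- character(0)
  if (length(molecules)) {
    per_mol <- lapply(molecules, function(m) {
      validate_molecule(m)
      tag_str <- if (length(m$tags))
        paste0(names(m$tags), "=", m$tags, collapse = ";") else ""
      c(paste0("+", m$id, "\t", m$depth, "\t", tag_str),
        vapply(m$segments, .format_segment, character(1)))
    })
    lines <- unlist(per_mol, use.names = FALSE)
  }
  if (is.null(path)) return(lines)
  if (!length(lines)) {
    # still touch the file so downstream steps see an (empty) stream
    if (is.character(path)) file.create(path)
    return(invisible(0L))
  }
  invisible(write_lines_lf(lines, path))
}
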