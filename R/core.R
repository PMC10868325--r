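# Core MDF -> MDF modules. Each op is a pure function of (input stream,
# parameters, seed): per-molecule randomness comes from
# derive_seed(seed, op, molecule id), so stream chunking and module order
# never change outcomes, and the caller's RNG state is never touched.

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
            R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
            B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

set_tag <- function(m, key, value) {
  m$tags[key] <- as.character(value)
  m
}

#' Attach end tags / adapters (core module)
#'
#' Instantiates `pattern5` (each IUPAC ambiguity code drawn uniformly over
#' its allowed bases) and prepends it as a literal segment; `pattern3`
#' likewise appended. The instantiated sequences are recorded in tags `tag5`
#' / `tag3`. Empty patterns leave the stream unchanged.
#'
#' @param molecules list of molecules.
#' @param pattern5,pattern3 IUPAC pattern strings (may be `""`).
#' @param seed global seed.
#' @return list of molecules.
#' @export
tag_ends <- function(molecules, pattern5 = "", pattern3 = "", seed = 1L) {
  for (p in c(pattern5, pattern3)) {
    if (nzchar(p) && !all(strsplit(p, "")[[1]] %in% names(.IUPAC)))
      stop("invalid IUPAC character in pattern '", p, "'", call. = FALSE)
  }
  if (!nzchar(pattern5) && !nzchar(pattern3)) return(molecules)
  p5 <- if (nzchar(pattern5)) strsplit(pattern5, "")[[1]] else character(0)
  p3 <- if (nzchar(pattern3)) strsplit(pattern3, "")[[1]] else character(0)
  ambiguous <- any(nchar(.IUPAC[c(p5, p3)]) > 1L)
  instantiate <- function(chars) {
    paste(vapply(chars, function(ch) {
      opts <- strsplit(.IUPAC[[ch]], "")[[1]]
      if (length(opts) == 1L) opts else sample(opts, 1L)
    }, character(1)), collapse = "")
  }
  with_preserved_rng({
    lapply(molecules, function(m) {
      if (ambiguous) set.seed(derive_seed(seed, "tag", m$id))
      if (length(p5)) {
        s5 <- instantiate(p5)
        m$segments <- c(list(literal_segment(s5)), m$segments)
        m <- set_tag(m, "tag5", s5)
      }
      if (length(p3)) {
        s3 <- instantiate(p3)
        m$segments <- c(m$segments, list(literal_segment(s3)))
        m <- set_tag(m, "tag3", s3)
      }
      m
    })
  })
}

#' Append polyA tails (core module)
#'
#' Per molecule, a tail length `L` is drawn from round(Normal(mu, sigma)),
#' clamped to `max(min_len, 0)`, and `A x L` is appended as a literal 3'
#' segment with the draw recorded in tag `pA=<L>`. A zero-length draw
#' appends nothing and sets no tag (the molecule is unchanged).
#'
#' @param molecules list of molecules.
#' @param mu,sigma tail length mean / sd in bases (`mu >= 0`, `sigma >= 0`).
#' @param min_len minimum tail length.
#' @param seed global seed.
#' @return list of molecules.
#' @export
add_polya <- function(molecules, mu, sigma, min_len = 0L, seed = 1L) {
  stopifnot(mu >= 0, sigma >= 0, min_len >= 0)
  with_preserved_rng({
    lapply(molecules, function(m) {
      L <- if (sigma > 0) {
        set.seed(derive_seed(seed, "polya", m$id))
        as.integer(round(stats::rnorm(1, mu, sigma)))
      } else as.integer(round(mu))
      L <- max(L, as.integer(min_len), 0L)
      if (L == 0L) return(m)
      m$segments <- c(m$segments, list(literal_segment(strrep("A", L))))
      set_tag(m, "pA", L)
    })
  })
}

# Reverse-complement one molecule in molecule space.
flip_molecule <- function(m) {
  m$segments <- lapply(rev(m$segments), function(seg) {
    if (seg$kind == "literal") {
      seg$sequence <- revcomp(seg$sequence)
    } else {
      len <- seg$end - seg$start
      seg$strand <- if (seg$strand == "+") "-" else "+"
      if (length(seg$sub_offset)) {
        seg$sub_offset <- rev(len - 1L - seg$sub_offset)
        seg$sub_base <- rev(comp_base(seg$sub_base))
      }
    }
    seg
  })
  if (!is.null(m$tags) && "flipped" %in% names(m$tags)) {
    m$tags <- m$tags[names(m$tags) != "flipped"]
    if (!length(m$tags)) m$tags <- character(0)
  } else {
    m <- set_tag(m, "flipped", "1")
  }
  m
}

#' Flip molecule strands (core module)
#'
#' Each molecule is independently reverse-complemented with probability `p`:
#' segment order reversed, genomic strands toggled, literal segments
#' reverse-complemented, substitution offsets remapped to `len - 1 - offset`
#' with complemented bases, and a `flipped=1` tag toggled. Flipping twice is
#' the identity.
#'
#' @param molecules list of molecules.
#' @param p flip probability in `[0, 1]`.
#' @param seed global seed.
#' @return list of molecules.
#' @export
flip_strand <- function(molecules, p, seed = 1L) {
  stopifnot(p >= 0, p <= 1)
  if (p == 0) return(molecules)
  with_preserved_rng({
    lapply(molecules, function(m) {
      do_flip <- p >= 1
      if (!do_flip) {
        set.seed(derive_seed(seed, "flip", m$id))
        do_flip <- stats::runif(1) < p
      }
      if (do_flip) flip_molecule(m) else m
    })
  })
}

# Trim d bases from the 5' end of an oriented segment chain.
trim_segments_5 <- function(segments, d) {
  out <- list()
  for (seg in segments) {
    if (d <= 0L) { out <- c(out, list(seg)); next }
    len <- segment_length(seg)
    if (d >= len) { d <- d - len; next }
    if (seg$kind == "literal") {
      seg$sequence <- substring(seg$sequence, d + 1L)
    } else {
      if (seg$strand == "+") seg$start <- seg$start + d else seg$end <- seg$end - d
      keep <- seg$sub_offset >= d
      seg$sub_offset <- seg$sub_offset[keep] - d
      seg$sub_base <- seg$sub_base[keep]
    }
    d <- 0L
    out <- c(out, list(seg))
  }
  out
}

trim_segments_3 <- function(segments, d) {
  out <- list()
  for (seg in rev(segments)) {
    if (d <= 0L) { out <- c(list(seg), out); next }
    len <- segment_length(seg)
    if (d >= len) { d <- d - len; next }
    if (seg$kind == "literal") {
      seg$sequence <- substring(seg$sequence, 1L, len - d)
    } else {
      if (seg$strand == "+") seg$end <- seg$end - d else seg$start <- seg$start + d
      keep <- seg$sub_offset < len - d
      seg$sub_offset <- seg$sub_offset[keep]
      seg$sub_base <- seg$sub_base[keep]
    }
    d <- 0L
    out <- c(list(seg), out)
  }
  out
}

#' Truncate molecule ends (core module)
#'
#' Per molecule, a (5' trim, 3' trim) pair is drawn from the truncation
#' model and that many bases are removed from each end of the oriented
#' segment chain (segments are shrunk or dropped; substitutions falling in
#' removed bases are discarded, remaining offsets remapped). A molecule whose
#' trims meet or exceed its length is dropped from the stream. Nonzero draws
#' are recorded in tags `trunc5` / `trunc3`; a (0,0) draw leaves the molecule
#' unchanged.
#'
#' @param molecules list of molecules.
#' @param model a [truncation_model] object.
#' @param seed global seed.
#' @return list of surviving molecules (`length(out) <= length(molecules)`).
#' @export
truncate_ends <- function(molecules, model, seed = 1L) {
  stopifnot(inherits(model, "truncation_model"))
  with_preserved_rng({
    out <- lapply(molecules, function(m) {
      set.seed(derive_seed(seed, "truncate", m$id))
      d <- sample_truncation(model, 1L)
      d5 <- d[1, "d5"]; d3 <- d[1, "d3"]
      if (d5 == 0L && d3 == 0L) return(m)
      if (d5 + d3 >= molecule_length(m)) return(NULL)
      segs <- trim_segments_5(m$segments, d5)
      segs <- trim_segments_3(segs, d3)
      m$segments <- segs
      if (d5 > 0L) m <- set_tag(m, "trunc5", d5)
      if (d3 > 0L) m <- set_tag(m, "trunc3", d3)
      m
    })
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Parse a filter predicate expression
#'
#' Grammar: `tag:<key>` (tag present), `tag:<key>=<value>` (tag equals;
#' molecules lacking the key fail), `len:<min>-<max>` (either bound may be
#' omitted, e.g. `len:200-`), `rand:<p>` (seeded Bernoulli, a pure function
#' of (seed, molecule id)), `locus:<contig>[:<start>-<end>]` (any genomic
#' segment on the contig / overlapping the interval).
#'
#' @param expr predicate string.
#' @param seed seed for `rand:` predicates.
#' @return a function `molecule -> logical`.
#' @export
parse_predicate <- function(expr, seed = 1L) {
  if (grepl("^tag:", expr)) {
    body <- sub("^tag:", "", expr)
    if (grepl("=", body, fixed = TRUE)) {
      kv <- strsplit(body, "=", fixed = TRUE)[[1]]
      key <- kv[1]; val <- paste(kv[-1], collapse = "=")
      function(m) !is.na(m$tags[key]) && identical(unname(m$tags[key]), val)
    } else {
      function(m) body %in% names(m$tags)
    }
  } else if (grepl("^len:", expr)) {
    body <- sub("^len:", "", expr)
    parts <- strsplit(body, "-", fixed = TRUE)[[1]]
    lo <- if (nzchar(parts[1])) as.numeric(parts[1]) else 0
    hi <- if (length(parts) >= 2 && nzchar(parts[2])) as.numeric(parts[2]) else Inf
    function(m) { L <- molecule_length(m); L >= lo && L <= hi }
  } else if (grepl("^rand:", expr)) {
    p <- as.numeric(sub("^rand:", "", expr))
    if (is.na(p) || p < 0 || p > 1) stop("rand predicate needs p in [0,1]", call. = FALSE)
    function(m) {
      with_preserved_rng({
        set.seed(derive_seed(seed, "filter-rand", m$id))
        stats::runif(1) < p
      })
    }
  } else if (grepl("^locus:", expr)) {
    parts <- strsplit(sub("^locus:", "", expr), ":", fixed = TRUE)[[1]]
    contig <- parts[1]
    rng <- if (length(parts) >= 2) as.numeric(strsplit(parts[2], "-")[[1]]) else NULL
    function(m) {
      any(vapply(m$segments, function(seg) {
        if (seg$kind != "genomic" || seg$contig != contig) return(FALSE)
        if (is.null(rng)) return(TRUE)
        seg$start < rng[2] && seg$end > rng[1]
      }, logical(1)))
    }
  } else {
    stop("unknown predicate expression '", expr, "'", call. = FALSE)
  }
}

#' Partition a stream by a predicate (core module)
#'
#' Every input molecule appears unmodified in exactly one output, order
#' preserved.
#'
#' @param molecules list of molecules.
#' @param predicate a function `molecule -> logical` or a
#'   [parse_predicate()] expression string.
#' @param seed seed forwarded to `rand:` predicates given as strings.
#' @return list with `pass` and `fail` molecule lists.
#' @export
filter_molecules <- function(molecules, predicate, seed = 1L) {
  if (is.character(predicate)) predicate <- parse_predicate(predicate, seed)
  keep <- vapply(molecules, function(m) isTRUE(predicate(m)), logical(1))
  list(pass = molecules[keep], fail = molecules[!keep])
}

#' Merge streams (core module)
#'
#' Concatenates streams in argument order. If molecule ids collide across
#' sources, every id is prefixed `S<k>_` by source index; total molecule
#' count and total depth are conserved.
#'
#' @param ... molecule lists.
#' @return a single molecule list.
#' @export
merge_streams <- function(...) {
  streams <- list(...)
  if (!length(streams)) stop("merge requires >= 1 input stream", call. = FALSE)
  ids <- unlist(lapply(streams, function(s) vapply(s, `[[`, character(1), "id")),
                use.names = FALSE)
  if (anyDuplicated(ids)) {
    streams <- lapply(seq_along(streams), function(k)
      lapply(streams[[k]], function(m) { m$id <- paste0("S", k, "_", m$id); m }))
  }
  do.call(c, streams)
}

#' Attach single-cell barcodes and UMIs (core module)
#'
#' Molecules carrying a `CB=<cell_id>` tag are prepended (5'->3') with:
#' literal adapter, the whitelist barcode assigned to their cell, and a
#' fresh random UMI of `umi_len` bases (10x 3' kit orientation:
#' adapter-barcode-UMI-cDNA). The cell-to-barcode assignment is a stable
#' map: distinct `cell_id` values, in order of first appearance, take
#' successive entries of a seeded shuffle of the whitelist. Tags `cb_seq`
#' and `umi` record the attached sequences. Molecules without a CB tag pass
#' through unchanged.
#'
#' @param molecules list of molecules.
#' @param whitelist character vector of barcodes (non-empty).
#' @param umi_len UMI length in bases.
#' @param adapter literal adapter sequence (may be `""`).
#' @param seed global seed.
#' @return list of molecules.
#' @export
barcode_cells <- function(molecules, whitelist, umi_len = 12L, adapter = "",
                          seed = 1L) {
  if (!length(whitelist)) stop("whitelist must be non-empty", call. = FALSE)
  cb <- vapply(molecules, function(m) {
    v <- m$tags["CB"]
    if (is.na(v)) NA_character_ else unname(v)
  }, character(1))
  cells <- unique(cb[!is.na(cb)])
  if (!length(cells)) return(molecules)
  if (length(cells) > length(whitelist))
    stop(sprintf("%d distinct cell ids exceed whitelist size %d",
                 length(cells), length(whitelist)), call. = FALSE)
  with_preserved_rng({
    set.seed(derive_seed(seed, "scb-whitelist"))
    shuffled <- sample(whitelist)
    bc_of <- stats::setNames(shuffled[seq_along(cells)], cells)
    lapply(seq_along(molecules), function(i) {
      m <- molecules[[i]]
      if (is.na(cb[i])) return(m)
      set.seed(derive_seed(seed, "scb-umi", m$id))
      umi <- random_dna(1L, umi_len)
      bc <- bc_of[[cb[i]]]
      pre <- list()
      if (nzchar(adapter)) pre <- c(pre, list(literal_segment(adapter)))
      pre <- c(pre, list(literal_segment(bc), literal_segment(umi)))
      m$segments <- c(pre, m$segments)
      m <- set_tag(m, "cb_seq", bc)
      set_tag(m, "umi", umi)
    })
  })
}
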