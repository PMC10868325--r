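#' Expected copy count after PCR
#'
#' Closed form `n0 * (1 + efficiency)^cycles`: in each cycle every existing
#' copy duplicates independently with probability `efficiency`.
#'
#' @param n0 starting copy count.
#' @param cycles number of cycles.
#' @param efficiency per-cycle duplication probability.
#' @return expected total copies (real).
#' @export
expected_copies <- function(n0, cycles, efficiency) {
  stopifnot(cycles >= 0, efficiency >= 0, efficiency <= 1)
  n0 * (1 + efficiency)^cycles
}

# Map molecule-space substitution offsets into the segment chain, returning
# updated segments. A new substitution at an offset already substituted
# overrides the previous one; edits into literal segments rewrite the
# sequence directly (literal segments are written already-final).
apply_molecule_substitutions <- function(segments, offsets, bases) {
  if (!length(offsets)) return(segments)
  lens <- vapply(segments, segment_length, numeric(1))
  bounds <- cumsum(lens)
  starts <- c(0, bounds[-length(bounds)])
  seg_of <- findInterval(offsets, starts)
  for (k in seq_along(offsets)) {
    si <- seg_of[k]
    seg <- segments[[si]]
    local_off <- as.integer(offsets[k] - starts[si])
    if (seg$kind == "literal") {
      substr(seg$sequence, local_off + 1L, local_off + 1L) <- bases[k]
    } else {
      hit <- match(local_off, seg$sub_offset)
      if (!is.na(hit)) {
        seg$sub_base[hit] <- bases[k]
      } else {
        ord <- order(c(seg$sub_offset, local_off))
        seg$sub_offset <- c(seg$sub_offset, local_off)[ord]
        seg$sub_base <- c(seg$sub_base, bases[k])[ord]
      }
    }
    segments[[si]] <- seg
  }
  segments
}

#' Simulate PCR amplification (core module)
#'
#' Simulates a per-molecule lineage: in each cycle every existing copy
#' duplicates with probability `efficiency`; each new copy draws
#' `Binomial(length, error_rate)` substitution positions, each set to a base
#' drawn uniformly among the three bases differing from the copy's current
#' base there, and passes all its edits to its own descendants. Copies with
#' identical edit sets aggregate into one MDF record by depth; the error-free
#' lineage keeps the template's record, errored lineages become new records
#' with ids `<parent>_p<k>`. Expected total copies are
#' [expected_copies()]`(sum depth, cycles, efficiency)`.
#'
#' @param molecules list of molecules.
#' @param cycles number of PCR cycles (>= 0; 0 is the identity).
#' @param efficiency per-cycle duplication probability in `[0, 1]`.
#' @param error_rate per-base substitution probability per new copy
#'   (`0 <= error_rate < 1`).
#' @param seed global seed.
#' @param reference a [load_reference()] object; required when
#'   `error_rate > 0` (substituted bases must differ from the current base).
#' @param target_count optional final subsample size: final copies are
#'   subsampled uniformly (adjusting depths) to exactly this count.
#' @param copy_ceiling per-molecule cap on total copies; exceeding it is an
#'   error suggesting `target_count`.
#' @return list of molecules.
#' @export
pcr_amplify <- function(molecules, cycles, efficiency, error_rate = 0,
                        seed = 1L, reference = NULL, target_count = NULL,
                        copy_ceiling = 1e6) {
  stopifnot(cycles >= 0, efficiency >= 0, efficiency <= 1,
            error_rate >= 0, error_rate < 1)
  if (cycles == 0) return(molecules)
  if (error_rate > 0 && is.null(reference))
    stop("error_rate > 0 requires a reference to draw differing bases",
         call. = FALSE)

  out <- vector("list", length(molecules))
  with_preserved_rng({
    for (mi in seq_along(molecules)) {
      m <- molecules[[mi]]
      base_seq <- if (error_rate > 0) realize(m, reference) else NULL
      len <- molecule_length(m)
      set.seed(derive_seed(seed, "pcr", m$id))
      # variants: edit maps over molecule space; variant 1 = the template
      v_off <- list(integer(0))
      v_base <- list(character(0))
      v_count <- m$depth
      for (cyc in seq_len(cycles)) {
        n_before <- length(v_count)
        for (vi in seq_len(n_before)) {
          ndup <- stats::rbinom(1L, v_count[vi], efficiency)
          if (ndup == 0L) next
          if (error_rate == 0) {
            v_count[vi] <- v_count[vi] + ndup
            next
          }
          nerr <- stats::rbinom(ndup, len, error_rate)
          clean <- sum(nerr == 0L)
          v_count[vi] <- v_count[vi] + clean
          for (k in which(nerr > 0L)) {
            pos <- sort(sample.int(len, nerr[k]))  # 1-based molecule space
            cur <- vapply(pos, function(p) {
              hit <- match(p - 1L, v_off[[vi]])
              if (!is.na(hit)) v_base[[vi]][hit] else substr(base_seq, p, p)
            }, character(1))
            newb <- vapply(cur, function(b)
              sample(setdiff(.BASES, b), 1L), character(1), USE.NAMES = FALSE)
            off <- v_off[[vi]]; bs <- v_base[[vi]]
            for (j in seq_along(pos)) {
              hit <- match(pos[j] - 1L, off)
              if (!is.na(hit)) bs[hit] <- newb[j]
              else { off <- c(off, pos[j] - 1L); bs <- c(bs, newb[j]) }
            }
            ord <- order(off)
            v_off <- c(v_off, list(off[ord]))
            v_base <- c(v_base, list(bs[ord]))
            v_count <- c(v_count, 1L)
          }
        }
        if (sum(v_count) > copy_ceiling)
          stop(sprintf("molecule '%s' exceeded the copy ceiling (%g); set target_count",
                       m$id, copy_ceiling), call. = FALSE)
      }
      recs <- vector("list", length(v_count))
      child <- 0L
      for (vi in seq_along(v_count)) {
        if (v_count[vi] == 0L) next
        if (vi == 1L) {
          mm <- m
          mm$depth <- as.integer(v_count[1L])
        } else {
          child <- child + 1L
          mm <- m
          mm$id <- paste0(m$id, "_p", child)
          mm$depth <- as.integer(v_count[vi])
          mm$segments <- apply_molecule_substitutions(m$segments, v_off[[vi]],
                                                      v_base[[vi]])
        }
        recs[[vi]] <- mm
      }
      out[[mi]] <- recs[!vapply(recs, is.null, logical(1))]
    }
    result <- unlist(out, recursive = FALSE)
    if (!is.null(target_count)) {
      depths <- vapply(result, `[[`, integer(1), "depth")
      total <- sum(depths)
      if (target_count > total)
        stop(sprintf("target_count %d exceeds total copies %d", target_count,
                     total), call. = FALSE)
      set.seed(derive_seed(seed, "pcr-subsample"))
      new_depths <- subsample_counts(depths, as.integer(target_count))
      keep <- new_depths > 0L
      result <- lapply(which(keep), function(i) {
        m <- result[[i]]; m$depth <- new_depths[i]; m
      })
    }
  })
  result
}

# Uniform subsample without replacement from a multiset given by counts:
# sequential multivariate hypergeometric.
subsample_counts <- function(counts, k) {
  remaining <- sum(counts)
  out <- integer(length(counts))
  for (i in seq_along(counts)) {
    if (k == 0L) break
    take <- stats::rhyper(1L, counts[i], remaining - counts[i], k)
    out[i] <- take
    k <- k - take
    remaining <- remaining - counts[i]
  }
  out
}
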