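#' Packaged pipeline presets
#'
#' Three example pipelines ship with the package, mirroring common
#' transcriptomic long-read protocols, each paired with a synthetic fixture
#' set from [make_fixtures()]:
#'
#' * `bulk` — linear bulk RNA-seq: transcribe, truncate (empirical grid),
#'   polyA, 5' adapter, sequence.
#' * `singlecell` — hybrid short-long single-cell protocol: a per-cell
#'   branch and an ambient (untagged) branch are pooled; molecules carrying
#'   a CB tag are split off, get the Illumina read-1 adapter, a 10x-style
#'   cell barcode and a UMI, and are merged back before sequencing.
#' * `fusion` — bulk RNA-seq with 100 random gene-fusion transcripts added
#'   to the profile, PCR amplification, and a truth table of fusion
#'   junctions. This preset deliberately omits truncation and strand
#'   flipping so every fusion read's error-free realization provably
#'   contains its junction 40-mer.
#'
#' @param name `"bulk"`, `"singlecell"` or `"fusion"`.
#' @return path to the installed YAML config.
#' @export
preset_config <- function(name = c("bulk", "singlecell", "fusion")) {
  name <- match.arg(name)
  p <- system.file("configs", paste0(name, ".yaml"), package = "lrtsim")
  if (!nzchar(p)) stop("preset config not found: ", name, call. = FALSE)
  p
}

# Empirical-looking 3'-biased truncation grid used by the bulk preset:
# little 5' loss, geometric-ish 3' loss up to ~100 bases.
.preset_trunc_model <- function() {
  p5 <- c(0.7, 0.2, 0.1)                # d5 bins 0..2 (0-29 bases)
  p3 <- 0.6 * 0.6^(0:9)
  p3 <- p3 / sum(p3)                    # d3 bins 0..9 (0-99 bases)
  grid <- expand.grid(bin5 = 0:2, bin3 = 0:9)
  grid$prob <- p5[grid$bin5 + 1] * p3[grid$bin3 + 1]
  truncation_model_grid(grid, 10L)
}

#' Generate the fixture inputs a packaged preset expects
#'
#' Writes, deterministically for a given seed, the synthetic reference,
#' annotation, expression profile(s), and (per preset) truncation model or
#' barcode whitelist into `outdir`, using the file names the preset config
#' references.
#'
#' @param preset `"bulk"`, `"singlecell"` or `"fusion"`.
#' @param seed fixture seed.
#' @param outdir output directory (becomes the pipeline workdir).
#' @return list with the generated file paths and the [fixture_spec()] used.
#' @export
make_fixtures <- function(preset = c("bulk", "singlecell", "fusion"),
                          seed = 1L, outdir) {
  preset <- match.arg(preset)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  spec <- switch(preset,
    bulk = fixture_spec(seed = seed, n_contigs = 2L, n_genes = 60L,
                        second_isoform_prob = 0.3),
    singlecell = fixture_spec(seed = seed, n_contigs = 2L, n_genes = 60L,
                              n_cells = 4L, whitelist_size = 48L),
    fusion = fixture_spec(seed = seed, n_contigs = 4L, n_genes = 420L))
  ref <- make_reference(spec, outdir)
  files <- list(fasta = ref$fasta, gtf = ref$gtf, spec = spec)
  tids <- names(ref$transcripts)
  if (preset == "singlecell") {
    files$abundance_cells <- file.path(outdir, "abundance_cells.tsv")
    make_abundance(spec, tids, files$abundance_cells)
    ambient_spec <- spec
    ambient_spec$n_cells <- 0L
    ambient_spec$seed <- derive_seed(seed, "ambient")
    files$abundance_ambient <- file.path(outdir, "abundance_ambient.tsv")
    make_abundance(ambient_spec, tids, files$abundance_ambient)
    files$whitelist <- file.path(outdir, "whitelist.txt")
    make_whitelist(spec, files$whitelist)
  } else {
    files$abundance <- file.path(outdir, "abundance.tsv")
    make_abundance(spec, tids, files$abundance)
  }
  if (preset == "bulk") {
    files$trunc_model <- file.path(outdir, "truncation_model.tsv")
    write_truncation_model(.preset_trunc_model(), files$trunc_model)
  }
  files
}
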