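# Configuration-driven pipeline runner. A pipeline is a YAML document listing
# named steps (module + params + MDF input references); the runner validates
# the step graph, derives one seed per step from the global seed, and
# executes steps in topological order. Every step materializes its outputs
# as files in the workdir, so the in-process mode (direct function calls)
# and the subprocess mode (one CLI invocation per step) produce identical
# bytes by construction.

.MODULES <- list(
  transcribe = list(type = "entry",
                    required = c("abundance", "gtf", "molecule_count"),
                    optional = c("patch", "id_prefix")),
  fusion = list(type = "util",
                required = c("gtf", "abundance", "reference", "events"),
                optional = c("expression_fraction")),
  tag = list(type = "core", required = character(0),
             optional = c("pattern5", "pattern3")),
  polya = list(type = "core", required = c("mu", "sigma"),
               optional = c("min_len")),
  flip = list(type = "core", required = c("probability"), optional = character(0)),
  truncate = list(type = "core", required = c("model"), optional = character(0)),
  filter = list(type = "filter", required = c("predicate"), optional = character(0)),
  merge = list(type = "merge", required = character(0), optional = character(0)),
  barcode = list(type = "core", required = c("whitelist"),
                 optional = c("umi_len", "adapter")),
  pcr = list(type = "core", required = c("cycles", "efficiency"),
             optional = c("error_rate", "reference", "target_count")),
  sequence = list(type = "exit", required = c("reference"),
                  optional = c("sub_rate", "ins_rate", "del_rate",
                               "max_indel_len", "p_geo", "q_match", "q_error",
                               "format", "truth_in_header"))
)

# MDF output references a step offers to downstream steps.
.step_outputs_mdf <- function(step) {
  switch(.MODULES[[step$module]]$type,
         entry = step$name,
         core = step$name,
         merge = step$name,
         filter = paste0(step$name, c(".pass", ".fail")),
         character(0))
}

#' Validate and normalize a pipeline configuration
#'
#' Checks that step names are unique, modules are known, parameters are
#' recognized and required ones present, every MDF input reference resolves
#' to a producing step of the right kind (exit and utility steps offer no
#' MDF stream), and the step graph (MDF inputs plus `after:` file
#' dependencies) is acyclic. All violations are collected and reported
#' together; validation is all-or-nothing.
#'
#' @param config a config file path (YAML) or an already-parsed list with a
#'   `steps` entry.
#' @return the normalized spec: list with `steps` (each with `name`,
#'   `module`, `params`, `input` (character vector of references), `after`)
#'   in topological order, and `seed` (may be `NULL` until run time).
#' @export
pipeline_validate <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- character(0)
  steps <- config$steps
  if (is.null(steps) || !length(steps)) {
    stop("pipeline config has no steps", call. = FALSE)
  }
  names_ <- vapply(steps, function(s) s$name %||% "", character(1))
  if (any(!nzchar(names_)))
    errs <- c(errs, "every step needs a name")
  if (anyDuplicated(names_))
    errs <- c(errs, paste0("duplicate step name '",
                           names_[duplicated(names_)][1], "'"))
  mdf_refs <- character(0)
  for (s in steps) {
    if (is.null(s$module) || !s$module %in% names(.MODULES)) {
      errs <- c(errs, sprintf("step '%s': unknown module '%s'",
                              s$name, s$module %||% "<none>"))
      next
    }
    mdf_refs <- c(mdf_refs, .step_outputs_mdf(s))
  }
  norm <- vector("list", length(steps))
  for (i in seq_along(steps)) {
    s <- steps[[i]]
    if (is.null(s$module) || !s$module %in% names(.MODULES)) next
    mod <- .MODULES[[s$module]]
    pnames <- names(s$params %||% list())
    unknown <- setdiff(pnames, c(mod$required, mod$optional))
    if (length(unknown))
      errs <- c(errs, sprintf("step '%s': unknown parameter(s) %s", s$name,
                              paste0("'", unknown, "'", collapse = ", ")))
    missing <- setdiff(mod$required, pnames)
    if (length(missing))
      errs <- c(errs, sprintf("step '%s': missing required parameter(s) %s",
                              s$name, paste0("'", missing, "'", collapse = ", ")))
    input <- as.character(s$input %||% character(0))
    if (mod$type %in% c("entry", "util")) {
      if (length(input))
        errs <- c(errs, sprintf("step '%s': %s steps take no MDF input",
                                s$name, mod$type))
    } else if (mod$type == "merge") {
      if (length(input) < 1L)
        errs <- c(errs, sprintf("step '%s': merge needs >= 1 input", s$name))
    } else {
      if (length(input) != 1L)
        errs <- c(errs, sprintf("step '%s': needs exactly one MDF input", s$name))
    }
    for (ref in input) {
      if (!ref %in% mdf_refs) {
        producer <- sub("\\.(pass|fail)$", "", ref)
        if (producer %in% names_) {
          errs <- c(errs, sprintf(
            "step '%s': input '%s' does not provide an MDF stream (exit/utility steps cannot feed core modules; filter outputs are referenced as '<name>.pass'/'<name>.fail')",
            s$name, ref))
        } else {
          errs <- c(errs, sprintf("step '%s': input references missing step '%s'",
                                  s$name, ref))
        }
      }
    }
    norm[[i]] <- list(name = s$name, module = s$module,
                      params = s$params %||% list(), input = input,
                      after = as.character(s$after %||% character(0)),
                      outputs = s$outputs %||% list())
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)

  # topological order over MDF + after dependencies
  producer_of <- list()
  for (s in norm) for (ref in .step_outputs_mdf(s)) producer_of[[ref]] <- s$name
  deps <- lapply(norm, function(s) {
    unique(c(unlist(lapply(s$input, function(r) producer_of[[r]])), s$after))
  })
  names(deps) <- names_
  order_ <- character(0)
  remaining <- names_
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(n)
      all(deps[[n]] %in% order_), logical(1))]
    if (!length(ready))
      stop("pipeline step graph has a cycle involving: ",
           paste(remaining, collapse = ", "), call. = FALSE)
    order_ <- c(order_, ready[1])  # stable: keep listed order among ready steps
    remaining <- setdiff(remaining, ready[1])
  }
  norm <- norm[match(order_, names_)]
  list(steps = norm, seed = config$seed %||% NULL)
}

.resolve <- function(path, workdir) {
  if (grepl("^/", path)) path else file.path(workdir, path)
}

# Default output file names per step, overridable via the step's `outputs:`.
.step_files <- function(step, workdir) {
  o <- step$outputs
  f <- switch(.MODULES[[step$module]]$type,
    filter = list(pass = o$pass %||% paste0(step$name, ".pass.mdf"),
                  fail = o$fail %||% paste0(step$name, ".fail.mdf")),
    exit = list(fastq = o$fastq %||% paste0(step$name, ".fastq"),
                truth = o$truth %||% paste0(step$name, "_truth.tsv")),
    util = list(patch = o$patch %||% paste0(step$name, "_transcripts.mdf"),
                abundance = o$abundance %||% paste0(step$name, "_abundance.tsv"),
                truth = o$truth %||% paste0(step$name, "_truth.tsv")),
    list(mdf = o$mdf %||% paste0(step$name, ".mdf")))
  lapply(f, .resolve, workdir = workdir)
}

.ref_file <- function(ref, steps, workdir) {
  producer <- sub("\\.(pass|fail)$", "", ref)
  s <- steps[[which(vapply(steps, `[[`, character(1), "name") == producer)]]
  files <- .step_files(s, workdir)
  if (grepl("\\.pass$", ref)) files$pass
  else if (grepl("\\.fail$", ref)) files$fail
  else files$mdf
}

# Annotation patch: fusion (or other synthetic) transcripts serialized as MDF
# molecules whose segment chains are the transcript structures.
apply_annotation_patch <- function(annotation, patch_path) {
  for (m in read_mdf(patch_path)) {
    gid <- unname(m$tags["gene_id"])
    annotation[[m$id]] <- structure(
      list(transcript_id = m$id,
           gene_id = if (is.na(gid)) paste0("PG_", m$id) else gid,
           contig = NA_character_, strand = "+", exons = NULL,
           segments = m$segments),
      class = "transcript_model")
  }
  annotation
}

#' Execute a single normalized pipeline step
#'
#' Reads the step's MDF/file inputs from `workdir`, runs the module, and
#' writes the step's output files. Used by both execution modes of
#' [pipeline_run()] and by the command-line `step` subcommand.
#'
#' @param step a normalized step (see [pipeline_validate()]).
#' @param all_steps the full normalized step list (to resolve input files).
#' @param workdir working directory holding inputs and outputs.
#' @param step_seed integer seed for this step.
#' @return list with `n_in`, `n_out` and named output files.
#' @export
pipeline_run_step <- function(step, all_steps, workdir, step_seed) {
  p <- step$params
  files <- .step_files(step, workdir)
  in_files <- vapply(step$input, .ref_file, character(1),
                     steps = all_steps, workdir = workdir)
  rp <- function(key) .resolve(p[[key]], workdir)
  n_in <- NA_integer_
  mols_in <- NULL
  if (length(in_files) && step$module != "merge") {
    mols_in <- read_mdf(in_files[[1]])
    n_in <- length(mols_in)
  }
  out <- switch(step$module,
    transcribe = {
      ab <- load_abundance(rp("abundance"))
      ann <- load_annotation(rp("gtf"))
      if (!is.null(p$patch)) ann <- apply_annotation_patch(ann, rp("patch"))
      mols <- transcribe(ab, ann, as.integer(p$molecule_count),
                         seed = step_seed,
                         id_prefix = p$id_prefix %||% "M")
      n_in <- 0L
      write_mdf(mols, files$mdf)
      list(n_out = length(mols))
    },
    fusion = {
      ann <- load_annotation(rp("gtf"))
      ab <- load_abundance(rp("abundance"))
      ref <- load_reference(rp("reference"))
      res <- generate_fusions(ann, ab, as.integer(p$events), seed = step_seed,
                              reference = ref,
                              expression_fraction =
                                as.numeric(p$expression_fraction %||% 1.0))
      patch_mols <- lapply(res$events$event_id, function(fid)
        new_molecule(fid, 1L, c(gene_id = res$annotation[[fid]]$gene_id),
                     res$annotation[[fid]]$segments))
      write_mdf(patch_mols, files$patch)
      write_abundance(res$abundance, files$abundance)
      utils::write.table(res$events, files$truth, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      n_in <- 0L
      list(n_out = nrow(res$events))
    },
    tag = {
      mols <- tag_ends(mols_in, p$pattern5 %||% "", p$pattern3 %||% "",
                       seed = step_seed)
      write_mdf(mols, files$mdf)
      list(n_out = length(mols))
    },
    polya = {
      mols <- add_polya(mols_in, as.numeric(p$mu), as.numeric(p$sigma),
                        as.integer(p$min_len %||% 0L), seed = step_seed)
      write_mdf(mols, files$mdf)
      list(n_out = length(mols))
    },
    flip = {
      mols <- flip_strand(mols_in, as.numeric(p$probability), seed = step_seed)
      write_mdf(mols, files$mdf)
      list(n_out = length(mols))
    },
    truncate = {
      model <- read_truncation_model(rp("model"))
      mols <- truncate_ends(mols_in, model, seed = step_seed)
      write_mdf(mols, files$mdf)
      list(n_out = length(mols))
    },
    filter = {
      res <- filter_molecules(mols_in, as.character(p$predicate),
                              seed = step_seed)
      write_mdf(res$pass, files$pass)
      write_mdf(res$fail, files$fail)
      list(n_out = length(res$pass) + length(res$fail))
    },
    merge = {
      streams <- lapply(in_files, read_mdf)
      n_in <- sum(lengths(streams))
      mols <- do.call(merge_streams, streams)
      write_mdf(mols, files$mdf)
      list(n_out = length(mols))
    },
    barcode = {
      wl <- readLines(rp("whitelist"))
      wl <- wl[nzchar(wl)]
      mols <- barcode_cells(mols_in, wl, as.integer(p$umi_len %||% 12L),
                            p$adapter %||% "", seed = step_seed)
      write_mdf(mols, files$mdf)
      list(n_out = length(mols))
    },
    pcr = {
      ref <- if (!is.null(p$reference)) load_reference(rp("reference")) else NULL
      mols <- pcr_amplify(mols_in, as.integer(p$cycles),
                          as.numeric(p$efficiency),
                          as.numeric(p$error_rate %||% 0),
                          seed = step_seed, reference = ref,
                          target_count =
                            if (!is.null(p$target_count)) as.integer(p$target_count) else NULL)
      write_mdf(mols, files$mdf)
      list(n_out = length(mols))
    },
    sequence = {
      ref <- load_reference(rp("reference"))
      model <- error_model(
        sub_rate = as.numeric(p$sub_rate %||% 0.03),
        ins_rate = as.numeric(p$ins_rate %||% 0.02),
        del_rate = as.numeric(p$del_rate %||% 0.02),
        max_indel_len = as.integer(p$max_indel_len %||% 6L),
        p_geo = as.numeric(p$p_geo %||% 0.5),
        q_match = as.integer(p$q_match %||% 20L),
        q_error = as.integer(p$q_error %||% 7L))
      res <- sequence_reads(mols_in, ref, model, seed = step_seed,
                            fastq = files$fastq, truth = files$truth,
                            format = p$format %||% "fastq",
                            truth_in_header = isTRUE(p$truth_in_header))
      list(n_out = res$n_reads)
    },
    stop("unhandled module '", step$module, "'", call. = FALSE))
  c(list(n_in = n_in, files = files), out)
}

#' Run a pipeline
#'
#' Validates the configuration, derives one seed per step
#' (`derive_seed(global_seed, step_name)`, so inserting a step never
#' perturbs unrelated steps' randomness), executes steps in topological
#' order, and writes a JSON-lines manifest (`manifest.jsonl` in `workdir`)
#' recording per step its module, parameters, seed, molecule counts and
#' output-file MD5 checksums. Reruns with the same config and seed produce
#' byte-identical outputs, in either execution mode.
#'
#' @param config config file path or parsed list (see [pipeline_validate()]).
#' @param workdir directory holding input files; outputs are written here.
#' @param seed global seed (overrides the config's `seed`; one of the two
#'   must be set).
#' @param mode `"inprocess"` (direct function calls) or `"subprocess"` (one
#'   CLI process per step).
#' @return the manifest, invisibly: list of per-step records.
#' @export
pipeline_run <- function(config, workdir, seed = NULL,
                         mode = c("inprocess", "subprocess")) {
  mode <- match.arg(mode)
  spec <- pipeline_validate(config)
  seed <- seed %||% spec$seed
  if (is.null(seed)) stop("no seed: set it in the config or pass seed=",
                          call. = FALSE)
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- vector("list", length(spec$steps))
  for (i in seq_along(spec$steps)) {
    step <- spec$steps[[i]]
    step_seed <- derive_seed(seed, step$name)
    if (mode == "inprocess") {
      res <- tryCatch(
        pipeline_run_step(step, spec$steps, workdir, step_seed),
        error = function(e)
          stop(sprintf("pipeline step '%s' failed: %s", step$name,
                       conditionMessage(e)), call. = FALSE))
    } else {
      res <- .run_step_subprocess(step, spec$steps, workdir, step_seed)
    }
    files <- res$files
    sums <- vapply(files, function(f)
      if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_,
      character(1))
    manifest[[i]] <- list(step = step$name, module = step$module,
                          seed = step_seed, params = step$params,
                          n_in = res$n_in, n_out = res$n_out,
                          outputs = as.list(stats::setNames(unname(sums),
                                                            names(files))))
  }
  man_path <- file.path(workdir, "manifest.jsonl")
  write_lines_lf(vapply(manifest, function(m)
    jsonlite::toJSON(m, auto_unbox = TRUE), character(1)), man_path)
  invisible(manifest)
}

cli_script_path <- function() {
  p <- system.file("cli", "lrtsim.R", package = "lrtsim")
  if (!nzchar(p)) stop("CLI script not found; is the package installed?",
                       call. = FALSE)
  p
}

.run_step_subprocess <- function(step, all_steps, workdir, step_seed) {
  payload <- jsonlite::toJSON(list(step = step,
                                   all_steps = all_steps,
                                   workdir = workdir,
                                   seed = step_seed),
                              auto_unbox = TRUE, digits = NA)
  payload_file <- tempfile(fileext = ".json")
  writeLines(as.character(payload), payload_file)
  on.exit(unlink(payload_file))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- system2(rscript, c(cli_script_path(), "step", "--payload",
                            shQuote(payload_file)),
                 stdout = TRUE, stderr = TRUE,
                 env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
  status <- attr(out, "status") %||% 0L
  if (status != 0L)
    stop(sprintf("pipeline step '%s' failed in subprocess:\n%s", step$name,
                 paste(out, collapse = "\n")), call. = FALSE)
  # the step's result record is the last line of stdout (JSON)
  rec_line <- out[max(grep("^\\{", out))]
  rec <- jsonlite::fromJSON(rec_line, simplifyVector = FALSE)
  list(n_in = rec$n_in %||% NA_integer_, n_out = rec$n_out,
       files = lapply(rec$files, as.character))
}

# Re-hydrate a normalized step arriving from JSON (subprocess payloads).
.step_from_json <- function(s) {
  list(name = s$name, module = s$module, params = s$params %||% list(),
       input = as.character(unlist(s$input %||% list())),
       after = as.character(unlist(s$after %||% list())),
       outputs = s$outputs %||% list())
}
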