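#' Truncation models
#'
#' A truncation model is a joint distribution over (5' trim, 3' trim) lengths
#' in bases, sampled per molecule by [truncate_ends()]. Two families are
#' provided: an empirical `grid` (joint histogram with a fixed bin width,
#' what [estimate_truncation()] emits) and a `lognormal` parametric model
#' (3' trim ~ round(lognormal(mu, sigma)), 5' trim fixed at 0, the classic
#' 3'-biased degradation shape of oligo-dT libraries).
#'
#' @name truncation_model
NULL

#' Empirical grid truncation model
#'
#' @param grid data.frame with integer columns `bin5`, `bin3` and numeric
#'   `prob` (must sum to 1 within 1e-9).
#' @param bin_width bin width in bases.
#' @return object of class `"truncation_model"`.
#' @export
truncation_model_grid <- function(grid, bin_width) {
  stopifnot(all(c("bin5", "bin3", "prob") %in% names(grid)), bin_width >= 1)
  if (abs(sum(grid$prob) - 1) > 1e-9)
    stop("grid probabilities must sum to 1", call. = FALSE)
  if (any(grid$bin5 < 0) || any(grid$bin3 < 0) || any(grid$prob < 0))
    stop("grid bins and probabilities must be non-negative", call. = FALSE)
  structure(list(kind = "grid",
                 grid = data.frame(bin5 = as.integer(grid$bin5),
                                   bin3 = as.integer(grid$bin3),
                                   prob = as.numeric(grid$prob)),
                 bin_width = as.integer(bin_width)),
            class = "truncation_model")
}

#' Lognormal truncation model (3'-only)
#'
#' @param meanlog,sdlog parameters of the lognormal 3' trim length.
#' @return object of class `"truncation_model"`.
#' @export
truncation_model_lognormal <- function(meanlog, sdlog) {
  stopifnot(sdlog >= 0)
  structure(list(kind = "lognormal", meanlog = meanlog, sdlog = sdlog),
            class = "truncation_model")
}

#' Sample (5' trim, 3' trim) pairs from a truncation model
#'
#' Grid models draw a bin pair by probability, then a uniform offset within
#' each bin (bin width 1 is therefore exact).
#'
#' @param model a truncation model.
#' @param n number of draws (uses the current RNG stream).
#' @return integer matrix with columns `d5`, `d3`.
#' @export
sample_truncation <- function(model, n) {
  if (model$kind == "grid") {
    i <- sample.int(nrow(model$grid), n, replace = TRUE, prob = model$grid$prob)
    w <- model$bin_width
    off5 <- if (w > 1L) sample.int(w, n, replace = TRUE) - 1L else 0L
    off3 <- if (w > 1L) sample.int(w, n, replace = TRUE) - 1L else 0L
    cbind(d5 = model$grid$bin5[i] * w + off5,
          d3 = model$grid$bin3[i] * w + off3)
  } else {
    cbind(d5 = rep(0L, n),
          d3 = as.integer(round(stats::rlnorm(n, model$meanlog, model$sdlog))))
  }
}

#' Write / read a truncation model as TSV
#'
#' Grid models: a `#bin_width=<w>` header comment then `bin5 bin3 prob`
#' columns. Lognormal models: `#family=lognormal meanlog=<m> sdlog=<s>`.
#'
#' @param model a truncation model.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_truncation_model <- function(model, path) {
  if (model$kind == "grid") {
    lines <- c(sprintf("#bin_width=%d", model$bin_width),
               "bin5\tbin3\tprob",
               sprintf("%d\t%d\t%.17g", model$grid$bin5, model$grid$bin3,
                       model$grid$prob))
  } else {
    lines <- sprintf("#family=lognormal meanlog=%.17g sdlog=%.17g",
                     model$meanlog, model$sdlog)
  }
  write_lines_lf(lines, path)
  invisible(path)
}

#' @rdname write_truncation_model
#' @export
read_truncation_model <- function(path) {
  lines <- readLines(path)
  h <- lines[1]
  if (startsWith(h, "#family=lognormal")) {
    m <- as.numeric(sub(".*meanlog=([-0-9.eE+]+).*", "\\1", h))
    s <- as.numeric(sub(".*sdlog=([-0-9.eE+]+).*", "\\1", h))
    return(truncation_model_lognormal(m, s))
  }
  if (!startsWith(h, "#bin_width="))
    stop("unrecognized truncation model file header: ", h, call. = FALSE)
  w <- as.integer(sub("#bin_width=", "", h, fixed = TRUE))
  df <- utils::read.table(text = lines[-1], header = TRUE, sep = "\t")
  truncation_model_grid(df, w)
}
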