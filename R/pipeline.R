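#' Read and validate a pipeline run configuration
#'
#' The YAML layout mirrors the pipeline stages:
#' ```yaml
#' grid: {min: 300, max: 700, step: 1}
#' windows: {sensitivity: [420, 620], msp: [440, 650]}
#' search: {sensitivity: [400, 650], msp: [450, 650]}
#' reference: Rh1
#' seed: 1
#' genotypes:
#'   - name: Rh1
#'     sensitivity: rh1_ss.tsv      # optional
#'     msp: rh1_ds.tsv              # optional
#'     n_SS: 3                      # optional metadata
#'     n_MSP: 7
#' ```
#' An optional `template: {a0: ..., a1: ..., a2: ...}` block overrides
#' the default alpha-band coefficients.  Relative input paths are
#' resolved against the config file's directory.
#'
#' @param path YAML config path.
#' @return A validated config list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (i in seq_along(cfg$genotypes)) {
    for (f in c("sensitivity", "msp")) {
      p <- cfg$genotypes[[i]][[f]]
      if (!is.null(p) && !file.exists(p))
        cfg$genotypes[[i]][[f]] <- file.path(base, p)
    }
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$genotypes) || length(cfg$genotypes) == 0)
    stop("config lists no genotypes", call. = FALSE)
  cfg$grid <- utils::modifyList(list(min = 300, max = 700, step = 1),
                                cfg$grid %||% list())
  cfg$windows <- utils::modifyList(
    list(sensitivity = c(420, 620), msp = c(440, 650)),
    cfg$windows %||% list())
  cfg$search <- utils::modifyList(
    list(sensitivity = c(400, 650), msp = c(450, 650)),
    cfg$search %||% list())
  cfg$seed <- cfg$seed %||% 1L
  for (w in cfg$windows)
    if (w[1] < cfg$grid$min || w[2] > cfg$grid$max)
      stop("fitting window extends outside the working grid", call. = FALSE)
  if (is.null(cfg$reference))
    stop("config must name a reference genotype", call. = FALSE)
  for (g in cfg$genotypes) {
    if (is.null(g$name)) stop("genotype entry without a name", call. = FALSE)
    for (f in c("sensitivity", "msp"))
      if (!is.null(g[[f]]) && !file.exists(g[[f]]))
        stop("input file not found for ", g$name, ": ", g[[f]],
             call. = FALSE)
  }
  cfg
}

pipeline_coefficients <- function(cfg) {
  if (is.null(cfg$template)) template_coefficients()
  else template_coefficients(cfg$template$a0, cfg$template$a1,
                             cfg$template$a2)
}

#' Run the full spectral-tuning pipeline over a batch of genotypes
#'
#' For each genotype: fit the sensitivity spectrum (if provided) to get
#' the R-form lambda-max, then decompose the difference spectrum (if
#' provided) with the R-form fixed to that genotype's fitted value --
#' mirroring how the R-form is determined electrophysiologically and
#' then held fixed in the microspectrophotometric decomposition.  A
#' genotype lacking an input, or whose fit fails, gets `NA` fields and a
#' logged message; one bad genotype never aborts the batch.  Output is
#' deterministic for a given config.
#'
#' @param config a config list from [read_run_config()], or assembled in
#'   code with the same shape.
#' @param out_dir optional directory; when given, writes `table.tsv`
#'   (full-precision pigment table), `table.txt` (rendered), one
#'   `<genotype>_fit.json` per genotype, and `log.txt`.
#' @return Invisibly, a list with `table` ([pigment_table()]), `fits`
#'   (per-genotype list of fit objects), and `log` (character).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- validate_run_config(config)
  coef <- pipeline_coefficients(cfg)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  fits <- list()
  records <- list()
  for (g in cfg$genotypes) {
    sfit <- mfit <- NULL
    if (!is.null(g$sensitivity)) {
      sfit <- tryCatch(
        fit_sensitivity(read_spectrum(g$sensitivity, kind = "sensitivity"),
                        window = as.numeric(cfg$windows$sensitivity),
                        search = as.numeric(cfg$search$sensitivity),
                        coefficients = coef),
        error = function(e) {
          note("%s: sensitivity fit failed: %s", g$name, conditionMessage(e))
          NULL
        })
      if (!is.null(sfit))
        note("%s: R-form lambda_max = %.2f nm (r = %.4f)",
             g$name, sfit$lambda_max_R, sfit$correlation)
    } else note("%s: no sensitivity spectrum", g$name)
    if (!is.null(g$msp)) {
      if (is.null(sfit)) {
        note("%s: difference spectrum skipped (no fitted R-form to fix)",
             g$name)
      } else {
        mfit <- tryCatch(
          fit_difference(read_spectrum(g$msp, kind = "difference"),
                         lambda_max_R_fixed = sfit$lambda_max_R,
                         window = as.numeric(cfg$windows$msp),
                         search = as.numeric(cfg$search$msp),
                         coefficients = coef),
          error = function(e) {
            note("%s: difference fit failed: %s", g$name,
                 conditionMessage(e))
            NULL
          })
        if (!is.null(mfit))
          note("%s: M-form lambda_max = %.2f nm (r = %.4f)",
               g$name, mfit$lambda_max_M, mfit$correlation)
      }
    } else note("%s: no difference spectrum", g$name)
    fits[[g$name]] <- list(sensitivity = sfit, msp = mfit)
    records[[g$name]] <- pigment_record(
      genotype = g$name,
      lambda_max_R = if (is.null(sfit)) NA else sfit$lambda_max_R,
      lambda_max_M = if (is.null(mfit)) NA else mfit$lambda_max_M,
      corr_SS = if (is.null(sfit)) NA else sfit$correlation,
      corr_MSP = if (is.null(mfit)) NA else mfit$correlation,
      n_SS = g$n_SS %||% if (is.null(sfit)) NA else 1,
      n_MSP = g$n_MSP %||% if (is.null(mfit)) NA else 1)
  }
  tab <- pigment_table(unname(records), reference = cfg$reference)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pigment_table(tab, file.path(out_dir, "table.tsv"))
    writeLines(format(tab), file.path(out_dir, "table.txt"))
    for (nm in names(fits)) {
      plain <- lapply(fits[[nm]], function(f)
        if (is.null(f)) NULL else unclass(f))
      jsonlite::write_json(
        plain, auto_unbox = TRUE, digits = NA, null = "null",
        path = file.path(out_dir, paste0(gsub("\\s+", "_", nm),
                                         "_fit.json")))
    }
    writeLines(log, file.path(out_dir, "log.txt"))
  }
  invisible(list(table = tab, fits = fits, log = log))
}
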