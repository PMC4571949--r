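#' Signed spectral shift of a mutant pigment versus a reference
#'
#' Positive shifts are red shifts (toward longer wavelengths), negative
#' shifts are blue shifts, following the usual sign convention for
#' spectral tuning.
#'
#' @param mutant_lambda_max,reference_lambda_max peak wavelengths in nm.
#' @return A list with `shift` (nm, mutant minus reference) and
#'   `direction` (`"red"`, `"blue"` or `"none"`).
#' @examples
#' compute_shift(484, 480)  # 4 nm red shift
#' @export
compute_shift <- function(mutant_lambda_max, reference_lambda_max) {
  m <- as.numeric(mutant_lambda_max)
  r <- as.numeric(reference_lambda_max)
  if (length(m) != 1 || length(r) != 1 || !is.finite(m) || !is.finite(r))
    stop("missing value: both lambda-max values must be finite",
         call. = FALSE)
  s <- m - r
  list(shift = s,
       direction = if (s > 0) "red" else if (s < 0) "blue" else "none")
}

#' One row of a pigment report
#'
#' Holds the estimated R- and M-form peaks, fit correlations and sample
#' counts for one genotype.  Unmeasured quantities are `NA` and render as
#' `"NA"` in the formatted table.
#'
#' @param genotype non-empty genotype label, e.g. `"Rh1 D96N"`.
#' @param lambda_max_R,lambda_max_M peak wavelengths in nm, or `NA`.
#' @param corr_SS,corr_MSP fit correlations for the sensitivity and
#'   difference-spectrum fits, or `NA`.
#' @param n_SS,n_MSP numbers of animals/recordings analyzed, or `NA`.
#' @return An object of class `pigment_record`.
#' @export
pigment_record <- function(genotype, lambda_max_R = NA, lambda_max_M = NA,
                           corr_SS = NA, corr_MSP = NA,
                           n_SS = NA, n_MSP = NA) {
  if (!is.character(genotype) || length(genotype) != 1 || !nzchar(genotype))
    stop("genotype must be a non-empty string", call. = FALSE)
  structure(list(genotype = genotype,
                 lambda_max_R = as.numeric(lambda_max_R),
                 lambda_max_M = as.numeric(lambda_max_M),
                 corr_SS = as.numeric(corr_SS),
                 corr_MSP = as.numeric(corr_MSP),
                 n_SS = as.numeric(n_SS),
                 n_MSP = as.numeric(n_MSP)),
            class = "pigment_record")
}

# round half away from zero, the convention used for whole-nm table entries
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Pigment report with spectral shifts versus a reference genotype
#'
#' Assembles [pigment_record()] rows into a table with signed R- and
#' M-form shifts against the named reference genotype.  Shifts are `NA`
#' wherever the needed lambda-max is missing.  The underlying data frame
#' keeps full precision; the print method rounds wavelengths and shifts
#' to whole nm (half away from zero) as such tables are conventionally
#' reported.
#'
#' @param records list of [pigment_record()] objects with unique
#'   genotypes.
#' @param reference genotype name of the reference (wild-type) pigment;
#'   must be present with a non-missing `lambda_max_R`.
#' @return An object of class `pigment_table`: list with `table` (data
#'   frame) and `reference`.
#' @export
pigment_table <- function(records, reference) {
  if (length(records) == 0)
    stop("no records: reference genotype absent", call. = FALSE)
  stopifnot(all(vapply(records, inherits, logical(1), "pigment_record")))
  gen <- vapply(records, `[[`, character(1), "genotype")
  if (anyDuplicated(gen))
    stop("duplicate genotype in report: ", gen[duplicated(gen)][1],
         call. = FALSE)
  if (!reference %in% gen)
    stop("reference genotype not present: ", reference, call. = FALSE)
  ref <- records[[match(reference, gen)]]
  if (!is.finite(ref$lambda_max_R))
    stop("reference genotype has no R-form lambda-max", call. = FALSE)
  num <- function(f) vapply(records, `[[`, numeric(1), f)
  df <- data.frame(genotype = gen,
                   R = num("lambda_max_R"), M = num("lambda_max_M"),
                   corr_SS = num("corr_SS"), corr_MSP = num("corr_MSP"),
                   n_SS = num("n_SS"), n_MSP = num("n_MSP"),
                   stringsAsFactors = FALSE)
  df$shift_R <- df$R - ref$lambda_max_R
  df$shift_M <- if (is.finite(ref$lambda_max_M)) df$M - ref$lambda_max_M
                else rep(NA_real_, nrow(df))
  structure(list(table = df, reference = reference),
            class = "pigment_table")
}

#' Format a pigment table for display
#'
#' @param x a [pigment_table()].
#' @param ... unused.
#' @return Character vector of table lines (tab-separated, wavelengths
#'   and shifts rounded to whole nm, missing values as `"NA"`).
#' @export
format.pigment_table <- function(x, ...) {
  df <- x$table
  fmt <- function(v, d) ifelse(is.finite(v),
                               formatC(round_half_away(v, d), format = "f",
                                       digits = d), "NA")
  body <- cbind(df$genotype,
                fmt(df$R, 0), fmt(df$M, 0),
                fmt(df$corr_SS, 3), fmt(df$corr_MSP, 3),
                fmt(df$n_SS, 0), fmt(df$n_MSP, 0),
                fmt(df$shift_R, 0), fmt(df$shift_M, 0))
  header <- c("genotype", "R", "M", "corr_SS", "corr_MSP",
              "n_SS", "n_MSP", "shift_R", "shift_M")
  apply(rbind(header, body), 1, paste, collapse = "\t")
}

#' @export
print.pigment_table <- function(x, ...) {
  cat(format(x), sep = "\n")
  cat(sprintf("(shifts vs %s; positive = red shift)\n", x$reference))
  invisible(x)
}

#' Write a pigment table to TSV in full precision
#'
#' The machine-readable form round-trips losslessly through
#' [read_pigment_table()].
#'
#' @param x a [pigment_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pigment_table <- function(x, path) {
  stopifnot(inherits(x, "pigment_table"))
  df <- x$table
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# reference=", x$reference), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  for (i in seq_len(nrow(df))) {
    vals <- vapply(df[i, -1], function(v)
      if (is.finite(v)) sprintf("%.17g", v) else "NA", character(1))
    writeLines(paste(c(df$genotype[i], vals), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a pigment table written by [write_pigment_table()]
#'
#' @param path TSV path.
#' @return A `pigment_table` object.
#' @export
read_pigment_table <- function(path) {
  lines <- readLines(path)
  reference <- sub("^# reference=", "", lines[1])
  df <- utils::read.delim(text = lines[-1], stringsAsFactors = FALSE,
                          na.strings = "NA")
  for (j in setdiff(colnames(df), "genotype")) df[[j]] <- as.numeric(df[[j]])
  structure(list(table = df, reference = reference),
            class = "pigment_table")
}
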