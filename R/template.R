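#' Log-normal alpha-band template coefficients
#'
#' The visible absorbance band (alpha band) of a rhodopsin has a nearly
#' invariant shape on a log-wavelength axis, so a single fixed-shape
#' template parameterized only by the peak wavelength describes the whole
#' family of pigments.  The template implemented here is the log-normal
#' form
#' \deqn{S(\lambda) = \exp[-a_0 x^2 (1 + a_1 x + a_2 x^2)], \quad
#'       x = \log_{10}(\lambda / \lambda_{max})}
#' with default coefficients `a0 = 380`, `a1 = 6.09`, `a2 = 3 a1^2 / 8`
#' (Stavenga, Smits & Hoenders 1993, Vision Res. 33:1011).  The
#' coefficients are data, not constants baked into the evaluator, so an
#' alternative published alpha-band parameterization can be supplied here
#' or through a YAML config (see [load_template_coefficients()]).
#'
#' @param a0,a1,a2 shape coefficients of the log-normal template.
#' @return Named numeric vector of coefficients.
#' @export
template_coefficients <- function(a0 = 380, a1 = 6.09, a2 = 3 * a1^2 / 8) {
  co <- c(a0 = as.numeric(a0), a1 = as.numeric(a1), a2 = as.numeric(a2))
  if (anyNA(co) || any(!is.finite(co)))
    stop("template coefficients must be finite", call. = FALSE)
  if (co["a0"] <= 0)
    stop("a0 must be positive", call. = FALSE)
  if (co["a1"]^2 - 4 * co["a2"] >= 0)
    stop("coefficients must keep the exponent polynomial positive ",
         "(a1^2 < 4 a2), otherwise the template is not unimodal",
         call. = FALSE)
  co
}

#' Template parameters: peak wavelength plus shape coefficients
#'
#' @param lambda_max peak absorbance wavelength in nm, inside (300, 700).
#' @param coefficients shape coefficients, see [template_coefficients()].
#' @return An object of class `template_params`.
#' @examples
#' p <- template_params(480)
#' alpha_band(480, p)  # 1 at the peak
#' @export
template_params <- function(lambda_max, coefficients = template_coefficients()) {
  lambda_max <- as.numeric(lambda_max)
  if (length(lambda_max) != 1 || !is.finite(lambda_max) ||
      lambda_max <= 300 || lambda_max >= 700)
    stop("lambda_max must lie inside (300, 700) nm", call. = FALSE)
  structure(list(lambda_max = lambda_max,
                 coefficients = template_coefficients(
                   coefficients[["a0"]], coefficients[["a1"]],
                   coefficients[["a2"]])),
            class = "template_params")
}

#' @export
print.template_params <- function(x, ...) {
  cat(sprintf("<alpha-band template lambda_max=%g nm a0=%g a1=%g a2=%g>\n",
              x$lambda_max, x$coefficients["a0"], x$coefficients["a1"],
              x$coefficients["a2"]))
  invisible(x)
}

#' Evaluate the log-normal alpha-band template
#'
#' Returns relative absorbance in \[0, 1\]: exactly 1 at `lambda_max`,
#' strictly unimodal, with the steeper limb on the long-wavelength side as
#' observed for rhodopsins.
#'
#' @param wavelength wavelengths in nm, all positive.
#' @param params a [template_params()] object.
#' @return Numeric vector of relative absorbances.
#' @export
alpha_band <- function(wavelength, params) {
  stopifnot(inherits(params, "template_params"))
  wavelength <- as.numeric(wavelength)
  if (any(!is.finite(wavelength)) || any(wavelength <= 0))
    stop("wavelengths must be positive and finite", call. = FALSE)
  co <- params$coefficients
  x <- log10(wavelength / params$lambda_max)
  exp(-co[["a0"]] * x^2 * (1 + co[["a1"]] * x + co[["a2"]] * x^2))
}

#' Generate a template absorbance spectrum on a grid
#'
#' @param params a [template_params()] object.
#' @param grid wavelengths in nm.
#' @return A [spectrum()] of kind `"absorbance"`.
#' @export
template_spectrum <- function(params, grid = default_grid()) {
  spectrum(grid, alpha_band(grid, params), kind = "absorbance",
           label = sprintf("template %g nm", params$lambda_max))
}

#' Correlation between a model curve and data over a fitting window
#'
#' The fit-quality statistic reported alongside every lambda-max estimate:
#' the Pearson product-moment correlation between the fitted template (or
#' calculated difference spectrum) and the measured values, computed over
#' the fitting window only.  The data's wavelength grid restricted to the
#' window is the common grid; the model is resampled onto it if needed.
#'
#' @param model a [spectrum()] holding the fitted curve; must cover the
#'   window.
#' @param data a [spectrum()] holding the measurement.
#' @param window numeric `c(lo, hi)` in nm.
#' @return Pearson correlation coefficient in \[-1, 1\].
#' @export
fit_correlation <- function(model, data, window) {
  dw <- spectrum_window(data, window)
  if (length(dw$wavelength) < 3)
    stop("fewer than 3 data points in window", call. = FALSE)
  mv <- if (identical(model$wavelength, dw$wavelength)) model$value
        else resample(model, dw$wavelength)$value
  if (stats::sd(dw$value) == 0 || stats::sd(mv) == 0)
    stop("correlation undefined: constant series in window", call. = FALSE)
  stats::cor(mv, dw$value)
}

#' Load template coefficients from a YAML config
#'
#' Reads `a0`, `a1`, `a2` from a named key of a YAML file, e.g.
#' ```yaml
#' templates:
#'   lognormal_alpha: {a0: 380.0, a1: 6.09, a2: 13.908}
#' ```
#'
#' @param path YAML file path.
#' @param key template name under the top-level `templates` mapping; if the
#'   file has no `templates` mapping, `key` is looked up at top level.
#' @return Named coefficient vector, see [template_coefficients()].
#' @export
load_template_coefficients <- function(path, key = "lognormal_alpha") {
  cfg <- yaml::read_yaml(path)
  pool <- if (!is.null(cfg$templates)) cfg$templates else cfg
  tc <- pool[[key]]
  if (is.null(tc))
    stop("template key not found in config: ", key, call. = FALSE)
  template_coefficients(tc$a0, tc$a1, tc$a2)
}
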