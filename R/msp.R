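#' Build a rhodopsin/metarhodopsin difference spectrum
#'
#' A microspectrophotometric difference spectrum is the absorbance of the
#' photoactivated M-form minus that of the dark R-form:
#' `DS(lambda) = aM * T(lambda; lambdaM) - aR * T(lambda; lambdaR)`,
#' with `T` the alpha-band template.  Separate non-negative amplitudes are
#' carried for the two states because photoconversion need not be complete
#' and the in-situ path length is uncalibrated.
#'
#' @param lambda_max_R,lambda_max_M peak wavelengths (nm) of the R- and
#'   M-form templates.
#' @param amplitude_R,amplitude_M non-negative state amplitudes.
#' @param grid wavelengths in nm.
#' @param coefficients template shape coefficients.
#' @return A [spectrum()] of kind `"difference"`.
#' @export
build_difference <- function(lambda_max_R, lambda_max_M,
                             amplitude_R = 1, amplitude_M = 1,
                             grid = default_grid(),
                             coefficients = template_coefficients()) {
  if (amplitude_R < 0 || amplitude_M < 0)
    stop("amplitudes must be non-negative", call. = FALSE)
  v <- amplitude_M * alpha_band(grid, template_params(lambda_max_M, coefficients)) -
       amplitude_R * alpha_band(grid, template_params(lambda_max_R, coefficients))
  spectrum(grid, v, kind = "difference",
           label = sprintf("DS R=%g M=%g", lambda_max_R, lambda_max_M))
}

# Exact non-negative least squares for the two-amplitude model
# d ~ aM * tM - aR * tR (+ baseline), aM >= 0, aR >= 0, baseline free.
# Solves the unconstrained normal equations and falls back to the two
# boundary problems when the interior solution is infeasible or the
# design is rank deficient (tM and tR collinear, e.g. candidate lambda_M
# equal to the fixed lambda_R).
nnls_two_state <- function(tM, tR, d, offset = FALSE) {
  one <- if (offset) rep(1, length(d)) else NULL
  solve_ls <- function(X) {
    g <- crossprod(X)
    if (rcond(g) <= 1e-12) return(NULL)
    co <- unname(drop(solve(g, crossprod(X, d))))
    list(co = co, sse = sum((d - X %*% co)^2))
  }
  fit1 <- function(t, sgn) {      # single-amplitude fit, sign constrained
    ls <- solve_ls(cbind(sgn * t, one))
    a <- if (is.null(ls)) 0 else ls$co[1]
    if (is.null(ls) || a < 0) {   # amplitude pinned at 0 too
      b0 <- if (offset) mean(d) else 0
      return(list(aM = 0, aR = 0, baseline = b0,
                  sse = sum((d - b0)^2), clamped = TRUE))
    }
    list(aM = if (sgn > 0) a else 0, aR = if (sgn > 0) 0 else a,
         baseline = if (offset) ls$co[2] else 0,
         sse = ls$sse, clamped = TRUE)
  }
  ls <- solve_ls(cbind(tM, -tR, one))
  if (!is.null(ls) && ls$co[1] >= 0 && ls$co[2] >= 0) {
    return(list(aM = ls$co[1], aR = ls$co[2],
                baseline = if (offset) ls$co[3] else 0,
                sse = ls$sse, clamped = FALSE))
  }
  bM <- fit1(tM, 1)               # aR clamped to 0
  bR <- fit1(tR, -1)              # aM clamped to 0
  if (bM$sse <= bR$sse) bM else bR
}

#' Decompose a difference spectrum with the R-form fixed
#'
#' Estimates the M-form lambda-max and the two state amplitudes by least
#' squares between [build_difference()] and a measured difference
#' spectrum, with the R-form lambda-max fixed to the value determined
#' electrophysiologically for the same genotype.  At each candidate
#' M-form lambda-max the amplitudes are solved in closed form under
#' non-negativity; if the unconstrained solution would drive an amplitude
#' negative, that amplitude is clamped to 0 and the fit is flagged
#' (`clamped = TRUE`).
#'
#' @param ds a [spectrum()] of kind `"difference"` covering `window`.
#' @param lambda_max_R_fixed R-form peak wavelength (nm), held fixed.
#' @param window fitting window `c(lo, hi)` in nm; the default 440-650 nm
#'   covers the negative R-depletion lobe through the M-form tail.
#' @param search M-form lambda-max search interval in nm.
#' @param coefficients template shape coefficients.
#' @param grid_step,tol coarse step and refinement tolerance in nm.
#' @param offset also fit a free constant baseline term, for difference
#'   spectra with instrumental drift; off by default since difference
#'   spectra are nominally zero in the absorption-free tails.
#' @return An object of class `msp_fit` with elements `lambda_max_M`,
#'   `amplitude_M`, `amplitude_R`, `baseline`, `correlation`,
#'   `lambda_max_R_fixed`, `clamped`, `window`, `n_points`.
#' @examples
#' ds <- build_difference(480, 560)
#' fit_difference(ds, lambda_max_R_fixed = 480)
#' @export
fit_difference <- function(ds, lambda_max_R_fixed, window = c(440, 650),
                           search = c(450, 650),
                           coefficients = template_coefficients(),
                           grid_step = 1, tol = 0.01, offset = FALSE) {
  stopifnot(inherits(ds, "spectrum"))
  if (ds$kind != "difference")
    stop("fit_difference expects a difference spectrum", call. = FALSE)
  if (lambda_max_R_fixed <= 300 || lambda_max_R_fixed >= 700)
    stop("lambda_max_R_fixed must lie inside (300, 700) nm", call. = FALSE)
  dw <- spectrum_window(ds, window)
  wl <- dw$wavelength
  if (length(wl) < 5)
    stop("insufficient data: fewer than 5 points in window", call. = FALSE)
  if (all(dw$value == 0))
    stop("degenerate decomposition: difference spectrum identically zero ",
         "in window", call. = FALSE)
  tR <- alpha_band(wl, template_params(lambda_max_R_fixed, coefficients))
  obj <- function(lm) {
    tM <- alpha_band(wl, template_params(lm, coefficients))
    nnls_two_state(tM, tR, dw$value, offset)$sse
  }
  lam <- profile_lambda_search(obj, search, grid_step, tol)
  tM <- alpha_band(wl, template_params(lam, coefficients))
  sol <- nnls_two_state(tM, tR, dw$value, offset)
  model <- structure(list(wavelength = wl,
                          value = sol$aM * tM - sol$aR * tR + sol$baseline,
                          kind = "difference", label = "calculated DS"),
                     class = "spectrum")
  structure(list(lambda_max_M = lam,
                 amplitude_M = sol$aM,
                 amplitude_R = sol$aR,
                 baseline = sol$baseline,
                 correlation = fit_correlation(model, dw, window),
                 lambda_max_R_fixed = as.numeric(lambda_max_R_fixed),
                 clamped = sol$clamped,
                 window = as.numeric(window),
                 n_points = length(wl)),
            class = "msp_fit")
}

#' @export
print.msp_fit <- function(x, ...) {
  cat(sprintf(
    "M-form fit: lambda_max = %.2f nm  aM = %.3f aR = %.3f  (r = %.4f, R fixed at %g nm)%s\n",
    x$lambda_max_M, x$amplitude_M, x$amplitude_R, x$correlation,
    x$lambda_max_R_fixed, if (x$clamped) "  [amplitude clamped]" else ""))
  invisible(x)
}

#' Convert a transmission spectrum to absorbance
#'
#' Pre-processing helper for raw microspectrophotometric transmissions:
#' `A = -log10(T)`.  The decomposition pipeline itself takes
#' absorbance-difference spectra as input.
#'
#' @param x a [spectrum()] whose values are transmissions in (0, 1\].
#' @return A [spectrum()] of kind `"absorbance"`.
#' @export
absorbance_from_transmission <- function(x) {
  stopifnot(inherits(x, "spectrum"))
  if (any(x$value <= 0 | x$value > 1))
    stop("transmissions must lie in (0, 1]", call. = FALSE)
  spectrum(x$wavelength, -log10(x$value), kind = "absorbance",
           label = x$label)
}
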