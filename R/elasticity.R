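#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Boltzmann constant in pN nm / K
.kB <- 0.01380649

#' Thermal energy at a given temperature
#'
#' @param temperature_K temperature in kelvin.
#' @return thermal energy kT in pN nm.
#' @export
kT <- function(temperature_K = 298) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  .kB * temperature_K
}

# maximum force (pN) before dsDNA overstretching; hard domain boundary
.FORCE_MAX <- 60

#' ssDNA elasticity parameters (extensible freely jointed chain)
#'
#' The eFJC describes the force-extension behaviour of single-stranded DNA:
#' a chain of rigid Kuhn segments of length `b` with enthalpic stretching
#' against a modulus `S`. Defaults are canonical literature values for
#' ssDNA in physiological buffer.
#'
#' @param contour_nm contour length per nucleotide, nm/nt.
#' @param kuhn_nm Kuhn segment length b, nm.
#' @param stretch_pN stretch modulus S, pN.
#' @param temperature_K temperature, K (must lie in 273-320 K).
#' @return an object of class `c("efjc_params", "polymer_params")`.
#' @export
#' @examples
#' ssdna_params()
#' polymer_extension(ssdna_params(), force = 30)
ssdna_params <- function(contour_nm = 0.56, kuhn_nm = 1.5, stretch_pN = 800,
                         temperature_K = 298) {
  .check_polymer(contour_nm, kuhn_nm, stretch_pN, temperature_K)
  structure(
    list(strand = "ssDNA", contour_nm = contour_nm, kuhn_nm = kuhn_nm,
         stretch_pN = stretch_pN, temperature_K = temperature_K),
    class = c("efjc_params", "polymer_params")
  )
}

#' dsDNA elasticity parameters (extensible worm-like chain, Odijk regime)
#'
#' @param contour_nm contour length per base pair, nm/bp.
#' @param persistence_nm persistence length P, nm.
#' @param stretch_pN stretch modulus S, pN.
#' @param temperature_K temperature, K (must lie in 273-320 K).
#' @return an object of class `c("ewlc_params", "polymer_params")`.
#' @export
dsdna_params <- function(contour_nm = 0.34, persistence_nm = 50,
                         stretch_pN = 1200, temperature_K = 298) {
  .check_polymer(contour_nm, persistence_nm, stretch_pN, temperature_K)
  structure(
    list(strand = "dsDNA", contour_nm = contour_nm,
         persistence_nm = persistence_nm, stretch_pN = stretch_pN,
         temperature_K = temperature_K),
    class = c("ewlc_params", "polymer_params")
  )
}

.check_polymer <- function(contour, bend, stretch, temperature) {
  if (!all(is.finite(c(contour, bend, stretch))) ||
      contour <= 0 || bend <= 0 || stretch <= 0) {
    abort("all polymer lengths and moduli must be strictly positive")
  }
  if (temperature < 273 || temperature > 320) {
    abort("temperature must lie in [273, 320] K")
  }
  invisible(TRUE)
}

#' @export
print.polymer_params <- function(x, ...) {
  cat("<polymer_params>", x$strand, "\n")
  for (nm in setdiff(names(x), "strand")) cat(" ", nm, "=", x[[nm]], "\n")
  invisible(x)
}

#' Mean extension per monomer at a given force
#'
#' For ssDNA the extensible freely jointed chain
#' \deqn{x(F) = L_c \left[\coth(bF/kT) - kT/(bF)\right](1 + F/S)}
#' and for dsDNA the extensible worm-like chain in the Odijk high-force form
#' \deqn{x(F) = L_c \left[1 - \tfrac12\sqrt{kT/(F P)} + F/S\right].}
#' Forces are valid on (0, 60] pN (below the overstretching transition);
#' for ssDNA `force = 0` returns the analytic limit 0.
#'
#' @param params a `polymer_params` object.
#' @param force force in pN; vectorised.
#' @return extension in nm per nucleotide (ssDNA) or nm per base pair (dsDNA).
#' @export
polymer_extension <- function(params, force) UseMethod("polymer_extension")

#' @export
polymer_extension.efjc_params <- function(params, force) {
  if (any(!is.finite(force)) || any(force < 0)) {
    abort("force must be finite and non-negative (pN)")
  }
  if (any(force > .FORCE_MAX)) {
    abort(sprintf("force outside eFJC validity window (0, %d] pN", .FORCE_MAX))
  }
  kt <- kT(params$temperature_K)
  out <- numeric(length(force))
  pos <- force > 0
  f <- force[pos]
  u <- params$kuhn_nm * f / kt
  # coth(u) - 1/u, numerically stable Langevin function
  lang <- ifelse(u < 1e-4, u / 3, 1 / tanh(u) - 1 / u)
  out[pos] <- params$contour_nm * lang * (1 + f / params$stretch_pN)
  out
}

#' @export
polymer_extension.ewlc_params <- function(params, force) {
  if (any(!is.finite(force))) abort("force must be finite (pN)")
  if (any(force <= 0) || any(force > .FORCE_MAX)) {
    abort(sprintf("force outside eWLC validity window (0, %d] pN", .FORCE_MAX))
  }
  kt <- kT(params$temperature_K)
  wlc_term <- 0.5 * sqrt(kt / (force * params$persistence_nm))
  if (any(wlc_term >= 1)) {
    abort(sprintf(
      "force below eWLC validity bound kT/(4P) = %.4g pN; Odijk form invalid",
      kt / (4 * params$persistence_nm)))
  }
  params$contour_nm * (1 - wlc_term + force / params$stretch_pN)
}

#' Tether-length change per unwound base pair
#'
#' Each unwound base pair replaces one tensioned duplex bp with one tensioned
#' ssDNA nt (the complementary nt joins a zero-extension relaxed coil), so the
#' end-to-end length changes by \eqn{x_{ss}(F) - x_{ds}(F)} per bp. Positive
#' above the ss/ds crossover force, negative below it.
#'
#' @param force force in pN; vectorised.
#' @param ss,ds elasticity parameter objects.
#' @return signed conversion factor in nm per unwound bp.
#' @export
#' @examples
#' unwound_bp_extension(30)  # ~ +0.19 nm/bp
unwound_bp_extension <- function(force, ss = ssdna_params(), ds = dsdna_params()) {
  polymer_extension(ss, force) - polymer_extension(ds, force)
}

#' Force at which ssDNA and dsDNA extensions per monomer are equal
#'
#' @param ss,ds elasticity parameter objects.
#' @param interval force bracket (pN) searched for the root.
#' @return crossover force in pN.
#' @export
crossover_force <- function(ss = ssdna_params(), ds = dsdna_params(),
                            interval = c(0.5, .FORCE_MAX)) {
  f <- function(x) unwound_bp_extension(x, ss, ds)
  stats::uniroot(f, interval, tol = 1e-10)$root
}

#' Invert a force-extension model
#'
#' Monotone root find returning the force at which the model's extension per
#' monomer equals `extension_nm`. `polymer_force(p, polymer_extension(p, F))`
#' recovers `F` to within 1e-6 pN.
#'
#' @param params a `polymer_params` object.
#' @param extension_nm target extension, nm per monomer; vectorised.
#' @return force in pN.
#' @export
polymer_force <- function(params, extension_nm) {
  lo <- if (inherits(params, "efjc_params")) 0 else
    kT(params$temperature_K) / (4 * params$persistence_nm) * (1 + 1e-9)
  x_hi <- polymer_extension(params, .FORCE_MAX)
  vapply(extension_nm, function(x) {
    if (!is.finite(x) || x < 0) abort("extension must be finite and >= 0")
    if (x == 0 && inherits(params, "efjc_params")) return(0)
    x_lo <- if (lo == 0) 0 else polymer_extension(params, lo)
    if (x < x_lo || x > x_hi) {
      abort(sprintf(
        "extension %.4g nm unattainable on (%.3g, %d] pN (range %.4g-%.4g nm)",
        x, lo, .FORCE_MAX, x_lo, x_hi))
    }
    stats::uniroot(function(f) polymer_extension(params, f) - x,
                   lower = max(lo, 1e-9), upper = .FORCE_MAX,
                   tol = 1e-9, extendInt = "no")$root
  }, numeric(1))
}

#' Fit elasticity parameters to force-extension data
#'
#' Least-squares fit of (contour length, Kuhn or persistence length, stretch
#' modulus) to measured force-extension points, via Levenberg-Marquardt.
#' This is how ssDNA elasticity constants are obtained from a measured
#' force-extension curve before converting length signals to base pairs.
#'
#' @param data a data frame with columns `force_pN` and `extension_nm`
#'   (extension per monomer).
#' @param strand `"ssDNA"` (eFJC) or `"dsDNA"` (eWLC).
#' @param start optional named list of start values overriding the defaults.
#' @param temperature_K temperature, K.
#' @return an object of class `fe_fit`: fitted `params`, a tibble of
#'   `residuals`, and `rmse`. Supports [generics::tidy()], [generics::glance()]
#'   and [ggplot2::autoplot()].
#' @export
fit_force_extension <- function(data, strand = c("ssDNA", "dsDNA"),
                                start = NULL, temperature_K = 298) {
  strand <- match.arg(strand)
  stopifnot(all(c("force_pN", "extension_nm") %in% names(data)))
  data <- as_tibble(data)[, c("force_pN", "extension_nm")]
  if (nrow(data) < 5) abort("need at least 5 force-extension points")
  if (diff(range(data$force_pN)) < 10) {
    abort("force range must span at least 10 pN for an identifiable fit")
  }
  kt <- kT(temperature_K)
  if (strand == "ssDNA") {
    defaults <- list(Lc = 0.56, b = 1.5, S = 800)
    model <- extension_nm ~ Lc * (1 / tanh(b * force_pN / kt) -
      kt / (b * force_pN)) * (1 + force_pN / S)
  } else {
    defaults <- list(Lc = 0.34, b = 50, S = 1200)
    model <- extension_nm ~ Lc * (1 - 0.5 * sqrt(kt / (force_pN * b)) +
      force_pN / S)
  }
  start <- utils::modifyList(defaults, as.list(start %||% list()))
  fit <- tryCatch(
    minpack.lm::nlsLM(model, data = data, start = start,
                      lower = c(1e-4, 1e-4, 1),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort(paste0("force-extension fit failed: ",
                                     conditionMessage(e))))
  est <- stats::coef(fit)
  params <- if (strand == "ssDNA") {
    ssdna_params(est[["Lc"]], est[["b"]], est[["S"]], temperature_K)
  } else {
    dsdna_params(est[["Lc"]], est[["b"]], est[["S"]], temperature_K)
  }
  res <- tibble(force_pN = data$force_pN, extension_nm = data$extension_nm,
                fitted_nm = stats::fitted(fit),
                residual_nm = stats::resid(fit))
  structure(list(params = params, residuals = res,
                 rmse = sqrt(mean(res$residual_nm^2)), strand = strand,
                 fit = fit),
            class = "fe_fit")
}

#' @export
print.fe_fit <- function(x, ...) {
  cat("<fe_fit>", x$strand, "fit on", nrow(x$residuals), "points, RMSE",
      signif(x$rmse, 4), "nm\n")
  print(x$params)
  invisible(x)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy fe_fit
#' @export
tidy.fe_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  lbl <- c(Lc = "contour_nm",
           b = if (x$strand == "ssDNA") "kuhn_nm" else "persistence_nm",
           S = "stretch_pN")
  tibble(term = unname(lbl[rownames(s)]),
         estimate = s[, "Estimate"], std.error = s[, "Std. Error"])
}

#' @method glance fe_fit
#' @export
glance.fe_fit <- function(x, ...) {
  tibble(n = nrow(x$residuals), rmse = x$rmse,
         converged = x$fit$convInfo$isConv)
}

#' @method autoplot fe_fit
#' @export
autoplot.fe_fit <- function(object, ...) {
  ggplot2::ggplot(object$residuals,
                  ggplot2::aes(x = .data$force_pN)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$extension_nm)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_nm), colour = "firebrick") +
    ggplot2::labs(x = "Force (pN)", y = "Extension (nm per monomer)",
                  title = paste(object$strand, "force-extension fit"))
}
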