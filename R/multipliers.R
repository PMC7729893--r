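#' Sigmoid stress multiplier (salinity, tree density)
#'
#' Evaluates \eqn{g(x) = (1 - a_0) / (1 + e^{d (x - tr)}) + a_0}: a
#' decreasing sigmoid equal to \eqn{(1 + a_0)/2} at the threshold `tr`,
#' approaching 1 for small `x` and the floor `a0` for large `x`.
#'
#' @param x Covariate value (ppt for salinity, trees/100 m^2 for density),
#'   non-negative. Vectorized.
#' @param p A [sigmoid_params()] object.
#' @return Multiplier in `(a0, 1)`.
#' @export
multiplier_sigmoid <- function(x, p) {
  stopifnot(inherits(p, "sigmoid_params"))
  if (any(x < 0)) stop("covariate must be non-negative")
  (1 - p$a0) / (1 + exp(p$d * (x - p$tr))) + p$a0
}

#' Elevation stress multiplier
#'
#' Rise--plateau--fall response of growth to ground elevation (a proxy for
#' inundation frequency and duration): zero below the minimum viable
#' elevation `elmin`, `a1e` at `elmin`, an interior plateau bounded by
#' `amax`, and the floor `a2e` at high (rarely flooded) ground. See
#' [elevation_params()] for the functional form.
#'
#' @param el Ground elevation (m). Vectorized.
#' @param p An [elevation_params()] object.
#' @return Multiplier in `[0, 1]`.
#' @export
multiplier_elevation <- function(el, p) {
  stopifnot(inherits(p, "elevation_params"))
  z <- pmax(el - p$elmin, 0)
  rising <- 1 - exp(-(z / p$el1)^p$alpha)
  falling <- exp(-(z / p$el2)^p$beta)
  out <- (p$a1e + (p$amax - p$a1e) * rising) * (p$a2e + (1 - p$a2e) * falling)
  out[el < p$elmin] <- 0
  out
}

#' Hormetic pollutant multiplier
#'
#' Evaluates the two-threshold dose--response
#' \eqn{P(x) = (1 - e^{-(x/th_1)^{\alpha_1}})\,e^{-(x/th_2)^{\alpha_2}}} on a
#' root metal concentration `x` (mg/kg DW). The curve rises with dose below
#' the lower threshold (hormetic stimulation relative to slightly lower
#' doses), peaks between the thresholds, and decays to zero at high dose.
#'
#' By scenario convention an *absent* pollutant contributes 1 (no stress);
#' `NA` values in `x` are treated as absent. Note that the literal curve has
#' \eqn{P(0^+) < 1}: a measured near-zero root burden is not the same state
#' as an unpolluted scenario.
#'
#' @param x Root concentration (mg/kg DW), non-negative; `NA` means absent.
#'   Vectorized.
#' @param p A [pollutant_params()] object.
#' @return Multiplier in `[0, 1]`.
#' @export
multiplier_pollutant <- function(x, p) {
  stopifnot(inherits(p, "pollutant_params"))
  if (any(x < 0, na.rm = TRUE)) stop("concentration must be non-negative")
  out <- (1 - exp(-(x / p$th1)^p$alpha1)) * exp(-(x / p$th2)^p$alpha2)
  out[is.na(x)] <- 1
  out
}

#' Environmental conditions at a plot or stand
#'
#' Lightweight container for the covariates entering the growth multiplier.
#'
#' @param salinity Pore-water salinity (ppt), non-negative.
#' @param density Tree density (trees per 100 m^2), non-negative.
#' @param elevation Ground elevation (m).
#' @param pollutant Named list/vector of root metal concentrations
#'   (mg/kg DW), e.g. `c(Cr = 35)`; `NULL` means unpolluted.
#' @return An object of class `env_conditions`. All fields may be vectors of
#'   a common length.
#' @export
env_conditions <- function(salinity, density, elevation, pollutant = NULL) {
  if (any(salinity < 0)) stop("salinity must be non-negative")
  if (any(density < 0)) stop("density must be non-negative")
  if (!is.null(pollutant)) {
    if (is.null(names(pollutant)) || any(!nzchar(names(pollutant))))
      stop("pollutant concentrations must be named by metal")
    if (any(unlist(pollutant) < 0, na.rm = TRUE))
      stop("pollutant concentrations must be non-negative")
  }
  structure(list(salinity = salinity, density = density,
                 elevation = elevation, pollutant = pollutant),
            class = "env_conditions")
}

#' Combined growth multiplier MUL
#'
#' Product of the salinity, density and elevation multipliers and, for each
#' metal present in `env`, the hormetic pollutant multiplier. Lies in
#' `[0, 1]`; it is 0 wherever elevation is below the viable minimum, and it
#' reduces to the elevation multiplier alone when the other factors are at
#' their no-stress limits.
#'
#' @param env An [env_conditions()] object (fields may be vectors).
#' @param mp A [multiplier_params()] object.
#' @return Multiplier value(s) in `[0, 1]`.
#' @examples
#' mp <- default_multiplier_params()
#' combined_mul(env_conditions(17.1, 17, 0.1, c(Cr = 5.24)), mp)
#' @export
combined_mul <- function(env, mp) {
  stopifnot(inherits(env, "env_conditions"), inherits(mp, "multiplier_params"))
  out <- multiplier_sigmoid(env$salinity, mp$salinity) *
    multiplier_sigmoid(env$density, mp$density) *
    multiplier_elevation(env$elevation, mp$elevation)
  if (!is.null(env$pollutant)) {
    for (metal in names(env$pollutant)) {
      pp <- mp$pollutant[[metal]]
      if (is.null(pp)) stop("no pollutant parameters for metal '", metal, "'")
      out <- out * multiplier_pollutant(env$pollutant[[metal]], pp)
    }
  }
  pmin(pmax(out, 0), 1)
}
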