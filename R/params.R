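#' Species parameters for the diameter growth model
#'
#' Bundles the species-specific constants of the gap-model growth equation:
#' the height--diameter parabola \eqn{H = b_1 + b_2\,dbh - b_3\,dbh^2}, the
#' maximum size (`Hmax`, `Dmax`), the optimal growth rate `Gopt`, and the
#' trunk-biomass allometry \eqn{Biom = a_1\,dbh^{c_1}}.
#'
#' `b2` and `b3` are always derived from (`Hmax`, `Dmax`, `b1`) via
#' [derive_height_coeffs()] so that the height curve passes through
#' (`Dmax`, `Hmax`) with zero slope.
#'
#' The defaults describe *Rhizophora apiculata* in the Can Gio plantation:
#' breast height 137 cm, maximum height 30 m, maximum dbh 50 cm, and `Gopt`
#' calibrated so that stands growing under the typical multiplier levels of
#' the surveyed plots reach the observed 10--22 cm dbh range by ages 23--40.
#' Trunk allometry coefficients give ~57 kg stem dry mass at dbh 15 cm,
#' consistent with destructive harvest data from the same forest.
#'
#' @param Hmax Maximum tree height (cm).
#' @param Dmax Maximum diameter at breast height (cm).
#' @param b1 Height intercept (cm); the breast height convention.
#' @param Gopt Optimal (unstressed) growth-rate constant of the Botkin
#'   equation, in cm units per year.
#' @param a1_biom,c1_biom Trunk-biomass allometry coefficient (kg) and
#'   exponent (dimensionless).
#' @return An object of class `species_params`.
#' @examples
#' sp <- species_params()
#' height_from_dbh(sp$Dmax, sp) # equals Hmax
#' @export
species_params <- function(Hmax = 3000, Dmax = 50, b1 = 137, Gopt = 700,
                           a1_biom = 0.05, c1_biom = 2.6) {
  stopifnot(is.numeric(Hmax), is.numeric(Dmax), is.numeric(b1))
  if (Dmax <= 0) stop("Dmax must be positive")
  if (b1 <= 0) stop("b1 must be positive")
  if (Hmax <= b1) stop("Hmax must exceed b1")
  if (Gopt <= 0) stop("Gopt must be positive")
  if (a1_biom <= 0 || c1_biom <= 0) stop("biomass allometry coefficients must be positive")
  bb <- derive_height_coeffs(Hmax, Dmax, b1)
  structure(
    list(Hmax = Hmax, Dmax = Dmax, b1 = b1, b2 = bb[["b2"]], b3 = bb[["b3"]],
         Gopt = Gopt, a1_biom = a1_biom, c1_biom = c1_biom),
    class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat("Species parameters (gap-model growth)\n")
  cat(sprintf("  Hmax %.0f cm, Dmax %.1f cm, b1 %.1f cm (b2 %.3f, b3 %.5f)\n",
              x$Hmax, x$Dmax, x$b1, x$b2, x$b3))
  cat(sprintf("  Gopt %.1f, trunk biomass %.4g * dbh^%.3g kg\n",
              x$Gopt, x$a1_biom, x$c1_biom))
  invisible(x)
}

#' Sigmoid response-function parameters (salinity, tree density)
#'
#' Parameters of the decreasing sigmoid multiplier
#' \eqn{g(x) = (1 - a_0) / (1 + e^{d (x - tr)}) + a_0}: growth is near the
#' optimum below the threshold `tr`, declines with slope controlled by `d`,
#' and levels off at the asymptotic floor `a0` so that some growth persists
#' even under strong stress.
#'
#' @param a0 Asymptotic floor, in `[0, 1)`.
#' @param d Slope (per unit of the covariate), positive. The multiplier is
#'   decreasing in the covariate; a negative printed slope in legacy
#'   parameter tables is interpreted as its magnitude.
#' @param tr Threshold (ppt for salinity, trees per 100 m^2 for density).
#' @return An object of class `sigmoid_params`.
#' @export
sigmoid_params <- function(a0, d, tr) {
  if (a0 < 0 || a0 >= 1) stop("a0 must lie in [0, 1)")
  d <- abs(d)
  if (d <= 0) stop("d must be non-zero")
  if (tr <= 0) stop("tr must be positive")
  structure(list(a0 = a0, d = d, tr = tr), class = "sigmoid_params")
}

#' Elevation response-function parameters
#'
#' The elevation multiplier is a rise--plateau--fall product
#' \deqn{f(el) = \{a_{1e} + (a_{max} - a_{1e}) R(el)\}\,
#'               \{a_{2e} + (1 - a_{2e}) F(el)\}}
#' with rising limb \eqn{R(el) = 1 - \exp[-((el - el_{min})/el_1)^\alpha]}
#' and falling limb \eqn{F(el) = \exp[-((el - el_{min})/el_2)^\beta]}.
#' It equals `a1e` at `el = elmin` (where `R = 0`, `F = 1`), tends to
#' `amax * a2e` as elevation grows, reaches an interior plateau bounded by
#' `amax`, and is set to zero below the minimum viable elevation `elmin`.
#'
#' @param a1e Low-elevation floor (value at `elmin`), in `[0, amax]`.
#' @param el1 Scale length of the rising limb (m); a negative value is
#'   interpreted as its magnitude.
#' @param alpha Shape exponent of the rising limb, positive.
#' @param el2 Scale length of the falling limb (m).
#' @param beta Shape exponent of the falling limb, positive.
#' @param a2e High-elevation floor, in `[0, amax]`.
#' @param amax Plateau ceiling, in `(0, 1]`.
#' @param elmin Minimum viable elevation (m); the multiplier is 0 below it.
#' @return An object of class `elevation_params`.
#' @export
elevation_params <- function(a1e, el1, alpha, el2, beta, a2e,
                             amax = 1, elmin = -1) {
  el1 <- abs(el1)
  if (amax <= 0 || amax > 1) stop("amax must lie in (0, 1]")
  if (a1e < 0 || a1e > amax) stop("a1e must lie in [0, amax]")
  if (a2e < 0 || a2e > amax) stop("a2e must lie in [0, amax]")
  if (el1 <= 0 || el2 <= 0) stop("scale lengths must be positive")
  if (alpha <= 0 || beta <= 0) stop("shape exponents must be positive")
  structure(list(a1e = a1e, el1 = el1, alpha = alpha, el2 = el2,
                 beta = beta, a2e = a2e, amax = amax, elmin = elmin),
            class = "elevation_params")
}

#' Pollutant (hormetic) response-function parameters
#'
#' Parameters of the two-threshold dose--response
#' \eqn{P(x) = (1 - e^{-(x/th_1)^{\alpha_1}})\,e^{-(x/th_2)^{\alpha_2}}}
#' applied to root metal concentration `x` (mg/kg dry weight). Below `th1`
#' growth is stimulated with increasing dose (hormesis); beyond `th2` the
#' decay term dominates and growth is suppressed towards zero.
#'
#' @param metal Metal identifier, e.g. `"Cr"`, `"Cu"`, `"Ni"`.
#' @param th1,th2 Lower and upper thresholds (mg/kg root DW), `0 < th1 < th2`.
#' @param alpha1,alpha2 Form factors, positive.
#' @return An object of class `pollutant_params`.
#' @export
pollutant_params <- function(metal, th1, th2, alpha1, alpha2) {
  if (!(th1 > 0 && th2 > th1)) stop("thresholds must satisfy 0 < th1 < th2")
  if (alpha1 <= 0 || alpha2 <= 0) stop("form factors must be positive")
  structure(list(metal = metal, th1 = th1, th2 = th2,
                 alpha1 = alpha1, alpha2 = alpha2),
            class = "pollutant_params")
}

#' Full multiplier parameter set
#'
#' Collects the response-function parameters for all four environmental
#' factors. [default_multiplier_params()] returns the set estimated from the
#' Can Gio plantation survey (the same survey whose 11-site tables ship as
#' package fixtures), which drives all package defaults.
#'
#' @param salinity,density [sigmoid_params()] objects.
#' @param elevation An [elevation_params()] object.
#' @param pollutant A named list of [pollutant_params()] objects, keyed by
#'   metal; may be empty.
#' @return An object of class `multiplier_params`.
#' @export
multiplier_params <- function(salinity, density, elevation, pollutant = list()) {
  stopifnot(inherits(salinity, "sigmoid_params"),
            inherits(density, "sigmoid_params"),
            inherits(elevation, "elevation_params"))
  if (length(pollutant)) {
    ok <- vapply(pollutant, inherits, logical(1), "pollutant_params")
    if (!all(ok)) stop("pollutant must be a list of pollutant_params")
    names(pollutant) <- vapply(pollutant, `[[`, character(1), "metal")
  }
  structure(list(salinity = salinity, density = density,
                 elevation = elevation, pollutant = pollutant),
            class = "multiplier_params")
}

#' @rdname multiplier_params
#' @export
default_multiplier_params <- function() {
  multiplier_params(
    salinity  = sigmoid_params(a0 = 0.21276, d = 0.4, tr = 11.348),
    density   = sigmoid_params(a0 = 0.402741, d = 0.156347, tr = 66.9241),
    elevation = elevation_params(a1e = 0.027, el1 = 0.96, alpha = 13.1,
                                 el2 = 1.48, beta = 6.02, a2e = 0.11,
                                 amax = 1, elmin = -1),
    pollutant = list(
      Cu = pollutant_params("Cu", th1 = 3.28, th2 = 54.47,
                            alpha1 = 0.68, alpha2 = 0.81),
      Cr = pollutant_params("Cr", th1 = 1.89, th2 = 170.25,
                            alpha1 = 0.12, alpha2 = 1.69),
      Ni = pollutant_params("Ni", th1 = 0.53, th2 = 105.43,
                            alpha1 = 0.06, alpha2 = 2.53)))
}

#' @export
print.multiplier_params <- function(x, ...) {
  cat("Environmental multiplier parameters\n")
  cat(sprintf("  salinity : a0 %.4g, d %.4g, tr %.4g ppt\n",
              x$salinity$a0, x$salinity$d, x$salinity$tr))
  cat(sprintf("  density  : a0 %.4g, d %.4g, tr %.4g /100m2\n",
              x$density$a0, x$density$d, x$density$tr))
  e <- x$elevation
  cat(sprintf("  elevation: a1e %.3g, el1 %.3g, alpha %.3g, el2 %.3g, beta %.3g, a2e %.3g (amax %.2g, elmin %.2g m)\n",
              e$a1e, e$el1, e$alpha, e$el2, e$beta, e$a2e, e$amax, e$elmin))
  for (p in x$pollutant)
    cat(sprintf("  pollutant %s: th1 %.4g, th2 %.4g, alpha1 %.3g, alpha2 %.3g\n",
                p$metal, p$th1, p$th2, p$alpha1, p$alpha2))
  invisible(x)
}

#' Read and write parameter configuration files
#'
#' Parameter sets are serialized as YAML with top-level keys `species`,
#' `salinity`, `density`, `elevation` and `pollutant.<metal>`, so a fitted
#' parameter set written by [write_params()] can be read back and fed to the
#' growth model unchanged (lossless round trip).
#'
#' @param path File path.
#' @param sp A [species_params()] object.
#' @param mp A [multiplier_params()] object.
#' @return `read_params()` returns `list(species =, multipliers =)`;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(path, sp, mp) {
  stopifnot(inherits(sp, "species_params"), inherits(mp, "multiplier_params"))
  obj <- list(
    species = sp[c("Hmax", "Dmax", "b1", "Gopt", "a1_biom", "c1_biom")],
    salinity = unclass(mp$salinity),
    density = unclass(mp$density),
    elevation = unclass(mp$elevation),
    pollutant = lapply(mp$pollutant, function(p)
      unclass(p)[c("metal", "th1", "th2", "alpha1", "alpha2")]))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  obj <- yaml::read_yaml(path)
  for (key in c("species", "salinity", "density", "elevation"))
    if (is.null(obj[[key]])) stop("parameter file lacks section '", key, "'")
  sp <- do.call(species_params, obj$species)
  mp <- multiplier_params(
    salinity = do.call(sigmoid_params, obj$salinity),
    density = do.call(sigmoid_params, obj$density),
    elevation = do.call(elevation_params, obj$elevation),
    pollutant = lapply(obj$pollutant %||% list(), function(p)
      do.call(pollutant_params, p)))
  list(species = sp, multipliers = mp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
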