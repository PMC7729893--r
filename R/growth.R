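#' Height-curve coefficients from maximum size
#'
#' Returns the parabola coefficients `(b2, b3)` such that the height curve
#' \eqn{H = b_1 + b_2\,dbh - b_3\,dbh^2} attains `Hmax` at `dbh = Dmax` with
#' zero slope there: \eqn{b_2 = 2(H_{max}-b_1)/D_{max}},
#' \eqn{b_3 = (H_{max}-b_1)/D_{max}^2}.
#'
#' @param Hmax Maximum height (cm).
#' @param Dmax Maximum dbh (cm).
#' @param b1 Height at dbh = 0, i.e. breast height (cm).
#' @return Named numeric vector `c(b2 =, b3 =)`.
#' @export
derive_height_coeffs <- function(Hmax, Dmax, b1) {
  if (Dmax <= 0) stop("Dmax must be positive")
  if (Hmax <= b1) stop("Hmax must exceed b1")
  c(b2 = 2 * (Hmax - b1) / Dmax, b3 = (Hmax - b1) / Dmax^2)
}

#' Tree height from diameter
#'
#' Evaluates \eqn{H = b_1 + b_2\,dbh - b_3\,dbh^2}, which increases
#' monotonically from `b1` at dbh 0 to `Hmax` at `Dmax`.
#'
#' @param dbh Diameter at breast height (cm), in `[0, Dmax]`. Vectorized.
#' @param sp A [species_params()] object.
#' @return Height (cm).
#' @export
height_from_dbh <- function(dbh, sp) {
  stopifnot(inherits(sp, "species_params"))
  if (any(dbh < 0) || any(dbh > sp$Dmax))
    stop("dbh must lie in [0, Dmax]")
  sp$b1 + sp$b2 * dbh - sp$b3 * dbh^2
}

#' Trunk biomass from diameter
#'
#' Power-law allometry \eqn{Biom = a_1\,dbh^{c_1}} for stem dry weight.
#'
#' @param dbh Diameter at breast height (cm), non-negative. Vectorized.
#' @param sp A [species_params()] object.
#' @return Trunk dry biomass (kg).
#' @export
trunk_biomass <- function(dbh, sp) {
  stopifnot(inherits(sp, "species_params"))
  if (any(dbh < 0)) stop("dbh must be non-negative")
  sp$a1_biom * dbh^sp$c1_biom
}

#' Right-hand side of the diameter growth equation
#'
#' The Botkin gap-model growth rate
#' \deqn{\frac{d\,dbh}{dt} = G_{opt}\; \frac{dbh\,\{1 - dbh\,H /
#'   (D_{max} H_{max})\}}{2 b_1 + 3 b_2\,dbh - 4 b_3\,dbh^2}\; MUL}
#' with `H` given by [height_from_dbh()]. The numerator vanishes at
#' `dbh = Dmax` (since then `dbh * H = Dmax * Hmax`), so `Dmax` is the
#' asymptotic size; the rate scales linearly in the environmental
#' multiplier `mul`.
#'
#' @param dbh Diameter (cm), in `[0, Dmax]`. Vectorized.
#' @param sp A [species_params()] object.
#' @param mul Environmental multiplier in `[0, 1]` (scalar or same length
#'   as `dbh`).
#' @return Diameter increment rate (cm/yr).
#' @export
growth_rhs <- function(dbh, sp, mul = 1) {
  stopifnot(inherits(sp, "species_params"))
  if (any(dbh < 0) || any(dbh > sp$Dmax)) stop("dbh must lie in [0, Dmax]")
  if (any(mul < 0) || any(mul > 1)) stop("mul must lie in [0, 1]")
  denom <- 2 * sp$b1 + 3 * sp$b2 * dbh - 4 * sp$b3 * dbh^2
  if (any(denom <= 0))
    stop("invalid species parameters: growth denominator non-positive on [0, Dmax]")
  H <- sp$b1 + sp$b2 * dbh - sp$b3 * dbh^2
  sp$Gopt * mul * dbh * (1 - dbh * H / (sp$Dmax * sp$Hmax)) / denom
}

# bare rhs used internally: G already folded in (G = Gopt * mul), no checks
.growth_rate <- function(dbh, sp, G) {
  H <- sp$b1 + sp$b2 * dbh - sp$b3 * dbh^2
  G * dbh * (1 - dbh * H / (sp$Dmax * sp$Hmax)) /
    (2 * sp$b1 + 3 * sp$b2 * dbh - 4 * sp$b3 * dbh^2)
}

#' Integrate the diameter growth equation
#'
#' Grows a tree from `dbh0` for `years` years under an environmental
#' multiplier that is held piecewise-constant over each year (a scalar `mul`
#' applies to the whole run). Integration uses an adaptive solver
#' ([deSolve::ode()], `lsoda`) with annual reporting steps.
#'
#' @param dbh0 Initial diameter (cm), positive (seedling default 0.5 cm at
#'   planting).
#' @param years Number of years (non-negative integer).
#' @param sp A [species_params()] object.
#' @param mul Multiplier in `[0, 1]`: either a scalar or a vector of length
#'   `years` giving the annual values.
#' @return Numeric vector of length `years + 1`: the dbh trajectory at
#'   integer years `0..years`. Non-decreasing and bounded by `Dmax`.
#' @examples
#' sp <- species_params()
#' dbh <- grow_tree(0.5, 40, sp, mul = 0.4)
#' tail(dbh, 1)
#' @export
grow_tree <- function(dbh0, years, sp, mul = 1) {
  stopifnot(inherits(sp, "species_params"))
  if (dbh0 <= 0 || dbh0 > sp$Dmax) stop("dbh0 must lie in (0, Dmax]")
  if (years < 0) stop("years must be non-negative")
  years <- as.integer(years)
  if (years == 0) return(dbh0)
  if (!(length(mul) %in% c(1L, years))) stop("mul must be scalar or length 'years'")
  if (any(mul < 0) || any(mul > 1)) stop("mul must lie in [0, 1]")

  deriv <- function(t, y, p) list(.growth_rate(min(y, sp$Dmax), sp, p))
  if (length(mul) == 1L) {
    out <- deSolve::ode(c(dbh = dbh0), times = 0:years, func = deriv,
                        parms = sp$Gopt * mul, rtol = 1e-9, atol = 1e-10)
    traj <- as.numeric(out[, "dbh"])
  } else {
    traj <- numeric(years + 1L)
    traj[1L] <- dbh0
    for (i in seq_len(years)) {
      out <- deSolve::ode(c(dbh = traj[i]), times = c(0, 1), func = deriv,
                          parms = sp$Gopt * mul[i], rtol = 1e-9, atol = 1e-10)
      traj[i + 1L] <- out[2L, "dbh"]
    }
  }
  pmin(pmax(traj, dbh0), sp$Dmax)
}
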