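#' Extract the lifetime growth rate G from an inventory record
#'
#' Under a constant multiplier the growth equation is separable, so the
#' constant \eqn{G = G_{opt} \cdot MUL} that carries a tree from `dbh0` to
#' `dbh_age` in `age` years is
#' \deqn{G = \frac{1}{age} \int_{dbh_0}^{dbh_{age}}
#'   \frac{2 b_1 + 3 b_2 x - 4 b_3 x^2}{x\,\{1 - x H(x)/(D_{max} H_{max})\}}
#'   \, dx,}
#' evaluated by adaptive quadrature to relative tolerance 1e-10. This exact
#' inversion replaces root-finding on forward simulations; the two routes
#' agree to better than 1e-6 relative (see the package tests, which compare
#' against the ODE integrator of [grow_tree()]).
#'
#' @param dbh0 Diameter at planting (cm), positive.
#' @param dbh_age Diameter at measurement (cm); must be below `Dmax`.
#' @param age Stand age (yr), positive.
#' @param sp A [species_params()] object.
#' @return The growth rate `G` (same units as `Gopt`). If
#'   `dbh_age <= dbh0`, returns 0 with a warning.
#' @examples
#' sp <- species_params()
#' extract_G(0.5, 18.62, 26, sp)
#' @export
extract_G <- function(dbh0, dbh_age, age, sp) {
  stopifnot(inherits(sp, "species_params"))
  if (age <= 0) stop("age must be positive")
  if (dbh0 <= 0) stop("dbh0 must be positive")
  if (dbh_age >= sp$Dmax)
    stop("dbh_age must be below Dmax: no finite G reaches the asymptote")
  if (dbh_age <= dbh0) {
    warning("dbh_age <= dbh0: returning G = 0")
    return(0)
  }
  integrand <- function(x) {
    H <- sp$b1 + sp$b2 * x - sp$b3 * x^2
    (2 * sp$b1 + 3 * sp$b2 * x - 4 * sp$b3 * x^2) /
      (x * (1 - x * H / (sp$Dmax * sp$Hmax)))
  }
  val <- stats::integrate(integrand, dbh0, dbh_age, rel.tol = 1e-10,
                          subdivisions = 500L)$value
  val / age
}

#' Extract G for every plot of an inventory table
#'
#' Convenience wrapper applying [extract_G()] row-wise to a plot table and
#' returning the table with a `G` column appended (overwritten if present).
#'
#' @param plots Plot inventory data frame with columns `mean_dbh` and `age`.
#' @param sp A [species_params()] object.
#' @param dbh0 Diameter at planting (cm).
#' @return `plots` with a numeric `G` column.
#' @export
extract_G_plots <- function(plots, sp, dbh0 = 0.5) {
  need <- c("mean_dbh", "age")
  miss <- setdiff(need, names(plots))
  if (length(miss)) stop("plots lacks column(s): ", paste(miss, collapse = ", "))
  plots$G <- vapply(seq_len(nrow(plots)), function(i)
    extract_G(dbh0, plots$mean_dbh[i], plots$age[i], sp), numeric(1))
  plots
}

# env_conditions built from plot-table columns; pollutant taken from any
# root_<metal> column that has matching parameters in mp
.env_from_plots <- function(plots, mp) {
  pol <- NULL
  if (length(mp$pollutant)) {
    cols <- paste0("root_", names(mp$pollutant))
    have <- cols %in% names(plots)
    if (any(have)) {
      pol <- lapply(cols[have], function(cl) plots[[cl]])
      names(pol) <- names(mp$pollutant)[have]
    }
  }
  env_conditions(plots$salinity, plots$density, plots$elevation, pol)
}

#' Stratified fit/validation split of an inventory
#'
#' Splits plots into a fitting and a validation set by stratified sampling
#' over the terciles of salinity, elevation and density (so the fitting set
#' spans all covariate gradients), allocating the fitting quota to strata by
#' largest remainder.
#'
#' @param plots Plot inventory data frame with columns `salinity`,
#'   `elevation`, `density`.
#' @param n_fit Number of plots in the fitting set.
#' @param seed Optional integer seed for reproducible sampling.
#' @return List with integer row indices `fit` and `validate`.
#' @export
stratified_split <- function(plots, n_fit = 76, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(plots)
  if (n_fit < 1 || n_fit >= n) stop("n_fit must lie in [1, nrow(plots) - 1]")
  terc <- function(x) {
    q <- stats::quantile(x, c(1 / 3, 2 / 3), names = FALSE)
    findInterval(x, q) + 1L
  }
  strata <- interaction(terc(plots$salinity), terc(plots$elevation),
                        terc(plots$density), drop = TRUE)
  tab <- table(strata)
  quota <- as.numeric(tab) * n_fit / n
  take <- floor(quota)
  rem <- n_fit - sum(take)
  if (rem > 0) {
    ord <- order(quota - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
  }
  take <- pmin(take, as.numeric(tab))
  idx <- unlist(lapply(seq_along(tab), function(k) {
    rows <- which(strata == names(tab)[k])
    if (take[k] >= length(rows)) rows else sample(rows, take[k])
  }), use.names = FALSE)
  # top up from the remainder if capping left the quota unfilled
  if (length(idx) < n_fit) {
    pool <- setdiff(seq_len(n), idx)
    idx <- c(idx, sample(pool, n_fit - length(idx)))
  }
  list(fit = sort(idx), validate = setdiff(seq_len(n), idx))
}

# parameter packing tables: name, lower, upper per free component ---------

.pack_spec <- function(free, plots, sp, start) {
  rngs <- list()
  add <- function(rngs, comp, par, lower, upper, init) {
    rngs[[length(rngs) + 1L]] <- list(comp = comp, par = par, lower = lower,
                                      upper = upper, init = init)
    rngs
  }
  if ("salinity" %in% free) {
    hi <- 2 * max(plots$salinity)
    s <- start$salinity
    rngs <- add(rngs, "salinity", "a0", 0, 0.95, s$a0)
    rngs <- add(rngs, "salinity", "d", 1e-3, 10, s$d)
    rngs <- add(rngs, "salinity", "tr", 0.01, hi, s$tr)
  }
  if ("density" %in% free) {
    hi <- 2 * max(plots$density)
    s <- start$density
    rngs <- add(rngs, "density", "a0", 0, 0.95, s$a0)
    rngs <- add(rngs, "density", "d", 1e-3, 10, s$d)
    rngs <- add(rngs, "density", "tr", 0.01, hi, s$tr)
  }
  if ("elevation" %in% free) {
    e <- start$elevation
    rngs <- add(rngs, "elevation", "a1e", 0, e$amax, e$a1e)
    rngs <- add(rngs, "elevation", "el1", 0.05, 10, e$el1)
    rngs <- add(rngs, "elevation", "alpha", 0.5, 30, e$alpha)
    rngs <- add(rngs, "elevation", "el2", 0.05, 10, e$el2)
    rngs <- add(rngs, "elevation", "beta", 0.5, 30, e$beta)
    rngs <- add(rngs, "elevation", "a2e", 0, e$amax, e$a2e)
  }
  if ("pollutant" %in% free) {
    for (metal in names(start$pollutant)) {
      if (!paste0("root_", metal) %in% names(plots)) next
      p <- start$pollutant[[metal]]
      rngs <- add(rngs, paste0("pollutant.", metal), "th1", 1e-3, 100, p$th1)
      rngs <- add(rngs, paste0("pollutant.", metal), "th2", 1, 2000, p$th2)
      rngs <- add(rngs, paste0("pollutant.", metal), "alpha1", 0.01, 5, p$alpha1)
      rngs <- add(rngs, paste0("pollutant.", metal), "alpha2", 0.01, 10, p$alpha2)
    }
  }
  if ("gopt" %in% free) {
    gmax <- max(plots$G)
    rngs <- add(rngs, "gopt", "gopt", 0.5 * gmax, 20 * gmax,
                min(max(sp$Gopt, 0.5 * gmax), 20 * gmax))
  }
  do.call(rbind, lapply(rngs, as.data.frame))
}

.unpack <- function(theta, spec, start) {
  mp <- start
  gopt <- NULL
  for (i in seq_len(nrow(spec))) {
    comp <- spec$comp[i]; par <- spec$par[i]; val <- theta[i]
    if (comp == "gopt") {
      gopt <- val
    } else if (startsWith(comp, "pollutant.")) {
      metal <- sub("^pollutant\\.", "", comp)
      mp$pollutant[[metal]][[par]] <- val
    } else {
      mp[[comp]][[par]] <- val
    }
  }
  list(mp = mp, gopt = gopt)
}

#' Fit multiplier parameters to extracted growth rates
#'
#' Estimates the environmental response-function parameters by nonlinear
#' least squares on the model \eqn{G_i = G_{opt}\,MUL(env_i;\theta)}, i.e.
#' minimising \eqn{\sum_i (G_i - G_{opt} MUL_i)^2} with a bounded
#' Levenberg--Marquardt optimizer ([minpack.lm::nls.lm()]). To guard against
#' local minima the fit is multi-started: the supplied `start` values plus
#' `n_starts - 1` random draws within the parameter bounds; the run with the
#' lowest residual sum of squares wins (ties broken by the smaller parameter
#' norm).
#'
#' Estimation is staged by choosing `free`: components not listed are held
#' at their `start` values. The default frees the salinity and density
#' sigmoids plus `Gopt`, with the elevation response held at its shipped
#' calibration; add `"elevation"` or `"pollutant"` to free those too
#' (pollutant components require `root_<metal>` columns in `plots`).
#'
#' @param plots Plot table with columns `G` (from [extract_G_plots()]),
#'   `salinity`, `density`, `elevation`, and optionally `root_<metal>`.
#' @param sp A [species_params()] object (its `Gopt` seeds the `gopt`
#'   start).
#' @param gopt If a number, `Gopt` is fixed at this value; if `NULL`
#'   (default) it is estimated jointly.
#' @param start A [multiplier_params()] object providing starting values and
#'   the values of non-free components.
#' @param free Character vector among `"salinity"`, `"density"`,
#'   `"elevation"`, `"pollutant"`; `"gopt"` is appended automatically when
#'   `gopt` is `NULL`.
#' @param n_starts Number of multi-starts (>= 1).
#' @param seed Optional seed for the random starts.
#' @return An object of class `mul_fit`: fitted `multipliers`
#'   (a full [multiplier_params()] set), `gopt`, `rss`, `r2`, `n`,
#'   coefficient table `coef` (estimate, se), covariance `vcov` of the free
#'   parameters, and bookkeeping fields.
#' @export
fit_multipliers <- function(plots, sp, gopt = NULL,
                            start = default_multiplier_params(),
                            free = c("salinity", "density"),
                            n_starts = 8, seed = NULL) {
  stopifnot(inherits(sp, "species_params"), inherits(start, "multiplier_params"))
  if (!"G" %in% names(plots))
    stop("plots needs a 'G' column; run extract_G_plots() first")
  free <- match.arg(free, c("salinity", "density", "elevation", "pollutant"),
                    several.ok = TRUE)
  if (is.null(gopt)) free <- c(free, "gopt")

  covar_of <- c(salinity = "salinity", density = "density",
                elevation = "elevation")
  for (comp in intersect(free, names(covar_of))) {
    x <- plots[[covar_of[[comp]]]]
    if (is.null(x)) stop("plots lacks column '", covar_of[[comp]], "'")
    if (stats::sd(x) == 0)
      stop("covariate '", covar_of[[comp]], "' is constant: the ",
           comp, " response is not identifiable")
  }
  spec <- .pack_spec(free, plots, sp, start)
  if (is.null(spec) || nrow(spec) == 0) stop("no free parameters to fit")
  if (nrow(plots) < nrow(spec))
    stop("need at least as many plots as free parameters (",
         nrow(spec), ")")

  G <- plots$G
  resid_fun <- function(theta) {
    u <- .unpack(theta, spec, start)
    g0 <- if (is.null(u$gopt)) gopt else u$gopt
    G - g0 * combined_mul(.env_from_plots(plots, u$mp), u$mp)
  }

  if (!is.null(seed)) set.seed(seed)
  starts <- vector("list", n_starts)
  starts[[1L]] <- spec$init
  if (n_starts > 1)
    for (k in 2:n_starts)
      starts[[k]] <- stats::runif(nrow(spec), spec$lower, spec$upper)

  best <- NULL
  for (th0 in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = pmin(pmax(th0, spec$lower), spec$upper), fn = resid_fun,
      lower = spec$lower, upper = spec$upper,
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) ||
        fit$deviance < best$deviance - 1e-12 ||
        (abs(fit$deviance - best$deviance) <= 1e-12 &&
         sum(fit$par^2) < sum(best$par^2))) {
      best <- fit
    }
  }
  if (is.null(best)) stop("all optimizer starts failed")

  u <- .unpack(best$par, spec, start)
  g0 <- if (is.null(u$gopt)) gopt else u$gopt
  rss <- best$deviance
  r2 <- 1 - rss / sum((G - mean(G))^2)

  cf <- data.frame(component = spec$comp, parameter = spec$par,
                   estimate = best$par, se = NA_real_)
  vc <- NULL
  dof <- length(G) - nrow(spec)
  if (dof > 0) {
    sigma2 <- rss / dof
    hinv <- try(solve(best$hessian), silent = TRUE)
    if (!inherits(hinv, "try-error")) {
      vc <- 2 * sigma2 * hinv   # hessian approximates 2 J'J
      cf$se <- sqrt(pmax(diag(vc), 0))
      dimnames(vc) <- list(paste(spec$comp, spec$par, sep = "."),
                           paste(spec$comp, spec$par, sep = "."))
    }
  }

  structure(list(multipliers = u$mp, gopt = g0, rss = rss, r2 = r2,
                 n = length(G), coef = cf, vcov = vc, free = free,
                 spec = spec, start = start,
                 converged = best$info %in% 1:4),
            class = "mul_fit")
}

#' @export
print.mul_fit <- function(x, ...) {
  cat(sprintf("Multiplier fit: n = %d plots, RSS = %.4g, R^2 = %.4f, Gopt = %.4g\n",
              x$n, x$rss, x$r2, x$gopt))
  cat("Free components:", paste(x$free, collapse = ", "), "\n")
  print(x$coef, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Predict growth rates with pointwise confidence bands
#'
#' Predicted \eqn{\hat G = \hat G_{opt}\,MUL(env;\hat\theta)} with optional
#' 95% pointwise bands from the delta method (numeric gradient of the
#' prediction with respect to the free parameters, propagated through the
#' fit covariance).
#'
#' @param object A `mul_fit` object.
#' @param env An [env_conditions()] object (vector fields allowed).
#' @param interval If `TRUE` and a covariance is available, add `lwr`/`upr`.
#' @param ... Unused.
#' @return A data frame with column `fit` and optionally `lwr`, `upr`.
#' @export
predict.mul_fit <- function(object, env, interval = FALSE, ...) {
  pred_at <- function(theta) {
    u <- .unpack(theta, object$spec, object$start)
    g0 <- if (is.null(u$gopt)) object$gopt else u$gopt
    g0 * combined_mul(env, u$mp)
  }
  theta_hat <- object$coef$estimate
  fit <- pred_at(theta_hat)
  out <- data.frame(fit = fit)
  if (interval && !is.null(object$vcov)) {
    eps <- pmax(abs(theta_hat), 1e-3) * 1e-5
    Jc <- vapply(seq_along(theta_hat), function(j) {
      tp <- theta_hat; tp[j] <- tp[j] + eps[j]
      (pred_at(tp) - fit) / eps[j]
    }, numeric(length(fit)))
    Jc <- matrix(Jc, nrow = length(fit))
    se <- sqrt(pmax(rowSums((Jc %*% object$vcov) * Jc), 0))
    out$lwr <- fit - 1.96 * se
    out$upr <- fit + 1.96 * se
  }
  out
}

#' Validate a fitted parameter set on held-out plots
#'
#' For each validation plot, predicts dbh at the plot's age by integrating
#' the growth equation from the seedling diameter under the fitted
#' multiplier, and reports the coefficient of determination of predicted
#' versus observed dbh.
#'
#' @param plots Held-out plot table (columns `mean_dbh`, `age`, `salinity`,
#'   `density`, `elevation`, optionally `root_<metal>`).
#' @param fit A `mul_fit` object.
#' @param sp A [species_params()] object.
#' @param dbh0 Diameter at planting (cm).
#' @return List with `r2` and a `table` data frame (observed, predicted).
#' @export
validate_fit <- function(plots, fit, sp, dbh0 = 0.5) {
  stopifnot(inherits(fit, "mul_fit"), inherits(sp, "species_params"))
  if (nrow(plots) == 0) stop("validation set is empty")
  mul <- combined_mul(.env_from_plots(plots, fit$multipliers), fit$multipliers)
  sp2 <- sp
  sp2$Gopt <- fit$gopt
  pred <- vapply(seq_len(nrow(plots)), function(i) {
    traj <- grow_tree(dbh0, plots$age[i], sp2, mul = min(mul[i], 1))
    traj[length(traj)]
  }, numeric(1))
  obs <- plots$mean_dbh
  r2 <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  list(r2 = r2,
       table = data.frame(plot_id = plots$plot_id %||% seq_len(nrow(plots)),
                          observed = obs, predicted = pred))
}
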