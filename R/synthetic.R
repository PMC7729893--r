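#' Configuration for the synthetic survey generator
#'
#' Describes the statistical structure of the emulated field survey: 208
#' plots of 10 x 10 m, stand ages 19--40 yr, pore-water salinity about
#' 8--18 ppt, densities 10--115 trees per plot, ground elevation spanning
#' the band in which the species establishes (about -0.5 to 0.5 m), and a
#' 5% multiplicative lognormal observation error on dbh and height.
#'
#' @param n_plots Number of plots.
#' @param salinity_range,elevation_range Uniform covariate ranges.
#' @param density_range Integer range of trees per 100 m^2.
#' @param age_range Integer range of stand ages (yr).
#' @param sigma Relative observation noise on dbh and height (lognormal
#'   sdlog; 0 disables noise).
#' @param dbh0 Diameter at planting (cm).
#' @param sp True [species_params()].
#' @param mp True [multiplier_params()].
#' @param seed Optional integer seed.
#' @return An object of class `survey_config`.
#' @export
survey_config <- function(n_plots = 208,
                          salinity_range = c(8, 18.2),
                          elevation_range = c(-0.5, 0.5),
                          density_range = c(10, 115),
                          age_range = c(19, 40),
                          sigma = 0.05, dbh0 = 0.5,
                          sp = species_params(),
                          mp = default_multiplier_params(),
                          seed = NULL) {
  stopifnot(n_plots >= 1, sigma >= 0,
            diff(salinity_range) > 0, diff(elevation_range) > 0,
            diff(density_range) > 0, diff(age_range) > 0)
  structure(list(n_plots = as.integer(n_plots),
                 salinity_range = salinity_range,
                 elevation_range = elevation_range,
                 density_range = as.integer(density_range),
                 age_range = as.integer(age_range),
                 sigma = sigma, dbh0 = dbh0, sp = sp, mp = mp, seed = seed),
            class = "survey_config")
}

#' Generate a synthetic plot inventory
#'
#' Draws covariates uniformly within the configured ranges, computes the
#' true multiplier and growth rate `G_true = Gopt * MUL` per plot, grows
#' each plot's mean tree from the seedling diameter to its age with
#' [grow_tree()], derives the height from the height--diameter curve, and
#' applies mean-one multiplicative lognormal noise to dbh and height.
#' `G_true` and `mul_true` are retained for parameter-recovery studies.
#'
#' @param cfg A [survey_config()] object.
#' @return Plot inventory data frame with the [read_plot_csv()] schema plus
#'   `G_true` and `mul_true`.
#' @export
generate_inventory <- function(cfg) {
  stopifnot(inherits(cfg, "survey_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_plots
  sal <- stats::runif(n, cfg$salinity_range[1], cfg$salinity_range[2])
  el <- stats::runif(n, cfg$elevation_range[1], cfg$elevation_range[2])
  den <- sample(seq(cfg$density_range[1], cfg$density_range[2]), n,
                replace = TRUE)
  age <- sample(seq(cfg$age_range[1], cfg$age_range[2]), n, replace = TRUE)
  mul <- combined_mul(env_conditions(sal, den, el), cfg$mp)
  dbh_true <- vapply(seq_len(n), function(i) {
    traj <- grow_tree(cfg$dbh0, age[i], cfg$sp, mul = mul[i])
    traj[length(traj)]
  }, numeric(1))
  h_true <- height_from_dbh(dbh_true, cfg$sp)
  s <- cfg$sigma
  noise <- function(k) if (s > 0) stats::rlnorm(k, -s^2 / 2, s) else rep(1, k)
  dbh_obs <- pmin(dbh_true * noise(n), cfg$sp$Dmax * 0.999)
  dbh_obs <- pmax(dbh_obs, cfg$dbh0 * 1.001)
  h_obs <- h_true * noise(n)
  data.frame(plot_id = sprintf("SYN%03d", seq_len(n)),
             age = age, mean_dbh = dbh_obs, mean_height = h_obs,
             density = den, salinity = sal, elevation = el,
             G_true = cfg$sp$Gopt * mul, mul_true = mul)
}

#' Configuration for the synthetic heavy-metal table generator
#'
#' Region-contrasted lognormal concentrations: soil levels drawn per metal
#' around region means (industrially impacted region above the reference
#' region for Cr and Ni, mirroring the surveyed contrast), root and leaf
#' levels as noisy fractions of soil. Iron is generated for all soil rows
#' so enrichment factors can always be computed.
#'
#' @param soil_mean Named list per metal of `c(reference_region, impacted_region)`
#'   soil means (mg/kg).
#' @param cv Lognormal coefficient of variation of soil concentrations.
#' @param root_frac,leaf_frac Mean tissue-to-soil concentration ratios.
#' @param seed Optional integer seed.
#' @return An object of class `hm_config`.
#' @export
hm_config <- function(soil_mean = list(Cu = c(72, 84), Cr = c(4.4, 16.4),
                                       Ni = c(3.0, 9.3),
                                       Fe = c(25000, 25000)),
                      cv = 0.3, root_frac = 0.25, leaf_frac = 0.1,
                      seed = NULL) {
  stopifnot(cv >= 0, root_frac > 0, leaf_frac > 0)
  structure(list(soil_mean = soil_mean, cv = cv, root_frac = root_frac,
                 leaf_frac = leaf_frac, seed = seed),
            class = "hm_config")
}

#' Generate a synthetic heavy-metal survey table
#'
#' @param n_sites Number of sites (split between a reference region
#'   `"CanGio"` and an impacted region `"ThiVai"`).
#' @param cfg An [hm_config()] object.
#' @return Long-format heavy-metal table with soil, root and leaf rows per
#'   site and metal (Fe in soil only), passing the table invariants.
#' @export
generate_hm_table <- function(n_sites, cfg = hm_config()) {
  stopifnot(inherits(cfg, "hm_config"), n_sites >= 1)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_ref <- ceiling(n_sites / 2)
  region <- c(rep("CanGio", n_ref), rep("ThiVai", n_sites - n_ref))
  sdlog <- sqrt(log(1 + cfg$cv^2))
  rows <- list()
  for (i in seq_len(n_sites)) {
    ridx <- if (region[i] == "CanGio") 1L else 2L
    for (metal in names(cfg$soil_mean)) {
      mu <- cfg$soil_mean[[metal]][ridx]
      soil <- stats::rlnorm(1, log(mu) - sdlog^2 / 2, sdlog)
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = sprintf("S%02d", i), region = region[i],
        compartment = "soil", metal = metal, conc = soil)
      if (metal != "Fe") {
        for (tis in c("root", "leaf")) {
          frac <- if (tis == "root") cfg$root_frac else cfg$leaf_frac
          conc <- soil * frac * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
          rows[[length(rows) + 1L]] <- data.frame(
            site_id = sprintf("S%02d", i), region = region[i],
            compartment = tis, metal = metal, conc = conc)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  .check_hm_table(out)
  out
}

#' Configuration for the synthetic raster generator
#'
#' Smooth correlated fields for elevation, salinity and root-Cr plus a
#' binary forest mask, on a square grid of 100 m cells (emulating the
#' spatial inputs of the scenario simulator). Fields are low-pass-filtered
#' Gaussian noise rescaled to the configured ranges; `corr_length` is the
#' lag (m) at which the field autocorrelation falls to 1/e.
#'
#' The default root-Cr range spans from near-background up to levels well
#' beyond the onset of growth inhibition, as a scenario exercise confined
#' to sub-hormetic concentrations would be insensitive to the pollutant
#' load.
#'
#' @param nrow,ncol Grid shape (at least 2 x 2).
#' @param cellsize Cell size (m).
#' @param ranges Named list of `c(min, max)` per layer
#'   (`elevation`, `salinity`, `root_Cr`).
#' @param corr_length Named list of correlation lengths (m) per layer.
#' @param forest_fraction Fraction of cells marked forested.
#' @param seed Optional integer seed.
#' @return An object of class `raster_config`.
#' @export
raster_config <- function(nrow = 30, ncol = 30, cellsize = 100,
                          ranges = list(elevation = c(-0.8, 0.8),
                                        salinity = c(8, 18),
                                        root_Cr = c(5, 250)),
                          corr_length = list(elevation = 500,
                                             salinity = 800,
                                             root_Cr = 600),
                          forest_fraction = 0.7, seed = NULL) {
  stopifnot(nrow >= 2, ncol >= 2, cellsize > 0,
            forest_fraction > 0, forest_fraction <= 1)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 cellsize = cellsize, ranges = ranges,
                 corr_length = corr_length,
                 forest_fraction = forest_fraction, seed = seed),
            class = "raster_config")
}

# separable Gaussian low-pass filter with edge replication
.smooth2d <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  h <- max(1L, ceiling(3 * sd_cells))
  k <- stats::dnorm(seq(-h, h), sd = sd_cells)
  k <- k / sum(k)
  blur1 <- function(x) {
    xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
    as.numeric(stats::filter(xp, k, sides = 2))[(h + 1):(h + length(x))]
  }
  m <- apply(m, 2, blur1)
  t(apply(m, 1, blur1))
}

.rescale <- function(m, rng) {
  lo <- min(m); hi <- max(m)
  if (hi == lo) return(matrix(mean(rng), nrow(m), ncol(m)))
  rng[1] + (m - lo) / (hi - lo) * diff(rng)
}

#' Generate a synthetic raster stack
#'
#' @param cfg A [raster_config()] object.
#' @return Named list of aligned [ascii_grid()] layers: `elevation`,
#'   `salinity`, `root_Cr`, and a 0/1 forest `mask`.
#' @export
generate_rasters <- function(cfg = raster_config()) {
  stopifnot(inherits(cfg, "raster_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  field <- function(corr_m, rng) {
    # autocorrelation of a Gaussian-smoothed white field falls to 1/e at a
    # lag of twice the kernel sd
    sd_cells <- corr_m / (2 * cfg$cellsize)
    raw <- matrix(stats::rnorm(cfg$nrow * cfg$ncol), cfg$nrow, cfg$ncol)
    .rescale(.smooth2d(raw, sd_cells), rng)
  }
  layers <- list(
    elevation = field(cfg$corr_length$elevation, cfg$ranges$elevation),
    salinity = field(cfg$corr_length$salinity, cfg$ranges$salinity),
    root_Cr = field(cfg$corr_length$root_Cr, cfg$ranges$root_Cr))
  mask_field <- .smooth2d(matrix(stats::rnorm(cfg$nrow * cfg$ncol),
                                 cfg$nrow, cfg$ncol),
                          cfg$corr_length$elevation / (2 * cfg$cellsize))
  thr <- stats::quantile(mask_field, 1 - cfg$forest_fraction, names = FALSE)
  mask <- (mask_field >= thr) * 1
  if (sum(mask) == 0) mask[which.max(mask_field)] <- 1
  out <- lapply(c(layers, list(mask = mask)), ascii_grid,
                cellsize = cfg$cellsize)
  out
}
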