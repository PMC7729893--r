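test_that("growth-rate extraction inverts forward simulation", {
  set.seed(202)
  for (i in 1:20) {
    G <- runif(1, 80, 650)
    age <- sample(10:45, 1)
    dbh0 <- runif(1, 0.2, 2)
    sp <- species_params(Gopt = G)
    endpoint <- grow_tree(dbh0, age, sp, mul = 1)[age + 1]
    expect_equal(extract_G(dbh0, endpoint, age, sp), G,
                 tolerance = 1e-5)
  }
})

test_that("extraction is strictly increasing in the measured diameter", {
  g <- vapply(seq(2, 45, 1), function(d)
    extract_G(0.5, d, 30, sp_default), numeric(1))
  expect_true(all(diff(g) > 0))
})

test_that("degenerate extraction inputs are handled", {
  expect_warning(g0 <- extract_G(5, 5, 30, sp_default), "G = 0")
  expect_identical(g0, 0)
  expect_error(extract_G(0.5, sp_default$Dmax, 30, sp_default), "Dmax")
  expect_error(extract_G(0.5, 10, 0, sp_default), "age")
})

test_that("extracted growth rate declines with salinity in the survey", {
  sv <- cangio_survey()
  pl <- extract_G_plots(sv$plots, sp_default)
  expect_lt(stats::cor(pl$G, pl$salinity), -0.5)
  # within the low-density subset the ordering is monotone-negative too
  low <- pl[pl$density <= 20, ]
  expect_lt(stats::cor(low$G, low$salinity), 0)
})

test_that("noiseless synthetic data give exact parameter recovery", {
  cfg <- survey_config(n_plots = 120, sigma = 0, seed = 11)
  inv <- extract_G_plots(generate_inventory(cfg), sp_default)
  fit <- fit_multipliers(inv, sp_default, free = c("salinity", "density"),
                         n_starts = 4, seed = 1)
  truth <- mp_default
  expect_equal(fit$multipliers$salinity$a0, truth$salinity$a0, tolerance = 1e-3)
  expect_equal(fit$multipliers$salinity$d, truth$salinity$d, tolerance = 1e-3)
  expect_equal(fit$multipliers$salinity$tr, truth$salinity$tr, tolerance = 1e-3)
  expect_equal(fit$multipliers$density$a0, truth$density$a0, tolerance = 1e-3)
  expect_equal(fit$multipliers$density$d, truth$density$d, tolerance = 1e-3)
  expect_equal(fit$multipliers$density$tr, truth$density$tr, tolerance = 1e-3)
  expect_equal(fit$gopt, sp_default$Gopt, tolerance = 1e-3)
  expect_gt(fit$r2, 0.999)
})

test_that("rank-deficient designs fail with the covariate named", {
  cfg <- survey_config(n_plots = 40, sigma = 0, seed = 3)
  inv <- extract_G_plots(generate_inventory(cfg), sp_default)
  inv$salinity <- 12
  expect_error(fit_multipliers(inv, sp_default, seed = 1),
               "salinity.*not identifiable")
})

test_that("validation reproduces the training set and rejects noise", {
  cfg <- survey_config(n_plots = 60, sigma = 0, seed = 19)
  inv <- extract_G_plots(generate_inventory(cfg), sp_default)
  fit <- fit_multipliers(inv, sp_default, free = c("salinity", "density"),
                         n_starts = 4, seed = 2)
  v <- validate_fit(inv, fit, sp_default)
  expect_gt(v$r2, 0.999)
  expect_equal(nrow(v$table), 60)

  # negative control: permuting the environments destroys the fit
  shuf <- inv
  set.seed(4)
  perm <- sample(nrow(shuf))
  shuf[c("salinity", "density", "elevation")] <-
    shuf[perm, c("salinity", "density", "elevation")]
  expect_lt(validate_fit(shuf, fit, sp_default)$r2, 0.3)
  expect_error(validate_fit(inv[0, ], fit, sp_default), "empty")
})

test_that("stratified splits are disjoint, exhaustive and sized", {
  cfg <- survey_config(n_plots = 208, sigma = 0.05, seed = 8)
  inv <- generate_inventory(cfg)
  idx <- stratified_split(inv, n_fit = 76, seed = 8)
  expect_length(idx$fit, 76)
  expect_length(idx$validate, 132)
  expect_length(intersect(idx$fit, idx$validate), 0)
  expect_setequal(c(idx$fit, idx$validate), seq_len(208))
  # the fitting set spans the covariate gradients
  expect_gt(diff(range(inv$salinity[idx$fit])), 0.8 * diff(range(inv$salinity)))
})

test_that("prediction bands are pointwise and bracket the fit", {
  cfg <- survey_config(n_plots = 80, sigma = 0.05, seed = 23)
  inv <- extract_G_plots(generate_inventory(cfg), sp_default)
  fit <- fit_multipliers(inv, sp_default, free = c("salinity", "density"),
                         n_starts = 4, seed = 5)
  env <- env_conditions(c(9, 12, 16), c(20, 60, 100), c(0.1, 0.1, 0.1))
  pr <- predict(fit, env, interval = TRUE)
  expect_true(all(pr$lwr <= pr$fit & pr$fit <= pr$upr))
})
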