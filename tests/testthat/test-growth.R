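test_that("height curve coefficients force H(Dmax) = Hmax with zero slope", {
  bb <- derive_height_coeffs(3000, 50, 137)
  expect_equal(unname(bb["b2"]), 2 * 2863 / 50)
  expect_equal(unname(bb["b3"]), 2863 / 2500)

  # stationarity and endpoint identities over random valid parameter sets
  set.seed(101)
  for (i in 1:20) {
    b1 <- runif(1, 50, 200)
    Hmax <- b1 + runif(1, 500, 4000)
    Dmax <- runif(1, 10, 120)
    sp <- species_params(Hmax, Dmax, b1)
    expect_equal(height_from_dbh(Dmax, sp), Hmax, tolerance = 1e-12)
    expect_equal(height_from_dbh(0, sp), b1)
    # analytic derivative b2 - 2 b3 dbh vanishes at Dmax
    expect_equal(sp$b2 - 2 * sp$b3 * Dmax, 0, tolerance = 1e-10)
  }
  expect_error(derive_height_coeffs(100, 50, 100), "Hmax")
})

test_that("height is monotone increasing on [0, Dmax] and domain-checked", {
  grid <- seq(0, sp_default$Dmax, length.out = 200)
  h <- height_from_dbh(grid, sp_default)
  expect_true(all(diff(h) > 0))
  expect_error(height_from_dbh(-1, sp_default), "dbh")
  expect_error(height_from_dbh(sp_default$Dmax + 0.1, sp_default), "dbh")
})

test_that("growth rhs matches the hand-expanded formula and its limits", {
  sp <- sp_default
  expect_equal(growth_rhs(sp$Dmax, sp), 0, tolerance = 1e-12)
  expect_equal(growth_rhs(10, sp, mul = 0), 0)

  # independent arithmetic expansion at dbh = 10, mul = 1
  dbh <- 10
  H <- 137 + (2 * 2863 / 50) * dbh - (2863 / 2500) * dbh^2
  expected <- 700 * dbh * (1 - dbh * H / (50 * 3000)) /
    (2 * 137 + 3 * (2 * 2863 / 50) * dbh - 4 * (2863 / 2500) * dbh^2)
  expect_equal(growth_rhs(10, sp, 1), expected, tolerance = 1e-12)

  # linear scaling in the multiplier
  expect_equal(growth_rhs(10, sp, 0.37), 0.37 * expected, tolerance = 1e-12)
  expect_true(all(growth_rhs(seq(0, 50, 0.5), sp) >= 0))
})

test_that("trunk biomass follows the power law", {
  sp <- species_params(a1_biom = 0.05, c1_biom = 2.6)
  expect_equal(trunk_biomass(0, sp), 0)
  expect_equal(trunk_biomass(1, sp), 0.05)
  expect_equal(trunk_biomass(20, sp), 0.05 * 20^2.6)
  expect_error(trunk_biomass(-1, sp), "non-negative")
})

test_that("diameter trajectories are monotone, bounded and mul-ordered", {
  expect_identical(grow_tree(0.5, 0, sp_default), 0.5)
  traj <- grow_tree(0.5, 40, sp_default, mul = 1)
  expect_length(traj, 41)
  expect_true(all(diff(traj) >= 0))
  expect_true(all(traj <= sp_default$Dmax))

  full <- grow_tree(0.5, 30, sp_default, mul = 1)
  half <- grow_tree(0.5, 30, sp_default, mul = 0.5)
  expect_lt(half[31], full[31])

  # final size monotone non-decreasing in mul over random runs
  set.seed(77)
  for (i in 1:10) {
    m <- sort(runif(2))
    y <- sample(10:50, 1)
    lo <- grow_tree(0.5, y, sp_default, mul = m[1])
    hi <- grow_tree(0.5, y, sp_default, mul = m[2])
    expect_lte(lo[y + 1], hi[y + 1] + 1e-10)
  }
})

test_that("the unstressed trajectory approaches Dmax", {
  traj <- grow_tree(0.5, 200, sp_default, mul = 1)
  expect_equal(traj[201], sp_default$Dmax, tolerance = 1e-3)
})

test_that("adaptive integration agrees with a small-step Euler oracle", {
  sp <- sp_default
  mul <- 0.6
  h <- 1e-3
  d <- 0.5
  for (i in seq_len(40 / h)) d <- d + h * growth_rhs(d, sp, mul)
  traj <- grow_tree(0.5, 40, sp, mul = mul)
  expect_equal(traj[41], d, tolerance = 1e-3)
})

test_that("annual multiplier series are honoured piecewise", {
  muls <- c(rep(1, 5), rep(0.2, 5))
  traj <- grow_tree(0.5, 10, sp_default, mul = muls)
  # first five years match the constant-mul run exactly
  ref <- grow_tree(0.5, 5, sp_default, mul = 1)
  expect_equal(traj[1:6], ref, tolerance = 1e-7)
  expect_error(grow_tree(0.5, 10, sp_default, mul = c(1, 0.5)), "length")
})
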