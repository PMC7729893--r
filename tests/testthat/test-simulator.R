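test_that("initialization is seed-reproducible and densities are uniform", {
  layers <- two_cell_layers()
  cfg <- scenario_config("SC0", seed = 42)
  set.seed(1)
  s1 <- initialize_stands(layers, cfg)
  set.seed(1)
  s2 <- initialize_stands(layers, cfg)
  expect_identical(s1, s2)
  expect_true(all(s1$cohorts$dbh == cfg$dbh0))
  expect_true(all(s1$cohorts$age == 0L))

  # empirical mean per-plot density over many cells within 3 SE of U{10..115}
  big <- list(elevation = ascii_grid(matrix(0.1, 25, 40)),
              salinity = ascii_grid(matrix(10, 25, 40)),
              mask = ascii_grid(matrix(1, 25, 40)))
  set.seed(2)
  st <- initialize_stands(big, cfg)
  per_plot <- st$cohorts$n / (st$cells$area_ha * 100)
  mu <- mean(10:115)
  se <- sd(10:115) / sqrt(length(per_plot))
  expect_lt(abs(mean(per_plot) - mu), 3 * se)

  empty <- list(elevation = ascii_grid(matrix(0, 2, 2)),
                salinity = ascii_grid(matrix(10, 2, 2)),
                mask = ascii_grid(matrix(0, 2, 2)))
  expect_error(initialize_stands(empty, cfg), "mask")
})

test_that("favourable cells outgrow stressed cells under the same seed", {
  layers <- two_cell_layers(sal = c(8, 18), el = c(0.1, 0.45), cr = c(10, 200))
  cfg <- scenario_config("SC0P1", seed = 7)
  set.seed(cfg$seed)
  st <- initialize_stands(layers, cfg)
  for (y in 1:10) st <- step_year(st, cfg, mp_default, sp_default)
  md <- mean_dbh_by_cell(st)
  expect_gt(md[1], md[2])
})

test_that("an emptied cell stays empty with recruitment disabled", {
  layers <- two_cell_layers()
  cfg <- scenario_config("SC0", seed = 3, fecundity = 0)
  set.seed(cfg$seed)
  st <- initialize_stands(layers, cfg)
  st$cohorts <- st$cohorts[0, ]
  st2 <- step_year(st, cfg, mp_default, sp_default)
  expect_identical(nrow(st2$cohorts), 0L)
})

test_that("runs are deterministic, bounded, and zero-year runs are initial", {
  layers <- generate_rasters(raster_config(nrow = 8, ncol = 8, seed = 31))
  cfg <- scenario_config("SC0P1", years = 15, seed = 31)
  r1 <- run_scenario(layers, cfg, mp_default, sp_default)
  r2 <- run_scenario(layers, cfg, mp_default, sp_default)
  expect_identical(r1$final_biomass, r2$final_biomass)
  expect_identical(r1$total_tons, r2$total_tons)

  expect_true(all(r1$final_biomass >= 0))
  expect_true(all(r1$state$cohorts$dbh <= sp_default$Dmax))
  # totals aggregate the per-cell biomass by area
  expect_equal(tail(r1$total_tons, 1),
               sum(r1$final_biomass * r1$cells$area_ha) / 1000)

  r0 <- run_scenario(layers, scenario_config("SC0", years = 0, seed = 31),
                     mp_default, sp_default)
  expect_length(r0$total_tons, 1)
  expect_equal(r0$total_tons[1],
               sum(r0$final_biomass * r0$cells$area_ha) / 1000)
})

test_that("biomass declines with the pollutant scaling in expectation", {
  tot <- sapply(1:4, function(s) {
    layers <- generate_rasters(raster_config(nrow = 12, ncol = 12, seed = s))
    vapply(c("SC0", "SC0P2"), function(nm)
      tail(run_scenario(layers, scenario_config(nm, years = 25, seed = s),
                        mp_default, sp_default)$total_tons, 1), numeric(1))
  })
  expect_gt(mean(tot["SC0", ]), mean(tot["SC0P2", ]))
  expect_true(all(tot["SC0", ] >= tot["SC0P2", ]))
})

test_that("snapshots and outputs are written in exchange formats", {
  layers <- generate_rasters(raster_config(nrow = 6, ncol = 6, seed = 13))
  res <- run_scenario(layers, scenario_config("SC0", years = 8, seed = 13),
                      mp_default, sp_default)
  expect_true(length(res$snapshots) >= 1)
  dir <- file.path(tempdir(), "simout")
  write_scenario(res, dir)
  files <- list.files(dir)
  expect_true(any(grepl("^biomass_SC0_.*\\.asc$", files)))
  expect_true("histogram_SC0.csv" %in% files)
  expect_true("summary_SC0.json" %in% files)
  js <- jsonlite::read_json(file.path(dir, "summary_SC0.json"))
  expect_equal(js$total_tons_final, tail(res$total_tons, 1))
  g <- read_ascii_grid(file.path(dir, files[grepl("\\.asc$", files)][1]))
  expect_identical(dim(g$data), dim(layers$mask$data))
  unlink(dir, recursive = TRUE)
})
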