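test_that("summary statistics use sample sd and handle singleton groups", {
  tab <- data.frame(site_id = c("a", "b", "c", "d"),
                    region = c("R1", "R1", "R1", "R2"),
                    compartment = "soil", metal = "Cu",
                    conc = c(10, 12, 14, 99))
  s <- hm_summarize(tab, by = "region")
  r1 <- s[s$region == "R1", ]
  expect_equal(r1$mean, 12)
  expect_equal(r1$sd, sd(c(10, 12, 14)))
  expect_equal(r1$min, 10)
  expect_equal(r1$max, 14)
  r2 <- s[s$region == "R2", ]
  expect_equal(r2$mean, 99)
  expect_true(is.na(r2$sd))
})

test_that("enrichment factor is a normalised ratio with half-open classes", {
  bg <- shale_background()
  mk <- function(cu, fe) data.frame(
    site_id = "s1", region = "R", compartment = "soil",
    metal = c("Cu", "Fe"), conc = c(cu, fe))
  # sample ratios identical to background: EF = 1, natural
  ef <- enrichment_factor(mk(45, 47200), bg)
  expect_equal(ef$EF, 1)
  expect_identical(ef$class, "natural")
  # doubled metal-to-iron ratio: EF = 2
  ef2 <- enrichment_factor(mk(90, 47200), bg)
  expect_equal(ef2$EF, 2)
  expect_identical(ef2$class, "anthropogenic")
  # class boundaries: [0,1.5) natural, [1.5,5] anthropogenic, (5,) significant
  ef_at <- function(mult) enrichment_factor(mk(45 * mult, 47200), bg)$EF
  expect_identical(enrichment_factor(mk(45 * 1.4999, 47200), bg)$class, "natural")
  expect_identical(enrichment_factor(mk(45 * 1.5, 47200), bg)$class, "anthropogenic")
  expect_identical(enrichment_factor(mk(45 * 5, 47200), bg)$class, "anthropogenic")
  expect_identical(enrichment_factor(mk(45 * 5.001, 47200), bg)$class, "significant")
  expect_equal(ef_at(3), 3)
})

test_that("EF is invariant under common rescaling of a site's concentrations", {
  sv <- cangio_survey(with_synthetic_fe = TRUE)
  ef1 <- enrichment_factor(sv$hm)
  scaled <- sv$hm
  scaled$conc <- scaled$conc * 7.3
  ef2 <- enrichment_factor(scaled)
  expect_equal(ef1$EF, ef2$EF, tolerance = 1e-12)
})

test_that("forward EF on the packaged fixture matches the published values", {
  sv <- cangio_survey(with_synthetic_fe = TRUE)
  ef <- enrichment_factor(sv$hm)
  pl <- sv$plots
  for (m in c("Cu", "Cr", "Ni")) {
    got <- ef$EF[ef$metal == m][match(pl$plot_id, ef$site_id[ef$metal == m])]
    expect_equal(round(got, 2), pl[[paste0("EF_", m)]], tolerance = 0.011)
  }
  # NP1 copper enrichment as printed
  expect_equal(round(ef$EF[ef$site_id == "NP1" & ef$metal == "Cu"], 2), 3.41)
})

test_that("missing reference element yields a per-site error record", {
  sv <- cangio_survey(with_synthetic_fe = TRUE)
  hm <- sv$hm[!(sv$hm$site_id == "M1" & sv$hm$metal == "Fe"), ]
  ef <- enrichment_factor(hm)
  bad <- ef[ef$site_id == "M1", ]
  expect_true(all(!bad$ok))
  expect_true(all(is.na(bad$EF)))
  expect_match(bad$note[1], "Fe")
  expect_true(all(ef$ok[ef$site_id != "M1"]))
})

test_that("bioconcentration ratios divide tissue by soil and flag zeros", {
  sv <- cangio_survey()
  bc <- bioconcentration_ratio(sv$hm)
  np1_cr_root <- bc$ratio[bc$site_id == "NP1" & bc$metal == "Cr" &
                            bc$tissue == "root"]
  expect_equal(np1_cr_root, 1.06 / 4.96, tolerance = 1e-12)

  tab <- data.frame(site_id = "x", region = "R",
                    compartment = c("soil", "root", "leaf"),
                    metal = "Cu", conc = c(5, 5, 0))
  bc2 <- bioconcentration_ratio(tab)
  expect_equal(bc2$ratio[bc2$tissue == "root"], 1)

  tab0 <- data.frame(site_id = "x", region = "R",
                     compartment = c("soil", "root"),
                     metal = "Cu", conc = c(0, 2))
  bc0 <- bioconcentration_ratio(tab0)
  expect_false(bc0$ok)
  expect_true(is.na(bc0$ratio))
})

test_that("heavy-metal tables reject duplicates and negatives", {
  tab <- data.frame(site_id = c("a", "a"), region = "R",
                    compartment = "soil", metal = "Cu", conc = c(1, 2))
  expect_error(hm_summarize(tab, by = character()), "duplicate")
  tab2 <- data.frame(site_id = "a", region = "R", compartment = "soil",
                     metal = "Cu", conc = -1)
  expect_error(hm_summarize(tab2, by = character()), "non-negative")
})
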