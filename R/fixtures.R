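#' The 11-site Can Gio field survey
#'
#' Returns the packaged tables of the 2018 Can Gio / Thi Vai field survey:
#' the heavy-metal concentrations (Cu, Cr, Ni in soil, root and leaf at the
#' 11 sampling sites) and the matching plot inventory records (mean dbh,
#' mean height, density, age, pore-water salinity, extracted growth rate,
#' and soil enrichment factors). Iron was not published for these sites;
#' a *synthetic* soil-Fe column, back-calculated so that forward
#' enrichment-factor computation against the continental-shale background
#' reproduces the published Cu enrichment factors, is returned separately
#' and can be appended for exercising [enrichment_factor()].
#'
#' Packaged files are verified against stored checksums so silent fixture
#' corruption fails loudly.
#'
#' @param with_synthetic_fe If `TRUE`, append the synthetic soil-Fe rows to
#'   the heavy-metal table (they carry `metal = "Fe"`).
#' @return A list with elements `hm` (long-format heavy-metal table, 99
#'   measured rows), `plots` (11 plot records), and `fe_synthetic` (the
#'   synthetic soil-Fe rows).
#' @examples
#' sv <- cangio_survey()
#' nrow(sv$hm) / 9  # 11 sites
#' @export
cangio_survey <- function(with_synthetic_fe = FALSE) {
  files <- c(hm = "cangio_hm.csv", plots = "cangio_plots.csv",
             fe = "cangio_fe_synthetic.csv")
  sums <- c(hm = "f6292bb5c2ef11d152ddb01ecc39613b",
            plots = "66df6dd413e0f3a5f605b4af53521042",
            fe = "42a51622afb97de48ca770c3b4d5cd3b")
  paths <- vapply(files, function(f)
    system.file("extdata", f, package = "mangrovehm", mustWork = TRUE),
    character(1))
  got <- unname(tools::md5sum(paths))
  bad <- files[got != sums]
  if (length(bad))
    stop("packaged fixture checksum mismatch: ", paste(bad, collapse = ", "))
  hm <- read_hm_csv(paths[["hm"]])
  fe <- read_hm_csv(paths[["fe"]])
  plots <- utils::read.csv(paths[["plots"]], stringsAsFactors = FALSE)
  if (with_synthetic_fe) {
    fe2 <- fe
    fe2$position <- hm$position[match(fe2$site_id, hm$site_id)]
    hm <- rbind(hm, fe2[names(hm)])
  }
  list(hm = hm, plots = plots, fe_synthetic = fe)
}
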