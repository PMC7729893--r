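# shared objects for the test suite
sp_default <- species_params()
mp_default <- default_multiplier_params()

# tiny two-cell raster stack: cell 1 favourable, cell 2 stressed
two_cell_layers <- function(sal = c(8, 18), el = c(0.1, 0.45),
                            cr = c(10, 200), cellsize = 100) {
  list(elevation = ascii_grid(matrix(el, 1, 2), cellsize = cellsize),
       salinity = ascii_grid(matrix(sal, 1, 2), cellsize = cellsize),
       root_Cr = ascii_grid(matrix(cr, 1, 2), cellsize = cellsize),
       mask = ascii_grid(matrix(1, 1, 2), cellsize = cellsize))
}

# per-cell mean dbh of a stand state (weighted by cohort counts)
mean_dbh_by_cell <- function(state) {
  co <- state$cohorts
  vapply(state$cells$cell, function(cl) {
    rows <- co[co$cell == cl, , drop = FALSE]
    if (!nrow(rows)) return(NA_real_)
    sum(rows$dbh * rows$n) / sum(rows$n)
  }, numeric(1))
}
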