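#' Background reference concentrations for enrichment factors
#'
#' A labelled set of per-metal background concentrations (mg/kg) and the
#' normalising reference element. The default ships the continental shale
#' averages of Turekian & Wedepohl (1961) with iron as reference element;
#' these are conventional crustal values and can be overridden for regional
#' baselines.
#'
#' @param values Named numeric vector of background concentrations (mg/kg),
#'   all positive, including the reference element.
#' @param reference Name of the reference element (default `"Fe"`).
#' @param source Free-text label recording where the values come from.
#' @return An object of class `background_reference`.
#' @export
background_reference <- function(values, reference = "Fe", source = "user") {
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("background values must be named by metal")
  if (any(values <= 0)) stop("background values must be positive")
  if (!reference %in% names(values))
    stop("reference element '", reference, "' missing from background values")
  structure(list(values = values, reference = reference, source = source),
            class = "background_reference")
}

#' @rdname background_reference
#' @export
shale_background <- function() {
  background_reference(
    c(Cr = 90, Cu = 45, Ni = 68, Fe = 47200),
    reference = "Fe",
    source = "continental shale average (Turekian & Wedepohl 1961)")
}

.check_hm_table <- function(table) {
  need <- c("site_id", "compartment", "metal", "conc")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("heavy-metal table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(table$conc < 0, na.rm = TRUE)) stop("concentrations must be non-negative")
  key <- paste(table$site_id, table$compartment, table$metal)
  if (anyDuplicated(key))
    stop("duplicate (site, compartment, metal) rows in heavy-metal table")
  invisible(table)
}

#' Summary statistics of a heavy-metal survey table
#'
#' Per-metal arithmetic mean, sample (n-1) standard deviation, minimum and
#' maximum, grouped by any combination of table columns (typically `region`
#' and/or `compartment`). Groups of a single observation report `NA` for
#' the standard deviation. Values are not rounded; rounding to the 2
#' decimals of printed survey tables is presentation only.
#'
#' @param table Long-format heavy-metal table with columns `site_id`,
#'   `region`, `compartment`, `metal`, `conc` (mg/kg DW).
#' @param by Character vector of grouping columns in addition to `metal`
#'   (default `c("region", "compartment")`; may be `character()`).
#' @return Data frame with the grouping columns, `metal`, `n`, `mean`,
#'   `sd`, `min`, `max`.
#' @examples
#' hm <- cangio_survey()$hm
#' hm_summarize(hm[hm$compartment == "soil", ], by = character())
#' @export
hm_summarize <- function(table, by = c("region", "compartment")) {
  .check_hm_table(table)
  miss <- setdiff(by, names(table))
  if (length(miss)) stop("grouping column(s) not in table: ",
                         paste(miss, collapse = ", "))
  keys <- c(by, "metal")
  grp <- interaction(table[keys], drop = TRUE, sep = "\r")
  res <- lapply(levels(grp), function(g) {
    rows <- table[grp == g, , drop = FALSE]
    x <- rows$conc
    out <- rows[1, keys, drop = FALSE]
    out$n <- length(x)
    out$mean <- mean(x)
    out$sd <- if (length(x) > 1) stats::sd(x) else NA_real_
    out$min <- min(x)
    out$max <- max(x)
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[do.call(order, out[keys]), , drop = FALSE]
}

.classify_ef <- function(ef) {
  ifelse(ef < 1.5, "natural",
         ifelse(ef <= 5, "anthropogenic", "significant"))
}

#' Enrichment factors of soil metals
#'
#' Computes, per site and metal, the enrichment factor
#' \deqn{EF = \frac{(Me/Fe)_{sample}}{(Me/Fe)_{background}}}
#' from the soil compartment of a heavy-metal table, normalised by the
#' reference element (Fe). Classification thresholds are half-open:
#' `[0, 1.5)` natural, `[1.5, 5]` anthropogenic enrichment, `(5, Inf)`
#' significant enrichment. EF is invariant under rescaling all of a site's
#' concentrations by a common factor.
#'
#' Sites lacking a reference-element measurement yield a per-site error
#' record (`ok = FALSE`, `EF = NA`) rather than failing the whole call.
#'
#' @param table Long-format heavy-metal table (see [hm_summarize()]).
#' @param bg A [background_reference()] object.
#' @return Data frame with `site_id`, `metal`, `EF`, `class`, `ok`, `note`.
#' @export
enrichment_factor <- function(table, bg = shale_background()) {
  .check_hm_table(table)
  stopifnot(inherits(bg, "background_reference"))
  soil <- table[table$compartment == "soil", , drop = FALSE]
  if (nrow(soil) == 0) stop("table has no soil compartment rows")
  ref <- bg$reference
  sites <- unique(soil$site_id)
  out <- lapply(sites, function(s) {
    rows <- soil[soil$site_id == s, , drop = FALSE]
    fe <- rows$conc[rows$metal == ref]
    metals <- setdiff(intersect(rows$metal, names(bg$values)), ref)
    if (length(fe) != 1 || is.na(fe) || fe <= 0) {
      return(data.frame(site_id = s, metal = metals, EF = NA_real_,
                        class = NA_character_, ok = FALSE,
                        note = paste0("missing ", ref, " measurement")))
    }
    ef <- vapply(metals, function(m) {
      me <- rows$conc[rows$metal == m]
      (me / fe) / (bg$values[[m]] / bg$values[[ref]])
    }, numeric(1))
    data.frame(site_id = s, metal = metals, EF = unname(ef),
               class = .classify_ef(unname(ef)), ok = TRUE, note = "")
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Tissue-to-soil concentration ratios
#'
#' Per site and metal, the ratio of root and leaf concentrations to the soil
#' concentration, a crude bioconcentration descriptor. A zero soil
#' concentration is flagged (`ok = FALSE`) rather than raised.
#'
#' @param table Long-format heavy-metal table (see [hm_summarize()]).
#' @return Data frame with `site_id`, `metal`, `tissue`, `ratio`, `ok`.
#' @export
bioconcentration_ratio <- function(table) {
  .check_hm_table(table)
  soil <- table[table$compartment == "soil", , drop = FALSE]
  tissues <- table[table$compartment %in% c("root", "leaf"), , drop = FALSE]
  if (nrow(soil) == 0 || nrow(tissues) == 0)
    stop("table needs both soil and tissue rows")
  key <- paste(tissues$site_id, tissues$metal)
  soil_key <- paste(soil$site_id, soil$metal)
  soil_conc <- soil$conc[match(key, soil_key)]
  ok <- !is.na(soil_conc) & soil_conc > 0
  data.frame(site_id = tissues$site_id, metal = tissues$metal,
             tissue = tissues$compartment,
             ratio = ifelse(ok, tissues$conc / soil_conc, NA_real_),
             ok = ok)
}
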