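# Conversion of literature cell-count reports to percent of total cells.
# Studies report non-adipocyte counts in six different units; four of them
# are linearly convertible to percent of total cells given two explicit
# assumptions: the fraction of total cells that are adipocytes, and the
# total number of cells per gram of tissue. Counts per high-power field and
# per mm^2 have no such conversion and are excluded, never converted.

LIT_UNITS <- c("per_100_adipocytes", "per_gram", "percent_svf",
               "per_total_nuclei", "per_high_power_field", "per_mm2")

#' Conversion assumptions for literature counts
#'
#' Both parameters must be supplied explicitly; there are no defaults.
#'
#' @param adipocyte_fraction Fraction of total cells that are adipocytes,
#'   in (0, 1).
#' @param cells_per_gram Total cells per gram of tissue (> 0).
#' @return A `td_assumptions` list.
#' @export
conversion_assumptions <- function(adipocyte_fraction, cells_per_gram) {
  stopifnot(is.numeric(adipocyte_fraction), length(adipocyte_fraction) == 1L,
            adipocyte_fraction > 0, adipocyte_fraction < 1,
            is.numeric(cells_per_gram), length(cells_per_gram) == 1L,
            cells_per_gram > 0)
  structure(list(adipocyte_fraction = adipocyte_fraction,
                 cells_per_gram = cells_per_gram),
            class = "td_assumptions")
}

# Linear factor mapping a count in `unit` to percent of total cells, or NA
# for the excluded units.
conversion_factor <- function(unit, a) {
  stopifnot(inherits(a, "td_assumptions"))
  vapply(unit, function(u) {
    switch(u,
      per_100_adipocytes = a$adipocyte_fraction,
      per_gram = 100 / a$cells_per_gram,
      percent_svf = 1 - a$adipocyte_fraction,
      per_total_nuclei = 100,
      per_high_power_field = NA_real_,
      per_mm2 = NA_real_,
      stop("unknown unit: ", u))
  }, numeric(1))
}

#' Convert literature records to percent of total cells
#'
#' `per_100_adipocytes` counts become `x * adipocyte_fraction` (each
#' adipocyte stands for `1/adipocyte_fraction` total cells); `per_gram`
#' becomes `100 * x / cells_per_gram`; `percent_svf` becomes
#' `x * (1 - adipocyte_fraction)` (the SVF is the non-adipocyte compartment);
#' `per_total_nuclei`, given as a fraction, becomes `100 * x`. The same
#' linear factor is applied to mean, sd/se, min and max. Records in
#' `per_high_power_field` or `per_mm2` are marked `"excluded"` and carry no
#' number.
#'
#' @param records Data frame with columns `unit` and `mean` (optionally
#'   `sd_or_se`, `min`, `max` and any identifying columns, which are kept).
#' @param assumptions A [conversion_assumptions()] object.
#' @return The input with added columns `percent_total_mean`,
#'   `percent_total_sd_or_se`, `percent_total_min`, `percent_total_max` and
#'   `status` (`"converted"` or `"excluded"`).
#' @export
to_percent_total <- function(records, assumptions) {
  stopifnot(is.data.frame(records), all(c("unit", "mean") %in% names(records)))
  bad <- setdiff(unique(records$unit), LIT_UNITS)
  if (length(bad)) stop("unknown unit: ", paste(bad, collapse = ", "))
  if (any(records$mean < 0, na.rm = TRUE)) stop("negative cell counts")
  fac <- conversion_factor(records$unit, assumptions)
  out <- records
  for (col in c("mean", "sd_or_se", "min", "max")) {
    src <- if (col %in% names(records)) records[[col]] else NA_real_
    out[[paste0("percent_total_", col)]] <- src * fac
  }
  out$status <- ifelse(is.na(fac), "excluded", "converted")
  out
}

#' Invert a percent-of-total conversion
#'
#' Returns the value in the original unit that converts to `pct`; errors for
#' the excluded units.
#'
#' @param pct Percent of total cells.
#' @param unit One of the convertible units.
#' @param assumptions A [conversion_assumptions()] object.
#' @return Numeric of the same length as `pct`.
#' @export
from_percent_total <- function(pct, unit, assumptions) {
  fac <- conversion_factor(unit, assumptions)
  if (anyNA(fac)) stop("unit not convertible: ", unit)
  unname(pct / fac)
}

#' Compare literature records with deconvolution estimates
#'
#' Aligns converted literature reports for one cell type (or a combined
#' class, e.g. macrophages plus monocytes, whose member fractions are summed
#' per sample before summarizing) with the distribution of estimated
#' fractions.
#'
#' @param records Converted records (output of [to_percent_total()]) with a
#'   `cell_type` column and, ideally, a `study_id` column.
#' @param est A `td_deconv` or samples-by-cell-type fraction matrix
#'   (fractions in [0, 1]).
#' @param cell_type Cell type to compare (matched against `records$cell_type`).
#' @param combine Optional character vector of estimate columns to sum per
#'   sample; default is the single column named `cell_type`.
#' @return List with `literature` (study-level rows: percent mean/min/max)
#'   and `estimate` (one row: mean, median, IQR of the estimated percent).
#' @export
summarize_vs_estimates <- function(records, est, cell_type, combine = NULL) {
  frac <- if (inherits(est, "td_deconv")) est$fractions else as.matrix(est)
  lit <- records[records$cell_type == cell_type &
                   records$status == "converted", , drop = FALSE]
  if (!nrow(lit)) stop("no converted literature records for ", cell_type)
  cols <- if (is.null(combine)) cell_type else combine
  miss <- setdiff(cols, colnames(frac))
  if (length(miss)) stop("estimates lack cell type(s): ", paste(miss, collapse = ", "))
  x <- 100 * rowSums(frac[, cols, drop = FALSE])
  lit_tab <- data.frame(
    study_id = if ("study_id" %in% names(lit)) lit$study_id else seq_len(nrow(lit)),
    percent_mean = lit$percent_total_mean,
    percent_min = lit$percent_total_min,
    percent_max = lit$percent_total_max,
    stringsAsFactors = FALSE)
  est_tab <- data.frame(
    cell_type = cell_type, n = length(x),
    percent_mean = mean(x), percent_median = stats::median(x),
    percent_q25 = unname(stats::quantile(x, 0.25)),
    percent_q75 = unname(stats::quantile(x, 0.75)),
    stringsAsFactors = FALSE)
  list(literature = lit_tab, estimate = est_tab)
}
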