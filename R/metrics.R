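# Deviation statistics used throughout: signed percent deviation of a model
# value from a datum, its per-set mean (AAD) and maximum (PDm), RMSE on the
# native N/m scale and the coefficient of determination about each set's own
# mean. Percent deviations are scale-free; RMSE is not.

#' Signed percent deviation of a model value from a datum
#'
#' `PD = 100 * (sigma_model - sigma_data) / sigma_data`. Undefined where the
#' measured value is zero; since surface tension vanishes at the critical
#' point, deviations blow up there — callers exclude near-zero data via the
#' `sigma_floor` argument of [st_fit_report()].
#'
#' @param sigma_model Model values, N/m (vectorised).
#' @param sigma_data Measured values, N/m, strictly positive.
#' @return Percent deviations, same length as the inputs.
#' @export
percent_deviation <- function(sigma_model, sigma_data) {
  if (length(sigma_model) != length(sigma_data)) {
    abort("sigma_model and sigma_data must have equal length",
          class = "st_domain_error")
  }
  if (any(sigma_data <= 0)) {
    abort("percent deviation undefined for sigma_data <= 0 (sigma vanishes at the critical point)",
          class = "st_domain_error")
  }
  100 * (sigma_model - sigma_data) / sigma_data
}

#' Absolute average deviation (percent)
#'
#' Mean of |PD| over a set of deviations; computed per fluid or per data
#' subset depending on what is passed in.
#'
#' @param pds Numeric vector of signed percent deviations, non-empty.
#' @return The AAD in percent.
#' @export
aad <- function(pds) {
  if (length(pds) == 0) abort("AAD of an empty set is undefined", class = "st_domain_error")
  mean(abs(pds))
}

#' Maximum absolute percent deviation
#'
#' @param pds Numeric vector of signed percent deviations, non-empty.
#' @return max |PD|, the model's worst deviation in the set.
#' @export
pdm <- function(pds) {
  if (length(pds) == 0) abort("PDm of an empty set is undefined", class = "st_domain_error")
  max(abs(pds))
}

#' Root mean square error on the native scale
#'
#' @param sigma_data Measured values, N/m.
#' @param sigma_calc Model values, N/m, same length.
#' @return RMSE in N/m.
#' @export
st_rmse <- function(sigma_data, sigma_calc) {
  if (length(sigma_data) != length(sigma_calc) || length(sigma_data) == 0) {
    abort("need equal-length non-empty vectors", class = "st_domain_error")
  }
  sqrt(mean((sigma_data - sigma_calc)^2))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`, with the total sum of squares taken about the
#' mean of `sigma_data` itself — when applied per subset, each subset uses its
#' own mean.
#'
#' @inheritParams st_rmse
#' @return Dimensionless; 1 for perfect predictions, 0 for predicting the mean.
#' @export
st_r2 <- function(sigma_data, sigma_calc) {
  if (length(sigma_data) != length(sigma_calc) || length(sigma_data) == 0) {
    abort("need equal-length non-empty vectors", class = "st_domain_error")
  }
  ss_tot <- sum((sigma_data - mean(sigma_data))^2)
  if (ss_tot == 0) {
    abort("R^2 undefined: all measured values identical", class = "st_domain_error")
  }
  1 - sum((sigma_data - sigma_calc)^2) / ss_tot
}

#' Per-subset fit report
#'
#' Assembles AAD, PDm, RMSE and R^2 for the training, test and prediction
#' subsets and for the complete set. Data with `sigma` below `sigma_floor`
#' are excluded from the PD-based statistics (AAD, PDm) with a warning,
#' because percent deviations diverge as sigma approaches zero near the
#' critical point; RMSE and R^2 always use all points.
#'
#' @param data Dataset tibble; if it has a `subset` column the three subsets
#'   are reported in addition to the complete set.
#' @param sigma_calc Model predictions, N/m, one per row of `data`.
#' @param sigma_floor Exclusion threshold for PD statistics, N/m.
#' @return A tibble with columns `subset`, `n`, `AAD`, `PDm`, `RMSE`, `R2`.
#' @export
st_fit_report <- function(data, sigma_calc, sigma_floor = 1e-6) {
  if (length(sigma_calc) != nrow(data)) {
    abort(paste0("got ", length(sigma_calc), " predictions for ", nrow(data), " data"),
          class = "st_domain_error")
  }
  usable <- data$sigma >= sigma_floor
  if (!all(usable)) {
    warn(paste0(sum(!usable), " data point(s) below the sigma floor of ",
                sigma_floor, " N/m excluded from PD-based statistics"))
  }
  one <- function(idx, label) {
    pd_idx <- idx & usable
    pds <- percent_deviation(sigma_calc[pd_idx], data$sigma[pd_idx])
    tibble::tibble(
      subset = label,
      n = sum(idx),
      AAD = aad(pds),
      PDm = pdm(pds),
      RMSE = st_rmse(data$sigma[idx], sigma_calc[idx]),
      R2 = st_r2(data$sigma[idx], sigma_calc[idx])
    )
  }
  rows <- list()
  if ("subset" %in% names(data)) {
    for (label in c("training", "test", "prediction")) {
      idx <- data$subset == label
      if (any(idx)) rows[[label]] <- one(idx, label)
    }
  }
  rows$complete <- one(rep(TRUE, nrow(data)), "complete")
  dplyr::bind_rows(rows)
}

#' Per-fluid deviation table
#'
#' AAD and PDm for each fluid over that fluid's own data (the per-fluid mean
#' uses the fluid's own point count), plus the point count. The overall AAD
#' of the pooled data equals the data-count-weighted mean of these per-fluid
#' AADs.
#'
#' @inheritParams st_fit_report
#' @return A tibble with columns `fluid`, `n`, `AAD`, `PDm`, sorted by fluid.
#' @export
st_fluid_report <- function(data, sigma_calc, sigma_floor = 1e-6) {
  if (length(sigma_calc) != nrow(data)) {
    abort(paste0("got ", length(sigma_calc), " predictions for ", nrow(data), " data"),
          class = "st_domain_error")
  }
  data |>
    dplyr::mutate(.calc = sigma_calc) |>
    dplyr::filter(.data$sigma >= sigma_floor) |>
    dplyr::group_by(.data$fluid) |>
    dplyr::summarise(
      n = dplyr::n(),
      AAD = aad(percent_deviation(.data$.calc, .data$sigma)),
      PDm = pdm(percent_deviation(.data$.calc, .data$sigma)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$fluid)
}

#' Render a report tibble as aligned text
#'
#' Percent columns are shown with 2 decimals (full precision is retained in
#' the tibble itself); RMSE keeps 6 significant digits.
#'
#' @param report A tibble from [st_fit_report()] or [st_fluid_report()].
#' @return A character vector of lines, invisibly printed-friendly.
#' @export
st_render_report <- function(report) {
  fmt <- report
  for (cl in intersect(c("AAD", "PDm"), names(fmt))) {
    fmt[[cl]] <- sprintf("%.2f", fmt[[cl]])
  }
  for (cl in intersect(c("RMSE", "R2"), names(fmt))) {
    fmt[[cl]] <- signif(fmt[[cl]], 6)
  }
  out <- utils::capture.output(print(as.data.frame(fmt), row.names = FALSE))
  out
}
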