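# Dataset schema and plumbing: one row per surface-tension observation,
# per-fluid constants repeated on each row. Internal units are SI throughout:
# K, N/m, bar (Pc), g/mol (Mw), m (radius of gyration), L/mol (Vm), debye (mu).

# required columns of a surface-tension dataset tibble
st_required_cols <- c("fluid", "family", "Tc_K", "Tb_K", "omega", "T_K", "sigma")

# optional per-fluid descriptor columns (recognised if present)
st_optional_cols <- c("Pc_bar", "Mw_g_mol", "rgyr_m", "Vm_L_mol", "mu_D", "source")

st_families <- c("carboxylic", "aliphatic", "polyfunctional", "unknown")

#' Validate a surface-tension dataset
#'
#' Checks the schema and physical invariants of a dataset tibble: required
#' columns present and numeric, `Tc_K > Tb_K > 0`, finite acentric factor,
#' `Pc_bar > 0` where present, `0 < T_K < Tc_K` (so the reduced temperature
#' lies in (0, 1)), `sigma > 0`, and per-fluid constants consistent across a
#' fluid's rows. Duplicate `(fluid, T_K)` rows with different `sigma` are
#' permitted: multi-source corpora routinely carry several measurements at
#' one temperature.
#'
#' @param data A tibble with one row per observation. Required columns:
#'   `fluid`, `family`, `Tc_K`, `Tb_K`, `omega`, `T_K`, `sigma` (N/m).
#'   Recognised optional columns: `Pc_bar`, `Mw_g_mol`, `rgyr_m`, `Vm_L_mol`,
#'   `mu_D`, `source`.
#' @return `data`, invisibly, if valid; otherwise an error naming the first
#'   offending column or row.
#' @export
st_validate <- function(data) {
  missing_cols <- setdiff(st_required_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("dataset is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "st_schema_error")
  }
  num_cols <- intersect(c("Tc_K", "Tb_K", "omega", "T_K", "sigma",
                          "Pc_bar", "Mw_g_mol", "rgyr_m", "Vm_L_mol", "mu_D"),
                        names(data))
  for (cl in num_cols) {
    if (!is.numeric(data[[cl]])) {
      abort(paste0("column '", cl, "' must be numeric"), class = "st_parse_error")
    }
  }
  bad_family <- !data$family %in% st_families
  if (any(bad_family)) {
    abort(paste0("unknown family '", data$family[which(bad_family)[1]],
                 "' at row ", which(bad_family)[1],
                 " (expected one of: ", paste(st_families, collapse = ", "), ")"),
          class = "st_validation_error")
  }
  check_rows <- function(ok, what) {
    if (!all(ok)) {
      i <- which(!ok)[1]
      abort(paste0("row ", i, " violates ", what,
                   " (fluid '", data$fluid[i], "')"),
            class = "st_validation_error")
    }
  }
  check_rows(is.finite(data$Tc_K) & is.finite(data$Tb_K) &
               data$Tc_K > data$Tb_K & data$Tb_K > 0, "Tc > Tb > 0")
  check_rows(is.finite(data$omega), "finite acentric factor")
  if ("Pc_bar" %in% names(data)) {
    check_rows(is.na(data$Pc_bar) | data$Pc_bar > 0, "Pc > 0 when present")
  }
  check_rows(is.finite(data$T_K) & data$T_K > 0 & data$T_K < data$Tc_K,
             "0 < T < Tc")
  check_rows(is.finite(data$sigma) & data$sigma > 0, "sigma > 0")

  # each fluid must carry a single, consistent set of constants
  const_cols <- intersect(c("family", "Tc_K", "Tb_K", "omega",
                            "Pc_bar", "Mw_g_mol", "rgyr_m", "Vm_L_mol", "mu_D"),
                          names(data))
  n_variants <- data |>
    dplyr::distinct(dplyr::pick(dplyr::all_of(c("fluid", const_cols)))) |>
    dplyr::count(.data$fluid)
  if (any(n_variants$n > 1)) {
    abort(paste0("fluid '", n_variants$fluid[n_variants$n > 1][1],
                 "' has inconsistent per-fluid constants across rows"),
          class = "st_validation_error")
  }
  invisible(data)
}

#' Extract the per-fluid constants table
#'
#' @param data A validated dataset tibble.
#' @return A tibble with one row per fluid: the constants plus `n_data`,
#'   the number of observations for that fluid.
#' @export
st_fluids <- function(data) {
  const_cols <- intersect(c("fluid", "family", "Tc_K", "Tb_K", "omega",
                            "Pc_bar", "Mw_g_mol", "rgyr_m", "Vm_L_mol", "mu_D"),
                          names(data))
  data |>
    dplyr::group_by(dplyr::pick(dplyr::all_of(const_cols))) |>
    dplyr::summarise(n_data = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$fluid)
}

#' Read a surface-tension dataset from CSV
#'
#' Comma-separated, UTF-8, '.' decimal separator, one header row. The file's
#' `sigma` column may be in N/m or mN/m; it is converted to N/m internally.
#'
#' @param path Path to a CSV file with columns
#'   `fluid,family,Tc_K,Tb_K,omega,T_K,sigma` (plus any of
#'   `Pc_bar,Mw_g_mol,rgyr_m,Vm_L_mol,mu_D,source`).
#' @param units Unit of the `sigma` column in the file: `"N_per_m"` (default)
#'   or `"mN_per_m"`.
#' @return A validated dataset tibble with `sigma` in N/m.
#' @export
st_read_dataset <- function(path, units = c("N_per_m", "mN_per_m")) {
  units <- match.arg(units)
  if (!file.exists(path)) {
    abort(paste0("dataset file not found: ", path), class = "st_io_error")
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(st_required_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("dataset file '", path, "' is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "st_schema_error")
  }
  if (units == "mN_per_m") {
    data$sigma <- data$sigma / 1000
  }
  if (nrow(data) > 0) st_validate(data)
  data
}

#' Write a surface-tension dataset to CSV
#'
#' Inverse of [st_read_dataset()]: writing and re-reading with the same
#' `units` flag round-trips the dataset.
#'
#' @param data A validated dataset tibble (`sigma` in N/m).
#' @param path Output CSV path.
#' @param units Unit in which to write the `sigma` column.
#' @return `path`, invisibly.
#' @export
st_write_dataset <- function(data, path, units = c("N_per_m", "mN_per_m")) {
  units <- match.arg(units)
  if (nrow(data) > 0) st_validate(data)
  out <- data
  if (units == "mN_per_m") {
    out$sigma <- out$sigma * 1000
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a fluid-constants CSV (no measurements)
#'
#' For prediction-only use: one row per fluid, columns
#' `fluid,family,Tc_K,Tb_K,omega` plus optional descriptors.
#'
#' @param path Path to the CSV file.
#' @return A tibble of fluid constants.
#' @export
st_read_fluids <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("fluid-constants file not found: ", path), class = "st_io_error")
  }
  fl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("fluid", "Tc_K", "Tb_K", "omega")
  missing_cols <- setdiff(need, names(fl))
  if (length(missing_cols) > 0) {
    abort(paste0("fluid-constants file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "st_schema_error")
  }
  bad <- !(fl$Tc_K > fl$Tb_K & fl$Tb_K > 0)
  if (any(bad)) {
    abort(paste0("row ", which(bad)[1], " violates Tc > Tb > 0"),
          class = "st_validation_error")
  }
  fl
}

# ---- min-max normalisation ---------------------------------------------

#' Fit a min-max normalisation to a numeric vector
#'
#' Variables entering the network are scaled to \[0, 1\] over their fitted
#' range so that no input dominates and the sigmoid layer is not driven into
#' saturation by raw magnitudes.
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @param name Variable label stored in the normalisation object.
#' @return An object of class `st_norm` with fields `name`, `vmin`, `vmax`.
#' @export
st_normalizer <- function(x, name = deparse(substitute(x))) {
  x <- x[is.finite(x)]
  if (length(x) < 2) {
    abort("need at least two finite values to fit a normalisation",
          class = "st_domain_error")
  }
  vmin <- min(x)
  vmax <- max(x)
  if (vmax <= vmin) {
    abort(paste0("degenerate range for '", name, "': all values equal ", vmin),
          class = "st_degenerate_range_error")
  }
  structure(list(name = name, vmin = vmin, vmax = vmax), class = "st_norm")
}

#' @export
print.st_norm <- function(x, ...) {
  cat("<st_norm> ", x$name, ": [", format(x$vmin), ", ", format(x$vmax), "] -> [0, 1]\n",
      sep = "")
  invisible(x)
}

#' Apply / invert a min-max normalisation
#'
#' `st_normalize()` maps `vmin -> 0` and `vmax -> 1`; `st_denormalize()` is
#' its exact inverse. Values outside the fitted range map outside \[0, 1\]
#' (extrapolation is flagged downstream, not forbidden here).
#'
#' @param spec An `st_norm` object from [st_normalizer()].
#' @param x Numeric vector in native units (`st_normalize`) or on the
#'   normalised scale (`st_denormalize`).
#' @return Numeric vector.
#' @export
st_normalize <- function(spec, x) {
  stopifnot(inherits(spec, "st_norm"))
  (x - spec$vmin) / (spec$vmax - spec$vmin)
}

#' @rdname st_normalize
#' @export
st_denormalize <- function(spec, x) {
  stopifnot(inherits(spec, "st_norm"))
  spec$vmin + x * (spec$vmax - spec$vmin)
}

# ---- random three-way split --------------------------------------------

#' Randomly split a dataset into training / test / prediction subsets
#'
#' Observations (not fluids) are partitioned uniformly at random into the
#' three subsets, reproducibly from `seed`. Subset sizes follow a
#' deterministic rounding rule: `n_training = floor(f1 * N + 0.5)`,
#' `n_test = floor(f2 * N + 0.5)`, and the prediction subset takes the
#' remainder, so the sizes always sum to `N`.
#'
#' @param data A dataset tibble with at least 10 rows.
#' @param fractions Named or positional numeric vector of length 3
#'   (training, test, prediction), positive, summing to 1.
#' @param seed Integer seed; the assignment is a pure function of
#'   `(data row count, fractions, seed)`.
#' @return `data` with an added factor column `subset` with levels
#'   `training`, `test`, `prediction`; `seed` and `fractions` are attached
#'   as attributes.
#' @export
st_split <- function(data, fractions = c(training = 0.75, test = 0.15, prediction = 0.10),
                     seed = 1L) {
  if (length(fractions) != 3 || any(fractions <= 0)) {
    abort("fractions must be three positive numbers", class = "st_config_error")
  }
  if (abs(sum(fractions) - 1) > 1e-8) {
    abort(paste0("fractions must sum to 1 (got ", sum(fractions), ")"),
          class = "st_config_error")
  }
  n <- nrow(data)
  if (n < 10) {
    abort("need at least 10 observations to split", class = "st_domain_error")
  }
  n_tr <- floor(fractions[[1]] * n + 0.5)
  n_te <- floor(fractions[[2]] * n + 0.5)
  n_pr <- n - n_tr - n_te
  if (n_pr < 0) {
    abort("rounding produced a negative prediction subset; adjust fractions",
          class = "st_config_error")
  }
  labels <- rep(c("training", "test", "prediction"), times = c(n_tr, n_te, n_pr))
  perm <- withr::with_seed(seed, sample.int(n))
  subset <- factor(character(n), levels = c("training", "test", "prediction"))
  subset[perm] <- labels
  out <- dplyr::mutate(data, subset = subset)
  attr(out, "split_seed") <- as.integer(seed)
  attr(out, "split_fractions") <- unname(fractions)
  out
}

#' Subset sizes implied by the split rounding rule
#'
#' @param n Number of observations.
#' @param fractions As in [st_split()].
#' @return Named integer vector `c(training, test, prediction)`.
#' @export
st_split_sizes <- function(n, fractions = c(0.75, 0.15, 0.10)) {
  n_tr <- floor(fractions[[1]] * n + 0.5)
  n_te <- floor(fractions[[2]] * n + 0.5)
  c(training = n_tr, test = n_te, prediction = n - n_tr - n_te)
}
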