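# Input-variable ranking and hidden-layer-size selection.

#' Effect-factor ranking of candidate input variables
#'
#' Scores each candidate input by its multilinear least-squares coefficient
#' when the min-max-normalised surface tension is regressed jointly on all
#' min-max-normalised candidates. The signed coefficient plays the role of
#' an "effect factor": its sign gives the direction of influence (negative
#' when sigma decreases as the factor grows) and its magnitude the strength
#' on the common \[0, 1\] scale. This is a transparent surrogate for the
#' factor analysis implemented in commercial optimisation suites, whose
#' internal formula is not public; ranks and signs are the meaningful
#' output, not the absolute values.
#'
#' Factors available for fewer than 80 percent of rows are dropped with a
#' warning; the fit then uses rows complete across the retained factors.
#' Strong collinearity between candidates triggers a warning but both
#' factors are retained.
#'
#' @param data A validated dataset tibble.
#' @param factors Candidate factor names; `"Tr"` denotes `T_K / Tc_K`, other
#'   names must be numeric dataset columns. The default is the classical
#'   nine-candidate list: molecular weight, radius of gyration, critical
#'   temperature, reduced temperature, liquid molar volume, boiling
#'   temperature, critical pressure, acentric factor, dipole moment.
#' @param kappa_warn Condition-number threshold for the collinearity warning.
#' @return A tibble of class `st_eff` with columns `factor`, `eff`, `rank`,
#'   `n_used`, ordered by decreasing |eff|.
#' @export
effect_factors <- function(data,
                           factors = c("Mw_g_mol", "rgyr_m", "Tc_K", "Tr",
                                       "Vm_L_mol", "Tb_K", "Pc_bar", "omega",
                                       "mu_D"),
                           kappa_warn = 1e8) {
  st_validate(data)
  n <- nrow(data)
  vals <- list()
  for (f in factors) {
    v <- if (f == "Tr") data$T_K / data$Tc_K
         else if (f %in% names(data)) data[[f]]
         else rep(NA_real_, n)
    avail <- mean(!is.na(v))
    if (avail < 0.8) {
      warn(paste0("factor '", f, "' available for only ",
                  round(100 * avail), "% of rows; dropped"))
    } else {
      vals[[f]] <- v
    }
  }
  if (length(vals) == 0) {
    abort("no candidate factor is sufficiently available", class = "st_domain_error")
  }
  M <- do.call(cbind, vals)
  keep <- stats::complete.cases(M)
  M <- M[keep, , drop = FALSE]
  y <- data$sigma[keep]
  Mn <- apply(M, 2, function(v) st_normalize(st_normalizer(v, "f"), v))
  yn <- st_normalize(st_normalizer(y, "sigma"), y)
  kn <- kappa(cbind(1, Mn), exact = FALSE)
  if (is.finite(kn) && kn > kappa_warn) {
    warn(paste0("candidate factors are strongly collinear (condition number ",
                format(kn, digits = 3), "); all retained"))
  }
  fit <- lm(yn ~ Mn)
  eff <- coef(fit)[-1]
  names(eff) <- colnames(M)
  out <- tibble::tibble(factor = names(eff), eff = unname(eff),
                        n_used = sum(keep)) |>
    dplyr::arrange(dplyr::desc(abs(.data$eff))) |>
    dplyr::mutate(rank = dplyr::row_number(), .after = "eff")
  class(out) <- c("st_eff", class(out))
  out
}

#' Hidden-layer-size sweep with multi-restart selection
#'
#' Trains a best-of-`restarts` model for every hidden size in `hidden` on a
#' single fixed split, then selects the size with the lowest test-subset AAD
#' (ties go to the smaller network). The prediction subset is never
#' consulted during selection. Each (size, restart) cell is seeded as
#' `seed + 1000 * size + restart`, so any cell can be reproduced in
#' isolation. Set `resplit = TRUE` to re-randomise the split for every size
#' (each size then sees a different partition; curves are noisier but match
#' protocols that re-draw subsets per run).
#'
#' @param data A validated dataset tibble.
#' @param hidden Integer vector of hidden sizes to try (classically 2 to 50).
#' @param restarts Restarts per size (default 30).
#' @param seed Base seed.
#' @param inputs,control,fractions Passed to [mlp_fit()].
#' @param resplit Re-randomise the split per hidden size (default FALSE).
#' @return An object of class `st_sweep`: list with `table` (tibble: hidden,
#'   train_AAD, test_AAD, prediction_AAD, test_RMSE, winner_restart) and
#'   `selected` (the chosen hidden size). Supports `autoplot()`.
#' @export
architecture_sweep <- function(data, hidden = 2:50, restarts = 30, seed = 1L,
                               inputs = c("Tr", "Tb_K", "omega"),
                               control = mlp_control(),
                               fractions = c(training = 0.75, test = 0.15,
                                             prediction = 0.10),
                               resplit = FALSE) {
  st_validate(data)
  if (!"subset" %in% names(data) && !resplit) {
    data <- st_split(data, fractions = fractions, seed = seed)
  }
  rows <- list()
  for (h in hidden) {
    d <- if (resplit) {
      st_split(dplyr::select(data, -dplyr::any_of("subset")),
               fractions = fractions, seed = as.integer(seed) + 1000L * h)
    } else data
    fit <- tryCatch(
      mlp_fit(d, inputs = inputs, hidden = h, restarts = restarts,
              seed = as.integer(seed) + 1000L * h, control = control),
      error = function(e) {
        warn(paste0("hidden size ", h, " skipped: ", conditionMessage(e)))
        NULL
      }
    )
    if (is.null(fit)) next
    rep <- fit$report
    g <- function(s, col) rep[[col]][rep$subset == s]
    rows[[as.character(h)]] <- tibble::tibble(
      hidden = as.integer(h),
      train_AAD = g("training", "AAD"),
      test_AAD = g("test", "AAD"),
      prediction_AAD = g("prediction", "AAD"),
      test_RMSE = g("test", "RMSE"),
      winner_restart = fit$winner,
      winner_seed = fit$seed + fit$winner
    )
  }
  if (length(rows) == 0) abort("every hidden size failed", class = "st_training_error")
  table <- dplyr::bind_rows(rows)
  # minimum test AAD; ties -> smaller network
  ord <- order(table$test_AAD, table$hidden)
  structure(list(table = table,
                 selected = table$hidden[ord[1]],
                 seed = as.integer(seed), restarts = as.integer(restarts),
                 inputs = inputs, resplit = resplit),
            class = "st_sweep")
}

#' @export
print.st_sweep <- function(x, ...) {
  cat("<st_sweep> hidden sizes ", min(x$table$hidden), "..", max(x$table$hidden),
      ", ", x$restarts, " restart(s); selected: ", x$selected, "\n", sep = "")
  print(as.data.frame(dplyr::mutate(
    x$table, dplyr::across(dplyr::ends_with("AAD"), ~ round(.x, 3)))),
    row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.st_sweep <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.st_sweep <- function(x, ...) {
  best <- x$table[x$table$hidden == x$selected, ]
  tibble::tibble(selected = x$selected, n_sizes = nrow(x$table),
                 restarts = x$restarts, seed = x$seed,
                 test_AAD = best$test_AAD, train_AAD = best$train_AAD,
                 prediction_AAD = best$prediction_AAD)
}

#' @rdname autoplot.st_mlp
#' @exportS3Method ggplot2::autoplot
autoplot.st_sweep <- function(object, ...) {
  long <- object$table |>
    dplyr::select(dplyr::all_of(c("hidden", "train_AAD", "test_AAD",
                                  "prediction_AAD"))) |>
    tidyr::pivot_longer(-"hidden", names_to = "subset", values_to = "AAD") |>
    dplyr::mutate(subset = sub("_AAD$", "", .data$subset))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$hidden, y = .data$AAD,
                                     colour = .data$subset)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$selected, linetype = 3) +
    ggplot2::labs(x = "hidden neurons", y = "AAD (%)", colour = NULL) +
    ggplot2::theme_minimal()
}
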