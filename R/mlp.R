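# Feed-forward (n_in, n_hidden, 1) perceptron. Inputs and the target are
# min-max normalised to [0, 1]; the hidden layer is sigmoidal, the output
# neuron linear by default (configurable to sigmoid). Parameters are packed
# into a single vector theta = c(vec(W), b, v, c) with W the n_hidden x n_in
# hidden weight matrix (column-major), b the hidden biases, v the output
# weights and c the output bias.

#' Logistic sigmoid activation
#'
#' The standard increasing form `1 / (1 + exp(-x))`. `form = "printed"`
#' selects the decreasing variant `1 / (1 + exp(x))`; the two are equivalent
#' up to a sign flip absorbed by the hidden weights, so either trains to the
#' same family of models.
#'
#' @param x Numeric vector.
#' @param form `"standard"` (default) or `"printed"`.
#' @return Values in (0, 1); saturates smoothly at the extremes.
#' @export
sigmoid <- function(x, form = c("standard", "printed")) {
  form <- match.arg(form)
  if (form == "printed") x <- -x
  1 / (1 + exp(-x))
}

#' Trainable-parameter count of an (n_in, n_hidden, 1) perceptron
#'
#' `n_hidden * (n_in + 1) + n_hidden + 1`: hidden weights and biases plus
#' output weights and bias. For (3, 41, 1) this is 206.
#'
#' @param n_in Number of inputs.
#' @param n_hidden Number of hidden neurons.
#' @return Integer parameter count.
#' @export
mlp_n_params <- function(n_in, n_hidden) {
  as.integer(n_hidden * (n_in + 1) + n_hidden + 1)
}

# pack / unpack between theta and the weight matrices
mlp_unpack <- function(theta, n_in, n_hidden) {
  stopifnot(length(theta) == mlp_n_params(n_in, n_hidden))
  i <- n_hidden * n_in
  list(
    W = matrix(theta[seq_len(i)], nrow = n_hidden, ncol = n_in),
    b = theta[i + seq_len(n_hidden)],
    v = theta[i + n_hidden + seq_len(n_hidden)],
    c = theta[length(theta)]
  )
}

mlp_pack <- function(W, b, v, c) {
  c(as.vector(W), b, v, c)
}

# forward pass on normalised inputs; returns the output and the hidden
# activations (needed by the Jacobian)
mlp_forward_norm <- function(theta, Xn, n_hidden,
                             sigmoid_form = "standard",
                             output_activation = "linear") {
  p <- mlp_unpack(theta, ncol(Xn), n_hidden)
  Z <- Xn %*% t(p$W) + matrix(p$b, nrow(Xn), n_hidden, byrow = TRUE)
  A <- sigmoid(Z, form = sigmoid_form)
  u <- drop(A %*% p$v) + p$c
  y <- if (output_activation == "sigmoid") sigmoid(u, form = sigmoid_form) else u
  list(y = y, A = A, u = u)
}

# analytic Jacobian d y_i / d theta_j of the network output wrt every
# parameter, N x P, columns ordered as theta
mlp_jacobian <- function(theta, Xn, n_hidden,
                         sigmoid_form = "standard",
                         output_activation = "linear") {
  p <- mlp_unpack(theta, ncol(Xn), n_hidden)
  fw <- mlp_forward_norm(theta, Xn, n_hidden, sigmoid_form, output_activation)
  A <- fw$A
  n <- nrow(Xn)
  # d sigmoid / d x = +s(1-s) for the standard form, -s(1-s) for the printed
  sgn <- if (sigmoid_form == "printed") -1 else 1
  S <- sgn * A * (1 - A) * matrix(p$v, n, n_hidden, byrow = TRUE)
  Jw <- do.call(cbind, lapply(seq_len(ncol(Xn)), function(k) S * Xn[, k]))
  J <- cbind(Jw, S, A, rep(1, n))
  if (output_activation == "sigmoid") {
    yp <- sgn * fw$y * (1 - fw$y)
    J <- J * yp
  }
  J
}

#' Training control for the Levenberg--Marquardt optimiser
#'
#' The damped Gauss--Newton loop operates on normalised residuals with RMSE
#' as the target function. The damping `lambda` starts at `lambda_init`, is
#' multiplied by `lambda_up` on a rejected step and divided by `lambda_down`
#' on an accepted one; training stops after `max_iter` accepted steps, when
#' the relative RMSE improvement stays below `rmse_tol` for `tol_streak`
#' consecutive accepted steps, or when `lambda` exceeds `lambda_max`
#' (singular normal equations; the restart is abandoned).
#'
#' @param max_iter Maximum accepted LM steps per restart.
#' @param lambda_init,lambda_up,lambda_down,lambda_max Damping schedule.
#' @param rmse_tol,tol_streak Convergence rule on relative RMSE improvement.
#' @param output_activation `"linear"` (default, standard for regression) or
#'   `"sigmoid"` for sensitivity checks.
#' @param sigmoid_form Hidden activation variant, see [sigmoid()].
#' @param init_range Half-width of the uniform weight initialisation.
#' @return A list of class `mlp_control`.
#' @export
mlp_control <- function(max_iter = 1000, lambda_init = 1e-3, lambda_up = 10,
                        lambda_down = 10, lambda_max = 1e10,
                        rmse_tol = 1e-9, tol_streak = 10,
                        output_activation = c("linear", "sigmoid"),
                        sigmoid_form = c("standard", "printed"),
                        init_range = 0.5) {
  stopifnot(max_iter >= 1, lambda_init > 0, rmse_tol > 0, init_range > 0)
  structure(list(
    max_iter = max_iter, lambda_init = lambda_init, lambda_up = lambda_up,
    lambda_down = lambda_down, lambda_max = lambda_max,
    rmse_tol = rmse_tol, tol_streak = tol_streak,
    output_activation = match.arg(output_activation),
    sigmoid_form = match.arg(sigmoid_form),
    init_range = init_range
  ), class = "mlp_control")
}

# one Levenberg-Marquardt run from a seeded random start.
# Returns NULL when the run is abandoned (lambda blew past lambda_max with
# no accepted step available).
lm_run <- function(Xtr, ttr, Xte, tte, n_hidden, init_seed, control) {
  n_in <- ncol(Xtr)
  P <- mlp_n_params(n_in, n_hidden)
  theta <- withr::with_seed(init_seed,
                            runif(P, -control$init_range, control$init_range))
  sf <- control$sigmoid_form
  oa <- control$output_activation
  rmse_of <- function(th, X, t) {
    sqrt(mean((mlp_forward_norm(th, X, n_hidden, sf, oa)$y - t)^2))
  }
  lambda <- control$lambda_init
  train_rmse <- rmse_of(theta, Xtr, ttr)
  test_rmse <- rmse_of(theta, Xte, tte)
  best_test <- test_rmse
  best_theta <- theta
  best_train_at_best <- train_rmse
  best_iter <- 0L
  trace_train <- train_rmse
  trace_test <- test_rmse
  streak <- 0L
  accepted <- 0L
  converged <- FALSE
  while (accepted < control$max_iter) {
    r <- mlp_forward_norm(theta, Xtr, n_hidden, sf, oa)$y - ttr
    J <- mlp_jacobian(theta, Xtr, n_hidden, sf, oa)
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    step_taken <- FALSE
    while (lambda <= control$lambda_max) {
      delta <- tryCatch(
        solve(JtJ + lambda * diag(P), -g),
        error = function(e) NULL
      )
      if (!is.null(delta)) {
        cand <- theta + drop(delta)
        cand_rmse <- rmse_of(cand, Xtr, ttr)
        if (is.finite(cand_rmse) && cand_rmse < train_rmse) {
          rel_impr <- (train_rmse - cand_rmse) / train_rmse
          theta <- cand
          train_rmse <- cand_rmse
          lambda <- lambda / control$lambda_down
          accepted <- accepted + 1L
          test_rmse <- rmse_of(theta, Xte, tte)
          trace_train <- c(trace_train, train_rmse)
          trace_test <- c(trace_test, test_rmse)
          if (test_rmse < best_test) {
            best_test <- test_rmse
            best_theta <- theta
            best_train_at_best <- train_rmse
            best_iter <- accepted
          }
          streak <- if (rel_impr < control$rmse_tol) streak + 1L else 0L
          step_taken <- TRUE
          break
        }
      }
      lambda <- lambda * control$lambda_up
    }
    if (!step_taken) break # damping exhausted: local minimum or singularity
    if (streak >= control$tol_streak) {
      converged <- TRUE
      break
    }
  }
  if (accepted == 0L) return(NULL)
  list(theta = best_theta, final_theta = theta,
       train_rmse = best_train_at_best, test_rmse = best_test,
       final_train_rmse = train_rmse,
       best_iter = best_iter, n_accepted = accepted, converged = converged,
       trace = tibble::tibble(iteration = seq_along(trace_train) - 1L,
                              train_rmse = trace_train,
                              test_rmse = trace_test))
}

# assemble the native input matrix named by `inputs`; "Tr" is computed as
# T_K / Tc_K, any other name must be a numeric dataset column
st_input_matrix <- function(data, inputs) {
  cols <- lapply(inputs, function(nm) {
    if (nm == "Tr") {
      data$T_K / data$Tc_K
    } else {
      if (!nm %in% names(data)) {
        abort(paste0("input '", nm, "' is not a column of the dataset"),
              class = "st_schema_error")
      }
      data[[nm]]
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- inputs
  m
}

#' Fit the surface-tension perceptron by Levenberg--Marquardt
#'
#' Trains an `(length(inputs), hidden, 1)` network on the training subset,
#' with early stopping at the minimum test-subset RMSE, restarted `restarts`
#' times from seeded random initialisations (`seed + restart index`); the
#' returned model is the restart with the lowest test RMSE (ties broken by
#' training RMSE, then restart index). Inputs and the target are min-max
#' normalised over the full dataset (configurable to training-only bounds)
#' and the bounds are stored in the model for prediction-time reuse.
#'
#' @param data A validated dataset tibble; if it lacks a `subset` column it
#'   is split with [st_split()] using `fractions` and `seed`.
#' @param inputs Character vector of input names; `"Tr"` denotes the reduced
#'   temperature `T_K / Tc_K`. Default `c("Tr", "Tb_K", "omega")`.
#' @param hidden Hidden-layer size (default 41).
#' @param restarts Number of random restarts (default 30).
#' @param seed Integer seed controlling the split (if taken here) and every
#'   restart initialisation.
#' @param fractions Split fractions, see [st_split()].
#' @param control An [mlp_control()] list.
#' @param norm_scope `"full"` (default) or `"training"`: which rows define
#'   the normalisation bounds.
#' @return An object of class `st_mlp` carrying the weights, normalisation
#'   specs, restart history, the per-subset fit report and a per-datum
#'   deviation table. Supports `predict()`, `tidy()`, `glance()`,
#'   `autoplot()`, [mlp_save()].
#' @export
mlp_fit <- function(data, inputs = c("Tr", "Tb_K", "omega"), hidden = 41,
                    restarts = 30, seed = 1L,
                    fractions = c(training = 0.75, test = 0.15, prediction = 0.10),
                    control = mlp_control(),
                    norm_scope = c("full", "training")) {
  norm_scope <- match.arg(norm_scope)
  st_validate(data)
  if (hidden < 1) abort("hidden must be >= 1", class = "st_config_error")
  if (restarts < 1) abort("restarts must be >= 1", class = "st_config_error")
  if (!"subset" %in% names(data)) {
    data <- st_split(data, fractions = fractions, seed = seed)
  }
  if (!any(data$subset == "training")) {
    abort("training subset is empty", class = "st_domain_error")
  }
  X <- st_input_matrix(data, inputs)
  scope_rows <- if (norm_scope == "full") rep(TRUE, nrow(data)) else data$subset == "training"
  input_norms <- lapply(seq_along(inputs), function(k) {
    st_normalizer(X[scope_rows, k], name = inputs[k])
  })
  output_norm <- st_normalizer(data$sigma[scope_rows], name = "sigma")
  Xn <- vapply(seq_along(inputs),
               function(k) st_normalize(input_norms[[k]], X[, k]),
               numeric(nrow(X)))
  tn <- st_normalize(output_norm, data$sigma)
  tr_rows <- data$subset == "training"
  te_rows <- data$subset == "test"
  if (!any(te_rows)) te_rows <- tr_rows # degenerate fallback: no held-out set
  runs <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    runs[[r]] <- lm_run(Xn[tr_rows, , drop = FALSE], tn[tr_rows],
                        Xn[te_rows, , drop = FALSE], tn[te_rows],
                        hidden, init_seed = as.integer(seed) + r, control)
    if (is.null(runs[[r]])) {
      warn(paste0("restart ", r, " abandoned: no accepted LM step"))
    }
  }
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) abort("all restarts failed", class = "st_training_error")
  history <- purrr::map2_dfr(runs[ok], which(ok), function(run, r) {
    tibble::tibble(restart = r, init_seed = as.integer(seed) + r,
                   n_accepted = run$n_accepted, best_iter = run$best_iter,
                   train_rmse = run$train_rmse, test_rmse = run$test_rmse,
                   converged = run$converged)
  })
  # lowest test RMSE; ties by training RMSE, then restart index
  ord <- order(history$test_rmse, history$train_rmse, history$restart)
  winner <- history$restart[ord[1]]
  best <- runs[[winner]]
  p <- mlp_unpack(best$theta, length(inputs), hidden)
  model <- structure(list(
    n_in = length(inputs), hidden = as.integer(hidden),
    hidden_weights = p$W, hidden_biases = p$b,
    output_weights = p$v, output_bias = p$c,
    input_names = inputs, input_norms = input_norms, output_norm = output_norm,
    output_activation = control$output_activation,
    sigmoid_form = control$sigmoid_form,
    seed = as.integer(seed), restarts = as.integer(restarts),
    winner = winner, history = history, control = control,
    norm_scope = norm_scope,
    split_fractions = attr(data, "split_fractions") %||% unname(fractions)
  ), class = "st_mlp")
  fw <- mlp_forward_norm(best$theta, Xn, hidden,
                         control$sigmoid_form, control$output_activation)
  sigma_calc <- st_denormalize(output_norm, fw$y)
  model$report <- st_fit_report(data, sigma_calc)
  model$pd_table <- tibble::tibble(
    fluid = data$fluid, T_K = data$T_K, Tr = data$T_K / data$Tc_K,
    sigma = data$sigma, sigma_calc = sigma_calc, subset = data$subset,
    PD = 100 * (sigma_calc - data$sigma) / data$sigma
  )
  model$trace <- best$trace
  model
}

#' @export
print.st_mlp <- function(x, ...) {
  cat("<st_mlp> (", x$n_in, ",", x$hidden, ",1) perceptron on (",
      paste(x$input_names, collapse = ", "), ")\n", sep = "")
  cat("  ", mlp_n_params(x$n_in, x$hidden), " parameters; restart ", x$winner,
      " of ", x$restarts, " (seed ", x$seed, ")\n", sep = "")
  print(as.data.frame(dplyr::mutate(
    x$report, dplyr::across(c("AAD", "PDm"), ~ round(.x, 2)),
    dplyr::across(c("RMSE", "R2"), ~ signif(.x, 4)))), row.names = FALSE)
  invisible(x)
}

#' Predict surface tension with a fitted perceptron
#'
#' @param object An `st_mlp` model.
#' @param newdata A tibble with columns `T_K`, `Tc_K` and every model input
#'   (e.g. `Tb_K`, `omega`); `0 < T_K < Tc_K` is enforced.
#' @param ... Unused.
#' @return `newdata` with added columns `sigma_calc` (N/m) and
#'   `extrapolated` (TRUE where any normalised input fell outside the
#'   training range \[0, 1\]; a warning reports the count — predictions are
#'   still returned).
#' @export
predict.st_mlp <- function(object, newdata, ...) {
  if (!all(c("T_K", "Tc_K") %in% names(newdata))) {
    abort("newdata must contain T_K and Tc_K", class = "st_schema_error")
  }
  bad <- !(newdata$T_K > 0 & newdata$T_K < newdata$Tc_K)
  if (any(bad)) {
    abort(paste0("row ", which(bad)[1], " violates 0 < T < Tc"),
          class = "st_validation_error")
  }
  X <- st_input_matrix(newdata, object$input_names)
  Xn <- vapply(seq_along(object$input_names),
               function(k) st_normalize(object$input_norms[[k]], X[, k]),
               numeric(nrow(X)))
  if (nrow(X) == 1) Xn <- matrix(Xn, nrow = 1)
  extrapolated <- apply(Xn < -1e-12 | Xn > 1 + 1e-12, 1, any)
  if (any(extrapolated)) {
    warn(paste0(sum(extrapolated),
                " prediction(s) extrapolate outside the fitted input range"))
  }
  theta <- mlp_pack(object$hidden_weights, object$hidden_biases,
                    object$output_weights, object$output_bias)
  fw <- mlp_forward_norm(theta, Xn, object$hidden,
                         object$sigmoid_form, object$output_activation)
  dplyr::mutate(newdata,
                sigma_calc = st_denormalize(object$output_norm, fw$y),
                extrapolated = extrapolated)
}

#' @exportS3Method generics::tidy
tidy.st_mlp <- function(x, ...) {
  W <- x$hidden_weights
  terms_w <- as.vector(outer(seq_len(x$hidden), seq_len(x$n_in),
                             function(j, k) sprintf("hidden_weight[%d,%s]", j, x$input_names[k])))
  tibble::tibble(
    term = c(terms_w,
             sprintf("hidden_bias[%d]", seq_len(x$hidden)),
             sprintf("output_weight[%d]", seq_len(x$hidden)),
             "output_bias"),
    estimate = c(as.vector(W), x$hidden_biases, x$output_weights, x$output_bias)
  )
}

#' @exportS3Method generics::glance
glance.st_mlp <- function(x, ...) {
  wide <- x$report |>
    dplyr::select(dplyr::all_of(c("subset", "AAD", "PDm", "RMSE", "R2"))) |>
    tidyr::pivot_wider(names_from = "subset",
                       values_from = c("AAD", "PDm", "RMSE", "R2"),
                       names_sep = "_")
  dplyr::bind_cols(
    tibble::tibble(n_in = x$n_in, hidden = x$hidden,
                   n_params = mlp_n_params(x$n_in, x$hidden),
                   restarts = x$restarts, winner = x$winner,
                   seed = x$seed),
    wide
  )
}

#' Plot methods for fitted objects
#'
#' `autoplot.st_mlp()` shows the signed percent deviation of every datum
#' against reduced temperature, coloured by subset — the standard residual
#' diagnostic for surface-tension models, where deviations fan out towards
#' the critical point. `autoplot.st_sweep()` draws the AAD-versus-hidden-size
#' curves used for architecture selection. `autoplot.st_csp_benchmark()`
#' compares per-fluid AAD distributions across baselines.
#'
#' @param object A fitted object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.st_mlp <- function(object, ...) {
  ggplot2::ggplot(object$pd_table,
                  ggplot2::aes(x = .data$Tr, y = .data$PD, colour = .data$subset)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::labs(x = expression(T[r] == T / T[c]), y = "PD (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

# ---- serialisation ------------------------------------------------------

#' Save / load a fitted perceptron as JSON
#'
#' The file records the schema version, architecture, input names,
#' normalisation specs and full-precision weights — everything needed to
#' reproduce predictions exactly. Metadata are deterministic (no timestamp),
#' so identical fits yield byte-identical files.
#'
#' @param model An `st_mlp` object.
#' @param path Output / input path.
#' @return `path` invisibly (`mlp_save`); an `st_mlp` (`mlp_load`).
#' @export
mlp_save <- function(model, path) {
  stopifnot(inherits(model, "st_mlp"))
  doc <- list(
    schema_version = 1L,
    generator = "surftens",
    architecture = c(model$n_in, model$hidden, 1L),
    input_names = model$input_names,
    input_norms = lapply(model$input_norms, function(s)
      list(name = s$name, vmin = s$vmin, vmax = s$vmax)),
    output_norm = list(name = model$output_norm$name,
                       vmin = model$output_norm$vmin,
                       vmax = model$output_norm$vmax),
    hidden_weights = model$hidden_weights,
    hidden_biases = model$hidden_biases,
    output_weights = model$output_weights,
    output_bias = model$output_bias,
    output_activation = model$output_activation,
    sigmoid_form = model$sigmoid_form
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname mlp_save
#' @export
mlp_load <- function(path) {
  if (!file.exists(path)) abort(paste0("model file not found: ", path),
                                class = "st_io_error")
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version) || doc$schema_version != 1L) {
    abort(paste0("unsupported model schema version: ",
                 doc$schema_version %||% "<missing>"),
          class = "st_load_error")
  }
  arch <- as.integer(doc$architecture)
  n_in <- arch[1]; hidden <- arch[2]
  W <- matrix(as.numeric(doc$hidden_weights), nrow = hidden, ncol = n_in)
  n_found <- length(doc$hidden_weights) + length(doc$hidden_biases) +
    length(doc$output_weights) + 1L
  if (n_found != mlp_n_params(n_in, hidden) ||
      length(doc$hidden_biases) != hidden || length(doc$output_weights) != hidden) {
    abort(paste0("model file is inconsistent: expected ",
                 mlp_n_params(n_in, hidden), " parameters for (",
                 n_in, ",", hidden, ",1), found ", n_found),
          class = "st_load_error")
  }
  norms <- lapply(seq_len(nrow(doc$input_norms)), function(i) {
    structure(list(name = doc$input_norms$name[i],
                   vmin = doc$input_norms$vmin[i],
                   vmax = doc$input_norms$vmax[i]), class = "st_norm")
  })
  structure(list(
    n_in = n_in, hidden = hidden,
    hidden_weights = W,
    hidden_biases = as.numeric(doc$hidden_biases),
    output_weights = as.numeric(doc$output_weights),
    output_bias = as.numeric(doc$output_bias),
    input_names = as.character(doc$input_names),
    input_norms = norms,
    output_norm = structure(list(name = doc$output_norm$name,
                                 vmin = doc$output_norm$vmin,
                                 vmax = doc$output_norm$vmax),
                            class = "st_norm"),
    output_activation = doc$output_activation %||% "linear",
    sigmoid_form = doc$sigmoid_form %||% "standard"
  ), class = "st_mlp")
}

#' Build a perceptron with given or random weights
#'
#' Used as a frozen "teacher" in recovery experiments and tests: a network
#' with seeded random weights defines a smooth ground-truth surface from
#' which synthetic data are generated.
#'
#' @param input_norms List of `st_norm` for each input.
#' @param output_norm `st_norm` for sigma.
#' @param hidden Hidden-layer size.
#' @param seed Seed for the uniform weight draw.
#' @param input_names Input labels (default `c("Tr", "Tb_K", "omega")`).
#' @param range Half-width of the uniform draw.
#' @param calibrate_to Optional tibble (with `T_K`, `Tc_K` and the model
#'   inputs): the output layer is rescaled affinely so the network's
#'   normalised outputs span \[0.2, 0.8\] over those rows, keeping generated
#'   surface tensions positive and on a realistic scale.
#' @return An `st_mlp` with random weights (untrained).
#' @export
mlp_random <- function(input_norms, output_norm, hidden = 5, seed = 1L,
                       input_names = c("Tr", "Tb_K", "omega"), range = 1.5,
                       calibrate_to = NULL) {
  n_in <- length(input_norms)
  P <- mlp_n_params(n_in, hidden)
  theta <- withr::with_seed(seed, runif(P, -range, range))
  p <- mlp_unpack(theta, n_in, hidden)
  model <- structure(list(
    n_in = n_in, hidden = as.integer(hidden),
    hidden_weights = p$W, hidden_biases = p$b,
    output_weights = p$v, output_bias = p$c,
    input_names = input_names, input_norms = input_norms,
    output_norm = output_norm,
    output_activation = "linear", sigmoid_form = "standard"
  ), class = "st_mlp")
  if (!is.null(calibrate_to)) {
    X <- st_input_matrix(calibrate_to, input_names)
    Xn <- vapply(seq_len(n_in),
                 function(k) st_normalize(input_norms[[k]], X[, k]),
                 numeric(nrow(X)))
    y <- mlp_forward_norm(mlp_pack(p$W, p$b, p$v, p$c), Xn, hidden)$y
    if (max(y) > min(y)) {
      k <- 0.6 / (max(y) - min(y))
      model$output_weights <- p$v * k
      model$output_bias <- 0.2 + (p$c - min(y)) * k
    }
  }
  model
}
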