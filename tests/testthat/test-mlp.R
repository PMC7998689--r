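test_that("sigmoid has the textbook values and symmetry", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(2), 0.880797, tolerance = 1e-6)
  x <- withr::with_seed(1, runif(30, -20, 20))
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, 30), tolerance = 1e-12)
  # the printed decreasing variant is the mirror image
  expect_equal(sigmoid(x, form = "printed"), sigmoid(-x), tolerance = 1e-15)
  expect_true(all(diff(sigmoid(seq(-5, 5, 0.1))) > 0))
})

test_that("parameter count follows n_hidden*(n_in+1) + n_hidden + 1", {
  expect_identical(mlp_n_params(3, 41), 206L)
  expect_identical(mlp_n_params(3, 5), 26L)
  expect_identical(mlp_n_params(4, 41), 247L)
  # and the weight table of an actual (3,41,1) model has exactly that many rows
  norms <- list(st_normalizer(0:1, "Tr"), st_normalizer(c(300, 700), "Tb_K"),
                st_normalizer(c(0.2, 1.2), "omega"))
  m <- mlp_random(norms, st_normalizer(c(0.002, 0.06), "sigma"), hidden = 41)
  expect_equal(nrow(tidy(m)), 206)
})

test_that("forward pass matches a hand-computed chain and batches consistently", {
  norms <- list(st_normalizer(c(0, 1), "Tr"),
                st_normalizer(c(300, 700), "Tb_K"),
                st_normalizer(c(0.2, 1.2), "omega"))
  out_norm <- st_normalizer(c(0.002, 0.060), "sigma")

  # all-zero network: output is denormalize(0) = vmin of the sigma norm
  zero <- mlp_random(norms, out_norm, hidden = 4, seed = 1)
  zero$hidden_weights[] <- 0
  zero$hidden_biases[] <- 0
  zero$output_weights[] <- 0
  zero$output_bias <- 0
  nd <- tibble::tibble(T_K = c(330, 390), Tc_K = 600, Tb_K = 450, omega = 0.7)
  expect_equal(predict(zero, nd)$sigma_calc, rep(out_norm$vmin, 2))

  # one hidden neuron with stated weights: sigmoid -> linear -> denormalise,
  # expected value computed by hand for Tr=0.55, Tb=450 K, omega=0.7
  one <- mlp_random(norms, out_norm, hidden = 1, seed = 1)
  one$hidden_weights <- matrix(c(0.8, -0.5, 0.3), nrow = 1)
  one$hidden_biases <- 0.1
  one$output_weights <- 1.2
  one$output_bias <- -0.4
  nd1 <- tibble::tibble(T_K = 0.55 * 600, Tc_K = 600, Tb_K = 450, omega = 0.7)
  expect_equal(predict(one, nd1)$sigma_calc, 0.022164047561516492,
               tolerance = 1e-12)

  # batch forward equals per-row forward
  m <- mlp_random(norms, out_norm, hidden = 6, seed = 3)
  batch <- tibble::tibble(T_K = seq(320, 500, length.out = 7), Tc_K = 620,
                          Tb_K = 410, omega = 0.5)
  all_at_once <- predict(m, batch)$sigma_calc
  one_by_one <- vapply(seq_len(nrow(batch)),
                       function(i) predict(m, batch[i, ])$sigma_calc,
                       numeric(1))
  expect_equal(all_at_once, one_by_one, tolerance = 1e-14)
})

test_that("analytic Jacobian agrees with central finite differences", {
  for (case in list(c(3, 5), c(2, 4), c(3, 1))) {
    n_in <- case[1]
    hidden <- case[2]
    P <- mlp_n_params(n_in, hidden)
    theta <- withr::with_seed(hidden, runif(P, -1, 1))
    Xn <- withr::with_seed(hidden + 50, matrix(runif(12 * n_in), 12, n_in))
    J <- surftens:::mlp_jacobian(theta, Xn, hidden)
    h <- 1e-6
    J_fd <- matrix(0, nrow(Xn), P)
    for (j in seq_len(P)) {
      tp <- theta
      tm <- theta
      tp[j] <- tp[j] + h
      tm[j] <- tm[j] - h
      J_fd[, j] <- (surftens:::mlp_forward_norm(tp, Xn, hidden)$y -
                      surftens:::mlp_forward_norm(tm, Xn, hidden)$y) / (2 * h)
    }
    expect_lt(max(abs(J - J_fd)) / max(abs(J)), 1e-6)
  }
})

test_that("a noise-free linear relation is fitted to high precision with 1 hidden neuron", {
  # sigma depends linearly on T for a single fluid; a low-gain sigmoid is
  # near-linear so one hidden neuron suffices
  T_K <- seq(300, 480, length.out = 60)
  d <- tibble::tibble(
    fluid = "lin", family = "unknown", Tc_K = 600, Tb_K = 400, omega = 0.5,
    T_K = T_K, sigma = 0.05 - 5e-5 * T_K, source = "synthetic"
  )
  fit <- mlp_fit(d, inputs = "Tr", hidden = 1, restarts = 3, seed = 2,
                 control = mlp_control(max_iter = 200))
  # training RMSE on the normalised residuals
  expect_lt(min(fit$history$train_rmse), 1e-4)
})

test_that("training is deterministic given seed and config", {
  d <- st_split(simulate_dataset(n_fluids = 6, seed = 5), seed = 5)
  ctl <- mlp_control(max_iter = 40)
  f1 <- mlp_fit(d, hidden = 3, restarts = 2, seed = 9, control = ctl)
  f2 <- mlp_fit(d, hidden = 3, restarts = 2, seed = 9, control = ctl)
  expect_identical(f1$hidden_weights, f2$hidden_weights)
  expect_identical(f1$output_weights, f2$output_weights)
  expect_identical(f1$history, f2$history)
})

test_that("accepted LM steps never increase the training RMSE", {
  d <- st_split(simulate_dataset(n_fluids = 6, seed = 5), seed = 5)
  fit <- mlp_fit(d, hidden = 4, restarts = 1, seed = 1,
                 control = mlp_control(max_iter = 120))
  expect_true(all(diff(fit$trace$train_rmse) <= 0))
})

test_that("our damped Gauss-Newton reaches the same optimum as an independent LM solver", {
  skip_if_not_installed("minpack.lm")
  d <- st_split(simulate_dataset(n_fluids = 5, seed = 8), seed = 8)
  hidden <- 3
  inputs <- c("Tr", "Tb_K", "omega")
  X <- surftens:::st_input_matrix(d, inputs)
  norms <- lapply(1:3, function(k) st_normalizer(X[, k], inputs[k]))
  onorm <- st_normalizer(d$sigma, "sigma")
  Xn <- vapply(1:3, function(k) st_normalize(norms[[k]], X[, k]),
               numeric(nrow(X)))
  tn <- st_normalize(onorm, d$sigma)
  tr <- d$subset == "training"
  theta0 <- withr::with_seed(4, runif(mlp_n_params(3, hidden), -0.5, 0.5))

  res <- minpack.lm::nls.lm(
    par = theta0,
    fn = function(th) surftens:::mlp_forward_norm(th, Xn[tr, ], hidden)$y - tn[tr],
    control = minpack.lm::nls.lm.control(maxiter = 400)
  )
  rmse_ref <- sqrt(mean(res$fvec^2))

  run <- surftens:::lm_run(Xn[tr, ], tn[tr], Xn[tr, ], tn[tr], hidden,
                           init_seed = 4, control = mlp_control(max_iter = 400))
  # same start: both solvers should land at optima of comparable quality
  expect_lt(run$final_train_rmse, 1.3 * rmse_ref + 1e-6)
})

test_that("model JSON round-trips exactly and rejects tampered files", {
  d <- st_split(simulate_dataset(n_fluids = 6, seed = 5), seed = 5)
  fit <- mlp_fit(d, hidden = 3, restarts = 1, seed = 2,
                 control = mlp_control(max_iter = 40))
  path <- withr::local_tempfile(fileext = ".json")
  mlp_save(fit, path)
  back <- mlp_load(path)
  probe <- tibble::tibble(T_K = seq(350, 500, length.out = 9), Tc_K = 640,
                          Tb_K = 420, omega = 0.6)
  expect_equal(suppressWarnings(predict(back, probe))$sigma_calc,
               suppressWarnings(predict(fit, probe))$sigma_calc,
               tolerance = 1e-12)

  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$hidden_biases <- doc$hidden_biases[-1]
  bad_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, bad_path, auto_unbox = TRUE, digits = NA)
  expect_error(mlp_load(bad_path), "expected 16", class = "st_load_error")

  doc$schema_version <- 99
  jsonlite::write_json(doc, bad_path, auto_unbox = TRUE, digits = NA)
  expect_error(mlp_load(bad_path), "schema", class = "st_load_error")
})

test_that("a hand-written minimal model file loads and predicts per hand computation", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "schema_version": 1,
    "architecture": [3, 1, 1],
    "input_names": ["Tr", "Tb_K", "omega"],
    "input_norms": [
      {"name": "Tr", "vmin": 0, "vmax": 1},
      {"name": "Tb_K", "vmin": 300, "vmax": 700},
      {"name": "omega", "vmin": 0.2, "vmax": 1.2}
    ],
    "output_norm": {"name": "sigma", "vmin": 0.002, "vmax": 0.060},
    "hidden_weights": [[0.8, -0.5, 0.3]],
    "hidden_biases": [0.1],
    "output_weights": [1.2],
    "output_bias": -0.4,
    "output_activation": "linear",
    "sigmoid_form": "standard"
  }', path)
  m <- mlp_load(path)
  nd <- tibble::tibble(T_K = 330, Tc_K = 600, Tb_K = 450, omega = 0.7)
  expect_equal(predict(m, nd)$sigma_calc, 0.022164047561516492,
               tolerance = 1e-12)
})

test_that("predictions outside the fitted input range are flagged, not refused", {
  d <- st_split(simulate_dataset(n_fluids = 6, seed = 5), seed = 5)
  fit <- mlp_fit(d, hidden = 2, restarts = 1, seed = 2,
                 control = mlp_control(max_iter = 30))
  inside <- tibble::tibble(T_K = 0.5 * 700, Tc_K = 700, Tb_K = 450, omega = 0.6)
  expect_silent(p_in <- predict(fit, inside))
  expect_false(any(p_in$extrapolated))
  outside <- tibble::tibble(T_K = 0.97 * 700, Tc_K = 700, Tb_K = 450, omega = 0.6)
  expect_warning(p_out <- predict(fit, outside), "extrapolate")
  expect_true(all(p_out$extrapolated))
  # T >= Tc is a hard validation error, with the row named
  expect_error(predict(fit, tibble::tibble(T_K = 710, Tc_K = 700,
                                           Tb_K = 450, omega = 0.6)),
               "row 1", class = "st_validation_error")
})
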