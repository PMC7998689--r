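test_that("deviation statistics reproduce hand-computed values", {
  expect_equal(percent_deviation(0.04, 0.04), 0)
  expect_equal(percent_deviation(0.05, 0.04), 25)
  expect_error(percent_deviation(0.05, 0), class = "st_domain_error")
  expect_error(percent_deviation(c(1, 2), 1), class = "st_domain_error")

  expect_equal(aad(c(0, 0, 0)), 0)
  expect_equal(aad(c(2, -4, 6)), 4)
  expect_equal(aad(-3.2), 3.2)
  expect_error(aad(numeric(0)), class = "st_domain_error")

  expect_equal(st_rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(st_rmse(c(1, 2, 3), c(1, 2, 3) + 0.007), 0.007) # constant offset
  expect_equal(st_rmse(c(0.003, -0.004), c(0, 0)), sqrt(12.5e-6),
               tolerance = 1e-12)

  expect_equal(st_r2(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(st_r2(c(1, 2, 3), rep(2, 3)), 0) # predicting the mean
  expect_equal(st_r2(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(st_r2(rep(2, 4), rep(2, 4)), class = "st_domain_error")
})

test_that("a printed absolute difference and percent deviation are mutually consistent", {
  # back-solving PD = 100 * d / sigma with d = 0.0004095 N/m and PD = 14.53%
  sigma_data <- 0.0004095 / 0.1453
  expect_equal(sigma_data, 0.002818, tolerance = 5e-4)
  expect_equal(abs(percent_deviation(sigma_data + 0.0004095, sigma_data)),
               14.53, tolerance = 1e-10)
})

test_that("vectorised statistics agree with naive per-datum loops to 1e-12 relative", {
  for (seed in 1:5) {
    n <- 200
    obs <- withr::with_seed(seed, runif(n, 0.001, 0.07))
    calc <- obs * withr::with_seed(seed + 100, (1 + rnorm(n, 0, 0.05)))
    pds <- percent_deviation(calc, obs)

    pd_loop <- numeric(n)
    for (i in seq_len(n)) pd_loop[i] <- 100 * (calc[i] - obs[i]) / obs[i]
    expect_equal(pds, pd_loop, tolerance = 1e-12)

    s_abs <- 0
    m_abs <- 0
    ss_res <- 0
    for (i in seq_len(n)) {
      s_abs <- s_abs + abs(pd_loop[i])
      m_abs <- max(m_abs, abs(pd_loop[i]))
      ss_res <- ss_res + (obs[i] - calc[i])^2
    }
    expect_equal(aad(pds), s_abs / n, tolerance = 1e-12)
    expect_equal(pdm(pds), m_abs, tolerance = 1e-12)
    expect_equal(st_rmse(obs, calc), sqrt(ss_res / n), tolerance = 1e-12)
    expect_equal(st_r2(obs, calc),
                 1 - ss_res / sum((obs - mean(obs))^2), tolerance = 1e-12)

    # PDm >= AAD always; percent stats scale-free, RMSE linear in scale
    expect_gte(pdm(pds), aad(pds))
    pds_k <- percent_deviation(calc * 1000, obs * 1000)
    expect_equal(aad(pds_k), aad(pds), tolerance = 1e-12)
    expect_equal(pdm(pds_k), pdm(pds), tolerance = 1e-12)
    expect_equal(st_rmse(obs * 1000, calc * 1000), 1000 * st_rmse(obs, calc),
                 tolerance = 1e-12)
  }
})

test_that("report assembly matches brute-force per-fluid and weighted-mean identities", {
  d <- st_split(simulate_dataset(n_fluids = 8, seed = 21), seed = 4)
  calc <- d$sigma * withr::with_seed(9, (1 + rnorm(nrow(d), 0, 0.03)))

  rep <- st_fit_report(d, calc)
  expect_setequal(rep$subset, c("training", "test", "prediction", "complete"))
  expect_true(all(rep$PDm >= rep$AAD))
  expect_true(all(rep$R2 <= 1))

  fl <- st_fluid_report(d, calc)
  # brute-force re-aggregation per fluid
  for (f in unique(d$fluid)) {
    idx <- d$fluid == f
    pds_f <- 100 * (calc[idx] - d$sigma[idx]) / d$sigma[idx]
    expect_equal(fl$AAD[fl$fluid == f], mean(abs(pds_f)), tolerance = 1e-12)
    expect_equal(fl$PDm[fl$fluid == f], max(abs(pds_f)), tolerance = 1e-12)
  }
  # complete-set AAD is the data-count-weighted mean of per-fluid AADs
  complete_aad <- rep$AAD[rep$subset == "complete"]
  expect_equal(complete_aad, sum(fl$AAD * fl$n) / sum(fl$n), tolerance = 1e-12)

  # perfect predictions: zero deviations, unit R2
  perfect <- st_fit_report(d, d$sigma)
  expect_true(all(perfect$AAD == 0 & perfect$PDm == 0 & perfect$RMSE == 0))
  expect_true(all(perfect$R2 == 1))

  expect_error(st_fit_report(d, calc[-1]), class = "st_domain_error")
})

test_that("near-zero data are excluded from percent statistics with a warning", {
  d <- tiny_dataset()
  d$sigma[1] <- 5e-7 # below the default 1e-6 N/m floor
  calc <- d$sigma * 1.02
  expect_warning(rep <- st_fit_report(d, calc), "sigma floor")
  # the floored point is excluded from AAD but still counted in n and RMSE
  expect_equal(rep$n[rep$subset == "complete"], nrow(d))
  expect_equal(rep$AAD[rep$subset == "complete"], 2, tolerance = 1e-9)
})
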