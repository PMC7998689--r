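# In-code fixtures: small datasets built programmatically, no files.

# a hand-written valid dataset: 3 fluids, 12 rows, constants in range
tiny_dataset <- function() {
  fl <- tibble::tibble(
    fluid = c("acid-a", "acid-b", "acid-c"),
    family = c("carboxylic", "aliphatic", "polyfunctional"),
    Tc_K = c(600, 700, 650),
    Tb_K = c(390, 455, 420),
    omega = c(0.45, 0.80, 0.60),
    Pc_bar = c(45, 30, 38),
    Mw_g_mol = c(60, 150, 104)
  )
  n_per <- c(5L, 4L, 3L)
  dplyr::bind_cols(
    fl[rep(1:3, n_per), ],
    tibble::tibble(
      T_K = c(300, 340, 380, 420, 460, 320, 380, 440, 500, 330, 390, 450),
      sigma = c(0.030, 0.026, 0.022, 0.018, 0.014,
                0.028, 0.023, 0.018, 0.013, 0.027, 0.022, 0.017),
      source = "hand"
    )
  )
}

# a dataset lying exactly on a corresponding-states model (per-fluid, no noise)
csp_exact_dataset <- function(model = "brock_bird", n_fluids = 8, seed = 42) {
  simulate_dataset(n_fluids = n_fluids, noise_sd = 0, dup_prob = 0,
                   seed = seed, teacher = "csp", csp_model = model)
}

# frozen random (3, hidden, 1) teacher over standard acid-like input ranges,
# output layer calibrated to positive sigma over the given fluids' data grid
make_teacher <- function(fluids, hidden = 5, seed = 11) {
  norms <- list(
    st_normalizer(c(0.2, 0.95), "Tr"),
    st_normalizer(range(fluids$Tb_K) + c(-1, 1), "Tb_K"),
    st_normalizer(range(fluids$omega) + c(-0.01, 0.01), "omega")
  )
  out_norm <- st_normalizer(c(0.002, 0.060), "sigma")
  grid <- tidyr::crossing(fluids, Tr_grid = seq(0.25, 0.92, length.out = 25)) |>
    dplyr::mutate(T_K = .data$Tr_grid * .data$Tc_K)
  mlp_random(norms, out_norm, hidden = hidden, seed = seed,
             calibrate_to = grid)
}

# teacher-generated dataset of about 2000 points (34 points per fluid x 60)
teacher_dataset <- function(hidden = 5, seed = 11, noise_sd = 0,
                            n_fluids = 60, points = c(34, 34)) {
  fluids <- simulate_fluids(n_fluids, seed = seed)
  teacher <- make_teacher(fluids, hidden = hidden, seed = seed)
  data <- simulate_dataset(points = points, noise_sd = noise_sd, dup_prob = 0,
                           seed = seed, teacher = "network", network = teacher,
                           fluids = fluids)
  list(data = data, teacher = teacher, fluids = fluids)
}
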