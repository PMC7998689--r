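# Synthetic organic-acid surface-tension corpora. The generator emulates the
# statistical structure of multi-source experimental collections: smooth
# per-fluid sigma(T) curves vanishing at Tc, very uneven per-fluid point
# counts, and occasional duplicated temperatures with independent scatter
# (several sources reporting the same state point). It makes no claim to
# physical accuracy for any real acid.

#' Simulate per-fluid constants for synthetic organic acids
#'
#' Draws plausible, mutually consistent constants: Tc uniform on
#' \[550, 900\] K, Tb via a reduced boiling temperature Tb/Tc uniform on
#' \[0.55, 0.75\], acentric factor on \[0.3, 1.1\], Pc on \[10, 60\] bar,
#' Mw on \[46, 350\] g/mol, plus radius of gyration, liquid molar volume and
#' dipole moment so that the full nine-candidate effect-factor list is
#' exercisable. Families are assigned round-robin.
#'
#' @param n_fluids Number of fluids.
#' @param seed Integer seed; each fluid draws from its own derived stream
#'   (`seed * 1000 + index`), so fluid i is reproducible in isolation.
#' @return A tibble of fluid constants, one row per fluid.
#' @export
simulate_fluids <- function(n_fluids = 98, seed = 1L) {
  stopifnot(n_fluids >= 1)
  fams <- rep(c("carboxylic", "aliphatic", "polyfunctional"),
              length.out = n_fluids)
  rows <- lapply(seq_len(n_fluids), function(i) {
    withr::with_seed(as.integer(seed) * 1000L + i, {
      Tc <- runif(1, 550, 900)
      tbr <- runif(1, 0.55, 0.75)
      tibble::tibble(
        fluid = sprintf("synthacid-%03d", i),
        family = fams[i],
        Tc_K = Tc,
        Tb_K = tbr * Tc,
        omega = runif(1, 0.3, 1.1),
        Pc_bar = runif(1, 10, 60),
        Mw_g_mol = runif(1, 46, 350),
        rgyr_m = runif(1, 2e-10, 8e-10),
        Vm_L_mol = runif(1, 0.05, 0.40),
        mu_D = runif(1, 0, 3)
      )
    })
  })
  dplyr::bind_rows(rows)
}

# ground-truth amplitude: increasing in Tb, decreasing in omega (mN/m -> N/m).
# The encoded monotonicities give the effect-factor ranking a known sign
# structure to assert against.
st_sigma0 <- function(Tb_K, omega) {
  1e-3 * (12 + 0.09 * Tb_K - 14 * omega)
}

#' Simulate a synthetic surface-tension dataset
#'
#' Per fluid, the ground truth is a van der Waals-type curve
#' `sigma_true(T) = sigma0 * (1 - Tr)^p` with the classical critical exponent
#' `p = 11/9` jittered per fluid by +/- 0.1, and amplitude
#' `sigma0 = 1e-3 * (12 + 0.09 Tb - 14 omega)` N/m (increasing in Tb,
#' decreasing in omega). Observations are `sigma_true * (1 + e)` with
#' multiplicative Gaussian noise; with probability `dup_prob` a temperature
#' is duplicated under a second source tag with independent noise, mimicking
#' multi-source scatter. Alternative ground truths: a corresponding-states
#' model (`teacher = "csp"`) or a frozen random network
#' (`teacher = "network"`), for closed-loop and recovery tests.
#'
#' @param n_fluids Number of fluids (default 98, a corpus-sized set).
#' @param points Integer range of points per fluid; counts are drawn
#'   log-uniformly on the range (default `c(4, 165)`), giving the strongly
#'   right-skewed per-fluid counts typical of compiled corpora.
#' @param tr_window Reduced-temperature coverage, default `c(0.25, 0.92)`.
#' @param noise_sd Relative (multiplicative) noise standard deviation,
#'   default 0.01.
#' @param dup_prob Probability that a point is duplicated under a second
#'   source with independent noise, default 0.15.
#' @param seed Integer seed; all randomness derives from it via per-fluid
#'   sub-streams.
#' @param teacher `"guggenheim"` (default: the closed-form curve above, whose
#' critical exponent is the classical Guggenheim-type 11/9), `"csp"`,
#'   or `"network"`.
#' @param csp_model Corresponding-states teacher id, used when
#'   `teacher = "csp"`.
#' @param network An `st_mlp` teacher, used when `teacher = "network"`.
#' @param fluids Optional pre-built fluid table (from [simulate_fluids()]).
#' @return A validated dataset tibble; the generator truth (per-fluid
#'   `sigma0` and `p`, or the teacher spec) is attached as attribute
#'   `"truth"` and retrievable with [st_truth()].
#' @export
simulate_dataset <- function(n_fluids = 98, points = c(4, 165),
                             tr_window = c(0.25, 0.92), noise_sd = 0.01,
                             dup_prob = 0.15, seed = 1L,
                             teacher = c("guggenheim", "csp", "network"),
                             csp_model = "brock_bird", network = NULL,
                             fluids = NULL) {
  teacher <- match.arg(teacher)
  stopifnot(noise_sd >= 0, dup_prob >= 0, dup_prob <= 1,
            tr_window[1] > 0, tr_window[2] < 1, tr_window[1] < tr_window[2])
  if (teacher == "network" && !inherits(network, "st_mlp")) {
    abort("teacher = 'network' requires an st_mlp in `network`",
          class = "st_config_error")
  }
  if (is.null(fluids)) fluids <- simulate_fluids(n_fluids, seed = seed)
  n_fluids <- nrow(fluids)
  truth <- dplyr::mutate(
    fluids[, "fluid"],
    sigma0 = st_sigma0(fluids$Tb_K, fluids$omega),
    p = vapply(seq_len(n_fluids), function(i) {
      withr::with_seed(as.integer(seed) * 1000L + 500000L + i,
                       11 / 9 + runif(1, -0.1, 0.1))
    }, numeric(1))
  )
  rows <- lapply(seq_len(n_fluids), function(i) {
    fl <- fluids[i, ]
    withr::with_seed(as.integer(seed) * 1000L + 250000L + i, {
      n_i <- round(exp(runif(1, log(points[1]), log(points[2]))))
      tr <- sort(runif(n_i, tr_window[1], tr_window[2]))
      T_K <- tr * fl$Tc_K
      sigma_true <- switch(
        teacher,
        guggenheim = truth$sigma0[i] * (1 - tr)^truth$p[i],
        csp = csp_sigma(csp_model, T_K = T_K, Tc_K = fl$Tc_K, Tb_K = fl$Tb_K,
                        omega = fl$omega, Pc_bar = fl$Pc_bar,
                        Mw_g_mol = fl$Mw_g_mol),
        network = {
          nd <- dplyr::bind_cols(fl[rep(1, n_i), ], tibble::tibble(T_K = T_K))
          suppressWarnings(predict(network, nd))$sigma_calc
        }
      )
      eps <- pmax(rnorm(n_i, 0, noise_sd), -0.9)
      base <- dplyr::bind_cols(
        fl[rep(1, n_i), ],
        tibble::tibble(T_K = T_K, sigma = sigma_true * (1 + eps),
                       source = "src-A")
      )
      dup <- runif(n_i) < dup_prob
      if (any(dup)) {
        eps2 <- pmax(rnorm(sum(dup), 0, noise_sd), -0.9)
        extra <- dplyr::bind_cols(
          fl[rep(1, sum(dup)), ],
          tibble::tibble(T_K = T_K[dup], sigma = sigma_true[dup] * (1 + eps2),
                         source = "src-B")
        )
        base <- dplyr::bind_rows(base, extra)
      }
      base
    })
  })
  out <- dplyr::bind_rows(rows)
  st_validate(out)
  attr(out, "truth") <- truth
  attr(out, "teacher") <- teacher
  attr(out, "generator_seed") <- as.integer(seed)
  out
}

#' Retrieve the generator truth attached to a synthetic dataset
#'
#' @param data A tibble produced by [simulate_dataset()].
#' @return The per-fluid truth tibble (`fluid`, `sigma0`, `p`).
#' @export
st_truth <- function(data) {
  tr <- attr(data, "truth")
  if (is.null(tr)) abort("no generator truth attached to this dataset",
                         class = "st_domain_error")
  tr
}
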