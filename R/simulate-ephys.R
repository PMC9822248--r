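#' Simulate a four-group nested electrophysiology dataset
#'
#' Generates amplitude-like measurements with the three-level structure of a
#' culture experiment: independent batches (cultures) per group, cells within
#' batches, sweeps within cells. Values are log-normal: positive and
#' right-skewed, as postsynaptic current amplitudes are. Group effects are
#' multiplicative; batch- and cell-level random effects are multiplicative
#' mean-one log-normals (additive on the log scale) with standard deviations
#' `batch_sd` and `cell_sd` in log units; sweep noise is a mean-one log-normal
#' with coefficient of variation `sweep_cv`.
#'
#' The default group effects emulate a strong knockout phenotype: line A
#' retains 15% of control transmission and line B a further ~50% less (7.5%),
#' so the true ratio-of-ratios is
#' `T_true = (0.15/1) / (0.075/1) = 2`.
#'
#' @param n_batches batches (cultures) per group; a single count or a length-2
#'   inclusive range sampled per group.
#' @param n_cells cells per batch; count or length-2 range sampled per batch.
#' @param n_sweeps sweeps per cell; count or length-2 range sampled per cell.
#' @param baseline_mean control-group mean amplitude (pA).
#' @param group_effects named multiplicative factor per group (> 0), names as
#'   in [GROUP_LABELS].
#' @param batch_sd,cell_sd standard deviation of the batch-/cell-level
#'   log-effect (log units, >= 0).
#' @param sweep_cv coefficient of variation of within-cell sweep noise (>= 0).
#' @param single_sweep generate one sweep per cell and flag the dataset as a
#'   single-sweep design (ignores `n_sweeps`).
#' @param seed integer seed; the generator is a pure function of its arguments
#'   including the seed.
#' @return a [nested_dataset()] with attribute `ground_truth`: a list with the
#'   group effects, `T_true`, and the drawn batch/cell random effects.
#' @examples
#' d <- simulate_ephys_dataset(seed = 1)
#' attr(d, "ground_truth")$T_true
#' @export
simulate_ephys_dataset <- function(n_batches = 3, n_cells = 6, n_sweeps = 3,
                                   baseline_mean = 500,
                                   group_effects = c(control_A = 1, ko_A = 0.15,
                                                     control_B = 1, ko_B = 0.075),
                                   batch_sd = 0.3, cell_sd = 0.3, sweep_cv = 0.3,
                                   single_sweep = FALSE, seed = NULL) {
  stop_if_not_count(n_batches, "n_batches")
  stop_if_not_count(n_cells, "n_cells")
  stop_if_not_count(n_sweeps, "n_sweeps")
  stop_if_negative(batch_sd, "batch_sd")
  stop_if_negative(cell_sd, "cell_sd")
  stop_if_negative(sweep_cv, "sweep_cv")
  stop_if_negative(baseline_mean, "baseline_mean")
  if (!setequal(names(group_effects), GROUP_LABELS) || any(group_effects <= 0))
    stop("`group_effects` must be a named positive vector over the four groups",
         call. = FALSE)

  draw_count <- function(spec) {
    if (length(spec) == 1) spec else sample(seq(spec[1], spec[2]), 1)
  }
  # mean-one log-normal: E[exp(N(-s^2/2, s^2))] = 1
  rlnorm1 <- function(n, sdlog) exp(rnorm(n, -sdlog^2 / 2, sdlog))
  sweep_sdlog <- sqrt(log(1 + sweep_cv^2))

  with_seed_or_current(seed, {
    rows <- vector("list", 4L)
    effects <- list()
    for (g in GROUP_LABELS) {
      nb <- draw_count(n_batches)
      b_eff <- rlnorm1(nb, batch_sd)
      g_rows <- list()
      g_eff <- list()
      for (b in seq_len(nb)) {
        nc <- draw_count(n_cells)
        c_eff <- rlnorm1(nc, cell_sd)
        g_eff[[b]] <- c_eff
        for (ce in seq_len(nc)) {
          ns <- if (single_sweep) 1L else draw_count(n_sweeps)
          mu <- baseline_mean * group_effects[[g]] * b_eff[b] * c_eff[ce]
          vals <- mu * exp(rnorm(ns, -sweep_sdlog^2 / 2, sweep_sdlog))
          g_rows[[length(g_rows) + 1L]] <- data.frame(
            group = g, batch = paste0("b", b), cell = paste0("c", ce),
            sweep = seq_len(ns), value = vals)
        }
      }
      rows[[match(g, GROUP_LABELS)]] <- do.call(rbind, g_rows)
      effects[[g]] <- list(batch = b_eff, cell = g_eff)
    }
    d <- nested_dataset(do.call(rbind, rows), single_sweep = single_sweep)
    ge <- group_effects[GROUP_LABELS]
    attr(d, "ground_truth") <- list(
      group_effects = ge,
      T_true = (ge[["ko_A"]] / ge[["control_A"]]) /
               (ge[["ko_B"]] / ge[["control_B"]]),
      random_effects = effects,
      baseline_mean = baseline_mean, batch_sd = batch_sd, cell_sd = cell_sd,
      sweep_cv = sweep_cv, seed = seed)
    d
  })
}
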