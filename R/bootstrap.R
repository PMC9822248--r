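#' Ratio-of-ratios statistic T for a four-group nested design
#'
#' `T = (mean(ko_A) / mean(control_A)) / (mean(ko_B) / mean(control_B))`,
#' where each mean is the grand mean of the group. The null value is 1: the
#' knockout effect, normalized to its own control, is the same in both lines.
#' With amplitude-like measurements, `T > 1` means line B is more strongly
#' impaired than line A.
#'
#' @param dataset a [nested_dataset()].
#' @param group_mean `"pooled"` (grand mean over all sweep values in the
#'   group; default) or `"cell"` (mean of per-cell means).
#' @return the dimensionless ratio T.
#' @export
statistic_T <- function(dataset, group_mean = c("pooled", "cell")) {
  stopifnot(inherits(dataset, "nested_dataset"))
  group_mean <- match.arg(group_mean)
  m <- group_means(dataset, group_mean)
  if (m[["control_A"]] == 0 || m[["control_B"]] == 0)
    stop("control group mean is zero: T undefined", call. = FALSE)
  (m[["ko_A"]] / m[["control_A"]]) / (m[["ko_B"]] / m[["control_B"]])
}

group_means <- function(dataset, group_mean = "pooled") {
  vapply(stats::setNames(GROUP_LABELS, GROUP_LABELS), function(g) {
    xg <- dataset[dataset$group == g, , drop = FALSE]
    if (group_mean == "pooled") mean(xg$value)
    else mean(tapply(xg$value, paste(xg$batch, xg$cell), mean))
  }, numeric(1))
}

#' One hierarchical resample of a nested dataset
#'
#' Within each group independently (group identity is preserved): batches are
#' drawn with replacement (as many as the group has); within each drawn batch
#' its cells are drawn with replacement (that batch's own cell count); within
#' each drawn cell its sweeps are drawn with replacement (that cell's own
#' sweep count). For single-sweep designs the sweep level is skipped. The
#' resampled tree therefore has identical level-wise counts along every path,
#' and unbalanced designs keep the drawn unit's own size.
#'
#' Uses the current RNG stream; seed control belongs to the caller (or use
#' [run_bootstrap()], which vectorizes this resampling internally).
#'
#' @param dataset a [nested_dataset()].
#' @return a resampled `nested_dataset` (batches/cells relabelled by draw
#'   position).
#' @export
resample_nested <- function(dataset) {
  stopifnot(inherits(dataset, "nested_dataset"))
  single <- isTRUE(attr(dataset, "single_sweep"))
  tree <- as_nested_tree(dataset)
  rows <- list()
  for (g in GROUP_LABELS) {
    batches <- tree[[g]]
    nb <- length(batches)
    for (bi in seq_len(nb)) {
      b <- batches[[sample.int(nb, 1)]]
      nc <- length(b)
      for (ci in seq_len(nc)) {
        v <- b[[sample.int(nc, 1)]]
        ns <- length(v)
        vals <- if (single) v else v[sample.int(ns, ns, replace = TRUE)]
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, batch = paste0("b", bi), cell = paste0("c", ci),
          sweep = seq_along(vals), value = vals)
      }
    }
  }
  nested_dataset(do.call(rbind, rows), single_sweep = single)
}

#' Percentile confidence interval
#'
#' Empirical quantiles of the replicate sample at `(1 - level) / 2` and
#' `1 - (1 - level) / 2`, using linear interpolation between order statistics
#' (type 7).
#'
#' @param samples numeric replicate vector (>= 2 values unless `level` is 0).
#' @param level confidence level in `[0, 1)`; `level = 0` degenerates to the
#'   median for both endpoints.
#' @return named numeric vector `c(low, high)`.
#' @export
percentile_interval <- function(samples, level = 0.95) {
  if (!length(samples)) stop("empty replicate sample", call. = FALSE)
  if (level < 0 || level >= 1) stop("`level` must be in [0, 1)", call. = FALSE)
  alpha <- (1 - level) / 2
  q <- quantile(samples, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' Directional null probability from bootstrap replicates
#'
#' The fraction of replicates on the null side of 1: for direction
#' `"greater"` (alternative T > 1) the fraction with `T* <= 1`, for
#' `"less"` (alternative T < 1) the fraction with `T* >= 1`. Ties at exactly
#' 1 count toward the null in both directions.
#'
#' @param samples numeric replicate vector.
#' @param direction `"greater"` or `"less"` (the alternative hypothesis).
#' @return probability in `[0, 1]`.
#' @export
p_null <- function(samples, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (!length(samples)) stop("empty replicate sample", call. = FALSE)
  if (direction == "greater") mean(samples <= 1) else mean(samples >= 1)
}

#' Three-level hierarchical bootstrap of the ratio statistic T
#'
#' Estimates the sampling distribution of [statistic_T()] by resampling with
#' replacement at the three nested levels of the design (batch of culture,
#' cell, sweep), independently within each group so that group identity is
#' preserved. From the `n_iter` replicates it reports the percentile 95%
#' confidence interval and the directional null probability
#' ([p_null()]). Iterations in which a resampled control mean is exactly zero
#' (possible only if a group contains zero values) are re-drawn and counted.
#'
#' @param dataset a [nested_dataset()]; single-sweep datasets skip the sweep
#'   resampling level.
#' @param n_iter number of bootstrap iterations (the headline analyses use
#'   100,000).
#' @param direction alternative hypothesis: `"greater"` (T > 1; evoked and
#'   sucrose-evoked responses) or `"less"` (T < 1; paired-pulse ratios).
#' @param seed integer seed; results are bit-identical for identical
#'   `(dataset, n_iter, seed)`.
#' @param level confidence level of the percentile interval.
#' @param group_mean see [statistic_T()].
#' @return an object of class `bootstrap_result`: list with `t_obs`, `t_star`
#'   (length `n_iter`), `ci` (percentile interval), `p_h0`, `direction`,
#'   `n_iter`, `seed`, `n_redrawn`, `level`, `group_mean`.
#' @examples
#' d <- simulate_ephys_dataset(seed = 7)
#' b <- run_bootstrap(d, n_iter = 2000, seed = 7)
#' b
#' @export
run_bootstrap <- function(dataset, n_iter = 100000,
                          direction = c("greater", "less"), seed = NULL,
                          level = 0.95, group_mean = c("pooled", "cell")) {
  stopifnot(inherits(dataset, "nested_dataset"))
  direction <- match.arg(direction)
  group_mean <- match.arg(group_mean)
  stop_if_not_count(n_iter, "n_iter")
  t_obs <- statistic_T(dataset, group_mean)
  tree <- as_nested_tree(dataset)
  resample_sweeps <- !isTRUE(attr(dataset, "single_sweep"))
  cell_means <- group_mean == "cell"

  draw_means <- function(k) {
    vapply(GROUP_LABELS, function(g)
      hb_group_means(tree[[g]], k, resample_sweeps, cell_means),
      numeric(k))
  }
  with_seed_or_current(seed, {
    m <- draw_means(n_iter)
    if (n_iter == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, GROUP_LABELS))
    n_redrawn <- 0L
    for (round in 1:100) {
      bad <- which(m[, "control_A"] == 0 | m[, "control_B"] == 0)
      if (!length(bad)) break
      n_redrawn <- n_redrawn + length(bad)
      mr <- draw_means(length(bad))
      if (length(bad) == 1) mr <- matrix(mr, nrow = 1)
      m[bad, ] <- mr
      if (round == 100)
        stop("T undefined on (almost) every resample: degenerate dataset",
             call. = FALSE)
    }
    t_star <- (m[, "ko_A"] / m[, "control_A"]) / (m[, "ko_B"] / m[, "control_B"])
    structure(list(t_obs = t_obs, t_star = as.numeric(t_star),
                   ci = percentile_interval(t_star, level),
                   p_h0 = p_null(t_star, direction),
                   direction = direction, n_iter = n_iter, seed = seed,
                   n_redrawn = n_redrawn, level = level,
                   group_mean = group_mean,
                   quantile_rule = "type 7 (linear interpolation)"),
              class = "bootstrap_result")
  })
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> T = %.4g, %g%% CI [%.4g, %.4g]\n",
              x$t_obs, 100 * x$level, x$ci[["low"]], x$ci[["high"]]))
  cat(sprintf("  P_H0 (alternative T %s 1) = %.5g from %d iterations",
              if (x$direction == "greater") ">" else "<", x$p_h0, x$n_iter))
  if (x$n_redrawn > 0) cat(sprintf(" (%d re-drawn)", x$n_redrawn))
  cat("\n")
  invisible(x)
}

#' Write a bootstrap result as JSON
#'
#' Scalars (`t_obs`, CI, `p_h0`, iteration/seed metadata) go to `path`; the
#' full replicate sample is optionally written as a one-column table.
#'
#' @param x a `bootstrap_result`.
#' @param path JSON output path.
#' @param t_star_path optional path for the replicate sample.
#' @export
write_bootstrap_result <- function(x, path, t_star_path = NULL) {
  stopifnot(inherits(x, "bootstrap_result"))
  jsonlite::write_json(
    list(t_obs = x$t_obs, ci_low = x$ci[["low"]], ci_high = x$ci[["high"]],
         p_h0 = x$p_h0, direction = x$direction, n_iter = x$n_iter,
         seed = x$seed, n_redrawn = x$n_redrawn, level = x$level,
         group_mean = x$group_mean, quantile_rule = x$quantile_rule),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(t_star_path))
    utils::write.table(data.frame(t_star = x$t_star), t_star_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
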