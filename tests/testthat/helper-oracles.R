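# Independent oracles and fixture builders shared across tests.

# Build a nested_dataset from a list: group -> list of batches -> list of cell
# sweep vectors.
make_dataset <- function(groups, single_sweep = FALSE) {
  rows <- list()
  for (g in names(groups)) {
    for (b in seq_along(groups[[g]])) {
      for (ce in seq_along(groups[[g]][[b]])) {
        v <- groups[[g]][[b]][[ce]]
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, batch = paste0("b", b), cell = paste0("c", ce),
          sweep = seq_along(v), value = v)
      }
    }
  }
  nested_dataset(do.call(rbind, rows), single_sweep = single_sweep)
}

# four-group dataset with 2 batches x 1 cell x 1 sweep per group
tiny_two_batch_dataset <- function(vals) {
  make_dataset(lapply(vals, function(v) list(list(v[1]), list(v[2]))))
}

# Exhaustive enumeration of the hierarchical bootstrap for the 2-batch x
# 1-cell x 1-sweep-per-group design: each group's resampled mean is the mean
# of an ordered pair drawn with replacement from its two values (4 equiprobable
# draws), so the joint T* distribution has 4^4 = 256 equiprobable atoms.
enumerate_tiny_T <- function(vals) {
  pair_means <- function(v) {
    g <- expand.grid(i = 1:2, j = 1:2)
    (v[g$i] + v[g$j]) / 2
  }
  m <- lapply(vals, pair_means)
  g <- expand.grid(a = 1:4, ka = 1:4, b = 1:4, kb = 1:4)
  t_all <- (m$ko_A[g$ka] / m$control_A[g$a]) /
    (m$ko_B[g$kb] / m$control_B[g$b])
  t_all  # 256 equiprobable T* values
}

# Independently coded type-7 quantile (linear interpolation between order
# statistics), used to cross-check percentile_interval.
manual_quantile_type7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- pmin(lo + 1, n)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Check that an estimated quantile is consistent with a discrete reference
# distribution: the reference CDF strictly below / at the estimate must
# bracket the target probability within the Monte-Carlo tolerance.
quantile_consistent <- function(q_est, ref_values, target_p, tol) {
  below <- mean(ref_values < q_est - 1e-12)
  at_or_below <- mean(ref_values <= q_est + 1e-12)
  below <= target_p + tol && at_or_below >= target_p - tol
}
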