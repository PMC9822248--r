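#' Normalize knockout measurements to their own control
#'
#' Divides each knockout cell's value by the mean of the control cells of the
#' same line, producing dimensionless per-cell values comparable across lines
#' (1 = control level).
#'
#' @param ko_values per-cell knockout measurements.
#' @param control_values per-cell control measurements of the same line.
#' @param line optional line label carried through.
#' @return list of class `normalized_set`: `values` (dimensionless),
#'   `control_mean` (original units), `line`.
#' @export
normalize_to_control <- function(ko_values, control_values, line = NULL) {
  if (!length(control_values)) stop("no control values", call. = FALSE)
  m <- mean(control_values)
  if (m == 0) stop("control mean is zero: normalization undefined", call. = FALSE)
  structure(list(values = as.numeric(ko_values) / m, control_mean = m,
                 line = line),
            class = "normalized_set")
}

#' Two-group test selection policy
#'
#' Chooses and runs the standard two-group test under the policy: parametric
#' if both groups pass Shapiro-Wilk normality at `alpha` or both have
#' n >= 30; then Student's t if an F-ratio variance-equality test does not
#' reject at `alpha`, else Welch's t; otherwise Mann-Whitney. Groups with zero
#' variance never pass the normality gate (Shapiro-Wilk is undefined there).
#'
#' @param group_a,group_b numeric vectors (>= 3 values each).
#' @param alpha significance level used for the normality and
#'   variance-equality gates.
#' @return list of class `test_decision`: `test` (`"student_t"`, `"welch_t"`
#'   or `"mann_whitney"`), `p_value`, `statistic`, `parametric`,
#'   `normality_p` (per group), `equal_variance_p` (NA on the nonparametric
#'   branch), `n`, `alpha`. The decision is a pure function of the inputs.
#' @export
choose_test <- function(group_a, group_b, alpha = 0.05) {
  n <- c(a = length(group_a), b = length(group_b))
  if (any(n < 3)) stop("need at least 3 values per group", call. = FALSE)
  swp <- function(x) {
    if (length(x) > 5000 || var(x) == 0) return(NA_real_)
    shapiro.test(x)$p.value
  }
  norm_p <- c(a = swp(group_a), b = swp(group_b))
  normal <- !is.na(norm_p) & norm_p > alpha
  parametric <- all(normal) || all(n >= 30)
  if (parametric) {
    vp <- var.test(group_a, group_b)$p.value
    equal_var <- !is.na(vp) && vp > alpha
    ht <- t.test(group_a, group_b, var.equal = equal_var)
    test <- if (equal_var) "student_t" else "welch_t"
  } else {
    vp <- NA_real_
    ht <- suppressWarnings(wilcox.test(group_a, group_b, exact = FALSE))
    if (is.na(ht$p.value)) ht$p.value <- 1  # complete ties: no evidence at all
    test <- "mann_whitney"
  }
  structure(list(test = test, p_value = ht$p.value,
                 statistic = unname(ht$statistic), parametric = parametric,
                 normality_p = norm_p, equal_variance_p = vp,
                 n = n, alpha = alpha),
            class = "test_decision")
}

#' @export
print.test_decision <- function(x, ...) {
  cat(sprintf("<test_decision> %s (n = %d, %d), p = %.4g\n",
              x$test, x$n[["a"]], x$n[["b"]], x$p_value))
  invisible(x)
}

#' Factorial comparison of aligned line profiles within a window
#'
#' Two-way (condition x position) analysis of aligned intensity profiles,
#' restricted to a window along the trans-synaptic axis (the convention for
#' active-zone profiles is a 200-nm window centered on the active-zone peak),
#' followed by Bonferroni-adjusted per-position two-group comparisons.
#'
#' @param profiles numeric matrix, one row per profile (synapse), one column
#'   per axis position.
#' @param positions numeric axis (nm), length `ncol(profiles)`.
#' @param condition factor/character of length `nrow(profiles)` with exactly
#'   two levels.
#' @param window length-2 window (nm) within the axis range; default
#'   `center + c(-width, width) / 2`.
#' @param center,width used to build `window` when it is NULL; the default
#'   center -45 nm is the midpoint of the typical active-zone peak region
#'   (about -70 to -20 nm presynaptic of the PSD peak).
#' @return list of class `profile_test`: `anova` (the two-way ANOVA table),
#'   `per_position` data frame (`position`, `p`, `p_adj`,
#'   mean difference), `window`, `n_positions`.
#' @export
factorial_profile_test <- function(profiles, positions, condition,
                                   window = NULL, center = -45, width = 200) {
  profiles <- as.matrix(profiles)
  if (length(positions) != ncol(profiles))
    stop("`positions` must match the profile columns", call. = FALSE)
  if (length(condition) != nrow(profiles))
    stop("`condition` must match the profile rows", call. = FALSE)
  condition <- factor(condition)
  if (nlevels(condition) != 2)
    stop("exactly two conditions are required", call. = FALSE)
  if (is.null(window)) window <- center + c(-width, width) / 2
  if (window[1] < min(positions) || window[2] > max(positions))
    stop("window lies outside the profile axis", call. = FALSE)
  sel <- which(positions >= window[1] & positions <= window[2])
  if (!length(sel)) stop("window contains no axis positions", call. = FALSE)

  long <- data.frame(
    value = as.vector(profiles[, sel]),
    position = factor(rep(positions[sel], each = nrow(profiles))),
    condition = rep(condition, times = length(sel)))
  long <- long[is.finite(long$value), ]
  fit <- aov(value ~ condition * position, data = long)

  lv <- levels(condition)
  per <- do.call(rbind, lapply(sel, function(j) {
    a <- profiles[condition == lv[1], j]; b <- profiles[condition == lv[2], j]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    p <- if (length(a) > 1 && length(b) > 1 && (var(a) > 0 || var(b) > 0))
      t.test(a, b)$p.value else NA_real_
    data.frame(position = positions[j], mean_diff = mean(a) - mean(b), p = p)
  }))
  per$p_adj <- pmin(1, per$p * length(sel))  # Bonferroni over in-window positions
  structure(list(anova = summary(fit), per_position = per,
                 window = window, n_positions = length(sel)),
            class = "profile_test")
}

#' @export
print.profile_test <- function(x, ...) {
  cat(sprintf("<profile_test> window [%g, %g] nm, %d positions, %d significant (p_adj < 0.05)\n",
              x$window[1], x$window[2], x$n_positions,
              sum(x$per_position$p_adj < 0.05, na.rm = TRUE)))
  invisible(x)
}
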