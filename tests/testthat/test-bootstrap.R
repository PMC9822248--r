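test_that("statistic_T is the ratio of control-normalized group means", {
  d <- make_dataset(list(control_A = list(list(10)), ko_A = list(list(2)),
                         control_B = list(list(10)), ko_B = list(list(1))))
  expect_equal(statistic_T(d), 2)

  d1 <- make_dataset(list(control_A = list(list(c(5, 7))), ko_A = list(list(6)),
                          control_B = list(list(6)), ko_B = list(list(c(4, 8)))))
  expect_equal(statistic_T(d1), 1)  # all group means equal: null value

  d0 <- make_dataset(list(control_A = list(list(c(-1, 1))), ko_A = list(list(2)),
                          control_B = list(list(10)), ko_B = list(list(1))))
  expect_error(statistic_T(d0), "control group mean is zero")
})

test_that("statistic_T can use cell-level means instead of pooled sweeps", {
  # unbalanced sweeps: pooled and cell-mean answers differ in a known way
  d <- make_dataset(list(
    control_A = list(list(c(10, 10, 10, 2), c(4))),
    ko_A = list(list(2)), control_B = list(list(10)), ko_B = list(list(1))))
  pooled_ctrl <- mean(c(10, 10, 10, 2, 4))
  cellm_ctrl <- mean(c(mean(c(10, 10, 10, 2)), 4))
  expect_equal(statistic_T(d), (2 / pooled_ctrl) / (1 / 10))
  expect_equal(statistic_T(d, group_mean = "cell"), (2 / cellm_ctrl) / (1 / 10))
})

test_that("resample_nested preserves tree structure and is identity on 1x1x1", {
  d <- make_dataset(list(control_A = list(list(3)), ko_A = list(list(4)),
                         control_B = list(list(5)), ko_B = list(list(6))))
  r <- resample_nested(d)
  expect_equal(sort(r$value), sort(d$value))

  # unbalanced design: level-wise counts preserved along every path
  du <- make_dataset(list(
    control_A = list(list(c(1, 2), c(3)), list(c(4, 5, 6))),
    ko_A = list(list(c(1))), control_B = list(list(c(2, 2))),
    ko_B = list(list(c(3), c(4)))))
  set.seed(11)
  for (i in 1:20) {
    r <- resample_nested(du)
    expect_s3_class(r, "nested_dataset")
    cnt <- function(x) {
      xg <- x[x$group == "control_A", ]
      sort(tapply(xg$value, paste(xg$batch, xg$cell), length))
    }
    # batch count preserved; cell counts per drawn batch come from that batch
    expect_equal(length(unique(r[r$group == "control_A", "batch"])), 2)
    expect_true(all(cnt(r) %in% c(1, 2, 3)))
  }
})

test_that("resampled group mean matches brute-force enumeration on 2 batches", {
  # group with values {a, b}: resampled mean is a, (a+b)/2, b w.p. 1/4, 1/2, 1/4
  a <- 2; b <- 10
  d <- tiny_two_batch_dataset(list(control_A = c(a, b), ko_A = c(1, 1),
                                   control_B = c(1, 1), ko_B = c(1, 1)))
  n <- 4000
  set.seed(42)
  means <- replicate(n, {
    r <- resample_nested(d)
    mean(r$value[r$group == "control_A"])
  })
  p_hat <- c(mean(means == a), mean(means == (a + b) / 2), mean(means == b))
  se <- sqrt(c(.25 * .75, .5 * .5, .25 * .75) / n)
  expect_true(all(abs(p_hat - c(0.25, 0.5, 0.25)) < 3 * se))
})

test_that("percentile_interval matches an independent quantile computation", {
  expect_equal(percentile_interval(rep(3.3, 10)), c(low = 3.3, high = 3.3))
  x <- as.numeric(1:1000)
  ci <- percentile_interval(x, 0.95)
  expect_equal(ci[["low"]], manual_quantile_type7(x, 0.025))
  expect_equal(ci[["high"]], manual_quantile_type7(x, 0.975))
  # degenerate level: both endpoints collapse to the median
  ci0 <- percentile_interval(x, 0)
  expect_equal(unname(ci0), rep(manual_quantile_type7(x, 0.5), 2))
  expect_error(percentile_interval(numeric(0)), "empty")
})

test_that("p_null counts the null side of 1, ties included", {
  s <- c(0.5, 0.9, 1.0, 1.2)
  expect_equal(p_null(s, "greater"), 0.75)
  expect_equal(p_null(s, "less"), 0.5)
  expect_equal(p_null(c(1.1, 2, 3), "greater"), 0)
  # exact complement identity with the strictly-greater fraction
  set.seed(3)
  x <- exp(rnorm(500, 0, 0.4)); x[sample(500, 20)] <- 1
  expect_identical(p_null(x, "greater") + mean(x > 1), 1)
})

test_that("run_bootstrap is reproducible and seed-sensitive", {
  d <- simulate_ephys_dataset(seed = 5)
  b1 <- run_bootstrap(d, n_iter = 500, seed = 9)
  b2 <- run_bootstrap(d, n_iter = 500, seed = 9)
  b3 <- run_bootstrap(d, n_iter = 500, seed = 10)
  expect_identical(b1$t_star, b2$t_star)
  expect_false(identical(b1$t_star, b3$t_star))
  expect_length(b1$t_star, 500)
  expect_lte(b1$ci[["low"]], b1$ci[["high"]])
  expect_gte(b1$p_h0, 0); expect_lte(b1$p_h0, 1)
})

test_that("bootstrap statistic is scale-equivariant group-wise", {
  d <- simulate_ephys_dataset(n_batches = 2, n_cells = 3, n_sweeps = 2, seed = 21)
  scale_group <- function(d, g, c) { d$value[d$group == g] <- d$value[d$group == g] * c; d }
  # scaling a whole line (ko and control together) leaves T and T* unchanged
  d_line <- scale_group(scale_group(d, "ko_A", 3.7), "control_A", 3.7)
  b0 <- run_bootstrap(d, n_iter = 300, seed = 1)
  b1 <- run_bootstrap(d_line, n_iter = 300, seed = 1)
  expect_equal(b1$t_obs, b0$t_obs)
  expect_equal(b1$t_star, b0$t_star)
  # scaling only ko_A multiplies T and every T* by the same factor
  d_ko <- scale_group(d, "ko_A", 2.5)
  b2 <- run_bootstrap(d_ko, n_iter = 300, seed = 1)
  expect_equal(b2$t_obs, 2.5 * b0$t_obs)
  expect_equal(b2$t_star, 2.5 * b0$t_star, tolerance = 1e-12)
})

test_that("single-sweep datasets skip the sweep resampling level", {
  vals <- list(control_A = c(10, 12), ko_A = c(2, 3),
               control_B = c(9, 11), ko_B = c(1, 2))
  d <- tiny_two_batch_dataset(vals)
  ds <- nested_dataset(as.data.frame(d), single_sweep = TRUE)
  # with one sweep per cell the two flags give identical resampling paths up
  # to RNG consumption; both must only ever produce enumerable atom values
  b <- run_bootstrap(ds, n_iter = 400, seed = 2)
  atoms <- sort(unique(enumerate_tiny_T(vals)))
  expect_true(all(vapply(b$t_star, function(t) any(abs(atoms - t) < 1e-12), logical(1))))
})

test_that("bootstrap null probability matches enumeration on a tiny design", {
  vals <- list(control_A = c(10, 12), ko_A = c(2, 3),
               control_B = c(9, 11), ko_B = c(1, 2))
  d <- tiny_two_batch_dataset(vals)
  t_enum <- enumerate_tiny_T(vals)
  p_true <- mean(t_enum <= 1)
  b <- run_bootstrap(d, n_iter = 20000, direction = "greater", seed = 31)
  se <- sqrt(p_true * (1 - p_true) / 20000)
  expect_lt(abs(b$p_h0 - p_true), 3 * se + 1e-12)
})

test_that("a dataset with a clear effect yields a small null probability", {
  d <- simulate_ephys_dataset(seed = 77)  # T_true = 2 under default effects
  b <- run_bootstrap(d, n_iter = 10000, direction = "greater", seed = 77)
  expect_lt(b$p_h0, 0.05)
})

test_that("bootstrap results serialize to JSON with the full replicate table", {
  d <- simulate_ephys_dataset(n_batches = 2, n_cells = 2, n_sweeps = 2, seed = 3)
  b <- run_bootstrap(d, n_iter = 100, seed = 4)
  tmp <- tempfile(fileext = ".json"); tstar <- tempfile(fileext = ".tsv")
  write_bootstrap_result(b, tmp, tstar)
  j <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(j$t_obs, b$t_obs)
  expect_equal(j$p_h0, b$p_h0)
  expect_equal(nrow(utils::read.delim(tstar)), 100)
})
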