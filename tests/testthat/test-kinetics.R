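test_that("normalization divides by the last pre-inducer value", {
  rec <- data.frame(id = 1, time = c(-1, 1, 2), value = c(10, 8, 5))
  nn <- normalize_to_reference(rec, 0, value_col = "value")
  expect_equal(nn$normalized, c(1.0, 0.8, 0.5))
  expect_equal(nn$reference_time, rep(-1, 3))
  # scale invariance
  rec2 <- rec; rec2$value <- rec2$value * 7.3
  expect_equal(normalize_to_reference(rec2, 0, value_col = "value")$normalized,
               nn$normalized)
  # idempotence: normalizing a normalized trace is the identity
  rec3 <- data.frame(id = 1, time = nn$time, value = nn$normalized)
  expect_equal(normalize_to_reference(rec3, 0, value_col = "value")$normalized,
               nn$normalized)
  # no pre-inducer point is an error
  expect_error(normalize_to_reference(
    data.frame(id = 1, time = 1:3, value = 1:3), 0, value_col = "value"),
    "precede")
  # non-positive reference drops the trace with a warning
  rec4 <- rbind(rec, data.frame(id = 2, time = c(-1, 1, 2),
                                value = c(0, 1, 1)))
  expect_warning(nn4 <- normalize_to_reference(rec4, 0, value_col = "value"),
                 "dropped")
  expect_equal(unique(nn4$id), 1)
  expect_equal(attr(nn4, "dropped"), 2)
})

test_that("population average does two-level (synapse then neuron) pooling", {
  tr <- data.frame(id = rep(1:2, each = 3), neuron = rep(1:2, each = 3),
                   time = rep(0:2, 2),
                   normalized = c(1, 0.5, 0.25, 1, 0.5, 0.25))
  pa <- population_average(tr)
  expect_equal(pa$mean, c(1, 0.5, 0.25))
  expect_equal(pa$sd, c(0, 0, 0))
  tr2 <- data.frame(id = 1:2, neuron = 1:2, time = 0,
                    normalized = c(0.4, 0.6))
  expect_equal(population_average(tr2)$mean, 0.5)
  # 20 simulated neurons vs brute-force two-level averaging
  set.seed(8)
  rows <- list()
  for (nr in 1:20) for (sy in 1:5) {
    rows[[length(rows) + 1]] <- data.frame(
      id = paste(nr, sy), neuron = nr, time = 0:3,
      normalized = runif(4))
  }
  tr3 <- do.call(rbind, rows)
  pa3 <- population_average(tr3)
  for (ti in 0:3) {
    per_neuron <- vapply(1:20, function(nr)
      mean(tr3$normalized[tr3$neuron == nr & tr3$time == ti]), 0)
    expect_equal(pa3$mean[pa3$time == ti], mean(per_neuron))
    expect_equal(pa3$sd[pa3$time == ti], sd(per_neuron))
  }
  # mismatched grids are rejected
  bad <- rbind(tr2, data.frame(id = 3, neuron = 3, time = 1,
                               normalized = 0.5))
  expect_error(population_average(bad), "common time grid")
})

test_that("grid fitter recovers a single exponential in the f -> 1 limit", {
  tt <- c(-1, 0:24)
  step <- 10^(1 / 40)
  # tau off the grid: headline constant still within one grid step
  y <- ifelse(tt < 0, 1, exp(-pmax(tt, 0) / 3))
  fit <- fit_biexponential(tt, y, t_inducer = 0)
  expect_lt(abs(log(fit$tau_major / 3)), log(step) * 1.0001)
  expect_false(fit$flags$non_decaying)
  # tau on a grid node: exact zero-residual solution, single pool reported
  tau_g <- biexp_grid()$taus[which.min(abs(biexp_grid()$taus - 3))]
  yg <- ifelse(tt < 0, 1, exp(-pmax(tt, 0) / tau_g))
  fitg <- fit_biexponential(tt, yg, t_inducer = 0)
  expect_equal(fitg$tau_major, tau_g)
  expect_gte(fitg$f_major, 0.98)
  expect_lt(fitg$ssr, 1e-20)
})

test_that("grid fitter matches truth and a continuous oracle on biexponentials", {
  skip_if_not_installed("minpack.lm")
  tt <- c(-2, -1, 0:24)
  ks <- kinetics_spec(1, 0.9, 2, 30, 0)
  y <- kinetics_value(ks, tt)
  fit <- fit_biexponential(tt, y, t_inducer = 0)
  step <- 10^(1 / 40)
  expect_lt(abs(log(fit$tau_major / 2)), log(step) * 1.0001)
  expect_lt(abs(log(fit$tau_minor / 30)), log(step) * 1.0001)
  expect_lt(abs(fit$f_major - 0.9), 0.01 * 1.0001)
  # independent continuous least-squares oracle (Levenberg-Marquardt)
  post <- tt >= 0
  df <- data.frame(dt = tt[post], y = y[post])
  nls_fit <- minpack.lm::nlsLM(
    y ~ f * exp(-dt / t1) + (1 - f) * exp(-dt / t2), data = df,
    start = list(f = 0.8, t1 = 3, t2 = 20),
    lower = c(0, 0.1, 0.1), upper = c(1, 1000, 1000))
  ssr_oracle <- sum(residuals(nls_fit)^2)
  # discretization bound: SSR at the grid node nearest to the truth
  taus <- fit$grid$taus
  snap <- function(x) taus[which.min(abs(log(taus) - log(x)))]
  dt <- tt[post]
  ynear <- 0.9 * exp(-dt / snap(2)) + 0.1 * exp(-dt / snap(30))
  bound <- sum((ynear - y[post])^2)
  expect_lte(fit$ssr, ssr_oracle + bound + 1e-12)
})

test_that("constant traces are flagged non-decaying at the grid edge", {
  tt <- c(-1, 0:10)
  fit <- fit_biexponential(tt, rep(1, length(tt)), t_inducer = 0)
  expect_true(fit$flags$non_decaying)
  expect_equal(fit$tau_major, max(fit$grid$taus))
  expect_true(fit$flags$boundary_hit)
})

test_that("grid search is exhaustive and reports the true SSR", {
  set.seed(9)
  tt <- 0:16
  y <- 0.85 * exp(-tt / 2.5) + 0.15 * exp(-tt / 60) + rnorm(17, 0, 0.02)
  g <- biexp_grid()
  fit <- fit_biexponential(tt, y, t_inducer = -1, grid = g)
  naive_ssr <- function(t1, t2, f)
    sum((f * exp(-(tt + 1) / t1) + (1 - f) * exp(-(tt + 1) / t2) - y)^2)
  # reported SSR equals the naive computation at the reported parameters
  expect_equal(fit$ssr, naive_ssr(fit$tau1, fit$tau2, fit$f_fast),
               tolerance = 1e-8)
  # no randomly sampled grid point beats the reported minimum
  for (k in 1:500) {
    i <- sample(length(g$taus), 1); j <- sample(i:length(g$taus), 1)
    f <- sample(g$fs, 1)
    expect_gte(naive_ssr(g$taus[i], g$taus[j], f), fit$ssr - 1e-10)
  }
})

test_that("doubling the grid density never increases the minimal SSR", {
  set.seed(10)
  tt <- c(-1, 0:20)
  y <- kinetics_value(kinetics_spec(1, 0.8, 3.3, 45, 0), tt) +
    c(0, rnorm(21, 0, 0.01))
  coarse <- fit_biexponential(tt, y, 0, grid = biexp_grid())
  dense <- fit_biexponential(
    tt, y, 0, grid = biexp_grid(steps_per_decade = 80, f_step = 0.005))
  expect_lte(dense$ssr, coarse$ssr + 1e-12)
})

test_that("reported fits always use the major-pool convention", {
  set.seed(11)
  tt <- c(-1, 0:20)
  for (k in 1:5) {
    f_true <- runif(1, 0.55, 0.95)
    y <- kinetics_value(kinetics_spec(1, f_true, runif(1, 1, 5),
                                      runif(1, 20, 80), 0), tt)
    fit <- fit_biexponential(tt, y, 0)
    expect_gte(fit$f_major, 0.5)
    expect_equal(fit$f_major >= 0.5, TRUE)
    # model value is invariant under the (tau1,f) <-> (tau2,1-f) relabeling
    pred <- predict(fit, tt, t_inducer = 0)
    swap <- fit$amplitude * ((1 - fit$f_fast) * exp(-pmax(tt, 0) / fit$tau2) +
                               fit$f_fast * exp(-pmax(tt, 0) / fit$tau1))
    expect_equal(pred, swap)
  }
})

test_that("initial rate is the OLS slope of the first five post-inducer points", {
  tt <- 0:4
  ir <- fit_initial_rate(tt, c(1.0, 0.9, 0.8, 0.7, 0.6), t_inducer = 0)
  expect_equal(ir$slope, -0.1, tolerance = 1e-12)
  expect_equal(ir$n_points, 5L)
  # exponential sampled at the first 5 h: slope equals the closed-form
  # OLS slope of those samples
  tt2 <- c(-1, 0:7)
  y2 <- 100 * exp(-pmax(tt2, 0) / 3.7)
  ir2 <- fit_initial_rate(tt2, y2, t_inducer = 0)
  x <- 0:4; yy <- 100 * exp(-x / 3.7)
  slope_cf <- sum((x - mean(x)) * (yy - mean(yy))) / sum((x - mean(x))^2)
  expect_equal(ir2$slope, slope_cf, tolerance = 1e-12)
  expect_error(fit_initial_rate(0:3, rep(1, 4), 0), "at least 5")
})

test_that("per-synapse correlation is Pearson pooled and per neuron", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(per_synapse_correlation(x, x)$r, 1)
  expect_equal(per_synapse_correlation(x, -x)$r, -1)
  expect_error(per_synapse_correlation(x, rep(1, 5)), "variance")
  set.seed(12)
  n <- 500
  a <- rnorm(n)
  b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(n)
  grp <- rep(1:10, each = 50)
  res <- per_synapse_correlation(a, b, grouping = grp)
  ci <- tanh(atanh(0.6) + c(-1, 1) * 1.96 / sqrt(n - 3))
  expect_gt(res$r, ci[1]); expect_lt(res$r, ci[2])
  expect_lt(res$p, 1e-10)
  # per-neuron summary equals direct computation
  rs <- vapply(1:10, function(g) cor(a[grp == g], b[grp == g]), 0)
  expect_equal(res$per_neuron$r, rs)
  expect_equal(res$r_mean, mean(rs))
  expect_equal(res$r_sd, sd(rs))
})

test_that("loss-delta analysis computes per-synapse losses and their ratio", {
  ta <- data.frame(id = rep(1:2, each = 2), time = rep(c(-1, 6), 2),
                   value = c(100, 0, 80, 40))
  tb <- data.frame(id = rep(1:2, each = 2), time = rep(c(-1, 6), 2),
                   value = c(50, 25, 30, 30))
  # needs >= 3 pairs for the correlation; add a third synapse
  ta <- rbind(ta, data.frame(id = 3, time = c(-1, 6), value = c(60, 20)))
  tb <- rbind(tb, data.frame(id = 3, time = c(-1, 6), value = c(40, 28)))
  res <- loss_delta_analysis(ta, tb, t_inducer = 0, t_end = 6)
  expect_equal(res$deltas$delta_a, c(100, 40, 40))
  expect_equal(res$deltas$delta_b, c(25, 0, 12))
  expect_equal(res$deltas$ratio, c(0.25, 0, 0.3))
  # synthetic co-loss with correlated losses round-trips within the CI
  set.seed(13)
  n <- 300
  la <- runif(n, 20, 100)
  lb <- 0.4 * scale(la)[, 1] + sqrt(1 - 0.16) * rnorm(n)
  lb <- 10 + 3 * lb
  mk <- function(losses, base) do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(id = i, time = c(-1, 6),
               value = c(base[i], base[i] - losses[i]))))
  res2 <- loss_delta_analysis(mk(la, la + 5), mk(lb, lb + 50),
                              t_inducer = 0, t_end = 6)
  r <- res2$correlation$r
  ci <- tanh(atanh(0.4) + c(-1, 1) * 1.96 / sqrt(n - 3))
  expect_gt(r, ci[1]); expect_lt(r, ci[2])
  # missing end point errors
  expect_error(loss_delta_analysis(ta[-2, ], tb, 0, 6), "missing")
})

test_that("group comparison matches hand-computed statistics", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  # Welch t: means 2 and 5, each variance 1, n = 3
  t_hand <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  res <- group_compare(a, b, "welch_t")
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(t_hand, df = 4), tolerance = 1e-12)
  same <- group_compare(c(1, 2, 3), c(1, 2, 3), "welch_t")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # rank sum on fully separated groups of 5: exact enumeration gives the
  # minimal two-sided p = 2 / choose(10, 5)
  w <- group_compare(1:5, 11:15, "wilcoxon")
  expect_equal(w$p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_error(group_compare(numeric(0), b), "empty")
})
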