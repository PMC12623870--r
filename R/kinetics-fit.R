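#' Normalize traces to the last pre-inducer time point
#'
#' Divides every value of a trace by that trace's value at the last time
#' point preceding inducer addition, so the reference point equals 1
#' exactly. Traces whose reference value is zero or negative are dropped
#' with a warning.
#'
#' @param records Long data.frame with columns `id`, `time` and a value
#'   column (`value_col`), e.g. the `corrected` column of
#'   [quantify_culture()] records.
#' @param t_inducer Inducer addition time, hours.
#' @param value_col Name of the value column (default `"corrected"`, falls
#'   back to `"value"`).
#' @return data.frame `id`, `time`, `normalized`, plus `reference_time`;
#'   attribute `dropped` lists ids removed for non-positive reference.
#' @export
normalize_to_reference <- function(records, t_inducer,
                                   value_col = NULL) {
  if (is.null(value_col))
    value_col <- if ("corrected" %in% names(records)) "corrected" else "value"
  stopifnot(all(c("id", "time", value_col) %in% names(records)))
  pre <- records$time < t_inducer
  if (!any(pre)) stop("no time point precedes the inducer time")
  out <- list(); dropped <- c()
  for (id in unique(records$id)) {
    tr <- records[records$id == id, ]
    tr <- tr[order(tr$time), ]
    pre_t <- tr$time[tr$time < t_inducer]
    if (length(pre_t) == 0) { dropped <- c(dropped, id); next }
    ref_t <- max(pre_t)
    ref_v <- tr[[value_col]][tr$time == ref_t][1]
    if (!is.finite(ref_v) || ref_v <= 0) { dropped <- c(dropped, id); next }
    out[[length(out) + 1]] <- data.frame(
      id = id, time = tr$time, normalized = tr[[value_col]] / ref_v,
      reference_time = ref_t)
  }
  if (length(dropped) > 0)
    warning(length(dropped), " trace(s) dropped: non-positive reference value")
  res <- do.call(rbind, out)
  attr(res, "dropped") <- dropped
  res
}

#' Two-level population average of normalized traces
#'
#' Averages synapse traces within each neuron first, then reports the mean
#' and standard deviation across neurons at every time point (each thin
#' line one neuron, the thick line their average).
#'
#' @param traces data.frame with `id`, `neuron`, `time`, `normalized` (or
#'   `value`), all traces on a common time grid.
#' @return data.frame `time`, `mean`, `sd`, `n_neurons`.
#' @export
population_average <- function(traces) {
  vc <- if ("normalized" %in% names(traces)) "normalized" else "value"
  stopifnot(all(c("neuron", "time", vc) %in% names(traces)))
  grids <- tapply(traces$time, traces$neuron,
                  function(t) paste(sort(unique(t)), collapse = ","))
  if (length(unique(grids)) != 1)
    stop("traces are not on a common time grid")
  per_neuron <- stats::aggregate(traces[[vc]],
                                 by = list(neuron = traces$neuron,
                                           time = traces$time), FUN = mean)
  agg_m <- stats::aggregate(per_neuron$x, by = list(time = per_neuron$time),
                            FUN = mean)
  agg_s <- stats::aggregate(per_neuron$x, by = list(time = per_neuron$time),
                            FUN = stats::sd)
  n <- length(unique(per_neuron$neuron))
  data.frame(time = agg_m$time, mean = agg_m$x, sd = agg_s$x,
             n_neurons = n)
}

#' Grid specification for the biexponential fitter
#'
#' @param tau_min,tau_max Time-constant range, hours.
#' @param steps_per_decade Logarithmic grid density for both components.
#' @param f_step Step of the major-fraction grid over \[0, 1\].
#' @return A list with the tau grid (`taus`) and fraction grid (`fs`).
#' @export
biexp_grid <- function(tau_min = 0.1, tau_max = 1000,
                       steps_per_decade = 40, f_step = 0.01) {
  taus <- 10^seq(log10(tau_min), log10(tau_max), by = 1 / steps_per_decade)
  fs <- seq(0, 1, by = f_step)
  list(taus = taus, fs = fs, steps_per_decade = steps_per_decade,
       tau_min = tau_min, tau_max = tau_max, f_step = f_step)
}

#' Fit a two-pool exponential decay by exhaustive grid search
#'
#' Fits the post-inducer portion of a normalized trace to
#' \deqn{F(\Delta t) = A [ f e^{-\Delta t/\tau_1} + (1-f) e^{-\Delta t/\tau_2} ]}
#' with \eqn{\Delta t} the time since inducer addition, by exhaustive search
#' over a logarithmic grid of the two time constants (ordered
#' \eqn{\tau_1 \le \tau_2}) and a linear grid of the fraction f, returning
#' the global grid minimizer of the sum of squared residuals. The amplitude
#' A is fixed (default 1, the normalized reference value), so the search has
#' exactly three free parameters.
#'
#' The two components are reported under the major/minor convention: the
#' major pool is the component carrying a fraction >= 0.5 (ties go to the
#' faster component), and the headline time constant is `tau_major`.
#'
#' The SSR surface over f at fixed (tau1, tau2) is a quadratic whose
#' coefficients come from the Gram matrix of the exponential basis; values
#' are algebraically identical to the naive triple loop.
#'
#' @param times Clock times, hours.
#' @param values Normalized trace values.
#' @param t_inducer Inducer addition time, hours; points at `time >=
#'   t_inducer` enter the fit.
#' @param grid A [biexp_grid()].
#' @param amplitude Fixed amplitude A (default 1).
#' @return An object of class `biexp_fit`: `f_major`, `tau_major`,
#'   `tau_minor`, `amplitude`, `ssr`, `n_points`, `flags`
#'   (`boundary_hit`, `non_decaying`) and the grid description.
#' @export
fit_biexponential <- function(times, values, t_inducer = 0,
                              grid = biexp_grid(), amplitude = 1) {
  stopifnot(length(times) == length(values))
  post <- times >= t_inducer & is.finite(values) & is.finite(times)
  dt <- times[post] - t_inducer
  y <- values[post]
  if (length(y) < 4) stop("need at least 4 post-inducer points")
  taus <- grid$taus; fs <- grid$fs
  n_tau <- length(taus)
  E <- exp(-outer(1 / taus, dt))            # n_tau x n_points
  G <- tcrossprod(E)                        # Gram matrix
  h <- as.vector(E %*% y)
  yy <- sum(y^2)
  A <- amplitude
  Gd <- diag(G)
  Gii <- matrix(Gd, n_tau, n_tau)           # varies along rows (tau1)
  Gjj <- t(Gii)
  Hi <- matrix(h, n_tau, n_tau)
  Hj <- t(Hi)
  upper <- upper.tri(matrix(0, n_tau, n_tau), diag = TRUE)  # tau1 <= tau2
  # numerically perfect fits: snap cancellation noise to an exact zero so
  # tie-breaking across f is deterministic (first f scanned wins)
  eps0 <- 1e-12 * max(yy, 1)
  best <- list(ssr = Inf)
  for (f in fs) {
    S <- A^2 * (f^2 * Gii + (1 - f)^2 * Gjj + 2 * f * (1 - f) * G) -
      2 * A * (f * Hi + (1 - f) * Hj) + yy
    S[S < eps0] <- 0
    S[!upper] <- Inf
    k <- which.min(S)
    if (S[k] < best$ssr) {
      ij <- arrayInd(k, dim(S))
      best <- list(ssr = S[k], i = ij[1], j = ij[2], f = f)
    }
  }
  tau1 <- taus[best$i]; tau2 <- taus[best$j]; f <- best$f
  # major/minor convention (ties -> faster component)
  if (f >= 0.5) {
    f_major <- f; tau_major <- tau1; tau_minor <- tau2
  } else {
    f_major <- 1 - f; tau_major <- tau2; tau_minor <- tau1
  }
  fitted_post <- A * (f * exp(-dt / tau1) + (1 - f) * exp(-dt / tau2))
  decline <- if (length(dt) > 1)
    1 - fitted_post[which.max(dt)] / fitted_post[which.min(dt)] else 0
  edge <- function(tau) tau <= min(taus) * (1 + 1e-12) ||
    tau >= max(taus) * (1 - 1e-12)
  boundary_hit <- (f_major > 0 && edge(tau_major)) ||
    (f_major < 1 && edge(tau_minor))
  structure(
    list(f_major = f_major, tau_major = tau_major, tau_minor = tau_minor,
         amplitude = A, ssr = max(best$ssr, 0), n_points = length(y),
         flags = list(boundary_hit = boundary_hit,
                      non_decaying = decline < 0.01),
         grid = grid, tau1 = tau1, tau2 = tau2, f_fast = f),
    class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(
    "biexp_fit: tau_major = %.3g h (%.0f%% pool), tau_minor = %.3g h, SSR = %.4g\n",
    x$tau_major, 100 * x$f_major, x$tau_minor, x$ssr))
  if (x$flags$boundary_hit) cat("  [boundary hit]\n")
  if (x$flags$non_decaying) cat("  [non-decaying]\n")
  invisible(x)
}

#' Predicted values of a biexponential fit
#'
#' @param object A `biexp_fit`.
#' @param times Clock times, hours.
#' @param t_inducer Inducer time used in the fit.
#' @param ... Unused.
#' @return Fitted values (pre-inducer times return the amplitude).
#' @export
predict.biexp_fit <- function(object, times, t_inducer = 0, ...) {
  dt <- pmax(times - t_inducer, 0)
  object$amplitude * (object$f_fast * exp(-dt / object$tau1) +
                        (1 - object$f_fast) * exp(-dt / object$tau2))
}

#' Initial degradation rate from the first five post-inducer points
#'
#' Ordinary least-squares linear fit to the first 5 time points following
#' inducer addition, on absolute (non-normalized) fluorescence, giving the
#' initial loss rate in a.u. per hour.
#'
#' @param times Clock times, hours.
#' @param values Absolute fluorescence values, a.u.
#' @param t_inducer Inducer addition time, hours.
#' @return List with `slope` (a.u./h), `intercept`, `n_points` (5) and
#'   `ssr`.
#' @export
fit_initial_rate <- function(times, values, t_inducer = 0) {
  o <- order(times)
  times <- times[o]; values <- values[o]
  post <- which(times >= t_inducer)
  if (length(post) < 5) stop("need at least 5 post-inducer points")
  idx <- post[1:5]
  fit <- stats::lm(values[idx] ~ times[idx])
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n_points = 5L, ssr = sum(stats::residuals(fit)^2))
}

#' Pooled and per-neuron Pearson correlation of paired synapse values
#'
#' @param values_a,values_b Paired numeric vectors (one entry per synapse).
#' @param grouping Optional neuron id per synapse; when given, r is also
#'   computed within each neuron (with >= 3 synapses) and summarized as
#'   mean +/- sd.
#' @return List with `r`, `p` (two-sided, pooled), `n`, and when grouped
#'   `per_neuron` (data.frame neuron, r, n), `r_mean`, `r_sd`.
#' @export
per_synapse_correlation <- function(values_a, values_b, grouping = NULL) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 3)
  if (stats::sd(values_a) == 0 || stats::sd(values_b) == 0)
    stop("zero variance in one of the vectors")
  ct <- stats::cor.test(values_a, values_b, method = "pearson")
  out <- list(r = unname(ct$estimate), p = ct$p.value,
              n = length(values_a))
  if (!is.null(grouping)) {
    per <- lapply(split(seq_along(grouping), grouping), function(ix) {
      if (length(ix) < 3) return(NULL)
      if (stats::sd(values_a[ix]) == 0 || stats::sd(values_b[ix]) == 0)
        return(NULL)
      data.frame(neuron = grouping[ix[1]],
                 r = stats::cor(values_a[ix], values_b[ix]),
                 n = length(ix))
    })
    per <- do.call(rbind, per)
    out$per_neuron <- per
    out$r_mean <- mean(per$r)
    out$r_sd <- stats::sd(per$r)
  }
  out
}

#' Per-synapse co-loss analysis of two channels
#'
#' For synapses tracked in both channels, computes the absolute fluorescence
#' loss between the reference (last pre-inducer) time point and `t_end` in
#' each channel, their ratio, and the across-synapse correlation of the
#' losses. Uses non-normalized values, which scale linearly with fusion
#' protein quantity.
#'
#' @param traces_a,traces_b data.frames `id`, `time`, value column (default
#'   `corrected`, falling back to `value`) for the two channels.
#' @param t_inducer Inducer time, hours.
#' @param t_end End time point, hours (must exist in both).
#' @param grouping Optional neuron id per synapse id (named vector).
#' @return List with `deltas` (id, delta_a, delta_b, ratio) and
#'   `correlation` (see [per_synapse_correlation()]).
#' @export
loss_delta_analysis <- function(traces_a, traces_b, t_inducer, t_end,
                                grouping = NULL) {
  vc <- function(df) if ("corrected" %in% names(df)) "corrected" else "value"
  pick <- function(df, id, t) {
    v <- df[df$id == id & df$time == t, vc(df)]
    if (length(v) == 0) NA_real_ else v[1]
  }
  ids <- intersect(unique(traces_a$id), unique(traces_b$id))
  pre_t <- max(traces_a$time[traces_a$time < t_inducer])
  rows <- lapply(ids, function(id) {
    a0 <- pick(traces_a, id, pre_t); a1 <- pick(traces_a, id, t_end)
    b0 <- pick(traces_b, id, pre_t); b1 <- pick(traces_b, id, t_end)
    if (anyNA(c(a0, a1, b0, b1)))
      stop("missing reference or t_end measurement for synapse ", id)
    da <- a0 - a1; db <- b0 - b1
    data.frame(id = id, delta_a = da, delta_b = db,
               ratio = if (da != 0) db / da else NA_real_)
  })
  deltas <- do.call(rbind, rows)
  grp <- if (!is.null(grouping)) unname(grouping[as.character(deltas$id)])
         else NULL
  list(deltas = deltas,
       correlation = per_synapse_correlation(deltas$delta_a,
                                             deltas$delta_b, grp))
}

#' Two-group comparison: Welch t-test or Wilcoxon rank sum
#'
#' @param group_a,group_b Numeric vectors (e.g. last-time-point values).
#' @param test `"welch_t"` (two-tailed, unequal variances) or
#'   `"wilcoxon"` (two-sided rank sum; exact for small samples without
#'   ties, normal approximation otherwise).
#' @return List with `statistic`, `p`, `test`.
#' @export
group_compare <- function(group_a, group_b,
                          test = c("welch_t", "wilcoxon")) {
  test <- match.arg(test)
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("empty group")
  if (test == "welch_t") {
    if (length(group_a) < 2 || length(group_b) < 2)
      stop("welch_t needs at least 2 values per group")
    ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  } else {
    ht <- stats::wilcox.test(group_a, group_b, alternative = "two.sided")
  }
  list(statistic = unname(ht$statistic), p = ht$p.value, test = test)
}
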