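#' Two-pool degradation kinetics specification
#'
#' Describes the noiseless fluorescence time course of one degron-tagged
#' protein pool: constant at `amplitude` before the inducer is added, then a
#' sum of two exponentials
#' \deqn{F(t) = A [ f e^{-(t - t_0)/\tau_1} + (1 - f) e^{-(t - t_0)/\tau_2} ]}
#' where \eqn{t_0} is the inducer-addition time, \eqn{f} the fraction of the
#' major (fast-degrading) pool and \eqn{\tau_1, \tau_2} the two time
#' constants in hours. If a washout time is given, the signal recovers
#' towards the pre-treatment amplitude as a saturating exponential with time
#' constant `recovery_tau`.
#'
#' @param amplitude Pre-inducer fluorescence in arbitrary units (> 0).
#' @param f_major Fraction of the major pool, in \[0, 1\].
#' @param tau_major,tau_minor Time constants of the two pools, hours (> 0).
#' @param t_inducer Clock time of inducer addition, hours.
#' @param t_washout Optional clock time of inducer washout, hours
#'   (> `t_inducer`), or `NA` for no washout.
#' @param recovery_tau Recovery time constant after washout, hours;
#'   required when `t_washout` is given.
#' @return An object of class `kinetics_spec`.
#' @export
kinetics_spec <- function(amplitude = 1, f_major = 1, tau_major = 3.7,
                          tau_minor = 37, t_inducer = 0,
                          t_washout = NA_real_, recovery_tau = NA_real_) {
  stopifnot(is.finite(amplitude), amplitude > 0)
  if (!is.finite(f_major) || f_major < 0 || f_major > 1)
    stop("f_major must lie in [0, 1]")
  if (!is.finite(tau_major) || tau_major <= 0 ||
      !is.finite(tau_minor) || tau_minor <= 0)
    stop("time constants must be strictly positive")
  if (!is.na(t_washout)) {
    if (t_washout <= t_inducer) stop("t_washout must exceed t_inducer")
    if (is.na(recovery_tau) || recovery_tau <= 0)
      stop("recovery_tau must be a positive number when t_washout is set")
  }
  structure(
    list(amplitude = amplitude, f_major = f_major,
         tau_major = tau_major, tau_minor = tau_minor,
         t_inducer = t_inducer, t_washout = t_washout,
         recovery_tau = recovery_tau),
    class = "kinetics_spec")
}

#' Evaluate the noiseless kinetic curve
#'
#' @param spec A [kinetics_spec()].
#' @param times Clock times in hours (any order, may precede the inducer).
#' @return Numeric vector of fluorescence values, same length as `times`.
#' @export
kinetics_value <- function(spec, times) {
  stopifnot(inherits(spec, "kinetics_spec"), is.numeric(times))
  v <- rep(spec$amplitude, length(times))
  post <- times >= spec$t_inducer
  dt <- times[post] - spec$t_inducer
  decay <- spec$f_major * exp(-dt / spec$tau_major) +
    (1 - spec$f_major) * exp(-dt / spec$tau_minor)
  v[post] <- spec$amplitude * decay
  if (!is.na(spec$t_washout)) {
    rec <- times >= spec$t_washout
    if (any(rec)) {
      # value at washout, then saturating relaxation back to amplitude
      v0 <- kinetics_value(
        kinetics_spec(spec$amplitude, spec$f_major, spec$tau_major,
                      spec$tau_minor, spec$t_inducer),
        spec$t_washout)
      dtw <- times[rec] - spec$t_washout
      v[rec] <- spec$amplitude - (spec$amplitude - v0) *
        exp(-dtw / spec$recovery_tau)
    }
  }
  v
}

#' Simulate noisy degradation traces with ground truth
#'
#' Generates one or more measurement traces from a kinetics specification by
#' adding i.i.d. Gaussian measurement noise to the closed-form curve.
#'
#' @param spec A [kinetics_spec()] (or list of them, one per trace).
#' @param times Strictly increasing clock times in hours; at least one must
#'   precede `t_inducer`.
#' @param noise_sd Gaussian noise standard deviation, a.u. (>= 0).
#' @param n_traces Number of traces when `spec` is a single spec.
#' @param seed Integer seed; equal seeds give bit-identical output.
#' @return A list with `traces` (long data.frame: trace_id, time, value,
#'   true_value) and `ground_truth` (data.frame of the true parameters per
#'   trace, plus the seed).
#' @export
simulate_decay_traces <- function(spec, times, noise_sd = 0, n_traces = 1,
                                  seed = 1L) {
  if (length(times) == 0) stop("times must be non-empty")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  specs <- if (inherits(spec, "kinetics_spec")) {
    rep(list(spec), n_traces)
  } else {
    stopifnot(all(vapply(spec, inherits, logical(1), "kinetics_spec")))
    spec
  }
  if (!any(times < specs[[1]]$t_inducer))
    stop("at least one time point must precede t_inducer")
  set.seed(as.integer(seed))
  rows <- lapply(seq_along(specs), function(i) {
    tv <- kinetics_value(specs[[i]], times)
    data.frame(trace_id = i, time = times,
               value = tv + stats::rnorm(length(times), 0, noise_sd),
               true_value = tv)
  })
  gt <- do.call(rbind, lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    data.frame(trace_id = i, amplitude = s$amplitude, f_major = s$f_major,
               tau_major = s$tau_major, tau_minor = s$tau_minor,
               t_inducer = s$t_inducer)
  }))
  gt$seed <- as.integer(seed)
  list(traces = do.call(rbind, rows), ground_truth = gt)
}
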