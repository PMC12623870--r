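#' Random punctum positions with a minimum separation
#'
#' Rejection-samples positions (0-based row, col) inside the image with a
#' margin large enough for a 9x9 ROI footprint.
#'
#' @param n Number of puncta.
#' @param shape Image shape `c(rows, cols)` in pixels.
#' @param min_sep Minimum pairwise distance, pixels.
#' @param margin Border to keep free, pixels (default 6 fits the ROI).
#' @param seed Integer seed.
#' @return Integer matrix `n x 2` of (row, col), 0-based.
#' @export
random_positions <- function(n, shape, min_sep = 10, margin = 6, seed = 1L) {
  set.seed(as.integer(seed))
  pos <- matrix(NA_real_, 0, 2)
  tries <- 0
  while (nrow(pos) < n) {
    cand <- c(stats::runif(1, margin, shape[1] - 1 - margin),
              stats::runif(1, margin, shape[2] - 1 - margin))
    ok <- nrow(pos) == 0 ||
      min(sqrt((pos[, 1] - cand[1])^2 + (pos[, 2] - cand[2])^2)) >= min_sep
    if (ok) pos <- rbind(pos, cand)
    tries <- tries + 1
    if (tries > 10000 * n)
      stop("could not place ", n, " puncta with min_sep ", min_sep)
  }
  pos <- round(pos)
  dimnames(pos) <- NULL
  pos
}

#' Scene specification for a synthetic culture movie
#'
#' Describes punctate synaptic signals on a diffuse background, rendered as
#' isotropic 2-D Gaussians (peak on the brightest z-plane with Gaussian
#' axial falloff), with optional correlated reporter channel, scheduled
#' punctum appearance/disappearance, Poisson-Gaussian noise and slow
#' photobleaching.
#'
#' @param shape Image shape `c(rows, cols)` pixels.
#' @param n_z Number of focal planes.
#' @param z_spacing_um Plane spacing, micrometres.
#' @param channels Character vector of channel labels.
#' @param positions `n x 2` matrix of 0-based (row, col) punctum centres.
#' @param kinetics List of [kinetics_spec()], one per channel: the template
#'   time course of that channel's puncta.
#' @param amp_cv Coefficient of variation of per-punctum amplitude
#'   multipliers (lognormal, mean 1).
#' @param reporter_rho Pearson correlation between the log-amplitude
#'   multipliers of channel 1 and each further channel, in \[-1, 1\].
#' @param psf_sigma Lateral Gaussian sigma of a punctum, pixels.
#' @param psf_sigma_z Axial sigma, in planes.
#' @param background Diffuse background level per channel (recycled), a.u.
#' @param t_appear,t_disappear Per-punctum event times, hours (`-Inf`/`Inf`
#'   for always present).
#' @param poisson_gain Photons per a.u. for Poisson shot noise; `NA` off.
#' @param gaussian_sd Additive Gaussian read-noise sd, a.u.
#' @param bleach_rate Per-frame multiplicative bleaching constant k in
#'   exp(-k * frame); default 0 (off).
#' @param seed Integer seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(128, 128), n_z = 3, z_spacing_um = 0.8,
                       channels = "target", positions,
                       kinetics, amp_cv = 0, reporter_rho = NA_real_,
                       psf_sigma = 1.5, psf_sigma_z = 1,
                       background = 0,
                       t_appear = NULL, t_disappear = NULL,
                       poisson_gain = NA_real_, gaussian_sd = 0,
                       bleach_rate = 0, seed = 1L) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (inherits(kinetics, "kinetics_spec")) kinetics <- list(kinetics)
  stopifnot(length(kinetics) == length(channels))
  if (any(positions[, 1] < 0 | positions[, 1] > shape[1] - 1 |
          positions[, 2] < 0 | positions[, 2] > shape[2] - 1))
    stop("punctum positions outside image bounds")
  if (!is.na(reporter_rho) && abs(reporter_rho) > 1)
    stop("reporter_rho must lie in [-1, 1]")
  if (is.null(t_appear)) t_appear <- rep(-Inf, n)
  if (is.null(t_disappear)) t_disappear <- rep(Inf, n)
  stopifnot(length(t_appear) == n, length(t_disappear) == n)
  structure(
    list(shape = shape, n_z = n_z, z_spacing_um = z_spacing_um,
         channels = channels, positions = positions, kinetics = kinetics,
         amp_cv = amp_cv, reporter_rho = reporter_rho,
         psf_sigma = psf_sigma, psf_sigma_z = psf_sigma_z,
         background = rep(background, length.out = length(channels)),
         t_appear = t_appear, t_disappear = t_disappear,
         poisson_gain = poisson_gain, gaussian_sd = gaussian_sd,
         bleach_rate = bleach_rate, seed = as.integer(seed)),
    class = "scene_spec")
}

# Additive render of one Gaussian punctum (peak = `peak`) into `img`,
# in place semantics via return value. 0-based centre.
render_punctum <- function(img, row0, col0, peak, sigma) {
  half <- ceiling(4 * sigma)
  r <- max(0, row0 - half):min(nrow(img) - 1, row0 + half)
  cc <- max(0, col0 - half):min(ncol(img) - 1, col0 + half)
  g <- outer(exp(-(r - row0)^2 / (2 * sigma^2)),
             exp(-(cc - col0)^2 / (2 * sigma^2)))
  img[r + 1, cc + 1] <- img[r + 1, cc + 1] + peak * g
  img
}

#' Render a synthetic multi-channel culture time-lapse movie
#'
#' Renders the scene at every requested time point into a TZCYX pixel array
#' and returns the ground truth needed to validate detection, tracking,
#' quantification and kinetics downstream. With noise off and background 0,
#' the peak pixel of each punctum on the max projection equals its kinetic
#' value at that frame exactly.
#'
#' @param scene A [scene_spec()].
#' @param times Strictly increasing acquisition times, hours.
#' @return A `timelapse_stack` (see [read_stack()]) with an extra
#'   `ground_truth` element: `tracks` (punctum presence and position per
#'   frame), `params` (true kinetics and amplitude multiplier per punctum
#'   and channel) and the seed.
#' @export
simulate_culture_movie <- function(scene, times) {
  stopifnot(inherits(scene, "scene_spec"))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  set.seed(scene$seed)
  n <- nrow(scene$positions)
  n_c <- length(scene$channels)
  # correlated lognormal amplitude multipliers across channels
  if (scene$amp_cv > 0) {
    sdl <- sqrt(log(1 + scene$amp_cv^2))
    z1 <- stats::rnorm(n)
    zc <- sapply(seq_len(n_c), function(ci) {
      if (ci == 1 || is.na(scene$reporter_rho)) {
        if (ci == 1) z1 else stats::rnorm(n)
      } else {
        scene$reporter_rho * z1 +
          sqrt(1 - scene$reporter_rho^2) * stats::rnorm(n)
      }
    })
    amps <- exp(sdl * zc - sdl^2 / 2)  # mean 1
  } else {
    amps <- matrix(1, n, n_c)
  }
  # brightest plane per punctum
  z_peak <- if (scene$n_z == 1) rep(1L, n) else
    sample(seq_len(scene$n_z), n, replace = TRUE)

  stack <- array(0, dim = c(length(times), scene$n_z, n_c,
                            scene$shape[1], scene$shape[2]))
  present <- matrix(FALSE, length(times), n)
  for (ti in seq_along(times)) {
    t <- times[ti]
    bleach <- exp(-scene$bleach_rate * (ti - 1))
    present[ti, ] <- t >= scene$t_appear & t < scene$t_disappear
    for (ci in seq_len(n_c)) {
      kin_t <- kinetics_value(scene$kinetics[[ci]], t)
      base <- matrix(scene$background[ci], scene$shape[1], scene$shape[2])
      for (zi in seq_len(scene$n_z)) {
        img <- base
        for (p in seq_len(n)) {
          if (!present[ti, p]) next
          axial <- exp(-(zi - z_peak[p])^2 / (2 * scene$psf_sigma_z^2))
          img <- render_punctum(img, scene$positions[p, 1],
                                scene$positions[p, 2],
                                amps[p, ci] * kin_t * axial,
                                scene$psf_sigma)
        }
        img <- img * bleach
        if (!is.na(scene$poisson_gain))
          img <- stats::rpois(length(img), img * scene$poisson_gain) /
            scene$poisson_gain
        if (scene$gaussian_sd > 0)
          img <- img + stats::rnorm(length(img), 0, scene$gaussian_sd)
        stack[ti, zi, ci, , ] <- img
      }
    }
  }
  tracks <- do.call(rbind, lapply(seq_len(n), function(p) {
    data.frame(punctum = p, time = times,
               row = scene$positions[p, 1], col = scene$positions[p, 2],
               present = present[, p])
  }))
  params <- do.call(rbind, lapply(seq_len(n_c), function(ci) {
    k <- scene$kinetics[[ci]]
    data.frame(punctum = seq_len(n), channel = scene$channels[ci],
               amplitude = amps[, ci] * k$amplitude,
               f_major = k$f_major, tau_major = k$tau_major,
               tau_minor = k$tau_minor, t_inducer = k$t_inducer,
               z_peak = z_peak)
  }))
  out <- timelapse_stack(stack, timestamps = times,
                         channels = scene$channels,
                         pixel_size_um = 0.1,
                         t_inducer = scene$kinetics[[1]]$t_inducer)
  out$ground_truth <- list(tracks = tracks, params = params,
                           seed = scene$seed)
  out
}
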