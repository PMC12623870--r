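#' Specification of a longitudinal in-vivo imaging experiment
#'
#' Describes repeated imaging sessions of the same field: cells carry a
#' stable nuclear-reference channel (constant across sessions) and a
#' cytosolic signal channel that follows per-cell degradation kinetics.
#' Later sessions are related to the first by a global translation plus a
#' mild affine perturbation (rotation/scale jitter).
#'
#' @param shape Image shape `c(rows, cols)` pixels.
#' @param n_z Planes per session stack.
#' @param z_spacing_um Plane spacing, micrometres.
#' @param session_times Session clock times, hours.
#' @param n_nuclei Number of cells.
#' @param nucleus_radius Nuclear disk radius, pixels.
#' @param positions Optional `n x 2` 0-based (row, col) centroids in the
#'   session-1 frame; random with 14 px separation if omitted.
#' @param kinetics [kinetics_spec()] for the cytosolic signal.
#' @param amp_cv Per-cell lognormal amplitude variability (CV).
#' @param nuclear_intensity Nuclear-reference intensity, a.u.
#' @param cyto_radius Cytosolic disk radius, pixels (must exceed the ring
#'   outer radius used in quantification).
#' @param max_shift_px Max |translation| per axis between sessions.
#' @param rot_sd_deg SD of inter-session rotation, degrees.
#' @param scale_sd SD of inter-session isotropic scale jitter.
#' @param gaussian_sd Additive Gaussian noise sd, a.u.
#' @param seed Integer seed.
#' @return An object of class `invivo_spec`.
#' @export
invivo_spec <- function(shape = c(256, 256), n_z = 1, z_spacing_um = 2,
                        session_times = c(-2, 1, 2, 3, 4, 5, 6, 8),
                        n_nuclei = 40, nucleus_radius = 4,
                        positions = NULL,
                        kinetics = kinetics_spec(amplitude = 60,
                                                 f_major = 0.9,
                                                 tau_major = 1.6,
                                                 tau_minor = 1000,
                                                 t_inducer = 0),
                        amp_cv = 0.2, nuclear_intensity = 100,
                        cyto_radius = 10, max_shift_px = 10,
                        rot_sd_deg = 1, scale_sd = 0.005,
                        gaussian_sd = 0, seed = 1L) {
  stopifnot(inherits(kinetics, "kinetics_spec"))
  if (is.null(positions))
    positions <- random_positions(n_nuclei, shape, min_sep = 2.2 * cyto_radius,
                                  margin = cyto_radius + max_shift_px + 6,
                                  seed = seed)
  structure(
    list(shape = shape, n_z = n_z, z_spacing_um = z_spacing_um,
         session_times = session_times, n_nuclei = nrow(positions),
         nucleus_radius = nucleus_radius, positions = positions,
         kinetics = kinetics, amp_cv = amp_cv,
         nuclear_intensity = nuclear_intensity, cyto_radius = cyto_radius,
         max_shift_px = max_shift_px, rot_sd_deg = rot_sd_deg,
         scale_sd = scale_sd, gaussian_sd = gaussian_sd,
         seed = as.integer(seed)),
    class = "invivo_spec")
}

# apply a 2x3 affine [A | b] to 0-based (row, col) points about the centre
apply_affine <- function(points, map, centre) {
  pts <- sweep(as.matrix(points), 2, centre)
  out <- pts %*% t(map[, 1:2])
  sweep(out, 2, centre + map[, 3], `+`)
}

# build a 2x3 affine from rotation (deg), scale and translation
make_affine <- function(rot_deg = 0, scale = 1, shift = c(0, 0)) {
  th <- rot_deg * pi / 180
  A <- scale * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2,
                      byrow = TRUE)
  cbind(A, shift)
}

#' Render longitudinal in-vivo sessions with ground truth
#'
#' Each session is a two-channel stack: channel 1 a stable nuclear
#' reference (filled disks of constant intensity), channel 2 the cytosolic
#' signal (filled disks of radius `cyto_radius`, value = per-cell kinetic
#' value at the session time). The per-session affine transform (ground
#' truth) maps session-1 centroids exactly onto later-session centroids in
#' the noiseless limit.
#'
#' @param spec An [invivo_spec()].
#' @return List with `sessions` (list of `timelapse_stack`s with channels
#'   `nuclear`, `signal`), and `ground_truth`: `centroids` (session, cell,
#'   row, col), `transforms` (list of 2x3 matrices, session 1 = identity),
#'   `params` (per-cell amplitude and kinetics), `seed`.
#' @export
simulate_invivo_sessions <- function(spec) {
  stopifnot(inherits(spec, "invivo_spec"))
  set.seed(spec$seed)
  n <- spec$n_nuclei
  amps <- if (spec$amp_cv > 0) {
    sdl <- sqrt(log(1 + spec$amp_cv^2))
    exp(stats::rnorm(n, -sdl^2 / 2, sdl))
  } else rep(1, n)
  centre <- (spec$shape - 1) / 2
  n_s <- length(spec$session_times)
  transforms <- vector("list", n_s)
  transforms[[1]] <- make_affine()
  if (n_s > 1) for (s in 2:n_s) {
    transforms[[s]] <- make_affine(
      rot_deg = stats::rnorm(1, 0, spec$rot_sd_deg),
      scale = 1 + stats::rnorm(1, 0, spec$scale_sd),
      shift = stats::runif(2, -spec$max_shift_px, spec$max_shift_px))
    if (abs(det(transforms[[s]][, 1:2])) < 1e-6)
      stop("degenerate inter-session transform")
  }
  ny <- spec$shape[1]; nx <- spec$shape[2]
  rr <- matrix(0:(ny - 1), ny, nx)
  cc <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  sessions <- vector("list", n_s)
  cent_rows <- list()
  for (s in seq_len(n_s)) {
    t <- spec$session_times[s]
    kv <- kinetics_value(spec$kinetics, t)
    cents <- apply_affine(spec$positions, transforms[[s]], centre)
    nuc <- matrix(0, ny, nx); sig <- matrix(0, ny, nx)
    for (i in seq_len(n)) {
      d2 <- (rr - cents[i, 1])^2 + (cc - cents[i, 2])^2
      nuc[d2 <= spec$nucleus_radius^2] <- spec$nuclear_intensity
      sig[d2 <= spec$cyto_radius^2] <-
        pmax(sig[d2 <= spec$cyto_radius^2], amps[i] * kv)
    }
    px <- array(0, dim = c(1, spec$n_z, 2, ny, nx))
    for (z in seq_len(spec$n_z)) {
      nz <- nuc; sz <- sig
      if (spec$gaussian_sd > 0) {
        nz <- nz + stats::rnorm(length(nz), 0, spec$gaussian_sd)
        sz <- sz + stats::rnorm(length(sz), 0, spec$gaussian_sd)
      }
      px[1, z, 1, , ] <- nz
      px[1, z, 2, , ] <- sz
    }
    sessions[[s]] <- timelapse_stack(px, timestamps = t,
                                     channels = c("nuclear", "signal"),
                                     t_inducer = spec$kinetics$t_inducer,
                                     z_spacing_um = spec$z_spacing_um)
    cent_rows[[s]] <- data.frame(session = s, cell = seq_len(n),
                                 row = cents[, 1], col = cents[, 2])
  }
  k <- spec$kinetics
  list(sessions = sessions,
       ground_truth = list(
         centroids = do.call(rbind, cent_rows),
         transforms = transforms,
         params = data.frame(cell = seq_len(n),
                             amplitude = amps * k$amplitude,
                             f_major = k$f_major, tau_major = k$tau_major,
                             tau_minor = k$tau_minor,
                             t_inducer = k$t_inducer),
         seed = spec$seed))
}

#' Simulate a single histology field of view with labelled regions
#'
#' Renders an image with synapse-rich neuropil regions at one mean
#' intensity and signal-free (vessel-like) background regions at another,
#' returning the region masks as ground truth for ratio quantification.
#'
#' @param shape Image shape `c(rows, cols)`.
#' @param neuropil_value,background_value Region mean intensities, a.u.
#' @param n_rois Number of circular ROIs per region kind.
#' @param roi_radius ROI radius, pixels.
#' @param poisson_gain Photons per a.u. for shot noise; `NA` off.
#' @param gaussian_sd Additive Gaussian noise sd, a.u.
#' @param seed Integer seed.
#' @return List with `image`, `neuropil_mask`, `background_mask` (logical
#'   matrices), `neuropil_rois`, `background_rois` (lists of [roi()]-like
#'   centres) and `ground_truth` (the set values and seed).
#' @export
simulate_histology_fov <- function(shape = c(128, 128),
                                   neuropil_value = 200,
                                   background_value = 50,
                                   n_rois = 4, roi_radius = 8,
                                   poisson_gain = NA_real_,
                                   gaussian_sd = 0, seed = 1L) {
  set.seed(as.integer(seed))
  ny <- shape[1]; nx <- shape[2]
  img <- matrix(neuropil_value, ny, nx)
  rr <- matrix(0:(ny - 1), ny, nx)
  cc <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  # vessel-like background stripes
  vess <- cc >= nx %/% 3 & cc < nx %/% 3 + 10
  img[vess] <- background_value
  cent_np <- random_positions(n_rois, shape, min_sep = 2 * roi_radius + 2,
                              margin = roi_radius + 1, seed = seed + 1L)
  # keep neuropil ROIs clear of the vessel stripe
  cent_np[, 2] <- ifelse(cent_np[, 2] >= nx %/% 3 - roi_radius - 1 &
                           cent_np[, 2] < nx %/% 3 + 10 + roi_radius + 1,
                         (cent_np[, 2] + nx %/% 2) %% (nx - 2 * roi_radius) +
                           roi_radius, cent_np[, 2])
  col_bg <- nx %/% 3 + 5
  cent_bg <- cbind(seq(roi_radius + 2, ny - roi_radius - 2,
                       length.out = n_rois), col_bg)
  mask_from <- function(cents) {
    m <- matrix(FALSE, ny, nx)
    for (i in seq_len(nrow(cents)))
      m <- m | ((rr - cents[i, 1])^2 + (cc - cents[i, 2])^2 <= roi_radius^2)
    m
  }
  np_mask <- mask_from(cent_np) & !vess
  bg_mask <- mask_from(cent_bg) & vess
  if (!is.na(poisson_gain))
    img <- matrix(stats::rpois(length(img), img * poisson_gain) /
                    poisson_gain, ny, nx)
  if (gaussian_sd > 0)
    img <- img + stats::rnorm(length(img), 0, gaussian_sd)
  list(image = img, neuropil_mask = np_mask, background_mask = bg_mask,
       neuropil_centers = cent_np, background_centers = cent_bg,
       ground_truth = list(neuropil_value = neuropil_value,
                           background_value = background_value,
                           seed = as.integer(seed)))
}
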