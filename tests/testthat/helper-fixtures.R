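# Shared fixture builders. Everything is generated in code; no files.

# default culture kinetics: 90% pool at 3.7 h, slow minor pool
fix_kinetics <- function(amplitude = 100, f_major = 0.9, tau_major = 3.7,
                         tau_minor = 37, t_inducer = 0) {
  kinetics_spec(amplitude = amplitude, f_major = f_major,
                tau_major = tau_major, tau_minor = tau_minor,
                t_inducer = t_inducer)
}

# small noiseless culture movie with n puncta
fix_movie <- function(n = 8, shape = c(96, 96), n_z = 2, times = c(-2, -1, 0:6),
                      gaussian_sd = 0, background = 10, seed = 3,
                      kin = fix_kinetics(), ...) {
  pos <- random_positions(n, shape, min_sep = 12, seed = seed)
  scene <- scene_spec(shape = shape, n_z = n_z, positions = pos,
                      kinetics = kin, background = background,
                      gaussian_sd = gaussian_sd, seed = seed, ...)
  simulate_culture_movie(scene, times)
}

# image with disks of given radius/intensity at 0-based positions
fix_disks <- function(shape, positions, radius = 5, value = 100, base = 0) {
  img <- matrix(base, shape[1], shape[2])
  rr <- matrix(0:(shape[1] - 1), shape[1], shape[2])
  cc <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE)
  for (i in seq_len(nrow(positions)))
    img[(rr - positions[i, 1])^2 + (cc - positions[i, 2])^2 <= radius^2] <-
      value
  img
}

# 2-D isotropic Gaussian spot added to an image (peak = value), 0-based
fix_spot <- function(img, row0, col0, value = 100, sigma = 1.5) {
  rr <- matrix(0:(nrow(img) - 1), nrow(img), ncol(img))
  cc <- matrix(0:(ncol(img) - 1), nrow(img), ncol(img), byrow = TRUE)
  img + value * exp(-((rr - row0)^2 + (cc - col0)^2) / (2 * sigma^2))
}
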