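test_that("FOV selection computes plane indices from depth arithmetic", {
  # 70 planes at 2 um: 13 FOVs from 60 um down in 10 um steps need plane 91
  expect_error(select_fovs(70, 2), "exceed")
  sel <- select_fovs(70, 2, truncate = TRUE)
  expect_equal(sel$planes, seq(31, 66, by = 5))
  expect_equal(sel$truncated, 5)
  # offset 0, step = spacing: consecutive planes
  sel2 <- select_fovs(20, 2, offset_um = 0, n_planes = 5, step_um = 2)
  expect_equal(sel2$planes, 1:5)
  # arbitrary request equals brute-force arithmetic
  sel3 <- select_fovs(120, 1.5, surface_plane = 4, offset_um = 30,
                      n_planes = 7, step_um = 12)
  brute <- 4 + round((30 + 12 * (0:6)) / 1.5)
  expect_equal(sel3$planes, brute)
})

test_that("FOV matching finds the reference plane in a candidate stack", {
  set.seed(14)
  pos <- random_positions(25, c(128, 128), min_sep = 12, seed = 14)
  ref <- fix_disks(c(128, 128), pos, radius = 4, value = 100) +
    rnorm(128^2, 0, 5)
  noise <- function() matrix(rnorm(128^2, 0, 30), 128, 128)
  # the reference itself is in the stack
  m <- match_fov(ref, list(noise(), ref, noise()))
  expect_equal(m$plane, 2)
  expect_false(m$unmatched)
  # a translated copy at plane 3 is still found
  shifted <- fix_disks(c(128, 128), sweep(pos, 2, c(6, -4), `+`),
                       radius = 4, value = 100) + rnorm(128^2, 0, 5)
  m2 <- match_fov(ref, list(noise(), noise(), shifted))
  expect_equal(m2$plane, 3)
  # pure-noise candidates are flagged unmatched
  m3 <- match_fov(ref, list(noise(), noise()))
  expect_true(m3$unmatched)
  expect_error(match_fov(ref, list()), "candidate")
})

test_that("nucleus detection recovers synthetic disks", {
  expect_equal(nrow(detect_nuclei(matrix(0, 64, 64))), 0)
  expect_equal(nrow(detect_nuclei(matrix(7, 64, 64))), 0)
  set.seed(15)
  pos <- random_positions(20, c(128, 128), min_sep = 14, margin = 10,
                          seed = 15)
  img <- fix_disks(c(128, 128), pos, radius = 5, value = 100) +
    rnorm(128^2, 0, 100 / 8)                     # SNR 8
  det <- detect_nuclei(img, nucleus_radius = 5)
  err <- vapply(seq_len(nrow(pos)), function(i)
    min(sqrt((det$row - pos[i, 1])^2 + (det$col - pos[i, 2])^2)), 0)
  expect_gte(sum(err <= 2), 19)
  # two heavily overlapping disks yield a single maximum, separated two
  two_near <- fix_disks(c(64, 64), rbind(c(32, 30), c(32, 34)), radius = 5,
                        value = 100)
  two_far <- fix_disks(c(64, 64), rbind(c(32, 20), c(32, 44)), radius = 5,
                       value = 100)
  expect_equal(nrow(detect_nuclei(two_near, nucleus_radius = 5,
                                  min_separation_px = 3)), 1)
  expect_equal(nrow(detect_nuclei(two_far, nucleus_radius = 5,
                                  min_separation_px = 3)), 2)
})

test_that("registration recovers identity, shifts and mild affines", {
  set.seed(16)
  pts <- cbind(runif(50, 20, 200), runif(50, 20, 200))
  # identity
  reg0 <- register_and_track(pts, pts)
  expect_equal(reg0$affine, cbind(diag(2), c(0, 0)), tolerance = 1e-9)
  expect_equal(reg0$mean_residual, 0, tolerance = 1e-9)
  # pure shift recovered exactly
  reg1 <- register_and_track(pts, sweep(pts, 2, c(5, 3), `+`))
  expect_equal(unname(reg1$translation), c(5, 3), tolerance = 1e-9)
  expect_equal(reg1$affine[, 1:2], diag(2), tolerance = 1e-9)
  # rotation 2 deg + scale 1.01 + jitter sd 0.3 px
  th <- 2 * pi / 180
  A <- 1.01 * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2,
                     byrow = TRUE)
  tgt <- t(A %*% t(pts)) + matrix(c(5, 3), 50, 2, byrow = TRUE) +
    matrix(rnorm(100, 0, 0.3), 50)
  reg2 <- register_and_track(pts, tgt)
  expect_lt(max(abs(reg2$affine[, 1:2] - A)), 0.01)
  expect_lt(reg2$mean_residual, 1)
  expect_false(reg2$translation_only)
  # fewer than 3 pairs: translation-only flag
  reg3 <- register_and_track(pts[1:2, ], pts[1:2, ] + 2)
  expect_true(reg3$translation_only)
})

test_that("transform recovery succeeds across random seeded scenes", {
  set.seed(17)
  ok <- 0; n_scenes <- 20
  for (k in 1:n_scenes) {
    pts <- cbind(runif(40, 20, 220), runif(40, 20, 220))
    th <- runif(1, -3, 3) * pi / 180
    s <- 1 + runif(1, -0.02, 0.02)
    A <- s * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2,
                    byrow = TRUE)
    shift <- runif(2, -15, 15)
    tgt <- t(A %*% t(pts)) + matrix(shift, 40, 2, byrow = TRUE) +
      matrix(rnorm(80, 0, 0.2), 40)
    reg <- register_and_track(pts, tgt, match_radius = 10)
    mapped <- cbind(pts, 1) %*% t(reg$affine)
    true_tgt <- t(A %*% t(pts)) + matrix(shift, 40, 2, byrow = TRUE)
    err <- sqrt(rowSums((mapped - true_tgt)^2))
    if (mean(err) < 1) ok <- ok + 1
  }
  expect_gte(ok / n_scenes, 0.95)
})

test_that("ring quantification matches brute-force annulus enumeration", {
  img <- matrix(42, 40, 40)
  expect_equal(as.numeric(ring_quantify(img, c(20, 20))), 42)
  set.seed(18)
  img2 <- matrix(runif(1600, 0, 10), 40, 40)
  for (ctr in list(c(20, 20), c(15.5, 22.3), c(9, 9))) {
    got <- ring_quantify(img2, ctr, r_in = 4, r_out = 8)
    # brute force over every pixel of the image
    sel <- matrix(FALSE, 40, 40)
    for (y in 0:39) for (x in 0:39) {
      d <- sqrt((y - ctr[1])^2 + (x - ctr[2])^2)
      sel[y + 1, x + 1] <- d >= 4 && d < 8
    }
    expect_equal(as.numeric(got), mean(img2[sel]))
  }
  # nuclear signal confined to r < 4 does not leak into the ring
  img3 <- fix_disks(c(40, 40), matrix(c(20, 20), 1), radius = 3.4,
                    value = 500, base = 7)
  expect_equal(as.numeric(ring_quantify(img3, c(20, 20))), 7)
  expect_error(ring_quantify(img, c(20, 20), r_in = 8, r_out = 4), "r_in")
  # clipping at the border is flagged
  expect_true(attr(ring_quantify(img, c(2, 20)), "clipped"))
})

test_that("nuclear normalization corrects session gain", {
  rec <- data.frame(cell = c(1, 2, 1, 2), session = c(1, 1, 2, 2),
                    ring_mean = c(30, 60, 45, 90),
                    nuclear_mean = c(100, 100, 150, 150))
  nn <- normalize_nuclear(rec)
  expect_equal(nn$normalized, c(0.3, 0.6, 0.3, 0.6))
  # doubling both channels' gain leaves normalized signal unchanged
  rec2 <- rec
  rec2$ring_mean <- rec2$ring_mean * 2
  rec2$nuclear_mean <- rec2$nuclear_mean * 2
  expect_equal(normalize_nuclear(rec2)$normalized, nn$normalized)
  # per-cell mode divides by each cell's own nucleus
  pc <- normalize_nuclear(rec, per_cell = TRUE)
  expect_equal(pc$normalized, rec$ring_mean / rec$nuclear_mean)
  expect_error(normalize_nuclear(transform(rec, nuclear_mean = 0)),
               "nuclear mean")
})

test_that("gain drift at one session does not bend a constant trace", {
  spec <- invivo_spec(n_nuclei = 12, gaussian_sd = 0, seed = 19,
                      session_times = c(-3, -2, -1),
                      kinetics = kinetics_spec(amplitude = 60, f_major = 1,
                                               tau_major = 1e6,
                                               t_inducer = 0))
  sim <- simulate_invivo_sessions(spec)
  # apply a x1.5 gain to both channels of session 3
  sim$sessions[[3]]$pixels <- sim$sessions[[3]]$pixels * 1.5
  q <- quantify_invivo(sim$sessions, min_initial_norm = 0)
  agg <- tapply(q$records$normalized, q$records$session, mean)
  expect_equal(unname(agg[3] / agg[1]), 1, tolerance = 0.02)
})

test_that("inclusion filters drop close pairs and dim cells", {
  rec <- data.frame(cell = rep(1:4, 2), session = rep(1:2, each = 4),
                    normalized = c(0.5, 0.2, 0.8, 0.9, 0.4, 0.1, 0.7, 0.8))
  cent <- data.frame(cell = 1:4, row = c(10, 30, 50, 52),
                     col = c(10, 30, 50, 50))
  # cell 2 is dim (0.2 < 0.3); cells 3 and 4 are 2 px apart
  res <- apply_inclusion_filters(rec, cent)
  expect_equal(res$kept, 1)
  expect_setequal(res$dropped$cell[res$dropped$rule == "pair_distance"],
                  c(3, 4))
  expect_true(2 %in% res$dropped$cell[res$dropped$rule == "initial_norm"])
  # random scenes equal brute-force rule application
  set.seed(20)
  for (k in 1:5) {
    n <- 15
    cent2 <- data.frame(cell = 1:n, row = runif(n, 0, 60),
                        col = runif(n, 0, 60))
    init <- runif(n, 0, 1)
    rec2 <- data.frame(cell = 1:n, session = 1, normalized = init)
    res2 <- apply_inclusion_filters(rec2, cent2)
    dm <- as.matrix(dist(cent2[, c("row", "col")])); diag(dm) <- Inf
    brute <- (1:n)[apply(dm, 1, min) >= 3 & init >= 0.3]
    expect_equal(res2$kept, brute)
  }
})

test_that("neuropil/background ratio divides across-ROI means", {
  img <- matrix(50, 60, 60)
  img[, 1:30] <- 200
  np <- list(roi(c(15, 10), "soma", 9), roi(c(40, 20), "soma", 9))
  bg <- list(roi(c(15, 45), "soma", 9), roi(c(40, 50), "soma", 9))
  res <- neuropil_background_ratio(img, np, bg)
  expect_equal(res$ratio, 4.0)
  res2 <- neuropil_background_ratio(img, bg, bg)
  expect_equal(res2$ratio, 1.0)
  expect_error(neuropil_background_ratio(img - 50, np, bg), "positive")
  # noisy synthetic FOV: ratio within 3 SE of the specified value
  h <- simulate_histology_fov(neuropil_value = 200, background_value = 50,
                              poisson_gain = 1, seed = 21)
  res3 <- neuropil_background_ratio(h$image, h$neuropil_mask,
                                    h$background_mask)
  se_np <- sqrt(200 / sum(h$neuropil_mask))
  se_bg <- sqrt(50 / sum(h$background_mask))
  se_ratio <- 4 * sqrt((se_np / 200)^2 + (se_bg / 50)^2)
  expect_lt(abs(res3$ratio - 4), 3 * se_ratio)
})

test_that("in-vivo pipeline tracks cells and recovers the kinetics", {
  spec <- invivo_spec(n_nuclei = 15, gaussian_sd = 1, seed = 22,
                      session_times = c(-2, 1, 3, 6))
  sim <- simulate_invivo_sessions(spec)
  q <- quantify_invivo(sim$sessions)
  expect_gte(q$tracked_fraction, 0.95)
  agg <- tapply(q$filtered$records$normalized,
                q$filtered$records$session, mean)
  rec <- as.numeric(agg / agg[1])
  truth <- kinetics_value(spec$kinetics, spec$session_times) /
    spec$kinetics$amplitude
  expect_equal(rec, truth, tolerance = 0.05)
})
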