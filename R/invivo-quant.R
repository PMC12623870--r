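#' Select analysis planes (FOVs) from a z-stack
#'
#' Computes the plane indices corresponding to a fixed depth series below a
#' reference surface plane: the first FOV at `offset_um` below the surface,
#' then `n_planes - 1` deeper FOVs in steps of `step_um` (defaults: 13
#' planes starting 60 um down, 10 um apart).
#'
#' @param n_z Number of planes in the stack.
#' @param z_spacing_um Plane spacing of the stack, micrometres.
#' @param surface_plane Index (1-based) of the surface plane.
#' @param offset_um Depth of the first FOV below the surface, micrometres.
#' @param n_planes Number of FOVs.
#' @param step_um Depth step between FOVs, micrometres.
#' @param truncate Drop FOVs beyond the stack instead of erroring.
#' @return List with `planes` (1-based indices), `depths_um`, and
#'   `truncated` (number of requested planes that did not fit).
#' @export
select_fovs <- function(n_z, z_spacing_um, surface_plane = 1,
                        offset_um = 60, n_planes = 13, step_um = 10,
                        truncate = FALSE) {
  depths <- offset_um + step_um * (seq_len(n_planes) - 1)
  planes <- surface_plane + round(depths / z_spacing_um)
  bad <- planes > n_z | planes < 1
  if (any(bad) && !truncate)
    stop("requested FOVs exceed stack depth (deepest plane ",
         max(planes), " of ", n_z, "); use truncate = TRUE to clip")
  list(planes = planes[!bad], depths_um = depths[!bad],
       truncated = sum(bad))
}

# LoG-maxima keypoints with normalized square patch descriptors
keypoint_descriptors <- function(image, sigma = 2, patch = 9,
                                 max_keypoints = 80) {
  det <- detect_puncta(image, sigma_range = sigma,
                       min_separation_px = patch, threshold = "auto",
                       k_sd = 1.5)
  half <- (patch - 1) %/% 2
  ny <- nrow(image); nx <- ncol(image)
  keep <- det$row - half >= 0 & det$row + half <= ny - 1 &
    det$col - half >= 0 & det$col + half <= nx - 1
  det <- det[keep, , drop = FALSE]
  if (nrow(det) > max_keypoints) det <- det[seq_len(max_keypoints), ]
  desc <- t(vapply(seq_len(nrow(det)), function(i) {
    p <- image[(det$row[i] - half):(det$row[i] + half) + 1,
               (det$col[i] - half):(det$col[i] + half) + 1]
    v <- as.vector(p)
    s <- stats::sd(v)
    if (s == 0) rep(0, patch^2) else (v - mean(v)) / s
  }, numeric(patch^2)))
  list(points = det[, c("row", "col")], desc = desc)
}

# translation-invariant normalized cross-correlation: the peak of the
# circular cross-covariance (computed by FFT) over all integer shifts,
# normalized by the two image standard deviations
ncc <- function(a, b) {
  av <- a - mean(a); bv <- b - mean(b)
  den <- sqrt(sum(av^2) * sum(bv^2))
  if (den == 0) return(0)
  cc <- Re(stats::fft(stats::fft(bv) * Conj(stats::fft(av)),
                      inverse = TRUE)) / length(a)
  max(cc) / den
}

#' Find the z-plane of a stack that matches a reference image
#'
#' Computes intensity-normalized patch keypoints on the reference and on
#' every candidate plane, matches descriptors by mutual nearest neighbour
#' with a Lowe distance-ratio validation, and returns the plane with the
#' most validated matches. The score is validated matches / reference
#' keypoints. When fewer than `min_keypoints` keypoints are found, falls
#' back to whole-image normalized cross-correlation (flagged).
#'
#' @param reference 2-D reference image.
#' @param candidate_stack 3-D array (z, rows, cols) or list of 2-D images.
#' @param ratio Lowe ratio-test threshold (best/second-best distance).
#' @param min_keypoints Below this count the NCC fallback is used.
#' @param score_threshold Scores below this are flagged unmatched.
#' @return List with `plane` (1-based index), `score`, `method`
#'   (`keypoints` or `ncc`), `matched` (validated match count per plane)
#'   and `unmatched` flag.
#' @export
match_fov <- function(reference, candidate_stack, ratio = 0.8,
                      min_keypoints = 4, score_threshold = 0.1) {
  cands <- if (is.list(candidate_stack)) candidate_stack
           else lapply(seq_len(dim(candidate_stack)[1]),
                       function(z) candidate_stack[z, , ])
  if (length(cands) == 0) stop("no candidate planes")
  kp_ref <- keypoint_descriptors(reference)
  use_ncc <- nrow(kp_ref$points) < min_keypoints
  if (!use_ncc) {
    matched <- vapply(cands, function(img) {
      kp <- keypoint_descriptors(img)
      if (nrow(kp$points) < 2) return(0L)
      d <- as.matrix(stats::dist(rbind(kp_ref$desc, kp$desc)))
      d <- d[seq_len(nrow(kp_ref$desc)),
             nrow(kp_ref$desc) + seq_len(nrow(kp$desc)), drop = FALSE]
      # mutual nearest neighbours, then validate by descriptor-distance
      # ratio or by consensus with the dominant displacement (repeated,
      # near-identical objects defeat the ratio test alone)
      mnn <- list()
      for (i in seq_len(nrow(d))) {
        j <- unname(which.min(d[i, ]))
        if (unname(which.min(d[, j])) != i) next
        second <- if (ncol(d) > 1) min(d[i, -j]) else Inf
        mnn[[length(mnn) + 1]] <-
          c(i = i, j = j, ratio_ok = as.numeric(d[i, j] <= ratio * second))
      }
      if (length(mnn) == 0) return(0L)
      mnn <- do.call(rbind, mnn)
      dy <- kp$points$row[mnn[, "j"]] - kp_ref$points$row[mnn[, "i"]]
      dx <- kp$points$col[mnn[, "j"]] - kp_ref$points$col[mnn[, "i"]]
      consensus <- sqrt((dy - stats::median(dy))^2 +
                          (dx - stats::median(dx))^2) <= 3
      sum(mnn[, "ratio_ok"] == 1 | (consensus & length(dy) >= 3))
    }, 0L)
    score <- max(matched) / nrow(kp_ref$points)
    if (max(matched) >= 2) {
      return(list(plane = which.max(matched), score = score,
                  method = "keypoints", matched = matched,
                  unmatched = score < score_threshold))
    }
    use_ncc <- TRUE
  }
  sc <- vapply(cands, function(img) ncc(reference, img), 0)
  list(plane = which.max(sc), score = max(sc), method = "ncc",
       matched = sc, unmatched = max(sc) < score_threshold)
}

#' Detect nuclei by Gaussian blur, Otsu threshold and LoG blob detection
#'
#' The reference-channel image is equalized with a Gaussian blur, binarized
#' with a global Otsu threshold, and Laplacian-of-Gaussian blob detection is
#' run with maxima restricted to the foreground.
#'
#' @param image 2-D nuclear-reference image.
#' @param blur_sigma Gaussian blur sigma, pixels (default 2).
#' @param nucleus_radius Expected nuclear radius, pixels; LoG scales probe
#'   this radius +/- 40%.
#' @param min_separation_px Minimum distance between nuclei, pixels.
#' @return data.frame with 0-based `row`, `col`, `score`, `sigma` (empty,
#'   without error, on blank or single-intensity images).
#' @export
detect_nuclei <- function(image, blur_sigma = 2, nucleus_radius = 4,
                          min_separation_px = 6) {
  stopifnot(is.matrix(image))
  if (length(unique(as.vector(image))) < 2)
    return(data.frame(row = numeric(0), col = numeric(0),
                      score = numeric(0), sigma = numeric(0)))
  rng <- range(image)
  norm <- (image - rng[1]) / (rng[2] - rng[1])
  blurred <- EBImage::gblur(norm, sigma = blur_sigma)
  thr <- EBImage::otsu(EBImage::Image(blurred))
  fg <- blurred > thr
  # blob scale for a disk of radius r peaks near sigma = r / sqrt(2)
  s0 <- nucleus_radius / sqrt(2)
  sig <- unique(pmax(0.8, s0 * c(0.6, 1, 1.4)))
  det <- detect_puncta(blurred, sigma_range = sig,
                       min_separation_px = min_separation_px,
                       threshold = 0)
  if (nrow(det) == 0) return(det)
  inside <- fg[cbind(round(det$row) + 1, round(det$col) + 1)]
  det[inside, , drop = FALSE]
}

# greedy mutual-nearest matching of two 0-based point sets within a radius;
# returns index pairs (i in a, j in b)
match_points <- function(a, b, radius) {
  if (nrow(a) == 0 || nrow(b) == 0)
    return(cbind(i = integer(0), j = integer(0)))
  dm <- sqrt(outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2)
  cand <- which(dm <= radius, arr.ind = TRUE)
  if (nrow(cand) == 0) return(cbind(i = integer(0), j = integer(0)))
  cand <- cand[order(dm[cand]), , drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  out <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    out[[length(out) + 1]] <- c(i, j)
  }
  m <- do.call(rbind, out)
  colnames(m) <- c("i", "j")
  m
}

# robust global translation between two point sets: every (ref, tgt) pair
# within max_shift casts a vote; the densest 4 px displacement bin wins and
# the returned shift is the mean displacement of its voters (a 1-step
# Hough consensus, immune to the neighbour mislinks that bias a median)
consensus_translation <- function(ref, tgt, max_shift = 32, bin = 4) {
  dy <- outer(tgt[, 1], ref[, 1], `-`)
  dx <- outer(tgt[, 2], ref[, 2], `-`)
  keep <- abs(dy) <= max_shift & abs(dx) <= max_shift
  if (!any(keep)) return(c(0, 0))
  dy <- dy[keep]; dx <- dx[keep]
  key <- paste(round(dy / bin), round(dx / bin))
  top <- names(which.max(table(key)))
  sel <- key == top
  c(mean(dy[sel]), mean(dx[sel]))
}

# translation between two images by FFT phase correlation, returned as
# (dy, dx) such that shifting `a` by (dy, dx) aligns it with `b`
phase_correlation <- function(a, b) {
  fa <- stats::fft(a); fb <- stats::fft(b)
  cp <- fb * Conj(fa)
  mag <- Mod(cp); mag[mag == 0] <- 1
  r <- Re(stats::fft(cp / mag, inverse = TRUE))
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  dy <- pk[1] - 1; dx <- pk[2] - 1
  if (dy > nrow(a) / 2) dy <- dy - nrow(a)
  if (dx > ncol(a) / 2) dx <- dx - ncol(a)
  c(dy, dx)
}

#' Register a session to the reference and track nuclei
#'
#' Two-stage alignment mirroring the longitudinal pipeline: a global
#' xy-translation (phase correlation when images are supplied, median
#' displacement of matched centroids otherwise), then a least-squares local
#' affine refined on matched centroid pairs. Reference centroids are mapped
#' through the composite transform; each reference cell is assigned the
#' nearest target detection within `match_radius`.
#'
#' @param reference_centroids data.frame/matrix of 0-based (row, col) in
#'   the reference session.
#' @param target_centroids Detected centroids in the target session.
#' @param reference_image,target_image Optional images for the
#'   phase-correlation translation stage.
#' @param match_radius Pairing radius after translation, pixels.
#' @return List with `translation` (dy, dx), `affine` (2x3 matrix mapping
#'   reference to target, 0-based coordinates), `mapped` (reference
#'   centroids mapped through the transform), `assignment` (data.frame
#'   cell, target_index, residual; NA target = lost cell), `mean_residual`,
#'   and `translation_only` flag (TRUE when < 3 pairs supported the affine).
#' @export
register_and_track <- function(reference_centroids, target_centroids,
                               reference_image = NULL, target_image = NULL,
                               match_radius = 8) {
  ref <- as.matrix(reference_centroids)[, 1:2, drop = FALSE]
  tgt <- as.matrix(target_centroids)[, 1:2, drop = FALSE]
  shift <- if (!is.null(reference_image) && !is.null(target_image)) {
    phase_correlation(reference_image, target_image)
  } else {
    consensus_translation(ref, tgt, max_shift = 4 * match_radius)
  }
  # refine the translation on the pairs it brings into register
  m0 <- match_points(sweep(ref, 2, shift, `+`), tgt, radius = match_radius)
  if (nrow(m0) > 0)
    shift <- c(mean(tgt[m0[, "j"], 1] - ref[m0[, "i"], 1]),
               mean(tgt[m0[, "j"], 2] - ref[m0[, "i"], 2]))
  affine <- cbind(diag(2), shift)
  mapped <- cbind(ref, 1) %*% t(affine)
  translation_only <- TRUE
  # iterative refinement: match under the current map, refit, remap --
  # soaks up the field-dependent residual of rotation/scale about a far
  # origin that a single translation-stage match cannot absorb
  for (it in 1:3) {
    m <- match_points(mapped, tgt, radius = match_radius)
    if (nrow(m) < 3) break
    X <- cbind(ref[m[, "i"], , drop = FALSE], 1)
    Y <- tgt[m[, "j"], , drop = FALSE]
    if (qr(X)$rank < 3) break            # collinear support
    affine <- t(qr.solve(X, Y))          # 2 x 3, rows = (row', col')
    mapped <- cbind(ref, 1) %*% t(affine)
    translation_only <- FALSE
  }
  asg <- match_points(mapped, tgt, radius = match_radius)
  assignment <- data.frame(cell = seq_len(nrow(ref)),
                           target_index = NA_integer_,
                           residual = NA_real_)
  if (nrow(asg) > 0) {
    res <- sqrt(rowSums((mapped[asg[, "i"], , drop = FALSE] -
                           tgt[asg[, "j"], , drop = FALSE])^2))
    assignment$target_index[asg[, "i"]] <- asg[, "j"]
    assignment$residual[asg[, "i"]] <- res
  }
  list(translation = shift, affine = affine, mapped = mapped,
       assignment = assignment,
       mean_residual = mean(assignment$residual, na.rm = TRUE),
       translation_only = translation_only)
}

#' Mean fluorescence in a ring around a centroid
#'
#' Averages the signal over pixels whose centre distance d from the
#' centroid satisfies `r_in <= d < r_out` (half-open annulus, disjoint from
#' the nuclear disk d < r_in).
#'
#' @param image 2-D signal-channel image.
#' @param centroid 0-based `c(row, col)`.
#' @param r_in,r_out Annulus radii, pixels (default 4 and 8).
#' @return Scalar ring mean; attribute `clipped` is TRUE when the annulus
#'   was cut by the image border.
#' @export
ring_quantify <- function(image, centroid, r_in = 4, r_out = 8) {
  if (r_in >= r_out) stop("r_in must be smaller than r_out")
  ny <- nrow(image); nx <- ncol(image)
  r0 <- max(0, floor(centroid[1] - r_out)):min(ny - 1, ceiling(centroid[1] + r_out))
  c0 <- max(0, floor(centroid[2] - r_out)):min(nx - 1, ceiling(centroid[2] + r_out))
  d <- sqrt(outer((r0 - centroid[1])^2, (c0 - centroid[2])^2, `+`))
  sel <- d >= r_in & d < r_out
  clipped <- centroid[1] - r_out < -0.5 || centroid[2] - r_out < -0.5 ||
    centroid[1] + r_out > ny - 0.5 || centroid[2] + r_out > nx - 0.5
  out <- mean(image[r0 + 1, c0 + 1][sel])
  attr(out, "clipped") <- clipped
  out
}

#' Normalize ring signals to the session-level nuclear reference
#'
#' Divides each cell's ring mean by the mean nuclear-reference fluorescence
#' of its session (all cells pooled), correcting session-to-session
#' recording gain. Per-cell normalization (each ring divided by its own
#' nucleus) is available as an option.
#'
#' @param records data.frame with `cell`, `session`, `ring_mean`,
#'   `nuclear_mean`.
#' @param per_cell Use each cell's own nuclear mean instead of the session
#'   mean.
#' @return `records` with a `normalized` column added.
#' @export
normalize_nuclear <- function(records, per_cell = FALSE) {
  stopifnot(all(c("cell", "session", "ring_mean", "nuclear_mean") %in%
                  names(records)))
  if (per_cell) {
    if (any(records$nuclear_mean <= 0)) stop("non-positive nuclear mean")
    records$normalized <- records$ring_mean / records$nuclear_mean
    return(records)
  }
  sess_mean <- tapply(records$nuclear_mean, records$session, mean)
  if (any(sess_mean <= 0)) stop("non-positive session nuclear mean")
  records$normalized <- records$ring_mean /
    as.numeric(sess_mean[as.character(records$session)])
  records
}

#' Apply the longitudinal-analysis inclusion filters
#'
#' Drops cells whose nearest-neighbour centroid distance in the reference
#' session is below `min_pair_distance` and cells whose initial normalized
#' signal is below `min_initial_norm`.
#'
#' @param records Normalized records (see [normalize_nuclear()]) with
#'   `cell`, `session`, `normalized`.
#' @param centroids Reference-session centroids: data.frame `cell`, `row`,
#'   `col`.
#' @param min_pair_distance Minimum pairwise distance, pixels (default 3).
#' @param min_initial_norm Minimum initial normalized signal (default 0.3).
#' @param initial_session Session id defining "initial" (default the
#'   smallest).
#' @return List with `records` (filtered), `kept` (cell ids) and `dropped`
#'   (data.frame cell, rule).
#' @export
apply_inclusion_filters <- function(records, centroids,
                                    min_pair_distance = 3,
                                    min_initial_norm = 0.3,
                                    initial_session = NULL) {
  if (is.null(initial_session)) initial_session <- min(records$session)
  cells <- sort(unique(records$cell))
  dropped <- list()
  # pair-distance rule: both members of a too-close pair go
  too_close <- c()
  if (nrow(centroids) > 1) {
    dm <- as.matrix(stats::dist(centroids[, c("row", "col")]))
    diag(dm) <- Inf
    too_close <- centroids$cell[apply(dm, 1, min) < min_pair_distance]
  }
  for (cl in too_close)
    dropped[[length(dropped) + 1]] <- data.frame(cell = cl,
                                                 rule = "pair_distance")
  init <- records[records$session == initial_session, ]
  dim_cells <- init$cell[init$normalized < min_initial_norm]
  for (cl in setdiff(dim_cells, too_close))
    dropped[[length(dropped) + 1]] <- data.frame(cell = cl,
                                                 rule = "initial_norm")
  bad <- union(too_close, dim_cells)
  keep <- setdiff(cells, bad)
  list(records = records[records$cell %in% keep, ],
       kept = keep,
       dropped = if (length(dropped)) do.call(rbind, dropped)
                 else data.frame(cell = integer(0), rule = character(0)))
}

#' Neuropil-to-background fluorescence ratio of a field of view
#'
#' Divides the across-ROI mean neuropil fluorescence by the across-ROI mean
#' background fluorescence, a normalized read-out of bulk synaptic signal.
#'
#' @param image 2-D image (one channel).
#' @param neuropil_rois,background_rois Lists of [roi()]s, or logical masks.
#' @return List with `neuropil_mean`, `background_mean`, `ratio`.
#' @export
neuropil_background_ratio <- function(image, neuropil_rois,
                                      background_rois) {
  region_mean <- function(spec) {
    if (is.matrix(spec) && is.logical(spec)) return(mean(image[spec]))
    if (length(spec) == 0) stop("need at least one ROI per region")
    mean(vapply(spec, function(r) measure_roi(image, r), 0))
  }
  np <- region_mean(neuropil_rois)
  bg <- region_mean(background_rois)
  if (bg <= 0) stop("background mean must be positive")
  list(neuropil_mean = np, background_mean = bg, ratio = np / bg)
}

#' Full longitudinal in-vivo quantification pipeline
#'
#' For a list of per-session two-channel stacks: detects nuclei on the
#' reference channel of the first session, registers and tracks them into
#' every later session (translation + local affine), quantifies the 4-8 px
#' ring signal around each tracked centroid, normalizes to the session-level
#' nuclear mean and applies the inclusion filters.
#'
#' @param sessions List of `timelapse_stack`s (channels `nuclear`,
#'   `signal`), one per session.
#' @param z_plane Plane used per session (default 1).
#' @param nucleus_radius Expected nuclear radius for detection, pixels.
#' @param r_in,r_out Ring radii, pixels.
#' @param match_radius Tracking assignment radius, pixels.
#' @param min_pair_distance,min_initial_norm Inclusion-filter settings.
#' @return List with `records` (cell, session, time, row, col, ring_mean,
#'   nuclear_mean, normalized), `filtered` ([apply_inclusion_filters()]
#'   output), `transforms`, `tracked_fraction` (cells followed through all
#'   sessions / cells detected in session 1).
#' @export
quantify_invivo <- function(sessions, z_plane = 1, nucleus_radius = 4,
                            r_in = 4, r_out = 8, match_radius = 8,
                            min_pair_distance = 3, min_initial_norm = 0.3) {
  get_img <- function(s, ch) {
    ci <- match(ch, sessions[[s]]$channels)
    matrix(sessions[[s]]$pixels[1, z_plane, ci, , ],
           dim(sessions[[s]]$pixels)[4], dim(sessions[[s]]$pixels)[5])
  }
  n_s <- length(sessions)
  ref_nuc <- get_img(1, "nuclear")
  ref_det <- detect_nuclei(ref_nuc, nucleus_radius = nucleus_radius)
  if (nrow(ref_det) == 0) stop("no nuclei detected in the reference session")
  n_cells <- nrow(ref_det)
  ref_cent <- as.matrix(ref_det[, c("row", "col")])
  transforms <- vector("list", n_s)
  recs <- list()
  cents_by_session <- vector("list", n_s)
  cents_by_session[[1]] <- ref_cent
  tracked <- matrix(FALSE, n_s, n_cells)
  tracked[1, ] <- TRUE
  for (s in seq_len(n_s)) {
    nuc <- get_img(s, "nuclear"); sig <- get_img(s, "signal")
    if (s == 1) {
      cents <- ref_cent
      transforms[[1]] <- cbind(diag(2), c(0, 0))
    } else {
      det <- detect_nuclei(nuc, nucleus_radius = nucleus_radius)
      reg <- register_and_track(ref_cent, as.matrix(det[, c("row", "col")]),
                                reference_image = ref_nuc,
                                target_image = nuc,
                                match_radius = match_radius)
      transforms[[s]] <- reg$affine
      cents <- reg$mapped
      ok <- !is.na(reg$assignment$target_index)
      cents[ok, ] <- as.matrix(det[reg$assignment$target_index[ok],
                                   c("row", "col")])
      tracked[s, ] <- ok
      cents_by_session[[s]] <- cents
    }
    # interior disk: robust to ~1 px centroid error after registration
    nuc_means <- vapply(seq_len(n_cells), function(i)
      disk_mean(nuc, cents[i, ], max(1, nucleus_radius - 1)), 0)
    ring_means <- vapply(seq_len(n_cells), function(i)
      as.numeric(ring_quantify(sig, cents[i, ], r_in, r_out)), 0)
    recs[[s]] <- data.frame(cell = seq_len(n_cells), session = s,
                            time = sessions[[s]]$timestamps[1],
                            row = cents[, 1], col = cents[, 2],
                            ring_mean = ring_means,
                            nuclear_mean = nuc_means)
  }
  records <- normalize_nuclear(do.call(rbind, recs))
  filt <- apply_inclusion_filters(
    records, data.frame(cell = seq_len(n_cells),
                        row = ref_cent[, 1], col = ref_cent[, 2]),
    min_pair_distance = min_pair_distance,
    min_initial_norm = min_initial_norm)
  list(records = records, filtered = filt, transforms = transforms,
       tracked_fraction = mean(colSums(tracked) == n_s))
}

# mean over the disk d <= r around a 0-based centroid
disk_mean <- function(image, centroid, r) {
  ny <- nrow(image); nx <- ncol(image)
  r0 <- max(0, floor(centroid[1] - r)):min(ny - 1, ceiling(centroid[1] + r))
  c0 <- max(0, floor(centroid[2] - r)):min(nx - 1, ceiling(centroid[2] + r))
  d <- sqrt(outer((r0 - centroid[1])^2, (c0 - centroid[2])^2, `+`))
  mean(image[r0 + 1, c0 + 1][d <= r])
}
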