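#' Maximum-intensity projection over z
#'
#' @param stack A `timelapse_stack`.
#' @param t Time index (1-based).
#' @param channel Channel index or label.
#' @return 2-D matrix (rows x cols).
#' @export
max_project <- function(stack, t, channel) {
  stopifnot(inherits(stack, "timelapse_stack"))
  d <- dim(stack$pixels)
  ci <- if (is.character(channel)) match(channel, stack$channels) else channel
  if (is.na(ci) || ci < 1 || ci > d[3]) stop("channel out of range")
  if (t < 1 || t > d[1]) stop("time index out of range")
  sub <- stack$pixels[t, , ci, , , drop = FALSE]
  apply(array(sub, dim = d[c(2, 4, 5)]), c(2, 3), max)
}

# Scale-normalized (negated) Laplacian-of-Gaussian kernel: positive
# response on bright blobs of scale ~ sigma.
log_kernel <- function(sigma) {
  half <- max(2L, ceiling(3 * sigma))
  x <- -half:half
  r2 <- outer(x^2, x^2, "+")
  k <- -(r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k * sigma^2 - mean(k * sigma^2)  # scale-normalized, zero-mean
}

# 2-D local maxima of `resp` (8-neighbourhood), strictly above ties on
# lexicographically earlier pixels to keep plateaus single.
local_maxima <- function(resp) {
  ny <- nrow(resp); nx <- ncol(resp)
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- resp
  ge <- matrix(TRUE, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx)]
    cmp <- if (dy < 0 || (dy == 0 && dx < 0)) resp > nb else resp >= nb
    ge <- ge & cmp
  }
  which(ge, arr.ind = TRUE)
}

#' Detect fluorescent puncta by multi-scale LoG blob detection
#'
#' Convolves the image with scale-normalized Laplacian-of-Gaussian kernels
#' over `sigma_range`, takes the per-pixel maximum response across scales,
#' finds local maxima and keeps those above threshold, enforcing a minimum
#' pairwise separation greedily by descending score.
#'
#' @param image 2-D matrix.
#' @param sigma_range Blob scales (Gaussian sigmas) to probe, pixels.
#' @param min_separation_px Minimum distance between detections, pixels.
#' @param threshold Either a number (absolute LoG-response cutoff) or
#'   `"auto"` for mean + `k_sd` * sd of the response.
#' @param k_sd Multiplier for the automatic threshold (default 4).
#' @return data.frame with 0-based `row`, `col`, `score`, `sigma`, sorted by
#'   descending score. Empty for a blank image.
#' @export
detect_puncta <- function(image, sigma_range = c(1, 1.5, 2),
                          min_separation_px = 4, threshold = "auto",
                          k_sd = 4) {
  stopifnot(is.matrix(image))
  if (any(sigma_range <= 0)) stop("sigma values must be positive")
  resp <- matrix(-Inf, nrow(image), ncol(image))
  best_sigma <- matrix(sigma_range[1], nrow(image), ncol(image))
  for (s in sigma_range) {
    r <- EBImage::filter2(image, log_kernel(s), boundary = "replicate")
    upd <- r > resp
    resp[upd] <- r[upd]
    best_sigma[upd] <- s
  }
  thr <- if (identical(threshold, "auto"))
    mean(resp) + k_sd * stats::sd(resp) else threshold
  pk <- local_maxima(resp)
  if (nrow(pk) > 0) {
    sc <- resp[pk]
    keep <- sc > thr
    pk <- pk[keep, , drop = FALSE]; sc <- sc[keep]
  } else sc <- numeric(0)
  if (nrow(pk) == 0)
    return(data.frame(row = numeric(0), col = numeric(0),
                      score = numeric(0), sigma = numeric(0)))
  o <- order(sc, decreasing = TRUE)
  pk <- pk[o, , drop = FALSE]; sc <- sc[o]
  keep <- rep(TRUE, nrow(pk))
  for (i in seq_len(nrow(pk))) {
    if (!keep[i]) next
    if (i < nrow(pk)) {
      j <- (i + 1):nrow(pk)
      d <- sqrt((pk[j, 1] - pk[i, 1])^2 + (pk[j, 2] - pk[i, 2])^2)
      keep[j][d < min_separation_px] <- FALSE
    }
  }
  data.frame(row = pk[keep, 1] - 1, col = pk[keep, 2] - 1,
             score = sc[keep],
             sigma = best_sigma[pk[keep, , drop = FALSE]])
}

#' Track puncta across time points by greedy nearest-neighbour linking
#'
#' Tracks are seeded from the first time point. At each subsequent time
#' point, candidate (track, detection) pairs within `search_radius_px` are
#' linked greedily by ascending distance. Unlinked tracks are marked absent;
#' a second track whose nearest detection was already claimed is flagged
#' merged; a spare detection within the radius of an already-linked track
#' flags that track split; remaining spare detections start new tracks
#' flagged formed. A track is persistent iff present at every time point
#' with no merge/split involvement.
#'
#' @param detections List of data.frames (one per time point) with 0-based
#'   `row`, `col` (as returned by [detect_puncta()]).
#' @param search_radius_px Maximum link distance, pixels.
#' @return A list with `tracks` (long data.frame: track, time_index, row,
#'   col, status in present/absent) and `summary` (per-track class in
#'   persistent/formed/disappeared/merged/split and the persistent flag).
#' @export
track_puncta <- function(detections, search_radius_px = 4) {
  stopifnot(is.list(detections), length(detections) >= 2)
  if (nrow(detections[[1]]) == 0)
    stop("no detections at the reference time point")
  n_t <- length(detections)
  ref <- detections[[1]]
  pos <- lapply(seq_len(nrow(ref)),
                function(i) c(ref$row[i], ref$col[i]))
  origin <- rep(1L, length(pos))        # first time point seen
  flags <- rep("", length(pos))          # "merged"/"split" once set
  rows <- list(data.frame(track = seq_along(pos), time_index = 1,
                          row = ref$row, col = ref$col,
                          status = "present"))
  present <- matrix(FALSE, n_t, length(pos))
  present[1, ] <- TRUE
  for (ti in 2:n_t) {
    det <- detections[[ti]]
    n_tr <- length(pos); n_d <- nrow(det)
    link <- rep(NA_integer_, n_tr)
    det_taken <- rep(FALSE, max(n_d, 1))
    if (n_d > 0) {
      dm <- outer(vapply(pos, `[`, 0, 1), det$row, `-`)^2 +
        outer(vapply(pos, `[`, 0, 2), det$col, `-`)^2
      dm <- sqrt(dm)
      cand <- which(dm <= search_radius_px, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        cand <- cand[order(dm[cand]), , drop = FALSE]
        for (k in seq_len(nrow(cand))) {
          tr <- cand[k, 1]; de <- cand[k, 2]
          if (!is.na(link[tr])) next
          if (det_taken[de]) {
            # nearest free? this pair lost to an earlier link -> merge call
            if (flags[tr] == "") flags[tr] <- "merged"
            next
          }
          link[tr] <- de
          det_taken[de] <- TRUE
        }
      }
    }
    # spare detections near an already-linked track => split flag
    if (n_d > 0) {
      spare <- which(!det_taken)
      for (de in spare) {
        dists <- sqrt((vapply(pos, `[`, 0, 1) - det$row[de])^2 +
                        (vapply(pos, `[`, 0, 2) - det$col[de])^2)
        near <- which(dists <= search_radius_px & !is.na(link))
        if (length(near) > 0) {
          tr <- near[which.min(dists[near])]
          if (flags[tr] == "") flags[tr] <- "split"
          det_taken[de] <- TRUE  # consumed by the split call
        }
      }
    }
    # update linked tracks, record absences, open new (formed) tracks
    status <- ifelse(is.na(link), "absent", "present")
    for (tr in seq_len(n_tr))
      if (!is.na(link[tr])) pos[[tr]] <- c(det$row[link[tr]],
                                           det$col[link[tr]])
    rows[[length(rows) + 1]] <- data.frame(
      track = seq_len(n_tr), time_index = ti,
      row = vapply(pos, `[`, 0, 1), col = vapply(pos, `[`, 0, 2),
      status = status)
    present[ti, seq_len(n_tr)] <- !is.na(link)
    if (n_d > 0) {
      new_d <- which(!det_taken)
      for (de in new_d) {
        pos[[length(pos) + 1]] <- c(det$row[de], det$col[de])
        origin <- c(origin, ti)
        flags <- c(flags, "")
        present <- cbind(present, FALSE)
        present[ti, ncol(present)] <- TRUE
        rows[[length(rows) + 1]] <- data.frame(
          track = ncol(present), time_index = ti,
          row = det$row[de], col = det$col[de], status = "present")
      }
    }
  }
  tracks <- do.call(rbind, rows)
  tracks <- tracks[order(tracks$track, tracks$time_index), ]
  rownames(tracks) <- NULL
  n_tr <- ncol(present)
  class_of <- character(n_tr)
  for (tr in seq_len(n_tr)) {
    all_present <- all(present[origin[tr]:n_t, tr])
    class_of[tr] <-
      if (flags[tr] != "") flags[tr]
      else if (origin[tr] > 1) "formed"
      else if (!all_present || !all(present[, tr])) "disappeared"
      else "persistent"
  }
  summary <- data.frame(track = seq_len(n_tr), class = class_of,
                        persistent = class_of == "persistent" &
                          colSums(present) == n_t)
  list(tracks = tracks, summary = summary)
}

#' Construct a measurement ROI
#'
#' @param center 0-based `c(row, col)` centre.
#' @param kind One of `"synapse"` (fixed 9x9 square), `"soma"` or
#'   `"background"` (square of side `size`).
#' @param size Side length for soma/background ROIs (odd integer).
#' @return An object of class `roi`.
#' @export
roi <- function(center, kind = c("synapse", "soma", "background"),
                size = 9L) {
  kind <- match.arg(kind)
  if (kind == "synapse") size <- 9L
  if (size %% 2 == 0) stop("ROI size must be odd")
  structure(list(center = round(center), kind = kind, size = as.integer(size)),
            class = "roi")
}

#' Mean pixel intensity within an ROI
#'
#' Arithmetic mean of the pixels in the square footprint centred on the ROI
#' centre (9x9 = 81 pixels for synapse ROIs).
#'
#' @param image 2-D matrix (typically a max projection).
#' @param r An [roi()].
#' @return Scalar mean, a.u.
#' @export
measure_roi <- function(image, r) {
  stopifnot(inherits(r, "roi"))
  half <- (r$size - 1L) %/% 2L
  rr <- (r$center[1] - half):(r$center[1] + half)
  cc <- (r$center[2] - half):(r$center[2] + half)
  if (min(rr) < 0 || min(cc) < 0 ||
      max(rr) > nrow(image) - 1 || max(cc) > ncol(image) - 1)
    stop("ROI footprint extends outside the image")
  # plain sum / count: matches brute-force enumeration bit for bit
  sum(image[rr + 1, cc + 1]) / (r$size^2)
}

#' Estimate the background fluorescence level of an image
#'
#' Background subtraction uses values from cell-free regions. Three ways to
#' find them: `"user"`, the mean over a user-drawn ROI; `"auto"`, the mean
#' of the dimmest `p` percent of pixels (simple, but biased low when noise
#' is appreciable, since it averages the lower tail of the noise); and
#' `"cellfree"`, the mean over all pixels below the Otsu threshold of a
#' blurred copy -- an unbiased estimate of the level of programmatically
#' found cell-free regions, robust to noise.
#'
#' @param image 2-D matrix.
#' @param mode `"cellfree"`, `"auto"` or `"user"`.
#' @param user_roi An [roi()] (required for `mode = "user"`).
#' @param p Percentile for auto mode (default 1, i.e. dimmest 1%).
#' @param blur_sigma Blur for cellfree mode, pixels.
#' @return Scalar background level, a.u.
#' @export
estimate_background <- function(image, mode = c("auto", "user", "cellfree"),
                                user_roi = NULL, p = 1, blur_sigma = 2) {
  mode <- match.arg(mode)
  if (length(image) == 0) stop("empty image")
  if (mode == "user") {
    if (is.null(user_roi)) stop("user mode requires a ROI")
    return(measure_roi(image, user_roi))
  }
  if (mode == "cellfree") {
    return(mean(image[cellfree_mask(image, blur_sigma = blur_sigma)]))
  }
  cut <- stats::quantile(image, p / 100, names = FALSE)
  mean(image[image <= cut])
}

#' Cell-free region mask of a fluorescence image
#'
#' Blurs the image, thresholds it globally (Otsu) and dilates the
#' foreground by `exclude_radius` so that the dim skirts of bright objects
#' are excluded too; the complement is the cell-free region. Falls back to
#' the whole image when everything ends up foreground (or the image is
#' constant).
#'
#' @param image 2-D matrix.
#' @param blur_sigma Gaussian blur sigma, pixels.
#' @param exclude_radius Dilation radius around foreground objects, pixels.
#' @return Logical matrix, `TRUE` on cell-free pixels.
#' @export
cellfree_mask <- function(image, blur_sigma = 2, exclude_radius = 7) {
  rng <- range(image)
  if (diff(rng) == 0) return(matrix(TRUE, nrow(image), ncol(image)))
  norm <- (image - rng[1]) / diff(rng)
  blurred <- EBImage::gblur(norm, sigma = blur_sigma)
  thr <- EBImage::otsu(EBImage::Image(blurred))
  fg <- EBImage::Image(blurred > thr)
  brush <- EBImage::makeBrush(2 * exclude_radius + 1, shape = "disc")
  fg <- as.matrix(EBImage::dilate(fg, brush)) > 0
  if (all(fg)) return(matrix(TRUE, nrow(image), ncol(image)))
  !fg
}

#' Spectral unmixing of a multi-channel stack
#'
#' Applies the inverse of the channel mixing matrix per pixel. Negative
#' unmixed values are clipped at zero; the number of clipped pixels is
#' attached as attribute `n_clipped`.
#'
#' @param stack A `timelapse_stack`.
#' @param mixing_matrix Square invertible matrix, `M[i, j]` = contribution
#'   of fluorophore `j` to recorded channel `i`.
#' @return Unmixed `timelapse_stack`.
#' @export
unmix_channels <- function(stack, mixing_matrix) {
  stopifnot(inherits(stack, "timelapse_stack"))
  d <- dim(stack$pixels)
  m <- as.matrix(mixing_matrix)
  if (nrow(m) != ncol(m) || nrow(m) != d[3])
    stop("mixing matrix must be square with one row per channel")
  if (abs(det(m)) < 1e-12) stop("mixing matrix is singular")
  inv <- solve(m)
  px <- stack$pixels
  flat <- matrix(aperm(px, c(3, 1, 2, 4, 5)), nrow = d[3])
  un <- inv %*% flat
  n_clip <- sum(un < 0)
  un[un < 0] <- 0
  px <- aperm(array(un, dim = d[c(3, 1, 2, 4, 5)]), c(2, 3, 1, 4, 5))
  out <- stack
  out$pixels <- px
  attr(out, "n_clipped") <- n_clip
  out
}

#' Per-time-point punctum counts from independent segmentation
#'
#' Detects puncta independently at every time point (no tracking) and
#' reports counts plus percent change relative to the last pre-inducer time
#' point.
#'
#' @param stack A `timelapse_stack` with `t_inducer` set.
#' @param channel Channel index or label.
#' @param ... Passed to [detect_puncta()].
#' @return data.frame with `time`, `count`, `pct_change` (NA when the
#'   reference count is zero).
#' @export
segment_and_count <- function(stack, channel = 1, ...) {
  stopifnot(inherits(stack, "timelapse_stack"))
  n_t <- dim(stack$pixels)[1]
  counts <- vapply(seq_len(n_t), function(ti)
    nrow(detect_puncta(max_project(stack, ti, channel), ...)), 0L)
  ref_i <- last_pre_inducer(stack$timestamps, stack$t_inducer)
  ref <- counts[ref_i]
  data.frame(time = stack$timestamps, count = counts,
             pct_change = if (ref > 0) 100 * (counts - ref) / ref
                          else NA_real_)
}

# index of the last time point strictly before the inducer time
last_pre_inducer <- function(times, t_inducer) {
  i <- which(times < t_inducer)
  if (length(i) == 0) stop("no time point precedes the inducer time")
  max(i)
}

#' Quantify tracked synaptic puncta in a culture movie
#'
#' The full per-movie measurement pipeline: detect puncta on the max
#' projection at every time point, track them from the first time point,
#' keep persistent tracks only, place a 9x9 ROI at each tracked centre and
#' record the background-corrected mean at every (punctum, time, channel).
#'
#' Tracks flagged formed, merged or split are always excluded. How absence
#' is treated depends on `disappear_policy`: under `"pre_inducer"` (default)
#' a track is excluded only if it is undetected at a time point before
#' inducer addition -- once degradation is under way a punctum is expected
#' to fall below the detection limit, and its ROI (held at the last tracked
#' position) keeps reporting the near-zero fluorescence that constitutes the
#' measurement. Under `"any"` a single missed detection anywhere excludes
#' the track (the strict persistence rule of [track_puncta()]).
#'
#' @param stack A `timelapse_stack`.
#' @param detect_channel Channel used for detection/tracking.
#' @param search_radius_px Tracking search radius, pixels.
#' @param background_mode Passed to [estimate_background()].
#' @param disappear_policy `"pre_inducer"` or `"any"` (see Details).
#' @param ... Passed to [detect_puncta()].
#' @return A list with `records` (long data.frame: punctum, time, channel,
#'   raw, background, corrected), `tracking` (the [track_puncta()] result)
#'   and `n_persistent`.
#' @export
quantify_culture <- function(stack, detect_channel = 1,
                             search_radius_px = 4,
                             background_mode = "cellfree",
                             disappear_policy = c("pre_inducer", "any"),
                             ...) {
  stopifnot(inherits(stack, "timelapse_stack"))
  disappear_policy <- match.arg(disappear_policy)
  n_t <- dim(stack$pixels)[1]
  projs <- lapply(seq_len(n_t), function(ti)
    max_project(stack, ti, detect_channel))
  dets <- lapply(projs, detect_puncta, ...)
  trk <- track_puncta(dets, search_radius_px = search_radius_px)
  keep <- trk$summary$track[trk$summary$persistent]
  if (disappear_policy == "pre_inducer" && !is.na(stack$t_inducer)) {
    pre_idx <- which(stack$timestamps < stack$t_inducer)
    cand <- trk$summary$track[trk$summary$class == "disappeared"]
    for (tr in cand) {
      st <- trk$tracks$status[trk$tracks$track == tr]
      if (all(st[pre_idx] == "present") && st[1] == "present")
        keep <- c(keep, tr)
    }
    keep <- sort(keep)
  }
  if (length(keep) == 0) stop("no tracks survive the persistence filter")
  recs <- list()
  for (ci in seq_along(stack$channels)) {
    # cell-free region fixed at the reference frame, reused at every frame
    ref_img <- if (ci == detect_channel) projs[[1]]
               else max_project(stack, 1, ci)
    mask <- if (background_mode == "cellfree") cellfree_mask(ref_img)
    for (ti in seq_len(n_t)) {
      img <- if (ci == detect_channel) projs[[ti]]
             else max_project(stack, ti, ci)
      bg <- if (background_mode == "cellfree") mean(img[mask])
            else estimate_background(img, mode = background_mode)
      tt <- trk$tracks[trk$tracks$time_index == ti &
                         trk$tracks$track %in% keep, ]
      if (nrow(tt) == 0) next
      raw <- vapply(seq_len(nrow(tt)), function(i)
        measure_roi(img, roi(c(tt$row[i], tt$col[i]), "synapse")), 0)
      recs[[length(recs) + 1]] <- data.frame(
        punctum = tt$track, time = stack$timestamps[ti],
        channel = stack$channels[ci], raw = raw, background = bg,
        corrected = raw - bg)
    }
  }
  records <- do.call(rbind, recs)
  records <- records[order(records$punctum, records$channel,
                           records$time), ]
  rownames(records) <- NULL
  list(records = records, tracking = trk, n_persistent = length(keep))
}
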