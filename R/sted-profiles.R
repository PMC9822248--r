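# Images are numeric matrices indexed [x, y] (EBImage convention); pixel (i, j)
# sits at nm coordinates ((i-1) * pixel_size, (j-1) * pixel_size).

# vectorized bilinear interpolation at continuous 1-based pixel coordinates
bilinear <- function(img, x, y) {
  nx <- nrow(img); ny <- ncol(img)
  if (any(x < 1 | x > nx | y < 1 | y > ny))
    stop("sampling rectangle exits the image", call. = FALSE)
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(x0, y0); i10 <- cbind(x0 + 1L, y0)
  i01 <- cbind(x0, y0 + 1L); i11 <- cbind(x0 + 1L, y0 + 1L)
  img[i00] * (1 - fx) * (1 - fy) + img[i10] * fx * (1 - fy) +
    img[i01] * (1 - fx) * fy + img[i11] * fx * fy
}

weighted_centroid <- function(img) {
  w <- pmax(img, 0); s <- sum(w)
  if (s == 0) return(c((nrow(img) + 1) / 2, (ncol(img) + 1) / 2))
  c(sum(row(img) * w), sum(col(img) * w)) / s
}

#' Fit an ellipse to a PSD mask
#'
#' Determines the center (intensity-weighted centroid) and orientation
#' (major-axis angle from the second image moments) of an elongated
#' postsynaptic-density mask, the reference frame for perpendicular line
#' profiles.
#'
#' @param mask logical/0-1 matrix marking the PSD region.
#' @param intensity optional intensity image used to weight the moments;
#'   unweighted moments otherwise.
#' @param pixel_size nm per pixel, carried into the ROI.
#' @param min_elongation minimum major/minor axis ratio; a near-circular mask
#'   has no usable orientation and is an error.
#' @return list of class `sideview_roi`: `center` (pixels), `orientation`
#'   (degrees in `[0, 180)`), `axis_ratio`, `pixel_size`, `mask`.
#' @export
fit_psd_ellipse <- function(mask, intensity = NULL, pixel_size = 11.4,
                            min_elongation = 1.3) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask", call. = FALSE)
  w <- if (is.null(intensity)) rep(1, nrow(idx)) else pmax(intensity[idx], 0)
  if (sum(w) == 0) stop("mask has zero total weight", call. = FALSE)
  cx <- sum(idx[, 1] * w) / sum(w); cy <- sum(idx[, 2] * w) / sum(w)
  dx <- idx[, 1] - cx; dy <- idx[, 2] - cy
  # second central moments (+1/12 pixel variance so a 1-px-wide mask is valid)
  sxx <- sum(w * dx^2) / sum(w) + 1 / 12
  syy <- sum(w * dy^2) / sum(w) + 1 / 12
  sxy <- sum(w * dx * dy) / sum(w)
  e <- eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2), symmetric = TRUE)
  ratio <- sqrt(e$values[1] / max(e$values[2], .Machine$double.eps))
  if (ratio < min_elongation)
    stop(sprintf("mask is too round (axis ratio %.2f): orientation ambiguous", ratio),
         call. = FALSE)
  ang <- atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi
  ang <- ang %% 180
  structure(list(center = c(x = cx, y = cy), orientation = ang,
                 axis_ratio = ratio, pixel_size = pixel_size, mask = mask),
            class = "sideview_roi")
}

#' Extract perpendicular line profiles across a side-view synapse
#'
#' Samples a rectangle (default ~1200 nm long, 200 nm wide) perpendicular to
#' the PSD ellipse's major axis through its center. Intensities are averaged
#' across the rectangle's width at each position along its long axis, sampled
#' at the pixel pitch with bilinear interpolation. Negative positions are
#' presynaptic: the axis sign is chosen so the vesicle-channel centroid lies
#' on the negative side.
#'
#' @param channels list of image matrices, ordered (vesicle marker, PSD,
#'   test protein).
#' @param roi a [fit_psd_ellipse()] result.
#' @param length_nm,width_nm rectangle dimensions (nm).
#' @param vesicle_channel index of the vesicle-marker channel.
#' @return list of class `line_profiles`: `positions` (nm, strictly
#'   increasing), `intensities` (positions x channels matrix), `roi`,
#'   `pixel_size`.
#' @export
extract_profile <- function(channels, roi, length_nm = 1200, width_nm = 200,
                            vesicle_channel = 1) {
  stopifnot(inherits(roi, "sideview_roi"))
  if (!is.list(channels)) channels <- list(channels)
  px <- roi$pixel_size
  th <- roi$orientation * pi / 180
  u <- c(cos(th), sin(th))        # along the PSD band
  v <- c(-sin(th), cos(th))       # trans-synaptic axis
  ves_c <- weighted_centroid(channels[[vesicle_channel]])
  if (sum((ves_c - roi$center) * v) > 0) v <- -v  # vesicle side = negative

  positions <- seq(-length_nm / 2, length_nm / 2, by = px)
  offsets <- seq(-width_nm / 2, width_nm / 2, by = px)
  # sample grid: one row per position, one column per width offset
  sx <- roi$center[1] + outer(positions, offsets * 0, "+") / px * v[1] +
    outer(positions * 0, offsets, "+") / px * u[1]
  sy <- roi$center[2] + outer(positions, offsets * 0, "+") / px * v[2] +
    outer(positions * 0, offsets, "+") / px * u[2]
  intens <- vapply(channels, function(ch)
    rowMeans(matrix(bilinear(ch, as.vector(sx), as.vector(sy)), nrow = length(positions))),
    numeric(length(positions)))
  structure(list(positions = positions, intensities = intens, roi = roi,
                 pixel_size = px),
            class = "line_profiles")
}

# centered moving average with shrinking window at the edges
moving_average <- function(x, k = 5) {
  h <- (k - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - h):min(n, i + h)]), numeric(1))
}

#' Align line profiles to the smoothed PSD peak
#'
#' The PSD channel of each profile is smoothed with a centered 5-sample moving
#' average; the peak of the smoothed signal defines position 0, and all
#' channels (vesicle marker, test protein, and the smoothed PSD) are shifted
#' accordingly, cropped to the reporting axis (default -400 nm presynaptic to
#' +200 nm postsynaptic) and averaged across synapses. Peak values per profile
#' are taken independent of peak position (maximum over the reported axis);
#' non-PSD channels stay unsmoothed. Ties in the smoothed peak are broken
#' toward the position closest to 0.
#'
#' @param profiles a `line_profiles` object or list of them (common axis).
#' @param smoothing moving-average length in samples (pixels).
#' @param psd_channel index of the PSD channel.
#' @param crop reported axis range (nm).
#' @return list of class `line_profile_set`: `axis` (nm), `profiles` (array
#'   synapse x position x channel, NA where a shifted profile does not cover
#'   the axis), `mean` and `sem` (position x channel), `peak_values`
#'   (synapse x channel), `peak_shift_px` (per synapse), `edge_peak` (logical
#'   per synapse: smoothed PSD peak sat at the extraction-window edge),
#'   `smoothing`, `psd_channel`.
#' @export
align_profiles <- function(profiles, smoothing = 5, psd_channel = 2,
                           crop = c(-400, 200)) {
  if (inherits(profiles, "line_profiles")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1)
  px <- profiles[[1]]$pixel_size
  pos <- profiles[[1]]$positions
  axis <- seq(ceiling(crop[1] / px) * px, floor(crop[2] / px) * px, by = px)
  n_ch <- ncol(profiles[[1]]$intensities)
  out <- array(NA_real_, c(length(profiles), length(axis), n_ch))
  peak_shift <- integer(length(profiles))
  edge_peak <- logical(length(profiles))

  for (s in seq_along(profiles)) {
    p <- profiles[[s]]
    stopifnot(length(p$positions) == length(pos))
    ints <- p$intensities
    sm <- moving_average(ints[, psd_channel], smoothing)
    mx <- max(sm)
    cand <- which(sm == mx)
    ipk <- cand[which.min(abs(pos[cand]))]  # tie-break toward 0
    edge_peak[s] <- ipk == 1 || ipk == length(pos)
    peak_shift[s] <- ipk - which.min(abs(pos))
    ints[, psd_channel] <- sm  # the aligned PSD channel is the smoothed one
    shifted <- pos - pos[ipk]
    j <- match(round(axis / px), round(shifted / px))
    ok <- !is.na(j)
    out[s, ok, ] <- ints[j[ok], ]
  }
  mean_prof <- apply(out, c(2, 3), function(v) mean(v, na.rm = TRUE))
  sem_prof <- apply(out, c(2, 3), function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  })
  peaks <- apply(out, c(1, 3), function(v) max(v, na.rm = TRUE))
  structure(list(axis = axis, profiles = out, mean = mean_prof,
                 sem = sem_prof, peak_values = peaks,
                 peak_shift_px = peak_shift, edge_peak = edge_peak,
                 smoothing = smoothing, psd_channel = psd_channel,
                 pixel_size = px, n = length(profiles)),
            class = "line_profile_set")
}

#' Peak value of a line profile, independent of peak position
#'
#' @param profile numeric intensity profile.
#' @return the maximum intensity, wherever it occurs.
#' @export
profile_peak <- function(profile) {
  if (!length(profile)) stop("empty profile", call. = FALSE)
  max(profile, na.rm = TRUE)
}

#' Axis position of a channel's peak on an aligned profile set
#'
#' Convenience accessor: for each synapse, the axis position (nm) where the
#' stated channel of the aligned profile is maximal.
#'
#' @param set a `line_profile_set`.
#' @param channel channel index.
#' @return numeric vector of peak positions (nm), one per synapse.
#' @export
aligned_peak_positions <- function(set, channel = 3) {
  stopifnot(inherits(set, "line_profile_set"))
  vapply(seq_len(dim(set$profiles)[1]), function(s) {
    v <- set$profiles[s, , channel]
    set$axis[which.max(v)]
  }, numeric(1))
}
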