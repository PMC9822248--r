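#' Simulate a three-channel side-view synapse image
#'
#' Renders the geometry that side-view selection relies on: an elongated PSD
#' band (anisotropic Gaussian ridge), an isotropic vesicle cloud centered on
#' the presynaptic side of the band, and a test-protein ridge offset along the
#' trans-synaptic axis (negative offsets = presynaptic, as for active-zone
#' proteins, which peak around -70 to -20 nm from the PSD). Detector-like
#' additive Gaussian noise and a constant background complete the image.
#' Channels are ordered (vesicle marker, PSD, test protein).
#'
#' @param pixel_size nm per pixel (the acquisition convention is 11.4).
#' @param image_size image side in pixels (square).
#' @param psd_length,psd_width PSD band FWHM along/across its axis (nm).
#' @param psd_orientation band major-axis angle (degrees).
#' @param psd_center band center in pixels; default image center.
#' @param vesicle_cloud_sigma vesicle cloud Gaussian sigma (nm).
#' @param vesicle_distance distance of the cloud center from the PSD center
#'   along the presynaptic direction (nm).
#' @param test_peak_offset signed trans-synaptic offset of the test-protein
#'   ridge (nm; negative = presynaptic). Default -45, the midpoint of the
#'   typical active-zone peak region.
#' @param test_width test-protein ridge FWHM across the axis (nm).
#' @param channel_amplitudes peak intensities (a.u.) for (vesicle, psd, test).
#' @param background_level,noise_sd background offset and Gaussian noise SD.
#' @param seed integer seed; deterministic given the seed.
#' @return list of class `sideview_image`: `channels` (list of matrices),
#'   `pixel_size`, and `ground_truth` (center, orientation, offsets,
#'   amplitudes, and the noise-free PSD half-maximum `psd_mask` standing in
#'   for a manually drawn ROI).
#' @export
simulate_sideview_image <- function(pixel_size = 11.4, image_size = 256,
                                    psd_length = 300, psd_width = 80,
                                    psd_orientation = 90, psd_center = NULL,
                                    vesicle_cloud_sigma = 150,
                                    vesicle_distance = 150,
                                    test_peak_offset = -45, test_width = 90,
                                    channel_amplitudes = c(vesicle = 150,
                                                           psd = 200,
                                                           test = 120),
                                    background_level = 10, noise_sd = 5,
                                    seed = NULL) {
  if (pixel_size <= 0) stop("`pixel_size` must be > 0", call. = FALSE)
  stop_if_negative(noise_sd, "noise_sd")
  n <- image_size
  if (is.null(psd_center)) psd_center <- c(n / 2, n / 2)
  half_extent_nm <- (max(psd_length, psd_width) / 2 + 3 * pixel_size)
  if (any(psd_center * pixel_size - half_extent_nm < 0) ||
      any(psd_center * pixel_size + half_extent_nm > (n - 1) * pixel_size))
    stop("PSD does not fit inside the image", call. = FALSE)

  th <- psd_orientation * pi / 180
  xs <- ((1:n) - 1) * pixel_size
  cx <- (psd_center[1] - 1) * pixel_size
  cy <- (psd_center[2] - 1) * pixel_size
  dx <- matrix(xs - cx, n, n)          # varies along rows (x)
  dy <- matrix(xs - cy, n, n, byrow = TRUE)
  u <- dx * cos(th) + dy * sin(th)     # along the band
  w <- -dx * sin(th) + dy * cos(th)    # trans-synaptic; presynaptic = negative

  fwhm2sig <- function(f) f / (2 * sqrt(2 * log(2)))
  s_along <- fwhm2sig(psd_length); s_across <- fwhm2sig(psd_width)
  s_test <- fwhm2sig(test_width)
  a <- channel_amplitudes
  psd <- a[[2]] * exp(-u^2 / (2 * s_along^2) - w^2 / (2 * s_across^2))
  ves <- a[[1]] * exp(-(u^2 + (w + vesicle_distance)^2) /
                        (2 * vesicle_cloud_sigma^2))
  tst <- a[[3]] * exp(-u^2 / (2 * s_along^2) -
                        (w - test_peak_offset)^2 / (2 * s_test^2))
  mask <- psd >= 0.5 * max(psd)

  with_seed_or_current(seed, {
    noisy <- lapply(list(vesicle = ves, psd = psd, test = tst), function(ch) {
      ch <- ch + background_level
      if (noise_sd > 0) ch <- ch + matrix(rnorm(n * n, 0, noise_sd), n, n)
      ch
    })
    structure(list(channels = noisy, pixel_size = pixel_size,
                   ground_truth = list(center = psd_center,
                                       orientation = psd_orientation %% 180,
                                       test_peak_offset = test_peak_offset,
                                       vesicle_distance = vesicle_distance,
                                       amplitudes = a,
                                       background_level = background_level,
                                       noise_sd = noise_sd,
                                       psd_mask = mask)),
              class = "sideview_image")
  })
}

#' Simulate a field of fluorescence puncta
#'
#' Places `n_puncta` Gaussian spots (sigma = radius / 2) with centers at least
#' `min_separation` apart (rejection sampling with a bounded number of
#' retries), over a constant background with additive Gaussian noise.
#'
#' @param n_puncta number of puncta (>= 0).
#' @param radius_range punctum radius range (nm), sampled uniformly.
#' @param intensity_range peak intensity range (a.u.), sampled uniformly.
#' @param background_level,noise_sd background offset and noise SD (a.u.).
#' @param min_separation minimum center-to-center distance (nm).
#' @param image_size image side (pixels); `pixel_size` nm per pixel.
#' @param pixel_size nm per pixel.
#' @param margin_nm keep-out border so spots lie fully inside the image.
#' @param max_tries placement attempts before giving up.
#' @param seed integer seed.
#' @return list of class `puncta_field`: `image` (matrix), `pixel_size`,
#'   `ground_truth` data frame (`x`, `y` in pixels, `radius_nm`,
#'   `intensity`).
#' @export
simulate_puncta_field <- function(n_puncta = 50, radius_range = c(80, 150),
                                  intensity_range = c(100, 200),
                                  background_level = 10, noise_sd = 5,
                                  min_separation = 350, image_size = 512,
                                  pixel_size = 11.4, margin_nm = 400,
                                  max_tries = 200 * max(n_puncta, 1),
                                  seed = NULL) {
  stop_if_not_count(n_puncta, "n_puncta", min = 0L)
  stop_if_negative(min_separation, "min_separation")
  stop_if_negative(noise_sd, "noise_sd")
  n <- image_size
  extent <- (n - 1) * pixel_size
  if (n_puncta > 0 && 2 * margin_nm >= extent)
    stop(sprintf("could not place %d puncta: image extent %g nm is smaller than twice the margin",
                 n_puncta, extent), call. = FALSE)

  with_seed_or_current(seed, {
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(centers) < n_puncta) {
      if (tries >= max_tries)
        stop(sprintf("could not place %d puncta at min_separation %g nm in %d tries",
                     n_puncta, min_separation, max_tries), call. = FALSE)
      cand <- runif(2, margin_nm, extent - margin_nm)
      ok <- !nrow(centers) ||
        min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= min_separation
      if (ok) centers <- rbind(centers, cand)
      tries <- tries + 1
    }
    radii <- if (n_puncta) runif(n_puncta, radius_range[1], radius_range[2]) else numeric(0)
    amps <- if (n_puncta) runif(n_puncta, intensity_range[1], intensity_range[2]) else numeric(0)

    img <- matrix(background_level, n, n)
    xs <- ((1:n) - 1) * pixel_size
    for (k in seq_len(n_puncta)) {
      sig <- radii[k] / 2
      # render on a local window (4 sigma) for speed
      ix <- which(abs(xs - centers[k, 1]) <= 4 * sig)
      iy <- which(abs(xs - centers[k, 2]) <= 4 * sig)
      g <- outer(exp(-(xs[ix] - centers[k, 1])^2 / (2 * sig^2)),
                 exp(-(xs[iy] - centers[k, 2])^2 / (2 * sig^2)))
      img[ix, iy] <- img[ix, iy] + amps[k] * g
    }
    if (noise_sd > 0) img <- img + matrix(rnorm(n * n, 0, noise_sd), n, n)
    gt <- data.frame(x = centers[, 1] / pixel_size + 1,
                     y = centers[, 2] / pixel_size + 1,
                     radius_nm = radii, intensity = amps)
    structure(list(image = img, pixel_size = pixel_size, ground_truth = gt),
              class = "puncta_field")
  })
}
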