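# merge 4-connected components that touch diagonally, giving 8-connectivity
merge_diagonal_labels <- function(labels) {
  nx <- nrow(labels); ny <- ncol(labels)
  pairs <- rbind(
    cbind(as.vector(labels[-nx, -ny]), as.vector(labels[-1, -1])),
    cbind(as.vector(labels[-1, -ny]), as.vector(labels[-nx, -1])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (!nrow(pairs)) return(labels)
  n_lab <- max(labels)
  parent <- seq_len(n_lab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n_lab), find, integer(1))
  remap <- match(root, sort(unique(root)))
  out <- labels
  out[out > 0] <- remap[out[out > 0]]
  out
}

#' Automatic two-dimensional puncta segmentation
#'
#' Thresholds the raw image (no background subtraction) at
#' `median + k x robust SD` (median absolute deviation scaled to the normal),
#' labels connected components (8-connectivity by default), filters them by
#' area, and quantifies each object's intensity-weighted centroid, pixel area
#' (nm^2 via the pixel size) and mean intensity. Deterministic: identical
#' image and parameters give identical objects.
#'
#' @param image single-channel numeric matrix.
#' @param pixel_size nm per pixel.
#' @param k threshold multiplier in robust-SD units.
#' @param min_area,max_area object area limits in pixels.
#' @param connectivity 8 (default) or 4.
#' @param threshold absolute intensity threshold overriding the automatic one.
#' @return list of class `segmentation_result`: `objects` data frame (`id`,
#'   `x`, `y` centroid in pixels, `area_px`, `area_nm2`, `mean_intensity`),
#'   `labels` (labelled matrix, 0 = background), `n_objects`,
#'   `density_per_image`, `density_per_um2`, `image_area_um2`, `threshold`,
#'   `params`. A constant image yields zero objects, not an error.
#' @export
segment_puncta <- function(image, pixel_size = 11.4, k = 4,
                           min_area = 4, max_area = Inf, connectivity = 8,
                           threshold = NULL) {
  stopifnot(is.matrix(image))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8", call. = FALSE)
  if (is.null(threshold)) threshold <- median(image) + k * mad(image)
  mask <- image > threshold
  labels <- EBImage::bwlabel(mask)
  labels <- matrix(as.integer(round(labels)), nrow(image), ncol(image))
  if (connectivity == 8 && max(labels) > 1)
    labels <- merge_diagonal_labels(labels)

  objects <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                        area_px = integer(0), area_nm2 = numeric(0),
                        mean_intensity = numeric(0))
  if (max(labels) > 0) {
    sizes <- tabulate(labels[labels > 0])
    keep <- which(sizes >= min_area & sizes <= max_area)
    if (length(keep)) {
      idx <- which(labels > 0)
      lab <- labels[idx]
      sel <- lab %in% keep
      idx <- idx[sel]; lab <- lab[sel]
      xi <- (idx - 1) %% nrow(image) + 1
      yi <- (idx - 1) %/% nrow(image) + 1
      wt <- image[idx]
      sw <- tapply(wt, lab, sum)
      objects <- data.frame(
        id = seq_along(keep),
        x = as.numeric(tapply(wt * xi, lab, sum) / sw),
        y = as.numeric(tapply(wt * yi, lab, sum) / sw),
        area_px = as.integer(sizes[keep]),
        area_nm2 = sizes[keep] * pixel_size^2,
        mean_intensity = as.numeric(tapply(wt, lab, mean)))
      # relabel kept objects 1..n, drop the rest
      new_lab <- integer(max(labels))
      new_lab[keep] <- seq_along(keep)
      labels[labels > 0] <- new_lab[labels[labels > 0]]
    } else {
      labels[] <- 0L
    }
  }
  image_area_um2 <- prod(dim(image)) * (pixel_size / 1000)^2
  structure(list(objects = objects, labels = labels,
                 n_objects = nrow(objects),
                 density_per_image = nrow(objects),
                 density_per_um2 = nrow(objects) / image_area_um2,
                 image_area_um2 = image_area_um2,
                 threshold = threshold,
                 params = list(pixel_size = pixel_size, k = k,
                               min_area = min_area, max_area = max_area,
                               connectivity = connectivity)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d objects over %.2f um^2 (%.3g / um^2), threshold %.4g\n",
              x$n_objects, x$image_area_um2, x$density_per_um2, x$threshold))
  invisible(x)
}

#' Summary statistics over one or several segmentation results
#'
#' Density is reported per image (and per um^2 as auxiliary); intensity and
#' area are per-object means. With zero objects the means are `NA`.
#'
#' @param results a `segmentation_result` or list of them (e.g. one per
#'   image of a condition).
#' @return list: `n_images`, `n_objects`, `density_per_image`,
#'   `density_per_um2`, `mean_intensity`, `mean_area_nm2`.
#' @export
puncta_statistics <- function(results) {
  if (inherits(results, "segmentation_result")) results <- list(results)
  objs <- do.call(rbind, lapply(results, `[[`, "objects"))
  n_img <- length(results)
  n_obj <- if (is.null(objs)) 0L else nrow(objs)
  list(n_images = n_img, n_objects = n_obj,
       density_per_image = n_obj / n_img,
       density_per_um2 = n_obj / sum(vapply(results, `[[`, numeric(1), "image_area_um2")),
       mean_intensity = if (n_obj) mean(objs$mean_intensity) else NA_real_,
       mean_area_nm2 = if (n_obj) mean(objs$area_nm2) else NA_real_)
}

#' Colocalization filter by fractional pixel overlap
#'
#' Retains an object of set A iff the fraction of its pixels shared with the
#' union of set B's objects strictly exceeds `threshold`. At the conventional
#' threshold of 0, any shared pixel retains the object; at `threshold = 1`
#' only objects fully inside B are retained. Output is always a subset of the
#' input, and the filter is idempotent.
#'
#' @param a,b `segmentation_result` objects on the same pixel grid.
#' @param threshold overlap fraction in `[0, 1]`.
#' @return a `segmentation_result` with the retained subset of `a` (objects
#'   keep their ids; `overlap_fraction` column added).
#' @export
filter_by_overlap <- function(a, b, threshold = 0) {
  stopifnot(inherits(a, "segmentation_result"), inherits(b, "segmentation_result"))
  if (!all(dim(a$labels) == dim(b$labels)))
    stop("object sets are not on a common pixel grid", call. = FALSE)
  in_b <- b$labels > 0
  frac <- vapply(a$objects$id, function(id) {
    pix <- a$labels == id
    sum(in_b & pix) / sum(pix)
  }, numeric(1))
  keep <- if (threshold >= 1) frac >= 1 else frac > threshold
  out <- a
  out$objects <- a$objects[keep, , drop = FALSE]
  out$objects$overlap_fraction <- frac[keep]
  out$labels[!(a$labels %in% out$objects$id)] <- 0L
  out$n_objects <- nrow(out$objects)
  out$density_per_image <- out$n_objects
  out$density_per_um2 <- out$n_objects / out$image_area_um2
  out$params$overlap_threshold <- threshold
  out
}

#' Match detected objects to ground-truth centers
#'
#' Greedy nearest-neighbor matching within `max_dist` pixels: the closest
#' detection-truth pair is matched first, then removed, until no pair is
#' within range. Reports precision, recall and the mean centroid error of
#' matched pairs.
#'
#' @param detected data frame with columns `x`, `y` (e.g.
#'   `segmentation_result$objects`).
#' @param truth data frame with columns `x`, `y` (ground-truth centers).
#' @param max_dist maximum matching distance (pixels).
#' @return list: `matches` (data frame `detected`, `truth`, `dist`),
#'   `precision`, `recall`, `mean_centroid_error`.
#' @export
match_objects <- function(detected, truth, max_dist = 3) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (!nd || !nt) {
    return(list(matches = data.frame(detected = integer(0), truth = integer(0),
                                     dist = numeric(0)),
                precision = if (nd) 0 else NA_real_,
                recall = if (nt) 0 else NA_real_,
                mean_centroid_error = NA_real_))
  }
  d <- outer(detected$x, truth$x, "-")^2 + outer(detected$y, truth$y, "-")^2
  d <- sqrt(d)
  matches <- data.frame(detected = integer(0), truth = integer(0), dist = numeric(0))
  while (TRUE) {
    mi <- which.min(d)
    if (!length(mi) || d[mi] > max_dist) break
    i <- (mi - 1) %% nd + 1; j <- (mi - 1) %/% nd + 1
    matches <- rbind(matches, data.frame(detected = i, truth = j, dist = d[mi]))
    d[i, ] <- Inf; d[, j] <- Inf
    if (all(!is.finite(d))) break
  }
  list(matches = matches,
       precision = nrow(matches) / nd,
       recall = nrow(matches) / nt,
       mean_centroid_error = if (nrow(matches)) mean(matches$dist) else NA_real_)
}
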