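#' Detection parameters
#'
#' Tuning knobs for ommatidium detection. `expected_radius = NULL` (the
#' default) triggers auto-estimation from the median equivalent radius of
#' connected components after a provisional Otsu threshold, followed by one
#' re-run of the enhancement chain with the estimate.
#'
#' @param expected_radius Approximate facet radius in pixels (> 1), or `NULL`
#'   to auto-estimate.
#' @param min_separation_factor Fraction of the estimated lattice spacing
#'   below which two candidate centers merge (non-maximum suppression radius),
#'   in `(0, 1)`.
#' @param flatten_sigma_factor Bright-field illumination flattening: the image
#'   is divided by a Gaussian-blurred copy at
#'   `sigma = flatten_sigma_factor * expected_radius` before the top-hat.
#'   Set to 0 to disable.
#' @param mask_enabled Restrict detections to the convex hull of the largest
#'   connected foreground region (drops stray background blobs).
#' @return A `detection_params` list.
#' @export
detection_params <- function(expected_radius = NULL,
                             min_separation_factor = 0.5,
                             flatten_sigma_factor = 4,
                             mask_enabled = TRUE) {
  if (!is.null(expected_radius)) {
    check_number(expected_radius, "expected_radius", min = 1, strict_min = TRUE)
  }
  check_number(min_separation_factor, "min_separation_factor",
               min = 0, max = 1, strict_min = TRUE, strict_max = TRUE)
  check_number(flatten_sigma_factor, "flatten_sigma_factor", min = 0)
  structure(
    list(expected_radius = expected_radius,
         min_separation_factor = min_separation_factor,
         flatten_sigma_factor = flatten_sigma_factor,
         mask_enabled = isTRUE(mask_enabled)),
    class = "detection_params"
  )
}

# provisional facet-radius estimate: Otsu on the raw grid, median equivalent
# radius sqrt(area / pi) of connected components with area >= 9 px
estimate_radius <- function(image) {
  px <- image$pixels
  thr <- EBImage::otsu(as_eb(px), range = c(0, 1))
  bw <- px > thr
  if (!any(bw)) {
    stop_ommatidia("too few ommatidia: no foreground found while estimating facet radius",
                   class = "too_few")
  }
  lab <- EBImage::bwlabel(as_eb(bw * 1))
  areas <- tabulate(as.integer(EBImage::imageData(lab)))
  areas <- areas[areas >= 9]
  if (length(areas) == 0) {
    stop_ommatidia("too few ommatidia: no components large enough to estimate facet radius",
                   class = "too_few")
  }
  r <- median(sqrt(areas / pi))
  min(max(r, 2), min(image$height, image$width) / 8)
}

#' Enhance an eye image for detection
#'
#' Turns ommatidial facets into bright blobs on a near-zero background.
#' Bright-field chain: divisive illumination flattening (image over its
#' large-sigma Gaussian blur), morphological white top-hat with a disk
#' structuring element of radius `1.5 * expected_radius`, then Gaussian
#' smoothing at `expected_radius / 2` so each facet peaks at its center.
#' SEM chain: a difference-of-Gaussians band-pass (sigmas `expected_radius`
#' and `3 * expected_radius`, negative lobe clipped) replaces the flattening,
#' followed by the same top-hat and smoothing. The result is rescaled to
#' `[0, 1]`; an all-flat field maps to all zeros.
#'
#' @param image An [as_eye_image()] object.
#' @param params [detection_params()]; `expected_radius` is auto-estimated
#'   when `NULL`.
#' @return Numeric matrix in `[0, 1]`, same size as the input.
#' @export
preprocess_eye <- function(image, params = detection_params()) {
  r <- params$expected_radius %||% estimate_radius(image)
  px <- image$pixels
  if (image$modality == "sem") {
    lo <- gblur_safe(px, sigma = r)
    hi <- gblur_safe(px, sigma = 3 * r)
    x <- pmax(lo - hi, 0)
  } else if (params$flatten_sigma_factor > 0) {
    bgr <- gblur_safe(px, sigma = params$flatten_sigma_factor * r)
    x <- px / (bgr + 0.05)
  } else {
    x <- px
  }
  th <- from_eb(EBImage::whiteTopHat(as_eb(x), disc_brush(1.5 * r)))
  sm <- pmax(gblur_safe(th, sigma = max(1, r / 2)), 0)
  m <- max(sm)
  if (m < 1e-12) return(matrix(0, nrow(sm), ncol(sm)))  # flat-field floor
  clamp01(sm / m)
}

# measurement grid for sub-pixel refinement: the plain white top-hat of the
# (band-passed, for SEM) image, with no equalization or smoothing. Divisive
# flattening and Gaussian smoothing help thresholding but tilt blob profiles
# slightly; the bare top-hat keeps each facet's intensity profile symmetric
# about its true center, which matters for centroid accuracy.
measurement_grid <- function(image, r) {
  px <- image$pixels
  if (image$modality == "sem") {
    px <- pmax(gblur_safe(px, sigma = r) - gblur_safe(px, sigma = 3 * r), 0)
  }
  pmax(from_eb(EBImage::whiteTopHat(as_eb(px), disc_brush(1.5 * r))), 0)
}

# greedy non-maximum suppression: order by response desc, ties by (y, x);
# accept a candidate iff no accepted center lies within `radius`
nms_greedy <- function(x, y, response, radius) {
  ord <- order(-response, y, x)
  keep <- integer(0)
  r2 <- radius^2
  for (i in ord) {
    if (length(keep) == 0 ||
        all((x[keep] - x[i])^2 + (y[keep] - y[i])^2 >= r2)) {
      keep <- c(keep, i)
    }
  }
  sort(keep)
}

# sub-pixel refinement: iterated Gaussian-weighted intensity centroid around
# (x, y) (0-based). The smooth window avoids the truncation bias of a hard
# circular mask; re-centering the window on each new estimate removes the
# residual asymmetry, converging in a few iterations.
refine_centroid <- function(grid, x, y, radius, iterations = 4) {
  h <- nrow(grid); w <- ncol(grid)
  sigma <- radius / 1.5
  ext <- ceiling(2.5 * sigma)
  for (it in seq_len(iterations)) {
    i0 <- max(1L, floor(y - ext) + 1L); i1 <- min(h, ceiling(y + ext) + 1L)
    j0 <- max(1L, floor(x - ext) + 1L); j1 <- min(w, ceiling(x + ext) + 1L)
    ii <- i0:i1; jj <- j0:j1
    d2 <- outer((ii - 1 - y)^2, (jj - 1 - x)^2, `+`)
    ww <- grid[ii, jj, drop = FALSE] * exp(-d2 / (2 * sigma^2))
    s <- sum(ww)
    if (s <= 0) return(c(x, y))
    x <- sum(ww * rep(jj - 1, each = length(ii))) / s
    y <- sum(ww * rep(ii - 1, times = length(jj))) / s
  }
  c(x, y)
}

#' Detect ommatidium centers in an enhanced grid
#'
#' Thresholds the enhanced grid with Otsu's method, takes local maxima of the
#' foreground distance transform as candidate centers, suppresses candidates
#' closer than `min_separation_factor` times the estimated lattice spacing,
#' refines each surviving center by intensity-weighted centroid within
#' `expected_radius`, and assigns each a radius from the distance transform at
#' its peak. The estimated spacing is the median nearest-neighbor distance
#' among accepted centers. Detections are sorted by (y, x); the whole chain is
#' deterministic.
#'
#' @param enhanced Matrix from [preprocess_eye()].
#' @param params [detection_params()] with a numeric `expected_radius`.
#' @param source_name Carried into the result attributes.
#' @param measure Optional measurement grid for the final centroid refinement
#'   (defaults to `enhanced`); [detect_ommatidia()] passes the bare top-hat
#'   grid, whose facet profiles are symmetric about their true centers.
#' @return A tibble (class `ommatidia_detections`) with columns `x`, `y`
#'   (0-based sub-pixel centers), `radius` and `peak_response`, plus
#'   attributes `estimated_spacing` and `source_name`.
#' @export
detect_centers <- function(enhanced, params = detection_params(),
                           source_name = "image", measure = NULL) {
  measure <- measure %||% enhanced
  r <- params$expected_radius
  if (is.null(r)) {
    stop_ommatidia("`expected_radius` must be set (detect_ommatidia() resolves it automatically)",
                   class = "validation", field = "expected_radius")
  }
  too_few <- function(n) stop_ommatidia(
    sprintf("too few ommatidia: %d found, at least 7 are needed for 6-neighbor fans", n),
    class = "too_few"
  )
  if (max(enhanced) <= 0) too_few(0L)
  thr <- EBImage::otsu(as_eb(clamp01(enhanced)), range = c(0, 1))
  bw <- enhanced > thr
  if (!any(bw)) too_few(0L)

  dm <- from_eb(EBImage::distmap(as_eb(bw * 1)))
  dmax <- from_eb(EBImage::dilate(as_eb(dm), EBImage::makeBrush(3, "box")))
  cand <- which(dm >= dmax & dm > 0, arr.ind = TRUE)
  if (nrow(cand) < 7) too_few(nrow(cand))
  cx <- cand[, 2] - 1; cy <- cand[, 1] - 1
  resp <- dm[cand]

  # eye-region mask: convex hull of the largest blob cluster
  if (params$mask_enabled) {
    inside <- eye_region_mask(bw, r, cx, cy)
    if (sum(inside) >= 7) {
      cx <- cx[inside]; cy <- cy[inside]; resp <- resp[inside]
    }
  }

  # pass 1: merge distance-transform plateaus at the facet-radius scale
  k1 <- nms_greedy(cx, cy, resp, radius = max(2, r))
  cx <- cx[k1]; cy <- cy[k1]; resp <- resp[k1]
  if (length(cx) < 7) too_few(length(cx))
  spacing0 <- median_nn_distance(cx, cy)

  # pass 2: suppression at the lattice scale
  k2 <- nms_greedy(cx, cy, resp, radius = params$min_separation_factor * spacing0)
  cx <- cx[k2]; cy <- cy[k2]; resp <- resp[k2]
  if (length(cx) < 7) too_few(length(cx))

  refined <- vapply(seq_along(cx), function(i) {
    coarse <- refine_centroid(enhanced, cx[i], cy[i], r, iterations = 2)
    refine_centroid(measure, coarse[1], coarse[2], r, iterations = 4)
  }, numeric(2))
  rx <- refined[1, ]; ry <- refined[2, ]
  # refinement can nudge centers together, and the spacing estimate moves as
  # points merge; iterate suppression until the minimum-separation invariant
  # holds against the final spacing estimate
  spacing <- spacing0
  for (pass in 1:3) {
    n_before <- length(rx)
    k3 <- nms_greedy(rx, ry, resp, radius = params$min_separation_factor * spacing)
    rx <- rx[k3]; ry <- ry[k3]; resp <- resp[k3]
    if (length(rx) < 7) too_few(length(rx))
    new_spacing <- median_nn_distance(rx, ry)
    converged <- length(rx) == n_before && new_spacing <= spacing
    spacing <- new_spacing
    if (converged) break
  }

  ord <- order(ry, rx)
  out <- tibble(x = rx[ord], y = ry[ord],
                radius = resp[ord], peak_response = resp[ord])
  attr(out, "estimated_spacing") <- spacing
  attr(out, "source_name") <- source_name
  attr(out, "params") <- params
  class(out) <- c("ommatidia_detections", class(out))
  out
}

# convex hull of the largest connected component after closing the binary
# foreground at roughly one lattice cell; returns logical inclusion for the
# candidate centers (0-based coordinates)
eye_region_mask <- function(bw, r, cx, cy) {
  merged <- EBImage::closing(as_eb(bw * 1), disc_brush(2 * r))
  lab <- EBImage::bwlabel(merged)
  labm <- t(EBImage::imageData(lab))            # [y, x]
  counts <- tabulate(as.integer(labm))
  if (length(counts) == 0) return(rep(TRUE, length(cx)))
  big <- which.max(counts)
  idx <- which(labm == big, arr.ind = TRUE)
  px <- idx[, 2] - 1; py <- idx[, 1] - 1
  hull <- grDevices::chull(px, py)
  bnd <- list(x = px[hull], y = py[hull])
  # pad the hull outward by half a facet so rim centers are not clipped
  mx <- mean(bnd$x); my <- mean(bnd$y)
  sc <- 1 + r / (2 * max(sqrt((bnd$x - mx)^2 + (bnd$y - my)^2)))
  bnd$x <- mx + (bnd$x - mx) * sc
  bnd$y <- my + (bnd$y - my) * sc
  mgcv::in.out(cbind(c(bnd$x, bnd$x[1]), c(bnd$y, bnd$y[1])), cbind(cx, cy))
}

#' Detect ommatidia in an eye image
#'
#' The single detection entry point: resolves `expected_radius` (auto-estimate
#' when unset), runs [preprocess_eye()] and [detect_centers()].
#'
#' @inheritParams preprocess_eye
#' @return See [detect_centers()].
#' @export
#' @examples
#' spec <- eye_spec(image_width = 240, image_height = 280,
#'                  mask_semiaxes = c(90, 110), noise_sigma = 0)
#' img <- render_eye_image(generate_lattice_points(spec), spec)
#' det <- detect_ommatidia(img)
#' nrow(det)
detect_ommatidia <- function(image, params = detection_params()) {
  if (is.null(params$expected_radius)) {
    params$expected_radius <- estimate_radius(image)
  }
  enhanced <- preprocess_eye(image, params)
  detect_centers(enhanced, params, source_name = image$source_name,
                 measure = measurement_grid(image, params$expected_radius))
}
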