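#' Specify a synthetic compound-eye image
#'
#' Collects the parameters of the synthetic eye generator: a hexagonally packed
#' (triangular) lattice of ommatidial centers clipped to an elliptical eye
#' region, with optional positional jitter, random dropout, and pixel noise.
#' The defaults emulate a wild-type bright-field eye micrograph: roughly 400
#' facets at a 20 px center-to-center spacing inside a vertical ellipse.
#'
#' All coordinates are 0-based pixels, origin at the top-left, x rightward and
#' y downward; centers are real-valued (sub-pixel).
#'
#' @param image_width,image_height Image size in pixels.
#' @param lattice_spacing Center-to-center distance in pixels (> 0).
#' @param disk_radius Facet radius in pixels, in `(0, lattice_spacing / 2)`.
#' @param jitter_sigma Standard deviation (pixels) of isotropic Gaussian
#'   positional noise applied independently to each center.
#' @param dropout_fraction Probability in `[0, 1)` that a lattice point is
#'   removed (ommatidium loss).
#' @param mask_semiaxes Length-2 numeric, the x and y semi-axes (pixels) of the
#'   elliptical eye region, centered in the image; must fit inside the bounds.
#' @param background_level,foreground_level Background and facet intensities
#'   in `[0, 1]`.
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise
#'   (intensity units, >= 0).
#' @param modality `"brightfield"` (filled disks) or `"sem"` (shaded domes).
#' @param orientation `"vertical"` (native) or `"horizontal"` (the rendered
#'   image is rotated 90 degrees clockwise).
#' @param seed Integer seed; one RNG stream is consumed in the documented
#'   order dropout draws, then jitter draws, then pixel noise, so downstream
#'   replay oracles are simple.
#' @return A validated `eye_spec` list.
#' @seealso [generate_lattice_points()], [render_eye_image()],
#'   [write_fixture_set()]
#' @export
#' @examples
#' spec <- eye_spec(lattice_spacing = 20, jitter_sigma = 1, seed = 7)
#' truth <- generate_lattice_points(spec)
#' nrow(truth)
eye_spec <- function(image_width = 480, image_height = 560,
                     lattice_spacing = 20, disk_radius = 6,
                     jitter_sigma = 0, dropout_fraction = 0,
                     mask_semiaxes = c(190, 240),
                     background_level = 0.15, foreground_level = 0.85,
                     noise_sigma = 0.01,
                     modality = c("brightfield", "sem"),
                     orientation = c("vertical", "horizontal"),
                     seed = 1L) {
  modality <- match.arg(modality)
  orientation <- match.arg(orientation)
  check_number(image_width, "image_width", min = 8, integer = TRUE)
  check_number(image_height, "image_height", min = 8, integer = TRUE)
  check_number(lattice_spacing, "lattice_spacing", min = 0, strict_min = TRUE)
  check_number(disk_radius, "disk_radius", min = 0, max = lattice_spacing / 2,
               strict_min = TRUE, strict_max = TRUE)
  check_number(jitter_sigma, "jitter_sigma", min = 0)
  check_number(dropout_fraction, "dropout_fraction", min = 0, max = 1,
               strict_max = TRUE)
  if (!is.numeric(mask_semiaxes) || length(mask_semiaxes) != 2L ||
      any(!is.finite(mask_semiaxes)) || any(mask_semiaxes <= 0)) {
    stop_ommatidia("invalid value for field `mask_semiaxes`",
                   class = "validation", field = "mask_semiaxes")
  }
  if (mask_semiaxes[1] > (image_width - 1) / 2 ||
      mask_semiaxes[2] > (image_height - 1) / 2) {
    stop_ommatidia(
      "invalid value for field `mask_semiaxes`: ellipse must fit inside the image bounds",
      class = "validation", field = "mask_semiaxes"
    )
  }
  check_number(background_level, "background_level", min = 0, max = 1)
  check_number(foreground_level, "foreground_level", min = 0, max = 1)
  check_number(noise_sigma, "noise_sigma", min = 0)
  check_number(seed, "seed", integer = TRUE)
  structure(
    list(
      image_width = as.integer(image_width),
      image_height = as.integer(image_height),
      lattice_spacing = lattice_spacing, disk_radius = disk_radius,
      jitter_sigma = jitter_sigma, dropout_fraction = dropout_fraction,
      mask_semiaxes = as.numeric(mask_semiaxes),
      background_level = background_level,
      foreground_level = foreground_level, noise_sigma = noise_sigma,
      modality = modality, orientation = orientation, seed = as.integer(seed)
    ),
    class = "eye_spec"
  )
}

# Lattice coordinates are laid on a 2^-36 px binary grid: with the spacing and
# row pitch quantized to that grid, every lattice coordinate (and hence every
# inter-center offset) is computed exactly in double precision, so all interior
# fans of a jitter-free lattice share bit-identical offset vectors. The grid
# perturbs the geometry by < 2^-37 px, far below the 1e-6 lattice-fidelity
# tolerance.
quantize_grid <- function(v) round(v * 2^36) / 2^36

# Row pitch: the 2^-36-grid value near spacing * sqrt(3) / 2 whose ideal
# hexagonal fan has the smallest floating-point disorder score (typically
# ~1e-12 per fan; an exactly regular hexagon is not representable in binary
# floats, so the floor cannot be exactly zero). Cached per spacing.
.pitch_cache <- new.env(parent = emptyenv())

row_pitch <- function(spacing) {
  key <- sprintf("%.17g", spacing)
  hit <- .pitch_cache[[key]]
  if (!is.null(hit)) return(hit)
  sq <- quantize_grid(spacing)
  base <- round(sq * sqrt(3) / 2 * 2^36)
  cands <- (base + (-40:40)) / 2^36
  floor_odi <- vapply(cands, function(p) {
    fan <- fan_from_offsets(c(sq, sq / 2, -sq / 2, -sq, -sq / 2, sq / 2),
                            c(0, p, p, 0, -p, -p))
    sc <- score_ommatidium(fan$lengths, fan$gaps)
    sc$odi_a + sc$odi_d
  }, numeric(1))
  best <- which(floor_odi == min(floor_odi))
  p <- cands[best[which.min(abs(best - 41L))]]
  .pitch_cache[[key]] <- p
  p
}

#' Generate ground-truth ommatidial centers
#'
#' Lays a triangular lattice (rows parallel to the x-axis, vertical pitch
#' `spacing * sqrt(3) / 2`, alternate rows offset by `spacing / 2`) over the
#' elliptical eye mask, keeps points whose disks fit inside the mask, then
#' applies seeded dropout and Gaussian jitter. Jittered points that leave the
#' mask are discarded so every returned center lies inside the eye region.
#'
#' The seeded RNG stream is consumed in a fixed order — one uniform per
#' interior lattice point (dropout), then two normals per surviving point
#' (x jitter, y jitter) — so tests can replay the draws.
#'
#' @param spec An [eye_spec()].
#' @return A tibble with columns `x`, `y` (0-based pixel coordinates, vertical
#'   orientation convention) and attributes `spacing`, `count`, `n_lattice`
#'   (interior lattice points before dropout) and `n_jitter_draws`.
#' @export
generate_lattice_points <- function(spec) {
  if (!inherits(spec, "eye_spec")) spec <- do.call(eye_spec, as.list(spec))
  w <- spec$image_width; h <- spec$image_height
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  a <- spec$mask_semiaxes[1]; b <- spec$mask_semiaxes[2]
  s <- spec$lattice_spacing
  sq <- quantize_grid(s)
  p <- row_pitch(s)

  kmax <- ceiling(b / p)
  jmax <- ceiling(a / s) + 1L
  ks <- seq.int(-kmax, kmax)
  js <- seq.int(-jmax, jmax)
  pts <- do.call(rbind, lapply(ks, function(k) {
    cbind(x = cx + (js + (k %% 2) / 2) * sq, y = cy + k * p, k = k)
  }))
  # keep points whose disks fit inside the mask (margin of one disk radius)
  am <- a - spec$disk_radius; bm <- b - spec$disk_radius
  if (am <= 0 || bm <= 0) {
    stop_ommatidia("invalid value for field `mask_semiaxes`: smaller than disk_radius",
                   class = "validation", field = "mask_semiaxes")
  }
  inside <- ((pts[, "x"] - cx) / am)^2 + ((pts[, "y"] - cy) / bm)^2 <= 1
  pts <- pts[inside, , drop = FALSE]
  n_lattice <- nrow(pts)

  set.seed(spec$seed)
  u <- runif(n_lattice)
  keep <- u >= spec$dropout_fraction
  pts <- pts[keep, , drop = FALSE]
  n_keep <- nrow(pts)
  z <- rnorm(2L * n_keep)
  x <- pts[, "x"] + spec$jitter_sigma * z[seq(1L, length.out = n_keep, by = 2L)]
  y <- pts[, "y"] + spec$jitter_sigma * z[seq(2L, length.out = n_keep, by = 2L)]
  in_mask <- ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
  x <- x[in_mask]; y <- y[in_mask]

  truth <- tibble(x = x, y = y)
  attr(truth, "spacing") <- s
  attr(truth, "count") <- nrow(truth)
  attr(truth, "n_lattice") <- n_lattice
  attr(truth, "n_jitter_draws") <- 2L * n_keep
  attr(truth, "seed") <- spec$seed
  class(truth) <- c("eye_truth", class(truth))
  truth
}

#' Render a synthetic eye image from ground-truth centers
#'
#' Bright-field modality renders each ommatidium as a filled disk of
#' `disk_radius` at `foreground_level` on `background_level`, with
#' area-coverage anti-aliasing at the rim; SEM modality renders a radially
#' shaded dome (brightest at the center, smooth quadratic falloff to the
#' background at the rim). Additive Gaussian pixel noise of `noise_sigma` is
#' applied and intensities are clipped to `[0, 1]`. For horizontal
#' orientation the vertical rendering is rotated 90 degrees clockwise.
#'
#' When `truth` carries the RNG bookkeeping attributes written by
#' [generate_lattice_points()], the render replays (burns) those draws before
#' drawing pixel noise, so a whole image is a deterministic function of the
#' single seed with the stream consumed in the documented order.
#'
#' @param truth Tibble of centers `x`, `y` (vertical convention), e.g. from
#'   [generate_lattice_points()].
#' @param spec The matching [eye_spec()].
#' @return An [as_eye_image()] object.
#' @export
render_eye_image <- function(truth, spec) {
  if (!inherits(spec, "eye_spec")) spec <- do.call(eye_spec, as.list(spec))
  w <- spec$image_width; h <- spec$image_height
  if (nrow(truth) > 0 &&
      (min(truth$x) < 0 || max(truth$x) > w - 1 ||
       min(truth$y) < 0 || max(truth$y) > h - 1)) {
    stop_ommatidia("truth centers fall outside the image bounds",
                   class = "validation", field = "truth")
  }
  bg <- spec$background_level; fg <- spec$foreground_level
  r <- spec$disk_radius
  px <- matrix(bg, nrow = h, ncol = w)

  for (i in seq_len(nrow(truth))) {
    x0 <- truth$x[i]; y0 <- truth$y[i]
    j0 <- max(1L, floor(x0 - r) ); j1 <- min(w, ceiling(x0 + r) + 2L)
    i0 <- max(1L, floor(y0 - r) ); i1 <- min(h, ceiling(y0 + r) + 2L)
    jj <- j0:j1; ii <- i0:i1
    dx <- (jj - 1) - x0; dy <- (ii - 1) - y0
    d <- sqrt(outer(dy^2, dx^2, `+`))
    if (spec$modality == "brightfield") {
      cov <- clamp01(r + 0.5 - d)          # area-coverage anti-aliasing
      val <- bg + (fg - bg) * cov
    } else {
      dome <- pmax(0, 1 - (d / r)^2)       # shaded dome, brightest at center
      val <- bg + (fg - bg) * dome
    }
    px[ii, jj] <- pmax(px[ii, jj], val)
  }

  set.seed(spec$seed)
  n_unif <- attr(truth, "n_lattice") %||% 0L
  n_norm <- attr(truth, "n_jitter_draws") %||% 0L
  if (n_unif > 0) runif(n_unif)
  if (n_norm > 0) rnorm(n_norm)
  if (spec$noise_sigma > 0) {
    px <- px + spec$noise_sigma * matrix(rnorm(h * w), nrow = h, ncol = w)
  }
  px <- clamp01(px)
  if (spec$orientation == "horizontal") px <- rot90_cw(px)
  as_eye_image(px, modality = spec$modality,
               source_name = sprintf("synthetic_seed%d", spec$seed))
}

#' Write a set of synthetic fixtures to disk
#'
#' Renders each spec, writes the image as an 8-bit grayscale PNG, a sidecar
#' ground-truth table (tab-separated, header `x  y`, vertical-orientation
#' coordinates), and one `manifest.csv` listing filenames, spec fields and
#' center counts.
#'
#' @param specs List of [eye_spec()] objects.
#' @param directory Output directory (created if needed).
#' @return The manifest as a tibble, invisibly.
#' @export
write_fixture_set <- function(specs, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_ommatidia(paste0("cannot create directory: ", directory),
                            class = "io", path = directory)
  }
  rows <- purrr::imap(specs, function(spec, i) {
    if (!inherits(spec, "eye_spec")) spec <- do.call(eye_spec, as.list(spec))
    stem <- sprintf("eye_%03d", i)
    truth <- generate_lattice_points(spec)
    img <- render_eye_image(truth, spec)
    img_file <- file.path(directory, paste0(stem, ".png"))
    truth_file <- file.path(directory, paste0(stem, "_truth.tsv"))
    tryCatch({
      png::writePNG(img$pixels, img_file)
      utils::write.table(truth[, c("x", "y")], truth_file, sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }, error = function(e) {
      stop_ommatidia(paste0("failed to write fixture under: ", directory),
                     class = "io", path = directory, parent = e)
    })
    n_centers <- attr(truth, "count")
    tibble(
      image = basename(img_file), truth = basename(truth_file),
      count = n_centers,
      image_width = spec$image_width, image_height = spec$image_height,
      lattice_spacing = spec$lattice_spacing, disk_radius = spec$disk_radius,
      jitter_sigma = spec$jitter_sigma,
      dropout_fraction = spec$dropout_fraction,
      mask_semiaxis_x = spec$mask_semiaxes[1],
      mask_semiaxis_y = spec$mask_semiaxes[2],
      background_level = spec$background_level,
      foreground_level = spec$foreground_level,
      noise_sigma = spec$noise_sigma, modality = spec$modality,
      orientation = spec$orientation, seed = spec$seed
    )
  })
  manifest <- dplyr::bind_rows(rows)
  if (nrow(manifest) == 0) {
    manifest <- tibble(
      image = character(), truth = character(), count = integer(),
      image_width = integer(), image_height = integer(),
      lattice_spacing = numeric(), disk_radius = numeric(),
      jitter_sigma = numeric(), dropout_fraction = numeric(),
      mask_semiaxis_x = numeric(), mask_semiaxis_y = numeric(),
      background_level = numeric(), foreground_level = numeric(),
      noise_sigma = numeric(), modality = character(),
      orientation = character(), seed = integer()
    )
  }
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
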