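new_eye_analysis <- function(result, scores, fans, detections, spacing, n) {
  structure(
    list(result = result, scores = scores, fans = fans,
         detections = detections, estimated_spacing = spacing, n = n),
    class = "eye_analysis"
  )
}

#' Analyze one eye image
#'
#' The full per-image pipeline: detect ommatidia, build 6-neighbor fans,
#' score each fan, flag stable ommatidia, and aggregate the five per-image
#' statistics (ODI_D, ODI_A, ODI, Z, P).
#'
#' @param image An [as_eye_image()] object (see [load_image()] or
#'   [render_eye_image()]).
#' @param params [detection_params()].
#' @param n Number of most-ordered stable ommatidia aggregated into ODI
#'   (the `-n` count flag; default 200).
#' @param stable_factor Stability threshold, see [classify_stable()].
#' @return An `eye_analysis` object. Use [glance()] for the one-row result
#'   tibble and [tidy()] for the per-ommatidium table.
#' @export
#' @examples
#' spec <- eye_spec(image_width = 240, image_height = 280,
#'                  mask_semiaxes = c(90, 110), noise_sigma = 0)
#' img <- render_eye_image(generate_lattice_points(spec), spec)
#' fit <- analyze_eye(img, n = 50)
#' glance(fit)
analyze_eye <- function(image, params = detection_params(), n = 200,
                        stable_factor = 2) {
  check_number(n, "n", min = 1, integer = TRUE)
  det <- detect_ommatidia(image, params)
  spacing <- attr(det, "estimated_spacing")
  fans <- build_neighbor_fans(det)
  scores <- score_fans(fans)
  scores$stable <- classify_stable(fans, spacing, stable_factor)
  scores$radius <- det$radius
  if (sum(scores$stable) < n) {
    inform(sprintf("%s: only %d stable ommatidia for N = %d; using all of them",
                   image$source_name, sum(scores$stable), n))
  }
  result <- aggregate_scores(scores, n = n, z = nrow(det),
                             source_name = image$source_name)
  new_eye_analysis(result = result, scores = scores, fans = fans,
                   detections = det, spacing = spacing, n = n)
}

#' @export
print.eye_analysis <- function(x, ...) {
  cat(sprintf("<eye_analysis> %s\n", x$result$file))
  cat(sprintf("  Z = %d detected, %d stable, spacing ~ %.2f px\n",
              x$result$Z, sum(x$scores$stable), x$estimated_spacing))
  cat(sprintf("  ODI_D = %.4f  ODI_A = %.4f  ODI = %.4f  P = %.4f (N_used = %d)\n",
              x$result$ODI_D, x$result$ODI_A, x$result$ODI, x$result$P,
              x$result$N_used))
  invisible(x)
}

#' Per-ommatidium score table of an eye analysis
#'
#' @param x An `eye_analysis` from [analyze_eye()] or [score_centers()].
#' @param ... Unused.
#' @return A tibble with one row per ommatidium: `index`, `x`, `y`, `odi_d`,
#'   `odi_a`, `odi`, `stable` (and `radius` when detection was involved).
#' @export
tidy.eye_analysis <- function(x, ...) {
  as_tibble(x$scores)
}

#' One-row summary of an eye analysis
#'
#' @param x An `eye_analysis`.
#' @param ... Unused.
#' @return A one-row tibble: `file`, `ODI_D`, `ODI_A`, `ODI`, `Z`, `P`,
#'   `N_used`.
#' @export
glance.eye_analysis <- function(x, ...) {
  x$result
}
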