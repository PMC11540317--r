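#' Construct an eye image object
#'
#' An `eye_image` wraps a 2-D grid of intensities in `[0, 1]` together with the
#' imaging modality. The matrix convention is rows = y (downward), columns = x
#' (rightward); public coordinates are 0-based with the origin at the top-left
#' pixel center, so matrix element `[i, j]` sits at `(x, y) = (j - 1, i - 1)`.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`.
#' @param modality `"brightfield"` or `"sem"`.
#' @param source_name Identifier carried through results (usually a file
#'   basename).
#' @return An `eye_image` object with elements `pixels`, `height`, `width`,
#'   `modality` and `source_name`.
#' @export
#' @examples
#' img <- as_eye_image(matrix(0.5, 80, 80))
#' img$height
as_eye_image <- function(pixels, modality = c("brightfield", "sem"),
                         source_name = "image") {
  modality <- match.arg(modality)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_ommatidia("`pixels` must be a numeric matrix", class = "validation",
                   field = "pixels")
  }
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1) {
    stop_ommatidia("pixel intensities must lie in [0, 1]", class = "validation",
                   field = "pixels")
  }
  structure(
    list(
      pixels = pixels,
      height = nrow(pixels),
      width = ncol(pixels),
      modality = modality,
      source_name = source_name
    ),
    class = "eye_image"
  )
}

#' @export
print.eye_image <- function(x, ...) {
  cat(sprintf("<eye_image> %s: %d x %d px, %s\n",
              x$source_name, x$width, x$height, x$modality))
  invisible(x)
}

#' @export
dim.eye_image <- function(x) c(x$height, x$width)
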