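# shared internal helpers: error constructors, matrix rotations, EBImage bridging

stop_ommatidia <- function(message, class, ...) {
  abort(message, class = c(paste0("ommatidia_error_", class), "ommatidia_error"), ...)
}

check_number <- function(x, field, min = -Inf, max = Inf, integer = FALSE,
                         strict_min = FALSE, strict_max = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_min) x > min else x >= min) &&
    (if (strict_max) x < max else x <= max) &&
    (!integer || x == round(x))
  if (!ok) {
    stop_ommatidia(
      sprintf("invalid value for field `%s`", field),
      class = "validation", field = field
    )
  }
  invisible(x)
}

# 90 degree clockwise rotation of an image matrix (rows = y down, cols = x right):
# pixel (y, x) maps to (x, H - y + 1)
rot90_cw <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])

# 90 degree counterclockwise rotation, the inverse of rot90_cw
rot90_ccw <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

# EBImage stores images as [x, y]; the package convention is a matrix [y, x]
as_eb <- function(px) EBImage::Image(t(px))

from_eb <- function(img) t(EBImage::imageData(img))

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Gaussian blur with the kernel capped to the image size (EBImage errors when
# the filter exceeds the image)
gblur_safe <- function(px, sigma) {
  radius <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  maxr <- min(dim(px)) - 1L
  if (maxr %% 2L == 0L) maxr <- maxr - 1L
  from_eb(EBImage::gblur(as_eb(px), sigma = sigma, radius = min(radius, maxr)))
}

# odd-sized disc brush with diameter covering radius r
disc_brush <- function(r) {
  size <- 2L * as.integer(ceiling(r)) + 1L
  EBImage::makeBrush(size, shape = "disc")
}

# median nearest-neighbor distance among points (x, y); NA when fewer than 2
median_nn_distance <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  nn <- vapply(seq_len(n), function(i) {
    d2 <- (x - x[i])^2 + (y - y[i])^2
    d2[i] <- Inf
    sqrt(min(d2))
  }, numeric(1))
  median(nn)
}
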