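SUPPORTED_EXTENSIONS <- c("png", "jpg", "jpeg", "bmp", "tif", "tiff")

#' Load an eye image from disk
#'
#' Decodes PNG, JPG, JPEG, BMP, TIF or TIFF into a normalized intensity grid.
#' Color inputs are converted to luminance with Rec. 601 weights
#' (0.299 R + 0.587 G + 0.114 B); alpha channels are dropped; integer
#' containers are rescaled to `[0, 1]` by their bit depth (8-bit by 255,
#' 16-bit by 65535). Images flagged `horizontal` are rotated 90 degrees
#' counterclockwise so all downstream processing sees the vertical
#' convention.
#'
#' @param path Image file path; extension decides the decoder
#'   (case-insensitive).
#' @param modality `"brightfield"` or `"sem"`; selects the preprocessing used
#'   later by [detect_ommatidia()].
#' @param horizontal Logical; set when the image was acquired horizontally.
#' @return An [as_eye_image()] object; `source_name` is the file basename.
#' @export
load_image <- function(path, modality = c("brightfield", "sem"),
                       horizontal = FALSE) {
  modality <- match.arg(modality)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% SUPPORTED_EXTENSIONS) {
    stop_ommatidia(
      sprintf("unsupported image format '%s'; supported extensions: %s",
              ext, paste(SUPPORTED_EXTENSIONS, collapse = ", ")),
      class = "format", path = path
    )
  }
  if (!file.exists(path)) {
    stop_ommatidia(paste0("file not found: ", path), class = "io", path = path)
  }
  px <- tryCatch({
    if (ext == "bmp") {
      read_bmp(path)
    } else {
      arr <- EBImage::imageData(EBImage::readImage(path))
      decode_array(arr)
    }
  }, ommatidia_error = function(e) rlang::cnd_signal(e),
     error = function(e) {
    stop_ommatidia(paste0("cannot decode image: ", path), class = "decode",
                   path = path, parent = e)
  })
  px <- clamp01(px)
  if (nrow(px) < 64 || ncol(px) < 64) {
    stop_ommatidia(
      sprintf("degenerate input: image is %d x %d px; both dimensions must be >= 64",
              ncol(px), nrow(px)),
      class = "degenerate", path = path
    )
  }
  if (isTRUE(horizontal)) px <- rot90_ccw(px)
  as_eye_image(px, modality = modality, source_name = basename(path))
}

# EBImage arrays are [x, y] or [x, y, channels]; convert to a [y, x] luminance
# matrix. readImage already rescales integer containers by their bit depth.
decode_array <- function(arr) {
  if (length(dim(arr)) == 2L) return(t(arr))
  nc <- dim(arr)[3]
  if (nc >= 3L) {
    lum <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  } else {
    lum <- arr[, , 1]
  }
  t(lum)
}

# Minimal reader for uncompressed (BI_RGB) Windows BMP: 8-bit paletted,
# 24-bit and 32-bit. Rows are stored bottom-up and padded to 4 bytes.
# Written here because no installed package decodes BMP.
read_bmp <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM") {
    stop_ommatidia(paste0("cannot decode image: ", path), class = "decode",
                   path = path)
  }
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  data_offset <- u32(10)
  header_size <- u32(14)
  width <- u32(18)
  height_raw <- u32(22)
  top_down <- FALSE
  if (height_raw >= 2^31) {          # negative height => top-down rows
    height <- 2^32 - height_raw
    top_down <- TRUE
  } else height <- height_raw
  bpp <- u16(28)
  compression <- u32(30)
  if (compression != 0 || !bpp %in% c(8, 24, 32)) {
    stop_ommatidia(
      paste0("cannot decode image (only uncompressed 8/24/32-bit BMP supported): ", path),
      class = "decode", path = path
    )
  }
  palette <- NULL
  if (bpp == 8) {
    n_colors <- u32(46)
    if (n_colors == 0) n_colors <- 256
    pal_raw <- raw[(14 + header_size) + seq_len(4 * n_colors)]
    pal <- matrix(as.integer(pal_raw), ncol = 4, byrow = TRUE)  # B, G, R, 0
    palette <- (0.299 * pal[, 3] + 0.587 * pal[, 2] + 0.114 * pal[, 1]) / 255
  }
  bytes_pp <- bpp / 8
  stride <- 4 * ceiling(width * bytes_pp / 4)
  px <- matrix(0, nrow = height, ncol = width)
  for (row in seq_len(height)) {
    off <- data_offset + (row - 1) * stride
    line <- as.integer(raw[off + seq_len(width * bytes_pp)])
    vals <- if (bpp == 8) {
      palette[line + 1]
    } else {
      b <- line[seq(1, by = bytes_pp, length.out = width)]
      g <- line[seq(2, by = bytes_pp, length.out = width)]
      r <- line[seq(3, by = bytes_pp, length.out = width)]
      (0.299 * r + 0.587 * g + 0.114 * b) / 255
    }
    target <- if (top_down) row else height - row + 1
    px[target, ] <- vals
  }
  px
}
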