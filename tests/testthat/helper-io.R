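# minimal 24-bit uncompressed BMP writer for read_bmp round-trip tests;
# `rgb` is a list of three [y, x] matrices in [0, 1]
write_bmp24 <- function(rgb, path) {
  h <- nrow(rgb[[1]]); w <- ncol(rgb[[1]])
  stride <- 4 * ceiling(w * 3 / 4)
  data_size <- stride * h
  file_size <- 54 + data_size
  u16 <- function(v) as.raw(c(v %% 256, v %/% 256))
  u32 <- function(v) as.raw(c(v %% 256, (v %/% 256) %% 256,
                              (v %/% 65536) %% 256, (v %/% 16777216) %% 256))
  header <- c(
    charToRaw("BM"), u32(file_size), u32(0), u32(54),
    u32(40), u32(w), u32(h), u16(1), u16(24), u32(0), u32(data_size),
    u32(2835), u32(2835), u32(0), u32(0)
  )
  body <- raw(data_size)
  to8 <- function(m) {
    m <- round(m * 255)
    storage.mode(m) <- "integer"
    m
  }
  r <- to8(rgb[[1]]); g <- to8(rgb[[2]]); b <- to8(rgb[[3]])
  for (row in seq_len(h)) {
    src <- h - row + 1          # bottom-up storage
    off <- (row - 1) * stride
    idx <- off + seq_len(3 * w)
    line <- integer(3 * w)
    line[seq(1, by = 3, length.out = w)] <- b[src, ]
    line[seq(2, by = 3, length.out = w)] <- g[src, ]
    line[seq(3, by = 3, length.out = w)] <- r[src, ]
    body[idx] <- as.raw(line)
  }
  writeBin(c(header, body), path)
  invisible(path)
}
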