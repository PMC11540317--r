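# Brute-force, scalar-loop re-implementations of the fan geometry and the
# disorder statistics, kept deliberately naive (O(n^2) all-pairs sorts, no
# vectorization) for use as an independent oracle.

oracle_fan_one <- function(xs, ys, i) {
  n <- length(xs)
  d <- numeric(n)
  for (j in seq_len(n)) d[j] <- sqrt((xs[j] - xs[i])^2 + (ys[j] - ys[i])^2)
  d[i] <- Inf
  nb <- order(d, seq_len(n))[1:6]
  dx <- xs[nb] - xs[i]
  dy <- ys[nb] - ys[i]
  az <- atan2(dy, dx)
  ord <- order(az, seq_along(az))
  nb <- nb[ord]; dx <- dx[ord]; dy <- dy[ord]
  lengths <- numeric(6); gaps <- numeric(6)
  for (k in 1:6) {
    k2 <- if (k == 6) 1 else k + 1
    lengths[k] <- sqrt(dx[k]^2 + dy[k]^2)
    g <- atan2(dx[k] * dy[k2] - dy[k] * dx[k2],
               dx[k] * dx[k2] + dy[k] * dy[k2]) * 180 / pi
    if (g < 0) g <- g + 360
    gaps[k] <- g
  }
  list(neighbors = nb, lengths = lengths, gaps = gaps)
}

oracle_fans <- function(xs, ys) {
  lapply(seq_along(xs), function(i) oracle_fan_one(xs, ys, i))
}

oracle_score <- function(lengths, gaps) {
  ls <- sort(lengths); gs <- sort(gaps)
  dd <- numeric(5); da <- numeric(5)
  for (k in 2:6) {
    dd[k - 1] <- ls[k] - ls[1]
    da[k - 1] <- gs[k] - gs[1]
  }
  # terms derived independently above; sum() itself is base R's accumulator
  odi_d <- sum(dd); odi_a <- sum(da)
  list(odi_d = odi_d, odi_a = odi_a, odi = odi_d + odi_a)
}

oracle_stable <- function(fans, spacing, factor = 2) {
  vapply(fans, function(f) {
    ok <- TRUE
    for (l in f$lengths) if (l > factor * spacing) ok <- FALSE
    ok
  }, logical(1))
}

# five per-image statistics from oracle fans; returns NULL when nothing stable
oracle_statistics <- function(xs, ys, spacing, n_count, factor = 2) {
  fans <- oracle_fans(xs, ys)
  stable <- oracle_stable(fans, spacing, factor)
  if (!any(stable)) return(NULL)
  odis <- t(vapply(fans, function(f) {
    s <- oracle_score(f$lengths, f$gaps)
    c(s$odi_d, s$odi_a, s$odi)
  }, numeric(3)))
  idx <- which(stable)
  idx <- idx[order(odis[idx, 3], idx)]
  n_used <- min(n_count, length(idx))
  top <- idx[seq_len(n_used)]
  odi_d <- sum(odis[top, 1]); odi_a <- sum(odis[top, 2])
  list(ODI_D = odi_d, ODI_A = odi_a, ODI = odi_d + odi_a,
       Z = length(xs), P = (odi_d + odi_a) / n_used, N_used = n_used)
}

# jittered lattice patch (plain construction, independent of the generator)
jittered_patch <- function(n, spacing = 20, jitter = 1, seed = 1) {
  set.seed(seed)
  side <- ceiling(sqrt(n * 2 / sqrt(3)))
  pts <- expand.grid(j = 0:side, k = 0:side)
  x <- pts$j * spacing + (pts$k %% 2) * spacing / 2
  y <- pts$k * spacing * sqrt(3) / 2
  keep <- sample(length(x), n)
  tibble::tibble(x = x[keep] + rnorm(n, 0, jitter),
                 y = y[keep] + rnorm(n, 0, jitter))
}

# greedy one-to-one matching of detections to ground truth; returns the
# number of true positives within max_dist
match_count <- function(det, truth, max_dist) {
  used <- rep(FALSE, nrow(truth))
  tp <- 0L
  for (i in seq_len(nrow(det))) {
    d <- sqrt((truth$x - det$x[i])^2 + (truth$y - det$y[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && d[j] <= max_dist) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  tp
}

min_pair_distance <- function(x, y) {
  n <- length(x)
  best <- Inf
  for (i in seq_len(n - 1)) {
    d <- sqrt((x[(i + 1):n] - x[i])^2 + (y[(i + 1):n] - y[i])^2)
    best <- min(best, min(d))
  }
  best
}

small_eye_spec <- function(...) {
  args <- list(image_width = 300, image_height = 340,
               mask_semiaxes = c(120, 140), noise_sigma = 0, seed = 1)
  do.call(eye_spec, utils::modifyList(args, list(...)))
}
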