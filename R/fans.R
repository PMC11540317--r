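# fan geometry from the six offset vectors (dx, dy) of one focal point:
# sort by azimuth (ties by the supplied order), then compute each consecutive
# angular gap as atan2(cross, dot) of the vector pair (wrapping past the last
# vector back to the first). The pairwise form is symmetric in the two
# vectors, which keeps the gaps of a geometrically regular fan bit-identical
# instead of accumulating azimuth-subtraction rounding; gaps > 180 degrees
# (possible for rim points with all neighbors to one side) come out negative
# from atan2 and are wrapped up by 360.
fan_from_offsets <- function(dx, dy) {
  az <- atan2(dy, dx)
  ord <- order(az, seq_along(az))
  dx <- dx[ord]; dy <- dy[ord]
  nxt <- c(2:6, 1)
  cross <- dx * dy[nxt] - dy * dx[nxt]
  dot <- dx * dx[nxt] + dy * dy[nxt]
  gaps <- atan2(cross, dot) * 180 / pi
  gaps[gaps < 0] <- gaps[gaps < 0] + 360
  list(order = ord, lengths = sqrt(dx^2 + dy^2), gaps = gaps)
}

#' Build 6-neighbor vector fans
#'
#' For every detected ommatidium, draws the six vectors from its center to the
#' centers of its six nearest neighbors (Euclidean distance; ties broken by
#' point index). Vectors are stored in ascending azimuth order (`atan2(dy, dx)`
#' measured from the +x axis with y downward); the six angular gaps are the
#' angles between consecutive vectors (computed pairwise as
#' `atan2(cross, dot)`, wrapping through 360 degrees), so they always sum
#' to 360.
#'
#' @param centers A tibble with columns `x` and `y`, e.g. from
#'   [detect_ommatidia()]; at least 7 rows.
#' @return A tibble with one row per ommatidium: `index`, `x`, `y`, and
#'   list-columns `neighbors` (6 integer indices, azimuth order), `lengths`
#'   (6 vector lengths, pixels) and `gaps` (6 consecutive angular gaps,
#'   degrees).
#' @export
#' @examples
#' pts <- tibble::tibble(
#'   x = c(0, 10 * cospi((0:5) / 3)),
#'   y = c(0, 10 * sinpi((0:5) / 3))
#' )
#' fans <- build_neighbor_fans(pts)
#' fans$lengths[[1]]  # all 10
#' fans$gaps[[1]]     # all 60
build_neighbor_fans <- function(centers) {
  n <- nrow(centers)
  if (n < 7) {
    stop_ommatidia(
      sprintf("too few ommatidia: %d found, at least 7 are needed for 6-neighbor fans", n),
      class = "too_few"
    )
  }
  x <- centers$x; y <- centers$y
  rows <- lapply(seq_len(n), function(i) {
    dx <- x - x[i]; dy <- y - y[i]
    d <- sqrt(dx^2 + dy^2)
    d[i] <- Inf
    nb <- order(d, seq_len(n))[1:6]
    fan <- fan_from_offsets(dx[nb], dy[nb])
    list(neighbors = nb[fan$order], lengths = fan$lengths, gaps = fan$gaps)
  })
  out <- tibble(
    index = seq_len(n), x = x, y = y,
    neighbors = lapply(rows, `[[`, "neighbors"),
    lengths = lapply(rows, `[[`, "lengths"),
    gaps = lapply(rows, `[[`, "gaps")
  )
  class(out) <- c("ommatidia_fans", class(out))
  out
}

#' Score one vector fan
#'
#' Distance disorderliness `odi_d` is the summed excess of the five longest
#' vector lengths over the shortest (`sum(v_i - v_min)`); angle
#' disorderliness `odi_a` is the summed excess of the five largest angular
#' gaps over the smallest (`sum(theta_i - theta_min)`); `odi` is their sum.
#' A perfectly hexagonal fan (equal lengths, six 60-degree gaps) scores zero.
#'
#' @param lengths Six vector lengths in pixels.
#' @param gaps Six consecutive angular gaps in degrees.
#' @return A list with `odi_d` (pixels), `odi_a` (degrees) and `odi`.
#' @export
#' @examples
#' score_ommatidium(c(10, 10, 10, 10, 10, 12), rep(60, 6))$odi_d  # 2
score_ommatidium <- function(lengths, gaps) {
  if (length(lengths) != 6L || length(gaps) != 6L) {
    stop_ommatidia("a fan has exactly 6 lengths and 6 gaps",
                   class = "validation", field = "fan")
  }
  ls <- sort(lengths)
  gs <- sort(gaps)
  odi_d <- sum(ls[2:6] - ls[1])
  odi_a <- sum(gs[2:6] - gs[1])
  list(odi_d = odi_d, odi_a = odi_a, odi = odi_d + odi_a)
}

#' Score every fan in a set
#'
#' Applies [score_ommatidium()] to each row of a fan table.
#'
#' @param fans From [build_neighbor_fans()].
#' @return A tibble with `index`, `x`, `y`, `odi_d`, `odi_a`, `odi`.
#' @export
score_fans <- function(fans) {
  sc <- Map(score_ommatidium, fans$lengths, fans$gaps)
  tibble(
    index = fans$index, x = fans$x, y = fans$y,
    odi_d = vapply(sc, `[[`, numeric(1), "odi_d"),
    odi_a = vapply(sc, `[[`, numeric(1), "odi_a"),
    odi = vapply(sc, `[[`, numeric(1), "odi")
  )
}

#' Flag stable ommatidia
#'
#' An ommatidium is stable when all six of its fan vectors are no longer than
#' `stable_factor` times the lattice spacing. Border or isolated detections
#' whose "neighbors" are distant interior points are thereby excluded from
#' aggregation.
#'
#' @param fans From [build_neighbor_fans()].
#' @param spacing Lattice spacing in pixels (for detections, the
#'   `estimated_spacing` attribute).
#' @param stable_factor Length threshold as a multiple of `spacing`
#'   (default 2).
#' @return Logical vector, one flag per fan.
#' @export
classify_stable <- function(fans, spacing, stable_factor = 2) {
  check_number(spacing, "spacing", min = 0, strict_min = TRUE)
  check_number(stable_factor, "stable_factor", min = 0, strict_min = TRUE)
  stable <- vapply(fans$lengths, function(l) max(l) <= stable_factor * spacing,
                   logical(1))
  if (!any(stable)) {
    stop_ommatidia("no stable ommatidia: every fan has a neighbor beyond the stability threshold",
                   class = "no_stable")
  }
  stable
}

#' Aggregate per-ommatidium scores into per-image statistics
#'
#' Ranks stable ommatidia by ascending `odi` (ties by index), keeps the
#' `N_used = min(N, number of stable)` most ordered, and sums their
#' components: `ODI_D`, `ODI_A`, and `ODI = ODI_D + ODI_A`. `Z` is the total
#' number of detected ommatidia (stable or not). The phenotypic score is the
#' mean disorderliness of the ranked set, `P = ODI / N_used`, which makes P
#' comparable across images with different facet counts; higher P means a
#' rougher eye.
#'
#' @param scores Tibble from [score_fans()] with a logical `stable` column
#'   (see [classify_stable()]).
#' @param n Number of most-ordered ommatidia to aggregate (the `-n` count
#'   flag; default 200).
#' @param z Total number of detected ommatidia.
#' @param source_name Image identifier for the `file` column.
#' @return A one-row tibble: `file`, `ODI_D`, `ODI_A`, `ODI`, `Z`, `P`,
#'   `N_used`.
#' @export
#' @examples
#' sc <- tibble::tibble(index = 1:5, odi_d = 1:5, odi_a = 0,
#'                      odi = as.numeric(1:5), stable = TRUE)
#' aggregate_scores(sc, n = 3, z = 5)  # ODI = 6, P = 2
aggregate_scores <- function(scores, n = 200, z, source_name = "image") {
  check_number(n, "n", min = 1, integer = TRUE)
  check_number(z, "z", min = 0, integer = TRUE)
  if (!"stable" %in% names(scores)) {
    stop_ommatidia("`scores` needs a logical `stable` column (see classify_stable())",
                   class = "validation", field = "stable")
  }
  s <- scores[scores$stable, , drop = FALSE]
  if (nrow(s) == 0) {
    stop_ommatidia("no stable ommatidia to aggregate", class = "no_stable")
  }
  s <- s[order(s$odi, s$index), , drop = FALSE]
  n_used <- min(n, nrow(s))
  top <- s[seq_len(n_used), , drop = FALSE]
  odi_d <- sum(top$odi_d)
  odi_a <- sum(top$odi_a)
  odi <- odi_d + odi_a
  tibble(
    file = source_name,
    ODI_D = odi_d, ODI_A = odi_a, ODI = odi,
    Z = as.integer(z), P = odi / n_used, N_used = as.integer(n_used)
  )
}

#' Score a set of exact center coordinates
#'
#' Geometry-only pipeline (no image round-trip): fans, per-ommatidium scores,
#' stability, and the per-image statistics, straight from coordinates. Used
#' for synthetic ground truth and for invariance analysis.
#'
#' @param centers Tibble with columns `x`, `y` (at least 7 rows).
#' @param spacing Lattice spacing; when `NULL`, the median nearest-neighbor
#'   distance of `centers`.
#' @param n Count of most-ordered ommatidia to aggregate (default 200).
#' @param stable_factor See [classify_stable()].
#' @param source_name Identifier for the result row.
#' @return An `eye_analysis` object; see [analyze_eye()].
#' @export
score_centers <- function(centers, spacing = NULL, n = 200, stable_factor = 2,
                          source_name = "coordinates") {
  fans <- build_neighbor_fans(centers)
  spacing <- spacing %||% median_nn_distance(centers$x, centers$y)
  scores <- score_fans(fans)
  scores$stable <- classify_stable(fans, spacing, stable_factor)
  result <- aggregate_scores(scores, n = n, z = nrow(centers),
                             source_name = source_name)
  new_eye_analysis(result = result, scores = scores, fans = fans,
                   detections = centers, spacing = spacing, n = n)
}
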