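test_that("a perfect hexagon gives equal lengths and 60-degree gaps", {
  pts <- tibble::tibble(
    x = c(0, 10 * cos((0:5) * pi / 3)),
    y = c(0, 10 * sin((0:5) * pi / 3))
  )
  fans <- build_neighbor_fans(pts)
  expect_equal(fans$lengths[[1]], rep(10, 6))
  expect_equal(fans$gaps[[1]], rep(60, 6), tolerance = 1e-12)
  expect_setequal(fans$neighbors[[1]], 2:7)
  sc <- score_ommatidium(fans$lengths[[1]], fans$gaps[[1]])
  expect_equal(sc$odi_d, 0)
  expect_lt(sc$odi_a, 1e-9)
})

test_that("worked arithmetic matches the stated component formulas", {
  sc1 <- score_ommatidium(c(10, 10, 10, 10, 10, 12), rep(60, 6))
  expect_identical(sc1$odi_d, 2)
  expect_identical(sc1$odi_a, 0)
  expect_identical(sc1$odi, 2)

  sc2 <- score_ommatidium(rep(10, 6), c(50, 60, 60, 60, 60, 70))
  expect_identical(sc2$odi_a, 60)
  expect_identical(sc2$odi_d, 0)
  expect_identical(sc2$odi, 60)
})

test_that("fans match the exhaustive all-pairs oracle on random point sets", {
  for (seed in 1:5) {
    set.seed(seed)
    pts <- tibble::tibble(x = runif(20, 0, 100), y = runif(20, 0, 100))
    fans <- build_neighbor_fans(pts)
    oracle <- oracle_fans(pts$x, pts$y)
    expect_identical(fans$neighbors, lapply(oracle, `[[`, "neighbors"))
    expect_identical(fans$lengths, lapply(oracle, `[[`, "lengths"))
    expect_identical(fans$gaps, lapply(oracle, `[[`, "gaps"))
    expect_equal(nrow(fans), nrow(pts))  # one fan per point
  }
})

test_that("all five statistics match the brute-force oracle on jittered lattices", {
  for (seed in 1:5) {
    pts <- jittered_patch(n = 40, spacing = 20, jitter = 2, seed = seed)
    spacing <- median(vapply(seq_len(nrow(pts)), function(i) {
      d <- sqrt((pts$x - pts$x[i])^2 + (pts$y - pts$y[i])^2)
      d[i] <- Inf
      min(d)
    }, numeric(1)))
    fit <- score_centers(pts, spacing = spacing, n = 15)
    want <- oracle_statistics(pts$x, pts$y, spacing, n_count = 15)
    got <- glance(fit)
    expect_identical(got$ODI_D, want$ODI_D)
    expect_identical(got$ODI_A, want$ODI_A)
    expect_identical(got$ODI, want$ODI)
    expect_identical(got$Z, as.integer(want$Z))
    expect_identical(got$P, want$P)
  }
})

test_that("gaps are positive and sum to 360 degrees", {
  for (seed in 6:10) {
    set.seed(seed)
    pts <- tibble::tibble(x = runif(30, 0, 200), y = runif(30, 0, 200))
    fans <- build_neighbor_fans(pts)
    sums <- vapply(fans$gaps, sum, numeric(1))
    expect_lt(max(abs(sums - 360)), 1e-6)
    expect_true(all(unlist(fans$gaps) >= 0))
  }
})

test_that("stability thresholds on neighbor distance behave as specified", {
  truth <- generate_lattice_points(small_eye_spec())
  fans <- build_neighbor_fans(truth)
  stable <- classify_stable(fans, spacing = 20)
  expect_identical(stable, oracle_stable(oracle_fans(truth$x, truth$y), 20))
  # deep interior point is stable
  mid <- which.min((truth$x - 150)^2 + (truth$y - 170)^2)
  expect_true(stable[mid])

  # an isolated point beyond 2x spacing is unstable
  iso <- dplyr::bind_rows(truth, tibble::tibble(x = 10, y = 10))
  fans_iso <- build_neighbor_fans(iso)
  stable_iso <- classify_stable(fans_iso, spacing = 20)
  expect_false(stable_iso[nrow(iso)])

  # everything isolated: no stable ommatidia
  set.seed(1)
  sparse <- tibble::tibble(x = runif(8, 0, 1000), y = runif(8, 0, 1000))
  fans_sparse <- build_neighbor_fans(sparse)
  expect_error(classify_stable(fans_sparse, spacing = 5),
               class = "ommatidia_error_no_stable")
})

test_that("aggregation ranks by odi, caps at the stable count and averages into P", {
  zeros <- tibble::tibble(index = 1:8, odi_d = 0, odi_a = 0, odi = 0,
                          stable = TRUE)
  r0 <- aggregate_scores(zeros, n = 5, z = 8)
  expect_identical(r0$ODI, 0)
  expect_identical(r0$P, 0)

  sc <- tibble::tibble(index = 1:5, odi_d = as.numeric(1:5), odi_a = 0,
                       odi = as.numeric(1:5), stable = TRUE)
  r <- aggregate_scores(sc, n = 3, z = 5)
  expect_identical(r$ODI, 6)
  expect_identical(r$P, 2)
  expect_identical(r$N_used, 3L)
  expect_identical(r$Z, 5L)

  # N larger than the stable count: cap, and ODI covers all stable scores
  sc2 <- sc
  sc2$stable <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  r2 <- aggregate_scores(sc2, n = 200, z = 5)
  expect_identical(r2$N_used, 4L)
  expect_identical(r2$ODI, 10)

  expect_error(aggregate_scores(sc, n = 0, z = 5),
               class = "ommatidia_error_validation")
  sc$stable <- FALSE
  expect_error(aggregate_scores(sc, n = 3, z = 5),
               class = "ommatidia_error_no_stable")
})

test_that("scores are invariant to rigid motion and covariant to scale", {
  pts <- jittered_patch(n = 30, spacing = 20, jitter = 1.5, seed = 12)
  base <- tidy(score_centers(pts, spacing = 20, n = 10))

  th <- 17 * pi / 180
  moved <- tibble::tibble(
    x = 31.7 + pts$x * cos(th) - pts$y * sin(th),
    y = -12.3 + pts$x * sin(th) + pts$y * cos(th)
  )
  rot <- tidy(score_centers(moved, spacing = 20, n = 10))
  expect_lt(max(abs(rot$odi_d - base$odi_d)), 1e-6)
  expect_lt(max(abs(rot$odi_a - base$odi_a)), 1e-6)

  k <- 2.5
  scaled <- tibble::tibble(x = k * pts$x, y = k * pts$y)
  scl <- tidy(score_centers(scaled, spacing = k * 20, n = 10))
  expect_lt(max(abs(scl$odi_d - k * base$odi_d)), 1e-6)
  expect_lt(max(abs(scl$odi_a - base$odi_a)), 1e-9)
})

test_that("a jitter-free lattice scores at the numerical zero floor", {
  truth <- generate_lattice_points(eye_spec(noise_sigma = 0))
  fit <- score_centers(truth, spacing = 20, n = 200)
  r <- glance(fit)
  expect_lt(r$ODI_D, 1e-6)
  expect_lt(r$ODI_A, 1e-6)
  expect_lt(r$P, 1e-8)
  expect_identical(r$ODI, r$ODI_D + r$ODI_A)
})

test_that("fan construction requires at least seven points", {
  pts <- tibble::tibble(x = runif(6), y = runif(6))
  expect_error(build_neighbor_fans(pts), class = "ommatidia_error_too_few")
})
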