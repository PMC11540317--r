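test_that("invalid spec fields raise validation errors naming the field", {
  expect_error(eye_spec(jitter_sigma = -1), class = "ommatidia_error_validation")
  expect_error(eye_spec(dropout_fraction = 1), class = "ommatidia_error_validation")
  expect_error(eye_spec(foreground_level = 1.2), class = "ommatidia_error_validation")
  expect_error(eye_spec(disk_radius = 15, lattice_spacing = 20),
               class = "ommatidia_error_validation")
  err <- tryCatch(eye_spec(noise_sigma = -0.1), error = identity)
  expect_equal(err$field, "noise_sigma")
  # mask must fit inside the image bounds
  expect_error(
    eye_spec(image_width = 100, image_height = 100, mask_semiaxes = c(80, 40)),
    class = "ommatidia_error_validation"
  )
})

test_that("unjittered lattice has single-valued nearest-neighbor distances", {
  spec <- eye_spec(image_width = 220, image_height = 180,
                   mask_semiaxes = c(100, 80), lattice_spacing = 20,
                   disk_radius = 6, jitter_sigma = 0, dropout_fraction = 0)
  truth <- generate_lattice_points(spec)
  expect_gt(nrow(truth), 50)
  nn <- vapply(seq_len(nrow(truth)), function(i) {
    d <- sqrt((truth$x - truth$x[i])^2 + (truth$y - truth$y[i])^2)
    d[i] <- Inf
    min(d)
  }, numeric(1))
  expect_lt(max(abs(nn - 20)), 1e-6)
  # row structure: y values fall on rows spaced by spacing * sqrt(3) / 2
  ys <- sort(unique(truth$y))
  expect_lt(max(abs(diff(ys) - 20 * sqrt(3) / 2)), 1e-6)
})

test_that("dropout replays as seeded Bernoulli draws over the interior lattice", {
  base <- small_eye_spec(seed = 42)
  full <- generate_lattice_points(base)
  n_lattice <- attr(full, "n_lattice")
  expect_equal(n_lattice, nrow(full))  # no dropout, no jitter

  spec <- small_eye_spec(seed = 42, dropout_fraction = 0.1)
  truth <- generate_lattice_points(spec)
  set.seed(42)
  u <- runif(n_lattice)
  expect_equal(nrow(truth), sum(u >= 0.1))
})

test_that("generation and rendering are deterministic for a fixed seed", {
  spec <- small_eye_spec(seed = 7, jitter_sigma = 1.5, dropout_fraction = 0.05,
                         noise_sigma = 0.02)
  t1 <- generate_lattice_points(spec)
  t2 <- generate_lattice_points(spec)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$y, t2$y)
  i1 <- render_eye_image(t1, spec)
  i2 <- render_eye_image(t2, spec)
  expect_identical(i1$pixels, i2$pixels)
})

test_that("rendered-disk count tracks the dropout rate within binomial noise", {
  observed <- 0; n_total <- 0
  for (seed in 1:8) {
    spec <- small_eye_spec(seed = seed, dropout_fraction = 0.2)
    truth <- generate_lattice_points(spec)
    observed <- observed + nrow(truth)
    n_total <- n_total + attr(truth, "n_lattice")
  }
  expected <- n_total * 0.8
  sd_binom <- sqrt(n_total * 0.8 * 0.2)
  expect_lt(abs(observed - expected), 3 * sd_binom)
})

test_that("rendering matches the stated intensity model", {
  spec <- small_eye_spec()
  empty <- tibble::tibble(x = numeric(), y = numeric())
  img <- render_eye_image(empty, spec)
  expect_true(all(img$pixels == spec$background_level))

  one <- tibble::tibble(x = 150, y = 170)
  img1 <- render_eye_image(one, spec)
  expect_equal(img1$pixels[171, 151], spec$foreground_level)
  expect_equal(img1$pixels[171, 151 + 2 * spec$disk_radius],
               spec$background_level)

  sem <- small_eye_spec(modality = "sem")
  img2 <- render_eye_image(one, sem)
  expect_equal(img2$pixels[171, 151], sem$foreground_level)
  # dome falls off monotonically to background along a ray
  ray <- img2$pixels[171, 151 + 0:8]
  expect_true(all(diff(ray) <= 0))
  expect_equal(ray[8], sem$background_level)
})

test_that("horizontal orientation is the vertical rendering rotated 90 degrees clockwise", {
  sv <- small_eye_spec(seed = 3, noise_sigma = 0.01)
  sh <- do.call(eye_spec, utils::modifyList(unclass(sv),
                                            list(orientation = "horizontal")))
  iv <- render_eye_image(generate_lattice_points(sv), sv)
  ih <- render_eye_image(generate_lattice_points(sh), sh)
  rot_cw <- t(iv$pixels[rev(seq_len(nrow(iv$pixels))), ])
  expect_identical(ih$pixels, rot_cw)
})

test_that("write_fixture_set writes images, sidecars and a consistent manifest", {
  dir <- withr::local_tempdir()
  specs <- lapply(c(0, 1, 2), function(j) small_eye_spec(jitter_sigma = j, seed = 5))
  manifest <- write_fixture_set(specs, dir)
  expect_equal(nrow(manifest), 3)
  expect_true(all(file.exists(file.path(dir, manifest$image))))
  expect_true(all(file.exists(file.path(dir, manifest$truth))))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_identical(manifest$jitter_sigma, c(0, 1, 2))
  # sidecar matches the generated truth
  truth <- generate_lattice_points(specs[[2]])
  side <- utils::read.delim(file.path(dir, manifest$truth[2]))
  expect_equal(side$x, truth$x)
  expect_equal(side$y, truth$y)
  expect_equal(manifest$count[2], nrow(truth))

  empty <- write_fixture_set(list(), withr::local_tempdir())
  expect_equal(nrow(empty), 0)
})
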