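make_rgb <- function(r, g, b) {
  img <- array(0L, c(1L, 1L, 3L))
  img[1, 1, ] <- as.integer(c(r, g, b))
  img
}

test_that("rgb_to_od implements od = -log10((i + 1) / 256)", {
  # white is the minimum attainable OD: -log10(256/256) = 0 exactly
  expect_equal(as.vector(rgb_to_od(make_rgb(255, 255, 255))), rep(0, 3))
  expect_equal(as.vector(rgb_to_od(make_rgb(0, 0, 0))),
               rep(log10(256), 3), tolerance = 1e-12)
  expect_equal(as.vector(rgb_to_od(make_rgb(127, 127, 127))),
               rep(log10(2), 3), tolerance = 1e-12)
  # monotone decreasing in intensity, non-negative, finite
  od <- rgb_to_od(array(rep(0:255, times = 3), c(256, 1, 3)))
  expect_true(all(diff(od[, 1, 1]) < 0))
  expect_true(all(od >= 0) && all(is.finite(od)))
})

test_that("build_stain_basis normalizes, completes and inverts", {
  b <- build_stain_basis(c(1, 0, 0), c(0, 1, 0))
  expect_equal(b$v_residual, c(0, 0, 1))
  expect_equal(unname(b$mixing_matrix), diag(3))

  he <- he_basis()
  expect_equal(sqrt(sum(he$v_h^2)), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(he$v_e^2)), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(he$v_residual^2)), 1, tolerance = 1e-12)
  expect_lt(max(abs(he$mixing_matrix %*% he$inverse_matrix - diag(3))), 1e-10)
  expect_lt(abs(sum(he$v_residual * he$v_h)), 1e-12)
  expect_lt(abs(sum(he$v_residual * he$v_e)), 1e-12)

  expect_error(build_stain_basis(c(1, 1, 0), c(2, 2, 0)),
               "parallel", class = "chromaseg_basis_error")
  expect_error(build_stain_basis(c(0, 0, 0), c(0, 1, 0)),
               class = "chromaseg_basis_error")
  expect_error(build_stain_basis(c(-1, 1, 0), c(0, 1, 0)),
               class = "chromaseg_basis_error")
})

test_that("deconvolve recovers pure stains and white", {
  basis <- he_basis()
  white <- array(255L, c(2, 2, 3))
  ch <- deconvolve(rgb_to_od(white), basis)
  expect_true(all(ch$haematoxylin >= 254))
  expect_true(all(ch$eosin >= 254))
  expect_true(all(ch$residual >= 254))

  # forward-render a pure unit-concentration haematoxylin pixel, invert
  img <- render_stains(matrix(1, 1, 1), matrix(0, 1, 1), basis)
  conc <- stain_concentrations(rgb_to_od(img), basis)
  expect_equal(conc[1, 1, 1], 1, tolerance = 0.02)
  expect_equal(conc[1, 1, 2], 0, tolerance = 0.02)
  # independent check: solve the 3x3 system directly
  od_direct <- solve(t(basis$mixing_matrix), as.vector(rgb_to_od(img)))
  expect_equal(unname(od_direct[1]), 1, tolerance = 0.02)
  hval <- deconvolve(rgb_to_od(img), basis)$haematoxylin[1, 1]
  expect_equal(hval, 26, tolerance = 1)   # round(255 * 10^-1) = 26
})

test_that("render/deconvolve round-trip is quantization-limited on [0,1]^2", {
  # 8-bit log coding limits recovery: on [0,1]^2 the max abs error is ~0.045
  # (see the methods vignette for why the bound grows with concentration).
  basis <- he_basis()
  set.seed(101)
  n <- 1000
  ch <- matrix(runif(n), 1); ce <- matrix(runif(n), 1)
  img <- render_stains(ch, ce, basis)
  conc <- stain_concentrations(rgb_to_od(img), basis)
  err <- max(abs(conc[, , 1] - ch), abs(conc[, , 2] - ce))
  expect_lt(err, 0.05)
})

test_that("eosin does not bleed into the haematoxylin channel", {
  basis <- he_basis()
  ce <- matrix(seq(0.1, 1.5, by = 0.1), 1)
  img <- render_stains(matrix(0, 1, ncol(ce)), ce, basis)
  h <- deconvolve(rgb_to_od(img), basis)$haematoxylin
  expect_true(all(h >= 250))
})

test_that("enhance_contrast stretches, saturates and stays monotone", {
  two <- matrix(c(100L, 150L), 1)
  expect_identical(as.vector(enhance_contrast(two, 0)), c(0L, 255L))

  flat <- matrix(77L, 3, 3)
  expect_identical(enhance_contrast(flat, 0), flat)

  full <- matrix(0:255, 16, 16)
  expect_identical(as.vector(enhance_contrast(full, 0)), as.vector(full))

  # monotone: never inverts the ordering of two pixel values
  set.seed(7)
  ch <- matrix(sample(0:255, 600, replace = TRUE), 20, 30)
  out <- enhance_contrast(ch, 0.02)
  o <- order(as.vector(ch))
  expect_true(all(diff(as.vector(out)[o]) >= 0))

  expect_error(enhance_contrast(two, 0.5))
})

test_that("rgb_to_gray weights channels correctly", {
  expect_identical(rgb_to_gray(make_rgb(30, 60, 90))[1, 1], 60L)
  expect_identical(rgb_to_gray(make_rgb(255, 0, 0),
                               c(0.299, 0.587, 0.114))[1, 1], 76L)
  # any gray pixel maps to itself under any valid weights
  for (v in c(0L, 17L, 255L)) {
    expect_identical(rgb_to_gray(make_rgb(v, v, v), c(0.2, 0.5, 0.3))[1, 1], v)
  }
  # equal weights are permutation-invariant over channels
  set.seed(3)
  px <- sample(0:255, 3)
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  vals <- vapply(perms, function(p) {
    rgb_to_gray(make_rgb(px[p[1]], px[p[2]], px[p[3]]))[1, 1]
  }, integer(1))
  expect_true(all(vals == vals[1]))
  expect_identical(attr(rgb_to_gray(make_rgb(1, 2, 3)), "label"), "grayscale")

  expect_error(rgb_to_gray(make_rgb(0, 0, 0), c(0.5, 0.6, 0.2)),
               class = "chromaseg_argument_error")
})
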