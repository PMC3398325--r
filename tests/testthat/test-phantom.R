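small_spec <- function(...) {
  do.call(phantom_spec, utils::modifyList(
    list(width = 300, height = 260, n_nests = 2, nest_radius_range = c(20, 30),
         noise_sd = 0, seed = 9), list(...)))
}

test_that("render_stains inverts the OD convention", {
  basis <- he_basis()
  # zero concentrations -> pure white
  img <- render_stains(matrix(0, 2, 3), matrix(0, 2, 3), basis)
  expect_true(all(img == 255L))

  # unit haematoxylin: close to 255 * 10^(-v_h) per channel
  img <- render_stains(matrix(1, 1, 1), matrix(0, 1, 1), basis)
  expect_true(all(abs(as.vector(img) - c(58, 49, 138)) <= 1))

  # render -> od -> concentrations round-trips (quantization-limited)
  set.seed(61)
  ch <- matrix(runif(200), 10, 20); ce <- matrix(runif(200), 10, 20)
  conc <- stain_concentrations(rgb_to_od(render_stains(ch, ce, basis)), basis)
  expect_lt(max(abs(conc[, , 1] - ch)), 0.05)
  expect_lt(max(abs(conc[, , 2] - ce)), 0.05)

  expect_error(render_stains(matrix(0, 2, 2), matrix(0, 3, 3), basis),
               class = "chromaseg_shape_error")
})

test_that("generate_phantom is deterministic and honors its spec", {
  a <- generate_phantom(small_spec())
  b <- generate_phantom(small_spec())
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)

  # no objects, no noise -> uniform background, empty truth
  flat <- generate_phantom(small_spec(n_nests = 0))
  expect_identical(length(unique(as.vector(flat$image[, , 2]))), 1L)
  expect_false(any(flat$truth))

  # truth equals the union of nest disks, by brute-force rasterization
  ph <- generate_phantom(small_spec(n_nests = 3, nest_radius_range = c(30, 30)))
  nests <- ph$placements[ph$placements$kind == "nest", ]
  want <- matrix(FALSE, 260, 300)
  for (y in 1:260) for (x in 1:300) {
    for (i in seq_len(nrow(nests))) {
      if ((y - nests$cy[i])^2 + (x - nests$cx[i])^2 <= nests$r[i]^2) {
        want[y, x] <- TRUE
      }
    }
  }
  expect_identical(ph$truth, want)
  expect_equal(sum(ph$truth), 3 * pi * 30^2, tolerance = 0.01)
})

test_that("distractors are excluded from truth and placed clear of nests", {
  ph <- generate_phantom(small_spec(n_distractors = 8,
                                    distractor_radius_range = c(4, 8)))
  pl <- ph$placements
  nests <- pl[pl$kind == "nest", ]
  dis <- pl[pl$kind == "distractor", ]
  expect_identical(nrow(dis), 8L)
  # clearance: centre distance at least r1 + r2 + clearance for all pairs
  for (i in seq_len(nrow(dis))) {
    d <- sqrt((nests$cy - dis$cy[i])^2 + (nests$cx - dis$cx[i])^2)
    expect_true(all(d >= nests$r + dis$r[i] + ph$spec$clearance))
    # truth never intersects a distractor's disk
    for (y in max(1, floor(dis$cy[i] - dis$r[i])):min(260, ceiling(dis$cy[i] + dis$r[i])))
      for (x in max(1, floor(dis$cx[i] - dis$r[i])):min(300, ceiling(dis$cx[i] + dis$r[i]))) {
        if ((y - dis$cy[i])^2 + (x - dis$cx[i])^2 <= dis$r[i]^2) {
          expect_false(ph$truth[y, x])
        }
      }
  }
})

test_that("impossible placements raise a placement error", {
  expect_error(
    generate_phantom(phantom_spec(width = 80, height = 80, n_nests = 6,
                                  nest_radius_range = c(30, 30), seed = 1)),
    "could not place", class = "chromaseg_placement_error")
})

test_that("phantom_spec validates nest and distractor size ranges", {
  expect_error(phantom_spec(nest_radius_range = c(10, 20)),
               class = "chromaseg_argument_error")
  expect_error(phantom_spec(n_distractors = 5,
                            distractor_radius_range = c(5, 20)),
               class = "chromaseg_argument_error")
})

test_that("generate_suite cycles presets deterministically", {
  base <- phantom_spec(width = test_frame$width, height = test_frame$height)
  s1 <- generate_suite(3, base, seed = 17)
  s2 <- generate_suite(3, base, seed = 17)
  expect_identical(vapply(s1, `[[`, "", "subtype"),
                   c("nodular-like", "superficial-like", "infiltrative-like"))
  for (i in 1:3) {
    expect_identical(s1[[i]]$image, s2[[i]]$image)
    expect_identical(s1[[i]]$truth, s2[[i]]$truth)
  }

  # every nodular-like truth component exceeds the 750 px cutoff, and all
  # distractor components (outside truth) are below it
  nod <- s1[[1]]
  expect_true(all(label_components(nod$truth)$areas > 750))
  sup <- s1[[2]]
  dis <- sup$placements[sup$placements$kind == "distractor", ]
  expect_gt(nrow(dis), 0)
  expect_true(all(pi * dis$r^2 < 750))
})
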