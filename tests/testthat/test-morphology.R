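test_that("remove_outliers is inert on uniform masks and kills speckle", {
  full <- matrix(TRUE, 9, 9)
  none <- matrix(FALSE, 9, 9)
  for (mode in c("bright", "dark")) {
    expect_identical(remove_outliers(full, 2, 50, mode), full)
    expect_identical(remove_outliers(none, 2, 50, mode), none)
  }

  # a single isolated foreground pixel: removed in bright mode (median 0,
  # deviation 255 > 50), untouched in dark mode
  speck <- matrix(FALSE, 11, 11); speck[6, 6] <- TRUE
  expect_identical(remove_outliers(speck, 2, 50, "bright"),
                   matrix(FALSE, 11, 11))
  expect_identical(remove_outliers(speck, 2, 50, "dark"), speck)

  # the symmetric case: a single hole in solid foreground is filled in dark
  # mode and untouched in bright mode
  hole <- matrix(TRUE, 11, 11); hole[6, 6] <- FALSE
  expect_identical(remove_outliers(hole, 2, 50, "dark"), matrix(TRUE, 11, 11))
  expect_identical(remove_outliers(hole, 2, 50, "bright"), hole)
})

test_that("remove_outliers changes only pixels deviating from the local median", {
  set.seed(31)
  for (i in 1:20) {
    m <- rand_mask(24, 31, runif(1, 0.2, 0.8))
    rad <- sample(1:3, 1)
    out <- remove_outliers(m, rad, 50, sample(c("bright", "dark"), 1))
    changed <- which(out != m)
    if (length(changed) == 0) next
    # recompute the neighborhood median independently at changed pixels
    for (idx in changed[seq_len(min(10, length(changed)))]) {
      y <- (idx - 1) %% 24 + 1; x <- (idx - 1) %/% 24 + 1
      vals <- c()
      for (dy in -rad:rad) for (dx in -rad:rad) {
        if (dy^2 + dx^2 > rad^2) next
        ny <- y + dy; nx <- x + dx
        if (ny >= 1 && ny <= 24 && nx >= 1 && nx <= 31) {
          vals <- c(vals, m[ny, nx] * 255)
        }
      }
      expect_gt(abs(m[y, x] * 255 - median(vals)), 50)
    }
  }
})

test_that("binary_close fills sub-element holes and matches the set oracle", {
  expect_identical(binary_close(matrix(FALSE, 8, 8), 1, 1), matrix(FALSE, 8, 8))

  sq <- matrix(FALSE, 9, 9); sq[3:7, 3:7] <- TRUE
  holed <- sq; holed[5, 5] <- FALSE
  expect_identical(binary_close(holed, 1, 1), sq)

  set.seed(32)
  for (i in 1:25) {
    m <- rand_mask(64, 64, runif(1, 0.1, 0.9))
    k <- sample(1:2, 1); it <- sample(1:2, 1)
    expect_identical(binary_close(m, k, it), oracle_close(m, k, it))
  }
})

test_that("binary_close is extensive, idempotent and border-safe", {
  set.seed(33)
  for (i in 1:12) {
    m <- rand_mask(40, 40, 0.4)
    cl <- binary_close(m, 1, 1)
    expect_true(all(cl[m]))                      # extensive everywhere
    expect_identical(binary_close(cl, 1, 1), cl) # idempotent
  }
  # closing never shrinks foreground at the border
  edge <- matrix(FALSE, 10, 10); edge[1, ] <- TRUE
  expect_true(all(binary_close(edge, 2, 1)[1, ]))
})

test_that("repair_mask composes the three stages in order", {
  p <- morphology_params(bright_radius = 2, dark_radius = 2)

  # one isolated speck and one 1-pixel hole inside a large nest
  m <- matrix(FALSE, 40, 40)
  m[10:30, 10:30] <- TRUE
  m[20, 20] <- FALSE        # hole
  m[3, 35] <- TRUE          # speck
  out <- repair_mask(m, p)
  expect_false(out[3, 35])
  expect_true(out[20, 20])

  # a clean region whose boundary has no convex protrusions is unchanged;
  # convex corners of free-standing shapes are clipped by the median (the
  # known rim-erosion effect, see the methods vignette)
  band <- matrix(FALSE, 40, 40); band[10:30, ] <- TRUE
  expect_identical(mask_of(repair_mask(band, p)), band)
  clean <- matrix(FALSE, 40, 40); clean[10:30, 10:30] <- TRUE
  rep1 <- mask_of(repair_mask(clean, p))
  clipped <- which(clean & !rep1, arr.ind = TRUE)
  expect_identical(nrow(clipped), 4L)        # exactly the four corners
  expect_setequal(paste(clipped[, 1], clipped[, 2]),
                  c("10 10", "10 30", "30 10", "30 30"))
  expect_false(any(rep1 & !clean))           # and nothing is added

  # equals the manual composition of the three stages
  set.seed(34)
  for (i in 1:8) {
    m <- rand_mask(48, 37, runif(1, 0.2, 0.8))
    manual <- remove_outliers(m, p$bright_radius, p$bright_deviation, "bright")
    manual <- binary_close(manual, p$close_se_halfwidth, p$close_iterations)
    manual <- remove_outliers(manual, p$dark_radius, p$dark_deviation, "dark")
    expect_identical(mask_of(repair_mask(m, p)), manual)
  }

  # stage-change log is present and consistent
  log <- attr(repair_mask(m, p), "stage_changes")
  expect_named(log, c("bright_outliers", "binary_close", "dark_outliers"))
})

test_that("morphology_params validates its fields", {
  expect_error(morphology_params(bright_radius = 0))
  expect_error(morphology_params(bright_deviation = 300))
  expect_error(morphology_params(close_iterations = 0))
})
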