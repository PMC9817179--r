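test_that("projection collapses z as documented", {
  plane <- matrix(runif(64), 8, 8)
  expect_equal(project(plane, "max"), plane)
  expect_equal(project(plane, "sum"), plane)
  two <- array(c(rep(1, 64), rep(3, 64)), dim = c(8, 8, 2))
  expect_equal(project(two, "max"), matrix(3, 8, 8))
  expect_equal(project(two, "sum"), matrix(4, 8, 8))
  st <- array(runif(8 * 8 * 4), dim = c(8, 8, 4))
  expect_equal(sum(project(st, "sum")), sum(st))
  expect_error(project(st, "median"), "arg")
  st[1] <- -1
  expect_error(project(st, "max"), ">= 0")
})

test_that("normalization gives unit nuclear intensity and scale invariance", {
  mask <- matrix(FALSE, 10, 10); mask[3:8, 3:8] <- TRUE
  img <- matrix(5, 10, 10)
  norm <- normalize_to_mask(img, mask)
  expect_equal(sum(norm[mask]), 1, tolerance = 1e-12)
  expect_true(all(norm[mask] == 1 / sum(mask)))
  expect_true(all(norm[!mask] == 0))
  img2 <- matrix(runif(100), 10, 10)
  expect_equal(normalize_to_mask(img2 * 10, mask),
               normalize_to_mask(img2, mask))
  expect_error(normalize_to_mask(matrix(0, 10, 10), mask), "zero")
})

test_that("surface roughness follows the population-sd definition", {
  mask <- matrix(TRUE, 6, 6)
  expect_equal(surface_roughness(matrix(2, 6, 6), mask), 0)
  img <- matrix(c(rep(1, 18), rep(5, 18)), 6, 6)
  expect_equal(surface_roughness(img, mask), 2)  # |a - b| / 2
  expect_error(surface_roughness(matrix(1, 1, 1), matrix(TRUE, 1, 1)),
               "2 pixels")
  # monotone in punctum amplitude on clean planted images
  rough <- vapply(c(0.5, 1, 2, 4), function(a) {
    im <- gaussian_image(48, 48, c(24, 24), sigma = 2, amplitude = a,
                         background = 1)
    surface_roughness(normalize_to_mask(im, mask = matrix(TRUE, 48, 48)),
                      matrix(TRUE, 48, 48))
  }, numeric(1))
  expect_true(all(diff(rough) > 0))
})

test_that("radial-slice FWHM matches Gaussian theory within 2%", {
  img <- gaussian_image(64, 64, c(32, 32), sigma = 3)
  p <- refine_center_and_fwhm(img, c(32, 32))
  expect_equal(p$fwhm, 2 * sqrt(2 * log(2)) * 3, tolerance = 0.02)
  expect_true(p$resolved)
  # elliptical punctum: the maximum over slices is the major-axis width
  ell <- gaussian_image(64, 64, c(32, 32), sigma = c(4, 2))
  pe <- refine_center_and_fwhm(ell, c(32, 32))
  expect_equal(pe$fwhm, 2 * sqrt(2 * log(2)) * 4, tolerance = 0.02)
  expect_equal(pe$angle, 90)  # widest slice runs along y
  # a symmetric peak on an integer pixel refines onto itself
  expect_lt(max(abs(p$refined_center - c(32, 32))), 0.5)
  # an off-center preliminary pixel is pulled toward the center along the
  # winning slice (the perpendicular offset is not correctable)
  off <- refine_center_and_fwhm(img, c(34, 31))
  expect_lt(sqrt(sum((off$refined_center - c(32, 32))^2)),
            sqrt(sum((c(34, 31) - c(32, 32))^2)))
  # every slice of a featureless image is flat: flagged unresolved
  expect_warning(pu <- refine_center_and_fwhm(matrix(1, 32, 32),
                                              c(16, 16)),
                 "unresolved")
  expect_false(pu$resolved)
  expect_true(is.na(pu$fwhm))
})

test_that("punctate percentage equals the Gaussian encircled-energy value", {
  mask <- matrix(TRUE, 96, 96)
  img <- gaussian_image(96, 96, c(48, 48), sigma = 4)
  pu <- refine_center_and_fwhm(img, c(48, 48))
  # a disk of diameter FWHM captures exactly half the energy of a 2-D
  # Gaussian: 1 - exp(-(FWHM/2)^2 / (2 sigma^2)) = 1 - exp(-ln 2) = 1/2
  pp <- punctate_percentage(img, mask, list(pu))
  expect_equal(pp, 50, tolerance = 0.02 * 50)
  expect_equal(punctate_percentage(img, mask, list()), 0)
  # two identical well-separated puncta: numerator and denominator double
  img2 <- gaussian_image(96, 96, rbind(c(30, 30), c(66, 66)), sigma = 4)
  pu1 <- refine_center_and_fwhm(img2, c(30, 30))
  pu2 <- refine_center_and_fwhm(img2, c(66, 66))
  pp2 <- punctate_percentage(img2, mask, list(pu1, pu2))
  expect_equal(pp2, pp, tolerance = 0.01)
  # overlapping disks count once: duplicating a punctum changes nothing
  expect_equal(punctate_percentage(img, mask, list(pu, pu)), pp)
  expect_error(punctate_percentage(matrix(0, 8, 8), matrix(TRUE, 8, 8),
                                   list()), "zero total")
})

test_that("full quantification is invariant to intensity scaling", {
  out <- make_nucleus_stack(synthetic_image_spec(seed = 3))
  q1 <- quantify_puncta(out$stack, out$mask, 2e-4)
  q2 <- quantify_puncta(out$stack * 7.3, out$mask, 2e-4)
  expect_equal(q1$n_puncta, q2$n_puncta)
  expect_equal(q1$surface_roughness, q2$surface_roughness,
               tolerance = 1e-10)
  expect_equal(q1$punctate_percentage, q2$punctate_percentage,
               tolerance = 1e-10)
  expect_equal(q1$n_puncta, 12L)
  expect_true(q1$punctate_percentage >= 0 && q1$punctate_percentage <= 100)
})

test_that("paired comparison reports percent and absolute changes", {
  fake_quant <- function(n, rough, pp, tol = 1) {
    structure(list(n_puncta = n, surface_roughness = rough,
                   punctate_percentage = pp, puncta = list(),
                   noise_tolerance = tol), class = "puncta_quant")
  }
  ch <- compare_live_fixed(fake_quant(20, 0.5, 30), fake_quant(30, 0.26, 45))
  expect_equal(ch$percent_change[ch$parameter == "n_puncta"], 50)
  expect_equal(ch$percent_change[ch$parameter == "surface_roughness"],
               -48)
  expect_equal(ch$absolute_change[ch$parameter == "punctate_percentage"],
               15)
  # zero-live parameter: percent change undefined but absolute reported
  ch0 <- compare_live_fixed(fake_quant(0, 0.5, 0), fake_quant(4, 0.5, 10))
  row <- ch0[ch0$parameter == "n_puncta", ]
  expect_false(row$percent_valid)
  expect_true(is.na(row$percent_change))
  expect_equal(row$absolute_change, 4)
  expect_error(compare_live_fixed(fake_quant(1, 1, 1, tol = 1),
                                  fake_quant(1, 1, 1, tol = 2)),
               "noise tolerance")
})

test_that("otsu helper separates bright nuclei from background", {
  img <- matrix(0.1, 40, 40)
  img[10:30, 10:30] <- 0.9
  m <- mask_from_otsu(img)
  expect_true(all(m[15:25, 15:25]))
  expect_false(any(m[1:5, 1:5]))
  expect_false(any(mask_from_otsu(matrix(1, 8, 8))))
})
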