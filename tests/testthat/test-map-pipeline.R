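test_that("phantom construction honours its stated geometry and T2 range", {
  ph <- make_phantom(shape = c(32, 32), sigma = 40, seed = 61)
  truth <- ph$truth
  expect_s3_class(truth, "quant_map")
  expect_equal(truth$te, seq(10, 70, by = 10))
  t2_in <- truth$t2[truth$mask]
  expect_gte(min(t2_in), 20)
  expect_lte(max(t2_in), 60)
  expect_true(all(is.na(truth$t2[!truth$mask])))
  # same seed, same stack
  ph2 <- make_phantom(shape = c(32, 32), sigma = 40, seed = 61)
  expect_identical(ph2$noisy$stack, ph$noisy$stack)
  expect_error(make_phantom(shape = c(8, 8)), class = "t2relax_invalid_input")
})

test_that("noise-free phantom round trip recovers truth for every LSE fitter", {
  ph <- make_phantom(shape = c(16, 16))
  for (m in c("lse", "olse", "nclse")) {
    fit <- fit_map(ph$noisy, m, sigma = if (m == "nclse") 0 else NULL)
    err <- abs(fit$t2[fit$mask] - ph$truth$t2[ph$truth$mask])
    expect_lt(max(err / ph$truth$t2[ph$truth$mask]), 1e-6)
    expect_true(all(is.na(fit$t2[!fit$mask])))
  }
})

test_that("map fitting is mask-equivariant", {
  ph <- make_phantom(shape = c(16, 16), sigma = 60, seed = 62)
  full <- fit_map(ph$noisy, "lse")
  sub <- ph$noisy$mask
  keep <- which(sub)[1:5]
  sub[] <- FALSE
  sub[keep] <- TRUE
  qm_sub <- quant_map(ph$noisy$stack, ph$noisy$te, sub, sigma = ph$noisy$sigma)
  fit_sub <- fit_map(qm_sub, "lse")
  expect_equal(fit_sub$t2[sub], full$t2[sub])
  expect_equal(sum(!is.na(fit_sub$t2)), 5)
})

test_that("reference comparison yields zero against itself and correct single-voxel RQE", {
  ph <- make_phantom(shape = c(16, 16), sigma = 30, seed = 63)
  f <- fit_map(ph$noisy, "lse")
  self <- compare_to_reference(f, f)
  expect_true(all(self$rqe == 0))
  expect_true(all(self$arqe == 0))
  # one-voxel maps: prediction 62 against reference 50 is +24%
  mk <- function(val) {
    m <- matrix(NA_real_, 16, 16); m[8, 8] <- val
    mask <- matrix(FALSE, 16, 16); mask[8, 8] <- TRUE
    qm <- quant_map(array(1, c(16, 16, 2)), c(10, 20), mask, t2 = m)
    qm
  }
  cmp <- compare_to_reference(mk(62), mk(50))
  expect_equal(nrow(cmp), 1)
  expect_equal(cmp$rqe, 24)
  # mask mismatch is an error
  other <- mk(50); other$mask[1, 1] <- TRUE
  expect_error(compare_to_reference(mk(62), other),
               class = "t2relax_invalid_input")
})

test_that("low-SNR phantom: noise-corrected map beats the traditional map", {
  # per-voxel SNR 5 inside the band
  ph <- make_phantom(shape = c(24, 24), s0_level = 500, sigma = 100, seed = 64)
  truth <- ph$truth
  med_arqe <- function(fit) {
    median(arqe(fit$t2[fit$mask], truth$t2[truth$mask]))
  }
  lse <- fit_map(ph$noisy, "lse")
  nclse <- fit_map(ph$noisy, "nclse", sigma = 100)
  expect_lt(med_arqe(nclse), med_arqe(lse))
})

test_that("NIfTI round trips preserve shape and values", {
  ph <- make_phantom(shape = c(16, 16), sigma = 20, seed = 65)
  dir <- withr::local_tempdir()
  write_echo_stack(ph$noisy, dir)
  back <- read_echo_stack(file.path(dir, "stack.nii.gz"),
                          file.path(dir, "tes.json"),
                          file.path(dir, "mask.nii.gz"))
  expect_equal(back$stack, ph$noisy$stack, tolerance = 1e-7)
  expect_identical(back$mask, ph$noisy$mask)
  expect_equal(back$te, ph$noisy$te)
  fit <- fit_map(ph$noisy, "lse")
  write_quant_map(fit, dir)
  t2_back <- as.array(RNifti::readNifti(file.path(dir, "T2.nii.gz")))
  expect_equal(matrix(t2_back, 16, 16)[fit$mask], fit$t2[fit$mask],
               tolerance = 1e-7)
})

test_that("timing harness reports one mean per requested method", {
  ph <- make_phantom(shape = c(16, 16), sigma = 10, seed = 66)
  tm <- timing_harness(ph$noisy, c("lse", "olse"), repeats = 2)
  expect_equal(tm$method, c("lse", "olse"))
  expect_equal(tm$repeats, c(2, 2))
  expect_true(all(tm$mean_seconds >= 0))
  empty <- timing_harness(ph$noisy, character(0), repeats = 1)
  expect_equal(nrow(empty), 0)
})

test_that("fitted maps stay within bounds and flag unknown methods", {
  ph <- make_phantom(shape = c(16, 16), sigma = 80, seed = 67)
  fit <- fit_map(ph$noisy, "olse")
  vals <- fit$t2[fit$mask]
  expect_true(all(vals >= 5 & vals <= 500))
  expect_error(fit_map(ph$noisy, "bogus"))
  # empty mask rejected
  qm <- quant_map(ph$noisy$stack, ph$noisy$te,
                  matrix(FALSE, 16, 16))
  expect_error(fit_map(qm, "lse"), class = "t2relax_invalid_input")
})
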