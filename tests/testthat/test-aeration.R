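test_that("gas fraction is HU / -1000 clipped to [0, 1]", {
  expect_equal(gas_fraction(-1000), 1)
  expect_equal(gas_fraction(-500), 0.5)
  expect_equal(gas_fraction(60), 0)
  expect_equal(gas_fraction(-1024), 1)
  expect_error(gas_fraction(NA), "non-finite")
  # monotone non-increasing in HU
  hu <- seq(-1100, 200, by = 7)
  expect_true(all(diff(gas_fraction(hu)) <= 0))
})

test_that("aeration classes use left-closed HU bins", {
  expect_equal(as.character(classify_aeration(c(-950, -900, -500, -100, -50, 0))),
               c("hyper", "normal", "poor", "non", "non", "non"))
  expect_equal(as.character(classify_aeration(-501)), "normal")
  expect_equal(as.character(classify_aeration(-101)), "poor")
})

test_that("uniform volumes give the closed-form mass and gas volume", {
  # 1000 voxels of -500 HU at 1 mm^3: mass 0.5 g, gas volume 0.5 ml
  s <- summarize_aeration(rep(-500, 1000))
  expect_equal(s$total_mass_g, 0.5)
  expect_equal(s$gas_volume_ml, 0.5)
  expect_equal(s$lung_volume_ml, 1)
  expect_equal(unname(s$relative_mass_pct["poor"]), 100)

  # all gas: zero mass, gas volume equals anatomical volume
  sg <- summarize_aeration(rep(-1000, 500), voxel_dims_mm = c(2, 1, 1))
  expect_equal(sg$total_mass_g, 0)
  expect_equal(sg$gas_volume_ml, sg$lung_volume_ml)
  expect_true(all(is.na(sg$relative_mass_pct)))
})

test_that("masks select voxels and empty masks fail", {
  hu <- c(-1000, -1000, 0, 0)
  s <- summarize_aeration(hu, mask = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(s$n_voxels, 2)
  expect_equal(s$gas_volume_ml, 0)
  expect_error(summarize_aeration(hu, mask = rep(FALSE, 4)), "empty mask")
  expect_error(summarize_aeration(hu, mask = c(TRUE, TRUE)), "mismatch")
})

test_that("compartment partition is exhaustive and closed", {
  ct <- simulate_ct(n_voxels = 5e4, seed = 2)
  s <- summarize_aeration(ct$hu, ct$mask)
  expect_equal(sum(s$mass_g), s$total_mass_g, tolerance = 1e-12)
  expect_equal(sum(s$relative_mass_pct), 100, tolerance = 1e-9)
  expect_equal(s$net_aerated_pct,
               100 - unname(s$relative_mass_pct["non"]), tolerance = 1e-9)
  expect_lte(s$gas_volume_ml, s$lung_volume_ml)
  # generator labels agree with the classifier on every voxel
  expect_equal(as.character(classify_aeration(ct$hu)),
               as.character(ct$labels))
})

test_that("simulated mixtures recover the target mass fractions", {
  ct <- simulate_ct(fractions = c(0.005, 0.60, 0.25, 0.145),
                    n_voxels = 2e5, seed = 7)
  s <- summarize_aeration(ct$hu, ct$mask)
  expect_lt(max(abs(s$relative_mass_pct / 100 - ct$fractions)), 0.01)

  # 100 % normal compartment reports 100 % normal
  s1 <- summarize_aeration(simulate_ct(c(0, 1, 0, 0), 1e4, seed = 1)$hu)
  expect_equal(unname(s1$relative_mass_pct["normal"]), 100)
})

test_that("relative masses are invariant to voxel rescaling, masses are not", {
  ct <- simulate_ct(n_voxels = 2e4, seed = 9)
  s1 <- summarize_aeration(ct$hu, voxel_dims_mm = c(1, 1, 1))
  s2 <- summarize_aeration(ct$hu, voxel_dims_mm = c(2, 1, 1))
  expect_equal(s2$relative_mass_pct, s1$relative_mass_pct)
  expect_equal(s2$total_mass_g, 2 * s1$total_mass_g)
  expect_equal(s2$gas_volume_ml, 2 * s1$gas_volume_ml)
})

test_that("aeration differences are second minus first per field", {
  a <- summarize_aeration(rep(-500, 1000))
  b <- summarize_aeration(rep(-600, 1000))
  d <- delta_aeration(a, b)
  expect_equal(d$total_mass_g, 0.4 - 0.5)
  expect_equal(d$gas_volume_ml, 0.6 - 0.5)
  z <- delta_aeration(a, a)
  expect_equal(z$total_mass_g, 0)
  expect_true(all(unlist(z$mass_g) == 0))
})

test_that("histogram input and NIfTI round-trip match the voxel path", {
  hu <- c(rep(-900, 10), rep(-300, 5), rep(0, 3))
  s_hist <- summarize_aeration_hist(c(-900, -300, 0), c(10, 5, 3))
  s_vox <- summarize_aeration(hu)
  expect_equal(s_hist$mass_g, s_vox$mass_g)

  ctdir <- withr::local_tempdir()
  arr <- array(rep(c(-800, -200), 32), dim = c(4, 4, 4))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1.5, 1.5, 2)
  RNifti::writeNifti(img, file.path(ctdir, "ct.nii.gz"))
  mask <- RNifti::asNifti(array(1L, dim = c(4, 4, 4)))
  RNifti::pixdim(mask) <- c(1.5, 1.5, 2)
  RNifti::writeNifti(mask, file.path(ctdir, "mask.nii.gz"))
  v <- read_ct_nifti(file.path(ctdir, "ct.nii.gz"),
                     file.path(ctdir, "mask.nii.gz"))
  s <- summarize_aeration(v$hu, v$mask, v$voxel_dims_mm)
  expect_equal(s$n_voxels, 64)
  expect_equal(s$lung_volume_ml, 64 * 1.5 * 1.5 * 2 / 1000)
})
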