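# The phantom generator's analytic ground truth and its contracts.

test_that("cluster-class ground truth respects the 120 mm3 boundary", {
  lobes <- default_lobe_layout(c(30, 36, 40))
  mid <- function(nm) vapply(lobes[[nm]], mean, numeric(1))
  # 5x5x5 = 125 mm3 (> 120, counts); 4x4x4 = 64 mm3 (does not)
  spec <- phantom_spec(
    emphysema = list(list(center = mid("RUL"), size = c(5, 5, 5)),
                     list(center = mid("LLL"), size = c(4, 4, 4))))
  ph <- generate_phantom(spec)
  tr <- ph$truth$regions
  n_lung <- tr$lung$voxel_count
  expect_equal(tr$lung$ei_pct, 100 * (125 + 64) / n_lung)
  expect_equal(tr$lung$ei_cc120_pct, 100 * 125 / n_lung)
  expect_equal(tr$lung$bi_pct, 0)
  # per-lobe: the RUL cluster qualifies, the LLL one does not
  expect_equal(tr$RUL$ei_cc120_pct, 100 * 125 / tr$RUL$voxel_count)
  expect_equal(tr$LLL$ei_cc120_pct, 0)
  expect_equal(tr$LLL$ei_pct, 100 * 64 / tr$LLL$voxel_count)

  # the measurement pipeline reproduces the constructed truth
  pr <- region_profile(ph$ct, ph$labels, "lung")
  expect_equal(pr$ei_pct, tr$lung$ei_pct)
  expect_equal(pr$ei_cc120_pct, tr$lung$ei_cc120_pct)
})

test_that("zero-emphysema phantom has EI 0 and missing pEI", {
  ph <- generate_phantom(phantom_spec())
  expect_equal(ph$truth$regions$lung$ei_pct, 0)
  expect_true(is.na(ph$truth$regions$lung$pei_pct))
  pr <- region_profile(ph$ct, ph$labels, "lung")
  expect_equal(pr$ei_pct, 0)
  expect_true(is.na(pr$pei_pct))
})

test_that("overlapping compartments raise a collision error", {
  lobes <- default_lobe_layout(c(30, 36, 40))
  mid <- vapply(lobes$RML, mean, numeric(1))
  spec <- phantom_spec(
    emphysema = list(list(center = mid, size = c(5, 5, 5)),
                     list(center = mid + 1, size = c(5, 5, 5))))
  expect_error(generate_phantom(spec), "collision")
  # out-of-band HU is rejected up front
  expect_error(
    generate_phantom(phantom_spec(
      emphysema = list(list(center = mid, size = c(3, 3, 3), hu = -900)))),
    "-950")
})

test_that("phantom generation is deterministic given the seed", {
  a <- generate_phantom(random_phantom_spec(5, noise_sd = 8))
  b <- generate_phantom(random_phantom_spec(5, noise_sd = 8))
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$labels$labels, b$labels$labels)
  expect_identical(a$truth$regions, b$truth$regions)
})

test_that("threshold-safe noise moves no voxel across a class threshold", {
  clean <- generate_phantom(random_phantom_spec(13, noise_sd = 0))
  noisy <- generate_phantom(random_phantom_spec(13, noise_sd = 12))
  expect_identical(clean$labels$labels, noisy$labels$labels)
  prn <- region_profile(noisy$ct, noisy$labels, "lung",
                        nodule_lobe = noisy$truth$nodule_lobe)
  tr <- clean$truth$regions$lung
  # class counts (hence all index percentages) stay exact under noise
  expect_equal(prn$ei_pct, tr$ei_pct)
  expect_equal(prn$ggoi_pct, tr$ggoi_pct)
  expect_equal(prn$fibi_pct, tr$fibi_pct)
  expect_equal(prn$ei_cc120_pct, tr$ei_cc120_pct)
  expect_equal(prn$pei_pct, tr$pei_pct)
  # MLD shifts, but within a few noise SDs of the noise-free mean
  expect_false(isTRUE(all.equal(prn$mld_hu, tr$mld_hu)))
  expect_lt(abs(prn$mld_hu - tr$mld_hu), 12)
})

test_that("ground-truth invariants hold on randomized phantoms", {
  for (seed in c(21, 22, 23)) {
    ph <- generate_phantom(random_phantom_spec(seed))
    tr <- ph$truth$regions
    lobe_n <- vapply(tr[c("RUL", "RML", "RLL", "LUL", "LLL")],
                     `[[`, numeric(1), "voxel_count")
    expect_equal(sum(lobe_n), tr$lung$voxel_count)
    for (r in tr) {
      pcts <- unlist(r[c("ei_pct", "ei_cc120_pct", "bi_pct", "ggoi_pct",
                         "fibi_pct")])
      expect_true(all(pcts >= 0 & pcts <= 100))
      expect_lte(r$ei_cc120_pct, r$ei_pct)
      expect_lte(r$bi_pct, r$ei_cc120_pct)
      expect_true(is.finite(r$perc15_hu))
    }
  }
})
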