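# Density metrics, cluster analysis, segmentation, zones, pEI, profiles.

test_that("density metrics on constant and two-value volumes", {
  ct <- as_ct(array(-780, c(10, 10, 10)))
  m <- array(TRUE, c(10, 10, 10))
  dm <- density_metrics(ct, m)
  expect_equal(dm$mld_hu, -780)
  expect_equal(dm$ei_pct, 0)
  expect_equal(dm$ggoi_pct, 100)
  expect_equal(dm$fibi_pct, 0)
  expect_equal(dm$perc15_hu, -780)
  expect_equal(dm$volume_ml, 1.0)

  v <- array(c(rep(-1000, 100), rep(-900, 900)), c(10, 10, 10))
  dm2 <- density_metrics(as_ct(v), m)
  expect_equal(dm2$ei_pct, 10.0)
  expect_equal(dm2$mld_hu, -910)
  expect_equal(dm2$perc15_hu, -900)

  expect_error(density_metrics(ct, array(FALSE, c(10, 10, 10))), "empty")
})

test_that("density metrics match the brute-force oracle on random grids", {
  set.seed(31)
  for (i in 1:5) {
    v <- array(sample(seq(-1050, 200, by = 10), 20^3, TRUE), c(20, 20, 20))
    m <- array(runif(20^3) < 0.8, c(20, 20, 20))
    got <- density_metrics(as_ct(v), m)
    want <- oracle_density(v, m, c(1, 1, 1))
    for (k in names(want)) expect_equal(got[[k]], want[[k]], info = k)
  }
})

test_that("cluster table: boundary algebra, connectivity, oracle match", {
  v <- array(-780, c(9, 25, 5))      # 1125-voxel lung
  v[3:7, 3:7, 1:5] <- -980           # one 5x5x5 cluster
  ct <- as_ct(v)
  m <- array(TRUE, dim(v))
  cm <- cluster_metrics(ct, m)
  expect_equal(nrow(cm$clusters), 1)
  expect_equal(cm$clusters$voxel_count, 125)
  expect_equal(cm$ei_cc120_pct, 100 * 125 / 1125)
  expect_equal(cm$bi_pct, 0)

  # diagonal touch: one cluster under 26-connectivity, two under 6
  v2 <- array(-800, c(5, 5, 5))
  v2[2, 2, 2] <- -980
  v2[3, 3, 3] <- -980
  m2 <- array(TRUE, c(5, 5, 5))
  expect_equal(nrow(cluster_metrics(as_ct(v2), m2)$clusters), 1)
  expect_equal(nrow(cluster_metrics(as_ct(v2), m2, connectivity = 6L)$clusters), 2)
})

test_that("cluster labelling equals flood-fill oracle on sparse grids", {
  set.seed(41)
  for (i in 1:10) {
    v <- array(ifelse(runif(12^3) < 0.2, -980, -800), c(12, 12, 12))
    m <- array(TRUE, c(12, 12, 12))
    got <- sort(cluster_metrics(as_ct(v), m)$clusters$voxel_count,
                decreasing = TRUE)
    want <- oracle_cluster_table(v, m, c(1, 1, 1))$voxel_count
    expect_equal(got, want)
  }
})

test_that("EI monotonicity: lowering HU or adding emphysema never lowers EI", {
  set.seed(43)
  v <- array(sample(seq(-1000, -700, 25), 10^3, TRUE), c(10, 10, 10))
  m <- array(TRUE, c(10, 10, 10))
  base <- density_metrics(as_ct(v), m)$ei_pct
  v2 <- v
  v2[v2 > -1050] <- v2[v2 > -1050] - 60
  expect_gte(density_metrics(as_ct(v2), m)$ei_pct, base)
})

test_that("threshold segmentation recovers the phantom lung and fills holes", {
  ph <- generate_phantom(random_phantom_spec(17))
  mask <- segment_lungs(ph$ct)
  want <- array(ph$labels$labels %in% c(1:5, 8L), dim(ph$labels$labels))
  expect_identical(mask, want)

  expect_error(segment_lungs(as_ct(array(-1000, c(8, 8, 8)))), "no lung")

  # a small dense inclusion inside the lung is filled into the mask
  ph2 <- generate_phantom(phantom_spec())
  v <- ph2$ct$values
  lungvox <- which(ph2$labels$labels == 1L, arr.ind = TRUE)
  cz <- round(colMeans(lungvox))
  v[cz[1], cz[2], cz[3] + (0:2)] <- 50
  mask2 <- segment_lungs(ct_volume(v, ph2$ct$spacing_mm))
  expect_identical(mask2, array(ph2$labels$labels %in% 1:5,
                                dim(ph2$labels$labels)))
})

test_that("zone partition: cube fractions, oracle distances, symmetry", {
  m <- array(FALSE, c(12, 12, 12))
  m[2:11, 2:11, 2:11] <- TRUE       # 10^3 cube with background margin
  zp <- partition_zones(m, c(1, 1, 1))
  pf <- zp$n_peripheral / sum(m)
  d <- distance_to_boundary(m, c(1, 1, 1))
  tie_share <- mean(d[m] == zp$cutoff_mm)
  expect_gte(pf, 0.50)
  expect_lte(pf, 0.50 + tie_share)
  # cube shells have integer distances 1..5; median 2 -> outer two shells
  # (488 + 296 of 1000 voxels) are peripheral, ties included
  expect_equal(pf, 0.784)
  # distances agree with the brute-force oracle
  expect_equal(distance_to_boundary(m, c(1, 1, 1)), oracle_edt(m, c(1, 1, 1)),
               tolerance = 1e-12)

  # single-voxel lung is peripheral
  m1 <- array(FALSE, c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  zp1 <- partition_zones(m1, c(1, 1, 1))
  expect_equal(zp1$zones[2, 2, 2], 2L)

  # two disjoint equal cubes get identical cutoffs
  m2 <- array(FALSE, c(8, 8, 18))
  m2[2:7, 2:7, 2:7] <- TRUE
  m2[2:7, 2:7, 11:16] <- TRUE
  zp2 <- partition_zones(m2, c(1, 1, 1))
  expect_equal(length(zp2$cutoff_mm), 2)
  expect_equal(zp2$cutoff_mm[1], zp2$cutoff_mm[2])

  expect_error(partition_zones(array(FALSE, c(3, 3, 3)), c(1, 1, 1)), "empty")
})

test_that("anisotropic distance transform matches the oracle", {
  set.seed(47)
  m <- array(runif(10 * 9 * 8) < 0.7, c(10, 9, 8))
  sp <- c(2.5, 0.7, 1.3)
  expect_equal(distance_to_boundary(m, sp), oracle_edt(m, sp),
               tolerance = 1e-12)
})

test_that("peripheral emphysema index counts the peripheral share", {
  v <- array(-780, c(6, 6, 6))
  m <- array(TRUE, c(6, 6, 6))
  # 10 emphysema voxels along one line
  v[1, 1, 1:6] <- -980
  v[2, 1, 1:4] <- -980
  zones <- structure(list(zones = array(1L, c(6, 6, 6)), cutoff_mm = 0,
                          n_central = 0, n_peripheral = 0),
                     class = "zone_partition")
  zones$zones[1, , ] <- 2L          # z = 1 plane: 6 of the 10 peripheral
  zones$zones[1, 1, 5:6] <- 1L      # retract 2: 4 of 10 peripheral
  expect_equal(peripheral_emphysema_index(as_ct(v), m, zones), 40)

  zones$zones[] <- 2L
  expect_equal(peripheral_emphysema_index(as_ct(v), m, zones), 100)

  v0 <- array(-780, c(6, 6, 6))
  expect_true(is.na(peripheral_emphysema_index(as_ct(v0), m, zones)))

  zbad <- zones; zbad$zones <- zbad$zones[1:5, , ]
  dim(zbad$zones) <- c(5, 6, 6)
  expect_error(peripheral_emphysema_index(as_ct(v), m, zbad), "shape")
})

test_that("profiles satisfy the partition and mixture identities", {
  ph <- generate_phantom(random_phantom_spec(19))
  nl <- ph$truth$nodule_lobe
  whole <- region_profile(ph$ct, ph$labels, "lung", nodule_lobe = nl)
  lobes <- lobe_profiles(ph$ct, ph$labels, nodule_lobe = nl)
  w <- vapply(lobes, `[[`, numeric(1), "voxel_count")
  expect_equal(sum(w), whole$voxel_count)
  expect_equal(sum(vapply(lobes, `[[`, numeric(1), "volume_ml")),
               whole$volume_ml)
  for (k in c("mld_hu", "ei_pct", "ggoi_pct", "fibi_pct")) {
    mix <- sum(w * vapply(lobes, `[[`, numeric(1), k)) / sum(w)
    expect_equal(mix, whole[[k]], tolerance = 1e-9, info = k)
  }
  expect_lte(whole$perc15_hu, quantile(ph$ct$values[
    array(ph$labels$labels %in% c(1:5, 8), dim(ph$ct$values))], 0.5))
  expect_error(region_profile(ph$ct, ph$labels, 7), "lobe")
})

test_that("nodule voxels are included by default and excludable by flag", {
  ph <- generate_phantom(random_phantom_spec(29))
  nl <- ph$truth$nodule_lobe
  expect_false(is.na(nl))
  with_nod <- region_profile(ph$ct, ph$labels, "lung")
  without <- region_profile(ph$ct, ph$labels, "lung", exclude_nodule = TRUE)
  n_nod <- sum(ph$labels$labels == 8L)
  expect_gt(n_nod, 0)
  expect_equal(with_nod$voxel_count - without$voxel_count, n_nod)
  # nodule at -50 HU adds to the fibrosis band
  expect_gt(with_nod$fibi_pct, without$fibi_pct)
})
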