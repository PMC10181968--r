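# Airway cross-section measurement, wall percentage, Pi10.

test_that("voxelized annulus measurements approach the closed form", {
  ap <- generate_airway_phantom(list(airway_tube(c(7, 7), 2, 1)),
                                shape = c(6, 60, 60),
                                spacing_mm = c(1, 0.25, 0.25))
  m <- measure_airways(ap$ct, ap$labels)
  expect_equal(nrow(m), 1)
  expect_lt(abs(m$lumen_area_mm2 - 4 * pi) / (4 * pi), 0.05)
  wp <- wall_percentage(m)
  expect_lt(abs(wp - 500 / 9) / (500 / 9), 0.05)
})

test_that("two identical tubes give identical measurements", {
  tubes <- list(airway_tube(c(5, 5), 1.5, 0.8),
                airway_tube(c(5, 11), 1.5, 0.8))
  ap <- generate_airway_phantom(tubes, shape = c(5, 40, 64),
                                spacing_mm = c(1, 0.25, 0.25))
  m <- measure_airways(ap$ct, ap$labels)
  expect_equal(nrow(m), 2)
  for (k in c("lumen_area_mm2", "wall_area_mm2", "internal_perimeter_mm",
              "wall_thickness_mm"))
    expect_equal(m[[k]][1], m[[k]][2], info = k)
})

test_that("tubes without wall labels are skipped with a warning", {
  ap <- generate_airway_phantom(list(airway_tube(c(7, 7), 2, 1)),
                                shape = c(4, 60, 60),
                                spacing_mm = c(1, 0.25, 0.25))
  lv <- ap$labels$labels
  lv[lv == 7L] <- 0L
  nl <- label_volume(lv, ap$labels$spacing_mm)
  expect_warning(m <- measure_airways(ap$ct, nl), "no wall")
  expect_equal(nrow(m), 0)

  empty <- label_volume(array(0L, dim(lv)), ap$labels$spacing_mm)
  expect_warning(m0 <- measure_airways(ap$ct, empty), "no airway")
  expect_equal(nrow(m0), 0)
})

test_that("generator geometry: annulus algebra and linear thickness lines", {
  # wall 5pi on lumen 4pi gives WP 55.56; thin-wall limit pushes WP to 0
  tubes <- list(airway_tube(c(6, 6), 2, 1), airway_tube(c(6, 14), 2, 0.01))
  ap <- generate_airway_phantom(tubes, shape = c(3, 48, 80),
                                spacing_mm = c(1, 0.25, 0.25))
  g <- ap$geometry
  expect_equal(g$lumen_area_mm2[1], 4 * pi)
  expect_equal(g$wall_area_mm2[1], 5 * pi)
  expect_equal(g$wp_pct[1], 500 / 9)
  expect_lt(g$wp_pct[2], 1)

  # tubes constructed with thickness linear in perimeter lie on that line
  radii <- c(1, 1.5, 2, 2.5)
  tl <- lapply(seq_along(radii), function(i)
    airway_tube(c(8, 8 + 10 * (i - 1)), radii[i], 0.5 + 0.1 * 2 * pi * radii[i]))
  apl <- generate_airway_phantom(tl, shape = c(3, 64, 184),
                                 spacing_mm = c(1, 0.25, 0.25))
  fitline <- lm(wall_thickness_mm ~ internal_perimeter_mm, apl$geometry)
  expect_equal(unname(coef(fitline)), c(0.5, 0.1), tolerance = 1e-9)
})

test_that("wall percentage filters early generations and averages the rest", {
  m <- data.frame(segment_id = 1:3, generation = c(1, 3, 4),
                  lumen_area_mm2 = c(50, 6, 6),
                  wall_area_mm2 = c(20, 4, 9),
                  internal_perimeter_mm = c(25, 9, 9),
                  wall_thickness_mm = c(0.8, 0.44, 1))
  expect_equal(wall_percentage(m), mean(c(100 * 4 / 10, 100 * 9 / 15)))
  expect_error(wall_percentage(m[m$generation < 3, ]), "eligible")
})

test_that("Pi10 recovers a generating line and matches the OLS oracle", {
  pi_mm <- c(6, 8, 10, 12, 14)
  m <- data.frame(internal_perimeter_mm = pi_mm,
                  wall_thickness_mm = 1.0 + 0.12 * pi_mm)
  p10 <- awt_pi10(m)
  expect_equal(as.numeric(p10), 0.22)
  expect_equal(attr(p10, "slope"), 0.12)

  set.seed(51)
  mn <- data.frame(internal_perimeter_mm = runif(50, 4, 20))
  mn$wall_thickness_mm <- 0.7 + 0.09 * mn$internal_perimeter_mm + rnorm(50, 0, 0.1)
  p <- awt_pi10(mn)
  ref <- lm(wall_thickness_mm ~ internal_perimeter_mm, mn)
  expect_equal(attr(p, "intercept_mm"), unname(coef(ref)[1]), tolerance = 1e-9)
  expect_equal(attr(p, "slope"), unname(coef(ref)[2]), tolerance = 1e-9)

  dup <- data.frame(internal_perimeter_mm = rep(10, 4),
                    wall_thickness_mm = rep(2, 4))
  expect_error(awt_pi10(dup), "variance")
  expect_error(awt_pi10(m[1, ]), "2 segments")
})
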