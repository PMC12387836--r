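test_that("HU classification maps the densitometric window correctly", {
  fx <- uniform_fixture(-750)
  cm <- classify_volume(fx$vol, fx$labels)
  expect_true(all(cm$classes == 1L))  # mid-window: all well-aerated

  # single extreme voxels
  hu <- array(-750, dim = c(4, 4, 4))
  hu[1, 1, 1] <- -950   # emphysematous
  hu[2, 1, 1] <- -200   # non-aerated
  tab <- data.frame(code = 1L, laterality = "right", lobe = "RUL", segment = "S1")
  labels <- lung_label_map(array(1L, dim = c(4, 4, 4)), tab)
  cm <- classify_volume(hu_volume(hu), labels)
  expect_identical(cm$classes[1, 1, 1], 2L)
  expect_identical(cm$classes[2, 1, 1], 3L)

  # boundary semantics: [-900, -501] well; below emph; above non-aerated
  hu_b <- array(c(-900, -501, -500.5, -500, -900.5, -750, -1000, -499),
                dim = c(8, 1, 1))
  labels_b <- lung_label_map(array(1L, dim = c(8, 1, 1)), tab)
  cm_b <- classify_volume(hu_volume(hu_b), labels_b)
  expect_identical(as.vector(cm_b$classes), c(1L, 1L, 3L, 3L, 2L, 1L, 2L, 3L))

  # background exactly where label map is 0
  lab0 <- array(1L, dim = c(4, 4, 4)); lab0[, , 1] <- 0L
  cm0 <- classify_volume(hu_volume(array(-750, dim = c(4, 4, 4))),
                         lung_label_map(lab0, tab))
  expect_true(all(cm0$classes[, , 1] == 0L))
  expect_true(all(cm0$classes[, , -1] == 1L))
})

test_that("classification reproduces exact constructed class counts", {
  # 70,000 / 20,000 / 10,000 voxels at -750 / -950 / -200 HU
  vals <- c(rep(-750, 70000), rep(-950, 20000), rep(-200, 10000))
  hu <- array(vals, dim = c(100, 100, 10))
  tab <- data.frame(code = 1L, laterality = "right", lobe = "RUL", segment = "S1")
  labels <- lung_label_map(array(1L, dim = c(100, 100, 10)), tab)
  cm <- classify_volume(hu_volume(hu), labels)
  counts <- tabulate(cm$classes, nbins = 3L)
  expect_identical(counts, c(70000L, 20000L, 10000L))
})

test_that("classification rejects invalid inputs", {
  fx <- uniform_fixture(-750, dims = c(4, 4, 4))
  big <- lung_label_map(array(1L, dim = c(5, 4, 4)), fx$labels$table)
  expect_error(classify_volume(fx$vol, big), "same grid shape")
  expect_error(hu_volume(array(c(NA, rep(-750, 7)), dim = c(2, 2, 2))), "finite")
  expect_error(hu_volume(array(c(Inf, rep(-750, 7)), dim = c(2, 2, 2))), "finite")
  expect_error(classify_volume(fx$vol, fx$labels, theta_emph = -400,
                               theta_well_max = -500), "below")
})

test_that("region volumetrics convert voxel counts to mL and aggregate exactly", {
  # 10x10x10 at 1 mm: 1000 mm^3 = 1 mL, all well-aerated
  fx <- uniform_fixture(-750, dims = c(10, 10, 10))
  rv <- region_volumetrics(classify_volume(fx$vol, fx$labels), fx$labels, fx$vol)
  seg <- rv[rv$level == "segment", ]
  expect_equal(seg$volume_total_ml, 1)
  expect_equal(seg$volume_well_aerated_ml, 1)

  # two segments of 500 voxels each at 2x2x2 mm: 4 mL each, whole lung 8 mL
  lab <- array(rep(c(1L, 2L), each = 500), dim = c(10, 10, 10))
  labels <- lung_label_map(lab, two_segment_table())
  vol <- hu_volume(array(-750, dim = c(10, 10, 10)), spacing = c(2, 2, 2))
  rv <- region_volumetrics(classify_volume(vol, labels), labels, vol)
  expect_equal(rv$volume_total_ml[rv$level == "segment"], c(4, 4))
  expect_equal(rv$volume_total_ml[rv$region_id == "whole_lung"], 8)

  # class volumes sum to the total on every row
  expect_equal(rv$volume_well_aerated_ml + rv$volume_emphysematous_ml +
                 rv$volume_non_aerated_ml, rv$volume_total_ml)
})

test_that("a segment in the table but absent from the grid yields a zero row", {
  lab <- array(1L, dim = c(4, 4, 4))   # code 2 never appears
  labels <- lung_label_map(lab, two_segment_table())
  vol <- hu_volume(array(-750, dim = c(4, 4, 4)))
  cm <- classify_volume(vol, labels)
  expect_warning(rv <- region_volumetrics(cm, labels, vol), "absent from grid")
  expect_equal(rv$volume_total_ml[rv$level == "segment" & rv$region_id == "2"], 0)
})

test_that("region volumetrics agree with a per-voxel brute-force oracle", {
  set.seed(421)
  for (rep in 1:3) {
    dims <- c(sample(6:12, 1), sample(6:12, 1), sample(6:12, 1))
    hu <- array(runif(prod(dims), -1100, 0), dim = dims)
    lab <- array(sample(0:2, prod(dims), replace = TRUE), dim = dims)
    labels <- lung_label_map(lab, two_segment_table())
    vol <- hu_volume(hu, spacing = c(0.7, 0.7, 1.25))
    rv <- region_volumetrics(classify_volume(vol, labels), labels, vol)
    oracle <- brute_force_volumetrics(vol, labels)
    for (cd in names(oracle)) {
      row <- rv[rv$level == "segment" & rv$region_id == cd, ]
      expect_equal(row$volume_total_ml, unname(oracle[[cd]]["total"]))
      expect_equal(row$volume_well_aerated_ml, unname(oracle[[cd]]["well"]))
      expect_equal(row$volume_emphysematous_ml, unname(oracle[[cd]]["emph"]))
      expect_equal(row$volume_non_aerated_ml, unname(oracle[[cd]]["non"]))
    }
  }
})

test_that("classification partitions the lung mask and responds to HU shifts", {
  for (seed in c(5, 6)) {
    ph <- make_phantom(phantom_spec(shape = c(20, 20, 42), seed = seed))
    cm <- classify_volume(ph$volume, ph$labels)
    n_lung <- sum(ph$labels$labels > 0L)
    expect_identical(sum(tabulate(cm$classes, nbins = 3L)), n_lung)

    # +1000 HU pushes every lung voxel above the window; -1000 below it
    up <- hu_volume(ph$volume$values + 1000, spacing = ph$volume$spacing)
    cm_up <- classify_volume(up, ph$labels)
    expect_identical(sum(cm_up$classes == 3L), n_lung)
    down <- hu_volume(ph$volume$values - 1000, spacing = ph$volume$spacing)
    cm_down <- classify_volume(down, ph$labels)
    expect_identical(sum(cm_down$classes == 2L), n_lung)
  }
})

test_that("simulated resection computes the five fractions", {
  # all-healthy lung, remove half the volume
  v <- rbind(manual_volumetrics("1", "right", 500, 500),
             manual_volumetrics("2", "right", 500, 500))
  plan <- resection_plan(1L, two_segment_table())
  sim <- simulate_resection(v, plan)
  expect_equal(sim$removed_total_fraction, 0.5)
  expect_equal(sim$removed_functional_fraction, 0.5)
  expect_equal(sim$removed_healthy_over_removed_total, 1.0)

  # A: 600 mL all well-aerated; B: 400 mL with 100 mL well; remove B
  v <- rbind(manual_volumetrics("1", "right", 600, 600),
             manual_volumetrics("2", "right", 400, 100))
  sim <- simulate_resection(v, resection_plan(2L, two_segment_table()))
  expect_equal(sim$removed_total_fraction, 0.4)
  expect_equal(sim$removed_functional_fraction, 100 / 700)
  expect_equal(sim$removed_healthy_over_removed_total, 0.25)
  expect_equal(sim$healthy_over_total, 0.7)
  expect_equal(sim$ipsi_remaining_healthy_over_total, 1.0)
})

test_that("resection bookkeeping conserves every tissue class exactly", {
  ph <- make_phantom(phantom_spec(shape = c(24, 24, 44), seed = 9))
  rv <- region_volumetrics(classify_volume(ph$volume, ph$labels),
                           ph$labels, ph$volume)
  sim <- simulate_resection(rv, resection_plan(c("S1", "S2", "S3"),
                                               ph$labels$table))
  expect_equal(sim$removed_ml + sim$remaining_ml, sim$whole_lung_ml)
  fr <- c(sim$removed_total_fraction, sim$removed_functional_fraction,
          sim$healthy_over_total, sim$ipsi_remaining_healthy_over_total,
          sim$removed_healthy_over_removed_total)
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("degenerate resection inputs are rejected explicitly", {
  expect_error(resection_plan(integer(0), two_segment_table()), "non-empty")
  expect_error(resection_plan(9L, two_segment_table()), "unknown segment code")
  tab <- data.frame(code = 1:2, laterality = c("right", "left"),
                    lobe = c("RUL", "left_lung"), segment = c("S1", "left_bulk"))
  expect_error(resection_plan(1:2, tab), "one laterality")

  # no functional tissue anywhere: undefined fraction, not a silent 0 or 1
  v <- rbind(manual_volumetrics("1", "right", 500, 0, non = 500),
             manual_volumetrics("2", "right", 500, 0, non = 500))
  expect_error(simulate_resection(v, resection_plan(1L, two_segment_table())),
               "undefined fraction")
})
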