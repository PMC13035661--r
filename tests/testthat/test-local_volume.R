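test_that("the two largest-diameter positions respect the separation rule", {
  prof <- tibble::tibble(
    arclen = c(45, 50, 55, 80, 90),
    diameter = c(30, 40, 38, 35, 30),
    valid = TRUE
  )
  pos <- select_diameter_positions(prof, min_separation = 10)
  expect_equal(pos$s1, 50)
  expect_equal(pos$s2, 80)   # the 38 mm neighbour at 55 is inside the exclusion zone

  # monotone profile: runner-up is simply the second-largest eligible sample
  prof2 <- tibble::tibble(arclen = seq(0, 50, 10),
                          diameter = seq(20, 45, 5), valid = TRUE)
  pos2 <- select_diameter_positions(prof2, min_separation = 10)
  expect_equal(pos2$s1, 50)
  expect_equal(pos2$s2, 40)

  # no sample far enough away -> no second candidate
  prof3 <- tibble::tibble(arclen = c(0, 2, 4), diameter = c(5, 7, 6),
                          valid = TRUE)
  pos3 <- select_diameter_positions(prof3, min_separation = 10)
  expect_equal(pos3$s1, 2)
  expect_true(is.na(pos3$s2))

  # diameter ties break toward the smaller arc length
  prof4 <- tibble::tibble(arclen = c(10, 30), diameter = c(9, 9), valid = TRUE)
  expect_equal(select_diameter_positions(prof4, 5)$s1, 10)

  expect_error(select_diameter_positions(
    tibble::tibble(arclen = 1, diameter = 2, valid = FALSE)), "valid")
})

test_that("section windows clip to the centerline without re-centering", {
  w <- section_window(50, ao_length = 100, half_width = 15)
  expect_equal(c(w$lo, w$hi, w$effective_span), c(35, 65, 30))
  w2 <- section_window(5, ao_length = 100, half_width = 15)
  expect_equal(c(w2$lo, w2$hi, w2$effective_span), c(0, 20, 20))
  expect_error(section_window(120, ao_length = 100), "within")
})

test_that("uniform tube window volume is proportional to the window span", {
  fx <- fixture("tube05")
  m <- fx$meas
  L <- fx$cl$ao_length
  v30 <- local_false_lumen_volume(fx$ph$volume, fx$cl, 50, half_width = 15)
  expect_lt(abs(v30 - m$fl_glo * 30 / L) / (m$fl_glo * 30 / L), 0.03)

  # clipped window at the proximal end: span 20 mm instead of 30
  v_clip <- local_false_lumen_volume(fx$ph$volume, fx$cl, 5, half_width = 15)
  expect_lt(abs(v_clip - m$fl_glo * 20 / L) / (m$fl_glo * 20 / L), 0.04)
})

test_that("a volume with no false lumen yields zero local volume", {
  ph <- quick_phantom(fl_fraction = 0)
  cl <- extract_centerline(ph$volume)
  expect_identical(local_false_lumen_volume(ph$volume, cl, 25, half_width = 15), 0)
})

test_that("disjoint window tiling reproduces the global false-lumen volume exactly", {
  for (nm in c("tube05", "cane1")) {
    fx <- fixture(nm)
    L <- fx$cl$ao_length
    # boundaries at midpoints between sample arc lengths, so each false-lumen
    # voxel lands in exactly one window
    edges <- c(-0.1, seq(12, L - 12, length.out = 7), L + 0.1)
    total <- 0
    for (k in seq_len(length(edges) - 1)) {
      centre <- (edges[k] + edges[k + 1]) / 2
      hw <- (edges[k + 1] - edges[k]) / 2
      total <- total + local_false_lumen_volume(
        fx$ph$volume, fx$cl, section_window(min(max(centre, 0), L), L, hw))
    }
    expect_equal(total, fx$meas$fl_glo, tolerance = 1e-9)
  }
})

test_that("the local radiomarker captures a bulge-concentrated false lumen", {
  fx <- fixture("bulge05")
  v <- fl_loc(fx$ph$volume, fx$cl, fx$prof, section_length = 30)
  an <- fx$ph$analytic
  expect_lt(abs(as.numeric(v) - an$fl_loc) / an$fl_loc, 0.05)
  expect_lte(abs(attr(v, "s1") - 50), 2)
  # two-candidate rule can only increase the local volume
  v1 <- local_false_lumen_volume(fx$ph$volume, fx$cl,
                                 section_window(attr(v, "s1"), fx$cl$ao_length, 15))
  expect_gte(as.numeric(v), v1)
})

test_that("local volume is monotone in section length and bounded by the global volume", {
  for (nm in c("tube05", "bulge05", "cane1")) {
    fx <- fixture(nm)
    sw <- fl_loc_sweep(fx$ph$volume, fx$cl, fx$prof,
                       section_lengths = c(10, 15, 30, 50))
    expect_true(all(diff(sw$fl_loc) >= 0))
    expect_true(all(sw$fl_loc <= fx$meas$fl_glo + 1e-12))
    expect_true(all(sw$fl_loc >= 0))
  }
})

test_that("a window covering the whole vessel returns the global volume exactly", {
  fx <- fixture("tube05")
  expect_warning(
    v <- fl_loc(fx$ph$volume, fx$cl, fx$prof,
                section_length = 2 * fx$cl$ao_length),
    "studied set"
  )
  expect_equal(as.numeric(v), fx$meas$fl_glo, tolerance = 1e-12)
})

test_that("measure_aorta assembles measures and the section sweep", {
  ph <- quick_phantom(fl_fraction = 0.5, th_fraction = 0.2)
  m <- measure_aorta(ph$volume, sweep = c(10, 15, 30, 50))
  expect_s3_class(m, "aorta_measures")
  expect_false(is.na(m$fl_loc))
  expect_equal(m$fl_loc, m$fl_loc_30)
  expect_true(all(c("fl_loc_10", "fl_loc_15", "fl_loc_30", "fl_loc_50") %in% names(m)))
  expect_identical(m$ao_glo, m$v_tl + m$v_cfl + m$v_th)
})
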