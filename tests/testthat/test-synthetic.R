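test_that("phantom labels partition the tube exactly", {
  fx <- fixture("cane1")
  vol <- fx$ph$volume
  counts <- table(vol$grid)
  expect_true(all(as.integer(names(counts)) %in% 0:3))
  union_n <- sum(vol$grid != 0L)
  expect_equal(sum(vol$grid == 1L) + sum(vol$grid == 2L) + sum(vol$grid == 3L),
               union_n)
  expect_gt(sum(vol$grid == 2L), 0)
  expect_gt(sum(vol$grid == 3L), 0)
})

test_that("cylinder analytic measures equal closed forms", {
  an <- phantom_analytic(phantom_spec("straight", length = 100, r0 = 15,
                                      fl_fraction = 0.5))
  expect_equal(an$ao_glo, pi * 15^2 * 100 / 1000, tolerance = 1e-8)
  expect_equal(an$fl_glo, pi * 15^2 * 50 / 1000, tolerance = 1e-8)
  expect_equal(an$d_max, 30)
  expect_equal(an$ao_length, 100)
  expect_equal(an$fl_loc, an$fl_glo * 30 / 100, tolerance = 1e-8)

  bulged <- phantom_analytic(phantom_spec(
    "straight", length = 100, r0 = 15,
    bulge = list(amplitude = 5, center = 50, width = 10)))
  expect_equal(bulged$d_max, 40)
  expect_equal(bulged$d_max_position, 50)
  expect_gt(bulged$ao_glo, pi * 15^2 * 100 / 1000)
})

test_that("measured phantom values track the analytic truth", {
  fx <- fixture("tube05")
  an <- fx$ph$analytic
  expect_lt(abs(fx$meas$ao_glo - an$ao_glo) / an$ao_glo, 0.03)
  expect_lt(abs(fx$meas$fl_glo - an$fl_glo) / an$fl_glo, 0.03)
  expect_lt(abs(fx$meas$ao_length - an$ao_length) / an$ao_length, 0.02)
})

test_that("too-coarse spacing is rejected", {
  expect_error(voxelize_phantom(phantom_spec("straight", r0 = 2, spacing = 1)),
               "coarse")
  expect_error(phantom_spec("straight", r0 = -1), "positive")
  expect_error(phantom_spec("straight", fl_fraction = 1.5), "fl_fraction")
})

test_that("cohort simulation is reproducible and exchangeable", {
  cp <- remodeling_cohort_params("center1")
  c1 <- simulate_marker_cohort(cp$params, cp$n_event, cp$n_nonevent, seed = 5)
  c2 <- simulate_marker_cohort(cp$params, cp$n_event, cp$n_nonevent, seed = 5)
  expect_identical(c1, c2)
  c3 <- simulate_marker_cohort(cp$params, cp$n_event, cp$n_nonevent, seed = 6)
  expect_false(identical(c1$fl_loc, c3$fl_loc))
  expect_equal(sum(c1$outcome), cp$n_event)
  expect_error(simulate_marker_cohort(cp$params, 1, 10), "n >= 2")
})

test_that("identical groups give a null AUC", {
  params <- tibble::tibble(marker = "m", mean_event = 10, sd_event = 2,
                           mean_nonevent = 10, sd_nonevent = 2)
  sim <- simulate_auc(10, 2, 40, 10, 2, 40, replicates = 2000, seed = 2)
  expect_lt(abs(sim$auc_mean - 0.5), 0.02)
})

test_that("replicate-averaged AUC matches the binormal closed form", {
  cp <- remodeling_cohort_params("center1")
  row <- cp$params[cp$params$marker == "fl_loc", ]
  sim <- simulate_auc(row$mean_event, row$sd_event, cp$n_event,
                      row$mean_nonevent, row$sd_nonevent, cp$n_nonevent,
                      replicates = 2000, seed = 3)
  closed <- binormal_auc(row$mean_event, row$sd_event,
                         row$mean_nonevent, row$sd_nonevent)
  expect_lt(abs(sim$auc_mean - closed), 0.005)
})

test_that("paired cohorts satisfy the annualisation identities by construction", {
  params <- tibble::tibble(marker = "fl_loc", mean_event = 22.4, sd_event = 9.9,
                           mean_nonevent = 10, sd_nonevent = 8.1)
  # zero growth, zero noise: the annualised value is the baseline
  pc <- simulate_paired_cohort(params, 10, 10, growth_event = c(0, 0),
                               growth_nonevent = c(0, 0), seed = 8)
  out <- annualize_cohort(pc, "fl_loc")
  expect_equal(out$fl_loc_plus, out$fl_loc_t1)
  expect_true(all(pc$delta_days > 30))

  # interval exactly one year: the annualised value is the T2 value
  pc2 <- simulate_paired_cohort(params, 10, 10, growth_event = c(8, 2),
                                growth_nonevent = c(1, 1),
                                delta_days_mean = 365, delta_days_sd = 0,
                                seed = 9)
  out2 <- annualize_cohort(pc2, "fl_loc")
  expect_equal(out2$fl_loc_plus, out2$fl_loc_t2)
})

test_that("growth concentrated in the event group adds prognostic signal", {
  params <- tibble::tibble(marker = "m", mean_event = 11, sd_event = 9,
                           mean_nonevent = 10, sd_nonevent = 9)
  set.seed(30)
  wins <- replicate(200, {
    pc <- simulate_paired_cohort(params, 20, 20, growth_event = c(30, 5),
                                 growth_nonevent = c(0, 5))
    out <- annualize_cohort(pc, "m")
    roc_auc(out$m_plus, out$outcome)$auc >
      roc_auc(out$m_t1, out$outcome)$auc
  })
  expect_gte(mean(wins), 0.90)
})
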