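# Fast parameter set shared across the generator tests: small images keep
# rendering cheap while the ROI auto-shrinks to fit.
fast_params <- function(...) erythema_params(image_size = c(16, 16), ...)

test_that("dose sampling is reproducible, biased by site, and clamps", {
  a <- sample_doses(8, seed = 123)
  b <- sample_doses(8, seed = 123)
  expect_equal(a, b)
  expect_false(isTRUE(all.equal(a, sample_doses(8, seed = 124))))
  big <- sample_doses(10000, seed = 7)
  expect_lt(mean(big$inner), mean(big$upper))
  expect_lt(mean(big$inner), mean(big$lower))
  degenerate <- sample_doses(5, seed = 1, dose_interval = c(200, 200))
  expect_true(all(as.matrix(degenerate[, c("upper", "lower", "inner",
                                           "outer")]) == 200))
  rng <- erythema_params()$dose_interval
  expect_true(all(as.matrix(big[, c("upper", "lower", "inner", "outer")]) >=
                    rng[1] &
                  as.matrix(big[, c("upper", "lower", "inner", "outer")]) <=
                    rng[2]))
})

test_that("the null model renders identical breasts", {
  p <- fast_params(dose_slope_a = 0, control_drift = 0, pixel_noise_sd = 0)
  base <- c(72, -1, 20)
  irr <- render_skin_image(base, 250, "RT_after", "irradiated", p, seed = 5)
  ctl <- render_skin_image(base, 250, "RT_after", "unirradiated", p, seed = 5)
  expect_equal(irr$pixels, ctl$pixels)
})

test_that("without noise the irradiated a* rises strictly over time", {
  p <- fast_params(pixel_noise_sd = 0)
  base <- c(72, -1, 20)
  a_by_time <- vapply(study_levels()$time_point, function(tp) {
    img <- render_skin_image(base, 250, tp, "irradiated", p, seed = 5)
    extract_parameters(img)[["astar"]]
  }, numeric(1))
  expect_true(all(diff(a_by_time) > 0))
})

test_that("noise-free renders invert back to the constructed Lab shift", {
  p <- fast_params(pixel_noise_sd = 0)
  base <- c(72, -1, 20)
  img <- render_skin_image(base, 250, "RT_14days", "irradiated", p, seed = 5)
  got <- extract_parameters(img)[c("Lstar", "astar", "bstar")]
  shift_a <- p$dose_slope_a * 250 * p$time_profile[3]
  want <- base + shift_a * c(p$frac_L, 1, p$frac_b)
  expect_equal(unname(got), want, tolerance = 1e-6)
})

test_that("cohorts have the full design arithmetic and are seeded", {
  co <- generate_cohort(3, params = fast_params(), seed = 42)
  expect_length(co$images, 96)  # 32 images per patient
  expect_equal(nrow(co$dose_table), 3)
  cells <- vapply(co$images, function(i) {
    paste(i$patient_id, i$breast, i$site, i$time_point)
  }, character(1))
  expect_equal(anyDuplicated(cells), 0L)
  again <- generate_cohort(3, params = fast_params(), seed = 42)
  expect_equal(co$images[[10]]$pixels, again$images[[10]]$pixels)
  other <- generate_cohort(3, params = fast_params(), seed = 43)
  expect_false(isTRUE(all.equal(co$images[[10]]$pixels,
                                other$images[[10]]$pixels)))
})

test_that("RTOG grades never exceed 1 and key the a* shift", {
  co <- generate_cohort(5, params = fast_params(), seed = 9)
  expect_true(all(co$rtog$grade %in% 0:1))
  null_co <- generate_cohort(5, params = fast_params(dose_slope_a = 0),
                             seed = 9)
  expect_true(all(null_co$rtog$grade == 0))
})

test_that("irradiated time trends carry the expected sign pattern", {
  co <- generate_cohort(12, params = fast_params(), seed = 77)
  rec <- extract_all(co$images)
  t3 <- summarize_table3(rec)
  irr <- t3[t3$breast == "irradiated", ]
  trend <- function(parm, from = "RT_before") {
    sub <- irr[irr$parameter == parm, ]
    sub$mean[sub$time_point == "RT_after"] -
      sub$mean[sub$time_point == from]
  }
  up <- c("R", "S", "V", "astar", "Cr")
  down <- c("G", "H", "Lstar")
  for (parm in up) expect_gt(trend(parm), 0)
  for (parm in down) expect_lt(trend(parm), 0)
  # B and Cb decline from RT_7days on
  expect_lt(trend("B", from = "RT_7days"), 0)
  expect_lt(trend("Cb", from = "RT_7days"), 0)
  # the control breast stays near-flat by comparison
  ctl <- t3[t3$breast == "unirradiated" & t3$parameter == "astar", ]
  expect_lt(max(ctl$mean) - min(ctl$mean), 1)
})

test_that("cohorts survive a disk round trip through the CLI layout", {
  co <- generate_cohort(2, params = fast_params(), seed = 3)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_length(back$images, 64)
  expect_equal(back$dose_table$mean, co$dose_table$mean, tolerance = 1e-9)
  # quantization on write moves channels by at most half a count
  cells <- vapply(back$images, function(i) {
    paste(i$patient_id, i$breast, i$site, i$time_point)
  }, character(1))
  orig <- vapply(co$images, function(i) {
    paste(i$patient_id, i$breast, i$site, i$time_point)
  }, character(1))
  m <- match(cells, orig)
  expect_false(anyNA(m))
  expect_lt(max(abs(back$images[[1]]$pixels - co$images[[m[1]]]$pixels)), 0.5 + 1e-9)
})
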