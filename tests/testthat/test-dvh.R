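test_that("curve construction enforces the cumulative-DVH invariants", {
  expect_error(dvh_curve("s", numeric(0), numeric(0)), class = "jawsearch_invalid_input")
  expect_error(dvh_curve("s", c(1, 2), c(100, 0)), class = "jawsearch_invalid_input")
  expect_error(dvh_curve("s", c(0, 10), c(99, 0)), class = "jawsearch_invalid_input")
  expect_error(dvh_curve("s", c(0, 10), c(100, 101)), class = "jawsearch_invalid_input")
  expect_error(dvh_curve("s", c(0, 10, 10), c(100, 50, 0)), class = "jawsearch_invalid_input")
  cv <- dvh_curve("s", c(0, 10), c(100, 0))
  expect_s3_class(cv, "dvh_curve")
  expect_identical(cv$volume[1], 100)
})

test_that("resampling interpolates linearly onto the uniform grid", {
  cv <- resample_dvh(dvh_curve("s", c(0, 10), c(100, 0)), 5)
  expect_equal(cv$dose, c(0, 5, 10))
  expect_equal(cv$volume, c(100, 50, 0))
  # aligned grid is the identity
  cv2 <- resample_dvh(dvh_curve("s", c(0, 10, 20), c(100, 100, 0)), 10)
  expect_equal(cv2$dose, c(0, 10, 20))
  expect_equal(cv2$volume, c(100, 100, 0))
  # hand-computed midpoint on an unaligned curve
  cv3 <- resample_dvh(dvh_curve("s", c(0, 8, 16), c(100, 25, 5)), 4)
  expect_equal(volume_at_dose(cv3, 4), 62.5)
})

test_that("resampling error is bounded by the Lipschitz interpolation bound", {
  set.seed(11)
  probe <- seq(0, 60, by = 0.37)
  for (r in 1:10) {
    cv <- random_curve(n = 9)
    slope <- max(abs(diff(cv$volume) / diff(cv$dose)))
    for (h in c(2, 1, 0.5)) {
      rs <- resample_dvh(cv, h)
      err <- max(abs(volume_at_dose(rs, probe) - volume_at_dose(cv, probe)))
      expect_lte(err, slope * h + 1e-9)
    }
  }
})

test_that("dose_at_volume inverts the cumulative curve at the clinical boundary", {
  expect_equal(dose_at_volume(dvh_curve("s", c(0, 10), c(100, 0)), 50), 5)
  expect_equal(dose_at_volume(dvh_curve("s", c(0, 10), c(100, 0)), 0), 10)
  # flat 100% segment: D100 is the right boundary of the segment
  flat <- dvh_curve("s", c(0, 10, 20), c(100, 100, 0))
  expect_equal(dose_at_volume(flat, 100), 10)
  # immediate fall-off: D100 is 0
  expect_equal(dose_at_volume(dvh_curve("s", c(0, 10), c(100, 0)), 100), 0)
  expect_error(dose_at_volume(flat, 101), class = "jawsearch_invalid_input")
})

test_that("volume_at_dose interpolates and vanishes beyond the last sample", {
  expect_equal(volume_at_dose(dvh_curve("s", c(0, 10), c(100, 0)), 2.5), 75)
  cv <- dvh_curve("s", c(0, 30, 40, 50), c(100, 100, 50, 0))
  expect_equal(volume_at_dose(cv, 0), 100)
  expect_equal(volume_at_dose(cv, 45), 25)
  expect_equal(volume_at_dose(cv, 60), 0)
})

test_that("max_dose is where the interpolated volume first reaches the floor", {
  expect_equal(max_dose(dvh_curve("s", c(0, 10), c(100, 0))), 10)
  expect_equal(max_dose(dvh_curve("s", c(0, 50, 55), c(100, 1, 0))), 55)
  # epsilon floor moves the maximum to the first sub-threshold grid point
  expect_equal(max_dose(dvh_curve("s", c(0, 50, 55), c(100, 1, 0)), epsilon = 1), 50)
})

test_that("dose scaling acts homogeneously on curve queries", {
  set.seed(23)
  for (r in 1:10) {
    cv <- random_curve()
    s <- runif(1, 0.5, 2)
    scaled <- dvh_curve(cv$structure, cv$dose * s, cv$volume)
    expect_equal(max_dose(scaled), s * max_dose(cv))
    for (v in c(0, 5, 50, 95)) {
      expect_equal(dose_at_volume(scaled, v), s * dose_at_volume(cv, v))
    }
    for (d in c(0, 10, 25)) {
      expect_equal(volume_at_dose(scaled, d * s), volume_at_dose(cv, d))
    }
  }
})

test_that("normalization drives target coverage to prescription and scales all curves together", {
  pl <- step_plan("p1", d95 = 47.5)
  norm <- normalize_to_prescription(pl, "ptv", 50, 95)
  s <- 50 / 47.5
  expect_equal(norm$scale_applied, s)
  expect_equal(dose_at_volume(norm$curves$ptv, 95), 50)
  # OAR doses scale by the same factor; volumes are untouched
  expect_equal(norm$curves$small_bowel$dose, pl$curves$small_bowel$dose * s)
  expect_equal(norm$curves$small_bowel$volume, pl$curves$small_bowel$volume)
  # already on prescription: identity
  pl50 <- step_plan("p2", d95 = 50)
  expect_equal(normalize_to_prescription(pl50, "ptv", 50, 95)$scale_applied, 1)
  # idempotence
  again <- normalize_to_prescription(norm, "ptv", 50, 95)
  expect_equal(again$curves$ptv$dose, norm$curves$ptv$dose)
  expect_equal(again$scale_applied, norm$scale_applied)
})

test_that("degenerate target coverage raises a flagged error, not a silent drop", {
  # immediate fall-off: D100 is 0 Gy, so normalizing at 100% coverage divides
  # by zero dose
  tgt <- dvh_curve("ptv", c(0, 10), c(100, 0))
  pl <- plan_dose("p", list(tgt))
  expect_error(normalize_to_prescription(pl, "ptv", 50, 100),
               class = "jawsearch_degenerate_plan")
  expect_error(normalize_to_prescription(pl, "missing", 50, 95),
               class = "jawsearch_invalid_input")
})

test_that("hotspot exclusion is strict at the limit", {
  mk <- function(dmax) {
    plan_dose("p", list(dvh_curve("ptv", c(0, dmax - 0.5, dmax), c(100, 95, 0))))
  }
  # 53.5 Gy on a 50 Gy prescription is exactly 107%: kept
  expect_false(is_hotspot_unacceptable(mk(53.5), "ptv", 50, 107))
  expect_true(is_hotspot_unacceptable(mk(53.6), "ptv", 50, 107))
  expect_true(is_hotspot_unacceptable(mk(54.0), "ptv", 50, 107))
})

test_that("DVH CSV serialization round-trips doubles bit-exactly", {
  set.seed(5)
  plans <- list(
    plan_dose("p1", list(random_curve(structure = "a"), random_curve(structure = "b"))),
    plan_dose("p2", list(random_curve(structure = "a")))
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_dvh_csv(plans, path)
  back <- read_dvh_csv(path)
  expect_identical(names(back), c("p1", "p2"))
  expect_identical(back$p1$curves$a$dose, plans[[1]]$curves$a$dose)
  expect_identical(back$p1$curves$a$volume, plans[[1]]$curves$a$volume)
  expect_identical(back$p2$curves$a$volume, plans[[2]]$curves$a$volume)
  # write(read(write(x))) is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_dvh_csv(back, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})
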