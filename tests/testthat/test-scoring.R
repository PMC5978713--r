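test_that("mdvp matches the term-by-term Riemann sum on hand curves", {
  # 0*(100-100) + 10*(100-0) + 20*(0-0) = 1000
  expect_equal(mdvp(dvh_curve("s", c(0, 10, 20), c(100, 100, 0))), 1000)
  # all mass at zero dose contributes nothing
  expect_equal(mdvp(dvh_curve("s", 0, 100)), 0)
  # independent term-by-term oracle on random curves
  set.seed(31)
  for (r in 1:10) {
    cv <- random_curve()
    v_next <- c(cv$volume[-1], 0)
    oracle <- sum(cv$dose * (cv$volume - v_next))
    expect_equal(mdvp(cv), oracle)
    expect_gte(mdvp(cv), 0)
  }
})

test_that("mdvp/100 on a fine grid recovers the analytic mean dose", {
  # triangle curve: uniform dose distribution on [0, 10], mean 5 Gy
  tri <- resample_dvh(dvh_curve("s", c(0, 10), c(100, 0)), 0.01)
  expect_equal(mdvp(tri) / 100, 5, tolerance = 0.01)
  # stretched-exponential curve with known mean
  cv <- resample_dvh(jawsearch:::oar_curve("s", 20, 2.5, 0.1), 0.01)
  expect_equal(mdvp(cv) / 100, 20, tolerance = 0.002)
})

test_that("hdvp restricts the sum to doses strictly above the threshold", {
  cv <- dvh_curve("s", c(0, 30, 40, 50), c(100, 100, 50, 0))
  expect_equal(hdvp(cv, 35), 2000) # only the 40 Gy term: 40 * (50 - 0)
  expect_equal(hdvp(cv, 40), 0)    # strict: the 40 Gy sample is excluded
  # entirely below threshold: empty sum
  low <- dvh_curve("s", c(0, 20, 30), c(100, 40, 0))
  expect_equal(hdvp(low, 35), 0)
  # threshold 0 equals mdvp (the zero-dose term contributes nothing anyway)
  set.seed(37)
  for (r in 1:10) {
    rc <- random_curve()
    expect_equal(hdvp(rc, 0), mdvp(rc))
  }
})

test_that("hdvp is monotone non-increasing in the threshold and bounded by mdvp", {
  set.seed(41)
  for (r in 1:20) {
    cv <- random_curve()
    thresholds <- sort(runif(6, 0, max(cv$dose)))
    vals <- vapply(thresholds, function(dt) hdvp(cv, dt), numeric(1))
    expect_true(all(diff(vals) <= 1e-9))
    expect_true(all(vals <= mdvp(cv) + 1e-9))
    expect_true(all(vals >= 0))
  }
})

make_cohort <- function(oar_ends, d95 = 50) {
  lapply(seq_along(oar_ends), function(i)
    step_plan(sprintf("p%02d", i), d95 = d95, oar_slope_end = oar_ends[i]))
}

test_that("cohort normalization forces a per-OAR mean score of one", {
  plans <- make_cohort(c(20, 30, 40, 55))
  oars <- list(oar_spec("small_bowel", 35))
  tab <- score_cohort(plans, oars)
  expect_equal(mean(tab$organ$normalized_score), 1, tolerance = 1e-12)
  # forced two-plan example: combined {2, 4} -> scores {2/3, 4/3}
  two <- make_cohort(c(20, 40))
  tab2 <- score_cohort(two, oars)
  ratio <- tab2$organ$combined / mean(tab2$organ$combined)
  expect_equal(tab2$organ$normalized_score, ratio)
  expect_equal(mean(tab2$organ$normalized_score), 1)
})

test_that("total score sums the per-OAR normalized evaluators", {
  plans <- make_cohort(c(20, 30, 40))
  # duplicate the same structure under three OAR specs via three real OARs
  plans <- lapply(plans, function(p) {
    cs <- p$curves
    sb <- cs$small_bowel
    plan_dose(p$plan_id, list(cs$ptv, sb,
                              dvh_curve("femoral_head", sb$dose, sb$volume),
                              dvh_curve("urinary_bladder", sb$dose, sb$volume)))
  })
  tab <- score_cohort(plans, default_oars())
  org <- tab$organ
  for (pid in tab$plan$plan_id) {
    expect_equal(tab$plan$total_score[tab$plan$plan_id == pid],
                 sum(org$normalized_score[org$plan_id == pid]))
  }
  # identical curves across the three OARs: each normalized score mean is 1,
  # and a plan sitting exactly on the cohort mean would score 3.0
  means <- tapply(org$normalized_score, org$structure, mean)
  expect_equal(as.numeric(means), rep(1, 3))
})

test_that("scoring is scale-invariant per OAR and reacts to cohort composition", {
  oars <- list(oar_spec("small_bowel", 35))
  plans <- make_cohort(c(20, 30, 40))
  base <- score_cohort(plans, oars)
  # multiplying every plan's combined value by c > 0 (here via the component
  # weights) cancels in the cohort normalization
  oars_scaled <- list(oar_spec("small_bowel", 35, weight_mdvp = 3,
                               weight_hdvp = 3))
  tab2 <- score_cohort(plans, oars_scaled)
  expect_equal(tab2$organ$combined, 3 * base$organ$combined)
  expect_equal(tab2$organ$normalized_score, base$organ$normalized_score)
  # adding an above-mean plan lowers everyone else's normalized score
  bigger <- c(plans, make_cohort(70)[1])
  bigger[[4]]$plan_id <- "p99"
  tab3 <- score_cohort(bigger, oars)
  old <- base$organ$normalized_score
  new <- tab3$organ$normalized_score[match(base$organ$plan_id, tab3$organ$plan_id)]
  expect_true(all(new < old))
})

test_that("component weights shift the combined metric", {
  oars_h <- list(oar_spec("small_bowel", 35, weight_mdvp = 0, weight_hdvp = 1))
  plans <- make_cohort(c(30, 55))
  tab <- score_cohort(plans, oars_h)
  m <- tab$organ
  expect_equal(m$combined, m$hdvp)
  # a curve entirely below 35 Gy has zero weighted combined value
  expect_equal(m$combined[m$plan_id == "p01"], 0)
})

test_that("degenerate cohorts raise flagged errors", {
  oars <- list(oar_spec("small_bowel", 35))
  plans <- make_cohort(c(20, 30))
  expect_error(score_cohort(plans, oars, accepted = c(FALSE, FALSE),
                            normalization_set = "accepted"),
               class = "jawsearch_empty_cohort")
  # an OAR with zero dose everywhere cannot be cohort-normalized
  zero <- lapply(plans, function(p)
    plan_dose(p$plan_id, list(p$curves$ptv, dvh_curve("small_bowel", 0, 100))))
  expect_error(score_cohort(zero, oars),
               class = "jawsearch_degenerate_normalization")
})

test_that("ranking is ascending over accepted plans with deterministic ties", {
  plans <- make_cohort(c(40, 25, 33))
  oars <- list(oar_spec("small_bowel", 35))
  tab <- score_cohort(plans, oars) # scores ordered like the OAR ends
  rk <- rank_plans(tab, conformal_id = "p01")
  expect_equal(rk$best, "p02")
  expect_equal(rk$worst, "p01")
  expect_equal(rk$ranking, c("p02", "p03", "p01"))
  expect_equal(rk$conformal, "p01")
  # excluding the best promotes the runner-up
  tab2 <- score_cohort(plans, oars, accepted = c(TRUE, FALSE, TRUE))
  rk2 <- rank_plans(tab2)
  expect_equal(rk2$best, "p03")
  # exact ties resolve to the lowest plan index
  dup <- make_cohort(c(30, 30, 45))
  tab3 <- score_cohort(dup, oars)
  expect_equal(rank_plans(tab3)$best, "p01")
  # no accepted plans at all
  expect_error(rank_plans(score_cohort(plans, oars,
                                       accepted = c(FALSE, FALSE, FALSE))),
               class = "jawsearch_empty_cohort")
})
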