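# Preprocessing: repeatability, triplet windows, filters, labelling, noise
# reduction and normalization.

test_that("repeatability limit is 1.96 * sqrt(2) times the within-subject SD", {
  unit <- setNames(rep(1, 5), kc_variables())
  rt <- compute_repeatability(unit)
  expect_equal(round(rt$r, 2), rep(2.77, 5))
  expect_true(all(abs(rt$r - rt$sw * 1.96 * sqrt(2)) < 1e-9))

  zero <- compute_repeatability(setNames(rep(0, 5), kc_variables()))
  expect_equal(zero$r, rep(0, 5))

  kmax <- compute_repeatability(c(KmaxZonalMean3mm = 0.26, RsF = 0, BFSF = 0,
                                  RmB = 0, LOGIK = 0))
  expect_equal(round(kmax$r[kmax$variable == "KmaxZonalMean3mm"], 2), 0.72)

  expect_error(compute_repeatability(c(KmaxZonalMean3mm = -0.1, RsF = 0,
                                       BFSF = 0, RmB = 0, LOGIK = 0)),
               "negative")
})

test_that("the clinical direction map is fixed", {
  rt <- default_rt()
  dirs <- setNames(rt$direction, rt$variable)
  expect_identical(dirs[["KmaxZonalMean3mm"]], "INCREASING")
  expect_identical(dirs[["LOGIK"]], "INCREASING")
  expect_identical(dirs[["RsF"]], "DECREASING")
  expect_identical(dirs[["BFSF"]], "DECREASING")
  expect_identical(dirs[["RmB"]], "DECREASING")
})

test_that("an eye with k exams yields the k - 2 overlapping windows", {
  co <- generate_cohort(cohort_spec(n_eyes = 1, visits_per_eye = 5, seed = 5))
  tr <- build_triplets(co)
  expect_equal(nrow(tr), 3L)
  ex <- co$exams[order(co$exams$exam_date), ]
  expect_equal(tr$date_bl, ex$exam_date[1:3])
  expect_equal(tr$window_index, 1:3)

  co3 <- generate_cohort(cohort_spec(n_eyes = 1, visits_per_eye = 3, seed = 5))
  expect_equal(nrow(build_triplets(co3)), 1L)
  co2 <- generate_cohort(cohort_spec(n_eyes = 1, visits_per_eye = 2, seed = 5))
  expect_equal(nrow(build_triplets(co2)), 0L)
})

test_that("total window count is the sum of max(0, k - 2) over eyes", {
  co <- generate_cohort(cohort_spec(n_eyes = 60, visits_per_eye = c(2, 8),
                                    seed = 9))
  k <- table(co$exams$eye_id)
  expect_equal(nrow(build_triplets(co)), sum(pmax(0L, as.integer(k) - 2L)))
})

test_that("duplicate exam dates are rejected naming the eye", {
  co <- generate_cohort(cohort_spec(n_eyes = 1, visits_per_eye = 3, seed = 5))
  ex <- co$exams
  ex$exam_date[2] <- ex$exam_date[1]
  expect_error(build_triplets(ex), "E0001")
})

test_that("sub-5-month spacing warns but is not rejected", {
  co <- generate_cohort(cohort_spec(n_eyes = 1, visits_per_eye = 3, seed = 5))
  ex <- co$exams[order(co$exams$exam_date), ]
  ex$exam_date[2] <- ex$exam_date[1] + 30
  ex$Age <- ex$Age[1] + as.numeric(ex$exam_date - ex$exam_date[1]) / 365.25
  expect_warning(tr <- build_triplets(ex), "5 months")
  expect_equal(nrow(tr), 1L)
})

test_that("quality policies keep and drop the right flag patterns", {
  cases <- list(
    # flags, kept under OPTION1, kept under OPTION2
    list(c("OK", "OK", "OK"), TRUE, TRUE),
    list(c("OK", "YELLOW", "OK"), FALSE, TRUE),
    list(c("YELLOW", "OK", "OK"), FALSE, TRUE),
    list(c("OK", "RED", "OK"), FALSE, FALSE),
    list(c("RED", "OK", "OK"), FALSE, FALSE),
    list(c("YELLOW", "YELLOW", "OK"), FALSE, FALSE)
  )
  e <- as.list(base_exam())
  for (case in cases) {
    tr <- make_triplet(e, e, e, quality = case[[1]])
    expect_equal(nrow(filter_quality(tr, "OPTION1")) == 1L, case[[2]],
                 label = paste(case[[1]], collapse = "-"))
    expect_equal(nrow(filter_quality(tr, "OPTION2")) == 1L, case[[3]],
                 label = paste(case[[1]], collapse = "-"))
  }
})

test_that("severity exclusion tests only the baseline, strictly above 3.5", {
  e <- as.list(base_exam())
  sev_triplet <- function(logik_bl, logik_f2) {
    bl <- e; bl$LOGIK <- logik_bl
    f2 <- e; f2$LOGIK <- logik_f2
    make_triplet(bl, e, f2)
  }
  expect_equal(nrow(filter_severity(sev_triplet(3.6, 1))), 0L)   # severe baseline
  expect_equal(nrow(filter_severity(sev_triplet(3.5, 1))), 1L)   # boundary kept
  expect_equal(nrow(filter_severity(sev_triplet(1.0, 4.0))), 1L) # only baseline tested
})

test_that("labelling follows the one-directional 95 CI rule", {
  rt <- worked_rt()
  e <- as.list(base_exam())

  # Kmax 44 -> 45 D with r = 0.72 D: suspect progressive
  bl <- e; bl$KmaxZonalMean3mm <- 44
  f2 <- e; f2$KmaxZonalMean3mm <- 45
  lab <- label_progression(make_triplet(bl, bl, f2), rt)
  expect_equal(lab$label, "SUSPECT_PROGRESSIVE")
  expect_equal(lab$n_exceed, 1L)

  # all follow-up values equal to baseline: stable, count 0
  lab <- label_progression(make_triplet(e, e, e), rt)
  expect_equal(lab$label, "STABLE")
  expect_equal(lab$n_exceed, 0L)

  # RsF increasing opposes its clinical direction: stable
  rt_rsf <- repeatability_from_r(c(KmaxZonalMean3mm = 0.72, RsF = 0.10,
                                   BFSF = 0.1, RmB = 0.1, LOGIK = 0.3))
  bl <- e; bl$RsF <- 7.50
  f2 <- e; f2$RsF <- 7.70
  lab <- label_progression(make_triplet(bl, bl, f2), rt_rsf)
  expect_equal(lab$label, "STABLE")

  # a change exactly equal to r is inside the interval (strict rule)
  bl <- e
  f2 <- e; f2$KmaxZonalMean3mm <- e$KmaxZonalMean3mm + 0.72
  expect_equal(label_progression(make_triplet(bl, bl, f2), rt)$label, "STABLE")

  # first-follow-up excursions never set the label
  f1 <- e; f1$KmaxZonalMean3mm <- e$KmaxZonalMean3mm + 5
  expect_equal(label_progression(make_triplet(e, f1, e), rt)$label, "STABLE")
})

test_that("the vectorized labeller agrees with the brute-force oracle", {
  rt <- default_rt()
  tr <- random_triplets(10000, rt, seed = 21)
  fast <- label_progression(tr, rt)
  slow <- oracle_label(tr, rt)
  expect_identical(fast$label, slow$label)
  expect_identical(fast$n_exceed, slow$n_exceed)
})

test_that("noise reduction applies the documented three branches", {
  rt <- worked_rt()
  e <- as.list(base_exam())

  # inside the interval, toward progression: delta 0.4 D halves to 0.2 D
  f1 <- e; f1$KmaxZonalMean3mm <- e$KmaxZonalMean3mm + 0.4
  nr <- noise_reduce(make_triplet(e, f1, e), rt)
  expect_equal(nr$KmaxZonalMean3mm_f1, e$KmaxZonalMean3mm + 0.2)

  # boundary: delta exactly r is still the inside branch
  f1 <- e; f1$KmaxZonalMean3mm <- e$KmaxZonalMean3mm + 0.72
  nr <- noise_reduce(make_triplet(e, f1, e), rt)
  expect_equal(nr$KmaxZonalMean3mm_f1, e$KmaxZonalMean3mm + 0.36)

  # beyond the interval, toward progression: untouched
  f1 <- e; f1$KmaxZonalMean3mm <- e$KmaxZonalMean3mm + 1.5
  nr <- noise_reduce(make_triplet(e, f1, e), rt)
  expect_equal(nr$KmaxZonalMean3mm_f1, e$KmaxZonalMean3mm + 1.5)

  # opposing direction: reduced by 5 (decreasing variable moving up)
  f1 <- e; f1$RsF <- e$RsF + 0.25
  nr <- noise_reduce(make_triplet(e, f1, e), rt)
  expect_equal(nr$RsF_f1, e$RsF + 0.05)

  # the baseline and age are never modified
  tr <- worked_triplet()
  nr <- noise_reduce(tr, rt)
  expect_equal(nr$KmaxZonalMean3mm_bl, tr$KmaxZonalMean3mm_bl)
  expect_equal(nr$Age_f1, tr$Age_f1)
  expect_equal(nr$Age_f2, tr$Age_f2)
})

test_that("noise reduction never changes the progression label", {
  rt <- default_rt()
  tr <- random_triplets(10000, rt, seed = 31)
  before <- label_progression(tr, rt)
  after <- label_progression(noise_reduce(tr, rt), rt)
  expect_identical(after$label, before$label)
  expect_identical(after$n_exceed, before$n_exceed)
})

test_that("normalization divides by the per-variable Euclidean norm and inverts", {
  rt <- default_rt()
  tr <- random_triplets(50, rt, seed = 41)
  norm <- normalize_triplets(tr)
  for (v in ALL_VARS) {
    vals <- unlist(tr[paste(v, c("bl", "f1", "f2"), sep = "_")])
    expect_equal(norm$constants[[v]], sqrt(sum(vals^2)))
  }
  # denormalize o normalize = identity
  f2 <- as.matrix(setNames(norm$triplets[paste0(VARS, "_f2")], VARS))
  back <- denormalize_values(f2, norm$constants)
  expect_equal(unname(back), unname(as.matrix(tr[paste0(VARS, "_f2")])),
               tolerance = 1e-12)

  # constants are reusable on held-out rows
  held <- random_triplets(10, rt, seed = 43)
  reapplied <- normalize_triplets(held, norm$constants)
  expect_equal(reapplied$constants, norm$constants)
  expect_equal(reapplied$triplets$KmaxZonalMean3mm_bl,
               held$KmaxZonalMean3mm_bl / norm$constants[["KmaxZonalMean3mm"]])

  # zero-norm columns are rejected by name
  z <- tr
  for (s in c("bl", "f1", "f2")) z[[paste0("LOGIK_", s)]] <- 0
  expect_error(normalize_triplets(z), "LOGIK")
})

test_that("labels are invariant to a consistent rescaling of values and r", {
  rt <- default_rt()
  tr <- random_triplets(500, rt, seed = 51)
  ref <- label_progression(tr, rt)$label
  scale <- c(KmaxZonalMean3mm = 3, RsF = 0.5, BFSF = 2, RmB = 10, LOGIK = 0.2)
  scaled <- tr
  for (v in VARS) {
    for (s in c("bl", "f1", "f2")) {
      col <- paste(v, s, sep = "_")
      scaled[[col]] <- scaled[[col]] * scale[[v]]
    }
  }
  rt_scaled <- compute_repeatability(setNames(rt$sw * scale[rt$variable],
                                              rt$variable))
  expect_identical(label_progression(scaled, rt_scaled)$label, ref)
})

test_that("prepare_triplets composes the stages in the fixed order", {
  rt <- default_rt()
  spec <- cohort_spec(n_eyes = 80, visits_per_eye = c(3, 5), seed = 61,
                      p_yellow = 0.2, p_red = 0.05, p_severe = 0.15)
  co <- generate_cohort(spec)
  pp <- prepare_triplets(co, rt, option = "OPTION1")
  funnel <- attr(pp, "funnel")
  expect_true(all(diff(funnel) <= 0))  # each stage only removes rows
  expect_equal(unname(funnel["built"]),
               sum(pmax(0L, as.integer(table(co$exams$eye_id)) - 2L)))
  expect_true(all(!is.na(pp$label)))

  # manual composition gives the same result
  manual <- build_triplets(co)
  manual <- filter_quality(manual, "OPTION1")
  manual <- filter_severity(manual, 3.5)
  manual <- label_progression(manual, rt)
  manual <- noise_reduce(manual, rt)
  expect_equal(pp, manual, ignore_attr = TRUE)

  # option 2 never keeps fewer triplets than option 1
  pp2 <- prepare_triplets(co, rt, option = "OPTION2")
  expect_gte(nrow(pp2), nrow(pp))
})
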