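test_that("multiclass AUC has its closed forms and warns on absent classes", {
  labels <- c("NC", "NC", "MCI", "MCI", "AD", "AD")
  perfect <- rbind(c(.8, .1, .1), c(.9, .05, .05), c(.1, .8, .1),
                   c(.2, .7, .1), c(.1, .2, .7), c(.05, .05, .9))
  expect_equal(mauc(perfect, labels), 1)
  # identical scores for everyone: pure ties, AUC 1/2 per class
  flat <- matrix(1 / 3, 6, 3)
  expect_equal(mauc(flat, labels), 0.5)
  expect_warning(mauc(perfect[1:4, ], labels[1:4]), "absent")
})

test_that("multiclass AUC equals the pairwise-counting oracle under fuzz", {
  set.seed(101)
  for (trial in 1:300) {
    n <- sample(3:30, 1)
    labels <- sample(dx_levels(), n, replace = TRUE)
    probs <- matrix(round(runif(n * 3), 1), n, 3)   # rounding induces ties
    probs <- probs / pmax(rowSums(probs), 1e-9)
    got <- suppressWarnings(mauc(probs, labels))
    want <- oracle_mauc(probs, labels)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("label shuffling drives mAUC to chance", {
  set.seed(102)
  n <- 600
  labels <- sample(dx_levels(), n, replace = TRUE)
  probs <- matrix(runif(n * 3), n, 3)
  probs <- probs / rowSums(probs)
  expect_equal(mauc(probs, sample(labels)), 0.5, tolerance = 0.06)
})

test_that("balanced class accuracy averages sensitivity and specificity", {
  labels <- c("NC", "NC", "MCI", "AD")
  expect_equal(bca(labels, labels), 1)
  # chance level under independence
  set.seed(103)
  lab <- sample(dx_levels(), 3000, replace = TRUE)
  prd <- sample(dx_levels(), 3000, replace = TRUE)
  expect_equal(bca(prd, lab), 0.5, tolerance = 0.03)
  expect_warning(bca(c("NC", "MCI"), c("NC", "MCI")), "absent")
  # hand-computed two-class case folded into three classes
  lab2 <- c("NC", "NC", "NC", "MCI")
  prd2 <- c("NC", "NC", "MCI", "MCI")
  # NC: sens 2/3, spec 1 -> 5/6 ; MCI: sens 1, spec 2/3 -> 5/6
  expect_equal(suppressWarnings(bca(prd2, lab2)), 5 / 6)
})

test_that("MAE is exact, translation-faithful, and NA-safe", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(1, 2, 3) + 0.7, c(1, 2, 3)), 0.7)
  expect_equal(mae(c(2, 4, 1, 9), c(1, 1, 1, 1)), (1 + 3 + 0 + 8) / 4)
  expect_true(is.na(mae(numeric(0), numeric(0))))
})

test_that("the corrected resampled t-test matches the closed formula", {
  expect_equal(corrected_resampled_ttest(1:5, 1:5, 90, 5)$p, 1)
  set.seed(104)
  d <- round(rnorm(20, 0.02, 0.05), 4)
  a <- runif(20); b <- a - d
  r <- corrected_resampled_ttest(a, b, n_train = 180, n_test = 10)
  t_hand <- mean(d) / sqrt((1 / 20 + 10 / 180) * var(d))
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$p, 2 * pt(-abs(t_hand), 19), tolerance = 1e-12)

  # the correction always shrinks |t| relative to the naive paired test
  t_naive <- mean(d) / sqrt(var(d) / 20)
  expect_lt(abs(r$t), abs(t_naive))

  # as n_test/n_train -> 0 it reduces to the classical paired t-test
  r0 <- corrected_resampled_ttest(a, b, n_train = 1e12, n_test = 1)
  classical <- t.test(a, b, paired = TRUE)
  expect_equal(r0$t, unname(classical$statistic), tolerance = 1e-6)
  expect_equal(r0$p, classical$p.value, tolerance = 1e-6)

  expect_warning(r1 <- corrected_resampled_ttest(rep(1, 5), rep(0, 5),
                                                 10, 1), "variance")
  expect_equal(r1$p, 0)
})

test_that("BH step-up decisions match the hand-run procedure", {
  expect_true(fdr_adjust(0.01)$reject)
  expect_false(any(fdr_adjust(rep(1, 6))$reject))
  r <- fdr_adjust(c(0.01, 0.02, 0.04, 0.9))
  expect_equal(r$adjusted, c(0.04, 0.04, 4 * 0.04 / 3, 0.9))
  expect_identical(r$reject, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("forecast scoring aligns to observed months only", {
  tt <- make_traj(c(0, 6, 12, 18), dx = c("NC", "NC", NA, "MCI"),
                  ADAS13 = c(10, 11, NA, 14),
                  Ventricles = c(4e4, NA, NA, 4.4e4),
                  ICV = c(1.6e6, NA, NA, 1.6e6))
  x <- cohort(list(tt))
  fc <- data.frame(subject_id = "s1", month = 7:18,
                   p_NC = 0.6, p_MCI = 0.3, p_AD = 0.1,
                   ADAS13 = 12, Ventricles = 4.2e4, ICV = 1.6e6,
                   check.names = FALSE)
  ev <- evaluate_forecasts(fc, x)
  expect_equal(ev$n_dx, 1L)            # only month 18 has an observed DX
  expect_equal(ev$n_adas, 1L)
  expect_equal(ev$adas_mae, 2)         # |12 - 14|
  expect_equal(ev$n_vent, 1L)          # needs Ventricles AND ICV observed
  expect_equal(ev$ventricles_mae, abs(4.2e4 - 4.4e4) / 1.6e6,
               tolerance = 1e-10)
  # a precomputed ventricles_icv column takes precedence
  fc2 <- fc
  fc2$ventricles_icv <- 4.4e4 / 1.6e6
  ev2 <- evaluate_forecasts(fc2, x)
  expect_equal(ev2$ventricles_mae, 0)
})

test_that("subjects are grouped by their diagnostic trajectory", {
  mk <- function(id, dxs) {
    n <- length(dxs)
    make_full_traj(seq(0, by = 6, length.out = n), dxs, id = id)
  }
  x <- cohort(list(
    mk("a", c("NC", "NC", "NC", "NC")),       # NC-S
    mk("b", c("MCI", "MCI", "AD", "AD")),     # MCI-P
    mk("c", c("NC", "NC", "MCI", "NC")),      # NC-S (worked example)
    mk("d", c("MCI", "MCI", "NC", "NC")),     # MCI-R
    mk("e", c("AD", "AD", "AD", "AD")),       # AD
    mk("f", c("AD", "AD", "MCI", "MCI"))))    # AD reverter: excluded
  fc <- do.call(rbind, lapply(x$subjects, function(s)
    constant_forecast(s, 18, input_slots = split_timepoints(s)$input_slots)))
  gb <- group_breakdown(fc, x)
  expect_identical(gb$group, c("NC-S", "NC-P", "MCI-R", "MCI-S", "MCI-P",
                               "AD"))
  expect_equal(gb$n_subjects[gb$group == "NC-S"], 2L)
  expect_equal(gb$n_subjects[gb$group == "MCI-P"], 1L)
  expect_equal(gb$n_subjects[gb$group == "MCI-R"], 1L)
  expect_equal(gb$n_subjects[gb$group == "AD"], 1L)
  expect_equal(sum(gb$n_subjects), 5L)        # the reverter is dropped
  # constant prediction is perfect on stable groups, wrong on movers
  expect_equal(gb$dx_accuracy[gb$group == "AD"], 1)
  expect_equal(gb$dx_accuracy[gb$group == "MCI-R"], 0)
})

test_that("yearly buckets split at 12-month boundaries", {
  tt <- make_traj(c(0, 6, 12, 18, 24), dx = rep("NC", 5),
                  ADAS13 = c(10, 11, 12, 13, 14))
  x <- cohort(list(tt))
  # inputs: first 3 timepoints (months 0-12); targets at months 18 and 24
  fc <- constant_forecast(tt, 12, input_slots = split_timepoints(tt)$input_slots)
  yb <- yearly_breakdown(fc, x)
  expect_equal(yb$n_dx[1], 2L)   # rel months 6 and 12 both land in year 1
  expect_equal(yb$n_dx[2], 0L)
  # month 13 after the last input is year 2: check the boundary directly
  tt2 <- make_traj(c(0, 12, 24, 25), dx = rep("NC", 4))
  x2 <- cohort(list(tt2))
  fc2 <- constant_forecast(tt2, 13,
                           input_slots = split_timepoints(tt2)$input_slots)
  yb2 <- yearly_breakdown(fc2, x2)
  expect_equal(yb2$n_dx[1], 1L)         # rel 12 -> year 1
  expect_equal(yb2$n_dx[2], 1L)         # rel 13 -> year 2
  expect_true(all(yb2$n_dx[3:6] == 0L))
  expect_true(all(is.na(yb2$mauc[3:6])))

  # growing errors produce nondecreasing yearly MAE
  tt3 <- make_traj(c(0, 6, 18, 30, 42), dx = rep("NC", 5),
                   ADAS13 = c(10, 10, 12, 14, 16))
  x3 <- cohort(list(tt3))
  fc3 <- constant_forecast(tt3, 36,
                           input_slots = split_timepoints(tt3)$input_slots)
  yb3 <- yearly_breakdown(fc3, x3)
  maes <- yb3$adas_mae[!is.na(yb3$adas_mae)]
  expect_true(all(diff(maes) >= 0))
})
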