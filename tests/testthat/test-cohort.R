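test_that("long CSV round trip preserves subjects, visits and values", {
  df <- rbind(
    make_visits(c(0, 6, 12), dx = c("NC", NA, "MCI"),
                ADAS13 = c(20, NA, 25), MMSE = c(29, 28, NA)),
    make_visits(c(0, 7, 13), dx = c("AD", "AD", NA),
                Ventricles = c(5e4, 5.1e4, 5.2e4), ICV = c(1.5e6, NA, 1.5e6)))
  df <- cbind(subject_id = rep(c("a", "b"), each = 3), df)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")

  x <- read_cohort(path)
  expect_length(x, 2L)
  expect_identical(names(x$subjects), c("a", "b"))
  expect_equal(nrow(x$subjects$a$visit_record), 3L)
  expect_equal(nrow(x$subjects$b$visit_record), 3L)
  # values land on the right slots
  a <- x$subjects$a
  expect_equal(a$values[1, 3 + match("ADAS13", marker_names)], 20)
  expect_equal(a$values[13, 3 + match("ADAS13", marker_names)], 25)
  expect_identical(a$values[1, 1:3], c(1, 0, 0))

  # write-out and re-read is stable
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(x, path2)
  x2 <- read_cohort(path2)
  expect_equal(x$subjects$a$values, x2$subjects$a$values)
  expect_equal(x$subjects$b$observed, x2$subjects$b$observed)
})

test_that("degenerate and malformed CSV inputs are handled per contract", {
  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_length(read_cohort(empty), 0L)

  df <- cbind(subject_id = "a", make_visits(0, dx = "Dementia"))
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, bad, row.names = FALSE, na = "")
  expect_error(read_cohort(bad), "Dementia")

  df2 <- cbind(subject_id = "a", make_visits(0, dx = "NC"))
  df2$bogus <- 1
  bad2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df2, bad2, row.names = FALSE, na = "")
  expect_error(read_cohort(bad2), "bogus")

  df3 <- cbind(subject_id = "a", make_visits(c(0, 6), dx = c("NC", "NC")))
  df3$ADAS13 <- c("twenty", "")
  bad3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df3, bad3, row.names = FALSE, na = "")
  expect_error(read_cohort(bad3), "ADAS13")
})

test_that("TADPOLE dialect columns and labels are mapped", {
  df <- cbind(RID = c("7", "7"), make_visits(c(0, 6), dx = c("NL", "Dementia"),
                                             ADAS13 = c(10, 12)))
  names(df)[2] <- "Month_bl"
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  x <- read_cohort_tadpole(path)
  expect_identical(names(x$subjects), "7")
  expect_identical(x$subjects[["7"]]$values[1, 1:3], c(1, 0, 0))
  expect_identical(x$subjects[["7"]]$values[7, 1:3], c(0, 0, 1))
})

test_that("monthly grid assigns visits to nearest slots", {
  t1 <- make_traj(c(0, 8), dx = c("NC", "NC"))
  expect_length(t1$grid_months, 9L)
  expect_true(all(t1$observed[c(1, 9), 1]))
  expect_false(any(t1$observed[2:8, 1]))

  # resolution 6: month 8 is nearer slot 6 (distance 2) than slot 12
  t6 <- make_traj(c(0, 8), dx = c("NC", "MCI"), resolution = 6)
  expect_identical(t6$grid_months, c(0, 6))
  expect_identical(t6$values[2, 1:3], c(0, 1, 0))

  # month 4 maps to slot 6 (distance 2 < 4)
  t6b <- make_traj(c(0, 4), dx = c("NC", "MCI"), resolution = 6)
  expect_identical(t6b$grid_months, c(0, 6))
  expect_identical(t6b$values[2, 1:3], c(0, 1, 0))

  # exhaustive nearest-slot oracle for months 0..30 at resolution 6
  for (m in 1:30) {
    tt <- make_traj(c(0, m), dx = c("NC", "MCI"), resolution = 6)
    slots <- seq(0, 36, by = 6)
    best <- slots[order(abs(slots - m), slots)][1]
    got <- tt$grid_months[tt$visit_record$slot[2]]
    expect_equal(got, best, info = paste("month", m))
  }
})

test_that("gridding at resolution 1 conserves observations (round trip)", {
  sim <- sim_small(10, seed = 42)
  for (s in sim$cohort$subjects) {
    expect_identical(s$grid_months[s$visit_record$slot], s$visit_record$month)
    # every visit's observations present: count mask entries
    expect_identical(sum(s$observed), sum(s$observed[s$visit_record$slot, ]))
  }
})

test_that("grid slot collisions merge with nearest-visit priority", {
  # months 5 and 8 both map to slot 6 at resolution 6; 5 is nearer (dist 1)
  tt <- make_traj(c(0, 5, 8), dx = c("NC", "MCI", "AD"),
                  ADAS13 = c(10, NA, 30), resolution = 6)
  expect_identical(tt$grid_months, c(0, 6))
  expect_identical(tt$values[2, 1:3], c(0, 1, 0))    # nearer visit wins DX
  # disjoint features of the farther visit are merged in
  expect_equal(tt$values[2, 3 + match("ADAS13", marker_names)], 30)
})

test_that("one-hot diagnosis encoding follows the NC/MCI/AD convention", {
  expect_identical(one_hot_diagnosis("NC"), c(1, 0, 0))
  expect_identical(one_hot_diagnosis("MCI"), c(0, 1, 0))
  expect_identical(one_hot_diagnosis("AD"), c(0, 0, 1))
  expect_true(all(is.na(one_hot_diagnosis(NA))))
  expect_error(one_hot_diagnosis("dementia"), "dementia")
})

test_that("z-normalization centers and scales training observations", {
  sim <- sim_small(25, seed = 7)
  x <- sim$cohort
  st <- fit_norm_stats(x)
  xn <- znormalize(x, st)
  vals <- do.call(rbind, lapply(xn$subjects, function(s) {
    v <- s$values[, 4:25, drop = FALSE]
    v[!s$observed[, 2:23, drop = FALSE]] <- NA
    v
  }))
  expect_equal(unname(colMeans(vals, na.rm = TRUE)), rep(0, 22),
               tolerance = 1e-8)
  expect_equal(unname(apply(vals, 2, sd, na.rm = TRUE)), rep(1, 22),
               tolerance = 1e-8)

  # round trip is the identity
  back <- denormalize(xn, st)
  expect_equal(back$subjects[[1]]$values, x$subjects[[1]]$values,
               tolerance = 1e-10)

  # a single observed value equal to the training mean maps to 0
  j <- match("MMSE", marker_names)
  tt <- make_traj(0, dx = "NC", MMSE = unname(st$mean[j]))
  tn <- adprogress:::.normalize_traj(tt, st)
  expect_equal(tn$values[1, 3 + j], 0, tolerance = 1e-12)

  # constant features are refused by name
  flat <- cohort(list(make_traj(c(0, 6), dx = c("NC", "NC"),
                                MMSE = c(28, 28), ADAS13 = c(10, 11))))
  expect_error(fit_norm_stats(flat), "MMSE")
})

test_that("split plans give 18:1:1 ratios and disjoint covering test sets", {
  ids <- sprintf("x%03d", 1:400)
  subs <- lapply(ids, function(id) make_traj(0, dx = "NC", id = id))
  x <- cohort(subs)
  plans <- make_split_plan(x, 20, seed = 5)
  test_sets <- lapply(plans, `[[`, "test")
  expect_true(all(lengths(test_sets) == 20L))
  expect_identical(sort(unlist(test_sets)), ids)     # tiling coverage
  for (p in plans) {
    expect_length(p$train, 360L)
    expect_length(p$val, 20L)
    expect_length(intersect(p$train, p$test), 0L)
    expect_length(intersect(p$val, p$test), 0L)
  }
  # too-small cohorts and too many repeats are refused
  small <- cohort(lapply(1:19, function(i)
    make_traj(0, dx = "NC", id = paste0("s", i))))
  expect_error(make_split_plan(small, 2), "too small")
  expect_error(make_split_plan(x, 21), "20")
})

test_that("held-out subjects split timepoints first half input, rest target", {
  tt <- make_traj(seq(0, 30, by = 6), dx = rep("NC", 6))
  sp <- split_timepoints(tt)
  expect_length(sp$input_slots, 3L)
  expect_length(sp$target_slots, 3L)
  expect_true(max(sp$input_slots) < min(sp$target_slots))

  odd <- make_traj(seq(0, 24, by = 6), dx = rep("NC", 5))
  spo <- split_timepoints(odd)
  expect_length(spo$input_slots, 3L)      # ceil(5/2) on the input side

  single <- make_traj(0, dx = "NC")
  sps <- split_timepoints(single)
  expect_length(sps$input_slots, 1L)
  expect_length(sps$target_slots, 0L)
})
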