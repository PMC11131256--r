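test_that("per-frame pose JSON is parsed into a skeleton sequence", {
  dir <- withr::local_tempdir()
  # frame 0: one person, recognizable numbers; neck (joint 1) = entries 4-6
  kp <- as.numeric(seq_len(75))
  jsonlite::write_json(list(version = 1.3, people = list(list(pose_keypoints_2d = kp / 100))),
                       file.path(dir, "sub_000000000000_keypoints.json"),
                       auto_unbox = TRUE, digits = 8)
  # frame 1: nobody detected
  jsonlite::write_json(list(version = 1.3, people = list()),
                       file.path(dir, "sub_000000000001_keypoints.json"),
                       auto_unbox = TRUE, digits = 8)
  seq <- read_openpose_sequence(dir, "sub", "ADHD")
  expect_s3_class(seq, "skeleton_sequence")
  expect_equal(n_frames(seq), 2L)
  fr <- get_frame(seq, 1)
  expect_equal(unname(fr["neck", ]), c(4, 5, 6) / 100)
  expect_true(all(get_frame(seq, 2)[, "confidence"] == 0))
  expect_true(all(is.na(get_frame(seq, 2)[, c("x", "y")])))
})

test_that("malformed pose files raise errors naming the file", {
  dir <- withr::local_tempdir()
  writeLines("{not json", file.path(dir, "f_1.json"))
  expect_error(read_openpose_sequence(dir, "s", "ADHD"), "f_1\\.json")

  dir2 <- withr::local_tempdir()
  jsonlite::write_json(list(people = list(list(pose_keypoints_2d = as.numeric(1:74)))),
                       file.path(dir2, "g_1.json"), auto_unbox = TRUE)
  expect_error(read_openpose_sequence(dir2, "s", "ADHD"), "74.*g_1\\.json")

  dir3 <- withr::local_tempdir()
  jsonlite::write_json(list(people = list()), file.path(dir3, "noframe.json"),
                       auto_unbox = TRUE)
  expect_error(read_openpose_sequence(dir3, "s", "ADHD"), "noframe\\.json")
})

test_that("frames are ordered by numeric suffix, not lexicographically", {
  dir <- withr::local_tempdir()
  for (i in c(2, 10, 1)) {
    kp <- rep(0, 75); kp[1] <- i; kp[3] <- 0.9   # nose x encodes frame number
    jsonlite::write_json(list(people = list(list(pose_keypoints_2d = kp))),
                         file.path(dir, sprintf("v_%d_keypoints.json", i)),
                         auto_unbox = TRUE, digits = 8)
  }
  seq <- read_openpose_sequence(dir, "v", "non-ADHD")
  expect_equal(seq$x[, 1], c(1, 2, 10))
})

test_that("primary-person selection follows the tracking and confidence rules", {
  near <- cbind(matrix(c(100, 100), 25, 2, byrow = TRUE), 0.5)
  far <- cbind(matrix(c(500, 500), 25, 2, byrow = TRUE), 0.9)
  prev <- cbind(matrix(c(101, 99), 25, 2, byrow = TRUE), 0.8)
  # hand computation: mean distance near -> sqrt(1+1), far -> sqrt(399^2+401^2)
  expect_equal(select_primary_person(list(far, near), prev), near)
  # no previous frame: largest confidence sum wins (20.1 vs 3.2 scaled)
  hi <- cbind(matrix(0, 25, 2), 20.1 / 25); lo <- cbind(matrix(0, 25, 2), 3.2 / 25)
  expect_equal(select_primary_person(list(hi, lo)), hi)
  expect_equal(select_primary_person(list(lo, hi)), hi)
  # single candidate
  expect_equal(select_primary_person(list(near)), near)
  # all-missing previous falls back to the confidence rule
  gone <- cbind(matrix(0, 25, 2), 0)
  expect_equal(select_primary_person(list(lo, hi), gone), hi)
})

test_that("selection is permutation-invariant up to the index tie-break", {
  set.seed(11)
  prev <- cbind(runif(25, 0, 100), runif(25, 0, 100), runif(25, 0.2, 1))
  cands <- lapply(1:4, function(i)
    cbind(runif(25, 0, 100), runif(25, 0, 100), runif(25, 0.2, 1)))
  chosen <- select_primary_person(cands, prev)
  for (perm in list(4:1, c(2, 4, 1, 3))) {
    expect_equal(select_primary_person(cands[perm], prev), chosen)
  }
})

test_that("gap repair interpolates short interior runs and reports the rest", {
  Tn <- 30
  x <- matrix(100, Tn, 25); y <- matrix(200, Tn, 25)
  conf <- matrix(0.8, Tn, 25)
  # joint 0: single missing frame between x=100 (t=11) and x=104 (t=13)
  x[13, 1] <- 104; x[11, 1] <- 100
  conf[12, 1] <- 0
  # joint 2: run of 7 missing frames (exceeds max_gap = 5)
  conf[10:16, 3] <- 0
  # joint 3: missing run touching the start
  conf[1:2, 4] <- 0
  seq <- skeleton_sequence(x, y, conf, "s", "ADHD")
  rep5 <- repair_missing_joints(seq, max_gap = 5)
  expect_equal(rep5$sequence$x[12, 1], 102)  # midpoint
  expect_equal(rep5$sequence$confidence[12, 1], 0.8)
  expect_equal(rep5$report$filled[1], 1L)
  expect_true(all(rep5$sequence$confidence[10:16, 3] == 0))
  expect_equal(rep5$report$unfilled[3], 7L)
  expect_true(all(rep5$sequence$confidence[1:2, 4] == 0))
  expect_equal(rep5$report$unfilled[4], 2L)
})

test_that("repair never alters detected joints and never adds missingness", {
  set.seed(21)
  co <- generate_cohort(cohort_config(n_adhd = 1, n_non_adhd = 1, duration_s = 4,
                                      missing_prob = 0.1), seed = 21)
  for (seq in co) {
    out <- repair_missing_joints(seq, max_gap = 3)$sequence
    was <- seq$confidence > 0
    expect_equal(out$x[was], seq$x[was])
    expect_equal(out$y[was], seq$y[was])
    expect_lte(sum(out$confidence == 0), sum(seq$confidence == 0))
  }
  # a fully detected sequence is returned unchanged
  full <- make_sequence(random_coords(10, seed = 3))
  rep0 <- repair_missing_joints(full)
  expect_equal(rep0$sequence, full)
  expect_equal(sum(rep0$report$filled) + sum(rep0$report$unfilled), 0L)
})

test_that("CSV round trip is lossless and validates its columns", {
  set.seed(31)
  seq <- generate_cohort(cohort_config(n_adhd = 1, n_non_adhd = 1, duration_s = 2,
                                       missing_prob = 0.05), seed = 31)[[1]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_sequence_csv(seq, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), n_frames(seq) * 25)
  back <- read_sequence_csv(path)
  expect_equal(back, seq)

  # a 3-frame fixture has exactly 3 x 25 rows
  small <- make_sequence(random_coords(3, seed = 5))
  write_sequence_csv(small, path)
  expect_equal(nrow(utils::read.csv(path)), 75L)
  expect_equal(read_sequence_csv(path), small)

  # missing required column
  bad <- utils::read.csv(path)
  bad$joint <- NULL
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_sequence_csv(path), "joint")
  # empty file
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("", empty)
  expect_error(read_sequence_csv(empty))
})

test_that("pose JSON written by the generator reads back identically", {
  seq <- generate_cohort(cohort_config(n_adhd = 1, n_non_adhd = 1, duration_s = 1,
                                       missing_prob = 0.02), seed = 41)[[1]]
  dir <- withr::local_tempdir()
  write_openpose_json(seq, dir, spurious_person_prob = 0)
  back <- read_openpose_sequence(dir, seq$subject_id, seq$label, fps = seq$fps)
  expect_equal(back$x, seq$x, tolerance = 1e-6)
  expect_equal(back$confidence, seq$confidence, tolerance = 1e-6)

  # with a second person in some frames, tracking still follows the subject
  dir2 <- withr::local_tempdir()
  write_openpose_json(seq, dir2, spurious_person_prob = 0.5, seed = 42)
  back2 <- read_openpose_sequence(dir2, seq$subject_id, seq$label, fps = seq$fps)
  expect_equal(back2$x, seq$x, tolerance = 1e-6)
})
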