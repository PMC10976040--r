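# 1 s epochs at 0.5 s steps: 60 epochs start inside each full 30 s window
make_epoch_grid <- function(duration_s) {
  seq(0, duration_s - 1, by = 0.5)
}

test_that("the majority window rule is strict at 50%", {
  starts <- make_epoch_grid(60)       # two 30 s windows, 60 epochs each
  pred <- rep(0L, length(starts))
  w1 <- starts < 30

  pred[which(w1)[1:31]] <- 1L         # 31/60 = 51.7% -> positive
  dec <- window_decisions(pred, starts, duration_s = 60)
  expect_true(dec$positive[1])
  expect_equal(dec$n_epochs[1], 60L)
  expect_equal(dec$n_positive[1], 31L)

  pred[which(w1)[31]] <- 0L           # exactly 30/60 -> negative
  dec <- window_decisions(pred, starts, duration_s = 60)
  expect_false(dec$positive[1])

  dec0 <- window_decisions(rep(0L, length(starts)), starts, duration_s = 60)
  expect_false(any(dec0$positive))
  expect_error(window_decisions(integer(0), numeric(0)), "No epoch")
})

test_that("consecutive false windows merge into single false detections", {
  starts <- make_epoch_grid(360)      # 12 windows
  pred <- rep(0L, length(starts))
  for (w in c(3, 4, 5, 9)) {          # windows indexed from 1
    idx <- which(starts >= (w - 1) * 30 & starts < w * 30)
    pred[idx[1:40]] <- 1L
  }
  dec <- window_decisions(pred, starts, duration_s = 360)
  expect_equal(which(dec$positive), c(3L, 4L, 5L, 9L))
  rep_ <- score_events(dec, annotation_set(numeric(0)), duration_h = 0.1)
  expect_equal(rep_$false_detections, 2L)
  expect_equal(rep_$fd_per_hour, 20)
})

test_that("detection latency is the first covering window end minus onset", {
  duration_s <- 3000
  starts <- make_epoch_grid(duration_s)
  ann <- annotation_set(2807, 2866)
  pred <- as.integer(starts >= 2807 & starts < 2866)
  dec <- window_decisions(pred, starts, duration_s = duration_s)
  # window 94 spans [2790, 2820): 26 of 60 epochs ictal -> negative;
  # window 95 spans [2820, 2850): fully ictal -> positive
  rep_ <- score_events(dec, ann, duration_h = duration_s / 3600)
  expect_true(rep_$seizures$detected[1])
  expect_equal(rep_$seizures$latency_s[1], 2850 - 2807)
  expect_equal(rep_$false_detections, 0L)

  # a manually asserted positive window overlapping the seizure start
  dec2 <- tibble::tibble(index = 94:95, start_s = c(2790, 2820),
                         end_s = c(2820, 2850), n_epochs = c(60L, 60L),
                         n_positive = c(40L, 60L), positive = c(TRUE, TRUE))
  rep2 <- score_events(dec2, ann, duration_h = 1)
  expect_equal(rep2$seizures$latency_s[1], 2820 - 2807)
})

test_that("missed seizures and empty predictions score cleanly", {
  starts <- make_epoch_grid(120)
  dec <- window_decisions(rep(0L, length(starts)), starts, duration_s = 120)
  rep_ <- score_events(dec, annotation_set(50, 80), duration_h = 120 / 3600)
  expect_equal(rep_$false_detections, 0L)
  expect_equal(rep_$n_detected, 0L)
  expect_false(rep_$seizures$detected[1])
  expect_true(is.na(rep_$seizures$latency_s[1]))
})

count_runs_ref <- function(idx) {
  if (length(idx) == 0) return(0L)
  sum(diff(idx) > 1) + 1L
}

test_that("false-detection merging changes the count by at most one per window", {
  withr::with_seed(31, {
    for (i in 1:25) {
      idx <- sort(sample(1:40, sample(0:12, 1)))
      base <- count_runs_ref(idx)
      extra <- sample(setdiff(1:40, idx), 1)
      grown <- count_runs_ref(sort(c(idx, extra)))
      expect_gte(grown, base - 1)
      expect_lte(grown, base + 1)
    }
  })
})

test_that("rates scale inversely with duration and reject bad durations", {
  expect_equal(round(fd_per_hour(28, 24.1), 1), 1.2)
  expect_equal(round(fd_per_hour(5, 24), 1), 0.2)
  expect_equal(fd_per_hour(0, 10), 0)
  expect_equal(fd_per_hour(6, 2), 2 * fd_per_hour(6, 4))
  expect_error(fd_per_hour(1, 0), "positive")
})

test_that("aggregation reproduces totals, means and population deviations", {
  per <- tibble::tibble(
    duration_h = c(10, 20), n_seizures = c(2L, 4L),
    false_detections = c(1L, 3L), fd_per_hour = c(0.1, 0.15)
  )
  agg <- aggregate_reports(per)$aggregate
  expect_equal(agg$duration_h, c(30, 15, 5))
  expect_equal(agg$false_detections, c(4, 2, 1))
  expect_equal(agg$fd_per_hour[2], 0.125)
  expect_equal(agg$fd_per_hour[3], 0.025)

  single <- aggregate_reports(per[1, ])$aggregate
  expect_equal(single$duration_h, c(10, 10, 0))
  expect_equal(single$fd_per_hour[3], 0)

  expect_error(aggregate_reports(list()), "No reports")
})

test_that("aggregation accepts a list of scored event reports", {
  starts <- make_epoch_grid(120)
  dec <- window_decisions(as.integer(starts >= 30 & starts < 60), starts,
                          duration_s = 120)
  r1 <- score_events(dec, annotation_set(30, 60), duration_h = 1, "a")
  r2 <- score_events(dec, annotation_set(numeric(0)), duration_h = 2, "b")
  agg <- aggregate_reports(list(r1, r2))
  expect_equal(nrow(agg$per_recording), 2L)
  expect_equal(agg$aggregate$false_detections[1], 0 + 1)
  expect_equal(agg$per_recording$fd_per_hour, c(0, 0.5))
})

test_that("channel-vote fusion implements majority, any and all", {
  pm <- rbind(c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 0, 0, 0))
  expect_equal(fuse_predictions(pm, "majority"), c(1L, 0L, 0L, 0L))
  expect_equal(fuse_predictions(pm, "any"), c(1L, 1L, 1L, 0L))
  expect_equal(fuse_predictions(pm, "all"), c(1L, 0L, 0L, 0L))
})
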