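map_case <- function(map, id = "c1") {
  tibble::tibble(case_id = id, time_min = seq_along(map) - 1, MAP = map)
}

test_that("event detection finds maximal sub-threshold runs", {
  ev <- detect_ioh_events(map_case(c(70, 64, 64, 70)))
  expect_equal(ev$start_min, 1L)
  expect_equal(ev$end_min, 2L)
  expect_equal(ev$threshold, 65)

  expect_equal(nrow(detect_ioh_events(map_case(c(70, 80, 66)))), 0L)

  # missing MAP breaks a run
  ev2 <- detect_ioh_events(map_case(c(60, NA, 60, 60)))
  expect_equal(ev2$start_min, c(0L, 2L))
  expect_equal(ev2$end_min, c(0L, 3L))

  # minimum duration filters short runs
  ev3 <- detect_ioh_events(map_case(c(60, 70, 60, 60)),
                           label_config(min_duration = 2))
  expect_equal(ev3$start_min, 2L)

  expect_warning(ev4 <- detect_ioh_events(map_case(rep(NA_real_, 5))),
                 "entirely missing")
  expect_equal(nrow(ev4), 0L)
})

test_that("event detection matches the brute-force scan on random series", {
  set.seed(11)
  for (i in 1:200) {
    D <- sample(5:80, 1)
    map <- rnorm(D, 68, 6)
    map[runif(D) < 0.1] <- NA
    md <- sample(1:3, 1)
    got <- detect_ioh_events(map_case(map), label_config(min_duration = md))
    ref <- ref_detect_events(map, 65, md)
    expect_equal(got$start_min, ref$start_min)
    expect_equal(got$end_min, ref$end_min)
  }
  # one long series exercises the linear scan at scale
  set.seed(12)
  long <- rnorm(10000, 67, 5)
  got <- detect_ioh_events(map_case(long))
  ref <- ref_detect_events(long, 65, 1)
  expect_equal(got$start_min, ref$start_min)
  expect_equal(got$end_min, ref$end_min)
})

test_that("epoch labels mark horizons before event starts", {
  # event starting at minute 30: epochs ending 25..29 are positive (horizon 5)
  map <- rep(85, 60)
  map[31:34] <- 60   # minutes 30..33
  labs <- label_epochs(map_case(map), label_config(horizon = 5, seq_len = 15))
  pos <- labs$t_end[!is.na(labs$label) & labs$label == 1L]
  expect_equal(pos, 25:29)
  # epochs inside the event are excluded, not negative
  expect_true(all(labs$reason[labs$t_end %in% 30:33] == "in_event"))
  # all other retained epochs negative
  expect_true(all(labs$label[labs$t_end < 25 & !is.na(labs$label)] == 0L))

  # a series with no sub-threshold minutes: all retained epochs negative
  labs2 <- label_epochs(map_case(rep(80, 40)), label_config(horizon = 5))
  expect_true(all(labs2$label == 0L))
  expect_equal(labs2$t_end, 14:34)   # full history + full future required
})

test_that("epoch labeling matches the exhaustive window scan on random series", {
  set.seed(13)
  for (i in 1:200) {
    D <- sample(25:90, 1)
    map <- rnorm(D, 67, 5)
    h <- sample(c(5L, 10L, 15L), 1)
    excl <- sample(c(TRUE, FALSE), 1)
    cfg <- label_config(horizon = h, seq_len = 15,
                        exclude_in_event_epochs = excl)
    got <- label_epochs(map_case(map), cfg)
    ref <- ref_label_epochs(map, 65, 1, h, 15, excl)
    expect_equal(got$t_end, ref$t_end)
    expect_identical(got$label, ref$label)
  }
})

test_that("lowering the threshold shrinks and nests the detected events", {
  # Sub-threshold coverage is monotone in the threshold, and every event at a
  # lower threshold nests inside an event at a higher one. (The raw event
  # COUNT is not monotone: a single 65-run can split into several 60-runs.)
  set.seed(14)
  minutes_of <- function(ev) {
    if (!nrow(ev)) return(integer(0))
    unlist(Map(seq.int, ev$start_min, ev$end_min))
  }
  for (i in 1:50) {
    map <- rnorm(sample(30:120, 1), 66, 6)
    e65 <- detect_ioh_events(map_case(map), label_config(threshold = 65))
    e60 <- detect_ioh_events(map_case(map), label_config(threshold = 60))
    e55 <- detect_ioh_events(map_case(map), label_config(threshold = 55))
    m65 <- minutes_of(e65); m60 <- minutes_of(e60); m55 <- minutes_of(e55)
    expect_lte(length(m60), length(m65))
    expect_lte(length(m55), length(m60))
    expect_true(all(m60 %in% m65))
    expect_true(all(m55 %in% m60))
  }
})

test_that("dataset construction counts epochs and stacks cases additively", {
  v1 <- make_simple_case(D = 30, case_id = "a", map = rep(80, 30))
  v2 <- make_simple_case(D = 42, case_id = "b", map = rep(80, 42))
  cases <- simple_cases_table(dplyr::bind_rows(v1, v2))
  cfg <- label_config(horizon = 5, seq_len = 15)
  d1 <- build_dataset(v1, cases, cfg)
  d2 <- build_dataset(v2, cases, cfg)
  d12 <- build_dataset(dplyr::bind_rows(v1, v2), cases, cfg)
  expect_equal(length(d1$y), 30 - 15 - 5 + 1)   # 11 epochs
  expect_equal(length(d12$y), length(d1$y) + length(d2$y))
  expect_equal(dim(d12$X_dyn), c(length(d12$y), 15, 17))
  expect_equal(ncol(d12$X_static), 2)

  # empty cohort -> empty dataset
  d0 <- build_dataset(v1[0, ], cases, cfg)
  expect_equal(length(d0$y), 0L)
})

test_that("windows hold the right history slice", {
  D <- 40
  v <- make_simple_case(D = D, map = seq_len(D) + 100)  # MAP = 101..140, no events
  cases <- simple_cases_table(v)
  ds <- build_dataset(v, cases, label_config(horizon = 5, seq_len = 15))
  st <- ds$stats[ds$stats$channel == "MAP", ]
  # epoch ending at t carries MAP at minutes t-14..t (de-normalized check)
  for (k in c(1L, length(ds$y))) {
    t_end <- ds$t_end[k]
    got <- ds$X_dyn[k, , match("MAP", ds$feature_names)] * st$sigma + st$mu
    expect_equal(got, (t_end - 14):t_end + 101, tolerance = 1e-8)
  }
})

test_that("patient-level splitting keeps families together and is reproducible", {
  cases <- tibble::tibble(case_id = sprintf("c%03d", 1:120),
                          patient_id = sprintf("p%03d", c(1:100, 1:20)))
  s1 <- split_by_patient(cases, train_frac = 0.8, seed = 7)
  s2 <- split_by_patient(cases, train_frac = 0.8, seed = 7)
  expect_identical(s1$train$case_id, s2$train$case_id)
  expect_length(intersect(s1$train$patient_id, s1$validation$patient_id), 0)
  expect_setequal(c(s1$train$case_id, s1$validation$case_id), cases$case_id)
  # multi-surgery patients land in one fold
  for (p in sprintf("p%03d", 1:20)) {
    folds <- c(p %in% s1$train$patient_id, p %in% s1$validation$patient_id)
    expect_equal(sum(folds), 1)
  }
  expect_error(split_by_patient(cases[1, ], seed = 1), "at least 2")

  # achieved case fraction close to target on a larger cohort
  set.seed(20)
  big <- tibble::tibble(case_id = as.character(1:550),
                        patient_id = as.character(c(1:500, sample(500, 50))))
  sb <- split_by_patient(big, train_frac = 0.8, seed = 3)
  expect_lt(abs(nrow(sb$train) / nrow(big) - 0.8), 0.02)
})
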