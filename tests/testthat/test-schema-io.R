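make_schema_yaml <- function(path, n_tn = 75, n_tc = 8) {
  writeLines(c(
    "time_name: charttime",
    "max_seq_len: 30",
    "static_numeric: [age, gender, mortality]",
    "static_categorical:",
    "  marital_status: [married, single, divorced]",
    "  religion: [none, catholic, other]",
    "  insurance: [medicare, private, medicaid]",
    "temporal_numeric:",
    paste0("  - lab", seq_len(n_tn)),
    "temporal_categorical:",
    vapply(seq_len(n_tc), function(i)
      paste0("  code", i, ": [a, b, c]"), "")
  ), path)
  path
}

test_that("schema config loads, validates and deduplicates vocabularies", {
  path <- make_schema_yaml(tempfile(fileext = ".yaml"))
  s <- load_schema(path)
  expect_length(s$static_numeric, 3L)
  expect_length(s$static_categorical, 3L)
  expect_length(s$temporal_numeric, 75L)
  expect_length(s$temporal_categorical, 8L)
  expect_equal(s$max_seq_len, 30L)

  minimal <- ehr_schema(temporal_numeric = "hr", max_seq_len = 1)
  expect_s3_class(minimal, "ehr_schema")

  expect_error(ehr_schema(static_numeric = c("age", "hr"),
                          temporal_numeric = "age"), "duplicate.*age")
  expect_error(ehr_schema(static_categorical = list(sex = "m")), ">= 2")
  expect_error(ehr_schema(time_name = "age", static_numeric = "age"),
               "clashes")
  expect_error(load_schema(tempfile()), "not found")

  s2 <- ehr_schema(static_categorical = list(g = c("m", "f", "m")),
                   temporal_numeric = "hr")
  expect_equal(s2$static_categorical$g, c("m", "f"))
  # write/load round trip
  p2 <- tempfile(fileext = ".yaml")
  write_schema(s, p2)
  expect_equal(load_schema(p2), s)
})

test_that("hand-built tables read into the expected padded record", {
  sch <- ehr_schema(static_numeric = "age",
                    static_categorical = list(sex = c("m", "f")),
                    temporal_numeric = c("hr", "glucose"),
                    temporal_categorical = list(rhythm = c("sinus", "afib")),
                    time_name = "time", max_seq_len = 4)
  sdir <- tempfile(); dir.create(sdir)
  writeLines(c("id,age,sex", "p1,60,m", "p2,70,"),
             file.path(sdir, "static.csv"))
  writeLines(c("id,time,feature,value",
               "p1,1,time,1", "p1,3,time,3",
               "p1,1,hr,80", "p1,1,glucose,100", "p1,3,hr,90",
               "p1,1,rhythm,sinus",
               "p2,2,time,2", "p2,2,hr,70"),
             file.path(sdir, "temporal.csv"))
  rd <- read_cohort(file.path(sdir, "static.csv"),
                    file.path(sdir, "temporal.csv"), sch)
  expect_equal(rd$data$lengths, c(2L, 1L))
  # visit 2 of p1 misses glucose: mask 0 exactly there
  expect_equal(rd$masks$m_tn[1, 1:2, "glucose"], c(1, 0))
  expect_equal(unname(rd$data$temporal_num[1, 2, "hr"]), 90)
  expect_true(is.na(rd$data$static_cat[2, "sex"]))
  expect_equal(rd$masks$step_present[1, ], c(1, 1, 0, 0))

  # unknown temporal feature
  writeLines(c("id,time,feature,value", "p1,1,time,1", "p1,1,spo2,99",
               "p2,1,time,1"),
             file.path(sdir, "bad.csv"))
  expect_error(read_cohort(file.path(sdir, "static.csv"),
                           file.path(sdir, "bad.csv"), sch), "spo2")
  # patient with zero temporal rows is rejected
  writeLines(c("id,time,feature,value", "p1,1,time,1"),
             file.path(sdir, "short.csv"))
  expect_error(read_cohort(file.path(sdir, "static.csv"),
                           file.path(sdir, "short.csv"), sch),
               "zero temporal steps.*p2")
})

test_that("write/read round trip is the identity on data and masks", {
  g <- tiny_cohort(n = 60, t_max = 6, seed = 21)
  td <- tempfile()
  paths <- write_cohort(g$data, g$masks, td)
  rt <- read_cohort(paths["static"], paths["temporal"], g$data$schema)
  for (blk in c("lengths", "ids", "temporal_cat", "static_cat")) {
    expect_identical(rt$data[[blk]], g$data[[blk]])
  }
  expect_equal(rt$data$time, g$data$time)
  expect_equal(rt$data$temporal_num, g$data$temporal_num)
  expect_equal(rt$data$static_num, g$data$static_num)
  for (blk in names(g$masks)) expect_equal(rt$masks[[blk]], g$masks[[blk]])
})

test_that("temporal row count follows the all-observed formula", {
  sch <- ehr_schema(temporal_numeric = c("a", "b"),
                    temporal_categorical = list(cc = c("x", "y")),
                    max_seq_len = 3)
  lens <- c(3L, 2L)
  tim <- rbind(c(1, 2, 3), c(1, 2, NA))
  tn <- array(1, c(2, 3, 2)); tn[2, 3, ] <- NA
  tc <- array("x", c(2, 3, 1)); tc[2, 3, ] <- NA
  d <- ehr_cohort(sch, c("p1", "p2"), matrix(NA_real_, 2, 0),
                  matrix(NA_character_, 2, 0), lens, tim, tn, tc)
  td <- tempfile()
  paths <- write_cohort(d, derive_masks(d), td)
  rows <- data.table::fread(paths["temporal"])
  expect_equal(nrow(rows), sum(lens) * (2 + 1 + 1))  # features + cat + time
  # empty cohort: valid (empty) tables
  d0 <- subset_cohort(d, integer(0))
  p0 <- write_cohort(d0, derive_masks(d0), tempfile())
  expect_equal(nrow(data.table::fread(p0["temporal"])), 0L)
})

test_that("percentile outlier filter masks the extreme tail", {
  sch <- ehr_schema(temporal_numeric = "v", max_seq_len = 1)
  n <- 1000
  d <- ehr_cohort(sch, sprintf("p%04d", 1:n), matrix(NA_real_, n, 0),
                  matrix(NA_character_, n, 0), rep(1L, n),
                  matrix(0, n, 1), array(1:n, c(n, 1, 1)),
                  array(NA_character_, c(n, 1, 0)))
  m <- derive_masks(d)
  out <- filter_outliers(d, m)
  masked <- which(is.na(out$data$temporal_num[, 1, 1]))
  expect_equal(sort(masked), c(1L, 1000L))  # the two most extreme values

  # drop_patient removes the offending records instead
  out2 <- filter_outliers(d, m, mode = "drop_patient")
  expect_equal(n_records(out2$data), n - 2L)

  # identity bounds leave everything untouched
  out3 <- filter_outliers(d, m, low_pct = 0, high_pct = 1)
  expect_equal(out3$data$temporal_num, d$temporal_num)

  # constant feature: nothing removed
  d2 <- d; d2$temporal_num[] <- 5
  out4 <- filter_outliers(d2, derive_masks(d2))
  expect_equal(sum(is.na(out4$data$temporal_num)), 0L)

  # fewer than 2 observed values: skipped with a warning
  d3 <- d; d3$temporal_num[2:n, 1, 1] <- NA
  d3$lengths <- rep(1L, n)
  expect_warning(filter_outliers(d3, derive_masks(d3)), "skipped")
})

test_that("tightening percentile bounds never unmasks a value", {
  g <- tiny_cohort(n = 60, t_max = 6, seed = 3)
  loose <- filter_outliers(g$data, g$masks, 0.01, 0.99)
  tight <- filter_outliers(g$data, g$masks, 0.05, 0.95)
  loose_na <- is.na(loose$data$temporal_num)
  tight_na <- is.na(tight$data$temporal_num)
  expect_true(all(tight_na[loose_na]))  # loose-masked stays masked
})

test_that("truncation keeps the last steps, pads the rest, and is idempotent", {
  g <- tiny_cohort(n = 50, t_max = 8, seed = 13)
  tp <- truncate_pad(g$data, g$masks, 3)
  i <- which(g$data$lengths >= 5)[1]
  src <- (g$data$lengths[i] - 2):g$data$lengths[i]
  expect_equal(tp$data$time[i, 1:3], g$data$time[i, src])
  expect_equal(tp$data$lengths[i], 3L)
  expect_equal(attr(tp$data, "orig_lengths")[i], g$data$lengths[i])
  j <- which(g$data$lengths == 1)[1]
  if (!is.na(j)) expect_equal(tp$masks$step_present[j, ], c(1, 0, 0))

  tp2 <- truncate_pad(tp$data, tp$masks, 3)
  expect_equal(tp2$data$temporal_num, tp$data$temporal_num)
  expect_equal(tp2$data$time, tp$data$time)

  one <- truncate_pad(g$data, g$masks, 1)
  expect_true(all(one$data$lengths == 1L))
  expect_equal(one$data$time[, 1],
               g$data$time[cbind(seq_len(50), g$data$lengths)])
  expect_silent(validate_cohort(tp$data, tp$masks))
})

test_that("per-patient split partitions the cohort reproducibly", {
  g <- tiny_cohort(n = 50, t_max = 4, seed = 2)
  sp <- split_cohort(g$data, 0.8, seed = 5)
  expect_equal(n_records(sp$train), 40L)
  expect_length(intersect(sp$train$ids, sp$test$ids), 0L)
  sp2 <- split_cohort(g$data, 0.8, seed = 5)
  expect_identical(sp$train$ids, sp2$train$ids)
})
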