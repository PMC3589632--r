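make_csv <- function(path, drop_amt = FALSE) {
  rows <- tibble::tibble(
    ID = rep(c("a", "b"), each = 4),
    TIME = rep(c(0, 24, 96, 170), 2),
    AMT = rep(c(64, NA, NA, NA), 2),
    RATE = rep(c(64 / 168, NA, NA, NA), 2),
    EVID = rep(c(1L, 0L, 0L, 0L), 2),
    DV = rep(c(NA, 8.5, 9.8, 4.1), 2),
    MDV = rep(c(1L, 0L, 0L, 0L), 2),
    CYCLE = 1L,
    AGE = rep(c(63, 55), each = 4), SEX = rep(c("male", "female"), each = 4),
    WT = rep(c(82, 70), each = 4), BSA = rep(c(1.97, 1.70), each = 4),
    SCR = rep(c(88.4, 70), each = 4), ALT = rep(c(19, 30), each = 4),
    STUDY = rep(c("NSCLC", "MM"), each = 4))
  if (drop_amt) rows$AMT <- NULL
  readr::write_csv(rows, path, na = "")
  path
}

test_that("loading a NONMEM-dialect file preserves counts and derives CLCR", {
  f <- make_csv(withr::local_tempfile(fileext = ".csv"))
  ds <- read_pk_dataset(f)
  expect_s3_class(ds, "pk_dataset")
  expect_equal(nrow(ds$patients), 2)
  expect_equal(nrow(ds$doses), 2)
  expect_equal(nrow(ds$observations), 6)
  expect_equal(sum(!ds$observations$excluded), 6)
  # CLCR derived from the umol/L creatinine at load time
  expect_equal(ds$patients$clcr[1],
               cockcroft_gault(63, 82, 1.0, "male"), tolerance = 1e-10)
  # observation at 170 h is after the 168-h infusion stop
  expect_equal(ds$observations$during_infusion,
               rep(c(TRUE, TRUE, FALSE), 2))
})

test_that("sub-LLOQ and missing concentrations are excluded, not dropped", {
  f <- withr::local_tempfile(fileext = ".csv")
  make_csv(f)
  raw <- readr::read_csv(f, show_col_types = FALSE)
  raw$DV[raw$ID == "a" & raw$TIME == 96] <- 0.04
  readr::write_csv(raw, f, na = "")
  ds <- read_pk_dataset(f)
  o <- ds$observations[ds$observations$patient_id == "a" &
                         ds$observations$time == 96, ]
  expect_true(o$blq)
  expect_true(o$excluded)
  expect_equal(nrow(ds$observations), 6)   # row retained for audit
  expect_equal(sum(!ds$observations$excluded), 5)
})

test_that("a file whose dose rows lack an amount fails closed", {
  f <- make_csv(withr::local_tempfile(fileext = ".csv"), drop_amt = TRUE)
  expect_error(read_pk_dataset(f), "schema error")
  # negative time names the offending row
  f2 <- withr::local_tempfile(fileext = ".csv")
  make_csv(f2)
  raw <- readr::read_csv(f2, show_col_types = FALSE)
  raw$TIME[2] <- -5
  readr::write_csv(raw, f2, na = "")
  expect_error(read_pk_dataset(f2), "row")
})

test_that("write/read round-trips every analysed field", {
  f <- make_csv(withr::local_tempfile(fileext = ".csv"))
  ds <- read_pk_dataset(f)
  ds <- flag_outliers(ds)
  out <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(ds, out)
  ds2 <- read_pk_dataset(out)
  for (col in c("patient_id", "time", "conc", "cycle", "blq"))
    expect_identical(ds2$observations[[col]], ds$observations[[col]])
  for (col in c("patient_id", "start", "duration", "amount", "rate"))
    expect_equal(ds2$doses[[col]], ds$doses[[col]], tolerance = 1e-12)
  for (col in c("age", "weight", "scr", "alt", "clcr"))
    expect_equal(ds2$patients[[col]], ds$patients[[col]], tolerance = 1e-12)
})

test_that("Cockcroft-Gault matches hand arithmetic and its unit conversion", {
  expect_equal(cockcroft_gault(40, 72, 1.0, "male"), 100)
  expect_equal(cockcroft_gault(40, 72, 1.0, "female"), 85)
  # frozen from hand evaluation of (140-63)*82/(72*1.0)
  expect_equal(cockcroft_gault(63, 82, 88.4, "male", scr_unit = "umol/L"),
               87.69, tolerance = 1e-3)
  expect_error(cockcroft_gault(40, 72, 0, "male"), "positive")
  expect_error(cockcroft_gault(40, 72, 1, "unknown"), "sex")
})

test_that("Cockcroft-Gault is monotone in age, weight and creatinine", {
  ages <- seq(30, 80, by = 10)
  expect_true(all(diff(cockcroft_gault(ages, 70, 1, "male")) < 0))
  wts <- seq(50, 110, by = 10)
  expect_true(all(diff(cockcroft_gault(60, wts, 1, "male")) > 0))
  scrs <- seq(0.6, 2.4, by = 0.2)
  expect_true(all(diff(cockcroft_gault(60, 70, scrs, "male")) < 0))
})

test_that("IQR outlier rule reproduces the enumerated quartile example", {
  vals <- c(1:8, 100)
  ds <- toy_dataset(conc_list = list(vals),
                    times_list = list(seq(8, 168, length.out = 9)))
  ds <- flag_outliers(ds)
  thr <- outlier_thresholds(ds)
  expect_equal(thr$q1, 3)
  expect_equal(thr$q3, 7)
  expect_equal(thr$iqr, 4)
  expect_equal(thr$high_limit, 19)
  expect_equal(thr$low_limit, -9)
  expect_equal(sum(ds$observations$high_outlier), 1)
  expect_equal(ds$observations$conc[ds$observations$high_outlier], 100)
  expect_equal(ds$patients$error_group, "outlier_patient")
})

test_that("degenerate spread produces no flags (strict inequalities)", {
  ds <- toy_dataset(conc_list = list(rep(7, 6)),
                    times_list = list(seq(24, 168, length.out = 6)))
  ds <- flag_outliers(ds)
  expect_equal(outlier_thresholds(ds)$iqr, 0)
  expect_false(any(ds$observations$high_outlier))
  expect_false(any(ds$observations$low_outlier))
  expect_equal(ds$patients$error_group, "normal")
})

test_that("outlier flags are permutation-invariant and use only during-infusion rows", {
  vs <- simulate_study(small_config(), seed = 31)
  ds <- flag_outliers(vs$dataset)

  shuffled <- vs$dataset
  set.seed(99)
  shuffled$observations <- shuffled$observations[
    sample(nrow(shuffled$observations)), ]
  shuffled$patients <- shuffled$patients[sample(nrow(shuffled$patients)), ]
  ds2 <- flag_outliers(shuffled)
  expect_equal(outlier_thresholds(ds2), outlier_thresholds(ds))

  key <- function(d) {
    o <- d$observations[d$observations$high_outlier, ]
    sort(paste(o$patient_id, o$time))
  }
  expect_identical(key(ds2), key(ds))

  # dropping post-infusion rows leaves the thresholds untouched
  trimmed <- vs$dataset
  trimmed$observations <- trimmed$observations[
    trimmed$observations$during_infusion, ]
  ds3 <- flag_outliers(trimmed)
  expect_equal(outlier_thresholds(ds3), outlier_thresholds(ds))
})

test_that("quartiles need at least four eligible observations", {
  ds <- toy_dataset(conc_list = list(c(5, 6, 7)),
                    times_list = list(c(24, 72, 120)))
  expect_error(flag_outliers(ds), "fewer than 4")
})

test_that("validation rejects inconsistent inputs", {
  pats <- tibble::tibble(patient_id = "p1", age = 60, sex = "male",
                         weight = 80, scr = 88.4)
  dose <- tibble::tibble(patient_id = "p1", start = 0, duration = 168,
                         amount = 64)
  obs <- tibble::tibble(patient_id = "p1", time = 24, conc = 9)
  expect_s3_class(pk_dataset(pats, dose, obs), "pk_dataset")
  expect_error(pk_dataset(pats, dose,
                          dplyr::mutate(obs, patient_id = "ghost")),
               "unknown patient")
  expect_error(pk_dataset(dplyr::mutate(pats, age = -1), dose, obs),
               "positive")
  expect_error(pk_dataset(dplyr::mutate(pats, scr = NA_real_), dose, obs),
               "missing")
  expect_error(pk_dataset(pats, dplyr::mutate(dose, amount = -2), obs),
               "row")
})
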