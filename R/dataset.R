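#' Assemble a population-PK analysis dataset
#'
#' Bundles the three tables the analysis works on — patient covariates, dose
#' events, and concentration observations — into a validated `pk_dataset`
#' object. Concentrations below the lower limit of quantitation (LLOQ) or
#' missing are marked `blq`/`excluded` and never enter the likelihood; they
#' are retained in the table for auditability.
#'
#' @param patients Tibble with one row per patient. `patient_id` is required;
#'   recognised covariate columns are `study` (`"NSCLC"`, `"HRPC"`, `"MM"`),
#'   `sex` (`"male"`/`"female"`), `age` (years), `weight` (kg), `bsa` (m^2),
#'   `height` (m), `scr` (serum creatinine, umol/L), `alt`, `ast` (U/L),
#'   `albumin` (g/L), `a1agp` (umol/L), `ecog` (grade), `clcr` (mL/min).
#'   If `clcr` is absent but `age`, `weight`, `scr` and `sex` are present it
#'   is derived by [cockcroft_gault()].
#' @param doses Tibble with `patient_id`, `start` (h since first infusion
#'   start), `duration` (h), `amount` (mg of the cationic moiety) and
#'   optionally `rate` (mg/h, defaults to `amount/duration`) and `cycle`.
#' @param observations Tibble with `patient_id`, `time` (h), `conc` (ng/mL;
#'   `NA` allowed for missing samples) and optionally `cycle`. A
#'   `during_infusion` flag is derived from the dose events when absent.
#' @param lloq Lower limit of quantitation in ng/mL. Default 0.05.
#'
#' @return A `pk_dataset`: a list with elements `patients`, `doses`,
#'   `observations` (tibbles), `lloq`, and (after [flag_outliers()])
#'   `thresholds`.
#' @export
#' @examples
#' pats <- tibble::tibble(patient_id = "p1", study = "NSCLC", sex = "male",
#'                        age = 60, weight = 80, bsa = 1.9, scr = 88.4, alt = 20)
#' dose <- tibble::tibble(patient_id = "p1", start = 0, duration = 168,
#'                        amount = 64)
#' obs <- tibble::tibble(patient_id = "p1", time = c(24, 168, 172),
#'                       conc = c(9.1, 10.2, 5.3))
#' pk_dataset(pats, dose, obs)
pk_dataset <- function(patients, doses, observations, lloq = 0.05) {
  patients <- tibble::as_tibble(patients)
  doses <- tibble::as_tibble(doses)
  observations <- tibble::as_tibble(observations)

  stopifnot("patient_id" %in% names(patients),
            all(c("patient_id", "start", "duration", "amount") %in% names(doses)),
            all(c("patient_id", "time", "conc") %in% names(observations)))
  if (anyDuplicated(patients$patient_id))
    stop("duplicated patient_id in `patients`", call. = FALSE)

  bad_dose <- which(!(doses$amount > 0) | !(doses$duration > 0) |
                      doses$start < 0 | !is.finite(doses$start))
  if (length(bad_dose))
    stop("invalid dose event in row(s) ", paste(bad_dose, collapse = ", "),
         ": amount and duration must be positive, start non-negative",
         call. = FALSE)
  if (!"rate" %in% names(doses)) doses$rate <- doses$amount / doses$duration
  if (any(abs(doses$rate * doses$duration - doses$amount) >
            1e-6 * pmax(doses$amount, 1)))
    stop("dose rate x duration does not match amount", call. = FALSE)
  if (!"cycle" %in% names(doses)) doses$cycle <- seq_len(nrow(doses)) # per file order

  bad_t <- which(!is.finite(observations$time) | observations$time < 0)
  if (length(bad_t))
    stop("negative or non-finite observation time in row(s) ",
         paste(bad_t, collapse = ", "), call. = FALSE)
  neg_c <- which(!is.na(observations$conc) & observations$conc < 0)
  if (length(neg_c))
    stop("negative concentration in row(s) ", paste(neg_c, collapse = ", "),
         call. = FALSE)

  orphans <- setdiff(c(doses$patient_id, observations$patient_id),
                     patients$patient_id)
  if (length(orphans))
    stop("dose/observation rows reference unknown patient(s): ",
         paste(unique(orphans), collapse = ", "), call. = FALSE)

  # positivity of covariates that feed the model
  for (col in c("age", "weight", "bsa", "height", "scr", "alt", "clcr")) {
    if (col %in% names(patients)) {
      v <- patients[[col]]
      if (anyNA(v))
        stop("missing values in covariate `", col,
             "` (no imputation is performed)", call. = FALSE)
      if (any(v <= 0))
        stop("covariate `", col, "` must be strictly positive", call. = FALSE)
    }
  }
  if ("sex" %in% names(patients) &&
      !all(patients$sex %in% c("male", "female")))
    stop('`sex` must be "male" or "female"', call. = FALSE)
  if ("study" %in% names(patients) &&
      !all(patients$study %in% c("NSCLC", "HRPC", "MM")))
    stop('`study` must be one of "NSCLC", "HRPC", "MM"', call. = FALSE)

  if (!"clcr" %in% names(patients) &&
      all(c("age", "weight", "scr", "sex") %in% names(patients)))
    patients$clcr <- cockcroft_gault(patients$age, patients$weight,
                                     patients$scr, patients$sex,
                                     scr_unit = "umol/L")
  if (!"error_group" %in% names(patients)) patients$error_group <- "normal"

  if (!"cycle" %in% names(observations)) observations$cycle <- 1L
  if (!"during_infusion" %in% names(observations)) {
    observations$during_infusion <- purrr::map2_lgl(
      observations$patient_id, observations$time,
      function(id, t) {
        d <- doses[doses$patient_id == id, ]
        any(t >= d$start & t <= d$start + d$duration)
      })
  }
  observations$blq <- !is.na(observations$conc) & observations$conc < lloq
  observations$excluded <- observations$blq | is.na(observations$conc)
  if (!"high_outlier" %in% names(observations))
    observations$high_outlier <- FALSE
  if (!"low_outlier" %in% names(observations))
    observations$low_outlier <- FALSE

  structure(list(patients = patients, doses = doses,
                 observations = observations, lloq = lloq,
                 thresholds = NULL),
            class = "pk_dataset")
}

#' @export
print.pk_dataset <- function(x, ...) {
  n_an <- sum(!x$observations$excluded)
  cat("<pk_dataset> ", nrow(x$patients), " patients, ",
      nrow(x$doses), " dose events, ", nrow(x$observations),
      " observations (", n_an, " in analysis set, LLOQ ", x$lloq,
      " ng/mL)\n", sep = "")
  if (!is.null(x$thresholds)) {
    cat("  outlier limits: [", signif(x$thresholds$low_limit, 4), ", ",
        signif(x$thresholds$high_limit, 4), "] ng/mL; ",
        sum(x$patients$error_group == "outlier_patient"),
        " outlier-group patient(s)\n", sep = "")
  }
  invisible(x)
}

#' Default column map for NONMEM-dialect CSV files
#'
#' @param ... Overrides, e.g. `dv = "CONC"`.
#' @param scr_unit Unit of the serum-creatinine column: `"umol/L"` (stored
#'   as-is; converted with 88.4 umol/L per mg/dL when Cockcroft-Gault is
#'   applied) or `"mg/dL"`.
#' @return A list with elements `cols` (canonical name -> file column) and
#'   `scr_unit`.
#' @export
nonmem_schema <- function(..., scr_unit = "umol/L") {
  cols <- c(id = "ID", time = "TIME", amt = "AMT", rate = "RATE",
            evid = "EVID", dv = "DV", mdv = "MDV", cycle = "CYCLE",
            age = "AGE", sex = "SEX", weight = "WT", bsa = "BSA",
            height = "HT", scr = "SCR", alt = "ALT", ast = "AST",
            albumin = "ALB", a1agp = "A1AGP", ecog = "ECOG", study = "STUDY")
  over <- c(...)
  cols[names(over)] <- over
  list(cols = cols, scr_unit = match.arg(scr_unit, c("umol/L", "mg/dL")))
}

sex_decode <- function(x) {
  if (is.numeric(x)) return(ifelse(x == 0, "male", "female"))
  out <- tolower(as.character(x))
  out[out %in% c("m", "1")] <- "male"
  out[out %in% c("f", "2")] <- "female"
  out
}

study_decode <- function(x) {
  if (is.numeric(x)) return(c("NSCLC", "HRPC", "MM")[x])
  toupper(as.character(x))
}

#' Read a NONMEM-dialect CSV into a `pk_dataset`
#'
#' Expects one row per dose event (`EVID == 1`, with `AMT` and `RATE`) or
#' concentration observation (`EVID == 0`, with `DV` in ng/mL). Covariate
#' columns are taken from the first row of each patient. Observations that
#' are missing or below the LLOQ are marked excluded from the analysis set.
#'
#' @param path CSV file path.
#' @param schema Column map from [nonmem_schema()].
#' @param lloq Lower limit of quantitation, ng/mL.
#' @return A [pk_dataset()].
#' @export
read_pk_dataset <- function(path, schema = nonmem_schema(), lloq = 0.05) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cols <- schema$cols
  need <- c("id", "time", "evid", "dv", "amt")
  missing_cols <- need[!cols[need] %in% names(raw)]
  if (length(missing_cols))
    stop("schema error: required column(s) ",
         paste(cols[missing_cols], collapse = ", "), " not found in ", path,
         call. = FALSE)
  gc <- function(key) if (cols[[key]] %in% names(raw)) raw[[cols[[key]]]] else NULL

  evid <- gc("evid")
  is_dose <- evid == 1
  if (any(is_dose & (is.na(gc("amt")) | gc("amt") <= 0)))
    stop("schema error: dose rows must carry a positive ", cols[["amt"]],
         call. = FALSE)

  drows <- raw[is_dose, ]
  rate <- gc("rate")
  amt_d <- drows[[cols[["amt"]]]]
  rate_d <- if (!is.null(rate)) rate[is_dose] else NA_real_
  if (all(is.na(rate_d)))
    stop("schema error: dose rows need ", cols[["rate"]],
         " to derive the infusion duration", call. = FALSE)
  doses <- tibble::tibble(
    patient_id = as.character(drows[[cols[["id"]]]]),
    start = drows[[cols[["time"]]]],
    amount = amt_d,
    rate = rate_d,
    duration = amt_d / rate_d,
    cycle = if (cols[["cycle"]] %in% names(drows))
      as.integer(drows[[cols[["cycle"]]]]) else 1L)

  orows <- raw[!is_dose, ]
  observations <- tibble::tibble(
    patient_id = as.character(orows[[cols[["id"]]]]),
    time = orows[[cols[["time"]]]],
    conc = orows[[cols[["dv"]]]],
    cycle = if (cols[["cycle"]] %in% names(orows))
      as.integer(orows[[cols[["cycle"]]]]) else 1L)
  if (cols[["mdv"]] %in% names(orows))
    observations$conc[orows[[cols[["mdv"]]]] == 1] <- NA_real_

  first <- raw[!duplicated(raw[[cols[["id"]]]]), ]
  patients <- tibble::tibble(patient_id = as.character(first[[cols[["id"]]]]))
  for (key in c("age", "weight", "bsa", "height", "scr", "alt", "ast",
                "albumin", "a1agp", "ecog")) {
    # a column that is entirely empty means the covariate was not recorded
    if (cols[[key]] %in% names(first) && !all(is.na(first[[cols[[key]]]])))
      patients[[key]] <- first[[cols[[key]]]]
  }
  if (cols[["sex"]] %in% names(first) && !all(is.na(first[[cols[["sex"]]]])))
    patients$sex <- sex_decode(first[[cols[["sex"]]]])
  if (cols[["study"]] %in% names(first) &&
      !all(is.na(first[[cols[["study"]]]])))
    patients$study <- study_decode(first[[cols[["study"]]]])
  if ("scr" %in% names(patients) && schema$scr_unit == "mg/dL")
    patients$scr <- patients$scr * 88.4   # stored unit is umol/L

  pk_dataset(patients, doses, observations, lloq = lloq)
}

#' Write a `pk_dataset` back to NONMEM-dialect CSV
#'
#' Emits the dose and observation rows with the derived columns `CLCR`,
#' `BLQFLAG`, `OUTLIER` and `ERRGRP` appended, so a written file round-trips
#' through [read_pk_dataset()].
#'
#' @param dataset A [pk_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(dataset, path) {
  p <- dataset$patients
  covs <- tibble::tibble(
    ID = p$patient_id,
    AGE = p[["age"]] %||% NA_real_, SEX = p[["sex"]] %||% NA_character_,
    WT = p[["weight"]] %||% NA_real_, BSA = p[["bsa"]] %||% NA_real_,
    HT = p[["height"]] %||% NA_real_, SCR = p[["scr"]] %||% NA_real_,
    ALT = p[["alt"]] %||% NA_real_, AST = p[["ast"]] %||% NA_real_,
    ALB = p[["albumin"]] %||% NA_real_, A1AGP = p[["a1agp"]] %||% NA_real_,
    ECOG = p[["ecog"]] %||% NA_real_, STUDY = p[["study"]] %||% NA_character_,
    CLCR = p[["clcr"]] %||% NA_real_, ERRGRP = p$error_group)

  d <- dataset$doses
  drows <- tibble::tibble(ID = d$patient_id, TIME = d$start, AMT = d$amount,
                          RATE = d$rate, EVID = 1L, DV = NA_real_, MDV = 1L,
                          CYCLE = d$cycle, BLQFLAG = 0L, OUTLIER = 0L)
  o <- dataset$observations
  orows <- tibble::tibble(ID = o$patient_id, TIME = o$time, AMT = NA_real_,
                          RATE = NA_real_, EVID = 0L, DV = o$conc,
                          MDV = as.integer(is.na(o$conc)), CYCLE = o$cycle,
                          BLQFLAG = as.integer(o$blq),
                          OUTLIER = as.integer(o$high_outlier | o$low_outlier))
  out <- dplyr::bind_rows(drows, orows) |>
    dplyr::left_join(covs, by = "ID") |>
    dplyr::arrange(.data$ID, .data$TIME, dplyr::desc(.data$EVID))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Cockcroft-Gault creatinine clearance
#'
#' `CLCR = (140 - age) * weight / (72 * Scr[mg/dL])`, times 0.85 for females.
#' Serum creatinine in umol/L is converted with 88.4 umol/L per mg/dL.
#'
#' @param age Years.
#' @param weight Body weight, kg.
#' @param scr Serum creatinine, in `scr_unit`.
#' @param sex `"male"` or `"female"` (vectorised).
#' @param scr_unit `"mg/dL"` (default) or `"umol/L"`.
#' @return Creatinine clearance, mL/min.
#' @export
#' @examples
#' cockcroft_gault(40, 72, 1.0, "male")    # 100
#' cockcroft_gault(40, 72, 1.0, "female")  # 85
cockcroft_gault <- function(age, weight, scr, sex,
                            scr_unit = c("mg/dL", "umol/L")) {
  scr_unit <- match.arg(scr_unit)
  if (any(scr <= 0) || any(age <= 0) || any(weight <= 0))
    stop("age, weight and serum creatinine must be positive", call. = FALSE)
  if (!all(sex %in% c("male", "female")))
    stop('`sex` must be "male" or "female"', call. = FALSE)
  scr_mgdl <- if (scr_unit == "umol/L") scr / 88.4 else scr
  out <- (140 - age) * weight / (72 * scr_mgdl)
  out * ifelse(sex == "female", 0.85, 1)
}

#' Flag concentration outliers and assign residual-error groups
#'
#' Computes Q1 and Q3 of the during-infusion, quantifiable concentrations
#' (pooled across patients and cycles by default), flags observations
#' strictly above `Q3 + k*IQR` as high outliers and strictly below
#' `Q1 - k*IQR` as low outliers, and assigns every patient owning at least
#' one flagged observation to the `outlier_patient` residual-error group.
#' Flagged observations are retained in the analysis set; only their error
#' model changes.
#'
#' @param dataset A [pk_dataset()].
#' @param k IQR multiplier (default 3).
#' @param pooled Pool during-infusion concentrations across all patients
#'   (default) or compute per-patient limits.
#' @param group_level `"patient"` (default): all observations of a flagged
#'   patient share the larger error variance; `"observation"`: only flagged
#'   observations do.
#' @param type Quantile estimator passed to [stats::quantile()] (default 7,
#'   linear interpolation between order statistics).
#' @return The dataset with updated flags, `error_group`, and a
#'   `thresholds` tibble (`q1`, `q3`, `iqr`, `low_limit`, `high_limit`);
#'   retrieve it with [outlier_thresholds()].
#' @export
flag_outliers <- function(dataset, k = 3, pooled = TRUE,
                          group_level = c("patient", "observation"),
                          type = 7) {
  group_level <- match.arg(group_level)
  obs <- dataset$observations
  eligible <- obs$during_infusion & !obs$excluded
  if (pooled) {
    if (sum(eligible) < 4)
      stop("fewer than 4 during-infusion quantifiable concentrations: ",
           "quartiles are undefined", call. = FALSE)
    q <- quantile(obs$conc[eligible], c(0.25, 0.75), type = type,
                  names = FALSE)
    thr <- tibble::tibble(q1 = q[1], q3 = q[2], iqr = q[2] - q[1],
                          low_limit = q[1] - k * (q[2] - q[1]),
                          high_limit = q[2] + k * (q[2] - q[1]))
    lo <- thr$low_limit
    hi <- thr$high_limit
  } else {
    per <- obs[eligible, ] |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(
        n = dplyr::n(),
        q1 = quantile(.data$conc, 0.25, type = type, names = FALSE),
        q3 = quantile(.data$conc, 0.75, type = type, names = FALSE),
        .groups = "drop")
    if (any(per$n < 4))
      stop("per-patient quartiles need >= 4 eligible observations each",
           call. = FALSE)
    per$iqr <- per$q3 - per$q1
    per$low_limit <- per$q1 - k * per$iqr
    per$high_limit <- per$q3 + k * per$iqr
    thr <- per
    idx <- match(obs$patient_id, per$patient_id)
    lo <- per$low_limit[idx]
    hi <- per$high_limit[idx]
  }
  obs$high_outlier <- eligible & !is.na(obs$conc) & obs$conc > hi
  obs$low_outlier <- eligible & !is.na(obs$conc) & obs$conc < lo

  flagged <- unique(obs$patient_id[obs$high_outlier | obs$low_outlier])
  dataset$patients$error_group <-
    ifelse(dataset$patients$patient_id %in% flagged, "outlier_patient",
           "normal")
  dataset$observations <- obs
  dataset$thresholds <- thr
  attr(dataset, "group_level") <- group_level
  dataset
}

#' Retrieve the outlier thresholds computed by [flag_outliers()]
#' @param dataset A [pk_dataset()].
#' @return Tibble of thresholds, or `NULL` if flagging has not been run.
#' @export
outlier_thresholds <- function(dataset) dataset$thresholds

`%||%` <- function(a, b) if (is.null(a)) b else a
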