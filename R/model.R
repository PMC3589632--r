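#' Define a covariate term on clearance
#'
#' Continuous covariates enter as power functions of the ratio to a
#' reference value, `(X / X_ref)^theta`; binary indicators enter as ratio
#' factors, `theta^Z`. Terms sharing a `block` are added and removed
#' together during stepwise selection (the cancer-type indicators form one
#' 2-df block).
#'
#' @param covariate Patient-table column name (e.g. `"clcr"`, `"alt"`), or
#'   for indicator terms the categorical column (e.g. `"study"`).
#' @param form `"power"` (continuous) or `"ratio"` (0/1 indicator).
#' @param reference Reference value `X_ref` for power terms (required,
#'   positive).
#' @param level For ratio terms on a categorical column: the level whose
#'   indicator this term carries (e.g. `"MM"`).
#' @param value Coefficient: the exponent for power terms (null value 0) or
#'   the multiplicative factor for ratio terms (null value 1). Used as the
#'   starting value when fitting.
#' @param block Selection block label; defaults to `covariate`.
#' @return A `cov_term` list.
#' @export
#' @examples
#' cov_term("clcr", "power", reference = 79.22)
#' cov_term("study", "ratio", level = "MM")
cov_term <- function(covariate, form = c("power", "ratio"), reference = NULL,
                     level = NULL, value = NULL, block = covariate) {
  form <- match.arg(form)
  if (form == "power") {
    if (is.null(reference) || !(reference > 0))
      stop("power terms need a positive `reference`", call. = FALSE)
    value <- value %||% 0
  } else {
    if (is.null(value)) value <- 1
    if (!(value > 0)) stop("ratio coefficients must be positive", call. = FALSE)
  }
  structure(list(covariate = covariate, form = form, reference = reference,
                 level = level, value = value, block = block,
                 label = if (form == "ratio" && !is.null(level))
                   paste0(covariate, ":", level) else covariate),
            class = "cov_term")
}

#' Specify a population-PK model
#'
#' One-compartment infusion kinetics with typical clearance `cl` and volume
#' `v`, a single exponential inter-individual random effect on CL
#' (`CL_i = TVCL_i * exp(eta_i)`, `eta ~ N(0, omega2)`), proportional
#' residual error in two magnitudes chosen by the patient's error group, and
#' an optional multiplicative covariate model on CL.
#'
#' @param cl Typical clearance, L/h.
#' @param v Volume of distribution, L.
#' @param omega2 Variance of the CL random effect (log scale).
#' @param sigma2_normal,sigma2_outlier Proportional residual-error variances
#'   for the normal and outlier error groups.
#' @param covariates List of [cov_term()] objects (empty = base model).
#' @return A `pk_model` list.
#' @export
#' @examples
#' pk_model()                      # base-model defaults
#' sepantronium_final_model()      # reference covariate model
pk_model <- function(cl = 40, v = 300, omega2 = 0.1, sigma2_normal = 0.1,
                     sigma2_outlier = 0.1, covariates = list()) {
  stopifnot(cl > 0, v > 0, omega2 >= 0, sigma2_normal > 0, sigma2_outlier > 0)
  if (inherits(covariates, "cov_term")) covariates <- list(covariates)
  stopifnot(all(purrr::map_lgl(covariates, inherits, "cov_term")))
  structure(list(cl = cl, v = v, omega2 = omega2,
                 sigma2_normal = sigma2_normal,
                 sigma2_outlier = sigma2_outlier,
                 covariates = covariates),
            class = "pk_model")
}

#' @export
print.pk_model <- function(x, ...) {
  cat("<pk_model> CL", signif(x$cl, 4), "L/h, V", signif(x$v, 4),
      "L, omega2", signif(x$omega2, 4), ", sigma2 (normal/outlier)",
      signif(x$sigma2_normal, 4), "/", signif(x$sigma2_outlier, 4), "\n")
  for (tm in x$covariates)
    cat("  ", tm$label, " [", tm$form, "] coef ", signif(tm$value, 4),
        if (tm$form == "power") paste0(" ref ", tm$reference) else "",
        "\n", sep = "")
  invisible(x)
}

#' Reference final covariate model for sepantronium 7-day CIVI
#'
#' The published population estimates for the 4.8 mg/m^2/day 168-h infusion
#' regimen: CL 42.1 L/h, V 319 L, CLCR power 0.425 (reference 79.22 mL/min),
#' ALT power 0.124 (reference 19.0 U/L), HRPC ratio 0.955, MM ratio 1.24,
#' omega2 0.0385, normal-group sigma2 0.0934.
#'
#' @param sigma2_outlier Residual variance of the outlier error group
#'   (reported on an ambiguous scale in the source analysis; default 1.0,
#'   i.e. CV 100%).
#' @return A [pk_model()].
#' @export
sepantronium_final_model <- function(sigma2_outlier = 1.0) {
  pk_model(cl = 42.1, v = 319, omega2 = 0.0385, sigma2_normal = 0.0934,
           sigma2_outlier = sigma2_outlier,
           covariates = list(
             cov_term("clcr", "power", reference = 79.22, value = 0.425),
             cov_term("alt", "power", reference = 19.0, value = 0.124),
             cov_term("study", "ratio", level = "HRPC", value = 0.955,
                      block = "study"),
             cov_term("study", "ratio", level = "MM", value = 1.24,
                      block = "study")))
}

# design matrix of the log-linear covariate model:
# log TVCL_i = log cl_pop + M %*% b, b = (theta_power..., log theta_ratio...)
covariate_design <- function(patients, terms) {
  if (!length(terms))
    return(matrix(0, nrow(patients), 0))
  cols <- purrr::map(terms, function(tm) {
    if (!tm$covariate %in% names(patients))
      stop("covariate `", tm$covariate, "` not present in patient table",
           call. = FALSE)
    x <- patients[[tm$covariate]]
    if (tm$form == "power") {
      if (any(x <= 0))
        stop("covariate `", tm$covariate,
             "` must be positive for a power term", call. = FALSE)
      log(x / tm$reference)
    } else {
      as.numeric(x == tm$level)
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- purrr::map_chr(terms, "label")
  m
}

term_coefs <- function(terms)
  purrr::map_dbl(terms, function(tm)
    if (tm$form == "power") tm$value else log(tm$value))

set_term_coefs <- function(terms, b) {
  purrr::map2(terms, as.numeric(b), function(tm, bi) {
    tm$value <- if (tm$form == "power") bi else exp(bi)
    tm
  })
}

#' Typical (covariate-predicted) clearance per patient
#'
#' Evaluates the multiplicative covariate model
#' `TVCL = CL_pop * prod (X/X_ref)^theta_power * prod theta_ratio^Z`
#' for each row of a patient table.
#'
#' @param patients Patient tibble (as in a [pk_dataset()]).
#' @param model A [pk_model()].
#' @return The input tibble with a `tvcl` column (L/h) appended.
#' @export
#' @examples
#' pats <- tibble::tibble(patient_id = "p", clcr = 79.22, alt = 19,
#'                        study = "NSCLC")
#' typical_cl(pats, sepantronium_final_model())$tvcl   # 42.1
typical_cl <- function(patients, model) {
  patients <- tibble::as_tibble(patients)
  m <- covariate_design(patients, model$covariates)
  b <- term_coefs(model$covariates)
  patients$tvcl <- as.numeric(exp(log(model$cl) + m %*% b))
  patients
}

#' Convert a random-effect or proportional-error variance to CV%
#'
#' For a log-normal random effect or a proportional residual error with
#' variance `omega2`, the coefficient of variation is approximately
#' `100 * sqrt(omega2)` percent.
#'
#' @param omega2 Variance (log or proportional scale).
#' @return CV in percent.
#' @export
#' @examples
#' variance_cv(0.0385)  # 19.6
variance_cv <- function(omega2) 100 * sqrt(omega2)
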