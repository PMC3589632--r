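#' Steady-state concentration during continuous infusion
#'
#' `Css (ng/mL) = dose (mg) / (CL (L/h) x duration (h)) x 1000` — the
#' average steady-state concentration implied by the total amount infused
#' over one cycle and the individual clearance.
#'
#' @param dose Total mg infused over the cycle.
#' @param cl Clearance, L/h (typically the individual post-hoc estimate).
#' @param duration Infusion duration, h (168 for the 7-day regimen).
#' @return Css in ng/mL (vectorised).
#' @export
#' @examples
#' compute_css(66.19, 42.1, 168)  # ~9.36 ng/mL
compute_css <- function(dose, cl, duration = 168) {
  if (any(dose <= 0) || any(cl <= 0) || any(duration <= 0))
    stop("dose, cl and duration must be positive", call. = FALSE)
  dose / (cl * duration) * 1000
}

#' Per-patient steady-state exposure table
#'
#' Combines each patient's cycle-1 infusion (total amount and duration) with
#' the individual post-hoc clearance to compute Css.
#'
#' @param dataset A [pk_dataset()].
#' @param etas Post-hoc estimates from [posthoc_etas()] (or the `etas`
#'   element of a `pk_fit`).
#' @return Tibble: `patient_id`, `dose` (mg), `infusion_duration` (h), `cl`
#'   (L/h), `css` (ng/mL).
#' @export
exposure_table <- function(dataset, etas) {
  first_dose <- dataset$doses |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_min(.data$start, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", dose = "amount",
                  infusion_duration = "duration")
  dplyr::inner_join(first_dose,
                    etas[, c("patient_id", "individual_cl")],
                    by = "patient_id") |>
    dplyr::rename(cl = "individual_cl") |>
    dplyr::mutate(css = compute_css(.data$dose, .data$cl,
                                    .data$infusion_duration))
}

#' Predicted effect of renal function on clearance and exposure
#'
#' With a CLCR power term on clearance, `CL ratio = (CLCR/ref)^power` and,
#' because Css is inversely proportional to CL at constant infusion rate,
#' `Css ratio = 1 / CL ratio`. Reported as percent change versus the
#' reference.
#'
#' @param clcr Vector of creatinine-clearance values, mL/min.
#' @param power CLCR power exponent (0.425 in the reference model).
#' @param reference Reference CLCR, mL/min (default 79.22).
#' @return Tibble: `clcr`, `cl_ratio`, `cl_change_pct`, `css_ratio`,
#'   `css_change_pct`.
#' @export
#' @examples
#' renal_effect_summary(40)  # CL -25%, Css +34%
renal_effect_summary <- function(clcr, power = 0.425, reference = 79.22) {
  if (any(clcr <= 0) || reference <= 0)
    stop("clcr and reference must be positive", call. = FALSE)
  cl_ratio <- (clcr / reference)^power
  tibble::tibble(clcr = clcr, cl_ratio = cl_ratio,
                 cl_change_pct = 100 * (cl_ratio - 1),
                 css_ratio = 1 / cl_ratio,
                 css_change_pct = 100 * (1 / cl_ratio - 1))
}
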