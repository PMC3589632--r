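#' One-compartment concentration prediction under piecewise-constant infusions
#'
#' Closed-form solution of `dC/dt = R(t)/V - k*C` with `k = CL/V` for a set
#' of constant-rate infusions, superposed additively. For a single infusion
#' of rate `R` (mg/h) starting at `t0` with duration `D`:
#' `C(t) = (R/CL) * (1 - exp(-k*(t - t0)))` while the pump runs, and the
#' end-of-infusion concentration decays as `exp(-k*(t - t0 - D))` afterwards.
#' Query times exactly at the infusion stop use the during-infusion branch
#' (left-continuous convention; the two branches agree there anyway).
#' Output is converted from mg/L to ng/mL (x 1000).
#'
#' @param doses Tibble (or data frame) of dose events with columns `start`
#'   (h), `duration` (h) and either `rate` (mg/h) or `amount` (mg).
#' @param times Numeric vector of query times, h.
#' @param cl Clearance, L/h. Scalar or one value per time point.
#' @param v Volume of distribution, L.
#' @return Tibble with columns `time` and `conc` (ng/mL).
#' @export
#' @examples
#' doses <- tibble::tibble(start = 0, duration = 168, amount = 66.19)
#' predict_conc(doses, c(0, 24, 168, 180), cl = 42.1, v = 319)
predict_conc <- function(doses, times, cl, v) {
  if (any(cl <= 0) || any(v <= 0))
    stop("cl and v must be strictly positive", call. = FALSE)
  doses <- tibble::as_tibble(doses)
  if (!"rate" %in% names(doses)) doses$rate <- doses$amount / doses$duration
  tibble::tibble(time = times,
                 conc = conc_profile(times, doses$start, doses$duration,
                                     doses$rate, cl, v))
}

# vectorised over times; cl scalar or length(times)
conc_profile <- function(times, start, duration, rate, cl, v) {
  k <- cl / v
  conc <- numeric(length(times))
  for (i in seq_along(start)) {
    t1 <- times - start[i]
    t2 <- t1 - duration[i]
    during <- t1 >= 0 & t2 <= 0
    after <- t2 > 0
    add <- numeric(length(times))
    if (length(cl) > 1) {
      add[during] <- rate[i] / cl[during] * (1 - exp(-k[during] * t1[during]))
      add[after] <- rate[i] / cl[after] *
        (1 - exp(-k[after] * duration[i])) * exp(-k[after] * t2[after])
    } else {
      add[during] <- rate[i] / cl * (1 - exp(-k * t1[during]))
      add[after] <- rate[i] / cl * (1 - exp(-k * duration[i])) *
        exp(-k * t2[after])
    }
    conc <- conc + add
  }
  conc * 1000
}
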