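# Independent oracles used by the tests. These deliberately avoid the
# package's own computational paths: the ODE oracle integrates the
# one-compartment system numerically, and the quadrature oracle evaluates
# the exact marginal likelihood that FOCE approximates.

# Gauss-Hermite nodes/weights by Golub-Welsch (physicists' convention:
# integral of exp(-x^2) g(x) ~ sum w_i g(x_i))
gh_rule <- function(n) {
  if (n == 1) return(list(x = 0, w = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# exact -2 log marginal likelihood by adaptive Gauss-Hermite quadrature
# over the CL random effect, one patient at a time
marginal_ofv_gh <- function(dataset, model, n_nodes = 64) {
  rule <- gh_rule(n_nodes)
  obs <- dataset$observations[!dataset$observations$excluded, ]
  pats <- dataset$patients
  tv <- typical_cl(pats, model)$tvcl
  total <- 0
  for (i in seq_len(nrow(pats))) {
    id <- pats$patient_id[i]
    oi <- obs[obs$patient_id == id, ]
    if (!nrow(oi)) next
    di <- dataset$doses[dataset$doses$patient_id == id, ]
    s2 <- if (pats$error_group[i] == "outlier_patient")
      model$sigma2_outlier else model$sigma2_normal
    logpost <- function(eta) {
      f <- predict_conc(di, oi$time, cl = tv[i] * exp(eta), v = model$v)$conc
      sum(stats::dnorm(oi$conc, f, sqrt(s2) * f, log = TRUE)) +
        stats::dnorm(eta, 0, sqrt(model$omega2), log = TRUE)
    }
    opt <- stats::optimize(function(e) -logpost(e), c(-10, 10), tol = 1e-12)
    m <- opt$minimum
    h <- 1e-4
    H <- -(logpost(m + h) - 2 * logpost(m) + logpost(m - h)) / h^2
    if (!is.finite(H) || H <= 0) H <- 1 / model$omega2
    s <- sqrt(2 / H)
    lp <- vapply(m + s * rule$x, logpost, numeric(1))
    terms <- lp + rule$x^2 + log(rule$w)
    mx <- max(terms)
    total <- total - 2 * (log(s) + mx + log(sum(exp(terms - mx))))
  }
  total
}

# numerical ODE solution of dC/dt = R(t)/V - (CL/V) C, integrated segment
# by segment between rate changes so discontinuities are hit exactly
ode_conc <- function(doses, times, cl, v) {
  breaks <- sort(unique(c(0, doses$start, doses$start + doses$duration,
                          times)))
  rate_at <- function(t) {
    sum(doses$rate[t >= doses$start & t < doses$start + doses$duration])
  }
  conc <- numeric(0)
  state <- c(C = 0)
  for (s in seq_len(length(breaks) - 1)) {
    r <- rate_at(mean(breaks[s:(s + 1)]))
    sol <- deSolve::lsoda(
      y = state, times = c(breaks[s], breaks[s + 1]),
      func = function(t, y, p) list(r / v - (cl / v) * y),
      rtol = 1e-12, atol = 1e-14)
    state <- c(C = unname(sol[nrow(sol), 2]))
    conc <- c(conc, unname(state))
  }
  grid <- breaks[-1]
  out <- vapply(times, function(t) {
    if (t <= 0) return(0)
    conc[which.min(abs(grid - t))]
  }, numeric(1))
  out * 1000
}

# tiny single-arm dataset built in code: n patients on one 168-h infusion,
# observation times and concentrations supplied per patient
toy_dataset <- function(conc_list, times_list, rate = 0.4,
                        during = NULL, lloq = 0.05) {
  n <- length(conc_list)
  ids <- sprintf("t%02d", seq_len(n))
  pats <- tibble::tibble(patient_id = ids)
  doses <- tibble::tibble(patient_id = ids, start = 0, duration = 168,
                          amount = rate * 168, rate = rate)
  obs <- dplyr::bind_rows(purrr::map(seq_len(n), function(i)
    tibble::tibble(patient_id = ids[i], time = times_list[[i]],
                   conc = conc_list[[i]])))
  ds <- pk_dataset(pats, doses, obs, lloq = lloq)
  if (!is.null(during)) ds$observations$during_infusion <- during
  ds
}

# random small test instances for the oracle-equivalence checks
random_toy_instance <- function(seed) {
  set.seed(seed)
  n_pat <- sample(1:3, 1)
  cl <- runif(1, 20, 60)
  v <- runif(1, 150, 500)
  omega2 <- runif(1, 0.02, 0.2)
  sigma2 <- runif(1, 0.01, 0.1)
  rate <- runif(1, 0.2, 0.6)
  times_list <- purrr::map(seq_len(n_pat),
                           ~ sort(runif(sample(2:6, 1), 4, 190)))
  model <- pk_model(cl = cl, v = v, omega2 = omega2, sigma2_normal = sigma2,
                    sigma2_outlier = sigma2)
  conc_list <- purrr::map(seq_len(n_pat), function(i) {
    eta <- rnorm(1, 0, sqrt(omega2))
    f <- conc_at(times_list[[i]], rate, cl * exp(eta), v)
    pmax(f * (1 + rnorm(length(f), 0, sqrt(sigma2))), 0.06)
  })
  list(dataset = toy_dataset(conc_list, times_list, rate = rate),
       model = model)
}

# closed-form single-infusion concentration, written independently of the
# package's vectorised implementation
conc_at <- function(t, rate, cl, v) {
  k <- cl / v
  ifelse(t < 0, 0,
         ifelse(t <= 168, rate / cl * (1 - exp(-k * t)),
                rate / cl * (1 - exp(-k * 168)) * exp(-k * (t - 168)))) * 1000
}

small_config <- function(n = c(NSCLC = 8, HRPC = 8, MM = 8), ...)
  sim_config(n_per_study = n, ...)
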