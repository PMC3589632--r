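# Engine: flat index structures handed to the compiled FOCE kernel.
# Built once per fit; only parameter values change between evaluations.
build_engine <- function(dataset) {
  obs <- dataset$observations[!dataset$observations$excluded, ]
  pat_ids <- unique(obs$patient_id)
  patients <- dataset$patients[match(pat_ids, dataset$patients$patient_id), ]
  obs <- obs[order(match(obs$patient_id, pat_ids)), ]
  obs_pat <- match(obs$patient_id, pat_ids) - 1L

  obs_level <- identical(attr(dataset, "group_level"), "observation")
  if (obs_level) {
    obs_grp <- as.integer(obs$high_outlier | obs$low_outlier)
  } else {
    obs_grp <- as.integer(
      patients$error_group[obs_pat + 1L] == "outlier_patient")
  }

  d <- dataset$doses
  idx <- purrr::map(seq_len(nrow(obs)), function(j)
    which(d$patient_id == obs$patient_id[j]))
  pair_obs <- rep.int(seq_len(nrow(obs)) - 1L, lengths(idx))
  di <- unlist(idx)
  oj <- pair_obs + 1L
  list(obs = obs, patients = patients,
       y = obs$conc, obs_pat = obs_pat, obs_grp = obs_grp,
       pair_obs = pair_obs,
       pair_t1 = obs$time[oj] - d$start[di],
       pair_t2 = obs$time[oj] - d$start[di] - d$duration[di],
       pair_dur = d$duration[di], pair_rate = d$rate[di],
       has_outlier_group = any(obs_grp == 1L))
}

engine_ofv <- function(eng, log_tvcl, v, omega2, sig2n, sig2o) {
  cpp_foce(eng$y, eng$obs_pat, eng$obs_grp, eng$pair_obs, eng$pair_t1,
           eng$pair_t2, eng$pair_dur, eng$pair_rate, log_tvcl, v, omega2,
           sig2n, sig2o)
}

model_log_tvcl <- function(eng, model, b = term_coefs(model$covariates)) {
  m <- covariate_design(eng$patients, model$covariates)
  as.numeric(log(model$cl) + m %*% b)
}

#' FOCE-I objective function value for a model on a dataset
#'
#' Returns minus twice the approximate log marginal likelihood: a per-patient
#' Laplace approximation at the conditional mode of the CL random effect,
#' with interaction (the proportional residual variance is evaluated at the
#' conditional prediction), each observation's variance chosen by its
#' patient's error group. Additive constants follow the extended
#' least-squares convention and are held fixed, so OFV differences between
#' nested models are likelihood-ratio statistics. With `omega2 = 0` the
#' value is the exact pooled Gaussian -2 log-likelihood at `eta = 0`.
#' Non-finite predictions yield `Inf` rather than an error, so optimizers
#' can back off.
#'
#' @param dataset A preprocessed [pk_dataset()] (BLQ excluded, error groups
#'   assigned).
#' @param model A [pk_model()].
#' @return The OFV (scalar). Attributes `etas` (conditional modes, one per
#'   patient with data) and `ofv_i` (per-patient contributions).
#' @export
foce_ofv <- function(dataset, model) {
  eng <- build_engine(dataset)
  res <- engine_ofv(eng, model_log_tvcl(eng, model), model$v, model$omega2,
                    model$sigma2_normal, model$sigma2_outlier)
  structure(res$ofv,
            etas = setNames(as.numeric(res$etas), eng$patients$patient_id),
            ofv_i = as.numeric(res$ofv_i))
}

# transformed parameter vector: positivity via log; power coefs unbounded,
# ratio coefs estimated as log(theta_ratio)
pack_params <- function(model, est_sig2o) {
  labs <- purrr::map_chr(model$covariates, "label")
  par <- c(log(model$cl), log(model$v), term_coefs(model$covariates),
           log(max(model$omega2, 1e-8)), log(model$sigma2_normal),
           if (est_sig2o) log(model$sigma2_outlier))
  names(par) <- c("cl", "v", labs, "omega2", "sigma2_normal",
                  if (est_sig2o) "sigma2_outlier")
  par
}

unpack_params <- function(par, model, est_sig2o) {
  nt <- length(model$covariates)
  b <- par[2 + seq_len(nt)]
  model$cl <- exp(par[[1]])
  model$v <- exp(par[[2]])
  model$covariates <- set_term_coefs(model$covariates, b)
  model$omega2 <- exp(par[[nt + 3]])
  model$sigma2_normal <- exp(par[[nt + 4]])
  if (est_sig2o) model$sigma2_outlier <- exp(par[[nt + 5]])
  model
}

#' Fit a population-PK model by FOCE-I
#'
#' Minimizes [foce_ofv()] over the transformed parameter vector (log scale
#' for CL, V, omega2 and the sigma2s; log for ratio coefficients; raw for
#' power exponents) with a quasi-Newton optimizer. Standard errors come from
#' the inverse numerical Hessian at the optimum and are reported as CV% of
#' each estimate. The outlier-group sigma2 is only estimated when the
#' dataset actually contains outlier-group observations.
#'
#' @param dataset A preprocessed [pk_dataset()].
#' @param model A [pk_model()] whose values are used as starting values.
#' @param seed Unused placeholder for interface uniformity (the fit is
#'   deterministic); kept so pipeline stages share a signature.
#' @param compute_se Compute the Hessian-based CV% (default TRUE; skipped
#'   during bootstrap replicates for speed).
#' @param control Passed to [stats::nlminb()] (defaults: `iter.max = 500`,
#'   `eval.max = 2000`, `rel.tol = 1e-9`).
#' @return A `pk_fit` object: estimated `model`, `ofv`, `parameters` tibble
#'   (term, estimate, cv_pct, transform), `etas` tibble, `gof` tibble,
#'   `converged`, `n_function_evals`, `n_obs`, `n_patients`. Methods:
#'   [tidy.pk_fit()], [glance.pk_fit()], [autoplot.pk_fit()].
#' @export
fit_pk_model <- function(dataset, model = pk_model(), seed = NULL,
                         compute_se = TRUE, control = list()) {
  eng <- build_engine(dataset)
  est_sig2o <- eng$has_outlier_group
  m <- covariate_design(eng$patients, model$covariates)
  nt <- length(model$covariates)
  log_cl0 <- log(model$cl)
  s2o_fixed <- model$sigma2_outlier

  npat_eng <- nrow(eng$patients)
  fn <- function(par) {
    ltv <- if (nt) as.numeric(par[[1]] + m %*% par[2 + seq_len(nt)]) else
      rep(par[[1]], npat_eng)
    res <- engine_ofv(eng, ltv, exp(par[[2]]), exp(par[[nt + 3]]),
                      exp(par[[nt + 4]]),
                      if (est_sig2o) exp(par[[nt + 5]]) else s2o_fixed)
    if (!is.finite(res$ofv)) 1e10 else res$ofv
  }

  start <- pack_params(model, est_sig2o)
  ctl <- modifyList(list(iter.max = 500, eval.max = 2000, rel.tol = 1e-9),
                    control)
  opt <- nlminb(start, fn, control = ctl, lower = -30, upper = 30)
  converged <- opt$convergence == 0 && opt$objective < 1e10
  if (!converged && opt$objective < 1e10) {
    # nlminb's gradient test is conservative; confirm by restarting at the
    # candidate optimum and requiring no further improvement
    opt2 <- nlminb(opt$par, fn, control = ctl, lower = -30, upper = 30)
    improved <- opt$objective - opt2$objective
    if (opt2$objective <= opt$objective) opt <- opt2
    converged <- opt$objective < 1e10 &&
      (opt$convergence == 0 || improved < 1e-3)
  }
  par <- setNames(opt$par, names(start))
  fitted_model <- unpack_params(par, model, est_sig2o)
  converged <- converged && is.finite(opt$objective)

  cv_pct <- rep(NA_real_, length(par))
  if (compute_se && converged) {
    hess <- try(optimHess(par, fn), silent = TRUE)
    if (!inherits(hess, "try-error")) {
      cov <- try(2 * solve(hess), silent = TRUE)   # OFV = -2 logL
      if (!inherits(cov, "try-error") && all(diag(cov) > 0)) {
        se_t <- sqrt(diag(cov))
        # log-scale parameters: SE(log x) ~= CV; raw power exponents: SE/|est|
        est <- parameter_estimates(fitted_model, names(par))
        is_log <- !names(par) %in% power_labels(fitted_model)
        cv_pct <- ifelse(is_log, 100 * se_t, 100 * se_t / abs(est))
      }
    }
  }

  res <- engine_ofv(eng, model_log_tvcl(eng, fitted_model), fitted_model$v,
                    fitted_model$omega2, fitted_model$sigma2_normal,
                    fitted_model$sigma2_outlier)
  etas <- tibble::tibble(
    patient_id = eng$patients$patient_id,
    eta_cl = as.numeric(res$etas),
    tvcl = exp(model_log_tvcl(eng, fitted_model)),
    individual_cl = tvcl * exp(eta_cl))
  no_data <- setdiff(dataset$patients$patient_id, etas$patient_id)
  if (length(no_data))
    etas <- dplyr::bind_rows(
      etas, tibble::tibble(patient_id = no_data, eta_cl = 0,
                           tvcl = NA_real_, individual_cl = NA_real_))

  parameters <- tibble::tibble(
    term = names(par),
    estimate = parameter_estimates(fitted_model, names(par)),
    cv_pct = cv_pct,
    transform = ifelse(names(par) %in% power_labels(fitted_model),
                       "identity", "log"))

  fit <- structure(list(model = fitted_model, ofv = opt$objective,
                        parameters = parameters, etas = etas,
                        converged = converged,
                        n_function_evals = sum(unlist(opt$evaluations)),
                        n_obs = length(eng$y),
                        n_patients = nrow(eng$patients)),
                   class = "pk_fit")
  fit$gof <- gof_table(fit, dataset)
  fit
}

power_labels <- function(model)
  purrr::map_chr(purrr::keep(model$covariates, ~ .x$form == "power"), "label")

parameter_estimates <- function(model, terms) {
  labs <- purrr::map_chr(model$covariates, "label")
  vals <- c(cl = model$cl, v = model$v,
            setNames(purrr::map_dbl(model$covariates, "value"), labs),
            omega2 = model$omega2, sigma2_normal = model$sigma2_normal,
            sigma2_outlier = model$sigma2_outlier)
  as.numeric(vals[terms])
}

#' Empirical-Bayes (post-hoc) random-effect estimates
#'
#' With all population parameters fixed, each patient's eta is the mode of
#' the conditional joint density of that patient's data and eta; the
#' individual clearance is `TVCL_i * exp(eta_i)`. Patients without included
#' observations get `eta = 0` and are flagged.
#'
#' @param dataset A preprocessed [pk_dataset()].
#' @param model A fitted [pk_model()] (parameters fixed).
#' @return Tibble: `patient_id`, `eta_cl`, `tvcl`, `individual_cl`, `n_obs`,
#'   `no_data`.
#' @export
posthoc_etas <- function(dataset, model) {
  eng <- build_engine(dataset)
  res <- engine_ofv(eng, model_log_tvcl(eng, model), model$v, model$omega2,
                    model$sigma2_normal, model$sigma2_outlier)
  out <- tibble::tibble(
    patient_id = eng$patients$patient_id,
    eta_cl = as.numeric(res$etas),
    tvcl = exp(model_log_tvcl(eng, model)),
    individual_cl = tvcl * exp(eta_cl),
    n_obs = as.integer(table(factor(eng$obs$patient_id,
                                    levels = eng$patients$patient_id))),
    no_data = FALSE)
  missing <- setdiff(dataset$patients$patient_id, out$patient_id)
  if (length(missing))
    out <- dplyr::bind_rows(
      out, tibble::tibble(patient_id = missing, eta_cl = 0, tvcl = NA_real_,
                          individual_cl = NA_real_, n_obs = 0L,
                          no_data = TRUE))
  out
}

#' Goodness-of-fit table: PRED, IPRED and population WRES
#'
#' PRED is the population prediction at `eta = 0`, IPRED the prediction at
#' each patient's conditional eta. WRES are classic population weighted
#' residuals from the first-order linearization at `eta = 0`: per patient,
#' `Cov = diag(sigma2 * PRED^2) + omega2 * G G'` with `G = dF/deta`, and
#' `WRES = Cov^(-1/2) (DV - PRED)`.
#'
#' @param fit A `pk_fit`.
#' @param dataset The dataset the model was fit to.
#' @return Tibble: `patient_id`, `time`, `dv`, `pred`, `ipred`, `wres`.
#' @export
gof_table <- function(fit, dataset) {
  model <- fit$model
  eng <- build_engine(dataset)
  ltv <- model_log_tvcl(eng, model)
  etas <- fit$etas$eta_cl[match(eng$patients$patient_id,
                                fit$etas$patient_id)]
  obs <- eng$obs
  d <- dataset$doses
  h <- 1e-4
  rows <- purrr::map(seq_len(nrow(eng$patients)), function(i) {
    id <- eng$patients$patient_id[i]
    oi <- obs[obs$patient_id == id, ]
    di <- d[d$patient_id == id, ]
    fpred <- function(eta) conc_profile(oi$time, di$start, di$duration,
                                        di$rate, exp(ltv[i] + eta), model$v)
    pred <- fpred(0)
    ipred <- fpred(etas[i])
    g <- (fpred(h) - fpred(-h)) / (2 * h)
    grp_i <- eng$obs_grp[eng$obs_pat == i - 1L]
    s2 <- ifelse(grp_i == 1L, model$sigma2_outlier, model$sigma2_normal)
    cov <- diag(s2 * pred^2, nrow = length(pred)) +
      model$omega2 * tcrossprod(g)
    e <- eigen(cov, symmetric = TRUE)
    inv_sqrt <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)),
                                   nrow = length(pred)) %*% t(e$vectors)
    tibble::tibble(patient_id = id, time = oi$time, dv = oi$conc,
                   pred = pred, ipred = ipred,
                   wres = as.numeric(inv_sqrt %*% (oi$conc - pred)))
  })
  dplyr::bind_rows(rows)
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("<pk_fit> OFV ", format(x$ofv, digits = 8), ", ",
      x$n_patients, " patients / ", x$n_obs, " observations, ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  print(x$parameters)
  invisible(x)
}

#' Tidy a fitted population-PK model
#' @param x A `pk_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `cv_pct`, `transform`.
#' @method tidy pk_fit
#' @export
tidy.pk_fit <- function(x, ...) x$parameters

#' One-row summary of a fitted population-PK model
#' @param x A `pk_fit`.
#' @param ... Unused.
#' @return Tibble with `ofv`, `n_obs`, `n_patients`, `converged`,
#'   `n_function_evals`.
#' @method glance pk_fit
#' @export
glance.pk_fit <- function(x, ...)
  tibble::tibble(ofv = x$ofv, n_obs = x$n_obs, n_patients = x$n_patients,
                 converged = x$converged,
                 n_function_evals = x$n_function_evals)

#' Diagnostic plots for a fitted population-PK model
#'
#' Four standard goodness-of-fit panels: DV vs PRED, DV vs IPRED, WRES vs
#' PRED and WRES vs time.
#'
#' @param object A `pk_fit`.
#' @param ... Unused.
#' @return A ggplot object (facetted panels).
#' @method autoplot pk_fit
#' @export
autoplot.pk_fit <- function(object, ...) {
  g <- object$gof
  long <- dplyr::bind_rows(
    tibble::tibble(panel = "DV vs PRED", x = g$pred, y = g$dv),
    tibble::tibble(panel = "DV vs IPRED", x = g$ipred, y = g$dv),
    tibble::tibble(panel = "WRES vs PRED", x = g$pred, y = g$wres),
    tibble::tibble(panel = "WRES vs TIME", x = g$time, y = g$wres))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL)
}
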