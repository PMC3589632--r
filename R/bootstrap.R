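#' Nonparametric bootstrap of a fitted population-PK model
#'
#' Resamples whole patients with replacement to the original count (by
#' default within study strata, so the cancer-type indicator columns stay
#' non-degenerate in every replicate), refits the model on each replicate
#' with the point estimates as starting values, and summarises the converged
#' replicates by percentile 95% confidence intervals (2.5th and 97.5th
#' percentiles, linear interpolation between order statistics).
#'
#' All replicate index sets are drawn up front from `seed`, so the same seed
#' gives bit-identical resampling regardless of how individual fits behave.
#' Non-converged replicates are counted and excluded from the percentiles.
#'
#' @param dataset A preprocessed [pk_dataset()].
#' @param model A fitted [pk_model()] (point estimates = starting values).
#' @param n_replicates Number of bootstrap data sets (default 300).
#' @param seed Integer seed (required).
#' @param stratify Resample within `study` strata (default TRUE).
#' @param control Optimizer control, see [fit_pk_model()].
#' @return A `pk_bootstrap`: `replicates` (tibble of per-replicate
#'   estimates with a `converged` flag), `summary` (term, original
#'   estimate, bootstrap mean, `ci_low`, `ci_high`), `n_requested`,
#'   `n_converged`, `seed`. Methods: `tidy()`, `glance()`, `autoplot()`.
#' @export
bootstrap_pk <- function(dataset, model, n_replicates = 300, seed,
                         stratify = TRUE, control = list()) {
  stopifnot(n_replicates >= 1)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  pats <- dataset$patients
  set.seed(seed)
  strata <- if (stratify && "study" %in% names(pats))
    split(pats$patient_id, pats$study) else list(all = pats$patient_id)
  index_sets <- purrr::map(seq_len(n_replicates), function(r)
    unlist(purrr::map(strata, ~ sample(.x, length(.x), replace = TRUE)),
           use.names = FALSE))

  reps <- purrr::imap(index_sets, function(ids, r) {
    ds <- resample_dataset(dataset, ids)
    f <- try(fit_pk_model(ds, model, compute_se = FALSE, control = control),
             silent = TRUE)
    if (inherits(f, "try-error"))
      return(tibble::tibble(replicate = r, term = "cl", estimate = NA_real_,
                            converged = FALSE))
    dplyr::mutate(f$parameters[, c("term", "estimate")],
                  replicate = r, converged = f$converged,
                  .before = 1)
  })
  replicates <- dplyr::bind_rows(reps)

  conv <- replicates[replicates$converged, ]
  n_converged <- length(unique(conv$replicate))
  if (n_converged == 0)
    stop("all ", n_replicates, " bootstrap replicates failed to converge",
         call. = FALSE)
  summary <- conv |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      boot_mean = mean(.data$estimate),
      ci_low = quantile(.data$estimate, 0.025, type = 7, names = FALSE),
      ci_high = quantile(.data$estimate, 0.975, type = 7, names = FALSE),
      .groups = "drop")
  orig <- tibble::tibble(
    term = c("cl", "v", purrr::map_chr(model$covariates, "label"),
             "omega2", "sigma2_normal", "sigma2_outlier"),
    estimate = parameter_estimates(model, c(
      "cl", "v", purrr::map_chr(model$covariates, "label"), "omega2",
      "sigma2_normal", "sigma2_outlier")))
  summary <- dplyr::left_join(orig, summary, by = "term") |>
    dplyr::filter(!is.na(.data$boot_mean))

  structure(list(replicates = replicates, summary = summary,
                 n_requested = n_replicates, n_converged = n_converged,
                 seed = seed, index_sets = index_sets),
            class = "pk_bootstrap")
}

# rebuild a pk_dataset from sampled patient ids (duplicates get fresh ids)
resample_dataset <- function(dataset, ids) {
  new_id <- paste0(ids, "#", seq_along(ids))
  pats <- dataset$patients[match(ids, dataset$patients$patient_id), ]
  pats$patient_id <- new_id
  pick <- function(tbl) {
    idx <- purrr::map(ids, ~ which(tbl$patient_id == .x))
    out <- tbl[unlist(idx), ]
    out$patient_id <- rep(new_id, lengths(idx))
    out
  }
  ds <- dataset
  ds$patients <- pats
  ds$doses <- pick(dataset$doses)
  ds$observations <- pick(dataset$observations)
  ds
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat("<pk_bootstrap> ", x$n_converged, "/", x$n_requested,
      " replicates converged (seed ", x$seed, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Tidy bootstrap summary
#' @param x A `pk_bootstrap`.
#' @param ... Unused.
#' @return The summary tibble (`term`, `estimate`, `boot_mean`, `ci_low`,
#'   `ci_high`).
#' @method tidy pk_bootstrap
#' @export
tidy.pk_bootstrap <- function(x, ...) x$summary

#' One-row bootstrap overview
#' @param x A `pk_bootstrap`.
#' @param ... Unused.
#' @return Tibble with `n_requested`, `n_converged`, `seed`.
#' @method glance pk_bootstrap
#' @export
glance.pk_bootstrap <- function(x, ...)
  tibble::tibble(n_requested = x$n_requested, n_converged = x$n_converged,
                 seed = x$seed)

#' Bootstrap distribution plot
#' @param object A `pk_bootstrap`.
#' @param ... Unused.
#' @return A ggplot: per-parameter histogram of converged replicate
#'   estimates with the percentile CI marked.
#' @method autoplot pk_bootstrap
#' @export
autoplot.pk_bootstrap <- function(object, ...) {
  conv <- object$replicates[object$replicates$converged, ]
  ggplot2::ggplot(conv, ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(data = object$summary,
                        ggplot2::aes(xintercept = .data$ci_low),
                        linetype = 2) +
    ggplot2::geom_vline(data = object$summary,
                        ggplot2::aes(xintercept = .data$ci_high),
                        linetype = 2) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "bootstrap estimate", y = "replicates")
}
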