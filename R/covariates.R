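#' Screen covariates against post-hoc eta estimates
#'
#' For each continuous covariate, a simple linear regression of the
#' post-hoc `eta_CL` on the covariate; for categorical covariates a
#' two-sample t-test (two levels) or one-way ANOVA (more levels).
#' Covariates with `p < alpha` pass the screen. Constant covariates are
#' skipped with a warning.
#'
#' @param fit A base-model `pk_fit` (supplies the etas).
#' @param dataset The [pk_dataset()] the fit used.
#' @param covariates Character vector of patient-table columns to screen.
#' @param alpha Screening significance level (default 0.1).
#' @return Tibble: `covariate`, `type`, `p_value`, `passed`.
#' @export
screen_covariates <- function(fit, dataset,
                              covariates = c("age", "weight", "bsa", "scr",
                                             "clcr", "alt", "ast", "albumin",
                                             "a1agp", "study", "sex", "ecog"),
                              alpha = 0.1) {
  pats <- dataset$patients
  covariates <- intersect(covariates, names(pats))
  etas <- fit$etas[!is.na(fit$etas$individual_cl), ]
  df <- dplyr::inner_join(etas, pats, by = "patient_id")
  rows <- purrr::map(covariates, function(cv) {
    x <- df[[cv]]
    categorical <- is.character(x) || is.factor(x) ||
      (is.numeric(x) && length(unique(x)) <= 3)
    if (length(unique(x)) < 2) {
      warning("covariate `", cv, "` is constant; skipped", call. = FALSE)
      return(tibble::tibble(covariate = cv, type = "constant",
                            p_value = NA_real_, passed = FALSE))
    }
    if (categorical) {
      x <- factor(x)
      p <- if (nlevels(x) == 2) {
        t.test(df$eta_cl ~ x)$p.value
      } else {
        summary(aov(df$eta_cl ~ x))[[1]][["Pr(>F)"]][1]
      }
      tibble::tibble(covariate = cv, type = "categorical", p_value = p,
                     passed = p < alpha)
    } else {
      sm <- summary(lm(df$eta_cl ~ x))
      p <- sm$coefficients[2, 4]
      tibble::tibble(covariate = cv, type = "continuous", p_value = p,
                     passed = p < alpha)
    }
  })
  dplyr::bind_rows(rows)
}

#' Build candidate covariate terms from a screening result
#'
#' Continuous covariates become power terms; `clcr` and `alt` use the fixed
#' reference values 79.22 mL/min and 19.0 U/L, other continuous covariates
#' the dataset median. Categorical covariates become one ratio term per
#' non-reference level, grouped into a single selection block (`study`
#' yields the 2-df HRPC + MM block against the NSCLC reference).
#'
#' @param screened Output of [screen_covariates()] (only `passed` rows are
#'   used), or a character vector of covariate names.
#' @param dataset The [pk_dataset()] (for medians and level sets).
#' @return List of [cov_term()] objects.
#' @export
candidate_terms <- function(screened, dataset) {
  fixed_refs <- c(clcr = 79.22, alt = 19.0)
  if (is.data.frame(screened))
    screened <- screened$covariate[screened$passed]
  pats <- dataset$patients
  purrr::flatten(purrr::map(screened, function(cv) {
    x <- pats[[cv]]
    if (is.character(x) || is.factor(x) ||
        (is.numeric(x) && length(unique(x)) <= 3)) {
      lev <- sort(unique(as.character(x)))
      if (cv == "study") lev <- intersect(c("NSCLC", "HRPC", "MM"), lev)
      ref <- lev[1]
      purrr::map(setdiff(lev, ref),
                 ~ cov_term(cv, "ratio", level = .x, block = cv))
    } else {
      ref <- if (cv %in% names(fixed_refs)) fixed_refs[[cv]] else
        median(x)
      list(cov_term(cv, "power", reference = ref, block = cv))
    }
  }))
}

fit_with_terms <- function(dataset, model, terms, control = list()) {
  model$covariates <- terms
  fit_pk_model(dataset, model, compute_se = FALSE, control = control)
}

block_split <- function(terms) split(terms, purrr::map_chr(terms, "block"))

#' Forward addition of covariate terms by likelihood-ratio test
#'
#' Starting from the base model, repeatedly fits the current model plus each
#' remaining candidate block, and adds the block with the largest
#' significant OFV drop (chi-squared test with df = number of terms in the
#' block; ties broken by candidate order) until no candidate is significant
#' at `alpha`. Added blocks start from their null coefficients and all other
#' parameters from the current estimates, so the objective can only
#' improve. Candidate fits that fail to converge are skipped that round.
#'
#' @param dataset A preprocessed [pk_dataset()].
#' @param base A [pk_model()] for the starting point (usually the base
#'   model).
#' @param candidates List of [cov_term()] candidates, e.g. from
#'   [candidate_terms()].
#' @param alpha Inclusion significance level (default 0.05).
#' @param control Optimizer control, see [fit_pk_model()].
#' @return List: `model` (selected), `fit` (its `pk_fit`), `trace` tibble
#'   (`step`, `block`, `delta_ofv`, `df`, `p_value`, `decision`).
#' @export
forward_addition <- function(dataset, base, candidates, alpha = 0.05,
                             control = list()) {
  cur_fit <- fit_with_terms(dataset, base, base$covariates, control)
  remaining <- block_split(candidates)
  trace <- list()
  step <- 0L
  while (length(remaining)) {
    step <- step + 1L
    trials <- purrr::imap(remaining, function(terms, blk) {
      f <- try(fit_with_terms(dataset, cur_fit$model,
                              c(cur_fit$model$covariates, terms), control),
               silent = TRUE)
      if (inherits(f, "try-error") || !f$converged)
        return(list(fit = NULL, d = NA_real_, df = length(terms),
                    p = NA_real_))
      d <- cur_fit$ofv - f$ofv
      list(fit = f, d = d, df = length(terms),
           p = pchisq(max(d, 0), df = length(terms), lower.tail = FALSE))
    })
    for (blk in names(trials))
      trace[[length(trace) + 1L]] <- tibble::tibble(
        step = step, block = blk, delta_ofv = trials[[blk]]$d,
        df = trials[[blk]]$df, p_value = trials[[blk]]$p,
        decision = "evaluated")
    sig <- purrr::keep(trials, ~ !is.na(.x$p) && .x$p < alpha)
    if (!length(sig)) break
    best <- names(sig)[which.max(purrr::map_dbl(sig, "d"))]
    trace[[length(trace) + 1L]] <- tibble::tibble(
      step = step, block = best, delta_ofv = trials[[best]]$d,
      df = trials[[best]]$df, p_value = trials[[best]]$p,
      decision = "added")
    cur_fit <- trials[[best]]$fit
    remaining[[best]] <- NULL
  }
  list(model = cur_fit$model, fit = cur_fit,
       trace = if (length(trace)) dplyr::bind_rows(trace) else
         tibble::tibble(step = integer(), block = character(),
                        delta_ofv = double(), df = integer(),
                        p_value = double(), decision = character()))
}

#' Backward elimination of covariate terms by likelihood-ratio test
#'
#' Repeatedly refits the model with each block removed in turn; whenever the
#' smallest OFV rise is not significant at `alpha` (chi-squared, df = block
#' size), that block is dropped. Stops when every remaining block is
#' significant.
#'
#' @param dataset A preprocessed [pk_dataset()].
#' @param full The full [pk_model()] (with coefficients at their estimates).
#' @param alpha Retention significance level (default 0.01).
#' @param control Optimizer control, see [fit_pk_model()].
#' @return Same shape as [forward_addition()]; `decision` is
#'   `"removed"`/`"kept"`/`"evaluated"`.
#' @export
backward_elimination <- function(dataset, full, alpha = 0.01,
                                 control = list()) {
  cur_fit <- fit_with_terms(dataset, full, full$covariates, control)
  trace <- list()
  step <- 0L
  repeat {
    blocks <- block_split(cur_fit$model$covariates)
    if (!length(blocks)) break
    step <- step + 1L
    trials <- purrr::imap(blocks, function(terms, blk) {
      keep <- purrr::discard(cur_fit$model$covariates,
                             ~ .x$block == blk)
      f <- try(fit_with_terms(dataset, cur_fit$model, keep, control),
               silent = TRUE)
      if (inherits(f, "try-error") || !f$converged)
        return(list(fit = NULL, rise = NA_real_, df = length(terms),
                    p = NA_real_))
      rise <- f$ofv - cur_fit$ofv
      list(fit = f, rise = rise, df = length(terms),
           p = pchisq(max(rise, 0), df = length(terms), lower.tail = FALSE))
    })
    for (blk in names(trials))
      trace[[length(trace) + 1L]] <- tibble::tibble(
        step = step, block = blk, delta_ofv = trials[[blk]]$rise,
        df = trials[[blk]]$df, p_value = trials[[blk]]$p,
        decision = "evaluated")
    droppable <- purrr::keep(trials, ~ !is.na(.x$p) && .x$p >= alpha)
    if (!length(droppable)) {
      for (blk in names(trials))
        trace[[length(trace) + 1L]] <- tibble::tibble(
          step = step, block = blk, delta_ofv = trials[[blk]]$rise,
          df = trials[[blk]]$df, p_value = trials[[blk]]$p,
          decision = "kept")
      break
    }
    worst <- names(droppable)[which.min(purrr::map_dbl(droppable, "rise"))]
    trace[[length(trace) + 1L]] <- tibble::tibble(
      step = step, block = worst, delta_ofv = trials[[worst]]$rise,
      df = trials[[worst]]$df, p_value = trials[[worst]]$p,
      decision = "removed")
    cur_fit <- trials[[worst]]$fit
  }
  list(model = cur_fit$model, fit = cur_fit,
       trace = if (length(trace)) dplyr::bind_rows(trace) else
         tibble::tibble(step = integer(), block = character(),
                        delta_ofv = double(), df = integer(),
                        p_value = double(), decision = character()))
}
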