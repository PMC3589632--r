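#' Configuration for the end-to-end analysis pipeline
#'
#' @param data Either a [sim_config()] (a virtual study is generated) or a
#'   path to a NONMEM-dialect CSV readable by [read_pk_dataset()].
#' @param base_model Starting [pk_model()] for the base fit.
#' @param covariates Covariates offered to the screening step.
#' @param alpha_screen,alpha_forward,alpha_backward Significance levels of
#'   the three selection stages (defaults 0.1 / 0.05 / 0.01).
#' @param bootstrap_n Bootstrap replicates (0 skips the bootstrap stage).
#' @param stratify_bootstrap Stratify resampling by study.
#' @param seed Integer master seed; per-stage seeds are derived as
#'   `seed * 100 + stage offset` (1 = simulate, 2 = fit, 3 = bootstrap), so
#'   any stage can be reproduced in isolation.
#' @param out_dir Output directory for the report bundle (`NULL` = no files
#'   written).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(data = sim_config(),
                            base_model = pk_model(),
                            covariates = c("age", "weight", "bsa", "scr",
                                           "clcr", "alt", "ast", "albumin",
                                           "a1agp", "study", "sex", "ecog"),
                            alpha_screen = 0.1, alpha_forward = 0.05,
                            alpha_backward = 0.01, bootstrap_n = 300,
                            stratify_bootstrap = TRUE, seed = 1,
                            out_dir = NULL) {
  stopifnot(alpha_screen > 0, alpha_screen < 1, alpha_forward > 0,
            alpha_forward < 1, alpha_backward > 0, alpha_backward < 1,
            bootstrap_n >= 0)
  structure(list(data = data, base_model = base_model,
                 covariates = covariates, alpha_screen = alpha_screen,
                 alpha_forward = alpha_forward,
                 alpha_backward = alpha_backward, bootstrap_n = bootstrap_n,
                 stratify_bootstrap = stratify_bootstrap, seed = seed,
                 out_dir = out_dir),
            class = "analysis_config")
}

stage_seed <- function(seed, stage) (seed * 100 + stage) %% .Machine$integer.max

#' Run the full population-PK analysis pipeline
#'
#' Executes, in order: data simulation (or loading), BLQ exclusion and
#' outlier-driven error-group assignment, base-model fit, covariate
#' screening on the post-hoc etas, forward addition, backward elimination,
#' final fit with standard errors, bootstrap validation, and the
#' steady-state exposure table. Every stochastic stage uses a seed derived
#' from the master seed, so the bundle is a pure function of the
#' configuration.
#'
#' @param config An [analysis_config()].
#' @return A `pk_analysis` list: `dataset`, `thresholds`, `base_fit`,
#'   `screening`, `forward`, `backward`, `final_fit`, `bootstrap` (`NULL`
#'   when `bootstrap_n = 0`), `exposure`, `config`. If `out_dir` is set the
#'   bundle is also written as CSV/JSON files.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  state <- list(config = config, error = NULL)

  stages <- list(
    data = function(s) {
      if (inherits(config$data, "sim_config")) {
        sim <- simulate_study(config$data, seed = stage_seed(config$seed, 1))
        s$dataset <- sim$dataset
        s$truth <- sim$truth
      } else {
        s$dataset <- read_pk_dataset(config$data)
      }
      s$dataset <- flag_outliers(s$dataset)
      s$thresholds <- outlier_thresholds(s$dataset)
      s
    },
    base_fit = function(s) {
      s$base_fit <- fit_pk_model(s$dataset, config$base_model,
                                 seed = stage_seed(config$seed, 2))
      s
    },
    selection = function(s) {
      s$screening <- screen_covariates(s$base_fit, s$dataset,
                                       covariates = config$covariates,
                                       alpha = config$alpha_screen)
      cands <- candidate_terms(s$screening, s$dataset)
      s$forward <- forward_addition(s$dataset, s$base_fit$model, cands,
                                    alpha = config$alpha_forward)
      s$backward <- backward_elimination(s$dataset, s$forward$model,
                                         alpha = config$alpha_backward)
      s
    },
    final_fit = function(s) {
      s$final_fit <- fit_pk_model(s$dataset, s$backward$model,
                                  seed = stage_seed(config$seed, 2))
      s
    },
    bootstrap = function(s) {
      if (config$bootstrap_n > 0)
        s$bootstrap <- bootstrap_pk(s$dataset, s$final_fit$model,
                                    n_replicates = config$bootstrap_n,
                                    seed = stage_seed(config$seed, 3),
                                    stratify = config$stratify_bootstrap)
      s
    },
    exposure = function(s) {
      s$exposure <- exposure_table(s$dataset, s$final_fit$etas)
      s
    })

  for (nm in names(stages)) {
    state <- tryCatch(stages[[nm]](state), error = function(e) {
      state$error <- list(stage = nm, message = conditionMessage(e))
      state
    })
    if (!is.null(state$error)) break
  }

  out <- structure(state, class = "pk_analysis")
  if (!is.null(config$out_dir)) write_bundle(out, config$out_dir)
  out
}

write_bundle <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) if (!is.null(x))
    readr::write_csv(x, file.path(dir, name))
  if (!is.null(analysis$dataset))
    write_pk_dataset(analysis$dataset, file.path(dir, "dataset.csv"))
  w(analysis$thresholds, "outlier_thresholds.csv")
  if (!is.null(analysis$base_fit))
    w(tidy(analysis$base_fit), "parameters_base.csv")
  w(analysis$screening, "screening.csv")
  if (!is.null(analysis$backward))
    w(dplyr::bind_rows(
      dplyr::mutate(analysis$forward$trace, stage = "forward"),
      dplyr::mutate(analysis$backward$trace, stage = "backward")),
      "selection_trace.csv")
  if (!is.null(analysis$final_fit)) {
    w(tidy(analysis$final_fit), "parameters_final.csv")
    w(analysis$final_fit$gof, "gof.csv")
  }
  w(analysis$exposure, "exposure.csv")
  if (!is.null(analysis$bootstrap)) {
    w(tidy(analysis$bootstrap), "bootstrap_summary.csv")
    w(analysis$bootstrap$replicates, "bootstrap_replicates.csv")
  }
  if (!is.null(analysis$error))
    jsonlite::write_json(analysis$error, file.path(dir, "error.json"),
                         auto_unbox = TRUE)
  if (!is.null(analysis$final_fit))
    jsonlite::write_json(
      list(seed = analysis$config$seed,
           final_model = model_to_list(analysis$final_fit$model),
           ofv_base = analysis$base_fit$ofv,
           ofv_final = analysis$final_fit$ofv),
      file.path(dir, "analysis.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

model_to_list <- function(model) {
  list(cl = model$cl, v = model$v, omega2 = model$omega2,
       sigma2_normal = model$sigma2_normal,
       sigma2_outlier = model$sigma2_outlier,
       covariates = purrr::map(model$covariates, function(tm)
         tm[c("covariate", "form", "reference", "level", "value", "block")]))
}

#' Re-create a [pk_model()] from its serialized list form
#' @param x A list as produced by the JSON bundle.
#' @return A [pk_model()].
#' @export
model_from_list <- function(x) {
  pk_model(cl = x$cl, v = x$v, omega2 = x$omega2,
           sigma2_normal = x$sigma2_normal,
           sigma2_outlier = x$sigma2_outlier,
           covariates = purrr::map(x$covariates, function(tm)
             cov_term(tm$covariate, tm$form,
                      reference = tm$reference, level = tm$level,
                      value = tm$value, block = tm$block)))
}

#' @export
print.pk_analysis <- function(x, ...) {
  if (!is.null(x$error)) {
    cat("<pk_analysis> FAILED at stage `", x$error$stage, "`: ",
        x$error$message, "\n", sep = "")
    return(invisible(x))
  }
  cat("<pk_analysis>\n  base OFV ", format(x$base_fit$ofv, digits = 8),
      " -> final OFV ", format(x$final_fit$ofv, digits = 8), "\n  final: ",
      sep = "")
  print(x$final_fit$model)
  invisible(x)
}
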