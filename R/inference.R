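#' One-sample t test against a chance level
#'
#' Classical one-sample t test, used to compare temporal organization scores
#' to the chance level of 0.5.
#'
#' @param scores Numeric vector (NAs dropped).
#' @param mu0 Null value (default 0.5).
#' @return A one-row tibble: `n`, `mean`, `sd`, `t`, `df`, `p`.
#' @export
one_sample_t <- function(scores, mu0 = 0.5) {
  x <- scores[!is.na(scores)]
  if (length(x) < 2L) {
    stop("need at least 2 defined scores for a one-sample t test",
         call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("degenerate sample: all scores identical (sd = 0)", call. = FALSE)
  }
  tt <- stats::t.test(x, mu = mu0)
  tibble::tibble(n = length(x), mean = mean(x), sd = stats::sd(x),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
}

#' Chance-level tests by group and by timepoint
#'
#' Runs [one_sample_t()] on temporal organization scores against `mu0`
#' separately for each group and for each timepoint, within each task.
#'
#' @param scores A score table from [score_sequences()].
#' @param mu0 Chance level (default 0.5).
#' @return A tibble with one row per test: `task`, `subset` ("group" or
#'   "timepoint"), `level`, and the t-test columns.
#' @export
chance_tests <- function(scores, mu0 = 0.5) {
  run <- function(tab, subset_col) {
    dplyr::bind_rows(lapply(split(tab, tab[[subset_col]]), function(d) {
      dplyr::bind_cols(
        tibble::tibble(task = d$task[1L], subset = subset_col,
                       level = as.character(d[[subset_col]][1L])),
        one_sample_t(d$score, mu0))
    }))
  }
  dplyr::bind_rows(lapply(split(scores, scores$task), function(tab) {
    dplyr::bind_rows(run(tab, "group"), run(tab, "timepoint"))
  }))
}

new_model_fit <- function(kind, formula, data, cluster, coefficients,
                          log_lik, converged, n_obs, boot, extra = list()) {
  structure(
    list(kind = kind, formula = formula, data = data, cluster = cluster,
         coefficients = coefficients, log_lik = log_lik,
         converged = converged, n_obs = n_obs, boot = boot, extra = extra),
    class = "model_fit"
  )
}

#' @export
print.model_fit <- function(x, digits = 4, ...) {
  cat("<model_fit> ", x$kind, " model: ", deparse(x$formula),
      "\n  n = ", x$n_obs, ", logLik = ", format(x$log_lik, digits = 8),
      if (x$boot$B > 0) paste0(", cluster bootstrap B = ", x$boot$B) else
        ", model-based SEs",
      "\n\n", sep = "")
  print(as.data.frame(x$coefficients), digits = digits)
  invisible(x)
}

#' @export
coef.model_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
logLik.model_fit <- function(object, ...) object$log_lik

# ---- shared fixed-effects + participant-cluster bootstrap machinery -------

cluster_boot_coefs <- function(data, cluster, B, seed, fit_fun) {
  ids <- unique(data[[cluster]])
  rows <- split(seq_len(nrow(data)), data[[cluster]])
  set.seed(seed)
  reps <- matrix(NA_real_, nrow = B, ncol = 0L)
  est_list <- vector("list", B)
  for (b in seq_len(B)) {
    take <- sample(length(ids), replace = TRUE)
    idx <- unlist(rows[take], use.names = FALSE)
    est_list[[b]] <- tryCatch(
      suppressWarnings(fit_fun(data[idx, , drop = FALSE])),
      error = function(e) NULL)
  }
  est_list <- est_list[!vapply(est_list, is.null, logical(1))]
  do.call(rbind, est_list)
}

coef_table <- function(est, se, df = Inf, ci = NULL) {
  statistic <- est / se
  p <- if (is.finite(df)) 2 * stats::pt(-abs(statistic), df) else
    2 * stats::pnorm(-abs(statistic))
  out <- tibble::tibble(term = names(est), estimate = unname(est),
                        se = unname(se), statistic = unname(statistic),
                        p = unname(p))
  if (!is.null(ci)) {
    out$ci_lo <- ci[1L, ]
    out$ci_hi <- ci[2L, ]
  } else {
    q <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
    out$ci_lo <- out$estimate - q * out$se
    out$ci_hi <- out$estimate + q * out$se
  }
  out
}

fit_fixed_cluster <- function(data, formula, kind = c("linear", "binomial"),
                              cluster = "participant_id", B = 1000L,
                              seed = 1L) {
  kind <- match.arg(kind)
  data <- as.data.frame(data)
  if (!cluster %in% names(data)) {
    stop("cluster column `", cluster, "` not found", call. = FALSE)
  }
  fitter <- function(d) {
    if (kind == "binomial") {
      stats::glm(formula, family = stats::binomial(), data = d)
    } else {
      stats::lm(formula, data = d)
    }
  }
  fit <- suppressWarnings(fitter(data))
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; aliased terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  if (kind == "binomial") {
    if (!fit$converged || any(abs(cf) > 12)) {
      worst <- names(cf)[which.max(abs(cf))]
      stop("(quasi-)complete separation detected; offending term: ", worst,
           call. = FALSE)
    }
  }
  B <- as.integer(B)
  if (B > 0L) {
    boots <- cluster_boot_coefs(data, cluster, B, seed,
                                function(d) stats::coef(fitter(d)))
    if (is.null(boots) || nrow(boots) < max(20L, B %/% 2L)) {
      stop("cluster bootstrap failed in too many replicates", call. = FALSE)
    }
    se <- apply(boots, 2L, stats::sd)
    ci <- apply(boots, 2L, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE)
    coefs <- coef_table(cf, se, df = Inf, ci = ci)
  } else {
    sm <- summary(fit)$coefficients
    df <- if (kind == "linear") fit$df.residual else Inf
    coefs <- coef_table(cf, sm[, 2L], df = df)
  }
  new_model_fit(
    kind = kind, formula = formula, data = data, cluster = cluster,
    coefficients = coefs, log_lik = as.numeric(stats::logLik(fit)),
    converged = TRUE, n_obs = stats::nobs(fit),
    boot = list(B = B, seed = seed)
  )
}

#' Recall-accuracy model
#'
#' Logistic regression (logit link) predicting the probability of recalling
#' an item from group, timepoint and their interaction, fitted by maximum
#' likelihood with fixed effects. Within-participant dependence is handled
#' by a nonparametric cluster bootstrap that resamples participants with
#' replacement (percentile CIs; p-values from a normal approximation to the
#' bootstrap distribution). Set `B = 0` for model-based standard errors.
#'
#' @param outcomes Per-item binary outcomes from [recall_outcomes()] (or any
#'   data frame with the response and covariates); the response must be 0/1.
#' @param formula Model formula, default `recalled ~ group * timepoint`.
#' @param cluster Name of the participant-cluster column.
#' @param B Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap resampling.
#' @return A `model_fit` object.
#' @export
fit_recall_model <- function(outcomes, formula = recalled ~ group * timepoint,
                             cluster = "participant_id", B = 1000L,
                             seed = 1L) {
  resp <- stats::model.response(
    stats::model.frame(formula, data = as.data.frame(outcomes)))
  if (!all(resp %in% c(0, 1))) {
    stop("response must be binary 0/1", call. = FALSE)
  }
  if (length(unique(resp)) < 2L) {
    stop("(quasi-)complete separation detected; offending term: (Intercept)",
         " - all outcomes identical", call. = FALSE)
  }
  fit <- fit_fixed_cluster(outcomes, formula, kind = "binomial",
                           cluster = cluster, B = B, seed = seed)
  fit$kind <- "binomial"
  fit
}

#' Temporal organization score model
#'
#' Linear model predicting temporal organization scores from group,
#' timepoint and their interaction, optionally adjusting for percent recall
#' (grand-mean-centered). Estimated by ordinary least squares with
#' participant-cluster bootstrap standard errors (see [fit_recall_model()]
#' for the bootstrap scheme). Rows with undefined scores are dropped.
#'
#' @param scores A score table from [score_sequences()].
#' @param formula Model formula, default `score ~ group * timepoint`.
#' @param percent_recall_covariate If `TRUE`, adds grand-mean-centered
#'   percent recall (`percent_recall_c`) to the model.
#' @inheritParams fit_recall_model
#' @return A `model_fit` object.
#' @export
fit_score_model <- function(scores, formula = score ~ group * timepoint,
                            percent_recall_covariate = FALSE,
                            cluster = "participant_id", B = 1000L,
                            seed = 1L) {
  scores <- as.data.frame(scores)
  resp_name <- all.vars(formula)[1L]
  scores <- scores[!is.na(scores[[resp_name]]), , drop = FALSE]
  if (percent_recall_covariate) {
    scores$percent_recall_c <-
      scores$percent_recall - mean(scores$percent_recall)
    formula <- stats::update(formula, . ~ . + percent_recall_c)
  }
  fit_fixed_cluster(scores, formula, kind = "linear", cluster = cluster,
                    B = B, seed = seed)
}

#' Refit a model with a different factor reference level
#'
#' Re-bases the dummy coding of one factor and refits. This is a pure
#' reparameterization: the log-likelihood and fitted values are unchanged,
#' while simple effects are re-expressed at the new reference level (the
#' "reverse dummy coding" used to probe interactions).
#'
#' @param fit A `model_fit` from [fit_recall_model()], [fit_score_model()]
#'   or [fit_zib()].
#' @param factor Name of the factor column to re-base.
#' @param new_reference Level to use as the new reference.
#' @return A new `model_fit`.
#' @export
recode_reference <- function(fit, factor, new_reference) {
  stopifnot(inherits(fit, "model_fit"))
  data <- fit$data
  if (!factor %in% names(data)) {
    stop("factor `", factor, "` not in model data", call. = FALSE)
  }
  f <- as.factor(data[[factor]])
  if (!new_reference %in% levels(f)) {
    stop("level `", new_reference, "` not found in factor `", factor, "`",
         call. = FALSE)
  }
  data[[factor]] <- stats::relevel(f, ref = new_reference)
  if (fit$kind == "zib") {
    fit_zib(data, formula = fit$formula,
            zero_formula = fit$extra$zero_formula,
            link = fit$extra$link, adjust_ones = FALSE)
  } else {
    fit_fixed_cluster(data, fit$formula, kind = fit$kind,
                      cluster = fit$cluster, B = fit$boot$B,
                      seed = fit$boot$seed)
  }
}
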