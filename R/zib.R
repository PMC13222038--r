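#' Replace CRP values of exactly one by 0.999
#'
#' Beta regression requires responses strictly below 1. Conditional response
#' probabilities of exactly 1 (a lag transition made every time it was
#' possible) are rare, so they are adjusted to 0.999 rather than modelled as
#' a third mixture component.
#'
#' @param y Numeric vector of proportions in `[0, 1]`.
#' @return `y` with every exact 1 replaced by 0.999.
#' @export
one_adjust <- function(y) {
  y[!is.na(y) & y == 1] <- 0.999
  y
}

#' Prepare a lag-CRP table for zero-inflated beta regression
#'
#' Keeps cells where the lag transition was possible at least once
#' (structurally impossible transitions are not observed zeros and are
#' excluded), applies the one-adjustment ([one_adjust()]), and derives the
#' design covariates: `abs_lag` (1..max_lag, numeric) and `direction`
#' (backward = -0.5, forward = +0.5).
#'
#' @param crp_table Per-sequence lag-CRP rows from [crp_sequences()].
#' @return A tibble ready for [fit_zib()]: the identifying keys plus `crp`,
#'   `abs_lag`, `direction`.
#' @export
prepare_zib_data <- function(crp_table) {
  out <- crp_table[!is.na(crp_table$crp) & crp_table$possible > 0, ,
                   drop = FALSE]
  out$crp <- one_adjust(out$crp)
  out$abs_lag <- abs(out$lag)
  out$direction <- ifelse(out$lag > 0, 0.5, -0.5)
  tibble::as_tibble(out)
}

# beta log-likelihood of the positive part and its analytic gradient,
# parameterized as c(beta, log_phi) with mean link logit or log
beta_part_ll <- function(par, X, y, link) {
  p <- length(par) - 1L
  eta <- drop(X %*% par[seq_len(p)])
  mu <- if (link == "logit") stats::plogis(eta) else exp(eta)
  mu <- pmin(pmax(mu, 1e-8), 1 - 1e-8)
  phi <- exp(par[p + 1L])
  a <- mu * phi
  b <- (1 - mu) * phi
  sum(lgamma(phi) - lgamma(a) - lgamma(b) +
        (a - 1) * log(y) + (b - 1) * log1p(-y))
}

beta_part_grad <- function(par, X, y, link) {
  p <- length(par) - 1L
  eta <- drop(X %*% par[seq_len(p)])
  mu <- if (link == "logit") stats::plogis(eta) else exp(eta)
  mu <- pmin(pmax(mu, 1e-8), 1 - 1e-8)
  phi <- exp(par[p + 1L])
  a <- mu * phi
  b <- (1 - mu) * phi
  dmu <- phi * (-digamma(a) + digamma(b) + log(y) - log1p(-y))
  deta <- if (link == "logit") mu * (1 - mu) else mu
  g_beta <- drop(crossprod(X, dmu * deta))
  dphi <- digamma(phi) - mu * digamma(a) - (1 - mu) * digamma(b) +
    mu * log(y) + (1 - mu) * log1p(-y)
  c(g_beta, phi * sum(dphi))
}

#' Zero-inflated beta regression
#'
#' Two-part model for proportions with excess zeros, `0 <= y < 1`. The zero
#' part is a logistic regression for P(y = 0); conditional on y > 0, y
#' follows a Beta(mu * phi, (1 - mu) * phi) distribution with a linear
#' predictor for mu (logit link by default; `log` selectable) and a constant
#' precision phi. Because the likelihood factorizes, the zero part is fitted
#' by [stats::glm()] and the positive part by BFGS with analytic gradients;
#' the reported log-likelihood is the joint two-part value. Standard errors
#' come from the observed information of each part.
#'
#' @param data Data frame from [prepare_zib_data()] (or any data with the
#'   response and covariates).
#' @param formula Formula for the beta (mean) part, default
#'   `crp ~ group * timepoint * abs_lag * direction`.
#' @param zero_formula Formula for the zero part; default: same right-hand
#'   side as `formula`, response `I(y == 0)`.
#' @param link Mean link for the beta part: `"logit"` (default) or `"log"`.
#' @param adjust_ones If `TRUE`, apply [one_adjust()] to the response first;
#'   by default a response of exactly 1 is an error, pointing to the
#'   required preprocessing.
#' @return A `model_fit` of kind `"zib"`; its coefficient table has a
#'   `part` column with `"zero"`, `"mu"`, and a `"phi"` row (precision,
#'   reported on the natural scale).
#' @export
fit_zib <- function(data,
                    formula = crp ~ group * timepoint * abs_lag * direction,
                    zero_formula = NULL, link = c("logit", "log"),
                    adjust_ones = FALSE) {
  link <- match.arg(link)
  data <- as.data.frame(data)
  resp_name <- all.vars(formula)[1L]
  y <- data[[resp_name]]
  if (anyNA(y)) stop("response contains NA", call. = FALSE)
  if (any(y < 0 | y > 1)) {
    stop("response must lie in [0, 1]", call. = FALSE)
  }
  if (adjust_ones) {
    y <- one_adjust(y)
    data[[resp_name]] <- y
  }
  if (any(y == 1)) {
    stop("response contains values of exactly 1; adjust them to 0.999 ",
         "first (see one_adjust() / prepare_zib_data())", call. = FALSE)
  }
  if (all(y == 0) || all(y > 0)) {
    stop("zero-inflated beta regression needs both zero and positive ",
         "responses", call. = FALSE)
  }
  if (is.null(zero_formula)) {
    zero_formula <- formula
  }
  data$.zero <- as.integer(y == 0)
  zf <- stats::update(zero_formula, .zero ~ .)
  zero_fit <- suppressWarnings(
    stats::glm(zf, family = stats::binomial(), data = data))
  zcf <- stats::coef(zero_fit)
  if (anyNA(zcf)) {
    stop("rank-deficient zero-part design; aliased terms: ",
         paste(names(zcf)[is.na(zcf)], collapse = ", "), call. = FALSE)
  }
  zero_sm <- summary(zero_fit)$coefficients
  zero_tab <- coef_table(zcf, zero_sm[, 2L])
  zero_tab$part <- "zero"

  pos <- data[y > 0, , drop = FALSE]
  X <- stats::model.matrix(stats::delete.response(stats::terms(formula)),
                           data = pos)
  yp <- pos[[resp_name]]
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient beta-part design", call. = FALSE)
  }
  # starting values from a linear fit on the link scale
  eta0 <- if (link == "logit") stats::qlogis(pmin(pmax(yp, 0.01), 0.99)) else
    log(pmin(pmax(yp, 0.01), 0.99))
  beta0 <- stats::lm.fit(X, eta0)$coefficients
  mu0 <- if (link == "logit") stats::plogis(drop(X %*% beta0)) else
    pmin(exp(drop(X %*% beta0)), 1 - 1e-6)
  v <- stats::var(yp - mu0)
  phi0 <- max(1, mean(mu0 * (1 - mu0)) / max(v, 1e-6) - 1)
  par0 <- c(beta0, log(phi0))
  opt <- stats::optim(
    par0, fn = function(p) -beta_part_ll(p, X, yp, link),
    gr = function(p) -beta_part_grad(p, X, yp, link),
    method = "BFGS", control = list(maxit = 500, reltol = 1e-10))
  gnorm <- sqrt(sum(beta_part_grad(opt$par, X, yp, link)^2))
  if (opt$convergence != 0 || gnorm > 1e-2 * max(1, length(yp) / 100)) {
    stop("beta part did not converge (gradient norm ",
         format(gnorm, digits = 4), ")", call. = FALSE)
  }
  H <- stats::optimHess(opt$par, fn = function(p) -beta_part_ll(p, X, yp, link),
                        gr = function(p) -beta_part_grad(p, X, yp, link))
  V <- tryCatch(solve(H), error = function(e) NULL)
  p <- ncol(X)
  se <- if (is.null(V)) rep(NA_real_, p + 1L) else sqrt(pmax(diag(V), 0))
  est <- unname(opt$par)
  mu_tab <- coef_table(stats::setNames(est[seq_len(p)], colnames(X)),
                       se[seq_len(p)])
  mu_tab$part <- "mu"
  phi_hat <- exp(est[p + 1L])
  phi_tab <- tibble::tibble(
    term = "(phi)", estimate = phi_hat, se = phi_hat * se[p + 1L],
    statistic = NA_real_, p = NA_real_,
    ci_lo = exp(est[p + 1L] - 1.96 * se[p + 1L]),
    ci_hi = exp(est[p + 1L] + 1.96 * se[p + 1L]), part = "phi")
  ll <- as.numeric(stats::logLik(zero_fit)) - opt$value
  data$.zero <- NULL
  new_model_fit(
    kind = "zib", formula = formula, data = data, cluster = NULL,
    coefficients = dplyr::bind_rows(zero_tab, mu_tab, phi_tab),
    log_lik = ll, converged = TRUE, n_obs = length(y),
    boot = list(B = 0L, seed = NA_integer_),
    extra = list(zero_formula = zero_formula, link = link,
                 phi = phi_hat, gradient_norm = gnorm)
  )
}
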