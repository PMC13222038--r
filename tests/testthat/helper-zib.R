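# simulate straight from the two-part model: P(y = 0) from a logistic in
# the covariates, positive values Beta(mu * phi, (1 - mu) * phi)
simulate_zib <- function(n, gamma, beta, phi, link = "logit", seed = 1) {
  set.seed(seed)
  d <- data.frame(abs_lag = sample(1:5, n, replace = TRUE),
                  direction = sample(c(-0.5, 0.5), n, replace = TRUE))
  Xz <- model.matrix(~abs_lag, d)
  Xm <- model.matrix(~abs_lag * direction, d)
  pi0 <- plogis(drop(Xz %*% gamma))
  eta <- drop(Xm %*% beta)
  mu <- if (link == "logit") plogis(eta) else exp(eta)
  y <- ifelse(runif(n) < pi0, 0, rbeta(n, mu * phi, (1 - mu) * phi))
  d$crp <- pmin(y, 1 - 1e-12)
  d
}
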