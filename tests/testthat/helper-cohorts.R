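# Shared fixtures, built in code.

# step thresholds with locations spread over the trait range: the usual
# recovery-simulation configuration (7 five-category items + 1 three-category)
moderate_delta <- function() {
  tau7 <- c(-1.5, -0.5, 0.5, 1.5)
  loc <- c(-1.5, -1, -0.5, 0, 0.5, 1, 1.5, 0)
  d <- c(lapply(loc[1:7], function(x) x + tau7), list(loc[8] + c(-0.75, 0.75)))
  names(d) <- paste0("item_", 1:8)
  d
}

# thresholds confined to the +/- 1.6 logit band a unit-normal cohort of a few
# hundred persons populates well in every category: the configuration for
# parameter-recovery experiments
recovery_delta <- function() {
  tau7 <- c(-0.6, -0.2, 0.2, 0.6)
  loc <- seq(-1, 1, length.out = 7)
  d <- c(lapply(loc, function(x) x + tau7), list(c(-0.4, 0.4)))
  names(d) <- paste0("item_", 1:8)
  d
}

# sample PCM responses directly (persons x items category matrix)
sim_pcm_responses <- function(theta, delta, seed) {
  set.seed(seed)
  n <- length(theta)
  X <- matrix(NA_real_, n, length(delta),
              dimnames = list(NULL, names(delta) %||% paste0("item_", seq_along(delta))))
  for (i in seq_along(delta)) {
    p <- t(vapply(theta, function(th) pcm_prob(th, delta[[i]]), numeric(length(delta[[i]]) + 1)))
    cum <- t(apply(p, 1, cumsum))
    X[, i] <- rowSums(cum < stats::runif(n))
  }
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# center a true threshold list the way the estimator identifies the scale
center_delta <- function(delta) {
  c0 <- mean(vapply(delta, mean, numeric(1)))
  lapply(delta, function(d) d - c0)
}
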