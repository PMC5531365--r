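# Synthetic cohorts: one latent trait drives both the ordinal item responses
# (via the partial credit model) and a battery of DSM-5-style symptoms (via a
# logistic link), so the screen and the diagnosis are correlated the way the
# validation analyses assume, and every pipeline stage can be exercised
# without respondent data.

# run code with a private RNG stream; global .Random.seed is restored
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generative specification for a synthetic cohort
#'
#' Persons carry a latent problematic-use trait theta ~ Normal(theta_mean,
#' theta_sd). Item responses follow the partial credit model with the given
#' step thresholds; each of `n_symptoms` diagnostic symptoms is endorsed with
#' probability `plogis(symptom_slope * theta + b_s)`, independently given
#' theta. Diagnosis is `symptom_count >= diagnosis_threshold` (DSM-5 rule:
#' two or more), and severity follows the DSM-5 count bands (mild 2-3,
#' moderate 4-5, severe 6+).
#'
#' @param n number of persons (>= 2).
#' @param delta list of 8 step-threshold vectors (logits), on the category
#'   scale (item 8 has 2 steps).
#' @param n_symptoms number of diagnostic symptoms (10 or 11 in the emulated
#'   samples).
#' @param symptom_intercepts numeric vector of per-symptom intercepts b_s.
#' @param theta_mean,theta_sd latent-trait Normal parameters (logits).
#' @param symptom_slope logistic slope a linking theta to symptom
#'   endorsement; the default 1.7 is the usual logistic-to-probit scaling.
#' @param diagnosis_threshold minimum symptom count for a positive diagnosis.
#' @param severity_cuts lower bounds of the mild/moderate/severe bands.
#' @param label cohort label carried into reports.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, delta, n_symptoms, symptom_intercepts,
                        theta_mean = 0, theta_sd = 1, symptom_slope = 1.7,
                        diagnosis_threshold = 2, severity_cuts = c(2, 4, 6),
                        label = "cohort") {
  assert_that(n >= 2, "n must be at least 2")
  assert_that(theta_sd > 0, "theta_sd must be positive")
  assert_that(length(delta) == 8 && all(vapply(delta, function(d) all(is.finite(d)), logical(1))),
              "delta must be 8 finite threshold vectors")
  assert_that(length(symptom_intercepts) == n_symptoms,
              "need one intercept per symptom")
  assert_that(all(is.finite(symptom_intercepts)), "symptom intercepts must be finite")
  assert_that(diagnosis_threshold >= 1, "diagnosis_threshold must be >= 1")
  assert_that(length(severity_cuts) == 3 && all(diff(severity_cuts) > 0),
              "severity_cuts must be 3 increasing bounds")
  structure(list(n = as.integer(n), theta_mean = theta_mean,
                 theta_sd = theta_sd, delta = delta,
                 n_symptoms = as.integer(n_symptoms),
                 symptom_slope = symptom_slope,
                 symptom_intercepts = symptom_intercepts,
                 diagnosis_threshold = as.integer(diagnosis_threshold),
                 severity_cuts = severity_cuts, label = label),
            class = "cohort_spec")
}

# step offsets shared by the default specs: items 1-7 have four steps spread
# over +/- 1.5 logits around the item location, item 8 two steps over +/- 0.75
.tau7 <- c(-1.5, -0.5, 0.5, 1.5)
.tau8 <- c(-0.75, 0.75)

# item locations calibrated offline (theta-grid integration under N(0,1)) so
# that large-n endorsement P(X >= 1) matches the emulated samples' item
# endorsement margins; symptom-ladder centers calibrated the same way so that
# P(count >= 2) hits the emulated diagnosis prevalence (47% / 46%)
.sample1_locations <- c(-2.036, -0.845, 3.038, 2.871, 2.473, 1.419, 2.871, 0.785)
.sample2_locations <- c(-1.678, -0.338, 2.817, 2.381, 2.162, 1.419, 2.520, 0.345)
.sample1_ladder <- list(center = -2.4894, spacing = 0.5)
.sample2_ladder <- list(center = -2.2238, spacing = 0.25)

ladder_intercepts <- function(center, spacing, S) {
  center - spacing * (seq_len(S) - (S + 1) / 2)
}

#' Default cohort specifications for the two emulated samples
#'
#' Sample-1-like: n = 207, 10 symptoms, prevalence calibrated to 47%.
#' Sample-2-like: n = 369, 11 symptoms, prevalence calibrated to 46%.
#' Item thresholds are calibrated so large-n endorsement margins (any
#' response >= 1) approximate the published per-item endorsement of the two
#' community samples.
#'
#' @return named list with `sample1_like` and `sample2_like` [cohort_spec()]s.
#' @export
default_specs <- function() {
  d1 <- c(lapply(.sample1_locations[1:7], function(d) d + .tau7),
          list(.sample1_locations[8] + .tau8))
  d2 <- c(lapply(.sample2_locations[1:7], function(d) d + .tau7),
          list(.sample2_locations[8] + .tau8))
  names(d1) <- names(d2) <- paste0("item_", 1:8)
  list(
    sample1_like = cohort_spec(
      n = 207, delta = d1, n_symptoms = 10,
      symptom_intercepts = ladder_intercepts(.sample1_ladder$center,
                                             .sample1_ladder$spacing, 10),
      label = "sample1_like"),
    sample2_like = cohort_spec(
      n = 369, delta = d2, n_symptoms = 11,
      symptom_intercepts = ladder_intercepts(.sample2_ladder$center,
                                             .sample2_ladder$spacing, 11),
      label = "sample2_like")
  )
}

#' Generate a synthetic cohort
#'
#' Deterministic given `spec` and `seed`; the global RNG state is left
#' untouched.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return object of class `synthetic_cohort`: `data` (data frame with raw
#'   item codes `item_1..item_8`, `dsm_positive`, `symptom_count`,
#'   `severity`, `theta_true`), `responses` (a [response_matrix()] on the
#'   category scale), `spec`, `seed`.
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "seed must be a single integer")
  out <- with_seed(seed, {
    n <- spec$n
    theta <- stats::rnorm(n, spec$theta_mean, spec$theta_sd)
    cats <- matrix(NA_real_, n, 8, dimnames = list(NULL, names(spec$delta)))
    for (i in 1:8) {
      p <- pcm_prob_matrix(theta, spec$delta[[i]])
      cum <- t(apply(p, 1, cumsum))
      u <- stats::runif(n)
      cats[, i] <- rowSums(cum < u)
    }
    S <- spec$n_symptoms
    ps <- stats::plogis(outer(spec$symptom_slope * theta, spec$symptom_intercepts, "+"))
    sym <- matrix(stats::runif(n * S) < ps, n, S)
    count <- rowSums(sym)
    list(theta = theta, cats = cats, count = count)
  })
  severity <- cut(out$count,
                  breaks = c(-Inf, spec$severity_cuts, Inf), right = FALSE,
                  labels = c("none", "mild", "moderate", "severe"))
  mat <- response_matrix(out$cats, m = c(rep(4L, 7), 2L))
  raw <- matrix_to_raw(mat)
  data <- cbind(raw,
                data.frame(dsm_positive = as.integer(out$count >= spec$diagnosis_threshold),
                           symptom_count = out$count,
                           severity = severity,
                           theta_true = out$theta))
  structure(list(data = data, responses = mat, spec = spec, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %s: n = %d, prevalence %.1f%%, seed %s\n",
              x$spec$label, nrow(x$data),
              100 * mean(x$data$dsm_positive), format(x$seed)))
  invisible(x)
}

#' Score the instrument: full-form and short-form totals
#'
#' Totals are on the raw instrument scale (item 8 contributes 0/2/4), giving
#' a full-form range of 0-32. The short form sums items 3, 5 and 6 (range
#' 0-12) and screens positive at `sf_cut` or higher.
#'
#' @param raw data frame of raw item codes (`item_1..item_8`), a
#'   [response_matrix()] on the category scale, or a `synthetic_cohort`.
#' @param sf_items the short-form items (default 3, 5, 6).
#' @param sf_cut short-form positivity cut (default 2).
#' @return data frame with `total` (NA when any item is missing), `sf_total`,
#'   `sf_positive`.
#' @export
score_cudit <- function(raw, sf_items = c(3, 5, 6), sf_cut = 2) {
  if (inherits(raw, "synthetic_cohort")) raw <- raw$data
  if (inherits(raw, "response_matrix")) raw <- matrix_to_raw(raw)
  raw <- as.data.frame(raw)
  cols <- paste0("item_", 1:8)
  if (!all(cols %in% names(raw))) stop_domain("need columns item_1..item_8")
  maps <- cudit_raw_maps()
  for (j in cols) {
    x <- raw[[j]]
    bad <- !is.na(x) & !(x %in% maps[[j]]$raw)
    if (any(bad)) {
      stop_domain(sprintf("%s: invalid raw code(s) %s (allowed: %s)", j,
                          paste(unique(x[bad]), collapse = ", "),
                          paste(maps[[j]]$raw, collapse = "/")))
    }
  }
  rmat <- as.matrix(raw[cols])
  total <- rowSums(rmat)
  sf_total <- rowSums(rmat[, paste0("item_", sf_items), drop = FALSE])
  data.frame(total = total, sf_total = sf_total,
             sf_positive = as.integer(sf_total >= sf_cut))
}
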