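test_that("category probabilities follow the partial credit form", {
  # dichotomous symmetry at theta = delta
  expect_equal(pcm_prob(0.7, 0.7), c(0.5, 0.5))
  # hand-derived three-category case: (1, e, 1)/(2 + e)
  expect_equal(pcm_prob(0, c(-1, 1)), c(1, exp(1), 1) / (2 + exp(1)),
               tolerance = 1e-12)
  # normalization and range over random inputs
  set.seed(1)
  for (r in 1:25) {
    m <- sample(1:5, 1)
    p <- pcm_prob(rnorm(1, 0, 2), sort(rnorm(m, 0, 2)))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0 & p < 1))
  }
  # m = 1 reduces exactly to the dichotomous Rasch model
  th <- seq(-3, 3, by = 0.5)
  for (d in c(-1, 0, 2)) {
    p1 <- vapply(th, function(t) pcm_prob(t, d)[2], numeric(1))
    expect_equal(p1, plogis(th - d), tolerance = 1e-12)
  }
  expect_error(pcm_prob(Inf, 0), "finite")
  expect_error(pcm_prob(0, c(0, NA)), "finite")
})

test_that("item information is the category-score variance and the slope of the expected score", {
  expect_equal(item_information(0.5, 0.5), 0.25, tolerance = 1e-12)
  # hand value: E[X] = 1, E[X^2] = (e + 4)/(2 + e)
  expect_equal(item_information(0, c(-1, 1)),
               (exp(1) + 4) / (2 + exp(1)) - 1, tolerance = 1e-12)
  # central-difference oracle: info = dE[X]/dtheta
  set.seed(2)
  h <- 1e-5
  for (r in 1:20) {
    th <- rnorm(1); d <- sort(rnorm(sample(1:4, 1), 0, 1.5))
    ex <- function(t) sum((0:length(d)) * pcm_prob(t, d))
    expect_equal(item_information(th, d), (ex(th + h) - ex(th - h)) / (2 * h),
                 tolerance = 1e-6)
  }
  expect_true(all(item_information(seq(-4, 4, 0.5), c(-2, 0, 2)) >= 0))
})

test_that("test information is additive and peaks where it should", {
  params <- list(delta = list(item_1 = c(-1, 0, 1), item_2 = 0.5))
  ti <- test_information(params)
  expect_equal(ti$total,
               item_information(ti$theta, c(-1, 0, 1)) +
                 item_information(ti$theta, 0.5), tolerance = 1e-12)
  # single dichotomous item: information peaks at its threshold
  ti1 <- test_information(params, items = "item_2")
  expect_equal(ti1$theta_star, 0.5, tolerance = 1e-9)
  # grid refinement moves the argmax by less than the coarse step
  tic <- test_information(params, theta_grid = seq(-6, 6, by = 0.01))
  tif <- test_information(params, theta_grid = seq(-6, 6, by = 0.001))
  expect_lt(abs(tic$theta_star - tif$theta_star), 0.01 + 1e-9)
  expect_error(test_information(params, items = character(0)), "non-empty")
})

test_that("joint maximum likelihood recovers generating parameters", {
  delta <- recovery_delta()
  set.seed(11)
  theta <- rnorm(500)
  X <- sim_pcm_responses(theta, delta, seed = 12)
  data <- response_matrix(X, m = c(rep(4L, 7), 2L))
  fit <- suppressMessages(fit_jmle(data))
  expect_true(fit$converged)
  # centering constraint
  expect_lt(abs(mean(fit$item_location)), 1e-6)
  dt <- unlist(center_delta(delta))
  de <- unlist(fit$delta)
  expect_gt(cor(dt, de), 0.95)
  expect_lt(sqrt(mean((dt - de)^2)), 0.3)
  # person measures track the generating trait
  est <- setdiff(seq_along(theta), fit$extreme_persons)
  expect_gt(cor(theta[est], fit$theta[est]), 0.8)
})

test_that("exchangeable items get identical estimates", {
  set.seed(21)
  theta <- rnorm(150)
  x <- sim_pcm_responses(theta, list(a = c(-0.5, 0.5)), seed = 22)
  X <- cbind(item_a = x[, 1], item_b = x[, 1],
             item_c = sim_pcm_responses(theta, list(c = c(-1, 1)), seed = 23)[, 1])
  fit <- suppressMessages(fit_jmle(response_matrix(X, m = c(2L, 2L, 2L))))
  expect_equal(fit$delta$item_a, fit$delta$item_b, tolerance = 1e-6)
})

test_that("anchored estimation decomposes into independent per-item problems", {
  set.seed(31)
  theta <- rnorm(120)
  delta <- list(item_1 = -0.8, item_2 = 0.3, item_3 = 1.1)
  X <- sim_pcm_responses(theta, delta, seed = 32)
  data <- response_matrix(X, m = c(1L, 1L, 1L))
  anchors <- setNames(theta, as.character(seq_along(theta)))
  fit <- fit_jmle(data, anchors = anchors)
  # anchored measures returned bit-for-bit
  expect_identical(fit$theta, theta)
  # brute-force 1-D likelihood search per dichotomous item
  for (i in 1:3) {
    ll <- function(d) sum(dbinom(X[, i], 1, plogis(theta - d), log = TRUE))
    d_star <- optimize(ll, c(-6, 6), maximum = TRUE, tol = 1e-9)$maximum
    expect_equal(unname(fit$delta[[i]]), d_star, tolerance = 0.01)
  }
})

test_that("JMLE threshold error shrinks as the cohort grows", {
  delta <- recovery_delta()
  dt <- unlist(center_delta(delta))
  mae <- vapply(c(200, 1000, 5000), function(n) {
    set.seed(1000 + n)
    X <- sim_pcm_responses(rnorm(n), delta, seed = 2000 + n)
    fit <- suppressMessages(fit_jmle(response_matrix(X, m = c(rep(4L, 7), 2L))))
    mean(abs(unlist(fit$delta) - dt))
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
})

test_that("unobserved intermediate categories are collapsed and reported", {
  set.seed(41)
  theta <- rnorm(200)
  X <- sim_pcm_responses(theta, moderate_delta(), seed = 42)
  X[, 3][X[, 3] == 2] <- 3  # category 2 never observed for item 3
  fit <- suppressMessages(fit_jmle(response_matrix(X, m = c(rep(4L, 7), 2L))))
  map3 <- fit$category_maps$item_3
  expect_true(fit$converged)
  expect_lt(max(map3$new), 4)               # fewer categories after collapse
  expect_equal(map3$new, cummax(map3$new))  # order-preserving
  expect_equal(length(fit$delta$item_3), max(map3$new))
})

test_that("extreme persons are excluded then extrapolated", {
  set.seed(51)
  theta <- rnorm(80)
  X <- sim_pcm_responses(theta, moderate_delta(), seed = 52)
  X[1, ] <- 0                       # all-minimum person
  X[2, ] <- c(rep(4, 7), 2)         # all-maximum person
  expect_message(fit <- fit_jmle(response_matrix(X, m = c(rep(4L, 7), 2L))),
                 "extreme person")
  expect_setequal(fit$extreme_persons, c(1, 2))
  others <- fit$theta[-(1:2)]
  expect_true(is.finite(fit$theta[1]) && fit$theta[1] < min(others))
  expect_true(is.finite(fit$theta[2]) && fit$theta[2] > max(others))
})

test_that("fit statistics are calibrated under the model and flag misfits", {
  delta <- moderate_delta()
  set.seed(61)
  X <- sim_pcm_responses(rnorm(1000), delta, seed = 62)
  data <- response_matrix(X, m = c(rep(4L, 7), 2L))
  fit <- suppressMessages(fit_jmle(data))
  fs <- fit_statistics(data, fit)
  expect_true(all(fs$items$infit > 0) && all(fs$items$outfit > 0))
  in_band <- fs$items$infit >= 0.8 & fs$items$infit <= 1.2 &
    fs$items$outfit >= 0.8 & fs$items$outfit <= 1.2
  expect_gte(sum(in_band), 7)
  # a person with responses flipped to be maximally inconsistent becomes the
  # cohort outfit maximum
  Y <- X
  est <- setdiff(seq_len(nrow(X)), fit$extreme_persons)
  victim <- est[which.max(fit$theta[est])]
  Y[victim, ] <- c(rep(4L, 7), 2L) - Y[victim, ]  # reverse every response
  data2 <- response_matrix(Y, m = c(rep(4L, 7), 2L))
  fit2 <- suppressMessages(fit_jmle(data2))
  fs2 <- fit_statistics(data2, fit2)
  ok <- setdiff(seq_len(nrow(Y)), fit2$extreme_persons)
  expect_equal(ok[which.max(fs2$persons$outfit[ok])], victim)
})

test_that("fit statistics match a hand-computed small example", {
  X <- matrix(c(1, 0, 1, 0, 1, 1, 0, 0), 4, 2,
              dimnames = list(NULL, c("item_1", "item_2")))
  data <- response_matrix(X, m = c(1L, 1L))
  fit <- suppressMessages(fit_jmle(data))
  fs <- fit_statistics(data, fit)
  # recompute from first principles with the fitted parameters
  for (i in 1:2) {
    p <- plogis(fit$theta - fit$delta[[i]])
    z2 <- (X[, i] - p)^2 / (p * (1 - p))
    keep <- p * (1 - p) > 1e-10
    expect_equal(fs$items$outfit[i], mean(z2[keep]), tolerance = 1e-10)
    expect_equal(fs$items$infit[i],
                 sum((X[keep, i] - p[keep])^2) / sum(p[keep] * (1 - p[keep])),
                 tolerance = 1e-10)
  }
})

test_that("residual PCA separates planted structure from noise", {
  delta <- moderate_delta()
  set.seed(71)
  X <- sim_pcm_responses(rnorm(800), delta, seed = 72)
  data <- response_matrix(X, m = c(rep(4L, 7), 2L))
  fit <- suppressMessages(fit_jmle(data))
  pca <- residual_pca(data, fit)
  # trace identity: eigenvalues of a correlation matrix sum to n items
  expect_equal(sum(pca$eigenvalues), 8, tolerance = 1e-6)
  # model-true data: first contrast stays near the unidimensionality bound
  expect_lt(pca$eigenvalues[1], 2.0)
  # plant a second dimension on items 2 and 7: a shared binary nuisance
  set.seed(73)
  nuis <- rbinom(800, 1, 0.5)
  Y <- X
  Y[, 2] <- pmin(pmax(X[, 2] + ifelse(nuis == 1, 1, -1), 0), 4)
  Y[, 7] <- pmin(pmax(X[, 7] + ifelse(nuis == 1, 1, -1), 0), 4)
  data2 <- response_matrix(Y, m = c(rep(4L, 7), 2L))
  fit2 <- suppressMessages(fit_jmle(data2))
  pca2 <- residual_pca(data2, fit2)
  l <- pca2$first_contrast
  expect_identical(sort(names(sort(abs(l), decreasing = TRUE)[1:2])),
                   c("item_2", "item_7"))
  expect_gt(l[["item_2"]] * l[["item_7"]], 0)  # same sign: they load together
  expect_error(residual_pca(response_matrix(X[1:4, ], m = c(rep(4L, 7), 2L)), fit),
               "persons")
})
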