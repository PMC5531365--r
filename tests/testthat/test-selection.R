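test_that("information matching equals exhaustive search and honours tie-breaks", {
  delta <- moderate_delta()
  params <- list(delta = delta)
  sel <- select_tcc(params, 3)
  # independent exhaustive oracle on the same grid
  grid <- seq(-6, 6, by = 0.01)
  info <- vapply(delta, function(d) item_information(grid, d), numeric(length(grid)))
  star <- grid[which.max(rowSums(info))]
  combos <- combn(8, 3)
  crit <- apply(combos, 2, function(s) {
    cv <- rowSums(info[, s, drop = FALSE])
    c(abs(grid[which.max(cv)] - star), cv[which.max(rowSums(info))])
  })
  best <- combos[, order(crit[1, ], -crit[2, ])[1]]
  expect_setequal(sel$items, paste0("item_", best))
  expect_equal(sel$trace$theta_star_full, star)
  expect_equal(nrow(sel$trace$subsets), choose(8, 3))
})

test_that("information matching returns the full set at k = n and is label-invariant", {
  delta <- moderate_delta()
  sel_all <- select_tcc(list(delta = delta), 8)
  expect_setequal(sel_all$items, paste0("item_", 1:8))
  expect_equal(min(sel_all$trace$subsets$criterion), sel_all$trace$subsets$criterion[1])
  # permutation equivariance: relabelled items give the same selection
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  delta_p <- delta[perm]
  sel <- select_tcc(list(delta = delta), 3)
  sel_p <- select_tcc(list(delta = delta_p), 3)
  expect_setequal(sel$items, sel_p$items)
  expect_error(select_tcc(list(delta = delta), 9), "k exceeds")
})

test_that("information matching finds items planted at the full-form peak", {
  # three high-information items concentrated at the full-form peak; five
  # weak items whose information sits 2.5 logits away on either side
  delta <- c(lapply(1:3, function(i) rep(0, 4)),
             lapply(4:8, function(i) c(-2.5, 2.5)))
  names(delta) <- paste0("item_", 1:8)
  ti <- test_information(list(delta = delta))
  sel <- select_tcc(list(delta = delta), 3)
  expect_setequal(sel$items, paste0("item_", 1:3))
  expect_equal(ti$theta_star, 0)  # the planted peak dominates the full curve
})

test_that("Rasch regression anchors persons and demotes a diagnosis-independent item", {
  set.seed(81)
  n <- 300
  theta <- rnorm(n)
  diagnosis <- as.integer(theta > 0)
  delta <- c(lapply(c(-1, -0.5, 0, 0.3, 0.7, 1, 0.5), function(d) d + c(-1, 1)),
             list(c(-0.5, 0.5)))
  names(delta) <- paste0("item_", 1:8)
  X <- sim_pcm_responses(theta, delta, seed = 82)
  set.seed(83)
  X[, 8] <- sample(0:2, n, replace = TRUE)  # pure noise, diagnosis-independent
  data <- response_matrix(X, m = c(rep(2L, 7), 2L))
  sel <- select_rasch_regression(data, diagnosis, k = 3)
  # anchoring contract: fitted measures are exactly the anchor values
  expect_identical(unname(sel$trace$fit$theta), as.numeric(diagnosis))
  expect_identical(sort(unique(sel$trace$fit$theta)), c(0, 1))
  # the noise item ranks last on the differentiation-led composite
  expect_equal(sel$trace$items$item[sel$trace$items$rank == 8], "item_8")
  expect_equal(which.min(sel$trace$items$point_measure), 8L)
  expect_false("item_8" %in% sel$items)
  # k = n items returns the full set
  expect_setequal(select_rasch_regression(data, diagnosis, k = 8)$items,
                  paste0("item_", 1:8))
  expect_error(select_rasch_regression(data, rep(1, n), k = 3), "constant")
})

test_that("Rasch regression favours items that straddle the anchor gap", {
  # items 1-3 have thresholds inside the 0/1 anchor gap; items 4-8 sit 3
  # logits out, where anchored persons are indistinguishable
  delta <- c(lapply(1:3, function(i) c(0.2, 0.8)),
             lapply(4:8, function(i) c(3, 4)))
  names(delta) <- paste0("item_", 1:8)
  hits <- 0
  for (s in 1:20) {
    set.seed(900 + s)
    theta <- rnorm(250, 0.5, 1)
    diagnosis <- as.integer(theta > 0.5)
    X <- sim_pcm_responses(theta, delta, seed = 950 + s)
    data <- response_matrix(X, m = rep(2L, 8))
    sel <- tryCatch(select_rasch_regression(data, diagnosis, k = 3),
                    error = function(e) NULL)
    if (!is.null(sel) && setequal(sel$items, paste0("item_", 1:3))) hits <- hits + 1
  }
  expect_gt(hits, 10)
})

test_that("the internal logistic fitter matches glm", {
  set.seed(91)
  X <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(200, 1, plogis(X %*% c(1, -0.5, 0)))
  fit <- shortscreen:::fit_logistic(X, y)
  ref <- glm(y ~ X, family = binomial())
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_equal(unname(diag(fit$vcov)), unname(diag(vcov(ref))), tolerance = 1e-4)
})

test_that("stepwise logistic entry matches the exhaustive score-test oracle", {
  set.seed(92)
  n <- 250
  theta <- rnorm(n)
  delta <- moderate_delta()
  X <- sim_pcm_responses(theta, delta, seed = 93)
  y <- rbinom(n, 1, plogis(1.5 * theta))
  data <- response_matrix(X, m = c(rep(4L, 7), 2L))
  sel <- select_stepwise_logistic(data, y, criterion = "wald", k = 3)
  # step-1 oracle: Rao score test of each single covariate via stats::add1
  null_fit <- glm(y ~ 1, family = binomial(), data = as.data.frame(X))
  sc <- add1(null_fit, scope = as.formula(paste("~", paste(colnames(X), collapse = "+"))),
             test = "Rao")
  oracle_first <- rownames(sc)[-1][which.max(sc$`Rao score`[-1])]
  expect_equal(sel$items[1], oracle_first)
  expect_equal(sel$trace$steps$statistic[1], max(sc$`Rao score`[-1]),
               tolerance = 1e-6)
  expect_length(sel$items, 3)
})

test_that("a dominant covariate enters first and the criteria agree without collinearity", {
  set.seed(94)
  n <- 300
  y <- rbinom(n, 1, 0.5)
  X <- matrix(sample(0:4, n * 8, replace = TRUE), n, 8,
              dimnames = list(NULL, paste0("item_", 1:8)))
  X[, 4] <- pmin(pmax(y * 3 + sample(0:1, n, replace = TRUE), 0), 4)  # dominant
  data <- response_matrix(X, m = rep(4L, 8))
  for (crit in c("wald", "lr", "conditional")) {
    sel <- select_stepwise_logistic(data, y, criterion = crit, k = 3)
    expect_equal(sel$items[1], "item_4")
  }
  w <- select_stepwise_logistic(data, y, "wald", k = 3)$items
  l <- select_stepwise_logistic(data, y, "lr", k = 3)$items
  cnd <- select_stepwise_logistic(data, y, "conditional", k = 3)$items
  expect_identical(w, l)
  expect_identical(w, cnd)
})

test_that("stepwise DFA matches the direct F oracle and guards collinearity", {
  set.seed(95)
  n <- 260
  theta <- rnorm(n)
  y <- as.integer(theta + rnorm(n, 0, 0.7) > 0)
  delta <- moderate_delta()
  X <- sim_pcm_responses(theta, delta, seed = 96)
  data <- response_matrix(X, m = c(rep(4L, 7), 2L))
  sel <- select_stepwise_dfa(data, y, k = 3)
  # step-1 oracle: the covariate with the largest two-group F
  f1 <- vapply(seq_len(8), function(i) {
    summary(aov(X[, i] ~ factor(y)))[[1]][1, "F value"]
  }, numeric(1))
  expect_equal(sel$items[1], paste0("item_", which.max(f1)))
  expect_equal(sel$trace$steps$F[1], max(f1), tolerance = 1e-8)
  expect_length(unique(sel$items), length(sel$items))
  # duplicated covariate never enters twice
  X2 <- X; X2[, 5] <- X2[, 4]
  colnames(X2) <- paste0("item_", 1:8)
  sel2 <- select_stepwise_dfa(response_matrix(X2, m = c(rep(4L, 7), 2L)), y, k = 3)
  expect_false(all(c("item_4", "item_5") %in% sel2$items))
  # one dominant discriminator: DFA and logistic agree on the first entry
  sel_log <- select_stepwise_logistic(data, y, "wald", k = 1)
  Xd <- X; Xd[, 2] <- y * 4
  datad <- response_matrix(Xd, m = c(rep(4L, 7), 2L))
  expect_equal(select_stepwise_dfa(datad, y, k = 1)$items,
               select_stepwise_logistic(datad, y, "wald", k = 1)$items)
})

test_that("selection is deterministic given the data", {
  set.seed(97)
  theta <- rnorm(150)
  X <- sim_pcm_responses(theta, moderate_delta(), seed = 98)
  y <- as.integer(theta > 0)
  data <- response_matrix(X, m = c(rep(4L, 7), 2L))
  a <- select_stepwise_dfa(data, y, k = 3)
  b <- select_stepwise_dfa(data, y, k = 3)
  expect_identical(a$items, b$items)
  fitp <- suppressMessages(fit_jmle(data))
  expect_identical(select_tcc(fitp, 3)$items, select_tcc(fitp, 3)$items)
})
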