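# Four routes from the 8-item instrument to a k-item short form: information
# matching against the full form's test information curve, Rasch calibration
# with persons anchored at their diagnosis, forward stepwise logistic
# regression, and stepwise discriminant function analysis.

selection_result <- function(method, items, trace) {
  if (anyDuplicated(items)) stop_domain("selected items must be distinct")
  structure(list(method = method, items = items, trace = trace),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %s\n", x$method,
              paste(x$items, collapse = ", ")))
  invisible(x)
}

#' Select items by matching the full form's information peak
#'
#' Scores every k-subset of items by how closely the subset's test
#' information peak sits to the full form's peak theta*. The default
#' criterion is the absolute distance between the two argmax points, with
#' ties broken by larger subset information at theta*, then by item order;
#' `criterion = "integrated"` instead minimizes the mean absolute difference
#' between the subset curve and the (k/n-scaled) full curve over the grid.
#' Exhaustive for up to 12 items; beyond that a greedy forward search adds
#' the item that most improves the criterion.
#'
#' @param params a `pcm_parameters` fit of the full item set.
#' @param k short-form size.
#' @param criterion `"argmax"` (default) or `"integrated"`.
#' @param theta_grid evaluation grid, default -6..6 by 0.01.
#' @return a `selection_result`; `trace` holds every evaluated subset's
#'   criterion (exhaustive case), plus `theta_star_full`.
#' @export
select_tcc <- function(params, k, criterion = c("argmax", "integrated"),
                       theta_grid = seq(-6, 6, by = 0.01)) {
  criterion <- match.arg(criterion)
  ids <- names(params$delta) %||% params$item_ids
  n_items <- length(ids)
  if (k > n_items) stop_domain("k exceeds the number of items")
  ti <- test_information(params, theta_grid)
  theta_star <- ti$theta_star
  star_idx <- which.max(ti$total)
  item_info <- ti$item_info  # grid x items

  score_subset <- function(sub) {
    curve <- rowSums(item_info[, sub, drop = FALSE])
    if (criterion == "argmax") {
      c(crit = abs(theta_grid[which.max(curve)] - theta_star),
        info_at_star = curve[star_idx])
    } else {
      c(crit = mean(abs(curve - ti$total * length(sub) / n_items)),
        info_at_star = curve[star_idx])
    }
  }

  if (n_items <= 12) {
    subsets <- utils::combn(n_items, k)
    crit <- apply(subsets, 2, function(s) score_subset(s))
    ord <- order(crit["crit", ], -crit["info_at_star", ])  # combn order = lexicographic
    best <- subsets[, ord[1]]
    trace <- data.frame(
      subset = apply(subsets, 2, function(s) paste(ids[s], collapse = "+")),
      criterion = crit["crit", ], info_at_star = crit["info_at_star", ])
  } else {
    sel <- integer(0)
    for (step in seq_len(k)) {
      cand <- setdiff(seq_len(n_items), sel)
      sc <- vapply(cand, function(j) score_subset(c(sel, j))["crit"], numeric(1))
      sel <- c(sel, cand[which.min(sc)])
    }
    best <- sort(sel)
    trace <- data.frame(subset = paste(ids[best], collapse = "+"),
                        criterion = score_subset(best)["crit"],
                        info_at_star = score_subset(best)["info_at_star"])
  }
  trace <- list(theta_star_full = theta_star, subsets = trace,
                criterion = criterion)
  selection_result("tcc", ids[best], trace)
}

#' Select items by Rasch regression
#'
#' Calibrates the items with every person's measure anchored at their
#' diagnosis value (positive = 1 logit, negative = 0), then ranks items by
#' how well they measure that anchored scale. The primary criterion is the
#' point-measure correlation (the correlation between item scores and the
#' anchored measures, descending): under anchoring the person measure IS the
#' diagnosis, so this is the item's ability to differentiate the two groups.
#' Ties are resolved by the fit composite `|infit - 1| + |outfit - 1|`
#' (ascending) and then by the magnitude of the item's loading on the first
#' contrast of the residual PCA (ascending, smaller = more unidimensional
#' with the diagnosis-anchored trait); all three criteria are reported in the
#' trace. Fit mean squares alone do not rank trait-driven items reliably
#' here -- with every person pinned to 0 or 1 logits they concentrate near 1
#' for any item the trait drives -- so differentiation leads the composite.
#'
#' @param data a [response_matrix()].
#' @param diagnosis binary vector aligned with persons.
#' @param k short-form size.
#' @param anchor_values measures assigned to (negative, positive) persons;
#'   default `c(0, 1)` logits.
#' @return a `selection_result`; `trace` has per-item fit and loading.
#' @export
select_rasch_regression <- function(data, diagnosis, k, anchor_values = c(0, 1)) {
  diagnosis <- as.integer(diagnosis)
  n <- nrow(data$responses)
  if (length(diagnosis) != n) stop_domain("diagnosis must align with persons")
  if (length(unique(diagnosis[!is.na(diagnosis)])) < 2) {
    stop_domain("diagnosis is constant; no discrimination possible")
  }
  if (k > length(data$item_ids)) stop_domain("k exceeds the number of items")
  anchors <- stats::setNames(anchor_values[diagnosis + 1], as.character(seq_len(n)))
  anchors <- anchors[!is.na(anchors)]
  fit <- fit_jmle(data, anchors = anchors)
  fs <- fit_statistics(data, fit)
  pca <- residual_pca(data, fit)
  misfit <- abs(fs$items$infit - 1) + abs(fs$items$outfit - 1)
  loading <- abs(pca$first_contrast[fs$items$item])
  ptme <- vapply(seq_along(fs$items$item), function(i) {
    x <- data$responses[, i]
    ok <- !is.na(x)
    if (stats::sd(x[ok]) == 0) return(0)
    stats::cor(x[ok], fit$theta[ok])
  }, numeric(1))
  ord <- order(-ptme, misfit, loading, seq_along(misfit))
  trace <- data.frame(item = fs$items$item, point_measure = ptme,
                      infit = fs$items$infit, outfit = fs$items$outfit,
                      misfit = misfit, first_contrast_loading = loading,
                      rank = order(ord))
  selection_result("rasch_regression", fs$items$item[ord[seq_len(k)]],
                   list(items = trace, fit = fit))
}

# logistic IRLS with optional ridge penalty (used when separation leaves the
# unpenalized likelihood without a maximum); returns coef, vcov, loglik
fit_logistic <- function(X, y, ridge = 0, max_iter = 100, tol = 1e-10) {
  X <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X)
  beta <- stats::setNames(rep(0, p), colnames(X))
  pen <- diag(c(0, rep(ridge, p - 1)), p)  # intercept unpenalized
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X, X * w) + 2 * pen
    g <- crossprod(X, y - mu) - 2 * pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  H <- crossprod(X, X * w) + 2 * pen
  list(coef = beta, vcov = solve(H),
       loglik = sum(y * eta - log1p(exp(eta))),
       fitted = mu, X = X, y = y,
       separated = any(mu < 1e-8 | mu > 1 - 1e-8) || any(abs(beta) > 15))
}

# log-likelihood of a logistic model at a fixed coefficient vector
loglik_at <- function(X, y, beta) {
  eta <- drop(cbind(1, X) %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

# Rao score test for adding column j to the current fit
score_test_add <- function(fit, xj) {
  r <- fit$y - fit$fitted
  w <- pmax(fit$fitted * (1 - fit$fitted), 1e-12)
  U <- sum(xj * r)
  Xw <- crossprod(fit$X, xj * w)
  V <- sum(xj^2 * w) - drop(t(Xw) %*% solve(crossprod(fit$X, fit$X * w), Xw))
  if (V < 1e-10) return(c(chi2 = NA_real_, p = NA_real_))
  chi2 <- U^2 / V
  c(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Forward stepwise logistic regression item selection
#'
#' Item scores enter as numeric covariates for a logistic model of the
#' diagnosis. Entry at each step is by the Rao score test (enter the
#' candidate with the smallest p-value below `p_enter`); after each entry,
#' included items are tested for removal (p above `p_remove`) by the chosen
#' criterion: `wald` (Wald chi-square), `lr` (likelihood ratio with refit),
#' or `conditional` (likelihood ratio evaluated at the current estimates with
#' the coefficient zeroed, no refit). Selection stops after `k` entries or
#' when no candidate passes. Under complete separation the model is refit
#' with a small ridge penalty (1e-4) and flagged in the trace.
#'
#' @param data a [response_matrix()].
#' @param diagnosis binary vector aligned with persons.
#' @param criterion removal criterion: `"wald"`, `"lr"`, or `"conditional"`.
#' @param k number of items to retain.
#' @param p_enter,p_remove entry and removal p-value thresholds (defaults
#'   0.05 / 0.10, the conventional stepwise defaults).
#' @return a `selection_result`; `trace$steps` records each step's statistic.
#' @export
select_stepwise_logistic <- function(data, diagnosis,
                                     criterion = c("wald", "lr", "conditional"),
                                     k = 3, p_enter = 0.05, p_remove = 0.10) {
  criterion <- match.arg(criterion)
  X <- data$responses
  y <- as.integer(diagnosis)
  keep <- stats::complete.cases(X, y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (length(unique(y)) < 2) stop_domain("diagnosis is constant")
  ids <- data$item_ids
  if (k > length(ids)) stop_domain("k exceeds the number of items")

  included <- character(0)
  steps <- list()
  ridge_used <- FALSE
  refit <- function(vars) {
    f <- fit_logistic(X[, vars, drop = FALSE], y)
    if (f$separated) {
      ridge_used <<- TRUE
      f <- fit_logistic(X[, vars, drop = FALSE], y, ridge = 1e-4)
    }
    f
  }
  fit <- refit(character(0))
  while (length(included) < k) {
    cand <- setdiff(ids, included)
    if (!length(cand)) break
    sc <- t(vapply(cand, function(j) score_test_add(fit, X[, j]), numeric(2)))
    best <- which.min(sc[, "p"])
    if (!length(best) || is.na(sc[best, "p"]) || sc[best, "p"] >= p_enter) break
    included <- c(included, cand[best])
    fit <- refit(included)
    steps[[length(steps) + 1]] <- data.frame(
      action = "enter", item = cand[best],
      statistic = sc[best, "chi2"], p = sc[best, "p"])
    # removal pass
    repeat {
      if (length(included) < 2) break
      rem <- vapply(included, function(j) {
        others <- setdiff(included, j)
        chi2 <- switch(criterion,
          wald = {
            b <- fit$coef[j]; v <- fit$vcov[j, j]; b^2 / v
          },
          lr = 2 * (fit$loglik - refit(others)$loglik),
          conditional = {
            b0 <- fit$coef; b0[j] <- 0
            2 * (fit$loglik - loglik_at(X[, included, drop = FALSE], y, b0))
          })
        stats::pchisq(max(chi2, 0), 1, lower.tail = FALSE)
      }, numeric(1))
      worst <- which.max(rem)
      if (rem[worst] <= p_remove) break
      steps[[length(steps) + 1]] <- data.frame(
        action = "remove", item = included[worst],
        statistic = NA_real_, p = rem[worst])
      included <- setdiff(included, included[worst])
      fit <- refit(included)
    }
  }
  selection_result(paste0("stepwise_logistic_", criterion), included,
                   list(steps = do.call(rbind, steps),
                        ridge_fallback = ridge_used,
                        final_coef = fit$coef))
}

# Wilks' lambda |W|/|T| for a variable set in a two-group design
wilks_lambda <- function(X, g) {
  if (!ncol(X)) return(1)
  Tm <- crossprod(scale(X, scale = FALSE))
  W <- Reduce(`+`, lapply(split(seq_len(nrow(X)), g), function(ix) {
    crossprod(scale(X[ix, , drop = FALSE], scale = FALSE))
  }))
  dT <- det(Tm)
  if (abs(dT) < 1e-10) return(NA_real_)  # singular: collinear candidate
  det(W) / dT
}

#' Stepwise discriminant function analysis item selection
#'
#' Classic Wilks'-lambda stepwise selection for a two-group linear
#' discriminant: at each step the candidate whose entry most reduces lambda
#' enters if its partial F exceeds `f_enter`; included items whose
#' F-to-remove falls below `f_remove` are removed. Candidates that would make
#' the total SSCP singular (duplicated or collinear items) are skipped and
#' noted. The first `k` entries are retained.
#'
#' @param data a [response_matrix()].
#' @param diagnosis binary vector aligned with persons.
#' @param k number of items to retain.
#' @param f_enter,f_remove F thresholds (defaults 3.84 / 2.71, the
#'   conventional stepwise DFA defaults).
#' @return a `selection_result`; `trace$steps` records lambda and F per step.
#' @export
select_stepwise_dfa <- function(data, diagnosis, k = 3,
                                f_enter = 3.84, f_remove = 2.71) {
  X <- data$responses
  y <- as.integer(diagnosis)
  keep <- stats::complete.cases(X, y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (length(unique(y)) < 2) stop_domain("diagnosis is constant")
  ids <- data$item_ids
  if (k > length(ids)) stop_domain("k exceeds the number of items")
  n <- nrow(X); g <- 2

  included <- character(0)
  steps <- list()
  lam_cur <- 1
  while (length(included) < k) {
    cand <- setdiff(ids, included)
    if (!length(cand)) break
    p <- length(included)
    f_stats <- vapply(cand, function(j) {
      lam_new <- wilks_lambda(X[, c(included, j), drop = FALSE], y)
      if (is.na(lam_new)) return(NA_real_)      # singular total SSCP: skip
      if (lam_new < 1e-12) return(Inf)          # perfect discrimination
      (n - g - p) / (g - 1) * (lam_cur / lam_new - 1)
    }, numeric(1))
    if (all(is.na(f_stats))) break
    best <- which.max(f_stats)
    if (is.na(f_stats[best]) || f_stats[best] < f_enter) break
    included <- c(included, cand[best])
    lam_cur <- wilks_lambda(X[, included, drop = FALSE], y)
    steps[[length(steps) + 1]] <- data.frame(
      action = "enter", item = cand[best], lambda = lam_cur,
      F = f_stats[best])
    # removal pass
    repeat {
      if (length(included) < 2) break
      p <- length(included)
      f_rem <- vapply(included, function(j) {
        lam_red <- wilks_lambda(X[, setdiff(included, j), drop = FALSE], y)
        (n - g - p + 1) / (g - 1) * (lam_red / lam_cur - 1)
      }, numeric(1))
      worst <- which.min(f_rem)
      if (f_rem[worst] >= f_remove) break
      steps[[length(steps) + 1]] <- data.frame(
        action = "remove", item = included[worst], lambda = lam_cur,
        F = f_rem[worst])
      included <- setdiff(included, included[worst])
      lam_cur <- wilks_lambda(X[, included, drop = FALSE], y)
    }
  }
  selection_result("stepwise_dfa", included,
                   list(steps = do.call(rbind, steps), final_lambda = lam_cur))
}
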