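#' Partial credit model category probabilities
#'
#' Probability of each response category 0..m for a person at `theta` on an
#' item with step thresholds `delta`, under Masters' partial credit
#' parameterization: P(X = k) is proportional to exp(sum_{j<=k} (theta -
#' delta_j)), with the empty sum for k = 0 equal to zero. With a single step
#' this reduces exactly to the dichotomous Rasch model.
#'
#' @param theta person measure (logits), scalar.
#' @param delta numeric vector of step thresholds (logits), length m.
#' @return probability vector of length m + 1 summing to 1.
#' @export
pcm_prob <- function(theta, delta) {
  if (!all(is.finite(theta)) || !all(is.finite(delta))) {
    stop_domain("theta and delta must be finite")
  }
  s <- c(0, cumsum(theta - delta))
  e <- exp(s - max(s))
  e / sum(e)
}

# n x (m+1) probability matrix for a vector of thetas on one item.
pcm_prob_matrix <- function(theta, delta) {
  m <- length(delta)
  s <- outer(theta, 0:m) - matrix(rep(c(0, cumsum(delta)), each = length(theta)),
                                  length(theta), m + 1)
  s <- s - apply(s, 1, max)
  e <- exp(s)
  e / rowSums(e)
}

#' Item information function
#'
#' Fisher information of a partial credit item at `theta`: the conditional
#' variance of the category score, `sum(k^2 P_k) - (sum(k P_k))^2`. It equals
#' the slope of the item's expected-score curve, dE[X|theta]/dtheta.
#'
#' @param theta person measure(s), logits; vectorized.
#' @param delta item step thresholds, logits.
#' @return information values (logit^-2), same length as `theta`.
#' @export
item_information <- function(theta, delta) {
  if (!all(is.finite(theta)) || !all(is.finite(delta))) {
    stop_domain("theta and delta must be finite")
  }
  p <- pcm_prob_matrix(theta, delta)
  k <- 0:length(delta)
  ex <- drop(p %*% k)
  ex2 <- drop(p %*% k^2)
  ex2 - ex^2
}

# Expected score E[X|theta] for one item, vectorized over theta.
pcm_expected <- function(theta, delta) {
  p <- pcm_prob_matrix(theta, delta)
  drop(p %*% (0:length(delta)))
}

#' Test information over a theta grid
#'
#' Sums item information functions over an item subset on a grid of person
#' measures and locates the grid point of maximum information.
#'
#' @param params a `pcm_parameters` object from [fit_jmle()], or a plain list
#'   with a `delta` element (list of per-item threshold vectors).
#' @param theta_grid strictly increasing grid of measures (logits); default
#'   -6..6 by 0.01, covering the instrument's effective range at a resolution
#'   below reporting precision.
#' @param items item ids or indices to include; default all.
#' @return list with `theta` (grid), `item_info` (grid x items matrix),
#'   `total` (summed curve), `theta_star` (grid argmax of `total`).
#' @export
test_information <- function(params, theta_grid = seq(-6, 6, by = 0.01),
                             items = NULL) {
  delta <- params$delta
  if (is.null(names(delta))) names(delta) <- paste0("item_", seq_along(delta))
  if (is.null(items)) items <- names(delta)
  if (is.numeric(items)) items <- names(delta)[items]
  if (length(items) == 0) stop_domain("item subset must be non-empty")
  if (!all(items %in% names(delta))) stop_domain("unknown item id in subset")
  if (any(diff(theta_grid) <= 0)) stop_domain("theta_grid must be strictly increasing")
  info <- vapply(items, function(i) item_information(theta_grid, delta[[i]]),
                 numeric(length(theta_grid)))
  info <- matrix(info, nrow = length(theta_grid),
                 dimnames = list(NULL, items))
  total <- rowSums(info)
  list(theta = theta_grid, item_info = info, total = total,
       theta_star = theta_grid[which.max(total)])
}

# Collapse categories never observed for an item so its steps stay estimable.
# Returns list(responses = recoded column, map = data.frame(old, new), m).
collapse_unobserved <- function(x, m) {
  observed <- sort(unique(x[!is.na(x)]))
  full <- 0:m
  if (length(observed) < 2) {
    return(list(x = x, map = data.frame(old = full, new = full), m = m,
                collapsed = FALSE, degenerate = TRUE))
  }
  if (identical(observed, full)) {
    return(list(x = x, map = data.frame(old = full, new = full), m = m,
                collapsed = FALSE, degenerate = FALSE))
  }
  # each observed category gets the next consecutive code; unobserved raw
  # codes inherit the code of the nearest lower observed category (adjacent
  # collapse), so ordering is preserved
  new <- integer(m + 1)
  code <- -1L
  last <- 0L
  for (k in full) {
    if (k %in% observed) code <- code + 1L
    new[k + 1] <- max(code, 0L)
  }
  list(x = new[x + 1], map = data.frame(old = full, new = new),
       m = max(new), collapsed = TRUE, degenerate = FALSE)
}

#' Fit the partial credit model by joint maximum likelihood
#'
#' Alternating per-parameter Newton-Raphson estimation of item step thresholds
#' and person measures. Persons listed in `anchors` keep their measures fixed
#' (bit-for-bit) throughout; when no anchors are given the scale is identified
#' by centering mean item location at zero. Persons or items with all-minimum
#' or all-maximum observed responses have no finite JMLE estimate; they are
#' excluded from estimation and assigned measures by a 0.3-score-unit
#' adjustment extrapolation afterwards. Categories never observed for an item
#' are collapsed into their lower neighbour for estimation and the mapping is
#' reported.
#'
#' @param data a [response_matrix()].
#' @param anchors optional named numeric vector of fixed person measures;
#'   names are person row indices (as character) or row names.
#' @param max_iter maximum outer iterations (default 200).
#' @param conv_score convergence tolerance on the largest absolute score
#'   residual (expected minus observed score), default 0.01.
#' @param conv_change convergence tolerance on the largest parameter change in
#'   logits, default 0.001.
#' @param bias_correction apply Wright's (L-1)/L dispersion correction to the
#'   jointly estimated scale (L = number of calibrated items). Joint
#'   estimation with a short test is known to over-disperse both person and
#'   item estimates (by roughly L/(L-1)); the correction rescales theta and
#'   delta together and is skipped when anchors pin the scale externally.
#'   Default TRUE.
#' @return object of class `pcm_parameters`: `delta` (list of per-item step
#'   thresholds on the collapsed scale), `theta` (person measures),
#'   `item_location` (mean threshold per item), `anchored_persons`,
#'   `extreme_persons`, `extreme_items`, `category_maps`, `converged`,
#'   `iterations`.
#' @export
fit_jmle <- function(data, anchors = NULL, max_iter = 200,
                     conv_score = 0.01, conv_change = 0.001,
                     bias_correction = TRUE) {
  stopifnot(inherits(data, "response_matrix"))
  X <- data$responses
  n <- nrow(X)
  I <- ncol(X)

  anchor_theta <- rep(NA_real_, n)
  if (!is.null(anchors)) {
    if (!all(is.finite(anchors))) stop_domain("anchor values must be finite")
    idx <- names(anchors)
    ridx <- if (!is.null(rownames(X)) && all(idx %in% rownames(X))) {
      match(idx, rownames(X))
    } else {
      as.integer(idx)
    }
    if (any(is.na(ridx)) || any(ridx < 1 | ridx > n)) {
      stop_domain("anchor names must identify person rows")
    }
    anchor_theta[ridx] <- anchors
  }
  anchored <- !is.na(anchor_theta)

  # collapse unobserved categories per item
  maps <- vector("list", I)
  m <- integer(I)
  for (i in seq_len(I)) {
    cl <- collapse_unobserved(X[, i], data$m[i])
    X[, i] <- cl$x
    maps[[i]] <- cl$map
    m[i] <- cl$m
  }
  names(maps) <- data$item_ids

  obs <- !is.na(X)
  person_score <- rowSums(X, na.rm = TRUE)
  person_max <- obs %*% m
  item_score <- colSums(X, na.rm = TRUE)
  item_max <- colSums(obs) * m

  extreme_person <- !anchored &
    (person_score == 0 | person_score == person_max) & rowSums(obs) > 0
  extreme_item <- item_score == 0 | item_score == item_max | m < 1
  est_p <- which(!extreme_person & rowSums(obs) > 0)
  est_i <- which(!extreme_item)
  if (length(est_i) == 0 || length(est_p) == 0) {
    stop_domain("all persons or all items are extreme; model inestimable")
  }
  if (all(anchored) == FALSE && length(est_p) < 2) {
    stop_domain("fewer than 2 estimable persons")
  }

  # initial values: log-odds of the proportion of the maximum score
  theta <- rep(0, n)
  theta[!anchored] <- log((person_score[!anchored] + 0.5) /
                          (pmax(person_max[!anchored] - person_score[!anchored], 0) + 0.5))
  theta[!is.finite(theta)] <- 0
  theta[anchored] <- anchor_theta[anchored]
  delta <- lapply(seq_len(I), function(i) rep(0, m[i]))
  names(delta) <- data$item_ids

  free_theta <- setdiff(est_p, which(anchored))
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    max_change <- 0
    # --- person updates ---
    if (length(free_theta)) {
      ex <- matrix(0, n, I)
      vx <- matrix(0, n, I)
      for (i in est_i) {
        p <- pcm_prob_matrix(theta, delta[[i]])
        k <- 0:m[i]
        e1 <- drop(p %*% k)
        ex[, i] <- e1
        vx[, i] <- drop(p %*% k^2) - e1^2
      }
      use <- obs
      use[, setdiff(seq_len(I), est_i)] <- FALSE
      sc <- rowSums((X - ex) * use, na.rm = TRUE)
      inf <- rowSums(vx * use)
      step <- sc / pmax(inf, 1e-8)
      step <- pmin(pmax(step, -1), 1)
      theta[free_theta] <- theta[free_theta] + step[free_theta]
      max_change <- max(max_change, max(abs(step[free_theta])))
    }
    # --- item step updates ---
    for (i in est_i) {
      rows <- which(obs[, i] & (seq_len(n) %in% est_p | anchored))
      if (!length(rows)) next
      x <- X[rows, i]
      for (j in seq_len(m[i])) {
        p <- pcm_prob_matrix(theta[rows], delta[[i]])
        pj <- rowSums(p[, (j + 1):(m[i] + 1), drop = FALSE])  # P(X >= j)
        score <- sum(pj) - sum(x >= j)
        d2 <- sum(pj * (1 - pj))
        step <- score / max(d2, 1e-8)
        step <- min(max(step, -1), 1)
        # score residual dLL/ddelta_j = sum(P(X>=j)) - count(x>=j): a positive
        # value means the model over-predicts reaching step j, so raise delta_j
        delta[[i]][j] <- delta[[i]][j] + step
        max_change <- max(max_change, abs(step))
      }
    }
    # --- recenter (identification) ---
    if (!any(anchored)) {
      cshift <- mean(vapply(delta[est_i], mean, numeric(1)))
      for (i in est_i) delta[[i]] <- delta[[i]] - cshift
      theta <- theta - cshift
    }
    # --- convergence check on score residuals ---
    max_resid <- 0
    ex <- matrix(0, n, I)
    for (i in est_i) ex[, i] <- pcm_expected(theta, delta[[i]])
    use <- obs
    use[, setdiff(seq_len(I), est_i)] <- FALSE
    if (length(free_theta)) {
      sc_p <- rowSums((X - ex) * use, na.rm = TRUE)
      max_resid <- max(max_resid, max(abs(sc_p[free_theta])))
    }
    for (i in est_i) {
      rows <- which(obs[, i] & (seq_len(n) %in% est_p | anchored))
      x <- X[rows, i]
      p <- pcm_prob_matrix(theta[rows], delta[[i]])
      for (j in seq_len(m[i])) {
        pj <- rowSums(p[, (j + 1):(m[i] + 1), drop = FALSE])
        max_resid <- max(max_resid, abs(sum(pj) - sum(x >= j)))
      }
    }
    if (max_resid < conv_score && max_change < conv_change) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }

  # --- dispersion correction (unanchored scale only) ---
  if (isTRUE(bias_correction) && !any(anchored) && length(est_i) > 1) {
    fac <- (length(est_i) - 1) / length(est_i)
    for (i in est_i) delta[[i]] <- delta[[i]] * fac
    theta <- theta * fac
  }

  # --- extreme person extrapolation: 0.3-score-unit adjustment ---
  if (any(extreme_person)) {
    for (nidx in which(extreme_person)) {
      items_n <- intersect(which(obs[nidx, ]), est_i)
      if (!length(items_n)) { theta[nidx] <- NA_real_; next }
      maxs <- sum(m[items_n])
      target <- if (person_score[nidx] == 0) 0.3 else maxs - 0.3
      f <- function(t) sum(vapply(items_n, function(i)
        pcm_expected(t, delta[[i]]), numeric(1))) - target
      theta[nidx] <- stats::uniroot(f, c(-15, 15), extendInt = "yes")$root
    }
    message(sprintf("assigned extrapolated measures to %d extreme person(s)",
                    sum(extreme_person)))
  }
  # --- extreme items: equal steps solving the adjusted score equation ---
  if (any(extreme_item)) {
    for (i in which(extreme_item)) {
      rows <- which(obs[, i])
      if (!length(rows) || m[i] < 1) { delta[[i]] <- rep(NA_real_, m[i]); next }
      target <- if (item_score[i] == 0) 0.3 else item_max[i] - 0.3
      f <- function(d) sum(pcm_expected(theta[rows], rep(d, m[i]))) - target
      d0 <- stats::uniroot(f, c(-15, 15), extendInt = "yes")$root
      delta[[i]] <- rep(d0, m[i])
    }
    message(sprintf("assigned extrapolated thresholds to %d extreme item(s)",
                    sum(extreme_item)))
  }

  if (any(anchored)) theta[anchored] <- anchor_theta[anchored]

  structure(list(
    delta = delta,
    theta = theta,
    item_location = vapply(delta, mean, numeric(1)),
    item_ids = data$item_ids,
    m = m,
    anchored_persons = which(anchored),
    extreme_persons = which(extreme_person),
    extreme_items = which(extreme_item),
    category_maps = maps,
    converged = converged,
    iterations = iter
  ), class = "pcm_parameters")
}

#' @export
print.pcm_parameters <- function(x, ...) {
  cat(sprintf("<pcm_parameters> %d items, %d persons; %s in %d iterations\n",
              length(x$delta), length(x$theta),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(data.frame(item = x$item_ids, location = round(x$item_location, 3)))
  invisible(x)
}

# expected scores and variances for all persons x items under fitted params;
# internal substrate for fit statistics and residuals
pcm_moments <- function(data, params) {
  X <- data$responses
  # re-apply category collapse used at fit time
  for (i in seq_along(params$category_maps)) {
    map <- params$category_maps[[i]]
    X[, i] <- map$new[X[, i] + 1]
  }
  n <- nrow(X); I <- ncol(X)
  E <- V <- matrix(NA_real_, n, I)
  for (i in seq_len(I)) {
    if (anyNA(params$delta[[i]])) next
    p <- pcm_prob_matrix(params$theta, params$delta[[i]])
    k <- 0:params$m[i]
    E[, i] <- drop(p %*% k)
    V[, i] <- drop(p %*% k^2) - E[, i]^2
  }
  list(X = X, E = E, V = V, obs = !is.na(X) & !is.na(E))
}

#' Rasch fit statistics (infit and outfit mean squares)
#'
#' Outfit is the unweighted mean of squared standardized residuals; infit is
#' the information-weighted version (sum of squared raw residuals over summed
#' model variance). Both have expectation 1 under the model. Observations with
#' (numerically) zero model variance are excluded and counted.
#'
#' @param data a [response_matrix()].
#' @param params the [fit_jmle()] fit for `data`.
#' @return list with data frames `items` (`item`, `infit`, `outfit`) and
#'   `persons` (`person`, `infit`, `outfit`), plus `n_excluded`.
#' @export
fit_statistics <- function(data, params) {
  mo <- pcm_moments(data, params)
  ok <- mo$obs & mo$V > 1e-10
  n_excluded <- sum(mo$obs & !ok)
  R <- (mo$X - mo$E)
  Z2 <- R^2 / mo$V
  Z2[!ok] <- NA; R2 <- R^2; R2[!ok] <- NA; V <- mo$V; V[!ok] <- NA
  items <- data.frame(
    item = data$item_ids,
    infit = colSums(R2, na.rm = TRUE) / colSums(V, na.rm = TRUE),
    outfit = colMeans(Z2, na.rm = TRUE),
    row.names = NULL
  )
  persons <- data.frame(
    person = seq_len(nrow(mo$X)),
    infit = rowSums(R2, na.rm = TRUE) / rowSums(V, na.rm = TRUE),
    outfit = rowMeans(Z2, na.rm = TRUE)
  )
  list(items = items, persons = persons, n_excluded = n_excluded)
}

#' Principal components analysis of standardized residuals
#'
#' Eigen-decomposition of the item-by-item correlation matrix of standardized
#' response residuals, the usual screen for a second dimension in Rasch
#' residuals: items loading together on the first contrast share structure
#' the model did not absorb.
#'
#' @param data a [response_matrix()].
#' @param params the [fit_jmle()] fit for `data`.
#' @return list with `eigenvalues` (descending; they sum to the number of
#'   items), `loadings` (items x components, scaled by sqrt eigenvalue),
#'   `first_contrast` (named loadings on the first component).
#' @export
residual_pca <- function(data, params) {
  if (nrow(data$responses) < ncol(data$responses)) {
    stop_domain("need at least as many persons as items")
  }
  mo <- pcm_moments(data, params)
  Z <- (mo$X - mo$E) / sqrt(mo$V)
  Z[!mo$obs | mo$V <= 1e-10] <- NA
  C <- stats::cor(Z, use = "pairwise.complete.obs")
  C[is.na(C)] <- 0; diag(C) <- 1
  eg <- eigen(C, symmetric = TRUE)
  loadings <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  rownames(loadings) <- data$item_ids
  first <- loadings[, 1]
  names(first) <- data$item_ids
  list(eigenvalues = eg$values, loadings = loadings, first_contrast = first)
}
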