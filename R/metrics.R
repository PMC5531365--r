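#' Build a 2x2 confusion table from summary counts
#'
#' Reconstructs the confusion table implied by the counts a validation report
#' typically prints: the analyzed total, the number of diagnosed positives,
#' the number of positives screening positive, and the number of negatives
#' screening negative. Rows are truth (diagnosis), columns the screen.
#'
#' @param n analyzed total.
#' @param n_pos diagnosed positives.
#' @param pos_screen_pos diagnosed positives at/above the screen cut.
#' @param neg_screen_neg diagnosed negatives below the cut.
#' @return object of class `confusion_table` with fields `tp`, `fn`, `fp`,
#'   `tn`, `n`.
#' @export
table_from_counts <- function(n, n_pos, pos_screen_pos, neg_screen_neg) {
  tp <- pos_screen_pos
  fn <- n_pos - tp
  tn <- neg_screen_neg
  fp <- n - n_pos - tn
  confusion_table(tp, fn, fp, tn)
}

#' Construct a confusion table from its four cells
#'
#' @param tp,fn,fp,tn non-negative counts; truth in rows, screen in columns.
#' @return a `confusion_table`.
#' @export
confusion_table <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0)) {
    stop_domain("inconsistent counts: negative cell(s) ",
                paste(names(cells)[cells < 0], collapse = ", "))
  }
  n <- sum(cells)
  if (n <= 0) stop_domain("empty table")
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn, n = n),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("pos", "neg"),
                              screen = c("pos", "neg")))
  print(m)
  invisible(x)
}

#' Sensitivity and specificity of a confusion table
#'
#' Sensitivity is the percent of diagnosed positives the screen classifies
#' positive; specificity the percent of negatives classified negative.
#'
#' @param t a `confusion_table`.
#' @return named vector `c(se, sp)` in percent.
#' @export
sensitivity_specificity <- function(t) {
  if ((t$tp + t$fn) == 0 || (t$tn + t$fp) == 0) {
    stop_domain("sensitivity/specificity undefined: empty truth margin")
  }
  c(se = 100 * t$tp / (t$tp + t$fn),
    sp = 100 * t$tn / (t$tn + t$fp))
}

#' Cohen's kappa for a 2x2 table
#'
#' Unweighted kappa, (Po - Pe)/(1 - Pe), with chance agreement from the
#' marginal products.
#'
#' @param t a `confusion_table`.
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(t) {
  n <- t$n
  po <- (t$tp + t$tn) / n
  pe <- ((t$tp + t$fn) * (t$tp + t$fp) + (t$fp + t$tn) * (t$fn + t$tn)) / n^2
  if (abs(1 - pe) < 1e-12) stop_domain("kappa undefined: degenerate margins")
  (po - pe) / (1 - pe)
}

#' Pearson chi-square for a 2x2 table
#'
#' The uncorrected Pearson statistic `n (tp*tn - fn*fp)^2 / (r1 r2 c1 c2)`,
#' referred to the chi-square distribution with one degree of freedom.
#'
#' @param t a `confusion_table`.
#' @return list with `chi2`, `df` (1) and `p`.
#' @export
pearson_chi2 <- function(t) {
  r1 <- t$tp + t$fn; r2 <- t$fp + t$tn
  c1 <- t$tp + t$fp; c2 <- t$fn + t$tn
  if (any(c(r1, r2, c1, c2) == 0)) stop_domain("chi-square undefined: zero margin")
  chi2 <- t$n * (t$tp * t$tn - t$fn * t$fp)^2 / (r1 * r2 * c1 * c2)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Percent agreement
#'
#' For a confusion table, the percent of concordant classifications
#' `100 (tp + tn)/n`. For two classification vectors, the percent of equal
#' entries; with `subset` given, agreement is computed within that subgroup
#' only (the "x% of screen positives were also ..." style of statement).
#'
#' @param t a `confusion_table`, or a logical/0-1 vector of classifications.
#' @param other second classification vector when `t` is a vector.
#' @param subset optional logical vector restricting the comparison.
#' @return percent agreement in `[0, 100]`.
#' @export
percent_agreement <- function(t, other = NULL, subset = NULL) {
  if (inherits(t, "confusion_table")) {
    return(100 * (t$tp + t$tn) / t$n)
  }
  a <- as.integer(t); b <- as.integer(other)
  if (length(a) != length(b)) stop_domain("classification vectors differ in length")
  keep <- stats::complete.cases(a, b)
  if (!is.null(subset)) keep <- keep & subset
  if (!sum(keep)) stop_domain("empty subgroup")
  100 * sum(a[keep] == b[keep]) / sum(keep)
}

#' ROC analysis with Youden-optimal cut point
#'
#' Empirical ROC for an integer (or otherwise discrete) score against a
#' binary criterion, with the screen-positive convention `score >= cut`.
#' Candidate cuts are every distinct observed score plus a sentinel above the
#' maximum (at which nobody screens positive). AUC is the trapezoidal area
#' under the empirical curve, which equals the Mann-Whitney two-sample rank
#' statistic with ties counted one half. The optimal cut maximizes Youden's
#' J = se + sp - 100; ties go to the lowest cut (favouring sensitivity, as a
#' screen should). The 95% AUC interval uses the Hanley-McNeil standard
#' error.
#'
#' @param scores numeric scores, higher = more severe.
#' @param labels binary criterion (0/1 or logical), 1 = diagnosed positive.
#' @return object of class `roc_result`: data frame `curve` (`cut`, `se`,
#'   `sp`), `auc`, `auc_ci`, `optimal_cut`, `youden_j`, and the `n_pos`,
#'   `n_neg` used.
#' @export
roc_analysis <- function(scores, labels) {
  keep <- stats::complete.cases(scores, labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  if (!all(labels %in% 0:1)) stop_domain("labels must be binary 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_domain("both classes must be present")
  cuts <- sort(unique(scores))
  cuts <- c(cuts, max(cuts) + 1)
  se <- vapply(cuts, function(cc) 100 * sum(scores >= cc & labels == 1) / n1,
               numeric(1))
  sp <- vapply(cuts, function(cc) 100 * sum(scores < cc & labels == 0) / n0,
               numeric(1))
  # trapezoid over (FPR, TPR), cuts ascending -> FPR descending
  fpr <- (100 - sp) / 100; tpr <- se / 100
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (utils::head(tpr[ord], -1) + utils::tail(tpr[ord], -1)) / 2)
  j <- se + sp - 100
  opt <- which(j == max(j))[1]  # cuts ascending, first max = lowest cut
  # Hanley-McNeil SE
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  se_auc <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                  (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  ci <- pmin(pmax(auc + c(-1, 1) * 1.959964 * se_auc, 0), 1)
  structure(list(curve = data.frame(cut = cuts, se = se, sp = sp),
                 auc = auc, auc_ci = ci,
                 optimal_cut = cuts[opt], youden_j = j[opt],
                 n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f); optimal cut %g (J = %.2f)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$optimal_cut, x$youden_j))
  invisible(x)
}

#' Cronbach's alpha
#'
#' Internal consistency `k/(k-1) (1 - sum(var_i)/var_total)` with unbiased
#' variances. Rows with any missing item are dropped first (listwise
#' deletion) and the number dropped is reported as an attribute.
#'
#' @param items persons x items score matrix or data frame.
#' @return alpha, with attribute `n_dropped`.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) < 2) stop_domain("alpha needs at least 2 items")
  cc <- stats::complete.cases(items)
  n_dropped <- sum(!cc)
  items <- items[cc, , drop = FALSE]
  if (nrow(items) < 2) stop_domain("alpha needs at least 2 complete persons")
  total_var <- stats::var(rowSums(items))
  if (total_var < 1e-12) stop_domain("alpha undefined: zero total-score variance")
  k <- ncol(items)
  a <- k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / total_var)
  attr(a, "n_dropped") <- n_dropped
  a
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties get average ranks).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop_domain("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop_domain("rho undefined for constant vector")
  stats::cor(x, y, method = "spearman")
}

#' One-way ANOVA with eta-squared
#'
#' Standard between/within decomposition via [stats::aov()], plus the effect
#' size eta^2 = SSB/SST and per-group descriptives.
#'
#' @param values numeric outcome.
#' @param groups factor (or coercible) of group membership.
#' @return list with `F`, `df` (numerator, denominator), `p`, `eta2`, and a
#'   `groups` data frame (`group`, `n`, `mean`, `sd`).
#' @export
oneway_anova_eta2 <- function(values, groups) {
  keep <- stats::complete.cases(values, groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2) stop_domain("need at least 2 groups")
  if (stats::var(values) < 1e-12) stop_domain("F undefined: all values identical")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  ssb <- tab[1, "Sum Sq"]; ssw <- tab[2, "Sum Sq"]
  desc <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
  list(F = tab[1, "F value"], df = c(tab[1, "Df"], tab[2, "Df"]),
       p = tab[1, "Pr(>F)"], eta2 = ssb / (ssb + ssw), groups = desc)
}
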