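# Orchestration: load or generate cohorts, run the full validation sequence
# (descriptives, full-form ROC and agreement, item selection, short-form ROC
# and agreement, construct validity), and render a report.

#' Write a cohort to CSV in the pipeline's input schema
#'
#' Columns `item_1..item_8` (raw instrument codes), `dsm_positive`,
#' `symptom_count`; missing cells are written empty. Generated cohorts
#' round-trip through [read_cohort()].
#'
#' @param cohort a `synthetic_cohort` or a data frame with those columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (inherits(cohort, "synthetic_cohort")) cohort <- cohort$data
  cols <- c(paste0("item_", 1:8),
            intersect(c("dsm_positive", "symptom_count"), names(cohort)))
  utils::write.csv(cohort[cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort CSV
#'
#' Validates the schema (columns `item_1..item_8`, optional `dsm_positive`
#' and `symptom_count`), checks every raw code against the per-item maps, and
#' reports violations with row numbers. Empty cells become missing responses:
#' the person is retained for calibration but drops out of total-score
#' analyses.
#'
#' @param path CSV path.
#' @param maps raw-code maps, default [cudit_raw_maps()].
#' @return list with `responses` (a [response_matrix()] on the category
#'   scale), `raw` (data frame of raw codes), `dsm_positive`,
#'   `symptom_count` (NULL when absent), `n`, `load_log` (character).
#' @export
read_cohort <- function(path, maps = cudit_raw_maps()) {
  raw <- utils::read.csv(path, na.strings = c("", "NA"))
  item_cols <- names(maps)
  missing_cols <- setdiff(item_cols, names(raw))
  if (length(missing_cols)) {
    stop_domain("missing item columns: ", paste(missing_cols, collapse = ", "))
  }
  known <- c(item_cols, "dsm_positive", "symptom_count", "severity", "theta_true")
  unknown <- setdiff(names(raw), known)
  errors <- character(0)
  if (length(unknown)) {
    errors <- c(errors, paste("unknown column(s):", paste(unknown, collapse = ", ")))
  }
  for (j in item_cols) {
    x <- raw[[j]]
    if (!is.numeric(x)) {
      errors <- c(errors, sprintf("%s: non-numeric responses", j)); next
    }
    bad <- which(!is.na(x) & (x != floor(x) | !(x %in% maps[[j]]$raw)))
    if (length(bad)) {
      errors <- c(errors, sprintf("%s: invalid code(s) in row(s) %s (allowed: %s)",
                                  j, paste(utils::head(bad, 10), collapse = ", "),
                                  paste(maps[[j]]$raw, collapse = "/")))
    }
  }
  if ("dsm_positive" %in% names(raw)) {
    bad <- which(!is.na(raw$dsm_positive) & !(raw$dsm_positive %in% 0:1))
    if (length(bad)) {
      errors <- c(errors, sprintf("dsm_positive: non-binary value(s) in row(s) %s",
                                  paste(utils::head(bad, 10), collapse = ", ")))
    }
  }
  if (length(errors)) stop_domain(paste(errors, collapse = "\n"))
  responses <- raw_to_matrix(raw[item_cols], maps)
  n_incomplete <- sum(!stats::complete.cases(raw[item_cols]))
  list(responses = responses, raw = raw[item_cols],
       dsm_positive = raw$dsm_positive, symptom_count = raw$symptom_count,
       severity = raw$severity, n = nrow(raw),
       load_log = sprintf("loaded %d persons (%d with incomplete responses)",
                          nrow(raw), n_incomplete))
}

#' Study configuration
#'
#' @param cohorts named list of inputs: `synthetic_cohort` objects, CSV
#'   paths, or lists as returned by [read_cohort()].
#' @param cut_full full-form positivity cut (default 13, the published
#'   DSM-IV-derived recommendation).
#' @param cut_sf short-form positivity cut (default 2).
#' @param k short-form size (default 3).
#' @param methods selection methods to run.
#' @param logistic_criterion removal criterion for the stepwise logistic
#'   method.
#' @param drop_item1_zero drop persons answering 0 to item 1 (reported no
#'   use) from agreement/ROC analyses.
#' @param seed seed recorded in the report (generation happens upstream; the
#'   analyses themselves are deterministic).
#' @return object of class `study_config`.
#' @export
study_config <- function(cohorts, cut_full = 13, cut_sf = 2, k = 3,
                         methods = c("rasch_regression", "tcc",
                                     "stepwise_logistic", "stepwise_dfa"),
                         logistic_criterion = "wald",
                         drop_item1_zero = TRUE, seed = NULL) {
  assert_that(length(cohorts) >= 1, "at least one cohort required")
  assert_that(cut_full >= 1 && cut_sf >= 1, "cuts must be positive")
  if (is.null(names(cohorts))) {
    names(cohorts) <- paste0("sample_", seq_along(cohorts))
  }
  structure(list(cohorts = cohorts, cut_full = cut_full, cut_sf = cut_sf,
                 k = k, methods = methods,
                 logistic_criterion = logistic_criterion,
                 drop_item1_zero = drop_item1_zero, seed = seed),
            class = "study_config")
}

coerce_cohort <- function(x) {
  if (inherits(x, "synthetic_cohort")) {
    list(responses = x$responses, raw = x$data[paste0("item_", 1:8)],
         dsm_positive = x$data$dsm_positive,
         symptom_count = x$data$symptom_count,
         severity = x$data$severity, n = nrow(x$data),
         load_log = sprintf("synthetic cohort %s (seed %s)", x$spec$label,
                            format(x$seed)))
  } else if (is.character(x)) {
    read_cohort(x)
  } else if (is.list(x) && !is.null(x$responses)) {
    x
  } else {
    stop_domain("cannot interpret cohort input")
  }
}

agreement_block <- function(truth, screen) {
  keep <- stats::complete.cases(truth, screen)
  tab <- confusion_table(tp = sum(truth == 1 & screen == 1, na.rm = TRUE),
                         fn = sum(truth == 1 & screen == 0, na.rm = TRUE),
                         fp = sum(truth == 0 & screen == 1, na.rm = TRUE),
                         tn = sum(truth == 0 & screen == 0, na.rm = TRUE))
  chi <- tryCatch(pearson_chi2(tab), error = function(e) list(chi2 = NA, df = 1L, p = NA))
  list(table = tab,
       kappa = tryCatch(cohens_kappa(tab), error = function(e) NA_real_),
       percent_agreement = percent_agreement(tab),
       chi2 = chi$chi2, chi2_df = chi$df, chi2_p = chi$p,
       n = sum(keep))
}

#' Run the full short-form construction and validation study
#'
#' For each cohort, in order: exclusion bookkeeping (persons without a
#' complete full-form total, and optionally item-1 zero responders, leave the
#' agreement/ROC analyses but stay in the descriptives), descriptive
#' statistics and Cronbach's alpha, full-form ROC with the standard and the
#' Youden-optimal alternative cut, partial credit calibration, every
#' requested item-selection method, short-form ROC and agreement (against
#' the diagnosis and against the full form), Spearman correlations, and --
#' where a severity column exists -- a one-way ANOVA of short-form score by
#' severity category. Deterministic given the config.
#'
#' @param config a [study_config()].
#' @return object of class `study_report` (nested list; see
#'   [render_report()]).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  samples <- lapply(names(config$cohorts), function(nm) {
    co <- coerce_cohort(config$cohorts[[nm]])
    scores <- score_cudit(co$raw, sf_cut = config$cut_sf)
    n_in <- co$n

    analyzed <- !is.na(scores$total)
    n_missing <- sum(!analyzed)
    n_item1_zero <- 0L
    if (isTRUE(config$drop_item1_zero)) {
      i1z <- !is.na(co$raw$item_1) & co$raw$item_1 == 0
      n_item1_zero <- sum(i1z & analyzed)
      analyzed <- analyzed & !i1z
    }
    if (!is.null(co$dsm_positive)) analyzed <- analyzed & !is.na(co$dsm_positive)
    stopifnot(n_in - sum(!analyzed) == sum(analyzed))  # exclusion accounting

    endorsement <- vapply(co$raw, function(x) 100 * mean(x >= 1, na.rm = TRUE),
                          numeric(1))
    descriptives <- list(
      n = n_in,
      n_analyzed = sum(analyzed),
      n_excluded_missing = n_missing,
      n_excluded_item1_zero = n_item1_zero,
      prevalence = if (!is.null(co$dsm_positive))
        100 * mean(co$dsm_positive, na.rm = TRUE) else NA_real_,
      mean_total = mean(scores$total, na.rm = TRUE),
      sd_total = stats::sd(scores$total, na.rm = TRUE),
      alpha = tryCatch(as.numeric(cronbach_alpha(co$raw)),
                       error = function(e) NA_real_),
      endorsement = endorsement
    )

    dsm <- co$dsm_positive
    rows <- list()
    agreement <- list()
    construct <- list()
    selections <- list()
    sf_final <- NULL

    if (!is.null(dsm) && sum(analyzed) > 0 &&
        length(unique(dsm[analyzed])) == 2) {
      tot_a <- scores$total[analyzed]; dsm_a <- dsm[analyzed]
      roc_full <- roc_analysis(tot_a, dsm_a)
      cut_row <- function(label, roc, cut, items = NA) {
        i <- match(cut, roc$curve$cut)
        data.frame(configuration = label, cut = cut,
                   items = paste(items, collapse = ","),
                   sensitivity = roc$curve$se[i], specificity = roc$curve$sp[i],
                   auc = roc$auc, ci_lo = roc$auc_ci[1], ci_hi = roc$auc_ci[2])
      }
      rows$full_standard <- cut_row("full form, standard cut", roc_full,
                                    config$cut_full, "1-8")
      rows$full_alternative <- cut_row("full form, alternative cut", roc_full,
                                       roc_full$optimal_cut, "1-8")
      agreement$full_vs_dsm <- agreement_block(dsm_a,
                                               as.integer(tot_a >= config$cut_full))

      # calibration on all persons (missing responses allowed)
      pcm <- fit_jmle(co$responses)

      for (meth in config$methods) {
        sel <- switch(meth,
          tcc = select_tcc(pcm, config$k),
          rasch_regression = select_rasch_regression(co$responses, dsm,
                                                     config$k),
          stepwise_logistic = select_stepwise_logistic(
            co$responses, dsm, criterion = config$logistic_criterion,
            k = config$k),
          stepwise_dfa = select_stepwise_dfa(co$responses, dsm, k = config$k),
          stop_domain("unknown selection method: ", meth)
        )
        selections[[meth]] <- sel
        items_idx <- match(sel$items, paste0("item_", 1:8))
        sf <- score_cudit(co$raw, sf_items = items_idx, sf_cut = config$cut_sf)
        sf_a <- sf$sf_total[analyzed]
        ok <- !is.na(sf_a)
        roc_sf <- roc_analysis(sf_a[ok], dsm_a[ok])
        rows[[meth]] <- cut_row(meth, roc_sf, roc_sf$optimal_cut, items_idx)
        if (meth == "tcc") sf_final <- sf
      }

      # construct validity for the final short form (information-matching
      # items; falls back to the first method run)
      if (is.null(sf_final) && length(selections)) {
        first <- selections[[1]]
        sf_final <- score_cudit(co$raw,
                                sf_items = match(first$items, paste0("item_", 1:8)),
                                sf_cut = config$cut_sf)
      }
      if (!is.null(sf_final)) {
        sfa <- sf_final[analyzed, ]
        ok <- !is.na(sfa$sf_total)
        agreement$sf_vs_dsm <- agreement_block(dsm_a[ok], sfa$sf_positive[ok])
        agreement$sf_vs_full <- agreement_block(
          as.integer(tot_a[ok] >= config$cut_full), sfa$sf_positive[ok])
        pos_full <- tot_a[ok] >= config$cut_full
        agreement$sf_among_full_pos <- if (any(pos_full))
          100 * mean(sfa$sf_positive[ok][pos_full] == 1) else NA_real_
        construct$spearman_sf_full <- spearman_rho(sfa$sf_total[ok], tot_a[ok])
        if (!is.null(co$symptom_count)) {
          construct$spearman_sf_symptoms <-
            spearman_rho(sfa$sf_total[ok], co$symptom_count[analyzed][ok])
        }
        if (!is.null(co$severity)) {
          construct$anova_by_severity <- tryCatch(
            oneway_anova_eta2(sf_final$sf_total, co$severity),
            error = function(e) NULL)
        }
      }
    }

    list(name = nm, load_log = co$load_log, descriptives = descriptives,
         selections = selections,
         roc_table = if (length(rows)) do.call(rbind, rows) else NULL,
         agreement = agreement, construct = construct)
  })
  names(samples) <- names(config$cohorts)
  structure(list(config = config[c("cut_full", "cut_sf", "k", "methods",
                                   "logistic_criterion", "drop_item1_zero",
                                   "seed")],
                 samples = samples),
            class = "study_report")
}

#' Render a study report
#'
#' `format = "json"` serializes the full report; `format = "markdown"`
#' renders the tables with all statistics at 2 decimals, including the
#' footnote that the Pearson statistic for a 2x2 table is referred to 1
#' degree of freedom. Rendering is deterministic.
#'
#' @param report a `study_report`.
#' @param format `"json"` or `"markdown"`.
#' @return a single character string.
#' @export
render_report <- function(report, format = c("json", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(strip_report(report), auto_unbox = TRUE,
                                         digits = NA, null = "null")))
  }
  out <- c("# Short-form construction and validation report", "")
  for (s in report$samples) {
    d <- s$descriptives
    out <- c(out, sprintf("## %s", s$name), "",
             sprintf("- persons: %d (analyzed %d; excluded %d incomplete, %d item-1 zero)",
                     d$n, d$n_analyzed, d$n_excluded_missing, d$n_excluded_item1_zero),
             sprintf("- diagnosis prevalence: %s%%", fmt2(d$prevalence)),
             sprintf("- full-form total: mean %s (SD %s); alpha %s",
                     fmt2(d$mean_total), fmt2(d$sd_total), fmt2(d$alpha)), "")
    if (!is.null(s$roc_table)) {
      out <- c(out, "| Configuration | Cut | Items | Sensitivity | Specificity | AUC | CI |",
               "|---|---|---|---|---|---|---|")
      for (i in seq_len(nrow(s$roc_table))) {
        r <- s$roc_table[i, ]
        out <- c(out, sprintf("| %s | %g | %s | %s | %s | %s | %s-%s |",
                              r$configuration, r$cut, r$items,
                              fmt2(r$sensitivity), fmt2(r$specificity),
                              fmt2(r$auc), fmt2(r$ci_lo), fmt2(r$ci_hi)))
      }
      out <- c(out, "")
    }
    if (length(s$agreement)) {
      out <- c(out, "| Comparison | kappa | % agreement | chi2 (df=1) |", "|---|---|---|---|")
      for (nm in intersect(c("full_vs_dsm", "sf_vs_dsm", "sf_vs_full"),
                           names(s$agreement))) {
        a <- s$agreement[[nm]]
        out <- c(out, sprintf("| %s | %s | %s | %s |", nm, fmt2(a$kappa),
                              fmt2(a$percent_agreement), fmt2(a$chi2)))
      }
      out <- c(out, "")
    }
    if (length(s$construct)) {
      if (!is.null(s$construct$spearman_sf_full))
        out <- c(out, sprintf("- Spearman(short form, full form) = %s",
                              fmt2(s$construct$spearman_sf_full)))
      if (!is.null(s$construct$spearman_sf_symptoms))
        out <- c(out, sprintf("- Spearman(short form, symptom count) = %s",
                              fmt2(s$construct$spearman_sf_symptoms)))
      a <- s$construct$anova_by_severity
      if (!is.null(a))
        out <- c(out, sprintf("- ANOVA by severity: F(%d, %d) = %s, eta2 = %s",
                              a$df[1], a$df[2], fmt2(a$F), fmt2(a$eta2)))
      out <- c(out, "")
    }
  }
  out <- c(out,
           "Note: Pearson chi-square for a 2x2 table is referred to 1 degree of",
           "freedom (some published tables print df = 2 for the same statistic).",
           "'Test characteristic curve' labels the summed statistical information",
           "curve, conventionally the test information function.")
  paste(out, collapse = "\n")
}

# drop classes and non-serializable internals (fitted pcm objects inside
# traces) before JSON rendering
strip_report <- function(report) {
  rep <- unclass(report)
  rep$samples <- lapply(rep$samples, function(s) {
    s$selections <- lapply(s$selections, function(sel) {
      list(method = sel$method, items = sel$items)
    })
    s$agreement <- lapply(s$agreement, function(a) {
      if (is.list(a) && !is.null(a$table)) a$table <- unclass(a$table)
      a
    })
    s
  })
  rep
}
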