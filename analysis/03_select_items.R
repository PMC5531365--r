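#!/usr/bin/env Rscript
# Run all four item-selection methods on each cohort and record which 3-item
# short forms they nominate, with each method's selection trace.

library(shortscreen)

out <- list()
for (nm in c("sample1_like", "sample2_like")) {
  co <- read_cohort(file.path("results", paste0(nm, ".csv")))
  fit <- fit_jmle(co$responses)
  dx <- co$dsm_positive

  sels <- list(
    rasch_regression = select_rasch_regression(co$responses, dx, k = 3),
    tcc = select_tcc(fit, 3),
    logistic_wald = select_stepwise_logistic(co$responses, dx, "wald", k = 3),
    logistic_lr = select_stepwise_logistic(co$responses, dx, "lr", k = 3),
    logistic_conditional = select_stepwise_logistic(co$responses, dx,
                                                    "conditional", k = 3),
    dfa = select_stepwise_dfa(co$responses, dx, k = 3)
  )
  cat(nm, "\n")
  for (m in names(sels)) {
    cat(sprintf("  %-22s -> %s\n", m, paste(sels[[m]]$items, collapse = ", ")))
  }
  out[[nm]] <- lapply(sels, function(s) list(method = s$method, items = s$items))
}
jsonlite::write_json(out, "results/selected_items.json", auto_unbox = TRUE)
cat("wrote results/selected_items.json\n")
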