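## Shared replicated study of the calibrated two-site preset, computed once
## and reused by the acceptance checks (ICC recovery and model selection
## draw on the same replicate fits).
.study_cache <- new.env(parent = emptyenv())

preset_replicate_study <- function(n_rep = 100) {
  key <- paste0("study", n_rep)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  out <- matrix(NA_real_, n_rep, 7,
                dimnames = list(NULL, c("icc_household", "icc_interviewer",
                                        "icc_site", "beta0", "aic3", "aic0",
                                        "converged")))
  spec3 <- model_spec(tol = 1e-6)
  for (r in seq_len(n_rep)) {
    cfg <- preset_survey_config(seed = 140000 + r)
    d <- generate_population(cfg)$data
    f3 <- fit_glmm(d, spec3)
    f0 <- fit_intercept_only(d)
    out[r, ] <- c(icc(f3$varcomps, "household"),
                  icc(f3$varcomps, "interviewer"),
                  icc(f3$varcomps, "site"),
                  f3$beta0_hat, f3$aic, f0$aic, as.numeric(f3$converged))
  }
  .study_cache[[key]] <- out
  out
}
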