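## Small-footprint study configuration for unit tests; full-size defaults are
## exercised in test-acceptance.R.
small_config <- function(seed = 1L, ...) {
  base <- list(n_mrna = 400L, n_lncrna = 120L, n_rrna = 3L,
               depth = 2e6, n_cells = 60L, frac_periodic = 0.15, seed = seed)
  override <- list(...)
  base[names(override)] <- override
  do.call(sim_config, base)
}

## every stochastic knob off: measurements become deterministic functions of
## the truth (Poisson counting replaced by its expectation)
zero_noise_config <- function(seed = 1L, ...) {
  base <- list(seed = seed, seq_noise_cv = 0, poisson_counts = FALSE,
               ncounter_cv = 0, ms_response_cv = 0, ms_replicate_cv = 0,
               ms_detection_scale = 0, q_jitter_sdlog = 0)
  override <- list(...)
  base[names(override)] <- override
  do.call(small_config, base)
}

## independent hypergeometric upper-tail by explicit binomial coefficients
hyper_tail_oracle <- function(k, K, N, n) {
  kk <- seq(k, min(n, K))
  kk <- kk[kk >= max(0, n - (N - K))]
  if (length(kk) == 0) return(0)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

## minimal expression table constructor for toy examples
make_expression <- function(ids, copies, detected = !is.na(copies)) {
  out <- tibble::tibble(id = ids, copies = copies, detected = detected)
  class(out) <- c("expression_table", class(out))
  out
}

## run the RNA arm of the pipeline on synthetic data; returns estimated
## expression and the matching truth
run_rna_pipeline <- function(cfg, condition = "proliferating") {
  catalog <- generate_catalog(cfg)
  truth <- generate_truth(catalog, cfg)
  rc <- generate_readcounts(truth, catalog, cfg, condition = condition)
  sim <- generate_readcounts(truth, catalog, cfg, type = "simulated")
  corrected <- apply_correction(rc, mappability_factors(sim))
  anchors <- calibrate_spikes(generate_ncounter(truth, cfg, condition = condition))
  ## anchors that happen to draw zero reads are legitimately excluded
  model <- suppressWarnings(fit_anchor_model(corrected, anchors))
  expr <- predict_copies(model, corrected, condition = condition)
  list(catalog = catalog, truth = truth, corrected = corrected,
       anchors = anchors, model = model, expression = expr)
}

## median fold error of estimates against the truth
median_fold_error <- function(expression, truth_copies) {
  est <- expression$copies[expression$detected]
  names(est) <- expression$id[expression$detected]
  tr <- truth_copies[names(est)]
  keep <- !is.na(tr) & tr > 0 & est > 0
  median(exp(abs(log(est[keep] / tr[keep]))))
}
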