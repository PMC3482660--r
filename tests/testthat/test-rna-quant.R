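test_that("RPK scores follow the reads-per-kilobase definition", {
  expect_equal(compute_rpk(1000, 2000), 500)
  expect_equal(compute_rpk(0, 12345), 0)
  expect_equal(compute_rpk(100, 500), 200)
  expect_error(compute_rpk(10, 0), "length")
  expect_error(compute_rpk(-1, 100), "reads")
})

toy_counts <- function(reads, length_nt = rep(1000L, length(reads)),
                       ids = sprintf("g%02d", seq_along(reads))) {
  out <- tibble::tibble(id = ids, reads = reads, length_nt = length_nt)
  class(out) <- c("read_count_table", class(out))
  out
}

test_that("mappability factors are median-centred with unquantifiable flags", {
  uniform <- toy_counts(rep(500, 7))
  f <- mappability_factors(uniform)
  expect_equal(f$factor, rep(1, 7))

  ## one feature at half the simulated RPK of the others: factor 0.5
  half <- toy_counts(c(100, 200, 200, 200, 200))
  fh <- mappability_factors(half)
  expect_equal(fh$factor[1], 0.5)
  expect_equal(median(fh$factor), 1)

  ## absent from simulated reads -> unquantifiable
  gap <- mappability_factors(toy_counts(c(0, 100, 100)))
  expect_true(gap$unquantifiable[1])
  expect_true(is.na(gap$factor[1]))
  expect_error(mappability_factors(toy_counts(numeric(0))), "empty")
})

test_that("correction divides by the factor and drops missing features", {
  rpk <- tibble::tibble(id = c("a", "b", "c"), score = c(100, 100, 0))
  factors <- tibble::tibble(id = c("a", "b", "c"),
                            factor = c(1, 0.5, 1),
                            unquantifiable = c(FALSE, FALSE, FALSE))
  out <- apply_correction(rpk, factors)
  expect_equal(out$score, c(100, 200, 0))

  factors$factor[3] <- NA
  expect_warning(out2 <- apply_correction(rpk, factors), "dropped")
  expect_equal(out2$id, c("a", "b"))
})

test_that("correction computed from already-corrected data is the identity", {
  cfg <- small_config(seed = 2)
  catalog <- generate_catalog(cfg)
  truth <- generate_truth(catalog, cfg)
  sim <- generate_readcounts(truth, catalog, cfg, type = "simulated")
  f <- mappability_factors(sim)
  corrected <- apply_correction(sim, f)
  ## re-derive factors from the corrected table: all 1 up to Poisson noise 0
  corrected_counts <- toy_counts(corrected$score, rep(1000L, nrow(corrected)),
                                 corrected$id)
  f2 <- mappability_factors(corrected_counts)
  ## the corrected simulated scores are all equal in expectation; the second
  ## round of median-centring must not move them further
  expect_equal(median(f2$factor, na.rm = TRUE), 1, tolerance = 1e-12)
  reapplied <- apply_correction(tibble::tibble(id = corrected$id,
                                               score = corrected$score), f2)
  expect_equal(sort(reapplied$score / corrected$score),
               sort(1 / f2$factor[!f2$unquantifiable]), tolerance = 1e-9)
})

test_that("sequencibility ratios flag duplicated and unsequencable features", {
  sim <- toy_counts(rep(100, 5))
  same <- sequencibility(sim, sim)
  expect_equal(same$ratio, rep(1, 5))
  expect_true(all(same$flag == "ok"))

  dna <- toy_counts(c(100, 100, 200, 100, 100))
  dup <- sequencibility(dna, sim)
  expect_equal(dup$ratio[3], 2)
  expect_equal(sum(dup$flag != "ok"), 0)   # 2 is not > 2

  dna2 <- toy_counts(c(100, 100, 300, 10, 100))
  fl <- sequencibility(dna2, sim)
  expect_equal(sum(fl$flag == "high"), 1)
  expect_equal(sum(fl$flag == "low"), 1)
  expect_equal(attr(fl, "n_flagged"), 2)

  simz <- toy_counts(c(100, 100, 100, 100, 0))
  und <- sequencibility(dna, simz)
  expect_equal(und$flag[5], "undefined")
})

toy_ncounter <- function(copies, counts, n_anchor = 3) {
  n <- length(copies)
  roles <- rep(c("anchor", "spike"), c(n_anchor, n - n_anchor))
  tibble::tibble(probe = sprintf("p%02d", seq_len(n)), role = roles,
                 known_copies = ifelse(roles == "spike", copies, NA),
                 true_copies = copies, replicate = 1L, run = 1L,
                 counts = counts)
}

test_that("spike calibration inverts the count-copies relationship exactly", {
  copies <- c(5, 50, 500, 2, 20, 200, 2000)     # 3 anchors then 4 spikes
  run <- toy_ncounter(copies, counts = 10 * copies)
  out <- calibrate_spikes(run)
  expect_equal(out$copies, copies[1:3], tolerance = 1e-12)

  ## perfect power law counts = g * copies^b
  run2 <- toy_ncounter(copies, counts = 3 * copies^0.8)
  out2 <- calibrate_spikes(run2)
  expect_equal(out2$copies, copies[1:3], tolerance = 1e-9)
  expect_equal(out$copies, copies[1:3], tolerance = 1e-12)

  ## zero-count spike excluded with warning; < 3 usable spikes fails
  run3 <- toy_ncounter(copies, counts = 10 * copies)
  run3$counts[run3$role == "spike"][1] <- 0
  expect_warning(calibrate_spikes(run3), "zero counts")
  run4 <- run3
  run4$counts[run4$role == "spike"] <- 0
  expect_error(suppressWarnings(calibrate_spikes(run4)), "fewer than 3")
})

test_that("spike calibration recovers anchors under noise", {
  fe <- vapply(1:50, function(s) {
    cfg <- small_config(seed = s, ncounter_cv = 0.2)
    truth <- generate_truth(generate_catalog(cfg), cfg)
    run <- generate_ncounter(truth, cfg)
    est <- calibrate_spikes(run)
    truth_copies <- run$true_copies[match(est$id, run$probe)]
    mean(exp(abs(log(est$copies / truth_copies))))
  }, numeric(1))
  expect_lt(mean(fe), 1.5)
})

test_that("anchor regression recovers an exact log-log line", {
  copies <- exp(seq(log(0.5), log(800), length.out = 49))
  scores <- tibble::tibble(id = sprintf("a%02d", 1:49), score = copies)
  anchors <- tibble::tibble(id = scores$id, copies = copies)
  m <- fit_anchor_model(scores, anchors)
  expect_equal(m$slope, 1, tolerance = 1e-12)
  expect_equal(m$intercept, 0, tolerance = 1e-12)
  expect_equal(m$sigma, 0, tolerance = 1e-9)
  expect_equal(m$n_anchors, 49L)

  ## synthetic distortion score = exp(2) * copies^0.9, noiseless:
  ## inverse line has slope 1/0.9 and intercept -2/0.9
  scores2 <- tibble::tibble(id = scores$id, score = exp(2) * copies^0.9)
  m2 <- fit_anchor_model(scores2, anchors)
  expect_equal(m2$slope, 1 / 0.9, tolerance = 1e-9)
  expect_equal(m2$intercept, -2 / 0.9, tolerance = 1e-9)

  ## zero-score anchors excluded with warning
  scores3 <- scores
  scores3$score[1] <- 0
  expect_warning(m3 <- fit_anchor_model(scores3, anchors), "excluded")
  expect_equal(m3$n_anchors, 48L)
})

test_that("slope recovery under multiplicative noise is accurate on average", {
  slopes <- vapply(1:100, function(s) {
    set.seed(s)
    copies <- exp(runif(49, log(0.05), log(800)))
    noise <- rlnorm(49, 0, sqrt(log(1 + 0.3^2)))
    scores <- tibble::tibble(id = sprintf("a%02d", 1:49),
                             score = copies * noise)
    fit_anchor_model(scores, tibble::tibble(id = scores$id, copies = copies))$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1), 0.05)
})

test_that("copy prediction handles zeros and is log-base invariant", {
  copies <- exp(seq(log(0.5), log(800), length.out = 20))
  ids <- sprintf("a%02d", 1:20)
  scores <- tibble::tibble(id = ids, score = 5 * copies^0.95)
  anchors <- tibble::tibble(id = ids, copies = copies)
  m <- fit_anchor_model(scores, anchors)

  pred <- predict_copies(m, scores)
  expect_equal(pred$copies, copies, tolerance = 1e-9)   # anchors round-trip

  z <- predict_copies(m, tibble::tibble(id = "z", score = 0))
  expect_false(z$detected)
  expect_true(is.na(z$copies))
  expect_error(predict_copies(m, tibble::tibble(id = "n", score = -1)),
               "negative")

  ## base-2 fit gives identical predictions (affine reparameterization)
  fit2 <- lm(log2(copies) ~ log2(score), data = merge(scores, anchors))
  newx <- tibble::tibble(id = "q", score = 123.4)
  pred_nat <- predict_copies(m, newx)$copies
  pred_b2 <- 2^(coef(fit2)[1] + coef(fit2)[2] * log2(newx$score))
  expect_equal(pred_nat, unname(pred_b2), tolerance = 1e-12)
})

test_that("bootstrap fold errors are >= 1, exactly 1 for perfect fits, and track noise", {
  copies <- exp(seq(log(0.5), log(800), length.out = 30))
  ids <- sprintf("a%02d", 1:30)
  anchors <- tibble::tibble(id = ids, copies = copies)
  perfect <- tibble::tibble(id = ids, score = 2 * copies)
  e0 <- bootstrap_fold_error(perfect, anchors, n_resamples = 200)
  expect_equal(e0$mean_fold_error, 1, tolerance = 1e-9)
  expect_true(all(e0$per_anchor$fold_error >= 1))

  ## analytic expectation at CV c: 2 * exp(s^2/2) * pnorm(s), s^2 = log(1+c^2)
  set.seed(11)
  noisy <- tibble::tibble(id = ids,
                          score = 2 * copies * rlnorm(30, 0, sqrt(log(1 + 0.35^2))))
  e1 <- bootstrap_fold_error(noisy, anchors, n_resamples = 500)
  expect_gt(e1$mean_fold_error, 1.2)
  expect_lt(e1$mean_fold_error, 1.6)

  expect_error(bootstrap_fold_error(perfect, anchors, n_resamples = 50),
               ">= 100")
})

test_that("calibrated copies converge to the truth as noise vanishes", {
  med_fe <- vapply(c(0.6, 0.3, 0.1, 0), function(cv) {
    cfg <- small_config(seed = 9, seq_noise_cv = cv, ncounter_cv = min(cv, 0.2),
                        poisson_counts = FALSE)
    res <- run_rna_pipeline(cfg)
    truth_copies <- setNames(res$truth$rna$proliferating, res$truth$rna$id)
    median_fold_error(res$expression, truth_copies)
  }, numeric(1))
  expect_true(all(diff(med_fe) <= 1e-9))       # monotone improvement
  expect_equal(med_fe[4], 1, tolerance = 1e-6) # exact at zero noise
})

test_that("features with positive reads are always detected", {
  cfg <- small_config(seed = 4)
  res <- run_rna_pipeline(cfg)
  rc <- generate_readcounts(res$truth, res$catalog, cfg)
  pos <- rc$id[rc$reads > 0]
  pos <- intersect(pos, res$expression$id)
  expect_true(all(res$expression$detected[match(pos, res$expression$id)]))
})
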