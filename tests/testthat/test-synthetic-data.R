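test_that("generators are deterministic for a fixed seed", {
  cfg <- small_config(seed = 42)
  c1 <- generate_catalog(cfg)
  c2 <- generate_catalog(cfg)
  expect_identical(c1, c2)
  t1 <- generate_truth(c1, cfg)
  t2 <- generate_truth(c2, cfg)
  expect_identical(t1, t2)
  expect_identical(generate_readcounts(t1, c1, cfg),
                   generate_readcounts(t2, c2, cfg))
})

test_that("catalog respects class counts, empty classes, and uniqueness", {
  cfg <- small_config()
  catalog <- generate_catalog(cfg)
  expect_equal(sum(catalog$class == "mRNA"), 400L)
  expect_equal(sum(catalog$class == "lncRNA"), 120L)
  expect_false(anyDuplicated(catalog$id) > 0)
  expect_true(all(catalog$length_nt >= 1))
  expect_true(all(catalog$mappability > 0))
  ## protein sequences only on mRNAs
  expect_true(all(catalog$class[!is.na(catalog$protein_sequence)] == "mRNA"))

  none <- generate_catalog(small_config(n_mrna = 0L))
  expect_equal(sum(none$class == "mRNA"), 0L)
})

test_that("catalog at genome scale carries the annotated feature counts", {
  catalog <- generate_catalog(sim_config())
  expect_equal(sum(catalog$class == "mRNA"), 5110L)
  expect_equal(sum(catalog$class == "lncRNA"), 1557L)
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(n_mrna = -5L), "n_mrna")
  expect_error(sim_config(depth = 0), "depth")
  expect_error(sim_config(q_mrna_scale = 1.5), "q_mrna_scale")
  expect_error(sim_config(seq_noise_cv = -0.1), "seq_noise_cv")
  expect_error(sim_config(timepoints = c(1, 2)), "timepoints")
})

test_that("zero-noise truth couples protein to mRNA exactly", {
  cfg <- zero_noise_config(ratio_meanlog = log(1000), ratio_sdlog = 0)
  catalog <- generate_catalog(cfg)
  truth <- generate_truth(catalog, cfg)
  m <- truth$rna$proliferating[match(truth$protein$id, truth$rna$id)]
  expect_equal(truth$protein$proliferating, 1000 * m, tolerance = 1e-12)
})

test_that("mRNA abundance law hits the configured median at genome scale", {
  cfg0 <- sim_config()
  catalog <- generate_catalog(cfg0)
  meds <- vapply(1:20, function(s) {
    tr <- generate_truth(catalog, sim_config(seed = s))
    median(tr$rna$proliferating[tr$rna$class == "mRNA"])
  }, numeric(1))
  expect_lt(abs(mean(meds) / 2.4 - 1), 0.10)
})

test_that("quiescent totals scale by the configured class factor", {
  cfg <- small_config(seed = 3, n_mrna = 2000L)
  catalog <- generate_catalog(cfg)
  truth <- generate_truth(catalog, cfg)
  m <- truth$rna[truth$rna$class == "mRNA", ]
  ## totals are dominated by a few abundant genes, so the per-gene jitter
  ## does not fully average out; tolerance reflects that effective n
  expect_equal(sum(m$quiescent) / sum(m$proliferating), 0.18, tolerance = 0.15)
  r <- truth$rna[truth$rna$class == "rRNA", ]
  expect_equal(sum(r$quiescent) / sum(r$proliferating), 0.112, tolerance = 0.25)
})

test_that("expected read counts are proportional to copies x length x mappability", {
  cfg <- zero_noise_config(n_mrna = 4L, n_lncrna = 0L, n_rrna = 0L,
                           n_spike = 0L, frac_periodic = 0)
  catalog <- generate_catalog(cfg)
  catalog$length_nt <- c(1000L, 2000L, 1000L, 1000L)
  catalog$mappability <- rep(1, 4)
  truth <- generate_truth(catalog, cfg)
  truth$rna$proliferating <- c(10, 10, 0, 5)
  rc <- generate_readcounts(truth, catalog, cfg)
  ## equal copies, double length -> double reads
  expect_equal(rc$reads[2] / rc$reads[1], 2, tolerance = 1e-12)
  ## zero copies -> zero reads, always
  expect_identical(rc$reads[3], 0)
  expect_equal(sum(rc$reads), cfg$depth, tolerance = 1e-9)
})

test_that("Poisson counting matches its theoretical mean and variance", {
  counts <- unlist(lapply(1:100, function(s) {
    cfg <- small_config(seed = s, n_mrna = 100L, n_lncrna = 0L, n_rrna = 0L,
                        n_spike = 0L, depth = 1e5, seq_noise_cv = 0,
                        frac_periodic = 0)
    catalog <- generate_catalog(cfg)
    catalog$length_nt <- rep(1000L, 100)
    catalog$mappability <- rep(1, 100)
    truth <- generate_truth(catalog, cfg)
    truth$rna$proliferating <- rep(1, 100)
    generate_readcounts(truth, catalog, cfg)$reads
  }))
  ## each count ~ Poisson(1000): mean 1000, variance 1000
  expect_equal(mean(counts), 1000, tolerance = 0.01)
  expect_equal(var(counts), 1000, tolerance = 0.10)
})

test_that("nCounter emulation: gain, spike coverage, replicate CV", {
  cfg <- zero_noise_config(ncounter_gain = 10)
  catalog <- generate_catalog(cfg)
  truth <- generate_truth(catalog, cfg)
  run <- generate_ncounter(truth, cfg)
  expect_equal(run$counts, 10 * run$true_copies, tolerance = 1e-12)

  anchors <- run[run$role == "anchor" & run$replicate == 1, ]
  spikes <- run[run$role == "spike" & run$replicate == 1, ]
  expect_lte(min(spikes$known_copies), min(anchors$true_copies))
  expect_gte(max(spikes$known_copies), max(anchors$true_copies))

  cvs <- unlist(lapply(1:50, function(s) {
    cfgn <- small_config(seed = s, n_mrna = 120L, ncounter_cv = 0.2)
    tr <- generate_truth(generate_catalog(cfgn), cfgn)
    rn <- generate_ncounter(tr, cfgn)
    tapply(rn$counts, rn$probe, function(x) sd(x) / mean(x))
  }))
  ## sample CV from 3 replicates underestimates the population CV (~c4 bias)
  expect_gt(mean(cvs), 0.15)
  expect_lt(mean(cvs), 0.24)
})

test_that("MS emulation: zero-noise identity, undetectable proteins, anchor span", {
  cfg <- zero_noise_config(ms_detection_limit = 1)
  catalog <- generate_catalog(cfg)
  truth <- generate_truth(catalog, cfg)
  ms <- generate_ms(truth, catalog, cfg)
  expect_equal(ms$intensity / ms$n_ms_suitable, ms$true_copies,
               tolerance = 1e-12)
  expect_true(all(ms$n_ms_suitable >= 1))

  ## full-size anchors span at least four orders of magnitude
  cfg0 <- sim_config(seed = 5)
  cat0 <- generate_catalog(cfg0)
  tr0 <- generate_truth(cat0, cfg0)
  ms0 <- generate_ms(tr0, cat0, cfg0)
  anchors <- unique(ms0$known_copies[ms0$anchor])
  expect_equal(length(anchors), 39L)
  expect_gte(diff(range(log10(anchors))), 4)
})

test_that("cell geometry reproduces the quiescent volume shrinkage", {
  ratios <- vapply(1:20, function(s) {
    mv <- median_volumes(generate_cells(small_config(seed = s)))
    mv[["quiescent"]] / mv[["proliferating"]]
  }, numeric(1))
  expect_lt(abs(mean(ratios) / 0.55 - 1), 0.05)
})

test_that("time course: normalized start, requested grid, declining RNA content", {
  cfg <- small_config()
  catalog <- generate_catalog(cfg)
  truth <- generate_truth(catalog, cfg)
  tc <- generate_timecourse(truth, cfg, catalog)
  expect_identical(unname(tc$content_fraction[1]), 1)
  expect_equal(ncol(tc$ratios), 16L)
  expect_true(all(tc$ratios[, 1] == 1))
  expect_true(all(diff(tc$content_fraction) <= 0))
  expect_lt(tc$content_fraction[2], 1)
})
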