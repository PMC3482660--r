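#' Generate synthetic sequencing read counts
#'
#' Emulates a sequencing run over the cellular features of the catalog. The
#' expected count of a feature is proportional to
#' `copies^distort_slope * length_kb * mappability` times a per-feature
#' multiplicative log-normal bias (CV `seq_noise_cv`), scaled so the expected
#' total equals `depth`. Counts are Poisson around that expectation (or the
#' expectation itself when `poisson_counts = FALSE`, the zero-noise limit of
#' the counting process). `type = "simulated"` emulates uniform simulated-read
#' coverage of the genome (copies replaced by 1, no biological noise), used to
#' derive mappability correction factors; `type = "dna"` emulates genomic DNA
#' sequencing and additionally reflects `genome_copies`.
#'
#' @param truth a [generate_truth()] result (ignored for `simulated`/`dna`).
#' @param catalog the matching [generate_catalog()] result.
#' @param config the [sim_config()].
#' @param condition `"proliferating"` or `"quiescent"`.
#' @param type `"rna"`, `"simulated"` or `"dna"`.
#' @return a `read_count_table` tibble (`id`, `reads`, `length_nt`) with
#'   attributes `sample_type` and `condition`.
#' @export
generate_readcounts <- function(truth, catalog, config,
                                condition = c("proliferating", "quiescent"),
                                type = c("rna", "simulated", "dna")) {
  validate_sim_config(config)
  condition <- match.arg(condition)
  type <- match.arg(type)
  if (config$depth <= 0) stop("depth must be > 0", call. = FALSE)
  set.seed(stage_seed(config, 10L + match(type, c("rna", "simulated", "dna")) +
                        3L * match(condition, c("proliferating", "quiescent"))))

  feats <- catalog[catalog$class != "spike", ]
  len_kb <- feats$length_nt / 1000

  mu <- switch(type,
    rna = {
      copies <- truth$rna[[condition]][match(feats$id, truth$rna$id)]
      copies^config$distort_slope * len_kb * feats$mappability *
        rmultnoise(nrow(feats), config$seq_noise_cv)
    },
    simulated = len_kb * feats$mappability,
    dna = len_kb * feats$mappability * feats$genome_copies
  )
  if (sum(mu) <= 0) stop("all expected counts are zero", call. = FALSE)
  lambda <- mu / sum(mu) * config$depth
  reads <- if (config$poisson_counts) rpois(length(lambda), lambda) else lambda

  out <- tibble::tibble(id = feats$id, reads = reads,
                        length_nt = feats$length_nt)
  class(out) <- c("read_count_table", class(out))
  attr(out, "sample_type") <- type
  attr(out, "condition") <- condition
  out
}

## calibration mRNAs spanning the dynamic range: quantile-spaced picks
select_anchors <- function(copies, ids, n, lo = 0.02, hi = 0.98) {
  ord <- order(copies)
  ranks <- unique(pmax(1L, round(seq(lo, hi, length.out = n) * length(ids))))
  while (length(ranks) < n) {
    extra <- setdiff(seq_along(ids), ranks)
    ranks <- sort(c(ranks, extra[seq_len(n - length(ranks))]))
  }
  ids[ord][ranks]
}

#' Generate a synthetic nCounter run
#'
#' Emulates digital counting of the 49 calibration mRNAs together with
#' external spike-in controls of known copies/cell. Counts are
#' `gain * copies` times multiplicative log-normal noise (CV `ncounter_cv`),
#' drawn independently per technical replicate; replicates are split across
#' instrument runs. Spike concentrations are log-spaced so they cover the
#' expression range of the calibration mRNAs.
#'
#' @inheritParams generate_readcounts
#' @return an `ncounter_run` tibble (`probe`, `role`, `known_copies`,
#'   `true_copies`, `replicate`, `run`, `counts`) with a `condition` attribute.
#' @export
generate_ncounter <- function(truth, config,
                              condition = c("proliferating", "quiescent")) {
  validate_sim_config(config)
  condition <- match.arg(condition)
  if (config$n_anchor_rna < 1L || config$n_spike < 1L) {
    stop("anchor and spike lists must be nonempty", call. = FALSE)
  }
  set.seed(stage_seed(config, 30L +
                        match(condition, c("proliferating", "quiescent"))))

  mrna <- truth$rna[truth$rna$class == "mRNA", ]
  anchor_ids <- select_anchors(mrna$proliferating, mrna$id, config$n_anchor_rna)
  anchor_copies <- mrna[[condition]][match(anchor_ids, mrna$id)]

  ref <- mrna$proliferating[match(anchor_ids, mrna$id)]
  spike_copies <- exp(seq(log(min(ref) * 0.9), log(max(ref) * 1.1),
                          length.out = config$n_spike))
  spike_ids <- sprintf("spike_%05d", seq_len(config$n_spike))

  probes <- c(anchor_ids, spike_ids)
  roles <- rep(c("anchor", "spike"), c(length(anchor_ids), length(spike_ids)))
  copies <- c(anchor_copies, spike_copies)
  known <- c(rep(NA_real_, length(anchor_ids)), spike_copies)

  reps <- config$ncounter_replicates
  runs <- rep(seq_len(config$ncounter_runs), length.out = reps)
  out <- do.call(rbind, lapply(seq_len(reps), function(r) {
    tibble::tibble(
      probe = probes, role = roles, known_copies = known, true_copies = copies,
      replicate = r, run = runs[r],
      counts = config$ncounter_gain * copies *
        rmultnoise(length(copies), config$ncounter_cv)
    )
  }))
  out <- tibble::as_tibble(out)
  class(out) <- c("ncounter_run", class(out))
  attr(out, "condition") <- condition
  out
}

#' Generate synthetic mass-spectrometry intensities
#'
#' Emulates label-free protein quantification: each protein's summed precursor
#' intensity is `copies * n_ms_suitable * response` per replicate, where
#' `n_ms_suitable` is its census of fully tryptic peptides with monoisotopic
#' mass 700-6000 Da (computed from the catalog sequence via
#' [tryptic_digest()]), `response` is a per-protein log-normal ionization
#' factor (CV `ms_response_cv`, shared across replicates) and replicates add
#' independent log-normal noise (CV `ms_replicate_cv`). Proteins without a
#' sequence are excluded with a warning; proteins with no MS-suitable peptide
#' or falling below the (logistic) detection limit yield no intensity rows.
#' `n_anchor_protein` heavy-peptide anchors spanning the abundance range are
#' flagged with their known copies.
#'
#' @inheritParams generate_readcounts
#' @return an `ms_intensity_table` tibble (`id`, `replicate`, `intensity`,
#'   `n_ms_suitable`, `anchor`, `known_copies`, `true_copies`) with a
#'   `condition` attribute.
#' @export
generate_ms <- function(truth, catalog, config,
                        condition = c("proliferating", "quiescent")) {
  validate_sim_config(config)
  condition <- match.arg(condition)
  set.seed(stage_seed(config, 40L +
                        match(condition, c("proliferating", "quiescent"))))

  prot <- truth$protein
  seqs <- catalog$protein_sequence[match(prot$id, catalog$id)]
  no_seq <- is.na(seqs)
  if (any(no_seq)) {
    warning(sprintf("%d proteins without sequence excluded from MS simulation",
                    sum(no_seq)))
    prot <- prot[!no_seq, , drop = FALSE]
    seqs <- seqs[!no_seq]
  }
  if (nrow(prot) == 0L) stop("no proteins with sequences to simulate", call. = FALSE)

  n_ms <- count_ms_peptides(seqs)
  copies <- prot[[condition]]
  detected <- if (config$ms_detection_scale > 0) {
    runif(length(copies)) < stats::plogis(
      (log(pmax(copies, .Machine$double.xmin)) - log(config$ms_detection_limit)) /
        config$ms_detection_scale)
  } else {
    copies >= config$ms_detection_limit
  }
  detectable <- n_ms >= 1L & detected
  ids <- prot$id[detectable]
  copies <- copies[detectable]
  n_ms <- n_ms[detectable]
  if (length(ids) == 0L) stop("no detectable proteins under this config", call. = FALSE)

  ## heavy-peptide anchors cover the full detected dynamic range
  anchor_ids <- select_anchors(copies, ids, min(config$n_anchor_protein,
                                                length(ids)),
                               lo = 0.001, hi = 0.999)
  response <- rmultnoise(length(ids), config$ms_response_cv)

  out <- do.call(rbind, lapply(seq_len(config$ms_replicates), function(r) {
    tibble::tibble(
      id = ids, replicate = r,
      intensity = copies * n_ms * response *
        rmultnoise(length(ids), config$ms_replicate_cv),
      n_ms_suitable = n_ms,
      anchor = ids %in% anchor_ids,
      known_copies = ifelse(ids %in% anchor_ids, copies, NA_real_),
      true_copies = copies
    )
  }))
  out <- tibble::as_tibble(out)
  class(out) <- c("ms_intensity_table", class(out))
  attr(out, "condition") <- condition
  out
}
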