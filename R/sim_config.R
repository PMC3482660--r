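#' Simulation configuration for the synthetic measurement process
#'
#' Bundles every parameter of the synthetic-data generator: how many features
#' of each class exist, the log-abundance law per class, the behaviour of the
#' three measurement instruments (sequencer, nCounter, LC-MS), the coupling
#' between the proliferating and quiescent conditions, and the cell-geometry
#' and time-course settings. Defaults reproduce the study conditions of a
#' haploid fission-yeast-like genome: 5,110 protein-coding genes with a median
#' of 2.4 mRNA copies/cell, 1,557 lncRNAs mostly repressed below 1 copy/cell,
#' ~802,000 rRNA molecules/cell, 49 RNA and 39 protein calibration anchors,
#' 13 spike-ins, and a quiescent state with mRNA shrunk to 18%, rRNA to 11.2%
#' and protein to 51.7% of proliferating totals.
#'
#' @param n_mrna,n_lncrna,n_rrna number of features per class.
#' @param mrna_meanlog,mrna_sdlog log-normal law for mRNA copies/cell
#'   (`mrna_meanlog` is the log of the target median; functional-category
#'   shifts are re-centred so the mixture median equals `exp(mrna_meanlog)`).
#' @param lncrna_meanlog,lncrna_sdlog log-normal law for lncRNA copies/cell.
#' @param rrna_meanlog,rrna_sdlog log-normal law for rRNA copies/cell.
#' @param ratio_meanlog,ratio_sdlog per-gene protein/mRNA ratio law.
#' @param ratio_saturation logical; damp the ratio at high mRNA abundance
#'   (translation saturating for the most abundant transcripts).
#' @param ratio_saturation_k mRNA copies/cell at which damping sets in.
#' @param depth expected total mapped reads of a sequencing run.
#' @param seq_noise_cv per-feature multiplicative coefficient of variation of
#'   the sequencing score around its expectation (library/capture bias).
#' @param distort_slope exponent of the score-versus-copies relationship the
#'   calibration must recover (1 = proportional response).
#' @param poisson_counts logical; draw integer read counts from a Poisson law
#'   around the expectation. `FALSE` returns the (real-valued) expectations,
#'   the zero-noise limit of the counting process.
#' @param n_anchor_rna,n_spike number of calibration mRNAs and external
#'   spike-in controls on the nCounter run.
#' @param ncounter_gain instrument counts per molecule.
#' @param ncounter_cv multiplicative CV of nCounter counts.
#' @param ncounter_replicates,ncounter_runs technical replicates and the
#'   number of instrument runs they are split across.
#' @param n_anchor_protein number of heavy-peptide protein anchors.
#' @param ms_response_cv per-protein multiplicative CV of the MS response
#'   factor (ionization efficiency), shared across replicates.
#' @param ms_replicate_cv per-replicate multiplicative CV of MS intensities.
#' @param ms_replicates number of LC-MS replicates.
#' @param ms_detection_limit copies/cell at which a protein has a 50% chance
#'   of being detected by MS.
#' @param ms_detection_scale width (natural-log copies) of the logistic
#'   detection curve around `ms_detection_limit`; 0 gives a hard,
#'   deterministic threshold.
#' @param frac_periodic fraction of mRNAs with cell-cycle-periodic expression.
#' @param periodic_f_peak fraction of the cycle spent at peak expression.
#' @param amplitude_meanlog,amplitude_sdlog law of the peak/basal amplitude
#'   (clamped at 1 from below).
#' @param n_experiments number of cell-cycle time courses providing
#'   independent amplitude estimates per gene.
#' @param q_mrna_scale,q_lncrna_scale,q_rrna_scale,q_protein_scale class-level
#'   scaling of quiescent copies relative to proliferating copies.
#' @param q_jitter_sdlog per-gene log-normal jitter around the class scaling
#'   (keeps cross-condition correlation high).
#' @param n_cells cells measured per condition for geometry.
#' @param cell_length_mean named vector (proliferating, quiescent) of mean
#'   cell lengths in micrometres.
#' @param cell_length_sd,cell_diameter_mean,cell_diameter_sd geometry spread
#'   and diameter law (micrometres).
#' @param timepoints time grid (hours) of the quiescence-entry time course,
#'   strictly increasing and starting at 0.
#' @param rna_content_plateau,rna_content_tau total-RNA content per cell
#'   declines as `plateau + (1 - plateau) * exp(-t / tau)`.
#' @param mrna_length_meanlog,mrna_length_sdlog mRNA length law (nucleotides).
#' @param lncrna_length_meanlog,lncrna_length_sdlog lncRNA length law.
#' @param mappability_sdlog spread of per-feature mappability around 1.
#' @param category_probs named probabilities of the synthetic functional
#'   categories attached to mRNAs (`none` entries carry no label).
#' @param seed integer seed; all generators derive their streams from it.
#'
#' @return an object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_mrna = 5110L,
                       n_lncrna = 1557L,
                       n_rrna = 4L,
                       mrna_meanlog = log(2.4),
                       mrna_sdlog = 1.6,
                       lncrna_meanlog = log(0.1),
                       lncrna_sdlog = 1.4,
                       rrna_meanlog = log(2e5),
                       rrna_sdlog = 0.25,
                       ratio_meanlog = log(1600),
                       ratio_sdlog = 1.1,
                       ratio_saturation = FALSE,
                       ratio_saturation_k = 50,
                       depth = 2e7,
                       seq_noise_cv = 0.35,
                       distort_slope = 1,
                       poisson_counts = TRUE,
                       n_anchor_rna = 49L,
                       n_spike = 13L,
                       ncounter_gain = 12,
                       ncounter_cv = 0.2,
                       ncounter_replicates = 3L,
                       ncounter_runs = 2L,
                       n_anchor_protein = 39L,
                       ms_response_cv = 0.4,
                       ms_replicate_cv = 0.15,
                       ms_replicates = 3L,
                       ms_detection_limit = 1400,
                       ms_detection_scale = 0.8,
                       frac_periodic = 241 / 5110,
                       periodic_f_peak = 0.1,
                       amplitude_meanlog = log(3),
                       amplitude_sdlog = 0.5,
                       n_experiments = 6L,
                       q_mrna_scale = 0.18,
                       q_lncrna_scale = 0.18,
                       q_rrna_scale = 0.112,
                       q_protein_scale = 0.517,
                       q_jitter_sdlog = 0.35,
                       n_cells = 260L,
                       cell_length_mean = c(proliferating = 12, quiescent = 7.1),
                       cell_length_sd = 1.3,
                       cell_diameter_mean = 3.5,
                       cell_diameter_sd = 0.2,
                       timepoints = c(0, 0.5, 1, 2, 3, 4, 6, 9, 12, 16,
                                      20, 24, 48, 72, 120, 168),
                       rna_content_plateau = 0.15,
                       rna_content_tau = 3,
                       mrna_length_meanlog = log(1400),
                       mrna_length_sdlog = 0.45,
                       lncrna_length_meanlog = log(1000),
                       lncrna_length_sdlog = 0.5,
                       mappability_sdlog = 0.1,
                       category_probs = c(none = 0.70, translation = 0.08,
                                          stress = 0.10, meiosis = 0.12),
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  for (fld in c("n_mrna", "n_lncrna", "n_rrna", "n_anchor_rna", "n_spike",
                "n_anchor_protein", "ncounter_replicates", "ncounter_runs",
                "ms_replicates", "n_experiments", "n_cells")) {
    v <- cfg[[fld]]
    if (length(v) != 1L || is.na(v) || v < 0 || v != round(v)) {
      stop(sprintf("invalid config: `%s` must be a single non-negative integer", fld),
           call. = FALSE)
    }
  }
  for (fld in c("mrna_sdlog", "lncrna_sdlog", "rrna_sdlog", "ratio_sdlog",
                "seq_noise_cv", "ncounter_cv", "ms_response_cv",
                "ms_replicate_cv", "amplitude_sdlog", "q_jitter_sdlog",
                "mappability_sdlog", "cell_length_sd", "cell_diameter_sd")) {
    if (cfg[[fld]] < 0) {
      stop(sprintf("invalid config: `%s` must be >= 0", fld), call. = FALSE)
    }
  }
  if (cfg$depth <= 0) stop("invalid config: `depth` must be > 0", call. = FALSE)
  for (fld in c("q_mrna_scale", "q_lncrna_scale", "q_rrna_scale")) {
    v <- cfg[[fld]]
    if (v <= 0 || v > 1) {
      stop(sprintf("invalid config: `%s` must be in (0, 1]", fld), call. = FALSE)
    }
  }
  if (cfg$q_protein_scale <= 0) {
    stop("invalid config: `q_protein_scale` must be > 0", call. = FALSE)
  }
  if (cfg$periodic_f_peak <= 0 || cfg$periodic_f_peak >= 1) {
    stop("invalid config: `periodic_f_peak` must be in (0, 1)", call. = FALSE)
  }
  if (cfg$frac_periodic < 0 || cfg$frac_periodic > 1) {
    stop("invalid config: `frac_periodic` must be in [0, 1]", call. = FALSE)
  }
  tp <- cfg$timepoints
  if (length(tp) < 1L || tp[1] != 0 || any(diff(tp) <= 0)) {
    stop("invalid config: `timepoints` must strictly increase starting at 0",
         call. = FALSE)
  }
  if (!all(c("proliferating", "quiescent") %in% names(cfg$cell_length_mean))) {
    stop("invalid config: `cell_length_mean` needs proliferating and quiescent entries",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  features: %d mRNA, %d lncRNA, %d rRNA, %d spikes\n",
              x$n_mrna, x$n_lncrna, x$n_rrna, x$n_spike))
  cat(sprintf("  anchors: %d RNA, %d protein; depth %.3g reads\n",
              x$n_anchor_rna, x$n_anchor_protein, x$depth))
  cat(sprintf("  noise CVs: seq %.2f, nCounter %.2f, MS response %.2f\n",
              x$seq_noise_cv, x$ncounter_cv, x$ms_response_cv))
  cat(sprintf("  quiescence scales: mRNA %.3g, rRNA %.3g, protein %.3g\n",
              x$q_mrna_scale, x$q_rrna_scale, x$q_protein_scale))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

## log-normal sdlog corresponding to a multiplicative coefficient of variation
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

## mean-one multiplicative log-normal noise
rmultnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- cv_to_sdlog(cv)
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

## deterministic sub-seed per generator stage
stage_seed <- function(cfg, offset) {
  as.integer((cfg$seed + offset * 1009L) %% .Machine$integer.max)
}
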