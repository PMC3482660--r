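## Approximate amino-acid frequencies of a yeast proteome; used to draw
## synthetic protein sequences with a realistic density of K/R cleavage sites.
AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_FREQS <- c(0.074, 0.052, 0.045, 0.053, 0.025, 0.040, 0.063, 0.074, 0.026,
              0.068, 0.099, 0.058, 0.025, 0.040, 0.046, 0.081, 0.062, 0.013,
              0.033, 0.068)

#' Generate a synthetic feature catalog
#'
#' Builds the simulated "genome": mRNAs (all with protein sequences, a subset
#' cell-cycle periodic and carrying per-experiment amplitudes), lncRNAs, rRNAs
#' (annotated with two genomic copies to emulate under-annotated repeats), and
#' external spike-in probes. mRNAs are tagged with synthetic functional
#' categories (`translation`, `stress`, `meiosis`) that later bias their
#' abundance, so zone/enrichment analyses have structure to find.
#'
#' @param config a [sim_config()].
#' @return a `feature_catalog` tibble with columns `id`, `class`, `length_nt`,
#'   `mappability`, `genome_copies`, `category`, `periodic`, `cluster`,
#'   `amplitudes` (list column), `protein_sequence`.
#' @export
generate_catalog <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config, 0L))

  mk_ids <- function(prefix, n) {
    if (n == 0L) return(character(0))
    sprintf("%s_%05d", prefix, seq_len(n))
  }

  n_m <- config$n_mrna
  n_l <- config$n_lncrna
  n_r <- config$n_rrna
  n_s <- config$n_spike

  len_m <- pmax(150L, as.integer(round(rlnorm(n_m, config$mrna_length_meanlog,
                                              config$mrna_length_sdlog))))
  len_l <- pmax(100L, as.integer(round(rlnorm(n_l, config$lncrna_length_meanlog,
                                              config$lncrna_length_sdlog))))
  len_r <- if (n_r > 0L) {
    as.integer(round(seq(1800, 3500, length.out = n_r)))
  } else integer(0)

  probs <- config$category_probs / sum(config$category_probs)
  cat_m <- sample(names(probs), n_m, replace = TRUE, prob = probs)
  cat_m[cat_m == "none"] <- NA_character_

  periodic <- rep(FALSE, n_m)
  n_per <- round(config$frac_periodic * n_m)
  cluster <- rep(NA_character_, n_m)
  amplitudes <- vector("list", n_m)
  if (n_per > 0L) {
    idx <- sample.int(n_m, n_per)
    periodic[idx] <- TRUE
    cluster[idx] <- sample(c("M", "G1", "S"), n_per, replace = TRUE)
    for (i in idx) {
      amplitudes[[i]] <- pmax(1, rlnorm(config$n_experiments,
                                        config$amplitude_meanlog,
                                        config$amplitude_sdlog))
    }
  }

  ## one long draw, split per protein (length ~ coding fraction of the mRNA)
  aa_len <- pmax(50L, as.integer(round(len_m / 3)))
  seqs <- character(0)
  if (n_m > 0L) {
    pool <- sample(AA_LETTERS, sum(aa_len), replace = TRUE, prob = AA_FREQS)
    seqs <- vapply(split(pool, rep.int(seq_len(n_m), aa_len)),
                   paste0, character(1), collapse = "")
    names(seqs) <- NULL
  }

  n_all <- n_m + n_l + n_r + n_s
  catalog <- tibble::tibble(
    id = c(mk_ids("mRNA", n_m), mk_ids("lncRNA", n_l),
           mk_ids("rRNA", n_r), mk_ids("spike", n_s)),
    class = rep(c("mRNA", "lncRNA", "rRNA", "spike"), c(n_m, n_l, n_r, n_s)),
    length_nt = c(len_m, len_l, len_r, rep(1000L, n_s)),
    mappability = c(rlnorm(n_m + n_l + n_r, 0, config$mappability_sdlog),
                    rep(1, n_s)),
    genome_copies = rep(c(1L, 1L, 2L, 1L), c(n_m, n_l, n_r, n_s)),
    category = c(cat_m, rep(NA_character_, n_l + n_r + n_s)),
    periodic = c(periodic, rep(FALSE, n_l + n_r + n_s)),
    cluster = c(cluster, rep(NA_character_, n_l + n_r + n_s)),
    amplitudes = c(amplitudes, vector("list", n_l + n_r + n_s)),
    protein_sequence = c(seqs, rep(NA_character_, n_l + n_r + n_s))
  )
  stopifnot(nrow(catalog) == n_all, !anyDuplicated(catalog$id))
  class(catalog) <- c("feature_catalog", class(catalog))
  catalog
}

## offset (in log space) that recentres the category-shift mixture so the
## theoretical median of mRNA copies equals exp(mrna_meanlog)
category_shifts <- c(translation = 1.5, stress = -0.5, meiosis = -2.5)

mixture_median_offset <- function(config, cats) {
  shift <- ifelse(is.na(cats), 0, category_shifts[cats])
  if (all(shift == 0)) return(0)
  w <- table(shift) / length(shift)
  sh <- as.numeric(names(w))
  f <- function(delta) {
    sum(w * stats::pnorm(0, mean = sh + delta, sd = config$mrna_sdlog)) - 0.5
  }
  stats::uniroot(f, c(-5, 5), tol = 1e-10)$root
}

#' Generate ground-truth copy numbers per condition
#'
#' Draws true copies/cell for every cellular feature in both conditions, plus
#' true protein copies for every mRNA. Per class the law is log-normal;
#' mRNA category shifts are recentred so the configured median holds for the
#' mixture. Protein copies are mRNA copies times a per-gene log-normal
#' protein/mRNA ratio (optionally damped at high mRNA abundance). Quiescent
#' copies are proliferating copies times the class-level scaling times
#' per-gene log-normal jitter with unit mean, preserving the high
#' cross-condition correlation.
#'
#' @param catalog a [generate_catalog()] result.
#' @param config the matching [sim_config()].
#' @return a `truth_table`: list with `$rna` (id, class, proliferating,
#'   quiescent) and `$protein` (id, proliferating, quiescent) tibbles.
#' @export
generate_truth <- function(catalog, config) {
  validate_sim_config(config)
  set.seed(stage_seed(config, 1L))

  cellular <- catalog[catalog$class != "spike", ]
  n <- nrow(cellular)
  copies <- numeric(n)

  is_m <- cellular$class == "mRNA"
  is_l <- cellular$class == "lncRNA"
  is_r <- cellular$class == "rRNA"

  if (any(is_m)) {
    cats <- cellular$category[is_m]
    delta <- mixture_median_offset(config, cats)
    shift <- ifelse(is.na(cats), 0, category_shifts[cats]) + delta
    copies[is_m] <- rlnorm(sum(is_m), config$mrna_meanlog + shift,
                           config$mrna_sdlog)
  }
  if (any(is_l)) {
    copies[is_l] <- rlnorm(sum(is_l), config$lncrna_meanlog, config$lncrna_sdlog)
  }
  if (any(is_r)) {
    copies[is_r] <- rlnorm(sum(is_r), config$rrna_meanlog, config$rrna_sdlog)
  }

  scale <- numeric(n)
  scale[is_m] <- config$q_mrna_scale
  scale[is_l] <- config$q_lncrna_scale
  scale[is_r] <- config$q_rrna_scale
  jitter <- rmultnoise(n, sdlog_to_cv(config$q_jitter_sdlog))
  quiescent <- copies * scale * jitter

  rna <- tibble::tibble(id = cellular$id, class = cellular$class,
                        proliferating = copies, quiescent = quiescent)

  prot <- tibble::tibble(id = character(0), proliferating = numeric(0),
                         quiescent = numeric(0))
  if (any(is_m)) {
    m <- copies[is_m]
    ratio <- rlnorm(sum(is_m), config$ratio_meanlog, config$ratio_sdlog)
    if (config$ratio_saturation) {
      ratio <- ratio * (1 + m / config$ratio_saturation_k)^-0.3
    }
    p <- m * ratio
    pj <- rmultnoise(sum(is_m), sdlog_to_cv(config$q_jitter_sdlog))
    prot <- tibble::tibble(id = cellular$id[is_m],
                           proliferating = p,
                           quiescent = p * config$q_protein_scale * pj)
  }

  out <- list(rna = rna, protein = prot)
  class(out) <- "truth_table"
  out
}

## inverse of cv_to_sdlog, for reusing the mean-one noise helper with an sdlog
sdlog_to_cv <- function(sdlog) sqrt(exp(sdlog^2) - 1)

#' @export
print.truth_table <- function(x, ...) {
  cat("<truth_table>\n")
  tot <- tapply(x$rna$proliferating, x$rna$class, sum)
  cat("  proliferating totals (copies/cell):\n")
  for (cl in names(tot)) cat(sprintf("    %-8s %.4g\n", cl, tot[[cl]]))
  cat(sprintf("  proteins: %d, total %.4g copies/cell\n",
              nrow(x$protein), sum(x$protein$proliferating)))
  invisible(x)
}
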