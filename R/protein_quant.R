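## Monoisotopic residue masses (Da) of the 20 standard amino acids; a peptide
## mass is the residue sum plus one water.
MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
WATER_MASS <- 18.010565

#' In-silico tryptic digestion with MS-suitability census
#'
#' Cleaves a protein sequence after lysine or arginine unless the next residue
#' is proline (full tryptic specificity), computes each peptide's monoisotopic
#' mass (residue masses plus one water), and counts the peptides whose mass
#' lies in the instrument-compatible precursor window. The peptides tile the
#' sequence: concatenating them reproduces the input exactly. Optionally
#' peptides with up to `missed_cleavages` internal missed sites are added to
#' the census (they do not change the tiling set reported in `peptides`).
#'
#' @param sequence a single amino-acid string (20 standard residues;
#'   nonstandard residues leave the affected peptide's mass undefined and flag
#'   the result).
#' @param mass_range accepted precursor monoisotopic mass window in daltons.
#' @param missed_cleavages number of missed cleavage sites allowed when
#'   counting MS-suitable peptides (0 = fully cleaved only).
#' @return a `digest_result`: list with `peptides` tibble (`peptide`, `mass`),
#'   `n_ms_suitable`, and `nonstandard` flag.
#' @export
tryptic_digest <- function(sequence, mass_range = c(700, 6000),
                           missed_cleavages = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  nonstandard <- !all(chars %in% names(MONO_MASS))
  if (nonstandard) {
    warning("sequence contains nonstandard residues; affected masses undefined")
  }
  n <- length(chars)
  ## cleavage after K/R not followed by P
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[cut_after + 1L] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)

  res_mass <- unname(MONO_MASS[chars])        # NA for nonstandard
  cum <- cumsum(ifelse(is.na(res_mass), NaN, res_mass))
  seg_mass <- function(s, e) {
    m <- cum[e] - ifelse(s > 1L, cum[pmax(s - 1L, 1L)], 0)
    ifelse(is.nan(m), NA_real_, m + WATER_MASS)
  }
  pep <- substring(sequence, starts, ends)
  mass <- seg_mass(starts, ends)

  suitable_mass <- mass
  if (missed_cleavages > 0L && length(starts) > 1L) {
    extra <- unlist(lapply(seq_len(missed_cleavages), function(mc) {
      i <- seq_len(length(starts) - mc)
      seg_mass(starts[i], ends[i + mc])
    }))
    suitable_mass <- c(suitable_mass, extra)
  }
  n_ms <- sum(suitable_mass >= mass_range[1] & suitable_mass <= mass_range[2],
              na.rm = TRUE)

  structure(list(peptides = tibble::tibble(peptide = pep, mass = mass),
                 n_ms_suitable = as.integer(n_ms),
                 nonstandard = nonstandard),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("<digest_result> %d peptides, %d MS-suitable%s\n",
              nrow(x$peptides), x$n_ms_suitable,
              if (x$nonstandard) " (nonstandard residues present)" else ""))
  invisible(x)
}

#' Count MS-suitable tryptic peptides for many sequences
#'
#' Vectorized census used to normalize summed intensities: the number of fully
#' tryptic peptides with monoisotopic mass inside `mass_range`.
#'
#' @param sequences character vector of protein sequences.
#' @inheritParams tryptic_digest
#' @return integer vector of counts (NA for NA sequences).
#' @export
count_ms_peptides <- function(sequences, mass_range = c(700, 6000),
                              missed_cleavages = 0L) {
  vapply(sequences, function(s) {
    if (is.na(s)) return(NA_integer_)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(chars)
    cut_after <- which(chars %in% c("K", "R"))
    cut_after <- cut_after[cut_after < n & chars[cut_after + 1L] != "P"]
    starts <- c(1L, cut_after + 1L)
    ends <- c(cut_after, n)
    cum <- cumsum(ifelse(is.na(MONO_MASS[chars]), NaN,
                         unname(MONO_MASS[chars])))
    seg <- function(st, en) {
      cum[en] - ifelse(st > 1L, cum[pmax(st - 1L, 1L)], 0) + WATER_MASS
    }
    mass <- seg(starts, ends)
    if (missed_cleavages > 0L && length(starts) > 1L) {
      for (mc in seq_len(missed_cleavages)) {
        if (length(starts) > mc) {
          i <- seq_len(length(starts) - mc)
          mass <- c(mass, seg(starts[i], ends[i + mc]))
        }
      }
    }
    sum(mass >= mass_range[1] & mass <= mass_range[2], na.rm = TRUE)
  }, integer(1), USE.NAMES = FALSE)
}

#' Peptide-count-normalized MS intensity
#'
#' Summed precursor intensity divided by the number of expected (MS-suitable)
#' tryptic peptides, making intensities comparable across proteins of
#' different size. A protein with no MS-suitable peptide is unquantifiable
#' (NA with a warning).
#'
#' @param summed_intensity non-negative summed intensities.
#' @param n_ms_suitable MS-suitable peptide counts.
#' @return numeric normalized scores.
#' @export
normalized_intensity <- function(summed_intensity, n_ms_suitable) {
  if (any(summed_intensity < 0, na.rm = TRUE)) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  bad <- !is.na(n_ms_suitable) & n_ms_suitable == 0
  if (any(bad)) {
    warning(sprintf("%d proteins with no MS-suitable peptide are unquantifiable",
                    sum(bad)))
  }
  ifelse(bad, NA_real_, summed_intensity / n_ms_suitable)
}

## replicate-averaged normalized scores from an MS intensity table
ms_scores <- function(ms_table) {
  mean_int <- tapply(ms_table$intensity, ms_table$id, mean)
  n_ms <- tapply(ms_table$n_ms_suitable, ms_table$id, function(x) x[1])
  tibble::tibble(id = names(mean_int),
                 score = normalized_intensity(as.numeric(mean_int),
                                              as.numeric(n_ms)))
}

#' Fit the protein intensity-to-copies calibration model
#'
#' Averages intensities across replicates, normalizes by the MS-suitable
#' peptide count, and fits the same log-log anchor regression as the RNA
#' stage ([fit_anchor_model()]) on the heavy-peptide anchors. One model is
#' fitted per condition/sample table.
#'
#' @param ms_table an `ms_intensity_table` (columns `id`, `replicate`,
#'   `intensity`, `n_ms_suitable`, `anchor`, `known_copies`).
#' @param anchors optional tibble (`id`, `copies`); defaults to the anchors
#'   flagged in `ms_table`.
#' @return a `calibration_model`.
#' @export
fit_protein_model <- function(ms_table, anchors = NULL) {
  scores <- ms_scores(ms_table)
  if (is.null(anchors)) {
    an <- ms_table[ms_table$anchor & ms_table$replicate == ms_table$replicate[1], ]
    anchors <- tibble::tibble(id = an$id, copies = an$known_copies)
  }
  fit_anchor_model(scores, anchors)
}

#' Estimate protein copies/cell for all quantified proteins
#'
#' @param ms_table an `ms_intensity_table`.
#' @param model a `calibration_model` from [fit_protein_model()].
#' @return an `expression_table` (`id`, `copies`, `detected`).
#' @export
protein_copies <- function(ms_table, model) {
  scores <- ms_scores(ms_table)
  scores <- scores[!is.na(scores$score), , drop = FALSE]
  predict_copies(model, scores,
                 condition = attr(ms_table, "condition", exact = TRUE))
}

#' Replicate variability of MS intensities
#'
#' Percent coefficient of variation (100 * sd / mean, sample sd) per protein
#' across replicates, summarized by the number of quantified peptides
#' (classes 1, 2, 3+), mirroring how label-free variability is reported.
#'
#' @param ms_table an `ms_intensity_table` with >= 2 replicates.
#' @return a `replicate_stats`: list with `per_protein` tibble (`id`,
#'   `cv_pct`, `n_peptides`) and `by_peptide_class` summary tibble.
#' @export
replicate_cv <- function(ms_table) {
  if (length(unique(ms_table$replicate)) < 2L) {
    stop("need >= 2 replicates", call. = FALSE)
  }
  sp <- split(ms_table$intensity, ms_table$id)
  keep <- vapply(sp, function(x) any(x != 0), logical(1))
  if (any(!keep)) warning(sprintf("%d all-zero proteins skipped", sum(!keep)))
  sp <- sp[keep]
  cv <- vapply(sp, function(x) 100 * sd(x) / mean(x), numeric(1))
  n_pep <- tapply(ms_table$n_ms_suitable, ms_table$id, function(x) x[1])[names(sp)]
  per <- tibble::tibble(id = names(sp), cv_pct = unname(cv),
                        n_peptides = as.integer(n_pep))
  cls <- cut(per$n_peptides, breaks = c(0.5, 1.5, 2.5, Inf),
             labels = c("1", "2", "3+"))
  summ <- do.call(rbind, lapply(levels(cls), function(lv) {
    x <- per$cv_pct[cls == lv]
    tibble::tibble(peptide_class = lv, n = length(x),
                   median_cv = if (length(x)) median(x) else NA_real_,
                   mean_cv = if (length(x)) mean(x) else NA_real_)
  }))
  structure(list(per_protein = per, by_peptide_class = tibble::as_tibble(summ)),
            class = "replicate_stats")
}

#' @export
print.replicate_stats <- function(x, ...) {
  cat(sprintf("<replicate_stats> %d proteins\n", nrow(x$per_protein)))
  print(x$by_peptide_class)
  invisible(x)
}

#' Stoichiometry check for a 1:1 protein complex
#'
#' Ratios of each detected member to the member median, with the percent CV
#' across members and a flag for members deviating beyond `fold_threshold`.
#' Complexes with an expected 1:1 stoichiometry should show ratios near 1.
#'
#' @param expression an `expression_table` of protein copies.
#' @param complex_members character vector of member protein ids.
#' @param fold_threshold flag members with ratio above it or below its
#'   reciprocal.
#' @return list with `members` tibble (`id`, `copies`, `ratio`, `flagged`),
#'   `cv_pct`, `n_detected`; all NA when fewer than 2 members are detected.
#' @export
complex_stoichiometry <- function(expression, complex_members,
                                  fold_threshold = 2) {
  rows <- expression[expression$id %in% complex_members & expression$detected, ]
  if (nrow(rows) < 2L) {
    warning("fewer than 2 detected members; stoichiometry undefined")
    return(list(members = tibble::tibble(id = character(0), copies = numeric(0),
                                         ratio = numeric(0), flagged = logical(0)),
                cv_pct = NA_real_, n_detected = nrow(rows)))
  }
  med <- median(rows$copies)
  ratio <- rows$copies / med
  list(members = tibble::tibble(id = rows$id, copies = rows$copies,
                                ratio = ratio,
                                flagged = ratio > fold_threshold |
                                  ratio < 1 / fold_threshold),
       cv_pct = 100 * sd(rows$copies) / mean(rows$copies),
       n_detected = nrow(rows))
}
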