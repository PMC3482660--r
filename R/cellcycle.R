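#' Basal and peak copies of a periodic gene from the asynchronous average
#'
#' In an asynchronous culture the population-average copy number of a
#' cell-cycle-regulated gene mixes cells at basal and peak expression.
#' Assuming two discrete states related by the amplitude A (peak = A x basal)
#' and a fraction `f_peak` of the cycle at peak, conservation of molecules
#' gives `Cbas = Ctot / (A * f_peak + (1 - f_peak))` and `Cpeak = A * Cbas`.
#'
#' @param Ctot average copies/cell in the asynchronous population (>= 0).
#' @param A peak/basal fold amplitude; values below 1 are clamped to 1 with a
#'   warning (an amplitude is a fold difference).
#' @param f_peak fraction of the cycle at peak expression, in (0, 1).
#' @return list with numeric `Cbas` and `Cpeak` (vectorized over inputs).
#' @export
basal_peak <- function(Ctot, A, f_peak) {
  if (any(f_peak <= 0 | f_peak >= 1)) {
    stop("f_peak must be in (0, 1)", call. = FALSE)
  }
  if (any(Ctot < 0)) stop("Ctot must be >= 0", call. = FALSE)
  A <- clamp_amplitude(A)
  cbas <- Ctot / (A * f_peak + (1 - f_peak))
  list(Cbas = cbas, Cpeak = A * cbas)
}

clamp_amplitude <- function(A) {
  if (any(A < 1)) {
    warning("amplitudes below 1 clamped to 1")
    A <- pmax(A, 1)
  }
  A
}

## ramping term: cells transiting between basal and peak in nstep equal
## stages contribute A * (f_ramp/nstep) * sum_{k=1}^{nstep-1} k/nstep
ramp_term <- function(A, f_ramp, nstep) {
  A * (f_ramp / nstep) * (nstep - 1) / 2
}

#' Basal and peak copies allowing a ramping transition
#'
#' Extends [basal_peak()] with a ramping period: a fraction `f_ramp` of the
#' cycle during which expression climbs from basal to peak in `nstep` equal
#' increments of `A / nstep`. The population balance becomes
#' `Cbas = Ctot / (A * f_peak + (1 - f_peak - f_ramp) + R)` with the ramping
#' term `R = A * (f_ramp / nstep) * sum_{k=1}^{nstep-1} k / nstep`
#' (closed form `A * f_ramp * (nstep - 1) / (2 * nstep)`). With `f_ramp = 0`
#' this reduces exactly to the two-state model.
#'
#' @inheritParams basal_peak
#' @param f_ramp fraction of the cycle spent ramping, `f_peak + f_ramp <= 1`.
#' @param nstep number of intermediate stages (>= 1).
#' @return list with `Cbas`, `Cpeak` and the ramping term `R`.
#' @export
basal_peak_ramped <- function(Ctot, A, f_peak, f_ramp, nstep = 1000L) {
  if (any(f_peak <= 0 | f_peak >= 1)) {
    stop("f_peak must be in (0, 1)", call. = FALSE)
  }
  if (any(f_ramp < 0) || any(f_peak + f_ramp > 1)) {
    stop("need 0 <= f_ramp and f_peak + f_ramp <= 1", call. = FALSE)
  }
  if (any(nstep < 1)) stop("nstep must be >= 1", call. = FALSE)
  if (any(Ctot < 0)) stop("Ctot must be >= 0", call. = FALSE)
  A <- clamp_amplitude(A)
  R <- ramp_term(A, f_ramp, nstep)
  cbas <- Ctot / (A * f_peak + (1 - f_peak - f_ramp) + R)
  list(Cbas = cbas, Cpeak = A * cbas, R = R)
}

#' Brute-force basal/peak estimate from a discrete cell population
#'
#' Independent check of the closed-form deconvolution: builds an explicit
#' population of `n_cells` cells assigned to the basal compartment, the peak
#' compartment, and `nstep` ramp stages (stage k expresses `A * k / nstep`
#' times basal, k = 0..nstep-1), then solves for the basal level that makes
#' the population average equal `Ctot`.
#'
#' @inheritParams basal_peak_ramped
#' @param n_cells population size used for the discrete assignment.
#' @return list with `Cbas`, `Cpeak` and the realized population `average`
#'   (equals `Ctot` up to the discreteness of the assignment).
#' @export
simulate_phase_population <- function(Ctot, A, f_peak, f_ramp = 0,
                                      nstep = 1L, n_cells = 1e6) {
  stopifnot(length(Ctot) == 1L, f_peak > 0, f_peak < 1,
            f_ramp >= 0, f_peak + f_ramp <= 1, nstep >= 1)
  A <- clamp_amplitude(A)
  n_peak <- round(f_peak * n_cells)
  n_stage <- rep(round(f_ramp / nstep * n_cells), nstep)
  n_bas <- n_cells - n_peak - sum(n_stage)
  ## expression per compartment in units of the basal level
  w <- c(rep(1, 1), A, if (nstep >= 1) A * (seq_len(nstep) - 1) / nstep)
  counts <- c(n_bas, n_peak, n_stage)
  total_weight <- sum(w * counts)
  cbas <- Ctot * sum(counts) / total_weight
  list(Cbas = cbas, Cpeak = A * cbas,
       average = total_weight * cbas / sum(counts))
}

#' Classify the switch behaviour of one periodic gene
#'
#' Computes basal/peak copies per cell-cycle experiment from the gene's
#' per-experiment amplitudes, takes the medians across experiments, assigns
#' zones, and flags the gene as switch-like when the median basal level is in
#' zone 1 while the median peak level reaches zone 2 or 3 (expression
#' crossing the ~1 copy/cell threshold).
#'
#' @param Ctot asynchronous average copies/cell.
#' @param amplitudes numeric vector of per-experiment fold amplitudes.
#' @param f_peak fraction of the cycle at peak (default 0.1).
#' @param f_ramp,nstep optional ramping model (defaults: no ramping).
#' @param t_low,t_high zone thresholds passed to [zone_of()].
#' @return a `phase_profile` tibble row: `median_cbas`, `median_cpeak`,
#'   `basal_zone`, `peak_zone`, `switch`, `ramp_term`.
#' @export
classify_switch <- function(Ctot, amplitudes, f_peak = 0.1, f_ramp = 0,
                            nstep = 1000L, t_low = 0.5, t_high = 2) {
  if (length(amplitudes) < 1L) stop("need >= 1 amplitude", call. = FALSE)
  bp <- basal_peak_ramped(Ctot, amplitudes, f_peak, f_ramp, nstep)
  mb <- median(bp$Cbas)
  mp <- median(bp$Cpeak)
  bz <- zone_of(mb, t_low, t_high)
  pz <- zone_of(mp, t_low, t_high)
  out <- tibble::tibble(median_cbas = mb, median_cpeak = mp,
                        basal_zone = bz, peak_zone = pz,
                        switch = bz == 1L & pz %in% c(2L, 3L),
                        ramp_term = median(bp$R))
  class(out) <- c("phase_profile", class(out))
  out
}

#' Classify switch behaviour for a cohort of periodic genes
#'
#' @param genes tibble with columns `id`, `Ctot`, `cluster`, and `amplitudes`
#'   (a list column of per-experiment amplitude vectors).
#' @inheritParams classify_switch
#' @return tibble: one [classify_switch()] row per gene plus `id`, `cluster`.
#' @export
classify_switches <- function(genes, f_peak = 0.1, f_ramp = 0, nstep = 1000L,
                              t_low = 0.5, t_high = 2) {
  stopifnot(all(c("id", "Ctot", "amplitudes") %in% names(genes)))
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    classify_switch(genes$Ctot[i], genes$amplitudes[[i]], f_peak, f_ramp,
                    nstep, t_low, t_high)
  })
  out <- do.call(rbind, rows)
  out$id <- genes$id
  out$cluster <- if ("cluster" %in% names(genes)) genes$cluster else NA_character_
  out[, c("id", "cluster", setdiff(names(out), c("id", "cluster")))]
}

#' Scan switch counts over peak-length and ramping assumptions
#'
#' Counts switch-like genes per cell-cycle cluster across a grid of assumed
#' peak durations and ramping durations, showing how sensitive the switch
#' census is to the phase-fraction assumptions.
#'
#' @param genes as in [classify_switches()].
#' @param f_peak_grid,f_ramp_grid numeric grids; combinations violating
#'   `f_peak + f_ramp <= 1` are dropped.
#' @param nstep ramp stages.
#' @inheritParams classify_switch
#' @return tibble (`f_peak`, `f_ramp`, `cluster`, `n_switch`).
#' @export
peak_length_scan <- function(genes, f_peak_grid, f_ramp_grid = 0,
                             nstep = 1000L, t_low = 0.5, t_high = 2) {
  if (any(f_peak_grid <= 0 | f_peak_grid >= 1)) {
    stop("f_peak grid must be within (0, 1)", call. = FALSE)
  }
  grid <- expand.grid(f_peak = f_peak_grid, f_ramp = f_ramp_grid)
  grid <- grid[grid$f_peak + grid$f_ramp <= 1, , drop = FALSE]
  clusters <- sort(unique(genes$cluster))
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    cls <- classify_switches(genes, grid$f_peak[i], grid$f_ramp[i], nstep,
                             t_low, t_high)
    do.call(rbind, lapply(clusters, function(cl) {
      tibble::tibble(f_peak = grid$f_peak[i], f_ramp = grid$f_ramp[i],
                     cluster = cl,
                     n_switch = sum(cls$switch[cls$cluster == cl], na.rm = TRUE))
    }))
  }))
  tibble::as_tibble(out)
}

#' Periodic-gene table from a synthetic catalog and truth
#'
#' Convenience extractor pairing each periodic gene's asynchronous average
#' (the truth or an estimated expression table) with its per-experiment
#' amplitudes and cluster, ready for [classify_switches()].
#'
#' @param catalog a [generate_catalog()] result.
#' @param copies named copies/cell (or an `expression_table`).
#' @return tibble (`id`, `Ctot`, `cluster`, `amplitudes`).
#' @export
periodic_genes <- function(catalog, copies) {
  if (is.data.frame(copies)) {
    copies <- setNames(copies$copies, copies$id)
  }
  per <- catalog[catalog$periodic, ]
  tibble::tibble(id = per$id,
                 Ctot = as.numeric(copies[per$id]),
                 cluster = per$cluster,
                 amplitudes = per$amplitudes)
}
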