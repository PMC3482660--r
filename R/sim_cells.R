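#' Generate synthetic cell geometry measurements
#'
#' Draws per-cell length and diameter (micrometres) for the proliferating and
#' quiescent conditions. Quiescent cells are stubby: shorter at similar
#' diameter, so the median volume (capped-rod formula, see [cell_volume()])
#' drops to roughly 55% of proliferating cells.
#'
#' @param config a [sim_config()].
#' @return a tibble (`cell_id`, `condition`, `length_um`, `diameter_um`).
#' @export
generate_cells <- function(config) {
  validate_sim_config(config)
  if (any(config$cell_length_mean <= 0) || config$cell_diameter_mean <= 0) {
    stop("geometry scales must be positive", call. = FALSE)
  }
  set.seed(stage_seed(config, 50L))
  conds <- c("proliferating", "quiescent")
  out <- do.call(rbind, lapply(conds, function(cond) {
    d <- rnorm(config$n_cells, config$cell_diameter_mean, config$cell_diameter_sd)
    l <- rnorm(config$n_cells, config$cell_length_mean[[cond]], config$cell_length_sd)
    d <- pmax(d, 0.5)
    l <- pmax(l, d * 1.05)
    tibble::tibble(cell_id = sprintf("%s_%03d", cond, seq_len(config$n_cells)),
                   condition = cond, length_um = l, diameter_um = d)
  }))
  tibble::as_tibble(out)
}

#' Generate a synthetic quiescence-entry time course
#'
#' Emulates a microarray time course after nitrogen removal: per-gene
#' expression ratios relative to time zero, hybridized at equal RNA mass, plus
#' the fraction of total RNA per cell remaining at each time point (monotone
#' decline `plateau + (1 - plateau) * exp(-t / tau)`, exactly 1 at t = 0).
#' Because equal RNA mass is hybridized, the observed ratios are the true
#' absolute ratios divided by the RNA content fraction; [correct_timecourse()]
#' undoes exactly this. Category-specific true trajectories: `stress` genes
#' burst transiently before declining, `translation` genes decline faster than
#' total RNA, other genes track it.
#'
#' @param truth a [generate_truth()] result (mRNA rows define the gene set;
#'   categories are taken from the catalog when supplied).
#' @param config a [sim_config()].
#' @param catalog optional [generate_catalog()] result supplying categories.
#' @return a `timecourse_table`: list with `times` (hours), `content_fraction`
#'   (per time point), `ratios` (genes x time observed matrix, 1 at t = 0) and
#'   `absolute_ratio` (the underlying truth, for validation).
#' @export
generate_timecourse <- function(truth, config, catalog = NULL) {
  validate_sim_config(config)
  set.seed(stage_seed(config, 60L))
  t <- config$timepoints
  content <- config$rna_content_plateau +
    (1 - config$rna_content_plateau) * exp(-t / config$rna_content_tau)
  names(content) <- paste0("t", t)

  genes <- truth$rna$id[truth$rna$class == "mRNA"]
  cats <- rep(NA_character_, length(genes))
  if (!is.null(catalog)) cats <- catalog$category[match(genes, catalog$id)]

  base <- matrix(rep(content, each = length(genes)),
                 nrow = length(genes), dimnames = list(genes, names(content)))
  burst <- 1 + 3 * (t / 2) * exp(1 - t / 2)   # peaks ~3h after removal
  absolute <- base
  is_stress <- !is.na(cats) & cats == "stress"
  is_growth <- !is.na(cats) & cats == "translation"
  if (any(is_stress)) {
    absolute[is_stress, ] <- outer(rep(1, sum(is_stress)), content^0.8 * burst)
  }
  if (any(is_growth)) {
    absolute[is_growth, ] <- outer(rep(1, sum(is_growth)), content^1.3)
  }
  ## per-gene multiplicative measurement noise, none at t = 0
  noise <- matrix(rlnorm(length(absolute), 0, 0.05), nrow = nrow(absolute))
  noise[, 1] <- 1
  observed <- sweep(absolute, 2, content, "/") * noise

  out <- list(times = t, content_fraction = content,
              ratios = observed, absolute_ratio = absolute)
  class(out) <- "timecourse_table"
  out
}

#' @export
print.timecourse_table <- function(x, ...) {
  cat(sprintf("<timecourse_table> %d genes x %d time points (%g-%g h)\n",
              nrow(x$ratios), length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  RNA content fraction: 1 -> %.3f\n", min(x$content_fraction)))
  invisible(x)
}
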