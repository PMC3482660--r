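#' Cell volume of a capped rod
#'
#' Rod-shaped cells of length L and diameter D (hemispherical caps) have
#' volume `V = pi * D^2 * (L - D/3) / 4` cubic micrometres. With `L = D` this
#' reduces to the sphere volume `pi * D^3 / 6`.
#'
#' @param L cell length (micrometres), `L >= D`.
#' @param D cell diameter (micrometres), `> 0`.
#' @return volume in cubic micrometres (vectorized).
#' @export
cell_volume <- function(L, D) {
  if (any(D <= 0)) stop("diameter must be > 0", call. = FALSE)
  if (any(L < D)) stop("length must be >= diameter (capped rod)", call. = FALSE)
  pi * D^2 * (L - D / 3) / 4
}

#' Median cell volumes per condition
#'
#' @param cells a [generate_cells()]-style tibble (`condition`, `length_um`,
#'   `diameter_um`).
#' @return named numeric vector of median volumes per condition.
#' @export
median_volumes <- function(cells) {
  v <- cell_volume(cells$length_um, cells$diameter_um)
  tapply(v, cells$condition, median)
}

total_copies <- function(x) {
  if (is.numeric(x) && length(x) == 1L) return(x)
  sum(as_copies(x))
}

#' Per-cell and per-volume retention between two conditions
#'
#' Total copies in condition B as a percentage of condition A (per-cell
#' retention), and the same after adjusting for the volume change
#' (per-volume retention = per-cell retention divided by the volume ratio
#' B/A). A molecule class that scales with cell volume keeps a per-volume
#' retention near 100% even when per-cell totals drop.
#'
#' @param expr_a,expr_b `expression_table`s (or precomputed numeric totals)
#'   for conditions A and B.
#' @param vol_a,vol_b (median) cell volumes of the two conditions.
#' @return a `condition_comparison`: list with `total_a`, `total_b`,
#'   `per_cell_pct`, `per_volume_pct`, `volume_ratio`.
#' @export
retention_stats <- function(expr_a, expr_b, vol_a = 1, vol_b = 1) {
  if (vol_a <= 0 || vol_b <= 0) stop("volumes must be positive", call. = FALSE)
  ta <- total_copies(expr_a)
  tb <- total_copies(expr_b)
  if (ta <= 0 || tb <= 0) stop("totals must be positive", call. = FALSE)
  per_cell <- 100 * tb / ta
  structure(list(total_a = ta, total_b = tb,
                 per_cell_pct = per_cell,
                 per_volume_pct = per_cell / (vol_b / vol_a),
                 volume_ratio = vol_b / vol_a),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> totals %.4g -> %.4g\n", x$total_a, x$total_b))
  cat(sprintf("  per-cell retention %.1f%%, per-volume %.1f%% (volume ratio %.3f)\n",
              x$per_cell_pct, x$per_volume_pct, x$volume_ratio))
  invisible(x)
}

#' Census of fold changes between two conditions
#'
#' Classifies every feature of the shared universe by its B/A fold change:
#' more than `threshold`-fold up, more than `threshold`-fold down, or within
#' (ratios exactly at the threshold count as within); features detected in
#' only one condition are reported separately.
#'
#' @param expr_a,expr_b `expression_table`s on a shared universe.
#' @param threshold fold-change threshold (default 2).
#' @return list with `n_up`, `n_down`, `n_within`, `n_only_a`, `n_only_b`,
#'   `n_undetected`, `universe_size`, and the per-feature `table`.
#' @export
fold_change_census <- function(expr_a, expr_b, threshold = 2) {
  universe <- union(expr_a$id, expr_b$id)
  a <- expr_a$copies[match(universe, expr_a$id)]
  da <- expr_a$detected[match(universe, expr_a$id)] %in% TRUE
  b <- expr_b$copies[match(universe, expr_b$id)]
  db <- expr_b$detected[match(universe, expr_b$id)] %in% TRUE
  both <- da & db
  ratio <- ifelse(both, b / a, NA_real_)
  cls <- rep("undetected", length(universe))
  cls[da & !db] <- "only_a"
  cls[!da & db] <- "only_b"
  cls[both] <- ifelse(ratio[both] > threshold, "up",
                      ifelse(ratio[both] < 1 / threshold, "down", "within"))
  tab <- tibble::tibble(id = universe, copies_a = a, copies_b = b,
                        ratio = ratio, class = cls)
  list(n_up = sum(cls == "up"), n_down = sum(cls == "down"),
       n_within = sum(cls == "within"),
       n_only_a = sum(cls == "only_a"), n_only_b = sum(cls == "only_b"),
       n_undetected = sum(cls == "undetected"),
       universe_size = length(universe), table = tab)
}

#' Correct a time course for total-RNA content per cell
#'
#' Expression ratios measured at equal RNA mass are compositional: a gene
#' whose absolute abundance tracks the global RNA decline appears flat.
#' Multiplying each time point's ratios by the fraction of total RNA per cell
#' remaining at that time restores absolute (per-cell) trajectories.
#'
#' @param tc a `timecourse_table` ([generate_timecourse()]): list with
#'   `times`, `content_fraction`, and a genes-by-time `ratios` matrix.
#' @return `tc` with `ratios` replaced by content-corrected ratios (time
#'   points without a content fraction are dropped with a warning).
#' @export
correct_timecourse <- function(tc) {
  stopifnot(is.list(tc), !is.null(tc$ratios), !is.null(tc$content_fraction))
  frac <- tc$content_fraction[colnames(tc$ratios)]
  missing <- is.na(frac)
  if (any(missing)) {
    warning(sprintf("%d time points without content fraction dropped",
                    sum(missing)))
  }
  out <- tc
  out$ratios <- sweep(tc$ratios[, !missing, drop = FALSE], 2,
                      frac[!missing], "*")
  out$times <- tc$times[!missing]
  out$content_fraction <- frac[!missing]
  out
}

#' Protein/mRNA ratio analysis
#'
#' Per-gene protein-to-mRNA copy ratios for genes detected in both tables,
#' a sliding median of the ratio along the protein-abundance rank, summary
#' statistics (mean and median of per-gene ratios, ratio of totals, ratio of
#' medians), and a rank-based location test comparing a highlighted group
#' (e.g. ribosomal proteins) against abundance-matched background genes
#' (nearest protein-abundance rank matching).
#'
#' @param rna,prot `expression_table`s of mRNA and protein copies.
#' @param highlight optional ids of a group to contrast.
#' @param window sliding-median window (genes).
#' @return list with `per_gene` tibble (`id`, `mrna`, `protein`, `ratio`,
#'   `sliding_median`, ordered by protein abundance), `summary`,
#'   `n_excluded_zero_mrna`, and (if `highlight` given) `group_test` with the
#'   Wilcoxon p value.
#' @export
protein_mrna_ratios <- function(rna, prot, highlight = NULL, window = 200L) {
  m <- merge(data.frame(id = rna$id, mrna = rna$copies, dr = rna$detected),
             data.frame(id = prot$id, protein = prot$copies, dp = prot$detected),
             by = "id")
  m <- m[m$dr %in% TRUE & m$dp %in% TRUE, , drop = FALSE]
  zero <- m$mrna == 0
  n_excl <- sum(zero)
  if (n_excl > 0) m <- m[!zero, , drop = FALSE]
  if (nrow(m) == 0L) stop("no genes detected in both tables", call. = FALSE)
  m <- m[order(m$protein, m$id), ]
  ratio <- m$protein / m$mrna
  k <- min(nrow(m), window)
  k <- if (k %% 2 == 0) k + 1 else k
  sliding <- if (nrow(m) >= k) {
    as.numeric(runmed(ratio, k, endrule = "median"))
  } else rep(median(ratio), nrow(m))

  per_gene <- tibble::tibble(id = m$id, mrna = m$mrna, protein = m$protein,
                             ratio = ratio, sliding_median = sliding)
  summary <- list(mean_ratio = mean(ratio), median_ratio = median(ratio),
                  ratio_of_totals = sum(m$protein) / sum(m$mrna),
                  ratio_of_medians = median(m$protein) / median(m$mrna),
                  range = range(ratio))
  out <- list(per_gene = per_gene, summary = summary,
              n_excluded_zero_mrna = n_excl)

  if (!is.null(highlight)) {
    hi <- which(per_gene$id %in% highlight)
    bg <- which(!per_gene$id %in% highlight)
    if (length(hi) >= 2L && length(bg) >= 2L) {
      ## nearest-rank matching on protein abundance (rows are rank-ordered)
      matched <- vapply(hi, function(i) bg[which.min(abs(bg - i))], integer(1))
      test <- wilcox.test(per_gene$ratio[hi], per_gene$ratio[matched])
      out$group_test <- list(p_value = test$p.value,
                             n_group = length(hi),
                             median_group = median(per_gene$ratio[hi]),
                             median_matched = median(per_gene$ratio[matched]))
    }
  }
  out
}
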