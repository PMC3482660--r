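#' Expression zone of a copy number
#'
#' Three abundance strata set relative to the one-copy/cell mark: zone 1
#' below `t_low` copies/cell (tightly repressed), zone 2 between `t_low` and
#' `t_high` inclusive (around one copy/cell), zone 3 above `t_high` (robust
#' expression). Boundary values belong to zone 2.
#'
#' @param copies non-negative copies/cell.
#' @param t_low,t_high zone thresholds (defaults 0.5 and 2 copies/cell).
#' @return integer zones (1, 2 or 3).
#' @export
zone_of <- function(copies, t_low = 0.5, t_high = 2) {
  if (any(copies < 0, na.rm = TRUE)) stop("copies must be >= 0", call. = FALSE)
  ifelse(copies < t_low, 1L, ifelse(copies > t_high, 3L, 2L))
}

#' Zone summary over a gene universe
#'
#' Counts and fractions of the universe per expression zone, the fraction of
#' each zone with a detected protein, median copies per zone, and the
#' fraction of zone-2/3 features below 10 copies/cell. Universe members
#' absent from the expression table (or not detected) form a separate
#' "no signal" bucket, never zone 1.
#'
#' @param expression an `expression_table` (`id`, `copies`, `detected`).
#' @param detected_proteins ids with a detected protein.
#' @param universe the gene universe (default: ids in `expression`).
#' @param t_low,t_high zone thresholds.
#' @return a `zone_summary`: list with `zones` tibble (`zone`, `n`,
#'   `fraction`, `pct`, `n_protein`, `protein_pct`, `median_copies`),
#'   `universe_size`, `n_no_signal`, `pct_zone23_below10`.
#' @export
zone_summary <- function(expression, detected_proteins = character(0),
                         universe = expression$id, t_low = 0.5, t_high = 2) {
  if (length(universe) == 0L) stop("universe must be nonempty", call. = FALSE)
  expr <- expression[expression$id %in% universe & expression$detected &
                       !is.na(expression$copies), ]
  no_signal <- setdiff(universe, expr$id)
  z <- zone_of(expr$copies, t_low, t_high)
  n_u <- length(universe)
  zones <- do.call(rbind, lapply(1:3, function(k) {
    in_z <- expr$id[z == k]
    tibble::tibble(
      zone = k, n = length(in_z),
      fraction = length(in_z) / n_u,
      pct = percent_of(length(in_z), n_u),
      n_protein = sum(in_z %in% detected_proteins),
      protein_pct = if (length(in_z)) {
        percent_of(sum(in_z %in% detected_proteins), length(in_z))
      } else NA_real_,
      median_copies = if (length(in_z)) median(expr$copies[z == k]) else NA_real_
    )
  }))
  z23 <- expr$copies[z %in% c(2L, 3L)]
  structure(list(zones = tibble::as_tibble(zones),
                 universe_size = n_u,
                 n_no_signal = length(no_signal),
                 pct_zone23_below10 = if (length(z23)) {
                   percent_of(sum(z23 < 10), length(z23))
                 } else NA_real_),
            class = "zone_summary")
}

#' @export
print.zone_summary <- function(x, ...) {
  cat(sprintf("<zone_summary> universe %d, no signal %d\n",
              x$universe_size, x$n_no_signal))
  print(x$zones)
  cat(sprintf("  zone 2-3 below 10 copies: %.1f%%\n", x$pct_zone23_below10))
  invisible(x)
}

#' Percentage with one-decimal reporting
#'
#' Bookkeeping helper used by the summaries: `100 * n / total`, rounded to
#' `digits` decimals (matching how such fractions are conventionally printed).
#'
#' @param n,total counts.
#' @param digits decimals to round to.
#' @return numeric percentage.
#' @export
percent_of <- function(n, total, digits = 1) round(100 * n / total, digits)

## extract detected copies from an expression table or pass numerics through
as_copies <- function(x) {
  if (is.numeric(x)) return(x[!is.na(x)])
  stopifnot(is.data.frame(x), all(c("copies", "detected") %in% names(x)))
  x$copies[x$detected & !is.na(x$copies)]
}

#' Cumulative expression share of the top-ranked features
#'
#' Fraction of all molecules contributed by the top `top_fraction` most
#' abundant features (the "20-80" skew of expression).
#'
#' @param expression an `expression_table` or numeric abundances.
#' @param top_fraction fraction of features to take from the top, in (0, 1].
#' @return the share of total molecules, in `[0, 1]`.
#' @export
cumulative_share <- function(expression, top_fraction) {
  v <- as_copies(expression)
  if (length(v) == 0L) stop("empty expression table", call. = FALSE)
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must be in (0, 1]", call. = FALSE)
  }
  v <- sort(v, decreasing = TRUE)
  k <- ceiling(top_fraction * length(v))
  sum(v[seq_len(k)]) / sum(v)
}

#' Power-law fit of abundance versus expression rank
#'
#' Least squares of log(abundance) on log(rank) over a declared rank range;
#' the slope is the power-law exponent (Zipf-style rank plots).
#'
#' @param expression an `expression_table` or numeric abundances.
#' @param rank_range integer vector `c(first, last)` of ranks to fit
#'   (default: all ranks).
#' @return a `rank_fit`: list with `exponent`, `intercept`, `rank_range`.
#' @export
powerlaw_rank_fit <- function(expression, rank_range = NULL) {
  v <- sort(as_copies(expression), decreasing = TRUE)
  n <- length(v)
  if (n < 3L) stop("need >= 3 abundances", call. = FALSE)
  if (is.null(rank_range)) rank_range <- c(1L, n)
  if (rank_range[1] < 1L || rank_range[2] > n || rank_range[1] >= rank_range[2]) {
    stop("rank_range must lie within the data", call. = FALSE)
  }
  r <- seq(rank_range[1], rank_range[2])
  y <- v[r]
  pos <- y > 0
  if (any(!pos)) {
    warning(sprintf("%d zero abundances in range excluded", sum(!pos)))
    r <- r[pos]; y <- y[pos]
  }
  cf <- ols_loglog(log(r), log(y))
  structure(list(exponent = unname(cf["slope"]),
                 intercept = unname(cf["intercept"]),
                 rank_range = rank_range),
            class = "rank_fit")
}

#' @export
print.rank_fit <- function(x, ...) {
  cat(sprintf("<rank_fit> exponent %.4f over ranks %d-%d\n",
              x$exponent, x$rank_range[1], x$rank_range[2]))
  invisible(x)
}
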