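#' Reads per kilobase (RPK)
#'
#' The relative sequencing expression score: reads mapped to a feature divided
#' by the feature length in kilobases.
#'
#' @param reads non-negative read counts.
#' @param length_nt feature lengths in nucleotides (>= 1).
#' @return numeric scores, `reads / (length_nt / 1000)`.
#' @export
compute_rpk <- function(reads, length_nt) {
  if (any(length_nt < 1)) stop("length_nt must be >= 1", call. = FALSE)
  if (any(reads < 0)) stop("reads must be >= 0", call. = FALSE)
  reads / (length_nt / 1000)
}

rpk_of <- function(tbl) compute_rpk(tbl$reads, tbl$length_nt)

#' Mappability correction factors from simulated reads
#'
#' Scores derived from uniform simulated coverage of the genome are
#' median-centred and used as correction factors: a feature whose simulated
#' RPK is half the median has factor 0.5, and dividing its observed RPK by the
#' factor undoes the mappability bias. Features with zero simulated RPK are
#' flagged unquantifiable (no coverage can reach them).
#'
#' @param simulated a `read_count_table` from simulated reads covering all
#'   features.
#' @return a `correction_factors` tibble (`id`, `factor`, `unquantifiable`)
#'   with a `provenance` attribute.
#' @export
mappability_factors <- function(simulated) {
  if (is.null(simulated) || nrow(simulated) == 0L) {
    stop("empty simulated read table", call. = FALSE)
  }
  rpk <- rpk_of(simulated)
  unq <- rpk == 0
  med <- median(rpk[!unq])
  out <- tibble::tibble(id = simulated$id,
                        factor = ifelse(unq, NA_real_, rpk / med),
                        unquantifiable = unq)
  class(out) <- c("correction_factors", class(out))
  attr(out, "provenance") <- attr(simulated, "sample_type", exact = TRUE)
  out
}

#' Apply mappability correction to RPK scores
#'
#' @param rpk a tibble (`id`, `score`) of raw RPK scores, or a
#'   `read_count_table` (converted via [compute_rpk()]).
#' @param factors a [mappability_factors()] result.
#' @return tibble (`id`, `score`) of corrected scores; features without a
#'   defined factor are dropped with a warning.
#' @export
apply_correction <- function(rpk, factors) {
  if (inherits(rpk, "read_count_table")) {
    rpk <- tibble::tibble(id = rpk$id, score = rpk_of(rpk))
  }
  f <- factors$factor[match(rpk$id, factors$id)]
  missing <- is.na(f)
  if (any(missing)) {
    warning(sprintf("%d features without correction factor dropped", sum(missing)))
  }
  tibble::tibble(id = rpk$id[!missing], score = rpk$score[!missing] / f[!missing])
}

#' DNA-over-simulated sequencibility ratios
#'
#' Compares median-centred RPK from genomic DNA sequencing with median-centred
#' RPK from simulated reads. Ratios well below 1 mark regions that are hard to
#' sequence; ratios well above 1 mark features whose genomic copy number
#' exceeds the annotation (duplicated rRNA genes, subtelomeric duplications).
#'
#' @param dna_counts,simulated `read_count_table`s over the same feature set.
#' @param low,high flagging thresholds on the ratio.
#' @return tibble (`id`, `ratio`, `flag` in `ok`/`low`/`high`/`undefined`)
#'   with attribute `n_flagged`.
#' @export
sequencibility <- function(dna_counts, simulated, low = 0.5, high = 2) {
  ids <- dna_counts$id
  if (!setequal(ids, simulated$id)) {
    stop("DNA and simulated tables must cover the same features", call. = FALSE)
  }
  d <- rpk_of(dna_counts)
  s <- rpk_of(simulated)[match(ids, simulated$id)]
  dc <- d / median(d)
  sc <- s / median(s)
  ratio <- ifelse(sc == 0, NA_real_, dc / sc)
  flag <- ifelse(is.na(ratio), "undefined",
                 ifelse(ratio < low, "low", ifelse(ratio > high, "high", "ok")))
  out <- tibble::tibble(id = ids, ratio = ratio, flag = flag)
  attr(out, "n_flagged") <- sum(flag != "ok")
  out
}

#' Absolute copies for calibration mRNAs from spike-in regression
#'
#' Per technical replicate, a log-log least-squares line is fitted to the
#' external controls (known copies/cell versus observed counts) and inverted
#' to predict copies/cell for the calibration mRNAs. Replicate predictions are
#' averaged in linear space, first within and then between instrument runs.
#'
#' @param run an `ncounter_run` (see [generate_ncounter()] for the layout:
#'   columns `probe`, `role`, `known_copies`, `replicate`, `run`, `counts`).
#' @return tibble (`id`, `copies`) of anchor copies/cell.
#' @export
calibrate_spikes <- function(run) {
  reps <- split(run, run$replicate)
  per_rep <- lapply(reps, function(tb) {
    sp <- tb[tb$role == "spike", ]
    usable <- sp$counts > 0
    if (any(!usable)) {
      warning(sprintf("replicate %s: %d spikes with zero counts excluded",
                      tb$replicate[1], sum(!usable)))
    }
    sp <- sp[usable, ]
    if (nrow(sp) < 3L) {
      stop("fewer than 3 usable spikes in a replicate", call. = FALSE)
    }
    fit <- lm(log(known_copies) ~ log(counts), data = sp)
    an <- tb[tb$role == "anchor", ]
    pred <- exp(predict(fit, newdata = data.frame(counts = an$counts)))
    tibble::tibble(id = an$probe, run = an$run, copies = pred)
  })
  all <- do.call(rbind, per_rep)
  ## mean within each run, then mean across runs
  by_run <- stats::aggregate(copies ~ id + run, data = all, FUN = mean)
  final <- stats::aggregate(copies ~ id, data = by_run, FUN = mean)
  tibble::as_tibble(final[match(unique(all$id), final$id), c("id", "copies")])
}

#' Fit the log-log calibration model from anchor features
#'
#' Ordinary least squares of log(copies/cell) on log(relative score) over the
#' anchor set. The natural log is used internally; predictions from
#' [predict_copies()] are invariant to that choice because the fit is affine
#' in log space.
#'
#' @param scores tibble (`id`, `score`) of corrected relative scores.
#' @param anchors tibble (`id`, `copies`) of absolutely quantified anchors.
#' @return a `calibration_model` (slope, intercept, residual spread `sigma`,
#'   `n_anchors`, `log_base`).
#' @export
fit_anchor_model <- function(scores, anchors) {
  d <- merge(as.data.frame(anchors), as.data.frame(scores), by = "id")
  bad <- d$score <= 0 | d$copies <= 0
  if (any(bad)) {
    warning(sprintf("%d anchors with non-positive score or copies excluded",
                    sum(bad)))
    d <- d[!bad, , drop = FALSE]
  }
  if (nrow(d) < 3L) stop("need >= 3 usable anchors", call. = FALSE)
  fit <- lm(log(copies) ~ log(score), data = d)
  sigma <- sqrt(sum(fit$residuals^2) / fit$df.residual)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         sigma = sigma, n_anchors = nrow(d), log_base = "natural"),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> log(copies) = %.4f + %.4f * log(score)\n",
              x$intercept, x$slope))
  cat(sprintf("  residual spread %.4f (natural log), %d anchors\n",
              x$sigma, x$n_anchors))
  invisible(x)
}

#' Predict absolute copies/cell from relative scores
#'
#' Applies a fitted [fit_anchor_model()] line in log space and exponentiates.
#' Zero scores are reported as not detected (no copies value) rather than
#' zero copies; negative scores are rejected.
#'
#' @param model a `calibration_model`.
#' @param scores tibble (`id`, `score`) or a numeric vector of scores.
#' @param condition optional condition label stored on the result.
#' @return an `expression_table` tibble (`id`, `copies`, `detected`).
#' @export
predict_copies <- function(model, scores, condition = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  if (is.numeric(scores)) {
    scores <- tibble::tibble(id = names(scores) %||% as.character(seq_along(scores)),
                             score = unname(scores))
  }
  if (any(scores$score < 0)) stop("negative scores are invalid", call. = FALSE)
  detected <- scores$score > 0
  copies <- rep(NA_real_, nrow(scores))
  copies[detected] <- exp(model$intercept +
                            model$slope * log(scores$score[detected]))
  out <- tibble::tibble(id = scores$id, copies = copies, detected = detected)
  class(out) <- c("expression_table", class(out))
  attr(out, "condition") <- condition
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## closed-form simple OLS in log space; fast path for resampling
ols_loglog <- function(logx, logy) {
  mx <- mean(logx); my <- mean(logy)
  slope <- sum((logx - mx) * (logy - my)) / sum((logx - mx)^2)
  c(intercept = my - slope * mx, slope = slope)
}

#' Bootstrap fold-error estimate of a calibration
#'
#' Resamples the anchors with replacement, refits the log-log line, predicts
#' the copies of every anchor from its score and compares with the anchor's
#' true copies. The per-anchor fold error is `exp(|log(pred) - log(true)|)`
#' averaged over resamples; degenerate resamples (all anchors identical) are
#' skipped. With a perfect fit every fold error is exactly 1.
#'
#' @param scores,anchors as in [fit_anchor_model()].
#' @param n_resamples number of bootstrap resamples (>= 100).
#' @return an `error_estimate`: list with `per_anchor` tibble (`id`,
#'   `fold_error`), `mean_fold_error` and `n_resamples`.
#' @export
bootstrap_fold_error <- function(scores, anchors, n_resamples = 1000L) {
  if (n_resamples < 100L) stop("n_resamples must be >= 100", call. = FALSE)
  d <- merge(as.data.frame(anchors), as.data.frame(scores), by = "id")
  d <- d[d$score > 0 & d$copies > 0, , drop = FALSE]
  if (nrow(d) < 3L) stop("need >= 3 usable anchors", call. = FALSE)
  lx <- log(d$score); ly <- log(d$copies)
  n <- nrow(d)
  acc <- matrix(NA_real_, nrow = n_resamples, ncol = n)
  for (b in seq_len(n_resamples)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(lx[idx])) < 2L) next   # degenerate resample
    cf <- ols_loglog(lx[idx], ly[idx])
    pred <- cf[1] + cf[2] * lx
    acc[b, ] <- exp(abs(pred - ly))
  }
  per_anchor <- colMeans(acc, na.rm = TRUE)
  out <- list(per_anchor = tibble::tibble(id = d$id, fold_error = per_anchor),
              mean_fold_error = mean(per_anchor),
              n_resamples = n_resamples)
  class(out) <- "error_estimate"
  out
}

#' @export
print.error_estimate <- function(x, ...) {
  cat(sprintf("<error_estimate> mean fold error %.3f over %d anchors (%d resamples)\n",
              x$mean_fold_error, nrow(x$per_anchor), x$n_resamples))
  invisible(x)
}
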