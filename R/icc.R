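# Intraclass correlation and the missing-day reliability simulation.
#
# How reliable is a k-day activity average relative to the full monitoring
# week? For each participant of a perfectly compliant panel (7 valid days:
# 5 weekdays, 2 weekend days), k days are drawn at random, averaged, and
# compared to the 7-day reference average with an ICC across participants.
# The subset shares its days with the reference, so the reliability exceeds
# the naive Spearman-Brown value for an independent k-day mean; closed-form
# or simulated oracles must account for that overlap.

#' Intraclass correlation of paired measurements
#'
#' Two-way single-measure ICC between two measurements per subject, from
#' the standard ANOVA mean-square decomposition with k = 2 raters. The
#' default absolute-agreement form penalises systematic shifts between the
#' measurements; the consistency form does not.
#'
#' @param x,y paired measurements (one pair per subject)
#' @param type `"agreement"` (ICC(A,1), default) or `"consistency"`
#'   (ICC(C,1))
#' @return list with `icc`, `type`, `n`, and the mean squares (`msr` rows,
#'   `msc` columns, `mse` error)
#' @export
icc_agreement <- function(x, y, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) stop("ICC needs at least 2 subjects")
  k <- 2
  grand <- mean(c(x, y))
  row_means <- (x + y) / 2
  col_means <- c(mean(x), mean(y))
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((x - grand)^2) + sum((y - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- if (type == "agreement")
    msr + (k - 1) * mse + k / n * (msc - mse)
  else msr + (k - 1) * mse
  if (denom <= 0 || !is.finite(denom))
    return(list(icc = NA_real_, type = type, n = n, msr = msr, msc = msc,
                mse = mse, undefined = TRUE))
  list(icc = (msr - mse) / denom, type = type, n = n,
       msr = msr, msc = msc, mse = mse, undefined = FALSE)
}

#' Missing-day reliability simulation
#'
#' For each participant, one random permutation of the 7 days is drawn and
#' its first k days are averaged, for k = 1..6 against the 7-day average,
#' k = 1..4 of the 5 weekdays against the weekday average, and k = 1 of the
#' 2 weekend days against the weekend average. Nested subsets (the first k
#' of one permutation) make the reliability curve monotone in k draw by
#' draw. One draw per participant per k; replication across seeds is the
#' caller's loop.
#'
#' @param panel a day-summary panel as from [generate_day_summary_panel()]:
#'   columns `participant_id`, `day`, `is_weekend`, `value` (or the columns
#'   named by `metrics`), exactly 7 days per participant (5 weekday, 2
#'   weekend)
#' @param seed RNG seed for the subset draws
#' @param metrics names of the value columns to analyse
#' @param type ICC form, see [icc_agreement()]
#' @return data.frame with `metric`, `comparison` (`vs_7day`,
#'   `vs_weekday5`, `vs_weekend2`), `k`, `n`, `icc`
#' @export
run_missing_day_simulation <- function(panel, seed = 1L, metrics = "value",
                                       type = c("agreement", "consistency")) {
  type <- match.arg(type)
  stopifnot(all(c("participant_id", "day", "is_weekend") %in% names(panel)),
            all(metrics %in% names(panel)))
  ids <- unique(panel$participant_id)
  n <- length(ids)
  cnt <- table(panel$participant_id)
  if (any(cnt != 7)) stop("panel must contain exactly 7 days per participant")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  ord <- order(match(panel$participant_id, ids), panel$day)
  panel <- panel[ord, , drop = FALSE]
  we <- matrix(panel$is_weekend, nrow = n, ncol = 7, byrow = TRUE)
  if (any(rowSums(we) != 2))
    stop("each participant needs 5 weekdays and 2 weekend days")

  # one permutation per participant; subsets are its prefixes
  perm <- t(vapply(seq_len(n), function(i) sample.int(7), integer(7)))

  out <- NULL
  for (metric in metrics) {
    vals <- matrix(panel[[metric]], nrow = n, ncol = 7, byrow = TRUE)
    ref7 <- rowMeans(vals)
    wd_ix <- t(apply(we, 1, function(r) which(!r)))
    wk_ix <- t(apply(we, 1, function(r) which(r)))
    refwd <- rowMeans(matrix(vals[cbind(rep(seq_len(n), 5), as.vector(wd_ix))],
                             n, 5))
    refwk <- rowMeans(matrix(vals[cbind(rep(seq_len(n), 2), as.vector(wk_ix))],
                             n, 2))

    subset_mean <- function(source_ix) {
      # prefixes of one per-participant permutation of the day pool
      # `source_ix` (a matrix n x pool-size)
      pool <- ncol(source_ix)
      pperm <- t(vapply(seq_len(n), function(i) sample.int(pool), integer(pool)))
      function(kk) {
        ix <- pperm[, seq_len(kk), drop = FALSE]
        sel <- matrix(source_ix[cbind(rep(seq_len(n), kk), as.vector(ix))],
                      n, kk)
        rowMeans(matrix(vals[cbind(rep(seq_len(n), kk), as.vector(sel))],
                        n, kk))
      }
    }

    # vs the 7-day average: first k of the all-day permutation
    for (k in 1:6) {
      sub <- rowMeans(matrix(vals[cbind(rep(seq_len(n), k),
                                        as.vector(perm[, seq_len(k), drop = FALSE]))],
                             n, k))
      out <- rbind(out, data.frame(
        metric = metric, comparison = "vs_7day", k = k, n = n,
        icc = icc_agreement(sub, ref7, type)$icc))
    }
    # vs the 5-weekday average
    wd_sub <- subset_mean(wd_ix)
    for (k in 1:4)
      out <- rbind(out, data.frame(
        metric = metric, comparison = "vs_weekday5", k = k, n = n,
        icc = icc_agreement(wd_sub(k), refwd, type)$icc))
    # vs the weekend average
    wk_sub <- subset_mean(wk_ix)
    out <- rbind(out, data.frame(
      metric = metric, comparison = "vs_weekend2", k = 1, n = n,
      icc = icc_agreement(wk_sub(1), refwk, type)$icc))
  }
  class(out) <- c("icc_results", "data.frame")
  out
}
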