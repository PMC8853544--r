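#' Variability measures of a log2 expression series
#'
#' Four scale measures computed on the normalized log2 values of one
#' probe: the standard deviation (n - 1 denominator), the range
#' (maximum minus minimum), the interquartile range (third minus first
#' quartile under linear interpolation between order statistics at
#' positions h = (n - 1) p + 1) and the mean absolute deviation from the
#' median.
#'
#' @param values numeric vector of at least 2 finite log2 values.
#' @return named numeric vector `c(sd, range, iqr, madm)`.
#' @examples
#' variability_measures(c(1, 2, 3, 4))
#' @export
variability_measures <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (!all(is.finite(values))) stop("non-finite values")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  c(sd = stats::sd(values),
    range = max(values) - min(values),
    iqr = q[2] - q[1],
    madm = mean(abs(values - stats::median(values))))
}

#' Rank probes by ascending variability
#'
#' Rank 1 is the least variable probe; ties receive the average of the
#' tied positions.
#'
#' @param values named numeric vector, one finite measure value per probe.
#' @return named numeric rank vector.
#' @export
rank_probes <- function(values) {
  if (!length(values)) stop("empty input")
  if (!all(is.finite(values))) stop("non-finite values")
  rank(values, ties.method = "average")
}

MEASURES <- c("sd", "range", "iqr", "madm")

#' Fit a combined stability ranking of miRNAs
#'
#' The central estimator of the package. For each retained endogenous
#' miRNA, computes the four variability measures of its log2-normalized
#' values under each ranking strategy (by default housekeeping and
#' total-miRNA normalization), ranks the probes within every
#' (measure, strategy) pair, and sums the ranks — all pairs weighted
#' equally — into a combined rank sum. The most stable miRNAs are those
#' with the smallest rank sum; ties are broken by the SD under the last
#' strategy (total-miRNA when present), then by probe id.
#'
#' @param x a [count_matrix()].
#' @param group group label or `"pooled"` (default).
#' @param rule a [filter_rule()] applied before ranking.
#' @param strategies strategies whose ranks enter the sum; the default two
#'   give 4 measures x 2 strategies = 8 ranks per probe.
#' @param top_k `top75` normalizer size, if that strategy is requested.
#' @param count_floor numerator floor for [normalize_counts()].
#' @return an object of class `mir_stability` with elements `table` (the
#'   per-probe data.frame of measures, ranks, `rank_sum` and `final_rank`,
#'   ordered most-stable first), `group`, `strategies`, `retained`,
#'   `n_samples` and `normalizers`.
#' @examples
#' fit <- mir_stability(make_fixture("tiny")$matrix)
#' fit
#' top_k_stable(fit, 3)
#' @export
mir_stability <- function(x, group = "pooled", rule = filter_rule(),
                          strategies = c("housekeeping", "total_mirna"),
                          top_k = 75L, count_floor = 1) {
  strategies <- vapply(strategies, match.arg, "", choices = NORM_STRATEGIES)
  retained <- filter_probes(x, group, rule)
  if (length(retained) < 2L)
    stop("fewer than 2 probes retained in group '", group, "'")
  tab <- data.frame(probe_id = retained, stringsAsFactors = FALSE)
  ranks <- matrix(0, nrow = length(retained),
                  ncol = length(MEASURES) * length(strategies))
  normalizers <- list()
  k <- 0L
  n_samples <- NULL
  for (st in strategies) {
    nm <- normalize_counts(x, group, retained, st, top_k, count_floor)
    normalizers[[st]] <- nm$normalizer_probes
    n_samples <- ncol(nm$values)
    meas <- t(apply(nm$values, 1L, variability_measures))
    for (m in MEASURES) {
      k <- k + 1L
      tab[[paste(m, st, sep = "_")]] <- meas[, m]
      r <- rank_probes(stats::setNames(meas[, m], retained))
      tab[[paste("rank", m, st, sep = "_")]] <- r
      ranks[, k] <- r
    }
  }
  tab$rank_sum <- rowSums(ranks)
  tiebreak_st <- if ("total_mirna" %in% strategies) "total_mirna" else
    strategies[length(strategies)]
  tiebreak_sd <- tab[[paste0("sd_", tiebreak_st)]]
  ord <- order(tab$rank_sum, tiebreak_sd, tab$probe_id)
  tab <- tab[ord, , drop = FALSE]
  tab$final_rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, group = group, strategies = strategies,
                 retained = retained, n_samples = n_samples,
                 normalizers = normalizers),
            class = "mir_stability")
}

#' The k most stable miRNAs of a fitted ranking
#'
#' @param fit a [mir_stability()] object.
#' @param k how many probes (`k = 0` gives an empty list).
#' @return character vector: the first `k` probe ids in stability order.
#' @export
top_k_stable <- function(fit, k) {
  stopifnot(inherits(fit, "mir_stability"))
  if (k > nrow(fit$table)) stop("k exceeds the number of ranked probes")
  fit$table$probe_id[seq_len(k)]
}

#' @export
print.mir_stability <- function(x, n = 10L, ...) {
  cat(sprintf("mir_stability: %d miRNAs ranked in group '%s' (%d samples)\n",
              nrow(x$table), x$group, x$n_samples))
  cat("  strategies:", paste(x$strategies, collapse = " + "),
      sprintf(" (%d ranks per probe)\n",
              length(x$strategies) * length(MEASURES)))
  n <- min(n, nrow(x$table))
  cat(sprintf("  %d most stable (rank sum):\n", n))
  top <- x$table[seq_len(n), c("probe_id", "rank_sum")]
  for (i in seq_len(n))
    cat(sprintf("    %2d. %-28s %g\n", i, top$probe_id[i], top$rank_sum[i]))
  invisible(x)
}

#' @export
summary.mir_stability <- function(object, n = 10L, ...) {
  cols <- c("probe_id", grep("^(sd|madm)_", names(object$table), value = TRUE),
            "rank_sum", "final_rank")
  out <- list(group = object$group,
              n_probes = nrow(object$table),
              n_samples = object$n_samples,
              strategies = object$strategies,
              top = utils::head(object$table[, cols], n))
  class(out) <- "summary.mir_stability"
  out
}

#' @export
print.summary.mir_stability <- function(x, ...) {
  cat(sprintf("Stability ranking, group '%s': %d miRNAs, %d samples\n",
              x$group, x$n_probes, x$n_samples))
  print(x$top, digits = 4)
  invisible(x)
}

#' Plot a stability ranking
#'
#' Dot chart of the combined rank sums of the `n` most stable miRNAs;
#' smaller is more stable.
#'
#' @param x a `mir_stability` object.
#' @param n number of probes shown.
#' @param ... passed to [graphics::dotchart()].
#' @export
plot.mir_stability <- function(x, n = 20L, ...) {
  n <- min(n, nrow(x$table))
  tab <- x$table[seq_len(n), ]
  graphics::dotchart(rev(tab$rank_sum), labels = rev(tab$probe_id),
                     xlab = "combined rank sum",
                     main = sprintf("Most stable miRNAs, group '%s'",
                                    x$group), ...)
  invisible(x)
}
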