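## Paired tests of dispersion for the composite-normalizer comparison:
## the mean log2 value of the five most stable miRNAs (the log of their
## geometric mean) against the mean log2 value of the next five, computed
## on the same samples, hence paired.

new_paired_dispersion <- function(method, statistic, p_value, n_pairs) {
  structure(list(method = method, statistic = statistic,
                 p_value = p_value, n_pairs = n_pairs),
            class = "paired_dispersion")
}

#' @export
print.paired_dispersion <- function(x, ...) {
  lab <- c(grambsch = "paired Grambsch test (variances)",
           bonett_seier = "paired Bonett-Seier test (MADMs)")[x$method]
  cat(sprintf("%s: statistic = %.4f, two-sided p = %.4g, n = %d pairs\n",
              lab, x$statistic, x$p_value, x$n_pairs))
  invisible(x)
}

check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("paired series of unequal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
}

#' Paired Grambsch test of equal variances
#'
#' Robust paired comparison of variances built on the Pitman-Morgan
#' structure: with `D = x - y` and `S = x + y`, `var(x) = var(y)` exactly
#' when `cov(D, S) = 0`. The statistic is the self-normalized mean of the
#' centred products `u_i = (D_i - mean(D)) (S_i - mean(S))`,
#' `T = sqrt(n) mean(u) / sd(u)`, referred to the standard normal
#' (two-sided).
#'
#' @param x,y paired numeric series of equal length `n >= 3`.
#' @return a `paired_dispersion` result (method `"grambsch"`).
#' @examples
#' set.seed(1)
#' a <- rnorm(30); b <- 2 * rnorm(30)
#' grambsch_paired(a, b)
#' @export
grambsch_paired <- function(x, y) {
  check_pair(x, y)
  n <- length(x)
  D <- x - y
  S <- x + y
  u <- (D - mean(D)) * (S - mean(S))
  s_u <- stats::sd(u)
  if (s_u == 0)
    stop("degenerate input: the products (D - mean(D))(S - mean(S)) are ",
         "constant (e.g. x identical to y)")
  stat <- sqrt(n) * mean(u) / s_u
  new_paired_dispersion("grambsch", stat,
                        2 * stats::pnorm(-abs(stat)), n)
}

#' Paired Bonett-Seier test of equal mean absolute deviations
#'
#' Compares the mean absolute deviations from the median (MADM) of two
#' paired series via the delta method on the log ratio of the estimates.
#' With `a_i = |x_i - median(x)|`, `b_i = |y_i - median(y)|`,
#' `tau_x = mean(a)` and `tau_y = mean(b)`, the statistic is
#' `z = log(tau_x / tau_y) / SE` with
#' `SE^2 = (var(a)/tau_x^2 + var(b)/tau_y^2 - 2 cov(a, b)/(tau_x tau_y))/n`,
#' referred to the standard normal (two-sided). A pure shift
#' (`y = x + c`) leaves the absolute deviations identical, giving `z = 0`,
#' `p = 1`.
#'
#' @inheritParams grambsch_paired
#' @return a `paired_dispersion` result (method `"bonett_seier"`).
#' @export
bonett_seier_paired <- function(x, y) {
  check_pair(x, y)
  n <- length(x)
  a <- abs(x - stats::median(x))
  b <- abs(y - stats::median(y))
  tau_x <- mean(a)
  tau_y <- mean(b)
  if (tau_x == 0 || tau_y == 0)
    stop("degenerate input: zero mean absolute deviation from median")
  if (isTRUE(all.equal(a, b, tolerance = 1e-12)))
    return(new_paired_dispersion("bonett_seier", 0, 1, n))
  se2 <- (stats::var(a) / tau_x^2 + stats::var(b) / tau_y^2 -
            2 * stats::cov(a, b) / (tau_x * tau_y)) / n
  if (se2 <= 0) {
    ## exactly collinear deviations (e.g. y = c * x): the ratio of MADMs
    ## is measured without sampling error, the log-ratio limit is +/-Inf
    return(new_paired_dispersion("bonett_seier",
                                 sign(log(tau_x / tau_y)) * Inf, 0, n))
  }
  stat <- log(tau_x / tau_y) / sqrt(se2)
  new_paired_dispersion("bonett_seier", stat,
                        2 * stats::pnorm(-abs(stat)), n)
}

#' Composite normalizer series
#'
#' The per-sample arithmetic mean of several probes' log2-normalized
#' values — i.e. the log2 of their geometric mean on the count scale.
#'
#' @param normalized a `normalized_matrix` from [normalize_counts()].
#' @param probes probe ids to combine; must all be rows of `normalized`.
#' @return named numeric vector, one composite value per sample.
#' @export
composite_series <- function(normalized, probes) {
  stopifnot(inherits(normalized, "normalized_matrix"), length(probes) >= 1L)
  missing <- setdiff(probes, rownames(normalized$values))
  if (length(missing))
    stop("probe(s) not in normalized matrix: ",
         paste(missing, collapse = ", "))
  colMeans(normalized$values[probes, , drop = FALSE])
}

#' Compare the top-5 and next-5 composite normalizers
#'
#' Builds, from the combined stability ranking of a group, the composite
#' series of the 5 most stable miRNAs (positions 1-5) and of the next 5
#' (positions 6-10) under the given normalization strategy, and tests
#' whether the two composites disperse equally with both the paired
#' Grambsch and the paired Bonett-Seier test. A clearly smaller dispersion
#' of the top composite supports using it as a reference normalizer.
#'
#' @param x a [count_matrix()].
#' @param group group label or `"pooled"`.
#' @param strategy normalization strategy under which the composites are
#'   recomputed (the probe sets stay fixed by the combined ranking).
#' @param fit optional pre-computed [mir_stability()] fit for this group.
#' @param top,nxt sizes of the two composites (defaults 5 and 5).
#' @param rule,top_k,count_floor passed to [mir_stability()] /
#'   [normalize_counts()] when `fit` is not supplied.
#' @return list with elements `grambsch` and `bonett_seier` (both
#'   `paired_dispersion`), plus `top_probes` and `next_probes`.
#' @export
compare_top5_next5 <- function(x, group = "pooled",
                               strategy = "housekeeping", fit = NULL,
                               top = 5L, nxt = 5L, rule = filter_rule(),
                               top_k = 75L, count_floor = 1) {
  if (is.null(fit)) fit <- mir_stability(x, group, rule = rule,
                                         top_k = top_k,
                                         count_floor = count_floor)
  stopifnot(inherits(fit, "mir_stability"))
  if (nrow(fit$table) < top + nxt)
    stop("need at least ", top + nxt, " retained probes, have ",
         nrow(fit$table))
  ord <- fit$table$probe_id
  top_probes <- ord[seq_len(top)]
  next_probes <- ord[top + seq_len(nxt)]
  nm <- normalize_counts(x, group, fit$retained, strategy, top_k,
                         count_floor)
  xs <- composite_series(nm, top_probes)
  ys <- composite_series(nm, next_probes)
  list(grambsch = grambsch_paired(xs, ys),
       bonett_seier = bonett_seier_paired(xs, ys),
       top_probes = top_probes, next_probes = next_probes)
}
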