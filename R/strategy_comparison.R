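## Permutation test on rank concordance: do two normalization strategies
## agree on which miRNAs are the "five best" (least variance)? The union
## of the two top-5 lists (5-10 probes) is ranked within-list under each
## strategy; the statistic is the sum of absolute rank differences, and
## its null distribution assigns equal probability to every permutation of
## one strategy's ranks.

#' Build the union list and within-list ranks for a strategy pair
#'
#' Takes per-probe variances of log2-normalized values under strategies A
#' and B (over the same retained probe set), forms the union of the `k`
#' least-variance probes under each — between `k` and `2k` entries — and
#' ranks the union's members 1..|L| by ascending variance under each
#' strategy separately. Exact variance ties are resolved by probe id so
#' each rank vector is a permutation.
#'
#' @param variances_A,variances_B named numeric vectors of per-probe
#'   variances covering the same probes (see [normalize_counts()]).
#' @param k how many "best" probes per strategy (default 5).
#' @return a `rank_concordance` object: `union` (probe ids, sorted),
#'   `ranks_A`, `ranks_B` (integer permutations of `1..|L|`), `k`.
#' @export
build_union_list <- function(variances_A, variances_B, k = 5L) {
  if (!setequal(names(variances_A), names(variances_B)))
    stop("the two variance maps must cover the same probes")
  if (length(variances_A) < k) stop("fewer than k = ", k, " probes")
  top_of <- function(v) {
    names(v)[order(v, names(v))][seq_len(k)]
  }
  L <- sort(union(top_of(variances_A), top_of(variances_B)))
  within_ranks <- function(v) {
    vv <- v[L]
    r <- integer(length(L))
    r[order(vv, L)] <- seq_along(L)
    stats::setNames(r, L)
  }
  structure(list(union = L,
                 ranks_A = within_ranks(variances_A),
                 ranks_B = within_ranks(variances_B),
                 k = k),
            class = "rank_concordance")
}

#' Sum of absolute rank differences
#'
#' @param ranks_A,ranks_B equal-length rank vectors.
#' @return integer `T = sum(|ranks_A - ranks_B|)`; symmetric in its
#'   arguments.
#' @export
rank_distance <- function(ranks_A, ranks_B) {
  if (length(ranks_A) != length(ranks_B))
    stop("rank vectors of unequal length")
  sum(abs(ranks_A - ranks_B))
}

## Exact null distribution of T = sum |i - sigma(i)| over uniform
## permutations sigma of 1..n, by dynamic programming over the bitmask of
## assigned rank values: identical to enumerating all n! permutations but
## polynomial in work. Cached per n.
.perm_cache <- new.env(parent = emptyenv())
perm_T_counts <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  max_t <- floor(n^2 / 2)
  nmask <- bitwShiftL(1L, n)
  dist <- matrix(0, nrow = nmask, ncol = max_t + 1L)
  dist[1L, 1L] <- 1
  popcnt <- integer(nmask)
  for (m in seq_len(nmask - 1L))
    popcnt[m + 1L] <- popcnt[bitwShiftR(m, 1L) + 1L] + m %% 2L
  for (m in 0:(nmask - 2L)) {
    row <- dist[m + 1L, ]
    if (!any(row > 0)) next
    i <- popcnt[m + 1L] + 1L          # position being assigned
    for (j in seq_len(n)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(m, bit) == 0L) {
        d <- abs(i - j)
        idx <- (d + 1L):(max_t + 1L)
        dist[bitwOr(m, bit) + 1L, idx] <-
          dist[bitwOr(m, bit) + 1L, idx] + row[seq_len(max_t + 1L - d)]
      }
    }
  }
  out <- dist[nmask, ]
  names(out) <- 0:max_t
  .perm_cache[[key]] <- out
  out
}

#' Permutation p-value for the rank-distance statistic
#'
#' The p-value is the probability, under uniformly random permutations of
#' one strategy's within-list ranks, of a sum of absolute rank differences
#' at least as large as the observed one ("as or more extreme" includes
#' equality, so `T_obs = 0` always gives p = 1). Exhaustive mode evaluates
#' the exact distribution over all `|L|!` permutations (by symmetry the
#' null depends only on `|L|`); Monte-Carlo mode samples `n_mc` uniform
#' permutations and applies the add-one estimator
#' `(count + 1) / (n_mc + 1)`.
#'
#' @param input a `rank_concordance` from [build_union_list()], or any
#'   list with elements `ranks_A` and `ranks_B` that are permutations of
#'   `1..|L|`.
#' @param mode `"exhaustive"` (default, `|L| <= 10`) or `"monte_carlo"`.
#' @param n_mc Monte-Carlo sample size.
#' @param seed optional seed for Monte-Carlo mode.
#' @return a `strategy_comparison` result: `T_obs`, `p_unadjusted`,
#'   `n_permutations`, `mode`, `union_size` (plus `pair`, filled by
#'   [compare_all_strategies()]).
#' @export
permutation_p <- function(input, mode = c("exhaustive", "monte_carlo"),
                          n_mc = 10000L, seed = NULL) {
  mode <- match.arg(mode)
  rA <- input$ranks_A
  rB <- input$ranks_B
  L <- length(rA)
  if (!L || !identical(sort(as.integer(rA)), seq_len(L)) ||
      !identical(sort(as.integer(rB)), seq_len(L)))
    stop("ranks_A and ranks_B must each be a permutation of 1..|L|")
  t_obs <- rank_distance(rA, rB)
  if (mode == "exhaustive") {
    if (L > 10L)
      stop("|L|! too large for exhaustive enumeration (|L| > 10); ",
           "use monte_carlo")
    counts <- perm_T_counts(L)
    p <- sum(counts[(t_obs + 1L):length(counts)]) / factorial(L)
    n_perm <- factorial(L)
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    hits <- sum(vapply(seq_len(n_mc), function(i) {
      sum(abs(rA - rB[sample.int(L)])) >= t_obs
    }, logical(1)))
    p <- (hits + 1) / (n_mc + 1)
    n_perm <- n_mc
  }
  structure(list(pair = NULL, T_obs = t_obs, p_unadjusted = p,
                 p_adjusted = NA_real_, n_permutations = n_perm,
                 mode = mode, union_size = L),
            class = "strategy_comparison")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a family of p-values (a validating front for
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @examples
#' bh_adjust(c(0.13, 0.014, 0.77, 0.77, 0.014, 0.014))
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' All six pairwise comparisons of the four normalization strategies
#'
#' For every unordered pair of strategies, selects each strategy's five
#' least-variance miRNAs within the group, builds the union list, runs the
#' rank-concordance permutation test, and BH-adjusts the six unadjusted
#' p-values. A small adjusted p means the two strategies disagree about
#' which miRNAs are most stable.
#'
#' @param x a [count_matrix()].
#' @param group group label or `"pooled"` (the default, as the comparison
#'   is most informative across all samples).
#' @param strategies strategies to compare pairwise (default all four).
#' @param k "best" list size per strategy (default 5).
#' @param mode,n_mc,seed see [permutation_p()].
#' @param rule,top_k,count_floor see [mir_stability()].
#' @return a `strategy_comparisons` list of six `strategy_comparison`
#'   results, each with `pair` and `p_adjusted` filled in.
#' @examples
#' cm <- make_fixture("tiny")$matrix
#' compare_all_strategies(cm, "pooled", top_k = 10)
#' @export
compare_all_strategies <- function(x, group = "pooled",
                                   strategies = NORM_STRATEGIES, k = 5L,
                                   mode = c("exhaustive", "monte_carlo"),
                                   n_mc = 10000L, seed = NULL,
                                   rule = filter_rule(), top_k = 75L,
                                   count_floor = 1) {
  mode <- match.arg(mode)
  strategies <- unname(vapply(strategies, match.arg, "",
                              choices = NORM_STRATEGIES))
  retained <- filter_probes(x, group, rule)
  vars <- lapply(strategies, function(st) {
    probe_variances(normalize_counts(x, group, retained, st, top_k,
                                     count_floor))
  })
  names(vars) <- strategies
  pairs <- utils::combn(strategies, 2L, simplify = FALSE)
  results <- lapply(pairs, function(pr) {
    input <- build_union_list(vars[[pr[1]]], vars[[pr[2]]], k)
    res <- permutation_p(input, mode, n_mc, seed)
    res$pair <- pr
    res
  })
  adj <- bh_adjust(vapply(results, `[[`, 0, "p_unadjusted"))
  for (i in seq_along(results)) results[[i]]$p_adjusted <- adj[i]
  structure(results, class = "strategy_comparisons")
}

#' @export
print.strategy_comparisons <- function(x, ...) {
  cat("Pairwise strategy comparisons (rank-concordance permutation test):\n")
  for (r in x) {
    cat(sprintf("  %-18s vs %-18s |L| = %2d  T = %2d  p = %.4g (adj %.4g)\n",
                r$pair[1], r$pair[2], r$union_size, r$T_obs,
                r$p_unadjusted, r$p_adjusted))
  }
  invisible(x)
}

#' @export
print.strategy_comparison <- function(x, ...) {
  pair <- if (is.null(x$pair)) "A vs B" else paste(x$pair, collapse = " vs ")
  cat(sprintf(
    "strategy_comparison %s: T_obs = %d, p = %.4g (%s, %g permutations)\n",
    pair, x$T_obs, x$p_unadjusted, x$mode, x$n_permutations))
  invisible(x)
}
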