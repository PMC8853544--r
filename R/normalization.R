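NORM_STRATEGIES <- c("housekeeping", "total_mirna", "top75",
                     "positive_control")

#' Resolve the normalizer probe set for a strategy within a group
#'
#' The four strategies: `housekeeping` uses the five control mRNAs
#' (ACTB, B2M, GAPDH, RPL19, RPLP0 on the real codeset); `total_mirna`
#' uses every endogenous miRNA retained by the group's low-count filter
#' ("all miRNAs found"); `top75` uses the `top_k` retained miRNAs with the
#' largest total count over the group's samples (ties broken by probe id);
#' `positive_control` uses the six positive spike-in probes.
#'
#' @param x a [count_matrix()].
#' @param group group label or `"pooled"`.
#' @param retained retained endogenous probe ids for this group, as
#'   returned by [filter_probes()].
#' @param name one of `"housekeeping"`, `"total_mirna"`, `"top75"`,
#'   `"positive_control"`.
#' @param top_k size of the `top75` normalizer set (default 75).
#' @return character vector of normalizer probe ids.
#' @export
resolve_normalizer <- function(x, group, retained, name, top_k = 75L) {
  name <- match.arg(name, NORM_STRATEGIES)
  switch(name,
    housekeeping = {
      hk <- probe_ids(x, "housekeeping_mrna")
      if (length(hk) != 5L)
        stop("expected 5 housekeeping mRNA probes, found ", length(hk))
      hk
    },
    positive_control = {
      pos <- probe_ids(x, "positive_control")
      if (length(pos) != 6L)
        stop("expected 6 positive-control probes, found ", length(pos))
      pos
    },
    total_mirna = {
      if (!length(retained)) stop("no retained probes to normalize to")
      retained
    },
    top75 = {
      if (length(retained) < top_k)
        stop("fewer than top_k = ", top_k, " retained probes (",
             length(retained), ")")
      tot <- rowSums(group_counts(x, retained, group))
      ## largest totals first; ties resolved lexicographically by probe_id
      ord <- order(-tot, retained)
      sel <- retained[ord[seq_len(top_k)]]
      sel[order(match(sel, retained))]   # keep probe order
    })
}

#' Log2-normalize counts under one strategy
#'
#' For every retained endogenous probe p and group sample s,
#' `value(p, s) = log2(max(count(p, s), count_floor)) - log2(N_s)` where
#' `N_s` is the total molecule count of the normalizer probes in sample s
#' (a plain sum, not a geometric mean). The floor only guards the
#' numerator: a zero count has no binary logarithm, and retained probes
#' rarely sit at zero given the 50-molecule filter. Floored cells are
#' counted in `n_floored`.
#'
#' @inheritParams resolve_normalizer
#' @param strategy strategy name (see [resolve_normalizer()]).
#' @param count_floor numerator floor (default 1).
#' @return a `normalized_matrix`: list with `values` (retained probes x
#'   group samples, log2 units), `strategy`, `normalizer_probes`, `group`,
#'   `n_floored`.
#' @examples
#' cm <- make_fixture("tiny")$matrix
#' nm <- normalize_counts(cm, "pooled", filter_probes(cm, "pooled"),
#'                        "housekeeping")
#' range(nm$values)
#' @export
normalize_counts <- function(x, group, retained, strategy, top_k = 75L,
                             count_floor = 1) {
  strategy <- match.arg(strategy, NORM_STRATEGIES)
  if (!length(retained)) stop("no retained probes to normalize")
  normalizer <- resolve_normalizer(x, group, retained, strategy, top_k)
  num <- group_counts(x, retained, group)
  totals <- colSums(group_counts(x, normalizer, group))
  if (any(totals <= 0))
    stop("zero normalizer total in sample(s): ",
         paste(names(totals)[totals <= 0], collapse = ", "))
  floored <- num < count_floor
  vals <- log2(pmax(num, count_floor)) -
    rep(log2(totals), each = nrow(num))
  structure(list(values = vals,
                 strategy = strategy,
                 normalizer_probes = normalizer,
                 group = group,
                 n_floored = sum(floored)),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf(
    "normalized_matrix (%s): %d miRNAs x %d samples, group '%s', %d normalizer probes%s\n",
    x$strategy, nrow(x$values), ncol(x$values), x$group,
    length(x$normalizer_probes),
    if (x$n_floored > 0) sprintf(" [%d floored cells]", x$n_floored) else ""))
  invisible(x)
}

## per-probe variance of log2 values; selection measure for "best" miRNAs
probe_variances <- function(normalized) {
  v <- normalized$values
  apply(v, 1L, stats::var)
}
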