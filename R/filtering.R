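#' Low-count exclusion rule
#'
#' A probe is excluded from a group's analysis when it shows fewer than
#' `min_molecules` molecules in more than `max_low_fraction` of the
#' group's samples. Both bounds are strict: a count of exactly 50 is not
#' "low", and exactly half the samples low does not exclude.
#'
#' @param min_molecules count threshold (default 50).
#' @param max_low_fraction fraction of samples allowed at low counts
#'   (default 0.5, strict).
#' @return a `filter_rule` object.
#' @export
filter_rule <- function(min_molecules = 50, max_low_fraction = 0.5) {
  stopifnot(min_molecules >= 0, max_low_fraction >= 0, max_low_fraction <= 1)
  structure(list(min_molecules = min_molecules,
                 max_low_fraction = max_low_fraction),
            class = "filter_rule")
}

#' Apply the low-count rule within one group
#'
#' Only endogenous miRNA probes are subject to the rule (and only they are
#' ever returned); control and housekeeping probes are never analysis
#' targets. Filtering is per group: `"pooled"` applies the rule over the
#' union of all samples, which is not the same as intersecting per-group
#' survivor lists.
#'
#' @param x a [count_matrix()].
#' @param group group label or `"pooled"`.
#' @param rule a [filter_rule()].
#' @return character vector of retained endogenous probe ids, in probe
#'   order.
#' @examples
#' cm <- make_fixture("tiny")$matrix
#' filter_probes(cm, "pooled")
#' @export
filter_probes <- function(x, group, rule = filter_rule()) {
  stopifnot(inherits(rule, "filter_rule"))
  endo <- probe_ids(x, "endogenous_mirna")
  cnt <- group_counts(x, endo, group)   # errors on empty group
  n <- ncol(cnt)
  n_low <- rowSums(cnt < rule$min_molecules)
  excluded <- n_low > rule$max_low_fraction * n
  endo[!excluded]
}
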