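#' Run the full reference-miRNA selection analysis
#'
#' End-to-end orchestration for every requested group: low-count
#' filtering, the combined stability ranking (written as
#' `<group>_stability.tsv`), the top-5 vs next-5 composite dispersion
#' tests under the housekeeping and total-miRNA normalizations
#' (`<group>_composite_tests.json`), and the six pairwise strategy
#' comparisons (`<group>_strategy_comparison.json`), plus a run manifest
#' (`manifest.json`) recording parameters, seed and filter survivor
#' counts. Groups with fewer than 10 retained probes skip the composite
#' tests with a warning; any other stage failure aborts with the stage
#' named.
#'
#' @param x a [count_matrix()].
#' @param out_dir output directory (created if needed).
#' @param groups groups to analyse; default every sample group plus
#'   `"pooled"`.
#' @param strategies the four normalization strategies to compare.
#' @param rank_strategies the strategies entering the combined rank sum.
#' @param rule a [filter_rule()].
#' @param top_report rows reported by the per-group summary (default 10).
#' @param k_comparison "best" list size for the permutation test.
#' @param mode,n_mc,seed permutation-test settings (see
#'   [permutation_p()]).
#' @param top_k,count_floor see [normalize_counts()].
#' @param quiet suppress progress messages.
#' @return invisibly, a named list per group with elements `stability`,
#'   `composite`, `comparisons`, plus `manifest`.
#' @export
run_reference_analysis <- function(x, out_dir,
                                   groups = NULL,
                                   strategies = NORM_STRATEGIES,
                                   rank_strategies = c("housekeeping",
                                                       "total_mirna"),
                                   rule = filter_rule(),
                                   top_report = 10L,
                                   k_comparison = 5L,
                                   mode = "exhaustive",
                                   n_mc = 10000L,
                                   seed = 1L,
                                   top_k = 75L,
                                   count_floor = 1,
                                   quiet = FALSE) {
  validate_count_matrix(x)
  if (is.null(groups)) groups <- c(unique(x$samples$group), "pooled")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- list()
  survivors <- integer(0)
  for (g in groups) {
    say("group '%s': filtering (min %g molecules in > %g of samples)",
        g, rule$min_molecules, rule$max_low_fraction)
    retained <- stage("filter", filter_probes(x, g, rule))
    survivors[[g]] <- length(retained)
    say("group '%s': %d endogenous miRNAs retained", g, length(retained))

    fit <- stage("stability",
                 mir_stability(x, g, rule = rule,
                               strategies = rank_strategies,
                               top_k = top_k, count_floor = count_floor))
    write_stability_table(fit$table,
                          file.path(out_dir,
                                    paste0(g, "_stability.tsv")))

    composite <- NULL
    if (length(retained) >= 10L) {
      composite <- stage("composite_tests", lapply(
        stats::setNames(rank_strategies, rank_strategies),
        function(st) {
          r <- compare_top5_next5(x, g, strategy = st, fit = fit,
                                  top_k = top_k,
                                  count_floor = count_floor)
          list(strategy = st,
               top_probes = r$top_probes, next_probes = r$next_probes,
               grambsch = unclass(r$grambsch),
               bonett_seier = unclass(r$bonett_seier))
        }))
      jsonlite::write_json(composite,
                           file.path(out_dir,
                                     paste0(g, "_composite_tests.json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else {
      warning("group '", g, "': fewer than 10 retained probes; ",
              "composite dispersion tests skipped", call. = FALSE)
    }

    comparisons <- stage("strategy_comparison",
                         compare_all_strategies(x, g, strategies,
                                                k = k_comparison,
                                                mode = mode, n_mc = n_mc,
                                                seed = seed, rule = rule,
                                                top_k = top_k,
                                                count_floor = count_floor))
    write_comparison(comparisons,
                     file.path(out_dir,
                               paste0(g, "_strategy_comparison.json")))
    out[[g]] <- list(stability = fit, composite = composite,
                     comparisons = comparisons)
  }
  manifest <- list(
    package = "mirstab",
    version = as.character(utils::packageVersion("mirstab")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    groups = groups,
    strategies = strategies,
    rank_strategies = rank_strategies,
    filter = list(min_molecules = rule$min_molecules,
                  max_low_fraction = rule$max_low_fraction),
    k_comparison = k_comparison,
    top_k = top_k,
    count_floor = count_floor,
    permutation_mode = mode,
    n_mc = n_mc,
    n_probes = nrow(x$counts),
    n_samples = ncol(x$counts),
    filter_survivors = as.list(survivors))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
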