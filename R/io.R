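## Tabular interchange. Count tables are probe-rows x sample-columns TSV
## with a header row and "probe_id" as first column (the orientation of
## nSolver CSV exports); annotations are plain TSV; stability tables are
## TSV and strategy comparisons JSON.

#' Read a count table plus annotations from delimited text
#'
#' @param path TSV of counts: first column `probe_id`, remaining columns one
#'   per sample.
#' @param probe_annot_path TSV with columns `probe_id`, `probe_class` and
#'   optionally `merged`.
#' @param sample_annot_path TSV with columns `sample_id`, `group` and
#'   optionally `subgroup`, `codeset`.
#' @return a validated [count_matrix()].
#' @export
read_count_table <- function(path, probe_annot_path, sample_annot_path) {
  for (p in c(path, probe_annot_path, sample_annot_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "probe_id")
    stop("count table must have 'probe_id' as its first column")
  cnt <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(cnt)) stop("non-numeric count in ", path)
  rownames(cnt) <- tab$probe_id
  probes <- utils::read.delim(probe_annot_path, stringsAsFactors = FALSE)
  samples <- utils::read.delim(sample_annot_path, stringsAsFactors = FALSE)
  samples$sample_id <- as.character(samples$sample_id)
  ## reorder annotations to the matrix, flagging unknown/missing ids
  if (!setequal(rownames(cnt), probes$probe_id))
    stop("probe ids of count table and annotation do not match")
  if (!setequal(colnames(cnt), samples$sample_id))
    stop("sample ids of count table and annotation do not match")
  probes <- probes[match(rownames(cnt), probes$probe_id), , drop = FALSE]
  samples <- samples[match(colnames(cnt), samples$sample_id), , drop = FALSE]
  rownames(probes) <- rownames(samples) <- NULL
  count_matrix(cnt, probes, samples)
}

#' Write a count_matrix to TSV files
#'
#' Inverse of [read_count_table()]; `read(write(x)) == x`.
#'
#' @param x a `count_matrix`.
#' @inheritParams read_count_table
#' @return `x` invisibly.
#' @export
write_count_matrix <- function(x, path, probe_annot_path, sample_annot_path) {
  validate_count_matrix(x)
  tab <- data.frame(probe_id = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$probes, probe_annot_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, sample_annot_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

## RCC CodeClass labels -> probe classes. nCounter miRNA cartridges label
## endogenous probes "Endogenous" (sometimes with a suffix), spike-ins
## "Positive"/"Negative" and the mRNA controls "Housekeeping".
rcc_class_map <- function(code_class) {
  out <- rep(NA_character_, length(code_class))
  out[grepl("^Endogenous", code_class)] <- "endogenous_mirna"
  out[grepl("^Housekeeping", code_class)] <- "housekeeping_mrna"
  out[grepl("^Positive", code_class)] <- "positive_control"
  out[grepl("^Negative", code_class)] <- "negative_control"
  if (anyNA(out))
    stop("unmapped RCC CodeClass: ",
         paste(unique(code_class[is.na(out)]), collapse = ", "))
  out
}

parse_rcc_one <- function(path) {
  lines <- readLines(path, warn = FALSE)
  section <- function(name) {
    open <- grep(sprintf("^<%s>$", name), lines)
    close <- grep(sprintf("^</%s>$", name), lines)
    if (length(open) != 1L || length(close) != 1L || close <= open)
      stop("unparseable RCC file (missing <", name, "> section): ", path)
    lines[(open + 1L):(close - 1L)]
  }
  attrs <- section("Sample_Attributes")
  id_line <- grep("^ID,", attrs, value = TRUE)
  sample_id <- if (length(id_line)) sub("^ID,", "", id_line[1]) else
    sub("\\.[Rr][Cc][Cc]$", "", basename(path))
  body <- section("Code_Summary")
  con <- textConnection(body)
  on.exit(close(con))
  cs <- utils::read.csv(con, stringsAsFactors = FALSE)
  need <- c("CodeClass", "Name", "Count")
  if (!all(need %in% names(cs)))
    stop("unparseable RCC Code_Summary record in ", path)
  counts <- suppressWarnings(as.numeric(cs$Count))
  if (anyNA(counts)) stop("unparseable count field in ", path)
  list(sample_id = sample_id,
       probe_id = cs$Name,
       probe_class = rcc_class_map(cs$CodeClass),
       count = counts)
}

#' Read per-sample NanoString RCC files into one count matrix
#'
#' Each RCC file is the plain-text report for one lane/sample, with the
#' probe counts in its `Code_Summary` section. All files must carry the
#' identical probe list (same codeset); the sample group is not part of an
#' RCC file, so every sample is assigned `group = "unknown"` unless a
#' `groups` vector is supplied.
#'
#' @param paths character vector of RCC file paths.
#' @param groups optional character vector of group labels, one per file.
#' @return a validated [count_matrix()].
#' @export
read_rcc <- function(paths, groups = NULL) {
  stopifnot(length(paths) >= 1L)
  parsed <- lapply(paths, parse_rcc_one)
  ref <- parsed[[1]]$probe_id
  for (p in parsed[-1]) {
    if (!identical(sort(p$probe_id), sort(ref))) {
      d <- union(setdiff(p$probe_id, ref), setdiff(ref, p$probe_id))
      stop("inconsistent probe sets across RCC files; symmetric difference: ",
           paste(d, collapse = ", "))
    }
  }
  cnt <- vapply(parsed, function(p) p$count[match(ref, p$probe_id)],
                numeric(length(ref)))
  cnt <- matrix(cnt, nrow = length(ref),
                dimnames = list(ref, vapply(parsed, `[[`, "", "sample_id")))
  if (is.null(groups)) groups <- rep("unknown", length(paths))
  stopifnot(length(groups) == length(paths))
  probes <- data.frame(probe_id = ref,
                       probe_class = parsed[[1]]$probe_class,
                       stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = colnames(cnt), group = groups,
                        stringsAsFactors = FALSE)
  count_matrix(cnt, probes, samples)
}

#' Write / read a stability table
#'
#' The per-probe table of variability measures, ranks and rank sums is
#' written as TSV so it can be diffed and re-read losslessly.
#'
#' @param table data.frame as found in the `table` element of a
#'   [mir_stability()] fit.
#' @param path output TSV path.
#' @export
write_stability_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(table)
}

#' @rdname write_stability_table
#' @export
read_stability_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write / read strategy-comparison results as JSON
#'
#' Each element records the strategy pair, the observed rank-distance
#' statistic, the unadjusted and BH-adjusted permutation p-values (the
#' "adjusted p-value (unadjusted p-value)" presentation), the enumeration
#' mode and the number of permutations.
#'
#' @param results a `strategy_comparisons` object or plain list of results.
#' @param path output JSON path.
#' @export
write_comparison <- function(results, path) {
  out <- lapply(unclass(results), function(r) {
    r[c("pair", "T_obs", "p_unadjusted", "p_adjusted", "n_permutations",
        "mode", "union_size")]
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(results)
}

#' @rdname write_comparison
#' @export
read_comparison <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
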