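#' @keywords internal
"_PACKAGE"

## Probe classes recognised on an nCounter miRNA codeset. Endogenous miRNA
## probes are the analysis targets; the other three classes are assay
## controls and are never themselves ranked for stability.
PROBE_CLASSES <- c("endogenous_mirna", "housekeeping_mrna",
                   "positive_control", "negative_control")

#' Construct a validated NanoString count matrix
#'
#' Bundles a probe-by-sample matrix of molecule counts with its probe and
#' sample annotations into a `count_matrix` object, the container every
#' pipeline stage consumes. Counts must be non-negative integers (the
#' platform reports absolute molecule counts, not intensities), and the
#' matrix dimnames must agree exactly with the annotation tables.
#'
#' @param counts numeric matrix of non-negative integer counts; rownames are
#'   probe ids, colnames are sample ids.
#' @param probes data.frame with columns `probe_id`, `probe_class` (one of
#'   `"endogenous_mirna"`, `"housekeeping_mrna"`, `"positive_control"`,
#'   `"negative_control"`) and optionally `merged` (logical; `TRUE` for
#'   probes that measure the summed content of two miRNAs, conventionally
#'   named with a `"+"`, e.g. `"miR-500a-5p+miR-501-5p"`).
#' @param samples data.frame with columns `sample_id`, `group` and
#'   optionally `subgroup` and `codeset`.
#' @return an object of class `count_matrix` with elements `counts`,
#'   `probes`, `samples`.
#' @examples
#' cm <- make_fixture("tiny")$matrix
#' cm
#' @export
count_matrix <- function(counts, probes, samples) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(probes$merged)) {
    probes$merged <- grepl("+", probes$probe_id, fixed = TRUE)
  }
  probes$merged <- as.logical(probes$merged)
  x <- structure(list(counts = counts, probes = probes, samples = samples),
                 class = "count_matrix")
  validate_count_matrix(x)
  x
}

#' Validate a count_matrix against its invariants
#'
#' Checks integrality and non-negativity of every cell, uniqueness of probe
#' and sample ids, one known class per probe, and exact agreement between
#' the matrix dimnames and the annotation tables. Called by all
#' constructors and readers; exposed so corrupted objects can be detected.
#'
#' @param x object to validate.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_count_matrix <- function(x) {
  if (!inherits(x, "count_matrix")) stop("not a count_matrix object")
  cnt <- x$counts
  if (is.null(rownames(cnt)) || is.null(colnames(cnt)))
    stop("count matrix must have probe rownames and sample colnames")
  if (anyNA(cnt)) stop("missing cells in count matrix")
  if (any(cnt < 0)) stop("negative count in matrix")
  if (any(cnt != round(cnt))) stop("non-integer count in matrix")
  for (col in c("probe_id", "probe_class")) {
    if (is.null(x$probes[[col]])) stop("probe annotation lacks column ", col)
  }
  for (col in c("sample_id", "group")) {
    if (is.null(x$samples[[col]])) stop("sample annotation lacks column ", col)
  }
  if (anyDuplicated(x$probes$probe_id)) stop("duplicate probe_id in annotation")
  if (anyDuplicated(x$samples$sample_id))
    stop("duplicate sample_id in annotation")
  bad <- setdiff(unique(x$probes$probe_class), PROBE_CLASSES)
  if (length(bad))
    stop("unknown probe_class: ", paste(bad, collapse = ", "))
  if (!identical(rownames(cnt), x$probes$probe_id))
    stop("probe ids of count matrix and annotation do not match")
  if (!identical(colnames(cnt), x$samples$sample_id))
    stop("sample ids of count matrix and annotation do not match")
  if ("pooled" %in% x$samples$group)
    stop("'pooled' is a reserved group name (it denotes all samples)")
  invisible(x)
}

#' @export
print.count_matrix <- function(x, ...) {
  cls <- table(factor(x$probes$probe_class, levels = PROBE_CLASSES))
  cat(sprintf("count_matrix: %d probes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  endogenous miRNA: %d  housekeeping mRNA: %d  pos ctrl: %d  neg ctrl: %d\n",
              cls[["endogenous_mirna"]], cls[["housekeeping_mrna"]],
              cls[["positive_control"]], cls[["negative_control"]]))
  grp <- table(x$samples$group)
  cat("  groups:", paste(sprintf("%s (%d)", names(grp), grp), collapse = ", "),
      "\n")
  invisible(x)
}

#' Probe ids of a count matrix, optionally restricted to one class
#'
#' @param x a `count_matrix`.
#' @param class optional probe class to filter on.
#' @return character vector of probe ids.
#' @export
probe_ids <- function(x, class = NULL) {
  validate_count_matrix(x)
  if (is.null(class)) return(x$probes$probe_id)
  class <- match.arg(class, PROBE_CLASSES)
  x$probes$probe_id[x$probes$probe_class == class]
}

#' @rdname probe_ids
#' @export
sample_ids <- function(x) {
  validate_count_matrix(x)
  x$samples$sample_id
}

#' Sample ids belonging to an analysis group
#'
#' The special group `"pooled"` denotes the union of all samples, matching
#' the convention of analysing thyroid, glioma and bone-marrow cohorts both
#' separately and together.
#'
#' @param x a `count_matrix`.
#' @param group a group label present in the sample annotation, or
#'   `"pooled"`.
#' @return character vector of sample ids; errors if the group is unknown
#'   or empty.
#' @export
samples_in_group <- function(x, group) {
  validate_count_matrix(x)
  stopifnot(is.character(group), length(group) == 1L)
  if (group == "pooled") return(x$samples$sample_id)
  ids <- x$samples$sample_id[x$samples$group == group]
  if (!length(ids)) stop("empty or unknown group: ", group)
  ids
}

## internal: counts sub-matrix for a set of probes and one group's samples
group_counts <- function(x, probes, group) {
  s <- samples_in_group(x, group)
  x$counts[probes, s, drop = FALSE]
}
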