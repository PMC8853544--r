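## Independent oracles and small fixture builders shared across tests.

## a count_matrix around an explicit endogenous count matrix, with minimal
## control probes appended (constant counts so controls never interfere)
make_cm <- function(endo_counts, groups = NULL, hk_counts = NULL,
                    pos_counts = NULL) {
  n_s <- ncol(endo_counts)
  if (is.null(rownames(endo_counts)))
    rownames(endo_counts) <- sprintf("miR-t-%02d", seq_len(nrow(endo_counts)))
  if (is.null(colnames(endo_counts)))
    colnames(endo_counts) <- sprintf("S%02d", seq_len(n_s))
  if (is.null(groups)) groups <- rep("g1", n_s)
  hk <- c("ACTB", "B2M", "GAPDH", "RPL19", "RPLP0")
  pos <- paste0("POS_", LETTERS[1:6])
  neg <- paste0("NEG_", LETTERS[1:8])
  if (is.null(hk_counts))
    hk_counts <- matrix(rep(c(500, 300, 200, 100, 400), n_s), nrow = 5,
                        dimnames = list(hk, colnames(endo_counts)))
  if (is.null(pos_counts))
    pos_counts <- matrix(rep(c(3200, 800, 200, 50, 12, 3), n_s), nrow = 6,
                         dimnames = list(pos, colnames(endo_counts)))
  neg_counts <- matrix(5, nrow = 8, ncol = n_s,
                       dimnames = list(neg, colnames(endo_counts)))
  cnt <- rbind(endo_counts, hk_counts, pos_counts, neg_counts)
  probes <- data.frame(
    probe_id = rownames(cnt),
    probe_class = c(rep("endogenous_mirna", nrow(endo_counts)),
                    rep("housekeeping_mrna", 5),
                    rep("positive_control", 6),
                    rep("negative_control", 8)),
    stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = colnames(cnt), group = groups,
                        stringsAsFactors = FALSE)
  count_matrix(cnt, probes, samples)
}

## literal re-count of the exclusion rule, one probe at a time
brute_filter <- function(endo_counts, min_molecules, max_low_fraction) {
  keep <- character(0)
  for (p in rownames(endo_counts)) {
    low <- 0
    for (s in colnames(endo_counts)) {
      if (endo_counts[p, s] < min_molecules) low <- low + 1
    }
    if (!(low > max_low_fraction * ncol(endo_counts))) keep <- c(keep, p)
  }
  keep
}

## step-up BH from its definition, independent of stats::p.adjust
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

## all permutations of 1..n as a matrix (rows)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, p + (p >= k))))
}

## exhaustive permutation p by literal enumeration
brute_perm_p <- function(ranks_A, ranks_B) {
  n <- length(ranks_A)
  t_obs <- sum(abs(ranks_A - ranks_B))
  P <- all_perms(n)
  mean(apply(P, 1, function(s) sum(abs(ranks_A - ranks_B[s])) >= t_obs))
}

## random small count_matrix for property tests (counts straddling the
## 50-molecule threshold so the filter boundary is exercised)
random_cm <- function(n_probes = 8, n_samples = 6) {
  cnt <- matrix(sample(c(0:5, 45:55, 100, 500), n_probes * n_samples,
                       replace = TRUE),
                nrow = n_probes)
  make_cm(cnt, groups = rep(c("g1", "g2"), length.out = n_samples))
}
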