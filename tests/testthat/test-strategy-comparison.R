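test_that("union lists honour overlap between the two top-5 sets", {
  v <- setNames(1:6 / 10, letters[1:6])
  same <- build_union_list(v, v, k = 5)
  expect_length(same$union, 5L)
  expect_equal(rank_distance(same$ranks_A, same$ranks_B), 0)

  ## reversed variances: union of {a..e} and {f,e,d,c,b} has 6 entries
  rev_v <- setNames(rev(v), names(v))
  both <- build_union_list(v, rev_v, k = 5)
  expect_length(both$union, 6L)

  ## disjoint top-5 sets give the full 10 entries
  vA <- setNames(c(1:5, 11:15) / 100, letters[1:10])
  vB <- setNames(c(11:15, 1:5) / 100, letters[1:10])
  disj <- build_union_list(vA, vB, k = 5)
  expect_length(disj$union, 10L)
  expect_error(build_union_list(v[1:3], v[1:3], k = 5), "fewer than k")
  expect_error(build_union_list(v, v[-1], k = 3), "same probes")
})

test_that("within-list ranks are permutations even under ties", {
  v_tied <- setNames(c(0.1, 0.1, 0.1, 0.2, 0.3), letters[1:5])
  v_other <- setNames(c(0.5, 0.4, 0.3, 0.2, 0.1), letters[1:5])
  inp <- build_union_list(v_tied, v_other, k = 5)
  expect_setequal(inp$ranks_A, 1:5)
  expect_setequal(inp$ranks_B, 1:5)
  ## exact ties resolved by probe id: a before b before c
  expect_true(inp$ranks_A[["a"]] < inp$ranks_A[["b"]])
  expect_true(inp$ranks_A[["b"]] < inp$ranks_A[["c"]])
})

test_that("rank distance is the symmetric sum of absolute differences", {
  expect_equal(rank_distance(1:5, 1:5), 0)
  expect_equal(rank_distance(1:5, 5:1), 12)   # 4+2+0+2+4
  a <- c(2L, 4L, 1L, 3L); b <- c(4L, 1L, 3L, 2L)
  expect_equal(rank_distance(a, b), rank_distance(b, a))
  expect_error(rank_distance(1:4, 1:5), "unequal")
})

test_that("exhaustive p matches literal enumeration over all permutations", {
  set.seed(1234)
  for (n in 2:6) {
    for (rep in 1:3) {
      inp <- list(ranks_A = sample(n), ranks_B = sample(n))
      p_dp <- permutation_p(inp, mode = "exhaustive")$p_unadjusted
      expect_equal(p_dp, brute_perm_p(inp$ranks_A, inp$ranks_B))
    }
  }
})

test_that("edge-case permutation p-values are exact", {
  ## T_obs = 0: every permutation is as extreme, p = 1
  r <- permutation_p(list(ranks_A = 1:5, ranks_B = 1:5))
  expect_equal(r$T_obs, 0L)
  expect_equal(r$p_unadjusted, 1)
  ## |L| = 2 reversal: T in {0, 2} equally likely
  r2 <- permutation_p(list(ranks_A = 1:2, ranks_B = 2:1))
  expect_equal(r2$p_unadjusted, 0.5)
  ## |L| = 5 full reversal attains the maximum T = 12
  r5 <- permutation_p(list(ranks_A = 1:5, ranks_B = 5:1))
  expect_equal(r5$T_obs, 12L)
  expect_error(permutation_p(list(ranks_A = c(1, 1), ranks_B = 1:2)),
               "permutation of")
})

test_that("the maximum attainable T is floor(n^2 / 2)", {
  for (n in 2:8) {
    counts <- mirstab:::perm_T_counts(n)
    attained <- max(which(counts > 0)) - 1L
    expect_equal(attained, floor(n^2 / 2))
    expect_equal(sum(counts), factorial(n))
  }
})

test_that("Monte-Carlo p agrees with the exhaustive value", {
  set.seed(77)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    inp <- list(ranks_A = sample(n), ranks_B = sample(n))
    pe <- permutation_p(inp, "exhaustive")$p_unadjusted
    pm <- permutation_p(inp, "monte_carlo", n_mc = 20000L,
                        seed = rep)$p_unadjusted
    se <- sqrt(pe * (1 - pe) / 20000)
    expect_lt(abs(pm - pe), 3 * se + 2 / 20001)
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.13, 0.014, 0.77, 0.77, 0.014, 0.014)),
               c(0.195, 0.028, 0.77, 0.77, 0.028, 0.028))
  expect_equal(bh_adjust(0.42), 0.42)
  set.seed(88)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, brute_bh(p))
    expect_true(all(adj >= p))
    expect_equal(order(adj[order(p)]), seq_along(p))  # order preserved
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("all six strategy pairs are compared and BH-adjusted", {
  sim <- make_fixture("tiny", seed = 6)
  res <- compare_all_strategies(sim$matrix, "pooled", top_k = 10)
  expect_length(res, 6L)
  pairs <- t(vapply(res, `[[`, character(2), "pair"))
  expect_equal(nrow(unique(pairs)), 6L)
  p <- vapply(res, `[[`, 0, "p_unadjusted")
  adj <- vapply(res, `[[`, 0, "p_adjusted")
  expect_equal(adj, bh_adjust(p))
  expect_true(all(adj >= p))
  for (r in res) expect_lte(r$T_obs, floor(r$union_size^2 / 2))
})

test_that("strategies with identical variances give T = 0 and p = 1", {
  ## top75 with top_k equal to the retained set duplicates total_mirna
  cm <- make_cm(matrix(sample(60:500, 48), nrow = 12))
  res <- compare_all_strategies(cm, "pooled",
                                strategies = c("total_mirna", "top75"),
                                top_k = 12)
  expect_length(res, 1L)
  expect_equal(res[[1]]$T_obs, 0L)
  expect_equal(res[[1]]$p_unadjusted, 1)
  expect_equal(res[[1]]$p_adjusted, 1)
})

test_that("comparisons are invariant to sample order in exhaustive mode", {
  sim <- make_fixture("tiny", seed = 7)
  res1 <- compare_all_strategies(sim$matrix, "pooled", top_k = 10)
  perm <- sample(ncol(sim$matrix$counts))
  cm2 <- count_matrix(sim$matrix$counts[, perm], sim$matrix$probes,
                      sim$matrix$samples[perm, ])
  res2 <- compare_all_strategies(cm2, "pooled", top_k = 10)
  expect_equal(res2, res1)
})
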