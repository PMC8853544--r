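test_that("composite series is the per-sample mean of member probes", {
  vals <- matrix(c(-3, -2, -5, -6), nrow = 2, byrow = TRUE,
                 dimnames = list(c("p1", "p2"), c("S1", "S2")))
  nm <- structure(list(values = vals, strategy = "housekeeping",
                       normalizer_probes = "ACTB", group = "pooled",
                       n_floored = 0L), class = "normalized_matrix")
  expect_equal(composite_series(nm, c("p1", "p2")), c(S1 = -4, S2 = -4))
  expect_equal(composite_series(nm, "p1"), vals["p1", ])
  ## shifting every member by c shifts the composite by c
  nm2 <- nm; nm2$values <- nm$values + 1.5
  expect_equal(composite_series(nm2, c("p1", "p2")),
               composite_series(nm, c("p1", "p2")) + 1.5)
  expect_error(composite_series(nm, c("p1", "p9")), "p9")
})

test_that("the paired Grambsch statistic is antisymmetric and sign-faithful", {
  set.seed(10)
  for (i in 1:20) {
    x <- rnorm(15, sd = runif(1, 0.5, 2))
    y <- 0.4 * x + rnorm(15, sd = runif(1, 0.5, 2))
    a <- grambsch_paired(x, y)
    b <- grambsch_paired(y, x)
    expect_equal(b$statistic, -a$statistic)
    expect_equal(b$p_value, a$p_value)
    ## sign agrees with the Pitman-Morgan correlation of (D, S)
    pm <- cor(x - y, x + y)
    expect_equal(sign(a$statistic), sign(pm))
  }
})

test_that("degenerate paired inputs error out", {
  x <- rnorm(10)
  expect_error(grambsch_paired(x, x), "degenerate")
  expect_error(grambsch_paired(x, rnorm(9)), "unequal length")
  expect_error(grambsch_paired(x[1:2], x[1:2] * 2), "at least 3")
  expect_error(bonett_seier_paired(rep(1, 10), x), "zero mean absolute")
})

test_that("both tests are invariant to a common additive shift", {
  set.seed(20)
  x <- rnorm(25); y <- rnorm(25, sd = 1.7)
  for (f in list(grambsch_paired, bonett_seier_paired)) {
    r0 <- f(x, y); r1 <- f(x + 10, y + 10)
    expect_equal(r1$statistic, r0$statistic, tolerance = 1e-9)
    expect_equal(r1$p_value, r0$p_value, tolerance = 1e-9)
  }
})

test_that("Bonett-Seier responds to scale and degenerates to p = 1 on shifts", {
  set.seed(30)
  x <- rnorm(20)
  shifted <- bonett_seier_paired(x, x + 5)   # identical MADMs
  expect_equal(shifted$statistic, 0)
  expect_equal(shifted$p_value, 1)
  doubled <- bonett_seier_paired(x, 2 * x)   # tau ratio exactly 1/2
  expect_lt(doubled$statistic, 0)
  swap <- bonett_seier_paired(2 * x, x)
  expect_equal(swap$statistic, -doubled$statistic, tolerance = 1e-12)
})

test_that("both tests hold their nominal size under a correlated null", {
  ## bivariate normal, equal variances, rho = 0.5, n = 30
  set.seed(40)
  B <- 2000
  rej <- c(g = 0, b = 0)
  for (i in 1:B) {
    z1 <- rnorm(30); z2 <- rnorm(30)
    x <- z1
    y <- 0.5 * z1 + sqrt(0.75) * z2
    rej["g"] <- rej["g"] + (grambsch_paired(x, y)$p_value < 0.05)
    rej["b"] <- rej["b"] + (bonett_seier_paired(x, y)$p_value < 0.05)
  }
  expect_gt(rej[["g"]] / B, 0.03); expect_lt(rej[["g"]] / B, 0.07)
  expect_gt(rej[["b"]] / B, 0.03); expect_lt(rej[["b"]] / B, 0.07)
})

test_that("null p-values are close to uniform", {
  set.seed(50)
  pg <- replicate(1500, {
    z1 <- rnorm(30); z2 <- rnorm(30)
    grambsch_paired(z1, 0.5 * z1 + sqrt(0.75) * z2)$p_value
  })
  ks <- suppressWarnings(ks.test(pg, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("a large planted dispersion gap is detected with high power", {
  ## composite series with CV 0.02 vs 0.4 on the count scale, n = 56 pairs
  set.seed(60)
  hits <- c(g = 0, b = 0)
  n_rep <- 50
  for (i in 1:n_rep) {
    x <- log2(rlnorm(56, 0, sqrt(log1p(0.02^2))))
    y <- log2(rlnorm(56, 0, sqrt(log1p(0.4^2))))
    hits["g"] <- hits["g"] + (grambsch_paired(x, y)$p_value < 0.001)
    hits["b"] <- hits["b"] + (bonett_seier_paired(x, y)$p_value < 0.001)
  }
  expect_gte(hits[["g"]] / n_rep, 0.9)
  expect_gte(hits[["b"]] / n_rep, 0.9)
})

test_that("top-5 vs next-5 comparison runs the full route", {
  sim <- simulate_counts(
    sim_config(n_mirna_probes = 20L, n_expressed = 20L, n_stable = 5L,
               n_variable = 15L, biological_cv_stable = 0.02), seed = 123)
  res <- compare_top5_next5(sim$matrix, "pooled", "housekeeping")
  expect_s3_class(res$grambsch, "paired_dispersion")
  expect_s3_class(res$bonett_seier, "paired_dispersion")
  expect_equal(res$grambsch$n_pairs, 56L)
  expect_length(res$top_probes, 5L)
  expect_length(intersect(res$top_probes, res$next_probes), 0L)
  ## the planted gap shows up as small p for both tests
  expect_lt(res$grambsch$p_value, 0.05)
  expect_lt(res$bonett_seier$p_value, 0.05)
})

test_that("identical top and next composites raise a degenerate-input error", {
  ## ten most stable probes share the identical count pattern, so the two
  ## composites coincide sample by sample
  base <- c(100, 120, 90, 110, 105, 95)
  wild <- matrix(c(60, 500, 70, 400, 80, 300,
                   300, 60, 450, 75, 380, 65), nrow = 2, byrow = TRUE)
  cm <- make_cm(rbind(matrix(rep(base, each = 10), nrow = 10), wild))
  expect_error(compare_top5_next5(cm, "pooled", "housekeeping"),
               "degenerate")
})
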