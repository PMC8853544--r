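## Synthetic nCounter-like data with known ground truth. The real assay
## reports counts for ~800 endogenous miRNA probes of which only ~200 are
## expressed at usable levels, plus 5 housekeeping mRNAs, 6 positive
## spike-ins at a known concentration ladder and 8 negative probes
## measuring background. All simulator distributions are stand-ins: the
## source study deposited no raw counts and described no noise model, so
## counts are negative binomial (the standard overdispersed model for
## digital counting data) around per-probe abundances scaled by per-sample
## size factors.

HK_NAMES <- c("ACTB", "B2M", "GAPDH", "RPL19", "RPLP0")
POS_NAMES <- paste0("POS_", LETTERS[1:6])
NEG_NAMES <- paste0("NEG_", LETTERS[1:8])
## NanoString positive-control ladder concentrations (fM)
POS_LADDER_FM <- c(128, 32, 8, 2, 0.5, 0.125)

#' Simulation configuration for nCounter-like count matrices
#'
#' Defaults emulate a full miRNA codeset: 800 endogenous probes, 200 of
#' them expressed above background, and three patient cohorts of 32 + 12 +
#' 12 samples. Among the expressed probes, `n_stable` are planted as
#' tightly regulated (low biological CV, no group effect) and `n_variable`
#' as group-differential (high CV plus a `group_effect_log2` shift in one
#' randomly chosen group); the remaining expressed probes get an
#' intermediate "bulk" CV of 0.2, the typical spread of ordinary miRNAs.
#'
#' @param n_mirna_probes total endogenous miRNA probes.
#' @param n_expressed how many of them are expressed above background.
#' @param n_stable,n_variable planted stable / group-differential probes
#'   (`n_stable + n_variable <= n_expressed`).
#' @param groups named integer vector: samples per group.
#' @param size_factor_sd SD, in log2 units, of the lognormal per-sample
#'   size factors (per-lane binding-density variation).
#' @param biological_cv_stable,biological_cv_variable,biological_cv_bulk
#'   coefficient of variation of the lognormal biological term for each
#'   planted class.
#' @param group_effect_log2 multiplicative group effect, in log2 units,
#'   applied to variable probes in one group.
#' @param dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2); `0` selects the noise-free limit in which
#'   counts are the rounded expected values.
#' @param hk_levels mean counts of the five housekeeping mRNAs.
#' @param pos_ladder the six positive-control concentrations (fM).
#' @param pos_counts_per_fm expected counts per fM for positive probes.
#' @param neg_mean background mean count (negative controls and
#'   non-expressed miRNAs).
#' @param expressed_range log2 range from which expressed-probe base
#'   abundances are drawn.
#' @param seed default seed used by [simulate_counts()].
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_mirna_probes = 800L,
                       n_expressed = 200L,
                       n_stable = 10L,
                       n_variable = 40L,
                       groups = c(thyroid = 32L, glioma = 12L,
                                  bone_marrow = 12L),
                       size_factor_sd = 0.25,
                       biological_cv_stable = 0.05,
                       biological_cv_variable = 0.4,
                       biological_cv_bulk = 0.2,
                       group_effect_log2 = 1.0,
                       dispersion = 0.02,
                       hk_levels = c(18000, 4000, 9000, 2500, 6000),
                       pos_ladder = POS_LADDER_FM,
                       pos_counts_per_fm = 200,
                       neg_mean = 10,
                       expressed_range = c(log2(100), log2(20000)),
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_stable + n_variable > n_expressed)
      stop("n_stable + n_variable must not exceed n_expressed")
    if (n_expressed > n_mirna_probes)
      stop("n_expressed must not exceed n_mirna_probes")
    if (any(groups <= 0) || is.null(names(groups)))
      stop("groups must be a named vector of positive sample counts")
    if (dispersion < 0) stop("dispersion must be >= 0")
    if (length(hk_levels) != 5L) stop("exactly 5 housekeeping levels")
    if (length(pos_ladder) != 6L) stop("exactly 6 positive-control levels")
    if (any(c(hk_levels, pos_ladder, neg_mean, pos_counts_per_fm) <= 0))
      stop("all control means must be positive")
    if (any(c(biological_cv_stable, biological_cv_variable,
              biological_cv_bulk) < 0) || size_factor_sd < 0)
      stop("CVs and size_factor_sd must be >= 0")
  })
  invisible(cfg)
}

## lognormal multiplier with mean 1 and the requested CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

## NB draw with mean mu and var mu + dispersion*mu^2; dispersion 0 is the
## deterministic noise-free limit (rounded means keep counts integral)
rcounts <- function(mu, dispersion) {
  if (dispersion == 0) return(round(mu))
  stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Simulate an nCounter-like count matrix with known ground truth
#'
#' Draws, in a single seeded RNG stream (sample-level quantities, then
#' probe-level quantities, then counts probe by probe), a
#' probes-by-samples count matrix. For an expressed miRNA probe p in
#' sample s the count is negative binomial with mean
#' `f_s * mu_p * g(p, s)` where `f_s` is the lognormal size factor, `mu_p`
#' the base abundance and `g` a mean-1 lognormal biological term with the
#' CV of the probe's planted class times, for variable probes, a
#' `2^group_effect_log2` shift in the probe's assigned group.
#' Non-expressed miRNAs and negative controls draw around the background
#' mean; housekeeping and positive probes draw around their configured
#' levels scaled by `f_s`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`. The same config and
#'   seed always reproduce the identical matrix.
#' @return list with elements `matrix` (a [count_matrix()]) and `truth`
#'   (class `sim_truth`: `stable_set`, `variable_set`, `expressed_set`,
#'   `size_factors`, `base_abundance`, `group_effect` per variable probe).
#' @examples
#' sim <- simulate_counts(sim_config(n_mirna_probes = 30, n_expressed = 12,
#'                                   n_stable = 3, n_variable = 3,
#'                                   groups = c(a = 4, b = 4)))
#' sim$matrix
#' @export
simulate_counts <- function(config = sim_config(), seed = config$seed) {
  validate_sim_config(config)
  set.seed(as.integer(seed))
  groups <- config$groups
  n_samp <- sum(groups)
  sample_group <- rep(names(groups), groups)
  sample_id <- sprintf("S%02d_%s", seq_len(n_samp), sample_group)

  ## sample-level: lognormal size factors
  f <- 2^stats::rnorm(n_samp, 0, config$size_factor_sd)
  names(f) <- sample_id

  ## probe-level: names, expressed subset, planted classes, abundances
  mir_id <- sprintf("miR-sim-%03d", seq_len(config$n_mirna_probes))
  if (config$n_mirna_probes >= 6L) {
    ## a couple of merged probes: total content of two miRNAs, "+"-joined
    k <- config$n_mirna_probes
    mir_id[k - 1L] <- paste0(mir_id[k - 1L], "a+", "miR-sim-", k - 1L, "b")
  }
  expressed <- sort(sample.int(config$n_mirna_probes, config$n_expressed))
  planted <- sample(expressed, config$n_stable + config$n_variable)
  stable_idx <- planted[seq_len(config$n_stable)]
  variable_idx <- setdiff(planted, stable_idx)
  mu <- rep(config$neg_mean, config$n_mirna_probes)
  mu[expressed] <- 2^stats::runif(config$n_expressed,
                                  config$expressed_range[1],
                                  config$expressed_range[2])
  cv <- rep(0, config$n_mirna_probes)
  cv[expressed] <- config$biological_cv_bulk
  cv[stable_idx] <- config$biological_cv_stable
  cv[variable_idx] <- config$biological_cv_variable
  ## each variable probe is shifted in one randomly assigned group
  eff_group <- if (length(variable_idx))
    sample(names(groups), length(variable_idx), replace = TRUE) else
    character(0)
  names(eff_group) <- mir_id[variable_idx]

  ## counts, probe major
  all_id <- c(mir_id, HK_NAMES, POS_NAMES, NEG_NAMES)
  all_class <- c(rep("endogenous_mirna", config$n_mirna_probes),
                 rep("housekeeping_mrna", 5L),
                 rep("positive_control", 6L),
                 rep("negative_control", 8L))
  cnt <- matrix(0, nrow = length(all_id), ncol = n_samp,
                dimnames = list(all_id, sample_id))
  for (i in seq_len(config$n_mirna_probes)) {
    is_expr <- i %in% expressed
    m <- if (is_expr) {
      g <- rlnorm_cv(n_samp, cv[i])
      shift <- rep(1, n_samp)
      if (i %in% variable_idx)
        shift[sample_group == eff_group[[mir_id[i]]]] <-
          2^config$group_effect_log2
      f * mu[i] * g * shift
    } else {
      ## background: unexpressed probes do not track RNA input
      rep(mu[i], n_samp)
    }
    cnt[i, ] <- rcounts(m, config$dispersion)
  }
  for (j in seq_len(5L))
    cnt[config$n_mirna_probes + j, ] <-
      rcounts(f * config$hk_levels[j], config$dispersion)
  for (j in seq_len(6L))
    cnt[config$n_mirna_probes + 5L + j, ] <-
      rcounts(f * config$pos_ladder[j] * config$pos_counts_per_fm,
              config$dispersion)
  for (j in seq_len(8L))
    cnt[config$n_mirna_probes + 11L + j, ] <-
      rcounts(rep(config$neg_mean, n_samp), config$dispersion)

  probes <- data.frame(probe_id = all_id, probe_class = all_class,
                       stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sample_id, group = sample_group,
                        stringsAsFactors = FALSE)
  truth <- structure(
    list(stable_set = mir_id[stable_idx],
         variable_set = mir_id[variable_idx],
         expressed_set = mir_id[expressed],
         size_factors = f,
         base_abundance = stats::setNames(mu, mir_id),
         group_effect = eff_group,
         seed = as.integer(seed)),
    class = "sim_truth")
  list(matrix = count_matrix(cnt, probes, samples), truth = truth)
}

#' Ready-made simulated fixtures
#'
#' `"tiny"` is a 20-miRNA, 8-sample, two-group dataset for fast unit
#' tests; `"full_study"` is a full-size codeset (800 miRNA probes) with
#' cohorts of 32, 12 and 12 samples, the scale of a three-tissue
#' reference-gene study.
#'
#' @param kind `"tiny"` or `"full_study"`.
#' @param seed integer seed.
#' @return as [simulate_counts()].
#' @export
make_fixture <- function(kind = c("tiny", "full_study"), seed = 1L) {
  kind <- match.arg(kind)
  cfg <- switch(kind,
    tiny = sim_config(n_mirna_probes = 20L, n_expressed = 14L,
                      n_stable = 3L, n_variable = 4L,
                      groups = c(thyroid = 4L, glioma = 4L),
                      seed = seed),
    full_study = sim_config(seed = seed))
  simulate_counts(cfg, seed = seed)
}
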