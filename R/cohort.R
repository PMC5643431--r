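#' Construct a simulated-cohort specification
#'
#' Defaults mirror the discovery-cohort conditions the pipeline targets:
#' 64 cases, 3--74 tiles per case, ~2000 genes of which 14 carry planted
#' correlation with vascular features, a hazard ratio of 2.4 between the
#' two planted vascular-phenotype groups, and ~30% censoring.
#'
#' @param n_cases,tiles_per_case,n_genes,n_signal_genes see slots of
#'   [SyntheticCohortSpec-class].
#' @param planted_hazard_ratio,correlation_strength,censoring_rate,seed idem.
#' @return A validated [SyntheticCohortSpec-class].
#' @export
cohortSpec <- function(n_cases = 64L, tiles_per_case = c(3L, 74L),
                       n_genes = 2000L, n_signal_genes = 14L,
                       planted_hazard_ratio = 2.4,
                       correlation_strength = 0.6,
                       censoring_rate = 0.3, seed = 1L) {
  obj <- new("SyntheticCohortSpec", nCases = as.integer(n_cases),
             tilesPerCase = as.integer(tiles_per_case),
             nGenes = as.integer(n_genes),
             nSignalGenes = as.integer(n_signal_genes),
             plantedHazardRatio = planted_hazard_ratio,
             correlationStrength = correlation_strength,
             censoringRate = censoring_rate, seed = as.integer(seed))
  validObject(obj)
  obj
}

## Uniform-censoring upper bound b with P(C < T) = rate for the exponential
## mixture across groups: P(C < T) = mean_g [1 - (1 - exp(-h_g b)) / (h_g b)].
censoringBound <- function(hazards, p_group, rate) {
  if (rate <= 0) return(Inf)
  f <- function(b) {
    pc <- sum(p_group * (1 - exp(-hazards * b)) / (hazards * b))
    pc - rate
  }
  if (rate >= 1) return(1e-6)
  uniroot(f, c(1e-6, 1e6))$root
}

#' Simulate an expression/survival cohort with planted vascular structure
#'
#' Two vascular-phenotype groups (high-risk prevalence 24/64, as in the
#' discovery cohort) differ in the means of 9 designated signal features of
#' the 88-feature vascular profile by \code{effect_size} within-group SDs.
#' Signal genes are linear in the z-scored signal features on the log2
#' scale, with Pearson correlation \code{correlation_strength} (sign
#' alternating per gene); survival times are exponential with hazard ratio
#' \code{planted_hazard_ratio} between groups, censored by an independent
#' uniform time calibrated to the requested censoring rate.
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @param effect_size group mean shift of signal features, in SD units.
#' @param n_signal_features number of planted signal features (default 9).
#' @param baseline_median_dfs median disease-free survival of the low-risk
#'   group, in months.
#' @return A [VascularCohort-class]; planted truth (groups, signal genes,
#'   signal features) is in \code{colData()} and \code{metadata()}.
#' @examples
#' coh <- simulateCohort(cohortSpec(n_cases = 32, n_genes = 200, seed = 3))
#' coh
#' @export
simulateCohort <- function(spec, effect_size = 2.5, n_signal_features = 9L,
                           baseline_median_dfs = 40) {
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@nCases
  case_ids <- sprintf("case_%03d", seq_len(n))
  group <- factor(ifelse(runif(n) < 24 / 64, "high", "low"), c("low", "high"))

  ## --- vascular-feature profiles (88 = 22 primaries x 4 moments) ----------
  feat_names <- as.vector(t(outer(primaryFeatureRoster(),
                                  c("mean", "sd", "skewness", "kurtosis"),
                                  paste, sep = "_")))
  p <- length(feat_names)
  base_mean <- runif(p, 0.5, 5)
  cv <- runif(p, 0.1, 0.6)
  base_sd <- base_mean * cv
  ## signal features: spread across distinct primaries, forced past the
  ## std/mean >= 0.3 variance filter
  sig_feat <- seq(1L, by = 4L, length.out = n_signal_features)
  cv[sig_feat] <- runif(n_signal_features, 0.4, 0.6)
  base_sd <- base_mean * cv
  Z <- matrix(rnorm(n * p), n, p)
  shift <- matrix(0, n, p)
  shift[group == "high", sig_feat] <- effect_size
  profiles <- sweep(sweep(Z + shift, 2, base_sd, "*"), 2, base_mean, "+")
  dimnames(profiles) <- list(case_ids, feat_names)

  ## --- expression: signal genes linear in z-scored signal features --------
  g <- spec@nGenes
  gene_ids <- sprintf("GENE%04d", seq_len(g))
  rho <- spec@correlationStrength
  L <- matrix(rnorm(g * n, mean = rep(runif(g, 3, 8), n), sd = 1.2), g, n)
  sig_genes <- seq_len(spec@nSignalGenes)
  map <- rep(seq_len(n_signal_features), length.out = length(sig_genes))
  sign_g <- rep(c(1, -1), length.out = length(sig_genes))
  for (i in seq_along(sig_genes)) {
    zf <- scale(profiles[, sig_feat[map[i]]])[, 1]
    eps <- rnorm(n)
    L[sig_genes[i], ] <- 5 + 2 * sign_g[i] * (rho * zf + sqrt(1 - rho^2) * eps)
  }
  expr <- pmax(2^L - 1, 0)
  dimnames(expr) <- list(gene_ids, case_ids)

  ## --- survival: exponential hazards, uniform censoring --------------------
  h0 <- log(2) / baseline_median_dfs
  hz <- ifelse(group == "high", h0 * spec@plantedHazardRatio, h0)
  t_event <- rexp(n, hz)
  b <- censoringBound(c(h0, h0 * spec@plantedHazardRatio),
                      c(mean(group == "low"), mean(group == "high")),
                      spec@censoringRate)
  c_time <- if (is.finite(b)) runif(n, 0, b) else rep(Inf, n)
  dfs <- pmin(t_event, c_time)
  event <- as.integer(t_event <= c_time)
  stage_high <- runif(n) < ifelse(group == "high", 0.5, 0.25)
  grade_high <- runif(n) < ifelse(group == "high", 0.55, 0.3)
  tiles <- pmin(pmax(round(rgamma(n, shape = (25 / 18)^2, scale = 18^2 / 25)),
                     spec@tilesPerCase[1]), spec@tilesPerCase[2])

  se <- SummarizedExperiment(
    assays = list(rpkm = expr),
    colData = DataFrame(dfs_months = dfs, event = event,
                        stage_high = stage_high, grade_high = grade_high,
                        true_group = group, n_tiles = tiles,
                        row.names = case_ids))
  out <- new("VascularCohort", se, vfProfiles = profiles)
  metadata(out) <- list(spec = spec,
                        signal_genes = gene_ids[sig_genes],
                        signal_features = feat_names[sig_feat],
                        censoring_bound = b)
  out
}
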