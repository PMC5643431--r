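#' Run the cohort-level discovery pipeline
#'
#' Chains the survival-driven feature-selection and signature-derivation
#' stages on a cohort: coefficient-of-variation filtering, stochastic
#' backward selection against the log-rank objective, consensus choice of
#' the number of risk groups, Ward clustering into risk groups,
#' per-feature correlation ranking of all genes, top-slice candidate
#' selection, and MDL information-gain-ratio filtering to the final gene
#' set.
#'
#' @param cohort a [VascularCohort-class] (or list with \code{profiles},
#'   \code{expr}, \code{survival}).
#' @param n_iter backward-selection iterations.
#' @param fraction candidate slice fraction per direction per feature.
#' @param cv_threshold variance-filter threshold.
#' @param k_range candidate cluster counts for consensus clustering.
#' @param n_resamples consensus subsamples per k.
#' @param seed integer seed.
#' @return list with \code{retained}, \code{selection}, \code{consensus},
#'   \code{risk_groups}, \code{rankings}, \code{candidates}, \code{genes}
#'   (the \code{geneSelection}), and \code{logrank}.
#' @export
runDiscoveryPipeline <- function(cohort, n_iter = 100L, fraction = 0.0005,
                                 cv_threshold = 0.3, k_range = 2:4,
                                 n_resamples = 50L, seed = 1L) {
  if (is(cohort, "VascularCohort")) {
    profiles <- vfProfiles(cohort)
    expr <- assay(cohort, "rpkm")
    surv <- survivalTable(cohort)
  } else {
    profiles <- cohort$profiles; expr <- cohort$expr; surv <- cohort$survival
  }
  retained <- varianceFilter(profiles, cv_threshold)
  sel <- stochasticBackwardSelection(profiles[, retained, drop = FALSE], surv,
                                     n_iter = n_iter, seed = seed)
  cons <- consensusClusterK(profiles, sel$selected, k_range = k_range,
                            n_resamples = n_resamples, seed = seed)
  ## the signature stage always works on the 2-group risk split (the
  ## consensus k is reported alongside as a structure check)
  groups <- clusterRiskGroups(profiles, sel$selected, k = 2L, survival = surv)
  lr <- logrankTest(surv$dfs_months, surv$event, groups)
  rk <- correlateGenes(expr, profiles, sel$selected)
  cand <- selectCandidates(rk, fraction = fraction)
  genes <- informationGainFilter(expr, cand, groups)
  list(retained = retained, selection = sel, consensus = cons,
       risk_groups = groups, rankings = rk, candidates = cand,
       genes = genes, logrank = lr)
}
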