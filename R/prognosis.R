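#' Coefficient-of-variation feature filter
#'
#' Keeps features with \code{|sd/mean| >= cv_threshold} across cases (raw
#' scale).  Features with mean exactly 0 are retained iff their SD is
#' positive (logged via message).
#'
#' @param profiles cases x features numeric matrix.
#' @param cv_threshold threshold on |std/mean| (default 0.3; features below
#'   it are considered low-variance and dropped).
#' @return character vector of retained feature names.
#' @export
varianceFilter <- function(profiles, cv_threshold = 0.3) {
  if (is.null(dim(profiles)) || nrow(profiles) < 2) stop("need >= 2 cases")
  mu <- colMeans(profiles, na.rm = TRUE)
  s <- apply(profiles, 2, sd, na.rm = TRUE)
  cv <- abs(s / mu)
  keep <- ifelse(mu == 0, s > 0, cv >= cv_threshold & s > 0)
  if (any(mu == 0 & s > 0))
    message(sum(mu == 0 & s > 0), " zero-mean feature(s) retained on sd > 0")
  colnames(profiles)[keep & !is.na(keep)]
}

#' Two-group log-rank test
#'
#' The standard log-rank statistic: at every distinct event time the
#' observed minus hypergeometric-expected events in group 1 are accumulated
#' and scaled by the hypergeometric variance; p from chi-square with 1 df.
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators.
#' @param groups two-level grouping.
#' @return list with \code{statistic}, \code{p}, \code{observed},
#'   \code{expected} (per group).
#' @export
logrankTest <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) stop("exactly 2 non-empty groups required")
  if (sum(events) < 1) stop("need >= 1 event")
  g1 <- groups == levels(droplevels(groups))[1]
  ut <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ut) {
    at <- times >= t
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  obs <- c(O, sum(events) - O)
  exp_ <- c(E, sum(events) - E)
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE),
       observed = obs, expected = exp_)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators.
#' @return data.frame with \code{time}, \code{n_risk}, \code{n_event},
#'   \code{surv} (non-increasing, S(0) = 1 implicitly).
#' @export
kmCurve <- function(times, events) {
  if (any(times < 0)) stop("negative times")
  ut <- sort(unique(times))
  n_risk <- vapply(ut, function(t) sum(times >= t), 0)
  n_event <- vapply(ut, function(t) sum(times == t & events == 1), 0)
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ut, n_risk = n_risk, n_event = n_event, surv = surv)
}

kmSurvivalAt <- function(km, t) {
  if (nrow(km) == 0) return(1)
  i <- findInterval(t, km$time)
  if (i == 0) 1 else km$surv[i]
}

#' Cluster cases into risk groups
#'
#' Z-scores the selected features across cases, clusters by Ward-linkage
#' agglomerative clustering on Euclidean distances, and cuts to \code{k}
#' groups.  With survival data supplied and \code{k = 2}, the group with
#' the worse Kaplan-Meier survival at median follow-up is labeled
#' \code{high}.
#'
#' @param profiles cases x features matrix.
#' @param feature_subset features to cluster on (>= 1).
#' @param k number of groups.
#' @param survival optional data.frame with \code{dfs_months}, \code{event}
#'   aligned to the profile rows, used for risk-labeling.
#' @return factor of group labels per case (\code{low}/\code{high} when
#'   \code{k = 2} and survival is given, else \code{"1"..."k"}).
#' @export
clusterRiskGroups <- function(profiles, feature_subset, k = 2L,
                              survival = NULL) {
  if (length(feature_subset) < 1) stop("feature_subset must be non-empty")
  if (k > nrow(profiles)) stop("k exceeds the number of cases")
  X <- profiles[, feature_subset, drop = FALSE]
  s <- apply(X, 2, sd); s[s == 0] <- 1
  X <- sweep(sweep(X, 2, colMeans(X)), 2, s, "/")
  cl <- cutree(hclust(dist(X), method = "ward.D2"), k = k)
  if (k == 2 && !is.null(survival)) {
    med_fu <- median(survival$dfs_months)
    s_at <- vapply(1:2, function(g) {
      sel <- cl == g
      kmSurvivalAt(kmCurve(survival$dfs_months[sel], survival$event[sel]), med_fu)
    }, 0)
    high <- which.min(s_at)
    factor(ifelse(cl == high, "high", "low"), c("low", "high"))
  } else factor(cl)
}

## Precomputed sufficient statistics for repeated two-group log-rank tests
## on the same (times, events) with varying group labels.
logrankPrecompute <- function(times, events) {
  ord <- order(times)
  t <- times[ord]; e <- events[ord]
  uniq <- sort(unique(t[e == 1]))
  first <- match(uniq, t)
  n_at <- length(t) - first + 1L
  time_id <- match(t, uniq)
  time_id[is.na(time_id)] <- 1L          # e = 0 there, contributes nothing
  d <- as.vector(rowsum(e, time_id, reorder = TRUE))[seq_along(uniq)]
  list(ord = ord, e = e, uniq = uniq, first = first, n_at = n_at,
       time_id = time_id, d = d, n = length(t))
}

## p-value of the two-group log-rank test; g1 = logical membership vector.
logrankFast <- function(pre, g1) {
  gs <- g1[pre$ord]
  n1 <- rev(cumsum(rev(gs)))[pre$first]
  d1 <- as.vector(rowsum((pre$e * gs), pre$time_id,
                         reorder = TRUE))[seq_along(pre$uniq)]
  nn <- pre$n_at; d <- pre$d
  E <- sum(d * n1 / nn)
  ok <- nn > 1
  V <- sum((d * (n1 / nn) * (1 - n1 / nn) * (nn - d) / (nn - 1))[ok])
  if (V <= 0) return(1)
  pchisq((sum(d1) - E)^2 / V, 1, lower.tail = FALSE)
}

## log-rank p of the 2-cluster split on a feature subset; splits isolating
## fewer than ~10% of cases are degenerate (spurious outlier clusters) and
## score 1.
subsetLogrankP <- function(profiles, survival, feats) {
  cl <- tryCatch(clusterRiskGroups(profiles, feats, k = 2L),
                 error = function(e) NULL)
  if (is.null(cl) || min(table(cl)) < max(3, round(0.1 * nrow(profiles))))
    return(1)
  tryCatch(logrankTest(survival$dfs_months, survival$event, cl)$p,
           error = function(e) 1)
}

#' Stochastic backward feature selection against the log-rank objective
#'
#' Each iteration subsamples \code{subsample_frac} of the cases (own RNG
#' stream) and runs a full sequential backward elimination from the full
#' candidate set down to 2 features.  The elimination objective for a
#' feature subset is the worst-case (maximum) log10 log-rank p-value of
#' its 2-group Ward clustering over \code{inner_resamples} nested case
#' subsamples: a single p-value is trivially overfit at this cohort size
#' (adversarial splits on noise features reach smaller p than the true
#' risk split), whereas a split must persist across every nested subsample
#' to score well under the worst case.  At each step the feature whose
#' removal minimizes the objective is dropped (ties broken at random --
#' the stochastic element).  The iteration's best set is the smallest set
#' along the path whose objective lies within \code{p_log_tolerance} of
#' the path minimum (a 1-SE-style parsimony rule; plain
#' first-non-improvement stopping stalls on the p plateaus created by
#' redundant features).  Best sets are aggregated into per-feature
#' selection frequencies; the final set takes features above the knee of
#' the sorted-frequency curve, located by Otsu's two-class criterion on
#' the frequency distribution, with a fixed 0.5 fallback when the
#' frequencies show no two-class structure.
#'
#' @param profiles cases x features matrix (already variance-filtered).
#' @param survival data.frame with \code{dfs_months}, \code{event} aligned
#'   to profile rows.
#' @param n_iter iterations (1500 is the canonical setting; scale down
#'   for interactive use).
#' @param subsample_frac case subsampling fraction per iteration.
#' @param inner_resamples nested subsamples averaged in the objective.
#' @param inner_frac case fraction of each nested subsample.
#' @param max_eval_per_step at most this many randomly chosen removal
#'   candidates are scored per elimination step (caps the quadratic path
#'   cost on wide feature sets).
#' @param p_log_tolerance parsimony tolerance in log10-p units for the
#'   per-iteration best set.
#' @param seed integer seed; results are reproducible per seed.
#' @return list of class \code{featureSelection}: \code{selected},
#'   \code{frequency}, \code{n_iter}, \code{seed}, \code{final_logrank_p}
#'   (p of the selected set's clustering on the full cohort).
#' @export
stochasticBackwardSelection <- function(profiles, survival, n_iter = 1500L,
                                        subsample_frac = 0.8,
                                        inner_resamples = 5L,
                                        inner_frac = 0.7,
                                        max_eval_per_step = 20L,
                                        p_log_tolerance = 1, seed = 1L) {
  feats <- colnames(profiles)
  if (length(feats) < 2) stop("need >= 2 candidate features")
  if (nrow(profiles) < 10) stop("need >= 10 cases")
  n <- nrow(profiles)
  counts <- setNames(numeric(length(feats)), feats)
  for (it in seq_len(n_iter)) {
    set.seed(as.integer(seed) + 7919L * it)
    sub <- sort(sample.int(n, max(10L, round(subsample_frac * n))))
    P <- scale(profiles[sub, , drop = FALSE])
    P[, attr(P, "scaled:scale") == 0] <- 0
    S <- survival[sub, , drop = FALSE]
    ## nested subsamples; per-feature squared-distance columns allow O(n^2)
    ## incremental updates of a subset's case-distance matrix
    inner <- lapply(seq_len(inner_resamples), function(i) {
      idx <- sort(sample.int(nrow(P), max(8L, round(inner_frac * nrow(P)))))
      M <- vapply(seq_along(feats), function(j) as.vector(dist(P[idx, j]))^2,
                  numeric(length(idx) * (length(idx) - 1L) / 2L))
      list(idx = idx, M = M, D2 = numeric(nrow(M)),
           lr = logrankPrecompute(S$dfs_months[idx], S$event[idx]),
           min_cl = max(3, round(0.1 * length(idx))))
    })
    for (k in seq_along(inner))
      inner[[k]]$D2 <- rowSums(inner[[k]]$M)
    ## worst-case (max) log10 log-rank p over the nested subsamples: a
    ## split must persist across all of them, which blocks the adversarial
    ## minima a single subsample admits
    objective <- function(drop_j) {
      out <- -Inf
      for (k in seq_along(inner)) {
        st <- inner[[k]]
        D2 <- if (is.na(drop_j)) st$D2 else st$D2 - st$M[, drop_j]
        m <- length(st$idx)
        cl <- cutree(hclust(structure(sqrt(pmax(D2, 0)), Size = m,
                                      class = "dist"), method = "ward.D2"),
                     k = 2L)
        lp <- if (min(tabulate(cl, 2L)) < st$min_cl) 0 else
          log10(max(logrankFast(st$lr, cl == 1L), 1e-300))
        if (lp > out) out <- lp
        if (out >= 0) break
      }
      out
    }
    cur <- seq_along(feats)
    path_sets <- vector("list", length(feats))
    path_obj <- rep(0, length(feats))
    step <- 1L
    path_sets[[1L]] <- cur
    path_obj[1L] <- objective(NA)
    while (length(cur) > 2) {
      cand <- if (length(cur) > max_eval_per_step)
        sort(sample(cur, max_eval_per_step)) else cur
      ps <- vapply(cand, objective, 0)
      tied <- cand[ps <= min(ps) + 1e-12]
      drop <- tied[sample.int(length(tied), 1L)]
      for (k in seq_along(inner))
        inner[[k]]$D2 <- inner[[k]]$D2 - inner[[k]]$M[, drop]
      cur <- setdiff(cur, drop)
      step <- step + 1L
      path_sets[[step]] <- cur
      path_obj[step] <- min(ps)
    }
    path_obj <- path_obj[seq_len(step)]
    ok <- path_obj <= min(path_obj) + p_log_tolerance
    best <- path_sets[[max(which(ok))]]           # path shrinks monotonically
    counts[feats[best]] <- counts[feats[best]] + 1
  }
  freq <- counts / n_iter
  ## knee of the sorted-frequency curve = the threshold separating the
  ## high-frequency cluster from the low-frequency tail, found by Otsu's
  ## two-class criterion on the frequency distribution; fixed 0.5 fallback
  ## when the frequencies show no two-class structure
  thr <- if (sd(freq) > 0.01) otsuThreshold(freq, n_bins = 64L) else 0.5
  selected <- names(freq)[freq > thr]
  if (length(selected) < 1) selected <- names(sf)[1]
  structure(list(selected = selected, frequency = freq,
                 n_iter = as.integer(n_iter), seed = as.integer(seed),
                 threshold = thr,
                 final_logrank_p = subsetLogrankP(profiles, survival, selected)),
            class = "featureSelection")
}

#' Consensus clustering for the number of risk groups
#'
#' Subsample-and-recluster consensus: for each k, cases are repeatedly
#' subsampled and Ward-clustered; the consensus matrix holds the fraction
#' of co-sampled pairs that co-clustered.  The selected k maximizes the
#' average silhouette width of the consensus-derived partition under the
#' consensus dissimilarity (1 - consensus).
#'
#' @param profiles cases x features matrix.
#' @param feature_subset features to cluster on.
#' @param k_range candidate cluster numbers (within [2, n/3]).
#' @param n_resamples subsamples per k.
#' @param subsample_frac fraction of cases per subsample.
#' @param seed integer seed.
#' @return list with \code{selected_k}, \code{silhouette} (named by k),
#'   \code{consensus} (list of consensus matrices).
#' @export
consensusClusterK <- function(profiles, feature_subset, k_range = 2:4,
                              n_resamples = 100L, subsample_frac = 0.8,
                              seed = 1L) {
  n <- nrow(profiles)
  k_range <- k_range[k_range >= 2 & k_range <= max(2, floor(n / 3))]
  if (!length(k_range)) stop("empty k_range after bounds check")
  X <- profiles[, feature_subset, drop = FALSE]
  s <- apply(X, 2, sd)
  if (all(s == 0)) stop("degenerate profiles: all features constant")
  s[s == 0] <- 1
  X <- sweep(sweep(X, 2, colMeans(X)), 2, s, "/")
  sil <- setNames(numeric(length(k_range)), k_range)
  cons_list <- list()
  m <- max(10L, round(subsample_frac * n))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    co <- matrix(0, n, n); tog <- matrix(0, n, n)
    set.seed(as.integer(seed) + 131L * k)
    for (b in seq_len(n_resamples)) {
      sub <- sample.int(n, m)
      cl <- cutree(hclust(dist(X[sub, , drop = FALSE]), "ward.D2"), k = k)
      tog[sub, sub] <- tog[sub, sub] + 1
      same <- outer(cl, cl, "==") + 0
      co[sub, sub] <- co[sub, sub] + same
    }
    cons <- ifelse(tog > 0, co / pmax(tog, 1), 0)
    diag(cons) <- 1
    part <- cutree(hclust(as.dist(1 - cons), "average"), k = k)
    if (min(table(part)) < 1 || length(unique(part)) < 2) { sil[ki] <- -1; next }
    sw <- cluster::silhouette(part, dmatrix = 1 - cons)
    sil[ki] <- mean(sw[, "sil_width"])
    cons_list[[as.character(k)]] <- cons
  }
  list(selected_k = k_range[which.max(sil)], silhouette = sil,
       consensus = cons_list)
}

#' Cox proportional-hazards fit with Harrell's C-index
#'
#' Partial-likelihood fit (Efron ties) via \code{survival::coxph}; Wald 95%
#' CIs; Harrell's C counts concordant comparable pairs with 0.5 per tie.
#' Constant covariates or non-convergence yield a flagged result with NA
#' estimates instead of an error.
#'
#' @param times,events survival outcome.
#' @param covariates data.frame of predictors (factors allowed).
#' @return list with \code{hr} (named), \code{ci_lower}, \code{ci_upper},
#'   \code{p}, \code{c_index}, \code{loglik}, \code{flagged}.
#' @export
coxFit <- function(times, events, covariates) {
  if (sum(events) < 1) stop("need >= 1 event")
  covariates <- as.data.frame(covariates)
  const <- vapply(covariates, function(v) length(unique(v)) < 2, TRUE)
  if (any(const))
    return(list(hr = setNames(rep(NA_real_, ncol(covariates)), names(covariates)),
                ci_lower = NA_real_, ci_upper = NA_real_, p = NA_real_,
                c_index = NA_real_, loglik = NA_real_, flagged = TRUE,
                reason = "constant covariate"))
  df <- cbind(data.frame(.time = times, .event = events), covariates)
  flagged <- FALSE
  fit <- withCallingHandlers(
    coxph(Surv(.time, .event) ~ ., data = df, ties = "efron"),
    warning = function(w) { flagged <<- TRUE; invokeRestart("muffleWarning") })
  sm <- summary(fit)
  list(hr = setNames(sm$conf.int[, "exp(coef)"], rownames(sm$conf.int)),
       ci_lower = sm$conf.int[, "lower .95"],
       ci_upper = sm$conf.int[, "upper .95"],
       p = sm$coefficients[, "Pr(>|z|)"],
       c_index = unname(sm$concordance["C"]),
       loglik = fit$loglik[2], flagged = flagged)
}

#' Intra- versus inter-case variance F-test
#'
#' One-way ANOVA on tile-level feature values grouped by case:
#' F = between-case mean square / within-case mean square, p from the F
#' distribution.  Zero within-case variance follows the sentinel path
#' (infinite F, NA p, flagged).
#'
#' @param values tile-level feature values.
#' @param case_ids case membership of each tile.
#' @return list with \code{F}, \code{p}, \code{df}, \code{flagged}.
#' @export
intraInterVarianceFtest <- function(values, case_ids) {
  case_ids <- as.factor(case_ids)
  tab <- table(case_ids)
  if (length(tab) < 2 || any(tab < 2)) stop("need >= 2 cases with >= 2 tiles each")
  n <- length(values); k <- length(tab)
  gm <- mean(values)
  means <- tapply(values, case_ids, mean)
  ssb <- sum(tab * (means - gm)^2)
  ssw <- sum((values - means[case_ids])^2)
  msb <- ssb / (k - 1); msw <- ssw / (n - k)
  if (msw == 0)
    return(list(F = Inf, p = NA_real_, df = c(k - 1, n - k), flagged = TRUE))
  Fv <- msb / msw
  list(F = Fv, p = pf(Fv, k - 1, n - k, lower.tail = FALSE),
       df = c(k - 1, n - k), flagged = FALSE)
}
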