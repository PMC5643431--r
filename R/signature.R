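## Surrogate gene-signature derivation from selected vascular features.
## Expression is log2(x + 1)-transformed before correlation and modeling:
## Pearson on raw RPKM is dominated by high-expression outliers.

logTransformExpr <- function(expr) log2(pmax(expr, 0) + 1)

#' Rank genes by Pearson correlation with each vascular feature
#'
#' @param expr genes x cases expression matrix (RPKM-like; log2(x+1) is
#'   applied internally).
#' @param vf_table cases x features matrix (rownames = case ids).
#' @param vf_names features to correlate against (default: all columns).
#' @return list of class \code{geneRankings}: per-feature named vectors of
#'   Pearson r across shared cases (constant genes get r = 0, recorded in
#'   \code{attr(, "constant_genes")}); plus \code{n_shared}.
#' @export
correlateGenes <- function(expr, vf_table, vf_names = colnames(vf_table)) {
  shared <- intersect(colnames(expr), rownames(vf_table))
  if (length(shared) < 3) stop("need >= 3 shared cases between tables")
  if (length(shared) < ncol(expr))
    message("dropping ", ncol(expr) - length(shared), " cases absent from vf_table")
  L <- t(logTransformExpr(expr[, shared, drop = FALSE]))  # cases x genes
  const <- apply(L, 2, sd) == 0
  rk <- lapply(vf_names, function(f) {
    r <- suppressWarnings(as.vector(cor(L, vf_table[shared, f])))
    r[const | !is.finite(r)] <- 0
    setNames(r, colnames(L))
  })
  names(rk) <- vf_names
  structure(rk, class = "geneRankings", n_shared = length(shared),
            constant_genes = colnames(L)[const])
}

#' Select candidate genes from the top correlation slices
#'
#' For each feature, the \code{ceiling(fraction * n_genes)} most-positively
#' and most-negatively correlated genes; the union over features is the
#' candidate set.  Ties at a slice boundary break by gene-id lexicographic
#' order (logged via message).
#'
#' @param rankings a \code{geneRankings} from [correlateGenes()].
#' @param fraction per-direction slice fraction in (0, 0.5); the default
#'   0.0005 (0.05%) takes 10 genes per direction at 20000 genes.
#' @return character vector of candidate gene ids (possibly empty, with a
#'   warning, when the slice rounds to 0).
#' @export
selectCandidates <- function(rankings, fraction = 0.0005) {
  if (fraction <= 0 || fraction >= 0.5) stop("fraction must be in (0, 0.5)")
  n_genes <- length(rankings[[1]])
  m <- ceiling(fraction * n_genes)
  if (m == 0) { warning("slice size 0: no candidates"); return(character(0)) }
  out <- character(0)
  for (r in rankings) {
    ## lexicographic gene-id order breaks ties deterministically
    ord_pos <- order(-r, names(r))
    ord_neg <- order(r, names(r))
    if (anyDuplicated(r[ord_pos[seq_len(min(m + 1, length(r)))]]))
      message("correlation tie at slice boundary; gene-id order applied")
    out <- c(out, names(r)[ord_pos[seq_len(m)]], names(r)[ord_neg[seq_len(m)]])
  }
  sort(unique(out))
}

## Fayyad-Irani MDL discretization: recursive entropy-minimizing binary
## splits, each accepted only if information gain beats the MDL cost.
entropyOf <- function(y) {
  p <- table(y) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

mdlCuts <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  rec <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 4) return(numeric(0))
    xs <- x[lo:hi]; ys <- y[lo:hi]
    ent <- entropyOf(ys)
    k <- length(unique(ys))
    if (k < 2) return(numeric(0))
    ## candidate cuts between adjacent distinct values
    idx <- which(diff(xs) > 0)
    if (!length(idx)) return(numeric(0))
    best <- NULL; best_e <- Inf
    for (i in idx) {
      e <- (i / n) * entropyOf(ys[1:i]) + ((n - i) / n) * entropyOf(ys[(i + 1):n])
      if (e < best_e) { best_e <- e; best <- i }
    }
    gain <- ent - best_e
    k1 <- length(unique(ys[1:best])); k2 <- length(unique(ys[(best + 1):n]))
    delta <- log2(3^k - 2) - (k * ent - k1 * entropyOf(ys[1:best]) -
                              k2 * entropyOf(ys[(best + 1):n]))
    if (gain <= (log2(n - 1) + delta) / n) return(numeric(0))
    cut <- (xs[best] + xs[best + 1]) / 2
    c(rec(lo, lo + best - 1), cut, rec(lo + best, hi))
  }
  rec(1, length(x))
}

gainRatio <- function(bins, y) {
  hy <- entropyOf(y)
  hcond <- sum(vapply(split(y, bins), function(s) length(s) * entropyOf(s), 0)) /
    length(y)
  hbins <- entropyOf(bins)
  if (hbins == 0) return(0)
  max((hy - hcond) / hbins, 0)
}

#' Information-gain-ratio filtering of candidate genes
#'
#' Each candidate is discretized by entropy-based MDL binning
#' (Fayyad-Irani); genes where MDL accepts at least one cut and the gain
#' ratio \code{(H(risk) - H(risk | bins)) / H(bins)} is positive form the
#' final set.  For genes with no accepted cut, the reported gain falls back
#' to a median split (the gene is still excluded from the final set).
#'
#' @param expr genes x cases expression matrix.
#' @param candidates candidate gene ids (subset of rownames).
#' @param risk_labels binary risk-group labels aligned to the cases.
#' @param binning \code{"mdl"} (default) or \code{"median"}.
#' @return list of class \code{geneSelection}: \code{candidates},
#'   \code{gain} (named gain ratios), \code{accepted} (MDL acceptance),
#'   \code{final} (gene set).
#' @export
informationGainFilter <- function(expr, candidates, risk_labels,
                                  binning = c("mdl", "median")) {
  binning <- match.arg(binning)
  y <- as.factor(risk_labels)
  if (nlevels(droplevels(y)) != 2) stop("risk_labels must have exactly 2 classes")
  if (!all(candidates %in% rownames(expr))) stop("candidates must be gene ids")
  if (!length(candidates))
    return(structure(list(candidates = character(0), gain = numeric(0),
                          accepted = logical(0), final = character(0)),
                     class = "geneSelection"))
  L <- logTransformExpr(expr[candidates, , drop = FALSE])
  gain <- setNames(numeric(length(candidates)), candidates)
  accepted <- setNames(logical(length(candidates)), candidates)
  for (g in candidates) {
    x <- L[g, ]
    cuts <- if (binning == "mdl") mdlCuts(x, y) else median(x)
    if (length(cuts)) {
      accepted[g] <- TRUE
      bins <- findInterval(x, sort(cuts))
    } else {
      bins <- findInterval(x, median(x))     # reporting fallback only
    }
    gain[g] <- gainRatio(bins, y)
  }
  if (binning == "median") accepted[] <- TRUE
  structure(list(candidates = candidates, gain = gain, accepted = accepted,
                 final = candidates[accepted & gain > 0]),
            class = "geneSelection")
}

risk24moLabels <- function(survival) {
  keep <- !(survival$event == 0 & survival$dfs_months < 24)
  lab <- ifelse(survival$dfs_months < 24 & survival$event == 1, "high", "low")
  list(labels = factor(ifelse(keep, lab, NA), c("low", "high")), keep = keep)
}

#' Train an elastic-net risk model on a gene signature
#'
#' Binomial-loss generalized linear model with elastic-net penalty on the
#' standardized log2 expression of the signature genes; lambda chosen by
#' n-fold cross-validated deviance with the 1-SE rule.  The
#' \code{vf_risk} target trains on supplied risk-group labels; the
#' \code{ground_truth_24mo} target derives labels from 24-month
#' disease-free status, excluding cases censored before 24 months.
#'
#' @param expr genes x cases expression matrix.
#' @param gene_set signature gene ids (non-empty).
#' @param labels two-level risk labels (for target \code{vf_risk}).
#' @param survival survival data.frame (for target \code{ground_truth_24mo}).
#' @param target training target.
#' @param alpha elastic-net mixing (default 0.5).
#' @param n_folds CV folds (default 10).
#' @param seed integer seed governing the fold split.
#' @return list of class \code{riskModel}: the \code{glmnet} cv fit, chosen
#'   lambda, coefficients, target, excluded cases, seed.
#' @export
trainRiskModel <- function(expr, gene_set, labels = NULL, survival = NULL,
                           target = c("vf_risk", "ground_truth_24mo"),
                           alpha = 0.5, n_folds = 10L, seed = 1L) {
  target <- match.arg(target)
  if (!length(gene_set)) stop("empty gene set")
  excluded <- character(0)
  if (target == "ground_truth_24mo") {
    if (is.null(survival)) stop("ground_truth_24mo target needs survival data")
    gt <- risk24moLabels(survival)
    labels <- gt$labels[gt$keep]
    cases <- colnames(expr)[gt$keep]
    excluded <- colnames(expr)[!gt$keep]
  } else {
    if (is.null(labels)) stop("vf_risk target needs labels")
    cases <- colnames(expr)
  }
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2) stop("both risk labels must be present after exclusions")
  X <- t(logTransformExpr(expr[gene_set, cases, drop = FALSE]))
  set.seed(as.integer(seed))
  foldid <- integer(length(y))
  for (l in levels(y)) {
    idx <- which(y == l)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = alpha,
                          foldid = foldid, standardize = TRUE,
                          type.measure = "deviance")
  co <- as.matrix(stats::coef(cv, s = "lambda.1se"))
  structure(list(cv = cv, lambda = cv$lambda.1se, alpha = alpha,
                 coefficients = setNames(co[, 1], rownames(co)),
                 genes = gene_set, levels = levels(y), target = target,
                 excluded_cases = excluded, foldid = foldid,
                 seed = as.integer(seed)),
            class = "riskModel")
}

#' Predict risk groups from a trained model
#'
#' @param model a \code{riskModel}.
#' @param expr genes x cases expression matrix.
#' @param threshold probability threshold for the high-risk call.
#' @return factor of predicted risk groups (levels of the training labels).
#' @export
predictRiskGroup <- function(model, expr, threshold = 0.5) {
  X <- t(logTransformExpr(expr[model$genes, , drop = FALSE]))
  p <- as.vector(stats::predict(model$cv, newx = X, s = "lambda.1se",
                                type = "response"))
  factor(ifelse(p > threshold, model$levels[2], model$levels[1]), model$levels)
}

#' Evaluate a risk model against survival outcomes
#'
#' Predicts risk groups, then reports Kaplan-Meier curves per group, the
#' log-rank test, the univariate Cox hazard ratio of the predicted group,
#' multivariate Cox fits, and Harrell's C-index per covariate set.  For
#' ground-truth-trained models the 24-month rule is applied first (cases
#' censored before 24 months are excluded).
#'
#' @param model a \code{riskModel}.
#' @param expr genes x cases expression matrix.
#' @param survival data.frame with \code{dfs_months}, \code{event}, and
#'   optionally \code{stage_high}, \code{grade_high}, rows aligned to
#'   \code{colnames(expr)}.
#' @param covariate_sets named list of covariate-column sets for C-index
#'   comparison; the predicted risk group is referenced as \code{"risk"}.
#' @return list with \code{groups}, \code{km}, \code{logrank}, \code{cox}
#'   (univariate), \code{cox_multi}, \code{c_index}, \code{flagged}.
#' @export
evaluateRiskModel <- function(model, expr, survival,
                              covariate_sets = list(risk = "risk")) {
  stopifnot(nrow(survival) == ncol(expr))
  if (model$target == "ground_truth_24mo") {
    keep <- !(survival$event == 0 & survival$dfs_months < 24)
    expr <- expr[, keep, drop = FALSE]
    survival <- survival[keep, , drop = FALSE]
  }
  if (ncol(expr) < 10) stop("need >= 10 shared cases for evaluation")
  grp <- predictRiskGroup(model, expr)
  if (length(unique(grp)) < 2)
    return(list(groups = grp, flagged = TRUE,
                reason = "degenerate single predicted group"))
  km <- lapply(split(seq_along(grp), grp), function(i)
    kmCurve(survival$dfs_months[i], survival$event[i]))
  lr <- logrankTest(survival$dfs_months, survival$event, grp)
  cox_uni <- coxFit(survival$dfs_months, survival$event,
                    data.frame(risk = grp))
  covars <- data.frame(risk = grp)
  for (v in c("stage_high", "grade_high"))
    if (v %in% names(survival)) covars[[v]] <- survival[[v]]
  cox_multi <- if (ncol(covars) > 1)
    coxFit(survival$dfs_months, survival$event, covars) else NULL
  cidx <- vapply(covariate_sets, function(set) {
    cc <- covars[, intersect(set, names(covars)), drop = FALSE]
    if (!ncol(cc)) return(NA_real_)
    coxFit(survival$dfs_months, survival$event, cc)$c_index
  }, 0)
  list(groups = grp, km = km, logrank = lr, cox = cox_uni,
       cox_multi = cox_multi, c_index = cidx, flagged = FALSE)
}
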