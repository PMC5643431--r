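## Radial-kernel max-margin classification.  The soft-margin dual
##   min 1/2 a' Q a - 1'a  s.t.  y'a = 0,  0 <= a_i <= C_i
## is a box-constrained QP with one equality, solved exactly with
## quadprog::solve.QP (no SVM package ships in this environment).

rbfKernel <- function(X, Y, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-gamma * pmax(d2, 0))
}

svmFitBinary <- function(X, y, C = 1, gamma = 0.1, weights = c(1, 1)) {
  n <- nrow(X)
  K <- rbfKernel(X, X, gamma)
  Q <- (y %o% y) * K + diag(1e-8, n)
  Ci <- C * ifelse(y > 0, weights[2], weights[1])
  sol <- quadprog::solve.QP(
    Dmat = Q, dvec = rep(1, n),
    Amat = cbind(y, diag(n), -diag(n)),
    bvec = c(0, rep(0, n), -Ci), meq = 1)
  a <- pmin(pmax(sol$solution, 0), Ci)
  sv <- a > 1e-6
  margin <- sv & a < Ci - 1e-6
  f0 <- as.vector(K %*% (a * y))
  b <- if (any(margin)) mean(y[margin] - f0[margin]) else mean(y[sv] - f0[sv])
  list(X = X[sv, , drop = FALSE], coef = (a * y)[sv], b = b, gamma = gamma)
}

svmDecision <- function(fit, X)
  as.vector(rbfKernel(X, fit$X, fit$gamma) %*% fit$coef) + fit$b

#' Train the three-class nucleus classifier
#'
#' One-vs-rest radial-kernel max-margin machines with class-balanced
#' weighting on z-scored features, hyperparameters chosen by grid search
#' with stratified 5-fold cross-validation.
#'
#' @param features numeric matrix, nuclei x features (e.g. the 63-feature
#'   matrix from [extractNuclearFeatures()]).
#' @param classes character/factor vector of true classes (all of
#'   \code{endothelial}, \code{lymphocyte}, \code{cancer} must be present,
#'   or at least two classes for reduced problems).
#' @param cost_grid,gamma_grid hyperparameter grids.
#' @param n_folds stratified cross-validation folds.
#' @param seed integer seed governing the fold split.
#' @return an object of class \code{nucleusClassifier} with per-class
#'   machines, the scaling, CV fold accuracies, and the seed.
#' @export
trainNucleusClassifier <- function(features, classes,
                                   cost_grid = c(1, 10),
                                   gamma_grid = NULL,
                                   n_folds = 5L, seed = 1L) {
  classes <- as.character(classes)
  lv <- sort(unique(classes))
  if (length(lv) < 2) stop("training needs >= 2 classes")
  X <- as.matrix(features)
  ctr <- colMeans(X); scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  if (is.null(gamma_grid)) gamma_grid <- c(0.5, 1, 2) / ncol(Xs)
  set.seed(as.integer(seed))
  folds <- integer(nrow(Xs))
  for (l in lv) {
    idx <- which(classes == l)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fitAll <- function(Xtr, ytr, C, gamma) {
    lapply(lv, function(l) {
      y <- ifelse(ytr == l, 1, -1)
      n1 <- sum(y > 0); n0 <- sum(y < 0)
      w <- length(y) / (2 * c(n0, n1))            # balanced
      svmFitBinary(Xtr, y, C = C, gamma = gamma, weights = w)
    })
  }
  predictAll <- function(fits, Xte)
    vapply(fits, function(f) svmDecision(f, Xte), numeric(nrow(Xte)))
  grid <- expand.grid(C = cost_grid, gamma = gamma_grid)
  cv_acc <- matrix(NA_real_, nrow(grid), n_folds)
  for (g in seq_len(nrow(grid))) {
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      if (length(unique(classes[tr])) < length(lv)) next
      fits <- fitAll(Xs[tr, , drop = FALSE], classes[tr], grid$C[g], grid$gamma[g])
      sc <- predictAll(fits, Xs[!tr, , drop = FALSE])
      pred <- lv[max.col(sc, ties.method = "first")]
      cv_acc[g, f] <- mean(pred == classes[!tr])
    }
  }
  best <- which.max(rowMeans(cv_acc, na.rm = TRUE))
  fits <- fitAll(Xs, classes, grid$C[best], grid$gamma[best])
  structure(list(machines = fits, levels = lv, center = ctr, scale = scl,
                 C = grid$C[best], gamma = grid$gamma[best],
                 cv_accuracy = cv_acc, grid = grid, folds = folds,
                 seed = as.integer(seed)),
            class = "nucleusClassifier")
}

#' Predict nucleus classes
#'
#' @param object a \code{nucleusClassifier}.
#' @param features nuclei x features matrix on the training roster.
#' @param ... unused.
#' @return data.frame with \code{predicted_class} and one decision-score
#'   column per class.
#' @export
predictNucleusClass <- function(object, features, ...) {
  X <- sweep(sweep(as.matrix(features), 2, object$center), 2, object$scale, "/")
  sc <- vapply(object$machines, function(f) svmDecision(f, X), numeric(nrow(X)))
  if (is.null(dim(sc))) sc <- matrix(sc, nrow = nrow(X))
  colnames(sc) <- object$levels
  data.frame(predicted_class = object$levels[max.col(sc, ties.method = "first")],
             sc, check.names = FALSE)
}

#' Evaluate a multi-class classifier
#'
#' Confusion matrix, observed agreement (trace/total), Cohen's kappa
#' \code{(po - pe) / (1 - pe)} with chance agreement from the marginals, and
#' per-class one-vs-rest AUC from decision scores by the midrank statistic.
#'
#' @param predictions character vector of predicted classes.
#' @param truth character vector of true classes (same length, >= 2 classes).
#' @param scores optional items x classes score matrix for AUC.
#' @return list with \code{confusion}, \code{observed_agreement},
#'   \code{cohen_kappa}, and \code{auc_per_class} (NA without scores).
#' @export
evaluateClassifier <- function(predictions, truth, scores = NULL) {
  if (length(predictions) != length(truth)) stop("length mismatch")
  truth <- as.character(truth); predictions <- as.character(predictions)
  if (length(unique(truth)) < 2) stop("truth must contain >= 2 classes")
  lv <- sort(unique(c(truth, predictions)))
  conf <- table(factor(truth, lv), factor(predictions, lv))
  n <- sum(conf)
  po <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  auc <- setNames(rep(NA_real_, length(lv)), lv)
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    for (l in intersect(lv, colnames(scores))) {
      pos <- truth == l
      if (!any(pos) || all(pos)) next
      r <- rank(scores[, l])            # midranks handle ties (AUC 0.5)
      auc[l] <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
        (sum(pos) * sum(!pos))
    }
  }
  list(confusion = unclass(conf), observed_agreement = po,
       cohen_kappa = kappa, auc_per_class = auc)
}
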