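test_that("gene-feature correlation ranking handles exact and planted dependence", {
  # exact +/- linear dependence after the log transform
  n <- 12
  vf <- matrix(seq_len(n), n, 1, dimnames = list(sprintf("c%02d", 1:n), "vf1"))
  expr <- rbind(UP = 2^(seq_len(n)) - 1, DOWN = 2^(n + 1 - seq_len(n)) - 1,
                CONST = rep(3, n))
  colnames(expr) <- rownames(vf)
  rk <- correlateGenes(expr, vf)
  expect_equal(unname(rk$vf1["UP"]), 1)
  expect_equal(unname(rk$vf1["DOWN"]), -1)
  expect_equal(unname(rk$vf1["CONST"]), 0)       # constant gene flagged to 0
  expect_true("CONST" %in% attr(rk, "constant_genes"))

  expect_error(correlateGenes(expr[, 1:2], vf[1:2, , drop = FALSE]), "3 shared")

  # planted correlation recovered within 3 Fisher-z SEs across replicates
  set.seed(14)
  z <- vapply(1:20, function(i) {
    co <- simulateCohort(cohortSpec(n_cases = 64, n_genes = 30,
                                    correlation_strength = 0.6, seed = 400 + i))
    md <- S4Vectors::metadata(co)
    r <- correlateGenes(SummarizedExperiment::assay(co, "rpkm"),
                        vfProfiles(co), md$signal_features[1])[[1]][md$signal_genes[1]]
    atanh(abs(r))
  }, 0)
  se <- 1 / sqrt(64 - 3) / sqrt(20)
  expect_lt(abs(mean(z) - atanh(0.6)), 3 * se * sqrt(20))
})

test_that("candidate slices take the top fraction per direction with deterministic ties", {
  mkRankings <- function(rs) structure(rs, class = "geneRankings")
  genes <- sprintf("G%05d", 1:20000)
  set.seed(15)
  r <- setNames(rnorm(20000), genes)
  # ceil(0.0005 * 20000) = 10 genes per direction
  cand <- selectCandidates(mkRankings(list(vf1 = r)), fraction = 0.0005)
  expect_length(cand, 20)
  expect_setequal(cand, c(names(sort(r, decreasing = TRUE))[1:10],
                          names(sort(r))[1:10]))

  # 9 features with disjoint top slices -> 180 candidates
  rs <- lapply(1:9, function(k) {
    rr <- setNames(rep(0, 20000), genes)
    rr[(k - 1) * 20 + 1:10] <- seq(0.9, 0.5, length.out = 10)
    rr[(k - 1) * 20 + 11:20] <- -seq(0.9, 0.5, length.out = 10)
    rr
  })
  names(rs) <- paste0("vf", 1:9)
  expect_length(selectCandidates(mkRankings(rs), fraction = 0.0005), 180)

  # the ceiling rule keeps one gene per direction even at tiny fractions
  small <- mkRankings(list(vf1 = setNames(rnorm(100), sprintf("g%03d", 1:100))))
  expect_length(selectCandidates(small, fraction = 1e-9), 2)

  # invariant to rank-preserving monotone transforms of the correlations
  r2 <- setNames(tanh(r * 2), genes)       # strictly monotone
  expect_identical(selectCandidates(mkRankings(list(vf1 = r))),
                   selectCandidates(mkRankings(list(vf1 = r2))))

  expect_error(selectCandidates(mkRankings(list(vf1 = r)), fraction = 0.7),
               "fraction")
})

test_that("MDL information-gain filtering accepts separators and rejects noise", {
  # perfect separator into two equal bins: gain ratio exactly 1
  expr <- matrix(2^c(rep(2, 16), rep(6, 16)) - 1, 1, 32,
                 dimnames = list("G1", sprintf("s%02d", 1:32)))
  y <- rep(c("low", "high"), each = 16)
  ig <- informationGainFilter(expr, "G1", y)
  expect_equal(unname(ig$gain["G1"]), 1)
  expect_identical(ig$final, "G1")

  # empty candidate list
  ig0 <- informationGainFilter(expr, character(0), y)
  expect_length(ig0$final, 0)

  # label-independent genes rejected by the MDL criterion in >= 95% of
  # permutations
  set.seed(16)
  rej <- vapply(1:100, function(i) {
    x <- rnorm(40)
    yy <- factor(sample(rep(0:1, 20)))
    length(vasculomorph:::mdlCuts(x, yy)) == 0
  }, TRUE)
  expect_gte(mean(rej), 0.95)

  # gain ratio bounded in [0, 1] on random candidates
  set.seed(17)
  E <- matrix(2^matrix(rnorm(20 * 40, 5), 20, 40) - 1, 20, 40,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:40)))
  igr <- informationGainFilter(E, rownames(E), rep(c("a", "b"), 20))
  expect_true(all(igr$gain >= 0 & igr$gain <= 1))

  expect_error(informationGainFilter(expr, "G1", rep("low", 32)), "2 classes")
  expect_error(informationGainFilter(expr, "NOPE", y), "gene ids")
})

test_that("elastic-net risk models train, reproduce, and respect the 24-month rule", {
  set.seed(18)
  n <- 80
  g1 <- c(rep(2, n / 2), rep(9, n / 2)) + rnorm(n, sd = 0.3)   # decisive gene
  noise <- matrix(rnorm(9 * n, 5), 9, n)
  expr <- 2^rbind(g1, noise) - 1
  rownames(expr) <- sprintf("G%02d", 1:10)
  colnames(expr) <- sprintf("c%02d", 1:n)
  labels <- factor(rep(c("low", "high"), each = n / 2), c("low", "high"))

  m <- trainRiskModel(expr, rownames(expr), labels = labels, seed = 4)
  expect_true(m$coefficients["G01"] != 0)        # decisive gene kept
  pr <- predictRiskGroup(m, expr)
  expect_gte(mean(pr == labels), 0.95)

  # same seed, same fold split, same lambda
  m2 <- trainRiskModel(expr, rownames(expr), labels = labels, seed = 4)
  expect_identical(m$lambda, m2$lambda)
  expect_identical(m$foldid, m2$foldid)

  # intercept-only at the top of the lambda path
  co_max <- as.matrix(stats::coef(m$cv$glmnet.fit, s = max(m$cv$lambda)))
  expect_true(all(co_max[-1, 1] == 0))

  # 24-month ground-truth target: censored-before-24 cases are excluded
  surv <- data.frame(dfs_months = c(10, 30, 10, 40, rep(c(12, 36), n / 2 - 2)),
                     event = c(0, 1, 1, 0, rep(c(1, 0), n / 2 - 2)))
  mg <- trainRiskModel(expr, rownames(expr), survival = surv,
                       target = "ground_truth_24mo", seed = 4)
  expect_identical(mg$excluded_cases, "c01")     # censored at 10 months
  expect_equal(mg$target, "ground_truth_24mo")

  expect_error(trainRiskModel(expr, character(0), labels = labels), "empty")
  expect_error(trainRiskModel(expr, rownames(expr),
                              labels = factor(rep("low", n))), "present")
})

test_that("risk-model evaluation recovers planted hazards and calibrates C-index", {
  # planted cohort: model trained on true groups evaluates near the planted HR
  # near-noiseless expression so the model reproduces the planted groups
  set.seed(19)
  loghr <- vapply(1:12, function(i) {
    co <- simulateCohort(cohortSpec(n_genes = 40, correlation_strength = 0.95,
                                    seed = 600 + i))
    md <- S4Vectors::metadata(co)
    ex <- SummarizedExperiment::assay(co, "rpkm")
    m <- trainRiskModel(ex, md$signal_genes, labels = riskGroups(co), seed = i)
    ev <- evaluateRiskModel(m, ex, survivalTable(co))
    if (isTRUE(ev$flagged)) return(NA_real_)
    log(ev$cox$hr[1])
  }, 0)
  loghr <- loghr[is.finite(loghr)]
  expect_gte(length(loghr), 8)
  se <- sd(loghr) / sqrt(length(loghr))
  expect_lt(abs(mean(loghr) - log(2.4)), 2 * se)

  # outcome-independent covariates give C-index near 0.5 (a refitted Cox
  # model is optimistically biased by ~c/sqrt(n), hence the absolute band)
  set.seed(20)
  cs <- vapply(1:20, function(i) {
    t <- rexp(60, 0.05); e <- rbinom(60, 1, 0.8); x <- rnorm(60)
    coxFit(t, e, data.frame(x = x))$c_index
  }, 0)
  expect_lt(abs(mean(cs) - 0.5), 0.05)

  # adding an informative covariate does not decrease the training C-index
  co <- simulateCohort(cohortSpec(seed = 77, n_genes = 40))
  sv <- survivalTable(co)
  c_stage <- coxFit(sv$dfs_months, sv$event,
                    data.frame(stage = sv$stage_high))$c_index
  c_both <- coxFit(sv$dfs_months, sv$event,
                   data.frame(stage = sv$stage_high,
                              risk = riskGroups(co)))$c_index
  expect_gte(c_both, c_stage - 1e-9)
})
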