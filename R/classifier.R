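#' Build balanced training sets from activity extremes
#'
#' Splits the candidate regions by promoter overlap (>= 1 bp with the
#' supplied promoter windows, typically 500 bp upstream of TSSs), then
#' within each branch selects the `fraction` highest-scoring regions as
#' the active class and the equally many lowest-scoring as the inactive
#' class - 1% extremes for the (non-promoter) enhancer model and 10% for
#' the E-promoter model by default, mirroring the much smaller promoter
#' branch.
#'
#' @param regions `GRanges` of candidate regions.
#' @param logScore per-region log STARR scores, parallel to `regions`.
#' @param promoters `GRanges` of promoter windows.
#' @param fractionEnhancer,fractionPromoter extreme fractions per branch.
#' @return list with elements `enhancer` and `promoter`, each a list of
#'   integer indices `active`, `inactive` (into `regions`) and `indices`
#'   (the branch membership).
#' @export
buildTrainingSets <- function(regions, logScore, promoters,
                              fractionEnhancer = 0.01,
                              fractionPromoter = 0.10) {
  stopifnot(length(regions) == length(logScore))
  inProm <- GenomicRanges::countOverlaps(regions, promoters,
    minoverlap = 1L, ignore.strand = TRUE) > 0
  branch <- function(idx, fraction) {
    if (length(idx) == 0L) stop("empty promoter/non-promoter split")
    ext <- selectExtremes(logScore[idx], fraction)
    list(active = idx[ext$top], inactive = idx[ext$bottom], indices = idx)
  }
  list(enhancer = branch(which(!inProm), fractionEnhancer),
       promoter = branch(which(inProm), fractionPromoter))
}

#' Sequence feature table for activity classification
#'
#' One row per region: region width plus, per motif, the count of
#' significant non-overlapping hits ([countHitsPerRegion()]). Columns are
#' named by motif cluster. Counts are left unstandardized here;
#' standardization happens inside the cross-validation on training folds
#' only, to avoid information leakage.
#'
#' @param sequences region sequences (`DNAStringSet` or character).
#' @param motifs list of [MotifMatrix-class].
#' @param thresholdP hit tail probability (default 1e-4).
#' @return numeric matrix with a `width` column followed by one column per
#'   motif.
#' @export
buildFeatureTable <- function(sequences, motifs, thresholdP = 1e-4) {
  counts <- countHitsPerRegion(sequences, motifs, thresholdP,
                               perMotif = TRUE)
  colnames(counts) <- vapply(motifs, motifCluster, "")
  cbind(width = nchar(as.character(sequences)), counts)
}

#' Nested cross-validated elastic-net activity classifier
#'
#' Fits a regularized logistic regression (elastic net) to separate active
#' from inactive regions, with nested cross-validation: the outer loop
#' holds out each of `outerFolds` stratified folds (25% with the default
#' 4) to measure predictive performance on unseen data; the inner loop
#' grid-searches the mixing parameter alpha and penalty strength lambda on
#' the remaining 75%, selecting the pair that maximizes the mean inner-fold
#' AUC. Feature standardization parameters are learned on the training
#' portion of each split only. Final coefficients come from refitting the
#' overall best configuration on all data.
#'
#' @param features numeric matrix (rows = regions), e.g. from
#'   [buildFeatureTable()].
#' @param labels binary labels (logical, 0/1, or a 2-level factor whose
#'   first level is the positive class).
#' @param outerFolds,innerFolds fold counts (defaults 4 and 5).
#' @param alphaGrid elastic-net mixing grid (default 0, 0.1, ..., 1).
#' @param lambdaGrid penalty grid (default 30 log-spaced values in
#'   1e-3..1e2).
#' @param seed seed for the fold assignment.
#' @return a [ClassifierReport-class].
#' @export
nestedCvElasticNet <- function(features, labels, outerFolds = 4L,
                               innerFolds = 5L,
                               alphaGrid = seq(0, 1, by = 0.1),
                               lambdaGrid = 10^seq(2, -3, length.out = 30),
                               seed = 1L) {
  y <- if (is.factor(labels)) as.integer(labels == levels(labels)[1L])
       else as.integer(labels)
  stopifnot(all(y %in% 0:1), nrow(features) == length(y))
  if (min(table(y)) < outerFolds * 2L)
    stop("too few observations per class for ", outerFolds, " outer folds")
  x <- as.matrix(features)
  lambdaGrid <- sort(lambdaGrid, decreasing = TRUE)

  stratFolds <- function(yy, k) {
    f <- integer(length(yy))
    for (cls in unique(yy)) {
      idx <- sample(which(yy == cls))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  }
  standardize <- function(train, test) {
    mu <- colMeans(train)
    sdv <- apply(train, 2, sd)
    sdv[sdv == 0] <- 1
    list(train = scale(train, mu, sdv), test = scale(test, mu, sdv))
  }
  ## mean inner-CV AUC for every (alpha, lambda) on rows `idx`
  innerSearch <- function(idx, innerFold) {
    aucs <- array(NA_real_, c(length(alphaGrid), length(lambdaGrid),
                              innerFolds))
    for (f in seq_len(innerFolds)) {
      tr <- idx[innerFold != f]; va <- idx[innerFold == f]
      st <- standardize(x[tr, , drop = FALSE], x[va, , drop = FALSE])
      for (a in seq_along(alphaGrid)) {
        fit <- glmnet::glmnet(st$train, y[tr], family = "binomial",
                              alpha = alphaGrid[a], lambda = lambdaGrid,
                              standardize = FALSE)
        pred <- glmnet::predict.glmnet(fit, st$test, s = lambdaGrid)
        aucs[a, , f] <- apply(pred, 2, function(p)
          tryCatch(aucFromScores(p, y[va]), error = function(e) NA_real_))
      }
    }
    apply(aucs, c(1, 2), mean, na.rm = TRUE)
  }
  bestConfig <- function(meanAuc) {
    ## ties: prefer larger lambda (more regularized), then smaller alpha
    best <- which(meanAuc == max(meanAuc, na.rm = TRUE), arr.ind = TRUE)
    best <- best[order(best[, 2L], best[, 1L]), , drop = FALSE]
    c(alpha = alphaGrid[best[1L, 1L]], lambda = lambdaGrid[best[1L, 2L]])
  }

  withSeed(seed, {
    outer <- stratFolds(y, outerFolds)
    innerAucSum <- NULL
    foldAUC <- numeric(outerFolds)
    for (k in seq_len(outerFolds)) {
      trainIdx <- which(outer != k)
      testIdx <- which(outer == k)
      innerFold <- stratFolds(y[trainIdx], innerFolds)
      meanAuc <- innerSearch(trainIdx, innerFold)
      innerAucSum <- if (is.null(innerAucSum)) meanAuc
                     else innerAucSum + meanAuc
      cfg <- bestConfig(meanAuc)
      st <- standardize(x[trainIdx, , drop = FALSE],
                        x[testIdx, , drop = FALSE])
      fit <- glmnet::glmnet(st$train, y[trainIdx], family = "binomial",
                            alpha = cfg["alpha"], lambda = lambdaGrid,
                            standardize = FALSE)
      pred <- glmnet::predict.glmnet(fit, st$test, s = cfg["lambda"])
      foldAUC[k] <- aucFromScores(as.numeric(pred), y[testIdx])
    }
    cfg <- bestConfig(innerAucSum / outerFolds)
    stAll <- standardize(x, x)
    fitAll <- glmnet::glmnet(stAll$train, y, family = "binomial",
                             alpha = cfg["alpha"], lambda = lambdaGrid,
                             standardize = FALSE)
    beta <- as.numeric(glmnet::coef.glmnet(fitAll, s = cfg["lambda"]))[-1L]
    coefs <- data.frame(feature = colnames(x), coefficient = beta,
                        stringsAsFactors = FALSE)
    new("ClassifierReport", foldAUC = foldAUC, coefficients = coefs,
        alpha = unname(cfg["alpha"]), lambda = unname(cfg["lambda"]),
        nObs = length(y))
  })
}

#' Rank classifier features by coefficient magnitude
#'
#' @param report a [ClassifierReport-class].
#' @param topN number of features to return (default 30; all nonzero
#'   features if fewer).
#' @return data.frame ordered by decreasing |coefficient|, sign retained
#'   (positive = associated with the active class). Warns when the model
#'   is all-zero.
#' @export
rankCoefficients <- function(report, topN = 30L) {
  co <- classifierCoefficients(report)
  co <- co[co$coefficient != 0, , drop = FALSE]
  if (nrow(co) == 0L) {
    warning("model has no nonzero coefficients")
    return(co)
  }
  co <- co[order(-abs(co$coefficient), co$feature), , drop = FALSE]
  rownames(co) <- NULL
  head(co, topN)
}
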