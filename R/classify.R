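# Elastic-net regularised logistic classification of HICs vs non-HICs:
# class-balanced training subsampling, leave-one-out lambda selection,
# Youden-index probability threshold, and repeated class-imbalanced test
# evaluation with rank-based AUC, balanced accuracy and Cohen's kappa.

# Coerce labels of any reasonable encoding to logical "is HIC".
asHicLabel <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) return(labels == "HIC")
  if (is.numeric(labels)) return(labels != 0)
  stop("cannot interpret labels of class ", class(labels)[1])
}

#' Balance a training table by subsampling the majority class
#'
#' Retains the HIC rows (up to \code{nPerClass}) and randomly subsamples the
#' non-HIC rows without replacement to the same count, yielding a 50/50
#' training set.
#'
#' @param table data.frame with a \code{label} column ("HIC"/"non-HIC").
#' @param nPerClass target rows per class; default = number of HIC rows.
#' @param seed RNG seed (subsampling is reproducible).
#' @return the balanced data.frame (row order: HICs then non-HICs).
#' @export
balanceTrainingSet <- function(table, nPerClass = NULL, seed = 1L) {
  isHic <- asHicLabel(table$label)
  nH <- sum(isHic); nN <- sum(!isHic)
  if (nH < 1 || nN < 1) stop("need at least one row of each class")
  if (is.null(nPerClass)) nPerClass <- nH
  if (nH < nPerClass) {
    warning("only ", nH, " HIC rows available (requested ", nPerClass,
            "); using all of them")
    nPerClass <- nH
  }
  if (nN < nPerClass) stop("fewer non-HIC rows (", nN, ") than target ", nPerClass)
  withSeed(seed, {
    hi <- sample(which(isHic), nPerClass)
    ni <- sample(which(!isHic), nPerClass)
    table[c(hi, ni), , drop = FALSE]
  })
}

#' Youden-index probability threshold
#'
#' Maximises J = sensitivity + specificity - 1 over all candidate
#' cut-points (midpoints of consecutive sorted unique probabilities), with a
#' classification rule of "HIC if probability > threshold". Ties in J break
#' toward the lower threshold, favouring sensitivity.
#'
#' @param probabilities predicted HIC probabilities.
#' @param labels true labels ("HIC"/"non-HIC", factor or logical).
#' @return list with \code{threshold}, \code{J} and \code{degenerate}
#'   (TRUE when all probabilities coincide, in which case J = 0).
#' @export
youdenThreshold <- function(probabilities, labels) {
  y <- asHicLabel(labels)
  stopifnot(length(probabilities) == length(y))
  if (!any(y) || all(y)) stop("both classes must be present")
  u <- sort(unique(probabilities))
  if (length(u) == 1)
    return(list(threshold = u, J = 0, degenerate = TRUE))
  cand <- (u[-1] + u[-length(u)]) / 2
  J <- vapply(cand, function(th)
    mean(probabilities[y] > th) + mean(probabilities[!y] <= th) - 1, 0)
  best <- which.max(J)             # first maximum = lowest threshold
  list(threshold = cand[best], J = J[best], degenerate = FALSE)
}

#' Fit the elastic-net HIC classifier
#'
#' Penalised logistic regression over a lambda path with the shrinkage
#' parameter chosen by leave-one-out cross-validated deviance. The
#' probability threshold is frozen at training time by applying the Youden
#' index to the leave-one-out held-out probabilities at the selected lambda,
#' avoiding both resubstitution optimism and test-set leakage.
#'
#' @param x numeric feature matrix (rows = components); should be the
#'   normalized features of a balanced training set.
#' @param labels training labels ("HIC"/"non-HIC", factor or logical).
#' @param mixingAlpha elastic-net mixing parameter (0 = ridge, 1 = lasso;
#'   default 0.5).
#' @param seed RNG seed recorded in the metadata (the LOO fold structure is
#'   deterministic).
#' @return a fitted \linkS4class{HicModel}.
#' @export
fitHicModel <- function(x, labels, mixingAlpha = 0.5, seed = 1L) {
  x <- as.matrix(x)
  y <- asHicLabel(labels)
  stopifnot(nrow(x) == length(y), !anyNA(x))
  if (!any(y) || all(y)) stop("both classes must be present for fitting")
  n <- nrow(x)
  cv <- withSeed(seed, glmnet::cv.glmnet(
    x, factor(y, levels = c(FALSE, TRUE)), family = "binomial",
    alpha = mixingAlpha, nfolds = n, foldid = seq_len(n), grouped = FALSE,
    type.measure = "deviance", keep = TRUE))
  iBest <- which(cv$lambda == cv$lambda.min)[1]
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
  names(beta) <- rownames(stats::coef(cv, s = "lambda.min"))
  looProb <- stats::plogis(cv$fit.preval[, iBest])
  thr <- youdenThreshold(looProb, y)
  new("HicModel",
      coefficients = beta[-1], intercept = unname(beta[1]),
      mixingAlpha = mixingAlpha, shrinkageLambda = cv$lambda.min,
      probabilityThreshold = min(max(thr$threshold, 1e-8), 1 - 1e-8),
      trainingMetadata = list(seed = seed, nTraining = n,
                              folds = "leave-one-out",
                              selection = "min mean held-out deviance",
                              youdenJ = thr$J,
                              thresholdSource = "LOO held-out probabilities",
                              lambdaPath = range(cv$lambda)))
}

#' Predicted HIC probabilities or classes
#'
#' @param object a fitted \linkS4class{HicModel}.
#' @param newdata feature matrix or data.frame containing the model's
#'   feature columns.
#' @param type "response" for probabilities, "class" for thresholded
#'   "HIC"/"non-HIC" calls (rule: probability > stored threshold).
#' @param ... ignored.
#' @return numeric probabilities or character classes.
#' @export
setMethod("predict", "HicModel", function(object, newdata,
                                          type = c("response", "class"), ...) {
  type <- match.arg(type)
  feats <- names(object@coefficients)
  if (is.data.frame(newdata)) {
    missing <- setdiff(feats, colnames(newdata))
    if (length(missing)) stop("newdata lacks features: ",
                              paste(missing, collapse = ", "))
    newdata <- as.matrix(newdata[, feats, drop = FALSE])
  }
  stopifnot(ncol(newdata) == length(feats))
  p <- stats::plogis(object@intercept +
                     as.numeric(newdata %*% object@coefficients))
  if (type == "response") p
  else ifelse(p > object@probabilityThreshold, "HIC", "non-HIC")
})

#' Rank-based AUC (Mann-Whitney with midrank ties)
#'
#' The probability that a randomly chosen HIC receives a higher score than a
#' randomly chosen non-HIC, with ties counted half.
#'
#' @param scores predicted probabilities or any monotone score.
#' @param labels true labels.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, labels) {
  y <- asHicLabel(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)                 # midranks
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cohen's kappa for binary agreement
#'
#' Chance-corrected agreement (p_o - p_e) / (1 - p_e), with chance agreement
#' p_e from the marginal products. When both raters are constant and equal
#' (p_e = 1) kappa is defined as 1.
#'
#' @param predicted,truth equal-length binary vectors (logical, 0/1 or
#'   "HIC"/"non-HIC").
#' @return kappa in [-1, 1].
#' @export
cohensKappa <- function(predicted, truth) {
  p <- asHicLabel(predicted); y <- asHicLabel(truth)
  stopifnot(length(p) == length(y))
  po <- mean(p == y)
  pe <- mean(p) * mean(y) + mean(!p) * mean(!y)
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Evaluate a fitted model on repeated imbalanced test subsamples
#'
#' Repeatedly samples (without replacement, per iteration) \code{nHic} HICs
#' and \code{nNonHic} non-HICs from a held-out test pool, mirroring the
#' roughly 1:10 class ratio of real component shortlists, and computes AUC
#' (threshold-free), sensitivity, specificity, balanced accuracy and
#' Cohen's kappa at the model's frozen probability threshold.
#'
#' @param model a fitted \linkS4class{HicModel}.
#' @param table test-pool data.frame (disjoint from the training rows) with
#'   a \code{label} column and the model's feature columns.
#' @param nIterations number of test subsamples (default 50).
#' @param nHic,nNonHic per-iteration class counts (default 5 and 50).
#' @param seed RNG seed.
#' @return a \linkS4class{MetricsReport}.
#' @export
evaluateModel <- function(model, table, nIterations = 50L, nHic = 5L,
                          nNonHic = 50L, seed = 1L) {
  stopifnot(is(model, "HicModel"))
  y <- asHicLabel(table$label)
  iH <- which(y); iN <- which(!y)
  if (length(iH) < nHic || length(iN) < nNonHic)
    stop("test pool too small: has ", length(iH), " HICs (need ", nHic,
         ") and ", length(iN), " non-HICs (need ", nNonHic, ")")
  prob <- predict(model, table, type = "response")
  thr <- model@probabilityThreshold
  withSeed(seed, {
    rows <- lapply(seq_len(nIterations), function(it) {
      s <- c(sample(iH, nHic), sample(iN, nNonHic))
      ys <- y[s]; ps <- prob[s]
      call <- ps > thr
      sens <- mean(call[ys]); spec <- mean(!call[!ys])
      data.frame(iteration = it, auc = aucScore(ps, ys),
                 balancedAccuracy = (sens + spec) / 2,
                 sensitivity = sens, specificity = spec,
                 kappa = cohensKappa(call, ys))
    })
    iterations <- do.call(rbind, rows)
    med <- vapply(iterations[, -1], stats::median, 0)
    new("MetricsReport", iterations = iterations, medians = med,
        nIterations = as.integer(nIterations))
  })
}

#' Per-feature odds ratios
#'
#' The multiplicative change in HIC odds per unit increase of each
#' (normalized) feature: exp of the model coefficients. Features removed by
#' the penalty have coefficient 0 and odds ratio exactly 1.
#'
#' @param model a fitted \linkS4class{HicModel}.
#' @return named positive numeric vector.
#' @export
oddsRatios <- function(model) {
  stopifnot(is(model, "HicModel"))
  exp(model@coefficients)
}
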