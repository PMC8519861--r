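# End-to-end classifier protocol on synthetic feature tables: draw labelled
# feature vectors from the reference per-class distributions, min-max
# normalize, train on a balanced subsample with LOO-CV elastic net and a
# frozen Youden threshold, then evaluate on repeated imbalanced subsamples
# of the held-out pool.

#' Run the full HIC classifier protocol on a synthetic feature table
#'
#' Draws \code{nHic} HIC and \code{nNonHic} non-HIC feature vectors from the
#' per-class reference distributions, min-max normalizes each classifier
#' feature across the table, trains an elastic-net logistic model on a
#' balanced subsample of \code{nTrainPerClass} rows per class (lambda by
#' leave-one-out CV, probability threshold by Youden's index on the LOO
#' held-out probabilities) and evaluates it over \code{nIterations} random
#' test subsamples of 5 HICs and 50 non-HICs drawn from the held-out rows.
#'
#' @param nHic,nNonHic synthetic pool sizes (defaults 57 and 471).
#' @param nTrainPerClass rows per class in the balanced training set
#'   (default 23).
#' @param moments per-class feature moments
#'   (default \code{\link{referenceFeatureMoments}}).
#' @param mixingAlpha elastic-net mixing parameter (default 0.5).
#' @param nIterations,nTestHic,nTestNonHic test protocol sizes
#'   (defaults 50, 5, 50).
#' @param seed master RNG seed; table draw, training subsample and test
#'   subsamples all derive from it.
#' @return list with \code{model} (\linkS4class{HicModel}),
#'   \code{metrics} (\linkS4class{MetricsReport}), \code{table} (the drawn
#'   feature table) and \code{trainingRows} (row indices used in training).
#' @export
runClassifierProtocol <- function(nHic = 57L, nNonHic = 471L,
                                  nTrainPerClass = 23L,
                                  moments = referenceFeatureMoments(),
                                  mixingAlpha = 0.5, nIterations = 50L,
                                  nTestHic = 5L, nTestNonHic = 50L,
                                  seed = 1L) {
  seed <- as.integer(seed)
  table <- simulateFeatureTable(nHic, nNonHic, moments, seed = seed)
  feats <- intersect(hicModelFeatures(), colnames(table))

  norm <- table
  for (f in feats) norm[[f]] <- as.numeric(minmaxNormalize(table[[f]]))

  norm$row <- seq_len(nrow(norm))
  train <- balanceTrainingSet(norm, nPerClass = nTrainPerClass,
                              seed = seed + 1L)
  model <- fitHicModel(train[, feats], train$label, mixingAlpha,
                       seed = seed + 2L)
  pool <- norm[-train$row, , drop = FALSE]
  metrics <- evaluateModel(model, pool, nIterations = nIterations,
                           nHic = nTestHic, nNonHic = nTestNonHic,
                           seed = seed + 3L)
  list(model = model, metrics = metrics, table = table,
       trainingRows = train$row)
}
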