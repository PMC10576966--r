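# F-score feature ranking, incremental selection, NearMiss undersampling,
# classifier training and evaluation.

#' F-score ranking of features
#'
#' For feature i with class means m+, m-, grand mean m and sample variances
#' v+, v- (divisor n-1), the F-score is
#' \code{((m+ - m)^2 + (m- - m)^2) / (v+ + v-)}. A zero denominator
#' (feature constant within both classes) scores 0. Higher scores mark
#' features that separate the classes more strongly.
#'
#' @param features numeric matrix, samples in rows.
#' @param labels class labels; both classes must have at least 2 samples.
#' @return an \linkS4class{FScoreRanking} (scores plus the permutation
#'   ordering them non-increasingly, ties broken by ascending index).
#' @examples
#' fScores(matrix(c(0, 2, 4, 6)), c(1, 1, 0, 0))  # F = 2
#' @export
fScores <- function(features, labels) {
  features <- as.matrix(features)
  pos <- .isPositive(labels)
  if (sum(pos) < 2 || sum(!pos) < 2)
    stop("each class needs at least 2 samples")
  mp <- colMeans(features[pos, , drop = FALSE])
  mn <- colMeans(features[!pos, , drop = FALSE])
  mg <- colMeans(features)
  vp <- apply(features[pos, , drop = FALSE], 2, var)
  vn <- apply(features[!pos, , drop = FALSE], 2, var)
  num <- (mp - mg)^2 + (mn - mg)^2
  den <- vp + vn
  sc <- ifelse(den == 0, 0, num / den)
  sc <- unname(sc)
  new("FScoreRanking", scores = sc,
      order = as.integer(order(-sc, seq_along(sc))))
}

#' NearMiss undersampling (version 1)
#'
#' Keeps every minority-class sample and the \code{|minority|}
#' majority-class samples with the smallest mean Euclidean distance to
#' their \code{k} nearest minority neighbours (all minority samples when
#' fewer than \code{k} exist). Distances are computed on the raw feature
#' values; ties break by ascending sample index. Already-balanced input is
#' returned unchanged.
#'
#' @param features numeric matrix, samples in rows.
#' @param labels class labels.
#' @param k number of minority neighbours averaged (default 3).
#' @return sorted integer vector of retained row indices.
#' @export
nearMiss <- function(features, labels, k = 3) {
  features <- as.matrix(features)
  pos <- .isPositive(labels)
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0 || nN == 0) stop("both classes must be present")
  if (nP == nN) return(seq_len(nrow(features)))
  minority <- if (nP < nN) which(pos) else which(!pos)
  majority <- setdiff(seq_len(nrow(features)), minority)
  Mi <- features[minority, , drop = FALSE]
  kk <- min(k, length(minority))
  meanDist <- vapply(majority, function(j) {
    d <- sqrt(colSums((t(Mi) - features[j, ])^2))
    mean(sort(d)[seq_len(kk)])
  }, 1.0)
  sel <- majority[order(meanDist, majority)][seq_len(length(minority))]
  sort(c(minority, sel))
}

#' Classifier configuration
#'
#' @param kind \code{"gbc"} (gradient boosting), \code{"rfc"} (random
#'   forest) or \code{"svc"} (RBF support-vector classifier).
#' @param nEstimators ensemble size; defaults to 500 for gbc and 370 for
#'   rfc, the published settings.
#' @param seed integer seed used for every fit.
#' @return a \linkS4class{ModelConfig}.
#' @export
modelConfig <- function(kind = c("gbc", "rfc", "svc"), nEstimators = NULL,
                        seed = 1) {
  kind <- match.arg(kind)
  if (is.null(nEstimators))
    nEstimators <- switch(kind, gbc = 500, rfc = 370, svc = 0)
  new("ModelConfig", kind = kind, nEstimators = nEstimators, seed = seed)
}

# fit on (xtr, ptr) and return P(positive) for xte
.fitPredict <- function(cfg, xtr, ptr, xte) {
  xtr <- as.matrix(xtr); xte <- as.matrix(xte)
  set.seed(cfg@seed)
  if (cfg@kind == "gbc") {
    fit <- xgboost::xgboost(
      x = xtr, y = factor(ptr, levels = c(FALSE, TRUE)),
      objective = "binary:logistic", nrounds = cfg@nEstimators,
      learning_rate = 0.1, max_depth = 3, nthreads = 1,
      tree_method = "exact", seed = cfg@seed, verbosity = 0)
    # probability of the positive (second) factor level
    as.numeric(predict(fit, xte, type = "response"))
  } else if (cfg@kind == "rfc") {
    fit <- randomForest::randomForest(
      x = xtr, y = factor(ptr, levels = c(FALSE, TRUE)),
      ntree = cfg@nEstimators, mtry = max(1, floor(sqrt(ncol(xtr)))))
    predict(fit, xte, type = "prob")[, "TRUE"]
  } else {
    keep <- apply(xtr, 2, function(v) var(v) > 0)
    fit <- e1071::svm(
      x = xtr[, keep, drop = FALSE],
      y = factor(ptr, levels = c(FALSE, TRUE)),
      kernel = "radial", gamma = 1 / sum(keep), probability = TRUE,
      scale = TRUE)
    pr <- predict(fit, xte[, keep, drop = FALSE], probability = TRUE)
    attr(pr, "probabilities")[, "TRUE"]
  }
}

# stratified fold assignment (seeded shuffling within classes)
.stratifiedFolds <- function(pos, k, seed) {
  out <- integer(length(pos))
  set.seed(seed)
  for (cls in c(TRUE, FALSE)) {
    i <- which(pos == cls)
    if (length(i) == 0) next
    out[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  out
}

#' Stratified k-fold cross-validation
#'
#' Seeded stratified folds; each fold is held out once. Confusion counts
#' are pooled over folds at the 0.5 probability threshold and the AUC is
#' computed on the pooled out-of-fold probabilities, giving one ROC per
#' run. The per-fold metric breakdown is kept in the report.
#'
#' @param features numeric matrix, samples in rows.
#' @param labels class labels.
#' @param cfg a \linkS4class{ModelConfig}.
#' @param k number of folds (at most the minority-class size).
#' @param seed seed for the fold assignment.
#' @return an \linkS4class{EvalReport}.
#' @export
crossValidate <- function(features, labels, cfg = modelConfig("gbc"),
                          k = 10, seed = 1) {
  features <- as.matrix(features)
  pos <- .isPositive(labels)
  if (k < 2) stop("k must be at least 2")
  if (k > min(sum(pos), sum(!pos)))
    stop("k exceeds the smaller class size")
  fold <- .stratifiedFolds(pos, k, seed)
  prob <- numeric(length(pos))
  perFold <- vector("list", k)
  for (f in seq_len(k)) {
    te <- fold == f
    prob[te] <- .fitPredict(cfg, features[!te, , drop = FALSE], pos[!te],
                            features[te, , drop = FALSE])
    m <- confusionMetrics(sum(prob[te] >= 0.5 & pos[te]),
                          sum(prob[te] < 0.5 & !pos[te]),
                          sum(prob[te] >= 0.5 & !pos[te]),
                          sum(prob[te] < 0.5 & pos[te]))
    perFold[[f]] <- data.frame(fold = f, t(m))
  }
  .evalReport(prob, pos, folds = do.call(rbind, perFold))
}

#' Repeated stratified independent-set tests
#'
#' Splits the data into train/test at the given ratio (stratified,
#' seeded), evaluates once per repeat, and summarises each metric as mean
#' and standard deviation over the repeats.
#'
#' @param features numeric matrix, samples in rows.
#' @param labels class labels.
#' @param cfg a \linkS4class{ModelConfig}.
#' @param testSize held-out fraction (e.g. 0.2, 0.25, 0.3).
#' @param repeats number of random splits.
#' @param seed base seed; repeat r uses \code{seed + r}.
#' @return list with \code{reports} (one \linkS4class{EvalReport} per
#'   repeat) and \code{summary} (data.frame of metric means and sds).
#' @export
independentTest <- function(features, labels, cfg = modelConfig("gbc"),
                            testSize = 0.2, repeats = 50, seed = 1) {
  features <- as.matrix(features)
  pos <- .isPositive(labels)
  stopifnot(testSize > 0, testSize < 1, repeats >= 1)
  reports <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    te <- logical(length(pos))
    for (cls in c(TRUE, FALSE)) {
      i <- which(pos == cls)
      te[sample(i, max(1, round(testSize * length(i))))] <- TRUE
    }
    prob <- .fitPredict(cfg, features[!te, , drop = FALSE], pos[!te],
                        features[te, , drop = FALSE])
    reports[[r]] <- .evalReport(prob, pos[te])
  }
  met <- t(vapply(reports, metrics, numeric(5)))
  summary <- data.frame(metric = colnames(met), mean = colMeans(met),
                        sd = apply(met, 2, sd), row.names = NULL)
  list(reports = reports, summary = summary)
}

#' Incremental feature selection along an F-score ranking
#'
#' Adds features one at a time in ranking order, cross-validates the
#' classifier on each prefix, and returns the MCC-versus-size curve
#' together with the smallest prefix attaining the maximal MCC. A
#' \code{stride} larger than 1 evaluates every stride-th prefix (the full
#' dimension is always included), which keeps small-scale runs cheap.
#'
#' @param features numeric matrix, samples in rows.
#' @param labels class labels.
#' @param ranking an \linkS4class{FScoreRanking} for these features.
#' @param cfg a \linkS4class{ModelConfig}.
#' @param k cross-validation folds.
#' @param seed fold seed.
#' @param stride prefix-size step.
#' @return list with \code{curve} (data.frame \code{m}, \code{mcc}),
#'   \code{optimalM} and \code{optimalFeatures} (column indices).
#' @export
incrementalSelection <- function(features, labels, ranking,
                                 cfg = modelConfig("gbc"), k = 10,
                                 seed = 1, stride = 1) {
  features <- as.matrix(features)
  d <- ncol(features)
  ms <- unique(c(seq(1, d, by = stride), d))
  mcc <- vapply(ms, function(m) {
    idx <- ranking@order[seq_len(m)]
    crossValidate(features[, idx, drop = FALSE], labels, cfg, k,
                  seed)@mcc
  }, 1.0)
  best <- ms[which.max(mcc)]  # first maximum = smallest prefix
  list(curve = data.frame(m = ms, mcc = mcc), optimalM = best,
       optimalFeatures = ranking@order[seq_len(best)])
}
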