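# Classification protocol: z-normalization (fit on training rows only),
# stratified 70/30 split, radial-kernel SVM (cost 1.0, gamma 0.155),
# random forest (500 trees) and a single-hidden-layer neural network
# (5 units, decay 0.1, weight cap 1000), with full held-out evaluation.

.FEATURES <- paste0("F", 1:9)

#' Default model configuration
#'
#' Hyperparameters of the three classifiers and the split design: radial
#' SVM with cost 1.0 and gamma 0.155; random forest with 500 trees;
#' single-hidden-layer neural network with 5 units, weight decay 0.1 and
#' at most 1000 weights; 70% training / 30% testing, stratified by class.
#'
#' @param svmCost,svmGamma radial-kernel SVM parameters.
#' @param rfTrees number of random-forest trees.
#' @param annSize,annDecay,annMaxWeights neural-network parameters.
#' @param trainFraction fraction of rows used for training.
#' @return a named list.
#' @export
modelConfig <- function(svmCost = 1.0, svmGamma = 0.155, rfTrees = 500L,
                        annSize = 5L, annDecay = 0.1, annMaxWeights = 1000L,
                        trainFraction = 0.7) {
  stopifnot(
    svmCost > 0, svmGamma > 0, rfTrees > 0, annSize > 0, annDecay > 0,
    annMaxWeights > 0, trainFraction > 0, trainFraction < 1
  )
  list(
    svmCost = svmCost, svmGamma = svmGamma, rfTrees = rfTrees,
    annSize = annSize, annDecay = annDecay, annMaxWeights = annMaxWeights,
    trainFraction = trainFraction
  )
}

#' Fit / apply per-column z-normalization
#'
#' `zscoreFit()` computes per-column mean and sample standard deviation
#' (n-1) from training rows; `zscoreApply()` centers and scales rows with
#' those training statistics -- test rows are always scaled with training
#' parameters, never their own. A constant column is an error, named.
#'
#' @param table feature table (data.frame with columns `F1`..`F9`).
#' @param columns columns to scale (default the nine features).
#' @return `zscoreFit()`: list with `mean`, `sd`, `columns`;
#'   `zscoreApply()`: the table with scaled columns.
#' @examples
#' sc <- zscoreFit(data.frame(F1 = c(1, 2, 3)), columns = "F1")
#' zscoreApply(sc, data.frame(F1 = c(1, 2, 3))) # -1, 0, 1
#' @export
zscoreFit <- function(table, columns = .FEATURES) {
  m <- vapply(columns, function(cn) mean(table[[cn]]), numeric(1))
  s <- vapply(columns, function(cn) stats::sd(table[[cn]]), numeric(1))
  if (any(s == 0)) {
    stop("constant feature column(s): ", paste(columns[s == 0], collapse = ", "),
      call. = FALSE
    )
  }
  list(mean = m, sd = s, columns = columns)
}

#' @rdname zscoreFit
#' @param scaler result of `zscoreFit()`.
#' @export
zscoreApply <- function(scaler, table) {
  for (cn in scaler$columns) {
    table[[cn]] <- (table[[cn]] - scaler$mean[[cn]]) / scaler$sd[[cn]]
  }
  table
}

# stratified train/test row split
.stratifiedSplit <- function(labels, trainFraction) {
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    nTrain <- round(trainFraction * length(idx))
    train[sample(idx, nTrain)] <- TRUE
  }
  if (length(unique(labels[train])) < 2L || length(unique(labels[!train])) < 2L) {
    stop("degenerate split: both classes must be present in both halves", call. = FALSE)
  }
  train
}

# fit one model and return list(classes = factor predictions, scores =
# numeric, higher = more positive-like)
.fitPredict <- function(model, xTrain, yTrain, xTest, config) {
  if (model == "svm_rbf") {
    fit <- e1071::svm(xTrain, yTrain,
      kernel = "radial", cost = config$svmCost,
      gamma = config$svmGamma, scale = FALSE
    )
    pred <- stats::predict(fit, xTest, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    score <- if (startsWith(colnames(dv)[1], "1")) dv[, 1] else -dv[, 1]
    list(classes = pred, scores = as.numeric(score))
  } else if (model == "random_forest") {
    fit <- randomForest::randomForest(xTrain, yTrain, ntree = config$rfTrees)
    list(
      classes = stats::predict(fit, xTest),
      scores = as.numeric(stats::predict(fit, xTest, type = "prob")[, "1"])
    )
  } else if (model == "ann") {
    fit <- nnet::nnet(xTrain, as.integer(yTrain == "1"),
      size = config$annSize,
      decay = config$annDecay, MaxNWts = config$annMaxWeights,
      entropy = TRUE, maxit = 500, trace = FALSE
    )
    p <- as.numeric(stats::predict(fit, xTest, type = "raw"))
    list(
      classes = factor(ifelse(p > 0.5, "1", "0"), levels = c("0", "1")),
      scores = p
    )
  } else {
    stop("unknown model '", model, "'", call. = FALSE)
  }
}

#' Train and evaluate one classifier
#'
#' Splits the feature table into stratified 70%/30% training and test
#' halves, fits z-normalization on the training rows only, trains the
#' requested model and evaluates it on the held-out rows: confusion
#' matrix, sensitivity, specificity, accuracy with exact binomial 95% CI,
#' ROC points and trapezoidal AUC (positive class = label 1).
#' Deterministic given `seed`.
#'
#' @param table feature table (`ID`, `F1`..`F9`, `Class`).
#' @param model `"svm_rbf"`, `"random_forest"` or `"ann"`.
#' @param seed integer seed controlling the split and any model randomness.
#' @param config hyperparameters, see [modelConfig()].
#' @return an [EvalReport-class].
#' @export
trainEval <- function(table, model = c("svm_rbf", "random_forest", "ann"),
                      seed = 1L, config = modelConfig()) {
  model <- match.arg(model)
  y <- factor(table$Class, levels = c("0", "1"))
  if (anyNA(y) || length(unique(y)) < 2L) {
    stop("Class column must contain both 0 and 1", call. = FALSE)
  }
  .withSeed(seed, {
    train <- .stratifiedSplit(as.character(y), config$trainFraction)
    scaler <- zscoreFit(table[train, , drop = FALSE])
    xTrain <- as.matrix(zscoreApply(scaler, table[train, , drop = FALSE])[, .FEATURES])
    xTest <- as.matrix(zscoreApply(scaler, table[!train, , drop = FALSE])[, .FEATURES])
    yTrain <- y[train]
    yTest <- y[!train]
    fp <- .fitPredict(model, xTrain, yTrain, xTest, config)
    ids <- if ("ID" %in% names(table)) table$ID[!train] else which(!train)
    .evalReport(model, fp$classes, fp$scores, yTest, config, seed, ids)
  })
}

.evalReport <- function(model, predClasses, scores, yTest, config, seed, ids = NULL) {
  tp <- sum(predClasses == "1" & yTest == "1")
  fp <- sum(predClasses == "1" & yTest == "0")
  tn <- sum(predClasses == "0" & yTest == "0")
  fn <- sum(predClasses == "0" & yTest == "1")
  cm <- matrix(c(tn, fp, fn, tp), 2L, 2L,
    dimnames = list(predicted = c("0", "1"), actual = c("0", "1"))
  )
  total <- tp + fp + tn + fn
  ci <- stats::binom.test(tp + tn, total)$conf.int # exact Clopper-Pearson
  roc <- rocAuc(scores, as.integer(yTest == "1"))
  methods::new("EvalReport",
    model = model, confusion = cm,
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    accuracy = (tp + tn) / total,
    accuracyCI = as.numeric(ci), auc = roc$auc, rocPoints = roc$rocPoints,
    predictions = data.frame(
      ID = if (is.null(ids)) seq_along(scores) else ids,
      actual = as.character(yTest),
      predicted = as.character(predClasses),
      score = scores
    ),
    config = c(config, list(seed = as.integer(seed)))
  )
}

#' ROC curve and AUC
#'
#' Full threshold sweep of a score vector against 0/1 labels: ROC points
#' (FPR, TPR) at every distinct score and the area under the curve by the
#' trapezoidal rule. Tied scores are collapsed into one ROC step, which
#' gives ties half credit; the result equals the normalized Mann-Whitney
#' U statistic.
#'
#' @param scores numeric scores, higher = more positive-like.
#' @param labels 0/1 labels.
#' @return list with `auc` and `rocPoints` (data.frame `FPR`, `TPR`,
#'   monotone non-decreasing in both coordinates).
#' @examples
#' rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc # 1
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  P <- sum(labels == 1L)
  N <- sum(labels == 0L)
  if (P == 0L || N == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y == 1L)
  fp <- cumsum(y == 0L)
  keep <- c(s[-1] != s[-length(s)], TRUE) # last index of each tie group
  tpr <- c(0, tp[keep] / P)
  fpr <- c(0, fp[keep] / N)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(auc = auc, rocPoints = data.frame(FPR = fpr, TPR = tpr))
}

#' @describeIn metrics named list of the headline metrics of a report.
#' @export
setMethod("metrics", "EvalReport", function(object) {
  list(
    model = object@model,
    sensitivity = object@sensitivity,
    specificity = object@specificity,
    accuracy = object@accuracy,
    accuracyCI = object@accuracyCI,
    auc = object@auc
  )
})

#' @describeIn confusion 2x2 predicted-by-actual confusion matrix.
#' @export
setMethod("confusion", "EvalReport", function(object) object@confusion)

#' @describeIn rocPoints ROC points (FPR, TPR) of a report.
#' @export
setMethod("rocPoints", "EvalReport", function(object) object@rocPoints)

#' @describeIn predictions per-test-sequence predictions of a report.
#' @export
setMethod("predictions", "EvalReport", function(object) object@predictions)

#' @describeIn auc area under the ROC curve of a report.
#' @export
setMethod("auc", "EvalReport", function(object) object@auc)

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (%s)\n", object@model))
  print(object@confusion)
  cat(sprintf(
    "accuracy %.3f (95%% CI %.3f-%.3f)  sensitivity %.3f  specificity %.3f  AUC %.3f\n",
    object@accuracy, object@accuracyCI[1], object@accuracyCI[2],
    object@sensitivity, object@specificity, object@auc
  ))
})

#' Export an evaluation report as JSON
#'
#' @param report an [EvalReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEvalReport <- function(report, path) {
  stopifnot(methods::is(report, "EvalReport"))
  out <- c(
    metrics(report),
    list(
      confusion = as.list(stats::setNames(
        as.vector(report@confusion), c("TN", "FP", "FN", "TP")
      )),
      config = report@config
    )
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Repeated evaluation over re-sampled control sets
#'
#' Re-draws the negative (control) set `nSubsets` times with child seeds
#' derived from `seed`, rebuilds the feature table against the fixed
#' positive set, and re-runs [trainEval()] per subset. The split/model
#' seed is held fixed across subsets so the reported one-sigma spread
#' isolates control-sampling variability -- the many-subset design used to
#' verify that classification accuracy is stable (about 1% sd) across
#' genomic control samples.
#'
#' @param positives [MaskedDNA-class] positive sequences.
#' @param controlSampler function of one argument (`seed`) returning a
#'   control sequence set.
#' @param nSubsets number of control subsets (>= 2).
#' @param model,config,seed as in [trainEval()].
#' @param minLength passed to [buildFeatureTable()].
#' @return list with `accuracies`, `aucs` (per subset), `mean`, `sd`.
#' @export
repeatedEval <- function(positives, controlSampler, nSubsets = 100L,
                         model = "svm_rbf", seed = 1L, config = modelConfig(),
                         minLength = 200L) {
  stopifnot(nSubsets >= 2L)
  seeds <- .childSeeds(seed, nSubsets)
  acc <- numeric(nSubsets)
  aucs <- numeric(nSubsets)
  for (i in seq_len(nSubsets)) {
    controls <- controlSampler(seeds[i])
    tab <- buildFeatureTable(positives, controls, minLength = minLength)
    rep <- trainEval(tab, model = model, seed = seed, config = config)
    acc[i] <- rep@accuracy
    aucs[i] <- rep@auc
  }
  list(accuracies = acc, aucs = aucs, mean = mean(acc), sd = stats::sd(acc))
}
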