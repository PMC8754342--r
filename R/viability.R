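#' Binary cross-entropy loss
#'
#' Standard binary cross-entropy between a predicted probability and a 0/1
#' label: \code{-[y log p + (1 - y) log(1 - p)]}. It is zero only at a
#' perfectly confident correct prediction, and equals \code{ln 2} per sample
#' when the prediction is 0.5 everywhere.
#'
#' @param pred predicted probabilities in `[0, 1]`
#' @param label 0/1 labels (1 = positive class)
#' @param reduce `"mean"`, `"sum"` or `"none"`
#' @return loss value(s)
#' @examples
#' crossEntropyLoss(0.5, 1)          # log(2)
#' crossEntropyLoss(c(1, 0), c(1, 0))  # 0
#' @export
crossEntropyLoss <- function(pred, label, reduce = c("mean", "sum", "none")) {
    reduce <- match.arg(reduce)
    if (any(pred < 0 | pred > 1)) stop("pred must lie in [0, 1]")
    if (!all(label %in% c(0, 1))) stop("label must be 0/1")
    p <- pmin(pmax(pred, 1e-15), 1 - 1e-15)
    ce <- -(label * log(p) + (1 - label) * log(1 - p))
    ce[pred == label] <- 0   # exact zero at perfect confident prediction
    switch(reduce, mean = mean(ce), sum = sum(ce), none = ce)
}

.viabilityLabels <- function(labels) {
    if (is.character(labels) || is.factor(labels)) {
        labels <- as.character(labels)
        if (!all(labels %in% c("Live", "Dead")))
            stop("labels must be 'Live'/'Dead' or 0/1")
        as.numeric(labels == "Live")
    } else as.numeric(labels > 0)
}

#' Train the live/dead crop classifier
#'
#' A small dense network over the (downsampled, flattened) brightfield crop,
#' trained with binary cross-entropy and Adam; the positive class is
#' \code{Live}. Dead cells and debris flagged by this classifier are removed
#' before encoding so they cannot distort the learned morphology space.
#'
#' @param crops a \linkS4class{CropSet}
#' @param labels per-crop annotations, `"Live"`/`"Dead"` or 1/0
#' @param steps Adam steps
#' @param seed integer seed
#' @param hidden hidden layer widths
#' @param inputSide crops are resampled to this side before flattening
#' @param batch minibatch size
#' @param lr learning rate
#' @param holdout fraction held out to report a validation loss
#' @return object of class `"ViabilityModel"`
#' @export
trainViability <- function(crops, labels, steps = 600L, seed = 1,
                           hidden = c(64L), inputSide = 24L, batch = 32L,
                           lr = 1e-3, holdout = 0.15) {
    y <- .viabilityLabels(labels)
    if (length(unique(y)) < 2L)
        stop("training set must contain both Live and Dead crops")
    if (length(y) != nCells(crops))
        stop("labels length must match number of crops")
    X <- .viabilityFeatures(crops, inputSide)
    D <- ncol(X)
    .withSeed(seed, {
        n <- nrow(X)
        ord <- sample.int(n)
        nHold <- max(1L, round(holdout * n))
        holdIdx <- ord[seq_len(nHold)]
        trainIdx <- ord[-seq_len(nHold)]
        if (length(unique(y[trainIdx])) < 2L) trainIdx <- ord
        net <- .nnInit(c(D, hidden, 1L),
                       c(rep("lrelu", length(hidden)), "linear"))
        st <- .adamInit(net)
        predProb <- function(idx) {
            o <- .nnForward(net, X[idx, , drop = FALSE])$h
            as.vector(1 / (1 + exp(-pmin(pmax(o[[length(o)]], -30), 30))))
        }
        loss0 <- crossEntropyLoss(predProb(holdIdx), y[holdIdx])
        for (s in seq_len(steps)) {
            idx <- trainIdx[.sampleBatch(length(trainIdx), batch)]
            cache <- .nnForward(net, X[idx, , drop = FALSE])
            pre <- cache$h[[length(cache$h)]]
            p <- 1 / (1 + exp(-pmin(pmax(pre, -30), 30)))
            dOut <- (p - y[idx]) / length(idx)
            bk <- .nnBackward(net, cache, dOut)
            up <- .adamStep(net, bk$grads, st, lr = lr)
            net <- up$net; st <- up$state
        }
        structure(list(net = net, inputSide = inputSide,
                       cropSide = dim(brightfield(crops))[1L],
                       holdoutLoss0 = loss0,
                       holdoutLoss = crossEntropyLoss(predProb(holdIdx),
                                                      y[holdIdx])),
                  class = "ViabilityModel")
    })
}

.viabilityFeatures <- function(crops, inputSide) {
    bf <- brightfield(crops)
    n <- dim(bf)[3L]
    X <- matrix(0, n, inputSide^2)
    for (i in seq_len(n))
        X[i, ] <- as.matrix(EBImage::resize(EBImage::Image(bf[, , i]),
                                            w = inputSide, h = inputSide))
    X
}

#' Score crops and flag dead cells for removal
#'
#' @param model a trained [trainViability()] model
#' @param crops a \linkS4class{CropSet}
#' @param threshold decision threshold on the Live probability; a crop is
#'   labeled `Live` iff its score is `>= threshold`
#' @return \linkS4class{DataFrame} with `crop_id`, `score` (probability of
#'   Live) and `label`; crops labeled `Dead` are the ones to discard
#' @export
classifyViability <- function(model, crops, threshold = 0.5) {
    stopifnot(inherits(model, "ViabilityModel"))
    if (nCells(crops) == 0)
        return(DataFrame(crop_id = integer(), score = numeric(),
                         label = character()))
    if (dim(brightfield(crops))[1L] != model$cropSide)
        stop("crop size differs from the size the classifier was trained on")
    X <- .viabilityFeatures(crops, model$inputSide)
    o <- .nnForward(model$net, X)$h
    score <- as.vector(1 / (1 + exp(-pmin(pmax(o[[length(o)]], -30), 30))))
    DataFrame(crop_id = cellMeta(crops)$crop_id, score = score,
              label = ifelse(score >= threshold, "Live", "Dead"))
}

#' Receiver operating characteristic curve and AUC
#'
#' @param scores predicted probabilities of the positive (Live) class
#' @param labels true labels (`"Live"`/`"Dead"` or 1/0)
#' @return list with `fpr`, `tpr`, `thresholds` and `auc`
#' @export
rocCurve <- function(scores, labels) {
    y <- .viabilityLabels(labels)
    if (length(unique(y)) < 2L)
        stop("both classes must be present")
    r <- pROC::roc(response = y, predictor = scores, levels = c(0, 1),
                   direction = "<", quiet = TRUE)
    list(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities),
         thresholds = rev(r$thresholds), auc = as.numeric(r$auc))
}
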