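#' Train the label-free fluorescence predictor
#'
#' Learns to regress a cytoplasm-fluorescence image from the brightfield
#' channel, the trick that makes segmentation possible without staining the
#' experiment itself. The model is a patch-based dense encoder--decoder: it
#' maps a flattened \code{patch x patch} brightfield tile through hidden
#' layers to the corresponding fluorescence tile, and whole frames are
#' predicted by tiling with overlap averaging. Training minimizes mean
#' squared error with Adam.
#'
#' @param pairs list of paired frames, each a list with elements
#'   `brightfield` and `fluorescence` (equal-size matrices in `[0, 1]`)
#' @param steps number of Adam steps (> 0)
#' @param seed integer seed controlling initialization and patch sampling
#' @param patch tile side in px
#' @param hidden integer vector of hidden layer widths
#' @param nPatches training tiles sampled from the frame pairs
#' @param batch minibatch size
#' @param lr Adam learning rate
#' @return an object of class `"LabelFreeModel"` carrying the fitted
#'   network, the tile size, and initial/final holdout loss
#' @seealso [predictFluorescence()], [evaluatePrediction()]
#' @export
trainLabelFree <- function(pairs, steps = 500L, seed = 1, patch = 16L,
                           hidden = c(128L), nPatches = 4000L,
                           batch = 32L, lr = 1e-3) {
    if (length(pairs) < 1) stop("at least one brightfield/fluorescence ",
                                "pair is required")
    if (steps <= 0) stop("steps must be positive")
    for (p in pairs) {
        if (!identical(dim(p$brightfield), dim(p$fluorescence)))
            stop("brightfield and fluorescence shapes differ")
        .stopIfNot2D(p$brightfield, "brightfield frame")
    }
    D <- patch^2
    .withSeed(seed, {
        ## sample training tiles uniformly over frames and positions
        X <- matrix(0, nPatches, D); Y <- matrix(0, nPatches, D)
        for (i in seq_len(nPatches)) {
            fr <- pairs[[sample.int(length(pairs), 1L)]]
            h <- nrow(fr$brightfield); w <- ncol(fr$brightfield)
            if (h < patch || w < patch)
                stop("frames smaller than the patch size")
            r0 <- sample.int(h - patch + 1L, 1L)
            c0 <- sample.int(w - patch + 1L, 1L)
            X[i, ] <- fr$brightfield[r0:(r0 + patch - 1L),
                                     c0:(c0 + patch - 1L)]
            Y[i, ] <- fr$fluorescence[r0:(r0 + patch - 1L),
                                      c0:(c0 + patch - 1L)]
        }
        nHold <- max(1L, round(0.1 * nPatches))
        holdIdx <- seq_len(nHold)
        trainIdx <- setdiff(seq_len(nPatches), holdIdx)

        net <- .nnInit(c(D, hidden, D),
                       c(rep("lrelu", length(hidden)), "sigmoid"))
        st <- .adamInit(net)
        holdLoss <- function() {
            pred <- .nnForward(net, X[holdIdx, , drop = FALSE])$h
            mean((pred[[length(pred)]] - Y[holdIdx, , drop = FALSE])^2)
        }
        loss0 <- holdLoss()
        for (s in seq_len(steps)) {
            idx <- trainIdx[.sampleBatch(length(trainIdx), batch)]
            cache <- .nnForward(net, X[idx, , drop = FALSE])
            pred <- cache$h[[length(cache$h)]]
            dOut <- 2 * (pred - Y[idx, , drop = FALSE]) / length(idx)
            bk <- .nnBackward(net, cache, dOut)
            up <- .adamStep(net, bk$grads, st, lr = lr)
            net <- up$net; st <- up$state
        }
        structure(list(net = net, patch = patch,
                       holdoutLoss0 = loss0, holdoutLoss = holdLoss()),
                  class = "LabelFreeModel")
    })
}

#' Predict the fluorescence channel for a brightfield frame
#'
#' Tiles the frame with 50% overlap, predicts each tile and averages
#' overlapping predictions.
#'
#' @param model a trained [trainLabelFree()] model
#' @param frame 2-d brightfield matrix
#' @return predicted fluorescence matrix, same shape as `frame`
#' @export
predictFluorescence <- function(model, frame) {
    stopifnot(inherits(model, "LabelFreeModel"))
    .stopIfNot2D(frame, "brightfield frame")
    p <- model$patch
    h <- nrow(frame); w <- ncol(frame)
    padH <- max(0L, p - h); padW <- max(0L, p - w)
    if (padH > 0 || padW > 0) {
        bg <- stats::median(frame)
        fr <- matrix(bg, h + padH, w + padW)
        fr[seq_len(h), seq_len(w)] <- frame
        frame <- fr; h <- nrow(frame); w <- ncol(frame)
    }
    stride <- max(1L, p %/% 2L)
    rows <- unique(c(seq(1L, h - p + 1L, by = stride), h - p + 1L))
    cols <- unique(c(seq(1L, w - p + 1L, by = stride), w - p + 1L))
    acc <- matrix(0, h, w); cnt <- matrix(0, h, w)
    tiles <- expand.grid(r = rows, c = cols)
    X <- matrix(0, nrow(tiles), p^2)
    for (i in seq_len(nrow(tiles)))
        X[i, ] <- frame[tiles$r[i]:(tiles$r[i] + p - 1L),
                        tiles$c[i]:(tiles$c[i] + p - 1L)]
    out <- .nnForward(model$net, X)$h
    pred <- out[[length(out)]]
    for (i in seq_len(nrow(tiles))) {
        rr <- tiles$r[i]:(tiles$r[i] + p - 1L)
        cc <- tiles$c[i]:(tiles$c[i] + p - 1L)
        acc[rr, cc] <- acc[rr, cc] + matrix(pred[i, ], p, p)
        cnt[rr, cc] <- cnt[rr, cc] + 1
    }
    res <- acc / cnt
    res[seq_len(h - padH), seq_len(w - padW), drop = FALSE]
}

#' Segment objects from a predicted fluorescence frame
#'
#' Global Otsu threshold followed by a distance-transform watershed to split
#' touching objects; components outside the area window are dropped.
#'
#' @param pred predicted fluorescence matrix
#' @param minArea,maxArea component area window in px^2
#' @param frame frame index recorded in the detection table
#' @return list with `table`: data.frame `(frame, id, y, x, area)` of
#'   detections (centroids as float px), and `labels`: an integer matrix
#'   labeling each detection's pixels with its id
#' @export
segmentFrame <- function(pred, minArea = 40, maxArea = Inf, frame = 1L) {
    if (!is.matrix(pred)) stop("pred must be a 2-d matrix")
    if (all(is.na(pred))) stop("all-NaN frame cannot be segmented")
    empty <- list(table = data.frame(frame = integer(), id = integer(),
                                     y = numeric(), x = numeric(),
                                     area = numeric()),
                  labels = matrix(0L, nrow(pred), ncol(pred)))
    if (max(pred) - min(pred) < 1e-8) return(empty)
    th <- EBImage::otsu(EBImage::Image(.clip01(pred)))
    bw <- pred > th
    if (!any(bw)) return(empty)
    wsLabels <- EBImage::watershed(EBImage::distmap(bw), tolerance = 1,
                                   ext = 1)
    lab <- matrix(as.integer(EBImage::imageData(wsLabels)),
                  nrow(pred), ncol(pred))
    ids <- setdiff(sort(unique(as.vector(lab))), 0L)
    if (!length(ids)) return(empty)
    keep <- integer(0)
    out <- matrix(0L, nrow(pred), ncol(pred))
    tab <- list()
    nextId <- 0L
    for (id in ids) {
        px <- which(lab == id)
        area <- length(px)
        if (area < minArea || area > maxArea) next
        nextId <- nextId + 1L
        out[px] <- nextId
        r <- ((px - 1L) %% nrow(pred)) + 1L
        c <- ((px - 1L) %/% nrow(pred)) + 1L
        tab[[nextId]] <- data.frame(frame = frame, id = nextId,
                                    y = mean(r), x = mean(c), area = area)
    }
    if (nextId == 0L) return(empty)
    list(table = do.call(rbind, tab), labels = out)
}

#' Pearson correlation between predicted and true fluorescence
#'
#' @param pred,truth equal-shape matrices
#' @return correlation coefficient in `[-1, 1]`
#' @export
evaluatePrediction <- function(pred, truth) {
    if (!identical(dim(pred), dim(truth)))
        stop("pred and truth shapes differ")
    if (stats::sd(pred) == 0 || stats::sd(truth) == 0)
        stop("correlation undefined for zero-variance input")
    stats::cor(as.vector(pred), as.vector(truth))
}

#' Cut per-cell crops around detections
#'
#' Windows are centered on detection centroids; positions falling outside
#' the frame are padded with the frame's median background. The detection's
#' mask patch is carried along.
#'
#' @param frame brightfield matrix the detections came from
#' @param detections a [segmentFrame()] result
#' @param cropSize odd window side in px
#' @return a \linkS4class{CropSet} (empty detection list gives an empty set)
#' @export
cutCrops <- function(frame, detections, cropSize = 65L) {
    if (cropSize %% 2L == 0L) stop("cropSize must be odd")
    tab <- detections$table
    n <- nrow(tab)
    bf <- array(0, c(cropSize, cropSize, n))
    mk <- array(0L, c(cropSize, cropSize, n))
    if (n > 0) {
        bg <- stats::median(frame)
        half <- (cropSize - 1L) %/% 2L
        for (i in seq_len(n)) {
            r0 <- round(tab$y[i]); c0 <- round(tab$x[i])
            rr <- (r0 - half):(r0 + half)
            cc <- (c0 - half):(c0 + half)
            patchB <- matrix(bg, cropSize, cropSize)
            patchM <- matrix(0L, cropSize, cropSize)
            okR <- rr >= 1 & rr <= nrow(frame)
            okC <- cc >= 1 & cc <= ncol(frame)
            patchB[okR, okC] <- frame[rr[okR], cc[okC]]
            patchM[okR, okC] <-
                (detections$labels[rr[okR], cc[okC]] == tab$id[i]) * 1L
            bf[, , i] <- patchB
            mk[, , i] <- patchM
        }
    }
    new("CropSet", brightfield = bf, mask = mk,
        meta = DataFrame(crop_id = tab$id, frame = tab$frame,
                         y = tab$y, x = tab$x, area = tab$area))
}
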