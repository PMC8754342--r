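#' @rdname CropSet-class
#' @export
setMethod("nCells", "CropSet", function(x) dim(x@brightfield)[3L])
#' @rdname CanonicalSet-class
#' @export
setMethod("nCells", "CanonicalSet", function(x) dim(x@maskImages)[3L])
#' @rdname LatentSet-class
#' @export
setMethod("nCells", "LatentSet", function(x) nrow(x@zShape))

#' @rdname CropSet-class
#' @export
setMethod("cellMeta", "CropSet", function(x) x@meta)
#' @rdname CanonicalSet-class
#' @export
setMethod("cellMeta", "CanonicalSet", function(x) x@meta)
#' @rdname LatentSet-class
#' @export
setMethod("cellMeta", "LatentSet", function(x) x@meta)

#' @rdname CropSet-class
#' @export
setReplaceMethod("cellMeta", "CropSet", function(x, value) {
    x@meta <- value; validObject(x); x
})
#' @rdname LatentSet-class
#' @export
setReplaceMethod("cellMeta", "LatentSet", function(x, value) {
    x@meta <- value; validObject(x); x
})

#' @rdname CropSet-class
#' @export
setMethod("brightfield", "CropSet", function(x) x@brightfield)
#' @rdname CropSet-class
#' @export
setMethod("masks", "CropSet", function(x) x@mask)

#' @rdname CanonicalSet-class
#' @export
setMethod("maskImages", "CanonicalSet", function(x) x@maskImages)
#' @rdname CanonicalSet-class
#' @export
setMethod("textureImages", "CanonicalSet", function(x) x@textureImages)
#' @rdname CanonicalSet-class
#' @export
setMethod("pose", "CanonicalSet", function(x) x@pose)

#' @rdname LatentSet-class
#' @export
setMethod("latentShape", "LatentSet", function(x) x@zShape)
#' @rdname LatentSet-class
#' @export
setMethod("latentTexture", "LatentSet", function(x) x@zTexture)

#' @rdname fusedLatents
#' @export
setMethod("fusedLatents", "LatentSet", function(x, w) {
    if (missing(w)) w <- x@weight
    combineLatents(x@zShape, x@zTexture, w)
})

#' @rdname LinkageSet-class
#' @export
setMethod("links", "LinkageSet", function(x) x@links)

#' @rdname TransitionMatrix-class
#' @export
setMethod("transitionProbs", "TransitionMatrix", function(x) x@probs)
#' @rdname TransitionMatrix-class
#' @export
setMethod("transitionCounts", "TransitionMatrix", function(x) x@counts)

## subsetting by cell index keeps arrays and metadata in register

#' @rdname CropSet-class
#' @param i integer or logical index over cells
#' @param j,drop,... ignored
#' @export
setMethod("[", "CropSet", function(x, i, j, ..., drop = FALSE) {
    new("CropSet",
        brightfield = x@brightfield[, , i, drop = FALSE],
        mask = x@mask[, , i, drop = FALSE],
        meta = x@meta[i, , drop = FALSE])
})

#' @rdname CanonicalSet-class
#' @param i integer or logical index over cells
#' @param j,drop,... ignored
#' @export
setMethod("[", "CanonicalSet", function(x, i, j, ..., drop = FALSE) {
    new("CanonicalSet",
        maskImages = x@maskImages[, , i, drop = FALSE],
        textureImages = x@textureImages[, , i, drop = FALSE],
        pose = x@pose[i, , drop = FALSE],
        meta = x@meta[i, , drop = FALSE])
})

#' @rdname LatentSet-class
#' @param i integer or logical index over cells
#' @param j,drop,... ignored
#' @export
setMethod("[", "LatentSet", function(x, i, j, ..., drop = FALSE) {
    new("LatentSet",
        zShape = x@zShape[i, , drop = FALSE],
        zTexture = x@zTexture[i, , drop = FALSE],
        weight = x@weight,
        meta = x@meta[i, , drop = FALSE])
})

setMethod("show", "CropSet", function(object) {
    d <- dim(object@brightfield)
    cat("CropSet with", d[3L], "crops of", d[1L], "x", d[2L], "px\n")
    cat("meta columns:", paste(colnames(object@meta), collapse = ", "), "\n")
})

setMethod("show", "CanonicalSet", function(object) {
    d <- dim(object@maskImages)
    cat("CanonicalSet with", d[3L], "pose-normalized crops of",
        d[1L], "x", d[2L], "px\n")
})

setMethod("show", "LatentSet", function(object) {
    cat("LatentSet:", nrow(object@zShape), "cells, J =",
        ncol(object@zShape), "per branch, fusion weight w =",
        object@weight, "\n")
})

setMethod("show", "MarkovModel", function(object) {
    cat("MarkovModel with", nrow(object@P), "states\n")
    print(round(object@P, 3))
})

setMethod("show", "LinkageSet", function(object) {
    cat("LinkageSet:", nrow(object@links), "validated links (D0 =",
        object@D0, "px, D1 =", object@D1, "px)\n")
})

setMethod("show", "TransitionMatrix", function(object) {
    cat("TransitionMatrix over", nrow(object@probs), "states,",
        sum(object@counts), "transitions")
    if (!is.na(object@minutesPerFrame))
        cat(" per", object@minutesPerFrame, "min interval")
    cat("\n")
    print(round(object@probs, 3))
})

setMethod("show", "EncoderModel", function(object) {
    cat("EncoderModel kind =", object@kind,
        if (nzchar(object@branch)) paste0("(", object@branch, " branch)"),
        "\n")
    if (!is.null(object@config$J))
        cat("latent dimension J =", object@config$J, "\n")
})
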