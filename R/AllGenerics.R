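#' @rdname CropSet-class
#' @param x a \linkS4class{CropSet}, \linkS4class{CanonicalSet} or
#'   \linkS4class{LatentSet}
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname CropSet-class
#' @export
setGeneric("cellMeta", function(x) standardGeneric("cellMeta"))

#' @rdname CropSet-class
#' @param value replacement metadata DataFrame
#' @export
setGeneric("cellMeta<-", function(x, value) standardGeneric("cellMeta<-"))

#' @rdname CropSet-class
#' @export
setGeneric("brightfield", function(x) standardGeneric("brightfield"))

#' @rdname CropSet-class
#' @export
setGeneric("masks", function(x) standardGeneric("masks"))

#' @rdname CanonicalSet-class
#' @param x a \linkS4class{CanonicalSet}
#' @export
setGeneric("maskImages", function(x) standardGeneric("maskImages"))

#' @rdname CanonicalSet-class
#' @export
setGeneric("textureImages", function(x) standardGeneric("textureImages"))

#' @rdname CanonicalSet-class
#' @export
setGeneric("pose", function(x) standardGeneric("pose"))

#' @rdname LatentSet-class
#' @param x a \linkS4class{LatentSet}
#' @export
setGeneric("latentShape", function(x) standardGeneric("latentShape"))

#' @rdname LatentSet-class
#' @export
setGeneric("latentTexture", function(x) standardGeneric("latentTexture"))

#' Fused weighted-concatenation latent representation
#'
#' Builds the representation used for clustering and embedding:
#' \code{c(w * z_shape, (1 - w) * z_texture)}, a length-\code{2J} vector per
#' cell. \code{w = 1} silences the texture block, \code{w = 0} the shape
#' block.
#'
#' @param x a \linkS4class{LatentSet}
#' @param w fusion weight in \code{[0, 1]}; defaults to the set's stored
#'   weight
#' @return numeric matrix \code{n x 2J}
#' @export
setGeneric("fusedLatents", function(x, w) standardGeneric("fusedLatents"))

#' @rdname LinkageSet-class
#' @param x a \linkS4class{LinkageSet}
#' @export
setGeneric("links", function(x) standardGeneric("links"))

#' @rdname TransitionMatrix-class
#' @param x a \linkS4class{TransitionMatrix}
#' @export
setGeneric("transitionProbs", function(x) standardGeneric("transitionProbs"))

#' @rdname TransitionMatrix-class
#' @export
setGeneric("transitionCounts", function(x) standardGeneric("transitionCounts"))
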