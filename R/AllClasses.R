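#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' CropSet: a collection of segmented cell crops
#'
#' Holds per-cell brightfield patches, binary mask patches and per-crop
#' metadata (crop id, frame of origin, centroid, area, optional class or
#' condition labels). All patches share one size; the third array dimension
#' indexes crops.
#'
#' @slot brightfield numeric array \code{h x w x n} of brightfield patches,
#'   values in \code{[0, 1]}.
#' @slot mask integer/logical array \code{h x w x n} of binary masks.
#' @slot meta a \linkS4class{DataFrame} with one row per crop; always carries
#'   \code{crop_id}, and typically \code{frame}, \code{y}, \code{x},
#'   \code{area}.
#'
#' @seealso [makeCropDataset()], [cutCrops()], [canonicalizeSet()]
#' @export
setClass("CropSet",
    representation(brightfield = "array", mask = "array", meta = "DataFrame"))

setValidity("CropSet", function(object) {
    db <- dim(object@brightfield); dm <- dim(object@mask)
    if (length(db) != 3L || length(dm) != 3L)
        return("brightfield and mask must be 3-d arrays (h x w x n)")
    if (!identical(db, dm))
        return("brightfield and mask dimensions differ")
    if (nrow(object@meta) != db[3L])
        return("meta rows must match number of crops")
    if (!"crop_id" %in% colnames(object@meta))
        return("meta must contain a crop_id column")
    if (anyDuplicated(object@meta$crop_id))
        return("crop_id values must be unique")
    TRUE
})

#' CanonicalSet: pose-normalized crops ready for encoding
#'
#' Each crop has been re-centered, rotated so its major axis is vertical,
#' reflected so pixel mass is biased to the top and right, and isotropically
#' rescaled into a fixed-size frame. \code{maskImages} are binary silhouettes;
#' \code{textureImages} hold the interior brightfield signal standardized to
#' zero mean / unit variance then mapped linearly to \code{[0, 1]}, with all
#' exterior pixels fixed at 0.5.
#'
#' @slot maskImages numeric array \code{s x s x n}, values in \{0, 1\}.
#' @slot textureImages numeric array \code{s x s x n}, values in
#'   \code{[0, 1]}; exterior exactly 0.5.
#' @slot pose \linkS4class{DataFrame} of the applied transform per crop
#'   (rotation degrees, flips, scale) plus degenerate-texture flags.
#' @slot meta \linkS4class{DataFrame} carried over from the source
#'   \linkS4class{CropSet}.
#' @export
setClass("CanonicalSet",
    representation(maskImages = "array", textureImages = "array",
                   pose = "DataFrame", meta = "DataFrame"))

setValidity("CanonicalSet", function(object) {
    dm <- dim(object@maskImages); dt <- dim(object@textureImages)
    if (!identical(dm, dt)) return("mask and texture dimensions differ")
    if (length(dm) != 3L) return("images must be 3-d arrays")
    if (dm[1L] != dm[2L]) return("canonical images must be square")
    if (nrow(object@meta) != dm[3L] || nrow(object@pose) != dm[3L])
        return("pose/meta rows must match number of crops")
    tx <- object@textureImages
    if (length(tx) && (min(tx) < 0 || max(tx) > 1))
        return("texture values must lie in [0, 1]")
    TRUE
})

#' LatentSet: per-cell shape and texture encodings
#'
#' Latent vectors from the twin autoencoders. Rows are cells; \code{zShape}
#' and \code{zTexture} have \code{J} columns each. The fused representation
#' used downstream is the weighted concatenation
#' \code{c(w * z_shape, (1 - w) * z_texture)}; see [fusedLatents()].
#'
#' @slot zShape numeric matrix \code{n x J} of shape-branch encodings.
#' @slot zTexture numeric matrix \code{n x J} of texture-branch encodings.
#' @slot weight default fusion weight \code{w} in \code{[0, 1]}.
#' @slot meta \linkS4class{DataFrame} with one row per cell.
#' @export
setClass("LatentSet",
    representation(zShape = "matrix", zTexture = "matrix",
                   weight = "numeric", meta = "DataFrame"))

setValidity("LatentSet", function(object) {
    if (!identical(dim(object@zShape), dim(object@zTexture)))
        return("zShape and zTexture must have identical dimensions")
    if (nrow(object@meta) != nrow(object@zShape))
        return("meta rows must match number of cells")
    w <- object@weight
    if (length(w) != 1L || is.na(w) || w < 0 || w > 1)
        return("weight must be a single value in [0, 1]")
    TRUE
})

#' MarkovModel: a finite-state Markov chain specification
#'
#' @slot P row-stochastic \code{k x k} transition matrix.
#' @slot pi initial distribution over the \code{k} states.
#' @export
setClass("MarkovModel", representation(P = "matrix", pi = "numeric"))

setValidity("MarkovModel", function(object) {
    P <- object@P
    if (nrow(P) != ncol(P)) return("P must be square")
    if (any(P < 0)) return("P entries must be non-negative")
    if (any(abs(rowSums(P) - 1) > 1e-12))
        return("every row of P must sum to 1")
    if (length(object@pi) != nrow(P)) return("pi length must match P")
    if (any(object@pi < 0) || abs(sum(object@pi) - 1) > 1e-12)
        return("pi must be a probability vector")
    TRUE
})

#' LinkageSet: validated frame-to-frame cell pairings
#'
#' Each link pairs an isolated cell at frame \code{t} with its nearest
#' neighbour at frame \code{t + 1}, subject to the isolation radius \code{D0}
#' (no same-frame neighbour closer than \code{D0}) and the maximum travel
#' distance \code{D1}. Within a frame pair each cell appears in at most one
#' link per role.
#'
#' @slot links data.frame with columns \code{frame}, \code{src}, \code{dst},
#'   \code{distance} (px).
#' @slot D0 isolation radius in px.
#' @slot D1 maximum travel distance in px.
#' @export
setClass("LinkageSet",
    representation(links = "data.frame", D0 = "numeric", D1 = "numeric"))

setValidity("LinkageSet", function(object) {
    l <- object@links
    need <- c("frame", "src", "dst", "distance")
    if (!all(need %in% colnames(l)))
        return("links must have columns frame, src, dst, distance")
    if (nrow(l)) {
        if (any(l$distance >= object@D1))
            return("every link distance must be < D1")
        if (anyDuplicated(l[, c("frame", "src")]) ||
            anyDuplicated(l[, c("frame", "dst")]))
            return("a cell may appear in at most one link per role per frame")
    }
    TRUE
})

#' TransitionMatrix: estimated cluster-to-cluster transition probabilities
#'
#' Row-stochastic estimate \code{P[i, j] = f_ij / sum_k f_ik} from linked
#' cell pairs, together with the raw transition counts. Rows with zero counts
#' are undefined and reported as \code{NA} rather than imputed.
#'
#' @slot probs \code{k x k} matrix of probabilities (rows with counts sum
#'   to 1; zero-count rows are \code{NA}).
#' @slot counts \code{k x k} integer matrix of transition counts.
#' @slot minutesPerFrame frame interval in minutes (\code{NA} if unknown).
#' @export
setClass("TransitionMatrix",
    representation(probs = "matrix", counts = "matrix",
                   minutesPerFrame = "numeric"))

setValidity("TransitionMatrix", function(object) {
    if (!identical(dim(object@probs), dim(object@counts)))
        return("probs and counts dimensions differ")
    if (nrow(object@probs) != ncol(object@probs))
        return("matrices must be square")
    if (any(object@counts < 0)) return("counts must be non-negative")
    rs <- rowSums(object@counts)
    ok <- rs > 0
    if (any(ok) && any(abs(rowSums(object@probs)[ok] - 1) > 1e-12))
        return("rows with observed counts must sum to 1")
    if (any(!ok) && !all(is.na(object@probs[!ok, ])))
        return("zero-count rows must be NA")
    TRUE
})

#' EncoderModel: a trained encoder/decoder for one branch
#'
#' Wraps the weights and configuration of one representation learner: the
#' variational autoencoder (\code{"VAE"}), the plain autoencoder
#' (\code{"AE"}), adversarial autoencoders regularized toward a unit
#' Gaussian (\code{"AAE1x"}) or a 4-component Gaussian mixture
#' (\code{"AAE4x"}), or \code{"PCA"}.
#'
#' @slot kind one of \code{"VAE"}, \code{"AE"}, \code{"AAE1x"},
#'   \code{"AAE4x"}, \code{"PCA"}.
#' @slot branch \code{"mask"}, \code{"texture"} or \code{""}.
#' @slot params list of fitted weights.
#' @slot config list of training configuration (see [vaeConfig()]).
#' @export
setClass("EncoderModel",
    representation(kind = "character", branch = "character",
                   params = "list", config = "list"))

setValidity("EncoderModel", function(object) {
    if (!object@kind %in% c("VAE", "AE", "AAE1x", "AAE4x", "PCA"))
        return("unknown model kind")
    TRUE
})
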