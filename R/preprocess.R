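## Second central moments of a binary mask. Returns centroid, the
## orientation (radians, direction of the major axis in (col, row) = (x, y)
## coordinates) and the eigenvalue ratio used for the rotation tie rule.
.maskMoments <- function(mask) {
    px <- which(mask > 0, arr.ind = TRUE)
    n <- nrow(px)
    ctr <- colMeans(px)                       # (row, col)
    dy <- px[, 1] - ctr[1]; dx <- px[, 2] - ctr[2]
    mxx <- mean(dx * dx); myy <- mean(dy * dy); mxy <- mean(dx * dy)
    ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2), symmetric = TRUE)
    major <- ev$vectors[, 1]                  # (x, y) direction
    lam <- pmax(ev$values, 1e-12)
    list(centroid = ctr, major = major, ratio = lam[1] / lam[2],
         eccentricity = sqrt(max(0, 1 - lam[2] / lam[1])))
}

## Resample `img` on a size x size canvas so that the source point `center`
## maps to the canvas center, rotated by `beta` (radians) and scaled by `s`.
## interp: "bilinear" or "nearest"; `fill` is used outside the source.
.resampleAffine <- function(img, center, beta, s, size, interp, fill) {
    ctrOut <- (size + 1) / 2
    grid <- expand.grid(r = seq_len(size), c = seq_len(size))
    dy <- (grid$r - ctrOut) / s; dx <- (grid$c - ctrOut) / s
    ## inverse rotation: output -> source
    sx <- cos(-beta) * dx - sin(-beta) * dy + center[2]
    sy <- sin(-beta) * dx + cos(-beta) * dy + center[1]
    h <- nrow(img); w <- ncol(img)
    out <- rep(fill, size * size)
    if (interp == "nearest") {
        ri <- round(sy); ci <- round(sx)
        ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
        out[ok] <- img[cbind(ri[ok], ci[ok])]
    } else {
        r0 <- floor(sy); c0 <- floor(sx)
        fr <- sy - r0; fc <- sx - c0
        ok <- r0 >= 1 & r0 + 1 <= h & c0 >= 1 & c0 + 1 <= w
        i00 <- cbind(r0[ok], c0[ok]); i01 <- cbind(r0[ok], c0[ok] + 1)
        i10 <- cbind(r0[ok] + 1, c0[ok]); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
        out[ok] <- img[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
                   img[i01] * (1 - fr[ok]) * fc[ok] +
                   img[i10] * fr[ok] * (1 - fc[ok]) +
                   img[i11] * fr[ok] * fc[ok]
    }
    matrix(out, size, size)
}

#' Pose-normalize one cell crop
#'
#' Canonicalization removes the trivial variation a latent representation
#' should not spend capacity on: the cell is re-centered on its mask
#' centroid, rotated so the mask's second-moment major axis is vertical,
#' isotropically rescaled so the rotated mask fits the canonical frame with
#' a fixed margin, and reflected so that pixel mass is biased to the top and
#' the right. Near-circular masks (moment ratio below `tieRatio`) skip the
#' rotation, whose angle would be undefined.
#'
#' @param brightfieldCrop brightfield patch (matrix)
#' @param maskCrop binary mask patch, same shape, non-empty
#' @param size canonical output side in px
#' @param margin fraction of the frame kept free around the mask
#' @param tieRatio moment-eigenvalue ratio under which rotation is skipped
#' @param background fill value for brightfield pixels sampled outside the
#'   source crop
#' @param scale global scale factor (a shared micrometers-per-pixel
#'   convention). Relative cell size is preserved: a cell is only shrunk
#'   below this scale when its rotated bounding box would not fit the
#'   canonical frame with the requested margin
#' @return list with `mask` (0/1 matrix `size x size`), `brightfield`
#'   (matrix, same size) and `pose` (rotation degrees, flips, scale)
#' @export
canonicalizeCrop <- function(brightfieldCrop, maskCrop, size = 64L,
                             margin = 0.1, tieRatio = 1.05,
                             background = 0.5, scale = 1) {
    if (!any(maskCrop > 0)) stop("empty mask cannot be canonicalized")
    border <- c(maskCrop[1, ], maskCrop[nrow(maskCrop), ],
                maskCrop[, 1], maskCrop[, ncol(maskCrop)])
    if (mean(border > 0) > 0.5)
        stop("mask touches more than half of the crop border")
    ## keep the largest connected component
    lab <- EBImage::bwlabel(maskCrop > 0)
    counts <- tabulate(as.integer(lab))
    maskCrop <- (lab == which.max(counts)) * 1

    mom <- .maskMoments(maskCrop)
    beta <- 0
    if (mom$ratio >= tieRatio) {
        alpha <- atan2(mom$major[2], mom$major[1])  # angle from x-axis
        beta <- pi / 2 - alpha                      # rotate major axis to y
    }
    ## scale from the rotated bounding box of the mask
    px <- which(maskCrop > 0, arr.ind = TRUE)
    dy <- px[, 1] - mom$centroid[1]; dx <- px[, 2] - mom$centroid[2]
    qx <- cos(beta) * dx - sin(beta) * dy
    qy <- sin(beta) * dx + cos(beta) * dy
    extent <- 2 * max(abs(c(qx, qy))) + 2
    ## undo rotation inflation only: shrink when the rotated content would
    ## overflow the frame, never inflate, so relative cell size survives
    s <- min(scale, size * (1 - 2 * margin) / extent)

    mask <- .resampleAffine(maskCrop, mom$centroid, beta, s, size,
                            "nearest", 0)
    bf <- .resampleAffine(brightfieldCrop, mom$centroid, beta, s, size,
                          "bilinear", background)
    ## reflect so the pixel-count majority sits in the top and right
    ## halves (the centroid itself is centered, so a count rule is the
    ## stable reading of density skew)
    half <- floor(size / 2)
    flipV <- sum(mask[seq_len(half), ]) <
        sum(mask[(size - half + 1):size, ])
    if (flipV) { mask <- mask[size:1, ]; bf <- bf[size:1, ] }
    flipH <- sum(mask[, (size - half + 1):size]) <
        sum(mask[, seq_len(half)])
    if (flipH) { mask <- mask[, size:1]; bf <- bf[, size:1] }
    list(mask = mask, brightfield = bf,
         pose = list(rotation_deg = beta * 180 / pi, flipV = flipV,
                     flipH = flipH, scale = s))
}

#' Binary mask image at the canonical resolution
#'
#' @param mask a canonicalized mask matrix
#' @param size output side; resampled (nearest neighbour) if it differs
#' @return matrix with values in \{0, 1\}
#' @export
makeMaskImage <- function(mask, size = nrow(mask)) {
    if (nrow(mask) != size || ncol(mask) != size)
        mask <- as.matrix(EBImage::resize(EBImage::Image(mask), w = size,
                                          h = size, filter = "none"))
    (mask > 0.5) * 1
}

#' Texture image: standardized interior intensities on a neutral field
#'
#' Interior brightfield values are standardized to zero mean and unit
#' variance, then mapped linearly onto `[0, 1]` (so the interior minimum is
#' exactly 0 and the maximum exactly 1); every pixel outside the mask is set
#' to 0.5. A constant interior is degenerate: the whole image becomes 0.5
#' and the result is flagged.
#'
#' @param brightfield canonicalized brightfield matrix
#' @param mask canonicalized binary mask, same shape
#' @return matrix in `[0, 1]` with attribute `degenerate` (logical)
#' @export
makeTextureImage <- function(brightfield, mask) {
    stopifnot(identical(dim(brightfield), dim(mask)))
    inside <- mask > 0
    out <- matrix(0.5, nrow(mask), ncol(mask))
    vals <- brightfield[inside]
    degenerate <- length(vals) < 2 || stats::sd(vals) == 0
    if (!degenerate) {
        z <- (vals - mean(vals)) / stats::sd(vals)
        out[inside] <- (z - min(z)) / (max(z) - min(z))
    }
    attr(out, "degenerate") <- degenerate
    out
}

#' Pose-normalize a whole CropSet
#'
#' Applies [canonicalizeCrop()], [makeMaskImage()] and [makeTextureImage()]
#' to every crop. Crops that cannot be canonicalized (empty masks, masks
#' covering most of the border) are dropped with a warning.
#'
#' @param crops a \linkS4class{CropSet}
#' @param size canonical image side
#' @param margin,tieRatio,scale passed to [canonicalizeCrop()]
#' @return a \linkS4class{CanonicalSet}
#' @export
canonicalizeSet <- function(crops, size = 64L, margin = 0.1,
                            tieRatio = 1.05, scale = 1) {
    n <- nCells(crops)
    bf <- brightfield(crops); mk <- masks(crops)
    maskImgs <- array(0, c(size, size, n))
    texImgs <- array(0, c(size, size, n))
    rot <- numeric(n); fv <- logical(n); fh <- logical(n)
    sc <- numeric(n); dg <- logical(n); ok <- logical(n)
    for (i in seq_len(n)) {
        res <- tryCatch(
            canonicalizeCrop(bf[, , i], mk[, , i], size = size,
                             margin = margin, tieRatio = tieRatio,
                             scale = scale),
            error = function(e) NULL)
        if (is.null(res)) next
        ok[i] <- TRUE
        maskImgs[, , i] <- makeMaskImage(res$mask, size)
        tex <- makeTextureImage(res$brightfield, res$mask)
        texImgs[, , i] <- tex
        dg[i] <- attr(tex, "degenerate")
        rot[i] <- res$pose$rotation_deg
        fv[i] <- res$pose$flipV; fh[i] <- res$pose$flipH
        sc[i] <- res$pose$scale
    }
    if (!all(ok))
        warning(sum(!ok), " crop(s) could not be canonicalized and were ",
                "dropped")
    keep <- which(ok)
    new("CanonicalSet",
        maskImages = maskImgs[, , keep, drop = FALSE],
        textureImages = texImgs[, , keep, drop = FALSE],
        pose = DataFrame(rotation_deg = rot[keep], flipV = fv[keep],
                         flipH = fh[keep], scale = sc[keep],
                         degenerate = dg[keep]),
        meta = cellMeta(crops)[keep, , drop = FALSE])
}
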