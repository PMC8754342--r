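#' Gaussian Kullback-Leibler divergence of the latent posterior
#'
#' Closed form of the divergence between a diagonal Gaussian
#' \code{N(mu, sigma^2)} and the unit Gaussian prior:
#' \deqn{KLD = -\tfrac12 \sum_i (1 + \log\sigma_i^2 - \mu_i^2 - \sigma_i^2)}
#' It is non-negative, and zero exactly at \code{mu = 0, sigma = 1}.
#'
#' @param mu,sigma latent mean and standard deviation vectors
#' @return divergence (scalar)
#' @examples
#' kldGaussian(0, 1)     # 0
#' kldGaussian(1, 1)     # 0.5
#' @export
kldGaussian <- function(mu, sigma) {
    if (any(sigma <= 0)) stop("sigma must be positive")
    -0.5 * sum(1 + log(sigma^2) - mu^2 - sigma^2)
}

#' Combined VAE objective
#'
#' The training loss is the weighted combination
#' \code{L = A * (gamma * MSE + (1 - gamma) * KLD)}; \code{gamma = 1}
#' reduces it to pure reconstruction, \code{gamma = 0} to pure
#' regularization.
#'
#' @param mse reconstruction error term
#' @param kld KL-divergence term
#' @param A positive overall scale
#' @param gamma reconstruction weight in `[0, 1]`
#' @return scalar loss
#' @export
vaeLoss <- function(mse, kld, A = 1, gamma = 0.9) {
    if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
    if (A <= 0) stop("A must be positive")
    A * (gamma * mse + (1 - gamma) * kld)
}

#' Training configuration for the latent-representation models
#'
#' @param A positive loss scale
#' @param gamma reconstruction weight in `[0, 1]`; the remainder weights
#'   the KL regularizer
#' @param J latent dimension per branch
#' @param steps optimizer steps
#' @param seed integer seed
#' @param hidden encoder hidden widths (decoder mirrors them)
#' @param batch minibatch size
#' @param lr Adam learning rate
#' @param advWeight adversarial-loss weight (AAE variants only)
#' @return list of class `"VaeLossConfig"`
#' @export
vaeConfig <- function(A = 1, gamma = 0.9, J = 100L, steps = 2000L,
                      seed = 1, hidden = c(256L, 64L), batch = 32L,
                      lr = 1e-3, advWeight = 1) {
    if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
    if (A <= 0) stop("A must be positive")
    if (J < 1) stop("J must be >= 1")
    structure(list(A = A, gamma = gamma, J = as.integer(J),
                   steps = as.integer(steps), seed = seed,
                   hidden = as.integer(hidden), batch = as.integer(batch),
                   lr = lr, advWeight = advWeight),
              class = "VaeLossConfig")
}

.checkImages <- function(images) {
    d <- dim(images)
    if (is.null(d) || length(d) != 3L)
        stop("images must be an s x s x n array")
    if (d[3L] < 1L) stop("at least one image is required")
    if (min(images) < 0 || max(images) > 1)
        stop("image values must lie in [0, 1]")
    d
}

#' Train a variational autoencoder on one branch
#'
#' Encoder and decoder are dense networks; the encoder trunk feeds two
#' linear heads producing the posterior mean and log-variance, a latent
#' sample is drawn by reparameterization (`z = mu + sigma * eps`), and the
#' decoder reconstructs the image through a sigmoid output. The loss is
#' [vaeLoss()] with per-sample `MSE = ||x - xhat||^2` and the closed-form
#' Gaussian divergence [kldGaussian()], optimized with Adam.
#'
#' @param images array `s x s x n` of canonical images in `[0, 1]`
#' @param cfg a [vaeConfig()]
#' @param branch `"mask"`, `"texture"` or `""` (bookkeeping only)
#' @return an \linkS4class{EncoderModel} of kind `"VAE"` whose config
#'   records the loss trace (`lossTrace`)
#' @seealso [encodeImages()], [decodeImages()], [trainBaseline()]
#' @export
trainVAE <- function(images, cfg = vaeConfig(), branch = "") {
    d <- .checkImages(images)
    side <- d[1L]; D <- side * d[2L]
    X <- .flattenImages(images)
    J <- cfg$J
    .withSeed(cfg$seed, {
        trunk <- .nnInit(c(D, cfg$hidden), rep("lrelu", length(cfg$hidden)))
        H <- cfg$hidden[length(cfg$hidden)]
        heads <- .nnInit(c(H, 2L * J), "linear")   # [mu | logvar]
        dec <- .nnInit(c(J, rev(cfg$hidden), D),
                       c(rep("lrelu", length(cfg$hidden)), "sigmoid"))
        stT <- .adamInit(trunk); stH <- .adamInit(heads)
        stD <- .adamInit(dec)
        trace <- numeric(0)
        for (s in seq_len(cfg$steps)) {
            idx <- .sampleBatch(nrow(X), cfg$batch)
            xb <- X[idx, , drop = FALSE]
            nb <- nrow(xb)
            cT <- .nnForward(trunk, xb)
            hT <- cT$h[[length(cT$h)]]
            cH <- .nnForward(heads, hT)
            mulv <- cH$h[[2L]]
            mu <- mulv[, seq_len(J), drop = FALSE]
            lv <- pmin(pmax(mulv[, J + seq_len(J), drop = FALSE], -8), 8)
            eps <- matrix(stats::rnorm(nb * J), nb, J)
            z <- mu + exp(0.5 * lv) * eps
            cD <- .nnForward(dec, z)
            xhat <- cD$h[[length(cD$h)]]

            mse <- mean(rowSums((xb - xhat)^2))
            kld <- mean(rowSums(-0.5 * (1 + lv - mu^2 - exp(lv))))
            loss <- vaeLoss(mse, kld, cfg$A, cfg$gamma)
            if (!is.finite(loss))
                stop("NaN/Inf loss at step ", s,
                     " (mse = ", signif(mse, 4), ", kld = ",
                     signif(kld, 4), "); lower the learning rate")
            if (s %% 50L == 1L) trace <- c(trace, loss)

            dxhat <- cfg$A * cfg$gamma * 2 * (xhat - xb) / nb
            bkD <- .nnBackward(dec, cD, dxhat)
            dz <- bkD$dInput
            dmu <- dz + cfg$A * (1 - cfg$gamma) * mu / nb
            dlv <- dz * eps * 0.5 * exp(0.5 * lv) +
                cfg$A * (1 - cfg$gamma) * 0.5 * (exp(lv) - 1) / nb
            bkH <- .nnBackward(heads, cH, cbind(dmu, dlv))
            bkT <- .nnBackward(trunk, cT, bkH$dInput)

            up <- .adamStep(dec, bkD$grads, stD, lr = cfg$lr)
            dec <- up$net; stD <- up$state
            up <- .adamStep(heads, bkH$grads, stH, lr = cfg$lr)
            heads <- up$net; stH <- up$state
            up <- .adamStep(trunk, bkT$grads, stT, lr = cfg$lr)
            trunk <- up$net; stT <- up$state
        }
        new("EncoderModel", kind = "VAE", branch = branch,
            params = list(trunk = trunk, heads = heads, dec = dec),
            config = c(unclass(cfg), list(side = side, lossTrace = trace)))
    })
}

#' Encode images into latent vectors
#'
#' For the VAE the deterministic encoding is the posterior mean `mu`;
#' duplicated images therefore get identical encodings.
#'
#' @param model a trained \linkS4class{EncoderModel}
#' @param images array `s x s x n` at the model's canonical size
#' @return numeric matrix `n x J`
#' @export
encodeImages <- function(model, images) {
    stopifnot(is(model, "EncoderModel"))
    d <- dim(images)
    if (length(d) != 3L || d[1L] != model@config$side ||
        d[2L] != model@config$side)
        stop("images must be ", model@config$side, " x ",
             model@config$side, " x n")
    X <- .flattenImages(images)
    J <- model@config$J
    if (model@kind == "PCA") {
        sc <- sweep(X, 2L, model@params$center) %*% model@params$rotation
        return(sc[, seq_len(J), drop = FALSE])
    }
    cT <- .nnForward(model@params$trunk, X)
    hT <- cT$h[[length(cT$h)]]
    if (model@kind == "VAE") {
        mulv <- .nnForward(model@params$heads, hT)$h[[2L]]
        mulv[, seq_len(J), drop = FALSE]
    } else {
        hT   # AE/AAE encoder ends in the latent layer
    }
}

#' Decode latent vectors back into images
#'
#' @param model a trained \linkS4class{EncoderModel}
#' @param z latent matrix `m x J` (or a single length-`J` vector)
#' @return array `s x s x m` with values in `[0, 1]`
#' @export
decodeImages <- function(model, z) {
    stopifnot(is(model, "EncoderModel"))
    if (is.null(dim(z))) z <- matrix(z, 1L)
    if (ncol(z) != model@config$J)
        stop("z must have length J = ", model@config$J)
    side <- model@config$side
    if (model@kind == "PCA") {
        X <- z %*% t(model@params$rotation[, seq_len(ncol(z)), drop = FALSE])
        X <- sweep(X, 2L, model@params$center, "+")
        return(.unflattenImages(.clip01(X), side))
    }
    cD <- .nnForward(model@params$dec, z)
    .unflattenImages(cD$h[[length(cD$h)]], side)
}

#' Weighted concatenation of shape and texture latents
#'
#' \code{z = c(w * z_shape, (1 - w) * z_texture)}. The weight trades off the
#' two branches; it is swept with [weightSweep()] to maximize cell-type
#' homogeneity in the fused space.
#'
#' @param zShape,zTexture latent matrices (or vectors) of equal dimension
#' @param w fusion weight in `[0, 1]`
#' @return fused matrix with `2J` columns
#' @export
combineLatents <- function(zShape, zTexture, w = 0.5) {
    if (is.null(dim(zShape))) zShape <- matrix(zShape, 1L)
    if (is.null(dim(zTexture))) zTexture <- matrix(zTexture, 1L)
    if (!identical(dim(zShape), dim(zTexture)))
        stop("zShape and zTexture dimensions differ")
    if (w < 0 || w > 1) stop("w must lie in [0, 1]")
    cbind(w * zShape, (1 - w) * zTexture)
}

#' Encode a CanonicalSet with the twin models
#'
#' @param shapeModel,textureModel trained \linkS4class{EncoderModel}s for
#'   the mask and texture branches
#' @param canon a \linkS4class{CanonicalSet}
#' @param w default fusion weight stored in the result
#' @return a \linkS4class{LatentSet}
#' @export
encodeLatents <- function(shapeModel, textureModel, canon, w = 0.5) {
    zs <- encodeImages(shapeModel, maskImages(canon))
    zt <- encodeImages(textureModel, textureImages(canon))
    new("LatentSet", zShape = zs, zTexture = zt, weight = w,
        meta = cellMeta(canon))
}

#' Decode a feature-exaggerated latent vector
#'
#' Interpretation device: starting from a base latent vector (by default
#' the population mean encoding of `images`), the selected latent
#' dimensions are increased by `magnitude`, and both the base and the
#' exaggerated vectors are decoded. The signed difference image shows what
#' the selected features encode in image space; magnitude 0 gives an
#' identically zero difference.
#'
#' @param model a trained \linkS4class{EncoderModel}
#' @param features integer indices of latent dimensions (a "feature group")
#' @param magnitude shift applied to the selected dimensions
#' @param base base latent vector; defaults to the mean encoding of
#'   `images`
#' @param images used to compute the mean latent when `base` is missing
#' @return list with `image` (decoded exaggerated image), `baseImage`
#'   (decoded base) and `difference` (`image - baseImage`)
#' @export
exaggerateFeatures <- function(model, features, magnitude, base = NULL,
                               images = NULL) {
    J <- model@config$J
    if (any(features < 1 | features > J))
        stop("feature indices out of range 1..J")
    if (is.null(base)) {
        if (is.null(images))
            stop("either base or images must be supplied")
        base <- colMeans(encodeImages(model, images))
    }
    z2 <- base
    z2[features] <- z2[features] + magnitude
    img0 <- decodeImages(model, base)[, , 1L]
    img1 <- decodeImages(model, z2)[, , 1L]
    list(image = img1, baseImage = img0, difference = img1 - img0)
}

#' Train a baseline encoder (AE, adversarial AE, or PCA)
#'
#' Baselines share the branch interface of the VAE. The plain autoencoder
#' minimizes reconstruction MSE. The adversarial autoencoders additionally
#' train a discriminator with
#' \code{L = -(1/N) sum[log D(z_real) + log(1 - D(z_enc))]}, pulling the
#' latent distribution toward a unit Gaussian (`AAE1x`) or a 4-component
#' Gaussian mixture with means (-1, -0.5, 0.5, 1) and unit sds (`AAE4x`).
#' PCA fits `J` principal components on the flattened images.
#'
#' @param kind `"AE"`, `"AAE1x"`, `"AAE4x"` or `"PCA"`
#' @param images array `s x s x n` in `[0, 1]`
#' @param cfg a [vaeConfig()]; `gamma`/`A` are ignored except by the VAE
#' @param branch bookkeeping label
#' @return an \linkS4class{EncoderModel}
#' @export
trainBaseline <- function(kind = c("AE", "AAE1x", "AAE4x", "PCA"),
                          images, cfg = vaeConfig(), branch = "") {
    kind <- match.arg(kind)
    d <- .checkImages(images)
    side <- d[1L]; D <- side * d[2L]
    X <- .flattenImages(images)
    J <- cfg$J
    if (kind == "PCA") {
        if (J > min(dim(X)))
            stop("J cannot exceed min(n, pixels) for PCA")
        pc <- stats::prcomp(X, center = TRUE, rank. = J)
        return(new("EncoderModel", kind = "PCA", branch = branch,
                   params = list(rotation = pc$rotation,
                                 center = pc$center),
                   config = c(unclass(cfg), list(side = side))))
    }
    adversarial <- kind %in% c("AAE1x", "AAE4x")
    mixMeans <- c(-1, -0.5, 0.5, 1)
    .withSeed(cfg$seed, {
        enc <- .nnInit(c(D, cfg$hidden, J),
                       c(rep("lrelu", length(cfg$hidden)), "linear"))
        dec <- .nnInit(c(J, rev(cfg$hidden), D),
                       c(rep("lrelu", length(cfg$hidden)), "sigmoid"))
        stE <- .adamInit(enc); stD <- .adamInit(dec)
        if (adversarial) {
            disc <- .nnInit(c(J, 32L, 1L), c("lrelu", "linear"))
            stDisc <- .adamInit(disc)
        }
        sigm <- function(x) 1 / (1 + exp(-pmin(pmax(x, -30), 30)))
        trace <- numeric(0)
        for (s in seq_len(cfg$steps)) {
            idx <- .sampleBatch(nrow(X), cfg$batch)
            xb <- X[idx, , drop = FALSE]; nb <- nrow(xb)
            cE <- .nnForward(enc, xb)
            z <- cE$h[[length(cE$h)]]
            cD <- .nnForward(dec, z)
            xhat <- cD$h[[length(cD$h)]]
            mse <- mean(rowSums((xb - xhat)^2))
            if (!is.finite(mse)) stop("NaN/Inf loss at step ", s)
            if (s %% 50L == 1L) trace <- c(trace, mse)
            dxhat <- 2 * (xhat - xb) / nb
            bkD <- .nnBackward(dec, cD, dxhat)
            dz <- bkD$dInput
            if (adversarial) {
                ## discriminator step: real prior sample vs current encodings
                if (kind == "AAE1x") {
                    zr <- matrix(stats::rnorm(nb * J), nb, J)
                } else {
                    comp <- sample.int(4L, nb * J, replace = TRUE)
                    zr <- matrix(stats::rnorm(nb * J, mixMeans[comp], 1),
                                 nb, J)
                }
                cR <- .nnForward(disc, zr)
                cF <- .nnForward(disc, z)
                pR <- sigm(cR$h[[length(cR$h)]])
                pF <- sigm(cF$h[[length(cF$h)]])
                bkR <- .nnBackward(disc, cR, (pR - 1) / nb)
                bkF <- .nnBackward(disc, cF, (pF - 0) / nb)
                gD <- mapply(function(a, b)
                    list(W = a$W + b$W, b = a$b + b$b),
                    bkR$grads, bkF$grads, SIMPLIFY = FALSE)
                up <- .adamStep(disc, gD, stDisc, lr = cfg$lr)
                disc <- up$net; stDisc <- up$state
                ## generator step: encoder fools the (frozen) discriminator
                cF2 <- .nnForward(disc, z)
                pF2 <- sigm(cF2$h[[length(cF2$h)]])
                bkG <- .nnBackward(disc, cF2,
                                   cfg$advWeight * (pF2 - 1) / nb)
                dz <- dz + bkG$dInput
            }
            bkE <- .nnBackward(enc, cE, dz)
            up <- .adamStep(dec, bkD$grads, stD, lr = cfg$lr)
            dec <- up$net; stD <- up$state
            up <- .adamStep(enc, bkE$grads, stE, lr = cfg$lr)
            enc <- up$net; stE <- up$state
        }
        params <- list(trunk = enc, dec = dec)
        if (adversarial) params$disc <- disc
        new("EncoderModel", kind = kind, branch = branch, params = params,
            config = c(unclass(cfg), list(side = side, lossTrace = trace)))
    })
}
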