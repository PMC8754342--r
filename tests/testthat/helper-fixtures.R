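## Shared small phenotype fixtures. Kept deliberately modest in size so the
## full suite stays fast; the heavier end-to-end studies live in
## test-acceptance.R.

roundSmallSpec <- function()
    cellPhenotype(1, area_mean = 180, area_sd = 25, ecc_mean = 0.1,
                  ecc_sd = 0.05, granule_density = 0, edge_contrast = 0.3)

elongatedLargeSpec <- function()
    cellPhenotype(2, area_mean = 420, area_sd = 50, ecc_mean = 0.7,
                  ecc_sd = 0.05, granule_density = 0.08,
                  edge_contrast = 0.15)

## tiny canonical image set for encoder unit tests (8x8, two blob types)
tinyImageSet <- function(n = 40, side = 8, seed = 1) {
    set.seed(seed)
    imgs <- array(0, c(side, side, n))
    for (i in seq_len(n)) {
        r <- if (i %% 2 == 0) 2.2 else 3.2
        ctr <- (side + 1) / 2
        d <- sqrt(outer((seq_len(side) - ctr)^2,
                        (seq_len(side) - ctr)^2, "+"))
        img <- (d < r) * 0.9 + matrix(rnorm(side^2, 0, 0.02), side, side)
        imgs[, , i] <- pmin(pmax(img, 0), 1)
    }
    imgs
}

## toy images with several independent factors of variation (radius,
## position, intensity), for checks that need a non-degenerate latent space
richImageSet <- function(n = 200, side = 8, seed = 1) {
    set.seed(seed)
    imgs <- array(0, c(side, side, n))
    for (i in seq_len(n)) {
        r <- runif(1, 1.3, 3.4)
        cy <- 4.5 + runif(1, -1.5, 1.5); cx <- 4.5 + runif(1, -1.5, 1.5)
        amp <- runif(1, 0.5, 1)
        d <- sqrt(outer((seq_len(side) - cy)^2,
                        (seq_len(side) - cx)^2, "+"))
        img <- (d < r) * amp + matrix(rnorm(side^2, 0, 0.03), side, side)
        imgs[, , i] <- pmin(pmax(img, 0), 1)
    }
    imgs
}

## rotate+mirror a crop with the package-independent EBImage transforms,
## used to build inputs for the canonicalization invariance checks
rotateMirrorCrop <- function(bf, mask, angle, mirror = FALSE) {
    big <- function(m, fill) {
        out <- matrix(fill, nrow(m) + 40, ncol(m) + 40)
        out[20 + seq_len(nrow(m)), 20 + seq_len(ncol(m))] <- m
        out
    }
    bf2 <- big(bf, 0.5); mk2 <- big(mask, 0)
    bfr <- as.matrix(EBImage::rotate(EBImage::Image(bf2), angle,
                                     bg.col = 0.5, output.dim = dim(bf2)))
    mkr <- as.matrix(EBImage::rotate(EBImage::Image(mk2), angle,
                                     filter = "none", bg.col = 0,
                                     output.dim = dim(mk2)))
    if (mirror) { bfr <- bfr[, ncol(bfr):1]; mkr <- mkr[, ncol(mkr):1] }
    list(brightfield = bfr, mask = (mkr > 0.5) * 1)
}
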