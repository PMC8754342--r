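#' Describe one morphological cell class for the synthetic generator
#'
#' A phenotype bundles the observable features the downstream latent analysis
#' is expected to recover: size (mask area), elongation (eccentricity),
#' boundary contrast (dark rim amplitude), interior granularity and overall
#' interior brightness.
#'
#' @param class_id integer class label carried into generated metadata
#' @param area_mean,area_sd mask area in px^2 (mean and spread across cells)
#' @param ecc_mean,ecc_sd second-moment eccentricity in \code{[0, 1)}
#' @param edge_contrast amplitude of the dark rim just inside the boundary
#'   (a matching lighter halo is drawn just outside); 0 disables the rim
#' @param granule_density expected granules per px^2 of interior
#' @param granule_density_sd cell-to-cell spread of the granule density
#'   (truncated at 0); lets texture vary independently of class
#' @param granule_darkness intensity offset of one granule (negative =
#'   darker than interior)
#' @param interior_level mean interior intensity offset relative to the
#'   background (negative = darker cell body)
#' @param step_sd random-walk step scale (px per frame) used when this class
#'   appears in a movie; controls the velocity of cells in this state
#' @return a validated list of class \code{"CellPhenotypeSpec"}
#' @examples
#' round_small <- cellPhenotype(1, area_mean = 200, ecc_mean = 0.1)
#' @export
cellPhenotype <- function(class_id, area_mean, area_sd = 0,
                          ecc_mean = 0.3, ecc_sd = 0,
                          edge_contrast = 0.25, granule_density = 0,
                          granule_density_sd = 0,
                          granule_darkness = -0.25, interior_level = -0.08,
                          step_sd = 1) {
    if (area_mean <= 0) stop("area_mean must be positive")
    if (ecc_mean < 0 || ecc_mean >= 1)
        stop("ecc_mean must lie in [0, 1)")
    if (granule_density < 0) stop("granule_density must be >= 0")
    if (edge_contrast < 0) stop("edge_contrast must be >= 0")
    structure(list(class_id = as.integer(class_id),
                   area_mean = area_mean, area_sd = area_sd,
                   ecc_mean = ecc_mean, ecc_sd = ecc_sd,
                   edge_contrast = edge_contrast,
                   granule_density = granule_density,
                   granule_density_sd = granule_density_sd,
                   granule_darkness = granule_darkness,
                   interior_level = interior_level,
                   step_sd = step_sd),
              class = "CellPhenotypeSpec")
}

#' Describe a synthetic imaging scene
#'
#' @param frameShape frame size in px, \code{c(rows, cols)}
#' @param nCells number of cells placed in the scene
#' @param umPerPx spatial calibration (micrometers per pixel)
#' @param minutesPerFrame acquisition interval in minutes
#' @param background background intensity level (fraction of dynamic range)
#' @param noiseSd Gaussian pixel-noise standard deviation
#' @param exclusionRadius minimum distance (px) between initial centroids
#' @param margin border margin (px) cells are kept away from
#' @return a list of class \code{"SceneSpec"}
#' @export
sceneSpec <- function(frameShape = c(512L, 512L), nCells = 30L,
                      umPerPx = 0.33, minutesPerFrame = 3,
                      background = 0.5, noiseSd = 0.02,
                      exclusionRadius = 24, margin = 24) {
    if (minutesPerFrame <= 0) stop("minutesPerFrame must be positive")
    if (nCells < 1) stop("nCells must be >= 1")
    structure(list(frameShape = as.integer(frameShape),
                   nCells = as.integer(nCells), umPerPx = umPerPx,
                   minutesPerFrame = minutesPerFrame,
                   background = background, noiseSd = noiseSd,
                   exclusionRadius = exclusionRadius, margin = margin),
              class = "SceneSpec")
}

#' Construct a finite-state Markov model
#'
#' @param P row-stochastic transition matrix (k x k)
#' @param pi initial state distribution; defaults to uniform
#' @return a \linkS4class{MarkovModel}
#' @examples
#' markovModel(matrix(c(.9, .1, .2, .8), 2, byrow = TRUE))
#' @export
markovModel <- function(P, pi = rep(1 / nrow(P), nrow(P))) {
    new("MarkovModel", P = as.matrix(P), pi = pi)
}

## low-order Fourier perturbation of the ellipse boundary radius
.boundaryPerturbation <- function(phi, amps, phases) {
    out <- rep(1, length(phi))
    for (k in seq_along(amps))
        out <- out + amps[k] * cos((k + 2) * phi + phases[k])
    out
}

#' Render one synthetic cell
#'
#' Draws a randomly oriented, boundary-perturbed ellipse with the requested
#' area and eccentricity on a square patch. The brightfield channel shows the
#' interior intensity offset, a dark rim just inside the boundary (amplitude
#' \code{edge_contrast}) with a lighter halo outside, and Poisson-placed dark
#' granules. The fluorescence channel is a smoothed copy of the mask plus
#' noise, emulating a cytoplasm stain.
#'
#' @param spec a [cellPhenotype()] specification
#' @param seed integer seed; identical seeds give identical pixels
#' @param size odd patch side in px; chosen from the cell size when `NULL`
#' @param background background intensity
#' @param noiseSd pixel noise standard deviation
#' @return list with `brightfield`, `mask` (0/1 matrix, one connected
#'   component) and `fluorescence`, all `size x size`
#' @examples
#' cell <- renderCell(cellPhenotype(1, area_mean = 300), seed = 1)
#' @export
renderCell <- function(spec, seed = NULL, size = NULL,
                       background = 0.5, noiseSd = 0.02) {
    stopifnot(inherits(spec, "CellPhenotypeSpec"))
    if (spec$area_mean < 4) stop("degenerate spec: area_mean below 4 px^2")
    .withSeed(seed, {
        area <- max(4, stats::rnorm(1, spec$area_mean, spec$area_sd))
        ecc <- min(max(stats::rnorm(1, spec$ecc_mean, spec$ecc_sd), 0), 0.95)
        axisRatio <- sqrt(1 - ecc^2)          # b / a
        a <- sqrt(area / (pi * axisRatio))
        b <- a * axisRatio
        theta <- stats::runif(1, 0, pi)
        amps <- stats::rnorm(3, 0, 0.03)
        phases <- stats::runif(3, 0, 2 * pi)
        if (is.null(size)) {
            size <- 2L * as.integer(ceiling(a * 1.2)) + 9L
        }
        if (size %% 2L == 0L) size <- size + 1L
        if (a * 1.15 > size / 2 - 2)
            stop("cell does not fit the requested patch size")
        ctr <- (size + 1) / 2
        cols <- matrix(seq_len(size), size, size, byrow = TRUE) - ctr
        rows <- matrix(seq_len(size), size, size) - ctr
        u <- cos(theta) * cols + sin(theta) * rows
        v <- -sin(theta) * cols + cos(theta) * rows
        m <- sqrt((u / a)^2 + (v / b)^2)
        phi <- atan2(v / b, u / a)
        mask <- (m <= .boundaryPerturbation(phi, amps, phases)) * 1

        bf <- background +
            matrix(stats::rnorm(size^2, 0, noiseSd), size, size)
        bf <- bf + mask * spec$interior_level
        if (spec$edge_contrast > 0) {
            din <- EBImage::distmap(mask)
            dout <- EBImage::distmap(1 - mask)
            bf <- bf - spec$edge_contrast * exp(-(din - 1)^2 / 1.6) *
                (mask == 1)
            bf <- bf + 0.6 * spec$edge_contrast *
                exp(-(dout - 1)^2 / 1.6) * (mask == 0)
        }
        dens <- max(0, stats::rnorm(1, spec$granule_density,
                                    spec$granule_density_sd))
        nGran <- stats::rpois(1, dens * area)
        if (nGran > 0) {
            inside <- which(mask == 1)
            pick <- inside[sample.int(length(inside), nGran, replace = TRUE)]
            gr <- ((pick - 1) %% size) + 1
            gc <- ((pick - 1) %/% size) + 1
            for (g in seq_len(nGran)) {
                r0 <- max(1, gr[g] - 3):min(size, gr[g] + 3)
                c0 <- max(1, gc[g] - 3):min(size, gc[g] + 3)
                d2 <- outer((r0 - gr[g])^2, (c0 - gc[g])^2, "+")
                bf[r0, c0] <- bf[r0, c0] +
                    spec$granule_darkness * exp(-d2 / 2.2) *
                    mask[r0, c0]
            }
        }
        fl <- as.matrix(EBImage::gblur(mask * 0.8, sigma = 1.5)) +
            matrix(stats::rnorm(size^2, 0, noiseSd), size, size)
        list(brightfield = .clip01(bf), mask = mask,
             fluorescence = .clip01(fl))
    })
}

#' Generate a labeled crop population from several phenotypes
#'
#' @param specs list of [cellPhenotype()] specifications (one per class)
#' @param nPerClass crops rendered per class
#' @param seed integer seed; the whole dataset is reproducible from it
#' @param size patch side in px (odd); must accommodate the largest class
#' @param background,noiseSd passed to [renderCell()]
#' @return a \linkS4class{CropSet} whose metadata carries `class_id`
#' @examples
#' cs <- makeCropDataset(list(cellPhenotype(1, 150), cellPhenotype(2, 350)),
#'                       nPerClass = 5, seed = 1, size = 49)
#' @export
makeCropDataset <- function(specs, nPerClass, seed = 1, size = 65,
                            background = 0.5, noiseSd = 0.02) {
    if (length(specs) == 0) stop("specs must be a non-empty list")
    if (nPerClass < 1) stop("nPerClass must be >= 1")
    k <- length(specs)
    n <- k * nPerClass
    seeds <- .childSeeds(seed, n)
    bf <- array(0, c(size, size, n))
    mk <- array(0L, c(size, size, n))
    cls <- integer(n)
    i <- 0L
    for (ci in seq_len(k)) {
        for (r in seq_len(nPerClass)) {
            i <- i + 1L
            cell <- renderCell(specs[[ci]], seed = seeds[i], size = size,
                               background = background, noiseSd = noiseSd)
            bf[, , i] <- cell$brightfield
            mk[, , i] <- cell$mask
            cls[i] <- specs[[ci]]$class_id
        }
    }
    new("CropSet", brightfield = bf, mask = mk,
        meta = DataFrame(crop_id = seq_len(n), class_id = cls))
}

#' Simulate Markov state sequences
#'
#' @param model a \linkS4class{MarkovModel}
#' @param nCells number of independent chains
#' @param T number of time points (>= 2)
#' @param seed integer seed
#' @return integer matrix `nCells x T` of states in `1..k`
#' @examples
#' m <- markovModel(matrix(c(.5, .5, .5, .5), 2))
#' s <- simulateMarkovStates(m, nCells = 10, T = 20, seed = 1)
#' @export
simulateMarkovStates <- function(model, nCells, T, seed = 1) {
    stopifnot(is(model, "MarkovModel"))
    if (T < 2) stop("T must be >= 2")
    P <- model@P; k <- nrow(P)
    .withSeed(seed, {
        S <- matrix(0L, nCells, T)
        S[, 1L] <- sample.int(k, nCells, replace = TRUE, prob = model@pi)
        for (t in 2L:T) {
            prev <- S[, t - 1L]
            nxt <- integer(nCells)
            for (s in unique(prev)) {
                idx <- which(prev == s)
                nxt[idx] <- sample.int(k, length(idx), replace = TRUE,
                                       prob = P[s, ])
            }
            S[, t] <- nxt
        }
        S
    })
}

#' Simulate a brightfield/fluorescence movie of motile state-switching cells
#'
#' Cells are placed with a minimum separation, perform an isotropic Gaussian
#' random walk whose step scale is set by the phenotype of their current
#' state, and switch states according to the supplied Markov model. No
#' division or death is modeled. Every cell's rendered phenotype at frame t
#' matches its Markov state at t.
#'
#' @param scene a [sceneSpec()]
#' @param model a \linkS4class{MarkovModel} with as many states as `specs`
#' @param specs list of [cellPhenotype()]; element s renders state s
#' @param T number of frames
#' @param seed integer seed
#' @param render if `FALSE`, only ground-truth tracks are produced (fast
#'   path for dynamics benchmarks); frames are `NULL`
#' @return list with `brightfield` and `fluorescence` (arrays
#'   `h x w x T`, or `NULL`), and `tracks`: a data.frame
#'   `(cell_id, frame, y, x, state)` with one row per cell per frame
#' @export
simulateMovie <- function(scene, model, specs, T = 50L, seed = 1,
                          render = TRUE) {
    stopifnot(inherits(scene, "SceneSpec"), is(model, "MarkovModel"))
    if (nrow(model@P) != length(specs))
        stop("number of Markov states must match number of phenotype specs")
    k <- length(specs)
    h <- scene$frameShape[1L]; w <- scene$frameShape[2L]
    n <- scene$nCells
    seeds <- .childSeeds(seed, 3L + n * T)

    ## initial placement with exclusion radius (rejection sampling)
    pos0 <- .withSeed(seeds[1L], {
        placed <- matrix(NA_real_, n, 2)
        tries <- 0L
        i <- 1L
        while (i <= n) {
            cand <- c(stats::runif(1, scene$margin, h - scene$margin),
                      stats::runif(1, scene$margin, w - scene$margin))
            ok <- i == 1L ||
                min(sqrt(colSums((t(placed[seq_len(i - 1L), , drop = FALSE])
                                  - cand)^2))) >= scene$exclusionRadius
            if (ok) { placed[i, ] <- cand; i <- i + 1L }
            tries <- tries + 1L
            if (tries > 2000L * n)
                stop("overcrowded scene: cells cannot be placed without ",
                     "violating the exclusion radius")
        }
        placed
    })

    states <- if (T == 1L) {
        matrix(.withSeed(seeds[2L],
            sample.int(k, n, replace = TRUE, prob = model@pi)), n, 1L)
    } else simulateMarkovStates(model, n, T, seed = seeds[2L])

    ## random walk, reflected at the margins
    stepSd <- vapply(specs, function(s) s$step_sd, numeric(1))
    pos <- array(0, c(n, 2, T)); pos[, , 1L] <- pos0
    .withSeed(seeds[3L], {
        for (t in seq_len(T)[-1L]) {
            sd_t <- stepSd[states[, t - 1L]]
            step <- matrix(stats::rnorm(2 * n, 0, rep(sd_t, 2)), n, 2)
            p <- pos[, , t - 1L] + step
            p[, 1] <- pmin(pmax(p[, 1], scene$margin), h - scene$margin)
            p[, 2] <- pmin(pmax(p[, 2], scene$margin), w - scene$margin)
            pos[, , t] <- p
        }
    })

    tracks <- data.frame(
        cell_id = rep(seq_len(n), T),
        frame = rep(seq_len(T), each = n),
        y = as.vector(pos[, 1, ]),
        x = as.vector(pos[, 2, ]),
        state = as.vector(states))

    bfFrames <- flFrames <- NULL
    if (render) {
        bfFrames <- array(0, c(h, w, T))
        flFrames <- array(0, c(h, w, T))
        cellSeeds <- matrix(seeds[-(1:3)], n, T)
        noiseSeeds <- .childSeeds(seeds[1L] + 1L, T)
        for (t in seq_len(T)) {
            bfC <- scene$background + .withSeed(noiseSeeds[t],
                matrix(stats::rnorm(h * w, 0, scene$noiseSd), h, w))
            flC <- .withSeed(noiseSeeds[t] + 1L,
                matrix(abs(stats::rnorm(h * w, 0, scene$noiseSd)), h, w))
            for (i in seq_len(n)) {
                cell <- renderCell(specs[[states[i, t]]],
                                   seed = cellSeeds[i, t],
                                   background = scene$background,
                                   noiseSd = 0)
                ps <- nrow(cell$mask); half <- (ps - 1L) %/% 2L
                r0 <- round(pos[i, 1, t]); c0 <- round(pos[i, 2, t])
                rr <- (r0 - half):(r0 + half); cc <- (c0 - half):(c0 + half)
                keepR <- rr >= 1 & rr <= h; keepC <- cc >= 1 & cc <= w
                bfC[rr[keepR], cc[keepC]] <-
                    bfC[rr[keepR], cc[keepC]] +
                    (cell$brightfield - scene$background)[keepR, keepC]
                flC[rr[keepR], cc[keepC]] <- pmax(
                    flC[rr[keepR], cc[keepC]],
                    cell$fluorescence[keepR, keepC])
            }
            bfFrames[, , t] <- .clip01(bfC)
            flFrames[, , t] <- .clip01(flC)
        }
    }
    list(brightfield = bfFrames, fluorescence = flFrames, tracks = tracks)
}
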