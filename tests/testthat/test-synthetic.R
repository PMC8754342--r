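test_that("rendered cells honor the phenotype specification", {
    ## circle case: mask eccentricity stays near zero
    circ <- cellPhenotype(1, area_mean = 300, ecc_mean = 0)
    cell <- renderCell(circ, seed = 3, size = 49)
    expect_lt(morphometrics(cell$mask)$eccentricity, 0.15)
    expect_equal(max(EBImage::bwlabel(cell$mask)), 1)  # single component

    ## granule-free interior is quieter than its granulated twin
    plain <- renderCell(cellPhenotype(1, 400, granule_density = 0,
                                      edge_contrast = 0),
                        seed = 5, size = 49, noiseSd = 0.01)
    grain <- renderCell(cellPhenotype(1, 400, granule_density = 0.15,
                                      edge_contrast = 0),
                        seed = 5, size = 49, noiseSd = 0.01)
    inner <- EBImage::erode(plain$mask, EBImage::makeBrush(5, "disc")) > 0
    expect_lt(var(plain$brightfield[inner]), var(grain$brightfield[inner]))

    ## Monte-Carlo mean mask area tracks area_mean
    spec <- cellPhenotype(1, area_mean = 400, area_sd = 0)
    areas <- vapply(1:100, function(s)
        sum(renderCell(spec, seed = s, size = 55)$mask), numeric(1))
    expect_lt(abs(mean(areas) - 400) / 400, 0.10)

    expect_error(renderCell(cellPhenotype(1, area_mean = 3), seed = 1),
                 "degenerate")
})

test_that("crop datasets are labeled, sized and seed-deterministic", {
    specs <- list(roundSmallSpec(), elongatedLargeSpec())
    a <- makeCropDataset(specs, nPerClass = 50, seed = 9, size = 65)
    expect_equal(nCells(a), 100)
    expect_equal(as.vector(table(cellMeta(a)$class_id)), c(50, 50))
    b <- makeCropDataset(specs, nPerClass = 50, seed = 9, size = 65)
    expect_identical(brightfield(a), brightfield(b))
    expect_identical(masks(a), masks(b))
    expect_error(makeCropDataset(list(), 10), "non-empty")
})

test_that("well-separated classes are recoverable from handcrafted features", {
    ## oracle: logistic fit on area + eccentricity, holdout accuracy
    specs <- list(
        cellPhenotype(1, 150, 15, ecc_mean = 0.1, ecc_sd = 0.05),
        cellPhenotype(2, 420, 30, ecc_mean = 0.2, ecc_sd = 0.05),
        cellPhenotype(3, 150, 15, ecc_mean = 0.75, ecc_sd = 0.04),
        cellPhenotype(4, 420, 30, ecc_mean = 0.75, ecc_sd = 0.04))
    cs <- makeCropDataset(specs, nPerClass = 30, seed = 2, size = 65)
    feats <- t(vapply(seq_len(nCells(cs)), function(i) {
        m <- morphometrics(masks(cs)[, , i])
        c(area = m$area, ecc = m$eccentricity)
    }, numeric(2)))
    df <- data.frame(feats, cls = factor(cellMeta(cs)$class_id))
    set.seed(1)
    hold <- sample(nrow(df), 30)
    fit <- nnet::multinom(cls ~ area + ecc, df[-hold, ], trace = FALSE)
    acc <- mean(predict(fit, df[hold, ]) == df$cls[hold])
    expect_gt(acc, 0.9)
})

test_that("Markov state sequences follow the supplied chain", {
    ## identity chain never moves
    mI <- markovModel(diag(3))
    sI <- simulateMarkovStates(mI, 20, 15, seed = 4)
    expect_true(all(sI == sI[, 1]))

    ## uniform 2-state chain: empirical switch rate within binomial CI
    mU <- markovModel(matrix(0.5, 2, 2))
    sU <- simulateMarkovStates(mU, 500, 100, seed = 7)
    prev <- sU[, -ncol(sU)]; nxt <- sU[, -1]
    expect_lt(abs(mean(nxt[prev == 1] == 2) - 0.5), 0.03)

    ## deterministic alternation
    mA <- markovModel(rbind(c(0, 1), c(1, 0)), pi = c(1, 0))
    sA <- simulateMarkovStates(mA, 5, 10, seed = 1)
    expect_true(all(sA == matrix(rep(c(1, 2), 5), 5, 10, byrow = TRUE)))

    ## detailed counting: total transitions = (T-1) * n
    expect_equal(sum(table(sU[, -ncol(sU)], sU[, -1])), 500 * 99)

    expect_error(markovModel(matrix(c(0.5, 0.6, 0.6, 0.4), 2)), "sum")
    expect_error(simulateMarkovStates(mU, 5, 1), "T must be")
})

test_that("simulated movies carry consistent ground truth", {
    specs <- list(roundSmallSpec(), elongatedLargeSpec())
    P <- rbind(c(0.8, 0.2), c(0.3, 0.7))
    scene <- sceneSpec(frameShape = c(128L, 128L), nCells = 4,
                       exclusionRadius = 30)

    ## stationary single cell under identity dynamics
    still <- sceneSpec(frameShape = c(96L, 96L), nCells = 1)
    spec0 <- list(cellPhenotype(1, 200, step_sd = 0))
    sim0 <- simulateMovie(still, markovModel(matrix(1, 1, 1)), spec0,
                          T = 5, seed = 2, render = FALSE)
    expect_equal(length(unique(sim0$tracks$x)), 1)
    expect_equal(length(unique(sim0$tracks$y)), 1)

    sim <- simulateMovie(scene, markovModel(P), specs, T = 6, seed = 3)
    ## every frame has exactly nCells ground-truth detections
    expect_true(all(table(sim$tracks$frame) == 4))
    expect_equal(dim(sim$brightfield), c(128, 128, 6))
    expect_true(all(sim$brightfield >= 0 & sim$brightfield <= 1))

    ## state-conditional morphology is visible in the rendered frames:
    ## determinism of the render
    sim2 <- simulateMovie(scene, markovModel(P), specs, T = 6, seed = 3)
    expect_identical(sim$brightfield, sim2$brightfield)
    expect_identical(sim$tracks, sim2$tracks)

    ## overcrowding is reported
    tight <- sceneSpec(frameShape = c(64L, 64L), nCells = 40,
                       exclusionRadius = 30)
    expect_error(simulateMovie(tight, markovModel(P), specs, T = 2,
                               seed = 1, render = FALSE), "overcrowded")
})

test_that("transition recovery from ground-truth tracks matches the chain", {
    P <- rbind(c(0.7, 0.2, 0.1), c(0.15, 0.7, 0.15), c(0.1, 0.3, 0.6))
    m <- markovModel(P)
    S <- simulateMarkovStates(m, 300, 25, seed = 11)  # 7200 transitions
    Phat <- countTransitions(S)
    expect_lt(max(abs(Phat - P)), 0.05)
})

test_that("movie TIFF round-trips through disk", {
    arr <- array(runif(32 * 32 * 3), c(32, 32, 3))
    f <- tempfile(fileext = ".tif")
    writeMovieTIFF(arr, f)
    back <- readMovieTIFF(f)
    expect_equal(dim(back), dim(arr))
    expect_lt(max(abs(back - arr)), 2 / 65535)
})
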