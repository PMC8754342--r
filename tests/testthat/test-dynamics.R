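randomFramePair <- function(n, seed, spread = 100) {
    set.seed(seed)
    data.frame(frame = rep(1:2, each = n),
               id = rep(seq_len(n), 2),
               y = runif(2 * n, 0, spread),
               x = runif(2 * n, 0, spread))
}

test_that("pair linking follows the isolation and travel rules", {
    ## single cell, small displacement: one link
    det <- data.frame(frame = c(1, 2), id = c(1, 1),
                      y = c(10, 13), x = c(10, 12.6))
    ls <- linkPairs(det, D0 = 5, D1 = 10)
    expect_equal(nrow(links(ls)), 1)
    expect_equal(links(ls)$distance, sqrt(9 + 2.6^2))

    ## a same-frame neighbour inside D0 disqualifies the source
    det2 <- rbind(det,
                  data.frame(frame = 1, id = 2, y = 12, x = 10))
    ls2 <- linkPairs(det2, D0 = 5, D1 = 10)
    expect_equal(nrow(links(ls2)), 0)

    ## distance beyond D1 blocks the link
    det3 <- det; det3$y[2] <- 40
    expect_equal(nrow(links(linkPairs(det3, D0 = 5, D1 = 10))), 0)

    ## single frame: empty set, not an error
    expect_equal(nrow(links(linkPairs(det[1, ], 5, 10))), 0)
    expect_error(linkPairs(det, D0 = -1, D1 = 5), "positive")
})

test_that("linking equals the brute-force pseudocode oracle", {
    for (seed in 1:100) {
        n <- sample(5:60, 1)
        det <- randomFramePair(n, seed = seed, spread = 60)
        D0 <- runif(1, 2, 10); D1 <- runif(1, 3, 15)
        got <- links(linkPairs(det, D0, D1))
        want <- bruteForceLinks(det, D0, D1)
        got <- got[order(got$frame, got$src), ]
        rownames(got) <- rownames(want) <- NULL
        expect_equal(got, want)
    }
})

test_that("links are injective in both roles", {
    for (seed in 101:110) {
        det <- randomFramePair(300, seed = seed, spread = 150)
        l <- links(linkPairs(det, D0 = 4, D1 = 12))
        if (!nrow(l)) next
        expect_false(any(duplicated(l[, c("frame", "src")])))
        expect_false(any(duplicated(l[, c("frame", "dst")])))
        expect_true(all(l$distance < 12))
    }
})

test_that("transition matrix implements row-normalized counting", {
    lk <- data.frame(frame = c(1, 1, 1, 1), src = 1:4, dst = 1:4,
                     distance = 1)
    labels <- c("1:1" = 1, "1:2" = 1, "1:3" = 1, "1:4" = 1,
                "2:1" = 1, "2:2" = 1, "2:3" = 1, "2:4" = 2)
    ls <- new("LinkageSet", links = lk, D0 = 5, D1 = 10)
    tm <- transitionMatrix(ls, labels)
    expect_equal(transitionProbs(tm)["1", "2"], 0.25)
    expect_equal(transitionProbs(tm)["1", "1"], 0.75)
    expect_equal(sum(transitionCounts(tm)), 4)

    ## identity dynamics give the identity matrix
    labI <- c("1:1" = 1, "1:2" = 2, "2:1" = 1, "2:2" = 2)
    lsI <- new("LinkageSet",
               links = data.frame(frame = c(1, 1), src = 1:2, dst = 1:2,
                                  distance = 0.5), D0 = 5, D1 = 10)
    tmI <- transitionMatrix(lsI, labI)
    expect_equal(unname(transitionProbs(tmI)), diag(2))

    ## unlabeled links are excluded with a warning
    expect_warning(transitionMatrix(ls, labels[-1]), "unlabeled")
})

test_that("planted Markov dynamics are recovered from a simulated movie", {
    P <- rbind(c(0.70, 0.20, 0.10),
               c(0.15, 0.70, 0.15),
               c(0.10, 0.30, 0.60))
    specs <- list(cellPhenotype(1, 150, step_sd = 1.5),
                  cellPhenotype(2, 250, step_sd = 1.5),
                  cellPhenotype(3, 380, step_sd = 1.5))
    scene <- sceneSpec(frameShape = c(900L, 900L), nCells = 60,
                       exclusionRadius = 40, margin = 30)
    sim <- simulateMovie(scene, markovModel(P), specs, T = 120,
                         seed = 51, render = FALSE)
    det <- data.frame(frame = sim$tracks$frame, id = sim$tracks$cell_id,
                      y = sim$tracks$y, x = sim$tracks$x)
    ls <- linkPairs(det, D0 = 12, D1 = 12)
    expect_gt(nrow(links(ls)), 5000)
    labels <- stats::setNames(sim$tracks$state,
                              paste0(sim$tracks$frame, ":",
                                     sim$tracks$cell_id))
    tm <- transitionMatrix(ls, labels)
    expect_lt(max(abs(transitionProbs(tm) - P)), 0.05)
    expect_equal(unname(rowSums(transitionProbs(tm))), rep(1, 3))

    ## reversed movie: probabilities match the transpose-count
    ## normalization of the forward counts. The agreement is approximate,
    ## not exact: the isolation test and the nearest-neighbour argmin are
    ## evaluated from the source side, so a handful of links near the
    ## D0/D1 boundaries differ between the two time directions.
    detR <- det; detR$frame <- max(det$frame) + 1 - det$frame
    lsR <- linkPairs(detR, D0 = 12, D1 = 12)
    labelsR <- stats::setNames(sim$tracks$state,
                               paste0(max(det$frame) + 1 - sim$tracks$frame,
                                      ":", sim$tracks$cell_id))
    tmR <- transitionMatrix(lsR, labelsR)
    fwd <- t(transitionCounts(tm))
    expect_lt(max(abs(transitionCounts(tmR) - fwd)) /
              mean(transitionCounts(tmR)), 0.02)
    expect_lt(max(abs(transitionProbs(tmR) - fwd / rowSums(fwd))), 0.01)
})

test_that("velocities convert displacement to physical speed", {
    lk <- data.frame(frame = 1, src = 1, dst = 1, distance = 6)
    ls <- new("LinkageSet", links = lk, D0 = 5, D1 = 10)
    ## 6 um over 3 minutes -> 2 um/min (umPerPx = 1 means px are um here)
    v <- velocities(ls, minutesPerFrame = 3)
    expect_equal(v$speeds$speed, 2)
    expect_error(velocities(ls, 0), "positive")

    ## planted 1:3 step-scale ratio is recovered from links
    specs <- list(cellPhenotype(1, 150, ecc_mean = 0.1, step_sd = 1),
                  cellPhenotype(2, 150, ecc_mean = 0.7, step_sd = 3))
    scene <- sceneSpec(frameShape = c(700L, 700L), nCells = 40,
                       exclusionRadius = 45, margin = 30)
    sim <- simulateMovie(scene, markovModel(diag(2)), specs, T = 60,
                         seed = 61, render = FALSE)
    det <- data.frame(frame = sim$tracks$frame, id = sim$tracks$cell_id,
                      y = sim$tracks$y, x = sim$tracks$x)
    ls2 <- linkPairs(det, D0 = 15, D1 = 15)
    labels <- stats::setNames(sim$tracks$state,
                              paste0(sim$tracks$frame, ":",
                                     sim$tracks$cell_id))
    v2 <- velocities(ls2, minutesPerFrame = 1, labels = labels)
    sp <- v2$byCluster$speed
    expect_lt(abs(sp[2] / sp[1] - 3), 0.3)

    ## stationary cells move only by rounding noise
    spec0 <- list(cellPhenotype(1, 150, step_sd = 0))
    sim0 <- simulateMovie(sceneSpec(frameShape = c(200L, 200L),
                                    nCells = 5, exclusionRadius = 40),
                          markovModel(matrix(1)), spec0, T = 10,
                          seed = 71, render = FALSE)
    det0 <- data.frame(frame = sim0$tracks$frame,
                       id = sim0$tracks$cell_id,
                       y = sim0$tracks$y, x = sim0$tracks$x)
    v0 <- velocities(linkPairs(det0, 10, 5), 1)
    expect_true(all(v0$speeds$speed < 0.1))
})

test_that("UMAP vector field averages displacements and conserves flow", {
    set.seed(14)
    n <- 200
    um <- rbind(cbind(runif(n, 0, 1), runif(n, 0, 1)),
                cbind(runif(n, 0, 1) + 4, runif(n, 0, 1)))
    rownames(um) <- c(paste0("1:", 1:n), paste0("2:", 1:n))
    lk <- data.frame(frame = 1, src = 1:n, dst = 1:n, distance = 1)
    ls <- new("LinkageSet", links = lk, D0 = 5, D1 = 10)
    vf <- transitionVectorField(ls, um, gridSize = 5)
    ## planted flow points from region A toward region B (positive dx)
    expect_gt(mean(vf$dx > 0), 0.8)
    ## count-weighted vector sum equals the total displacement
    tot <- colSums(um[paste0("2:", 1:n), ] - um[paste0("1:", 1:n), ])
    expect_equal(c(sum(vf$dx * vf$n), sum(vf$dy * vf$n)), unname(tot))

    ## identity dynamics: all vectors vanish
    um2 <- um; um2[paste0("2:", 1:n), ] <- um[paste0("1:", 1:n), ]
    vf0 <- transitionVectorField(ls, um2, gridSize = 4)
    expect_true(all(abs(vf0$dx) < 1e-12 & abs(vf0$dy) < 1e-12))
})

test_that("population dynamics yield normalized fractions and chi-square", {
    st <- data.frame(frame = rep(1:10, each = 40),
                     cluster = rep(rep(0:1, each = 20), 10),
                     condition = rep(rep(c("ctrl", "drug"), 20), 10))
    pd <- populationDynamics(st)
    byCF <- split(pd$fractions$fraction,
                  paste(pd$fractions$condition, pd$fractions$frame))
    expect_true(all(abs(vapply(byCF, sum, numeric(1)) - 1) < 1e-12))
    ## identical distributions: statistic near zero
    expect_lt(pd$test$statistic, 1e-10)
    expect_gt(pd$test$p.value, 0.99)

    ## hand-computed 2x2 chi-square without continuity correction
    st2 <- data.frame(
        frame = 1,
        cluster = rep(c(0, 1, 0, 1), times = c(30, 10, 10, 30)),
        condition = rep(c("a", "b"), each = 40))
    pd2 <- populationDynamics(st2, endpointWindow = 1)
    tab <- table(st2$condition, st2$cluster)
    expect_equal(pd2$test$statistic, bruteForceChisq(tab))
    expect_equal(pd2$test$df, 1)

    ## single condition: fractions only
    pd1 <- populationDynamics(st[st$condition == "ctrl", ])
    expect_null(pd1$test)
})
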