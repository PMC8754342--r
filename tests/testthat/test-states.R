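test_that("Louvain clustering separates well-separated blobs", {
    set.seed(3)
    Z <- rbind(matrix(rnorm(100 * 16), 100),
               matrix(rnorm(100 * 16, 20 / 4), 100))  # 20 sd separation
    lab <- clusterLatents(Z, seed = 1)
    expect_equal(length(unique(lab)), 2)
    expect_equal(min(lab), 0L)
    truth <- rep(0:1, each = 100)
    expect_true(mclust::adjustedRandIndex(lab, truth) == 1)
    ## determinism and degenerate input
    expect_identical(lab, clusterLatents(Z, seed = 1))
    same <- matrix(1, 30, 4)
    expect_equal(length(unique(clusterLatents(same, knn_k = 5,
                                              seed = 1))), 1)
    expect_error(clusterLatents(Z[1:10, ], knn_k = 15), "smaller")
    ## merge map can only reduce the label count
    merged <- clusterLatents(Z, seed = 1, mergeMap = c("0" = 0, "1" = 0))
    expect_lte(length(unique(merged)), length(unique(lab)))
})

test_that("UMAP embedding is finite, deterministic and separates blobs", {
    set.seed(4)
    Z <- rbind(matrix(rnorm(80 * 10), 80),
               matrix(rnorm(80 * 10, 6), 80))
    e1 <- embedUMAP(Z, seed = 5)
    expect_equal(dim(e1), c(160L, 2L))
    expect_true(all(is.finite(e1)))
    expect_identical(e1, embedUMAP(Z, seed = 5))
    c1 <- colMeans(e1[1:80, ]); c2 <- colMeans(e1[81:160, ])
    spread <- mean(c(sqrt(rowSums(sweep(e1[1:80, ], 2, c1)^2)),
                     sqrt(rowSums(sweep(e1[81:160, ], 2, c2)^2))))
    expect_gt(sqrt(sum((c1 - c2)^2)), 3 * spread)
    expect_error(embedUMAP(Z[1:5, ]), "n_neighbors")
})

test_that("z-score matrix matches its defining formula", {
    set.seed(6)
    f <- cbind(a = rnorm(90, 1, 0.5), b = rnorm(90))
    lab <- rep(1:3, each = 30)
    zm <- zscoreMatrix(f, lab)
    ## direct formula check per entry
    for (cl in 1:3) for (j in 1:2) {
        expect_equal(zm$Z[as.character(cl), j],
                     (mean(f[lab == cl, j]) - mean(f[, j])) / sd(f[, j]))
    }
    ## hand value: cluster mean 2, dataset mean 1, sd 0.5 -> Z = 2
    g <- matrix(c(rep(2, 10), rep(0.5, 30)))
    glab <- c(rep("hi", 10), rep("lo", 30))
    expect_equal(unname(zscoreMatrix(g, glab)$Z["hi", 1]),
                 (2 - mean(g)) / sd(g))
    ## single cluster: all zeros
    expect_true(all(zscoreMatrix(f, rep(1, 90))$Z == 0))
    ## weighted cluster means reproduce the dataset mean exactly
    w <- as.vector(table(lab)) / length(lab)
    expect_equal(as.vector(w %*% zm$clusterMeans), unname(zm$datasetMean))
    ## relabeling permutes rows identically
    zmP <- zscoreMatrix(f, c("c", "a", "b")[lab])
    expect_equal(unname(zmP$Z[c("c", "a", "b"), ]), unname(zm$Z))
    expect_warning(zscoreMatrix(cbind(f, const = 1), lab), "zero-variance")
})

test_that("feature correlation groups recover planted structure", {
    set.seed(8)
    base <- matrix(rnorm(4000), 1000, 4)
    lat <- cbind(base, base + matrix(rnorm(4000, 0, 0.01), 1000, 4))
    fg <- featureCorrelationGroups(lat, n_groups = 4)
    expect_true(isSymmetric(fg$correlation))
    expect_equal(unname(diag(fg$correlation)), rep(1, 8))
    ## each duplicated pair lands in one group
    gOf <- integer(8)
    for (gi in seq_along(fg$groups)) gOf[fg$groups[[gi]]] <- gi
    for (j in 1:4) expect_equal(gOf[j], gOf[j + 4])
    ## independent features: off-diagonal correlations stay small
    ind <- matrix(rnorm(10000 * 5), 10000, 5)
    ci <- featureCorrelationGroups(ind, n_groups = 2)$correlation
    expect_lt(max(abs(ci[upper.tri(ci)])), 0.05)
    expect_warning(featureCorrelationGroups(cbind(base, 1), 2), "constant")
})

test_that("homogeneity score matches exhaustive enumeration", {
    set.seed(9)
    ## 50 random small instances against the brute-force oracle
    for (rep in 1:50) {
        n <- sample(6:30, 1)
        d <- sample(2:5, 1)
        Z <- matrix(rnorm(n * d), n)
        types <- sample(letters[1:3], n, replace = TRUE)
        if (length(unique(types)) < 2) next
        N <- sample(seq_len(min(5, n - 1)), 1)
        got <- homogeneityScore(Z, types, N)$perType
        want <- bruteForceHomogeneity(Z, types, N)
        expect_equal(got, want[names(got)])
    }
    ## two far-separated blobs: perfect homogeneity
    Z2 <- rbind(matrix(rnorm(40 * 3), 40), matrix(rnorm(40 * 3, 100), 40))
    h2 <- homogeneityScore(Z2, rep(c("a", "b"), each = 40), N = 10)
    expect_equal(unname(h2$perType), c(1, 1))
    ## random labels among 4 types: mean H near 1/4
    Zr <- matrix(rnorm(2000 * 8), 2000)
    tr <- sample(1:4, 2000, replace = TRUE)
    hr <- homogeneityScore(Zr, tr, N = 20)
    expect_lt(abs(hr$mean - 0.25), 0.03)
    expect_error(homogeneityScore(Zr, tr, N = 2000), "smaller")
})

test_that("homogeneity is invariant under latent-space isometries", {
    set.seed(10)
    Z <- matrix(rnorm(60 * 4), 60)
    types <- rep(1:3, each = 20)
    h0 <- homogeneityScore(Z, types, N = 7)$perType
    ## random rotation + translation
    M <- qr.Q(qr(matrix(rnorm(16), 4)))
    Zr <- sweep(Z %*% M, 2, c(5, -3, 2, 0.5), "+")
    expect_equal(homogeneityScore(Zr, types, N = 7)$perType, h0)
})

test_that("weight sweep returns the grid argmax", {
    set.seed(11)
    ## synthetic latents where only the shape branch is informative; the
    ## class offset is moderate so the homogeneity curve is strictly shaped
    ## rather than saturating at 1 for every weight
    zs <- rbind(matrix(rnorm(50 * 4), 50),
                matrix(rnorm(50 * 4, 1.2), 50))
    zt <- matrix(rnorm(100 * 4), 100)
    types <- rep(1:2, each = 50)
    sw <- weightSweep(zs, zt, types, grid = seq(0, 1, 0.1), N = 10)
    expect_gte(sw$best, 0.8)
    ## mirrored: only texture informative
    sw2 <- weightSweep(zt, zs, types, grid = seq(0, 1, 0.1), N = 10)
    expect_lte(sw2$best, 0.2)
    ## singleton grid returns that value
    expect_equal(weightSweep(zs, zt, types, grid = 0.4, N = 10)$best, 0.4)
    expect_error(weightSweep(zs, zt, types, grid = numeric(0)), "empty")
})

test_that("morphometrics match closed forms on analytic shapes", {
    ## disc
    d <- sqrt(outer((1:61 - 31)^2, (1:61 - 31)^2, "+"))
    disc <- (d < 20) * 1
    m <- morphometrics(disc)
    expect_lt(m$eccentricity, 0.05)
    expect_equal(m$area, sum(disc))
    ## ellipse with a = 2b: eccentricity sqrt(3)/2
    y <- matrix(1:81 - 41, 81, 81); x <- t(y)
    ell <- ((x / 30)^2 + (y / 15)^2 <= 1) * 1
    expect_lt(abs(morphometrics(ell)$eccentricity - sqrt(3) / 2), 0.02)
    ## constant crop: zero edge strength
    expect_equal(morphometrics(disc, matrix(0.5, 61, 61))$edge_strength, 0)
    ## calibration scales area quadratically
    expect_equal(morphometrics(disc, umPerPx = 2)$area, 4 * sum(disc))
    expect_error(morphometrics(matrix(0, 5, 5)), "empty")
})

test_that("marker quantification subtracts background and recovers gates", {
    lab <- matrix(0L, 60, 60)
    lab[10:20, 10:20] <- 1L; lab[40:50, 40:50] <- 2L
    det <- list(table = data.frame(frame = 1, id = 1:2,
                                   y = c(15, 45), x = c(15, 45),
                                   area = c(121, 121)),
                labels = lab)
    ch <- matrix(0, 60, 60)
    ch[lab == 1L] <- 100; ch[lab == 2L] <- 200
    q <- quantifyMarkers(det, list(CD34 = ch))
    expect_equal(q$CD34, c(100, 200))
    ## constant background is removed
    q2 <- quantifyMarkers(det, list(CD34 = ch + 7))
    expect_equal(q2$CD34, c(100, 200))

    ## bimodal gating on planted fractions
    set.seed(12)
    n <- 2000
    stem <- runif(n) < 0.3
    cd34 <- ifelse(stem, rnorm(n, 5), rnorm(n, 1, 0.5))
    cd38 <- ifelse(stem, rnorm(n, 1, 0.5), rnorm(n, 5))
    gate <- cd34 > 3 & cd38 < 3
    expect_lt(abs(mean(gate) - 0.3), 0.05)

    ## nearest-frame assignment with tolerance
    expect_equal(nearestMarkerFrame(62, c(0, 60, 120), 30), 2)
    expect_true(is.na(nearestMarkerFrame(200, c(0, 60), 30)))
})

test_that("cluster composition is normalized, balanced and truthful", {
    set.seed(13)
    labels <- rep(c(0, 1, 2), times = c(40, 40, 20))
    types <- c(sample(c("a", "b"), 40, TRUE, prob = c(0.9, 0.1)),
               sample(c("a", "b"), 40, TRUE, prob = c(0.1, 0.9)),
               sample(c("a", "b"), 20, TRUE))
    comp <- clusterComposition(labels, types)
    expect_equal(unname(rowSums(comp)), rep(1, 3), tolerance = 1e-12)
    expect_gt(comp["0", "a"], 0.7)
    expect_gt(comp["1", "b"], 0.7)
    ## single type: every cluster is 100% that type
    one <- clusterComposition(labels, rep("x", 100))
    expect_true(all(one[, "x"] == 1))
    ## balanced mode subsamples equal counts per type
    compB <- clusterComposition(labels, types, balanced = TRUE, seed = 2)
    expect_equal(unname(rowSums(compB)), rep(1, 3), tolerance = 1e-12)
    expect_error(clusterComposition(labels, types, balanced = TRUE,
                                    nSample = 1000), "at least")
})
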