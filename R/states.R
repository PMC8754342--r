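#' Louvain clustering of fused latent vectors
#'
#' Builds an unweighted k-nearest-neighbour graph (Euclidean) over cells
#' and partitions it with Louvain modularity optimization. Raw communities
#' can be relabeled into named clusters through an explicit merge map,
#' mirroring manual post-merging of adjacent communities; merging never
#' increases the number of labels.
#'
#' @param latents numeric matrix `n x d` of fused latent vectors
#' @param knn_k neighbours per cell in the graph
#' @param resolution Louvain resolution parameter. The default is below 1
#'   because latent manifolds are continuous: plain modularity tends to
#'   fragment one dense, connected group of cells into several communities,
#'   while lowering the resolution only ever merges communities that are
#'   actually connected in the k-NN graph -- well-separated groups can
#'   never be merged by it
#' @param seed integer seed (Louvain is stochastic)
#' @param mergeMap optional named map `raw label -> merged label`, e.g.
#'   `c("0" = 0, "1" = 0, "2" = 1)`
#' @return integer cluster labels, contiguous from 0
#' @export
clusterLatents <- function(latents, knn_k = 15L, resolution = 0.1,
                           seed = 1, mergeMap = NULL) {
    latents <- as.matrix(latents)
    n <- nrow(latents)
    if (knn_k >= n) stop("knn_k must be smaller than the number of points")
    D <- .crossDist(latents, latents)
    diag(D) <- Inf
    edges <- integer(0)
    for (i in seq_len(n)) {
        nb <- order(D[i, ])[seq_len(knn_k)]
        edges <- c(edges, rbind(i, nb))
    }
    g <- igraph::simplify(igraph::make_graph(edges, n = n,
                                             directed = FALSE))
    comm <- .withSeed(seed,
        igraph::cluster_louvain(g, resolution = resolution))
    raw <- igraph::membership(comm) - 1L
    labels <- as.integer(raw)
    if (!is.null(mergeMap)) {
        mapped <- mergeMap[as.character(labels)]
        if (any(is.na(mapped)))
            stop("mergeMap is missing raw labels: ",
                 paste(unique(labels[is.na(mapped)]), collapse = ", "))
        labels <- as.integer(mapped)
    }
    as.integer(factor(labels, levels = sort(unique(labels)))) - 1L
}

#' 2-d UMAP embedding of latent vectors
#'
#' @param latents numeric matrix `n x d`
#' @param n_neighbors,min_dist UMAP parameters
#' @param seed integer seed; identical seeds give identical layouts
#' @return numeric matrix `n x 2`
#' @export
embedUMAP <- function(latents, n_neighbors = 15L, min_dist = 0.1,
                      seed = 1) {
    latents <- as.matrix(latents)
    if (nrow(latents) < n_neighbors)
        stop("need at least n_neighbors points")
    .withSeed(seed,
        uwot::umap(latents, n_neighbors = n_neighbors,
                   min_dist = min_dist, n_threads = 1, n_sgd_threads = 1))
}

#' Per-cluster feature z-scores with hierarchical ordering
#'
#' For feature `f` and cluster `C`,
#' \code{Z[f, C] = (mean_C(f) - mean(f)) / sd(f)}: the fold difference, in
#' dataset standard deviations, between the cluster mean and the dataset
#' mean. Rows (clusters) and columns (features) are ordered by average-
#' linkage hierarchical clustering for clustergram display.
#'
#' @param features numeric matrix `n x f` (typically latent vectors)
#' @param labels per-cell cluster labels
#' @return list with `Z` (clusters x features), `rowOrder`, `colOrder`,
#'   `clusterMeans`, `datasetMean`, `datasetSd`
#' @export
zscoreMatrix <- function(features, labels) {
    features <- as.matrix(features)
    labels <- as.vector(labels)
    stopifnot(nrow(features) == length(labels))
    mu <- colMeans(features)
    sd_f <- apply(features, 2L, stats::sd)
    zero <- sd_f == 0
    if (any(zero)) {
        warning(sum(zero), " zero-variance feature(s); z-scores set to 0")
        sd_f[zero] <- 1
    }
    lv <- sort(unique(labels))
    cm <- matrix(0, length(lv), ncol(features),
                 dimnames = list(lv, colnames(features)))
    for (i in seq_along(lv))
        cm[i, ] <- colMeans(features[labels == lv[i], , drop = FALSE])
    Z <- sweep(sweep(cm, 2L, mu), 2L, sd_f, "/")
    Z[, zero] <- 0
    rowOrder <- if (nrow(Z) > 2L)
        stats::hclust(stats::dist(Z), "average")$order else seq_len(nrow(Z))
    colOrder <- if (ncol(Z) > 2L)
        stats::hclust(stats::dist(t(Z)), "average")$order
        else seq_len(ncol(Z))
    list(Z = Z, rowOrder = rowOrder, colOrder = colOrder,
         clusterMeans = cm, datasetMean = mu, datasetSd = sd_f)
}

#' Correlated groups of latent features
#'
#' Latent texture dimensions tend to act in concert: individual dimensions
#' are hard to read, but groups of strongly correlated dimensions decode
#' into coherent image features. This computes the feature-by-feature
#' Pearson correlation across cells and cuts its average-linkage dendrogram
#' into `n_groups` groups.
#'
#' @param latents numeric matrix `n x f`
#' @param n_groups number of feature groups to cut
#' @return list with `correlation` (f x f) and `groups` (list of feature
#'   index vectors); constant features are excluded with a warning
#' @export
featureCorrelationGroups <- function(latents, n_groups = 8L) {
    latents <- as.matrix(latents)
    if (ncol(latents) < 2L || nrow(latents) < 3L)
        stop("need at least 2 features and 3 samples")
    sds <- apply(latents, 2L, stats::sd)
    keep <- which(sds > 0)
    if (length(keep) < ncol(latents))
        warning(ncol(latents) - length(keep),
                " constant feature(s) excluded")
    cc <- stats::cor(latents[, keep, drop = FALSE])
    hc <- stats::hclust(stats::as.dist(1 - cc), "average")
    cut <- stats::cutree(hc, k = min(n_groups, length(keep)))
    groups <- lapply(sort(unique(cut)), function(g) keep[cut == g])
    list(correlation = cc, groups = groups, features = keep)
}

#' Neighbour-similarity (homogeneity) score
#'
#' For each cell, the fraction of its `N` nearest neighbours in latent
#' space (Euclidean, excluding itself) that share its type; the per-type
#' score `H_C` is the mean of this fraction over cells of type `C`. A score
#' of 1 means the type is perfectly separated; under random labels the
#' expected score is the type's frequency. Ties at the `N`-th neighbour are
#' broken by point index.
#'
#' @param latents numeric matrix `n x d`
#' @param types per-cell type labels
#' @param N neighbour count (< n)
#' @return list with `perType` (named numeric), `mean` and `N`
#' @export
homogeneityScore <- function(latents, types, N = 20L) {
    latents <- as.matrix(latents)
    types <- as.vector(types)
    n <- nrow(latents)
    stopifnot(length(types) == n)
    if (N >= n) stop("N must be smaller than the number of cells")
    D <- .crossDist(latents, latents)
    diag(D) <- Inf
    frac <- numeric(n)
    for (i in seq_len(n)) {
        nb <- order(D[i, ])[seq_len(N)]   # stable: ties broken by index
        frac[i] <- mean(types[nb] == types[i])
    }
    perType <- vapply(split(frac, types), mean, numeric(1))
    list(perType = perType, mean = mean(perType), N = as.integer(N))
}

#' Sweep the shape/texture fusion weight
#'
#' Recomputes the fused latents for every weight in `grid` and scores the
#' mean type homogeneity; the maximizing weight is reported. Types that
#' differ only in shape push the optimum toward `w = 1`; types that differ
#' only in texture push it toward `w = 0`.
#'
#' @param zShape,zTexture per-branch latent matrices
#' @param types per-cell type labels
#' @param grid weights to evaluate, all in `[0, 1]`
#' @param N neighbour count for [homogeneityScore()]
#' @return list with `sweep` (data.frame `w`, `H`) and `best` (argmax `w`)
#' @export
weightSweep <- function(zShape, zTexture, types, grid = seq(0, 1, 0.1),
                        N = 20L) {
    if (length(grid) == 0) stop("empty weight grid")
    if (any(grid < 0 | grid > 1)) stop("grid values must lie in [0, 1]")
    H <- vapply(grid, function(w) {
        fused <- combineLatents(zShape, zTexture, w)
        homogeneityScore(fused, types, N)$mean
    }, numeric(1))
    list(sweep = data.frame(w = grid, H = H), best = grid[which.max(H)])
}

#' Mask and intensity morphometrics for one cell
#'
#' Area is the mask pixel count (scaled by `umPerPx^2` if calibrated),
#' eccentricity comes from the second central moments of the mask, and edge
#' strength is the maximum Sobel gradient magnitude of the brightfield
#' signal within the mask dilated by 2 px (so the rim is included).
#'
#' @param mask binary mask matrix (non-empty)
#' @param brightfieldCrop brightfield matrix, same shape; `NULL` skips edge
#'   strength
#' @param umPerPx spatial calibration; 1 reports pixel units
#' @return list with `area`, `eccentricity`, `edge_strength`
#' @export
morphometrics <- function(mask, brightfieldCrop = NULL, umPerPx = 1) {
    if (!any(mask > 0)) stop("empty mask")
    mom <- .maskMoments(mask)
    area <- sum(mask > 0) * umPerPx^2
    edge <- NA_real_
    if (!is.null(brightfieldCrop)) {
        gx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
        fx <- as.matrix(EBImage::filter2(EBImage::Image(brightfieldCrop),
                                         gx))
        fy <- as.matrix(EBImage::filter2(EBImage::Image(brightfieldCrop),
                                         t(gx)))
        gmag <- sqrt(fx^2 + fy^2)
        dil <- EBImage::dilate(mask > 0, EBImage::makeBrush(5, "disc"))
        edge <- max(gmag[dil > 0])
    }
    list(area = area, eccentricity = mom$eccentricity, edge_strength = edge)
}

#' Background-subtracted marker intensities per detection
#'
#' Mean marker intensity inside each detection mask, minus the frame
#' background estimated as the median intensity over non-cell pixels.
#' Values near background can legitimately be negative.
#'
#' @param detections a [segmentFrame()] result for the matching timepoint
#' @param markerFrames named list of marker-channel matrices (e.g.
#'   `list(CD34 = ..., CD38 = ...)`)
#' @return data.frame with `id` and one column per marker channel
#' @export
quantifyMarkers <- function(detections, markerFrames) {
    tab <- detections$table
    lab <- detections$labels
    out <- data.frame(id = tab$id)
    for (ch in names(markerFrames)) {
        mf <- markerFrames[[ch]]
        stopifnot(identical(dim(mf), dim(lab)))
        bg <- stats::median(mf[lab == 0L])
        out[[ch]] <- vapply(tab$id, function(id)
            mean(mf[lab == id]) - bg, numeric(1))
    }
    out
}

#' Match detections to the nearest marker timepoint
#'
#' @param frameTime acquisition time of the brightfield frame (minutes)
#' @param markerTimes acquisition times of available marker frames
#' @param tolerance maximum |gap| accepted, typically half the marker
#'   interval; returns `NA` when no marker frame is close enough
#' @return index into `markerTimes`, or `NA`
#' @export
nearestMarkerFrame <- function(frameTime, markerTimes, tolerance) {
    gaps <- abs(markerTimes - frameTime)
    i <- which.min(gaps)
    if (gaps[i] > tolerance) NA_integer_ else i
}

#' Fractional composition of each cluster
#'
#' @param labels per-cell cluster labels
#' @param types per-cell type (or condition) labels
#' @param balanced subsample an equal number of cells per type first
#' @param nSample cells per type in balanced mode; defaults to the
#'   smallest type count
#' @param seed seed for the balanced subsample
#' @return matrix clusters x types; each row sums to 1 (empty clusters get
#'   a zero row with a warning)
#' @export
clusterComposition <- function(labels, types, balanced = FALSE,
                               nSample = NULL, seed = 1) {
    labels <- as.vector(labels); types <- as.vector(types)
    stopifnot(length(labels) == length(types))
    idx <- seq_along(labels)
    if (balanced) {
        counts <- table(types)
        if (is.null(nSample)) nSample <- min(counts)
        if (any(counts < nSample))
            stop("every type needs at least nSample cells in balanced mode")
        idx <- .withSeed(seed, unlist(lapply(split(idx, types),
            function(ii) ii[sample.int(length(ii), nSample)])))
    }
    tab <- table(factor(labels[idx], levels = sort(unique(labels))),
                 types[idx])
    rs <- rowSums(tab)
    if (any(rs == 0))
        warning("empty cluster(s) after sampling: ",
                paste(rownames(tab)[rs == 0], collapse = ", "))
    frac <- sweep(unclass(tab), 1L, pmax(rs, 1), "/")
    frac
}
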