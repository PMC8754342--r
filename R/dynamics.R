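#' Validated frame-to-frame cell pairing
#'
#' Instead of assembling full trajectories, state dynamics are inferred from
#' stringent one-step links. A cell at frame `t` qualifies as a link source
#' only if it is isolated: every other same-frame cell is farther than `D0`.
#' A qualifying source links to its nearest cell in frame `t + 1` provided
#' that distance is below `D1`. If two sources select the same target, the
#' closer pair is kept and the other dropped, preserving injectivity.
#'
#' @param detections data.frame with columns `frame`, `id`, `y`, `x`
#'   (centroids in px); linking runs over consecutive frame values
#' @param D0 isolation radius (px); sources with a same-frame neighbour at
#'   distance `<= D0` are excluded
#' @param D1 maximum travel distance (px)
#' @return a \linkS4class{LinkageSet}; a single frame yields an empty set
#' @export
linkPairs <- function(detections, D0, D1) {
    if (D0 <= 0 || D1 <= 0) stop("D0 and D1 must be positive")
    need <- c("frame", "id", "y", "x")
    if (!all(need %in% colnames(detections)))
        stop("detections must have columns frame, id, y, x")
    if (!all(is.finite(detections$x)) || !all(is.finite(detections$y)))
        stop("centroids must be finite")
    frames <- sort(unique(detections$frame))
    out <- list()
    for (fi in seq_len(length(frames) - 1L)) {
        t0 <- frames[fi]; t1 <- frames[fi + 1L]
        if (t1 != t0 + 1L) next   # only adjacent frames are linked
        A <- detections[detections$frame == t0, , drop = FALSE]
        B <- detections[detections$frame == t1, , drop = FALSE]
        if (!nrow(A) || !nrow(B)) next
        PA <- cbind(A$y, A$x); PB <- cbind(B$y, B$x)
        DA <- .crossDist(PA, PA); diag(DA) <- Inf
        isolated <- if (nrow(A) == 1L) TRUE else
            apply(DA, 1L, min) > D0
        DAB <- .crossDist(PA, PB)
        cand <- data.frame(src = integer(), dst = integer(),
                           distance = numeric())
        for (i in which(isolated)) {
            j <- which.min(DAB[i, ])
            if (DAB[i, j] < D1)
                cand <- rbind(cand, data.frame(
                    src = A$id[i], dst = B$id[j],
                    distance = DAB[i, j]))
        }
        if (nrow(cand)) {
            ## collision rule: keep the closer source per contested target
            cand <- cand[order(cand$distance), , drop = FALSE]
            cand <- cand[!duplicated(cand$dst), , drop = FALSE]
            out[[length(out) + 1L]] <- data.frame(
                frame = t0, src = cand$src, dst = cand$dst,
                distance = cand$distance)
        }
    }
    links <- if (length(out)) do.call(rbind, out) else
        data.frame(frame = integer(), src = integer(), dst = integer(),
                   distance = numeric())
    rownames(links) <- NULL
    new("LinkageSet", links = links, D0 = D0, D1 = D1)
}

#' Estimate the cluster-to-cluster transition matrix
#'
#' Counts transitions `f_ij` over all validated links and row-normalizes:
#' `P[i, j] = f_ij / sum_k f_ik`. Rows with no observed transitions are
#' undefined and reported as `NA`.
#'
#' @param linkages a \linkS4class{LinkageSet}
#' @param labels named vector (or function of id) mapping detection key
#'   `"frame:id"` for the source and `"frame+1:id"` for the target to a
#'   cluster label; see Details
#' @param minutesPerFrame frame interval recorded in the result
#'
#' @details `labels` must be a named integer/character vector keyed by
#' `"<frame>:<id>"`, giving the cluster of each detection. Links whose
#' source or target has no label are excluded with a warning.
#'
#' @return a \linkS4class{TransitionMatrix}
#' @export
transitionMatrix <- function(linkages, labels, minutesPerFrame = NA_real_) {
    l <- links(linkages)
    srcKey <- paste0(l$frame, ":", l$src)
    dstKey <- paste0(l$frame + 1L, ":", l$dst)
    si <- labels[srcKey]; di <- labels[dstKey]
    ok <- !is.na(si) & !is.na(di)
    if (any(!ok))
        warning(sum(!ok), " link(s) with unlabeled endpoints excluded")
    lv <- sort(unique(c(si[ok], di[ok])))
    k <- length(lv)
    counts <- matrix(0L, k, k, dimnames = list(lv, lv))
    for (i in which(ok))
        counts[as.character(si[i]), as.character(di[i])] <-
            counts[as.character(si[i]), as.character(di[i])] + 1L
    probs <- counts / pmax(rowSums(counts), 1)
    probs[rowSums(counts) == 0, ] <- NA_real_
    new("TransitionMatrix", probs = probs, counts = counts,
        minutesPerFrame = minutesPerFrame)
}

#' Instantaneous speeds from validated links
#'
#' Speed is the link displacement divided by the frame interval, i.e. the
#' per-frame displacement of a cell. When cluster labels are supplied,
#' speeds are grouped by the source cell's cluster, the summary the
#' velocity-versus-eccentricity comparison is built from.
#'
#' @param linkages a \linkS4class{LinkageSet}
#' @param minutesPerFrame frame interval in minutes (> 0)
#' @param umPerPx spatial calibration; 1 keeps px units
#' @param labels optional named vector keyed by `"<frame>:<id>"` giving the
#'   source cell's cluster
#' @return list with `speeds` (per-link data.frame) and, when labels are
#'   given, `byCluster` (mean speed per cluster)
#' @export
velocities <- function(linkages, minutesPerFrame, umPerPx = 1,
                       labels = NULL) {
    if (minutesPerFrame <= 0) stop("minutesPerFrame must be positive")
    l <- links(linkages)
    sp <- data.frame(frame = l$frame, src = l$src, dst = l$dst,
                     speed = l$distance * umPerPx / minutesPerFrame)
    out <- list(speeds = sp)
    if (!is.null(labels)) {
        cl <- labels[paste0(l$frame, ":", l$src)]
        sp$cluster <- cl
        out$speeds <- sp
        agg <- stats::aggregate(speed ~ cluster, data = sp, FUN = mean)
        out$byCluster <- agg
    }
    out
}

#' Average latent-flow vector field on a UMAP grid
#'
#' Each link contributes the displacement between the UMAP positions of its
#' two endpoints; displacements are averaged inside a regular grid over the
#' embedding, yielding a coarse vector field of state flow (with the mean
#' displacement magnitude per grid cell).
#'
#' @param linkages a \linkS4class{LinkageSet}
#' @param umapCoords matrix `n x 2` with rownames `"<frame>:<id>"` keying
#'   every linked detection
#' @param gridSize number of grid cells per axis
#' @return data.frame `(gx, gy, dx, dy, magnitude, n)`; unoccupied grid
#'   cells are absent
#' @export
transitionVectorField <- function(linkages, umapCoords, gridSize = 10L) {
    l <- links(linkages)
    srcKey <- paste0(l$frame, ":", l$src)
    dstKey <- paste0(l$frame + 1L, ":", l$dst)
    if (!all(c(srcKey, dstKey) %in% rownames(umapCoords)))
        stop("umapCoords must cover every linked detection")
    p0 <- umapCoords[srcKey, , drop = FALSE]
    p1 <- umapCoords[dstKey, , drop = FALSE]
    disp <- p1 - p0
    rx <- range(umapCoords[, 1]); ry <- range(umapCoords[, 2])
    bx <- seq(rx[1], rx[2], length.out = gridSize + 1L)
    by <- seq(ry[1], ry[2], length.out = gridSize + 1L)
    gx <- pmin(findInterval(p0[, 1], bx, rightmost.closed = TRUE), gridSize)
    gy <- pmin(findInterval(p0[, 2], by, rightmost.closed = TRUE), gridSize)
    key <- paste(gx, gy)
    res <- lapply(split(seq_len(nrow(p0)), key), function(ii) {
        data.frame(gx = gx[ii[1L]], gy = gy[ii[1L]],
                   dx = mean(disp[ii, 1]), dy = mean(disp[ii, 2]),
                   magnitude = mean(sqrt(rowSums(
                       disp[ii, , drop = FALSE]^2))),
                   n = length(ii))
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Cluster population dynamics and condition comparison
#'
#' Computes per-cluster population fractions over time for each condition
#' and, when at least two conditions are present, tests the dependence
#' between condition and cluster identity in an endpoint window with a
#' chi-square test of independence (no continuity correction).
#'
#' @param stateTable data.frame with columns `frame`, `cluster` and
#'   optionally `condition`
#' @param endpointWindow fraction of final frames used for the endpoint
#'   comparison
#' @return list with `fractions` (data.frame `condition, frame, cluster,
#'   fraction`; fractions sum to 1 within each condition-frame) and, with
#'   >= 2 conditions, `test` (`statistic`, `df`, `p.value`,
#'   `lowExpected` flag) over the endpoint window
#' @export
populationDynamics <- function(stateTable, endpointWindow = 0.05) {
    stopifnot(all(c("frame", "cluster") %in% colnames(stateTable)))
    if (!"condition" %in% colnames(stateTable))
        stateTable$condition <- "all"
    cl <- sort(unique(stateTable$cluster))
    fr <- lapply(split(stateTable, list(stateTable$condition,
                                        stateTable$frame), drop = TRUE),
        function(d) {
            tab <- table(factor(d$cluster, levels = cl))
            data.frame(condition = d$condition[1L], frame = d$frame[1L],
                       cluster = cl, fraction = as.numeric(tab) / nrow(d))
        })
    fractions <- do.call(rbind, fr)
    rownames(fractions) <- NULL
    out <- list(fractions = fractions)
    conds <- unique(stateTable$condition)
    if (length(conds) >= 2L) {
        fmax <- max(stateTable$frame); fmin <- min(stateTable$frame)
        cutoff <- fmax - endpointWindow * (fmax - fmin)
        endp <- stateTable[stateTable$frame >= cutoff, , drop = FALSE]
        tab <- table(endp$condition, endp$cluster)
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        out$test <- list(statistic = unname(ct$statistic),
                         df = unname(ct$parameter),
                         p.value = ct$p.value,
                         lowExpected = any(ct$expected < 5))
    }
    out
}
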