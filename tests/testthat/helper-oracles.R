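## Independent oracles used to cross-check the implementation. These are
## deliberately naive (exhaustive loops over all pairs) and share no code
## with the package internals they validate.

## Brute-force frame-to-frame linking: literal translation of the rule set.
## For every cell i at frame t: if every other same-frame cell is farther
## than D0, find its nearest frame-(t+1) cell; link if that distance < D1.
## Contested targets keep the closer source.
bruteForceLinks <- function(detections, D0, D1) {
    frames <- sort(unique(detections$frame))
    out <- data.frame(frame = integer(), src = integer(), dst = integer(),
                      distance = numeric())
    for (t in frames) {
        if (!(t + 1) %in% frames) next
        A <- detections[detections$frame == t, ]
        B <- detections[detections$frame == t + 1, ]
        if (!nrow(A) || !nrow(B)) next
        cand <- data.frame(src = integer(), dst = integer(),
                           distance = numeric())
        for (i in seq_len(nrow(A))) {
            isolated <- TRUE
            for (j in seq_len(nrow(A))) {
                if (i == j) next
                dij <- sqrt((A$y[i] - A$y[j])^2 + (A$x[i] - A$x[j])^2)
                if (dij <= D0) { isolated <- FALSE; break }
            }
            if (!isolated) next
            best <- Inf; bestK <- NA
            for (k in seq_len(nrow(B))) {
                dik <- sqrt((A$y[i] - B$y[k])^2 + (A$x[i] - B$x[k])^2)
                if (dik < best) { best <- dik; bestK <- k }
            }
            if (is.finite(best) && best < D1)
                cand <- rbind(cand, data.frame(src = A$id[i],
                                               dst = B$id[bestK],
                                               distance = best))
        }
        if (nrow(cand)) {
            cand <- cand[order(cand$distance), ]
            cand <- cand[!duplicated(cand$dst), ]
            out <- rbind(out, data.frame(frame = t, src = cand$src,
                                         dst = cand$dst,
                                         distance = cand$distance))
        }
    }
    out[order(out$frame, out$src), ]
}

## Exhaustive neighbour-similarity score: all pairwise distances, sorted
## per point with index tie-breaks, fraction of same-type labels among the
## first N.
bruteForceHomogeneity <- function(Z, types, N) {
    n <- nrow(Z)
    frac <- numeric(n)
    for (i in seq_len(n)) {
        d <- numeric(n)
        for (j in seq_len(n))
            d[j] <- sqrt(sum((Z[i, ] - Z[j, ])^2))
        d[i] <- Inf
        nb <- order(d)[seq_len(N)]
        frac[i] <- mean(types[nb] == types[i])
    }
    vapply(split(frac, types), mean, numeric(1))
}

## AUC by exhaustive pair counting: P(score_pos > score_neg) + 0.5 ties.
bruteForceAUC <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
}

## Chi-square statistic summed term by term.
bruteForceChisq <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
}

## Empirical transition matrix by direct counting over state sequences.
countTransitions <- function(states) {
    k <- max(states)
    f <- matrix(0, k, k)
    for (i in seq_len(nrow(states)))
        for (t in seq_len(ncol(states) - 1))
            f[states[i, t], states[i, t + 1]] <-
                f[states[i, t], states[i, t + 1]] + 1
    f / rowSums(f)
}
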