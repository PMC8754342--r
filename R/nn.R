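## Minimal dense-network engine: fully connected layers, leaky-ReLU /
## sigmoid / linear activations, reverse-mode gradients and Adam updates.
## All training randomness goes through R's RNG so runs are reproducible
## from a single seed. Matrices are (batch x features) throughout.

.actApply <- function(a, act) {
    switch(act,
        lrelu = pmax(a, 0.1 * a),
        sigmoid = 1 / (1 + exp(-pmin(pmax(a, -30), 30))),
        linear = a,
        stop("unknown activation: ", act))
}

## gradient of the activation, from pre-activation a and post-activation h
.actGrad <- function(a, h, act) {
    switch(act,
        lrelu = 0.1 + 0.9 * (a > 0),
        sigmoid = h * (1 - h),
        linear = 1,
        stop("unknown activation: ", act))
}

.nnInit <- function(sizes, acts) {
    stopifnot(length(acts) == length(sizes) - 1L)
    layers <- vector("list", length(acts))
    for (l in seq_along(acts)) {
        fanIn <- sizes[l]; fanOut <- sizes[l + 1L]
        layers[[l]] <- list(
            W = matrix(stats::rnorm(fanIn * fanOut, 0, sqrt(2 / fanIn)),
                       fanIn, fanOut),
            b = numeric(fanOut))
    }
    list(layers = layers, acts = acts)
}

.nnForward <- function(net, X) {
    L <- length(net$layers)
    h <- vector("list", L + 1L); a <- vector("list", L)
    h[[1L]] <- X
    for (l in seq_len(L)) {
        a[[l]] <- h[[l]] %*% net$layers[[l]]$W +
            rep(net$layers[[l]]$b, each = nrow(X))
        h[[l + 1L]] <- .actApply(a[[l]], net$acts[l])
    }
    list(h = h, a = a)
}

## dOut: gradient of the loss w.r.t. the network output (post-activation),
## already scaled by any 1/batch factor. Returns per-layer weight gradients
## and the gradient w.r.t. the input.
.nnBackward <- function(net, cache, dOut) {
    L <- length(net$layers)
    grads <- vector("list", L)
    d <- dOut
    for (l in rev(seq_len(L))) {
        da <- d * .actGrad(cache$a[[l]], cache$h[[l + 1L]], net$acts[l])
        grads[[l]] <- list(W = crossprod(cache$h[[l]], da),
                           b = colSums(da))
        d <- tcrossprod(da, net$layers[[l]]$W)
    }
    list(grads = grads, dInput = d)
}

.adamInit <- function(net) {
    list(t = 0L, m = lapply(net$layers, function(l)
             list(W = l$W * 0, b = l$b * 0)),
         v = lapply(net$layers, function(l)
             list(W = l$W * 0, b = l$b * 0)))
}

.adamStep <- function(net, grads, st, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
    st$t <- st$t + 1L
    ## fold the bias corrections into the step size and epsilon so the
    ## per-parameter update is two fused multiply-adds and one divide
    lrT <- lr * sqrt(1 - beta2^st$t) / (1 - beta1^st$t)
    epsT <- eps * sqrt(1 - beta2^st$t)
    for (l in seq_along(net$layers)) {
        for (p in c("W", "b")) {
            g <- grads[[l]][[p]]
            m <- st$m[[l]][[p]] <- beta1 * st$m[[l]][[p]] +
                (1 - beta1) * g
            v <- st$v[[l]][[p]] <- beta2 * st$v[[l]][[p]] +
                (1 - beta2) * g * g
            net$layers[[l]][[p]] <- net$layers[[l]][[p]] -
                lrT * m / (sqrt(v) + epsT)
        }
    }
    list(net = net, state = st)
}

.sampleBatch <- function(n, size) {
    if (n <= size) seq_len(n) else sample.int(n, size)
}

## flatten an s x s x n image array into an n x s^2 matrix (and back)
.flattenImages <- function(images) {
    d <- dim(images)
    t(matrix(images, d[1L] * d[2L], d[3L]))
}

.unflattenImages <- function(X, side) {
    array(t(X), dim = c(side, side, nrow(X)))
}
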