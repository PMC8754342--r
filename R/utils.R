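## Evaluate expr with a temporary RNG state seeded from `seed`, restoring
## the caller's RNG afterwards. Keeps generator determinism local.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(eval.parent(substitute(expr)))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

## derive a stream of child seeds from one parent seed (32-bit safe)
.childSeeds <- function(seed, n) {
    .withSeed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)

## pairwise Euclidean distances between rows of two matrices
.crossDist <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    sqrt(pmax(d2, 0))
}

.stopIfNot2D <- function(x, what = "image") {
    if (!is.matrix(x)) stop(what, " must be a 2-d matrix", call. = FALSE)
    if (!all(is.finite(x))) stop(what, " contains non-finite values",
                                 call. = FALSE)
    invisible(x)
}
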