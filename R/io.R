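#' Read a multi-page TIFF movie into an array
#'
#' @param path TIFF file path
#' @return numeric array `h x w x T` with values in `[0, 1]`
#' @export
readMovieTIFF <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
        if (length(dim(p)) == 3L) p <- p[, , 1L]   # drop extra channels
        p
    })
    array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
}

#' Write an image stack as a multi-page TIFF
#'
#' @param frames array `h x w x T` (values clipped to `[0, 1]`)
#' @param path output file
#' @param bitsPerSample 8 or 16
#' @export
writeMovieTIFF <- function(frames, path, bitsPerSample = 16L) {
    stopifnot(length(dim(frames)) == 3L)
    pages <- lapply(seq_len(dim(frames)[3L]),
                    function(t) .clip01(frames[, , t]))
    tiff::writeTIFF(pages, path, bits.per.sample = bitsPerSample)
    invisible(path)
}

#' Write ground-truth or inferred tracks to CSV
#'
#' @param tracks data.frame with columns `cell_id, frame, y, x` and
#'   optionally `state`
#' @param path output CSV
#' @export
writeTracksCSV <- function(tracks, path) {
    utils::write.csv(tracks, path, row.names = FALSE)
    invisible(path)
}
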