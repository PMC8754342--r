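#' Combine CropSets (e.g. per-frame crops) into one set
#'
#' @param sets list of \linkS4class{CropSet}s with identical crop sizes
#' @return a single \linkS4class{CropSet}; crop ids are made unique by
#'   prefixing the frame
#' @export
combineCropSets <- function(sets) {
    sets <- Filter(function(s) nCells(s) > 0, sets)
    if (!length(sets))
        stop("no non-empty CropSets to combine")
    side <- dim(brightfield(sets[[1L]]))[1L]
    n <- sum(vapply(sets, nCells, integer(1)))
    bf <- array(0, c(side, dim(brightfield(sets[[1L]]))[2L], n))
    mk <- array(0L, dim(bf))
    metas <- list(); at <- 0L
    for (s in sets) {
        m <- nCells(s)
        bf[, , at + seq_len(m)] <- brightfield(s)
        mk[, , at + seq_len(m)] <- masks(s)
        metas[[length(metas) + 1L]] <- cellMeta(s)
        at <- at + m
    }
    meta <- do.call(rbind, metas)
    meta$crop_id <- if ("frame" %in% colnames(meta))
        paste0(meta$frame, ":", meta$crop_id) else seq_len(n)
    new("CropSet", brightfield = bf, mask = mk, meta = meta)
}

#' Default pipeline configuration
#'
#' Returns the full parameter tree driving [runPipeline()], ready to be
#' edited or serialized as YAML. Stage parameters mirror the individual
#' stage functions.
#'
#' @param seed master seed; stage seeds are derived from it
#' @return nested list of class `"PipelineConfig"`
#' @export
pipelineConfig <- function(seed = 1) {
    structure(list(
        seed = seed,
        simulate = list(enabled = TRUE, nCells = 12L, T = 8L,
                        frameShape = c(256L, 256L), minutesPerFrame = 3,
                        exclusionRadius = 26, classes = list(
            list(class_id = 1L, area_mean = 180, ecc_mean = 0.15,
                 granule_density = 0, step_sd = 1),
            list(class_id = 2L, area_mean = 380, ecc_mean = 0.65,
                 granule_density = 0.06, step_sd = 3)),
            P = rbind(c(0.9, 0.1), c(0.1, 0.9))),
        labelfree = list(steps = 300L, patch = 16L, nTrainFrames = 3L,
                         nPatches = 1500L),
        segment = list(minArea = 40, maxArea = 5000),
        viability = list(enabled = FALSE, threshold = 0.5, steps = 400L),
        preprocess = list(cropSize = 49L, canonicalSize = 48L),
        encoders = list(J = 16L, steps = 400L, gamma = 0.9, A = 1,
                        hidden = c(128L, 32L), w = 0.5),
        cluster = list(knn_k = 15L, resolution = 0.1, mergeMap = NULL),
        umap = list(n_neighbors = 15L, min_dist = 0.1),
        dynamics = list(D0 = 20, D1 = 15)
    ), class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Values present in the file override [pipelineConfig()] defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file
#' @return a `"PipelineConfig"` list
#' @export
readPipelineConfig <- function(path) {
    user <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
            else jsonlite::fromJSON(path, simplifyVector = TRUE)
    base <- pipelineConfig(seed = user$seed %||% 1)
    merge2 <- function(a, b) {
        for (k in names(b)) {
            a[[k]] <- if (is.list(a[[k]]) && is.list(b[[k]]))
                merge2(a[[k]], b[[k]]) else b[[k]]
        }
        a
    }
    structure(merge2(unclass(base), user), class = "PipelineConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end pipeline
#'
#' Orchestrates simulation (or movie input), label-free prediction,
#' segmentation, optional viability filtering, pose normalization, twin-VAE
#' training, encoding, clustering, embedding and transition dynamics,
#' writing versioned CSV artifacts plus a manifest to `outDir`. A rerun
#' with the identical configuration reproduces the CSV outputs.
#'
#' @param config a `"PipelineConfig"` (see [pipelineConfig()],
#'   [readPipelineConfig()])
#' @param outDir output directory, created if needed
#' @param movie optional brightfield array `h x w x T` to analyze instead
#'   of simulating (fluorescence pairs for label-free training must then be
#'   supplied via `trainPairs`)
#' @param trainPairs optional list of brightfield/fluorescence pairs
#' @return invisibly, a list of in-memory stage results
#' @export
runPipeline <- function(config, outDir, movie = NULL, trainPairs = NULL) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(config_hash = .configHash(config), outputs = list())
    logLines <- character(0)
    note <- function(...) {
        msg <- paste0(...)
        logLines <<- c(logLines, msg)
        message(msg)
    }
    emit <- function(obj, file, stage) {
        path <- file.path(outDir, file)
        utils::write.csv(obj, path, row.names = FALSE)
        manifest$outputs[[file]] <<- list(stage = stage,
                                          rows = nrow(obj))
        path
    }
    seeds <- .childSeeds(config$seed, 8L)
    note("pipeline seed = ", config$seed)

    ## ---- simulate ----------------------------------------------------
    sim <- NULL
    if (is.null(movie)) {
        if (!isTRUE(config$simulate$enabled))
            stop("no input movie supplied and the simulate stage is ",
                 "disabled")
        cs <- config$simulate
        specs <- lapply(cs$classes, function(cl)
            do.call(cellPhenotype, cl))
        scene <- sceneSpec(frameShape = cs$frameShape, nCells = cs$nCells,
                           minutesPerFrame = cs$minutesPerFrame,
                           exclusionRadius = cs$exclusionRadius)
        model <- markovModel(as.matrix(cs$P))
        sim <- simulateMovie(scene, model, specs, T = cs$T,
                             seed = seeds[1L])
        movie <- sim$brightfield
        emit(sim$tracks, "tracks_truth.csv", "simulate")
        note("simulated ", cs$nCells, " cells over ", cs$T, " frames")
        if (is.null(trainPairs))
            trainPairs <- lapply(
                seq_len(min(config$labelfree$nTrainFrames, dim(movie)[3L])),
                function(t) list(brightfield = sim$brightfield[, , t],
                                 fluorescence = sim$fluorescence[, , t]))
    }
    if (is.null(trainPairs))
        stop("label-free stage requires training pairs (missing upstream ",
             "artifact: fluorescence frames)")

    ## ---- label-free prediction + segmentation ------------------------
    lf <- trainLabelFree(trainPairs, steps = config$labelfree$steps,
                         seed = seeds[2L], patch = config$labelfree$patch,
                         nPatches = config$labelfree$nPatches)
    T <- dim(movie)[3L]
    dets <- vector("list", T)
    for (t in seq_len(T)) {
        pred <- predictFluorescence(lf, movie[, , t])
        dets[[t]] <- segmentFrame(pred, minArea = config$segment$minArea,
                                  maxArea = config$segment$maxArea,
                                  frame = t)
    }
    detTab <- do.call(rbind, lapply(dets, `[[`, "table"))
    emit(detTab, "detections.csv", "segment")
    note("segmented ", nrow(detTab), " detections over ", T, " frames")

    ## ---- crops (+ optional viability filter) -------------------------
    cropSets <- lapply(seq_len(T), function(t)
        cutCrops(movie[, , t], dets[[t]],
                 cropSize = config$preprocess$cropSize))
    crops <- combineCropSets(cropSets)
    nBefore <- nCells(crops)
    if (isTRUE(config$viability$enabled)) {
        ann <- config$viability$annotations
        if (is.null(ann))
            stop("viability stage requires an annotations table ",
                 "(crop_id, label)")
        vm <- trainViability(crops[match(ann$crop_id,
                                         cellMeta(crops)$crop_id)],
                             ann$label, steps = config$viability$steps,
                             seed = seeds[3L])
        calls <- classifyViability(vm, crops,
                                   threshold = config$viability$threshold)
        crops <- crops[calls$label == "Live"]
        note("viability filter removed ", nBefore - nCells(crops),
             " of ", nBefore, " crops")
    }

    ## ---- preprocessing ------------------------------------------------
    canon <- canonicalizeSet(crops, size = config$preprocess$canonicalSize)
    note("canonicalized ", nCells(canon), " of ", nCells(crops), " crops")

    ## ---- twin VAEs + encoding -----------------------------------------
    ce <- config$encoders
    cfgS <- vaeConfig(A = ce$A, gamma = ce$gamma, J = ce$J,
                      steps = ce$steps, seed = seeds[4L],
                      hidden = ce$hidden)
    cfgT <- vaeConfig(A = ce$A, gamma = ce$gamma, J = ce$J,
                      steps = ce$steps, seed = seeds[5L],
                      hidden = ce$hidden)
    shapeModel <- trainVAE(maskImages(canon), cfgS, branch = "mask")
    texModel <- trainVAE(textureImages(canon), cfgT, branch = "texture")
    lat <- encodeLatents(shapeModel, texModel, canon, w = ce$w)
    latOut <- cbind(data.frame(crop_id = cellMeta(lat)$crop_id),
                    as.data.frame(latentShape(lat)),
                    as.data.frame(latentTexture(lat)))
    colnames(latOut) <- c("crop_id",
                          paste0("zs_", seq_len(ce$J)),
                          paste0("zt_", seq_len(ce$J)))
    emit(latOut, "latents.csv", "encode")

    ## ---- clustering + embedding + state table -------------------------
    fused <- fusedLatents(lat)
    labels <- clusterLatents(fused, knn_k = config$cluster$knn_k,
                             resolution = config$cluster$resolution,
                             seed = seeds[6L],
                             mergeMap = config$cluster$mergeMap)
    um <- embedUMAP(fused, n_neighbors = config$umap$n_neighbors,
                    min_dist = config$umap$min_dist, seed = seeds[7L])
    mm <- lapply(seq_len(nCells(crops)), function(i)
        morphometrics(masks(crops)[, , i], brightfield(crops)[, , i]))
    keep <- match(cellMeta(canon)$crop_id, cellMeta(crops)$crop_id)
    state <- data.frame(
        crop_id = cellMeta(canon)$crop_id,
        frame = cellMeta(canon)$frame,
        cluster = labels,
        umap_x = um[, 1], umap_y = um[, 2],
        area = vapply(mm[keep], `[[`, numeric(1), "area"),
        eccentricity = vapply(mm[keep], `[[`, numeric(1), "eccentricity"),
        edge_strength = vapply(mm[keep], `[[`, numeric(1),
                               "edge_strength"))
    emit(state, "state_table.csv", "cluster")
    note("found ", length(unique(labels)), " morphological clusters")

    ## ---- dynamics ------------------------------------------------------
    ls <- linkPairs(detTab, D0 = config$dynamics$D0,
                    D1 = config$dynamics$D1)
    key <- paste0(state$frame, ":",
                  sub("^[0-9]+:", "", state$crop_id))
    clLabels <- stats::setNames(state$cluster, key)
    tm <- transitionMatrix(ls, clLabels,
                           minutesPerFrame =
                               config$simulate$minutesPerFrame %||% NA)
    emit(as.data.frame(transitionProbs(tm)), "transition_probs.csv",
         "dynamics")
    emit(as.data.frame(transitionCounts(tm)), "transition_counts.csv",
         "dynamics")
    vel <- velocities(ls, config$simulate$minutesPerFrame %||% 1,
                      labels = clLabels)
    emit(vel$speeds, "velocities.csv", "dynamics")
    emit(links(ls), "links.csv", "dynamics")
    note(nrow(links(ls)), " validated links; ",
         sum(transitionCounts(tm)), " labeled transitions")

    ## ---- manifest + log ------------------------------------------------
    writeLines(logLines, file.path(outDir, "run_log.txt"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(detections = detTab, crops = crops, canonical = canon,
                   latents = lat, stateTable = state, linkages = ls,
                   transitions = tm, manifest = manifest))
}

.configHash <- function(config) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(unclass(config), f)
    unname(tools::md5sum(f))
}
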