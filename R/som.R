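## Self-organizing map over kinase temporal-functionality profiles.
## Online (random-sampling) training with a Gaussian neighborhood and
## inverse-time decay of learning rate and neighborhood width.

#' SOM training configuration
#'
#' @param rows,cols grid dimensions (default 6 x 6).
#' @param sigma initial Gaussian neighborhood width (grid units).
#' @param learning_rate initial learning rate.
#' @param iterations number of update steps; `NULL` means 500 x number of
#'   profiles.
#' @param seed RNG seed for codebook initialization and sample order.
#' @return a list of settings for [trainSOM()]
#' @export
somConfig <- function(rows = 6, cols = 6, sigma = 1.0, learning_rate = 0.5,
                      iterations = NULL, seed = 1L) {
    stopifnot(rows >= 1, cols >= 1, sigma > 0, learning_rate > 0)
    list(rows = as.integer(rows), cols = as.integer(cols), sigma = sigma,
         learning_rate = learning_rate, iterations = iterations,
         seed = as.integer(seed))
}

## best-matching unit index (row-major); ties broken toward the lowest
## row-major coordinate (which.min returns the first minimum)
.bmu <- function(codebook, x) {
    d2 <- rowSums(sweep(codebook, 2L, x)^2)
    which.min(d2)
}

.quantizationError <- function(codebook, profiles) {
    mean(apply(profiles, 1L, function(x)
        sqrt(min(rowSums(sweep(codebook, 2L, x)^2)))))
}

#' Train a self-organizing map on temporal profiles
#'
#' Profiles (typically kinase functionality rows in \{-1, 0, +1\}) are used
#' raw, without rescaling. The codebook is initialized uniformly at random
#' within the per-feature data range; training draws one random profile per
#' step and pulls the best-matching unit and its Gaussian neighborhood toward
#' it. Learning rate and sigma decay as `1 / (1 + t/(T/2))`. Deterministic
#' given the configured seed.
#'
#' @param profiles numeric matrix, profiles (kinases) x features (windows)
#' @param config see [somConfig()]
#' @return a [SOMMap-class]
#' @export
trainSOM <- function(profiles, config = somConfig()) {
    profiles <- as.matrix(profiles)
    if (nrow(profiles) == 0L) stop("no profiles to train on")
    nNeurons <- config$rows * config$cols
    nFeat <- ncol(profiles)
    iters <- config$iterations %||% (500L * nrow(profiles))
    set.seed(config$seed)
    lo <- apply(profiles, 2L, min)
    hi <- apply(profiles, 2L, max)
    codebook <- matrix(stats::runif(nNeurons * nFeat), nrow = nNeurons) *
        rep(hi - lo, each = nNeurons) + rep(lo, each = nNeurons)
    # neuron grid coordinates, row-major
    gi <- rep(seq_len(config$rows), each = config$cols)
    gj <- rep(seq_len(config$cols), times = config$rows)
    qe0 <- .quantizationError(codebook, profiles)
    sampleIdx <- sample.int(nrow(profiles), iters, replace = TRUE)
    halfT <- iters / 2
    for (t in seq_len(iters)) {
        decay <- 1 / (1 + (t - 1) / halfT)
        lr <- config$learning_rate * decay
        sg <- config$sigma * decay
        x <- profiles[sampleIdx[t], ]
        b <- .bmu(codebook, x)
        h <- exp(-((gi - gi[b])^2 + (gj - gj[b])^2) / (2 * sg^2))
        codebook <- codebook + (lr * h) * (rep(x, each = nNeurons) - codebook)
    }
    qe1 <- .quantizationError(codebook, profiles)
    methods::new("SOMMap", codebook = codebook, rows = config$rows,
                 cols = config$cols,
                 config = c(config, list(iterations_used = iters)),
                 qeInitial = qe0, qeFinal = qe1)
}

#' Assign profiles to their best-matching neurons
#'
#' Each profile maps to the neuron whose codebook vector is nearest in
#' Euclidean distance; exact ties go to the lowest (i, j) coordinate in
#' row-major order. When a [FunctionalityMatrix-class] accompanies the
#' profiles, per-neuron mean functionality traces are attached.
#'
#' @param map a trained [SOMMap-class]
#' @param profiles numeric matrix, profiles x features, with rownames
#' @return a [NeuronAssignment-class]
#' @export
assignNeurons <- function(map, profiles) {
    profiles <- as.matrix(profiles)
    if (ncol(profiles) != ncol(map@codebook))
        stop("profile length ", ncol(profiles), " does not match codebook (",
             ncol(map@codebook), ")")
    if (is.null(rownames(profiles)))
        rownames(profiles) <- paste0("profile", seq_len(nrow(profiles)))
    bmus <- apply(profiles, 1L, function(x) .bmu(map@codebook, x))
    assignment <- data.frame(
        kinase = rownames(profiles),
        neuron_i = ((bmus - 1L) %/% map@cols) + 1L,
        neuron_j = ((bmus - 1L) %% map@cols) + 1L,
        stringsAsFactors = FALSE)
    traces <- lapply(split(seq_len(nrow(profiles)),
                           paste(assignment$neuron_i, assignment$neuron_j,
                                 sep = ",")),
                     function(idx) colMeans(profiles[idx, , drop = FALSE]))
    methods::new("NeuronAssignment", assignment = assignment, map = map,
                 traces = traces)
}

#' Mean functionality trace of one neuron
#'
#' Per window, the arithmetic mean of the member kinases' calls: +1 iff all
#' members are barrier-strengthening in that window, -1 iff all are
#' barrier-weakening, intermediate values the signed proportion.
#'
#' @param assignment a [NeuronAssignment-class]
#' @param m the [FunctionalityMatrix-class] the profiles came from
#' @param neuron integer vector `c(i, j)`
#' @return numeric vector, one mean per window
#' @export
neuronMeanTrace <- function(assignment, m, neuron) {
    a <- assignment@assignment
    members <- a$kinase[a$neuron_i == neuron[1] & a$neuron_j == neuron[2]]
    if (!length(members))
        stop("neuron (", neuron[1], ",", neuron[2], ") has no members")
    colMeans(m@calls[members, , drop = FALSE])
}

#' Members of one neuron
#' @param assignment a [NeuronAssignment-class]
#' @param neuron integer vector `c(i, j)`
#' @return character vector of member kinases
#' @export
neuronMembers <- function(assignment, neuron) {
    a <- assignment@assignment
    a$kinase[a$neuron_i == neuron[1] & a$neuron_j == neuron[2]]
}

#' Occupied neurons of an assignment
#' @param assignment a [NeuronAssignment-class]
#' @return data.frame of distinct (neuron_i, neuron_j) with member counts
#' @export
occupiedNeurons <- function(assignment) {
    a <- assignment@assignment
    agg <- stats::aggregate(list(members = a$kinase),
                            by = list(neuron_i = a$neuron_i,
                                      neuron_j = a$neuron_j),
                            FUN = length)
    agg[order(agg$neuron_i, agg$neuron_j), , drop = FALSE]
}

#' Neighbor-distance map (U-matrix) of a trained SOM
#'
#' Per neuron, the sum of Euclidean distances between its codebook vector and
#' those of its 8-connected grid neighbors, normalized by the maximum such
#' sum (so the largest cell is 1). Large values mark cluster boundaries.
#'
#' @param map a trained [SOMMap-class]
#' @return rows x cols numeric matrix in \[0, 1\]
#' @export
distanceMap <- function(map) {
    if (map@rows * map@cols < 2L)
        stop("distance map undefined on a 1x1 grid (no neighbors)")
    dm <- matrix(0, nrow = map@rows, ncol = map@cols)
    idx <- function(i, j) (i - 1L) * map@cols + j
    for (i in seq_len(map@rows)) for (j in seq_len(map@cols)) {
        s <- 0
        for (di in -1:1) for (dj in -1:1) {
            if (di == 0L && dj == 0L) next
            ni <- i + di; nj <- j + dj
            if (ni < 1L || ni > map@rows || nj < 1L || nj > map@cols) next
            s <- s + sqrt(sum((map@codebook[idx(i, j), ] -
                               map@codebook[idx(ni, nj), ])^2))
        }
        dm[i, j] <- s
    }
    mx <- max(dm)
    if (mx > 0) dm <- dm / mx
    dm
}

#' Quantization error of a map on a profile set
#'
#' Mean Euclidean distance from each profile to its best-matching codebook
#' vector.
#'
#' @param map a [SOMMap-class]
#' @param profiles numeric matrix, profiles x features
#' @return numeric scalar
#' @export
quantizationError <- function(map, profiles) {
    .quantizationError(map@codebook, as.matrix(profiles))
}

#' Topographic error of a map on a profile set
#'
#' Fraction of profiles whose best and second-best matching units are not
#' grid neighbors (8-connectivity). A diagnostic of topology preservation,
#' reported rather than asserted.
#'
#' @param map a [SOMMap-class]
#' @param profiles numeric matrix
#' @return numeric scalar in \[0, 1\]
#' @export
topographicError <- function(map, profiles) {
    profiles <- as.matrix(profiles)
    if (map@rows * map@cols < 2L) return(0)
    bad <- apply(profiles, 1L, function(x) {
        d2 <- rowSums(sweep(map@codebook, 2L, x)^2)
        o <- order(d2)[1:2]
        i1 <- (o[1] - 1L) %/% map@cols; j1 <- (o[1] - 1L) %% map@cols
        i2 <- (o[2] - 1L) %/% map@cols; j2 <- (o[2] - 1L) %% map@cols
        max(abs(i1 - i2), abs(j1 - j2)) > 1L
    })
    mean(bad)
}

#' Write a neuron-assignment table to CSV
#' @param assignment a [NeuronAssignment-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeAssignment <- function(assignment, path) {
    utils::write.csv(assignment@assignment, path, row.names = FALSE,
                     quote = FALSE)
    invisible(path)
}
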