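#' @import methods
NULL

#' Annotated cell-index time courses for one plate
#'
#' Holds impedance-derived cell-index kinetics for a set of wells, each well
#' annotated with the inhibitor it received (or the vehicle control), a
#' condition label and a replicate index. Times are minutes relative to
#' inhibitor addition and may be negative for pre-treatment samples.
#'
#' @slot times numeric vector of sampling times (minutes), strictly increasing.
#' @slot wells data.frame with columns `well`, `inhibitor`, `condition`,
#'   `replicate` (one row per well).
#' @slot values numeric matrix, wells x times; `rownames` are well ids.
#' @slot annotations list with at least `thrombin_time_min`,
#'   `inhibitor_time_min`, `tnf_preconditioned`, `control_id`.
#' @export
setClass("TimeSeriesPlate",
    slots = c(
        times = "numeric",
        wells = "data.frame",
        values = "matrix",
        annotations = "list"
    )
)

setValidity("TimeSeriesPlate", function(object) {
    msg <- character()
    if (length(object@times) < 2L)
        msg <- c(msg, "need at least two sampling times")
    if (any(diff(object@times) <= 0))
        msg <- c(msg, "times must be strictly increasing")
    req <- c("well", "inhibitor", "condition", "replicate")
    if (!all(req %in% names(object@wells)))
        msg <- c(msg, paste("wells must have columns:", paste(req, collapse = ", ")))
    if (nrow(object@values) != nrow(object@wells) ||
        ncol(object@values) != length(object@times))
        msg <- c(msg, "values must be wells x times")
    if (anyNA(object@values))
        msg <- c(msg, "values must be complete (every well sampled at every time)")
    if ("replicate" %in% names(object@wells) &&
        any(object@wells$replicate < 1))
        msg <- c(msg, "replicate indices must be >= 1")
    ctrl <- object@annotations$control_id
    if (is.null(ctrl)) {
        msg <- c(msg, "annotations$control_id is required")
    } else if (!ctrl %in% object@wells$inhibitor) {
        msg <- c(msg, sprintf("control inhibitor '%s' absent from plate", ctrl))
    }
    if (length(msg)) msg else TRUE
})

#' Sliding-window grid over a time course
#'
#' Ordered fixed-width windows: a fine-stepped first phase followed by a
#' coarser-stepped second phase, mirroring 1-min acquisition for the first
#' 2 h after inhibitor addition and 5-min acquisition afterwards.
#'
#' @slot starts,ends,midpoints numeric vectors (minutes), one per window.
#' @slot width window width in minutes.
#' @export
setClass("WindowGrid",
    slots = c(starts = "numeric", ends = "numeric",
              midpoints = "numeric", width = "numeric")
)

setValidity("WindowGrid", function(object) {
    msg <- character()
    n <- length(object@starts)
    if (length(object@ends) != n || length(object@midpoints) != n)
        msg <- c(msg, "starts, ends, midpoints must have equal length")
    if (n == 0L)
        msg <- c(msg, "grid must contain at least one window")
    if (n > 0L) {
        if (any(abs((object@ends - object@starts) - object@width) > 1e-9))
            msg <- c(msg, "every window must have end - start == width")
        if (n > 1L && any(diff(object@midpoints) <= 0))
            msg <- c(msg, "midpoints must be strictly increasing")
    }
    if (length(msg)) msg else TRUE
})

#' Per-window area-under-curve matrix
#'
#' Trapezoidal AUC of the baseline-normalized cell index for each inhibitor in
#' each sliding window (`raw`), plus its linear transform to the 0/100 scale
#' (`normalized`): per window, AUCs are control-subtracted and mapped so the
#' vehicle control sits at 100 and the most negative delta at 0.
#'
#' @slot raw,normalized numeric matrices, inhibitor x window; column names are
#'   window midpoints.
#' @slot controlId the control (vehicle) inhibitor id.
#' @slot minDelta per-window minimum control-subtracted AUC used for scaling.
#' @slot noiseSD per-window noise sd of a control-subtracted AUC, estimated
#'   from replicate spread (zeros when replicates are unavailable).
#' @slot grid the [WindowGrid-class] the columns refer to.
#' @export
setClass("AUCMatrix",
    slots = c(raw = "matrix", normalized = "matrix",
              controlId = "character", minDelta = "numeric",
              noiseSD = "numeric", grid = "WindowGrid")
)

setValidity("AUCMatrix", function(object) {
    msg <- character()
    if (!identical(dim(object@raw), dim(object@normalized)))
        msg <- c(msg, "raw and normalized must share shape")
    if (!identical(rownames(object@raw), rownames(object@normalized)))
        msg <- c(msg, "raw and normalized must share row labels")
    if (!object@controlId %in% rownames(object@raw))
        msg <- c(msg, "control row missing")
    if (ncol(object@raw) != length(object@grid@starts))
        msg <- c(msg, "column count must match window grid")
    if (length(object@minDelta) != ncol(object@raw))
        msg <- c(msg, "minDelta must have one entry per window")
    if (length(object@noiseSD) != ncol(object@raw))
        msg <- c(msg, "noiseSD must have one entry per window")
    if (length(msg)) msg else TRUE
})

#' Inhibitor x kinase residual-activity panel
#'
#' In-vitro biochemical specificity panel: percent of each kinase's activity
#' remaining under each inhibitor (0 = fully inhibited, 100 = untouched).
#' This is the design matrix of the kinase regression.
#'
#' @slot activity numeric matrix in \[0, 100\], inhibitors as rows, kinases as
#'   columns.
#' @export
setClass("KinaseActivityPanel", slots = c(activity = "matrix"))

setValidity("KinaseActivityPanel", function(object) {
    msg <- character()
    a <- object@activity
    if (is.null(rownames(a)) || is.null(colnames(a)))
        msg <- c(msg, "activity needs inhibitor rownames and kinase colnames")
    if (anyNA(a) || any(a < 0) || any(a > 100))
        msg <- c(msg, "residual activities must lie in [0, 100]")
    if (anyDuplicated(colnames(a)))
        msg <- c(msg, "duplicate kinase names")
    if (anyDuplicated(rownames(a)))
        msg <- c(msg, "duplicate inhibitor names")
    if (length(msg)) msg else TRUE
})

#' One elastic-net fit for one time window
#'
#' @slot window window index in the grid.
#' @slot intercept fitted intercept.
#' @slot coefficients named numeric vector, one per panel kinase.
#' @slot lambda,alpha penalty parameters actually used.
#' @slot cvError cross-validation error trace (may be length 0 when lambda
#'   was fixed).
#' @slot selected names of kinases with nonzero coefficients.
#' @export
setClass("WindowFit",
    slots = c(window = "integer", intercept = "numeric",
              coefficients = "numeric", lambda = "numeric",
              alpha = "numeric", cvError = "numeric",
              selected = "character")
)

setValidity("WindowFit", function(object) {
    msg <- character()
    if (is.null(names(object@coefficients)))
        msg <- c(msg, "coefficients must be named by kinase")
    if (!all(object@selected %in% names(object@coefficients)))
        msg <- c(msg, "selected set must be a subset of kinases")
    if (length(msg)) msg else TRUE
})

#' Kinase x window functionality calls
#'
#' Integer matrix in \{-1, 0, +1\}: -1 barrier-weakening, +1
#' barrier-strengthening, 0 not predicted in that window.
#'
#' @slot calls integer matrix, kinase x window; column names are window
#'   midpoints.
#' @slot condition free-text condition label.
#' @slot grid the [WindowGrid-class] the columns refer to.
#' @export
setClass("FunctionalityMatrix",
    slots = c(calls = "matrix", condition = "character", grid = "WindowGrid")
)

setValidity("FunctionalityMatrix", function(object) {
    msg <- character()
    if (!all(object@calls %in% c(-1L, 0L, 1L)))
        msg <- c(msg, "calls must be in {-1, 0, +1}")
    if (ncol(object@calls) != length(object@grid@midpoints))
        msg <- c(msg, "column count must match window grid")
    if (length(msg)) msg else TRUE
})

#' Trained self-organizing map
#'
#' @slot codebook numeric matrix, (rows*cols) neurons x features, neuron order
#'   row-major over the grid.
#' @slot rows,cols grid dimensions.
#' @slot config training configuration actually used (list).
#' @slot qeInitial,qeFinal quantization error before and after training.
#' @export
setClass("SOMMap",
    slots = c(codebook = "matrix", rows = "integer", cols = "integer",
              config = "list", qeInitial = "numeric", qeFinal = "numeric")
)

setValidity("SOMMap", function(object) {
    msg <- character()
    if (object@rows < 1L || object@cols < 1L)
        msg <- c(msg, "grid must be at least 1x1")
    if (nrow(object@codebook) != object@rows * object@cols)
        msg <- c(msg, "codebook must have rows*cols neurons")
    if (length(msg)) msg else TRUE
})

#' Placement of kinases on a trained SOM
#'
#' @slot assignment data.frame with columns `kinase`, `neuron_i`, `neuron_j`
#'   (1-based grid coordinates).
#' @slot map the [SOMMap-class] used.
#' @slot traces per-neuron mean functionality trace (list keyed "i,j"), each a
#'   numeric vector in \[-1, 1\] per window.
#' @export
setClass("NeuronAssignment",
    slots = c(assignment = "data.frame", map = "SOMMap", traces = "list")
)

setValidity("NeuronAssignment", function(object) {
    msg <- character()
    req <- c("kinase", "neuron_i", "neuron_j")
    if (!all(req %in% names(object@assignment)))
        msg <- c(msg, "assignment needs kinase, neuron_i, neuron_j")
    if (anyDuplicated(object@assignment$kinase))
        msg <- c(msg, "each kinase must be assigned to exactly one neuron")
    if (length(object@traces) &&
        any(vapply(object@traces, function(tr) any(tr < -1 - 1e-9 | tr > 1 + 1e-9),
                   logical(1))))
        msg <- c(msg, "mean traces must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})

#' Directed kinase-kinase background phosphorylation graph
#'
#' Edges run kinase -> substrate kinase, deduplicated across phosphosites;
#' self-loops (autophosphorylation) are permitted.
#'
#' @slot graph directed `igraph` object.
#' @slot organism organism tag the rows were filtered to.
#' @slot provenance list: source path, row counts before/after filters.
#' @export
setClass("BackgroundNetwork",
    slots = c(graph = "ANY", organism = "character", provenance = "list")
)

setValidity("BackgroundNetwork", function(object) {
    msg <- character()
    if (!igraph::is_igraph(object@graph))
        msg <- c(msg, "graph must be an igraph object")
    else {
        if (!igraph::is_directed(object@graph))
            msg <- c(msg, "graph must be directed")
        if (igraph::any_multiple(object@graph))
            msg <- c(msg, "duplicate directed edges are not allowed")
    }
    if (length(msg)) msg else TRUE
})

#' Local phosphosignaling network for a neuron (or pooled neurons)
#'
#' Union of all shortest directed paths between every ordered pair of member
#' kinases over the background graph. Nodes are labeled `member` (a predicted
#' kinase of the neuron) or `inferred` (a pass-through kinase lying on a
#' shortest path).
#'
#' @slot graph directed `igraph`; vertex attribute `role` in
#'   \{"member", "inferred"\}, optional `functionality`.
#' @slot members the member kinases the search started from.
#' @slot neurons source neuron labels.
#' @slot provenance list: unmapped members, unreachable ordered pairs.
#' @export
setClass("LocalNetwork",
    slots = c(graph = "ANY", members = "character",
              neurons = "character", provenance = "list")
)

setValidity("LocalNetwork", function(object) {
    msg <- character()
    if (!igraph::is_igraph(object@graph))
        msg <- c(msg, "graph must be an igraph object")
    else if (!"role" %in% igraph::vertex_attr_names(object@graph))
        msg <- c(msg, "vertices must carry a 'role' attribute")
    if (length(msg)) msg else TRUE
})

## ---- show methods ----

setMethod("show", "TimeSeriesPlate", function(object) {
    cat(sprintf("TimeSeriesPlate: %d wells x %d timepoints (%g..%g min)\n",
                nrow(object@values), length(object@times),
                min(object@times), max(object@times)))
    cat(sprintf("  inhibitors: %d (control: %s)\n",
                length(unique(object@wells$inhibitor)),
                object@annotations$control_id))
    cat(sprintf("  thrombin at %g min; TNF preconditioned: %s\n",
                object@annotations$thrombin_time_min %||% NA,
                isTRUE(object@annotations$tnf_preconditioned)))
})

setMethod("show", "WindowGrid", function(object) {
    cat(sprintf("WindowGrid: %d windows of %g min (midpoints %g..%g)\n",
                length(object@starts), object@width,
                object@midpoints[1], object@midpoints[length(object@midpoints)]))
})

setMethod("show", "AUCMatrix", function(object) {
    cat(sprintf("AUCMatrix: %d inhibitors x %d windows (control: %s)\n",
                nrow(object@raw), ncol(object@raw), object@controlId))
})

setMethod("show", "KinaseActivityPanel", function(object) {
    cat(sprintf("KinaseActivityPanel: %d inhibitors x %d kinases\n",
                nrow(object@activity), ncol(object@activity)))
})

setMethod("show", "WindowFit", function(object) {
    cat(sprintf("WindowFit (window %d): %d/%d kinases selected, lambda=%.4g, alpha=%.2f\n",
                object@window, length(object@selected),
                length(object@coefficients), object@lambda, object@alpha))
})

setMethod("show", "FunctionalityMatrix", function(object) {
    k <- rowSums(object@calls != 0) > 0
    cat(sprintf("FunctionalityMatrix [%s]: %d kinases x %d windows (%d ever called)\n",
                object@condition, nrow(object@calls), ncol(object@calls), sum(k)))
})

setMethod("show", "SOMMap", function(object) {
    cat(sprintf("SOMMap: %dx%d grid, %d features; QE %.4g -> %.4g\n",
                object@rows, object@cols, ncol(object@codebook),
                object@qeInitial, object@qeFinal))
})

setMethod("show", "NeuronAssignment", function(object) {
    occ <- nrow(unique(object@assignment[, c("neuron_i", "neuron_j")]))
    cat(sprintf("NeuronAssignment: %d kinases on %d occupied neurons (%dx%d grid)\n",
                nrow(object@assignment), occ, object@map@rows, object@map@cols))
})

setMethod("show", "BackgroundNetwork", function(object) {
    cat(sprintf("BackgroundNetwork [%s]: %d kinases, %d directed edges\n",
                object@organism, igraph::vcount(object@graph),
                igraph::ecount(object@graph)))
})

setMethod("show", "LocalNetwork", function(object) {
    role <- igraph::V(object@graph)$role
    cat(sprintf("LocalNetwork (%s): %d nodes (%d member, %d inferred), %d edges\n",
                paste(object@neurons, collapse = "+"),
                igraph::vcount(object@graph), sum(role == "member"),
                sum(role == "inferred"), igraph::ecount(object@graph)))
})
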