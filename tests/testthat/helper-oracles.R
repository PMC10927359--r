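# Independent oracles and shared fixtures. The oracles deliberately avoid
# the package's own code paths (and igraph): brute-force BFS for shortest
# paths, fine Riemann sums for integrals.

# Riemann-sum AUC of the piecewise-linear interpolant, on a fine grid.
riemannAUC <- function(times, values, start, end, n = 1e4) {
    xs <- seq(start, end, length.out = n + 1)
    ys <- approx(times, values, xout = xs)$y
    mids <- (ys[-1] + ys[-(n + 1)]) / 2
    sum(mids * diff(xs))
}

# Adjacency-list BFS distances from a source over a directed edge list.
bfsDistances <- function(adj, nodes, from) {
    dist <- setNames(rep(Inf, length(nodes)), nodes)
    dist[from] <- 0
    queue <- from
    while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]]) {
            if (is.infinite(dist[w])) {
                dist[w] <- dist[v] + 1
                queue <- c(queue, w)
            }
        }
    }
    dist
}

# All shortest paths a -> b by DFS over the BFS distance field; returns a
# two-column matrix of edges on any shortest path (deduplicated).
bruteShortestPathEdges <- function(edges, nodes, a, b) {
    adj <- lapply(setNames(nm = nodes), function(v)
        edges$to[edges$from == v])
    dist <- bfsDistances(adj, nodes, a)
    if (is.infinite(dist[b])) return(NULL)
    out <- NULL
    walk <- function(v, path) {
        if (v == b) {
            for (i in seq_len(length(path) - 1))
                out <<- rbind(out, c(path[i], path[i + 1]))
            return()
        }
        for (w in adj[[v]])
            if (dist[w] == dist[v] + 1 && dist[w] <= dist[b])
                walk(w, c(path, w))
    }
    walk(a, a)
    unique(out)
}

# Union of all shortest-path edges over every ordered member pair; the
# independent counterpart of buildLocalNetwork (plus the singleton
# self-loop rule).
bruteLocalEdges <- function(edges, nodes, members) {
    members <- intersect(members, nodes)
    out <- NULL
    for (a in members) for (b in members) {
        if (a == b) next
        out <- rbind(out, bruteShortestPathEdges(edges, nodes, a, b))
    }
    if (length(members) == 1L &&
        any(edges$from == members & edges$to == members))
        out <- rbind(out, c(members, members))
    if (is.null(out)) NULL else unique(out)
}

# Random directed graph as an edge-list data.frame.
randomDigraph <- function(n, p, seed) {
    set.seed(seed)
    nodes <- sprintf("N%02d", seq_len(n))
    pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    edges <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
    rownames(edges) <- NULL
    list(nodes = nodes, edges = edges)
}

backgroundFromEdges <- function(edges, nodes) {
    g <- if (nrow(edges)) {
        igraph::graph_from_data_frame(edges, directed = TRUE,
                                      vertices = data.frame(name = nodes))
    } else {
        igraph::make_empty_graph(directed = TRUE) + igraph::vertices(nodes)
    }
    methods::new("BackgroundNetwork", graph = g, organism = "synthetic",
                 provenance = list())
}

# Small plate built in code: nWells wells, linear-ish kinetics.
toyPlate <- function(values, times, inhibitors, replicates = NULL,
                     thrombin_time = -2, control = "DMSO") {
    nw <- nrow(values)
    wells <- data.frame(
        well = sprintf("W%02d", seq_len(nw)),
        inhibitor = inhibitors,
        condition = "toy",
        replicate = replicates %||% rep(1L, nw),
        stringsAsFactors = FALSE)
    rownames(values) <- wells$well
    methods::new("TimeSeriesPlate", times = times, wells = wells,
                 values = values,
                 annotations = list(thrombin_time_min = thrombin_time,
                                    inhibitor_time_min = 0,
                                    tnf_preconditioned = FALSE,
                                    control_id = control))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The default synthetic screen run end-to-end once per session and cached;
# several tests and the acceptance checks reuse it.
defaultScreenRun <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        sim <- simulateScreen(simConfig(seed = 101L))
        plate <- normalizeBaseline(sim$plate)
        grid <- enumerateWindows(360)
        auc <- suppressWarnings(computeAUCMatrix(plate, grid))
        fm <- buildFunctionalityMatrix(auc, sim$truth$panel,
                                       condition = "default")
        cache <<- list(sim = sim, plate = plate, grid = grid, auc = auc,
                       fm = fm)
        cache
    }
})
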