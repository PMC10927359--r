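## Kinase-substrate background graph and per-neuron local phosphosignaling
## networks as unions of all shortest directed paths.

#' Bundled human kinome gene-symbol list
#'
#' Reads the packaged reference list of human protein-kinase gene symbols
#' (editable plain text, one symbol per line) used to restrict the
#' kinase-substrate background graph to kinase-kinase edges. Users with a
#' preferred kinome definition can pass their own list anywhere a `kinome`
#' argument is accepted.
#'
#' @param path optional path to an alternative list
#' @return character vector of gene symbols
#' @export
humanKinome <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "human_kinome.txt",
                            package = "treking", mustWork = TRUE)
    symbols <- readLines(path)
    symbols <- trimws(symbols[!grepl("^#", symbols) & nzchar(symbols)])
    unique(symbols)
}

#' Load a kinase-substrate table into a background network
#'
#' Reads a kinase-substrate phosphorylation flat file (PhosphoSitePlus
#' `Kinase_Substrate_Dataset` dialect: optional preamble lines, then a
#' tab-separated header containing `GENE`, `KIN_ORGANISM`, `SUB_GENE`,
#' `SUB_ORGANISM`). Rows are kept when both organisms equal `organism` and
#' the substrate gene is itself a kinase (member of `kinome`); multiple
#' phosphosites collapse to one directed edge per (kinase, substrate) pair;
#' autophosphorylation rows become self-loops.
#'
#' @param path TSV path (plain or gzip)
#' @param organism organism label as used in the file (e.g. `"human"`)
#' @param kinome character vector of kinase gene symbols; defaults to the
#'   bundled list from [humanKinome()]
#' @param synonyms optional data.frame with columns `from`, `to` applied to
#'   both kinase and substrate gene symbols before filtering
#' @return a [BackgroundNetwork-class]
#' @export
loadKinaseSubstrate <- function(path, organism = "human",
                                kinome = humanKinome(), synonyms = NULL) {
    lines <- readLines(path)
    hdr <- grep("\\bGENE\\b.*\\bSUB_GENE\\b", lines)[1]
    if (is.na(hdr))
        stop("no header row with GENE and SUB_GENE columns found in ", path)
    df <- utils::read.delim(text = lines[hdr:length(lines)],
                            stringsAsFactors = FALSE, check.names = TRUE)
    req <- c("GENE", "KIN_ORGANISM", "SUB_GENE", "SUB_ORGANISM")
    missing <- setdiff(req, names(df))
    if (length(missing))
        stop("kinase-substrate file lacks column(s): ",
             paste(missing, collapse = ", "))
    nBefore <- nrow(df)
    if (!is.null(synonyms)) {
        df$GENE <- applySynonyms(df$GENE, synonyms)
        df$SUB_GENE <- applySynonyms(df$SUB_GENE, synonyms)
    }
    keep <- tolower(df$KIN_ORGANISM) == tolower(organism) &
        tolower(df$SUB_ORGANISM) == tolower(organism)
    df <- df[keep, , drop = FALSE]
    nOrganism <- nrow(df)
    df <- df[df$SUB_GENE %in% kinome, , drop = FALSE]
    edges <- unique(df[, c("GENE", "SUB_GENE")])
    if (nrow(edges) == 0L) {
        warning("no kinase-kinase edges left after filtering")
        g <- igraph::make_empty_graph(directed = TRUE)
    } else {
        g <- igraph::graph_from_data_frame(edges, directed = TRUE)
    }
    methods::new("BackgroundNetwork", graph = g, organism = organism,
                 provenance = list(source = path, rows_total = nBefore,
                                   rows_organism = nOrganism,
                                   rows_kinase_substrate = nrow(df),
                                   edges = nrow(edges)))
}

#' Apply a synonym table to gene symbols
#'
#' @param x character vector of symbols
#' @param synonyms data.frame with columns `from`, `to`
#' @return `x` with every `from` replaced by its `to`
#' @export
applySynonyms <- function(x, synonyms) {
    hit <- match(x, synonyms$from)
    x[!is.na(hit)] <- synonyms$to[hit[!is.na(hit)]]
    x
}

#' Build a neuron's local phosphosignaling network
#'
#' For every ordered pair of member kinases (a, b), a != b, with b reachable
#' from a in the background graph, every shortest directed path is included;
#' the local network is the union of those paths. A singleton member with an
#' autophosphorylation self-loop yields a one-node network. Returns `NULL`
#' ("no network") when the combined edge set is empty — a single member
#' without a self-loop, or mutually unreachable members. Non-member kinases
#' appearing inside paths are labeled `inferred`.
#'
#' @param members character vector of member kinases
#' @param background a [BackgroundNetwork-class]
#' @param functionality optional [FunctionalityMatrix-class]; members present
#'   in it get a summary node annotation (weakening / strengthening / both)
#' @param neurons source neuron label(s) recorded on the result
#' @return a [LocalNetwork-class], or `NULL` when no network exists
#' @export
buildLocalNetwork <- function(members, background, functionality = NULL,
                              neurons = "neuron") {
    if (!length(members)) stop("members must be nonempty")
    g <- background@graph
    known <- igraph::V(g)$name
    unmapped <- setdiff(members, known)
    mapped <- intersect(members, known)
    edgeFrom <- character(0)
    edgeTo <- character(0)
    unreachable <- 0L
    for (a in mapped) {
        for (b in mapped) {
            if (a == b) next
            sp <- suppressWarnings(
                igraph::all_shortest_paths(g, from = a, to = b, mode = "out"))
            if (!length(sp$res)) { unreachable <- unreachable + 1L; next }
            for (p in sp$res) {
                nm <- names(p)
                edgeFrom <- c(edgeFrom, nm[-length(nm)])
                edgeTo <- c(edgeTo, nm[-1])
            }
        }
    }
    # a singleton member forms a network only through autophosphorylation
    if (length(mapped) == 1L && igraph::are_adjacent(g, mapped, mapped)) {
        edgeFrom <- c(edgeFrom, mapped)
        edgeTo <- c(edgeTo, mapped)
    }
    edges <- unique(data.frame(from = edgeFrom, to = edgeTo,
                               stringsAsFactors = FALSE))
    if (nrow(edges) == 0L) return(NULL)
    lg <- igraph::graph_from_data_frame(edges, directed = TRUE)
    role <- ifelse(igraph::V(lg)$name %in% mapped, "member", "inferred")
    lg <- igraph::set_vertex_attr(lg, "role", value = role)
    if (!is.null(functionality)) {
        ann <- vapply(igraph::V(lg)$name, function(k) {
            if (!k %in% rownames(functionality@calls)) return("none")
            row <- functionality@calls[k, ]
            hasNeg <- any(row == -1L); hasPos <- any(row == 1L)
            if (hasNeg && hasPos) "both"
            else if (hasNeg) "weakening"
            else if (hasPos) "strengthening"
            else "none"
        }, character(1))
        lg <- igraph::set_vertex_attr(lg, "functionality", value = ann)
    }
    methods::new("LocalNetwork", graph = lg, members = members,
                 neurons = as.character(neurons),
                 provenance = list(unmapped = unmapped,
                                   unreachable_pairs = unreachable))
}

#' Composite network from pooled neurons
#'
#' Pools the member kinases of several neurons and builds a single local
#' network from the pooled set.
#'
#' @param neuron_list list of integer `c(i, j)` neuron coordinates
#' @param assignment a [NeuronAssignment-class]
#' @param background a [BackgroundNetwork-class]
#' @param functionality optional [FunctionalityMatrix-class]
#' @return a [LocalNetwork-class], or `NULL`
#' @export
compositeNetwork <- function(neuron_list, assignment, background,
                             functionality = NULL) {
    members <- unique(unlist(lapply(neuron_list, function(n)
        neuronMembers(assignment, n))))
    if (!length(members)) stop("all pooled neurons are empty")
    labels <- vapply(neuron_list, function(n)
        sprintf("(%d,%d)", n[1], n[2]), character(1))
    buildLocalNetwork(members, background, functionality, neurons = labels)
}

#' Size and path-length statistics of a local network
#'
#' `max_path_nodes` is the maximum, over ordered reachable node pairs within
#' the network, of the number of nodes on the shortest path — the
#' kinase-count convention, where a direct edge scores 2 and an isolated or
#' self-looped node scores 1.
#'
#' @param network a [LocalNetwork-class]
#' @return list with `max_path_nodes`, `n_nodes`, `n_edges`, `n_members`,
#'   `n_inferred`
#' @export
networkStats <- function(network) {
    g <- network@graph
    d <- igraph::distances(g, mode = "out")
    maxHops <- max(d[is.finite(d)])
    role <- igraph::V(g)$role
    list(max_path_nodes = as.integer(maxHops) + 1L,
         n_nodes = igraph::vcount(g),
         n_edges = igraph::ecount(g),
         n_members = sum(role == "member"),
         n_inferred = sum(role == "inferred"))
}

#' Export a local network for visualization
#'
#' `sif` writes one `source phosphorylates target` line per edge plus a node
#' attribute sidecar CSV (`<path>.nodes.csv`); `graphml` serializes the full
#' labeled graph via igraph; `csv` writes an edge list with the same node
#' sidecar.
#'
#' @param network a [LocalNetwork-class]
#' @param path output path
#' @param format `"sif"`, `"graphml"` or `"csv"`
#' @return `path`, invisibly
#' @export
exportNetwork <- function(network, path, format = c("sif", "graphml", "csv")) {
    format <- match.arg(format)
    g <- network@graph
    el <- igraph::as_data_frame(g, what = "edges")
    nodes <- igraph::as_data_frame(g, what = "vertices")
    names(nodes)[names(nodes) == "name"] <- "node"
    if (format == "sif") {
        writeLines(paste(el$from, "phosphorylates", el$to, sep = "\t"), path)
        utils::write.csv(nodes, paste0(path, ".nodes.csv"),
                         row.names = FALSE, quote = FALSE)
    } else if (format == "graphml") {
        igraph::write_graph(g, path, format = "graphml")
    } else {
        utils::write.csv(el, path, row.names = FALSE, quote = FALSE)
        utils::write.csv(nodes, paste0(path, ".nodes.csv"),
                         row.names = FALSE, quote = FALSE)
    }
    invisible(path)
}

#' Read back a GraphML export as a local network
#' @param path GraphML path
#' @return a [LocalNetwork-class]
#' @export
readNetworkGraphML <- function(path) {
    g <- igraph::read_graph(path, format = "graphml")
    members <- igraph::V(g)$name[igraph::V(g)$role == "member"]
    methods::new("LocalNetwork", graph = g, members = members,
                 neurons = "imported", provenance = list())
}

#' Overlay functionality and neuron networks on the background graph
#'
#' Annotates every background node with its functionality class within a
#' phase (any -1 call -> `weakening`, any +1 -> `strengthening`, both ->
#' `both`, otherwise `unclassified`) across the supplied condition matrices,
#' and every edge with the signs of the neuron networks it appears in
#' (`weakening`, `strengthening`, `both`, or `background` when it belongs to
#' no neuron network). A neuron network's sign is the sign of the summed
#' member calls within the phase.
#'
#' @param background a [BackgroundNetwork-class]
#' @param matrices list of [FunctionalityMatrix-class] (one per condition)
#' @param networks list of [LocalNetwork-class]
#' @param phase integer vector of window indices
#' @return the background `igraph` with vertex attribute `class` and edge
#'   attribute `class`
#' @export
overlayBackground <- function(background, matrices, networks, phase) {
    nw <- length(matrices[[1]]@grid@midpoints)
    if (any(phase < 1L | phase > nw))
        stop("phase outside the window grid (1..", nw, ")")
    g <- background@graph
    nodeClass <- function(k) {
        hasNeg <- FALSE; hasPos <- FALSE
        for (m in matrices) {
            if (!k %in% rownames(m@calls)) next
            row <- m@calls[k, phase]
            hasNeg <- hasNeg || any(row == -1L)
            hasPos <- hasPos || any(row == 1L)
        }
        if (hasNeg && hasPos) "both"
        else if (hasNeg) "weakening"
        else if (hasPos) "strengthening"
        else "unclassified"
    }
    g <- igraph::set_vertex_attr(g, "class",
        value = vapply(igraph::V(g)$name, nodeClass, character(1)))
    netSign <- function(net) {
        vals <- unlist(lapply(matrices, function(m) {
            ks <- intersect(net@members, rownames(m@calls))
            m@calls[ks, phase]
        }))
        s <- sum(vals)
        if (s < 0) "weakening" else if (s > 0) "strengthening" else "both"
    }
    edgeKey <- function(gr) {
        el <- igraph::as_data_frame(gr, what = "edges")
        paste(el$from, el$to, sep = "\r")
    }
    bgKeys <- edgeKey(g)
    eClass <- rep("background", length(bgKeys))
    for (net in networks) {
        s <- netSign(net)
        hit <- bgKeys %in% edgeKey(net@graph)
        eClass[hit & eClass == "background"] <- s
        eClass[hit & !eClass %in% c("background", s)] <- "both"
    }
    igraph::set_edge_attr(g, "class", value = eClass)
}
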