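pspFixture <- function(path, rows) {
    writeLines(c("kinase-substrate dataset", "",
                 paste("GENE", "KIN_ORGANISM", "SUB_GENE", "SUB_ORGANISM",
                       "SUB_MOD_RSD", sep = "\t"),
                 rows), path)
    path
}

test_that("kinase-substrate loading filters organism, kinome and phosphosites", {
    path <- withr::local_tempfile(fileext = ".tsv")
    rows <- c("AKT1\thuman\tGSK3B\thuman\tS9",
              "AKT1\thuman\tGSK3B\thuman\tS21",      # second site, same edge
              "AKT1\tmouse\tGSK3B\tmouse\tS9",       # wrong organism
              "MAPK1\thuman\tRPS6KA1\thuman\tT359",
              "SRC\thuman\tCTNNB1\thuman\tY86",      # substrate not a kinase
              "SRC\thuman\tSRC\thuman\tY419")        # autophosphorylation
    pspFixture(path, rows)
    kinome <- c("AKT1", "GSK3B", "MAPK1", "RPS6KA1", "SRC")
    bg <- loadKinaseSubstrate(path, organism = "human", kinome = kinome)
    g <- networkGraph(bg)
    expect_equal(igraph::ecount(g), 3L)
    expect_true(igraph::are_adjacent(g, "SRC", "SRC"))
    expect_true(igraph::are_adjacent(g, "AKT1", "GSK3B"))
    expect_equal(bg@provenance$rows_total, 6L)
    expect_equal(bg@provenance$rows_organism, 5L)

    badPath <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("GENE\tSUB_GENE", "AKT1\tGSK3B"), badPath)
    expect_error(loadKinaseSubstrate(badPath, kinome = kinome),
                 "KIN_ORGANISM")
    emptyPath <- withr::local_tempfile(fileext = ".tsv")
    pspFixture(emptyPath, "AKT1\tyeast\tGSK3B\tyeast\tS9")
    expect_warning(empty <- loadKinaseSubstrate(emptyPath, kinome = kinome),
                   "no kinase-kinase edges")
    expect_equal(igraph::ecount(networkGraph(empty)), 0L)
})

test_that("synonym tables remap gene symbols before filtering", {
    path <- withr::local_tempfile(fileext = ".tsv")
    pspFixture(path, "PKB\thuman\tGSK3B\thuman\tS9")
    syn <- data.frame(from = "PKB", to = "AKT1")
    bg <- loadKinaseSubstrate(path, kinome = c("AKT1", "GSK3B"),
                              synonyms = syn)
    expect_true(igraph::are_adjacent(networkGraph(bg), "AKT1", "GSK3B"))
})

test_that("the bundled kinome list loads and contains canonical kinases", {
    kinome <- humanKinome()
    expect_gt(length(kinome), 400)
    expect_true(all(c("MAPK1", "MAPK14", "MAPKAPK2", "MAP2K1", "SRC",
                      "AKT1", "PRKCA") %in% kinome))
    expect_false(anyDuplicated(kinome) > 0)
})

test_that("local networks are unions of shortest paths with inferred labels", {
    bg <- backgroundFromEdges(
        data.frame(from = c("A", "B"), to = c("B", "C")), c("A", "B", "C"))
    net <- buildLocalNetwork(c("A", "C"), bg)
    g <- networkGraph(net)
    expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
    expect_equal(igraph::ecount(g), 2L)
    expect_equal(igraph::V(g)$role[igraph::V(g)$name == "B"], "inferred")

    # diamond: both length-3 routes included
    bgd <- backgroundFromEdges(
        data.frame(from = c("A", "A", "B", "C"), to = c("B", "C", "D", "D")),
        LETTERS[1:4])
    netd <- buildLocalNetwork(c("A", "D"), bgd)
    expect_equal(igraph::vcount(networkGraph(netd)), 4L)
    expect_equal(igraph::ecount(networkGraph(netd)), 4L)

    # disconnected members: no network
    bgx <- backgroundFromEdges(
        data.frame(from = "X", to = "Z"), c("X", "Y", "Z", "W"))
    expect_null(buildLocalNetwork(c("X", "W"), bgx))

    # singleton with / without autophosphorylation
    bgs <- backgroundFromEdges(
        data.frame(from = c("S", "T"), to = c("S", "U")), c("S", "T", "U"))
    nets <- buildLocalNetwork("S", bgs)
    expect_equal(igraph::vcount(networkGraph(nets)), 1L)
    expect_null(buildLocalNetwork("T", bgs))
})

test_that("local networks match the brute-force all-shortest-paths oracle", {
    for (i in 1:100) {
        rg <- randomDigraph(sample(4:12, 1), 0.25, seed = 1000 + i)
        bg <- backgroundFromEdges(rg$edges, rg$nodes)
        members <- sample(rg$nodes, sample(2:4, 1))
        net <- buildLocalNetwork(members, bg)
        want <- bruteLocalEdges(rg$edges, rg$nodes, members)
        if (is.null(want)) {
            expect_null(net)
        } else {
            el <- igraph::as_data_frame(networkGraph(net), what = "edges")
            got <- paste(el$from, el$to)
            expect_setequal(got, paste(want[, 1], want[, 2]))
        }
    }
})

test_that("inferred nodes lie strictly inside paths", {
    for (i in 1:25) {
        rg <- randomDigraph(10, 0.25, seed = 2000 + i)
        bg <- backgroundFromEdges(rg$edges, rg$nodes)
        net <- buildLocalNetwork(sample(rg$nodes, 3), bg)
        if (is.null(net)) next
        g <- networkGraph(net)
        inferred <- igraph::V(g)[igraph::V(g)$role == "inferred"]
        if (length(inferred)) {
            expect_true(all(igraph::degree(g, inferred, mode = "in") >= 1))
            expect_true(all(igraph::degree(g, inferred, mode = "out") >= 1))
        }
    }
    succeed()
})

test_that("adding a member never removes edges from a local network", {
    for (i in 1:20) {
        rg <- randomDigraph(10, 0.3, seed = 3000 + i)
        bg <- backgroundFromEdges(rg$edges, rg$nodes)
        members <- sample(rg$nodes, 3)
        extra <- sample(setdiff(rg$nodes, members), 1)
        n1 <- buildLocalNetwork(members, bg)
        n2 <- buildLocalNetwork(c(members, extra), bg)
        if (is.null(n1)) next
        e1 <- igraph::as_data_frame(networkGraph(n1), what = "edges")
        e2 <- igraph::as_data_frame(networkGraph(n2), what = "edges")
        expect_true(all(paste(e1$from, e1$to) %in% paste(e2$from, e2$to)))
    }
    succeed()
})

test_that("composite networks pool neuron members", {
    bg <- backgroundFromEdges(
        data.frame(from = c("A", "B"), to = c("B", "C")), c("A", "B", "C"))
    profiles <- matrix(c(1, 1, -1, -1), 2, 2, byrow = TRUE,
                       dimnames = list(c("A", "C"), NULL))
    map <- trainSOM(profiles, somConfig(rows = 2, cols = 1, seed = 3))
    assignment <- assignNeurons(map, profiles)
    tb <- neuronTable(assignment)
    neurons <- lapply(seq_len(nrow(tb)),
                      function(r) c(tb$neuron_i[r], tb$neuron_j[r]))
    comp <- compositeNetwork(neurons, assignment, bg)
    expect_setequal(igraph::V(networkGraph(comp))$name, c("A", "B", "C"))
    # single neuron is identical to buildLocalNetwork on its members
    one <- compositeNetwork(neurons[1], assignment, bg)
    direct <- buildLocalNetwork(tb$kinase[1], bg)
    expect_identical(is.null(one), is.null(direct))
})

test_that("network statistics use the kinase-count path convention", {
    bg <- backgroundFromEdges(
        data.frame(from = c("A", "B"), to = c("B", "C")), c("A", "B", "C"))
    net <- buildLocalNetwork(c("A", "C"), bg)
    st <- networkStats(net)
    expect_equal(st$max_path_nodes, 3L)
    expect_equal(st$n_nodes, 3L)
    expect_equal(st$n_edges, 2L)
    expect_equal(st$n_inferred, 1L)

    loop <- backgroundFromEdges(data.frame(from = "S", to = "S"), "S")
    expect_equal(networkStats(buildLocalNetwork("S", loop))$max_path_nodes, 1L)
})

test_that("max path length equals exhaustive all-pairs BFS on random DAGs", {
    for (i in 1:20) {
        rg <- randomDigraph(10, 0.25, seed = 4000 + i)
        bg <- backgroundFromEdges(rg$edges, rg$nodes)
        net <- buildLocalNetwork(sample(rg$nodes, 4), bg)
        if (is.null(net)) next
        g <- networkGraph(net)
        nodes <- igraph::V(g)$name
        el <- igraph::as_data_frame(g, what = "edges")
        adj <- lapply(setNames(nm = nodes), function(v) el$to[el$from == v])
        best <- 0
        for (a in nodes) {
            d <- bfsDistances(adj, nodes, a)
            best <- max(best, max(d[is.finite(d)]))
        }
        expect_equal(networkStats(net)$max_path_nodes, as.integer(best) + 1L)
    }
    succeed()
})

test_that("a simple directed path of n nodes scores n", {
    for (n in c(2, 5, 8)) {
        nodes <- sprintf("P%d", seq_len(n))
        bg <- backgroundFromEdges(
            data.frame(from = nodes[-n], to = nodes[-1]), nodes)
        net <- buildLocalNetwork(c(nodes[1], nodes[n]), bg)
        expect_equal(networkStats(net)$max_path_nodes, n)
    }
})

test_that("network exports round-trip and carry node attributes", {
    bg <- backgroundFromEdges(
        data.frame(from = c("A", "B"), to = c("B", "C")), c("A", "B", "C"))
    net <- buildLocalNetwork(c("A", "C"), bg)

    sif <- withr::local_tempfile(fileext = ".sif")
    exportNetwork(net, sif, "sif")
    lines <- readLines(sif)
    expect_length(lines, 2L)
    expect_true(all(grepl("\tphosphorylates\t", lines)))
    nodes <- read.csv(paste0(sif, ".nodes.csv"))
    expect_equal(nodes$role[nodes$node == "B"], "inferred")

    gml <- withr::local_tempfile(fileext = ".graphml")
    exportNetwork(net, gml, "graphml")
    back <- readNetworkGraphML(gml)
    g0 <- networkGraph(net); g1 <- networkGraph(back)
    expect_setequal(igraph::V(g1)$name, igraph::V(g0)$name)
    e0 <- igraph::as_data_frame(g0); e1 <- igraph::as_data_frame(g1)
    expect_setequal(paste(e1$from, e1$to), paste(e0$from, e0$to))
    expect_setequal(networkMembers(back), c("A", "C"))

    expect_error(exportNetwork(net, sif, "dot"), "arg")
})

test_that("background overlay classifies nodes and edges by phase calls", {
    grid <- enumerateWindows(8, width = 5, fine_span = 8)
    calls <- rbind(A = c(-1L, -1L, 0L, 0L),
                   B = c(0L, 0L, 0L, 0L),
                   C = c(1L, 1L, 0L, 0L),
                   D = c(-1L, 0L, 1L, 0L))
    colnames(calls) <- as.character(windowMidpoints(grid))
    m <- methods::new("FunctionalityMatrix", calls = calls,
                      condition = "c1", grid = grid)
    bg <- backgroundFromEdges(
        data.frame(from = c("A", "B", "C", "A"), to = c("B", "C", "D", "D")),
        LETTERS[1:4])
    netW <- buildLocalNetwork(c("A", "C"), bg)   # weakening member A
    netS <- buildLocalNetwork(c("C", "D"), bg)   # strengthening members
    ann <- overlayBackground(bg, list(m), list(netW, netS), phase = 1:2)
    vclass <- setNames(igraph::V(ann)$class, igraph::V(ann)$name)
    expect_equal(unname(vclass["A"]), "weakening")
    expect_equal(unname(vclass["B"]), "unclassified")
    expect_equal(unname(vclass["C"]), "strengthening")
    expect_equal(unname(vclass["D"]), "weakening")  # only -1 inside phase 1:2
    el <- igraph::as_data_frame(ann, what = "edges")
    # B->C lies on both the weakening and the strengthening network
    expect_equal(el$class[el$from == "B" & el$to == "C"], "both")
    expect_equal(el$class[el$from == "A" & el$to == "D"], "background")

    expect_error(overlayBackground(bg, list(m), list(), phase = 9:10),
                 "outside")
    # empty phase classification: all nodes unclassified
    ann2 <- overlayBackground(bg, list(m), list(), phase = 4)
    expect_true(all(igraph::V(ann2)$class %in% c("unclassified")))
})
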