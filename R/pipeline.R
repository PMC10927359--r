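## End-to-end orchestration: staged pipeline over a single YAML/list
## configuration, with a run manifest recording seeds, digests and timings.

#' Default pipeline configuration
#'
#' One list with per-stage sections; every threshold of the underlying
#' modules is surfaced here. Stages read their inputs from the run directory
#' written by earlier stages (or from paths given in the config).
#'
#' @param seed master seed; each stochastic stage derives its own seed from
#'   it
#' @return nested configuration list
#' @export
pipelineConfig <- function(seed = 1L) {
    list(
        seed = as.integer(seed),
        simulate = list(n_inhibitors = 28, n_kinases = 60, replicates = 3,
                        background_p = 0.08),
        auc = list(total_min = 360, width = 5, fine_step = 1,
                   fine_span = 120, coarse_step = 5,
                   baseline_mode = "delta"),
        tkir = list(alpha = 0.9, nlambda = 50, tol = 1e-8,
                    condition = "synthetic"),
        som = list(rows = 6, cols = 6, sigma = 1.0, learning_rate = 0.5),
        networks = list(min_members = 1),
        report = list()
    )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the structure of [pipelineConfig()]
#' @return configuration list (defaults filled in for absent fields)
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- pipelineConfig(seed = user$seed %||% 1L)
    for (sec in intersect(names(user), names(cfg))) {
        if (is.list(cfg[[sec]]) && is.list(user[[sec]])) {
            for (k in names(user[[sec]])) cfg[[sec]][[k]] <- user[[sec]][[k]]
        } else {
            cfg[[sec]] <- user[[sec]]
        }
    }
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
        stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg
}

.stageSeed <- function(cfg, offset) (cfg$seed * 101L + offset) %% 2147483647L

#' Run pipeline stages
#'
#' Executes the requested stages in order, writing each stage's artifacts to
#' `outdir` and a JSON run manifest (config snapshot, derived seeds, input
#' digests, stage timings) at `outdir/manifest.json`. Stages:
#' \describe{
#'   \item{simulate}{synthetic plate, panel, background TSV, ground truth}
#'   \item{auc}{baseline normalization, window grid, AUC matrix CSV}
#'   \item{tkir}{per-window elastic-net fits, functionality matrix CSV}
#'   \item{som}{SOM training, assignment CSV, distance map CSV}
#'   \item{networks}{per-neuron local networks, GraphML + SIF, stats CSV}
#'   \item{report}{recovery scores against the simulated ground truth (JSON)}
#' }
#'
#' @param stages character vector from
#'   `c("simulate","auc","tkir","som","networks","report")`
#' @param config configuration list (see [pipelineConfig()]) or a YAML path
#' @param outdir run directory (created if absent)
#' @return invisibly, a list with the stage results and the manifest
#' @export
runPipeline <- function(stages = c("simulate", "auc", "tkir", "som",
                                   "networks", "report"),
                        config = pipelineConfig(), outdir = tempfile("run")) {
    if (is.character(config)) config <- readPipelineConfig(config)
    known <- c("simulate", "auc", "tkir", "som", "networks", "report")
    if (length(bad <- setdiff(stages, known)))
        stop("unknown stage(s): ", paste(bad, collapse = ", "))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    state <- list()
    manifest <- list(config = config, seeds = list(), timings = list(),
                     digests = list(),
                     resources = list(kinome = "inst/extdata/human_kinome.txt"))
    tic <- function() proc.time()[["elapsed"]]

    for (stage in known[known %in% stages]) {
        t0 <- tic()
        state <- switch(stage,
            simulate = .stageSimulate(state, config, outdir, manifest),
            auc = .stageAUC(state, config, outdir),
            tkir = .stageTkir(state, config, outdir),
            som = .stageSOM(state, config, outdir),
            networks = .stageNetworks(state, config, outdir),
            report = .stageReport(state, config, outdir))
        manifest$timings[[stage]] <- round(tic() - t0, 3)
        manifest$seeds[[stage]] <- state$last_seed
    }
    for (f in list.files(outdir, full.names = TRUE)) {
        if (basename(f) != "manifest.json" && !dir.exists(f))
            manifest$digests[[basename(f)]] <- unname(tools::md5sum(f))
    }
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(c(state, list(manifest = manifest, outdir = outdir)))
}

.stageSimulate <- function(state, config, outdir, manifest) {
    sc <- config$simulate
    seed <- .stageSeed(config, 1L)
    cfg <- simConfig(n_inhibitors = sc$n_inhibitors,
                     n_kinases = sc$n_kinases,
                     replicates = sc$replicates,
                     total_min = config$auc$total_min, seed = seed)
    sim <- simulateScreen(cfg)
    panel <- sim$truth$panel
    kinases <- colnames(panel@activity)
    bg <- simulateBackground(kinases, p = sc$background_p,
                             planted_paths = list(c("KIN01", "KIN02", "KIN03")),
                             seed = seed + 1L)
    writePlate(sim$plate, file.path(outdir, "plate.csv"))
    writePanel(panel, file.path(outdir, "panel.csv"))
    writeKinaseSubstrate(bg, file.path(outdir, "background.tsv"),
                         organism = "synthetic")
    writeFunctionalityMatrix(sim$truth$matrix,
                             file.path(outdir, "truth_matrix.csv"))
    state$plate <- sim$plate
    state$panel <- panel
    state$background <- bg
    state$truth <- sim$truth
    state$last_seed <- seed
    state
}

.stageAUC <- function(state, config, outdir) {
    ac <- config$auc
    if (is.null(state$plate)) {
        path <- ac$plate %||% file.path(outdir, "plate.csv")
        if (!file.exists(path)) stop("auc stage: plate file not found: ", path)
        state$plate <- readPlate(path)
    }
    plate <- normalizeBaseline(state$plate, mode = ac$baseline_mode)
    grid <- enumerateWindows(ac$total_min, width = ac$width,
                             fine_step = ac$fine_step,
                             fine_span = ac$fine_span,
                             coarse_step = ac$coarse_step)
    auc <- computeAUCMatrix(plate, grid)
    writeAUCMatrix(auc, file.path(outdir, "auc_normalized.csv"))
    state$grid <- grid
    state$auc <- auc
    state$last_seed <- NULL
    state
}

.stageTkir <- function(state, config, outdir) {
    tc <- config$tkir
    if (is.null(state$auc)) stop("tkir stage requires the auc stage")
    if (is.null(state$panel)) {
        path <- tc$panel %||% file.path(outdir, "panel.csv")
        if (!file.exists(path))
            stop("tkir stage: panel file not found: ", path)
        state$panel <- readPanel(path)
    }
    fm <- buildFunctionalityMatrix(
        state$auc, state$panel,
        config = tkirConfig(alpha = tc$alpha, nlambda = tc$nlambda,
                            tol = tc$tol),
        condition = tc$condition)
    writeFunctionalityMatrix(fm, file.path(outdir, "functionality_matrix.csv"))
    state$functionality <- fm
    state$last_seed <- NULL
    state
}

.stageSOM <- function(state, config, outdir) {
    so <- config$som
    if (is.null(state$functionality)) stop("som stage requires the tkir stage")
    calls <- state$functionality@calls
    profiles <- calls[rowSums(calls != 0L) > 0L, , drop = FALSE]
    if (nrow(profiles) == 0L) stop("no kinases were predicted; nothing to cluster")
    seed <- .stageSeed(config, 4L)
    map <- trainSOM(profiles, somConfig(rows = so$rows, cols = so$cols,
                                        sigma = so$sigma,
                                        learning_rate = so$learning_rate,
                                        seed = seed))
    assignment <- assignNeurons(map, profiles)
    writeAssignment(assignment, file.path(outdir, "som_assignment.csv"))
    utils::write.csv(distanceMap(map), file.path(outdir, "som_distance_map.csv"),
                     row.names = FALSE)
    state$som <- map
    state$assignment <- assignment
    state$last_seed <- seed
    state
}

.stageNetworks <- function(state, config, outdir) {
    if (is.null(state$assignment)) stop("networks stage requires the som stage")
    if (is.null(state$background))
        stop("networks stage: no background network loaded")
    occ <- occupiedNeurons(state$assignment)
    nets <- list()
    stats <- NULL
    for (r in seq_len(nrow(occ))) {
        n <- c(occ$neuron_i[r], occ$neuron_j[r])
        if (occ$members[r] < config$networks$min_members) next
        label <- sprintf("(%d,%d)", n[1], n[2])
        net <- buildLocalNetwork(neuronMembers(state$assignment, n),
                                 state$background,
                                 functionality = state$functionality,
                                 neurons = label)
        if (is.null(net)) next
        nets[[label]] <- net
        fname <- sprintf("network_%d_%d", n[1], n[2])
        exportNetwork(net, file.path(outdir, paste0(fname, ".graphml")),
                      "graphml")
        exportNetwork(net, file.path(outdir, paste0(fname, ".sif")), "sif")
        st <- networkStats(net)
        stats <- rbind(stats, data.frame(neuron = label,
                                         max_path_nodes = st$max_path_nodes,
                                         n_nodes = st$n_nodes,
                                         n_edges = st$n_edges,
                                         n_inferred = st$n_inferred))
    }
    # global view: composite network pooling every occupied neuron
    allNeurons <- lapply(seq_len(nrow(occ)),
                         function(r) c(occ$neuron_i[r], occ$neuron_j[r]))
    comp <- compositeNetwork(allNeurons, state$assignment, state$background,
                             functionality = state$functionality)
    if (!is.null(comp)) {
        exportNetwork(comp, file.path(outdir, "network_composite.graphml"),
                      "graphml")
        st <- networkStats(comp)
        stats <- rbind(stats, data.frame(neuron = "composite",
                                         max_path_nodes = st$max_path_nodes,
                                         n_nodes = st$n_nodes,
                                         n_edges = st$n_edges,
                                         n_inferred = st$n_inferred))
        nets[["composite"]] <- comp
    }
    if (!is.null(stats))
        utils::write.csv(stats, file.path(outdir, "network_stats.csv"),
                         row.names = FALSE, quote = FALSE)
    state$networks <- nets
    state$network_stats <- stats
    state$last_seed <- NULL
    state
}

.stageReport <- function(state, config, outdir) {
    if (is.null(state$functionality) || is.null(state$truth))
        stop("report stage requires tkir results and simulated ground truth")
    scores <- scoreRecovery(state$functionality, state$truth)
    switches <- detectSwitchKinases(state$functionality)
    report <- list(
        recovery = scores[c("precision", "recall", "sign_accuracy", "jaccard")],
        true_positives = scores$true_positives,
        false_positives = scores$false_positives,
        switch_kinases = switches,
        occupied_neurons = if (!is.null(state$assignment))
            nrow(occupiedNeurons(state$assignment)) else NA,
        n_networks = length(state$networks %||% list()))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    state$report <- report
    state$last_seed <- NULL
    state
}
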