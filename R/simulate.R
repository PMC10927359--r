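## Synthetic screens with planted ground truth: residual-activity panels,
## disruption/recovery kinetics with additive time-windowed signed kinase
## effects, background graphs with planted pathways, and recovery scoring.

#' Planted kinase effect
#'
#' One signed, time-windowed contribution of a kinase to the cell index.
#' Under full inhibition of the kinase the cell index changes by
#' `-sign * magnitude` inside `[t_on, t_off]`; partial inhibition scales
#' linearly with `1 - activity/100`, matching the linear-combination
#' assumption of kinase regression.
#'
#' @param kinase kinase name (must exist in the panel)
#' @param sign +1 barrier-strengthening, -1 barrier-weakening
#' @param t_on,t_off active window (minutes after inhibitor addition)
#' @param magnitude effect size in cell-index units per unit inhibition (> 0)
#' @return a `plantedEffect` list
#' @export
plantedEffect <- function(kinase, sign, t_on, t_off, magnitude) {
    stopifnot(sign %in% c(-1, 1), t_on < t_off, magnitude > 0)
    structure(list(kinase = kinase, sign = sign, t_on = t_on, t_off = t_off,
                   magnitude = magnitude), class = "plantedEffect")
}

#' Default planted effects of the reference synthetic screen
#'
#' Six kinases with signed, windowed effects spanning early disruption,
#' mid-course and late recovery, including one switch kinase (KIN05:
#' weakening at 5-30 min, strengthening at 100-140 min).
#'
#' @return list of [plantedEffect()]s
#' @export
defaultPlantedEffects <- function() {
    list(
        plantedEffect("KIN01", -1,   5,  30, 0.30),
        plantedEffect("KIN02", -1,  20,  90, 0.25),
        plantedEffect("KIN03", +1,  10,  60, 0.30),
        plantedEffect("KIN04", +1, 150, 300, 0.25),
        plantedEffect("KIN05", -1,   5,  30, 0.25),
        plantedEffect("KIN05", +1, 100, 140, 0.25),
        plantedEffect("KIN06", -1, 200, 360, 0.20)
    )
}

#' Synthetic-screen configuration
#'
#' Defaults mirror the reference screen design: 28 inhibitors in triplicate,
#' a 6-h course sampled every minute for 2 h then every 5 min, an acute
#' barrier drop of 0.4 index units bottoming out 25 min after thrombin, and
#' measurement noise at 5% of the smallest planted effect magnitude.
#'
#' @param n_inhibitors,n_kinases screen dimensions
#' @param replicates replicate wells per inhibitor
#' @param drop_depth,t_min,thrombin_time control-curve parameters: depth of
#'   the disruption dip (index units), time of minimum (min after thrombin),
#'   thrombin addition time (min relative to inhibitor addition)
#' @param noise_sd Gaussian measurement noise sd (index units); `NULL` means
#'   5% of the smallest planted magnitude
#' @param total_min span after inhibitor addition
#' @param seed RNG seed
#' @return a list of settings
#' @export
simConfig <- function(n_inhibitors = 28, n_kinases = 60, replicates = 3,
                      drop_depth = 0.4, t_min = 25, thrombin_time = -6,
                      noise_sd = NULL, total_min = 360, seed = 1L) {
    stopifnot(n_inhibitors >= 3, replicates >= 1, is.null(noise_sd) || noise_sd >= 0)
    list(n_inhibitors = n_inhibitors, n_kinases = n_kinases,
         replicates = replicates, drop_depth = drop_depth, t_min = t_min,
         thrombin_time = thrombin_time, noise_sd = noise_sd,
         total_min = total_min, seed = as.integer(seed))
}

#' Simulate an inhibitor x kinase residual-activity panel
#'
#' Residual activities are drawn uniformly in \[0, 100\]; as an
#' identifiability guarantee every kinase is inhibited below 50% residual
#' activity by at least `min_hitters` inhibitors. Deterministic given the
#' seed.
#'
#' @param config see [simConfig()]
#' @param min_hitters minimum number of inhibitors hitting each kinase below
#'   50% residual activity
#' @return a [KinaseActivityPanel-class]
#' @export
simulatePanel <- function(config = simConfig(), min_hitters = 2L) {
    if (min_hitters > config$n_inhibitors)
        stop("cannot guarantee ", min_hitters, " hitters with only ",
             config$n_inhibitors, " inhibitors")
    set.seed(config$seed)
    m <- matrix(stats::runif(config$n_inhibitors * config$n_kinases, 0, 100),
                nrow = config$n_inhibitors,
                dimnames = list(sprintf("INH%02d", seq_len(config$n_inhibitors)),
                                sprintf("KIN%02d", seq_len(config$n_kinases))))
    for (k in seq_len(config$n_kinases)) {
        hitters <- which(m[, k] < 50)
        need <- min_hitters - length(hitters)
        if (need > 0L) {
            fix <- sample(setdiff(seq_len(config$n_inhibitors), hitters), need)
            m[fix, k] <- stats::runif(need, 0, 50)
        }
    }
    methods::new("KinaseActivityPanel", activity = m)
}

## thrombin disruption/recovery curve: gamma-style dip reaching -depth at
## t_min minutes after thrombin, recovering toward baseline
.controlCurve <- function(t, thrombin_time, depth, t_min) {
    ts <- t - thrombin_time
    ifelse(ts <= 0, 0, -depth * (ts / t_min) * exp(1 - ts / t_min))
}

#' Simulate a full screen plate with known ground truth
#'
#' The control wells follow a disruption/recovery curve `c(t)`; inhibitor
#' `i`'s signal is `c(t) - sum_k sign_k * mag_k * (1 - a_ik/100) *
#' 1[t in window_k]` plus independent Gaussian noise per replicate well.
#' Inhibiting a barrier-strengthening (+1) kinase therefore lowers the cell
#' index inside its active window, so regressing window AUC on residual
#' activity recovers a positive slope, matching the tKiR sign convention.
#'
#' @param config see [simConfig()]
#' @param planted list of [plantedEffect()]s; defaults to
#'   [defaultPlantedEffects()]
#' @param panel a [KinaseActivityPanel-class]; defaults to
#'   `simulatePanel(config)`
#' @return list with `plate` (a [TimeSeriesPlate-class], control id `DMSO`)
#'   and `truth` (planted effects, panel, and the true kinase x window
#'   functionality matrix on the default grid)
#' @export
simulateScreen <- function(config = simConfig(),
                           planted = defaultPlantedEffects(),
                           panel = NULL) {
    if (is.null(panel)) panel <- simulatePanel(config)
    a <- panel@activity
    bad <- setdiff(vapply(planted, `[[`, character(1), "kinase"), colnames(a))
    if (length(bad))
        stop("planted kinase(s) absent from panel: ",
             paste(unique(bad), collapse = ", "))
    if (is.null(config$noise_sd)) {
        mags <- vapply(planted, `[[`, numeric(1), "magnitude")
        config$noise_sd <- if (length(mags)) 0.05 * min(mags) else 0
    }
    set.seed(config$seed + 1L)
    # pre-thrombin baseline, then 1-min sampling for 2 h, 5-min for 4 h
    fineEnd <- min(120, config$total_min)
    times <- c(seq(config$thrombin_time - 4, -1, by = 1),
               seq(0, fineEnd, by = 1),
               if (config$total_min > fineEnd)
                   seq(fineEnd + 5, config$total_min, by = 5))
    times <- sort(unique(times))
    ctrl <- .controlCurve(times, config$thrombin_time, config$drop_depth,
                          config$t_min)
    inhibitors <- c(rownames(a), "DMSO")
    signal <- matrix(rep(ctrl, each = length(inhibitors)),
                     nrow = length(inhibitors),
                     dimnames = list(inhibitors, times))
    for (pe in planted) {
        inWin <- times >= pe$t_on & times <= pe$t_off
        inhibition <- 1 - a[, pe$kinase] / 100      # per-inhibitor scaling
        for (i in rownames(a))
            signal[i, inWin] <- signal[i, inWin] -
                pe$sign * pe$magnitude * inhibition[[i]]
    }
    wells <- expand.grid(replicate = seq_len(config$replicates),
                         inhibitor = inhibitors, stringsAsFactors = FALSE)
    wells <- data.frame(
        well = sprintf("W%03d", seq_len(nrow(wells))),
        inhibitor = wells$inhibitor, condition = "synthetic",
        replicate = wells$replicate, stringsAsFactors = FALSE)
    values <- signal[wells$inhibitor, , drop = FALSE] +
        matrix(stats::rnorm(nrow(wells) * length(times), sd = config$noise_sd),
               nrow = nrow(wells))
    rownames(values) <- wells$well
    plate <- methods::new("TimeSeriesPlate", times = times, wells = wells,
                          values = values,
                          annotations = list(
                              thrombin_time_min = config$thrombin_time,
                              inhibitor_time_min = 0,
                              tnf_preconditioned = FALSE,
                              control_id = "DMSO"))
    grid <- enumerateWindows(config$total_min)
    truth <- list(planted = planted, panel = panel,
                  matrix = trueFunctionalityMatrix(planted, grid))
    list(plate = plate, truth = truth)
}

#' True functionality matrix implied by planted effects
#'
#' A window is active for a planted effect when its midpoint lies within the
#' effect's `[t_on, t_off]` span.
#'
#' @param planted list of [plantedEffect()]s
#' @param grid a [WindowGrid-class]
#' @return a [FunctionalityMatrix-class] over the planted kinases
#' @export
trueFunctionalityMatrix <- function(planted, grid) {
    kinases <- unique(vapply(planted, `[[`, character(1), "kinase"))
    calls <- matrix(0L, nrow = length(kinases),
                    ncol = length(grid@midpoints),
                    dimnames = list(kinases, as.character(grid@midpoints)))
    for (pe in planted) {
        act <- grid@midpoints >= pe$t_on & grid@midpoints <= pe$t_off
        calls[pe$kinase, act] <- as.integer(pe$sign)
    }
    methods::new("FunctionalityMatrix", calls = calls, condition = "truth",
                 grid = grid)
}

#' Simulate a background kinase graph with planted pathways
#'
#' Erdos-Renyi directed graph over `nodes` with edge probability `p`; every
#' consecutive edge of every planted chain is guaranteed present.
#'
#' @param nodes character vector of node names
#' @param p background edge probability
#' @param planted_paths list of character vectors (node chains)
#' @param seed RNG seed
#' @return a [BackgroundNetwork-class] (organism tag `"synthetic"`)
#' @export
simulateBackground <- function(nodes, p = 0.1, planted_paths = list(),
                               seed = 1L) {
    if (length(planted_paths) &&
        any(vapply(planted_paths, length, integer(1)) < 1L))
        stop("planted chains must be nonempty")
    nodes <- unique(c(nodes, unlist(planted_paths)))
    set.seed(seed)
    pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
    keep <- stats::runif(nrow(pairs)) < p
    edges <- pairs[keep, , drop = FALSE]
    for (chain in planted_paths) {
        if (length(chain) < 2L) next
        edges <- rbind(edges, data.frame(from = chain[-length(chain)],
                                         to = chain[-1],
                                         stringsAsFactors = FALSE))
    }
    edges <- unique(edges)
    g <- if (nrow(edges)) {
        igraph::graph_from_data_frame(edges, directed = TRUE,
                                      vertices = data.frame(name = nodes))
    } else {
        igraph::make_empty_graph(directed = TRUE) + igraph::vertices(nodes)
    }
    methods::new("BackgroundNetwork", graph = g, organism = "synthetic",
                 provenance = list(p = p, planted_paths = planted_paths,
                                   seed = seed))
}

#' Score recovery of planted kinase effects
#'
#' Kinase-level detection with window slack: a predicted kinase (any nonzero
#' call) counts as a true positive when it is planted and its called windows
#' overlap the true active windows dilated by `slack_windows` on both sides.
#' Precision is 1 by convention when nothing is predicted. Sign accuracy is
#' the fraction of true positives whose calls inside the dilated true span
#' all carry the planted sign. The window-overlap Jaccard per true positive
#' is `|pred windows ∩ dilated true| / |pred ∪ true|`, averaged over true
#' positives.
#'
#' @param predicted a [FunctionalityMatrix-class]
#' @param truth the `truth` element of [simulateScreen()]
#' @param slack_windows tolerance on window boundaries (windows)
#' @return list with `precision`, `recall`, `sign_accuracy`, `jaccard`,
#'   `true_positives`, `false_positives`, `false_negatives`
#' @export
scoreRecovery <- function(predicted, truth, slack_windows = 2L) {
    tm <- truth$matrix
    if (!isTRUE(all.equal(predicted@grid@midpoints, tm@grid@midpoints)))
        stop("predicted and true matrices use different window grids")
    dilate <- function(idx, n) {
        if (!length(idx)) return(integer(0))
        sort(unique(unlist(lapply(idx, function(i)
            max(1L, i - slack_windows):min(n, i + slack_windows)))))
    }
    nw <- ncol(predicted@calls)
    predKinases <- rownames(predicted@calls)[rowSums(predicted@calls != 0L) > 0L]
    # only planted kinases with at least one active window can be recovered
    planted <- rownames(tm@calls)[rowSums(tm@calls != 0L) > 0L]
    tp <- character(0); signOK <- logical(0); jac <- numeric(0)
    for (k in intersect(predKinases, planted)) {
        predWin <- which(predicted@calls[k, ] != 0L)
        trueWin <- which(tm@calls[k, ] != 0L)
        dil <- dilate(trueWin, nw)
        inter <- intersect(predWin, dil)
        if (!length(inter)) next
        tp <- c(tp, k)
        # per-window sign agreement against the nearest true call
        agree <- vapply(inter, function(w) {
            near <- trueWin[which.min(abs(trueWin - w))]
            predicted@calls[k, w] == tm@calls[k, near]
        }, logical(1))
        signOK <- c(signOK, all(agree))
        jac <- c(jac, length(inter) / length(union(predWin, trueWin)))
    }
    fp <- setdiff(predKinases, tp)
    fn <- setdiff(planted, tp)
    list(precision = if (length(predKinases)) length(tp) / length(predKinases) else 1,
         recall = length(tp) / length(planted),
         sign_accuracy = if (length(tp)) mean(signOK) else NA_real_,
         jaccard = if (length(tp)) mean(jac) else 0,
         true_positives = tp, false_positives = fp, false_negatives = fn)
}

#' Write a background network in the kinase-substrate TSV dialect
#'
#' Produces a file readable by [loadKinaseSubstrate()]: two preamble lines,
#' then tab-separated `GENE`, `KIN_ORGANISM`, `SUB_GENE`, `SUB_ORGANISM`.
#'
#' @param background a [BackgroundNetwork-class]
#' @param path output path
#' @param organism organism label to stamp on every row
#' @return `path`, invisibly
#' @export
writeKinaseSubstrate <- function(background, path, organism = "human") {
    el <- igraph::as_data_frame(background@graph, what = "edges")
    lines <- c("synthetic kinase-substrate table", "",
               paste("GENE", "KIN_ORGANISM", "SUB_GENE", "SUB_ORGANISM",
                     sep = "\t"),
               paste(el$from, organism, el$to, organism, sep = "\t"))
    writeLines(lines, path)
    invisible(path)
}
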