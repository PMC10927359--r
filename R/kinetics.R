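## Impedance kinetics: plate I/O, baseline normalization, sliding windows,
## trapezoidal AUC and the per-window 0/100 linear transform.

#' Read a plate of cell-index kinetics from CSV
#'
#' Long-format CSV with columns `time_min`, `well`, `inhibitor`, `condition`,
#' `replicate`, `cell_index`. Plate-level metadata is carried as commented
#' header lines of the form `# key=value` (recognized keys:
#' `thrombin_time_min`, `inhibitor_time_min`, `tnf_preconditioned`,
#' `control_id`). Every well must be sampled at every time.
#'
#' @param path path to the plate CSV.
#' @param control_id inhibitor id of the vehicle control; overrides the file
#'   metadata when given.
#' @return a [TimeSeriesPlate-class]
#' @export
readPlate <- function(path, control_id = NULL) {
    if (!file.exists(path))
        stop("plate file not found: ", path)
    lines <- readLines(path)
    metaLines <- grep("^#", lines, value = TRUE)
    meta <- list(thrombin_time_min = 0, inhibitor_time_min = 0,
                 tnf_preconditioned = FALSE, control_id = "DMSO")
    for (ml in metaLines) {
        kv <- sub("^#\\s*", "", ml)
        if (!grepl("=", kv, fixed = TRUE)) next
        key <- trimws(sub("=.*", "", kv))
        val <- trimws(sub("^[^=]*=", "", kv))
        if (key %in% c("thrombin_time_min", "inhibitor_time_min"))
            meta[[key]] <- as.numeric(val)
        else if (key == "tnf_preconditioned")
            meta[[key]] <- tolower(val) %in% c("true", "1", "yes")
        else meta[[key]] <- val
    }
    if (!is.null(control_id)) meta$control_id <- control_id
    df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                          stringsAsFactors = FALSE)
    req <- c("time_min", "well", "inhibitor", "condition", "replicate",
             "cell_index")
    missing <- setdiff(req, names(df))
    if (length(missing))
        stop("plate CSV lacks required column(s): ",
             paste(missing, collapse = ", "))
    if (anyDuplicated(df[, c("time_min", "well")]))
        stop("duplicated (time, well) rows in plate CSV")
    times <- sort(unique(df$time_min))
    wellIds <- unique(df$well)
    values <- matrix(NA_real_, nrow = length(wellIds), ncol = length(times),
                     dimnames = list(wellIds, times))
    values[cbind(match(df$well, wellIds), match(df$time_min, times))] <-
        df$cell_index
    if (anyNA(values))
        stop("missing cell-index values: every well must be sampled at every time")
    first <- df[!duplicated(df$well), ]
    wells <- data.frame(well = first$well, inhibitor = first$inhibitor,
                        condition = first$condition,
                        replicate = as.integer(first$replicate),
                        stringsAsFactors = FALSE)
    methods::new("TimeSeriesPlate", times = times, wells = wells,
                 values = values, annotations = meta)
}

#' Write a plate of cell-index kinetics to CSV
#'
#' Inverse of [readPlate()]: long format with a commented metadata header.
#'
#' @param plate a [TimeSeriesPlate-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writePlate <- function(plate, path) {
    a <- plate@annotations
    hdr <- c(sprintf("# thrombin_time_min=%g", a$thrombin_time_min %||% 0),
             sprintf("# inhibitor_time_min=%g", a$inhibitor_time_min %||% 0),
             sprintf("# tnf_preconditioned=%s",
                     tolower(isTRUE(a$tnf_preconditioned))),
             sprintf("# control_id=%s", a$control_id))
    w <- plate@wells
    df <- data.frame(
        time_min = rep(plate@times, each = nrow(w)),
        well = rep(w$well, times = length(plate@times)),
        inhibitor = rep(w$inhibitor, times = length(plate@times)),
        condition = rep(w$condition, times = length(plate@times)),
        replicate = rep(w$replicate, times = length(plate@times)),
        cell_index = as.vector(plate@values),
        stringsAsFactors = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Normalize cell index to baseline zero
#'
#' Sets the cell index to 0 in every well at the last sampled timepoint
#' strictly before thrombin addition, either by subtracting the reference
#' value (`mode = "delta"`) or by dividing by it and subtracting one
#' (`mode = "ratio_minus_one"`). Both conventions anchor the baseline at 0;
#' `delta` preserves the cell-index scale and is the default.
#'
#' @param plate a [TimeSeriesPlate-class]
#' @param mode `"delta"` or `"ratio_minus_one"`
#' @return a baseline-normalized [TimeSeriesPlate-class]
#' @export
normalizeBaseline <- function(plate, mode = c("delta", "ratio_minus_one")) {
    mode <- match.arg(mode)
    tt <- plate@annotations$thrombin_time_min
    if (is.null(tt)) stop("plate lacks thrombin_time_min annotation")
    pre <- which(plate@times < tt)
    if (!length(pre))
        stop("no sample strictly before thrombin addition (t = ", tt, " min)")
    refIdx <- max(pre)
    ref <- plate@values[, refIdx]
    v <- plate@values
    if (mode == "delta") {
        v <- v - ref
    } else {
        if (any(ref == 0))
            stop("ratio_minus_one undefined: zero cell index at reference time")
        v <- sweep(v, 1L, ref, "/") - 1
    }
    methods::initialize(plate, values = v)
}

#' Enumerate sliding AUC windows
#'
#' Fixed-width windows with starts `0, fine_step, ...` up to
#' `fine_span - width`, then `fine_span, fine_span + coarse_step, ...` up to
#' `total_min - width`. Spans not divisible by the step truncate the last
#' start downward. Midpoint = start + width/2.
#'
#' @param total_min total span after inhibitor addition (minutes)
#' @param width window width (minutes)
#' @param fine_step,fine_span,coarse_step stepping scheme (minutes)
#' @return a [WindowGrid-class]
#' @export
enumerateWindows <- function(total_min, width = 5, fine_step = 1,
                             fine_span = 120, coarse_step = 5) {
    if (width > total_min)
        stop("window width (", width, ") exceeds total span (", total_min, ")")
    if (fine_span > total_min)
        fine_span <- total_min
    starts <- numeric(0)
    if (fine_span >= width)
        starts <- seq(0, fine_span - width, by = fine_step)
    if (total_min - width >= fine_span)
        starts <- c(starts, seq(fine_span, total_min - width, by = coarse_step))
    starts <- unique(starts)
    methods::new("WindowGrid", starts = starts, ends = starts + width,
                 midpoints = starts + width / 2, width = width)
}

#' Trapezoidal AUC of one well over one window
#'
#' Exact integral of the piecewise-linear interpolant of `(times, values)`
#' over the closed interval `[start, end]`; values at window boundaries not
#' on the sample grid are linearly interpolated.
#'
#' @param times,values one well's samples (times strictly increasing)
#' @param start,end window bounds (minutes), within the sampled range
#' @return the trapezoidal AUC (numeric scalar)
#' @export
windowAUC <- function(times, values, start, end) {
    if (length(times) < 2L) stop("need at least two samples")
    if (start < times[1] || end > times[length(times)])
        stop(sprintf("window [%g, %g] outside sampled range [%g, %g]",
                     start, end, times[1], times[length(times)]))
    if (end < start) stop("window end before start")
    knots <- sort(unique(c(start, end, times[times > start & times < end])))
    v <- stats::approx(times, values, xout = knots, method = "linear")$y
    sum(diff(knots) * (v[-1] + v[-length(v)]) / 2)
}

#' Normalize one window's AUC column to the 0/100 scale
#'
#' Subtracts the control AUC from every inhibitor's AUC, then maps linearly so
#' that the most negative delta becomes 0 and the control (delta 0) becomes
#' 100. When no delta is negative the affine map is undefined; the column
#' falls back to `100 + delta` (unscaled offset, control anchor preserved)
#' with a warning.
#'
#' @param raw_column named numeric vector of per-inhibitor AUCs in one window
#' @param control_id name of the control entry
#' @return list with `normalized` (named vector) and `min_delta`
#' @export
normalizeAUCColumn <- function(raw_column, control_id) {
    if (!control_id %in% names(raw_column))
        stop("control '", control_id, "' missing from AUC column")
    delta <- raw_column - raw_column[[control_id]]
    m <- min(delta)
    if (m < 0) {
        # anchor exactness: (delta - m)/(-m) is exactly 1 for the control
        normalized <- 100 * ((delta - m) / (-m))
    } else {
        warning("no negative control-subtracted AUC in window; ",
                "using unscaled offset 100 + delta")
        normalized <- 100 + delta
    }
    list(normalized = normalized, min_delta = m)
}

#' Compute the per-window AUC matrix of a screen
#'
#' Averages cell index across replicate wells per inhibitor, computes the
#' trapezoidal AUC in every window of `grid` (window clock: t = 0 at inhibitor
#' addition) and applies the 0/100 linear transform per window.
#'
#' @param plate a baseline-normalized [TimeSeriesPlate-class]
#' @param grid a [WindowGrid-class]
#' @param average_replicates average replicate wells per inhibitor before AUC
#'   (default); set `FALSE` to keep well-level rows labeled
#'   `inhibitor.replicate`.
#' @return an [AUCMatrix-class]
#' @export
computeAUCMatrix <- function(plate, grid, average_replicates = TRUE) {
    ctrl <- plate@annotations$control_id
    w <- plate@wells
    if (average_replicates) {
        groups <- split(seq_len(nrow(w)), w$inhibitor)
        series <- t(vapply(groups, function(idx)
            colMeans(plate@values[idx, , drop = FALSE]),
            numeric(length(plate@times))))
    } else {
        labels <- paste(w$inhibitor, w$replicate, sep = ".")
        series <- plate@values
        rownames(series) <- labels
        ctrlRows <- which(w$inhibitor == ctrl)
        # replicate-level fitting still needs a single control row
        series <- rbind(series,
                        matrix(colMeans(plate@values[ctrlRows, , drop = FALSE]),
                               nrow = 1, dimnames = list(ctrl, NULL)))
    }
    raw <- matrix(NA_real_, nrow = nrow(series), ncol = length(grid@starts),
                  dimnames = list(rownames(series),
                                  as.character(grid@midpoints)))
    for (j in seq_along(grid@starts)) {
        raw[, j] <- apply(series, 1L, function(v)
            windowAUC(plate@times, v, grid@starts[j], grid@ends[j]))
    }
    normalized <- raw
    minDelta <- numeric(ncol(raw))
    for (j in seq_len(ncol(raw))) {
        nc <- normalizeAUCColumn(raw[, j], ctrl)
        normalized[, j] <- nc$normalized
        minDelta[j] <- nc$min_delta
    }
    methods::new("AUCMatrix", raw = raw, normalized = normalized,
                 controlId = ctrl, minDelta = minDelta,
                 noiseSD = .aucNoiseSD(plate, grid), grid = grid)
}

## Per-window noise sd of a control-subtracted mean AUC, from replicate
## spread: pooled within-inhibitor sd of replicate-well AUCs, propagated
## through the replicate mean and the control subtraction. Zeros when no
## inhibitor has >= 2 replicate wells.
.aucNoiseSD <- function(plate, grid) {
    w <- plate@wells
    groups <- split(seq_len(nrow(w)), w$inhibitor)
    reps <- vapply(groups, length, integer(1))
    nWin <- length(grid@starts)
    if (!any(reps >= 2L)) return(numeric(nWin))
    ctrl <- plate@annotations$control_id
    out <- numeric(nWin)
    for (j in seq_len(nWin)) {
        wellAUC <- apply(plate@values, 1L, function(v)
            windowAUC(plate@times, v, grid@starts[j], grid@ends[j]))
        ss <- 0; df <- 0L
        for (idx in groups) {
            if (length(idx) < 2L) next
            a <- wellAUC[idx]
            ss <- ss + sum((a - mean(a))^2)
            df <- df + length(idx) - 1L
        }
        sdWell <- sqrt(ss / df)
        # sem of the per-inhibitor mean, plus the control mean's sem
        out[j] <- sdWell * sqrt(1 / mean(reps) + 1 / reps[[ctrl]])
    }
    out
}

#' Write an AUC or functionality matrix with midpoint column headers
#'
#' CSV with row labels in the first column and window midpoints as the
#' remaining column headers.
#'
#' @param m an [AUCMatrix-class] (writes the normalized matrix) or a plain
#'   matrix with midpoint colnames
#' @param path output path
#' @return `path`, invisibly
#' @export
writeAUCMatrix <- function(m, path) {
    x <- if (methods::is(m, "AUCMatrix")) m@normalized else m
    df <- data.frame(id = rownames(x), x, check.names = FALSE)
    colnames(df)[1] <- ""
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
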