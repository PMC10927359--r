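## Time-resolved kinase regression (tKiR): per-window elastic-net fits of
## normalized AUC on residual kinase activity, functionality calling, switch
## kinases, phase summaries and cross-condition correlation.

#' Read an inhibitor x kinase residual-activity panel from CSV
#'
#' Inhibitors as rows (first column), kinases as columns, percent remaining
#' activity in \[0, 100\].
#'
#' @param path panel CSV path
#' @return a [KinaseActivityPanel-class]
#' @export
readPanel <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    methods::new("KinaseActivityPanel", activity = m)
}

#' Write a residual-activity panel to CSV
#' @param panel a [KinaseActivityPanel-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writePanel <- function(panel, path) {
    df <- data.frame(inhibitor = rownames(panel@activity), panel@activity,
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Default tKiR fitting configuration
#'
#' @param alpha elastic-net mixing (1 = lasso); near-lasso default keeps the
#'   per-window kinase sets sparse.
#' @param lambda fixed penalty; `NULL` selects lambda at the minimum
#'   cross-validation error over `nlambda` values on a log grid.
#' @param nlambda size of the lambda grid.
#' @param nfolds CV folds; `NULL` means leave-one-out (preferred at the
#'   screen's n of ~28 observations).
#' @param tol nonzero-coefficient tolerance: |beta| > tol counts as selected.
#' @param thresh glmnet convergence threshold.
#' @param min_effect_sigma minimum resolvable effect, in multiples of the
#'   per-window noise sd of a control-subtracted AUC: a kinase is called in a
#'   window only when its full-inhibition effect, de-scaled to raw AUC units
#'   (cell-index x minutes), exceeds `min_effect_sigma` times the
#'   replicate-estimated noise floor. Ignored when the AUC matrix carries no
#'   replicate noise estimate. Set to 0 for the bare nonzero-coefficient
#'   rule.
#' @return a list of settings for [fitWindow()]
#' @export
tkirConfig <- function(alpha = 0.9, lambda = NULL, nlambda = 50,
                       nfolds = NULL, tol = 1e-8, thresh = 1e-10,
                       min_effect_sigma = 3) {
    list(alpha = alpha, lambda = lambda, nlambda = nlambda,
         nfolds = nfolds, tol = tol, thresh = thresh,
         min_effect_sigma = min_effect_sigma)
}

#' Elastic-net fit of one window's normalized AUC on the panel
#'
#' Minimizes `(1/2n) sum(y - b0 - x b)^2 + lambda (alpha |b|_1 +
#' (1-alpha)/2 |b|_2^2)` with residual activity rescaled to fraction activity
#' in \[0, 1\], no column standardization and an unpenalized intercept.
#' Lambda is chosen at minimum leave-one-out CV error unless fixed in
#' `config`. Fold order is deterministic, so results are reproducible for a
#' given seed.
#'
#' @param y named numeric vector of normalized AUCs, one per inhibitor
#'   (control excluded upstream)
#' @param panel a [KinaseActivityPanel-class]
#' @param config see [tkirConfig()]
#' @param window window index recorded in the result
#' @return a [WindowFit-class]
#' @export
fitWindow <- function(y, panel, config = tkirConfig(), window = NA_integer_) {
    if (anyNA(y)) stop("NaN/NA in response")
    x <- panel@activity[names(y), , drop = FALSE] / 100
    n <- length(y)
    if (n < 3L) stop("need at least 3 observations")
    kinases <- colnames(x)
    zeroFit <- function() {
        beta <- stats::setNames(numeric(length(kinases)), kinases)
        methods::new("WindowFit", window = as.integer(window),
                     intercept = mean(y), coefficients = beta,
                     lambda = Inf, alpha = config$alpha,
                     cvError = numeric(0), selected = character(0))
    }
    if (stats::sd(y) == 0) return(zeroFit())
    cvError <- numeric(0)
    if (is.null(config$lambda)) {
        nfolds <- config$nfolds %||% n
        cv <- glmnet::cv.glmnet(x, y, alpha = config$alpha,
                                nlambda = config$nlambda,
                                foldid = rep_len(seq_len(nfolds), n),
                                standardize = FALSE, thresh = config$thresh,
                                grouped = FALSE)
        lambda <- cv$lambda.min
        cvError <- cv$cvm
        fit <- glmnet::glmnet(x, y, alpha = config$alpha, lambda = cv$lambda,
                              standardize = FALSE, thresh = config$thresh)
        cf <- stats::coef(fit, s = lambda, exact = FALSE)
    } else {
        lambda <- config$lambda
        # descending path ending at the requested lambda: glmnet's warm starts
        # make the terminal solution accurate even at lambda = 0
        path <- sort(unique(c(lambda, lambda + 10^seq(1, -4) * max(1, lambda))),
                     decreasing = TRUE)
        fit <- glmnet::glmnet(x, y, alpha = config$alpha, lambda = path,
                              standardize = FALSE, thresh = config$thresh,
                              maxit = 1e7)
        # the requested lambda terminates the path; read it off directly
        idx <- which.min(abs(fit$lambda - lambda))
        cf <- c(fit$a0[idx], as.numeric(fit$beta[, idx]))
    }
    beta <- stats::setNames(as.numeric(cf)[-1], kinases)
    methods::new("WindowFit", window = as.integer(window),
                 intercept = as.numeric(cf)[1], coefficients = beta,
                 lambda = lambda, alpha = config$alpha, cvError = cvError,
                 selected = kinases[abs(beta) > config$tol])
}

#' Call kinase functionality from coefficient signs
#'
#' Positive coefficients mean barrier-strengthening (+1), negative mean
#' barrier-weakening (-1), coefficients within tolerance of zero mean not
#' predicted (0).
#'
#' @param fit a [WindowFit-class]
#' @param tol nonzero tolerance
#' @return named integer vector in \{-1, 0, +1\}
#' @export
classifyFunctionality <- function(fit, tol = 1e-8) {
    beta <- fit@coefficients
    calls <- integer(length(beta))
    calls[beta > tol] <- 1L
    calls[beta < -tol] <- -1L
    stats::setNames(calls, names(beta))
}

#' Build the kinase x window functionality matrix
#'
#' One elastic-net fit per window of the normalized AUC matrix (control row
#' excluded from the response), assembled column-wise into calls in
#' \{-1, 0, +1\}.
#'
#' @param auc an [AUCMatrix-class]
#' @param panel a [KinaseActivityPanel-class]
#' @param config see [tkirConfig()]
#' @param condition condition label stored on the result
#' @param drop_never_selected drop kinase rows that are zero in every window
#' @return a [FunctionalityMatrix-class]
#' @export
buildFunctionalityMatrix <- function(auc, panel, config = tkirConfig(),
                                     condition = "condition",
                                     drop_never_selected = FALSE) {
    inhibitors <- setdiff(rownames(auc@normalized), auc@controlId)
    if (!all(inhibitors %in% rownames(panel@activity)))
        stop("panel is missing inhibitors: ",
             paste(setdiff(inhibitors, rownames(panel@activity)), collapse = ", "))
    kinases <- colnames(panel@activity)
    nw <- ncol(auc@normalized)
    calls <- matrix(0L, nrow = length(kinases), ncol = nw,
                    dimnames = list(kinases, colnames(auc@normalized)))
    # de-scaling of a normalized-AUC coefficient back to raw AUC units:
    # normalized = 100 (delta - m) / (-m) when m < 0, else 100 + delta
    descale <- ifelse(auc@minDelta < 0, -auc@minDelta / 100, 1)
    sigma <- config$min_effect_sigma %||% 0
    for (j in seq_len(nw)) {
        y <- auc@normalized[inhibitors, j]
        fit <- tryCatch(fitWindow(y, panel, config, window = j),
                        error = function(e)
                            stop("window ", j, " (midpoint ",
                                 auc@grid@midpoints[j], " min): ",
                                 conditionMessage(e)))
        callsJ <- classifyFunctionality(fit, tol = config$tol)
        floorJ <- sigma * auc@noiseSD[j]
        if (floorJ > 0) {
            rawEffect <- abs(fit@coefficients) * descale[j]
            callsJ[rawEffect <= floorJ] <- 0L
        }
        calls[, j] <- callsJ
    }
    if (drop_never_selected)
        calls <- calls[rowSums(calls != 0L) > 0L, , drop = FALSE]
    methods::new("FunctionalityMatrix", calls = calls, condition = condition,
                 grid = auc@grid)
}

#' Kinases called with both signs over time
#'
#' A switch kinase is predicted barrier-weakening in some windows and
#' barrier-strengthening in others.
#'
#' @param m a [FunctionalityMatrix-class]
#' @return character vector of switch-kinase names
#' @export
detectSwitchKinases <- function(m) {
    has_neg <- rowSums(m@calls == -1L) > 0L
    has_pos <- rowSums(m@calls == 1L) > 0L
    rownames(m@calls)[has_neg & has_pos]
}

#' Per-phase counts of weakening/strengthening kinases
#'
#' For each named phase (a range of window indices) counts kinases with any
#' -1 (weakening) and any +1 (strengthening) call inside the phase. When a
#' second matrix is supplied, also returns Venn counts (common / unique) of
#' the per-phase kinase sets across the two conditions.
#'
#' @param m a [FunctionalityMatrix-class]
#' @param phases named list of integer window-index ranges, e.g.
#'   `list(early = 1:30, late = 100:164)`
#' @param m2 optional second [FunctionalityMatrix-class] to compare against
#' @return a data.frame of per-phase counts; with `m2`, a list with elements
#'   `counts` (both conditions) and `venn`
#' @export
summarizePhases <- function(m, phases, m2 = NULL) {
    nw <- ncol(m@calls)
    for (ph in phases)
        if (any(ph < 1L | ph > nw))
            stop("phase outside the window grid (1..", nw, ")")
    phaseSets <- function(mm) {
        lapply(phases, function(ph) {
            sub <- mm@calls[, ph, drop = FALSE]
            list(weakening = rownames(sub)[rowSums(sub == -1L) > 0L],
                 strengthening = rownames(sub)[rowSums(sub == 1L) > 0L])
        })
    }
    s1 <- phaseSets(m)
    counts <- data.frame(
        phase = names(phases),
        condition = m@condition,
        weakening = vapply(s1, function(s) length(s$weakening), integer(1)),
        strengthening = vapply(s1, function(s) length(s$strengthening), integer(1)),
        row.names = NULL)
    if (is.null(m2)) return(counts)
    s2 <- phaseSets(m2)
    counts2 <- data.frame(
        phase = names(phases),
        condition = m2@condition,
        weakening = vapply(s2, function(s) length(s$weakening), integer(1)),
        strengthening = vapply(s2, function(s) length(s$strengthening), integer(1)),
        row.names = NULL)
    venn <- do.call(rbind, lapply(names(phases), function(ph) {
        do.call(rbind, lapply(c("weakening", "strengthening"), function(sign) {
            a <- s1[[ph]][[sign]]; b <- s2[[ph]][[sign]]
            data.frame(phase = ph, sign = sign,
                       common = length(intersect(a, b)),
                       only_first = length(setdiff(a, b)),
                       only_second = length(setdiff(b, a)),
                       union = length(union(a, b)))
        }))
    }))
    list(counts = rbind(counts, counts2), venn = venn)
}

#' Per-window Pearson correlation between two conditions
#'
#' Correlates the two conditions' per-inhibitor normalized AUC vectors within
#' each window, excluding the vehicle control by default (its fixed anchor at
#' 100 would inflate r).
#'
#' @param aucA,aucB [AUCMatrix-class] objects on identical inhibitor sets and
#'   window grids
#' @param exclude_control drop the control row before correlating
#' @return numeric vector of r per window (named by midpoint); windows with
#'   zero variance give `NA` with a warning
#' @export
conditionCorrelation <- function(aucA, aucB, exclude_control = TRUE) {
    if (!identical(sort(rownames(aucA@normalized)),
                   sort(rownames(aucB@normalized))))
        stop("inhibitor sets differ")
    if (!isTRUE(all.equal(aucA@grid@midpoints, aucB@grid@midpoints)))
        stop("window grids differ")
    rows <- rownames(aucA@normalized)
    if (exclude_control) rows <- setdiff(rows, aucA@controlId)
    a <- aucA@normalized[rows, , drop = FALSE]
    b <- aucB@normalized[rows, , drop = FALSE]
    r <- vapply(seq_len(ncol(a)), function(j) {
        if (stats::sd(a[, j]) == 0 || stats::sd(b[, j]) == 0)
            return(NA_real_)
        stats::cor(a[, j], b[, j])
    }, numeric(1))
    if (anyNA(r))
        warning("zero variance in ", sum(is.na(r)),
                " window(s); r undefined there")
    stats::setNames(r, colnames(a))
}

#' Write a functionality matrix in the midpoint-header CSV dialect
#'
#' Kinases as rows, window midpoints as column headers, cells in
#' \{-1, 0, 1\}.
#'
#' @param m a [FunctionalityMatrix-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeFunctionalityMatrix <- function(m, path) {
    df <- data.frame(kinase = rownames(m@calls), m@calls, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a functionality matrix written by [writeFunctionalityMatrix()]
#'
#' @param path CSV path (kinase rows, midpoint headers)
#' @param width window width used to reconstruct the grid
#' @param condition condition label
#' @return a [FunctionalityMatrix-class]
#' @export
readFunctionalityMatrix <- function(path, width = 5, condition = "condition") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "integer"
    mid <- as.numeric(colnames(m))
    grid <- methods::new("WindowGrid", starts = mid - width / 2,
                         ends = mid + width / 2, midpoints = mid,
                         width = width)
    methods::new("FunctionalityMatrix", calls = m, condition = condition,
                 grid = grid)
}
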