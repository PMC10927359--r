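## Validation-side quantification: densitometry fold changes, the
## activation-call decision rule, and relative qPCR expression (2^-ddCT).

#' Densitometry fold changes relative to a reference timepoint
#'
#' Band intensities of the target are first normalized to the loading
#' control within each (replicate, timepoint), then to the same ratio at the
#' reference timepoint of that replicate, so the reference fold change is
#' exactly 1.
#'
#' @param table data.frame with columns `replicate`, `timepoint`,
#'   `target_intensity`, `loading_intensity`
#' @param reference the reference timepoint label (media-only baseline)
#' @return data.frame with columns `replicate`, `timepoint`, `fold_change`
#' @export
foldChange <- function(table, reference = "0") {
    req <- c("replicate", "timepoint", "target_intensity", "loading_intensity")
    missing <- setdiff(req, names(table))
    if (length(missing))
        stop("densitometry table lacks column(s): ",
             paste(missing, collapse = ", "))
    if (any(table$loading_intensity <= 0))
        stop("non-positive loading-control intensity")
    if (any(table$target_intensity <= 0))
        stop("non-positive target intensity")
    out <- do.call(rbind, lapply(split(table, table$replicate), function(rep) {
        refRow <- rep[rep$timepoint == reference, , drop = FALSE]
        if (nrow(refRow) != 1L)
            stop("replicate ", rep$replicate[1],
                 ": reference timepoint '", reference, "' must appear exactly once")
        ratio <- rep$target_intensity / rep$loading_intensity
        refRatio <- refRow$target_intensity / refRow$loading_intensity
        data.frame(replicate = rep$replicate, timepoint = rep$timepoint,
                   fold_change = ratio / refRatio)
    }))
    rownames(out) <- NULL
    out
}

#' Activation call from replicate fold changes
#'
#' A kinase's activity at a timepoint is called different from the untreated
#' baseline when the t-test gives p < `alpha`, OR every biological replicate
#' reports a fold change of at least `1 + min_change`, OR every replicate
#' reports at most `1 - min_change`. The default test is a two-sided
#' one-sample t on log2 fold changes against 0; a two-sample t on raw
#' normalized intensities is available via `baseline`.
#'
#' @param fcs numeric vector of per-replicate fold changes (>= 2 values)
#' @param alpha significance level
#' @param min_change minimal consistent fractional change (0.20 = 20%)
#' @param baseline optional vector of untreated normalized intensities for a
#'   two-sample test (then `fcs` is interpreted as treated intensities)
#' @param use_ttest set `FALSE` to disable the t-test clause
#' @return list with `call` (logical), `evidence` (which clause fired:
#'   `"t-test"`, `"all_up"`, `"all_down"` or `"none"`), `p_value`
#' @export
activationCall <- function(fcs, alpha = 0.05, min_change = 0.20,
                           baseline = NULL, use_ttest = TRUE) {
    if (length(fcs) < 2L) stop("need at least 2 replicates")
    p <- NA_real_
    if (use_ttest) {
        p <- if (is.null(baseline)) {
            if (stats::sd(log2(fcs)) == 0 && mean(log2(fcs)) == 0) 1
            else stats::t.test(log2(fcs), mu = 0)$p.value
        } else {
            stats::t.test(fcs, baseline)$p.value
        }
    }
    evidence <- if (all(fcs >= 1 + min_change)) "all_up"
    else if (all(fcs <= 1 - min_change)) "all_down"
    else if (!is.na(p) && p < alpha) "t-test"
    else "none"
    list(call = evidence != "none", evidence = evidence, p_value = p)
}

#' Relative expression by the 2^-ddCT method
#'
#' `ddCT = (CT_target - CT_housekeeping)_test - (CT_target -
#' CT_housekeeping)_reference`; relative transcript abundance is
#' `2^-ddCT`.
#'
#' @param ct_target_test,ct_hk_test CT values in the test sample
#' @param ct_target_ref,ct_hk_ref CT values in the reference (control) sample
#' @return numeric scalar
#' @export
relativeExpression <- function(ct_target_test, ct_hk_test,
                               ct_target_ref, ct_hk_ref) {
    cts <- c(ct_target_test, ct_hk_test, ct_target_ref, ct_hk_ref)
    if (any(!is.finite(cts)) || any(cts <= 0))
        stop("CT values must be finite and positive")
    ddct <- (ct_target_test - ct_hk_test) - (ct_target_ref - ct_hk_ref)
    2^(-ddct)
}
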