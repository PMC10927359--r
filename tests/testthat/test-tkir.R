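toyPanel <- function(n = 28, p = 10, seed = 5) {
    set.seed(seed)
    act <- matrix(runif(n * p, 0, 100), n, p,
                  dimnames = list(sprintf("I%02d", 1:n),
                                  sprintf("K%02d", 1:p)))
    methods::new("KinaseActivityPanel", activity = act)
}

test_that("panel CSV round-trips", {
    panel <- toyPanel(5, 3)
    path <- withr::local_tempfile(fileext = ".csv")
    writePanel(panel, path)
    expect_equal(activityMatrix(readPanel(path)), activityMatrix(panel))
})

test_that("near-zero penalty reproduces the least-squares oracle", {
    panel <- toyPanel()
    x <- activityMatrix(panel) / 100
    set.seed(6)
    beta <- rnorm(ncol(x), 0, 3)
    y <- setNames(drop(x %*% beta) + 5 + rnorm(nrow(x), 0, 0.3), rownames(x))
    fit <- fitWindow(y, panel, tkirConfig(lambda = 0, thresh = 1e-20))
    ols <- coef(lm(y ~ x))
    expect_equal(unname(fit@coefficients), unname(ols[-1]), tolerance = 1e-6)
    expect_equal(fit@intercept, unname(ols[1]), tolerance = 1e-6)
})

test_that("a response proportional to one column selects only that kinase", {
    panel <- toyPanel()
    x <- activityMatrix(panel) / 100
    y <- setNames(10 * x[, 4], rownames(x))
    fit <- fitWindow(y, panel, tkirConfig(lambda = 0, thresh = 1e-20))
    expect_gt(fit@coefficients[4], 9.9)
    expect_lt(max(abs(fit@coefficients[-4])), 1e-6)
})

test_that("degenerate responses give empty or all-zero selections", {
    panel <- toyPanel()
    y <- setNames(rep(100, 28), rownames(activityMatrix(panel)))
    fit <- fitWindow(y, panel)
    expect_length(fit@selected, 0L)
    expect_true(all(fit@coefficients == 0))

    set.seed(7)
    y2 <- setNames(rnorm(28, 50, 20), rownames(activityMatrix(panel)))
    fit2 <- fitWindow(y2, panel, tkirConfig(lambda = 1e6))
    expect_true(all(abs(fit2@coefficients) < 1e-8))

    y2[3] <- NA
    expect_error(fitWindow(y2, panel), "NA")
})

test_that("functionality calls follow the coefficient sign rule", {
    fit <- methods::new("WindowFit", window = 1L, intercept = 0,
                        coefficients = c(A = 0.3, B = -0.3, C = 0,
                                         D = 5e-9),
                        lambda = 0.1, alpha = 0.9, cvError = numeric(0),
                        selected = c("A", "B"))
    calls <- classifyFunctionality(fit)
    expect_identical(calls, c(A = 1L, B = -1L, C = 0L, D = 0L))
})

test_that("calls never flip sign when the response is rescaled", {
    panel <- toyPanel()
    x <- activityMatrix(panel) / 100
    set.seed(8)
    y <- setNames(drop(x[, 1:2] %*% c(40, -30)) + rnorm(28, 0, 1),
                  rownames(x))
    f1 <- classifyFunctionality(fitWindow(y, panel))
    f2 <- classifyFunctionality(fitWindow(3 * y, panel))
    both <- f1 != 0L & f2 != 0L
    expect_true(all(f1[both] == f2[both]))
    expect_equal(f1[1:2], c(K01 = 1L, K02 = -1L))
})

test_that("switch kinases are rows carrying both signs", {
    grid <- enumerateWindows(20, fine_span = 20)
    calls <- rbind(A = c(-1L, -1L, 0L, 1L, rep(0L, 12)),
                   B = c(-1L, -1L, 0L, 0L, rep(0L, 12)),
                   C = rep(0L, 16),
                   D = c(1L, rep(0L, 14), -1L))
    colnames(calls) <- as.character(windowMidpoints(grid))
    m <- methods::new("FunctionalityMatrix", calls = calls,
                      condition = "toy", grid = grid)
    expect_setequal(detectSwitchKinases(m), c("A", "D"))

    # brute-force row scan on random matrices
    set.seed(9)
    for (i in 1:20) {
        rc <- matrix(sample(c(-1L, 0L, 1L), 20 * 16, replace = TRUE), 20, 16,
                     dimnames = list(sprintf("k%02d", 1:20),
                                     colnames(calls)))
        mm <- methods::new("FunctionalityMatrix", calls = rc,
                           condition = "r", grid = grid)
        brute <- rownames(rc)[apply(rc, 1, function(r)
            any(r == -1) && any(r == 1))]
        expect_setequal(detectSwitchKinases(mm), brute)
    }
})

test_that("phase summaries count kinases and obey set algebra", {
    grid <- enumerateWindows(10, fine_span = 10)
    calls <- rbind(A = c(-1L, 0L, 0L, 0L, 0L, 0L),
                   B = c(0L, 1L, 0L, 0L, 0L, 0L))
    colnames(calls) <- as.character(windowMidpoints(grid))
    m <- methods::new("FunctionalityMatrix", calls = calls,
                      condition = "c1", grid = grid)
    counts <- summarizePhases(m, list(all = 1:6))
    expect_equal(counts$weakening, 1L)
    expect_equal(counts$strengthening, 1L)

    m2 <- methods::new("FunctionalityMatrix", calls = calls,
                       condition = "c2", grid = grid)
    res <- summarizePhases(m, list(all = 1:6), m2)
    expect_equal(res$venn$common, res$venn$union)
    expect_equal(res$venn$only_first, c(0L, 0L))

    expect_error(summarizePhases(m, list(bad = 5:9)), "outside")
})

test_that("phase Venn counts match exhaustive set enumeration", {
    grid <- enumerateWindows(34, width = 5, fine_span = 34)
    set.seed(10)
    mk <- function(cond) {
        rc <- matrix(sample(c(-1L, 0L, 1L), 20 * 30, replace = TRUE), 20, 30,
                     dimnames = list(sprintf("k%02d", 1:20),
                                     as.character(windowMidpoints(grid))))
        methods::new("FunctionalityMatrix", calls = rc, condition = cond,
                     grid = grid)
    }
    mA <- mk("A"); mB <- mk("B")
    phases <- list(early = 1:10, mid = 11:20, late = 21:30)
    res <- summarizePhases(mA, phases, mB)
    for (r in seq_len(nrow(res$venn))) {
        row <- res$venn[r, ]
        ph <- phases[[row$phase]]
        val <- if (row$sign == "weakening") -1L else 1L
        setA <- rownames(functionalityCalls(mA))[
            rowSums(functionalityCalls(mA)[, ph] == val) > 0]
        setB <- rownames(functionalityCalls(mB))[
            rowSums(functionalityCalls(mB)[, ph] == val) > 0]
        expect_equal(row$common, length(intersect(setA, setB)))
        expect_equal(row$union, length(union(setA, setB)))
        # |A u B| = |A| + |B| - |A n B|
        expect_equal(row$union, length(setA) + length(setB) - row$common)
    }
})

test_that("cross-condition correlation handles identity, anti- and toy cases", {
    grid <- enumerateWindows(10, fine_span = 10)
    set.seed(14)
    raw <- matrix(rnorm(36), 6, 6,
                  dimnames = list(c("DMSO", paste0("I", 1:5)),
                                  as.character(windowMidpoints(grid))))
    mk <- function(normalized) methods::new("AUCMatrix",
        raw = raw, normalized = normalized, controlId = "DMSO",
        minDelta = rep(-1, 6), noiseSD = numeric(6), grid = grid)
    a <- mk(raw)
    expect_equal(unname(conditionCorrelation(a, a)), rep(1, 6))
    b <- mk(-raw + 200)
    expect_equal(unname(conditionCorrelation(a, b)), rep(-1, 6))

    # hand-computed Pearson r on a 5-inhibitor column pair
    xa <- raw[-1, 1]; xb <- raw[-1, 2]
    handR <- sum((xa - mean(xa)) * (xb - mean(xb))) /
        sqrt(sum((xa - mean(xa))^2) * sum((xb - mean(xb))^2))
    shift <- mk(cbind(raw[, 2], raw[, -1]))
    expect_equal(unname(conditionCorrelation(a, shift)[1]), handR)

    flat <- mk(matrix(5, 6, 6, dimnames = dimnames(raw)))
    expect_warning(r <- conditionCorrelation(a, flat), "zero variance")
    expect_true(all(is.na(r)))
})

test_that("functionality matrix CSV uses midpoint headers and round-trips", {
    run <- defaultScreenRun()
    path <- withr::local_tempfile(fileext = ".csv")
    writeFunctionalityMatrix(run$fm, path)
    hdr <- strsplit(readLines(path, n = 1), ",")[[1]]
    expect_equal(as.numeric(hdr[-1]), windowMidpoints(run$grid))
    back <- readFunctionalityMatrix(path)
    expect_equal(functionalityCalls(back), functionalityCalls(run$fm))
})
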