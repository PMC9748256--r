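test_that("orientation normalization reverses order and round-trips", {
    ss <- ScoreSet(c("a", "b"), c(0.01, 0.5), "sift-like",
                   orientation = "lower")
    norm <- normalizeOrientation(ss)
    sc <- scores(norm)
    expect_true(sc[["a"]] > sc[["b"]])       # 0.01 now maps above 0.5
    expect_identical(norm@orientation, "higher")
    ## already-normalized input is untouched
    hi <- ScoreSet("a", 1, orientation = "higher")
    expect_identical(normalizeOrientation(hi), hi)
    ## denormalizing a normalized threshold recovers the native value
    expect_equal(nativeScore(norm, scores(norm)[["a"]]), 0.01)
    expect_equal(nativeScore(hi, 1), 1)
    expect_error(ScoreSet(c("a", "a"), c(1, 2)), "unique")
})

test_that("window half-width satisfies the smallest-window definition", {
    ## a labeled score exactly at s with degenerate requirements
    st <- calibrationSettings(minLabeled = 1, minUnlabeledFrac = 0,
                              nBootstrap = 0)
    expect_equal(windowHalfwidth(2, c(0, 2, 5), settings = st), 0)
    ## labeled {0..4}, unlabeled {0..4}, s = 2: 3 labeled and half the
    ## unlabeled first fit at eps = 1
    st2 <- calibrationSettings(minLabeled = 3, minUnlabeledFrac = 0.5,
                               nBootstrap = 0)
    expect_equal(windowHalfwidth(2, 0:4, 0:4, st2), 1)
    ## duplicating labeled scores can never widen any window
    set.seed(5)
    lab <- rnorm(60)
    st3 <- calibrationSettings(minLabeled = 10, minUnlabeledFrac = 0,
                               nBootstrap = 0)
    e1 <- windowHalfwidth(lab, lab, settings = st3)
    e2 <- windowHalfwidth(lab, c(lab, lab), settings = st3,
                          range = range(lab))
    expect_true(all(e2 <= e1 + 1e-12))
    expect_error(windowHalfwidth(0, numeric()), "non-empty")
})

test_that("benign weight matches counts against the prior odds", {
    expect_equal(benignWeight(4000, 7834, 0.0441),
                 (4000 / 7834) / (0.0441 / (1 - 0.0441)))
    expect_equal(round(benignWeight(4000, 7834, 0.0441), 3), 11.068)
    ## counts already in prior proportion give weight 1
    p <- 0.2
    expect_equal(benignWeight(200, 200 / priorOdds(p), p), 1)
    expect_error(benignWeight(10, 0, 0.1), "nBenign")
})

test_that("prior-matching: windows mirroring the data composition return the prior", {
    ## every window spans all data, so each composition equals the full set
    set.seed(11)
    prior <- 0.0441
    path <- runif(30, 0.4, 0.6)
    ben <- runif(70, 0.4, 0.6)
    cur <- calibrateRaw(path, ben, prior = prior,
                        minLabeled = 100, minUnlabeledFrac = 0,
                        nBootstrap = 0, edgeScaling = "none")
    expect_true(all(abs(cur@posterior - prior) < 1e-9))
    expect_true(all(abs(cur@lrPlus - 1) < 1e-6))
})

test_that("degenerate windows behave: pure classes and fixed weight", {
    ## window containing only pathogenic variants: posterior 1, lr+ = Inf
    cur <- calibrateRaw(c(10, 10.1), c(0, 0.1), minLabeled = 2,
                        minUnlabeledFrac = 0, nBootstrap = 0, weight = 1,
                        edgeScaling = "none")
    expect_equal(cur@posterior[cur@score == 10.1],
                 1)
    expect_true(is.infinite(cur@lrPlus[length(cur@score)]))
    ## w = 1, window spanning everything: posterior = P / (P + B) = 0.5
    cur2 <- calibrateRaw(c(0.8, 0.9), c(0.1, 0.2), minLabeled = 4,
                         minUnlabeledFrac = 0, nBootstrap = 0, weight = 1,
                         edgeScaling = "none")
    expect_true(all(cur2@posterior == 0.5))
})

test_that("curve estimates match the brute-force oracle exactly", {
    set.seed(301)
    nBad <- 0L
    for (i in 1:120) {
        nP <- sample(2:20, 1)
        nB <- sample(2:20, 1)
        nU <- sample(0:30, 1)
        digits <- sample(c(1, 2, 8), 1)      # coarse rounding induces ties
        path <- round(rnorm(nP), digits)
        ben <- round(rnorm(nB), digits)
        unl <- round(rnorm(nU), digits)
        frac <- if (nU > 0) sample(c(0, 0.1, 0.4), 1) else 0
        edge <- sample(c("proportional", "none"), 1)
        minLab <- sample(1:min(6, nP + nB), 1)
        cur <- calibrateRaw(path, ben, unl, minLabeled = minLab,
                            minUnlabeledFrac = frac, nBootstrap = 0,
                            weight = 1, edgeScaling = edge)
        oracle <- bruteCurve(path, ben, unl, minLab, frac, 1, edge)
        if (!isTRUE(all.equal(oracle$epsilon, cur@epsilon,
                              tolerance = 1e-12)) ||
            !isTRUE(all.equal(oracle$posterior, cur@posterior,
                              tolerance = 1e-12)))
            nBad <- nBad + 1L
    }
    expect_identical(nBad, 0L)
})

test_that("missing scores are excluded from estimation", {
    lab <- makeLabeled(c(1, 2, NA), c(-1, NA, 0))
    cur <- calibrateScores(lab[, c("variant_key", "score")],
                           lab[, c("variant_key", "label")],
                           config = evidenceConfig(0.5, 1124),
                           settings = calibrationSettings(
                               minLabeled = 2, minUnlabeledFrac = 0,
                               nBootstrap = 0, weight = 1))
    expect_identical(length(cur@score), 4L)   # 2 path + 2 benign scores
})

test_that("bootstrap bounds are conservative, seeded and tightening", {
    set.seed(77)
    path <- rnorm(300, 1.5)
    ben <- rnorm(300)
    cur1 <- {
        lab <- makeLabeled(path, ben)
        calibrateScores(lab[, c("variant_key", "score")],
                        lab[, c("variant_key", "label")],
                        config = evidenceConfig(0.5, 1124),
                        settings = calibrationSettings(
                            minLabeled = 50, minUnlabeledFrac = 0,
                            nBootstrap = 200, weight = 1), seed = 9)
    }
    expect_true(all(cur1@boundPathogenic <= cur1@posterior + 1e-12))
    expect_true(all(cur1@boundBenign >= cur1@posterior - 1e-12))
    expect_true(all(cur1@boundPathogenic >= 0 & cur1@boundBenign <= 1))
    ## identical seed reproduces the bounds exactly
    lab <- makeLabeled(path, ben)
    cur2 <- calibrateScores(lab[, c("variant_key", "score")],
                            lab[, c("variant_key", "label")],
                            config = evidenceConfig(0.5, 1124),
                            settings = calibrationSettings(
                                minLabeled = 50, minUnlabeledFrac = 0,
                                nBootstrap = 200, weight = 1), seed = 9)
    expect_identical(cur1@boundPathogenic, cur2@boundPathogenic)
    ## all variants at one score with one label: bounds equal the estimate
    one <- calibrateRaw(rep(1, 60), rep(0, 60), minLabeled = 10,
                        minUnlabeledFrac = 0, nBootstrap = 50, weight = 1)
    at1 <- which(one@score == 1)
    expect_equal(one@boundPathogenic[at1], one@posterior[at1])
    expect_equal(one@boundBenign[at1], one@posterior[at1])
})

test_that("bound gap shrinks as the labeled sample grows", {
    gap <- sapply(c(100, 5000), function(n) {
        set.seed(123)
        lab <- makeLabeled(rnorm(n, 2), rnorm(n, 0))
        unl <- c(rnorm(n, 2), rnorm(n, 0))
        cur <- calibrateScores(lab[, c("variant_key", "score")],
                               lab[, c("variant_key", "label")], unl,
                               config = evidenceConfig(0.5, 1124),
                               settings = calibrationSettings(
                                   minLabeled = 50,
                                   minUnlabeledFrac = 0.05,
                                   nBootstrap = 100, weight = 1), seed = 4)
        mean(cur@posterior - cur@boundPathogenic)
    })
    expect_lt(gap[2], gap[1])
})

test_that("closed-form lr+ of equal-variance Gaussians is recovered", {
    ## N(2,1) vs N(0,1): lr+(s) = exp(2s - 2)
    set.seed(2024)
    n <- 20000
    lab <- makeLabeled(rnorm(n, 2), rnorm(n, 0))
    unl <- c(rnorm(n / 2, 2), rnorm(n / 2, 0))
    cur <- calibrateScores(lab[, c("variant_key", "score")],
                           lab[, c("variant_key", "label")], unl,
                           config = evidenceConfig(0.5, 1124),
                           settings = calibrationSettings(
                               minLabeled = 100, minUnlabeledFrac = 0.03,
                               nBootstrap = 0, weight = 1))
    for (s in c(0.5, 1.0, 1.5)) {
        i <- which.min(abs(cur@score - s))
        expect_equal(cur@lrPlus[i], exp(2 * s - 2), tolerance = 0.2)
    }
})

test_that("curves serialize to TSV and back losslessly", {
    cur <- calibrateRaw(c(1, 2, 3), c(-1, 0, 0.5), minLabeled = 2,
                        minUnlabeledFrac = 0, nBootstrap = 20, weight = 2)
    tsv <- tempfile(fileext = ".tsv")
    writeCurve(cur, tsv)
    back <- readCurve(tsv)
    expect_equal(back@score, cur@score)
    expect_equal(back@posterior, cur@posterior)
    expect_equal(back@boundPathogenic, cur@boundPathogenic)
    expect_equal(back@weight, cur@weight)
    unlink(c(tsv, paste0(tsv, ".json")))
})
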