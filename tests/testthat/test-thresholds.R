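## Helper: wrap a hand-made bound curve in a CalibrationCurve so the
## selection rule can be exercised on exact, known inputs.
curveFromBounds <- function(score, boundPath, boundBenign = boundPath,
                            prior = 0.0441) {
    post <- pmax(boundPath, boundBenign)
    new("CalibrationCurve", score = as.numeric(score),
        epsilon = rep(0, length(score)),
        nPathogenic = rep(1, length(score)),
        nBenign = rep(1, length(score)),
        posterior = post, lrPlus = lrFromPosterior(post, prior),
        boundPathogenic = pmin(boundPath, post),
        boundBenign = pmax(boundBenign, post),
        ciLower = boundPath, ciUpper = boundBenign, prior = prior,
        weight = 1, nBoot = 0,
        settings = calibrationSettings(nBootstrap = 0),
        toolName = "synthetic", flipped = FALSE)
}

test_that("threshold selection applies the suffix rule on bounds", {
    prior <- 0.0441
    toPost <- function(lr) posteriorFromLR(lr, prior)
    ## bounds rising 1..5 in lr: suffix of lr >= 2.406 starts at score 3
    cur <- curveFromBounds(1:5, toPost(1:5))
    expect_equal(selectThreshold(cur, 2.406, "pathogenic"), 3)
    ## a dip blocks earlier candidates: lr bounds 3,2,3,4 -> tau = 3
    cur2 <- curveFromBounds(1:4, toPost(c(3, 2, 3, 4)))
    expect_equal(selectThreshold(cur2, 2.406, "pathogenic"), 3)
    ## bounds everywhere below the cutoff -> not met
    cur3 <- curveFromBounds(1:4, toPost(c(1, 1.5, 2, 2.3)))
    expect_true(is.na(selectThreshold(cur3, 2.406, "pathogenic")))
    expect_error(selectThreshold(curveFromBounds(numeric(), numeric()),
                                 2, "pathogenic"), "empty")
})

test_that("threshold selection matches the quadratic brute-force scan", {
    set.seed(17)
    prior <- 0.0441
    for (i in 1:200) {
        n <- sample(3:40, 1)
        bp <- runif(n)
        bb <- pmin(bp + runif(n, 0, 0.2), 1)
        cur <- curveFromBounds(sort(runif(n)), bp, bb, prior)
        lrCut <- sample(c(2.406, 5.79, 33.53), 1)
        tauP <- selectThreshold(cur, lrCut, "pathogenic")
        refP <- bruteSelectThreshold(cur@score, cur@boundPathogenic,
                                     posteriorFromLR(lrCut, prior),
                                     "pathogenic")
        expect_identical(tauP, refP)
        tauB <- selectThreshold(cur, lrCut, "benign")
        refB <- bruteSelectThreshold(cur@score, cur@boundBenign,
                                     posteriorFromLR(1 / lrCut, prior),
                                     "benign")
        expect_identical(tauB, refB)
    }
})

test_that("well-separated classes meet every strength in both directions", {
    set.seed(31)
    cur <- calibrateRaw(runif(4000, 10, 11), runif(4000, 0, 1),
                        prior = 0.5, minLabeled = 100,
                        minUnlabeledFrac = 0, nBootstrap = 60, weight = 1)
    ths <- buildThresholdSets(cur, evidenceConfig(0.5, 1124))
    expect_false(anyNA(thresholds(ths$pathogenic)))
    expect_false(anyNA(thresholds(ths$benign)))
    ## nesting in both directions
    expect_true(all(diff(thresholds(ths$pathogenic)) >= 0))
    expect_true(all(diff(thresholds(ths$benign)) <= 0))
})

test_that("uninformative scores never claim evidence", {
    set.seed(32)
    scores <- runif(3000)
    cur <- calibrateRaw(scores[1:1500], scores[1501:3000], prior = 0.5,
                        minLabeled = 150, minUnlabeledFrac = 0,
                        nBootstrap = 60, weight = 1)
    ths <- buildThresholdSets(cur, evidenceConfig(0.5, 1124))
    expect_true(all(is.na(thresholds(ths$pathogenic))))
    expect_true(all(is.na(thresholds(ths$benign))))
    iv <- evidenceIntervals(ths)
    expect_identical(nrow(iv@table), 1L)
    expect_identical(iv@table$strength, "indeterminate")
    expect_true(all(assignStrength(runif(50), iv) == "indeterminate"))
})

test_that("evidence intervals partition the line with half-open bounds", {
    prior <- 0.0441
    toPost <- function(lr) posteriorFromLR(lr, prior)
    lrs <- exp(seq(log(0.0001), log(5000), length.out = 400))
    cur <- curveFromBounds(seq_along(lrs), toPost(lrs), toPost(lrs), prior)
    ths <- buildThresholdSets(cur, evidenceConfig(0.0441, 1124))
    iv <- evidenceIntervals(ths)
    tab <- iv@table
    expect_identical(nrow(tab), 9L)
    ## contiguous cover: each upper equals the next lower, ends infinite
    expect_equal(tab$lower[1], -Inf)
    expect_equal(tab$upper[9], Inf)
    expect_equal(tab$lower[-1], tab$upper[-9])
    ## every score maps to exactly one label; boundary scores honour
    ## closedness (pathogenic left-closed, benign right-closed)
    tauPsu <- thresholds(ths$pathogenic)[["supporting"]]
    expect_identical(assignStrength(tauPsu, iv), "pathogenic.supporting")
    tauBsu <- thresholds(ths$benign)[["supporting"]]
    expect_identical(assignStrength(tauBsu, iv), "benign.supporting")
    expect_identical(assignStrength(NA_real_, iv), "indeterminate")
    ## strength below the benign very strong threshold
    tauBvs <- thresholds(ths$benign)[["very_strong"]]
    expect_identical(assignStrength(tauBvs - 1, iv), "benign.very_strong")
    ## totality over a fine sweep
    sweep <- seq(-5, 410, by = 0.5)
    lab <- assignStrength(sweep, iv)
    expect_true(all(lab %in% strengthLevels()))
    counts <- table(factor(lab, strengthLevels()))
    expect_true(all(counts > 0))
})

test_that("subsampling does not systematically claim more strength", {
    ## over replicates, thresholds from a quarter of the data should not be
    ## stochastically more permissive (smaller tau) than full-data ones
    set.seed(55)
    fullAtLeast <- 0L
    reps <- 20L
    metCount <- function(cur) {
        th <- buildThresholdSets(cur, evidenceConfig(0.5, 1124))
        sum(!is.na(thresholds(th$pathogenic))) +
            sum(!is.na(thresholds(th$benign)))
    }
    for (r in seq_len(reps)) {
        path <- rnorm(2000, 2)
        ben <- rnorm(2000, 0)
        curF <- calibrateRaw(path, ben, prior = 0.5, minLabeled = 100,
                             minUnlabeledFrac = 0, nBootstrap = 40,
                             weight = 1)
        keep <- sample.int(2000, 500)
        curS <- calibrateRaw(path[keep], ben[keep], prior = 0.5,
                             minLabeled = 100, minUnlabeledFrac = 0,
                             nBootstrap = 40, weight = 1)
        if (metCount(curF) >= metCount(curS)) fullAtLeast <- fullAtLeast + 1L
    }
    expect_gte(fullAtLeast, as.integer(0.7 * reps))
})

test_that("native-scale thresholds undo orientation normalization", {
    set.seed(41)
    ## lower-is-pathogenic tool: small scores pathogenic
    lab <- makeLabeled(runif(2000, 0, 0.2), runif(2000, 0.8, 1))
    ss <- ScoreSet(lab$variant_key, lab$score, "inverted",
                   orientation = "lower")
    cur <- calibrateScores(ss, lab[, c("variant_key", "label")],
                           config = evidenceConfig(0.5, 1124),
                           settings = calibrationSettings(
                               minLabeled = 100, minUnlabeledFrac = 0,
                               nBootstrap = 40, weight = 1))
    ths <- buildThresholdSets(cur, evidenceConfig(0.5, 1124))
    tauNorm <- thresholds(ths$pathogenic)[["supporting"]]
    tauNative <- ths$pathogenic@nativeThreshold[["supporting"]]
    expect_equal(tauNative, -tauNorm)
    expect_true(tauNative <= 0.2)  # lies in the native pathogenic range
    expect_true(evidenceIntervals(ths)@flipped)
})
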