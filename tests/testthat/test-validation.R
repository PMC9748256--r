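## A reusable calibrated setup: clearly separated Gaussian classes with a
## matched unlabeled mixture, calibrated once per file load.
.valSetup <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        set.seed(404)
        model <- gaussianScoreModel(meanPath = 2, meanBenign = 0,
                                    nPathogenic = 4000, nBenign = 4000,
                                    nUnlabeled = 8000, alpha = 0.5,
                                    missingness = 0)
        sim <- simulateScores(model, seed = 404)
        cfg <- evidenceConfig(0.5, 1124)
        cur <- calibrateScores(sim$labeled[, c("variant_key", "score")],
                               sim$labeled[, c("variant_key", "label")],
                               sim$unlabeled$score, config = cfg,
                               settings = calibrationSettings(
                                   nBootstrap = 150), seed = 1)
        iv <- evidenceIntervals(buildThresholdSets(cur, cfg), cfg)
        cache <<- list(model = model, sim = sim, cfg = cfg, cur = cur,
                       iv = iv)
        cache
    }
})

test_that("interval LR reduces to simple rate ratios", {
    score <- c(seq(0.1, 1, 0.1), seq(0.01, 0.09, 0.01), 0.5)
    label <- rep(c("P", "B"), each = 10)
    ## whole line: both rates are 1
    expect_equal(intervalLR(score, label, -Inf, Inf), 1)
    ## 8 of 10 pathogenic and 1 of 10 benign inside
    expect_equal(intervalLR(score, label, 0.26, Inf), 8)
    ## zero benign denominator with pathogenic mass: +Inf sentinel
    expect_true(is.infinite(intervalLR(score, label, 0.96, Inf)))
    ## empty interval: 0/0 undefined
    expect_true(is.nan(intervalLR(score, label, 5, 6)))
    ## weighting scales the benign denominator
    expect_equal(intervalLR(score, label, 0.26, Inf, weight = 2), 4)
    expect_error(intervalLR(score, rep("P", 20), 0, 1), "both classes")
})

test_that("mediant invariant: weighted interval LR meets each selected cutoff", {
    st <- .valSetup()
    cur <- st$cur
    cuts <- lrCutoffs(st$cfg, "pathogenic")
    tab <- st$iv@table
    for (i in which(tab$direction == "pathogenic")) {
        inside <- cur@score >= tab$lower[i] & cur@score < tab$upper[i]
        expect_true(any(inside))
        P <- sum(cur@nPathogenic[inside])
        B <- sum(cur@nBenign[inside])
        aggPost <- P / (P + cur@weight * B)
        aggLR <- lrFromPosterior(aggPost, cur@prior)
        expect_gte(aggLR, cuts[[tab$strength[i]]])
    }
})

test_that("validation report on independent data has coherent accounting", {
    st <- .valSetup()
    sim2 <- simulateScores(st$model, seed = 808)
    rep <- validateThresholds(st$iv, sim2$labeled$score, sim2$labeled$label,
                              population = sim2$unlabeled$score,
                              config = st$cfg)
    tab <- as.data.frame(rep)
    expect_equal(sum(tab$population_fraction), 1, tolerance = 1e-9)
    expect_equal(sum(tab$n_pathogenic) + sum(tab$n_benign),
                 nrow(sim2$labeled))
    expect_true(all(tab$n_pathogenic >= 0 & tab$n_benign >= 0))
    ## report serialization round-trips losslessly
    tsv <- tempfile(fileext = ".tsv")
    write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    back <- read.delim(tsv)
    expect_equal(back$interval_lr, tab$interval_lr)
    expect_equal(back$population_fraction, tab$population_fraction)
    unlink(tsv)
})

test_that("population fractions: missing scores land in indeterminate", {
    st <- .valSetup()
    fr <- populationFractions(st$iv, rep(NA_real_, 25))
    expect_equal(unname(fr[["indeterminate"]]), 1)
    expect_equal(sum(fr), 1)
    ## uniform scores over a known measure split by interval length
    set.seed(2)
    u <- runif(40000, -3, 5)
    fr2 <- populationFractions(st$iv, u)
    tab <- st$iv@table
    for (i in seq_len(nrow(tab))) {
        len <- min(tab$upper[i], 5) - max(tab$lower[i], -3)
        lab <- if (tab$direction[i] == "none") "indeterminate"
               else paste(tab$direction[i], tab$strength[i], sep = ".")
        expect_lt(abs(unname(fr2[[lab]]) - max(len, 0) / 8), 0.005)
    }
})

test_that("a benign-only population rarely reaches strong pathogenic evidence", {
    st <- .valSetup()
    set.seed(13)
    pop <- rnorm(20000, 0)        # drawn from the benign generator
    fr <- populationFractions(st$iv, pop)
    strongPlus <- sum(fr[c("pathogenic.strong", "pathogenic.very_strong")],
                      na.rm = TRUE)
    expect_lt(strongPlus, st$cfg@prior)
})

test_that("fresh-data interval LRs meet their cutoffs in most replicates", {
    st <- .valSetup()
    cuts <- lrCutoffs(st$cfg, "pathogenic")
    tab <- st$iv@table
    pathRows <- which(tab$direction == "pathogenic")
    expect_gte(length(pathRows), 2)   # supporting and moderate at least
    nRep <- 50L
    ok <- 0L
    set.seed(99)
    for (r in seq_len(nRep)) {
        path <- rnorm(3000, 2)
        ben <- rnorm(3000, 0)
        score <- c(path, ben)
        label <- rep(c("P", "B"), each = 3000)
        pass <- TRUE
        for (i in pathRows) {
            lr <- intervalLR(score, label, tab$lower[i], tab$upper[i],
                             tab$lower_closed[i], tab$upper_closed[i])
            if (!(is.na(lr) || lr >= cuts[[tab$strength[i]]])) pass <- FALSE
        }
        if (pass) ok <- ok + 1L
    }
    expect_gte(ok, as.integer(0.9 * nRep))
})

test_that("fixed-threshold assessment reports lr, interval and strength", {
    st <- .valSetup()
    ## at the analytic moderate region: s = 2 has lr+ = e^2 ~ 7.39
    res <- assessFixedThreshold(st$cur, 2, "pathogenic", st$cfg)
    expect_equal(res$lr, exp(2), tolerance = 0.35)
    expect_identical(res$strength, "moderate")
    expect_true(res$ci[1] <= res$lr && res$lr <= res$ci[2])
    ## a threshold in lr < supporting territory is not met
    res0 <- assessFixedThreshold(st$cur, 0, "pathogenic", st$cfg)
    expect_identical(res0$strength, "not_met")
    ## at a selected supporting threshold the curve itself meets supporting
    tau <- thresholds(st$iv@pathogenic)[["supporting"]]
    resTau <- assessFixedThreshold(st$cur, tau, "pathogenic", st$cfg)
    expect_true(resTau$strength %in%
                    c("supporting", "moderate", "strong", "very_strong"))
    ## population fraction counts scores at or beyond the threshold
    resPop <- assessFixedThreshold(st$cur, 2, "pathogenic", st$cfg,
                                   population = c(1, 2, 3, NA))
    expect_equal(resPop$population_fraction, 0.5)
    expect_error(assessFixedThreshold(st$cur, 99, "pathogenic", st$cfg),
                 "outside")
})

test_that("consensus curves collapse to the univariate estimate when degenerate", {
    set.seed(21)
    n <- 1500
    path <- rnorm(n, 2); ben <- rnorm(n, 0)
    lab <- makeLabeled(path, ben)
    s1 <- ScoreSet(lab$variant_key, lab$score, "t1")
    st <- calibrationSettings(minLabeled = 100, minUnlabeledFrac = 0,
                              nBootstrap = 0, weight = 1)
    cfg <- evidenceConfig(0.5, 1124)
    ## duplicated tool: joint estimate at (t, t) tracks the univariate one
    lrJoint <- consensusCurve(list(s1, s1), lab[, c("variant_key", "label")],
                              at = rbind(c(1, 1), c(2, 2)), config = cfg,
                              settings = st)
    cur <- calibrateScores(s1, lab[, c("variant_key", "label")],
                           config = cfg, settings = st)
    for (k in 1:2) {
        i <- which.min(abs(cur@score - k))
        expect_equal(log(lrJoint[k]), log(cur@lrPlus[i]), tolerance = 0.5)
    }
    ## an independent uninformative second score barely changes the estimate
    junk <- ScoreSet(lab$variant_key, runif(2 * n), "noise")
    lrNoise <- consensusCurve(list(s1, junk),
                              lab[, c("variant_key", "label")],
                              at = rbind(c(2, 0.5)), config = cfg,
                              settings = st)
    expect_equal(log(lrNoise), log(exp(2 * 2 - 2)), tolerance = 0.8)
    ## anti-correlated informative scores leave no joint pathogenic tail
    anti <- ScoreSet(lab$variant_key, -lab$score, "anti",
                     orientation = "higher")
    lrAnti <- consensusCurve(list(s1, anti),
                             lab[, c("variant_key", "label")],
                             at = rbind(c(2.5, 2.5)), config = cfg,
                             settings = st)
    expect_lt(lrAnti, 2.406)
    expect_error(consensusCurve(list(s1), lab[, c("variant_key", "label")],
                                at = rbind(1)), "2 or 3")
})
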