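M_example <- matrix(c(50L, 5L, 10L, 35L), 2L, 2L)   # TP FN / FP TN layout

test_that("confusion matrix follows the (positive, negative) convention", {
    M <- confusionMatrix2(c(rep(1L, 10), rep(-1L, 10)),
                          c(rep(1L, 10), rep(-1L, 10)))
    expect_equal(unname(M), matrix(c(10L, 0L, 0L, 10L), 2L))
    M2 <- confusionMatrix2(c(rep(1L, 5), rep(-1L, 5)), rep(1L, 10))
    expect_equal(unname(M2), matrix(c(5L, 5L, 0L, 0L), 2L))
    expect_error(confusionMatrix2(integer(0), integer(0)), "empty")
    expect_error(confusionMatrix2(1L, c(1L, -1L)), "aligned")
})

test_that("per-class metrics match hand arithmetic on the worked matrix", {
    pc <- perClassMetrics(M_example)
    expect_equal(pc$PR[1L], 50 / 55)
    expect_equal(pc$SE[1L], 50 / 60)
    expect_equal(pc$PR[2L], 35 / 45)
    expect_equal(pc$SE[2L], 35 / 40)
    ov <- overallMetrics(M_example)
    expect_equal(ov$Acc, 85 / 100)
    pr <- 50 / 55; se <- 50 / 60
    expect_equal(f1Positive(M_example), 2 * pr * se / (pr + se))
})

test_that("degenerate denominators yield NA markers, not zeros", {
    all_neg <- confusionMatrix2(c(1L, -1L), c(-1L, -1L))
    pc <- perClassMetrics(all_neg)
    expect_true(is.na(pc$PR[1L]))      # positive class never predicted
    expect_true(is.na(f1Positive(matrix(c(0L, 0L, 5L, 5L), 2L))))
    expect_error(overallMetrics(matrix(0L, 2L, 2L)), "empty")
    perfect <- matrix(c(7L, 0L, 0L, 3L), 2L)
    expect_equal(perClassMetrics(perfect)$MCC, c(1, 1))
    expect_equal(overallMetrics(perfect)$Acc, 1)
})

test_that("metric suite equals the brute-force oracle on random labels", {
    withr::local_seed(41)
    for (rep in 1:1000) {
        n <- sample(4:40, 1L)
        truth <- sample(c(1L, -1L), n, replace = TRUE)
        pred <- sample(c(1L, -1L), n, replace = TRUE)
        M <- confusionMatrix2(truth, pred)
        o <- oracle_metrics(truth, pred)
        expect_identical(M[1L, 1L], o$TP)
        expect_identical(M[1L, 2L], o$FN)
        expect_identical(M[2L, 1L], o$FP)
        expect_identical(M[2L, 2L], o$TN)
        pc <- perClassMetrics(M)
        ov <- overallMetrics(M)
        expect_equal(pc$PR, c(o$PRpos, o$PRneg), tolerance = 1e-12)
        expect_equal(pc$SE, c(o$SEpos, o$SEneg), tolerance = 1e-12)
        expect_equal(pc$MCC, c(o$MCCpos, o$MCCneg), tolerance = 1e-12)
        expect_equal(ov$Acc, o$Acc, tolerance = 1e-12)
        expect_equal(ov$MCC, o$MCC, tolerance = 1e-12)
        expect_equal(f1Positive(M), o$F1, tolerance = 1e-12)
    }
})

test_that("the two per-class MCCs coincide; the pooled MCC is 2*Acc - 1", {
    withr::local_seed(43)
    for (rep in 1:200) {
        truth <- sample(c(1L, -1L), 30, replace = TRUE)
        pred <- sample(c(1L, -1L), 30, replace = TRUE)
        M <- confusionMatrix2(truth, pred)
        pc <- perClassMetrics(M)
        if (!any(is.na(pc$MCC)))
            expect_equal(pc$MCC[1L], pc$MCC[2L], tolerance = 1e-12)
        ov <- overallMetrics(M)
        expect_equal(ov$MCC, 2 * ov$Acc - 1, tolerance = 1e-12)
    }
})

test_that("random predictions give near-zero MCC on balanced data", {
    withr::local_seed(47)
    truth <- rep(c(1L, -1L), each = 2000L)
    mccs <- replicate(50, {
        overallMetrics(confusionMatrix2(truth, sample(truth)))$MCC
    })
    ## null sd of 2*Acc-1 on n=4000 is ~ 1/sqrt(n); 3 sigma band
    expect_lt(abs(mean(mccs)), 3 / sqrt(4000) / sqrt(50) * 3 + 0.01)
    expect_true(all(abs(mccs) < 3 / sqrt(4000) * 3))
})

test_that("ROC-AUC equals pairwise counting, with ties at one half", {
    expect_equal(rocAUC(c(1L, 1L, -1L, -1L), c(9, 8, 2, 1)), 1)
    expect_equal(rocAUC(c(1L, -1L, 1L, -1L), rep(3, 4)), 0.5)
    ## 3 per class: one strict inversion loses a full pair, one tied
    ## positive-negative pair loses half a pair
    expect_equal(rocAUC(c(1L, 1L, 1L, -1L, -1L, -1L),
                        c(6, 5, 3, 4, 2, 1)), 8 / 9)
    expect_equal(rocAUC(c(1L, 1L, 1L, -1L, -1L, -1L),
                        c(6, 5, 3, 3, 2, 1)), 8.5 / 9)
    withr::local_seed(53)
    for (rep in 1:100) {
        n <- sample(4:200, 1L)
        truth <- c(1L, -1L, sample(c(1L, -1L), n - 2L, replace = TRUE))
        scores <- sample(seq_len(20L), n, replace = TRUE)  # forces ties
        expect_equal(rocAUC(truth, scores), oracle_auc(truth, scores))
    }
    expect_error(rocAUC(c(1L, 1L), c(1, 2)), "both classes")
})

test_that("ROC-AUC agrees with an established implementation", {
    skip_if_not_installed("pROC")
    withr::local_seed(59)
    truth <- sample(c(1L, -1L), 100, replace = TRUE)
    scores <- rnorm(100) + 0.5 * (truth == 1L)
    ref <- suppressMessages(as.numeric(pROC::auc(
        pROC::roc(response = truth, predictor = scores,
                  levels = c(-1, 1), direction = "<"))))
    expect_equal(rocAUC(truth, scores), ref, tolerance = 1e-12)
})

test_that("negative sampling avoids positives, self-pairs and duplicates", {
    withr::local_seed(61)
    dtm <- random_target_map(20L, 25L)
    nm <- drugNames(dtm)
    pos <- DrugPairSet(nm[1:10], nm[11:20], 1L)
    neg <- sampleNegatives(dtm, pos, 50L, seed = 5L)
    expect_equal(length(neg), 50L)
    expect_true(all(pairLabels(neg) == -1L))
    pk <- paste(pos@drugA, pos@drugB); nk <- paste(neg@drugA, neg@drugB)
    expect_length(intersect(pk, nk), 0L)
    expect_false(anyDuplicated(nk) > 0L)
    ## reproducible under the same seed
    expect_identical(pairTable(sampleNegatives(dtm, pos, 50L, seed = 5L)),
                     pairTable(neg))
    expect_error(sampleNegatives(nm[1:3], pos[integer(0)], 100L),
                 "only")
})

test_that("cross-validation is seed-reproducible and leakage-guarded", {
    ds <- synthGenerate(synthConfig(nDrugs = 60L, nGenes = 80L,
                                    nPositivePairs = 150L,
                                    nNegativePairs = 150L, seed = 3L))
    pos <- ds$pairs[pairLabels(ds$pairs) == 1L]
    cv1 <- kfoldCV(ds$targets, pos, k = 3L, seed = 9L)
    cv2 <- kfoldCV(ds$targets, pos, k = 3L, seed = 9L)
    expect_identical(cv1$report, cv2$report)
    expect_identical(cv1$folds, cv2$folds)
    cv3 <- kfoldCV(ds$targets, pos, k = 3L, seed = 10L)
    expect_false(identical(cv1$folds, cv3$folds))
    expect_equal(rownames(cv1$report),
                 c("fold1", "fold2", "fold3", "mean", "sd"))
    expect_error(kfoldCV(ds$targets, pos[1:2], k = 5L, seed = 1L),
                 "fewer examples")
    f <- withr::local_tempfile()
    writeMetricsReport(cv1$report, f)
    expect_equal(length(readLines(f)), 6L)
})

test_that("independent recall guards disjointness and single-class input", {
    ds <- synthGenerate(synthConfig(nDrugs = 60L, nGenes = 80L,
                                    nPositivePairs = 200L,
                                    nNegativePairs = 200L, seed = 13L))
    pos <- ds$pairs[pairLabels(ds$pairs) == 1L]
    hold <- pos[1:40]
    train_pos <- pos[41:200]
    neg <- ds$pairs[pairLabels(ds$pairs) == -1L][1:160]
    train <- DrugPairSet(c(train_pos@drugA, neg@drugA),
                         c(train_pos@drugB, neg@drugB),
                         c(pairLabels(train_pos), pairLabels(neg)))
    uni <- buildUniverse(ds$targets, drugNames(train))
    dm <- designMatrix(train, ds$targets, uni)
    model <- trainLogistic(dm$X, dm$y, C = 1)
    rec <- independentRecall(model, uni, hold, ds$targets, train)
    expect_gte(rec, 0)
    expect_lte(rec, 1)
    expect_error(independentRecall(model, uni, train_pos[1:5],
                                   ds$targets, train), "overlap")
    expect_error(independentRecall(model, uni, hold[integer(0)],
                                   ds$targets, train), "empty")
    expect_error(independentRecall(model, uni, ds$pairs[1:400],
                                   ds$targets, train), "single-class")
})

test_that("a model trained on fully planted data recalls held-out pairs", {
    ds <- synthGenerate(synthConfig(nDrugs = 150L, nGenes = 200L,
                                    nPositivePairs = 600L,
                                    nNegativePairs = 600L,
                                    shareProb = 1, proximityProb = 0,
                                    targetsPerDrug = c(1L, 3L),
                                    driverBoost = 19, seed = 31L))
    pos <- ds$pairs[pairLabels(ds$pairs) == 1L]
    neg <- ds$pairs[pairLabels(ds$pairs) == -1L]
    withr::local_seed(5)
    hi <- sample(length(pos), 60L)
    train <- DrugPairSet(c(pos[-hi]@drugA, neg@drugA),
                         c(pos[-hi]@drugB, neg@drugB),
                         c(pairLabels(pos[-hi]), pairLabels(neg)))
    uni <- buildUniverse(ds$targets, drugNames(train))
    dm <- designMatrix(train, ds$targets, uni)
    model <- trainLogistic(dm$X, dm$y, C = 1)
    expect_gt(independentRecall(model, uni, pos[hi], ds$targets, train),
              0.8)
})
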