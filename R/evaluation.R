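## Confusion-matrix metric suite, ROC-AUC, the k-fold cross-validation
## protocol with uniform negative sampling, and independent-test recall.
##
## Conventions: the confusion matrix M has class order (positive, negative)
## on both axes and M[i, j] counts true class i classified as class j.
## Per class l the intermediates are
##   p_l = M[l,l]             (correct for class l)
##   q_l = sum of M[i,j], i != l, j != l
##   r_l = sum of M[i,l], i != l    (others classified as l)
##   s_l = sum of M[l,j], j != l    (class l classified as other)
## and the pooled p, q, r, s are the sums over classes. A metric whose
## denominator is zero is reported as NA, never as 0.

CLASS_LEVELS <- c(1L, -1L)    # positive first

#' Confusion matrix of +1/-1 label vectors
#'
#' @param truth,predicted aligned integer vectors of +1/-1 labels.
#' @return 2x2 integer matrix, rows = true class, columns = predicted
#'   class, class order (positive, negative).
#' @export
confusionMatrix2 <- function(truth, predicted) {
    truth <- as.integer(truth); predicted <- as.integer(predicted)
    if (length(truth) != length(predicted))
        stop("truth and predicted are not aligned")
    if (length(truth) == 0L)
        stop("empty input")
    if (!all(c(truth, predicted) %in% CLASS_LEVELS))
        stop("labels must be +1 or -1")
    M <- table(factor(truth, levels = CLASS_LEVELS),
               factor(predicted, levels = CLASS_LEVELS))
    M <- matrix(as.integer(M), 2L, 2L,
                dimnames = list(true = c("positive", "negative"),
                                predicted = c("positive", "negative")))
    M
}

pqrs <- function(M, l) {
    o <- 3L - l
    c(p = M[l, l], q = M[o, o], r = M[o, l], s = M[l, o])
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

mcc_from_pqrs <- function(v) {
    den <- sqrt(v["p"] + v["r"]) * sqrt(v["p"] + v["s"]) *
        sqrt(v["q"] + v["r"]) * sqrt(v["q"] + v["s"])
    if (den == 0) return(NA_real_)
    unname((v["p"] * v["q"] - v["r"] * v["s"]) / den)
}

#' Per-class precision, sensitivity and MCC
#'
#' @param M a 2x2 confusion matrix from [confusionMatrix2()].
#' @return data.frame with one row per class (positive, negative) and
#'   columns `PR`, `SE`, `MCC`; zero-denominator metrics are `NA`.
#' @export
perClassMetrics <- function(M) {
    stopifnot(is.matrix(M), all(dim(M) == 2L))
    rows <- lapply(1:2, function(l) {
        v <- pqrs(M, l)
        data.frame(class = c("positive", "negative")[l],
                   PR = safe_ratio(v["p"], v["p"] + v["r"]),
                   SE = safe_ratio(v["p"], v["p"] + v["s"]),
                   MCC = mcc_from_pqrs(v), row.names = NULL)
    })
    do.call(rbind, rows)
}

#' Overall accuracy and pooled MCC
#'
#' Accuracy is the trace over the total; the overall MCC pools the
#' per-class intermediates p, q, r, s across classes before applying the
#' MCC formula (for two classes this pooled form reduces to `2*Acc - 1`).
#'
#' @inheritParams perClassMetrics
#' @return list with elements `Acc` and `MCC`.
#' @export
overallMetrics <- function(M) {
    stopifnot(is.matrix(M), all(dim(M) == 2L))
    total <- sum(M)
    if (total == 0L)
        stop("empty confusion matrix")
    pooled <- pqrs(M, 1L) + pqrs(M, 2L)
    list(Acc = sum(diag(M)) / total, MCC = mcc_from_pqrs(pooled))
}

#' F1 score of the positive class
#'
#' Harmonic mean of positive-class precision and sensitivity; `NA` when
#' either is undefined or their sum is zero.
#'
#' @inheritParams perClassMetrics
#' @return numeric F1, or `NA`.
#' @export
f1Positive <- function(M) {
    pc <- perClassMetrics(M)
    pr <- pc$PR[1L]; se <- pc$SE[1L]
    if (is.na(pr) || is.na(se) || pr + se == 0) return(NA_real_)
    2 * pr * se / (pr + se)
}

#' ROC-AUC from decision scores
#'
#' Computed as the Mann-Whitney probability that a random positive example
#' outscores a random negative one, with ties counted one half (midrank
#' formula; exact, no binning).
#'
#' @param truth integer +1/-1 labels.
#' @param scores numeric decision scores or probabilities, aligned.
#' @return AUC in \[0, 1\].
#' @export
rocAUC <- function(truth, scores) {
    truth <- as.integer(truth)
    if (length(truth) != length(scores))
        stop("truth and scores are not aligned")
    npos <- sum(truth == 1L); nneg <- sum(truth == -1L)
    if (npos == 0L || nneg == 0L)
        stop("both classes must be present")
    r <- rank(scores)
    (sum(r[truth == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

metrics_row <- function(truth, predicted, scores) {
    M <- confusionMatrix2(truth, predicted)
    pc <- perClassMetrics(M)
    ov <- overallMetrics(M)
    data.frame(PRpos = pc$PR[1L], PRneg = pc$PR[2L],
               SEpos = pc$SE[1L], SEneg = pc$SE[2L],
               MCCpos = pc$MCC[1L], MCCneg = pc$MCC[2L],
               Acc = ov$Acc, MCC = ov$MCC,
               AUC = rocAUC(truth, scores), F1 = f1Positive(M))
}

#' Sample presumed non-interacting drug pairs
#'
#' Uniform sampling over the unordered non-self pairs of the drug roster,
#' excluding the known positives, without replacement. This is the
#' negative-sampling protocol of the training pipeline: negatives are
#' sampled once, before any fold split.
#'
#' @param drugs character vector of drug identifiers (the roster), or a
#'   [DrugTargetMap] whose drugs form the roster.
#' @param positives a [DrugPairSet] of known interactions to exclude.
#' @param n number of negative pairs to draw.
#' @param seed integer seed.
#' @return a [DrugPairSet] with all labels -1.
#' @export
sampleNegatives <- function(drugs, positives, n, seed = NULL) {
    if (is(drugs, "DrugTargetMap")) drugs <- drugNames(drugs)
    drugs <- unique(drugs)
    nd <- length(drugs)
    npairs <- nd * (nd - 1) / 2
    exclude <- paste(positives@drugA, positives@drugB, sep = "\t")
    if (npairs - length(exclude) < n)
        stop("requested ", n, " negatives but only ",
             npairs - length(exclude), " non-positive pairs exist")
    with_seed(seed, {
        keys <- character(0)
        a_out <- b_out <- character(0)
        while (length(keys) < n) {
            m <- max(2L * (n - length(keys)), 100L)
            a <- sample(drugs, m, replace = TRUE)
            b <- sample(drugs, m, replace = TRUE)
            ok <- a != b
            a <- a[ok]; b <- b[ok]
            swap <- a > b
            tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
            key <- paste(a, b, sep = "\t")
            new <- !key %in% exclude & !key %in% keys & !duplicated(key)
            keys <- c(keys, key[new])
            a_out <- c(a_out, a[new]); b_out <- c(b_out, b[new])
        }
        DrugPairSet(a_out[seq_len(n)], b_out[seq_len(n)], -1L)
    })
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Given known positive pairs, samples an equally sized negative set once
#' (uniformly over non-positive roster pairs), splits all pairs into k
#' stratified folds, and for each fold rebuilds the gene universe from the
#' training-fold drugs only, trains the classifier on the training folds
#' and scores the held-out fold. Rebuilding the universe per fold prevents
#' feature leakage from held-out drugs.
#'
#' @param targets a [DrugTargetMap]; its drug roster is the negative
#'   sampling space.
#' @param positives a [DrugPairSet]; pairs labeled +1 are the positive
#'   class.
#' @param k number of folds (>= 2).
#' @param seed integer seed driving negative sampling and fold assignment.
#' @param C penalty parameter; ignored when `grid` is given.
#' @param grid optional C grid; when supplied, C is tuned by [tuneC()]
#'   inside each training split.
#' @param threshold probability cutoff for the thresholded metrics.
#' @param negatives optional pre-sampled [DrugPairSet] of negatives
#'   (labels -1); when supplied, no sampling is done.
#' @param intercept fit an intercept? (see [trainLogistic()]).
#' @return list with `report` (data.frame: one row per fold plus `mean`
#'   and `sd` rows; columns PRpos..F1), `negatives` (the sampled
#'   [DrugPairSet]), `folds` (fold assignment aligned with
#'   `rbind(positives, negatives)` order) and `C` (per-fold C used).
#' @export
kfoldCV <- function(targets, positives, k = 5L, seed = NULL, C = 1,
                    grid = NULL, threshold = 0.5, negatives = NULL,
                    intercept = TRUE) {
    stopifnot(is(targets, "DrugTargetMap"), is(positives, "DrugPairSet"))
    pos <- positives[pairLabels(positives) == 1L]
    if (length(pos) == 0L)
        stop("no positive pairs")
    seeds <- if (is.null(seed)) list(NULL, NULL)
             else list(seed, seed + 1L)
    if (is.null(negatives))
        negatives <- sampleNegatives(targets, pos, length(pos),
                                     seed = seeds[[1L]])
    all_pairs <- DrugPairSet(c(pos@drugA, negatives@drugA),
                             c(pos@drugB, negatives@drugB),
                             c(pos@label, negatives@label))
    y <- pairLabels(all_pairs)
    fold <- make_folds(y, k, seed = seeds[[2L]])
    rows <- vector("list", k)
    used_C <- numeric(k)
    for (f in seq_len(k)) {
        tr_pairs <- all_pairs[fold != f]
        te_pairs <- all_pairs[fold == f]
        uni <- buildUniverse(targets, drugNames(tr_pairs))
        tr <- designMatrix(tr_pairs, targets, uni)
        te <- designMatrix(te_pairs, targets, uni)
        Cf <- if (is.null(grid)) C
              else tuneC(tr$X, tr$y, grid = grid, k = 3L,
                         seed = seeds[[2L]], intercept = intercept)$bestC
        used_C[f] <- Cf
        model <- trainLogistic(tr$X, tr$y, C = Cf, intercept = intercept)
        prob <- suppressWarnings(predictProba(model, te$X))
        pred <- ifelse(prob >= threshold, 1L, -1L)
        rows[[f]] <- metrics_row(te$y, pred, prob)
    }
    per_fold <- do.call(rbind, rows)
    report <- rbind(per_fold, colMeans(per_fold),
                    apply(per_fold, 2L, stats::sd))
    rownames(report) <- c(paste0("fold", seq_len(k)), "mean", "sd")
    list(report = report, negatives = negatives, folds = fold, C = used_C)
}

#' Write a cross-validation metrics report
#'
#' One TSV row per fold plus `mean` and `sd` rows; `NA` marks metrics
#' undefined by a zero denominator.
#'
#' @param report the `report` element of a [kfoldCV()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
    df <- cbind(fold = rownames(report), as.data.frame(report))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Recall on an independent single-class test set
#'
#' Scores test pairs with a trained model and reports the fraction
#' classified with their stated label at the given threshold. The test set
#' must be disjoint (as unordered pairs) from the training pairs; overlap
#' is an error listing the offending pairs.
#'
#' @param model a [DDIModel].
#' @param universe the [GeneUniverse] the model was trained on.
#' @param testPairs a single-class [DrugPairSet] (all labels +1 or all -1).
#' @param targets a [DrugTargetMap] resolving the test drugs.
#' @param trainPairs the [DrugPairSet] used in training (for the
#'   disjointness guard).
#' @param threshold probability cutoff.
#' @return the recall rate, a fraction in \[0, 1\].
#' @export
independentRecall <- function(model, universe, testPairs, targets,
                              trainPairs, threshold = 0.5) {
    stopifnot(is(testPairs, "DrugPairSet"), is(trainPairs, "DrugPairSet"))
    if (length(testPairs) == 0L)
        stop("empty test set")
    lab <- unique(pairLabels(testPairs))
    if (length(lab) != 1L)
        stop("test set must be single-class")
    tkey <- paste(testPairs@drugA, testPairs@drugB, sep = "|")
    rkey <- paste(trainPairs@drugA, trainPairs@drugB, sep = "|")
    bad <- tkey %in% rkey
    if (any(bad))
        stop("test pairs overlap the training set: ",
             paste(utils::head(tkey[bad], 10L), collapse = ", "),
             if (sum(bad) > 10L) " ...")
    X <- designMatrix(testPairs, targets, universe)$X
    pred <- classifyPairs(model, X, threshold)
    mean(pred == lab)
}
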