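## l2-regularized logistic regression on pair-profile features.
## The trained weights minimize
##     0.5 * w'w + C * sum_i log(1 + exp(-y_i * (w'x_i + b)))
## with labels y in {-1,+1} and an (unpenalized, optional) intercept b.
## Any convex optimizer satisfies this contract; L-BFGS-B on the exact
## analytic gradient is used here.

## numerically stable log(1 + exp(t))
log1pexp <- function(t) {
    out <- numeric(length(t))
    pos <- t > 0
    out[pos] <- t[pos] + log1p(exp(-t[pos]))
    out[!pos] <- log1p(exp(t[!pos]))
    out
}

logistic_objective <- function(w, b, X, y, C) {
    z <- as.numeric(X %*% w) + b
    0.5 * sum(w * w) + C * sum(log1pexp(-y * z))
}

## restore the caller's RNG stream after seeded work
with_seed <- function(seed, expr) {
    if (is.null(seed))
        return(eval.parent(substitute(expr)))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
    eval.parent(substitute(expr))
}

#' Train the l2-regularized logistic-regression base learner
#'
#' Minimizes `0.5 * w'w + C * sum(log(1 + exp(-y * (Xw + b))))` over the
#' weight vector `w` (one weight per universe gene) and, by default, an
#' unpenalized intercept `b`. The fit is deterministic given the inputs:
#' optimization starts from the zero vector, so no seed enters training
#' itself (the `seed` argument is accepted for interface symmetry with the
#' sampling-based routines and is unused).
#'
#' @param X feature matrix (sparse `dgCMatrix` from [designMatrix()] or a
#'   base matrix), columns named by universe gene.
#' @param y integer labels, +1/-1, one per row of `X`.
#' @param C positive penalty parameter; larger C = weaker regularization.
#' @param intercept fit an unpenalized intercept? (default `TRUE`).
#' @param maxit maximum L-BFGS-B iterations.
#' @param factr L-BFGS-B convergence tolerance (see [stats::optim()]);
#'   the default asks for about 12 significant digits on the objective.
#' @param seed unused; see Details.
#' @return a [DDIModel].
#' @seealso [predictProba()], [classifyPairs()], [tuneC()]
#' @export
trainLogistic <- function(X, y, C = 1, intercept = TRUE, maxit = 1000L,
                          factr = 1e4, seed = NULL) {
    if (is.null(colnames(X)))
        stop("X must carry universe genes as column names")
    y <- as.integer(y)
    if (nrow(X) != length(y))
        stop("X and y are not aligned")
    if (!all(y %in% c(-1L, 1L)))
        stop("labels must be +1 or -1")
    if (length(unique(y)) < 2L)
        stop("training data contain a single class")
    xvals <- if (is(X, "sparseMatrix")) X@x else X
    if (any(!is.finite(xvals)))
        stop("non-finite feature values")
    if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0)
        stop("C must be a single positive number")
    p <- ncol(X)
    fn <- function(par) {
        w <- par[seq_len(p)]
        b <- if (intercept) par[p + 1L] else 0
        logistic_objective(w, b, X, y, C)
    }
    gr <- function(par) {
        w <- par[seq_len(p)]
        b <- if (intercept) par[p + 1L] else 0
        z <- as.numeric(X %*% w) + b
        s <- stats::plogis(-y * z)      # sigmoid of the margin deficit
        gw <- w + C * as.numeric(Matrix::crossprod(X, -y * s))
        if (intercept) c(gw, C * sum(-y * s)) else gw
    }
    par0 <- numeric(p + as.integer(intercept))
    fit <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = factr))
    w <- fit$par[seq_len(p)]
    names(w) <- colnames(X)
    new("DDIModel", weights = w,
        intercept = if (intercept) fit$par[p + 1L] else 0,
        hasIntercept = intercept, penaltyC = as.numeric(C),
        universe = colnames(X),
        universeHash = universe_fingerprint(colnames(X)),
        converged = fit$convergence == 0L, objective = fit$value)
}

check_universe <- function(model, X) {
    if (is.null(colnames(X)) ||
        universe_fingerprint(colnames(X)) != model@universeHash)
        stop("universe fingerprint mismatch: X was not built on the ",
             "model's gene universe")
}

#' Predict interaction probabilities
#'
#' `p = 1 / (1 + exp(-(Xw + b)))` per row, the probability of the positive
#' (interacting) class. `X` must be built on the model's gene universe;
#' a fingerprint mismatch is an error.
#'
#' @param model a [DDIModel].
#' @param X feature matrix on the model's universe.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predictProba <- function(model, X) {
    stopifnot(is(model, "DDIModel"))
    check_universe(model, X)
    as.numeric(stats::plogis(as.numeric(X %*% model@weights) +
                             model@intercept))
}

#' Threshold probabilities into interaction labels
#'
#' Label +1 iff the predicted probability is at least `threshold`
#' (boundary inclusive). A higher threshold filters out weaker predicted
#' interactions, e.g. 0.7 to keep only confident ones.
#'
#' @inheritParams predictProba
#' @param threshold probability cutoff, strictly inside (0, 1).
#' @return integer vector of +1/-1 labels.
#' @export
classifyPairs <- function(model, X, threshold = 0.5) {
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        threshold <= 0 || threshold >= 1)
        stop("threshold must lie strictly inside (0, 1)")
    p <- predictProba(model, X)
    ifelse(p >= threshold, 1L, -1L)
}

## stratified fold assignment: each class is shuffled and dealt round-robin
make_folds <- function(y, k, seed = NULL) {
    if (k < 2L)
        stop("k must be at least 2")
    if (min(table(y)) < k)
        stop("fewer examples than folds in some class")
    fold <- integer(length(y))
    with_seed(seed, {
        for (cls in unique(y)) {
            idx <- sample(which(y == cls))
            fold[idx] <- rep_len(seq_len(k), length(idx))
        }
    })
    fold
}

#' Select the penalty parameter C by cross-validated ROC-AUC
#'
#' Evaluates each candidate C with stratified k-fold cross-validation on
#' `(X, y)` and returns the C maximizing mean held-out ROC-AUC. Ties break
#' toward the smaller C, i.e. toward the more regularized model. The
#' default grid is the powers of two from 2^-16 to 2^16.
#'
#' @inheritParams trainLogistic
#' @param grid positive candidate values of C.
#' @param k number of folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @return list with `bestC` and `scores` (data.frame of C, meanAUC, sdAUC).
#' @export
tuneC <- function(X, y, grid = 2^(-16:16), k = 5L, seed = NULL,
                  intercept = TRUE) {
    stopifnot(all(grid > 0), length(grid) >= 1L)
    y <- as.integer(y)
    fold <- make_folds(y, k, seed)
    aucs <- matrix(NA_real_, length(grid), k)
    for (f in seq_len(k)) {
        tr <- fold != f
        for (ci in seq_along(grid)) {
            m <- trainLogistic(X[tr, , drop = FALSE], y[tr], C = grid[ci],
                               intercept = intercept)
            aucs[ci, f] <- rocAUC(y[!tr], predictProba(m, X[!tr, ,
                                                            drop = FALSE]))
        }
    }
    mean_auc <- rowMeans(aucs)
    ord <- order(-mean_auc, grid)      # best AUC, then smaller C
    list(bestC = grid[ord[1L]],
         scores = data.frame(C = grid, meanAUC = mean_auc,
                             sdAUC = apply(aucs, 1L, stats::sd)))
}

#' Persist a trained model as plain text
#'
#' Key-value text format: header comments with the universe fingerprint,
#' C and intercept state, then one `gene<TAB>weight` row per universe gene
#' (universe order) and a final `__intercept__` row.
#'
#' @param model a [DDIModel].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readModel()]
#' @export
writeModel <- function(model, path) {
    stopifnot(is(model, "DDIModel"))
    writeLines(c(
        sprintf("# universe_md5=%s", model@universeHash),
        sprintf("# C=%.17g", model@penaltyC),
        sprintf("# intercept_enabled=%s", model@hasIntercept),
        sprintf("# converged=%s", model@converged),
        sprintf("# objective=%.17g", model@objective),
        sprintf("%s\t%.17g", names(model@weights), model@weights),
        sprintf("__intercept__\t%.17g", model@intercept)), path)
    invisible(path)
}

#' Load a model written by [writeModel()]
#'
#' @param path path to a model file.
#' @return a [DDIModel].
#' @export
readModel <- function(path) {
    raw <- readLines(path)
    hdr <- raw[startsWith(raw, "# ")]
    get_hdr <- function(key) {
        m <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
        if (!length(m)) stop("model file missing header: ", key)
        sub(sprintf("^# %s=", key), "", m[1L])
    }
    body <- strsplit(raw[!startsWith(raw, "#") & nzchar(raw)], "\t",
                     fixed = TRUE)
    keys <- vapply(body, `[`, character(1), 1L)
    vals <- as.numeric(vapply(body, `[`, character(1), 2L))
    is_b <- keys == "__intercept__"
    if (sum(is_b) != 1L)
        stop("model file must contain exactly one __intercept__ row")
    w <- stats::setNames(vals[!is_b], keys[!is_b])
    hash <- get_hdr("universe_md5")
    if (universe_fingerprint(names(w)) != hash)
        stop("model file corrupt: universe fingerprint mismatch")
    new("DDIModel", weights = w, intercept = vals[is_b],
        hasIntercept = as.logical(get_hdr("intercept_enabled")),
        penaltyC = as.numeric(get_hdr("C")), universe = names(w),
        universeHash = hash,
        converged = as.logical(get_hdr("converged")),
        objective = as.numeric(get_hdr("objective")))
}
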