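## Independent oracles used across the suite. Each recomputes a quantity
## from first principles by a different route than the package code.

## confusion-derived metrics straight from label lists
oracle_metrics <- function(truth, pred) {
    TP <- sum(truth == 1 & pred == 1)
    FN <- sum(truth == 1 & pred == -1)
    FP <- sum(truth == -1 & pred == 1)
    TN <- sum(truth == -1 & pred == -1)
    div <- function(num, den) if (den == 0) NA_real_ else num / den
    mcc <- function(p, q, r, s) {
        d <- sqrt(p + r) * sqrt(p + s) * sqrt(q + r) * sqrt(q + s)
        if (d == 0) NA_real_ else (p * q - r * s) / d
    }
    pr <- div(TP, TP + FP); se <- div(TP, TP + FN)
    f1 <- if (is.na(pr) || is.na(se) || pr + se == 0) NA_real_
          else 2 * pr * se / (pr + se)
    list(TP = TP, FN = FN, FP = FP, TN = TN,
         PRpos = pr, SEpos = se,
         PRneg = div(TN, TN + FN), SEneg = div(TN, TN + FP),
         MCCpos = mcc(TP, TN, FP, FN), MCCneg = mcc(TN, TP, FN, FP),
         Acc = (TP + TN) / (TP + FN + FP + TN),
         MCC = mcc(TP + TN, TN + TP, FP + FN, FN + FP),
         F1 = f1)
}

## O(n^2) pairwise-counting AUC, ties counted one half
oracle_auc <- function(truth, scores) {
    sp <- scores[truth == 1]; sn <- scores[truth == -1]
    tot <- 0
    for (a in sp) for (b in sn)
        tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(sp) * length(sn))
}

## exhaustive recursive DFS over an adjacency list (1-based integer
## vectors); counts simple paths of <= cap edges from `from` to `to`
oracle_paths <- function(adj, from, to, cap) {
    lens <- integer(0)
    visited <- rep(FALSE, length(adj))
    rec <- function(u, depth) {
        if (depth > cap) return(invisible(NULL))
        if (u == to) {
            lens <<- c(lens, depth)
            return(invisible(NULL))
        }
        if (depth == cap) return(invisible(NULL))
        visited[u] <<- TRUE
        for (v in adj[[u]]) if (!visited[v]) rec(v, depth + 1L)
        visited[u] <<- FALSE
        invisible(NULL)
    }
    rec(from, 0L)
    list(count = length(lens),
         shortest = if (length(lens)) min(lens) else NA_real_,
         longest = if (length(lens)) max(lens) else NA_real_)
}

## random undirected simple graph as an edge matrix + adjacency list
random_graph <- function(n, p) {
    pairs <- t(utils::combn(n, 2L))
    keep <- stats::runif(nrow(pairs)) < p
    if (!any(keep)) keep[sample.int(nrow(pairs), 1L)] <- TRUE
    edges <- pairs[keep, , drop = FALSE]
    adj <- lapply(seq_len(n), function(i)
        sort(unique(c(edges[edges[, 1L] == i, 2L],
                      edges[edges[, 2L] == i, 1L]))))
    labels <- sprintf("N%02d", seq_len(n))
    list(n = n, edges = edges, adj = adj, labels = labels,
         edge_labels = cbind(labels[edges[, 1L]], labels[edges[, 2L]]))
}

## small random drug-target map for property tests
random_target_map <- function(n_drugs = 8L, n_genes = 12L) {
    genes <- sprintf("G%02d", seq_len(n_genes))
    tg <- lapply(seq_len(n_drugs), function(i)
        sample(genes, sample(1:4, 1L)))
    names(tg) <- sprintf("D%02d", seq_len(n_drugs))
    DrugTargetMap(tg)
}

## the printed two-drug example used throughout the docs
example_map <- function() {
    DrugTargetMap(list(DB14582 = c("ALB", "ORM1", "ORM2"),
                       DB01294 = c("ALB", "TF")))
}
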