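## Interaction-intensity statistics of drug pairs: Jaccard index of target
## sets, the Sim_U thresholded fraction, and PPI path statistics (average
## number of bounded simple paths, shortest and longest path length between
## the two drugs' target gene sets).

#' Jaccard index of two drugs' target gene sets
#'
#' Intersection over union of the target sets; the basic interaction
#' intensity of a drug pair. 1 for identical target sets, 0 for disjoint
#' ones.
#'
#' @param drugA,drugB drug identifiers present in `targets`.
#' @param targets a [DrugTargetMap].
#' @return numeric in \[0, 1\].
#' @examples
#' dtm <- DrugTargetMap(list(DB14582 = c("ALB", "ORM1", "ORM2"),
#'                           DB01294 = c("ALB", "TF")))
#' jaccardIndex("DB14582", "DB01294", dtm)   # 1/4
#' @export
jaccardIndex <- function(drugA, drugB, targets) {
    ga <- targetGenes(targets, drugA)
    gb <- targetGenes(targets, drugB)
    length(intersect(ga, gb)) / length(union(ga, gb))
}

jaccard_vec <- function(pairs, targets) {
    tg <- targetGenes(targets)
    mapply(function(a, b) {
        length(intersect(tg[[a]], tg[[b]])) /
            length(union(tg[[a]], tg[[b]]))
    }, pairs@drugA, pairs@drugB, USE.NAMES = FALSE)
}

#' Minimum reciprocal union size over a pair set
#'
#' `min over pairs of 1 / |G_a union G_b|`: with this value as the
#' threshold, [simU()] counts exactly the pairs that target at least one
#' common gene.
#'
#' @param pairs a non-empty [DrugPairSet].
#' @param targets a [DrugTargetMap] resolving every pair drug.
#' @return numeric threshold in (0, 1\].
#' @export
minXi <- function(pairs, targets) {
    stopifnot(is(pairs, "DrugPairSet"))
    if (length(pairs) == 0L)
        stop("empty pair set")
    tg <- targetGenes(targets)
    missing <- setdiff(drugNames(pairs), names(tg))
    if (length(missing))
        stop("unknown drug(s): ", paste(missing, collapse = ", "))
    unions <- mapply(function(a, b) length(union(tg[[a]], tg[[b]])),
                     pairs@drugA, pairs@drugB, USE.NAMES = FALSE)
    min(1 / unions)
}

#' Fraction of pairs whose interaction intensity meets a threshold
#'
#' The share of drug pairs in `pairs` with Jaccard index at least `xi`.
#' Non-increasing in `xi`.
#'
#' @inheritParams minXi
#' @param xi intensity threshold, in (0, 1\].
#' @return fraction in \[0, 1\].
#' @seealso [minXi()] for the threshold at which this counts pairs sharing
#'   at least one target gene.
#' @export
simU <- function(pairs, targets, xi) {
    if (!is.numeric(xi) || length(xi) != 1L || xi <= 0 || xi > 1)
        stop("xi must lie in (0, 1]")
    if (length(pairs) == 0L)
        stop("empty pair set")
    mean(jaccard_vec(pairs, targets) >= xi)
}

## adjacency representation shared by the enumeration routines
ppi_adjacency <- function(ppi) {
    g <- ppiGraph(ppi)
    adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
    list(adj = adj,
         index = stats::setNames(seq_along(adj),
                                 if (length(adj)) igraph::V(g)$name
                                 else character(0)))
}

## core per-gene-pair enumeration against a prebuilt adjacency;
## returns c(count, shortest, longest, truncated) with NA = unreachable
gene_pair_paths <- function(adjrep, g1, g2, maxLen, maxCount) {
    if (g1 == g2)            # shared gene: one path of length 0
        return(c(count = 1, shortest = 0, longest = 0, truncated = 0))
    i <- adjrep$index[g1]; j <- adjrep$index[g2]
    if (is.na(i) || is.na(j))    # gene not in the network: isolated node
        return(c(count = 0, shortest = NA_real_, longest = NA_real_,
                 truncated = 0))
    r <- .count_simple_paths(adjrep$adj, unname(i), unname(j),
                             as.integer(maxLen), as.numeric(maxCount))
    c(count = r[1L],
      shortest = if (r[2L] < 0) NA_real_ else r[2L],
      longest = if (r[3L] < 0) NA_real_ else r[3L],
      truncated = r[4L])
}

#' Enumerate bounded simple paths between two genes
#'
#' Counts all simple paths (no repeated node) of at most `maxLen` edges
#' between two genes in the PPI network, and the shortest and longest
#' lengths among them. All quantities respect the cap: a gene pair whose
#' only connections are longer than `maxLen` is reported unreachable.
#' Identical genes count as one path of length 0; a gene absent from the
#' network is treated as isolated (count 0) with a warning.
#'
#' @param gene1,gene2 gene symbols.
#' @param ppi a [PPINetwork].
#' @param maxLen path-length cap in edges (default 8).
#' @param maxCount per-pair path-count ceiling; the search stops there and
#'   flags truncation rather than enumerate without bound.
#' @return list with `count`, `shortest`, `longest` (`NA` = unreachable
#'   within the cap) and `truncated`.
#' @export
enumeratePaths <- function(gene1, gene2, ppi, maxLen = 8L,
                           maxCount = 1e6) {
    stopifnot(is(ppi, "PPINetwork"), maxLen >= 0L)
    gene1 <- toupper(gene1); gene2 <- toupper(gene2)
    adjrep <- ppi_adjacency(ppi)
    absent <- setdiff(unique(c(gene1, gene2)), names(adjrep$index))
    if (length(absent) && gene1 != gene2)
        warning("gene(s) absent from the PPI network, treated as ",
                "isolated: ", paste(absent, collapse = ", "))
    r <- gene_pair_paths(adjrep, gene1, gene2, maxLen, maxCount)
    list(count = unname(r["count"]), shortest = unname(r["shortest"]),
         longest = unname(r["longest"]),
         truncated = unname(r["truncated"]) > 0)
}

pair_stats_core <- function(ga, gb, adjrep, maxLen, maxCount,
                            cache = NULL) {
    stats <- matrix(NA_real_, length(ga) * length(gb), 4L)
    k <- 0L
    for (g1 in ga) for (g2 in gb) {
        k <- k + 1L
        if (!is.null(cache)) {
            key <- if (g1 <= g2) paste(g1, g2) else paste(g2, g1)
            hit <- cache[[key]]
            if (is.null(hit)) {
                hit <- gene_pair_paths(adjrep, g1, g2, maxLen, maxCount)
                cache[[key]] <- hit
            }
            stats[k, ] <- hit
        } else {
            stats[k, ] <- gene_pair_paths(adjrep, g1, g2, maxLen,
                                          maxCount)
        }
    }
    sh <- stats[, 2L]; lo <- stats[, 3L]
    list(avg = sum(stats[, 1L]) / nrow(stats),
         shortest = if (all(is.na(sh))) NA_real_ else min(sh, na.rm = TRUE),
         longest = if (all(is.na(lo))) NA_real_ else max(lo, na.rm = TRUE),
         truncated = any(stats[, 4L] > 0), detail = stats)
}

#' PPI path statistics of a drug pair
#'
#' For every cross gene pair (one target gene of each drug) the bounded
#' simple paths in the PPI network are enumerated; the pair-level
#' statistics are the average path count over all `|G_a| * |G_b|` cross
#' gene pairs, the minimum shortest length and the maximum (capped)
#' longest length. A shared target gene contributes one path of length 0,
#' so `shortest == 0` exactly when the drugs target a common gene, and
#' `avgPaths == 0` means no connection at all within the cap.
#'
#' @inheritParams jaccardIndex
#' @inheritParams enumeratePaths
#' @return a [PathStats].
#' @export
pairPathStats <- function(drugA, drugB, targets, ppi, maxLen = 8L,
                          maxCount = 1e6) {
    ga <- targetGenes(targets, drugA)
    gb <- targetGenes(targets, drugB)
    adjrep <- ppi_adjacency(ppi)
    absent <- setdiff(setdiff(unique(c(ga, gb)), names(adjrep$index)),
                      intersect(ga, gb))
    if (length(absent))
        warning("gene(s) absent from the PPI network, treated as ",
                "isolated: ", paste(absent, collapse = ", "))
    core <- pair_stats_core(ga, gb, adjrep, maxLen, maxCount)
    detail <- data.frame(geneA = rep(ga, each = length(gb)),
                         geneB = rep(gb, times = length(ga)),
                         count = core$detail[, 1L],
                         shortest = core$detail[, 2L],
                         longest = core$detail[, 3L],
                         truncated = core$detail[, 4L] > 0)
    new("PathStats", drugA = drugA, drugB = drugB, avgPaths = core$avg,
        shortest = core$shortest, longest = core$longest,
        maxLen = as.integer(maxLen), truncated = core$truncated,
        detail = detail)
}

#' Path-statistic distributions over a labeled pair cohort
#'
#' Computes the per-pair path statistics for every pair of a labeled
#' [DrugPairSet] and tabulates, per label class, the histograms of the
#' shortest and longest path lengths (with an explicit `unreachable` bin)
#' and the mean average-path count. Gene-pair enumerations are cached
#' across drug pairs.
#'
#' @inheritParams minXi
#' @inheritParams enumeratePaths
#' @return list with `perPair` (data.frame: drugA, drugB, label, jaccard,
#'   avgPaths, shortest, longest, truncated), `shortestHist` and
#'   `longestHist` (class x length count tables) and `meanAvg` (named
#'   numeric, mean avgPaths per class).
#' @export
cohortPathSummary <- function(pairs, targets, ppi, maxLen = 8L,
                              maxCount = 1e6) {
    stopifnot(is(pairs, "DrugPairSet"))
    adjrep <- ppi_adjacency(ppi)
    tg <- targetGenes(targets)
    missing <- setdiff(drugNames(pairs), names(tg))
    if (length(missing))
        stop("unknown drug(s): ", paste(missing, collapse = ", "))
    cache <- new.env(parent = emptyenv())
    n <- length(pairs)
    avg <- sh <- lo <- numeric(n)
    tr <- logical(n)
    for (i in seq_len(n)) {
        core <- pair_stats_core(tg[[pairs@drugA[i]]],
                                tg[[pairs@drugB[i]]],
                                adjrep, maxLen, maxCount, cache)
        avg[i] <- core$avg; sh[i] <- core$shortest
        lo[i] <- core$longest; tr[i] <- core$truncated
    }
    per_pair <- data.frame(drugA = pairs@drugA, drugB = pairs@drugB,
                           label = pairs@label,
                           jaccard = jaccard_vec(pairs, targets),
                           avgPaths = avg, shortest = sh, longest = lo,
                           truncated = tr)
    lev <- c(as.character(0:maxLen), "unreachable")
    bin <- function(v) factor(ifelse(is.na(v), "unreachable",
                                     as.character(v)), levels = lev)
    cls <- factor(ifelse(pairs@label == 1L, "positive", "negative"),
                  levels = c("positive", "negative"))
    list(perPair = per_pair,
         shortestHist = table(class = cls, shortest = bin(sh)),
         longestHist = table(class = cls, longest = bin(lo)),
         meanAvg = tapply(avg, cls, mean))
}
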