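#' @import methods
#' @importFrom Matrix sparseMatrix t colSums rowSums
#' @importFrom Rcpp sourceCpp
#' @useDynLib targetDDI, .registration = TRUE
NULL

#' DrugTargetMap: drugs and their target gene sets
#'
#' Maps each drug identifier to the set of human genes it is known to target.
#' Only drugs targeting at least one gene are representable: a drug with an
#' empty target set is rejected by the validity method, mirroring the
#' restriction of the modeling framework to drugs with at least one known
#' human target gene.
#'
#' @slot targets named list; one character vector of uppercased, deduplicated
#'   gene symbols per drug.
#'
#' @seealso [readDrugTargets()], [buildUniverse()], [jaccardIndex()]
#' @examples
#' dtm <- DrugTargetMap(list(DB14582 = c("ALB", "ORM1", "ORM2"),
#'                           DB01294 = c("ALB", "TF")))
#' drugNames(dtm)
#' targetGenes(dtm, "DB14582")
#' @export
setClass("DrugTargetMap", representation(targets = "list"))

setValidity("DrugTargetMap", function(object) {
    tg <- object@targets
    msgs <- character()
    if (is.null(names(tg)) || any(!nzchar(names(tg))))
        msgs <- c(msgs, "all drugs must be named")
    if (anyDuplicated(names(tg)))
        msgs <- c(msgs, "duplicated drug identifiers")
    bad <- vapply(tg, function(g) {
        !is.character(g) || length(g) == 0L || any(!nzchar(g)) ||
            anyDuplicated(g) > 0L || any(g != toupper(g))
    }, logical(1))
    if (any(bad))
        msgs <- c(msgs, paste0("invalid target sets (empty, duplicated or ",
                               "not uppercased) for: ",
                               paste(names(tg)[bad], collapse = ", ")))
    if (length(msgs)) msgs else TRUE
})

#' @rdname DrugTargetMap-class
#' @param targets named list of character vectors (drug id -> gene symbols).
#'   Symbols are uppercased and deduplicated; a drug whose set is empty after
#'   cleaning is an error.
#' @export
DrugTargetMap <- function(targets) {
    cleaned <- lapply(targets, function(g) {
        g <- toupper(as.character(g))
        unique(g[nzchar(g)])
    })
    empty <- lengths(cleaned) == 0L
    if (any(empty))
        stop("drugs with zero valid target genes: ",
             paste(names(targets)[empty], collapse = ", "))
    new("DrugTargetMap", targets = cleaned)
}

#' DrugPairSet: labeled unordered drug pairs
#'
#' A set of unordered drug pairs with interaction labels (+1 interacting,
#' -1 non-interacting). Pairs are stored in canonical form with the
#' lexicographically smaller drug id first; self-pairs and duplicate
#' unordered pairs are rejected.
#'
#' @slot drugA,drugB character; canonical pair members (`drugA < drugB`).
#' @slot label integer; +1 or -1 per pair.
#'
#' @seealso [readInteractions()], [designMatrix()], [kfoldCV()]
#' @export
setClass("DrugPairSet",
         representation(drugA = "character", drugB = "character",
                        label = "integer"))

setValidity("DrugPairSet", function(object) {
    a <- object@drugA; b <- object@drugB; y <- object@label
    msgs <- character()
    if (length(a) != length(b) || length(a) != length(y))
        msgs <- c(msgs, "drugA, drugB and label must have equal length")
    if (any(a == b))
        msgs <- c(msgs, "self-pairs are not allowed")
    if (any(a > b))
        msgs <- c(msgs, "pairs must be canonical (drugA < drugB)")
    if (anyDuplicated(paste(a, b, sep = "\t")))
        msgs <- c(msgs, "duplicate unordered pairs")
    if (length(y) && !all(y %in% c(-1L, 1L)))
        msgs <- c(msgs, "labels must be +1 or -1")
    if (length(msgs)) msgs else TRUE
})

#' @rdname DrugPairSet-class
#' @param drugA,drugB character vectors of drug identifiers (any order; pairs
#'   are canonicalized internally).
#' @param label integer vector of +1/-1 labels, recycled if length one.
#' @export
DrugPairSet <- function(drugA, drugB, label = 1L) {
    drugA <- as.character(drugA); drugB <- as.character(drugB)
    if (length(drugA) != length(drugB))
        stop("drugA and drugB must have equal length")
    label <- as.integer(rep_len(label, length(drugA)))
    if (any(self <- drugA == drugB))
        stop("self-pairs are not allowed: ",
             paste(unique(drugA[self]), collapse = ", "))
    swap <- drugA > drugB
    tmp <- drugA[swap]; drugA[swap] <- drugB[swap]; drugB[swap] <- tmp
    key <- paste(drugA, drugB, sep = "\t")
    if (anyDuplicated(key)) {
        lab_by_key <- split(label, key)
        conflict <- vapply(lab_by_key, function(v) length(unique(v)) > 1L,
                           logical(1))
        if (any(conflict))
            stop("conflicting labels for unordered pair(s): ",
                 paste(gsub("\t", "|", names(lab_by_key)[conflict]),
                       collapse = ", "))
        keep <- !duplicated(key)
        drugA <- drugA[keep]; drugB <- drugB[keep]; label <- label[keep]
    }
    new("DrugPairSet", drugA = drugA, drugB = drugB, label = label)
}

#' PPINetwork: undirected protein-protein interaction network
#'
#' A simple undirected graph over gene symbols, used to measure the proximity
#' of two drugs' target gene sets via path statistics.
#'
#' @slot graph an undirected, simple, vertex-named igraph object.
#'
#' @seealso [readPPI()], [enumeratePaths()], [pairPathStats()]
#' @export
setClass("PPINetwork", representation(graph = "ANY"))

setValidity("PPINetwork", function(object) {
    g <- object@graph
    msgs <- character()
    if (!igraph::is_igraph(g))
        return("graph slot must be an igraph object")
    if (igraph::is_directed(g))
        msgs <- c(msgs, "graph must be undirected")
    if (!igraph::is_simple(g))
        msgs <- c(msgs, "graph must be simple (no loops or multi-edges)")
    if (igraph::vcount(g) > 0L && is.null(igraph::V(g)$name))
        msgs <- c(msgs, "vertices must be named by gene symbol")
    if (length(msgs)) msgs else TRUE
})

#' @rdname PPINetwork-class
#' @param edges two-column character matrix or data.frame of gene pairs, or
#'   an igraph object. Self-loops and duplicate (undirected) edges are
#'   dropped; gene symbols are uppercased.
#' @export
PPINetwork <- function(edges) {
    if (igraph::is_igraph(edges)) {
        g <- igraph::as_undirected(edges, mode = "collapse")
        g <- igraph::simplify(g)
        return(new("PPINetwork", graph = g))
    }
    edges <- as.matrix(edges)
    if (length(edges) && ncol(edges) != 2L)
        stop("edges must have two columns")
    edges[] <- toupper(edges)
    if (nrow(edges)) {
        loops <- edges[, 1L] == edges[, 2L]
        if (any(loops))
            message("dropping ", sum(loops), " self-loop(s)")
        edges <- edges[!loops, , drop = FALSE]
    }
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::simplify(g)
    new("PPINetwork", graph = g)
}

#' PathwayCollection: named gene sets
#'
#' A collection of gene sets keyed by pathway or GO-term identifier. The
#' `kind` tag distinguishes signaling pathways from cellular-process (GO
#' biological process) collections; both are handled identically by the
#' overlap machinery.
#'
#' @slot sets named list of character vectors of gene symbols.
#' @slot kind either `"pathway"` or `"process"`.
#'
#' @seealso [readGeneSets()], [commonSets()]
#' @export
setClass("PathwayCollection",
         representation(sets = "list", kind = "character"))

setValidity("PathwayCollection", function(object) {
    msgs <- character()
    if (length(object@kind) != 1L ||
        !object@kind %in% c("pathway", "process"))
        msgs <- c(msgs, "kind must be 'pathway' or 'process'")
    s <- object@sets
    if (length(s)) {
        if (is.null(names(s)) || any(!nzchar(names(s))))
            msgs <- c(msgs, "all sets must be named")
        if (anyDuplicated(names(s)))
            msgs <- c(msgs, "duplicate set identifiers")
        if (any(lengths(s) == 0L))
            msgs <- c(msgs, "empty gene sets are not allowed")
    }
    if (length(msgs)) msgs else TRUE
})

#' @rdname PathwayCollection-class
#' @param sets named list of character vectors; genes are uppercased and
#'   deduplicated.
#' @param kind `"pathway"` or `"process"`.
#' @export
PathwayCollection <- function(sets, kind = c("pathway", "process")) {
    kind <- match.arg(kind)
    sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
    new("PathwayCollection", sets = sets, kind = kind)
}

#' GeneUniverse: the ordered feature space of target genes
#'
#' The entire target gene set of a drug roster, i.e. the union of the drugs'
#' target sets, in a fixed order that pins every gene to a feature position.
#' The default constructor sorts lexicographically for determinism; an
#' explicit order may be supplied (e.g. to reproduce a published example).
#'
#' @slot genes character; ordered, deduplicated gene symbols.
#'
#' @seealso [buildUniverse()], [drugProfile()], [pairProfile()]
#' @export
setClass("GeneUniverse", representation(genes = "character"))

setValidity("GeneUniverse", function(object) {
    g <- object@genes
    msgs <- character()
    if (length(g) == 0L) msgs <- c(msgs, "universe must be non-empty")
    if (anyDuplicated(g)) msgs <- c(msgs, "duplicate genes in universe")
    if (any(!nzchar(g))) msgs <- c(msgs, "empty gene symbol")
    if (length(msgs)) msgs else TRUE
})

#' @rdname GeneUniverse-class
#' @param genes character vector of gene symbols.
#' @param sort if `TRUE` (default) sort lexicographically (C locale);
#'   otherwise keep the given order.
#' @export
GeneUniverse <- function(genes, sort = TRUE) {
    genes <- unique(toupper(as.character(genes)))
    if (sort) genes <- sort_c(genes)
    new("GeneUniverse", genes = genes)
}

#' DDIModel: a trained l2-regularized logistic-regression classifier
#'
#' Holds the weight vector over the gene universe (one weight per universe
#' position of the pair-profile features), the optional unpenalized
#' intercept, the regularizer C, and a fingerprint of the gene universe the
#' model was trained on. Scoring refuses feature matrices whose column
#' universe does not match the fingerprint.
#'
#' @slot weights named numeric; one weight per universe gene, in universe
#'   order.
#' @slot intercept numeric(1); 0 when the intercept is disabled.
#' @slot hasIntercept logical(1).
#' @slot penaltyC numeric(1); the penalty parameter C of the training objective.
#' @slot universe character; the gene universe (column order of features).
#' @slot universeHash character(1); fingerprint of the universe.
#' @slot converged logical(1); optimizer convergence flag.
#' @slot objective numeric(1); objective value at the returned weights.
#'
#' @seealso [trainLogistic()], [predictProba()], [writeModel()]
#' @export
setClass("DDIModel",
         representation(weights = "numeric", intercept = "numeric",
                        hasIntercept = "logical", penaltyC = "numeric",
                        universe = "character", universeHash = "character",
                        converged = "logical", objective = "numeric"))

setValidity("DDIModel", function(object) {
    msgs <- character()
    if (length(object@weights) != length(object@universe))
        msgs <- c(msgs, "one weight per universe gene required")
    if (length(object@penaltyC) != 1L || object@penaltyC <= 0)
        msgs <- c(msgs, "C must be a single positive number")
    if (length(msgs)) msgs else TRUE
})

#' PathStats: PPI path statistics for one drug pair
#'
#' Interaction-intensity statistics of a drug pair in a PPI network: the
#' average number of bounded simple paths between cross target-gene pairs
#' (`avgPaths`), the minimum shortest-path length (`shortest`; 0 when the
#' drugs share a target gene, `NA` when no gene pair is reachable within the
#' cap) and the maximum path length found within the cap (`longest`).
#'
#' @slot drugA,drugB character(1).
#' @slot avgPaths numeric(1); total path count over all cross gene pairs
#'   divided by the number of cross gene pairs.
#' @slot shortest,longest numeric(1); edge counts, `NA` = unreachable within
#'   the cap.
#' @slot maxLen integer(1); the path-length cap used.
#' @slot truncated logical(1); `TRUE` if any gene pair hit the per-pair path
#'   count ceiling.
#' @slot detail data.frame; per gene pair: geneA, geneB, count, shortest,
#'   longest, truncated.
#'
#' @seealso [pairPathStats()], [enumeratePaths()]
#' @export
setClass("PathStats",
         representation(drugA = "character", drugB = "character",
                        avgPaths = "numeric", shortest = "numeric",
                        longest = "numeric", maxLen = "integer",
                        truncated = "logical", detail = "data.frame"))

#' OverlapResult: common pathways or processes of a drug pair
#'
#' The pathway/process identifiers hit by at least one target gene of each
#' drug of a pair, with the supporting genes of each drug per identifier.
#'
#' @slot drugA,drugB character(1).
#' @slot kind `"pathway"` or `"process"`.
#' @slot commonSets character; identifiers common to both drugs.
#' @slot support named list; per identifier a list with elements `genesA`
#'   and `genesB` (each drug's target genes inside that set).
#'
#' @seealso [commonSets()], [exportOverlapNetwork()]
#' @export
setClass("OverlapResult",
         representation(drugA = "character", drugB = "character",
                        kind = "character", commonSets = "character",
                        support = "list"))

## locale-independent lexicographic sort: feature positions must not depend
## on the session locale (radix sort orders by byte, i.e. C locale)
sort_c <- function(x) {
    if (!length(x)) return(character(0))
    sort(x, method = "radix")
}
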