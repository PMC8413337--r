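#' Accessors for targetDDI classes
#'
#' Small accessor generics for the package's S4 containers. Slot access
#' (`@`) is internal; user code should go through these.
#'
#' @param x a targetDDI object.
#' @param drug a single drug identifier, or `NULL` for all.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("drugNames", function(x) standardGeneric("drugNames"))

#' @rdname accessors
#' @export
setGeneric("targetGenes", function(x, drug = NULL)
    standardGeneric("targetGenes"))

#' @rdname accessors
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname accessors
#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))

#' @rdname accessors
#' @export
setGeneric("ppiGraph", function(x) standardGeneric("ppiGraph"))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("collectionKind", function(x) standardGeneric("collectionKind"))

#' @rdname accessors
#' @export
setGeneric("universeGenes", function(x) standardGeneric("universeGenes"))

#' @rdname accessors
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))

#' @rdname accessors
#' @export
setGeneric("modelIntercept", function(x) standardGeneric("modelIntercept"))

#' @rdname accessors
#' @export
setGeneric("modelC", function(x) standardGeneric("modelC"))

#' @rdname accessors
#' @export
setMethod("drugNames", "DrugTargetMap", function(x) names(x@targets))

#' @rdname accessors
#' @export
setMethod("targetGenes", "DrugTargetMap", function(x, drug = NULL) {
    if (is.null(drug)) return(x@targets)
    if (!drug %in% names(x@targets))
        stop("unknown drug: ", drug)
    x@targets[[drug]]
})

#' @rdname accessors
#' @export
setMethod("drugNames", "DrugPairSet",
          function(x) unique(c(x@drugA, x@drugB)))

#' @rdname accessors
#' @export
setMethod("pairTable", "DrugPairSet", function(x)
    data.frame(drugA = x@drugA, drugB = x@drugB, label = x@label,
               stringsAsFactors = FALSE))

#' @rdname accessors
#' @export
setMethod("pairLabels", "DrugPairSet", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("ppiGraph", "PPINetwork", function(x) x@graph)

#' @rdname accessors
#' @export
setMethod("geneSets", "PathwayCollection", function(x) x@sets)

#' @rdname accessors
#' @export
setMethod("collectionKind", "PathwayCollection", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("universeGenes", "GeneUniverse", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("modelWeights", "DDIModel", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("modelIntercept", "DDIModel", function(x) x@intercept)

#' @rdname accessors
#' @export
setMethod("modelC", "DDIModel", function(x) x@penaltyC)

#' @rdname accessors
#' @export
setMethod("length", "DrugPairSet", function(x) length(x@drugA))

#' @rdname accessors
#' @param i index vector for subsetting pairs.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "DrugPairSet", function(x, i, j, ..., drop = TRUE)
    new("DrugPairSet", drugA = x@drugA[i], drugB = x@drugB[i],
        label = x@label[i]))

setMethod("show", "DrugTargetMap", function(object) {
    ng <- length(unique(unlist(object@targets, use.names = FALSE)))
    cat("DrugTargetMap with", length(object@targets), "drugs and",
        ng, "distinct target genes\n")
    cat("  mean targets per drug:",
        round(mean(lengths(object@targets)), 2), "\n")
})

setMethod("show", "DrugPairSet", function(object) {
    cat("DrugPairSet with", length(object@drugA), "unordered pairs (",
        sum(object@label == 1L), "positive /",
        sum(object@label == -1L), "negative )\n")
})

setMethod("show", "PPINetwork", function(object) {
    cat("PPINetwork:", igraph::vcount(object@graph), "genes,",
        igraph::ecount(object@graph), "undirected interactions\n")
})

setMethod("show", "PathwayCollection", function(object) {
    cat("PathwayCollection (", object@kind, "): ",
        length(object@sets), " sets, sizes ",
        if (length(object@sets))
            paste0(min(lengths(object@sets)), "-",
                   max(lengths(object@sets))) else "-", "\n", sep = "")
})

setMethod("show", "GeneUniverse", function(object) {
    n <- length(object@genes)
    cat("GeneUniverse of", n, "genes:",
        paste(utils::head(object@genes, 5L), collapse = ", "),
        if (n > 5L) "..." else "", "\n")
})

setMethod("show", "DDIModel", function(object) {
    cat("DDIModel: l2-regularized logistic regression\n")
    cat("  universe:", length(object@universe), "genes ( fingerprint",
        substr(object@universeHash, 1L, 8L), ")\n")
    cat("  C =", format(object@penaltyC), "; intercept =",
        if (object@hasIntercept) format(object@intercept, digits = 4)
        else "disabled", "\n")
    cat("  converged:", object@converged, "; objective =",
        format(object@objective, digits = 6), "\n")
})

setMethod("show", "PathStats", function(object) {
    cat("PathStats for (", object@drugA, ",", object@drugB, ") cap =",
        object@maxLen, "\n")
    cat("  avgPaths =", format(object@avgPaths, digits = 4),
        "; shortest =",
        if (is.na(object@shortest)) "unreachable" else object@shortest,
        "; longest =",
        if (is.na(object@longest)) "unreachable" else object@longest,
        if (object@truncated) "(truncated)" else "", "\n")
})

setMethod("show", "OverlapResult", function(object) {
    cat("OverlapResult (", object@kind, ") for (", object@drugA, ",",
        object@drugB, "):", length(object@commonSets), "common sets\n")
    if (length(object@commonSets))
        cat("  ", paste(utils::head(object@commonSets, 5L),
                        collapse = ", "),
            if (length(object@commonSets) > 5L) "..." else "", "\n")
})
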