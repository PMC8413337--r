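## Pathway / cellular-process overlap of drug pairs: which gene sets are
## hit by at least one target gene of each drug. The identical machinery
## serves signaling-pathway collections and GO biological-process
## collections; only the kind tag differs.

## reverse index: gene -> set ids
gene_set_index <- function(collection) {
    s <- geneSets(collection)
    genes <- unlist(s, use.names = FALSE)
    ids <- rep(names(s), lengths(s))
    split(ids, genes)
}

#' Gene sets containing a gene
#'
#' @param gene a gene symbol (case-insensitive).
#' @param collection a [PathwayCollection].
#' @return character vector of set ids (empty if the gene is annotated
#'   nowhere).
#' @export
geneToSets <- function(gene, collection) {
    stopifnot(is(collection, "PathwayCollection"))
    idx <- gene_set_index(collection)
    ids <- idx[[toupper(gene)]]
    if (is.null(ids)) character(0) else sort_c(unique(ids))
}

#' Gene sets targeted by a drug
#'
#' Union of [geneToSets()] over the drug's target genes.
#'
#' @param drug a drug identifier.
#' @param targets a [DrugTargetMap].
#' @param collection a [PathwayCollection].
#' @return character vector of set ids.
#' @export
drugSets <- function(drug, targets, collection) {
    idx <- gene_set_index(collection)
    g <- targetGenes(targets, drug)
    sort_c(unique(unlist(idx[g], use.names = FALSE)))
}

#' Common pathways or processes of a drug pair
#'
#' Intersection of the two drugs' targeted set ids, with the supporting
#' target genes of each drug recorded per common id. Symmetric in the two
#' drugs up to swapping the supporting-gene columns.
#'
#' @param drugA,drugB drug identifiers.
#' @inheritParams drugSets
#' @return an [OverlapResult].
#' @examples
#' dtm <- DrugTargetMap(list(D1 = c("ALOX5"), D2 = c("MMP9")))
#' pc <- PathwayCollection(list(NEUTRO_DEGRAN = c("ALOX5", "MMP9")))
#' commonSets("D1", "D2", dtm, pc)
#' @export
commonSets <- function(drugA, drugB, targets, collection) {
    stopifnot(is(collection, "PathwayCollection"))
    ga <- targetGenes(targets, drugA)
    gb <- targetGenes(targets, drugB)
    idx <- gene_set_index(collection)
    idsA <- unique(unlist(idx[ga], use.names = FALSE))
    idsB <- unique(unlist(idx[gb], use.names = FALSE))
    common <- sort_c(intersect(idsA, idsB))
    sets <- geneSets(collection)
    support <- lapply(common, function(id)
        list(genesA = intersect(ga, sets[[id]]),
             genesB = intersect(gb, sets[[id]])))
    names(support) <- common
    new("OverlapResult", drugA = drugA, drugB = drugB,
        kind = collectionKind(collection), commonSets = common,
        support = support)
}

#' Export an overlap result as node and edge tables
#'
#' Writes two TSVs importable by standard network-visualization tools: a
#' node table (`id`, `type` in drug / gene / common_gene / set) and an
#' edge table (drug-to-supporting-gene and gene-to-set links). A
#' supporting gene targeted by both drugs is typed `common_gene`.
#'
#' @param result an [OverlapResult].
#' @param nodesPath,edgesPath output paths.
#' @param allowEmpty write header-only files when the result has no
#'   common sets (default is an error).
#' @return invisibly, a list with the node and edge data.frames.
#' @export
exportOverlapNetwork <- function(result, nodesPath, edgesPath,
                                 allowEmpty = FALSE) {
    stopifnot(is(result, "OverlapResult"))
    if (length(result@commonSets) == 0L && !allowEmpty)
        stop("empty overlap result (use allowEmpty = TRUE to export ",
             "header-only files)")
    genesA <- unique(unlist(lapply(result@support, `[[`, "genesA")))
    genesB <- unique(unlist(lapply(result@support, `[[`, "genesB")))
    shared <- intersect(genesA, genesB)
    all_genes <- union(genesA, genesB)
    nodes <- rbind(
        data.frame(id = c(result@drugA, result@drugB), type = "drug"),
        if (length(all_genes))
            data.frame(id = sort_c(all_genes),
                       type = ifelse(sort_c(all_genes) %in% shared,
                                     "common_gene", "gene")),
        if (length(result@commonSets))
            data.frame(id = result@commonSets, type = "set"))
    edges <- rbind(
        if (length(genesA))
            data.frame(from = result@drugA, to = sort_c(genesA)),
        if (length(setdiff(genesB, genesA)))
            data.frame(from = result@drugB,
                       to = sort_c(setdiff(genesB, genesA))),
        if (length(shared))
            data.frame(from = result@drugB, to = sort_c(shared)),
        do.call(rbind, lapply(names(result@support), function(id) {
            g <- union(result@support[[id]]$genesA,
                       result@support[[id]]$genesB)
            data.frame(from = sort_c(g), to = id)
        })))
    if (is.null(edges))
        edges <- data.frame(from = character(0), to = character(0))
    ## a shared supporting gene gets one drug edge from each drug and no
    ## duplicates
    edges <- unique(edges)
    utils::write.table(nodes, nodesPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(edges, edgesPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(list(nodes = nodes, edges = edges))
}

#' Common-set counts over a labeled pair cohort
#'
#' Number of common pathways and (optionally) common processes per pair,
#' for cohort-level comparison of interacting against non-interacting
#' pairs. Per-drug set memberships are computed once.
#'
#' @inheritParams minXi
#' @param pathways a [PathwayCollection] (kind `"pathway"`).
#' @param processes optional second [PathwayCollection] (kind
#'   `"process"`).
#' @return data.frame: drugA, drugB, label, nCommonPathways and, when
#'   `processes` is given, nCommonProcesses.
#' @export
overlapSummary <- function(pairs, targets, pathways, processes = NULL) {
    stopifnot(is(pairs, "DrugPairSet"))
    count_common <- function(collection) {
        idx <- gene_set_index(collection)
        tg <- targetGenes(targets)
        per_drug <- lapply(tg, function(g)
            unique(unlist(idx[g], use.names = FALSE)))
        mapply(function(a, b)
            length(intersect(per_drug[[a]], per_drug[[b]])),
            pairs@drugA, pairs@drugB, USE.NAMES = FALSE)
    }
    out <- data.frame(drugA = pairs@drugA, drugB = pairs@drugB,
                      label = pairs@label,
                      nCommonPathways = count_common(pathways))
    if (!is.null(processes))
        out$nCommonProcesses <- count_common(processes)
    out
}
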