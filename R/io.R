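## File readers and writers. All formats are UTF-8, tab-delimited; lines
## starting with "#" and blank lines are skipped. Parse errors report the
## 1-based physical line number of the offending line.

read_tab_lines <- function(path) {
    raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
    keep <- which(nzchar(trimws(raw)) & !startsWith(trimws(raw), "#"))
    list(fields = strsplit(raw[keep], "\t", fixed = TRUE), lineno = keep)
}

check_ncol <- function(parsed, n, path, exact = TRUE) {
    bad <- if (exact) lengths(parsed$fields) != n
           else lengths(parsed$fields) < n
    if (any(bad))
        stop("malformed line ", parsed$lineno[which(bad)[1L]], " in ",
             path, ": expected ", if (exact) "" else "at least ", n,
             " tab-separated fields", call. = FALSE)
}

#' Read a drug-target table
#'
#' Reads a two-column TSV of `drug_id<TAB>gene_symbol` records into a
#' [DrugTargetMap]. Gene symbols are uppercased and deduplicated per drug.
#' A drug whose records leave no valid gene is rejected, and any malformed
#' line is reported with its line number.
#'
#' @param path path to a tab-separated file; `#` comments and blank lines
#'   are skipped.
#' @return a [DrugTargetMap].
#' @seealso [writeDrugTargets()]
#' @export
readDrugTargets <- function(path) {
    parsed <- read_tab_lines(path)
    check_ncol(parsed, 2L, path)
    drug <- vapply(parsed$fields, `[`, character(1), 1L)
    gene <- vapply(parsed$fields, `[`, character(1), 2L)
    empty <- !nzchar(trimws(drug)) | !nzchar(trimws(gene))
    if (any(empty))
        stop("malformed line ", parsed$lineno[which(empty)[1L]], " in ",
             path, ": empty drug id or gene symbol", call. = FALSE)
    DrugTargetMap(split(toupper(trimws(gene)), trimws(drug)))
}

#' Write a drug-target table
#'
#' @param x a [DrugTargetMap].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDrugTargets <- function(x, path) {
    stopifnot(is(x, "DrugTargetMap"))
    tg <- targetGenes(x)
    lines <- unlist(lapply(names(tg), function(d)
        paste(d, tg[[d]], sep = "\t")), use.names = FALSE)
    writeLines(c("# drug_id\tgene_symbol", lines), path)
    invisible(path)
}

#' Read a drug-pair interaction list
#'
#' Reads `drug_a<TAB>drug_b[<TAB>label]` records into a [DrugPairSet].
#' Pairs are unordered: `(a,b)` and `(b,a)` are the same record and are
#' canonicalized with the lexicographically smaller id first; duplicates
#' collapse, conflicting labels for one unordered pair are an error, and
#' self-pairs are rejected.
#'
#' @param path path to a tab-separated file.
#' @param defaultLabel label (+1 or -1) assigned to rows without a label
#'   column.
#' @return a [DrugPairSet].
#' @seealso [writeInteractions()]
#' @export
readInteractions <- function(path, defaultLabel = 1L) {
    stopifnot(defaultLabel %in% c(-1L, 1L))
    parsed <- read_tab_lines(path)
    nf <- lengths(parsed$fields)
    if (any(nf < 2L | nf > 3L))
        stop("malformed line ", parsed$lineno[which(nf < 2L | nf > 3L)[1L]],
             " in ", path, ": expected 2 or 3 tab-separated fields",
             call. = FALSE)
    a <- trimws(vapply(parsed$fields, `[`, character(1), 1L))
    b <- trimws(vapply(parsed$fields, `[`, character(1), 2L))
    if (any(!nzchar(a) | !nzchar(b)))
        stop("malformed line ",
             parsed$lineno[which(!nzchar(a) | !nzchar(b))[1L]], " in ",
             path, ": empty drug id", call. = FALSE)
    lab <- rep(as.integer(defaultLabel), length(a))
    has3 <- nf == 3L
    if (any(has3)) {
        raw <- trimws(vapply(parsed$fields[has3], `[`, character(1), 3L))
        val <- suppressWarnings(as.integer(sub("^\\+", "", raw)))
        if (any(is.na(val) | !val %in% c(-1L, 1L)))
            stop("invalid label on line ",
                 parsed$lineno[has3][which(is.na(val) |
                                           !val %in% c(-1L, 1L))[1L]],
                 " in ", path, " (must be +1 or -1)", call. = FALSE)
        lab[has3] <- val
    }
    DrugPairSet(a, b, lab)
}

#' Write a drug-pair interaction list
#'
#' @param x a [DrugPairSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeInteractions <- function(x, path) {
    stopifnot(is(x, "DrugPairSet"))
    tab <- pairTable(x)
    writeLines(c("# drug_a\tdrug_b\tlabel",
                 sprintf("%s\t%s\t%+d", tab$drugA, tab$drugB, tab$label)),
               path)
    invisible(path)
}

#' Read a PPI edge list
#'
#' Reads a two-column TSV of undirected gene-gene interactions into a
#' [PPINetwork]. Duplicate edges (in either orientation) collapse;
#' self-loops are dropped with a message. An empty file yields an empty
#' network.
#'
#' @param path path to a tab-separated edge list.
#' @return a [PPINetwork].
#' @export
readPPI <- function(path) {
    parsed <- read_tab_lines(path)
    if (!length(parsed$lineno))
        return(PPINetwork(matrix(character(), 0L, 2L)))
    check_ncol(parsed, 2L, path)
    a <- trimws(vapply(parsed$fields, `[`, character(1), 1L))
    b <- trimws(vapply(parsed$fields, `[`, character(1), 2L))
    if (any(!nzchar(a) | !nzchar(b)))
        stop("malformed line ",
             parsed$lineno[which(!nzchar(a) | !nzchar(b))[1L]], " in ",
             path, ": empty gene symbol", call. = FALSE)
    PPINetwork(cbind(a, b))
}

#' Write a PPI edge list
#'
#' @param x a [PPINetwork].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePPI <- function(x, path) {
    stopifnot(is(x, "PPINetwork"))
    el <- igraph::as_edgelist(ppiGraph(x))
    writeLines(c("# gene_a\tgene_b",
                 if (nrow(el)) paste(el[, 1L], el[, 2L], sep = "\t")),
               path)
    invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: `set_id<TAB>description<TAB>gene1<TAB>gene2...`
#' per line. Genes are uppercased and deduplicated; duplicate set ids and
#' lines with fewer than three fields are errors.
#'
#' @param path path to a GMT file.
#' @param kind collection kind, `"pathway"` or `"process"`.
#' @return a [PathwayCollection].
#' @export
readGeneSets <- function(path, kind = c("pathway", "process")) {
    kind <- match.arg(kind)
    parsed <- read_tab_lines(path)
    check_ncol(parsed, 3L, path, exact = FALSE)
    ids <- vapply(parsed$fields, `[`, character(1), 1L)
    if (anyDuplicated(ids))
        stop("duplicate set id(s) in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "),
             call. = FALSE)
    sets <- lapply(parsed$fields, function(f) {
        g <- trimws(f[-(1:2)])
        g[nzchar(g)]
    })
    names(sets) <- ids
    if (any(lengths(sets) == 0L))
        stop("set(s) with no genes in ", path, ": ",
             paste(ids[lengths(sets) == 0L], collapse = ", "),
             call. = FALSE)
    PathwayCollection(sets, kind)
}

#' Write a GMT gene-set file
#'
#' @param x a [PathwayCollection].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneSets <- function(x, path) {
    stopifnot(is(x, "PathwayCollection"))
    s <- geneSets(x)
    writeLines(vapply(names(s), function(id)
        paste(c(id, collectionKind(x), s[[id]]), collapse = "\t"),
        character(1)), path)
    invisible(path)
}

#' Write a prediction table
#'
#' Writes one row per scored drug pair: `drug_a`, `drug_b`, the predicted
#' interaction probability (6 decimal places) and the predicted label.
#' Row order equals input order.
#'
#' @param pairs a [DrugPairSet] or a two-column data.frame/matrix of drug
#'   ids.
#' @param probabilities numeric vector of interaction probabilities, aligned
#'   with `pairs`.
#' @param labels integer vector of predicted labels (+1/-1), aligned with
#'   `pairs`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePredictions <- function(pairs, probabilities, labels, path) {
    if (is(pairs, "DrugPairSet")) {
        tab <- pairTable(pairs)
    } else {
        pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
        tab <- data.frame(drugA = as.character(pairs[[1L]]),
                          drugB = as.character(pairs[[2L]]))
    }
    if (nrow(tab) != length(probabilities) ||
        nrow(tab) != length(labels))
        stop("pairs, probabilities and labels must have equal length")
    writeLines(c("drug_a\tdrug_b\tprobability\tpredicted_label",
                 if (nrow(tab))
                     sprintf("%s\t%s\t%.6f\t%+d", tab$drugA, tab$drugB,
                             probabilities, as.integer(labels))),
               path)
    invisible(path)
}
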