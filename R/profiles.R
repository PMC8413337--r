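## Target-profile feature construction. A drug is a binary indicator vector
## over the gene universe; a drug pair is the elementwise sum of the two
## drug vectors, so an entry of 2 marks a common target gene. Genes outside
## the universe are discarded, which is what keeps train- and test-time
## features on identical descriptors.

#' Build the gene universe of a drug roster
#'
#' The universe is the union of the target gene sets of the listed drugs,
#' sorted lexicographically so that feature positions are deterministic and
#' independent of input file order. Build it from the *training* roster
#' only: at prediction time, target genes unseen in training fall outside
#' the universe and are discarded, keeping every feature matrix on the same
#' descriptors.
#'
#' @param targets a [DrugTargetMap].
#' @param drugs drug ids to include; defaults to every drug in `targets`.
#' @return a [GeneUniverse].
#' @examples
#' dtm <- DrugTargetMap(list(D1 = c("ALB", "ORM1"), D2 = c("ALB", "TF")))
#' universeGenes(buildUniverse(dtm))
#' @export
buildUniverse <- function(targets, drugs = drugNames(targets)) {
    stopifnot(is(targets, "DrugTargetMap"))
    if (length(drugs) == 0L)
        stop("empty drug list")
    missing <- setdiff(drugs, drugNames(targets))
    if (length(missing))
        stop("drugs absent from the target map: ",
             paste(missing, collapse = ", "))
    GeneUniverse(unlist(targetGenes(targets)[drugs], use.names = FALSE))
}

#' Binary target profile of one drug
#'
#' Indicator vector over the universe order: 1 exactly at the universe
#' positions of the drug's target genes. Target genes absent from the
#' universe are discarded; if all of a drug's targets fall outside, the
#' profile is all-zero and a warning is emitted.
#'
#' @param drug a drug identifier present in `targets`.
#' @param targets a [DrugTargetMap].
#' @param universe a [GeneUniverse].
#' @return named integer vector of 0/1 of length `length(universeGenes(universe))`.
#' @examples
#' dtm <- DrugTargetMap(list(DB14582 = c("ALB", "ORM1", "ORM2"),
#'                           DB01294 = c("ALB", "TF")))
#' u <- GeneUniverse(c("TF", "ALB", "XDH", "ORM1", "ORM2"), sort = FALSE)
#' drugProfile("DB14582", dtm, u)   # 0 1 0 1 1
#' @export
drugProfile <- function(drug, targets, universe) {
    stopifnot(is(targets, "DrugTargetMap"), is(universe, "GeneUniverse"))
    g <- targetGenes(targets, drug)
    u <- universeGenes(universe)
    v <- integer(length(u))
    names(v) <- u
    hit <- intersect(g, u)
    if (!length(hit))
        warning("all target genes of ", drug, " fall outside the universe")
    v[hit] <- 1L
    v
}

#' Combined target profile of a drug pair
#'
#' Elementwise sum of the two drug profiles: entries are 0, 1 or 2, with 2
#' exactly at common target genes. Symmetric in its two drug arguments.
#'
#' @inheritParams drugProfile
#' @param drugA,drugB distinct drug identifiers.
#' @return named integer vector with entries in \{0, 1, 2\}.
#' @examples
#' dtm <- DrugTargetMap(list(DB14582 = c("ALB", "ORM1", "ORM2"),
#'                           DB01294 = c("ALB", "TF")))
#' u <- GeneUniverse(c("TF", "ALB", "XDH", "ORM1", "ORM2"), sort = FALSE)
#' pairProfile("DB14582", "DB01294", dtm, u)   # 1 2 0 1 1
#' @export
pairProfile <- function(drugA, drugB, targets, universe) {
    if (drugA == drugB)
        stop("self-pairs are not modeled: ", drugA)
    drugProfile(drugA, targets, universe) +
        drugProfile(drugB, targets, universe)
}

#' Sparse design matrix of pair profiles
#'
#' Stacks the combined profile of every pair of a [DrugPairSet] into a
#' sparse row-per-pair matrix (columns = universe genes, in universe
#' order), with the label vector aligned to row order.
#'
#' @param pairs a [DrugPairSet].
#' @param targets a [DrugTargetMap]; every pair member must resolve here.
#' @param universe a [GeneUniverse].
#' @return list with `X` (a `dgCMatrix`, one row per pair, dimnames
#'   `pair-key x gene`) and `y` (integer +1/-1 labels).
#' @export
designMatrix <- function(pairs, targets, universe) {
    stopifnot(is(pairs, "DrugPairSet"), is(targets, "DrugTargetMap"),
              is(universe, "GeneUniverse"))
    if (length(pairs) == 0L)
        stop("empty pair list")
    tab <- pairTable(pairs)
    missing <- setdiff(unique(c(tab$drugA, tab$drugB)), drugNames(targets))
    if (length(missing))
        stop("pair drugs absent from the target map: ",
             paste(missing, collapse = ", "))
    u <- universeGenes(universe)
    idx <- stats::setNames(seq_along(u), u)
    tg <- targetGenes(targets)
    ## per pair, the concatenated universe positions of both drugs' genes;
    ## duplicated positions sum to 2 in sparseMatrix()
    posA <- lapply(tg[tab$drugA], function(g) unname(idx[intersect(g, u)]))
    posB <- lapply(tg[tab$drugB], function(g) unname(idx[intersect(g, u)]))
    cols <- mapply(c, posA, posB, SIMPLIFY = FALSE)
    rows <- rep.int(seq_len(nrow(tab)), lengths(cols))
    X <- Matrix::sparseMatrix(i = rows, j = unlist(cols, use.names = FALSE),
                              x = 1, dims = c(nrow(tab), length(u)),
                              dimnames = list(paste(tab$drugA, tab$drugB,
                                                    sep = "|"), u))
    list(X = X, y = tab$label)
}

## md5 fingerprint of a gene universe; base R has no in-memory digest, so
## the gene list is hashed through a temp file
universe_fingerprint <- function(genes) {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(genes, tf)
    unname(tools::md5sum(tf))
}
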