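## Seeded synthetic-data generator. Emulates the statistical structure the
## framework exploits: interacting drug pairs preferentially share target
## genes or have target genes close in the PPI network, and pathway gene
## sets are PPI-coherent so pathway overlap correlates with path proximity.
## Planted sharing is concentrated on a small pool of high-degree "driver"
## genes: a linear classifier on summed pair profiles is blind to sharing
## per se (the profile sum does not depend on which genes coincide), so
## learnable signal must be carried by gene identity, as it is in real
## interaction corpora where a few pharmacogenes recur across interacting
## pairs.

#' Configuration of the synthetic-data generator
#'
#' Validates and assembles the generator parameters. The defaults define
#' the package's reference simulation: 300 drugs over 400 genes with 1-6
#' targets per drug, a preferential-attachment PPI network, 2000 positive
#' and 2000 negative pairs, and 60% of positives planted to share a driver
#' gene plus 20% planted to have targets within PPI distance 2.
#'
#' @param nDrugs,nGenes roster sizes.
#' @param targetsPerDrug length-2 integer range of target-set sizes.
#' @param ppiDegree edges added per vertex (preferential attachment) or
#'   mean degree (Erdos-Renyi).
#' @param ppiModel `"pa"` (scale-free-like, default) or `"er"` (null
#'   topology).
#' @param nPathways,pathwaySize pathway collection size and set-size range.
#' @param nProcesses,processSize same for the cellular-process collection.
#' @param nPositivePairs,nNegativePairs pair counts.
#' @param shareProb probability a positive pair is planted to share a
#'   driver gene.
#' @param proximityProb probability a positive pair is instead planted to
#'   have targets within PPI distance <= 2; `shareProb + proximityProb`
#'   must not exceed 1.
#' @param nDriverGenes size of the high-degree driver-gene pool carrying
#'   the planted signal.
#' @param driverBoost sampling-weight multiplier for driver-targeting
#'   drugs when positive pairs are drawn: a drug targeting at least one
#'   driver gene is `1 + driverBoost` times as likely to enter a positive
#'   pair. This is what makes the planted signal visible to a linear
#'   classifier on summed pair profiles (which is blind to gene sharing
#'   per se and can only exploit class-dependent gene frequencies, the
#'   way recurring pharmacogenes mark interaction-prone drugs in real
#'   corpora). Set to 0 for a fully uniform null.
#' @param seed integer seed; the whole bundle is a deterministic function
#'   of it.
#' @return a validated `SynthConfig` list.
#' @export
synthConfig <- function(nDrugs = 300L, nGenes = 400L,
                        targetsPerDrug = c(1L, 6L), ppiDegree = 2L,
                        ppiModel = c("pa", "er"), nPathways = 50L,
                        pathwaySize = c(5L, 25L), nProcesses = 80L,
                        processSize = c(10L, 40L),
                        nPositivePairs = 2000L, nNegativePairs = 2000L,
                        shareProb = 0.6, proximityProb = 0.2,
                        nDriverGenes = 40L, driverBoost = 9,
                        seed = 1L) {
    ppiModel <- match.arg(ppiModel)
    cfg <- list(nDrugs = as.integer(nDrugs), nGenes = as.integer(nGenes),
                targetsPerDrug = as.integer(targetsPerDrug),
                ppiDegree = as.integer(ppiDegree), ppiModel = ppiModel,
                nPathways = as.integer(nPathways),
                pathwaySize = as.integer(pathwaySize),
                nProcesses = as.integer(nProcesses),
                processSize = as.integer(processSize),
                nPositivePairs = as.integer(nPositivePairs),
                nNegativePairs = as.integer(nNegativePairs),
                shareProb = shareProb, proximityProb = proximityProb,
                nDriverGenes = as.integer(nDriverGenes),
                driverBoost = as.numeric(driverBoost),
                seed = as.integer(seed))
    counts <- c(cfg$nDrugs, cfg$nGenes, cfg$nPathways, cfg$nProcesses,
                cfg$nPositivePairs, cfg$nNegativePairs, cfg$nDriverGenes)
    if (any(counts <= 0L))
        stop("all counts must be positive")
    if (length(cfg$targetsPerDrug) != 2L || cfg$targetsPerDrug[1L] < 1L ||
        diff(cfg$targetsPerDrug) < 0L)
        stop("targetsPerDrug must be an increasing range starting >= 1")
    probs <- c(cfg$shareProb, cfg$proximityProb)
    if (any(probs < 0) || any(probs > 1) || sum(probs) > 1)
        stop("shareProb and proximityProb must lie in [0,1] and sum to ",
             "at most 1")
    if (cfg$nDriverGenes > cfg$nGenes)
        stop("more driver genes than genes")
    if (cfg$driverBoost < 0)
        stop("driverBoost must be non-negative")
    npairs <- cfg$nDrugs * (cfg$nDrugs - 1) / 2
    if (cfg$nPositivePairs + cfg$nNegativePairs > npairs)
        stop("requested pair counts exceed the available pair space (",
             npairs, ")")
    class(cfg) <- "SynthConfig"
    cfg
}

## grow a PPI-coherent gene set from a degree-biased seed gene; stops
## early if the gene pool is exhausted
grow_gene_set <- function(g, genes, size) {
    size <- min(size, length(genes))
    deg <- igraph::degree(g)
    members <- sample(genes, 1L, prob = deg + 1)
    while (length(members) < size) {
        frontier <- setdiff(names(unlist(igraph::ego(
            g, order = 1L, nodes = members))), members)
        if (!length(frontier))
            frontier <- setdiff(genes, members)
        if (!length(frontier)) break
        members <- c(members, frontier[sample.int(length(frontier), 1L)])
    }
    members
}

#' Generate a seeded synthetic dataset
#'
#' Produces a drug-target map, a PPI network, pathway and process
#' collections, and labeled drug pairs with planted signal, as a
#' deterministic function of the config seed. Positive pairs are planted
#' to share a driver gene (with probability `shareProb`) or to have
#' targets within PPI distance 2 of a driver (with probability
#' `proximityProb`); negatives are sampled uniformly among the remaining
#' pairs, disjoint from the positives.
#'
#' @param config a [synthConfig()] list.
#' @return list with elements `targets` ([DrugTargetMap]), `ppi`
#'   ([PPINetwork]), `pathways` and `processes` ([PathwayCollection]),
#'   `pairs` (labeled [DrugPairSet]), `drivers` (character) and `config`.
#' @export
synthGenerate <- function(config) {
    stopifnot(inherits(config, "SynthConfig"))
    with_seed(config$seed, {
        genes <- sprintf("G%04d", seq_len(config$nGenes))
        drugs <- sprintf("D%04d", seq_len(config$nDrugs))
        g <- if (config$ppiModel == "pa")
                 igraph::sample_pa(config$nGenes, m = config$ppiDegree,
                                   directed = FALSE)
             else
                 igraph::sample_gnm(config$nGenes,
                                    config$ppiDegree * config$nGenes)
        igraph::V(g)$name <- genes
        g <- igraph::simplify(g)
        deg <- igraph::degree(g)
        drivers <- genes[order(-deg, seq_along(genes))][
            seq_len(config$nDriverGenes)]
        ## 2-hop neighborhoods of the drivers, for proximity planting
        hood <- lapply(igraph::ego(g, order = 2L, nodes = drivers),
                       function(v) setdiff(names(v), drivers))
        names(hood) <- drivers

        sizes <- sample(seq(config$targetsPerDrug[1L],
                            config$targetsPerDrug[2L]),
                        config$nDrugs, replace = TRUE)
        tg <- lapply(sizes, function(k) sample(genes, k))
        names(tg) <- drugs

        ## positive pairs: distinct canonical pairs, drawn with a boost
        ## for driver-targeting drugs, then per-pair planting
        wts <- 1 + config$driverBoost *
            vapply(tg, function(g) any(g %in% drivers), logical(1))
        keys <- character(0); pa <- pb <- character(0)
        while (length(keys) < config$nPositivePairs) {
            m <- 2L * (config$nPositivePairs - length(keys)) + 10L
            a <- sample(drugs, m, replace = TRUE, prob = wts)
            b <- sample(drugs, m, replace = TRUE, prob = wts)
            ok <- a != b
            a <- a[ok]; b <- b[ok]
            swap <- a > b
            tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
            key <- paste(a, b, sep = "\t")
            new <- !key %in% keys & !duplicated(key)
            keys <- c(keys, key[new])
            pa <- c(pa, a[new]); pb <- c(pb, b[new])
        }
        pa <- pa[seq_len(config$nPositivePairs)]
        pb <- pb[seq_len(config$nPositivePairs)]
        ## planting reuses a driver the pair already targets where
        ## possible, so per-drug driver sets stay small and coherent
        pick_driver <- function(a, b) {
            have <- intersect(union(tg[[a]], tg[[b]]), drivers)
            if (length(have)) have[sample.int(length(have), 1L)]
            else sample(drivers, 1L)
        }
        u <- stats::runif(config$nPositivePairs)
        for (i in seq_len(config$nPositivePairs)) {
            if (u[i] < config$shareProb) {
                d <- pick_driver(pa[i], pb[i])
                tg[[pa[i]]] <- union(tg[[pa[i]]], d)
                tg[[pb[i]]] <- union(tg[[pb[i]]], d)
            } else if (u[i] < config$shareProb + config$proximityProb) {
                d <- pick_driver(pa[i], pb[i])
                nb <- hood[[d]]
                tg[[pa[i]]] <- union(tg[[pa[i]]], d)
                tg[[pb[i]]] <- union(tg[[pb[i]]],
                                     if (length(nb)) sample(nb, 1L) else d)
            }
        }
        targets <- DrugTargetMap(tg)
        positives <- DrugPairSet(pa, pb, 1L)
        negatives <- sampleNegatives(drugs, positives,
                                     config$nNegativePairs)
        pairs <- DrugPairSet(c(positives@drugA, negatives@drugA),
                             c(positives@drugB, negatives@drugB),
                             c(positives@label, negatives@label))

        pw <- lapply(seq_len(config$nPathways), function(i)
            grow_gene_set(g, genes, sample(seq(config$pathwaySize[1L],
                                               config$pathwaySize[2L]),
                                           1L)))
        names(pw) <- sprintf("PW%03d", seq_len(config$nPathways))
        bp <- lapply(seq_len(config$nProcesses), function(i)
            grow_gene_set(g, genes, sample(seq(config$processSize[1L],
                                               config$processSize[2L]),
                                           1L)))
        names(bp) <- sprintf("BP%03d", seq_len(config$nProcesses))

        list(targets = targets, ppi = PPINetwork(g),
             pathways = PathwayCollection(pw, "pathway"),
             processes = PathwayCollection(bp, "process"),
             pairs = pairs, drivers = drivers, config = config)
    })
}

#' Per-class signal summary of a synthetic dataset
#'
#' Reports, per label class, the mean Jaccard index, the mean shortest
#' PPI path length between target sets (finite values only, capped at
#' `maxLen`), the fraction of pairs unreachable within the cap, and the
#' mean numbers of common pathways and processes. This is the
#' planted-signal acceptance surface: on a default bundle the positive
#' class should dominate the negative one on every column except the
#' shortest path, where it should be smaller.
#'
#' @param dataset a [synthGenerate()] result (or any list with the same
#'   elements).
#' @param maxLen shortest-path cap; longer or absent connections count as
#'   unreachable.
#' @return data.frame with rows `positive` and `negative`.
#' @export
expectedSignalCheck <- function(dataset, maxLen = 8L) {
    pairs <- dataset$pairs
    tg <- targetGenes(dataset$targets)
    dm <- igraph::distances(ppiGraph(dataset$ppi))
    net_genes <- rownames(dm)
    s_of <- function(a, b) {
        ga <- tg[[a]]; gb <- tg[[b]]
        if (length(intersect(ga, gb))) return(0)
        ga <- intersect(ga, net_genes); gb <- intersect(gb, net_genes)
        if (!length(ga) || !length(gb)) return(NA_real_)
        s <- min(dm[ga, gb, drop = FALSE])
        if (is.finite(s) && s <= maxLen) s else NA_real_
    }
    s <- mapply(s_of, pairs@drugA, pairs@drugB, USE.NAMES = FALSE)
    jac <- jaccard_vec(pairs, dataset$targets)
    ov <- overlapSummary(pairs, dataset$targets, dataset$pathways,
                         dataset$processes)
    cls <- pairs@label == 1L
    one <- function(sel) data.frame(
        nPairs = sum(sel),
        meanJaccard = mean(jac[sel]),
        meanShortest = mean(s[sel], na.rm = TRUE),
        fracUnreachable = mean(is.na(s[sel])),
        meanCommonPathways = mean(ov$nCommonPathways[sel]),
        meanCommonProcesses = mean(ov$nCommonProcesses[sel]))
    out <- rbind(one(cls), one(!cls))
    rownames(out) <- c("positive", "negative")
    out
}

#' Write a synthetic bundle to disk
#'
#' Writes the four input files in the package's file dialects
#' (drug-target TSV, interaction TSV, PPI edge list, two GMT files) plus
#' a manifest recording the full generator config.
#'
#' @param dataset a [synthGenerate()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeSynthBundle <- function(dataset, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(targets = file.path(dir, "drug_targets.tsv"),
               pairs = file.path(dir, "interactions.tsv"),
               ppi = file.path(dir, "ppi.tsv"),
               pathways = file.path(dir, "pathways.gmt"),
               processes = file.path(dir, "processes.gmt"),
               manifest = file.path(dir, "manifest.tsv"))
    writeDrugTargets(dataset$targets, paths["targets"])
    writeInteractions(dataset$pairs, paths["pairs"])
    writePPI(dataset$ppi, paths["ppi"])
    writeGeneSets(dataset$pathways, paths["pathways"])
    writeGeneSets(dataset$processes, paths["processes"])
    cfg <- dataset$config
    writeLines(c("# key\tvalue",
                 vapply(names(cfg), function(k)
                     paste(k, paste(cfg[[k]], collapse = ","),
                           sep = "\t"), character(1))),
               paths["manifest"])
    invisible(paths)
}
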