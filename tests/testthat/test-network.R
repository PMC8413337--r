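test_that("Jaccard index matches the printed target sets", {
    dtm <- example_map()
    expect_equal(jaccardIndex("DB14582", "DB01294", dtm), 0.25)
    same <- DrugTargetMap(list(D1 = c("A", "B"), D2 = c("B", "A")))
    expect_equal(jaccardIndex("D1", "D2", same), 1)
    disj <- DrugTargetMap(list(D1 = "A", D2 = "B"))
    expect_equal(jaccardIndex("D1", "D2", disj), 0)
    expect_error(jaccardIndex("D1", "NOPE", disj), "unknown drug")
})

test_that("the minimum reciprocal union threshold counts gene-sharers", {
    dtm <- DrugTargetMap(list(
        A = c("G1", "G2"), B = c("G3", "G4"),          # union 4
        C = c("G1", "G2", "G3"), D = c("G4", "G5"),    # union 5
        E = "G1", F = c("G1", "G9")))                  # union 2, shares G1
    ps <- DrugPairSet(c("A", "C", "E"), c("B", "D", "F"), 1L)
    expect_equal(minXi(ps, dtm), 1 / 5)
    single <- DrugPairSet("E", "F", 1L)
    dtm1 <- DrugTargetMap(list(E = "G1", F = "G1"))
    expect_equal(minXi(single, dtm1), 1)
    expect_error(minXi(ps[integer(0)], dtm), "empty")

    ## with xi = minXi, simU counts exactly the pairs sharing >= 1 gene
    withr::local_seed(67)
    for (rep in 1:10) {
        m <- random_target_map(10L, 12L)
        nm <- drugNames(m)
        pp <- DrugPairSet(nm[1:5], nm[6:10], 1L)
        xi <- minXi(pp, m)
        direct <- mean(mapply(function(a, b)
            length(intersect(targetGenes(m, a), targetGenes(m, b))) > 0L,
            pp@drugA, pp@drugB))
        expect_equal(simU(pp, m, xi), direct)
    }
})

test_that("simU is monotone non-increasing in xi", {
    withr::local_seed(71)
    m <- random_target_map(12L, 10L)
    nm <- drugNames(m)
    pp <- DrugPairSet(nm[1:6], nm[7:12], 1L)
    vals <- vapply(seq(0.05, 1, by = 0.05),
                   function(x) simU(pp, m, x), numeric(1))
    expect_true(all(diff(vals) <= 0))
    expect_equal(simU(pp, m, 1)[1] <= vals[1L], TRUE)
    ## xi above every Jaccard present -> 0
    disj <- DrugTargetMap(list(D1 = "A", D2 = "B"))
    expect_equal(simU(DrugPairSet("D1", "D2", 1L), disj, 0.5), 0)
    expect_error(simU(pp, m, 0), "xi")
    expect_error(simU(pp, m, 1.5), "xi")
})

test_that("path enumeration handles the canonical toy graphs", {
    path3 <- PPINetwork(cbind(c("A", "B"), c("B", "C")))
    r <- enumeratePaths("A", "C", path3, maxLen = 8L)
    expect_equal(r[c("count", "shortest", "longest")],
                 list(count = 1, shortest = 2, longest = 2))
    square <- PPINetwork(cbind(c("A", "B", "C", "D"),
                               c("B", "C", "D", "A")))
    r2 <- enumeratePaths("A", "C", square, maxLen = 8L)
    expect_equal(r2$count, 2)
    expect_equal(r2$shortest, 2)
    expect_equal(r2$longest, 2)
    ## cap semantics: everything respects the cap
    r3 <- enumeratePaths("A", "C", square, maxLen = 1L)
    expect_equal(r3$count, 0)
    expect_true(is.na(r3$shortest) && is.na(r3$longest))
    ## identical genes: one length-0 path by convention
    r4 <- enumeratePaths("A", "A", square)
    expect_equal(r4[c("count", "shortest", "longest")],
                 list(count = 1, shortest = 0, longest = 0))
    ## absent gene = isolated node
    expect_warning(r5 <- enumeratePaths("A", "ZZ", square), "absent")
    expect_equal(r5$count, 0)
})

test_that("enumeration equals exhaustive DFS on random graphs", {
    withr::local_seed(73)
    for (rep in 1:40) {
        n <- sample(3:12, 1L)
        g <- random_graph(n, stats::runif(1, 0.15, 0.5))
        net <- PPINetwork(g$edge_labels)
        cap <- sample(1:8, 1L)
        vs <- igraph::V(ppiGraph(net))$name
        ends <- sample(vs, 2L)
        mine <- enumeratePaths(ends[1L], ends[2L], net, maxLen = cap)
        ref <- oracle_paths(g$adj, match(ends[1L], g$labels),
                            match(ends[2L], g$labels), cap)
        expect_equal(mine$count, ref$count)
        expect_equal(mine$shortest, ref$shortest)
        expect_equal(mine$longest, ref$longest)
        ## raising the cap never loses paths or lengthens the shortest
        wider <- enumeratePaths(ends[1L], ends[2L], net,
                                maxLen = cap + 2L)
        expect_gte(wider$count, mine$count)
        if (!is.na(mine$shortest))
            expect_equal(wider$shortest, mine$shortest)
        if (!is.na(mine$longest))
            expect_gte(wider$longest, mine$longest)
    }
})

test_that("the per-pair ceiling truncates instead of hanging", {
    ## complete graph on 7 nodes has many simple paths
    nodes <- sprintf("K%d", 1:7)
    edges <- t(utils::combn(nodes, 2L))
    net <- PPINetwork(edges)
    full <- enumeratePaths("K1", "K2", net, maxLen = 6L)
    expect_false(full$truncated)
    capped <- enumeratePaths("K1", "K2", net, maxLen = 6L, maxCount = 10)
    expect_true(capped$truncated)
    expect_gte(capped$count, 10)
})

test_that("drug-pair path statistics follow the shared-gene conventions", {
    dtm <- DrugTargetMap(list(D1 = c("A", "B"), D2 = c("A", "C"),
                              D3 = "X", D4 = "Y"))
    net <- PPINetwork(cbind(c("A", "B", "X"), c("B", "C", "X2")))
    ## shared target gene A => shortest 0
    ps <- suppressWarnings(pairPathStats("D1", "D2", dtm, net))
    expect_equal(ps@shortest, 0)
    expect_s4_class(ps, "PathStats")
    ## disconnected components, no shared genes => Avg 0, unreachable
    ps2 <- suppressWarnings(pairPathStats("D3", "D4", dtm, net))
    expect_equal(ps2@avgPaths, 0)
    expect_true(is.na(ps2@shortest) && is.na(ps2@longest))
})

test_that("pair statistics equal brute-force enumeration on toy networks", {
    withr::local_seed(79)
    for (rep in 1:15) {
        n <- sample(5:12, 1L)
        g <- random_graph(n, stats::runif(1, 0.2, 0.45))
        net <- PPINetwork(g$edge_labels)
        vs <- igraph::V(ppiGraph(net))$name
        ga <- sample(vs, min(length(vs), sample(1:3, 1L)))
        gb <- sample(vs, min(length(vs), sample(1:3, 1L)))
        dtm <- DrugTargetMap(list(DA = ga, DB = gb))
        cap <- sample(2:6, 1L)
        ps <- pairPathStats("DA", "DB", dtm, net, maxLen = cap)
        ## oracle aggregation over all ordered cross gene pairs
        tot <- 0; smin <- Inf; lmax <- -Inf
        for (x in ga) for (y in gb) {
            if (x == y) { cnt <- 1; s <- 0; l <- 0 }
            else {
                r <- oracle_paths(g$adj, match(x, g$labels),
                                  match(y, g$labels), cap)
                cnt <- r$count; s <- r$shortest; l <- r$longest
            }
            tot <- tot + cnt
            if (!is.na(s)) smin <- min(smin, s)
            if (!is.na(l)) lmax <- max(lmax, l)
        }
        expect_equal(ps@avgPaths, tot / (length(ga) * length(gb)))
        expect_equal(ps@shortest,
                     if (is.finite(smin)) smin else NA_real_)
        expect_equal(ps@longest,
                     if (is.finite(lmax)) lmax else NA_real_)
        ## invariants and drug-order symmetry
        if (!is.na(ps@shortest) && !is.na(ps@longest))
            expect_lte(ps@shortest, ps@longest)
        shared <- length(intersect(ga, gb)) > 0L
        expect_equal(identical(ps@shortest, 0), shared)
        expect_equal(jaccardIndex("DA", "DB", dtm) > 0, shared)
        rev <- pairPathStats("DB", "DA", dtm, net, maxLen = cap)
        expect_equal(rev@avgPaths, ps@avgPaths)
        expect_equal(rev@shortest, ps@shortest)
        expect_equal(rev@longest, ps@longest)
    }
})

test_that("cohort summaries separate classes on planted data", {
    ds <- synthGenerate(synthConfig(nDrugs = 50L, nGenes = 60L,
                                    nPositivePairs = 60L,
                                    nNegativePairs = 60L,
                                    targetsPerDrug = c(1L, 3L),
                                    seed = 17L))
    summ <- cohortPathSummary(ds$pairs, ds$targets, ds$ppi,
                              maxLen = 3L, maxCount = 1e4)
    expect_equal(nrow(summ$perPair), 120L)
    s <- summ$perPair$shortest
    lab <- summ$perPair$label
    expect_lt(mean(s[lab == 1L], na.rm = TRUE),
              mean(s[lab == -1L], na.rm = TRUE))
    expect_equal(sum(summ$shortestHist), sum(!is.na(s)) + sum(is.na(s)))
    ## all pairs sharing genes -> shortest histogram mass entirely at 0
    dtm <- DrugTargetMap(list(D1 = "A", D2 = "A", D3 = c("A", "B")))
    pp <- DrugPairSet(c("D1", "D1"), c("D2", "D3"), 1L)
    net <- PPINetwork(cbind("A", "B"))
    h <- cohortPathSummary(pp, dtm, net)
    expect_equal(sum(h$shortestHist["positive", ]),
                 h$shortestHist["positive", "0"])
    ## empty network -> everything unreachable unless genes are shared
    empty <- PPINetwork(matrix(character(0), 0L, 2L))
    dtm2 <- DrugTargetMap(list(D1 = "A", D2 = "B"))
    h2 <- suppressWarnings(cohortPathSummary(
        DrugPairSet("D1", "D2", 1L), dtm2, empty))
    expect_equal(unname(h2$shortestHist["positive", "unreachable"]), 1L)
})
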