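# neighborhood: profiles, Jaccard context similarity, subgroup partitioning

test_that("neighborhood extraction enumerates the window correctly", {
    pg <- toy_pangenome(list(
        G1 = list(c("A", "B", "FOC", "C", "D", "E"))))
    focal <- geneTable(pg)$gene_id[3]
    p <- extractNeighborhood(pg, focal, windowK = 2)
    expect_setequal(p@neighborFamilies, c("A", "B", "C", "D"))
    expect_identical(p@orderedNeighbors$offset, c(-2L, -1L, 1L, 2L))

    # contig start: only right-side neighbors
    first <- geneTable(pg)$gene_id[1]
    p2 <- extractNeighborhood(pg, first, windowK = 3)
    expect_identical(p2@orderedNeighbors$offset, c(1L, 2L, 3L))

    expect_error(extractNeighborhood(pg, "nope", 2), "not found")
})

test_that("unassigned neighbors are excluded unless requested", {
    pg <- toy_pangenome(list(G1 = list(c(NA, "FOC", "Q"))))
    focal <- geneTable(pg)$gene_id[2]
    p <- extractNeighborhood(pg, focal, windowK = 1)
    expect_identical(p@neighborFamilies, "Q")
    p2 <- extractNeighborhood(pg, focal, windowK = 1,
                              includeUnassigned = TRUE)
    expect_true(any(grepl("^singleton:", p2@neighborFamilies)))
})

test_that("a queuosine-pathway-style context is captured in the profile", {
    # focal family member planted adjacent to QueC/QueE-labelled neighbors
    pg <- toy_pangenome(list(
        G1 = list(c("QueC", "QueE", "PTPS", "FolE"))))
    focal <- geneTable(pg)$gene_id[3]
    p <- extractNeighborhood(pg, focal, windowK = 5)
    expect_true(all(c("QueC", "QueE", "FolE") %in% p@neighborFamilies))
    expect_false("PTPS" %in% p@neighborFamilies)  # own family excluded
})

test_that("profile similarity is the Jaccard index with both-empty -> 0", {
    mkp <- function(fams) new("NeighborhoodProfile", focalGene = "g",
                              focalFamily = "F", windowK = 5L,
                              neighborFamilies = fams,
                              orderedNeighbors = data.frame())
    expect_equal(neighborhoodSimilarity(mkp(c("A", "B")), mkp(c("A", "B"))), 1)
    expect_equal(neighborhoodSimilarity(mkp(c("A", "B")), mkp(c("C", "D"))), 0)
    expect_equal(neighborhoodSimilarity(mkp(c("A", "B", "C")),
                                        mkp(c("B", "C", "D"))), 0.5)
    expect_equal(neighborhoodSimilarity(mkp(character()), mkp(character())), 0)
    # property: matches brute-force element counting, symmetric
    set.seed(5)
    pool <- sprintf("F%02d", 1:12)
    for (i in 1:25) {
        a <- sample(pool, sample(0:6, 1)); b <- sample(pool, sample(0:6, 1))
        expect_equal(neighborhoodSimilarity(mkp(a), mkp(b)),
                     oracle_jaccard(a, b))
        expect_equal(neighborhoodSimilarity(mkp(a), mkp(b)),
                     neighborhoodSimilarity(mkp(b), mkp(a)))
    }
})

# helper: profiles + genome map from a toy pan-genome for family FOC
foc_profiles <- function(pg, k = 5) {
    gt <- geneTable(pg)
    profiles <- familyProfiles(pg, "FOC", windowK = k)
    list(profiles = profiles,
         genomes = setNames(gt$genome_id, gt$gene_id))
}

test_that("context graph edges equal brute-force pairwise enumeration", {
    set.seed(9)
    pool <- sprintf("N%02d", 1:8)
    gs <- lapply(1:6, function(i)
        list(c(sample(pool, 3), "FOC", sample(pool, 3))))
    names(gs) <- paste0("G", 1:6)
    pg <- toy_pangenome(gs)
    fp <- foc_profiles(pg)
    for (tau in c(0, 0.25, 0.5)) {
        g <- buildContextGraph(fp$profiles, tau, fp$genomes)
        ids <- names(fp$profiles)
        brute <- list()
        for (i in seq_along(ids)[-length(ids)]) {
            for (j in seq(i + 1, length(ids))) {
                s <- oracle_jaccard(fp$profiles[[i]]@neighborFamilies,
                                    fp$profiles[[j]]@neighborFamilies)
                if (s >= tau)
                    brute[[length(brute) + 1L]] <- c(ids[i], ids[j])
            }
        }
        expect_identical(nrow(g@edges), length(brute))
    }
    # tau above 1 gives an empty edge set
    g0 <- buildContextGraph(fp$profiles, 1.01, fp$genomes)
    expect_identical(nrow(g0@edges), 0L)
})

test_that("partitioning equals exhaustive components and is label-stable", {
    mkgraph <- function(ids, genomes, edges) {
        profs <- lapply(ids, function(i)
            new("NeighborhoodProfile", focalGene = i, focalFamily = "F",
                windowK = 5L, neighborFamilies = c("X"),
                orderedNeighbors = data.frame()))
        names(profs) <- ids
        new("ContextGraph", nodes = ids, genomes = genomes,
            edges = edges, tau = 0.3, profiles = profs)
    }
    set.seed(21)
    for (rep in 1:20) {
        n <- sample(3:8, 1)
        ids <- sprintf("g%02d", sample(100, n))
        genomes <- setNames(sprintf("G%d", sample(1:4, n, replace = TRUE)),
                            ids)
        pairs <- t(combn(sort(ids), 2))
        pick <- which(runif(nrow(pairs)) < 0.3)
        edges <- data.frame(from = pairs[pick, 1], to = pairs[pick, 2],
                            weight = rep(1, length(pick)),
                            stringsAsFactors = FALSE)
        part <- partitionFamily(mkgraph(ids, genomes, edges), "F")
        comp <- oracle_components(sort(ids), edges)
        # each subgroup must be exactly one oracle component that passes
        # the >=2 members / >=2 genomes support rule
        placed <- character()
        for (sg in names(subgroups(part))) {
            mem <- subgroups(part)[[sg]]$members
            expect_identical(length(unique(comp[mem])), 1L)
            expect_identical(sort(names(comp)[comp == comp[mem[1]]]), mem)
            expect_gte(length(mem), 2L)
            expect_gte(length(unique(genomes[mem])), 2L)
            placed <- c(placed, mem)
        }
        # unplaced components fail the support rule
        for (u in unplacedGenes(part)) {
            mem <- names(comp)[comp == comp[u]]
            expect_true(length(mem) < 2 ||
                        length(unique(genomes[mem])) < 2)
        }
        expect_setequal(c(placed, unplacedGenes(part)), ids)
        # label stability under node input order
        perm <- sample(n)
        part2 <- partitionFamily(
            mkgraph(ids[perm], genomes[ids[perm]], edges), "F")
        expect_identical(lapply(subgroups(part), `[[`, "members"),
                         lapply(subgroups(part2), `[[`, "members"))
    }
})

test_that("an all-isolated graph leaves every member unplaced", {
    ids <- c("a", "b", "c")
    profs <- lapply(ids, function(i)
        new("NeighborhoodProfile", focalGene = i, focalFamily = "F",
            windowK = 5L, neighborFamilies = character(),
            orderedNeighbors = data.frame()))
    names(profs) <- ids
    g <- new("ContextGraph", nodes = ids,
             genomes = setNames(c("G1", "G2", "G3"), ids),
             edges = data.frame(from = character(), to = character(),
                                weight = numeric()),
             tau = 0.3, profiles = profs)
    part <- partitionFamily(g, "F")
    expect_identical(length(subgroups(part)), 0L)
    expect_setequal(unplacedGenes(part), ids)
})

test_that("two conserved contexts separate into two supported subgroups", {
    # Fig-3B-style encoding: one subgroup clustered with Que-labelled
    # neighbors, the other with Fol-labelled neighbors, across genomes
    # including two-paralog genomes
    que <- c("QueC", "QueE", "QueF"); fol <- c("FolE", "FolB", "FolK")
    gs <- list(
        G1 = list(c(que[1:2], "FOC", que[3]), c(fol[1:2], "FOC", fol[3])),
        G2 = list(c(que, "FOC")),
        G3 = list(c("FOC", fol)),
        G4 = list(c(que[c(2, 1)], "FOC", que[3]), c(fol[2:3], "FOC", fol[1])))
    pg <- toy_pangenome(gs)
    fp <- foc_profiles(pg)
    part <- partitionFamily(
        buildContextGraph(fp$profiles, 0.3, fp$genomes), "FOC")
    expect_identical(length(subgroups(part)), 2L)
    expect_identical(length(unplacedGenes(part)), 0L)
    supports <- lapply(subgroups(part), `[[`, "support")
    expect_setequal(unlist(lapply(supports, function(s)
        if (all(grepl("^Que", s))) "que" else "fol")), c("que", "fol"))
    # the planted split is recovered exactly
    gt <- geneTable(pg)
    members <- lapply(subgroups(part), `[[`, "members")
    que_genes <- gt$gene_id[gt$contig_id == "c01" & gt$family_id %in% "FOC" &
                            gt$genome_id != "G3"]
    expect_true(any(vapply(members, function(m)
        setequal(m, sort(que_genes)), FALSE)))
})

test_that("raising tau never merges subgroups (monotone refinement)", {
    set.seed(33)
    pool <- sprintf("N%02d", 1:10)
    gs <- lapply(1:8, function(i)
        list(c(sample(pool, 2), "FOC", sample(pool, 2))))
    names(gs) <- paste0("G", 1:8)
    pg <- toy_pangenome(gs)
    fp <- foc_profiles(pg)
    taus <- seq(0, 1, by = 0.2)
    parts <- lapply(taus, function(t)
        partitionFamily(buildContextGraph(fp$profiles, t, fp$genomes), "F"))
    for (i in seq_along(taus)[-1]) {
        # members grouped at the higher tau are grouped at the lower tau
        hi <- parts[[i]]; lo <- parts[[i - 1]]
        lo_lab <- subgroupOf(lo, names(fp$profiles))
        for (sg in names(subgroups(hi))) {
            mem <- subgroups(hi)[[sg]]$members
            expect_identical(length(unique(lo_lab[mem])), 1L)
        }
    }
})

test_that("GNN summary tallies neighbor families per subgroup", {
    que <- c("QueC", "QueE", "QueF")
    gs <- lapply(1:5, function(i) list(c(que, "FOC")))
    names(gs) <- paste0("G", 1:5)
    pg <- toy_pangenome(gs)
    fp <- foc_profiles(pg)
    part <- partitionFamily(
        buildContextGraph(fp$profiles, 0.3, fp$genomes), "FOC")
    tab <- gnnSummary(part, fp$profiles)
    expect_identical(tab$n_members[1], 5L)
    expect_equal(tab$fraction_members[1], 1)
    expect_setequal(tab$neighbor_family, que)
    expect_identical(tab$n_genomes, rep(5L, 3))
    # empty partition -> empty table
    empty <- new("SubgroupPartition", familyId = "F", subgroups = list(),
                 unplaced = character(), genomes = character())
    expect_identical(nrow(gnnSummary(empty, fp$profiles)), 0L)
})
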