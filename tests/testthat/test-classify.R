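# classify: motif matching, PSSM backstop, annotation propagation

test_that("pattern matching reports all (overlapping) wildcard matches", {
    p <- "AACELLHGHAA"
    expect_identical(matchMotif(p, "CxxxHGH"), 3L)
    expect_identical(matchMotif(p, "ExxHGH"), 4L)   # offset +1: hybrid core
    expect_identical(matchMotif("AAKLMNP", "CxxxHGH"), integer(0))
    expect_identical(matchMotif("AAKLMNP", "ExxHGH"), integer(0))
    # overlapping matches are all reported
    expect_identical(matchMotif("HGHGHGH", "HGH"), c(1L, 3L, 5L))
    expect_error(matchMotif(p, "Cx#H"), "invalid pattern")
})

test_that("PSSM scoring equals exhaustive window enumeration", {
    set.seed(51)
    rows <- vapply(1:8, function(i) seq_with("CLAHGH", 30, 12), "")
    b <- block_of(rows)
    win <- selectMotifWindow(b, 6)
    pfm <- buildPFM(b, win)
    freqs <- pfm@freqs[c(AA20, "X"), , drop = FALSE]
    for (i in 1:5) {
        prot <- random_protein(25)
        got <- scorePssm(prot, pfm)
        want <- oracle_pssm(prot, freqs)
        expect_equal(got$score, want$score, tolerance = 1e-9)
        expect_identical(got$position, want$position)
    }
    # the consensus sequence achieves the maximal score at the planted spot
    cons <- paste0(strrep("A", 5), "CLAHGH", strrep("A", 5))
    got <- scorePssm(cons, pfm)
    expect_identical(got$position, 6L)
    rand <- scorePssm(random_protein(16), pfm)
    expect_gt(got$score, rand$score)
    expect_error(scorePssm("ACD", pfm), "shorter")
})

test_that("classification follows the context > motif precedence rules", {
    sigs <- c(SGI = "CxxxHGH", SGIII = "ExxHGH")
    part <- new("SubgroupPartition", familyId = "F",
                subgroups = list(
                    SGI = list(members = c("g1", "g2"), support = "QueC"),
                    SGIII = list(members = c("g3", "g4"), support = "FolE")),
                unplaced = c("g5", "g6", "g7"),
                genomes = setNames(paste0("G", 1:7), paste0("g", 1:7)))

    # rule 1: context member whose own signature matches -> high confidence
    c1 <- classifyGene("g1", "AACTTTHGHAA", sigs, part)
    expect_identical(c1$subgroup, "SGI")
    expect_identical(c1$evidence, "context+motif")
    expect_identical(c1$confidence, "high")

    # adversarial: context member matching only the OTHER signature keeps
    # its context subgroup (context overrides motif)
    c2 <- classifyGene("g3", "AACTTTHGHAA", sigs, part)
    expect_identical(c2$subgroup, "SGIII")
    expect_identical(c2$evidence, "context")

    # rule 2: unplaced member, single match
    c3 <- classifyGene("g5", "AAETTHGHAA", sigs, part)
    expect_identical(c3$subgroup, "SGIII")
    expect_identical(c3$evidence, "motif")
    expect_identical(c3$confidence, "medium")

    # rule 3: the CExxHGH hybrid matches both parental patterns
    c4 <- classifyGene("g6", "AACETTHGHAA", sigs, part)
    expect_identical(c4$evidence, "hybrid")
    expect_identical(c4$subgroup, "SGI+SGIII")
    expect_identical(c4$motif_matched, "CxxxHGH;ExxHGH")

    # rule 4: no match
    c5 <- classifyGene("g7", "AAKLMNPQRAA", sigs, part)
    expect_identical(c5$subgroup, "unresolved")
    expect_identical(c5$evidence, "none")
    expect_identical(c5$confidence, "low")

    # short sequence: flagged like a wrong start call
    c6 <- classifyGene("g7", "ACD", sigs, part)
    expect_identical(c6$subgroup, "unresolved")
    expect_match(c6$note, "short")

    expect_error(classifyGene("g7", "AAA", character(), part), "non-empty")
})

test_that("annotateFamily covers every member exactly once", {
    sim <- default_sim(61, n_genomes = 8)
    gm <- setNames(geneTable(sim$pg)$genome_id, geneTable(sim$pg)$gene_id)
    profiles <- familyProfiles(sim$pg, "FAM0001")
    part <- partitionFamily(buildContextGraph(profiles, 0.3, gm), "FAM0001")
    sigs <- setNames(unique(sim$truth$pattern),
                     unique(sim$truth$subgroup))
    calls <- annotateFamily(sim$pg, "FAM0001", part, sigs)
    expect_setequal(calls$gene_id, sim$truth$gene_id)
    expect_identical(anyDuplicated(calls$gene_id), 0L)
    placed <- unlist(lapply(subgroups(part), `[[`, "members"))
    expect_true(all(calls$evidence[calls$gene_id %in% placed] %in%
                    c("context", "context+motif")))
    # empty signature set: unplaced members come back unresolved
    calls0 <- annotateFamily(sim$pg, "FAM0001", part, character())
    un <- calls0[calls0$gene_id %in% unplacedGenes(part), ]
    expect_true(all(un$subgroup == "unresolved" & un$evidence == "none"))
})

test_that("held-out recovery is accurate and degrades with motif mutation", {
    specific_correct <- function(mut, seed) {
        sim <- default_sim(seed, motif_mutation = mut)
        res <- suppressWarnings(
            evaluateRecovery(sim$pg, sim$truth, holdoutFraction = 0.2,
                             seed = seed + 1))
        # fraction of held-out members with a *correct specific* call
        res$heldout_coverage * ifelse(is.na(res$heldout_accuracy), 0,
                                      res$heldout_accuracy)
    }
    lo <- specific_correct(0.02, 71)
    mid <- specific_correct(0.25, 71)
    hi <- specific_correct(0.6, 71)
    expect_gte(lo, 0.95)
    expect_gte(lo, mid - 1e-9)
    expect_gte(mid, hi - 1e-9)
})
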