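# motif: stacking alignment, window selection, PFM/IC, consensus,
# two-sample logo statistics

test_that("stacking alignment honors the common coordinate frame", {
    s <- "MKLVHGHAALQ"
    b <- alignSubgroup(c(a = s, b = s, c = s))
    expect_identical(unique(as.character(b@alignment)), s)

    s2 <- sub("V", "I", s)
    b2 <- alignSubgroup(c(a = s, b = s2))
    m <- as.matrix(b2@alignment)
    expect_identical(sum(m[1, ] != m[2, ]), 1L)

    b3 <- alignSubgroup(c(a = s, b = paste0(s, "WWW")))
    expect_identical(Biostrings::width(b3@alignment),
                     rep(nchar(s) + 3L, 2))
    expect_identical(as.character(Biostrings::subseq(b3@alignment[[1]],
                                                     nchar(s) + 1L)), "---")
    expect_error(alignSubgroup(c(a = s)), "at least 2")
})

test_that("planted motifs share columns with the generator truth", {
    sim <- generatePanGenome(synthConfig(seed = 19, n_genomes = 10,
                                         motif_mutation = 0))
    pg <- readPanGenome(sim$gff, sim$fasta, sim$family)
    for (sg in unique(sim$truth$subgroup)) {
        tr <- sim$truth[sim$truth$subgroup == sg, ]
        if (nrow(tr) < 2) next
        blk <- alignSubgroup(as.character(proteins(pg)[tr$gene_id]), sg)
        m <- as.matrix(blk@alignment)
        off <- unique(tr$motif_start)
        expect_identical(length(off), 1L)  # homologous motif positions
        pat <- strsplit(tr$pattern[1], "")[[1]]
        for (k in which(pat != "x"))
            expect_true(all(m[, off + k - 1L] == pat[k]))
    }
})

test_that("PFM columns carry analytic frequencies and information content", {
    b <- block_of(rep("H", 10))   # 10 rows of single-column 'H'
    pfm <- buildPFM(b)
    expect_equal(unname(pfm@freqs["H", 1]), 1)
    expect_equal(pfm@ic[1], log2(20))

    b2 <- block_of(rep(c("C", "E"), each = 5))
    pfm2 <- buildPFM(b2)
    expect_equal(pfm2@ic[1], log2(20) - 1)

    b3 <- block_of(AA20)   # uniform over the 20 residues
    expect_equal(buildPFM(b3)@ic[1], 0)

    # frequencies always sum to 1; IC within bounds (property)
    set.seed(2)
    rows <- vapply(1:9, function(i) random_protein(30), "")
    pfm4 <- buildPFM(block_of(rows))
    expect_true(all(abs(colSums(pfm4@freqs) - 1) < 1e-12))
    expect_true(all(pfm4@ic >= 0 & pfm4@ic <= log2(20)))

    # all-gap column: IC 0, zero occupancy
    b5 <- block_of(c("A-A", "C-C"))
    pfm5 <- buildPFM(b5)
    expect_equal(pfm5@ic[2], 0)
    expect_equal(pfm5@occupancy[2], 0)
})

test_that("the motif window scan finds the conserved run, leftmost on ties", {
    set.seed(13)
    conserved <- "CLHGHQW"
    rows <- vapply(1:8, function(i)
        paste0(random_protein(20), conserved, random_protein(20)), "")
    b <- block_of(rows)
    win <- selectMotifWindow(b, 7)
    expect_identical(win, c(21L, 27L))
    # exhaustive scan oracle: summed occupancy-weighted IC is maximal there
    pfm <- buildPFM(b)
    sc <- pfm@ic * pfm@occupancy
    sums <- vapply(1:(47 - 6), function(s) sum(sc[s:(s + 6)]), 0)
    expect_identical(which.max(sums), 21L)

    # full-width window and exact ties
    expect_identical(selectMotifWindow(b, 47), c(1L, 47L))
    bt <- block_of(rep("AAAAA", 4))
    expect_identical(selectMotifWindow(bt, 3), c(1L, 3L))  # leftmost tie
    expect_error(selectMotifWindow(bt, 9), "width")
})

test_that("consensus signatures recover subfamily patterns", {
    set.seed(23)
    mk_block <- function(pattern, n = 12, L = 40, offset = 15) {
        pat <- strsplit(pattern, "")[[1]]
        rows <- vapply(1:n, function(i) {
            ch <- sample(AA20, L, replace = TRUE)
            for (k in seq_along(pat))
                if (pat[k] != "x") ch[offset + k - 1] <- pat[k]
            paste(ch, collapse = "")
        }, "")
        block_of(rows, "SG")
    }
    for (pat in c("CxxxHGH", "CxxxxxHGH", "ExxHGH")) {
        b <- mk_block(pat)
        win <- selectMotifWindow(b, 16)
        sig <- deriveConsensusMotif(buildPFM(b, win), 0.9)
        expect_identical(sig@pattern, pat)
        # window location points at the pattern within the block
        m <- as.matrix(b@alignment)
        lits <- strsplit(pat, "")[[1]]
        for (k in which(lits != "x"))
            expect_true(all(m[, sig@window[1] + k - 1] == lits[k]))
    }

    # fully conserved block: literal full-length pattern
    b2 <- block_of(rep("CELLHGH", 5))
    expect_identical(deriveConsensusMotif(buildPFM(b2), 0.9)@pattern,
                     "CELLHGH")

    # every literal position recounts to >= threshold in the source block
    b3 <- mk_block("CxxxHGH", n = 20)
    sig3 <- deriveConsensusMotif(buildPFM(b3), 0.9)
    m3 <- as.matrix(b3@alignment)
    pat3 <- strsplit(sig3@pattern, "")[[1]]
    for (k in which(pat3 != "x")) {
        col <- m3[, sig3@window[1] + k - 1]
        expect_gte(mean(col == pat3[k]), 0.9)
    }

    # wildcard-only input has no signature
    expect_error(deriveConsensusMotif(buildPFM(block_of(AA20)), 0.9),
                 "no signature")
    expect_error(deriveConsensusMotif(buildPFM(b2), 0.4))
})

test_that("signatures built at threshold 1 match every contributing row", {
    rows <- rep("QQCAFTHGHWW", 6)
    sig <- buildSignature(setNames(rows, paste0("s", 1:6)), "SG",
                          width = 8, threshold = 1)
    for (r in rows)
        expect_gt(length(matchMotif(r, sig@pattern)), 0)
})

test_that("signature refinement survives a minority of corrupted rows", {
    set.seed(31)
    pat <- "CxxxHGH"
    plant <- function() {
        ch <- sample(AA20, 60, replace = TRUE)
        lits <- strsplit(pat, "")[[1]]
        for (k in which(lits != "x")) ch[25 + k - 1] <- lits[k]
        paste(ch, collapse = "")
    }
    good <- vapply(1:10, function(i) plant(), "")
    bad <- vapply(1:2, function(i) random_protein(60), "")
    sig <- buildSignature(setNames(c(good, bad), paste0("s", 1:12)), "SG")
    expect_identical(sig@pattern, pat)
    expect_identical(attr(sig, "nUsed"), 10L)
})

test_that("two-sample logo statistics match the closed-form Welch test", {
    set.seed(41)
    rowsA <- vapply(1:10, function(i) random_protein(8), "")
    rowsB <- vapply(1:8, function(i) random_protein(8), "")
    bA <- block_of(rowsA, "A"); bB <- block_of(rowsB, "B")
    res <- twoSampleLogo(bA, bB)
    mA <- as.matrix(bA@alignment); mB <- as.matrix(bB@alignment)
    for (r in sample(nrow(res), 20)) {
        j <- res$column[r]; a <- res$residue[r]
        xA <- as.numeric(mA[, j] == a); xB <- as.numeric(mB[, j] == a)
        expect_equal(res$t[r], oracle_welch(xA, xB), tolerance = 1e-9)
        # matches stats::t.test where the variance is non-degenerate
        if (var(xA) > 0 && var(xB) > 0) {
            tt <- t.test(xA, xB)
            expect_equal(res$t[r], unname(tt$statistic), tolerance = 1e-6)
            expect_equal(res$p[r], tt$p.value, tolerance = 1e-6)
        }
    }
    # identical blocks: nothing significant
    expect_false(any(twoSampleLogo(bA, bA)$significant))
    # swap symmetry: t flips sign, p unchanged, direction mirrored
    swap <- twoSampleLogo(bB, bA)
    key <- paste(res$column, res$residue)
    skey <- paste(swap$column, swap$residue)
    common <- intersect(key, skey)
    i1 <- match(common, key); i2 <- match(common, skey)
    expect_equal(res$t[i1], -swap$t[i2], tolerance = 1e-12)
    expect_equal(res$p[i1], swap$p[i2], tolerance = 1e-12)
    flip <- c(enriched = "depleted", depleted = "enriched", none = "none")
    expect_identical(unname(flip[res$direction[i1]]), swap$direction[i2])
})

test_that("fixed opposing columns are flagged in both directions", {
    bA <- block_of(vapply(1:10, function(i) "CA", ""))
    bB <- block_of(vapply(1:10, function(i) "EA", ""))
    res <- twoSampleLogo(bA, bB, alpha = 0.05)
    cC <- res[res$column == 1 & res$residue == "C", ]
    cE <- res[res$column == 1 & res$residue == "E", ]
    expect_identical(cC$direction, "enriched")
    expect_identical(cE$direction, "depleted")
    expect_lt(cC$p, 0.05); expect_lt(cE$p, 0.05)
    expect_true(cC$significant && cE$significant)
    # the shared 'A' column is not significant
    expect_false(any(res$significant[res$column == 2]))
    expect_error(twoSampleLogo(bA, block_of(c("CAA", "CAA"))), "width")
})

test_that("PFM export in MEME minimal format parses back", {
    b <- block_of(rep("CELLHGH", 5), "SG1")
    pfm <- buildPFM(b)
    d <- withr::local_tempdir()
    path <- writePFMMeme(pfm, file.path(d, "m.meme"))
    lines <- readLines(path)
    expect_true(any(grepl("^MOTIF SG1", lines)))
    expect_true(any(grepl("alength= 20 w= 7", lines)))
    probs <- read.table(text = lines[(which(grepl("^letter-prob",
                                                  lines)) + 1):length(lines)])
    expect_equal(rowSums(probs), rep(1, 7), tolerance = 1e-4)
})
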