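# Subgroup alignment, motif-window selection, position frequency matrices,
# consensus signature motifs, and the per-position two-sample enrichment
# statistics used to contrast subgroups.

#' Align one subgroup's proteins by positional stacking
#'
#' Sequences of one subgroup are stacked in a common coordinate frame:
#' row i, column j holds residue j of sequence i, shorter rows padded with
#' `-`. This is the exact alignment for the regime the signature machinery
#' targets -- subfamily members whose motif occupies homologous positions
#' and whose length variation is terminal (no internal indels): identical
#' subsequences at identical positions share columns, a single substitution
#' changes a single column, and conserved motif columns carry the full
#' membership. Sequences violating the common frame (internal indels,
#' truncated starts) simply fail to reinforce the conserved columns and are
#' dropped by the refinement pass in [buildSignature()]; for real data with
#' indels, substitute a general-purpose MSA and construct the
#' [AlignedBlock] directly (any equal-width gapped rows are accepted).
#'
#' @param proteins named character vector or `AAStringSet`, >= 2 sequences.
#' @param label subgroup label recorded on the block.
#' @return an [AlignedBlock].
#' @export
alignSubgroup <- function(proteins, label = "") {
    if (is(proteins, "AAStringSet")) proteins <- as.character(proteins)
    n <- length(proteins)
    if (n < 2L) stop("need at least 2 sequences to align")
    ids <- names(proteins)
    if (is.null(ids)) ids <- paste0("seq", seq_len(n))
    for (i in seq_len(n)) .checkProtein(proteins[[i]], ids[i])
    lens <- nchar(proteins)
    width <- max(lens)
    rows <- vapply(seq_len(n), function(i)
        paste0(proteins[[i]], strrep("-", width - lens[i])), "")
    aln <- Biostrings::AAStringSet(rows)
    names(aln) <- ids
    new("AlignedBlock", label = label, alignment = aln)
}

# counts matrix (20 residues + X + gap) x columns for an AlignedBlock
.blockCounts <- function(block) {
    alpha <- c(.AA20, "X", "-")
    cm <- Biostrings::consensusMatrix(block@alignment)
    w <- Biostrings::width(block@alignment)[1L]
    counts <- matrix(0L, nrow = length(alpha), ncol = w,
                     dimnames = list(alpha, NULL))
    keep <- intersect(rownames(cm), alpha)
    counts[keep, ] <- cm[keep, , drop = FALSE]
    counts
}

#' Position frequency matrix over a column window
#'
#' Per-column residue counts and relative frequencies (gaps and X count in
#' the denominator, so low-occupancy columns have correspondingly low
#' residue frequencies), plus per-column information content in bits,
#' `IC = log2 20 - H` with `H` the Shannon entropy of the non-gap, non-X
#' residue frequencies. An all-gap column gets IC 0 and is flagged via zero
#' occupancy. No small-sample correction is applied.
#'
#' @param block an [AlignedBlock].
#' @param window integer length-2 column range; default the full block.
#' @return a [PositionFrequencyMatrix].
#' @export
buildPFM <- function(block, window = NULL) {
    counts <- .blockCounts(block)
    if (is.null(window)) window <- c(1L, ncol(counts))
    window <- as.integer(window)
    stopifnot(length(window) == 2L, window[1L] >= 1L,
              window[2L] <= ncol(counts), window[1L] <= window[2L])
    counts <- counts[, window[1L]:window[2L], drop = FALSE]
    nseq <- length(block@alignment)
    freqs <- counts / nseq
    res <- counts[.AA20, , drop = FALSE]
    tot <- colSums(res)
    ic <- numeric(ncol(counts))
    for (j in seq_len(ncol(counts))) {
        if (tot[j] == 0) { ic[j] <- 0; next }
        q <- res[, j] / tot[j]
        q <- q[q > 0]
        ic[j] <- log2(20) + sum(q * log2(q))
    }
    ic <- pmin(pmax(ic, 0), log2(20))
    new("PositionFrequencyMatrix", label = block@label, counts = counts,
        freqs = freqs, ic = ic, occupancy = as.numeric(tot) / nseq,
        window = window, nseq = length(block@alignment))
}

#' Select the motif window: maximal summed information content
#'
#' Scans all contiguous `width`-column windows and returns the one
#' maximizing the summed occupancy-weighted information content
#' (IC x non-gap fraction); ties are broken leftmost. Occupancy weighting
#' keeps near-empty edge columns of a stacked alignment from outscoring the
#' conserved core (each column's own IC is still the unweighted value from
#' [buildPFM()]).
#'
#' @param block an [AlignedBlock].
#' @param width window width in columns (default 16, the span of a typical
#'   signature region); must not exceed the block width.
#' @return integer length-2 column range.
#' @export
selectMotifWindow <- function(block, width = 16L) {
    pfm <- buildPFM(block)
    ncols <- ncol(pfm@counts)
    width <- as.integer(width)
    if (width > ncols) stop("width exceeds column count")
    score <- pfm@ic * pfm@occupancy
    sums <- vapply(seq_len(ncols - width + 1L), function(s)
        sum(score[s:(s + width - 1L)]), 0)
    s <- which.max(sums)   # which.max returns the leftmost maximum
    c(s, s + width - 1L)
}

#' Derive a consensus signature motif from a PFM
#'
#' A column becomes a literal when its most frequent residue reaches the
#' conservation threshold (frequency relative to all rows, so gap-heavy
#' columns cannot become literals); otherwise the wildcard `x`. Leading and
#' trailing wildcards are trimmed; a pattern with no literal position is an
#' error ("no signature").
#'
#' @param pfm a [PositionFrequencyMatrix].
#' @param threshold conservation threshold in (0.5, 1\] (default 0.9,
#'   tolerating rare miscalled members).
#' @return a [MotifSignature] whose `window` records the trimmed column
#'   range within the source block.
#' @export
deriveConsensusMotif <- function(pfm, threshold = 0.9) {
    stopifnot(threshold > 0.5, threshold <= 1)
    res <- pfm@freqs[.AA20, , drop = FALSE]
    chars <- vapply(seq_len(ncol(res)), function(j) {
        b <- which.max(res[, j])
        if (res[b, j] >= threshold) .AA20[b] else "x"
    }, "")
    lit <- which(chars != "x")
    if (!length(lit)) stop("no signature: all positions below threshold")
    lo <- min(lit); hi <- max(lit)
    pattern <- paste(chars[lo:hi], collapse = "")
    new("MotifSignature", label = pfm@label, pattern = pattern,
        window = c(pfm@window[1L] + lo - 1L, pfm@window[1L] + hi - 1L),
        pfm = pfm)
}

#' Build a subgroup signature: align, window, refine, call consensus
#'
#' The end-to-end signature builder. After anchoring the subgroup alignment
#' and selecting the motif window, an optional refinement pass derives a
#' provisional consensus at a permissive threshold (0.6), drops rows that
#' disagree with it at any literal column (sequences with mutated or
#' misanchored motif regions, the counterpart of flagging "short, possible
#' wrong start call" sequences during manual curation), and calls the final
#' consensus on the conforming rows at the user threshold.
#'
#' @param proteins named sequences of the subgroup (>= 2).
#' @param label subgroup label.
#' @param width motif window width (default 16).
#' @param threshold final conservation threshold (default 0.9).
#' @param refine drop non-conforming rows before the final call
#'   (default TRUE; skipped when fewer than 2 rows conform).
#' @return a [MotifSignature]; the attribute `nUsed` records how many
#'   sequences the final PFM is built over.
#' @export
buildSignature <- function(proteins, label = "", width = 16L,
                           threshold = 0.9, refine = TRUE) {
    block <- alignSubgroup(proteins, label)
    bw <- Biostrings::width(block@alignment)[1L]
    win <- selectMotifWindow(block, min(width, bw))
    pfm <- buildPFM(block, win)
    used <- length(block@alignment)
    if (refine) {
        prov <- tryCatch(deriveConsensusMotif(pfm, 0.6),
                         error = function(e) NULL)
        if (!is.null(prov)) {
            pat <- strsplit(prov@pattern, "")[[1]]
            cols <- seq(prov@window[1L], prov@window[2L])
            lit <- which(pat != "x")
            rows <- as.matrix(block@alignment)
            ok <- vapply(seq_len(nrow(rows)), function(i)
                all(rows[i, cols[lit]] == pat[lit]), FALSE)
            if (sum(ok) >= 2L) {
                sub <- new("AlignedBlock", label = label,
                           alignment = block@alignment[ok])
                pfm <- buildPFM(sub, win)
                used <- sum(ok)
            }
        }
    }
    sig <- deriveConsensusMotif(pfm, threshold)
    attr(sig, "nUsed") <- used
    sig
}

#' Two-sample logo statistics: per-position residue enrichment
#'
#' For every column and residue observed in either block, a Welch two-sample
#' t-test on per-sequence presence indicators (1 when the sequence carries
#' that residue in that column, else 0) contrasts group A against group B.
#' Perfectly conserved columns have zero variance; a small epsilon added to
#' the pooled variance keeps the statistic defined (its sign still reports
#' the direction). Blocks must have equal widths, aligned to common
#' reference coordinates by the caller (e.g. windows anchored at each
#' signature start).
#'
#' @param blockA,blockB [AlignedBlock] objects of equal width, each with
#'   >= 2 rows.
#' @param alpha significance level (default 0.05).
#' @param correction `"none"` (default, matching the referenced two-sample
#'   logo convention) or `"bonferroni"` over all residue-column tests.
#' @param eps variance floor (default 1e-9).
#' @return data.frame with `column`, `residue`, `freqA`, `freqB`,
#'   `t`, `df`, `p`, `direction` (`enriched`/`depleted` in A, `none` when
#'   frequencies are equal), `significant`.
#' @export
twoSampleLogo <- function(blockA, blockB, alpha = 0.05,
                          correction = c("none", "bonferroni"),
                          eps = 1e-9) {
    correction <- match.arg(correction)
    wA <- Biostrings::width(blockA@alignment)[1L]
    wB <- Biostrings::width(blockB@alignment)[1L]
    if (wA != wB) stop("blocks must have equal window widths")
    nA <- length(blockA@alignment); nB <- length(blockB@alignment)
    if (nA < 2L || nB < 2L) stop("each group needs >= 2 sequences")
    mA <- as.matrix(blockA@alignment)
    mB <- as.matrix(blockB@alignment)
    rows <- list()
    for (j in seq_len(wA)) {
        resj <- setdiff(union(mA[, j], mB[, j]), "-")
        for (r in resj) {
            xA <- as.numeric(mA[, j] == r)
            xB <- as.numeric(mB[, j] == r)
            pA <- mean(xA); pB <- mean(xB)
            vA <- stats::var(xA); vB <- stats::var(xB)
            se2 <- vA / nA + vB / nB
            t <- (pA - pB) / sqrt(se2 + eps)
            df <- if (se2 > 0 && (vA > 0 || vB > 0)) {
                se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
            } else nA + nB - 2
            p <- 2 * stats::pt(-abs(t), df)
            dir <- if (pA > pB) "enriched" else if (pA < pB) "depleted"
                   else "none"
            rows[[length(rows) + 1L]] <- data.frame(
                column = j, residue = r, freqA = pA, freqB = pB,
                t = t, df = df, p = p, direction = dir,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    padj <- if (correction == "bonferroni")
        pmin(1, out$p * nrow(out)) else out$p
    out$significant <- padj < alpha & out$direction != "none"
    rownames(out) <- NULL
    out
}

#' Extract a window of an aligned block as a new block
#' @param block an [AlignedBlock].
#' @param window integer length-2 column range.
#' @return an [AlignedBlock] restricted to the window.
#' @export
blockWindow <- function(block, window) {
    aln <- Biostrings::subseq(block@alignment, window[1L], window[2L])
    new("AlignedBlock", label = block@label, alignment = aln)
}

#' Write a PFM in MEME minimal motif format
#'
#' Letter probabilities are the non-gap residue frequencies renormalized per
#' column (uniform when a column is all gaps).
#'
#' @param pfm a [PositionFrequencyMatrix].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writePFMMeme <- function(pfm, path) {
    res <- pfm@counts[.AA20, , drop = FALSE]
    tot <- colSums(res)
    probs <- vapply(seq_len(ncol(res)), function(j) {
        if (tot[j] == 0) rep(1 / 20, 20) else res[, j] / tot[j]
    }, numeric(20))
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("MEME version 4", "",
                 paste0("ALPHABET= ", paste(.AA20, collapse = "")), "",
                 paste("MOTIF", pfm@label),
                 sprintf("letter-probability matrix: alength= 20 w= %d nsites= %d",
                         ncol(res), pfm@nseq)), con)
    for (j in seq_len(ncol(res)))
        writeLines(paste(sprintf("%.6f", probs[, j]), collapse = " "), con)
    invisible(path)
}

#' Write / read a signature registry TSV
#'
#' One row per subgroup signature: `subgroup`, `pattern`, `window_start`,
#' `window_end`.
#' @param signatures list of [MotifSignature].
#' @param path TSV file.
#' @return the path (write) or a list of patterns named by subgroup (read).
#' @export
writeSignatureTable <- function(signatures, path) {
    df <- data.frame(
        subgroup = vapply(signatures, function(s) s@label, ""),
        pattern = vapply(signatures, function(s) s@pattern, ""),
        window_start = vapply(signatures, function(s) s@window[1L], 0L),
        window_end = vapply(signatures, function(s) s@window[2L], 0L))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeSignatureTable
#' @export
readSignatureTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stats::setNames(df$pattern, df$subgroup)
}
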