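# Sequence similarity networks and the threshold-sweep diagnostic.
#
# All-vs-all Smith-Waterman bit scores (BLOSUM62, affine gaps 11/1) define a
# graph whose edges are pruned at increasing score thresholds. On families
# whose between-subgroup similarity overlaps the within-subgroup range, no
# single threshold both separates the functional groups and keeps each group
# in one cluster -- the failure mode that motivates context-based grouping.

# Karlin-Altschul constants for gapped BLOSUM62 with gap open 11 / extend 1
# (standard ungapped-approximation values; see the methods vignette).
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

#' All-vs-all pairwise alignment bit scores
#'
#' Optimal local (Smith-Waterman) alignment of every sequence pair under
#' BLOSUM62 with affine gap penalties (opening a gap of length L costs
#' `gapOpening + L * gapExtension`). Raw scores S are converted to bit
#' scores `(lambda * S - ln K) / ln 2` with the standard gapped BLOSUM62
#' 11/1 constants (lambda = 0.267, K = 0.041) and clamped at 0.
#'
#' @param proteins named character vector or `AAStringSet` (>= 2 sequences,
#'   standard residues plus X; empty or invalid sequences are an error
#'   naming the offender).
#' @param gapOpening,gapExtension affine gap penalties (defaults 11 / 1).
#' @param substitutionMatrix substitution matrix name (default BLOSUM62).
#' @return symmetric numeric matrix of bit scores with a positive diagonal
#'   of self-scores.
#' @export
pairwiseScores <- function(proteins, gapOpening = 11, gapExtension = 1,
                           substitutionMatrix = "BLOSUM62") {
    if (is(proteins, "AAStringSet")) proteins <- as.character(proteins)
    n <- length(proteins)
    if (n < 2L) stop("need at least 2 sequences")
    ids <- names(proteins)
    if (is.null(ids) || anyDuplicated(ids))
        stop("sequences must carry unique names")
    for (i in seq_len(n)) .checkProtein(proteins[[i]], ids[i])
    raw <- matrix(0, n, n, dimnames = list(ids, ids))
    seqs <- Biostrings::AAStringSet(proteins)
    for (i in seq_len(n)) {
        for (j in i:n) {
            s <- Biostrings::pairwiseAlignment(
                seqs[[i]], seqs[[j]], type = "local",
                substitutionMatrix = substitutionMatrix,
                gapOpening = gapOpening, gapExtension = gapExtension,
                scoreOnly = TRUE)
            raw[i, j] <- raw[j, i] <- s
        }
    }
    bits <- (.KA_LAMBDA * raw - log(.KA_K)) / log(2)
    pmax(bits, 0)
}

#' Build a sequence similarity network at one threshold
#'
#' Edges connect pairs whose bit score is at least `threshold`; connected
#' components are computed eagerly. The edge set at a higher threshold is
#' always a subset of the edge set at a lower one.
#'
#' @param scores symmetric score matrix from [pairwiseScores()].
#' @param threshold alignment bit-score threshold; the named presets
#'   [ssnThresholdPresets] mirror commonly used values 15/25/30 (EFI-style
#'   alignment scores are approximately bit scores; the unit caveat is
#'   documented in the vignette).
#' @return an [SSNGraph].
#' @export
buildSSN <- function(scores, threshold) {
    ids <- rownames(scores)
    stopifnot(!is.null(ids), nrow(scores) == ncol(scores))
    from <- character(); to <- character(); sc <- numeric()
    n <- length(ids)
    for (i in seq_len(max(0L, n - 1L))) {
        for (j in seq(i + 1L, n)) {
            if (scores[i, j] >= threshold) {
                from <- c(from, ids[i]); to <- c(to, ids[j])
                sc <- c(sc, scores[i, j])
            }
        }
    }
    edges <- data.frame(from = from, to = to, score = sc,
                        stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = data.frame(name = ids))
    memb <- igraph::components(g)$membership[ids]
    new("SSNGraph", threshold = threshold, nodes = ids, edges = edges,
        membership = stats::setNames(as.integer(memb), ids))
}

#' Named SSN threshold presets
#'
#' Alignment-score thresholds 15 / 25 / 30 commonly used to build, regroup
#' and fully separate subfamily clusters.
#' @export
ssnThresholdPresets <- c(initial = 15, regroup = 25, separate = 30)

#' Sweep all observed score thresholds against known subgroup labels
#'
#' For every distinct off-diagonal score value (an exact, exhaustive sweep),
#' clusters the SSN and reports: number of clusters; purity (fraction of
#' nodes whose cluster's majority label is their own; majority ties broken
#' by the alphabetically first label); the number of subgroups split across
#' two or more clusters; and `fully_separated` -- whether every cluster is
#' label-pure and every label occupies exactly one cluster.
#'
#' @param scores symmetric score matrix.
#' @param labels named character gene_id -> subgroup covering all nodes.
#' @return data.frame `threshold`, `n_clusters`, `purity`,
#'   `n_split_subgroups`, `fully_separated`.
#' @export
thresholdSweep <- function(scores, labels) {
    ids <- rownames(scores)
    if (!all(ids %in% names(labels)))
        stop("labels must cover all sequences")
    lab <- labels[ids]
    off <- scores[upper.tri(scores)]
    cands <- sort(unique(off))
    rows <- lapply(cands, function(t) {
        ssn <- buildSSN(scores, t)
        cl <- ssn@membership
        clusters <- split(ids, cl[ids])
        maj_ok <- logical(0)
        pure <- TRUE
        for (members in clusters) {
            tl <- table(lab[members])
            maj <- sort(names(tl)[tl == max(tl)])[1L]
            maj_ok <- c(maj_ok, lab[members] == maj)
            if (length(tl) > 1L) pure <- FALSE
        }
        nsplit <- sum(vapply(split(cl[ids], lab), function(x)
            length(unique(x)) > 1L, FALSE))
        data.frame(threshold = t, n_clusters = length(clusters),
                   purity = mean(maj_ok), n_split_subgroups = nsplit,
                   fully_separated = pure && nsplit == 0L)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Write a score matrix as TSV
#' @param scores score matrix.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeScoreMatrix <- function(scores, path) {
    df <- data.frame(gene_id = rownames(scores), scores,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
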