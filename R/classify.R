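# Annotation propagation: signature-motif matching with explicit hybrid and
# ambiguity handling. Context evidence always takes precedence over motif
# evidence; motif matching extends subgroup annotations to members without
# conserved gene-neighborhood support.

#' Match a signature pattern against a protein
#'
#' The wildcard `x` matches any residue (including the unknown-residue code
#' X); literal positions match exactly. All start offsets are reported,
#' including overlapping matches.
#'
#' @param protein amino-acid string.
#' @param pattern signature pattern over the 20 residues plus `x`, or a
#'   [MotifSignature].
#' @return integer vector of 1-based match start positions (possibly empty).
#' @examples
#' matchMotif("AACELLHGHAA", "CxxxHGH")  # 3
#' matchMotif("AACELLHGHAA", "ExxHGH")   # 4
#' @export
matchMotif <- function(protein, pattern) {
    if (is(pattern, "MotifSignature")) pattern <- pattern@pattern
    ch <- strsplit(pattern, "")[[1]]
    if (!all(ch %in% c(.AA20, "x")))
        stop("invalid pattern character in '", pattern, "'")
    .checkProtein(protein, "query")
    rx <- paste0("(?=", gsub("x", ".", pattern, fixed = TRUE), ")")
    m <- gregexpr(rx, protein, perl = TRUE)[[1]]
    if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Best-window PSSM log-odds score of a protein
#'
#' Quantitative backstop for pattern matching: slides the PFM window along
#' the protein and returns the maximal summed log-odds
#' `sum(log2((freq + pseudocount) / background))` with a per-cell
#' pseudocount of 0.5/20 and a uniform background by default.
#'
#' @param protein amino-acid string at least as long as the PFM window.
#' @param pfm a [PositionFrequencyMatrix] (e.g. `signature@pfm`).
#' @param background named numeric of background residue frequencies
#'   (default uniform 1/20; the unknown residue X scores against 1/20).
#' @param pseudocount per-cell pseudocount (default 0.025).
#' @return list with `score` (bits) and `position` (first maximal window).
#' @export
scorePssm <- function(protein, pfm,
                      background = stats::setNames(rep(1 / 20, 20), .AA20),
                      pseudocount = 0.5 / 20) {
    .checkProtein(protein, "query")
    W <- ncol(pfm@freqs)
    L <- nchar(protein)
    if (L < W) stop("protein shorter than the PFM window")
    chars <- strsplit(protein, "")[[1]]
    bg <- c(background, X = 1 / 20)
    lo <- log2((pfm@freqs[c(.AA20, "X"), , drop = FALSE] + pseudocount))
    best <- -Inf; bestPos <- NA_integer_
    for (s in seq_len(L - W + 1L)) {
        win <- chars[s:(s + W - 1L)]
        ri <- match(win, rownames(lo))
        sc <- sum(lo[cbind(ri, seq_len(W))] - log2(bg[win]))
        if (sc > best + 1e-12) { best <- sc; bestPos <- s }
    }
    list(score = best, position = bestPos)
}

#' Classify one gene against subgroup signatures and the context partition
#'
#' Decision rule, in order of precedence:
#' 1. a member of a context subgroup keeps that subgroup (evidence
#'    `context`; `context+motif` with high confidence when its own
#'    signature also matches);
#' 2. exactly one signature matches: that subgroup, evidence `motif`,
#'    medium confidence;
#' 3. two or more signatures match: evidence `hybrid`, all patterns listed,
#'    the subgroup label joins the matched labels (bifunctional hybrids are
#'    calls, not errors);
#' 4. no match: `unresolved`, evidence `none`, low confidence. A protein too
#'    short to contain any signature window is unresolved with the note
#'    "short, possible wrong start call".
#'
#' @param geneId gene identifier.
#' @param protein amino-acid string, or `NA` when unavailable.
#' @param signatures list of [MotifSignature] (non-empty), or a named
#'   character vector of patterns.
#' @param partition a [SubgroupPartition] (or `NULL` for motif-only calls).
#' @return one-row data.frame: `gene_id`, `subgroup`, `evidence`,
#'   `confidence`, `motif_matched` (patterns joined by `;`), `note`.
#' @export
classifyGene <- function(geneId, protein, signatures, partition = NULL) {
    pats <- if (is.character(signatures)) signatures
            else stats::setNames(vapply(signatures, function(s) s@pattern, ""),
                                 vapply(signatures, function(s) s@label, ""))
    if (!length(pats)) stop("signatures must be non-empty")
    call <- function(subgroup, evidence, confidence, matched = character(),
                     note = "")
        data.frame(gene_id = geneId, subgroup = subgroup,
                   evidence = evidence, confidence = confidence,
                   motif_matched = paste(matched, collapse = ";"),
                   note = note, stringsAsFactors = FALSE)

    ctx <- if (!is.null(partition))
        unname(subgroupOf(partition, geneId)) else NA_character_

    hasProt <- !is.na(protein) && nzchar(protein)
    matched <- character()
    if (hasProt) {
        long_enough <- nchar(protein) >= nchar(pats)
        hit <- vapply(seq_along(pats), function(i)
            long_enough[i] && length(matchMotif(protein, pats[[i]])) > 0L,
            FALSE)
        matched <- pats[hit]
        if (!any(long_enough) && is.na(ctx))
            return(call("unresolved", "none", "low",
                        note = "short, possible wrong start call"))
    }

    if (!is.na(ctx)) {
        own <- pats[names(pats) == ctx]
        own_hit <- length(own) == 1L && own %in% matched
        if (own_hit)
            return(call(ctx, "context+motif", "high", matched = own))
        return(call(ctx, "context", "medium"))
    }
    if (length(matched) == 1L)
        return(call(names(matched), "motif", "medium", matched = matched))
    if (length(matched) >= 2L)
        return(call(paste(sort(names(matched)), collapse = "+"), "hybrid",
                    "medium", matched = matched[order(names(matched))]))
    call("unresolved", "none", "low")
}

#' Annotate every member of a family
#'
#' One [classifyGene()] call per member, in deterministic
#' (genome_id, gene_id) order, with genome and family columns attached,
#' ready for [writeAnnotationTable()]. With an empty signature set, members
#' outside context subgroups are unresolved.
#'
#' @param pg a [PanGenome].
#' @param familyId the family to annotate.
#' @param partition a [SubgroupPartition] of that family.
#' @param signatures list of [MotifSignature] or named pattern vector; may
#'   be empty (`character()`).
#' @return data.frame of annotation calls, one row per member.
#' @export
annotateFamily <- function(pg, familyId, partition, signatures) {
    gt <- geneTable(pg)
    mem <- gt[!is.na(gt$family_id) & gt$family_id == familyId, , drop = FALSE]
    if (!nrow(mem)) stop("no members of family ", familyId)
    mem <- mem[order(mem$genome_id, mem$gene_id), , drop = FALSE]
    empty_sig <- length(signatures) == 0L
    rows <- lapply(seq_len(nrow(mem)), function(i) {
        gid <- mem$gene_id[i]
        prot <- .proteinOf(pg, gid)
        if (empty_sig) {
            ctx <- unname(subgroupOf(partition, gid))
            df <- data.frame(gene_id = gid,
                             subgroup = if (is.na(ctx)) "unresolved" else ctx,
                             evidence = if (is.na(ctx)) "none" else "context",
                             confidence = if (is.na(ctx)) "low" else "medium",
                             motif_matched = "", note = "",
                             stringsAsFactors = FALSE)
        } else {
            df <- classifyGene(gid, prot, signatures, partition)
        }
        df$genome_id <- mem$genome_id[i]
        df$family_id <- familyId
        df
    })
    out <- do.call(rbind, rows)
    out[, c("gene_id", "genome_id", "family_id", "subgroup", "evidence",
            "confidence", "motif_matched", "note")]
}
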