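# Paralog flagging and family copy-number statistics.
#
# Any single genome containing two or more members of a protein family must
# encode paralogs; that observation is the workflow's entry point, and the
# copy-number census over an ortholog-group membership matrix quantifies how
# often sequence-similarity families mix paralogs.

#' Find paralogs: multi-member (family, genome) pairs
#'
#' Emits one flag per family/genome combination with at least two members.
#' Genes without a family label are ignored. Multiple contigs (chromosome,
#' plasmids) count within the same genome.
#'
#' @param pg a [PanGenome].
#' @return data.frame with columns `family_id`, `genome_id`, `copy_number`
#'   and a list-column `members` (gene_ids, sorted), ordered by
#'   (family_id, genome_id).
#' @examples
#' gt <- data.frame(gene_id = c("g1", "g2", "g3"), genome_id = "G1",
#'                  contig_id = "c1", start = c(1, 100, 200),
#'                  end = c(90, 190, 290), strand = "+",
#'                  family_id = c("F", "F", "H"))
#' findParalogs(PanGenome(gt))
#' @export
findParalogs <- function(pg) {
    gt <- geneTable(pg)
    gt <- gt[!is.na(gt$family_id), , drop = FALSE]
    if (!nrow(gt))
        return(data.frame(family_id = character(), genome_id = character(),
                          copy_number = integer(),
                          members = I(list())))
    key <- paste(gt$family_id, gt$genome_id, sep = "\r")
    sp <- split(gt$gene_id, key)
    sp <- sp[lengths(sp) >= 2L]
    if (!length(sp))
        return(data.frame(family_id = character(), genome_id = character(),
                          copy_number = integer(), members = I(list())))
    parts <- strsplit(names(sp), "\r", fixed = TRUE)
    out <- data.frame(
        family_id = vapply(parts, `[`, "", 1L),
        genome_id = vapply(parts, `[`, "", 2L),
        copy_number = lengths(sp),
        stringsAsFactors = FALSE)
    out$members <- I(lapply(sp, sort))
    o <- order(out$family_id, out$genome_id)
    out <- out[o, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Family copy-number statistics over a membership matrix
#'
#' Given per-family, per-genome member counts, computes the fraction of
#' families that are single-copy in every genome and its complement, the
#' fraction for which at least one genome encodes paralogs. Families with
#' zero members everywhere are excluded from the denominator.
#'
#' @param membership numeric matrix, families x genomes, entries are member
#'   counts (>= 0).
#' @return list with `n_families`, `n_genomes`, `max_copy` (named per-family
#'   maxima), `fraction_single_copy_everywhere`, `fraction_with_paralogs`.
#' @examples
#' m <- matrix(1, 3, 5, dimnames = list(paste0("F", 1:3), paste0("G", 1:5)))
#' familyCopyStats(m)$fraction_single_copy_everywhere  # 1
#' @export
familyCopyStats <- function(membership) {
    if (!is.matrix(membership) || length(membership) == 0L)
        stop("empty membership matrix")
    if (any(membership < 0)) stop("negative member counts")
    keep <- rowSums(membership) > 0
    if (!any(keep)) stop("no family has any member")
    m <- membership[keep, , drop = FALSE]
    maxc <- apply(m, 1L, max)
    fs <- mean(maxc <= 1)
    list(n_families = nrow(m),
         n_genomes = ncol(m),
         max_copy = maxc,
         fraction_single_copy_everywhere = fs,
         fraction_with_paralogs = 1 - fs)
}

#' Membership count matrix of a PanGenome
#'
#' @param pg a [PanGenome].
#' @return integer matrix families x genomes of member counts.
#' @export
membershipMatrix <- function(pg) {
    gt <- geneTable(pg)
    gt <- gt[!is.na(gt$family_id), , drop = FALSE]
    tab <- table(factor(gt$family_id), factor(gt$genome_id))
    m <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
    m[order(rownames(m)), order(colnames(m)), drop = FALSE]
}

#' Read an external membership table into a count matrix
#'
#' Accepts either a long TSV with columns `family_id`, `genome_id` (and
#' optionally `gene_id`; rows are counted) or a wide CSV/TSV whose first
#' column holds family ids and remaining columns per-genome counts.
#'
#' @param path input file.
#' @param sep field separator; default tab.
#' @return integer matrix families x genomes.
#' @export
readMembershipTable <- function(path, sep = "\t") {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
    if (all(c("family_id", "genome_id") %in% names(df))) {
        tab <- table(factor(df$family_id), factor(df$genome_id))
        return(matrix(as.integer(tab), nrow = nrow(tab),
                      dimnames = dimnames(tab)))
    }
    fam <- df[[1L]]
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- fam
    m
}

#' Annotation-confidence downgrades for members of paralogous families
#'
#' Every member of a family flagged by [findParalogs()] receives exactly one
#' downgrade reason: `paralog_in_same_genome` when its own genome holds >= 2
#' members, else `family_has_paralogs_elsewhere` (same-genome evidence takes
#' precedence). Families that are single-copy everywhere yield no rows.
#'
#' @param pg a [PanGenome].
#' @param flags output of [findParalogs()]; recomputed when omitted.
#' @return data.frame `gene_id`, `genome_id`, `family_id`, `reason`,
#'   ordered by (family_id, genome_id, gene_id).
#' @export
flagAnnotations <- function(pg, flags = findParalogs(pg)) {
    gt <- geneTable(pg)
    gt <- gt[!is.na(gt$family_id), , drop = FALSE]
    fams <- unique(flags$family_id)
    gt <- gt[gt$family_id %in% fams, , drop = FALSE]
    if (!nrow(gt))
        return(data.frame(gene_id = character(), genome_id = character(),
                          family_id = character(), reason = character()))
    flagged_pair <- paste(flags$family_id, flags$genome_id, sep = "\r")
    own_pair <- paste(gt$family_id, gt$genome_id, sep = "\r")
    gt$reason <- ifelse(own_pair %in% flagged_pair,
                        "paralog_in_same_genome",
                        "family_has_paralogs_elsewhere")
    gt <- gt[order(gt$family_id, gt$genome_id, gt$gene_id),
             c("gene_id", "genome_id", "family_id", "reason"), drop = FALSE]
    rownames(gt) <- NULL
    gt
}
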