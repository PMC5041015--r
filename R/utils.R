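# Internal helpers shared across modules.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.checkProtein <- function(x, id = "sequence") {
    if (is.na(x) || !nzchar(x))
        stop("empty protein sequence for ", id, call. = FALSE)
    if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", x))
        stop("invalid residues in protein for ", id, call. = FALSE)
    invisible(TRUE)
}

# Jaccard index on label sets; both-empty convention: 0.
.jaccard <- function(a, b) {
    a <- unique(a); b <- unique(b)
    u <- length(union(a, b))
    if (u == 0L) return(0)
    length(intersect(a, b)) / u
}

#' Flat gene table of a PanGenome
#'
#' One row per gene, ordered by (genome_id, contig_id, start); the
#' positional substrate for neighborhood extraction.
#'
#' @param pg a [PanGenome].
#' @return data.frame with columns `gene_id`, `genome_id`, `contig_id`,
#'   `start`, `end`, `strand`, `family_id`.
#' @export
geneTable <- function(pg) {
    stopifnot(is(pg, "PanGenome"))
    g <- pg@genes
    mc <- S4Vectors::mcols(g)
    df <- data.frame(gene_id = mc$gene_id,
                     genome_id = mc$genome_id,
                     contig_id = as.character(GenomicRanges::seqnames(g)),
                     start = GenomicRanges::start(g),
                     end = GenomicRanges::end(g),
                     strand = as.character(GenomicRanges::strand(g)),
                     family_id = mc$family_id,
                     stringsAsFactors = FALSE)
    df[order(df$genome_id, df$contig_id, df$start, df$gene_id), , drop = FALSE]
}

#' Construct a PanGenome from a gene table and proteins
#'
#' @param geneDf data.frame with columns `gene_id`, `genome_id`,
#'   `contig_id`, `start`, `end`, `strand`, `family_id`.
#' @param proteins `AAStringSet` or named character vector keyed by gene_id
#'   (may cover only a subset of genes).
#' @return a [PanGenome].
#' @export
PanGenome <- function(geneDf, proteins = Biostrings::AAStringSet()) {
    stopifnot(all(c("gene_id", "genome_id", "contig_id", "start", "end",
                    "strand", "family_id") %in% names(geneDf)))
    if (any(geneDf$start > geneDf$end))
        stop("start must be <= end for all genes")
    dup <- geneDf$gene_id[duplicated(geneDf$gene_id)]
    if (length(dup))
        stop("duplicate gene_id: ", dup[1L])
    o <- order(geneDf$genome_id, geneDf$contig_id, geneDf$start, geneDf$gene_id)
    geneDf <- geneDf[o, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
        seqnames = geneDf$contig_id,
        ranges = IRanges::IRanges(start = geneDf$start, end = geneDf$end),
        strand = geneDf$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        gene_id = geneDf$gene_id,
        genome_id = geneDf$genome_id,
        family_id = geneDf$family_id)
    if (!is(proteins, "AAStringSet"))
        proteins <- Biostrings::AAStringSet(proteins)
    new("PanGenome", genes = gr, proteins = proteins)
}

# genome lookup: named character gene_id -> genome_id
.genomeMap <- function(pg) {
    mc <- S4Vectors::mcols(pg@genes)
    stats::setNames(mc$genome_id, mc$gene_id)
}

# protein lookup for one gene; NA when absent
.proteinOf <- function(pg, geneId) {
    p <- pg@proteins
    if (geneId %in% names(p)) as.character(p[[geneId]]) else NA_character_
}
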