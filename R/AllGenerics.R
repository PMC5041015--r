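# Generics, accessors and show methods.

#' @rdname PanGenome-class
#' @param x,object a `PanGenome` (or other paraSign object as documented).
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname PanGenome-class
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @rdname PanGenome-class
#' @export
setGeneric("familyTable", function(x) standardGeneric("familyTable"))

#' @rdname PanGenome-class
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))

#' @rdname SubgroupPartition-class
#' @export
setGeneric("subgroups", function(x) standardGeneric("subgroups"))

#' @rdname SubgroupPartition-class
#' @export
setGeneric("unplacedGenes", function(x) standardGeneric("unplacedGenes"))

#' @rdname SubgroupPartition-class
#' @export
setGeneric("subgroupOf", function(x, geneIds) standardGeneric("subgroupOf"))

#' @rdname MotifSignature-class
#' @export
setGeneric("motifPattern", function(x) standardGeneric("motifPattern"))

#' @describeIn PanGenome-class the gene `GRanges`.
#' @export
setMethod("genes", "PanGenome", function(x) x@genes)

#' @describeIn PanGenome-class the protein `AAStringSet`.
#' @export
setMethod("proteins", "PanGenome", function(x) x@proteins)

#' @describeIn PanGenome-class data.frame of (gene_id, family_id) for
#'   genes carrying a family label.
#' @export
setMethod("familyTable", "PanGenome", function(x) {
    mc <- S4Vectors::mcols(x@genes)
    keep <- !is.na(mc$family_id)
    data.frame(gene_id = mc$gene_id[keep], family_id = mc$family_id[keep],
               stringsAsFactors = FALSE)
})

#' @describeIn PanGenome-class sorted unique genome identifiers.
#' @export
setMethod("genomeIds", "PanGenome", function(x)
    sort(unique(S4Vectors::mcols(x@genes)$genome_id)))

#' @describeIn SubgroupPartition-class named list of subgroups, each
#'   `list(members=, support=)`.
#' @export
setMethod("subgroups", "SubgroupPartition", function(x) x@subgroups)

#' @describeIn SubgroupPartition-class gene_ids without context placement.
#' @export
setMethod("unplacedGenes", "SubgroupPartition", function(x) x@unplaced)

#' @describeIn SubgroupPartition-class subgroup label for each requested
#'   gene_id (`NA` for unplaced or unknown genes).
#' @param geneIds character vector of gene identifiers.
#' @export
setMethod("subgroupOf", "SubgroupPartition", function(x, geneIds) {
    lab <- rep(NA_character_, length(geneIds))
    for (sg in names(x@subgroups))
        lab[geneIds %in% x@subgroups[[sg]]$members] <- sg
    names(lab) <- geneIds
    lab
})

#' @describeIn MotifSignature-class the signature pattern string.
#' @export
setMethod("motifPattern", "MotifSignature", function(x) x@pattern)

setMethod("show", "PanGenome", function(object) {
    mc <- S4Vectors::mcols(object@genes)
    cat("PanGenome with", length(object@genes), "genes in",
        length(unique(mc$genome_id)), "genomes\n")
    cat("  families:", length(unique(stats::na.omit(mc$family_id))),
        "| proteins:", length(object@proteins), "\n")
})

setMethod("show", "NeighborhoodProfile", function(object) {
    cat("NeighborhoodProfile for", object@focalGene,
        "(k =", paste0(object@windowK, ")"), "\n")
    cat("  neighbor families:",
        paste(object@neighborFamilies, collapse = ", "), "\n")
})

setMethod("show", "ContextGraph", function(object) {
    cat("ContextGraph:", length(object@nodes), "members,",
        nrow(object@edges), "edges at tau =", object@tau, "\n")
})

setMethod("show", "SubgroupPartition", function(object) {
    cat("SubgroupPartition of", object@familyId, "-",
        length(object@subgroups), "subgroups,",
        length(object@unplaced), "unplaced\n")
    for (sg in names(object@subgroups)) {
        s <- object@subgroups[[sg]]
        cat(" ", sg, ":", length(s$members), "members; support {",
            paste(s$support, collapse = ", "), "}\n")
    }
})

setMethod("show", "AlignedBlock", function(object) {
    cat("AlignedBlock", object@label, ":", length(object@alignment),
        "rows x", Biostrings::width(object@alignment)[1L], "columns\n")
})

setMethod("show", "PositionFrequencyMatrix", function(object) {
    cat("PositionFrequencyMatrix", object@label, ":", ncol(object@counts),
        "columns over", object@nseq, "sequences\n")
    cat("  IC (bits):", paste(sprintf("%.2f", object@ic), collapse = " "), "\n")
})

setMethod("show", "MotifSignature", function(object) {
    cat("MotifSignature", object@label, ":", object@pattern,
        sprintf("(columns %d-%d)\n", object@window[1L], object@window[2L]))
})

setMethod("show", "SSNGraph", function(object) {
    cat("SSNGraph at threshold", object@threshold, ":",
        length(object@nodes), "nodes,", nrow(object@edges), "edges,",
        length(unique(object@membership)), "components\n")
})
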