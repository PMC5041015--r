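#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges start end strand seqnames
#' @importFrom Biostrings AAStringSet
NULL

#' PanGenome: joined gene models, proteins and family labels
#'
#' Container for a multi-genome gene model. Genes live in a
#' [GenomicRanges::GRanges] whose `seqnames` are contig identifiers and whose
#' metadata columns carry `gene_id`, `genome_id` and `family_id`
#' (`NA` for genes without a family assignment). Protein sequences, where
#' available, are held in an [Biostrings::AAStringSet] named by `gene_id`;
#' neighbor genes need only a family label, so most genes may lack a protein.
#'
#' Within each (genome, contig) the genes are stored in increasing order of
#' start coordinate (GFF3 convention, 1-based inclusive); the constructor
#' sorts and the validity method enforces this, so downstream neighborhood
#' extraction can index genes positionally.
#'
#' @slot genes `GRanges` of gene models with mcols `gene_id`, `genome_id`,
#'   `family_id`.
#' @slot proteins `AAStringSet` named by `gene_id` (possibly empty).
#' @seealso [readPanGenome()], [geneTable()], [extractNeighborhood()]
#' @exportClass PanGenome
setClass("PanGenome", slots = c(genes = "GRanges", proteins = "AAStringSet"))

setValidity("PanGenome", function(object) {
    mc <- S4Vectors::mcols(object@genes)
    need <- c("gene_id", "genome_id", "family_id")
    if (!all(need %in% colnames(mc)))
        return(paste("genes mcols must contain", paste(need, collapse = ", ")))
    ids <- mc$gene_id
    if (anyDuplicated(ids))
        return(paste0("duplicate gene_id: ", ids[duplicated(ids)][1L]))
    prot <- object@proteins
    if (length(prot)) {
        if (is.null(names(prot)) || !all(names(prot) %in% ids))
            return("protein names must be gene_ids present in the gene model")
        bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", as.character(prot))
        if (any(bad))
            return(paste0("protein for gene ", names(prot)[bad][1L],
                          " contains non-standard residues"))
    }
    # gene order within (genome, contig) strictly increasing by start
    key <- paste(mc$genome_id, as.character(GenomicRanges::seqnames(object@genes)))
    st <- GenomicRanges::start(object@genes)
    for (k in unique(key)) {
        s <- st[key == k]
        if (is.unsorted(s, strictly = FALSE))
            return(paste("genes not ordered by start within contig", k))
    }
    TRUE
})

#' NeighborhoodProfile: gene-neighborhood context of one family member
#'
#' The set (and ordered list) of neighbor family labels within a window of
#' `windowK` genes on each side of a focal gene, truncated at contig ends.
#' The focal gene's own family never appears in `neighborFamilies`; genes
#' without a family label are excluded from the set by default (see
#' [extractNeighborhood()]).
#'
#' @slot focalGene focal `gene_id`.
#' @slot focalFamily family of the focal gene.
#' @slot windowK genes per side.
#' @slot neighborFamilies character set of neighbor family labels.
#' @slot orderedNeighbors data.frame with columns `offset` (in
#'   \[-k, k\] \\ \{0\}), `family` (may be `NA`) and `strand`.
#' @exportClass NeighborhoodProfile
setClass("NeighborhoodProfile",
         slots = c(focalGene = "character", focalFamily = "character",
                   windowK = "integer", neighborFamilies = "character",
                   orderedNeighbors = "data.frame"))

setValidity("NeighborhoodProfile", function(object) {
    if (nrow(object@orderedNeighbors) > 2L * object@windowK)
        return("more neighbors than 2k")
    off <- object@orderedNeighbors$offset
    if (length(off) && (any(off == 0L) || any(abs(off) > object@windowK)))
        return("neighbor offsets must lie in [-k, k] \\ {0}")
    if (!is.na(object@focalFamily) &&
        object@focalFamily %in% object@neighborFamilies)
        return("focal family must not appear among neighbor families")
    TRUE
})

#' ContextGraph: neighborhood-similarity graph over family members
#'
#' Nodes are the focal-family gene_ids; undirected weighted edges connect
#' members whose neighborhood Jaccard similarity reaches `tau`.
#'
#' @slot nodes gene_ids.
#' @slot genomes named character, genome of each node.
#' @slot edges data.frame `from`, `to`, `weight` with `from < to`.
#' @slot tau similarity threshold used to admit edges.
#' @slot profiles the `NeighborhoodProfile` list the graph was built from.
#' @exportClass ContextGraph
setClass("ContextGraph",
         slots = c(nodes = "character", genomes = "character",
                   edges = "data.frame", tau = "numeric", profiles = "list"))

setValidity("ContextGraph", function(object) {
    e <- object@edges
    if (nrow(e)) {
        if (!all(c(e$from, e$to) %in% object@nodes))
            return("edge endpoints must be nodes")
        if (any(e$from == e$to)) return("self-edges are not allowed")
    }
    if (!all(object@nodes %in% names(object@genomes)))
        return("every node needs a genome assignment")
    TRUE
})

#' SubgroupPartition: provisional isofunctional subgroups of one family
#'
#' A partition of a family's members into context-supported subgroups plus
#' an `unplaced` remainder (members with no usable context evidence).
#' Subgroups are labelled `SG1`, `SG2`, ... deterministically, ordered by the
#' lexicographically smallest member gene_id, and each carries the set of
#' neighbor families supporting it.
#'
#' @slot familyId the family being partitioned.
#' @slot subgroups named list; each element is `list(members=, support=)`.
#' @slot unplaced gene_ids not placed in any subgroup.
#' @slot genomes named character, genome of each member.
#' @exportClass SubgroupPartition
setClass("SubgroupPartition",
         slots = c(familyId = "character", subgroups = "list",
                   unplaced = "character", genomes = "character"))

setValidity("SubgroupPartition", function(object) {
    mem <- unlist(lapply(object@subgroups, `[[`, "members"), use.names = FALSE)
    all_ids <- c(mem, object@unplaced)
    if (anyDuplicated(all_ids))
        return("subgroups and unplaced must form a partition (no overlaps)")
    TRUE
})

#' AlignedBlock: gapped alignment of one subgroup's proteins
#'
#' Equal-width rows over the amino-acid alphabet plus the gap character `-`.
#'
#' @slot label subgroup label.
#' @slot alignment `AAStringSet`, all rows the same width, named by gene_id.
#' @exportClass AlignedBlock
setClass("AlignedBlock",
         slots = c(label = "character", alignment = "AAStringSet"))

setValidity("AlignedBlock", function(object) {
    w <- Biostrings::width(object@alignment)
    if (length(w) < 2L) return("an aligned block needs at least 2 rows")
    if (length(unique(w)) != 1L) return("all rows must have equal width")
    TRUE
})

#' PositionFrequencyMatrix: per-column residue statistics of a motif window
#'
#' Counts and relative frequencies over the 20 standard residues, the
#' unknown-residue code `X` and the gap `-`, plus per-column information
#' content in bits (`log2 20` minus the Shannon entropy of the non-gap,
#' non-X residue frequencies) and per-column occupancy (non-gap fraction).
#'
#' @slot label subgroup label.
#' @slot counts matrix (residues + X + gap) x columns.
#' @slot freqs relative frequencies, columns sum to 1.
#' @slot ic numeric, information content per column in \[0, log2 20\].
#' @slot occupancy numeric, non-gap fraction per column.
#' @slot window integer length-2, column range in the source block.
#' @slot nseq number of sequences the counts are over.
#' @exportClass PositionFrequencyMatrix
setClass("PositionFrequencyMatrix",
         slots = c(label = "character", counts = "matrix", freqs = "matrix",
                   ic = "numeric", occupancy = "numeric", window = "integer",
                   nseq = "integer"))

setValidity("PositionFrequencyMatrix", function(object) {
    if (ncol(object@counts) != length(object@ic))
        return("ic must have one entry per column")
    cs <- colSums(object@freqs)
    if (any(abs(cs - 1) > 1e-8 & cs != 0))
        return("column frequencies must sum to 1")
    if (any(object@ic < -1e-9 | object@ic > log2(20) + 1e-9))
        return("information content out of [0, log2 20]")
    TRUE
})

#' MotifSignature: consensus signature pattern for one subgroup
#'
#' A pattern over the 20 residues plus the any-residue wildcard `x`
#' (e.g. `CxxxHGH`), derived from a [PositionFrequencyMatrix] by calling a
#' literal wherever one residue reaches the conservation threshold.
#'
#' @slot label subgroup label.
#' @slot pattern signature string; at least one literal position.
#' @slot window integer length-2, alignment columns spanned after trimming.
#' @slot pfm the source `PositionFrequencyMatrix`.
#' @exportClass MotifSignature
setClass("MotifSignature",
         slots = c(label = "character", pattern = "character",
                   window = "integer", pfm = "PositionFrequencyMatrix"))

setValidity("MotifSignature", function(object) {
    p <- object@pattern
    if (length(p) != 1L || !nzchar(p)) return("empty pattern")
    ch <- strsplit(p, "")[[1]]
    if (!all(ch %in% c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "x")))
        return("pattern may contain only the 20 residues and wildcard 'x'")
    if (all(ch == "x")) return("pattern needs at least one literal position")
    TRUE
})

#' SSNGraph: sequence similarity network at one score threshold
#'
#' @slot threshold alignment bit-score threshold.
#' @slot nodes gene_ids.
#' @slot edges data.frame `from`, `to`, `score` with `score >= threshold`.
#' @slot membership named integer, connected-component id per node.
#' @exportClass SSNGraph
setClass("SSNGraph",
         slots = c(threshold = "numeric", nodes = "character",
                   edges = "data.frame", membership = "integer"))

setValidity("SSNGraph", function(object) {
    if (nrow(object@edges) && any(object@edges$score < object@threshold))
        return("edges below the threshold")
    if (!all(object@nodes %in% names(object@membership)))
        return("membership must cover all nodes")
    TRUE
})
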