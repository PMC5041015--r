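# Reading and writing the standard interchange formats: GFF3 gene models,
# protein FASTA, TSV family tables, TSV annotation output and graph exports.

#' Read a pan-genome from GFF3 + protein FASTA + family table
#'
#' Joins per-genome gene models, protein sequences and a COG-style
#' gene-to-family assignment table into a single [PanGenome]. One GFF3 file
#' per genome; the genome identifier defaults to the file name without its
#' extension. Only `gene` (or, failing that, `CDS`) features are consulted;
#' the `ID` attribute (falling back to `locus_tag`) becomes the gene_id.
#' Coordinates follow the GFF3 convention (1-based, inclusive).
#'
#' Genes without a protein sequence are retained (neighbors only need family
#' labels), as are genes without a family row (family `NA`). Family rows
#' referencing unknown gene_ids are skipped with a warning reporting the
#' count. A duplicated gene_id, or a gene_id with two family rows
#' (fusion-style multi-family assignment is unsupported), is a hard error.
#'
#' @param gffPaths character vector of GFF3 files, one per genome.
#' @param fastaPaths character vector of protein FASTA files; headers are
#'   resolved to gene_ids by their first whitespace-delimited token.
#' @param familyPath TSV with header columns `gene_id`, `family_id`.
#' @param genomeIds optional genome identifiers matching `gffPaths`;
#'   default: file base names.
#' @return a [PanGenome].
#' @examples
#' sim <- generatePanGenome(synthConfig(seed = 1, n_genomes = 4))
#' pg <- readPanGenome(sim$gff, sim$fasta, sim$family)
#' pg
#' @export
readPanGenome <- function(gffPaths, fastaPaths, familyPath,
                          genomeIds = NULL) {
    if (is.null(genomeIds))
        genomeIds <- sub("\\.gff3?$", "", basename(gffPaths),
                         ignore.case = TRUE)
    stopifnot(length(genomeIds) == length(gffPaths))
    tabs <- vector("list", length(gffPaths))
    for (i in seq_along(gffPaths)) {
        gr <- rtracklayer::import(gffPaths[i])
        gr <- gr[as.character(gr$type) %in% c("gene", "CDS")]
        if (any(as.character(gr$type) == "gene"))
            gr <- gr[as.character(gr$type) == "gene"]
        ids <- as.character(gr$ID)
        if ("locus_tag" %in% colnames(S4Vectors::mcols(gr))) {
            lt <- as.character(gr$locus_tag)
            ids[is.na(ids) | !nzchar(ids)] <- lt[is.na(ids) | !nzchar(ids)]
        }
        if (any(is.na(ids) | !nzchar(ids)))
            stop("GFF feature without ID/locus_tag in ", gffPaths[i])
        tabs[[i]] <- data.frame(
            gene_id = ids, genome_id = genomeIds[i],
            contig_id = as.character(GenomicRanges::seqnames(gr)),
            start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
            strand = as.character(GenomicRanges::strand(gr)),
            family_id = NA_character_, stringsAsFactors = FALSE)
    }
    geneDf <- do.call(rbind, tabs)
    dup <- geneDf$gene_id[duplicated(geneDf$gene_id)]
    if (length(dup)) stop("duplicate gene_id: ", dup[1L])

    fam <- utils::read.delim(familyPath, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "family_id") %in% names(fam)))
        stop("family table must have columns gene_id, family_id")
    dupf <- unique(fam$gene_id[duplicated(fam$gene_id)])
    if (length(dupf))
        stop("gene_id ", dupf[1L],
             " has multiple family rows (fusions unsupported)")
    known <- fam$gene_id %in% geneDf$gene_id
    if (any(!known))
        warning(sum(!known),
                " family row(s) reference unknown gene_ids; skipped")
    fam <- fam[known, , drop = FALSE]
    geneDf$family_id[match(fam$gene_id, geneDf$gene_id)] <- fam$family_id

    prot <- Biostrings::AAStringSet()
    for (fp in fastaPaths) {
        p <- Biostrings::readAAStringSet(fp)
        names(p) <- sub("\\s.*$", "", names(p))
        prot <- c(prot, p)
    }
    if (length(prot)) {
        unknown <- !(names(prot) %in% geneDf$gene_id)
        if (any(unknown)) {
            warning(sum(unknown),
                    " protein(s) with headers not matching any gene; dropped")
            prot <- prot[!unknown]
        }
    }
    PanGenome(geneDf, prot)
}

#' Write annotation calls as a TSV table
#'
#' Columns `gene_id`, `genome_id`, `family_id`, `subgroup`, `evidence`,
#' `confidence`, `motif_matched`; rows ordered by (genome_id, gene_id).
#' For hybrid calls `motif_matched` joins all matched patterns with `;`.
#'
#' @param calls data.frame of annotation calls (see [annotateFamily()]).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeAnnotationTable <- function(calls, path) {
    cols <- c("gene_id", "genome_id", "family_id", "subgroup", "evidence",
              "confidence", "motif_matched")
    if (nrow(calls) == 0L) {
        writeLines(paste(cols, collapse = "\t"), path)
        return(invisible(path))
    }
    missing <- setdiff(cols, names(calls))
    for (m in missing) calls[[m]] <- NA_character_
    calls <- calls[order(calls$genome_id, calls$gene_id), cols, drop = FALSE]
    utils::write.table(calls, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read back an annotation TSV written by [writeAnnotationTable()]
#' @param path TSV file.
#' @return data.frame of calls.
#' @export
readAnnotationTable <- function(path)
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = "character")

#' Export a weighted gene graph
#'
#' Writes a weighted edge list (`from to weight`, whitespace-delimited,
#' the NCOL dialect readable by standard network viewers) or GraphML.
#' Node identifiers are gene_ids.
#'
#' @param edges data.frame with columns `from`, `to` and a numeric weight
#'   column (`weight` or `score`).
#' @param path output file.
#' @param format `"edgelist"` or `"graphml"`.
#' @param nodes optional node ids to include even when isolated.
#' @return the path, invisibly.
#' @export
writeGraph <- function(edges, path, format = c("edgelist", "graphml"),
                       nodes = NULL) {
    format <- match.arg(format)
    wcol <- intersect(c("weight", "score"), names(edges))[1L]
    if (nrow(edges) && is.na(wcol)) stop("edges need a weight/score column")
    e <- if (nrow(edges))
        data.frame(from = edges$from, to = edges$to,
                   weight = edges[[wcol]], stringsAsFactors = FALSE)
    else data.frame(from = character(), to = character(), weight = numeric())
    verts <- unique(c(nodes, e$from, e$to))
    if (format == "edgelist") {
        lines <- if (nrow(e))
            sprintf("%s %s %s", e$from, e$to, format(e$weight, trim = TRUE))
        else character()
        writeLines(lines, path)
    } else {
        g <- igraph::graph_from_data_frame(
            e, directed = FALSE,
            vertices = if (length(verts)) data.frame(name = verts) else NULL)
        igraph::write_graph(g, path, format = "graphml")
    }
    invisible(path)
}

#' Read back a graph written by [writeGraph()]
#' @param path graph file.
#' @param format `"edgelist"` or `"graphml"`.
#' @return data.frame `from`, `to`, `weight`.
#' @export
readGraph <- function(path, format = c("edgelist", "graphml")) {
    format <- match.arg(format)
    if (format == "edgelist") {
        if (file.size(path) == 0L)
            return(data.frame(from = character(), to = character(),
                              weight = numeric()))
        df <- utils::read.table(path, col.names = c("from", "to", "weight"),
                                colClasses = c("character", "character",
                                               "numeric"))
        return(df)
    }
    g <- igraph::read_graph(path, format = "graphml")
    df <- igraph::as_data_frame(g, what = "edges")
    names(df)[1:2] <- c("from", "to")
    if (!"weight" %in% names(df)) df$weight <- rep(NA_real_, nrow(df))
    df[, c("from", "to", "weight")]
}
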