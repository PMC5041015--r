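# Fixture builders: everything is constructed in code at test time.

# Minimal gene table row
gene_row <- function(gene_id, genome_id, contig_id, start, family_id = NA,
                     strand = "+") {
    data.frame(gene_id = gene_id, genome_id = genome_id,
               contig_id = contig_id, start = start, end = start + 899,
               strand = strand, family_id = family_id,
               stringsAsFactors = FALSE)
}

# A contig laid out from a vector of family labels (NA = unassigned);
# gene ids <genome>_<contig>_gNN.
contig_genes <- function(genome_id, contig_id, families) {
    do.call(rbind, lapply(seq_along(families), function(i)
        gene_row(sprintf("%s_%s_g%02d", genome_id, contig_id, i),
                 genome_id, contig_id, (i - 1L) * 1000L + 1L,
                 families[i])))
}

# Pan-genome where each genome is a list of contig family-label vectors
toy_pangenome <- function(genomes, proteins = character()) {
    dfs <- list()
    for (g in names(genomes)) {
        for (ci in seq_along(genomes[[g]])) {
            dfs[[length(dfs) + 1L]] <-
                contig_genes(g, sprintf("c%02d", ci), genomes[[g]][[ci]])
        }
    }
    PanGenome(do.call(rbind, dfs), proteins)
}

# default synthetic scenario, read back through the io layer
default_sim <- function(seed, ...) {
    sim <- generatePanGenome(synthConfig(seed = seed, ...))
    pg <- readPanGenome(sim$gff, sim$fasta, sim$family)
    list(sim = sim, pg = pg, truth = sim$truth)
}

# plant a motif instance into a random background at a fixed offset
seq_with <- function(motif, L = 60, offset = 20) {
    chars <- sample(AA20, L, replace = TRUE)
    m <- strsplit(motif, "")[[1]]
    stopifnot(offset + length(m) - 1L <= L)
    chars[offset + seq_along(m) - 1L] <- m
    paste(chars, collapse = "")
}

# aligned block straight from equal-width row strings
block_of <- function(rows, label = "SG") {
    aln <- Biostrings::AAStringSet(rows)
    names(aln) <- if (is.null(names(rows)))
        paste0("s", seq_along(rows)) else names(rows)
    new("AlignedBlock", label = label, alignment = aln)
}
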