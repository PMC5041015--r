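# Seeded synthetic pan-genomes with planted subgroup structure: each focal
# family member sits in a conserved gene-neighborhood cassette specific to
# its subgroup and carries that subgroup's signature motif embedded in an
# otherwise diverged protein. Gene loss, cassette rearrangement and motif
# mutation are configurable noise processes. A machine-readable truth set
# accompanies the emitted files so every pipeline stage is testable without
# downloads.

#' Configuration for the synthetic pan-genome generator
#'
#' Defaults describe the standard validation scenario: 20 genomes, one focal
#' family with three subgroups carrying the signature patterns CxxxHGH,
#' CxxxxxHGH and ExxHGH, three conserved neighbor families per subgroup,
#' 120-residue proteins, per-literal motif mutation probability 0.02,
#' neighbor gene-loss probability 0.1, and half of the genomes carrying
#' members of two or more subgroups (the paralog genomes the workflow keys
#' on). See the methods vignette for what the generator does and does not
#' emulate.
#'
#' @param seed mandatory RNG seed (integer).
#' @param n_genomes number of genomes.
#' @param patterns named character vector of subgroup signature patterns
#'   (residues plus wildcard `x`); names are the planted subgroup labels.
#' @param family_id focal family label.
#' @param context_size conserved neighbor families per subgroup.
#' @param protein_length focal protein length (must exceed every pattern).
#' @param motif_mutation per-literal-position mutation probability.
#' @param gene_loss per-neighbor loss probability.
#' @param rearrangement probability that a cassette's neighbor order is
#'   shuffled.
#' @param paralog_fraction fraction of genomes carrying members of >= 2
#'   subgroups.
#' @param second_copy_prob probability that a present subgroup contributes
#'   two members to a paralog genome.
#' @param decoy_families size of the unrelated (decoy) family pool placed
#'   on separate contigs.
#' @param decoy_contig_genes genes per decoy contig.
#' @param edge_decoy_max maximal number of unannotated filler genes on each
#'   side of a cassette.
#' @param background residue background: `"uniform"` or a named probability
#'   vector over the 20 residues.
#' @return a list of class `SynthConfig`.
#' @export
synthConfig <- function(seed,
                        n_genomes = 20L,
                        patterns = c(SG1 = "CxxxHGH", SG2 = "CxxxxxHGH",
                                     SG3 = "ExxHGH"),
                        family_id = "FAM0001",
                        context_size = 3L,
                        protein_length = 120L,
                        motif_mutation = 0.02,
                        gene_loss = 0.1,
                        rearrangement = 0.1,
                        paralog_fraction = 0.5,
                        second_copy_prob = 0.2,
                        decoy_families = 40L,
                        decoy_contig_genes = 4L,
                        edge_decoy_max = 1L,
                        background = "uniform") {
    if (missing(seed)) stop("seed is mandatory")
    probs <- c(motif_mutation, gene_loss, rearrangement, paralog_fraction,
               second_copy_prob)
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
    if (any(nchar(patterns) >= protein_length))
        stop("motif longer than protein")
    if (is.null(names(patterns)) || anyDuplicated(names(patterns)))
        stop("patterns must carry unique subgroup labels")
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYx]", patterns)
    if (any(bad)) stop("invalid pattern: ", patterns[bad][1L])
    cfg <- list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
                patterns = patterns, family_id = family_id,
                context_size = as.integer(context_size),
                protein_length = as.integer(protein_length),
                motif_mutation = motif_mutation, gene_loss = gene_loss,
                rearrangement = rearrangement,
                paralog_fraction = paralog_fraction,
                second_copy_prob = second_copy_prob,
                decoy_families = as.integer(decoy_families),
                decoy_contig_genes = as.integer(decoy_contig_genes),
                edge_decoy_max = as.integer(edge_decoy_max),
                background = background)
    class(cfg) <- "SynthConfig"
    cfg
}

.bgProbs <- function(config) {
    if (identical(config$background, "uniform"))
        return(stats::setNames(rep(1 / 20, 20), .AA20))
    p <- config$background[.AA20]
    p / sum(p)
}

# Sample a focal protein with the subgroup motif planted at the subgroup's
# offset (motifs occupy homologous positions within a subfamily; indels are
# not modelled). Literal positions mutate with the configured probability;
# wildcard positions are background-sampled. Proteins accidentally
# containing a different subgroup's pattern are re-sampled, so planted
# members conform to exactly one signature (hybrids are constructed
# explicitly, not by chance).
.plantProtein <- function(config, subgroup, offset) {
    pat <- strsplit(config$patterns[[subgroup]], "")[[1]]
    others <- config$patterns[names(config$patterns) != subgroup]
    L <- config$protein_length
    bg <- .bgProbs(config)
    for (try in seq_len(200L)) {
        chars <- sample(.AA20, L, replace = TRUE, prob = bg)
        mutated <- FALSE
        for (k in seq_along(pat)) {
            if (pat[k] == "x") next
            if (stats::runif(1) < config$motif_mutation) {
                chars[offset + k - 1L] <- sample(setdiff(.AA20, pat[k]), 1L)
                mutated <- TRUE
            } else chars[offset + k - 1L] <- pat[k]
        }
        prot <- paste(chars, collapse = "")
        cross <- any(vapply(others, function(p)
            length(matchMotif(prot, p)) > 0L, FALSE))
        if (!cross)
            return(list(protein = prot, offset = offset, mutated = mutated))
    }
    stop("could not sample a conforming protein; patterns too permissive")
}

#' Generate a synthetic pan-genome with planted subgroups
#'
#' Emits per-genome GFF3 files, a protein FASTA for the focal family, a
#' gene-to-family TSV and a JSON truth set into `dir`. Each focal member
#' occupies its own cassette contig: its subgroup's conserved neighbor
#' families around it (each lost with `gene_loss`, order shuffled with
#' probability `rearrangement`), flanked by 0 to `edge_decoy_max`
#' unannotated filler genes per side; labelled decoy families occupy
#' separate decoy contigs. Deterministic given the seed: two runs with the
#' same configuration produce byte-identical files.
#'
#' @param config a [synthConfig()].
#' @param dir output directory (created; default a fresh temporary
#'   directory).
#' @return list with `dir`, file paths (`gff`, `fasta`, `family`,
#'   `truth_json`), the `truth` data.frame (per focal gene: planted
#'   subgroup, pattern, motif offset, mutated flag, planted context labels)
#'   and the `config`.
#' @export
generatePanGenome <- function(config, dir = tempfile("synthpg")) {
    stopifnot(inherits(config, "SynthConfig"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(config$seed)
    labs <- names(config$patterns)
    nsub <- length(labs)
    ctx <- lapply(labs, function(l)
        sprintf("CTX_%s_%02d", l, seq_len(config$context_size)))
    names(ctx) <- labs

    npar <- round(config$paralog_fraction * config$n_genomes)
    paralog <- seq_len(config$n_genomes) %in%
        sample.int(config$n_genomes, npar)
    # subgroup-specific motif offsets: homologous positions within a
    # subfamily (no indels are modelled)
    offsets <- vapply(labs, function(l)
        sample.int(config$protein_length -
                   nchar(config$patterns[[l]]) + 1L, 1L), 0L)

    truth <- list(); fam_rows <- list(); prot <- character()
    gff_paths <- character(config$n_genomes)
    gene_orders <- list()

    for (g in seq_len(config$n_genomes)) {
        gid <- sprintf("G%02d", g)
        present <- if (paralog[g]) {
            k <- if (nsub >= 3L) sample(2:nsub, 1L) else 2L
            sort(sample(labs, k))
        } else sample(labs, 1L)
        contigs <- list()   # each: data.frame gene_id, family, strand
        gcount <- 0L
        nextGene <- function() {
            gcount <<- gcount + 1L
            sprintf("%s_g%04d", gid, gcount)
        }
        for (sg in present) {
            copies <- if (paralog[g])
                1L + stats::rbinom(1L, 1L, config$second_copy_prob) else 1L
            for (cp in seq_len(copies)) {
                kept <- ctx[[sg]][stats::runif(config$context_size) >=
                                  config$gene_loss]
                if (length(kept) > 1L && stats::runif(1) < config$rearrangement)
                    kept <- sample(kept)
                side <- if (length(kept))
                    stats::runif(length(kept)) < 0.5 else logical(0)
                nl <- sample.int(config$edge_decoy_max + 1L, 1L) - 1L
                nr <- sample.int(config$edge_decoy_max + 1L, 1L) - 1L
                fams <- c(rep(NA_character_, nl), kept[side],
                          config$family_id, kept[!side],
                          rep(NA_character_, nr))
                ids <- vapply(seq_along(fams), function(.) nextGene(), "")
                focal_id <- ids[nl + sum(side) + 1L]
                pl <- .plantProtein(config, sg, offsets[[sg]])
                prot[focal_id] <- pl$protein
                truth[[length(truth) + 1L]] <- data.frame(
                    gene_id = focal_id, genome_id = gid, subgroup = sg,
                    pattern = unname(config$patterns[sg]),
                    motif_start = pl$offset, mutated = pl$mutated,
                    context = paste(sort(kept), collapse = ";"),
                    family_id = config$family_id, stringsAsFactors = FALSE)
                contigs[[length(contigs) + 1L]] <- data.frame(
                    gene_id = ids, family = fams,
                    strand = sample(c("+", "-"), length(ids), replace = TRUE),
                    stringsAsFactors = FALSE)
            }
        }
        # decoy contigs with labelled unrelated families
        for (d in 1:2) {
            fams <- sprintf("DEC%03d",
                            sample.int(config$decoy_families,
                                       config$decoy_contig_genes,
                                       replace = TRUE))
            ids <- vapply(seq_along(fams), function(.) nextGene(), "")
            contigs[[length(contigs) + 1L]] <- data.frame(
                gene_id = ids, family = fams,
                strand = sample(c("+", "-"), length(ids), replace = TRUE),
                stringsAsFactors = FALSE)
        }
        # write this genome's GFF3
        lines <- "##gff-version 3"
        order_ids <- character()
        for (ci in seq_along(contigs)) {
            cdf <- contigs[[ci]]
            contig <- sprintf("%s_c%02d", gid, ci)
            lines <- c(lines, sprintf("##sequence-region %s 1 %d",
                                      contig, nrow(cdf) * 1000L))
            for (i in seq_len(nrow(cdf))) {
                s <- (i - 1L) * 1000L + 1L
                lines <- c(lines, sprintf(
                    "%s\tparaSign\tgene\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s",
                    contig, s, s + 899L, cdf$strand[i], cdf$gene_id[i],
                    cdf$gene_id[i]))
            }
            order_ids <- c(order_ids, cdf$gene_id)
            keep <- !is.na(cdf$family)
            if (any(keep))
                fam_rows[[length(fam_rows) + 1L]] <-
                    data.frame(gene_id = cdf$gene_id[keep],
                               family_id = cdf$family[keep],
                               stringsAsFactors = FALSE)
        }
        gff_paths[g] <- file.path(dir, paste0(gid, ".gff3"))
        writeLines(lines, gff_paths[g])
        gene_orders[[gid]] <- order_ids
    }

    fasta <- file.path(dir, "proteins.faa")
    writeLines(as.vector(rbind(paste0(">", names(prot)), prot)), fasta)
    famp <- file.path(dir, "families.tsv")
    famdf <- do.call(rbind, fam_rows)
    utils::write.table(famdf, famp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    truthp <- file.path(dir, "truth.json")
    jsonlite::write_json(
        list(config = config[setdiff(names(config), "background")],
             genes = truth, gene_order = gene_orders),
        truthp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(dir = dir, gff = gff_paths, fasta = fasta, family = famp,
         truth_json = truthp, truth = truth, config = config)
}

#' Corrupt a truth annotation table by cross-subgroup label transfer
#'
#' Models annotation-transfer errors between functionally divergent
#' paralogs: exactly `round(fraction * n)` members are relabelled with a
#' different subgroup's annotation.
#'
#' @param truth truth data.frame from [generatePanGenome()].
#' @param fraction fraction of members to mislabel, in \[0, 1\].
#' @param seed RNG seed.
#' @return list with `table` (gene_id, subgroup after corruption) and
#'   `corrupted` (the affected gene_ids).
#' @export
corruptAnnotations <- function(truth, fraction, seed) {
    stopifnot(fraction >= 0, fraction <= 1)
    set.seed(seed)
    n <- nrow(truth)
    k <- round(fraction * n)
    labs <- unique(truth$subgroup)
    if (k > 0L && length(labs) < 2L)
        stop("need >= 2 subgroups to corrupt labels")
    idx <- if (k > 0L) sort(sample.int(n, k)) else integer(0)
    out <- data.frame(gene_id = truth$gene_id, subgroup = truth$subgroup,
                      stringsAsFactors = FALSE)
    for (i in idx)
        out$subgroup[i] <- sample(setdiff(labs, truth$subgroup[i]), 1L)
    list(table = out, corrupted = truth$gene_id[idx])
}
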