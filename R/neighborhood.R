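# Gene-neighborhood profiles, context similarity, and partitioning of a
# family into provisional isofunctional subgroups.
#
# Paralogs that physically cluster with the same gene families across
# different genomes are grouped together; paralogs clustering with different
# families are separated. Similarity is the Jaccard index on neighbor-family
# label sets, ignoring order, strand and distance; grouping is single-linkage
# over edges at or above a permissive threshold tau.

#' Extract the neighborhood profile of one gene
#'
#' Collects up to `windowK` genes on each side of the focal gene on the same
#' contig (truncated at contig ends). Neighbors without a family label are
#' excluded from the neighbor-family set by default; with
#' `includeUnassigned = TRUE` they enter under a reserved
#' `singleton:<gene_id>` label. The focal gene's own family never enters the
#' set (other family members in the window remain visible in the ordered
#' neighbor list).
#'
#' @param pg a [PanGenome].
#' @param geneId focal gene identifier.
#' @param windowK genes per side (default 5).
#' @param includeUnassigned include label-less neighbors under reserved
#'   singleton labels.
#' @return a [NeighborhoodProfile].
#' @export
extractNeighborhood <- function(pg, geneId, windowK = 5L,
                                includeUnassigned = FALSE) {
    gt <- geneTable(pg)
    i <- match(geneId, gt$gene_id)
    if (is.na(i)) stop("gene not found: ", geneId)
    windowK <- as.integer(windowK)
    sub <- gt[gt$genome_id == gt$genome_id[i] &
              gt$contig_id == gt$contig_id[i], , drop = FALSE]
    pos <- match(geneId, sub$gene_id)
    idx <- seq(max(1L, pos - windowK), min(nrow(sub), pos + windowK))
    idx <- idx[idx != pos]
    fam <- sub$family_id[idx]
    lab <- fam
    if (includeUnassigned)
        lab[is.na(fam)] <- paste0("singleton:", sub$gene_id[idx][is.na(fam)])
    ord <- data.frame(offset = idx - pos, family = lab,
                      strand = sub$strand[idx], stringsAsFactors = FALSE)
    fams <- unique(lab[!is.na(lab)])
    focalFam <- sub$family_id[pos]
    if (!is.na(focalFam)) fams <- setdiff(fams, focalFam)
    new("NeighborhoodProfile", focalGene = geneId,
        focalFamily = focalFam, windowK = windowK,
        neighborFamilies = sort(fams), orderedNeighbors = ord)
}

#' Neighborhood profiles for all members of one family
#'
#' @inheritParams extractNeighborhood
#' @param familyId the focal family.
#' @return named list of [NeighborhoodProfile] (names are gene_ids), ordered
#'   by (genome_id, gene_id).
#' @export
familyProfiles <- function(pg, familyId, windowK = 5L,
                           includeUnassigned = FALSE) {
    gt <- geneTable(pg)
    mem <- gt[!is.na(gt$family_id) & gt$family_id == familyId, , drop = FALSE]
    if (!nrow(mem)) stop("no members of family ", familyId)
    mem <- mem[order(mem$genome_id, mem$gene_id), , drop = FALSE]
    out <- lapply(mem$gene_id, extractNeighborhood, pg = pg,
                  windowK = windowK, includeUnassigned = includeUnassigned)
    names(out) <- mem$gene_id
    out
}

#' Jaccard similarity of two neighborhood profiles
#'
#' `|intersection| / |union|` of the neighbor-family sets; 0 when both are
#' empty. Symmetric; 1 iff the non-empty sets are equal.
#'
#' @param p1,p2 [NeighborhoodProfile] objects from the same focal family.
#' @return a proportion in \[0, 1\].
#' @export
neighborhoodSimilarity <- function(p1, p2)
    .jaccard(p1@neighborFamilies, p2@neighborFamilies)

#' Build the context graph over a family's members
#'
#' Edge (i, j) iff the neighborhood Jaccard similarity is >= `tau` (i != j);
#' weights are the similarities.
#'
#' @param profiles named list of [NeighborhoodProfile] (see
#'   [familyProfiles()]).
#' @param tau similarity threshold in \[0, 1\] (values above 1 give an empty
#'   edge set).
#' @param genomes named character mapping gene_id to genome_id (e.g. from
#'   [geneTable()]); required for the downstream multi-genome support rule.
#' @return a [ContextGraph].
#' @export
buildContextGraph <- function(profiles, tau = 0.3, genomes) {
    stopifnot(is.list(profiles), !is.null(names(profiles)))
    ids <- names(profiles)
    if (missing(genomes)) stop("genomes map is required")
    if (!all(ids %in% names(genomes)))
        stop("genomes must cover every profile")
    n <- length(ids)
    from <- character(); to <- character(); w <- numeric()
    if (n >= 2L) {
        for (i in seq_len(n - 1L)) {
            for (j in seq(i + 1L, n)) {
                s <- neighborhoodSimilarity(profiles[[i]], profiles[[j]])
                if (s >= tau) {
                    from <- c(from, ids[i]); to <- c(to, ids[j])
                    w <- c(w, s)
                }
            }
        }
    }
    new("ContextGraph", nodes = ids,
        genomes = genomes[ids],
        edges = data.frame(from = from, to = to, weight = w,
                           stringsAsFactors = FALSE),
        tau = tau, profiles = profiles)
}

#' Partition a family into provisional isofunctional subgroups
#'
#' Subgroups are the connected components of the context graph that contain
#' at least two members spanning at least two genomes (conserved context
#' "across multiple species"); smaller components and isolated nodes go to
#' `unplaced`. Labels `SG1`, `SG2`, ... are assigned in order of the
#' lexicographically smallest member gene_id, so the partition is invariant
#' under member input order. The supporting neighbor-family set is the
#' intersection of the members' neighbor families, falling back to labels
#' shared by at least half the members when the intersection is empty.
#'
#' @param graph a [ContextGraph].
#' @param familyId family label recorded on the partition.
#' @return a [SubgroupPartition].
#' @export
partitionFamily <- function(graph, familyId = NA_character_) {
    ids <- graph@nodes
    g <- igraph::graph_from_data_frame(
        graph@edges[, c("from", "to")], directed = FALSE,
        vertices = data.frame(name = ids))
    comp <- igraph::components(g)$membership
    comp <- comp[ids]
    sgs <- list(); unplaced <- character()
    comps <- split(ids, comp)
    for (members in comps) {
        members <- sort(members)
        genomes <- unique(graph@genomes[members])
        if (length(members) >= 2L && length(genomes) >= 2L) {
            sets <- lapply(graph@profiles[members],
                           function(p) p@neighborFamilies)
            supp <- Reduce(intersect, sets)
            if (!length(supp)) {
                tab <- table(unlist(lapply(sets, unique)))
                supp <- names(tab)[tab >= length(members) / 2]
            }
            sgs[[length(sgs) + 1L]] <-
                list(members = members, support = sort(supp))
        } else {
            unplaced <- c(unplaced, members)
        }
    }
    if (length(sgs)) {
        o <- order(vapply(sgs, function(s) s$members[1L], ""))
        sgs <- sgs[o]
        names(sgs) <- paste0("SG", seq_along(sgs))
    }
    new("SubgroupPartition", familyId = familyId, subgroups = sgs,
        unplaced = sort(unplaced), genomes = graph@genomes)
}

#' GNN-style summary: neighbor families per subgroup
#'
#' For each subgroup, tabulates every neighbor family with the number of
#' members whose profile contains it, the number of distinct genomes those
#' members come from, and the member fraction; rows sorted by decreasing
#' member count within subgroup.
#'
#' @param partition a [SubgroupPartition].
#' @param profiles the profile list the partition was derived from.
#' @return data.frame `subgroup`, `neighbor_family`, `n_members`,
#'   `n_genomes`, `fraction_members`.
#' @export
gnnSummary <- function(partition, profiles) {
    rows <- list()
    for (sg in names(partition@subgroups)) {
        members <- partition@subgroups[[sg]]$members
        sets <- lapply(profiles[members], function(p) p@neighborFamilies)
        fams <- sort(unique(unlist(sets)))
        if (!length(fams)) next
        cnt <- vapply(fams, function(f)
            sum(vapply(sets, function(s) f %in% s, FALSE)), 0L)
        ngen <- vapply(fams, function(f) {
            has <- members[vapply(sets, function(s) f %in% s, FALSE)]
            length(unique(partition@genomes[has]))
        }, 0L)
        df <- data.frame(subgroup = sg, neighbor_family = fams,
                         n_members = cnt, n_genomes = ngen,
                         fraction_members = cnt / length(members),
                         stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <-
            df[order(-df$n_members, df$neighbor_family), , drop = FALSE]
    }
    if (!length(rows))
        return(data.frame(subgroup = character(),
                          neighbor_family = character(),
                          n_members = integer(), n_genomes = integer(),
                          fraction_members = numeric()))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Sensitivity sweep over the context-similarity threshold tau
#'
#' Re-partitions the family at each candidate tau, reporting the number of
#' subgroups and unplaced members; raising tau can only shrink the edge set,
#' so subgroups never merge as tau grows.
#'
#' @param profiles named profile list.
#' @param genomes named gene_id -> genome_id map.
#' @param taus thresholds to evaluate.
#' @param familyId family label.
#' @return data.frame `tau`, `n_subgroups`, `n_unplaced`.
#' @export
tauSweep <- function(profiles, genomes, taus = seq(0, 1, by = 0.1),
                     familyId = NA_character_) {
    res <- lapply(taus, function(t) {
        p <- partitionFamily(buildContextGraph(profiles, t, genomes),
                             familyId)
        data.frame(tau = t, n_subgroups = length(p@subgroups),
                   n_unplaced = length(p@unplaced))
    })
    do.call(rbind, res)
}
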