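# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles, sharing no code path with the package.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Jaccard by explicit element counting
oracle_jaccard <- function(a, b) {
    a <- unique(a); b <- unique(b)
    inter <- 0L
    for (x in a) if (any(b == x)) inter <- inter + 1L
    uni <- length(a) + length(b) - inter
    if (uni == 0L) 0 else inter / uni
}

# connected components by BFS over an edge list
oracle_components <- function(nodes, edges) {
    adj <- setNames(vector("list", length(nodes)), nodes)
    if (nrow(edges)) {
        for (r in seq_len(nrow(edges))) {
            adj[[edges$from[r]]] <- c(adj[[edges$from[r]]], edges$to[r])
            adj[[edges$to[r]]] <- c(adj[[edges$to[r]]], edges$from[r])
        }
    }
    comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
    k <- 0L
    for (n0 in nodes) {
        if (!is.na(comp[[n0]])) next
        k <- k + 1L
        queue <- n0
        while (length(queue)) {
            v <- queue[[1L]]; queue <- queue[-1L]
            if (!is.na(comp[[v]])) next
            comp[[v]] <- k
            queue <- c(queue, adj[[v]])
        }
    }
    comp
}

# Smith-Waterman with affine gaps (Gotoh), raw score only.
# A gap of length L costs open + L * ext (matching the package's stated
# scoring scheme).
oracle_sw <- function(a, b, submat, open = 11, ext = 1) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    n <- length(ca); m <- length(cb)
    M <- matrix(0, n + 1L, m + 1L)
    Ix <- matrix(-Inf, n + 1L, m + 1L)
    Iy <- matrix(-Inf, n + 1L, m + 1L)
    best <- 0
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext,
                                      Ix[i, j + 1L] - ext)
            Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext,
                                      Iy[i + 1L, j] - ext)
            s <- submat[ca[i], cb[j]]
            M[i + 1L, j + 1L] <- max(0,
                                     M[i, j] + s,
                                     Ix[i, j] + s,
                                     Iy[i, j] + s)
            best <- max(best, M[i + 1L, j + 1L])
        }
    }
    best
}

# Welch two-sample t on 0/1 indicators, closed form
oracle_welch <- function(xA, xB, eps = 1e-9) {
    nA <- length(xA); nB <- length(xB)
    pA <- mean(xA); pB <- mean(xB)
    vA <- sum((xA - pA)^2) / (nA - 1)
    vB <- sum((xB - pB)^2) / (nB - 1)
    se2 <- vA / nA + vB / nB
    (pA - pB) / sqrt(se2 + eps)
}

# adjusted Rand index by pair counting over all item pairs
oracle_ari <- function(a, b) {
    n <- length(a)
    s11 <- s00 <- s10 <- s01 <- 0
    for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
            sa <- a[i] == a[j]; sb <- b[i] == b[j]
            if (sa && sb) s11 <- s11 + 1
            else if (!sa && !sb) s00 <- s00 + 1
            else if (sa) s10 <- s10 + 1
            else s01 <- s01 + 1
        }
    }
    tot <- s11 + s00 + s10 + s01
    expected <- (s11 + s10) * (s11 + s01) / tot
    maxi <- ((s11 + s10) + (s11 + s01)) / 2
    if (maxi == expected) return(1)
    (s11 - expected) / (maxi - expected)
}

# best-window PSSM score by direct window enumeration
oracle_pssm <- function(protein, freqs, pc = 0.5 / 20, bg = 1 / 20) {
    chars <- strsplit(protein, "")[[1]]
    W <- ncol(freqs)
    best <- -Inf; pos <- NA
    for (s in seq_len(length(chars) - W + 1L)) {
        sc <- 0
        for (j in seq_len(W)) {
            r <- chars[s + j - 1L]
            sc <- sc + log2((freqs[r, j] + pc) / bg)
        }
        if (sc > best + 1e-12) { best <- sc; pos <- s }
    }
    list(score = unname(best), position = pos)
}

random_protein <- function(L) paste(sample(AA20, L, replace = TRUE),
                                    collapse = "")

blosum62 <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
})
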