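# deterministic random binary association matrix
randomAssoc <- function(nc, nd, p = 0.3, seed = 1) {
    m <- circGCN:::withSeed(seed, matrix(rbinom(nc * nd, 1, p), nc, nd))
    AssociationMatrix(m, paste0("c", seq_len(nc)), paste0("d", seq_len(nd)))
}

# small synthetic dataset for fast end-to-end tests
smallDataset <- function(seed = 1, ...) {
    generateDataset(syntheticConfig(nCirc = 40L, nDis = 12L, nGenes = 20L,
                                    nClusters = 2L, seqLen = 200L,
                                    seed = seed, ...))
}

# brute-force GIP kernel: entrywise double loop over profiles in rows of P
bruteGip <- function(P, gammaPrime = 1) {
    n <- nrow(P)
    gamma <- gammaPrime / mean(apply(P, 1, function(r) sum(r^2)))
    K <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
        K[i, j] <- exp(-gamma * sum((P[i, ] - P[j, ])^2))
    K
}

# Mann-Whitney AUC: concordant pos/neg pairs, ties count one half
bruteAuc <- function(scores, labels) {
    ps <- scores[labels == 1]; ns <- scores[labels == 0]
    tot <- 0
    for (p in ps) for (q in ns)
        tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(ps) * length(ns))
}
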