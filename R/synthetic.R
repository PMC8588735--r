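## Seeded synthetic datasets with planted bipartite block structure. Shared
## latent clusters drive the associations, the sequence composition, the
## gene sharing and the DAG placement, so every similarity channel carries
## (tunable) signal about the same ground truth.

#' Configuration for the synthetic generator
#'
#' @param nCirc,nDis,nGenes entity counts (defaults 150 circRNAs, 40
#'   diseases, 60 genes).
#' @param nClusters number of shared latent clusters (default 3).
#' @param pIn,pOut association probability when circRNA and disease share
#'   a cluster / otherwise (defaults 0.25 / 0.01). \code{pIn == pOut}
#'   gives a null dataset with no planted signal.
#' @param seqLen nucleotide sequence length (default 500).
#' @param motifStrength in [0, 1]: how far cluster-specific base
#'   compositions deviate from uniform (default 0.8).
#' @param dagDepth depth of the disease DAG tree (default 4).
#' @param geneIn,geneOut circRNA-gene link probability within / across
#'   clusters (defaults 0.3 / 0.02).
#' @param pSeqMissing,pDagMissing fraction of circRNAs without a sequence
#'   and of diseases outside the DAG (defaults 0.1 each), exercising the
#'   fusion fallback branches.
#' @param seed RNG seed (default 0).
#' @return a \code{SyntheticConfig} list.
#' @export
syntheticConfig <- function(nCirc = 150L, nDis = 40L, nGenes = 60L,
                            nClusters = 3L, pIn = 0.25, pOut = 0.01,
                            seqLen = 500L, motifStrength = 0.8,
                            dagDepth = 4L, geneIn = 0.3, geneOut = 0.02,
                            pSeqMissing = 0.1, pDagMissing = 0.1,
                            seed = 0L) {
    cfg <- list(nCirc = as.integer(nCirc), nDis = as.integer(nDis),
                nGenes = as.integer(nGenes), nClusters = as.integer(nClusters),
                pIn = pIn, pOut = pOut, seqLen = as.integer(seqLen),
                motifStrength = motifStrength, dagDepth = as.integer(dagDepth),
                geneIn = geneIn, geneOut = geneOut,
                pSeqMissing = pSeqMissing, pDagMissing = pDagMissing,
                seed = as.integer(seed))
    stopifnot(cfg$pOut >= 0, cfg$pOut <= cfg$pIn, cfg$pIn <= 1,
              cfg$nClusters >= 1,
              cfg$nClusters <= min(cfg$nCirc, cfg$nDis),
              cfg$motifStrength >= 0, cfg$motifStrength <= 1,
              cfg$dagDepth >= 2, cfg$seqLen >= 1)
    structure(cfg, class = "SyntheticConfig")
}

#' Synthetic configuration matching the benchmark dataset shape
#'
#' 533 circRNAs x 89 diseases with association probabilities chosen so the
#' expected positive count is about 616 (density about 0.013), mimicking
#' the sparsity of the curated benchmark network of that size.
#'
#' @param ... overrides forwarded to \code{\link{syntheticConfig}}.
#' @return a \code{SyntheticConfig}.
#' @export
benchmarkShapeConfig <- function(...) {
    syntheticConfig(nCirc = 533L, nDis = 89L, nGenes = 120L,
                    pIn = 0.0336, pOut = 0.0027, ...)
}

#' Generate a complete synthetic circRNA-disease dataset
#'
#' circRNAs, diseases and genes are assigned to \code{nClusters} latent
#' clusters uniformly at random. Associations are Bernoulli with
#' probability \code{pIn} when the clusters match and \code{pOut}
#' otherwise. Sequences are drawn i.i.d. from a cluster-specific base
#' composition interpolated toward uniform by \code{1 - motifStrength}.
#' Gene links follow the same in/out-cluster Bernoulli scheme. The disease
#' DAG is a rooted tree with one branch per cluster: each in-DAG disease
#' attaches to a node of its own cluster's branch, so semantic similarity
#' correlates with the planted structure. All draws derive from
#' \code{cfg$seed}: identical configurations produce identical datasets.
#'
#' @param cfg a \code{SyntheticConfig} from \code{\link{syntheticConfig}}.
#' @return a \linkS4class{CircDiseaseData} whose \code{clusters} slot
#'   carries the ground-truth assignments and the generating config.
#' @export
generateDataset <- function(cfg = syntheticConfig()) {
    stopifnot(inherits(cfg, "SyntheticConfig"))
    withSeed(cfg$seed, {
        circIds <- sprintf("circ_%03d", seq_len(cfg$nCirc))
        disIds <- sprintf("disease_%02d", seq_len(cfg$nDis))
        geneIds <- sprintf("gene_%03d", seq_len(cfg$nGenes))
        circCl <- sample.int(cfg$nClusters, cfg$nCirc, replace = TRUE)
        disCl <- sample.int(cfg$nClusters, cfg$nDis, replace = TRUE)
        geneCl <- sample.int(cfg$nClusters, cfg$nGenes, replace = TRUE)

        pMat <- ifelse(outer(circCl, disCl, "=="), cfg$pIn, cfg$pOut)
        A <- matrix(rbinom(length(pMat), 1, pMat), cfg$nCirc, cfg$nDis,
                    dimnames = list(circIds, disIds))

        ## cluster base compositions, interpolated toward uniform
        comps <- vapply(seq_len(cfg$nClusters), function(k) {
            w <- rexp(4)
            w / sum(w)
        }, numeric(4))
        comps <- cfg$motifStrength * comps + (1 - cfg$motifStrength) * 0.25
        seqs <- vapply(seq_len(cfg$nCirc), function(i) {
            paste(sample(c("A", "C", "G", "T"), cfg$seqLen, replace = TRUE,
                         prob = comps[, circCl[i]]), collapse = "")
        }, character(1))
        names(seqs) <- circIds
        nMissSeq <- floor(cfg$pSeqMissing * cfg$nCirc)
        if (nMissSeq > 0)
            seqs[sample.int(cfg$nCirc, nMissSeq)] <- NA_character_

        pGene <- ifelse(outer(circCl, geneCl, "=="), cfg$geneIn, cfg$geneOut)
        Acg <- matrix(rbinom(length(pGene), 1, pGene), cfg$nCirc, cfg$nGenes,
                      dimnames = list(circIds, geneIds))
        storage.mode(Acg) <- "double"

        ## rooted DAG: one chain of internal terms per cluster under the root
        depth <- cfg$dagDepth - 1L
        chains <- lapply(seq_len(cfg$nClusters),
                         function(k) sprintf("branch%d_lvl%d", k, seq_len(depth)))
        edges <- do.call(rbind, lapply(seq_len(cfg$nClusters), function(k) {
            ch <- chains[[k]]
            cbind(parent = c("ROOT", head(ch, -1)), child = ch)
        }))
        nMissDag <- floor(cfg$pDagMissing * cfg$nDis)
        outDag <- if (nMissDag > 0) sample.int(cfg$nDis, nMissDag) else integer(0)
        anc <- list()
        for (j in seq_len(cfg$nDis)) {
            if (j %in% outDag) next
            ch <- chains[[disCl[j]]]
            attach <- sample.int(depth, 1L)
            edges <- rbind(edges, cbind(parent = ch[attach], child = disIds[j]))
            anc[[disIds[j]]] <- c(disIds[j], ch[seq_len(attach)], "ROOT")
        }
        dag <- list(ancestors = anc,
                    universe = unique(c(edges[, "parent"], edges[, "child"])),
                    edges = as.data.frame(edges, stringsAsFactors = FALSE))

        new("CircDiseaseData",
            assoc = AssociationMatrix(A),
            sequences = seqs,
            geneAssoc = Acg,
            dag = dag,
            clusters = list(circ = setNames(circCl, circIds),
                            disease = setNames(disCl, disIds),
                            gene = setNames(geneCl, geneIds),
                            config = cfg))
    })
}
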