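## End-to-end pipeline: similarity -> fusion -> (diffusion) -> (PCA) ->
## heterogeneous network -> training -> scores, with a reproducibility
## manifest of parameters and stage fingerprints.

## cheap deterministic stage fingerprint (dims + two moments)
.fingerprint <- function(m) {
    m <- as.matrix(m)
    sprintf("%dx%d|%.12e|%.12e", nrow(m), ncol(m), sum(m), sum(m^2))
}

#' Run the full prediction pipeline on a dataset
#'
#' Builds the comprehensive similarities (unless precomputed CS/DS are
#' supplied), runs the selected mode's diffusion/PCA stages, assembles the
#' heterogeneous network and trains the encoder/decoder on all known
#' positives plus sampled negatives. The returned scores rank every
#' circRNA-disease pair; known pairs score high, and high-scoring zero
#' cells are the predicted novel associations.
#'
#' @param data a \linkS4class{CircDiseaseData}.
#' @param mode \code{"full"}, \code{"no-rwr"} or \code{"no-rwr-no-pca"}.
#' @param c walk mixing coefficient (default 0.4).
#' @param kPca PCA retained fraction (default 0.3).
#' @param lfn latent factor number (default 65).
#' @param negRatio negatives per positive for training (default 5).
#' @param lr learning rate (default 0.01).
#' @param epochs training epochs (default 200).
#' @param reg L2 penalty coefficient (default 0.01).
#' @param seed RNG seed.
#' @param precomputed optional list with \code{cs}, \code{ds} (and
#'   optionally \code{a}) supplied from files; skips similarity
#'   construction.
#' @return list with \code{scores} (\linkS4class{ScoreMatrix}),
#'   \code{params} (\linkS4class{GCNParams}) and \code{manifest}.
#' @export
runPipeline <- function(data, mode = c("full", "no-rwr", "no-rwr-no-pca"),
                        c = 0.4, kPca = 0.3, lfn = 65L, negRatio = 5,
                        lr = 0.01, epochs = 200L, reg = 1e-2, seed = 1L,
                        precomputed = NULL) {
    mode <- match.arg(mode)
    A <- associations(data)
    Am <- as.matrix(A)
    stages <- list()
    if (is.null(precomputed)) {
        sims <- buildSimilarities(data)
        CS <- sims$cs; DS <- sims$ds
        stages$similarity <- .fingerprint(CS)
    } else {
        CS <- precomputed$cs; DS <- precomputed$ds
        stages$similarity <- "precomputed"
    }
    feats <- .stageFeatures(Am, CS, DS, mode, c, kPca)
    stages$diffusion <- if (mode == "full")
        .fingerprint(feats$crs) else "skipped"
    stages$features <- .fingerprint(feats$cf)
    net <- buildHetero(A, CS, DS, feats$cf, feats$df)
    posMask <- (Am == 1) * 1
    negPairs <- sampleNegatives(A, ratio = negRatio, seed = seed)
    negMask <- .maskFromPairs(negPairs, nrow(Am), ncol(Am))
    fit <- trainGCN(net, Am, posMask, negMask, lfn = lfn, lr = lr,
                    epochs = epochs, reg = reg, seed = seed)
    stages$scores <- .fingerprint(fit$scores)
    manifest <- list(parameters = list(mode = mode, c = c, kPca = kPca,
                                       lfn = lfn, negRatio = negRatio,
                                       lr = lr, epochs = epochs, reg = reg,
                                       seed = seed,
                                       nCirc = nrow(Am), nDis = ncol(Am)),
                     stages = stages)
    list(scores = fit$scores, params = fit$params, manifest = manifest)
}
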