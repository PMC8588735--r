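## Negative sampling, k-fold cross-validation over positive pairs, and the
## classification / ranking metric suite.

## pairs are 2-column integer matrices (circ index, disease index)
.pairsFromLinear <- function(lin, nrowA) {
    cbind(circ = ((lin - 1L) %% nrowA) + 1L,
          disease = ((lin - 1L) %/% nrowA) + 1L)
}

.linearFromPairs <- function(pairs, nrowA) {
    (pairs[, 2L] - 1L) * nrowA + pairs[, 1L]
}

#' Sample negative (unobserved) circRNA-disease pairs
#'
#' Uniform sample without replacement from the zero cells of the
#' association matrix, excluding any supplied pairs. The sample size is
#' \code{ratio} times the positive count, capped at the number of
#' available zero cells (with a warning).
#'
#' @param A \linkS4class{AssociationMatrix} (or binary matrix).
#' @param ratio negatives per positive (default 5).
#' @param seed RNG seed; \code{NULL} uses the current stream.
#' @param exclude optional 2-column index matrix of pairs to exclude.
#' @param nPositives positive count the ratio refers to; defaults to
#'   \code{sum(A)}.
#' @return 2-column integer matrix (circ, disease).
#' @export
sampleNegatives <- function(A, ratio = 5, seed = NULL, exclude = NULL,
                            nPositives = sum(as.matrix(A) == 1)) {
    Am <- as.matrix(A)
    stopifnot(ratio >= 1)
    zeros <- which(Am == 0)
    if (!is.null(exclude) && nrow(exclude) > 0)
        zeros <- setdiff(zeros, .linearFromPairs(exclude, nrow(Am)))
    if (length(zeros) == 0) stop("no zero cells available for negative sampling")
    want <- round(ratio * nPositives)
    if (want > length(zeros)) {
        warning(sprintf("only %d zero cells available (wanted %d)",
                        length(zeros), want))
        want <- length(zeros)
    }
    pick <- function() sample(zeros, want, replace = FALSE)
    lin <- if (is.null(seed)) pick() else withSeed(seed, pick())
    .pairsFromLinear(sort(lin), nrow(Am))
}

#' Split the known positives into k cross-validation folds
#'
#' Positives are shuffled and partitioned into k near-equal folds (the
#' remainder spread over the leading folds). Per fold, test negatives and
#' train negatives are sampled disjointly from the zero cells at
#' \code{ratio} negatives per positive.
#'
#' @param A \linkS4class{AssociationMatrix}.
#' @param k number of folds.
#' @param ratio negatives per positive (default 5).
#' @param seed RNG seed driving both the shuffle and the negative samples.
#' @return list of fold objects, each with \code{trainPos},
#'   \code{testPos}, \code{trainNeg}, \code{testNeg} (2-column index
#'   matrices), \code{fold} and \code{seed}.
#' @export
kfoldSplit <- function(A, k = 5L, ratio = 5, seed = 1L) {
    Am <- as.matrix(A)
    pos <- which(Am == 1)
    nPos <- length(pos)
    if (k > nPos) stop(sprintf("k = %d exceeds the %d positives", k, nPos))
    withSeed(seed, {
        pos <- sample(pos)
        sizes <- rep(nPos %/% k, k)
        rem <- nPos %% k
        if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
        bounds <- cumsum(c(0L, sizes))
        lapply(seq_len(k), function(f) {
            testLin <- pos[(bounds[f] + 1L):bounds[f + 1L]]
            trainLin <- setdiff(pos, testLin)
            nTest <- round(ratio * length(testLin))
            nTrain <- round(ratio * length(trainLin))
            zeros <- which(Am == 0)
            if (nTest + nTrain > length(zeros)) {
                warning("negative pool smaller than requested; capping")
                scale <- length(zeros) / (nTest + nTrain)
                nTest <- floor(nTest * scale)
                nTrain <- length(zeros) - nTest
            }
            negLin <- sample(zeros, nTest + nTrain, replace = FALSE)
            list(trainPos = .pairsFromLinear(sort(trainLin), nrow(Am)),
                 testPos = .pairsFromLinear(sort(testLin), nrow(Am)),
                 testNeg = .pairsFromLinear(sort(negLin[seq_len(nTest)]),
                                            nrow(Am)),
                 trainNeg = .pairsFromLinear(sort(negLin[-seq_len(nTest)]),
                                             nrow(Am)),
                 fold = f, seed = seed)
        })
    })
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the TPR/FPR curve over all score
#' thresholds; tied scores are grouped, so the value equals the
#' Mann-Whitney pairwise statistic with ties counted one half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
    stopifnot(length(scores) == length(labels))
    nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
    if (nPos == 0 || nNeg == 0) stop("both classes must be present")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; y <- labels[ord]
    grp <- cumsum(!duplicated(s))            # tied scores share a group
    tp <- c(0, cumsum(y)[cumsum(table(grp))])
    fp <- c(0, cumsum(1 - y)[cumsum(table(grp))])
    tpr <- tp / nPos; fpr <- fp / nNeg
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Area under the precision-recall curve
#'
#' Step integration \eqn{\sum_t (R_t - R_{t-1}) P_t} over grouped score
#' thresholds in decreasing order (average-precision form).
#'
#' @inheritParams rocAuc
#' @return AUPR in (0, 1].
#' @export
prAuc <- function(scores, labels) {
    stopifnot(length(scores) == length(labels))
    nPos <- sum(labels == 1)
    if (nPos == 0 || sum(labels == 0) == 0) stop("both classes must be present")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; y <- labels[ord]
    grp <- cumsum(!duplicated(s))
    cut <- cumsum(table(grp))
    tp <- cumsum(y)[cut]
    n <- cut
    precision <- tp / n
    recall <- tp / nPos
    sum(diff(c(0, recall)) * precision)
}

#' Threshold classification metrics
#'
#' Confusion counts at the decision threshold plus the derived rates:
#' TPR, FPR, F1, Matthews correlation coefficient (0 by convention when a
#' denominator factor vanishes), accuracy and recall, together with the
#' threshold-free AUC and AUPR.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @param threshold decision cut-off in (0, 1), default 0.5.
#' @return one-row data.frame with columns tp, fp, tn, fn, tpr, fpr, f1,
#'   mcc, acc, recall, auc, aupr, threshold.
#' @export
classificationMetrics <- function(scores, labels, threshold = 0.5) {
    stopifnot(length(scores) == length(labels), length(scores) > 0,
              threshold > 0, threshold < 1)
    pred <- as.integer(scores >= threshold)
    tp <- as.numeric(sum(pred == 1 & labels == 1))
    fp <- as.numeric(sum(pred == 1 & labels == 0))
    tn <- as.numeric(sum(pred == 0 & labels == 0))
    fn <- as.numeric(sum(pred == 0 & labels == 1))
    tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
    fpr <- if (fp + tn > 0) fp / (fp + tn) else 0
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
    acc <- (tp + tn) / length(labels)
    data.frame(tp = tp, fp = fp, tn = tn, fn = fn, tpr = tpr, fpr = fpr,
               f1 = f1, mcc = mcc, acc = acc, recall = tpr,
               auc = rocAuc(scores, labels), aupr = prAuc(scores, labels),
               threshold = threshold)
}

.maskFromPairs <- function(pairs, nc, nd) {
    m <- matrix(0, nc, nd)
    m[.linearFromPairs(pairs, nc)] <- 1
    m
}

#' k-fold cross-validation of the full pipeline
#'
#' For each fold the test positives are zeroed out of the association
#' matrix, the GIP kernels and fused CS/DS are rebuilt from the masked
#' matrix (no leakage; the sequence-, gene- and DAG-based pieces do not
#' depend on the associations and are cached), the selected pipeline mode
#' runs (diffusion, PCA, heterogeneous network, training), and the test
#' positives plus sampled test negatives are scored.
#'
#' @param data a \linkS4class{CircDiseaseData}.
#' @param k number of folds (default 5).
#' @param ratio negatives per positive (default 5).
#' @param c random-walk mixing coefficient (default 0.4).
#' @param kPca PCA retained fraction (default 0.3).
#' @param lfn latent factor number (default 65).
#' @param lr learning rate (default 0.01).
#' @param epochs training epochs (default 200).
#' @param reg L2 penalty coefficient (default 0.01).
#' @param seed master seed; drives the fold split, the negative samples
#'   and the per-fold parameter initialisation.
#' @param mode \code{"full"} (diffusion + PCA), \code{"no-rwr"} (PCA on
#'   the undiffused concatenation), or \code{"no-rwr-no-pca"} (raw
#'   concatenation as features).
#' @param threshold decision threshold for the count-based metrics.
#' @param precomputed optional list with \code{cs} and \code{ds}
#'   similarity matrices supplied externally (reproduction mode); when
#'   given, per-fold similarity reconstruction is skipped.
#' @param cache optional precomputed \code{\link{similarityCache}}.
#' @return list with \code{folds} (per-fold metric data.frame),
#'   \code{mean} (named numeric vector over the metric columns), and
#'   \code{config}.
#' @export
crossValidate <- function(data, k = 5L, ratio = 5, c = 0.4, kPca = 0.3,
                          lfn = 65L, lr = 0.01, epochs = 200L, reg = 1e-2,
                          seed = 1L,
                          mode = c("full", "no-rwr", "no-rwr-no-pca"),
                          threshold = 0.5, precomputed = NULL, cache = NULL) {
    mode <- match.arg(mode)
    A <- as.matrix(associations(data))
    nc <- nrow(A); nd <- ncol(A)
    if (is.null(precomputed) && is.null(cache)) cache <- similarityCache(data)
    folds <- kfoldSplit(associations(data), k = k, ratio = ratio, seed = seed)
    rows <- lapply(folds, function(fold) {
        Atrain <- A
        Atrain[.linearFromPairs(fold$testPos, nc)] <- 0
        Aobj <- AssociationMatrix(Atrain)
        if (is.null(precomputed)) {
            sims <- buildSimilarities(data, A = Aobj, cache = cache)
            CS <- sims$cs; DS <- sims$ds
        } else {
            CS <- precomputed$cs; DS <- precomputed$ds
        }
        feats <- .stageFeatures(Atrain, CS, DS, mode, c, kPca)
        net <- buildHetero(Aobj, CS, DS, feats$cf, feats$df)
        posMask <- .maskFromPairs(fold$trainPos, nc, nd)
        negMask <- .maskFromPairs(fold$trainNeg, nc, nd)
        fit <- trainGCN(net, Atrain, posMask, negMask, lfn = lfn, lr = lr,
                        epochs = epochs, reg = reg,
                        seed = seed * 131L + fold$fold)
        testPairs <- rbind(fold$testPos, fold$testNeg)
        sc <- as.matrix(fit$scores)[.linearFromPairs(testPairs, nc)]
        lab <- rep(c(1, 0), c(nrow(fold$testPos), nrow(fold$testNeg)))
        cbind(fold = fold$fold,
              classificationMetrics(sc, lab, threshold = threshold))
    })
    folds_df <- do.call(rbind, rows)
    metricCols <- setdiff(names(folds_df), "fold")
    list(folds = folds_df,
         mean = colMeans(folds_df[, metricCols, drop = FALSE]),
         config = list(k = k, ratio = ratio, c = c, kPca = kPca, lfn = lfn,
                       lr = lr, epochs = epochs, reg = reg, seed = seed,
                       mode = mode,
                       threshold = threshold,
                       precomputed = !is.null(precomputed)))
}

## features per pipeline mode; Atrain is the fold-masked plain matrix
.stageFeatures <- function(Atrain, CS, DS, mode, c, kPca) {
    if (mode == "full") {
        ## transition probabilities must be non-negative: fused similarities
        ## are floored at 0 before walk normalisation (sequence-based terms
        ## can be slightly negative)
        CRS <- rwr(pmax(as.matrix(CS), 0), c = c)
        DRS <- rwr(pmax(as.matrix(DS), 0), c = c)
        Mc <- cbind(as.matrix(CRS), Atrain)
        Md <- cbind(as.matrix(DRS), t(Atrain))
    } else {
        CRS <- DRS <- NULL
        Mc <- cbind(as.matrix(CS), Atrain)
        Md <- cbind(as.matrix(DS), t(Atrain))
    }
    if (mode == "no-rwr-no-pca") {
        list(cf = Mc, df = Md, crs = CRS, drs = DRS)
    } else {
        list(cf = pcaReduce(Mc, k = kPca), df = pcaReduce(Md, k = kPca),
             crs = CRS, drs = DRS)
    }
}
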