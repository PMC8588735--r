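## Base similarity construction: GIP kernels, gene-based similarity,
## chaos-game-representation sequence similarity, DAG semantic similarity,
## and the fusion into comprehensive CS / DS matrices.

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Computes the GIP kernel over the rows (\code{axis = "circ"}) or columns
#' (\code{axis = "disease"}) of a binary association matrix. Entry
#' \eqn{(i,j)} is \eqn{\exp(-\gamma \|IP_i - IP_j\|^2)} where the
#' bandwidth \eqn{\gamma = \gamma' / \mathrm{mean}_i \|IP_i\|^2} is
#' normalised by the mean squared profile norm.
#'
#' @param A an \linkS4class{AssociationMatrix} (or binary matrix).
#' @param axis \code{"circ"} for row profiles, \code{"disease"} for column
#'   profiles.
#' @param gammaPrime raw dimensionless bandwidth \eqn{\gamma'} (default 1).
#' @param role role tag of the result; defaults to \code{"CIS"} /
#'   \code{"DIS"} by axis.
#' @return a \linkS4class{SimilarityMatrix} with unit diagonal.
#' @examples
#' A <- AssociationMatrix(diag(2), c("c1", "c2"), c("d1", "d2"))
#' gipKernel(A, "circ")["c1", "c2"]  # exp(-2)
#' @export
gipKernel <- function(A, axis = c("circ", "disease"), gammaPrime = 1,
                      role = NULL) {
    axis <- match.arg(axis)
    stopifnot(gammaPrime > 0)
    P <- if (axis == "circ") as.matrix(A) else t(as.matrix(A))
    if (nrow(P) == 0L || ncol(P) == 0L)
        stop("empty association matrix")
    sqnorm <- rowSums(P^2)
    meanNorm <- mean(sqnorm)
    if (meanNorm == 0)
        stop(sprintf("degenerate GIP bandwidth on axis '%s': all profiles are zero",
                     axis))
    gamma <- gammaPrime / meanNorm
    ## ||p_i - p_j||^2 = |p_i|^2 + |p_j|^2 - 2 p_i . p_j
    G <- tcrossprod(P)
    d2 <- outer(sqnorm, sqnorm, "+") - 2 * G
    d2[d2 < 0] <- 0
    K <- exp(-gamma * d2)
    K <- (K + t(K)) / 2
    diag(K) <- 1
    if (is.null(role)) role <- if (axis == "circ") "CIS" else "DIS"
    SimilarityMatrix(K, role = role, ids = rownames(P))
}

#' Gene-based circRNA similarity
#'
#' Conjugates the gene GIP kernel by the circRNA-gene association matrix:
#' \eqn{CGS = A_{cg} \cdot GIS \cdot A_{cg}^T}. A circRNA with no gene
#' links gets an all-zero row and column.
#'
#' @param Acg binary circRNA x gene matrix.
#' @param GIS gene GIP kernel \linkS4class{SimilarityMatrix} (genes as
#'   profiled entities); computed from \code{Acg} when missing.
#' @return a \linkS4class{SimilarityMatrix} with role \code{"CGS"}.
#' @export
geneSimilarity <- function(Acg, GIS = NULL) {
    Acg <- as.matrix(Acg)
    if (is.null(GIS))
        GIS <- gipKernel(AssociationMatrix(Acg), axis = "disease", role = "GIS")
    if (ncol(Acg) != nrow(GIS))
        stop("gene dimension mismatch between Acg and GIS")
    CGS <- Acg %*% as.matrix(GIS) %*% t(Acg)
    CGS <- (CGS + t(CGS)) / 2
    SimilarityMatrix(CGS, role = "CGS", ids = rownames(Acg))
}

.CGR_CORNERS <- matrix(c(0, 0,   # A
                         0, 1,   # C
                         1, 1,   # G
                         1, 0),  # T / U
                       ncol = 2, byrow = TRUE,
                       dimnames = list(c("A", "C", "G", "T"), c("x", "y")))

#' Chaos game representation descriptor of a nucleotide sequence
#'
#' Maps the sequence into the unit square by iterated midpoint moves from
#' the centre (0.5, 0.5) towards the corner of each base (A lower-left,
#' C upper-left, G upper-right, T/U lower-right), bins the trajectory into
#' an 8 x 8 grid, and summarises each of the 64 cells by the triple
#' (sum of x coordinates, sum of y coordinates, z-score of the point
#' count). Ambiguous bases (anything outside ACGTU) are dropped.
#'
#' @param sequence a nucleotide string (case-insensitive; U allowed).
#' @return a list of class \code{CGRDescriptor} with elements
#'   \code{X}, \code{Y}, \code{Z} (length 64), \code{counts},
#'   \code{points} (n x 2), and \code{descriptor} (the 192-long
#'   concatenation of per-grid (X, Y, Z) triples).
#' @export
cgrDescriptor <- function(sequence) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    s <- chartr("u", "t", tolower(sequence))
    bases <- strsplit(s, "")[[1]]
    bases <- bases[bases %in% c("a", "c", "g", "t")]
    n <- length(bases)
    if (n == 0L)
        stop("sequence empty after removing ambiguous symbols")
    idx <- match(bases, c("a", "c", "g", "t"))
    cx <- .CGR_CORNERS[idx, 1]
    cy <- .CGR_CORNERS[idx, 2]
    ## x_j = (x_{j-1} + corner_x)/2  =>  x_n = sum_j corner_{x,j}/2^{n-j+1} + 0.5/2^n
    x <- numeric(n); y <- numeric(n)
    px <- 0.5; py <- 0.5
    for (j in seq_len(n)) {
        px <- (px + cx[j]) / 2
        py <- (py + cy[j]) / 2
        x[j] <- px; y[j] <- py
    }
    bx <- pmin(floor(8 * x), 7)
    by <- pmin(floor(8 * y), 7)
    cell <- bx + 8L * by + 1L   # 1..64, row-major over y
    counts <- tabulate(cell, nbins = 64L)
    X <- as.numeric(rowsum(x, cell, reorder = FALSE))
    Y <- as.numeric(rowsum(y, cell, reorder = FALSE))
    Xf <- numeric(64); Yf <- numeric(64)
    occupied <- sort(unique(cell))
    ord <- order(unique(cell))
    Xf[occupied] <- X[ord]; Yf[occupied] <- Y[ord]
    mu <- mean(counts)
    sdev <- sqrt(mean((counts - mu)^2))   # population SD over the 64 grids
    Z <- if (sdev == 0) rep(0, 64) else (counts - mu) / sdev
    desc <- as.numeric(rbind(Xf, Yf, Z))  # grid-wise (X, Y, Z) triples
    structure(list(X = Xf, Y = Yf, Z = Z, counts = counts,
                   points = cbind(x = x, y = y), descriptor = desc),
              class = "CGRDescriptor")
}

#' @export
print.CGRDescriptor <- function(x, ...) {
    cat(sprintf("CGRDescriptor: %d points over 64 grids (%d occupied)\n",
                sum(x$counts), sum(x$counts > 0)))
    invisible(x)
}

#' Pearson similarity of two CGR descriptors
#'
#' Standard Pearson correlation between the flattened 192-component
#' descriptors. A zero-variance descriptor yields 0 by convention.
#'
#' @param d1,d2 \code{CGRDescriptor} objects or numeric descriptor vectors.
#' @return correlation in [-1, 1].
#' @export
sequenceSimilarity <- function(d1, d2) {
    v1 <- if (inherits(d1, "CGRDescriptor")) d1$descriptor else as.numeric(d1)
    v2 <- if (inherits(d2, "CGRDescriptor")) d2$descriptor else as.numeric(d2)
    stopifnot(length(v1) == 192L, length(v2) == 192L)
    if (sd(v1) == 0 || sd(v2) == 0) return(0)
    unname(cor(v1, v2))
}

#' Sequence-based circRNA similarity matrix (CES)
#'
#' Builds CGR descriptors for all circRNAs with a sequence and fills the
#' pairwise Pearson similarity matrix. Pairs where either circRNA lacks a
#' sequence are 0 and flagged unavailable.
#'
#' @param sequences named character vector over all circRNA labels
#'   (NA = no sequence).
#' @return list with \code{ces} (a \linkS4class{SimilarityMatrix}, role
#'   \code{"CES"}) and \code{hasSequence} (logical per circRNA).
#' @export
sequenceSimilarityMatrix <- function(sequences) {
    ids <- names(sequences)
    stopifnot(!is.null(ids))
    has <- !is.na(sequences) & nzchar(sequences)
    n <- length(sequences)
    CES <- matrix(0, n, n, dimnames = list(ids, ids))
    if (any(has)) {
        D <- vapply(sequences[has], function(s) cgrDescriptor(s)$descriptor,
                    numeric(192))
        sds <- apply(D, 2, sd)
        ok <- sds > 0
        sub <- matrix(0, sum(has), sum(has))
        if (any(ok)) sub[ok, ok] <- cor(D[, ok, drop = FALSE])
        diag(sub) <- 1
        CES[has, has] <- sub
    }
    diag(CES) <- 1   # self-similarity, also for sequence-less circRNAs
    list(ces = SimilarityMatrix(CES, role = "CES", ids = ids),
         hasSequence = setNames(has, ids))
}

#' Contribution value of a DAG term
#'
#' \eqn{S(f) = \log(1 + m_f / m)} where \eqn{m_f} is the number of
#' diseases whose ancestor set contains term \eqn{f} and \eqn{m} the total
#' number of diseases.
#'
#' @param dag disease DAG list (\code{ancestors}, \code{universe}).
#' @param f a DAG term.
#' @param nDiseases total disease count (defaults to the number of
#'   ancestor sets).
#' @return non-negative contribution value.
#' @export
diseaseContribution <- function(dag, f, nDiseases = length(dag$ancestors)) {
    if (!f %in% dag$universe) stop(sprintf("unknown DAG term '%s'", f))
    m <- sum(vapply(dag$ancestors, function(t) f %in% t, logical(1)))
    log(1 + m / nDiseases)
}

#' DAG semantic similarity of two diseases
#'
#' Shared-ancestor contribution ratio:
#' \deqn{DSS(d_i, d_j) = \frac{\sum_{f \in T(d_i) \cap T(d_j)} (S(f) + S(f))}
#'   {\sum_{f \in T(d_i)} S(f) + \sum_{f \in T(d_j)} S(f)}}
#' bounded in [0, 1] with \eqn{DSS(d, d) = 1}.
#'
#' @param dag disease DAG list.
#' @param di,dj disease labels present in \code{dag$ancestors}.
#' @return semantic similarity in [0, 1].
#' @export
semanticSimilarity <- function(dag, di, dj) {
    Ti <- dag$ancestors[[di]]; Tj <- dag$ancestors[[dj]]
    if (is.null(Ti) || length(Ti) == 0L || is.null(Tj) || length(Tj) == 0L)
        stop(sprintf("disease without DAG membership: '%s'",
                     if (is.null(Ti) || !length(Ti)) di else dj))
    S <- setNames(vapply(union(Ti, Tj), function(f) diseaseContribution(dag, f),
                         numeric(1)), union(Ti, Tj))
    common <- intersect(Ti, Tj)
    num <- 2 * sum(S[common])
    den <- sum(S[Ti]) + sum(S[Tj])
    num / den
}

#' DAG semantic similarity matrix (DSS)
#'
#' @param dag disease DAG list.
#' @param diseaseIds ordered disease labels (the association-matrix column
#'   order).
#' @return list with \code{dss} (\linkS4class{SimilarityMatrix}, role
#'   \code{"DSS"}; rows/cols of diseases outside the DAG are 0 off-diagonal)
#'   and \code{hasDag} (logical per disease).
#' @export
semanticSimilarityMatrix <- function(dag, diseaseIds) {
    has <- vapply(diseaseIds,
                  function(d) !is.null(dag$ancestors[[d]]) &&
                      length(dag$ancestors[[d]]) > 0, logical(1))
    n <- length(diseaseIds)
    DSS <- matrix(0, n, n, dimnames = list(diseaseIds, diseaseIds))
    inDag <- which(has)
    if (length(inDag)) {
        ## precompute contributions once
        allTerms <- unique(unlist(dag$ancestors[diseaseIds[inDag]]))
        S <- setNames(vapply(allTerms,
                             function(f) diseaseContribution(dag, f),
                             numeric(1)), allTerms)
        tot <- vapply(diseaseIds[inDag],
                      function(d) sum(S[dag$ancestors[[d]]]), numeric(1))
        for (a in seq_along(inDag)) for (b in seq_len(a)) {
            i <- inDag[a]; j <- inDag[b]
            common <- intersect(dag$ancestors[[diseaseIds[i]]],
                                dag$ancestors[[diseaseIds[j]]])
            v <- 2 * sum(S[common]) / (tot[a] + tot[b])
            DSS[i, j] <- v; DSS[j, i] <- v
        }
    }
    diag(DSS) <- 1
    list(dss = SimilarityMatrix(DSS, role = "DSS", ids = diseaseIds),
         hasDag = setNames(has, diseaseIds))
}

#' Fuse circRNA similarities into the comprehensive CS
#'
#' Per-pair mean of the GIP kernel (CIS), gene-based (CGS) and
#' sequence-based (CES) similarities when both circRNAs have a sequence,
#' otherwise the mean of CIS and CGS only.
#'
#' @param CIS,CGS,CES conformable \linkS4class{SimilarityMatrix} objects.
#' @param hasSequence logical per circRNA: sequence available.
#' @return \linkS4class{SimilarityMatrix}, role \code{"CS"}.
#' @export
fuseCircSimilarity <- function(CIS, CGS, CES, hasSequence) {
    n <- nrow(CIS)
    if (nrow(CGS) != n || nrow(CES) != n || length(hasSequence) != n)
        stop("shape mismatch among CIS, CGS, CES, hasSequence")
    avail <- outer(hasSequence, hasSequence, "&")
    CS <- ifelse(avail,
                 (as.matrix(CIS) + as.matrix(CGS) + as.matrix(CES)) / 3,
                 (as.matrix(CIS) + as.matrix(CGS)) / 2)
    SimilarityMatrix(CS, role = "CS", ids = rownames(CIS))
}

#' Fuse disease similarities into the comprehensive DS
#'
#' Mean of the GIP kernel (DIS) and semantic (DSS) similarities when both
#' diseases belong to the DAG, otherwise DIS alone.
#'
#' @param DIS,DSS conformable \linkS4class{SimilarityMatrix} objects.
#' @param hasDag logical per disease: DAG membership.
#' @return \linkS4class{SimilarityMatrix}, role \code{"DS"}.
#' @export
fuseDiseaseSimilarity <- function(DIS, DSS, hasDag) {
    n <- nrow(DIS)
    if (nrow(DSS) != n || length(hasDag) != n)
        stop("shape mismatch among DIS, DSS, hasDag")
    avail <- outer(hasDag, hasDag, "&")
    DS <- ifelse(avail, (as.matrix(DIS) + as.matrix(DSS)) / 2, as.matrix(DIS))
    SimilarityMatrix(DS, role = "DS", ids = rownames(DIS))
}

#' Build the comprehensive similarity matrices for a dataset
#'
#' Convenience wrapper running the full similarity stage: CIS/DIS from the
#' (possibly masked) association matrix, CGS from the gene links, CES from
#' the sequences, DSS from the DAG, and the fusion into CS and DS.
#' The association-independent pieces (CES, CGS, DSS) can be passed in
#' precomputed, which cross-validation uses to avoid recomputing them per
#' fold (only the GIP kernels depend on the masked associations).
#'
#' @param data a \linkS4class{CircDiseaseData}.
#' @param A association matrix to use (defaults to \code{associations(data)};
#'   cross-validation passes the fold-masked copy).
#' @param cache optional list with precomputed \code{ces}, \code{hasSequence},
#'   \code{cgs}, \code{dss}, \code{hasDag}.
#' @return list with \code{cs}, \code{ds} (fused
#'   \linkS4class{SimilarityMatrix} objects) and the base matrices.
#' @export
buildSimilarities <- function(data, A = associations(data), cache = NULL) {
    CIS <- gipKernel(A, "circ")
    DIS <- gipKernel(A, "disease")
    if (is.null(cache)) cache <- similarityCache(data)
    CS <- fuseCircSimilarity(CIS, cache$cgs, cache$ces, cache$hasSequence)
    DS <- fuseDiseaseSimilarity(DIS, cache$dss, cache$hasDag)
    list(cs = CS, ds = DS, cis = CIS, dis = DIS, cgs = cache$cgs,
         ces = cache$ces, dss = cache$dss,
         hasSequence = cache$hasSequence, hasDag = cache$hasDag)
}

#' Precompute the association-independent similarity pieces
#'
#' @param data a \linkS4class{CircDiseaseData}.
#' @return list with \code{ces}, \code{hasSequence}, \code{cgs},
#'   \code{dss}, \code{hasDag}.
#' @export
similarityCache <- function(data) {
    seqres <- sequenceSimilarityMatrix(circSequences(data))
    Acg <- geneAssociations(data)
    cgs <- if (ncol(Acg) > 0 && any(Acg > 0)) {
        geneSimilarity(Acg)
    } else {
        SimilarityMatrix(matrix(0, nrow(data@assoc), nrow(data@assoc)),
                         role = "CGS", ids = rownames(data@assoc))
    }
    dssres <- semanticSimilarityMatrix(diseaseDag(data), colnames(data@assoc))
    list(ces = seqres$ces, hasSequence = seqres$hasSequence, cgs = cgs,
         dss = dssres$dss, hasDag = dssres$hasDag)
}
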