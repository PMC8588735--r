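## Feature extraction: diffused-similarity/adjacency concatenation, PCA,
## and assembly of the heterogeneous network.

#' Concatenate a diffused similarity with the adjacency matrix
#'
#' circRNA side: \code{[CRS | A]} (n_c x (n_c + n_d)); disease side:
#' \code{[DRS | t(A)]} (n_d x (n_d + n_c)).
#'
#' @param diffused square \linkS4class{DiffusedMatrix} (or matrix) for the
#'   chosen side.
#' @param A \linkS4class{AssociationMatrix}.
#' @param side \code{"circ"} or \code{"disease"}.
#' @return plain matrix with the diffused block left and the adjacency
#'   block right.
#' @export
concatWithAdjacency <- function(diffused, A, side = c("circ", "disease")) {
    side <- match.arg(side)
    Dm <- as.matrix(diffused)
    Am <- if (side == "circ") as.matrix(A) else t(as.matrix(A))
    if (nrow(Dm) != nrow(Am) || nrow(Dm) != ncol(Dm))
        stop("shape mismatch between diffused matrix and adjacency")
    cbind(Dm, Am)
}

#' PCA feature extraction
#'
#' Centres the columns of \code{M} and projects onto the top
#' \eqn{\max(1, \lceil k \cdot n_{cols} \rceil)} principal directions
#' (capped at the number of computable components,
#' \eqn{\min(n_{rows}, n_{cols})}), ordered by decreasing variance.
#' Computed by SVD with a deterministic sign convention: in each loading
#' vector the entry of largest magnitude is positive.
#'
#' @param M numeric matrix, rows = entities, columns = raw features.
#' @param k retained-component fraction in (0, 1]; default 0.3.
#' @return a \linkS4class{FeatureMatrix}: the projected scores, with the
#'   loadings in \code{@components} and per-component variances in
#'   \code{@explainedVariance}.
#' @export
pcaReduce <- function(M, k = 0.3) {
    M <- as.matrix(M)
    stopifnot(k > 0, k <= 1)
    if (nrow(M) < 2) stop("PCA needs at least 2 rows")
    keep <- max(1L, ceiling(k * ncol(M)))
    keep <- min(keep, nrow(M), ncol(M))
    mu <- colMeans(M)
    X <- sweep(M, 2, mu)
    sv <- svd(X, nu = 0, nv = keep)
    V <- sv$v
    ## sign convention: largest-|loading| entry positive
    for (j in seq_len(ncol(V))) {
        i <- which.max(abs(V[, j]))
        if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    Y <- X %*% V
    rownames(Y) <- rownames(M)
    colnames(Y) <- paste0("PC", seq_len(ncol(Y)))
    ev <- (sv$d[seq_len(keep)]^2) / (nrow(M) - 1)
    new("FeatureMatrix", Y, components = V, explainedVariance = ev,
        center = mu)
}

#' Assemble the heterogeneous network
#'
#' \deqn{A_{cd} = \begin{pmatrix} CS & A \\ A^T & DS \end{pmatrix}, \qquad
#'       CD = \begin{pmatrix} CF & 0 \\ 0 & DF \end{pmatrix}}
#' with node degrees the row sums of \eqn{A_{cd}}.
#'
#' @param A \linkS4class{AssociationMatrix}.
#' @param CS,DS comprehensive similarity matrices.
#' @param CF,DF feature matrices (circRNA and disease side).
#' @return a \linkS4class{HeteroNetwork}.
#' @export
buildHetero <- function(A, CS, DS, CF, DF) {
    Am <- as.matrix(A); CSm <- as.matrix(CS); DSm <- as.matrix(DS)
    CFm <- as.matrix(CF); DFm <- as.matrix(DF)
    nc <- nrow(Am); nd <- ncol(Am)
    if (nrow(CSm) != nc || nrow(DSm) != nd || nrow(CFm) != nc ||
        nrow(DFm) != nd)
        stop("block shape mismatch")
    Acd <- rbind(cbind(CSm, Am), cbind(t(Am), DSm))
    CD <- rbind(cbind(CFm, matrix(0, nc, ncol(DFm))),
                cbind(matrix(0, nd, ncol(CFm)), DFm))
    nodes <- c(rownames(Am), colnames(Am))
    dimnames(Acd) <- list(nodes, nodes)
    rownames(CD) <- nodes
    colnames(CD) <- c(paste0("c.", seq_len(ncol(CFm))),
                      paste0("d.", seq_len(ncol(DFm))))
    deg <- rowSums(Acd)
    new("HeteroNetwork", adjacency = Acd, features = CD,
        degrees = unname(deg), nCirc = as.integer(nc), nDis = as.integer(nd))
}

#' Recover the four blocks of a heterogeneous adjacency
#'
#' Exact inverse of the block assembly in \code{\link{buildHetero}}.
#'
#' @param net a \linkS4class{HeteroNetwork}.
#' @return list with \code{cs}, \code{a}, \code{ds} matrices.
#' @export
heteroBlocks <- function(net) {
    nc <- net@nCirc; nd <- net@nDis
    Acd <- net@adjacency
    list(cs = Acd[seq_len(nc), seq_len(nc), drop = FALSE],
         a = Acd[seq_len(nc), nc + seq_len(nd), drop = FALSE],
         ds = Acd[nc + seq_len(nd), nc + seq_len(nd), drop = FALSE])
}
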