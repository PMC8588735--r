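## Random walk with restart (RWR) over a similarity network.

#' Column-normalise a similarity matrix into a transfer matrix
#'
#' Divides each column by its sum so every non-zero column of the returned
#' matrix sums to 1; all-zero columns are left zero with a warning (an
#' isolated node receives no walk mass).
#'
#' @param S non-negative square matrix (a \linkS4class{SimilarityMatrix}
#'   or plain matrix).
#' @return column-stochastic matrix of the same shape.
#' @export
normalizeTransfer <- function(S) {
    W <- as.matrix(S)
    if (nrow(W) != ncol(W)) stop("transfer matrix must be square")
    if (min(W) < 0) stop("negative entries in similarity matrix")
    cs <- colSums(W)
    zero <- cs == 0
    if (any(zero)) {
        warning(sprintf("%d all-zero column(s) left unnormalised", sum(zero)))
        cs[zero] <- 1
    }
    sweep(W, 2, cs, "/")
}

#' Random walk with restart over a similarity network
#'
#' For every basis seed \eqn{e_l}, iterates the fixed point
#' \deqn{r \leftarrow c \tilde{W} r + (1 - c) e_l}
#' from \eqn{r^0 = e_l} until the sup-norm update falls below \code{tol},
#' where \eqn{\tilde{W}} is the column-normalised transfer matrix. For
#' \eqn{c < 1} this converges to the linear-system solution
#' \eqn{(I - c\tilde{W})^{-1} (1-c) e_l}. Walk coefficient \code{c}
#' multiplies the propagation term exactly as in the update rule; the
#' complementary weight \code{1 - c} restarts at the seed.
#'
#' @param S non-negative square \linkS4class{SimilarityMatrix} (or matrix).
#' @param c walk/restart mixing coefficient in [0, 1]; default 0.4.
#' @param tol convergence tolerance on successive iterates (default 1e-6).
#' @param maxIter iteration cap (default 1000); seeds hitting the cap are
#'   flagged, not an error.
#' @param method \code{"iterative"} (default) or \code{"solve"} for the
#'   direct linear-system solution (c < 1 only).
#' @return a \linkS4class{DiffusedMatrix} whose row \eqn{l} is the
#'   converged vector for seed \eqn{l}.
#' @examples
#' S <- SimilarityMatrix(matrix(c(1, .5, .5, 1), 2), "CS", c("a", "b"))
#' rwr(S, c = 0.4)
#' @export
rwr <- function(S, c = 0.4, tol = 1e-6, maxIter = 1000L,
                method = c("iterative", "solve")) {
    method <- match.arg(method)
    stopifnot(c >= 0, c <= 1, tol > 0, maxIter >= 1)
    W <- normalizeTransfer(S)
    n <- nrow(W)
    ids <- rownames(as.matrix(S))
    if (method == "solve") {
        if (c >= 1) stop("direct solve requires c < 1")
        R <- solve(diag(n) - c * W, (1 - c) * diag(n))
        out <- t(R)
        dimnames(out) <- list(ids, ids)
        return(new("DiffusedMatrix", out,
                   iterations = rep(1L, n),
                   residuals = rep(0, n),
                   converged = rep(TRUE, n)))
    }
    ## iterate all seeds at once; columns of R are the r_l
    R <- diag(n)
    E <- (1 - c) * diag(n)
    iters <- integer(n)
    resid <- rep(Inf, n)
    active <- rep(TRUE, n)
    for (it in seq_len(maxIter)) {
        Rnew <- c * (W %*% R) + E
        delta <- apply(abs(Rnew - R), 2, max)
        R <- Rnew
        newly <- active & delta <= tol
        iters[newly] <- it
        resid[active] <- delta[active]
        active[newly] <- FALSE
        if (!any(active)) break
    }
    iters[active] <- as.integer(maxIter)
    out <- t(R)
    dimnames(out) <- list(ids, ids)
    new("DiffusedMatrix", out, iterations = iters, residuals = resid,
        converged = !active)
}
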