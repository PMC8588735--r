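test_that("Glorot initialisation is bounded, seeded, and centred", {
    W <- glorotInit(2, 2, seed = 1)
    expect_true(all(abs(W) <= sqrt(6 / 4)))
    expect_identical(glorotInit(7, 3, seed = 42), glorotInit(7, 3, seed = 42))
    # 10^4 draws: empirical mean within 3 standard errors of 0
    W2 <- glorotInit(100, 100, seed = 3)
    lim <- sqrt(6 / 200)
    se <- (lim / sqrt(3)) / 100
    expect_lt(abs(mean(W2)), 3 * se)
})

# minimal hetero network with explicit blocks, for hand-checkable forwards
mkNet <- function(Acd, CD, nc, nd) {
    new("HeteroNetwork", adjacency = Acd, features = CD,
        degrees = unname(rowSums(Acd)), nCirc = as.integer(nc),
        nDis = as.integer(nd))
}

test_that("encoder forward matches hand evaluation and a loop oracle", {
    # diagonal adjacency: D = I, propagation = 2I, identity features/weights
    net <- mkNet(diag(2), diag(2), 1, 1)
    params <- new("GCNParams", We = diag(2), Wd = diag(2),
                  B = matrix(0, 2, 2), lfn = 2L)
    expect_equal(gcnForward(net, params), 2 * diag(2))

    # a large negative bias floors everything at zero
    paramsNeg <- new("GCNParams", We = diag(2), Wd = diag(2),
                     B = matrix(-100, 2, 2), lfn = 2L)
    expect_true(all(gcnForward(net, paramsNeg) == 0))

    # random small network against an explicit elementwise evaluation
    circGCN:::withSeed(31, {
        nc <- 3L; nd <- 2L; n <- nc + nd; p <- 4L; lfn <- 3L
        Acd <- matrix(runif(n * n, 0.05, 1), n); Acd <- (Acd + t(Acd)) / 2
        CD <- matrix(rnorm(n * p), n, p)
        We <- matrix(rnorm(p * lfn) / 2, p, lfn)
        B <- matrix(rnorm(n * lfn) / 2, n, lfn)
        net2 <- mkNet(Acd, CD, nc, nd)
        params2 <- new("GCNParams", We = We, Wd = diag(lfn), B = B,
                       lfn = lfn)
        D <- rowSums(Acd)
        P <- matrix(0, n, n)
        for (i in 1:n) for (j in 1:n) {
            P[i, j] <- Acd[i, j] / sqrt(D[i] * D[j])
            if (i == j) P[i, j] <- P[i, j] + 1
        }
        U <- matrix(0, n, lfn)
        for (i in 1:n) for (l in 1:lfn) {
            acc <- 0
            for (j in 1:n) for (q in 1:p)
                acc <- acc + P[i, j] * CD[j, q] * We[q, l]
            U[i, l] <- acc + B[i, l]
        }
        expect_equal(gcnForward(net2, params2), pmax(U, 0),
                     tolerance = 1e-12)
    })
})

test_that("bilinear decoder produces sigmoid scores with a loop oracle", {
    H <- circGCN:::withSeed(12, matrix(rnorm(15), 5, 3))
    # zero decoder weight: everything scores 0.5
    expect_true(all(decodeScores(H, matrix(0, 3, 3), 2) == 0.5))

    Wd <- circGCN:::withSeed(14, matrix(rnorm(9) / 3, 3, 3))
    M <- decodeScores(H, Wd, 2)
    expect_equal(dim(M), c(2, 3))
    expect_true(all(M > 0 & M < 1))
    want <- matrix(0, 2, 3)
    for (i in 1:2) for (j in 1:3) {
        z <- 0
        for (a in 1:3) for (b in 1:3)
            z <- z + H[i, a] * Wd[a, b] * H[2 + j, b]
        want[i, j] <- 1 / (1 + exp(-z))
    }
    expect_equal(M, want, tolerance = 1e-12)
})

test_that("objective value follows the masked RMSE definition", {
    A <- matrix(c(1, 0, 0, 1), 2)
    # perfect reconstruction on the masked entries, no parameters
    expect_equal(gcnLoss(A, A, matrix(1, 2, 2), matrix(0, 2, 2)), 0)
    # single masked entry with residual 0.5 -> sqrt(0.25 / 1)
    Mp <- A; Mp[1, 1] <- 0.5
    mask1 <- matrix(0, 2, 2); mask1[1, 1] <- 1
    expect_equal(gcnLoss(Mp, A, mask1, matrix(0, 2, 2)), 0.5)
    expect_error(gcnLoss(A, A, matrix(0, 2, 2), matrix(0, 2, 2)), "empty")
    expect_error(gcnLoss(A, A, matrix(1, 2, 2), matrix(1, 2, 2)), "overlap")
})

test_that("analytic gradients match central finite differences", {
    circGCN:::withSeed(23, {
        nc <- 3L; nd <- 2L; n <- 5L; p <- 3L; lfn <- 2L
        Acd <- matrix(runif(25, 0.1, 1), 5); Acd <- (Acd + t(Acd)) / 2
        CD <- matrix(rnorm(n * p), n, p)
        net <- mkNet(Acd, CD, nc, nd)
        A <- matrix(rbinom(6, 1, 0.5), nc, nd)
        mask <- matrix(1, nc, nd)
        params <- new("GCNParams",
                      We = glorotInit(p, lfn), Wd = glorotInit(lfn, lfn),
                      B = glorotInit(n, lfn), lfn = lfn)
        Fm <- circGCN:::.propagation(net) %*% CD
        reg <- 0.01
        g <- circGCN:::.gcnGrad(Fm, params, A, mask, nc, reg = reg)
        lossAt <- function(prm) circGCN:::.gcnGrad(Fm, prm, A, mask, nc,
                                                   reg = reg)$loss
        h <- 1e-6
        for (nm in c("We", "Wd", "B")) {
            analytic <- g[[paste0("g", nm)]]
            M <- slot(params, nm)
            idx <- cbind(sample(nrow(M), 6, replace = TRUE),
                         sample(ncol(M), 6, replace = TRUE))
            for (r in seq_len(nrow(idx))) {
                i <- idx[r, 1]; j <- idx[r, 2]
                pp <- params; mm <- slot(pp, nm); mm[i, j] <- mm[i, j] + h
                slot(pp, nm) <- mm; up <- lossAt(pp)
                pm <- params; md <- slot(pm, nm); md[i, j] <- md[i, j] - h
                slot(pm, nm) <- md; dn <- lossAt(pm)
                fd <- (up - dn) / (2 * h)
                expect_equal(analytic[i, j], fd, tolerance = 1e-4)
            }
        }
    })
})

test_that("training descends, is seed-deterministic, and fits all-negative labels", {
    d <- smallDataset(seed = 3)
    A <- as.matrix(associations(d))
    sims <- buildSimilarities(d)
    feats <- circGCN:::.stageFeatures(A, sims$cs, sims$ds, "full", 0.4, 0.3)
    net <- buildHetero(associations(d), sims$cs, sims$ds, feats$cf, feats$df)
    posMask <- (A == 1) * 1
    negMask <- circGCN:::.maskFromPairs(
        sampleNegatives(associations(d), ratio = 2, seed = 9), nrow(A), ncol(A))
    fit <- trainGCN(net, A, posMask, negMask, lfn = 16, epochs = 60, seed = 4)
    tr <- lossTrace(fit$scores)
    expect_lt(tr[length(tr)], tr[1])
    # same seed, same everything
    fit2 <- trainGCN(net, A, posMask, negMask, lfn = 16, epochs = 60, seed = 4)
    expect_identical(as.matrix(fit$scores), as.matrix(fit2$scores))

    # all-negative supervision pushes the mean score below 0.5
    A0 <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
    m1 <- circGCN:::.maskFromPairs(cbind(1:10, rep(1:2, 5)), nrow(A), ncol(A))
    m2 <- circGCN:::.maskFromPairs(cbind(11:20, rep(3:4, 5)), nrow(A), ncol(A))
    fit0 <- trainGCN(net, A0, m1, m2, lfn = 16, epochs = 80, seed = 4)
    expect_lt(mean(as.matrix(fit0$scores)), 0.5)
})

test_that("forward and decoder are equivariant under consistent node permutation", {
    circGCN:::withSeed(41, {
        nc <- 4L; nd <- 3L; n <- 7L; p <- 3L; lfn <- 2L
        Acd <- matrix(runif(n * n, 0.1, 1), n); Acd <- (Acd + t(Acd)) / 2
        CD <- matrix(rnorm(n * p), n, p)
        params <- new("GCNParams", We = glorotInit(p, lfn, 1),
                      Wd = glorotInit(lfn, lfn, 2),
                      B = glorotInit(n, lfn, 3), lfn = lfn)
        H <- gcnForward(mkNet(Acd, CD, nc, nd), params)
        M <- decodeScores(H, params@Wd, nc)
        pc <- sample(nc); pd <- sample(nd)
        permN <- c(pc, nc + pd)
        paramsP <- new("GCNParams", We = params@We, Wd = params@Wd,
                       B = params@B[permN, , drop = FALSE], lfn = lfn)
        Hp <- gcnForward(mkNet(Acd[permN, permN], CD[permN, , drop = FALSE],
                               nc, nd), paramsP)
        Mp <- decodeScores(Hp, paramsP@Wd, nc)
        expect_equal(Hp, H[permN, ], tolerance = 1e-12)
        expect_equal(Mp, M[pc, pd], tolerance = 1e-12)
    })
})
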