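test_that("GIP kernel matches hand evaluation and brute-force oracle", {
    A <- AssociationMatrix(diag(2), c("c1", "c2"), c("d1", "d2"))
    CIS <- gipKernel(A, "circ")
    # profiles (1,0), (0,1): squared norms 1,1 -> gamma = 1; distance^2 = 2
    expect_equal(CIS["c1", "c2"], exp(-2), tolerance = 1e-12)
    expect_equal(diag(as.matrix(CIS)), c(c1 = 1, c2 = 1))

    # identical profiles give similarity 1
    B <- AssociationMatrix(rbind(c(1, 0, 1), c(1, 0, 1), c(0, 1, 0)),
                           paste0("c", 1:3), paste0("d", 1:3))
    expect_equal(as.matrix(gipKernel(B, "circ"))[1, 2], 1)

    A6 <- randomAssoc(6, 4, p = 0.4, seed = 7)
    expect_equal(unname(as.matrix(gipKernel(A6, "circ"))),
                 bruteGip(as.matrix(A6)), tolerance = 1e-12)
    expect_equal(unname(as.matrix(gipKernel(A6, "disease"))),
                 bruteGip(t(as.matrix(A6))), tolerance = 1e-12)
})

test_that("GIP kernel rejects an all-zero matrix, naming the axis", {
    A0 <- AssociationMatrix(matrix(0, 2, 2), c("c1", "c2"), c("d1", "d2"))
    expect_error(gipKernel(A0, "circ"), "circ")
    expect_error(gipKernel(A0, "disease"), "disease")
})

test_that("gene-based similarity is the GIS conjugation", {
    # identity gene links: CGS reduces to GIS
    Acg <- diag(3); dimnames(Acg) <- list(paste0("c", 1:3), paste0("g", 1:3))
    GIS <- gipKernel(AssociationMatrix(Acg), "disease", role = "GIS")
    CGS <- geneSimilarity(Acg, GIS)
    expect_equal(unname(as.matrix(CGS)), unname(as.matrix(GIS)))

    # circRNA with no gene links has an all-zero row and column
    Acg2 <- rbind(c(1, 1, 0), c(0, 0, 0), c(0, 1, 1))
    dimnames(Acg2) <- list(paste0("c", 1:3), paste0("g", 1:3))
    CGS2 <- as.matrix(geneSimilarity(Acg2))
    expect_true(all(CGS2[2, ] == 0) && all(CGS2[, 2] == 0))

    # triple-loop matrix product oracle on a random 5x3 case
    Acg3 <- circGCN:::withSeed(3, matrix(rbinom(15, 1, 0.5), 5, 3))
    dimnames(Acg3) <- list(paste0("c", 1:5), paste0("g", 1:3))
    GIS3 <- as.matrix(gipKernel(AssociationMatrix(Acg3), "disease",
                                role = "GIS"))
    want <- matrix(0, 5, 5)
    for (i in 1:5) for (j in 1:5) for (a in 1:3) for (b in 1:3)
        want[i, j] <- want[i, j] + Acg3[i, a] * GIS3[a, b] * Acg3[j, b]
    expect_equal(unname(as.matrix(geneSimilarity(Acg3))), want,
                 tolerance = 1e-12)
})

test_that("CGR descriptor conserves counts and stays in the seed corner", {
    d <- cgrDescriptor("AAAA")
    expect_equal(sum(d$counts), 4)
    # A is the (0,0) corner: repeated contraction keeps x,y < 0.5
    expect_true(all(d$points[, "x"] < 0.5) && all(d$points[, "y"] < 0.5))

    # count conservation over random sequences (ambiguous symbols dropped)
    circGCN:::withSeed(11, {
        for (i in 1:100) {
            len <- sample(5:120, 1)
            s <- paste(sample(c("A", "C", "G", "T", "N", "U"), len,
                              replace = TRUE), collapse = "")
            eff <- sum(strsplit(chartr("U", "T", s), "")[[1]] %in%
                           c("A", "C", "G", "T"))
            if (eff == 0) next
            expect_equal(sum(cgrDescriptor(s)$counts), eff)
        }
    })
})

test_that("CGR z-scores follow the population-SD formula", {
    s <- circGCN:::withSeed(5, paste(sample(c("A", "C", "G", "T"), 200,
                                            replace = TRUE), collapse = ""))
    d <- cgrDescriptor(s)
    mu <- mean(d$counts)
    sdev <- sqrt(sum((d$counts - mu)^2) / 64)
    expect_equal(d$Z, (d$counts - mu) / sdev, tolerance = 1e-12)
    expect_equal(sum(d$Z), 0, tolerance = 1e-8)
    expect_true(all(d$X >= 0) && all(d$Y >= 0))
    expect_length(d$descriptor, 192)
})

test_that("sequence similarity is standard Pearson with a zero-variance convention", {
    s1 <- circGCN:::withSeed(9, paste(sample(c("A", "C", "G", "T"), 300,
                                             replace = TRUE), collapse = ""))
    s2 <- circGCN:::withSeed(10, paste(sample(c("A", "C", "G", "T"), 300,
                                              replace = TRUE), collapse = ""))
    d1 <- cgrDescriptor(s1); d2 <- cgrDescriptor(s2)
    expect_equal(sequenceSimilarity(d1, d1), 1)
    # affine transform with positive slope preserves Pearson
    expect_equal(sequenceSimilarity(d1$descriptor, 2 + 3 * d1$descriptor), 1)
    # independent textbook cov/(sd1*sd2) computation
    v1 <- d1$descriptor; v2 <- d2$descriptor
    want <- sum((v1 - mean(v1)) * (v2 - mean(v2))) /
        (sqrt(sum((v1 - mean(v1))^2)) * sqrt(sum((v2 - mean(v2))^2)))
    expect_equal(sequenceSimilarity(d1, d2), want, tolerance = 1e-12)
    expect_equal(sequenceSimilarity(d1, d2), sequenceSimilarity(d2, d1))
    # zero-variance descriptor -> 0 by convention
    expect_equal(sequenceSimilarity(rep(1, 192), v1), 0)
})

test_that("disease contribution values follow the log inclusion ratio", {
    dag <- list(ancestors = list(d1 = c("d1", "root"), d2 = c("d2", "root"),
                                 d3 = c("d3", "x", "root"),
                                 d4 = c("d4", "x", "root"),
                                 d5 = c("d5", "root")),
                universe = c("root", "x", "orphan",
                             paste0("d", 1:5)))
    expect_equal(diseaseContribution(dag, "root"), log(2))      # in all 5
    expect_equal(diseaseContribution(dag, "orphan"), 0)         # in none
    expect_equal(diseaseContribution(dag, "x"), log(1.4))       # in 2 of 5
    expect_error(diseaseContribution(dag, "nope"), "unknown")
})

test_that("semantic similarity matches a hand-expanded toy DAG", {
    # root r with two leaf diseases: T(d1)={d1,r}, T(d2)={d2,r}
    dag <- list(ancestors = list(d1 = c("d1", "r"), d2 = c("d2", "r")),
                universe = c("r", "d1", "d2"))
    expect_equal(semanticSimilarity(dag, "d1", "d1"), 1)
    # S(r)=log(2), S(d1)=S(d2)=log(1.5); common = {r}
    want <- 2 * log(2) / (2 * (log(2) + log(1.5)))
    expect_equal(semanticSimilarity(dag, "d1", "d2"), want, tolerance = 1e-12)

    # disjoint ancestor sets give 0
    dag2 <- list(ancestors = list(a = c("a", "p"), b = c("b", "q")),
                 universe = c("p", "q", "a", "b"))
    expect_equal(semanticSimilarity(dag2, "a", "b"), 0)
    expect_error(semanticSimilarity(dag2, "a", "missing"), "DAG")
})

test_that("semantic similarity matrix is bounded with unit diagonal on generated DAGs", {
    for (s in 1:3) {
        d <- smallDataset(seed = s)
        res <- semanticSimilarityMatrix(diseaseDag(d),
                                        colnames(associations(d)))
        M <- as.matrix(res$dss)
        expect_true(all(M >= 0 - 1e-12) && all(M <= 1 + 1e-12))
        expect_equal(unname(diag(M)), rep(1, ncol(M)))
        expect_equal(M, t(M))
    }
})

test_that("similarity fusion applies the availability branches", {
    mk <- function(v) SimilarityMatrix(matrix(c(1, v, v, 1), 2), "CES",
                                       c("a", "b"))
    CIS <- SimilarityMatrix(matrix(c(1, .3, .3, 1), 2), "CIS", c("a", "b"))
    CGS <- SimilarityMatrix(matrix(c(1, .6, .6, 1), 2), "CGS", c("a", "b"))
    CES <- mk(.9)
    # both sequences present: mean of the three
    cs <- fuseCircSimilarity(CIS, CGS, CES, c(a = TRUE, b = TRUE))
    expect_equal(as.matrix(cs)["a", "b"], 0.6)
    # sequence term unavailable: mean of CIS and CGS
    cs2 <- fuseCircSimilarity(CIS, CGS, CES, c(a = TRUE, b = FALSE))
    expect_equal(as.matrix(cs2)["a", "b"], 0.45)
    # all three equal s stays s
    cs3 <- fuseCircSimilarity(mk(.5), mk(.5), mk(.5), c(a = TRUE, b = TRUE))
    expect_equal(as.matrix(cs3)["a", "b"], 0.5)

    DIS <- SimilarityMatrix(matrix(c(1, .4, .4, 1), 2), "DIS", c("x", "y"))
    DSS <- SimilarityMatrix(matrix(c(1, .8, .8, 1), 2), "DSS", c("x", "y"))
    ds <- fuseDiseaseSimilarity(DIS, DSS, c(x = TRUE, y = TRUE))
    expect_equal(as.matrix(ds)["x", "y"], 0.6)
    ds2 <- fuseDiseaseSimilarity(DIS, DSS, c(x = TRUE, y = FALSE))
    expect_equal(as.matrix(ds2)["x", "y"], 0.4)
    ds3 <- fuseDiseaseSimilarity(DIS, DIS, c(x = TRUE, y = TRUE))
    expect_equal(as.matrix(ds3), as.matrix(DIS))
})

test_that("fusion commutes with node relabelling", {
    n <- 5
    rnd <- function(s) circGCN:::withSeed(s, {
        m <- matrix(runif(n * n, 0, 1), n); m <- (m + t(m)) / 2
        diag(m) <- 1; m
    })
    ids <- paste0("c", 1:n)
    CIS <- SimilarityMatrix(rnd(1), "CIS", ids)
    CGS <- SimilarityMatrix(rnd(2), "CGS", ids)
    CES <- SimilarityMatrix(rnd(3), "CES", ids)
    has <- setNames(c(TRUE, FALSE, TRUE, TRUE, FALSE), ids)
    perm <- c(3, 1, 5, 2, 4)
    fuseThenPerm <- as.matrix(fuseCircSimilarity(CIS, CGS, CES, has))[perm, perm]
    permThenFuse <- as.matrix(fuseCircSimilarity(
        SimilarityMatrix(as.matrix(CIS)[perm, perm], "CIS", ids[perm]),
        SimilarityMatrix(as.matrix(CGS)[perm, perm], "CGS", ids[perm]),
        SimilarityMatrix(as.matrix(CES)[perm, perm], "CES", ids[perm]),
        has[perm]))
    expect_equal(unname(fuseThenPerm), unname(permThenFuse))
})

test_that("every constructed similarity matrix is symmetric with a valid diagonal", {
    d <- smallDataset(seed = 2)
    sims <- buildSimilarities(d)
    for (nm in c("cs", "ds", "cis", "dis", "cgs", "ces", "dss")) {
        M <- as.matrix(sims[[nm]])
        expect_lt(max(abs(M - t(M))), 1e-10)
    }
    expect_equal(unname(diag(as.matrix(sims$cis))), rep(1, nrow(sims$cis)))
    expect_equal(unname(diag(as.matrix(sims$dis))), rep(1, nrow(sims$dis)))
})
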