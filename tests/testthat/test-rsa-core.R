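test_that("similarity vectors have triangle length and clipped extremes", {
  withr::with_seed(1, {
    pat <- matrix(rnorm(20 * 30), 20)
    sv <- similarity_vector(pat)
    expect_length(sv, 190)
    expect_true(all(is.finite(sv)))

    # duplicated scenario pattern -> its pair entry is the clipped maximum
    pat2 <- rbind(pat[1, ], pat)[1:20, ]
    sv2 <- similarity_vector(pat2)
    expect_equal(max(sv2), atanh(1 - 1e-7))

    # degenerate constant scenario is rejected
    pat3 <- pat; pat3[4, ] <- 2
    expect_error(similarity_vector(pat3), "zero-variance")
    expect_error(similarity_vector(pat[1:2, ]), "at least 3")
  })
})

test_that("similarity vector matches a direct covariance-formula oracle", {
  withr::with_seed(7, {
    pat <- matrix(rnorm(4 * 6), 4)
    sv <- similarity_vector(pat)
    # brute-force pairwise Pearson, column-major lower-triangle traversal
    oracle <- c()
    for (j in 1:3) for (i in (j + 1):4) {
      x <- pat[i, ]; y <- pat[j, ]
      r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      oracle <- c(oracle, atanh(r))
    }
    expect_equal(as.numeric(sv), oracle, tolerance = 1e-12)
  })
})

test_that("similarity vector is invariant to per-scenario affine rescaling", {
  withr::with_seed(2, {
    pat <- matrix(rnorm(8 * 12), 8)
    scaled <- diag(runif(8, 0.5, 3)) %*% pat + matrix(rnorm(8), 8, 12)
    expect_equal(as.numeric(similarity_vector(pat)),
                 as.numeric(similarity_vector(scaled)), tolerance = 1e-10)
  })
})

test_that("multimodal fusion z-scores then sums", {
  withr::with_seed(3, {
    v <- rnorm(15)  # C(6,2) entries
    a <- rnorm(15)
    fused <- fuse_multimodal(v, a)
    # hand-computed population z-scores and sum
    zs <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
    expect_equal(as.numeric(fused), zs(v) + zs(a), tolerance = 1e-12)
    expect_lt(abs(mean(fused)), 1e-10)

    # duplicated channel: twice the z-scored input, same rank order
    dup <- fuse_multimodal(v, v)
    expect_equal(as.numeric(dup), 2 * zs(v), tolerance = 1e-12)
    expect_equal(rank(dup), rank(v))
    expect_error(fuse_multimodal(v, a[-1]), "length")
  })
})

test_that("leave-one-out group averaging works in both spaces", {
  sims <- random_sims(5, s = 3, seed = 4)  # length-3 vectors
  g <- group_average_loo(sims, exclude = 2)
  hand <- (sims[[1]][1:3] + sims[[3]][1:3] + sims[[4]][1:3] +
             sims[[5]][1:3]) / 4
  expect_equal(as.numeric(g), hand, tolerance = 1e-12)

  # n = 2: excluding one returns the other exactly
  expect_equal(as.numeric(group_average_loo(sims[1:2], exclude = 1)),
               as.numeric(sims[[2]]))

  # identical participants: G-1 equals any individual vector
  same <- rep(sims[1], 4)
  expect_equal(as.numeric(group_average_loo(same, exclude = 3)),
               as.numeric(sims[[1]]))

  # feature space: average the matrices first, then correlate
  withr::with_seed(5, {
    feats <- lapply(1:4, function(i) matrix(rnorm(5 * 6), 5))
    gf <- group_average_loo(pattern_sims(4, 5, 6), exclude = 1,
                            space = "feature", features = feats)
    manual <- similarity_vector((feats[[2]] + feats[[3]] + feats[[4]]) / 3)
    expect_equal(as.numeric(gf), as.numeric(manual), tolerance = 1e-12)
  })
  expect_error(group_average_loo(sims[1], exclude = 1), "at least 2")
})

test_that("Spearman RSA handles monotone transforms, symmetry and ties", {
  withr::with_seed(6, {
    a <- rnorm(20)
    expect_equal(rsa_spearman(a, exp(a)), 1)
    expect_equal(rsa_spearman(a, -a^3), -1)
    b <- rnorm(20)
    expect_equal(rsa_spearman(a, b), rsa_spearman(b, a))
    # invariance under a common monotone transform
    expect_equal(rsa_spearman(a, b), rsa_spearman(exp(a), b), tolerance = 1e-12)

    # ties: compare against independent rank-then-Pearson
    x <- c(1, 2, 2, 5, 7, 7, 8, 3)
    y <- c(4, 4, 1, 2, 9, 6, 6, 5)
    expect_equal(rsa_spearman(x, y), spearman_oracle(x, y), tolerance = 1e-12)
    expect_error(rsa_spearman(rep(1, 8), y), "constant")
  })
})

test_that("row/column-shuffle permutation test separates match from null", {
  withr::with_seed(8, {
    pat <- matrix(rnorm(20 * 40), 20)
    cm <- cor(t(pat))
    model <- similarity_vector(pat)  # model identical to fMRI structure
    res <- rsa_permutation_test(cm, model, n_perm = 1000, seed = 11)
    expect_lte(res$p_perm, 0.01)
    expect_gte(res$p_perm, 0)
    expect_equal(res$rho, 1, tolerance = 1e-9)

    # determinism under a fixed seed
    res2 <- rsa_permutation_test(cm, model, n_perm = 1000, seed = 11)
    expect_identical(res$p_perm, res2$p_perm)

    # add-one estimator can never be zero
    res3 <- rsa_permutation_test(cm, model, n_perm = 50, seed = 1,
                                 estimator = "add_one")
    expect_gt(res3$p_perm, 0)
    expect_error(rsa_permutation_test(cm[1:3, 1:4], model), "symmetric")
  })
})

test_that("partial RSA matches the closed-form partial correlation on ranks", {
  withr::with_seed(9, {
    x <- rnorm(10); y <- rnorm(10); z <- rnorm(10)
    rho <- partial_rsa(x, y, z)
    rx <- rank(x); ry <- rank(y); rz <- rank(z)
    rxy <- cor(rx, ry); rxz <- cor(rx, rz); ryz <- cor(ry, rz)
    closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(rho, closed, tolerance = 1e-12)

    # control with ranks exactly orthogonal to both others: the control has
    # two tied levels splitting the positions so that both rank covariances
    # vanish, hence partial == plain Spearman
    a <- as.numeric(1:8)
    b <- c(3, 1, 8, 6, 5, 2, 7, 4)
    ctrl <- c(1, 2, 2, 1, 1, 2, 2, 1)
    expect_equal(cor(rank(ctrl), rank(a)), 0)
    expect_equal(cor(rank(ctrl), rank(b)), 0)
    expect_equal(partial_rsa(a, b, ctrl), rsa_spearman(a, b),
                 tolerance = 1e-6)

    # collinear control is degenerate
    expect_error(partial_rsa(x, y, y), "rank-identical")
  })
})

test_that("residual-shuffle machinery restores the observed statistic", {
  withr::with_seed(10, {
    s <- 12
    fmri <- as.numeric(similarity_vector(matrix(rnorm(s * 10), s)))
    pers <- as.numeric(similarity_vector(matrix(rnorm(s * 10), s)))
    grp <- as.numeric(similarity_vector(matrix(rnorm(s * 10), s)))

    # steps A-F identity: regress -> residual -> add-back with no shuffle
    rf <- rank(fmri); rg <- rank(grp)
    xm <- cbind(1, rg)
    beta <- solve(crossprod(xm), crossprod(xm, rf))
    fitted <- as.numeric(xm %*% beta)
    res <- rf - fitted
    m <- matrix(NA_real_, s, s)
    m[lower.tri(m)] <- res
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    restored <- fitted + m[lower.tri(m)]
    expect_equal(restored, rf, tolerance = 1e-10)

    # strong personal signal: permutation p-value is small
    strong <- partial_rsa_permutation_test(pers + 0.05 * rnorm(length(pers)),
                                           pers, grp,
                                           n_perm = 1000, seed = 3)
    expect_lte(strong$p_perm, 0.01)

    # deterministic under fixed seed
    a1 <- partial_rsa_permutation_test(fmri, pers, grp, n_perm = 200, seed = 4)
    a2 <- partial_rsa_permutation_test(fmri, pers, grp, n_perm = 200, seed = 4)
    expect_identical(a1$p_perm, a2$p_perm)
    expect_equal(a1$rho, partial_rsa(fmri, pers, grp))
  })
})
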