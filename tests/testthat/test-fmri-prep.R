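test_that("nuisance regression removes trend/motion and nothing else", {
  tlen <- 40
  # pure linear ramp, zero motion: trend captures everything
  ramp <- matrix(seq_len(tlen) * 2 + 1, tlen, 3)
  res <- regress_nuisance(ramp, matrix(0, tlen, 6))
  expect_true(all(abs(res) < 1e-10))

  withr::with_seed(1, {
    data <- matrix(rnorm(tlen * 5), tlen)
    motion <- matrix(rnorm(tlen * 6, sd = 0.1), tlen)
    res2 <- regress_nuisance(data, motion)
    # residuals uncorrelated with every regressor
    zs <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
    regs <- cbind(apply(motion, 2, zs), zs(seq_len(tlen)))
    expect_lt(max(abs(cor(res2, regs))), 1e-8)

    # closed-form least-squares oracle on a 10-timepoint toy
    t10 <- 10
    vox <- sin(seq_len(t10))
    mot10 <- matrix(rnorm(t10 * 6), t10)
    r10 <- regress_nuisance(cbind(vox), mot10)
    y <- zs(vox)
    x <- cbind(1, apply(mot10, 2, zs), zs(seq_len(t10)))
    beta <- solve(t(x) %*% x, t(x) %*% y)   # normal equations
    expect_equal(as.numeric(r10), as.numeric(y - x %*% beta),
                 tolerance = 1e-10)

    # duplicated motion column -> rank-deficient -> error
    bad <- motion; bad[, 2] <- bad[, 1]
    expect_error(regress_nuisance(data, bad), "rank-deficient")
    expect_error(regress_nuisance(data[1:6, ], motion[1:6, ]), "8 time points")
    expect_error(regress_nuisance(data, motion[-1, ]), "align")
  })
})

test_that("the response window averages exactly the intended volumes", {
  tlen <- 30
  # residuals equal to the 0-based volume index at every voxel: the window
  # mean identifies which volumes were averaged
  res <- matrix(rep(0:(tlen - 1), 2), tlen)
  onsets <- data.frame(volume = c(0, 12), scenario = c(1, 2))
  out <- average_scenario_window(res, onsets, tr_seconds = 2.5,
                                 window = c(5, 15))
  # offsets +2..+5 -> means 3.5 and 15.5
  expect_equal(out$patterns[, 1], c(3.5, 15.5))
  expect_identical(out$scenario, c(1, 2))

  # constant residuals -> the constant; direct arithmetic mean
  resc <- matrix(5, tlen, 1)
  expect_equal(average_scenario_window(resc, onsets, 2.5)$patterns[, 1],
               c(5, 5))
  res4 <- matrix(0, tlen, 1); res4[3:6, 1] <- 1:4
  expect_equal(average_scenario_window(res4, data.frame(volume = 0,
                                                        scenario = 1),
                                       2.5)$patterns[1, 1], 2.5)

  # window truncated at run end warns; fractional-volume window errors
  expect_warning(average_scenario_window(res, data.frame(volume = 26,
                                                         scenario = 1), 2.5),
                 "truncated")
  expect_error(average_scenario_window(res, onsets, 2.5, window = c(4, 15)),
               "whole volumes")
  expect_error(average_scenario_window(res, data.frame(volume = c(5, 2),
                                                       scenario = 1:2), 2.5),
               "increasing")
})

test_that("voxel stability averages the Fisher-z inter-run correlations", {
  withr::with_seed(2, {
    s <- 20
    base <- matrix(rnorm(s * 4), s)
    # identical across 5 runs: stability is the clipped maximum
    runs <- rep(list(base), 5)
    stab <- voxel_stability(runs)
    expect_equal(stab, rep(atanh(1 - 1e-7), 4))

    # hand-checked against an explicit pair loop on noisy runs
    runs2 <- lapply(1:5, function(r) base + matrix(rnorm(s * 4), s))
    stab2 <- voxel_stability(runs2)
    pairs <- combn(5, 2)
    expect_equal(ncol(pairs), 10)  # 5 runs -> 10 coefficients per voxel
    oracle <- sapply(1:4, function(v) {
      mean(sapply(seq_len(ncol(pairs)), function(k) {
        atanh(cor(runs2[[pairs[1, k]]][, v], runs2[[pairs[2, k]]][, v]))
      }))
    })
    expect_equal(stab2, oracle, tolerance = 1e-10)

    # white-noise voxels: mean stability is near zero
    null_runs <- lapply(1:5, function(r) matrix(rnorm(20 * 1000), 20))
    expect_lt(abs(mean(voxel_stability(null_runs))), 0.05)

    # zero-variance voxel: undefined pairs contribute 0 or are dropped
    runs3 <- lapply(runs2, function(m) m)
    runs3[[1]][, 2] <- 7
    z0 <- voxel_stability(runs3, undefined = "zero")
    zd <- voxel_stability(runs3, undefined = "drop")
    k_ok <- 6  # pairs not involving run 1
    expect_equal(z0[2] * 10, zd[2] * k_ok, tolerance = 1e-10)
    expect_error(voxel_stability(runs2[1]), "at least 2 runs")
  })
})

test_that("stable-voxel selection matches a full sort and breaks ties by index", {
  withr::with_seed(3, {
    stab <- rnorm(50)
    roi <- rep(1:2, each = 25)
    sel <- select_stable_voxels(stab, roi, k = 10)
    for (r in 1:2) {
      idx <- which(roi == r)
      brute <- sort(idx[order(stab[idx], decreasing = TRUE)][1:10])
      expect_equal(sel[[as.character(r)]], brute)
    }
    # ROI smaller than k: everything returned
    sel_all <- select_stable_voxels(stab, roi, k = 100)
    expect_equal(sel_all[["1"]], 1:25)
    # k equal to ROI size: identity
    expect_equal(select_stable_voxels(stab, roi, k = 25)[["2"]], 26:50)
    # ties broken by ascending voxel index
    tied <- c(1, 1, 1, 0)
    expect_equal(select_stable_voxels(tied, rep(1, 4), k = 2)[["1"]], c(1, 2))
    # background label 0 ignored
    expect_null(select_stable_voxels(stab, rep(0, 50), k = 5)[["0"]])
  })
})

test_that("scenario patterns are replicate-averaged then voxel-normalized", {
  # 2 scenarios x 3 voxels, replicates listed by hand
  pres <- rbind(c(1, 2, 3),    # scenario 1
                c(3, 2, 5),    # scenario 1
                c(5, 8, 1),    # scenario 2
                c(7, 8, 3))    # scenario 2
  sc <- c(1, 1, 2, 2)
  sp <- build_scenario_patterns(pres, sc, roi_id = "toy")
  # replicate means: s1 = (2,2,4), s2 = (6,8,2); z-scored per voxel across
  # the two scenarios -> (-1, 1) per column up to sign
  expect_equal(unname(sp$patterns), rbind(c(-1, -1, 1), c(1, 1, -1)))
  expect_equal(unname(sp$replicate_counts), c(2L, 2L))
  expect_equal(sp$roi_id, "toy")

  # identical replicates: the average equals any replicate pre-normalization
  same <- rbind(c(1, 4), c(1, 4), c(2, 9))
  sp2 <- build_scenario_patterns(same, c(1, 1, 2))
  expect_equal(unname(sp2$replicate_counts), c(2L, 1L))

  withr::with_seed(4, {
    pres3 <- matrix(rnorm(40 * 6), 40)
    sp3 <- build_scenario_patterns(pres3, rep(1:8, 5))
    expect_true(all(abs(colMeans(sp3$patterns)) < 1e-10))
    expect_true(all(abs(sqrt(colMeans(sp3$patterns^2)) - 1) < 1e-10))
  })
  # zero-variance voxel across scenarios is zeroed with a warning
  flat <- rbind(c(1, 7), c(2, 7), c(3, 7))
  expect_warning(sp4 <- build_scenario_patterns(flat, 1:3), "zero-variance")
  expect_equal(sp4$patterns[, 2], c(0, 0, 0), ignore_attr = TRUE)
  expect_error(build_scenario_patterns(pres, sc, scenario_levels = 1:3),
               "no presentations")
})

test_that("stability selection is invariant to uniform voxel-wise rescaling", {
  withr::with_seed(5, {
    runs <- lapply(1:4, function(r) matrix(rnorm(12 * 30), 12))
    gain <- runif(30, 0.5, 4)
    offset <- rnorm(30)
    scaled <- lapply(runs, function(m) sweep(sweep(m, 2, gain, `*`), 2,
                                             offset, `+`))
    expect_equal(voxel_stability(runs), voxel_stability(scaled),
                 tolerance = 1e-10)
  })
})
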