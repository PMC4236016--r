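test_that("log transform is the elementwise natural logarithm", {
  x <- makeExpr(cbind(c(1, exp(2)), c(exp(1), 10)))
  y <- logTransform(x)
  expect_equal(unname(exprValues(y)),
               cbind(c(0, 2), c(1, log(10))))

  set.seed(5)
  v <- matrix(runif(20, 0.1, 50), 5, 4)
  expect_equal(unname(exprValues(logTransform(makeExpr(v)))), log(v))
})

test_that("a rank-1 constant matrix yields exactly one non-negligible pattern", {
  x <- makeExpr(matrix(100, 3, 2))
  d <- surprisalDecompose(logTransform(x))
  om <- singularValues(d)
  expect_equal(effectiveRank(d), 1L)
  expect_lt(om[2] / om[1], 1e-10)
  # alpha >= 1 contributions vanish
  dev <- patternWeights(d)[, 2] %o% multipliers(d)[2, ]
  expect_lt(max(abs(dev)), 1e-10)
  # rank-1 reconstruction is exact
  expect_equal(exprValues(reconstruct(d, 1)),
               exprValues(logTransform(x)), tolerance = 1e-12)
})

test_that("a diagonal 2 x 2 log matrix matches the brute-force SVD oracle", {
  y <- new("LogExpressionMatrix",
           values = matrix(c(2, 0, 0, 1), 2, 2,
                           dimnames = list(c("a", "b"), c("T1", "T2"))))
  d <- surprisalDecompose(y)
  expect_equal(unname(singularValues(d)), c(2, 1))
  # patterns align with coordinate axes up to the sign convention
  expect_equal(abs(unname(patternWeights(d))), diag(2), tolerance = 1e-12)
  expect_equal(abs(unname(multipliers(d))), diag(c(2, 1)), tolerance = 1e-12)
  # Eckart-Young: rank-1 truncation error equals the second singular value
  err <- exprValues(y) - exprValues(reconstruct(d, 1))
  expect_equal(sqrt(sum(err^2)), 1, tolerance = 1e-12)
})

test_that("four conditions give a 4 x 4 Lagrange-multiplier matrix", {
  x <- randomExpr(50, 4, seed = 2)
  d <- surprisalDecompose(logTransform(x))
  expect_identical(dim(multipliers(d)), c(4L, 4L))
  expect_identical(rownames(multipliers(d)),
                   paste0("pattern", 0:3))
  expect_lte(effectiveRank(d), 4L)
})

test_that("small-matrix and full-SVD routes agree after sign normalization", {
  for (seed in 1:25) {
    m <- sample(5:60, 1)
    t <- sample(2:min(m, 8), 1)
    y <- logTransform(randomExpr(m, t, seed = seed))
    a <- surprisalDecompose(y, method = "small_matrix")
    b <- surprisalDecompose(y, method = "full_svd")
    expect_lt(max(abs(singularValues(a) - singularValues(b))) /
                singularValues(a)[1], 1e-8)
    expect_lt(max(abs(patternWeights(a) - patternWeights(b))), 1e-8)
    expect_lt(max(abs(multipliers(a) - multipliers(b))), 1e-8)
  }
})

test_that("decompositions satisfy orthonormality and exact reconstruction", {
  for (seed in c(3, 14, 27)) {
    y <- logTransform(randomExpr(80, 5, seed = seed))
    for (method in c("small_matrix", "full_svd")) {
      d <- surprisalDecompose(y, method = method)
      G <- patternWeights(d); lam <- multipliers(d); om <- singularValues(d)
      expect_lt(max(abs(crossprod(G) - diag(ncol(G)))), 1e-10)
      expect_lt(max(abs(tcrossprod(lam) - diag(om^2))) / om[1]^2, 1e-10)
      expect_false(is.unsorted(rev(om)))
      recon <- G %*% lam
      expect_lt(max(abs(recon - exprValues(y))),
                1e-10 * max(abs(exprValues(y))))
    }
  }
})

test_that("the sign convention is deterministic and matches the steady-state reading", {
  y <- logTransform(randomExpr(100, 4, seed = 9))
  d <- surprisalDecompose(y)
  # steady-state weights predominantly negative, multipliers negative,
  # product reproduces positive log expression
  expect_lt(sum(patternWeights(d)[, 1]), 0)
  expect_true(all(multipliers(d)[1, ] < 0))
  expect_true(all(patternWeights(d)[, 1] %o% multipliers(d)[1, ] > 0))
  # deviation patterns: largest-magnitude multiplier entry positive
  for (a in 2:4) {
    row <- multipliers(d)[a, ]
    expect_gt(row[which.max(abs(row))], 0)
  }
})

test_that("transposed input and the zero matrix hit the documented edges", {
  bad <- new("LogExpressionMatrix",
             values = matrix(1, 2, 3, dimnames = list(c("a", "b"),
                                                      c("x", "y", "z"))))
  expect_error(surprisalDecompose(bad), "transpose")

  z <- new("LogExpressionMatrix",
           values = matrix(0, 4, 2, dimnames = list(letters[1:4],
                                                    c("T1", "T2"))))
  d <- surprisalDecompose(z)
  expect_equal(unname(singularValues(d)), c(0, 0))
  expect_equal(effectiveRank(d), 0L)
  expect_lt(max(abs(crossprod(patternWeights(d)) - diag(2))), 1e-10)
})

test_that("truncated reconstruction obeys Eckart-Young on random input", {
  y <- logTransform(randomExpr(40, 5, seed = 21))
  d <- surprisalDecompose(y)
  om <- singularValues(d)
  for (k in 1:5) {
    err <- exprValues(y) - exprValues(reconstruct(d, k))
    expect_equal(sqrt(sum(err^2)), sqrt(sum(om[seq_len(5 - k) + k]^2)),
                 tolerance = 1e-8)
  }
  expect_error(reconstruct(d, 0))
  expect_error(reconstruct(d, 6))
})

test_that("steady-state residual vanishes for steady-state-only genes and ranks planted groups", {
  # gene exactly proportional to the steady-state profile
  sim <- smallPlanted()
  d <- surprisalDecompose(logTransform(sim$expression))
  g <- patternWeights(d)[, 1, drop = FALSE]
  lam0 <- multipliers(d)[1, , drop = FALSE]
  pure <- new("LogExpressionMatrix", values = {
    v <- g %*% lam0
    dimnames(v) <- list(rownames(g), colnames(lam0))
    v
  })
  dp <- surprisalDecompose(pure)
  expect_lt(max(steadyStateResidual(dp)), 1e-10)

  # planted deviating genes carry the residual; stable genes sit at noise level
  r <- steadyStateResidual(d)
  roles <- sim$truth@roles
  expect_gt(mean(r[roles == "deviating"]), mean(r[roles == "stable"]))
  # deviating residual matches the planted deviation magnitude
  truthDev <- abs(outer(sim$truth@trueG[, 2], sim$truth@trueLambda[2, ]))
  expected <- apply(truthDev, 1, max)[roles == "deviating"]
  expect_equal(unname(r[roles == "deviating"]), unname(expected),
               tolerance = 0.15)
})

test_that("decomposition tables round-trip through the TSV writers", {
  d <- surprisalDecompose(logTransform(randomExpr(15, 3, seed = 4)))
  dir <- tempfile()
  writeDecomposition(d, dir)
  d2 <- readDecomposition(dir)
  expect_identical(patternWeights(d2), patternWeights(d))
  expect_identical(multipliers(d2), multipliers(d))
  expect_identical(singularValues(d2), singularValues(d))
})
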