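test_that("glasso at lambda 0 is the unpenalised MLE", {
  set.seed(1)
  S <- cov_ml(matrix(rnorm(100 * 4), 100, 4))
  fit <- glasso_fit(S, 0)
  expect_equal(fit$omega, solve(S), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("full shrinkage empties the graph", {
  set.seed(2)
  S <- cov_ml(matrix(rnorm(100 * 4), 100, 4))
  fit <- glasso_fit(S, max(abs(S[upper.tri(S)])) * 1.001)
  expect_equal(length(fit$edges), 0)
  expect_equal(diag(fit$omega), 1 / diag(S), tolerance = 1e-6)
})

test_that("glasso objective matches the generic convex-optimiser oracle", {
  set.seed(3)
  for (i in 1:4) {
    S <- cov_ml(matrix(rnorm(60 * 3), 60, 3))
    for (lambda in c(0.05, 0.1, 0.3)) {
      fit <- glasso_fit(S, lambda)
      expect_lt(fit$kkt, 1e-6)
      expect_equal(fit$objective, oracle_glasso_objective(S, lambda),
                   tolerance = 1e-6)
    }
  }
})

test_that("the glasso path densifies as the penalty shrinks", {
  set.seed(4)
  X <- matrix(rnorm(300 * 8), 300, 8) %*%
    chol(0.4 + diag(0.6, 8))
  path <- glasso_path(cov_ml(X), n_lambda = 40)
  counts <- vapply(path, function(f) length(f$edges), numeric(1))
  # lambda decreases along the path; the active set grows overall, but an
  # exact solution path may let a single edge exit transiently
  expect_true(all(diff(counts) >= -1))
  expect_gte(counts[length(counts)], counts[1])
  expect_gte(max(counts), 8)
  expect_true(all(vapply(path, function(f) f$kkt < 1e-6, TRUE)))
})

test_that("constrained MLE reproduces S on the diagonal and edge set", {
  set.seed(5)
  S <- cov_ml(matrix(rnorm(200 * 5), 200, 5))
  edges <- list(c(1, 2), c(2, 3), c(4, 5))
  fit <- constrained_mle(S, edges)
  expect_equal(diag(fit$sigma), diag(S), tolerance = 1e-9)
  for (e in edges) {
    expect_equal(fit$sigma[e[1], e[2]], S[e[1], e[2]], tolerance = 1e-9)
  }
  # off-graph precision entries are exactly zero
  expect_identical(fit$omega[1, 4], 0)
  expect_identical(fit$omega[3, 5], 0)
})

test_that("constrained MLE edge cases: complete and empty graphs", {
  set.seed(6)
  S <- cov_ml(matrix(rnorm(150 * 4), 150, 4))
  all_pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  full <- constrained_mle(S, all_pairs)
  expect_equal(full$omega, solve(S), tolerance = 1e-8, ignore_attr = TRUE)
  empty <- constrained_mle(S, list())
  expect_equal(empty$omega, diag(1 / diag(S)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("constrained MLE matches a generic-optimiser oracle on 3 nodes", {
  set.seed(7)
  S <- cov_ml(matrix(rnorm(120 * 3), 120, 3))
  fit <- constrained_mle(S, list(c(1, 2), c(2, 3)))  # (1,3) constrained
  orc <- oracle_constrained_mle(S, list(c(1, 2), c(2, 3)))
  expect_equal(fit$loglik_terms, orc$objective, tolerance = 1e-6)
  expect_equal(fit$omega, orc$omega, tolerance = 1e-3)
})

test_that("partial correlations follow the precision-matrix identity", {
  omega <- matrix(c(2, -0.5, 0, -0.5, 1.5, -0.3, 0, -0.3, 1), 3, 3)
  rp <- partial_correlations(omega)
  expect_equal(rp[1, 2], 0.5 / sqrt(2 * 1.5))
  expect_equal(rp[2, 3], 0.3 / sqrt(1.5 * 1))
  expect_identical(rp[1, 3], 0)
  expect_identical(diag(rp), c(0, 0, 0))
  # bivariate case: partial equals marginal correlation
  set.seed(8)
  x <- matrix(rnorm(500 * 2), 500, 2)
  x[, 2] <- 0.6 * x[, 1] + 0.8 * x[, 2]
  S <- cov_ml(x)
  rp2 <- partial_correlations(solve(S))
  expect_equal(rp2[1, 2], cov2cor(S)[1, 2], tolerance = 1e-10)
})

test_that("stepwise selection never worsens the starting EBIC", {
  set.seed(9)
  for (i in 1:3) {
    X <- matrix(rnorm(400 * 5), 400, 5)
    m <- stepwise_select(cov_ml(X), 400)
    expect_lte(m$ebic, m$ebic_start + 1e-9)
  }
})

test_that("independent variables yield an (almost always) empty graph", {
  set.seed(10)
  empties <- replicate(10, {
    X <- matrix(rnorm(2000 * 6), 2000, 6)
    length(stepwise_select(cov_ml(X), 2000)$edges) == 0
  })
  expect_gte(mean(empties), 0.9)
})

test_that("stepwise recovers a 6-node chain at n = 2000", {
  omega <- diag(1, 6)
  for (i in 1:5) omega[i, i + 1] <- omega[i + 1, i] <- -0.4
  Sig <- solve(omega)
  set.seed(11)
  hits <- replicate(5, {
    X <- matrix(rnorm(2000 * 6), 2000, 6) %*% chol(Sig)
    got <- stepwise_select(cov_ml(X), 2000)$edges
    chain <- lapply(1:5, function(i) c(i, i + 1))
    identical(lapply(got, as.integer), lapply(chain, as.integer))
  })
  expect_gte(mean(hits), 0.8)
})

test_that("fit_ggm uses complete cases and returns a consistent network", {
  set.seed(12)
  X <- as.data.frame(matrix(rnorm(500 * 4), 500, 4))
  names(X) <- c("w", "x", "y", "z")
  X$w[1:25] <- NA
  res <- fit_ggm(X)
  expect_equal(res$n_used, 475)
  expect_equal(res$network$weights, res$model$r_p)
  expect_equal(res$network$mask, abs(res$model$r_p) > 0)
})
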