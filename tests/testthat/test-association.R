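test_that("identical group distributions give statistic 0 and p 1", {
  d <- data.frame(x = rep(c("a", "b"), each = 40),
                  g = rep(c("g1", "g2"), 40))
  cmp <- compare_groups(d, "x", "g")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p, 1)
})

test_that("chi-square statistic equals the hand formula", {
  tab <- matrix(c(30, 20, 10, 40), 2, 2, byrow = TRUE)
  d <- data.frame(
    x = rep(rep(c("yes", "no"), 2), times = as.vector(t(tab))),
    g = rep(c("g1", "g2"), times = rowSums(tab)))
  cmp <- compare_groups(d, "x", "g")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(cmp$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(cmp$test, "chi_square")
})

test_that("two-group Kruskal-Wallis equals the tie-corrected rank-sum test", {
  set.seed(1)
  x <- sample(0:10, 90, replace = TRUE)  # heavy ties
  g <- rep(c("g1", "g2"), c(50, 40))
  cmp <- compare_groups(data.frame(x = x, g = g), "x", "g")
  expect_equal(cmp$test, "kruskal_wallis")
  expect_equal(cmp$p, oracle_ranksum_p(x, g), tolerance = 1e-10)
})

test_that("sparse tables trigger the Fisher recommendation warning", {
  d <- data.frame(x = c(rep("a", 50), "b"),
                  g = rep(c("g1", "g2"), length.out = 51))
  expect_warning(compare_groups(d, "x", "g"), "fisher")
  expect_silent(cmp <- compare_groups(d, "x", "g", test = "fisher"))
  expect_true(cmp$p >= 0 && cmp$p <= 1)
})

test_that("descriptive tables have overall, per-group and p columns", {
  coh <- generate_cohort(paper_like_config(n = 400, seed = 3,
                                           missing_rate = 0.05))
  ind <- dichotomize_items(coh)
  grp <- assign_group(ind)
  dat <- cbind(coh, ind, use_group = factor(
    grp, levels = c("alcohol_tobacco_other", "cannabis_no_ats", "ats")))
  tab <- describe_by_group(dat, c("tobacco_used", "age"), "use_group")
  expect_equal(names(tab),
               c("variable", "level", "overall", "alcohol_tobacco_other",
                 "cannabis_no_ats", "ats", "test", "p"))
  expect_true(any(tab$variable == "age"))
})

# ---- multiple imputation --------------------------------------------------

test_that("a complete table yields m identical copies", {
  d <- data.frame(x = rnorm(50), y = rnorm(50))
  imp <- mice_impute(d, m = 3, seed = 1)
  expect_length(imp$imputations, 3)
  for (cp in imp$imputations) expect_identical(cp, d)
})

test_that("PMM imputations come from the observed donor set", {
  set.seed(2)
  n <- 200
  d <- data.frame(x = rnorm(n))
  d$y <- 2 * d$x + rnorm(n)
  miss <- sample(n, 30)
  truth <- d$y[miss]
  d$y[miss] <- NA
  imp <- mice_impute(d, m = 3, maxit = 3, seed = 7)
  donors <- d$y[!is.na(d$y)]
  for (cp in imp$imputations) {
    expect_true(all(cp$y[miss] %in% donors))
    expect_false(any(is.na(cp$y)))
  }
})

test_that("imputation is deterministic given the seed", {
  set.seed(3)
  d <- data.frame(x = rnorm(100), z = factor(sample(c("u", "v"), 100, TRUE)))
  d$x[1:10] <- NA
  d$z[11:18] <- NA
  a <- mice_impute(d, m = 2, maxit = 2, seed = 42)
  b <- mice_impute(d, m = 2, maxit = 2, seed = 42)
  expect_identical(a$imputations, b$imputations)
})

test_that("a constant incomplete variable is rejected by name", {
  d <- data.frame(x = rnorm(30), k = c(rep(1, 29), NA))
  expect_error(mice_impute(d, m = 2, seed = 1), "'k'")
})

test_that("MCAR imputation keeps the pooled slope near the full-data fit", {
  set.seed(4)
  n <- 400
  x <- rnorm(n); w <- rnorm(n)
  y <- 1 + 0.8 * x + 0.3 * w + rnorm(n)
  full <- lm(y ~ x + w)
  ci <- confint(full)["x", ]
  d <- data.frame(y = y, x = x, w = w)
  d$x[sample(n, 40)] <- NA
  imp <- mice_impute(d, m = 5, maxit = 5, seed = 9)
  fits <- lapply(imp$imputations, function(cp) {
    f <- lm(y ~ x + w, cp)
    list(coef = coef(f), vcov = vcov(f))
  })
  pooled <- pool_rubin(fits, n_obs = n)
  expect_gt(pooled$estimate[pooled$term == "x"], ci[1])
  expect_lt(pooled$estimate[pooled$term == "x"], ci[2])
})

# ---- multinomial fit and pooling ------------------------------------------

test_that("two-level multinomial equals binary logistic regression", {
  set.seed(5)
  n <- 300
  d <- data.frame(x = rnorm(n), f = factor(sample(c("p", "q"), n, TRUE)))
  eta <- -0.3 + 0.8 * d$x + 0.5 * (d$f == "q")
  d$y <- factor(ifelse(runif(n) < plogis(eta), "one", "zero"),
                levels = c("zero", "one"))
  fit <- fit_multinomial(y ~ x + f, d)
  ref <- glm(y ~ x + f, d, family = binomial())
  expect_equal(as.vector(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-8)
  expect_equal(unname(diag(fit$vcov)), unname(diag(vcov(ref))),
               tolerance = 1e-6)
})

test_that("saturated-model RRRs equal contingency cross-product ratios", {
  counts <- matrix(c(40, 25, 20, 30, 15, 35), nrow = 2, byrow = TRUE,
                   dimnames = list(c("x0", "x1"), c("a", "b", "c")))
  d <- data.frame(
    x = rep(rep(c(0, 1), times = 3), as.vector(counts)),
    y = factor(rep(rep(colnames(counts), each = 2), as.vector(counts)),
               levels = c("a", "b", "c")))
  fit <- fit_multinomial(y ~ x, d)
  for (lev in c("b", "c")) {
    cross <- (counts["x1", lev] / counts["x1", "a"]) /
      (counts["x0", lev] / counts["x0", "a"])
    expect_equal(exp(fit$coefficients[lev, "x"]), cross, tolerance = 1e-7)
  }
})

test_that("the multinomial fit matches an established optimiser", {
  set.seed(6)
  n <- 500
  d <- data.frame(x = rnorm(n), w = rnorm(n))
  lp2 <- 0.5 + 0.7 * d$x
  lp3 <- -0.5 + 0.4 * d$x - 0.6 * d$w
  pr <- cbind(1, exp(lp2), exp(lp3))
  pr <- pr / rowSums(pr)
  d$y <- factor(apply(pr, 1, function(p) sample(c("a", "b", "c"), 1, prob = p)),
                levels = c("a", "b", "c"))
  fit <- fit_multinomial(y ~ x + w, d)
  ref <- nnet::multinom(y ~ x + w, d, trace = FALSE, reltol = 1e-14)
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-4, ignore_attr = TRUE)
  expect_gt(fit$loglik + 1e-6, -ref$value)  # at least as good a maximum
})

test_that("an independent predictor is rarely flagged at the 3-SE level", {
  set.seed(7)
  flags <- replicate(20, {
    n <- 1000
    d <- data.frame(x = rnorm(n),
                    y = factor(sample(c("a", "b", "c"), n, TRUE,
                                      prob = c(0.5, 0.3, 0.2))))
    fit <- fit_multinomial(y ~ x, d)
    se <- sqrt(diag(fit$vcov))
    b <- abs(c(t(fit$coefficients)) / se)
    any(b[c(2, 4)] > 3)  # the x terms
  })
  expect_lte(mean(flags), 0.15)
})

test_that("separation is reported as an error naming the term", {
  d <- data.frame(x = c(rep(0, 20), rep(1, 20)),
                  y = factor(rep(c("a", "b"), each = 20)))
  expect_error(fit_multinomial(y ~ x, d), "separation.*x")
})

test_that("Rubin pooling reproduces a hand-computed toy example", {
  fits <- lapply(c(1.0, 1.2, 1.4), function(b)
    list(coef = c(term = b), vcov = matrix(0.04, 1, 1,
                                           dimnames = list("term", "term"))))
  pooled <- pool_rubin(fits, n_obs = 100)
  expect_equal(pooled$estimate, 1.2)
  B <- var(c(1.0, 1.2, 1.4))
  expect_equal(pooled$between_var, B)
  expect_equal(pooled$within_var, 0.04)
  expect_equal(pooled$se^2, 0.04 + (1 + 1 / 3) * B, tolerance = 1e-12)
})

test_that("pooling identical fits returns the common estimate exactly", {
  f <- list(coef = c(a = 0.5, b = -1), vcov = diag(c(0.01, 0.02)))
  dimnames(f$vcov) <- list(c("a", "b"), c("a", "b"))
  pooled <- pool_rubin(list(f, f, f), n_obs = 50)
  expect_equal(pooled$estimate, c(0.5, -1), ignore_attr = TRUE)
  expect_equal(pooled$between_var, c(0, 0), ignore_attr = TRUE)
  expect_equal(pooled$se, sqrt(c(0.01, 0.02)), ignore_attr = TRUE)
})

test_that("growing between-imputation variance widens the interval", {
  widths <- vapply(c(0.01, 0.05, 0.2), function(b) {
    fits <- lapply(c(-1, 0, 1) * sqrt(b * 1.0) + 1, function(est)
      list(coef = c(t = est), vcov = matrix(0.04, dimnames = list("t", "t"))))
    pooled <- pool_rubin(fits, n_obs = 1000)
    pooled$ci_high / pooled$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("mismatched term sets are rejected", {
  f1 <- list(coef = c(a = 1), vcov = matrix(1, dimnames = list("a", "a")))
  f2 <- list(coef = c(b = 1), vcov = matrix(1, dimnames = list("b", "b")))
  expect_error(pool_rubin(list(f1, f2)), "mismatch")
})

test_that("with no missing data the pooled fit equals the complete-data fit", {
  coh <- generate_cohort(paper_like_config(n = 600, seed = 8,
                                           missing_rate = 0))
  grp <- assign_group(dichotomize_items(coh))
  res <- regress_groups(coh, grp, m = 3, maxit = 2, seed = 1)
  single <- res$fits[[1]]
  expect_identical(res$fits[[2]]$coefficients, single$coefficients)
  flat <- flatten_fit(single)
  expect_equal(res$pooled$estimate, unname(flat$coef))
  expect_true(all(res$pooled$between_var == 0))
})
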