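# Independent oracles used to check the package's estimators. These stay
# deliberately naive (quadrature, enumeration, generic optimisers) and do
# not share code with the implementation.

# bivariate normal CDF F(h, k; rho) by 1-D quadrature over the correlation
# (Plackett's identity: dF/drho = phi2(h, k; rho))
oracle_binorm_cdf <- function(h, k, rho) {
  phi2 <- function(t) {
    exp(-(h^2 - 2 * t * h * k + k^2) / (2 * (1 - t^2))) /
      (2 * pi * sqrt(1 - t^2))
  }
  base <- pnorm(h) * pnorm(k)
  if (rho == 0) return(base)
  base + integrate(Vectorize(phi2), 0, rho, rel.tol = 1e-11)$value
}

oracle_orthant <- function(h, k, rho) {
  1 - pnorm(h) - pnorm(k) + oracle_binorm_cdf(h, k, rho)
}

# grid search + local refinement of the two-step tetrachoric likelihood
oracle_tetrachoric <- function(tab) {
  tc <- if (any(tab == 0)) tab + 0.5 else tab
  n <- sum(tc)
  tau_r <- qnorm(1 - sum(tc[1, ]) / n)
  tau_c <- qnorm(1 - sum(tc[, 1]) / n)
  ll <- function(rho) {
    p11 <- oracle_orthant(tau_r, tau_c, rho)
    p1. <- 1 - pnorm(tau_r); p.1 <- 1 - pnorm(tau_c)
    p10 <- p1. - p11; p01 <- p.1 - p11; p00 <- 1 - p1. - p.1 + p11
    eps <- 1e-14
    tc[1, 1] * log(max(p11, eps)) + tc[1, 2] * log(max(p10, eps)) +
      tc[2, 1] * log(max(p01, eps)) + tc[2, 2] * log(max(p00, eps))
  }
  grid <- seq(-0.99, 0.99, by = 0.01)
  vals <- vapply(grid, ll, numeric(1))
  best <- grid[which.max(vals)]
  optimize(ll, interval = c(max(-0.999, best - 0.02),
                            min(0.999, best + 0.02)),
           maximum = TRUE, tol = 1e-9)$maximum
}

# two-sided Fisher exact p by full hypergeometric enumeration
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# betweenness by exhaustive enumeration of simple paths (small graphs)
oracle_betweenness <- function(W) {
  p <- nrow(W)
  len <- 1 / abs(W)
  len[W == 0] <- Inf
  diag(len) <- Inf
  all_paths <- function(from, to) {
    out <- list()
    grow <- function(path) {
      last <- path[length(path)]
      if (last == to) { out[[length(out) + 1]] <<- path; return() }
      for (nxt in seq_len(p)) {
        if (is.finite(len[last, nxt]) && !(nxt %in% path)) grow(c(path, nxt))
      }
    }
    grow(from)
    out
  }
  btw <- numeric(p)
  for (s in seq_len(p - 1)) for (t in (s + 1):p) {
    paths <- all_paths(s, t)
    if (!length(paths)) next
    lens <- vapply(paths, function(pt)
      sum(len[cbind(pt[-length(pt)], pt[-1])]), numeric(1))
    geo <- paths[abs(lens - min(lens)) < 1e-12]
    for (pt in geo) {
      inner <- setdiff(pt, c(s, t))
      btw[inner] <- btw[inner] + 1 / length(geo)
    }
  }
  btw
}

# penalised glasso objective by smoothed-l1 generic optimisation over a
# Cholesky parameterisation
oracle_glasso_objective <- function(S, lambda, eps = 1e-14) {
  p <- nrow(S)
  f <- function(par) {
    L <- matrix(0, p, p)
    L[lower.tri(L, diag = TRUE)] <- par
    O <- L %*% t(L)
    -(determinant(O)$modulus[1] - sum(S * O) -
        lambda * 2 * sum(sqrt(O[upper.tri(O)]^2 + eps)))
  }
  init <- t(chol(chol2inv(chol(S))))[lower.tri(diag(p), diag = TRUE)]
  res <- nlminb(init, f, control = list(iter.max = 5000, eval.max = 10000))
  -res$objective
}

# zero-constrained Gaussian likelihood maximised by a generic optimiser
# over the free precision entries
oracle_constrained_mle <- function(S, edges) {
  p <- nrow(S)
  free <- cbind(seq_len(p), seq_len(p))
  for (e in edges) free <- rbind(free, e)
  build <- function(par) {
    O <- matrix(0, p, p)
    for (i in seq_len(nrow(free))) {
      O[free[i, 1], free[i, 2]] <- par[i]
      O[free[i, 2], free[i, 1]] <- par[i]
    }
    O
  }
  f <- function(par) {
    O <- build(par)
    ld <- determinant(O)
    if (ld$sign <= 0) return(1e10)
    -(as.numeric(ld$modulus) - sum(S * O))
  }
  init <- c(1 / diag(S), rep(0, length(edges)))
  res <- nlminb(init, f, control = list(iter.max = 5000, eval.max = 10000))
  list(omega = build(res$par), objective = -res$objective)
}

# pool-adjacent-violators isotonic regression (for MDS stress recomputation)
oracle_pava <- function(y) {
  n <- length(y)
  val <- y; w <- rep(1, n)
  i <- 1
  repeat {
    viol <- which(diff(val) < -1e-15)
    if (!length(viol)) break
    k <- viol[1]
    new_val <- (val[k] * w[k] + val[k + 1] * w[k + 1]) / (w[k] + w[k + 1])
    val <- c(val[seq_len(k - 1)], new_val, val[-seq_len(k + 1)])
    w <- c(w[seq_len(k - 1)], w[k] + w[k + 1], w[-seq_len(k + 1)])
  }
  rep(val, w)
}

# tie-corrected two-group rank-sum test (normal approximation, no
# continuity correction)
oracle_ranksum_p <- function(x, g) {
  g <- factor(g)
  stopifnot(nlevels(g) == 2)
  r <- rank(x)
  n <- length(x); n1 <- sum(g == levels(g)[1])
  W <- sum(r[g == levels(g)[1]])
  mu <- n1 * (n + 1) / 2
  ties <- table(x)
  sig2 <- n1 * (n - n1) / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (W - mu) / sqrt(sig2)
  2 * pnorm(-abs(z))
}

random_2x2 <- function(n = 100) {
  repeat {
    rho <- runif(1, -0.9, 0.9)
    tr <- runif(1, 0.2, 0.8); tc <- runif(1, 0.2, 0.8)
    z <- matrix(rnorm(2 * n), n, 2)
    z[, 2] <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
    x <- z[, 1] > qnorm(tr); y <- z[, 2] > qnorm(tc)
    tab <- matrix(c(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y)),
                  2, 2, byrow = TRUE)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}
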