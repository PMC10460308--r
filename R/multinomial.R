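# ---- Multinomial logistic regression (Newton ML) and Rubin pooling --------

#' Multinomial logistic regression by Newton-Raphson
#'
#' Full maximum-likelihood fit of a baseline-category multinomial logit
#' model. The first outcome level is the reference; each other level gets
#' its own coefficient vector. Convergence is declared when the largest
#' score (gradient) component falls below `tol`; step-halving guards the
#' Newton updates. Quasi-complete separation is reported as an error when
#' a coefficient diverges beyond `sep_limit` on the scale of a
#' standardised predictor.
#'
#' @param formula Model formula (`outcome ~ covariates`).
#' @param data Data frame; rows with missing outcome or covariates are
#'   dropped.
#' @param ref Reference outcome level (default: first factor level).
#' @param tol Score convergence tolerance.
#' @param maxit Maximum Newton iterations.
#' @param sep_limit Separation guard on the standardised-coefficient scale.
#' @return Object of class `multinom_fit`: list with `coefficients`
#'   ((K-1) x P matrix), `vcov` (full ((K-1)P) square matrix, row-major by
#'   outcome level), `levels`, `terms` (column names), `loglik`, `n`,
#'   `fitted` (n x K probabilities), `iterations`.
#' @export
fit_multinomial <- function(formula, data, ref = NULL, tol = 1e-8,
                            maxit = 100, sep_limit = 15) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- factor(stats::model.response(mf))
  if (!is.null(ref)) y <- stats::relevel(y, ref = ref)
  X <- model.matrix(attr(mf, "terms"), mf)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  K <- nlevels(y)
  if (K < 2) stop("outcome needs at least 2 levels")
  n <- nrow(X); P <- ncol(X)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  sdx <- apply(X, 2, sd); sdx[sdx == 0] <- 1
  B <- matrix(0, K - 1, P, dimnames = list(levels(y)[-1], colnames(X)))
  loglik <- function(B) {
    eta <- X %*% t(B)
    denom <- log1p(rowSums(exp(eta)))
    sum(rowSums(Y[, -1, drop = FALSE] * eta)) - sum(denom)
  }
  probs <- function(B) {
    eta <- cbind(0, X %*% t(B))
    eta <- eta - apply(eta, 1, max)
    e <- exp(eta)
    e / rowSums(e)
  }
  ll <- loglik(B)
  for (it in seq_len(maxit)) {
    Pi <- probs(B)
    R <- Y[, -1, drop = FALSE] - Pi[, -1, drop = FALSE]  # n x (K-1)
    score <- as.vector(crossprod(X, R))                  # P x (K-1), col-major by level
    if (max(abs(score)) < tol) break
    # observed-information blocks H[(k,l)] = X' diag(pi_k (delta_kl - pi_l)) X
    H <- matrix(0, (K - 1) * P, (K - 1) * P)
    for (k in seq_len(K - 1)) {
      for (l in k:(K - 1)) {
        w <- if (k == l) Pi[, k + 1] * (1 - Pi[, k + 1]) else
          -Pi[, k + 1] * Pi[, l + 1]
        blk <- crossprod(X * w, X)
        rk <- (k - 1) * P + seq_len(P); rl <- (l - 1) * P + seq_len(P)
        H[rk, rl] <- blk
        H[rl, rk] <- t(blk)
      }
    }
    step <- tryCatch(solve(H, score), error = function(e)
      stop("Hessian is singular; model may be unidentifiable"))
    step_mat <- matrix(step, K - 1, P, byrow = TRUE)
    fac <- 1
    repeat {
      B_new <- B + fac * step_mat
      ll_new <- loglik(B_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-10) break
      fac <- fac / 2
      if (fac < 1e-8) { B_new <- B; ll_new <- ll; break }
    }
    B <- B_new; ll <- ll_new
    std <- sweep(abs(B), 2, sdx, "*")
    if (max(std) > sep_limit) {
      bad <- which(std == max(std), arr.ind = TRUE)[1, ]
      stop("separation detected: coefficient for term '",
           colnames(X)[bad[2]], "' (outcome '", rownames(B)[bad[1]],
           "') diverges")
    }
  }
  Pi <- probs(B)
  R <- Y[, -1, drop = FALSE] - Pi[, -1, drop = FALSE]
  if (max(abs(crossprod(X, R))) >= tol) {
    warning("Newton iterations stopped before full score convergence")
  }
  H <- matrix(0, (K - 1) * P, (K - 1) * P)
  for (k in seq_len(K - 1)) for (l in k:(K - 1)) {
    w <- if (k == l) Pi[, k + 1] * (1 - Pi[, k + 1]) else
      -Pi[, k + 1] * Pi[, l + 1]
    blk <- crossprod(X * w, X)
    rk <- (k - 1) * P + seq_len(P); rl <- (l - 1) * P + seq_len(P)
    H[rk, rl] <- blk
    H[rl, rk] <- t(blk)
  }
  V <- solve(H)
  nm <- as.vector(t(outer(rownames(B), colnames(X), paste, sep = ":")))
  # vcov indexed level-major to match as.vector(t(B))
  perm <- as.vector(matrix(seq_len((K - 1) * P), P, K - 1))
  Vp <- V[perm, perm, drop = FALSE]
  dimnames(Vp) <- list(nm, nm)
  structure(list(coefficients = B, vcov = Vp, levels = levels(y),
                 terms = colnames(X), loglik = ll, n = n,
                 fitted = Pi, iterations = it),
            class = "multinom_fit")
}

#' @export
print.multinom_fit <- function(x, ...) {
  cat("Multinomial logit fit:", x$n, "observations,",
      length(x$levels), "outcome levels (ref =", x$levels[1],
      "), log-likelihood =", format(x$loglik, digits = 6), "\n")
  invisible(x)
}

#' Flatten a multinomial fit to a coefficient vector and covariance
#'
#' @param fit `multinom_fit`.
#' @return List with `coef` (named, level-major) and `vcov`.
#' @export
flatten_fit <- function(fit) {
  b <- as.vector(t(fit$coefficients))
  names(b) <- rownames(fit$vcov)
  list(coef = b, vcov = fit$vcov)
}

#' Rubin's rules for multiply imputed fits
#'
#' Pools coefficient vectors and covariances across `m` imputed-data fits:
#' pooled point = mean; total variance `T = W + (1 + 1/m) B` with `W` the
#' mean within-imputation variance and `B` the between-imputation
#' variance; intervals and p-values use the Barnard-Rubin small-sample
#' degrees of freedom. Exponentiated estimates are reported as relative
#' risk ratios.
#'
#' @param fits List of `multinom_fit` objects or of lists with `coef` and
#'   `vcov` (identical parameterisation required).
#' @param conf_level Interval coverage.
#' @param n_obs Complete-data sample size (for Barnard-Rubin; taken from
#'   the fits when available).
#' @return Data frame (class `pooled_effects`) with columns `term`,
#'   `estimate`, `se`, `rrr`, `ci_low`, `ci_high`, `p`, `df`,
#'   `within_var`, `between_var`, `m`.
#' @export
pool_rubin <- function(fits, conf_level = 0.95, n_obs = NULL) {
  m <- length(fits)
  if (m < 2) stop("need at least 2 fits to pool")
  fl <- lapply(fits, function(f)
    if (inherits(f, "multinom_fit")) flatten_fit(f) else f)
  nms <- names(fl[[1]]$coef)
  for (f in fl) {
    if (!identical(names(f$coef), nms)) stop("mismatched term sets across fits")
  }
  if (is.null(n_obs)) {
    n_obs <- if (inherits(fits[[1]], "multinom_fit")) fits[[1]]$n else Inf
  }
  Q <- do.call(rbind, lapply(fl, `[[`, "coef"))
  qbar <- colMeans(Q)
  Ubar <- Reduce(`+`, lapply(fl, function(f) diag(as.matrix(f$vcov)))) / m
  B <- apply(Q, 2, var)
  if (m == 1) B <- 0 * qbar
  T_ <- Ubar + (1 + 1 / m) * B
  se <- sqrt(T_)
  k <- length(qbar)
  lambda <- (1 + 1 / m) * B / T_
  lambda <- pmin(pmax(lambda, 0), 1 - 1e-12)
  df_old <- (m - 1) / lambda^2
  nu_com <- max(n_obs - k, 1)
  df_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - lambda)
  df <- ifelse(B > 0, 1 / (1 / df_old + 1 / df_obs), nu_com)
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  p <- 2 * pt(-abs(qbar / se), df)
  out <- data.frame(term = nms, estimate = qbar, se = se,
                    rrr = exp(qbar), ci_low = exp(qbar - tcrit * se),
                    ci_high = exp(qbar + tcrit * se), p = p, df = df,
                    within_var = Ubar, between_var = B, m = m,
                    row.names = NULL)
  class(out) <- c("pooled_effects", "data.frame")
  out
}
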