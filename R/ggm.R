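# ---- Gaussian graphical models: glasso path + stepwise unregularised fit --

#' Maximum-likelihood covariance (denominator n)
#'
#' @param x Numeric matrix, rows = observations.
#' @return Covariance matrix with the ML (1/n) denominator.
#' @export
cov_ml <- function(x) {
  x <- as.matrix(x)
  xc <- sweep(x, 2, colMeans(x))
  crossprod(xc) / nrow(x)
}

# Gaussian log-likelihood of n observations summarised by S, at precision
# Omega (constants included so EBIC values are absolute).
gauss_loglik <- function(S, omega, n) {
  p <- nrow(S)
  ld <- determinant(omega, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  n / 2 * (as.numeric(ld$modulus) - sum(S * omega) - p * log(2 * pi))
}

edge_matrix <- function(p, edges) {
  E <- matrix(FALSE, p, p)
  if (length(edges)) {
    idx <- do.call(rbind, edges)
    E[idx] <- TRUE
    E[idx[, c(2, 1), drop = FALSE]] <- TRUE
  }
  E
}

edges_from_omega <- function(omega, tol = 1e-8) {
  p <- nrow(omega)
  out <- list()
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (abs(omega[i, j]) > tol) out[[length(out) + 1]] <- c(i, j)
  }
  out
}

#' Graphical lasso
#'
#' Maximises the l1-penalised Gaussian log-likelihood
#' `log det(Omega) - tr(S Omega) - lambda * sum(|omega_ij|)` (off-diagonal
#' penalty) by block coordinate descent over columns, each column solved as
#' a lasso by coordinate descent. At `lambda = 0` with nonsingular `S` the
#' fit is the unpenalised MLE `solve(S)`.
#'
#' @param S Sample covariance (ML denominator), symmetric PSD.
#' @param lambda Non-negative penalty.
#' @param maxit,tol Outer-loop controls; convergence on the mean absolute
#'   change of the working covariance.
#' @return List with `omega`, `sigma` (working covariance estimate),
#'   `edges`, `lambda`, `kkt` (maximum KKT residual) and `objective`
#'   (penalised log-likelihood terms `log det - tr - lambda*|.|_1`).
#' @export
glasso_fit <- function(S, lambda, maxit = 200, tol = 1e-9) {
  S <- as.matrix(S)
  p <- nrow(S)
  if (p < 2) stop("need at least 2 variables")
  if (lambda < 0) stop("'lambda' must be non-negative")
  if (lambda == 0) {
    omega <- tryCatch(chol2inv(chol(S)), error = function(e)
      stop("S is singular; lambda = 0 has no maximum-likelihood solution"))
    dimnames(omega) <- dimnames(S)
    return(list(omega = omega, sigma = S, edges = edges_from_omega(omega),
                lambda = 0, kkt = 0,
                objective = glasso_objective(S, omega, 0)))
  }
  W <- S  # off-diagonal-only penalty: the diagonal of Omega^{-1} stays at S
  B <- matrix(0, p - 1, p)  # per-column lasso coefficients
  for (it in seq_len(maxit)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- B[, j]
      # lasso coordinate descent: min .5 b'W11 b - s12'b + lambda|b|_1
      for (inner in seq_len(200)) {
        delta_max <- 0
        for (k in seq_len(p - 1)) {
          r <- s12[k] - sum(W11[k, ] * beta) + W11[k, k] * beta[k]
          bk <- sign(r) * max(abs(r) - lambda, 0) / W11[k, k]
          delta_max <- max(delta_max, abs(bk - beta[k]))
          beta[k] <- bk
        }
        if (delta_max < tol * 10) break
      }
      B[, j] <- beta
      w12 <- W11 %*% beta
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (mean(abs(W - W_old)) < tol * mean(abs(S) + 1e-12)) break
  }
  omega <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    o22 <- 1 / (W[j, j] - sum(W[idx, j] * B[, j]))
    omega[j, j] <- o22
    omega[idx, j] <- -B[, j] * o22
  }
  omega <- (omega + t(omega)) / 2
  dimnames(omega) <- dimnames(S)
  # KKT: grad of logdet - tr is W - S; off-diagonals must satisfy the
  # subgradient condition of the l1 penalty
  Winv <- W - S
  kkt <- max(abs(ifelse(abs(omega) > 1e-10,
                        Winv - lambda * sign(omega),
                        pmax(abs(Winv) - lambda, 0)))[upper.tri(S)])
  list(omega = omega, sigma = W, edges = edges_from_omega(omega, 1e-10),
       lambda = lambda, kkt = kkt,
       objective = glasso_objective(S, omega, lambda))
}

#' Penalised glasso objective
#'
#' `log det(Omega) - tr(S Omega) - lambda * sum_offdiag |omega_ij|`.
#' @param S Covariance; @param omega Precision; @param lambda Penalty.
#' @return Objective value (to be maximised).
#' @export
glasso_objective <- function(S, omega, lambda) {
  ld <- determinant(omega, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  pen <- sum(abs(omega[upper.tri(omega)])) * 2
  as.numeric(ld$modulus) - sum(S * omega) - lambda * pen
}

#' Zero-constrained Gaussian MLE (iterative proportional scaling)
#'
#' Maximum-likelihood precision matrix under the constraint that entries
#' outside `edges` are exactly zero. Solved by iterative proportional
#' scaling over vertices and edges: at convergence the fitted covariance
#' equals `S` on the diagonal and on every unconstrained pair.
#'
#' @param S Positive-definite covariance.
#' @param edges List of integer pairs `c(i, j)` (unordered) forming the
#'   graph, or a logical adjacency matrix.
#' @param omega_start Optional warm start (must respect the zero pattern).
#' @param maxit,tol Controls; convergence on the maximum absolute deviation
#'   of the fitted covariance from `S` over constrained-to-match entries,
#'   relative to `max(diag(S))`.
#' @return List with `omega`, `sigma` (fitted covariance), `edges`,
#'   `loglik_terms` (`log det - tr`), `iterations`, `converged`.
#' @export
constrained_mle <- function(S, edges, omega_start = NULL,
                            maxit = 5000, tol = 1e-10) {
  S <- as.matrix(S)
  p <- nrow(S)
  if (is.matrix(edges)) edges <- edges_from_omega(edges * 1, 0.5)
  E <- edge_matrix(p, edges)
  # complete graph: unconstrained MLE in closed form
  if (length(edges) == p * (p - 1) / 2) {
    omega <- chol2inv(chol(S))
    dimnames(omega) <- dimnames(S)
    return(list(omega = omega, sigma = S, edges = edges,
                loglik_terms = as.numeric(determinant(omega)$modulus) -
                  sum(S * omega),
                iterations = 0, converged = TRUE))
  }
  scale_ref <- max(diag(S))
  omega <- diag(1 / diag(S), p)
  if (!is.null(omega_start)) {
    cand <- omega_start * E
    diag(cand) <- diag(omega_start)
    ch <- tryCatch(chol(cand), error = function(e) NULL)
    if (!is.null(ch)) omega <- cand
  }
  sigma <- chol2inv(chol(omega))
  inv2 <- function(M) {
    d <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
    matrix(c(M[2, 2], -M[1, 2], -M[2, 1], M[1, 1]), 2) / d
  }
  # Woodbury: adding delta on block a of omega updates sigma at O(p^2);
  # sigma is refreshed from omega once per sweep to stop numerical drift
  apply_update <- function(a, delta) {
    omega[a, a] <<- omega[a, a] + delta
    upd <- tryCatch({
      Sa <- sigma[, a, drop = FALSE]
      M <- solve(diag(length(a)) + delta %*% sigma[a, a, drop = FALSE], delta)
      sigma - Sa %*% M %*% t(Sa)
    }, error = function(e) NULL)
    sigma <<- if (is.null(upd)) chol2inv(chol(omega)) else upd
  }
  converged <- FALSE
  it <- 0
  dev <- Inf
  repeat {
    it <- it + 1
    sigma <- chol2inv(chol(omega))
    for (i in seq_len(p)) {
      d <- 1 / S[i, i] - 1 / sigma[i, i]
      if (abs(d) > 1e-16) apply_update(i, matrix(d, 1, 1))
    }
    for (e in edges) {
      delta <- inv2(S[e, e]) - inv2(sigma[e, e])
      apply_update(e, delta)
    }
    dev <- max(abs(diag(sigma) - diag(S)))
    if (length(edges)) {
      idx <- do.call(rbind, edges)
      dev <- max(dev, abs(sigma[idx] - S[idx]))
    }
    if (dev < tol * scale_ref) { converged <- TRUE; break }
    if (it >= maxit) break
  }
  if (!converged && it >= maxit) {
    stop("constrained MLE did not converge; last deviation = ",
         format(dev, digits = 4))
  }
  sigma <- chol2inv(chol(omega))  # refresh accumulated Woodbury error
  omega[!E & row(E) != col(E)] <- 0  # exact zeros off the graph
  omega <- (omega + t(omega)) / 2
  dimnames(omega) <- dimnames(S)
  list(omega = omega, sigma = sigma, edges = edges,
       loglik_terms = as.numeric(determinant(omega)$modulus) - sum(S * omega),
       iterations = it, converged = converged)
}

#' Extended BIC of a fitted Gaussian graphical model
#'
#' `-2 loglik + df log n + 4 gamma |E| log p` with `df = p + |E|`
#' (free precision entries); `gamma = 0` reduces to the ordinary BIC.
#'
#' @param S Covariance; @param omega Precision; @param n Sample size;
#' @param n_edges Edge count; @param gamma EBIC hyperparameter.
#' @return EBIC value (smaller is better).
#' @export
ebic <- function(S, omega, n, n_edges, gamma = 0) {
  p <- nrow(S)
  ll <- gauss_loglik(S, omega, n)
  -2 * ll + (p + n_edges) * log(n) + 4 * gamma * n_edges * log(p)
}

#' Glasso regularisation path
#'
#' @param S Covariance; @param n_lambda Path length;
#' @param lambda_min_ratio Smallest lambda as a fraction of
#'   `lambda_max = max |off-diagonal S|`.
#' @return List of `glasso_fit` results, decreasing lambda.
#' @export
glasso_path <- function(S, n_lambda = 100, lambda_min_ratio = 0.01) {
  lam_max <- max(abs(S[upper.tri(S)]))
  lambdas <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                     length.out = n_lambda))
  lapply(lambdas, function(l) glasso_fit(S, l))
}

edge_key <- function(edges) {
  if (!length(edges)) return("")
  paste(vapply(edges, function(e) paste(sort(e), collapse = "-"),
               character(1)), collapse = ",")
}

#' Stepwise unregularised GGM selection
#'
#' Model search in two stages, both scored on unregularised
#' (zero-constrained MLE) refits: (1) the EBIC(`gamma_path`)-best graph on
#' a `n_lambda`-point glasso path seeds the search; (2) all single-edge
#' additions and removals are evaluated and the best EBIC(`gamma`)
#' improvement accepted until none remains. Ties within `1e-9` prefer
#' removal over addition, then lexicographic node order.
#'
#' @param S Positive-definite ML covariance.
#' @param n Sample size (must exceed the node count).
#' @param gamma EBIC hyperparameter for the stepwise stage (0 = BIC).
#' @param gamma_path EBIC hyperparameter for the path start.
#' @param n_lambda,lambda_min_ratio Path controls.
#' @return Object of class `precision_model`: list with `omega`, `sigma`,
#'   `edges`, `r_p` (partial-correlation matrix), `loglik`, `ebic`,
#'   `ebic_start`, `gamma`, `lambda = 0`, `path` (lambda/edge-count/EBIC
#'   trace) and `steps` (accepted moves).
#' @export
stepwise_select <- function(S, n, gamma = 0, gamma_path = 0.5,
                            n_lambda = 100, lambda_min_ratio = 0.01) {
  S <- as.matrix(S)
  p <- nrow(S)
  if (n <= p) stop("need n > p")
  path <- glasso_path(S, n_lambda, lambda_min_ratio)
  cache <- new.env(parent = emptyenv())
  refit <- function(edges, warm = NULL) {
    key <- edge_key(edges)
    if (!is.null(cache[[paste0("k", key)]])) return(cache[[paste0("k", key)]])
    fit <- constrained_mle(S, edges, omega_start = warm)
    cache[[paste0("k", key)]] <- fit
    fit
  }
  path_trace <- data.frame(lambda = numeric(0), n_edges = integer(0),
                           ebic = numeric(0))
  best_start <- NULL; best_start_ebic <- Inf
  for (g in path) {
    fit <- refit(g$edges, warm = g$omega)
    val <- ebic(S, fit$omega, n, length(g$edges), gamma_path)
    path_trace <- rbind(path_trace,
                        data.frame(lambda = g$lambda,
                                   n_edges = length(g$edges), ebic = val))
    if (val < best_start_ebic - 1e-12) {
      best_start_ebic <- val
      best_start <- fit
    }
  }
  current <- best_start
  current_ebic <- ebic(S, current$omega, n, length(current$edges), gamma)
  start_ebic <- current_ebic
  all_pairs <- list()
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    all_pairs[[length(all_pairs) + 1]] <- c(i, j)
  }
  steps <- list()
  repeat {
    in_graph <- vapply(all_pairs, function(e)
      any(vapply(current$edges, function(f) all(f == e), TRUE)), TRUE)
    best_move <- NULL; best_val <- current_ebic - 1e-9
    # removals first so equal-improvement ties resolve to removal,
    # then lexicographic pair order within each move type
    ord <- c(which(in_graph), which(!in_graph))
    for (k in ord) {
      e <- all_pairs[[k]]
      new_edges <- if (in_graph[k]) {
        Filter(function(f) !all(f == e), current$edges)
      } else {
        c(current$edges, list(e))
      }
      fit <- refit(new_edges, warm = current$omega)
      val <- ebic(S, fit$omega, n, length(new_edges), gamma)
      if (val < best_val - 1e-9) {
        best_val <- val
        best_move <- list(fit = fit, edge = e,
                          action = if (in_graph[k]) "remove" else "add")
      }
    }
    if (is.null(best_move)) break
    current <- best_move$fit
    current_ebic <- best_val
    steps[[length(steps) + 1]] <- list(action = best_move$action,
                                       edge = best_move$edge,
                                       ebic = current_ebic)
  }
  stopifnot(current_ebic <= start_ebic + 1e-9)
  structure(list(omega = current$omega, sigma = current$sigma,
                 edges = current$edges,
                 r_p = partial_correlations(current$omega),
                 loglik = gauss_loglik(S, current$omega, n),
                 ebic = current_ebic, ebic_start = start_ebic,
                 gamma = gamma, gamma_path = gamma_path, lambda = 0,
                 n = n, path = path_trace, steps = steps),
            class = "precision_model")
}

#' Partial correlations from a precision matrix
#'
#' `r_p(i, j) = -omega_ij / sqrt(omega_ii * omega_jj)`; the diagonal is set
#' to zero so the matrix can be used directly as network weights. Entries
#' are exactly zero wherever the precision entry is zero (absent edge).
#'
#' @param omega Positive-definite precision matrix.
#' @return Symmetric matrix of partial correlations, zero diagonal.
#' @export
partial_correlations <- function(omega) {
  if (inherits(omega, "precision_model")) omega <- omega$omega
  d <- sqrt(diag(omega))
  rp <- -omega / tcrossprod(d)
  diag(rp) <- 0
  (rp + t(rp)) / 2
}

#' @export
print.precision_model <- function(x, ...) {
  cat("Gaussian graphical model:", nrow(x$omega), "nodes,",
      length(x$edges), "edges; EBIC(gamma =", x$gamma, ") =",
      format(x$ebic, digits = 6), "\n")
  invisible(x)
}

#' Fit the partial-correlation network of log involvement scores
#'
#' Convenience wrapper: takes a matrix/data frame of log-transformed
#' involvement scores, keeps complete rows, fits the glasso-path +
#' stepwise GGM and returns it together with a `weighted_network` view
#' (weights = partial correlations, mask = selected edges).
#'
#' @param logscores Numeric matrix or data frame (columns = substances).
#' @param gamma,gamma_path See [stepwise_select()].
#' @param drop_constant Drop zero-variance columns (with a warning)?
#' @return List with `model` (`precision_model`), `network`
#'   (`weighted_network`), `n_used`, `nodes`.
#' @export
fit_ggm <- function(logscores, gamma = 0, gamma_path = 0.5,
                    drop_constant = TRUE) {
  x <- as.matrix(as.data.frame(logscores))
  keep <- complete.cases(x)
  x <- x[keep, , drop = FALSE]
  v <- apply(x, 2, var)
  if (drop_constant && any(v < .Machine$double.eps)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(x)[v < .Machine$double.eps], collapse = ", "))
    x <- x[, v >= .Machine$double.eps, drop = FALSE]
  }
  S <- cov_ml(x)
  model <- stepwise_select(S, nrow(x), gamma = gamma, gamma_path = gamma_path)
  W <- model$r_p
  mask <- abs(W) > 0
  net <- structure(list(nodes = colnames(x), weights = W, p = NULL,
                        mask = mask, mean_r = mean(W[upper.tri(W)]),
                        dropped = character(0), type = "partial"),
                   class = "weighted_network")
  list(model = model, network = net, n_used = nrow(x), nodes = colnames(x))
}
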