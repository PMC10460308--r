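# ---- Nonmetric multidimensional scaling layout ---------------------------

#' Kruskal stress-1
#'
#' @param d Fitted configuration distances (vector).
#' @param dhat Disparities (monotone-regressed dissimilarities).
#' @return `sqrt(sum((d - dhat)^2) / sum(d^2))`.
#' @export
stress1 <- function(d, dhat) sqrt(sum((d - dhat)^2) / sum(d^2))

# Monotone (isotonic) regression of configuration distances on the rank
# order of the input dissimilarities. Kruskal's primary approach to ties:
# within a tied block of dissimilarities the distances are free to order
# themselves, so the block is pre-sorted by distance before pooling.
monotone_disparities <- function(delta, d) {
  ord <- order(delta, d)
  fit <- isoreg(seq_along(ord), d[ord])$yf
  dhat <- numeric(length(d))
  dhat[ord] <- fit
  dhat
}

#' Nonmetric MDS layout of a weighted network
#'
#' Embeds nodes in the plane so that stronger associations sit closer
#' together. Dissimilarities are `sqrt(2 * (1 - w))`; the configuration is
#' found by alternating monotone regression (Kruskal's primary tie
#' handling) with the Guttman majorization transform, started from
#' classical scaling. Iteration stops when stress-1 decreases by less than
#' `tol` (a step that would increase stress is rejected, so the reported
#' stress trace is non-increasing).
#'
#' @param net `weighted_network` object, or a symmetric weight matrix.
#' @param seed Integer seed (used only to jitter a rank-degenerate classical
#'   start; the algorithm is otherwise deterministic).
#' @param ndim Embedding dimension.
#' @param maxit,tol Iteration controls.
#' @return Object of class `mds_layout`: list with `points` (n x ndim
#'   matrix), `stress` (final stress-1), `trace` (stress per iteration) and
#'   `dissimilarities`.
#' @export
mds_layout <- function(net, seed = 1L, ndim = 2, maxit = 200, tol = 1e-9) {
  W <- if (inherits(net, "weighted_network")) net$weights else as.matrix(net)
  nodes <- rownames(W)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(nrow(W)))
  D <- sqrt(2 * (1 - W))
  diag(D) <- 0
  if (any(!is.finite(D))) {
    bad <- which(!is.finite(D) & upper.tri(D), arr.ind = TRUE)
    stop("non-finite dissimilarity for pair(s): ",
         paste(apply(bad, 1, function(ij)
           paste(nodes[ij[1]], nodes[ij[2]], sep = "--")), collapse = ", "))
  }
  n <- nrow(D)
  X <- cmdscale(D, k = ndim)
  if (ncol(X) < ndim || qr(scale(X, scale = FALSE))$rank < ndim) {
    set.seed(seed)
    X <- cbind(X, matrix(0, n, ndim - ncol(X)))
    X <- X + matrix(rnorm(n * ndim, sd = 1e-4 * (max(D) + 1e-12)), n, ndim)
  }
  delta <- D[lower.tri(D)]
  pair_i <- row(D)[lower.tri(D)]
  pair_j <- col(D)[lower.tri(D)]
  conf_dist <- function(X) {
    sqrt(rowSums((X[pair_i, , drop = FALSE] - X[pair_j, , drop = FALSE])^2))
  }
  d <- conf_dist(X)
  dhat <- monotone_disparities(delta, d)
  s <- stress1(d, dhat)
  trace <- s
  for (it in seq_len(maxit)) {
    # Guttman transform with current disparities
    ratio <- ifelse(d > 0, dhat / d, 0)
    B <- matrix(0, n, n)
    B[cbind(pair_i, pair_j)] <- -ratio
    B[cbind(pair_j, pair_i)] <- -ratio
    diag(B) <- -rowSums(B)
    X_new <- B %*% X / n
    d_new <- conf_dist(X_new)
    dhat_new <- monotone_disparities(delta, d_new)
    s_new <- stress1(d_new, dhat_new)
    if (!is.finite(s_new) || s_new > s + 1e-15) break
    X <- X_new; d <- d_new; dhat <- dhat_new
    improved <- s - s_new
    s <- s_new
    trace <- c(trace, s)
    if (improved < tol) break
  }
  rownames(X) <- nodes
  colnames(X) <- paste0("dim", seq_len(ndim))
  structure(list(points = X, stress = s, trace = trace,
                 dissimilarities = D), class = "mds_layout")
}

#' @export
print.mds_layout <- function(x, ...) {
  cat("Nonmetric MDS layout:", nrow(x$points), "nodes, stress-1 =",
      format(x$stress, digits = 4), "\n")
  invisible(x)
}
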