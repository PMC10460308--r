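# ---- Tetrachoric correlation and Fisher-exact edge filtering --------------

# Upper-orthant probability P(X > h, Y > k) for standard bivariate normal
# with correlation rho.
binorm_upper <- function(h, k, rho) {
  if (abs(rho) >= 1) rho <- sign(rho) * 0.999999
  mvtnorm::pmvnorm(lower = c(h, k), upper = c(Inf, Inf),
                   corr = matrix(c(1, rho, rho, 1), 2))[1]
}

#' Tetrachoric correlation of a 2x2 table
#'
#' Two-step maximum-likelihood estimator: thresholds are fixed at the
#' standard-normal quantiles of the (continuity-corrected) margins, then the
#' latent correlation maximises the multinomial likelihood of the table
#' under a bivariate-normal model. Rows and columns are oriented so the
#' first row/column is the "positive" category.
#'
#' @param table 2x2 matrix of non-negative integer counts `[[a,b],[c,d]]`;
#'   `a` counts joint positives.
#' @return Object of class `tetrachoric`: list with `r` (estimate, `NA` with
#'   a `note` when a margin of the original table is empty), `tau_row`,
#'   `tau_col` (thresholds), `table`, `p_fisher` (two-sided Fisher exact
#'   p-value of the original table) and `corrected` (continuity correction
#'   applied?).
#' @export
tetrachoric <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    stop("'table' must be a 2x2 matrix of non-negative integer counts")
  }
  n <- sum(tab)
  if (n < 4) stop("total count must be at least 4")
  p_fisher <- fisher_exact(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(structure(list(r = NA_real_, tau_row = NA_real_, tau_col = NA_real_,
                          table = tab, p_fisher = p_fisher, corrected = FALSE,
                          note = "empty margin: latent correlation undefined"),
                     class = "tetrachoric"))
  }
  corrected <- any(tab == 0)
  tc <- if (corrected) tab + 0.5 else tab
  nc <- sum(tc)
  # thresholds: latent exceeds tau for the first ("positive") category
  p_row <- sum(tc[1, ]) / nc
  p_col <- sum(tc[, 1]) / nc
  tau_row <- qnorm(1 - p_row)
  tau_col <- qnorm(1 - p_col)
  if (tab[1, 1] * tab[2, 2] == tab[1, 2] * tab[2, 1]) {
    r <- 0
  } else {
    negll <- function(rho) {
      p11 <- binorm_upper(tau_row, tau_col, rho)
      p1. <- 1 - pnorm(tau_row)
      p.1 <- 1 - pnorm(tau_col)
      p10 <- p1. - p11
      p01 <- p.1 - p11
      p00 <- 1 - p1. - p.1 + p11
      eps <- 1e-12
      -(tc[1, 1] * log(max(p11, eps)) + tc[1, 2] * log(max(p10, eps)) +
          tc[2, 1] * log(max(p01, eps)) + tc[2, 2] * log(max(p00, eps)))
    }
    r <- optimize(negll, interval = c(-0.9999, 0.9999), tol = 1e-8)$minimum
  }
  structure(list(r = r, tau_row = tau_row, tau_col = tau_col, table = tab,
                 p_fisher = p_fisher, corrected = corrected, note = NULL),
            class = "tetrachoric")
}

#' @export
print.tetrachoric <- function(x, ...) {
  cat("Tetrachoric correlation: r =", format(x$r, digits = 4),
      " (Fisher p =", format(x$p_fisher, digits = 3), ")\n")
  invisible(x)
}

#' Two-sided Fisher exact test p-value
#'
#' Point-probability rule: sums hypergeometric probabilities of all tables
#' with the same margins that are no more probable than the observed one.
#' Degenerate tables (an empty margin) give p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return p-value in \[0, 1\].
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    stop("'table' must be a 2x2 matrix of non-negative integer counts")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Zero-order tetrachoric network of binary indicators
#'
#' Pairwise tetrachoric correlations on pairwise-complete rows, with an
#' edge-display mask from the two-sided Fisher exact test. Constant columns
#' (and columns with fewer than `min_n` complete pairs with every partner)
#' cannot support an estimate and are dropped with a warning.
#'
#' @param indicators Data frame or matrix of logical/0-1 columns.
#' @param alpha Display threshold for the Fisher exact p-value.
#' @param min_n Minimum pairwise-complete count for estimation.
#' @return Object of class `weighted_network`: list with `nodes`, `weights`
#'   (symmetric tetrachoric matrix, diagonal 1), `p` (Fisher p matrix),
#'   `mask` (symmetric logical display matrix), `mean_r` (mean off-diagonal
#'   estimate over estimable pairs), `n_pairwise`, `dropped` and
#'   `type = "tetrachoric"`.
#' @export
build_zero_order_network <- function(indicators, alpha = 0.05, min_n = 10) {
  m <- as.data.frame(indicators)
  m <- m[, vapply(m, function(x) is.logical(x) || is.numeric(x), TRUE),
         drop = FALSE]
  x <- as.matrix(m) * 1
  const <- apply(x, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) == 0 || length(unique(v)) < 2
  })
  dropped <- colnames(x)[const]
  if (length(dropped)) {
    warning("dropping constant indicator column(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  p <- ncol(x)
  if (p < 2) stop("need at least 2 non-constant indicator columns")
  nodes <- colnames(x)
  W <- diag(1, p); P <- matrix(NA_real_, p, p); N <- matrix(0L, p, p)
  dimnames(W) <- dimnames(P) <- dimnames(N) <- list(nodes, nodes)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ok <- !is.na(x[, i]) & !is.na(x[, j])
      N[i, j] <- N[j, i] <- sum(ok)
      if (sum(ok) < min_n) next
      xi <- x[ok, i]; xj <- x[ok, j]
      tab <- matrix(c(sum(xi == 1 & xj == 1), sum(xi == 1 & xj == 0),
                      sum(xi == 0 & xj == 1), sum(xi == 0 & xj == 0)),
                    2, 2, byrow = TRUE)
      est <- tetrachoric(tab)
      W[i, j] <- W[j, i] <- est$r
      P[i, j] <- P[j, i] <- est$p_fisher
    }
  }
  mask <- !is.na(P) & P < alpha
  off <- W[upper.tri(W)]
  structure(list(nodes = nodes, weights = W, p = P, mask = mask,
                 mean_r = mean(off, na.rm = TRUE), n_pairwise = N,
                 dropped = dropped, alpha = alpha, type = "tetrachoric"),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("Weighted network (", x$type, "): ", length(x$nodes), " nodes, ",
      sum(x$mask[upper.tri(x$mask)]), " displayed edges",
      if (!is.null(x$mean_r)) paste0(", mean off-diagonal r = ",
                                     format(x$mean_r, digits = 3)), "\n",
      sep = "")
  invisible(x)
}
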