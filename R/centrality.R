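# ---- Weighted-network centrality ------------------------------------------

#' Node centrality indices of a weighted network
#'
#' Local indices: strength (sum of absolute edge weights) and expected
#' influence (sum of signed edge weights). Global indices use geodesics
#' with edge length `1/|weight|`: closeness is the reciprocal of the total
#' geodesic distance to reachable nodes (per-component convention, flagged
#' when the network is disconnected) and betweenness is the standard
#' shortest-path count with equal splitting over tied geodesics. Masked or
#' zero-weight edges are absent (infinite length).
#'
#' @param net `weighted_network` object or symmetric weight matrix.
#' @param use_mask Apply the display mask (if present) before computing?
#' @return Object of class `centrality_profile`: data frame with columns
#'   `node`, `strength`, `expected_influence`, `closeness`, `betweenness`
#'   and z-standardised versions `z_*`; attribute `disconnected` flags a
#'   non-connected network.
#' @export
centrality_indices <- function(net, use_mask = TRUE) {
  if (inherits(net, "weighted_network")) {
    W <- net$weights
    if (use_mask && !is.null(net$mask)) W <- W * net$mask
  } else {
    W <- as.matrix(net)
  }
  diag(W) <- 0
  if (any(is.na(W))) stop("weight matrix contains NA")
  if (all(W == 0)) stop("all edge weights are zero: no defined geodesics")
  nodes <- rownames(W)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(nrow(W)))
  strength <- rowSums(abs(W))
  ei <- rowSums(W)
  A <- abs(W)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- 1 / igraph::E(g)$weight
  D <- igraph::distances(g, weights = len)
  disconnected <- any(!is.finite(D))
  closeness <- vapply(seq_len(nrow(D)), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) return(0)
    1 / sum(d)
  }, numeric(1))
  betweenness <- igraph::betweenness(g, weights = len, directed = FALSE)
  z <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  out <- data.frame(node = nodes, strength = strength,
                    expected_influence = ei, closeness = closeness,
                    betweenness = as.numeric(betweenness),
                    z_strength = z(strength), z_expected_influence = z(ei),
                    z_closeness = z(closeness), z_betweenness = z(betweenness),
                    row.names = NULL)
  attr(out, "disconnected") <- disconnected
  class(out) <- c("centrality_profile", "data.frame")
  out
}

#' Rank substances by centrality
#'
#' Orders nodes per index (descending, lexicographic tie-break) and names
#' nodes that are top-ranked on at least three of the four indices.
#'
#' @param profile `centrality_profile` from [centrality_indices()].
#' @return List with `ranking` (list of node-name vectors per index),
#'   `ties` (per index, `TRUE` if the top value is tied), `top_nodes`
#'   (nodes first on >= 3 indices).
#' @export
rank_substances <- function(profile) {
  idx <- c("strength", "expected_influence", "closeness", "betweenness")
  ranking <- list(); ties <- logical(0); firsts <- character(0)
  for (k in idx) {
    v <- profile[[k]]
    ord <- order(-v, profile$node)
    ranking[[k]] <- profile$node[ord]
    ties[k] <- sum(v == max(v)) > 1
    firsts <- c(firsts, ranking[[k]][1])
  }
  tab <- table(firsts)
  list(ranking = ranking, ties = ties,
       top_nodes = names(tab)[tab >= 3])
}
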