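# Small in-code fixtures.

# one-participant cohort row with the given ASSIST answers, e.g.
# make_cohort_row(cannabis = list(q2 = "daily_or_almost_daily", q3 = "never"))
make_cohort_row <- function(..., n = 1) {
  answers <- list(...)
  out <- data.frame(participant_id = seq_len(n))
  for (s in assist_substances()) {
    for (it in assist_items(s)) {
      v <- answers[[s]][[it]]
      if (is.null(v)) v <- "never"
      out[[paste0(s, "_", it)]] <- rep(v, n)
    }
  }
  out
}

# maximal answers for one substance
max_answers <- function() {
  list(q2 = "daily_or_almost_daily", q3 = "daily_or_almost_daily",
       q4 = "daily_or_almost_daily", q5 = "daily_or_almost_daily",
       q6 = "yes_past_3mo", q7 = "yes_past_3mo")
}

# small star-shaped weight matrix: node 1 is the hub
star_network <- function(p = 5, w = 0.5) {
  W <- matrix(0, p, p)
  W[1, 2:p] <- w; W[2:p, 1] <- w
  rownames(W) <- colnames(W) <- paste0("n", seq_len(p))
  W
}

random_weighted_graph <- function(p = 6, density = 0.6) {
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (runif(1) < density) {
      W[i, j] <- W[j, i] <- runif(1, 0.1, 0.9) * sample(c(-1, 1), 1)
    }
  }
  rownames(W) <- colnames(W) <- paste0("n", seq_len(p))
  W
}
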