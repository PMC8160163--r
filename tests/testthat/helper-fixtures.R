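# Shared fixtures and independent oracles, built in code at test time.

# Hand-assembled match record: segments given as (kind, duration) pairs,
# attack onsets on the combat clock.
make_match <- function(kinds, durations, onsets_combat = numeric(0)) {
  seg <- data.frame(kind = kinds, duration = durations,
                    stringsAsFactors = FALSE)
  seg$start_wall <- cumsum(c(0, durations[-length(durations)]))
  structure(list(segments = seg,
                 attacks = data.frame(onset_combat = onsets_combat),
                 shido_count = 0L),
            class = "judo_match")
}

# Brute-force Friedman statistic: explicit within-block ranking and the
# classical (untied) rank-sum formula. Valid oracle for tables without
# within-block ties.
friedman_bruteforce <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- matrix(0, n, k)
  for (i in seq_len(n)) r[i, ] <- rank(m[i, ])
  Rj <- colSums(r)
  12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
}

# Random connected-ish weighted graph on n nodes for PageRank checks.
random_graph <- function(n, p_edge = 0.3) {
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  if (!any(keep)) keep[sample.int(ncol(pairs), 1)] <- TRUE
  edges <- data.frame(from = nodes[pairs[1, keep]],
                      to = nodes[pairs[2, keep]],
                      rho = stats::runif(sum(keep), 0.2, 1) *
                        sample(c(-1, 1), sum(keep), replace = TRUE),
                      stringsAsFactors = FALSE)
  correlation_graph(nodes, edges)
}

# Dense damped transition matrix of a correlation_graph, for checking that
# the returned PageRank vector is stationary.
transition_matrix <- function(graph, damping = 0.85) {
  nodes <- graph$nodes
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (e in seq_len(nrow(graph$edges))) {
    i <- match(graph$edges$from[e], nodes)
    j <- match(graph$edges$to[e], nodes)
    W[i, j] <- W[i, j] + graph$edges$weight[e]
    W[j, i] <- W[j, i] + graph$edges$weight[e]
  }
  s <- rowSums(W)
  P <- matrix(1 / n, n, n)   # dangling rows: uniform
  P[s > 0, ] <- W[s > 0, , drop = FALSE] / s[s > 0]
  damping * P + (1 - damping) / n
}
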