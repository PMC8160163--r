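## Significance-filtered Spearman correlation graphs and centrality.

#' Build a correlation graph for one scenario
#'
#' For every unordered pair of parameter columns, computes the Spearman
#' correlation and its two-sided p-value (see \code{\link{spearman_test}});
#' an undirected edge joins the pair iff the correlation is defined and
#' p <= alpha. Edge weight is |rho| (PageRank needs nonnegative weights);
#' the correlation sign is kept as an edge attribute. Every parameter stays
#' in the node set even when isolated (constant columns, for instance,
#' yield undefined correlations and no incident edges). Raw per-pair
#' p-values are used with no multiple-testing correction across the 1326
#' pairs, mirroring the original per-edge p <= 0.05 rule; reports flag the
#' threshold as uncorrected.
#'
#' @param dataset Data frame for one scenario: optional \code{athlete}
#'   column plus numeric parameter columns (normally the 52 catalog codes).
#' @param alpha Per-edge significance level in (0, 1]; default 0.05.
#' @param method p-value method passed to \code{\link{spearman_test}};
#'   default \code{"auto"} (exact enumeration for n <= 8, t approximation
#'   above).
#' @param scenario Label stored on the graph.
#' @return A \code{correlation_graph}: list with \code{scenario},
#'   \code{nodes}, \code{alpha}, \code{method}, and \code{edges} (data
#'   frame: from, to, rho, p, n, weight, sign; from < to in node order).
#' @export
build_graph <- function(dataset, alpha = 0.05, method = "auto",
                        scenario = NA_character_) {
  stopifnot(alpha > 0, alpha <= 1)
  cols <- setdiff(names(dataset), "athlete")
  x <- as.data.frame(dataset)[cols]
  np <- length(cols)
  from <- character(); to <- character(); rho <- numeric()
  p <- numeric(); nn <- integer()
  for (i in seq_len(np - 1L)) {
    for (j in seq((i + 1L), np)) {
      xi <- x[[i]]; xj <- x[[j]]
      ok <- stats::complete.cases(xi, xj)
      if (sum(ok) < 4) next  # pairwise deletion; too few pairs -> no edge
      ct <- spearman_test(xi[ok], xj[ok], method = method)
      if (is.na(ct$rho) || is.na(ct$p_value)) next
      if (ct$p_value <= alpha) {
        from <- c(from, cols[i]); to <- c(to, cols[j])
        rho <- c(rho, ct$rho); p <- c(p, ct$p_value); nn <- c(nn, ct$n)
      }
    }
  }
  edges <- data.frame(from = from, to = to, rho = rho, p = p, n = nn,
                      weight = abs(rho), sign = sign(rho),
                      stringsAsFactors = FALSE)
  structure(list(scenario = scenario, nodes = cols, alpha = alpha,
                 method = method, edges = edges),
            class = "correlation_graph")
}

#' Construct a correlation graph from explicit parts
#'
#' Low-level constructor used by tests and importers: supply the node set
#' and an edge data frame (\code{from}, \code{to}, optionally \code{rho},
#' \code{p}, \code{weight}).
#'
#' @param nodes Character vector of node labels.
#' @param edges Data frame of edges; unknown endpoints are an error.
#' @param scenario Optional label.
#' @return A \code{correlation_graph}.
#' @export
correlation_graph <- function(nodes, edges = NULL, scenario = NA_character_) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        rho = numeric(), p = numeric(), n = integer(),
                        weight = numeric(), sign = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    stopifnot(all(edges$from %in% nodes), all(edges$to %in% nodes),
              all(edges$from != edges$to))
    if (is.null(edges$rho)) edges$rho <- 1
    if (is.null(edges$weight)) edges$weight <- abs(edges$rho)
    if (is.null(edges$p)) edges$p <- NA_real_
    if (is.null(edges$n)) edges$n <- NA_integer_
    if (is.null(edges$sign)) edges$sign <- sign(edges$rho)
    stopifnot(all(edges$weight > 0))
  }
  structure(list(scenario = scenario, nodes = nodes, alpha = NA_real_,
                 method = NA_character_, edges = edges),
            class = "correlation_graph")
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat("correlation_graph", if (!is.na(x$scenario)) paste0("[", x$scenario, "]"),
      "-", length(x$nodes), "nodes,", nrow(x$edges), "edges",
      if (!is.na(x$alpha)) paste0("(alpha = ", x$alpha, ")"), "\n")
  invisible(x)
}

#' Degree centrality
#'
#' Unweighted incident-edge count per node ("the number of edges of the
#' node"). Sums to twice the edge count over all nodes.
#'
#' @param graph A \code{correlation_graph}.
#' @return Named integer vector over all nodes (isolated nodes get 0).
#' @export
degree_centrality <- function(graph) {
  d <- integer(length(graph$nodes))
  names(d) <- graph$nodes
  if (nrow(graph$edges)) {
    t1 <- table(factor(graph$edges$from, levels = graph$nodes))
    t2 <- table(factor(graph$edges$to, levels = graph$nodes))
    d <- as.integer(t1 + t2)
    names(d) <- graph$nodes
  }
  d
}

#' Weighted PageRank on an undirected graph
#'
#' Power iteration for the damped random walk: each undirected edge acts
#' as two directed edges; the walk leaves node i for neighbour j with
#' probability \code{w_ij / sum_k w_ik}; isolated (dangling) nodes
#' redistribute their mass uniformly over all nodes. Iteration starts from
#' the uniform vector and stops when the L1 change drops below \code{tol};
#' the result sums to 1 and is the stationary distribution of the damped
#' transition matrix.
#'
#' @param graph A \code{correlation_graph}.
#' @param damping Damping factor in (0, 1); default 0.85.
#' @param tol L1 convergence tolerance; default 1e-9.
#' @param max_iter Iteration cap; exceeding it is an error (with the last
#'   residual in the message).
#' @return Named numeric vector of probability masses over all nodes.
#' @export
pagerank <- function(graph, damping = 0.85, tol = 1e-9, max_iter = 1000L) {
  stopifnot(damping > 0, damping < 1, tol > 0)
  nodes <- graph$nodes
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph$edges)) {
    ii <- match(graph$edges$from, nodes)
    jj <- match(graph$edges$to, nodes)
    for (e in seq_along(ii)) {
      W[ii[e], jj[e]] <- W[ii[e], jj[e]] + graph$edges$weight[e]
      W[jj[e], ii[e]] <- W[jj[e], ii[e]] + graph$edges$weight[e]
    }
  }
  s <- rowSums(W)
  dangling <- s == 0
  P <- W
  P[!dangling, ] <- W[!dangling, , drop = FALSE] / s[!dangling]
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    xn <- (1 - damping) / n +
      damping * (as.numeric(crossprod(P, x)) + sum(x[dangling]) / n)
    res <- sum(abs(xn - x))
    x <- xn
    if (res < tol) {
      names(x) <- nodes
      return(x / sum(x))
    }
  }
  stop(sprintf("pagerank did not converge in %d iterations (last L1 residual %.3e)",
               max_iter, res))
}

#' Tie-aware top-k ranking
#'
#' Sorts a per-node metric in descending order, assigns competition ranks
#' (equal values share the rank of their first member), and cuts after the
#' k-th node, extending the cut to every node whose value ties the k-th
#' value. Integer metrics (Degree) compare exactly; real-valued metrics
#' (PageRank) tie within a relative tolerance. The default k for the
#' 52-node networks is 10% of the nodes: \code{max(1, round(0.10 * 52)) = 5}.
#'
#' @param values Named numeric vector (one entry per node).
#' @param k Base cut size (>= 1).
#' @param tol_rel Relative tie tolerance for non-integer metrics.
#' @return A data frame sorted by value descending with columns
#'   \code{node}, \code{value}, \code{rank}, \code{in_top_k}; attributes
#'   \code{k} and \code{metric}.
#' @export
top_k_with_ties <- function(values, k = default_top_k(length(values)),
                            tol_rel = 1e-9) {
  stopifnot(k >= 1, !is.null(names(values)))
  ord <- order(-values, names(values))  # value desc, label for stable output
  v <- values[ord]
  n <- length(v)
  tol <- if (all(v == round(v))) 0 else tol_rel * pmax(1, abs(v))
  ## competition ranks: new group when the value drops by more than tol
  rank_out <- integer(n)
  rank_out[1] <- 1L
  for (i in seq_len(n)[-1]) {
    rank_out[i] <- if (v[i - 1] - v[i] <= tol[min(i, length(tol))])
      rank_out[i - 1] else i
  }
  kk <- min(k, n)
  cut_value <- v[kk]
  in_top <- v >= cut_value - (if (length(tol) == 1) tol else tol[kk])
  out <- data.frame(node = names(v), value = as.numeric(v),
                    rank = rank_out, in_top_k = in_top,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "k") <- k
  out
}

#' Default top-k cut: 10% of the node count
#' @param n_nodes Number of nodes.
#' @return \code{max(1, round(0.10 * n_nodes))}; 5 for the 52-node networks.
#' @export
default_top_k <- function(n_nodes = 52L) max(1L, round(0.10 * n_nodes))

#' Degree and PageRank table for a graph
#'
#' @param graph A \code{correlation_graph}.
#' @param damping,tol,max_iter Passed to \code{\link{pagerank}}.
#' @return Data frame with \code{node}, \code{degree}, \code{pagerank}.
#' @export
centrality_table <- function(graph, damping = 0.85, tol = 1e-9,
                             max_iter = 1000L) {
  d <- degree_centrality(graph)
  pr <- pagerank(graph, damping = damping, tol = tol, max_iter = max_iter)
  data.frame(node = graph$nodes, degree = as.integer(d[graph$nodes]),
             pagerank = as.numeric(pr[graph$nodes]),
             stringsAsFactors = FALSE)
}
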