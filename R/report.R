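## Pipeline orchestration and cross-scenario comparison.

#' Percent change in edge count relative to a baseline
#'
#' \code{100 * (e_other - e_base) / e_base}, exact arithmetic on the
#' integer counts; display rounding (one decimal, matching the reporting
#' style) is left to the caller.
#'
#' @param e_base Baseline count (> 0).
#' @param e_other Comparison count.
#' @return Percent change, or \code{NA} with a warning when the baseline
#'   is zero.
#' @examples
#' percent_change(145, 167)  # 15.17241, printed as 15.2
#' @export
percent_change <- function(e_base, e_other) {
  if (e_base == 0) {
    warning("baseline edge count is zero; percent change undefined")
    return(NA_real_)
  }
  100 * (e_other - e_base) / e_base
}

#' Category composition of a top-k set
#'
#' Counts the top-k members of a rank table per catalog category, and
#' returns the ordered member list with category labels.
#'
#' @param ranktable Output of \code{\link{top_k_with_ties}}.
#' @param catalog Parameter catalog.
#' @return List with \code{counts} (named integer vector over the five
#'   categories) and \code{members} (data frame node, value, rank,
#'   category).
#' @export
category_composition <- function(ranktable, catalog = default_catalog()) {
  cats <- c("profile", "physical", "physiological", "psychophysiological",
            "technical_tactical")
  top <- ranktable[ranktable$in_top_k, , drop = FALSE]
  if (nrow(top) > 0 && !all(top$node %in% catalog$code)) {
    stop("unknown node code(s): ",
         paste(setdiff(top$node, catalog$code), collapse = ", "))
  }
  lab <- catalog$category[match(top$node, catalog$code)]
  counts <- table(factor(lab, levels = cats))
  members <- data.frame(node = top$node, value = top$value,
                        rank = top$rank, category = lab,
                        stringsAsFactors = FALSE)
  list(counts = stats::setNames(as.integer(counts), cats),
       members = members)
}

#' Run the full three-scenario network pipeline
#'
#' Either simulates a cohort (\code{config} given) or analyses three
#' existing scenario tables (\code{datasets} given), then: validates the
#' tables against the catalog, builds the significance-filtered Spearman
#' graph per scenario, computes Degree and PageRank, ranks the tie-aware
#' top-k per metric, and assembles the cross-scenario comparison (edge
#' counts, percent change relative to CON, category composition of each
#' top-k set). Optionally writes every artifact (scenario CSVs in simulate
#' mode, GraphML/GEXF/edge-CSV and centrality CSV per scenario, report
#' JSON, log) under \code{out_dir}.
#'
#' @param config A \code{\link{sim_config}} (simulate mode); ignored when
#'   \code{datasets} is supplied.
#' @param datasets Named list of three scenario data frames (analyze mode).
#' @param alpha Per-edge significance level (default 0.05, uncorrected).
#' @param k Top-k base cut; default 10% of the node count.
#' @param damping PageRank damping factor.
#' @param pvalue_method Passed to \code{\link{build_graph}}.
#' @param out_dir Output directory, or \code{NULL} to skip file output.
#' @param formats Graph formats to write, subset of
#'   \code{c("graphml", "gexf", "csv")}.
#' @param validate Abort on catalog validation failure (default TRUE).
#' @return A \code{scenario_comparison}: list with per-scenario results
#'   (\code{graph}, \code{centrality}, \code{rank_degree},
#'   \code{rank_pagerank}, composition) and the comparison summary.
#' @export
run_pipeline <- function(config = sim_config(), datasets = NULL,
                         alpha = 0.05, k = NULL, damping = 0.85,
                         pvalue_method = "auto", out_dir = NULL,
                         formats = c("graphml", "gexf", "csv"),
                         validate = TRUE) {
  log_lines <- character()
  log_add <- function(...) {
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), ...))
  }
  simulate_mode <- is.null(datasets)
  if (simulate_mode) {
    log_add("simulate mode: n_athletes=", config$n_athletes,
            " seed=", config$seed, " noise_sd=", config$noise_sd)
    datasets <- simulate_cohort(config)
  } else {
    log_add("analyze mode: ", paste(names(datasets), collapse = ", "))
  }
  catalog <- default_catalog()
  viol <- validate_datasets(datasets, catalog)
  if (nrow(viol) > 0 && validate) {
    stop("dataset validation failed:\n",
         paste(utils::capture.output(print(viol)), collapse = "\n"))
  }
  if (is.null(k)) {
    k <- default_top_k(length(setdiff(names(datasets[[1]]), "athlete")))
  }
  log_add("alpha=", alpha, " k=", k, " damping=", damping,
          " pvalue_method=", pvalue_method, " (p-values uncorrected)")
  scen <- names(datasets)
  per <- list()
  for (s in scen) {
    g <- build_graph(datasets[[s]], alpha = alpha, method = pvalue_method,
                     scenario = s)
    ct <- centrality_table(g, damping = damping)
    deg <- stats::setNames(as.numeric(ct$degree), ct$node)
    pr <- stats::setNames(ct$pagerank, ct$node)
    rk_d <- top_k_with_ties(deg, k = k)
    rk_p <- top_k_with_ties(pr, k = k)
    in_catalog <- all(g$nodes %in% catalog$code)
    per[[s]] <- list(
      graph = g, centrality = ct,
      n_edges = nrow(g$edges), n_nodes = length(g$nodes),
      rank_degree = rk_d, rank_pagerank = rk_p,
      composition_degree = if (in_catalog)
        category_composition(rk_d, catalog),
      composition_pagerank = if (in_catalog)
        category_composition(rk_p, catalog))
    log_add(s, ": ", nrow(g$edges), " edges over ", length(g$nodes),
            " nodes")
  }
  counts <- vapply(per, `[[`, numeric(1), "n_edges")
  pc <- if ("CON" %in% scen) {
    vapply(scen, function(s) {
      if (counts[["CON"]] > 0) percent_change(counts[["CON"]], counts[[s]])
      else if (counts[[s]] == 0) 0  # 0 -> 0 edges: no change
      else NA_real_
    }, numeric(1))
  } else rep(NA_real_, length(scen))
  comparison <- data.frame(
    scenario = scen,
    n_edges = as.integer(counts),
    pct_change_vs_CON = as.numeric(pc),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- structure(list(per_scenario = per, comparison = comparison,
                        alpha = alpha, k = k, damping = damping,
                        simulate_mode = simulate_mode,
                        config = if (simulate_mode) config else NULL),
                   class = "scenario_comparison")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (simulate_mode) write_scenario_csvs(datasets, out_dir)
    for (s in scen) {
      g <- per[[s]]$graph
      if ("graphml" %in% formats)
        write_graphml(g, file.path(out_dir, paste0(s, ".graphml")), catalog)
      if ("gexf" %in% formats)
        write_gexf(g, file.path(out_dir, paste0(s, ".gexf")), catalog)
      if ("csv" %in% formats)
        write_edge_csv(g, file.path(out_dir, paste0(s, "_edges.csv")))
      ct <- per[[s]]$centrality
      ct$category <- catalog$category[match(ct$node, catalog$code)]
      ct$degree_rank <- per[[s]]$rank_degree$rank[
        match(ct$node, per[[s]]$rank_degree$node)]
      ct$pagerank_rank <- per[[s]]$rank_pagerank$rank[
        match(ct$node, per[[s]]$rank_pagerank$node)]
      ct$in_top_k <- ct$node %in%
        per[[s]]$rank_degree$node[per[[s]]$rank_degree$in_top_k] |
        ct$node %in%
        per[[s]]$rank_pagerank$node[per[[s]]$rank_pagerank$in_top_k]
      utils::write.csv(ct, file.path(out_dir, paste0(s, "_centrality.csv")),
                       row.names = FALSE)
    }
    write_report_json(out, file.path(out_dir, "report.json"))
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }
  attr(out, "log") <- log_lines
  out
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("Three-scenario correlation-network comparison",
      sprintf("(alpha = %g, uncorrected; k = %d)\n", x$alpha, x$k))
  df <- x$comparison
  df$pct_change_vs_CON <- round(df$pct_change_vs_CON, 1)
  print(df, row.names = FALSE)
  for (s in names(x$per_scenario)) {
    comp <- x$per_scenario[[s]]$composition_degree
    if (is.null(comp)) {
      rk <- x$per_scenario[[s]]$rank_degree
      cat("\n", s, " top-", x$k, " (degree): ",
          paste(rk$node[rk$in_top_k], collapse = ", "), "\n", sep = "")
    } else {
      top <- comp$members
      cat("\n", s, " top-", x$k, " (degree): ",
          paste0(top$node, " (", top$category, ")", collapse = ", "),
          "\n", sep = "")
    }
  }
  invisible(x)
}

#' Serialise a scenario comparison to JSON
#'
#' The report embeds the resolved analysis parameters and, in simulate
#' mode, the seed, for provenance. Parsing the file back yields the same
#' summary structure (round-trip safe).
#'
#' @param comparison A \code{scenario_comparison}.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_report_json <- function(comparison, path) {
  per <- lapply(comparison$per_scenario, function(ps) {
    list(n_nodes = ps$n_nodes,
         n_edges = ps$n_edges,
         top_degree = ps$rank_degree[ps$rank_degree$in_top_k, ],
         top_pagerank = ps$rank_pagerank[ps$rank_pagerank$in_top_k, ],
         category_counts_degree = as.list(ps$composition_degree$counts),
         category_counts_pagerank = as.list(ps$composition_pagerank$counts))
  })
  payload <- list(
    parameters = list(alpha = comparison$alpha, k = comparison$k,
                      damping = comparison$damping,
                      p_values = "uncorrected per pair",
                      seed = if (!is.null(comparison$config))
                        comparison$config$seed else NULL),
    comparison = comparison$comparison,
    scenarios = per)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
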