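# Rendering of loop reports: text, JSON and DOT.

REPORT_SCHEMA_VERSION <- "1.0"

loop_to_list <- function(G, c) {
  list(nodes = dsr_node_name(G, c$nodes),
       edge_signs = ifelse(c$signs > 0, "+", "-"),
       species_count = c$species_count,
       sign = c$sign,
       motif = motif_signature(c))
}

#' @export
print.loop_report <- function(x, ...) {
  cat(report_text(x), sep = "\n")
  invisible(x)
}

#' Human-readable loop report
#'
#' @param rep A \code{loop_report} from [find_relevant_loops()].
#' @param all_loops Also list every positive feedback loop of the graph,
#'   not just the relevant ones.
#' @return Character vector of lines.
#' @export
report_text <- function(rep, all_loops = FALSE) {
  stopifnot(inherits(rep, "loop_report"))
  G <- rep$graph
  p <- rep$polynomial
  lines <- c(
    sprintf("Network: %d species, %d reactions, rank s = %d",
            length(rep$network$species), length(rep$network$reactions), rep$s),
    sprintf("Injectivity polynomial: %d terms (%d positive, %d negative), wrong sign (-1)^(s+1) = %s",
            n_terms(p), sum(p$num > 0), sum(p$num < 0),
            if (rep$s %% 2 == 0) "-" else "+"),
    sprintf("Verdict: %s%s", rep$verdict,
            switch(rep$verdict,
                   INJECTIVE = " (injective on all positive compatibility classes; cannot be multi-stationary)",
                   INCONCLUSIVE = " (terms of both signs; multi-stationarity cannot be excluded)",
                   DEGENERATE = " (polynomial identically zero)")),
    sprintf("Wrong-sign terms: %d", nrow(rep$wrong_sign_terms)))
  for (r in seq_len(nrow(rep$wrong_sign_terms))) {
    key <- rep$wrong_sign_terms$monomial[r]
    kept <- rep$wrong_sign_nuclei[[key]]
    total <- rep$nuclei_by_term[[key]]
    lines <- c(lines, sprintf("  %s (%d nuclei, %d wrong-sign)",
                              rep$wrong_sign_terms$pretty[r],
                              length(total), length(kept)))
  }
  lines <- c(lines, sprintf("Relevant positive feedback loops: %d (of %d positive loops in the DSR-graph)",
                            length(rep$relevant_loops),
                            length(rep$all_positive_loops)))
  for (c in rep$relevant_loops) {
    lines <- c(lines, sprintf("  %s  motif %s",
                              format(c, graph = G), motif_signature(c)))
  }
  if (all_loops) {
    lines <- c(lines, "All positive feedback loops:")
    for (c in rep$all_positive_loops) {
      lines <- c(lines, sprintf("  %s  motif %s",
                                format(c, graph = G), motif_signature(c)))
    }
  }
  lines
}

#' JSON rendering of a loop report
#'
#' The schema is versioned via a top-level \code{schema_version} field.
#' Parsing the JSON back reconstructs the same loop set (node sequences,
#' edge signs, motifs) as the in-memory report.
#'
#' @param rep A \code{loop_report}.
#' @return JSON string (class \code{json}).
#' @export
report_json <- function(rep) {
  stopifnot(inherits(rep, "loop_report"))
  G <- rep$graph
  terms <- lapply(seq_len(nrow(rep$wrong_sign_terms)), function(r) {
    key <- rep$wrong_sign_terms$monomial[r]
    f <- mono_factors(key)
    list(monomial = rep$wrong_sign_terms$pretty[r],
         factors = lapply(seq_len(nrow(f)), function(k) {
           list(species = G$species[f[k, 1]], reaction = G$rids[f[k, 2]])
         }),
         coefficient = rep$wrong_sign_terms$num[r] /
                       rep$wrong_sign_terms$den[r],
         nuclei = lapply(rep$wrong_sign_nuclei[[key]], function(D) {
           lapply(D$circuits, function(c) loop_to_list(G, c))
         }))
  })
  obj <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    verdict = rep$verdict,
    s = rep$s,
    polynomial = format_polynomial(rep$polynomial),
    n_terms = n_terms(rep$polynomial),
    n_positive_terms = sum(rep$polynomial$num > 0),
    n_negative_terms = sum(rep$polynomial$num < 0),
    wrong_sign_terms = terms,
    relevant_loops = lapply(rep$relevant_loops,
                            function(c) loop_to_list(G, c)),
    all_positive_loops = lapply(rep$all_positive_loops,
                                function(c) loop_to_list(G, c)))
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' DOT export of the signed DSR-graph
#'
#' Species nodes are ellipses, reaction nodes boxes; edges carry their sign
#' as label, negative edges dashed.
#'
#' @param G A \code{dsr_graph}.
#' @param path Optional output file.
#' @return Character vector of DOT lines (invisibly when written).
#' @export
write_dot <- function(G, path = NULL) {
  stopifnot(inherits(G, "dsr_graph"))
  q <- function(x) paste0("\"", x, "\"")
  lines <- c("digraph DSR {", "  rankdir=LR;")
  for (i in seq_len(G$n)) {
    lines <- c(lines, sprintf("  %s [shape=ellipse];", q(G$species[i])))
  }
  for (j in seq_len(G$m)) {
    lines <- c(lines, sprintf("  %s [shape=box];", q(G$rids[j])))
  }
  for (i in seq_len(G$n)) {
    for (j in seq_len(G$m)) {
      if (G$z[i, j] != 0) {
        lines <- c(lines, sprintf("  %s -> %s [label=\"%s\"%s];",
                                  q(G$species[i]), q(G$rids[j]),
                                  if (G$z[i, j] > 0) "+" else "-",
                                  if (G$z[i, j] < 0) ", style=dashed" else ""))
      }
      if (G$a[i, j] != 0) {
        lines <- c(lines, sprintf("  %s -> %s [label=\"%d\"%s];",
                                  q(G$rids[j]), q(G$species[i]), G$a[i, j],
                                  if (G$a[i, j] < 0) ", style=dashed" else ""))
      }
    }
  }
  lines <- c(lines, "}")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
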