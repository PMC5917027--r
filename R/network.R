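#' Minimum spanning haplotype network
#'
#' Builds the epsilon = 0 minimum spanning network among haplotypes:
#' pairwise resolved-site distances are computed between haplotype
#' representative sequences, then edges are added in increasing weight
#' order, one weight class at a time; within a weight class *all* edges that
#' connect components distinct at the start of the class are retained. The
#' result is the minimum spanning tree plus every tied-weight alternative
#' edge, as drawn in standard haplotype-network software. Edges are
#' processed in (weight, label, label) order so the network is deterministic.
#'
#' @param table A `haplotype_table` from [call_haplotypes].
#' @param groups Optional named character vector mapping sample id to a group
#'   label; per-group membership counts are then attached to each node.
#' @return A `haplotype_network`: list with `nodes` (`data.frame` of label,
#'   count and optional per-group counts), `edges` (`data.frame` of `from`,
#'   `to`, `weight`), and `graph` (an igraph object).
#' @export
min_spanning_network <- function(table, groups = NULL) {
  H <- table$H
  labels <- table$labels
  nodes <- data.frame(label = labels, count = table$counts,
                      stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    glev <- sort(unique(groups))
    for (g in glev) {
      nodes[[paste0("n_", g)]] <- vapply(table$members, function(m) {
        sum(groups[m] == g, na.rm = TRUE)
      }, integer(1))
    }
  }

  if (H == 1L) {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = integer(0))
  } else {
    pairs <- utils::combn(H, 2L)
    w <- apply(pairs, 2L, function(p) {
      resolved_diff(table$representatives[[p[1L]]],
                    table$representatives[[p[2L]]])
    })
    cand <- data.frame(i = pairs[1L, ], j = pairs[2L, ], weight = w)
    cand <- cand[order(cand$weight, labels[cand$i], labels[cand$j]), ]
    comp <- seq_len(H)
    keep <- logical(nrow(cand))
    for (wc in sort(unique(cand$weight))) {
      in_class <- which(cand$weight == wc)
      snapshot <- comp
      added <- in_class[snapshot[cand$i[in_class]] != snapshot[cand$j[in_class]]]
      keep[added] <- TRUE
      for (e in added) {
        ci <- comp[cand$i[e]]; cj <- comp[cand$j[e]]
        if (ci != cj) comp[comp == cj] <- ci
      }
      if (length(unique(comp)) == 1L) break
    }
    kept <- cand[keep, ]
    edges <- data.frame(from = labels[kept$i], to = labels[kept$j],
                        weight = kept$weight, stringsAsFactors = FALSE)
    rownames(edges) <- NULL
  }

  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("haplotype_network:", nrow(x$nodes), "haplotypes,",
      nrow(x$edges), "edges, total weight", sum(x$edges$weight), "\n")
  invisible(x)
}

#' Export a haplotype network as GraphML
#' @param net A `haplotype_network`.
#' @param path Output GraphML path.
#' @return Invisibly, `path`.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' Export a haplotype network edge list as TSV
#' @param net A `haplotype_network`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_network_edgelist <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
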