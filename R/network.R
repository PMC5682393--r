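# Minimum spanning network over a node set: iteratively find the smallest
# inter-component distance w*, add every inter-component link of weight
# <= w* + epsilon, merge, repeat until connected. With epsilon = 0 this
# keeps all minimal connections (every MST edge set is contained in it).
msn_edges <- function(d, epsilon = 0) {
  nn <- nrow(d)
  comp <- seq_len(nn)
  edges <- NULL
  while (length(unique(comp)) > 1) {
    inter <- outer(comp, comp, "!=") & upper.tri(d)
    wstar <- min(d[inter])
    take <- which(inter & d <= wstar + epsilon, arr.ind = TRUE)
    edges <- rbind(edges, take)
    for (r in seq_len(nrow(take))) {
      ci <- comp[take[r, 1]]; cj <- comp[take[r, 2]]
      if (ci != cj) comp[comp == cj] <- ci
    }
  }
  data.frame(from = edges[, 1], to = edges[, 2],
             steps = d[edges])
}

msn_cost <- function(d, epsilon = 0) sum(msn_edges(d, epsilon)$steps)

# Per-site majority consensus of three sequences; sites with three distinct
# states resolve toward the first sequence in lexicographic order of the
# three (deterministic tie-break).
median_vector <- function(trip) {
  ord <- order(apply(trip, 1, paste, collapse = ""))
  trip <- trip[ord, , drop = FALSE]
  vapply(seq_len(ncol(trip)), function(s) {
    tab <- table(trip[, s])
    if (max(tab) >= 2) names(tab)[which.max(tab)] else trip[1, s]
  }, "")
}

#' Median-joining haplotype network
#'
#' Implements the median-joining construction: starting from the observed
#' haplotypes, repeatedly (1) build the minimum spanning network (all links
#' within `epsilon` of minimal), (2) propose the per-site majority
#' consensus (median) vector of every connected triplet, (3) accept, one at
#' a time in deterministic lexicographic order, median vectors whose
#' addition strictly lowers the network cost, and (4) after fixation prune
#' median vectors whose removal does not raise the cost. Median nodes carry
#' frequency 0.
#'
#' @param hs a `haplotype_set` with at least 2 haplotypes (equal-length,
#'   gap-free sequences; apply [filter_sites()] upstream).
#' @param epsilon weight tolerance for extra links (default 0, the usual
#'   published default).
#' @return list of class `hap_network`: `seq` (node x site matrix, observed
#'   haplotypes then medians `MV1...`), `is_median`, `freq` (copies,
#'   0 for medians), `pop_counts`, `edges` (data frame `from`, `to`,
#'   `steps`, `sites` — 1-based changed-site lists for reporting).
#' @export
median_joining_network <- function(hs, epsilon = 0) {
  m <- hs$seq
  if (nrow(m) < 2) stop("need at least 2 haplotypes", call. = FALSE)
  nodes <- m
  is_median <- rep(FALSE, nrow(m))
  repeat {
    added <- FALSE
    d <- seq_dist(nodes)
    ed <- msn_edges(d, epsilon)
    base_cost <- sum(ed$steps)
    adj <- edge_adj(ed, nrow(nodes))
    cands <- list()
    for (v in seq_len(nrow(nodes))) {
      nb <- adj[[v]]
      if (length(nb) < 2) next
      for (i in seq_len(length(nb) - 1)) for (j in (i + 1):length(nb)) {
        trip <- nodes[c(v, nb[i], nb[j]), , drop = FALSE]
        med <- median_vector(trip)
        key <- paste(med, collapse = "")
        if (!key %in% apply(nodes, 1, paste, collapse = ""))
          cands[[key]] <- med
      }
    }
    if (length(cands)) {
      for (key in sort(names(cands))) {  # lexicographic, deterministic
        cand <- rbind(nodes, cands[[key]])
        if (msn_cost(seq_dist(cand), epsilon) < base_cost) {
          nodes <- cand
          is_median <- c(is_median, TRUE)
          added <- TRUE
          break  # re-derive MSN and triplets after each acceptance
        }
      }
    }
    if (!added) break
  }
  # obsolescence pruning
  repeat {
    d <- seq_dist(nodes)
    cost <- msn_cost(d, epsilon)
    drop <- NA
    for (v in which(is_median)) {
      keep <- setdiff(seq_len(nrow(nodes)), v)
      if (msn_cost(d[keep, keep, drop = FALSE], epsilon) <= cost) {
        drop <- v; break
      }
    }
    if (is.na(drop)) break
    nodes <- nodes[-drop, , drop = FALSE]
    is_median <- is_median[-drop]
  }
  rn <- rownames(m)
  labels <- character(nrow(nodes))
  labels[!is_median] <- rn              # observed rows stay first
  labels[is_median] <- paste0("MV", seq_len(sum(is_median)))
  rownames(nodes) <- labels
  d <- seq_dist(nodes)
  ed <- msn_edges(d, epsilon)
  ed$sites <- vapply(seq_len(nrow(ed)), function(r) {
    paste(which(nodes[ed$from[r], ] != nodes[ed$to[r], ]), collapse = ";")
  }, "")
  ed$from <- labels[ed$from]; ed$to <- labels[ed$to]
  freq <- c(haplotype_counts(hs)[rn], rep(0L, sum(is_median)))
  names(freq) <- labels
  pc <- matrix(0L, nrow(hs$counts), nrow(nodes),
               dimnames = list(rownames(hs$counts), labels))
  pc[, rn] <- hs$counts[, rn]
  structure(list(seq = nodes, is_median = is_median, freq = freq,
                 pop_counts = pc, edges = ed, epsilon = epsilon),
            class = "hap_network")
}

seq_dist <- function(m) {
  H <- nrow(m)
  d <- matrix(0L, H, H)
  if (H < 2) return(d)
  for (i in seq_len(H - 1)) for (j in (i + 1):H)
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  d
}

edge_adj <- function(ed, n) {
  adj <- rep(list(integer(0)), n)
  for (r in seq_len(nrow(ed))) {
    adj[[ed$from[r]]] <- c(adj[[ed$from[r]]], ed$to[r])
    adj[[ed$to[r]]] <- c(adj[[ed$to[r]]], ed$from[r])
  }
  adj
}

#' @export
print.hap_network <- function(x, ...) {
  cat(sprintf("<hap_network> %d observed + %d median nodes, %d edges (%d steps)\n",
              sum(!x$is_median), sum(x$is_median), nrow(x$edges),
              sum(x$edges$steps)))
  invisible(x)
}

#' Convert a haplotype network to igraph
#'
#' Node attributes: `freq`, `is_median`, per-population counts as
#' `pop_<code>`. Edge attribute: `steps`.
#'
#' @param net a `hap_network`.
#' @return an `igraph` graph.
#' @export
network_to_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[c("from", "to", "steps")], directed = FALSE,
    vertices = data.frame(name = rownames(net$seq),
                          freq = as.integer(net$freq),
                          is_median = net$is_median))
  for (pop in rownames(net$pop_counts)) {
    g <- igraph::set_vertex_attr(g, paste0("pop_", pop),
                                 value = net$pop_counts[pop,
                                   igraph::V(g)$name])
  }
  g
}

#' Write a network as edge-list CSV and GraphML
#'
#' @param net a `hap_network`.
#' @param edge_csv path for the edge list (columns from, to, steps, sites).
#' @param graphml optional path for GraphML output.
#' @export
write_network <- function(net, edge_csv, graphml = NULL) {
  utils::write.csv(net$edges, edge_csv, row.names = FALSE)
  if (!is.null(graphml))
    igraph::write_graph(network_to_igraph(net), graphml, format = "graphml")
  invisible(net)
}
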