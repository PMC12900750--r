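#' Read a gene network from an edge-list or SIF file
#'
#' Produces a simple undirected graph: duplicate edges (in either
#' orientation) are merged and self-loops are dropped with a message. The
#' `tsv2col` dialect expects two whitespace/tab-separated node columns per
#' line; the SIF dialect expects `source relation target1 [target2 ...]`,
#' where a single-token line declares an isolated node.
#'
#' @param path File path.
#' @param dialect `"tsv2col"` (default) or `"sif"`.
#' @param header Logical; skip a header line (tsv2col only). Default FALSE.
#' @return An undirected simple [igraph::graph].
#' @export
read_edge_list <- function(path, dialect = c("tsv2col", "sif"), header = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  if (header && length(lines)) lines <- lines[-1]
  keep <- nzchar(trimws(lines))
  offset <- as.integer(header)
  nodes <- character(0)
  from <- character(0)
  to <- character(0)
  for (i in which(keep)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (dialect == "tsv2col") {
      if (length(tok) < 2) {
        stop("malformed edge-list line ", i + offset, ": '", lines[i], "'")
      }
      from <- c(from, tok[1]); to <- c(to, tok[2])
      nodes <- c(nodes, tok[1:2])
    } else {
      if (length(tok) == 1) {
        nodes <- c(nodes, tok)
      } else if (length(tok) >= 3) {
        targets <- tok[3:length(tok)]
        from <- c(from, rep(tok[1], length(targets))); to <- c(to, targets)
        nodes <- c(nodes, tok[1], targets)
      } else {
        stop("malformed SIF line ", i + offset,
             " (source + relation but no target): '", lines[i], "'")
      }
    }
  }
  graph_from_edges(from, to, nodes)
}

# Build a deduplicated simple graph, reporting dropped self-loops.
graph_from_edges <- function(from, to, nodes = c(from, to)) {
  nodes <- sort(unique(nodes))
  loops <- sum(from == to)
  if (loops > 0) message("dropped ", loops, " self-loop(s)")
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = nodes))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Subgraph centrality ranking
#'
#' Subgraph centrality counts the closed walks starting and ending at each
#' node, weighting walks of length k by 1/k!; equivalently the diagonal of
#' the matrix exponential of the adjacency matrix, computed here through the
#' symmetric eigendecomposition `SC_i = sum_j V_ij^2 exp(lambda_j)`. Every
#' node has SC >= 1 (the empty walk).
#'
#' @param graph An undirected [igraph::graph].
#' @return Data frame (`node`, `sc`, `rank`) sorted by descending centrality,
#'   ties broken lexicographically by node id.
#' @export
subgraph_centrality <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) stop("empty graph")
  a <- as.matrix(igraph::as_adjacency_matrix(graph, sparse = FALSE))
  eig <- eigen(a, symmetric = TRUE)
  sc <- as.vector((eig$vectors^2) %*% exp(eig$values))
  nodes <- igraph::V(graph)$name %||% as.character(seq_len(n))
  ord <- order(-sc, nodes)
  data.frame(node = nodes[ord], sc = sc[ord], rank = seq_len(n),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Top-k nodes of a centrality ranking
#'
#' @param ranking Output of [subgraph_centrality()].
#' @param k Number of nodes to keep (default 25). Ties at the boundary are
#'   already broken lexicographically in the ranking.
#' @return Character vector of node ids, highest centrality first.
#' @export
top_k_nodes <- function(ranking, k = 25) {
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(ranking)) {
    warning("k = ", k, " exceeds the number of nodes (", nrow(ranking),
            "); returning all nodes")
    k <- nrow(ranking)
  }
  ranking$node[seq_len(k)]
}

#' MCODE vertex weights (core-clustering coefficient)
#'
#' For each vertex v, take the subgraph induced by its closed neighborhood
#' N[v], find that subgraph's highest k-core, and set
#' `w(v) = k * density(highest k-core)`. Degree-0 vertices get weight 0.
#'
#' @param graph An undirected [igraph::graph].
#' @return Named numeric vector of weights.
#' @export
mcode_vertex_weights <- function(graph) {
  nodes <- igraph::V(graph)$name %||% as.character(seq_len(igraph::vcount(graph)))
  w <- stats::setNames(numeric(length(nodes)), nodes)
  for (v in seq_along(nodes)) {
    nb <- igraph::neighbors(graph, v)
    if (length(nb) == 0) next
    sub <- igraph::induced_subgraph(graph, c(v, nb))
    core <- igraph::coreness(sub)
    kmax <- max(core)
    core_sub <- igraph::induced_subgraph(sub, which(core == kmax))
    dens <- igraph::edge_density(core_sub)
    if (!is.finite(dens)) dens <- 0
    w[nodes[v]] <- kmax * dens
  }
  w
}

#' Find dense network modules (MCODE)
#'
#' Seeded greedy complex detection: vertices are weighted by their
#' core-clustering coefficient ([mcode_vertex_weights()]); starting from the
#' highest-weight unassigned vertex, the module grows outward admitting
#' neighbors whose weight exceeds `(1 - vwp) * seed weight` (strict).
#' Post-processing optionally fluffs the module with dense-neighborhood
#' boundary vertices, applies the haircut (iterative removal of members with
#' fewer than two within-module neighbors), and discards modules lacking a
#' 2-core. Modules are scored `density * size` and returned sorted by score;
#' each vertex belongs to at most one module. Ties in seed selection and in
#' score are broken lexicographically by node id.
#'
#' @param graph An undirected [igraph::graph].
#' @param vwp Vertex weight percentage in [0, 1), default 0.2.
#' @param haircut Remove degree-1 members iteratively (default TRUE).
#' @param fluff Add boundary vertices with closed-neighborhood density above
#'   `fluff_density` (default FALSE).
#' @param fluff_density Density cutoff for fluff, default 0.2.
#' @return Object of class `mcode_modules`: list of modules, each with
#'   `members`, `score`, `seed`.
#' @export
mcode_find_modules <- function(graph, vwp = 0.2, haircut = TRUE, fluff = FALSE,
                               fluff_density = 0.2) {
  if (vwp < 0 || vwp >= 1) stop("vwp must be in [0, 1)")
  nodes <- igraph::V(graph)$name %||% as.character(seq_len(igraph::vcount(graph)))
  w <- mcode_vertex_weights(graph)
  assigned <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  order_seed <- nodes[order(-w[nodes], nodes)]
  modules <- list()
  for (seed in order_seed) {
    if (assigned[seed] || w[seed] <= 0) next
    thresh <- (1 - vwp) * w[seed]
    members <- seed
    frontier <- seed
    while (length(frontier)) {
      nxt <- character(0)
      for (v in frontier) {
        nb <- igraph::V(graph)$name[igraph::neighbors(graph, v)]
        cand <- nb[!assigned[nb] & !(nb %in% members) & w[nb] > thresh]
        members <- c(members, cand)
        nxt <- c(nxt, cand)
      }
      frontier <- unique(nxt)
    }
    if (fluff) {
      boundary <- setdiff(
        unique(unlist(lapply(members, function(v)
          igraph::V(graph)$name[igraph::neighbors(graph, v)]))), members)
      boundary <- boundary[!assigned[boundary]]
      keep <- vapply(boundary, function(v) {
        nb <- igraph::V(graph)$name[igraph::neighbors(graph, v)]
        sub <- igraph::induced_subgraph(graph, c(v, nb))
        d <- igraph::edge_density(sub)
        is.finite(d) && d > fluff_density
      }, logical(1))
      members <- c(members, boundary[keep])
    }
    sub <- igraph::induced_subgraph(graph, members)
    # 2-core requirement: a module must contain a nonempty 2-core
    if (max(igraph::coreness(sub)) < 2) next
    if (haircut) {
      core2 <- igraph::coreness(sub) >= 2
      members <- igraph::V(sub)$name[core2]
      sub <- igraph::induced_subgraph(graph, members)
    }
    assigned[members] <- TRUE
    score <- igraph::edge_density(sub) * length(members)
    modules[[length(modules) + 1L]] <- list(members = sort(members),
                                            score = score, seed = seed)
  }
  if (length(modules)) {
    ord <- order(-vapply(modules, `[[`, numeric(1), "score"),
                 vapply(modules, function(m) m$members[1], character(1)))
    modules <- modules[ord]
  }
  structure(modules, class = "mcode_modules")
}

#' @export
print.mcode_modules <- function(x, ...) {
  cat("MCODE modules found:", length(x), "\n")
  for (i in seq_along(x)) {
    cat(sprintf("  [%d] score %.3f, %d members: %s\n", i, x[[i]]$score,
                length(x[[i]]$members),
                paste(utils::head(x[[i]]$members, 10), collapse = ", ")))
  }
  invisible(x)
}

#' Consensus hub genes
#'
#' Intersection of the top-centrality node set with the union of MCODE
#' module members, preserving the centrality ordering of `topk`.
#'
#' @param topk Character vector of top-ranked nodes (highest first).
#' @param modules An `mcode_modules` object (or list of modules).
#' @return Character vector of consensus hubs, descending centrality.
#' @export
consensus_hubs <- function(topk, modules) {
  in_module <- unique(unlist(lapply(modules, `[[`, "members")))
  topk[topk %in% in_module]
}
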