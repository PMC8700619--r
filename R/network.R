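#' Global edge threshold: cohort-wide median
#'
#' Edges below the median edge value - pooled over ALL subjects and element
#' pairs for one edge definition - are excluded from the per-subject graphs,
#' so graphs retain only non-trivial connections. The usual midpoint
#' convention is used for even counts.
#'
#' @param values Numeric edge values pooled across the cohort.
#' @return The median.
#' @export
global_edge_threshold <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop_invalid("no edge values to threshold")
  median(values)
}

#' Build one subject's metabolic network
#'
#' Constructs the weighted undirected graph on the seven network elements
#' (Ba, Cu, Li, Mg, Mn, Sr, Zn; Pb is never a node). Edges with value >= the
#' threshold are retained at their value; ties at the threshold are kept
#' (exclusion applies to values strictly below the median). All 21 unordered
#' pairs must be present.
#'
#' @param edges Data frame with columns `element_a`, `element_b` and a value
#'   column named by `edge_definition` (`rr` or `entropy`).
#' @param edge_definition `"rr"` or `"entropy"`.
#' @param threshold Weight threshold, typically [global_edge_threshold()].
#' @param binarize If `TRUE`, retained edges get weight 1 instead of their
#'   value (sensitivity analysis; default `FALSE`).
#' @return An object of class `metabolic_network`: list with `weights`
#'   (symmetric 7 x 7 matrix, zero diagonal), `edge_definition`,
#'   `threshold_applied`.
#' @export
build_network <- function(edges, edge_definition = c("rr", "entropy"),
                          threshold, binarize = FALSE) {
  edge_definition <- match.arg(edge_definition)
  if (!edge_definition %in% names(edges))
    stop_invalid("edge value column '", edge_definition, "' not found")
  el <- NETWORK_ELEMENTS
  w <- matrix(0, length(el), length(el), dimnames = list(el, el))
  key_have <- paste(pmin(edges$element_a, edges$element_b),
                    pmax(edges$element_a, edges$element_b))
  pairs <- utils::combn(el, 2L)
  key_need <- paste(pairs[1L, ], pairs[2L, ])
  miss <- setdiff(key_need, key_have)
  if (length(miss))
    stop_invalid("missing element pair(s): ", paste(miss, collapse = ", "))
  for (r in seq_len(nrow(edges))) {
    a <- edges$element_a[r]; b <- edges$element_b[r]
    if (!(a %in% el) || !(b %in% el)) next   # Pb or foreign rows ignored
    v <- edges[[edge_definition]][r]
    if (is.finite(v) && v >= threshold)
      w[a, b] <- w[b, a] <- if (binarize) 1 else v
  }
  structure(list(weights = w, edge_definition = edge_definition,
                 threshold_applied = threshold),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat("Metabolic network (", x$edge_definition, " edges): ",
      nrow(x$weights), " nodes, ", ne, " retained edges (threshold ",
      format(x$threshold_applied), ")\n", sep = "")
  invisible(x)
}

net_graph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' All-pairs shortest-path distances
#'
#' Edge length is the reciprocal of the weight (strong edges are short), the
#' standard convention for similarity-weighted graphs. Unreachable pairs get
#' `Inf`.
#'
#' @param net A `metabolic_network`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
shortest_path_distances <- function(net) {
  g <- net_graph(net)
  wts <- igraph::E(g)$weight
  d <- igraph::distances(g, weights = if (length(wts)) 1 / wts else NULL)
  d[rownames(net$weights), colnames(net$weights)]
}

#' Node strength (weighted degree)
#'
#' Sum of incident retained edge weights.
#'
#' @param net A `metabolic_network`.
#' @return Named numeric vector over the seven elements.
#' @export
degree_strength <- function(net) rowSums(net$weights)

#' Closeness and eccentricity
#'
#' Closeness uses the Wasserman-Faust disconnection correction: with `r`
#' reachable others and `D` their summed shortest-path distance,
#' `closeness = (r/(n-1)) * (r/D)`. Eccentricity is the largest finite
#' shortest-path distance to a reachable node. Isolated nodes get 0 for
#' both, so every subject yields finite metrics.
#'
#' @param net A `metabolic_network`.
#' @return List with numeric vectors `closeness` and `eccentricity`.
#' @export
path_metrics <- function(net) {
  d <- shortest_path_distances(net)
  n <- nrow(d)
  clo <- ecc <- setNames(numeric(n), rownames(d))
  for (i in seq_len(n)) {
    dd <- d[i, -i]
    dd <- dd[is.finite(dd)]
    if (length(dd)) {
      r <- length(dd)
      clo[i] <- (r / (n - 1)) * (r / sum(dd))
      ecc[i] <- max(dd)
    }
  }
  list(closeness = clo, eccentricity = ecc)
}

#' Betweenness centrality
#'
#' Fraction of shortest paths between other node pairs passing through the
#' node, with equal splitting over tied shortest paths, normalized by
#' `(n-1)(n-2)/2`.
#'
#' @param net A `metabolic_network`.
#' @return Named numeric vector in `[0, 1]`.
#' @export
betweenness_centrality <- function(net) {
  g <- net_graph(net)
  wts <- igraph::E(g)$weight
  n <- nrow(net$weights)
  b <- igraph::betweenness(g, weights = if (length(wts)) 1 / wts else NULL,
                           directed = FALSE)
  out <- b / ((n - 1) * (n - 2) / 2)
  setNames(as.numeric(out), rownames(net$weights))
}

#' Eigenvector centrality
#'
#' Leading eigenvector of the weighted adjacency matrix, with non-negative
#' components and unit Euclidean norm. The empty graph returns all zeros.
#' Scaling all weights by a positive constant leaves the result unchanged.
#'
#' @param net A `metabolic_network`.
#' @return Named numeric vector.
#' @export
eigenvector_centrality <- function(net) {
  w <- net$weights
  out <- setNames(numeric(nrow(w)), rownames(w))
  if (all(w == 0)) return(out)
  e <- eigen(w, symmetric = TRUE)
  v <- e$vectors[, 1L]
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  out[] <- v / sqrt(sum(v^2))
  out
}

#' Local clustering coefficient (Onnela weighted form)
#'
#' With weights rescaled by the maximum retained weight, node i's
#' coefficient is the sum of geometric means of its triangles' scaled
#' weights, divided by `k_i (k_i - 1)` where `k_i` is the binary degree.
#' Nodes with fewer than two neighbours get 0.
#'
#' @param net A `metabolic_network`.
#' @return Named numeric vector in `[0, 1]`.
#' @export
clustering_coefficient <- function(net) {
  w <- net$weights
  out <- setNames(numeric(nrow(w)), rownames(w))
  mx <- max(w)
  if (mx == 0) return(out)
  wh <- (w / mx)^(1 / 3)
  k <- rowSums(w > 0)
  num <- diag(wh %*% wh %*% wh)
  ok <- k >= 2
  out[ok] <- num[ok] / (k[ok] * (k[ok] - 1))
  out
}

#' All six node metrics for one network
#'
#' @param net A `metabolic_network`.
#' @return Data frame with one row per element and columns `degree`,
#'   `closeness`, `betweenness`, `eigenvector`, `clustering`,
#'   `eccentricity`.
#' @export
node_metrics <- function(net) {
  pm <- path_metrics(net)
  data.frame(element = rownames(net$weights),
             degree = as.numeric(degree_strength(net)),
             closeness = as.numeric(pm$closeness),
             betweenness = as.numeric(betweenness_centrality(net)),
             eigenvector = as.numeric(eigenvector_centrality(net)),
             clustering = as.numeric(clustering_coefficient(net)),
             eccentricity = as.numeric(pm$eccentricity),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Export networks as GraphML
#'
#' Writes one GraphML file per subject into `dir`.
#'
#' @param networks Named list of `metabolic_network` objects (names are
#'   subject ids).
#' @param dir Output directory (created if absent).
#' @return Invisible character vector of file paths.
#' @export
export_graphml <- function(networks, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (sid in names(networks)) {
    net <- networks[[sid]]
    f <- file.path(dir, paste0(sid, "_", net$edge_definition, ".graphml"))
    igraph::write_graph(net_graph(net), f, format = "graphml")
    paths <- c(paths, f)
  }
  invisible(paths)
}
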