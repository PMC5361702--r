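#' Feature correlation network
#'
#' Tests every feature pair (over pairwise co-observed samples; pairs with
#' fewer than `min_overlap` shared observations or a constant member are
#' skipped) with the t-transform of the correlation coefficient, adjusts
#' the whole tested family by BH, and keeps edges with q <= `q_max`.
#' Nodes are the features incident to at least one kept edge.
#'
#' @param pt A [peak_table()] with >= 4 samples.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param q_max BH q-value threshold for edges. Default 0.05.
#' @param min_overlap Minimum co-observed samples per pair. Default 5.
#' @return A `correlation_graph`: a list with `graph` (an undirected
#'   [igraph::graph] whose edges carry `r`, `p`, `q`) and `tests` (the full
#'   tested-pair tibble).
#' @export
correlation_network <- function(pt, method = c("pearson", "spearman"),
                                q_max = 0.05, min_overlap = 5) {
  method <- match.arg(method)
  if (n_samples(pt) < 4) stop("need >= 4 samples", call. = FALSE)
  m <- intensity_matrix(pt)
  sds <- apply(m, 1, stats::sd, na.rm = TRUE)
  const <- !is.na(sds) & sds == 0
  if (any(const)) {
    warning(sum(const), " constant feature(s) skipped in correlation network",
            call. = FALSE)
  }
  keep <- !const & rowSums(!is.na(m)) >= 2
  m <- m[keep, , drop = FALSE]
  cors <- stats::cor(t(m), use = "pairwise.complete.obs", method = method)
  n_ov <- tcrossprod(!is.na(m) * 1)
  idx <- which(upper.tri(cors), arr.ind = TRUE)
  ok <- n_ov[idx] >= max(min_overlap, 3) & !is.na(cors[idx])
  idx <- idx[ok, , drop = FALSE]
  r <- cors[idx]
  n <- n_ov[idx]
  r_c <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r_c * sqrt((n - 2) / (1 - r_c^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  tests <- tibble::tibble(
    from = rownames(m)[idx[, 1]], to = rownames(m)[idx[, 2]],
    r = r, n = n, p = p, q = bh_adjust(p))
  new_correlation_graph(tests[tests$q <= q_max, , drop = FALSE], tests)
}

#' Differential correlation network
#'
#' For every feature pair, compares the correlation in group A against
#' group B through the Fisher z statistic
#' `Z = (atanh r_a - atanh r_b) / sqrt(1/(n_a - 3) + 1/(n_b - 3))`,
#' with a two-sided p from the standard normal and BH adjustment over the
#' tested family; pairs with q <= `q_max` form the network edges.
#' Correlations of magnitude 1 are clipped to `1 - 1e-12` before `atanh`
#' (with a warning).
#'
#' @param pt A [peak_table()].
#' @param meta [sample_meta()].
#' @param group_a,group_b Class labels compared; each must have >= 5
#'   samples.
#' @param q_max Edge q-value threshold. Default 0.01.
#' @param method Correlation estimator. Default `"pearson"`.
#' @param min_overlap Minimum co-observed samples per pair within each
#'   group. Default 5.
#' @return A `correlation_graph`; edges carry `r_a`, `r_b`, `z`, `p`, `q`.
#' @export
differential_correlation <- function(pt, meta, group_a, group_b,
                                     q_max = 0.01,
                                     method = c("pearson", "spearman"),
                                     min_overlap = 5) {
  method <- match.arg(method)
  meta <- align_meta(pt, meta)
  sel_a <- !is.na(meta$class) & meta$class == group_a
  sel_b <- !is.na(meta$class) & meta$class == group_b
  if (sum(sel_a) < 5 || sum(sel_b) < 5) {
    stop("each group needs >= 5 samples", call. = FALSE)
  }
  m <- intensity_matrix(pt)
  ga <- pair_cors(m[, sel_a, drop = FALSE], method)
  gb <- pair_cors(m[, sel_b, drop = FALSE], method)
  idx <- which(upper.tri(ga$r), arr.ind = TRUE)
  ok <- ga$n[idx] >= max(min_overlap, 4) & gb$n[idx] >= max(min_overlap, 4) &
    !is.na(ga$r[idx]) & !is.na(gb$r[idx])
  idx <- idx[ok, , drop = FALSE]
  ra <- ga$r[idx]; rb <- gb$r[idx]
  if (any(abs(ra) >= 1) || any(abs(rb) >= 1)) {
    warning("correlation(s) of magnitude 1 clipped before Fisher transform",
            call. = FALSE)
  }
  clip <- function(r) pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  z <- (atanh(clip(ra)) - atanh(clip(rb))) /
    sqrt(1 / (ga$n[idx] - 3) + 1 / (gb$n[idx] - 3))
  p <- 2 * stats::pnorm(-abs(z))
  tests <- tibble::tibble(
    from = rownames(m)[idx[, 1]], to = rownames(m)[idx[, 2]],
    r_a = ra, r_b = rb, n_a = ga$n[idx], n_b = gb$n[idx],
    z = z, p = p, q = bh_adjust(p))
  new_correlation_graph(tests[tests$q <= q_max, , drop = FALSE], tests)
}

pair_cors <- function(m, method) {
  list(r = stats::cor(t(m), use = "pairwise.complete.obs", method = method),
       n = tcrossprod(!is.na(m) * 1))
}

new_correlation_graph <- function(edges, tests = NULL, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  structure(list(graph = g, tests = tests, modularity = NULL),
            class = "correlation_graph")
}

#' Build a correlation graph from an edge table
#'
#' Mainly for constructing small fixture networks; `correlation_network()`
#' and `differential_correlation()` are the analysis entry points.
#'
#' @param edges A data frame with columns `from` and `to` (plus any edge
#'   attributes).
#' @param nodes Optional node id vector (defaults to the ids in `edges`).
#' @return A `correlation_graph`.
#' @export
correlation_graph <- function(edges, nodes = NULL) {
  new_correlation_graph(tibble::as_tibble(edges), tests = NULL, nodes = nodes)
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat("<correlation_graph> ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges\n", sep = "")
  invisible(x)
}

#' Node centralities
#'
#' Adds `degree` (incident edge count), `closeness`
#' (`(reachable - 1) / sum(distances)` within the node's component; 0 for
#' isolated nodes) and `betweenness` (unnormalized shortest-path counts)
#' as node attributes.
#'
#' @param g A `correlation_graph`.
#' @return The graph with centrality node attributes; retrieve the node
#'   table with `tidy()`.
#' @export
graph_centralities <- function(g) {
  gr <- g$graph
  if (igraph::vcount(gr) == 0) stop("empty graph", call. = FALSE)
  deg <- igraph::degree(gr)
  dist <- igraph::distances(gr)
  clo <- vapply(seq_len(nrow(dist)), function(i) {
    d <- dist[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else length(d) / sum(d)
  }, numeric(1))
  btw <- igraph::betweenness(gr, directed = FALSE, normalized = FALSE)
  gr <- igraph::set_vertex_attr(gr, "degree", value = unname(deg))
  gr <- igraph::set_vertex_attr(gr, "closeness", value = clo)
  gr <- igraph::set_vertex_attr(gr, "betweenness", value = unname(btw))
  g$graph <- gr
  g
}

#' Fast-greedy community detection
#'
#' Agglomerative greedy modularity maximization (Clauset-Newman-Moore),
#' cutting the merge tree at the maximum-modularity partition
#' (`Q = sum_c (e_c/m - (d_c/2m)^2)`). Every node belongs to exactly one
#' community; an edgeless graph yields singleton communities with Q = 0.
#'
#' @param g A `correlation_graph` (undirected, simple).
#' @return The graph with a `community` node attribute and `modularity`
#'   recorded.
#' @export
detect_communities <- function(g) {
  gr <- g$graph
  if (igraph::ecount(gr) == 0) {
    g$graph <- igraph::set_vertex_attr(gr, "community",
                                       value = seq_len(igraph::vcount(gr)))
    g$modularity <- 0
    return(g)
  }
  gs <- igraph::simplify(gr)
  cl <- igraph::cluster_fast_greedy(gs, weights = NULL)
  # cut the merge tree at maximum modularity ourselves: near-ties (within
  # 1e-10) resolve toward fewer communities, avoiding floating-point noise
  mods <- cl$modularity
  best_step <- max(which(mods >= max(mods) - 1e-10)) - 1L
  memb <- igraph::cut_at(cl, steps = best_step)
  names(memb) <- igraph::V(gs)$name
  g$graph <- igraph::set_vertex_attr(
    gr, "community", value = as.integer(memb[igraph::V(gr)$name]))
  g$modularity <- igraph::modularity(gs, memb)
  g
}

#' Export a network to GML or Pajek
#'
#' GML carries node attributes (community, centralities) along; Pajek NET
#' writes the vertex and edge lists.
#'
#' @param g A `correlation_graph`.
#' @param path Output file path.
#' @param format `"gml"` or `"pajek"`.
#' @export
export_graph <- function(g, path, format = c("gml", "pajek")) {
  format <- match.arg(format)
  gr <- g$graph
  if (format == "pajek") {
    # Pajek needs integer-compatible handling; names go to the id attribute
    gr <- igraph::set_vertex_attr(gr, "id", value = igraph::V(gr)$name)
  }
  igraph::write_graph(gr, path, format = format)
  invisible(path)
}

#' Import a network from GML or Pajek
#'
#' @param path File written by [export_graph()].
#' @param format `"gml"` or `"pajek"`.
#' @return A `correlation_graph`.
#' @export
import_graph <- function(path, format = c("gml", "pajek")) {
  format <- match.arg(format)
  gr <- igraph::read_graph(path, format = format)
  nm <- igraph::vertex_attr(gr, if (format == "pajek") "id" else "label")
  if (!is.null(nm)) gr <- igraph::set_vertex_attr(gr, "name", value = nm)
  structure(list(graph = gr, tests = NULL, modularity = NULL),
            class = "correlation_graph")
}

#' Node table of a correlation graph
#'
#' @param x A `correlation_graph`.
#' @param ... Unused.
#' @return A tibble with one row per node and any computed attributes
#'   (degree, closeness, betweenness, community).
#' @export
tidy.correlation_graph <- function(x, ...) {
  gr <- x$graph
  out <- tibble::tibble(feature_id = igraph::V(gr)$name)
  for (a in setdiff(igraph::vertex_attr_names(gr), "name")) {
    out[[a]] <- igraph::vertex_attr(gr, a)
  }
  out
}

#' One-row summary of a correlation graph
#'
#' @param x A `correlation_graph`.
#' @param ... Unused.
#' @return Node/edge counts, number of components, giant-component
#'   fraction, community count and modularity (when detected).
#' @export
glance.correlation_graph <- function(x, ...) {
  gr <- x$graph
  comp <- igraph::components(gr)
  tibble::tibble(
    n_nodes = igraph::vcount(gr),
    n_edges = igraph::ecount(gr),
    n_components = comp$no,
    giant_component_frac = if (igraph::vcount(gr) > 0)
      max(comp$csize) / igraph::vcount(gr) else NA_real_,
    n_communities = if ("community" %in% igraph::vertex_attr_names(gr))
      length(unique(igraph::vertex_attr(gr, "community"))) else NA_integer_,
    modularity = x$modularity %||% NA_real_
  )
}

#' Edge table of a correlation graph
#'
#' @param g A `correlation_graph`.
#' @param all Return every tested pair (`TRUE`) or only the kept edges
#'   (default).
#' @return A tibble of pairs with their statistics.
#' @export
graph_edges <- function(g, all = FALSE) {
  if (all) return(graph_tests(g))
  tibble::as_tibble(igraph::as_data_frame(g$graph, what = "edges"))
}

#' @rdname graph_edges
#' @export
graph_tests <- function(g) {
  if (is.null(g$tests)) stop("no tested-pair table stored", call. = FALSE)
  g$tests
}
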