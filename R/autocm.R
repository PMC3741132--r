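# Auto-Contractive Map training, weight-to-distance conversion, minimum
# spanning tree filtering, and the semantic connectivity map.
#
# The Auto-CM is an unsupervised two-layer network with mono-dedicated
# first-layer weights v (one per variable) and a square second-layer
# matrix w.  Training contracts the signal: v saturates toward the
# contraction parameter C, the hidden activations die out, and w freezes
# at values proportional to how strongly variables co-activate.  The
# symmetrized converged w, converted to distances and filtered by a
# minimum spanning tree, is the semantic connectivity map.

#' Train an Auto-Contractive Map
#'
#' Per-record online updates in fixed dataset order, each epoch:
#' \deqn{h_i = x_i (1 - v_i/C), \quad \Delta v_i = (x_i - h_i)(1 - v_i/C)}
#' \deqn{net_i = \sum_j h_j (1 - w_{ij}/C), \quad out_i = h_i (1 - net_i/C)}
#' \deqn{\Delta w_{ij} = (h_i - out_i)(1 - w_{ij}/C)\, h_j}
#' Training stops when the epoch mean of |Δv| falls below `tolerance` or
#' at `max_epochs`.  Weights start at the small positive constant
#' `init_frac * C` (an exact zero start is a fixed point of the v update,
#' so learning could never begin from it).
#'
#' @param x Records-by-variables matrix with all entries in \[0, 1\]
#'   (>= 2 variables).
#' @param C Contraction parameter (> 0).  Default `"auto"` = number of
#'   variables, which keeps `net` within range for \[0, 1\] inputs.
#' @param max_epochs Epoch budget.
#' @param tolerance Convergence threshold on the epoch mean |Δv|.
#' @param init_frac Initial weights as a fraction of C.
#' @return An `autocm_model`: `v` (per-variable first-layer weights),
#'   `w` (square second-layer matrix), `C`, `epochs`, `converged`, and
#'   `trace` (per-epoch mean |Δv|).
#' @export
train_autocm <- function(x, C = "auto", max_epochs = 2000, tolerance = 1e-6,
                         init_frac = 1e-3) {
  x <- as.matrix(x)
  if (ncol(x) < 2) ocm_stop("need >= 2 variables")
  if (nrow(x) < 1) ocm_stop("need >= 1 record")
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    ocm_stop("Auto-CM input entries must lie in [0, 1]")
  if (identical(C, "auto")) C <- ncol(x)
  if (!is.numeric(C) || C <= 0) ocm_stop("C must be > 0")
  p <- ncol(x)
  v <- rep(init_frac * C, p)
  w <- matrix(init_frac * C, p, p)
  trace <- numeric(0)
  converged <- FALSE
  for (epoch in seq_len(max_epochs)) {
    dv_sum <- 0
    for (r in seq_len(nrow(x))) {
      xs <- x[r, ]
      h <- xs * (1 - v / C)
      dv <- (xs - h) * (1 - v / C)
      v <- v + dv
      net <- as.vector((1 - w / C) %*% h)
      out <- h * (1 - net / C)
      w <- w + (h - out) * (1 - w / C) * rep(h, each = p)
      dv_sum <- dv_sum + mean(abs(dv))
    }
    trace <- c(trace, dv_sum / nrow(x))
    if (trace[epoch] < tolerance) { converged <- TRUE; break }
  }
  structure(list(v = stats::setNames(v, colnames(x)), w = w, C = C,
                 variables = colnames(x) %||% paste0("V", seq_len(p)),
                 epochs = length(trace), converged = converged, trace = trace),
            class = "autocm_model")
}

#' @export
print.autocm_model <- function(x, ...) {
  cat(sprintf("Auto-CM model: %d variables, C = %g, %d epochs (%s)\n",
              length(x$v), x$C, x$epochs,
              if (x$converged) "converged" else "epoch budget reached"))
  invisible(x)
}

#' Convert converged Auto-CM weights to distances
#'
#' `d_ij = C - (w_ij + w_ji) / 2`: strongly coupled variable pairs become
#' near, and the transform is strictly decreasing in the symmetrized
#' weight.  Associations are treated as undirected, hence the
#' symmetrization by averaging.  The diagonal is forced to 0.
#'
#' @param model An `autocm_model`.
#' @return Symmetric non-negative distance matrix with zero diagonal and
#'   the variable names as dimnames.
#' @export
weights_to_distances <- function(model) {
  if (!inherits(model, "autocm_model")) ocm_stop("expected an autocm_model")
  sym <- (model$w + t(model$w)) / 2
  d <- model$C - sym
  d[d < 0] <- 0
  diag(d) <- 0
  dimnames(d) <- list(model$variables, model$variables)
  d
}

# ---- minimum spanning tree -------------------------------------------------

#' Minimum spanning tree of a distance matrix (Kruskal)
#'
#' Edges are sorted by weight with a deterministic tie-break on the
#' lexicographic node-pair order; union-find yields exactly `n - 1` edges
#' forming the spanning tree of minimal total weight.
#'
#' @param distances Symmetric finite distance matrix (>= 2 nodes).
#' @return Data frame `from`, `to`, `weight` with `n - 1` rows; node names
#'   come from the matrix dimnames.
#' @export
minimum_spanning_tree <- function(distances) {
  d <- as.matrix(distances)
  n <- nrow(d)
  if (n < 2) ocm_stop("need >= 2 nodes")
  if (any(!is.finite(d))) ocm_stop("distances must be finite")
  if (max(abs(d - t(d))) > 1e-9) ocm_stop("distances must be symmetric")
  nodes <- rownames(d) %||% paste0("V", seq_len(n))
  ij <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[ij], ij[, 1], ij[, 2])  # weight, then lexicographic pair
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (e in ord) {
    a <- ij[e, 1]; b <- ij[e, 2]
    ra <- find(a); rb <- find(b)
    if (ra != rb) {
      parent[ra] <- rb
      from <- c(from, a); to <- c(to, b); wt <- c(wt, d[a, b])
      if (length(from) == n - 1) break
    }
  }
  if (length(from) != n - 1) ocm_stop("distance matrix is not connected")
  data.frame(from = nodes[from], to = nodes[to], weight = wt,
             stringsAsFactors = FALSE)
}

#' Build the semantic connectivity map
#'
#' Each MST edge carries a link strength `ls` in \[0, 1\]: the symmetrized
#' weight of the pair divided by the maximum symmetrized weight over all
#' variable pairs, so the strongest association in the dataset scores
#' 1.00.  Hubs are the nodes attaining the maximal MST degree — the
#' variables with the maximal amount of connections.
#'
#' @param model A trained `autocm_model`.
#' @param distances Optional distance matrix (recomputed from the model if
#'   omitted).
#' @param mst Optional MST edge table (recomputed if omitted).
#' @return A `connectivity_map`: `nodes`, `distances`, `edges` (with `ls`),
#'   `hubs`, `degree`.
#' @export
build_map <- function(model, distances = NULL, mst = NULL) {
  distances <- distances %||% weights_to_distances(model)
  mst <- mst %||% minimum_spanning_tree(distances)
  sym <- (model$w + t(model$w)) / 2
  dimnames(sym) <- dimnames(distances)
  w_max <- max(sym[upper.tri(sym)])
  ls <- if (w_max > 0)
    mapply(function(a, b) sym[a, b] / w_max, mst$from, mst$to)
  else rep(0, nrow(mst))
  edges <- data.frame(from = mst$from, to = mst$to, weight = mst$weight,
                      ls = as.numeric(ls), stringsAsFactors = FALSE)
  nodes <- rownames(distances)
  degree <- table(factor(c(edges$from, edges$to), levels = nodes))
  degree <- stats::setNames(as.integer(degree), nodes)
  structure(list(nodes = nodes, distances = distances, edges = edges,
                 hubs = nodes[degree == max(degree)], degree = degree),
            class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("semantic connectivity map: %d nodes, %d MST edges\n",
              length(x$nodes), nrow(x$edges)))
  cat("hubs:", paste(x$hubs, collapse = ", "), "\n")
  top <- x$edges[order(-x$edges$ls), ][seq_len(min(5, nrow(x$edges))), ]
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %s -- %s  ls=%.2f\n", top$from[i], top$to[i], top$ls[i]))
  invisible(x)
}

# ---- export ----------------------------------------------------------------

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub("\"", "&quot;", s, fixed = TRUE)
}

#' Export a connectivity map as GraphML or DOT
#'
#' Edges carry the full-precision `ls` attribute plus a two-decimal label
#' (the style used on the arches of the published maps); nodes carry a
#' `hub` flag.  GraphML exports round-trip through [import_map_graphml()].
#'
#' @param map A `connectivity_map`.
#' @param path Output file path.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_map <- function(map, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  if (format == "graphml") {
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="d0" for="node" attr.name="hub" attr.type="boolean"/>',
      '  <key id="d1" for="edge" attr.name="ls" attr.type="double"/>',
      '  <key id="d2" for="edge" attr.name="label" attr.type="string"/>',
      '  <graph id="connectivity_map" edgedefault="undirected">')
    for (nd in map$nodes)
      lines <- c(lines, sprintf('    <node id="%s"><data key="d0">%s</data></node>',
                                xml_escape(nd),
                                tolower(nd %in% map$hubs)))
    for (i in seq_len(nrow(map$edges)))
      lines <- c(lines, sprintf(
        '    <edge source="%s" target="%s"><data key="d1">%.17g</data><data key="d2">%.2f</data></edge>',
        xml_escape(map$edges$from[i]), xml_escape(map$edges$to[i]),
        map$edges$ls[i], map$edges$ls[i]))
    lines <- c(lines, "  </graph>", "</graphml>")
  } else {
    q <- function(s) sprintf('"%s"', gsub('"', '\\\\"', s))
    lines <- c("graph connectivity_map {")
    for (nd in map$nodes)
      lines <- c(lines, sprintf("  %s%s;", q(nd),
                                if (nd %in% map$hubs) " [shape=box]" else ""))
    for (i in seq_len(nrow(map$edges)))
      lines <- c(lines, sprintf('  %s -- %s [label="%.2f"];',
                                q(map$edges$from[i]), q(map$edges$to[i]),
                                map$edges$ls[i]))
    lines <- c(lines, "}")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Re-import a GraphML connectivity map export
#'
#' Reads back node ids, hub flags, and edges with their full-precision
#' `ls` attribute.
#'
#' @param path GraphML file written by [export_map()].
#' @return List with `nodes`, `hubs`, `edges` (`from`, `to`, `ls`).
#' @export
import_map_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  node_els <- xml2::xml_find_all(doc, ".//g:node", ns)
  nodes <- xml2::xml_attr(node_els, "id")
  hubflag <- vapply(node_els, function(nd) {
    v <- xml2::xml_text(xml2::xml_find_first(nd, ".//g:data[@key='d0']", ns))
    identical(v, "true")
  }, logical(1))
  edge_els <- xml2::xml_find_all(doc, ".//g:edge", ns)
  edges <- data.frame(
    from = xml2::xml_attr(edge_els, "source"),
    to = xml2::xml_attr(edge_els, "target"),
    ls = vapply(edge_els, function(e)
      as.numeric(xml2::xml_text(xml2::xml_find_first(e, ".//g:data[@key='d1']", ns))),
      numeric(1)),
    stringsAsFactors = FALSE)
  list(nodes = nodes, hubs = nodes[hubflag], edges = edges)
}
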