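# Cycle-space analytics on molecular graphs. All edge types are pooled as an
# undirected simple graph; the minimum cycle basis comes from Horton's
# candidate set (one BFS shortest-path tree per root, candidate cycle
# path(v,x) + edge (x,y) + path(y,v)) with greedy GF(2) independence in
# ascending weight order.

# pooled undirected simple edge list (matrix cols i, j over vertex positions)
pooled_edges <- function(g) {
  idx <- stats::setNames(seq_len(nrow(g$vertices)), g$vertices$atom)
  if (!nrow(g$edges)) return(cbind(i = integer(), j = integer()))
  i <- idx[as.character(g$edges$from)]
  j <- idx[as.character(g$edges$to)]
  m <- cbind(i = pmin(i, j), j = pmax(i, j))
  unique(m)
}

# deterministic BFS tree: parent chosen as smallest-id reachable neighbour
bfs_parents <- function(adj, root, n) {
  parent <- rep(NA_integer_, n)
  depth <- rep(NA_integer_, n)
  parent[root] <- 0L; depth[root] <- 0L
  queue <- root
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) {
      if (is.na(depth[v])) {
        depth[v] <- depth[u] + 1L
        parent[v] <- u
        queue <- c(queue, v)
      }
    }
  }
  list(parent = parent, depth = depth)
}

path_to_root <- function(parent, v) {
  p <- v
  while (parent[v] != 0L) { v <- parent[v]; p <- c(p, v) }
  p
}

# canonical rotation/reflection of a cyclic vertex sequence
canonical_cycle <- function(seq) {
  k <- length(seq)
  i0 <- which.min(seq)
  rot <- c(seq(i0, k), seq_len(i0 - 1L))
  fwd <- seq[rot]
  bwd <- c(fwd[1], rev(fwd[-1]))
  if (paste(fwd, collapse = ",") <= paste(bwd, collapse = ",")) fwd else bwd
}

#' Minimum cycle basis of a molecular graph
#'
#' Computes a minimum-weight (unit edge weights) cycle basis via Horton
#' candidate enumeration and greedy GF(2) independence. All edge types are
#' pooled and treated as undirected. Ties among equal-weight candidates are
#' broken by the lexicographic canonical vertex sequence, making the basis
#' deterministic.
#'
#' @param g A `mol_graph`.
#' @return A `cycle_basis` object: list with `cycles` (list of vertex-id
#'   sequences, each a simple cycle without repeated vertices), `dimension`
#'   (`|E| - |V| + C`), and `graph` (the input).
#' @export
minimum_cycle_basis <- function(g) {
  n <- nrow(g$vertices)
  em <- pooled_edges(g)
  m <- nrow(em)
  comp <- if (n) {
    ig <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (m) ig <- igraph::add_edges(ig, t(em))
    igraph::components(ig)$no
  } else 0L
  dim_target <- m - n + comp
  atoms <- g$vertices$atom
  empty <- structure(list(cycles = list(), dimension = 0L, graph = g),
                     class = "cycle_basis")
  if (dim_target <= 0L) return(empty)
  adj <- lapply(seq_len(n), function(u) {
    sort(c(em[em[, "i"] == u, "j"], em[em[, "j"] == u, "i"]))
  })
  edge_index <- stats::setNames(seq_len(m), paste(em[, "i"], em[, "j"]))
  cyc_edge_vec <- function(seq) {
    v <- logical(m)
    k <- length(seq)
    for (t in seq_len(k)) {
      a <- seq[t]; b <- seq[t %% k + 1L]
      v[edge_index[paste(min(a, b), max(a, b))]] <- TRUE
    }
    v
  }
  # Horton candidates
  cands <- list(); seen <- character(0)
  for (v in seq_len(n)) {
    bt <- bfs_parents(adj, v, n)
    for (e in seq_len(m)) {
      x <- em[e, "i"]; y <- em[e, "j"]
      if (is.na(bt$depth[x]) || is.na(bt$depth[y])) next
      px <- path_to_root(bt$parent, x)  # x ... v
      py <- path_to_root(bt$parent, y)
      if (length(intersect(px, py)) != 1L) next  # must meet only at v
      cyc <- c(rev(px), py[-length(py)])  # v..x, y..(v excluded at end)
      if (length(cyc) < 3 || anyDuplicated(cyc)) next
      cc <- canonical_cycle(cyc)
      key <- paste(cc, collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        cands[[length(cands) + 1L]] <- cc
      }
    }
  }
  if (!length(cands)) return(empty)
  lens <- vapply(cands, length, 0L)
  keys <- vapply(cands, paste, "", collapse = ",")
  ord <- order(lens, keys)
  basis <- list()
  pivots <- list()  # reduced GF(2) vectors with their pivot positions
  pivot_pos <- integer(0)
  for (ci in ord) {
    vec <- cyc_edge_vec(cands[[ci]])
    red <- vec
    repeat {
      p <- which(red)[1]
      if (is.na(p)) break
      hit <- match(p, pivot_pos)
      if (is.na(hit)) break
      red <- xor(red, pivots[[hit]])
    }
    if (any(red)) {
      basis[[length(basis) + 1L]] <- cands[[ci]]
      pivots[[length(pivots) + 1L]] <- red
      pivot_pos <- c(pivot_pos, which(red)[1])
      if (length(basis) == dim_target) break
    }
  }
  if (length(basis) != dim_target) {
    stop("internal error: Horton candidate set did not span the cycle space", call. = FALSE)
  }
  structure(list(
    cycles = lapply(basis, function(s) atoms[s]),
    dimension = dim_target, graph = g
  ), class = "cycle_basis")
}

#' @export
print.cycle_basis <- function(x, ...) {
  cat("<cycle_basis> dimension ", x$dimension, sep = "")
  if (x$dimension) {
    cat("; sizes: ", paste(sort(vapply(x$cycles, length, 0L)), collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Connected-component size histogram
#'
#' Pools all edge types as undirected and returns the distribution of
#' component vertex counts (isolated vertices count as components of size 1).
#'
#' @param g A `mol_graph`.
#' @return Tibble with columns `size` and `count`.
#' @export
connected_component_sizes <- function(g) {
  n <- nrow(g$vertices)
  if (!n) return(tibble::tibble(size = integer(), count = integer()))
  em <- pooled_edges(g)
  ig <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(em)) ig <- igraph::add_edges(ig, t(em))
  sizes <- igraph::components(ig)$csize
  tab <- table(sizes)
  tibble::tibble(size = as.integer(names(tab)), count = as.integer(tab))
}

#' Ring-size distribution over a set of graphs
#'
#' Pools the minimum-cycle-basis cycles of every graph (per-frame bases, then
#' pooled) and returns relative frequencies over all cycles.
#'
#' @param graphs A list of `mol_graph` objects (a single graph is accepted).
#' @return Tibble with columns `size` and `frequency` (summing to 1); empty
#'   when no graph has a cycle.
#' @export
ring_size_histogram <- function(graphs) {
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  sizes <- unlist(lapply(graphs, function(g) {
    vapply(minimum_cycle_basis(g)$cycles, length, 0L)
  }))
  if (!length(sizes)) return(tibble::tibble(size = integer(), frequency = numeric()))
  tab <- table(sizes)
  tibble::tibble(size = as.integer(names(tab)),
                 frequency = as.integer(tab) / sum(tab))
}

#' Percentage of vertices belonging to basis polygons
#'
#' For each graph, the percentage of vertices lying on at least one
#' minimum-cycle-basis cycle; the result is the average over graphs.
#'
#' @param graphs A list of `mol_graph` objects (a single graph is accepted).
#' @return Percentage in `[0, 100]`.
#' @export
polygon_membership_fraction <- function(graphs) {
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  fr <- vapply(graphs, function(g) {
    n <- nrow(g$vertices)
    if (!n) stop("polygon membership is undefined for an empty graph", call. = FALSE)
    on_cycle <- unique(unlist(minimum_cycle_basis(g)$cycles))
    length(on_cycle) / n * 100
  }, 0)
  mean(fr)
}

#' Coarse-grained graph of H-bonded cycles
#'
#' Vertices are the basis cycles containing at least one H-bond arc; two
#' cycles are joined when they interact, i.e. share at least one vertex or
#' edge.
#'
#' @param g A `mol_graph`.
#' @param basis A `cycle_basis` computed from `g` (computed when `NULL`).
#' @return A `cycle_graph`: list with tibbles `vertices` (`cycle`, `size`) and
#'   `edges` (`from`, `to`), plus the member atom sets.
#' @export
cycle_interaction_graph <- function(g, basis = NULL) {
  if (is.null(basis)) basis <- minimum_cycle_basis(g)
  hb <- g$edges[g$edges$type == "hbond", c("from", "to")]
  hb_key <- c(paste(hb$from, hb$to), paste(hb$to, hb$from))
  has_hbond <- vapply(basis$cycles, function(cyc) {
    k <- length(cyc)
    any(paste(cyc, cyc[c(2:k, 1)]) %in% hb_key)
  }, TRUE)
  members <- basis$cycles[has_hbond]
  nv <- length(members)
  edges <- tibble::tibble(from = integer(), to = integer())
  if (nv > 1) {
    cp <- t(utils::combn(nv, 2))
    share <- vapply(seq_len(nrow(cp)), function(r) {
      length(intersect(members[[cp[r, 1]]], members[[cp[r, 2]]])) > 0
    }, TRUE)
    edges <- tibble::tibble(from = cp[share, 1], to = cp[share, 2])
  }
  structure(list(
    vertices = tibble::tibble(cycle = seq_len(nv),
                              size = vapply(members, length, 0L)),
    edges = edges,
    members = members
  ), class = "cycle_graph")
}

#' @export
print.cycle_graph <- function(x, ...) {
  cat("<cycle_graph> ", nrow(x$vertices), " H-bonded cycle(s), ",
      nrow(x$edges), " interaction(s)\n", sep = "")
  invisible(x)
}

#' Plot a ring-size histogram
#'
#' @param graphs A list of `mol_graph` objects, or a precomputed tibble from
#'   [ring_size_histogram()].
#' @return A ggplot object.
#' @export
plot_ring_sizes <- function(graphs) {
  df <- if (is.data.frame(graphs)) graphs else ring_size_histogram(graphs)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$size), .data$frequency)) +
    ggplot2::geom_col(fill = "#2980b9") +
    ggplot2::labs(x = "ring size (vertices)", y = "relative frequency")
}

#' Select atoms inside a z slab
#'
#' Convenience filter for interfacial-layer analyses: keeps atoms whose z
#' coordinate lies in `[zmin, zmax]` (optionally restricted by element). The
#' caller remains responsible for choosing a chemically meaningful slab.
#'
#' @param snapshot Snapshot tibble.
#' @param zmin,zmax Slab bounds (Angstrom).
#' @param elements Optional element filter.
#' @return The filtered snapshot tibble.
#' @export
z_slab_filter <- function(snapshot, zmin, zmax, elements = NULL) {
  out <- snapshot[snapshot$z >= zmin & snapshot$z <= zmax, ]
  if (!is.null(elements)) out <- out[out$element %in% elements, ]
  tibble::as_tibble(out)
}
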