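# Sequential-game + linear-reward-inaction generation of a 3D structure from
# a hydrogen-inclusive molecular graph. Each covering-tree edge (u, v) is a
# player choosing the position of v among 42 icosphere directions around u;
# utilities couple local VSEPR comfort (direct) with the discomfort induced
# downstream (indirect). No energy function anywhere.

#' Construct a hydrogen-inclusive molecular graph for 3D generation
#'
#' Unlike the heavy-atom analysis graph, this graph contains every atom
#' (hydrogens included) and its edges are the covalent bonds plus the target
#' H-bonds (heavy-donor to heavy-acceptor pairs). It must be connected.
#'
#' @param vertices Tibble with columns `atom` and `element`.
#' @param edges Tibble with columns `from`, `to`, `type` (`"covalent"` or
#'   `"hbond"`).
#' @return A `full_mol_graph` object.
#' @export
full_mol_graph <- function(vertices, edges) {
  vertices <- tibble::as_tibble(vertices)[, c("atom", "element")]
  edges <- tibble::as_tibble(edges)[, c("from", "to", "type")]
  if (!all(c(edges$from, edges$to) %in% vertices$atom)) {
    stop("edge endpoint is not a vertex", call. = FALSE)
  }
  structure(list(vertices = vertices, edges = edges), class = "full_mol_graph")
}

#' @export
print.full_mol_graph <- function(x, ...) {
  cat("<full_mol_graph> ", nrow(x$vertices), " atoms, ",
      sum(x$edges$type == "covalent"), " covalent bond(s), ",
      sum(x$edges$type == "hbond"), " target H-bond(s)\n", sep = "")
  invisible(x)
}

graph_adjacency <- function(g) {
  n <- nrow(g$vertices)
  idx <- stats::setNames(seq_len(n), g$vertices$atom)
  adj <- vector("list", n)
  for (k in seq_len(nrow(g$edges))) {
    i <- idx[as.character(g$edges$from[k])]
    j <- idx[as.character(g$edges$to[k])]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) sort(unique(v)))
}

#' Breadth-first covering tree of a molecular graph
#'
#' BFS with deterministic neighbour order (ascending atom id). The default
#' root is the highest-degree vertex, ties broken by lowest id. The root's
#' position is fixed at the origin during the game.
#'
#' @param g A `full_mol_graph`.
#' @param root Optional atom id of the root.
#' @return A `covering_tree`: list with `root`, `parent` (0 for the root),
#'   `children`, `order` (BFS vertex order), `depth`, and the tree distance
#'   matrix `dist` (all in vertex positions 1..n; `atoms` maps back to ids).
#' @export
bfs_covering_tree <- function(g, root = NULL) {
  n <- nrow(g$vertices)
  adj <- graph_adjacency(g)
  deg <- vapply(adj, length, 0L)
  root_pos <- if (is.null(root)) {
    order(-deg, g$vertices$atom)[1]
  } else {
    match(root, g$vertices$atom)
  }
  if (is.na(root_pos)) stop("root atom not in graph", call. = FALSE)
  parent <- rep(NA_integer_, n); depth <- rep(NA_integer_, n)
  parent[root_pos] <- 0L; depth[root_pos] <- 0L
  ord <- integer(0); queue <- root_pos
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    ord <- c(ord, u)
    for (v in adj[[u]]) {
      if (is.na(depth[v])) {
        depth[v] <- depth[u] + 1L; parent[v] <- u
        queue <- c(queue, v)
      }
    }
  }
  if (length(ord) < n) stop("graph is not connected", call. = FALSE)
  children <- lapply(seq_len(n), function(u) which(parent == u))
  tree_edges <- which(parent > 0)
  ig <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(tree_edges)) ig <- igraph::add_edges(ig, rbind(parent[tree_edges], tree_edges))
  structure(list(root = root_pos, parent = parent, children = children,
                 order = ord, depth = depth,
                 dist = igraph::distances(ig),
                 atoms = g$vertices$atom),
            class = "covering_tree")
}

#' Precompute the static state of a structure-generation game
#'
#' Gathers everything the game rounds reuse: the covering tree, the player
#' list (one per tree edge), per-edge grid radii, the shared 42-direction
#' grid, graph adjacency split into tree/non-tree neighbours, descendant
#' lists, and VSEPR template data.
#'
#' @param g A `full_mol_graph` (connected).
#' @param params Parameter list from [load_params()].
#' @param hbond_length Ideal heavy-heavy H-bond length (Angstrom).
#' @param root Optional root atom id.
#' @return A `game_setup` object.
#' @export
game_setup <- function(g, params = load_params(), hbond_length = 2.9, root = NULL) {
  n <- nrow(g$vertices)
  el <- g$vertices$element
  idx <- stats::setNames(seq_len(n), g$vertices$atom)
  tree <- bfs_covering_tree(g, root)
  adj <- graph_adjacency(g)
  rcov <- params$elements$covalent_radius[match(el, params$elements$symbol)]
  radius_of <- matrix(NA_real_, n, n)
  for (k in seq_len(nrow(g$edges))) {
    i <- idx[as.character(g$edges$from[k])]; j <- idx[as.character(g$edges$to[k])]
    r <- if (g$edges$type[k] == "covalent") rcov[i] + rcov[j] else hbond_length
    radius_of[i, j] <- r; radius_of[j, i] <- r
  }
  players <- do.call(rbind, lapply(tree$order, function(u) {
    ch <- tree$children[[u]]
    if (!length(ch)) return(NULL)
    data.frame(u = u, v = ch, radius = radius_of[u, ch])
  }))
  if (is.null(players)) players <- data.frame(u = integer(), v = integer(), radius = numeric())
  nontree_nb <- lapply(seq_len(n), function(w) {
    setdiff(adj[[w]], c(tree$children[[w]], if (tree$parent[w] > 0) tree$parent[w]))
  })
  nonadj <- lapply(seq_len(n), function(w) setdiff(seq_len(n), c(w, adj[[w]])))
  descendants <- lapply(seq_len(n), function(u) {
    out <- integer(0); frontier <- tree$children[[u]]
    while (length(frontier)) {
      out <- c(out, frontier)
      frontier <- unlist(lapply(frontier, function(x) tree$children[[x]]))
    }
    out
  })
  grid_radius <- vapply(seq_len(n), function(w) {
    r <- radius_of[w, adj[[w]]]
    if (length(r)) max(r) else 0
  }, 0)
  structure(list(
    graph = g, n = n, elements = el, tree = tree, adj = adj,
    players = players, directions = icosphere_directions(),
    radius_of = radius_of, nontree_nb = nontree_nb, nonadj = nonadj,
    descendants = descendants, grid_radius = grid_radius,
    templates = vsepr_templates(), lone_pairs = lone_pairs_of(el)
  ), class = "game_setup")
}

#' Place the children of a vertex from sampled strategies
#'
#' Applies the grid rotation of `u` — the minimal rotation taking the grid's
#' virtual-parent direction (direction 1) onto the actual direction of `u`'s
#' parent, or the identity for the root — and places each child at its
#' strategy direction scaled by the player's grid radius.
#'
#' @param setup A `game_setup`.
#' @param u Vertex position (1..n) whose children are placed.
#' @param strategies Integer vector of strategy indices (1..42), one per child
#'   of `u` in `setup$players` order.
#' @param positions n x 3 matrix of current positions (`u`, and its parent if
#'   any, must be placed).
#' @return The updated positions matrix.
#' @export
place_children <- function(setup, u, strategies, positions) {
  ch <- setup$tree$children[[u]]
  if (!length(ch)) return(positions)
  stopifnot(length(strategies) == length(ch))
  par <- setup$tree$parent[u]
  rot <- if (par == 0L) diag(3) else {
    dir_par <- positions[par, ] - positions[u, ]
    rotation_between(setup$directions[1, ], dir_par)
  }
  for (k in seq_along(ch)) {
    v <- ch[k]
    r <- setup$radius_of[u, v]
    positions[v, ] <- positions[u, ] + r * as.numeric(rot %*% setup$directions[strategies[k], ])
  }
  positions
}

#' Direct utility of a vertex
#'
#' The deviation of the placed neighbours of `u` (all graph neighbours,
#' radius-normalised onto the unit sphere around `u`) from the VSEPR ideal
#' arrangement: minimum over neighbour-to-slot assignments and template
#' rotations of the summed distances. Isolated or singly-bonded vertices
#' score 0.
#'
#' @inheritParams place_children
#' @param refine Exactly minimise the distance sum over rotations (see
#'   [vsepr_deviation()]).
#' @return Non-negative deviation.
#' @export
direct_utility <- function(setup, positions, u, refine = TRUE) {
  nb <- setup$adj[[u]]
  nb <- nb[!is.na(positions[nb, 1])]
  if (length(nb) <= 1) return(0)
  dirs <- positions[nb, , drop = FALSE] -
    matrix(positions[u, ], length(nb), 3, byrow = TRUE)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  vsepr_deviation(dirs, setup$elements[u], setup$templates, refine = refine)
}

#' Local discomfort of a vertex
#'
#' Sum over non-tree graph neighbours `v` of the distance between `v`'s
#' position and its projection onto `w`'s grid sphere, plus, for every vertex
#' `z` not adjacent to `w` that intrudes into `w`'s grid sphere
#' (`||p(z) - p(w)|| <=` grid radius), the distance `||p(z) - p(w)||`.
#'
#' @inheritParams place_children
#' @param w Vertex position (1..n).
#' @return Non-negative sum.
#' @export
local_term <- function(setup, positions, w) {
  total <- 0
  for (v in setup$nontree_nb[[w]]) {
    if (is.na(positions[v, 1])) next
    d <- sqrt(sum((positions[v, ] - positions[w, ])^2))
    total <- total + abs(d - setup$radius_of[w, v])
  }
  gr <- setup$grid_radius[w]
  for (z in setup$nonadj[[w]]) {
    if (is.na(positions[z, 1])) next
    d <- sqrt(sum((positions[z, ] - positions[w, ])^2))
    if (d <= gr) total <- total + d
  }
  total
}

#' Indirect utility of a vertex
#'
#' Sum over the proper descendants `v` of `u` in the covering tree of
#' `local_term(v) / dist_T(u, v)`: the (bad) impact of `u`'s choices on the
#' part of the molecule placed after it.
#'
#' @inheritParams local_term
#' @param u Vertex position (1..n).
#' @param locals Optional precomputed vector of local terms.
#' @return Non-negative sum; 0 for a leaf.
#' @export
indirect_utility <- function(setup, positions, u, locals = NULL) {
  ds <- setup$descendants[[u]]
  if (!length(ds)) return(0)
  if (is.null(locals)) {
    locals <- rep(NA_real_, setup$n)
    for (v in ds) locals[v] <- local_term(setup, positions, v)
  }
  sum(locals[ds] / (setup$tree$depth[ds] - setup$tree$depth[u]))
}

#' Round cost of a player
#'
#' `(direct + indirect) / 2`; every player sharing the same parent vertex `u`
#' receives the same cost.
#'
#' @param direct,indirect Utilities from [direct_utility()] and
#'   [indirect_utility()].
#' @return The cost.
#' @export
round_cost <- function(direct, indirect) (direct + indirect) / 2

#' Normalised utility of a player
#'
#' `(Max(s) - R) / (Max(s) - Min(s))` where `Max(s)`/`Min(s)` are the
#' player's running extremes of the cost over rounds in which the same
#' strategy was played (including the current round). When the extremes
#' coincide (first play of a strategy) the utility is neutral, 0.5.
#'
#' @param r Current cost.
#' @param max_s,min_s Running extremes including `r`.
#' @return Utility in `[0, 1]`.
#' @export
normalized_utility <- function(r, max_s, min_s) {
  if (max_s > min_s) (max_s - r) / (max_s - min_s) else 0.5
}

#' Linear reward-inaction update of a strategy vector
#'
#' The played strategy gains `(1 - V(s)) * b * u`; every other entry loses
#' `V(s') * b * u`. The vector remains a probability distribution, and a zero
#' utility leaves it unchanged (inaction).
#'
#' @param v Probability vector over strategies.
#' @param chosen Index of the played strategy.
#' @param utility Utility in `[0, 1]`.
#' @param b Slowing factor in `[0, 1]`.
#' @return The updated probability vector.
#' @export
lri_update <- function(v, chosen, utility, b) {
  step <- b * utility
  out <- v - v * step
  out[chosen] <- v[chosen] + (1 - v[chosen]) * step
  if (any(out < -1e-12)) stop("LRI update produced a negative probability", call. = FALSE)
  out
}

#' Generate a 3D structure from a molecular graph by game play
#'
#' Repeats rounds of the sequential game: every player samples a strategy
#' from its current probability vector, children are placed in BFS order,
#' costs and normalised utilities are computed, and strategy vectors receive
#' the linear reward-inaction update. Per block, the best round-average
#' utility `m_k` and its positions are tracked, with early stopping after `t`
#' rounds without improvement; blocks are independent restarts (strategy
#' vectors and cost histories reset).
#'
#' @param g A `full_mol_graph` (connected).
#' @param blocks Number of independent blocks.
#' @param rounds Maximum rounds per block.
#' @param b LRI slowing factor in `[0, 1]`.
#' @param t Early-stop patience (rounds without `m_k` improvement).
#' @param seed RNG seed.
#' @param params Parameter list from [load_params()].
#' @param hbond_length Ideal heavy-heavy H-bond length (Angstrom).
#' @param root Optional root atom id.
#' @param target Optional target snapshot tibble; per-block superposition
#'   RMSD against it is reported.
#' @param refine Exact rotation minimisation inside the direct utility
#'   (slower); the default uses the least-squares alignment, which preserves
#'   the cost ranking the learning needs.
#' @param trace_every Keep every k-th round in the trace (1 = all).
#' @return A `game_result`: list with `best` (snapshot tibble of the overall
#'   best structure), `best_m`, `best_block`, `blocks` (per-block tibble in
#'   best-m / RMSD table format), `trace` (tibble `block`, `round`, `m`,
#'   `best_m`), and `setup`.
#' @export
#' @examples
#' g <- full_mol_graph(
#'   tibble::tibble(atom = 1:2, element = c("H", "H")),
#'   tibble::tibble(from = 1, to = 2, type = "covalent")
#' )
#' res <- run_game(g, blocks = 1, rounds = 50, t = 25, seed = 1)
#' glance(res)
run_game <- function(g, blocks = 10, rounds = 5000, b = 0.1, t = 500, seed = 1,
                     params = load_params(), hbond_length = 2.9, root = NULL,
                     target = NULL, refine = FALSE, trace_every = 1L) {
  setup <- game_setup(g, params, hbond_length, root)
  n <- setup$n
  pl <- setup$players
  np <- nrow(pl)
  if (!np) stop("graph has a single vertex; nothing to place", call. = FALSE)
  set.seed(seed)
  n_strat <- nrow(setup$directions)
  parents <- unique(pl$u)
  players_of_u <- lapply(seq_len(n), function(u) which(pl$u == u))
  overall_best_m <- -Inf; overall_best_pos <- NULL; overall_best_block <- NA_integer_
  block_rows <- vector("list", blocks)
  trace <- vector("list", blocks)
  for (blk in seq_len(blocks)) {
    v_mat <- matrix(1 / n_strat, np, n_strat)
    max_c <- matrix(NA_real_, np, n_strat)
    min_c <- matrix(NA_real_, np, n_strat)
    best_m <- -Inf; best_pos <- NULL; best_round <- NA_integer_
    stall <- 0L
    tr_round <- integer(0); tr_m <- numeric(0); tr_best <- numeric(0)
    for (k in seq_len(rounds)) {
      positions <- matrix(NA_real_, n, 3)
      positions[setup$tree$root, ] <- 0
      played <- integer(np)
      for (u in setup$tree$order) {
        ps <- players_of_u[[u]]
        if (!length(ps)) next
        for (p in ps) played[p] <- sample.int(n_strat, 1L, prob = v_mat[p, ])
        positions <- place_children(setup, u, played[ps], positions)
      }
      locals <- vapply(seq_len(n), function(w) local_term(setup, positions, w), 0)
      util <- numeric(np)
      for (u in parents) {
        du <- direct_utility(setup, positions, u, refine = refine)
        iu <- indirect_utility(setup, positions, u, locals = locals)
        rc <- round_cost(du, iu)
        for (p in players_of_u[[u]]) {
          s <- played[p]
          max_c[p, s] <- max(max_c[p, s], rc, na.rm = TRUE)
          min_c[p, s] <- min(min_c[p, s], rc, na.rm = TRUE)
          util[p] <- normalized_utility(rc, max_c[p, s], min_c[p, s])
          v_mat[p, ] <- lri_update(v_mat[p, ], s, util[p], b)
        }
      }
      m <- mean(util)
      if (m >= best_m) {
        # ties keep the latest round: with converged strategies the same best
        # m recurs, and the late geometry reflects the learned equilibrium
        if (m > best_m) stall <- 0L else stall <- stall + 1L
        best_m <- m; best_pos <- positions; best_round <- k
      } else {
        stall <- stall + 1L
      }
      if (k %% trace_every == 0L) {
        tr_round <- c(tr_round, k); tr_m <- c(tr_m, m); tr_best <- c(tr_best, best_m)
      }
      if (stall >= t) break
    }
    rms <- if (!is.null(target)) {
      rmsd(positions_to_snapshot(setup, best_pos), target, superpose = TRUE)
    } else NA_real_
    block_rows[[blk]] <- tibble::tibble(block = blk, best_m = best_m,
                                        best_round = best_round, rmsd = rms)
    trace[[blk]] <- tibble::tibble(block = blk, round = tr_round,
                                   m = tr_m, best_m = tr_best)
    if (best_m > overall_best_m) {
      overall_best_m <- best_m; overall_best_pos <- best_pos
      overall_best_block <- blk
    }
  }
  structure(list(
    best = positions_to_snapshot(setup, overall_best_pos),
    best_m = overall_best_m, best_block = overall_best_block,
    blocks = dplyr::bind_rows(block_rows),
    trace = dplyr::bind_rows(trace),
    setup = setup
  ), class = "game_result")
}

positions_to_snapshot <- function(setup, positions) {
  tibble::tibble(atom = setup$graph$vertices$atom,
                 element = setup$elements,
                 x = positions[, 1], y = positions[, 2], z = positions[, 3])
}

#' @export
print.game_result <- function(x, ...) {
  cat("<game_result> best m = ", format(x$best_m, digits = 4),
      " (block ", x$best_block, ")\n", sep = "")
  print(x$blocks)
  invisible(x)
}

#' Tidy / summarise a game result
#'
#' `tidy()` returns the per-block best-m/RMSD table; `glance()` a one-row
#' summary.
#'
#' @param x A `game_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.game_result <- function(x, ...) x$blocks

#' @rdname tidy.game_result
#' @export
glance.game_result <- function(x, ...) {
  tibble::tibble(best_m = x$best_m, best_block = x$best_block,
                 blocks = nrow(x$blocks),
                 rounds = nrow(x$trace),
                 best_rmsd = suppressWarnings(min(x$blocks$rmsd, na.rm = TRUE)))
}

#' Plot the utility trace of a game
#'
#' Round-average utility `m_k` and its running best per block.
#'
#' @param object A `game_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.game_result <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$round)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$m), alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = .data$best_m), colour = "#c0392b") +
    ggplot2::facet_wrap(~block) +
    ggplot2::labs(x = "round", y = expression(m[k]))
}
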