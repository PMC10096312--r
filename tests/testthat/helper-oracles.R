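# Independent test oracles: exhaustive colour-respecting bijection search for
# graph isomorphism, GF(2) rank checks for cycle bases, brute-force rotation
# minimisation, and random fixture generators. These deliberately share no
# code with the implementation paths they check.

.perm_cache <- new.env(parent = emptyenv())

all_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  out <- if (n == 1) list(1L) else {
    acc <- list()
    for (p in all_perms(n - 1L)) {
      for (pos in 0:(n - 1L)) {
        acc[[length(acc) + 1L]] <- append(p, n, after = pos)
      }
    }
    acc
  }
  .perm_cache[[key]] <- out
  out
}

# ordered-pair typed edge keys of a mol_graph under a vertex mapping
# map: named vector old atom id -> new atom id
mapped_edge_keys <- function(g, map = NULL) {
  e <- g$edges
  from <- e$from; to <- e$to
  if (!is.null(map)) {
    from <- unname(map[as.character(from)])
    to <- unname(map[as.character(to)])
  }
  und <- e$type != "hbond"
  keys <- character(nrow(e))
  keys[und] <- paste(e$type[und], pmin(from[und], to[und]), pmax(from[und], to[und]))
  keys[!und] <- paste("hbond", from[!und], to[!und])
  sort(keys)
}

# exhaustive oracle: try every colour-respecting bijection
iso_oracle <- function(g1, g2) {
  n <- nrow(g1$vertices)
  if (n != nrow(g2$vertices)) return(FALSE)
  if (!identical(sort(g1$vertices$element), sort(g2$vertices$element))) return(FALSE)
  if (n == 0) return(TRUE)
  a1 <- g1$vertices$atom; a2 <- g2$vertices$atom
  e1 <- g1$vertices$element; e2 <- g2$vertices$element
  k2 <- mapped_edge_keys(g2)
  for (p in all_perms(n)) {
    perm <- unlist(p)
    if (!all(e1 == e2[perm])) next
    map <- stats::setNames(a2[perm], a1)
    if (identical(mapped_edge_keys(g1, map), k2)) return(TRUE)
  }
  FALSE
}

# random coloured mixed graph on <= n vertices
rand_colored_graph <- function(n, p_edge = 0.45, elements = c("C", "N", "O")) {
  el <- sample(elements, n, replace = TRUE)
  edges <- NULL
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge) {
        ty <- sample(c("covalent", "hbond", "electrostatic", "organometallic"), 1)
        if (ty == "hbond" && stats::runif(1) < 0.5) {
          edges <- rbind(edges, data.frame(from = j, to = i, type = ty))
        } else {
          edges <- rbind(edges, data.frame(from = i, to = j, type = ty))
        }
      }
    }
  }
  mol_graph(tibble::tibble(atom = seq_len(n), element = el),
            if (is.null(edges)) NULL else tibble::as_tibble(edges),
            n_atoms = n)
}

# relabel the vertices of a graph by a random permutation
permute_graph <- function(g) {
  n <- nrow(g$vertices)
  perm <- sample.int(n)
  map <- stats::setNames(perm, g$vertices$atom)
  v <- tibble::tibble(atom = unname(map[as.character(g$vertices$atom)]),
                      element = g$vertices$element)
  e <- g$edges
  if (nrow(e)) {
    e$from <- unname(map[as.character(e$from)])
    e$to <- unname(map[as.character(e$to)])
  }
  mol_graph(v[order(v$atom), ], e, n_atoms = g$n_atoms)
}

# GF(2) rank of a logical matrix (rows = vectors)
gf2_rank <- function(m) {
  m <- m[rowSums(m) > 0, , drop = FALSE]
  rank <- 0L
  for (col in seq_len(ncol(m))) {
    piv <- which(m[, col])
    piv <- piv[piv > rank]
    if (!length(piv)) next
    rank <- rank + 1L
    if (piv[1] != rank) m[c(rank, piv[1]), ] <- m[c(piv[1], rank), ]
    for (r in which(m[, col])) {
      if (r != rank) m[r, ] <- xor(m[r, ], m[rank, ])
    }
  }
  rank
}

# edge-set incidence vectors of cycles over a fixed edge universe
cycles_to_matrix <- function(cycles, edge_keys) {
  m <- matrix(FALSE, length(cycles), length(edge_keys))
  for (r in seq_along(cycles)) {
    cyc <- cycles[[r]]
    k <- length(cyc)
    for (t in seq_len(k)) {
      a <- cyc[t]; b <- cyc[t %% k + 1]
      m[r, match(paste(min(a, b), max(a, b)), edge_keys)] <- TRUE
    }
  }
  m
}

graph_edge_keys <- function(g) {
  e <- g$edges
  unique(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
}

# enumerate all simple cycles of a small mol_graph (pooled undirected), as
# edge-incidence vectors; DFS over vertex sequences starting at the minimum
# vertex of each cycle
all_simple_cycles <- function(g) {
  e <- g$edges
  adj <- list()
  vs <- g$vertices$atom
  for (v in vs) adj[[as.character(v)]] <- integer(0)
  for (r in seq_len(nrow(e))) {
    a <- e$from[r]; b <- e$to[r]
    adj[[as.character(a)]] <- unique(c(adj[[as.character(a)]], b))
    adj[[as.character(b)]] <- unique(c(adj[[as.character(b)]], a))
  }
  found <- list(); seen <- character(0)
  dfs <- function(path) {
    u <- path[length(path)]
    for (w in adj[[as.character(u)]]) {
      if (w == path[1] && length(path) >= 3) {
        key <- paste(sort(path), collapse = ",")
        cyc_edges <- sort(paste(pmin(path, c(path[-1], path[1])),
                                pmax(path, c(path[-1], path[1]))))
        ekey <- paste(cyc_edges, collapse = "|")
        if (!ekey %in% seen) {
          seen <<- c(seen, ekey)
          found[[length(found) + 1L]] <<- path
        }
      } else if (!w %in% path && w > path[1]) {
        dfs(c(path, w))
      }
    }
  }
  for (v in vs) dfs(v)
  found
}

# minimum total weight of any cycle basis, by exhaustive greedy over all
# simple cycles sorted by length (matroid greedy is optimal)
min_basis_weight_oracle <- function(g) {
  cycles <- all_simple_cycles(g)
  if (!length(cycles)) return(0L)
  keys <- graph_edge_keys(g)
  lens <- vapply(cycles, length, 0L)
  ord <- order(lens)
  mat <- cycles_to_matrix(cycles, keys)
  chosen <- matrix(FALSE, 0, length(keys))
  total <- 0L
  for (i in ord) {
    cand <- rbind(chosen, mat[i, ])
    if (gf2_rank(cand) > nrow(chosen)) {
      chosen <- cand
      total <- total + lens[i]
    }
  }
  total
}

# uniform random rotation matrix (quaternion method)
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# independent brute force for the VSEPR deviation: own permutation code and
# many random-start local searches over rotations (no Kabsch initialisation)
vsepr_brute_force <- function(neighbor_dirs, template, n_starts = 120) {
  d <- nrow(template)
  perms <- all_perms(d)
  best <- Inf
  for (p in perms) {
    tp <- template[unlist(p), , drop = FALSE]
    obj <- function(w) {
      th <- sqrt(sum(w^2))
      r <- if (th < 1e-12) diag(3) else {
        k <- w / th
        kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
        diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
      }
      sum(sqrt(rowSums((neighbor_dirs - tp %*% t(r))^2)))
    }
    for (s in seq_len(n_starts)) {
      w0 <- stats::rnorm(3); w0 <- w0 / sqrt(sum(w0^2)) * stats::runif(1, 0, pi)
      o <- stats::optim(w0, obj, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-12))
      if (o$value < best) best <- o$value
    }
  }
  best
}

# random plausible structure for IO round trips
random_structure <- function(n) {
  tibble::tibble(
    atom = seq_len(n),
    element = sample(c("H", "C", "N", "O", "S"), n, replace = TRUE),
    x = stats::runif(n, -20, 20), y = stats::runif(n, -20, 20),
    z = stats::runif(n, -20, 20)
  )
}
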