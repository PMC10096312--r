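#' Construct a molecular graph object
#'
#' A `mol_graph` is a coloured mixed graph: vertices are the heavy (non-H)
#' atoms coloured by element, and typed edges hold covalent bonds, directed
#' hydrogen-bond arcs (donor heavy atom to acceptor heavy atom, with the
#' mediating hydrogen recorded), electrostatic contacts and organometallic
#' contacts. Hydrogens enter only through the arcs that they mediate.
#'
#' @param vertices Tibble with columns `atom` (id) and `element`.
#' @param edges Tibble with columns `from`, `to`, `type` (one of `"covalent"`,
#'   `"hbond"`, `"electrostatic"`, `"organometallic"`) and `hydrogen`
#'   (mediating H id for `hbond` rows, `NA` otherwise). Undirected types are
#'   stored with `from < to`; `hbond` rows are ordered donor -> acceptor.
#' @param n_atoms Total atom count of the originating snapshot (hydrogens
#'   included); used to check that two graphs live over the same atom universe.
#' @return A `mol_graph` object.
#' @export
mol_graph <- function(vertices, edges = NULL, n_atoms = max(vertices$atom, 0L)) {
  vertices <- tibble::as_tibble(vertices)[, c("atom", "element")]
  if (is.null(edges) || !nrow(edges)) {
    edges <- tibble::tibble(from = integer(), to = integer(),
                            type = character(), hydrogen = integer())
  }
  edges <- tibble::as_tibble(edges)
  if (!"hydrogen" %in% names(edges)) edges$hydrogen <- NA_integer_
  undirected <- edges$type != "hbond"
  swap <- undirected & edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  edges <- dplyr::distinct(dplyr::arrange(edges, .data$type, .data$from, .data$to))
  if (nrow(edges) && !all(c(edges$from, edges$to) %in% vertices$atom)) {
    stop("edge endpoint is not a vertex", call. = FALSE)
  }
  structure(list(vertices = vertices, edges = edges, n_atoms = as.integer(n_atoms)),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  tab <- table(x$edges$type)
  cat("<mol_graph> ", nrow(x$vertices), " heavy-atom vertices (",
      paste(sprintf("%s:%d", names(table(x$vertices$element)), table(x$vertices$element)),
            collapse = " "), ")\n", sep = "")
  if (length(tab)) {
    cat("  edges:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  } else cat("  edges: none\n")
  invisible(x)
}

#' @export
format.mol_graph <- function(x, ...) {
  paste0("<mol_graph: ", nrow(x$vertices), " vertices, ", nrow(x$edges), " edges>")
}

snapshot_coords <- function(snapshot) {
  m <- cbind(snapshot$x, snapshot$y, snapshot$z)
  rownames(m) <- snapshot$atom
  m
}

#' Compute the orbit of every atom
#'
#' The orbit of atom `a` is the set of atoms within `orbit_radius` of `a` at a
#' reference snapshot; perception scans are restricted to orbit pairs so that
#' an all-pairs distance search is only needed when orbits are refreshed.
#'
#' @param snapshot Snapshot tibble.
#' @param orbit_radius Orbit radius in Angstrom; must be at least the largest
#'   interaction cutoff for perception restricted to orbits to be exact.
#' @param reference_frame Frame index recorded as the orbit reference.
#' @return An `mt_orbits` object: per-atom candidate id sets plus the reference
#'   positions used to decide when a refresh is due.
#' @export
compute_orbits <- function(snapshot, orbit_radius, reference_frame = 1L) {
  pos <- snapshot_coords(snapshot)
  n <- nrow(pos)
  d <- as.matrix(stats::dist(pos))
  nb <- lapply(seq_len(n), function(i) {
    snapshot$atom[which(d[i, ] <= orbit_radius & seq_len(n) != i)]
  })
  names(nb) <- snapshot$atom
  structure(list(neighbors = nb, radius = orbit_radius,
                 reference_positions = pos,
                 reference_frame = as.integer(reference_frame)),
            class = "mt_orbits")
}

# Candidate unordered atom-id pairs (matrix with columns i, j) from orbits,
# or all pairs when orbits is NULL.
candidate_pairs <- function(snapshot, orbits = NULL) {
  ids <- snapshot$atom
  if (is.null(orbits)) {
    if (length(ids) < 2) return(cbind(i = integer(), j = integer()))
    cp <- t(utils::combn(ids, 2))
    return(cbind(i = cp[, 1], j = cp[, 2]))
  }
  pairs <- do.call(rbind, lapply(ids, function(a) {
    b <- orbits$neighbors[[as.character(a)]]
    b <- b[b > a]
    if (length(b)) cbind(i = a, j = b) else NULL
  }))
  if (is.null(pairs)) cbind(i = integer(), j = integer()) else pairs
}

#' Perceive covalent bonds
#'
#' A pair (a, b) is covalent when the distance does not exceed
#' `r_cov(a) + r_cov(b) + covalent_tolerance` and neither atom exceeds its
#' valence cap. When candidates overflow a cap, bonds are granted greedily in
#' ascending distance order (ties broken by the smaller atom-id pair), so the
#' nearest atoms win and perception is order-independent.
#'
#' @inheritParams compute_orbits
#' @param params Parameter list from [load_params()].
#' @param thresholds Thresholds list (defaults to `params$thresholds`).
#' @param orbits Optional `mt_orbits` restricting the candidate scan.
#' @return Tibble of covalent pairs (`from` < `to`), all atoms included
#'   (hydrogens too).
#' @export
perceive_covalent <- function(snapshot, params = load_params(),
                              thresholds = params$thresholds, orbits = NULL) {
  pairs <- candidate_pairs(snapshot, orbits)
  if (!nrow(pairs)) return(tibble::tibble(from = integer(), to = integer()))
  pos <- snapshot_coords(snapshot)
  idx <- match(snapshot$atom, snapshot$atom)  # identity; atoms index pos rows
  el <- snapshot$element
  rcov <- params$elements$covalent_radius[match(el, params$elements$symbol)]
  caps <- params$elements$max_covalent_bonds[match(el, params$elements$symbol)]
  if (anyNA(rcov)) {
    stop("unknown element(s): ",
         paste(unique(el[is.na(rcov)]), collapse = ", "), call. = FALSE)
  }
  row_of <- stats::setNames(seq_along(snapshot$atom), snapshot$atom)
  ri <- row_of[as.character(pairs[, "i"])]
  rj <- row_of[as.character(pairs[, "j"])]
  d <- sqrt(rowSums((pos[ri, , drop = FALSE] - pos[rj, , drop = FALSE])^2))
  cut <- rcov[ri] + rcov[rj] + thresholds$covalent_tolerance
  keep <- d <= cut
  ri <- ri[keep]; rj <- rj[keep]; d <- d[keep]
  ord <- order(d, pmin(snapshot$atom[ri], snapshot$atom[rj]),
               pmax(snapshot$atom[ri], snapshot$atom[rj]))
  ri <- ri[ord]; rj <- rj[ord]
  degree <- integer(nrow(snapshot))
  from <- integer(0); to <- integer(0)
  for (k in seq_along(ri)) {
    a <- ri[k]; b <- rj[k]
    if (degree[a] < caps[a] && degree[b] < caps[b]) {
      degree[a] <- degree[a] + 1L
      degree[b] <- degree[b] + 1L
      from <- c(from, snapshot$atom[a]); to <- c(to, snapshot$atom[b])
    }
  }
  tibble::tibble(from = pmin(from, to), to = pmax(from, to))
}

#' Perceive hydrogen bonds as directed donor-to-acceptor arcs
#'
#' An arc D -> A exists when a hydrogen H is covalently bonded to heavy donor
#' D, A is an acceptor element distinct from D, the heavy-heavy distance
#' d(D, A) is within `hbond_heavy_max`, and the D-H...A angle (at the
#' hydrogen) is at least `hbond_angle_min`.
#'
#' @inheritParams perceive_covalent
#' @param covalent Covalent pair tibble from [perceive_covalent()].
#' @return Tibble with columns `donor`, `acceptor`, `hydrogen`.
#' @export
perceive_hbonds <- function(snapshot, covalent, thresholds = default_thresholds()) {
  pos <- snapshot_coords(snapshot)
  row_of <- stats::setNames(seq_along(snapshot$atom), snapshot$atom)
  el <- snapshot$element
  out <- list()
  h_atoms <- snapshot$atom[el == "H"]
  acceptors <- snapshot$atom[el %in% thresholds$acceptor_elements]
  for (h in h_atoms) {
    partners <- c(covalent$to[covalent$from == h], covalent$from[covalent$to == h])
    partners <- partners[el[row_of[as.character(partners)]] != "H"]
    for (d_atom in partners) {
      for (a_atom in acceptors) {
        if (a_atom == d_atom) next
        dv <- pos[row_of[as.character(a_atom)], ] - pos[row_of[as.character(d_atom)], ]
        dist_da <- sqrt(sum(dv^2))
        if (dist_da > thresholds$hbond_heavy_max) next
        hp <- pos[row_of[as.character(h)], ]
        v1 <- pos[row_of[as.character(d_atom)], ] - hp
        v2 <- pos[row_of[as.character(a_atom)], ] - hp
        ang <- angle_deg(v1, v2)
        if (ang >= thresholds$hbond_angle_min) {
          out[[length(out) + 1L]] <- tibble::tibble(
            donor = d_atom, acceptor = a_atom, hydrogen = h)
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(donor = integer(), acceptor = integer(), hydrogen = integer()))
  }
  dplyr::distinct(dplyr::bind_rows(out))
}

angle_deg <- function(v1, v2) {
  c1 <- sqrt(sum(v1^2)); c2 <- sqrt(sum(v2^2))
  if (c1 == 0 || c2 == 0) return(0)
  ct <- sum(v1 * v2) / (c1 * c2)
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Perceive electrostatic or organometallic contacts
#'
#' A pair is included when exactly one endpoint carries the kind-specific flag
#' (`is_ion_candidate` for electrostatic, `is_metal` for organometallic), the
#' distance is within the kind's cutoff, and the pair is not already covalent.
#' Hydrogens are excluded (these contacts join graph vertices, which are heavy
#' atoms).
#'
#' @inheritParams perceive_covalent
#' @param kind `"electrostatic"` or `"organometallic"`.
#' @param covalent Covalent pair tibble.
#' @return Tibble of pairs (`from` < `to`).
#' @export
perceive_special <- function(snapshot, kind = c("electrostatic", "organometallic"),
                             params = load_params(), thresholds = params$thresholds,
                             covalent = NULL) {
  kind <- match.arg(kind)
  flag <- if (kind == "electrostatic") "is_ion_candidate" else "is_metal"
  cutoff <- if (kind == "electrostatic") thresholds$electrostatic_max else thresholds$organometallic_max
  heavy <- snapshot[snapshot$element != "H", ]
  if (nrow(heavy) < 2) return(tibble::tibble(from = integer(), to = integer()))
  flagged <- params$elements[[flag]][match(heavy$element, params$elements$symbol)]
  flagged[is.na(flagged)] <- FALSE
  pos <- snapshot_coords(heavy)
  cp <- t(utils::combn(seq_len(nrow(heavy)), 2))
  one_flagged <- xor(flagged[cp[, 1]], flagged[cp[, 2]])
  d <- sqrt(rowSums((pos[cp[, 1], , drop = FALSE] - pos[cp[, 2], , drop = FALSE])^2))
  keep <- one_flagged & d <= cutoff
  out <- tibble::tibble(from = pmin(heavy$atom[cp[keep, 1]], heavy$atom[cp[keep, 2]]),
                        to = pmax(heavy$atom[cp[keep, 1]], heavy$atom[cp[keep, 2]]))
  if (!is.null(covalent) && nrow(covalent) && nrow(out)) {
    cov_key <- paste(covalent$from, covalent$to)
    out <- out[!paste(out$from, out$to) %in% cov_key, ]
  }
  out
}

#' Build the 2D molecular graph of a snapshot
#'
#' Runs covalent, hydrogen-bond, electrostatic and organometallic perception
#' and assembles the coloured mixed graph. Vertices are the non-hydrogen atoms
#' coloured by element; hydrogens appear only as mediators of H-bond arcs.
#'
#' @inheritParams perceive_covalent
#' @return A [mol_graph()] object.
#' @export
#' @examples
#' w <- make_molecule("water")
#' build_molgraph(w$structure)
build_molgraph <- function(snapshot, params = load_params(),
                           thresholds = params$thresholds, orbits = NULL) {
  cov <- perceive_covalent(snapshot, params, thresholds, orbits)
  hb <- perceive_hbonds(snapshot, cov, thresholds)
  ei <- perceive_special(snapshot, "electrostatic", params, thresholds, cov)
  eo <- perceive_special(snapshot, "organometallic", params, thresholds, cov)
  heavy <- snapshot[snapshot$element != "H", c("atom", "element")]
  is_heavy <- function(a) snapshot$element[match(a, snapshot$atom)] != "H"
  cov_heavy <- cov[is_heavy(cov$from) & is_heavy(cov$to), ]
  edges <- dplyr::bind_rows(
    tibble::tibble(from = cov_heavy$from, to = cov_heavy$to,
                   type = "covalent", hydrogen = NA_integer_),
    tibble::tibble(from = hb$donor, to = hb$acceptor,
                   type = "hbond", hydrogen = hb$hydrogen),
    tibble::tibble(from = ei$from, to = ei$to,
                   type = "electrostatic", hydrogen = NA_integer_),
    tibble::tibble(from = eo$from, to = eo$to,
                   type = "organometallic", hydrogen = NA_integer_)
  )
  mol_graph(heavy, edges, n_atoms = nrow(snapshot))
}

#' Element-plus-ordinal atom labels (N1, O2, ...)
#'
#' Labels follow first-appearance order of each element across the snapshot,
#' mirroring the conventional bond labels of transition-graph exports.
#'
#' @param snapshot Snapshot tibble.
#' @return Named character vector keyed by atom id.
#' @export
atom_labels <- function(snapshot) {
  ord <- stats::ave(seq_len(nrow(snapshot)), snapshot$element, FUN = seq_along)
  stats::setNames(paste0(snapshot$element, ord), snapshot$atom)
}

#' Export a molecular graph as GraphML
#'
#' Vertices carry an `element` attribute; edges carry `bond_type`
#' (`covalent`/`hbond`/`electrostatic`/`organometallic`). H-bond arcs are
#' written with `directed="true"` and a `hydrogen_id` attribute; other edge
#' types are undirected.
#'
#' @param g A `mol_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path, call. = FALSE)
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="element" for="node" attr.name="element" attr.type="string"/>',
    '  <key id="bond_type" for="edge" attr.name="bond_type" attr.type="string"/>',
    '  <key id="hydrogen_id" for="edge" attr.name="hydrogen_id" attr.type="string"/>',
    '  <graph id="G" edgedefault="undirected">'
  ), con)
  for (i in seq_len(nrow(g$vertices))) {
    writeLines(sprintf('    <node id="a%d"><data key="element">%s</data></node>',
                       g$vertices$atom[i], g$vertices$element[i]), con)
  }
  for (i in seq_len(nrow(g$edges))) {
    e <- g$edges[i, ]
    if (e$type == "hbond") {
      writeLines(sprintf(
        '    <edge source="a%d" target="a%d" directed="true"><data key="bond_type">hbond</data><data key="hydrogen_id">%s</data></edge>',
        e$from, e$to, ifelse(is.na(e$hydrogen), "", as.character(e$hydrogen))), con)
    } else {
      writeLines(sprintf(
        '    <edge source="a%d" target="a%d" directed="false"><data key="bond_type">%s</data></edge>',
        e$from, e$to, e$type), con)
    }
  }
  writeLines(c("  </graph>", "</graphml>"), con)
  invisible(path)
}

#' Convert a molecular graph to an igraph object
#'
#' The mixed graph is encoded as a directed igraph: undirected edge types
#' become mutual arc pairs, H-bond arcs a single arc. Vertex attribute
#' `element` and edge attribute `bond_type` are set.
#'
#' @param g A `mol_graph`.
#' @return An igraph graph.
#' @export
as_igraph <- function(g) {
  n <- nrow(g$vertices)
  idx <- stats::setNames(seq_len(n), g$vertices$atom)
  el <- g$edges
  from <- idx[as.character(el$from)]; to <- idx[as.character(el$to)]
  undirected <- el$type != "hbond"
  ig <- igraph::make_empty_graph(n = n, directed = TRUE)
  ig <- igraph::set_vertex_attr(ig, "element", value = g$vertices$element)
  ig <- igraph::set_vertex_attr(ig, "atom", value = g$vertices$atom)
  all_from <- c(from, to[undirected])
  all_to <- c(to, from[undirected])
  all_type <- c(el$type, el$type[undirected])
  if (length(all_from)) {
    ig <- igraph::add_edges(ig, rbind(all_from, all_to))
    ig <- igraph::set_edge_attr(ig, "bond_type", value = all_type)
  }
  ig
}
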