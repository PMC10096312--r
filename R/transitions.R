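#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Analyze a trajectory into conformers and a graph of transitions
#'
#' Runs the frame-by-frame loop: build the molecular graph of each snapshot
#' (with the orbit-based candidate scan, refreshed at reference snapshots),
#' assign it to a conformer by exact coloured-graph isomorphism (checking the
#' previous frame's conformer first), and accumulate the directed graph of
#' transitions between conformers.
#'
#' Orbits are recomputed when any atom's displacement since the reference
#' frame exceeds `(orbit_radius - largest cutoff) / 2`, or every
#' `refresh_every` frames, whichever comes first; this guarantees that the
#' orbit-restricted scan equals an all-pairs scan.
#'
#' @param traj A trajectory tibble from [read_trajectory()] or [as_trajectory()].
#' @param params Parameter list from [load_params()].
#' @param orbit_margin Extra radius (Angstrom) added to the largest interaction
#'   cutoff to form the orbit radius.
#' @param refresh_every Hard cap on frames between orbit refreshes.
#' @return An object of class `mt_analysis`: a list with `registry`
#'   (a [conformer_registry()]), `transitions` (a `transition_graph`), and
#'   `assignment` (tibble `frame`, `conformer`).
#' @export
#' @examples
#' tr <- make_scripted_trajectory(schedule = c(0, 0, 1, 1, 0))
#' res <- analyze_trajectory(tr$trajectory)
#' tidy(res$registry)
analyze_trajectory <- function(traj, params = load_params(),
                               orbit_margin = 2.0, refresh_every = 100L) {
  frames <- sort(unique(traj$frame))
  if (!length(frames)) stop("empty trajectory", call. = FALSE)
  cutoff <- max_interaction_cutoff(params)
  orbit_radius <- cutoff + orbit_margin
  drift_limit <- (orbit_radius - cutoff) / 2
  registry <- conformer_registry()
  ids <- integer(length(frames))
  graphs <- vector("list", length(frames))
  orbits <- NULL
  frames_since_refresh <- 0L
  prev_id <- NULL
  for (k in seq_along(frames)) {
    snap <- traj_snapshot(traj, frames[k])
    pos <- snapshot_coords(snap)
    refresh <- is.null(orbits) || frames_since_refresh >= refresh_every ||
      max(sqrt(rowSums((pos - orbits$reference_positions)^2))) > drift_limit
    if (refresh) {
      orbits <- compute_orbits(snap, orbit_radius, reference_frame = frames[k])
      frames_since_refresh <- 0L
    } else {
      frames_since_refresh <- frames_since_refresh + 1L
    }
    g <- build_molgraph(snap, params, orbits = orbits)
    res <- assign_conformer(registry, g, frames[k], previous_id = prev_id)
    registry <- res$registry
    ids[k] <- res$id
    graphs[[k]] <- g
    prev_id <- res$id
  }
  tg <- build_transition_graph(ids, registry)
  structure(list(
    registry = registry,
    transitions = tg,
    assignment = tibble::tibble(frame = frames, conformer = ids)
  ), class = "mt_analysis")
}

#' @export
print.mt_analysis <- function(x, ...) {
  cat("<mt_analysis> ", nrow(x$assignment), " frames, ",
      length(x$registry$keys), " conformer(s), ",
      nrow(x$transitions$edges), " transition edge(s)\n", sep = "")
  invisible(x)
}

#' Typed-edge differences between two molecular graphs
#'
#' Compares the edge sets of two graphs over the same atom universe by atom id
#' and edge type; H-bond arcs are compared as ordered pairs, so an arc
#' reversal appears as one broken and one formed arc.
#'
#' @param gi,gj `mol_graph` objects from the same trajectory.
#' @return A `bond_diff` list with tibbles `formed` (edges of `gj` absent from
#'   `gi`) and `broken` (edges of `gi` absent from `gj`).
#' @export
diff_bonds <- function(gi, gj) {
  if (gi$n_atoms != gj$n_atoms ||
      !identical(gi$vertices$atom, gj$vertices$atom)) {
    stop("graphs are not over the same atom universe", call. = FALSE)
  }
  key <- function(g) paste(g$edges$type, g$edges$from, g$edges$to)
  ki <- key(gi); kj <- key(gj)
  formed <- gj$edges[!kj %in% ki, c("from", "to", "type")]
  broken <- gi$edges[!ki %in% kj, c("from", "to", "type")]
  structure(list(formed = tibble::as_tibble(formed),
                 broken = tibble::as_tibble(broken)),
            class = "bond_diff")
}

#' Build the directed graph of transitions
#'
#' Vertices are conformers labelled with their appearance percentage over all
#' frames; an edge (i, j) with i != j is counted once per adjacent frame pair
#' whose conformer changes from i to j, and carries the typed-bond difference
#' between the two representative graphs. Consecutive identical conformers are
#' not edges (residence lives in the vertex percentages).
#'
#' @param ids Integer vector of per-frame conformer ids (frame order).
#' @param registry The [conformer_registry()] the ids refer to.
#' @return A `transition_graph`: list with tibbles `vertices` (`conformer`,
#'   `count`, `percentage`) and `edges` (`from`, `to`, `count`, plus list
#'   columns `formed`, `broken`).
#' @export
build_transition_graph <- function(ids, registry) {
  s <- length(ids)
  counts <- tabulate(ids, nbins = length(registry$keys))
  vertices <- tibble::tibble(
    conformer = seq_along(registry$keys),
    count = counts,
    percentage = counts / s * 100
  )
  edges <- tibble::tibble(from = integer(), to = integer(), count = integer(),
                          formed = list(), broken = list())
  if (s > 1) {
    a <- ids[-s]; b <- ids[-1]
    chg <- which(a != b)
    if (length(chg)) {
      pair_tab <- dplyr::count(tibble::tibble(from = a[chg], to = b[chg]),
                               .data$from, .data$to, name = "count")
      diffs <- lapply(seq_len(nrow(pair_tab)), function(r) {
        diff_bonds(registry$graphs[[pair_tab$from[r]]], registry$graphs[[pair_tab$to[r]]])
      })
      edges <- dplyr::mutate(pair_tab,
        formed = lapply(diffs, `[[`, "formed"),
        broken = lapply(diffs, `[[`, "broken"))
    }
  }
  structure(list(vertices = vertices, edges = tibble::as_tibble(edges),
                 n_frames = s), class = "transition_graph")
}

#' @export
print.transition_graph <- function(x, ...) {
  cat("<transition_graph> ", nrow(x$vertices), " conformer(s), ",
      nrow(x$edges), " directed edge(s) over ", x$n_frames, " frames\n", sep = "")
  invisible(x)
}

#' @rdname tidy.conformer_registry
#' @export
tidy.transition_graph <- function(x, ...) {
  dplyr::mutate(x$edges,
    formed = vapply(x$edges$formed, bond_list_label, ""),
    broken = vapply(x$edges$broken, bond_list_label, ""))
}

bond_list_label <- function(df, labels = NULL) {
  if (!nrow(df)) return("")
  lab <- function(a) if (is.null(labels)) as.character(a) else labels[as.character(a)]
  paste(sprintf("%s %s-%s", substr(df$type, 1, 3), lab(df$from), lab(df$to)),
        collapse = ", ")
}

#' Export a transition graph as DOT and GraphML
#'
#' Conformers with appearance percentage at least `p_min` are coloured red,
#' the rest green. Edge labels carry the transition count and the
#' formed/broken bond lists (atoms named by element + first-appearance
#' ordinal when `snapshot` is supplied).
#'
#' @param tg A `transition_graph`.
#' @param path Output path without extension; `<path>.dot` and
#'   `<path>.graphml` are written.
#' @param p_min Percentage threshold for the red/green vertex colouring.
#' @param snapshot Optional snapshot tibble used to produce N1/O2-style atom
#'   labels in edge annotations.
#' @return Character vector of the two written paths, invisibly.
#' @export
export_transition_graph <- function(tg, path, p_min = 4, snapshot = NULL) {
  stopifnot(p_min >= 0, p_min <= 100)
  labels <- if (!is.null(snapshot)) atom_labels(snapshot)
  col <- ifelse(tg$vertices$percentage >= p_min, "red", "green")
  edge_label <- vapply(seq_len(nrow(tg$edges)), function(r) {
    fb <- c(
      if (nrow(tg$edges$formed[[r]])) paste0("+[", bond_list_label(tg$edges$formed[[r]], labels), "]"),
      if (nrow(tg$edges$broken[[r]])) paste0("-[", bond_list_label(tg$edges$broken[[r]], labels), "]")
    )
    paste(c(sprintf("%d", tg$edges$count[r]), fb), collapse = "; ")
  }, "")

  dot_path <- paste0(path, ".dot")
  con <- try(file(dot_path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", dot_path, call. = FALSE)
  writeLines("digraph transitions {", con)
  for (i in seq_len(nrow(tg$vertices))) {
    writeLines(sprintf(
      '  c%d [label="%d\\n%.2f%%", style=filled, fillcolor=%s];',
      tg$vertices$conformer[i], tg$vertices$conformer[i],
      tg$vertices$percentage[i], col[i]), con)
  }
  for (r in seq_len(nrow(tg$edges))) {
    writeLines(sprintf('  c%d -> c%d [label="%s"];',
                       tg$edges$from[r], tg$edges$to[r], edge_label[r]), con)
  }
  writeLines("}", con)
  close(con)

  gml_path <- paste0(path, ".graphml")
  con <- file(gml_path, "w")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="percentage" for="node" attr.name="percentage" attr.type="double"/>',
    '  <key id="color" for="node" attr.name="color" attr.type="string"/>',
    '  <key id="count" for="edge" attr.name="count" attr.type="int"/>',
    '  <key id="label" for="edge" attr.name="label" attr.type="string"/>',
    '  <graph id="transitions" edgedefault="directed">'
  ), con)
  for (i in seq_len(nrow(tg$vertices))) {
    writeLines(sprintf(
      '    <node id="c%d"><data key="percentage">%.10g</data><data key="color">%s</data></node>',
      tg$vertices$conformer[i], tg$vertices$percentage[i], col[i]), con)
  }
  for (r in seq_len(nrow(tg$edges))) {
    writeLines(sprintf(
      '    <edge source="c%d" target="c%d"><data key="count">%d</data><data key="label">%s</data></edge>',
      tg$edges$from[r], tg$edges$to[r], tg$edges$count[r],
      xml_escape(edge_label[r])), con)
  }
  writeLines(c("  </graph>", "</graphml>"), con)
  close(con)
  invisible(c(dot_path, gml_path))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Plot a transition graph
#'
#' Conformer occupancy as a bar chart, coloured by the `p_min` threshold used
#' for transition-graph exports.
#'
#' @param object A `transition_graph`.
#' @param p_min Percentage threshold separating major (red) from minor (green)
#'   conformers.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transition_graph <- function(object, p_min = 4, ...) {
  df <- dplyr::mutate(object$vertices,
                      class = ifelse(.data$percentage >= p_min, "major", "minor"))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$conformer), .data$percentage,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(major = "#c0392b", minor = "#27ae60")) +
    ggplot2::labs(x = "conformer", y = "appearance (%)", fill = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
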