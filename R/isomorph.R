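# Exact isomorphism for coloured mixed molecular graphs.
#
# Engine: colour refinement (vertex colour = element, refined by the multiset
# of incident edge types with H-bond direction distinguished) followed by
# individualisation-refinement backtracking that enumerates discrete orderings
# and keeps the lexicographically smallest certificate. Edge types and arc
# direction are encoded as bit codes on ordered vertex pairs, so the
# certificate determines the graph up to relabelling: equal keys <=> isomorphic.

# bit codes on ordered pair (i, j)
.BIT_COV <- 1L; .BIT_HB_OUT <- 2L; .BIT_HB_IN <- 4L; .BIT_EI <- 8L; .BIT_EO <- 16L

# n x n integer code matrix for a mol_graph
edge_code_matrix <- function(g) {
  n <- nrow(g$vertices)
  idx <- stats::setNames(seq_len(n), g$vertices$atom)
  m <- matrix(0L, n, n)
  e <- g$edges
  for (k in seq_len(nrow(e))) {
    i <- idx[as.character(e$from[k])]; j <- idx[as.character(e$to[k])]
    bit <- switch(e$type[k],
      covalent = .BIT_COV, electrostatic = .BIT_EI, organometallic = .BIT_EO,
      hbond = NA_integer_)
    if (e$type[k] == "hbond") {
      m[i, j] <- bitwOr(m[i, j], .BIT_HB_OUT)
      m[j, i] <- bitwOr(m[j, i], .BIT_HB_IN)
    } else {
      m[i, j] <- bitwOr(m[i, j], bit)
      m[j, i] <- bitwOr(m[j, i], bit)
    }
  }
  m
}

# One colour-refinement pass to a stable partition. Colours are integer ranks
# of signature strings; signatures are built from invariant data only, so the
# refined partition (and its cell order) is identical across isomorphic graphs.
refine_colors <- function(code, colors) {
  n <- length(colors)
  repeat {
    sig <- vapply(seq_len(n), function(i) {
      nb <- which(code[i, ] != 0L | code[, i] != 0L)
      parts <- sort(sprintf("%02d:%09d", code[i, nb], colors[nb]))
      paste0(sprintf("%09d", colors[i]), "|", paste(parts, collapse = ","))
    }, "")
    new <- match(sig, sort(unique(sig)))
    if (identical(new, colors) || length(unique(new)) == length(unique(colors))) {
      if (!identical(new, colors)) colors <- new
      if (length(unique(colors)) == n) return(colors)
      # re-check stability with the renumbered colours
      sig2 <- vapply(seq_len(n), function(i) {
        nb <- which(code[i, ] != 0L | code[, i] != 0L)
        parts <- sort(sprintf("%02d:%09d", code[i, nb], colors[nb]))
        paste0(sprintf("%09d", colors[i]), "|", paste(parts, collapse = ","))
      }, "")
      new2 <- match(sig2, sort(unique(sig2)))
      if (identical(new2, colors)) return(colors)
      colors <- new2
    } else {
      colors <- new
    }
  }
}

certificate_string <- function(code, elements, ord) {
  n <- length(ord)
  codes <- if (n > 1) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    co <- code[ord, ord, drop = FALSE]
    paste(co[pairs], co[pairs[, c(2, 1), drop = FALSE]], sep = ":", collapse = ",")
  } else ""
  paste0(paste(elements[ord], collapse = ","), "#", codes)
}

canon_search <- function(code, elements, colors, best_env) {
  colors <- refine_colors(code, colors)
  n <- length(colors)
  if (length(unique(colors)) == n) {
    cert <- certificate_string(code, elements, order(colors))
    if (is.null(best_env$best) || cert < best_env$best) best_env$best <- cert
    return(invisible(NULL))
  }
  tab <- table(colors)
  target <- as.integer(names(tab)[tab > 1][1])
  cell <- which(colors == target)
  for (v in cell) {
    colors2 <- colors * 2L
    colors2[v] <- colors2[v] - 1L
    canon_search(code, elements, colors2, best_env)
  }
  invisible(NULL)
}

#' Canonical key of a molecular graph
#'
#' A string invariant under vertex relabelling that is equal for two graphs if
#' and only if they are isomorphic as coloured mixed graphs (vertex colours,
#' covalent/electrostatic/organometallic edges and directed H-bond arcs all
#' preserved). Obtained by canonical labelling, not hashing.
#'
#' @param g A `mol_graph`.
#' @return A character scalar.
#' @export
canonical_key <- function(g) {
  n <- nrow(g$vertices)
  if (n == 0) return("empty")
  code <- edge_code_matrix(g)
  elements <- g$vertices$element
  colors <- match(elements, sort(unique(elements)))
  best_env <- new.env(parent = emptyenv())
  canon_search(code, elements, colors, best_env)
  best_env$best
}

#' Test coloured mixed-graph isomorphism
#'
#' True when a bijection between the vertex sets exists that preserves element
#' colours and maps each typed edge set onto the corresponding set, with
#' H-bond arc direction preserved. The mediating hydrogen's identity is not
#' part of the test (hydrogens enter only through arc direction).
#'
#' @param g1,g2 `mol_graph` objects.
#' @return Logical scalar.
#' @export
are_isomorphic <- function(g1, g2) {
  if (nrow(g1$vertices) != nrow(g2$vertices)) return(FALSE)
  if (!identical(sort(g1$vertices$element), sort(g2$vertices$element))) return(FALSE)
  t1 <- table(factor(g1$edges$type, levels = c("covalent", "hbond", "electrostatic", "organometallic")))
  t2 <- table(factor(g2$edges$type, levels = c("covalent", "hbond", "electrostatic", "organometallic")))
  if (!identical(as.integer(t1), as.integer(t2))) return(FALSE)
  identical(canonical_key(g1), canonical_key(g2))
}

#' Create an empty conformer registry
#'
#' The registry holds the distinct (pairwise non-isomorphic) molecular graphs
#' seen so far, each with its canonical key and the list of frames where it
#' appeared.
#'
#' @return A `conformer_registry` object.
#' @export
conformer_registry <- function() {
  structure(list(graphs = list(), keys = character(),
                 appearance = list(), assigned_frames = integer(),
                 shortcut_hits = 0L),
            class = "conformer_registry")
}

#' Assign a snapshot's graph to a conformer
#'
#' Checks the previous frame's conformer first (a cheap shortcut, since
#' consecutive snapshots usually share a conformer), then looks the canonical
#' key up in the registry, and otherwise registers a new conformer. The frame
#' is appended to the winning conformer's appearance list.
#'
#' @param registry A `conformer_registry`.
#' @param g The snapshot's `mol_graph`.
#' @param frame Frame index (must not already be assigned).
#' @param previous_id Conformer id of the previous frame, or `NULL`.
#' @return A list with `registry` (updated) and `id` (the assigned conformer).
#' @export
assign_conformer <- function(registry, g, frame, previous_id = NULL) {
  if (frame %in% registry$assigned_frames) {
    stop("frame ", frame, " already assigned", call. = FALSE)
  }
  key <- canonical_key(g)
  id <- NA_integer_
  if (!is.null(previous_id) && !is.na(previous_id) &&
      previous_id <= length(registry$keys) &&
      identical(registry$keys[previous_id], key)) {
    id <- previous_id
    registry$shortcut_hits <- registry$shortcut_hits + 1L
  } else {
    id <- match(key, registry$keys)
  }
  if (is.na(id)) {
    id <- length(registry$keys) + 1L
    registry$graphs[[id]] <- g
    registry$keys[id] <- key
    registry$appearance[[id]] <- integer(0)
  }
  registry$appearance[[id]] <- c(registry$appearance[[id]], as.integer(frame))
  registry$assigned_frames <- c(registry$assigned_frames, as.integer(frame))
  list(registry = registry, id = id)
}

#' @export
print.conformer_registry <- function(x, ...) {
  cat("<conformer_registry> ", length(x$keys), " conformer(s), ",
      length(x$assigned_frames), " frame(s) assigned\n", sep = "")
  invisible(x)
}

#' Tidy a conformer registry
#'
#' @param x A `conformer_registry`.
#' @param ... Unused.
#' @return Tibble with one row per conformer: `id`, `count`, `percentage`
#'   (over all assigned frames), `first_frame`.
#' @export
tidy.conformer_registry <- function(x, ...) {
  n <- length(x$assigned_frames)
  tibble::tibble(
    id = seq_along(x$keys),
    count = vapply(x$appearance, length, 0L),
    percentage = if (n) vapply(x$appearance, length, 0L) / n * 100 else numeric(length(x$keys)),
    first_frame = vapply(x$appearance, function(a) if (length(a)) min(a) else NA_integer_, 0L)
  )
}

#' Export a conformer registry
#'
#' Writes a CSV summary (id, count, percentage, first frame, bond inventory)
#' and one GraphML file per representative graph.
#'
#' @param registry A `conformer_registry`.
#' @param dir Output directory (created if missing).
#' @return The CSV path, invisibly.
#' @export
export_registry <- function(registry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  td <- tidy(registry)
  td$bonds <- vapply(registry$graphs, function(g) {
    paste(sprintf("%s:%d", names(table(g$edges$type)), table(g$edges$type)), collapse = " ")
  }, "")
  csv <- file.path(dir, "conformers.csv")
  utils::write.csv(td, csv, row.names = FALSE)
  for (i in seq_along(registry$graphs)) {
    write_graphml(registry$graphs[[i]], file.path(dir, sprintf("conformer_%03d.graphml", i)))
  }
  invisible(csv)
}
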