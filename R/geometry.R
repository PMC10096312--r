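# Geometry kernels for the graph-to-3D game: the 42-direction icosphere
# strategy grid, VSEPR ideal-direction templates, minimal rotations, and
# superposition RMSD.

#' Icosphere direction grid
#'
#' The 42 unit directions of one icosphere refinement: the 12 icosahedron
#' vertices plus the 30 edge midpoints, re-normalised. Rows are ordered
#' lexicographically (rounded), so direction 1 is a fixed, reproducible slot
#' (used as the grid's virtual-parent direction).
#'
#' @return A 42 x 3 matrix of unit row vectors.
#' @export
icosphere_directions <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  d <- as.matrix(stats::dist(v))
  edge_len <- min(d[d > 1e-9])
  mids <- NULL
  for (i in 1:11) for (j in (i + 1):12) {
    if (abs(d[i, j] - edge_len) < 1e-9) mids <- rbind(mids, (v[i, ] + v[j, ]) / 2)
  }
  mids <- mids / sqrt(rowSums(mids^2))
  g <- rbind(v, mids)
  key <- apply(round(g, 9), 1, paste, collapse = ",")
  g <- g[order(key), , drop = FALSE]
  dimnames(g) <- NULL
  g
}

#' Strategy grid for one player
#'
#' A player places a child atom on a sphere around its parent: 42 icosphere
#' directions at a radius equal to the ideal bond length of the edge type
#' (sum of covalent radii for covalent edges, a configurable heavy-heavy
#' distance for H-bond edges).
#'
#' @param edge_type `"covalent"` or `"hbond"`.
#' @param elements Character pair of element symbols (parent, child); required
#'   for covalent radii.
#' @param params Parameter list from [load_params()].
#' @param hbond_length Ideal heavy-heavy H-bond distance (Angstrom).
#' @return A list with `directions` (42 x 3 unit rows) and `radius` (Angstrom).
#' @export
strategy_grid <- function(edge_type = c("covalent", "hbond"), elements = NULL,
                          params = load_params(), hbond_length = 2.9) {
  edge_type <- match.arg(edge_type)
  radius <- if (edge_type == "covalent") {
    if (is.null(elements) || length(elements) != 2) {
      stop("covalent strategy grids need the two element symbols", call. = FALSE)
    }
    sum(params$elements$covalent_radius[match(elements, params$elements$symbol)])
  } else hbond_length
  list(directions = icosphere_directions(), radius = radius)
}

#' VSEPR ideal-direction templates
#'
#' Unit-direction sets for the ideal local geometry of an atom with a given
#' number of bonded neighbours and lone pairs: single direction, linear
#' (180 degrees), bent (104.5 degrees with two lone pairs, 107 with one),
#' trigonal planar (120), trigonal pyramidal (107, one lone pair) and
#' tetrahedral (109.47). These templates replace any energy function: the
#' direct utility measures deviation from them.
#'
#' @return A nested list: `templates[[degree]][[lone_pairs + 1]]` is a matrix
#'   of unit row vectors (one per bonded neighbour), or `NULL` where the
#'   combination is not tabulated.
#' @export
vsepr_templates <- function() {
  deg2rad <- pi / 180
  bent <- function(theta) {
    h <- theta * deg2rad / 2
    rbind(c(sin(h), 0, cos(h)), c(-sin(h), 0, cos(h)))
  }
  tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  pyramidal <- function(theta) {
    # three directions with pairwise angle theta, symmetric about +z
    ct <- cos(theta * deg2rad)
    # rows at polar angle a from z with azimuths 0, 120, 240:
    # pairwise cos = cos^2 a + sin^2 a * cos(120)
    a <- acos(sqrt((2 * ct + 1) / 3))
    t(vapply(c(0, 120, 240) * deg2rad, function(az) {
      c(sin(a) * cos(az), sin(a) * sin(az), cos(a))
    }, numeric(3)))
  }
  trigonal <- t(vapply(c(90, 210, 330) * deg2rad, function(az) {
    c(cos(az), sin(az), 0)
  }, numeric(3)))
  list(
    `1` = list(`0` = rbind(c(0, 0, 1))),
    `2` = list(`0` = rbind(c(0, 0, 1), c(0, 0, -1)),
               `1` = bent(107), `2` = bent(104.5)),
    `3` = list(`0` = trigonal, `1` = pyramidal(107)),
    `4` = list(`0` = tetra)
  )
}

# lone pairs per element feeding the template lookup
.LONE_PAIRS <- c(O = 2L, N = 1L, S = 2L, F = 3L, Cl = 3L)

lone_pairs_of <- function(element) {
  lp <- .LONE_PAIRS[element]
  ifelse(is.na(lp), 0L, lp)
}

vsepr_template_for <- function(degree, lone_pairs, templates = vsepr_templates()) {
  fam <- templates[[as.character(degree)]]
  if (is.null(fam)) {
    stop("no VSEPR template for ", degree, " bonded neighbours", call. = FALSE)
  }
  # fall back to the highest tabulated lone-pair variant at this degree
  keys <- as.integer(names(fam))
  k <- max(keys[keys <= lone_pairs], 0L)
  fam[[as.character(k)]]
}

#' Minimal rotation taking one unit vector onto another
#'
#' The axis-angle rotation about the axis perpendicular to both vectors, with
#' the smallest rotation angle; the identity when the vectors coincide, and a
#' 180-degree rotation about a deterministic perpendicular axis when they are
#' antiparallel.
#'
#' @param a,b Unit 3-vectors.
#' @return A 3 x 3 rotation matrix `R` with `R %*% a == b`.
#' @export
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  ct <- sum(a * b)
  if (ct > 1 - 1e-12) return(diag(3))
  if (ct < -1 + 1e-12) {
    # any perpendicular axis; pick deterministically
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- p - sum(p * a) * a
    axis <- axis / sqrt(sum(axis^2))
    return(axis_angle_rotation(axis, pi))
  }
  axis <- c(a[2] * b[3] - a[3] * b[2],
            a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(axis^2))
  axis_angle_rotation(axis / s, atan2(s, ct))
}

axis_angle_rotation <- function(axis, theta) {
  k <- axis / sqrt(sum(axis^2))
  kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * kx + (1 - cos(theta)) * (kx %*% kx)
}

# rotation-only Kabsch: R minimising sum ||n_i - R t_i||^2 for row matrices
kabsch_rotation <- function(template, target) {
  h <- t(template) %*% target
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

# minimum over rigid rotations of sum of plain Euclidean distances between
# rotated template rows and target rows (both unit). Kabsch start plus
# Nelder-Mead polish over an axis-angle offset; |.| sums have their optimum
# away from the |.|^2 optimum whenever errors are uneven.
min_sum_distance_rotation <- function(template, target, refine = TRUE) {
  r0 <- kabsch_rotation(template, target)
  f <- function(w) {
    th <- sqrt(sum(w^2))
    r <- if (th < 1e-12) r0 else axis_angle_rotation(w / th, th) %*% r0
    sum(sqrt(rowSums((target - template %*% t(r))^2)))
  }
  best <- f(c(0, 0, 0))
  if (refine && nrow(template) > 1) {
    opt <- stats::optim(c(0, 0, 0), f, method = "Nelder-Mead",
                        control = list(maxit = 200, reltol = 1e-10))
    if (opt$value < best) best <- opt$value
  }
  best
}

#' Deviation of placed neighbours from the VSEPR ideal
#'
#' Measures how far a set of unit directions (an atom's neighbours projected
#' onto its unit sphere) is from the atom's ideal VSEPR arrangement: the
#' minimum over neighbour-to-slot assignments and rigid template rotations of
#' the summed Euclidean distances between neighbour directions and ideal
#' slots. Zero or one neighbour is always ideal (0).
#'
#' @param neighbor_dirs Matrix of unit row vectors (one per neighbour).
#' @param element Element symbol of the central atom (sets the lone-pair count).
#' @param templates Template table from [vsepr_templates()].
#' @param refine Polish the rotation beyond the least-squares alignment
#'   (exact minimisation of the distance sum); disable for speed inside hot
#'   loops where only the cost ranking matters.
#' @return Non-negative deviation (dimensionless, unit-sphere units).
#' @export
vsepr_deviation <- function(neighbor_dirs, element, templates = vsepr_templates(),
                            refine = TRUE) {
  d <- nrow(neighbor_dirs)
  if (d <= 1) return(0)
  tmpl <- vsepr_template_for(d, lone_pairs_of(element), templates)
  if (nrow(tmpl) != d) stop("template size mismatch", call. = FALSE)
  perms <- permutations_of(d)
  best <- Inf
  for (p in seq_len(nrow(perms))) {
    val <- min_sum_distance_rotation(tmpl[perms[p, ], , drop = FALSE],
                                     neighbor_dirs, refine = refine)
    if (val < best) best <- val
  }
  best
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

#' Root-mean-square deviation between two structures
#'
#' Atoms are paired by id; with `superpose = TRUE` the minimum RMSD over rigid
#' rotations and translations (least-squares superposition) is returned,
#' otherwise the raw coordinate RMSD.
#'
#' @param a,b Snapshot tibbles (`atom`, `element`, `x`, `y`, `z`) with the
#'   same atom count and element sequence.
#' @param superpose Superpose before measuring (default `TRUE`).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, superpose = TRUE) {
  if (nrow(a) != nrow(b)) stop("structures differ in atom count", call. = FALSE)
  a <- a[order(a$atom), ]; b <- b[order(b$atom), ]
  if (!identical(a$element, b$element)) {
    stop("structures differ in element sequence", call. = FALSE)
  }
  pa <- cbind(a$x, a$y, a$z); pb <- cbind(b$x, b$y, b$z)
  if (superpose && nrow(pa) > 1) {
    # pracma::kabsch maps column-vector set A onto B: U %*% A + r
    k <- pracma::kabsch(t(pa), t(pb))
    pa <- t(k$U %*% t(pa) + matrix(k$R, 3, nrow(pa)))
  }
  sqrt(mean(rowSums((pa - pb)^2)))
}
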