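# Synthetic inputs: idealized toy molecules, scripted conformational
# trajectories with known conformer schedules, and hexagonal water sheets.
# Everything is generated in code; peptide-like fixtures are topology-faithful
# (composition and bond graph) but make no claim to quantum-quality geometry.

# --- internal-coordinate construction (NeRF) --------------------------------

# Place atom D given positions A, B, C, the bond length r (C-D), the bond
# angle theta (B-C-D, degrees) and the dihedral phi (A-B-C-D, degrees).
nerf_place <- function(a, b, c, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a; ab <- ab / sqrt(sum(ab^2))
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  c + cbind(bc, m, n) %*% d2
}

# Incremental molecule builder used by the peptide fixtures: an environment
# holding positions, elements and declared covalent bonds.
new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$pos <- matrix(numeric(0), 0, 3)
  env$el <- character(0)
  env$bonds <- matrix(integer(0), 0, 2)
  env
}

builder_add <- function(bld, el, i = NULL, j = NULL, k = NULL,
                        r = NULL, theta = NULL, phi = NULL, bond_to = i) {
  n <- nrow(bld$pos)
  p <- if (n == 0) {
    c(0, 0, 0)
  } else if (is.null(j)) {
    bld$pos[i, ] + c(r, 0, 0)
  } else if (is.null(k)) {
    # bond to i at angle new-i-j, placed in the xy-plane (or a deterministic
    # perpendicular when i-j lies on z)
    th <- theta * pi / 180
    v <- bld$pos[j, ] - bld$pos[i, ]
    v <- v / sqrt(sum(v^2))
    perp <- c(-v[2], v[1], 0)
    if (sum(perp^2) < 1e-12) perp <- c(0, 0, 1)
    perp <- perp / sqrt(sum(perp^2))
    bld$pos[i, ] + r * (cos(th) * v + sin(th) * perp)
  } else {
    # bond to i; angle new-i-j; dihedral new-i-j-k
    as.numeric(nerf_place(bld$pos[k, ], bld$pos[j, ], bld$pos[i, ], r, theta, phi))
  }
  bld$pos <- rbind(bld$pos, as.numeric(p))
  bld$el <- c(bld$el, el)
  id <- nrow(bld$pos)
  if (!is.null(bond_to)) bld$bonds <- rbind(bld$bonds, c(bond_to, id))
  id
}

builder_snapshot <- function(bld) {
  tibble::tibble(atom = seq_along(bld$el), element = bld$el,
                 x = bld$pos[, 1], y = bld$pos[, 2], z = bld$pos[, 3])
}

# one alanine residue appended to a builder; returns the ids of interest
add_ala <- function(bld, prev_c, prev_o, prev_ca) {
  n <- builder_add(bld, "N", i = prev_c, j = prev_ca, k = prev_o, r = 1.33, theta = 115, phi = 180)
  hn <- builder_add(bld, "H", i = n, j = prev_c, k = prev_ca, r = 1.02, theta = 119, phi = 0)
  ca <- builder_add(bld, "C", i = n, j = prev_c, k = prev_ca, r = 1.47, theta = 122, phi = 180)
  ha <- builder_add(bld, "H", i = ca, j = n, k = prev_c, r = 1.09, theta = 109.5, phi = -60)
  cb <- builder_add(bld, "C", i = ca, j = n, k = prev_c, r = 1.53, theta = 109.5, phi = 60)
  for (ph in c(60, 180, -60)) {
    builder_add(bld, "H", i = cb, j = ca, k = n, r = 1.09, theta = 109.5, phi = ph)
  }
  cc <- builder_add(bld, "C", i = ca, j = n, k = prev_c, r = 1.53, theta = 109.5, phi = 180)
  o <- builder_add(bld, "O", i = cc, j = ca, k = n, r = 1.23, theta = 121, phi = 90)
  list(n = n, ca = ca, c = cc, o = o)
}

#' Build an idealised toy molecule and its hydrogen-inclusive graph
#'
#' Returns a structure with canonical geometry together with the matching
#' [full_mol_graph()]. `triala_like` is a 34-atom tri-alanine with protonated
#' N terminus and COOH C terminus (composition C9H18N3O4) whose graph carries
#' one terminus-to-terminus H-bond; `zala6_like` is an 80-atom
#' benzyloxycarbonyl-capped hexa-alanine amide (composition C26H39N7O8). Both
#' peptides are built in an extended conformation: their H-bonds are part of
#' the target topology, not of the reference geometry.
#'
#' @param name One of `"water"`, `"methane"`, `"ammonia"`, `"water_dimer"`,
#'   `"triala_like"`, `"zala6_like"`.
#' @return A list with `structure` (snapshot tibble) and `graph`
#'   (`full_mol_graph`).
#' @export
#' @examples
#' make_molecule("water")$structure
make_molecule <- function(name) {
  switch(name,
    water = {
      h <- 104.5 / 2 * pi / 180
      s <- tibble::tibble(
        atom = 1:3, element = c("O", "H", "H"),
        x = c(0, 0.9572 * sin(h), -0.9572 * sin(h)),
        y = 0, z = c(0, 0.9572 * cos(h), 0.9572 * cos(h)))
      list(structure = s, graph = full_mol_graph(
        s[, c("atom", "element")],
        tibble::tibble(from = c(1, 1), to = c(2, 3), type = "covalent")))
    },
    methane = {
      tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
      s <- tibble::tibble(
        atom = 1:5, element = c("C", rep("H", 4)),
        x = c(0, 1.09 * tet[, 1]), y = c(0, 1.09 * tet[, 2]), z = c(0, 1.09 * tet[, 3]))
      list(structure = s, graph = full_mol_graph(
        s[, c("atom", "element")],
        tibble::tibble(from = 1, to = 2:5, type = "covalent")))
    },
    ammonia = {
      ct <- cos(106.7 * pi / 180)
      a <- acos(sqrt((2 * ct + 1) / 3))
      dirs <- t(vapply(c(0, 120, 240) * pi / 180, function(az) {
        c(sin(a) * cos(az), sin(a) * sin(az), cos(a))
      }, numeric(3)))
      s <- tibble::tibble(
        atom = 1:4, element = c("N", rep("H", 3)),
        x = c(0, 1.012 * dirs[, 1]), y = c(0, 1.012 * dirs[, 2]),
        z = c(0, 1.012 * dirs[, 3]))
      list(structure = s, graph = full_mol_graph(
        s[, c("atom", "element")],
        tibble::tibble(from = 1, to = 2:4, type = "covalent")))
    },
    water_dimer = {
      roh <- 0.9572
      a2 <- 104.5 * pi / 180
      h <- 52.25 * pi / 180
      s <- tibble::tibble(
        atom = 1:6, element = c("O", "H", "H", "O", "H", "H"),
        x = c(0, roh, roh * cos(a2), 2.9, 2.9 + roh * cos(h), 2.9 + roh * cos(h)),
        y = c(0, 0, roh * sin(a2), 0, 0, 0),
        z = c(0, 0, 0, 0, roh * sin(h), -roh * sin(h)))
      list(structure = s, graph = full_mol_graph(
        s[, c("atom", "element")],
        tibble::tibble(from = c(1, 1, 4, 4, 1), to = c(2, 3, 5, 6, 4),
                       type = c(rep("covalent", 4), "hbond"))))
    },
    triala_like = {
      bld <- new_builder()
      n1 <- builder_add(bld, "N")
      ca <- builder_add(bld, "C", i = n1, r = 1.47)
      hph <- c(60, 180, -60)
      h1 <- builder_add(bld, "H", i = n1, j = ca, r = 1.02, theta = 109.5)
      h2 <- builder_add(bld, "H", i = n1, j = ca, k = h1, r = 1.02, theta = 109.5, phi = 120)
      h3 <- builder_add(bld, "H", i = n1, j = ca, k = h1, r = 1.02, theta = 109.5, phi = -120)
      ha <- builder_add(bld, "H", i = ca, j = n1, k = h1, r = 1.09, theta = 109.5, phi = 60)
      cb <- builder_add(bld, "C", i = ca, j = n1, k = h1, r = 1.53, theta = 109.5, phi = 180)
      for (ph in hph) builder_add(bld, "H", i = cb, j = ca, k = n1, r = 1.09, theta = 109.5, phi = ph)
      cc <- builder_add(bld, "C", i = ca, j = n1, k = h1, r = 1.53, theta = 109.5, phi = -60)
      o <- builder_add(bld, "O", i = cc, j = ca, k = n1, r = 1.23, theta = 121, phi = 90)
      res1 <- list(ca = ca, c = cc, o = o)
      res2 <- add_ala(bld, res1$c, res1$o, res1$ca)
      res3 <- add_ala(bld, res2$c, res2$o, res2$ca)
      # COOH terminus on the last carbonyl carbon
      oh <- builder_add(bld, "O", i = res3$c, j = res3$ca, k = res3$n, r = 1.34, theta = 115, phi = -90)
      builder_add(bld, "H", i = oh, j = res3$c, k = res3$ca, r = 0.97, theta = 110, phi = 180)
      s <- builder_snapshot(bld)
      edges <- tibble::tibble(from = bld$bonds[, 1], to = bld$bonds[, 2], type = "covalent")
      # target topology: NH3+ terminus donating to the terminal carbonyl O
      edges <- dplyr::bind_rows(edges, tibble::tibble(from = n1, to = res3$o, type = "hbond"))
      list(structure = s, graph = full_mol_graph(s[, c("atom", "element")], edges))
    },
    zala6_like = {
      bld <- new_builder()
      # benzyl ring
      c1 <- builder_add(bld, "C")
      c2 <- builder_add(bld, "C", i = c1, r = 1.39)
      c3 <- builder_add(bld, "C", i = c2, j = c1, r = 1.39, theta = 120)
      c4 <- builder_add(bld, "C", i = c3, j = c2, k = c1, r = 1.39, theta = 120, phi = 0)
      c5 <- builder_add(bld, "C", i = c4, j = c3, k = c2, r = 1.39, theta = 120, phi = 0)
      c6 <- builder_add(bld, "C", i = c5, j = c4, k = c3, r = 1.39, theta = 120, phi = 0)
      bld$bonds <- rbind(bld$bonds, c(c6, c1))  # ring closure
      for (cr in c(c2, c3, c4, c5, c6)) {
        jj <- cr - 1L
        builder_add(bld, "H", i = cr, j = jj, k = if (cr > 2) cr - 2L else c6,
                    r = 1.09, theta = 120, phi = 180)
      }
      ch2 <- builder_add(bld, "C", i = c1, j = c2, k = c3, r = 1.50, theta = 120, phi = 180)
      for (ph in c(60, -60)) builder_add(bld, "H", i = ch2, j = c1, k = c2, r = 1.09, theta = 109.5, phi = ph)
      oe <- builder_add(bld, "O", i = ch2, j = c1, k = c2, r = 1.43, theta = 109.5, phi = 180)
      cz <- builder_add(bld, "C", i = oe, j = ch2, k = c1, r = 1.36, theta = 116, phi = 180)
      oz <- builder_add(bld, "O", i = cz, j = oe, k = ch2, r = 1.21, theta = 125, phi = 0)
      prev <- list(c = cz, o = oz, ca = oe)  # carbamate C plays the carbonyl role
      residues <- vector("list", 6)
      for (rix in 1:6) {
        residues[[rix]] <- add_ala(bld, prev$c, prev$o, prev$ca)
        prev <- residues[[rix]]
      }
      # C-terminal amide NH2
      nt <- builder_add(bld, "N", i = prev$c, j = prev$ca, k = prev$o, r = 1.33, theta = 115, phi = 180)
      builder_add(bld, "H", i = nt, j = prev$c, k = prev$ca, r = 1.02, theta = 119, phi = 0)
      builder_add(bld, "H", i = nt, j = prev$c, k = prev$ca, r = 1.02, theta = 119, phi = 180)
      s <- builder_snapshot(bld)
      edges <- tibble::tibble(from = bld$bonds[, 1], to = bld$bonds[, 2], type = "covalent")
      # target topology: two backbone H-bonds closing rings
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        from = c(residues[[3]]$n, residues[[5]]$n),
        to = c(oz, residues[[2]]$o), type = "hbond"))
      list(structure = s, graph = full_mol_graph(s[, c("atom", "element")], edges))
    },
    stop("unknown molecule: ", name, call. = FALSE)
  )
}

#' Scripted conformational trajectory with a known conformer schedule
#'
#' Builds a trajectory whose per-frame molecular graphs follow a binary
#' schedule exactly under the default perception thresholds: state 0 is the
#' base structure, state 1 applies a reversible geometric toggle (for the
#' water dimer, the donor hydrogen is rotated away from the acceptor, which
#' breaks the single H-bond arc). The ground-truth conformer id sequence is
#' returned alongside, numbering states by first appearance.
#'
#' @param schedule Integer vector of per-frame states (0 = base, 1 = toggled).
#' @param base Base structure name (currently `"water_dimer"`).
#' @param toggle_angle Rotation applied to the donor hydrogen (degrees).
#' @param params Parameter list used to verify the toggle changes the graph.
#' @return A list with `trajectory` (an `mt_trajectory`) and `expected_ids`
#'   (integer conformer sequence).
#' @export
#' @examples
#' make_scripted_trajectory(schedule = c(0, 0, 1, 1, 0))$expected_ids
make_scripted_trajectory <- function(schedule = c(0, 0, 1, 1, 0),
                                     base = "water_dimer",
                                     toggle_angle = -100,
                                     params = load_params()) {
  stopifnot(all(schedule %in% c(0, 1)), length(schedule) >= 1)
  base_snap <- make_molecule(base)$structure
  toggled <- toggle_donor_h(base_snap, toggle_angle)
  g0 <- build_molgraph(base_snap, params)
  g1 <- build_molgraph(toggled, params)
  if (are_isomorphic(g0, g1)) {
    stop("toggle failed to change the molecular graph under the thresholds", call. = FALSE)
  }
  snaps <- lapply(schedule, function(s) if (s == 0) base_snap else toggled)
  expected <- match(schedule, unique(schedule))
  list(trajectory = as_trajectory(snaps), expected_ids = as.integer(expected))
}

# rotate the donor hydrogen (atom 2 of the dimer) about the z axis through
# the donor oxygen
toggle_donor_h <- function(snap, angle_deg) {
  th <- angle_deg * pi / 180
  rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  o <- as.numeric(snap[snap$atom == 1, c("x", "y", "z")])
  h <- as.numeric(snap[snap$atom == 2, c("x", "y", "z")])
  hn <- o + as.numeric(rz %*% (h - o))
  snap[snap$atom == 2, c("x", "y", "z")] <- as.list(hn)
  snap
}

#' Hexagonal water-sheet snapshot
#'
#' A planar honeycomb of water oxygens (O-O edge 2.8 Angstrom) with bridging
#' hydrogens placed on the O-O lines so that default perception yields the
#' hexagonal H-bond network exactly; each oxygen carries two covalent
#' hydrogens, with non-donated hydrogens pointing out of the plane. Emulates
#' the collective two-dimensional H-bond network of interfacial water.
#'
#' @param rows,cols Numbers of hexagon cells in the two lattice directions.
#' @param oo Nearest-neighbour O-O distance (Angstrom).
#' @return A snapshot tibble.
#' @export
#' @examples
#' sheet <- make_water_sheet(1, 1)
#' nrow(sheet[sheet$element == "O", ])  # 6 oxygens: one hexagon
make_water_sheet <- function(rows = 1, cols = 1, oo = 2.8) {
  stopifnot(rows >= 1, cols >= 1)
  u <- c(sqrt(3) * oo, 0); v <- c(sqrt(3) * oo / 2, 1.5 * oo)
  verts <- NULL
  hexes <- list()
  key_of <- function(p) paste(round(p[1], 6), round(p[2], 6))
  vert_id <- new.env(parent = emptyenv())
  for (i in seq_len(cols) - 1) for (j in seq_len(rows) - 1) {
    ctr <- i * u + j * v
    ids <- integer(6)
    for (k in 0:5) {
      ang <- (30 + 60 * k) * pi / 180
      p <- ctr + oo * c(cos(ang), sin(ang))
      ky <- key_of(p)
      if (is.null(vert_id[[ky]])) {
        verts <- rbind(verts, p)
        vert_id[[ky]] <- nrow(verts)
      }
      ids[k + 1] <- vert_id[[ky]]
    }
    hexes[[length(hexes) + 1]] <- ids
  }
  edges <- unique(do.call(rbind, lapply(hexes, function(ids) {
    cbind(pmin(ids, c(ids[-1], ids[1])), pmax(ids, c(ids[-1], ids[1])))
  })))
  n_o <- nrow(verts)
  # orient each O-O contact so no oxygen donates more than its two hydrogens
  donated <- integer(n_o)
  donors <- integer(nrow(edges)); acceptors <- integer(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    pick <- if (donated[a] <= donated[b]) c(a, b) else c(b, a)
    if (donated[pick[1]] >= 2) pick <- rev(pick)
    if (donated[pick[1]] >= 2) stop("could not orient the H-bond network", call. = FALSE)
    donors[e] <- pick[1]; acceptors[e] <- pick[2]
    donated[pick[1]] <- donated[pick[1]] + 1L
  }
  roh <- 0.9572
  o_rows <- tibble::tibble(element = "O", x = verts[, 1], y = verts[, 2], z = 0)
  h_list <- list()
  for (e in seq_len(nrow(edges))) {
    d <- donors[e]; a <- acceptors[e]
    dir <- (verts[a, ] - verts[d, ]) / oo
    h_list[[length(h_list) + 1]] <- tibble::tibble(
      element = "H", x = verts[d, 1] + roh * dir[1],
      y = verts[d, 2] + roh * dir[2], z = 0)
  }
  for (o in seq_len(n_o)) {
    need <- 2L - donated[o]
    if (need >= 1) h_list[[length(h_list) + 1]] <- tibble::tibble(
      element = "H", x = verts[o, 1], y = verts[o, 2], z = roh)
    if (need == 2) h_list[[length(h_list) + 1]] <- tibble::tibble(
      element = "H", x = verts[o, 1], y = verts[o, 2], z = -roh)
  }
  out <- dplyr::bind_rows(c(list(o_rows), h_list))
  dplyr::mutate(out, atom = dplyr::row_number(), .before = 1)
}
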