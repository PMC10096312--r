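two_atoms <- function(d, el = c("He", "He")) {
  tibble::tibble(atom = 1:2, element = el, x = c(0, d), y = 0, z = 0)
}

test_that("orbits are distance balls around each atom", {
  one <- tibble::tibble(atom = 1L, element = "He", x = 0, y = 0, z = 0)
  expect_length(compute_orbits(one, 5)$neighbors[["1"]], 0)

  near <- compute_orbits(two_atoms(3), 5)
  expect_equal(near$neighbors[["1"]], 2L)
  expect_equal(near$neighbors[["2"]], 1L)

  far <- compute_orbits(two_atoms(6), 5)
  expect_length(far$neighbors[["1"]], 0)
})

test_that("covalent perception applies radii, caps and nearest-first overflow", {
  w <- make_molecule("water")$structure
  cov <- perceive_covalent(w)
  expect_equal(nrow(cov), 2)
  expect_setequal(paste(cov$from, cov$to), c("1 2", "1 3"))

  hh <- two_atoms(10, c("H", "H"))
  expect_equal(nrow(perceive_covalent(hh)), 0)

  # H (cap 1) flanked by two O candidates: only the nearer O wins
  s <- tibble::tibble(atom = 1:3, element = c("H", "O", "O"),
                      x = c(0, 0.95, -1.05), y = 0, z = 0)
  cov <- perceive_covalent(s)
  expect_equal(nrow(cov), 1)
  expect_equal(c(cov$from, cov$to), c(1L, 2L))
})

test_that("H-bond arcs need a donor hydrogen, distance and near-linearity", {
  w <- make_molecule("water")$structure
  cov <- perceive_covalent(w)
  expect_equal(nrow(perceive_hbonds(w, cov)), 0)

  d <- make_molecule("water_dimer")$structure
  covd <- perceive_covalent(d)
  hb <- perceive_hbonds(d, covd)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor, 1L)
  expect_equal(hb$acceptor, 4L)
  expect_equal(hb$hydrogen, 2L)

  # rotate the donor hydrogen so the D-H...A angle drops below threshold
  th <- -100 * pi / 180
  rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  h <- as.numeric(d[2, c("x", "y", "z")])
  d2 <- d; d2[2, c("x", "y", "z")] <- as.list(as.numeric(rz %*% h))
  expect_equal(nrow(perceive_hbonds(d2, perceive_covalent(d2))), 0)
})

test_that("electrostatic and organometallic contacts require exactly one flag", {
  na_w <- tibble::tibble(atom = 1:4, element = c("Na", "O", "H", "H"),
                         x = c(2.4, 0, 0.3, -0.3), y = c(0, 0, 0.9, 0.9), z = 0)
  ei <- perceive_special(na_w, "electrostatic",
                         covalent = perceive_covalent(na_w))
  expect_equal(nrow(ei), 1)
  expect_setequal(c(ei$from, ei$to), c(1L, 2L))

  plain <- make_molecule("water")$structure
  expect_equal(nrow(perceive_special(plain, "electrostatic")), 0)

  au_n <- tibble::tibble(atom = 1:2, element = c("Au", "N"),
                         x = c(0, 2.2), y = 0, z = 0)
  eo <- perceive_special(au_n, "organometallic", covalent = tibble::tibble(from = integer(), to = integer()))
  expect_equal(nrow(eo), 1)
})

test_that("the molecular graph keeps heavy vertices and typed edges", {
  he <- tibble::tibble(atom = 1L, element = "He", x = 0, y = 0, z = 0)
  g <- build_molgraph(he)
  expect_equal(nrow(g$vertices), 1)
  expect_equal(nrow(g$edges), 0)

  d <- build_molgraph(make_molecule("water_dimer")$structure)
  expect_equal(nrow(d$vertices), 2)
  expect_equal(d$edges$type, "hbond")
  expect_equal(sum(d$edges$type == "covalent"), 0)

  pep <- make_molecule("triala_like")$structure
  g <- build_molgraph(pep)
  expect_equal(nrow(g$vertices), sum(pep$element %in% c("C", "N", "O")))
})

test_that("perception is deterministic and respects valence caps", {
  set.seed(7)
  p <- load_params()
  caps <- stats::setNames(p$elements$max_covalent_bonds, p$elements$symbol)
  for (i in 1:20) {
    s <- random_structure(12)
    g1 <- build_molgraph(s)
    g2 <- build_molgraph(s)
    expect_identical(g1, g2)
    cov <- perceive_covalent(s)
    deg <- table(factor(c(cov$from, cov$to), levels = s$atom))
    expect_true(all(as.integer(deg) <= caps[s$element]))
  }
})

test_that("orbit-restricted perception equals the all-pairs scan under the drift bound", {
  set.seed(11)
  base <- make_molecule("water_dimer")$structure
  cutoff <- moltopo:::max_interaction_cutoff(load_params())
  orbit_radius <- cutoff + 2.0
  orbits <- compute_orbits(base, orbit_radius)
  snap <- base
  for (f in 1:15) {
    step <- matrix(stats::runif(nrow(snap) * 3, -0.05, 0.05), ncol = 3)
    snap[, c("x", "y", "z")] <- snap[, c("x", "y", "z")] + step
    drift <- max(sqrt(rowSums((as.matrix(snap[, c("x", "y", "z")]) -
                               orbits$reference_positions)^2)))
    expect_lt(drift, (orbit_radius - cutoff) / 2)
    with_orbits <- build_molgraph(snap, orbits = orbits)
    all_pairs <- build_molgraph(snap, orbits = NULL)
    expect_identical(with_orbits, all_pairs)
  }
})

test_that("GraphML export carries elements, bond types and arc hydrogens", {
  skip_if_not_installed("xml2")
  g <- build_molgraph(make_molecule("water_dimer")$structure)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, f)
  doc <- xml2::read_xml(f)
  ns <- xml2::xml_ns(doc)
  nodes <- xml2::xml_find_all(doc, ".//d1:node", ns)
  expect_length(nodes, 2)
  edges <- xml2::xml_find_all(doc, ".//d1:edge", ns)
  expect_length(edges, 1)
  expect_equal(xml2::xml_attr(edges, "directed"), "true")
  expect_equal(xml2::xml_text(xml2::xml_find_first(edges, ".//d1:data[@key='bond_type']", ns)), "hbond")
})
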