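path_graph <- function(n, element = "O") {
  mol_graph(tibble::tibble(atom = seq_len(n), element = element),
            if (n > 1) tibble::tibble(from = 1:(n - 1), to = 2:n, type = "covalent"))
}

ring_graph <- function(n, type = "hbond", offset = 0L) {
  ids <- seq_len(n) + offset
  mol_graph(tibble::tibble(atom = ids, element = "O"),
            tibble::tibble(from = ids, to = c(ids[-1], ids[1]), type = type))
}

test_that("trees have empty bases and K4 decomposes into three triangles", {
  expect_equal(minimum_cycle_basis(path_graph(6))$dimension, 0)

  k4 <- mol_graph(tibble::tibble(atom = 1:4, element = "C"),
                  tibble::tibble(from = c(1, 1, 1, 2, 2, 3), to = c(2, 3, 4, 3, 4, 4),
                                 type = "covalent"))
  b <- minimum_cycle_basis(k4)
  expect_equal(b$dimension, 3)
  expect_true(all(vapply(b$cycles, length, 0L) == 3))
  # GF(2) independence of the returned basis
  mat <- cycles_to_matrix(b$cycles, graph_edge_keys(k4))
  expect_equal(gf2_rank(mat), 3)
})

test_that("hexagonal lattice patches decompose into hexagons only", {
  g <- build_molgraph(make_water_sheet(2, 2))
  b <- minimum_cycle_basis(g)
  expect_gt(b$dimension, 0)
  expect_true(all(vapply(b$cycles, length, 0L) == 6))
})

test_that("basis dimension, independence and simplicity hold on random graphs", {
  set.seed(77)
  for (i in 1:30) {
    n <- sample(3:10, 1)
    g <- rand_colored_graph(n, p_edge = stats::runif(1, 0.15, 0.6))
    b <- minimum_cycle_basis(g)
    em <- graph_edge_keys(g)
    expected_dim <- length(em) - n + sum(connected_component_sizes(g)$count)
    expect_equal(b$dimension, expected_dim)
    expect_equal(length(b$cycles), expected_dim)
    if (expected_dim > 0) {
      mat <- cycles_to_matrix(b$cycles, em)
      expect_equal(gf2_rank(mat), expected_dim)
      # every reported cycle is a simple cycle of the graph
      for (cyc in b$cycles) {
        expect_equal(anyDuplicated(cyc), 0)
        k <- length(cyc)
        pairs <- paste(pmin(cyc, c(cyc[-1], cyc[1])), pmax(cyc, c(cyc[-1], cyc[1])))
        expect_true(all(pairs %in% em))
      }
    }
  }
})

test_that("basis weight matches the exhaustive minimum on small graphs", {
  set.seed(41)
  for (i in 1:12) {
    g <- rand_colored_graph(sample(4:8, 1), p_edge = 0.45)
    b <- minimum_cycle_basis(g)
    expect_equal(sum(vapply(b$cycles, length, 0L)), min_basis_weight_oracle(g))
  }
})

test_that("component histograms pool all edge types", {
  edgeless <- mol_graph(tibble::tibble(atom = 1:5, element = "C"))
  expect_equal(connected_component_sizes(edgeless),
               tibble::tibble(size = 1L, count = 5L))

  two <- mol_graph(
    tibble::tibble(atom = 1:8, element = "C"),
    tibble::tibble(from = c(1, 2, 4, 5, 6, 7), to = c(2, 3, 5, 6, 7, 8),
                   type = c("covalent", "hbond", "covalent", "electrostatic",
                            "covalent", "covalent")))
  expect_equal(connected_component_sizes(two),
               tibble::tibble(size = c(3L, 5L), count = c(1L, 1L)))

  sheet48 <- build_molgraph(make_water_sheet(4, 4))
  expect_equal(connected_component_sizes(sheet48),
               tibble::tibble(size = 48L, count = 1L))
})

test_that("ring-size histograms normalise over pooled per-frame bases", {
  expect_equal(nrow(ring_size_histogram(list(path_graph(5)))), 0)

  sheet <- build_molgraph(make_water_sheet(2, 3))
  h <- ring_size_histogram(list(sheet))
  expect_equal(h, tibble::tibble(size = 6L, frequency = 1))

  sq_pent <- lapply(1:10, function(f) {
    mol_graph(
      tibble::tibble(atom = 1:9, element = "O"),
      dplyr::bind_rows(
        tibble::tibble(from = 1:4, to = c(2:4, 1), type = "hbond"),
        tibble::tibble(from = 5:9, to = c(6:9, 5), type = "hbond")))
  })
  h2 <- ring_size_histogram(sq_pent)
  expect_equal(h2$frequency, c(0.5, 0.5))
  expect_equal(h2$size, c(4L, 5L))
})

test_that("polygon membership averages the on-cycle vertex percentage", {
  ring <- ring_graph(6)
  expect_equal(polygon_membership_fraction(ring), 100)

  ring_chain <- mol_graph(
    tibble::tibble(atom = 1:12, element = "O"),
    dplyr::bind_rows(
      tibble::tibble(from = 1:6, to = c(2:6, 1), type = "hbond"),
      tibble::tibble(from = 6:11, to = 7:12, type = "covalent")))
  expect_equal(polygon_membership_fraction(ring_chain), 50)

  expect_equal(polygon_membership_fraction(path_graph(4)), 0)
  empty <- mol_graph(tibble::tibble(atom = integer(), element = character()))
  expect_error(polygon_membership_fraction(empty), "empty")
})

test_that("the graph of cycles joins H-bonded cycles that share atoms", {
  single <- ring_graph(6)
  cg <- cycle_interaction_graph(single)
  expect_equal(nrow(cg$vertices), 1)
  expect_equal(nrow(cg$edges), 0)

  # two hexagons sharing the 1-2 edge
  hex2 <- mol_graph(
    tibble::tibble(atom = 1:10, element = "O"),
    dplyr::bind_rows(
      tibble::tibble(from = c(1, 2, 3, 4, 5, 6), to = c(2, 3, 4, 5, 6, 1), type = "hbond"),
      tibble::tibble(from = c(1, 7, 8, 9, 10), to = c(7, 8, 9, 10, 2), type = "hbond")))
  cg2 <- cycle_interaction_graph(hex2)
  expect_equal(nrow(cg2$vertices), 2)
  expect_equal(nrow(cg2$edges), 1)

  disjoint <- mol_graph(
    tibble::tibble(atom = 1:12, element = "O"),
    dplyr::bind_rows(ring_graph(6)$edges,
                     tibble::tibble(from = 7:12, to = c(8:12, 7), type = "hbond")))
  cg3 <- cycle_interaction_graph(disjoint)
  expect_equal(nrow(cg3$vertices), 2)
  expect_equal(nrow(cg3$edges), 0)

  # a cycle without any H-bond arc is not a vertex
  cov_ring <- ring_graph(5, type = "covalent")
  expect_equal(nrow(cycle_interaction_graph(cov_ring)$vertices), 0)
})

test_that("z-slab filtering keeps atoms inside the slab", {
  s <- make_water_sheet(1, 1)
  s$z <- s$z + rep(c(0, 5), length.out = nrow(s))
  kept <- z_slab_filter(s, -1, 1)
  expect_true(all(kept$z >= -1 & kept$z <= 1))
  only_o <- z_slab_filter(s, -10, 10, elements = "O")
  expect_true(all(only_o$element == "O"))
})
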