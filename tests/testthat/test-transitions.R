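test_that("single-frame and frozen trajectories give one conformer", {
  w <- make_molecule("water_dimer")$structure
  one <- analyze_trajectory(as_trajectory(list(w)))
  expect_equal(nrow(tidy(one$registry)), 1)
  expect_equal(tidy(one$registry)$percentage, 100)
  expect_equal(nrow(one$transitions$edges), 0)

  frozen <- analyze_trajectory(as_trajectory(rep(list(w), 100)))
  expect_equal(length(frozen$registry$keys), 1)
  expect_equal(tidy(frozen$registry)$count, 100)
})

test_that("a scripted H-bond toggle reproduces its conformer schedule", {
  tr <- make_scripted_trajectory(schedule = c(0, 0, 1, 1, 0))
  res <- analyze_trajectory(tr$trajectory)
  expect_equal(res$assignment$conformer, tr$expected_ids)
  td <- tidy(res$registry)
  expect_equal(td$percentage, c(60, 40))
  e <- res$transitions$edges
  expect_equal(nrow(e), 2)
  expect_equal(e$count[e$from == 1 & e$to == 2], 1L)
  expect_equal(e$count[e$from == 2 & e$to == 1], 1L)
})

test_that("bond diffs are typed, directional set differences", {
  g <- build_molgraph(make_molecule("water_dimer")$structure)
  expect_equal(nrow(diff_bonds(g, g)$formed), 0)
  expect_equal(nrow(diff_bonds(g, g)$broken), 0)

  v <- tibble::tibble(atom = 1:2, element = c("N", "O"))
  gi <- mol_graph(v, tibble::tibble(from = 1, to = 2, type = "covalent"), n_atoms = 2)
  gj <- mol_graph(v, tibble::tibble(from = c(1, 1), to = c(2, 2),
                                    type = c("covalent", "hbond")), n_atoms = 2)
  d <- diff_bonds(gi, gj)
  expect_equal(nrow(d$broken), 0)
  expect_equal(d$formed$type, "hbond")

  rev1 <- mol_graph(v, tibble::tibble(from = 1, to = 2, type = "hbond"), n_atoms = 2)
  rev2 <- mol_graph(v, tibble::tibble(from = 2, to = 1, type = "hbond"), n_atoms = 2)
  dr <- diff_bonds(rev1, rev2)
  expect_equal(dr$broken$from, 1L)
  expect_equal(dr$formed$from, 2L)

  other <- mol_graph(tibble::tibble(atom = 1:2, element = c("N", "O")),
                     NULL, n_atoms = 5)
  expect_error(diff_bonds(gi, other), "atom universe")
})

test_that("transition counting and percentages are conserved", {
  reg <- conformer_registry()
  a <- build_molgraph(make_molecule("water_dimer")$structure)
  b <- build_molgraph(moltopo:::toggle_donor_h(make_molecule("water_dimer")$structure, -100))
  r <- assign_conformer(reg, a, 1); r <- assign_conformer(r$registry, b, 2)
  reg <- r$registry

  tg1 <- build_transition_graph(c(1, 1, 1), reg)
  expect_equal(nrow(tg1$edges), 0)

  tg <- build_transition_graph(c(1, 2, 1, 2, 1), reg)
  expect_equal(sort(tg$edges$count), c(2L, 2L))
  expect_true(all(tg$edges$from != tg$edges$to))

  tg2 <- build_transition_graph(c(1, 1, 2), reg)
  expect_equal(tg2$vertices$percentage, c(200 / 3, 100 / 3), tolerance = 1e-12)
  expect_equal(sum(tg2$vertices$percentage), 100, tolerance = 1e-9)
  ids <- c(1, 2, 2, 1, 2)
  tg3 <- build_transition_graph(ids, reg)
  expect_equal(sum(tg3$edges$count), sum(ids[-1] != ids[-length(ids)]))
})

test_that("exports colour vertices by the appearance threshold", {
  skip_if_not_installed("xml2")
  tr <- make_scripted_trajectory(schedule = c(0, 0, 0, 1, 1))
  res <- analyze_trajectory(tr$trajectory)
  base <- withr::local_tempfile()
  read_colors <- function(path) {
    doc <- xml2::read_xml(path)
    ns <- xml2::xml_ns(doc)
    xml2::xml_text(xml2::xml_find_all(doc, ".//d1:data[@key='color']", ns))
  }
  export_transition_graph(res$transitions, base, p_min = 0)
  expect_true(all(read_colors(paste0(base, ".graphml")) == "red"))
  export_transition_graph(res$transitions, base, p_min = 100)
  expect_true(all(read_colors(paste0(base, ".graphml")) == "green"))
  export_transition_graph(res$transitions, base, p_min = 4)
  expect_true(all(read_colors(paste0(base, ".graphml")) == "red"))
  expect_true(file.exists(paste0(base, ".dot")))
  expect_match(readLines(paste0(base, ".dot"))[1], "digraph")
})

test_that("frame permutation preserves the conformer set but not transitions", {
  tr <- make_scripted_trajectory(schedule = c(0, 1, 0, 1, 0, 0))
  res <- analyze_trajectory(tr$trajectory)
  set.seed(3)
  perm <- sample(6)
  snaps <- lapply(perm, function(f) traj_snapshot(tr$trajectory, f))
  res_p <- analyze_trajectory(as_trajectory(snaps))
  expect_setequal(res$registry$keys, res_p$registry$keys)
  expect_equal(sum(res$transitions$edges$count), 4)
  expect_false(identical(res$transitions$edges, res_p$transitions$edges))
})
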