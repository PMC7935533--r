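test_that("build_subnetwork induces edges and removes isolated vertices", {
  path3 <- toy_interactome(c("A B", "B C"))
  s1 <- build_subnetwork(c("A", "C"), path3)
  expect_equal(n_vertices(s1), 0L)
  expect_equal(n_edges(s1), 0L)
  expect_equal(attr(s1, "n_isolated"), 2L)

  s2 <- build_subnetwork(c("A", "B"), path3)
  expect_equal(n_vertices(s2), 2L)
  expect_equal(n_edges(s2), 1L)

  s3 <- build_subnetwork(interactome_vertices(path3), path3)
  expect_equal(n_edges(s3), n_edges(path3))

  expect_equal(n_vertices(build_subnetwork(character(0), path3)), 0L)
  expect_equal(attr(build_subnetwork(c("A", "B", "ZZZ"), path3), "n_absent"), 1L)
})

test_that("build_subnetwork is idempotent on its own vertex set", {
  set.seed(21)
  net <- generate_interactome(simulation_config(seed = 21, n_proteins = 200))
  sub <- build_subnetwork(sample(interactome_vertices(net), 80), net)
  sub2 <- build_subnetwork(interactome_vertices(sub), sub)
  expect_equal(sort(interactome_vertices(sub2)), sort(interactome_vertices(sub)))
  expect_equal(n_edges(sub2), n_edges(sub))
})

test_that("degree_counts tallies within-subnetwork connectivity", {
  star <- build_subnetwork(c("H", paste0("L", 1:4)),
                           toy_interactome(paste("H", paste0("L", 1:4))))
  expect_equal(degree_counts(star)$counts, c(`1` = 4L, `4` = 1L))

  tri <- toy_interactome(c("A B", "B C", "C A"))
  expect_equal(degree_counts(tri)$counts, c(`2` = 3L))

  p3 <- toy_interactome(c("A B", "B C"))
  expect_equal(degree_counts(p3)$counts, c(`1` = 2L, `2` = 1L))
  expect_equal(degree_counts(p3)$n_vertices, 3L)

  empty <- build_subnetwork(character(0), tri)
  expect_equal(degree_counts(empty)$n_vertices, 0L)
})

test_that("shannon_entropy matches hand-computed closed forms", {
  tri <- toy_interactome(c("A B", "B C", "C A"))
  expect_equal(shannon_entropy(degree_counts(tri)), 0)

  star <- toy_interactome(paste("H", paste0("L", 1:4)))
  expect_equal(shannon_entropy(degree_counts(star)),
               -(0.8 * log2(0.8) + 0.2 * log2(0.2)), tolerance = 1e-12)

  p3 <- toy_interactome(c("A B", "B C"))
  expect_equal(shannon_entropy(degree_counts(p3)),
               -(1 / 3 * log2(1 / 3) + 2 / 3 * log2(2 / 3)), tolerance = 1e-12)

  empty <- build_subnetwork(character(0), tri)
  expect_warning(h <- shannon_entropy(degree_counts(empty)), "undefined")
  expect_true(is.na(h))
})

test_that("degrees and entropy agree with a brute-force oracle on random graphs", {
  set.seed(31)
  for (rep in 1:20) {
    em <- random_edge_matrix(sample(5:50, 1), sample(4:60, 1))
    net <- interactome(em)
    ora <- oracle_degrees(em)
    deg <- interactome_degree(net)
    expect_equal(deg[sort(names(deg))], ora[sort(names(ora))])
    expect_equal(shannon_entropy(degree_counts(net)), oracle_entropy(ora),
                 tolerance = 1e-10)
    # entropy is bounded by log2(#distinct degrees)
    expect_lte(shannon_entropy(degree_counts(net)),
               log2(length(unique(ora))) + 1e-12)
  }
})

test_that("rank_hubs sorts by full-interactome degree with lexicographic ties", {
  star <- toy_interactome(c("H A", "H B", "H C"))
  expect_equal(rank_hubs(c("A", "B"), star),
               data.frame(accession = c("A", "B"), degree = c(1L, 1L)),
               ignore_attr = TRUE)
  expect_equal(rank_hubs(c("H", "A"), star),
               data.frame(accession = c("H", "A"), degree = c(3L, 1L)),
               ignore_attr = TRUE)
  expect_equal(nrow(rank_hubs(c("H", "A", "B"), star, n = 1)), 1L)
  expect_equal(rank_hubs(c("H", "A"), star, n = 1)$accession, "H")

  # ranking uses FULL-interactome degree, not within-list degree
  chain <- toy_interactome(c("A B", "B C", "C D", "C E"))
  r <- rank_hubs(c("A", "C"), chain)
  expect_equal(r$accession[1], "C")
  expect_equal(r$degree, c(3L, 1L))

  expect_equal(attr(rank_hubs(c("H", "NOPE"), star), "n_absent"), 1L)
})

test_that("rank_hubs is stable under permutation and finds the generator's hub", {
  cfg <- simulation_config(seed = 13, n_proteins = 500)
  net <- generate_interactome(cfg)
  genes <- interactome_vertices(net)
  set.seed(99)
  expect_identical(rank_hubs(genes, net), rank_hubs(sample(genes), net))
  top1 <- rank_hubs(genes, net, n = 1)
  expect_equal(top1$accession,
               names(which.max(interactome_degree(net)))[1])
})

test_that("target_recurrence keeps genes at or above the cohort threshold", {
  lists <- c(rep(list(c("P1", "P2")), 7), rep(list("P2"), 3))
  tab <- target_recurrence(lists, threshold = 0.70)
  expect_equal(tab$accession, c("P2", "P1"))
  expect_equal(tab$fraction, c(1.0, 0.7))
  expect_equal(tab$cohort_size, c(10L, 10L))

  # 6 of 10 misses a 70% threshold
  lists2 <- c(rep(list("P1"), 6), rep(list("PX"), 4))
  expect_false("P1" %in% target_recurrence(lists2, 0.70)$accession)

  # threshold 0 retains everything
  expect_equal(sort(target_recurrence(lists2, 0)$accession), c("P1", "PX"))
})
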