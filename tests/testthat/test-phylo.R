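test_that("model distances match closed forms, limits and an independent implementation", {
  m <- distance_model("K2P")
  a <- strrep("A", 100)
  expect_equal(model_distance(a, a, m), 0)
  # P = 0.1, Q = 0: d = -1/2 log(0.8)
  b <- paste0(strrep("G", 10), strrep("A", 90))
  expect_equal(model_distance(a, b, m), -0.5 * log(0.8), tolerance = 1e-12)
  # gamma correction converges to the uncorrected distance for large shape
  mg <- distance_model("K2P", gamma_shape = 1e6)
  expect_equal(model_distance(a, b, mg), model_distance(a, b, m),
               tolerance = 1e-6)

  set.seed(53)
  x <- sample(c("A", "C", "G", "T"), 500, replace = TRUE)
  y <- x
  mut <- sample(500, 70)
  y[mut] <- vapply(y[mut], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                   character(1))
  bin <- ape::as.DNAbin(rbind(x, y))
  expect_equal(model_distance(x, y, distance_model("K2P")),
               unname(ape::dist.dna(bin, model = "K80")[1]), tolerance = 1e-10)
  expect_equal(model_distance(x, y, distance_model("TN93")),
               unname(ape::dist.dna(bin, model = "TN93")[1]), tolerance = 1e-10)
  expect_equal(model_distance(x, y, distance_model("K2P", gamma_shape = 0.9136)),
               unname(ape::dist.dna(bin, model = "K80", gamma = 0.9136)[1]),
               tolerance = 1e-10)
  # symmetry
  expect_equal(model_distance(x, y, distance_model("TN93")),
               model_distance(y, x, distance_model("TN93")))
})

test_that("an invariant-site fraction rescales the distance consistently", {
  a <- strrep("A", 200)
  b <- paste0(strrep("G", 10), strrep("A", 190))  # P = 0.05
  m0 <- distance_model("K2P")
  mi <- distance_model("K2P", prop_invariant = 0.5)
  # P' = 0.1 on the variable half, scaled back by (1 - p_inv)
  expect_equal(model_distance(a, b, mi), 0.5 * (-0.5 * log(0.8)),
               tolerance = 1e-12)
  expect_gt(model_distance(a, b, mi), model_distance(a, b, m0))
  expect_error(distance_model("p", prop_invariant = 0.2), "requires")
})

test_that("saturated comparisons flag an infinite distance, never NaN", {
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 60), strrep("A", 40))  # P = 0.6 -> 1 - 2P < 0
  expect_warning(d <- model_distance(a, b, distance_model("K2P")), "saturated")
  expect_identical(d, Inf)
})

test_that("distance is monotone nondecreasing in the mismatch proportion", {
  a <- strrep("A", 200)
  prev <- 0
  for (k in seq(0, 60, by = 10)) {
    b <- paste0(strrep("G", k), strrep("A", 200 - k))  # transitions only
    d <- model_distance(a, b, distance_model("K2P"))
    expect_gte(d, prev)
    prev <- d
  }
})

test_that("neighbor joining reproduces additive trees exactly", {
  # 3 taxa: unique topology with the closed three-point branch lengths
  D <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  expect_equal(ape::Ntip(tr), 3L)
  dm <- ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(unname(dm), unname(D), tolerance = 1e-9)

  # additive 4-taxon matrix from a known tree is recovered exactly
  D4 <- matrix(c(0, 5, 9, 10, 5, 0, 10, 11, 9, 10, 0, 7, 10, 11, 7, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr4 <- nj_tree(D4)
  expect_true(is_monophyletic(tr4, c("a", "b")))
  expect_equal(unname(ape::cophenetic.phylo(tr4)[letters[1:4], letters[1:4]]),
               unname(D4), tolerance = 1e-9)

  expect_error(nj_tree(matrix(c(0, 1, 1, 0), 2, 2)), "3 taxa")
  Dbad <- D4; Dbad[1, 2] <- 99
  expect_error(nj_tree(Dbad), "symmetric")
})

test_that("NJ matches exhaustive least squares on additive 5-taxon matrices", {
  skip_if_not_installed("phangorn")
  topos <- phangorn::allTrees(5, rooted = FALSE, tip.label = paste0("t", 1:5))
  set.seed(59)
  for (rep in 1:8) {
    base <- ape::rtree(5, rooted = FALSE, tip.label = paste0("t", 1:5))
    base$edge.length <- stats::runif(nrow(base$edge), 0.3, 2)
    D <- ape::cophenetic.phylo(base)[paste0("t", 1:5), paste0("t", 1:5)]
    tr <- nj_tree(D)
    rss <- vapply(topos, function(tp) ls_rss(tp, D), numeric(1))
    best <- topos[[which.min(rss)]]
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(best)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("negative NJ branch estimates are clamped to zero", {
  # a strongly non-additive matrix that forces a negative branch estimate
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 10
  D["a", "c"] <- D["c", "a"] <- 1
  D["a", "d"] <- D["d", "a"] <- 1
  D["b", "c"] <- D["c", "b"] <- 1
  D["b", "d"] <- D["d", "b"] <- 1
  D["c", "d"] <- D["d", "c"] <- 10
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap support is reproducible, bounded and sensible for planted clades", {
  ev <- evolve_alignment(random_coding_seq(200, seed = 4), n_genera = 2,
                         species_per_genus = 1, types_per_species = 1,
                         subtypes_per_type = 3, seed = 14)
  aln <- ev$alignment
  b1 <- bootstrap_tree(aln, n_reps = 60, seed = 99)
  b2 <- bootstrap_tree(aln, n_reps = 60, seed = 99)
  expect_identical(b1$support$support, b2$support$support)
  expect_true(all(b1$support$support >= 0 & b1$support$support <= 100))
  # the deep split between the two well-separated clades is highly supported
  g1 <- aln$ids[grepl("^g1", aln$ids)]
  deep <- b1$support[b1$support$tips == paste(sort(g1), collapse = ",") |
                       b1$support$tips ==
                         paste(sort(setdiff(aln$ids, g1)), collapse = ","), ]
  expect_true(any(deep$support >= 95))

  # a single replicate gives all-or-nothing support
  b3 <- bootstrap_tree(aln, n_reps = 1, seed = 5)
  expect_true(all(b3$support$support %in% c(0, 100)))
  small <- alignment(c("a", "b", "c"), c("ACGT", "ACGA", "ACTT"))
  expect_error(bootstrap_tree(small), "fewer than 4")
})

test_that("monophyly queries agree with exhaustive bipartition enumeration", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(is_monophyletic(tr, "A"))
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_error(is_monophyletic(tr, c("A", "Z")), "unknown leaf")
  expect_error(is_monophyletic(tr, c("A", "B", "C", "D")), "proper subset")

  set.seed(61)
  for (rep in 1:10) {
    tr <- ape::unroot(ape::rtree(7))
    parts <- all_bipartitions(tr)
    part_keys <- vapply(parts, function(p) paste(p, collapse = ","),
                        character(1))
    for (trial in 1:12) {
      k <- sample(2:5, 1)
      sub <- sort(sample(seq_len(7), k))
      comp <- setdiff(seq_len(7), sub)
      expected <- paste(sub, collapse = ",") %in% part_keys ||
        paste(comp, collapse = ",") %in% part_keys
      expect_equal(is_monophyletic(tr, tr$tip.label[sub]), expected)
    }
  }
})

test_that("trees round-trip through Newick with support labels", {
  ev <- evolve_alignment(random_coding_seq(150, seed = 6), n_genera = 2,
                         species_per_genus = 1, types_per_species = 1,
                         subtypes_per_type = 2, seed = 16)
  b <- bootstrap_tree(ev$alignment, n_reps = 20, seed = 3)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(b$tree, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, ev$alignment$ids)
  expect_true(!is.null(back$node.label))
})
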