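test_that("p-distance counts differing comparable sites and excludes gaps/N pairwise", {
  expect_equal(p_distance(strrep("A", 100), strrep("A", 100)), 0)
  b <- paste0("T", strrep("A", 99))
  expect_equal(p_distance(strrep("A", 100), b), 0.01)
  # gap and N columns are excluded from the denominator
  expect_equal(p_distance("A-GTN", "ACGTN"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_error(p_distance("NNN", "AAA"), "comparable")

  set.seed(19)
  for (rep in 1:20) {
    L <- sample(30:80, 1)
    a <- sample(c("A", "C", "G", "T", "N", "-"), L, replace = TRUE,
                prob = c(rep(0.22, 4), 0.06, 0.06))
    b <- sample(c("A", "C", "G", "T", "N", "-"), L, replace = TRUE,
                prob = c(rep(0.22, 4), 0.06, 0.06))
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    if (sum(ok) == 0) next
    expect_equal(p_distance(a, b), sum(a[ok] != b[ok]) / sum(ok))
  }
})

test_that("group-mean identities equal the enumeration over cross pairs", {
  # two singleton groups differing at 16% of columns -> 84.0
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 16), strrep("A", 84))
  aln <- alignment(c("x", "y"), c(a, b))
  m <- group_mean_identity(aln, c(x = "G1", y = "G2"))
  expect_equal(m["G1", "G2"], 84)
  expect_equal(m["G1", "G1"], 100)  # singleton

  set.seed(29)
  seqs <- vapply(1:4, function(i) random_dna(60), character(1))
  aln <- alignment(paste0("s", 1:4), seqs)
  groups <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  m <- group_mean_identity(aln, groups)
  cross <- c(p_distance(seqs[1], seqs[3]), p_distance(seqs[1], seqs[4]),
             p_distance(seqs[2], seqs[3]), p_distance(seqs[2], seqs[4]))
  expect_equal(m["A", "B"], 100 * (1 - mean(cross)))
  expect_equal(m["A", "A"], 100 * (1 - p_distance(seqs[1], seqs[2])))
  expect_equal(m, t(m))
})

test_that("the demarcation cascade uses strict thresholds", {
  expect_equal(assign_rank(99.5), "same_subtype")
  expect_equal(assign_rank(91.0), "same_type")
  expect_equal(assign_rank(90.0), "same_species")  # strict: 90 is not > 90
  expect_equal(assign_rank(90.0, demarcation_config(strict_inequality = FALSE)),
               "same_type")
  expect_equal(assign_rank(65), "same_genus")
  expect_equal(assign_rank(50), "different_genus")
  expect_error(assign_rank(101), "outside")
  expect_error(demarcation_config(type_min = 99.5), "thresholds")
})

test_that("threshold clustering is nested, deterministic and order invariant", {
  # all-identical sequences form one subtype
  aln <- alignment(paste0("s", 1:3), rep(strrep("ACGT", 30), 3))
  ct <- cluster_types(aln)
  expect_equal(unique(ct$subtype), 1L)
  # two sequences at 50% identity sit in different genera
  half <- paste0(strrep("A", 50), strrep("G", 50))
  ct <- cluster_types(alignment(c("a", "b"), c(strrep("A", 100), half)))
  expect_equal(length(unique(ct$genus)), 2L)

  ev <- evolve_alignment(random_coding_seq(250, seed = 8), n_genera = 2,
                         species_per_genus = 2, types_per_species = 2,
                         subtypes_per_type = 2, seed = 81)
  ct <- cluster_types(ev$alignment)
  key <- order(ct$id)
  lab <- ev$labels[order(ev$labels$id), ]
  for (lev in c("genus", "species", "type", "subtype")) {
    expect_true(same_partition(ct[[lev]][key], lab[[lev]]),
                label = paste("recovered", lev))
  }
  # input order does not change the partition
  perm <- rev(seq_along(ev$alignment$ids))
  aln2 <- alignment(ev$alignment$ids[perm], ev$alignment$seqs[perm])
  ct2 <- cluster_types(aln2)
  for (lev in c("genus", "species", "type", "subtype")) {
    expect_true(same_partition(ct2[[lev]][order(ct2$id)], lab[[lev]]))
  }
  # nesting: each subtype lies within one type, each type within one species
  expect_true(all(tapply(ct$type, ct$subtype,
                         function(v) length(unique(v))) == 1L))
  expect_true(all(tapply(ct$species, ct$type,
                         function(v) length(unique(v))) == 1L))
})

test_that("substitutions are classified by codon-level translation comparison", {
  s <- substitution_summary("GGA", "GGG")
  expect_equal(c(s$n_sub, s$n_syn, s$n_nonsyn), c(1, 1, 0))
  s <- substitution_summary("ATG", "ACG")
  expect_equal(c(s$n_sub, s$n_syn, s$n_nonsyn), c(1, 0, 1))
  # a doubly hit codon with changed translation counts all hits non-synonymous
  s <- substitution_summary("AAA", "GGA")
  expect_equal(c(s$n_sub, s$n_syn, s$n_nonsyn), c(2, 0, 2))
  expect_error(substitution_summary("ACGT", "ACGA"), "divisible by 3")

  set.seed(37)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  for (rep in 1:30) {
    a <- sample(sense, 10, replace = TRUE)
    b <- sample(sense, 10, replace = TRUE)
    s <- substitution_summary(paste0(a, collapse = ""), paste0(b, collapse = ""))
    exp_sub <- sum(strsplit(paste0(a, collapse = ""), "")[[1]] !=
                     strsplit(paste0(b, collapse = ""), "")[[1]])
    diffs <- a != b
    exp_syn <- sum(vapply(which(diffs), function(i) {
      if (code[[a[i]]] == code[[b[i]]]) {
        sum(strsplit(a[i], "")[[1]] != strsplit(b[i], "")[[1]])
      } else 0L
    }, integer(1)))
    expect_equal(s$n_sub, exp_sub)
    expect_equal(s$n_syn, exp_syn)
    expect_equal(s$n_sub, s$n_syn + s$n_nonsyn)
  }
})

test_that("identity is symmetric with a 100 diagonal", {
  set.seed(43)
  aln <- alignment(paste0("s", 1:4),
                   vapply(1:4, function(i) random_dna(50), character(1)))
  m <- identity_matrix(aln)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(100, 4))
  expect_true(all(m >= 0 & m <= 100))
})

test_that("the bundled global aligner produces a usable pairwise alignment", {
  out <- align_global("ACGTACGT", "ACGTACGT")
  expect_equal(out$seqs[[1]], out$seqs[[2]])
  out <- align_global("ACGTTTACGT", "ACGTACGT")
  expect_equal(nchar(out$seqs[[1]]), nchar(out$seqs[[2]]))
  expect_true(grepl("-", paste(out$seqs, collapse = "")))
  # the aligned pair still recovers a sensible identity
  expect_gt(100 * (1 - p_distance(out$seqs[[1]], out$seqs[[2]])), 70)
})

test_that("type frequencies reproduce subtype shares within each type", {
  ct <- data.frame(id = paste0("s", 1:8),
                   genus = 1, species = 1,
                   type = c(1, 1, 1, 1, 1, 1, 2, 2),
                   subtype = c(1, 1, 1, 1, 2, 2, 3, 3))
  tf <- type_frequencies(ct)
  expect_equal(tf$k[tf$type == 1 & tf$subtype == 1], 4)
  expect_equal(tf$n[tf$type == 1], c(6, 6))
  expect_equal(tf$pct[tf$type == 1 & tf$subtype == 1], 66.7)
  expect_equal(tf$pct[tf$type == 2], 100)
})
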