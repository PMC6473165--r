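test_that("find_orfs reports maximal ORFs, gates GTG, and handles wrap-around", {
  gl <- circular_genome("lin", "ATGAAATAA", "linear")
  o <- find_orfs(gl, min_aa = 2)
  expect_equal(nrow(o), 1L)
  expect_equal(c(o$start, o$end, o$aa_len), c(1, 9, 2))

  # only a GTG start present
  gg <- circular_genome("g", "GTGAAATAA", "linear")
  expect_equal(nrow(find_orfs(gg, min_aa = 2, allow_gtg = FALSE)), 0L)
  expect_equal(nrow(find_orfs(gg, min_aa = 2, allow_gtg = TRUE)), 1L)

  # ORF wrapping the origin: ATG at 10..12, stop TAA read across the origin
  gc <- circular_genome("c", "TAACCCGGGATG", "circular")
  o <- find_orfs(gc, min_aa = 1)
  expect_true(any(o$wraps_origin & o$start == 10))
})

test_that("find_orfs agrees with a doubled-sequence brute-force oracle", {
  set.seed(23)
  for (rep in 1:15) {
    s <- random_dna(sample(60:150, 1))
    g <- circular_genome("r", s, "circular")
    mine <- find_orfs(g, min_aa = 3)
    oracle <- brute_orfs_circular(s, min_aa = 3)
    expect_equal(nrow(mine), length(oracle))
    for (k in seq_along(oracle)) {
      o <- oracle[[k]]
      row <- mine[mine$start == o[["start"]], , drop = FALSE]
      expect_equal(nrow(row), 1L)
      expect_equal(row$aa_len, unname(o[["aa"]]))
    }
  }
})

test_that("splice-acceptor scores equal the upstream pyrimidine fraction", {
  sa <- find_splice_acceptors(circular_genome("x", "TTTTTTTTTTTTAG", "linear"))
  expect_equal(sa$pos, 14)
  expect_equal(sa$score, 1)
  sa <- find_splice_acceptors(circular_genome("x", "AAAAAAAAAAAAAG", "linear"))
  expect_equal(sa$score, 0)

  set.seed(5)
  for (rep in 1:10) {
    s <- random_dna(80)
    g <- circular_genome("r", s, "circular")
    sa <- find_splice_acceptors(g, window = 12)
    ch <- strsplit(s, "")[[1]]
    L <- length(ch)
    for (i in seq_len(nrow(sa))) {
      gpos <- sa$pos[i]
      apos <- ((gpos - 2) %% L) + 1
      expect_equal(ch[apos], "A")
      expect_equal(ch[gpos], "G")
      ctx <- ch[((apos - 1 - seq_len(12)) %% L) + 1]
      expect_equal(sa$score[i], sum(ctx %in% c("C", "T")) / 12)
    }
  }
})

test_that("L1 selection prefers ATG overlap, admits GTG, and breaks ties deterministically", {
  g <- circular_genome("toy", random_dna(120), "circular")
  l2 <- data.frame(start = 1, end = 30, wraps_origin = FALSE)
  acc <- data.frame(pos = 26, score = 0.9)
  cand <- function(start, aa, codon) {
    data.frame(name = "unassigned", start = start, end = start + 3 * (aa + 1) - 1,
               wraps_origin = FALSE, strand = "+", start_codon = codon,
               aa_len = aa, protein = "M", fallback = FALSE,
               stringsAsFactors = FALSE)
  }
  # ATG overlapping the L2 stop wins over a longer GTG
  out <- detect_l1_start(g, l2, rbind(cand(30, 10, "ATG"), cand(29, 20, "GTG")), acc)
  expect_equal(out$start_codon, "ATG")
  expect_false(out$fallback)
  # only a GTG overlaps (the puffin configuration, acceptor 2 nt upstream)
  out <- detect_l1_start(g, l2, rbind(cand(29, 12, "GTG"), cand(40, 20, "ATG")),
                         data.frame(pos = 27, score = 0.97))
  expect_equal(out$start_codon, "GTG")
  # two overlap candidates: longer wins; equal lengths -> smaller start
  out <- detect_l1_start(g, l2, rbind(cand(28, 8, "ATG"), cand(29, 12, "ATG")), acc)
  expect_equal(out$start, 29)
  out <- detect_l1_start(g, l2, rbind(cand(29, 8, "ATG"), cand(28, 8, "ATG")), acc)
  expect_equal(out$start, 28)
  # no overlap at all: longest downstream candidate, flagged
  out <- detect_l1_start(g, l2, rbind(cand(50, 8, "ATG"), cand(60, 15, "ATG")), acc)
  expect_true(out$fallback)
  expect_equal(out$start, 60)
  expect_error(detect_l1_start(g, l2, cand(1, 1, "ATG")[0, ], acc), "L1 not found")
})

test_that("generated genomes are annotated exactly, including the GTG start", {
  for (s in c(101, 102)) {
    res <- generate_genome(random_genome_spec(seed = s))
    ann <- annotate_genome(res$genome)
    expect_equal(ann$orfs$name, res$truth$orfs$name)
    expect_equal(ann$orfs$start, res$truth$orfs$start)
    expect_equal(ann$orfs$end, res$truth$orfs$end)
    expect_equal(ann$lcr$start, res$truth$lcr$start)
    expect_equal(ann$ncr$start, res$truth$ncr$start)
    # every reported protein re-translates without internal stops
    expect_false(any(grepl("\\*.", ann$orfs$protein)))
  }
  res <- generate_genome(random_genome_spec(seed = 103, l1_start = "GTG"))
  ann <- annotate_genome(res$genome)
  expect_equal(ann$orfs$start_codon[ann$orfs$name == "L1"], "GTG")
  expect_equal(ann$orfs$start[ann$orfs$name == "L1"],
               res$truth$orfs$start[res$truth$orfs$name == "L1"])
})

test_that("annotation is invariant to genome rotation up to a coordinate shift", {
  res <- generate_genome(genome_spec(seed = 21))
  g <- res$genome
  ann0 <- annotate_genome(g)
  off <- 1234L
  annr <- annotate_genome(rotate_genome(g, off))
  expect_equal(annr$orfs$name, ann0$orfs$name)
  expect_equal(annr$orfs$aa_len, ann0$orfs$aa_len)
  shift <- function(p) ((p - off - 1L) %% g$length) + 1L
  expect_equal(annr$orfs$start, shift(ann0$orfs$start))
  expect_equal(annr$orfs$end, shift(ann0$orfs$end))
})

test_that("a genome lacking E6 yields an explicit absence, not a misassignment", {
  res <- generate_genome(genome_spec(seed = 31))
  g <- res$genome
  # knock out E6 entirely: replace its span with ORF-free, motif-free filler
  e6 <- res$truth$orfs[res$truth$orfs$name == "E6", ]
  filler <- strrep("TCA", ceiling((e6$end - e6$start + 1) / 3))
  seq2 <- paste0(substr(filler, 1, e6$end - e6$start + 1),
                 substr(g$seq, e6$end + 1, g$length))
  ann <- annotate_genome(circular_genome("noE6", seq2, "circular"))
  expect_true("E6" %in% ann$absent)
  expect_true(all(c("E7", "E1", "E2", "L2", "L1") %in% ann$orfs$name))
})

test_that("the NCR is dropped below the 2 nt floor and flagged above 50 nt", {
  res <- generate_genome(genome_spec(seed = 51, ncr_len = 2))
  ann <- annotate_genome(res$genome)
  expect_equal(span_length(ann$ncr), 2L)
  expect_false(ann$ncr_atypical)
  # shrink the gap to 1 nt: below the floor, reported absent
  g <- res$genome
  ncr <- res$truth$ncr
  seq2 <- paste0(substr(g$seq, 1, ncr$start - 1),
                 substr(g$seq, ncr$start + 1, g$length))
  ann2 <- annotate_genome(circular_genome("g2", seq2, "circular"))
  expect_null(ann2$ncr)
  expect_true(all(c("E2", "L2") %in% ann2$orfs$name))
})

test_that("GFF3 output is well formed and splits wrap-around features", {
  res <- generate_genome(genome_spec(seed = 61))
  ann <- annotate_genome(res$genome)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, res$genome, f)
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  body <- lines[!grepl("^#", lines)]
  fields <- strsplit(body, "\t")
  expect_true(all(lengths(fields) == 9L))
  types <- vapply(fields, `[`, character(1), 3)
  expect_true(all(c("gene", "CDS", "region", "misc_feature") %in% types))
  starts <- as.integer(vapply(fields, `[`, character(1), 4))
  ends <- as.integer(vapply(fields, `[`, character(1), 5))
  expect_true(all(starts <= ends))
  expect_true(all(ends <= res$genome$length))
})
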