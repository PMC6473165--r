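# Synthetic papillomavirus-like data with known ground truth: circular
# genomes laid out E6-E7-E1(E9)-E2-NCR-L2-L1-LCR, alignments evolved down a
# nested cluster design, and cohorts with set prevalences.

SENSE_CODONS <- NULL  # filled lazily

sense_codons <- function() {
  if (is.null(SENSE_CODONS)) {
    code <- genetic_code_table()
    utils::assignInMyNamespace("SENSE_CODONS",
                               names(code)[code != "*"])
  }
  SENSE_CODONS
}

# codons encoding each amino acid
codons_for_aa <- function() {
  code <- genetic_code_table()
  split(names(code), unname(code))
}

random_sense_codons <- function(n) sample(sense_codons(), n, replace = TRUE)

encode_aa <- function(aa_chars, tables = codons_for_aa()) {
  vapply(aa_chars, function(a) {
    opts <- tables[[a]]
    if (is.null(opts)) stop("cannot encode '", a, "'", call. = FALSE)
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1))
}

#' Random coding sequence
#'
#' `n_codons` random sense codons preceded by ATG and followed by a stop;
#' deterministic given `seed`.
#'
#' @param n_codons Number of body codons (excluding start/stop).
#' @param seed RNG seed (or `NULL` to use the current RNG state).
#' @return A nucleotide string of length `3 * (n_codons + 2)`.
#' @export
random_coding_seq <- function(n_codons, seed = NULL) {
  with_seed(seed, {
    paste0("ATG", paste0(random_sense_codons(n_codons), collapse = ""),
           sample(STOP_CODONS, 1L))
  })
}

#' Specification of a synthetic papillomavirus-like genome
#'
#' Defaults reflect the layout and size ranges characteristic of avian
#' papillomaviruses (~7.3--8.1 kb; E6 of 81--99 aa, E1 of 587--722 aa, an
#' E9 nested within E1, a 2--50 nt non-coding region between E2 and L2, and
#' high copy numbers of the atypical E2-binding site in the LCR).
#'
#' @param length_target Expected genome length (nt); the assembled length
#'   must land within 200 nt of it.
#' @param orf_lengths Named amino-acid lengths for E6, E7, E1, E9, E2, L2,
#'   L1 (excluding the stop codon).
#' @param ncr_len Non-coding region length between E2 and L2 (2--50 nt).
#' @param lcr_len Long control region length (nt).
#' @param e2bs_atypical_n,e2bs_typical_n Planted E2-binding-site copies.
#' @param tata,polya Plant a TATA box / late polyadenylation signal in the
#'   LCR.
#' @param l1_start `"ATG"` or `"GTG"` (the puffin-virus alternative start).
#' @param seed RNG seed.
#' @export
genome_spec <- function(length_target = 7300L,
                        orf_lengths = c(E6 = 90L, E7 = 120L, E1 = 650L,
                                        E9 = 70L, E2 = 380L, L2 = 470L,
                                        L1 = 510L),
                        ncr_len = 20L, lcr_len = 600L,
                        e2bs_atypical_n = 8L, e2bs_typical_n = 0L,
                        tata = TRUE, polya = TRUE,
                        l1_start = c("ATG", "GTG"), seed = 1L) {
  l1_start <- match.arg(l1_start)
  need <- c("E6", "E7", "E1", "E9", "E2", "L2", "L1")
  if (!all(need %in% names(orf_lengths))) {
    stop("orf_lengths must name ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (ncr_len < 2L || ncr_len > 50L) stop("ncr_len must be 2-50", call. = FALSE)
  if (e2bs_atypical_n < 0L || e2bs_atypical_n > 9L) {
    stop("e2bs_atypical_n must be 0-9", call. = FALSE)
  }
  if (e2bs_typical_n < 0L || e2bs_typical_n > 3L) {
    stop("e2bs_typical_n must be 0-3", call. = FALSE)
  }
  structure(list(length_target = as.integer(length_target),
                 orf_lengths = orf_lengths, ncr_len = as.integer(ncr_len),
                 lcr_len = as.integer(lcr_len),
                 e2bs_atypical_n = as.integer(e2bs_atypical_n),
                 e2bs_typical_n = as.integer(e2bs_typical_n),
                 tata = tata, polya = polya, l1_start = l1_start,
                 seed = seed),
            class = "genome_spec")
}

#' Draw a random genome specification in the observed size range
#'
#' ORF lengths are drawn within the ranges reported for avian
#' papillomaviruses and the LCR length chosen so the genome lands in
#' 7.3--8.1 kb.
#'
#' @param seed RNG seed.
#' @param l1_start Start codon for L1.
#' @export
random_genome_spec <- function(seed = 1L, l1_start = c("ATG", "GTG")) {
  l1_start <- match.arg(l1_start)
  with_seed(seed, {
    repeat {
      ol <- c(E6 = sample(81:99, 1), E7 = sample(100:130, 1),
              E1 = sample(587:722, 1), E9 = sample(60:80, 1),
              E2 = sample(360:400, 1), L2 = sample(440:500, 1),
              L1 = sample(495:530, 1))
      ncr <- sample(2:50, 1)
      rest <- 3L * (sum(ol[c("E6", "E7", "E1", "E2", "L2", "L1")]) + 6L) -
        1L + ncr
      lo <- max(400L, 7300L - rest)
      hi <- min(800L, 8100L - rest)
      if (lo <= hi) break
    }
    lcr <- sample(lo:hi, 1)
    genome_spec(length_target = rest + lcr, orf_lengths = ol, ncr_len = ncr,
                lcr_len = lcr,
                e2bs_atypical_n = sample(0:9, 1),
                e2bs_typical_n = sample(0:3, 1),
                l1_start = l1_start,
                seed = sample.int(2^30, 1))
  })
}

# ---- genome assembly -------------------------------------------------------

# an ORF block: codons (incl. stop), nt-level fixed mask, planted aa motifs
build_orf_block <- function(aa_len, plants = list(), stop_codon = NULL,
                            tables = codons_for_aa()) {
  codons <- random_sense_codons(aa_len)
  fixed_codon <- rep(FALSE, aa_len + 1L)
  fixed_codon[1] <- TRUE  # start
  codons[1] <- "ATG"
  truth <- list()
  for (p in plants) {
    aa <- seq_chars(p$aa)
    pos <- p$at:(p$at + length(aa) - 1L)
    codons[pos] <- encode_aa(aa, tables)
    truth[[p$name]] <- list(at = p$at, aa = p$aa)
  }
  stopc <- stop_codon %||% sample(STOP_CODONS, 1L)
  codons <- c(codons, stopc)
  fixed_codon[aa_len + 1L] <- TRUE
  list(codons = codons, fixed_codon = fixed_codon, plants = truth)
}

# instantiate a planted motif string: X -> random aa, spacer handled by caller
inst_aa <- function(template) {
  ch <- seq_chars(template)
  ch[ch == "X"] <- sample(setdiff(AA_LETTERS, c("C")), sum(ch == "X"),
                          replace = TRUE)
  paste0(ch, collapse = "")
}

zinc_plant_aa <- function() {
  spacer <- sample(39:42, 1)
  list(aa = paste0(inst_aa("CXXC"),
                   paste0(sample(setdiff(AA_LETTERS, "C"), spacer,
                                 replace = TRUE), collapse = ""),
                   inst_aa("CXXC")),
       spacer = spacer)
}

# repair the dual-frame E9 window inside the E1 codon vector (in place);
# returns the modified codons or NULL if it failed to converge
weave_e9 <- function(e1_codons, e9_aa_len, fixed_codon) {
  # E9 occupies E1-relative nt o..o+3*(e9_aa_len+1)-1 in frame +1 (o = 152)
  o <- 152L
  span <- 3L * (e9_aa_len + 1L)
  nt <- seq_chars(paste0(e1_codons, collapse = ""))
  set_tri <- function(at, val) nt[at:(at + 2L)] <<- seq_chars(val)
  set_tri(o - 3L, "TAG")     # frame +1 stop guarding the E9 start
  set_tri(o, "ATG")          # E9 start
  set_tri(o + span - 3L, "TAA")  # E9 stop
  fixed_nt_local <- c((o - 3L):(o + 2L), (o + span - 3L):(o + span - 1L))
  last_e1_codon <- ceiling((o + span - 1L) / 3L) + 1L
  e1_range <- (ceiling((o - 3L) / 3L)):min(last_e1_codon, length(e1_codons) - 1L)
  for (iter in seq_len(800L)) {
    bad <- integer(0)
    # E1 frame: no stop among the covered codons
    for (ci in e1_range) {
      cd <- paste0(nt[(3L * ci - 2L):(3L * ci)], collapse = "")
      if (cd %in% STOP_CODONS) bad <- c(bad, (3L * ci - 2L):(3L * ci))
    }
    # E9 frame: no internal stop, no internal ATG before position o
    for (s in seq.int(o + 3L, o + span - 6L, 3L)) {
      cd <- paste0(nt[s:(s + 2L)], collapse = "")
      if (cd %in% STOP_CODONS) bad <- c(bad, s:(s + 2L))
    }
    if (length(bad) == 0L) break
    bad <- setdiff(bad, fixed_nt_local)
    if (length(bad) == 0L) return(NULL)
    pos <- sample(bad, 1L)
    nt[pos] <- sample(setdiff(c("A", "C", "G", "T"), nt[pos]), 1L)
    if (iter == 800L) return(NULL)
  }
  out <- vapply(seq_len(length(e1_codons)), function(ci) {
    paste0(nt[(3L * ci - 2L):(3L * ci)], collapse = "")
  }, character(1))
  list(codons = out, fixed_nt = fixed_nt_local, e9_offset = o, e9_span = span)
}

# lay out the LCR: returns list(nt chars, fixed mask, planted starts by kind)
build_lcr <- function(spec) {
  n <- spec$lcr_len
  nt <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  fixed <- rep(FALSE, n)
  sites <- list(tata = integer(0), polya = integer(0),
                e2bs_typical = integer(0), e2bs_atypical = integer(0))
  blocks <- list()
  if (spec$tata) blocks <- c(blocks, list(list(kind = "tata", seq = "TATAAAA",
                                               fix = rep(TRUE, 7L))))
  if (spec$polya) blocks <- c(blocks, list(list(kind = "polya", seq = "AATAAA",
                                                fix = rep(TRUE, 6L))))
  for (i in seq_len(spec$e2bs_typical_n)) {
    mid <- paste0(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = "")
    blocks <- c(blocks, list(list(kind = "e2bs_typical",
                                  seq = paste0("ACC", mid, "GGT"),
                                  fix = c(TRUE, TRUE, TRUE, rep(FALSE, 6L),
                                          TRUE, TRUE, TRUE))))
  }
  for (i in seq_len(spec$e2bs_atypical_n)) {
    mid <- paste0(sample(c("A", "C", "G", "T"), 4, replace = TRUE), collapse = "")
    blocks <- c(blocks, list(list(kind = "e2bs_atypical",
                                  seq = paste0("ACC", mid, "GGT"),
                                  fix = c(TRUE, TRUE, TRUE, rep(FALSE, 4L),
                                          TRUE, TRUE, TRUE))))
  }
  total <- sum(vapply(blocks, function(b) nchar(b$seq), integer(1)))
  gap_n <- length(blocks) + 1L
  if (total + 4L * gap_n > n) {
    stop("infeasible spec: LCR too short for the planted motifs", call. = FALSE)
  }
  slack <- n - total - 4L * gap_n
  extra <- if (length(blocks)) {
    stats::rmultinom(1, slack, rep(1, gap_n))[, 1]
  } else slack
  pos <- 1L
  for (bi in seq_along(blocks)) {
    pos <- pos + 4L + extra[bi]
    b <- blocks[[bi]]
    w <- nchar(b$seq)
    nt[pos:(pos + w - 1L)] <- seq_chars(b$seq)
    fixed[pos:(pos + w - 1L)] <- b$fix
    sites[[b$kind]] <- c(sites[[b$kind]], pos)
    pos <- pos + w
  }
  list(nt = nt, fixed = fixed, sites = sites)
}

# remove unplanned regulatory-motif hits from a non-coding stretch
scrub_noncoding <- function(nt, fixed, planted, pats) {
  s <- paste0(nt, collapse = "")
  for (iter in seq_len(400L)) {
    offenders <- integer(0)
    for (pn in names(pats)) {
      h <- scan_motif(s, pats[[pn]])
      extra <- setdiff(h$start, planted[[pn]] %||% integer(0))
      for (st in extra) {
        row <- h[h$start == st, , drop = FALSE][1, ]
        offenders <- c(offenders, st:row$end)
      }
    }
    if (length(offenders) == 0L) return(list(nt = nt, ok = TRUE))
    offenders <- setdiff(unique(offenders), which(fixed))
    if (length(offenders) == 0L) return(list(nt = nt, ok = FALSE))
    pos <- sample(offenders, 1L)
    nt[pos] <- sample(setdiff(c("A", "C", "G", "T"), nt[pos]), 1L)
    s <- paste0(nt, collapse = "")
  }
  list(nt = nt, ok = FALSE)
}

#' Generate a papillomavirus-like circular genome with known ground truth
#'
#' Assembles a circular genome in the avian layout
#' E6-E7-E1(E9 nested in frame +1)-E2-NCR-L2-L1-LCR, with the L2 stop codon
#' overlapping the L1 start by one nucleotide (an ATG or, mirroring the
#' puffin virus, a GTG), a splice-acceptor context at the end of L2, planted
#' protein motifs (zinc domains in E6/E7, pRb-binding in E7, Walker motifs
#' in E1, the DNA-binding domain in E2, furin/transmembrane/SNX17/
#' syntaxin-18 motifs in L2) and planted regulatory sites in the LCR.
#' Random filler is repaired in place so that no reading frame at or above
#' the accessory threshold exists besides the planted ORF complement, and no
#' unplanned regulatory-motif hit remains in the LCR or NCR; repairs only
#' touch non-planted positions, and coding positions only synonymously, so
#' the ground truth is preserved.  The genome is reported with E6 starting
#' at position 1 and is a pure function of the spec (including its seed).
#'
#' @param spec A [genome_spec()].
#' @return A list with `genome` (a [circular_genome()]) and `truth` (named
#'   ORF intervals, LCR/NCR intervals, planted motif positions, L1 start
#'   codon and acceptor position).
#' @export
generate_genome <- function(spec = genome_spec()) {
  for (attempt in seq_len(6L)) {
    out <- with_seed(spec$seed + (attempt - 1L) * 7919L,
                     try(generate_genome_once(spec), silent = TRUE))
    if (!inherits(out, "try-error") && !is.null(out)) return(out)
    if (inherits(out, "try-error") &&
        grepl("infeasible spec", attr(out, "condition")$message)) {
      stop(attr(out, "condition"))
    }
  }
  stop("genome generation did not converge for this spec/seed", call. = FALSE)
}

generate_genome_once <- function(spec) {
  ol <- spec$orf_lengths
  tables <- codons_for_aa()
  phi <- PHI_HYDROPHOBIC

  z6 <- zinc_plant_aa()
  e6 <- build_orf_block(ol[["E6"]], list(
    list(name = "e6_zinc", at = 6L, aa = z6$aa)
  ), tables = tables)

  z7 <- zinc_plant_aa()
  e7 <- build_orf_block(ol[["E7"]], list(
    list(name = "e7_prb", at = 16L, aa = inst_aa("LXCXE")),
    list(name = "e7_zinc", at = 35L, aa = z7$aa)
  ), tables = tables)

  e1 <- build_orf_block(ol[["E1"]], list(
    list(name = "walker_a", at = 300L, aa = inst_aa("GXXDSGKT")),
    list(name = "walker_b", at = 335L,
         aa = paste0(paste0(sample(phi, 2, replace = TRUE), collapse = ""), "DD")),
    list(name = "walker_c", at = 365L,
         aa = paste0(sample(phi, 1), "TSN"))
  ), tables = tables)
  wv <- weave_e9(e1$codons, ol[["E9"]], e1$fixed_codon)
  if (is.null(wv)) return(NULL)
  e1$codons <- wv$codons

  e2 <- build_orf_block(ol[["E2"]], list(
    list(name = "e2_dbd", at = ol[["E2"]] - 30L, aa = inst_aa("GXTXQLKTIRXR"))
  ), tables = tables)

  l2_stop <- if (spec$l1_start == "ATG") "TAA" else "TAG"
  l2 <- build_orf_block(ol[["L2"]], list(
    list(name = "furin", at = 12L, aa = inst_aa("RXKR")),
    list(name = "gxxxg_tm", at = 200L, aa = inst_aa("GXXXG")),
    list(name = "snx17", at = 250L, aa = inst_aa("FXNPXF")),
    list(name = "syntaxin18", at = 300L, aa = inst_aa("DQILQ"))
  ), stop_codon = l2_stop, tables = tables)
  # acceptor context + frame-guard for the L1 start (see vignette):
  # ... TTC TTT TCT CCT AGA <stop>, giving a TAG in the L1 frame 6 nt
  # upstream of the start and an AG acceptor 4 nt upstream
  nL2 <- ol[["L2"]]
  l2$codons[(nL2 - 4L):nL2] <- c("TTC", "TTT", "TCT", "CCT", "AGA")
  l2$fixed_codon[(nL2 - 4L):nL2] <- TRUE

  l1 <- build_orf_block(ol[["L1"]], list(), tables = tables)
  # L1 contributes "TG" + remainder: its first nt is the last nt of L2's stop
  l1_nt_full <- seq_chars(paste0(l1$codons, collapse = ""))

  ncr_nt <- sample(c("A", "C", "G", "T"), spec$ncr_len, replace = TRUE)
  lcr <- build_lcr(spec)

  # assemble: E6 E7 E1 E2 NCR L2 L1[-1] LCR
  blocks <- list(
    E6 = list(nt = seq_chars(paste0(e6$codons, collapse = "")),
              fixed_codon = e6$fixed_codon, coding = TRUE),
    E7 = list(nt = seq_chars(paste0(e7$codons, collapse = "")),
              fixed_codon = e7$fixed_codon, coding = TRUE),
    E1 = list(nt = seq_chars(paste0(e1$codons, collapse = "")),
              fixed_codon = e1$fixed_codon, coding = TRUE,
              fixed_nt_extra = wv$fixed_nt),
    E2 = list(nt = seq_chars(paste0(e2$codons, collapse = "")),
              fixed_codon = e2$fixed_codon, coding = TRUE),
    NCR = list(nt = ncr_nt, coding = FALSE),
    L2 = list(nt = seq_chars(paste0(l2$codons, collapse = "")),
              fixed_codon = l2$fixed_codon, coding = TRUE),
    L1 = list(nt = l1_nt_full[-1L], fixed_codon = l1$fixed_codon,
              coding = TRUE, trimmed = TRUE),
    LCR = list(nt = lcr$nt, coding = FALSE, fixed_nt = lcr$fixed)
  )

  nt <- character(0); region <- character(0); fixed <- logical(0)
  codon_no <- integer(0)
  starts <- integer(0)
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    starts[nm] <- length(nt) + 1L
    w <- length(b$nt)
    f <- rep(FALSE, w)
    cn <- rep(NA_integer_, w)
    if (isTRUE(b$coding)) {
      offs <- if (isTRUE(b$trimmed)) 2L else 0L  # L1 misses its first nt
      cn <- ((seq_len(w) + offs - 1L) %/% 3L) + 1L
      f <- b$fixed_codon[cn]
      if (isTRUE(b$trimmed)) f[cn == 1L] <- TRUE
      if (!is.null(b$fixed_nt_extra)) f[b$fixed_nt_extra] <- TRUE
    } else if (!is.null(b$fixed_nt)) {
      f <- b$fixed_nt
    }
    nt <- c(nt, b$nt); region <- c(region, rep(nm, w)); fixed <- c(fixed, f)
    codon_no <- c(codon_no, cn)
  }
  L <- length(nt)
  if (abs(L - spec$length_target) > 200L) {
    stop("infeasible spec: assembled length ", L, " is more than 200 nt from ",
         "length_target ", spec$length_target, call. = FALSE)
  }

  # ground-truth intervals
  orf_iv <- list(
    E6 = c(starts[["E6"]], starts[["E7"]] - 1L),
    E7 = c(starts[["E7"]], starts[["E1"]] - 1L),
    E1 = c(starts[["E1"]], starts[["E2"]] - 1L),
    E9 = c(starts[["E1"]] + wv$e9_offset - 1L,
           starts[["E1"]] + wv$e9_offset + wv$e9_span - 2L),
    E2 = c(starts[["E2"]], starts[["NCR"]] - 1L),
    L2 = c(starts[["L2"]], starts[["L1"]] - 1L),
    L1 = c(starts[["L1"]] - 1L, starts[["LCR"]] - 1L)  # starts on L2's last nt
  )
  truth_orfs <- data.frame(
    name = names(orf_iv),
    start = vapply(orf_iv, `[`, integer(1), 1),
    end = vapply(orf_iv, `[`, integer(1), 2),
    stringsAsFactors = FALSE
  )
  lcr_iv <- interval(starts[["LCR"]], L)
  ncr_iv <- interval(starts[["NCR"]], starts[["L2"]] - 1L)

  truth <- list(
    orfs = truth_orfs,
    lcr = lcr_iv, ncr = ncr_iv,
    l1_start_codon = spec$l1_start,
    acceptor_pos = orf_iv$L1[1] - 4L,
    sites = lapply(lcr$sites, function(p) p + starts[["LCR"]] - 1L),
    protein_plants = list(E6 = e6$plants, E7 = e7$plants, E1 = e1$plants,
                          E2 = e2$plants, L2 = l2$plants),
    e6_zinc_spacer = z6$spacer, e7_zinc_spacer = z7$spacer
  )

  g <- circular_genome("synthetic", paste0(nt, collapse = ""), "circular")

  # ---- in-place repair -----------------------------------------------------
  truth_keys <- paste(truth_orfs$start, truth_orfs$end, sep = ":")
  nt_pats <- builtin_motifs()[c("e2bs_typical", "e2bs_atypical", "tata_box",
                                "polya_site")]
  names(nt_pats) <- c("e2bs_typical", "e2bs_atypical", "tata", "polya")
  # lcr$sites uses the same names as nt_pats keys

  spurious_orfs <- function(g) {
    # exactly the annotator's ATG-start view; GTG starts only ever enter the
    # annotation as core-sized L1 candidates, which the start guard next to
    # the L1 junction already constrains
    found <- find_orfs(g, min_aa = 60L, allow_gtg = FALSE)
    if (spec$l1_start == "GTG") {
      # the ATG-truncated view of L1 shares L1's stop; not spurious
      l1_end <- truth_orfs$end[truth_orfs$name == "L1"]
      l1_start <- truth_orfs$start[truth_orfs$name == "L1"]
      found <- found[!(found$end == l1_end & found$start != l1_start), ,
                     drop = FALSE]
    }
    keys <- paste(found$start, found$end, sep = ":")
    found[!(keys %in% truth_keys), , drop = FALSE]
  }

  code <- genetic_code_table()
  # a single-nucleotide change at genome position p to base `b` is
  # permissible when the position is free and either non-coding or the
  # implied host-codon change is synonymous
  permissible <- function(p, b) {
    if (fixed[p] || nt[p] == b) return(FALSE)
    if (region[p] %in% c("NCR", "LCR")) return(TRUE)
    idx <- which(region == region[p] & codon_no == codon_no[p])
    if (length(idx) != 3L) return(FALSE)
    cur <- paste0(nt[idx], collapse = "")
    alt_nt <- nt[idx]; alt_nt[idx == p] <- b
    alt <- paste0(alt_nt, collapse = "")
    !(alt %in% STOP_CODONS) &&
      identical(unname(code[cur]), unname(code[alt]))
  }
  # break a spurious ORF by planting a stop codon in its frame (preferring
  # positions near its midpoint, so residual fragments fall under the
  # threshold quickly) or, failing that, by destroying its start codon
  kill_orf <- function(r) {
    span <- if (r$wraps_origin) c(r$start:L, 1L:r$end) else r$start:r$end
    ncod <- length(span) %/% 3L
    internal <- setdiff(seq_len(ncod - 1L), 1L)  # skip start, stop is last
    mid <- ncod / 2
    for (k in internal[order(abs(internal - mid))]) {
      pos3 <- span[(3L * k - 2L):(3L * k)]
      tri <- nt[pos3]
      for (stp in STOP_CODONS) {
        sc <- seq_chars(stp)
        d <- which(tri != sc)
        if (length(d) != 1L) next
        if (permissible(pos3[d], sc[d])) {
          nt[pos3[d]] <<- sc[d]
          return(TRUE)
        }
      }
    }
    # destroy the start codon
    for (d in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), nt[span[d]])) {
        alt <- nt[span[1:3]]; alt[d] <- b
        if (paste0(alt, collapse = "") %in% c("ATG", "GTG")) next
        if (permissible(span[d], b)) {
          nt[span[d]] <<- b
          return(TRUE)
        }
      }
    }
    # last resort: reshuffle the span with random permissible changes, so
    # the next round's targeted search sees fresh material
    moved <- FALSE
    for (try_i in seq_len(40L)) {
      p <- sample(span, 1L)
      b <- sample(setdiff(c("A", "C", "G", "T"), nt[p]), 1L)
      if (permissible(p, b)) { nt[p] <<- b; moved <- TRUE }
    }
    moved
  }

  for (round in seq_len(80L)) {
    sp <- spurious_orfs(g)
    changed <- FALSE
    if (nrow(sp) > 0L) {
      for (i in seq_len(nrow(sp))) {
        if (!kill_orf(sp[i, ])) {
          if (isTRUE(getOption("avianpv.debug"))) {
            message("repair stuck on ORF ", sp$start[i], ":", sp$end[i],
                    " aa ", sp$aa_len[i])
          }
          return(NULL)
        }
      }
      g <- circular_genome("synthetic", paste0(nt, collapse = ""), "circular")
      changed <- TRUE
    }
    # scrub non-coding motifs
    for (reg in c("LCR", "NCR")) {
      idx <- which(region == reg)
      planted <- if (reg == "LCR") lcr$sites else list()
      sc <- scrub_noncoding(nt[idx], fixed[idx], planted, nt_pats)
      if (!sc$ok) {
        if (isTRUE(getOption("avianpv.debug"))) message("scrub stuck in ", reg)
        return(NULL)
      }
      if (!identical(sc$nt, nt[idx])) {
        nt[idx] <- sc$nt
        g <- circular_genome("synthetic", paste0(nt, collapse = ""), "circular")
        changed <- TRUE
      }
    }
    if (!changed && nrow(spurious_orfs(g)) == 0L) break
    if (round == 80L) {
      if (isTRUE(getOption("avianpv.debug"))) message("repair rounds exhausted")
      return(NULL)
    }
  }
  list(genome = g, truth = truth)
}

# ---- sequence evolution ----------------------------------------------------

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

# apply m substitution events to a character vector of bases
mutate_seq <- function(x, m, kappa = 4, syn_only = FALSE,
                       code = genetic_code_table()) {
  if (m == 0L) return(x)
  n <- length(x)
  for (e in seq_len(m)) {
    done <- FALSE
    for (tr in seq_len(2000L)) {
      pos <- sample.int(n, 1L)
      cur <- x[pos]
      ts <- TRANSITION[[cur]]
      tv <- setdiff(c("A", "C", "G", "T"), c(cur, ts))
      new <- sample(c(ts, tv), 1L, prob = c(kappa, 1, 1))
      if (syn_only) {
        ci <- (pos - 1L) %/% 3L
        cod <- x[(3L * ci + 1L):(3L * ci + 3L)]
        alt <- cod; alt[pos - 3L * ci] <- new
        if (!identical(unname(code[paste0(cod, collapse = "")]),
                       unname(code[paste0(alt, collapse = "")]))) next
      }
      x[pos] <- new
      done <- TRUE
      break
    }
    if (!done) {
      stop("unreachable identity target under synonymous constraint",
           call. = FALSE)
    }
  }
  x
}

#' Evolve an alignment down a nested cluster design
#'
#' Starting from a root coding sequence, generates a balanced hierarchy of
#' genera, species, types and subtypes by applying Kimura-style
#' substitution events (transitions favored `kappa`:1) along each branch.
#' Per-level branch lengths are calibrated so that the realized mean
#' pairwise identity of leaves whose most recent common ancestor sits at
#' each level matches the `identity` targets to within `tol` percentage
#' points.  With `coding_constraint = "synonymous_only"` every event
#' preserves the encoded protein.  No indels are simulated, so the leaves
#' are returned already aligned.  Deterministic given `seed`.
#'
#' @param root Root coding nucleotide string (length divisible by 3 when
#'   the synonymous constraint is active).
#' @param n_genera,species_per_genus,types_per_species,subtypes_per_type
#'   Balanced design counts.
#' @param leaves_per_subtype Integer (or vector recycled across subtypes).
#' @param identity Named targets (percent): `between_genus`, `genus`,
#'   `species`, `type`, `subtype` — the mean identity of leaf pairs whose
#'   most recent common ancestor is at that level.
#' @param kappa Transition/transversion weight.
#' @param coding_constraint `"none"` or `"synonymous_only"`.
#' @param seed RNG seed.
#' @param tol Calibration tolerance in identity percentage points.
#' @return A list with `alignment` (an [alignment()]), `labels` (data
#'   frame: `id`, `genus`, `species`, `type`, `subtype`) and `tree`
#'   (`ape::phylo` of the design, branch lengths in substitutions/site).
#' @export
evolve_alignment <- function(root,
                             n_genera = 1L, species_per_genus = 1L,
                             types_per_species = 1L, subtypes_per_type = 2L,
                             leaves_per_subtype = 1L,
                             identity = c(between_genus = 50, genus = 65,
                                          species = 80, type = 95,
                                          subtype = 99.5),
                             kappa = 4, coding_constraint = c("none",
                                                              "synonymous_only"),
                             seed = 1L, tol = 1) {
  coding_constraint <- match.arg(coding_constraint)
  syn <- coding_constraint == "synonymous_only"
  rt <- seq_chars(toupper(root))
  if (syn && length(rt) %% 3L != 0L) {
    stop("root length must be divisible by 3 under the synonymous constraint",
         call. = FALSE)
  }
  L <- length(rt)
  lv_names <- c("between_genus", "genus", "species", "type", "subtype")
  if (!all(lv_names %in% names(identity))) {
    stop("identity must name ", paste(lv_names, collapse = ", "), call. = FALSE)
  }
  if (any(diff(identity[lv_names]) <= 0)) {
    stop("identity targets must be strictly increasing from between_genus ",
         "to subtype", call. = FALSE)
  }
  counts <- c(n_genera, species_per_genus, types_per_species,
              subtypes_per_type)
  n_subtypes_total <- prod(counts)
  lps <- rep_len(leaves_per_subtype, n_subtypes_total)

  # which levels actually have leaf pairs under this design
  has_pairs <- c(between_genus = counts[1] > 1, genus = counts[2] > 1,
                 species = counts[3] > 1, type = counts[4] > 1,
                 subtype = any(lps > 1))

  # per-lineage cumulative events below each MRCA level; a level without
  # pairs inherits the next deeper level's budget, so its branch carries no
  # events and substitution capacity is not wasted
  div <- (100 - identity[lv_names]) / 100
  cum <- L * div / 2
  adjust_cum <- function(cum) {
    for (k in rev(seq_along(lv_names))) {
      if (!has_pairs[[lv_names[k]]]) {
        cum[lv_names[k]] <- if (k < length(lv_names)) cum[[lv_names[k + 1]]]
        else 0
      }
    }
    cum
  }
  cum <- adjust_cum(cum)

  if (syn) {
    # feasibility: only sites with a synonymous single-nucleotide alternative
    # can ever diverge, so the deepest divergence target must fit under that
    # fraction
    code0 <- genetic_code_table()
    n_cod <- L %/% 3L
    syn_sites <- 0L
    for (ci in seq_len(n_cod)) {
      cod <- rt[(3L * ci - 2L):(3L * ci)]
      for (p in 1:3) {
        for (b in setdiff(c("A", "C", "G", "T"), cod[p])) {
          alt <- cod; alt[p] <- b
          if (identical(unname(code0[paste0(cod, collapse = "")]),
                        unname(code0[paste0(alt, collapse = "")]))) {
            syn_sites <- syn_sites + 1L
            break
          }
        }
      }
    }
    if (max(div[has_pairs]) > 0.9 * syn_sites / L) {
      stop("unreachable identity target under synonymous constraint",
           call. = FALSE)
    }
  }

  with_seed(seed, {
    code <- genetic_code_table()
    # join child subtrees into a parent fragment; a single child collapses
    # the degree-2 node, carrying its branch length upward
    compose <- function(kids, own_len) {
      if (length(kids) == 1L) {
        return(list(frag = kids[[1]]$frag, len = own_len + kids[[1]]$len))
      }
      list(frag = paste0("(", paste(vapply(kids, function(k) {
        sprintf("%s:%.6g", k$frag, k$len)
      }, character(1)), collapse = ","), ")"), len = own_len)
    }
    build <- function(e_lv) {
      # e_lv: events per branch at depths genus, species, type, subtype, leaf
      seqs <- list(); labels <- list()
      n_sp <- 0L; n_ty <- 0L; n_st <- 0L
      g_kids <- list()
      for (gi in seq_len(counts[1])) {
        gseq <- mutate_seq(rt, e_lv[1], kappa, syn, code)
        s_kids <- list()
        for (si in seq_len(counts[2])) {
          sseq <- mutate_seq(gseq, e_lv[2], kappa, syn, code)
          n_sp <- n_sp + 1L
          t_kids <- list()
          for (ti in seq_len(counts[3])) {
            tseq <- mutate_seq(sseq, e_lv[3], kappa, syn, code)
            n_ty <- n_ty + 1L
            u_kids <- list()
            for (ui in seq_len(counts[4])) {
              useq <- mutate_seq(tseq, e_lv[4], kappa, syn, code)
              n_st <- n_st + 1L
              l_kids <- list()
              for (li in seq_len(lps[n_st])) {
                lseq <- mutate_seq(useq, e_lv[5], kappa, syn, code)
                id <- sprintf("g%d.s%d.t%d.st%d.l%d", gi, si, ti, ui, li)
                seqs[[id]] <- lseq
                labels[[id]] <- c(gi, n_sp, n_ty, n_st)
                l_kids[[li]] <- list(frag = id, len = e_lv[5] / L)
              }
              u_kids[[ui]] <- compose(l_kids, e_lv[4] / L)
            }
            t_kids[[ti]] <- compose(u_kids, e_lv[3] / L)
          }
          s_kids[[si]] <- compose(t_kids, e_lv[2] / L)
        }
        g_kids[[gi]] <- compose(s_kids, e_lv[1] / L)
      }
      nwk <- if (length(g_kids) == 1L) paste0(g_kids[[1]]$frag, ";")
      else paste0("(", paste(vapply(g_kids, function(k) {
        sprintf("%s:%.6g", k$frag, k$len)
      }, character(1)), collapse = ","), ");")
      list(seqs = seqs, labels = labels, newick = nwk)
    }

    realized <- function(res) {
      ids <- names(res$seqs)
      lab <- do.call(rbind, res$labels[ids])
      lev_sum <- stats::setNames(numeric(5), lv_names)
      lev_n <- stats::setNames(numeric(5), lv_names)
      for (i in seq_len(length(ids) - 1L)) {
        for (j in (i + 1L):length(ids)) {
          mrca <- if (lab[i, 1] != lab[j, 1]) "between_genus"
          else if (lab[i, 2] != lab[j, 2]) "genus"
          else if (lab[i, 3] != lab[j, 3]) "species"
          else if (lab[i, 4] != lab[j, 4]) "type"
          else "subtype"
          idn <- 100 * mean(res$seqs[[i]] == res$seqs[[j]])
          lev_sum[mrca] <- lev_sum[mrca] + idn
          lev_n[mrca] <- lev_n[mrca] + 1
        }
      }
      ifelse(lev_n > 0, lev_sum / lev_n, NA_real_)
    }

    # per-branch events from per-lineage cumulative budgets below each level
    events_from_cum <- function(cum) {
      e <- c(genus = max(0, round(cum[["between_genus"]] - cum[["genus"]])),
             species = max(0, round(cum[["genus"]] - cum[["species"]])),
             type = max(0, round(cum[["species"]] - cum[["type"]])),
             subtype = max(0, round(cum[["type"]] - cum[["subtype"]])),
             leaf = max(0, round(cum[["subtype"]])))
      if (any(e > 6 * L)) {
        stop("identity calibration did not converge", call. = FALSE)
      }
      e
    }
    e_lv <- events_from_cum(cum)
    res <- build(e_lv)
    for (it in seq_len(10L)) {
      r <- realized(res)
      dev <- abs(r - identity[lv_names])
      if (all(is.na(dev) | dev <= tol)) break
      # adjust cumulative event budgets multiplicatively
      cum_new <- cum
      for (k in seq_along(lv_names)) {
        lvn <- lv_names[k]
        if (is.na(r[lvn]) || dev[lvn] <= tol) next
        target_div <- (100 - identity[[lvn]]) / 100
        real_div <- (100 - r[[lvn]]) / 100
        if (real_div <= 0) real_div <- 0.5 / L
        cum_new[k] <- cum[k] * target_div / real_div
      }
      cum <- adjust_cum(cum_new)
      e_lv <- events_from_cum(cum)
      res <- build(e_lv)
      if (it == 10L) {
        r <- realized(res)
        dev <- abs(r - identity[lv_names])
        if (!all(is.na(dev) | dev <= 2 * tol)) {
          stop("identity calibration did not converge", call. = FALSE)
        }
      }
    }

    ids <- names(res$seqs)
    lab <- do.call(rbind, res$labels[ids])
    aln <- alignment(ids, vapply(res$seqs, paste0, character(1), collapse = ""))
    labels <- data.frame(id = ids, genus = lab[, 1], species = lab[, 2],
                         type = lab[, 3], subtype = lab[, 4],
                         stringsAsFactors = FALSE)
    tree <- try(ape::read.tree(text = res$newick), silent = TRUE)
    if (inherits(tree, "try-error")) tree <- NULL
    list(alignment = aln, labels = labels, tree = tree)
  })
}

#' Simulate a surveillance cohort with set prevalences
#'
#' Independent Bernoulli infection status per individual, with a
#' level-specific prevalence; deterministic given `seed`.
#'
#' @param levels Data frame with columns `level`, `n`, `prevalence`.
#' @param factor Name for the grouping column in the output.
#' @param seed RNG seed.
#' @return A cohort data frame: `individual`, the grouping column,
#'   `status`.
#' @export
generate_cohort <- function(levels, factor = "group", seed = 1L) {
  if (!all(c("level", "n", "prevalence") %in% names(levels))) {
    stop("levels needs columns level, n, prevalence", call. = FALSE)
  }
  if (any(levels$n < 1L)) stop("every level needs n >= 1", call. = FALSE)
  if (any(levels$prevalence < 0 | levels$prevalence > 1)) {
    stop("prevalence must be in [0,1]", call. = FALSE)
  }
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(levels)), function(i) {
      n <- levels$n[i]
      st <- ifelse(stats::rbinom(n, 1, levels$prevalence[i]) == 1,
                   "positive", "negative")
      df <- data.frame(
        individual = sprintf("%s_%03d", levels$level[i], seq_len(n)),
        g = levels$level[i], status = st, stringsAsFactors = FALSE
      )
      names(df)[2] <- factor
      df
    })
    do.call(rbind, rows)
  })
}
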