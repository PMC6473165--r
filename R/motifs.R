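# IUPAC nucleotide ambiguity expansions (subset used by the built-ins plus
# the full standard set, so user-supplied patterns can use any code).
IUPAC_NT <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")

#' The hydrophobic amino-acid class used in Walker-motif consensi
#'
#' The source consensi use an unnamed hydrophobic class (written \eqn{\Phi});
#' this package defines it as the Kyte-Doolittle-positive set
#' `{A, V, L, I, M, F, W, Y, C}`.  Override per pattern via the `phi`
#' argument of [motif_pattern()].
#' @export
PHI_HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W", "Y", "C")

#' Compile a degenerate consensus into a motif pattern
#'
#' Pattern syntax:
#' \itemize{
#'   \item plain letters match themselves (IUPAC ambiguity codes are
#'     expanded for nucleotide patterns; `N` is the nucleotide wildcard);
#'   \item `X` is the amino-acid wildcard (any of the 20 residues);
#'   \item `[TS]` or `[T/S]` is an explicit alternative class;
#'   \item `~` (or the Greek letter Phi) is the hydrophobic class;
#'   \item `{m,n}` is a variable spacer of between `m` and `n` wildcard
#'     positions.
#' }
#' An `N` in a scanned sequence matches nothing (conservative: ambiguous
#' input never produces a hit).
#'
#' @param name Pattern name.
#' @param pattern Consensus string in the syntax above.
#' @param alphabet `"nt"` or `"aa"`.
#' @param phi Residue set for the hydrophobic class.
#' @return An object of class `motif_pattern`.
#' @examples
#' motif_pattern("tata", "TATAWAW", "nt")
#' motif_pattern("walker_b", "~~DD", "aa")
#' @export
motif_pattern <- function(name, pattern, alphabet = c("nt", "aa"),
                          phi = PHI_HYDROPHOBIC) {
  alphabet <- match.arg(alphabet)
  stopifnot_scalar_string(pattern, "pattern")
  elements <- list()
  i <- 1L
  n <- nchar(pattern)
  push <- function(el) elements[[length(elements) + 1L]] <<- el
  while (i <= n) {
    c1 <- substr(pattern, i, i)
    if (c1 == "[") {
      j <- regexpr("]", substr(pattern, i, n), fixed = TRUE)
      if (j < 0) stop("unterminated [ in pattern ", name, call. = FALSE)
      inner <- substr(pattern, i + 1L, i + j - 2L)
      set <- setdiff(seq_chars(toupper(inner)), "/")
      push(list(type = "class", set = set))
      i <- i + j
    } else if (c1 == "{") {
      j <- regexpr("}", substr(pattern, i, n), fixed = TRUE)
      if (j < 0) stop("unterminated { in pattern ", name, call. = FALSE)
      inner <- substr(pattern, i + 1L, i + j - 2L)
      mm <- as.integer(strsplit(inner, ",", fixed = TRUE)[[1]])
      if (length(mm) == 1L) mm <- c(mm, mm)
      if (mm[1] > mm[2]) stop("spacer min > max in pattern ", name, call. = FALSE)
      push(list(type = "spacer", min = mm[1], max = mm[2]))
      i <- i + j
    } else if (c1 == "~" || c1 == "Φ") {
      if (alphabet != "aa") stop("hydrophobic class is amino-acid only", call. = FALSE)
      push(list(type = "class", set = phi))
      i <- i + 1L
    } else {
      ch <- toupper(c1)
      set <- if (alphabet == "nt") {
        if (is.null(IUPAC_NT[[ch]])) stop("unknown nt code '", ch, "'", call. = FALSE)
        IUPAC_NT[[ch]]
      } else {
        if (ch == "X") AA_LETTERS
        else if (!(ch %in% AA_LETTERS)) stop("unknown aa '", ch, "'", call. = FALSE)
        else ch
      }
      push(list(type = "class", set = set))
      i <- i + 1L
    }
  }
  if (!any(vapply(elements, function(e) e$type == "class", logical(1)))) {
    stop("pattern must contain at least one non-spacer element", call. = FALSE)
  }
  structure(list(name = name, alphabet = alphabet, pattern = pattern,
                 elements = elements),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s (%s): %s\n", x$name, x$alphabet, x$pattern))
  invisible(x)
}

# minimal and maximal match lengths of a compiled pattern
pattern_span <- function(p) {
  lens <- vapply(p$elements, function(e) {
    if (e$type == "spacer") c(e$min, e$max) else c(1L, 1L)
  }, integer(2))
  c(min = sum(lens[1, ]), max = sum(lens[2, ]))
}

#' The built-in avian papillomavirus motif catalogue
#'
#' The 15 degenerate consensi characterized across avian papillomavirus
#' genomes: the typical (`ACCNNNNNNGGT`) and atypical (`ACCNNNNGGT`)
#' E2-binding sites, the TATA box (`TATAWAW`), the late polyadenylation
#' signal (`ATTAAA`/`AATAAA`, encoded `AWTAAA`), the E6/E7 zinc-binding
#' domain (two `CXXC` pairs separated by 39--42 residues), the pRb-binding
#' domain (`LXCXE`), the Walker A/B/C helicase motifs (generic
#' `GXXXXGK[T/S]`, hydrophobic-`DD`, hydrophobic-`[T/S][T/S]N`) plus the
#' avian-conserved Walker A form (`GXXDSGK[T/S]`), the E2 DNA-binding
#' domain (`GXTXQ[L/V]KTIRXR`), and the L2 furin cleavage (`RX[K/R]R`),
#' transmembrane (`GXXXG`), sorting-nexin-17-binding (`[F/Y]XNPX[F/Y]`) and
#' syntaxin-18-binding (`D[Q/K]IL[Q/K]`) motifs.
#'
#' @param phi Hydrophobic residue set (see [PHI_HYDROPHOBIC]).
#' @return A named list of [motif_pattern()] objects.
#' @export
builtin_motifs <- function(phi = PHI_HYDROPHOBIC) {
  defs <- list(
    e2bs_typical = list("ACCNNNNNNGGT", "nt"),
    e2bs_atypical = list("ACCNNNNGGT", "nt"),
    tata_box = list("TATAWAW", "nt"),
    polya_site = list("AWTAAA", "nt"),
    e6_zinc = list("CXXC{39,42}CXXC", "aa"),
    e7_prb = list("LXCXE", "aa"),
    walker_a = list("GXXXXGK[TS]", "aa"),
    walker_a_apv = list("GXXDSGK[TS]", "aa"),
    walker_b = list("~~DD", "aa"),
    walker_c = list("~[TS][TS]N", "aa"),
    e2_dbd = list("GXTXQ[LV]KTIRXR", "aa"),
    furin = list("RX[KR]R", "aa"),
    gxxxg_tm = list("GXXXG", "aa"),
    snx17 = list("[FY]XNPX[FY]", "aa"),
    syntaxin18 = list("D[QK]IL[QK]", "aa")
  )
  out <- lapply(names(defs), function(nm) {
    motif_pattern(nm, defs[[nm]][[1]], defs[[nm]][[2]], phi = phi)
  })
  names(out) <- names(defs)
  out
}

#' Scan a sequence for a motif pattern
#'
#' All matches are reported, including overlapping ones; for patterns with
#' a variable spacer, every distinct (start, spacer length) combination is
#' a separate row.  On circular nucleotide sequences matches may span the
#' origin (reported with `end` mapped back into `1..L` and `wraps = TRUE`);
#' a match never exceeds the sequence length.
#'
#' @param seq Sequence string (nucleotide or protein, matching the
#'   pattern's alphabet).
#' @param pattern A [motif_pattern()].
#' @param circular Treat the sequence as circular (nucleotide only).
#' @return A data frame with `start`, `end`, `wraps`, `spacer` (`NA` for
#'   fixed-length patterns) and `match`.
#' @export
scan_motif <- function(seq, pattern, circular = FALSE) {
  stopifnot_scalar_string(seq, "seq")
  seq <- toupper(seq)
  L <- nchar(seq)
  ch <- seq_chars(if (circular) paste0(seq, seq) else seq)
  span <- pattern_span(pattern)
  max_start <- if (circular) L else L - span[["min"]] + 1L
  els <- pattern$elements
  res_start <- integer(0); res_end <- integer(0); res_spacer <- integer(0)

  match_from <- function(pos, ei, spacer_used) {
    # returns list of c(end, spacer) for matches of elements ei.. starting at pos
    if (ei > length(els)) return(list(c(pos - 1L, spacer_used)))
    e <- els[[ei]]
    if (e$type == "class") {
      if (pos > length(ch) || !(ch[pos] %in% e$set)) return(list())
      return(match_from(pos + 1L, ei + 1L, spacer_used))
    }
    out <- list()
    for (k in e$min:e$max) {
      if (pos + k - 1L > length(ch)) break
      out <- c(out, match_from(pos + k, ei + 1L, k))
    }
    out
  }

  if (max_start >= 1L) {
    for (s in seq_len(max_start)) {
      # quick first-class prefilter
      first <- els[[1]]
      if (first$type == "class" && !(ch[s] %in% first$set)) next
      ms <- match_from(s, 1L, NA_integer_)
      for (m in ms) {
        e <- m[1]
        if (e - s + 1L > L) next  # circular: match longer than the sequence
        res_start <- c(res_start, s)
        res_end <- c(res_end, e)
        res_spacer <- c(res_spacer, m[2])
      }
    }
  }
  if (length(res_start) == 0L) {
    return(data.frame(start = integer(), end = integer(), wraps = logical(),
                      spacer = integer(), match = character(),
                      stringsAsFactors = FALSE))
  }
  wraps <- res_end > L
  match_txt <- substring(paste0(ch, collapse = ""), res_start, res_end)
  data.frame(
    start = res_start,
    end = ifelse(wraps, res_end - L, res_end),
    wraps = wraps,
    spacer = res_spacer,
    match = match_txt,
    stringsAsFactors = FALSE
  )
}

#' Count E2-binding sites in the long control region
#'
#' Counts distinct hit start positions of the typical (`ACCNNNNNNGGT`) and
#' atypical (`ACCNNNNGGT`) E2-binding sites within the LCR (the two cannot
#' match the same site because their spacers differ).  With
#' `genome_wide = TRUE` the whole circular genome is scanned instead.
#'
#' @param ann A `genome_annotation` with a located LCR.
#' @param g The annotated [circular_genome()].
#' @param genome_wide Count over the whole genome rather than the LCR only.
#' @return Named integer vector `c(typical = , atypical = )`.
#' @export
count_e2bs <- function(ann, g, genome_wide = FALSE) {
  pats <- builtin_motifs()
  if (genome_wide) {
    circ <- g$topology == "circular"
    nt <- length(unique(scan_motif(g$seq, pats$e2bs_typical, circ)$start))
    na <- length(unique(scan_motif(g$seq, pats$e2bs_atypical, circ)$start))
    return(c(typical = nt, atypical = na))
  }
  if (is.null(ann$lcr)) stop("annotation has no LCR", call. = FALSE)
  s <- subsequence(g, ann$lcr)
  c(typical = length(unique(scan_motif(s, pats$e2bs_typical)$start)),
    atypical = length(unique(scan_motif(s, pats$e2bs_atypical)$start)))
}

# which built-in patterns belong to which protein
ORF_MOTIF_MAP <- list(
  E6 = c("e6_zinc"),
  E7 = c("e7_prb", "e6_zinc"),
  E1 = c("walker_a", "walker_a_apv", "walker_b", "walker_c"),
  E2 = c("e2_dbd"),
  L2 = c("furin", "gxxxg_tm", "snx17", "syntaxin18")
)

#' Profile protein motifs across the annotated ORFs
#'
#' Scans each named ORF's protein for the motifs characteristic of it
#' (E6: zinc domain; E7: pRb-binding and zinc; E1: Walker A/B/C; E2:
#' DNA-binding domain; L2: furin, transmembrane, SNX17- and
#' syntaxin-18-binding), returning both the individual hits and a
#' presence/absence table suitable for tabulation across genomes.
#'
#' @param ann A `genome_annotation`.
#' @param g The annotated [circular_genome()].
#' @param phi Hydrophobic residue set.
#' @return A list with `hits` (data frame: `orf`, `pattern`, `start`,
#'   `end`, `match`, amino-acid coordinates) and `presence` (data frame:
#'   `orf`, `pattern`, `present`).
#' @export
profile_proteins <- function(ann, g, phi = PHI_HYDROPHOBIC) {
  pats <- builtin_motifs(phi = phi)
  hits <- list(); presence <- list()
  for (orf_name in names(ORF_MOTIF_MAP)) {
    row <- ann$orfs[ann$orfs$name == orf_name, , drop = FALSE]
    if (nrow(row) == 0L) next
    prot <- sub("\\*$", "", row$protein[1])
    for (pn in ORF_MOTIF_MAP[[orf_name]]) {
      h <- scan_motif(prot, pats[[pn]])
      presence[[length(presence) + 1L]] <-
        data.frame(orf = orf_name, pattern = pn, present = nrow(h) > 0L,
                   stringsAsFactors = FALSE)
      if (nrow(h) > 0L) {
        hits[[length(hits) + 1L]] <-
          data.frame(orf = orf_name, pattern = pn, start = h$start,
                     end = h$end, match = h$match, stringsAsFactors = FALSE)
      }
    }
  }
  list(
    hits = if (length(hits)) do.call(rbind, hits)
    else data.frame(orf = character(), pattern = character(),
                    start = integer(), end = integer(),
                    match = character(), stringsAsFactors = FALSE),
    presence = do.call(rbind, presence)
  )
}
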