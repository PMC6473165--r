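#' Find open reading frames on the forward strand
#'
#' Scans the single ORF-bearing strand of a (possibly circular) genome for
#' maximal start-codon-to-stop reading frames.  On circular sequences ORFs
#' may wrap the origin; an ORF's total span (including the stop codon) never
#' exceeds the genome length.  For each stop codon only the longest ORF
#' (earliest in-frame start) is reported, and ORFs are returned longest
#' first (ties by smaller start).
#'
#' @param g A [circular_genome()].
#' @param min_aa Minimum protein length in amino acids (excluding the stop).
#' @param allow_gtg Also accept GTG start codons (used only for the L1
#'   alternative-start search; see [detect_l1_start()]).
#' @return A data frame with one row per ORF: `name` (always
#'   `"unassigned"`), `start`, `end`, `wraps_origin`, `strand`,
#'   `start_codon`, `aa_len` and `protein`.
#' @export
find_orfs <- function(g, min_aa = 60L, allow_gtg = FALSE) {
  if (min_aa < 1L) stop("min_aa must be >= 1", call. = FALSE)
  L <- g$length
  if (L < 3L) stop("genome shorter than 3 nt", call. = FALSE)
  circular <- g$topology == "circular"
  S <- if (circular) paste0(g$seq, g$seq) else g$seq
  nS <- nchar(S)
  starts_allowed <- if (allow_gtg) c("ATG", "GTG") else "ATG"
  last_start <- if (circular) L else L - 2L

  # all codons at every offset of the (doubled) sequence
  pos <- seq_len(nS - 2L)
  cods <- substring(S, pos, pos + 2L)
  is_stop <- cods %in% STOP_CODONS
  # next in-frame stop at or after each position (same residue class mod 3),
  # by a backward last-observation-carried fill within each residue class
  next_stop <- rep(NA_integer_, length(pos))
  for (r in 0:2) {
    ii <- seq.int(r + 1L, length(pos), by = 3L)
    z <- rev(ifelse(is_stop[ii], ii, NA_integer_))
    f <- cummax(ifelse(is.na(z), 0L, seq_along(z)))
    filled <- ifelse(f == 0L, NA_integer_, z[pmax(f, 1L)])
    next_stop[ii] <- rev(filled)
  }

  start_pos <- which(cods %in% starts_allowed)
  start_pos <- start_pos[start_pos <= last_start]
  hits <- list()
  for (i in start_pos) {
    j <- next_stop[i]
    if (is.na(j) || j == i) next
    if (j + 2L - i + 1L > L) next  # span may not exceed the genome
    aa_len <- (j - i) / 3L
    if (aa_len < min_aa) next
    end_raw <- j + 2L
    stop_key <- if (circular) ((end_raw - 1L) %% L) + 1L else end_raw
    key <- as.character(stop_key)
    prev <- hits[[key]]
    if (is.null(prev) || aa_len > prev$aa_len) {
      hits[[key]] <- list(start = i, end_raw = end_raw, aa_len = aa_len,
                          start_codon = cods[i])
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(name = character(), start = integer(), end = integer(),
                      wraps_origin = logical(), strand = character(),
                      start_codon = character(), aa_len = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(hits, function(h) {
    wraps <- h$end_raw > L
    nt <- substr(S, h$start, h$end_raw)
    data.frame(
      name = "unassigned",
      start = h$start,
      end = if (wraps) h$end_raw - L else h$end_raw,
      wraps_origin = wraps,
      strand = "+",
      start_codon = h$start_codon,
      aa_len = h$aa_len,
      protein = translate(nt, gtg_start = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  df <- df[order(-df$aa_len, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Score candidate splice-acceptor sites
#'
#' A lightweight stand-in for neural-network splice-site prediction: every
#' `AG` dinucleotide is scored by the pyrimidine (C/T) content of the
#' `window` nucleotides immediately upstream of the `A`, as a fraction in
#' \[0, 1\].  On circular genomes the upstream context wraps the origin.
#'
#' @param g A [circular_genome()].
#' @param window Upstream context length in nt (default 12).
#' @return A data frame with `pos` (1-based position of the acceptor's `G`)
#'   and `score`.
#' @export
find_splice_acceptors <- function(g, window = 12L) {
  if (window < 4L) stop("window must be >= 4", call. = FALSE)
  L <- g$length
  circular <- g$topology == "circular"
  ch <- seq_chars(g$seq)
  pyr <- as.integer(ch %in% c("C", "T"))
  if (circular) {
    nxt <- c(ch[-1L], ch[1L])
    a_pos <- which(ch == "A" & nxt == "G")
    cs <- cumsum(c(0L, pyr, pyr))  # doubled for wrap-around context
    counts <- cs[a_pos + L] - cs[a_pos + L - window]
    data.frame(pos = (a_pos %% L) + 1L, score = counts / window)
  } else {
    a_pos <- which(ch[-L] == "A" & ch[-1L] == "G")
    cs <- cumsum(c(0L, pyr))
    lo <- pmax(1L, a_pos - window)
    counts <- cs[a_pos] - cs[lo]
    denom <- pmax(a_pos - lo, 1L)
    data.frame(pos = a_pos + 1L, score = counts / denom)
  }
}

# circular distance from position a forward to position b (0 when equal)
circ_fwd <- function(from, to, L) ((to - from) %% L)

# positions (1-based, mod L) covered by a codon starting at `s`
codon_positions <- function(s, L) (((s - 1L):(s + 1L)) %% L) + 1L

#' Select the L1 ORF among candidate late ORFs
#'
#' In papillomaviruses the L1 start codon typically overlaps the stop codon
#' of L2 and lies immediately downstream of a strong splice acceptor.  The
#' selection prefers, in order: an ATG-start candidate whose start codon
#' shares at least one nucleotide with the L2 stop codon and has an acceptor
#' within `acceptor_window` nt upstream; then a GTG candidate meeting the
#' same tests (the puffin-virus configuration, where GTG substitutes the
#' typical ATG); then overlap without an acceptor.  Within a tier longer
#' ORFs win, ties broken by smaller start.  If no candidate overlaps the L2
#' stop, the longest candidate downstream of L2 is chosen and flagged
#' (`fallback = TRUE`).
#'
#' @param g A [circular_genome()].
#' @param l2 A one-row ORF data frame (the assigned L2), as returned by
#'   [find_orfs()].
#' @param candidates ORF data frame of L1 candidates.
#' @param acceptors Data frame from [find_splice_acceptors()].
#' @param acceptor_window Maximum distance (nt) from acceptor `G` to the L1
#'   start (default 10).
#' @return A one-row ORF data frame with `name = "L1"` and an extra
#'   `fallback` column.
#' @export
detect_l1_start <- function(g, l2, candidates, acceptors,
                            acceptor_window = 10L) {
  L <- g$length
  if (nrow(candidates) == 0L) stop("L1 not found", call. = FALSE)
  l2_end_raw <- if (l2$wraps_origin) l2$end + L else l2$end
  stop_pos <- (((l2_end_raw - 3L):(l2_end_raw - 1L)) %% L) + 1L

  tiers <- integer(nrow(candidates))
  for (k in seq_len(nrow(candidates))) {
    s <- candidates$start[k]
    start_pos <- codon_positions(s, L)
    overlaps <- length(intersect(start_pos, stop_pos)) >= 1L
    has_acc <- FALSE
    if (nrow(acceptors) > 0L) {
      d <- vapply(acceptors$pos, function(p) circ_fwd(p, s, L), numeric(1))
      has_acc <- any(d >= 1 & d <= acceptor_window)
    }
    atg <- candidates$start_codon[k] == "ATG"
    tiers[k] <- if (overlaps && has_acc && atg) 1L
    else if (overlaps && has_acc) 2L
    else if (overlaps && atg) 3L
    else if (overlaps) 4L
    else 5L
  }
  if (all(tiers == 5L)) {
    # fallback: longest candidate downstream of L2
    down <- candidates
    if (nrow(down) == 0L) stop("L1 not found", call. = FALSE)
    down <- down[order(-down$aa_len, down$start), , drop = FALSE]
    out <- down[1, , drop = FALSE]
    out$name <- "L1"; out$fallback <- TRUE
    rownames(out) <- NULL
    return(out)
  }
  best_tier <- min(tiers[tiers < 5L])
  pool <- candidates[tiers == best_tier, , drop = FALSE]
  pool <- pool[order(-pool$aa_len, pool$start), , drop = FALSE]
  out <- pool[1, , drop = FALSE]
  out$name <- "L1"; out$fallback <- FALSE
  rownames(out) <- NULL
  out
}

# Is interval (s1,e1,w1) nested inside (s2,e2,w2) on a circle of length L?
nested_in <- function(s1, e1, w1, s2, e2, w2, L) {
  off1 <- circ_fwd(s2, s1, L)
  len1 <- if (w1) L - s1 + 1L + e1 else e1 - s1 + 1L
  len2 <- if (w2) L - s2 + 1L + e2 else e2 - s2 + 1L
  off1 + len1 <= len2
}

#' Assign papillomavirus gene names to ORFs
#'
#' Names the characteristic avian-papillomavirus ORF complement by genome
#' layout alone (no homology search).  E1 is the longest core ORF; E2 the
#' next core ORF downstream; L2 the core ORF downstream of E2; L1 is chosen
#' by [detect_l1_start()] (which admits the GTG alternative start); E6 and
#' E7 are the accessory ORFs between the end of L1 and the start of E1 in
#' genome order (E6 first; a lone accessory ORF is taken as E7, the
#' configuration of the parrot virus that lacks E6); E9 is an accessory ORF
#' nested within E1 in a different reading frame.  The long control region
#' (LCR) is the gap between the L1 stop and the first early ORF; the short
#' non-coding region (NCR) is the gap between E2 and L2 when it is at least
#' 2 nt (gaps over 50 nt are still reported but flagged atypical).  The LCR
#' (and NCR) are scanned for E2-binding sites (typical `ACCNNNNNNGGT` and
#' atypical `ACCNNNNGGT`), the TATA box and polyadenylation signals.
#'
#' Missing core ORFs yield explicit `NA` markers, not silent omission.
#'
#' @param g A [circular_genome()].
#' @param orfs ORF data frame from [find_orfs()] at the accessory threshold
#'   (ATG starts only).
#' @param min_aa_core Minimum length (aa) for the four core ORFs.
#' @param acceptor_window Passed to [detect_l1_start()].
#' @param gtg_candidates Optional data frame of GTG-start core ORFs,
#'   consulted as L1 candidates only when no ATG candidate overlaps the L2
#'   stop (see [annotate_genome()]).
#' @return An object of class `genome_annotation`.
#' @export
assign_orf_names <- function(g, orfs, min_aa_core = 300L,
                             acceptor_window = 10L, gtg_candidates = NULL) {
  if (nrow(orfs) < 4L) stop("need at least 4 ORFs above threshold", call. = FALSE)
  L <- g$length
  orfs$fallback <- FALSE
  cores <- orfs[orfs$aa_len >= min_aa_core, , drop = FALSE]
  atg_cores <- cores[cores$start_codon == "ATG", , drop = FALSE]
  absent <- character(0)

  pick <- function(df, i) df[i, , drop = FALSE]
  used_key <- character(0)
  key_of <- function(row) paste(row$start, row$end, sep = ":")

  # E1: longest ATG core
  e1 <- NULL
  if (nrow(atg_cores) > 0L) {
    e1 <- pick(atg_cores[order(-atg_cores$aa_len, atg_cores$start), ], 1)
    e1$name <- "E1"; used_key <- c(used_key, key_of(e1))
  } else absent <- c(absent, "E1")

  next_core_downstream <- function(from_end) {
    rem <- cores[!(paste(cores$start, cores$end, sep = ":") %in% used_key), ,
                 drop = FALSE]
    rem <- rem[rem$start_codon == "ATG" | TRUE, , drop = FALSE]
    if (nrow(rem) == 0L) return(NULL)
    d <- vapply(rem$start, function(s) circ_fwd(from_end, s, L), numeric(1))
    pick(rem[order(d), , drop = FALSE], 1)
  }

  e2 <- NULL
  if (!is.null(e1)) {
    e2 <- next_core_downstream(e1$end)
    if (!is.null(e2)) { e2$name <- "E2"; used_key <- c(used_key, key_of(e2)) }
    else absent <- c(absent, "E2")
  } else absent <- c(absent, "E2")

  l2 <- NULL
  if (!is.null(e2)) {
    l2 <- next_core_downstream(e2$end)
    if (!is.null(l2)) { l2$name <- "L2"; used_key <- c(used_key, key_of(l2)) }
    else absent <- c(absent, "L2")
  } else absent <- c(absent, "L2")

  l1 <- NULL
  if (!is.null(l2)) {
    cand <- cores[!(paste(cores$start, cores$end, sep = ":") %in% used_key), ,
                  drop = FALSE]
    # admit GTG candidates only when no ATG candidate overlaps the L2 stop
    if (!is.null(gtg_candidates) && nrow(gtg_candidates) > 0L) {
      l2_end_raw <- if (l2$wraps_origin) l2$end + L else l2$end
      stop_pos <- (((l2_end_raw - 3L):(l2_end_raw - 1L)) %% L) + 1L
      atg_overlap <- nrow(cand) > 0L && any(vapply(cand$start, function(s) {
        length(intersect(codon_positions(s, L), stop_pos)) >= 1L
      }, logical(1)))
      if (!atg_overlap) {
        assigned_ends <- vapply(Filter(Negate(is.null), list(e1, e2, l2)),
                                `[[`, integer(1), "end")
        extra <- gtg_candidates[!(gtg_candidates$end %in% assigned_ends), ,
                                drop = FALSE]
        extra$fallback <- FALSE
        if (nrow(extra) > 0L) cand <- rbind(cand, extra)
      }
    }
    if (nrow(cand) > 0L) {
      acc <- find_splice_acceptors(g)
      l1 <- detect_l1_start(g, l2, cand, acc, acceptor_window)
      used_key <- c(used_key, key_of(l1))
    } else absent <- c(absent, "L1")
  } else absent <- c(absent, "L1")

  # accessory ORFs
  acc_orfs <- orfs[orfs$aa_len < min_aa_core & orfs$start_codon == "ATG", ,
                   drop = FALSE]

  # E9: nested within E1, different frame
  e9 <- NULL
  if (!is.null(e1) && nrow(acc_orfs) > 0L) {
    inside <- vapply(seq_len(nrow(acc_orfs)), function(i) {
      r <- acc_orfs[i, ]
      nested_in(r$start, r$end, r$wraps_origin,
                e1$start, e1$end, e1$wraps_origin, L) &&
        circ_fwd(e1$start, r$start, L) %% 3L != 0L
    }, logical(1))
    if (any(inside)) {
      e9 <- pick(acc_orfs[inside, , drop = FALSE][
        order(-acc_orfs$aa_len[inside], acc_orfs$start[inside]), , drop = FALSE], 1)
      e9$name <- "E9"
    }
  }

  # E6/E7: accessory ORFs in the arc from L1 end to E1 start
  e6 <- NULL; e7 <- NULL
  if (!is.null(e1) && nrow(acc_orfs) > 0L) {
    arc_from <- if (!is.null(l1)) l1$end else e1$end
    arc_len <- circ_fwd(arc_from, e1$start, L)
    in_arc <- vapply(seq_len(nrow(acc_orfs)), function(i) {
      r <- acc_orfs[i, ]
      if (!is.null(e9) && key_of(r) == key_of(e9)) return(FALSE)
      off <- circ_fwd(arc_from, r$start, L)
      len <- if (r$wraps_origin) L - r$start + 1L + r$end else r$end - r$start + 1L
      off > 0L && off + len <= arc_len + 1L
    }, logical(1))
    arc <- acc_orfs[in_arc, , drop = FALSE]
    if (nrow(arc) > 0L) {
      d <- vapply(arc$start, function(s) circ_fwd(arc_from, s, L), numeric(1))
      arc <- arc[order(d), , drop = FALSE]
      if (nrow(arc) >= 2L) {
        # two longest, kept in genome order
        keep <- order(-arc$aa_len)[1:2]
        keep <- sort(keep)
        e6 <- pick(arc, keep[1]); e6$name <- "E6"
        e7 <- pick(arc, keep[2]); e7$name <- "E7"
      } else {
        e7 <- pick(arc, 1); e7$name <- "E7"
        absent <- c(absent, "E6")
      }
    } else absent <- c(absent, "E6", "E7")
  }
  if (is.null(e9)) absent <- c(absent, "E9")

  named <- do.call(rbind, Filter(Negate(is.null), list(e6, e7, e1, e9, e2, l2, l1)))
  rownames(named) <- NULL

  # non-coding regions
  lcr <- NULL; ncr <- NULL; ncr_atypical <- FALSE
  first_early <- if (!is.null(e6)) e6 else if (!is.null(e7)) e7 else e1
  if (!is.null(l1) && !is.null(first_early)) {
    gap <- circ_fwd(l1$end, first_early$start, L) - 1L
    if (gap >= 1L) {
      s <- (l1$end %% L) + 1L
      e <- ((first_early$start - 2L) %% L) + 1L
      lcr <- interval(s, e, wraps_origin = s > e)
    }
  }
  if (!is.null(e2) && !is.null(l2)) {
    gap <- circ_fwd(e2$end, l2$start, L) - 1L
    if (gap >= 2L) {
      s <- (e2$end %% L) + 1L
      e <- ((l2$start - 2L) %% L) + 1L
      ncr <- interval(s, e, wraps_origin = s > e)
      ncr_atypical <- gap > 50L
    }
  }

  # regulatory motifs in the non-coding regions
  pats <- builtin_motifs()
  scan_region <- function(iv, pattern) {
    if (is.null(iv)) return(integer(0))
    s <- subsequence(g, iv)
    h <- scan_motif(s, pattern, circular = FALSE)
    if (nrow(h) == 0L) return(integer(0))
    ((iv$start + h$start - 2L) %% L) + 1L  # map back to genome coordinates
  }
  tata <- scan_region(lcr, pats$tata_box)
  polya <- sort(c(scan_region(lcr, pats$polya_site),
                  scan_region(ncr, pats$polya_site)))
  e2bs_typ <- scan_region(lcr, pats$e2bs_typical)
  e2bs_atyp <- scan_region(lcr, pats$e2bs_atypical)

  rotation <- if (!is.null(e6)) e6$start - 1L
  else if (!is.null(e7)) e7$start - 1L else NA_integer_

  structure(
    list(
      genome_id = g$id,
      orfs = named,
      absent = unique(absent),
      lcr = lcr,
      ncr = ncr,
      ncr_atypical = ncr_atypical,
      tata = tata,
      polya = polya,
      e2bs_typical = e2bs_typ,
      e2bs_atypical = e2bs_atyp,
      rotation_to_canonical = rotation,
      l1_fallback = if (!is.null(l1)) isTRUE(l1$fallback) else NA
    ),
    class = "genome_annotation"
  )
}

#' Annotate a papillomavirus genome
#'
#' Convenience wrapper: runs [find_orfs()] at the accessory threshold (with
#' GTG starts admitted so the L1 alternative-start rule can apply) and
#' [assign_orf_names()].
#'
#' @inheritParams assign_orf_names
#' @param min_aa_acc Minimum accessory ORF length in aa.
#' @param allow_gtg Admit GTG as an L1 start when no overlapping ATG exists.
#' @export
annotate_genome <- function(g, min_aa_core = 300L, min_aa_acc = 60L,
                            allow_gtg = TRUE, acceptor_window = 10L) {
  orfs <- find_orfs(g, min_aa = min_aa_acc, allow_gtg = FALSE)
  gtg_candidates <- NULL
  if (allow_gtg) {
    # GTG starts are consulted only as L1 candidates, and only core-sized
    # ones; ORFs that merely extend an ATG ORF upstream keep their stop and
    # are filtered against assigned genes inside the L1 step
    all_gtg <- find_orfs(g, min_aa = min_aa_core, allow_gtg = TRUE)
    gtg_candidates <- all_gtg[all_gtg$start_codon == "GTG", , drop = FALSE]
  }
  assign_orf_names(g, orfs, min_aa_core = min_aa_core,
                   acceptor_window = acceptor_window,
                   gtg_candidates = gtg_candidates)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s\n", x$genome_id))
  o <- x$orfs
  for (i in seq_len(nrow(o))) {
    cat(sprintf("  %-3s %6d..%-6d %s%s %4d aa\n", o$name[i], o$start[i], o$end[i],
                o$start_codon[i], if (o$wraps_origin[i]) "~" else " ",
                o$aa_len[i]))
  }
  if (length(x$absent)) cat("  absent:", paste(x$absent, collapse = ", "), "\n")
  if (!is.null(x$lcr)) cat(sprintf("  LCR %d..%d  E2BS typical/atypical: %d/%d\n",
                                   x$lcr$start, x$lcr$end,
                                   length(x$e2bs_typical), length(x$e2bs_atypical)))
  if (!is.null(x$ncr)) cat(sprintf("  NCR %d..%d%s\n", x$ncr$start, x$ncr$end,
                                   if (x$ncr_atypical) " (atypical length)" else ""))
  invisible(x)
}

#' Write an annotation as GFF3
#'
#' Feature types: `gene`/`CDS` for ORFs, `region` for LCR and NCR,
#' `misc_feature` for regulatory motifs.  Coordinates are 1-based inclusive;
#' a feature that wraps the origin is split into two lines sharing an `ID`.
#'
#' @param ann A `genome_annotation`.
#' @param g The annotated [circular_genome()].
#' @param path Output path.
#' @export
write_gff3 <- function(ann, g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", g$id, g$length), con)
  L <- g$length
  emit <- function(type, start, end, wraps, id, extra = "") {
    attrs <- paste0("ID=", id, extra)
    if (!wraps) {
      writeLines(paste(g$id, "avianpv", type, start, end, ".", "+", ".", attrs,
                       sep = "\t"), con)
    } else {
      writeLines(paste(g$id, "avianpv", type, start, L, ".", "+", ".", attrs,
                       sep = "\t"), con)
      writeLines(paste(g$id, "avianpv", type, 1, end, ".", "+", ".", attrs,
                       sep = "\t"), con)
    }
  }
  o <- ann$orfs
  for (i in seq_len(nrow(o))) {
    emit("gene", o$start[i], o$end[i], o$wraps_origin[i],
         paste0("gene-", o$name[i]), paste0(";Name=", o$name[i]))
    emit("CDS", o$start[i], o$end[i], o$wraps_origin[i],
         paste0("cds-", o$name[i]),
         paste0(";Parent=gene-", o$name[i],
                ";start_codon=", o$start_codon[i]))
  }
  if (!is.null(ann$lcr)) {
    emit("region", ann$lcr$start, ann$lcr$end, ann$lcr$wraps_origin, "LCR")
  }
  if (!is.null(ann$ncr)) {
    emit("region", ann$ncr$start, ann$ncr$end, ann$ncr$wraps_origin, "NCR")
  }
  motif_sets <- list(TATA = ann$tata, polyA = ann$polya,
                     E2BS_typical = ann$e2bs_typical,
                     E2BS_atypical = ann$e2bs_atypical)
  widths <- c(TATA = 7L, polyA = 6L, E2BS_typical = 12L, E2BS_atypical = 10L)
  for (nm in names(motif_sets)) {
    ps <- motif_sets[[nm]]
    for (k in seq_along(ps)) {
      s <- ps[k]; e_raw <- s + widths[[nm]] - 1L
      wraps <- e_raw > L
      emit("misc_feature", s, if (wraps) e_raw - L else e_raw, wraps,
           paste0(nm, "-", k), paste0(";Name=", nm))
    }
  }
  invisible(path)
}
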