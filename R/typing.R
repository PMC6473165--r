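#' Construct a multiple sequence alignment
#'
#' Rows are equal-length gapped nucleotide sequences over `A,C,G,T,N,-`.
#'
#' @param ids Unique sequence identifiers.
#' @param seqs Gapped sequences (same length).
#' @return An object of class `msa` with fields `ids`, `seqs` and `mat`
#'   (character matrix, one row per sequence).
#' @export
alignment <- function(ids, seqs) {
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length", call. = FALSE)
  if (length(ids) < 2L) stop("an alignment needs at least 2 rows", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)
  seqs <- toupper(seqs)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("rows have unequal lengths", call. = FALSE)
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) stop("invalid characters in row ", which(bad)[1], call. = FALSE)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- ids
  structure(list(ids = ids, seqs = seqs, mat = mat), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", length(x$ids), ncol(x$mat)))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Like [read_fasta()] but admitting the gap character `-`.
#'
#' @param path Path to an aligned FASTA file.
#' @return An [alignment()].
#' @export
read_alignment <- function(path) {
  recs <- parse_fasta(path, alphabet_regex = "[^ACGTN-]")
  alignment(vapply(recs, `[[`, character(1), "id"),
            vapply(recs, `[[`, character(1), "seq"))
}

#' Subset alignment columns
#'
#' @param aln An [alignment()].
#' @param cols Column indices (may repeat, e.g. a bootstrap resample).
#' @export
alignment_columns <- function(aln, cols) {
  m <- aln$mat[, cols, drop = FALSE]
  alignment(aln$ids, apply(m, 1, paste0, collapse = ""))
}

# rows of an alignment as character vectors
aln_row <- function(aln, i) aln$mat[i, ]

as_chars <- function(x) {
  if (is.character(x) && length(x) == 1L) seq_chars(toupper(x)) else toupper(x)
}

#' Proportion of differing sites (p-distance)
#'
#' Computed over comparable columns only: positions where either sequence
#' has a gap or an ambiguous base are excluded pairwise.
#'
#' @param a,b Equal-length gapped sequences (strings or character vectors).
#' @return Proportion in \[0, 1\].
#' @export
p_distance <- function(a, b) {
  a <- as_chars(a); b <- as_chars(b)
  if (length(a) != length(b)) stop("sequences differ in length", call. = FALSE)
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0L) stop("no comparable positions", call. = FALSE)
  sum(a[ok] != b[ok]) / n
}

#' Pairwise percent-identity matrix
#'
#' `100 * (1 - p_distance)` for every pair; diagonal 100.
#'
#' @param aln An [alignment()].
#' @return A symmetric matrix of percent identities with an attribute
#'   `level = "pairwise"`.
#' @export
identity_matrix <- function(aln) {
  n <- length(aln$ids)
  m <- matrix(100, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- 100 * (1 - p_distance(aln$mat[i, ], aln$mat[j, ]))
      m[i, j] <- v; m[j, i] <- v
    }
  }
  attr(m, "level") <- "pairwise"
  m
}

#' Group-mean percent identities
#'
#' Entry (G, H) is `100 * (1 - mean p-distance)` over all cross pairs with
#' one member in each group; the diagonal uses within-group pairs (100 for
#' a singleton group).  This is the "inverse of the mean p-distance between
#' groups" convention used for papillomavirus type comparisons.
#'
#' @param aln An [alignment()].
#' @param groups Named character vector mapping sequence id to group label.
#' @return A symmetric matrix of group-mean identities with attribute
#'   `level = "group_mean"`.
#' @export
group_mean_identity <- function(aln, groups) {
  if (!all(aln$ids %in% names(groups))) {
    stop("groups must cover every sequence id", call. = FALSE)
  }
  gl <- unique(unname(groups[aln$ids]))
  if (any(is.na(gl)) || any(!nzchar(gl))) stop("empty group label", call. = FALSE)
  m <- matrix(NA_real_, length(gl), length(gl), dimnames = list(gl, gl))
  idx <- split(seq_along(aln$ids), unname(groups[aln$ids]))
  for (gi in seq_along(gl)) {
    for (gj in gi:length(gl)) {
      ii <- idx[[gl[gi]]]; jj <- idx[[gl[gj]]]
      if (gi == gj) {
        if (length(ii) == 1L) { m[gi, gj] <- 100; next }
        pairs <- utils::combn(ii, 2)
        ds <- apply(pairs, 2, function(p) p_distance(aln$mat[p[1], ], aln$mat[p[2], ]))
      } else {
        ds <- as.vector(outer(ii, jj, Vectorize(function(i, j) {
          p_distance(aln$mat[i, ], aln$mat[j, ])
        })))
      }
      v <- 100 * (1 - mean(ds))
      m[gi, gj] <- v; m[gj, gi] <- v
    }
  }
  attr(m, "level") <- "group_mean"
  m
}

#' Demarcation thresholds for papillomavirus taxonomy
#'
#' L1 nucleotide identity thresholds: two viruses are the same subtype
#' above `subtype_min` (default 99%), the same type above `type_min`
#' (default 90%), the same species above `species_min` (70%) and the same
#' genus above `genus_min` (60%).  Comparisons are strict (`>`) by default,
#' matching the ">90%" / ">99%" phrasing of the classification rules.
#'
#' @param subtype_min,type_min,species_min,genus_min Percent thresholds.
#' @param strict_inequality Use `>` (default) rather than `>=`.
#' @export
demarcation_config <- function(subtype_min = 99, type_min = 90,
                               species_min = 70, genus_min = 60,
                               strict_inequality = TRUE) {
  if (!(genus_min < species_min && species_min < type_min &&
        type_min < subtype_min)) {
    stop("thresholds must satisfy genus < species < type < subtype", call. = FALSE)
  }
  structure(list(subtype_min = subtype_min, type_min = type_min,
                 species_min = species_min, genus_min = genus_min,
                 strict_inequality = strict_inequality),
            class = "demarcation_config")
}

#' Taxonomic rank implied by an L1 identity
#'
#' @param identity Percent identity in \[0, 100\].
#' @param cfg A [demarcation_config()].
#' @return One of `"same_subtype"`, `"same_type"`, `"same_species"`,
#'   `"same_genus"`, `"different_genus"`.
#' @examples
#' assign_rank(99.5)  # same_subtype
#' assign_rank(90)    # same_species under strict thresholds
#' @export
assign_rank <- function(identity, cfg = demarcation_config()) {
  if (identity < 0 || identity > 100) stop("identity outside [0,100]", call. = FALSE)
  exceeds <- function(thr) {
    if (cfg$strict_inequality) identity > thr else identity >= thr
  }
  if (exceeds(cfg$subtype_min)) "same_subtype"
  else if (exceeds(cfg$type_min)) "same_type"
  else if (exceeds(cfg$species_min)) "same_species"
  else if (exceeds(cfg$genus_min)) "same_genus"
  else "different_genus"
}

# connected components of the graph linking pairs with identity above `thr`,
# restricted to `members`; returns list of integer vectors, ordered by first
# member
linkage_components <- function(im, members, thr, strict) {
  adj <- if (strict) im[members, members, drop = FALSE] > thr
  else im[members, members, drop = FALSE] >= thr
  n <- length(members)
  comp <- rep(NA_integer_, n)
  nc <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    nc <- nc + 1L
    queue <- s
    comp[s] <- nc
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- nc
      queue <- c(queue, nb)
    }
  }
  lapply(seq_len(nc), function(k) members[comp == k])
}

# complete-linkage components via hclust at the same threshold
complete_components <- function(im, members, thr, strict) {
  n <- length(members)
  if (n == 1L) return(list(members))
  d <- stats::as.dist(100 - im[members, members, drop = FALSE])
  hc <- stats::hclust(d, method = "complete")
  h <- 100 - thr
  cut_h <- if (strict) h - 1e-9 else h + 1e-9
  grp <- stats::cutree(hc, h = cut_h)
  lapply(seq_len(max(grp)), function(k) members[grp == k])
}

#' Cluster sequences into nested genus/species/type/subtype partitions
#'
#' Applies the demarcation cascade from genus down to subtype.  At each
#' level, clusters are formed within their parent cluster by single-linkage
#' (default: two sequences are linked when their identity exceeds the
#' level's threshold, so a sequence joins a type if it is close enough to
#' any member), giving nested partitions by construction.  Cluster numbers
#' are deterministic: ordered by each cluster's first member in input
#' order.
#'
#' @param aln An [alignment()].
#' @param cfg A [demarcation_config()].
#' @param linkage `"single"` (default) or `"complete"`.
#' @return A data frame with columns `id`, `genus`, `species`, `type`,
#'   `subtype` (integer labels, nested left to right).
#' @export
cluster_types <- function(aln, cfg = demarcation_config(),
                          linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  im <- identity_matrix(aln)
  n <- length(aln$ids)
  comp_fun <- if (linkage == "single") linkage_components else complete_components
  thresholds <- c(genus = cfg$genus_min, species = cfg$species_min,
                  type = cfg$type_min, subtype = cfg$subtype_min)
  out <- data.frame(id = aln$ids, stringsAsFactors = FALSE)
  parents <- list(seq_len(n))
  for (lev in names(thresholds)) {
    labels <- rep(NA_integer_, n)
    counter <- 0L
    children <- list()
    for (p in parents) {
      comps <- comp_fun(im, p, thresholds[[lev]], cfg$strict_inequality)
      # deterministic: order components by first member
      comps <- comps[order(vapply(comps, min, integer(1)))]
      for (cc in comps) {
        counter <- counter + 1L
        labels[cc] <- counter
        children[[length(children) + 1L]] <- cc
      }
    }
    out[[lev]] <- labels
    parents <- children
  }
  out
}

#' Type and subtype frequencies from a cluster assignment
#'
#' Tabulates, for each type cluster, the share of sequences in each of its
#' subtypes (the "frequency" column of a typing table).
#'
#' @param ct Output of [cluster_types()].
#' @return A data frame with `type`, `subtype`, `k`, `n` (type size) and
#'   `pct` (half-up rounded to 1 decimal).
#' @export
type_frequencies <- function(ct) {
  out <- list()
  for (tp in sort(unique(ct$type))) {
    sub <- ct[ct$type == tp, , drop = FALSE]
    n <- nrow(sub)
    for (st in sort(unique(sub$subtype))) {
      k <- sum(sub$subtype == st)
      out[[length(out) + 1L]] <- data.frame(
        type = tp, subtype = st, k = k, n = n,
        pct = round_half_up(100 * k / n, 1)
      )
    }
  }
  do.call(rbind, out)
}

#' Synonymous / non-synonymous substitution summary
#'
#' Compares two aligned coding sequences codon by codon.  Columns where
#' either sequence has a gap are removed pairwise (gaps are assumed
#' codon-aligned); the first `frame_offset` remaining columns are trimmed.
#' A substitution is synonymous iff the codon pair containing it translates
#' identically; when a codon differs at more than one position and the
#' translations differ, all its substitutions count as non-synonymous.
#' Codons containing ambiguous bases are excluded.
#'
#' @param a,b Aligned coding sequences (strings or character vectors).
#' @param frame_offset Columns to trim before the first complete codon.
#' @return A list with `n_sub`, `n_syn`, `n_nonsyn` and `identity_pct`.
#' @export
substitution_summary <- function(a, b, frame_offset = 0L) {
  a <- as_chars(a); b <- as_chars(b)
  if (length(a) != length(b)) stop("sequences differ in length", call. = FALSE)
  keep <- a != "-" & b != "-"
  a <- a[keep]; b <- b[keep]
  if (frame_offset > 0L) { a <- a[-seq_len(frame_offset)]; b <- b[-seq_len(frame_offset)] }
  if (length(a) %% 3L != 0L) {
    stop("ungapped length not divisible by 3 after frame_offset trim", call. = FALSE)
  }
  nt <- c("A", "C", "G", "T")
  n_sub <- 0L; n_syn <- 0L; n_nonsyn <- 0L; n_comp <- 0L
  code <- genetic_code_table()
  for (i in seq.int(1L, length(a), 3L)) {
    ca <- a[i:(i + 2L)]; cb <- b[i:(i + 2L)]
    if (!all(ca %in% nt) || !all(cb %in% nt)) next
    n_comp <- n_comp + 3L
    d <- sum(ca != cb)
    if (d == 0L) next
    n_sub <- n_sub + d
    same_aa <- identical(unname(code[paste0(ca, collapse = "")]),
                         unname(code[paste0(cb, collapse = "")]))
    if (same_aa) n_syn <- n_syn + d else n_nonsyn <- n_nonsyn + d
  }
  if (n_comp == 0L) stop("no comparable codons", call. = FALSE)
  list(n_sub = n_sub, n_syn = n_syn, n_nonsyn = n_nonsyn,
       identity_pct = 100 * (1 - n_sub / n_comp))
}

#' Simple global pairwise alignment
#'
#' A bundled Needleman-Wunsch-style global aligner (match +1, mismatch -1,
#' linear gap -2) for self-contained use; it is a convenience, not a
#' replacement for a production multiple aligner.  Externally produced
#' alignments can be supplied to every other function via
#' [read_alignment()].
#'
#' @param a,b Ungapped nucleotide strings.
#' @param ids Identifiers for the two rows.
#' @return An [alignment()] of the two gapped sequences.
#' @export
align_global <- function(a, b, ids = c("a", "b")) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2
  )
  alignment(ids, c(as.character(Biostrings::alignedPattern(pa)),
                   as.character(Biostrings::alignedSubject(pa))))
}
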