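#' Construct a circular (or linear) genome
#'
#' The basic sequence container used throughout the package.  Papillomavirus
#' genomes are circular double-stranded DNA of roughly 5.7--8.6 kb; the
#' single stored strand is the one carrying all open reading frames, which in
#' avian papillomaviruses lie on the same strand.
#'
#' @param id Sequence identifier.
#' @param seq Nucleotide sequence over `A,C,G,T,N` (case-insensitive; `U` is
#'   normalized to `T`).
#' @param topology `"circular"` or `"linear"`.
#' @return An object of class `circular_genome` with fields `id`, `seq`
#'   (upper case), `topology` and `length`.
#' @examples
#' g <- circular_genome("g1", "acgtacgt", "circular")
#' g$length
#' @export
circular_genome <- function(id, seq, topology = c("linear", "circular")) {
  stopifnot_scalar_string(id, "id")
  stopifnot_scalar_string(seq, "seq")
  topology <- match.arg(topology)
  seq <- toupper(seq)
  seq <- gsub("U", "T", seq, fixed = TRUE)
  if (nchar(seq) == 0L) stop("sequence must be non-empty", call. = FALSE)
  bad <- regmatches(seq, regexpr("[^ACGTN]", seq))
  if (length(bad) > 0L) {
    stop("invalid character '", bad, "' in sequence '", id, "'", call. = FALSE)
  }
  structure(
    list(id = id, seq = seq, topology = topology, length = nchar(seq)),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf(
    "<circular_genome> %s: %d nt, %s\n  %s%s\n",
    x$id, x$length, x$topology,
    substr(x$seq, 1, 60), if (x$length > 60) "..." else ""
  ))
  invisible(x)
}

#' Genomic interval (1-based, inclusive)
#'
#' Coordinates follow the GenBank convention: 1-based and inclusive at both
#' ends.  On circular sequences an interval may wrap the origin, in which
#' case it runs from `start` to the sequence end and continues from position
#' 1 to `end`.
#'
#' @param start,end 1-based inclusive positions.
#' @param wraps_origin Does the interval cross the origin of a circular
#'   sequence?
#' @return An object of class `genome_interval`.
#' @export
interval <- function(start, end, wraps_origin = FALSE) {
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end < 1L) stop("interval positions must be >= 1", call. = FALSE)
  if (!wraps_origin && start > end) {
    stop("start > end in a non-wrapping interval", call. = FALSE)
  }
  structure(list(start = start, end = end, wraps_origin = isTRUE(wraps_origin)),
            class = "genome_interval")
}

#' @export
print.genome_interval <- function(x, ...) {
  cat(sprintf("[%d..%d]%s\n", x$start, x$end,
              if (x$wraps_origin) " (wraps origin)" else ""))
  invisible(x)
}

#' Length spanned by an interval on a parent sequence
#'
#' @param iv A [interval()].
#' @param parent_length Length of the parent sequence (needed for wrapping
#'   intervals).
#' @export
span_length <- function(iv, parent_length = NULL) {
  if (!iv$wraps_origin) return(iv$end - iv$start + 1L)
  if (is.null(parent_length)) stop("parent_length required for wrapping interval")
  parent_length - iv$start + 1L + iv$end
}

#' Extract the bases spanned by an interval
#'
#' For a wrapping interval on a circular genome the suffix from `start` to
#' the end of the sequence is concatenated with the prefix up to `end`.
#'
#' @param g A [circular_genome()].
#' @param iv A [interval()].
#' @return A nucleotide string.
#' @examples
#' g <- circular_genome("g", "ACGTAC", "circular")
#' subsequence(g, interval(5, 2, wraps_origin = TRUE))  # "ACAC"
#' @export
subsequence <- function(g, iv) {
  L <- g$length
  if (iv$start > L || iv$end > L) stop("interval out of bounds", call. = FALSE)
  if (!iv$wraps_origin) return(substr(g$seq, iv$start, iv$end))
  if (g$topology != "circular") {
    stop("wrapping interval on a linear sequence", call. = FALSE)
  }
  paste0(substr(g$seq, iv$start, L), substr(g$seq, 1L, iv$end))
}

#' Rotate a circular genome so that `offset + 1` becomes position 1
#'
#' @param g A circular [circular_genome()].
#' @param offset Number of leading bases moved to the end (0 = no change).
#' @export
rotate_genome <- function(g, offset) {
  if (g$topology != "circular") stop("can only rotate a circular genome", call. = FALSE)
  offset <- as.integer(offset) %% g$length
  if (offset == 0L) return(g)
  circular_genome(
    g$id,
    paste0(substr(g$seq, offset + 1L, g$length), substr(g$seq, 1L, offset)),
    "circular"
  )
}

# Shared FASTA parser.  `alphabet_regex` names the characters allowed in
# sequence lines (after upper-casing and U->T); violations are reported with
# the 1-based file line number.
parse_fasta <- function(path, alphabet_regex = "[^ACGTN]") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) < length(lines)]
  if (length(lines) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- grep("^>", lines)
  if (length(headers) == 0L) {
    stop("malformed FASTA (no header) at line 1 of ", path, call. = FALSE)
  }
  if (headers[1] != 1L) {
    stop("malformed FASTA: sequence before first header at line 1 of ", path,
         call. = FALSE)
  }
  recs <- vector("list", length(headers))
  bounds <- c(headers, length(lines) + 1L)
  for (k in seq_along(headers)) {
    h <- sub("^>", "", lines[headers[k]])
    body_lines <- seq.int(headers[k] + 1L, bounds[k + 1L] - 1L)
    body_lines <- body_lines[body_lines <= length(lines)]
    if (length(body_lines) == 0L) {
      stop("malformed FASTA: record with no sequence at line ", headers[k],
           " of ", path, call. = FALSE)
    }
    body <- character(length(body_lines))
    for (j in seq_along(body_lines)) {
      ln <- toupper(gsub("\\s", "", lines[body_lines[j]]))
      ln <- gsub("U", "T", ln, fixed = TRUE)
      if (grepl(alphabet_regex, ln)) {
        stop("malformed FASTA: invalid sequence character at line ",
             body_lines[j], " of ", path, call. = FALSE)
      }
      body[j] <- ln
    }
    id <- sub("\\s.*$", "", h)
    recs[[k]] <- list(id = id, header = h, seq = paste0(body, collapse = ""))
  }
  recs
}

#' Read genomes from a FASTA file
#'
#' One record per FASTA entry.  Sequences are upper-cased and `U` characters
#' normalized to `T`.  A `topology=circular` token anywhere in the header
#' marks the record circular; the default is linear.
#'
#' @param path Path to a FASTA file.
#' @return A named list of [circular_genome()] objects.
#' @export
read_fasta <- function(path) {
  recs <- parse_fasta(path, alphabet_regex = "[^ACGTN]")
  out <- lapply(recs, function(r) {
    topo <- if (grepl("\\btopology=circular\\b", r$header)) "circular" else "linear"
    circular_genome(r$id, r$seq, topo)
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Write genomes to a FASTA file
#'
#' Circular records carry a `topology=circular` token in the header, so that
#' [read_fasta()] round-trips id, topology and sequence losslessly.
#'
#' @param genomes A list of [circular_genome()] objects (or a single one).
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "circular_genome")) genomes <- list(genomes)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genomes) {
    hdr <- if (g$topology == "circular") {
      paste0(">", g$id, " topology=circular")
    } else paste0(">", g$id)
    writeLines(hdr, con)
    starts <- seq.int(1L, g$length, by = width)
    writeLines(substring(g$seq, starts, pmin(starts + width - 1L, g$length)), con)
  }
  invisible(path)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Genetic-code lookup used by translate(); taken from the standard code.
genetic_code_table <- function() {
  Biostrings::GENETIC_CODE
}

#' Translate a nucleotide sequence
#'
#' Standard genetic code.  Stop codons are rendered `*`; codons containing
#' `N` translate to `X`.  When `gtg_start = TRUE` the first codon is treated
#' as an initiator and rendered `M` even for a GTG start (the alternative
#' initiation observed for the puffin virus L1).
#'
#' @param nt Nucleotide string, length divisible by 3.
#' @param gtg_start Treat the first codon as initiator methionine.
#' @return An amino-acid string (may include a trailing `*`).
#' @examples
#' translate("ATGAAATAA")          # "MK*"
#' translate("GTGAAA", gtg_start = TRUE)  # "MK"
#' @export
translate <- function(nt, gtg_start = FALSE) {
  stopifnot_scalar_string(nt, "nt")
  nt <- toupper(nt)
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("length not divisible by 3", call. = FALSE)
  if (n == 0L) return("")
  codons <- substring(nt, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
  code <- genetic_code_table()
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  if (gtg_start && codons[1] %in% c("ATG", "GTG")) aa[1] <- "M"
  paste0(aa, collapse = "")
}
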