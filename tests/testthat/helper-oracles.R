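# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# G statistic 2 * sum(o * log(o/e)) over a level-by-status table
g_stat_oracle <- function(k, n) {
  K <- sum(k); N <- sum(n)
  o <- cbind(k, n - k)
  e <- cbind(n * K / N, n * (N - K) / N)
  2 * sum(ifelse(o > 0, o * log(o / e), 0))
}

# brute-force motif matching: expand the pattern to all fixed spacer
# lengths, then test every window by per-position set membership
brute_motif_hits <- function(seq, pattern) {
  ch <- strsplit(toupper(seq), "")[[1]]
  spacer_idx <- which(vapply(pattern$elements, function(e) e$type == "spacer",
                             logical(1)))
  expand <- function(els) {
    si <- which(vapply(els, function(e) e$type == "spacer", logical(1)))
    if (length(si) == 0L) return(list(els))
    e <- els[[si[1]]]
    out <- list()
    wild <- if (pattern$alphabet == "nt") c("A", "C", "G", "T") else
      c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q",
        "R", "S", "T", "V", "W", "Y")
    for (k in e$min:e$max) {
      fill <- rep(list(list(type = "class", set = wild)), k)
      out <- c(out, expand(append(els[-si[1]], fill, after = si[1] - 1L)))
    }
    out
  }
  variants <- expand(pattern$elements)
  res <- NULL
  for (v in variants) {
    w <- length(v)
    if (w > length(ch)) next
    for (s in seq_len(length(ch) - w + 1L)) {
      ok <- TRUE
      for (q in seq_len(w)) {
        if (!(ch[s + q - 1L] %in% v[[q]]$set)) { ok <- FALSE; break }
      }
      if (ok) res <- rbind(res, c(start = s, end = s + w - 1L))
    }
  }
  if (is.null(res)) {
    return(data.frame(start = integer(), end = integer()))
  }
  res <- as.data.frame(res)
  unique(res[order(res$start, res$end), , drop = FALSE])
}

# brute-force ORF scan of a circular sequence via the doubled string
brute_orfs_circular <- function(seq, min_aa, allow_gtg = FALSE) {
  L <- nchar(seq)
  S <- paste0(seq, seq)
  ch <- strsplit(S, "")[[1]]
  stops <- c("TAA", "TAG", "TGA")
  starts <- if (allow_gtg) c("ATG", "GTG") else "ATG"
  found <- list()
  for (i in seq_len(L)) {
    cd <- paste0(ch[i:(i + 2L)], collapse = "")
    if (!(cd %in% starts)) next
    j <- i
    repeat {
      if (j + 2L > 2L * L || (j + 2L - i + 1L) > L) { j <- NA; break }
      cj <- paste0(ch[j:(j + 2L)], collapse = "")
      if (cj %in% stops && j > i) break
      j <- j + 3L
    }
    if (is.na(j)) next
    aa <- (j - i) / 3L
    if (aa < min_aa) next
    key <- as.character(((j + 2L - 1L) %% L) + 1L)
    if (is.null(found[[key]]) || aa > found[[key]]["aa"]) {
      found[[key]] <- c(start = i, end_raw = j + 2L, aa = aa)
    }
  }
  found
}

# least-squares branch fit of a distance matrix on a fixed topology;
# returns the residual sum of squares
ls_rss <- function(tree, D) {
  n <- length(tree$tip.label)
  pairs <- utils::combn(n, 2)
  # design: which edges lie on the path between each pair
  X <- matrix(0, ncol(pairs), nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    desc <- edge_tipset(tree, e)
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      # an edge lies on the i-j path iff it separates i from j
      X[p, e] <- as.integer(xor(i %in% desc, j %in% desc))
    }
  }
  y <- D[t(pairs)]
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

# tip indices below the child node of edge e (independent of ape::prop.part)
edge_tipset <- function(tree, e) {
  n <- length(tree$tip.label)
  child <- tree$edge[e, 2]
  if (child <= n) return(child)
  acc <- integer(0)
  stack <- child
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    acc <- c(acc, kids[kids <= n])
    stack <- c(stack, kids[kids > n])
  }
  sort(acc)
}

# all non-trivial bipartitions of an unrooted tree, as sorted tip-index sets
all_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    s <- edge_tipset(tree, e)
    if (length(s) > 1L && length(s) < n - 1L) out[[length(out) + 1L]] <- s
  }
  out
}

# do two labelings induce the same partition?
same_partition <- function(a, b) {
  identical(
    as.integer(factor(a, levels = unique(a))),
    as.integer(factor(b, levels = unique(b)))
  )
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
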