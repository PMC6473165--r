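#' Specify a nucleotide substitution distance model
#'
#' Supported models: raw proportion of differing sites (`"p"`), Kimura
#' 2-parameter (`"K2P"`) and Tamura-Nei (`"TN93"`).  `gamma_shape` applies
#' the standard gamma rate-heterogeneity correction (each logarithmic term
#' `-log(w)` of the closed form is replaced by `a * (w^(-1/a) - 1)`).
#' `prop_invariant` removes an externally estimated invariant-site fraction:
#' the observed mismatch proportions are rescaled by `1/(1 - p_inv)` and
#' the resulting distance by `(1 - p_inv)`.
#'
#' @param model `"p"`, `"K2P"` or `"TN93"`.
#' @param gamma_shape Positive gamma shape, or `NULL` for no correction.
#' @param prop_invariant Fraction in \[0, 1), or `NULL`.
#' @export
distance_model <- function(model = c("p", "K2P", "TN93"),
                           gamma_shape = NULL, prop_invariant = NULL) {
  model <- match.arg(model)
  if (!is.null(gamma_shape) && gamma_shape <= 0) {
    stop("gamma_shape must be > 0", call. = FALSE)
  }
  if (!is.null(prop_invariant)) {
    if (model == "p") stop("prop_invariant requires K2P or TN93", call. = FALSE)
    if (prop_invariant < 0 || prop_invariant >= 1) {
      stop("prop_invariant must be in [0,1)", call. = FALSE)
    }
  }
  structure(list(model = model, gamma_shape = gamma_shape,
                 prop_invariant = prop_invariant),
            class = "distance_model")
}

# -log(w), or its gamma-corrected analogue a*(w^(-1/a)-1); w <= 0 signals
# saturation
log_term <- function(w, a) {
  if (w <= 0) return(Inf)
  if (is.null(a)) -log(w) else a * (w^(-1 / a) - 1)
}

# mismatch composition of a comparable-site pair
pair_counts <- function(a, b) {
  nt <- c("A", "C", "G", "T")
  ok <- a %in% nt & b %in% nt
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L) stop("no comparable positions", call. = FALSE)
  diff <- a != b
  pur <- c("A", "G")
  ts_ag <- diff & a %in% pur & b %in% pur
  ts_ct <- diff & !(a %in% pur) & !(b %in% pur)
  q <- diff & !ts_ag & !ts_ct
  freqs <- (table(factor(a, nt)) + table(factor(b, nt))) / (2 * n)
  list(n = n, P1 = sum(ts_ag) / n, P2 = sum(ts_ct) / n, Q = sum(q) / n,
       freqs = as.numeric(freqs))
}

#' Model-based evolutionary distance between two aligned sequences
#'
#' Closed-form distances in substitutions per site.  K2P:
#' `d = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q))` with `P` the transition and
#' `Q` the transversion proportion.  TN93 uses the standard closed form
#' with separate purine and pyrimidine transition classes and base
#' frequencies estimated from the pair.  Saturated comparisons (a
#' non-positive logarithm argument) yield `Inf` with a warning rather than
#' `NaN`.
#'
#' @param a,b Equal-length gapped sequences (strings or character vectors);
#'   gap/ambiguous columns are excluded pairwise.
#' @param m A [distance_model()].
#' @return A non-negative distance (possibly `Inf` on saturation).
#' @export
model_distance <- function(a, b, m = distance_model("K2P")) {
  a <- as_chars(a); b <- as_chars(b)
  if (length(a) != length(b)) stop("sequences differ in length", call. = FALSE)
  pc <- pair_counts(a, b)
  pinv <- m$prop_invariant
  scale <- 1
  if (!is.null(pinv)) {
    scale <- 1 - pinv
    pc$P1 <- pc$P1 / scale; pc$P2 <- pc$P2 / scale; pc$Q <- pc$Q / scale
  }
  alpha <- m$gamma_shape
  d <- switch(
    m$model,
    p = pc$P1 + pc$P2 + pc$Q,
    K2P = {
      P <- pc$P1 + pc$P2; Q <- pc$Q
      0.5 * log_term(1 - 2 * P - Q, alpha) + 0.25 * log_term(1 - 2 * Q, alpha)
    },
    TN93 = {
      f <- pc$freqs  # A C G T
      gA <- f[1]; gC <- f[2]; gG <- f[3]; gT <- f[4]
      gR <- gA + gG; gY <- gC + gT
      if (gA * gG == 0 || gT * gC == 0) {
        stop("TN93 undefined: a purine or pyrimidine class is absent", call. = FALSE)
      }
      k1 <- 2 * gA * gG / gR
      k2 <- 2 * gT * gC / gY
      k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
      w1 <- 1 - pc$P1 / k1 - pc$Q / (2 * gR)
      w2 <- 1 - pc$P2 / k2 - pc$Q / (2 * gY)
      w3 <- 1 - pc$Q / (2 * gR * gY)
      k1 * log_term(w1, alpha) + k2 * log_term(w2, alpha) +
        k3 * log_term(w3, alpha)
    }
  )
  d <- d * scale
  if (!is.finite(d)) {
    warning("saturated comparison: distance set to Inf")
    return(Inf)
  }
  max(d, 0)
}

#' Pairwise distance matrix under a substitution model
#'
#' @param aln An [alignment()].
#' @param m A [distance_model()].
#' @return Symmetric matrix of distances with zero diagonal.
#' @export
distance_matrix <- function(aln, m = distance_model("K2P")) {
  n <- length(aln$ids)
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- model_distance(aln$mat[i, ], aln$mat[j, ], m)
      D[i, j] <- d; D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration.  Ties in the Q-criterion are broken by the
#' smallest `(i, j)` index pair in the current ordering, for determinism.
#' Negative branch lengths are clamped to zero with the deficit moved to
#' the adjacent branch of the joined pair.
#'
#' @param D Symmetric distance matrix with zero diagonal and at least 3
#'   labelled taxa.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  labels <- rownames(D) %||% paste0("t", seq_len(n))
  frag <- labels  # newick fragment per active node
  act <- seq_len(n)
  Dm <- D

  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }

  while (length(act) > 3L) {
    r <- length(act)
    sums <- rowSums(Dm)
    best <- NULL; bestq <- Inf
    for (i in seq_len(r - 1L)) {
      for (j in (i + 1L):r) {
        q <- (r - 2) * Dm[i, j] - sums[i] - sums[j]
        if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    li <- Dm[i, j] / 2 + (sums[i] - sums[j]) / (2 * (r - 2))
    lj <- Dm[i, j] - li
    ll <- clamp_pair(li, lj)
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], ll[1], frag[j], ll[2])
    dnew <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    act <- seq_len(r - 1L)
  }
  # final three nodes: closed three-point formulas
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], l1, frag[2], l2, frag[3], l3)
  ape::read.tree(text = nwk)
}

#' Neighbor-joining tree with nonparametric bootstrap support
#'
#' Alignment columns are resampled with replacement `n_reps` times; each
#' replicate distance matrix is re-estimated under the same model and a
#' replicate NJ tree built.  Support for each internal edge of the
#' point-estimate tree is the percentage of replicate trees containing the
#' same bipartition.  Column indices are drawn by a single seeded generator
#' in replicate order, so results are reproducible given `seed`.
#'
#' @param aln An [alignment()] of at least 4 sequences.
#' @param m A [distance_model()].
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @return A list with `tree` (point-estimate `phylo`, node labels carrying
#'   percent support) and `support` (data frame: `node`, `tips`,
#'   `support`).
#' @export
bootstrap_tree <- function(aln, m = distance_model("K2P"), n_reps = 100L,
                           seed = 1L) {
  n <- length(aln$ids)
  if (n < 4L) stop("bootstrap support undefined for fewer than 4 sequences",
                   call. = FALSE)
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  L <- ncol(aln$mat)
  point <- nj_tree(distance_matrix(aln, m))
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      nj_tree(distance_matrix(alignment_columns(aln, cols), m))
    })
  })
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / n_reps
  point$node.label <- as.character(round(support, 1))
  tips_of <- function(node) {
    paste(sort(ape::extract.clade(point, node)$tip.label), collapse = ",")
  }
  nodes <- seq_len(point$Nnode) + ape::Ntip(point)
  list(
    tree = point,
    support = data.frame(
      node = nodes,
      tips = vapply(nodes, tips_of, character(1)),
      support = support,
      stringsAsFactors = FALSE
    )
  )
}

#' Does a leaf set form a clade of an unrooted tree?
#'
#' True iff some edge of the unrooted tree bipartitions the leaves into
#' exactly the query set versus the rest (singletons are trivially
#' monophyletic).
#'
#' @param tree An `ape::phylo` tree.
#' @param leaves Character vector of tip labels (nonempty proper subset).
#' @return Logical.
#' @export
is_monophyletic <- function(tree, leaves) {
  tips <- tree$tip.label
  unknown <- setdiff(leaves, tips)
  if (length(unknown)) stop("unknown leaf: ", unknown[1], call. = FALSE)
  leaves <- unique(leaves)
  if (length(leaves) == 0L || length(leaves) >= length(tips)) {
    stop("leaves must be a nonempty proper subset", call. = FALSE)
  }
  if (length(leaves) == 1L) return(TRUE)
  parts <- ape::prop.part(tree)
  target <- sort(match(leaves, tips))
  comp <- sort(setdiff(seq_along(tips), target))
  for (p in parts) {
    sp <- sort(p)
    if (identical(sp, target) || identical(sp, comp)) return(TRUE)
  }
  FALSE
}

#' Write a tree to a Newick file
#'
#' Support values, when present as node labels, are written as internal
#' node labels.
#'
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
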