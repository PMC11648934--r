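#' Pairwise p-distance between aligned rows
#'
#' Fraction of mismatching sites among compared sites, where a site is
#' compared only if both rows carry a non-gap character there.
#'
#' @param a,b Equal-length gapped residue strings.
#' @return Mismatch fraction in \[0, 1\].
#' @export
p_distance <- function(a, b) {
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) stop("rows differ in length", call. = FALSE)
  keep <- ca != "-" & cb != "-"
  if (!any(keep)) stop("no compared sites (all-gap overlap)", call. = FALSE)
  mean(ca[keep] != cb[keep])
}

#' Poisson-correct a p-distance
#'
#' The multiple-hit correction `-log(1 - p)`. Saturated distances are
#' capped at `cap` before the transform (and flagged with a warning) so
#' the result stays finite.
#'
#' @param p Numeric vector of p-distances.
#' @param cap Saturation cap, default 0.95.
#' @return Corrected distances.
#' @export
poisson_distance <- function(p, cap = 0.95) {
  if (any(p < 0)) stop("p-distances must be nonnegative", call. = FALSE)
  if (any(p > cap)) {
    warning(sprintf("%d p-distance(s) capped at %.2f before Poisson correction",
                    sum(p > cap), cap), call. = FALSE)
    p <- pmin(p, cap)
  }
  -log(1 - p)
}

#' Distance matrix from an alignment
#'
#' Gap-rich columns are removed first (see [trim_columns()]), then
#' pairwise p-distances are computed on the surviving columns and,
#' optionally, Poisson-corrected. Trees for residue-typed families are
#' built from these distances.
#'
#' @param aln A [alignment()].
#' @param correction `"poisson"` (default) or `"p"` (uncorrected).
#' @param max_gap_frac Trimming threshold; `NULL` skips trimming.
#' @return Symmetric numeric matrix with row/column names.
#' @export
aln_distances <- function(aln, correction = c("poisson", "p"), max_gap_frac = 0.8) {
  correction <- match.arg(correction)
  if (!is.null(max_gap_frac)) aln <- trim_columns(aln, max_gap_frac)
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2) stop("need at least two sequences", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      keep <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(keep)) stop(sprintf("rows %s and %s share no compared sites",
                                   rownames(m)[i], rownames(m)[j]), call. = FALSE)
      d[i, j] <- d[j, i] <- mean(m[i, keep] != m[j, keep])
    }
  }
  if (correction == "poisson") {
    d[] <- suppressWarnings(poisson_distance(d))
    if (any(d == -log(1 - 0.95))) {
      warning("saturated p-distances capped at 0.95 before Poisson correction",
              call. = FALSE)
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with fully specified determinism: ties in
#' the Q criterion are broken by the smallest (i, j) pair in current node
#' order (leaves in input label order, joined nodes appended), and a
#' negative branch length is clamped to zero with the deficit moved to its
#' sibling branch so path lengths are preserved. On additive distances the
#' generating topology and branch lengths are recovered exactly. The tree
#' is unrooted and returned with the conventional trifurcating root.
#'
#' @param dm Symmetric numeric matrix with labelled rows/columns (or a
#'   `dist`), at least 3 labels.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  labels <- rownames(dm)
  if (is.null(labels) || is.null(colnames(dm))) stop("distance matrix must be labelled", call. = FALSE)
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-12)) || any(diag(dm) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal", call. = FALSE)
  }
  if (any(!is.finite(dm)) || any(dm < 0)) {
    stop("distances must be finite and nonnegative", call. = FALSE)
  }
  n <- length(labels)
  if (n < 3) stop("neighbor joining needs at least 3 labels", call. = FALSE)
  bad <- grepl("[(),:;\\[\\]' \t]", labels)
  if (any(bad)) stop("labels contain Newick metacharacters: ",
                     paste(labels[bad], collapse = ", "), call. = FALSE)

  # active nodes carried as Newick subtree strings
  sub <- labels
  d <- dm
  fmt <- function(x) sprintf("%.15g", x)
  while (length(sub) > 3) {
    r <- length(sub)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    hit <- which(Q <= qmin + abs(qmin) * 1e-12, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    bi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- d[i, j] - bi
    # clamp negatives, preserving the i-j path length
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- max(bi + bj, 0); bj <- 0 }
    new_sub <- sprintf("(%s:%s,%s:%s)", sub[i], fmt(bi), sub[j], fmt(bj))
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    sub <- c(sub[keep], new_sub)
    d <- d2
  }
  # final three-point resolution around the trifurcating root
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  lens <- pmax(c(la, lb, lc), 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[1], fmt(lens[1]),
                 sub[2], fmt(lens[2]), sub[3], fmt(lens[3]))
  ape::read.tree(text = nwk)
}

canonical_split <- function(taxa, all_leaves) {
  smallest <- min(all_leaves)
  side <- if (smallest %in% taxa) setdiff(all_leaves, taxa) else taxa
  sort(side)
}

#' Nontrivial bipartitions of an unrooted tree
#'
#' One leaf-set split per internal edge, canonicalized to the side not
#' containing the lexicographically smallest leaf. Trivial splits (a
#' single leaf versus the rest) are omitted.
#'
#' @param tree A `phylo` object (rooted trees are read as unrooted).
#' @return List of sorted character vectors.
#' @export
bipartitions <- function(tree) {
  leaves <- tree$tip.label
  n <- length(leaves)
  ntip <- length(leaves)
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(ntip))
  if (!length(internal)) return(list())
  desc <- phangorn::Descendants(tree, internal, type = "tips")
  splits <- list()
  seen <- character()
  for (k in seq_along(internal)) {
    side <- canonical_split(leaves[desc[[k]]], leaves)
    if (length(side) < 2 || length(side) > n - 2) next
    key <- paste(side, collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    splits[[length(splits) + 1L]] <- side
  }
  splits
}

#' Test monophyly of a leaf subset on an unrooted tree
#'
#' A subset is monophyletic when it (or its complement) forms one side of
#' a bipartition induced by some edge — the unrooted-tree criterion behind
#' statements like "the K-A type proteins form a monophyletic clade".
#' Singletons, complements of singletons and the full leaf set are
#' trivially monophyletic.
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector of leaf labels, nonempty subset of the
#'   tree's leaves.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, taxa) {
  leaves <- tree$tip.label
  taxa <- unique(as.character(taxa))
  if (!length(taxa)) stop("`taxa` must be nonempty", call. = FALSE)
  unknown <- setdiff(taxa, leaves)
  if (length(unknown)) stop("leaves not in tree: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  n <- length(leaves)
  if (length(taxa) %in% c(1L, n - 1L, n)) return(TRUE)
  target <- paste(canonical_split(taxa, leaves), collapse = "\r")
  keys <- vapply(bipartitions(tree), paste, "", collapse = "\r")
  target %in% keys
}

#' Distance to monophyly
#'
#' The minimum number of leaves that would have to be swapped in or out
#' for `taxa` to coincide with one side of an existing edge-induced split
#' (pendant edges included). Zero if and only if `taxa` is monophyletic;
#' reported alongside the strict verdict as an effect-size-style
#' diagnostic of *how far* from monophyly a residue type is.
#'
#' @inheritParams is_monophyletic
#' @return Nonnegative integer.
#' @export
monophyly_gap <- function(tree, taxa) {
  leaves <- tree$tip.label
  taxa <- unique(as.character(taxa))
  if (is_monophyletic(tree, taxa)) return(0L)
  sides <- c(bipartitions(tree), as.list(leaves), list(leaves))
  best <- length(leaves)
  for (s in sides) {
    comp <- setdiff(leaves, s)
    best <- min(best,
                length(setdiff(taxa, s)) + length(setdiff(s, taxa)),
                length(setdiff(taxa, comp)) + length(setdiff(comp, taxa)))
  }
  as.integer(best)
}
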