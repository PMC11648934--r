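# Brute-force oracles and random-input generators shared by the tests.

aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_protein <- function(len, gap_prob = 0, alphabet = aa_letters) {
  chars <- sample(alphabet, len, replace = TRUE)
  if (gap_prob > 0) chars[runif(len) < gap_prob] <- "-"
  paste(chars, collapse = "")
}

rand_seq_set <- function(n, len_range = c(5, 40), gap_prob = 0) {
  seqs <- vapply(seq_len(n), function(i) {
    rand_protein(sample(len_range[1]:len_range[2], 1), gap_prob)
  }, "")
  # guard against all-gap sequences
  seqs[!grepl("[A-Z]", seqs)] <- "MK"
  seq_set(sprintf("s%03d", seq_len(n)), seqs,
          descriptions = sprintf("random record %d", seq_len(n)))
}

rand_alignment <- function(n_rows, n_cols, gap_prob = 0.15) {
  m <- matrix(sample(aa_letters, n_rows * n_cols, replace = TRUE), n_rows)
  m[matrix(runif(n_rows * n_cols) < gap_prob, n_rows)] <- "-"
  # keep every row and column partially ungapped
  m[, colSums(m != "-") == 0] <- "A"
  m[rowSums(m != "-") == 0, 1] <- "A"
  alignment(seq_set(sprintf("r%02d", seq_len(n_rows)),
                    apply(m, 1, paste, collapse = "")))
}

# Exhaustive split enumeration: cut every edge of the (unrooted) tree and
# collect the leaf set on the child side, canonicalized like bipartitions().
brute_splits <- function(tree, keep_trivial = FALSE) {
  leaves <- tree$tip.label
  n <- length(leaves)
  edges <- tree$edge
  nodes <- sort(unique(as.vector(edges)))
  adj <- lapply(seq_len(max(nodes)), function(i) integer())
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  out <- list()
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    # BFS from b avoiding the edge back to a
    seen <- b
    queue <- b
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      if (v == b) nb <- setdiff(nb, a)
      nb <- setdiff(nb, seen)
      seen <- c(seen, nb)
      queue <- c(queue, nb)
    }
    side <- leaves[seen[seen <= n]]
    if (!keep_trivial && (length(side) < 2 || length(side) > n - 2)) next
    smallest <- min(leaves)
    if (smallest %in% side) side <- setdiff(leaves, side)
    out[[length(out) + 1L]] <- sort(side)
  }
  unique(out)
}

split_key <- function(sides) vapply(sides, paste, "", collapse = "\r")

# Monophyly by direct comparison against the exhaustively enumerated splits.
brute_monophyletic <- function(tree, taxa) {
  leaves <- tree$tip.label
  n <- length(leaves)
  if (length(taxa) %in% c(1L, n - 1L, n)) return(TRUE)
  smallest <- min(leaves)
  side <- if (smallest %in% taxa) sort(setdiff(leaves, taxa)) else sort(taxa)
  paste(side, collapse = "\r") %in% split_key(brute_splits(tree))
}

rand_unrooted_tree <- function(n_leaves, lengths = FALSE) {
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   br = if (lengths) function(k) runif(k, 0.1, 1) else NULL)
  tr$tip.label <- sprintf("t%02d", seq_len(n_leaves))
  tr
}
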