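test_that("column_of maps reference positions through gaps", {
  aln <- alignment(seq_set(c("r", "s"), c("MKAV", "MK-V")))
  expect_equal(column_of(aln, "r", 3), 3L)  # ungapped: col = pos
  aln2 <- alignment(seq_set("r", "M-KA"))
  expect_equal(column_of(aln2, "r", 2), 3L)  # gap skipped
  expect_error(column_of(aln2, "zz", 1), "reference id")
  expect_error(column_of(aln2, "r", 4), "beyond ungapped length")
})

test_that("column_of agrees with an ungapped scan on random rows", {
  set.seed(11)
  for (i in 1:200) {
    row <- rand_protein(sample(10:60, 1), gap_prob = 0.3)
    if (!grepl("[A-Z]", row)) row <- "MK"
    aln <- alignment(seq_set("ref", row))
    ungapped <- gsub("-", "", row)
    pos <- sample(nchar(ungapped), 1)
    col <- column_of(aln, "ref", pos)
    expect_identical(substr(row, col, col), substr(ungapped, pos, pos))
  }
})

test_that("trim_columns keeps exactly low-gap columns with provenance", {
  gap_free <- rand_alignment(4, 12, gap_prob = 0)
  tr <- trim_columns(gap_free, 0)
  expect_equal(tr$rows$seq, gap_free$rows$seq)
  expect_equal(tr$provenance, 1:12)

  aln <- alignment(seq_set(c("a", "b"), c("A-C", "A-C")))
  tr2 <- trim_columns(aln, 0)
  expect_equal(tr2$rows$seq, c("AC", "AC"))
  expect_equal(tr2$provenance, c(1L, 3L))

  expect_error(trim_columns(alignment(seq_set(c("a", "b"), c("A-", "-A"))), 0.2),
               "degenerate")
})

test_that("trim_columns matches per-column gap counting and is idempotent", {
  set.seed(12)
  for (i in 1:100) {
    aln <- rand_alignment(sample(2:8, 1), sample(5:30, 1), gap_prob = 0.3)
    thr <- runif(1)
    m <- do.call(rbind, strsplit(aln$rows$seq, ""))
    keep_oracle <- which(colMeans(m == "-") <= thr)
    if (!length(keep_oracle)) {
      expect_error(trim_columns(aln, thr), "degenerate")
      next
    }
    tr <- trim_columns(aln, thr)
    expect_equal(tr$provenance, keep_oracle)
    expect_false(is.unsorted(tr$provenance, strictly = TRUE))
    tr2 <- trim_columns(tr, thr)
    expect_equal(tr2$provenance, tr$provenance)
    expect_equal(tr2$rows$seq, tr$rows$seq)
  }
})

test_that("residues_at reads one column, gaps as '-'", {
  aln <- alignment(seq_set(c("a", "b"), c("MK", "M-")))
  expect_equal(residues_at(aln, 2), c(a = "K", b = "-"))
  expect_error(residues_at(aln, 3), "out of range")
  set.seed(13)
  aln2 <- rand_alignment(5, 20)
  m <- do.call(rbind, strsplit(aln2$rows$seq, ""))
  for (col in sample(20, 5)) {
    expect_equal(unname(residues_at(aln2, col)), unname(m[, col]))
  }
})

test_that("resolve_anchors composes mapping and lookup, flags trimmed anchors", {
  aln <- alignment(seq_set(c("ref", "x"), c("MKAV", "-QAV")))
  res <- resolve_anchors(aln, anchors("first", "ref", 1))
  expect_equal(res$first$column, 1L)
  expect_equal(res$first$residues, c(ref = "M", x = "-"))

  # anchor column trimmed away -> marked, not silently remapped
  aln2 <- alignment(seq_set(c("ref", "x", "y"), c("M-KA", "--KA", "--KA")))
  trimmed <- trim_columns(aln2, 0.5)   # drops columns 1 and 2
  res2 <- resolve_anchors(aln2, anchors(c("gone", "kept"), "ref", c(1, 2)),
                          trimmed = trimmed)
  expect_true(res2$gone$trimmed)
  expect_true(all(is.na(res2$gone$residues)))
  expect_equal(anchor_residue_table(res2)$gone, rep("trimmed", 3))
  expect_false(res2$kept$trimmed)
  expect_equal(res2$kept$trimmed_column, 1L)
  expect_equal(unname(res2$kept$residues), c("K", "K", "K"))

  expect_warning(resolve_anchors(aln, anchors("a1", "ref", 1, expected = "W")),
                 "expected")
})

test_that("anchor residues are invariant under gap-column insertion and trimming", {
  set.seed(14)
  for (i in 1:120) {
    aln <- rand_alignment(sample(3:6, 1), sample(8:25, 1), gap_prob = 0.2)
    ref <- aln$rows$id[1]
    ungapped_len <- nchar(gsub("-", "", aln$rows$seq[1]))
    pos <- sample(ungapped_len, 1)
    baseline <- residues_at(aln, column_of(aln, ref, pos))

    # insert all-gap columns at random positions
    m <- do.call(rbind, strsplit(aln$rows$seq, ""))
    at <- sort(sample(ncol(m) + 1, sample(1:4, 1), replace = TRUE))
    m2 <- m
    for (k in rev(at)) {
      m2 <- cbind(m2[, seq_len(k - 1), drop = FALSE],
                  matrix("-", nrow(m2), 1),
                  if (k <= ncol(m2)) m2[, k:ncol(m2), drop = FALSE])
    }
    aln_g <- alignment(seq_set(aln$rows$id, apply(m2, 1, paste, collapse = "")))
    expect_equal(residues_at(aln_g, column_of(aln_g, ref, pos)), baseline)

    # trimming the all-gap columns back out preserves the anchor
    trimmed <- trim_columns(aln_g, 0.99)
    res <- resolve_anchors(aln_g, anchors("a", ref, pos), trimmed = trimmed)
    expect_false(res$a$trimmed)
    expect_equal(res$a$residues, baseline)
  }
})
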