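test_that("p_distance counts mismatches over both-ungapped sites", {
  expect_equal(p_distance("MKAV", "MKAV"), 0)
  expect_equal(p_distance("AAAA", "AAAV"), 0.25)
  expect_equal(p_distance("A-KV", "AW-V"), 0)  # only cols 1 and 4 compared
  expect_error(p_distance("AA", "AAA"), "length")
  expect_error(p_distance("--A", "A--"), "compared sites")
  set.seed(41)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    a <- rand_protein(n, gap_prob = 0.2); b <- rand_protein(n, gap_prob = 0.2)
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    keep <- ca != "-" & cb != "-"
    if (!any(keep)) next
    expect_equal(p_distance(a, b), sum(ca[keep] != cb[keep]) / sum(keep))
  }
})

test_that("poisson_distance is -log(1-p), monotone, capped with warning", {
  expect_equal(poisson_distance(0), 0)
  expect_equal(poisson_distance(c(0.1, 0.5, 0.9)),
               c(0.105360515657826, 0.693147180559945, 2.30258509299405),
               tolerance = 1e-14)
  p <- seq(0, 0.9, by = 0.05)
  expect_false(is.unsorted(poisson_distance(p), strictly = TRUE))
  expect_warning(d <- poisson_distance(0.99), "capped")
  expect_equal(d, -log(1 - 0.95))
})

test_that("3-taxon neighbor joining solves the three-point formulas", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(tr$Nnode, 1L)
  cd <- ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(cd, dm, tolerance = 1e-12)  # lengths 1, 2, 3
})

test_that("neighbor joining is exact on additive 6-leaf distances", {
  set.seed(43)
  for (i in 1:50) {
    t0 <- rand_unrooted_tree(6, lengths = TRUE)
    dm <- ape::cophenetic.phylo(t0)
    tr <- nj_tree(dm)
    expect_equal(phangorn::RF.dist(ape::unroot(t0), tr), 0)
    cd <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
    expect_lt(max(abs(cd - dm)), 1e-9)
  }
})

test_that("neighbor joining ignores label order and matches the reference NJ", {
  set.seed(44)
  for (i in 1:15) {
    n <- sample(5:12, 1)
    t0 <- rand_unrooted_tree(n, lengths = TRUE)
    dm <- ape::cophenetic.phylo(t0)
    # add symmetric noise so distances are non-additive
    noise <- matrix(runif(n * n, 0, 0.05), n); noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    dmn <- dm + noise
    tr1 <- nj_tree(dmn)
    perm <- sample(n)
    tr2 <- nj_tree(dmn[perm, perm])
    expect_equal(phangorn::RF.dist(tr1, tr2), 0)
    # independent implementation agrees on the topology
    expect_equal(phangorn::RF.dist(tr1, ape::nj(dmn)), 0)
  }
  expect_error(nj_tree(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))),
               "at least 3")
})

test_that("negative NJ branch lengths are clamped to zero", {
  # classic non-additive configuration producing a negative estimate
  labs <- c("a", "b", "c", "d")
  dm <- matrix(c(0, 2, 2, 2,
                 2, 0, 2, 2,
                 2, 2, 0, 0.1,
                 2, 2, 0.1, 0), 4, dimnames = list(labs, labs))
  tr <- nj_tree(dm)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bipartitions enumerate internal edges, canonically", {
  tr <- read_newick("(a,b,(c,d));")
  sp <- bipartitions(tr)
  expect_equal(sp, list(c("c", "d")))

  # caterpillar on n leaves has n-3 nontrivial splits
  for (n in 5:8) {
    nwk <- paste0(paste(rep("(", n - 1), collapse = ""), "L01:1,L02:1)",
                  paste(sprintf(",L%02d:1)", 3:n), collapse = ""), ";")
    cat_tr <- read_newick(nwk)
    expect_equal(length(bipartitions(cat_tr)), n - 3)
  }

  set.seed(45)
  for (i in 1:50) {
    tr <- rand_unrooted_tree(sample(4:10, 1))
    got <- sort(split_key(bipartitions(tr)))
    want <- sort(split_key(brute_splits(tr)))
    expect_equal(got, want)
  }
})

test_that("monophyly is the bipartition criterion, symmetric in complement", {
  tr <- read_newick("(a,b,(c,d));")
  expect_true(is_monophyletic(tr, "a"))
  expect_true(is_monophyletic(tr, c("c", "d")))
  expect_false(is_monophyletic(tr, c("b", "c")))
  expect_true(is_monophyletic(tr, c("a", "b")))  # complement of {c,d}
  expect_error(is_monophyletic(tr, c("a", "zz")), "not in tree")
  expect_error(is_monophyletic(tr, character()), "nonempty")

  set.seed(46)
  for (i in 1:200) {
    tr <- rand_unrooted_tree(sample(4:10, 1))
    taxa <- sample(tr$tip.label, sample(length(tr$tip.label), 1))
    got <- is_monophyletic(tr, taxa)
    expect_identical(got, brute_monophyletic(tr, taxa))
    if (length(taxa) < length(tr$tip.label)) {
      expect_identical(got, is_monophyletic(tr, setdiff(tr$tip.label, taxa)))
    }
  }
})

test_that("monophyly_gap is zero iff monophyletic and counts mismatched leaves", {
  tr <- read_newick("((a,b),(c,d),(e,f));")
  expect_equal(monophyly_gap(tr, c("a", "b")), 0L)
  expect_equal(monophyly_gap(tr, c("a", "c")), 1L)  # one swap fixes it
  expect_equal(monophyly_gap(tr, c("a", "b", "c")), 1L)
  set.seed(47)
  for (i in 1:50) {
    tr <- rand_unrooted_tree(sample(5:10, 1))
    taxa <- sample(tr$tip.label, sample(length(tr$tip.label) - 1, 1))
    g <- monophyly_gap(tr, taxa)
    expect_identical(g == 0L, is_monophyletic(tr, taxa))
  }
})
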