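mk_quant <- function(...) {
  rows <- list(...)
  quant_table(do.call(rbind, lapply(rows, function(r) {
    data.frame(sample = r[[1]], probe = r[[2]], replicate = as.integer(r[[3]]),
               intensity = as.numeric(r[[4]]),
               fraction = if (length(r) > 4) r[[5]] else "total")
  })))
}

test_that("relative_levels divides by the same-replicate reference lane", {
  q <- mk_quant(list("ref", "baxL", 1, 2), list("ref", "baxL", 2, 4),
                list("s", "baxL", 1, 4), list("s", "baxL", 2, 4))
  rl <- relative_levels(q, "baxL", "ref")
  expect_equal(rl$level[rl$sample == "ref"], c(1, 1))
  expect_equal(rl$level[rl$sample == "s"], c(2, 1))

  # loading-control normalization per lane
  q2 <- mk_quant(list("ref", "baxL", 1, 2), list("s", "baxL", 1, 4),
                 list("ref", "tmRNA", 1, 2), list("s", "tmRNA", 1, 2))
  rl2 <- relative_levels(q2, "baxL", "ref", normalize_by = "tmRNA")
  expect_equal(rl2$level[rl2$sample == "s"], 2)

  # a common per-replicate gain factor cancels
  q3 <- q
  q3$intensity <- q3$intensity * ifelse(q3$replicate == 1, 7, 0.3)
  expect_equal(relative_levels(q3, "baxL", "ref")$level, rl$level)

  qz <- mk_quant(list("ref", "baxL", 1, 0), list("s", "baxL", 1, 4))
  expect_error(relative_levels(qz, "baxL", "ref"), "zero reference.*replicate 1")
  expect_error(relative_levels(q, "baxL", "nope"), "absent")
})

test_that("specificity scores subtract relative efficiencies per replicate", {
  rl_b <- data.frame(sample = rep(c("A", "D"), each = 2), replicate = c(1, 2, 1, 2),
                     level = c(0.3, 0.3, 1, 1))
  rl_g <- data.frame(sample = rep(c("A", "D"), each = 2), replicate = c(1, 2, 1, 2),
                     level = c(1, 1, 0.2, 0.2))
  sc <- specificity_score(rl_b, rl_g)
  expect_equal(sc$score[sc$sample == "D"], 0.8)
  expect_equal(sc$score_sd[sc$sample == "D"], 0)
  expect_equal(sc$score[sc$sample == "A"], -0.7)
  # antisymmetry under swapping the two efficiency tables
  sw <- specificity_score(rl_g, rl_b)
  expect_equal(sw$score, -sc$score)
  # equal efficiencies -> zero score
  expect_equal(specificity_score(rl_b, rl_b)$score, c(0, 0))
  expect_error(specificity_score(rl_b, rl_g[1:3, ]), "different")
})

test_that("readthrough fraction is 100*RT/(T+RT)", {
  expect_equal(readthrough_fraction(5, 5), 50)
  expect_equal(readthrough_fraction(5, 0), 0)
  expect_error(readthrough_fraction(0, 0), "positive")
  set.seed(61)
  t <- runif(50, 0.1, 10); rt <- runif(50, 0, 10)
  expect_equal(readthrough_fraction(t, rt), 100 * rt / (t + rt))
})

test_that("enrichment ratio sums component bands within fractions", {
  q <- mk_quant(list("s", "full", 1, 1, "bound"), list("s", "trunc", 1, 3, "bound"),
                list("s", "full", 1, 6, "crude"), list("s", "trunc", 1, 2, "crude"))
  er <- enrichment_ratio(q, "s", c("full", "trunc"))
  expect_equal(er$ratio, 0.5)  # (1+3)/(6+2)

  # bound == crude -> ratio 1
  q1 <- mk_quant(list("s", "full", 1, 2, "bound"), list("s", "full", 1, 2, "crude"))
  expect_equal(enrichment_ratio(q1, "s", "full")$ratio, 1)

  set.seed(62)
  for (i in 1:20) {
    b <- runif(3); cr <- runif(3, 0.5, 2)
    q2 <- mk_quant(list("s", "p1", 1, b[1], "bound"), list("s", "p2", 1, b[2], "bound"),
                   list("s", "p3", 1, b[3], "bound"),
                   list("s", "p1", 1, cr[1], "crude"), list("s", "p2", 1, cr[2], "crude"),
                   list("s", "p3", 1, cr[3], "crude"))
    expect_equal(enrichment_ratio(q2, "s", c("p1", "p2", "p3"))$ratio,
                 sum(b) / sum(cr))
  }
  expect_error(enrichment_ratio(q, "s", c("full", "missing")), "missing component")
  qz <- mk_quant(list("s", "full", 1, 1, "bound"), list("s", "full", 1, 0, "crude"))
  expect_error(enrichment_ratio(qz, "s", "full"), "zero crude")
})

test_that("noiseless simulated tables return planted efficiencies exactly", {
  q <- simulate_quant(noise_sigma = 0, seed = 9)
  eff <- default_quant_effects()
  rl_b <- relative_levels(q, "baxL", "CspD_like")
  rl_g <- relative_levels(q, "gdx", "CspA_like")
  sc <- specificity_score(rl_b, rl_g)
  for (i in seq_len(nrow(eff))) {
    expect_equal(sc$rel_baxL[sc$sample == eff$sample[i]], eff$rel_baxL[i])
    expect_equal(sc$rel_gdx[sc$sample == eff$sample[i]], eff$rel_gdx[i])
    expect_equal(sc$score[sc$sample == eff$sample[i]],
                 eff$rel_baxL[i] - eff$rel_gdx[i])
  }
  # seeded generator is reproducible
  expect_identical(simulate_quant(seed = 4), simulate_quant(seed = 4))
  expect_error(simulate_quant(noise_sigma = -1), "nonnegative")
})
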