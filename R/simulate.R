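#' @importFrom stats rnorm runif setNames
NULL

# Cold-shock-domain-like ancestral core (65 residues, CspA-like consensus
# minus the variable N-terminal tail). Positions 41-42 are the diagnostic
# loop pair; blocks 6-15 and 26-32 play the role of the invariant
# RNA-binding motifs (RNP1/RNP2) and are never mutated.
.csd_core <- "TGIVKWFNADKGFGFITPDDGSKDVFVHFSAIQNDGYKSLDEGQKVSFTIESGAKGPAAGNVTSL"
.csd_loop <- c(41L, 42L)
.csd_invariant <- c(6:15, 26:32)

# Type-specific N-terminal extensions. CspA-like (D-E) proteins carry the
# long unstructured tail with a lysine at position 4; the K-E type gets a
# short PfCsp-like tail with alanine in second position; CspD-like (K-A)
# and other proteins keep a minimal start.
.csd_ext <- c("K-A" = "M", "K-E" = "MA", "D-E" = "MSGKM", "other" = "M")

# Loop pairs observed among non-K, non-D-E Csps (the CspB/C/E/F/G/H/I
# variety); "other"-type members draw from this set.
.other_loop_pairs <- list(c("F", "E"), c("A", "E"), c("T", "T"),
                          c("N", "E"), c("I", "P"), c("T", "E"))

.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_subtree_fragment <- function(tips) {
  k <- length(tips)
  if (k == 1) return(tips)
  tr <- ape::rphylo(k, birth = 1, death = 0)
  tr$tip.label <- tips
  sub(";$", "", ape::write.tree(tr))
}

mutate_seq <- function(chars, sub_prob, mutable) {
  hit <- mutable[runif(length(mutable)) < sub_prob]
  for (i in hit) {
    chars[i] <- sample(setdiff(.aa20, chars[i]), 1)
  }
  chars
}

#' Simulate a cold-shock protein family with planted structure
#'
#' Generates a CSD-like protein family on a known tree: an ancestral
#' ~70-residue core with invariant RNP-motif blocks is evolved along a
#' seeded Yule-style tree (one random subtree per residue type, joined at
#' the root, so the K-A members form a true clade and the K-E members a
#' true cluster) with per-site per-edge substitutions; the diagnostic
#' loop residues are then overwritten according to each member's planted
#' type, so anchor sites are mutation-protected. Core evolution is
#' indel-free and type-specific N-terminal extensions have fixed lengths,
#' so the true alignment is known exactly (left gap-padding of the
#' extension block); D-E members carry the CspA-like tail with K4, K-E
#' members a short tail with alanine at position 2.
#'
#' @param n_per_type Named integer vector with entries `K-A`, `K-E`,
#'   `D-E`, `other` (types with 0 members are omitted). Default
#'   `c(12, 8, 12, 8)`, a 40-member family.
#' @param sub_prob Per-site per-edge substitution probability in
#'   \[0, 0.3\]. Default 0.05.
#' @param seed Integer seed; the output is a pure function of the
#'   arguments.
#' @return List of class `csp_family`: `seqs` (ungapped [seq_set()]),
#'   `alignment` (the true [alignment()]), `tree` (true `phylo`),
#'   `planted_type` (named labels), `anchors` (an [anchors()] table with
#'   loop/k4/pos2 anchors resolvable on the true alignment),
#'   `genome_assignment` (named genome ids), `quant_effects` (planted
#'   relative efficiencies per type), and the generator settings.
#' @export
simulate_family <- function(n_per_type = c("K-A" = 12, "K-E" = 8, "D-E" = 12, "other" = 8),
                            sub_prob = 0.05, seed = 1) {
  types <- c("K-A", "K-E", "D-E", "other")
  n_per_type <- n_per_type[types]
  names(n_per_type) <- types
  n_per_type[is.na(n_per_type)] <- 0L
  if (any(n_per_type < 0)) stop("type counts must be nonnegative", call. = FALSE)
  total <- sum(n_per_type)
  if (total < 4) stop("need at least 4 members in total", call. = FALSE)
  if (sub_prob < 0 || sub_prob > 0.3) {
    stop("`sub_prob` must lie in [0, 0.3]", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    prefix <- c("K-A" = "KA", "K-E" = "KE", "D-E" = "DE", "other" = "OT")
    tips_by_type <- lapply(types, function(t) {
      k <- n_per_type[[t]]
      if (k == 0) character() else sprintf("%s%02d", prefix[[t]], seq_len(k))
    })
    names(tips_by_type) <- types
    present <- types[n_per_type > 0]
    frags <- vapply(present, function(t) random_subtree_fragment(tips_by_type[[t]]), "")
    nwk <- if (length(frags) == 1) paste0(frags, ";") else
      paste0("(", paste0(frags, ":1", collapse = ","), ");")
    tree <- ape::read.tree(text = nwk)

    planted <- setNames(rep(types, n_per_type), unlist(tips_by_type))

    # evolve the core along the tree
    core <- strsplit(.csd_core, "", fixed = TRUE)[[1]]
    L <- length(core)
    mutable <- setdiff(seq_len(L), .csd_invariant)
    ntip <- length(tree$tip.label)
    tree_cw <- stats::reorder(tree, "cladewise")
    node_seq <- vector("list", ntip + tree_cw$Nnode)
    node_seq[[ntip + 1L]] <- core
    for (e in seq_len(nrow(tree_cw$edge))) {
      par <- tree_cw$edge[e, 1]; chd <- tree_cw$edge[e, 2]
      node_seq[[chd]] <- mutate_seq(node_seq[[par]], sub_prob, mutable)
    }

    ext_w <- max(nchar(.csd_ext))
    ids <- tree_cw$tip.label
    rows <- character(length(ids))
    for (i in seq_along(ids)) {
      ty <- planted[[ids[i]]]
      chars <- node_seq[[i]]
      pair <- switch(ty,
        "K-A" = c("K", "A"),
        "K-E" = c("K", "E"),
        "D-E" = c("D", "E"),
        "other" = .other_loop_pairs[[sample.int(length(.other_loop_pairs), 1)]])
      chars[.csd_loop] <- pair
      ext <- .csd_ext[[ty]]
      pad <- strrep("-", ext_w - nchar(ext))
      rows[i] <- paste0(pad, ext, paste(chars, collapse = ""))
    }
    aligned <- seq_set(ids, rows, sprintf("planted type %s", planted[ids]))
    aln <- alignment(aligned)
    seqs <- seq_set(ids, gsub("-", "", rows, fixed = TRUE),
                    sprintf("planted type %s", planted[ids]))

    # anchors, each defined on a reference member that carries the feature
    ref_for <- function(t) if (n_per_type[[t]] > 0) tips_by_type[[t]][1] else NA
    loop_ref <- ref_for("K-A")
    if (is.na(loop_ref)) loop_ref <- ids[1]
    loop_off <- nchar(.csd_ext[[planted[[loop_ref]]]])
    a_name <- c("loop1", "loop2"); a_ref <- c(loop_ref, loop_ref)
    a_pos <- loop_off + .csd_loop
    a_exp <- if (planted[[loop_ref]] == "K-A") c("K", "A") else c(NA, NA)
    if (!is.na(ref_for("D-E"))) {
      a_name <- c(a_name, "k4"); a_ref <- c(a_ref, ref_for("D-E"))
      a_pos <- c(a_pos, 4L); a_exp <- c(a_exp, "K")
    }
    if (!is.na(ref_for("K-E"))) {
      a_name <- c(a_name, "pos2"); a_ref <- c(a_ref, ref_for("K-E"))
      a_pos <- c(a_pos, 2L); a_exp <- c(a_exp, "A")
    }
    anch <- anchors(a_name, a_ref, a_pos, a_exp)

    # spread members over genomes, 1-4 per genome
    genome_of <- character(0)
    gi <- 0L
    left <- sample(ids)
    while (length(left)) {
      gi <- gi + 1L
      take <- min(length(left), sample.int(4, 1))
      genome_of[left[seq_len(take)]] <- sprintf("G%03d", gi)
      left <- left[-seq_len(take)]
    }

    structure(list(
      seqs = seqs, alignment = aln, tree = tree, planted_type = planted,
      anchors = anch, genome_assignment = genome_of[ids],
      quant_effects = default_quant_effects(),
      n_per_type = n_per_type, sub_prob = sub_prob, seed = as.integer(seed)
    ), class = "csp_family")
  })
}

#' Planted relative-efficiency profiles
#'
#' Default target-specificity effects used by the quantitation
#' simulation: a CspD-like sample fully induces the `baxL` target (its own
#' reference level 1) but only weakly the `gdx` target, a CspA-like sample
#' the reverse (5-fold strong:weak contrast), and a K-E-type sample is
#' gdx-directed like CspA.
#'
#' @return Data frame `sample`, `type`, `rel_baxL`, `rel_gdx`.
#' @export
default_quant_effects <- function() {
  data.frame(sample = c("CspD_like", "CspA_like", "KE_like"),
             type = c("K-A", "D-E", "K-E"),
             rel_baxL = c(1.0, 0.2, 0.2),
             rel_gdx = c(0.2, 1.0, 1.0),
             stringsAsFactors = FALSE)
}

#' Simulate genome records with a planted size/GC effect
#'
#' Draws per-genome Csp counts on 1..10 (defaults skewed so about two
#' thirds of genomes carry one or two Csps), then gives the high-count
#' group (`>= threshold` Csps) a larger genome and higher GC before
#' multiplicative/additive noise, emulating the association between Csp
#' multiplicity and genome characteristics.
#'
#' @param n_genomes Number of genomes (>= 2).
#' @param count_probs Probabilities for Csp counts 1..10.
#' @param size_shift Relative genome-size increase for the high group
#'   (0.3 = +30%); 0 plants no effect.
#' @param gc_shift Additive GC increase for the high group.
#' @param threshold Csp count defining the high group, default 3.
#' @param seed Integer seed.
#' @return Genome data frame (`genome_id`, `size_bp`, `gc`, `taxon`,
#'   `csp_ids`, `csp_count`).
#' @export
simulate_genomes <- function(n_genomes = 100,
                             count_probs = c(0.45, 0.22, 0.12, 0.08, 0.05,
                                             0.03, 0.02, 0.015, 0.01, 0.005),
                             size_shift = 0.3, gc_shift = 0.05,
                             threshold = 3, seed = 1) {
  if (n_genomes < 2) stop("need at least 2 genomes", call. = FALSE)
  if (length(count_probs) != 10 || any(count_probs < 0) || sum(count_probs) <= 0) {
    stop("`count_probs` must be 10 nonnegative weights for counts 1..10",
         call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    counts <- sample.int(10, n_genomes, replace = TRUE, prob = count_probs)
    high <- counts >= threshold
    size <- round(4e6 * (1 + size_shift * high) * exp(rnorm(n_genomes, 0, 0.2)))
    gc <- pmin(0.8, pmax(0.2, 0.5 + gc_shift * high + rnorm(n_genomes, 0, 0.04)))
    ids <- sprintf("G%04d", seq_len(n_genomes))
    csp_ids <- vapply(seq_len(n_genomes), function(i) {
      paste(sprintf("%s_csp%d", ids[i], seq_len(counts[i])), collapse = ",")
    }, "")
    taxa <- sample(c("Gammaproteobacteria", "Betaproteobacteria",
                     "Alphaproteobacteria", "Bacillota", "Actinomycetota"),
                   n_genomes, replace = TRUE)
    validate_genomes(data.frame(genome_id = ids, size_bp = size, gc = gc,
                                taxon = taxa, csp_ids = csp_ids,
                                stringsAsFactors = FALSE))
  })
}

#' Simulate a replicate band-quantitation table
#'
#' Intensities are `base_intensity * planted relative efficiency *
#' exp(N(0, noise_sigma))` per replicate, for probes `baxL` and `gdx`;
#' with `noise_sigma = 0` the planted relative efficiencies are recovered
#' exactly by [relative_levels()] against the samples whose planted
#' efficiency is 1.
#'
#' @param effects Data frame `sample`, `rel_baxL`, `rel_gdx`; default
#'   [default_quant_effects()].
#' @param noise_sigma Lognormal noise scale (sd on the log scale), >= 0.
#'   Default 0.15.
#' @param n_reps Replicates per lane (>= 1), default 3.
#' @param base_intensity Arbitrary reference band intensity.
#' @param seed Integer seed.
#' @return A [quant_table()] data frame.
#' @export
simulate_quant <- function(effects = default_quant_effects(), noise_sigma = 0.15,
                           n_reps = 3, base_intensity = 1000, seed = 1) {
  if (noise_sigma < 0) stop("`noise_sigma` must be nonnegative", call. = FALSE)
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  if (!all(c("sample", "rel_baxL", "rel_gdx") %in% names(effects))) {
    stop("`effects` needs columns sample, rel_baxL, rel_gdx", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    grid <- expand.grid(sample = effects$sample, probe = c("baxL", "gdx"),
                        replicate = seq_len(n_reps),
                        stringsAsFactors = FALSE)
    rel <- ifelse(grid$probe == "baxL",
                  effects$rel_baxL[match(grid$sample, effects$sample)],
                  effects$rel_gdx[match(grid$sample, effects$sample)])
    grid$intensity <- base_intensity * rel * exp(rnorm(nrow(grid), 0, noise_sigma))
    grid$fraction <- "total"
    quant_table(grid[order(grid$sample, grid$probe, grid$replicate), ])
  })
}
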