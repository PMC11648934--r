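write_manifest <- function(out_dir, config, inputs = character()) {
  checks <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    package = "csptyper",
    version = as.character(utils::packageVersion("csptyper")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_md5 = checks
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the family-typing workflow
#'
#' End-to-end residue typing of an aligned Csp family: resolve the
#' anchors on the untrimmed alignment, classify every member, tally the
#' types, obtain a tree (neighbor joining on Poisson-corrected distances
#' over the gap-trimmed alignment, or a user-supplied Newick tree), and
#' test each residue type for monophyly. Writes `type_table.tsv`,
#' `tally.json`, `tree.nwk`, `monophyly.tsv` and `manifest.json` into
#' `out_dir`.
#'
#' @param msa Aligned FASTA path or a [alignment()].
#' @param anchor_defs Anchor TSV path or an [anchors()] table. Must
#'   contain anchors named `loop1` and `loop2`; `k4` and `pos2` are used
#'   when present.
#' @param out_dir Output directory (created if needed).
#' @param tree Optional Newick path or `phylo`; when `NULL` a
#'   neighbor-joining tree is built from the alignment.
#' @param max_gap_frac Gap-trimming threshold for distance computation.
#' @param seed Recorded in the manifest (the workflow itself is
#'   deterministic).
#' @return Invisibly, a list with `calls`, `tally`, `tree`, `monophyly`.
#' @export
run_typing <- function(msa, anchor_defs, out_dir, tree = NULL,
                       max_gap_frac = 0.8, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- character()
  if (is.character(msa)) { inputs <- c(inputs, msa); msa <- read_alignment(msa) }
  stopifnot(inherits(msa, "csp_alignment"))
  if (is.character(anchor_defs)) {
    inputs <- c(inputs, anchor_defs)
    anchor_defs <- read_anchor_table(anchor_defs)
  }
  resolved <- resolve_anchors(msa, anchor_defs)
  calls <- classify_family(resolved)
  tally <- tally_types(calls)
  if (is.null(tree)) {
    tree <- nj_tree(aln_distances(msa, max_gap_frac = max_gap_frac))
    tree_source <- "built (neighbor joining, Poisson-corrected p-distances)"
  } else {
    if (is.character(tree)) { inputs <- c(inputs, tree); tree <- read_newick(tree) }
    tree_source <- "loaded"
    missing_leaves <- setdiff(calls$seq_id, tree$tip.label)
    if (length(missing_leaves)) {
      stop("tree lacks aligned sequences: ",
           paste(utils::head(missing_leaves, 5), collapse = ", "), call. = FALSE)
    }
  }
  mono <- do.call(rbind, lapply(c("K-A", "K-E", "D-E"), function(lab) {
    members <- calls$seq_id[calls$label == lab]
    members <- intersect(members, tree$tip.label)
    if (length(members) == 0) {
      return(data.frame(label = lab, n_members = 0L, monophyletic = NA,
                        mismatch_leaves = NA_integer_))
    }
    data.frame(label = lab, n_members = length(members),
               monophyletic = is_monophyletic(tree, members),
               mismatch_leaves = monophyly_gap(tree, members))
  }))
  write_tsv(calls, file.path(out_dir, "type_table.tsv"))
  jsonlite::write_json(tally, file.path(out_dir, "tally.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_newick(tree, file.path(out_dir, "tree.nwk"))
  write_tsv(mono, file.path(out_dir, "monophyly.tsv"))
  write_manifest(out_dir,
                 list(workflow = "typing", tree_source = tree_source,
                      max_gap_frac = max_gap_frac, seed = seed,
                      anchors_resolved_on = "untrimmed alignment"),
                 inputs)
  invisible(list(calls = calls, tally = tally, tree = tree, monophyly = mono))
}

#' Run the genome-distribution workflow
#'
#' Per-genome Csp counts and the low-versus-high Csp-count comparison of
#' genome size and GC content (Mann-Whitney U). Writes
#' `genome_counts.tsv`, `group_comparison.tsv` and `manifest.json`.
#'
#' @param genomes Genome TSV path or data frame.
#' @param out_dir Output directory.
#' @param threshold Csp count defining the high group, default 3.
#' @return Invisibly, a list with `genomes` and `comparisons` (one report
#'   per feature).
#' @export
run_distribution <- function(genomes, out_dir, threshold = 3) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- character()
  if (is.character(genomes)) { inputs <- c(inputs, genomes); genomes <- read_genome_table(genomes) }
  genomes <- validate_genomes(genomes)
  comparisons <- lapply(c("size", "gc"), function(f) {
    compare_groups(genomes, feature = f, threshold = threshold)
  })
  names(comparisons) <- c("size", "gc")
  if (!all(vapply(comparisons, `[[`, TRUE, "testable"))) {
    warning("one Csp-count group is empty; comparison reported as not testable",
            call. = FALSE)
  }
  cmp_df <- do.call(rbind, lapply(comparisons, function(r) {
    as.data.frame(r[c("feature", "threshold", "n_low", "n_high", "median_low",
                      "median_high", "iqr_low", "iqr_high", "mean_low",
                      "mean_high", "direction", "U", "p", "testable")])
  }))
  write_tsv(genomes[, c("genome_id", "size_bp", "gc", "csp_count")],
            file.path(out_dir, "genome_counts.tsv"))
  write_tsv(cmp_df, file.path(out_dir, "group_comparison.tsv"))
  write_manifest(out_dir, list(workflow = "distribution", threshold = threshold),
                 inputs)
  invisible(list(genomes = genomes, comparisons = comparisons))
}

#' Run the quantitation workflow
#'
#' Computes per-sample relative levels for the `baxL` and `gdx` probes
#' against the given reference samples and the resulting specificity
#' scores. Writes `relative_levels.tsv`, `specificity_scores.tsv` and
#' `manifest.json`.
#'
#' @param quant Quantitation TSV path or data frame.
#' @param reference_baxL Sample defining level 1 for the `baxL` probe
#'   (a CspD-like lane).
#' @param reference_gdx Sample defining level 1 for the `gdx` probe
#'   (a CspA-like lane).
#' @param out_dir Output directory.
#' @param normalize_by Optional loading-control probe (e.g. `"tmRNA"`).
#' @return Invisibly, a list with `rel_baxL`, `rel_gdx`, `scores`.
#' @export
run_quant <- function(quant, reference_baxL, reference_gdx, out_dir,
                      normalize_by = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- character()
  if (is.character(quant)) { inputs <- c(inputs, quant); quant <- read_quant_table(quant) }
  quant <- quant_table(quant)
  rel_b <- relative_levels(quant, "baxL", reference_baxL, normalize_by = normalize_by)
  rel_g <- relative_levels(quant, "gdx", reference_gdx, normalize_by = normalize_by)
  scores <- specificity_score(rel_b, rel_g)
  levels_out <- rbind(cbind(probe = "baxL", rel_b), cbind(probe = "gdx", rel_g))
  write_tsv(levels_out, file.path(out_dir, "relative_levels.tsv"))
  write_tsv(scores, file.path(out_dir, "specificity_scores.tsv"))
  write_manifest(out_dir,
                 list(workflow = "quant", reference_baxL = reference_baxL,
                      reference_gdx = reference_gdx,
                      normalize_by = normalize_by %||% "none",
                      score_convention = "per-replicate scores, then mean +/- SD"),
                 inputs)
  invisible(list(rel_baxL = rel_b, rel_gdx = rel_g, scores = scores))
}
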