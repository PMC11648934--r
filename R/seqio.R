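#' @importFrom utils read.delim write.table
NULL

.protein_alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "-")
.nucleotide_alphabet <- c("A", "C", "G", "T", "N", "-")

#' Create a sequence set
#'
#' A sequence set is the package's container for identified biological
#' sequences: a data frame with columns `id`, `description` and `seq`, plus a
#' `moltype` attribute (`"protein"` or `"nucleotide"`). Gaps are written `-`;
#' the dot gap dialect is rejected so that downstream column arithmetic has a
#' single gap character to reason about. Unknown residues are `X` (protein)
#' or `N` (nucleotide).
#'
#' @param ids Character vector of unique, non-empty identifiers.
#' @param seqs Character vector of sequences (upper- or lower-case; stored
#'   upper-case).
#' @param descriptions Optional free-text descriptions, recycled to length.
#' @param moltype `"protein"` or `"nucleotide"`.
#' @return An object of class `csp_seqs` (a data frame).
#' @export
seq_set <- function(ids, seqs, descriptions = "", moltype = c("protein", "nucleotide")) {
  moltype <- match.arg(moltype)
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) {
    stop("`ids` and `seqs` must have the same length", call. = FALSE)
  }
  descriptions <- rep_len(as.character(descriptions), length(ids))
  if (length(ids)) {
    if (any(!nzchar(ids))) stop("sequence ids must be non-empty", call. = FALSE)
    if (anyDuplicated(ids)) {
      stop("duplicate sequence ids: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
    }
    if (any(!nzchar(seqs))) stop("sequences must be non-empty", call. = FALSE)
    if (any(grepl(".", seqs, fixed = TRUE))) {
      stop("'.' gap characters are not supported; use '-' gaps", call. = FALSE)
    }
    alphabet <- if (moltype == "protein") .protein_alphabet else .nucleotide_alphabet
    chars <- unique(unlist(strsplit(seqs, "", fixed = TRUE)))
    bad <- setdiff(chars, alphabet)
    if (length(bad)) {
      stop(sprintf("invalid %s characters: %s", moltype,
                   paste(bad, collapse = " ")), call. = FALSE)
    }
  }
  out <- data.frame(id = ids, description = descriptions, seq = seqs,
                    stringsAsFactors = FALSE)
  attr(out, "moltype") <- moltype
  class(out) <- c("csp_seqs", "data.frame")
  out
}

#' @export
print.csp_seqs <- function(x, ...) {
  cat(sprintf("<csp_seqs> %d %s sequence(s)\n", nrow(x), attr(x, "moltype")))
  if (nrow(x)) {
    shown <- utils::head(x, 10)
    cat(sprintf("  %-20s %5d aa/nt  %s\n", shown$id, nchar(shown$seq),
                substr(shown$seq, 1, 30)), sep = "")
    if (nrow(x) > 10) cat(sprintf("  ... and %d more\n", nrow(x) - 10))
  }
  invisible(x)
}

#' Read a FASTA file
#'
#' Identifiers are the first whitespace-delimited token of each header; the
#' remainder of the header is kept as the description. Duplicate ids are an
#' error, an empty file yields an empty set.
#'
#' @param path Path to a (possibly aligned, gapped) FASTA file.
#' @param moltype `"protein"` or `"nucleotide"`.
#' @return A [seq_set()].
#' @export
read_fasta <- function(path, moltype = c("protein", "nucleotide")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) return(seq_set(character(), character(), moltype = moltype))
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_set(ids, as.character(ss), desc, moltype = moltype)
}

#' Write a FASTA file
#'
#' @param x A [seq_set()] (or alignment rows coerced to one).
#' @param path Output path.
#' @param width Positive line-wrap width (residues per line).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60) {
  stopifnot(inherits(x, "csp_seqs"))
  if (width < 1) stop("`width` must be a positive integer", call. = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    header <- if (nzchar(x$description[i])) paste(x$id[i], x$description[i]) else x$id[i]
    writeLines(paste0(">", header), con)
    s <- x$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a Newick tree
#'
#' Accepts a file path or a literal Newick string. Branch lengths and
#' internal (support) labels are preserved; polytomies are allowed.
#' Duplicate leaf labels are rejected because every downstream operation
#' treats leaf labels as keys.
#'
#' @param source Path to a Newick file, or the Newick text itself (must
#'   contain a semicolon to be treated as text).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(source) {
  tr <- if (grepl(";", source, fixed = TRUE)) {
    ape::read.tree(text = source)
  } else {
    if (!file.exists(source)) stop("file not found: ", source, call. = FALSE)
    ape::read.tree(source)
  }
  if (is.null(tr)) stop("could not parse Newick input", call. = FALSE)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels in tree: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  tr
}

#' Write a tree in Newick format
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Collapse exact duplicate sequences
#'
#' Two records collapse if and only if their ungapped, upper-cased residue
#' strings are identical; the first occurrence (input order) represents the
#' group. This is the 100%-identity deduplication used to reduce a
#' redundant CDS collection to unique proteins before tree building.
#'
#' @param x A [seq_set()].
#' @return A list with `unique` (a [seq_set()] of representatives, input
#'   order) and `representative_of` (named character vector mapping every
#'   input id to its representative's id).
#' @export
dedup_exact <- function(x) {
  stopifnot(inherits(x, "csp_seqs"))
  key <- toupper(gsub("-", "", x$seq, fixed = TRUE))
  first <- !duplicated(key)
  rep_id <- x$id[first][match(key, key[first])]
  names(rep_id) <- x$id
  uniq <- x[first, , drop = FALSE]
  rownames(uniq) <- NULL
  attr(uniq, "moltype") <- attr(x, "moltype")
  class(uniq) <- c("csp_seqs", "data.frame")
  list(unique = uniq, representative_of = rep_id)
}

#' Read a genome metadata table
#'
#' Expects a TSV with header columns `genome_id`, `size_bp`, `gc`, optional
#' `taxon`, and `csp_ids` (comma-separated member sequence ids). A
#' `csp_count` column is added.
#'
#' @param path TSV path.
#' @return A data frame.
#' @export
read_genome_table <- function(path) {
  g <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "size_bp", "gc", "csp_ids")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("genome table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  validate_genomes(g)
}

#' Validate a genome table
#'
#' Checks sizes, GC range and member-id uniqueness and (re)computes
#' `csp_count` from `csp_ids`.
#'
#' @param g Data frame with `genome_id`, `size_bp`, `gc`, `csp_ids`.
#' @return The validated data frame with a `csp_count` column.
#' @export
validate_genomes <- function(g) {
  if (anyDuplicated(g$genome_id)) stop("duplicate genome ids", call. = FALSE)
  if (any(g$size_bp <= 0)) stop("genome sizes must be positive", call. = FALSE)
  if (any(g$gc < 0 | g$gc > 1)) stop("gc must lie in [0, 1]", call. = FALSE)
  members <- strsplit(ifelse(is.na(g$csp_ids), "", g$csp_ids), ",", fixed = TRUE)
  members <- lapply(members, function(m) m[nzchar(trimws(m))])
  if (any(vapply(members, anyDuplicated, 1L) > 0)) {
    stop("duplicate Csp ids within a genome", call. = FALSE)
  }
  g$csp_count <- lengths(members)
  g
}

#' Read a band-quantitation table
#'
#' Expects a TSV with columns `sample`, `probe`, `replicate`, `intensity`
#' and optionally `fraction` (defaults to `"total"`).
#'
#' @param path TSV path.
#' @return A validated quantitation data frame (see [quant_table()]).
#' @export
read_quant_table <- function(path) {
  q <- read.delim(path, stringsAsFactors = FALSE)
  quant_table(q)
}

#' Read an anchor definition table
#'
#' Expects a TSV with columns `name`, `ref_id`, `ref_pos` and optionally
#' `expected` (the residue the reference itself carries there).
#'
#' @param path TSV path.
#' @return An anchor data frame (see [anchors()]).
#' @export
read_anchor_table <- function(path) {
  a <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "ref_id", "ref_pos") %in% names(a))) {
    stop("anchor table needs columns name, ref_id, ref_pos", call. = FALSE)
  }
  anchors(a$name, a$ref_id, a$ref_pos,
          expected = if ("expected" %in% names(a)) a$expected else NA)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
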