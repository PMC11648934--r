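#' Construct an alignment with column provenance
#'
#' An alignment is a set of equal-length gapped rows plus a provenance map:
#' for every current column, the index of the column in the original
#' (untrimmed) alignment. On a fresh alignment the map is the identity;
#' [trim_columns()] composes with it, so anchor columns can always be traced
#' back to original coordinates however many trimming passes were applied.
#' Columns are 1-based throughout, matching R indexing and the 1-based
#' residue numbering used for anchors (e.g. "K43").
#'
#' @param rows A [seq_set()] whose sequences all have the same length.
#' @param provenance Integer vector, one entry per column, strictly
#'   increasing; defaults to the identity.
#' @return An object of class `csp_alignment`.
#' @export
alignment <- function(rows, provenance = NULL) {
  stopifnot(inherits(rows, "csp_seqs"))
  if (!nrow(rows)) stop("alignment needs at least one row", call. = FALSE)
  lens <- nchar(rows$seq)
  if (length(unique(lens)) != 1L) {
    stop("alignment rows must all have the same length (ragged input)",
         call. = FALSE)
  }
  n_cols <- lens[1]
  if (is.null(provenance)) provenance <- seq_len(n_cols)
  provenance <- as.integer(provenance)
  if (length(provenance) != n_cols || is.unsorted(provenance, strictly = TRUE)) {
    stop("provenance must be strictly increasing with one entry per column",
         call. = FALSE)
  }
  structure(list(rows = rows, n_cols = n_cols, provenance = provenance),
            class = "csp_alignment")
}

#' Read an aligned FASTA file as an alignment
#'
#' @inheritParams read_fasta
#' @return A [alignment()] with identity provenance.
#' @export
read_alignment <- function(path, moltype = c("protein", "nucleotide")) {
  alignment(read_fasta(path, moltype = match.arg(moltype)))
}

#' @export
print.csp_alignment <- function(x, ...) {
  trimmed <- !identical(x$provenance, seq_len(x$n_cols))
  cat(sprintf("<csp_alignment> %d rows x %d columns%s\n",
              nrow(x$rows), x$n_cols,
              if (trimmed) sprintf(" (trimmed from %d)", max(x$provenance)) else ""))
  invisible(x)
}

#' Alignment as a character matrix
#'
#' @param aln A [alignment()].
#' @return Character matrix, rows named by sequence id.
#' @export
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows$seq, "", fixed = TRUE))
  rownames(m) <- aln$rows$id
  m
}

#' Map a reference residue position to an alignment column
#'
#' Finds the column holding the `ref_pos`-th non-gap character of the
#' reference row, i.e. projects a reference numbering such as "CspD K43"
#' onto the alignment so the homologous position can be read in every row.
#'
#' @param aln A [alignment()].
#' @param ref_id Row id carrying the reference numbering.
#' @param ref_pos 1-based residue index in the ungapped reference.
#' @return 1-based column index (in the alignment's current coordinates).
#' @export
column_of <- function(aln, ref_id, ref_pos) {
  stopifnot(inherits(aln, "csp_alignment"))
  i <- match(ref_id, aln$rows$id)
  if (is.na(i)) stop("reference id not in alignment: ", ref_id, call. = FALSE)
  ref_pos <- as.integer(ref_pos)
  if (ref_pos < 1) stop("`ref_pos` must be >= 1", call. = FALSE)
  chars <- strsplit(aln$rows$seq[i], "", fixed = TRUE)[[1]]
  nongap <- which(chars != "-")
  if (ref_pos > length(nongap)) {
    stop(sprintf("ref_pos %d beyond ungapped length %d of '%s'",
                 ref_pos, length(nongap), ref_id), call. = FALSE)
  }
  nongap[ref_pos]
}

#' Remove gap-rich columns, keeping provenance
#'
#' Keeps exactly the columns whose gap fraction is `<= max_gap_frac`
#' (fixed-threshold gap trimming, the flavour commonly applied to an MSA
#' before distance/tree computation). The returned alignment's provenance
#' maps its columns back to the *original* coordinates of `aln`, composing
#' with any earlier trimming.
#'
#' @param aln A [alignment()].
#' @param max_gap_frac Maximum tolerated gap fraction per column, in
#'   \[0, 1\]. Default 0.8.
#' @return A trimmed [alignment()].
#' @export
trim_columns <- function(aln, max_gap_frac = 0.8) {
  stopifnot(inherits(aln, "csp_alignment"))
  if (max_gap_frac < 0 || max_gap_frac > 1) {
    stop("`max_gap_frac` must lie in [0, 1]", call. = FALSE)
  }
  m <- aln_matrix(aln)
  gap_frac <- colMeans(m == "-")
  keep <- which(gap_frac <= max_gap_frac)
  if (!length(keep)) {
    stop("trimming removed every column (degenerate alignment)", call. = FALSE)
  }
  rows <- aln$rows
  rows$seq <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  attr(rows, "moltype") <- attr(aln$rows, "moltype")
  class(rows) <- c("csp_seqs", "data.frame")
  alignment(rows, provenance = aln$provenance[keep])
}

#' Residues in one alignment column
#'
#' @param aln A [alignment()].
#' @param col 1-based column index.
#' @return Named character vector (one single-character entry per row; gaps
#'   are `"-"`).
#' @export
residues_at <- function(aln, col) {
  stopifnot(inherits(aln, "csp_alignment"))
  col <- as.integer(col)
  if (col < 1 || col > aln$n_cols) {
    stop(sprintf("column %d out of range [1, %d]", col, aln$n_cols), call. = FALSE)
  }
  out <- substr(aln$rows$seq, col, col)
  names(out) <- aln$rows$id
  out
}

#' Define anchor positions
#'
#' An anchor names a residue position on a reference sequence (for example
#' the loop lysine "K43" of a CspD-like reference) so that the homologous
#' column can be interrogated in every aligned family member.
#'
#' @param name Anchor names (tokens).
#' @param ref_id Reference sequence id per anchor.
#' @param ref_pos 1-based residue position in the ungapped reference.
#' @param expected Optional expected residue letter in the reference itself;
#'   `NA` to skip the check.
#' @return A data frame of class `csp_anchors`.
#' @export
anchors <- function(name, ref_id, ref_pos, expected = NA) {
  ref_pos <- as.integer(ref_pos)
  if (any(ref_pos < 1)) stop("anchor `ref_pos` must be >= 1", call. = FALSE)
  out <- data.frame(name = as.character(name), ref_id = as.character(ref_id),
                    ref_pos = ref_pos,
                    expected = toupper(rep_len(as.character(expected), length(name))),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$name)) stop("duplicate anchor names", call. = FALSE)
  class(out) <- c("csp_anchors", "data.frame")
  out
}

#' Resolve anchors to columns and per-sequence residues
#'
#' Each anchor is located on the (untrimmed) alignment and the residue at
#' its column is reported for every row. If a trimmed alignment derived
#' from `aln` is supplied, anchors are additionally mapped through its
#' provenance: an anchor whose column survived reports its column index in
#' the trimmed coordinates, and an anchor whose column was removed is
#' marked trimmed (residues `NA`) rather than silently mis-mapped.
#'
#' @param aln The alignment the anchors' reference rows live in. Anchors
#'   are interpreted against this alignment's *original* column
#'   coordinates, so `aln` should normally be untrimmed.
#' @param anch An [anchors()] table.
#' @param trimmed Optional alignment produced by [trim_columns()] from
#'   `aln`, used only to flag/trace anchors through trimming.
#' @return Named list (one entry per anchor) of lists with elements
#'   `name`, `column` (original coordinates), `trimmed_column` (`NA` when
#'   no trimmed alignment given or the column was removed), `trimmed`
#'   (logical) and `residues` (named character vector, `NA` if trimmed
#'   away).
#' @export
resolve_anchors <- function(aln, anch, trimmed = NULL) {
  stopifnot(inherits(aln, "csp_alignment"), inherits(anch, "csp_anchors"))
  out <- lapply(seq_len(nrow(anch)), function(i) {
    col <- column_of(aln, anch$ref_id[i], anch$ref_pos[i])
    orig <- aln$provenance[col]
    res <- residues_at(aln, col)
    if (!is.na(anch$expected[i]) && anch$expected[i] != "NA") {
      got <- unname(res[anch$ref_id[i]])
      if (got != anch$expected[i]) {
        warning(sprintf("anchor '%s': reference %s has '%s' at position %d, expected '%s'",
                        anch$name[i], anch$ref_id[i], got, anch$ref_pos[i],
                        anch$expected[i]), call. = FALSE)
      }
    }
    tcol <- NA_integer_
    was_trimmed <- FALSE
    if (!is.null(trimmed)) {
      stopifnot(inherits(trimmed, "csp_alignment"))
      tcol <- match(orig, trimmed$provenance)
      if (is.na(tcol)) {
        was_trimmed <- TRUE
        res[] <- NA_character_
      }
    }
    list(name = anch$name[i], column = orig, trimmed_column = tcol,
         trimmed = was_trimmed, residues = res)
  })
  names(out) <- anch$name
  out
}

#' Tabulate resolved anchors
#'
#' @param resolved Output of [resolve_anchors()].
#' @return Data frame with one row per sequence and one column per anchor
#'   (trimmed-away anchors become `"trimmed"`).
#' @export
anchor_residue_table <- function(resolved) {
  ids <- names(resolved[[1]]$residues)
  out <- data.frame(seq_id = ids, stringsAsFactors = FALSE)
  for (a in resolved) {
    v <- unname(a$residues[ids])
    if (a$trimmed) v <- rep("trimmed", length(ids))
    out[[a$name]] <- v
  }
  out
}
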