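#' Fuse two parent sequences at a junction
#'
#' Builds a chimeric protein: the first `left_end` residues of the left
#' parent followed by the right parent with its first `right_skip`
#' residues dropped. `left_end = len(left), right_skip = len(right)`
#' returns the left parent unchanged; `left_end = 0, right_skip = 0`
#' returns the right parent. The resulting length is always
#' `left_end + nchar(right) - right_skip`.
#'
#' @param left,right Single records: one-row [seq_set()]s or lists with
#'   `id` and `seq` (ungapped).
#' @param left_end Number of N-terminal residues taken from `left`
#'   (0..len(left)).
#' @param right_skip Number of N-terminal residues dropped from `right`
#'   (0..len(right)).
#' @param id Identifier for the chimera; default records both parents and
#'   the junction.
#' @return A one-row [seq_set()].
#' @export
fuse <- function(left, right, left_end, right_skip, id = NULL) {
  l <- as_record(left); r <- as_record(right)
  left_end <- as.integer(left_end); right_skip <- as.integer(right_skip)
  if (left_end < 0 || left_end > nchar(l$seq)) {
    stop("`left_end` outside [0, len(left)]", call. = FALSE)
  }
  if (right_skip < 0 || right_skip > nchar(r$seq)) {
    stop("`right_skip` outside [0, len(right)]", call. = FALSE)
  }
  seq <- paste0(substr(l$seq, 1, left_end),
                substr(r$seq, right_skip + 1, nchar(r$seq)))
  if (is.null(id)) id <- sprintf("%s(1-%d)_%s(%d-)", l$id, left_end, r$id, right_skip + 1)
  seq_set(id, seq, sprintf("chimera of %s and %s", l$id, r$id))
}

#' Apply point mutations to a sequence
#'
#' @param x A single record (one-row [seq_set()] or list with `id`, `seq`).
#' @param positions 1-based positions to edit; must be distinct and within
#'   the sequence.
#' @param residues Replacement residues, one per position.
#' @param id Identifier for the mutant; default appends the edits in
#'   `pos`-`new` notation (e.g. `"CspD_K43D_A44E"`).
#' @return A one-row [seq_set()] of unchanged length.
#' @export
point_mutate <- function(x, positions, residues, id = NULL) {
  rec <- as_record(x)
  positions <- as.integer(positions)
  residues <- toupper(as.character(residues))
  if (length(positions) != length(residues)) {
    stop("`positions` and `residues` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(positions)) stop("duplicate edit positions", call. = FALSE)
  if (any(positions < 1 | positions > nchar(rec$seq))) {
    stop("edit positions outside the sequence", call. = FALSE)
  }
  if (any(nchar(residues) != 1L)) stop("replacement residues must be single characters", call. = FALSE)
  chars <- strsplit(rec$seq, "", fixed = TRUE)[[1]]
  old <- chars[positions]
  chars[positions] <- residues
  if (is.null(id)) {
    id <- paste0(rec$id, "_", paste0(old, positions, residues, collapse = "_"))
  }
  seq_set(id, paste(chars, collapse = ""), sprintf("mutant of %s", rec$id))
}

#' Build chimeras from a junction recipe table
#'
#' The recipe table has columns `name`, `left_id`, `left_end`, `right_id`,
#' `right_skip` (see `inst/extdata/chimera_junctions.tsv` for the CspA/CspD
#' junction set transcribed from the alignment of the two parents; the
#' cross-parent offsets there are editable data, not hard-coded truth).
#'
#' @param seqs A [seq_set()] containing every parent id referenced.
#' @param recipes Data frame of junction recipes.
#' @return A [seq_set()] of chimeras in recipe order.
#' @export
apply_junctions <- function(seqs, recipes) {
  stopifnot(inherits(seqs, "csp_seqs"))
  need <- c("name", "left_id", "left_end", "right_id", "right_skip")
  miss <- setdiff(need, names(recipes))
  if (length(miss)) stop("recipe table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  out <- lapply(seq_len(nrow(recipes)), function(i) {
    fuse(get_record(seqs, recipes$left_id[i]), get_record(seqs, recipes$right_id[i]),
         recipes$left_end[i], recipes$right_skip[i], id = recipes$name[i])
  })
  do.call(rbind_seqs, out)
}

#' Extract one record from a sequence set
#'
#' @param x A [seq_set()].
#' @param id Record id.
#' @return A one-row [seq_set()].
#' @export
get_record <- function(x, id) {
  stopifnot(inherits(x, "csp_seqs"))
  i <- match(id, x$id)
  if (is.na(i)) stop("no record with id: ", id, call. = FALSE)
  out <- x[i, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "moltype") <- attr(x, "moltype")
  class(out) <- c("csp_seqs", "data.frame")
  out
}

as_record <- function(x) {
  if (inherits(x, "csp_seqs")) {
    if (nrow(x) != 1L) stop("expected a single sequence record", call. = FALSE)
    return(list(id = x$id, seq = x$seq))
  }
  if (is.list(x) && all(c("id", "seq") %in% names(x))) {
    return(list(id = x$id, seq = toupper(x$seq)))
  }
  stop("cannot interpret input as a sequence record", call. = FALSE)
}

rbind_seqs <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !inherits(parts[[1]], "csp_seqs")) {
    parts <- parts[[1]]
  }
  seq_set(unlist(lapply(parts, `[[`, "id")),
          unlist(lapply(parts, `[[`, "seq")),
          unlist(lapply(parts, `[[`, "description")),
          moltype = attr(parts[[1]], "moltype") %||% "protein")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
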