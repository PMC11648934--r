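.loop_labels <- c("K-A", "K-E", "K-other", "D-E", "unaligned", "other")

#' Classify a loop residue pair
#'
#' Csp subfamilies are defined by the two residues at the internal-loop
#' positions homologous to CspD 43-44 (CspA 46-47): lysine-alanine marks
#' CspD-like proteins (`K-A`), lysine-glutamate a distinct cluster (`K-E`),
#' aspartate-glutamate CspA-like proteins (`D-E`). Any other lysine-first
#' pair is `K-other`; a gap at either position means the sequence is not
#' aligned at the loop (`unaligned`); everything else (including the
#' ambiguity code `X` at either position) is `other`.
#'
#' @param first,second Single residue characters (or `-`), vectorized and
#'   case-insensitive.
#' @return Character vector of labels in
#'   `c("K-A", "K-E", "K-other", "D-E", "unaligned", "other")`.
#' @export
classify_loop <- function(first, second) {
  first <- as.character(first); second <- as.character(second)
  if (length(first) != length(second)) {
    stop("`first` and `second` must have the same length", call. = FALSE)
  }
  if (any(nchar(first) != 1L, na.rm = TRUE) || any(nchar(second) != 1L, na.rm = TRUE)) {
    stop("loop residues must be single characters", call. = FALSE)
  }
  f <- toupper(first); s <- toupper(second)
  out <- rep("other", length(f))
  gap <- is.na(f) | is.na(s) | f == "-" | s == "-"
  unk <- !gap & (f == "X" | s == "X")
  kfirst <- !gap & !unk & f == "K"
  out[kfirst] <- ifelse(s[kfirst] == "A", "K-A",
                        ifelse(s[kfirst] == "E", "K-E", "K-other"))
  out[!gap & !unk & f == "D" & s == "E"] <- "D-E"
  out[gap] <- "unaligned"
  out
}

#' Type every family member from resolved anchors
#'
#' Combines the loop-pair classification with the optional N-terminal
#' anchors: `k4` (lysine homologous to CspA K4, flagging CspA-like
#' N-terminal extensions) and `pos2` (the second residue, informative for
#' PfCsp-like proteins). Emits the raw anchor residues alongside the label
#' so alternative typings can be derived without re-resolving the
#' alignment.
#'
#' @param resolved Output of [resolve_anchors()].
#' @param loop_first,loop_second Names of the two loop anchors in
#'   `resolved` (required).
#' @param k4,pos2 Names of the optional anchors; `NULL` to skip.
#' @return Data frame with columns `seq_id`, `loop_first`, `loop_second`,
#'   `nterm_k4`, `pos2`, `label`, `k4_flag`.
#' @export
classify_family <- function(resolved, loop_first = "loop1", loop_second = "loop2",
                            k4 = "k4", pos2 = "pos2") {
  if (!all(c(loop_first, loop_second) %in% names(resolved))) {
    stop("resolved anchors must include the two loop anchors ('",
         loop_first, "', '", loop_second, "')", call. = FALSE)
  }
  r1 <- resolved[[loop_first]]; r2 <- resolved[[loop_second]]
  ids <- names(r1$residues)
  first <- unname(r1$residues[ids]); second <- unname(r2$residues[ids])
  if (r1$trimmed) first[] <- NA_character_
  if (r2$trimmed) second[] <- NA_character_
  get_opt <- function(nm) {
    if (is.null(nm) || !nm %in% names(resolved)) return(rep(NA_character_, length(ids)))
    a <- resolved[[nm]]
    if (a$trimmed) rep(NA_character_, length(ids)) else unname(a$residues[ids])
  }
  k4_res <- get_opt(k4)
  pos2_res <- get_opt(pos2)
  lab <- classify_loop(ifelse(is.na(first), "-", first),
                       ifelse(is.na(second), "-", second))
  data.frame(seq_id = ids,
             loop_first = first, loop_second = second,
             nterm_k4 = k4_res, pos2 = pos2_res,
             label = lab,
             k4_flag = !is.na(k4_res) & toupper(k4_res) == "K",
             stringsAsFactors = FALSE)
}

#' Tally type calls
#'
#' Counts and percentages per label; among lysine-first records (labels
#' `K-A`, `K-E`, `K-other`) the share whose second loop residue is A or E;
#' and the dual-lysine count (lysine at both the loop-first position and
#' the K4 position), the signature that rarely co-occurs in one protein.
#' Percentages are rounded to one decimal place.
#'
#' @param calls Output of [classify_family()].
#' @return List with `n`, `counts`, `percent`, `k_first_total`,
#'   `k_first_ae_count`, `k_first_ae_share_pct`, `dual_lysine_count`.
#' @export
tally_types <- function(calls) {
  counts <- vapply(.loop_labels, function(l) sum(calls$label == l), 1L)
  n <- nrow(calls)
  percent <- if (n) round(100 * counts / n, 1) else setNames(rep(NA_real_, length(counts)), names(counts))
  kfirst <- calls$label %in% c("K-A", "K-E", "K-other")
  k_total <- sum(kfirst)
  k_ae <- sum(calls$label %in% c("K-A", "K-E"))
  list(n = n,
       counts = counts,
       percent = percent,
       k_first_total = k_total,
       k_first_ae_count = k_ae,
       k_first_ae_share_pct = if (k_total) round(100 * k_ae / k_total, 1) else NA_real_,
       dual_lysine_count = sum(kfirst & calls$k4_flag, na.rm = TRUE))
}
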