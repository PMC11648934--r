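#' GC content of a nucleotide sequence
#'
#' (G + C) / (A + C + G + T); `N` bases are excluded from the denominator.
#'
#' @param seq Character vector of nucleotide strings (alphabet `ACGTN`,
#'   case-insensitive; gaps `-` ignored).
#' @return Numeric vector of GC fractions.
#' @export
gc_content <- function(seq) {
  vapply(toupper(as.character(seq)), function(s) {
    if (!nzchar(s)) stop("empty sequence", call. = FALSE)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N", "-"))
    if (length(bad)) stop("invalid nucleotide characters: ",
                          paste(bad, collapse = " "), call. = FALSE)
    counted <- sum(chars %in% c("A", "C", "G", "T"))
    if (counted == 0) stop("no countable (ACGT) bases", call. = FALSE)
    sum(chars %in% c("G", "C")) / counted
  }, 1, USE.NAMES = FALSE)
}

#' Split genomes by Csp count
#'
#' Partitions genomes into a low-count group (`csp_count < threshold`) and
#' a high-count group (`csp_count >= threshold`); the conventional
#' comparison contrasts genomes with one or two Csps against those with
#' three or more. Genomes with zero Csps fall outside the universe of
#' Csp-containing genomes and are dropped with a warning.
#'
#' @param genomes Genome data frame (see [validate_genomes()]); a
#'   `csp_count` column is computed from `csp_ids` if absent.
#' @param threshold Minimum count for the high group; default 3.
#' @return List with elements `low` and `high` (data frames).
#' @export
split_by_csp_count <- function(genomes, threshold = 3) {
  if (!"csp_count" %in% names(genomes)) genomes <- validate_genomes(genomes)
  zero <- genomes$csp_count == 0
  if (any(zero)) {
    warning(sum(zero), " genome(s) with zero Csps excluded", call. = FALSE)
    genomes <- genomes[!zero, , drop = FALSE]
  }
  list(low = genomes[genomes$csp_count < threshold, , drop = FALSE],
       high = genomes[genomes$csp_count >= threshold, , drop = FALSE])
}

#' Mann-Whitney U test
#'
#' Two-sample rank-sum test. `U` is the smaller of the two U statistics
#' computed from midrank sums. In `auto` mode the two-sided p-value is
#' exact — full enumeration of all `choose(n+m, n)` group assignments —
#' when the smaller sample has at most 8 observations and there are no
#' ties; otherwise the normal approximation with tie-corrected variance
#' and a 0.5 continuity correction is used. When every observation is
#' tied the variance vanishes and p is 1.
#'
#' @param x,y Nonempty numeric samples.
#' @param mode `"auto"` (default), `"exact"` or `"normal"`. `"exact"` with
#'   ties is refused rather than silently approximated.
#' @return List with `U`, `p_two_sided`, `U_x`, `U_y`, `method`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be nonempty", call. = FALSE)
  if (any(!is.finite(c(x, y)))) stop("samples must be finite", call. = FALSE)
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  rk <- rank(pooled)  # midranks
  Ux <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  Uy <- n * m - Ux
  U <- min(Ux, Uy)
  ties <- anyDuplicated(pooled) > 0

  do_exact <- switch(mode,
    exact = TRUE,
    normal = FALSE,
    auto = min(n, m) <= 8 && !ties)
  if (do_exact && ties) {
    stop("exact mode requires tie-free samples; use mode = 'normal'", call. = FALSE)
  }

  if (do_exact) {
    # null distribution of U_x by enumerating which ranks go to x
    combos <- utils::combn(N, n)
    ux_null <- colSums(matrix(rk[combos], nrow = n)) - n * (n + 1) / 2
    total <- length(ux_null)
    p <- 2 * min(sum(ux_null <= Ux), sum(ux_null >= Ux)) / total
    p <- min(1, p)
    method <- "exact enumeration"
  } else {
    mu <- n * m / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
      method <- "normal approximation (degenerate: all tied)"
    } else {
      z <- (Ux - mu)
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
      method <- "normal approximation with tie correction"
    }
  }
  list(U = U, p_two_sided = max(p, .Machine$double.xmin),
       U_x = Ux, U_y = Uy, method = method)
}

#' Compare a genome feature between Csp-count groups
#'
#' Splits genomes at `threshold` Csps and compares genome size or GC
#' content between the groups with [mann_whitney_u()]. Medians and
#' interquartile ranges are the primary summaries (the test is
#' rank-based); means are reported alongside. If either group is empty
#' the comparison is reported as not testable rather than fabricating a
#' p-value.
#'
#' @param genomes Genome data frame.
#' @param feature `"size"` (column `size_bp`) or `"gc"`.
#' @param threshold Csp-count split point, default 3.
#' @param mode Passed to [mann_whitney_u()].
#' @return List report: group sizes, medians, IQRs, means, `direction`
#'   (`"high > low"`, `"high < low"` or `"none"` by median), `U`, `p`,
#'   `testable`.
#' @export
compare_groups <- function(genomes, feature = c("size", "gc"), threshold = 3,
                           mode = "auto") {
  feature <- match.arg(feature)
  col <- if (feature == "size") "size_bp" else "gc"
  grp <- split_by_csp_count(genomes, threshold)
  lo <- grp$low[[col]]; hi <- grp$high[[col]]
  stat_or_na <- function(f, v) if (length(v)) f(v) else NA_real_
  base <- list(feature = feature, threshold = threshold,
               n_low = length(lo), n_high = length(hi),
               median_low = stat_or_na(stats::median, lo),
               median_high = stat_or_na(stats::median, hi),
               iqr_low = stat_or_na(stats::IQR, lo),
               iqr_high = stat_or_na(stats::IQR, hi),
               mean_low = stat_or_na(mean, lo), mean_high = stat_or_na(mean, hi))
  if (!length(lo) || !length(hi)) {
    return(c(base, list(direction = NA_character_, U = NA_real_, p = NA_real_,
                        testable = FALSE)))
  }
  mw <- mann_whitney_u(hi, lo, mode = mode)
  direction <- if (base$median_high > base$median_low) "high > low"
               else if (base$median_high < base$median_low) "high < low"
               else "none"
  c(base, list(direction = direction, U = mw$U, p = mw$p_two_sided,
               testable = TRUE, method = mw$method))
}
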