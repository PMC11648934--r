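#' Validate a band-quantitation table
#'
#' A quantitation table holds one band intensity per (sample, probe,
#' replicate, fraction): `sample` is the lane's strain/construct, `probe`
#' the hybridization probe (e.g. `baxL`, `gdx`, `tmRNA`), `fraction`
#' distinguishes total RNA, crude extract and pull-down bound material.
#'
#' @param q Data frame with columns `sample`, `probe`, `replicate`,
#'   `intensity`, optional `fraction` (default `"total"`).
#' @return The validated data frame.
#' @export
quant_table <- function(q) {
  need <- c("sample", "probe", "replicate", "intensity")
  miss <- setdiff(need, names(q))
  if (length(miss)) stop("quant table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!"fraction" %in% names(q)) q$fraction <- "total"
  if (any(q$intensity < 0)) stop("intensities must be nonnegative", call. = FALSE)
  if (any(q$replicate < 1)) stop("replicates are numbered from 1", call. = FALSE)
  key <- paste(q$sample, q$probe, q$replicate, q$fraction, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (sample, probe, replicate, fraction) rows", call. = FALSE)
  }
  q
}

#' Per-replicate RNA levels relative to a reference sample
#'
#' Each replicate's intensity is divided by the reference sample's
#' intensity in the *same* replicate (so the reference maps to 1 in every
#' replicate), optionally after per-lane division by a loading-control
#' probe such as tmRNA. This reproduces "relative RNA levels with the
#' reference sample set to 1" band arithmetic.
#'
#' @param q A [quant_table()].
#' @param probe Probe to quantify.
#' @param reference_sample Sample whose lane defines level 1.
#' @param normalize_by Optional loading-control probe; each lane's
#'   intensity is divided by the control intensity of the same
#'   (sample, replicate, fraction) lane first.
#' @param fraction Fraction to use, default `"total"`.
#' @return Data frame `sample`, `replicate`, `level`.
#' @export
relative_levels <- function(q, probe, reference_sample, normalize_by = NULL,
                            fraction = "total") {
  q <- quant_table(q)
  sub <- q[q$probe == probe & q$fraction == fraction, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for probe '", probe, "'", call. = FALSE)
  if (!is.null(normalize_by)) {
    ctrl <- q[q$probe == normalize_by & q$fraction == fraction, , drop = FALSE]
    idx <- match(paste(sub$sample, sub$replicate), paste(ctrl$sample, ctrl$replicate))
    if (anyNA(idx)) {
      stop("loading-control probe '", normalize_by, "' missing for some lanes",
           call. = FALSE)
    }
    if (any(ctrl$intensity[idx] == 0)) {
      stop("zero loading-control intensity", call. = FALSE)
    }
    sub$intensity <- sub$intensity / ctrl$intensity[idx]
  }
  ref <- sub[sub$sample == reference_sample, , drop = FALSE]
  if (!nrow(ref)) stop("reference sample '", reference_sample,
                       "' absent for probe '", probe, "'", call. = FALSE)
  reps <- sort(unique(sub$replicate))
  missing_rep <- setdiff(reps, ref$replicate)
  if (length(missing_rep)) {
    stop("reference sample '", reference_sample, "' missing replicate(s) ",
         paste(missing_rep, collapse = ", "), call. = FALSE)
  }
  ref_level <- ref$intensity[match(sub$replicate, ref$replicate)]
  zero <- ref_level == 0
  if (any(zero)) {
    stop(sprintf("zero reference intensity in lane (%s, %s, replicate %s)",
                 reference_sample, probe,
                 paste(unique(sub$replicate[zero]), collapse = ",")), call. = FALSE)
  }
  out <- data.frame(sample = sub$sample, replicate = sub$replicate,
                    level = sub$intensity / ref_level, stringsAsFactors = FALSE)
  out[order(out$sample, out$replicate), , drop = FALSE]
}

#' Target-specificity score
#'
#' For every sample, the per-replicate score is the relative efficiency
#' for the CspD-type target (`baxL` level relative to the CspD reference)
#' minus the relative efficiency for the CspA-type target (`gdx` level
#' relative to the CspA reference); scores are then averaged over
#' replicates with their standard deviation. Positive scores indicate
#' CspD-like specificity, negative scores CspA-like.
#'
#' @param rel_baxL,rel_gdx Data frames from [relative_levels()] over the
#'   same samples and replicates.
#' @return Data frame `sample`, `n_reps`, `rel_baxL`, `rel_gdx`, `score`,
#'   `score_sd`.
#' @export
specificity_score <- function(rel_baxL, rel_gdx) {
  key_b <- paste(rel_baxL$sample, rel_baxL$replicate)
  key_g <- paste(rel_gdx$sample, rel_gdx$replicate)
  if (!setequal(key_b, key_g)) {
    stop("the two relative-level tables cover different (sample, replicate) pairs",
         call. = FALSE)
  }
  g <- rel_gdx$level[match(key_b, key_g)]
  per_rep <- data.frame(sample = rel_baxL$sample, replicate = rel_baxL$replicate,
                        score = rel_baxL$level - g,
                        baxL = rel_baxL$level, gdx = g)
  agg <- function(v, f) tapply(v, per_rep$sample, f)
  samples <- sort(unique(per_rep$sample))
  data.frame(sample = samples,
             n_reps = as.integer(agg(per_rep$score, length)[samples]),
             rel_baxL = as.numeric(agg(per_rep$baxL, mean)[samples]),
             rel_gdx = as.numeric(agg(per_rep$gdx, mean)[samples]),
             score = as.numeric(agg(per_rep$score, mean)[samples]),
             score_sd = as.numeric(agg(per_rep$score, stats::sd)[samples]),
             stringsAsFactors = FALSE)
}

#' Terminator readthrough fraction
#'
#' Percentage of readthrough transcript relative to total signal:
#' `100 * RT / (T + RT)`, where `T` is the terminated band and `RT` the
#' band extending past the intrinsic terminator.
#'
#' @param terminated,readthrough Nonnegative intensities (vectorized).
#' @return Percentages in \[0, 100\].
#' @export
readthrough_fraction <- function(terminated, readthrough) {
  if (length(terminated) != length(readthrough)) {
    stop("inputs must have the same length", call. = FALSE)
  }
  if (any(terminated < 0 | readthrough < 0)) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  tot <- terminated + readthrough
  if (any(tot == 0)) stop("terminated + readthrough must be positive", call. = FALSE)
  100 * readthrough / tot
}

#' Pull-down enrichment ratio
#'
#' Bound-fraction signal over crude-extract signal for one sample and
#' probe, summing the listed component bands (e.g. full-length plus
#' truncated species) within each fraction before taking the ratio.
#'
#' @param q A [quant_table()].
#' @param sample Sample to evaluate.
#' @param probes Character vector of component band probes to sum.
#' @param bound_fraction,crude_fraction Fraction labels, defaults
#'   `"bound"` and `"crude"`.
#' @return List with `ratio` (mean over replicates), `sd`, and
#'   `per_replicate` (data frame `replicate`, `bound`, `crude`, `ratio`).
#' @export
enrichment_ratio <- function(q, sample, probes,
                             bound_fraction = "bound", crude_fraction = "crude") {
  q <- quant_table(q)
  pick <- function(frac) q[q$sample == sample & q$probe %in% probes &
                             q$fraction == frac, , drop = FALSE]
  bound <- pick(bound_fraction); crude <- pick(crude_fraction)
  reps <- sort(unique(c(bound$replicate, crude$replicate)))
  if (!length(reps)) stop("no bound/crude rows for sample '", sample, "'", call. = FALSE)
  per <- lapply(reps, function(r) {
    b <- bound[bound$replicate == r, , drop = FALSE]
    c_ <- crude[crude$replicate == r, , drop = FALSE]
    if (!setequal(b$probe, probes) || !setequal(c_$probe, probes)) {
      stop(sprintf("replicate %d: missing component band(s) for sample '%s'",
                   r, sample), call. = FALSE)
    }
    bs <- sum(b$intensity); cs <- sum(c_$intensity)
    if (cs == 0) stop(sprintf("zero crude-extract sum in replicate %d", r), call. = FALSE)
    data.frame(replicate = r, bound = bs, crude = cs, ratio = bs / cs)
  })
  per <- do.call(rbind, per)
  list(ratio = mean(per$ratio),
       sd = if (nrow(per) > 1) stats::sd(per$ratio) else NA_real_,
       per_replicate = per)
}
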