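#' Zygote vs matched polar-body reciprocity
#'
#' A chromosome mis-partitioned between the egg and the second polar
#' body at anaphase II (or carried unevenly into MII) shows up as a gain
#' in one product and a loss in the other. This function compares the
#' discrete calls of a matched zygote/polar-body pair chromosome by
#' chromosome (Y excluded: polar bodies carry no Y) and classifies each
#' as:
#'
#' * `reciprocal` — one gained, the other lost;
#' * `concordant` — both gained or both lost;
#' * `unmatched` — aneuploid in one product, neutral in the other;
#' * `neutral` — neutral in both.
#'
#' The reciprocity fraction is, among chromosomes aneuploid in the
#' polar body, the fraction whose zygote call has the opposite sign. It
#' is undefined (flagged, `NA`) when the polar body is fully neutral.
#'
#' @param zygote,pb `aneuploidy_calls` for the zygote and its matched
#'   polar body; their chromosome sets must agree once Y is dropped.
#' @param pair_id Optional pair label.
#' @return A `pair_reciprocity`: per-chromosome relation table, relation
#'   counts, `reciprocity_fraction` and a `defined` flag.
#' @export
reciprocity <- function(zygote, pb, pair_id = NULL) {
  stopifnot(inherits(zygote, "aneuploidy_calls"),
            inherits(pb, "aneuploidy_calls"))
  zc <- zygote$calls[names(zygote$calls) != "Y"]
  pc <- pb$calls[names(pb$calls) != "Y"]
  if (!setequal(names(zc), names(pc))) {
    stop("zygote and polar body cover different chromosome sets",
         call. = FALSE)
  }
  pc <- pc[names(zc)]
  relation <- ifelse(
    zc == "neutral" & pc == "neutral", "neutral",
    ifelse((zc == "gain" & pc == "loss") | (zc == "loss" & pc == "gain"),
           "reciprocal",
           ifelse(zc == pc, "concordant", "unmatched")))
  tab <- data.frame(chrom = names(zc), zygote_call = unname(zc),
                    pb_call = unname(pc), relation = unname(relation),
                    stringsAsFactors = FALSE)
  counts <- vapply(c("reciprocal", "concordant", "unmatched", "neutral"),
                   function(r) sum(relation == r), integer(1))
  denom <- sum(pc != "neutral")
  frac <- if (denom > 0) sum(pc != "neutral" & relation == "reciprocal") / denom
          else NA_real_
  structure(list(pair_id = pair_id %||%
                   paste(zygote$sample_id, pb$sample_id, sep = "|"),
                 zygote_id = zygote$sample_id, pb_id = pb$sample_id,
                 table = tab, counts = counts,
                 reciprocity_fraction = frac, defined = denom > 0),
            class = "pair_reciprocity")
}

#' Cohort-level summary of calls and reciprocity
#'
#' Assembles the heatmap-ready matrix of copy-number deviations (rows:
#' zygote and polar body of each pair interleaved; columns:
#' chromosomes) and summary statistics: the fraction of zygotes with
#' complex aneuploidy, the mean reciprocity fraction over pairs where
#' it is defined, per-chromosome aneuploidy frequencies, and a
#' chi-square uniformity statistic over autosomes quantifying (without
#' deciding) whether errors prefer particular chromosomes.
#'
#' Deviations are reported on a common diploid-equivalent scale,
#' `2 * (CN / baseline) - 2`, so a whole lost chromosome is -2 and a
#' gained single chromatid +1 regardless of sample sex or ploidy scale.
#'
#' @param pairs List of `pair_reciprocity` reports (>= 1).
#' @param calls List of `aneuploidy_calls` for all samples appearing in
#'   `pairs` (zygotes and polar bodies).
#' @return A `cohort_summary`: `deviation_matrix`, `call_matrix`, and
#'   `summary` record.
#' @export
cohort_summary <- function(pairs, calls) {
  if (length(pairs) == 0) stop("no pairs given", call. = FALSE)
  stopifnot(all(vapply(pairs, inherits, logical(1), "pair_reciprocity")),
            all(vapply(calls, inherits, logical(1), "aneuploidy_calls")))
  names(calls) <- vapply(calls, function(x) x$sample_id, character(1))
  if (anyDuplicated(names(calls))) {
    stop("duplicate sample ids in calls", call. = FALSE)
  }
  ids <- unlist(lapply(pairs, function(p) c(p$zygote_id, p$pb_id)))
  missing <- setdiff(ids, names(calls))
  if (length(missing)) {
    stop("calls missing for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  chroms <- unique(unlist(lapply(calls[ids], function(x) names(x$calls))))
  dev <- matrix(NA_real_, nrow = length(ids), ncol = length(chroms),
                dimnames = list(ids, chroms))
  cmat <- matrix(NA_character_, nrow = length(ids), ncol = length(chroms),
                 dimnames = list(ids, chroms))
  for (id in ids) {
    x <- calls[[id]]
    dev[id, names(x$calls)] <- 2 * x$copy_number / x$baseline - 2
    cmat[id, names(x$calls)] <- x$calls
  }

  zyg_ids <- vapply(pairs, function(p) p$zygote_id, character(1))
  zyg_complex <- vapply(calls[zyg_ids],
                        function(x) x$complexity == "complex", logical(1))
  rf <- vapply(pairs, function(p) p$reciprocity_fraction, numeric(1))
  defined <- vapply(pairs, function(p) p$defined, logical(1))

  aneu <- cmat != "neutral"
  freq <- colMeans(aneu, na.rm = TRUE)
  autos <- setdiff(chroms, c("X", "Y"))
  obs <- colSums(aneu[, autos, drop = FALSE], na.rm = TRUE)
  expd <- rep(mean(obs), length(obs))
  stat <- if (all(expd > 0)) sum((obs - expd)^2 / expd) else NA_real_
  df <- length(autos) - 1L

  structure(list(
    deviation_matrix = dev, call_matrix = cmat,
    summary = list(
      n_pairs = length(pairs),
      frac_zygotes_complex = mean(zyg_complex),
      mean_reciprocity = if (any(defined)) mean(rf[defined]) else NA_real_,
      n_reciprocity_defined = sum(defined),
      per_chrom_aneuploidy_freq = freq,
      uniformity = list(statistic = stat, df = df,
                        p_value = if (is.na(stat)) NA_real_ else
                          stats::pchisq(stat, df, lower.tail = FALSE))
    )), class = "cohort_summary")
}

#' @export
print.pair_reciprocity <- function(x, ...) {
  cat(sprintf("<pair_reciprocity> %s: %d reciprocal / %d concordant / %d unmatched; fraction=%s\n",
              x$pair_id, x$counts[["reciprocal"]], x$counts[["concordant"]],
              x$counts[["unmatched"]],
              if (x$defined) sprintf("%.3f", x$reciprocity_fraction)
              else "undefined"))
  invisible(x)
}

#' @export
print.cohort_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cohort_summary> %d pairs; %.0f%% zygotes complex; mean reciprocity %s (n=%d)\n",
              s$n_pairs, 100 * s$frac_zygotes_complex,
              if (is.na(s$mean_reciprocity)) "NA"
              else sprintf("%.3f", s$mean_reciprocity),
              s$n_reciprocity_defined))
  invisible(x)
}
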