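#' Build an empirical copy-number reference
#'
#' Averages per-chromosome read proportions over karyotypically normal
#' samples. In `sex_matched` mode (default) female and male samples are
#' averaged separately, and test samples are later compared against the
#' reference of their own sex; in `pooled` mode a single mixed-sex mean
#' is stored. Pooled references bias the sex chromosomes (a euploid
#' female X sits ~4/3 above a half-male pool before doubling) but leave
#' autosome calls unchanged.
#'
#' @param profiles List of `count_profile`s with `sex_label` set to
#'   `male` or `female`.
#' @param mode `"sex_matched"` or `"pooled"`.
#' @return A `reference_profile`: per-sex (or pooled) mean proportion
#'   maps plus sample counts.
#' @export
build_reference <- function(profiles, mode = c("sex_matched", "pooled")) {
  mode <- match.arg(mode)
  if (length(profiles) == 0) stop("no reference profiles given", call. = FALSE)
  stopifnot(all(vapply(profiles, inherits, logical(1), "count_profile")))
  chroms <- names(profiles[[1]]$counts)
  props <- t(vapply(profiles,
                    function(p) p$counts[chroms] / p$total_mapped,
                    numeric(length(chroms))))
  colnames(props) <- chroms
  sex <- vapply(profiles, function(p) p$sex_label, character(1))
  if (any(sex == "unknown")) {
    stop("reference samples must carry a male/female sex label",
         call. = FALSE)
  }
  n_female <- sum(sex == "female"); n_male <- sum(sex == "male")
  ref <- list(mode = mode, chroms = chroms,
              n_female = n_female, n_male = n_male)
  if (mode == "sex_matched") {
    if (n_female == 0 || n_male == 0) {
      stop("sex_matched reference needs at least one sample of each sex",
           call. = FALSE)
    }
    ref$female <- colMeans(props[sex == "female", , drop = FALSE])
    ref$male <- colMeans(props[sex == "male", , drop = FALSE])
  } else {
    ref$pooled <- colMeans(props)
  }
  structure(ref, class = "reference_profile")
}

# Proportion map a sample of a given sex is compared against.
ref_proportions <- function(ref, sex) {
  stopifnot(inherits(ref, "reference_profile"))
  if (ref$mode == "sex_matched") ref[[sex]] else ref$pooled
}

#' Infer sample sex from Y-chromosome read share
#'
#' A sample is called male when its Y read proportion reaches at least
#' half the male-reference Y proportion; samples without appreciable Y
#' signal (including polar bodies and female zygotes) are called
#' female.
#'
#' @param profile A `count_profile`.
#' @param ref A sex-matched `reference_profile`.
#' @return `"male"` or `"female"`.
#' @export
infer_sex <- function(profile, ref) {
  stopifnot(inherits(profile, "count_profile"),
            inherits(ref, "reference_profile"))
  if (ref$mode != "sex_matched") {
    stop("sex inference requires a sex_matched reference", call. = FALSE)
  }
  y_ref <- ref$male[["Y"]]
  if (is.null(y_ref) || is.na(y_ref) || y_ref <= 0) {
    stop("male reference carries no Y proportion; cannot infer sex",
         call. = FALSE)
  }
  y <- profile$counts[["Y"]] %||% 0
  if (y / profile$total_mapped >= 0.5 * y_ref) "male" else "female"
}

#' Predict copy number from read proportions
#'
#' The core transform of the low-coverage aneuploidy procedure. For
#' each chromosome the sample's read proportion is divided by the
#' reference proportion; the resulting ratio is doubled for all
#' autosomes and for the female X (euploid copy number 2), while for
#' male samples the X and Y ratios are left untransformed, since those
#' chromosomes are present in a single copy in euploid male cells. The
#' female Y, absent from the reference, is reported as `NA` (absent);
#' nonzero Y reads in a sample compared against a zero Y reference
#' signal an inconsistent reference and raise an error.
#'
#' @param profile A `count_profile`.
#' @param ref A `reference_profile`.
#' @param sex `"male"` or `"female"`; inferred via [infer_sex()] when
#'   `NULL` and the reference is sex-matched.
#' @return A `copy_number_profile`: per-chromosome `ratio` and
#'   continuous `copy_number` on the diploid-autosome scale.
#' @export
predict_copy_number <- function(profile, ref, sex = NULL) {
  stopifnot(inherits(profile, "count_profile"),
            inherits(ref, "reference_profile"))
  if (is.null(sex)) sex <- infer_sex(profile, ref)
  sex <- match.arg(sex, c("male", "female"))
  rp <- ref_proportions(ref, sex)
  chroms <- ref$chroms
  missing <- setdiff(names(profile$counts)[profile$counts > 0], chroms)
  if (length(missing)) {
    stop("reference does not cover chromosome(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sp <- stats::setNames(numeric(length(chroms)), chroms)
  common <- intersect(names(profile$counts), chroms)
  sp[common] <- profile$counts[common] / profile$total_mapped

  bad <- chroms[rp <= 0 & sp > 0]
  if (length(bad)) {
    stop("sample has reads on chromosome(s) absent from the ",
         sex, " reference: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ratio <- ifelse(rp > 0, sp / rp, NA_real_)
  names(ratio) <- chroms

  is_x <- chroms == "X"; is_y <- chroms == "Y"
  dbl <- if (sex == "female") !is_y else !(is_x | is_y)
  cn <- ifelse(dbl, 2 * ratio, ratio)
  names(cn) <- chroms

  structure(list(sample_id = profile$sample_id, sex_used = sex,
                 ratio = ratio, copy_number = cn),
            class = "copy_number_profile")
}

#' Calling thresholds
#'
#' A single relative-deviation threshold: a chromosome is called gained
#' (lost) when its copy number sits at least `delta_rel` above (below)
#' its euploid baseline, as a fraction of that baseline. The default
#' 0.2 calls half-chromatid imbalances (copy number 2.5 or 1.5, 25%
#' deviation) while tolerating sampling noise at ~200,000 reads.
#'
#' @param delta_rel Relative deviation in `(0, 1)`.
#' @return A `call_thresholds` object.
#' @export
call_thresholds <- function(delta_rel = 0.2) {
  if (!is.numeric(delta_rel) || length(delta_rel) != 1 ||
      is.na(delta_rel) || delta_rel <= 0 || delta_rel >= 1) {
    stop("delta_rel must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(delta_rel = delta_rel), class = "call_thresholds")
}

new_aneuploidy_calls <- function(sample_id, calls, copy_number, baseline) {
  n_aneuploid <- sum(calls != "neutral")
  structure(list(sample_id = sample_id, calls = calls,
                 copy_number = copy_number, baseline = baseline,
                 n_aneuploid = as.integer(n_aneuploid),
                 complexity = classify_complexity(n_aneuploid)),
            class = "aneuploidy_calls")
}

#' Call whole-chromosome gains and losses
#'
#' Compares each chromosome's predicted copy number against its euploid
#' baseline (2 for autosomes and the female X, 1 for the male X and Y)
#' and calls `gain`/`loss`/`neutral` at the relative threshold. The
#' female Y (copy number `NA`, absent) is excluded from the call map.
#'
#' @param cnp A `copy_number_profile`.
#' @param thresholds A `call_thresholds` object.
#' @param sex Sex used for baselines; defaults to the one recorded in
#'   `cnp`.
#' @return An `aneuploidy_calls` object: per-chromosome call map,
#'   `n_aneuploid`, and `complexity` (`euploid` 0, `simple` 1-2,
#'   `complex` >= 3 aneuploid chromosomes).
#' @export
call_aneuploidy <- function(cnp, thresholds = call_thresholds(), sex = NULL) {
  stopifnot(inherits(cnp, "copy_number_profile"),
            inherits(thresholds, "call_thresholds"))
  sex <- sex %||% cnp$sex_used
  cn <- cnp$copy_number
  keep <- !is.na(cn)
  cn <- cn[keep]
  chroms <- names(cn)
  base <- stats::setNames(rep(2, length(chroms)), chroms)
  if (sex == "male") base[chroms %in% c("X", "Y")] <- 1
  dev <- cn / base - 1
  calls <- ifelse(dev >= thresholds$delta_rel, "gain",
                  ifelse(-dev >= thresholds$delta_rel, "loss", "neutral"))
  new_aneuploidy_calls(cnp$sample_id, stats::setNames(calls, chroms),
                       cn, base)
}

#' Classify aneuploidy complexity
#'
#' `euploid` with no aneuploid chromosome, `simple` with one or two,
#' `complex` with gains and losses affecting three or more chromosomes.
#'
#' @param x An `aneuploidy_calls` object or a non-negative integer
#'   count of aneuploid chromosomes.
#' @return `"euploid"`, `"simple"` or `"complex"`.
#' @export
classify_complexity <- function(x) {
  n <- if (inherits(x, "aneuploidy_calls")) sum(x$calls != "neutral") else x
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0) {
    stop("x must be an aneuploidy_calls object or a count >= 0",
         call. = FALSE)
  }
  if (n == 0) "euploid" else if (n <= 2) "simple" else "complex"
}

#' @export
print.aneuploidy_calls <- function(x, ...) {
  ab <- x$calls[x$calls != "neutral"]
  cat(sprintf("<aneuploidy_calls> %s: %d aneuploid (%s)%s\n",
              x$sample_id, x$n_aneuploid, x$complexity,
              if (length(ab)) paste0(": ",
                paste(names(ab), ab, sep = ":", collapse = " ")) else ""))
  invisible(x)
}

#' @export
print.copy_number_profile <- function(x, ...) {
  cat(sprintf("<copy_number_profile> %s (sex %s)\n", x$sample_id, x$sex_used))
  print(round(x$copy_number, 3))
  invisible(x)
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf("<reference_profile> mode=%s, %d female + %d male samples, %d chromosomes\n",
              x$mode, x$n_female, x$n_male, length(x$chroms)))
  invisible(x)
}
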