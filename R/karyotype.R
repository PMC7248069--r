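#' Cell karyotypes at chromatid resolution
#'
#' A `cell_karyotype` records, for one meiotic product, how many intact
#' dyads (two sister chromatids joined by cohesion) and how many single
#' chromatids of each chromosome the cell contains. Zygotes additionally
#' carry a paternal complement of one chromatid per autosome plus one sex
#' chromosome, kept separate from the maternal content.
#'
#' @param stage One of `"MII_egg"`, `"PB1"`, `"PB2"`, `"zygote"`.
#' @param dyads,singles Named non-negative integer vectors over the
#'   maternal (oocyte) chromosomes.
#' @param paternal Named vector of paternal chromatid counts (zygotes
#'   only), or `NULL`.
#' @param meta List of provenance fields (seed, oocyte id, ...).
#'
#' @return A `cell_karyotype` object.
#' @export
cell_karyotype <- function(stage, dyads, singles, paternal = NULL,
                           meta = list()) {
  stage <- match.arg(stage, c("MII_egg", "PB1", "PB2", "zygote"))
  stopifnot(!is.null(names(dyads)), identical(names(dyads), names(singles)))
  if (any(dyads < 0) || any(singles < 0)) {
    stop("dyad and single-chromatid counts must be non-negative",
         call. = FALSE)
  }
  if (stage != "zygote" && !is.null(paternal)) {
    stop("only zygotes carry a paternal complement", call. = FALSE)
  }
  structure(list(stage = stage,
                 dyads = dyads, singles = singles,
                 paternal = paternal, meta = meta),
            class = "cell_karyotype")
}

#' Chromatid units per chromosome
#'
#' The DNA-mass weight of each chromosome: `2 * dyads + singles`, plus
#' the paternal chromatid for zygotes. Read output is proportional to
#' this quantity times chromosome length.
#'
#' @param karyotype A `cell_karyotype`.
#' @param genome A `genome_model`; the result covers its chromosomes in
#'   order, with 0 for chromosomes the cell lacks.
#' @param maternal_only If `TRUE`, exclude the paternal complement.
#' @return Named numeric vector over `genome$chrom`.
#' @export
chromatid_units <- function(karyotype, genome, maternal_only = FALSE) {
  stopifnot(inherits(karyotype, "cell_karyotype"),
            inherits(genome, "genome_model"))
  u <- stats::setNames(numeric(nrow(genome)), genome$chrom)
  m <- 2 * karyotype$dyads + karyotype$singles
  keep <- intersect(names(m), genome$chrom)
  u[keep] <- m[keep]
  if (!maternal_only && !is.null(karyotype$paternal)) {
    p <- karyotype$paternal
    keep <- intersect(names(p), genome$chrom)
    u[keep] <- u[keep] + p[keep]
  }
  u
}

#' Is a cell euploid?
#'
#' Euploid content by stage: MII egg and PB1 hold one dyad per
#' chromosome; PB2 holds one chromatid; a zygote holds one maternal
#' chromatid plus one paternal chromatid per chromosome (X or Y from the
#' sperm).
#'
#' @param karyotype A `cell_karyotype`.
#' @param genome A `genome_model` (the full genome; the maternal part is
#'   checked against its Y-free reduction).
#' @return `TRUE` if every chromosome matches the euploid content.
#' @export
is_euploid <- function(karyotype, genome) {
  fg <- oocyte_genome(genome)
  d <- stats::setNames(numeric(nrow(fg)), fg$chrom)
  s <- d
  d[names(karyotype$dyads)] <- karyotype$dyads
  s[names(karyotype$singles)] <- karyotype$singles
  ok <- switch(karyotype$stage,
    MII_egg = ,
    PB1 = all(d == 1) && all(s == 0),
    PB2 = all(d == 0) && all(s == 1),
    zygote = {
      if (is.null(karyotype$paternal)) return(FALSE)
      pat_ok <- all(karyotype$paternal == 1)
      all(d == 0) && all(s == 1) && pat_ok
    })
  isTRUE(ok)
}

#' Summarise a metaphase II egg
#'
#' Counts the chromosomes (dyads) and loose single chromatids in an MII
#' egg, the two quantities scored when spreading metaphase II oocytes: a
#' euploid egg has 20 chromosomes and 0 single chromatids.
#'
#' @param egg A `cell_karyotype` of stage `MII_egg`.
#' @return List with `n_chromosomes` (total dyads) and `n_chromatids`
#'   (total singles).
#' @export
mii_summary <- function(egg) {
  stopifnot(inherits(egg, "cell_karyotype"))
  if (egg$stage != "MII_egg") {
    stop("mii_summary expects an MII egg, got stage '", egg$stage, "'",
         call. = FALSE)
  }
  list(n_chromosomes = as.integer(sum(egg$dyads)),
       n_chromatids = as.integer(sum(egg$singles)))
}

#' Truth-level aneuploidy calls from a karyotype
#'
#' Derives gain/loss/neutral status per chromosome directly from the
#' simulated chromatid content, against the euploid expectation for the
#' cell's stage (2 units for eggs/PB1 and for zygote chromosomes with a
#' paternal homologue, 1 unit for PB2 and for the unmatched zygote sex
#' chromosome). Used as the ground truth that sequencing-based calls are
#' benchmarked against; the Y is only present (and only called) in male
#' zygotes.
#'
#' @param karyotype A `cell_karyotype`.
#' @param genome A `genome_model`.
#' @return An `aneuploidy_calls` object (see [call_aneuploidy()]).
#' @export
karyotype_calls <- function(karyotype, genome) {
  u <- chromatid_units(karyotype, genome)
  fg <- oocyte_genome(genome)
  base <- switch(karyotype$stage,
    MII_egg = ,
    PB1 = stats::setNames(rep(2, nrow(fg)), fg$chrom),
    PB2 = stats::setNames(rep(1, nrow(fg)), fg$chrom),
    zygote = {
      b <- stats::setNames(rep(2, nrow(fg)), fg$chrom)
      pat <- karyotype$paternal
      if (is.null(pat)) stop("zygote karyotype lacks paternal content",
                             call. = FALSE)
      if ("Y" %in% names(pat) && pat[["Y"]] > 0) {
        b[["X"]] <- 1           # XY zygote: one maternal X expected
        b <- c(b, Y = 1)
      }
      b
    })
  u <- u[names(base)]
  calls <- ifelse(u > base, "gain", ifelse(u < base, "loss", "neutral"))
  new_aneuploidy_calls(
    sample_id = karyotype$meta$sample_id %||% karyotype$stage,
    calls = stats::setNames(calls, names(base)),
    copy_number = stats::setNames(2 * u / base, names(base)),
    baseline = stats::setNames(rep(2, length(base)), names(base))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cell_karyotype <- function(x, ...) {
  u <- 2 * x$dyads + x$singles
  cat(sprintf("<cell_karyotype> stage=%s, %d dyads, %d singles%s\n",
              x$stage, sum(x$dyads), sum(x$singles),
              if (!is.null(x$paternal))
                sprintf(", paternal %d chromatids", sum(x$paternal)) else ""))
  ab <- names(u)[u != 2]
  if (length(ab) && is.null(x$paternal)) {
    cat(" maternal units != 2:", paste(ab, collapse = " "), "\n")
  }
  invisible(x)
}
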