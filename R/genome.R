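#' Construct a genome model
#'
#' A genome model is the coordinate frame for every other object in the
#' package: an ordered set of chromosomes with their lengths and a class
#' label (`autosome`, `X` or `Y`). Chromosome-level analyses never use
#' base-pair coordinates, only lengths.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length_bp Positive integer lengths in base pairs.
#' @param cls Character vector, each one of `"autosome"`, `"X"`, `"Y"`.
#'   Exactly one X is required; at most one Y.
#'
#' @return A `genome_model`: a data frame with columns `chrom`,
#'   `length_bp`, `cls`.
#' @examples
#' genome_model(c("1", "2", "X"), c(2e6, 1e6, 1.5e6),
#'              c("autosome", "autosome", "X"))
#' @export
genome_model <- function(chrom, length_bp, cls) {
  chrom <- as.character(chrom)
  length_bp <- as.numeric(length_bp)
  cls <- as.character(cls)
  if (length(chrom) != length(length_bp) || length(chrom) != length(cls)) {
    stop("chrom, length_bp and cls must have equal length", call. = FALSE)
  }
  if (anyDuplicated(chrom)) {
    stop("duplicate chromosome names: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(length_bp)) || any(length_bp <= 0)) {
    stop("all chromosome lengths must be positive", call. = FALSE)
  }
  if (!all(cls %in% c("autosome", "X", "Y"))) {
    stop("cls must be 'autosome', 'X' or 'Y'", call. = FALSE)
  }
  if (sum(cls == "X") != 1) stop("genome must have exactly one X", call. = FALSE)
  if (sum(cls == "Y") > 1) stop("genome may have at most one Y", call. = FALSE)
  g <- data.frame(chrom = chrom, length_bp = length_bp, cls = cls,
                  stringsAsFactors = FALSE)
  class(g) <- c("genome_model", "data.frame")
  g
}

#' Default mouse genome model
#'
#' The 19 autosomes plus X and Y of the GRCm38 mouse assembly, with
#' chromosome lengths in base pairs.
#'
#' @return A `genome_model` with 21 chromosomes.
#' @export
mouse_genome <- function() {
  genome_model(
    chrom = c(as.character(1:19), "X", "Y"),
    length_bp = c(195471971, 182113224, 160039680, 156508116, 151834684,
                  149736546, 145441459, 129401213, 124595110, 130694993,
                  122082543, 120129022, 120421639, 124902244, 104043685,
                  98207768, 94987271, 90702639, 61431566,
                  171031299, 91744698),
    cls = c(rep("autosome", 19), "X", "Y")
  )
}

#' Female (oocyte) genome: drop the Y chromosome
#'
#' Oocytes carry 19 autosomes and one X-pair; the Y only ever enters an
#' embryo through the sperm. All meiosis simulation runs on this reduced
#' genome.
#'
#' @param genome A `genome_model`.
#' @return A `genome_model` without the Y entry.
#' @export
oocyte_genome <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  g <- genome[genome$cls != "Y", , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("genome_model", "data.frame")
  g
}

is_autosome <- function(genome) genome$cls == "autosome"

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %d chromosomes (%d autosomes%s%s), %.1f Mb\n",
              nrow(x), sum(x$cls == "autosome"),
              if (any(x$cls == "X")) " + X" else "",
              if (any(x$cls == "Y")) " + Y" else "",
              sum(x$length_bp) / 1e6))
  print.data.frame(as.data.frame(x), ...)
  invisible(x)
}
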