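#' Sequencing noise model for per-chromosome counts
#'
#' Low-coverage single-cell libraries are modelled as a multinomial draw
#' of `depth` mapped reads over chromosomes, optionally overdispersed to
#' mimic whole-genome-amplification efficiency differences between
#' chromosomes: with `rho > 0`, each chromosome's expected proportion is
#' perturbed by an independent Gamma(shape = 1/rho, mean = 1) efficiency
#' factor before the multinomial draw, so `rho` is the squared
#' coefficient of variation of per-chromosome amplification efficiency
#' (`rho = 0.002` gives ~4.5% extra CV per chromosome; `rho = 0` is pure
#' multinomial sampling).
#'
#' @param depth Expected total mapped reads per sample (>= 1).
#' @param rho Overdispersion in `[0, 1)`.
#' @return A `noise_model` object.
#' @export
noise_model <- function(depth = 200000, rho = 0.002) {
  if (!is.numeric(depth) || length(depth) != 1 || is.na(depth) || depth < 1) {
    stop("depth must be a single number >= 1", call. = FALSE)
  }
  if (!is.numeric(rho) || length(rho) != 1 || is.na(rho) ||
      rho < 0 || rho >= 1) {
    stop("rho must lie in [0, 1)", call. = FALSE)
  }
  structure(list(depth = as.integer(round(depth)), rho = rho),
            class = "noise_model")
}

#' Expected read proportions of a karyotype
#'
#' The expected share of mapped reads per chromosome is proportional to
#' chromosome length times chromatid units (DNA mass): a retained extra
#' single chromatid raises a chromosome's share by half a copy. The
#' result sums to 1; chromosomes absent from the cell get 0.
#'
#' @param karyotype A `cell_karyotype`.
#' @param genome A `genome_model`.
#' @return Named numeric vector of proportions over `genome$chrom`.
#' @export
expected_proportions <- function(karyotype, genome) {
  u <- chromatid_units(karyotype, genome)
  bad <- setdiff(names(which(2 * karyotype$dyads + karyotype$singles > 0)),
                 genome$chrom)
  if (length(bad)) {
    stop("karyotype has content on chromosomes missing from the genome: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  w <- u * genome$length_bp
  if (sum(w) <= 0) stop("karyotype has no chromatin content", call. = FALSE)
  w / sum(w)
}

# Euploid chromatid units for a reference (somatic-scale) cell of a sex.
euploid_units <- function(genome, sex = c("female", "male")) {
  sex <- match.arg(sex)
  u <- stats::setNames(rep(2, nrow(genome)), genome$chrom)
  u[genome$cls == "Y"] <- 0
  if (sex == "male") {
    u[genome$cls == "X"] <- 1
    u[genome$cls == "Y"] <- 1
  }
  u
}

# Shared count draw over a fixed proportion vector.
draw_counts <- function(p, noise) {
  stopifnot(inherits(noise, "noise_model"))
  if (noise$rho > 0) {
    w <- numeric(length(p))
    pos <- p > 0
    shape <- 1 / noise$rho
    w[pos] <- stats::rgamma(sum(pos), shape = shape, rate = shape)
    p <- p * w
    p <- p / sum(p)
  }
  counts <- stats::rmultinom(1, size = noise$depth, prob = p)[, 1]
  stats::setNames(as.integer(counts), names(p))
}

#' Construct a per-chromosome count profile
#'
#' @param sample_id Sample label.
#' @param sex_label `"male"`, `"female"` or `"unknown"`.
#' @param counts Named non-negative integer vector over all chromosomes
#'   of the genome.
#' @return A `count_profile` with `total_mapped = sum(counts)`.
#' @export
count_profile <- function(sample_id, sex_label, counts) {
  sex_label <- match.arg(sex_label, c("male", "female", "unknown"))
  if (is.null(names(counts)) || any(counts < 0)) {
    stop("counts must be a named vector of non-negative integers",
         call. = FALSE)
  }
  structure(list(sample_id = sample_id, sex_label = sex_label,
                 counts = stats::setNames(as.integer(round(counts)),
                                          names(counts)),
                 total_mapped = as.integer(sum(counts))),
            class = "count_profile")
}

#' Simulate a low-coverage count profile from a karyotype
#'
#' @param karyotype A `cell_karyotype`.
#' @param noise A `noise_model`.
#' @param genome A `genome_model`.
#' @param sample_id Label; defaults to the karyotype's recorded id.
#' @return A `count_profile` whose counts sum exactly to `noise$depth`.
#'   Zygotes with a paternal Y are labelled `male`; all other cells
#'   `female`.
#' @export
simulate_counts <- function(karyotype, noise, genome,
                            sample_id = NULL) {
  p <- expected_proportions(karyotype, genome)
  counts <- draw_counts(p, noise)
  has_y <- !is.null(karyotype$paternal) &&
    "Y" %in% names(karyotype$paternal) && karyotype$paternal[["Y"]] > 0
  count_profile(
    sample_id = sample_id %||% karyotype$meta$sample_id %||% karyotype$stage,
    sex_label = if (has_y) "male" else "female",
    counts = counts
  )
}

#' Simulate a karyotypically normal reference cohort
#'
#' Euploid female (XX, no Y reads expected) and male (XY) count
#' profiles used to build the empirical copy-number reference.
#'
#' @param n_female,n_male Numbers of reference samples per sex
#'   (together >= 1).
#' @param noise A `noise_model`.
#' @param genome A `genome_model`.
#' @param seed Optional integer seed.
#' @return List of `count_profile`s, females first.
#' @export
simulate_reference_cohort <- function(n_female = 10, n_male = 10,
                                      noise = noise_model(),
                                      genome = mouse_genome(),
                                      seed = NULL) {
  if (n_female + n_male < 1) {
    stop("need at least one reference sample", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  one <- function(sex, i) {
    u <- euploid_units(genome, sex)
    p <- u * genome$length_bp
    p <- p / sum(p)
    count_profile(sprintf("ref_%s%02d", sex, i), sex, draw_counts(p, noise))
  }
  c(lapply(seq_len(n_female), function(i) one("female", i)),
    lapply(seq_len(n_male), function(i) one("male", i)))
}

#' @export
print.count_profile <- function(x, ...) {
  cat(sprintf("<count_profile> %s (%s), %d chromosomes, %d mapped reads\n",
              x$sample_id, x$sex_label, length(x$counts), x$total_mapped))
  invisible(x)
}
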