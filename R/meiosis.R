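#' Meiosis parameters
#'
#' Three probabilities govern how an oocyte segregates its chromosomes:
#'
#' * `p_bivalent` — probability that a homologue pair is tied into a
#'   crossover-linked bivalent at metaphase I. `1` models recombination-
#'   proficient control oocytes; `0` models recombination-null oocytes in
#'   which every chromosome persists as two unpaired univalents.
#' * `p_pssc` — probability that an individual univalent undergoes
#'   premature separation of its sister chromatids before anaphase I, so
#'   its two chromatids then segregate independently.
#' * `p_mii_ndj` — probability that a dyad nondisjoins at anaphase II
#'   (both chromatids drawn to the same spindle pole instead of one to
#'   the zygote and one to the second polar body).
#'
#' @param p_bivalent,p_pssc,p_mii_ndj Probabilities in `[0, 1]`.
#' @return A `meiosis_params` object.
#' @seealso [params_control()], [params_crossover_null()]
#' @export
meiosis_params <- function(p_bivalent = 1, p_pssc = 0, p_mii_ndj = 0) {
  p <- c(p_bivalent = p_bivalent, p_pssc = p_pssc, p_mii_ndj = p_mii_ndj)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("meiosis probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(as.list(p), class = "meiosis_params")
}

#' Preset: recombination-proficient control oocytes
#'
#' All chromosomes form bivalents; no premature sister separation, no
#' MII nondisjunction. Yields euploid eggs, polar bodies and zygotes.
#' @return A `meiosis_params` object.
#' @export
params_control <- function() meiosis_params(1, 0, 0)

#' Preset: crossover-null (univalent-only) oocytes
#'
#' No chromosome forms a bivalent; half of all univalents lose sister
#' cohesion prematurely. This is the regime where every metaphase II
#' egg ends up chromosomally abnormal and zygotes carry complex,
#' largely reciprocal aneuploidies with their polar bodies.
#' @param p_pssc Premature sister-separation probability per univalent.
#' @return A `meiosis_params` object.
#' @export
params_crossover_null <- function(p_pssc = 0.5) meiosis_params(0, p_pssc, 0)

#' Simulate the prophase/metaphase I configuration of one oocyte
#'
#' Each chromosome of the female genome independently forms a bivalent
#' with probability `p_bivalent`; otherwise it is present as two
#' univalents, each of which is independently flagged as having
#' prematurely separated sisters with probability `p_pssc`.
#'
#' Draws come from the session RNG; seed upstream (e.g. `set.seed()` or
#' the `seed` argument of [simulate_cohort()]).
#'
#' @param params A `meiosis_params` object.
#' @param genome A `genome_model`; its Y (if any) is excluded.
#' @return A `prophase_config`: data frame with columns `chrom`,
#'   `bivalent` (logical) and `sep1`, `sep2` (logical, `NA` for
#'   bivalents): premature sister separation of each univalent.
#' @export
simulate_prophase <- function(params, genome) {
  stopifnot(inherits(params, "meiosis_params"))
  fg <- oocyte_genome(genome)
  n <- nrow(fg)
  biv <- stats::runif(n) < params$p_bivalent
  sep1 <- ifelse(biv, NA, stats::runif(n) < params$p_pssc)
  sep2 <- ifelse(biv, NA, stats::runif(n) < params$p_pssc)
  cfg <- data.frame(chrom = fg$chrom, bivalent = biv,
                    sep1 = sep1, sep2 = sep2, stringsAsFactors = FALSE)
  class(cfg) <- c("prophase_config", "data.frame")
  cfg
}

#' Segregate chromosomes at anaphase I
#'
#' Reductional division of one oocyte. A bivalent sends exactly one
#' dyad to the egg and one to the first polar body. An intact univalent
#' goes whole (as a dyad) to the egg with probability 1/2, else to PB1.
#' A univalent whose sisters separated prematurely contributes two
#' single chromatids, each retained by the egg independently with
#' probability 1/2. Per chromosome, egg and PB1 chromatids always sum
#' to 4.
#'
#' @param config A `prophase_config` from [simulate_prophase()].
#' @return List with elements `egg` and `pb1`, both `cell_karyotype`s.
#' @export
segregate_mi <- function(config) {
  stopifnot(inherits(config, "prophase_config"))
  n <- nrow(config)
  chrom <- config$chrom
  egg_d <- integer(n); egg_s <- integer(n)
  pb1_d <- integer(n); pb1_s <- integer(n)

  biv <- config$bivalent
  egg_d[biv] <- 1L
  pb1_d[biv] <- 1L

  for (k in 1:2) {                      # the two univalents of each pair
    sep <- config[[paste0("sep", k)]]
    intact <- !biv & !sep
    # intact univalent: whole dyad flips one coin
    to_egg <- intact & (stats::runif(n) < 0.5)
    egg_d[to_egg] <- egg_d[to_egg] + 1L
    pb1_d[intact & !to_egg] <- pb1_d[intact & !to_egg] + 1L
    # separated univalent: its two chromatids segregate independently
    sepu <- !biv & sep
    s_egg <- integer(n)
    s_egg[sepu] <- stats::rbinom(sum(sepu), 2L, 0.5)
    egg_s <- egg_s + s_egg
    pb1_s[sepu] <- pb1_s[sepu] + 2L - s_egg[sepu]
  }

  egg <- cell_karyotype("MII_egg",
                        stats::setNames(egg_d, chrom),
                        stats::setNames(egg_s, chrom))
  pb1 <- cell_karyotype("PB1",
                        stats::setNames(pb1_d, chrom),
                        stats::setNames(pb1_s, chrom))
  list(egg = egg, pb1 = pb1)
}

#' Segregate at anaphase II and fertilise
#'
#' Equational division of an MII egg upon fertilisation. Each maternal
#' dyad normally splits, one chromatid to the zygote and one to the
#' second polar body; with probability `p_mii_ndj` it nondisjoins and
#' both chromatids go to the same product (either side with probability
#' 1/2). Each loose single chromatid goes to the zygote with
#' probability 1/2. The zygote then receives the paternal complement:
#' one chromatid per autosome plus one chromatid of the stated sex
#' chromosome. Maternal chromatids are conserved: zygote (maternal) +
#' PB2 equals the egg's chromatid units, chromosome by chromosome.
#'
#' @param egg A `cell_karyotype` of stage `MII_egg`.
#' @param params A `meiosis_params` object (only `p_mii_ndj` is used).
#' @param paternal_sex_chromosome `"X"` or `"Y"`.
#' @param genome A `genome_model` (supplies the paternal autosome set
#'   and sex-chromosome lengths).
#' @return List with elements `zygote` and `pb2`.
#' @export
segregate_mii_and_fertilise <- function(egg, params, paternal_sex_chromosome,
                                        genome) {
  stopifnot(inherits(egg, "cell_karyotype"), inherits(params, "meiosis_params"))
  if (egg$stage != "MII_egg") {
    stop("expected an MII egg, got stage '", egg$stage, "'", call. = FALSE)
  }
  sexchr <- match.arg(paternal_sex_chromosome, c("X", "Y"))
  chrom <- names(egg$dyads)
  n <- length(chrom)
  d <- as.integer(egg$dyads); s <- as.integer(egg$singles)

  ndj <- stats::rbinom(n, d, params$p_mii_ndj)       # nondisjoining dyads
  split <- d - ndj                                   # dyads that disjoin
  ndj_z <- stats::rbinom(n, ndj, 0.5)                # ndj dyads sent zygote-ward
  s_z <- stats::rbinom(n, s, 0.5)                    # singles retained by zygote

  zyg_m <- split + 2L * ndj_z + s_z
  pb2_m <- split + 2L * (ndj - ndj_z) + (s - s_z)

  pat_chrom <- c(genome$chrom[genome$cls == "autosome"], sexchr)
  paternal <- stats::setNames(rep(1L, length(pat_chrom)), pat_chrom)

  zygote <- cell_karyotype("zygote",
                           dyads = stats::setNames(integer(n), chrom),
                           singles = stats::setNames(zyg_m, chrom),
                           paternal = paternal)
  pb2 <- cell_karyotype("PB2",
                        dyads = stats::setNames(integer(n), chrom),
                        singles = stats::setNames(pb2_m, chrom))
  list(zygote = zygote, pb2 = pb2)
}

#' Simulate a cohort of oocytes through meiosis and fertilisation
#'
#' Runs `n` independent oocytes through prophase configuration,
#' anaphase I, and anaphase II plus fertilisation. The paternal sex
#' chromosome is X or Y with probability 1/2 each. All randomness comes
#' from one seeded generator so a fixed seed reproduces the cohort
#' bit-for-bit.
#'
#' @param n Number of oocytes (>= 1).
#' @param params A `meiosis_params` object.
#' @param genome A `genome_model`; default [mouse_genome()].
#' @param seed Optional integer seed, recorded in the output.
#' @return A `meiosis_cohort`: list with `oocytes` (each a list with
#'   `egg`, `pb1`, `zygote`, `pb2`, `paternal_sex_chromosome`),
#'   `params`, `genome`, `seed`.
#' @export
simulate_cohort <- function(n, params, genome = mouse_genome(), seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    stop("n must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  stopifnot(inherits(params, "meiosis_params"))
  if (!is.null(seed)) set.seed(seed)
  oocytes <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- simulate_prophase(params, genome)
    mi <- segregate_mi(cfg)
    sexchr <- if (stats::runif(1) < 0.5) "X" else "Y"
    mii <- segregate_mii_and_fertilise(mi$egg, params, sexchr, genome)
    id <- sprintf("oocyte%03d", i)
    mi$egg$meta$sample_id <- paste0(id, "_egg")
    mi$pb1$meta$sample_id <- paste0(id, "_pb1")
    mii$zygote$meta$sample_id <- paste0(id, "_zygote")
    mii$pb2$meta$sample_id <- paste0(id, "_pb2")
    oocytes[[i]] <- list(egg = mi$egg, pb1 = mi$pb1,
                         zygote = mii$zygote, pb2 = mii$pb2,
                         paternal_sex_chromosome = sexchr)
  }
  structure(list(oocytes = oocytes, params = params, genome = genome,
                 seed = seed),
            class = "meiosis_cohort")
}

#' @export
print.meiosis_cohort <- function(x, ...) {
  cat(sprintf(paste0("<meiosis_cohort> %d oocytes, p_bivalent=%g, ",
                     "p_pssc=%g, p_mii_ndj=%g%s\n"),
              length(x$oocytes), x$params$p_bivalent, x$params$p_pssc,
              x$params$p_mii_ndj,
              if (!is.null(x$seed)) sprintf(", seed=%d", x$seed) else ""))
  invisible(x)
}
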