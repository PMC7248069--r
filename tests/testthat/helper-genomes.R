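# Small genomes and karyotype builders used across tests.

# n_auto equal-length autosomes plus an X of the same length.
toy_genome <- function(n_auto = 3, len = 1e6, with_y = FALSE) {
  chrom <- c(as.character(seq_len(n_auto)), "X", if (with_y) "Y")
  genome_model(chrom, rep(len, length(chrom)),
               c(rep("autosome", n_auto), "X", if (with_y) "Y"))
}

# The 20-chromosome equal-length genome used for exact-arithmetic checks.
equal20_genome <- function(len = 1e6) toy_genome(n_auto = 19, len = len)

# A karyotype with the given chromatid units, stored as single chromatids.
units_karyotype <- function(units, stage = "MII_egg") {
  cell_karyotype(stage,
                 dyads = stats::setNames(integer(length(units)), names(units)),
                 singles = stats::setNames(as.integer(units), names(units)))
}

# Euploid MII egg (one dyad per chromosome) for a genome.
euploid_egg <- function(genome) {
  fg <- oocyte_genome(genome)
  cell_karyotype("MII_egg",
                 dyads = stats::setNames(rep(1L, nrow(fg)), fg$chrom),
                 singles = stats::setNames(integer(nrow(fg)), fg$chrom))
}

# A zygote with one paternal chromatid per autosome (+ sex chromosome) and
# maternal single-chromatid counts as given (default euploid: 1 each).
make_zygote <- function(genome, maternal = NULL, paternal_sex = "X") {
  fg <- oocyte_genome(genome)
  if (is.null(maternal)) {
    maternal <- stats::setNames(rep(1L, nrow(fg)), fg$chrom)
  }
  pat <- c(stats::setNames(rep(1L, sum(genome$cls == "autosome")),
                           genome$chrom[genome$cls == "autosome"]),
           stats::setNames(1L, paternal_sex))
  cell_karyotype("zygote",
                 dyads = stats::setNames(integer(nrow(fg)), fg$chrom),
                 singles = maternal, paternal = pat)
}

# Exact (noiseless) count profile: proportions times depth, which the
# caller must pick so that every count is an integer.
exact_profile <- function(id, sex, proportions, depth) {
  counts <- proportions * depth
  stopifnot(max(abs(counts - round(counts))) < 1e-6)
  count_profile(id, sex, round(counts))
}

# Exact euploid reference from one female and one male profile on an
# equal-length genome that includes a Y.
exact_reference <- function(genome, depth) {
  pf <- expected_proportions(units_karyotype(
    euploid_units_for(genome, "female"), "MII_egg"), genome)
  pm <- expected_proportions(units_karyotype(
    euploid_units_for(genome, "male"), "MII_egg"), genome)
  build_reference(list(exact_profile("f", "female", pf, depth),
                       exact_profile("m", "male", pm, depth)))
}

# Euploid somatic chromatid units by sex (2 per autosome; XX / XY).
euploid_units_for <- function(genome, sex) {
  u <- stats::setNames(rep(2L, nrow(genome)), genome$chrom)
  u[genome$cls == "Y"] <- 0L
  if (sex == "male") {
    u[genome$cls == "X"] <- 1L
    u[genome$cls == "Y"] <- 1L
  }
  u
}
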