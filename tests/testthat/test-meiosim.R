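test_that("meiosis parameters are validated", {
  expect_error(meiosis_params(p_bivalent = 1.2), "\\[0, 1\\]")
  expect_error(meiosis_params(p_pssc = -0.1), "\\[0, 1\\]")
  expect_equal(params_control()$p_bivalent, 1)
  expect_equal(params_crossover_null()$p_pssc, 0.5)
})

test_that("prophase configuration follows its degenerate probabilities", {
  g <- mouse_genome()
  set.seed(101)
  cfg <- simulate_prophase(params_control(), g)
  expect_equal(nrow(cfg), 20)          # oocyte genome: 19 autosomes + X
  expect_true(all(cfg$bivalent))
  cfg0 <- simulate_prophase(meiosis_params(0, 0, 0), g)
  expect_true(all(!cfg0$bivalent))
  expect_true(all(!cfg0$sep1) && all(!cfg0$sep2))
})

test_that("premature sister separation fires at the configured rate", {
  g <- mouse_genome()
  set.seed(102)
  seps <- replicate(500, {
    cfg <- simulate_prophase(meiosis_params(0, 0.5, 0), g)
    c(cfg$sep1, cfg$sep2)
  })
  n <- length(seps)                    # 20,000 univalent draws
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(seps) - 0.5), 3 * se)
})

test_that("anaphase I conserves four chromatids per chromosome", {
  g <- mouse_genome()
  set.seed(103)
  for (p in list(meiosis_params(1, 0, 0), meiosis_params(0, 0, 0),
                 meiosis_params(0, 1, 0), meiosis_params(0.4, 0.6, 0))) {
    for (i in 1:25) {
      mi <- segregate_mi(simulate_prophase(p, g))
      total <- chromatid_units(mi$egg, oocyte_genome(g)) +
        chromatid_units(mi$pb1, oocyte_genome(g))
      expect_true(all(total == 4))
    }
  }
})

test_that("all-bivalent configurations give euploid eggs and PB1s", {
  g <- mouse_genome()
  set.seed(104)
  mi <- segregate_mi(simulate_prophase(params_control(), g))
  expect_true(all(mi$egg$dyads == 1) && all(mi$egg$singles == 0))
  expect_true(all(mi$pb1$dyads == 1) && all(mi$pb1$singles == 0))
  expect_true(is_euploid(mi$egg, g))
})

test_that("intact univalents land in the egg as Bin(2, 1/2) dyads", {
  g <- toy_genome(n_auto = 1)
  set.seed(105)
  n <- 4000
  d <- replicate(n, {
    mi <- segregate_mi(simulate_prophase(meiosis_params(0, 0, 0), g))
    unname(mi$egg$dyads[["1"]])
  })
  # four equally likely univalent assignments: {0,1,2} w.p. {1/4,1/2,1/4}
  for (k in 0:2) {
    p <- c(0.25, 0.5, 0.25)[k + 1]
    expect_lt(abs(mean(d == k) - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("anaphase II splits dyads and fertilisation adds one paternal set", {
  g <- mouse_genome()
  fg <- oocyte_genome(g)
  set.seed(106)
  egg <- euploid_egg(g)
  out <- segregate_mii_and_fertilise(egg, params_control(), "X", g)
  u_z <- chromatid_units(out$zygote, g)
  expect_true(all(u_z[fg$chrom] == 2))      # 1 maternal + 1 paternal
  expect_equal(unname(u_z[["Y"]]), 0)
  expect_true(all(chromatid_units(out$pb2, fg) == 1))
  expect_true(is_euploid(out$zygote, g) && is_euploid(out$pb2, g))
})

test_that("a double-dyad chromosome yields a non-reciprocal double gain", {
  g <- mouse_genome()
  egg <- euploid_egg(g)
  egg$dyads[["1"]] <- 2L
  set.seed(107)
  out <- segregate_mii_and_fertilise(egg, meiosis_params(1, 0, 0), "X", g)
  # each of the two dyads splits deterministically: 2 chromatids each side
  expect_equal(unname(out$zygote$singles[["1"]]), 2)
  expect_equal(unname(out$pb2$singles[["1"]]), 2)
})

test_that("obligate MII nondisjunction is strictly reciprocal", {
  g <- mouse_genome()
  set.seed(108)
  for (i in 1:20) {
    out <- segregate_mii_and_fertilise(euploid_egg(g),
                                       meiosis_params(1, 0, 1), "X", g)
    z <- out$zygote$singles
    b <- out$pb2$singles
    expect_true(all(z %in% c(0, 2)))
    expect_true(all(z + b == 2))
  }
})

test_that("MII conserves the egg's maternal chromatids", {
  g <- mouse_genome()
  fg <- oocyte_genome(g)
  set.seed(109)
  for (i in 1:30) {
    mi <- segregate_mi(simulate_prophase(meiosis_params(0, 0.5, 0), g))
    out <- segregate_mii_and_fertilise(mi$egg, meiosis_params(0, 0.5, 0.2),
                                       "Y", g)
    lhs <- chromatid_units(out$zygote, fg, maternal_only = TRUE) +
      chromatid_units(out$pb2, fg)
    expect_equal(unname(lhs), unname(chromatid_units(mi$egg, fg)))
  }
})

test_that("control cohorts are euploid in all four products", {
  g <- mouse_genome()
  co <- simulate_cohort(200, params_control(), g, seed = 110)
  for (oo in co$oocytes) {
    expect_true(is_euploid(oo$egg, g) && is_euploid(oo$pb1, g) &&
                  is_euploid(oo$zygote, g) && is_euploid(oo$pb2, g))
  }
})

test_that("cohorts are reproducible from their seed and validated", {
  g <- toy_genome()
  a <- simulate_cohort(5, params_crossover_null(), g, seed = 111)
  b <- simulate_cohort(5, params_crossover_null(), g, seed = 111)
  expect_identical(a, b)
  expect_error(simulate_cohort(0, params_control(), g), ">= 1")
})

test_that("crossover-null eggs are essentially never euploid", {
  g <- mouse_genome()
  co <- simulate_cohort(1000, meiosis_params(0, 0, 0), g, seed = 112)
  # P(euploid egg) = 2^-20 per oocyte under all-intact univalents
  expect_equal(sum(vapply(co$oocytes, function(o) is_euploid(o$egg, g),
                          logical(1))), 0)
})

test_that("mii_summary counts chromosomes and loose chromatids", {
  g <- mouse_genome()
  egg <- euploid_egg(g)
  expect_equal(mii_summary(egg), list(n_chromosomes = 20L, n_chromatids = 0L))
  egg2 <- euploid_egg(g)
  egg2$dyads[["5"]] <- 0L
  egg2$singles[["5"]] <- 2L
  expect_equal(mii_summary(egg2),
               list(n_chromosomes = 19L, n_chromatids = 2L))
  pb <- cell_karyotype("PB1", egg$dyads, egg$singles)
  expect_error(mii_summary(pb), "MII egg")
})

test_that("obligate sister separation leaves no dyads and ~40 chromatids", {
  g <- mouse_genome()
  co <- simulate_cohort(300, meiosis_params(0, 1, 0), g, seed = 113)
  summ <- vapply(co$oocytes, function(o) unlist(mii_summary(o$egg)),
                 numeric(2))
  expect_true(all(summ["n_chromosomes", ] == 0))
  # per chromosome the egg keeps Bin(4, 1/2) chromatids: mean 2, var 1;
  # over 20 chromosomes mean 40, sd sqrt(20)
  se <- sqrt(20) / sqrt(ncol(summ))
  expect_lt(abs(mean(summ["n_chromatids", ]) - 40), 3 * se)
})
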