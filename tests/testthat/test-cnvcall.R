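# Equal-length genomes make the read-proportion arithmetic exact, so the
# doubling rule and renormalisation can be checked against closed forms.

test_that("reference building averages proportions per sex", {
  g <- toy_genome(n_auto = 18, with_y = TRUE)   # 20 chroms incl Y
  depth <- 38000                                # divisible by 38 units
  pf <- expected_proportions(units_karyotype(euploid_units_for(g, "female")),
                             g)
  pm <- expected_proportions(units_karyotype(euploid_units_for(g, "male")),
                             g)
  f <- exact_profile("f1", "female", pf, depth)
  m <- exact_profile("m1", "male", pm, depth)

  ref <- build_reference(list(f, m))
  expect_equal(unname(ref$female), unname(pf), tolerance = 1e-12)
  expect_equal(unname(ref$male), unname(pm), tolerance = 1e-12)

  # idempotence: duplicated profiles give the same reference
  ref2 <- build_reference(list(f, f, m, m))
  expect_equal(ref2$female, ref$female)
  expect_equal(ref2$male, ref$male)

  pooled <- build_reference(list(f, m), mode = "pooled")
  expect_equal(unname(pooled$pooled), unname((pf + pm) / 2),
               tolerance = 1e-12)

  expect_error(build_reference(list()), "no reference")
  expect_error(build_reference(list(f)), "each sex")
})

test_that("simulated references match the analytic expectation", {
  g <- mouse_genome()
  set.seed(301)
  refs <- simulate_reference_cohort(10, 10, noise_model(200000, 0), g)
  ref <- build_reference(refs)
  u <- euploid_units_for(g, "female")
  p <- u * g$length_bp / sum(u * g$length_bp)
  se <- sqrt(p * (1 - p) / 200000) / sqrt(10)
  auto <- g$chrom[g$cls == "autosome"]
  expect_true(all(abs(ref$female[auto] - p[auto]) <= 3 * se[auto]))
})

test_that("sex inference keys on the Y read share", {
  g <- toy_genome(n_auto = 18, with_y = TRUE)
  ref <- exact_reference(g, 38000)
  pm <- expected_proportions(units_karyotype(euploid_units_for(g, "male")), g)
  pf <- expected_proportions(units_karyotype(euploid_units_for(g, "female")),
                             g)
  expect_equal(infer_sex(exact_profile("m", "unknown", pm, 38000), ref),
               "male")
  expect_equal(infer_sex(exact_profile("f", "unknown", pf, 38000), ref),
               "female")
  expect_error(infer_sex(exact_profile("f", "unknown", pf, 38000),
                         build_reference(list(
                           exact_profile("a", "female", pf, 38000),
                           exact_profile("b", "male", pm, 38000)),
                           mode = "pooled")),
               "sex_matched")
})

test_that("euploid female samples at realistic noise are sexed female", {
  g <- mouse_genome()
  set.seed(302)
  ref <- build_reference(simulate_reference_cohort(10, 10,
                                                   noise_model(200000, 0), g))
  k <- units_karyotype(euploid_units_for(g, "female"))
  hits <- replicate(50, {
    prof <- simulate_counts(k, noise_model(200000, 0.002), g, sample_id = "f")
    infer_sex(prof, ref) == "female"
  })
  expect_true(all(hits))
})

test_that("the doubling rule recovers copy number 2 (female) and 1 (male X/Y)", {
  g <- toy_genome(n_auto = 18, with_y = TRUE)
  depth <- 38000
  ref <- exact_reference(g, depth)
  pf <- expected_proportions(units_karyotype(euploid_units_for(g, "female")),
                             g)
  pm <- expected_proportions(units_karyotype(euploid_units_for(g, "male")), g)

  cn_f <- predict_copy_number(exact_profile("f", "unknown", pf, depth), ref,
                              sex = "female")
  auto <- g$chrom[g$cls == "autosome"]
  expect_true(all(abs(cn_f$copy_number[c(auto, "X")] - 2) < 1e-9))
  expect_true(is.na(cn_f$copy_number[["Y"]]))   # absent from female reference

  cn_m <- predict_copy_number(exact_profile("m", "unknown", pm, depth), ref,
                              sex = "male")
  expect_true(all(abs(cn_m$copy_number[auto] - 2) < 1e-9))
  expect_lt(abs(cn_m$copy_number[["X"]] - 1), 1e-9)
  expect_lt(abs(cn_m$copy_number[["Y"]] - 1), 1e-9)
})

test_that("a single-chromatid gain renormalises to the closed-form values", {
  g <- equal20_genome()                 # 19 autosomes + X, equal lengths
  depth <- 820000                       # divisible by 41 and by 20
  u_eu <- stats::setNames(rep(2L, 20), g$chrom)
  p_eu <- expected_proportions(units_karyotype(u_eu), g)
  # the sample is compared against the female map only; the nominal male
  # entry just satisfies the sex_matched constructor on this Y-less genome
  ref <- build_reference(list(exact_profile("f1", "female", p_eu, depth),
                              exact_profile("m1", "male", p_eu, depth)))
  u3 <- u_eu; u3[["1"]] <- 3L
  p3 <- expected_proportions(units_karyotype(u3), g)
  cn <- predict_copy_number(exact_profile("s", "unknown", p3, depth), ref,
                            sex = "female")
  # hand derivation: sample shares are 3/41 vs reference 2/40, so
  # CN(chr1) = 2 * (3/41)/(1/20) = 120/41; others 80/41
  expect_lt(abs(cn$copy_number[["1"]] - 120 / 41), 1e-9)
  others <- setdiff(g$chrom, "1")
  expect_true(all(abs(cn$copy_number[others] - 80 / 41) < 1e-9))
})

test_that("inconsistent references are rejected", {
  g <- toy_genome(n_auto = 18, with_y = TRUE)
  ref <- exact_reference(g, 38000)
  pm <- expected_proportions(units_karyotype(euploid_units_for(g, "male")), g)
  # female comparison of a sample that carries Y reads
  expect_error(predict_copy_number(exact_profile("m", "unknown", pm, 38000),
                                   ref, sex = "female"),
               "absent from the female reference")
})

test_that("calls threshold relative deviation with sex-aware baselines", {
  cnp <- structure(list(
    sample_id = "s", sex_used = "female",
    ratio = c("1" = 1.25, "2" = 1, "3" = 0.7, "X" = 1),
    copy_number = c("1" = 2.5, "2" = 2, "3" = 1.4, "X" = 2)),
    class = "copy_number_profile")
  cs <- call_aneuploidy(cnp, call_thresholds(0.2))
  expect_equal(unname(cs$calls), c("gain", "neutral", "loss", "neutral"))
  expect_equal(cs$n_aneuploid, 2L)
  expect_equal(cs$complexity, "simple")

  # male baselines: X/Y euploid at copy number 1
  cnp_m <- structure(list(
    sample_id = "m", sex_used = "male",
    ratio = c("1" = 1, "X" = 1, "Y" = 1),
    copy_number = c("1" = 2, "X" = 1, "Y" = 1)),
    class = "copy_number_profile")
  cs_m <- call_aneuploidy(cnp_m, call_thresholds(0.2))
  expect_true(all(cs_m$calls == "neutral"))
  expect_equal(cs_m$complexity, "euploid")
})

test_that("complexity classes sit at the stated boundaries", {
  expect_equal(classify_complexity(0), "euploid")
  expect_equal(classify_complexity(1), "simple")
  expect_equal(classify_complexity(2), "simple")
  expect_equal(classify_complexity(3), "complex")
  expect_equal(classify_complexity(7), "complex")
  expect_error(classify_complexity(-1), "count")
})

test_that("calls are invariant to uniform count scaling", {
  g <- mouse_genome()
  set.seed(303)
  ref <- build_reference(simulate_reference_cohort(5, 5,
                                                   noise_model(200000, 0), g))
  z <- make_zygote(g)
  z$singles[["3"]] <- 2L
  prof <- simulate_counts(z, noise_model(200000, 0), g)
  prof10 <- count_profile(prof$sample_id, prof$sex_label, prof$counts * 10L)
  cs1 <- call_aneuploidy(predict_copy_number(prof, ref, "female"))
  cs10 <- call_aneuploidy(predict_copy_number(prof10, ref, "female"))
  expect_identical(cs1$calls, cs10$calls)
})

test_that("raising the threshold never adds calls", {
  g <- mouse_genome()
  set.seed(304)
  co <- simulate_cohort(1, params_crossover_null(), g)
  ref <- build_reference(simulate_reference_cohort(5, 5, noise_model(), g))
  cnp <- predict_copy_number(simulate_counts(co$oocytes[[1]]$zygote,
                                             noise_model(), g), ref)
  n_prev <- Inf
  for (d in c(0.05, 0.1, 0.2, 0.3, 0.5, 0.8)) {
    n <- call_aneuploidy(cnp, call_thresholds(d))$n_aneuploid
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("deep noiseless round trips recover every true call", {
  g <- mouse_genome()
  fg <- oocyte_genome(g)
  set.seed(305)
  ref <- build_reference(simulate_reference_cohort(10, 10,
                                                   noise_model(1e7, 0), g))
  thr <- call_thresholds(0.2)
  for (i in 1:1000) {
    mat <- stats::setNames(rep(1L, nrow(fg)), fg$chrom)
    k <- sample(0:3, 1)
    hit <- sample(fg$chrom, k)
    mat[hit] <- mat[hit] + sample(c(-1L, 1L), k, replace = TRUE)
    z <- make_zygote(g, maternal = mat,
                     paternal_sex = sample(c("X", "Y"), 1))
    z$meta$sample_id <- "z"
    prof <- simulate_counts(z, noise_model(1e7, 0), g)
    cs <- call_aneuploidy(predict_copy_number(prof, ref), thr)
    truth <- karyotype_calls(z, g)
    expect_identical(cs$calls[names(truth$calls)], truth$calls)
  }
})
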