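test_that("irreducibility matches the boolean-power oracle", {
  expect_true(is_irreducible(ppm(rbind(c(0.5, 2), c(0.3, 0)))))
  expect_false(is_irreducible(ppm(rbind(c(0.5, 0), c(0.3, 0.2)))))
  expect_true(is_irreducible(ppm(matrix(1))))

  set.seed(11)
  for (i in 1:30) {
    k <- sample(2:6, 1)
    A <- matrix(rexp(k * k), k, k)
    A[runif(k * k) < 0.6] <- 0   # sprinkle zeros so some cases are reducible
    expect_identical(is_irreducible(ppm(A)), brute_irreducible(A))
  }
})

test_that("primitivity distinguishes periodic from aperiodic life cycles", {
  expect_false(is_primitive(ppm(rbind(c(0, 2), c(0.3, 0)))))   # period 2
  expect_true(is_primitive(ppm(rbind(c(0.5, 2), c(0.3, 0)))))  # self-loop
  expect_true(is_primitive(ppm(matrix(1))))
  # 3-cycle without shortcut is periodic
  A3 <- rbind(c(0, 0, 5), c(0.3, 0, 0), c(0, 0.4, 0))
  expect_false(is_primitive(ppm(A3)))
  expect_error(is_primitive(ppm(rbind(c(0.5, 0), c(0.3, 0.2)))), "irreducible")
})

test_that("ergodicity is diagnosed by positivity of reproductive value", {
  expect_true(is_ergodic(ppm(rbind(c(0.5, 2), c(0.3, 0)))))
  expect_true(is_ergodic(ppm(matrix(1))))
  # reducible case: stage 1 cannot be reached from stage 2, v has a zero
  expect_false(is_ergodic(ppm(rbind(c(0.5, 0), c(0.3, 0.2)))))
})

test_that("seed problem detection follows the structural rule", {
  U <- rbind(c(0, 0, 0), c(0.2, 0.3, 0), c(0, 0.4, 0.8))
  Fm <- rbind(c(0, 0, 10), c(0, 0, 0), c(0, 0, 0))
  pm <- ppm(U + Fm, matU = U, matF = Fm)
  expect_true(detect_seed_problem(pm, 1))
  expect_true(detect_seed_problem(pm, "stage_1"))

  # recruitment entering seedlings directly is not the seed problem
  Fd <- rbind(c(0, 0, 0), c(0, 0, 6), c(0, 0, 0))
  pmd <- ppm(U + Fd, matU = U, matF = Fd)
  expect_false(detect_seed_problem(pmd, 1))

  # no designated seed stage: unknown, with a warning
  expect_warning(flag <- detect_seed_problem(pm, NULL), "metadata")
  expect_true(is.na(flag))
})

test_that("seed problem correction composes germination into recruitment", {
  # fecundity 10, germination 0.2, no seed-bank stasis
  U <- rbind(c(0, 0, 0), c(0.2, 0.3, 0), c(0, 0.4, 0.8))
  Fm <- rbind(c(0, 0, 10), c(0, 0, 0), c(0, 0, 0))
  pm <- ppm(U + Fm, matU = U, matF = Fm)
  cp <- correct_seed_problem(pm, 1)
  expect_equal(cp$matF[2, 3], 2)          # 10 * 0.2 direct recruitment
  expect_equal(cp$matF[1, 3], 0)          # seed row zeroed
  expect_equal(cp$matU, U)                # survival untouched
  expect_true(all(colSums(cp$matU) <= 1 + 1e-9))

  # with seed-bank stasis 0.5 the bank retains fecundity * stasis
  U2 <- U; U2[1, 1] <- 0.5
  pm2 <- ppm(U2 + Fm, matU = U2, matF = Fm)
  cp2 <- correct_seed_problem(pm2, 1)
  expect_equal(cp2$matF[2, 3], 2)
  expect_equal(cp2$matF[1, 3], 5)         # 10 * 0.5 residual seed input

  # first-generation recruit flow: corrected at t equals uncorrected at t+1
  adult <- c(0, 0, 1)
  uncorr <- project(pm, adult, 2)
  corr <- project(cp, adult, 1)
  expect_equal(corr$stage_vectors[2, 2], uncorr$stage_vectors[2, 3])

  # no seed problem: input returned unchanged
  pmd <- ppm(U + rbind(c(0, 0, 0), c(0, 0, 6), c(0, 0, 0)), matU = U,
             matF = rbind(c(0, 0, 0), c(0, 0, 6), c(0, 0, 0)))
  expect_identical(correct_seed_problem(pmd, 1)$A, pmd$A)
})

test_that("post- to pre-reproductive conversion applies the vital-rate rule", {
  # sigma = 1 (perfect survival): F_pre = F_post * g elementwise by column
  U <- rbind(c(0.5, 0), c(0.5, 1.0))
  Fp <- rbind(c(0, 4), c(0, 0))
  pm <- ppm(U + Fp, matU = U, matF = Fp, census = "post_reproductive")
  conv <- convert_post_to_pre(pm, g = c(0.5, 0))
  expect_equal(conv$matF[1, 2], 2)
  expect_equal(conv$census, "pre_reproductive")

  # sigma_2 = 0.8: phi = 4 / 0.8 = 5, F_pre = 5 * 0.5 = 2.5
  U2 <- rbind(c(0.1, 0), c(0.5, 0.8))
  pm2 <- ppm(U2 + Fp, matU = U2, matF = Fp, census = "post_reproductive")
  conv2 <- convert_post_to_pre(pm2, g = c(0.5, 0))
  expect_equal(conv2$matF[1, 2], 2.5)

  # already pre-reproductive: identity
  pre <- ppm(U + Fp, matU = U, matF = Fp, census = "pre_reproductive")
  expect_identical(convert_post_to_pre(pre), pre)

  # recruitment through a non-surviving stage is inconsistent
  U0 <- rbind(c(0.5, 0), c(0.2, 0))
  pm0 <- ppm(U0 + Fp, matU = U0, matF = Fp, census = "post_reproductive")
  expect_error(convert_post_to_pre(pm0), "non-surviving")

  # no split: passed through with a warning
  bare <- ppm(U + Fp, census = "post_reproductive")
  expect_warning(out <- convert_post_to_pre(bare), "unconverted")
  expect_true(isTRUE(attr(out, "conversion_skipped")))
})

test_that("conversion preserves lambda on consistent life cycles", {
  for (k in 2:6) {
    pm <- consistent_post_ppm(k, phi = 2.5, seed = 300 + k)
    pre <- convert_post_to_pre(pm)
    expect_equal(stable_growth_rate(pre), stable_growth_rate(pm),
                 tolerance = 1e-9)
    expect_true(all(pre$matF >= 0))
    expect_true(all(colSums(pre$matU) <= 1 + 1e-9))
  }
})

test_that("the filter engine applies and attributes every enabled rule", {
  mk <- function(id, ...) {
    base <- list(matrix_id = id, timestep_years = 1, pooled = FALSE,
                 setting = "field", matrix_type = "individual",
                 individuals_available = FALSE, treatment = "none",
                 pm = rand_ppm(3, 500 + nchar(id)))
    utils::modifyList(base, list(...))
  }
  reducible_pm <- ppm(rbind(c(0.5, 0), c(0.3, 0.2)))
  recs <- list(
    mk("a"),
    mk("b", setting = "greenhouse"),
    mk("c", pm = reducible_pm),
    mk("d"),
    mk("e")
  )
  out <- filter_records(recs)
  expect_equal(length(out$kept), 3)
  expect_equal(out$report$exclusion_reasons[out$report$matrix_id == "b"],
               "exclude_lab_greenhouse")
  expect_equal(out$report$exclusion_reasons[out$report$matrix_id == "c"],
               "exclude_reducible")
  expect_true(all(out$report$excluded ==
                    (out$report$exclusion_reasons != "")))

  # treatment keyword
  out2 <- filter_records(list(mk("f", treatment = "spring herbicide plots")))
  expect_equal(out2$report$exclusion_reasons, "exclude_manipulated")

  # missing metadata excludes conservatively with a named reason
  out3 <- filter_records(list(mk("g", pooled = NA)))
  expect_match(out3$report$exclusion_reasons, "missing_metadata:pooled")

  # non-integer timestep
  out4 <- filter_records(list(mk("h", timestep_years = 0.5)))
  expect_match(out4$report$exclusion_reasons, "require_annual_timestep")

  # all rules disabled keeps everything
  cfg_off <- filter_config(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(length(filter_records(recs, cfg_off)$kept), length(recs))

  # idempotence: filtering the kept set removes nothing
  again <- filter_records(out$kept)
  expect_equal(length(again$kept), length(out$kept))
})

test_that("filter configuration round-trips through its text form", {
  cfg <- filter_config(exclude_pooled = FALSE,
                       manipulation_keywords = c("burning", "mowing"))
  tf <- tempfile(fileext = ".yaml")
  write_filter_config(cfg, tf)
  back <- read_filter_config(tf)
  expect_identical(unclass(back), unclass(cfg))
})
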