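test_that("synthetic_spec validates the design", {
  p <- sfo_params(10, 0.5)
  expect_error(synthetic_spec(p), "seed")
  expect_error(synthetic_spec(p, times = c(1, 2, 3, 7), seed = 1), "include 0")
  expect_error(synthetic_spec(p, sigma = -1, seed = 1), ">= 0")
  sp <- synthetic_spec(p, seed = 1)
  expect_equal(sp$times, c(0, 1, 2, 3, 4, 7, 14, 21, 28))
  expect_equal(sp$n_replicates, 3L)
})

test_that("generation is deterministic and leaves the user RNG untouched", {
  sp <- synthetic_spec(sfo_params(10, 0.501), seed = 42)
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  tc1 <- simulate_timecourse(sp)
  after <- runif(1)
  tc2 <- simulate_timecourse(sp)
  expect_identical(tc1$concentration_mg_L, tc2$concentration_mg_L)
  expect_identical(before, after) # generator did not consume the user stream
  # byte-identical serialization
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_timecourse_csv(tc1, f1); write_timecourse_csv(tc2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("adding replicates never perturbs existing ones", {
  p <- hs_params(10, 0.7, 0.02, 3)
  tc3 <- simulate_timecourse(synthetic_spec(p, n_replicates = 3, seed = 7))
  tc5 <- simulate_timecourse(synthetic_spec(p, n_replicates = 5, seed = 7))
  for (r in as.character(1:3)) {
    expect_identical(tc3$concentration_mg_L[tc3$replicate == r],
                     tc5$concentration_mg_L[tc5$replicate == r])
  }
})

test_that("zero-noise generation is exact and round-trips through fitting", {
  cases <- list(sfo_params(10, 0.501),
                hs_params(10, 0.7, 0.02, 3),   # identifiable breakpoint
                fomc_params(10, 2.653, 17.547))
  for (p in cases) {
    model <- attr(p, "model")
    tc <- simulate_timecourse(synthetic_spec(p, sigma = 0, cv = 0, seed = 1))
    means <- summary_times(tc)
    expect_equal(means$concentration_mg_L,
                 predict_kin(p, means$time_days), tolerance = 1e-12)
    fit <- fit_kinetic(tc, model)
    for (nm in names(unclass(p)))
      expect_equal(fit$params[[nm]], p[[nm]], tolerance = 1e-4,
                   label = paste(model, nm))
    expect_equal(fit$dt50, dt50(p), tolerance = 1e-6)
  }
})

test_that("the additive noise level is reproduced empirically", {
  # M0 and K chosen so predictions stay far from the zero-clip
  p <- sfo_params(50, 0.02)
  draws <- sapply(1:400, function(s) {
    tc <- simulate_timecourse(synthetic_spec(p, n_replicates = 1, sigma = 0.2,
                                             cv = 0, seed = s))
    tc$concentration_mg_L
  })
  sds <- apply(draws, 1, sd)
  # sampling error of an SD at n = 400 is ~ sigma/sqrt(2n) ~ 0.007
  expect_true(all(abs(sds - 0.2) < 4 * 0.2 / sqrt(2 * 400)))
})

test_that("control series stay at M0 and are labelled as controls", {
  sp <- synthetic_spec(sfo_params(10, 0.5), sigma = 0, cv = 0, seed = 3,
                       control = TRUE)
  tc <- simulate_timecourse(sp)
  expect_true(attr(tc, "is_control"))
  expect_true(all(tc$concentration_mg_L == 10))
})

test_that("values below the detection limit are flagged", {
  tc <- simulate_timecourse(synthetic_spec(sfo_params(10, 1.5), sigma = 0,
                                           cv = 0, seed = 1))
  expect_true(any(tc$below_dl))
  expect_identical(tc$below_dl, tc$concentration_mg_L < 0.05)
})

test_that("dose-response generator is deterministic and validates the trend", {
  expect_error(simulate_dose_response("viability", 100, 10,
                                      doses = c(1, 10, 100), seed = 1),
               "must be < 0")
  expect_error(simulate_dose_response("luminescence_inhibition", 0, -5,
                                      doses = c(1, 10, 100), seed = 1),
               "must be > 0")
  s1 <- simulate_dose_response("viability", 120, -30,
                               doses = c(1, 10, 100, 1000), sigma = 3, seed = 5)
  s2 <- simulate_dose_response("viability", 120, -30,
                               doses = c(1, 10, 100, 1000), sigma = 3, seed = 5)
  expect_identical(s1$response, s2$response)
  expect_true(all(s1$response >= 0 & s1$response <= 120))
})

test_that("an IC50 beyond the tested doses sets the extrapolation flag", {
  s <- simulate_dose_response("viability", 90, -10, doses = c(1, 10, 100),
                              sigma = 0, seed = 1)
  est <- estimate_ic50(s) # crossing at 10^4, far above the dose range
  expect_true(est$extrapolated)
})

test_that("metabolite series follow formation-decay and censor below LOQ", {
  parent <- simulate_timecourse(synthetic_spec(sfo_params(10, 0.02),
                                               sigma = 0, cv = 0, seed = 1))
  out <- simulate_metabolites(parent, seed = 1)
  expect_named(out, c("1-OH-IBP", "2-OH-IBP", "CBX-IBP"))
  for (m in out) {
    vals <- m$concentration_ug_L
    expect_true(all(is.na(vals[m$censored])))
    expect_true(all(vals[!m$censored] >= attr(m, "loq")))
  }
  # closed-form check at one analyte/time: yield f, formation K, decay k
  f <- 0.01; K <- 0.02; k <- 0.05; t <- 14
  expected <- 1000 * f * 10 * K / (k - K) * (exp(-K * t) - exp(-k * t))
  got <- out[["1-OH-IBP"]]
  expect_equal(got$concentration_ug_L[got$time_days == 14], expected,
               tolerance = 1e-9)
})

test_that("zero yields censor everything; an undegraded parent makes none", {
  parent <- simulate_timecourse(synthetic_spec(sfo_params(10, 0.02),
                                               sigma = 0, cv = 0, seed = 1))
  out <- simulate_metabolites(parent,
                              yields = c("1-OH-IBP" = 0, "2-OH-IBP" = 0,
                                         "CBX-IBP" = 0), seed = 1)
  expect_true(all(vapply(out, function(m) all(m$censored), logical(1))))
  ctl <- simulate_timecourse(synthetic_spec(sfo_params(10, 0.5), sigma = 0,
                                            cv = 0, seed = 1, control = TRUE))
  out2 <- simulate_metabolites(ctl, seed = 1)
  expect_true(all(vapply(out2, function(m) all(m$censored), logical(1))))
})

test_that("a yield exists placing the 2-OH plateau in the observed field range", {
  # bisection on the yield fraction against the closed-form peak of the
  # formation-decay solution for a slowly degrading 10 mg/L parent
  K <- 0.02; k <- 0.05
  peak <- function(f) {
    tmax <- log(k / K) / (k - K)
    1000 * f * 10 * K / (k - K) * (exp(-K * tmax) - exp(-k * tmax))
  }
  lo <- 0; hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (peak(mid) < 190) lo <- mid else hi <- mid
  }
  f_star <- (lo + hi) / 2
  expect_gt(peak(f_star), 146); expect_lt(peak(f_star), 237)
  parent <- simulate_timecourse(synthetic_spec(sfo_params(10, K), sigma = 0,
                                               cv = 0, seed = 1,
                                               times = c(0, 1, 2, 3, 4, 7, 14,
                                                         21, 28, 35, 50)))
  out <- simulate_metabolites(parent,
                              yields = c("1-OH-IBP" = 0.01,
                                         "2-OH-IBP" = f_star,
                                         "CBX-IBP" = 0.009),
                              seed = 1)
  top <- max(out[["2-OH-IBP"]]$concentration_ug_L, na.rm = TRUE)
  expect_gt(top, 146); expect_lt(top, 237)
})
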