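test_that("causal marker selection applies the MAF-ratio rule", {
  # wild MAF 0.30 vs hybrid 0.10 -> ratio 3 eligible; 0.10/0.10 -> not
  wd <- cbind(mA = c(rep(1L, 6), rep(0L, 4)),   # freq 0.3
              mB = c(rep(1L, 2), rep(0L, 8)))   # freq 0.1
  hd <- cbind(mA = c(rep(1L, 2), rep(0L, 8)),   # freq 0.1
              mB = c(rep(1L, 2), rep(0L, 8)))   # freq 0.1
  w <- gm(wd, "wild"); h <- gm(hd)
  expect_identical(select_causal_marker(w, h, seed = 1), "mA")
  # with no eligible marker the error reports the best observed ratio
  expect_error(select_causal_marker(w[, "mB"], h[, "mB"]),
               "best observed ratio: 1")
})

test_that("phenotype noise variance follows the closed form", {
  g <- gm(cbind(mk = c(0L, 1L, 2L, 0L, 1L, 2L, 1L, 1L)))
  # noiseless limit: trait is an exact affine function of dosage
  ph1 <- simulate_phenotype(g, "mk", target_ve = 1, effect = 2, seed = 1)
  expect_equal(ph1$values, 2 * as.numeric(as.matrix(g)[, 1]))

  # dosage variance 0.5, effect 1, VE 0.5 -> sigma^2 = 0.5 exactly
  d <- c(0L, 1L, 1L, 1L, 2L)            # var(d) = 0.5
  expect_equal(var(as.numeric(d)), 0.5)
  gg <- gm(cbind(mk = d))
  ph <- simulate_phenotype(gg, "mk", target_ve = 0.5, seed = 42)
  set.seed(42)
  expect_equal(ph$values, as.numeric(d) + rnorm(5, 0, sqrt(0.5)))

  expect_error(simulate_phenotype(gm(cbind(mk = rep(1L, 5))), "mk", 0.5),
               "zero dosage variance")
  expect_error(simulate_phenotype(g, "mk", target_ve = 0), "0, 1")
})

test_that("realized variance explained recovers the target", {
  set.seed(3)
  g <- gm(cbind(mk = f2_dosage(2000)))
  for (ve in c(0.4, 0.8)) {
    ph <- simulate_phenotype(g, "mk", target_ve = ve, seed = round(100 * ve))
    expect_equal(realized_variance_explained(ph, as.matrix(g)[, 1]), ve,
                 tolerance = 0.05)
  }
  # identity and null cases
  expect_equal(realized_variance_explained(as.numeric(as.matrix(g)[, 1]),
                                           as.matrix(g)[, 1]), 1.0)
  set.seed(4)
  expect_lt(realized_variance_explained(rnorm(10000), f2_dosage(10000)), 0.01)
})

test_that("mean realized VE over 200 replicates is within 0.02 of target", {
  for (ve in c(0.4, 0.8)) {
    set.seed(1000 + round(ve * 10))
    r2 <- replicate(200, {
      d <- f2_dosage(500)
      g <- gm(cbind(mk = d))
      realized_variance_explained(simulate_phenotype(g, "mk", ve), d)
    })
    expect_equal(mean(r2), ve, tolerance = 0.02)
  }
})

test_that("trans-suppression removes the genetic term where the suppressor segregates", {
  set.seed(6)
  n <- 4000
  g <- gm(cbind(causal = f2_dosage(n), supp = f2_dosage(n)))
  ph <- simulate_phenotype(g, "causal", target_ve = 0.8, seed = 7)
  ps <- apply_trans_suppression(ph, g, "supp")
  # under 1:2:1 segregation about 75% of samples carry suppressor dosage > 0
  expect_equal(mean(ps$suppressed_mask), 0.75, tolerance = 3 * sqrt(0.75 * 0.25 / n))
  # suppressed samples retain pure noise: no causal correlation left
  sup <- ps$suppressed_mask
  expect_lt(abs(cor(ps$values[sup], as.matrix(g)[sup, "causal"])), 0.06)
  # unsuppressed samples are untouched
  expect_identical(ps$values[!sup], ph$values[!sup])
  # suppression can only reduce the realized VE
  expect_lt(realized_variance_explained(ps, as.matrix(g)[, "causal"]),
            realized_variance_explained(ph, as.matrix(g)[, "causal"]))
})

test_that("suppression edge cases behave per contract", {
  g <- gm(cbind(causal = c(0L, 1L, 2L, 1L), supp = rep(0L, 4)))
  ph <- simulate_phenotype(g, "causal", 0.5, seed = 1)
  ps <- apply_trans_suppression(ph, g, "supp")
  expect_identical(ps$values, ph$values)       # suppressor never expressed
  expect_false(any(ps$suppressed_mask))
  expect_error(apply_trans_suppression(ph, g, "causal"), "differ")
  # partial suppression attenuates rather than removes
  g2 <- gm(cbind(causal = c(0L, 2L, 2L, 0L), supp = c(2L, 2L, 2L, 2L)))
  ph2 <- simulate_phenotype(g2, "causal", 1, seed = 2)
  half <- apply_trans_suppression(ph2, g2, "supp", factor = 0.5)
  expect_equal(half$values, ph2$values - 0.5 * as.numeric(as.matrix(g2)[, 1]))
})

test_that("phenotype simulation is seed-deterministic", {
  g <- gm(cbind(mk = f2_dosage(50)))
  a <- simulate_phenotype(g, "mk", 0.4, seed = 123)
  b <- simulate_phenotype(g, "mk", 0.4, seed = 123)
  expect_identical(a$values, b$values)
})

test_that("suppressor selection avoids the causal marker's component", {
  tc <- toy_cross(seed = 9)
  causal <- select_causal_marker(tc$wild, tc$hybrid, seed = 1)
  filt <- suppressWarnings(filter_markers(tc$hybrid, causal_ids = causal,
                                          seed = 2))
  comp <- Filter(function(cmp) causal %in% cmp, filt$partition$components)[[1]]
  for (s in 1:5) {
    sup <- select_suppressor(tc$hybrid, causal, filt$partition, seed = s)
    expect_false(sup %in% comp)
  }
})
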