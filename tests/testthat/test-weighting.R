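test_that("top wild markers are ranked by absolute trait correlation", {
  d <- cbind(m1 = c(0, 0, 1, 1, 2, 2),    # equals the phenotype scale
             m2 = c(0, 2, 1, 0, 2, 1),
             m3 = c(1, 0, 1, 0, 1, 0))
  w <- gm(d, "wild")
  ph <- qtl_pheno(sample_ids(w), c(0, 0, 1, 1, 2, 2))
  expect_identical(top_wild_markers(w, ph, 1), "m1")
  expect_setequal(top_wild_markers(w, ph, 3), c("m1", "m2", "m3"))

  # constructed |r| ordering 0.9 / 0.5 / 0.1-ish: top two returned in order
  set.seed(14)
  n <- 300
  y <- rnorm(n)
  mk <- function(r) {
    x <- r * scale(y)[, 1] + sqrt(1 - r^2) * rnorm(n)
    as.integer(cut(x, quantile(x, c(0, 1/3, 2/3, 1)), include.lowest = TRUE)) - 1L
  }
  w2 <- gm(cbind(a = mk(0.9), b = mk(0.5), c = mk(0.1)), "wild")
  ph2 <- qtl_pheno(sample_ids(w2), y)
  expect_identical(top_wild_markers(w2, ph2, 2), c("a", "b"))
  expect_error(top_wild_markers(w2, qtl_pheno(sample_ids(w2), rep(1, n)), 2),
               "zero variance")
})

test_that("segregating samples are the phenotype tails", {
  ph <- qtl_pheno(paste0("s", 1:20), 1:20)
  expect_setequal(segregating_samples(ph, 0.05), c("s1", "s20"))
  expect_setequal(segregating_samples(ph, 0.05, "lower"), "s1")
  expect_setequal(segregating_samples(ph, 0.05, "upper"), "s20")
  expect_length(segregating_samples(ph, 0.499), 20)   # q -> 0.5 keeps all
  expect_error(segregating_samples(ph, 0.6), "0, 0.5")
  expect_error(segregating_samples(qtl_pheno("a", 1), 0.1), "constant")
})

test_that("Gower distance matches the printed formula on hand cases", {
  expect_equal(gower_distance(c(0, 2), c(2, 2), ranges = c(2, 2)), 0.5)
  expect_equal(gower_distance(c(0), c(2), ranges = 2), 1.0)
  expect_equal(gower_distance(c(1, 2, 0), c(1, 2, 0), ranges = c(2, 2, 2)), 0)
  # invalid markers (zero range / missing) are excluded by the delta weight
  expect_equal(gower_distance(c(0, 1), c(2, 1), ranges = c(2, 0)), 1.0)
  expect_equal(gower_distance(c(0, NA), c(2, 1), ranges = c(2, 2)), 1.0)
  expect_error(gower_distance(c(1), c(1), ranges = 0), "no valid markers")
})

test_that("Jaccard distance matches the printed formula on hand cases", {
  expect_equal(jaccard_distance(c(1, 0, 2), c(1, 1, 0)), 2 / 3)
  expect_equal(jaccard_distance(c(1, 0, 2), c(1, 0, 2)), 0)
  expect_equal(jaccard_distance(c(1, 0, 0), c(0, 2, 0)), 1)   # disjoint support
  expect_error(jaccard_distance(c(0, 0), c(0, 0)), "undefined")
})

test_that("both metrics agree with brute-force loops and are proper distances", {
  set.seed(15)
  for (trial in 1:200) {
    xi <- sample(0:2, 10, replace = TRUE)
    xj <- sample(0:2, 10, replace = TRUE)
    rng <- apply(rbind(xi, xj, sample(0:2, 10, TRUE)), 2,
                 function(z) diff(range(z)))
    if (any(rng > 0)) {
      g1 <- gower_distance(xi, xj, rng)
      expect_equal(g1, gower_loop(xi, xj, rng), tolerance = 1e-12)
      expect_equal(g1, gower_distance(xj, xi, rng))   # symmetry
      expect_true(g1 >= 0 && g1 <= 1)
      expect_equal(gower_distance(xi, xi, rng), 0)
    }
    if (any(xi > 0 | xj > 0)) {
      j1 <- jaccard_distance(xi, xj)
      expect_equal(j1, jaccard_loop(xi, xj), tolerance = 1e-12)
      expect_equal(j1, jaccard_distance(xj, xi))
      expect_true(j1 >= 0 && j1 <= 1)
    }
  }
})

test_that("mean distance averages pairwise distances to the reference set", {
  ctx <- distance_context(rbind(a = c(0, 0), b = c(2, 2), c = c(2, 0)))
  H <- rbind(h1 = c(0, 0))
  W <- rbind(w1 = c(2, 2), w2 = c(2, 0))   # distances 1.0 and 0.5
  expect_equal(unname(mean_distance(H, W, ctx, "gower")), 0.75)
  expect_equal(unname(mean_distance(H, W[1, , drop = FALSE], ctx, "gower")), 1)
  expect_equal(unname(mean_distance(W[1, , drop = FALSE], W, ctx, "gower")),
               0.25)
})

test_that("sampling probabilities follow the 1 - distance rule with baseline inclusion", {
  p <- sampling_probabilities(c(a = 0.2, b = 0.4, c = 0.8), rep(TRUE, 3))
  expect_equal(p$probabilities, c(0.5, 0.375, 0.125))
  expect_equal(sum(p$probabilities), 1, tolerance = 1e-9)

  # one filtered sample at distance 0 plus one unfiltered -> 50/50
  p2 <- sampling_probabilities(c(a = 0, b = 0.3), c(TRUE, FALSE))
  expect_equal(p2$probabilities, c(0.5, 0.5))

  # equal distances -> uniform
  p3 <- sampling_probabilities(rep(0.4, 5), rep(TRUE, 5))
  expect_equal(p3$probabilities, rep(0.2, 5))

  # strict reading: unfiltered samples excluded entirely
  p4 <- sampling_probabilities(c(0.2, 0.4), c(TRUE, FALSE),
                               exclude_unfiltered = TRUE)
  expect_equal(p4$probabilities, c(1, 0))

  # all raw weights zero falls back to uniform with a warning
  expect_warning(p5 <- sampling_probabilities(c(1, 1), c(TRUE, TRUE)),
                 "uniform")
  expect_equal(p5$probabilities, c(0.5, 0.5))
  expect_error(sampling_probabilities(c(0.2, 1.4), c(TRUE, TRUE)), "\\[0, 1\\]")
})

test_that("probabilities are monotone non-increasing in mean distance", {
  set.seed(16)
  for (trial in 1:20) {
    d <- runif(15)
    flt <- runif(15) < 0.7
    if (!any(flt)) flt[1] <- TRUE
    p <- sampling_probabilities(d, flt)
    di <- d[flt]; pi <- p$probabilities[flt]
    ord <- order(di)
    expect_true(all(diff(pi[ord]) <= 1e-12))
  }
})

test_that("weighted resampling respects point masses, probabilities and seeds", {
  set.seed(17)
  g <- random_panel(10, 4)
  ph <- qtl_pheno(sample_ids(g), rnorm(10))
  w <- sampling_probabilities(c(0, rep(1, 9)), rep(TRUE, 10))  # point mass on s1
  tr <- resample_training_set(g, ph, w, n_out = 25, seed = 1)
  expect_true(all(tr$index == 1))
  expect_equal(tr$values, rep(ph$values[1], 25))

  tr2 <- resample_training_set(g, ph, NULL, n_out = 20000, seed = 2)
  freq <- tabulate(tr2$index, 10) / 20000
  expect_true(all(abs(freq - 0.1) < 3 * sqrt(0.1 * 0.9 / 20000)))

  expect_identical(resample_training_set(g, ph, w, seed = 3)$index,
                   resample_training_set(g, ph, w, seed = 3)$index)
})

test_that("hybrid samples matching the wild trait-extreme genotypes get above-average probability", {
  # wild: causal dosage drives the trait; the upper-tail reference samples
  # carry causal dosage 2
  set.seed(18)
  n <- 40
  wd <- cbind(causal = rep(c(0L, 1L, 2L), length.out = n),
              noise1 = sample(0:2, n, TRUE), noise2 = sample(0:2, n, TRUE))
  w <- gm(wd, "wild")
  wph <- qtl_pheno(sample_ids(w), as.numeric(wd[, "causal"]) + rnorm(n, 0, 0.1))
  # hybrid: first 4 samples match the wild upper extreme at the causal
  # marker; the next 4 are intermediate and also pass the trait filter
  hd <- cbind(causal = c(rep(2L, 4), rep(1L, 4), rep(0L, 12)),
              noise1 = sample(0:2, 20, TRUE), noise2 = sample(0:2, 20, TRUE))
  h <- gm(hd)
  hph <- qtl_pheno(sample_ids(h), as.numeric(hd[, "causal"]) + rnorm(20, 0, 0.1))
  wts <- prioritize_samples(h, hph, w, wph,
                            weighting_config(top_marker_cutoff = 1,
                                             wild_seg_quantile = 0.2,
                                             hybrid_seg_quantile = 0.4,
                                             tail_mode = "upper"))
  expect_gt(mean(wts$probabilities[1:4]), mean(wts$probabilities))
})

test_that("weighting_config validates its domain", {
  expect_error(weighting_config(wild_seg_quantile = 0.6), "0, 0.5")
  expect_error(weighting_config(metric = "cosine"), "arg")
  expect_error(weighting_config(top_marker_cutoff = 0), "positive")
})

test_that("weights TSV round trip preserves probabilities", {
  p <- sampling_probabilities(c(a = 0.2, b = 0.4, c = 0.8), rep(TRUE, 3))
  path <- tempfile(fileext = ".tsv")
  write_weights_tsv(p, path)
  p2 <- read_weights_tsv(path)
  expect_equal(p2$probabilities, p$probabilities, tolerance = 1e-12)
  expect_identical(p2$sample_ids, p$sample_ids)
})
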