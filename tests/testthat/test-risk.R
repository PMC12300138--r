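test_that("distribution specs are validated and drawn correctly", {
  expect_error(check_dist_spec(list(normal = list(mean = 1, sd = 0)), "x"),
               "sd > 0")
  expect_error(check_dist_spec(list(triangular = list(min = 2, mode = 1,
                                                      max = 3)), "x"),
               "min <= mode")
  expect_error(check_dist_spec(list(gamma = list(shape = 1)), "x"),
               "unknown")

  expect_equal(draw_dist(list(value = 3.5), 10), rep(3.5, 10))
  set.seed(1)
  x <- draw_dist(list(normal = list(mean = 0.5, sd = 2)), 500)
  expect_true(all(x > 0))                      # truncated at zero
  y <- draw_dist(list(triangular = list(min = 2, mode = 5, max = 6)), 500)
  expect_true(all(y >= 2 & y <= 6))
  expect_equal(mean(y), (2 + 5 + 6) / 3, tolerance = 0.1)
  expect_equal(dist_mean(list(triangular = list(min = 2, mode = 5, max = 6))),
               13 / 3)
})

test_that("dose equations are linear in concentration and match arithmetic", {
  p <- list(IngR = 100, InhR = 7.6, SA = 2800, AF = 0.2, ABS = 0.001,
            EF = 350, ED = 6, BW = 15, AT = 2190, PEF = 1.36e9,
            CF = 1e-6, IR_food = 0.232)
  for (pw in c("ingest", "dermal", "inhale", "food")) {
    b <- if (pw == "food") 0.1 else NULL
    expect_equal(add_pathway(0, pw, p, bcf = b), 0)
    a1 <- add_pathway(10, pw, p, bcf = b)
    expect_equal(add_pathway(20, pw, p, bcf = b), 2 * a1)
  }
  # hand evaluation of the ingestion equation
  expect_equal(add_pathway(10, "ingest", p),
               10 * 100 * 350 * 6 * 1e-6 / (15 * 2190),
               tolerance = 1e-12)
  expect_equal(add_pathway(10, "ingest", p), 6.392694e-5, tolerance = 1e-6)
  expect_error(add_pathway(10, "food", p), "bcf")
})

test_that("hazard and cancer quotients aggregate conservatively", {
  expect_equal(hq(2e-4, 2e-4), 1)
  expect_equal(hi(rep(0.1, 8)), 0.8)
  expect_equal(cr(1e-5, 1.5), 1.5e-5)
  expect_equal(cr(0, 1.5), 0)
  expect_equal(hq(1, NA), 0)      # null reference: no contribution
  expect_error(hq(1, -1), "positive")

  d <- generate_soil_data(synthetic_config(n_sites = 10), seed = 8)
  r <- monte_carlo_risk(d$samples, "surface", "adult", n_iter = 200, seed = 3)
  expect_equal(mean(r$HI), sum(r$hq_metal_mean), tolerance = 1e-12)
  expect_equal(mean(r$HI), sum(r$hq_pathway_mean), tolerance = 1e-12)
  expect_equal(mean(r$TCR), sum(r$cr_metal_mean), tolerance = 1e-12)
  expect_equal(mean(r$TCR), sum(r$cr_pathway_mean), tolerance = 1e-12)
})

test_that("point distributions with mean concentration reproduce the
           deterministic pipeline exactly", {
  d <- generate_soil_data(synthetic_config(n_sites = 10), seed = 2)
  ex <- point_exposure()
  det <- deterministic_risk(d$samples, "surface", "child", exposure = ex)
  mc <- monte_carlo_risk(d$samples, "surface", "child", exposure = ex,
                         n_iter = 50, seed = 1, conc_mode = "mean")
  expect_equal(stats::sd(mc$HI), 0)            # every iteration identical
  expect_equal(mean(mc$HI), det$hi, tolerance = 1e-12)
  expect_equal(mean(mc$TCR), det$tcr, tolerance = 1e-12)
})

test_that("Monte Carlo summaries are reproducible under a fixed seed", {
  d <- generate_soil_data(synthetic_config(n_sites = 10), seed = 2)
  a <- monte_carlo_risk(d$samples, "deep", "adult", n_iter = 300, seed = 9)
  b <- monte_carlo_risk(d$samples, "deep", "adult", n_iter = 300, seed = 9)
  expect_identical(a$summary, b$summary)
  expect_identical(a$HI, b$HI)
})

test_that("simulated mean matches the closed form for a linear parameter", {
  # HI is linear in IngR when everything else is held at a point;
  # E[HI] must equal HI evaluated at E[IngR]
  d <- generate_soil_data(synthetic_config(n_sites = 10), seed = 2)
  ex <- point_exposure()
  ex$child$IngR <- list(normal = list(mean = 200, sd = 20))
  mc <- monte_carlo_risk(d$samples, "surface", "child", exposure = ex,
                         n_iter = 4000, seed = 5, conc_mode = "mean")
  ex0 <- point_exposure()
  ex0$child$IngR <- list(value = 200)   # the mean of the normal above
  det <- deterministic_risk(d$samples, "surface", "child", exposure = ex0)
  se <- stats::sd(mc$HI) / sqrt(mc$n_iter)
  expect_lt(abs(mean(mc$HI) - det$hi), 3 * se)
})

test_that("cumulative probability curves are monotone from ~0 to 1", {
  d <- generate_soil_data(synthetic_config(n_sites = 10), seed = 2)
  r <- monte_carlo_risk(d$samples, "surface", "child", n_iter = 500, seed = 2)
  for (ep in c("HI", "TCR")) {
    curve <- risk_curve(r, ep)
    expect_false(is.unsorted(curve$value))
    expect_false(is.unsorted(curve$prob))
    expect_equal(curve$prob[1], 1 / 500)
    expect_equal(curve$prob[nrow(curve)], 1)
  }
})

test_that("contribution fractions are proper and attribute dominance", {
  d <- generate_soil_data(synthetic_config(n_sites = 10), seed = 2)
  r <- monte_carlo_risk(d$samples, "surface", "child", n_iter = 500, seed = 2)
  for (by in c("metal", "pathway")) {
    fr <- risk_contributions(r, by)
    expect_true(all(fr$fraction >= 0))
    sums <- tapply(fr$fraction, fr$endpoint, sum)
    expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-12)
  }

  # single nonzero metal concentration -> that metal takes fraction 1
  tab <- as.data.frame(tiny_table(n = 3))
  tab[, soil_metals()] <- 0
  tab$As <- 20
  r1 <- monte_carlo_risk(sample_table(tab), "surface", "adult",
                         n_iter = 100, seed = 1)
  fr <- risk_contributions(r1, "metal")
  expect_equal(fr$fraction[fr$name == "As" & fr$endpoint == "HI"], 1)

  # a metal with a very low reference dose dominates the hazard index
  fr_def <- risk_contributions(r, "metal")
  as_share <- fr_def$fraction[fr_def$name == "As" & fr_def$endpoint == "HI"]
  expect_gt(as_share, 0.3)
})

test_that("crop 'none' disables the food pathway", {
  tab <- as.data.frame(tiny_table(n = 3))
  tab$crop_type <- "none"
  r <- monte_carlo_risk(sample_table(tab), "surface", "child",
                        n_iter = 100, seed = 1)
  expect_equal(unname(r$hq_pathway_mean["food"]), 0)
  expect_gt(unname(r$hq_pathway_mean["ingest"]), 0)
})

test_that("mean HI is stable across seeds at the default iteration count", {
  d <- generate_soil_data(seed = 1)
  his <- vapply(1:5, function(s) {
    mean(monte_carlo_risk(d$samples, "surface", "child",
                          n_iter = 10000, seed = s)$HI)
  }, numeric(1))
  expect_lt((max(his) - min(his)) / mean(his), 0.02)
})
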