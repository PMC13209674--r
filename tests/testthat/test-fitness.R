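test_that("MAE matches its closed form on scenario genes only", {
  expect_equal(mae_error(c(-1, 1), c(-1, 1)), 0) # perfect counteraction
  expect_equal(mae_error(c(-1, 1), c(0, 0)), 1)
  expect_equal(mae_error(c(-1), c(1)), 2) # maximal deviation at clip bounds
  # off-scenario genes (c = 0) never dilute the error
  expect_equal(mae_error(c(-1, 0, 0, 0), c(1, 1, 1, 1)), 2)
  expect_error(mae_error(c(0, 0), c(0, 0)), "nonzero")
})

test_that("waste penalty counts only same-direction overshoot", {
  # C = -1 with aligned credits -0.8 and -0.5: mass 1.3, overshoot 0.3
  A <- matrix(c(-0.8, -0.5), 1, 2)
  expect_equal(waste_penalty(c(-1), A), 0.3)
  # exact fulfillment -> no waste
  expect_equal(waste_penalty(c(-1), matrix(c(-0.6, -0.4), 1, 2)), 0)
  # opposite-signed credits contribute nothing
  expect_equal(waste_penalty(c(-1), matrix(c(0.9, 0.9), 1, 2)), 0)
  # symmetric for upregulation targets
  expect_equal(waste_penalty(c(1), matrix(c(0.8, 0.5), 1, 2)), 0.3)
})

test_that("mismatch penalty sums opposing credit magnitudes", {
  # C = +1, credits +0.6 and -0.2 -> mismatch 0.2
  expect_equal(mismatch_penalty(c(1), matrix(c(0.6, -0.2), 1, 2)), 0.2)
  expect_equal(mismatch_penalty(c(1), matrix(c(0.6, 0.2), 1, 2)), 0)
  # zero attributions belong to neither sign class
  expect_equal(mismatch_penalty(c(1), matrix(c(0.6, 0), 1, 2)), 0)
  # masked genes (C = 0) contribute nothing
  A <- matrix(c(0.5, -0.5), 2, 1)
  expect_equal(mismatch_penalty(c(1, 0), A), 0)
})

test_that("mismatch grows monotonically with opposing credit magnitude", {
  mags <- seq(0, 1, by = 0.1)
  vals <- vapply(
    mags,
    function(g) mismatch_penalty(c(1), matrix(c(0.6, -g), 1, 2)),
    numeric(1)
  )
  expect_true(all(diff(vals) >= 0))
})

test_that("entropy penalty has the uniform-share closed forms", {
  # one contributor -> H = 0
  expect_equal(entropy_penalty(c(1), matrix(c(0.7, 0), 1, 2)), 0)
  # n equal same-direction contributors -> H = log(n)
  expect_equal(entropy_penalty(c(1), matrix(c(0.4, 0.4), 1, 2)), log(2))
  expect_equal(entropy_penalty(c(1), matrix(c(0.2, 0.2, 0.2), 1, 3)), log(3))
  # opposing credit is excluded from the shares
  expect_equal(entropy_penalty(c(1), matrix(c(0.5, -0.3), 1, 2)), 0)
  # no same-direction mass -> H = 0 by convention
  expect_equal(entropy_penalty(c(1), matrix(c(-0.5, -0.3), 1, 2)), 0)
  # sums across genes
  A <- rbind(c(0.3, 0.3), c(0.5, 0))
  expect_equal(entropy_penalty(c(1, 1), A), log(2))
})

test_that("coverage rewards direction-correct fulfillment, capped per gene", {
  expect_equal(coverage_reward(c(1), matrix(c(0.5, 0), 1, 2)), 0.5)
  expect_equal(coverage_reward(c(1), matrix(c(0.6, 0.4), 1, 2)), 1)
  # overshoot earns no extra reward
  expect_equal(coverage_reward(c(1), matrix(c(0.9, 0.8), 1, 2)), 1)
  # per-gene weights scale each gene's cap
  A <- rbind(c(1, 0), c(0, 0.5))
  expect_equal(coverage_reward(c(1, -1), A, omega = c(2, 1)), 2)
  expect_equal(coverage_reward(c(1, 1), A, omega = c(2, 1)), 2.5)
  expect_error(coverage_reward(c(1), matrix(0.5), omega = -1), "omega")
})

test_that("usage, count and cost terms threshold on credited usage", {
  A <- matrix(c(0.4, 0.3, 0, 0, -0.2, 0.1), 2, 3,
    dimnames = list(NULL, c("a", "b", "c"))
  )
  u <- drug_usage(c(1, 1), A, epsilon = 1e-9)
  expect_equal(u$phi, c(a = 0.7, b = 0, c = 0.3))
  expect_equal(u$r_count, 2) # the null player is not counted
  expect_equal(u$r_cost, 0)
  u2 <- drug_usage(c(1, 1), A, costs = c(a = 1, c = -0.5, b = 100))
  expect_equal(u2$r_cost, 0.5) # 1 - 0.5; unused b's cost is ignored
  expect_error(drug_usage(c(1), matrix(1), epsilon = 0), "epsilon")
})

test_that("composite fitness reduces to MAE under MAE-only weights", {
  m <- random_effects(n_genes = 8, n_drugs = 5, seed = 21)
  scn <- random_scenario(m, 4, seed = 22)
  combos <- list("d01", c("d02", "d03"), c("d01", "d04", "d05"), m$drugs)
  for (combo in combos) {
    fb <- composite_fitness(m, scn, combo, weights = mae_only_weights())
    expect_equal(fb$composite_j, fb$mae)
  }
})

test_that("composite terms are invariant to drug order in the chromosome", {
  m <- random_effects(n_genes = 8, n_drugs = 5, seed = 31)
  scn <- random_scenario(m, 4, seed = 32)
  f1 <- glance(composite_fitness(m, scn, c("d01", "d03", "d05")))
  f2 <- glance(composite_fitness(m, scn, c("d05", "d01", "d03")))
  expect_equal(f1, f2)
})

test_that("adding a null-player drug changes only the count term", {
  m <- tiny_effects(cbind(c(-1, 0.5), c(0.3, -0.2), c(0, 0)))
  scn <- scenario("s", c(G01 = -1, G02 = 1))
  base <- glance(composite_fitness(m, scn, c("d01", "d02")))
  with_null <- glance(composite_fitness(m, scn, c("d01", "d02", "d03")))
  keep <- c(
    "mae", "r_waste", "r_mismatch", "r_entropy", "coverage", "r_count",
    "r_cost"
  )
  expect_equal(with_null[keep], base[keep])
  expect_equal(with_null$drug_count, 3)
})

test_that("a perfectly counteracting combination scores the ideal breakdown", {
  pl <- plant_scenario(n_genes = 4, planted_size = 2, seed = 3)
  fb <- composite_fitness(pl$effects, pl$scenario, pl$planted)
  expect_equal(fb$mae, 0)
  expect_equal(fb$r_waste, 0)
  expect_equal(fb$r_mismatch, 0)
  expect_equal(unname(fb$normalized["coverage"]), 1)
  # J = lambda * k/K - tau at defaults (entropy 0: one drug per gene)
  expect_equal(fb$r_entropy, 0)
  expect_equal(fb$composite_j, 0.05 * 2 / 6 - 0.2)
})

test_that("single-drug proportional credit never produces waste", {
  for (seed in 1:8) {
    m <- random_effects(n_genes = 6, n_drugs = 4, seed = 400 + seed)
    scn <- random_scenario(m, 4, seed = 500 + seed)
    for (d in m$drugs) {
      fb <- composite_fitness(m, scn, d)
      expect_equal(fb$r_waste, 0)
    }
  }
})

test_that("fitness breakdown tidiers expose all terms", {
  m <- tiny_effects(matrix(c(-0.5, 0.5), 1, 2))
  scn <- scenario("s", c(G01 = -1))
  fb <- composite_fitness(m, scn, c("d01", "d02"))
  td <- tidy(fb)
  expect_equal(nrow(td), 7)
  expect_named(td, c("term", "raw", "normalized"))
  gl <- glance(fb)
  expect_equal(gl$composite_j, fb$composite_j)
  expect_equal(gl$drug_count, 2)
})

test_that("weights must be non-negative and finite", {
  expect_error(fitness_weights(alpha = -1), "weights")
  expect_error(fitness_weights(tau = Inf), "weights")
})
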