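test_that("haplotype pool construction is deterministic and validated", {
  p1 <- suppressWarnings(haplotype_pool(seed = 1))
  p2 <- suppressWarnings(haplotype_pool(seed = 1))
  expect_identical(p1, p2)
  expect_equal(p1$n_snps, 24L)
  expect_true(all(p1$maf >= 0.1 & p1$maf <= 0.5))
  expect_error(haplotype_pool(n_snps = 1), "at least 2")
  expect_error(haplotype_pool(maf_range = c(0, 0.6)), "maf_range")
  expect_error(haplotype_pool(adjacent_r = 1), "adjacent_r")
})

test_that("zero adjacent correlation gives independent loci", {
  pool <- haplotype_pool(n_snps = 6, adjacent_r = 0, seed = 3)
  set.seed(4)
  h <- draw_haplotypes(pool, 100000)
  r <- sapply(1:5, function(j) cor(h[, j], h[, j + 1]))
  expect_true(all(r^2 < 0.01))
})

test_that("the Markov chain hits a feasible adjacent correlation target", {
  pool <- haplotype_pool(n_snps = 6, maf_range = c(0.3, 0.3),
                         adjacent_r = 0.9, seed = 5)
  set.seed(6)
  h <- draw_haplotypes(pool, 100000)
  r <- sapply(1:5, function(j) cor(h[, j], h[, j + 1]))
  expect_true(all(abs(r - 0.9) < 0.05))
})

test_that("infeasible targets are clipped with a warning", {
  expect_warning(haplotype_pool(n_snps = 4, maf_range = c(0.05, 0.5),
                                adjacent_r = 0.95, seed = 7), "clipped")
})

test_that("simulated genotypes follow Hardy-Weinberg proportions", {
  pool <- haplotype_pool(n_snps = 4, maf_range = c(0.3, 0.3),
                         adjacent_r = 0.5, seed = 9)
  g <- simulate_genotypes(pool, 50000, seed = 10)
  counts <- table(factor(g$dosages[, 2], levels = 0:2))
  freq <- counts / 50000
  expected <- c(0.49, 0.42, 0.09)
  expect_true(all(abs(freq - expected) < 0.01))
  chi <- chisq.test(counts, p = expected)
  expect_gt(chi$p.value, 0.01)
})

test_that("genotype simulation is deterministic and honours n = 0", {
  pool <- suppressWarnings(haplotype_pool(seed = 11))
  g1 <- simulate_genotypes(pool, 50, seed = 12)
  g2 <- simulate_genotypes(pool, 50, seed = 12)
  expect_identical(g1$dosages, g2$dosages)
  g0 <- simulate_genotypes(pool, 0)
  expect_equal(dim(g0), c(0L, 24L))
  expect_equal(g0$snp_ids, pool$snp_ids)
  expect_equal(g0$positions, pool$positions)
})

test_that("trait model validates its covariance", {
  expect_error(trait_model(delta = -0.1), "non-negative")
  expect_error(trait_model(sigma = matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)),
               "positive-definite")
  tm <- trait_model()
  expect_equal(unname(diag(tm$sigma)), c(100, 64, 12.25))
  expect_equal(tm$causal_index, 6L)
})

test_that("the causal allele shifts BMI and waist additively, hip untouched", {
  pool <- haplotype_pool(n_snps = 8, maf_range = c(0.3, 0.4),
                         adjacent_r = 0.5, seed = 13)
  g <- simulate_genotypes(pool, 30000, seed = 14)
  delta <- 0.30
  tm <- trait_model(delta = delta, causal_index = 6)
  ph <- simulate_phenotypes(g, tm, seed = 15)
  dose <- g$dosages[, 6]
  mc_se <- function(v, a, b) sqrt(var(v[dose == a]) / sum(dose == a) +
                                  var(v[dose == b]) / sum(dose == b))
  dbmi <- mean(ph$bmi[dose == 2]) - mean(ph$bmi[dose == 0])
  expect_lt(abs(dbmi - 2 * delta), 3 * mc_se(ph$bmi, 2, 0))
  dwaist <- mean(ph$waist[dose == 2]) - mean(ph$waist[dose == 0])
  expect_lt(abs(dwaist - tm$b_waist_per_bmi * 2 * delta),
            3 * mc_se(ph$waist, 2, 0))
  dhip <- mean(ph$hip[dose == 2]) - mean(ph$hip[dose == 0])
  expect_lt(abs(dhip), 3 * mc_se(ph$hip, 2, 0))

  # delta = 0: BMI means equal across genotype groups
  ph0 <- simulate_phenotypes(g, trait_model(delta = 0), seed = 16)
  d0 <- mean(ph0$bmi[dose == 2]) - mean(ph0$bmi[dose == 0])
  expect_lt(abs(d0), 3 * mc_se(ph0$bmi, 2, 0))
})

test_that("phenotype simulation is reproducible under a fixed seed", {
  pool <- suppressWarnings(haplotype_pool(seed = 17))
  g <- simulate_genotypes(pool, 100, seed = 18)
  ph1 <- simulate_phenotypes(g, trait_model(delta = 0.2), seed = 19)
  ph2 <- simulate_phenotypes(g, trait_model(delta = 0.2), seed = 19)
  expect_identical(ph1, ph2)
})

test_that("rejection-rate drivers respect their preconditions and limits", {
  pool <- suppressWarnings(haplotype_pool(n_snps = 8, seed = 21))
  expect_error(estimate_type1_error(pool, trait_model(delta = 0.1)),
               "delta = 0")
  expect_error(estimate_type1_error(pool, trait_model(), n_reps = 10),
               "at least 100")
  expect_error(estimate_power(pool, trait_model(delta = 0)), "delta > 0")
  expect_error(estimate_power(pool, trait_model(delta = 0.2,
                                                causal_index = 7),
                              window = c(1, 4)), "inside the window")
  # alpha = 1 always rejects, alpha = 0 never
  s1 <- estimate_type1_error(pool, trait_model(), n = 150, window = c(2, 5),
                             alpha = 1, n_reps = 100, n_boot = 20, seed = 1)
  expect_equal(s1$rate, 1)
  s0 <- estimate_type1_error(pool, trait_model(), n = 150, window = c(2, 5),
                             alpha = 1e-12, n_reps = 100, n_boot = 20,
                             seed = 1)
  expect_equal(s0$rate, 0)
  expect_equal(s1$rate * s1$n_reps, s1$rejections)
})

test_that("the replication loop is seed-reproducible", {
  pool <- suppressWarnings(haplotype_pool(n_snps = 8, seed = 23))
  a <- estimate_type1_error(pool, trait_model(), n = 200, window = c(2, 6),
                            alpha = 0.05, n_reps = 100, n_boot = 50,
                            seed = 77)
  b <- estimate_type1_error(pool, trait_model(), n = 200, window = c(2, 6),
                            alpha = 0.05, n_reps = 100, n_boot = 50,
                            seed = 77)
  expect_identical(a$rate, b$rate)
})

test_that("a YAML-style config drives the simulation grid", {
  cfg <- list(n_snps = 8, adjacent_r = 0.5, pool_seed = 1,
              window = c(2, 6), delta = 0, n = 150, alpha = c(0.05, 1),
              n_reps = 100, n_boot = 20, seed = 5)
  tab <- run_simulation_config(cfg)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$rate[tab$alpha == 1], 1)
  expect_true(all(tab$rate >= 0 & tab$rate <= 1))
})
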