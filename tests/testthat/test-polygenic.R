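test_that("polygenic fit returns the full schema with standardized scores", {
  reg <- make_region(n = 300, delta = 0.4, seed = 19, n_snps = 12)
  fit <- polygenic_fit(reg$geno, reg$traits, n_boot = 100, seed = 1)
  expect_s3_class(fit, "polygenic_fit")
  expect_length(fit$snp_loadings, 12)
  expect_length(fit$trait_loadings, 3)
  expect_length(fit$beta21, 1)
  expect_equal(mean(fit$prs), 0, tolerance = 1e-10)
  expect_equal(sd(fit$prs), 1, tolerance = 1e-10)
  expect_equal(mean(fit$bss), 0, tolerance = 1e-10)
  expect_equal(sd(fit$bss), 1, tolerance = 1e-10)
  expect_equal(unname(fit$indirect_effects),
               unname(fit$snp_loadings) * fit$beta21)
  expect_equal(fit$r_squared, fit$beta21^2, tolerance = 1e-10)
  # the boot table covers the path and every loading
  expect_equal(nrow(fit$boot), 1 + 12 + 3)
  # unweighted baseline is positively associated with the weighted PRS
  # (weak, since the loading vector has mixed signs under LD)
  expect_gt(cor(allele_count_score(reg$geno), fit$prs), 0)
})

test_that("PRS is invariant to SNP column order", {
  reg <- make_region(n = 200, delta = 0.4, seed = 23, n_snps = 6)
  fit1 <- polygenic_fit(reg$geno, reg$traits, n_boot = 0)
  set.seed(1); ord <- sample(6)
  geno2 <- genotype_matrix(reg$geno$dosages[, ord],
                           snp_ids = reg$geno$snp_ids[ord],
                           positions = sort(reg$geno$positions))
  fit2 <- polygenic_fit(geno2, reg$traits, n_boot = 0)
  expect_equal(fit2$prs, fit1$prs, tolerance = 1e-8)
  expect_equal(fit2$snp_loadings[reg$geno$snp_ids],
               fit1$snp_loadings[reg$geno$snp_ids], tolerance = 1e-8)
})

test_that("the trait-driving SNP carries the largest loading", {
  set.seed(29)
  n <- 500
  d <- matrix(rbinom(n * 5, 2, 0.3), n, 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  geno <- genotype_matrix(d, positions = seq_len(5) * 100L)
  base <- MASS::mvrnorm(n, c(100, 104, 28), diag(c(100, 64, 12.25)))
  traits <- cbind(waist = base[, 1] + 2 * d[, 3],
                  hip = base[, 2],
                  bmi = base[, 3] + 1.5 * d[, 3])
  fit <- polygenic_fit(geno, traits, n_boot = 0)
  expect_equal(which.max(abs(fit$snp_loadings)), 3L, ignore_attr = TRUE)
  # agreement with a per-SNP correlation ranking oracle
  r <- sapply(1:5, function(j) abs(cor(d[, j], fit$bss)))
  expect_equal(order(-abs(fit$snp_loadings)), order(-r))
})

test_that("indirect effects are exactly bilinear", {
  expect_equal(indirect_effect(0.5, 0.1), 0.05)
  expect_equal(indirect_effect(1, 0.3), 2 * indirect_effect(0.5, 0.3))
  expect_equal(indirect_effect(0, 123), 0)
  expect_equal(indirect_effect(c(0.2, -0.4), 0.5), c(0.1, -0.2))
})

test_that("body shape score reduces correctly in collapse cases", {
  set.seed(41)
  w <- rnorm(50, 100, 10)
  same <- cbind(waist = w, hip = w, bmi = w)
  expect_equal(body_shape_score(same, c(1, 1, 1)),
               drop(scale(w)), tolerance = 1e-10, ignore_attr = TRUE)
  tr <- cbind(waist = w, hip = rnorm(50, 104, 8), bmi = rnorm(50, 28, 3))
  expect_equal(body_shape_score(tr, c(1, 0, 0)),
               drop(scale(w)), tolerance = 1e-10, ignore_attr = TRUE)
  # published-style loadings against a direct arithmetic oracle
  lam <- c(0.9817, 0.7525, 0.8443)
  s <- drop(scale(tr) %*% lam)
  expect_equal(body_shape_score(tr, lam), (s - mean(s)) / sd(s),
               tolerance = 1e-10)
  # reporting-scale transform
  rs <- body_shape_score(tr, lam, center = 60, scale = 5)
  expect_equal(mean(rs), 60, tolerance = 1e-10)
  expect_equal(sd(rs), 5, tolerance = 1e-10)
  expect_error(body_shape_score(tr[, 1:2], lam), "3 columns")
  expect_error(body_shape_score(cbind(w, w, w)[c(1, 1, 1), ], lam))
})

test_that("body types partition the BMI x WHR grid", {
  th <- body_type_thresholds()
  expect_equal(classify_body_type(20, 0.7, "female", th)$code, 1L)
  expect_equal(classify_body_type(35, 1.2, "male", th)$code, 9L)
  # boundaries are lower-inclusive for the upper stratum
  expect_equal(classify_body_type(25, 0.85, "male", th)$code, 4L)
  expect_equal(classify_body_type(30, 0.85, "female", th)$code, 9L)
  # exhaustive 3 x 3 enumeration per sex
  for (sex in c("male", "female")) {
    cuts <- if (sex == "male") th$whr_cuts_male else th$whr_cuts_female
    bmis <- c(20, 27, 33)
    whrs <- c(cuts[1] - 0.05, mean(cuts), cuts[2] + 0.05)
    grid <- expand.grid(b = 1:3, w = 1:3)
    codes <- classify_body_type(bmis[grid$b], whrs[grid$w], sex, th)$code
    expect_setequal(codes, 1:9)
    expect_equal(codes, (grid$b - 1L) * 3L + grid$w)
  }
  expect_error(classify_body_type(-1, 0.9, "male", th), "positive")
  expect_error(body_type_thresholds(bmi_cuts = c(30, 25)), "ascending")
})

test_that("body type table counts sum to n within sex", {
  set.seed(43)
  n <- 200
  bmi <- runif(n, 18, 38)
  whr <- runif(n, 0.6, 1.2)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  bss <- rnorm(n)
  tab <- body_type_table(bmi, whr, sex, bss)
  for (s in c("male", "female")) {
    sel <- tab$sex == s
    expect_equal(sum(tab$n[sel]), sum(sex == s))
    expect_equal(sum(tab$pct[sel]), 100, tolerance = 1e-10)
  }
  # CI brackets the mean where defined
  ok <- !is.na(tab$ci_lo)
  expect_true(all(tab$ci_lo[ok] <= tab$bss_mean[ok]))
})

test_that("PRS effect table slope matches an independent OLS solve", {
  reg <- make_region(n = 300, delta = 0.5, seed = 47, n_snps = 8)
  fit <- polygenic_fit(reg$geno, reg$traits, n_boot = 0)
  pe <- prs_effect_table(fit, n_bins = 5)
  cf <- oracle_ols(fit$bss, fit$prs)
  expect_equal(pe$slope, cf[2], tolerance = 1e-10)
  expect_equal(sum(pe$table$n), length(fit$prs))
  # identity case
  id <- list(prs = fit$bss, bss = fit$bss)
  expect_equal(prs_effect_table(id)$slope, 1, tolerance = 1e-10)
  expect_error(prs_effect_table(list(prs = rep(1, 10), bss = rnorm(10))),
               "constant")
})
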