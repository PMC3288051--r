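test_that("model construction validates blocks and paths", {
  expect_error(plspm_model(list(a = "x", b = "x"), c("a", "b")), "unique")
  expect_error(plspm_model(list(a = "x", b = "y"),
                           rbind(c("a", "b"), c("b", "a"))), "DAG")
  expect_error(plspm_model(list(a = "x", b = "y"), c("a", "c")), "unknown")
  expect_error(plspm_model(list(a = "x", b = "y"),
                           matrix(character(0), 0, 2)), "at least one")
  m <- plspm_model(list(a = "x", b = "y"), c("a", "b"), modes = c("B", "A"))
  expect_s3_class(m, "plspm_model")
  expect_equal(unname(m$modes), c("B", "A"))
})

test_that("single-indicator two-block fit equals the Pearson correlation", {
  m <- plspm_model(list(a = "x", b = "y"), c("a", "b"))
  for (s in 1:20) {
    set.seed(s)
    x <- matrix(rnorm(120), 60, 2, dimnames = list(NULL, c("x", "y")))
    f <- plspm_fit(x, m)
    r <- cor(x[, 1], x[, 2])
    expect_lt(abs(unname(coef(f)) - r), 1e-10)
    expect_lt(abs(unname(f$r_squared) - coef(f)^2), 1e-10)
  }
})

test_that("perfectly dependent single-indicator blocks give beta 1", {
  set.seed(3)
  g <- rnorm(50)
  x <- cbind(x = g, y = g)
  f <- plspm_fit(x, plspm_model(list(a = "x", b = "y"), c("a", "b")))
  expect_equal(unname(coef(f)), 1, tolerance = 1e-12)
  expect_equal(unname(f$loadings), c(1, 1), tolerance = 1e-12)
})

test_that("fit matches the naive data-space Lohmoeller oracle", {
  x <- make_mvn_fixture(n = 200, p1 = 3, p2 = 3, seed = 42)
  m <- plspm_model(list(one = paste0("g", 1:3), two = paste0("t", 1:3)),
                   c("one", "two"))
  f <- plspm_fit(x, m, tol = 1e-12, maxit = 1000)
  o <- oracle_two_block(x, 3, tol = 1e-12)
  expect_lt(abs(unname(coef(f)) - o$beta), 1e-8)
  expect_lt(max(abs(unname(f$loadings) - o$loadings)), 1e-8)
  expect_lt(max(abs(f$scores - o$scores)), 1e-7)
})

test_that("specialized two-block core agrees with the generic core", {
  for (s in c(5, 17)) {
    x <- make_mvn_fixture(n = 150, p1 = 4, p2 = 2, seed = s)
    xs <- standardize(x)
    R <- crossprod(xs) / (nrow(xs) - 1)
    m <- plspm_model(list(one = paste0("g", 1:4), two = paste0("t", 1:2)),
                     c("one", "two"))
    a <- plspmscan:::.plspm_core(R, m, tol = 1e-8, maxit = 500)
    b <- plspmscan:::.two_block_core(R, 4, 1e-8, 500)
    expect_equal(unname(a$paths[1]), b$beta, tolerance = 1e-10)
    expect_equal(unname(a$loadings), unname(b$loadings), tolerance = 1e-10)
    # and both agree with the closed-form eigenvector solution
    e <- plspmscan:::.two_block_eigen(R[1:4, 1:4], R[1:4, 5:6, drop = FALSE],
                                      R[5:6, 5:6])
    expect_equal(e$beta, b$beta, tolerance = 1e-7)
    expect_equal(unname(e$loadings), unname(b$loadings), tolerance = 1e-7)
  }
})

test_that("mode-A loadings are manifest-latent correlations and scores are standardized", {
  x <- make_mvn_fixture(n = 200, p1 = 3, p2 = 3, seed = 9)
  m <- plspm_model(list(one = paste0("g", 1:3), two = paste0("t", 1:3)),
                   c("one", "two"))
  f <- plspm_fit(x, m)
  xs <- standardize(x)
  for (j in 1:3) {
    expect_lt(abs(f$loadings[paste0("g", j)] -
                  cor(xs[, paste0("g", j)], f$scores[, "one"])), 1e-10)
    expect_lt(abs(f$loadings[paste0("t", j)] -
                  cor(xs[, paste0("t", j)], f$scores[, "two"])), 1e-10)
  }
  expect_true(all(abs(colMeans(f$scores)) < 1e-10))
  expect_true(all(abs(apply(f$scores, 2, sd) - 1) < 1e-10))
  expect_true(f$converged)
  expect_lt(f$n_iterations, 300)
  # sign convention: per-block loading sums non-negative
  expect_gte(sum(f$loadings[paste0("g", 1:3)]), 0)
  expect_gte(sum(f$loadings[paste0("t", 1:3)]), 0)
})

test_that("fit is invariant to positive rescaling of raw columns", {
  x <- make_mvn_fixture(n = 120, p1 = 2, p2 = 2, seed = 13)
  m <- plspm_model(list(one = c("g1", "g2"), two = c("t1", "t2")),
                   c("one", "two"))
  f1 <- plspm_fit(x, m)
  x2 <- x
  x2[, "g1"] <- 37.5 * x2[, "g1"]
  x2[, "t2"] <- 0.004 * x2[, "t2"]
  f2 <- plspm_fit(x2, m)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  expect_equal(f1$loadings, f2$loadings, tolerance = 1e-10)
})

test_that("flipping one block's manifests flips the path sign, loadings restored", {
  x <- make_mvn_fixture(n = 120, p1 = 3, p2 = 3, seed = 21)
  m <- plspm_model(list(one = paste0("g", 1:3), two = paste0("t", 1:3)),
                   c("one", "two"))
  f1 <- plspm_fit(x, m)
  x2 <- x
  x2[, paste0("g", 1:3)] <- -x2[, paste0("g", 1:3)]
  f2 <- plspm_fit(x2, m)
  # sign-fixing anchors each block to its own loading sum, so loadings are
  # reproduced and the cross-block path changes sign
  expect_equal(f1$loadings, f2$loadings, tolerance = 1e-8)
  expect_equal(unname(coef(f1)), -unname(coef(f2)), tolerance = 1e-8)
})

test_that("all inner schemes coincide for two-block models", {
  x <- make_mvn_fixture(n = 150, p1 = 3, p2 = 3, seed = 31)
  for (sch in c("factorial", "path")) {
    m1 <- plspm_model(list(one = paste0("g", 1:3), two = paste0("t", 1:3)),
                      c("one", "two"), scheme = "centroid")
    m2 <- plspm_model(list(one = paste0("g", 1:3), two = paste0("t", 1:3)),
                      c("one", "two"), scheme = sch)
    expect_equal(coef(plspm_fit(x, m1)), coef(plspm_fit(x, m2)),
                 tolerance = 1e-8)
  }
})

test_that("three-latent chain fits with per-target OLS path coefficients", {
  set.seed(55)
  n <- 250
  a <- rnorm(n); b <- 0.6 * a + 0.8 * rnorm(n); c <- 0.5 * b + 0.9 * rnorm(n)
  x <- cbind(a1 = a + rnorm(n, sd = .3), a2 = a + rnorm(n, sd = .3),
             b1 = b + rnorm(n, sd = .3), b2 = b + rnorm(n, sd = .3),
             c1 = c + rnorm(n, sd = .3), c2 = c + rnorm(n, sd = .3))
  m <- plspm_model(list(A = c("a1", "a2"), B = c("b1", "b2"),
                        C = c("c1", "c2")),
                   rbind(c("A", "B"), c("B", "C")), scheme = "path")
  f <- plspm_fit(x, m)
  expect_true(f$converged)
  # single-predecessor OLS slope equals the latent correlation
  expect_equal(unname(coef(f)["A -> B"]),
               unname(f$latent_cor["A", "B"]), tolerance = 1e-10)
  expect_equal(unname(f$r_squared["B"]), unname(coef(f)["A -> B"]^2),
               tolerance = 1e-10)
  # residuals of each endogenous latent are orthogonal to its predictors
  r <- residuals(f)
  expect_lt(abs(cor(r[, "B"], f$scores[, "A"])), 1e-10)
  expect_lt(abs(cor(r[, "C"], f$scores[, "B"])), 1e-10)
})

test_that("covariate adjustment removes a confounder-driven association", {
  set.seed(77)
  n <- 400
  age <- rnorm(n)
  x <- cbind(g1 = age + rnorm(n), t1 = age + rnorm(n))
  m <- plspm_model(list(one = "g1", two = "t1"), c("one", "two"))
  raw <- plspm_fit(x, m)
  adj <- plspm_fit(x, m, covariates = cbind(age = age))
  expect_gt(abs(coef(raw)), 0.3)
  # adjusted path equals the correlation of the residualized columns
  res <- residualize(x, cbind(age = age))
  expect_equal(unname(coef(adj)), cor(res[, 1], res[, 2]),
               tolerance = 1e-10)
  expect_lt(abs(coef(adj)), abs(coef(raw)) / 2)
  # predict() on training data reproduces the scores
  pr <- predict(adj, x, covariates = cbind(age = age))
  expect_equal(unname(pr), unname(adj$scores), tolerance = 1e-10)
})

test_that("fit warns when n does not exceed the manifest count", {
  x <- make_mvn_fixture(n = 5, p1 = 3, p2 = 3, seed = 2)
  m <- plspm_model(list(one = paste0("g", 1:3), two = paste0("t", 1:3)),
                   c("one", "two"))
  expect_warning(plspm_fit(x, m), "unstable")
})
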