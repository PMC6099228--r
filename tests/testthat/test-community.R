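test_that("Bray-Curtis dissimilarity matches hand-computed values", {
  m <- rbind(u1 = c(2, 1, 0), u2 = c(0, 1, 1), u3 = c(2, 1, 0),
             u4 = c(0, 0, 5))
  D <- as.matrix(bray_curtis(m))
  expect_equal(D["u1", "u2"], 3 / 5)      # |2-0|+|1-1|+|0-1| over 2+2+1
  expect_equal(D["u1", "u3"], 0)          # identical units
  expect_equal(D["u1", "u4"], 1)          # disjoint supports
  expect_error(bray_curtis(rbind(c(1, 0), c(0, 0))), "all-zero")
  expect_error(bray_curtis(rbind(c(1, 0), c(-1, 2))), "negative")
})

test_that("SIMPER reproduces the single-pair hand computation", {
  m <- rbind(a = c(2, 0), b = c(0, 2))
  sm <- simper_bc(m, c("A", "B"), n_perm = 49, seed = 1)
  expect_equal(sm$contribution, c(0.5, 0.5))
  expect_equal(sm$cumulative, c(0.5, 1.0))
  expect_equal(attr(sm, "mean_dissimilarity"), 1)
  same <- simper_bc(rbind(c(3, 1), c(3, 1)), c("A", "B"), n_perm = 9, seed = 1)
  expect_equal(attr(same, "mean_dissimilarity"), 0)
  expect_equal(same$contribution, c(0, 0))
  expect_error(simper_bc(m, c("A", "A")), "two groups")
})

test_that("SIMPER contributions sum to the mean between-group dissimilarity", {
  set.seed(20)
  for (i in 1:20) {
    m <- matrix(rpois(8 * 5, 3), 8, 5)
    m[rowSums(m) == 0, 1] <- 1
    g <- rep(c("A", "B"), each = 4)
    sm <- simper_bc(m, g, n_perm = 0, seed = 1)
    D <- as.matrix(vegan::vegdist(m, "bray"))
    expect_equal(sum(sm$contribution), mean(D[1:4, 5:8]), tolerance = 1e-12)
  }
})

test_that("SIMPER contributions agree with the vegan reference", {
  set.seed(30)
  m <- matrix(rpois(10 * 6, 4), 10, 6,
              dimnames = list(paste0("u", 1:10), paste0("sp", 1:6)))
  g <- rep(c("A", "B"), each = 5)
  mine <- simper_bc(m, g, n_perm = 0, seed = 1)
  ref <- summary(vegan::simper(m, g, permutations = 0))$A_B
  expect_equal(mine$contribution[match(rownames(ref), mine$species)],
               unname(ref$average), tolerance = 1e-10)
})

test_that("SIMPER permutation p-values are uniform under the null", {
  set.seed(40)
  pvals <- c()
  for (rep in 1:40) {
    m <- matrix(rpois(10 * 5, 5), 10, 5)
    g <- sample(rep(c("A", "B"), each = 5))
    sm <- simper_bc(m, g, n_perm = 200, seed = rep)
    pvals <- c(pvals, sm$permutation_p)
  }
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
  expect_true(all(pvals > 0))  # +1 convention: never exactly zero
})

test_that("dbRDA on Euclidean distances equals direct linear RDA", {
  set.seed(50)
  for (i in 1:20) {
    n <- sample(8:15, 1)
    p <- sample(2:4, 1)
    Y <- matrix(rnorm(n * 5), n, 5)
    X <- matrix(rnorm(n * p), n, p)
    D <- dist(Y)
    got <- dbrda_bc(D, X, n_perm = 0)
    Yc <- scale(Y, scale = FALSE)
    R2 <- sum(qr.fitted(qr(cbind(1, X)), Yc)^2) / sum(Yc^2)
    expect_equal(got$constrained_proportion, R2, tolerance = 1e-6)
    # exact inertia decomposition
    expect_equal(got$conditioned + got$constrained + got$residual,
                 got$total, tolerance = 1e-8 * got$total)
  }
})

test_that("dbRDA agrees with vegan's constrained ordination on Bray-Curtis data", {
  set.seed(60)
  m <- matrix(rpois(20 * 6, 4), 20, 6)
  m[rowSums(m) == 0, 1] <- 1
  X <- data.frame(x1 = rnorm(20), x2 = factor(rep(c("a", "b"), 10)))
  D <- vegan::vegdist(m, "bray")
  got <- dbrda_bc(D, X, n_perm = 0)
  ref <- vegan::capscale(D ~ x1 + x2, data = X)
  expect_equal(got$constrained_proportion,
               unname(ref$CCA$tot.chi / (ref$CCA$tot.chi + ref$CA$tot.chi)),
               tolerance = 1e-6)
  expect_equal(got$pseudo_F,
               unname(vegan::anova.cca(ref, permutations = 1)$F[1]),
               tolerance = 1e-6)
})

test_that("conditioning a design out of itself leaves nothing to explain", {
  set.seed(70)
  Y <- matrix(rnorm(12 * 4), 12, 4)
  X <- matrix(rnorm(12 * 2), 12, 2)
  got <- dbrda_bc(dist(Y), X, Z = X, n_perm = 0)
  expect_lt(got$constrained_proportion, 1e-10)
})

test_that("dbRDA permutation p-values are uniform when X is pure noise", {
  set.seed(80)
  Y <- matrix(rnorm(15 * 4), 15, 4)
  D <- dist(Y)
  pvals <- vapply(1:120, function(i) {
    X <- matrix(rnorm(15), 15, 1)
    dbrda_bc(D, X, n_perm = 99, seed = i)$permutation_p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
  expect_true(all(pvals > 0))
})

test_that("collinear explanatory columns are dropped with a warning", {
  set.seed(90)
  Y <- matrix(rnorm(10 * 3), 10, 3)
  X <- cbind(a = rnorm(10), b = 0)
  X <- cbind(X, c = X[, "a"] * 2)
  expect_warning(got <- dbrda_bc(dist(Y), X, n_perm = 0), "collinear")
  expect_equal(got$df_model, 1L)
})
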