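test_that("interaction extraction follows the hyperparasitism definition", {
  s <- make_samples(
    make_sample("a", primary_species = "APuzb", hyper_species = "DEcar"),
    make_sample("b", primary_species = "APuzb;EPpla", hyper_species = "DEcar",
                endo_hd = 1L),
    make_sample("c", status = "mummy", hyper_species = "ALspp"),  # no primary ID
    make_sample("d", hyper_species = "DEcar"),                    # unparasitized
    make_sample("e", primary_species = "PRvol"))                  # no hyper
  expect_message(i <- extract_interactions(s), "1 hyperparasitized")
  expect_equal(nrow(i), 3L)  # a: 1 pair, b: 2 pairs
  expect_equal(sum(i$source_sample_id == "b"), 2L)
  expect_equal(attr(i, "n_hyper_without_primary"), 1L)
  expect_equal(attr(i, "n_hyper_on_unparasitized"), 1L)
  expect_true(all(i$fe_infected[i$source_sample_id == "b"]))
  i1 <- extract_interactions(s, multiplicity = "single")
  expect_equal(nrow(i1), 2L)
})

test_that("degenerate and constant-covariate sources propagate exactly", {
  ints <- make_interactions(rep("APuzb", 8), rep("DEcar", 8),
                            fe = TRUE, fert = TRUE)
  w <- resample_webs(ints, n_webs = 50, web_size = 20, seed = 3)
  expect_true(all(w$H2prime == 0))     # single-pair web: degenerate convention
  expect_true(all(w$prop_fe == 1))
  expect_true(all(w$prop_fert == 1))
  expect_true(all(w$prop_date2 == 0))
  expect_error(resample_webs(ints[0, ]), "empty interaction")
})

test_that("resampling is seed-reproducible and extends without reshuffling", {
  ints <- make_interactions(c("APuzb", "EPpla", "PRvol", "APuzb", "APerv"),
                            c("DEcar", "ALspp", "ASvul", "PHvil", "DEcar"),
                            fe = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  a <- resample_webs(ints, n_webs = 40, web_size = 30, seed = 9)
  b <- resample_webs(ints, n_webs = 40, web_size = 30, seed = 9)
  expect_identical(a, b)
  longer <- resample_webs(ints, n_webs = 80, web_size = 30, seed = 9)
  expect_identical(longer[1:40, ], a)
})

test_that("covariate proportions follow the binomial sampling law", {
  n <- 200
  set.seed(5)
  ints <- make_interactions(sample(c("APuzb", "EPpla"), n, TRUE),
                            sample(c("DEcar", "ALspp"), n, TRUE),
                            fe = c(rep(TRUE, 60), rep(FALSE, 140)))  # 30%
  w <- resample_webs(ints, n_webs = 10000, web_size = 100, seed = 6)
  se_pooled <- sqrt(0.3 * 0.7 / 100) / sqrt(10000)
  expect_lt(abs(mean(w$prop_fe) - 0.30), 3 * se_pooled)
  # proportions are multiples of 1/web_size
  expect_true(all(abs(w$prop_fe * 100 - round(w$prop_fe * 100)) < 1e-9))
})

test_that("resampling summaries are exchangeable over input order", {
  set.seed(11)
  ints <- make_interactions(sample(c("APuzb", "EPpla", "PRvol"), 120, TRUE),
                            sample(c("DEcar", "ALspp"), 120, TRUE),
                            fe = runif(120) < 0.4)
  a <- resample_webs(ints, n_webs = 3000, web_size = 100, seed = 21)
  perm <- ints[sample(nrow(ints)), ]
  b <- resample_webs(perm, n_webs = 3000, web_size = 100, seed = 22)
  se <- sqrt(var(a$H2prime) / 3000 + var(b$H2prime) / 3000)
  expect_lt(abs(mean(a$H2prime) - mean(b$H2prime)), 4 * se)
  expect_lt(abs(var(a$H2prime) - var(b$H2prime)),
            0.5 * (var(a$H2prime) + var(b$H2prime)))
})

test_that("a planted linear effect of infection on H2' is recovered by OLS", {
  set.seed(8)
  n <- 10000
  prop_fe <- rbinom(n, 100, 0.4) / 100
  rows <- data.frame(H2prime = 0.2 + 0.5 * prop_fe + rnorm(n, 0, 0.05),
                     prop_fe = prop_fe, prop_fert = runif(n),
                     prop_complex = runif(n), prop_date2 = runif(n))
  fit <- fit_h2_model(rows)
  expect_true("prop_fe" %in% fit$selected_terms)
  slope <- fit$coefficients[["prop_fe"]]
  se <- summary(fit$fit)$coefficients["prop_fe", "Std. Error"]
  expect_lt(abs(slope - 0.5), 3 * se)
})

test_that("AIC selection keeps models honest under the null", {
  set.seed(12)
  n <- 10000
  rows <- data.frame(H2prime = rnorm(n, 0.3, 0.05),
                     prop_fe = rbinom(n, 100, 0.4) / 100,
                     prop_fert = rbinom(n, 100, 0.5) / 100,
                     prop_complex = rbinom(n, 100, 0.5) / 100,
                     prop_date2 = rbinom(n, 100, 0.5) / 100)
  fit <- fit_h2_model(rows)
  full <- summary(lm(H2prime ~ prop_fe + prop_fert + prop_complex + prop_date2,
                     rows))$r.squared
  expect_lt(full, 0.01)
  expect_lt(fit$R2, 0.01)  # whatever AIC lets in explains essentially nothing

  # inert covariate loses to the true one in most replicates
  wins <- 0L
  for (r in 1:60) {
    set.seed(100 + r)
    m <- 2000
    pf <- rbinom(m, 100, 0.4) / 100
    d <- data.frame(H2prime = 0.2 + 0.3 * pf + rnorm(m, 0, 0.05),
                    prop_fe = pf, prop_date2 = rbinom(m, 100, 0.5) / 100)
    aic_fe <- AIC(lm(H2prime ~ prop_fe, d))
    aic_both <- AIC(lm(H2prime ~ prop_fe + prop_date2, d))
    if (aic_fe < aic_both) wins <- wins + 1L
  }
  expect_gte(wins, 45L)  # AIC penalty excludes the inert term ~84% of the time
})

test_that("constant terms are dropped with a warning rather than breaking the fit", {
  rows <- data.frame(H2prime = rnorm(500, 0.3, 0.05),
                     prop_fe = rbinom(500, 100, 0.4) / 100,
                     prop_fert = 1, prop_complex = 0,
                     prop_date2 = rbinom(500, 100, 0.5) / 100)
  expect_warning(fit <- fit_h2_model(rows), "constant")
  expect_false(any(c("prop_fert", "prop_complex") %in% fit$selected_terms))
})
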