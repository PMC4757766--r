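# Driver model: VIF pruning, gamma GLM, AICc, all-subsets selection,
# analysis of deviance, hierarchical partitioning.

test_that("orthogonal predictors have VIF near 1 and nothing is removed", {
  withr::with_seed(1, {
    n <- 200
    tab <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  })
  rep <- vif_prune(tab, c("x1", "x2", "x3"))
  expect_identical(rep$retained, c("x1", "x2", "x3"))
  expect_equal(nrow(rep$iterations), 0)
})

test_that("a duplicated predictor column is removed first with infinite VIF", {
  withr::with_seed(2, {
    tab <- data.frame(x1 = rnorm(50), x2 = rnorm(50))
    tab$x1copy <- tab$x1
  })
  rep <- vif_prune(tab, c("x1", "x1copy", "x2"))
  expect_identical(rep$iterations$removed[1], "x1")
  expect_identical(rep$iterations$vif[1], Inf)
  expect_true("x2" %in% rep$retained)
  expect_length(rep$retained, 2)
})

test_that("VIF of a correlated pair matches 1/(1-R^2) and survives threshold 3", {
  withr::with_seed(3, {
    n <- 4000
    x1 <- rnorm(n)
    x2 <- 0.8 * x1 + sqrt(1 - 0.64) * rnorm(n)
    tab <- data.frame(x1 = x1, x2 = x2)
  })
  # independent closed-form oracle: VIF = 1 / (1 - R^2 of x1 ~ x2)
  r2 <- summary(lm(x1 ~ x2, tab))$r.squared
  rep <- vif_prune(tab, c("x1", "x2"), threshold = 3)
  vifs <- rep$iterations # nothing removed, so consult a direct computation
  expect_identical(rep$retained, c("x1", "x2"))
  v <- car::vif(lm(seq_len(n) ~ x1 + x2, tab))
  expect_equal(unname(v["x1"]), 1 / (1 - r2), tolerance = 1e-8)
  expect_equal(unname(v["x1"]), 1 / (1 - 0.64), tolerance = 0.1)
})

test_that("vif_prune is deterministic", {
  withr::with_seed(4, {
    n <- 60
    tab <- data.frame(x1 = rnorm(n))
    tab$x2 <- tab$x1 + rnorm(n, sd = 0.1)
    tab$x3 <- tab$x1 - rnorm(n, sd = 0.1)
    tab$x4 <- rnorm(n)
  })
  r1 <- vif_prune(tab, paste0("x", 1:4))
  r2 <- vif_prune(tab, paste0("x", 1:4))
  expect_identical(r1$iterations$removed, r2$iterations$removed)
  expect_identical(r1$retained, r2$retained)
  expect_true(all(unlist(lapply(r1$iterations$remaining, max)) >= 3 |
                    nrow(r1$iterations) == 0))
})

test_that("an intercept-only log-link gamma GLM fits the arithmetic mean", {
  d <- make_glm_data(n = 30, seed = 5)
  f <- fit_gamma_glm(d$response, d$table, ~1)
  expect_equal(unname(exp(coef(f)[1])), mean(d$response), tolerance = 1e-8)
})

test_that("the reef-area by geomorphic-type interaction formula is accepted verbatim", {
  g <- generate_predictor_table(driver_truth(), seed = 2)
  f <- fit_gamma_glm(g$response, g$table,
                     ~ geomorphic_type + reef_area + bathy_slope +
                       population_status + reef_area:geomorphic_type)
  expect_s3_class(f, "ime_glm")
  expect_true("geomorphic_typeisland:reef_area" %in% names(coef(f)))
  expect_true(f$d2 > 0 && f$d2 <= 1)
  expect_equal(f$d2, 1 - f$deviance / f$null.deviance)
})

test_that("non-positive responses are rejected with a positivity message", {
  d <- make_glm_data(n = 20, seed = 6)
  resp <- d$response; resp[3] <- 0
  expect_error(fit_gamma_glm(resp, d$table, ~x1), "positive")
})

test_that("the AICc correction matches the closed form over a grid of n and k", {
  expect_equal(aicc(100, n = 28, k = 3) - 100, 1.0)
  for (n in c(15, 28, 60)) for (k in c(2, 4, 7)) {
    expect_equal(aicc(0, n = n, k = k), 2 * k * (k + 1) / (n - k - 1))
  }
  expect_error(aicc(10, n = 8, k = 7), "AICc undefined")
  # vanishing correction in the large-n limit
  expect_lt(aicc(50, n = 1e6, k = 4) - 50, 1e-4)
  d <- make_glm_data(n = 25, seed = 7)
  f <- fit_gamma_glm(d$response, d$table, ~ x1 + x2)
  expect_equal(f$aicc, AIC(f) + 2 * f$k * (f$k + 1) / (25 - f$k - 1))
})

test_that("one predictor enumerates exactly the null and single-term models", {
  d <- make_glm_data(n = 25, seed = 8)
  r <- all_subsets_selection(d$response, d$table, "x1")
  expect_equal(nrow(r$models), 2)
  expect_setequal(r$models$formula, c("~1", "~x1"))
  expect_equal(sum(r$models$weight), 1)
})

test_that("interactions with an empty crossed factor cell never enter a formula", {
  withr::with_seed(9, {
    n <- 40
    type <- factor(rep(c("atoll", "island"), each = n / 2))
    pop <- factor(ifelse(type == "island" & runif(n) < 0.5,
                         "populated", "unpopulated"))
    tab <- data.frame(geomorphic_type = type, population_status = pop,
                      x = rnorm(n))
    resp <- rgamma(n, 10, scale = exp(0.2 + 0.3 * tab$x) / 10)
  })
  expect_true(sum(tab$geomorphic_type == "atoll" &
                    tab$population_status == "populated") == 0)
  r <- all_subsets_selection(resp, tab,
                             c("geomorphic_type", "population_status", "x"),
                             interactions = TRUE)
  expect_true(any(grepl("geomorphic_type:population_status",
                        r$dropped_interactions$interaction)))
  expect_false(any(grepl("geomorphic_type:population_status",
                         r$models$formula)))
  expect_equal(sum(r$models$weight), 1, tolerance = 1e-12)
  expect_equal(r$models$delta_aicc[1], 0)
})

test_that("adding a predictor never increases the deviance", {
  d <- make_glm_data(n = 30, seed = 10)
  d$table$junk <- withr::with_seed(11, rnorm(30))
  f1 <- fit_gamma_glm(d$response, d$table, ~ x1 + x2)
  f2 <- fit_gamma_glm(d$response, d$table, ~ x1 + x2 + junk)
  expect_lte(f2$deviance, f1$deviance + 1e-10)
})

test_that("the deviance test is exact for identical models and rejects reversed ones", {
  d <- make_glm_data(n = 30, seed = 12)
  f1 <- fit_gamma_glm(d$response, d$table, ~x1)
  f2 <- fit_gamma_glm(d$response, d$table, ~ x1 + x2)
  expect_equal(deviance_test(f1, f1)$p, 1)
  expect_error(deviance_test(f2, f1), class = "ime_not_nested")
  res <- deviance_test(f1, f2)
  expect_equal(res$df, 1)
  expect_true(res$p >= 0 && res$p <= 1)
})

test_that("externally supplied deviances can be compared", {
  res <- deviance_test(list(deviance = 12, df.residual = 20),
                       list(deviance = 5, df.residual = 18, dispersion = 1))
  expect_equal(res$df, 2)
  expect_equal(res$statistic, 7)
  expect_equal(res$p, pchisq(7, 2, lower.tail = FALSE))
})

test_that("with one predictor the independent contribution is its D2", {
  d <- make_glm_data(n = 30, seed = 13)
  p <- hierarchical_partition(d$response, d$table, "x1")
  f <- fit_gamma_glm(d$response, d$table, ~x1)
  expect_equal(p$contributions$independent, f$d2, tolerance = 1e-12)
})

test_that("subset-formula contributions equal brute-force ordering averages (k = 3, 4)", {
  d <- make_glm_data(n = 40, seed = 14)
  p3 <- hierarchical_partition(d$response, d$table, c("x1", "x2", "x3"))
  o3 <- orderings_partition(d$response, d$table, c("x1", "x2", "x3"))
  expect_lt(max(abs(p3$contributions$independent - unname(o3))), 1e-10)

  d$table$x4 <- withr::with_seed(15, rnorm(40))
  p4 <- hierarchical_partition(d$response, d$table, paste0("x", 1:4))
  o4 <- orderings_partition(d$response, d$table, paste0("x", 1:4))
  expect_lt(max(abs(p4$contributions$independent - unname(o4))), 1e-10)
})

test_that("independent contributions always sum to the full-model D2", {
  for (s in 1:5) {
    d <- make_glm_data(n = 35, seed = 100 + s)
    p <- hierarchical_partition(d$response, d$table, c("x1", "x2", "x3"))
    f <- fit_gamma_glm(d$response, d$table, ~ x1 + x2 + x3)
    expect_equal(sum(p$contributions$independent), f$d2, tolerance = 1e-10)
    expect_equal(sum(p$contributions$percent), 100, tolerance = 1e-8)
  }
})

test_that("orthogonal balanced predictors recover their marginal contributions", {
  withr::with_seed(16, {
    n <- 10000
    tab <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    mu <- exp(0.1 + 0.3 * tab$x1 + 0.3 * tab$x2)
    resp <- rgamma(n, shape = 50, scale = mu / 50)
  })
  p <- hierarchical_partition(resp, tab, c("x1", "x2"))
  m1 <- fit_gamma_glm(resp, tab, ~x1)$d2
  m2 <- fit_gamma_glm(resp, tab, ~x2)$d2
  expect_equal(p$contributions$independent[1], m1, tolerance = 0.02)
  expect_equal(p$contributions$independent[2], m2, tolerance = 0.02)
})
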