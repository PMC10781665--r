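test_that("beta-binomial likelihood reproduces worked values", {
  # rho -> 0: Binomial(10, 0.5) pmf at C = 5 is choose(10,5) 0.5^10
  mod <- enrichment_model(5, 10, type = 1)
  expect_equal(exp(betabinom_loglik(c(0, 0), 1e-12, mod)),
               252 * 0.5^10, tolerance = 1e-6)
  # a single trial carries no overdispersion: P(C=1) = p for any rho
  mod1 <- enrichment_model(1, 1, type = 1)
  for (rho in c(0, 0.2, 0.7)) {
    expect_equal(exp(betabinom_loglik(c(qlogis(0.3), 0), rho, mod1)), 0.3,
                 tolerance = 1e-9)
  }
  # independent oracle: numerically integrate Binomial(N,q) against Beta(a,b)
  set.seed(21)
  for (i in 1:5) {
    N <- sample(5:40, 1); C <- sample(1:(N - 1), 1)
    p <- runif(1, 0.05, 0.95); rho <- runif(1, 0.02, 0.4)
    a <- p * (1 - rho) / rho; b <- (1 - p) * (1 - rho) / rho
    oracle <- integrate(function(q) dbinom(C, N, q) * dbeta(q, a, b),
                        0, 1, rel.tol = 1e-12)$value
    mod_i <- enrichment_model(C, N, type = 1)
    expect_equal(exp(betabinom_loglik(c(qlogis(p), 0), rho, mod_i)), oracle,
                 tolerance = 1e-8)
  }
  # invalid corners are -Inf, not errors
  expect_identical(betabinom_loglik(c(0, 0), -0.1, mod), -Inf)
  expect_identical(betabinom_loglik(c(0, 0), 1, mod), -Inf)
  expect_identical(betabinom_loglik(c(NA, 0), 0.1, mod), -Inf)
})

test_that("likelihood at tiny rho equals the binomial limit", {
  set.seed(22)
  for (i in 1:10) {
    n <- 30; N <- rep(5000, n)
    type <- rep(c(0, 1), length.out = n)
    beta <- c(qlogis(runif(1, 0.01, 0.2)), rnorm(1, 0, 0.5))
    p <- plogis(beta[1] + beta[2] * type)
    C <- rbinom(n, N, p)
    mod <- enrichment_model(C, N, type)
    expect_equal(betabinom_loglik(beta, 1e-12, mod),
                 sum(dbinom(C, N, p, log = TRUE)), tolerance = 1e-6)
  }
})

test_that("ML fit recovers planted coefficients and beats a parameter grid", {
  set.seed(23)
  est <- replicate(20, {
    N <- 10000; n <- 40; p0 <- 0.005
    C0 <- sample_beta_binomial(n, N, p0, 0.05)
    C1 <- sample_beta_binomial(n, N, plogis(qlogis(p0) + 2), 0.05)
    mod <- enrichment_model(c(C0, C1), rep(N, 2 * n), rep(c(0, 1), each = n))
    f <- fit_taxon(mod)
    c(beta = f$beta_type, rho = f$rho_hat, conv = f$converged)
  })
  expect_equal(mean(est["beta", ]), 2, tolerance = 0.15)
  expect_lt(abs(mean(est["rho", ]) - 0.05), 0.02)
  expect_true(all(est["conv", ] == 1))

  # optimizer solution dominates a dense (beta_type, rho) grid
  set.seed(24)
  C <- sample_beta_binomial(24, 500, 0.1, 0.1)
  type <- rep(c(0, 1), each = 12)
  mod <- enrichment_model(C, rep(500, 24), type)
  f <- fit_taxon(mod)
  grid_best <- max(sapply(seq(-1, 1, by = 0.05), function(bt)
    max(sapply(seq(0.01, 0.5, by = 0.01), function(r)
      betabinom_loglik(c(f$beta[1], bt), r, mod)))))
  expect_gte(f$loglik + 1e-6, grid_best)
})

test_that("degenerate fits are surfaced, never crash", {
  mod0 <- enrichment_model(rep(0, 10), rep(100, 10), rep(c(0, 1), 5))
  expect_error(fit_taxon(mod0), "all counts are zero")
  expect_error(enrichment_model(5, 10, type = 2), "binary")
  expect_error(enrichment_model(11, 10, type = 1), "N >= C")
  one_type <- enrichment_model(c(5, 6), c(10, 10), c(1, 1))
  expect_error(fit_taxon(one_type), "both sample types")
  # near-separation: finite answer with honest uncertainty
  sep <- enrichment_model(c(rep(0, 8), rep(95, 8)), rep(100, 16),
                          rep(c(0, 1), each = 8))
  f <- fit_taxon(sep)
  expect_true(is.finite(f$wald_p) && f$wald_p >= 0 && f$wald_p <= 1)
})

test_that("beta_type flips sign when the niche coding is swapped", {
  set.seed(25)
  N <- 5000; n <- 30
  C0 <- sample_beta_binomial(n, N, 0.02, 0.05)
  C1 <- sample_beta_binomial(n, N, plogis(qlogis(0.02) + 1.5), 0.05)
  C <- c(C0, C1); type <- rep(c(0, 1), each = n)
  f1 <- fit_taxon(enrichment_model(C, rep(N, 2 * n), type))
  f2 <- fit_taxon(enrichment_model(C, rep(N, 2 * n), 1 - type))
  expect_equal(f1$beta_type, -f2$beta_type, tolerance = 1e-3)
})

test_that("independent cross-check: glmmTMB beta-binomial agrees", {
  set.seed(26)
  N <- 10000; n <- 50
  C0 <- sample_beta_binomial(n, N, 0.01, 0.08)
  C1 <- sample_beta_binomial(n, N, plogis(qlogis(0.01) + 1), 0.08)
  df <- data.frame(C = c(C0, C1), N = N, type = rep(c(0, 1), each = n))
  f <- fit_taxon(enrichment_model(df$C, df$N, df$type))
  g <- suppressWarnings(glmmTMB::glmmTMB(
    cbind(C, N - C) ~ type, family = glmmTMB::betabinomial(), data = df))
  beta_ref <- unname(glmmTMB::fixef(g)$cond["type"])
  # glmmTMB's dispersion phi maps to rho = 1/(1 + phi)
  rho_ref <- 1 / (1 + exp(unname(glmmTMB::fixef(g)$disp)))
  expect_lt(abs(f$beta_type - beta_ref), 0.02)
  expect_lt(abs(f$rho_hat - rho_ref), 0.01)
})

test_that("BH classification implements the FDR rules", {
  fits <- data.frame(taxon_id = sprintf("t%02d", 1:10), site = "fundus",
                     beta_type = rep(c(1.5, -1.5), 5), se = 0.1,
                     wald_p = 0.001, rho_hat = 0.05, converged = TRUE)
  cl <- classify_enrichment(fits, alpha = 0.05)
  expect_equal(cl$fdr_q, rep(0.001, 10))
  expect_setequal(unique(cl$class), c("mucosa_enriched", "lumen_enriched"))
  expect_equal(cl$class[cl$beta_type > 0][1], "mucosa_enriched")

  single <- fits[1, ]; single$wald_p <- 0.2
  expect_equal(classify_enrichment(single)$class, "ns")

  # q-values are computed within site unless pooled
  two_sites <- rbind(transform(fits, site = "fundus"),
                     transform(fits, wald_p = 0.04, site = "antrum"))
  cl2 <- classify_enrichment(two_sites)
  expect_equal(unique(cl2$fdr_q[cl2$site == "antrum"]), 0.04)
  cl3 <- classify_enrichment(two_sites, pool_sites = TRUE)
  expect_true(all(cl3$fdr_q[cl3$site == "antrum"] >= 0.04 - 1e-12))
})

test_that("set comparison reproduces Jaccard arithmetic", {
  A <- sprintf("shared%02d", 1:9)
  res <- compare_enriched_sets(c(A, sprintf("a%02d", 1:29)),
                               c(A, sprintf("b%02d", 1:7)))
  expect_equal(res$n_a, 38); expect_equal(res$n_b, 16)
  expect_equal(res$jaccard_percent, 20)
  expect_equal(res$shared, sort(A))
  expect_equal(compare_enriched_sets(c("x", "y"), c("x", "y"))$jaccard_percent,
               100)
  expect_equal(compare_enriched_sets("x", "y")$jaccard_percent, 0)
  expect_equal(compare_enriched_sets(character(), character())$jaccard_percent,
               0)
})

test_that("planted enrichment is recovered with controlled errors", {
  res <- sapply(1:4, function(sd) {
    st <- generate_study(benchmark_enrichment_config(seed = 400 + sd))
    fits <- fit_enrichment(st$bundle$counts, st$bundle$samples,
                           "large_intestine", covariates = character())
    cl <- classify_enrichment(fits)
    truth <- st$truth$enrichment
    sig <- cl[cl$class != "ns", ]
    tp <- sum(sig$taxon_id %in% truth$taxon)
    dir_ok <- merge(sig, truth, by.x = "taxon_id", by.y = "taxon")
    c(sens = tp / nrow(truth),
      fdp = if (nrow(sig)) 1 - tp / nrow(sig) else 0,
      dir = all(sign(dir_ok$beta_type.x) == sign(dir_ok$beta_type.y)))
  })
  expect_gte(mean(res["sens", ]), 0.8)
  expect_lte(mean(res["fdp", ]), 0.1)
  expect_true(all(res["dir", ] == 1))
})
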