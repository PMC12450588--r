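test_that("nmix_loglik matches closed forms from Poisson thinning", {
  # one replicate y = 1, lambda = 2, p = 0.5: marginal y ~ Poisson(1), so
  # the likelihood is e^{-1}
  expect_equal(exp(nmix_loglik(1L, 2, 0.5, 100)), exp(-1), tolerance = 1e-12)
  # replicates (1, 0), lambda = 1, p = 0.5: closed form 0.25 e^{-0.75}
  expect_equal(exp(nmix_loglik(c(1L, 0L), 1, 0.5, 50)), 0.25 * exp(-0.75),
               tolerance = 1e-12)
  # all-zero with p = 1: only N = 0 contributes, likelihood e^{-lambda}
  expect_equal(nmix_loglik(0L, 3.7, 1, 40), -3.7, tolerance = 1e-12)
})

test_that("nmix_loglik equals brute-force summation on a small-instance grid", {
  worst <- 0
  for (lam in c(0.3, 1, 2.5, 5)) for (p in seq(0.1, 0.9, 0.2)) {
    for (y in list(0L, 2L, c(0L, 0L), c(1L, 0L), c(2L, 1L), c(4L, 0L, 1L),
                   c(3L, 3L, 3L))) {
      got <- nmix_loglik(y, lam, p, K_trunc = max(y) + 60)
      want <- bf_loglik(y, lam, p, max(y) + 60)
      worst <- max(worst, abs(got - want))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("nmix_loglik guards its truncation bound", {
  expect_error(nmix_loglik(c(3L, 1L), 1, 0.5, K_trunc = 2), "max\\(y\\)")
  expect_warning(nmix_loglik(0L, 50, 0.5, K_trunc = 55), "truncation")
  # doubling the margin changes nothing measurable for moderate lambda
  for (lam in c(1, 5, 10)) {
    a <- nmix_loglik(c(2L, 0L), lam, 0.4, K_trunc = 2 + 50)
    b <- nmix_loglik(c(2L, 0L), lam, 0.4, K_trunc = 2 + 100)
    expect_lt(abs(a - b), 1e-8)
  }
})

test_that("likelihood is invariant to replicate ordering", {
  set.seed(8)
  for (i in 1:20) {
    y <- rpois(4, 2)
    expect_equal(nmix_loglik(y, 2.3, 0.6, max(y) + 50),
                 nmix_loglik(rev(y), 2.3, 0.6, max(y) + 50), tolerance = 1e-13)
  }
})

test_that("with p = 1 and one replicate the marginal is plain Poisson", {
  # likelihood identity, and the lambda maximizing it equals the Poisson
  # regression (intercept-only GLM) answer on the same counts
  set.seed(12)
  y <- rpois(200, 2.7)
  for (v in unique(y))
    expect_equal(nmix_loglik(as.integer(v), 2.7, 1, v + 60),
                 dpois(v, 2.7, log = TRUE), tolerance = 1e-12)
  nll <- function(lam) -sum(vapply(y, function(v)
    nmix_loglik(as.integer(v), lam, 1, v + 60), numeric(1)))
  lam_hat <- optimize(nll, c(0.1, 10))$minimum
  glm_hat <- exp(coef(glm(y ~ 1, family = poisson()))[[1]])
  expect_equal(lam_hat, glm_hat, tolerance = 1e-4)
})

test_that("fit_species refuses all-zero species and recovers a known curve", {
  spp <- demo_species_set()["PKUP"]
  cfg <- sim_config(species = spp, seed = 19, n_stations = 112)
  sim <- simulate_dataset(cfg)
  cms <- build_count_matrices(sim$records)

  zero <- cms$PKUP
  for (prd in c("historical", "modern")) zero$periods[[prd]]$y[] <- 0L
  expect_error(fit_species(zero, sim$standardizer, fast_control()),
               "no detections")

  set.seed(91)
  fit <- fit_species(cms$PKUP, sim$standardizer, fast_control())
  expect_s3_class(fit, "nmix_fit")
  expect_equal(nrow(fit$draws), 2 * 500)
  expect_true(all(fit$draws$M_hist >= 0))
  expect_true(all(fit$draws$p > 0 & fit$draws$p < 1))
  expect_true(all(table(fit$draws$chain) == 500))
  # detection probability recovered: truth 0.5 inside a generous posterior band
  ph <- hdi(fit$draws$p, 0.99)
  expect_true(ph[1] <= 0.5 && 0.5 <= ph[2])
  # optimum shift posterior covers the simulated +150 m translation
  os <- optimum_shift(fit, elevation_grid(by = 4))
  expect_true(os$shift[["hdi_lo"]] <= 150 + 40 && 150 - 40 <= os$shift[["hdi_hi"]])
})

test_that("identifiability flag follows HDI width and Rhat rules", {
  s <- elev_standardizer(center_m = 822, scale_m = 700)
  curve <- hof_params(3, -1, 4, -1, 4)
  # degenerate draws: all identical -> zero-width HDIs -> well defined
  fit <- fake_fit(constant_draws(200, curve, curve), s)
  out <- assess_identifiability(fit, elevation_grid(by = 8))
  expect_equal(out$flag, "well_defined")
  # optimum draws split between the gradient ends -> HDI spans the gradient
  d <- constant_draws(200, curve, curve)
  half <- seq_len(100)
  d$a_hist <- 3; d$b_hist <- -8; d$c_hist <- -3; d$d_hist <- 8   # peak at top
  d$a_hist[half] <- -3; d$b_hist[half] <- 8                      # peak at bottom
  d$c_hist[half] <- 3; d$d_hist[half] <- -8
  fit2 <- fake_fit(d, s)
  out2 <- assess_identifiability(fit2, elevation_grid(by = 8))
  expect_equal(out2$flag, "poorly_defined")
  # convergence failure alone also flags
  fit3 <- fake_fit(constant_draws(200, curve, curve), s)
  fit3$diagnostics$max_rhat <- 1.2
  expect_equal(assess_identifiability(fit3, elevation_grid(by = 8))$flag,
               "poorly_defined")
})

test_that("split_rhat is 1 for iid draws and detects disagreement", {
  set.seed(5)
  x <- rnorm(4000); ch <- rep(1:4, each = 1000)
  expect_lt(split_rhat(x, ch), 1.02)
  x2 <- x + 3 * (ch == 1)
  expect_gt(split_rhat(x2, ch), 1.5)
  expect_equal(split_rhat(rep(1, 400), rep(1:2, each = 200)), 1)
})
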