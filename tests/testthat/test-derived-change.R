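std822 <- elev_standardizer(center_m = 822, scale_m = 700)

test_that("hdi matches the closed-form interval of a normal sample", {
  set.seed(33)
  x <- rnorm(4000)
  h <- hdi(x)
  # 89% HDI of N(0,1) is symmetric at +/- qnorm(0.945) = 1.598
  expect_equal(h[1], -qnorm(0.945), tolerance = 0.08)
  expect_equal(h[2], qnorm(0.945), tolerance = 0.08)
  expect_equal(hdi(rep(2.5, 100)), c(2.5, 2.5))
})

test_that("profiles from degenerate draws collapse to the point curve", {
  curve <- hof_params(2, -1, 3, -1, 3)
  fit <- fake_fit(constant_draws(50, curve, curve), std822)
  pr <- profile_from_draws(fit, "historical", elevation_grid(by = 16))
  lam <- hof_lambda(curve, standardize(pr$grid_m, std822))
  expect_equal(pr$median, lam, tolerance = 1e-12)
  expect_equal(unname(pr$hdi[, "lower"]), lam, tolerance = 1e-12)
  expect_equal(unname(pr$hdi[, "upper"]), lam, tolerance = 1e-12)
  expect_true(all(pr$hdi[, "lower"] <= pr$median & pr$median <= pr$hdi[, "upper"]))
})

test_that("profile medians scale linearly in M", {
  curve <- hof_params(2, -1, 3, -1, 3)
  curve2 <- hof_params(4, -1, 3, -1, 3)
  f1 <- fake_fit(constant_draws(20, curve, curve), std822)
  f2 <- fake_fit(constant_draws(20, curve2, curve2), std822)
  g <- elevation_grid(by = 32)
  expect_equal(2 * profile_from_draws(f1, "historical", g)$median,
               profile_from_draws(f2, "historical", g)$median, tolerance = 1e-12)
})

test_that("per-elevation change classes follow the HDI-overlap rule", {
  g <- elevation_grid(by = 16)
  hist <- fake_profile(g, med = 1.5, lo = 1, hi = 2)
  inc <- fake_profile(g, med = 3.5, lo = 3, hi = 4, period = "modern")
  ovl <- fake_profile(g, med = 2, lo = 1.5, hi = 3, period = "modern")
  dec <- fake_profile(g, med = 0.55, lo = 0.3, hi = 0.8, period = "modern")
  expect_true(all(classify_elevation_change(hist, inc) == "increase"))
  expect_true(all(classify_elevation_change(hist, ovl) == "stable"))
  expect_true(all(classify_elevation_change(hist, dec) == "decrease"))
  expect_true(all(classify_elevation_change(hist, hist) == "stable"))
})

test_that("range expansion and contraction label one-period elevations", {
  g <- elevation_grid(by = 8)
  # historical range in the lower half, modern range in the upper half
  lam_h <- ifelse(g < 800, 1, 0)
  lam_m <- ifelse(g >= 700, 1, 0)
  hist <- fake_profile(g, lam_h, lam_h, lam_h)
  mod <- fake_profile(g, lam_m, lam_m, lam_m, period = "modern")
  cls <- classify_elevation_change(hist, mod)
  expect_true(all(cls[g < 700] == "range_contraction"))
  expect_true(all(cls[g >= 800] == "range_expansion"))
  expect_true(all(cls[g >= 700 & g < 800] == "stable"))
})

test_that("swapping periods maps increase to decrease and fixes stable", {
  g <- elevation_grid(by = 8)
  set.seed(14)
  med_h <- runif(length(g), 0.5, 3)
  med_m <- med_h * exp(runif(length(g), -1, 1))
  hist <- fake_profile(g, med_h, med_h * 0.8, med_h * 1.2)
  mod <- fake_profile(g, med_m, med_m * 0.8, med_m * 1.2, period = "modern")
  fwd <- classify_elevation_change(hist, mod)
  rev <- classify_elevation_change(mod, hist)
  map <- c(stable = "stable", increase = "decrease", decrease = "increase",
           range_expansion = "range_contraction",
           range_contraction = "range_expansion", outside = "outside")
  expect_equal(as.character(rev), unname(map[as.character(fwd)]))
})

test_that("optimum shift recovers a constructed translation", {
  curve <- hof_params(3, -1, 4, -1, 4)
  # modern curve translated +0.2 standardized units (= +140 m at scale 700)
  shifted <- hof_params(3, -1 - 4 * 0.2, 4, -1 + 4 * 0.2, 4)
  fit <- fake_fit(constant_draws(30, curve, shifted), std822)
  g <- elevation_grid(by = 2)
  os <- optimum_shift(fit, g)
  expect_equal(unname(os$shift[["point"]]), 0.2 * 700, tolerance = 2)
  expect_equal(unname(os$shift[["median"]]), 0.2 * 700, tolerance = 2)
  # identical periods give zero shift
  os0 <- optimum_shift(fake_fit(constant_draws(30, curve, curve), std822), g)
  expect_equal(unname(os0$shift[["point"]]), 0)
  # mirrored translation has equal magnitude, opposite sign
  back <- hof_params(3, -1 + 4 * 0.2, 4, -1 - 4 * 0.2, 4)
  osb <- optimum_shift(fake_fit(constant_draws(30, curve, back), std822), g)
  expect_equal(unname(osb$shift[["point"]]), -unname(os$shift[["point"]]),
               tolerance = 2)
})

test_that("M = 0 draws are excluded from optima with a count", {
  curve <- hof_params(3, -1, 4, -1, 4)
  d <- constant_draws(40, curve, curve)
  d$M_hist[1:5] <- 0
  os <- optimum_shift(fake_fit(d, std822), elevation_grid(by = 8))
  expect_equal(os$n_excluded, 5)
  expect_equal(sum(is.na(os$draws$shift)), 5)
})

test_that("range categories read the touched gradient ends", {
  expect_equal(categorize_range(c(201, 1443)), "broad")
  expect_equal(categorize_range(c(210, 900)), "low")
  expect_equal(categorize_range(c(700, 1440)), "high")
  expect_equal(categorize_range(c(NA, NA)), "uncategorized")
  expect_warning(cat4 <- categorize_range(c(500, 900)), "interior")
  expect_equal(cat4, "interior")
})

test_that("scenario rules label constructed change patterns", {
  g <- elevation_grid(by = 8)
  mk <- function(cls_by_elev, lim = c(201, 1443)) {
    f <- factor(cls_by_elev, levels = c("stable", "increase", "decrease",
                                        "range_expansion", "range_contraction",
                                        "outside"))
    attr(f, "limits_hist") <- c(low_m = lim[1], high_m = lim[2])
    f
  }
  all_stable <- mk(rep("stable", length(g)))
  expect_equal(assign_scenario(all_stable, g), "stable")
  # increases confined to the upper third, stable below
  up <- mk(ifelse(g > 201 + 2 * 1242 / 3, "increase", "stable"))
  expect_equal(as.character(assign_scenario(up, g)), "abundance_expansion_up")
  # upper increases with lower decreases: a shift up
  sh <- mk(ifelse(g > 201 + 2 * 1242 / 3, "increase",
                  ifelse(g < 201 + 1242 / 3, "decrease", "stable")))
  expect_equal(as.character(assign_scenario(sh, g)), "abundance_shift_up")
  # losses at the lower limit of a high-elevation species
  hec <- mk(ifelse(g < 700 + 740 / 3, "range_contraction", "stable"),
            lim = c(700, 1440))
  hec[g < 700] <- "outside"
  expect_equal(as.character(assign_scenario(hec, g, range_category = "high")),
               "high_elevation_contraction")
  # widespread decreases
  dec <- mk(ifelse(g < 1100, "decrease", "stable"))
  expect_equal(as.character(assign_scenario(dec, g)), "decline")
  # increases at the bottom only
  down <- mk(ifelse(g < 201 + 1242 / 3, "increase", "stable"))
  expect_equal(as.character(assign_scenario(down, g)), "abundance_expansion_down")
})

test_that("cross-species mean shift propagates draws and honors exclusions", {
  sd1 <- list(AAAA = rep(100, 50), BBBB = rep(200, 50))
  ms <- mean_shift_across_species(sd1)
  expect_equal(ms$mean, 150)
  expect_equal(ms$hdi, c(150, 150))
  expect_equal(ms$range, c(100, 200))
  # all-zero shifts
  expect_equal(mean_shift_across_species(list(A = rep(0, 10), B = rep(0, 10)))$mean, 0)
  # invariance to ordering and to adding an excluded species
  set.seed(6)
  sd2 <- list(A = rnorm(100, 50), B = rnorm(100, 150), C = rnorm(100, 250))
  m1 <- mean_shift_across_species(sd2)
  m2 <- mean_shift_across_species(rev(sd2))
  expect_equal(m1$mean, m2$mean)
  sd3 <- c(sd2, list(D = rnorm(100, 999)))
  m3 <- mean_shift_across_species(sd3, exclude = "D")
  expect_equal(m1$mean, m3$mean)
  expect_error(mean_shift_across_species(sd2, exclude = "ZZZZ"), "unknown species")
  expect_error(mean_shift_across_species(sd2[1]), "at least two")
  # bootstrap alternative runs and centers near the same mean
  mb <- mean_shift_across_species(sd2, method = "bootstrap")
  expect_lt(abs(mb$mean - m1$mean), 10)
})

test_that("per-elevation classes tile the union of ranges", {
  g <- elevation_grid(by = 8)
  lam_h <- pmax(0, 1.2 - abs(g - 600) / 300)
  lam_m <- pmax(0, 1.2 - abs(g - 800) / 300)
  hist <- fake_profile(g, lam_h, lam_h * 0.8, lam_h * 1.2)
  mod <- fake_profile(g, lam_m, lam_m * 0.8, lam_m * 1.2, period = "modern")
  cls <- classify_elevation_change(hist, mod)
  rule <- range_rule()
  in_union <- hofnmix:::range_indicator(lam_h, rule) |
    hofnmix:::range_indicator(lam_m, rule)
  expect_false(any(cls[in_union] == "outside"))
  expect_true(all(cls[!in_union] == "outside"))
})
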