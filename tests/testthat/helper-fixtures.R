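# shared fixtures and independent oracles

# brute-force marginalized N-mixture likelihood: direct double-precision sum
# over N, written independently of the package's log-space implementation
bf_loglik <- function(y, lambda, p, K) {
  log(sum(vapply(max(y):K, function(N)
    dpois(N, lambda) * prod(dbinom(y, N, p)), numeric(1))))
}

# minimal well-formed survey record data.frame
make_records <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  validate_survey_records(df)
}

rec_row <- function(station = "A", elev = 500, period = "historical",
                    date = "1991-06-01", replicate = 1, species = "TEST",
                    count = 1, distance = 30) {
  list(station_id = station, elevation_m = elev, period = period,
       visit_date = date, replicate = replicate, species_code = species,
       count = count, distance_m = distance)
}

# abundance_profile with prescribed median and HDI bands (constant over grid)
fake_profile <- function(grid, med, lo, hi, species = "FAKE", period = "historical") {
  n <- length(grid)
  med <- rep_len(med, n); lo <- rep_len(lo, n); hi <- rep_len(hi, n)
  structure(list(species_code = species, period = period, grid_m = grid,
                 lambda = rbind(lo, med, hi),
                 median = med,
                 hdi = cbind(lower = lo, upper = hi)),
            class = "abundance_profile")
}

# nmix_fit whose draws are prescribed (for derivation-layer tests without MCMC)
fake_fit <- function(draws, standardizer, species = "FAKE") {
  structure(list(species_code = species, draws = draws,
                 diagnostics = list(rhat = 1, max_rhat = 1, min_ess = nrow(draws)),
                 standardizer = standardizer,
                 control = nmix_control(), accept = 0.23),
            class = "nmix_fit")
}

# one-row-per-draw data.frame of identical HOF parameters for both periods
constant_draws <- function(n, hist, mod, p = 0.5) {
  data.frame(chain = 1L, iter = seq_len(n),
             M_hist = hist$M, M_mod = mod$M,
             a_hist = hist$a, a_mod = mod$a,
             b_hist = hist$b, b_mod = mod$b,
             c_hist = hist$c, c_mod = mod$c,
             d_hist = hist$d, d_mod = mod$d,
             p = p, lp = 0)
}

fast_control <- function() nmix_control(n_chains = 2, n_iter = 1000, thin = 20)
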