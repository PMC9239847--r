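# Shared fixtures, built in code.  Correlated Gaussian draws with known
# (partial) correlations serve as closed-form oracles for the estimators.

rho_pair <- function(n, rho, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    list(x = x, y = rho * x + sqrt(1 - rho^2) * rnorm(n))
  })
}

# trivariate Gaussian with a prescribed partial correlation of x and y given z
partial_rho_triple <- function(n, rho_xy_z, load = 0.5, seed = 1) {
  withr::with_seed(seed, {
    z <- rnorm(n)
    ex <- rnorm(n); ey <- rnorm(n)
    x <- load * z + sqrt(1 - load^2) * ex
    y <- load * z + sqrt(1 - load^2) * (rho_xy_z * ex + sqrt(1 - rho_xy_z^2) * ey)
    list(x = x, y = y, z = z)
  })
}

small_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      cfg <- scenario_config(n_participants = 3, n_trials = 10,
                             tracking_lag = 0.1, snr = 4, seed = 42)
      memo <<- simulate_cohort(cfg)
    }
    memo
  }
})

# a band-limited pair with a planted integer-sample delay, already prepped
delayed_pair <- function(n = 6000, delay = 5, noise = 0.3, seed = 3,
                         band = canonical_bands()[["1-3"]]) {
  withr::with_seed(seed, {
    x <- copulatrack:::.shaped_noise(n, 1)[, 1]
    y <- copulatrack:::circ_shift(x, delay) + noise * rnorm(n)
    xa <- analytic_signal(bandpass_zero_phase(x, band))
    ya <- analytic_signal(bandpass_zero_phase(y, band))
    list(x = matrix(unclass(xa), ncol = 1), y = unclass(ya))
  })
}
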