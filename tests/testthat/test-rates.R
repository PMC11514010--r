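test_that("Strickler-Berg reproduces the reference radiative rates within 2%", {
  k <- strickler_berg_rate(table1_rates$e_s1, table1_rates$f)
  expect_equal(k, table1_rates$k_r, tolerance = 0.02)
  expect_equal(strickler_berg_rate(2.36, 0), 0)
  expect_error(strickler_berg_rate(1.67, -0.1), ">= 0")
  expect_error(strickler_berg_rate(0, 1), "> 0")
})

test_that("Strickler-Berg is exactly linear in f and quadratic in wavenumber", {
  set.seed(7)
  e <- runif(20, 0.5, 4)
  f <- runif(20, 0.01, 2)
  a <- runif(20, 0.1, 5)
  expect_equal(strickler_berg_rate(e, a * f),
               a * strickler_berg_rate(e, f), tolerance = 1e-12)
  expect_equal(strickler_berg_rate(a * e, f),
               a^2 * strickler_berg_rate(e, f))
})

test_that("the FCWD has the Marcus closed form at S = 0", {
  p <- fcwd_params(huang_rhys = 0, reorg_low = 800, temperature = 298.15)
  kt <- 0.695035 * 298.15
  expect_equal(fcwd(800, p), 1 / sqrt(4 * pi * 800 * kt))
  # displaced Gaussian value, independent closed form
  expect_equal(fcwd(1500, p),
               exp(-(1500 - 800)^2 / (4 * 800 * kt)) / sqrt(4 * pi * 800 * kt))
})

test_that("the FCWD integrates to one over the gap axis", {
  set.seed(13)
  for (i in 1:5) {
    p <- fcwd_params(
      mode_energy = runif(1, 600, 2500),
      huang_rhys = runif(1, 0, 4),
      reorg_low = runif(1, 100, 2000),
      temperature = runif(1, 150, 400)
    )
    span <- p$mode_energy * (p$n_max + 1)
    area <- stats::integrate(function(g) fcwd(g, p), -3e4, span + 3e4,
                             subdivisions = 4000L, rel.tol = 1e-9)$value
    expect_equal(area, 1, tolerance = 1e-6)
  }
})

test_that("the vibronic sum is converged at the default truncation", {
  for (s in c(0.5, 2, 5)) {
    p50 <- fcwd_params(huang_rhys = s, n_max = 50L)
    p500 <- fcwd_params(huang_rhys = s, n_max = 500L)
    g <- seq(0, 15000, by = 500)
    expect_equal(fcwd(g, p50), fcwd(g, p500), tolerance = 1e-10)
  }
  expect_warning(fcwd(1000, fcwd_params(huang_rhys = 6, n_max = 8L)),
                 "tail mass")
})

test_that("the ISC rate is quadratic in the coupling and zero without it", {
  expect_identical(isc_rate(0, 0.3), 0)
  set.seed(3)
  for (i in 1:10) {
    v <- runif(1, 0.5, 6)
    gap <- runif(1, 0.1, 0.6)
    expect_equal(isc_rate(2 * v, gap), 4 * isc_rate(v, gap))
    # k / V^2 independent of V
    expect_equal(isc_rate(v, gap) / v^2, isc_rate(1, gap))
  }
})

test_that("a calibrated FCWD reproduces the four reference ISC rates within 1.5x", {
  pts <- tibble::tibble(
    socme = table1_rates$socme,
    gap = table1_rates$e_s1 - table1_rates$e_t1,
    k_isc = table1_rates$k_isc
  )
  fit <- calibrate_fcwd(pts)
  expect_true(fit$converged)
  expect_lt(glance(fit)$max_factor, 1.5)
  # energy-gap law: observed k/V^2 strictly decreases with the gap
  kv2 <- (pts$k_isc / pts$socme^2)[c(1, 3, 4)]
  expect_true(all(diff(kv2) < 0))
  # and so does the calibrated model over the same window
  g <- seq(0.23, 0.39, by = 0.002)
  expect_true(all(diff(isc_rate(1, g, fit$params)) < 0))
})

test_that("calibration recovers noiseless generating parameters within 1%", {
  truth <- fcwd_params(mode_energy = 1400, huang_rhys = 1.2, reorg_low = 800)
  set.seed(2)
  pts <- tibble::tibble(socme = runif(20, 2, 4), gap = runif(20, 0.15, 0.5))
  pts$k_isc <- isc_rate(pts$socme, pts$gap, truth)
  fit <- calibrate_fcwd(
    pts, start = fcwd_params(mode_energy = 1100, huang_rhys = 0.7,
                             reorg_low = 1200)
  )
  est <- tidy(fit)
  expect_equal(est$estimate[est$term == "mode_energy"], 1400, tolerance = 0.01)
  expect_equal(est$estimate[est$term == "huang_rhys"], 1.2, tolerance = 0.01)
  expect_equal(est$estimate[est$term == "reorg_low"], 800, tolerance = 0.01)
  # invariant to point ordering
  perm <- sample(nrow(pts))
  fit2 <- calibrate_fcwd(
    pts[perm, ], start = fcwd_params(mode_energy = 1100, huang_rhys = 0.7,
                                     reorg_low = 1200)
  )
  expect_equal(tidy(fit2)$estimate, est$estimate, tolerance = 1e-8)
})

test_that("underdetermined or degenerate calibrations error", {
  one <- tibble::tibble(socme = 3, gap = 0.3, k_isc = 1e9)
  expect_error(calibrate_fcwd(one, free = c("mode_energy", "huang_rhys")),
               "distinct gaps|points")
  same_gap <- tibble::tibble(socme = c(2, 3), gap = c(0.3, 0.3),
                             k_isc = c(1e9, 2e9))
  expect_error(calibrate_fcwd(same_gap), "distinct gaps")
  two <- tibble::tibble(socme = c(2, 3), gap = c(0.25, 0.35),
                        k_isc = c(1e9, 5e8))
  expect_error(calibrate_fcwd(two), "underdetermined")
})

# Independent oracle: the same golden-rule X-H expression assembled by
# direct enumeration — factorials by explicit product, the bound Morse
# ladder by explicit level search — with no shared code path.
ic_oracle <- function(gap_ev, nacme, modes) {
  gap_cm <- gap_ev * 8065.544
  total <- 0
  for (r in seq_len(nrow(modes))) {
    w <- modes$frequency[r]; chi <- modes$anharmonicity[r]
    best_n <- 1L; best <- Inf
    for (n in seq_len(max(1, floor(1 / (2 * chi) - 0.5)))) {
      lev <- w * n - w * chi * n * (n + 1)
      if (abs(lev - gap_cm) < best) { best <- abs(lev - gap_cm); best_n <- n }
    }
    s <- best_n * chi
    fc <- exp(-s)
    for (n in seq_len(best_n)) fc <- fc * s / n
    total <- total + modes$count[r] * fc / w
  }
  4 * pi^2 * 2.99792458e10 * (nacme * 219474.6313)^2 * total
}

test_that("the X-H internal-conversion rate matches the brute-force oracle", {
  expect_identical(ic_rate_xh(1.67, 0), 0)
  set.seed(11)
  for (i in 1:10) {
    modes <- xh_modes(
      count = sample(1:25, 3, replace = TRUE),
      frequency = runif(3, 1500, 3800),
      anharmonicity = runif(3, 0.005, 0.09)
    )
    gap <- runif(1, 0.8, 3)       # <= 12 quanta for these frequencies
    nacme <- runif(1, 1e-5, 1e-3)
    expect_equal(ic_rate_xh(gap, nacme, modes),
                 ic_oracle(gap, nacme, modes), tolerance = 1e-8)
  }
})

test_that("the harmonic limit agrees with the analytic Poisson factor", {
  chi <- 1e-6
  modes <- xh_modes(10, 3000, chi)
  gap <- 1.115  # ~ 3 quanta of 3000 cm^-1
  n <- round(gap * 8065.544 / 3000)
  s <- n * chi
  analytic <- 4 * pi^2 * 2.99792458e10 * (5e-5 * 219474.6313)^2 *
    10 * exp(-s) * s^n / factorial(n) / 3000
  expect_equal(ic_rate_xh(gap, 5e-5, modes), analytic, tolerance = 1e-8)
})

test_that("the internal-conversion rate obeys the energy-gap law", {
  gaps <- seq(0.9, 3.2, by = 0.01)
  k <- vapply(gaps, ic_rate_xh, numeric(1), nacme = 5e-5,
              modes = default_xh_modes())
  expect_true(all(diff(k) <= 0))
  # default inventory and a weak coupling land on the ~1e6 s^-1 scale
  k167 <- ic_rate_xh(1.67, 5e-5, default_xh_modes())
  expect_gt(k167, 1e5)
  expect_lt(k167, 1e7)
  expect_error(ic_rate_xh(1.67, 1e-4, modes = xh_modes(integer(), numeric(),
                                                       numeric())),
               "no accepting channel")
})

test_that("compute_rates resolves channels with labelled provenance", {
  fx <- load_table1_fixtures()
  g16 <- fx[["Ag16(G)"]]
  rs <- compute_rates(g16, prefer = "computed")
  expect_equal(rs$rate[rs$channel == "k_r"], 1.61e8, tolerance = 0.02)
  expect_identical(rs$provenance[rs$channel == "k_r"], "computed")
  expect_identical(rs$provenance[rs$channel == "k_isc"], "computed")
  # k_IC has no NACME inputs: falls back to the supplied value
  expect_identical(rs$provenance[rs$channel == "k_ic"], "supplied")
  expect_equal(rs$rate[rs$channel == "k_ic"], 4.96e6)
  # supplied-precedence path returns the stored table verbatim
  rs2 <- compute_rates(g16, prefer = "supplied")
  expect_equal(rs2$rate, g16$supplied_rates$rate)
  expect_true(all(rs2$provenance == "supplied"))
})

test_that("compute_rates errors name what is missing", {
  dark <- minimal_descriptor(f = 0, supplied_rates = rate_set(k_ic = 1e6))
  rs <- compute_rates(dark, prefer = "computed")
  expect_identical(rs$rate[rs$channel == "k_r"], 0)
  no_t1 <- emitter_descriptor(
    name = "noT1",
    contexts = list("S1-opt" = electronic_states("S1", 1.9, 1.1)),
    socme_s1_t1 = 3, supplied_rates = rate_set(k_ic = 1e6)
  )
  expect_error(compute_rates(no_t1, prefer = "computed"), "E\\(T1\\)")
  no_kic <- minimal_descriptor()
  expect_error(compute_rates(no_kic), "k_ic")
})
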