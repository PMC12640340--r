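test_that("effective SLDs hit the pure-component endpoints exactly", {
  s <- sld_set()
  e0 <- effective_slds(0, s)
  expect_identical(e0$rho_i, s$rho_t)
  expect_identical(e0$rho_o, s$rho_h)
  e1 <- effective_slds(1, s)
  expect_identical(e1$rho_i, s$rho_p)
  expect_identical(e1$rho_o, s$rho_s)
  expect_equal(e1$drho_o, 0)
})

test_that("effective SLDs are affine in x and match a hand evaluation", {
  s <- sld_set()
  # hand evaluation at the refined fraction of the highest loading
  e <- effective_slds(0.030, s)
  expect_equal(e$rho_i, 8.79e-6, tolerance = 1e-10)
  # affinity: midpoint value equals mean of endpoint values
  xs <- runif(20)
  for (i in seq_len(10)) {
    a <- xs[2 * i - 1]
    b <- xs[2 * i]
    mid <- effective_slds((a + b) / 2, s)
    expect_equal(mid$rho_i,
                 (effective_slds(a, s)$rho_i + effective_slds(b, s)$rho_i) / 2)
    expect_equal(mid$rho_o,
                 (effective_slds(a, s)$rho_o + effective_slds(b, s)$rho_o) / 2)
  }
  expect_error(effective_slds(-0.01), "\\[0, 1\\]")
  expect_error(effective_slds(1.2), "\\[0, 1\\]")
})

test_that("uniform-contrast bilayer reduces to the slab form with exact zeros", {
  # make both layers share one contrast by using equal head/tail/protein SLDs
  rho <- 1.2e-5
  s <- sld_set(rho_s = 9.46e-6, rho_t = rho, rho_h = rho, rho_p = rho)
  m <- bilayer_model(L_t = 14.3, L_h = 6.65, slds = s)
  d <- m$L_t + m$L_h
  drho <- rho - s$rho_s
  q <- seq(0.01, 0.35, length.out = 200)
  expect_equal(lamellar_intensity(q, m),
               4 * pi * drho^2 * sin(q * d)^2 / (q^4 * d), tolerance = 1e-12)
  # zeros exactly at q = n pi / d
  qz <- (1:3) * pi / d
  expect_equal(lamellar_intensity(qz, m), rep(0, 3),
               tolerance = 1e-25 * lamellar_intensity(0.01, m))
})

test_that("lamellar curve approaches a -2 log-log slope at low q", {
  m <- bilayer_model(L_t = 14.3, L_h = 6.65, x = 0.012)
  q <- c(1e-5, 2e-5)
  I <- lamellar_intensity(q, m)
  slope <- diff(log(I)) / diff(log(q))
  expect_equal(slope, -2, tolerance = 1e-6)
  # and the q^2-scaled limit matches the Taylor value
  ec <- effective_slds(m$x, m$slds)
  lim <- 4 * pi * (ec$drho_o * m$L_h + ec$drho_i * m$L_t)^2 /
    (m$L_h + m$L_t)
  expect_equal(q^2 * I, rep(lim, 2), tolerance = 1e-6)
  expect_error(lamellar_intensity(c(-0.1, 0.1), m), "positive")
  expect_error(lamellar_intensity(0, m), "positive")
})

test_that("lamellar model agrees with the quadrature oracle", {
  set.seed(11)
  for (i in 1:10) {
    L_t <- runif(1, 10, 20)
    L_h <- runif(1, 4, 10)
    x <- runif(1, 0, 0.1)
    q <- sort(runif(5, 0.004, 0.35))
    m <- bilayer_model(L_t = L_t, L_h = L_h, x = x)
    expect_equal(lamellar_intensity(q, m), oracle_lamellar(q, L_t, L_h, x),
                 tolerance = 1e-8)
  }
})

test_that("core-shell micelle limits and oracle agreement hold", {
  s <- sld_set()
  v_c <- 4 / 3 * pi * 14.3^3
  v_tot <- 4 / 3 * pi * (14.3 + 6.65)^3
  # q -> 0 limit equals the squared total excess scattering length
  i0 <- ((s$rho_t - s$rho_h) * v_c + (s$rho_h - s$rho_s) * v_tot)^2
  expect_equal(micelle_intensity(1e-10, 14.3, 6.65, s$rho_t, s$rho_h,
                                 s$rho_s), i0, tolerance = 1e-12)
  # equal core and shell SLDs collapse to a homogeneous sphere
  q <- seq(0.01, 0.35, length.out = 50)
  rho <- 1.1e-5
  u <- q * (14.3 + 6.65)
  hom <- ((rho - s$rho_s) * v_tot * 3 * (sin(u) - u * cos(u)) / u^3)^2
  expect_equal(micelle_intensity(q, 14.3, 6.65, rho, rho, s$rho_s), hom,
               tolerance = 1e-12)
  # series branch is continuous at the switch point
  r <- 14.3
  q_sw <- 1e-4 / r
  expect_equal(micelle_intensity(q_sw * (1 - 1e-6), r, 6.65, s$rho_t,
                                 s$rho_h, s$rho_s),
               micelle_intensity(q_sw * (1 + 1e-6), r, 6.65, s$rho_t,
                                 s$rho_h, s$rho_s), tolerance = 1e-6)
  expect_error(micelle_intensity(0.1, -1, 6, s$rho_t, s$rho_h, s$rho_s),
               "positive")
  expect_error(micelle_intensity(0.1, 14, -1, s$rho_t, s$rho_h, s$rho_s),
               "non-negative")
  # radial quadrature oracle
  set.seed(12)
  for (i in 1:10) {
    rc <- runif(1, 10, 20)
    ts <- runif(1, 4, 10)
    qq <- sort(runif(5, 0.004, 0.35))
    expect_equal(micelle_intensity(qq, rc, ts, s$rho_t, s$rho_h, s$rho_s),
                 oracle_micelle(qq, rc, ts, s$rho_t, s$rho_h, s$rho_s),
                 tolerance = 1e-8)
  }
})

test_that("combined model equals the sum of its parts and degenerates cleanly", {
  q <- exp(seq(log(0.004), log(0.35), length.out = 80))
  m <- bilayer_model(L_t = 14.3, L_h = 6.65, x = 0.03, R = 5.37,
                     C1 = 2, C2 = 5e-7, B = 1e-11)
  # term-by-term recomputation
  damp <- exp(-m$R^2 * q^2)
  expect_equal(combined_intensity(q, m),
               m$C1 * lamellar_intensity(q, m) * damp +
                 m$C2 * micelle_intensity(q, m$L_t, m$L_h, m$slds$rho_t,
                                          m$slds$rho_h, m$slds$rho_s) * damp +
                 m$B, tolerance = 1e-14)
  # R = 0, C2 = 0, B = 0 collapses to the bare lamellar term
  m0 <- bilayer_model(L_t = 14.3, L_h = 6.65, x = 0.03, C1 = 2)
  expect_equal(combined_intensity(q, m0), 2 * lamellar_intensity(q, m0),
               tolerance = 1e-14)
  # C1 = C2 = 0 leaves the constant background
  mb <- bilayer_model(C1 = 0, C2 = 0, B = 3.5)
  expect_equal(combined_intensity(q, mb), rep(3.5, length(q)))
  expect_error(combined_intensity(rev(q), m), "increasing")
})

test_that("damping makes intensity non-increasing in roughness", {
  q <- exp(seq(log(0.004), log(0.35), length.out = 40))
  base <- bilayer_model(x = 0.012, C2 = 5e-7, B = 1e-11)
  Rs <- seq(0, 12, by = 1.5)
  curves <- sapply(Rs, function(r) {
    m <- base
    m$R <- r
    combined_intensity(q, m) - m$B
  })
  for (i in seq_len(length(Rs) - 1))
    expect_true(all(curves[, i + 1] <= curves[, i] + 1e-18))
})

test_that("inner-layer contrast match removes the tail term identically", {
  s <- sld_set()
  x_star <- (s$rho_s - s$rho_t) / (s$rho_p - s$rho_t)
  e <- effective_slds(x_star, s)
  expect_equal(e$drho_i, 0, tolerance = 1e-20)
  m <- bilayer_model(L_t = 14.3, L_h = 6.65, x = x_star, slds = s)
  q <- seq(0.01, 0.35, length.out = 100)
  d <- m$L_t + m$L_h
  outer_only <- 4 * pi / (q^4 * d) *
    (e$drho_o * (sin(q * d) - sin(q * m$L_t)))^2
  expect_equal(lamellar_intensity(q, m), outer_only, tolerance = 1e-12)
})
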