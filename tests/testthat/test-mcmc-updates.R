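test_that("global ancestry proposal is the documented Dirichlet and flat priors always accept", {
  set.seed(1)
  # omega = (1,1): acceptance ratio is identically 1, so the chain samples the
  # proposal Dirichlet(omega + sum gamma) = Dirichlet(31, 11) directly
  A <- matrix(0.5, 2000, 2)
  gs <- matrix(rep(c(30, 10), each = 2000), 2000)
  up <- update_global_ancestry(A, gs, c(1, 1))
  expect_true(all(up$accepted))
  expect_true(all(up$accept_prob == 1))
  expect_equal(mean(up$value[, 1]), 31 / 42, tolerance = 0.005)
  expect_equal(var(up$value[, 1]), 31 * 11 / (42^2 * 43), tolerance = 0.1)
  expect_equal(rowSums(up$value), rep(1, 2000), tolerance = 1e-12)
})

test_that("ancestry updates keep the simplex and acceptance in [0,1]", {
  set.seed(2)
  A <- rdirichlet(50, c(5, 3, 2))
  for (i in 1:20) {
    gs <- matrix(rgamma(150, 5), 50, 3)
    up <- update_global_ancestry(A, gs, c(8, 4, 2))
    A <- up$value
    expect_true(all(up$accept_prob >= 0 & up$accept_prob <= 1))
    expect_equal(rowSums(A), rep(1, 50), tolerance = 1e-12)
    expect_true(all(A > 0))
  }
})

test_that("X ancestry proposal concentrates around omega_X * A", {
  set.seed(3)
  # omega_X * A = (1, 1): exponents vanish, every proposal accepted,
  # and with no X windows the proposal is Dirichlet(omega_X * A)
  A <- matrix(0.5, 3000, 2)
  AX <- matrix(0.5, 3000, 2)
  up <- update_x_ancestry(AX, A, matrix(0, 3000, 2), omega_x = 2)
  expect_true(all(up$accepted))
  expect_equal(mean(up$value[, 1]), 0.5, tolerance = 0.02)   # Dir(1,1) mean
  # documented arithmetic: omega_X = 10, A = (0.8, 0.2), no X windows
  # -> concentration (8, 2); verify via the empirical mean 0.8 of a chain
  A2 <- matrix(rep(c(0.8, 0.2), each = 3000), 3000)
  AX2 <- matrix(rep(c(0.8, 0.2), each = 3000), 3000)
  up2 <- update_x_ancestry(AX2, A2, matrix(0, 3000, 2), omega_x = 10)
  moved <- up2$accepted
  expect_gt(mean(moved), 0.3)
  expect_equal(mean(up2$value[moved, 1]), 0.8, tolerance = 0.05)
})

test_that("lambda update with a flat Gamma kernel samples the conjugate proposal", {
  set.seed(4)
  # alpha = (1, 0): prior kernel is constant, so draws follow
  # Gamma(1 + crossovers, sum_d)
  lam <- rep(5, 5000)
  up <- update_lambda(lam, n_crossovers = rep(5, 5000), sum_d = 3,
                      alpha = c(1, 0))
  expect_true(all(up$accepted))
  expect_equal(mean(up$value), 6 / 3, tolerance = 0.02)
  expect_equal(var(up$value), 6 / 9, tolerance = 0.05)
})

test_that("allele frequency update uses conjugate counts in the coherent orientation", {
  set.seed(5)
  # tau = 2, P = 0.5: flat Beta(1,1) kernel, all proposals accepted;
  # variant counts enter the first (variant) shape: Beta(1 + 3, 1 + 7)
  p <- matrix(0.5, 4000, 1)
  up <- update_allele_freqs(p, n_var = matrix(3, 4000, 1),
                            n_ref = matrix(7, 4000, 1), tau = 2,
                            P = matrix(0.5, 4000, 1))
  expect_true(all(up$accepted))
  expect_equal(mean(up$value), 4 / 12, tolerance = 0.01)
  expect_true(all(up$value > 0 & up$value < 1))
})

test_that("beta update acceptance matches an independent quadratic-form oracle", {
  # re-derive proposal and acceptance outside the implementation
  b <- c(0.4, -1.2); bh <- c(1.1, 0.3); B0 <- c(0.2, -0.5)
  S <- c(0.5, 0.2); n <- 40; tau <- 30
  for (s in 1:20) {
    set.seed(s)
    up <- update_beta(b, bh, n, tau, B0, S)
    set.seed(s)
    prop <- rnorm(2, (n * bh + tau * B0) / (n + tau), sqrt(S) / (n + tau))
    qf <- function(x) sum((x - B0)^2 / S)
    ap <- min(1, exp(-tau^2 / 2 * (qf(prop) - qf(b))))
    expect_equal(up$accept_prob, ap, tolerance = 1e-12)
  }
  # shrinkage limits of the proposal mean: tau -> 0 gives beta_hat (all
  # proposals accepted since the kernel exponent carries tau^2)
  set.seed(6)
  bh2 <- c(2, 2); B2 <- c(-2, -2)
  ups <- replicate(2000, update_beta(c(0, 0), bh2, n = 50, tau = 1e-9,
                                     B = B2, Sigma_diag = c(1, 1))$value)
  expect_true(all(abs(rowMeans(ups) - bh2) < 0.01))
  # tau >> n: proposals collapse onto B and are accepted (qf ~ 0)
  ups2 <- replicate(2000, update_beta(c(0, 0), bh2, n = 0.001, tau = 1e6,
                                      B = B2, Sigma_diag = c(1, 1))$value)
  expect_true(all(abs(rowMeans(ups2) - B2) < 0.01))
})

test_that("hyperparameter P acceptance matches a direct Beta-density-ratio oracle", {
  P <- matrix(0.4, 1, 1); p <- matrix(0.3, 1, 1)
  Ov <- matrix(3.5, 1, 1); Or <- matrix(7.5, 1, 1); tau <- 80
  for (s in 1:20) {
    set.seed(s)
    up <- update_hyper_P(P, Ov, Or, tau, p)
    set.seed(s)
    prop <- min(max(rbeta(1, 3.5, 7.5), 1e-12), 1 - 1e-12)
    ap <- min(1, exp(dbeta(0.3, tau * prop, tau * (1 - prop), log = TRUE) -
                       dbeta(0.3, tau * 0.4, tau * 0.6, log = TRUE)))
    expect_equal(as.numeric(up$accept_prob), ap, tolerance = 1e-12)
    if (up$accepted) expect_equal(as.numeric(up$value), prop)
  }
})

test_that("hyperparameter B update always accepts as tau -> 0", {
  set.seed(8)
  for (i in 1:50) {
    up <- update_hyper_B(B = rnorm(3), H = rnorm(3), Sigma_diag = runif(3),
                         tau = 0, beta = rnorm(3))
    expect_equal(up$accept_prob, 1)
    expect_true(up$accepted)
  }
})

test_that("tau update: flat data gives acceptance 1 and the log-normal prior median", {
  set.seed(9)
  p0 <- matrix(numeric(0), 0, 1)   # no markers, no coefficients
  draws <- replicate(4000, update_tau(c(100), p0, p0)$value)
  expect_equal(median(log10(draws)), 2, tolerance = 0.03)   # prior median 100
  up <- update_tau(c(100), p0, p0)
  expect_equal(up$accept_prob, 1)
})

test_that("omega update respects its log-normal prior and Dirichlet ratio", {
  set.seed(10)
  A <- rdirichlet(5, c(8, 2))
  om <- c(10, 10)
  aps <- numeric(200)
  for (i in 1:200) {
    up <- update_omega(om, A)
    aps[i] <- up$accept_prob
    if (!up$accepted) expect_identical(up$value, om)
    om <- up$value
  }
  expect_true(all(aps >= 0 & aps <= 1))
  expect_true(all(om > 0))
  # selective component update leaves the frozen component unchanged
  up1 <- update_omega(c(10, 7), A, which = c(TRUE, FALSE))
  expect_equal(up1$value[2], 7)
})

test_that("alpha update reparameterizes by Gamma mean and variance", {
  # m = 6, v = 4 -> alpha = (9, 1.5)
  expect_equal(c(6^2 / 4, 6 / 4), c(9, 1.5))
  set.seed(11)
  # no lambda values: likelihood flat, components sampled from their priors
  up <- update_alpha(c(9, 1.5), numeric(0))
  expect_true(all(up$accepted))
  expect_equal(unname(up$value[1]), unname(up$mv["m"]^2 / up$mv["v"]))
  expect_equal(unname(up$value[2]), unname(up$mv["m"] / up$mv["v"]))
  draws <- replicate(3000, update_alpha(c(9, 1.5), numeric(0),
                                        which = "m")$mv["m"])
  expect_equal(median(log10(draws)), 1, tolerance = 0.03)
})

test_that("crossover augmentation matches a naive three-step rejection oracle", {
  set.seed(12)
  lam <- 6; d <- 8
  w <- build_windows(c(1, 1), c(0, 8), 5)   # two windows, midpoint gap 8 cM
  expect_equal(w$d_cm, c(NA, 8))
  A <- matrix(c(0.8, 0.2), 1)
  n <- 20000
  # implementation: same state at both windows
  G <- matrix(1L, 1, 2)
  got <- replicate(n, sample_crossovers(G, w, lam, A)$nx[1, 2])
  # naive oracle running the three steps literally
  rate <- lam * d / 100
  oracle <- replicate(n, {
    nx <- 0
    repeat { nx <- rpois(1, rate); if (nx >= 1) break }   # truncated Poisson
    e <- exp(-rate); Ag <- 0.8
    pgt0 <- Ag * (1 - e) / (e + Ag * (1 - e))
    if (runif(1) < 1 - (1 - pgt0)) nx else 0
  })
  tab_g <- table(factor(got, levels = 0:8))
  tab_o <- table(factor(oracle, levels = 0:8))
  tv <- sum(abs(tab_g / n - tab_o / n)) / 2
  expect_lt(tv, 0.02)
  # ancestry switch: crossover always retained, count >= 1
  G2 <- matrix(c(1L, 2L), 1)
  got2 <- replicate(2000, sample_crossovers(G2, w, lam, A))
  expect_true(all(unlist(lapply(got2["nx", ], function(m) m[1, 2])) >= 1))
  expect_true(all(unlist(lapply(got2["px0", ], function(m) m[1, 2])) == 0))
  # lambda * d -> 0 with equal states: px0 -> 1, almost never retained
  w3 <- build_windows(c(1, 1), c(0, 5.001), 5)
  got3 <- replicate(2000, sample_crossovers(G, w3, 0.01, A)$nx[1, 2])
  expect_lt(mean(got3 > 0), 0.01)
})

test_that("chain blending follows the burn-in weight schedule", {
  local <- list(A = matrix(c(0.6, 0.4), 1), lambda = c(4, 8),
                p = matrix(0.3, 2, 1), alpha = c(9, 1.5))
  remote <- list(A = matrix(c(0.8, 0.2), 1), lambda = c(6, 6),
                 p = matrix(0.5, 2, 1), alpha = c(4, 1))
  expect_equal(combine_chains(local, remote, 100, 100), local)
  expect_equal(combine_chains(local, remote, 0, 100), remote)
  mid <- combine_chains(local, remote, 50, 100)
  expect_equal(mid$lambda, c(5, 7))
  expect_equal(mid$alpha, c(6.5, 1.25))
  expect_equal(as.numeric(mid$A), c(0.7, 0.3))
  expect_equal(rowSums(mid$A), 1)
  bad <- remote; bad$lambda <- 1:3
  expect_error(combine_chains(local, bad, 10, 100), "mismatch")
})
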