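test_that("recombination probability has the stated closed form", {
  expect_equal(recomb_prob(0, 5), 0)
  # single-generation identity over a distance grid, machine precision
  d <- seq(0, 300, by = 0.5)
  expect_equal(recomb_prob(d, 1), (1 - exp(-2 * d / 100)) / 2,
               tolerance = 1e-15)
  # direct evaluation at lambda = 6, d = 10
  expect_equal(recomb_prob(10, 6), 1 - ((1 + exp(-0.2)) / 2)^6,
               tolerance = 1e-15)
  expect_equal(round(recomb_prob(10, 6), 4), 0.4345)
  expect_error(recomb_prob(-1, 2), "negative")
})

test_that("crossover probability is Poisson-based and monotone", {
  expect_equal(crossover_prob(0, 6), 0)
  expect_equal(crossover_prob(0.1, 6), 1 - exp(-0.006), tolerance = 1e-15)
  expect_equal(round(crossover_prob(0.1, 6), 6), 0.005982)
  w <- seq(0.1, 50, length.out = 200)
  expect_true(all(diff(crossover_prob(w, 3)) > 0))
  expect_true(all(crossover_prob(2 * w, 3) > crossover_prob(w, 3)))
})

test_that("transition prior is the stated convex combination", {
  g <- c(0.9, 0.1); A <- c(0.8, 0.2)
  expect_equal(transition_prior(g, A, 1), A)
  expect_equal(transition_prior(g, A, 0), g)
  expect_equal(transition_prior(g, A, 0.3), c(0.87, 0.13))
  expect_equal(sum(transition_prior(g, A, 0.42)), 1)
})

test_that("emission probability composes frequency and PCR terms", {
  s <- toy_study()
  j <- which(!vapply(s$priors$win, `[[`, logical(1), "freq_only"))[3]
  w <- s$priors$win[[j]]
  hap <- s$sim$haplotypes[1, ]
  x <- hap[w$members]
  sup <- hap[w$support]
  lambda <- 6
  p1 <- s$priors$P[w$members, 1]
  got <- emission_prob(x, sup, k = 1, win = w, p = p1, lambda = lambda,
                       support_cm = s$priors$support_cm)
  # independent composition of crossover_prob, projection and inverse logit
  cp <- 1 - exp(-lambda * s$priors$support_cm / 100)
  sc <- c(1, (sup - w$pop[[1]]$pca$center) %*% w$pop[[1]]$pca$loadings)
  q <- 1 / (1 + exp(-as.numeric(sc %*% w$pop[[1]]$H)))
  f <- p1 * cp + q * (1 - cp)
  oracle <- prod(ifelse(x == 1, f, 1 - f))
  expect_equal(got, oracle, tolerance = 1e-12)

  # missing observations contribute a factor of one
  expect_equal(emission_prob(rep(NA, length(x)), sup, 1, w, p1,
                             lambda = lambda), 1)
  # certain crossover collapses the mixture to the allele frequency
  got_inf <- emission_prob(x, sup, 1, w, p1, lambda = 1e9, support_cm = 2)
  expect_equal(got_inf, prod(ifelse(x == 1, p1, 1 - p1)), tolerance = 1e-9)
})

test_that("forward-backward equals exhaustive path enumeration", {
  set.seed(101)
  for (rep in 1:20) {
    K <- sample(2:3, 1)
    J <- sample(1:4, 1)
    emiss <- matrix(runif(J * K, 0.05, 1), J, K)
    d <- c(NA, runif(J - 1, 0.01, 5))[seq_len(J)]
    lambda <- runif(1, 1, 12)
    A <- as.numeric(rdirichlet(1, rep(2, K)))
    got <- forward_backward(emiss, d, lambda, A)
    oracle <- enum_fb_oracle(emiss, d, lambda, A)
    expect_equal(got$gamma, oracle, tolerance = 1e-10)
    expect_equal(rowSums(got$gamma), rep(1, J), tolerance = 1e-10)
  }
})

test_that("single-window chromosome with missing data reflects only the prior", {
  # both chains reduce to the global prior; the printed chain-product
  # combination then yields norm(A * A), which the enumeration oracle confirms
  A <- c(0.7, 0.3)
  got <- forward_backward(matrix(1, 1, 2), NA, 6, A)
  expect_equal(as.numeric(got$gamma), A^2 / sum(A^2))
  expect_equal(got$gamma, enum_fb_oracle(matrix(1, 1, 2), NA, 6, A),
               tolerance = 1e-12)
  expect_equal(as.numeric(got$forward), A)   # each single chain is the prior
  expect_equal(as.numeric(got$reverse), A)
})

test_that("uninformative emissions carry no information beyond the prior", {
  A <- c(0.6, 0.3, 0.1)
  emiss <- matrix(1, 5, 3)
  got <- forward_backward(emiss, c(NA, 1, 2, 0.5, 3), 4, A)
  for (j in 1:5) {
    expect_equal(got$forward[j, ], A, tolerance = 1e-12)
    expect_equal(got$reverse[j, ], A, tolerance = 1e-12)
    expect_equal(got$gamma[j, ], A^2 / sum(A^2), tolerance = 1e-12)
  }
})

test_that("reversing the window order swaps the two chains", {
  set.seed(55)
  J <- 6; K <- 2
  emiss <- matrix(runif(J * K, 0.1, 1), J, K)
  d <- c(NA, runif(J - 1, 0.1, 2))
  A <- c(0.8, 0.2)
  fwd <- forward_backward(emiss, d, 5, A)
  rev_d <- c(NA, rev(d[-1]))
  bwd <- forward_backward(emiss[J:1, ], rev_d, 5, A)
  expect_equal(bwd$gamma, fwd$gamma[J:1, ], tolerance = 1e-12)
  expect_equal(bwd$forward, fwd$reverse[J:1, ], tolerance = 1e-12)
})

test_that("large inter-window distance decouples windows", {
  A <- c(0.75, 0.25)
  emiss <- rbind(c(0.9, 0.1), c(0.2, 0.9))
  # note recomb_prob saturates at 1 - 2^(-lambda), so residual coupling of
  # that order remains; lambda = 40 makes it negligible
  near <- forward_backward(emiss, c(NA, 0.01), 40, A)
  far <- forward_backward(emiss, c(NA, 1e6), 40, A)
  # both chains decouple to the emission-weighted prior; the combination is
  # their normalized product
  ew <- emiss[2, ] * A / sum(emiss[2, ] * A)
  decoupled <- ew^2 / sum(ew^2)
  expect_equal(far$gamma[2, ], decoupled, tolerance = 1e-6)
  expect_gt(abs(near$gamma[2, 1] - decoupled[1]), 1e-4)
})

test_that("state sampling is categorical, calibrated and reproducible", {
  g <- matrix(c(1, 0), 50, 2, byrow = TRUE)
  expect_true(all(sample_states(g) == 1L))
  set.seed(8)
  draws <- sample_states(matrix(0.5, 1e5, 2))
  expect_equal(mean(draws == 1), 0.5, tolerance = 0.005)
  prop_rows <- function(m) m / rowSums(m)
  set.seed(123); a <- sample_states(prop_rows(matrix(runif(300), 100, 3)))
  set.seed(123); b <- sample_states(prop_rows(matrix(runif(300), 100, 3)))
  expect_identical(a, b)
})

test_that("batched forward-backward agrees with the per-copy function", {
  s <- toy_study()
  pre <- aldmix:::precompute_designs(s$sim$haplotypes[1:4, ], s$priors)
  beta <- lapply(s$priors$win, function(w)
    if (w$freq_only) NULL else lapply(w$pop, function(pk) pk$H))
  lambda <- c(4, 6, 8, 5)
  le <- aldmix:::emission_loglik(pre, s$priors, s$priors$P, beta, lambda)
  A <- rbind(c(0.8, 0.2), c(0.7, 0.3), c(0.9, 0.1), c(0.5, 0.5))
  g <- aldmix:::fb_batch(le, s$windows, lambda, A)$gamma
  for (cc in 1:4) {
    em <- exp(le[cc, , ] - apply(le[cc, , ], 1, max))
    ref <- forward_backward(em, s$windows$d_cm, lambda[cc], A[cc, ])
    expect_equal(g[cc, , ], ref$gamma, tolerance = 1e-10)
  }
})

test_that("batched emissions match the scalar emission function", {
  s <- toy_study()
  pre <- aldmix:::precompute_designs(s$sim$haplotypes[1:3, ], s$priors)
  beta <- lapply(s$priors$win, function(w)
    if (w$freq_only) NULL else lapply(w$pop, function(pk) pk$H))
  lambda <- c(5, 7, 6)
  le <- aldmix:::emission_loglik(pre, s$priors, s$priors$P, beta, lambda)
  for (j in c(2, 10, 25)) {
    w <- s$priors$win[[j]]
    for (cc in 1:3) for (k in 1:2) {
      hap <- s$sim$haplotypes[cc, ]
      ref <- emission_prob(hap[w$members], hap[w$support], k, w,
                           s$priors$P[w$members, k], lambda = lambda[cc],
                           support_cm = s$priors$support_cm)
      expect_equal(exp(le[cc, j, k]), ref, tolerance = 1e-8)
    }
  }
})

test_that("joint path sampling matches the enumerated path posterior", {
  set.seed(606)
  J <- 3; K <- 2
  emiss <- matrix(runif(J * K, 0.1, 1), J, K)
  d <- c(NA, 0.8, 1.4)
  lambda <- 6
  A <- c(0.75, 0.25)
  le <- array(log(emiss), c(1, J, K))
  le <- aperm(array(log(emiss), c(J, K, 1)), c(3, 1, 2))
  w <- build_windows(rep(1, J), c(0.05, 0.85, 2.25), 0.1)  # d = (NA, .8, 1.4)
  fb <- aldmix:::fb_batch(le, data.frame(d_cm = d), lambda, matrix(A, 1))
  n <- 40000
  paths <- matrix(0L, n, J)
  for (i in seq_len(n))
    paths[i, ] <- aldmix:::sample_paths(fb, matrix(A, 1))[1, ]
  # enumeration oracle over all K^J paths of the directional chain
  pr <- recomb_prob(c(0, d[-1]), lambda)
  Tm <- function(j) outer(rep(1, K), A * pr[j]) + diag(K) * (1 - pr[j])
  all_paths <- as.matrix(expand.grid(g1 = 1:K, g2 = 1:K, g3 = 1:K))
  wts <- apply(all_paths, 1, function(g)
    A[g[1]] * emiss[1, g[1]] * Tm(2)[g[1], g[2]] * emiss[2, g[2]] *
      Tm(3)[g[2], g[3]] * emiss[3, g[3]])
  wts <- wts / sum(wts)
  key <- function(m) m[, 1] * 100 + m[, 2] * 10 + m[, 3]
  emp <- table(factor(key(paths), levels = sort(key(all_paths)))) / n
  expect_lt(max(abs(as.numeric(emp) - wts[order(key(all_paths))])), 0.01)
  # switch counts follow the path posterior, not the marginal product
  exp_sw <- sum(wts * rowSums(all_paths[, -1] != all_paths[, -J]))
  obs_sw <- mean(rowSums(paths[, -1] != paths[, -J]))
  expect_lt(abs(obs_sw - exp_sw), 0.02)
})
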