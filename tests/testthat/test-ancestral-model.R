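test_that("window PCA matches a brute-force eigendecomposition", {
  set.seed(3)
  panel <- matrix(rbinom(500, 1, 0.4), 50, 10)
  pca <- fit_window_pca(panel, var_threshold = 0.8)
  # independent dense symmetric eigensolver on the covariance matrix
  ctr <- sweep(panel, 2, colMeans(panel))
  cv <- t(ctr) %*% ctr / (nrow(panel) - 1)
  ev <- eigen(cv, symmetric = TRUE)
  q <- pca$q
  expect_equal(pca$eigenvalues[seq_len(q)], ev$values[seq_len(q)],
               tolerance = 1e-10)
  for (i in seq_len(q))   # eigenvectors up to sign
    expect_equal(abs(sum(pca$loadings[, i] * ev$vectors[, i])), 1,
                 tolerance = 1e-8)
  # orthonormality
  expect_equal(crossprod(pca$loadings), diag(q), tolerance = 1e-8,
               ignore_attr = TRUE)
  # cumulative-variance retention rule
  frac <- cumsum(ev$values[ev$values > 0]) / sum(ev$values[ev$values > 0])
  expect_equal(q, which(frac >= 0.8)[1])
})

test_that("component count follows the cumulative 80% rule on fixed spectra", {
  # eigenvalue fractions (0.5, 0.3, 0.15, 0.05): two components reach 0.8
  frac <- cumsum(c(0.5, 0.3, 0.15, 0.05))
  expect_equal(which(frac >= 0.8)[1], 2)
  # a matrix constructed to have exactly that covariance spectrum retains 2
  n <- 8
  H <- stats::contr.helmert(n)                     # orthogonal, mean-zero columns
  H <- sweep(H, 2, sqrt(colSums(H^2)), "/")[, 1:4]
  Z <- H %*% diag(sqrt(c(0.5, 0.3, 0.15, 0.05) * (n - 1)))
  pca <- fit_window_pca(Z, var_threshold = 0.8)
  expect_equal(pca$q, 2L)
})

test_that("identical haplotypes give a degenerate PCA", {
  panel <- matrix(1L, 20, 5)
  pca <- fit_window_pca(panel)
  expect_true(pca$degenerate)
})

test_that("projection applies fit-time centering", {
  set.seed(5)
  panel <- matrix(rbinom(160, 1, 0.5), 20, 8)
  pca <- fit_window_pca(panel)
  # the column-mean haplotype projects to the origin
  expect_equal(as.numeric(project_pcs(matrix(colMeans(panel), 1), pca)),
               rep(0, pca$q), tolerance = 1e-12)
  # random haplotypes match a naive triple-loop matrix multiply
  h <- matrix(rbinom(64, 1, 0.5), 8, 8)
  got <- project_pcs(h, pca)
  ctr <- sweep(h, 2, pca$center)
  oracle <- matrix(0, 8, pca$q)
  for (i in 1:8) for (j in seq_len(pca$q)) for (m in 1:8)
    oracle[i, j] <- oracle[i, j] + ctr[i, m] * pca$loadings[m, j]
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_error(project_pcs(matrix(0, 1, 3), pca), "columns")
})

test_that("single-component unit loading returns the centered allele", {
  pca <- list(loadings = matrix(c(1, 0, 0), 3, 1), center = c(0.5, 0.2, 0.3),
              q = 1L)
  h <- matrix(c(1, 0, 1), 1, 3)
  expect_equal(as.numeric(project_pcs(h, pca)), 0.5)
})

test_that("label PCR recovers no-signal and strong-signal cases", {
  set.seed(21)
  # identical haplotype distributions: slopes near 0, intercept = log(n2/n1)
  base <- matrix(rbinom(3000, 1, 0.5), 150, 20)
  panels <- list(base[1:50, ], base[51:150, ])
  pca <- fit_window_pca(panels[[1]])
  fit <- fit_pcr(panels, pca)
  expect_lt(mean(abs(fit$H[-1, 1])), 0.35)
  expect_equal(fit$H[1, 1], log(100 / 50), tolerance = 0.5)

  # deterministic difference at marker 1, single informative PC:
  # complete separation is handled by the penalty and still classifies
  p1 <- cbind(1L, matrix(0L, 30, 4))
  p2 <- cbind(0L, matrix(0L, 30, 4))
  pca2 <- fit_window_pca(rbind(p1, p2))
  expect_equal(pca2$q, 1L)
  fit2 <- fit_pcr(list(p1, p2), pca2)
  expect_true(fit2$penalized)
  pr1 <- fit2$predict(p1); pr2 <- fit2$predict(p2)
  expect_true(all(pr1[, 1] >= 0.99))
  expect_true(all(pr2[, 2] >= 0.99))
  # agreement with an independent IRLS oracle (ridge-penalized glm via
  # repeated observations is equivalent here to the logistic fit at large
  # coefficient: both assign the training haplotypes to their own class)
  X <- rbind(project_pcs(p1, pca2), project_pcs(p2, pca2))
  y <- rep(c(0, 1), each = 30)
  or <- suppressWarnings(glm(y ~ X, family = binomial))
  pr_or <- predict(or, type = "response")
  expect_true(all(abs(c(1 - pr1[, 1], pr2[, 2]) - pr_or) < 0.02))
})

test_that("multinomial label PCR probabilities sum to one", {
  set.seed(31)
  panels <- lapply(c(0.2, 0.5, 0.8), function(f)
    matrix(rbinom(400, 1, f), 40, 10))
  pca <- fit_window_pca(panels[[1]])
  fit <- fit_pcr(panels, pca)
  pr <- fit$predict(matrix(rbinom(100, 1, 0.5), 10, 10))
  expect_equal(rowSums(pr), rep(1, 10), tolerance = 1e-12)
  expect_equal(dim(fit$H), c(pca$q + 1, 2))
})

test_that("prior allele counts use Jeffreys pseudocounts", {
  map <- toy_map(4, 0.3)   # all markers inside one window -> freq-only path
  panels <- list(pop1 = rbind(c(1, 0, 0, 1), c(1, 1, 0, 0), c(1, 0, 0, 0),
                              c(0, 0, 0, 1), c(0, 0, 0, 0)),
                 pop2 = matrix(rbinom(20, 1, 0.5), 5, 4))
  w <- build_windows(map$chromosome, map$position_cm, 1)
  pr <- compute_priors(panels, w, map$position_cm)
  # marker 1 pop 1: 3 variants of 5 haplotypes -> Omega (3.5, 2.5)
  expect_equal(unname(pr$Omega$var[1, 1]), 3.5)
  expect_equal(unname(pr$Omega$ref[1, 1]), 2.5)
  expect_equal(unname(pr$P[1, 1]), 3.5 / 6)
  # monomorphic reference marker 3 pop 1: P = 0.5 / 6
  expect_equal(unname(pr$P[3, 1]), 0.5 / 6)
  # brute-force tally over a random panel
  set.seed(2)
  big <- list(a = matrix(rbinom(2000, 1, 0.3), 100, 20),
              b = matrix(rbinom(2000, 1, 0.7), 100, 20))
  map2 <- toy_map(20, 0.5)
  w2 <- build_windows(map2$chromosome, map2$position_cm, 1)
  pr2 <- compute_priors(big, w2, map2$position_cm)
  expect_equal(unname(pr2$P[, 1]), unname(colSums(big$a) + 0.5) / 101)
  expect_equal(unname(pr2$P[, 2]), unname(colSums(big$b) + 0.5) / 101)
})

test_that("ten haplotypes with three variants give the documented prior", {
  # Omega = (3.5, 7.5), P = 3.5 / 11 = 0.318
  expect_equal(3.5 / (3.5 + 7.5), 0.318, tolerance = 0.001)
  map <- toy_map(2, 0.05)
  panels <- list(p1 = cbind(rep(c(1, 0), c(3, 7)), rbinom(10, 1, 0.5)),
                 p2 = cbind(rbinom(10, 1, 0.5), rbinom(10, 1, 0.5)))
  w <- build_windows(map$chromosome, map$position_cm, 0.1)
  pr <- compute_priors(panels, w, map$position_cm)
  expect_equal(unname(pr$Omega$var[1, 1]), 3.5)
  expect_equal(unname(pr$Omega$ref[1, 1]), 7.5)
  expect_equal(unname(pr$P[1, 1]), 3.5 / 11)
})

test_that("projection of training panels preserves eigenvalue variance order", {
  s <- toy_study()
  j <- which(!vapply(s$priors$win, `[[`, logical(1), "freq_only"))[5]
  w <- s$priors$win[[j]]
  sc <- project_pcs(s$panels[[1]][, w$support, drop = FALSE], w$pop[[1]]$pca)
  v <- apply(sc, 2, var)
  expect_false(is.unsorted(rev(v)))   # non-increasing variance across PCs
  expect_equal(v, w$pop[[1]]$pca$eigenvalues[seq_along(v)], tolerance = 1e-8)
})
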