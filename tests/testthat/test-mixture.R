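test_that("log_component_weight follows the coefficient-free multinomial form", {
  # 3 * log(1) = 0: a pure profile explains a pure contig perfectly
  expect_identical(log_component_weight(c(3, 0), c(1, 0), 1), 0)
  expect_equal(log_component_weight(c(3, 0), c(0.9, 0.1), 0.5),
               log(0.5) + 3 * log(0.9))
  # reads in a zero-probability sample: -Inf sentinel, not an error
  expect_identical(log_component_weight(c(3, 1), c(1, 0), 0.5), -Inf)
  expect_error(log_component_weight(c(0, 0), c(0.5, 0.5), 1))
})

test_that("E-step reduces to closed forms in degenerate cases", {
  x <- rcmm(matrix(c(3L, 2L, 0L, 5L), 2), lengths = c(10L, 10L))
  q1 <- e_step(x, mixture_params(1, matrix(c(0.5, 0.5), 1)))
  expect_equal(unname(q1), matrix(1, 2, 1))

  # identical components: symmetry forces 0.5 everywhere
  A <- rbind(c(0.3, 0.7), c(0.3, 0.7))
  q2 <- e_step(x, mixture_params(c(0.5, 0.5), A))
  expect_equal(unname(q2), matrix(0.5, 2, 2))
})

test_that("E-step matches direct Bayes arithmetic", {
  # frozen worked case: x = (3, 0) against (0.9, 0.1) vs (0.1, 0.9)
  x <- rcmm(matrix(c(3L, 0L), 1), lengths = 10L)
  prm <- mixture_params(c(0.5, 0.5), rbind(c(0.9, 0.1), c(0.1, 0.9)))
  q <- e_step(x, prm)
  expect_equal(q[1, 1], 0.9^3 / (0.9^3 + 0.1^3), tolerance = 1e-12)
  expect_equal(q[1, 1], 0.72900 / 0.73000, tolerance = 1e-10)

  # oracle sweep over tiny random instances (n_i <= 10, P <= 3, K <= 3)
  withr::with_seed(11, {
    for (rep in 1:25) {
      K <- sample(1:3, 1); P <- sample(2:3, 1); N <- sample(2:6, 1)
      A <- matrix(rgamma(K * P, 1) + 0.05, K); A <- A / rowSums(A)
      pi <- rgamma(K, 1) + 0.05; pi <- pi / sum(pi)
      X <- matrix(rpois(N * P, 1.2), N)
      X[rowSums(X) == 0, 1] <- 1L
      xr <- rcmm(X, lengths = rep(100L, N))
      expect_equal(unname(e_step(xr, mixture_params(pi, A))),
                   unname(oracle_posterior(X, pi, A)), tolerance = 1e-10)
    }
  })
})

test_that("M-step recovers weighted-count parameter updates", {
  x <- rcmm(rbind(c(2L, 2L), c(0L, 4L)), lengths = c(10L, 10L))
  prm <- m_step(x, rbind(c(1, 0), c(0, 1)), smoothing = 0)
  expect_equal(unname(prm$pi), c(0.5, 0.5))
  expect_equal(unname(prm$A), rbind(c(0.5, 0.5), c(0, 1)))

  # hard assignment of everything to component 1 pools the columns
  prm2 <- m_step(x, cbind(rep(1, 2), rep(0, 2)), smoothing = 0)
  expect_equal(unname(prm2$pi), c(1, 0))
  expect_equal(unname(prm2$A[1, ]), c(2 / 8, 6 / 8))

  # normalization contract holds for arbitrary soft posteriors
  withr::with_seed(3, {
    q <- matrix(rgamma(2 * 3, 1), 2); q <- q / rowSums(q)
    prm3 <- m_step(rcmm(matrix(rpois(6, 5) + 1L, 2), lengths = c(5L, 5L)), q)
    expect_equal(sum(prm3$pi), 1, tolerance = 1e-12)
    expect_equal(unname(rowSums(prm3$A)), rep(1, 3), tolerance = 1e-12)
  })
})

test_that("empty components are re-seeded rather than going NaN", {
  x <- rcmm(rbind(c(9L, 1L), c(1L, 9L)), lengths = c(10L, 10L))
  q <- rbind(c(1, 0), c(1, 0))   # component 2 gets zero responsibility
  prm <- m_step(x, q)
  expect_false(any(is.na(prm$A)))
  expect_equal(sum(prm$pi), 1, tolerance = 1e-12)
})

test_that("observed log-likelihood matches direct arithmetic", {
  x1 <- rcmm(matrix(5L, 1, 1), lengths = 10L)
  expect_equal(observed_loglik(x1, mixture_params(1, matrix(1, 1))), 0)

  x <- rcmm(matrix(c(3L, 0L), 1), lengths = 10L)
  prm <- mixture_params(c(0.5, 0.5), rbind(c(0.9, 0.1), c(0.1, 0.9)))
  expect_equal(observed_loglik(x, prm), log(0.5 * 0.9^3 + 0.5 * 0.1^3),
               tolerance = 1e-12)
  expect_equal(observed_loglik(x, prm), log(0.3650), tolerance = 1e-10)
})

test_that("one EM iteration never decreases the log-likelihood", {
  withr::with_seed(7, {
    for (rep in 1:50) {
      inst <- random_instance(N = sample(10:60, 1), P = sample(2:6, 1),
                              K = sample(1:4, 1))
      ll0 <- observed_loglik(inst$x, inst$params)
      prm1 <- m_step(inst$x, e_step(inst$x, inst$params))
      ll1 <- observed_loglik(inst$x, prm1)
      expect_gte(ll1, ll0 - 1e-8)
    }
  })
})

test_that("fit_em trace is monotone and labels are the posterior argmax", {
  sim <- simulate_community(K = 3, P = 8, N = 250, seed = 5)
  fit <- fit_em(sim$rcmm, 3)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_true(fit$converged)
  expect_identical(unname(fit$labels),
                   max.col(fit$posterior, ties.method = "first"))
  expect_equal(unname(rowSums(fit$posterior)), rep(1, fit$N), tolerance = 1e-10)
  expect_equal(sum(fit$params$pi), 1, tolerance = 1e-10)
})

test_that("a K=1 fit returns the pooled empirical profile", {
  sim <- simulate_community(K = 1, P = 5, N = 100, seed = 9)
  fit <- fit_em(sim$rcmm, 1)
  pooled <- colSums(sim$rcmm$counts) / sum(sim$rcmm$counts)
  expect_equal(unname(fit$params$A[1, ]), unname(pooled), tolerance = 1e-8)
  expect_equal(unname(fit$params$pi), 1)
})

test_that("sample permutation carries through to the fitted profiles", {
  sim <- simulate_community(K = 3, P = 6, N = 200, seed = 13)
  x <- sim$rcmm
  perm <- c(4, 1, 6, 2, 5, 3)
  xp <- rcmm(x$counts[, perm], lengths = x$lengths,
             library_sizes = x$library_sizes[perm])
  f1 <- fit_em(x, 3)
  f2 <- fit_em(xp, 3)
  expect_equal(unname(f2$params$A), unname(f1$params$A[, perm]),
               tolerance = 1e-6)
  expect_identical(f2$labels, f1$labels)
})

test_that("relabeling components permutes parameters with identical loglik", {
  sim <- simulate_community(K = 3, P = 6, N = 150, seed = 21)
  fit <- fit_em(sim$rcmm, 3)
  perm <- c(3, 1, 2)
  prm_p <- mixture_params(fit$params$pi[perm], fit$params$A[perm, ])
  expect_equal(observed_loglik(sim$rcmm, prm_p), fit$loglik, tolerance = 1e-10)
  expect_equal(unname(e_step(sim$rcmm, prm_p)),
               unname(fit$posterior[, perm]), tolerance = 1e-10)
})

test_that("fit_em rejects impossible inputs", {
  x <- rcmm(matrix(c(1L, 2L, 3L, 4L), 2), lengths = c(10L, 10L))
  expect_error(fit_em(x, 3), "exceeds the number of contigs")
  expect_error(fit_em(x, 0), "K must be >= 1")
  xz <- rcmm(rbind(c(1L, 1L), c(0L, 0L)), lengths = c(10L, 10L))
  expect_error(fit_em(xz, 1), "zero mapped reads")
})

test_that("fitted profiles recover the generating truth", {
  sim <- simulate_community(K = 5, P = 20, N = 2000, seed = 4)
  fit <- fit_em(sim$rcmm, 5)
  perm <- match_components(fit$params$A, sim$truth$A_true)
  err <- max(abs(fit$params$A[perm, ] - sim$truth$A_true))
  expect_lt(err, 0.05)
  expect_gte(evaluate_binning(fit$labels, sim$truth$labels)$ari, 0.95)
  # Hungarian matching agrees with exhaustive permutation search
  expect_identical(perm, oracle_match(fit$params$A, sim$truth$A_true))
})
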