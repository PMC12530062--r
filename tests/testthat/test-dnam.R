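# Methylation allocation model: signature clipping, E/M steps (sequencing
# and array), joint quantile normalization, full EM fit.

test_that("clip_signature bounds entries away from 0 and 1", {
  pi <- toy_signature(rbind(c(0, 0.5), c(1, 0.25)))
  cl <- clip_signature(pi, eps = 1e-6)
  expect_equal(unname(cl), rbind(c(1e-6, 0.5), c(1 - 1e-6, 0.25)))
  expect_error(clip_signature(toy_signature(rbind(c(1.1, 0)))), "outside")
})

test_that("E-step posteriors are row simplices with the hand-checked values", {
  pi <- toy_signature(rbind(c(0.9, 0.1)))
  e <- dnam_e_step(pi, c(0.3, 0.7))
  expect_equal(unname(e$psi1), rbind(c(0.27, 0.07) / 0.34))
  expect_equal(unname(e$psi0), rbind(c(0.3 * 0.1, 0.7 * 0.9) / 0.66))

  # uninformative locus returns the prior in both branches
  eu <- dnam_e_step(toy_signature(rbind(c(0.4, 0.4))), c(0.3, 0.7))
  expect_equal(unname(eu$psi1), rbind(c(0.3, 0.7)))
  expect_equal(unname(eu$psi0), rbind(c(0.3, 0.7)))

  # perfectly discriminating locus sends the posteriors to the corners
  eps <- 1e-9
  ed <- dnam_e_step(toy_signature(rbind(c(1 - eps, eps))), c(0.5, 0.5))
  expect_equal(unname(ed$psi1), rbind(c(1, 0)), tolerance = 1e-8)
  expect_equal(unname(ed$psi0), rbind(c(0, 1)), tolerance = 1e-8)

  # row-simplex property on random instances
  set.seed(8)
  for (rep in 1:20) {
    pi <- clip_signature(toy_signature(matrix(rbeta(30, 0.3, 0.3), 10, 3)))
    th <- rgamma(3, 1); th <- th / sum(th)
    e <- dnam_e_step(pi, th)
    expect_equal(unname(rowSums(e$psi1)), rep(1, 10), tolerance = 1e-9)
    expect_equal(unname(rowSums(e$psi0)), rep(1, 10), tolerance = 1e-9)
    expect_true(all(e$psi1 >= 0 & e$psi1 <= 1 & e$psi0 >= 0 & e$psi0 <= 1))
  }
})

test_that("sequencing M-step matches hand evaluation", {
  # uninformative signature: the prior is a fixed point
  th <- c(0.3, 0.7)
  psi_flat <- list(psi1 = rbind(th, th), psi0 = rbind(th, th))
  expect_equal(dnam_m_step_seq(psi_flat, c(4, 6), c(10, 10)), th)

  # single fully methylated locus assigned entirely to type 1
  psi1 <- list(psi1 = rbind(c(1, 0)), psi0 = rbind(c(0.5, 0.5)))
  expect_equal(dnam_m_step_seq(psi1, 10, 10), c(1, 0))

  # two loci, meth = (10, 0), cov = (10, 10), E-step at uniform theta with
  # pi rows (0.9, 0.1) and (0.1, 0.9): the methylated branch of locus 1 and
  # the unmethylated branch of locus 2 both weight (0.9, 0.1)
  pi <- toy_signature(rbind(c(0.9, 0.1), c(0.1, 0.9)))
  e <- dnam_e_step(pi, c(0.5, 0.5))
  expect_equal(unname(dnam_m_step_seq(e, c(10, 0), c(10, 10))), c(0.9, 0.1))

  expect_error(dnam_m_step_seq(psi1, 0, 0), "zero coverage")
  expect_error(dnam_m_step_seq(psi1, 5, 4), "0 <= meth <= cov")
})

test_that("array M-step equals the sequencing M-step at constant coverage", {
  set.seed(12)
  pi <- clip_signature(toy_signature(matrix(rbeta(24, 0.3, 0.3), 8, 3)))
  th <- c(0.2, 0.5, 0.3)
  e <- dnam_e_step(pi, th)
  cov <- rep(40, 8)
  meth <- rbinom(8, 40, drop(pi %*% th))
  expect_equal(dnam_m_step_array(e, meth / cov),
               dnam_m_step_seq(e, meth, cov), tolerance = 1e-12)

  # beta = 0.5 at uninformative loci leaves theta unchanged
  psi_flat <- list(psi1 = rbind(th, th), psi0 = rbind(th, th))
  expect_equal(dnam_m_step_array(psi_flat, c(0.5, 0.5)), th)

  # single locus, beta = 1: theta is the normalized methylated posterior
  psi <- list(psi1 = rbind(c(0.7941, 0.2059)), psi0 = rbind(c(0.1, 0.9)))
  expect_equal(dnam_m_step_array(psi, 1), c(0.7941, 0.2059))
})

test_that("log-likelihood is flat for K = 1 and concave along segments", {
  pi1 <- clip_signature(toy_signature(cbind(c(0.2, 0.8))))
  expect_equal(dnam_log_likelihood(c(3, 4), pi1, 1, cov = c(10, 10)),
               sum(c(3, 4) * log(pi1) + c(7, 6) * log(1 - pi1)))
  set.seed(4)
  for (rep in 1:10) {
    pi <- clip_signature(toy_signature(matrix(rbeta(20, 0.5, 0.5), 10, 2)))
    m <- rbinom(10, 20, 0.5); cv <- rep(20, 10)
    t1 <- rgamma(2, 1); t1 <- t1 / sum(t1)
    t2 <- rgamma(2, 1); t2 <- t2 / sum(t2)
    mid <- (t1 + t2) / 2
    expect_gte(dnam_log_likelihood(m, pi, mid, cov = cv) + 1e-10,
               mean(c(dnam_log_likelihood(m, pi, t1, cov = cv),
                      dnam_log_likelihood(m, pi, t2, cov = cv))))
  }
})

test_that("joint quantile normalization pools columns to rank-wise means", {
  ref <- toy_signature(cbind(c(0.1, 0.5, 0.9)), types = "r")
  bulk <- toy_signature(cbind(c(0.2, 0.6, 1.0)), types = "s")
  qn <- joint_quantile_normalize(ref, bulk)
  expect_equal(unname(qn$ref[, 1]), c(0.15, 0.55, 0.95))
  expect_equal(unname(qn$bulk[, 1]), c(0.15, 0.55, 0.95))

  # identical multisets are a fixed point
  a <- toy_signature(cbind(c(0.3, 0.1, 0.7)), types = "a")
  b <- toy_signature(cbind(c(0.1, 0.7, 0.3)), types = "b")
  qn2 <- joint_quantile_normalize(a, b)
  expect_equal(qn2$ref, a, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(qn2$bulk, b, tolerance = 1e-12, ignore_attr = TRUE)

  # defining property: all output columns share the same sorted values
  set.seed(19)
  ref3 <- toy_signature(matrix(rbeta(30, 2, 2), 10, 3))
  bulk3 <- toy_signature(matrix(rbeta(20, 0.5, 0.5), 10, 2),
                         types = c("s1", "s2"))
  qn3 <- joint_quantile_normalize(ref3, bulk3)
  all_cols <- cbind(qn3$ref, qn3$bulk)
  sorted <- apply(all_cols, 2, sort)
  expect_equal(sorted, sorted[, c(1, 1, 1, 1, 1)], ignore_attr = TRUE)

  expect_error(joint_quantile_normalize(ref3, bulk3[10:1, , drop = FALSE]),
               "identical loci")
})

test_that("fit_dnam recovers fractions in sequencing and array modes", {
  # K = 1 degenerate case
  pi1 <- toy_signature(cbind(c(0.2, 0.8, 0.5)))
  b1 <- suppressMessages(bulk_matrix(
    toy_signature(cbind(s1 = c(2, 7, 4))), "dnam_counts",
    coverage = toy_signature(cbind(s1 = c(10, 10, 10)))))
  f1 <- quiet_fit_dnam(b1, pi1)
  expect_equal(unname(f1$fractions[1, ]), 1)

  # sequencing recovery at moderate depth
  set.seed(55)
  cfg <- sim_config(n_types = 2, n_loci = 500, n_samples = 1, coverage = 50,
                    seed = 55)
  theta <- toy_fractions(rbind(c(0.2, 0.8)), samples = "s1")
  pi <- simulate_reference_dnam(cfg, seed = NULL)
  sim <- simulate_bulk_dnam(theta, pi, coverage = 50, seed = NULL)
  fit <- quiet_fit_dnam(sim$counts, pi)
  expect_lt(max(abs(fit$fractions - theta)), 0.03)

  # noise-free array identifiability: beta exactly the mixture
  set.seed(56)
  piw <- clip_signature(toy_signature(matrix(rbeta(300, 0.3, 0.3), 100, 3)))
  th <- c(0.25, 0.35, 0.4)
  beta <- toy_signature(cbind(s1 = drop(piw %*% th)), loci = rownames(piw))
  fitb <- quiet_fit_dnam(beta, piw,
                         control = emixed_control(quantile_norm = FALSE,
                                                  tol = 1e-12))
  expect_lt(max(abs(fitb$fractions[1, ] - th)), 1e-4)
})

test_that("sequencing and array paths give identical iterates at constant coverage", {
  set.seed(66)
  cfg <- sim_config(n_types = 3, n_loci = 200, n_samples = 4, coverage = 30,
                    seed = 66)
  theta <- simulate_fractions(cfg, seed = NULL)
  pi <- simulate_reference_dnam(cfg, seed = NULL)
  sim <- simulate_bulk_dnam(theta, pi, coverage = 30, seed = NULL)
  ctl <- emixed_control(quantile_norm = FALSE)
  fseq <- quiet_fit_dnam(sim$counts, pi, control = ctl)
  farr <- quiet_fit_dnam(sim$beta, pi, control = ctl)
  expect_equal(fseq$fractions, farr$fractions, tolerance = 1e-10)
  expect_identical(fseq$iterations, farr$iterations)
})

test_that("the collapsed fit update equals one textbook E/M cycle", {
  set.seed(72)
  pi <- clip_signature(toy_signature(matrix(rbeta(45, 0.3, 0.3), 15, 3)))
  th <- toy_fractions(rbind(c(0.2, 0.3, 0.5)), samples = "s1")
  sim <- simulate_bulk_dnam(th, pi, coverage = 30, seed = 72)
  one <- quiet_fit_dnam(sim$counts, pi,
                        control = emixed_control(tol = 1e-300, max_iter = 1))
  m <- sim$counts$values[, 1]; cv <- sim$counts$coverage[, 1]
  e <- dnam_e_step(pi, rep(1 / 3, 3))
  expect_equal(one$fractions[1, ], dnam_m_step_seq(e, m, cv),
               tolerance = 1e-12)
})

test_that("zero-coverage loci are skipped, not imputed", {
  set.seed(71)
  pi <- clip_signature(toy_signature(matrix(rbeta(60, 0.3, 0.3), 20, 3)))
  th <- toy_fractions(rbind(c(0.5, 0.3, 0.2)), samples = "s1")
  sim <- simulate_bulk_dnam(th, pi, coverage = 25, seed = 71)
  meth <- sim$counts$values; cov <- sim$counts$coverage
  meth[1:5, 1] <- 0; cov[1:5, 1] <- 0
  full <- quiet_fit_dnam(suppressMessages(
    bulk_matrix(meth, "dnam_counts", coverage = cov)), pi)
  trimmed <- quiet_fit_dnam(suppressMessages(
    bulk_matrix(meth[-(1:5), , drop = FALSE], "dnam_counts",
                coverage = cov[-(1:5), , drop = FALSE])),
    pi[-(1:5), , drop = FALSE])
  expect_equal(full$fractions, trimmed$fractions, tolerance = 1e-12)
})

test_that("fit_dnam is equivariant to permuting signature columns", {
  set.seed(81)
  pi <- toy_signature(matrix(rbeta(90, 0.3, 0.3), 30, 3))
  th <- toy_fractions(rbind(c(0.6, 0.1, 0.3)), samples = "s1")
  sim <- simulate_bulk_dnam(th, clip_signature(pi), coverage = 100, seed = 81)
  perm <- c(3, 1, 2)
  f1 <- quiet_fit_dnam(sim$counts, pi)
  f2 <- quiet_fit_dnam(sim$counts, pi[, perm])
  expect_equal(unname(f2$fractions), unname(f1$fractions[, perm, drop = FALSE]),
               tolerance = 1e-8)
})

test_that("DNAm log-likelihood traces are non-decreasing", {
  set.seed(91)
  cfg <- sim_config(n_types = 3, n_loci = 80, n_samples = 5, coverage = 15,
                    seed = 91)
  theta <- simulate_fractions(cfg, seed = NULL)
  pi <- simulate_reference_dnam(cfg, seed = NULL)
  sim <- simulate_bulk_dnam(theta, pi, coverage = 15, seed = NULL)
  fit <- quiet_fit_dnam(sim$counts, pi)
  for (tr in fit$loglik)
    expect_true(all(diff(tr) >= -1e-8))
})

test_that("fit_dnam matches a dense grid search of the likelihood (K = 2)", {
  set.seed(101)
  pi <- clip_signature(toy_signature(matrix(rbeta(20, 0.4, 0.4), 10, 2)))
  th_true <- c(0.3, 0.7)
  sim <- simulate_bulk_dnam(toy_fractions(rbind(th_true), samples = "s1"),
                            pi, coverage = 200, seed = 101)
  fit <- quiet_fit_dnam(sim$counts, pi,
                        control = emixed_control(tol = 1e-10,
                                                 quantile_norm = FALSE))
  m <- sim$counts$values[, 1]; cv <- sim$counts$coverage[, 1]
  oracle <- grid_argmax_theta1(function(t1)
    dnam_log_likelihood(m, pi, c(t1, 1 - t1), cov = cv))
  expect_lt(abs(fit$fractions[1, 1] - oracle), 1e-3)
})
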