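test_that("selection families map Z to frequencies as specified", {
  sp <- selection_spec("cumulative", rho = 1, gamma = 0, n_columns = 2)
  expect_equal(predict_frequencies(cbind(NA, 2), sp, f0 = 0.1)[1, 2], 0.2)
  sp2 <- selection_spec("cumulative", rho = 1, gamma = -1, n_columns = 2)
  expect_equal(predict_frequencies(cbind(NA, 1), sp2, f0 = 0.1)[1, 2], 0.05)
  # kinetic limits: delta -> +Inf keeps the unmodified (surviving) fraction
  spk <- selection_spec("kinetic", delta = c(NA, Inf, -Inf))
  f <- predict_frequencies(cbind(NA, 0, 0), spk, f0 = 1)
  expect_equal(f[1, 2], 1)   # Z = 0: nothing modified, all survive
  expect_equal(f[1, 3], 0)
  # non-cumulative references the input in every column
  spn <- selection_spec("non_cumulative", rho = c(0, 1, 0), gamma = c(0, -1, -1))
  Z <- cbind(NA, 3, 3)
  fn <- predict_frequencies(Z, spn, f0 = 2)
  expect_equal(fn[1, ], c(2, 2 * 3 / 4, 2 / 4))
})

test_that("kinetic fraction factors sum to one at every Z", {
  Z <- c(0, 1e-8, 0.3, 1, 5, 50)
  expect_equal(probefit:::kinetic_factor(Z, Inf) +
               probefit:::kinetic_factor(Z, -Inf), rep(1, length(Z)))
  # finite delta mixes the two branches
  s <- 1 / (1 + exp(-1.5))
  expect_equal(probefit:::kinetic_factor(2, 1.5),
               s * exp(-2) + (1 - s) * (1 - exp(-2)))
})

test_that("multinomial log-likelihood has the stated closed forms", {
  k <- matrix(c(3, 5), 2, 1)
  expect_equal(count_loglik(k, matrix(1, 2, 1)), 0)   # single column: p = 1
  k2 <- matrix(c(2, 1, 4, 3), 2, 2)
  f2 <- matrix(1, 2, 2)
  expect_equal(count_loglik(k2, f2), log(1 / 2))      # equal eta*f everywhere
  expect_error(count_loglik(matrix(c(1, 1), 1), matrix(c(0, 1), 1)),
               "degenerate")
})

test_that("likelihood is invariant to eta rescaling and probe-wise f scaling", {
  set.seed(20)
  k <- matrix(rpois(40, 6), 10, 4)
  f <- matrix(rexp(40), 10, 4)
  eta <- rnorm(4)
  base <- count_loglik(k, f, eta)
  expect_equal(count_loglik(k, f, eta + 1.7), base, tolerance = 1e-12)
  expect_equal(count_loglik(k, f * rexp(10), eta), base, tolerance = 1e-12)
})

test_that("Poisson form with profiled input frequency equals the multinomial form", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:20, 1); R <- sample(2:4, 1)
    k <- matrix(rpois(n * R, 5) + 1, n, R)
    g1 <- matrix(rexp(n * R), n, R); e1 <- rnorm(R)
    g2 <- matrix(rexp(n * R), n, R); e2 <- rnorm(R)
    d1 <- poisson_loglik(k, g1, e1) - count_loglik(k, g1, e1)
    d2 <- poisson_loglik(k, g2, e2) - count_loglik(k, g2, e2)
    # the difference is a parameter-independent constant of the counts
    expect_equal(d1, d2, tolerance = 1e-10)
  }
})

test_that("regularization penalty matches its definition and its gradient", {
  sp <- reg_spec(lambda = 0, k_dirichlet = 0, theta_max = 40)
  th <- rep(0, 6)
  pen <- regularization_penalty(th, list(1:3, 4:6), sp)
  expect_equal(pen$value, -2 * 6 * exp(-40))
  # uniform coefficients in a 4-letter class give p = 1/4 each
  sp2 <- reg_spec(lambda = 0, k_dirichlet = 8, theta_max = 40)
  pen2 <- regularization_penalty(rep(0.3, 4), list(1:4), sp2, k_total = 2)
  expect_equal(pen2$value, 4 * (8 / 2) * log(1 / 4) - 8 * exp(-40),
               tolerance = 1e-12)
  expect_error(regularization_penalty(th, list(integer()), sp), "empty")
  # numeric-gradient oracle
  set.seed(22)
  th <- rnorm(7)
  spg <- reg_spec(lambda = 0.3, k_dirichlet = 11, theta_max = 12)
  groups <- list(1:4, 5:7)
  g <- regularization_penalty(th, groups, spg, k_total = 5)$grad
  gn <- sapply(seq_along(th), function(i) {
    e <- 1e-6; tp <- th; tm <- th; tp[i] <- tp[i] + e; tm[i] <- tm[i] - e
    (regularization_penalty(tp, groups, spg, 5)$value -
     regularization_penalty(tm, groups, spg, 5)$value) / (2 * e)
  })
  expect_equal(g, gn, tolerance = 1e-6)
})

test_that("joint objective is additive over experiments and has exact gradients", {
  set.seed(23)
  tb <- rand_table(25, 6, 3)
  sel <- selection_spec("cumulative", rho = 1, gamma = -1, n_columns = 3)
  ex <- experiment(tb, sel, activity_tie = "free", ns_tie = "free")
  m <- rand_mode(L = 4, sd = 0.3, pairs = "adjacent")
  model <- recognition_model(list(m))
  reg <- reg_spec(lambda = 1e-4, k_dirichlet = 7)
  one <- joint_objective(ex, model, reg)
  expect_type(one$value, "double")
  # duplicated experiment doubles the likelihood term exactly (checked with
  # penalties off, since those are per-experiment too)
  reg0 <- reg_spec(lambda = 0, k_dirichlet = 0, theta_max = 1e6)
  v1 <- joint_objective(ex, model, reg0)$value
  v2 <- joint_objective(list(ex, ex), model, reg0)$value
  expect_equal(v2, 2 * v1, tolerance = 1e-9)
  # central-difference gradient check, all parameter classes
  obj <- probefit:::make_objective(model, list(ex), reg)
  th <- obj$layout$theta + rnorm(length(obj$layout$theta), sd = 0.15)
  g <- obj$gr(th)
  gn <- sapply(seq_along(th), function(i) {
    e <- 1e-6; tp <- th; tm <- th; tp[i] <- tp[i] + e; tm[i] <- tm[i] - e
    (obj$fn(tp) - obj$fn(tm)) / (2 * e)
  })
  expect_equal(g, gn, tolerance = 1e-6)
})

test_that("objective stays finite over the admissible parameter range", {
  set.seed(24)
  tb <- rand_table(10, 5, 2)
  sel <- selection_spec("cumulative", rho = 1, gamma = 0, n_columns = 2)
  ex <- experiment(tb, sel, activity_tie = "constant", ns_tie = "constant")
  model <- recognition_model(list(binding_mode(3, dna_alphabet())))
  obj <- probefit:::make_objective(model, list(ex), reg_spec(theta_max = 40))
  for (scale in c(-45, -10, 0, 10, 45)) {
    th <- rep(scale * 0.9, length(obj$layout$theta))
    expect_true(is.finite(obj$fn(th)))
  }
})

test_that("experiments reject mismatched tables and alphabets", {
  tb <- rand_table(10, 5, 2)
  sel3 <- selection_spec("cumulative", rho = 1, gamma = 0, n_columns = 3)
  expect_error(experiment(tb, sel3), "columns")
  sel2 <- selection_spec("cumulative", rho = 1, gamma = 0, n_columns = 2)
  ex <- experiment(tb, sel2)
  m <- binding_mode(3, peptide_alphabet(), strands = 1)
  expect_error(probefit:::make_objective(recognition_model(list(m)), list(ex),
                                         reg_spec()),
               "alphabet")
})
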