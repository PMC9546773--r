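test_that("the coupled equilibrium solver conserves mass", {
  set.seed(51)
  for (i in 1:5) {
    n <- 500
    kd <- exp(rnorm(n, 5, 2))
    dna <- rexp(n); dna <- 50 * dna / sum(dna)
    pt <- runif(1, 10, 500)
    eq <- solve_equilibrium(kd, dna, pt)
    expect_lt(abs(eq$p_free + sum(dna * eq$p_bound_i) - pt) / pt, 1e-9)
    expect_true(all(eq$p_bound_i > 0 & eq$p_bound_i < 1))
  }
})

test_that("bound and free probabilities are complementary and ordered by K_D", {
  kd <- c(1, 10, 100, 1000)
  eq <- solve_equilibrium(kd, rep(1, 4), 50)
  pB <- eq$p_bound_i
  expect_equal(pB + kd / (eq$p_free + kd), rep(1, 4))
  expect_true(all(diff(pB) < 0))   # weaker binder, lower bound probability
  # linear regime: K_D >> [P]_T gives p(B) ~ [P]_F/K_D
  eq2 <- solve_equilibrium(c(1e5, 1e6), c(1, 1), 10)
  expect_equal(eq2$p_bound_i, eq2$p_free / c(1e5, 1e6), tolerance = 1e-3)
})

test_that("equilibrium simulation obeys the mixture sum rule exactly", {
  set.seed(52)
  tm <- rand_mode(L = 4, sd = 1)
  lib <- enumerate_library(6, dna_alphabet(), c(0.288, 0.265, 0.144, 0.303))
  sim <- simulate_kdseq(tm, kd_scale = 50, p_total = 100, dna_input = 20,
                        reads = 5e4, V = 6, seed = 3)
  expect_lt(abs(sim$residual) / 100, 1e-9)
  kd <- sim$kd
  pB <- sim$p_free / (sim$p_free + kd)
  # sum rule p(i) = p(i|F)p(F) + p(i|B)p(B) on the noiseless frequencies
  f0 <- lib$f0
  pb_net <- sum(f0 * pB)
  lhs <- unname(f0)
  rhs <- unname((f0 * (1 - pB) / (1 - pb_net)) * (1 - pb_net) +
                (f0 * pB / pb_net) * pb_net)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_equal(unname(column_totals(sim$input)), 5e4)
})

test_that("three-fraction fitting recovers absolute dissociation constants", {
  set.seed(53)
  al <- dna_alphabet()
  bt <- matrix(rnorm(32, sd = 1.2), 4, 8)
  tm <- binding_mode(8, al, beta_mono = bt)
  pilot <- probefit:::truth_kd(tm, enumerate_library(8, al)$seqs, 1)
  ks <- 20 / min(pilot)       # strongest probe at 20 nM
  sim <- simulate_kdseq(tm, kd_scale = ks, p_total = 100, dna_input = 20,
                        reads = 2e5, V = 8, seed = 4)
  fit <- kdseq_fit(sim$input, sim$bound, sim$free, p_total = 100,
                   dna_input = 20, L = 8, greedy = FALSE, seed = 2)
  expect_equal(fit$p_bound, sim$p_bound, tolerance = 0.25)
  expect_equal(fit$p_free_protein, sim$p_free, tolerance = 0.01)
  top <- names(sort(sim$kd))[1]
  expect_lt(abs(log10(fit$kd[top]) - log10(min(sim$kd))), 0.15)
  common <- intersect(names(fit$kd), names(sim$kd))
  expect_gt(cor(log(fit$kd[common]), log(sim$kd[common]))^2, 0.95)
  expect_equal(fit$diagnostics$level, "ok")
})

test_that("a degenerate single-probe library yields one K_D and consistent p(B)", {
  # analytic two-sequence toy: counts are exact expectations, no sampling
  kd <- c(5, 500); f0 <- c(0.5, 0.5); pt <- 50; dna <- 1
  eq <- solve_equilibrium(kd, dna * f0, pt)
  pB <- eq$p_bound_i
  pb_net <- sum(f0 * pB)
  reads <- 1e6
  cI <- round(reads * f0)
  cB <- round(reads * f0 * pB / pb_net)
  cF <- round(reads * f0 * (1 - pB) / (1 - pb_net))
  mk <- function(cnt, lab) count_table(c("ACGTACGT", "TTTTAAAA"), cnt,
                                       col_labels = lab)
  fit <- kdseq_fit(mk(cI, "I"), mk(cB, "B"), mk(cF, "F"),
                   p_total = pt, dna_input = dna, L = 8, greedy = FALSE,
                   seed = 1, include_ns = FALSE)
  expect_equal(fit$p_bound, pb_net, tolerance = 0.02)
  expect_equal(unname(log10(fit$kd)), log10(kd), tolerance = 0.05)
})

test_that("binned binding curves match predictions on model-generated data", {
  set.seed(54)
  tm <- rand_mode(L = 4, sd = 1)
  pilot <- probefit:::truth_kd(tm, enumerate_library(6, dna_alphabet())$seqs, 1)
  ks <- 30 / min(pilot)
  sim <- simulate_kdseq(tm, kd_scale = ks, p_total = 100, dna_input = 10,
                        reads = 2e5, V = 6, seed = 5)
  fit <- kdseq_fit(sim$input, sim$bound, sim$free, p_total = 100,
                   dna_input = 10, L = 4, greedy = FALSE, seed = 2)
  bc <- binned_binding_curve(fit, bin_size = 200)
  expect_true(all(is.finite(bc$predicted)))
  # strongest-affinity bin binds most; observed tracks predicted
  expect_gt(bc$predicted[1], bc$predicted[nrow(bc)])
  expect_gt(cor(bc$observed, bc$predicted), 0.95)
  # single bin when fewer probes than one bin
  bc1 <- binned_binding_curve(fit, bin_size = 1e7)
  expect_equal(nrow(bc1), 1L)
})

test_that("kinetic simulation approaches equilibrium as incubation grows", {
  kd <- c(2, 20, 200, 2000)
  eqp <- 100 / (100 + kd)
  expect_equal(kinetic_bound_probability(kd, 100, 1e6), eqp, tolerance = 1e-9)
  # direct evaluation of the closed form
  kt <- 0.05
  manual <- (100 / (100 + kd)) * (1 - exp(-kt * (kd + 100) / min(kd)))
  expect_equal(kinetic_bound_probability(kd, 100, kt), manual)
  # monotone in incubation time
  p1 <- kinetic_bound_probability(kd, 100, 0.01)
  p2 <- kinetic_bound_probability(kd, 100, 0.1)
  expect_true(all(p2 > p1))
})

test_that("equilibration time matches direct integration of the rate equation", {
  expect_equal(equilibration_time(kd = 1, p_total = 9, k_off = 1), 0.1)
  expect_equal(equilibration_time(kd = 5, p_total = 1e-9, k_off = 2), 0.5,
               tolerance = 1e-8)
  # ODE oracle: d[B]/dt = kon*P*(1-B) - koff*B relaxes with rate
  # koff*(1+P/KD); measure the e-folding time numerically
  skip_if_not_installed("deSolve")
  kon <- 3; koff <- 0.7; P <- 4; kd <- koff / kon
  out <- deSolve::ode(c(B = 0), seq(0, 5, 0.001),
                      function(t, y, p) list(kon * P * (1 - y[1]) - koff * y[1]))
  Beq <- P / (P + kd)
  t_num <- unname(out[min(which(out[, "B"] >= Beq * (1 - exp(-1)))), "time"])
  expect_equal(t_num, equilibration_time(kd, P, koff), tolerance = 0.01)
})

test_that("gel-shift curve fitting recovers K_D and its stated limits", {
  pts <- c(2, 5, 10, 20, 50, 100, 300)
  p <- emsa_p_bound(pts, dna_total = 6.7, kd = 25)
  # noiseless intensities with arbitrary channel scales
  fit <- fit_emsa_kd(y_bound = p / 3, y_free = (1 - p) * 7, pts, 6.7)
  expect_lt(abs(fit$kd - 25) / 25, 1e-4)
  # scale invariance: x10 both channels, same K_D, scaled alphas
  fit10 <- fit_emsa_kd(y_bound = 10 * p / 3, y_free = 10 * (1 - p) * 7,
                       pts, 6.7)
  expect_equal(fit10$kd, fit$kd, tolerance = 1e-6)
  expect_equal(fit10$alpha_bound, fit$alpha_bound / 10, tolerance = 1e-6)
  # vanishing probe concentration reduces to the simple hyperbola
  expect_equal(emsa_p_bound(pts, 1e-12, 25), pts / (pts + 25),
               tolerance = 1e-6)
  expect_error(fit_emsa_kd(c(0, 0, 0), c(0, 0, 0), pts[1:3], 1), "zero")
  expect_error(fit_emsa_kd(1:2, 1:2, c(1, 2), 1), "3 concentration")
})

test_that("titration diagnostics warn in the depleted-protein regime", {
  set.seed(55)
  tm <- rand_mode(L = 4, sd = 1)
  pilot <- probefit:::truth_kd(tm, enumerate_library(6, dna_alphabet())$seqs, 1)
  ks <- 20 / min(pilot)
  # high-DNA scenario: the generator itself sits in the 5-10% bound-protein
  # band, which the diagnostics must flag
  sim <- simulate_kdseq(tm, kd_scale = ks, p_total = 100, dna_input = 500,
                        reads = 1e5, V = 6, seed = 6)
  true_bpf <- sim$p_bound * 500 / 100
  expect_gt(true_bpf, 0.04)
  expect_warning(
    fit <- kdseq_fit(sim$input, sim$bound, sim$free, p_total = 100,
                     dna_input = 500, L = 4, greedy = FALSE, seed = 2),
    "protein bound")
  expect_true(fit$diagnostics$level %in% c("warn", "error"))
  expect_gt(fit$diagnostics$bound_protein_fraction, 0.04)
})
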