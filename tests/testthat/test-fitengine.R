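test_that("mode seeding honors IUPAC codes and is deterministic", {
  m <- seed_mode(iupac = "TGACGTCA")
  cons <- apply(m$beta_mono, 2, function(v) m$alphabet$letters[which.max(v)])
  expect_equal(paste(cons, collapse = ""), "TGACGTCA")
  expect_true(all(m$beta_mono %in% c(0, 1)))
  mN <- seed_mode(iupac = "NNN")
  expect_true(all(mN$beta_mono == 0))
  mR <- seed_mode(iupac = "R")
  expect_equal(unname(mR$beta_mono[, 1]), c(1, 0, 1, 0))
  expect_error(seed_mode(iupac = "AXG"), "IUPAC")
  set.seed(31); a <- seed_mode(L = 5)
  set.seed(31); b <- seed_mode(L = 5)
  expect_identical(a$beta_mono, b$beta_mono)
})

test_that("staged fit recovers a planted motif and its objective never decreases", {
  fx <- selex_fixture(seed = 41, depth = 2e4)
  fit <- probefit(fx$table, fx$selection, L = 8, greedy = FALSE, seed = 1,
                  activity_tie = "free", ns_tie = "free")
  expect_true(all(diff(fit$trace) > -1e-6))
  r2 <- mode_recovery_r2(fit$gauged[[1]], fx$truth_gauged)
  expect_gt(r2, 0.9)
})

test_that("zero-specificity data yield an uninformative mode", {
  set.seed(42)
  al <- dna_alphabet()
  truth <- recognition_model(list(binding_mode(7, al)),
                             log_alpha = matrix(0, 1, 2),
                             log_alpha_ns = c(0, 0))
  sel <- selection_spec("cumulative", rho = 1, gamma = 0, n_columns = 3)
  tb <- simulate_selex(truth, sel, depth = 1e4, V = 7, seed = 5)
  # standard pseudocount weight for couplings-free fits keeps the mode from
  # chasing sampling noise
  fit <- probefit(tb, sel, L = 7, greedy = FALSE, seed = 2,
                  activity_tie = "free", ns_tie = "free",
                  reg = reg_spec(k_dirichlet = 20))
  expect_lt(information_content(fit$gauged[[1]]), 0.2)
})

test_that("duplicated experiments give the same model as a single one", {
  fx <- selex_fixture(seed = 43, depth = 5e3, V = 7, L = 7)
  ex <- experiment(fx$table, fx$selection, activity_tie = "free",
                   ns_tie = "free")
  f1 <- probefit(list(ex), seed = 3, greedy = FALSE, L = 7)
  f2 <- probefit(list(ex, ex), seed = 3, greedy = FALSE, L = 7)
  expect_gt(mode_recovery_r2(f1$gauged[[1]], f2$gauged[[1]]), 0.999)
})

test_that("greedy search grows a too-short footprint toward the planted one", {
  fx <- selex_fixture(seed = 44, depth = 1e4, sd = 1.2, V = 8, L = 7)
  fit5 <- probefit(fx$table, fx$selection, L = 5, greedy = TRUE, seed = 1,
                   activity_tie = "free", ns_tie = "free")
  expect_gte(fit5$gauged[[1]]$L, 6)
  # and a matching-geometry fit recovers the planted energies
  fit7 <- probefit(fx$table, fx$selection, L = 7, greedy = FALSE, seed = 1,
                   activity_tie = "free", ns_tie = "free")
  expect_gt(mode_recovery_r2(fit7$gauged[[1]], fx$truth_gauged), 0.9)
})

test_that("greedy search is a fixed point at an already-optimal geometry", {
  fx <- selex_fixture(seed = 45, depth = 1e4, V = 7, L = 7)
  fit <- probefit(fx$table, fx$selection, L = 7, greedy = TRUE, seed = 1,
                  activity_tie = "free", ns_tie = "free")
  expect_equal(fit$gauged[[1]]$L, 7)
  expect_equal(fit$gauged[[1]]$f, 0)   # no flanks available to grow into
})

test_that("rc-symmetry survives every substep of the staged fit", {
  set.seed(46)
  al <- dna_alphabet()
  bt <- matrix(rnorm(24, sd = 1), 4, 6)
  sym_truth <- binding_mode(6, al, beta_mono = bt, rc_symmetric = TRUE)
  truth <- recognition_model(list(sym_truth), log_alpha = matrix(0, 1, 2),
                             log_alpha_ns = c(0, 0))
  sel <- selection_spec("cumulative", rho = 1, gamma = 0, n_columns = 3)
  tb <- simulate_selex(truth, sel, depth = 1e4, V = 7, seed = 6)
  fit <- probefit(tb, sel, L = 6, rc_symmetric = TRUE, greedy = TRUE,
                  seed = 2, activity_tie = "free", ns_tie = "free")
  b <- fit$model$modes[[1]]$beta_mono
  expect_equal(b, probefit:::rc_map_mono(b, al), tolerance = 1e-9)
})

test_that("the Dirichlet-weight rule picks the first stabilized grid value", {
  # injected fitter returning canned models: identical coefficients
  # everywhere stabilize at the second grid value
  canned <- function(pairvals) {
    function(tables, selection = NULL, reg, ...) {
      m <- binding_mode(2, dna_alphabet(), pairs = "adjacent",
                        beta_pair = list(matrix(pairvals(reg$k_dirichlet),
                                                4, 4)),
                        reference = "AA")
      list(gauged = list(fix_gauge(m)))
    }
  }
  same <- canned(function(k) seq_len(16) / 10)
  res <- select_dirichlet_weight(NULL, NULL, grid = c(0, 10, 20),
                                 fitter = same)
  expect_equal(res$k_dirichlet, 10)
  expect_true(res$stabilized)
  # stabilize only at 200: small-k models are noise, large-k models agree
  set.seed(47)
  noisy <- canned(function(k) if (k < 200) rnorm(16) else seq_len(16) / 10)
  expect_warning(
    res2 <- select_dirichlet_weight(NULL, NULL, grid = c(0, 10, 20, 50),
                                    fitter = noisy),
    "stabilize")
  expect_false(res2$stabilized)
  expect_equal(res2$k_dirichlet, 50)
  res3 <- select_dirichlet_weight(NULL, NULL,
                                  grid = c(0, 10, 20, 50, 100, 200, 500),
                                  fitter = noisy)
  expect_equal(res3$k_dirichlet, 500)   # first pair above 200 that agrees
  # the default grid is the standard nine-point grid
  expect_equal(eval(formals(select_dirichlet_weight)$grid),
               c(0, 10, 20, 50, 100, 200, 500, 1000, 2000))
})

test_that("fit methods expose coefficients, predictions and residuals coherently", {
  fx <- selex_fixture(seed = 48, depth = 1e4)
  fit <- probefit(fx$table, fx$selection, L = 8, greedy = FALSE, seed = 1,
                  activity_tie = "free", ns_tie = "free")
  expect_output(print(fit), "modes: 1")
  s <- summary(fit)
  expect_s3_class(s, "summary.probefit")
  expect_equal(nrow(s$modes), 1)
  cf <- coef(fit)
  expect_equal(dim(cf), c(4L, 8L))
  ref <- strsplit(fit$gauged[[1]]$reference, "")[[1]]
  expect_equal(unname(cf[cbind(match(ref, rownames(cf)), 1:8)]), rep(0, 8))
  Z <- predict(fit, type = "zbound")
  expect_true(all(Z[, 2:3] > 0))
  E <- predict(fit, type = "counts")
  expect_equal(rowSums(E), rowSums(fx$table$counts), tolerance = 1e-8)
  r <- residuals(fit)
  expect_equal(dim(r), dim(fx$table$counts))
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  # parametric bootstrap keeps the column depths
  simt <- simulate(fit, nsim = 1, seed = 9)[[1]]
  expect_equal(column_totals(simt), column_totals(fx$table))
})
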