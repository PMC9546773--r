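test_that("k-mer counting tallies windows weighted by read counts", {
  tb <- count_table(c("ACGTA", "TTTTT"), matrix(c(2, 3), 2, 1))
  km <- count_kmers(tb, 4)
  expect_equal(unname(km["ACGT"]), 2)
  expect_equal(unname(km["CGTA"]), 2)
  expect_equal(unname(km["TTTT"]), 2 * 3)   # two windows x count 3
  expect_equal(sum(km), 2 * 2 + 2 * 3)
  expect_error(count_kmers(tb, 9), "shortest")
})

test_that("the divergence filter fails identical rounds and passes enriched ones", {
  set.seed(71)
  seqs <- rand_seqs(400, 8)
  same <- count_table(seqs, cbind(rep(30, length(seqs)), rep(30, length(seqs))))
  res <- kl_enrichment_filter(same, min_reads = 1000)
  expect_false(res$pass)
  expect_equal(res$kl$d_kl, 0, tolerance = 1e-12)
  # planted enrichment of one word
  counts2 <- cbind(rep(30, length(seqs)),
                   30 + 500 * grepl("ACGT", seqs))
  enr <- count_table(seqs, counts2)
  expect_true(kl_enrichment_filter(enr, min_reads = 1000)$pass)
  # coverage rules
  low <- count_table(seqs, cbind(rep(30, length(seqs)), rep(1, length(seqs))))
  expect_false(kl_enrichment_filter(low, min_reads = 1000)$pass)
  late <- count_table(seqs, cbind(rep(1, length(seqs)), rep(1, length(seqs)),
                                  rep(1, length(seqs)), rep(30, length(seqs)),
                                  rep(30, length(seqs))))
  res_late <- kl_enrichment_filter(late, min_reads = 1000)
  expect_false(res_late$pass)
  expect_match(res_late$reason, "before round three")
})

test_that("the divergence matches a direct hand computation", {
  tb <- count_table(c("AAAAA", "CCCCC"), cbind(c(100, 100), c(150, 50)))
  res <- kl_enrichment_filter(tb, min_reads = 100, pseudocount = 5)
  space <- 4^5
  p_of <- function(col) {
    cnt <- setNames(rep(5, space), all_seqs(5))
    cnt["AAAAA"] <- cnt["AAAAA"] + tb$counts[1, col]
    cnt["CCCCC"] <- cnt["CCCCC"] + tb$counts[2, col]
    cnt / sum(cnt)
  }
  p1 <- p_of(1); p2 <- p_of(2)
  expect_equal(res$kl$d_kl, sum(p2 * log2(p2 / p1)))
})

test_that("k-mer enrichment follows the pseudocount log-ratio formula", {
  tb0 <- count_table("AAAAAAAA", matrix(c(0, 0, 3), 1, 3) + c(1, 0, 0))
  # counts: round1 = 1 read, round3 = 3 reads of the same 8-mer
  f <- kmer_enrichment(tb0, tb0, k = 8)
  expect_equal(unname(f$f_obs["AAAAAAAA"]), log(4 / 2) / 2)
  expect_equal(f$r2, 1)       # observed == predicted
  set.seed(72)
  obs <- rand_table(40, 9, 2, lambda = 8)
  prd <- rand_table(40, 9, 2, lambda = 8)
  # brute-force tally for a random k-mer
  res <- kmer_enrichment(obs, prd, k = 8)
  km <- names(which.max(res$f_obs))
  n1 <- sum(vapply(seq_along(obs$seqs), function(i)
    obs$counts[i, 1] * (length(gregexpr(km, obs$seqs[i])[[1]]) *
      (gregexpr(km, obs$seqs[i])[[1]][1] != -1)), 1))
  n2 <- sum(vapply(seq_along(obs$seqs), function(i)
    obs$counts[i, 2] * (length(gregexpr(km, obs$seqs[i])[[1]]) *
      (gregexpr(km, obs$seqs[i])[[1]][1] != -1)), 1))
  expect_equal(unname(res$f_obs[km]), log((1 + n2) / (1 + n1)))
})

test_that("binned enrichment metrics behave on perfect and flat predictions", {
  set.seed(73)
  fx <- selex_fixture(seed = 73, depth = 2e4)
  tb <- fx$table
  # predicted table = noiseless expected counts from the generating model
  Z <- predict_zbound(fx$truth, tb)
  f <- predict_frequencies(cbind(NA, Z), fx$selection, f0 = 1)
  E <- tb$counts
  for (r in 1:3) {
    p <- f[, r]; if (all(is.na(p))) p <- rep(1, nrow(E))
    E[, r] <- sum(tb$counts[, r]) * p / sum(p)
  }
  prd <- count_table(tb$seqs, E + 1e-9)
  m <- binned_enrichment_metrics(tb, prd, bin_target = 1000, min_reads = 1e3)
  expect_gt(m$r2_affinity, 0.95)
  expect_gt(m$fold_range, 1)
  # constant enrichment: fold range collapses to 1
  flat <- count_table(tb$seqs, cbind(tb$counts[, 1], tb$counts[, 1]))
  mf <- binned_enrichment_metrics(flat, flat, bin_target = 1000,
                                  min_reads = 1e3)
  expect_equal(mf$fold_range, 1, tolerance = 0.2)
  # no eligible pair
  m0 <- binned_enrichment_metrics(tb, prd, min_reads = 1e9)
  expect_true(is.na(m0$r2_affinity))
})

test_that("threshold maps are increasing and centred at one half", {
  expect_equal(f_logit(0.5, 0.5), 0.5)
  expect_equal(f_log(5, 5), 0.5)
  expect_equal(f_logit(0.95, 0.95), 0.5)
  x <- seq(0.05, 0.95, 0.05)
  expect_true(all(diff(f_logit(x, 0.5)) > 0))
  expect_true(all(diff(f_log(x * 10, 5)) > 0))
})

test_that("the composite training score averages mapped sub-scores", {
  at_threshold <- list(r2_8mer = 0.5, r2_affinity = 0.95, fold_range = 5.0,
                       r2_scoring = 0.95, mafr = 5.0, i_mono = 3.0)
  res <- training_score(at_threshold)
  expect_equal(res$score, 0.5)
  expect_length(res$sub_scores, 6)
  # missing metrics are excluded and flagged
  res2 <- training_score(list(r2_8mer = 0.7, mafr = 10))
  expect_equal(res2$score, mean(c(f_logit(0.7, 0.5), f_log(10, 5))))
  expect_setequal(res2$missing, c("r2_affinity", "fold_range", "r2_scoring",
                                  "i_mono"))
  # manual-ordering check on random metric sets
  set.seed(74)
  ms <- replicate(5, list(r2_8mer = runif(1), r2_affinity = runif(1),
                          fold_range = runif(1, 1, 30),
                          r2_scoring = runif(1), mafr = runif(1, 1, 30),
                          i_mono = runif(1, 0.1, 10)), simplify = FALSE)
  scores <- vapply(ms, function(m) training_score(m)$score, 1)
  manual <- vapply(ms, function(m) mean(c(
    f_logit(m$r2_8mer, 0.5), f_logit(m$r2_affinity, 0.95),
    f_log(m$fold_range, 5), f_logit(m$r2_scoring, 0.95),
    f_log(m$mafr, 5), f_log(m$i_mono, 3))), 1)
  expect_equal(scores, manual)
})

test_that("mode quality ranks the planted specific mode above a leftover mode", {
  fx <- selex_fixture(seed = 75, depth = 2e4, sd = 1.2)
  fit <- probefit(fx$table, fx$selection, modes = 2, L = 8, greedy = FALSE,
                  seed = 1, activity_tie = "free", ns_tie = "free",
                  reg = reg_spec(k_dirichlet = 20))
  # the mode matching the planted truth must take the higher quality score
  match_r2 <- vapply(fit$gauged, mode_recovery_r2, 1, truth = fx$truth_gauged)
  specific <- which.max(match_r2)
  qs <- vapply(1:2, function(m) mode_quality_score(fit, m), 1)
  expect_gt(match_r2[specific], 0.8)
  expect_equal(which.max(qs), specific)
  expect_true(all(is.finite(qs) | qs == -Inf))
})

test_that("saturation-transform fitting recovers its own forward model", {
  set.seed(76)
  x <- sort(rexp(60, 1 / 50))
  b0 <- 2.5; bc <- 0.01; bn <- 5
  y <- b0 / (1 + 1 / (bc * (x + bn)))
  fit <- saturation_fit(x, y, loss = "log")
  expect_gt(fit$r2, 0.9999)
  expect_equal(fit$beta0, b0, tolerance = 0.05)
  expect_gte(fit$mafr, 1)
  # full-saturation limit: yhat approaches beta0
  ysat <- b0 / (1 + 1 / (1e6 * (x + bn)))
  expect_equal(max(abs(ysat - b0)) / b0, 0, tolerance = 1e-4)
  # linear loss recovers the same forward model and tolerates negative y
  fit2 <- saturation_fit(x, y, loss = "linear")
  expect_gt(fit2$r2, 0.999)
  expect_no_error(saturation_fit(x, y - mean(y), loss = "linear"))
  # MAFR is scale invariant and 1 for flat signal
  fit3 <- saturation_fit(x, 10 * y, loss = "log")
  expect_equal(fit3$mafr, fit$mafr, tolerance = 1e-6)
  flat <- saturation_fit(x, rep(1, length(x)), loss = "log")
  expect_equal(flat$mafr, 1)
})

test_that("AUPRC matches exhaustive threshold enumeration and its properties", {
  brute_auprc <- function(scores, labels) {
    labels <- as.logical(labels)
    ths <- sort(unique(scores), decreasing = TRUE)
    rec <- 0; ap <- 0
    for (t in ths) {
      called <- scores >= t
      prec <- sum(labels & called) / sum(called)
      r <- sum(labels & called) / sum(labels)
      ap <- ap + (r - rec) * prec
      rec <- r
    }
    ap
  }
  set.seed(77)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    scores <- sample(1:10, n, TRUE)   # plenty of ties
    labels <- runif(n) < 0.4
    if (!any(labels)) labels[1] <- TRUE
    expect_equal(auprc(scores, labels), brute_auprc(scores, labels))
  }
  # perfect separation
  expect_equal(auprc(c(3, 2, 1), c(1, 0, 0)), 1)
  # constant score: AUPRC equals prevalence
  expect_equal(auprc(rep(1, 9), c(1, 1, 1, 0, 0, 0, 0, 0, 0)), 1 / 3)
  expect_error(auprc(1:3, c(0, 0, 0)), "positive")
})
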