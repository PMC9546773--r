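test_that("window scores are linear sums of monomer and pair coefficients", {
  al <- dna_alphabet()
  m0 <- binding_mode(2, al)
  expect_equal(score_window(m0, "AC"), 0)
  b <- matrix(1:8, 4, 2); rownames(b) <- al$letters
  m <- binding_mode(2, al, beta_mono = b)
  expect_equal(score_window(m, "AC"), unname(b["A", 1] + b["C", 2]))
  expect_error(score_window(m, "ACG"), "length")
  # pair features: brute-force enumeration of the indicator set
  set.seed(4)
  mp <- rand_mode(L = 3, pairs = rbind(c(1L, 3L)))
  for (s in sample(all_seqs(3), 12)) {
    ch <- strsplit(s, "")[[1]]
    i <- match(ch, al$letters)
    manual <- sum(mp$beta_mono[cbind(i, 1:3)]) + mp$beta_pair[[1]][i[1], i[3]]
    expect_equal(score_window(mp, s), manual)
  }
})

test_that("relative K_D is exp of the energy difference to the reference", {
  set.seed(5)
  m <- rand_mode(L = 4)
  m$reference <- "ACGT"
  expect_equal(relative_kd(m, "ACGT"), 1.0)
  s <- "TGCA"
  expect_equal(relative_kd(m, s),
               exp(score_window(m, "ACGT") - score_window(m, s)))
  m2 <- m
  m2$beta_mono[, 1] <- m2$beta_mono[match("ACGT", "ACGT"), 1]  # no-op keep
  expect_error(relative_kd(rand_mode(L = 4), "ACGT"), "reference")
})

test_that("partition function matches window counting in the flat limit", {
  al <- dna_alphabet()
  m <- binding_mode(4, al)
  rm0 <- recognition_model(list(m), log_alpha = matrix(0, 1, 1))
  expect_equal(partition_function(rm0, "ACGTACGTAC"), 2 * 7)  # strands * windows
  rns <- recognition_model(list(m), log_alpha = matrix(-Inf, 1, 1),
                           log_alpha_ns = log(0.5))
  expect_equal(partition_function(rns, "ACGTACGTAC"), 0.5)
})

test_that("partition function equals brute-force enumeration for random models", {
  set.seed(6)
  al <- dna_alphabet()
  for (i in 1:25) {
    L1 <- sample(2:5, 1); L2 <- sample(2:4, 1)
    m1 <- rand_mode(L = L1, pairs = if (i %% 2) "adjacent" else "none")
    m2 <- rand_mode(L = L2)
    it <- cooperativity(1, 2, max_spacing = sample(3:6, 1),
                        clash = sample(1:2, 1))
    it$log_omega[] <- rnorm(length(it$log_omega), sd = 0.4)
    model <- recognition_model(
      list(m1, m2), list(it),
      log_alpha = matrix(rnorm(2), 2, 1),
      log_alpha_ns = rnorm(1),
      log_alpha_int = matrix(rnorm(1), 1, 1))
    probe <- paste(sample(al$letters, sample(8:14, 1), TRUE), collapse = "")
    expect_equal(partition_function(model, probe),
                 brute_zbound(model, probe), tolerance = 1e-12)
  }
})

test_that("Z is additive over modes when interactions are absent", {
  set.seed(7)
  m1 <- rand_mode(L = 4); m2 <- rand_mode(L = 3)
  ns <- log(0.7)
  both <- recognition_model(list(m1, m2), log_alpha = matrix(c(0.2, -0.3), 2, 1),
                            log_alpha_ns = ns)
  one <- recognition_model(list(m1), log_alpha = matrix(0.2, 1, 1),
                           log_alpha_ns = ns)
  two <- recognition_model(list(m2), log_alpha = matrix(-0.3, 1, 1),
                           log_alpha_ns = ns)
  p <- "ACGTTGCAAGTC"
  expect_equal(partition_function(both, p),
               partition_function(one, p) + partition_function(two, p) - exp(ns),
               tolerance = 1e-12)
})

test_that("gauge transforms leave every sequence score unchanged", {
  set.seed(8)
  m <- rand_mode(L = 3, pairs = "all")
  seqs <- all_seqs(3)
  base <- score_window(m, seqs)
  for (A in c(-1.3, 0.4, 2.2)) {
    for (n in dna_alphabet()$letters) {
      g <- gauge_shift(m, 1, 3, n, A)
      expect_equal(score_window(g, seqs), base, tolerance = 1e-12)
      g2 <- gauge_shift(m, 2, 3, n, A)
      expect_equal(score_window(g2, seqs), base, tolerance = 1e-12)
    }
  }
})

test_that("mismatch gauge is canonical, difference-preserving and idempotent", {
  set.seed(9)
  for (i in 1:5) {
    m <- rand_mode(L = 4, pairs = "adjacent")
    m$reference <- sample(all_seqs(4), 1)
    g <- fix_gauge(m)
    seqs <- sample(all_seqs(4), 120)
    expect_equal(score_window(g, seqs) - score_window(g, m$reference),
                 score_window(m, seqs) - score_window(m, m$reference),
                 tolerance = 1e-12)
    expect_equal(score_window(g, m$reference), 0, tolerance = 1e-12)
    # reference letter coefficients vanish; couplings vanish on reference rows
    ref <- strsplit(m$reference, "")[[1]]
    ri <- match(ref, m$alphabet$letters)
    expect_equal(unname(g$beta_mono[cbind(ri, 1:4)]), rep(0, 4))
    for (k in seq_len(nrow(g$pairs))) {
      x1 <- g$pairs[k, 1]; x2 <- g$pairs[k, 2]
      expect_equal(unname(g$beta_pair[[k]][ri[x1], ]), rep(0, 4))
      expect_equal(unname(g$beta_pair[[k]][, ri[x2]]), rep(0, 4))
    }
    # idempotence, and canonical-form uniqueness after arbitrary gauge moves
    g2 <- fix_gauge(g)
    expect_equal(g2$beta_mono, g$beta_mono, tolerance = 1e-12)
    shifted <- gauge_shift(m, 1, 2, "G", 1.7)
    expect_equal(fix_gauge(shifted)$beta_mono, g$beta_mono, tolerance = 1e-10)
  }
  expect_error(fix_gauge(rand_mode(L = 3)), "reference")
})

test_that("information content matches a direct Shannon computation", {
  al <- dna_alphabet()
  expect_equal(information_content(binding_mode(5, al)), 0)
  # a single strongly preferred letter approaches 2 bits per position
  b <- matrix(0, 4, 1); b[1, 1] <- 30
  expect_equal(information_content(binding_mode(1, al, beta_mono = b)), 2,
               tolerance = 1e-8)
  set.seed(10)
  m <- rand_mode(L = 6, sd = 1)
  direct <- 0
  for (p in 1:6) {
    pr <- exp(m$beta_mono[, p]) / sum(exp(m$beta_mono[, p]))
    direct <- direct + 2 + sum(pr * log2(pr))
  }
  expect_equal(information_content(m), direct)
})

test_that("reverse-complement symmetric modes treat both strands identically", {
  set.seed(12)
  m <- rand_mode(L = 4, rc_symmetric = TRUE)
  expect_equal(m$beta_mono, probefit:::rc_map_mono(m$beta_mono, m$alphabet))
  model <- recognition_model(list(m), log_alpha = matrix(0, 1, 1))
  for (p in rand_seqs(10, 9)) {
    expect_equal(partition_function(model, p),
                 partition_function(model, reverse_complement(p)),
                 tolerance = 1e-12)
  }
})

test_that("energy logo export writes a bit-exact coefficient table", {
  set.seed(13)
  m <- rand_mode(L = 5)
  m$reference <- "ACGTA"
  stem <- file.path(tempdir(), "logo")
  suppressMessages(export_energy_logo(m, stem))
  expect_true(file.exists(paste0(stem, ".png")))
  tsv <- read.table(paste0(stem, ".tsv"), header = TRUE, sep = "\t")
  g <- fix_gauge(m)
  expect_identical(tsv$beta, as.vector(g$beta_mono))
})
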