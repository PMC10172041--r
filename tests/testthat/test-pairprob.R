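# Sparse inside-outside over the pairwise SAF ensemble.

test_that("log partition function matches exhaustive enumeration on tiny pairs", {
  set.seed(41)
  for (rep in 1:8) {
    inst <- tiny_instance()
    o <- oracle_ensemble(inst$x, inst$y, inst$theta, inst$cands)
    expect_equal(inside_logZ(inst$x, inst$y, inst$theta, inst$cands), o$logz,
                 tolerance = 1e-10)
  }
})

test_that("empty sequences give log Z = 0 and theta = 0 counts alignments", {
  x0 <- structure(list(id = "x", res = integer(0)), class = "rna_seq")
  cands <- full_candidates(x0, x0)
  expect_equal(inside_logZ(x0, x0, saf_params(0), cands), 0)

  # theta = 0, no allowed pairs: log Z = log(#canonical pairwise alignments)
  x <- rna_seq("x", "ACG"); y <- rna_seq("y", "AG")
  cands <- full_candidates(x, y)
  n_aln <- length(oracle_matchings(cands$am))
  expect_equal(inside_logZ(x, y, saf_params(0), cands), log(n_aln))
})

test_that("nested and multibranch closures match enumeration", {
  set.seed(43)
  x <- rna_seq("x", "GGAAACCGGAAACCAA")
  y <- rna_seq("y", "GGAAACCGGAAACCAA")
  cands <- manual_candidates(16, 16,
    am = rbind(c(1,1), c(2,2), c(6,6), c(7,7), c(9,9), c(13,13), c(14,14),
               c(15,15), c(16,16)),
    px = rbind(c(1,16), c(2,7), c(9,14)),
    py = rbind(c(1,16), c(2,7), c(9,14)))
  th <- random_theta(0.5)
  o <- oracle_ensemble(x, y, th, cands)
  r <- centrifold:::saf_engine(x, y, th, cands, want_counts = TRUE,
                               want_post = TRUE)
  expect_equal(r$logz, o$logz, tolerance = 1e-10)
  expect_equal(r$pm, o$pm, tolerance = 1e-9)
  expect_equal(r$ecounts, unname(o$ecounts), tolerance = 1e-9)
})

test_that("posteriors satisfy the complement identities and symmetry", {
  # single-residue pair: p^I = p^D = 1 - p^M
  x <- rna_seq("x", "A"); y <- rna_seq("y", "A")
  th <- random_theta()
  post <- posteriors(x, y, th, full_candidates(x, y))
  expect_gt(post$pm[1, 1], 0); expect_lt(post$pm[1, 1], 1)
  expect_equal(post$pins[1], 1 - post$pm[1, 1])
  expect_equal(post$pdel[1], 1 - post$pm[1, 1])

  # swapping the sequences transposes every table (for a theta whose
  # transition block is direction-symmetric; indel transitions are
  # separate features by design, so general theta breaks this)
  set.seed(44)
  inst <- tiny_instance()
  inst$theta <- symmetric_theta()
  a <- posteriors(inst$x, inst$y, inst$theta, inst$cands)
  swapped <- full_candidates(inst$y, inst$x)
  b <- posteriors(inst$y, inst$x, inst$theta, swapped)
  expect_equal(a$pm, t(b$pm), tolerance = 1e-10)
  expect_equal(a$px, b$py, tolerance = 1e-10)
  expect_equal(a$pins, b$pdel, tolerance = 1e-10)

  # tiny instances: all probabilities match enumeration
  for (rep in 1:5) {
    inst <- tiny_instance()
    o <- oracle_ensemble(inst$x, inst$y, inst$theta, inst$cands)
    post <- posteriors(inst$x, inst$y, inst$theta, inst$cands)
    expect_equal(post$pm[inst$cands$am], o$pm, tolerance = 1e-9)
    expect_lte(max(rowSums(post$pm)), 1 + 1e-9)
    expect_equal(post$pins, 1 - rowSums(post$pm), tolerance = 1e-9)
  }
})

test_that("expected counts equal the enumeration average at theta = 0", {
  set.seed(45)
  inst <- tiny_instance()
  th0 <- saf_params(0)
  o <- oracle_ensemble(inst$x, inst$y, th0, inst$cands)
  ec <- expected_counts(inst$x, inst$y, th0, inst$cands)
  expect_equal(unname(ec), unname(o$ecounts), tolerance = 1e-9)
  # with no quadruples allowed, every structure feature has expectation 0
  cands2 <- inst$cands
  cands2$px <- cands2$py <- matrix(integer(0), ncol = 2)
  ec2 <- expected_counts(inst$x, inst$y, inst$theta, cands2)
  expect_true(all(ec2[grep("^(bp|stack|hairpin|bulge|internal|multi)",
                           names(ec2))] == 0))
})

test_that("expected counts are the gradient of log Z (finite differences)", {
  set.seed(46)
  inst <- tiny_instance(4)
  th <- inst$theta
  ec <- expected_counts(inst$x, inst$y, th, inst$cands)
  h <- 1e-5
  for (f in sample(seq_along(th), 40)) {
    tp <- as.numeric(th); tm <- as.numeric(th)
    tp[f] <- tp[f] + h; tm[f] <- tm[f] - h
    fd <- (inside_logZ(inst$x, inst$y, saf_params(tp), inst$cands) -
           inside_logZ(inst$x, inst$y, saf_params(tm), inst$cands)) / (2 * h)
    if (abs(fd) > 1e-8 || abs(ec[f]) > 1e-8)
      expect_lt(abs(fd - ec[f]) / max(1e-6, abs(ec[f])), 1e-4)
  }
})

test_that("with no structure candidates the model degrades to a pair-HMM", {
  # posteriors over alignment features alone must equal enumeration over
  # matchings only (the forward-backward limit)
  set.seed(47)
  inst <- tiny_instance()
  cands <- inst$cands
  cands$px <- cands$py <- matrix(integer(0), ncol = 2)
  o <- oracle_ensemble(inst$x, inst$y, inst$theta, cands)
  pm <- pairhmm_match_prob(inst$x, inst$y, inst$theta)
  expect_equal(pm[cands$am], o$pm, tolerance = 1e-9)
})

test_that("candidate generation respects thresholds, caps and forcing", {
  set.seed(48)
  x <- random_rna(8, "x"); y <- random_rna(8, "y")
  th <- random_theta()
  # monotonicity: candidate counts are non-increasing in the thresholds
  sizes <- vapply(c(0.01, 0.05, 0.2, 0.4), function(eps) {
    cc <- build_candidates(x, y, th, epsilon_match = eps, epsilon_pair = eps)
    nrow(cc$am) + nrow(cc$px) + nrow(cc$py)
  }, 0)
  expect_true(all(diff(sizes) <= 0))
  # small thresholds on tiny inputs recover the full candidate sets
  x5 <- random_rna(5, "x"); y5 <- random_rna(5, "y")
  cc <- build_candidates(x5, y5, saf_params(0), epsilon_match = 1e-4,
                         epsilon_pair = 1e-4)
  expect_equal(nrow(cc$am), 25L)
  expect_equal(cc$px, full_candidates(x5, y5)$px)
  # forced events survive even when their posterior is far below threshold
  forced <- pairwise_saf(rbind(c(1L, 8L)), nx = 8, ny = 8)
  cc <- build_candidates(x, y, th, epsilon_match = 0.49, forced = forced)
  expect_true(any(cc$am[, 1] == 1 & cc$am[, 2] == 8))
})

test_that("work scales with the candidate sets, not the full DP lattice", {
  set.seed(49)
  x <- random_rna(14, "x"); y <- random_rna(14, "y")
  th <- random_theta()
  sparse <- manual_candidates(14, 14, am = cbind(1:14, 1:14),
                              px = rbind(c(2L, 12L)), py = rbind(c(2L, 12L)))
  dense <- full_candidates(x, y)
  rs <- centrifold:::saf_engine(x, y, th, sparse, want_post = TRUE)
  rd <- centrifold:::saf_engine(x, y, th, dense, want_post = TRUE)
  expect_lt(rs$n_edges, rd$n_edges / 10)
})
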