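# Shared fixture builders for the test suite.  Everything is generated in
# code under fixed seeds; no data files.

random_rna <- function(n, id = "s") {
  rna_seq(id, paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                    collapse = ""))
}

random_theta <- function(sd = 0.4) {
  saf_params(rnorm(nrow(saf_catalog()), sd = sd))
}

# theta whose alignment-transition block is direction-symmetric
# (MD = MI, DD = II, DM = IM): the model is then invariant under swapping
# the two sequences
symmetric_theta <- function(sd = 0.4) {
  th <- random_theta(sd)
  th["trans_MI"] <- th["trans_MD"]
  th["trans_II"] <- th["trans_DD"]
  th["trans_IM"] <- th["trans_DM"]
  th
}

# full candidate sets for a tiny pair (no pruning): every match, every pair
# with hairpin span >= 3 on each side
full_candidates <- function(x, y, min_hairpin = 3L) {
  n <- length(x$res); m <- length(y$res)
  am <- if (n > 0 && m > 0)
    cbind(rep(seq_len(n), each = m), rep(seq_len(m), times = n))
  else matrix(integer(0), ncol = 2)
  all_pairs <- function(k) {
    out <- matrix(integer(0), ncol = 2)
    if (k >= min_hairpin + 2)
      for (i in seq_len(k - min_hairpin - 1))
        for (j in seq(i + min_hairpin + 1, k)) out <- rbind(out, c(i, j))
    out
  }
  structure(list(am = am, px = all_pairs(n), py = all_pairs(m),
                 nx = n, ny = m, min_hairpin = as.integer(min_hairpin)),
            class = "saf_candidates")
}

# hand-restricted candidate sets (used to exercise nested / multibranch
# closures with a still-enumerable ensemble)
manual_candidates <- function(nx, ny, am, px, py, min_hairpin = 3L) {
  fix <- function(m, k) {
    m <- matrix(as.integer(m), ncol = k)
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  structure(list(am = fix(am, 2), px = fix(px, 2), py = fix(py, 2),
                 nx = as.integer(nx), ny = as.integer(ny),
                 min_hairpin = as.integer(min_hairpin)),
            class = "saf_candidates")
}

# a tiny instance whose ensemble the oracle can enumerate: random short
# sequences, full matches, at most a couple of allowed base pairs
tiny_instance <- function(nmax = 5L, theta_sd = 0.4) {
  n <- sample(2:nmax, 1); m <- sample(2:nmax, 1)
  x <- random_rna(n, "x"); y <- random_rna(m, "y")
  list(x = x, y = y, theta = random_theta(theta_sd),
       cands = full_candidates(x, y))
}

# model-generated posterior tables for a short random pair (these satisfy
# every PosteriorTables invariant by construction)
random_posterior_tables <- function(nmax = 5L, theta_sd = 0.6) {
  inst <- tiny_instance(nmax, theta_sd)
  posteriors(inst$x, inst$y, inst$theta, inst$cands)
}

# small synthetic family configuration used across tests (desk scale)
test_family_config <- function(seed, n_seq = 3L, length = 28L, ...) {
  family_config(n_seq = n_seq, length = length, pair_density = 0.25,
                sub_rate = 0.12, compensatory_prob = 0.9,
                indel_rate = 0.06, indel_mean_len = 1.3, seed = seed, ...)
}

# short training pairs sampled from the model at a known theta
# (Boltzmann sampling via stochastic traceback); alignment-only when
# allow_pairs = FALSE
sampled_training_set <- function(theta_true, n_examples, len = 10L,
                                 seed = 1L, allow_pairs = TRUE) {
  set.seed(seed)
  out <- vector("list", n_examples)
  for (d in seq_len(n_examples)) {
    x <- random_rna(len, paste0("x", d))
    y <- random_rna(len, paste0("y", d))
    cands <- full_candidates(x, y)
    if (!allow_pairs) {
      cands$px <- cands$py <- matrix(integer(0), ncol = 2)
    }
    saf <- sample_saf(x, y, theta_true, cands, n = 1)[[1]]
    out[[d]] <- training_example(x, y, saf)
  }
  out
}
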