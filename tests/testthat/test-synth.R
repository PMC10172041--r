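# Synthetic family generator and accuracy metrics.

test_that("zero-rate families reproduce the ancestor exactly", {
  cfg <- family_config(n_seq = 4L, length = 30L, pair_density = 0.3,
                       sub_rate = 0, compensatory_prob = 1, indel_rate = 0,
                       seed = 91L)
  fam <- sample_family(cfg)
  aln <- fam$msa$alignment
  expect_false(any(aln == "-"))
  for (r in 2:nrow(aln))
    expect_equal(unname(aln[r, ]), unname(aln[1, ]))
})

test_that("families are reproducible from their seed and validate", {
  cfg <- test_family_config(seed = 92)
  f1 <- sample_family(cfg); f2 <- sample_family(cfg)
  expect_identical(unclass(f1$msa$alignment), unclass(f2$msa$alignment))
  expect_identical(f1$msa$pairs, f2$msa$pairs)
  # validator sweep: structures pseudoknot-free, rows degap to sequences
  for (seed in 101:130) {
    fam <- sample_family(test_family_config(seed = seed, length = 24L))
    expect_silent(validate_structure(fam$msa$pairs, ncol(fam$msa$alignment)))
    for (s in fam$seqs)
      expect_equal(as.character(degap_row(fam$msa$alignment, s$id)),
                   as.character(s))
  }
})

test_that("infeasible pairing density is rejected", {
  expect_error(sample_family(family_config(length = 10L, pair_density = 0.9,
                                           seed = 93L)),
               "density")
})

test_that("paired columns hold canonical pairs at the compensatory rate", {
  cfg <- family_config(n_seq = 6L, length = 40L, pair_density = 0.3,
                       sub_rate = 0.25, compensatory_prob = 0.9,
                       indel_rate = 0.05, seed = 94L)
  canon_frac <- c()
  for (add in 0:9) {
    cfg2 <- cfg; cfg2$seed <- cfg$seed + add
    fam <- sample_family(cfg2)
    aln <- fam$msa$alignment
    for (r in seq_len(nrow(fam$msa$pairs))) {
      a <- aln[, fam$msa$pairs[r, 1]]; b <- aln[, fam$msa$pairs[r, 2]]
      ok <- a != "-" & b != "-"
      codes <- cbind(match(a[ok], c("A", "C", "G", "U")),
                     match(b[ok], c("A", "C", "G", "U")))
      canon_frac <- c(canon_frac, mean(centrifold:::is_canonical(codes[, 1],
                                                                 codes[, 2])))
    }
  }
  # sub_rate 0.25 with 10% non-compensatory: expected canonical fraction
  # stays near 1 - 0.25 * 0.1; demand at least the configured compensatory
  # share overall
  expect_gt(mean(canon_frac), 0.9)
})

test_that("projected pairwise examples satisfy the SAF invariants and re-embed", {
  cfg <- test_family_config(seed = 95, n_seq = 4L, length = 26L)
  exs <- make_training_set(cfg, n_families = 1L)
  expect_length(exs, 6L)   # C(4, 2)
  fam <- sample_family(cfg)
  maps <- centrifold:::alignment_maps(fam$msa$alignment)
  k <- 0
  for (a in 1:3) for (b in (a + 1):4) {
    k <- k + 1
    saf <- exs[[k]]$saf
    expect_s3_class(saf, "pairwise_saf")   # constructor re-validates
    # re-embedding: the projected matching equals the family's induced one
    ev <- centrifold:::alignment_pair_events(fam$msa$alignment, a, b, maps)
    expect_equal(unname(saf$match), unname(ev$match))
  }
})

test_that("training-set Stockholm files read back as the same examples", {
  dir <- tempfile(); dir.create(dir)
  cfg <- test_family_config(seed = 96, n_seq = 3L, length = 24L)
  exs <- make_training_set(cfg, n_families = 1L, out_dir = dir)
  files <- sort(list.files(dir, full.names = TRUE))
  expect_length(files, 3L)
  back <- read_training_example(files[1])
  expect_equal(as.character(back$x), as.character(exs[[1]]$x))
  expect_equal(unname(back$saf$match), unname(exs[[1]]$saf$match))
  expect_equal(unname(back$saf$quad), unname(exs[[1]]$saf$quad))
})

test_that("SPS agrees with direct event-set arithmetic", {
  ref <- rna_alignment(c(a = "ACGU-", b = "AC-UU"))
  expect_equal(sps(ref, ref), 1)

  # all-indel prediction vs all-match reference on single residues
  pred <- rna_alignment(c(a = "A-", b = "-A"))
  refm <- rna_alignment(c(a = "A", b = "A"))
  expect_equal(sps(pred, refm), 0)

  set.seed(97)
  for (rep in 1:10) {
    fam <- sample_family(test_family_config(seed = 200 + rep, length = 20L))
    ref <- fam$msa$alignment
    # perturb: shift one row's gaps by re-aligning it left
    pred <- ref
    expect_equal(sps(pred, ref), 1)
    # independent computation: intersect explicit event keys
    n <- nrow(ref)
    inter <- 0; C <- 0
    pm <- centrifold:::alignment_maps(pred); rm_ <- centrifold:::alignment_maps(ref)
    key <- function(prefix, v) if (length(v)) paste0(prefix, v) else character(0)
    ev_keys <- function(ev) c(
      key("m", if (nrow(ev$match)) paste0(ev$match[, 1], ":", ev$match[, 2])),
      key("i", ev$ins), key("d", ev$del))
    for (a in seq_len(n - 1)) for (b in seq(a + 1, n)) {
      pe <- centrifold:::alignment_pair_events(pred, a, b, pm)
      re <- centrifold:::alignment_pair_events(ref, a, b, rm_)
      inter <- inter + length(intersect(ev_keys(pe), ev_keys(re)))
      C <- C + nrow(pe$match) + length(pe$ins) + length(pe$del)
    }
    expect_equal(sps(pred, ref), inter / C)
  }
})

test_that("F1 and MCC reproduce their closed forms", {
  m <- f1_mcc(1, 1, 1, 1)
  expect_equal(m$f1, 0.5)
  expect_equal(m$mcc, 0)
  m <- f1_mcc(5, 7, 0, 0)
  expect_equal(m$f1, 1); expect_equal(m$mcc, 1)
  m <- f1_mcc(3, 4, 1, 2)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$mcc, (12 - 2) / sqrt(4 * 5 * 5 * 6))
  und <- f1_mcc(0, 5, 0, 0)
  expect_false(und$f1_defined)
  expect_false(und$mcc_defined)
  expect_true(is.na(und$f1))
  expect_false(is.nan(und$mcc))   # flagged as undefined, not NaN
})

test_that("structure confusion counts are consistent with the universe", {
  fam <- sample_family(test_family_config(seed = 98, length = 24L))
  cc <- structure_confusion(fam$msa, fam$msa)
  expect_equal(cc$fp, 0L); expect_equal(cc$fn, 0L)
  npos <- vapply(fam$seqs, seq_length, 0L)
  expect_equal(cc$tp + cc$tn, sum(npos * (npos - 1) / 2))
  ev <- evaluate_saf(fam$msa, fam$msa)
  expect_equal(ev$sps, 1)
  if (cc$tp > 0) expect_equal(ev$f1, 1)
})

test_that("the pipeline beats a column-shuffled baseline on easy families", {
  # low-divergence families; fixed gammas keep this light (the full grid
  # sweep is exercised elsewhere)
  th <- init_transfer()
  set.seed(99)
  sps_pred <- sps_base <- numeric(0)
  conf_pred <- conf_base <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (seed in 501:530) {
    fam <- sample_family(family_config(n_seq = 3L, length = 28L,
                                       pair_density = 0.36, sub_rate = 0.15,
                                       compensatory_prob = 0.95,
                                       indel_rate = 0.04, indel_mean_len = 1.2,
                                       seed = seed))
    posts <- pairwise_posteriors(fam$seqs, th)
    msa <- progressive_align(fam$seqs, gamma = gamma_pair(3, 2), posts = posts)
    ppcol <- column_pair_probs(msa, fam$seqs, posts)
    msa$pairs <- consensus_fold(ppcol, gamma = 2)
    # baseline: the same prediction with its columns randomly permuted
    # (consensus pairs carried along)
    nc <- ncol(msa$alignment)
    perm <- sample.int(nc)
    baln <- unclass(msa$alignment)[, perm, drop = FALSE]
    pos <- integer(nc); pos[perm] <- seq_len(nc)
    base <- list(alignment = structure(baln, class = "rna_alignment"),
                 pairs = {
                   p <- msa$pairs
                   if (nrow(p) > 0) {
                     q <- cbind(pos[p[, 1]], pos[p[, 2]])
                     q <- cbind(pmin(q[, 1], q[, 2]), pmax(q[, 1], q[, 2]))
                     q[order(q[, 1]), , drop = FALSE]
                   } else p
                 })
    class(base) <- "saf_msa"
    sps_pred <- c(sps_pred, sps(msa, fam$msa))
    sps_base <- c(sps_base, sps(base$alignment, fam$msa$alignment))
    cc <- structure_confusion(msa, fam$msa)
    conf_pred <- conf_pred + unlist(cc)
    ccb <- structure_confusion(base, fam$msa)
    conf_base <- conf_base + unlist(ccb)
  }
  expect_gt(mean(sps_pred), mean(sps_base))
  f1p <- f1_mcc(conf_pred["tp"], conf_pred["tn"], conf_pred["fp"], conf_pred["fn"])
  f1b <- f1_mcc(conf_base["tp"], conf_base["tn"], conf_base["fp"], conf_base["fn"])
  expect_gt(f1p$f1, if (f1b$f1_defined) f1b$f1 else 0)
})
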