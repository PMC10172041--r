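# Progressive multiple SAF: similarity, guide tree, profile merging,
# consensus folding.

test_that("stochastic similarity applies the eligibility indicator", {
  pm <- matrix(0, 2, 2); pm[1, 1] <- 0.6; pm[2, 2] <- 0.4
  expect_equal(similarity(pm, 2), 0.6)
  expect_equal(similarity(matrix(0.3, 3, 3), 2), 0)
  # non-decreasing in gamma_match
  set.seed(61)
  post <- random_posterior_tables(5)
  vals <- vapply(c(2, 3, 5, 9, 17, 33, 65, 129),
                 function(g) similarity(post, g), 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("UPGMA joins the most similar pair first and matches hclust", {
  sim <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  sim[1, 2] <- sim[2, 1] <- 5
  sim[1, 3] <- sim[3, 1] <- 1
  sim[2, 3] <- sim[3, 2] <- 1
  tree <- upgma_tree(sim)
  # the deepest join is (a, b)
  leaf_pair <- function(node) {
    if (!is.null(node$leaf)) return(NULL)
    if (!is.null(node$left$leaf) && !is.null(node$right$leaf))
      return(sort(c(node$left$leaf, node$right$leaf)))
    c(leaf_pair(node$left), leaf_pair(node$right))
  }
  expect_equal(leaf_pair(tree), c(1L, 2L))

  # random matrices agree with average-linkage clustering (tie-free)
  set.seed(62)
  for (rep in 1:5) {
    n <- 5
    sim <- matrix(0, n, n)
    sim[upper.tri(sim)] <- runif(n * (n - 1) / 2)
    sim <- sim + t(sim)
    rownames(sim) <- colnames(sim) <- paste0("s", 1:n)
    d <- max(sim[upper.tri(sim)]) - sim
    diag(d) <- 0
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(tree_cophenetic(upgma_tree(sim), n),
                 as.matrix(stats::cophenetic(hc)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_error(upgma_tree(matrix(0, 1, 1)), "two sequences")
})

test_that("guide-tree heights are monotone toward the root", {
  set.seed(63)
  sim <- matrix(0, 6, 6)
  sim[upper.tri(sim)] <- runif(15)
  sim <- sim + t(sim)
  tree <- upgma_tree(sim)
  ok <- TRUE
  walk <- function(node) {
    if (is.null(node$leaf)) {
      for (ch in list(node$left, node$right)) {
        if (is.null(ch$leaf) && ch$height > node$height + 1e-12) ok <<- FALSE
        walk(ch)
      }
    }
  }
  walk(tree)
  expect_true(ok)
})

test_that("merging two single-sequence profiles equals pairwise decoding", {
  set.seed(64)
  fam <- sample_family(test_family_config(seed = 64, n_seq = 2L, length = 24L))
  th <- init_transfer()
  posts <- pairwise_posteriors(fam$seqs, th)
  g <- gamma_pair(3, 2)
  msa <- progressive_align(fam$seqs, gamma = g, posts = posts)
  pw <- align_pair(posts[["1|2"]], g)
  aln2 <- saf_to_alignment(pw$saf, fam$seqs[[1]], fam$seqs[[2]])
  expect_equal(unclass(msa$alignment), unclass(aln2), ignore_attr = TRUE)
  # identical matched base-pair columns
  maps <- centrifold:::alignment_maps(msa$alignment)
  if (nrow(msa$pairs) > 0) {
    qx <- cbind(maps[1, msa$pairs[, 1]], maps[1, msa$pairs[, 2]])
    expect_equal(unname(qx), unname(pw$saf$quad[, 1:2, drop = FALSE]))
  } else {
    expect_equal(nrow(pw$saf$quad), 0L)
  }
})

test_that("column probability aggregation matches the printed averages", {
  # hand-built 2-member profiles: p^M_IK = mean over member pairs with
  # gapped members contributing zero
  pm <- matrix(1:9 / 10, 3, 3)
  posts <- list("1|2" = list(pm = pm))
  X <- list(aln = matrix(c("A", "C"), 1, 2, dimnames = list("a", NULL)),
            map = matrix(c(1L, 2L), 1), ids = "a", index = 1L)
  Y <- list(aln = matrix(c("A", "-", "G"), 1, 3, dimnames = list("b", NULL)),
            map = matrix(c(1L, NA, 2L), 1), ids = "b", index = 2L)
  tabs <- centrifold:::profile_tables(X, Y, posts,
                                      list(matrix(0, 2, 2), matrix(0, 2, 2)))
  expect_equal(tabs$pm[, 2], c(0, 0))           # gap column contributes 0
  expect_equal(tabs$pm[1, 1], pm[1, 1])
  expect_equal(tabs$pm[2, 3], pm[2, 2])
})

test_that("progressive alignment preserves residues and input order", {
  fam <- sample_family(test_family_config(seed = 66, n_seq = 4L, length = 24L))
  th <- init_transfer()
  msa <- progressive_align(fam$seqs, th, gamma_pair(3, 2),
                           epsilon_match = 0.02, epsilon_pair = 0.02)
  expect_equal(rownames(msa$alignment),
               vapply(fam$seqs, function(s) s$id, ""))
  for (i in seq_along(fam$seqs))
    expect_equal(as.character(degap_row(msa$alignment, fam$seqs[[i]]$id)),
                 as.character(fam$seqs[[i]]))
  expect_false(any(colSums(unclass(msa$alignment) != "-") == 0))
})

test_that("permuting the input order does not change the product", {
  fam <- sample_family(test_family_config(seed = 67, n_seq = 3L, length = 22L))
  th <- init_transfer()
  msa1 <- progressive_align(fam$seqs, th, gamma_pair(3, 2))
  perm <- c(3, 1, 2)
  msa2 <- progressive_align(fam$seqs[perm], th, gamma_pair(3, 2))
  ids <- rownames(msa1$alignment)
  expect_equal(unclass(msa1$alignment)[ids, ],
               unclass(msa2$alignment)[ids, ], ignore_attr = TRUE)
  expect_equal(msa1$pairs, msa2$pairs)
})

test_that("three homologs: induced pairwise matchings score non-negatively", {
  fam <- sample_family(test_family_config(seed = 68, n_seq = 3L, length = 24L))
  th <- init_transfer()
  posts <- pairwise_posteriors(fam$seqs, th)
  g <- gamma_pair(3, 2)
  msa <- progressive_align(fam$seqs, gamma = g, posts = posts)
  maps <- centrifold:::alignment_maps(msa$alignment)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    ev <- centrifold:::alignment_pair_events(msa$alignment, pair[1], pair[2], maps)
    saf <- pairwise_saf(ev$match,
                        nx = seq_length(fam$seqs[[pair[1]]]),
                        ny = seq_length(fam$seqs[[pair[2]]]))
    p <- posts[[centrifold:::pair_key(pair[1], pair[2])]]
    expect_gte(objective(saf, p, g), 0)
  }
})

test_that("consensus folding equals exhaustive search on few columns", {
  set.seed(69)
  for (rep in 1:10) {
    nc <- sample(6:8, 1)
    pp <- matrix(0, nc, nc)
    pp[upper.tri(pp)] <- runif(nc * (nc - 1) / 2)
    got <- consensus_fold(pp, gamma = 2, min_hairpin = 3L)
    gain <- function(pairs) if (nrow(pairs) == 0) 0 else sum(2 * pp[pairs] - 1)
    # exhaustive search over nested pairings of eligible columns
    elig <- which(upper.tri(pp) & pp >= 0.5, arr.ind = TRUE)
    elig <- elig[elig[, 2] - elig[, 1] - 1 >= 3, , drop = FALSE]
    best <- 0
    if (nrow(elig) > 0) {
      for (size in seq_len(nrow(elig))) {
        for (cmb in combn_list(seq_len(nrow(elig)), size)) {
          q <- cbind(elig[cmb, , drop = FALSE], elig[cmb, , drop = FALSE])
          if (quadset_valid(q, 0)) best <- max(best, gain(elig[cmb, , drop = FALSE]))
        }
      }
    }
    expect_equal(gain(got), best, tolerance = 1e-12)
  }
  # single eligible pair and the all-ineligible case
  pp <- matrix(0, 7, 7); pp[2, 6] <- 0.9
  expect_equal(unname(consensus_fold(pp, 2)), rbind(c(2L, 6L)))
  expect_equal(nrow(consensus_fold(matrix(0.4, 7, 7), 2)), 0L)
})
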