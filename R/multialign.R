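## Progressive multiple SAF: stochastic similarity, UPGMA guide tree,
## column-probability profiles, profile-profile gamma-centroid merging and
## the consensus-folding post-process.

#' Stochastic similarity between two homologs
#'
#' `sigma = sum_{(i,k)} p^M_ik * 1[p^M_ik >= 1/gamma_M]`: the expected
#' number of eligible nucleotide matches, computed without aligning.
#'
#' @param post An `saf_posteriors` object (or a dense match-probability
#'   matrix).
#' @param gamma_match The gamma_M hyper-parameter (> 1).
#' @return A single number.
#' @export
similarity <- function(post, gamma_match) {
  stopifnot(gamma_match > 1)
  pm <- if (is.matrix(post)) post else post$pm
  sum(pm[pm >= 1 / gamma_match])
}

#' UPGMA guide tree from a similarity matrix
#'
#' Distances are `d = max(sigma) - sigma`; clusters are merged by average
#' linkage, ties resolved toward the lowest-index pair.  Node heights are
#' ultrametric (`d/2`), non-decreasing toward the root.
#'
#' @param sim Symmetric numeric similarity matrix with one row per
#'   sequence; row names are used as leaf labels.
#' @return A nested-list binary tree of class `guide_tree`; internal nodes
#'   carry `height`, leaves carry the sequence index `leaf`.
#' @export
upgma_tree <- function(sim) {
  n <- nrow(sim)
  if (n < 2) stop("need at least two sequences")
  labels <- rownames(sim) %||% as.character(seq_len(n))
  off <- sim[upper.tri(sim)]
  d <- max(off) - sim
  diag(d) <- NA
  nodes <- lapply(seq_len(n), function(i)
    list(leaf = i, label = labels[i], members = i, height = 0))
  sizes <- rep(1L, n)
  active <- seq_len(n)
  while (length(active) > 1) {
    best <- NULL; bestd <- Inf
    for (ai in seq_along(active)[-length(active)]) {
      for (bi in seq(ai + 1, length(active))) {
        dd <- d[active[ai], active[bi]]
        if (dd < bestd) { bestd <- dd; best <- c(ai, bi) }
      }
    }
    i <- active[best[1]]; j <- active[best[2]]
    node <- list(left = nodes[[i]], right = nodes[[j]],
                 members = c(nodes[[i]]$members, nodes[[j]]$members),
                 height = bestd / 2)
    ## average-linkage update into slot i
    for (k in active) {
      if (k == i || k == j) next
      dk <- (sizes[i] * d[i, k] + sizes[j] * d[j, k]) / (sizes[i] + sizes[j])
      d[i, k] <- dk; d[k, i] <- dk
    }
    sizes[i] <- sizes[i] + sizes[j]
    nodes[[i]] <- node
    active <- setdiff(active, j)
  }
  structure(nodes[[active]], class = "guide_tree")
}

#' Cophenetic merge distances of a guide tree
#' @param tree A `guide_tree`.
#' @param n Number of leaves.
#' @return A symmetric matrix of the distances (2 x merge height) at which
#'   each leaf pair is first joined.
#' @export
tree_cophenetic <- function(tree, n) {
  out <- matrix(0, n, n)
  walk <- function(node) {
    if (!is.null(node$leaf)) return(invisible(NULL))
    for (a in node$left$members)
      for (b in node$right$members) {
        out[a, b] <<- 2 * node$height
        out[b, a] <<- 2 * node$height
      }
    walk(node$left); walk(node$right)
  }
  walk(tree)
  out
}

#' @export
print.guide_tree <- function(x, ...) {
  cat("UPGMA guide tree: ", length(x$members), " leaves\n", sep = "")
  cat(tree_newick(x), "\n")
  invisible(x)
}

#' Newick rendering of a guide tree
#' @param tree A `guide_tree`.
#' @return A Newick string with ultrametric branch lengths.
#' @export
tree_newick <- function(tree) {
  walk <- function(node, parent_h) {
    if (!is.null(node$leaf))
      return(sprintf("%s:%.6g", node$label, parent_h))
    sprintf("(%s,%s):%.6g", walk(node$left, node$height),
            walk(node$right, node$height), parent_h - node$height)
  }
  if (!is.null(tree$leaf)) return(paste0(tree$label, ";"))
  paste0("(", walk(tree$left, tree$height), ",",
         walk(tree$right, tree$height), ");")
}

## ---------------------------------------------------------------------------
## profiles
## ---------------------------------------------------------------------------

## a profile is an aligned set: character matrix `aln` over its members plus
## `map` (member x column -> residue index or NA)
single_profile <- function(seq, index) {
  aln <- matrix(RES_ALPHA[seq$res], nrow = 1,
                dimnames = list(seq$id, NULL))
  map <- matrix(seq_along(seq$res), nrow = 1, dimnames = list(seq$id, NULL))
  list(aln = aln, map = map, ids = seq$id, index = index)
}

## dense residue-level match table for ordered member pair (a, b),
## a and b being input indices; tables are stored for a < b
pm_table <- function(posts, a, b) {
  if (a < b) posts[[pair_key(a, b)]]$pm else t(posts[[pair_key(b, a)]]$pm)
}

pair_key <- function(a, b) paste0(a, "|", b)

## column-level probability tables between two profiles
profile_tables <- function(X, Y, posts, avg_pair) {
  ci <- ncol(X$aln); ck <- ncol(Y$aln)
  pmcol <- matrix(0, ci, ck)
  for (ax in seq_along(X$index)) {
    for (ay in seq_along(Y$index)) {
      tab <- pm_table(posts, X$index[ax], Y$index[ay])
      mi <- X$map[ax, ]; mk <- Y$map[ay, ]
      oi <- !is.na(mi); ok <- !is.na(mk)
      pmcol[oi, ok] <- pmcol[oi, ok] + tab[mi[oi], mk[ok], drop = FALSE]
    }
  }
  pmcol <- pmcol / (length(X$index) * length(Y$index))
  list(pm = pmcol,
       px = profile_pair_table(X, avg_pair),
       py = profile_pair_table(Y, avg_pair))
}

profile_pair_table <- function(X, avg_pair) {
  ci <- ncol(X$aln)
  out <- matrix(0, ci, ci)
  for (ax in seq_along(X$index)) {
    tab <- avg_pair[[X$index[ax]]]
    mi <- X$map[ax, ]
    oi <- !is.na(mi)
    out[oi, oi] <- out[oi, oi] + tab[mi[oi], mi[oi], drop = FALSE]
  }
  out / length(X$index)
}

#' Merge two profiles by the gamma-centroid column recursion
#'
#' Runs the pairwise recursion with column matching probabilities
#' `p^M_IK = mean over member pairs` and column base-pairing probabilities
#' `p^P_IJ = mean over members` (gapped members contribute 0); unmatched
#' columns become gap columns in the other profile's rows, deletions before
#' insertions within every run.
#'
#' @param X,Y Profiles as built by [progressive_align()] internals.
#' @param posts Named list of pairwise `saf_posteriors` keyed "a|b".
#' @param avg_pair Per-sequence partner-averaged base-pair probability
#'   tables.
#' @param gamma A [gamma_pair].
#' @param min_hairpin Minimum hairpin span.
#' @return The merged profile with component `quads` (matched column
#'   quadruples in merged coordinates).
#' @keywords internal
merge_profiles <- function(X, Y, posts, avg_pair, gamma, min_hairpin = 3L) {
  tabs <- profile_tables(X, Y, posts, avg_pair)
  gamma <- as_gamma(gamma)
  res <- cpp_centroid(tabs$pm, tabs$px, tabs$py,
                      gamma[["match"]], gamma[["pair"]], prune = TRUE,
                      min_hairpin = as.integer(min_hairpin))
  mm <- res$match
  ci <- ncol(X$aln); ck <- ncol(Y$aln)
  ## interleave: per run, X columns (deletions) before Y columns
  xcol <- integer(0); ycol <- integer(0)
  px <- 0L; py <- 0L
  emit <- function(xto, yto) {
    if (xto > px) { xcol <<- c(xcol, seq(px + 1L, xto)); ycol <<- c(ycol, rep(NA, xto - px)) }
    if (yto > py) { xcol <<- c(xcol, rep(NA, yto - py)); ycol <<- c(ycol, seq(py + 1L, yto)) }
    px <<- xto; py <<- yto
  }
  if (nrow(mm) > 0) {
    for (r in seq_len(nrow(mm))) {
      emit(mm[r, 1] - 1L, mm[r, 2] - 1L)
      xcol <- c(xcol, mm[r, 1]); ycol <- c(ycol, mm[r, 2])
      px <- mm[r, 1]; py <- mm[r, 2]
    }
  }
  emit(ci, ck)
  nc <- length(xcol)
  aln <- matrix(GAP, nrow(X$aln) + nrow(Y$aln), nc,
                dimnames = list(c(rownames(X$aln), rownames(Y$aln)), NULL))
  map <- matrix(NA_integer_, nrow(aln), nc, dimnames = dimnames(aln))
  okx <- !is.na(xcol); oky <- !is.na(ycol)
  aln[seq_len(nrow(X$aln)), okx] <- X$aln[, xcol[okx], drop = FALSE]
  map[seq_len(nrow(X$aln)), okx] <- X$map[, xcol[okx], drop = FALSE]
  aln[nrow(X$aln) + seq_len(nrow(Y$aln)), oky] <- Y$aln[, ycol[oky], drop = FALSE]
  map[nrow(X$aln) + seq_len(nrow(Y$aln)), oky] <- Y$map[, ycol[oky], drop = FALSE]
  ## matched column quadruples in merged coordinates
  quads <- matrix(integer(0), ncol = 2)
  if (nrow(res$quad) > 0) {
    xpos <- match(seq_len(ci), xcol)
    quads <- cbind(xpos[res$quad[, 1]], xpos[res$quad[, 2]])
  }
  list(aln = aln, map = map, ids = c(X$ids, Y$ids),
       index = c(X$index, Y$index), quads = quads)
}

#' Progressive multiple simultaneous alignment and folding
#'
#' Computes pairwise posterior tables once, builds the UPGMA guide tree
#' from the stochastic similarities at the current `gamma_match`, and
#' merges profiles leaf-to-root by the gamma-centroid column recursion.
#' The returned consensus structure is the matched column pair set of the
#' root merge.  No iterative refinement is performed.
#'
#' @param seqs List of [rna_seq] (length >= 2, unique ids).
#' @param theta [saf_params]; ignored when `posts` is supplied.
#' @param gamma A [gamma_pair].
#' @param posts Optional precomputed pairwise posteriors
#'   ([pairwise_posteriors()]).
#' @param min_hairpin Minimum hairpin span.
#' @param ... Passed to [build_candidates()] when posteriors are computed
#'   here.
#' @return An [saf_msa] with rows in input order; its `tree` attribute
#'   holds the guide tree.
#' @export
progressive_align <- function(seqs, theta = NULL, gamma = gamma_pair(),
                              posts = NULL, min_hairpin = 3L, ...) {
  n <- length(seqs)
  if (n < 2) stop("need at least two sequences")
  ids <- vapply(seqs, function(s) s$id, "")
  if (anyDuplicated(ids)) stop("sequence ids must be unique")
  gamma <- as_gamma(gamma)
  if (is.null(posts)) posts <- pairwise_posteriors(seqs, theta, ...)
  avg_pair <- partner_averaged_pairs(seqs, posts)
  sim <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n - 1)) for (b in seq(a + 1, n)) {
    s <- similarity(posts[[pair_key(a, b)]], gamma[["match"]])
    sim[a, b] <- s; sim[b, a] <- s
  }
  tree <- upgma_tree(sim)
  build <- function(node) {
    if (!is.null(node$leaf)) return(single_profile(seqs[[node$leaf]], node$leaf))
    L <- build(node$left); R <- build(node$right)
    ## canonical orientation: the child holding the lexicographically
    ## smallest sequence id plays the x role, making the product invariant
    ## under permuting the input order
    if (min(R$ids) < min(L$ids)) { tmp <- L; L <- R; R <- tmp }
    merge_profiles(L, R, posts, avg_pair, gamma, min_hairpin)
  }
  root <- build(tree)
  ord <- order(root$index)
  aln <- rna_alignment(setNames(apply(root$aln, 1, paste, collapse = "")[ord],
                                rownames(root$aln)[ord]))
  msa <- saf_msa(aln, root$quads, gamma = unclass(gamma))
  attr(msa, "tree") <- tree
  msa
}

#' All pairwise posterior tables of an input set
#'
#' Each pair is evaluated in a canonical orientation (the sequence with the
#' lexicographically smaller id first) and transposed back to input order;
#' the gap transitions are directional features, so without this the
#' product would depend on the order sequences were supplied in.
#'
#' @param seqs List of [rna_seq].
#' @param theta [saf_params].
#' @param ... Passed to [build_candidates()].
#' @return Named list keyed `"a|b"` over input index pairs a < b.
#' @export
pairwise_posteriors <- function(seqs, theta, ...) {
  n <- length(seqs)
  posts <- list()
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      if (seqs[[a]]$id <= seqs[[b]]$id) {
        cands <- build_candidates(seqs[[a]], seqs[[b]], theta, ...)
        posts[[pair_key(a, b)]] <- posteriors(seqs[[a]], seqs[[b]], theta, cands)
      } else {
        cands <- build_candidates(seqs[[b]], seqs[[a]], theta, ...)
        posts[[pair_key(a, b)]] <-
          transpose_posteriors(posteriors(seqs[[b]], seqs[[a]], theta, cands))
      }
    }
  }
  posts
}

## swap the roles of the two sequences in a posterior table set
transpose_posteriors <- function(post) {
  structure(list(pm = t(post$pm), px = post$py, py = post$px,
                 pins = post$pdel, pdel = post$pins,
                 logz = post$logz, logz_out = post$logz_out,
                 n_nodes = post$n_nodes, n_edges = post$n_edges,
                 ids = rev(post$ids)), class = "saf_posteriors")
}

## per-sequence base-pair probabilities averaged over all partners
## ("consistency" transformation)
partner_averaged_pairs <- function(seqs, posts) {
  n <- length(seqs)
  lapply(seq_len(n), function(a) {
    acc <- NULL; cnt <- 0
    for (b in seq_len(n)) {
      if (b == a) next
      p <- if (a < b) posts[[pair_key(a, b)]]$px else posts[[pair_key(b, a)]]$py
      acc <- if (is.null(acc)) p else acc + p
      cnt <- cnt + 1
    }
    acc / cnt
  })
}

#' Consensus folding of an alignment from column pair probabilities
#'
#' Nussinov-style maximization of `sum (gamma p^P_IJ - 1)` over
#' pseudoknot-free column pairings; only column pairs with
#' `p^P >= 1/gamma` are eligible.  Used as the post-process that replaces
#' the progressive product's consensus structure.
#'
#' @param pp Dense column-pair probability matrix (upper triangle used).
#' @param gamma The folding gamma (> 1); 2 by default.
#' @param min_hairpin Minimum column span between paired columns.
#' @return Integer matrix of chosen column pairs.
#' @export
consensus_fold <- function(pp, gamma = 2, min_hairpin = 3L) {
  stopifnot(gamma > 1)
  nc <- nrow(pp)
  if (nc == 0) return(matrix(integer(0), ncol = 2))
  gain <- gamma * pp - 1
  elig <- pp >= 1 / gamma
  W <- matrix(0, nc + 1, nc)   # W[i, j] over i..j, row nc+1 = empty
  tb <- matrix(0L, nc + 1, nc) # 0 leave j unpaired, k>0: pair (k, j)
  for (span in seq_len(nc)) {
    for (i in seq_len(nc - span + 1)) {
      j <- i + span - 1
      best <- if (j > i) W[i, j - 1] else 0
      bk <- 0L
      ks <- seq(i, max(i, j - min_hairpin - 1))
      for (k in ks) {
        if (j - k - 1 < min_hairpin || !elig[k, j]) next
        v <- gain[k, j] +
          (if (k > i) W[i, k - 1] else 0) +
          (if (j - k > 1) W[k + 1, j - 1] else 0)
        if (v > best) { best <- v; bk <- k }
      }
      W[i, j] <- best; tb[i, j] <- bk
    }
  }
  pairs <- list()
  stack <- list(c(1L, nc))
  while (length(stack) > 0) {
    iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    if (i > j) next
    k <- tb[i, j]
    if (k == 0L) {
      if (j > i) stack[[length(stack) + 1]] <- c(i, j - 1L)
    } else {
      pairs[[length(pairs) + 1]] <- c(k, j)
      if (k > i) stack[[length(stack) + 1]] <- c(i, k - 1L)
      if (j - k > 1) stack[[length(stack) + 1]] <- c(k + 1L, j - 1L)
    }
  }
  out <- if (length(pairs) > 0) do.call(rbind, pairs) else matrix(integer(0), ncol = 2)
  out <- out[order(out[, 1]), , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Column base-pair probability table of a multiple alignment
#'
#' `p^P_IJ = (1/|X|) sum_x p^P_{I_x J_x}`, gapped members contributing 0.
#'
#' @param msa An [saf_msa] (rows in input order).
#' @param seqs The input sequences (same order as alignment rows).
#' @param posts Pairwise posteriors from [pairwise_posteriors()].
#' @return A dense column-by-column probability matrix.
#' @export
column_pair_probs <- function(msa, seqs, posts) {
  aln <- msa$alignment
  maps <- alignment_maps(aln)
  avg <- partner_averaged_pairs(seqs, posts)
  nc <- ncol(aln)
  out <- matrix(0, nc, nc)
  for (r in seq_len(nrow(aln))) {
    mi <- maps[r, ]; oi <- !is.na(mi)
    out[oi, oi] <- out[oi, oi] + avg[[r]][mi[oi], mi[oi], drop = FALSE]
  }
  out / nrow(aln)
}
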