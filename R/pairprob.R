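## Sparse candidate generation and posterior inference for a sequence pair.
##
## Candidate nucleotide matches come from the pair-HMM obtained by dropping
## all structure candidates from the joint model (alignment features only);
## candidate base pairs per sequence come from a single-sequence
## McCaskill-style partition function over the structure features.
## Candidate quadruples are all consistent combinations.  During training
## the reference example's events are force-included so that its score is
## always inside the sparse ensemble.

all_pairs_matrix <- function(n, min_hairpin = 3L) {
  if (n < min_hairpin + 2L) return(matrix(integer(0), ncol = 2))
  idx <- which(outer(seq_len(n), seq_len(n),
                     function(i, j) j - i - 1L >= min_hairpin), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

all_matches_matrix <- function(n, m) {
  if (n == 0L || m == 0L) return(matrix(integer(0), ncol = 2))
  cbind(rep(seq_len(n), each = m), rep(seq_len(m), times = n))
}

#' Pair-HMM match posteriors
#'
#' Posterior probabilities of every nucleotide match under the alignment
#' part of the model alone (no structure candidates); this is the exact
#' pair-HMM limit of the joint model.
#'
#' @param x,y [rna_seq] objects.
#' @param theta [saf_params].
#' @return A dense `length(x)` by `length(y)` matrix of match posteriors.
#' @export
pairhmm_match_prob <- function(x, y, theta) {
  theta <- check_params(theta)
  n <- seq_length(x); m <- seq_length(y)
  am <- all_matches_matrix(n, m)
  g <- cpp_saf_build(x$res, y$res, am,
                     matrix(integer(0), ncol = 2), matrix(integer(0), ncol = 2))
  res <- cpp_saf_eval(g, theta, want_post = TRUE)
  pm <- matrix(0, n, m)
  if (nrow(am) > 0) pm[am] <- res$pm
  pm
}

#' Single-sequence base-pairing posteriors
#'
#' McCaskill-style pair probabilities under the structure part of the model
#' (base-pair composition, stacking and loop features); used to nominate
#' candidate base pairs for the sparse joint model.
#'
#' @param x An [rna_seq].
#' @param theta [saf_params].
#' @param min_hairpin Minimum hairpin loop length.
#' @param max_loop Cap on the total length of one internal/bulge loop
#'   considered between two candidate pairs.
#' @return A dense symmetric-use upper-triangular matrix of probabilities.
#' @export
ss_pair_prob <- function(x, theta, min_hairpin = 3L, max_loop = 30L) {
  theta <- check_params(theta)
  n <- seq_length(x)
  pr <- all_pairs_matrix(n, min_hairpin)
  pp <- matrix(0, n, n)
  if (nrow(pr) > 0) {
    res <- cpp_ss(x$res, pr, theta, min_hairpin, max_loop)
    pp[pr] <- res$pp
  }
  pp
}

#' Build sparse SAF candidates for a sequence pair
#'
#' Keeps nucleotide matches whose pair-HMM posterior reaches
#' `epsilon_match` and per-sequence base pairs whose single-sequence
#' posterior reaches `epsilon_pair`; candidate quadruples are all
#' consistent combinations of kept pairs and matches.  Events of `forced`
#' (a reference SAF) are always included.
#'
#' @param x,y [rna_seq] objects.
#' @param theta [saf_params] used for the nominating models.
#' @param epsilon_match,epsilon_pair Posterior inclusion thresholds in
#'   (0, 0.5).
#' @param forced Optional [pairwise_saf] whose matches and quadruples are
#'   force-included.
#' @param max_match_keep,max_pair_keep Optional per-position caps (keep the
#'   top-probability candidates); `Inf` disables the caps.
#' @param max_pair_total Optional cap on the total number of candidate base
#'   pairs per sequence (top probabilities kept); bounds the number of
#'   candidate quadruples when the nominating model is still uninformative.
#' @param min_hairpin Minimum hairpin loop length.
#' @return An object of class `saf_candidates` with components `am`
#'   (matches), `px`, `py` (per-sequence pairs).
#' @export
build_candidates <- function(x, y, theta, epsilon_match = 0.01,
                             epsilon_pair = 0.01, forced = NULL,
                             max_match_keep = Inf, max_pair_keep = Inf,
                             max_pair_total = Inf, min_hairpin = 3L) {
  stopifnot(epsilon_match > 0, epsilon_match < 0.5,
            epsilon_pair > 0, epsilon_pair < 0.5)
  n <- seq_length(x); m <- seq_length(y)
  pm <- pairhmm_match_prob(x, y, theta)
  am <- which(pm >= epsilon_match, arr.ind = TRUE)
  if (is.finite(max_match_keep) && nrow(am) > 0)
    am <- cap_per_position(am, pm[am], max_match_keep)
  ppx <- ss_pair_prob(x, theta, min_hairpin)
  ppy <- ss_pair_prob(y, theta, min_hairpin)
  px <- threshold_pairs(ppx, epsilon_pair, max_pair_keep)
  py <- threshold_pairs(ppy, epsilon_pair, max_pair_keep)
  if (is.finite(max_pair_total)) {
    px <- cap_total(px, ppx[px], max_pair_total)
    py <- cap_total(py, ppy[py], max_pair_total)
  }
  if (!is.null(forced)) {
    stopifnot(inherits(forced, "pairwise_saf"))
    am <- rbind(am, forced$match)
    px <- rbind(px, forced$quad[, c(1, 2), drop = FALSE])
    py <- rbind(py, forced$quad[, c(3, 4), drop = FALSE])
  }
  am <- unique_sorted(am); px <- unique_sorted(px); py <- unique_sorted(py)
  structure(list(am = am, px = px, py = py, nx = n, ny = m,
                 min_hairpin = as.integer(min_hairpin),
                 cache = new.env(parent = emptyenv())),
            class = "saf_candidates")
}

threshold_pairs <- function(pp, eps, max_keep) {
  keep <- which(pp >= eps, arr.ind = TRUE)
  if (is.finite(max_keep) && nrow(keep) > 0)
    keep <- cap_per_position(keep, pp[keep], max_keep)
  keep
}

cap_total <- function(idx, p, k) {
  if (nrow(idx) <= k) return(idx)
  keep <- order(p, decreasing = TRUE)[seq_len(k)]
  idx[sort(keep), , drop = FALSE]
}

cap_per_position <- function(idx, p, k) {
  sel <- unlist(lapply(split(seq_len(nrow(idx)), idx[, 1]), function(rows) {
    rows[order(p[rows], decreasing = TRUE)][seq_len(min(k, length(rows)))]
  }))
  idx[sort(sel), , drop = FALSE]
}

unique_sorted <- function(idx) {
  if (nrow(idx) == 0) {
    storage.mode(idx) <- "integer"
    return(idx)
  }
  idx <- unique(idx)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  storage.mode(idx) <- "integer"
  dimnames(idx) <- NULL
  idx
}

#' @export
print.saf_candidates <- function(x, ...) {
  cat("SAF candidates: ", nrow(x$am), " matches, ", nrow(x$px), " + ",
      nrow(x$py), " base pairs (", x$nx, " x ", x$ny, " nt)\n", sep = "")
  invisible(x)
}

## one engine invocation; everything else unwraps this.  The DP hypergraph
## depends only on the candidate sets, so it is built once per candidate
## object and re-swept for every theta.
saf_engine <- function(x, y, theta, cands, want_counts = FALSE,
                       want_post = FALSE, n_sample = 0L) {
  stopifnot(inherits(cands, "saf_candidates"))
  cpp_saf_eval(saf_graph(x, y, cands), check_params(theta),
               want_counts = want_counts, want_post = want_post,
               n_sample = as.integer(n_sample))
}

saf_graph <- function(x, y, cands) {
  env <- cands$cache
  if (!is.environment(env)) env <- NULL
  if (!is.null(env) && !is.null(env$graph)) return(env$graph)
  g <- cpp_saf_build(x$res, y$res, cands$am, cands$px, cands$py,
                     min_hairpin = cands$min_hairpin)
  if (!is.null(env)) env$graph <- g
  g
}

#' Log partition function of the sparse SAF ensemble
#'
#' @inheritParams build_candidates
#' @param cands An `saf_candidates` object.
#' @return `log Z^S`, the log of the total Boltzmann weight of all
#'   candidate alignment-and-folding products.
#' @export
inside_logZ <- function(x, y, theta, cands) {
  saf_engine(x, y, theta, cands)$logz
}

#' Posterior probability tables for a sequence pair
#'
#' Runs the sparse inside-outside algorithm and returns the posterior
#' probability of every candidate nucleotide match (`pm`), the per-sequence
#' base-pairing marginals (`px`, `py`), and the posterior insertion and
#' deletion probabilities `pins[i] = 1 - sum_k pm[i,k]`,
#' `pdel[k] = 1 - sum_i pm[i,k]`.
#'
#' @inheritParams inside_logZ
#' @return An object of class `saf_posteriors`.
#' @export
posteriors <- function(x, y, theta, cands) {
  res <- saf_engine(x, y, theta, cands, want_post = TRUE)
  n <- cands$nx; m <- cands$ny
  pm <- matrix(0, n, m)
  if (nrow(cands$am) > 0) pm[cands$am] <- res$pm
  px <- matrix(0, n, n); py <- matrix(0, m, m)
  if (nrow(res$quads) > 0) {
    for (r in seq_len(nrow(res$quads))) {
      q <- res$quads[r, ]
      px[q[1], q[2]] <- px[q[1], q[2]] + res$pq[r]
      py[q[3], q[4]] <- py[q[3], q[4]] + res$pq[r]
    }
  }
  structure(list(
    pm = pm, px = px, py = py,
    pins = pmin(pmax(1 - rowSums(pm), 0), 1),
    pdel = pmin(pmax(1 - colSums(pm), 0), 1),
    logz = res$logz, logz_out = res$logz_out,
    n_nodes = res$n_nodes, n_edges = res$n_edges,
    ids = c(x$id, y$id)), class = "saf_posteriors")
}

#' @export
print.saf_posteriors <- function(x, ...) {
  cat("SAF posteriors ", x$ids[1], " x ", x$ids[2], ": log Z = ",
      format(x$logz, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Expected feature counts of the sparse ensemble
#'
#' `E^S[phi_f] = sum_A p^S(A) phi_f(A)`, computed by inside-outside without
#' enumeration; identical to the gradient of [inside_logZ()] in theta.
#'
#' @inheritParams inside_logZ
#' @return A named numeric vector over the catalog.
#' @export
expected_counts <- function(x, y, theta, cands) {
  res <- saf_engine(x, y, theta, cands, want_counts = TRUE)
  setNames(res$ecounts, saf_catalog()$descriptor)
}

#' Sample alignment-and-folding products from the sparse ensemble
#'
#' Stochastic traceback of the inside algorithm: draws SAF candidates with
#' their Boltzmann probabilities.  Uses R's RNG stream.
#'
#' @inheritParams inside_logZ
#' @param n Number of samples.
#' @return A list of [pairwise_saf] objects.
#' @export
sample_saf <- function(x, y, theta, cands, n = 1L) {
  res <- saf_engine(x, y, theta, cands, want_post = TRUE, n_sample = n)
  lapply(res$samples, function(s) {
    am <- cands$am[s$match + 1L, , drop = FALSE]
    qd <- if (length(s$quad) > 0)
      res$quads[s$quad + 1L, 1:4, drop = FALSE]
    else matrix(integer(0), ncol = 4)
    pairwise_saf(am, qd, cands$nx, cands$ny, min_hairpin = cands$min_hairpin)
  })
}

## TSV debugging dump of posterior tables
#' @rdname posteriors
#' @param post An `saf_posteriors` object.
#' @param path Output TSV path (three blocks: match, pair-x, pair-y).
#' @export
write_posteriors_tsv <- function(post, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# kind\ti\tj\tprob", con)
  w <- which(post$pm > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(w)))
    writeLines(sprintf("match\t%d\t%d\t%.8g", w[r, 1], w[r, 2],
                       post$pm[w[r, 1], w[r, 2]]), con)
  for (side in c("px", "py")) {
    w <- which(post[[side]] > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(w)))
      writeLines(sprintf("%s\t%d\t%d\t%.8g",
                         if (side == "px") "pair_x" else "pair_y",
                         w[r, 1], w[r, 2], post[[side]][w[r, 1], w[r, 2]]), con)
  }
  invisible(path)
}
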