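## Expected-SPS hyper-parameter auto-correction over the gamma grid, the
## two-model probability ensemble, and the top-level prediction entry point.

#' The gamma hyper-parameter grid
#'
#' Grid values are `2^e + 1` over exponent bounds; the defaults
#' (`i` in 0..7 for gamma_M, `j` in 0..3 for gamma_P) give the 8 x 4 grid
#' {2,3,5,9,17,33,65,129} x {2,3,5,9}.
#'
#' @param imin,imax,jmin,jmax Integer exponent bounds.
#' @return A data frame with columns `i`, `j`, `gamma_match`, `gamma_pair`,
#'   ordered with `i` varying slowest.
#' @export
gamma_grid <- function(imin = 0L, imax = 7L, jmin = 0L, jmax = 3L) {
  stopifnot(imin <= imax, jmin <= jmax)
  g <- expand.grid(j = seq(jmin, jmax), i = seq(imin, imax))[, c("i", "j")]
  g$gamma_match <- 2^g$i + 1
  g$gamma_pair <- 2^g$j + 1
  rownames(g) <- NULL
  g
}

## induced pairwise events of a multiple alignment for row pair (a, b):
## matched position pairs, unmatched x positions ("insertions"), unmatched
## y positions ("deletions")
alignment_pair_events <- function(aln, a, b, maps = alignment_maps(aln)) {
  ma <- maps[a, ]; mb <- maps[b, ]
  both <- !is.na(ma) & !is.na(mb)
  list(match = cbind(ma[both], mb[both]),
       ins = ma[!is.na(ma) & is.na(mb)],
       del = mb[is.na(ma) & !is.na(mb)])
}

#' Approximate expected sum-of-pairs score of a prediction
#'
#' The posterior-weighted SPS of a multiple SAF against the whole ensemble:
#' every predicted match event contributes its match posterior, every
#' unmatched position its insertion/deletion posterior, normalized by the
#' total number of scored events C (which makes the score of a prediction
#' against itself equal to 1).
#'
#' @param msa An [saf_msa] whose rows follow the input order of `posts`.
#' @param posts Pairwise posteriors from [pairwise_posteriors()].
#' @return A list with `value` (the estimate in `[0, 1]`) and `C`.
#' @export
expected_sps <- function(msa, posts) {
  aln <- msa$alignment
  n <- nrow(aln)
  if (ncol(aln) == 0) stop("expected SPS of an empty alignment is undefined")
  maps <- alignment_maps(aln)
  num <- 0; C <- 0L
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      ev <- alignment_pair_events(aln, a, b, maps)
      p <- posts[[pair_key(a, b)]]
      if (nrow(ev$match) > 0) num <- num + sum(p$pm[ev$match])
      if (length(ev$ins) > 0) num <- num + sum(p$pins[ev$ins])
      if (length(ev$del) > 0) num <- num + sum(p$pdel[ev$del])
      C <- C + nrow(ev$match) + length(ev$ins) + length(ev$del)
    }
  }
  list(value = num / C, C = C)
}

#' Hyper-parameter auto-correction by expected SPS
#'
#' Runs [progressive_align()] at every grid point and keeps the candidate
#' with the highest expected SPS; ties resolve toward the smaller exponent
#' pair (i, j).
#'
#' @param seqs List of [rna_seq].
#' @param theta [saf_params]; ignored when `posts` is given.
#' @param grid A data frame from [gamma_grid()].
#' @param posts Optional precomputed pairwise posteriors.
#' @param ... Passed to [progressive_align()].
#' @return A list with `msa` (best [saf_msa]), `gamma` (chosen pair),
#'   `expected_sps`, and `table` (the per-grid-point report).
#' @export
autocorrect <- function(seqs, theta = NULL, grid = gamma_grid(),
                        posts = NULL, ...) {
  stopifnot(nrow(grid) >= 1)
  if (is.null(posts)) posts <- pairwise_posteriors(seqs, theta, ...)
  best <- NULL
  tab <- grid
  tab$expected_sps <- NA_real_
  for (r in seq_len(nrow(grid))) {
    g <- gamma_pair(grid$gamma_match[r], grid$gamma_pair[r])
    msa <- progressive_align(seqs, theta, gamma = g, posts = posts, ...)
    es <- expected_sps(msa, posts)$value
    tab$expected_sps[r] <- es
    if (is.null(best) || es > best$expected_sps) {
      best <- list(msa = msa, gamma = g, expected_sps = es)
    }
  }
  c(best, list(table = tab))
}

#' Average two posterior tables (model ensemble)
#'
#' Entrywise arithmetic mean of the match and base-pair probability tables
#' of two inference models for the same sequence pair; indel posteriors are
#' recomputed from the averaged match table (equivalently, averaged).
#'
#' @param postA,postB `saf_posteriors` of congruent shape.
#' @return An `saf_posteriors` object.
#' @export
ensemble_average <- function(postA, postB) {
  if (!all(dim(postA$pm) == dim(postB$pm)))
    stop("posterior tables have different shapes")
  pm <- (postA$pm + postB$pm) / 2
  structure(list(
    pm = pm,
    px = (postA$px + postB$px) / 2,
    py = (postA$py + postB$py) / 2,
    pins = pmin(pmax(1 - rowSums(pm), 0), 1),
    pdel = pmin(pmax(1 - colSums(pm), 0), 1),
    logz = NA_real_, ids = postA$ids), class = "saf_posteriors")
}

#' Predict a multiple SAF for unaligned RNA homologs
#'
#' The full prediction pipeline: pairwise posterior inference (optionally
#' as the two-model ensemble with alignment parameters transplanted into
#' the partner model), expected-SPS auto-correction of the gamma
#' hyper-parameters over the grid, and the consensus-folding post-process
#' (gamma = 2) that replaces the progressive product's consensus structure.
#'
#' @param seqs List of [rna_seq], or a FASTA path handed to [read_fasta()].
#' @param params Trained [saf_params]; defaults to the packaged transfer
#'   table.
#' @param model `"trained"` (default), `"ensemble"`, or `"partner"`.
#' @param grid Hyper-parameter grid from [gamma_grid()].
#' @param consensus_gamma Gamma for the consensus-folding post-process.
#' @param epsilon_match,epsilon_pair Candidate thresholds.
#' @param min_hairpin Minimum hairpin loop length.
#' @param ... Further arguments to [build_candidates()].
#' @return A list of class `saf_result`: `msa`, `gamma`, `expected_sps`,
#'   `grid_table`.
#' @export
saf_align <- function(seqs, params = init_transfer(),
                      model = c("trained", "ensemble", "partner"),
                      grid = gamma_grid(), consensus_gamma = 2,
                      epsilon_match = 0.01, epsilon_pair = 0.01,
                      min_hairpin = 3L, ...) {
  model <- match.arg(model)
  if (is.character(seqs)) seqs <- read_fasta(seqs)
  mk_posts <- function(th) pairwise_posteriors(
    seqs, th, epsilon_match = epsilon_match, epsilon_pair = epsilon_pair,
    min_hairpin = min_hairpin, ...)
  posts <- switch(model,
    trained = mk_posts(params),
    partner = mk_posts(transplant_alignment_params(partner_params(), params)),
    ensemble = {
      pa <- mk_posts(params)
      pb <- mk_posts(transplant_alignment_params(partner_params(), params))
      setNames(lapply(names(pa), function(k) ensemble_average(pa[[k]], pb[[k]])),
               names(pa))
    })
  sel <- autocorrect(seqs, grid = grid, posts = posts,
                     min_hairpin = min_hairpin)
  msa <- sel$msa
  ppcol <- column_pair_probs(msa, seqs, posts)
  msa$pairs <- consensus_fold(ppcol, gamma = consensus_gamma,
                              min_hairpin = min_hairpin)
  structure(list(msa = msa, gamma = sel$gamma,
                 expected_sps = sel$expected_sps, grid_table = sel$table),
            class = "saf_result")
}

#' @export
print.saf_result <- function(x, ...) {
  print(x$msa)
  cat("  expected SPS ", format(x$expected_sps, digits = 4),
      " at gamma (", x$gamma[["match"]], ", ", x$gamma[["pair"]], ")\n",
      sep = "")
  invisible(x)
}
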