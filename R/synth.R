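## Synthetic RNA family generator and the alignment/structure accuracy
## metrics.  Families are grown from a pseudoknot-free ancestor with
## canonical pairs at paired sites; homologs evolve by (compensatory)
## substitutions and by indels confined to unpaired ancestor regions, so
## the planted consensus structure stays well defined in every row.

#' Configuration of a synthetic RNA family
#'
#' @param n_seq Number of homologs.
#' @param length Ancestor sequence length (nt).
#' @param pair_density Target fraction of paired ancestor positions.
#' @param sub_rate Per-site substitution probability (per pair for paired
#'   sites).
#' @param compensatory_prob Probability that a substituted paired site is
#'   replaced by another canonical/wobble pair (both sides changed
#'   together).
#' @param indel_rate Per unpaired site probability of starting a deletion
#'   or an insertion in one homolog.
#' @param indel_mean_len Mean length of an indel event.
#' @param seed Mandatory integer seed.
#' @return A list of class `family_config`.
#' @export
family_config <- function(n_seq = 5L, length = 60L, pair_density = 0.25,
                          sub_rate = 0.15, compensatory_prob = 0.9,
                          indel_rate = 0.05, indel_mean_len = 1.5,
                          seed) {
  if (missing(seed)) stop("a seed is mandatory")
  rates <- c(pair_density, sub_rate, compensatory_prob, indel_rate)
  stopifnot(all(rates >= 0), all(rates <= 1), n_seq >= 1, length >= 1,
            indel_mean_len >= 1)
  structure(list(n_seq = as.integer(n_seq), length = as.integer(length),
                 pair_density = pair_density, sub_rate = sub_rate,
                 compensatory_prob = compensatory_prob,
                 indel_rate = indel_rate, indel_mean_len = indel_mean_len,
                 seed = as.integer(seed)), class = "family_config")
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## sample a pseudoknot-free structure with helix bias; errors out when the
## density target is infeasible for the length
sample_structure <- function(n, density, min_hairpin = 3L, max_tries = 400L) {
  target <- floor(density * n / 2)
  pairs <- matrix(integer(0), ncol = 2)
  if (target == 0) return(pairs)
  if (n < 2 * target + min_hairpin)
    stop("pairing density ", density, " is infeasible for length ", n)
  compatible <- function(i, j) {
    if (nrow(pairs) == 0) return(TRUE)
    if (any(pairs == i) || any(pairs == j)) return(FALSE)
    ok <- (pairs[, 1] > i & pairs[, 2] < j) | (pairs[, 2] < i) |
      (pairs[, 1] > j) | (pairs[, 1] < i & pairs[, 2] > j)
    all(ok)
  }
  hairpin_ok <- function(cand) {
    ## adding cand must not leave any hairpin shorter than min_hairpin
    all_p <- rbind(pairs, cand)
    for (r in seq_len(nrow(all_p))) {
      i <- all_p[r, 1]; j <- all_p[r, 2]
      inner <- all_p[, 1] > i & all_p[, 2] < j
      if (!any(inner) && j - i - 1 < min_hairpin) return(FALSE)
    }
    TRUE
  }
  tries <- 0L
  while (nrow(pairs) < target && tries < max_tries) {
    tries <- tries + 1L
    cand <- NULL
    if (nrow(pairs) > 0 && runif(1) < 0.7) {
      ## helix extension: stack a new pair just inside or outside one
      base <- pairs[sample.int(nrow(pairs), 1), ]
      cand <- if (runif(1) < 0.5) c(base[1] + 1L, base[2] - 1L)
              else c(base[1] - 1L, base[2] + 1L)
      if (cand[1] < 1 || cand[2] > n || cand[2] - cand[1] - 1 < min_hairpin)
        cand <- NULL
    }
    if (is.null(cand)) {
      i <- sample.int(n, 1)
      j_lo <- i + min_hairpin + 1L
      if (j_lo > n) next
      j <- sample(seq(j_lo, n), 1)
      cand <- c(i, j)
    }
    if (compatible(cand[1], cand[2]) && hairpin_ok(cand))
      pairs <- rbind(pairs, cand)
  }
  if (nrow(pairs) < target)
    stop("could not reach pairing density ", density, " for length ", n)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  storage.mode(pairs) <- "integer"
  pairs
}

## canonical pair sampling weights (GC-rich, little wobble)
PAIR_WEIGHTS <- c(0.2, 0.25, 0.25, 0.05, 0.2, 0.05)

sample_canonical <- function() CANONICAL_PAIRS[sample.int(6, 1, prob = PAIR_WEIGHTS), ]

#' Sample a synthetic RNA family
#'
#' Draws a pseudoknot-free ancestor structure (minimum hairpin length 3)
#' with canonical pairs at paired sites, evolves each homolog by
#' substitutions (compensatory at paired columns with the configured
#' probability) and by indels restricted to unpaired ancestor regions, and
#' returns the true alignment with its planted consensus structure plus
#' the unaligned sequences.
#'
#' @param config A [family_config] (its seed fully determines the family).
#' @return A list with `msa` (the reference [saf_msa]) and `seqs` (list of
#'   degapped [rna_seq]).
#' @export
sample_family <- function(config) {
  stopifnot(inherits(config, "family_config"))
  with_seed(config$seed, {
    n <- config$length
    pairs <- sample_structure(n, config$pair_density)
    paired <- logical(n)
    if (nrow(pairs) > 0) paired[c(pairs[, 1], pairs[, 2])] <- TRUE
    anc <- integer(n)
    anc[!paired] <- sample.int(4, sum(!paired), replace = TRUE)
    if (nrow(pairs) > 0)
      for (r in seq_len(nrow(pairs))) {
        bp <- sample_canonical()
        anc[pairs[r, 1]] <- bp[1]; anc[pairs[r, 2]] <- bp[2]
      }
    rows <- list()        # per homolog: residues per ancestor column (0 = deleted)
    inserts <- list()     # per homolog: list col -> inserted residues after col
    for (s in seq_len(config$n_seq)) {
      res <- anc
      if (nrow(pairs) > 0)
        for (r in seq_len(nrow(pairs))) {
          if (runif(1) < config$sub_rate) {
            if (runif(1) < config$compensatory_prob) {
              bp <- sample_canonical()
              res[pairs[r, 1]] <- bp[1]; res[pairs[r, 2]] <- bp[2]
            } else {
              side <- if (runif(1) < 0.5) pairs[r, 1] else pairs[r, 2]
              res[side] <- sample.int(4, 1)
            }
          }
        }
      for (p in which(!paired))
        if (runif(1) < config$sub_rate)
          res[p] <- sample(setdiff(1:4, res[p]), 1)
      ## deletions may not shrink any hairpin loop below 3 nt, or the
      ## planted structure would violate the model's minimum hairpin span
      hp_loop <- rep(NA_integer_, n)
      hp_room <- integer(0)
      if (nrow(pairs) > 0) {
        for (r in seq_len(nrow(pairs))) {
          i <- pairs[r, 1]; j <- pairs[r, 2]
          if (!any(pairs[, 1] > i & pairs[, 2] < j)) {
            hp_room <- c(hp_room, j - i - 1 - 3L)
            hp_loop[seq(i + 1, j - 1)] <- length(hp_room)
          }
        }
      }
      ins <- vector("list", n + 1)
      for (p in which(!paired)) {
        if (runif(1) < config$indel_rate / 2) {
          h <- hp_loop[p]
          if (is.na(h)) {
            res[p] <- 0L
          } else if (hp_room[h] > 0L) {
            res[p] <- 0L
            hp_room[h] <- hp_room[h] - 1L
          }
        }
        if (runif(1) < config$indel_rate / 2) {
          len <- 1L + rgeom(1, 1 / config$indel_mean_len)
          ins[[p + 1L]] <- sample.int(4, len, replace = TRUE)
        }
      }
      rows[[s]] <- res
      inserts[[s]] <- ins
    }
    ## assemble reference alignment: ancestor columns plus per-homolog
    ## insertion columns (each insertion event gets its own columns)
    ids <- sprintf("seq%02d", seq_len(config$n_seq))
    blocks <- list()
    colpair_of <- integer(n)   # ancestor column -> alignment column
    colidx <- 0L
    add_block <- function(mat) blocks[[length(blocks) + 1L]] <<- mat
    ins_block <- function(slot) {
      lens <- vapply(seq_len(config$n_seq),
                     function(s) length(inserts[[s]][[slot]]), 0L)
      if (all(lens == 0)) return(invisible(NULL))
      m <- matrix(GAP, config$n_seq, sum(lens > 0) * max(lens))
      ## each homolog's insertion occupies its own columns
      at <- 0L
      for (s in which(lens > 0)) {
        m[s, at + seq_len(lens[s])] <- RES_ALPHA[inserts[[s]][[slot]]]
        at <- at + lens[s]
      }
      add_block(m[, seq_len(at), drop = FALSE])
      colidx <<- colidx + at
    }
    ins_block(1L)
    for (p in seq_len(n)) {
      col <- vapply(seq_len(config$n_seq), function(s) {
        if (rows[[s]][p] == 0L) GAP else RES_ALPHA[rows[[s]][p]]
      }, "")
      if (all(col == GAP)) {
        colpair_of[p] <- NA_integer_
      } else {
        add_block(matrix(col, ncol = 1))
        colidx <- colidx + 1L
        colpair_of[p] <- colidx
      }
      ins_block(p + 1L)
    }
    mat <- do.call(cbind, blocks)
    rownames(mat) <- ids
    aln <- rna_alignment(setNames(apply(mat, 1, paste, collapse = ""), ids))
    ref_pairs <- matrix(integer(0), ncol = 2)
    if (nrow(pairs) > 0) {
      cp <- cbind(colpair_of[pairs[, 1]], colpair_of[pairs[, 2]])
      ref_pairs <- cp[!is.na(cp[, 1]) & !is.na(cp[, 2]), , drop = FALSE]
    }
    msa <- saf_msa(aln, ref_pairs)
    seqs <- lapply(ids, function(id) degap_row(aln, id))
    list(msa = msa, seqs = seqs)
  })
}

#' Build a pairwise training set from synthetic families
#'
#' For every family, the induced pairwise SAF of every sequence pair is
#' extracted from the reference alignment (pair events with a gapped side
#' removed) and returned as a training example.
#'
#' @param config A [family_config] template; family f uses seed
#'   `config$seed + f - 1`.
#' @param n_families Number of families.
#' @param out_dir Optional directory: examples are also written as
#'   two-sequence Stockholm files.
#' @return A list of [training_example].
#' @export
make_training_set <- function(config, n_families, out_dir = NULL) {
  stopifnot(n_families >= 1)
  out <- list()
  for (fidx in seq_len(n_families)) {
    cfg <- config
    cfg$seed <- config$seed + fidx - 1L
    fam <- sample_family(cfg)
    aln <- fam$msa$alignment
    n <- nrow(aln)
    for (a in seq_len(n - 1)) {
      for (b in seq(a + 1, n)) {
        saf <- project_pair(aln, a, b, fam$msa$pairs)
        ex <- training_example(fam$seqs[[a]], fam$seqs[[b]], saf)
        out[[length(out) + 1L]] <- ex
        if (!is.null(out_dir)) {
          sub <- saf_to_alignment(saf, fam$seqs[[a]], fam$seqs[[b]])
          sspairs <- matrix(integer(0), ncol = 2)
          if (nrow(saf$quad) > 0) {
            maps <- alignment_maps(sub)
            sspairs <- cbind(match(saf$quad[, 1], maps[1, ]),
                             match(saf$quad[, 2], maps[1, ]))
          }
          write_stockholm(saf_msa(sub, sspairs),
                          file.path(out_dir, sprintf("fam%03d_%d_%d.sto",
                                                     fidx, a, b)))
        }
      }
    }
  }
  out
}

## ---------------------------------------------------------------------------
## accuracy metrics
## ---------------------------------------------------------------------------

#' Sum-of-pairs score of a predicted alignment
#'
#' The fraction of the prediction's pairwise match and indel events that
#' are present in the reference, normalized by the prediction's total
#' event count C (so `sps(A, A) = 1`).  Shares its event bookkeeping with
#' [expected_sps()].
#'
#' @param predicted,reference `rna_alignment` (or [saf_msa]) over the same
#'   sequences.
#' @return A number in `[0, 1]`.
#' @export
sps <- function(predicted, reference) {
  pa <- if (inherits(predicted, "saf_msa")) predicted$alignment else predicted
  ra <- if (inherits(reference, "saf_msa")) reference$alignment else reference
  ids <- rownames(pa)
  if (!setequal(ids, rownames(ra)))
    stop("predicted and reference alignments hold different sequences")
  ra <- ra[ids, , drop = FALSE]
  class(ra) <- "rna_alignment"
  pmaps <- alignment_maps(pa); rmaps <- alignment_maps(ra)
  n <- nrow(pa)
  hits <- 0L; C <- 0L
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      pe <- alignment_pair_events(pa, a, b, pmaps)
      re <- alignment_pair_events(ra, a, b, rmaps)
      rkey <- paste(re$match[, 1], re$match[, 2])
      if (nrow(pe$match) > 0)
        hits <- hits + sum(paste(pe$match[, 1], pe$match[, 2]) %in% rkey)
      hits <- hits + sum(pe$ins %in% re$ins) + sum(pe$del %in% re$del)
      C <- C + nrow(pe$match) + length(pe$ins) + length(pe$del)
    }
  }
  hits / C
}

#' F1 score and Matthews correlation coefficient
#'
#' `F1 = 2TP / (2TP + FP + FN)`;
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A zero denominator is flagged as undefined rather than returned as NaN.
#'
#' @param tp,tn,fp,fn Confusion counts.
#' @return A list with `f1`, `mcc`, and logical flags `f1_defined`,
#'   `mcc_defined`.
#' @export
f1_mcc <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  f1_den <- 2 * tp + fp + fn
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  list(f1 = if (f1_den > 0) 2 * tp / f1_den else NA_real_,
       mcc = if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_,
       f1_defined = f1_den > 0, mcc_defined = mcc_den > 0)
}

#' Structure confusion counts of a predicted consensus
#'
#' Projects predicted and reference consensus column pairs onto every
#' sequence (keeping pairs whose both residues are present) and counts
#' base-pair TP/FP/FN/TN over each sequence's universe of position pairs.
#'
#' @param predicted,reference [saf_msa] objects over the same sequences.
#' @return A list with `tp`, `tn`, `fp`, `fn`.
#' @export
structure_confusion <- function(predicted, reference) {
  ids <- rownames(predicted$alignment)
  stopifnot(setequal(ids, rownames(reference$alignment)))
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (id in ids) {
    pp <- project_structure(predicted, id)
    rp <- project_structure(reference, id)
    nres <- sum(predicted$alignment[id, ] != GAP)
    pk <- paste(pp[, 1], pp[, 2]); rk <- paste(rp[, 1], rp[, 2])
    tp <- tp + sum(pk %in% rk)
    fp <- fp + sum(!pk %in% rk)
    fn <- fn + sum(!rk %in% pk)
    universe <- nres * (nres - 1) / 2
    tn <- tn + universe - length(union(pk, rk))
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

## consensus column pairs of one row as residue-index pairs
project_structure <- function(msa, id) {
  maps <- alignment_maps(msa$alignment)
  r <- which(rownames(msa$alignment) == id)
  if (nrow(msa$pairs) == 0) return(matrix(integer(0), ncol = 2))
  i <- maps[r, msa$pairs[, 1]]; j <- maps[r, msa$pairs[, 2]]
  keep <- !is.na(i) & !is.na(j)
  cbind(i, j)[keep, , drop = FALSE]
}

#' Evaluate a prediction against a reference family
#'
#' @param predicted,reference [saf_msa] objects over the same sequences.
#' @return A list with `sps`, `f1`, `mcc` and the raw confusion counts.
#' @export
evaluate_saf <- function(predicted, reference) {
  cc <- structure_confusion(predicted, reference)
  m <- f1_mcc(cc$tp, cc$tn, cc$fp, cc$fn)
  list(sps = sps(predicted, reference), f1 = m$f1, mcc = m$mcc,
       counts = cc)
}
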