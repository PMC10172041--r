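## Feature counts phi(A) of a pairwise SAF and the linear score s(A; theta).
## The tallies here define the model; the DP engine emits exactly the same
## features edge by edge, and the gradient identity tests keep the two in
## lock step.

feature_index <- function() {
  if (is.null(.pkgenv$fidx)) {
    cat <- saf_catalog()
    .pkgenv$fidx <- setNames(cat$id, cat$descriptor)
  }
  .pkgenv$fidx
}

cap30 <- function(n) pmin(n, 30L)

#' Feature occurrence counts of a pairwise SAF
#'
#' Counts every scoring feature realized by the alignment-and-folding
#' candidate: match emissions (unordered residue pair) and insert emissions
#' per column, state-bigram transitions over the canonical column order
#' (deletions before insertions inside every gapped run), and the per-loop
#' structure features of both sequences (base-pair composition, helix
#' stacking between canonical pairs, hairpin/bulge/internal loop lengths
#' capped at 30, internal asymmetry, multibranch and external loop terms).
#'
#' @param saf A [pairwise_saf].
#' @param x,y The two [rna_seq] objects.
#' @return A named numeric vector over the full catalog.
#' @export
feature_counts <- function(saf, x, y) {
  stopifnot(inherits(saf, "pairwise_saf"))
  if (saf$nx != seq_length(x) || saf$ny != seq_length(y))
    stop("SAF does not fit the given sequences")
  idx <- feature_index()
  phi <- numeric(length(idx))

  cols <- saf_columns(saf)
  ncol_ <- length(cols$state)
  if (ncol_ > 0) {
    for (c in seq_len(ncol_)) {
      if (cols$state[c] == "M") {
        a <- x$res[cols$xi[c]]; b <- y$res[cols$yk[c]]
        d <- paste0("match_", paste(RES_ALPHA[sort(c(a, b))], collapse = ""))
      } else if (cols$state[c] == "D") {
        d <- paste0("insert_", RES_ALPHA[x$res[cols$xi[c]]])
      } else {
        d <- paste0("insert_", RES_ALPHA[y$res[cols$yk[c]]])
      }
      phi[idx[d]] <- phi[idx[d]] + 1
    }
    if (ncol_ > 1) {
      for (c in seq_len(ncol_ - 1)) {
        d <- paste0("trans_", cols$state[c], cols$state[c + 1])
        phi[idx[d]] <- phi[idx[d]] + 1
      }
    }
  }

  phi <- phi + loop_features(saf_structure(saf, "x"), x$res, idx)
  phi <- phi + loop_features(saf_structure(saf, "y"), y$res, idx)
  setNames(phi, names(idx))
}

## per-sequence loop decomposition tally
loop_features <- function(pairs, res, idx) {
  phi <- numeric(length(idx))
  n <- length(res)
  add <- function(d, v = 1) phi[idx[d]] <<- phi[idx[d]] + v
  np <- nrow(pairs)
  if (np > 0) {
    for (r in seq_len(np))
      add(paste0("bp_", RES_ALPHA[res[pairs[r, 1]]], RES_ALPHA[res[pairs[r, 2]]]))
    ## direct children of each pair
    for (r in seq_len(np)) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      inside <- which(pairs[, 1] > i & pairs[, 2] < j)
      ## keep only maximal (not nested in another inside pair)
      direct <- inside[vapply(inside, function(a) {
        !any(pairs[inside, 1] < pairs[a, 1] & pairs[inside, 2] > pairs[a, 2])
      }, logical(1))]
      nb <- length(direct)
      if (nb == 0) {
        add(paste0("hairpin_len_", cap30(j - i - 1)))
      } else if (nb == 1) {
        i2 <- pairs[direct, 1]; j2 <- pairs[direct, 2]
        a <- i2 - i - 1; b <- j - j2 - 1
        if (a == 0 && b == 0) {
          if (is_canonical(res[i], res[j]) && is_canonical(res[i2], res[j2]))
            add(paste0("stack_", RES_ALPHA[res[i]], RES_ALPHA[res[j]], "_",
                       RES_ALPHA[res[i2]], RES_ALPHA[res[j2]]))
        } else if (a == 0 || b == 0) {
          add(paste0("bulge_len_", cap30(a + b)))
        } else {
          add(paste0("internal_len_", cap30(a + b)))
          add(paste0("internal_asym_", cap30(abs(a - b))))
        }
      } else {
        add("multi_base")
        add("multi_branch", nb)
        add("multi_unpaired",
            (j - i - 1) - sum(pairs[direct, 2] - pairs[direct, 1] + 1))
      }
    }
  }
  ## external loop
  if (np > 0) {
    top <- which(vapply(seq_len(np), function(a) {
      !any(pairs[, 1] < pairs[a, 1] & pairs[, 2] > pairs[a, 2])
    }, logical(1)))
    add("external_branch", length(top))
    covered <- sum(pairs[top, 2] - pairs[top, 1] + 1)
    add("external_unpaired", n - covered)
  } else if (n > 0) {
    add("external_unpaired", n)
  }
  phi
}

## stack_XY_ZW naming uses residue characters of the ordered pairs
## (outer 5'->3', inner 5'->3'), matching the catalog descriptors.

#' Linear SAF score
#'
#' `s(A; theta) = theta . phi(A)`.
#'
#' @param saf A [pairwise_saf].
#' @param x,y The two [rna_seq] objects.
#' @param theta A [saf_params] vector.
#' @return A single number.
#' @export
score_saf <- function(saf, x, y, theta) {
  theta <- check_params(theta)
  sum(theta * feature_counts(saf, x, y))
}
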