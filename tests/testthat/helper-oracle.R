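# Independent brute-force oracles: exhaustive enumeration of the pairwise
# SAF ensemble on tiny instances, a from-scratch feature tally, and
# exhaustive gamma-centroid search.  None of this shares code with the
# package's DP paths.

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# all strictly increasing matchings (chains) over candidate match rows;
# returns a list of row-index vectors (including the empty chain)
oracle_matchings <- function(am) {
  n <- nrow(am)
  if (n == 0) return(list(integer(0)))
  ord <- order(am[, 1], am[, 2])
  am <- am[ord, , drop = FALSE]
  out <- list(integer(0))
  grow <- function(chain, last_i, last_k, from) {
    if (from > n) return(invisible(NULL))
    for (r in seq(from, n)) {
      if (am[r, 1] > last_i && am[r, 2] > last_k) {
        nc <- c(chain, r)
        out[[length(out) + 1]] <<- nc
        grow(nc, am[r, 1], am[r, 2], r + 1)
      }
    }
  }
  grow(integer(0), 0L, 0L, 1L)
  lapply(out, function(rows) ord[rows])
}

# valid subsets of candidate quadruples given a matching (rows of am):
# endpoints matched, no shared positions, no crossing, and every innermost
# pair leaves a hairpin loop of length >= 3 on both sides
oracle_quadsets <- function(match_rows, am, quads, min_hairpin = 3) {
  if (nrow(quads) == 0) return(list(integer(0)))
  mkey <- paste(am[match_rows, 1], am[match_rows, 2])
  ok <- vapply(seq_len(nrow(quads)), function(r) {
    paste(quads[r, 1], quads[r, 3]) %in% mkey &&
      paste(quads[r, 2], quads[r, 4]) %in% mkey
  }, logical(1))
  cand <- which(ok)
  sets <- list(integer(0))
  if (length(cand) > 0) {
    for (size in seq_along(cand)) {
      for (comb in combn_list(cand, size)) {
        if (quadset_valid(quads[comb, , drop = FALSE], min_hairpin))
          sets[[length(sets) + 1]] <- comb
      }
    }
  }
  sets
}

combn_list <- function(v, k) {
  if (k > length(v)) return(list())
  if (length(v) == 1) return(if (k == 1) list(v) else list())
  m <- combn(v, k)
  lapply(seq_len(ncol(m)), function(c) m[, c])
}

quadset_valid <- function(q, min_hairpin) {
  for (side in list(c(1, 2), c(3, 4))) {
    p <- q[, side, drop = FALSE]
    if (anyDuplicated(c(p))) return(FALSE)
    if (nrow(p) > 1) {
      for (a in seq_len(nrow(p) - 1)) for (b in seq(a + 1, nrow(p))) {
        i <- p[a, 1]; j <- p[a, 2]; k <- p[b, 1]; l <- p[b, 2]
        nested <- (i < k && l < j) || (k < i && j < l)
        disjoint <- j < k || l < i
        if (!nested && !disjoint) return(FALSE)
      }
    }
    for (a in seq_len(nrow(p))) {
      inner <- p[, 1] > p[a, 1] & p[, 2] < p[a, 2]
      if (!any(inner) && p[a, 2] - p[a, 1] - 1 < min_hairpin) return(FALSE)
    }
  }
  TRUE
}

# from-scratch feature tally of one SAF candidate (independent of
# feature_counts): builds the canonical column strings explicitly and
# decomposes each structure by parent-finding
oracle_phi <- function(xres, yres, match, quad) {
  cat <- centrifold::saf_catalog()
  phi <- setNames(numeric(nrow(cat)), cat$descriptor)
  bump <- function(d, v = 1) phi[d] <<- phi[d] + v
  A <- c("A", "C", "G", "U")

  states <- character(0)
  px <- 0; py <- 0
  emit_cols <- function(xt, yt) {
    if (xt > px) for (p in seq(px + 1, xt)) {
      states <<- c(states, "D"); bump(paste0("insert_", A[xres[p]]))
    }
    if (yt > py) for (p in seq(py + 1, yt)) {
      states <<- c(states, "I"); bump(paste0("insert_", A[yres[p]]))
    }
    px <<- xt; py <<- yt
  }
  if (nrow(match) > 0) for (r in seq_len(nrow(match))) {
    emit_cols(match[r, 1] - 1, match[r, 2] - 1)
    states <- c(states, "M")
    pair <- sort(c(A[xres[match[r, 1]]], A[yres[match[r, 2]]]))
    bump(paste0("match_", pair[1], pair[2]))
    px <- match[r, 1]; py <- match[r, 2]
  }
  emit_cols(length(xres), length(yres))
  if (length(states) > 1)
    for (c in seq_len(length(states) - 1))
      bump(paste0("trans_", states[c], states[c + 1]))

  phi <- phi + oracle_structure_phi(quad[, c(1, 2), drop = FALSE], xres)
  phi + oracle_structure_phi(quad[, c(3, 4), drop = FALSE], yres)
}

# structure-only feature tally of one sequence (parent-finding loop
# decomposition, independent of the package's loop_features)
oracle_structure_phi <- function(pairs, res) {
  cat <- centrifold::saf_catalog()
  phi <- setNames(numeric(nrow(cat)), cat$descriptor)
  bump <- function(d, v = 1) phi[d] <<- phi[d] + v
  A <- c("A", "C", "G", "U")
  canon <- c(AU = TRUE, CG = TRUE, GC = TRUE, GU = TRUE, UA = TRUE, UG = TRUE)
  n <- length(res)
  np <- nrow(pairs)
  if (np == 0) { if (n > 0) bump("external_unpaired", n); return(phi) }
  for (r in seq_len(np))
    bump(paste0("bp_", A[res[pairs[r, 1]]], A[res[pairs[r, 2]]]))
  # parent of each pair: smallest enclosing pair
  parent <- rep(0L, np)
  for (r in seq_len(np)) {
    enc <- which(pairs[, 1] < pairs[r, 1] & pairs[, 2] > pairs[r, 2])
    if (length(enc) > 0) parent[r] <- enc[which.min(pairs[enc, 2] - pairs[enc, 1])]
  }
  for (r in seq_len(np)) {
    kids <- which(parent == r)
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (length(kids) == 0) {
      bump(paste0("hairpin_len_", min(j - i - 1, 30)))
    } else if (length(kids) == 1) {
      i2 <- pairs[kids, 1]; j2 <- pairs[kids, 2]
      a <- i2 - i - 1; b <- j - j2 - 1
      if (a == 0 && b == 0) {
        po <- paste0(A[res[i]], A[res[j]]); pi2 <- paste0(A[res[i2]], A[res[j2]])
        if (isTRUE(canon[po]) && isTRUE(canon[pi2]))
          bump(paste0("stack_", po, "_", pi2))
      } else if (a == 0 || b == 0) bump(paste0("bulge_len_", min(a + b, 30)))
      else {
        bump(paste0("internal_len_", min(a + b, 30)))
        bump(paste0("internal_asym_", min(abs(a - b), 30)))
      }
    } else {
      bump("multi_base")
      bump("multi_branch", length(kids))
      bump("multi_unpaired",
           (j - i - 1) - sum(pairs[kids, 2] - pairs[kids, 1] + 1))
    }
  }
  top <- which(parent == 0L)
  bump("external_branch", length(top))
  bump("external_unpaired", n - sum(pairs[top, 2] - pairs[top, 1] + 1))
  phi
}

# enumerate all valid structures over allowed pairs of one sequence and
# return the exact pair marginals under the structure features
oracle_ss <- function(res, pairs, theta, min_hairpin = 3, max_loop = 30) {
  sets <- list(integer(0))
  np <- nrow(pairs)
  if (np > 0) {
    for (size in seq_len(np)) {
      for (comb in combn_list(seq_len(np), size)) {
        q <- cbind(pairs[comb, , drop = FALSE], pairs[comb, , drop = FALSE])
        if (quadset_valid(q, min_hairpin) &&
            ss_loop_ok(pairs[comb, , drop = FALSE], max_loop))
          sets[[length(sets) + 1]] <- comb
      }
    }
  }
  scores <- vapply(sets, function(s) {
    sum(as.numeric(theta) *
          oracle_structure_phi(pairs[s, , drop = FALSE], res))
  }, 0)
  logz <- logsumexp(scores)
  p <- exp(scores - logz)
  pp <- numeric(np)
  for (ci in seq_along(sets)) pp[sets[[ci]]] <- pp[sets[[ci]]] + p[ci]
  list(logz = logz, pp = pp)
}

# the single-sequence nominator skips one-branch loops whose total
# unpaired length exceeds max_loop
ss_loop_ok <- function(pairs, max_loop) {
  np <- nrow(pairs)
  if (np < 2) return(TRUE)
  parent <- rep(0L, np)
  for (r in seq_len(np)) {
    enc <- which(pairs[, 1] < pairs[r, 1] & pairs[, 2] > pairs[r, 2])
    if (length(enc) > 0) parent[r] <- enc[which.min(pairs[enc, 2] - pairs[enc, 1])]
  }
  for (r in seq_len(np)) {
    kids <- which(parent == r)
    if (length(kids) == 1) {
      a <- pairs[kids, 1] - pairs[r, 1] - 1
      b <- pairs[r, 2] - pairs[kids, 2] - 1
      if (a + b > max_loop) return(FALSE)
    }
  }
  TRUE
}

# derive the consistent quadruple set exactly as the candidate contract
# states: all combinations of allowed pairs whose endpoint matches are
# allowed
oracle_quads <- function(am, px, py) {
  out <- matrix(integer(0), ncol = 4)
  mkey <- paste(am[, 1], am[, 2])
  if (nrow(px) > 0 && nrow(py) > 0) {
    for (a in seq_len(nrow(px))) for (b in seq_len(nrow(py))) {
      q <- c(px[a, 1], px[a, 2], py[b, 1], py[b, 2])
      if (paste(q[1], q[3]) %in% mkey && paste(q[2], q[4]) %in% mkey)
        out <- rbind(out, q)
    }
  }
  out
}

# full ensemble enumeration: every candidate with its score, plus the
# quantities the inside-outside algorithm is supposed to produce
oracle_ensemble <- function(x, y, theta, cands) {
  am <- cands$am
  quads <- oracle_quads(am, cands$px, cands$py)
  scores <- numeric(0)
  members <- list()
  for (mr in oracle_matchings(am)) {
    m <- am[mr, , drop = FALSE]
    for (qs in oracle_quadsets(mr, am, quads, cands$min_hairpin)) {
      q <- quads[qs, , drop = FALSE]
      phi <- oracle_phi(x$res, y$res, m, q)
      scores <- c(scores, sum(as.numeric(theta) * phi))
      members[[length(members) + 1]] <- list(mrows = mr, qrows = qs, phi = phi)
    }
  }
  logz <- logsumexp(scores)
  p <- exp(scores - logz)
  pm <- numeric(nrow(am))
  pq <- numeric(nrow(quads))
  ec <- numeric(length(saf_catalog()$descriptor))
  for (ci in seq_along(members)) {
    pm[members[[ci]]$mrows] <- pm[members[[ci]]$mrows] + p[ci]
    pq[members[[ci]]$qrows] <- pq[members[[ci]]$qrows] + p[ci]
    ec <- ec + p[ci] * members[[ci]]$phi
  }
  list(logz = logz, pm = pm, quads = quads, pq = pq, ecounts = ec,
       n_candidates = length(scores))
}

# exhaustive maximization of the gamma-centroid objective.  Under pruning,
# base pairs must pass the 1/gp threshold, and a match below the 1/gm
# threshold may appear only as the endpoint of a chosen quadruple (the
# unpaired-match recursion case is what the match threshold gates).
oracle_best_objective <- function(pm, px, py, gm, gp, prune = TRUE,
                                  min_hairpin = 3) {
  n <- nrow(pm); m <- ncol(pm)
  pxk <- which(upper.tri(px) & (if (prune) px >= 1 / gp else TRUE), arr.ind = TRUE)
  pxk <- pxk[pxk[, 2] - pxk[, 1] - 1 >= min_hairpin, , drop = FALSE]
  pyk <- which(upper.tri(py) & (if (prune) py >= 1 / gp else TRUE), arr.ind = TRUE)
  pyk <- pyk[pyk[, 2] - pyk[, 1] - 1 >= min_hairpin, , drop = FALSE]
  elig <- if (prune) pm >= 1 / gm else matrix(TRUE, n, m)
  # candidate matches: threshold-eligible ones plus all quadruple endpoints
  endpoint <- matrix(FALSE, n, m)
  if (nrow(pxk) > 0 && nrow(pyk) > 0) {
    for (a in seq_len(nrow(pxk))) for (b in seq_len(nrow(pyk))) {
      endpoint[pxk[a, 1], pyk[b, 1]] <- TRUE
      endpoint[pxk[a, 2], pyk[b, 2]] <- TRUE
    }
  }
  am <- which(elig | endpoint, arr.ind = TRUE)
  quads <- oracle_quads(am, pxk, pyk)
  best <- 0   # the empty SAF is always feasible
  for (mr in oracle_matchings(am)) {
    mmat <- am[mr, , drop = FALSE]
    base <- if (nrow(mmat) > 0) sum(gm * pm[mmat] - 1) else 0
    for (qs in oracle_quadsets(mr, am, quads, min_hairpin)) {
      q <- quads[qs, , drop = FALSE]
      if (prune && nrow(mmat) > 0) {
        # ineligible matches must all be endpoints of chosen quadruples
        qkey <- character(0)
        if (nrow(q) > 0)
          qkey <- c(paste(q[, 1], q[, 3]), paste(q[, 2], q[, 4]))
        bad <- !elig[mmat]
        if (any(bad & !(paste(mmat[, 1], mmat[, 2]) %in% qkey))) next
      }
      v <- base
      if (nrow(q) > 0)
        v <- v + sum(gp * (px[q[, c(1, 2), drop = FALSE]] +
                           py[q[, c(3, 4), drop = FALSE]]) - 2)
      if (v > best) best <- v
    }
  }
  best
}
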