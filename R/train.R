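## Gradient-based training of the SAF scoring parameters: convex pair-CLLM
## cost over two-sequence alignment-and-folding examples, adaptive grouped
## L2 regularization, BFGS inner solves inside a majorization-minimization
## outer loop.

#' Construct a training example
#'
#' @param x,y [rna_seq] objects.
#' @param saf The reference [pairwise_saf] for the pair.
#' @return An object of class `training_example`.
#' @export
training_example <- function(x, y, saf) {
  stopifnot(inherits(saf, "pairwise_saf"),
            saf$nx == seq_length(x), saf$ny == seq_length(y))
  structure(list(x = x, y = y, saf = saf), class = "training_example")
}

#' Read a two-sequence Stockholm record as a training example
#'
#' The `#=GC SS_cons` line gives the matched base-pair quadruples: a
#' consensus column pair becomes a quadruple when all four residues are
#' present (no base-pairing indels).
#'
#' @param path Stockholm file with exactly two rows.
#' @return A [training_example].
#' @export
read_training_example <- function(path) {
  rec <- read_stockholm(path)
  aln <- rec$alignment
  if (nrow(aln) != 2) stop("training example must hold exactly two sequences")
  x <- degap_row(aln, rownames(aln)[1])
  y <- degap_row(aln, rownames(aln)[2])
  training_example(x, y, project_pair(aln, 1L, 2L,
                                      rec$structure %||% matrix(integer(0), ncol = 2)))
}

## induced pairwise SAF of rows (a, b) of an alignment with consensus
## column pairs; pair events where any of the four residues is gapped are
## dropped (no base-pairing indels)
project_pair <- function(aln, a, b, col_pairs, min_hairpin = 3L) {
  maps <- alignment_maps(aln)
  ev <- alignment_pair_events(aln, a, b, maps)
  quad <- matrix(integer(0), ncol = 4)
  if (nrow(col_pairs) > 0) {
    qi <- maps[a, col_pairs[, 1]]; qj <- maps[a, col_pairs[, 2]]
    qk <- maps[b, col_pairs[, 1]]; ql <- maps[b, col_pairs[, 2]]
    keep <- !is.na(qi) & !is.na(qj) & !is.na(qk) & !is.na(ql)
    quad <- cbind(qi, qj, qk, ql)[keep, , drop = FALSE]
  }
  pairwise_saf(ev$match, quad, sum(!is.na(maps[a, ])), sum(!is.na(maps[b, ])),
               min_hairpin = min_hairpin)
}

#' Training configuration
#'
#' @param alpha,beta Gamma-prior parameters of the adaptive regularization.
#' @param tol Relative change of the regularized cost that stops the outer
#'   loop.
#' @param max_epochs Maximum outer (majorization-minimization) epochs.
#' @param inner_maxit Maximum BFGS iterations per epoch.
#' @param rebuild_every Candidate sets are rebuilt from the current theta
#'   every this many epochs (reference events always force-included).
#' @param epsilon_match,epsilon_pair Candidate thresholds.
#' @param max_match_keep,max_pair_keep Per-position candidate caps.
#' @param max_pair_total Total candidate base-pair cap per sequence.
#' @param min_hairpin Minimum hairpin loop length.
#' @return A list of class `train_config`.
#' @export
train_config <- function(alpha = 0, beta = 1, tol = 1e-4, max_epochs = 200L,
                         inner_maxit = 100L, rebuild_every = 5L,
                         epsilon_match = 0.01, epsilon_pair = 0.01,
                         max_match_keep = 8L, max_pair_keep = 4L,
                         max_pair_total = 24L, min_hairpin = 3L) {
  stopifnot(alpha >= 0, beta > 0)
  structure(as.list(environment()), class = "train_config")
}

build_all_candidates <- function(examples, theta, config) {
  lapply(examples, function(ex)
    build_candidates(ex$x, ex$y, theta,
                     epsilon_match = config$epsilon_match,
                     epsilon_pair = config$epsilon_pair,
                     forced = ex$saf,
                     max_match_keep = config$max_match_keep,
                     max_pair_keep = config$max_pair_keep,
                     max_pair_total = config$max_pair_total,
                     min_hairpin = config$min_hairpin))
}

#' Pair-CLLM cost and gradient over a training dataset
#'
#' `cost = sum_d [log Z^S_d(theta) - s(A_d; theta)]`, each summand
#' non-negative because the reference example is force-included in its
#' sparse ensemble; the gradient is
#' `sum_d (E^S_d[phi] - phi(A_d))`.
#'
#' @param examples List of [training_example].
#' @param theta [saf_params].
#' @param cands Candidate sets (one per example) built with force
#'   inclusion; computed from `config` when `NULL`.
#' @param config A [train_config].
#' @return `saf_cost` returns the scalar cost; `saf_gradient` the gradient
#'   vector over the catalog.
#' @export
saf_cost <- function(examples, theta, cands = NULL, config = train_config()) {
  ev <- dataset_eval(examples, theta, cands, config, want_grad = FALSE)
  ev$cost
}

#' @rdname saf_cost
#' @export
saf_gradient <- function(examples, theta, cands = NULL,
                         config = train_config()) {
  ev <- dataset_eval(examples, theta, cands, config, want_grad = TRUE)
  ev$grad
}

dataset_eval <- function(examples, theta, cands, config, want_grad) {
  theta_num <- check_params(theta)
  if (is.null(cands)) cands <- build_all_candidates(examples, theta, config)
  phis <- lapply(examples, function(ex) feature_counts(ex$saf, ex$x, ex$y))
  cost <- 0
  grad <- numeric(length(theta_num))
  for (d in seq_along(examples)) {
    ex <- examples[[d]]
    res <- saf_engine(ex$x, ex$y, theta_num, cands[[d]],
                      want_counts = want_grad)
    s_d <- sum(theta_num * phis[[d]])
    cost <- cost + res$logz - s_d
    if (want_grad) grad <- grad + res$ecounts - phis[[d]]
  }
  list(cost = cost, grad = grad)
}

#' Adaptive grouped regularization constants
#'
#' The closed-form update
#' `lambda_g = (|G|/2 + alpha) / (beta + 0.5 * sum_{f in G} theta_f^2)`
#' shared by all features of a group.
#'
#' @param theta [saf_params] (or plain numeric over the catalog).
#' @param alpha,beta Gamma-prior parameters (`alpha >= 0`, `beta > 0`).
#' @param groups Group label per feature; defaults to the catalog groups.
#' @return Per-feature vector of regularization constants.
#' @export
lambda_update <- function(theta, alpha = 0, beta = 1, groups = NULL) {
  if (beta <= 0) stop("beta must be positive")
  if (alpha < 0) stop("alpha must be non-negative")
  if (is.null(groups)) groups <- saf_catalog()$group
  theta <- as.numeric(theta)
  stopifnot(length(groups) == length(theta))
  lam_g <- tapply(theta, groups, function(v) {
    (length(v) / 2 + alpha) / (beta + 0.5 * sum(v^2))
  })
  as.numeric(lam_g[groups])
}

#' @rdname saf_cost
#' @param lambda Per-feature regularization constants.
#' @export
regularized_cost <- function(examples, theta, lambda, cands = NULL,
                             config = train_config()) {
  saf_cost(examples, theta, cands, config) +
    0.5 * sum(lambda * as.numeric(theta)^2)
}

## the profiled (marginal-MAP) objective that the MM iteration provably
## decreases: cS + sum_g (|G|/2 + alpha) log(beta + 0.5 sum theta^2)
mm_objective <- function(cost_s, theta, alpha, beta, groups) {
  ss <- tapply(as.numeric(theta), groups, function(v) sum(v^2))
  ng <- tapply(groups, groups, length)
  cost_s + sum((ng / 2 + alpha) * log(beta + 0.5 * ss))
}

#' Fit SAF scoring parameters
#'
#' Alternates (a) the closed-form lambda refresh and (b) a BFGS
#' minimization of the regularized cost at fixed lambda, until the
#' relative change of the regularized objective drops below `tol` or
#' `max_epochs` is reached.  Candidate sets are rebuilt from the current
#' theta every `rebuild_every` epochs, always force-including the
#' reference events.
#'
#' @param examples List of [training_example].
#' @param init Initial [saf_params] (e.g. [init_transfer()] or
#'   [init_random()]).
#' @param config A [train_config].
#' @param verbose Print one line per epoch.
#' @return A list of class `saf_fit`: `theta` (fitted [saf_params]),
#'   `trace` (per-epoch data frame with the sparse cost, the regularized
#'   objective and the gradient norm), `epochs`, `converged`.
#' @export
fit_saf <- function(examples, init, config = train_config(), verbose = FALSE) {
  stopifnot(length(examples) > 0)
  groups <- saf_catalog()$group
  theta <- check_params(init)
  cands <- build_all_candidates(examples, saf_params(theta), config)
  phis <- lapply(examples, function(ex) feature_counts(ex$saf, ex$x, ex$y))

  eval_ds <- function(th, want_grad) {
    cost <- 0; grad <- numeric(length(th))
    for (d in seq_along(examples)) {
      res <- saf_engine(examples[[d]]$x, examples[[d]]$y, th, cands[[d]],
                        want_counts = want_grad)
      cost <- cost + res$logz - sum(th * phis[[d]])
      if (want_grad) grad <- grad + res$ecounts - phis[[d]]
    }
    list(cost = cost, grad = grad)
  }
  ## the line search probes many points with fn only: give those the
  ## cheaper inside-only sweep, and cache the full inside-outside pass
  ## for points where BFGS also requests the gradient
  cache <- new.env(parent = emptyenv())
  cost_cached <- function(th) {
    if (!is.null(cache$th) && identical(cache$th, th)) return(cache$val$cost)
    eval_ds(th, want_grad = FALSE)$cost
  }
  eval_cached <- function(th) {
    if (!is.null(cache$th) && identical(cache$th, th)) return(cache$val)
    val <- eval_ds(th, want_grad = TRUE)
    cache$th <- th; cache$val <- val
    val
  }

  trace <- data.frame(epoch = integer(0), cost_s = numeric(0),
                      cost_reg = numeric(0), grad_norm = numeric(0),
                      rebuilt = logical(0))
  prev_obj <- Inf
  converged <- FALSE
  epochs <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    rebuilt <- epoch > 1 && (epoch - 1) %% config$rebuild_every == 0
    if (rebuilt) {
      ## the sparse ensemble (and with it the objective) is refreshed, so
      ## cost comparisons across this boundary are not meaningful
      cands <- build_all_candidates(examples, saf_params(theta), config)
      cache$th <- NULL
    }
    lambda <- lambda_update(theta, config$alpha, config$beta, groups)
    fn <- function(th) cost_cached(th) + 0.5 * sum(lambda * th^2)
    gr <- function(th) eval_cached(th)$grad + lambda * th
    opt <- optim(theta, fn, gr, method = "BFGS",
                 control = list(maxit = config$inner_maxit, reltol = 1e-10))
    if (!is.finite(opt$value))
      stop("training diverged: non-finite regularized cost")
    theta <- opt$par
    ds <- eval_cached(theta)
    obj <- mm_objective(ds$cost, theta, config$alpha, config$beta, groups)
    trace <- rbind(trace, data.frame(
      epoch = epoch, cost_s = ds$cost, cost_reg = obj,
      grad_norm = sqrt(sum((ds$grad + lambda * theta)^2)),
      rebuilt = rebuilt))
    if (verbose)
      message(sprintf("epoch %3d  cS %.4f  reg %.4f", epoch, ds$cost, obj))
    epochs <- epoch
    if (is.finite(prev_obj) &&
        abs(prev_obj - obj) / max(1, abs(prev_obj)) < config$tol) {
      converged <- TRUE
      break
    }
    prev_obj <- obj
  }
  structure(list(theta = saf_params(theta), trace = trace, epochs = epochs,
                 converged = converged, config = config),
            class = "saf_fit")
}

#' @export
print.saf_fit <- function(x, ...) {
  cat("SAF fit: ", x$epochs, " epochs, ",
      if (x$converged) "converged" else "epoch limit reached", "\n", sep = "")
  cat("  final sparse cost ", format(tail(x$trace$cost_s, 1), digits = 6),
      ", regularized objective ",
      format(tail(x$trace$cost_reg, 1), digits = 6), "\n", sep = "")
  invisible(x)
}
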