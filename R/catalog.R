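#' The SAF feature catalog
#'
#' Enumerates the features of the scoring vector theta: match emissions over
#' unordered residue pairs, insert emissions shared by insertions and
#' deletions, alignment state-bigram transitions, ordered base-pair
#' compositions, canonical/wobble helix stackings, capped loop-length bins
#' (hairpin, bulge, internal, internal asymmetry), and the multibranch and
#' external loop terms.  Every feature belongs to exactly one regularization
#' group.  The enumeration is fixed for a catalog version so that serialized
#' parameter vectors remain comparable.
#'
#' @return A data frame with columns `id` (1-based feature index),
#'   `descriptor` (stable feature name) and `group` (regularization group
#'   label).
#' @export
#' @examples
#' cat <- saf_catalog()
#' nrow(cat)              # number of features F
#' table(cat$group)
saf_catalog <- function() {
  if (is.null(.pkgenv$catalog)) {
    raw <- cpp_catalog()
    .pkgenv$catalog <- data.frame(
      id = seq_along(raw$descriptor),
      descriptor = raw$descriptor,
      group = raw$group,
      stringsAsFactors = FALSE
    )
  }
  .pkgenv$catalog
}

CATALOG_VERSION <- "centrifold-1"

## groups copied by parameter transplantation (the sequence-alignment part
## of the model, shared between the two ensemble members)
ALIGNMENT_GROUPS <- c("match-emission", "insert-emission", "align-transition")

#' Construct a SAF parameter vector
#'
#' @param values A single number recycled over all features, or a numeric
#'   vector of length `nrow(saf_catalog())`, or a named vector/list keyed by
#'   feature descriptor (unnamed features are set to 0).
#' @return A numeric vector of class `saf_params`, named by feature
#'   descriptor.
#' @export
saf_params <- function(values = 0) {
  cat <- saf_catalog()
  out <- numeric(nrow(cat))
  names(out) <- cat$descriptor
  if (!is.null(names(values)) || is.list(values)) {
    values <- unlist(values)
    unknown <- setdiff(names(values), cat$descriptor)
    if (length(unknown) > 0)
      stop("unknown feature descriptor(s): ", paste(unknown, collapse = ", "))
    out[names(values)] <- values
  } else if (length(values) == 1L) {
    out[] <- values
  } else if (length(values) == nrow(cat)) {
    out[] <- values
  } else {
    stop("values must have length 1, F, or be named by descriptor")
  }
  if (any(!is.finite(out))) stop("parameter values must be finite")
  structure(out, class = "saf_params", version = CATALOG_VERSION)
}

#' @export
print.saf_params <- function(x, ...) {
  cat("SAF parameter vector (", length(x), " features, catalog ",
      attr(x, "version"), ")\n", sep = "")
  nz <- sum(x != 0)
  cat("  non-zero: ", nz, ", L2 norm: ", format(sqrt(sum(x^2)), digits = 4),
      "\n", sep = "")
  invisible(x)
}

check_params <- function(theta) {
  cat <- saf_catalog()
  if (length(theta) != nrow(cat)) stop("parameter vector has wrong length")
  as.numeric(theta)
}

#' Random initialization of SAF parameters
#'
#' Draws every feature value independently from a normal distribution with
#' mean 0 and variance 1/F, where F is the catalog size.
#'
#' @param seed Integer seed; the draw is reproducible and does not disturb
#'   the caller's RNG state.
#' @return A `saf_params` vector.
#' @export
init_random <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  f <- nrow(saf_catalog())
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  saf_params(rnorm(f, mean = 0, sd = sqrt(1 / f)))
}

#' Transfer initialization of SAF parameters
#'
#' Initializes trainable parameters from a packaged table of reference
#' values (the transfer-learning starting point).  Features named in the
#' table receive its value; features without a counterpart start at 0.
#'
#' @param path Path to a parameter JSON file; defaults to the packaged
#'   transfer table.
#' @return A `saf_params` vector.
#' @export
init_transfer <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "transfer_params_synthetic.json",
                        package = "centrifold")
  if (!nzchar(path) || !file.exists(path)) stop("transfer table not found")
  read_params(path)
}

#' Read / write parameter vectors as JSON
#'
#' Serialization is a flat descriptor-to-value map plus the catalog version
#' string, so files remain readable when feature order is irrelevant.
#'
#' @param path File path.
#' @return `read_params` returns a `saf_params` vector.
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$version, CATALOG_VERSION))
    stop("parameter file has catalog version '", obj$version,
         "', expected '", CATALOG_VERSION, "'")
  saf_params(obj$values)
}

#' @rdname read_params
#' @param theta A `saf_params` vector.
#' @export
write_params <- function(theta, path) {
  theta <- saf_params(theta)
  obj <- list(version = CATALOG_VERSION, values = as.list(unclass(theta)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Transplant sequence-alignment parameters between models
#'
#' Copies the features of the alignment groups (match emissions, insert
#' emissions, alignment transitions) from `src` into `dst`, leaving every
#' structure feature of `dst` untouched.  Used before ensembling so that the
#' two scoring models share their sequence-alignment component.
#'
#' @param dst,src `saf_params` vectors over the same catalog.
#' @return The modified copy of `dst`.
#' @export
transplant_alignment_params <- function(dst, src) {
  if (!identical(attr(dst, "version"), attr(src, "version")))
    stop("parameter vectors use different catalogs")
  cat <- saf_catalog()
  sel <- cat$group %in% ALIGNMENT_GROUPS
  dst[sel] <- src[sel]
  dst
}

#' The packaged partner scoring model
#'
#' A second, independently trained parameter vector over the same catalog,
#' used as the other member of the two-model probability ensemble.
#'
#' @return A `saf_params` vector.
#' @export
partner_params <- function() {
  path <- system.file("extdata", "partner_params_synthetic.json",
                      package = "centrifold")
  if (!nzchar(path)) stop("partner parameter table not found")
  read_params(path)
}
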