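## Data model and I/O: sequences, alignments, secondary structures, and the
## pairwise / multiple SAF containers.  Coordinates are 1-based inclusive
## everywhere; gap characters {-, ., _} normalize to "-" on input.

#' Construct an RNA sequence
#'
#' Residues are normalized (T to U, case folded) and stored as integer codes
#' 1..4 = A,C,G,U.
#'
#' @param id Sequence identifier.
#' @param seq A string over the (possibly lowercase, possibly DNA) alphabet.
#' @return An object of class `rna_seq` with fields `id` and `res`.
#' @export
rna_seq <- function(id, seq) {
  chars <- normalize_residues(strsplit(seq, "")[[1]], what = id)
  structure(list(id = as.character(id), res = chars), class = "rna_seq")
}

normalize_residues <- function(chars, what = "sequence") {
  chars <- toupper(chars)
  chars[chars == "T"] <- "U"
  codes <- match(chars, RES_ALPHA)
  if (anyNA(codes)) {
    pos <- which(is.na(codes))[1]
    stop("invalid residue '", chars[pos], "' at position ", pos,
         " in record '", what, "'")
  }
  codes
}

#' @export
print.rna_seq <- function(x, ...) {
  cat(">", x$id, " (", length(x$res), " nt)\n",
    paste(RES_ALPHA[x$res], collapse = ""), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.rna_seq <- function(x, ...) paste(RES_ALPHA[x$res], collapse = "")

seq_length <- function(x) length(x$res)

#' Read RNA sequences from FASTA
#'
#' Thin wrapper around [Biostrings::readBStringSet()] with the package's
#' residue normalization (T to U, case folding); any character outside
#' A,C,G,U,T after normalization is a format error naming the record and
#' position.
#'
#' @param path Path to a FASTA file, or a literal FASTA string containing a
#'   newline.
#' @return A list of [rna_seq] objects.
#' @export
read_fasta <- function(path) {
  if (grepl("\n", path)) {
    tmp <- tempfile(fileext = ".fa")
    on.exit(unlink(tmp))
    writeLines(path, tmp)
    path <- tmp
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no FASTA records found")
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    s <- as.character(set[[i]])
    if (nchar(s) == 0) stop("empty FASTA record '", names(set)[i], "'")
    out[[i]] <- rna_seq(names(set)[i], s)
  }
  out
}

#' Write sequences to FASTA
#' @param seqs List of [rna_seq].
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  lines <- unlist(lapply(seqs, function(s) c(paste0(">", s$id), as.character(s))))
  writeLines(lines, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## secondary structures
## ---------------------------------------------------------------------------

DB_UNPAIRED <- c(".", "-", "_", ",", ":")

#' Parse a dot-bracket secondary structure
#'
#' Accepts the WUSS subset with `()` pairs; `.`, `-`, `_`, `,`, `:` are
#' unpaired.  Letters and extra bracket types (pseudoknot annotation) are
#' rejected, as is any unbalanced string.
#'
#' @param text A dot-bracket string.
#' @return An integer matrix with columns `i`, `j` (1-based, `i < j`), one
#'   row per base pair, sorted by `i`.
#' @export
parse_dotbracket <- function(text) {
  chars <- strsplit(text, "")[[1]]
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  rows <- list()
  for (p in seq_along(chars)) {
    ch <- chars[p]
    if (ch == "(") {
      stack <- c(stack, p)
    } else if (ch == ")") {
      if (length(stack) == 0)
        stop("unbalanced ')' at position ", p)
      rows[[length(rows) + 1]] <- c(stack[length(stack)], p)
      stack <- stack[-length(stack)]
    } else if (!ch %in% DB_UNPAIRED) {
      stop("unsupported structure character '", ch, "' at position ", p)
    }
  }
  if (length(stack) > 0) stop("unbalanced '(' at position ", stack[1])
  if (length(rows) > 0) {
    pairs <- do.call(rbind, rows)
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    colnames(pairs) <- c("i", "j")
  }
  pairs
}

#' @rdname parse_dotbracket
#' @param pairs A pair matrix as returned by `parse_dotbracket`.
#' @param n Structure length.
#' @return `render_dotbracket` returns the dot-bracket string.
#' @export
render_dotbracket <- function(pairs, n) {
  out <- rep(".", n)
  if (nrow(pairs) > 0) {
    out[pairs[, 1]] <- "("
    out[pairs[, 2]] <- ")"
  }
  paste(out, collapse = "")
}

## structure sanity: disjoint positions, no crossing, optional hairpin span
validate_structure <- function(pairs, n, min_hairpin = 0L) {
  if (nrow(pairs) == 0) return(invisible(TRUE))
  if (any(pairs < 1) || any(pairs > n)) stop("pair index out of range")
  if (any(pairs[, 1] >= pairs[, 2])) stop("pairs must satisfy i < j")
  pos <- c(pairs[, 1], pairs[, 2])
  if (anyDuplicated(pos)) stop("a position takes part in two base pairs")
  if (any(pairs[, 2] - pairs[, 1] - 1 < min_hairpin))
    stop("hairpin span below ", min_hairpin)
  if (nrow(pairs) > 1) {
    for (a in seq_len(nrow(pairs) - 1)) {
      for (b in seq(a + 1, nrow(pairs))) {
        i <- pairs[a, 1]; j <- pairs[a, 2]
        k <- pairs[b, 1]; l <- pairs[b, 2]
        nested <- (i < k && l < j) || (k < i && j < l)
        disjoint <- j < k || l < i
        if (!nested && !disjoint) stop("crossing base pairs (pseudoknot)")
      }
    }
  }
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## alignments
## ---------------------------------------------------------------------------

#' Construct an alignment from gapped strings
#'
#' @param rows Named character vector of equal-length gapped strings; gap
#'   characters `-`, `.`, `_` are accepted and normalized to `-`.
#' @return A character matrix of class `rna_alignment` (rows = sequences),
#'   entries in A,C,G,U or `-`.
#' @export
rna_alignment <- function(rows) {
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("alignment rows must be named")
  lens <- nchar(rows)
  if (length(unique(lens)) != 1) stop("alignment rows have unequal lengths")
  mat <- do.call(rbind, strsplit(rows, ""))
  rownames(mat) <- names(rows)
  mat <- toupper(mat)
  mat[mat == "T"] <- "U"
  mat[mat %in% c(".", "_")] <- GAP
  bad <- !(mat %in% c(RES_ALPHA, GAP))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("invalid alignment character in row '", rownames(mat)[w[1]],
         "' column ", w[2])
  }
  if (ncol(mat) > 0 && any(colSums(mat != GAP) == 0))
    stop("alignment contains an all-gap column")
  structure(mat, class = "rna_alignment")
}

#' @export
print.rna_alignment <- function(x, ...) {
  cat("RNA alignment: ", nrow(x), " sequences x ", ncol(x), " columns\n",
      sep = "")
  for (r in rownames(x))
    cat(sprintf("  %-12s %s\n", r, paste(x[r, ], collapse = "")))
  invisible(x)
}

#' Remove gaps from one alignment row
#' @param aln An `rna_alignment`.
#' @param id Row name.
#' @return An [rna_seq].
#' @export
degap_row <- function(aln, id) {
  chars <- aln[id, ]
  rna_seq(id, paste(chars[chars != GAP], collapse = ""))
}

## map: for each row, column index -> residue index (NA at gaps)
alignment_maps <- function(aln) {
  ng <- unclass(aln) != GAP
  out <- matrix(NA_integer_, nrow(ng), ncol(ng), dimnames = dimnames(ng))
  for (r in seq_len(nrow(ng))) {
    m <- cumsum(ng[r, ])
    m[!ng[r, ]] <- NA_integer_
    out[r, ] <- m
  }
  out
}

#' Construct a multiple SAF product
#'
#' @param alignment An `rna_alignment`.
#' @param pairs Integer matrix of consensus column pairs (I < J).
#' @param gamma Optional named numeric `c(match=, pair=)`, the
#'   hyper-parameters the product was decoded with.
#' @return An object of class `saf_msa`.
#' @export
saf_msa <- function(alignment, pairs = matrix(integer(0), ncol = 2),
                    gamma = NULL) {
  stopifnot(inherits(alignment, "rna_alignment"))
  pairs <- matrix(as.integer(pairs), ncol = 2)
  colnames(pairs) <- c("i", "j")
  validate_structure(pairs, ncol(alignment))
  structure(list(alignment = alignment, pairs = pairs, gamma = gamma),
            class = "saf_msa")
}

#' @export
print.saf_msa <- function(x, ...) {
  print(x$alignment)
  cat("  SS_cons      ",
      render_dotbracket(x$pairs, ncol(x$alignment)), "\n", sep = "")
  if (!is.null(x$gamma))
    cat("  gamma: match ", x$gamma[["match"]], ", pair ", x$gamma[["pair"]],
        "\n", sep = "")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Stockholm 1.0 with #=GC SS_cons
## ---------------------------------------------------------------------------

#' Read a single-record Stockholm alignment
#'
#' Parses one Stockholm 1.0 record with optional `#=GC SS_cons` consensus
#' structure; sequence lines may be wrapped over several blocks.  A missing
#' `//` terminator is tolerated with a warning.
#'
#' @param path File path.
#' @return A list with elements `alignment` (an `rna_alignment`) and
#'   `structure` (a column-pair matrix, or `NULL` when no SS_cons line is
#'   present).
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("^# STOCKHOLM", lines)))
    stop("not a Stockholm file: ", path)
  if (!any(grepl("^//", lines)))
    warning("Stockholm record without '//' terminator")
  rows <- list()
  ss <- ""
  for (ln in lines) {
    if (grepl("^//", ln)) break
    if (grepl("^#=GC\\s+SS_cons\\s", ln)) {
      ss <- paste0(ss, sub("^#=GC\\s+SS_cons\\s+", "", ln))
    } else if (grepl("^#", ln) || !nzchar(trimws(ln))) {
      next
    } else {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(parts) != 2) stop("malformed Stockholm sequence line: ", ln)
      rows[[parts[1]]] <- paste0(rows[[parts[1]]] %||% "", parts[2])
    }
  }
  if (length(rows) == 0) stop("Stockholm record holds no sequences")
  lens <- nchar(unlist(rows))
  if (length(unique(lens)) != 1)
    stop("Stockholm rows have unequal lengths")
  aln <- rna_alignment(unlist(rows))
  structure_pairs <- NULL
  if (nzchar(ss)) {
    if (nchar(ss) != ncol(aln))
      stop("SS_cons length differs from alignment width")
    structure_pairs <- parse_dotbracket(ss)
  }
  list(alignment = aln, structure = structure_pairs)
}

#' Write a multiple SAF as Stockholm
#'
#' The consensus structure is rendered as matched `()` columns on the
#' `#=GC SS_cons` line (all dots when the consensus is empty); the output
#' round-trips through [read_stockholm()] to an identical alignment and
#' column pair set.
#'
#' @param msa An `saf_msa` (or a bare `rna_alignment`).
#' @param path Output path.
#' @export
write_stockholm <- function(msa, path) {
  if (inherits(msa, "rna_alignment")) msa <- saf_msa(msa)
  aln <- msa$alignment
  w <- max(nchar(rownames(aln)), nchar("#=GC SS_cons")) + 2
  lines <- c("# STOCKHOLM 1.0", "")
  for (r in rownames(aln))
    lines <- c(lines, sprintf("%-*s%s", w, r, paste(aln[r, ], collapse = "")))
  lines <- c(lines, sprintf("%-*s%s", w, "#=GC SS_cons",
                            render_dotbracket(msa$pairs, ncol(aln))))
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## pairwise SAF
## ---------------------------------------------------------------------------

#' Construct a pairwise SAF
#'
#' A pairwise simultaneous alignment and folding of sequences x and y: a
#' strictly increasing set of matched positions M and a set of matched
#' base-pairing quadruples (i, j, k, l) whose projections give the two
#' secondary structures.  Base-pairing indels are disallowed: every base
#' pair in either structure belongs to exactly one quadruple.
#'
#' @param match Integer matrix (m x 2) of matched positions (i in x, k in y).
#' @param quad Integer matrix (q x 4) of quadruples (i, j, k, l).
#' @param nx,ny Sequence lengths.
#' @param min_hairpin Minimum hairpin span enforced on both structures.
#' @return An object of class `pairwise_saf`.
#' @export
pairwise_saf <- function(match, quad = matrix(integer(0), ncol = 4), nx, ny,
                         min_hairpin = 3L) {
  match <- matrix(as.integer(match), ncol = 2)
  quad <- matrix(as.integer(quad), ncol = 4)
  colnames(match) <- c("i", "k")
  colnames(quad) <- c("i", "j", "k", "l")
  if (nrow(match) > 0) {
    match <- match[order(match[, 1]), , drop = FALSE]
    if (any(match < 1) || any(match[, 1] > nx) || any(match[, 2] > ny))
      stop("match index out of range")
    if (anyDuplicated(match[, 1]) || anyDuplicated(match[, 2]))
      stop("a position is matched twice")
    if (nrow(match) > 1 && any(diff(match[, 2]) <= 0))
      stop("matching is not strictly increasing")
  }
  if (nrow(quad) > 0) {
    mkey <- paste(match[, 1], match[, 2])
    if (!all(paste(quad[, 1], quad[, 3]) %in% mkey) ||
        !all(paste(quad[, 2], quad[, 4]) %in% mkey))
      stop("quadruple endpoints must be matched positions")
    validate_structure(quad[, c(1, 2), drop = FALSE], nx, min_hairpin = 0L)
    validate_structure(quad[, c(3, 4), drop = FALSE], ny, min_hairpin = 0L)
    ## hairpin span: only innermost pairs close hairpins
    check_hairpins(quad[, c(1, 2), drop = FALSE], min_hairpin)
    check_hairpins(quad[, c(3, 4), drop = FALSE], min_hairpin)
    quad <- quad[order(quad[, 1]), , drop = FALSE]
  }
  structure(list(match = match, quad = quad, nx = as.integer(nx),
                 ny = as.integer(ny)),
            class = "pairwise_saf")
}

check_hairpins <- function(pairs, min_hairpin) {
  if (nrow(pairs) == 0 || min_hairpin <= 0) return(invisible(TRUE))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    inner <- pairs[, 1] > i & pairs[, 2] < j
    if (!any(inner) && j - i - 1 < min_hairpin)
      stop("hairpin loop shorter than ", min_hairpin)
  }
  invisible(TRUE)
}

#' @export
print.pairwise_saf <- function(x, ...) {
  cat("Pairwise SAF: ", nrow(x$match), " matches, ", nrow(x$quad),
      " matched base-pair quadruples (", x$nx, " x ", x$ny, " nt)\n", sep = "")
  invisible(x)
}

## x-side / y-side structures induced by the quadruples
saf_structure <- function(saf, side = c("x", "y")) {
  side <- match.arg(side)
  cols <- if (side == "x") c(1L, 2L) else c(3L, 4L)
  saf$quad[, cols, drop = FALSE]
}

## canonical column sequence of a pairwise SAF: within every gapped run all
## deletions (x residues) precede all insertions (y residues).
## Returns a matrix with columns xi, yk (NA = gap) and the state M/D/I.
saf_columns <- function(saf) {
  m <- saf$match
  xi <- integer(0); yk <- integer(0); st <- character(0)
  px <- 0L; py <- 0L
  emit_run <- function(x_to, y_to) {
    if (x_to > px) {
      xi <<- c(xi, seq(px + 1L, x_to)); yk <<- c(yk, rep(NA, x_to - px))
      st <<- c(st, rep("D", x_to - px))
    }
    if (y_to > py) {
      xi <<- c(xi, rep(NA, y_to - py)); yk <<- c(yk, seq(py + 1L, y_to))
      st <<- c(st, rep("I", y_to - py))
    }
    px <<- x_to; py <<- y_to
  }
  if (nrow(m) > 0) {
    for (r in seq_len(nrow(m))) {
      emit_run(m[r, 1] - 1L, m[r, 2] - 1L)
      xi <- c(xi, m[r, 1]); yk <- c(yk, m[r, 2]); st <- c(st, "M")
      px <- m[r, 1]; py <- m[r, 2]
    }
  }
  emit_run(saf$nx, saf$ny)
  list(xi = xi, yk = yk, state = st)
}

#' Render a pairwise SAF as a two-row alignment
#' @param saf A `pairwise_saf`.
#' @param x,y The two [rna_seq] objects.
#' @return An `rna_alignment` with two rows.
#' @export
saf_to_alignment <- function(saf, x, y) {
  cols <- saf_columns(saf)
  xrow <- ifelse(is.na(cols$xi), GAP, RES_ALPHA[x$res[cols$xi]])
  yrow <- ifelse(is.na(cols$yk), GAP, RES_ALPHA[y$res[cols$yk]])
  rna_alignment(setNames(c(paste(xrow, collapse = ""),
                           paste(yrow, collapse = "")),
                         c(x$id, y$id)))
}
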