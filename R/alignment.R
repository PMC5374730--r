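#' Scoring scheme for bisulfite-aware local alignment
#'
#' Bundles the Smith-Waterman substitution and gap parameters together with a
#' bisulfite conversion mode. Bisulfite treatment converts unmethylated
#' cytosines to uracil, read as T after amplification, so a read from the
#' converted forward strand shows T where the reference has an unmethylated C.
#' Mode `"c_to_t"` therefore scores read-T against reference-C as a match
#' while leaving read-C against reference-T a mismatch (the asymmetry is the
#' point: the conversion only runs one way). Mode `"g_to_a"` is the mirrored
#' rule for reads representing the opposite strand compared against the
#' forward reference; `"none"` is plain symmetric matching, used for the
#' untreated anchor end of a pair.
#'
#' @param match positive match score.
#' @param mismatch negative mismatch score.
#' @param gap negative per-base (linear) gap penalty.
#' @param conversion_mode one of `"none"`, `"c_to_t"`, `"g_to_a"`.
#' @return An object of class `scoring_scheme`.
#' @examples
#' scoring_scheme(conversion_mode = "c_to_t")
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L, gap = -2L,
                           conversion_mode = c("none", "c_to_t", "g_to_a")) {
  conversion_mode <- match.arg(conversion_mode)
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap <- as.integer(gap)
  if (is.na(match) || match <= 0L) stop("`match` must be a positive score")
  if (is.na(mismatch) || mismatch >= 0L) stop("`mismatch` must be negative")
  if (is.na(gap) || gap >= 0L) stop("`gap` must be negative")
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 conversion_mode = conversion_mode),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> match=%+d mismatch=%+d gap=%+d mode=%s\n",
              x$match, x$mismatch, x$gap, x$conversion_mode))
  invisible(x)
}

.mode_code <- function(mode) {
  switch(mode, none = 0L, c_to_t = 1L, g_to_a = 2L,
         stop("unknown conversion mode: ", mode))
}

.check_bases <- function(x, what) {
  bad <- !x %in% c("A", "C", "G", "T", "N")
  if (any(bad))
    stop("illegal base '", x[which(bad)[1L]], "' in ", what,
         " (alphabet is A/C/G/T/N)")
}

#' Asymmetric substitution score
#'
#' Scores one read base against one reference (window) base under a scheme's
#' conversion mode. Under `"c_to_t"`, read T vs reference C scores as a match
#' (a converted cytosine must not be penalised) but read C vs reference T
#' stays a mismatch; `"g_to_a"` mirrors this for read A vs reference G. Any
#' comparison involving N is a mismatch. Vectorised over bases.
#'
#' @param read_base,ref_base character vectors of single bases (A/C/G/T/N).
#' @param scheme a [scoring_scheme()].
#' @return integer vector of scores.
#' @examples
#' sc <- scoring_scheme(conversion_mode = "c_to_t")
#' substitution_score("T", "C", sc)  # match: bisulfite-converted cytosine
#' substitution_score("C", "T", sc)  # mismatch: conversion is one-way
#' @export
substitution_score <- function(read_base, ref_base, scheme) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  if (length(read_base) != length(ref_base))
    stop("read_base and ref_base must have equal length")
  .check_bases(read_base, "read_base")
  .check_bases(ref_base, "ref_base")
  hit <- (read_base == ref_base) & read_base != "N"
  if (scheme$conversion_mode == "c_to_t")
    hit <- hit | (read_base == "T" & ref_base == "C")
  else if (scheme$conversion_mode == "g_to_a")
    hit <- hit | (read_base == "A" & ref_base == "G")
  ifelse(hit, scheme$match, scheme$mismatch)
}

#' Build Smith-Waterman score and direction matrices
#'
#' Fills the local-alignment dynamic-programming matrix
#' `H(i,j) = max(0, H(i-1,j-1) + s(read_i, window_j), H(i-1,j) + gap,
#' H(i,j-1) + gap)` with a zero first row and column, and records for every
#' cell the source direction that attained the maximum. Recording directions
#' during the fill lets traceback follow stored pointers instead of
#' re-evaluating the recurrence at every step. Ties are broken
#' DIAG > UP > LEFT; a cell points STOP exactly when its score is zero. The
#' argmax is the first maximal cell in row-major order, which makes the whole
#' construction deterministic.
#'
#' @param read,window non-empty base strings over A/C/G/T/N.
#' @param scheme a [scoring_scheme()].
#' @return An object of class `sw_matrices`: list with `score` and
#'   `direction` matrices of dimension `(nchar(read)+1) x (nchar(window)+1)`,
#'   `argmax` (row, column of the best cell, 1-based in read/window units),
#'   `max_score`, and the inputs.
#' @seealso [sw_traceback()], [align_in_window()]
#' @export
build_matrices <- function(read, window, scheme) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  if (!is.character(read) || length(read) != 1L || !nzchar(read))
    stop("`read` must be a single non-empty string")
  if (!is.character(window) || length(window) != 1L || !nzchar(window))
    stop("`window` must be a single non-empty string")
  res <- .sw_fill(read, window, scheme$match, scheme$mismatch, scheme$gap,
                  .mode_code(scheme$conversion_mode))
  structure(list(score = res$score, direction = res$direction,
                 argmax = res$argmax, max_score = res$max_score,
                 read = read, window = window, scheme = scheme),
            class = "sw_matrices")
}

#' @export
print.sw_matrices <- function(x, ...) {
  cat(sprintf("<sw_matrices> %d x %d, max score %d at (%d, %d)\n",
              nrow(x$score) - 1L, ncol(x$score) - 1L, x$max_score,
              x$argmax[1L], x$argmax[2L]))
  invisible(x)
}

.DIR_STOP <- 0L; .DIR_DIAG <- 1L; .DIR_UP <- 2L; .DIR_LEFT <- 3L

#' Traceback through stored direction pointers
#'
#' Walks the direction matrix from the argmax cell back to the first STOP
#' cell, emitting aligned base pairs in order. No score is recomputed and no
#' branch is re-evaluated: each step only reads the stored pointer. The
#' resulting pair scores re-sum exactly to the argmax cell's score.
#'
#' @param matrices an `sw_matrices` object from [build_matrices()].
#' @return An object of class `bs_alignment`: `score`; `read_start`/
#'   `read_end` and `window_start`/`window_end` (0-based half-open spans of
#'   the read and window consumed); `pairs`, a two-column character matrix of
#'   (read base or `"-"`, window base or `"-"`); `genome_start`/`genome_end`
#'   (`NA` until lifted by [align_in_window()]).
#' @export
sw_traceback <- function(matrices) {
  stopifnot(inherits(matrices, "sw_matrices"))
  D <- matrices$direction
  i <- matrices$argmax[1L]; j <- matrices$argmax[2L]
  score <- matrices$max_score
  rb <- strsplit(matrices$read, "", fixed = TRUE)[[1L]]
  wb <- strsplit(matrices$window, "", fixed = TRUE)[[1L]]
  end_i <- i; end_j <- j
  pr <- character(0); pw <- character(0)
  steps <- 0L; max_steps <- i + j
  while (i > 0L && j > 0L && D[i + 1L, j + 1L] != .DIR_STOP) {
    steps <- steps + 1L
    if (steps > max_steps) stop("corrupted direction matrix: traceback cycle")
    d <- D[i + 1L, j + 1L]
    if (d == .DIR_DIAG) {
      pr <- c(rb[i], pr); pw <- c(wb[j], pw); i <- i - 1L; j <- j - 1L
    } else if (d == .DIR_UP) {
      pr <- c(rb[i], pr); pw <- c("-", pw); i <- i - 1L
    } else if (d == .DIR_LEFT) {
      pr <- c("-", pr); pw <- c(wb[j], pw); j <- j - 1L
    } else stop("corrupted direction matrix: out-of-range pointer ", d)
  }
  structure(list(score = score,
                 read_start = i, read_end = end_i,
                 window_start = j, window_end = end_j,
                 pairs = cbind(read = pr, window = pw),
                 genome_start = NA_integer_, genome_end = NA_integer_),
            class = "bs_alignment")
}

#' @export
print.bs_alignment <- function(x, ...) {
  cat(sprintf(
    "<bs_alignment> score %d, read [%d,%d), window [%d,%d), %d columns",
    x$score, x$read_start, x$read_end, x$window_start, x$window_end,
    nrow(x$pairs)))
  if (!is.na(x$genome_start))
    cat(sprintf(", genome %d..%d", x$genome_start, x$genome_end))
  cat("\n")
  if (nrow(x$pairs) > 0L) {
    show <- seq_len(min(60L, nrow(x$pairs)))
    cat(" read:   ", paste(x$pairs[show, 1L], collapse = ""), "\n", sep = "")
    cat(" window: ", paste(x$pairs[show, 2L], collapse = ""), "\n", sep = "")
  }
  invisible(x)
}

#' Align a read inside a hinted reference window
#'
#' Composes [build_matrices()] and [sw_traceback()] and lifts the window-
#' relative span to genome coordinates: a window starting at 1-based genome
#' position `window_offset` whose alignment consumes the 0-based half-open
#' window span `[s, e)` covers genome positions `window_offset + s` to
#' `window_offset + e - 1` (1-based inclusive).
#'
#' @param read base string to align.
#' @param window reference window base string.
#' @param window_offset 1-based genome coordinate of the window's first base.
#' @param scheme a [scoring_scheme()].
#' @return A `bs_alignment` with `genome_start`/`genome_end` filled in.
#' @examples
#' al <- align_in_window("ACGT", "TTACGTTT", window_offset = 101,
#'                       scheme = scoring_scheme())
#' al$genome_start  # 103
#' @export
align_in_window <- function(read, window, window_offset, scheme) {
  window_offset <- as.integer(window_offset)
  if (is.na(window_offset) || window_offset < 1L)
    stop("`window_offset` must be a 1-based genome coordinate")
  al <- sw_traceback(build_matrices(read, window, scheme))
  if (al$window_end > al$window_start) {
    al$genome_start <- window_offset + al$window_start
    al$genome_end <- window_offset + al$window_end - 1L
  }
  al
}
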