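# Shared test utilities: random sequences, a reference local-alignment
# oracle written independently of the package's DP (plain recursion over the
# recurrence, memoised, no direction bookkeeping), and small fixture writers.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Recursive Smith-Waterman score oracle. Independent implementation: top-down
# recursion with memoisation, computing only the score.
sw_oracle_score <- function(read, window, match = 2L, mismatch = -3L,
                            gap = -2L, mode = "none") {
  rb <- strsplit(read, "")[[1L]]; wb <- strsplit(window, "")[[1L]]
  n <- length(rb); m <- length(wb)
  memo <- array(NA_integer_, c(n + 1L, m + 1L))
  s <- function(a, b) {
    if (a == "N" || b == "N") return(mismatch)
    if (a == b) return(match)
    if (mode == "c_to_t" && a == "T" && b == "C") return(match)
    if (mode == "g_to_a" && a == "A" && b == "G") return(match)
    mismatch
  }
  H <- function(i, j) {
    if (i == 0L || j == 0L) return(0L)
    if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
    v <- max(0L, H(i - 1L, j - 1L) + s(rb[i], wb[j]),
             H(i - 1L, j) + gap, H(i, j - 1L) + gap)
    memo[i + 1L, j + 1L] <<- v
    v
  }
  best <- 0L
  for (i in seq_len(n)) for (j in seq_len(m))
    best <- max(best, H(i, j))
  best
}

# score an alignment's pairs column by column, the way the traceback claims
# they were scored
resum_pairs <- function(al, scheme) {
  if (nrow(al$pairs) == 0L) return(0L)
  tot <- 0L
  for (k in seq_len(nrow(al$pairs))) {
    a <- unname(al$pairs[k, 1L]); b <- unname(al$pairs[k, 2L])
    tot <- tot + if (a == "-" || b == "-") scheme$gap else
      substitution_score(a, b, scheme)
  }
  unname(tot)
}

write_temp_fasta <- function(seqs, width = 50L) {
  path <- tempfile(fileext = ".fa")
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  close(con)
  path
}

write_temp_targets <- function(records) {
  path <- tempfile(fileext = ".txt")
  writeLines(format_target_lines(records), path)
  path
}

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
}
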