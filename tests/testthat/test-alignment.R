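test_that("substitution scoring is asymmetric under conversion modes", {
  none <- scoring_scheme()
  ct <- scoring_scheme(conversion_mode = "c_to_t")
  ga <- scoring_scheme(conversion_mode = "g_to_a")

  # bisulfite converts unmethylated C to T: read T over reference C is not
  # an error, but the reverse pairing still is
  expect_equal(substitution_score("T", "C", ct), ct$match)
  expect_equal(substitution_score("C", "T", ct), ct$mismatch)
  expect_equal(substitution_score("A", "G", ga), ga$match)
  expect_equal(substitution_score("G", "A", ga), ga$mismatch)
  # plain mode is symmetric over all base pairs
  for (a in c("A", "C", "G", "T"))
    for (b in c("A", "C", "G", "T"))
      expect_equal(substitution_score(a, b, none),
                   substitution_score(b, a, none))
  # N never matches, in any mode, on either side
  for (sc in list(none, ct, ga)) {
    expect_equal(substitution_score("N", "N", sc), sc$mismatch)
    expect_equal(substitution_score("N", "C", sc), sc$mismatch)
    expect_equal(substitution_score("T", "N", sc), sc$mismatch)
  }
  expect_error(substitution_score("X", "A", none), "illegal base")
})

test_that("scoring scheme validates its parameters", {
  expect_error(scoring_scheme(match = 0), "positive")
  expect_error(scoring_scheme(mismatch = 1), "negative")
  expect_error(scoring_scheme(gap = 0), "negative")
  expect_error(scoring_scheme(conversion_mode = "bogus"))
})

test_that("matrix fill matches hand-derived examples", {
  sc <- scoring_scheme()  # +2 / -3 / -2
  expect_equal(build_matrices("ACGT", "ACGT", sc)$max_score, 8L)
  # a converted cytosine inside the read costs nothing under c_to_t
  ct <- scoring_scheme(conversion_mode = "c_to_t")
  expect_equal(build_matrices("ATGT", "ACGT", ct)$max_score, 8L)
  # but is a mismatch in plain mode: best is the 2-mer suffix match
  expect_equal(build_matrices("ATGT", "ACGT", sc)$max_score, 4L)
  expect_error(build_matrices("", "ACGT", sc), "non-empty")
  expect_error(build_matrices("ACGT", "", sc), "non-empty")
})

test_that("matrix invariants hold: zero borders, STOP iff zero, bounded walk", {
  set.seed(501)
  for (k in 1:25) {
    sc <- scoring_scheme(conversion_mode = sample(c("none", "c_to_t",
                                                    "g_to_a"), 1L))
    m <- build_matrices(rand_seq(sample(1:12, 1L)),
                        rand_seq(sample(1:12, 1L)), sc)
    expect_true(all(m$score[1L, ] == 0L))
    expect_true(all(m$score[, 1L] == 0L))
    expect_true(all(m$score >= 0L))
    expect_true(all((m$direction == 0L) == (m$score == 0L)))
    # following pointers from every cell reaches STOP within i+j steps
    for (i in seq_len(nrow(m$score) - 1L)) {
      for (j in seq_len(ncol(m$score) - 1L)) {
        ci <- i; cj <- j; steps <- 0L
        while (m$direction[ci + 1L, cj + 1L] != 0L) {
          d <- m$direction[ci + 1L, cj + 1L]
          if (d == 1L) { ci <- ci - 1L; cj <- cj - 1L }
          else if (d == 2L) ci <- ci - 1L
          else cj <- cj - 1L
          steps <- steps + 1L
          expect_lte(steps, i + j)
        }
      }
    }
  }
})

test_that("scores equal the independent recursive oracle on random instances", {
  set.seed(502)
  for (k in 1:70) {
    r <- rand_seq(sample(1:12, 1L))
    w <- rand_seq(sample(1:12, 1L))
    for (mode in c("none", "c_to_t", "g_to_a")) {
      sc <- scoring_scheme(conversion_mode = mode)
      expect_equal(build_matrices(r, w, sc)$max_score,
                   sw_oracle_score(r, w, mode = mode),
                   info = paste(r, w, mode))
    }
  }
})

test_that("scores equal Biostrings local alignment under a custom matrix", {
  # fully independent implementation as a second oracle; the asymmetric
  # conversion rule is expressed as a non-symmetric substitution matrix
  set.seed(503)
  bases <- c("A", "C", "G", "T")
  for (mode in c("none", "c_to_t", "g_to_a")) {
    mat <- matrix(-3, 4L, 4L, dimnames = list(bases, bases))
    diag(mat) <- 2
    if (mode == "c_to_t") mat["T", "C"] <- 2
    if (mode == "g_to_a") mat["A", "G"] <- 2
    sc <- scoring_scheme(conversion_mode = mode)
    for (k in 1:40) {
      r <- rand_seq(sample(2:12, 1L)); w <- rand_seq(sample(2:12, 1L))
      expect_equal(build_matrices(r, w, sc)$max_score,
                   Biostrings::score(Biostrings::pairwiseAlignment(
                     r, w, substitutionMatrix = mat, gapOpening = 0,
                     gapExtension = 2, type = "local")),
                   info = paste(r, w, mode))
    }
  }
})

test_that("traceback follows stored pointers to the frozen tie-break result", {
  sc <- scoring_scheme()
  # perfect 4-mer: four diagonal pairs covering both spans
  al <- sw_traceback(build_matrices("ACGT", "ACGT", sc))
  expect_equal(al$score, 8L)
  expect_equal(nrow(al$pairs), 4L)
  expect_true(all(al$pairs[, 1L] == al$pairs[, 2L]))
  expect_equal(c(al$read_start, al$read_end), c(0L, 4L))
  expect_equal(c(al$window_start, al$window_end), c(0L, 4L))

  # AGT vs ACGT admits two score-4 local alignments (gapped A/A,-/C,G/G,T/T
  # and the gapless GT match); DIAG>UP>LEFT with the zero floor plus
  # row-major argmax selects the gapless one ending at (3,4)
  al2 <- sw_traceback(build_matrices("AGT", "ACGT", sc))
  expect_equal(al2$score, 4L)
  expect_equal(al2$pairs[, 1L], c("G", "T"))
  expect_equal(al2$pairs[, 2L], c("G", "T"))
  expect_equal(c(al2$read_start, al2$read_end), c(1L, 3L))
  expect_equal(c(al2$window_start, al2$window_end), c(2L, 4L))
})

test_that("pair scores re-sum to the argmax score on random instances", {
  set.seed(504)
  for (k in 1:70) {
    mode <- sample(c("none", "c_to_t", "g_to_a"), 1L)
    sc <- scoring_scheme(conversion_mode = mode)
    m <- build_matrices(rand_seq(sample(1:12, 1L)),
                        rand_seq(sample(1:12, 1L)), sc)
    al <- sw_traceback(m)
    expect_equal(resum_pairs(al, sc), al$score)
    expect_gte(al$score, 0L)
    # diagonal pair count equals both-side-base columns
    diag_cols <- sum(al$pairs[, 1L] != "-" & al$pairs[, 2L] != "-")
    expect_equal(al$read_end - al$read_start,
                 sum(al$pairs[, 1L] != "-"))
    expect_equal(al$window_end - al$window_start,
                 sum(al$pairs[, 2L] != "-"))
    expect_equal(nrow(al$pairs) - diag_cols,
                 sum(al$pairs[, 1L] == "-") + sum(al$pairs[, 2L] == "-"))
  }
})

test_that("window spans lift to 1-based genome coordinates", {
  sc <- scoring_scheme()
  al <- align_in_window("ACGT", "TTTACGTTTT", 1001L, sc)
  # window span [3,7) lifts to genome 1004..1007 inclusive
  expect_equal(c(al$window_start, al$window_end), c(3L, 7L))
  expect_equal(al$genome_start, 1004L)
  expect_equal(al$genome_end, 1007L)
})

test_that("a read placed at offset k maps to window_offset + k", {
  set.seed(505)
  for (rep in 1:10) {
    win <- rand_seq(300)
    k <- sample(0:250, 1L)
    read <- substr(win, k + 1L, k + 40L)
    off <- sample(1:100000, 1L)
    al <- align_in_window(read, win, off, scoring_scheme())
    expect_equal(al$score, 2L * 40L)
    expect_equal(al$genome_start, off + k)
  }
})

test_that("wrong-orientation reads score far below the correct orientation", {
  set.seed(506)
  win <- rand_seq(400)
  read <- substr(win, 101, 150)
  sc <- scoring_scheme()
  good <- align_in_window(read, win, 1L, sc)$score
  flipped <- align_in_window(revcomp(read), win, 1L, sc)$score
  expect_equal(good, 100L)
  expect_lt(flipped, 0.5 * good)
})

test_that("converting reference-C-matched read bases never lowers c_to_t score", {
  set.seed(507)
  ct <- scoring_scheme(conversion_mode = "c_to_t")
  for (rep in 1:20) {
    win <- rand_seq(60)
    read <- substr(win, 11, 40)
    converted <- chartr("C", "T", read)
    expect_gte(align_in_window(converted, win, 1L, ct)$score,
               align_in_window(read, win, 1L, ct)$score)
  }
})
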