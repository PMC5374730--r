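test_that("simulated references are seed-deterministic with the stated GC", {
  p <- simulation_params(seed = 1L, genome_length = 10000L)
  expect_identical(simulate_reference(p), simulate_reference(p))

  p_gc1 <- simulation_params(seed = 2L, genome_length = 2200L,
                             gc_fraction = 1.0)
  s <- simulate_reference(p_gc1)$sequences[[1L]]
  expect_true(grepl("^[GC]+$", s))

  p_big <- simulation_params(seed = 3L, genome_length = 100000L,
                             gc_fraction = 0.42)
  big <- simulate_reference(p_big)$sequences[[1L]]
  gc <- nchar(gsub("[AT]", "", big)) / nchar(big)
  expect_lt(abs(gc - 0.42), 0.01)
})

test_that("parameter validation rejects infeasible geometries and rates", {
  expect_error(simulation_params(genome_length = 500L), "genome_length")
  expect_error(simulation_params(hint_jitter = 980L), "hint_jitter")
  expect_error(simulation_params(meth_cpg = 1.5), "rates")
  expect_error(simulation_params(sequencing_error_rate = -0.1), "rates")
})

test_that("methylation states cover both strands at the context rates", {
  p <- simulation_params(seed = 11L, genome_length = 20000L,
                         meth_cpg = 1.0, meth_chh = 0.0, meth_chg = 0.0)
  ref <- simulate_reference(p)
  st <- assign_methylation_states(ref, p)
  expect_true(all(st$true_level[st$context == "CpG"] == 1))
  expect_true(all(st$true_level[st$context != "CpG"] == 0))
  expect_true(all(st$strand %in% c("+", "-")))
  # strand/base consistency
  bases <- vapply(seq_len(50L), function(i)
    ref_bases(ref, st$chrom[i], st$position[i], st$position[i]),
    character(1L))
  expect_true(all(ifelse(st$strand[1:50] == "+", "C", "G") == bases))

  # assigned levels average to the context parameter across many sites
  p2 <- simulation_params(seed = 12L, genome_length = 50000L,
                          meth_cpg = 0.7)
  st2 <- assign_methylation_states(simulate_reference(p2), p2)
  cpg <- st2$true_level[st2$context == "CpG"]
  expect_gt(length(cpg), 1000L)
  expect_lt(abs(mean(cpg) - 0.7), 0.02)
})

test_that("deterministic limits of the treated end hold", {
  # no methylation, complete conversion, no errors: the treated end is the
  # genomic substring with every strand cytosine converted
  p0 <- simulation_params(seed = 21L, n_groups = 30L, meth_cpg = 0,
                          meth_chg = 0, meth_chh = 0,
                          sequencing_error_rate = 0, conversion_rate = 1)
  sim <- simulate_dataset(p0)
  for (g in seq_len(nrow(sim$truth_groups))) {
    tg <- sim$truth_groups[g, ]
    treated <- sim$records[sim$records$group_id == tg$group_id &
                             sim$records$treated, ]
    genomic <- ref_bases(sim$ref, tg$chrom, tg$t_start,
                         tg$t_start + p0$read_length - 1L)
    expected <- if (tg$strand == "+") chartr("C", "T", genomic) else
      chartr("G", "A", genomic)
    expect_equal(treated$sequence, expected)
  }

  # full methylation, no errors: nothing converts, both ends are genomic
  p1 <- simulation_params(seed = 22L, n_groups = 30L, meth_cpg = 1,
                          meth_chg = 1, meth_chh = 1,
                          sequencing_error_rate = 0)
  sim1 <- simulate_dataset(p1)
  for (g in seq_len(nrow(sim1$truth_groups))) {
    tg <- sim1$truth_groups[g, ]
    treated <- sim1$records[sim1$records$group_id == tg$group_id &
                              sim1$records$treated, ]
    expect_equal(treated$sequence,
                 ref_bases(sim1$ref, tg$chrom, tg$t_start,
                           tg$t_start + p1$read_length - 1L))
  }
})

test_that("error-free treated ends differ from the reference only at converted cytosines", {
  p <- simulation_params(seed = 23L, n_groups = 40L,
                         sequencing_error_rate = 0)
  sim <- simulate_dataset(p)
  for (g in seq_len(nrow(sim$truth_groups))) {
    tg <- sim$truth_groups[g, ]
    treated <- sim$records[sim$records$group_id == tg$group_id &
                             sim$records$treated, ]
    genomic <- strsplit(ref_bases(sim$ref, tg$chrom, tg$t_start,
                                  tg$t_start + p$read_length - 1L),
                        "")[[1L]]
    got <- strsplit(treated$sequence, "")[[1L]]
    diff <- which(genomic != got)
    if (tg$strand == "+") {
      expect_true(all(genomic[diff] == "C" & got[diff] == "T"))
    } else {
      expect_true(all(genomic[diff] == "G" & got[diff] == "A"))
    }
  }
})

test_that("fixtures count groups, records and duplicates as specified", {
  p <- simulation_params(seed = 24L, n_groups = 100L,
                         duplicate_fraction = 0.1)
  sim <- simulate_dataset(p)
  expect_equal(nrow(sim$records), 200L)  # two ends per group
  expect_equal(length(unique(sim$records$group_id)), 100L)
  expect_equal(sum(!is.na(sim$truth_groups$duplicate_of)), 10L)
  # duplicates immediately follow their source and share its locus
  dups <- sim$truth_groups[!is.na(sim$truth_groups$duplicate_of), ]
  for (d in seq_len(nrow(dups))) {
    src <- sim$truth_groups[sim$truth_groups$group_id ==
                              dups$duplicate_of[d], ]
    expect_equal(dups$group_id[d], src$group_id + 1L)
    expect_equal(dups$t_start[d], src$t_start)
    expect_equal(dups$chrom[d], src$chrom)
    expect_equal(dups$strand[d], src$strand)
  }
})

test_that("realized truth counts sum molecule observations of originals", {
  p <- simulation_params(seed = 25L, n_groups = 50L,
                         sequencing_error_rate = 0)
  sim <- simulate_dataset(p)
  orig <- sim$truth_groups[is.na(sim$truth_groups$duplicate_of), ]
  # total realized observations = strand cytosines covered by treated ends
  expected_tot <- 0L
  for (g in seq_len(nrow(orig))) {
    tg <- orig[g, ]
    seq <- ref_bases(sim$ref, tg$chrom, tg$t_start,
                     tg$t_start + p$read_length - 1L)
    b <- if (tg$strand == "+") "C" else "G"
    expected_tot <- expected_tot +
      nchar(seq) - nchar(gsub(b, "", seq, fixed = TRUE))
  }
  expect_equal(sum(sim$truth_sites$realized_total), expected_tot)
  expect_true(all(sim$truth_sites$realized_m <=
                    sim$truth_sites$realized_total))
})

test_that("written fixtures are byte-identical per seed", {
  p <- simulation_params(seed = 26L, n_groups = 20L)
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- write_fixture(p, d1)
  f2 <- write_fixture(p, d2)
  for (k in names(f1))
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
})

test_that("hint jitter stays within the stated bound", {
  p <- simulation_params(seed = 27L, n_groups = 50L, hint_jitter = 200L)
  sim <- simulate_dataset(p)
  for (g in seq_len(nrow(sim$truth_groups))) {
    tg <- sim$truth_groups[g, ]
    recs <- sim$records[sim$records$group_id == tg$group_id, ]
    truth_start <- ifelse(recs$treated, tg$t_start, tg$u_start)
    expect_true(all(abs(recs$coord - truth_start) <= 200L))
  }
})
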