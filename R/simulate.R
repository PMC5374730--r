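#' Simulation parameters
#'
#' Describes a synthetic whole-genome bisulfite experiment with known ground
#' truth: a random reference, per-cytosine true methylation states, and
#' hybrid read pairs in the hinted target format — one untreated anchor end
#' (an exact genomic substring, up to sequencing error) and one
#' bisulfite-treated end in which each unmethylated cytosine is converted
#' with probability `conversion_rate`. Defaults emulate a mammalian-like
#' methylome at modest scale: heavily methylated CpGs, near-zero CHG/CHH
#' methylation, near-complete conversion, and a small sequencing error rate.
#'
#' @param seed integer RNG seed; every artifact is a pure function of the
#'   parameters, so a fixed seed reproduces byte-identical fixtures.
#' @param genome_length bases per chromosome (default 20000; must be at
#'   least twice window radius + read length so hinted windows always fit).
#' @param n_chromosomes number of chromosomes (default 1).
#' @param gc_fraction expected G+C fraction of the reference (default 0.42,
#'   roughly human-like).
#' @param n_groups number of read groups (pairs) to emit, duplicates
#'   included (default 100).
#' @param read_length bases per read (default 50).
#' @param pair_gap bases between the untreated end and the treated end of a
#'   pair (default 100, a short-insert library).
#' @param meth_cpg,meth_chg,meth_chh true methylation level per context
#'   (defaults 0.75 / 0.02 / 0.02, mammalian-like). Every cytosine of a
#'   context carries that level as its true value, and each sequenced
#'   molecule samples its methylation state Bernoulli(level), so a site's
#'   realized methylated fraction is binomial in its coverage.
#' @param sequencing_error_rate per-base probability of a uniform
#'   substitution error (default 0.001).
#' @param conversion_rate probability an unmethylated cytosine is actually
#'   converted by the bisulfite treatment (default 1.0 = complete
#'   conversion; lower values let the calling bias be measured).
#' @param duplicate_fraction fraction of groups that are PCR re-emissions of
#'   another group's molecule (default 0): `floor(duplicate_fraction *
#'   n_groups)` duplicate groups are emitted, each immediately after its
#'   source group so duplicates stay in one chunk.
#' @param hint_jitter maximum absolute noise (bases, uniform) added to each
#'   record's coordinate hint (default 100, emulating a coarse upstream
#'   locator); must stay below window radius minus read length so the true
#'   locus remains inside the window.
#' @return a `simulation_params` object.
#' @export
simulation_params <- function(seed = 1L, genome_length = 20000L,
                              n_chromosomes = 1L, gc_fraction = 0.42,
                              n_groups = 100L, read_length = 50L,
                              pair_gap = 100L, meth_cpg = 0.75,
                              meth_chg = 0.02, meth_chh = 0.02,
                              sequencing_error_rate = 0.001,
                              conversion_rate = 1.0,
                              duplicate_fraction = 0,
                              hint_jitter = 100L) {
  p <- list(seed = as.integer(seed),
            genome_length = as.integer(genome_length),
            n_chromosomes = as.integer(n_chromosomes),
            gc_fraction = gc_fraction, n_groups = as.integer(n_groups),
            read_length = as.integer(read_length),
            pair_gap = as.integer(pair_gap),
            meth_cpg = meth_cpg, meth_chg = meth_chg, meth_chh = meth_chh,
            sequencing_error_rate = sequencing_error_rate,
            conversion_rate = conversion_rate,
            duplicate_fraction = duplicate_fraction,
            hint_jitter = as.integer(hint_jitter))
  rates <- c(p$gc_fraction, p$meth_cpg, p$meth_chg, p$meth_chh,
             p$sequencing_error_rate, p$conversion_rate,
             p$duplicate_fraction)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (p$genome_length < 2L * (1000L + p$read_length))
    stop("genome_length must be at least 2 * (window radius 1000 + ",
         "read_length) per chromosome")
  if (p$hint_jitter >= 1000L - p$read_length)
    stop("hint_jitter must stay below window radius - read_length")
  if (p$n_groups < 1L || p$read_length < 1L || p$pair_gap < 0L)
    stop("n_groups and read_length must be positive, pair_gap >= 0")
  structure(p, class = "simulation_params")
}

.sim_seed <- function(params, offset) {
  # sub-seeds for the generation stages; kept well inside 32-bit range
  (params$seed * 7L + offset) %% 2147483647L
}

#' Simulate a reference genome
#'
#' Seeded i.i.d. bases: G and C each with probability `gc_fraction/2`, A and
#' T each with `(1 - gc_fraction)/2`.
#'
#' @param params a [simulation_params()].
#' @return a `flat_reference` with chromosomes `sim1`, `sim2`, ...
#' @export
simulate_reference <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(.sim_seed(params, 1L))
  gc <- params$gc_fraction
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(params$n_chromosomes), function(i)
    paste(sample(names(prob), params$genome_length, replace = TRUE,
                 prob = prob), collapse = ""),
    character(1L))
  names(seqs) <- paste0("sim", seq_len(params$n_chromosomes))
  new_flat_reference(seqs)
}

#' Assign true methylation states to every cytosine
#'
#' Enumerates every cytosine on both strands (reference C on `+`, reference
#' G on `-`), classifies its context, and assigns the context's true
#' methylation level. The level acts downstream as the per-molecule
#' probability of being methylated.
#'
#' @param ref a `flat_reference` from [simulate_reference()].
#' @param params the same [simulation_params()].
#' @return data.frame: `chrom`, `position`, `strand`, `context`,
#'   `true_level`.
#' @export
assign_methylation_states <- function(ref, params) {
  stopifnot(inherits(ref, "flat_reference"),
            inherits(params, "simulation_params"))
  per_chrom <- lapply(ref$chrom_names, function(nm) {
    bases <- strsplit(ref$sequences[[nm]], "", fixed = TRUE)[[1L]]
    plus <- which(bases == "C")
    minus <- which(bases == "G")
    pos <- c(plus, minus)
    strand <- c(rep("+", length(plus)), rep("-", length(minus)))
    ord <- order(pos, match(strand, c("+", "-")))
    pos <- pos[ord]; strand <- strand[ord]
    ctx <- classify_context(ref, nm, pos, strand)
    p <- c(CpG = params$meth_cpg, CHG = params$meth_chg,
           CHH = params$meth_chh)[ctx]
    data.frame(chrom = nm, position = pos, strand = strand, context = ctx,
               true_level = unname(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_chrom)
  rownames(out) <- NULL
  out
}

# one molecule: realized methylation + conversion of the treated end, and
# per-site realized observation bookkeeping
.realize_molecule <- function(ref, states_key, states_level, chrom,
                              t_start, t_len, strand, conversion_rate) {
  tseq <- strsplit(ref_bases(ref, chrom, t_start, t_start + t_len - 1L),
                   "", fixed = TRUE)[[1L]]
  target_base <- if (strand == "+") "C" else "G"
  conv_base <- if (strand == "+") "T" else "A"
  at <- which(tseq == target_base)
  pos <- t_start - 1L + at
  key <- paste(chrom, pos, strand, sep = "\r")
  lev <- states_level[match(key, states_key)]
  known <- !is.na(lev)
  at <- at[known]; pos <- pos[known]; lev <- lev[known]
  methylated <- rbinom(length(at), 1L, lev) == 1L
  converted <- !methylated & (runif(length(at)) < conversion_rate)
  tseq[at[converted]] <- conv_base
  list(seq = paste(tseq, collapse = ""), site_pos = pos,
       site_meth = methylated)
}

.apply_errors <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(bases)) < error_rate)
  for (k in hit) {
    alt <- setdiff(c("A", "C", "G", "T"), bases[k])
    bases[k] <- alt[sample.int(3L, 1L)]
  }
  paste(bases, collapse = "")
}

#' Simulate hinted hybrid read pairs with ground truth
#'
#' Per group a locus is drawn: a (chromosome, strand, start) combination
#' sampled uniformly without replacement, so every original molecule has
#' distinct mapped coordinates and identical coordinates identify planted
#' PCR duplicates and nothing else. The untreated anchor end is the exact
#' forward substring at the locus and the treated end, `pair_gap` bases
#' downstream,
#' carries per-molecule Bernoulli methylation at each cytosine of the
#' group's strand followed by bisulfite conversion of unmethylated
#' cytosines (`C -> T` on `+`, `G -> A` on `-`; both reads are written in
#' forward-reference orientation). Sequencing errors are applied to both
#' ends, and each record's coordinate hint is its true start plus uniform
#' jitter. Duplicate groups re-emit a previous group's molecule — same
#' realized methylation, fresh errors and jitter — immediately after their
#' source. The truth table records each original molecule's contribution to
#' per-site realized counts (duplicates deliberately excluded: the pipeline
#' is expected to collapse them).
#'
#' @param ref a `flat_reference` from [simulate_reference()].
#' @param states state map from [assign_methylation_states()].
#' @param params the same [simulation_params()].
#' @return list: `records` (target data.frame, ID-sorted, with `treated`
#'   column), `truth_sites` (states plus `realized_m`, `realized_total`),
#'   `truth_groups` (per group: true locus, strand, `duplicate_of`).
#' @export
simulate_read_pairs <- function(ref, states, params) {
  stopifnot(inherits(ref, "flat_reference"),
            inherits(params, "simulation_params"))
  set.seed(.sim_seed(params, 3L))
  rl <- params$read_length
  span <- 2L * rl + params$pair_gap
  if (any(ref$lengths < span))
    stop("read pair span (", span, ") exceeds a chromosome length")
  n_dup <- floor(params$duplicate_fraction * params$n_groups)
  n_orig <- params$n_groups - n_dup
  if (n_orig < 1L) stop("duplicate_fraction leaves no original groups")
  # which original groups get a duplicate emitted right after them
  dup_src <- if (n_dup > 0L) sort(sample.int(n_orig, n_dup)) else integer(0)

  states_key <- paste(states$chrom, states$position, states$strand,
                      sep = "\r")
  realized_m <- integer(nrow(states))
  realized_tot <- integer(nrow(states))

  rec_rows <- list(); grp_rows <- list()
  next_id <- 0L
  emit_group <- function(mol, dup_of) {
    next_id <<- next_id + 1L
    id <- next_id
    jit <- function() if (params$hint_jitter > 0L)
      sample(seq(-params$hint_jitter, params$hint_jitter), 1L) else 0L
    u_hint <- max(1L, min(ref$lengths[[mol$chrom]], mol$u_start + jit()))
    t_hint <- max(1L, min(ref$lengths[[mol$chrom]], mol$t_start + jit()))
    u_seq <- .apply_errors(mol$u_seq, params$sequencing_error_rate)
    t_seq <- .apply_errors(mol$t_seq, params$sequencing_error_rate)
    rec_rows[[length(rec_rows) + 1L]] <<- data.frame(
      group_id = id,
      sequence = c(u_seq, t_seq), strand = mol$strand, chrom = mol$chrom,
      coord = c(u_hint, t_hint), treated = c(FALSE, TRUE),
      stringsAsFactors = FALSE)
    grp_rows[[length(grp_rows) + 1L]] <<- data.frame(
      group_id = id, chrom = mol$chrom, strand = mol$strand,
      u_start = mol$u_start, t_start = mol$t_start,
      duplicate_of = dup_of, stringsAsFactors = FALSE)
    id
  }

  # original molecules occupy distinct loci: a (chrom, strand, start) is
  # drawn without replacement, so identical mapped coordinates identify
  # planted PCR duplicates and nothing else
  pool <- do.call(rbind, lapply(ref$chrom_names, function(nm)
    expand.grid(chrom = nm, strand = c("+", "-"),
                u_start = seq_len(ref$lengths[[nm]] - span + 1L),
                stringsAsFactors = FALSE)))
  if (n_orig > nrow(pool))
    stop("n_groups exceeds the number of distinct read-pair loci (",
         nrow(pool), ")")
  pool <- pool[sample.int(nrow(pool), n_orig), , drop = FALSE]
  for (g in seq_len(n_orig)) {
    chrom <- pool$chrom[g]
    strand <- pool$strand[g]
    u_start <- pool$u_start[g]
    t_start <- u_start + rl + params$pair_gap
    real <- .realize_molecule(ref, states_key, states$true_level, chrom,
                              t_start, rl, strand, params$conversion_rate)
    mol <- list(chrom = chrom, strand = strand, u_start = u_start,
                t_start = t_start,
                u_seq = ref_bases(ref, chrom, u_start, u_start + rl - 1L),
                t_seq = real$seq)
    # originals count toward the realized per-site truth
    idx <- match(paste(chrom, real$site_pos, strand, sep = "\r"),
                 states_key)
    realized_tot[idx] <- realized_tot[idx] + 1L
    realized_m[idx] <- realized_m[idx] + as.integer(real$site_meth)
    src_id <- emit_group(mol, NA_integer_)
    if (g %in% dup_src) emit_group(mol, src_id)
  }

  records <- do.call(rbind, rec_rows)
  rownames(records) <- NULL
  truth_sites <- states
  truth_sites$realized_m <- realized_m
  truth_sites$realized_total <- realized_tot
  truth_groups <- do.call(rbind, grp_rows)
  rownames(truth_groups) <- NULL
  list(records = records, truth_sites = truth_sites,
       truth_groups = truth_groups)
}

#' Generate a complete in-memory fixture
#'
#' @param params a [simulation_params()].
#' @return list: `ref`, `states`, `records`, `truth_sites`, `truth_groups`.
#' @export
simulate_dataset <- function(params) {
  ref <- simulate_reference(params)
  states <- assign_methylation_states(ref, params)
  rp <- simulate_read_pairs(ref, states, params)
  c(list(ref = ref, states = states), rp)
}

#' Materialise a fixture on disk
#'
#' Writes the flattened reference (`reference.fa`), the target file
#' (`targets.txt`, six-column format with explicit T/U markers), the truth
#' tables (`truth_sites.tsv`, `truth_groups.tsv`) and the parameters used
#' (`params.tsv`). Deterministic: the same parameters produce byte-identical
#' files.
#'
#' @param params a [simulation_params()].
#' @param output_dir directory to create/write.
#' @return named vector of file paths, invisibly.
#' @export
write_fixture <- function(params, output_dir) {
  sim <- simulate_dataset(params)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reference = file.path(output_dir, "reference.fa"),
             targets = file.path(output_dir, "targets.txt"),
             truth_sites = file.path(output_dir, "truth_sites.tsv"),
             truth_groups = file.path(output_dir, "truth_groups.tsv"),
             params = file.path(output_dir, "params.tsv"))
  write_flat_reference(sim$ref, paths[["reference"]])
  writeLines(format_target_lines(sim$records), paths[["targets"]])
  write.table(sim$truth_sites, paths[["truth_sites"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth_groups, paths[["truth_groups"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  pv <- unlist(params)
  write.table(data.frame(param = names(pv), value = as.character(pv)),
              paths[["params"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
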