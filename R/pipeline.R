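#' Pipeline configuration
#'
#' @param window_radius half-width in bases of the re-alignment window cut
#'   around each coordinate hint (default 1000, i.e. the read is re-aligned
#'   within roughly 1000 bp either side of its preliminary location).
#' @param chunk_size target records imported per concentrated IO pass
#'   (default two million).
#' @param min_score_fraction acceptance threshold: every member of a group
#'   must reach at least this fraction of its maximum attainable score
#'   (read length x match score). Default 0.6.
#' @param scheme base [scoring_scheme()]; its `conversion_mode` is
#'   overridden per record (none for untreated anchors, strand-appropriate
#'   conversion for treated ends).
#' @param n_workers number of parallel workers. The output contract
#'   guarantees byte-identical reports for any value.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(window_radius = 1000L, chunk_size = 2000000L,
                            min_score_fraction = 0.6,
                            scheme = scoring_scheme(), n_workers = 1L) {
  window_radius <- as.integer(window_radius)
  chunk_size <- as.integer(chunk_size)
  n_workers <- as.integer(n_workers)
  stopifnot(inherits(scheme, "scoring_scheme"))
  if (is.na(window_radius) || window_radius < 1L)
    stop("window_radius must be >= 1")
  if (is.na(chunk_size) || chunk_size < 1L) stop("chunk_size must be >= 1")
  if (!is.numeric(min_score_fraction) || min_score_fraction <= 0 ||
      min_score_fraction > 1)
    stop("min_score_fraction must be in (0, 1]")
  if (is.na(n_workers) || n_workers < 1L) stop("n_workers must be >= 1")
  structure(list(window_radius = window_radius, chunk_size = chunk_size,
                 min_score_fraction = min_score_fraction, scheme = scheme,
                 n_workers = n_workers),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_config> radius=%d chunk=%d threshold=%g ",
                     "workers=%d\n"),
              x$window_radius, x$chunk_size, x$min_score_fraction,
              x$n_workers))
  print(x$scheme)
  invisible(x)
}

#' Read a key=value pipeline configuration file
#'
#' Lines of the form `key = value` (or `key=value`), `#` comments allowed.
#' Recognised keys mirror the CLI flags: window_radius, chunk_size,
#' min_score_fraction, n_workers, match, mismatch, gap. Values supplied in
#' `overrides` (e.g. parsed command-line flags) take precedence.
#'
#' @param path config file path, or `NULL` for defaults only.
#' @param overrides named list of values overriding the file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- lines[grepl("=", lines, fixed = TRUE)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      key <- trimws(kv[[1L]])
      val <- trimws(paste(kv[-1L], collapse = "="))
      known <- c("window_radius", "chunk_size", "min_score_fraction",
                 "n_workers", "match", "mismatch", "gap")
      if (!key %in% known)
        stop("unknown configuration key '", key, "' in ", path)
      vals[[key]] <- as.numeric(val)
    }
  }
  vals[names(overrides)] <- overrides
  get_or <- function(key, default) if (is.null(vals[[key]])) default else
    vals[[key]]
  pipeline_config(
    window_radius = get_or("window_radius", 1000L),
    chunk_size = get_or("chunk_size", 2000000L),
    min_score_fraction = get_or("min_score_fraction", 0.6),
    scheme = scoring_scheme(match = get_or("match", 2L),
                            mismatch = get_or("mismatch", -3L),
                            gap = get_or("gap", -2L)),
    n_workers = get_or("n_workers", 1L))
}

#' Split ID-sorted records into groups
#'
#' One group per maximal run of records sharing a group ID, preserving file
#' order. The input must keep equal IDs contiguous (the target format orders
#' records by ID); a duplicate ID reappearing after other IDs is an error,
#' because such records could silently end up in different groups — and
#' hence different workers — breaking the rule that same-ID records are
#' processed together.
#'
#' @param records record data.frame ([read_targets()] /
#'   [read_target_chunks()]).
#' @return list of record data.frames, one per group.
#' @export
group_records <- function(records) {
  if (nrow(records) == 0L) return(list())
  ids <- records$group_id
  run_start <- c(TRUE, ids[-1L] != ids[-length(ids)])
  run_id <- cumsum(run_start)
  firsts <- which(run_start)
  dup <- duplicated(ids[firsts])
  if (any(dup)) {
    bad_id <- ids[firsts][dup][1L]
    at <- which(ids == bad_id)
    where <- if (!is.null(records$line))
      paste0("lines ", records$line[at[1L]], " and ",
             records$line[at[length(at)]])
    else paste0("records ", at[1L], " and ", at[length(at)])
    stop("group ID ", bad_id, " is not contiguous (", where, ")")
  }
  out <- split(records, run_id)
  names(out) <- NULL
  lapply(out, function(g) { rownames(g) <- NULL; g })
}

#' Cut the re-alignment window around a coordinate hint
#'
#' The window spans `[max(1, coord - radius), min(length, coord + radius)]`
#' (1-based inclusive) — up to `radius` bases either side of the preliminary
#' location — and is truncated silently at chromosome ends.
#'
#' @param ref a `flat_reference`.
#' @param chrom chromosome name.
#' @param coord 1-based coordinate hint.
#' @param radius window half-width in bases.
#' @return list with `window` (base string) and `window_offset` (1-based
#'   genome coordinate of the window's first base).
#' @export
extract_window <- function(ref, chrom, coord, radius) {
  stopifnot(inherits(ref, "flat_reference"))
  if (!chrom %in% ref$chrom_names) stop("unknown chromosome: ", chrom)
  len <- ref$lengths[[chrom]]
  coord <- as.integer(coord)
  if (is.na(coord) || coord < 1L || coord > len)
    stop("coordinate hint ", coord, " out of range for ", chrom,
         " (length ", len, ")")
  lo <- max(1L, coord - as.integer(radius))
  hi <- min(len, coord + as.integer(radius))
  list(window = substr(ref$sequences[[chrom]], lo, hi), window_offset = lo)
}

.record_mode <- function(treated, strand) {
  if (!treated) "none" else if (strand == "+") "c_to_t" else "g_to_a"
}

#' Align and judge one read group
#'
#' Each member is re-aligned in its own hinted window: untreated anchors
#' with plain matching, treated ends with the conversion mode their strand
#' implies. The group's combined score is the sum of member scores, and the
#' group is accepted only if every member reaches the threshold
#' `min_score_fraction * read length * match score` — a failed untreated
#' anchor means the location hint itself is unreliable, so the treated end's
#' calls cannot be trusted either. Methylation calls are extracted from the
#' treated members of accepted groups only.
#'
#' @param group one group's records (from [group_records()]).
#' @param ref a `flat_reference`.
#' @param config a [pipeline_config()].
#' @return a `group_result`: `group_id`, `alignments` (list), per-member
#'   `scores` and `thresholds`, `combined_score`, `accepted`, `dedup_key`
#'   (chrom/genome span/strand of the first treated member; `NA` until the
#'   group is accepted and has a treated member), `calls` (data.frame or
#'   `NULL`).
#' @export
process_group <- function(group, ref, config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(group) || nrow(group) == 0L)
    stop("process_group requires a non-empty group")
  n <- nrow(group)
  alignments <- vector("list", n)
  scores <- integer(n); thresholds <- numeric(n)
  for (k in seq_len(n)) {
    rec <- group[k, ]
    win <- extract_window(ref, rec$chrom, rec$coord, config$window_radius)
    scheme <- config$scheme
    scheme$conversion_mode <- .record_mode(rec$treated, rec$strand)
    al <- align_in_window(rec$sequence, win$window, win$window_offset,
                          scheme)
    alignments[[k]] <- al
    scores[k] <- al$score
    thresholds[k] <- config$min_score_fraction * nchar(rec$sequence) *
      config$scheme$match
  }
  accepted <- all(scores >= thresholds)
  dedup_key <- NA_character_
  calls <- NULL
  treated_idx <- which(group$treated)
  if (accepted && length(treated_idx) > 0L) {
    t1 <- treated_idx[1L]
    al <- alignments[[t1]]
    dedup_key <- paste(group$chrom[t1], al$genome_start, al$genome_end,
                       group$strand[t1], sep = ":")
    call_list <- lapply(treated_idx, function(k)
      call_methylation(alignments[[k]], group[k, ], ref))
    calls <- do.call(rbind, call_list)
  }
  structure(list(group_id = group$group_id[1L], alignments = alignments,
                 scores = scores, thresholds = thresholds,
                 combined_score = sum(scores), accepted = accepted,
                 dedup_key = dedup_key, calls = calls),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result> id=%d members=%d combined=%d %s\n",
              x$group_id, length(x$alignments), x$combined_score,
              if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

#' Collapse PCR duplicates
#'
#' Groups whose treated ends map to exactly the same genomic span and strand
#' are taken to be amplification copies of one original molecule; keeping
#' them all would count the same molecule several times. Among results
#' sharing a dedup key, the one with the highest combined score survives;
#' ties are broken by the smallest group ID, so the outcome is
#' deterministic. Results without a dedup key (no treated member) pass
#' through untouched. Idempotent.
#'
#' @param results list of accepted `group_result`s.
#' @return filtered list, in original order.
#' @export
remove_duplicates <- function(results) {
  if (length(results) == 0L) return(results)
  keys <- vapply(results, function(r) r$dedup_key, character(1L))
  scores <- vapply(results, function(r) r$combined_score, numeric(1L))
  ids <- vapply(results, function(r) as.numeric(r$group_id), numeric(1L))
  keep <- rep(TRUE, length(results))
  for (key in unique(keys[!is.na(keys)])) {
    at <- which(!is.na(keys) & keys == key)
    if (length(at) < 2L) next
    best <- at[order(-scores[at], ids[at])][1L]
    keep[setdiff(at, best)] <- FALSE
  }
  results[keep]
}

#' Partition groups contiguously across workers
#'
#' Groups are dealt to workers as contiguous slices (no group is ever
#' split), balancing by record count: each partition takes whole groups
#' until its record count reaches the ceiling of remaining records over
#' remaining workers. Under this greedy rule no partition exceeds
#' `ceiling(total / n_workers) + (largest group size - 1)` records. Workers
#' beyond the number of groups receive empty partitions.
#'
#' @param groups list of groups ([group_records()]).
#' @param n_workers number of partitions.
#' @return list of `n_workers` lists of groups; concatenating them restores
#'   the original group order.
#' @export
partition_groups <- function(groups, n_workers) {
  n_workers <- as.integer(n_workers)
  if (is.na(n_workers) || n_workers < 1L) stop("n_workers must be >= 1")
  sizes <- vapply(groups, nrow, integer(1L))
  parts <- vector("list", n_workers)
  i <- 1L
  remaining <- sum(sizes)
  for (w in seq_len(n_workers)) {
    quota <- ceiling(remaining / (n_workers - w + 1L))
    taken <- 0L; first <- i
    while (i <= length(groups) && taken < quota) {
      taken <- taken + sizes[i]
      i <- i + 1L
    }
    parts[[w]] <- if (i > first) groups[first:(i - 1L)] else list()
    remaining <- remaining - taken
  }
  parts
}

.process_partition <- function(part, ref, config) {
  lapply(part, function(g) {
    tryCatch(process_group(g, ref, config),
             error = function(e)
               structure(list(group_id = g$group_id[1L], alignments = list(),
                              scores = integer(0), thresholds = numeric(0),
                              combined_score = 0L, accepted = FALSE,
                              dedup_key = NA_character_, calls = NULL,
                              error = conditionMessage(e)),
                         class = "group_result"))
  })
}

#' Run the full methylation-calling pipeline
#'
#' For each input chunk: group the records, partition the groups across
#' workers, align and judge every group, collapse PCR duplicates among the
#' chunk's accepted results, and merge the surviving methylation calls into
#' the genome-wide counters. After the last chunk the CX-style and bedGraph
#' reports and a run summary are written. The output contract: reports are
#' byte-identical for any `n_workers >= 1` and any legal `chunk_size` —
#' parallel execution is an optimisation, never a change in results. The
#' pipeline itself uses no randomness.
#'
#' Per-group failures (bad chromosome, hint out of range) reject the group
#' and are counted in the summary; they never abort the run.
#'
#' @param reference path to a (flattened or ordinary) FASTA reference, or a
#'   `flat_reference` object.
#' @param targets path to the target-record file.
#' @param output_dir directory for reports and summary.
#' @param config a [pipeline_config()].
#' @param quiet suppress per-chunk progress messages.
#' @return Invisibly, a list: `counts` (`methylation_counts`), `summary`
#'   (named integer vector: groups_seen, groups_accepted, groups_rejected,
#'   groups_failed, duplicates_removed, calls_emitted), and the report file
#'   paths.
#' @export
run_pipeline <- function(reference, targets, output_dir,
                         config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  ref <- if (inherits(reference, "flat_reference")) reference else
    load_flat_reference(reference)
  reader <- read_target_chunks(targets, chunk_size = config$chunk_size)
  counts <- methylation_counts()
  seen_ids <- new.env(parent = emptyenv())
  tally <- c(groups_seen = 0L, groups_accepted = 0L, groups_rejected = 0L,
             groups_failed = 0L, duplicates_removed = 0L,
             calls_emitted = 0L)
  chunk_no <- 0L
  repeat {
    chunk <- reader$next_chunk()
    if (is.null(chunk)) break
    chunk_no <- chunk_no + 1L
    groups <- group_records(chunk)
    # cross-chunk contiguity: an ID may not reappear in a later chunk
    for (g in groups) {
      id <- as.character(g$group_id[1L])
      if (!is.null(seen_ids[[id]]))
        stop("group ID ", id, " reappears in chunk ", chunk_no,
             " (line ", g$line[1L], "); input must keep equal IDs ",
             "contiguous")
      seen_ids[[id]] <- TRUE
    }
    parts <- partition_groups(groups, config$n_workers)
    results <- if (config$n_workers == 1L)
      .process_partition(parts[[1L]], ref, config)
    else
      unlist(parallel::mclapply(parts, .process_partition, ref = ref,
                                config = config,
                                mc.cores = config$n_workers,
                                mc.preschedule = TRUE),
             recursive = FALSE)
    tally["groups_seen"] <- tally["groups_seen"] + length(results)
    failed <- vapply(results, function(r) !is.null(r$error), logical(1L))
    tally["groups_failed"] <- tally["groups_failed"] + sum(failed)
    accepted <- results[vapply(results, function(r) r$accepted,
                               logical(1L))]
    tally["groups_rejected"] <- tally["groups_rejected"] +
      sum(!failed) - length(accepted)
    surviving <- remove_duplicates(accepted)
    tally["duplicates_removed"] <- tally["duplicates_removed"] +
      length(accepted) - length(surviving)
    tally["groups_accepted"] <- tally["groups_accepted"] +
      length(surviving)
    calls <- do.call(rbind, lapply(surviving, function(r) r$calls))
    if (!is.null(calls)) {
      tally["calls_emitted"] <- tally["calls_emitted"] + nrow(calls)
      counts <- aggregate_calls(calls, counts)
    }
    if (!quiet)
      message(sprintf(
        "chunk %d: %d record(s), %d group(s), %d accepted, %d duplicate(s)",
        chunk_no, nrow(chunk), length(results), length(surviving),
        length(accepted) - length(surviving)))
  }
  files <- write_methylation_report(counts, ref, output_dir)
  summary_path <- file.path(output_dir, "summary.txt")
  writeLines(paste0(names(tally), "\t", tally), summary_path)
  if (!quiet)
    message(sprintf(
      "done: %d group(s) seen, %d accepted, %d call(s) emitted",
      tally[["groups_seen"]], tally[["groups_accepted"]],
      tally[["calls_emitted"]]))
  invisible(list(counts = counts, summary = tally,
                 files = c(files, summary = summary_path)))
}
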