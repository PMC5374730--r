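#' Flatten a multi-FASTA reference
#'
#' Reads a multi-FASTA reference and stores each chromosome as one contiguous
#' uppercase string, so that any base can later be addressed by coordinate in
#' constant time and windows can be cut with a plain substring. Line breaks
#' are removed while the 1-based coordinate of every base is preserved
#' exactly; any line width is accepted (references are commonly wrapped at
#' 50 or 60 bp). Lowercase bases are uppercased and characters outside
#' A/C/G/T/N (e.g. IUPAC ambiguity codes) are mapped to N with a warning.
#'
#' @param fasta_source path to a FASTA file.
#' @return An object of class `flat_reference`: list with `chrom_names`,
#'   `sequences` (named character vector, one unbroken string per
#'   chromosome) and `lengths` (named integer vector).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTA", "CGT"), fa)
#' ref <- flatten_reference(fa)
#' ref$sequences[["chr1"]]  # "ACGTACGT"
#' @export
flatten_reference <- function(fasta_source) {
  lines <- readLines(fasta_source, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA input: ", fasta_source)
  if (!startsWith(lines[[1L]], ">"))
    stop("sequence data before first FASTA header (line 1: '",
         substr(lines[[1L]], 1L, 40L), "')")
  set <- Biostrings::readBStringSet(fasta_source)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    stop("duplicate chromosome name in FASTA: ", nm[duplicated(nm)][1L])
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  n_other <- sum(vapply(seqs, function(s)
    nchar(s) - nchar(gsub("[^ACGTN]", "", s)), integer(1L)))
  if (n_other > 0L) {
    warning(n_other, " base(s) outside A/C/G/T/N mapped to N")
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1L))
  }
  new_flat_reference(seqs)
}

new_flat_reference <- function(sequences) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  structure(list(chrom_names = names(sequences),
                 sequences = sequences,
                 lengths = stats::setNames(nchar(sequences),
                                           names(sequences))),
            class = "flat_reference")
}

#' @export
print.flat_reference <- function(x, ...) {
  cat(sprintf("<flat_reference> %d chromosome(s), %d bases total\n",
              length(x$chrom_names), sum(x$lengths)))
  for (nm in utils::head(x$chrom_names, 10L))
    cat(sprintf("  %s  %d bp\n", nm, x$lengths[[nm]]))
  if (length(x$chrom_names) > 10L) cat("  ...\n")
  invisible(x)
}

#' Extract reference bases by coordinate
#'
#' @param ref a `flat_reference`.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates.
#' @return base string.
#' @export
ref_bases <- function(ref, chrom, start, end) {
  stopifnot(inherits(ref, "flat_reference"))
  if (!chrom %in% ref$chrom_names) stop("unknown chromosome: ", chrom)
  len <- ref$lengths[[chrom]]
  if (any(start < 1L) || any(end > len) || any(end < start))
    stop("coordinates ", start, "..", end, " out of range for ", chrom,
         " (length ", len, ")")
  substr(ref$sequences[[chrom]], start, end)
}

#' Write a flattened reference
#'
#' One header line and one unbroken sequence line per chromosome; the file
#' round-trips losslessly through [load_flat_reference()] (or indeed
#' [flatten_reference()], since it is valid FASTA). Loading a one-line-per-
#' chromosome file avoids per-line reassembly and is the fast path for
#' repeated runs.
#'
#' @param ref a `flat_reference`.
#' @param destination output path.
#' @return `destination`, invisibly.
#' @export
write_flat_reference <- function(ref, destination) {
  stopifnot(inherits(ref, "flat_reference"))
  con <- file(destination, open = "wb")
  on.exit(close(con))
  for (nm in ref$chrom_names)
    writeLines(c(paste0(">", nm), ref$sequences[[nm]]), con, sep = "\n")
  invisible(destination)
}

#' Load a flattened reference file
#'
#' @param path file written by [write_flat_reference()] (any FASTA works).
#' @return a `flat_reference`.
#' @export
load_flat_reference <- function(path) flatten_reference(path)

.parse_strand <- function(x, line_no) {
  bad <- !x %in% c("+", "-")
  if (any(bad))
    stop("line ", line_no[which(bad)[1L]], ": illegal strand symbol '",
         x[which(bad)[1L]], "' (must be + or -)")
  x
}

#' Parse target-record lines
#'
#' A target file carries one read per line in five whitespace-separated
#' columns: integer group ID (records sharing an ID form one group, a read
#' pair), read sequence, strand (`+`/`-`), chromosome, and a 1-based
#' coordinate hint locating the read approximately in the reference. An
#' optional sixth column `T`/`U` marks the record as the bisulfite-treated
#' end or the untreated anchor end; when it is absent the first record of
#' each group is taken as the untreated anchor and the rest as treated
#' (applied by [read_target_chunks()], which sees whole groups).
#'
#' @param lines character vector of data lines.
#' @param first_line line number of `lines[1]` in the file, for error
#'   messages.
#' @return data.frame with columns `group_id` (integer), `sequence`,
#'   `strand`, `chrom`, `coord` (integer), `treated` (logical, `NA` when the
#'   sixth column is absent) and `line` (integer line number).
#' @export
parse_target_lines <- function(lines, first_line = 1L) {
  line_no <- seq_along(lines) + first_line - 1L
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]; line_no <- line_no[keep]
  if (length(lines) == 0L)
    return(data.frame(group_id = integer(0), sequence = character(0),
                      strand = character(0), chrom = character(0),
                      coord = integer(0), treated = logical(0),
                      line = integer(0), stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- nf < 5L | nf > 6L
  if (any(bad))
    stop("line ", line_no[which(bad)[1L]], ": expected 5 or 6 columns, got ",
         nf[which(bad)[1L]])
  col <- function(k) vapply(fields, function(f)
    if (length(f) >= k) f[[k]] else NA_character_, character(1L))
  id_chr <- col(1L)
  id <- suppressWarnings(as.integer(id_chr))
  if (anyNA(id) || any(id_chr != as.character(id)))
    stop("line ", line_no[which(is.na(id) | id_chr != as.character(id))[1L]],
         ": non-integer group ID '",
         id_chr[which(is.na(id) | id_chr != as.character(id))[1L]], "'")
  seqs <- toupper(col(2L))
  okseq <- grepl("^[ACGTN]+$", seqs)
  if (!all(okseq))
    stop("line ", line_no[which(!okseq)[1L]],
         ": sequence contains characters outside A/C/G/T/N")
  strand <- .parse_strand(col(3L), line_no)
  chrom <- col(4L)
  coord_chr <- col(5L)
  coord <- suppressWarnings(as.integer(coord_chr))
  badc <- is.na(coord) | coord < 1L
  if (any(badc))
    stop("line ", line_no[which(badc)[1L]], ": coordinate must be a ",
         "positive integer, got '", coord_chr[which(badc)[1L]], "'")
  tu <- col(6L)
  treated <- rep(NA, length(lines))
  has6 <- !is.na(tu)
  if (any(has6)) {
    badt <- has6 & !tu %in% c("T", "U")
    if (any(badt))
      stop("line ", line_no[which(badt)[1L]],
           ": sixth column must be T (treated) or U (untreated), got '",
           tu[which(badt)[1L]], "'")
    treated[has6] <- tu[has6] == "T"
  }
  data.frame(group_id = id, sequence = seqs, strand = strand, chrom = chrom,
             coord = coord, treated = treated, line = line_no,
             stringsAsFactors = FALSE)
}

#' @rdname parse_target_lines
#' @param line a single line of text.
#' @param line_number its line number in the file.
#' @return `parse_target_line()`: a one-row data.frame (one target record).
#' @examples
#' parse_target_line("7 ACGTT + chr2 1204 T")
#' @export
parse_target_line <- function(line, line_number = 1L) {
  rec <- parse_target_lines(line, first_line = line_number)
  if (nrow(rec) != 1L) stop("line ", line_number, ": empty record")
  rec
}

#' Serialise target records back to text lines
#'
#' @param records data.frame as produced by [parse_target_lines()].
#' @return character vector of lines.
#' @export
format_target_lines <- function(records) {
  tu <- ifelse(is.na(records$treated), "",
               ifelse(records$treated, " T", " U"))
  paste0(records$group_id, " ", records$sequence, " ", records$strand, " ",
         records$chrom, " ", records$coord, tu)
}

# Default treated/untreated designation when the file has no sixth column:
# within each ID run the first record in file order is the untreated anchor,
# later records are treated.
fill_treated_defaults <- function(records) {
  na <- is.na(records$treated)
  if (!any(na)) return(records)
  first_of_run <- c(TRUE, records$group_id[-1L] !=
                      records$group_id[-nrow(records)])
  records$treated[na] <- !first_of_run[na]
  records
}

#' Chunked reader for target files
#'
#' Reads a target file in chunks of roughly `chunk_size` records, in a single
#' concentrated IO pass per chunk rather than line-by-line, so the pipeline
#' never holds more than one chunk in memory. Nominal cut points lie at
#' absolute multiples of `chunk_size`; each cut is moved back to the nearest
#' preceding group boundary so that no chunk splits a run of records sharing
#' a group ID (boundary records are deferred to the next chunk). The
#' concatenation of all chunks reproduces the file's records in order for
#' any legal `chunk_size`. A group occupying an entire nominal chunk window
#' (i.e. larger than `chunk_size`) is a hard error.
#'
#' @param path target file path.
#' @param chunk_size records per chunk (default two million).
#' @return A reader object; call `reader$next_chunk()` to obtain the next
#'   chunk as a record data.frame (with treated/untreated defaults filled
#'   in), or `NULL` at end of file.
#' @examples
#' tf <- tempfile()
#' writeLines(c("1 ACGT + chr1 10", "1 TTTT + chr1 60",
#'              "2 GGGG - chr1 99"), tf)
#' r <- read_target_chunks(tf, chunk_size = 2)
#' nrow(r$next_chunk())  # 2: the run of ID 1
#' @export
read_target_chunks <- function(path, chunk_size = 2000000L) {
  chunk_size <- as.integer(chunk_size)
  if (is.na(chunk_size) || chunk_size < 1L) stop("chunk_size must be >= 1")
  con <- file(path, open = "r")
  env <- new.env(parent = emptyenv())
  env$pending <- NULL         # parsed but unemitted records
  env$line_no <- 0L           # lines consumed from the file
  env$emitted <- 0L           # records emitted so far (absolute index)
  env$nchunks <- 0L           # chunks emitted so far
  env$eof <- FALSE
  env$closed <- FALSE

  abort <- function(...) {
    if (!env$closed) { close(con); env$closed <- TRUE }
    stop(...)
  }

  fetch <- function(n_lines) {
    lines <- readLines(con, n = n_lines, warn = FALSE)
    if (length(lines) < n_lines) env$eof <- TRUE
    if (length(lines) > 0L) {
      recs <- tryCatch(
        parse_target_lines(lines, first_line = env$line_no + 1L),
        error = function(e) abort(conditionMessage(e)))
      env$line_no <- env$line_no + length(lines)
      env$pending <- if (is.null(env$pending)) recs else
        rbind(env$pending, recs)
    }
    invisible(NULL)
  }

  next_chunk <- function() {
    if (env$closed) return(NULL)
    # nominal cut = absolute record index (nchunks + 1) * chunk_size,
    # expressed relative to the pending buffer
    target <- (env$nchunks + 1L) * chunk_size - env$emitted
    # need one record past the nominal cut to locate the run boundary
    repeat {
      np <- if (is.null(env$pending)) 0L else nrow(env$pending)
      if (env$eof || np >= target + 1L) break
      fetch(max(target + 1L - np, 1024L))
    }
    np <- if (is.null(env$pending)) 0L else nrow(env$pending)
    if (np == 0L) {
      close(con); env$closed <- TRUE
      return(NULL)
    }
    env$nchunks <- env$nchunks + 1L
    if (env$eof && np <= target) {
      out <- env$pending; env$pending <- NULL
      env$emitted <- env$emitted + nrow(out)
      close(con); env$closed <- TRUE
      return(fill_treated_defaults(out))
    }
    # largest group boundary at or before the nominal cut
    ids <- env$pending$group_id
    cut <- target
    while (cut >= 1L && ids[cut + 1L] == ids[cut]) cut <- cut - 1L
    if (cut == 0L)
      abort("group ", ids[1L], " spans more than chunk_size = ",
            chunk_size, " records; increase chunk_size")
    out <- env$pending[seq_len(cut), , drop = FALSE]
    env$pending <- env$pending[-seq_len(cut), , drop = FALSE]
    rownames(env$pending) <- NULL
    env$emitted <- env$emitted + cut
    fill_treated_defaults(out)
  }

  structure(list(next_chunk = next_chunk, path = path,
                 chunk_size = chunk_size),
            class = "target_chunk_reader")
}

#' Read an entire target file
#'
#' @param path target file path.
#' @return record data.frame with treated/untreated defaults filled in.
#' @export
read_targets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fill_treated_defaults(parse_target_lines(lines))
}

#' Write methylation reports
#'
#' Serialises aggregated per-cytosine counts as (a) a CX-style
#' tab-separated table (chrom, 1-based position, strand of the cytosine,
#' trinucleotide context, methylated count, unmethylated count), sorted by
#' reference chromosome order, position, then strand; and (b) a bedGraph of
#' methylation level m/(m+u) over 0-based half-open single-base intervals,
#' restricted to positions with at least one observation. Output is
#' byte-deterministic: the same counts always produce the same files.
#'
#' @param counts a `methylation_counts` object.
#' @param ref the `flat_reference` the counts refer to (bounds check and
#'   chromosome order).
#' @param output_dir directory to write into (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the two file paths, invisibly.
#' @export
write_methylation_report <- function(counts, ref, output_dir,
                                     prefix = "methylation") {
  stopifnot(inherits(counts, "methylation_counts"),
            inherits(ref, "flat_reference"))
  df <- as.data.frame(counts)
  if (nrow(df) > 0L) {
    if (!all(df$chrom %in% ref$chrom_names))
      stop("counts refer to unknown chromosome: ",
           setdiff(df$chrom, ref$chrom_names)[1L])
    over <- df$position > ref$lengths[df$chrom] | df$position < 1L
    if (any(over))
      stop("count position ", df$position[which(over)[1L]], " on ",
           df$chrom[which(over)[1L]], " outside reference bounds ",
           "(upstream coordinate bug)")
    ord <- order(match(df$chrom, ref$chrom_names), df$position,
                 match(df$strand, c("+", "-")))
    df <- df[ord, , drop = FALSE]
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  cx_path <- file.path(output_dir, paste0(prefix, "_cx.tsv"))
  bg_path <- file.path(output_dir, paste0(prefix, ".bedGraph"))
  header <- paste("chrom", "position", "strand", "context",
                  "count_methylated", "count_unmethylated", sep = "\t")
  cx_lines <- c(header, if (nrow(df) > 0L)
    paste(df$chrom, df$position, df$strand, df$context,
          df$count_methylated, df$count_unmethylated, sep = "\t"))
  writeLines(cx_lines, cx_path, sep = "\n")
  cov <- df[df$count_methylated + df$count_unmethylated > 0L, , drop = FALSE]
  bg_lines <- if (nrow(cov) > 0L)
    paste(cov$chrom, cov$position - 1L, cov$position,
          sprintf("%.6g", cov$count_methylated /
                    (cov$count_methylated + cov$count_unmethylated)),
          sep = "\t") else character(0)
  writeLines(bg_lines, bg_path, sep = "\n")
  invisible(c(cx = cx_path, bedgraph = bg_path))
}
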