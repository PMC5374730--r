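#' Classify the trinucleotide context of a cytosine
#'
#' Bisulfite analyses conventionally bin cytosines by the two downstream
#' bases on the cytosine's own strand: CpG (next base G), CHG (C, then H,
#' then G) and CHH, with H any of A/C/T. On the forward strand the context
#' is read left to right from the reference; on the reverse strand the
#' cytosine sits at a reference G and the context is read right to left on
#' the complement. Positions whose trinucleotide is truncated by the
#' chromosome end default to CHH; an N in the context is treated as H.
#' Vectorised over `position`/`strand`.
#'
#' @param ref a `flat_reference`.
#' @param chrom chromosome name.
#' @param position 1-based forward-reference coordinate(s); must hold a C
#'   (strand `+`) or a G (strand `-`).
#' @param strand `"+"` or `"-"`, recycled against `position`.
#' @return character vector over `"CpG"`, `"CHG"`, `"CHH"`.
#' @examples
#' ref <- bsrealign:::new_flat_reference(c(chr1 = "ACGT"))
#' classify_context(ref, "chr1", 2, "+")  # CpG
#' classify_context(ref, "chr1", 3, "-")  # CpG (reverse-strand mirror)
#' @export
classify_context <- function(ref, chrom, position, strand) {
  stopifnot(inherits(ref, "flat_reference"))
  if (!chrom %in% ref$chrom_names) stop("unknown chromosome: ", chrom)
  n <- length(position)
  strand <- rep_len(strand, n)
  len <- ref$lengths[[chrom]]
  if (any(position < 1L | position > len))
    stop("position outside chromosome ", chrom, " (length ", len, ")")
  seq <- ref$sequences[[chrom]]
  base_at <- function(p) {
    out <- rep(NA_character_, length(p))
    ok <- p >= 1L & p <= len
    if (any(ok)) out[ok] <- substring(seq, p[ok], p[ok])
    out
  }
  b0 <- base_at(position)
  plus <- strand == "+"
  if (any(plus & b0 != "C") || any(!plus & b0 != "G"))
    stop("position is not a cytosine on the requested strand ",
         "(expected C on + / G on -)")
  step <- ifelse(plus, 1L, -1L)
  b1 <- base_at(position + step)
  b2 <- base_at(position + 2L * step)
  # the base that closes CpG/CHG is G on + and (complemented) C on -
  closer <- ifelse(plus, "G", "C")
  ctx <- rep("CHH", n)
  ctx[!is.na(b1) & b1 == closer] <- "CpG"
  chg <- is.na(match(ctx, "CpG")) & !is.na(b2) & b2 == closer &
    !is.na(b1) & b1 != closer
  ctx[chg] <- "CHG"
  ctx
}

#' Empty per-cytosine counter set
#'
#' The genome-wide counter structure ("overall array") into which every
#' worker's methylation calls are merged: a sparse table keyed by
#' (chromosome, position, strand) holding methylated and unmethylated
#' observation counts, zero by default.
#'
#' @return a `methylation_counts` object.
#' @export
methylation_counts <- function() {
  structure(data.frame(chrom = character(0), position = integer(0),
                       strand = character(0), context = character(0),
                       count_methylated = integer(0),
                       count_unmethylated = integer(0),
                       stringsAsFactors = FALSE),
            class = c("methylation_counts", "data.frame"))
}

#' @export
print.methylation_counts <- function(x, ...) {
  m <- sum(x$count_methylated); u <- sum(x$count_unmethylated)
  cat(sprintf(
    "<methylation_counts> %d position(s), %d methylated + %d unmethylated observation(s)\n",
    nrow(x), m, u))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Extract methylation calls from one accepted alignment
#'
#' Walks the aligned columns of a treated read and emits one observation per
#' informative cytosine. Only match/mismatch (diagonal) columns are
#' considered; gapped columns carry no base-level evidence. On the forward
#' strand, at a reference C a read C means the cytosine was protected
#' (methylated) and a read T means it was converted (unmethylated); on the
#' reverse strand the same logic applies at reference G positions with read
#' G/A. Any other read base (a sequencing error or variant) yields no call.
#' Untreated anchor reads are uninformative and must not be passed here.
#'
#' @param alignment a `bs_alignment` with genome coordinates (from
#'   [align_in_window()]).
#' @param record the target record (one-row data.frame) the alignment
#'   belongs to; must be a treated end.
#' @param ref the `flat_reference`.
#' @return data.frame of calls: `chrom`, `position` (1-based forward
#'   coordinate of the cytosine), `strand` (+ for a reference C, - for a
#'   reference G), `context`, `status` (`"methylated"`/`"unmethylated"`).
#' @export
call_methylation <- function(alignment, record, ref) {
  stopifnot(inherits(alignment, "bs_alignment"),
            inherits(ref, "flat_reference"))
  if (!isTRUE(record$treated))
    stop("methylation calls are only defined for bisulfite-treated records")
  empty <- data.frame(chrom = character(0), position = integer(0),
                      strand = character(0), context = character(0),
                      status = character(0), stringsAsFactors = FALSE)
  if (nrow(alignment$pairs) == 0L) return(empty)
  rb <- alignment$pairs[, 1L]; wb <- alignment$pairs[, 2L]
  diag <- rb != "-" & wb != "-"
  # genome coordinate of each alignment column that consumes a window base
  gpos <- alignment$genome_start - 1L + cumsum(wb != "-")
  gpos[wb == "-"] <- NA_integer_
  refseq <- ref$sequences[[record$chrom]]
  refb <- substring(refseq, gpos[diag], gpos[diag])
  if (any(refb != wb[diag]))
    stop("window base disagrees with reference at ", record$chrom, ":",
         gpos[diag][which(refb != wb[diag])[1L]],
         " (alignment/reference inconsistency)")
  if (record$strand == "+") {
    at <- diag & wb == "C"
    meth <- rb == "C"; unmeth <- rb == "T"
  } else {
    at <- diag & wb == "G"
    meth <- rb == "G"; unmeth <- rb == "A"
  }
  keep <- at & (meth | unmeth)
  if (!any(keep)) return(empty)
  pos <- gpos[keep]
  data.frame(chrom = record$chrom, position = pos,
             strand = record$strand,
             context = classify_context(ref, record$chrom, pos,
                                        record$strand),
             status = ifelse(meth[keep], "methylated", "unmethylated"),
             stringsAsFactors = FALSE)
}

#' Merge methylation calls into the global counters
#'
#' Pure increment of the matching (chrom, position, strand) counters. The
#' operation is associative and commutative across call batches: however the
#' calls are split among workers or chunks and in whatever order the batches
#' are flushed, the final counts are identical. This is the property that
#' makes write-through buffering of per-worker results safe.
#'
#' @param calls data.frame of calls from [call_methylation()] (possibly
#'   several row-bound batches).
#' @param counts an existing `methylation_counts` to add to.
#' @return updated `methylation_counts`.
#' @examples
#' ref <- bsrealign:::new_flat_reference(c(chr1 = "AACGTT"))
#' calls <- data.frame(chrom = "chr1", position = 3L, strand = "+",
#'                     context = "CpG",
#'                     status = c("methylated", "methylated",
#'                                "unmethylated"))
#' aggregate_calls(calls)
#' @export
aggregate_calls <- function(calls, counts = methylation_counts()) {
  stopifnot(inherits(counts, "methylation_counts"))
  if (is.null(calls) || nrow(calls) == 0L) return(counts)
  new <- data.frame(chrom = calls$chrom, position = calls$position,
                    strand = calls$strand, context = calls$context,
                    count_methylated = as.integer(
                      calls$status == "methylated"),
                    count_unmethylated = as.integer(
                      calls$status == "unmethylated"),
                    stringsAsFactors = FALSE)
  all <- rbind(as.data.frame(counts), new)
  key <- paste(all$chrom, all$position, all$strand, sep = "\r")
  first <- !duplicated(key)
  sums <- rowsum(cbind(m = all$count_methylated,
                       u = all$count_unmethylated),
                 group = key, reorder = FALSE)
  out <- all[first, c("chrom", "position", "strand", "context")]
  out$count_methylated <- as.integer(sums[, "m"])
  out$count_unmethylated <- as.integer(sums[, "u"])
  # canonical order keeps aggregation results independent of batch order
  ord <- order(out$chrom, out$position, match(out$strand, c("+", "-")))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("methylation_counts", "data.frame"))
}

#' Methylation level at a position
#'
#' m/(m+u) when the position has at least one observation; `NA` (undefined,
#' deliberately distinct from 0) otherwise.
#'
#' @param counts a `methylation_counts`.
#' @param chrom,position,strand the cytosine to query (vectorised).
#' @return numeric vector of levels in `[0, 1]`, `NA` where uncovered.
#' @export
methylation_level <- function(counts, chrom, position, strand) {
  stopifnot(inherits(counts, "methylation_counts"))
  key <- paste(counts$chrom, counts$position, counts$strand, sep = "\r")
  q <- paste(chrom, position, strand, sep = "\r")
  idx <- match(q, key)
  m <- counts$count_methylated[idx]
  u <- counts$count_unmethylated[idx]
  lev <- ifelse(!is.na(idx) & (m + u) > 0L, m / (m + u), NA_real_)
  as.numeric(lev)
}
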