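#' Read transcriptome alignments from SAM/BAM
#'
#' Parses an all-best alignment file produced against a (haplotype-aware)
#' transcriptome reference into a flat alignment table with one row per
#' reported alignment. For paired-end data the two mates of a pair are
#' joined: only pairs with both mates mapped to the same reference sequence
#' are retained, their mismatch counts (NM) are summed to give the pair's
#' mismatch stratum, and the insert size is the absolute outer (TLEN-style)
#' distance. Unmapped reads are skipped.
#'
#' @param path SAM or BAM file, name-grouped (all records of a read
#'   adjacent, as aligners emit them).
#' @param paired Is the data paired-end?
#' @return Tibble with columns `read_id`, `key` (reference sequence name),
#'   `mismatches`, `insert_size` (NA for single-end) and `pos` (leftmost
#'   1-based alignment position, used by the bias model's start counts).
#' @export
read_alignments <- function(path, paired = FALSE) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "isize"), tag = "NM"
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !bitwAnd(x$flag, 4L)  # mapped records only
  if (is.null(x$tag$NM)) x$tag$NM <- rep(NA_integer_, length(x$qname))
  aln <- tibble(
    read_id = x$qname[keep],
    key = as.character(x$rname)[keep],
    flag = x$flag[keep],
    pos = x$pos[keep],
    isize = x$isize[keep],
    nm = x$tag$NM[keep]
  )
  if (nrow(aln) == 0L) {
    return(tibble(read_id = character(), key = character(),
                  mismatches = integer(), insert_size = integer(),
                  pos = integer()))
  }
  if (anyNA(aln$nm)) {
    bad <- aln$read_id[which(is.na(aln$nm))[1]]
    abort(paste0("alignment record for read '", bad,
                 "' lacks an NM (mismatch count) tag"))
  }
  is_paired_rec <- bitwAnd(aln$flag, 1L) > 0L
  if (paired) {
    if (!all(is_paired_rec)) {
      abort("paired = TRUE but the input contains unpaired records")
    }
    first <- bitwAnd(aln$flag, 64L) > 0L
    m1 <- aln[first, ]
    m2 <- aln[!first, ]
    joined <- dplyr::inner_join(
      m1, m2, by = c("read_id", "key"), suffix = c("_1", "_2"),
      relationship = "many-to-many"
    )
    # mates of one pair sit at reflected positions; keep the mate whose TLEN
    # is the negation of ours (standard SAM mate pairing on one reference)
    joined <- filter(joined, .data$isize_1 == -.data$isize_2)
    out <- tibble(
      read_id = joined$read_id,
      key = joined$key,
      mismatches = joined$nm_1 + joined$nm_2,
      insert_size = abs(joined$isize_1),
      pos = pmin(joined$pos_1, joined$pos_2)
    )
  } else {
    if (any(is_paired_rec)) {
      abort("paired = FALSE but the input contains paired records")
    }
    out <- tibble(
      read_id = aln$read_id,
      key = aln$key,
      mismatches = as.integer(aln$nm),
      insert_size = NA_integer_,
      pos = aln$pos
    )
  }
  distinct(out)
}

#' Keep only best-mismatch-stratum alignments
#'
#' For every read (or read pair), retains only the alignments whose mismatch
#' count equals the minimum over that read's alignments. This is what lets a
#' read spanning a heterozygous site discriminate between the two haplotype
#' copies of an isoform: the true haplotype matches with one mismatch fewer
#' than the alternative.
#'
#' @param alignments Alignment tibble (`read_id`, `key`, `mismatches`, ...).
#' @return The filtered alignment tibble.
#' @examples
#' aln <- tibble::tibble(read_id = "r1", key = c("t1", "t2", "t3"),
#'                       mismatches = c(0L, 1L, 1L))
#' best_stratum_filter(aln)
#' @export
best_stratum_filter <- function(alignments) {
  if (nrow(alignments) == 0L) return(alignments)
  alignments |>
    group_by(.data$read_id) |>
    filter(.data$mismatches == min(.data$mismatches)) |>
    ungroup()
}

#' Remove alignments with implausible insert sizes
#'
#' Paired-end only, applied after [best_stratum_filter()]. If at least one of
#' a read pair's alignments has an insert size nearer than `x` bp to the
#' expected insert size, all of that pair's alignments farther than `x` bp
#' from the expected insert size are removed; otherwise the pair's
#' alignments are left untouched. A sensible `x` is one standard deviation
#' of the library's insert-size distribution.
#'
#' @param alignments Alignment tibble with an `insert_size` column.
#' @param expected_insert Expected insert size (bp) of the library.
#' @param x Tolerance in bp (must be positive).
#' @return The filtered alignment tibble.
#' @export
insert_size_filter <- function(alignments, expected_insert, x) {
  if (x <= 0) abort("insert-size tolerance x must be positive")
  if (nrow(alignments) == 0L) return(alignments)
  alignments |>
    group_by(.data$read_id) |>
    mutate(.dev = abs(.data$insert_size - expected_insert)) |>
    filter(!(any(.data$.dev < x) & .data$.dev > x)) |>
    ungroup() |>
    select(-".dev")
}

#' Collapse filtered alignments into transcript-set counts
#'
#' Each retained read maps to the *set* of reference keys it aligns to
#' (duplicate hits of one read to different positions on the same transcript
#' count once). Reads mapping to the same set are pooled, giving the
#' sufficient data for the Poisson model: one row per unique set `i` with
#' its read count `k_i`, the rows of the sparse indicator matrix M.
#'
#' @param alignments Filtered alignment tibble.
#' @return Tibble with one row per unique transcript set, ordered
#'   lexicographically: `set_id`, `transcripts` (list column of sorted
#'   keys), `n_transcripts`, `count`.
#' @export
collect_transcript_sets <- function(alignments) {
  if (nrow(alignments) == 0L) {
    return(tibble(set_id = integer(), transcripts = list(),
                  n_transcripts = integer(), count = integer()))
  }
  per_read <- alignments |>
    distinct(.data$read_id, .data$key) |>
    group_by(.data$read_id) |>
    summarise(.set = paste(sort(.data$key), collapse = "\t"),
              .groups = "drop")
  sets <- per_read |>
    dplyr::count(.data$.set, name = "count") |>
    arrange(.data$.set)
  tibble(
    set_id = seq_len(nrow(sets)),
    transcripts = strsplit(sets$.set, "\t", fixed = TRUE),
    n_transcripts = lengths(strsplit(sets$.set, "\t", fixed = TRUE)),
    count = as.integer(sets$count)
  )
}

#' Write / read the plain-text hits interchange format
#'
#' One stanza per read: a `>read_id` line followed by one reference key per
#' line. This mirrors the intermediate format between alignment filtering
#' and model fitting so the two stages can run as separate processes.
#'
#' @param alignments Filtered alignment tibble.
#' @param path Output path.
#' @return `path` invisibly (writer); alignment tibble with `read_id` and
#'   `key` columns (reader).
#' @export
write_hits <- function(alignments, path) {
  per_read <- alignments |>
    distinct(.data$read_id, .data$key) |>
    arrange(.data$read_id, .data$key)
  chunks <- split(per_read$key, per_read$read_id)
  lines <- unlist(lapply(names(chunks), function(r) {
    c(paste0(">", r), chunks[[r]])
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, ">")
  read_id <- rep(sub("^>", "", lines[is_hdr]), diff(c(which(is_hdr),
                                                      length(lines) + 1L)) - 1L)
  tibble(read_id = read_id, key = lines[!is_hdr],
         mismatches = NA_integer_, insert_size = NA_integer_)
}

#' Write alignments as SAM
#'
#' Emits a minimal single-end SAM file (header plus one record per
#' alignment, NM tag carrying the mismatch count) so that simulated
#' alignments can exercise the SAM input path.
#'
#' @param alignments Tibble with `read_id`, `key`, `mismatches`, and
#'   optionally `pos` and `sequence`.
#' @param reference Transcript reference (for `@SQ` header lines).
#' @param path Output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", reference$key, "\tLN:", reference$true_length))
  pos <- if ("pos" %in% names(alignments)) alignments$pos else 1L
  seqs <- if ("sequence" %in% names(alignments)) alignments$sequence else "*"
  cigar <- ifelse(seqs == "*", "*", paste0(nchar(seqs), "M"))
  qual <- ifelse(seqs == "*", "*", strrep("I", nchar(seqs)))
  rec <- paste(alignments$read_id, 0L, alignments$key, pos, 255L, cigar,
               "*", 0L, 0L, seqs, qual,
               paste0("NM:i:", alignments$mismatches), sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}
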