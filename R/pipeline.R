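#' Run the quantification pipeline end to end
#'
#' Orchestrates the stages in their natural order — optional reference
#' editing (base FASTA + phased variants -> haplotype-aware reference),
#' alignment parsing and filtering (SAM -> transcript-set counts), optional
#' bias adjustment of effective lengths, and EM + Gibbs estimation — each
#' stage resumable from the previous stage's files. Outputs the three
#' estimate tables via [write_estimates()], each carrying provenance
#' headers.
#'
#' @param reference_fasta Path to the (possibly haplotype-aware) reference
#'   FASTA.
#' @param variants Optional path to phased variants (TSV or VCF); when
#'   given, the reference is edited with [apply_haplotypes()] first and the
#'   edited reference written to `<out_prefix>.reference.fa`.
#' @param alignments Path to a SAM/BAM of transcriptome alignments, or an
#'   alignment tibble, or a hits file written by [write_hits()].
#' @param paired Paired-end data?
#' @param read_length Read length in nt.
#' @param expected_insert,insert_sd Insert-size filter parameters; the
#'   filter runs only when both are given (`insert_sd` plays the role of
#'   the tolerance x).
#' @param adjusted_lengths Optional path to a previously computed
#'   adjusted-lengths file to reuse.
#' @param out_prefix Output path prefix.
#' @param seed Integer seed for the Gibbs chain (required).
#' @param ... Further arguments passed to [haplo_quantify()].
#' @return The `haplo_fit`, invisibly; estimate tables are written to
#'   `<out_prefix>.*.tsv`.
#' @export
run_pipeline <- function(reference_fasta, variants = NULL, alignments,
                         paired = FALSE, read_length,
                         expected_insert = NULL, insert_sd = NULL,
                         adjusted_lengths = NULL,
                         out_prefix, seed, ...) {
  if (!file.exists(reference_fasta)) {
    abort(paste0("reference stage: no such FASTA: ", reference_fasta))
  }
  reference <- read_transcript_fasta(reference_fasta)
  if (!is.null(variants)) {
    if (!file.exists(variants)) {
      abort(paste0("reference-editing stage: no such variant file: ", variants))
    }
    v <- read_phased_variants(variants)
    reference <- apply_haplotypes(reference, v)
    write_transcript_fasta(reference, paste0(out_prefix, ".reference.fa"))
  }
  aln <- if (is.data.frame(alignments)) {
    alignments
  } else if (!file.exists(alignments)) {
    abort(paste0("hits stage: no such alignment file: ", alignments))
  } else if (grepl("\\.(sam|bam)$", alignments, ignore.case = TRUE)) {
    read_alignments(alignments, paired = paired)
  } else {
    read_hits(alignments)
  }
  if (!all(is.na(aln$mismatches))) aln <- best_stratum_filter(aln)
  if (paired && !is.null(expected_insert) && !is.null(insert_sd)) {
    aln <- insert_size_filter(aln, expected_insert, insert_sd)
  }
  sets <- collect_transcript_sets(aln)
  lengths <- if (!is.null(adjusted_lengths)) {
    read_adjusted_lengths(adjusted_lengths, reference)
  } else {
    effective_lengths(reference, read_length)
  }
  fit <- haplo_quantify(sets, lengths, seed = seed, ...)
  write_estimates(fit, reference, out_prefix)
  invisible(fit)
}
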