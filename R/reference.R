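#' Build a transcript reference table
#'
#' A transcript reference is an ordinary tibble with one row per
#' (haplo-)transcript: `transcript_id`, `gene_id`, `haplotype`
#' (`"none"`, `"A"` or `"B"`), `sequence` (A/C/G/T/N string) and
#' `true_length` (nucleotides). The `key` column uniquely names the record:
#' it equals `transcript_id` for `haplotype == "none"` and
#' `"<transcript_id><delim><tag>"` otherwise, so downstream modules can
#' always recover the (transcript, haplotype) pair from the key.
#'
#' @param transcript_id Character vector of transcript identifiers.
#' @param sequence Character vector of nucleotide sequences (A/C/G/T/N).
#' @param gene_id Character vector of gene identifiers (defaults to the
#'   transcript id, i.e. every transcript its own gene).
#' @param haplotype Haplotype tag per record: `"none"`, `"A"` or `"B"`.
#' @param delim Single character separating transcript id and haplotype tag
#'   in keys and FASTA headers. Default `"|"`.
#' @return A tibble with columns `key`, `transcript_id`, `gene_id`,
#'   `haplotype`, `sequence`, `true_length`.
#' @examples
#' transcript_reference(c("t1", "t2"), c("ACGTACGT", "GGGTTTAA"))
#' @export
transcript_reference <- function(transcript_id, sequence,
                                 gene_id = transcript_id,
                                 haplotype = "none",
                                 delim = "|") {
  sequence <- toupper(sequence)
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    abort(paste0("sequences contain characters outside A/C/G/T/N: ",
                 paste(transcript_id[bad], collapse = ", ")))
  }
  ref <- tibble(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    haplotype = rep_len(as.character(haplotype), length(transcript_id)),
    sequence = sequence,
    true_length = nchar(sequence)
  )
  if (!all(ref$haplotype %in% c("none", "A", "B"))) {
    abort("haplotype must be one of 'none', 'A', 'B'")
  }
  ref$key <- ref_key(ref$transcript_id, ref$haplotype, delim)
  if (anyDuplicated(ref$key)) {
    abort("duplicate (transcript_id, haplotype) pairs in reference")
  }
  select(ref, "key", "transcript_id", "gene_id", "haplotype",
         "sequence", "true_length")
}

#' Reference keys from transcript ids and haplotype tags
#'
#' @param transcript_id Character vector.
#' @param haplotype Character vector of tags (`"none"`, `"A"`, `"B"`).
#' @param delim Delimiter between id and tag.
#' @return Character vector of keys.
#' @export
ref_key <- function(transcript_id, haplotype = "none", delim = "|") {
  ifelse(haplotype == "none", transcript_id,
         paste0(transcript_id, delim, haplotype))
}

#' Read a transcript reference from FASTA
#'
#' Headers of the form `id` or `id<delim>tag`, optionally followed by
#' ` gene=<gene_id>`, are parsed back into the reference columns written by
#' [write_transcript_fasta()].
#'
#' @param path FASTA file path.
#' @param delim Haplotype delimiter used in headers.
#' @return A transcript reference tibble (see [transcript_reference()]).
#' @export
read_transcript_fasta <- function(path, delim = "|") {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  name <- sub("\\s.*$", "", headers)
  gene <- ifelse(grepl("gene=", headers),
                 sub(".*gene=(\\S+).*", "\\1", headers), NA_character_)
  is_a <- endsWith(name, paste0(delim, "A"))
  is_b <- endsWith(name, paste0(delim, "B"))
  haplotype <- ifelse(is_a, "A", ifelse(is_b, "B", "none"))
  tid <- ifelse(is_a | is_b,
                substr(name, 1L, nchar(name) - nchar(delim) - 1L), name)
  gene <- ifelse(is.na(gene), tid, gene)
  transcript_reference(tid, unname(as.character(seqs)), gene_id = gene,
                       haplotype = haplotype, delim = delim)
}

#' Write a transcript reference to FASTA
#'
#' Sequences are wrapped at 60 columns; headers carry the key and the gene id
#' (`>t1|A gene=g1`) so [read_transcript_fasta()] round-trips the table.
#'
#' @param reference Transcript reference tibble.
#' @param path Output path.
#' @param delim Haplotype delimiter for headers.
#' @return `path`, invisibly.
#' @export
write_transcript_fasta <- function(reference, path, delim = "|") {
  seqs <- Biostrings::DNAStringSet(reference$sequence)
  names(seqs) <- paste0(
    ref_key(reference$transcript_id, reference$haplotype, delim),
    " gene=", reference$gene_id
  )
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Lift genomic SNVs to transcript coordinates
#'
#' Maps genomic single-nucleotide variants onto each transcript whose exons
#' overlap them. Positions are 1-based inclusive in both genomic and
#' transcript coordinates; for minus-strand transcripts the position is
#' counted from the transcript 5' end and the alleles are
#' reverse-complemented. Variants falling outside every exon are dropped.
#'
#' @param variants Tibble of genomic SNVs with columns `chrom`, `pos`,
#'   `allele_A`, `allele_B` (phased single-base alleles).
#' @param exons Tibble of exon intervals with columns `transcript_id`,
#'   `chrom`, `start`, `end`, `strand` (`"+"`/`"-"`), 1-based inclusive.
#' @param reference Optional transcript reference; when supplied, lifted
#'   variants whose alleles both disagree with the transcript base are
#'   flagged (`ref_mismatch = TRUE`) with a warning rather than applied
#'   silently.
#' @return Tibble of per-transcript phased variants: `transcript_id`, `pos`,
#'   `allele_A`, `allele_B`, `is_het`, `ref_mismatch`.
#' @export
lift_variants_to_transcripts <- function(variants, exons, reference = NULL) {
  if (any(nchar(variants$allele_A) != 1L | nchar(variants$allele_B) != 1L)) {
    abort("only single-nucleotide variants are supported; indels must be removed")
  }
  out <- vector("list", nrow(variants))
  exons <- arrange(exons, .data$transcript_id, .data$start)
  by_tx <- split(exons, exons$transcript_id)
  for (v in seq_len(nrow(variants))) {
    chrom <- variants$chrom[v]; gpos <- variants$pos[v]
    hits <- list()
    for (tx in names(by_tx)) {
      ex <- by_tx[[tx]]
      if (!any(ex$chrom == chrom & ex$start <= gpos & gpos <= ex$end)) next
      strand <- ex$strand[1]
      widths <- ex$end - ex$start + 1L
      idx <- which(ex$start <= gpos & gpos <= ex$end)[1]
      if (strand == "+") {
        tpos <- sum(widths[seq_len(idx - 1L)]) + (gpos - ex$start[idx] + 1L)
        aA <- variants$allele_A[v]; aB <- variants$allele_B[v]
      } else {
        # exons sorted by genomic start; on the minus strand the transcript
        # runs from the rightmost exon end leftwards
        after <- if (idx < nrow(ex)) sum(widths[(idx + 1L):nrow(ex)]) else 0L
        tpos <- after + (ex$end[idx] - gpos + 1L)
        aA <- revcomp(variants$allele_A[v]); aB <- revcomp(variants$allele_B[v])
      }
      hits[[length(hits) + 1L]] <- tibble(
        transcript_id = tx, pos = as.integer(tpos),
        allele_A = aA, allele_B = aB
      )
    }
    if (length(hits)) out[[v]] <- bind_rows(hits)
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble(transcript_id = character(), pos = integer(),
                  allele_A = character(), allele_B = character(),
                  is_het = logical(), ref_mismatch = logical()))
  }
  res$is_het <- res$allele_A != res$allele_B
  res$ref_mismatch <- FALSE
  if (!is.null(reference)) {
    base_ref <- reference[reference$haplotype == "none", ]
    for (r in seq_len(nrow(res))) {
      j <- match(res$transcript_id[r], base_ref$transcript_id)
      if (is.na(j)) next
      refbase <- substr(base_ref$sequence[j], res$pos[r], res$pos[r])
      if (res$allele_A[r] != refbase && res$allele_B[r] != refbase) {
        res$ref_mismatch[r] <- TRUE
      }
    }
    if (any(res$ref_mismatch)) {
      warn(paste0(sum(res$ref_mismatch),
                  " lifted variant(s) mismatch the reference base; ",
                  "flagged with ref_mismatch = TRUE"))
    }
  }
  res
}

#' Edit a reference to match inferred haplotypes
#'
#' Applies phased per-transcript variants to a base reference. A transcript
#' carrying at least one heterozygous variant is split into two records
#' tagged `A` and `B` that differ exactly at its heterozygous positions;
#' a transcript with only homozygous (non-reference) variants is edited in
#' place and keeps tag `none`; untouched transcripts pass through unchanged.
#'
#' @param reference Transcript reference tibble (all tags `"none"`).
#' @param variants Tibble of phased transcript-coordinate variants with
#'   columns `transcript_id`, `pos`, `allele_A`, `allele_B` and optionally
#'   `phased` (logical) — unphased heterozygotes are rejected unless
#'   `force_random_phase = TRUE`.
#' @param delim Haplotype delimiter for keys.
#' @param force_random_phase Assign a random phase (using the current RNG
#'   state) to unphased heterozygotes instead of failing.
#' @return A transcript reference tibble with haplotype tags applied.
#' @examples
#' ref <- transcript_reference("t1", "ACGTACGT")
#' v <- tibble::tibble(transcript_id = "t1", pos = 3L,
#'                     allele_A = "G", allele_B = "T")
#' apply_haplotypes(ref, v)
#' @export
apply_haplotypes <- function(reference, variants, delim = "|",
                             force_random_phase = FALSE) {
  if (any(reference$haplotype != "none")) {
    abort("apply_haplotypes expects an un-tagged base reference")
  }
  if (nrow(variants) == 0L) return(reference)
  if (any(nchar(variants$allele_A) != 1L | nchar(variants$allele_B) != 1L)) {
    abort("only single-nucleotide variants are supported; indels are rejected")
  }
  if ("ref_mismatch" %in% names(variants) && any(variants$ref_mismatch)) {
    warn("dropping variants flagged ref_mismatch")
    variants <- filter(variants, !.data$ref_mismatch)
  }
  variants$is_het <- variants$allele_A != variants$allele_B
  if ("phased" %in% names(variants)) {
    unphased <- variants$is_het & !variants$phased
    if (any(unphased)) {
      if (!force_random_phase) {
        abort("unphased heterozygotes present; rerun with force_random_phase = TRUE or phase them first")
      }
      flip <- unphased & (runif(nrow(variants)) < 0.5)
      tmp <- variants$allele_A[flip]
      variants$allele_A[flip] <- variants$allele_B[flip]
      variants$allele_B[flip] <- tmp
    }
  }
  dup <- duplicated(variants[, c("transcript_id", "pos")])
  if (any(dup)) {
    abort(paste0("multiple variants at the same transcript position: ",
                 paste(unique(variants$transcript_id[dup]), collapse = ", ")))
  }
  out <- vector("list", nrow(reference))
  for (r in seq_len(nrow(reference))) {
    rec <- reference[r, ]
    v <- filter(variants, .data$transcript_id == rec$transcript_id)
    if (nrow(v) == 0L) { out[[r]] <- rec; next }
    if (any(v$pos < 1L | v$pos > rec$true_length)) {
      abort(paste0("variant position outside transcript ", rec$transcript_id))
    }
    seq_A <- edit_sequence(rec$sequence, v$pos, v$allele_A)
    seq_B <- edit_sequence(rec$sequence, v$pos, v$allele_B)
    if (any(v$is_het)) {
      out[[r]] <- transcript_reference(
        rep(rec$transcript_id, 2), c(seq_A, seq_B),
        gene_id = rec$gene_id, haplotype = c("A", "B"), delim = delim
      )
    } else {
      out[[r]] <- transcript_reference(
        rec$transcript_id, seq_A, gene_id = rec$gene_id, delim = delim
      )
    }
  }
  bind_rows(out)
}

edit_sequence <- function(seq, pos, alleles) {
  s <- strsplit(seq, "")[[1]]
  s[pos] <- alleles
  paste(s, collapse = "")
}

#' Combine two parental references into a hybrid reference
#'
#' Transcripts whose sequences are identical in both parents appear once
#' (tag `none`); transcripts differing in sequence appear twice, tagged `A`
#' and `B`, so reads can be assigned to the parental copy they came from.
#' A transcript present in only one parent is kept with a warning.
#'
#' @param ref_A,ref_B Transcript reference tibbles for the two parents
#'   (tags `"none"`, sharing a transcript id namespace).
#' @param delim Haplotype delimiter for keys.
#' @return A hybrid transcript reference tibble.
#' @export
build_hybrid_reference <- function(ref_A, ref_B, delim = "|") {
  ids <- union(ref_A$transcript_id, ref_B$transcript_id)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    a <- filter(ref_A, .data$transcript_id == id)
    b <- filter(ref_B, .data$transcript_id == id)
    if (nrow(a) && nrow(b)) {
      if (a$sequence == b$sequence) {
        out[[i]] <- transcript_reference(id, a$sequence, gene_id = a$gene_id,
                                         delim = delim)
      } else {
        out[[i]] <- transcript_reference(
          rep(id, 2), c(a$sequence, b$sequence),
          gene_id = a$gene_id, haplotype = c("A", "B"), delim = delim
        )
      }
    } else {
      only <- if (nrow(a)) a else b
      warn(paste0("transcript ", id, " present in only one reference"))
      out[[i]] <- transcript_reference(id, only$sequence,
                                       gene_id = only$gene_id, delim = delim)
    }
  }
  bind_rows(out)
}

#' Read phased variants from a tab-delimited table or VCF
#'
#' The TSV dialect has four columns (`transcript_id`, `pos`, `allele_A`,
#' `allele_B`), positions 1-based on the transcript. VCF input uses `CHROM`
#' as the transcript id and requires a phased `GT` field (`a|b`); unphased
#' heterozygotes are marked `phased = FALSE` for [apply_haplotypes()] to
#' reject or randomly phase.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf"` (guessed from the extension by default).
#' @return Tibble with columns `transcript_id`, `pos`, `allele_A`,
#'   `allele_B`, `is_het`, `phased`.
#' @export
read_phased_variants <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    tab <- read.table(path, header = FALSE, sep = "\t",
                      col.names = c("transcript_id", "pos",
                                    "allele_A", "allele_B"),
                      colClasses = c("character", "integer",
                                    "character", "character"))
    v <- as_tibble(tab)
    v$phased <- TRUE
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      abort("VCF input requires the vcfR package")
    }
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")[, 1]
    alleles <- strsplit(gt, "[|/]")
    phased <- grepl("\\|", gt)
    pick <- function(code, ref, alt) {
      alts <- strsplit(alt, ",")[[1]]
      if (code == "0") ref else alts[as.integer(code)]
    }
    aA <- mapply(function(al, r, a) pick(al[1], r, a),
                 alleles, fix$REF, fix$ALT)
    aB <- mapply(function(al, r, a) pick(al[2], r, a),
                 alleles, fix$REF, fix$ALT)
    v <- tibble(transcript_id = fix$CHROM, pos = as.integer(fix$POS),
                allele_A = unname(aA), allele_B = unname(aB),
                phased = unname(phased))
  }
  if (any(nchar(v$allele_A) != 1L | nchar(v$allele_B) != 1L)) {
    abort("only single-nucleotide variants are supported")
  }
  v$is_het <- v$allele_A != v$allele_B
  select(v, "transcript_id", "pos", "allele_A", "allele_B", "is_het", "phased")
}

#' Read exon annotation from GFF3/GTF or a table
#'
#' @param path GFF3/GTF file; exon features are used, with the transcript id
#'   taken from the `transcript_id` or `Parent` attribute.
#' @return Tibble with columns `transcript_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_exon_annotation <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("GFF/GTF input requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "exon"]
  meta <- as.data.frame(gr)
  tid <- if ("transcript_id" %in% names(meta)) {
    as.character(meta$transcript_id)
  } else if ("Parent" %in% names(meta)) {
    vapply(meta$Parent, function(p) as.character(p)[1], character(1))
  } else {
    abort("exon features carry neither transcript_id nor Parent attributes")
  }
  tibble(transcript_id = tid, chrom = as.character(meta$seqnames),
         start = as.integer(meta$start), end = as.integer(meta$end),
         strand = as.character(meta$strand))
}
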