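#' Draw true expression values for a simulation
#'
#' Expression values are drawn from a Gamma (default, matching the vague
#' Gam(1.2, 0.001) shape of real expression distributions) or log-normal
#' prior; a fraction of transcripts is set exactly to zero to emulate
#' unexpressed annotation.
#'
#' @param n Number of transcripts.
#' @param distribution `"gamma"` or `"lognormal"`.
#' @param shape,rate Gamma parameters (defaults 1.2, 0.001).
#' @param meanlog,sdlog Log-normal parameters (defaults 4, 1.5).
#' @param zero_fraction Fraction of transcripts with mu = 0 (default 0.1).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n` on the RPKM scale.
#' @export
simulate_expression <- function(n, distribution = c("gamma", "lognormal"),
                                shape = 1.2, rate = 0.001,
                                meanlog = 4, sdlog = 1.5,
                                zero_fraction = 0.1, seed = NULL) {
  distribution <- match.arg(distribution)
  if (!is.null(seed)) set.seed(seed)
  mu <- switch(distribution,
               gamma = rgamma(n, shape = shape, rate = rate),
               lognormal = stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog))
  if (zero_fraction > 0) {
    mu[sample.int(n, round(zero_fraction * n))] <- 0
  }
  mu
}

#' Simulate reads from a reference with known expression
#'
#' Per transcript the read count is Poisson with mean `b * l~_t * mu_t`
#' (lengths in kb), start positions are sampled uniformly over the
#' effective length — or proportionally to the per-position sequence
#' preferences when a bias model is given — and bases are copied from the
#' (haplotype-specific) sequence with an independent per-base error rate.
#' Paired mode draws insert sizes from a Normal truncated to
#' `[2 * read_length, transcript length]` and emits the mate as the
#' reverse complement of the fragment end.
#'
#' @param reference Transcript reference tibble.
#' @param true_mu Expression vector (RPKM scale), one value per reference
#'   row, in reference order.
#' @param b Normalization constant (target depth, "reads in millions").
#' @param read_length Read length in nt.
#' @param paired Emit read pairs?
#' @param insert_mean,insert_sd Insert-size distribution for paired mode.
#' @param error_rate Per-base substitution error probability.
#' @param bias Optional `bias_model` shaping start positions.
#' @param seed Optional integer seed; fixed seed gives byte-identical
#'   output.
#' @return List with `reads` (tibble: `read_id`, `key`, `start`,
#'   `sequence`, plus `sequence2`/`insert_size` when paired) and `truth`
#'   (tibble: `key`, `true_mu`, `reads_emitted`, `config` fields).
#' @export
simulate_reads <- function(reference, true_mu, b, read_length,
                           paired = FALSE, insert_mean = NULL,
                           insert_sd = NULL, error_rate = 0,
                           bias = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(true_mu) == nrow(reference))
  expressed <- true_mu > 0
  if (any(expressed & reference$true_length < read_length)) {
    abort("an expressed transcript is shorter than the read length")
  }
  if (paired && (is.null(insert_mean) || is.null(insert_sd))) {
    abort("paired mode needs insert_mean and insert_sd")
  }
  reads <- list()
  n_emitted <- integer(nrow(reference))
  l_tilde <- numeric(nrow(reference))
  for (t in seq_len(nrow(reference))) {
    L <- reference$true_length[t]
    if (L < read_length) next
    n_pos <- L - read_length + 1
    pref <- if (is.null(bias)) rep(1, n_pos) else
      position_preferences(reference$sequence[t], bias, read_length)
    l_tilde[t] <- sum(pref)
    if (!expressed[t]) next
    r_t <- rpois(1, b * (l_tilde[t] / 1000) * true_mu[t])
    if (r_t == 0) next
    starts <- sample.int(n_pos, r_t, replace = TRUE, prob = pref)
    frag <- substring(reference$sequence[t], starts,
                      starts + read_length - 1)
    if (paired) {
      ins <- round(rnorm(r_t, insert_mean, insert_sd))
      ins <- pmin(pmax(ins, 2L * read_length), L)
      bad <- starts + ins - 1L > L
      ins[bad] <- L - starts[bad] + 1L
      drop <- ins < 2L * read_length
      if (any(drop)) {
        warn(paste0("dropping ", sum(drop),
                    " pair(s) with infeasible insert sizes"))
      }
      keep <- !drop
      mate2 <- revcomp(substring(reference$sequence[t],
                                 starts + ins - read_length,
                                 starts + ins - 1L))
      rd <- tibble(key = reference$key[t], start = starts,
                   sequence = frag, sequence2 = mate2,
                   insert_size = as.integer(ins))[keep, ]
    } else {
      rd <- tibble(key = reference$key[t], start = starts, sequence = frag)
    }
    n_emitted[t] <- nrow(rd)
    reads[[length(reads) + 1L]] <- rd
  }
  reads <- bind_rows(reads)
  if (nrow(reads)) {
    reads$read_id <- sprintf("read_%06d", seq_len(nrow(reads)))
    if (error_rate > 0) {
      reads$sequence <- mutate_bases(reads$sequence, error_rate)
      if (paired) reads$sequence2 <- mutate_bases(reads$sequence2, error_rate)
    }
    reads <- select(reads, "read_id", dplyr::everything())
  } else {
    reads <- tibble(read_id = character(), key = character(),
                    start = integer(), sequence = character())
  }
  truth <- tibble(key = reference$key, true_mu = true_mu,
                  reads_emitted = n_emitted,
                  read_length = read_length, b = b,
                  error_rate = error_rate,
                  adjusted_length = l_tilde)
  list(reads = reads, truth = truth)
}

position_preferences <- function(sequence, model, read_length) {
  L <- nchar(sequence)
  n_pos <- L - read_length + 1
  bases <- strsplit(sequence, "")[[1]]
  loga <- rep(model$intercept, n_pos)
  cf <- model$coefficients
  lookup <- matrix(0, nrow = 2 * model$window + 1, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  lookup[cbind(cf$offset + model$window + 1,
               match(cf$base, colnames(lookup)))] <- cf$estimate
  p <- seq_len(n_pos)
  for (o in -model$window:model$window) {
    at <- p + o
    ok <- at >= 1 & at <= L
    bo <- bases[at[ok]]
    valid <- bo %in% c("A", "C", "G", "T")
    add <- numeric(sum(ok))
    add[valid] <- lookup[cbind(rep(o + model$window + 1, sum(valid)),
                               match(bo[valid], colnames(lookup)))]
    loga[ok] <- loga[ok] + add
  }
  exp(loga)
}

mutate_bases <- function(seqs, error_rate) {
  vapply(seqs, function(s) {
    bases <- strsplit(s, "")[[1]]
    hit <- runif(length(bases)) < error_rate
    if (any(hit)) {
      bases[hit] <- vapply(bases[hit], function(bb) {
        sample(setdiff(c("A", "C", "G", "T"), bb), 1)
      }, character(1))
    }
    paste(bases, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write simulated reads as FASTQ
#'
#' Qualities are constant `I` (Phred+33 Q40); mate files get suffixes
#' `_1.fastq` / `_2.fastq` in paired mode.
#'
#' @param reads Read tibble from [simulate_reads()].
#' @param prefix Output path prefix (single-end writes `<prefix>.fastq`).
#' @return Character vector of paths written, invisibly.
#' @export
write_fastq <- function(reads, prefix) {
  write_one <- function(ids, seqs, path) {
    lines <- as.vector(rbind(paste0("@", ids), seqs, "+",
                             strrep("I", nchar(seqs))))
    writeLines(lines, path)
    path
  }
  if ("sequence2" %in% names(reads)) {
    paths <- c(write_one(reads$read_id, reads$sequence,
                         paste0(prefix, "_1.fastq")),
               write_one(reads$read_id, reads$sequence2,
                         paste0(prefix, "_2.fastq")))
  } else {
    paths <- write_one(reads$read_id, reads$sequence,
                       paste0(prefix, ".fastq"))
  }
  invisible(paths)
}

#' Exhaustively enumerate transcript sets and shared-region lengths
#'
#' The brute-force oracle behind the set-count machinery: for every
#' transcript and every start position `p` in `1..l_t`, the read-length
#' substring is matched exactly against every reference record; positions
#' are grouped by the set of records containing their substring, giving
#' each set's shared-region effective length `s_i`. By construction
#' `sum_i s_i M_it = l_t` for every transcript. Quadratic in total
#' positions — intended for small references only.
#'
#' @param reference Transcript reference tibble (<= a few dozen records).
#' @param read_length Read length in nt.
#' @return Tibble with one row per set: `set_id`, `transcripts` (sorted key
#'   list), `n_transcripts`, `s` (total shared-region length summed over
#'   member positions, per transcript — see Details).
#' @details `s` is the number of start positions (on any one member
#'   transcript) whose read maps to exactly that set; every member
#'   transcript contributes the same number of positions to a set, which
#'   is what makes `s_i` well defined.
#' @export
enumerate_region_lengths <- function(reference, read_length) {
  keys <- reference$key
  pos_sets <- list()
  for (t in seq_len(nrow(reference))) {
    L <- reference$true_length[t]
    if (L < read_length) next
    for (p in seq_len(L - read_length + 1)) {
      kmer <- substr(reference$sequence[t], p, p + read_length - 1)
      inset <- keys[vapply(reference$sequence, grepl, logical(1),
                           pattern = kmer, fixed = TRUE, USE.NAMES = FALSE)]
      pos_sets[[length(pos_sets) + 1L]] <- tibble(
        origin = keys[t], set = paste(sort(inset), collapse = "\t")
      )
    }
  }
  df <- bind_rows(pos_sets)
  # each member transcript of a set contributes equally many positions;
  # s_i is that per-transcript count
  per <- df |>
    dplyr::count(.data$set, .data$origin, name = "s_origin") |>
    group_by(.data$set) |>
    summarise(s = .data$s_origin[1],
              consistent = dplyr::n_distinct(.data$s_origin) == 1L,
              .groups = "drop") |>
    arrange(.data$set)
  if (!all(per$consistent)) {
    abort("internal oracle inconsistency: unequal position counts across set members")
  }
  tibble(
    set_id = seq_len(nrow(per)),
    transcripts = strsplit(per$set, "\t", fixed = TRUE),
    n_transcripts = lengths(strsplit(per$set, "\t", fixed = TRUE)),
    s = as.integer(per$s)
  )
}

#' Match simulated reads against a reference (testing aligner)
#'
#' A deterministic in-package stand-in for an external all-best
#' transcriptome aligner, used by the test-scale pipeline. With
#' `max_mismatches = 0` each read is matched exactly via a precomputed
#' dictionary of all read-length substrings of the reference (fast; the
#' post-stratum-filter ideal). With `max_mismatches > 0` every reference
#' record is scanned with [Biostrings::vmatchPattern()] and true mismatch
#' counts are reported, so the best-stratum filter has non-trivial work to
#' do (slow; small references only).
#'
#' @param reads Read tibble (`read_id`, `sequence`) from
#'   [simulate_reads()].
#' @param reference Transcript reference tibble.
#' @param max_mismatches Maximum mismatches per reported alignment.
#' @return Alignment tibble (`read_id`, `key`, `mismatches`,
#'   `insert_size = NA`) compatible with the alignment filters.
#' @export
match_reads <- function(reads, reference, max_mismatches = 0) {
  if (nrow(reads) == 0L) {
    return(tibble(read_id = character(), key = character(),
                  mismatches = integer(), insert_size = integer()))
  }
  if (max_mismatches == 0) {
    rl <- nchar(reads$sequence[1])
    dict <- kmer_dictionary(reference, rl)
    hit <- dict$sets[match(reads$sequence, dict$kmer)]
    found <- !vapply(hit, is.null, logical(1))
    out <- tibble(read_id = rep(reads$read_id[found],
                                lengths(hit[found])),
                  key = unlist(hit[found]),
                  mismatches = 0L, insert_size = NA_integer_)
    return(out)
  }
  subject <- Biostrings::DNAStringSet(reference$sequence)
  names(subject) <- reference$key
  rows <- list()
  for (r in seq_len(nrow(reads))) {
    pat <- Biostrings::DNAString(reads$sequence[r])
    m <- Biostrings::vmatchPattern(pat, subject,
                                   max.mismatch = max_mismatches)
    cnt <- S4Vectors::elementNROWS(m)
    for (j in which(cnt > 0)) {
      starts <- BiocGenerics::start(m[[j]])
      mm <- vapply(starts, function(st) {
        ref_sub <- substr(reference$sequence[j], st, st + length(pat) - 1L)
        sum(strsplit(ref_sub, "")[[1]] != strsplit(reads$sequence[r], "")[[1]])
      }, numeric(1))
      rows[[length(rows) + 1L]] <- tibble(
        read_id = reads$read_id[r], key = reference$key[j],
        mismatches = as.integer(min(mm)), insert_size = NA_integer_
      )
    }
  }
  bind_rows(rows)
}

kmer_dictionary <- function(reference, read_length) {
  kmers <- character(0); origin <- character(0)
  for (t in seq_len(nrow(reference))) {
    L <- reference$true_length[t]
    if (L < read_length) next
    p <- seq_len(L - read_length + 1)
    kmers <- c(kmers, substring(reference$sequence[t], p,
                                p + read_length - 1))
    origin <- c(origin, rep(reference$key[t], length(p)))
  }
  sets <- split(origin, kmers)
  sets <- lapply(sets, function(s) sort(unique(s)))
  list(kmer = names(sets), sets = unname(sets))
}

#' Analytic probability of single-allele dropout at low coverage
#'
#' For two equally expressed haplotype copies of an isoform differing at
#' exactly one heterozygous site, with uniform Poisson read sampling at
#' `rate_per_nt` reads per nucleotide and reads of length `read_length`,
#' there are `read_length` start positions per haplotype whose read covers
#' the site, so the number of site-covering reads per haplotype is
#' Pois(lambda), lambda = rate_per_nt * read_length, independently. The
#' probability that one allele is observed while the other is not
#' (either way round) is `2 (1 - e^-lambda) e^-lambda`; at the default
#' 0.01 reads/nt and 35 nt reads this is about 0.42, which is why the ML
#' estimate of the unobserved haplotype is frequently an exact zero.
#'
#' @param rate_per_nt Reads per nucleotide per haplotype (default 0.01).
#' @param read_length Read length in nt (default 35).
#' @return Probability in `[0, 1]`.
#' @export
allele_dropout_probability <- function(rate_per_nt = 0.01, read_length = 35) {
  lam <- rate_per_nt * read_length
  2 * (1 - exp(-lam)) * exp(-lam)
}

#' @rdname allele_dropout_probability
#' @param reps Monte Carlo replicates (default 1e6).
#' @param seed Optional integer seed.
#' @export
allele_dropout_probability_mc <- function(rate_per_nt = 0.01,
                                          read_length = 35,
                                          reps = 1e6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lam <- rate_per_nt * read_length
  n_a <- rpois(reps, lam)
  n_b <- rpois(reps, lam)
  mean((n_a > 0 & n_b == 0) | (n_a == 0 & n_b > 0))
}
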