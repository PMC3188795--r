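# Fixtures are generated in code; seeds fixed per helper for reproducibility.

random_sequence <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A reference of `n` random transcripts (lengths uniform in len_range),
# optionally with a heterozygote planted mid-transcript in `n_het` of them
# (yielding A/B haplo-isoform pairs).
make_random_reference <- function(n = 10, len_range = c(200, 400),
                                  n_het = 0, seed = 1) {
  set.seed(seed)
  choices <- seq(len_range[1], len_range[2])
  lens <- choices[sample.int(length(choices), n, replace = TRUE)]
  seqs <- vapply(lens, function(L) random_sequence(L), character(1))
  ref <- transcript_reference(sprintf("t%02d", seq_len(n)), seqs)
  if (n_het > 0) {
    het_ids <- ref$transcript_id[seq_len(n_het)]
    v <- do.call(rbind, lapply(het_ids, function(id) {
      L <- ref$true_length[ref$transcript_id == id]
      pos <- sample(seq(50, L - 50), 1)
      cur <- substr(ref$sequence[ref$transcript_id == id], pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
      tibble::tibble(transcript_id = id, pos = as.integer(pos),
                     allele_A = cur, allele_B = alt)
    }))
    ref <- apply_haplotypes(ref, v)
  }
  ref
}

# The classic cassette-exon gene: two isoforms sharing flanking exons, one
# skipping the middle exon. Exons are distinct random blocks so reads map
# unambiguously within each region.
make_cassette_reference <- function(exon_len = 100, seed = 42) {
  set.seed(seed)
  e1 <- random_sequence(exon_len); e2 <- random_sequence(exon_len)
  e3 <- random_sequence(exon_len)
  transcript_reference(c("iso1", "iso2"),
                       c(paste0(e1, e2, e3), paste0(e1, e3)),
                       gene_id = c("g1", "g1"))
}

# Single-exon transcript with one heterozygote in the middle -> A/B pair.
make_het_pair <- function(exon_len = 100, het_pos = 50, read_len = 35,
                          seed = 7) {
  set.seed(seed)
  s <- random_sequence(exon_len)
  cur <- substr(s, het_pos, het_pos)
  alt <- setdiff(c("A", "C", "G", "T"), cur)[1]
  v <- tibble::tibble(transcript_id = "tx", pos = as.integer(het_pos),
                      allele_A = cur, allele_B = alt)
  apply_haplotypes(transcript_reference("tx", s), v)
}

# Random small model instance (M, k, l, b) for EM/Gibbs property tests.
random_instance <- function(n_transcripts = 4, n_sets = 6, seed = 1) {
  set.seed(seed)
  sets <- list()
  seen <- character(0)
  max_tries <- 50 * n_sets  # distinct subsets may run out for tiny instances
  tries <- 0
  while (length(sets) < n_sets && tries < max_tries) {
    tries <- tries + 1
    sz <- sample(1:min(3, n_transcripts), 1)
    s <- sort(sample(sprintf("t%d", 1:n_transcripts), sz))
    keyd <- paste(s, collapse = ",")
    if (keyd %in% seen) next
    seen <- c(seen, keyd)
    sets[[length(sets) + 1L]] <- s
  }
  # ensure every transcript appears in at least one set
  for (t in sprintf("t%d", 1:n_transcripts)) {
    if (!any(vapply(sets, function(s) t %in% s, logical(1)))) {
      sets[[length(sets) + 1L]] <- t
    }
  }
  tab <- tibble::tibble(
    set_id = seq_along(sets), transcripts = sets,
    n_transcripts = lengths(sets),
    count = as.integer(rpois(length(sets), 20) + 1L)
  )
  lens <- tibble::tibble(
    key = sprintf("t%d", 1:n_transcripts),
    true_length = sample(500:2000, n_transcripts),
  )
  lens$effective_length <- lens$true_length - 34
  lens$adjusted_length <- lens$effective_length
  list(sets = tab, lengths = lens)
}

# Brute-force ML oracle: numerically maximize the observed-data Poisson
# log-likelihood over mu (independent of the EM code path).
brute_force_ml <- function(inputs, n_starts = 3) {
  nt <- length(inputs$keys)
  negll <- function(log_mu) -model_loglik(exp(log_mu), inputs)
  best <- NULL
  for (s in seq_len(n_starts)) {
    init <- log(pmax(em_initialize(inputs), 1e-4)) +
      if (s > 1) rnorm(nt, 0, 0.5) else 0
    opt <- optim(init, negll, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  exp(best$par)
}
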