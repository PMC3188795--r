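# Reference with realistic gene structure: `n_multi` genes with two isoforms
# sharing flanking exons (cassette-exon style, inducing genuine
# multi-mapping) plus single-isoform genes, and optional heterozygotes.
make_gene_reference <- function(n_multi = 30, n_single = 40,
                                exon_len = 150, seed = 1) {
  set.seed(seed)
  recs <- list()
  for (g in seq_len(n_multi)) {
    e1 <- random_sequence(exon_len); e2 <- random_sequence(exon_len)
    e3 <- random_sequence(exon_len)
    recs[[length(recs) + 1L]] <- tibble::tibble(
      transcript_id = sprintf("g%03d_iso%d", g, 1:2),
      gene_id = sprintf("g%03d", g),
      sequence = c(paste0(e1, e2, e3), paste0(e1, e3))
    )
  }
  for (g in seq_len(n_single)) {
    L <- sample(300:1200, 1)
    recs[[length(recs) + 1L]] <- tibble::tibble(
      transcript_id = sprintf("s%03d_iso1", g),
      gene_id = sprintf("s%03d", g),
      sequence = random_sequence(L)
    )
  }
  df <- dplyr::bind_rows(recs)
  transcript_reference(df$transcript_id, df$sequence, gene_id = df$gene_id)
}

# Simulate, exact-match (the post-stratum-filter ideal) and fit. The
# simulation's normalizer b is passed through to the fit so estimates are
# on the same absolute scale as the planted truth.
simulate_and_fit <- function(ref, mu, b, read_length = 35, seed = 1, ...) {
  sim <- simulate_reads(ref, mu, b = b, read_length = read_length,
                        seed = seed)
  aln <- match_reads(sim$reads, ref)
  sets <- collect_transcript_sets(aln)
  lens <- effective_lengths(ref, read_length)
  fit <- haplo_quantify(sets, lens, b = b, seed = seed + 1L, ...)
  list(fit = fit, truth = sim$truth, sets = sets)
}

# Expression draw for the adequate-depth recovery design: expressed
# transcripts are guaranteed a sequencing depth of at least `min_depth`
# reads per kb (i.e. mu >= min_depth / b), the regime where rank recovery
# is meaningful; a zero_fraction of transcripts stays unexpressed.
simulate_expression_at_depth <- function(n, b, min_depth = 20,
                                         zero_fraction = 0.1, seed = 1) {
  set.seed(seed)
  floor_mu <- min_depth / b
  mu <- rgamma(n, shape = 1.2, rate = 0.001)
  for (i in seq_len(n)) {
    while (mu[i] < floor_mu) mu[i] <- rgamma(1, shape = 1.2, rate = 0.001)
  }
  mu[sample.int(n, round(zero_fraction * n))] <- 0
  mu
}

log_rmse <- function(est, truth) sqrt(mean((log(est + 1) - log(truth + 1))^2))
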