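test_that("training selection keeps one top-coverage transcript per gene with lexicographic ties", {
  cov <- tibble::tibble(key = c("g1a", "g1b", "g2a"),
                        coverage = c(50, 40, 30))
  gm <- tibble::tibble(key = c("g1a", "g1b", "g2a"),
                       gene_id = c("g1", "g1", "g2"))
  expect_equal(select_training_transcripts(cov, gm, n = 2, min_eligible = 1),
               c("g1a", "g2a"))
  # n larger than the transcript count: all genes, one each
  expect_equal(select_training_transcripts(cov, gm, n = 10, min_eligible = 1),
               c("g1a", "g2a"))
  # coverage ties broken by key
  tied <- dplyr::mutate(cov, coverage = 10)
  expect_equal(select_training_transcripts(tied, gm, n = 10, min_eligible = 1),
               c("g1a", "g2a"))
  expect_error(select_training_transcripts(cov, gm, n = 10),
               "unfittable")
})

test_that("null model reproduces the uniform effective length exactly", {
  m0 <- null_bias_model(window = 3)
  s <- random_sequence(100, seed = 1)
  expect_equal(adjusted_effective_length(s, m0, read_length = 35), 66)
  ref <- transcript_reference("t1", s)
  lens <- effective_lengths(ref, 35, bias = m0)
  expect_equal(lens$adjusted_length, lens$effective_length)
  # constant intercept c scales l~ by e^c (closed form)
  mc <- null_bias_model(window = 3)
  mc$intercept <- 0.4
  expect_equal(adjusted_effective_length(s, mc, 35), 66 * exp(0.4))
  expect_error(adjusted_effective_length("ACGT", m0, 35), "shorter")
})

test_that("a single planted coefficient adds the hand-enumerated preference", {
  # model: coef +ln(2) for G at offset -1, all else 0, window 1
  m <- null_bias_model(window = 1)
  m$coefficients$estimate[m$coefficients$offset == -1 &
                            m$coefficients$base == "G"] <- log(2)
  # sequence with exactly one qualifying G context among start positions
  # positions p = 1..l; p has preference 2 iff base at p-1 == 'G'
  s <- "AAGTAAAAAAAA"  # G at position 3 -> start position 4 doubles
  rl <- 4
  l <- nchar(s) - rl + 1  # 9 start positions (p = 1..9); p=4 has G at p-1
  expect_equal(adjusted_effective_length(s, m, rl), l + 1)
})

test_that("Poisson regression recovers null and planted coefficients", {
  set.seed(202)
  W <- 2
  rl <- 10
  n_tx <- 40
  ref <- transcript_reference(
    sprintf("tr%02d", 1:n_tx),
    vapply(rep(400, n_tx), function(L) random_sequence(L), character(1))
  )
  mu <- rep(100, n_tx)
  b <- 1
  make_counts <- function(planted) {
    out <- list()
    for (t in seq_len(n_tx)) {
      L <- ref$true_length[t]
      n_pos <- L - rl + 1
      bases <- strsplit(ref$sequence[t], "")[[1]]
      pref <- rep(0, n_pos)
      if (!is.null(planted)) {
        # +0.5 for G at offset -1
        prev <- c("X", bases)[seq_len(n_pos)]  # base at p-1 ('X' for p=1)
        pref <- ifelse(prev == "G", 0.5, 0)
      }
      lam <- b * mu[t] / 1000 * exp(pref)
      cnt <- rpois(n_pos, lam)
      keep <- which(cnt > 0)
      if (length(keep)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          key = ref$key[t], pos = keep, count = cnt[keep])
      }
    }
    dplyr::bind_rows(out)
  }
  expr_tbl <- tibble::tibble(key = ref$key, mu = mu)

  null_fit <- fit_bias_model(ref, make_counts(NULL), expr_tbl, b = b,
                             read_length = rl, window = W)
  cf <- null_fit$coefficients
  est <- cf[cf$base != "A", ]
  expect_true(all(abs(est$estimate) <= 3 * est$std_error + 1e-8))

  planted_fit <- fit_bias_model(ref, make_counts(TRUE), expr_tbl, b = b,
                                read_length = rl, window = W)
  cfp <- planted_fit$coefficients
  g_m1 <- cfp$estimate[cfp$offset == -1 & cfp$base == "G"]
  se_m1 <- cfp$std_error[cfp$offset == -1 & cfp$base == "G"]
  expect_lt(abs(g_m1 - 0.5), 4 * se_m1)
  expect_gt(g_m1, 0.3)
  # other coefficients stay near zero
  others <- cfp[cfp$base != "A" & !(cfp$offset == -1 & cfp$base == "G"), ]
  expect_lt(max(abs(others$estimate)), 0.15)

  zero_counts <- tibble::tibble(key = ref$key[1], pos = 5L, count = 0L)
  expect_error(fit_bias_model(ref, zero_counts, expr_tbl, b = b,
                              read_length = rl, window = W), "zero")
})

test_that("adjustments on unbiased data are slight and expression responds inversely to length", {
  set.seed(303)
  rl <- 10
  ref <- transcript_reference(
    sprintf("u%02d", 1:30),
    vapply(rep(300, 30), function(L) random_sequence(L), character(1))
  )
  n_pos <- 300 - rl + 1
  counts <- dplyr::bind_rows(lapply(seq_len(30), function(t) {
    cnt <- rpois(n_pos, 0.2)
    keep <- which(cnt > 0)
    tibble::tibble(key = ref$key[t], pos = keep, count = cnt[keep])
  }))
  expr_tbl <- tibble::tibble(key = ref$key, mu = rep(200, 30))
  fit <- fit_bias_model(ref, counts, expr_tbl, b = 1, read_length = rl,
                        window = 2)
  lens <- effective_lengths(ref, rl, bias = fit)
  lr <- log(lens$adjusted_length / lens$effective_length)
  expect_lt(abs(median(lr)), 0.05)

  # single-transcript: scaling l~ by f scales mu_hat by exactly 1/f
  sets <- tibble::tibble(set_id = 1L, transcripts = list("u01"),
                         n_transcripts = 1L, count = 50L)
  base_len <- tibble::tibble(key = "u01", true_length = 300,
                             effective_length = n_pos,
                             adjusted_length = n_pos)
  f <- 1.37
  scaled <- dplyr::mutate(base_len, adjusted_length = n_pos * f)
  mu_base <- run_em(model_inputs(sets, base_len, b = 1))$mu
  mu_scaled <- run_em(model_inputs(sets, scaled, b = 1))$mu
  expect_equal(unname(mu_scaled), unname(mu_base) / f)

  # intercept shift by c: every l~ multiplied by e^c
  shifted <- fit
  shifted$intercept <- fit$intercept + 0.3
  lens2 <- effective_lengths(ref, rl, bias = shifted)
  expect_equal(lens2$adjusted_length, lens$adjusted_length * exp(0.3))
})

test_that("adjusted lengths persist, reload bit-identically, and reject mismatched references", {
  ref <- make_random_reference(n = 5, seed = 9)
  lens <- effective_lengths(ref, 35)
  lens$adjusted_length <- lens$adjusted_length * runif(nrow(lens), 0.9, 1.1)
  path <- tempfile(fileext = ".tsv")
  write_adjusted_lengths(lens, path)
  back <- read_adjusted_lengths(path, reference = ref)
  expect_identical(back$adjusted_length, lens$adjusted_length)
  expect_identical(back$key, lens$key)

  other <- make_random_reference(n = 5, len_range = c(150, 180), seed = 10)
  expect_error(read_adjusted_lengths(path, reference = other),
               "does not match")
  expect_error(read_adjusted_lengths(tempfile(), reference = ref),
               "no such")
})

test_that("transcripts shorter than the read length are excluded with a warning", {
  ref <- transcript_reference(c("long", "short"),
                              c(random_sequence(100, seed = 2),
                                random_sequence(20, seed = 3)))
  expect_warning(lens <- effective_lengths(ref, 35), "shorter")
  expect_equal(lens$key, "long")
  expect_equal(lens$effective_length, 66)
})

test_that("end-to-end bias stage runs from alignments", {
  set.seed(404)
  rl <- 20
  ref <- make_random_reference(n = 12, len_range = c(300, 500), seed = 21)
  mu <- rep(500, nrow(ref))
  sim <- simulate_reads(ref, mu, b = 1, read_length = rl, seed = 5)
  aln <- match_reads(sim$reads, ref)
  # exact matcher loses positions; attach them from the simulator truth
  aln <- dplyr::left_join(aln,
                          dplyr::select(sim$reads, "read_id", pos = "start"),
                          by = "read_id")
  res <- bias_adjusted_lengths(ref, aln, read_length = rl, window = 2,
                               top = 12, min_eligible = 5)
  expect_s3_class(res$model, "bias_model")
  expect_equal(nrow(res$lengths), nrow(ref))
  expect_true(all(res$lengths$adjusted_length > 0))
  expect_s3_class(autoplot(res$model), "ggplot")
})
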