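single_tx_inputs <- function(k = 10L, l_nt = 2000, b = 1) {
  sets <- tibble::tibble(set_id = 1L, transcripts = list("t1"),
                         n_transcripts = 1L, count = as.integer(k))
  lens <- tibble::tibble(key = "t1", true_length = l_nt + 34,
                         effective_length = l_nt, adjusted_length = l_nt)
  model_inputs(sets, lens, b = b)
}

test_that("EM initialization distributes each set's count evenly", {
  # one set {t1}, k = 6, b = 1, l = 2 kb -> mu0 = 3
  inp <- single_tx_inputs(k = 6L)
  expect_equal(em_initialize(inp), 3)

  # shared set {t1,t2}: even split
  sets <- tibble::tibble(set_id = 1L, transcripts = list(c("t1", "t2")),
                         n_transcripts = 2L, count = 6L)
  lens <- tibble::tibble(key = c("t1", "t2"), true_length = 2034,
                         effective_length = 2000, adjusted_length = 2000)
  expect_equal(em_initialize(model_inputs(sets, lens, b = 1)), c(1.5, 1.5))

  # transcript with no mapped sets starts at 0
  lens3 <- dplyr::bind_rows(lens, tibble::tibble(
    key = "t3", true_length = 2034, effective_length = 2000,
    adjusted_length = 2000))
  expect_equal(em_initialize(model_inputs(sets, lens3, b = 1))[3], 0)
})

test_that("EM reaches the closed-form ML for a single transcript and respects symmetry", {
  inp <- single_tx_inputs(k = 10L, l_nt = 2000, b = 1)
  for (start in c(0.01, 1, 50)) {
    expect_equal(em_update(start, inp), 10 / (1 * 2))  # one sweep suffices
  }
  res <- run_em(inp)
  expect_equal(unname(res$mu), 5)
  expect_lte(res$iterations, 2)

  # identical columns stay symmetric, sum = k / (b l)
  sets <- tibble::tibble(set_id = 1L, transcripts = list(c("t1", "t2")),
                         n_transcripts = 2L, count = 8L)
  lens <- tibble::tibble(key = c("t1", "t2"), true_length = 2034,
                         effective_length = 2000, adjusted_length = 2000)
  inp2 <- model_inputs(sets, lens, b = 1)
  mu <- c(1, 1)
  for (i in 1:50) mu <- em_update(mu, inp2)
  expect_equal(mu[1], mu[2])
  expect_equal(sum(mu), 8 / (1 * 2))

  expect_error(em_update(c(-1, 1), inp2), "non-negative")
})

test_that("EM matches brute-force likelihood maximization on the cassette-exon instance", {
  # two isoforms sharing flanking exons; three sets: shared {1,2}, and the
  # two exclusive regions (middle exon and its junctions)
  sets <- tibble::tibble(
    set_id = 1:3,
    transcripts = list(c("iso1", "iso2"), "iso1", "iso2"),
    n_transcripts = c(2L, 1L, 1L),
    count = c(40L, 25L, 9L)
  )
  lens <- tibble::tibble(key = c("iso1", "iso2"),
                         true_length = c(300, 200),
                         effective_length = c(266, 166),
                         adjusted_length = c(266, 166))
  inp <- model_inputs(sets, lens, b = 1)
  em <- run_em(inp, tol = 1e-10)
  set.seed(5)
  oracle <- brute_force_ml(inp)
  expect_equal(unname(em$mu), unname(oracle), tolerance = 1e-3)
  expect_gte(model_loglik(em$mu, inp), model_loglik(oracle, inp) - 1e-6)
})

test_that("EM sweep count and log-likelihood trace behave as specified", {
  inst <- random_instance(n_transcripts = 3, n_sets = 5, seed = 3)
  inp <- model_inputs(inst$sets, inst$lengths, b = 1)
  res5 <- run_em(inp, tol = 0, max_iter = 5)
  expect_equal(res5$iterations, 5L)

  res <- run_em(inp, trace = TRUE)
  expect_true(all(diff(res$loglik_trace) >= -1e-9))
})

test_that("EM log-likelihood is monotone on random instances", {
  for (seed in 1:20) {
    inst <- random_instance(n_transcripts = sample(2:6, 1),
                            n_sets = sample(3:8, 1), seed = seed)
    inp <- model_inputs(inst$sets, inst$lengths, b = 1)
    res <- run_em(inp, max_iter = 200, trace = TRUE)
    expect_true(all(diff(res$loglik_trace) >= -1e-8))
  }
})

test_that("RPKM equivalence: single transcript with r reads gives mu = r / (b l)", {
  r <- 250L
  total_reads <- 4e6
  b <- total_reads / 1e6
  inp <- single_tx_inputs(k = r, l_nt = 1500, b = b)
  expect_equal(unname(run_em(inp)$mu), r / (b * 1.5))
})

test_that("Gibbs matches the closed-form conjugate posterior when sets are singletons", {
  # k = 10, b = 1, l = 2 kb: posterior Gam(1.2 + 10, 0.001 + 2)
  inp <- single_tx_inputs(k = 10L, l_nt = 2000, b = 1)
  cfg <- gibbs_config(iterations = 8192, burn_in = 1024, thin = 4, seed = 42)
  s <- gibbs_run(inp, mu_init = run_em(inp)$mu, config = cfg)
  post_mean <- (1.2 + 10) / (0.001 + 2)
  expect_lt(abs(mean(s[, 1]) - post_mean), 3 * mcse(s[, 1]))

  # transcript with no mapped reads: pure prior conditional Gam(alpha, beta + b l)
  sets <- tibble::tibble(set_id = 1L, transcripts = list("t1"),
                         n_transcripts = 1L, count = 5L)
  lens <- tibble::tibble(key = c("t1", "t2"), true_length = 2034,
                         effective_length = 2000, adjusted_length = 2000)
  inp0 <- model_inputs(sets, lens, b = 1)
  s0 <- gibbs_run(inp0, mu_init = c(2.5, 0), config = cfg)
  prior_mean <- 1.2 / (0.001 + 2)
  expect_lt(abs(mean(s0[, "t2"]) - prior_mean), 3 * mcse(s0[, "t2"]))
  expect_true(all(s0[, "t2"] > 0))  # GS never returns exact zeros
})

test_that("every Gibbs sweep conserves reads within each set", {
  for (seed in 1:5) {
    inst <- random_instance(n_transcripts = 4, n_sets = 6, seed = seed)
    inp <- model_inputs(inst$sets, inst$lengths, b = 1)
    set.seed(seed)
    mu <- pmax(em_initialize(inp), 1e-6)
    for (sweep in 1:20) {
      sw <- gibbs_sweep(mu, inp)
      expect_equal(unname(rowSums(sw$X)), inp$k)
      mu <- sw$mu
    }
  }
})

test_that("compiled and R-level samplers agree in distribution on a shared-set instance", {
  sets <- tibble::tibble(
    set_id = 1:2, transcripts = list(c("t1", "t2"), "t1"),
    n_transcripts = c(2L, 1L), count = c(30L, 20L)
  )
  lens <- tibble::tibble(key = c("t1", "t2"), true_length = 1034,
                         effective_length = 1000, adjusted_length = 1000)
  inp <- model_inputs(sets, lens, b = 1)
  cfg <- gibbs_config(iterations = 4096, burn_in = 512, thin = 2, seed = 9)
  s_cpp <- gibbs_run(inp, mu_init = c(20, 10), config = cfg)

  set.seed(9)
  mu <- c(20, 10)
  keep <- matrix(NA_real_, 1000, 2)
  for (i in 1:1512) {
    sw <- gibbs_sweep(mu, inp)
    mu <- sw$mu
    if (i > 512) keep[i - 512, ] <- mu
  }
  for (j in 1:2) {
    se <- sqrt(mcse(s_cpp[, j])^2 + mcse(keep[, j])^2)
    expect_lt(abs(mean(s_cpp[, j]) - mean(keep[, j])), 4 * se)
  }
})

test_that("Gibbs chains are reproducible under a fixed seed", {
  inst <- random_instance(seed = 2)
  inp <- model_inputs(inst$sets, inst$lengths, b = 1)
  cfg <- gibbs_config(iterations = 200, burn_in = 50, seed = 77)
  mu0 <- em_initialize(inp)
  expect_identical(gibbs_run(inp, mu0, cfg), gibbs_run(inp, mu0, cfg))
})

test_that("batch-means MCSE is calibrated on iid, constant, and AR(1) chains", {
  set.seed(101)
  # iid N(0,1), n = 1e4: MCSE ~ 1/100
  x <- rnorm(1e4)
  expect_lt(abs(mcse(x) - 0.01), 0.003)

  expect_equal(mcse(rep(3.7, 500)), 0)
  expect_error(mcse(rnorm(50)), "at least 100")

  # AR(1), phi = 0.9: asymptotic SE = sd * sqrt((1+phi)/(1-phi)) / sqrt(n)
  phi <- 0.9; n <- 2e5
  ar <- as.numeric(stats::arima.sim(list(ar = phi), n))
  expected <- sd(ar) * sqrt((1 + phi) / (1 - phi)) / sqrt(n)
  expect_lt(abs(mcse(ar) - expected) / expected, 0.3)
})

test_that("identical-sequence transcripts amalgamate; gene and haplo-gene sums are per-sweep", {
  ref <- transcript_reference(
    c("a1", "a2", "b1", "h", "h"),
    c("ACGTACGTACGT", "ACGTACGTACGT", "TTTTCCCCGGGG",
      "ACACACACACAC", "ACACACACACAT"),
    gene_id = c("gA", "gA", "gB", "gH", "gH"),
    haplotype = c("none", "none", "none", "A", "B")
  )
  keys <- ref$key
  sets <- tibble::tibble(
    set_id = 1:4,
    transcripts = list(c("a1", "a2"), "b1", "h|A", "h|B"),
    n_transcripts = c(2L, 1L, 1L, 1L),
    count = c(50L, 20L, 40L, 10L)
  )
  lens <- tibble::tibble(key = keys, true_length = 1034,
                         effective_length = 1000, adjusted_length = 1000)
  fit <- haplo_quantify(sets, lens, b = 1, seed = 5,
                        iterations = 2000, burn_in = 200)

  am <- amalgamate_identical(fit, ref)
  grp <- am[am$n_members == 2, ]
  expect_equal(nrow(grp), 1L)
  expect_setequal(grp$members[[1]], c("a1", "a2"))
  members_mean <- sum(fit$transcripts$gs_mean[fit$transcripts$key %in%
                                                c("a1", "a2")])
  expect_equal(grp$gs_mean, members_mean, tolerance = 1e-8)
  # the sum is precisely estimated even though members are not
  expect_lt(grp$mcse, 0.1 * grp$gs_mean)

  genes <- aggregate_genes(fit, ref)
  gA <- genes[genes$gene_id == "gA" & genes$component == "all", ]
  expect_equal(gA$em,
               sum(fit$transcripts$em[fit$transcripts$key %in% c("a1", "a2")]))
  # haplo-gene components for the heterozygous gene
  hA <- genes[genes$gene_id == "gH" & genes$component == "A", ]
  hB <- genes[genes$gene_id == "gH" & genes$component == "B", ]
  expect_gt(hA$gs_mean, hB$gs_mean)  # 40 vs 10 reads
  # single-isoform gene table equals the transcript row
  gB <- genes[genes$gene_id == "gB" & genes$component == "all", ]
  expect_equal(gB$gs_mean,
               fit$transcripts$gs_mean[fit$transcripts$key == "b1"])
})

test_that("duplicated-sequence chains are anti-correlated with a stable sum", {
  sets <- tibble::tibble(set_id = 1L, transcripts = list(c("d1", "d2")),
                         n_transcripts = 2L, count = 60L)
  lens <- tibble::tibble(key = c("d1", "d2"), true_length = 1034,
                         effective_length = 1000, adjusted_length = 1000)
  fit <- haplo_quantify(sets, lens, b = 1, seed = 11)
  expect_lt(cor(fit$samples[, "d1"], fit$samples[, "d2"]), 0)
  sums <- rowSums(fit$samples)
  expect_lt(mcse(sums), 0.1 * mean(sums))
  # X_1 + X_2 = k every sweep, so the sum is Gam(2 alpha + k, beta + b l)
  # exactly (equal rates; shapes add to a constant)
  sum_mean <- (2 * 1.2 + 60) / (0.001 + 1 * 1)
  expect_lt(abs(mean(sums) - sum_mean), 4 * mcse(sums))
})

test_that("tidy, glance and autoplot expose the fit", {
  inst <- random_instance(seed = 6)
  inp_fit <- haplo_quantify(inst$sets, inst$lengths, b = 1, seed = 3,
                            iterations = 400, burn_in = 100)
  td <- tidy(inp_fit)
  expect_true(all(c("key", "em", "gs_mean", "gs_median", "mcse") %in%
                    names(td)))
  expect_true(all(td$mcse >= 0))
  gl <- glance(inp_fit)
  expect_equal(gl$n_reads, sum(inst$sets$count))
  expect_s3_class(autoplot(inp_fit), "ggplot")
  expect_s3_class(autoplot(inp_fit, type = "trace"), "ggplot")
})
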