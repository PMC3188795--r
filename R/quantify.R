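#' Estimate haplotype/isoform expression from transcript-set counts
#'
#' The central fitting routine: runs EM to the maximum-likelihood
#' expression estimates, then Poisson-Gamma Gibbs sampling initialized at
#' the EM solution, and summarizes the posterior per transcript with the
#' sample mean, median and Monte Carlo standard error. Expression is on the
#' RPKM scale when `b` is retained reads in millions and lengths are
#' nucleotides (converted to kb internally).
#'
#' @param sets Transcript-set table from [collect_transcript_sets()].
#' @param lengths Effective-length tibble from [effective_lengths()].
#' @param b Total retained reads in millions; default computed from `sets`.
#' @param alpha,beta Gamma hyperprior parameters (defaults 1.2 and 0.001).
#' @param iterations,burn_in,thin Gibbs schedule, see [gibbs_config()].
#' @param seed Integer seed for the Gibbs chain.
#' @param em_tol,em_max_iter EM convergence controls, see [run_em()].
#' @param keep_samples Keep the posterior sample matrix on the object
#'   (needed for amalgamation and gene aggregation). Default TRUE.
#' @return An object of class `haplo_fit` with elements `transcripts`
#'   (tibble: `key`, `em`, `gs_mean`, `gs_median`, `mcse`,
#'   `effective_length`, `n_reads_unique`, `n_sets`), `samples`, `inputs`,
#'   `em` (full EM result) and `config`.
#' @examples
#' sets <- tibble::tibble(set_id = 1L, transcripts = list("t1"),
#'                        n_transcripts = 1L, count = 10L)
#' lens <- tibble::tibble(key = "t1", true_length = 1034,
#'                        effective_length = 1000, adjusted_length = 1000)
#' fit <- haplo_quantify(sets, lens, b = 1, seed = 1, iterations = 1000,
#'                       burn_in = 100)
#' tidy(fit)
#' @export
haplo_quantify <- function(sets, lengths, b = NULL,
                           alpha = 1.2, beta = 0.001,
                           iterations = 8192, burn_in = 1024, thin = 4,
                           seed = NULL,
                           em_tol = 1e-6, em_max_iter = 10000,
                           keep_samples = TRUE) {
  inputs <- model_inputs(sets, lengths, b = b)
  em <- run_em(inputs, tol = em_tol, max_iter = em_max_iter, trace = TRUE)
  config <- gibbs_config(alpha = alpha, beta = beta, iterations = iterations,
                         burn_in = burn_in, thin = thin, seed = seed)
  samples <- gibbs_run(inputs, em$mu, config)
  n_unique <- unique_read_counts(sets, inputs$keys)
  n_sets_per <- as.integer(Matrix::colSums(inputs$M))
  lmatch <- match(inputs$keys, lengths$key)
  transcripts <- tibble(
    key = inputs$keys,
    em = unname(em$mu),
    gs_mean = unname(colMeans(samples)),
    gs_median = unname(apply(samples, 2, median)),
    mcse = unname(apply(samples, 2, mcse)),
    effective_length = (lengths$adjusted_length %||%
                          lengths$effective_length)[lmatch],
    n_reads_unique = n_unique,
    n_sets = n_sets_per
  )
  structure(
    list(transcripts = transcripts,
         samples = if (keep_samples) samples else NULL,
         inputs = inputs, em = em, config = config),
    class = "haplo_fit"
  )
}

unique_read_counts <- function(sets, keys) {
  singles <- sets[lengths(sets$transcripts) == 1L, ]
  cnt <- setNames(rep(0L, length(keys)), keys)
  if (nrow(singles)) {
    one <- unlist(singles$transcripts)
    cnt[one] <- cnt[one] + as.integer(singles$count)
  }
  unname(cnt)
}

#' @export
#' @method print haplo_fit
print.haplo_fit <- function(x, ...) {
  cat("<haplo_fit> ", length(x$inputs$keys), " transcripts, ",
      nrow(x$inputs$M), " sets, ", sum(x$inputs$k), " reads; EM ",
      x$em$iterations, " iterations, Gibbs ", nrow(x$samples %||% matrix(0, 0, 0)),
      " kept sweeps\n", sep = "")
  print(x$transcripts, n = 6)
  invisible(x)
}

#' @describeIn haplo_quantify Per-transcript estimates as a tibble.
#' @param x,object A `haplo_fit`.
#' @param ... Unused.
#' @export
tidy.haplo_fit <- function(x, ...) x$transcripts

#' @describeIn haplo_quantify One-row model-level summary.
#' @export
glance.haplo_fit <- function(x, ...) {
  tibble(
    n_transcripts = length(x$inputs$keys),
    n_sets = nrow(x$inputs$M),
    n_reads = sum(x$inputs$k),
    b = x$inputs$b,
    em_iterations = x$em$iterations,
    em_converged = x$em$converged,
    loglik = x$em$loglik,
    alpha = x$config$alpha,
    beta = x$config$beta,
    gibbs_kept = nrow(x$samples %||% matrix(0, 0, 0))
  )
}

#' Plot a fitted expression model
#'
#' `type = "estimates"` compares EM (maximum-likelihood) and Gibbs
#' posterior-mean estimates per transcript on log axes — the Bayesian
#' regularization is visible as low-expression transcripts pulled off zero.
#' `type = "trace"` shows posterior traces for selected transcripts.
#'
#' @param object A `haplo_fit`.
#' @param type `"estimates"` or `"trace"`.
#' @param keys Transcript keys to trace (default: first four).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.haplo_fit <- function(object, type = c("estimates", "trace"),
                               keys = NULL, ...) {
  type <- match.arg(type)
  if (type == "estimates") {
    df <- object$transcripts
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$em + 1e-3,
                                       y = .data$gs_mean + 1e-3)) +
        ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                             colour = "grey60") +
        ggplot2::geom_point(alpha = 0.6) +
        ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
        ggplot2::labs(x = "EM estimate (RPKM + 1e-3)",
                      y = "Gibbs posterior mean (RPKM + 1e-3)")
    )
  }
  if (is.null(object$samples)) abort("fit was run with keep_samples = FALSE")
  if (is.null(keys)) keys <- head(colnames(object$samples), 4)
  df <- as_tibble(object$samples[, keys, drop = FALSE])
  df$sweep <- seq_len(nrow(df))
  df <- tidyr::pivot_longer(df, -"sweep", names_to = "key",
                            values_to = "mu")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sweep, y = .data$mu)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~key, scales = "free_y") +
    ggplot2::labs(x = "kept sweep", y = expression(mu))
}

#' Amalgamate transcripts with identical sequences
#'
#' Transcripts whose sequences are byte-identical are unidentifiable
#' individually (their posterior chains are strongly anti-correlated), but
#' their summed expression is well determined. This groups such transcripts
#' and summarizes the per-sweep *sum* of their samples; sequences are
#' compared directly, not via shared M columns, since distinct sequences can
#' share columns at low depth.
#'
#' @param fit A `haplo_fit` with samples kept.
#' @param reference Transcript reference providing the sequences.
#' @return Tibble with one row per group: `group_id`, `members` (list of
#'   keys), `n_members`, `em`, `gs_mean`, `gs_median`, `mcse`.
#' @export
amalgamate_identical <- function(fit, reference) {
  if (is.null(fit$samples)) abort("fit was run with keep_samples = FALSE")
  keys <- fit$inputs$keys
  ref_keys <- ref_key(reference$transcript_id, reference$haplotype)
  seqs <- reference$sequence[match(keys, ref_keys)]
  if (anyNA(seqs)) abort("reference lacks sequences for some fitted transcripts")
  grp <- match(seqs, unique(seqs))
  summarise_groups(fit, split(keys, grp), prefix = "amalgam")
}

summarise_groups <- function(fit, groups, prefix) {
  em_hat <- setNames(fit$transcripts$em, fit$transcripts$key)
  rows <- lapply(seq_along(groups), function(g) {
    ks <- groups[[g]]
    sums <- rowSums(fit$samples[, ks, drop = FALSE])
    tibble(
      group_id = paste0(prefix, "_", g),
      members = list(ks),
      n_members = length(ks),
      em = sum(em_hat[ks]),
      gs_mean = mean(sums),
      gs_median = median(sums),
      mcse = mcse(sums)
    )
  })
  bind_rows(rows)
}

#' Aggregate transcript expression to genes and haplo-genes
#'
#' Gene-level expression is the per-sweep sum of the posterior samples over
#' all of a gene's transcripts (all haplotype tags collapsed). For genes
#' with heterozygous isoforms, haplo-gene estimates additionally sum tag-A
#' and tag-B isoforms separately; homozygous (tag `none`) isoforms of such
#' genes are reported as a distinct `shared` component rather than counted
#' into either haplotype.
#'
#' @param fit A `haplo_fit` with samples kept.
#' @param reference Transcript reference providing gene ids and tags.
#' @return Tibble with columns `gene_id`, `component` (`all`, `A`, `B`,
#'   `shared`), `em`, `gs_mean`, `gs_median`, `mcse`, `n_members`.
#' @export
aggregate_genes <- function(fit, reference) {
  if (is.null(fit$samples)) abort("fit was run with keep_samples = FALSE")
  keys <- fit$inputs$keys
  ref_keys <- ref_key(reference$transcript_id, reference$haplotype)
  idx <- match(keys, ref_keys)
  if (anyNA(idx)) {
    abort(paste0("fitted transcripts missing from the reference: ",
                 paste(head(keys[is.na(idx)], 5), collapse = ", ")))
  }
  info <- tibble(key = keys, gene_id = reference$gene_id[idx],
                 haplotype = reference$haplotype[idx])
  em_hat <- setNames(fit$transcripts$em, keys)
  out <- list()
  for (g in unique(info$gene_id)) {
    sub <- info[info$gene_id == g, ]
    comps <- list(all = sub$key)
    if (any(sub$haplotype != "none")) {
      comps$A <- sub$key[sub$haplotype == "A"]
      comps$B <- sub$key[sub$haplotype == "B"]
      comps$shared <- sub$key[sub$haplotype == "none"]
      comps <- comps[lengths(comps) > 0]
    }
    for (cname in names(comps)) {
      ks <- comps[[cname]]
      sums <- rowSums(fit$samples[, ks, drop = FALSE])
      out[[length(out) + 1L]] <- tibble(
        gene_id = g, component = cname,
        em = sum(em_hat[ks]), gs_mean = mean(sums),
        gs_median = median(sums), mcse = mcse(sums),
        n_members = length(ks)
      )
    }
  }
  bind_rows(out)
}

#' Write the three estimate tables
#'
#' Writes transcript/haplo-isoform, amalgamated-group, and gene/haplo-gene
#' tables as TSV, each preceded by `#`-comment provenance lines recording
#' the package version, b, the hyperprior, the Gibbs schedule and the seed.
#'
#' @param fit A `haplo_fit`.
#' @param reference Transcript reference used for the fit.
#' @param prefix Output path prefix; files are
#'   `<prefix>.transcripts.tsv`, `<prefix>.amalgamated.tsv`,
#'   `<prefix>.genes.tsv`.
#' @return Character vector of the three paths, invisibly.
#' @export
write_estimates <- function(fit, reference, prefix) {
  hdr <- c(
    paste0("# haploquant ", as.character(packageVersion("haploquant"))),
    paste0("# b=", fit$inputs$b, " alpha=", fit$config$alpha,
           " beta=", fit$config$beta),
    paste0("# iterations=", fit$config$iterations, " burn_in=",
           fit$config$burn_in, " thin=", fit$config$thin, " seed=",
           fit$config$seed %||% "NA", " rng=", RNGkind()[1])
  )
  paths <- paste0(prefix, c(".transcripts.tsv", ".amalgamated.tsv",
                            ".genes.tsv"))
  tabs <- list(
    fit$transcripts,
    mutate(amalgamate_identical(fit, reference),
           members = vapply(.data$members, paste, "", collapse = ",")),
    aggregate_genes(fit, reference)
  )
  for (j in 1:3) {
    con <- file(paths[j], "w")
    writeLines(hdr, con)
    write.table(tabs[[j]], con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(paths)
}
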