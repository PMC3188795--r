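#' Assemble model inputs from a set table and effective lengths
#'
#' Packs the transcript-set counts (M, k), the per-transcript effective
#' lengths and the normalization constant b into the object consumed by
#' [run_em()] and [gibbs_run()]. Lengths enter the Poisson rate in
#' kilobases and b is the number of retained reads in millions, so the
#' expression parameter mu_t is on the RPKM scale. Note the model needs
#' only (M, k, b, l): the shared-region lengths s_i cancel from every
#' update and are never computed here.
#'
#' @param sets Transcript-set table from [collect_transcript_sets()].
#' @param lengths Effective-length tibble from [effective_lengths()] with
#'   columns `key` and `adjusted_length` (falls back to
#'   `effective_length` when no bias adjustment was made).
#' @param b Normalization constant: total retained reads in millions.
#'   Default `sum(sets$count) / 1e6`.
#' @param keys Column (transcript) ordering; defaults to the order of
#'   `lengths$key`, i.e. reference order. Transcripts absent from every set
#'   are retained with zero counts.
#' @return An object of class `haplo_model_inputs`: list with the sparse
#'   indicator matrix `M` (sets x transcripts), counts `k`, transcript
#'   `keys`, lengths `l_kb`, and `b`.
#' @export
model_inputs <- function(sets, lengths, b = NULL, keys = lengths$key) {
  if (is.null(b)) b <- sum(sets$count) / 1e6
  if (b <= 0) abort("normalization constant b must be positive")
  l <- lengths$adjusted_length %||% lengths$effective_length
  if (is.null(l)) abort("lengths must carry adjusted_length or effective_length")
  names(l) <- lengths$key
  missing_l <- setdiff(unique(unlist(sets$transcripts)), lengths$key)
  if (length(missing_l)) {
    abort(paste0("sets reference transcripts with no effective length: ",
                 paste(head(missing_l, 5), collapse = ", ")))
  }
  l <- l[keys]
  if (any(!is.finite(l)) || any(l < 1)) {
    abort("every transcript needs a finite effective length >= 1")
  }
  n_sets <- nrow(sets)
  tidx <- lapply(sets$transcripts, function(s) match(s, keys))
  i <- rep(seq_len(n_sets), lengths(tidx))
  M <- Matrix::sparseMatrix(i = i, j = unlist(tidx), x = 1,
                            dims = c(n_sets, length(keys)))
  structure(
    list(M = M, k = as.numeric(sets$count), keys = keys,
         l_kb = unname(l) / 1000, b = b,
         set_members = lapply(tidx, as.integer)),
    class = "haplo_model_inputs"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
#' @method print haplo_model_inputs
print.haplo_model_inputs <- function(x, ...) {
  cat("<haplo_model_inputs> ", nrow(x$M), " transcript sets x ",
      length(x$keys), " transcripts, ", sum(x$k), " reads (b = ",
      signif(x$b, 4), ")\n", sep = "")
  invisible(x)
}

#' EM starting point: distribute each set's reads evenly
#'
#' mu_t^(0) = (1 / (b l_t)) * sum_i M_it k_i / |set i|, i.e. each set's
#' count split evenly among its member transcripts.
#'
#' @param inputs A `haplo_model_inputs` object.
#' @return Numeric vector of starting expression values (RPKM scale), one
#'   per transcript.
#' @export
em_initialize <- function(inputs) {
  share <- inputs$k / Matrix::rowSums(inputs$M)
  as.numeric(Matrix::crossprod(inputs$M, share)) / (inputs$b * inputs$l_kb)
}

#' One exact EM sweep
#'
#' E-step: expected allocation of each set's count across its members,
#' E(X_it) = k_i M_it mu_t / sum_t' M_it' mu_t'. M-step: Poisson ML with the
#' expectations plugged in, mu_t <- sum_i E(X_it) / (b l_t). Sets whose
#' members all have mu = 0 contribute nothing (consistent only if k_i = 0).
#'
#' @param mu Current expression vector (non-negative).
#' @param inputs A `haplo_model_inputs` object.
#' @return Updated expression vector.
#' @export
em_update <- function(mu, inputs) {
  if (any(mu < 0)) abort("expression values must be non-negative")
  denom <- as.numeric(inputs$M %*% mu)
  w <- ifelse(denom > 0, inputs$k / denom, 0)
  mu * as.numeric(Matrix::crossprod(inputs$M, w)) / (inputs$b * inputs$l_kb)
}

#' Observed-data Poisson log-likelihood (up to an additive constant)
#'
#' l(mu) = sum_i k_i log(sum_t M_it mu_t) - b sum_t l_t mu_t + const.
#' The shared-region lengths s_i only enter the constant, so the trace is
#' computable from (M, k, b, l) alone.
#'
#' @param mu Expression vector.
#' @param inputs A `haplo_model_inputs` object.
#' @return Scalar log-likelihood (relative).
#' @export
model_loglik <- function(mu, inputs) {
  tot <- as.numeric(inputs$M %*% mu)
  ll_terms <- ifelse(inputs$k > 0, inputs$k * log(tot), 0)
  if (any(inputs$k > 0 & tot <= 0)) return(-Inf)
  sum(ll_terms) - inputs$b * sum(inputs$l_kb * mu)
}

#' Run EM to convergence
#'
#' Iterates [em_update()] from [em_initialize()] until the maximum relative
#' change of mu (over transcripts with mu > active_floor) drops below `tol`
#' or `max_iter` sweeps have run.
#'
#' @param inputs A `haplo_model_inputs` object.
#' @param tol Relative-change convergence threshold (default 1e-6).
#' @param max_iter Maximum sweeps (default 10000).
#' @param active_floor Transcripts below this value are ignored in the
#'   convergence criterion (default 1e-8).
#' @param trace Record the log-likelihood at every sweep?
#' @return List with `mu` (named by transcript key), `iterations`,
#'   `loglik` (final relative log-likelihood), `converged`, and, when
#'   `trace = TRUE`, the per-sweep `loglik_trace`.
#' @export
run_em <- function(inputs, tol = 1e-6, max_iter = 10000,
                   active_floor = 1e-8, trace = FALSE) {
  mu <- em_initialize(inputs)
  ll_trace <- if (trace) numeric(max_iter) else NULL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    mu_new <- em_update(mu, inputs)
    if (trace) ll_trace[iter] <- model_loglik(mu_new, inputs)
    active <- mu > active_floor
    rel <- if (any(active)) {
      max(abs(mu_new[active] - mu[active]) / mu[active])
    } else 0
    mu <- mu_new
    if (rel < tol) { converged <- TRUE; break }
  }
  ll <- model_loglik(mu, inputs)
  if (!is.finite(ll) && any(inputs$k > 0)) {
    abort("EM produced a non-finite log-likelihood")
  }
  list(mu = setNames(mu, inputs$keys), iterations = iter, loglik = ll,
       converged = converged,
       loglik_trace = if (trace) ll_trace[seq_len(iter)] else NULL)
}

#' Gibbs sampler configuration
#'
#' Hyperprior Gam(alpha, beta) on each mu_t; defaults alpha = 1.2,
#' beta = 0.001 give a vague prior matching the broad, skewed distribution
#' of expression values.
#'
#' @param alpha,beta Gamma hyperprior shape and rate (both > 0).
#' @param iterations Kept sweeps after burn-in (before thinning).
#' @param burn_in Discarded initial sweeps.
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param seed Integer seed; required for reproducible chains.
#' @return A `gibbs_config` list.
#' @export
gibbs_config <- function(alpha = 1.2, beta = 0.001, iterations = 8192,
                         burn_in = 1024, thin = 4, seed = NULL) {
  stopifnot(alpha > 0, beta > 0, iterations > 0, burn_in >= 0, thin >= 1)
  structure(list(alpha = alpha, beta = beta,
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = seed),
            class = "gibbs_config")
}

#' Poisson-Gamma Gibbs sampling of expression
#'
#' Alternates the two closed-form full conditionals: (a) each set's count
#' k_i is allocated across its member transcripts by a multinomial draw
#' with probabilities proportional to mu_t; (b) each mu_t is redrawn from
#' Gam(alpha + sum_i X_it, beta + b l_t). Every sweep conserves reads:
#' sum_t X_it = k_i for all i.
#'
#' @param inputs A `haplo_model_inputs` object.
#' @param mu_init Initial expression vector, normally the EM estimate.
#' @param config A [gibbs_config()].
#' @return Matrix of kept posterior samples (sweeps x transcripts), columns
#'   named by transcript key.
#' @export
gibbs_run <- function(inputs, mu_init, config = gibbs_config()) {
  stopifnot(inherits(config, "gibbs_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  mu0 <- pmax(as.numeric(mu_init), 1e-12)
  samples <- cpp_gibbs(inputs$set_members, inputs$k, mu0,
                       inputs$b, inputs$l_kb,
                       config$alpha, config$beta,
                       config$iterations, config$burn_in, config$thin)
  colnames(samples) <- inputs$keys
  samples
}

#' One Gibbs sweep in plain R (reference implementation)
#'
#' Slow, explicit version of the sweep used by [gibbs_run()]'s compiled
#' loop, returning the latent allocation matrix as well. Used to verify
#' read conservation and as an independent cross-check of the compiled
#' sampler.
#'
#' @param mu Current expression vector.
#' @param inputs A `haplo_model_inputs` object.
#' @param config A [gibbs_config()] (for alpha and beta).
#' @return List with `X` (dense sets x transcripts allocation matrix) and
#'   `mu` (freshly drawn expression vector).
#' @export
gibbs_sweep <- function(mu, inputs, config = gibbs_config()) {
  n_sets <- length(inputs$k)
  n_t <- length(inputs$keys)
  X <- matrix(0, n_sets, n_t)
  for (i in seq_len(n_sets)) {
    members <- inputs$set_members[[i]]
    p <- mu[members]
    if (sum(p) <= 0) p <- rep(1, length(members))
    X[i, members] <- as.numeric(rmultinom(1, inputs$k[i], p))
  }
  shape <- config$alpha + colSums(X)
  rate <- config$beta + inputs$b * inputs$l_kb
  list(X = X, mu = rgamma(n_t, shape = shape, rate = rate))
}

#' Monte Carlo standard error by batch means
#'
#' Splits the chain into batches of size floor(sqrt(n)) and returns
#' sd(batch means) / sqrt(number of batches), a consistent estimator of
#' the standard error of the posterior-mean estimate that accounts for
#' chain autocorrelation. Any remainder after the last full batch is
#' discarded.
#'
#' @param chain Numeric vector of kept samples (length >= 100).
#' @return The Monte Carlo standard error (scalar >= 0).
#' @export
mcse <- function(chain) {
  n <- length(chain)
  if (n < 100L) abort("mcse needs a chain of at least 100 samples")
  bs <- floor(sqrt(n))
  nb <- n %/% bs
  means <- colMeans(matrix(chain[seq_len(nb * bs)], nrow = bs))
  sd(means) / sqrt(nb)
}
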