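#' Effective transcript lengths
#'
#' Under uniform read sampling the effective length of a transcript is the
#' number of possible read start positions, `true_length - read_length + 1`.
#' When a fitted [bias_model] is supplied, the adjusted effective length is
#' the sum of per-position sequence preferences
#' `l~_t = sum_p alpha_tp`, `alpha_tp = exp(intercept + sum_w coef)`,
#' which reduces to the uniform length for a null model. Transcripts
#' shorter than the read length are excluded with a warning.
#'
#' @param reference Transcript reference tibble.
#' @param read_length Read length in nt.
#' @param bias Optional `bias_model` from [fit_bias_model()].
#' @return Tibble with columns `key`, `true_length`, `effective_length`,
#'   `adjusted_length` (equal to `effective_length` when `bias` is NULL).
#' @export
effective_lengths <- function(reference, read_length, bias = NULL) {
  short <- reference$true_length < read_length
  if (any(short)) {
    warn(paste0("excluding ", sum(short),
                " transcript(s) shorter than the read length: ",
                paste(head(reference$key, 5)[head(short, 5)], collapse = ", ")))
    reference <- reference[!short, ]
  }
  l <- reference$true_length - read_length + 1
  adj <- if (is.null(bias)) {
    as.numeric(l)
  } else {
    vapply(reference$sequence, adjusted_effective_length, numeric(1),
           model = bias, read_length = read_length, USE.NAMES = FALSE)
  }
  tibble(key = reference$key, true_length = reference$true_length,
         effective_length = as.numeric(l), adjusted_length = adj)
}

#' Select high-coverage training transcripts for the bias fit
#'
#' Ranks transcripts by coverage (descending, ties broken by key) and keeps
#' the highest-coverage isoform of each gene, up to `n` transcripts, so that
#' shared exonic sequence is not double-counted in the regression.
#'
#' @param coverage Tibble with columns `key` and `coverage` (mean
#'   sequenced nucleotides per position, e.g. unique reads x read length /
#'   effective length).
#' @param gene_map Tibble with columns `key` and `gene_id`.
#' @param n Maximum transcripts to keep (default 500).
#' @param min_eligible Minimum transcripts required to proceed (default 10;
#'   below this the bias model is considered unfittable).
#' @return Character vector of selected transcript keys.
#' @export
select_training_transcripts <- function(coverage, gene_map, n = 500,
                                        min_eligible = 10) {
  eligible <- coverage |>
    filter(.data$coverage > 0) |>
    left_join(gene_map, by = "key") |>
    arrange(dplyr::desc(.data$coverage), .data$key) |>
    distinct(.data$gene_id, .keep_all = TRUE) |>
    slice_head(n = n)
  if (nrow(eligible) < min_eligible) {
    abort(paste0("only ", nrow(eligible),
                 " eligible training transcripts (need >= ", min_eligible,
                 "); bias model unfittable"))
  }
  eligible$key
}

#' Per-transcript coverage for training selection
#'
#' Coverage is computed from uniquely assigned reads only (singleton
#' transcript sets), as `unique_reads * read_length / effective_length` —
#' the mean number of sequenced nucleotides per transcript position.
#'
#' @param sets Transcript-set table.
#' @param lengths Effective-length tibble.
#' @param read_length Read length in nt.
#' @return Tibble with columns `key` and `coverage`.
#' @export
transcript_coverage <- function(sets, lengths, read_length) {
  uniq <- unique_read_counts(sets, lengths$key)
  tibble(key = lengths$key,
         coverage = uniq * read_length / lengths$effective_length)
}

new_bias_model <- function(intercept, coefficients, window) {
  stopifnot(all(c("offset", "base", "estimate") %in% names(coefficients)))
  structure(list(intercept = intercept,
                 coefficients = as_tibble(coefficients),
                 window = as.integer(window)),
            class = "bias_model")
}

#' A null (uniform-sampling) bias model
#'
#' @param window Window half-width in nt.
#' @return A `bias_model` with zero intercept and coefficients; under it
#'   the adjusted effective length equals the uniform effective length.
#' @export
null_bias_model <- function(window = 20) {
  grid <- tidyr::expand_grid(offset = -window:window,
                             base = c("A", "C", "G", "T"))
  grid$estimate <- 0
  grid$std_error <- NA_real_
  new_bias_model(0, grid, window)
}

#' @export
#' @method print bias_model
print.bias_model <- function(x, ...) {
  cat("<bias_model> window +/-", x$window, "nt, intercept ",
      signif(x$intercept, 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.bias_model <- function(x, ...) x$coefficients

#' Plot positional bias coefficients
#'
#' @param object A `bias_model`.
#' @param ... Unused.
#' @return A ggplot of coefficient vs offset, one line per base.
#' @export
autoplot.bias_model <- function(object, ...) {
  ggplot2::ggplot(object$coefficients,
                  ggplot2::aes(x = .data$offset, y = .data$estimate,
                               colour = .data$base)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offset from read start (nt)",
                  y = "log sequence preference")
}

#' Fit the positional sequence-bias Poisson regression
#'
#' Regresses per-position read-start counts on one-hot indicators of the
#' bases at offsets -window..+window around each possible start position
#' (offset 0 is the start base itself), with the transcript's expected
#' per-position rate `log(b * mu_hat_t)` as an exposure offset so that
#' expression differences between training transcripts are absorbed.
#' Positions whose window overhangs a transcript end, or whose window
#' contains an N, are excluded from the design. Reference-cell coding fixes
#' base A to 0 at every offset. After fitting, the intercept is recentred
#' so the mean preference over training positions is exactly 1: the
#' absolute start rate (reads per position) belongs to the expression
#' parameter, not the length, and this normalization keeps adjusted
#' lengths on the nucleotide scale (equal to the uniform effective length
#' when no bias is present).
#'
#' @param reference Transcript reference restricted to (or indexable by)
#'   the training transcripts.
#' @param start_counts Tibble with columns `key`, `pos`, `count`: read
#'   starts per position. Positions not listed are taken as zero within
#'   `1..(length - read_length + 1)`.
#' @param expression Tibble with columns `key` and `mu` — first-pass
#'   (uniform-length) expression estimates for the exposure term.
#' @param b Normalization constant (reads in millions), as used downstream.
#' @param read_length Read length in nt.
#' @param window Window half-width (default 20).
#' @param ridge Optional non-negative ridge penalty on the coefficients
#'   (default 0 = plain ML Poisson regression).
#' @return A `bias_model`.
#' @export
fit_bias_model <- function(reference, start_counts, expression, b,
                           read_length, window = 20, ridge = 0) {
  keys <- intersect(unique(start_counts$key), reference$key)
  if (!length(keys)) abort("no start counts match the reference")
  mu_hat <- setNames(expression$mu, expression$key)[keys]
  if (anyNA(mu_hat)) abort("expression estimates missing for some training transcripts")
  design <- list(); resp <- list(); expo <- list()
  for (key in keys) {
    rec <- reference[reference$key == key, ]
    L <- rec$true_length
    n_pos <- L - read_length + 1
    p_lo <- max(1L, 1L + window)
    p_hi <- min(n_pos, L - window)
    if (p_hi < p_lo) next
    p <- p_lo:p_hi
    bases <- strsplit(rec$sequence, "")[[1]]
    winmat <- vapply(-window:window, function(o) bases[p + o],
                     character(length(p)))
    has_n <- apply(winmat == "N", 1, any)
    p <- p[!has_n]; winmat <- winmat[!has_n, , drop = FALSE]
    if (!length(p)) next
    cnt <- integer(length(p))
    sc <- start_counts[start_counts$key == key, ]
    hit <- match(sc$pos, p)
    ok <- !is.na(hit)
    cnt[hit[ok]] <- sc$count[ok]
    design[[key]] <- winmat
    resp[[key]] <- cnt
    expo[[key]] <- rep(log(b * mu_hat[[key]]), length(p))
  }
  if (!length(design)) abort("no usable training positions (transcripts too short for the window?)")
  W <- do.call(rbind, design)
  y <- unlist(resp, use.names = FALSE)
  off <- unlist(expo, use.names = FALSE)
  if (all(y == 0)) abort("all training start counts are zero; bias model unfittable")
  offsets <- -window:window
  df <- as.data.frame(lapply(seq_along(offsets), function(j) {
    factor(W[, j], levels = c("A", "C", "G", "T"))
  }))
  names(df) <- paste0("o", gsub("-", "m", offsets))
  form <- stats::as.formula(paste("y ~", paste(names(df), collapse = " + ")))
  df$y <- y
  if (ridge > 0) {
    fit <- fit_ridge_poisson(df, form, off, ridge)
  } else {
    fit <- glm(form, family = poisson(), data = df, offset = off)
    if (!fit$converged) abort("bias-model Poisson regression did not converge")
  }
  cf <- coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  grid <- tidyr::expand_grid(offset = offsets, base = c("A", "C", "G", "T"))
  nm <- paste0("o", gsub("-", "m", grid$offset), grid$base)
  grid$estimate <- ifelse(grid$base == "A", 0, unname(cf[nm]))
  grid$std_error <- ifelse(grid$base == "A", NA_real_, unname(se[nm]))
  grid$estimate[is.na(grid$estimate)] <- 0
  # recentre: the regression intercept absorbs the absolute start rate
  # (reads per position), which belongs to mu, not to the length. Setting
  # the intercept so the mean preference over training positions is 1
  # makes l~ a length (l~ = l under no bias) and leaves the rate to mu.
  cf_full <- setNames(grid$estimate, paste0("o", gsub("-", "m", grid$offset),
                                            grid$base))
  mm <- stats::model.matrix(form, df)
  lp <- as.numeric(mm[, -1, drop = FALSE] %*%
                     cf_full[colnames(mm)[-1]])
  intercept <- -log(mean(exp(lp)))
  new_bias_model(intercept, grid, window)
}

fit_ridge_poisson <- function(df, form, off, ridge) {
  # small-sample stabilization: quadratic penalty via data augmentation is
  # messy for glm; use glm with a penalized IRLS refit instead
  X <- stats::model.matrix(form, df)
  y <- df$y
  beta <- rep(0, ncol(X))
  for (it in 1:100) {
    eta <- as.numeric(X %*% beta) + off
    muv <- exp(pmin(eta, 30))
    Wd <- muv
    z <- eta - off + (y - muv) / muv
    pen <- diag(ridge, ncol(X)); pen[1, 1] <- 0
    beta_new <- solve(crossprod(X, X * Wd) + pen, crossprod(X, Wd * z))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- as.numeric(beta_new)
  }
  fit <- list(coefficients = setNames(as.numeric(beta), colnames(X)))
  fit$vcov <- solve(crossprod(X, X * exp(pmin(as.numeric(X %*% beta) + off, 30))) +
                      diag(ridge, ncol(X)))
  class(fit) <- "ridge_poisson"
  fit
}

#' @export
#' @method coef ridge_poisson
coef.ridge_poisson <- function(object, ...) object$coefficients
#' @export
#' @method vcov ridge_poisson
vcov.ridge_poisson <- function(object, ...) object$vcov

#' Fit the bias model from filtered alignments and adjust all lengths
#'
#' Convenience wrapper tying the bias stage together: computes coverage
#' from uniquely mapped reads, selects one high-coverage transcript per
#' gene, obtains first-pass (uniform-length) EM expression for the
#' exposure term, tallies read-start counts on the training transcripts
#' from uniquely mapped alignments, fits the Poisson regression, and
#' returns adjusted effective lengths for the whole reference.
#'
#' @param reference Transcript reference tibble.
#' @param alignments Filtered alignment tibble carrying a `pos` column.
#' @param read_length Read length in nt.
#' @param window Window half-width (default 20).
#' @param top Maximum training transcripts (default 500).
#' @param min_eligible Passed to [select_training_transcripts()].
#' @return List with `model` (the `bias_model`) and `lengths` (the
#'   adjusted effective-length tibble).
#' @export
bias_adjusted_lengths <- function(reference, alignments, read_length,
                                  window = 20, top = 500,
                                  min_eligible = 10) {
  if (!"pos" %in% names(alignments)) {
    abort("alignments need a pos column for start counts; use read_alignments() on SAM/BAM")
  }
  sets <- collect_transcript_sets(alignments)
  lens <- effective_lengths(reference, read_length)
  cov <- transcript_coverage(sets, lens, read_length)
  train <- select_training_transcripts(
    cov, tibble(key = reference$key, gene_id = reference$gene_id),
    n = top, min_eligible = min_eligible
  )
  first_pass <- run_em(model_inputs(sets, lens))
  # uniquely mapping reads only: one alignment target per read
  uniq <- alignments |>
    group_by(.data$read_id) |>
    filter(dplyr::n_distinct(.data$key) == 1L) |>
    ungroup() |>
    filter(.data$key %in% train)
  starts <- dplyr::count(uniq, .data$key, .data$pos, name = "count")
  model <- fit_bias_model(
    reference, starts,
    expression = tibble(key = names(first_pass$mu),
                        mu = pmax(unname(first_pass$mu), 1e-8)),
    b = sum(sets$count) / 1e6, read_length = read_length, window = window
  )
  list(model = model,
       lengths = effective_lengths(reference, read_length, bias = model))
}

#' Adjusted effective length of one sequence
#'
#' `l~ = sum_{p=1}^{L - read_length + 1} alpha_p` with
#' `alpha_p = exp(intercept + sum_{o in -W..W} coef[o, base at p + o])`.
#' Offsets falling outside the sequence (window overhanging an end) and N
#' bases contribute 0 to the log preference, so a null model returns the
#' uniform effective length exactly.
#'
#' @param sequence Nucleotide string.
#' @param model A `bias_model`.
#' @param read_length Read length in nt (sequence must be at least this
#'   long).
#' @return The adjusted effective length (positive real).
#' @export
adjusted_effective_length <- function(sequence, model, read_length) {
  L <- nchar(sequence)
  if (L < read_length) abort("sequence shorter than the read length")
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
  sum(exp(loga))
}

#' Persist and reload adjusted lengths
#'
#' Adjusted lengths are highly stable across lanes and runs of the same
#' platform, so they can be computed once per reference and reused across
#' samples. The file is TSV with provenance comments; on reload the
#' transcript set is checked against the supplied reference.
#'
#' @param lengths Effective-length tibble from [effective_lengths()].
#' @param path File path.
#' @param reference Optional reference to validate against on read.
#' @return `path` invisibly (writer); the lengths tibble (reader).
#' @export
write_adjusted_lengths <- function(lengths, path) {
  con <- file(path, "w")
  writeLines(paste0("# haploquant adjusted lengths v",
                    as.character(packageVersion("haploquant"))), con)
  # %.17g guarantees doubles round-trip exactly through the text file
  out <- lengths
  for (cc in c("true_length", "effective_length", "adjusted_length")) {
    out[[cc]] <- sprintf("%.17g", out[[cc]])
  }
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_adjusted_lengths
#' @export
read_adjusted_lengths <- function(path, reference = NULL) {
  if (!file.exists(path)) abort(paste0("no such adjusted-lengths file: ", path))
  tab <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                              comment.char = "#",
                              colClasses = c("character", "numeric",
                                             "numeric", "numeric")))
  if (!is.null(reference)) {
    if (!all(tab$key %in% reference$key)) {
      abort("adjusted-lengths file does not match the reference (different transcript set)")
    }
    if (!all(reference$true_length[match(tab$key, reference$key)] ==
             tab$true_length)) {
      abort("adjusted-lengths file does not match the reference (lengths differ)")
    }
  }
  tab
}
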