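flat_names <- function() {
  ut <- character(0)
  for (i in 1:4) for (j in i:4) ut <- c(ut, paste(trait_names[i], trait_names[j], sep = "_"))
  ut
}

pair_names <- function() {
  out <- character(0)
  for (i in 1:3) for (j in (i + 1):4) out <- c(out, paste(trait_names[i], trait_names[j], sep = "_"))
  out
}

#' Per-sample derived genetic parameters
#'
#' Transforms stored covariance samples into the derived quantities of
#' interest: per-trait heritability `h2 = sigma2_a / (sigma2_a +
#' sigma2_pe + sigma2_e)`, genetic correlations `rg(i,j) = G0(i,j) /
#' sqrt(G0(i,i) G0(j,j))`, environmental correlations `re` (from the
#' pooled `P0 + R0` matrix by default, or from `R0` alone), and
#' phenotypic correlations `rp` from `G0 + P0 + R0`. Samples with a
#' nonpositive variance in any needed entry are excluded and counted in
#' attribute `"n_excluded"`.
#'
#' @param fit A `gibbs_fit` (or its `samples` tibble).
#' @param env_convention `"pooled"` (permanent environment + residual,
#'   default) or `"residual"` for the environmental correlation.
#' @return Long tibble with columns `cycle`, `parameter`, `value`;
#'   parameters are named `h2_<trait>`, `rg_<i>_<j>`, `re_<i>_<j>`,
#'   `rp_<i>_<j>` in trait order SCS, milk, fat, protein.
#' @export
derived_parameter_samples <- function(fit, env_convention = c("pooled", "residual")) {
  env_convention <- match.arg(env_convention)
  samples <- if (inherits(fit, "gibbs_fit")) fit$samples else tibble::as_tibble(fit)
  if (!nrow(samples)) stop("empty sample store")
  fn <- flat_names()
  G <- as.matrix(samples[paste0("g_", fn)])
  P <- as.matrix(samples[paste0("p_", fn)])
  R <- as.matrix(samples[paste0("r_", fn)])
  diag_idx <- match(paste(trait_names, trait_names, sep = "_"), fn)
  ok <- rowSums(G[, diag_idx, drop = FALSE] <= 0) +
    rowSums(P[, diag_idx, drop = FALSE] <= 0) +
    rowSums(R[, diag_idx, drop = FALSE] <= 0) == 0
  n_excl <- sum(!ok)
  if (n_excl) message(n_excl, " sample(s) with nonpositive variance excluded")
  G <- G[ok, , drop = FALSE]; P <- P[ok, , drop = FALSE]; R <- R[ok, , drop = FALSE]
  cyc <- samples$cycle[ok]
  E <- if (env_convention == "pooled") P + R else R
  Tot <- G + P + R
  out <- tibble::tibble(cycle = cyc)
  for (t in 1:4) {
    di <- diag_idx[t]
    out[[paste0("h2_", trait_names[t])]] <- G[, di] / Tot[, di]
  }
  corr_of <- function(M, i, j) {
    ij <- match(paste(trait_names[i], trait_names[j], sep = "_"), fn)
    M[, ij] / sqrt(M[, diag_idx[i]] * M[, diag_idx[j]])
  }
  for (i in 1:3) for (j in (i + 1):4) {
    nm <- paste(trait_names[i], trait_names[j], sep = "_")
    out[[paste0("rg_", nm)]] <- corr_of(G, i, j)
    out[[paste0("re_", nm)]] <- corr_of(E, i, j)
    out[[paste0("rp_", nm)]] <- corr_of(Tot, i, j)
  }
  out <- tidyr::pivot_longer(out, -"cycle", names_to = "parameter", values_to = "value")
  out <- dplyr::arrange(out, match(.data$parameter, unique(.data$parameter)), .data$cycle)
  attr(out, "n_excluded") <- n_excl
  out
}

#' Highest-posterior-density interval
#'
#' Shortest interval containing a fraction `prob` of the sorted
#' samples (exhaustive window scan).
#'
#' @param x Numeric samples.
#' @param prob Coverage probability.
#' @return `c(lo, hi)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - m)
  widths <- x[starts + m] - x[starts]
  s <- which.min(widths)
  c(x[s], x[s + m])
}

#' Monte Carlo standard error by batch means
#'
#' Splits the chain into `floor(sqrt(n))` consecutive batches and
#' reports `sd(batch means) / sqrt(n_batches)`.
#'
#' @param x Numeric samples in chain order.
#' @return MCSE of the mean.
#' @export
mcse_batch_means <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  nb <- floor(sqrt(n))
  bs <- n %/% nb
  means <- vapply(seq_len(nb), function(b) mean(x[((b - 1) * bs + 1):(b * bs)]), 0)
  if (nb < 2 || stats::sd(means) == 0) return(0)
  stats::sd(means) / sqrt(nb)
}

#' Summarize posterior samples of one parameter
#'
#' @param x Numeric samples in chain order (at least 2).
#' @return One-row tibble: `mean`, `sd`, equal-tail 2.5/97.5 %
#'   percentiles, 95 % HPD bounds, and batch-means MCSE.
#' @export
summarize_samples <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples to summarize")
  et <- unname(stats::quantile(x, c(0.025, 0.975), type = 7))
  hpd <- hpd_interval(x, 0.95)
  tibble::tibble(
    mean = mean(x), sd = stats::sd(x),
    et_lo = et[1], et_hi = et[2],
    hpd_lo = hpd[1], hpd_hi = hpd[2],
    mcse = mcse_batch_means(x)
  )
}

#' Posterior summary table for all (or selected) parameters
#'
#' Applies [summarize_samples()] per parameter of a long derived-sample
#' table (or of the raw covariance store), adding the flag
#' `excludes_zero` (the 95 % equal-tail interval does not contain 0,
#' the usual significance convention for correlations).
#'
#' @param samples Long tibble with `parameter` and `value` columns
#'   ([derived_parameter_samples()]), or a `gibbs_fit` whose covariance
#'   columns are summarized directly.
#' @param parameters Optional character vector restricting the output.
#' @return Tibble, one row per parameter.
#' @export
summarize_posterior <- function(samples, parameters = NULL) {
  if (inherits(samples, "gibbs_fit")) {
    samples <- tidyr::pivot_longer(samples$samples, -"cycle",
                                   names_to = "parameter", values_to = "value")
  }
  if (!is.null(parameters)) {
    bad <- setdiff(parameters, unique(samples$parameter))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           "; valid names: ", paste(unique(samples$parameter), collapse = ", "))
    }
    samples <- dplyr::filter(samples, .data$parameter %in% parameters)
  }
  out <- dplyr::group_modify(
    dplyr::group_by(samples, .data$parameter),
    ~ summarize_samples(.x$value)
  )
  out <- dplyr::ungroup(out)
  dplyr::mutate(out, excludes_zero = .data$et_lo > 0 | .data$et_hi < 0)
}

#' Export plot-ready traces and kernel densities
#'
#' @param samples Long derived-sample tibble
#'   ([derived_parameter_samples()]) or a `gibbs_fit`.
#' @param which Parameter names to export; default all.
#' @return List of tibbles: `trace` (`cycle`, `parameter`, `value`, one
#'   row per stored sample) and `density` (`parameter`, `x`, `density`;
#'   trapezoid integral 1 within 1e-3).
#' @export
export_traces <- function(samples, which = NULL) {
  if (inherits(samples, "gibbs_fit")) {
    samples <- tidyr::pivot_longer(samples$samples, -"cycle",
                                   names_to = "parameter", values_to = "value")
  }
  valid <- unique(samples$parameter)
  which <- which %||% valid
  bad <- setdiff(which, valid)
  if (length(bad)) {
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
         "; valid names: ", paste(valid, collapse = ", "))
  }
  tr <- dplyr::filter(samples, .data$parameter %in% which)
  dens <- dplyr::group_modify(
    dplyr::group_by(tr, .data$parameter),
    function(d, key) {
      if (stats::sd(d$value) == 0) {
        return(tibble::tibble(x = d$value[1], density = NA_real_))
      }
      k <- stats::density(d$value)
      tibble::tibble(x = k$x, density = k$y)
    }
  )
  list(trace = dplyr::ungroup(tr), density = dplyr::ungroup(dens))
}

#' Tidy a Gibbs fit into a posterior-summary table
#'
#' broom-style: one row per parameter (variance components and derived
#' heritabilities/correlations) with posterior mean, SD, intervals and
#' MCSE.
#'
#' @param x A `gibbs_fit`.
#' @param env_convention Passed to [derived_parameter_samples()].
#' @param ... Unused.
#' @export
tidy.gibbs_fit <- function(x, env_convention = "pooled", ...) {
  vc <- summarize_posterior(x)
  dv <- summarize_posterior(derived_parameter_samples(x, env_convention))
  dplyr::bind_rows(
    dplyr::mutate(vc, kind = "covariance", .before = 1),
    dplyr::mutate(dv, kind = "derived", .before = 1)
  )
}

#' Glance at a Gibbs fit
#'
#' @param x A `gibbs_fit`.
#' @param ... Unused.
#' @return One-row tibble of chain bookkeeping.
#' @export
glance.gibbs_fit <- function(x, ...) {
  tibble::tibble(
    chain_length = x$config$chain_length,
    burn_in = x$config$burn_in,
    thin = x$config$thin,
    n_stored = nrow(x$samples),
    n_records = x$n_records,
    n_animals = x$n_animals,
    n_cows = x$n_cows,
    seed = x$config$seed
  )
}

#' Geweke convergence diagnostic
#'
#' Z-score comparing the mean of the first `frac1` and last `frac2`
#' fractions of the chain, with variances estimated by batch means.
#' Offered as an aid to the usual visual trace inspection, not as a
#' convergence gate.
#'
#' @param x Numeric samples in chain order.
#' @param frac1,frac2 Leading/trailing fractions (0.1 / 0.5).
#' @return The z-score.
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2, floor(frac1 * n)))]
  b <- x[(n - max(2, floor(frac2 * n)) + 1):n]
  va <- mcse_batch_means(a)^2
  vb <- mcse_batch_means(b)^2
  (mean(a) - mean(b)) / sqrt(va + vb)
}

#' Trace/density plot of derived parameters
#'
#' @param object A `gibbs_fit`.
#' @param which Derived parameter names (default the four
#'   heritabilities).
#' @param env_convention Passed to [derived_parameter_samples()].
#' @param ... Unused.
#' @return A ggplot: trace (left) and marginal posterior density
#'   (right) per parameter.
#' @export
autoplot.gibbs_fit <- function(object, which = paste0("h2_", trait_names),
                               env_convention = "pooled", ...) {
  dv <- derived_parameter_samples(object, env_convention)
  ex <- export_traces(dv, which)
  tr <- dplyr::mutate(ex$trace, panel = "trace")
  p1 <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$cycle, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "cycle", y = NULL, title = "Trace")
  p2 <- ggplot2::ggplot(ex$density, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free", ncol = 1) +
    ggplot2::labs(x = NULL, y = "density", title = "Posterior density")
  patch <- tryCatch(getNamespace("patchwork"), error = function(e) NULL)
  if (!is.null(patch)) p1 + p2 else p1
}
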