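#' Gibbs sampler configuration
#'
#' @param chain_length Total number of Gibbs cycles.
#' @param burn_in Cycles discarded before storage begins; must be
#'   smaller than `chain_length`.
#' @param thin Storage interval in cycles; `(chain_length - burn_in) /
#'   thin` samples are retained (200,000 / 10,000 / 10 gives 19,000).
#' @param seed Integer seed; the whole chain is reproducible from it.
#' @param nu Prior degrees of freedom of the inverted-Wishart priors on
#'   each covariance matrix (default `traits + 2 = 6`, the smallest
#'   value giving the prior a finite mean).
#' @param scale Prior scale matrix shared by G0, P0 and R0 unless
#'   overridden via `scale_G`, `scale_P`, `scale_R`. The default
#'   (`NULL`) uses a third of the phenotypic covariance of the data,
#'   i.e. a weakly informative prior centred on an even split of the
#'   observed variance with minimal degrees of freedom. A small-scale
#'   inverted Wishart (e.g. `1e-4 * diag(4)`) is *not* vague here: its
#'   mode sits at essentially zero and it collapses covariance
#'   components the likelihood identifies only weakly.
#' @param scale_G,scale_P,scale_R Optional per-matrix prior scales.
#' @param checkpoint_every Cycles between checkpoints when a
#'   `checkpoint_path` is given to [run_chain()].
#' @return An object of class `gibbs_config`.
#' @export
gibbs_config <- function(chain_length = 200000L, burn_in = 10000L, thin = 10L,
                         seed = 1L, nu = 6, scale = NULL,
                         scale_G = NULL, scale_P = NULL, scale_R = NULL,
                         checkpoint_every = 10000L) {
  chain_length <- as.integer(chain_length)
  burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= chain_length) stop("burn_in must be smaller than chain_length")
  if (thin < 1L) stop("thin must be >= 1")
  structure(
    list(chain_length = chain_length, burn_in = burn_in, thin = thin,
         seed = as.integer(seed), nu = nu, scale = scale,
         scale_G = scale_G %||% scale, scale_P = scale_P %||% scale,
         scale_R = scale_R %||% scale,
         checkpoint_every = as.integer(checkpoint_every)),
    class = "gibbs_config"
  )
}

#' Retained-sample count of a chain configuration
#'
#' @param config A [gibbs_config()].
#' @return `floor((chain_length - burn_in) / thin)`.
#' @export
n_retained <- function(config) {
  (config$chain_length - config$burn_in) %/% config$thin
}

cov_col_names <- function() {
  # upper triangle stored row-wise in the core
  ut <- character(0)
  for (i in 1:4) for (j in i:4) ut <- c(ut, paste(trait_names[i], trait_names[j], sep = "_"))
  c(paste0("g_", ut), paste0("p_", ut), paste0("r_", ut))
}

# term construction shared by run_chain and the location-trace helper
frame_terms <- function(frame) {
  n <- frame$n_records
  ones <- rep(1, n)
  term_level <- list(frame$hym - 1L)
  term_cov <- list(ones)
  term_nlev <- frame$n_hym
  term_prior <- 0L
  for (q in seq_len(ncol(frame$Z_as))) {
    term_level <- c(term_level, list(frame$as_class - 1L))
    term_cov <- c(term_cov, list(frame$Z_as[, q]))
    term_nlev <- c(term_nlev, frame$n_as)
    term_prior <- c(term_prior, 0L)
  }
  for (q in seq_len(ncol(frame$Z_hy))) {
    term_level <- c(term_level, list(frame$hy_class - 1L))
    term_cov <- c(term_cov, list(frame$Z_hy[, q]))
    term_nlev <- c(term_nlev, frame$n_hy)
    term_prior <- c(term_prior, 0L)
  }
  term_level <- c(term_level, list(frame$animal - 1L), list(frame$cow - 1L))
  term_cov <- c(term_cov, list(ones), list(ones))
  term_nlev <- c(term_nlev, frame$n_animals, frame$n_cows)
  term_prior <- c(term_prior, 1L, 2L)
  list(level = term_level, cov = term_cov, nlev = as.integer(term_nlev),
       prior = as.integer(term_prior))
}

# project a symmetric matrix to positive definiteness by eigenvalue flooring
pd_floor <- function(S, eps_frac = 1e-3) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  floor_at <- max(e$values) * eps_frac
  e$vectors %*% (pmax(e$values, floor_at) * t(e$vectors))
}

init_state <- function(frame, terms, init_cov = NULL) {
  if (is.null(init_cov)) {
    init_cov <- moment_start_values(frame)
  }
  effects <- lapply(terms$nlev, function(nl) matrix(0, nl, 4))
  # start the effect fields consistently with the covariance start
  # values instead of at zero: the additive field otherwise rebuilds its
  # family structure over thousands of cycles, depressing the early
  # genetic-covariance draws
  mu <- colMeans(frame$y)
  effects[[1]][] <- matrix(mu, terms$nlev[1], 4, byrow = TRUE)  # HYM at means
  k <- tabulate(frame$cow)
  cm <- rowsum(frame$y, frame$cow) / k
  dev <- sweep(cm, 2, mu)
  w <- diag(init_cov$G0) / pmax(diag(init_cov$G0) + diag(init_cov$P0), 1e-12)
  n_terms <- length(effects)
  anim_term <- n_terms - 1L
  pe_term <- n_terms
  first <- !duplicated(frame$cow)
  cow_lev <- frame$cow[first]
  anim_lev <- frame$animal[first]
  a_cow <- dev * rep(w, each = nrow(dev))
  effects[[anim_term]][anim_lev, ] <- a_cow[cow_lev, , drop = FALSE]
  effects[[pe_term]][cow_lev, ] <- dev[cow_lev, , drop = FALSE] -
    a_cow[cow_lev, , drop = FALSE]
  # parents with recorded offspring start at the mean of their offspring
  id_map <- frame$relationship$id_map
  for (par in list(frame$cow_sire, frame$cow_dam)) {
    if (is.null(par)) next
    code <- id_map$code[match(par, id_map$id)]
    ok <- !is.na(code)
    if (!any(ok)) next
    pm <- rowsum(a_cow[cow_lev, , drop = FALSE][ok, , drop = FALSE], code[ok])
    cnt <- tabulate(code[ok], nbins = terms$nlev[anim_term])
    lev <- as.integer(rownames(pm))
    effects[[anim_term]][lev, ] <- pm / cnt[lev]
  }
  list(effects = effects, G0 = init_cov$G0, P0 = init_cov$P0, R0 = init_cov$R0)
}

#' Method-of-moments starting values for the covariance matrices
#'
#' Residual: pooled within-cow covariance. Additive genetic: four times
#' the corrected between-sire-family covariance of cow means (one-way
#' ANOVA on the paternal half-sib structure), falling back to an even
#' split of the between-cow covariance when the pedigree offers no
#' usable sire families. Permanent environment: the remaining
#' between-cow covariance. All three are floored to positive
#' definiteness. Starting a chain near the posterior's support
#' substantially shortens the burn-in transient; the stationary
#' distribution is unaffected.
#'
#' @param frame A [build_model_frame()] result.
#' @return List of matrices `G0`, `P0`, `R0`.
#' @export
moment_start_values <- function(frame) {
  cow <- frame$cow
  k <- tabulate(cow)
  cm <- rowsum(frame$y, cow) / k
  S <- stats::cov(frame$y)
  if (frame$n_cows < 3 || frame$n_records - frame$n_cows < 3) {
    return(list(G0 = S / 3, P0 = S / 3, R0 = S / 3))
  }
  within <- stats::cov(frame$y - cm[cow, , drop = FALSE]) *
    (frame$n_records - 1) / max(frame$n_records - frame$n_cows, 1)
  between_cow <- pd_floor(stats::cov(cm) - within / mean(k))
  G0 <- NULL
  sire <- frame$cow_sire
  if (!is.null(sire) && !all(is.na(sire))) {
    ok <- !is.na(sire)
    fam <- sire[ok]
    sizes <- table(fam)
    multi <- names(sizes)[sizes >= 2]
    if (length(multi) >= 20) {
      keep <- fam %in% multi
      cmk <- cm[ok, , drop = FALSE][keep, , drop = FALSE]
      famk <- fam[keep]
      nf <- table(famk)[unique(famk)]
      fmean <- rowsum(cmk, famk)[unique(famk), , drop = FALSE] / as.numeric(nf)
      W <- stats::cov(cmk - fmean[match(famk, unique(famk)), , drop = FALSE]) *
        (nrow(cmk) - 1) / max(nrow(cmk) - length(nf), 1)
      mh <- 1 / mean(1 / as.numeric(nf))    # harmonic mean family size
      B <- stats::cov(fmean)
      G0 <- pd_floor(4 * (B - W / mh))
      # cap at the total cow-level covariance
      sc <- sum(diag(G0)) / sum(diag(between_cow))
      if (sc > 0.95) G0 <- G0 * (0.95 / sc)
    }
  }
  if (is.null(G0)) G0 <- between_cow / 2
  P0 <- pd_floor(between_cow - G0)
  list(G0 = G0, P0 = P0, R0 = pd_floor(within))
}

#' Run the Gibbs chain
#'
#' One cycle consists of: a sweep of single-level blocked updates of the
#' fixed terms (order: HYM, the six age-season regression coefficients,
#' the five herd-year coefficients), a single joint draw of the entire
#' additive-genetic field (all animals, all traits, with the permanent-
#' environment effects integrated out of that conditional) via a sparse
#' Cholesky factorization of its full-conditional precision, a draw of
#' the permanent-environment effects given the additive field, and
#' inverted-Wishart draws of G0, P0 and R0. Covariance samples are
#' stored every `thin` cycles after `burn_in`. The chain is
#' bit-reproducible from `config$seed` and, when `checkpoint_path` is
#' given, resumable from the last checkpoint with an identical
#' continuation.
#'
#' Blocking the additive field into one draw matters: level-wise draws
#' of animal effects mix the genetic-versus-permanent-environment
#' partition of the cow-level variance extremely slowly, because each
#' cow's two effects enter its records only through their sum. With
#' `animal_block = FALSE` the sampler instead updates animals level by
#' level (each recorded cow's additive and permanent-environment
#' vectors as one joint 8-dimensional block); the stationary
#' distribution is identical, only the autocorrelation differs.
#'
#' @param frame A [build_model_frame()] result.
#' @param config A [gibbs_config()].
#' @param update_cov Set `FALSE` to hold G0/P0/R0 fixed at their
#'   initial values (used for conjugate-oracle checks).
#' @param update_location Set `FALSE` to hold all location effects fixed
#'   at their initial values and draw only the covariance matrices.
#' @param init_effects Optional list of effect matrices (one per term in
#'   sampling order, `levels x 4`) used as starting values.
#' @param init_cov Optional list `G0`, `P0`, `R0` of starting values;
#'   default [moment_start_values()].
#' @param checkpoint_path Optional RDS path; progress is saved every
#'   `config$checkpoint_every` cycles and a partial run restarted from
#'   it continues the identical chain.
#' @param trace_location Optional `c(term, level)` (1-based; terms in
#'   the sampling order above) whose 4-trait draws are stored alongside
#'   the covariance samples.
#' @param animal_block Draw the whole additive field jointly (default;
#'   see above).
#' @return An object of class `gibbs_fit`: `samples` (tibble, one row
#'   per stored sample: `cycle` plus 30 covariance columns, upper
#'   triangles of G0/P0/R0), `config`, level counts, and the final
#'   state.
#' @export
run_chain <- function(frame, config = gibbs_config(), update_cov = TRUE,
                      update_location = TRUE, init_cov = NULL,
                      init_effects = NULL, checkpoint_path = NULL,
                      trace_location = NULL, animal_block = TRUE) {
  terms <- frame_terms(frame)
  default_scale <- stats::cov(frame$y) / 3
  priors <- list(nu_G = config$nu, nu_P = config$nu, nu_R = config$nu,
                 S_G = config$scale_G %||% default_scale,
                 S_P = config$scale_P %||% default_scale,
                 S_R = config$scale_R %||% default_scale)
  Ainv <- methods::as(frame$relationship$A_inverse, "generalMatrix")
  Ainv <- methods::as(Ainv, "CsparseMatrix")

  cycle <- 0L
  samples <- NULL
  traces <- NULL
  if (!is.null(checkpoint_path) && file.exists(checkpoint_path)) {
    ck <- readRDS(checkpoint_path)
    cycle <- ck$cycle
    samples <- ck$samples
    traces <- ck$traces
    state <- ck$state
    assign(".Random.seed", ck$rng_state, envir = globalenv())
  } else {
    set.seed(config$seed)
    state <- init_state(frame, terms, init_cov)
    if (!is.null(init_effects)) state$effects <- init_effects
  }
  tt <- if (is.null(trace_location)) c(-1L, -1L) else as.integer(trace_location)

  if (animal_block) {
    out <- run_blocked(frame, terms, priors, Ainv, state, config,
                       update_cov, update_location, tt, cycle, samples,
                       traces, checkpoint_path)
    samples <- out$samples
    traces <- out$traces
    state <- out$state
  } else {
    first <- !duplicated(frame$cow)
    pe_animal <- integer(frame$n_cows)
    pe_animal[frame$cow[first]] <- frame$animal[first] - 1L
    while (cycle < config$chain_length) {
      seg <- min(config$checkpoint_every, config$chain_length - cycle)
      out <- .gibbs_segment(frame$y, terms$level, terms$cov, terms$nlev,
                            terms$prior, Ainv, state, priors,
                            cycle, seg, config$burn_in, config$thin,
                            update_cov, if (update_location) 1L else 0L,
                            tt[1], tt[2], pe_animal)
      samples <- rbind(samples, out$samples)
      traces <- rbind(traces, out$trace)
      state <- out$state
      cycle <- out$cycle_end
      if (!is.null(checkpoint_path)) {
        saveRDS(list(cycle = cycle, samples = samples, traces = traces,
                     state = state,
                     rng_state = get(".Random.seed", envir = globalenv())),
                checkpoint_path)
      }
    }
  }
  colnames(samples) <- c("cycle", cov_col_names())
  fit <- structure(
    list(samples = tibble::as_tibble(as.data.frame(samples)),
         config = config,
         n_records = frame$n_records, n_animals = frame$n_animals,
         n_cows = frame$n_cows,
         state = state),
    class = "gibbs_fit"
  )
  if (!is.null(trace_location)) {
    colnames(traces) <- trait_names
    fit$location_trace <- tibble::as_tibble(as.data.frame(traces))
  }
  fit
}

# inverted-Wishart draw through stats::rWishart (R RNG)
riw <- function(df, Scale) {
  W <- stats::rWishart(1, df, chol2inv(chol(Scale)))[, , 1]
  sym <- chol2inv(chol(W))
  (sym + t(sym)) / 2
}

# the blocked sampling loop: fixed terms in compiled code, the additive
# field in one sparse-Cholesky multivariate draw, PE given the field,
# then the covariance matrices
run_blocked <- function(frame, terms, priors, Ainv, state, config,
                        update_cov, update_location, tt, cycle, samples,
                        traces, checkpoint_path) {
  nA <- frame$n_animals
  nC <- frame$n_cows
  n <- frame$n_records
  if (update_cov) {
    if (nA + priors$nu_G <= 3 || nC + priors$nu_P <= 3 || n + priors$nu_R <= 3) {
      stop("Wishart degrees of freedom <= dimension - 1")
    }
  }
  K <- length(state$effects)
  A_t <- K - 1L
  P_t <- K
  first <- !duplicated(frame$cow)
  anim_of_cow <- integer(nC)
  anim_of_cow[frame$cow[first]] <- frame$animal[first]
  k_cow <- tabulate(frame$cow, nbins = nC)
  # sparsity pattern of the data blocks added to kron(Ainv, G0inv)
  blk <- as.matrix(expand.grid(1:4, 1:4))
  di <- rep((anim_of_cow - 1L) * 4L, each = 16L) + blk[, 1]
  dj <- rep((anim_of_cow - 1L) * 4L, each = 16L) + blk[, 2]
  k_lev <- sort(unique(k_cow))
  ch <- NULL

  n_keep <- sum(seq_len(config$chain_length) > config$burn_in &
                (seq_len(config$chain_length) - config$burn_in) %% config$thin == 0)
  samp_new <- matrix(0, n_keep, 31)
  trace_new <- if (tt[1] > 0) matrix(0, n_keep, 4) else NULL
  stored <- 0L

  while (cycle < config$chain_length) {
    cycle <- cycle + 1L
    if (update_location) {
      out <- .gibbs_segment(frame$y, terms$level, terms$cov, terms$nlev,
                            terms$prior, Ainv, state, priors,
                            cycle - 1L, 1L, config$chain_length + 1L, 1L,
                            FALSE, 2L, -1L, -1L, integer(0))
      state <- out$state
      E <- out$residuals
      al <- state$effects[[A_t]]
      ro <- state$effects[[P_t]]
      G0inv <- chol2inv(chol(state$G0))
      P0 <- state$P0
      R0 <- state$R0
      R0inv <- chol2inv(chol(R0))
      # residuals excluding the additive and PE effects; per-cow means
      Eex <- E + al[frame$animal, , drop = FALSE] + ro[frame$cow, , drop = FALSE]
      cmean <- rowsum(Eex, frame$cow) / k_cow
      # collapsed data precision per cow: (P0 + R0/k)^-1
      Dx <- matrix(0, nC, 16)
      b <- numeric(4L * nA)
      for (kk in k_lev) {
        idx <- which(k_cow == kk)
        Dk <- chol2inv(chol(P0 + R0 / kk))
        Dx[idx, ] <- matrix(Dk, length(idx), 16, byrow = TRUE)
        bc <- cmean[idx, , drop = FALSE] %*% Dk
        rows <- (anim_of_cow[idx] - 1L) * 4L
        for (t in 1:4) b[rows + t] <- bc[, t]
      }
      H <- methods::as(kronecker(Ainv, G0inv), "CsparseMatrix") +
        Matrix::sparseMatrix(i = di, j = dj, x = as.vector(t(Dx)),
                             dims = c(4L * nA, 4L * nA))
      H <- Matrix::forceSymmetric(H)
      if (is.null(ch)) {
        ch <- Matrix::Cholesky(H, LDL = FALSE, perm = TRUE)
      } else {
        ch <- Matrix::update(ch, H)
      }
      mu <- Matrix::solve(ch, b, system = "A")
      z <- stats::rnorm(4L * nA)
      w <- Matrix::solve(ch, z, system = "Lt")
      w <- Matrix::solve(ch, w, system = "Pt")
      u <- as.numeric(mu) + as.numeric(w)
      al <- matrix(u, nA, 4, byrow = TRUE)
      state$effects[[A_t]] <- al
      # PE given the additive field, vectorized per records-per-cow group
      mstar <- cmean - al[anim_of_cow, , drop = FALSE]
      ro <- matrix(0, nC, 4)
      for (kk in k_lev) {
        idx <- which(k_cow == kk)
        prec <- kk * R0inv + chol2inv(chol(P0))
        Sig <- chol2inv(chol(prec))
        mean_k <- mstar[idx, , drop = FALSE] %*% t(Sig %*% (kk * R0inv))
        zk <- matrix(stats::rnorm(4L * length(idx)), length(idx), 4)
        ro[idx, ] <- mean_k + zk %*% chol(Sig)
      }
      state$effects[[P_t]] <- ro
      Eres <- Eex - al[frame$animal, , drop = FALSE] - ro[frame$cow, , drop = FALSE]
    } else {
      al <- state$effects[[A_t]]
      ro <- state$effects[[P_t]]
      out <- .gibbs_segment(frame$y, terms$level, terms$cov, terms$nlev,
                            terms$prior, Ainv, state, priors,
                            cycle - 1L, 1L, config$chain_length + 1L, 1L,
                            FALSE, 0L, -1L, -1L, integer(0))
      Eres <- out$residuals
    }
    if (update_cov) {
      Sa <- as.matrix(Matrix::crossprod(al, Ainv %*% al))
      state$G0 <- riw(nA + priors$nu_G, (Sa + t(Sa)) / 2 + priors$S_G)
      state$P0 <- riw(nC + priors$nu_P, crossprod(ro) + priors$S_P)
      state$R0 <- riw(n + priors$nu_R, crossprod(Eres) + priors$S_R)
    }
    if (cycle > config$burn_in &&
        (cycle - config$burn_in) %% config$thin == 0) {
      stored <- stored + 1L
      row <- c(cycle, flatten_cov(state$G0), flatten_cov(state$P0),
               flatten_cov(state$R0))
      samp_new[stored, ] <- row
      if (!is.null(trace_new)) {
        trace_new[stored, ] <- state$effects[[tt[1]]][tt[2], ]
      }
    }
    if (!is.null(checkpoint_path) && (cycle %% config$checkpoint_every == 0 ||
                                      cycle == config$chain_length)) {
      saveRDS(list(cycle = cycle,
                   samples = rbind(samples, samp_new[seq_len(stored), , drop = FALSE]),
                   traces = rbind(traces,
                                  if (!is.null(trace_new)) trace_new[seq_len(stored), , drop = FALSE]),
                   state = state,
                   rng_state = get(".Random.seed", envir = globalenv())),
              checkpoint_path)
    }
  }
  list(samples = rbind(samples, samp_new[seq_len(stored), , drop = FALSE]),
       traces = rbind(traces,
                      if (!is.null(trace_new)) trace_new[seq_len(stored), , drop = FALSE]),
       state = state)
}

flatten_cov <- function(M) {
  v <- numeric(10)
  c <- 1
  for (i in 1:4) for (j in i:4) {
    v[c] <- M[i, j]
    c <- c + 1
  }
  v
}

#' Fit the multi-trait test-day animal model by Gibbs sampling
#'
#' One-call wrapper: builds the model frame from edited, class-assigned
#' records and a pedigree, then runs the chain.
#'
#' @inheritParams build_model_frame
#' @param config A [gibbs_config()].
#' @param ... Passed to [run_chain()].
#' @return A `gibbs_fit` (see [run_chain()]).
#' @export
fit_gibbs <- function(records, ped, config = gibbs_config(),
                      as_order = 6L, hy_order = 5L, ...) {
  frame <- build_model_frame(records, ped, as_order = as_order, hy_order = hy_order)
  run_chain(frame, config, ...)
}

#' @method print gibbs_fit
#' @export
print.gibbs_fit <- function(x, ...) {
  cat("<gibbs_fit> ", nrow(x$samples), " stored samples (chain ",
      x$config$chain_length, ", burn-in ", x$config$burn_in, ", thin ",
      x$config$thin, "); ", x$n_records, " records, ", x$n_animals,
      " animals\n", sep = "")
  invisible(x)
}

#' Extract covariance matrices from one stored sample
#'
#' @param fit A `gibbs_fit`.
#' @param i Row index into `fit$samples`.
#' @return List of symmetric 4x4 matrices `G0`, `P0`, `R0`.
#' @export
sample_covariances <- function(fit, i) {
  row <- as.numeric(fit$samples[i, -1])
  unflatten <- function(v) {
    M <- matrix(0, 4, 4, dimnames = list(trait_names, trait_names))
    c <- 1
    for (a in 1:4) for (b in a:4) {
      M[a, b] <- M[b, a] <- v[c]
      c <- c + 1
    }
    M
  }
  list(G0 = unflatten(row[1:10]), P0 = unflatten(row[11:20]),
       R0 = unflatten(row[21:30]))
}

#' Write the sample store as delimited text
#'
#' One row per stored sample: cycle index plus the 30 covariance
#' columns (upper triangles of G0, P0, R0 in trait order SCS, milk,
#' fat, protein).
#'
#' @param fit A `gibbs_fit`.
#' @param path Output path (CSV).
#' @return `fit`, invisibly.
#' @export
write_samples <- function(fit, path) {
  readr::write_csv(fit$samples, path)
  invisible(fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
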