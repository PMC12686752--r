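#' Gibbs chain configuration
#'
#' @param cycles total Gibbs cycles.
#' @param burn_in cycles discarded before retention (must be < `cycles`).
#' @param thinning keep every `thinning`-th post-burn-in cycle.
#' @param seed RNG seed making the chain reproducible.
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(cycles, burn_in, thinning = 10, seed = 1) {
  cycles <- as.integer(cycles); burn_in <- as.integer(burn_in)
  thinning <- as.integer(thinning)
  if (burn_in >= cycles) stop("burn_in must be smaller than cycles")
  if (thinning < 1L) stop("thinning must be >= 1")
  structure(list(cycles = cycles, burn_in = burn_in, thinning = thinning,
                 seed = as.integer(seed)), class = "chain_config")
}

#' Gibbs sampler for variance components of the multivariate animal model
#'
#' Samples the joint posterior of location effects and (co)variance
#' components. Location effects (fixed effects and breeding values, all
#' traits jointly) are drawn in one block from their multivariate-normal
#' full conditional via a sparse Cholesky factorization of the mixed-model
#' coefficient matrix; the genetic covariance matrix is drawn from its
#' inverse-Wishart full conditional with scale `U' K^-1 U`; each residual
#' variance from its scaled inverse-chi-square full conditional. Default
#' priors are flat on the (co)variance scale (inverse-Wishart degrees of
#' freedom `-(T + 1)` with a negligible scale floor for the genetic
#' covariance; `nu = -2` equivalent scaled inverse-chi-square for
#' residuals), matching common variance-component Gibbs defaults;
#' informative inverse-Wishart priors can be supplied via `priors`.
#'
#' @param blocks an `mme_blocks` from [build_incidence()].
#' @param K_inverse sparse inverse relationship matrix.
#' @param chain a [chain_config()].
#' @param start optional starting [variance_components()]; default uses
#'   half the phenotypic variance for both components.
#' @param priors optional list with `nu_G` and `S_G` overriding the genetic
#'   prior.
#' @return An object of class `gibbs_samples`: matrix of retained samples
#'   (columns `G_i_j` and `R_t`) plus metadata.
#' @export
run_gibbs <- function(blocks, K_inverse, chain, start = NULL, priors = NULL) {
  stopifnot(inherits(blocks, "mme_blocks"), inherits(chain, "chain_config"))
  set.seed(chain$seed)
  Tn <- length(blocks$blocks)
  na <- length(blocks$animal_ids)
  Xs <- lapply(blocks$blocks, `[[`, "X")
  Zs <- lapply(blocks$blocks, `[[`, "Z")
  ys <- lapply(blocks$blocks, `[[`, "y")
  nrec <- vapply(ys, length, integer(1))
  vy <- vapply(ys, stats::var, numeric(1))
  if (is.null(start)) {
    # mildly coupled start so the first coefficient matrix already has the
    # full cross-trait pattern
    G0s <- 0.95 * diag(vy / 2, Tn) + 0.05 * sqrt(outer(vy / 2, vy / 2))
    start <- variance_components(G0s, vy / 2)
  }
  nu_G <- if (!is.null(priors$nu_G)) priors$nu_G else -(Tn + 1)
  S_G <- if (!is.null(priors$S_G)) priors$S_G else diag(1e-8 * vy, Tn)

  # precompute unit-residual cross products; per-cycle LHS is a rescale
  XtX <- lapply(Xs, Matrix::crossprod)
  XtZ <- lapply(seq_len(Tn), function(t) Matrix::crossprod(Xs[[t]], Zs[[t]]))
  ZtZ <- lapply(Zs, Matrix::crossprod)
  Xty <- lapply(seq_len(Tn), function(t) as.vector(Matrix::crossprod(Xs[[t]], ys[[t]])))
  Zty <- lapply(seq_len(Tn), function(t) as.vector(Matrix::crossprod(Zs[[t]], ys[[t]])))
  n_fixed <- vapply(Xs, ncol, integer(1))
  nf <- sum(n_fixed)
  Ksp <- methods::as(K_inverse, "generalMatrix")

  build_lhs <- function(G0, R0) {
    A11 <- Matrix::bdiag(lapply(seq_len(Tn), function(t) XtX[[t]] / R0[t]))
    A12 <- Matrix::bdiag(lapply(seq_len(Tn), function(t) XtZ[[t]] / R0[t]))
    A22 <- Matrix::bdiag(lapply(seq_len(Tn), function(t) ZtZ[[t]] / R0[t]))
    G0inv <- chol2inv(chol(G0))
    Kron <- Matrix::kronecker(Matrix::Matrix(G0inv, sparse = TRUE), Ksp)
    Matrix::forceSymmetric(rbind(cbind(A11, A12), cbind(Matrix::t(A12), A22 + Kron)))
  }
  build_rhs <- function(R0) {
    c(unlist(lapply(seq_len(Tn), function(t) Xty[[t]] / R0[t])),
      unlist(lapply(seq_len(Tn), function(t) Zty[[t]] / R0[t])))
  }

  G0 <- start$G0; R0 <- start$R0
  # symbolic analysis on the fully coupled pattern: a diagonal start G0
  # would fix a block-diagonal sparsity pattern and make every later
  # numeric update (with cross-trait coupling) pay for the mismatch
  G0_pattern <- diag(diag(G0), Tn) + 0.05 * sqrt(outer(diag(G0), diag(G0)))
  ch <- Matrix::Cholesky(build_lhs(G0_pattern, R0), LDL = FALSE, perm = TRUE)
  LHS <- build_lhs(G0, R0)
  neq <- nrow(LHS)

  keep <- integer(0)
  labs <- c(outer(seq_len(Tn), seq_len(Tn), function(i, j) paste0("G_", i, "_", j)))
  labs <- labs[as.vector(lower.tri(diag(Tn), diag = TRUE))]
  cols <- c(labs, paste0("R_", seq_len(Tn)))
  n_keep <- length(seq.int(chain$burn_in + chain$thinning, chain$cycles, by = chain$thinning))
  samples <- matrix(NA_real_, n_keep, length(cols), dimnames = list(NULL, cols))
  k_row <- 0L

  for (cyc in seq_len(chain$cycles)) {
    LHS <- build_lhs(G0, R0)
    ch <- Matrix::update(ch, LHS)
    rhs <- build_rhs(R0)
    mu <- as.vector(Matrix::solve(ch, rhs, system = "A"))
    z <- stats::rnorm(neq)
    dev <- as.vector(Matrix::solve(ch, Matrix::solve(ch, z, system = "Lt"), system = "Pt"))
    sol <- mu + dev
    U <- matrix(sol[nf + seq_len(na * Tn)], nrow = na, ncol = Tn)

    S <- as.matrix(Matrix::crossprod(U, Ksp %*% U))
    Sc <- S_G + (S + t(S)) / 2
    G0 <- sample_invwishart(nu_G + na, Sc)
    tries <- 0L
    while (inherits(tryCatch(chol(G0), error = function(e) e), "error")) {
      tries <- tries + 1L
      G0 <- sample_invwishart(nu_G + na, Sc + diag(1e-8 * mean(diag(Sc)), Tn))
      if (tries > 10L) stop("could not draw a positive-definite genetic covariance")
    }

    for (t in seq_len(Tn)) {
      b <- sol[sum(n_fixed[seq_len(t - 1L)]) + seq_len(n_fixed[t])]
      e <- ys[[t]] - as.vector(Xs[[t]] %*% b) - as.vector(Zs[[t]] %*% U[, t])
      df <- max(nrec[t] - 2, 1)
      R0[t] <- sum(e * e) / stats::rchisq(1, df)
    }

    if (cyc > chain$burn_in && (cyc - chain$burn_in) %% chain$thinning == 0L) {
      k_row <- k_row + 1L
      samples[k_row, ] <- c(G0[lower.tri(G0, diag = TRUE)], R0)
    }
  }
  structure(list(samples = samples[seq_len(k_row), , drop = FALSE],
                 traits = blocks$traits, n_traits = Tn, chain = chain),
            class = "gibbs_samples")
}

# draw from an inverse-Wishart with the given degrees of freedom and scale
sample_invwishart <- function(df, S) {
  W <- stats::rWishart(1, df, chol2inv(chol(S)))[, , 1]
  Si <- chol2inv(chol((W + t(W)) / 2))
  (Si + t(Si)) / 2
}

#' Restrict phenotypes to genotyped animals for VCE
#'
#' The correlated-trait multi-breed scenarios estimate variance components
#' on phenotyped-and-genotyped animals only, so that phenotypes with no
#' genomic link between breeds do not enter; all other scenarios use the
#' phenotype table unchanged.
#'
#' @param pheno phenotype table.
#' @param genotyped_ids ids of genotyped animals.
#' @param scenario scenario name.
#' @return The (possibly subset) phenotype table.
#' @export
subset_for_vce <- function(pheno, genotyped_ids, scenario) {
  if (!scenario %in% c("MTMB_ssGBLUP", "MTMB_W_ssGBLUP")) return(pheno)
  out <- pheno[pheno$animal %in% genotyped_ids, , drop = FALSE]
  if (nrow(out) == 0L) stop("no phenotyped animal is genotyped; cannot subset for VCE")
  out
}

#' Posterior summaries of a Gibbs run
#'
#' Heritabilities are computed per retained sample as
#' `G_tt / (G_tt + R_t)` and then averaged; genetic correlations likewise
#' per sample. Posterior standard deviations over the retained samples are
#' reported as standard errors. Split-chain potential-scale-reduction and a
#' crude effective sample size are computed per parameter, with warnings
#' above 1.1 and below 100 respectively.
#'
#' @param store a `gibbs_samples` from [run_gibbs()].
#' @return An object of class `posterior_summary` with data frames
#'   `components`, `h2` and `correlations`, and the retained-sample count.
#' @export
summarize_posterior <- function(store) {
  S <- store$samples
  n <- nrow(S)
  if (n < 50L) stop("fewer than 50 retained samples (", n, "); lengthen the chain")
  Tn <- store$n_traits
  g_idx <- function(i, j) {
    lt <- which(lower.tri(diag(Tn), diag = TRUE), arr.ind = TRUE)
    which(lt[, 1] == max(i, j) & lt[, 2] == min(i, j))
  }
  comp <- data.frame(parameter = colnames(S), mean = colMeans(S),
                     se = apply(S, 2, stats::sd), row.names = NULL)
  h2 <- do.call(rbind, lapply(seq_len(Tn), function(t) {
    hh <- S[, g_idx(t, t)] / (S[, g_idx(t, t)] + S[, Tn * (Tn + 1) / 2 + t])
    data.frame(trait = store$traits[t], h2 = mean(hh), se = stats::sd(hh))
  }))
  pairs <- which(lower.tri(diag(Tn)), arr.ind = TRUE)
  correlations <- if (nrow(pairs)) do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    rr <- S[, g_idx(i, j)] / sqrt(S[, g_idx(i, i)] * S[, g_idx(j, j)])
    data.frame(trait_1 = store$traits[j], trait_2 = store$traits[i],
               r_g = mean(rr), se = stats::sd(rr))
  })) else data.frame(trait_1 = character(), trait_2 = character(),
                      r_g = numeric(), se = numeric())
  diag_tab <- data.frame(parameter = colnames(S),
                         rhat = apply(S, 2, split_rhat),
                         ess = apply(S, 2, ess_acf), row.names = NULL)
  if (any(diag_tab$rhat > 1.1, na.rm = TRUE)) {
    warning("split-chain Rhat above 1.1 for: ",
            paste(diag_tab$parameter[diag_tab$rhat > 1.1], collapse = ", "))
  }
  if (any(diag_tab$ess < 100, na.rm = TRUE)) {
    warning("effective sample size below 100 for: ",
            paste(diag_tab$parameter[diag_tab$ess < 100], collapse = ", "))
  }
  structure(list(components = comp, h2 = h2, correlations = correlations,
                 diagnostics = diag_tab, retained = n), class = "posterior_summary")
}

# split-in-half potential scale reduction factor
split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  if (n < 2) return(NA_real_)
  halves <- list(x[seq_len(n)], x[n + seq_len(n)])
  m <- vapply(halves, mean, numeric(1))
  v <- vapply(halves, stats::var, numeric(1))
  W <- mean(v)
  B <- n * stats::var(m)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# initial-positive-sequence effective sample size
ess_acf <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] < 0) break
    s <- s + ac[k]
  }
  n / (1 + 2 * s)
}

#' Write Gibbs samples to CSV (cycle, parameter, value)
#' @param store a `gibbs_samples`.
#' @param path output CSV path.
#' @export
write_samples <- function(store, path) {
  S <- store$samples
  long <- data.frame(
    cycle = rep(seq_len(nrow(S)), times = ncol(S)),
    parameter = rep(colnames(S), each = nrow(S)),
    value = as.vector(S))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
}
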