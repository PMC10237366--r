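# Grade-of-membership decomposition of the site x species presence matrix:
# each site is a mixture over K "motifs" (probability vectors over species),
# fitted by EM on the multinomial likelihood with random restarts.

PROB_FLOOR <- 1e-12

check_simplex <- function(m, what, tol = 1e-6) {
  if (any(m < -tol)) stop(what, ": negative entries")
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol)) stop(what, ": rows do not sum to 1")
  invisible(TRUE)
}

#' Grade-of-membership log-likelihood
#'
#' `l = sum_n sum_s x_ns log(sum_k omega_nk theta_ks)`. Cells where the
#' mixture probability is exactly zero but `x_ns > 0` contribute `-Inf`
#' (flagged via attribute `degenerate`).
#'
#' @param omega sites x K membership matrix, rows on the simplex
#' @param theta K x species motif matrix, rows on the simplex
#' @param X sites x species binary (or count) matrix
#' @return log-likelihood (attribute `degenerate` = TRUE when `-Inf`)
#' @export
gom_loglik <- function(omega, theta, X) {
  stopifnot(nrow(omega) == nrow(X), ncol(omega) == nrow(theta),
            ncol(theta) == ncol(X))
  check_simplex(omega, "omega")
  check_simplex(theta, "theta")
  P <- omega %*% theta
  pos <- X > 0
  if (any(P[pos] == 0)) {
    ll <- -Inf
    attr(ll, "degenerate") <- TRUE
    return(ll)
  }
  sum(X[pos] * log(P[pos]))
}

# one EM run from a given initialization; returns omega, theta, trace
gom_em_run <- function(X, omega, theta, tol, max_iter) {
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    P <- omega %*% theta
    P[P < PROB_FLOOR] <- PROB_FLOOR
    ll <- sum(X[X > 0] * log(P[X > 0]))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    R <- X / P                                   # n x s
    omega_new <- omega * (R %*% t(theta))        # E+M for omega
    omega <- omega_new / pmax(rowSums(omega_new), PROB_FLOOR)
    theta_new <- theta * (t(omega) %*% R) /
      pmax(colSums(omega), PROB_FLOOR)           # rescale before renormalizing
    theta <- theta_new / pmax(rowSums(theta_new), PROB_FLOOR)
  }
  list(omega = omega, theta = theta, trace = trace)
}

rdirichlet_rows <- function(n, k) {
  g <- matrix(stats::rgamma(n * k, shape = 1), n, k)
  g / rowSums(g)
}

#' Fit a grade-of-membership model by EM
#'
#' Maximizes the multinomial grade-of-membership likelihood over site
#' memberships `omega` and motif compositions `theta` with `n_starts` random
#' Dirichlet(1) initializations, keeping the best final likelihood. Presences
#' are treated as unit counts. Empty sites (no present species) are dropped
#' with a message. `K = 1` uses the closed-form MLE.
#'
#' @param X sites x species binary matrix
#' @param K number of motifs
#' @param tol convergence tolerance on the log-likelihood change
#' @param max_iter EM iteration cap per start
#' @param n_starts random restarts
#' @param seed integer seed
#' @return a `gom_fit`: `omega`, `theta`, `loglik`, `loglik_trace` (best
#'   start), `K`, `n_starts`, `tol`, `seed`, `sites` (retained site ids),
#'   `best_start`
#' @export
fit_gom <- function(X, K, tol = 0.1, max_iter = 500L, n_starts = 10L,
                    seed = 1L) {
  stopifnot(is.matrix(X), K >= 1)
  if (K > ncol(X)) stop("fit_gom: K exceeds the number of species")
  keep <- rowSums(X) > 0
  if (any(!keep))
    message(sprintf("fit_gom: dropping %d empty sites", sum(!keep)))
  X <- X[keep, , drop = FALSE]
  if (!nrow(X)) stop("fit_gom: no non-empty sites")
  n <- nrow(X); s <- ncol(X)
  site_ids <- if (!is.null(rownames(X))) rownames(X) else as.character(seq_len(n))

  if (K == 1) {
    theta <- matrix(colSums(X) / sum(X), 1, s, dimnames = list(NULL, colnames(X)))
    omega <- matrix(1, n, 1)
    ll <- gom_loglik(omega, theta, X)
    return(structure(list(omega = omega, theta = theta, loglik = as.numeric(ll),
                          loglik_trace = as.numeric(ll), K = 1L,
                          n_starts = 0L, tol = tol, seed = seed,
                          sites = site_ids, best_start = NA_integer_),
                     class = "gom_fit"))
  }

  best <- NULL
  with_seed(seed, {
    for (st in seq_len(n_starts)) {
      omega0 <- rdirichlet_rows(n, K)
      theta0 <- rdirichlet_rows(K, s)
      run <- gom_em_run(X, omega0, theta0, tol, max_iter)
      ll <- run$trace[length(run$trace)]
      if (is.null(best) || ll > best$ll) {
        best <- list(run = run, ll = ll, start = st)
      }
    }
  })
  omega <- best$run$omega
  theta <- best$run$theta
  rownames(omega) <- site_ids
  colnames(theta) <- colnames(X)
  structure(list(omega = omega, theta = theta, loglik = best$ll,
                 loglik_trace = best$run$trace, K = as.integer(K),
                 n_starts = as.integer(n_starts), tol = tol, seed = seed,
                 sites = site_ids, best_start = best$start),
            class = "gom_fit")
}

#' @export
print.gom_fit <- function(x, ...) {
  cat(sprintf("<gom_fit> K=%d, %d sites x %d species, loglik %.3f (%d EM iterations, start %s)\n",
              x$K, nrow(x$omega), ncol(x$theta), x$loglik,
              length(x$loglik_trace), x$best_start))
  invisible(x)
}

#' Simulate a binary site x species matrix from known memberships
#'
#' Each site draws `n_tokens` species from its mixture distribution
#' `omega_n %*% theta`; a species is present iff drawn at least once. Used
#' for parameter-recovery checks against the generative truth.
#'
#' @param omega sites x K matrix, rows on the simplex
#' @param theta K x species matrix, rows on the simplex
#' @param n_tokens multinomial draws per site
#' @param seed integer seed
#' @return binary sites x species matrix
#' @export
simulate_gom_pam <- function(omega, theta, n_tokens = 15L, seed = 1L) {
  check_simplex(omega, "omega")
  check_simplex(theta, "theta")
  P <- omega %*% theta
  with_seed(seed, {
    X <- t(apply(P, 1, function(p)
      as.integer(stats::rmultinom(1, n_tokens, p) > 0)))
    colnames(X) <- colnames(theta)
    X
  })
}

#' Match motif labels between two fits by theta similarity
#'
#' Greedy assignment on the Pearson correlation of motif rows (exact
#' Hungarian equivalent for the small K used here).
#'
#' @param theta_fit,theta_true K x species matrices
#' @return integer permutation: `perm[k]` is the row of `theta_true` matched
#'   to row k of `theta_fit`
#' @export
match_motifs <- function(theta_fit, theta_true) {
  K <- nrow(theta_fit)
  stopifnot(nrow(theta_true) == K)
  cors <- matrix(NA_real_, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    cors[i, j] <- suppressWarnings(cor(theta_fit[i, ], theta_true[j, ]))
  cors[!is.finite(cors)] <- -1
  if (K <= 8) {
    perms <- all_permutations(K)
    scores <- vapply(seq_len(nrow(perms)), function(r)
      sum(cors[cbind(seq_len(K), perms[r, ])]), 0)
    perms[which.max(scores), ]
  } else {
    perm <- integer(K)
    avail <- seq_len(K)
    for (i in order(apply(cors, 1, max), decreasing = TRUE)) {
      j <- avail[which.max(cors[i, avail])]
      perm[i] <- j
      avail <- setdiff(avail, j)
    }
    perm
  }
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Fit a series of grade-of-membership models over a K range
#'
#' @param X sites x species binary matrix
#' @param k_range integer vector of K values (default 2:14)
#' @param tol,max_iter,n_starts,seed passed to [fit_gom()]
#' @return list with `fits` (one `gom_fit` per K), `dominant` (data.frame of
#'   per-site dominant motif per K), `loglik` (data.frame `K, loglik`)
#' @export
motif_series <- function(X, k_range = 2:14, tol = 0.1, max_iter = 500L,
                         n_starts = 10L, seed = 1L) {
  k_range <- as.integer(k_range)
  stopifnot(all(k_range >= 1), all(k_range <= ncol(X)))
  fits <- lapply(k_range, function(K)
    fit_gom(X, K, tol = tol, max_iter = max_iter, n_starts = n_starts,
            seed = stage_seed(seed, "gom") + K))
  names(fits) <- paste0("K", k_range)
  dominant <- do.call(rbind, lapply(seq_along(k_range), function(i) {
    f <- fits[[i]]
    data.frame(K = k_range[i], site = f$sites,
               motif = max.col(f$omega, ties.method = "first"))
  }))
  list(fits = fits, dominant = dominant,
       loglik = data.frame(K = k_range,
                           loglik = vapply(fits, `[[`, 0, "loglik")))
}
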