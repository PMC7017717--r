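# category-response traces for every item at the grid nodes
model_traces <- function(model, X) {
  lapply(seq_len(model$n_items), function(j)
    softmax_cols(item_logits(model$items[[j]], model$scoring$s[[j]], X)))
}

# N x Q matrix of per-person log-likelihoods at each node, missing skipped
loglik_matrix <- function(traces, y) {
  N <- nrow(y); Q <- ncol(traces[[1L]])
  LL <- matrix(0, N, Q)
  for (j in seq_along(traces)) {
    obs <- which(!is.na(y[, j]))
    if (length(obs) > 0L)
      LL[obs, ] <- LL[obs, ] + log(traces[[j]])[y[obs, j] + 1L, , drop = FALSE]
  }
  LL
}

row_logsumexp_w <- function(LL, W) {
  m <- apply(LL, 1L, max)
  m + log(as.vector(exp(LL - m) %*% W))
}

#' Marginal log-likelihood of a response matrix
#'
#' Integrates each person's response-pattern likelihood over the latent
#' prior by quadrature:
#' `sum_i log sum_x W(x) prod_j T_j(y_ij | x)`, with missing items
#' skipped.
#'
#' @param model An [mnrm_model()].
#' @param grid A [latent_grid()] built with the model's correlation
#'   matrix.
#' @param responses `N x n` response matrix of 0-based codes.
#' @return The marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(model, grid, responses) {
  y <- as_responses(responses, K = vapply(model$items, `[[`, integer(1), "K"))
  if (nrow(y) == 0L || ncol(y) == 0L) stop("empty response matrix")
  if (ncol(y) != model$n_items)
    stop("response matrix has ", ncol(y), " items but model has ",
         model$n_items)
  LL <- loglik_matrix(model_traces(model, grid$X), y)
  sum(row_logsumexp_w(LL, grid$W))
}

# --- M-step machinery -------------------------------------------------------

# design matrix for one item's free parameters, stacked over (k, q) with k
# fastest: columns are the D slope directions (s_kd * x_qd) followed by the
# K-1 free intercept indicators
mstep_design <- function(s_j, X, include_a = TRUE, include_c = TRUE) {
  K <- nrow(s_j); Q <- nrow(X)
  cols <- list()
  if (include_a)
    for (d in seq_len(ncol(s_j)))
      cols[[length(cols) + 1L]] <- as.vector(outer(s_j[, d], X[, d]))
  if (include_c)
    for (m in 2:K)
      cols[[length(cols) + 1L]] <- rep(as.numeric(seq_len(K) == m), Q)
  do.call(cbind, cols)
}

# expected complete-data log-likelihood sum_k,q r_kq log T_kq
expected_ll <- function(Tm, r) sum(r[r > 0] * log(Tm[r > 0]))

# one Newton update cycle for an item given expected counts r (K x Q);
# returns updated (a, c).  Guarded by step-halving so the expected
# log-likelihood never decreases.
mstep_item <- function(item, s_j, X, r, include_a = TRUE, max_newton = 8L,
                       gtol = 1e-8) {
  K <- item$K; Q <- nrow(X)
  Bs <- mstep_design(s_j, X, include_a = include_a)
  nq <- colSums(r)
  theta <- if (include_a) c(item$a, item$c[-1L]) else item$c[-1L]
  unpack <- function(th) {
    if (include_a) {
      a <- th[seq_along(item$a)]
      cc <- c(0, th[-seq_along(item$a)])
    } else {
      a <- item$a
      cc <- c(0, th)
    }
    list(a = a, c = cc)
  }
  trace_of <- function(th) {
    p <- unpack(th)
    softmax_cols(item_logits(mnrm_item(p$a, p$c), s_j, X))
  }
  Tm <- trace_of(theta)
  ell <- expected_ll(Tm, r)
  for (it in seq_len(max_newton)) {
    vT <- as.vector(Tm)
    g <- crossprod(Bs, as.vector(r) - vT * rep(nq, each = K))[, 1L]
    if (max(abs(g)) < gtol) break
    w <- vT * rep(nq, each = K)
    H1 <- crossprod(Bs, Bs * w)
    P <- ncol(Bs)
    C <- matrix(0, P, Q)
    for (p in seq_len(P))
      C[p, ] <- colSums(matrix(Bs[, p] * vT, K, Q))
    H <- H1 - C %*% (t(C) * nq)          # negative Hessian, PSD
    step <- tryCatch(solve(H + diag(1e-9, P), g),
                     error = function(e) g / (max(diag(H)) + 1e-9))
    lambda <- 1
    repeat {
      cand <- theta + lambda * step
      Tc <- trace_of(cand)
      ec <- expected_ll(Tc, r)
      if (ec >= ell - 1e-12) {
        theta <- cand; Tm <- Tc; ell <- ec
        break
      }
      lambda <- lambda / 2
      if (lambda < 1e-8) break  # give up on this direction
    }
    if (lambda < 1e-8) break
  }
  unpack(theta)
}

# shared-slope M-step (equal-slopes constraint): alternate intercept
# updates per item with a joint Newton update of the common slopes
mstep_shared <- function(items, slist, X, rlist, sweeps = 3L) {
  D <- length(items[[1L]]$a)
  a <- items[[1L]]$a
  for (sw in seq_len(sweeps)) {
    for (j in seq_along(items)) {
      items[[j]]$a <- a
      upd <- mstep_item(items[[j]], slist[[j]], X, rlist[[j]],
                        include_a = FALSE)
      items[[j]]$c <- upd$c
    }
    # Newton step for the shared slopes with intercepts fixed
    g <- numeric(D); H <- matrix(0, D, D)
    for (j in seq_along(items)) {
      K <- items[[j]]$K
      Ba <- mstep_design(slist[[j]], X, include_c = FALSE)
      it <- items[[j]]; it$a <- a
      Tm <- softmax_cols(item_logits(it, slist[[j]], X))
      vT <- as.vector(Tm); r <- rlist[[j]]; nq <- colSums(r)
      g <- g + crossprod(Ba, as.vector(r) - vT * rep(nq, each = K))[, 1L]
      H1 <- crossprod(Ba, Ba * (vT * rep(nq, each = K)))
      C <- matrix(0, D, ncol(Tm))
      for (p in seq_len(D))
        C[p, ] <- colSums(matrix(Ba[, p] * vT, K, ncol(Tm)))
      H <- H + H1 - C %*% (t(C) * nq)
    }
    step <- tryCatch(solve(H + diag(1e-9, D), g),
                     error = function(e) g / (max(diag(H)) + 1e-9))
    ell0 <- sum(vapply(seq_along(items), function(j) {
      it <- items[[j]]; it$a <- a
      expected_ll(softmax_cols(item_logits(it, slist[[j]], X)), rlist[[j]])
    }, numeric(1)))
    lambda <- 1
    repeat {
      cand <- a + lambda * step
      ellc <- sum(vapply(seq_along(items), function(j) {
        it <- items[[j]]; it$a <- cand
        expected_ll(softmax_cols(item_logits(it, slist[[j]], X)), rlist[[j]])
      }, numeric(1)))
      if (ellc >= ell0 - 1e-12) { a <- cand; break }
      lambda <- lambda / 2
      if (lambda < 1e-8) break
    }
  }
  for (j in seq_along(items)) items[[j]]$a <- a
  items
}

nearest_correlation <- function(M) {
  M <- (M + t(M)) / 2
  d <- sqrt(diag(M))
  R <- M / tcrossprod(d)
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    diag(R) <- 1
  }
  R
}

default_start <- function(y, scoring) {
  D <- length(scoring$dims)
  items <- lapply(seq_len(ncol(y)), function(j) {
    K <- nrow(scoring$s[[j]])
    tab <- tabulate(y[, j] + 1L, nbins = K) + 0.5  # smoothed proportions
    cc <- log(tab / tab[1L])
    a0 <- c(1.0, rep(0.5, D - 1L))  # substantive dimension first
    mnrm_item(a0, cc)
  })
  mnrm_model(items, scoring, diag(D))
}

#' Fit the model by EM marginal maximum likelihood
#'
#' Bock-Aitkin EM over a fixed rectangular quadrature grid.  The E-step
#' computes each person's posterior weights over the grid nodes and
#' accumulates expected category counts per item and node; the M-step
#' maximizes each item's expected multinomial log-likelihood over its
#' slopes and intercepts by Newton-Raphson with step-halving, and (when
#' `estimate_R = TRUE` and `D > 1`) updates the latent correlation
#' matrix from posterior second moments projected to the nearest
#' correlation matrix, rebuilding the grid weights.  Iteration stops
#' when the marginal log-likelihood changes by less than `tol`.
#'
#' @param responses `N x n` response matrix of 0-based codes (`NA`
#'   missing).
#' @param scoring An [scoring_set()] defining the latent dimensions.
#' @param grid_points Nodes per dimension (default 21 for `D <= 2`, 15
#'   for `D = 3`).
#' @param grid_range Length-2 range (default `c(-5, 5)`).
#' @param max_iter,tol EM stopping rule (default 500 cycles, absolute
#'   log-likelihood change below 1e-5).
#' @param estimate_R Estimate latent correlations (default `TRUE`)?
#' @param equal_slopes Constrain every item to share one slope vector
#'   (the partial-credit-style constraint under which sum scores are
#'   sufficient), default `FALSE`.
#' @param start Optional [mnrm_model()] of starting values.
#' @param verbose Print an iteration trace to stderr.
#' @return An object of class `mnrm_fit`: list with `model`, `summary`
#'   (an `mnrm_fit_summary` holding `minus2LL`, `np`, `AIC`, `BIC`,
#'   `N`, `iterations`, `converged`), `trace` (log-likelihood per
#'   iteration), and `grid`.
#' @seealso [marginal_loglik()], [fit_indices()], [lr_test()]
#' @export
fit_mnrm <- function(responses, scoring, grid_points = NULL,
                     grid_range = NULL, max_iter = 500L, tol = 1e-5,
                     estimate_R = TRUE, equal_slopes = FALSE, start = NULL,
                     verbose = FALSE) {
  y <- as_responses(responses, K = vapply(scoring$s, nrow, integer(1)))
  if (nrow(y) == 0L) stop("empty response matrix")
  for (j in seq_len(ncol(y))) {
    check_identification(scoring$s[[j]], item = j)
    if (length(unique(y[!is.na(y[, j]), j])) < 2L)
      stop("item ", j, " has fewer than 2 observed categories")
  }
  D <- length(scoring$dims)
  N <- nrow(y)
  if (is.null(grid_points)) grid_points <- if (D <= 2L) 21L else 15L
  if (is.null(grid_range)) grid_range <- c(-5, 5)
  model <- if (is.null(start)) default_start(y, scoring) else start
  start_sign <- sign(vapply(seq_len(D), function(d)
    mean(vapply(model$items, function(it) it$a[d], numeric(1))), numeric(1)))
  R <- model$R
  make_grid <- function(Rm) {
    Rm2 <- Rm; dimnames(Rm2) <- list(scoring$dims, scoring$dims)
    latent_grid(grid_points, grid_range[1L], grid_range[2L], Rm2)
  }
  grid <- make_grid(R)
  X <- grid$X
  obs_idx <- lapply(seq_len(ncol(y)), function(j) which(!is.na(y[, j])))
  ind <- lapply(seq_len(ncol(y)), function(j) {
    K <- nrow(scoring$s[[j]])
    oi <- obs_idx[[j]]
    M <- matrix(0, length(oi), K)
    M[cbind(seq_along(oi), y[oi, j] + 1L)] <- 1
    M
  })
  trace <- numeric(0)
  prev_ll <- -Inf
  R_prev <- R
  R_changed <- FALSE
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    traces <- model_traces(model, X)
    LL <- loglik_matrix(traces, y)
    ll <- sum(row_logsumexp_w(LL, grid$W))
    if (R_changed && ll < prev_ll - 1e-10) {
      # the moment-based correlation update is not guaranteed to ascend;
      # revert it and continue with the previous prior
      R <- R_prev
      model$R <- R
      grid <- make_grid(R)
      ll <- sum(row_logsumexp_w(LL, grid$W))
    }
    trace <- c(trace, ll)
    if (verbose)
      message(sprintf("EM iter %3d  logLik %.6f", iter, ll))
    if (iter > 1L && abs(ll - prev_ll) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    prev_ll <- ll
    # E-step: posterior node weights per person
    A <- exp(LL - apply(LL, 1L, max))
    P <- sweep(A, 2L, grid$W, "*")
    P <- P / rowSums(P)
    rlist <- lapply(seq_len(ncol(y)), function(j)
      t(crossprod(P[obs_idx[[j]], , drop = FALSE], ind[[j]])))
    # M-step: item parameters
    if (equal_slopes) {
      model$items <- mstep_shared(model$items, scoring$s, X, rlist)
    } else {
      for (j in seq_len(ncol(y))) {
        upd <- mstep_item(model$items[[j]], scoring$s[[j]], X, rlist[[j]])
        model$items[[j]]$a <- upd$a
        model$items[[j]]$c <- upd$c
      }
    }
    # M-step: latent correlations from posterior second moments
    R_changed <- FALSE
    if (estimate_R && D > 1L) {
      M2 <- crossprod(X, X * colSums(P)) / N
      Rnew <- nearest_correlation(M2)
      if (max(abs(Rnew - R)) > 1e-12) {
        R_prev <- R
        R <- Rnew
        model$R <- R
        dimnames(model$R) <- list(scoring$dims, scoring$dims)
        grid <- make_grid(R)
        R_changed <- TRUE
      }
    }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations", call. = FALSE)
  end_sign <- sign(vapply(seq_len(D), function(d)
    mean(vapply(model$items, function(it) it$a[d], numeric(1))), numeric(1)))
  flipped <- which(start_sign * end_sign < 0)
  if (length(flipped) > 0L)
    warning("possible factor reflection: mean slope changed sign on ",
            "dimension(s) ", paste(scoring$dims[flipped], collapse = ", "),
            call. = FALSE)
  np_items <- if (equal_slopes) {
    D + sum(vapply(model$items, function(it) it$K - 1L, integer(1)))
  } else {
    sum(vapply(model$items, function(it) D + it$K - 1L, integer(1)))
  }
  np <- np_items + if (estimate_R && D > 1L) D * (D - 1L) / 2L else 0L
  minus2LL <- -2 * trace[length(trace)]
  ic <- fit_indices(minus2LL, np, N)
  summary <- structure(
    list(minus2LL = minus2LL, np = np, AIC = ic[["AIC"]], BIC = ic[["BIC"]],
         N = N, iterations = iter, converged = converged),
    class = "mnrm_fit_summary")
  structure(list(model = model, summary = summary, trace = trace,
                 grid = grid),
            class = "mnrm_fit")
}

#' @export
print.mnrm_fit_summary <- function(x, ...) {
  cat(sprintf("-2LL %.2f  np %d  AIC %.2f  BIC %.2f  N %d  (%s in %d iters)\n",
              x$minus2LL, x$np, x$AIC, x$BIC, x$N,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' @export
print.mnrm_fit <- function(x, ...) {
  cat("<mnrm_fit>\n")
  print(x$summary)
  print(x$model)
  invisible(x)
}

#' Information criteria from a deviance
#'
#' `AIC = -2LL + 2 np` and `BIC = -2LL + np log(N)`.
#'
#' @param minus2LL Deviance (-2 log marginal likelihood).
#' @param np Free-parameter count.
#' @param N Number of persons.
#' @return Named vector `c(AIC =, BIC =)`.
#' @examples
#' fit_indices(67424, 245, 586)
#' @export
fit_indices <- function(minus2LL, np, N) {
  if (N <= 0) stop("N must be positive")
  c(AIC = minus2LL + 2 * np, BIC = minus2LL + np * log(N))
}

#' Likelihood-ratio test of nested fits
#'
#' `chi2` is the deviance difference between the reduced and full model,
#' referred to a central chi-square with `df` equal to the difference in
#' free-parameter counts.  Nesting cannot be verified mechanically and
#' is the caller's responsibility.
#'
#' @param fit_full,fit_reduced `mnrm_fit`, `mnrm_fit_summary`, or any
#'   list with `minus2LL` and `np` fields; the reduced model must have
#'   fewer parameters.
#' @return List with `chi2`, `df`, `p`.
#' @examples
#' lr_test(list(minus2LL = 63958, np = 318), list(minus2LL = 67424, np = 245))
#' @export
lr_test <- function(fit_full, fit_reduced) {
  su <- function(f) if (inherits(f, "mnrm_fit")) f$summary else f
  full <- su(fit_full); red <- su(fit_reduced)
  if (red$np > full$np)
    stop("the reduced model must have fewer free parameters than the full")
  chi2 <- red$minus2LL - full$minus2LL
  df <- full$np - red$np
  if (chi2 < 0)
    warning("negative chi-square: models may not be nested or one fit ",
            "did not converge", call. = FALSE)
  p <- if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  list(chi2 = chi2, df = df, p = p)
}
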