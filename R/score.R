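#' Response-pattern EAP scores
#'
#' Expected a posteriori trait estimates: the posterior mean (and SD)
#' of each latent dimension given the full response pattern,
#' approximated on the quadrature grid as
#' `EAP_d = sum_x x_d L(y|x) W(x) / sum_x L(y|x) W(x)`.  Missing items
#' contribute nothing; an all-missing pattern receives the prior mean
#' and SD and is flagged.
#'
#' @param model An [mnrm_model()].
#' @param responses `N x n` response matrix of 0-based codes.
#' @param grid Optional [latent_grid()]; defaults to 49 equally spaced
#'   nodes on `[-6, 6]` per dimension with the model's correlations.
#' @return Data frame with columns `eap_<dim>`, `sd_<dim>` per
#'   dimension and `all_missing` flag.
#' @examples
#' S <- cbind(QOL = 0:6, ERS = scoring_template("ers", 7))
#' it <- mnrm_item(c(0.46, 1.03), c(0, 1.16, 1.17, 2.56, 2.89, 2.96, 2.72))
#' m <- mnrm_model(list(it, it, it), scoring_set(S, n_items = 3))
#' pattern_eap(m, rbind(c(0, 6, 6), c(3, 3, 2)))
#' @export
pattern_eap <- function(model, responses, grid = NULL) {
  if (is.null(grid)) grid <- default_grid(model$R, "scoring")
  y <- as_responses(responses, K = vapply(model$items, `[[`, integer(1), "K"))
  if (ncol(y) != model$n_items)
    stop("response matrix has ", ncol(y), " items but model has ",
         model$n_items)
  LL <- loglik_matrix(model_traces(model, grid$X), y)
  A <- exp(LL - apply(LL, 1L, max))
  P <- sweep(A, 2L, grid$W, "*")
  P <- P / rowSums(P)
  E1 <- P %*% grid$X
  E2 <- P %*% grid$X^2
  V <- pmax(E2 - E1^2, 0)
  out <- data.frame(row.names = seq_len(nrow(y)))
  for (d in seq_along(model$dims)) {
    out[[paste0("eap_", model$dims[d])]] <- E1[, d]
    out[[paste0("sd_", model$dims[d])]] <- sqrt(V[, d])
  }
  out$all_missing <- rowSums(!is.na(y)) == 0L
  out
}

#' Summed-score likelihoods by the Lord-Wingersky recursion
#'
#' Computes, at every quadrature node, the probability of each
#' attainable sum score on one dimension's recoded responses,
#' `L_d(v | x)`, by the polytomous Lord-Wingersky recursion: initialize
#' with the first item's collapsed response function, then for each
#' further item accumulate `L_j(v) = sum_m T_jd(m) L_{j-1}(v - m)`.
#' Sums are keyed on their exact values (rounded at 1e-9 for matching),
#' so non-integer scoring codes are supported.
#'
#' @inheritParams pattern_eap
#' @param d Dimension label or index to score.
#' @return Object of class `sumscore_likelihood`: list with `v`
#'   (attainable sums, ascending), `L` (`length(v) x Q` matrix; each
#'   column sums to 1), `grid`, `d` (label).
#' @export
summed_score_likelihood <- function(model, d, grid = NULL) {
  if (is.null(grid)) grid <- default_grid(model$R, "scoring")
  di <- dim_index(model, d)
  key <- function(v) sprintf("%.9f", v)
  v <- NULL; L <- NULL
  for (j in seq_len(model$n_items)) {
    s_j <- model$scoring$s[[j]]
    Tm <- collapsed_prob(model$items[[j]], s_j, di, grid$X)  # M x Q
    mvals <- sort(unique(s_j[, di]))
    if (j == 1L) {
      v <- mvals
      L <- Tm
    } else {
      vnew <- sort(unique(round(as.vector(outer(v, mvals, `+`)), 9L)))
      Lnew <- matrix(0, length(vnew), ncol(L))
      idx <- function(val) match(key(val), key(vnew))
      for (a in seq_along(v))
        for (b in seq_along(mvals)) {
          i <- idx(round(v[a] + mvals[b], 9L))
          Lnew[i, ] <- Lnew[i, ] + L[a, ] * Tm[b, ]
        }
      v <- vnew
      L <- Lnew
    }
  }
  rownames(L) <- format(v, trim = TRUE)
  structure(list(v = v, L = L, grid = grid, d = model$dims[di]),
            class = "sumscore_likelihood")
}

#' Sum-score-to-EAP translation table
#'
#' For each attainable sum score on the target dimension, multiplies
#' the summed-score likelihood by the normalized grid weights,
#' marginalizes over the nuisance dimensions, and reports the marginal
#' probability `p(v)`, the sum-score EAP `E(eta | v)` and its posterior
#' variance `V(eta | v)` from weighted node moments.
#'
#' @inheritParams summed_score_likelihood
#' @param ssl Optional precomputed [summed_score_likelihood()] (must
#'   match `d` and `grid`).
#' @return Object of class `translation_table`: data frame with columns
#'   `v`, `p`, `eap`, `var`, `sd`, and attributes `d` and `kernel` (the
#'   nuisance-marginalized `v x eta-node` kernel).  Unattainable rows
#'   (`p = 0`) carry `NA` moments.
#' @examples
#' ex <- worked_example()
#' translation_table(ex$model, "ERS", ex$grid)
#' @export
translation_table <- function(model, d, grid = NULL, ssl = NULL) {
  if (is.null(ssl)) ssl <- summed_score_likelihood(model, d, grid)
  grid <- ssl$grid
  di <- dim_index(model, ssl$d)
  eta <- grid$X[, di]
  eta_nodes <- sort(unique(eta))
  LW <- sweep(ssl$L, 2L, grid$W, "*")
  kernel <- vapply(eta_nodes,
                   function(e) rowSums(LW[, eta == e, drop = FALSE]),
                   numeric(nrow(LW)))
  kernel <- rbind(kernel)  # v x eta-node
  p <- rowSums(kernel)
  E <- as.vector(kernel %*% eta_nodes) / p
  V <- as.vector(kernel %*% eta_nodes^2) / p - E^2
  E[p == 0] <- NA_real_; V[p == 0] <- NA_real_
  V <- pmax(V, 0)
  tab <- data.frame(v = ssl$v, p = p, eap = E, var = V, sd = sqrt(V))
  attr(tab, "d") <- ssl$d
  attr(tab, "kernel") <- kernel
  class(tab) <- c("translation_table", "data.frame")
  tab
}

#' Look up a sum score in a translation table
#'
#' Deterministic table lookup: everyone with the same sum score gets
#' the same sum-score EAP and SD.
#'
#' @param table A [translation_table()].
#' @param v Sum score(s) to look up.
#' @return Data frame with `v`, `eap`, `sd` rows in the order of `v`.
#' @export
score_by_sum <- function(table, v) {
  i <- match(sprintf("%.9f", v), sprintf("%.9f", table$v))
  if (anyNA(i))
    stop("sum score ", paste(v[is.na(i)], collapse = ", "),
         " unattainable; attainable scores: ",
         paste(format(table$v, trim = TRUE), collapse = ", "))
  data.frame(v = table$v[i], eap = table$eap[i], sd = table$sd[i])
}

#' Compare sum scores, sum-score EAPs and pattern EAPs
#'
#' Builds, for each dimension, the three scores for every person
#' (recode-and-add sum score, translation-table EAP, and full
#' response-pattern EAP) and their Pearson and Spearman correlations
#' across methods and dimensions.  Persons with missing items get
#' pattern EAPs from their observed items but `NA` sum-score-based
#' entries (sum scores on incomplete patterns are not comparable across
#' persons).
#'
#' @inheritParams pattern_eap
#' @return List with `scores` (data frame: person, and per dimension
#'   `v_*`, `ss_eap_*`, `eap_*`), `pearson` and `spearman` correlation
#'   matrices over the score columns (complete observations).
#' @export
compare_scores <- function(model, responses, grid = NULL) {
  if (is.null(grid)) grid <- default_grid(model$R, "scoring")
  y <- as_responses(responses, K = vapply(model$items, `[[`, integer(1), "K"))
  ss <- sum_scores(y, model$scoring)
  pe <- pattern_eap(model, y, grid)
  incomplete <- ss$n_missing > 0L
  scores <- data.frame(person = seq_len(nrow(y)))
  for (lab in model$dims) {
    tab <- translation_table(model, lab, grid)
    v <- ss[[paste0("v_", lab)]]
    v[incomplete] <- NA_real_
    sseap <- rep(NA_real_, length(v))
    ok <- !is.na(v)
    if (any(ok)) sseap[ok] <- score_by_sum(tab, v[ok])$eap
    scores[[paste0("v_", lab)]] <- v
    scores[[paste0("ss_eap_", lab)]] <- sseap
    scores[[paste0("eap_", lab)]] <- pe[[paste0("eap_", lab)]]
  }
  M <- as.matrix(scores[, -1L, drop = FALSE])
  list(scores = scores,
       pearson = suppressWarnings(cor(M, use = "pairwise.complete.obs")),
       spearman = suppressWarnings(
         cor(M, use = "pairwise.complete.obs", method = "spearman")))
}
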