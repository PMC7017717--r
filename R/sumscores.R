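#' Validate a response matrix
#'
#' Responses are an `N x n` integer matrix of 0-based category codes
#' with `NA` marking missing entries.  Each non-missing entry must lie
#' in `0..K_j - 1` for its item.
#'
#' @param y Matrix or data frame of responses.
#' @param K Integer vector of per-item category counts (recycled); if
#'   `NULL`, `K_j` is inferred as `max(y[, j]) + 1`.
#' @return Integer matrix with attribute `K`.
#' @export
as_responses <- function(y, K = NULL) {
  y <- as.matrix(y)
  if (is.null(colnames(y))) colnames(y) <- paste0("item", seq_len(ncol(y)))
  num <- suppressWarnings(matrix(as.numeric(y), nrow(y), ncol(y),
                                 dimnames = dimnames(y)))
  bad <- which(!is.na(y) & (is.na(num) | num != round(num)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-integer response at row ", bad[1L, 1L], ", column '",
         colnames(y)[bad[1L, 2L]], "': '", y[bad[1L, 1L], bad[1L, 2L]], "'")
  y <- num
  storage.mode(y) <- "integer"
  if (is.null(K)) {
    K <- apply(y, 2L, function(col) {
      if (all(is.na(col))) 2L else max(col, na.rm = TRUE) + 1L
    })
  } else {
    K <- rep_len(as.integer(K), ncol(y))
  }
  for (j in seq_len(ncol(y))) {
    v <- y[, j]
    bad <- which(!is.na(v) & (v < 0L | v > K[j] - 1L))
    if (length(bad) > 0L)
      stop("response ", v[bad[1L]], " at row ", bad[1L], ", column '",
           colnames(y)[j], "' outside category range 0..", K[j] - 1L)
  }
  attr(y, "K") <- K
  y
}

#' Sum-score composites by category recoding
#'
#' The traditional construct measure: each response is recoded through
#' the dimension's scoring vector and the recodes are added across
#' items, `v_d = sum_j u_jd(y_j)`.  Persons with missing items get the
#' sum over their observed items together with an explicit count of
#' missing contributions (no imputation or proration).
#'
#' @param responses `N x n` response matrix (see [as_responses()]).
#' @param scoring An [scoring_set()].
#' @param d Dimension label or index; `NULL` (default) returns all
#'   dimensions.
#' @return A data frame with one sum-score column per requested
#'   dimension (`v_<dim>`) and a `n_missing` column.
#' @examples
#' S <- cbind(QOL = 0:6, ERS = scoring_template("ers", 7))
#' sc <- scoring_set(S, n_items = 3)
#' y <- rbind(c(0, 6, 3), c(2, 2, NA))
#' sum_scores(y, sc)
#' @export
sum_scores <- function(responses, scoring, d = NULL) {
  y <- as_responses(responses,
                    K = vapply(scoring$s, nrow, integer(1)))
  dd <- if (is.null(d)) scoring$dims else scoring$dims[dim_index(scoring$dims, d)]
  out <- data.frame(row.names = seq_len(nrow(y)))
  for (lab in dd) {
    di <- dim_index(scoring$dims, lab)
    U <- vapply(seq_len(ncol(y)),
                function(j) recode_response(y[, j], scoring$s[[j]][, di]),
                numeric(nrow(y)))
    U <- rbind(U)
    out[[paste0("v_", lab)]] <- rowSums(U, na.rm = TRUE)
  }
  out$n_missing <- rowSums(is.na(y))
  # a fully-missing person has no observed basis for a sum at all
  out[out$n_missing == ncol(y), grep("^v_", names(out))] <- NA_real_
  out
}

#' Attainable sum scores for one dimension
#'
#' Enumerates the sorted distinct values of `sum_j m_j` over each item's
#' distinct scoring codes.  For `n` items coded 0/1 this is `0..n`.
#' Codes must be integer-valued; arbitrary real codes are handled by the
#' recursion in [summed_score_likelihood()], which keys on exact sums.
#'
#' @inheritParams sum_scores
#' @param d Dimension label or index.
#' @return Sorted numeric vector of attainable sum scores.
#' @export
possible_scores <- function(scoring, d) {
  di <- dim_index(scoring$dims, d)
  codes <- lapply(scoring$s, function(m) sort(unique(m[, di])))
  if (any(vapply(codes, function(v) any(v != round(v)), logical(1))))
    stop("non-integer scoring codes; enumerate attainable sums with ",
         "summed_score_likelihood(), which keys on exact real sums")
  acc <- 0
  for (v in codes) acc <- sort(unique(as.vector(outer(acc, v, `+`))))
  acc
}
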