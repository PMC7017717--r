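#' Item parameters for one nominal-response item
#'
#' Bundles the overall slopes `a` (one per latent dimension, on the
#' log-odds scale per unit latent trait per unit scoring-code difference)
#' and the category intercepts `c` for a single item.  The first
#' intercept is the reference and must equal zero.
#'
#' @param a Numeric vector of D overall slopes, optionally named by
#'   dimension label.
#' @param c Numeric vector of K category intercepts; `c[1]` (the
#'   intercept of category 0) must be exactly 0.
#' @return An object of class `mnrm_item` with fields `a`, `c` and `K`.
#' @examples
#' it <- mnrm_item(a = c(QOL = 0.46, ERS = 1.03),
#'                 c = c(0, 1.16, 1.17, 2.56, 2.89, 2.96, 2.72))
#' it$K
#' @export
mnrm_item <- function(a, c) {
  a_num <- as.numeric(a)
  names(a_num) <- names(a)
  c <- as.numeric(c)
  if (length(c) < 2L)
    stop("an item needs at least 2 categories (length(c) >= 2)")
  if (!all(is.finite(a_num)) || !all(is.finite(c)))
    stop("item parameters must be finite")
  if (c[1L] != 0)
    stop("the reference-category intercept c[1] (category 0) must be 0, got ",
         format(c[1L]))
  structure(list(a = a_num, c = c, K = length(c)), class = "mnrm_item")
}

#' @export
print.mnrm_item <- function(x, ...) {
  cat("<mnrm_item> K =", x$K, "categories,", length(x$a), "dimensions\n")
  cat("  a:", paste(format(round(x$a, 3)), collapse = " "), "\n")
  cat("  c:", paste(format(round(x$c, 3)), collapse = " "), "\n")
  invisible(x)
}

#' Scoring-function templates
#'
#' Expands a named template to a scoring vector of length `K`:
#' `"trait"` gives the ordinal codes `0..K-1` (the generalized partial
#' credit convention), `"ers"` marks the two endpoint categories
#' (extreme responding), `"mrs"` marks the middle category (midpoint
#' responding; requires odd `K`), and `"midrange"` marks the middle
#' block of categories.
#'
#' @param template One of `"trait"`, `"ers"`, `"mrs"`, `"midrange"`.
#' @param K Number of categories.
#' @return Numeric scoring vector of length `K`.
#' @examples
#' scoring_template("ers", 7)   # 1 0 0 0 0 0 1
#' scoring_template("trait", 5) # 0 1 2 3 4
#' @export
scoring_template <- function(template, K) {
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2")
  switch(match.arg(template, c("trait", "ers", "mrs", "midrange")),
    trait = as.numeric(seq_len(K) - 1L),
    ers = { s <- numeric(K); s[c(1L, K)] <- 1; s },
    mrs = {
      if (K %% 2L == 0L)
        stop("the 'mrs' midpoint template needs an odd number of categories")
      s <- numeric(K); s[(K + 1L) / 2L] <- 1; s
    },
    midrange = {
      s <- numeric(K)
      lo <- floor(K / 3) + 1L
      s[lo:(K + 1L - lo)] <- 1
      s
    })
}

#' Scoring-function set for a test
#'
#' Holds, for each item, a `K_j x D` matrix of scoring-function codes
#' (one column per latent dimension).  Codes may be any reals, including
#' negative values.  On construction each item's matrix is checked for
#' identification: the columns together with an all-ones column must be
#' linearly independent, otherwise one dimension's codes are an affine
#' combination of the others (e.g. `[0,1,1,1,1,1,0]` alongside the
#' extreme-responding codes `[1,0,0,0,0,0,1]`) and the model is not
#' estimable.
#'
#' @param s Either a single `K x D` matrix (broadcast to all `n_items`
#'   items) or a list of per-item matrices with identical column labels.
#' @param dims Character vector of dimension labels; defaults to the
#'   matrix column names.
#' @param n_items Number of items when broadcasting a single matrix.
#' @return An object of class `mnrm_scoring`: a list with `s` (per-item
#'   matrices), `dims`, and `n_items`.
#' @examples
#' S <- cbind(QOL = 0:6, ERS = scoring_template("ers", 7))
#' sc <- scoring_set(S, n_items = 3)
#' sc$dims
#' @export
scoring_set <- function(s, dims = NULL, n_items = NULL) {
  if (is.matrix(s)) {
    if (is.null(n_items))
      stop("n_items is required when a single scoring matrix is broadcast")
    s <- rep(list(s), n_items)
  }
  if (!is.list(s) || !all(vapply(s, is.matrix, logical(1))))
    stop("s must be a matrix or a list of matrices")
  if (is.null(dims)) dims <- colnames(s[[1L]])
  if (is.null(dims)) stop("dimension labels are required (colnames or dims=)")
  if (anyDuplicated(dims)) stop("dimension labels must be unique")
  s <- lapply(seq_along(s), function(j) {
    m <- s[[j]]
    if (ncol(m) != length(dims))
      stop("item ", j, ": scoring matrix has ", ncol(m),
           " columns but there are ", length(dims), " dimensions")
    colnames(m) <- dims
    storage.mode(m) <- "double"
    check_identification(m, item = j)
    m
  })
  structure(list(s = s, dims = dims, n_items = length(s)),
            class = "mnrm_scoring")
}

#' @export
print.mnrm_scoring <- function(x, ...) {
  cat("<mnrm_scoring>", x$n_items, "items, dimensions:",
      paste(x$dims, collapse = ", "), "\n")
  invisible(x)
}

#' Identification check for one item's scoring functions
#'
#' The `K x (D+1)` matrix `[1, s_1, ..., s_D]` must have full column
#' rank: a scoring function that is an affine combination of the others
#' defines a redundant construct and is rejected.  Rank is judged by the
#' singular values with a relative tolerance of 1e-8.
#'
#' @param s_j `K x D` scoring matrix for one item.
#' @param item Item index used in the error message.
#' @return Invisibly `TRUE`; otherwise an error naming the dependent
#'   dimensions.
#' @export
check_identification <- function(s_j, item = NA) {
  M <- cbind(`(ones)` = rep(1, nrow(s_j)), s_j)
  sv <- svd(M, nu = 0, nv = 0)$d
  if (sv[length(sv)] < 1e-8 * sv[1L]) {
    lbl <- colnames(s_j)
    if (is.null(lbl)) lbl <- paste0("dim", seq_len(ncol(s_j)))
    stop(sprintf(paste0("scoring functions for item %s are linearly ",
                        "dependent (given an intercept): dimensions {%s} ",
                        "include a redundant definition"),
                 as.character(item), paste(lbl, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Multidimensional nominal response model
#'
#' Combines an ordered list of items, a scoring-function set, and the
#' latent correlation matrix.  Latent traits have fixed mean 0 and
#' variance 1; only their correlations are free.
#'
#' @param items List of [mnrm_item()] objects.
#' @param scoring An [scoring_set()] with one scoring matrix per item.
#' @param R `D x D` latent correlation matrix (default identity).
#' @return An object of class `mnrm_model`.
#' @examples
#' S <- cbind(QOL = 0:6, ERS = scoring_template("ers", 7))
#' items <- list(mnrm_item(c(0.46, 1.03), c(0, 1.16, 1.17, 2.56, 2.89, 2.96, 2.72)))
#' m <- mnrm_model(items, scoring_set(S, n_items = 1))
#' @export
mnrm_model <- function(items, scoring, R = NULL) {
  if (!inherits(scoring, "mnrm_scoring")) stop("scoring must be an mnrm_scoring")
  if (!all(vapply(items, inherits, logical(1), "mnrm_item")))
    stop("items must be a list of mnrm_item objects")
  if (length(items) != scoring$n_items)
    stop("item count (", length(items), ") and scoring set (",
         scoring$n_items, ") disagree")
  D <- length(scoring$dims)
  for (j in seq_along(items)) {
    if (length(items[[j]]$a) != D)
      stop("item ", j, ": ", length(items[[j]]$a), " slopes but ", D,
           " dimensions")
    if (items[[j]]$K != nrow(scoring$s[[j]]))
      stop("item ", j, ": K = ", items[[j]]$K,
           " but scoring matrix has ", nrow(scoring$s[[j]]), " rows")
    names(items[[j]]$a) <- scoring$dims
  }
  if (is.null(R)) R <- diag(D)
  R <- as.matrix(R)
  check_correlation(R, D)
  dimnames(R) <- list(scoring$dims, scoring$dims)
  structure(list(items = items, scoring = scoring, R = R,
                 dims = scoring$dims, D = D, n_items = length(items)),
            class = "mnrm_model")
}

check_correlation <- function(R, D) {
  if (!is.matrix(R) || nrow(R) != D || ncol(R) != D)
    stop("R must be a ", D, "x", D, " matrix")
  if (max(abs(R - t(R))) > 1e-10) stop("R must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-10) stop("R must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) stop("R is not positive definite")
  invisible(TRUE)
}

#' @export
print.mnrm_model <- function(x, ...) {
  cat("<mnrm_model>", x$n_items, "items,", x$D, "dimensions (",
      paste(x$dims, collapse = ", "), ")\n")
  if (x$D > 1L) {
    cat("latent correlations:\n")
    print(round(x$R, 3))
  }
  invisible(x)
}

dim_index <- function(model_or_dims, d) {
  dims <- if (is.character(model_or_dims)) model_or_dims else model_or_dims$dims
  if (is.character(d)) {
    i <- match(d, dims)
    if (is.na(i)) stop("unknown dimension '", d, "'; have: ",
                       paste(dims, collapse = ", "))
    i
  } else {
    d <- as.integer(d)
    if (d < 1L || d > length(dims)) stop("dimension index out of range")
    d
  }
}

# category logits z_k(x) = sum_d a_d s_kd x_d + c_k for a matrix of latent
# points; returns K x Q
item_logits <- function(item, s_j, X) {
  X <- rbind(X)  # single point -> 1 x D
  if (ncol(X) != length(item$a) || ncol(s_j) != length(item$a))
    stop("latent point / scoring / slope dimensions disagree for item (",
         "D = ", length(item$a), ")")
  sweep(s_j %*% (item$a * t(X)), 1L, -item$c)
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2L, apply(Z, 2L, max))
  E <- exp(Z)
  sweep(E, 2L, colSums(E), "/")
}

#' Category response probabilities
#'
#' Evaluates the nominal-model category response function
#' `T(k | x) = exp(sum_d a_d s_kd x_d + c_k) / sum_m exp(...)` at one or
#' more latent points.  Computed with max-subtraction so large logits do
#' not overflow.
#'
#' @param item An [mnrm_item()].
#' @param s `K x D` scoring matrix for the item.
#' @param x Latent point (length-D vector) or `Q x D` matrix of points.
#' @return A length-K probability vector (single point) or `K x Q`
#'   matrix with one column per point; categories are 0-based
#'   (`k = 0..K-1` maps to entries `1..K`).
#' @examples
#' it <- mnrm_item(c(0.46, 1.03), c(0, 1.16, 1.17, 2.56, 2.89, 2.96, 2.72))
#' S <- cbind(0:6, c(1, 0, 0, 0, 0, 0, 1))
#' round(category_prob(it, S, c(-3, 3)), 2)
#' @export
category_prob <- function(item, s, x) {
  P <- softmax_cols(item_logits(item, s, x))
  if (is.null(dim(x)) || nrow(rbind(x)) == 1L) drop(P) else P
}

#' Pairwise log-odds between two categories
#'
#' The log-odds of choosing category `k` over `kprime`, which under the
#' nominal model is linear in each latent trait:
#' `c_k - c_k' + sum_d a_d (s_kd - s_k'd) x_d`.
#'
#' @inheritParams category_prob
#' @param k,kprime 0-based category codes.
#' @return The log-odds (0 when `k == kprime`).
#' @examples
#' it <- mnrm_item(c(0.46, 1.03), c(0, 1.16, 1.17, 2.56, 2.89, 2.96, 2.72))
#' S <- cbind(0:6, c(1, 0, 0, 0, 0, 0, 1))
#' pairwise_logit(it, S, 1, 0, c(0, 0))  # 1.16
#' @export
pairwise_logit <- function(item, s, k, kprime, x) {
  K <- item$K
  for (kk in c(k, kprime))
    if (kk < 0L || kk > K - 1L)
      stop("category ", kk, " out of range 0..", K - 1L)
  if (k == kprime) return(0)
  i <- k + 1L; ip <- kprime + 1L
  item$c[i] - item$c[ip] +
    sum(item$a * (s[i, ] - s[ip, ]) * as.numeric(x))
}

#' Recode a response through a scoring vector
#'
#' Maps an observed 0-based category to its construct-relevant code,
#' `u(y) = s[y]`.  Missing responses propagate as `NA` (never silently
#' zero).
#'
#' @param y Integer vector of 0-based responses (NA allowed).
#' @param s_jd Scoring vector of length K for one item and dimension.
#' @return Numeric vector of recoded values.
#' @examples
#' recode_response(c(6, 3, NA), c(1, 0, 0, 0, 0, 0, 1))
#' @export
recode_response <- function(y, s_jd) {
  out <- rep(NA_real_, length(y))
  ok <- !is.na(y)
  if (any(ok)) {
    yk <- as.integer(y[ok])
    if (any(yk < 0L | yk > length(s_jd) - 1L))
      stop("response out of range 0..", length(s_jd) - 1L)
    out[ok] <- s_jd[yk + 1L]
  }
  out
}

#' Collapsed (dimension-specific) response function
#'
#' Collapses the K category probabilities onto the distinct values `m`
#' of one dimension's scoring vector:
#' `T_d(m | x) = sum_k 1(s_kd = m) T(k | x)`.  With endpoint codes
#' `1,0,...,0,1` this yields the probability of a non-extreme (m = 0)
#' versus extreme (m = 1) response.
#'
#' @inheritParams category_prob
#' @param d Dimension index or label (requires named scoring columns).
#' @return Named probability vector over the distinct codes in
#'   ascending order (single point), or a matrix with one column per
#'   point.
#' @examples
#' it <- mnrm_item(c(0.46, 1.03), c(0, 1.16, 1.17, 2.56, 2.89, 2.96, 2.72))
#' S <- cbind(QOL = 0:6, ERS = c(1, 0, 0, 0, 0, 0, 1))
#' round(collapsed_prob(it, S, "ERS", c(0, 0)), 3)
#' @export
collapsed_prob <- function(item, s, d, x) {
  di <- dim_index(colnames(s) %||% paste0("dim", seq_len(ncol(s))), d)
  vals <- sort(unique(s[, di]))
  P <- softmax_cols(item_logits(item, s, x))
  G <- vapply(vals, function(m) colSums(P[s[, di] == m, , drop = FALSE]),
              numeric(ncol(P)))
  G <- rbind(G)  # Q x M
  out <- t(G)
  rownames(out) <- format(vals, trim = TRUE)
  if (is.null(dim(x)) || nrow(rbind(x)) == 1L) out[, 1L] else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert overall slopes to per-category nominal slopes
#'
#' The nominal category-slope parameterization writes the model with a
#' slope per category and dimension, `a~_kd = a_d * s_kd`.
#'
#' @inheritParams category_prob
#' @return `K x D` matrix of category slopes.
#' @export
to_category_slopes <- function(item, s) {
  sweep(s, 2L, item$a, "*")
}

#' Reparameterize an item under an affine change of scoring functions
#'
#' Applies `s'_kd = (s_kd - shift_d) * scale_d` with the compensating
#' slope change `a'_d = a_d / scale_d`, and re-references the intercepts
#' (and the implied category slopes) so the chosen reference category
#' has intercept zero.  Category probabilities are invariant: shifting
#' a scoring function adds a constant to every category logit, and
#' rescaling is absorbed by the slope.  With `reference = "last"`, the
#' intercepts are also re-expressed relative to the last category and
#' the scoring codes shifted so its code is 0 on every dimension (the
#' convention used by software that anchors the last category).
#'
#' @inheritParams category_prob
#' @param shift,scale Per-dimension reals (recycled); `scale` nonzero.
#' @param reference `"first"` or `"last"` anchor category.
#' @return List with elements `item` (new [mnrm_item()], intercepts
#'   referenced to category 0 internally, plus attribute
#'   `intercept_offset` when `reference = "last"`) and `s` (new scoring
#'   matrix).
#' @export
reparameterize <- function(item, s, shift = 0, scale = 1,
                           reference = c("first", "last")) {
  reference <- match.arg(reference)
  D <- ncol(s)
  shift <- rep_len(as.numeric(shift), D)
  scale <- rep_len(as.numeric(scale), D)
  if (any(scale == 0)) stop("scale must be nonzero for every dimension")
  s2 <- sweep(sweep(s, 2L, shift), 2L, scale, "*")
  a2 <- item$a / scale
  c2 <- item$c
  ref <- if (reference == "first") 1L else item$K
  if (reference == "last") {
    # anchor the last category: code 0 on every dimension, intercept 0
    s2 <- sweep(s2, 2L, s2[ref, ])
    c2 <- c2 - c2[ref]
  }
  # shifting codes moves intercepts: z_k picks up a'_d * (code shift) * x_d
  # only through x-dependent terms, so intercepts are unchanged by shifts;
  # re-reference intercepts to category 0 for the constructor
  off <- c2[1L]
  c2 <- c2 - off
  out <- list(item = mnrm_item(a2, c2), s = s2)
  attr(out$item, "intercept_offset") <- off
  out
}
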