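#' Design for a synthetic response-style study
#'
#' Describes the generating conditions for [make_style_study()]: sample
#' size, item count and category count, one substantive trait plus the
#' requested style dimensions, the latent correlation matrix, and the
#' ranges the random item-parameter generator draws from.  Defaults
#' emulate a Likert battery of 20 seven-category items measuring one
#' trait alongside extreme responding: substantive slopes uniform on
#' `[0.3, 1.0]` (per unit scoring code), style slopes uniform on
#' `[0.5, 1.5]`, and unimodal intercept profiles with additive noise,
#' loosely matching the magnitudes seen in quality-of-life item
#' calibrations.
#'
#' @param N Persons (default 1000).
#' @param n_items Items (default 20).
#' @param K Categories per item (default 7).
#' @param dims Named character vector mapping dimension labels to
#'   scoring templates (see [scoring_template()]); the first entry is
#'   the substantive trait.  Default `c(trait = "trait", ERS = "ers")`.
#' @param R Latent correlation matrix (default identity).
#' @param slope_range Named list of per-dimension slope ranges; entries
#'   `trait` (default `c(0.3, 1)`) and `style` (default `c(0.5, 1.5)`).
#' @param seed Mandatory integer seed.
#' @return List of class `style_design`.
#' @export
style_design <- function(N = 1000L, n_items = 20L, K = 7L,
                         dims = c(trait = "trait", ERS = "ers"),
                         R = NULL, slope_range = NULL, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  D <- length(dims)
  if (is.null(R)) R <- diag(D)
  check_correlation(as.matrix(R), D)
  if (is.null(slope_range)) slope_range <- list()
  slope_range$trait <- slope_range$trait %||% c(0.3, 1.0)
  slope_range$style <- slope_range$style %||% c(0.5, 1.5)
  structure(list(N = as.integer(N), n_items = as.integer(n_items),
                 K = as.integer(K), dims = dims, R = as.matrix(R),
                 slope_range = slope_range, seed = as.integer(seed)),
            class = "style_design")
}

#' Draw correlated latent traits
#'
#' Rows are drawn from the mean-0, unit-variance multivariate normal
#' with correlation `R`, reproducibly under the given seed.
#'
#' @param n Number of persons.
#' @param R Correlation matrix.
#' @param seed Integer seed.
#' @return `n x D` matrix of latent traits.
#' @export
draw_latent <- function(n, R, seed) {
  R <- as.matrix(R)
  D <- nrow(R)
  check_correlation(R, D)
  X <- withr::with_seed(seed,
    matrix(rnorm(n * D), n, D) %*% chol(R))
  colnames(X) <- colnames(R)
  X
}

#' Simulate responses from a model
#'
#' Draws each response from the categorical distribution given by the
#' model's category response function at the person's latent point.
#'
#' @param model An [mnrm_model()].
#' @param latent `N x D` matrix of latent traits.
#' @param seed Integer seed.
#' @return `N x n` integer response matrix (0-based codes).
#' @export
simulate_responses <- function(model, latent, seed) {
  latent <- rbind(latent)
  if (ncol(latent) != model$D)
    stop("latent matrix has ", ncol(latent), " columns but model has ",
         model$D, " dimensions")
  N <- nrow(latent)
  y <- matrix(NA_integer_, N, model$n_items,
              dimnames = list(NULL, paste0("item", seq_len(model$n_items))))
  if (N == 0L) return(y)
  withr::with_seed(seed, {
    for (j in seq_len(model$n_items)) {
      Tm <- category_prob(model$items[[j]], model$scoring$s[[j]], latent)
      Tm <- rbind(Tm)                       # K x N (or 1-point vector)
      if (ncol(Tm) != N) Tm <- matrix(Tm, ncol = N)
      cum <- apply(Tm, 2L, cumsum)
      u <- runif(N)
      y[, j] <- colSums(cum < rep(u, each = nrow(cum)))
    }
  })
  y
}

# random item parameters for a design: unimodal intercepts with noise,
# slopes uniform in the design's ranges
draw_items <- function(design, seed) {
  K <- design$K
  D <- length(design$dims)
  withr::with_seed(seed, {
    lapply(seq_len(design$n_items), function(j) {
      a <- numeric(D)
      rngT <- design$slope_range$trait
      rngS <- design$slope_range$style
      a[1L] <- runif(1, rngT[1L], rngT[2L])
      if (D > 1L) a[2:D] <- runif(D - 1L, rngS[1L], rngS[2L])
      h <- runif(1, 2, 3.5)
      pk <- runif(1, 0.35, 0.65) * (K - 1)
      raw <- h - 0.25 * (seq_len(K) - 1 - pk)^2 + rnorm(K, 0, 0.25)
      mnrm_item(a, raw - raw[1L])
    })
  })
}

#' Generate a complete synthetic style study
#'
#' Returns simulated responses together with the generating truths
#' (model and latent traits), the end-to-end fixture for estimation
#' recovery and for demonstrating the style/content confounding of sum
#' scores: under a trait + extreme-responding generating model the ERS
#' sum score shows a U-shaped relationship with the trait sum score
#' even when the latent traits are uncorrelated, while pattern EAPs do
#' not.
#'
#' Sub-seeds for item drawing, latent traits, and responses are derived
#' deterministically from the design seed.
#'
#' @param design A [style_design()].
#' @return List with `responses`, `model` (true generating model),
#'   `latent` (true scores), `scoring`, `design`.
#' @export
make_style_study <- function(design) {
  stopifnot(inherits(design, "style_design"))
  D <- length(design$dims)
  S <- do.call(cbind, lapply(design$dims, scoring_template, K = design$K))
  colnames(S) <- names(design$dims)
  scoring <- scoring_set(S, n_items = max(design$n_items, 1L))
  if (design$n_items == 0L || design$N == 0L) {
    model <- NULL
    if (design$n_items > 0L) {
      items <- draw_items(design, design$seed + 1L)
      model <- mnrm_model(items, scoring, design$R)
    }
    return(list(responses = matrix(NA_integer_, design$N, design$n_items),
                model = model,
                latent = matrix(numeric(0), design$N, D),
                scoring = scoring, design = design))
  }
  items <- draw_items(design, design$seed + 1L)
  model <- mnrm_model(items, scoring, design$R)
  latent <- draw_latent(design$N, design$R, design$seed + 2L)
  colnames(latent) <- names(design$dims)
  responses <- simulate_responses(model, latent, design$seed + 3L)
  list(responses = responses, model = model, latent = latent,
       scoring = scoring, design = design)
}
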