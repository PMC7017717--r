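#' Read a response matrix from CSV
#'
#' Expects a header row of item identifiers and one row of integer
#' 0-based category codes per person; empty cells or `NA` mark missing
#' responses.  Cells are validated (integer, within each item's
#' category range) with errors naming the offending row and column.
#'
#' @param path CSV file path.
#' @param K Optional per-item category counts; inferred from the data
#'   when omitted.
#' @return Validated integer matrix with attribute `K` (see
#'   [as_responses()]).
#' @export
read_responses <- function(path, K = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  as_responses(df, K = K)
}

#' Write scores or parameters to CSV at full precision
#' @param x Data frame.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_full_csv <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write item parameters to CSV
#'
#' One row per item with columns `a_<dim>` ... then `c_0..c_{K-1}`
#' (ragged items padded with empty cells).
#'
#' @param model An [mnrm_model()].
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_parameters <- function(model, path) {
  Kmax <- max(vapply(model$items, `[[`, integer(1), "K"))
  rows <- lapply(seq_len(model$n_items), function(j) {
    it <- model$items[[j]]
    c(as.list(it$a), as.list(c(it$c, rep(NA_real_, Kmax - it$K))))
  })
  df <- as.data.frame(do.call(rbind, lapply(rows, function(r)
    unlist(r, use.names = FALSE))))
  names(df) <- c(paste0("a_", model$dims), paste0("c_", 0:(Kmax - 1L)))
  df <- cbind(item = seq_len(model$n_items), df)
  write_full_csv(df, path)
}

#' Read item parameters written by [write_parameters()]
#'
#' @param path CSV path.
#' @param scoring The [scoring_set()] the parameters belong to.
#' @return An [mnrm_model()] with identity correlations (set `$R`
#'   afterwards if needed).
#' @export
read_parameters <- function(path, scoring) {
  df <- read.csv(path, check.names = FALSE)
  acols <- paste0("a_", scoring$dims)
  if (!all(acols %in% names(df)))
    stop("parameter file lacks slope columns: ",
         paste(setdiff(acols, names(df)), collapse = ", "))
  items <- lapply(seq_len(nrow(df)), function(j) {
    K <- nrow(scoring$s[[j]])
    cc <- as.numeric(df[j, paste0("c_", 0:(K - 1L))])
    mnrm_item(as.numeric(df[j, acols]), cc)
  })
  mnrm_model(items, scoring)
}

#' Load a model configuration from JSON or YAML
#'
#' The configuration names the latent dimensions and gives, per
#' dimension, either a scoring-function template (`"trait"`, `"ers"`,
#' `"mrs"`, `"midrange"`) or an explicit scoring vector; a single
#' vector is broadcast to every item with a matching category count.
#' The per-item identification rank check runs on load, and a redundant
#' dimension pair is rejected with both dimensions named; no partially
#' constructed configuration is returned.
#'
#' Expected structure (JSON shown; YAML equivalent):
#' \preformatted{
#' {
#'   "n_items": 35, "K": 7,
#'   "dimensions": [
#'     {"label": "QOL", "role": "substantive", "scoring": "trait"},
#'     {"label": "ERS", "role": "style", "scoring": "ers"},
#'     {"label": "MRS", "role": "style", "scoring": [0,0,0,1,0,0,0]}
#'   ],
#'   "grid": {"points": 21, "range": [-5, 5]},
#'   "estimation": {"max_iter": 500, "tol": 1e-5, "estimate_R": true}
#' }
#' }
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @param n_items,K Override / supply item count and category count
#'   when absent from the file.
#' @return List of class `mnrm_config` with elements `scoring` (an
#'   [scoring_set()]), `roles`, `grid`, `estimation`.
#' @export
read_model_config <- function(path, n_items = NULL, K = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  n_items <- n_items %||% cfg$n_items
  K <- K %||% cfg$K
  if (is.null(n_items) || is.null(K))
    stop("config must state n_items and K (or pass them as arguments)")
  dims_raw <- cfg$dimensions
  if (is.data.frame(dims_raw))
    dims_raw <- lapply(seq_len(nrow(dims_raw)), function(i) {
      as.list(dims_raw[i, , drop = FALSE])
    })
  if (is.null(dims_raw) || length(dims_raw) == 0L)
    stop("config must define at least one dimension")
  labels <- vapply(dims_raw, function(d) as.character(d$label), character(1))
  if (anyDuplicated(labels))
    stop("dimension labels must be unique: ", paste(labels, collapse = ", "))
  roles <- vapply(dims_raw, function(d)
    as.character(d$role %||% "substantive"), character(1))
  vecs <- lapply(dims_raw, function(d) {
    sc <- d$scoring
    if (is.list(sc)) sc <- unlist(sc)
    if (is.character(sc)) {
      scoring_template(sc, K)
    } else {
      sc <- as.numeric(sc)
      if (length(sc) != K)
        stop("dimension '", d$label, "': scoring vector length ",
             length(sc), " != K = ", K)
      sc
    }
  })
  S <- do.call(cbind, vecs)
  colnames(S) <- labels
  scoring <- tryCatch(scoring_set(S, n_items = n_items),
                      error = function(e)
                        stop("invalid configuration: ", conditionMessage(e),
                             call. = FALSE))
  structure(list(scoring = scoring, roles = roles,
                 grid = cfg$grid, estimation = cfg$estimation),
            class = "mnrm_config")
}

#' Built-in worked example
#'
#' A small three-item quality-of-life + extreme-responding model with
#' published-style parameter magnitudes, used throughout the package
#' documentation and tests: three 7-category items loading on a
#' substantive QOL trait (scoring `0..6`) and an ERS style trait
#' (scoring `1,0,0,0,0,0,1`), latent correlation -0.18, and a tiny
#' 3 x 3 demonstration grid (ERS nodes `-2, 0, 2`; QOL nodes
#' `-1, 0, 1`).  `example_item` is the middle item, whose category
#' response surface is used for single-item illustrations.
#'
#' @return List with `items`, `scoring`, `model`, `grid` (3 x 3),
#'   `example_item`, `example_scoring` (its `K x D` matrix).
#' @examples
#' ex <- worked_example()
#' round(category_prob(ex$example_item, ex$example_scoring, c(-3, 3)), 2)
#' @export
worked_example <- function() {
  S <- cbind(QOL = as.numeric(0:6), ERS = c(1, 0, 0, 0, 0, 0, 1))
  items <- list(
    mnrm_item(c(QOL = 0.80, ERS = 1.68),
              c(0, 1.84, 2.39, 3.57, 3.94, 3.64, 2.49)),
    mnrm_item(c(QOL = 0.46, ERS = 1.03),
              c(0, 1.16, 1.17, 2.56, 2.89, 2.96, 2.72)),
    mnrm_item(c(QOL = 0.49, ERS = 1.49),
              c(0, 1.50, 1.97, 2.30, 2.95, 2.65, 1.61)))
  scoring <- scoring_set(S, n_items = 3L)
  R <- matrix(c(1, -0.18, -0.18, 1), 2,
              dimnames = list(c("QOL", "ERS"), c("QOL", "ERS")))
  model <- mnrm_model(items, scoring, R)
  grid <- latent_grid(nodes = list(QOL = c(-1, 0, 1), ERS = c(-2, 0, 2)),
                      R = R)
  list(items = items, scoring = scoring, model = model, grid = grid,
       example_item = items[[2L]], example_scoring = S)
}
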