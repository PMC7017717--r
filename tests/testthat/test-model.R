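test_that("category response surface matches the published example item", {
  ex <- worked_example()
  for (i in seq_len(nrow(ref_surface_points))) {
    p <- category_prob(ex$example_item, ex$example_scoring,
                       ref_surface_points[i, ])
    expect_close(p, ref_surface[i, ], TOL2)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("zero slopes and intercepts give a uniform category distribution", {
  it <- mnrm_item(c(0, 0), rep(0, 5))
  s <- cbind(0:4, c(1, 0, 0, 0, 1))
  expect_equal(unname(category_prob(it, s, c(2.3, -1.7))), rep(1 / 5, 5))
})

test_that("probabilities are normalized and stable at extreme logits", {
  set.seed(11)
  for (rep in 1:25) {
    ri <- rand_item()
    X <- matrix(runif(40 * 2, -6, 6), 40)
    P <- category_prob(ri$item, ri$s, X)
    expect_true(all(P > 0 & P < 1))
    expect_equal(colSums(P), rep(1, 40), tolerance = 1e-12)
  }
  # |a s x + c| near 700 must not overflow
  big <- mnrm_item(100, c(0, 1))
  expect_equal(sum(category_prob(big, cbind(c(0, 7)), 1)), 1)
})

test_that("pairwise logits agree with log probability ratios", {
  ex <- worked_example()
  expect_equal(pairwise_logit(ex$example_item, ex$example_scoring, 1, 0,
                              c(0, 0)), 1.16)
  expect_equal(pairwise_logit(ex$example_item, ex$example_scoring, 3, 3,
                              c(1.2, -0.4)), 0)
  p <- category_prob(ex$example_item, ex$example_scoring, c(1, 1))
  expect_equal(pairwise_logit(ex$example_item, ex$example_scoring, 6, 0,
                              c(1, 1)),
               log(p[7] / p[1]), tolerance = 1e-10)
  set.seed(21)
  for (rep in 1:10) {
    ri <- rand_item()
    x <- runif(2, -3, 3)
    p <- category_prob(ri$item, ri$s, x)
    for (k in 0:6) for (kp in 0:6)
      expect_equal(pairwise_logit(ri$item, ri$s, k, kp, x),
                   log(p[k + 1] / p[kp + 1]), tolerance = 1e-10)
  }
  expect_error(pairwise_logit(ex$example_item, ex$example_scoring, 7, 0,
                              c(0, 0)), "out of range")
})

test_that("extreme-responding codes leave within-block comparisons style-free", {
  ex <- worked_example()
  it <- ex$example_item
  s <- ex$example_scoring
  base <- pairwise_logit(it, s, 2, 1, c(0.7, 0))
  for (xe in c(-2, 0, 3)) {
    # two non-endpoint categories: no ERS contribution
    expect_equal(pairwise_logit(it, s, 2, 1, c(0.7, xe)), base)
    # the two endpoint categories: both are extreme, ERS cancels too
    expect_equal(pairwise_logit(it, s, 6, 0, c(0.7, xe)),
                 pairwise_logit(it, s, 6, 0, c(0.7, 0)))
  }
})

test_that("pairwise logit is linear in each trait with slope a_d (s_kd - s_k'd)", {
  set.seed(31)
  ri <- rand_item()
  for (d in 1:2) {
    for (k in c(0L, 3L, 6L)) for (kp in c(1L, 5L)) {
      x0 <- c(0.4, -0.2)
      x1 <- x0; x1[d] <- x1[d] + 1
      slope <- pairwise_logit(ri$item, ri$s, k, kp, x1) -
        pairwise_logit(ri$item, ri$s, k, kp, x0)
      expect_equal(slope,
                   ri$item$a[[d]] * (ri$s[k + 1, d] - ri$s[kp + 1, d]))
    }
  }
})

test_that("responses recode through scoring vectors with NA propagation", {
  expect_equal(recode_response(6, c(1, 0, 0, 0, 0, 0, 1)), 1)
  expect_equal(recode_response(4, 0:6), 4)
  expect_equal(recode_response(3, c(0, 0, 0, 1, 0, 0, 0)), 1)
  expect_equal(recode_response(c(NA, 2), 0:6), c(NA, 2))
  expect_error(recode_response(9, 0:6), "out of range")
})

test_that("collapsed response functions sum category probabilities by code", {
  ex <- worked_example()
  g <- collapsed_prob(ex$items[[2]], ex$example_scoring, "ERS", c(0, 0))
  expect_close(g, c(0.779, 0.221), TOL3)
  g1 <- collapsed_prob(ex$items[[1]], ex$example_scoring, "ERS", c(1, 2))
  expect_close(g1[2], 0.918, TOL3)
  # one-to-one scoring collapses to the raw category probabilities
  p <- category_prob(ex$items[[1]], ex$example_scoring, c(0.5, -0.5))
  q <- collapsed_prob(ex$items[[1]], ex$example_scoring, "QOL", c(0.5, -0.5))
  expect_equal(unname(q), unname(p))
  # normalization at many random points
  set.seed(41)
  X <- matrix(runif(1000 * 2, -5, 5), 1000)
  G <- collapsed_prob(ex$items[[3]], ex$example_scoring, "ERS", X)
  expect_equal(colSums(G), rep(1, 1000), tolerance = 1e-12)
  expect_true(all(G >= 0))
})

test_that("collapsed values at the worked-example grid match at node (2, 1)", {
  # ERS node eta = 2 with QOL node xi = 1 is the last grid column
  ex <- worked_example()
  G <- collapsed_prob(ex$items[[1]], ex$example_scoring, "ERS", ex$grid$X)
  expect_close(G[2, 9], 0.918, TOL3)
})

test_that("category-slope parameterization is equivalent", {
  ex <- worked_example()
  ac <- to_category_slopes(ex$example_item, ex$example_scoring)
  expect_equal(unname(ac[, 2]),
               1.03 * c(1, 0, 0, 0, 0, 0, 1))
  # anchored-last-category convention: middle slopes become -a_ERS
  s_anch <- cbind(QOL = 0:6, ERS = c(0, -1, -1, -1, -1, -1, 0))
  ac2 <- to_category_slopes(ex$example_item, s_anch)
  expect_equal(unname(ac2[2:6, 2]), rep(-1.03, 5))
  # nominal-slope softmax reproduces the scoring-function model
  set.seed(51)
  for (rep in 1:20) {
    ri <- rand_item()
    x <- runif(2, -4, 4)
    atil <- to_category_slopes(ri$item, ri$s)
    z <- as.vector(atil %*% x) + ri$item$c
    expect_equal(unname(exp(z - max(z)) / sum(exp(z - max(z)))),
                 unname(category_prob(ri$item, ri$s, x)), tolerance = 1e-12)
  }
})

test_that("reparameterization preserves the probability surface", {
  ex <- worked_example()
  it <- ex$example_item
  # rescaling endpoint codes by 2 halves the slope
  s_pm <- cbind(QOL = 0:6, ERS = c(1, -1, -1, -1, -1, -1, 1))
  rp <- reparameterize(it, s_pm, shift = c(0, 0), scale = c(1, 2))
  expect_equal(unname(rp$item$a[2]), 1.03 / 2)
  set.seed(61)
  for (rep in 1:20) {
    x <- runif(2, -4, 4)
    expect_equal(category_prob(rp$item, rp$s, x),
                 category_prob(it, s_pm, x), tolerance = 1e-12)
  }
  # identity
  id <- reparameterize(it, ex$example_scoring)
  expect_equal(id$item$a, it$a)
  expect_equal(id$item$c, it$c)
  expect_equal(id$s, ex$example_scoring)
  # reference flip leaves the surface untouched
  set.seed(62)
  for (rep in 1:20) {
    ri <- rand_item()
    fl <- reparameterize(ri$item, ri$s, reference = "last")
    x <- runif(2, -4, 4)
    expect_equal(unname(category_prob(fl$item, fl$s, x)),
                 unname(category_prob(ri$item, ri$s, x)), tolerance = 1e-12)
  }
  expect_error(reparameterize(it, ex$example_scoring, scale = c(1, 0)),
               "nonzero")
})

test_that("redundant scoring functions are rejected at construction", {
  S_bad <- cbind(QOL = 0:6, ERS = c(1, 0, 0, 0, 0, 0, 1),
                 MID = c(0, 1, 1, 1, 1, 1, 0))
  expect_error(scoring_set(S_bad, n_items = 2), "linearly dependent")
  S_ok <- cbind(QOL = 0:6, ERS = c(1, 0, 0, 0, 0, 0, 1),
                MRS = c(0, 0, 0, 1, 0, 0, 0))
  expect_silent(sc <- scoring_set(S_ok, n_items = 2))
  expect_equal(sc$dims, c("QOL", "ERS", "MRS"))
})

test_that("model construction validates shapes and the correlation matrix", {
  S <- cbind(QOL = 0:6, ERS = scoring_template("ers", 7))
  it <- mnrm_item(c(0.5, 1), rep(0, 7))
  expect_error(mnrm_model(list(it), scoring_set(S, n_items = 2)),
               "disagree")
  expect_error(mnrm_model(list(it, it), scoring_set(S, n_items = 2),
                          matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  expect_error(mnrm_item(c(0.5, 1), c(0.2, 1, 1)), "must be 0")
})
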