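test_that("uninformative likelihoods give prior-mean EAPs with unit SD", {
  S <- cbind(trait = 0:6, ERS = scoring_template("ers", 7))
  flat <- mnrm_item(c(0, 0), rep(0, 7))
  m <- mnrm_model(list(flat, flat), scoring_set(S, n_items = 2))
  pe <- pattern_eap(m, rbind(c(2, 5)))
  expect_close(c(pe$eap_trait, pe$eap_ERS), c(0, 0), 1e-3)
  expect_close(c(pe$sd_trait, pe$sd_ERS), c(1, 1), 1e-3)
})

test_that("pattern EAPs equal a direct posterior enumeration", {
  ex <- worked_example()
  g <- latent_grid(31, -5, 5, ex$model$R)
  y <- rbind(c(0, 6, 6), c(3, 2, 4), c(6, NA, 0))
  pe <- pattern_eap(ex$model, y, g)
  for (i in 1:3) {
    # oracle: raw products of category probabilities node by node
    lik <- rep(1, nrow(g$X))
    for (j in 1:3) {
      if (is.na(y[i, j])) next
      lik <- lik * vapply(seq_len(nrow(g$X)), function(q)
        category_prob(ex$items[[j]], ex$example_scoring,
                      g$X[q, ])[y[i, j] + 1], numeric(1))
    }
    post <- lik * g$W
    post <- post / sum(post)
    for (d in 1:2) {
      mu <- sum(post * g$X[, d])
      expect_equal(pe[[paste0("eap_", ex$model$dims[d])]][i], mu,
                   tolerance = 1e-8)
      expect_equal(pe[[paste0("sd_", ex$model$dims[d])]][i],
                   sqrt(sum(post * g$X[, d]^2) - mu^2), tolerance = 1e-8)
    }
  }
})

test_that("identical patterns score identically and informative ones shrink SD", {
  ex <- worked_example()
  pe <- pattern_eap(ex$model, rbind(c(0, 6, 6), c(0, 6, 6)))
  expect_equal(pe[1, ], pe[2, ], ignore_attr = TRUE)
  expect_true(all(pe$sd_QOL < 1) && all(pe$sd_ERS < 1))
  # all-missing pattern: prior returned, flagged
  pm <- pattern_eap(ex$model, matrix(NA_integer_, 1, 3))
  expect_true(pm$all_missing)
  expect_close(c(pm$eap_QOL, pm$eap_ERS), c(0, 0), 1e-6)
  expect_close(c(pm$sd_QOL, pm$sd_ERS), c(1, 1), 1e-3)
})

test_that("summed-score likelihoods reproduce the worked recursion", {
  ex <- worked_example()
  ssl <- summed_score_likelihood(ex$model, "ERS", ex$grid)
  expect_equal(ssl$v, 0:3)
  expect_close(ssl$L, ref_final_L, TOL3)
  expect_close(ssl$L[4, 9], 0.642, TOL3)   # L3(3 | eta = 2, xi = 1)
  # intermediate two-item value L2(1 | eta = 0, xi = 0)
  m2 <- ex$model
  m2$items <- ex$items[1:2]
  m2$scoring$s <- m2$scoring$s[1:2]
  m2$scoring$n_items <- 2L
  m2$n_items <- 2L
  ssl2 <- summed_score_likelihood(m2, "ERS", ex$grid)
  expect_close(ssl2$L[2, 5], 0.268, TOL3)
  # total probability over sum scores at every node
  expect_equal(colSums(ssl$L), rep(1, 9), tolerance = 1e-10)
})

test_that("a single item's table is its collapsed response function", {
  ex <- worked_example()
  m1 <- ex$model
  m1$items <- ex$items[1]
  m1$scoring$s <- m1$scoring$s[1]
  m1$scoring$n_items <- 1L
  m1$n_items <- 1L
  ssl <- summed_score_likelihood(m1, "ERS", ex$grid)
  expect_equal(ssl$L,
               collapsed_prob(ex$items[[1]], ex$example_scoring, "ERS",
                              ex$grid$X),
               tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("the recursion equals exhaustive enumeration over all patterns", {
  ex <- worked_example()
  ssl <- summed_score_likelihood(ex$model, "ERS", ex$grid)
  pats <- as.matrix(expand.grid(0:6, 0:6, 0:6))
  sER <- ex$example_scoring[, "ERS"]
  brute <- matrix(0, 4, 9)
  for (i in seq_len(nrow(pats))) {
    v <- sum(sER[pats[i, ] + 1])
    lik <- rep(1, 9)
    for (j in 1:3)
      lik <- lik * category_prob(ex$items[[j]], ex$example_scoring,
                                 ex$grid$X)[pats[i, j] + 1, ]
    brute[v + 1, ] <- brute[v + 1, ] + lik
  }
  expect_equal(unname(ssl$L), brute, tolerance = 1e-12)
})

test_that("the recursion keys on exact non-integer sums", {
  S1 <- cbind(d = c(0, 0.5, 1), o = c(0, 1, 3))
  S2 <- cbind(d = c(0, 0.25, 1), o = c(0, 1, 3))
  sc <- scoring_set(list(S1, S2))
  it <- mnrm_item(c(0.8, 0.4), c(0, 0.3, -0.2))
  m <- mnrm_model(list(it, it), sc)
  g <- latent_grid(7, -3, 3, m$R)
  ssl <- summed_score_likelihood(m, "d", g)
  expect_equal(ssl$v, c(0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 2))
  expect_equal(colSums(ssl$L), rep(1, nrow(g$X)), tolerance = 1e-10)
})

test_that("the translation table reproduces the worked example", {
  ex <- worked_example()
  tab <- translation_table(ex$model, "ERS", ex$grid)
  expect_close(tab$p, ref_table$p, TOL3)
  expect_close(tab$eap, ref_table$eap, TOL3)
  expect_close(tab$var, ref_table$var, TOL3)
  expect_close(attr(tab, "kernel"), ref_kernel, TOL3)
  expect_equal(sum(tab$p), 1, tolerance = 1e-6)
  # law of total expectation: E over sum scores recovers the prior mean
  expect_close(sum(tab$p * tab$eap), 0, 1e-2)
})

test_that("a style-blind model yields flat sum-score EAPs", {
  S <- cbind(trait = 0:6, ERS = scoring_template("ers", 7))
  sc <- scoring_set(S, n_items = 3)
  items <- lapply(1:3, function(j)
    mnrm_item(c(0.8, 0), c(0, 1, 1.5, 2, 1.8, 1.2, 0.5)))
  m <- mnrm_model(items, sc)
  tab <- translation_table(m, "ERS", latent_grid(21, -5, 5, m$R))
  expect_close(tab$eap, rep(0, 4), 1e-6)
})

test_that("sum-score lookup is deterministic and rejects unattainable scores", {
  ex <- worked_example()
  tab <- translation_table(ex$model, "ERS", ex$grid)
  got <- score_by_sum(tab, c(2, 2))
  expect_equal(got$eap[1], got$eap[2])
  expect_close(got$eap[1], 0.829, TOL3)
  expect_error(score_by_sum(tab, 4), "unattainable")
  expect_error(score_by_sum(tab, -1), "unattainable")
})

test_that("score comparison relates the three scoring routes coherently", {
  d <- style_design(N = 250, n_items = 12, seed = 211)
  b <- make_style_study(d)
  cmp <- compare_scores(b$model, b$responses,
                        latent_grid(21, -5, 5, b$model$R))
  sp <- cmp$spearman
  expect_equal(sp, t(sp))
  expect_equal(unname(diag(sp)), rep(1, ncol(sp)))
  expect_true(all(is.finite(cmp$pearson)))
  # translation is a monotone lookup: sum score and sum-score EAP agree in rank
  expect_equal(unname(sp["v_trait", "ss_eap_trait"]), 1)
  expect_equal(unname(sp["v_ERS", "ss_eap_ERS"]), 1)
})

test_that("equal-slope unidimensional fits rank-agree with sum scores", {
  # under the partial-credit constraint the sum score is sufficient, so
  # pattern EAPs must be a monotone function of it
  d <- style_design(N = 500, n_items = 8, K = 5,
                    dims = c(trait = "trait"), seed = 213)
  b <- make_style_study(d)
  fit <- fit_mnrm(b$responses, b$scoring, equal_slopes = TRUE, tol = 1e-6)
  pe <- pattern_eap(fit$model, b$responses)
  ss <- sum_scores(b$responses, b$scoring, "trait")
  # round away sub-1e-10 floating jitter so ties are exact before ranking
  expect_equal(cor(round(pe$eap_trait, 10), ss$v_trait,
                   method = "spearman"), 1)
})
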