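# toy generator for engine tests: g groups with kinship-structured effects
toy_mixed_data <- function(n_lev = 6, reps = 3, s2_g = 2, s2_e = 1,
                           seed = 1, structured = FALSE) {
  set.seed(seed)
  lev <- paste0("g", seq_len(n_lev))
  if (structured) {
    z <- matrix(rnorm(n_lev * 20), n_lev, dimnames = list(lev, NULL))
    K <- tcrossprod(scale(z, scale = FALSE)) / 20
  } else {
    K <- diag(n_lev)
    dimnames(K) <- list(lev, lev)
  }
  u <- drop(chol(K + 1e-8 * diag(n_lev)) %*% rnorm(n_lev)) * sqrt(s2_g)
  d <- data.frame(grp = rep(lev, each = reps))
  d$value <- 5 + u[d$grp] + rnorm(nrow(d), 0, sqrt(s2_e))
  list(data = d, K = K, levels = lev)
}

test_that("single identity-kernel REML matches the closed-form one-way ANOVA estimators", {
  for (case in list(c(6, 4, 2, 1), c(10, 3, 0.5, 2), c(5, 6, 4, 0.5))) {
    toy <- toy_mixed_data(case[1], case[2], case[3], case[4],
                          seed = sum(case))
    fit <- reml_fit(toy$data,
                    list(random_term("grp", "grp", levels = toy$levels)))
    aovt <- anova(lm(value ~ grp, toy$data))
    msb <- aovt["grp", "Mean Sq"]; msw <- aovt["Residuals", "Mean Sq"]
    expect_equal(unname(fit$sigma2["grp"]), max(0, (msb - msw) / case[2]),
                 tolerance = 1e-6)
    expect_equal(unname(fit$sigma2["residual"]), msw, tolerance = 1e-6)
  }
})

test_that("engine restricted log-likelihood beats a grid oracle on random toys", {
  set.seed(99)
  for (i in 1:6) {
    n_kernel <- sample(1:2, 1)
    toy <- toy_mixed_data(n_lev = 8, reps = 3, s2_g = runif(1, 0.5, 3),
                          s2_e = runif(1, 0.5, 2), seed = i,
                          structured = n_kernel > 1)
    terms <- list(random_term("grp", "grp",
                              kinship = hybridgs:::new_kinship(toy$K, "t"),
                              levels = toy$levels))
    fit <- reml_fit(toy$data, terms)
    G <- list(term_G(terms[[1]], toy$data))
    vy <- var(toy$data$value)
    grid <- exp(seq(log(vy / 50), log(vy * 5), length.out = 12))
    best <- -Inf
    for (a in grid) for (b in grid)
      best <- max(best, reml_loglik_oracle(toy$data$value, G, c(a, b)))
    expect_gte(fit$loglik, best - 1e-6)
    # and the engine's value agrees with the oracle formula at its optimum
    expect_equal(fit$loglik,
                 reml_loglik_oracle(toy$data$value, G,
                                    pmax(fit$sigma2, 1e-12)),
                 tolerance = 1e-6)
  }
})

test_that("permuted response against a structured kinship drives the genetic variance to the boundary", {
  set.seed(7)
  p <- random_panels(12, 12, 80, seed = 2)
  kf <- additive_kinship(center_transmitted(p$females))
  # under the null the REML estimate is the classic half-mixture: an atom
  # at the zero boundary (about half the replicates) plus small positive
  # values; check both the atom and the smallness of the rest
  at_boundary <- 0
  small <- 0
  n_rep <- 20
  for (i in seq_len(n_rep)) {
    y <- rnorm(12 * 4)  # pure noise, no genetic signal
    d <- data.frame(value = y,
                    female_id = sample(rep(parent_ids(p$females), 4)))
    fit <- reml_fit(d, list(random_term("female", "female_id", kf)))
    if (fit$boundary["female"]) at_boundary <- at_boundary + 1
    if (fit$sigma2["female"] < 0.1 * var(y)) small <- small + 1
  }
  expect_gte(at_boundary, 0.2 * n_rep)
  expect_gte(small, 0.5 * n_rep)
})

test_that("kernel scaling rescales components but leaves likelihood, BLUPs and z-ratios unchanged", {
  toy <- toy_mixed_data(8, 3, 2, 1, seed = 5, structured = TRUE)
  k1 <- hybridgs:::new_kinship(toy$K, "t")
  k5 <- hybridgs:::new_kinship(5 * toy$K, "t")
  f1 <- reml_fit(toy$data, list(random_term("grp", "grp", k1)))
  f5 <- reml_fit(toy$data, list(random_term("grp", "grp", k5)))
  expect_equal(f5$sigma2[["grp"]], f1$sigma2[["grp"]] / 5, tolerance = 1e-5)
  expect_equal(f5$loglik, f1$loglik, tolerance = 1e-6)
  expect_equal(f5$blup$grp, f1$blup$grp, tolerance = 1e-5)
  expect_equal(zratio(f5, "grp"), zratio(f1, "grp"), tolerance = 1e-4)
  crosses <- tibble::tibble(hybrid_id = toy$levels, female_id = toy$levels,
                            male_id = toy$levels)
  # prediction path: mu + blup identical under rescaling
  expect_equal(f5$mu + f5$blup$grp, f1$mu + f1$blup$grp, tolerance = 1e-5)
})

test_that("predictions equal the explicit multivariate-normal conditional formula on a toy", {
  p <- random_panels(4, 4, 30, seed = 8)
  des <- tidyr::expand_grid(female_id = parent_ids(p$females)[1:3],
                            male_id = parent_ids(p$males)[1:3]) |>
    dplyr::mutate(hybrid_id = paste0(female_id, "x", male_id))
  set.seed(8)
  d <- data.frame(des[sample(nrow(des), 8), ])
  d$value <- rnorm(8, 45, 2)
  kf <- additive_kinship(center_transmitted(p$females))
  km <- additive_kinship(center_transmitted(p$males))
  fit <- reml_fit(d, assemble_model("FM", list(kf = kf, km = km)))
  all_crosses <- tidyr::expand_grid(female_id = parent_ids(p$females),
                                    male_id = parent_ids(p$males)) |>
    dplyr::mutate(hybrid_id = paste0(female_id, "x", male_id))
  pred <- predict_hybrids(fit, all_crosses)
  # oracle: mu + sum_k s2_k K_k[new, obs] V^-1 (y - mu), via solve()
  Gf <- unclass(kf)[d$female_id, d$female_id]
  Gm <- unclass(km)[d$male_id, d$male_id]
  V <- fit$sigma2[["female"]] * Gf + fit$sigma2[["male"]] * Gm +
    fit$sigma2[["residual"]] * diag(8)
  Vi <- solve(V)
  mu <- drop(solve(t(rep(1, 8)) %*% Vi %*% rep(1, 8)) %*%
               t(rep(1, 8)) %*% Vi %*% d$value)
  r <- d$value - mu
  pf <- fit$sigma2[["female"]] *
    unclass(kf)[all_crosses$female_id, d$female_id] %*% Vi %*% r
  pm <- fit$sigma2[["male"]] *
    unclass(km)[all_crosses$male_id, d$male_id] %*% Vi %*% r
  expect_equal(pred$predicted, unname(drop(mu + pf + pm)), tolerance = 1e-8)
})

test_that("GBLUP predictions equal RR-BLUP ridge predictions with matched penalty", {
  p <- random_panels(8, 8, 60, seed = 12)
  xf <- center_transmitted(p$females)
  kf <- additive_kinship(xf, scale = 1)
  set.seed(12)
  d <- data.frame(female_id = rep(parent_ids(p$females), 2))
  d$value <- rnorm(16, 45, 2)
  fit <- reml_fit(d, list(random_term("female", "female_id", kf)))
  # marker-space oracle at the fitted variances: a = s2 M' Z' V^-1 (y - mu)
  M <- xf$values
  W <- M[d$female_id, ]
  V <- fit$sigma2[["female"]] * tcrossprod(W) +
    fit$sigma2[["residual"]] * diag(nrow(d))
  Vi <- solve(V)
  one <- rep(1, nrow(d))
  mu <- drop((t(one) %*% Vi %*% d$value) / (t(one) %*% Vi %*% one))
  a_hat <- fit$sigma2[["female"]] * t(W) %*% Vi %*% (d$value - mu)
  pred_rr <- mu + drop(M %*% a_hat)
  pred_gb <- fit$mu + fit$blup$female[parent_ids(p$females)]
  expect_equal(unname(pred_gb), unname(pred_rr), tolerance = 1e-8)
})

test_that("boundary components are reported as zero and flagged in z-ratios", {
  toy <- toy_mixed_data(8, 3, 0, 1, seed = 21)  # no genetic variance
  fit <- reml_fit(toy$data,
                  list(random_term("grp", "grp", levels = toy$levels)))
  if (fit$boundary["grp"]) {
    expect_identical(fit$sigma2[["grp"]], 0)
    expect_warning(z <- zratio(fit, "grp"), "boundary")
    expect_true(is.na(z))
  }
  expect_error(zratio(fit, "nope"), "unknown term")
})

test_that("simulated strong effects give z-ratios above 2 in most replicates", {
  set.seed(31)
  hits <- 0
  for (i in 1:10) {
    toy <- toy_mixed_data(15, 4, 4, 0.5, seed = 100 + i)
    fit <- reml_fit(toy$data,
                    list(random_term("grp", "grp", levels = toy$levels)))
    z <- suppressWarnings(zratio(fit, "grp"))
    if (!is.na(z) && z > 2) hits <- hits + 1
  }
  expect_gte(hits, 7)
})

test_that("non-PSD kernels and degenerate inputs are rejected", {
  bad <- matrix(c(1, 2, 2, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  d <- data.frame(value = rnorm(6), grp = rep(c("a", "b"), 3))
  expect_error(
    reml_fit(d, list(random_term("grp", "grp",
                                 kinship = structure(bad, class = c("kinship_matrix", "matrix", "array"))))),
    "positive semi-definite")
  expect_error(reml_fit(d[1:2, ], list(random_term("grp", "grp",
                                                   levels = c("a", "b")))),
               "too few")
})
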