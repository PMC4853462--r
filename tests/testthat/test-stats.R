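test_that("the ROC grids reproduce the published sweep steps", {
  rg <- emm_roc_ranges()
  g <- roc_grid(tibble::tibble(pred = runif(50, 0, 25), ref = runif(50, 0, 100)),
                pred_range = rg$uv, ref_range = rg$it)
  expect_length(g$ref_cutoffs, 40)
  expect_length(g$pred_thresholds, 40)
  expect_equal(unique(diff(g$ref_cutoffs)), 2.5)
  expect_equal(unique(diff(g$pred_thresholds)), 25 / 40)
  for (nm in c("bv", "lls", "wt")) {
    gp <- roc_grid(tibble::tibble(pred = runif(50, rg[[nm]][1], rg[[nm]][2]),
                                  ref = runif(50, 0, 100)),
                   pred_range = rg[[nm]], ref_range = rg$it)
    expect_lt(max(abs(diff(gp$pred_thresholds) -
                        c(bv = 0.3, lls = 2, wt = 0.5)[[nm]])), 1e-12)
  }
})

test_that("perfectly separated data yield AUC 1 with a perfect operating point", {
  set.seed(31)
  ref <- runif(400, 0, 100)
  pred <- ifelse(ref >= 50, 1, 10)
  g <- roc_grid(tibble::tibble(pred = pred, ref = ref),
                pred_range = c(0, 25), ref_range = c(0, 100))
  expect_equal(g$auc[g$ref_cutoffs == 50], 1)
  expect_equal(g$best$auc, 1)
  expect_equal(g$best$sens, 1)
  expect_equal(g$best$spec, 1)
})

test_that("sensitivity and specificity are monotone along the threshold axis", {
  set.seed(32)
  g <- roc_grid(tibble::tibble(pred = rnorm(300, 10, 4), ref = runif(300, 0, 100)),
                pred_range = c(0, 25), ref_range = c(0, 100))
  for (r in which(!is.na(g$auc))) {
    expect_true(all(diff(g$sens[r, ]) >= 0))
    expect_true(all(diff(g$spec[r, ]) <= 0))
  }
})

test_that("per-cutoff AUC matches the pairwise-concordance oracle within 0.02", {
  set.seed(33)
  n <- 200
  ref <- runif(n, 0, 100)
  pred <- 20 - 0.15 * ref + rnorm(n, 0, 3)
  g <- roc_grid(tibble::tibble(pred = pred, ref = ref),
                pred_range = c(0, 25), ref_range = c(0, 100))
  for (r in seq_along(g$ref_cutoffs)) {
    oracle <- concordance_auc(pred, ref, g$ref_cutoffs[r])
    if (is.na(oracle)) next
    expect_lt(abs(g$auc[r] - oracle), 0.02)
  }
})

test_that("AUC is invariant under monotone transforms up to grid discretization", {
  set.seed(34)
  n <- 300
  ref <- runif(n, 0, 100)
  pred <- 15 - 0.1 * ref + rnorm(n, 0, 2)
  g1 <- roc_grid(tibble::tibble(pred = pred, ref = ref),
                 pred_range = range(pred), ref_range = c(0, 100))
  pred2 <- exp(pred / 5)  # strictly increasing transform
  g2 <- roc_grid(tibble::tibble(pred = pred2, ref = ref),
                 pred_range = range(pred2), ref_range = c(0, 100))
  ok <- !is.na(g1$auc) & !is.na(g2$auc)
  expect_lt(max(abs(g1$auc[ok] - g2$auc[ok])), 0.02)
})

test_that("label-permuted data give chance-level best AUC", {
  set.seed(17)
  n <- 2000
  ref <- runif(n, 0, 100)
  pred <- runif(n, 0, 25)  # independent of ref
  g <- roc_grid(tibble::tibble(pred = pred, ref = ref),
                pred_range = c(0, 25), ref_range = c(0, 100))
  expect_lt(abs(g$best$auc - 0.5), 0.05)
})

test_that("point-to-reference pairing picks the closest vertex channel value", {
  ph <- generate_phantom(phantom_spec(n_slices = 8, seed = 8))
  mesh <- ph$mesh
  nv <- nrow(mesh$vertices)
  mesh$channels$it <- rep(40, nv)
  v <- mesh$vertices[123, ]
  emm <- tibble::tibble(id = 1:3,
                        x = c(v[1], v[1], 0), y = c(v[2], v[2], 0),
                        z = c(v[3], v[3], -30),
                        uv = c(9, 8, 7), bv = 1, lls = 2,
                        included = c(TRUE, TRUE, FALSE))
  pairs <- pair_points_with_reference(emm, mesh, "it")
  expect_equal(nrow(pairs), 2)  # excluded point dropped
  expect_true(all(pairs$ref == 40))

  # conservation: kept + dropped = included
  mesh$channels$it[seq_len(nv)] <- NA_real_
  mesh$channels$it[123] <- 40
  pairs2 <- pair_points_with_reference(emm, mesh, "it")
  expect_equal(nrow(pairs2) + attr(pairs2, "n_dropped"), 2)

  emm$included <- FALSE
  expect_error(pair_points_with_reference(emm, mesh, "it"),
               class = "emmfuse_validation_error")
})

test_that("mixed-model R2 recovers the generative variance fraction", {
  r2s <- vapply(1:20, function(s) {
    mixed_model_r2(simulate_hierarchical(s), "it", "uv")$r2
  }, numeric(1))
  # generative fraction: var explained / total = 5 / (16 + 4 + 5) = 0.2
  expect_lt(abs(mean(r2s) - 0.2), 0.04)
})

test_that("a constant covariate explains nothing", {
  d <- simulate_hierarchical(99)
  d$uv <- 0
  r2 <- mixed_model_r2(d, "it", "uv")
  expect_lt(abs(r2$r2), 0.01)
})

test_that("variance components match a direct likelihood-maximization oracle", {
  set.seed(41)
  d <- simulate_hierarchical(7, n_groups = 3, n_per = 25, tau00 = 6, sigma2 = 9)
  fit <- mixed_model_r2(d, "it", "uv")

  # oracle: profile the exact Gaussian ML over (log tau00, log sigma2) with
  # GLS fixed effects, via a direct 2-D optimization (independent of lme4)
  ml_oracle <- function(data, covariate) {
    X <- if (is.null(covariate)) matrix(1, nrow(data), 1) else cbind(1, data[[covariate]])
    y <- data$it
    groups <- split(seq_len(nrow(data)), data$animal)
    negll <- function(par) {
      tau <- exp(par[1]); s2 <- exp(par[2])
      XtVX <- 0; XtVy <- 0; ll_const <- 0
      for (ix in groups) {
        n <- length(ix)
        V <- s2 * diag(n) + tau
        Vi <- solve(V)
        XtVX <- XtVX + t(X[ix, , drop = FALSE]) %*% Vi %*% X[ix, , drop = FALSE]
        XtVy <- XtVy + t(X[ix, , drop = FALSE]) %*% Vi %*% y[ix]
        ll_const <- ll_const + determinant(V)$modulus
      }
      b <- solve(XtVX, XtVy)
      quad <- 0
      for (ix in groups) {
        n <- length(ix)
        V <- s2 * diag(n) + tau
        r <- y[ix] - X[ix, , drop = FALSE] %*% b
        quad <- quad + t(r) %*% solve(V, r)
      }
      0.5 * (ll_const + quad + nrow(data) * log(2 * pi))
    }
    o <- optim(c(log(5), log(10)), negll, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
    c(tau00 = exp(o$par[1]), sigma2 = exp(o$par[2]))
  }
  oracle_null <- ml_oracle(d, NULL)
  oracle_full <- ml_oracle(d, "uv")
  expect_equal(fit$tau00_null, unname(oracle_null["tau00"]), tolerance = 1e-3)
  expect_equal(fit$sigma2_null, unname(oracle_null["sigma2"]), tolerance = 1e-3)
  expect_equal(fit$tau00_full, unname(oracle_full["tau00"]), tolerance = 1e-3)
  expect_equal(fit$sigma2_full, unname(oracle_full["sigma2"]), tolerance = 1e-3)
})

test_that("R2 grows weakly with the true fixed-effect size", {
  betas <- seq(0, 1, by = 0.125)
  r2s <- vapply(betas, function(b) {
    mean(vapply(1:5, function(s) {
      mixed_model_r2(simulate_hierarchical(1000 + s, n_groups = 8, n_per = 40,
                                           beta = b), "it", "uv")$r2
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(betas, r2s, method = "spearman"), 0.9)
})

test_that("mixed-model preconditions are enforced", {
  d <- simulate_hierarchical(5, n_groups = 2, n_per = 10)
  expect_error(mixed_model_r2(d, "it", "uv"), "3 groups",
               class = "emmfuse_validation_error")
  d1 <- simulate_hierarchical(5, n_groups = 4, n_per = 5)
  d1 <- d1[-(1:4), ]  # leave group 1 with a single row
  expect_error(mixed_model_r2(d1, "it", "uv"), class = "emmfuse_validation_error")
  expect_error(mixed_model_r2(d, "it", "nope"), class = "emmfuse_format_error")
})
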