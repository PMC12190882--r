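test_that("class averages equal the element-wise mean of the class trials", {
  set.seed(10)
  trials <- replicate(6, matrix(rnorm(3 * 40), 3, 40), simplify = FALSE)
  ts <- structure(list(trials = trials, labels = rep(1L, 6), fs = 600,
                       montage = montage_reduced6(), n_samples = 40),
                  class = "trial_set")
  oracle <- Reduce(`+`, trials) / 6
  expect_equal(average_trials(ts, 1), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
  # identical trials average to any one of them; a and -a cancel
  ts$trials <- rep(trials[1], 6)
  expect_equal(average_trials(ts, 1), trials[[1]], ignore_attr = TRUE)
  ts$trials <- list(trials[[1]], -trials[[1]])
  ts$labels <- c(1L, 1L)
  expect_equal(average_trials(ts, 1), matrix(0, 3, 40), ignore_attr = TRUE)
  expect_error(average_trials(ts, 3), "no trials")
  ts$trials[[2]] <- matrix(0, 3, 39)
  expect_error(average_trials(ts, 1), "shape")
})

test_that("templates stack identical binary rows", {
  tl <- codes2[[2]]
  tmpl <- build_template(tl, 16)
  expect_equal(dim(tmpl), c(16L, 1260L))
  expect_true(all(tmpl %in% c(0, 1)))
  expect_true(all(apply(tmpl, 2, function(col) length(unique(col)) == 1)))
  expect_error(build_template(tl, 0), "m")
})

test_that("1-D canonical correlation reduces to the Pearson correlation", {
  set.seed(20)
  x <- matrix(rnorm(100), 1)
  y <- matrix(0.6 * x + 0.4 * rnorm(100), 1)
  cc <- canonical_correlation(x, y)
  expect_equal(cc$rho, abs(cor(x[1, ], y[1, ])), tolerance = 1e-9)
})

test_that("CCA is invariant to invertible channel mixing", {
  set.seed(21)
  X <- matrix(rnorm(4 * 300), 4)
  M <- matrix(rnorm(16), 4) + diag(4)
  cc <- canonical_correlation(X, M %*% X)
  expect_equal(cc$rho, 1, tolerance = 1e-9)
})

test_that("CCA matches a brute-force correlation maximizer", {
  # direct optimization over weight pairs, independent of the eigen solver
  brute_rho <- function(X, Y, restarts = 8) {
    obj <- function(par) {
      wx <- par[1:nrow(X)]; wy <- par[-(1:nrow(X))]
      px <- drop(crossprod(wx, X)); py <- drop(crossprod(wy, Y))
      if (sd(px) == 0 || sd(py) == 0) return(0)
      -abs(cor(px, py))
    }
    best <- -Inf
    for (r in seq_len(restarts)) {
      set.seed(r)
      fit <- optim(rnorm(nrow(X) + nrow(Y)), obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
      best <- max(best, -fit$value)
    }
    best
  }
  for (case_seed in c(31, 32, 33)) {
    set.seed(case_seed)
    X <- matrix(rnorm(3 * 200), 3)
    Y <- matrix(rnorm(3 * 200), 3)
    expect_equal(canonical_correlation(X, Y)$rho, brute_rho(X, Y),
                 tolerance = 1e-6)
  }
})

test_that("CCA agrees with the classical solver on full-rank data", {
  set.seed(40)
  X <- matrix(rnorm(5 * 400), 5)
  Y <- matrix(rnorm(5 * 400), 5) + 0.5 * X
  ref <- stats::cancor(t(X), t(Y))$cor[1]
  expect_equal(canonical_correlation(X, Y, ridge = 1e-12)$rho, ref,
               tolerance = 1e-6)
})

test_that("CCA is scale invariant and bounded", {
  set.seed(41)
  X <- matrix(rnorm(3 * 150), 3)
  Y <- matrix(rnorm(3 * 150), 3)
  r1 <- canonical_correlation(X, Y)$rho
  expect_equal(canonical_correlation(37.5 * X, Y)$rho, r1, tolerance = 1e-12)
  expect_lte(r1, 1 + 1e-9)
  expect_error(canonical_correlation(matrix(1, 2, 50), Y[1:2, 1:50]),
               "X \\(EEG\\) side")
  expect_error(canonical_correlation(X[, 1:50], matrix(2, 3, 50)),
               "template.* side")
})

test_that("the rank-one template side still yields the code projection", {
  subj <- sample_subject(91L, focus_target = 0.8)
  xbar <- simulate_epoch(subj, codes2[[1]], noise_scale = 0)$data
  tmpl <- build_template(codes2[[1]], 16)
  cc <- canonical_correlation(xbar, tmpl)
  proj <- drop(crossprod(cc$w_y, tmpl))
  expect_equal(abs(cor(proj, codes2[[1]]$values)), 1, tolerance = 1e-9)
  # spatial filtering cannot do worse than the best single channel
  oz_r <- abs(cor(xbar["Oz", ], codes2[[1]]$values))
  expect_gte(cc$rho + 1e-9, oz_r)
})

test_that("training yields one filter pair per class", {
  fx <- trained_fixture()
  expect_length(fx$filters$filters, 4)
  rhos <- vapply(fx$filters$filters, `[[`, numeric(1), "rho")
  expect_true(all(rhos >= 0 & rhos <= 1))
})

test_that("an impulse-response subject trains to near-perfect correlation", {
  subj <- sample_subject(92L, focus_target = 0.6, kernel = impulse_kernel,
                         latency_range = c(0, 0))
  ts <- with_seed(5L, simulate_training_session(subj, codes2,
                                                noise_scale = 0))
  f <- train_classifier(ts, codes2)
  for (fl in f$filters) expect_gte(fl$rho, 0.99)
})

test_that("the default oscillatory kernel trains well above cross-class level", {
  subj <- sample_subject(93L, focus_target = 0.6)
  ts <- with_seed(6L, simulate_training_session(subj, codes2,
                                                noise_scale = 0))
  f <- train_classifier(ts, codes2)
  for (k in 1:4) {
    fl <- f$filters[[k]]
    expect_gte(fl$rho, 0.4)
    px <- drop(crossprod(fl$w_x, average_trials(ts, k)))
    cross <- vapply(setdiff(1:4, k), function(j)
      abs(cor(px, codes2[[j]]$values)), numeric(1))
    expect_gt(fl$rho, 4 * max(cross))
  }
})

test_that("training is equivariant to channel permutation", {
  subj <- sample_subject(94L, focus_target = 0.6)
  ts <- with_seed(7L, simulate_training_session(subj, codes2))
  f <- train_classifier(ts, codes2)
  perm <- with_seed(8L, sample.int(16))
  tsp <- ts
  tsp$trials <- lapply(ts$trials, function(m) m[perm, ])
  fp <- train_classifier(tsp, codes2)
  for (k in 1:4) {
    expect_equal(fp$filters[[k]]$rho, f$filters[[k]]$rho, tolerance = 1e-9)
    # same filter up to the permutation and a global sign
    wa <- f$filters[[k]]$w_x[perm]
    wb <- fp$filters[[k]]$w_x
    expect_equal(abs(sum(wa * wb)), 1, tolerance = 1e-9)
  }
  expect_error(train_classifier(structure(list(trials = ts$trials[1:2],
                                               labels = c(1L, 1L),
                                               fs = 600,
                                               montage = ts$montage,
                                               n_samples = 1260),
                                          class = "trial_set"),
                                codes2),
               "missing training trials")
})

test_that("filters round-trip through JSON", {
  fx <- trained_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_filters_json(fx$filters, path)
  back <- read_filters_json(path)
  expect_identical(back$montage$names, fx$filters$montage$names)
  expect_equal(back$filters, fx$filters$filters, tolerance = 1e-12)
})
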