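# The five-feature logistic filter: featurization, prediction, MLE fitting,
# and stream filtering.

asg_row <- function(pid_bh = 90, e_bh = -10, pid_nlh = 45, e_nlh = -2,
                    lineage = "L1", subj = "t1|p1") {
  data.frame(query_id = "q", bh_subject = subj, bh_lineage = lineage,
             bh_supergroup = "S", bh_pident = pid_bh, bh_log10e = e_bh,
             bh_bitscore = 50,
             nlh_subject = if (is.na(pid_nlh)) NA_character_ else "t2|p1",
             nlh_lineage = if (is.na(pid_nlh)) NA_character_ else "L2",
             nlh_pident = pid_nlh, nlh_log10e = e_nlh,
             n_hits_seen = 2L, stringsAsFactors = FALSE)
}

test_that("featurize evaluates the five feature definitions", {
  sizes <- c(L1 = 1000)
  x <- featurize(asg_row(), sizes)
  expect_equal(unlist(x[1, 1:5], use.names = FALSE),
               c(90, 2.0, -10, 8, 1000))
  expect_false(x$nlh_imputed)
  # tied hits: ratio 1, difference 0
  xt <- featurize(asg_row(pid_nlh = 90, e_nlh = -10), sizes)
  expect_equal(xt$x2, 1); expect_equal(xt$x4, 0)
  # NLH absent: pseudo-NLH at the search cutoff and pid floor
  xi <- featurize(asg_row(pid_nlh = NA, e_nlh = NA), sizes,
                  impute = impute_policy(log10_evalue_cutoff = 5,
                                         pid_floor = 20))
  expect_true(xi$nlh_imputed)
  expect_equal(xi$x4, 5 - (-10))
  expect_equal(xi$x2, 90 / 20)
  expect_error(featurize(asg_row(lineage = "L9"), sizes), "L9")
})

test_that("predict is the stable logistic of the linear predictor", {
  m0 <- filter_model(0, rep(0, 5))
  expect_equal(predict(m0, data.frame(x1 = 1, x2 = 2, x3 = 3, x4 = 4, x5 = 5)),
               0.5)
  # hand-evaluated closed form: logistic(1 + .9 + 2 + 1 + 1.6) = logistic(6.5)
  m <- filter_model(1, c(0.01, 1, -0.1, 0.2, 0))
  p <- predict(m, data.frame(x1 = 90, x2 = 2, x3 = -10, x4 = 8, x5 = 1000))
  expect_equal(p, plogis(6.5))
  expect_equal(round(p, 5), 0.99850)
  # monotone saturation in x4 with positive weight
  m4 <- filter_model(0, c(0, 0, 0, 1, 0))
  xs <- data.frame(x1 = 0, x2 = 0, x3 = 0, x4 = c(0, 5, 50, 800), x5 = 0)
  ps <- predict(m4, xs)
  expect_equal(ps[1], 0.5)
  expect_true(all(diff(ps) >= 0))
  expect_equal(ps[4], 1)  # saturates but stays finite/defined
  expect_error(predict(m, data.frame(x1 = NA, x2 = 1, x3 = 1, x4 = 1, x5 = 1)),
               "NA")
})

test_that("predict is monotone in each feature according to the sign of beta", {
  set.seed(12)
  m <- filter_model(0.3, c(0.02, 0.7, -0.08, 0.25, -1e-7))
  base <- data.frame(x1 = 70, x2 = 1.5, x3 = -8, x4 = 3, x5 = 5e5)
  for (k in 1:5) {
    grid <- base[rep(1, 25), ]
    grid[[k]] <- sort(runif(25, -10, 10)) * abs(base[[k]]) / 5 + base[[k]]
    ps <- predict(m, grid)
    if (m$betas[k] > 0) expect_true(all(diff(ps) >= 0))
    else expect_true(all(diff(ps) <= 0))
  }
})

test_that("fit_filter recovers generating coefficients and is invariant to duplication/order", {
  beta <- c(-4, 0.03, 0.5, -0.05, 0.3, -2e-7)
  d <- make_feature_data(beta, n = 5000, seed = 42)
  m <- fit_filter(d)
  est <- c(m$beta0, unname(m$betas))
  expect_true(all(abs(est - beta) <= 3 * m$se),
              info = paste(round(est, 4), collapse = ", "))
  # doubling every row leaves the MLE unchanged
  m2 <- fit_filter(rbind(d, d))
  expect_equal(c(m2$beta0, unname(m2$betas)), est, tolerance = 1e-6)
  # shuffling rows leaves the fit unchanged (sorted internally)
  m3 <- fit_filter(d[sample(nrow(d)), ])
  expect_equal(c(m3$beta0, unname(m3$betas)), est, tolerance = 1e-10)
})

test_that("fit_filter: null data gives null slopes; degenerate inputs error", {
  d <- make_feature_data(c(0, 0, 0, 0, 0, 0), n = 4000, seed = 43)
  m <- fit_filter(d)
  expect_true(all(abs(unname(m$betas)) <= 3 * m$se[-1]))
  expect_error(fit_filter(d[d$y == 1, ]), "single-class")
  expect_error(fit_filter(d[1:20, ]), "at least 50")
})

test_that("fit_filter falls back to ridge under complete separation", {
  set.seed(13)
  n <- 200
  d <- data.frame(x1 = runif(n, 30, 100), x2 = 1 + rexp(n),
                  x3 = runif(n, -50, 5), x4 = rexp(n, 0.2),
                  x5 = runif(n, 1e4, 1e7))
  d$y <- as.integer(d$x4 > median(d$x4))  # perfectly separable in x4
  expect_warning(m <- fit_filter(d), "separation")
  expect_s3_class(m, "filter_model")
  expect_true(all(is.finite(c(m$beta0, m$betas))))
  # the separating feature dominates and predictions are near-perfect
  p <- predict(m, d)
  expect_gt(mean((p > 0.5) == (d$y == 1)), 0.99)
})

test_that("apply_filter conserves reads and honors cutoff boundaries", {
  set.seed(14)
  sizes <- c(L1 = 1000, L2 = 2000)
  rows <- do.call(rbind, lapply(1:50, function(i)
    asg_row(pid_bh = runif(1, 40, 100), e_bh = runif(1, -30, 2),
            pid_nlh = runif(1, 30, 90), e_nlh = runif(1, -5, 5),
            lineage = sample(c("L1", "L2"), 1))))
  rows$query_id <- sprintf("q%02d", 1:50)
  rows$nlh_log10e <- pmax(rows$nlh_log10e, rows$bh_log10e)
  # a few reads without any hit
  nohit <- rows[rep(NA_integer_, 5), ]
  nohit$query_id <- sprintf("n%02d", 1:5)
  all_rows <- rbind(rows, nohit)
  model <- filter_model(-1, c(0.02, 0.3, -0.05, 0.2, -1e-7), cutoff = 0.58)

  out <- apply_filter(all_rows, model, sizes)
  expect_equal(sum(table(out$status)), nrow(all_rows))   # conservation
  expect_equal(sum(out$status == "unclassified"), 5L)
  # per-read oracle: status determined by the probability alone
  feats <- featurize(rows, sizes)
  p <- predict(model, feats)
  expect_equal(out$status[1:50], ifelse(p >= 0.58, "assigned", "filtered"))
  expect_equal(out$p[1:50], p)
  # cutoff 1.0 filters every read with a BH; cutoff 0.0 assigns all
  out1 <- apply_filter(all_rows, model, sizes, cutoff = 1.0)
  expect_equal(sum(out1$status == "assigned"), 0L)
  out0 <- apply_filter(all_rows, model, sizes, cutoff = 0.0)
  expect_equal(sum(out0$status == "assigned"), 50L)
})

test_that("tied BH/NLH is never favored over real separation", {
  sizes <- c(L1 = 1000)
  m <- filter_model(0, c(0.01, 0.8, -0.05, 0.3, 1e-8))  # beta2, beta4 > 0
  tied <- featurize(asg_row(pid_nlh = 90, e_nlh = -10), sizes)
  for (sep in c(0.5, 2, 10)) {
    apart <- featurize(asg_row(pid_nlh = 90 / (1 + sep / 10),
                               e_nlh = -10 + sep), sizes)
    expect_lt(predict(m, tied), predict(m, apart))
  }
})

test_that("filter model JSON round-trips", {
  m <- filter_model(-2.5, c(0.03, 0.5, -0.05, 0.3, -2e-7), cutoff = 0.42)
  f <- tempfile(fileext = ".json")
  write_filter_model(m, f, impute = impute_policy(5, 25))
  back <- read_filter_model(f)
  expect_equal(back$model$beta0, m$beta0)
  expect_equal(back$model$betas, m$betas)
  expect_equal(back$model$cutoff, 0.42)
  expect_equal(back$impute$pid_floor, 25)
})
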