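# The assignment filter: a binary logistic-regression model on five BH/NLH
# properties. The model estimates P(BH lineage is correct | x1..x5) and an
# assignment is kept only when that probability reaches the cutoff:
#
#   P(y = 1 | x) = 1 / (1 + exp(-(beta0 + sum_k beta_k x_k)))
#
#   x1 = percent identity of the BH
#   x2 = ratio of percent identity, BH / NLH
#   x3 = log10 E-value of the BH
#   x4 = log10 E(NLH) - log10 E(BH)   (>= 0 for a real NLH)
#   x5 = database size (residues) of the BH's lineage

FEATURE_NAMES <- c("x1", "x2", "x3", "x4", "x5")

#' NLH imputation policy
#'
#' When a read has no next-lineage hit among its retained hits, the read is
#' maximally unambiguous; a pseudo-NLH is placed at the search E-value cutoff
#' and at a floor percent identity, giving it a large x4 and x2.
#'
#' @param log10_evalue_cutoff Pseudo-NLH log10 E-value (default 5, matching
#'   the loose search cutoff).
#' @param pid_floor Pseudo-NLH percent identity (default 20).
#' @return An `impute_policy` list.
#' @export
impute_policy <- function(log10_evalue_cutoff = 5, pid_floor = 20) {
  stopifnot(pid_floor > 0)
  structure(list(log10_evalue_cutoff = log10_evalue_cutoff,
                 pid_floor = pid_floor), class = "impute_policy")
}

#' Build the five-feature matrix from BH/NLH assignments
#'
#' Vectorized over the rows of an assignment data.frame (see [map_hits()]).
#'
#' @param assignments data.frame with bh_pident, bh_log10e, bh_lineage,
#'   nlh_pident, nlh_log10e columns (NLH columns NA when absent).
#' @param sizes Named group-size vector from [group_sizes()]; must cover
#'   every BH lineage.
#' @param impute An [impute_policy()] for NLH-less rows.
#' @return data.frame with columns x1..x5 and logical `nlh_imputed`.
#' @export
featurize <- function(assignments, sizes, impute = impute_policy()) {
  a <- assignments
  miss <- setdiff(unique(a$bh_lineage), names(sizes))
  if (length(miss) > 0L)
    stop("no group size for lineage(s): ", paste(miss, collapse = ", "))
  imp <- is.na(a$nlh_log10e)
  nlh_pid <- ifelse(imp, impute$pid_floor, a$nlh_pident)
  nlh_e <- ifelse(imp, impute$log10_evalue_cutoff, a$nlh_log10e)
  data.frame(x1 = a$bh_pident,
             x2 = a$bh_pident / nlh_pid,
             x3 = a$bh_log10e,
             x4 = nlh_e - a$bh_log10e,
             x5 = as.numeric(sizes[a$bh_lineage]),
             nlh_imputed = imp,
             stringsAsFactors = FALSE)
}

#' Construct a filter model from known coefficients
#'
#' @param beta0 Intercept.
#' @param betas Numeric vector of length 5 (coefficients of x1..x5).
#' @param cutoff Probability cutoff in \[0, 1\] (default 0.58, the operating
#'   point giving a false positive rate below 0.1).
#' @param se Optional standard errors (length 6, intercept first).
#' @return Object of class `filter_model`.
#' @export
filter_model <- function(beta0, betas, cutoff = 0.58, se = NULL) {
  stopifnot(length(betas) == 5L, is.finite(beta0), all(is.finite(betas)),
            cutoff >= 0, cutoff <= 1)
  structure(list(beta0 = as.numeric(beta0),
                 betas = stats::setNames(as.numeric(betas), FEATURE_NAMES),
                 cutoff = as.numeric(cutoff), se = se),
            class = "filter_model")
}

#' @export
print.filter_model <- function(x, ...) {
  cat("filter_model: logistic acceptance filter on 5 BH/NLH features\n")
  cat(sprintf("  beta0 = %.6g; cutoff = %.3f\n", x$beta0, x$cutoff))
  print(x$betas)
  invisible(x)
}

feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, FEATURE_NAMES, drop = FALSE])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  x
}

#' Acceptance probability under a filter model
#'
#' Numerically stable logistic transform of the linear predictor. The output
#' is kept strictly inside (0, 1) even where the double-precision logistic
#' would saturate (|linear predictor| beyond ~37): a probability of exactly
#' 1 would defeat the guarantee that a cutoff of 1.0 rejects every read.
#'
#' @param object A `filter_model`.
#' @param x Feature data.frame (columns x1..x5) or numeric matrix/vector.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.filter_model <- function(object, x, ...) {
  X <- feature_matrix(x)
  if (anyNA(X)) stop("NA/NaN feature value passed to predict()")
  lp <- drop(object$beta0 + X %*% object$betas)
  p <- stats::plogis(lp)
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

# Ridge-penalized IRLS, used as the fallback under complete separation.
# Features are standardized internally (the penalty acts on the standardized
# scale) and coefficients mapped back, so the raw-scale spread of the five
# features (x5 spans 1e4..1e7) cannot make the Hessian numerically singular.
ridge_logistic <- function(X, y, lambda = 1e-6, max_iter = 200L, tol = 1e-10) {
  mu_x <- colMeans(X)
  sd_x <- apply(X, 2L, stats::sd)
  sd_x[sd_x == 0] <- 1
  Z <- sweep(sweep(X, 2L, mu_x), 2L, sd_x, "/")
  X1 <- cbind(1, Z)
  p <- ncol(X1)
  beta <- rep(0, p)
  pen <- diag(lambda, p); pen[1L, 1L] <- 0  # intercept unpenalized
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X1 %*% beta), -700), 700)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X1, y - mu)) - drop(pen %*% beta)
    H <- crossprod(X1 * w, X1) + pen
    step <- solve(H + diag(1e-10, p), grad)
    beta <- beta + step
    if (max(abs(grad)) < 1e-6 || max(abs(step)) < tol) break
  }
  se_z <- sqrt(diag(solve(H + diag(1e-10, p))))
  b <- beta[-1L] / sd_x
  b0 <- beta[1L] - sum(beta[-1L] * mu_x / sd_x)
  se <- c(se_z[1L], se_z[-1L] / sd_x)  # delta-method scale-back (approximate)
  list(beta = c(b0, b), se = se)
}

#' Fit the filter model by maximum likelihood
#'
#' Binomial GLM (logit link) fit by iteratively reweighted least squares via
#' [stats::glm()]. Rows are sorted before fitting so the result does not
#' depend on input order. Under complete separation (divergent MLE) the fit
#' falls back to an L2-ridge (lambda = 1e-6) Newton solver with a warning.
#'
#' @param data data.frame with columns x1..x5 and binary `y`, or a feature
#'   data.frame/matrix if `y` is given separately.
#' @param y Optional response vector (0/1) when not a column of `data`.
#' @param cutoff Probability cutoff stored in the returned model.
#' @return A `filter_model` with standard errors in `$se`.
#' @export
fit_filter <- function(data, y = NULL, cutoff = 0.58) {
  if (is.null(y)) {
    if (!"y" %in% names(data)) stop("no response: supply `y`")
    y <- data$y
  }
  X <- feature_matrix(data)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("single-class input: both classes required")
  if (nrow(X) < 50L) stop("need at least 50 labeled examples, got ", nrow(X))
  o <- do.call(order, c(as.data.frame(X), list(y)))
  X <- X[o, , drop = FALSE]; y <- y[o]
  df <- data.frame(y = y, X)
  w <- NULL
  fit <- withCallingHandlers(
    stats::glm(y ~ x1 + x2 + x3 + x4 + x5, family = stats::binomial(),
               data = df, control = stats::glm.control(epsilon = 1e-10,
                                                       maxit = 100L)),
    warning = function(cnd) {
      w <<- conditionMessage(cnd)
      invokeRestart("muffleWarning")
    })
  separated <- !fit$converged ||
    (!is.null(w) && grepl("fitted probabilities numerically 0 or 1", w)) ||
    any(abs(stats::coef(fit)) > 1e3 & !is.na(stats::coef(fit)))
  if (separated) {
    warning("apparent complete separation; refitting with L2 ridge (lambda = 1e-6)")
    r <- ridge_logistic(X, y)
    return(filter_model(r$beta[1L], r$beta[-1L], cutoff = cutoff,
                        se = r$se))
  }
  b <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  filter_model(b[1L], b[-1L], cutoff = cutoff, se = unname(se))
}

#' Apply the filter to a stream of assignments
#'
#' Each read ends in exactly one of three states: `assigned` (has a BH and
#' acceptance probability >= cutoff), `filtered` (has a BH but P < cutoff) or
#' `unclassified` (no BH existed). Rows whose `bh_subject` is NA are treated
#' as unclassified.
#'
#' @param assignments Assignment data.frame (see [map_hits()]); may contain
#'   placeholder rows with NA `bh_subject` for reads without hits.
#' @param model A `filter_model`.
#' @param sizes Group sizes from [group_sizes()].
#' @param impute An [impute_policy()].
#' @param cutoff Overrides `model$cutoff` when given.
#' @return The input with columns `p` (acceptance probability, NA for
#'   unclassified) and `status` appended; status counts are available via
#'   `table(out$status)`.
#' @export
apply_filter <- function(assignments, model, sizes,
                         impute = impute_policy(), cutoff = NULL) {
  if (is.null(cutoff)) cutoff <- model$cutoff
  a <- assignments
  a$p <- NA_real_
  a$status <- "unclassified"
  has_bh <- !is.na(a$bh_subject)
  if (any(has_bh)) {
    feats <- featurize(a[has_bh, , drop = FALSE], sizes, impute)
    p <- predict(model, feats)
    a$p[has_bh] <- p
    a$status[has_bh] <- ifelse(p >= cutoff, "assigned", "filtered")
    a$nlh_imputed <- NA
    a$nlh_imputed[has_bh] <- feats$nlh_imputed
  }
  a
}

#' Serialize / deserialize a filter model (JSON)
#'
#' The JSON carries the coefficients, cutoff, feature definitions, the
#' imputation policy and a schema version.
#'
#' @param model A `filter_model`.
#' @param path Output (input) JSON file.
#' @param impute The [impute_policy()] recorded alongside the model.
#' @return `read_filter_model` returns a list with elements `model` and
#'   `impute`.
#' @export
write_filter_model <- function(model, path, impute = impute_policy()) {
  obj <- list(
    schema = "readtaxr-filter-model/1",
    beta0 = model$beta0,
    betas = as.list(model$betas),
    cutoff = model$cutoff,
    features = list(
      x1 = "percent identity of BH",
      x2 = "ratio of percent identity BH/NLH",
      x3 = "log10 E-value of BH",
      x4 = "log10 E(NLH) - log10 E(BH)",
      x5 = "database size (residues) of BH lineage"),
    impute = list(log10_evalue_cutoff = impute$log10_evalue_cutoff,
                  pid_floor = impute$pid_floor))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filter_model
#' @export
read_filter_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "readtaxr-filter-model/1"))
    stop("unrecognized model schema: ", obj$schema)
  list(model = filter_model(obj$beta0, unlist(obj$betas[FEATURE_NAMES]),
                            cutoff = obj$cutoff),
       impute = impute_policy(obj$impute$log10_evalue_cutoff,
                              obj$impute$pid_floor))
}
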