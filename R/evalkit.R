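# Training/evaluation machinery for the assignment filter: labeling,
# balanced sampling, Monte Carlo cross-validation, ROC/AUC/ACC, cutoff
# selection, the E-value-cutoff baseline, and random-read rejection.

#' Cross-validation split plan
#'
#' The labeled data is split once into a fixed holdout part (never trained
#' on) and a train/test part; the latter is re-split at random every round.
#'
#' @param holdout_frac Fraction held out up front (default 0.20).
#' @param test_frac Test fraction of the remainder per round (default 0.20).
#' @param n_rounds Monte Carlo rounds (default 100).
#' @param seed RNG seed; the whole procedure is bit-reproducible given it.
#' @return A `split_plan` list.
#' @export
split_plan <- function(holdout_frac = 0.20, test_frac = 0.20,
                       n_rounds = 100L, seed = 1L) {
  stopifnot(holdout_frac > 0, holdout_frac < 1, test_frac > 0, test_frac < 1)
  if (n_rounds < 1L) stop("n_rounds must be >= 1")
  structure(list(holdout_frac = holdout_frac, test_frac = test_frac,
                 n_rounds = as.integer(n_rounds), seed = as.integer(seed)),
            class = "split_plan")
}

#' Label assignments against known read origins
#'
#' y = 1 iff the BH lineage equals the read's true lineage. Reads of random
#' (nonsense) origin carry the reserved truth label `"none"` and are always
#' y = 0.
#'
#' @param assignments Assignment data.frame (see [map_hits()]).
#' @param truth Named character vector, query_id -> true lineage or `"none"`.
#' @return The assignments with an integer column `y` appended.
#' @export
label_reads <- function(assignments, truth) {
  missing <- setdiff(assignments$query_id, names(truth))
  if (length(missing) > 0L)
    stop("query id(s) missing from truth: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  tr <- truth[assignments$query_id]
  assignments$y <- as.integer(tr != "none" & assignments$bh_lineage == tr)
  assignments
}

#' Balanced class sample
#'
#' Draws `n_per_class` elements uniformly without replacement from each
#' class; seeded and reproducible.
#'
#' @param pos,neg Vectors (e.g. of row indices) for the two classes.
#' @param n_per_class Elements drawn per class.
#' @param seed RNG seed.
#' @return Concatenation of the two draws (positives first).
#' @export
balanced_sample <- function(pos, neg, n_per_class, seed = 1L) {
  if (length(pos) < n_per_class || length(neg) < n_per_class)
    stop(sprintf("insufficient class size: need %d per class, have %d / %d",
                 n_per_class, length(pos), length(neg)))
  with_seed(seed, {
    c(sample(pos, n_per_class), sample(neg, n_per_class))
  })
}

#' ROC curve, AUC and accuracy over score thresholds
#'
#' Thresholds are the sorted unique scores plus a sentinel above the maximum
#' (so the (FPR, TPR) = (0, 0) endpoint is present; the minimum score itself
#' gives (1, 1)). TPR(t) = P(score >= t | y = 1), FPR(t) = P(score >= t |
#' y = 0); AUC is the trapezoid area over (FPR, TPR) and therefore equals the
#' normalized Mann-Whitney pairwise concordance count with ties counted 1/2.
#' ACC(t) = (TP(t) + TN(t)) / n. `best_acc_cutoff` is the smallest threshold
#' maximizing ACC; `fpr01_cutoff` the smallest threshold with FPR < 0.1.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels (0/1); both classes must be present.
#' @return Object of class `roc_result`: list(thresholds, tpr, fpr, acc,
#'   auc, best_acc_cutoff, fpr01_cutoff).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("single-class labels: AUC undefined")
  uniq <- sort(unique(scores))
  thr <- c(uniq, if (is.finite(uniq[length(uniq)])) uniq[length(uniq)] + 1
           else Inf)
  idx <- match(scores, uniq)
  pos_ct <- tabulate(idx[labels == 1L], nbins = length(uniq))
  neg_ct <- tabulate(idx[labels == 0L], nbins = length(uniq))
  # counts of scores >= each unique threshold
  tp <- c(rev(cumsum(rev(pos_ct))), 0)
  fp <- c(rev(cumsum(rev(neg_ct))), 0)
  tpr <- tp / n1
  fpr <- fp / n0
  acc <- (tp + (n0 - fp)) / (n1 + n0)
  # points ordered by ascending threshold: fpr runs 1 -> 0; integrate
  auc <- sum(-diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  best_i <- which(acc == max(acc))[1L]  # thresholds ascending: first = smallest
  fpr01_i <- which(fpr < 0.1)[1L]
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, acc = acc,
                 auc = auc,
                 best_acc_cutoff = thr[best_i],
                 best_acc = acc[best_i],
                 fpr01_cutoff = thr[fpr01_i]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "roc_result: AUC %.4f; best ACC %.4f @ %.4g; FPR<0.1 @ %.4g\n",
    x$auc, x$best_acc, x$best_acc_cutoff, x$fpr01_cutoff))
  invisible(x)
}

#' Monte Carlo cross-validation of the filter model
#'
#' The labeled data is split once (stratified) into holdout and train/test
#' parts. Each round independently re-splits the train/test part
#' (stratified), fits the logistic model on the training portion, and
#' evaluates ROC/AUC/ACC on the round's test set and on the fixed holdout;
#' when a random-read feature set is supplied, the round's model is also
#' evaluated on it via [random_rejection()]. Aggregates are arithmetic means
#' over rounds.
#'
#' @param data data.frame with columns x1..x5 and binary `y`.
#' @param plan A [split_plan()].
#' @param random_features Optional all-negative feature data.frame
#'   (columns x1..x5) of random nonsense reads.
#' @return list(rounds = per-round results, aggregate = list of mean AUCs,
#'   accuracies and cutoffs, holdout_idx = indices of the holdout rows).
#' @export
monte_carlo_cv <- function(data, plan = split_plan(), random_features = NULL) {
  stopifnot(is.data.frame(data), "y" %in% names(data))
  if (length(unique(data$y)) < 2L) stop("both classes required")
  with_seed(plan$seed, {
    hold_idx <- stratified_pick(data$y, plan$holdout_frac)
    holdout <- data[hold_idx, , drop = FALSE]
    rest <- data[-hold_idx, , drop = FALSE]
    rounds <- vector("list", plan$n_rounds)
    for (r in seq_len(plan$n_rounds)) {
      test_idx <- stratified_pick(rest$y, plan$test_frac)
      train <- rest[-test_idx, , drop = FALSE]
      test <- rest[test_idx, , drop = FALSE]
      model <- fit_filter(train)
      roc_test <- roc_curve(predict(model, test), test$y)
      roc_hold <- roc_curve(predict(model, holdout), holdout$y)
      rnd <- if (!is.null(random_features))
        random_rejection(model, random_features)
      rounds[[r]] <- list(model = model, test = roc_test,
                          holdout = roc_hold, random = rnd)
    }
    agg <- list(
      auc_test = mean(vapply(rounds, function(x) x$test$auc, 0)),
      auc_holdout = mean(vapply(rounds, function(x) x$holdout$auc, 0)),
      acc_best_test = mean(vapply(rounds, function(x) x$test$best_acc, 0)),
      acc_best_holdout = mean(vapply(rounds, function(x) x$holdout$best_acc, 0)),
      cutoff_best_acc_test = mean(vapply(rounds,
                                         function(x) x$test$best_acc_cutoff, 0)),
      cutoff_fpr01_test = mean(vapply(rounds,
                                      function(x) x$test$fpr01_cutoff, 0)))
    if (!is.null(random_features))
      agg$cutoff_fpr01_random <- mean(vapply(rounds,
                                             function(x) x$random$fpr01_cutoff, 0))
    list(rounds = rounds, aggregate = agg, holdout_idx = hold_idx)
  })
}

#' Simple E-value-cutoff baseline
#'
#' Scores each read by -log10 E(BH) (higher = better) and computes the same
#' ROC statistics as the model; the selected cutoffs are re-expressed on the
#' log10 E-value scale (`*_log10e` elements, a read passes when its log10 E
#' is below them).
#'
#' @param bh_log10e log10 E-values of the best hits.
#' @param labels Binary labels.
#' @return A `roc_result` with extra elements `best_acc_cutoff_log10e` and
#'   `fpr01_cutoff_log10e`.
#' @export
evalue_baseline <- function(bh_log10e, labels) {
  r <- roc_curve(-bh_log10e, labels)
  r$best_acc_cutoff_log10e <- -r$best_acc_cutoff
  r$fpr01_cutoff_log10e <- -r$fpr01_cutoff
  r
}

#' Rejection behaviour on an all-negative (random nonsense) set
#'
#' For random reads every acceptance is a false positive, so accuracy at a
#' probability cutoff t is the fraction rejected, ACC(t) = P(p < t), and
#' FPR(t) = P(p >= t) = 1 - ACC(t). ACC(1.0) = 1 exactly (the model's
#' probabilities are strictly below 1). Curves are evaluated on a uniform
#' grid of 1001 cutoffs in \[0, 1\].
#'
#' @param model A `filter_model`.
#' @param features Feature data.frame (columns x1..x5) of random reads.
#' @param cutoffs Cutoff grid.
#' @return list(cutoffs, acc, fpr, fpr01_cutoff).
#' @export
random_rejection <- function(model, features,
                             cutoffs = seq(0, 1, length.out = 1001L)) {
  p <- predict(model, features)
  acc <- vapply(cutoffs, function(t) mean(p < t), 0)
  fpr <- 1 - acc
  list(cutoffs = cutoffs, acc = acc, fpr = fpr,
       fpr01_cutoff = cutoffs[which(fpr < 0.1)[1L]])
}
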