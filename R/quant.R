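# Count matrices over samples and community-composition plots.

#' Build a samples x groups count matrix from filtered assignments
#'
#' Only reads with status `"assigned"` contribute. Unclassified and filtered
#' reads can be added as explicit categories so that proportions remain
#' interpretable.
#'
#' @param assignments Named list (sample -> filtered assignment data.frame
#'   from [apply_filter()]) or a single data.frame with a `sample` column.
#' @param level `"lineage"` or `"supergroup"`.
#' @param include_unassigned Add explicit `"(filtered)"` and
#'   `"(unclassified)"` categories.
#' @return Object of class `count_matrix`: list(counts, normalized, level),
#'   with `counts` an integer matrix (samples x groups, groups sorted) and
#'   `normalized` filled by [normalize_total()].
#' @export
tax_counts <- function(assignments, level = c("lineage", "supergroup"),
                       include_unassigned = FALSE) {
  level <- match.arg(level)
  if (is.data.frame(assignments)) {
    if (!"sample" %in% names(assignments))
      stop("data.frame input needs a `sample` column")
    assignments <- split(assignments, assignments$sample)
  }
  if (anyDuplicated(names(assignments)))
    stop("duplicate sample names: ",
         paste(unique(names(assignments)[duplicated(names(assignments))]),
               collapse = ", "))
  col <- if (level == "lineage") "bh_lineage" else "bh_supergroup"
  per_sample <- lapply(assignments, function(a) {
    g <- a[[col]][a$status == "assigned"]
    extra <- character(0)
    if (include_unassigned)
      extra <- c(rep("(filtered)", sum(a$status == "filtered")),
                 rep("(unclassified)", sum(a$status == "unclassified")))
    table(c(g, extra))
  })
  groups <- sort(unique(unlist(lapply(per_sample, names))))
  counts <- matrix(0L, nrow = length(per_sample), ncol = length(groups),
                   dimnames = list(names(per_sample), groups))
  for (s in names(per_sample)) {
    tb <- per_sample[[s]]
    counts[s, names(tb)] <- as.integer(tb)
  }
  cm <- structure(list(counts = counts, normalized = NULL, level = level),
                  class = "count_matrix")
  normalize_total(cm)
}

#' Total-count normalization (per-sample proportions)
#'
#' Divides each sample's counts by the sample total. All-zero rows pass
#' through as zeros with a warning. Idempotent on already-normalized rows.
#'
#' @param cm A `count_matrix`.
#' @return The `count_matrix` with `normalized` filled.
#' @export
normalize_total <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  totals <- rowSums(cm$counts)
  if (any(totals == 0))
    warning("sample(s) with zero assigned reads: ",
            paste(rownames(cm$counts)[totals == 0], collapse = ", "))
  cm$normalized <- cm$counts / ifelse(totals == 0, 1, totals)
  cm
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix (%s level): %d sample(s) x %d group(s)\n",
              x$level, nrow(x$counts), ncol(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Write a count matrix as TSV (first column `sample`)
#'
#' @param cm A `count_matrix`.
#' @param path Output TSV.
#' @param what `"counts"` or `"normalized"`.
#' @export
write_counts <- function(cm, path, what = c("counts", "normalized")) {
  what <- match.arg(what)
  m <- cm[[what]]
  df <- data.frame(sample = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Deterministic group -> color map: stable across plots for a given group set.
composition_palette <- function(groups) {
  stats::setNames(grDevices::hcl(h = seq(15, 375, length.out = length(groups) + 1L)[
    seq_along(groups)], c = 70, l = 60), groups)
}

#' Stacked-bar community composition plot
#'
#' One bar per sample, one colored segment per group (fixed group order and a
#' deterministic group-to-color mapping), drawn from the normalized matrix.
#'
#' @param cm A `count_matrix` with `normalized` filled.
#' @param out Output file; device chosen from the extension (.pdf or .png).
#' @return Invisibly, the matrix of segment heights (groups x samples) that
#'   was drawn.
#' @export
plot_composition <- function(cm, out) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(cm$normalized) || ncol(cm$counts) == 0L || nrow(cm$counts) == 0L)
    stop("empty count matrix")
  heights <- t(cm$normalized)  # groups x samples
  pal <- composition_palette(rownames(heights))
  ext <- tolower(tools::file_ext(out))
  switch(ext,
         pdf = grDevices::pdf(out, width = 7, height = 5),
         png = grDevices::png(out, width = 900, height = 650),
         stop("unsupported plot format: .", ext))
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(5, 4, 2, 12), xpd = TRUE)
  on.exit(graphics::par(op), add = TRUE)
  graphics::barplot(heights, col = pal[rownames(heights)], border = NA,
                    ylab = "fraction of assigned reads", las = 2)
  graphics::legend("topright", inset = c(-0.45, 0), legend = rownames(heights),
                   fill = pal[rownames(heights)], bty = "n", cex = 0.8)
  invisible(heights)
}
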