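# Synthetic-data generation: reference databases, labeled reads of the three
# evaluation classes (in-database, related-taxon, random nonsense), and
# feature-level datasets drawn from a known logistic model. All generators
# are pure functions of (spec, seed).

SUPERGROUPS <- c("Alveolata", "Amorphea", "Archaeplastida", "Excavata",
                 "Hacrobia", "Rhizaria", "Stramenopile")

#' Synthetic-world specification
#'
#' Defaults state the emulated world: a reference database spanning the 28
#' main lineages nested in the 7 eukaryotic supergroups, 100-nt reads (the
#' evaluation reads were 50-101 bp), and an evaluation mix of in-database,
#' related-taxon and random nonsense reads.
#'
#' @param n_lineages Number of lineages (default 28).
#' @param taxa_per_lineage Taxa per lineage (default 2).
#' @param proteins_per_taxon Proteins per taxon (default 20).
#' @param protein_len Length range (aa) of each protein (default 100-300).
#' @param read_len Read length in nt (default 100; must be >= 50).
#' @param mutation_rate Per-site amino-acid substitution rate applied to
#'   source proteins of "related taxon" reads (default 0.1).
#' @param class_mix Proportions of (in_db, related, random) reads; must sum
#'   to 1 (default 0.6/0.2/0.2).
#' @param lineage_skew Mixing weight in \[0, 1) of a per-lineage Dirichlet
#'   amino-acid distribution against the uniform one; 0 = i.i.d. uniform
#'   proteins, larger values make lineages separable (default 0.5).
#' @param seed RNG seed.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_lineages = 28L, taxa_per_lineage = 2L,
                       proteins_per_taxon = 20L, protein_len = c(100L, 300L),
                       read_len = 100L, mutation_rate = 0.1,
                       class_mix = c(in_db = 0.6, related = 0.2, random = 0.2),
                       lineage_skew = 0.5, seed = 1L) {
  stopifnot(length(class_mix) == 3L, abs(sum(class_mix) - 1) < 1e-9,
            read_len >= 50L, mutation_rate >= 0, mutation_rate <= 1,
            lineage_skew >= 0, lineage_skew < 1)
  names(class_mix) <- c("in_db", "related", "random")
  structure(list(n_lineages = as.integer(n_lineages),
                 taxa_per_lineage = as.integer(taxa_per_lineage),
                 proteins_per_taxon = as.integer(proteins_per_taxon),
                 protein_len = as.integer(protein_len),
                 read_len = as.integer(read_len),
                 mutation_rate = mutation_rate,
                 class_mix = class_mix,
                 lineage_skew = lineage_skew,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

random_protein <- function(len, probs) {
  paste(sample(AA20, len, replace = TRUE, prob = probs), collapse = "")
}

#' Generate a synthetic reference database
#'
#' Writes `reference.fasta` (headers `>taxon_id|protein_id`) and
#' `taxonomy.tsv` under `dir`. Lineages are named `L01..`, assigned
#' round-robin to the seven supergroups; per-lineage amino-acid
#' distributions are skewed (see [synth_spec()]) so lineages are separable.
#' Deterministic: a fixed spec yields byte-identical files.
#'
#' @param spec A [synth_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, list(fasta, taxonomy, proteins, taxa): the file paths,
#'   the named protein vector (names `taxon|protein`) and the taxon table.
#' @export
make_refdb <- function(spec, dir) {
  stopifnot(inherits(spec, "synth_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed, {
    lineages <- sprintf("L%02d", seq_len(spec$n_lineages))
    sgs <- SUPERGROUPS[((seq_len(spec$n_lineages) - 1L) %% 7L) + 1L]
    lin_probs <- lapply(seq_len(spec$n_lineages), function(i) {
      base <- rep(1 / 20, 20)
      (1 - spec$lineage_skew) * base + spec$lineage_skew * rdirichlet1(rep(1, 20))
    })
    taxa <- data.frame(
      taxon_id = as.vector(t(outer(lineages, seq_len(spec$taxa_per_lineage),
                                   function(l, t) sprintf("%s_t%d", l, t)))),
      lineage = rep(lineages, each = spec$taxa_per_lineage),
      supergroup = rep(sgs, each = spec$taxa_per_lineage),
      stringsAsFactors = FALSE)
    taxa$taxon_name <- paste0("Synthetica ", tolower(taxa$taxon_id))

    proteins <- character(0)
    for (i in seq_len(nrow(taxa))) {
      li <- match(taxa$lineage[i], lineages)
      lens <- sample(spec$protein_len[1L]:spec$protein_len[2L],
                     spec$proteins_per_taxon, replace = TRUE)
      ps <- vapply(lens, random_protein, "", probs = lin_probs[[li]])
      names(ps) <- sprintf("%s|p%03d", taxa$taxon_id[i],
                           seq_len(spec$proteins_per_taxon))
      proteins <- c(proteins, ps)
    }
    fasta <- file.path(dir, "reference.fasta")
    writeLines(paste0(">", names(proteins), "\n", proteins), fasta)
    tsv <- file.path(dir, "taxonomy.tsv")
    utils::write.table(
      taxa[, c("taxon_id", "taxon_name", "lineage", "supergroup")],
      tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(list(fasta = fasta, taxonomy = tsv, proteins = proteins,
                   taxa = taxa))
  })
}

# First codon of the standard genetic code for every amino acid.
first_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  keep <- !duplicated(gc)
  stats::setNames(names(gc)[keep], gc[keep])
}

back_translate <- function(aa_seq, codons = first_codon_table()) {
  paste(codons[strsplit(aa_seq, "")[[1]]], collapse = "")
}

mutate_protein <- function(aa_seq, rate) {
  if (rate <= 0) return(aa_seq)
  chars <- strsplit(aa_seq, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit))
    chars[hit] <- vapply(chars[hit],
                         function(a) sample(setdiff(AA20, a), 1L), "")
  paste(chars, collapse = "")
}

revcomp_chr <- function(s) chartr("ACGT", "TGCA",
                                  paste(rev(strsplit(s, "")[[1]]), collapse = ""))

#' Generate labeled synthetic reads
#'
#' Three read classes, mixed per `spec$class_mix`:
#' \itemize{
#'   \item `in_db`: exact back-translations of windows of database proteins
#'     (truth = the source taxon's lineage);
#'   \item `related`: back-translations of windows of mutated copies of
#'     database proteins, emulating congeneric species absent from the
#'     database whose lineage is present (truth = the source lineage);
#'   \item `random`: i.i.d. uniform nucleotides (truth = `"none"`).
#' }
#' Back-translation uses the first codon of the standard genetic code per
#' amino acid; half the non-random reads are emitted reverse-complemented;
#' FASTQ quality strings are constant.
#'
#' @param db Result of [make_refdb()].
#' @param spec The [synth_spec()].
#' @param n_reads Number of reads (templates).
#' @param out Output prefix: writes `<out>.fastq` (or `<out>_1.fastq` and
#'   `<out>_2.fastq` when `paired`) and `<out>_truth.tsv`.
#' @param paired Emit mate pairs (mate 2 is the reverse complement of the
#'   fragment).
#' @param seed RNG seed (defaults to `spec$seed + 1`).
#' @return Invisibly, list(fastq, truth, classes).
#' @export
make_reads <- function(db, spec, n_reads = 1000L, out, paired = FALSE,
                       seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "synth_spec"))
  if (spec$read_len < 3L) stop("read_len shorter than one codon")
  aa_win <- ceiling(spec$read_len / 3)
  eligible <- db$proteins[nchar(db$proteins) >= aa_win]
  if (length(eligible) == 0L) stop("no protein long enough for the read window")
  taxon_of <- sub("\\|.*$", "", names(eligible))
  lineage_of <- db$taxa$lineage[match(taxon_of, db$taxa$taxon_id)]

  n_in <- round(spec$class_mix[["in_db"]] * n_reads)
  n_rel <- round(spec$class_mix[["related"]] * n_reads)
  n_rand <- n_reads - n_in - n_rel
  classes <- c(rep("in_db", n_in), rep("related", n_rel),
               rep("random", n_rand))
  codons <- first_codon_table()

  with_seed(seed, {
    seqs <- character(n_reads)
    truth <- character(n_reads)
    for (i in seq_len(n_reads)) {
      if (classes[i] == "random") {
        seqs[i] <- paste(sample(c("A", "C", "G", "T"), spec$read_len,
                                replace = TRUE), collapse = "")
        truth[i] <- "none"
      } else {
        j <- sample(length(eligible), 1L)
        prot <- eligible[[j]]
        start <- sample(nchar(prot) - aa_win + 1L, 1L)
        win <- substr(prot, start, start + aa_win - 1L)
        if (classes[i] == "related")
          win <- mutate_protein(win, spec$mutation_rate)
        nt <- substr(back_translate(win, codons), 1L, spec$read_len)
        if (stats::runif(1) < 0.5) nt <- revcomp_chr(nt)
        seqs[i] <- nt
        truth[i] <- lineage_of[j]
      }
    }
    ids <- sprintf("r%06d", seq_len(n_reads))
    qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
    fq1 <- paste0("@", ids, "\n", seqs, "\n+\n", qual)
    if (paired) {
      f1 <- paste0(out, "_1.fastq"); f2 <- paste0(out, "_2.fastq")
      writeLines(fq1, f1)
      seqs2 <- vapply(seqs, revcomp_chr, "")
      writeLines(paste0("@", ids, "\n", seqs2, "\n+\n", qual), f2)
      fastq <- c(f1, f2)
    } else {
      fastq <- paste0(out, ".fastq")
      writeLines(fq1, fastq)
    }
    truth_path <- paste0(out, "_truth.tsv")
    utils::write.table(data.frame(query_id = ids, true_lineage = truth),
                       truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(list(fastq = fastq, truth = truth_path, classes = classes))
  })
}

#' Read a truth TSV into a named vector
#'
#' @param path Truth TSV with columns query_id, true_lineage.
#' @return Named character vector, query_id -> true lineage or `"none"`.
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  stats::setNames(df$true_lineage, df$query_id)
}

#' Feature-level dataset from a known logistic model
#'
#' Draws features from the stated distributions (x1 ~ U(30, 100),
#' x2 ~ 1 + Exp(mean 1), x3 ~ U(-50, 5), x4 ~ Exp(mean 5),
#' x5 ~ U(1e4, 1e7)) and labels y ~ Bernoulli(logistic(beta0 + sum beta_k
#' x_k)). Used for parameter-recovery and evaluation tests where read-level
#' simulation is unnecessary.
#'
#' @param beta Numeric vector of length 6: intercept then coefficients of
#'   x1..x5.
#' @param n Number of rows.
#' @param seed RNG seed.
#' @param feature_dists Optional named list of generator functions
#'   (`function(n)`) overriding the defaults per feature.
#' @return data.frame with columns x1..x5, `p` (generating probability) and
#'   `y`.
#' @export
make_feature_data <- function(beta, n, seed = 1L, feature_dists = NULL) {
  stopifnot(length(beta) == 6L)
  dists <- list(
    x1 = function(n) stats::runif(n, 30, 100),
    x2 = function(n) 1 + stats::rexp(n, rate = 1),
    x3 = function(n) stats::runif(n, -50, 5),
    x4 = function(n) stats::rexp(n, rate = 0.2),
    x5 = function(n) stats::runif(n, 1e4, 1e7))
  if (!is.null(feature_dists)) dists[names(feature_dists)] <- feature_dists
  with_seed(seed, {
    X <- vapply(FEATURE_NAMES, function(f) dists[[f]](n), numeric(n))
    p <- stats::plogis(drop(beta[1L] + X %*% beta[-1L]))
    y <- stats::rbinom(n, 1L, p)
    data.frame(X, p = p, y = y)
  })
}
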