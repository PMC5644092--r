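# Shared fixtures (built in code) and independent oracles.

# Write a reference FASTA + taxonomy TSV from in-memory objects.
# proteins: named character vector, names "taxon_id|seq_id".
write_ref <- function(proteins, taxa_df, dir = withr_tempdir()) {
  fasta <- file.path(dir, "ref.fasta")
  writeLines(paste0(">", names(proteins), "\n", proteins), fasta)
  tsv <- file.path(dir, "tax.tsv")
  write.table(taxa_df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fasta, taxonomy = tsv, dir = dir)
}

withr_tempdir <- function() {
  d <- tempfile("fix")
  dir.create(d)
  d
}

tiny_taxa <- function(taxon_ids, lineages, supergroups = NULL) {
  if (is.null(supergroups)) {
    sgs <- c(L1 = "Stramenopile", L2 = "Alveolata", L3 = "Archaeplastida",
             L4 = "Rhizaria", L5 = "Excavata", L6 = "Hacrobia",
             L7 = "Amorphea")
    supergroups <- unname(sgs[lineages])
    supergroups[is.na(supergroups)] <- "Stramenopile"
  }
  data.frame(taxon_id = taxon_ids,
             taxon_name = paste("Taxon", taxon_ids),
             lineage = lineages, supergroup = supergroups,
             stringsAsFactors = FALSE)
}

# Random protein of length n (canonical alphabet).
rand_prot <- function(n) paste(sample(readtaxr:::AA20, n, replace = TRUE),
                               collapse = "")

# A well-formed ranked hit group over given subject lineage labels; subjects
# are "tk<i>|p1" resolving to taxa tk<i>. E-values are sorted ascending so
# ranks are consistent.
hit_group_from_lineages <- function(query, subject_taxa, log10e = NULL) {
  n <- length(subject_taxa)
  if (is.null(log10e)) log10e <- sort(round(runif(n, -30, 5), 3))
  data.frame(query_id = rep(query, n),
             subject_id = paste0(subject_taxa, "|p1"),
             pct_identity = round(runif(n, 30, 100), 2),
             aln_length = 30L, mismatches = 2L, gap_open = 0L,
             qstart = 1L, qend = 30L, sstart = 1L, send = 30L,
             log10_evalue = log10e,
             bit_score = round(rev(sort(runif(n, 20, 80))), 1),
             rank = seq_len(n), stringsAsFactors = FALSE)
}

# --- independent oracles -----------------------------------------------------

# Linear-scan BH/NLH oracle: bh index is 1; nlh is the first index whose
# lineage differs from the bh's; everything between must share bh's lineage.
oracle_bh_nlh <- function(lineages) {
  if (length(lineages) == 0L) return(NULL)
  nlh <- NA_integer_
  for (i in seq_along(lineages)[-1L]) {
    if (lineages[i] != lineages[1L]) { nlh <- i; break }
  }
  list(bh = 1L, nlh = nlh)
}

# Mann-Whitney pairwise-concordance AUC (ties counted 1/2).
oracle_auc_mw <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Exhaustive translated-alignment oracle: best subject over all six frames
# and all subjects, scored exactly like the builtin search (same aligner,
# same Karlin-Altschul constants) but with no seeding. Returns NULL when no
# positive-score alignment exists.
oracle_best_subject <- function(read_chr, db_path) {
  db <- Biostrings::readAAStringSet(db_path)
  names(db) <- sub("[[:space:]].*$", "", names(db))
  n_db <- sum(Biostrings::width(db))
  dna <- Biostrings::DNAString(read_chr)
  frames <- list()
  for (s in list(dna, Biostrings::reverseComplement(dna))) {
    for (f in 1:3) {
      n <- ((length(s) - f + 1L) %/% 3L) * 3L
      if (n < 3L) next
      frames[[length(frames) + 1L]] <- Biostrings::translate(
        Biostrings::subseq(s, start = f, width = n), if.fuzzy.codon = "solve")
    }
  }
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  best <- NULL
  for (fr in frames) {
    m_len <- length(fr)
    for (j in seq_along(db)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(list(fr)), db[[j]], type = "local",
        substitutionMatrix = e$BLOSUM62, gapOpening = 11, gapExtension = 1)
      sc <- Biostrings::score(aln)
      if (sc <= 0) next
      bits <- (0.267 * sc - log(0.041)) / log(2)
      log10e <- log10(m_len * n_db) - bits * log10(2)
      cand <- list(subject = names(db)[j], log10e = log10e, score = sc)
      if (is.null(best) || log10e < best$log10e ||
          (log10e == best$log10e && cand$subject < best$subject))
        best <- cand
    }
  }
  best
}

# A small reusable synthetic reference world for pipeline-level tests.
small_world <- function(seed = 11L, n_lineages = 5L) {
  spec <- synth_spec(n_lineages = n_lineages, taxa_per_lineage = 2L,
                     proteins_per_taxon = 4L, protein_len = c(80L, 150L),
                     lineage_skew = 0.6, seed = seed)
  dir <- withr_tempdir()
  db <- make_refdb(spec, dir)
  list(spec = spec, db = db, dir = dir,
       tab = load_taxonomy(db$fasta, db$taxonomy))
}
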