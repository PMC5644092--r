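# Reference database: taxonomy, per-lineage database sizes, k-mer spectra and
# group diversity statistics.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Load a reference taxonomy from a protein FASTA and a taxonomy table
#'
#' The reference database consists of a protein FASTA whose headers carry a
#' taxon identifier, and a tab-separated taxonomy table mapping each taxon to
#' one of the main eukaryotic lineages and one of the seven supergroups.
#' Per-taxon sequence counts and residue totals are computed from the FASTA;
#' byte-identical duplicate sequences within a taxon are dropped before
#' counting (redundancy removal by exact string identity, no clustering).
#'
#' @param fasta_path Path to the protein FASTA. Headers follow the
#'   `">taxon_id|sequence_id description"` dialect by default; other dialects
#'   can be accommodated via `id_pattern`.
#' @param taxonomy_tsv Path to a TSV with header columns
#'   `taxon_id`, `taxon_name`, `lineage`, `supergroup`.
#' @param id_pattern Regex whose first capture group extracts the taxon
#'   identifier from a FASTA header line (default: everything before the first
#'   `|` or whitespace).
#' @return An object of class `taxonomy_table`: a list with elements
#'   `taxa` (data.frame with columns taxon_id, taxon_name, lineage,
#'   supergroup, n_sequences, residue_total) and `lineage_to_supergroup`
#'   (named character vector).
#' @export
load_taxonomy <- function(fasta_path, taxonomy_tsv,
                          id_pattern = "^([^|[:space:]]+)") {
  tax <- utils::read.delim(taxonomy_tsv, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("taxon_id", "taxon_name", "lineage", "supergroup")
  missing <- setdiff(required, names(tax))
  if (length(missing) > 0L)
    stop("taxonomy table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(tax$taxon_id))
    stop("duplicate taxon_id in taxonomy table: ",
         paste(unique(tax$taxon_id[duplicated(tax$taxon_id)]), collapse = ", "))

  # lineage -> supergroup must be a function
  map <- unique(tax[, c("lineage", "supergroup")])
  dup <- map$lineage[duplicated(map$lineage)]
  if (length(dup) > 0L) {
    bad <- tax[tax$lineage %in% dup, , drop = FALSE]
    stop("lineage mapped to more than one supergroup: ",
         paste(sprintf("row %s (taxon_id=%s, lineage=%s, supergroup=%s)",
                       rownames(bad), bad$taxon_id, bad$lineage,
                       bad$supergroup), collapse = "; "))
  }
  l2s <- stats::setNames(map$supergroup, map$lineage)

  seqs <- Biostrings::readAAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty reference FASTA: ", fasta_path)
  m <- regmatches(names(seqs), regexec(id_pattern, names(seqs)))
  taxon_of <- vapply(m, function(g) if (length(g) >= 2L) g[2L] else NA_character_,
                     character(1))
  if (anyNA(taxon_of))
    stop("FASTA header(s) without a parseable taxon identifier: ",
         paste(utils::head(names(seqs)[is.na(taxon_of)], 3L), collapse = "; "))
  unknown <- setdiff(unique(taxon_of), tax$taxon_id)
  if (length(unknown) > 0L)
    stop("FASTA taxa absent from taxonomy table: ",
         paste(unknown, collapse = ", "))

  # drop exact duplicate sequences within each taxon
  seq_chr <- as.character(seqs)
  keep <- !duplicated(paste0(taxon_of, "\r", seq_chr))
  taxon_of <- taxon_of[keep]
  widths <- nchar(seq_chr[keep])

  n_seq <- tapply(widths, taxon_of, length)
  res_tot <- tapply(widths, taxon_of, sum)
  tax$n_sequences <- as.integer(ifelse(is.na(n_seq[tax$taxon_id]), 0L,
                                       n_seq[tax$taxon_id]))
  tax$residue_total <- as.numeric(ifelse(is.na(res_tot[tax$taxon_id]), 0,
                                         res_tot[tax$taxon_id]))

  structure(list(taxa = tax, lineage_to_supergroup = l2s),
            class = "taxonomy_table")
}

#' @export
print.taxonomy_table <- function(x, ...) {
  cat(sprintf("taxonomy_table: %d taxa, %d lineages, %d supergroups\n",
              nrow(x$taxa), length(unique(x$taxa$lineage)),
              length(unique(x$taxa$supergroup))))
  cat(sprintf("  sequences: %d, residues: %.0f\n",
              sum(x$taxa$n_sequences), sum(x$taxa$residue_total)))
  invisible(x)
}

#' Look up the lineage and supergroup of subject identifiers
#'
#' @param tab A `taxonomy_table`.
#' @param taxon_ids Character vector of taxon identifiers.
#' @return data.frame with columns lineage, supergroup (one row per id).
#' @export
lookup_taxa <- function(tab, taxon_ids) {
  i <- match(taxon_ids, tab$taxa$taxon_id)
  if (anyNA(i))
    stop("subject taxon not in taxonomy: ",
         paste(unique(taxon_ids[is.na(i)]), collapse = ", "))
  data.frame(lineage = tab$taxa$lineage[i],
             supergroup = tab$taxa$supergroup[i],
             stringsAsFactors = FALSE)
}

#' Per-lineage database sizes
#'
#' Sums `residue_total` over all member taxa of each lineage. This is the
#' "database size of the best hit's taxonomic group" feature (x5) of the
#' assignment filter. Sizes are in amino-acid residues (the database stores
#' proteins); the unit is recorded in the `"unit"` attribute.
#'
#' @param tab A `taxonomy_table`.
#' @return Named numeric vector, lineage -> total residues.
#' @export
group_sizes <- function(tab) {
  stopifnot(inherits(tab, "taxonomy_table"))
  gs <- tapply(tab$taxa$residue_total, tab$taxa$lineage, sum)
  out <- stats::setNames(as.numeric(gs), names(gs))
  attr(out, "unit") <- "residues"
  out
}

#' Amino-acid k-mer spectrum of a set of proteins
#'
#' Counts every overlapping k-mer over the 20-letter alphabet; windows
#' containing any non-canonical letter (X, B, Z, *, ...) are skipped entirely.
#'
#' @param proteins Character vector (or AAStringSet) of protein sequences.
#' @param k Word length (default 4).
#' @param taxon_id Optional identifier carried in the result.
#' @return Object of class `kmer_spectrum`: list(taxon_id, k, counts, total).
#' @export
kmer_spectrum <- function(proteins, k = 4L, taxon_id = NA_character_) {
  if (methods::is(proteins, "XStringSet")) proteins <- as.character(proteins)
  if (length(proteins) == 0L) stop("empty protein set")
  stopifnot(k >= 1L)
  valid <- sprintf("^[%s]+$", paste(AA20, collapse = ""))
  words <- unlist(lapply(proteins, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  words <- words[grepl(valid, words)]
  tb <- table(words)
  counts <- stats::setNames(as.integer(tb), names(tb))
  structure(list(taxon_id = taxon_id, k = as.integer(k),
                 counts = counts, total = sum(counts)),
            class = "kmer_spectrum")
}

#' Bray-Curtis dissimilarity between two k-mer spectra
#'
#' Computed on relative frequencies (counts / total) over the union of
#' k-mers: BC = sum |a_i - b_i| / sum (a_i + b_i). Symmetric, 0 for identical
#' spectra, 1 for disjoint support. Not a metric (no triangle inequality).
#'
#' @param a,b `kmer_spectrum` objects with the same `k`.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(a, b) {
  stopifnot(inherits(a, "kmer_spectrum"), inherits(b, "kmer_spectrum"))
  if (a$k != b$k) stop("k mismatch: ", a$k, " vs ", b$k)
  if (a$total == 0L || b$total == 0L) stop("spectrum with zero total")
  keys <- union(names(a$counts), names(b$counts))
  fa <- rep(0, length(keys)); names(fa) <- keys
  fb <- fa
  fa[names(a$counts)] <- a$counts / a$total
  fb[names(b$counts)] <- b$counts / b$total
  sum(abs(fa - fb)) / sum(fa + fb)
}

#' Within-group proteome diversity (max and mean Bray-Curtis)
#'
#' For every lineage and every supergroup with at least two member taxa,
#' reports the maximum and mean pairwise Bray-Curtis dissimilarity of the
#' taxa's k-mer spectra. Single-taxon groups report NA.
#'
#' @param tab A `taxonomy_table`.
#' @param spectra List of `kmer_spectrum` objects, one per taxon, each with a
#'   `taxon_id` present in `tab`.
#' @return data.frame with columns group, level ("lineage"/"supergroup"),
#'   n_taxa, bc_max, bc_mean.
#' @export
group_diversity <- function(tab, spectra) {
  stopifnot(inherits(tab, "taxonomy_table"))
  ids <- vapply(spectra, function(s) s$taxon_id, character(1))
  if (anyNA(ids) || anyDuplicated(ids))
    stop("spectra must carry unique non-NA taxon_id values")
  info <- lookup_taxa(tab, ids)

  one_level <- function(groups, level) {
    do.call(rbind, lapply(unique(groups), function(g) {
      members <- which(groups == g)
      if (length(members) < 2L)
        return(data.frame(group = g, level = level,
                          n_taxa = length(members),
                          bc_max = NA_real_, bc_mean = NA_real_,
                          stringsAsFactors = FALSE))
      prs <- utils::combn(members, 2L)
      bc <- apply(prs, 2L, function(p) bray_curtis(spectra[[p[1]]],
                                                   spectra[[p[2]]]))
      data.frame(group = g, level = level, n_taxa = length(members),
                 bc_max = max(bc), bc_mean = mean(bc),
                 stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(one_level(info$lineage, "lineage"),
               one_level(info$supergroup, "supergroup"))
  rownames(out) <- NULL
  out
}
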