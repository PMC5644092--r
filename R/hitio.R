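# Tabular similarity-hit I/O and a built-in translated search.
#
# External search tools (RAPSearch2, DIAMOND, BLASTX) are first-class input
# via their 12-column tabular output; the built-in search exists so that the
# whole pipeline runs self-contained, with no external binary, on small data.

# Murphy 10-letter reduced amino-acid alphabet:
# {LVIM} {C} {A} {G} {ST} {P} {FYW} {EDNQ} {KR} {H}
MURPHY10_FROM <- "LVIMCAGSTPFYWEDNQKRH"
MURPHY10_TO   <- "LLLLCAGSSPFFFEEEEKKH"
MURPHY10_LETTERS <- "LCAGSPFEKH"

# Karlin-Altschul parameters (ungapped defaults) used to turn raw local
# alignment scores into bit scores and E-values.
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Search configuration
#'
#' @param max_hits Hits retained per query (default 20; at least 2, since the
#'   next-lineage hit needs a second hit).
#' @param log10_evalue_cutoff Keep hits with log10(E) at or below this value
#'   (default 5, i.e. the loose cutoff E <= 1e5).
#' @param mode `"builtin"` or `"external_parse"`.
#' @param seed_k Seed word length of the built-in search (reduced alphabet).
#' @return A `search_config` list.
#' @export
search_config <- function(max_hits = 20L, log10_evalue_cutoff = 5,
                          mode = c("builtin", "external_parse"), seed_k = 4L) {
  mode <- match.arg(mode)
  max_hits <- as.integer(max_hits)
  if (max_hits < 2L) stop("max_hits must be >= 2 (the NLH needs a second hit)")
  if (!is.finite(log10_evalue_cutoff)) stop("log10_evalue_cutoff must be finite")
  structure(list(max_hits = max_hits,
                 log10_evalue_cutoff = log10_evalue_cutoff,
                 mode = mode, seed_k = as.integer(seed_k)),
            class = "search_config")
}

M8_COLS <- c("query_id", "subject_id", "pct_identity", "aln_length",
             "mismatches", "gap_open", "qstart", "qend", "sstart", "send",
             "evalue_col", "bit_score")

canonical_hit_order <- function(df) {
  df[order(df$log10_evalue, -df$bit_score, df$subject_id), , drop = FALSE]
}

#' Parse a tabular (m8 / outfmt 6) similarity-hit file
#'
#' Groups hits by query, sorts each group by log10 E-value ascending
#' (ties: bit score descending, then subject id lexicographic), drops rows
#' above the E-value cutoff, truncates to `max_hits` and assigns ranks.
#' Internally E-values are always represented on the log10 scale: the
#' `rapsearch2` dialect stores log10(E) natively in column 11, the
#' `blast_outfmt6` dialect stores raw E-values which are converted on read
#' (E = 0 is clamped to log10(E) = -400).
#'
#' @param path Tabular hit file; `#`-comment lines are skipped.
#' @param dialect `"blast_outfmt6"` or `"rapsearch2"`.
#' @param cfg A [search_config()].
#' @return Named list (query id -> data.frame of hits with columns
#'   query_id, subject_id, pct_identity, aln_length, mismatches, gap_open,
#'   qstart, qend, sstart, send, log10_evalue, bit_score, rank), queries in
#'   order of first appearance.
#' @export
parse_m8 <- function(path, dialect = c("blast_outfmt6", "rapsearch2"),
                     cfg = search_config()) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(stats::setNames(list(), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stop("malformed m8 row (expected 12 columns, got ", nf[nf != 12L][1L],
         ") at line ", line_no[nf != 12L][1L], " of ", path)
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop("non-numeric ", what, " at line ", line_no[which(is.na(v))[1L]],
           " of ", path)
    v
  }
  ev <- num(11L, "E-value")
  log10e <- if (dialect == "blast_outfmt6") {
    ifelse(ev <= 0, -400, log10(ev))
  } else ev
  df <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                   pct_identity = num(3L, "percent identity"),
                   aln_length = as.integer(num(4L, "alignment length")),
                   mismatches = as.integer(num(5L, "mismatch count")),
                   gap_open = as.integer(num(6L, "gap open count")),
                   qstart = as.integer(num(7L, "qstart")),
                   qend = as.integer(num(8L, "qend")),
                   sstart = as.integer(num(9L, "sstart")),
                   send = as.integer(num(10L, "send")),
                   log10_evalue = log10e, bit_score = num(12L, "bit score"),
                   stringsAsFactors = FALSE)
  df <- df[df$log10_evalue <= cfg$log10_evalue_cutoff, , drop = FALSE]
  qorder <- unique(m[, 1L])
  groups <- lapply(qorder, function(q) {
    g <- canonical_hit_order(df[df$query_id == q, , drop = FALSE])
    g <- utils::head(g, cfg$max_hits)
    if (nrow(g) > 0L) g$rank <- seq_len(nrow(g))
    rownames(g) <- NULL
    g
  })
  names(groups) <- qorder
  groups[vapply(groups, nrow, 0L) > 0L]
}

#' Write hit groups back to a tabular m8 file
#'
#' Inverse of [parse_m8()] on canonicalized groups (round-trip identity).
#'
#' @param groups Named list of hit data.frames as returned by [parse_m8()].
#' @param path Output file.
#' @param dialect E-value column semantics; see [parse_m8()].
#' @export
write_m8 <- function(groups, path, dialect = c("rapsearch2", "blast_outfmt6")) {
  dialect <- match.arg(dialect)
  if (length(groups) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- do.call(rbind, c(groups, list(make.row.names = FALSE)))
  ev <- if (dialect == "rapsearch2") df$log10_evalue else 10^df$log10_evalue
  out <- data.frame(df$query_id, df$subject_id,
                    formatC(df$pct_identity, format = "f", digits = 2),
                    df$aln_length, df$mismatches, df$gap_open,
                    df$qstart, df$qend, df$sstart, df$send,
                    formatC(ev, format = "g", digits = 6),
                    formatC(df$bit_score, format = "f", digits = 1))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_reads <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  reads <- Biostrings::readDNAStringSet(path, format = fmt)
  names(reads) <- sub("[[:space:]].*$", "", names(reads))
  reads
}

# Six-frame translation of a whole read set at once. Returns an AAStringSet
# of all frames with attribute "read" (index of the source read).
six_frames_all <- function(reads) {
  strands <- list(fwd = reads, rev = Biostrings::reverseComplement(reads))
  out <- list(); idx <- list()
  for (s in strands) {
    for (f in 1:3) {
      w <- Biostrings::width(s)
      wf <- ((w - f + 1L) %/% 3L) * 3L
      keep <- wf >= 3L
      if (!any(keep)) next
      fr <- Biostrings::translate(
        Biostrings::subseq(s[keep], start = f, width = wf[keep]),
        if.fuzzy.codon = "solve")
      out[[length(out) + 1L]] <- fr
      idx[[length(idx) + 1L]] <- which(keep)
    }
  }
  if (length(out) == 0L)
    return(structure(Biostrings::AAStringSet(), read = integer(0)))
  frames <- do.call(c, out)
  structure(frames, read = unlist(idx, use.names = FALSE))
}

reduced_kmers <- function(aa_string, k) {
  s <- chartr(MURPHY10_FROM, MURPHY10_TO, aa_string)
  n <- nchar(s)
  if (n < k) return(character(0))
  w <- substring(s, 1:(n - k + 1L), k:n)
  unique(w[grepl(sprintf("^[%s]+$", MURPHY10_LETTERS), w)])
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Built-in reduced-alphabet translated search
#'
#' A self-contained stand-in for an external translated protein search:
#' each read is translated in all six frames; candidate subjects are found by
#' exact seed matches of length `cfg$seed_k` after mapping both query frames
#' and subjects through the Murphy 10-letter reduced amino-acid alphabet;
#' every candidate (frame, subject) pair is then aligned locally
#' (Smith-Waterman, BLOSUM62, affine gaps open 11 / extend 1). Raw scores S
#' are converted to bit scores b = (lambda S - ln K)/ln 2 with the fixed
#' ungapped defaults lambda = 0.267, K = 0.041, and E = m n 2^(-b) where m is
#' the frame length (aa) and n the total database residues. Per query the
#' best `max_hits` subjects by E-value are reported. This is a test oracle
#' for the pipeline, not a re-implementation of a production search tool.
#'
#' @param reads_path FASTA or FASTQ file of nucleotide reads.
#' @param db_path Protein reference FASTA.
#' @param cfg A [search_config()].
#' @param out Optional path; if given, hits are written there in m8 format
#'   (`rapsearch2` dialect, log10 E-values).
#' @return Invisibly, the named list of hit groups (see [parse_m8()]).
#' @export
builtin_search <- function(reads_path, db_path, cfg = search_config(),
                           out = NULL) {
  db <- Biostrings::readAAStringSet(db_path)
  if (length(db) == 0L) stop("empty reference database: ", db_path)
  names(db) <- sub("[[:space:]].*$", "", names(db))
  db_chr <- as.character(db)
  n_db_residues <- sum(nchar(db_chr))

  reads <- read_reads(reads_path)
  too_short <- Biostrings::width(reads) < 3L * cfg$seed_k
  if (any(too_short))
    message(sum(too_short), " read(s) shorter than ", 3L * cfg$seed_k,
            " nt skipped")
  reads <- reads[!too_short]

  # subject seed index: reduced k-mer -> subject indices
  subj_kmers <- lapply(db_chr, reduced_kmers, k = cfg$seed_k)
  seed_index <- split(rep(seq_along(db_chr), lengths(subj_kmers)),
                      unlist(subj_kmers, use.names = FALSE))

  # collect candidate (frame, subject) pairs over all reads
  frames_set <- six_frames_all(reads)
  frame_read <- attr(frames_set, "read")
  frame_chr <- as.character(frames_set)
  cands <- lapply(frame_chr, function(s) {
    km <- reduced_kmers(s, cfg$seed_k)
    unique(unlist(seed_index[km[km %in% names(seed_index)]],
                  use.names = FALSE))
  })
  cand_frame <- rep(seq_along(cands), lengths(cands))
  cand_subj <- unlist(cands, use.names = FALSE)
  groups <- stats::setNames(list(), character(0))
  if (length(cand_frame) > 0L) {
    rows <- vector("list", length(unique(cand_subj)))
    ri <- 0L
    for (s in unique(cand_subj)) {
      fidx <- cand_frame[cand_subj == s]
      aln <- Biostrings::pairwiseAlignment(
        frames_set[fidx], db[[s]], type = "local",
        substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1)
      sc <- Biostrings::score(aln)
      ok <- sc > 0
      if (!any(ok)) next
      aln_len <- Biostrings::nchar(aln)[ok]
      ni <- Biostrings::nindel(aln)
      gaps <- (Biostrings::insertion(ni)[, "Length"] +
               Biostrings::deletion(ni)[, "Length"])[ok]
      pat <- Biostrings::pattern(aln)
      sub <- Biostrings::subject(aln)
      m_len <- Biostrings::width(frames_set[fidx])[ok]
      bits <- (KA_LAMBDA * sc[ok] - log(KA_K)) / log(2)
      log10e <- log10(m_len * n_db_residues) - bits * log10(2)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        query_id = names(reads)[frame_read[fidx][ok]],
        subject_id = names(db)[s],
        pct_identity = Biostrings::pid(aln)[ok],
        aln_length = aln_len,
        mismatches = Biostrings::nmismatch(aln)[ok],
        gap_open = as.integer(gaps),
        qstart = Biostrings::start(pat)[ok], qend = Biostrings::end(pat)[ok],
        sstart = Biostrings::start(sub)[ok], send = Biostrings::end(sub)[ok],
        log10_evalue = log10e, bit_score = round(bits, 1),
        stringsAsFactors = FALSE)
    }
    hits <- do.call(rbind, rows[seq_len(ri)])
    if (!is.null(hits) && nrow(hits) > 0L) {
      hits <- hits[hits$log10_evalue <= cfg$log10_evalue_cutoff, , drop = FALSE]
      # best frame per (query, subject)
      hits <- canonical_hit_order(hits)
      hits <- hits[!duplicated(paste0(hits$query_id, "\r", hits$subject_id)), ,
                   drop = FALSE]
      qorder <- intersect(names(reads), unique(hits$query_id))
      groups <- lapply(qorder, function(q) {
        g <- canonical_hit_order(hits[hits$query_id == q, , drop = FALSE])
        g <- utils::head(g, cfg$max_hits)
        g$rank <- seq_len(nrow(g))
        rownames(g) <- NULL
        g
      })
      names(groups) <- qorder
    }
  }
  if (!is.null(out)) write_m8(groups, out, dialect = "rapsearch2")
  invisible(groups)
}
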