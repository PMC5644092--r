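# BH/NLH extraction and paired-end combination.

make_tab <- function(n_taxa = 8, n_lineages = 4) {
  ids <- paste0("tk", seq_len(n_taxa))
  lins <- paste0("L", ((seq_len(n_taxa) - 1) %% n_lineages) + 1)
  prot <- setNames(replicate(n_taxa, rand_prot(30)), paste0(ids, "|p1"))
  ref <- write_ref(prot, tiny_taxa(ids, lins))
  load_taxonomy(ref$fasta, ref$taxonomy)
}

test_that("extract_bh_nlh picks the BH and the first different-lineage hit", {
  set.seed(6)
  tab <- make_tab()
  # single hit: NLH absent
  g1 <- hit_group_from_lineages("q", "tk1")
  a1 <- extract_bh_nlh(g1, tab)
  expect_equal(a1$bh_subject, "tk1|p1")
  expect_true(is.na(a1$nlh_subject))
  expect_equal(a1$n_hits_seen, 1L)

  # ranks 2-3 share the BH lineage and are skipped; NLH is rank 4
  # tk1 and tk5 share L1; tk2 is L2; tk3 is L3
  g2 <- hit_group_from_lineages("q", c("tk1", "tk5", "tk1", "tk2", "tk3"))
  a2 <- extract_bh_nlh(g2, tab)
  expect_equal(a2$bh_lineage, "L1")
  expect_equal(a2$nlh_subject, g2$subject_id[4L])
  expect_equal(a2$nlh_lineage, "L2")
  expect_gte(a2$nlh_log10e, a2$bh_log10e)

  # empty group -> NULL; unresolvable subject -> error naming it
  expect_null(extract_bh_nlh(g1[0, ], tab))
  g3 <- hit_group_from_lineages("q", c("tk1", "ghost"))
  expect_error(extract_bh_nlh(g3, tab), "ghost")
})

test_that("extract_bh_nlh agrees with the linear-scan oracle on random tables", {
  set.seed(7)
  tab <- make_tab(n_taxa = 10, n_lineages = 5)
  lin_of <- setNames(tab$taxa$lineage, tab$taxa$taxon_id)
  for (i in 1:300) {
    n <- sample(1:20, 1)
    taxa <- sample(tab$taxa$taxon_id, n, replace = TRUE)
    g <- hit_group_from_lineages("q", taxa)
    a <- extract_bh_nlh(g, tab)
    o <- oracle_bh_nlh(unname(lin_of[taxa]))
    expect_equal(a$bh_subject, g$subject_id[o$bh])
    if (is.na(o$nlh)) {
      expect_true(is.na(a$nlh_subject))
    } else {
      expect_equal(a$nlh_subject, g$subject_id[o$nlh])
    }
  }
})

test_that("output is invariant under appending worse same-lineage hits", {
  set.seed(8)
  tab <- make_tab()
  g <- hit_group_from_lineages("q", c("tk1", "tk2", "tk3"),
                               log10e = c(-20, -10, -5))
  a <- extract_bh_nlh(g, tab)
  extra <- hit_group_from_lineages("q", c("tk1", "tk5"), log10e = c(-2, -1))
  extra$rank <- 4:5
  g2 <- rbind(g, extra)
  a2 <- extract_bh_nlh(g2, tab)
  expect_equal(a2$bh_subject, a$bh_subject)
  expect_equal(a2$nlh_subject, a$nlh_subject)
})

test_that("combine_pairs implements best and concordant modes", {
  set.seed(9)
  tab <- make_tab()
  fwd <- extract_bh_nlh(hit_group_from_lineages("q", c("tk1", "tk2"),
                                                log10e = c(-8, -2)), tab)
  rev <- extract_bh_nlh(hit_group_from_lineages("q", c("tk2", "tk3"),
                                                log10e = c(-3, -1)), tab)
  # best: lower log10 E wins; missing mate yields the other
  expect_equal(combine_pairs(fwd, rev, pair_policy("best"))$bh_subject,
               fwd$bh_subject)
  expect_equal(combine_pairs(NULL, rev, pair_policy("best"))$bh_subject,
               rev$bh_subject)
  expect_null(combine_pairs(NULL, NULL, pair_policy("best")))
  # tie on E: higher bit score wins
  f2 <- fwd; r2 <- rev
  f2$bh_log10e <- r2$bh_log10e <- -5
  f2$bh_bitscore <- 40; r2$bh_bitscore <- 60
  expect_equal(combine_pairs(f2, r2, pair_policy("best"))$bh_subject,
               r2$bh_subject)
  # concordant: different lineages -> none
  expect_null(combine_pairs(fwd, rev, pair_policy("concordant")))
  # concordant agreement keeps the better mate
  rev_same <- extract_bh_nlh(hit_group_from_lineages("q", c("tk5", "tk2"),
                                                     log10e = c(-4, -2)), tab)
  got <- combine_pairs(fwd, rev_same, pair_policy("concordant"))
  expect_equal(got$bh_subject, fwd$bh_subject)  # both L1; fwd has lower E
  # single present mate: strict -> none; allow_single -> kept
  expect_null(combine_pairs(fwd, NULL, pair_policy("concordant")))
  expect_equal(combine_pairs(fwd, NULL,
                             pair_policy("concordant", allow_single = TRUE))$bh_subject,
               fwd$bh_subject)
})

test_that("combine_pairs(best) is commutative and matches a brute-force scan", {
  set.seed(10)
  tab <- make_tab(n_taxa = 10, n_lineages = 5)
  policy_b <- pair_policy("best")
  policy_c <- pair_policy("concordant")
  for (i in 1:200) {
    mk <- function() {
      if (runif(1) < 0.15) return(NULL)
      n <- sample(1:5, 1)
      extract_bh_nlh(hit_group_from_lineages("q",
        sample(tab$taxa$taxon_id, n, replace = TRUE)), tab)
    }
    fwd <- mk(); rev <- mk()
    got_b <- combine_pairs(fwd, rev, policy_b)
    swp_b <- combine_pairs(rev, fwd, policy_b)
    # commutative up to the documented tie-break
    if (!is.null(got_b))
      expect_equal(got_b$bh_subject, swp_b$bh_subject)
    else expect_null(swp_b)
    # brute-force oracle for concordant
    got_c <- combine_pairs(fwd, rev, policy_c)
    expect_c <- if (is.null(fwd) || is.null(rev)) NULL
      else if (fwd$bh_lineage != rev$bh_lineage) NULL
      else if (fwd$bh_log10e < rev$bh_log10e) fwd
      else if (rev$bh_log10e < fwd$bh_log10e) rev
      else if (fwd$bh_bitscore >= rev$bh_bitscore) fwd else rev
    if (is.null(expect_c)) expect_null(got_c)
    else expect_equal(got_c$bh_subject, expect_c$bh_subject)
  }
})

test_that("map_hits returns one row per query with hits", {
  set.seed(11)
  tab <- make_tab()
  groups <- list(qa = hit_group_from_lineages("qa", c("tk1", "tk2")),
                 qb = hit_group_from_lineages("qb", "tk3"))
  a <- map_hits(groups, tab)
  expect_equal(nrow(a), 2L)
  expect_setequal(a$query_id, c("qa", "qb"))
  expect_equal(nrow(map_hits(list(), tab)), 0L)
})
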