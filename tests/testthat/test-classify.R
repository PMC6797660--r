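test_that("global alignment scores match an independent dynamic program", {
  set_test_seed(4)
  p <- alignment_params()
  for (rep in 1:20) {
    n1 <- sample(8:30, 1); n2 <- sample(8:30, 1)
    q <- random_nucleotides(n1); r <- random_nucleotides(n2)
    got <- align_global(q, r, p)$score
    want <- oracle_align_score(q, r, p$match, p$mismatch, p$gap_open,
                               p$gap_extend, p$frameshift_penalty)
    expect_equal(got, want, info = paste(q, r))
  }
})

test_that("alignment handles the textbook cases", {
  p <- alignment_params()
  set_test_seed(40)
  seqA <- random_nucleotides(60)
  a <- align_global(seqA, seqA, p)
  expect_equal(a$score, nchar(seqA) * p$match)
  expect_false(grepl("-", a$query))
  # interior 1-bp deletion in the query -> exactly one gap column
  del <- paste0(substring(seqA, 1, 29), substring(seqA, 31))
  b <- align_global(del, seqA, p)
  expect_equal(lengths(regmatches(b$query, gregexpr("-", b$query))), 1)
  expect_false(grepl("-", b$reference))
  expect_error(align_global("", seqA), "empty")
})

test_that("in-frame gaps in codon repeats do not spawn frameshift calls", {
  # two glutamine runs differing by 4 codons: gaps must stay 3-periodic
  mk <- function(nq) paste0("ATGGATCGATCGTTC", strrep("CAA", nq),
                            "TTCGATCGATCGTAA")
  aln <- align_global(mk(10), mk(14))
  expect_equal(nrow(detect_frameshifts(aln)), 0)
})

test_that("TE insertions are excised, restoring the original translation", {
  lib <- default_te_library()
  ch <- cached_cohort(301, 9, p_stop_gain = 0, p_frameshift = 0,
                      p_truncation_5 = 0, p_truncation_3 = 0,
                      p_te_insertion = 0, p_gap = 0)
  g <- ch$genes[[1]]
  at <- 300
  with_te <- paste0(substring(g, 1, at), lib[["Sabrina"]], substring(g, at + 1))
  res <- detect_te_insertions(with_te, lib)
  expect_equal(nrow(res$events), 1)
  expect_identical(res$events$kind, "TE_insertion")
  expect_match(res$events$detail, "Sabrina")
  expect_equal(nchar(res$excised), nchar(g))
  expect_identical(res$excised, g)
  # no library hits: pass-through
  none <- detect_te_insertions(g, lib)
  expect_equal(nrow(none$events), 0)
  expect_identical(none$excised, g)
})

test_that("nested TE insertions resolve to the pre-insertion protein", {
  lib <- default_te_library()
  ch <- cached_cohort(301, 9, p_stop_gain = 0, p_frameshift = 0,
                      p_truncation_5 = 0, p_truncation_3 = 0,
                      p_te_insertion = 0, p_gap = 0)
  g <- ch$genes[[2]]
  outer_at <- 400
  one <- paste0(substring(g, 1, outer_at), lib[["Ada"]],
                substring(g, outer_at + 1))
  # second element inserted inside the first
  inner_at <- outer_at + 150
  two <- paste0(substring(one, 1, inner_at), lib[["Fatima"]],
                substring(one, inner_at + 1))
  res <- detect_te_insertions(two, lib)
  expect_identical(res$excised, g)
  expect_identical(translate_cds(res$excised, "read_through_mark"),
                   translate_cds(g, "read_through_mark"))
})

test_that("terminal truncations are called from unaligned reference ends", {
  set_test_seed(5)
  ref <- random_nucleotides(400)
  q5 <- substring(ref, 101)          # missing first 100 bp
  ev <- detect_truncations(align_global(q5, ref))
  expect_identical(ev$kind, "deletion_5prime")
  full <- detect_truncations(align_global(ref, ref))
  expect_equal(nrow(full), 0)
  q3 <- substring(ref, 1, 320)       # missing last 80 bp
  ev3 <- detect_truncations(align_global(q3, ref))
  expect_identical(ev3$kind, "deletion_3prime")
})

test_that("frameshift calls follow indel length mod 3", {
  set_test_seed(6)
  ref <- random_nucleotides(240)
  ins1 <- paste0(substring(ref, 1, 100), "G", substring(ref, 101))
  expect_equal(nrow(detect_frameshifts(align_global(ins1, ref))), 1)
  del3 <- paste0(substring(ref, 1, 99), substring(ref, 103))
  expect_equal(nrow(detect_frameshifts(align_global(del3, ref))), 0)
  # 2-bp deletion then a distant 1-bp deletion -> two events
  d2 <- paste0(substring(ref, 1, 60), substring(ref, 63))
  d21 <- paste0(substring(d2, 1, 170), substring(d2, 172))
  ev <- detect_frameshifts(align_global(d21, ref))
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$kind == "frameshift"))
})

test_that("premature stop detection excludes the terminal stop", {
  ev <- detect_premature_stops("ATGCAATAACAGTGA")
  expect_equal(nrow(ev), 1)
  expect_identical(ev$stop_codon_seq, "TAA")
  expect_equal(ev$position, 3)  # 1-based codon index
  expect_true(ev$next_to_Q)
  # intact simulated gene: no events
  ch <- cached_cohort(301, 9, p_stop_gain = 0, p_frameshift = 0,
                      p_truncation_5 = 0, p_truncation_3 = 0,
                      p_te_insertion = 0, p_gap = 0)
  expect_equal(nrow(detect_premature_stops(ch$genes[[1]])), 0)
})

test_that("k injected stop gains give exactly k events with mechanism flags", {
  cfg <- sim_config(seed = 77, n_genes = 30, p_frameshift = 0,
                    p_truncation_5 = 0, p_truncation_3 = 0,
                    p_te_insertion = 0, p_gap = 0)
  ch <- simulate_cohort(cfg)
  for (id in names(ch$genes)) {
    tr <- ch$truth[[id]]
    k <- sum(tr$events$kind == "stop_codon")
    res <- classify_gene(ch$genes[id],
                         references = c(ref = tr$intact_cds))
    st <- res$events[res$events$kind == "stop_codon", ]
    expect_equal(nrow(st), k)
    if (k > 0) {
      expect_true(all(st$stop_codon_seq %in% c("TAA", "TAG")))
      expect_true(all(st$q_to_stop_transition))
      expect_equal(sort(st$position),
                   sort(tr$events$position[tr$events$kind == "stop_codon"]))
    }
  }
})

test_that("stop context flags adjacency and the C-to-T mechanism", {
  ctx <- stop_context("GCTCAATAACAGGCT", 3)
  expect_true(ctx$next_to_Q)
  ctx2 <- stop_context("GCTGCTTGAGCTGCT", 3, reference = "GCTGCTCGAGCTGCT")
  expect_false(ctx2$q_to_stop_transition)  # TGA has no C->T path from CAA/CAG
  ctx3 <- stop_context("GCTGCTTAAGCTGCT", 3, reference = "GCTGCTCAAGCTGCT")
  expect_true(ctx3$q_to_stop_transition)
  expect_error(stop_context("ATGTAA", 5), "out of range")
  expect_error(stop_context("ATGGCTTAA", 1), "not a stop")
})

test_that("exactly {TAA, TAG} are reachable from a Q codon by one C->T", {
  # exhaustive enumeration over all 64 codons
  bases <- c("A", "C", "G", "T")
  all_codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  reachable <- character(0)
  for (codon in c("CAA", "CAG")) {
    for (pos in 1:3) {
      if (substring(codon, pos, pos) == "C") {
        mutated <- codon
        substring(mutated, pos, pos) <- "T"
        if (mutated %in% c("TAA", "TAG", "TGA"))
          reachable <- c(reachable, mutated)
      }
    }
  }
  expect_setequal(reachable, c("TAA", "TAG"))
  # and no other codon among the 64 is one C->T from a Q codon and a stop
  others <- setdiff(all_codons, c("TAA", "TAG"))
  for (codon in others) {
    for (pos in 1:3) {
      reverted <- codon
      substring(reverted, pos, pos) <- "C"
      if (substring(codon, pos, pos) == "T" &&
          reverted %in% c("CAA", "CAG")) {
        expect_false(codon %in% c("TAA", "TAG", "TGA"))
      }
    }
  }
})

test_that("an engineered frameshift + 8-stop gene reproduces its row", {
  # reference: 120 safe codons; mutant: 8 stops (5 next to Q) + 1-bp deletion
  set_test_seed(8)
  safe <- c("GCT", "ACT", "GGT", "TCT", "CTT", "ATT", "GAT", "CCA")
  codons <- c("ATG", sample(safe, 118, replace = TRUE), "TGA")
  # 5 stops adjacent to a glutamine codon, 3 isolated
  q_adj <- c(10, 20, 30, 40, 50)
  iso <- c(65, 75, 85)
  for (i in q_adj) codons[i + 1] <- "CAA"
  ref <- paste(codons, collapse = "")
  mut <- codons
  for (i in q_adj) mut[i] <- "TAA"
  for (i in iso) mut[i] <- "TAG"
  mut_seq <- paste(mut, collapse = "")
  mut_seq <- paste0(substring(mut_seq, 1, 300), substring(mut_seq, 302))
  res <- classify_gene(c("Sim-A12" = mut_seq), references = c(ref = ref))
  expect_identical(res$row$status, "pseudogene")
  expect_setequal(res$row$mutation_types[[1]], c("frameshift", "stop_codon"))
  expect_equal(res$row$n_stop, 8)
  expect_equal(res$row$n_stop_next_to_Q, 5)
})

test_that("catalogue rows conserve their event counts", {
  ch <- cached_cohort(42, 15)
  cc <- classify_cohort(ch$genes, te_library = default_te_library())
  ev <- attr(cc, "events")
  for (i in seq_len(nrow(cc))) {
    stops <- ev[[cc$gene_id[i]]]
    stops <- stops[stops$kind == "stop_codon", ]
    expect_equal(cc$n_stop[i], nrow(stops))
    expect_equal(cc$n_stop_next_to_Q[i], sum(stops$next_to_Q %in% TRUE))
    expect_lte(cc$n_stop_next_to_Q[i], cc$n_stop[i])
    expect_identical(cc$status[i],
                     if (length(ev[[cc$gene_id[i]]]$kind)) "pseudogene"
                     else "intact")
  }
})

test_that("TE excision commutes with classification", {
  lib <- default_te_library()
  cfg <- sim_config(seed = 91, n_genes = 8, p_te_insertion = 0,
                    p_truncation_5 = 0, p_truncation_3 = 0, p_gap = 0,
                    p_frameshift = 0)
  ch <- simulate_cohort(cfg)
  refs <- find_intact_references(ch$genes)
  id <- names(which(vapply(ch$truth, function(t)
    sum(t$events$kind == "stop_codon"), integer(1)) > 0))[1]
  g <- ch$genes[[id]]
  plain <- classify_gene(setNames(g, id), references = refs)
  with_te <- paste0(substring(g, 1, 333), lib[["Manor"]], substring(g, 334))
  inserted <- classify_gene(setNames(with_te, id), references = refs,
                            te_library = lib)
  expect_equal(inserted$row$length_bp, plain$row$length_bp)
  expect_equal(inserted$row$n_stop, plain$row$n_stop)
  expect_setequal(inserted$row$mutation_types[[1]],
                  union(plain$row$mutation_types[[1]], "TE_insertion"))
})

test_that("reference-free and guided stop counts agree without frameshifts", {
  cfg <- sim_config(seed = 55, n_genes = 12, p_frameshift = 0,
                    p_truncation_5 = 0, p_truncation_3 = 0,
                    p_te_insertion = 0, p_gap = 0)
  ch <- simulate_cohort(cfg)
  refs <- find_intact_references(ch$genes)
  for (id in names(ch$genes)) {
    free <- classify_gene(ch$genes[id], references = NULL)
    guided <- classify_gene(ch$genes[id], references = refs)
    expect_equal(guided$row$n_stop, free$row$n_stop, info = id)
  }
})
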