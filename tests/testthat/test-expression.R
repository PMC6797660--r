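test_that("FPKM follows the definition exactly", {
  # 100 reads on a 1000-bp gene with 1e6 total assigned -> FPKM 100
  asg <- list(counts = c(g1 = 100, rest = 999900))
  tab <- fpkm(asg, c(g1 = 1000, rest = 5000))
  expect_equal(tab$fpkm[tab$gene_id == "g1"], 100)
  # single-gene set: FPKM = 1e9 / length
  one <- fpkm(list(counts = c(solo = 42)), c(solo = 1234))
  expect_equal(one$fpkm, 1e9 / 1234)
  # conservation identity: sum fpkm * len * total / 1e9 == total assigned
  set_test_seed(19)
  counts <- c(a = 17, b = 0, c = 523, d = 99)
  lens <- c(a = 900, b = 1200, c = 700, d = 1500)
  tab2 <- fpkm(list(counts = counts), lens)
  expect_equal(sum(tab2$fpkm * tab2$length_bp) * sum(counts) / 1e9,
               sum(counts))
  expect_equal(tab2$fpkm[tab2$gene_id == "b"], 0)
  # zero totals warn and zero out
  expect_warning(z <- fpkm(list(counts = c(a = 0)), c(a = 100)), "no assigned")
  expect_equal(z$fpkm, 0)
})

test_that("assignment thresholds implement the stringent mapping contract", {
  ch <- cached_cohort(301, 9, p_stop_gain = 0, p_frameshift = 0,
                      p_truncation_5 = 0, p_truncation_3 = 0,
                      p_te_insertion = 0, p_gap = 0)
  genes <- ch$genes
  g <- genes[[1]]
  rd <- substring(g, 101, 200)          # exact 100-bp substring
  res <- assign_reads(c(r1 = rd), genes[1])
  expect_equal(unname(res$counts[1]), 1)
  expect_identical(res$assignments$gene_id, names(genes)[1])
  # 2 mismatches = 98% identity: rejected at the 0.99 default
  rd2 <- rd
  substring(rd2, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                    substring(rd, 10, 10))[1]
  substring(rd2, 60, 60) <- setdiff(c("A", "C", "G", "T"),
                                    substring(rd, 60, 60))[1]
  res2 <- assign_reads(c(r1 = rd2), genes[1])
  expect_equal(res2$n_assigned, 0)
  # ...but accepted when the threshold is relaxed to 0.95
  res2b <- assign_reads(c(r1 = rd2), genes[1],
                        mapping_params(min_similarity = 0.95))
  expect_equal(res2b$n_assigned, 1)
  # 1 mismatch = 99% identity passes the default
  rd1 <- rd
  substring(rd1, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                    substring(rd, 10, 10))[1]
  expect_equal(assign_reads(c(r1 = rd1), genes[1])$n_assigned, 1)
  expect_error(assign_reads(c(r1 = rd), character(0)), "empty gene set")
})

test_that("reads from two related genes go to their true source", {
  # two genes at ~95% mutual identity, error-free reads
  set_test_seed(20)
  g1 <- random_nucleotides(1000)
  g2 <- mutate_bases(g1, 50)
  genes <- c(g1 = g1, g2 = g2)
  starts <- sample(1:900, 2000, replace = TRUE)
  src <- sample(c("g1", "g2"), 2000, replace = TRUE)
  reads <- setNames(substring(genes[src], starts, starts + 99),
                    paste0("r", 1:2000))
  res <- assign_reads(reads, genes)
  hit <- match(res$assignments$read_id, names(reads))
  agree <- res$assignments$gene_id == src[hit]
  expect_gte(mean(agree), 0.99)
  expect_gte(res$n_assigned / 2000, 0.9)
})

test_that("raising min_similarity never increases assigned counts", {
  set_test_seed(21)
  ch <- cached_cohort(13, 10, n_reads = 2000L)
  reads <- simulate_reads(ch$genes, ch$truth, ch$config)
  prev <- NULL
  for (sim in c(0.90, 0.95, 0.99)) {
    cnt <- assign_reads(reads, ch$genes,
                        mapping_params(min_similarity = sim))$counts
    if (!is.null(prev)) expect_true(all(cnt <= prev + 1e-9))
    prev <- cnt
  }
})

test_that("ambiguous-read policies behave as declared", {
  # a read matching a region shared verbatim by two genes
  set_test_seed(22)
  common <- random_nucleotides(200)
  genes <- c(x = paste0(common, random_nucleotides(400)),
             y = paste0(common, random_nucleotides(400)))
  rd <- c(amb = substring(common, 50, 149))
  d <- assign_reads(rd, genes, mapping_params(ambiguous_policy = "discard"))
  expect_equal(d$n_assigned, 0)
  s <- assign_reads(rd, genes, mapping_params(ambiguous_policy = "split"))
  expect_equal(unname(s$counts), c(0.5, 0.5))
  r <- assign_reads(rd, genes, mapping_params(ambiguous_policy = "random"),
                    seed = 5)
  expect_equal(d$n_reads, 1)
  expect_equal(sum(r$counts), 1)
  # with discard, every read is counted at most once
  ch <- cached_cohort(13, 10, n_reads = 2000L)
  reads <- simulate_reads(ch$genes, ch$truth, ch$config)
  res <- assign_reads(reads, ch$genes)
  expect_lte(res$n_assigned, length(reads))
  expect_true(all(res$assignments$weight == 1))
  expect_false(any(duplicated(res$assignments$read_id)))
})

test_that("expression reports depress pseudogene FPKM and flag classes", {
  ch <- cached_cohort(13, 10, n_reads = 2000L)
  reads <- simulate_reads(ch$genes, ch$truth, ch$config)
  res <- assign_reads(reads, ch$genes)
  tab <- fpkm(res, ch$genes)
  status <- vapply(ch$truth, `[[`, character(1), "status")
  cat_df <- data.frame(gene_id = names(status), genome = "A",
                       length_bp = nchar(ch$genes),
                       n_stop = 0L, n_stop_next_to_Q = 0L,
                       status = unname(status), stringsAsFactors = FALSE)
  cat_df$mutation_types <- lapply(status, function(s)
    if (s == "pseudogene") "stop_codon" else character(0))
  rep <- expression_report(tab, cat_df)
  expect_lt(rep$summary$mean_fpkm_pseudogene, rep$summary$mean_fpkm_intact)
  expect_equal(sum(rep$table$read_share), 1)
  # all reads from one gene -> share 100%
  solo <- fpkm(list(counts = c(g = 50)), c(g = 500))
  rep2 <- expression_report(solo, data.frame(
    gene_id = "g", genome = "A", length_bp = 500L, n_stop = 0L,
    n_stop_next_to_Q = 0L, status = "intact",
    mutation_types = I(list(character(0)))))
  expect_equal(rep2$table$read_share, 1)
  # orphan ids are named in the error
  expect_error(expression_report(solo, cat_df), "g")
})
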