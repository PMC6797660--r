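test_that("translation follows the standard code under both stop policies", {
  expect_identical(translate_cds("CAACAGTAA", "read_through_mark"), "QQ*")
  expect_identical(translate_cds("ATGTAA", "truncate_at_stop"), "M")
  expect_error(translate_cds("ATGA", "read_through_mark"), "divisible")
  expect_error(translate_cds(""), "non-empty")
  expect_warning(out <- translate_cds("ATGNNN", "read_through_mark"), "X")
  expect_identical(out, "MX")
  # length conservation on a random 300-codon CDS
  set_test_seed(2)
  cds <- random_nucleotides(900)
  expect_equal(nchar(translate_cds(cds, "read_through_mark")), 300)
})

test_that("find_orf returns the longest ATG-initiated ORF on + strand", {
  # designed: 60-codon and 90-codon ORFs, the longer wins
  orf1 <- paste0("ATG", strrep("GCT", 58), "TAA")
  orf2 <- paste0("ATG", strrep("ACT", 88), "TGA")
  gene <- paste0("CCCC", orf1, "GGGG", orf2, "TTTT")
  hit <- find_orf(c(g = gene))
  expect_equal(hit$start, 4 + nchar(orf1) + 4)
  expect_equal(hit$end, hit$start + nchar(orf2))
  expect_equal((hit$end - hit$start) / 3, 90)
  # absence is a valid result
  expect_null(find_orf(strrep("N", 500)))
  expect_null(find_orf(paste0("ATG", strrep("GCT", 10), "TAA")))  # < min codons
})

test_that("simulator-designed ORF spans the whole CDS", {
  ch <- cached_cohort(301, 9, p_stop_gain = 0, p_frameshift = 0,
                      p_truncation_5 = 0, p_truncation_3 = 0,
                      p_te_insertion = 0, p_gap = 0)
  g <- ch$genes[1]
  hit <- find_orf(g)
  expect_equal(hit$start, 0)
  expect_equal(hit$end, unname(nchar(g)))
})

test_that("poly-Q segmentation finds designed runs and profiles them", {
  prot <- paste0(strrep("M", 20),            # stand-in signal peptide
                 "VRVPPSNP", strrep("Q", 9), # poly-Q I of 9
                 "NIPWDE", strrep("Q", 6),   # poly-Q II of 6
                 "SFRPLEAGIFGTN")
  seg <- segment_domains(prot)
  pq <- polyq_profile(prot, seg, strrep("NNN", nchar(prot)))
  expect_equal(pq$nQ_polyQ_I, 9)
  expect_equal(pq$nQ_polyQ_II, 6)
  kinds <- seg$features$kind
  expect_identical(kinds, c("signal_peptide", "repetitive_domain", "polyQ_I",
                            "unique_I", "polyQ_II", "c_terminal"))
  # intervals ordered, non-overlapping, within the protein
  expect_true(all(diff(as.vector(rbind(seg$features$start,
                                       seg$features$end))) >= 0))
  expect_lte(max(seg$features$end), nchar(prot))
})

test_that("run merging absorbs one interruption flanked by 3+ Q", {
  prot <- paste0(strrep("M", 20), "ASDF", "QQQQPQQQQ", "WENI", strrep("Q", 5),
                 "SFRPLEAGIFGTN")
  seg <- segment_domains(prot)
  pq <- polyq_profile(prot, seg, strrep("NNN", nchar(prot)))
  expect_equal(pq$nQ_polyQ_I, 8)  # 4 + 4 across the single P
  expect_equal(pq$nQ_polyQ_II, 5)
})

test_that("segmentation equals brute-force Q-run enumeration without merging", {
  set_test_seed(3)
  params <- segmentation_params(max_interruptions = 0)
  for (rep in 1:100) {
    prot <- paste0(strrep("A", params$signal_len),
                   random_protein(150, alphabet = c("Q", "P", "S", "N", "G")))
    # oracle: maximal pure-Q runs of length >= 5 after the signal peptide
    m <- gregexpr("Q{5,}", substring(prot, params$signal_len + 1))[[1]]
    runs <- if (m[1] == -1) integer(0) else attr(m, "match.length")
    seg <- try(suppressWarnings(segment_domains(prot, params)), silent = TRUE)
    if (length(runs) == 0) {
      expect_s3_class(seg, "try-error")
      next
    }
    pq <- suppressWarnings(polyq_profile(prot, seg, strrep("NNN", nchar(prot))))
    expect_equal(pq$nQ_polyQ_I, runs[1])
    expect_equal(pq$nQ_polyQ_II, if (length(runs) > 1) runs[2] else 0)
  }
})

test_that("glutamine codon fraction is exact codon counting", {
  cds <- paste0("ATG", "CAA", "CAG", "CAA", "CAG", "GCT", "GCT", "GCT",
                "GCT", "TGA")  # 4 Q codons of 10
  prot <- translate_cds(cds, "read_through_mark")
  seg <- suppressWarnings(try(segment_domains(prot), silent = TRUE))
  # use a minimal hand-built segmentation-free check via a zero-Q protein too
  expect_equal(sum(gliadinkit:::.split_codons(cds) %in% c("CAA", "CAG")) / 10,
               0.4)
  # through the public API on a simulated gene
  ch <- cached_cohort(301, 9, p_stop_gain = 0, p_frameshift = 0,
                      p_truncation_5 = 0, p_truncation_3 = 0,
                      p_te_insertion = 0, p_gap = 0)
  g <- ch$genes[[1]]
  p <- translate_cds(g, "read_through_mark")
  sg <- segment_domains(p)
  pq <- polyq_profile(p, sg, g)
  codons <- substring(g, seq(1, nchar(g) - 2, 3), seq(3, nchar(g), 3))
  expect_equal(pq$q_fraction_cds, mean(codons %in% c("CAA", "CAG")))
  # zero-Q protein profiles to zero
  prot0 <- paste0(strrep("M", 20), strrep("ASDFGW", 20))
  expect_error(segment_domains(prot0), "poly-Q")
})

test_that("poly-Q counts never exceed the protein's total Q count", {
  ch <- cached_cohort(301, 9, p_stop_gain = 0, p_frameshift = 0,
                      p_truncation_5 = 0, p_truncation_3 = 0,
                      p_te_insertion = 0, p_gap = 0)
  for (g in ch$genes) {
    p <- translate_cds(g, "read_through_mark")
    sg <- segment_domains(p)
    pq <- polyq_profile(p, sg, g)
    totQ <- sum(strsplit(p, "")[[1]] == "Q")
    expect_lte(pq$nQ_polyQ_I + pq$nQ_polyQ_II, totQ)
  }
})

test_that("terminal motifs are literal substrings at the stated offsets", {
  tm <- terminal_motifs("ABCDEFGHIJK")
  expect_identical(tm$first4, "ABCD")
  expect_identical(tm$last7, "EFGHIJK")
  expect_error(terminal_motifs("SHORTPEP"), "shorter")
  # simulator proteins end in GIFGTN like A-genome alpha-gliadins
  ch <- cached_cohort(301, 9, p_stop_gain = 0, p_frameshift = 0,
                      p_truncation_5 = 0, p_truncation_3 = 0,
                      p_te_insertion = 0, p_gap = 0)
  p <- translate_cds(ch$genes[[1]], "read_through_mark")
  mature <- substring(sub("\\*$", "", p), 21)
  tm2 <- terminal_motifs(mature)
  expect_match(tm2$last7, "GIFGTN$")
  expect_identical(tm2$first4, substring(mature, 1, 4))
})
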