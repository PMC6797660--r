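test_that("exact epitope occurrences are found with positions", {
  prot <- c(p1 = paste0("MKTA", "PFPQPQLPY", "SSSS"))
  hits <- scan_protein(prot, max_mismatch = 0)
  expect_equal(nrow(hits), 1)
  expect_identical(hits$epitope_name, "DQ2.5-Glia-a1a")
  expect_equal(hits$start, 4)
  expect_equal(hits$mismatches, 0)
  # epitope-free protein
  expect_equal(nrow(scan_protein(strrep("A", 50))), 0)
  # shorter than a window
  expect_equal(nrow(scan_protein("PFPQ")), 0)
})

test_that("the P-to-T variant is reported only at one mismatch", {
  prot <- c(p1 = paste0("GGGG", "PTPQPQLPY", "GGGG"))
  expect_equal(nrow(scan_protein(prot, max_mismatch = 0)), 0)
  hits <- scan_protein(prot, max_mismatch = 1)
  a1a <- hits[hits$epitope_name == "DQ2.5-Glia-a1a", ]
  expect_equal(nrow(a1a), 1)
  expect_equal(a1a$mismatches, 1)
  expect_identical(a1a$mutated_residues, "1:F>T")
})

test_that("sliding-window brute force agrees on random proteins", {
  set_test_seed(10)
  eps <- default_epitopes()
  for (rep in 1:100) {
    prot <- random_protein(60, alphabet = c("P", "Q", "L", "Y", "F", "R", "S"))
    for (mm in 0:1) {
      got <- scan_protein(prot, eps, max_mismatch = mm)
      want <- brute_scan(prot, eps, mm)
      if (is.null(want) || !nrow(got)) {
        expect_equal(nrow(got), if (is.null(want)) 0 else nrow(want))
      } else {
        got_key <- sort(paste(got$epitope_name, got$start, got$mismatches))
        want_key <- sort(paste(want$epitope_name, want$start, want$mismatches))
        expect_identical(got_key, want_key)
      }
    }
  }
})

test_that("scan at zero mismatches is a subset of one mismatch", {
  set_test_seed(11)
  for (rep in 1:20) {
    prot <- random_protein(80, alphabet = c("P", "Q", "L", "Y", "F", "R"))
    h0 <- scan_protein(prot, max_mismatch = 0)
    h1 <- scan_protein(prot, max_mismatch = 1)
    k0 <- paste(h0$epitope_name, h0$start)
    k1 <- paste(h1$epitope_name, h1$start)
    expect_true(all(k0 %in% k1))
  }
})

test_that("hits are invariant to renaming and shift under padding", {
  prot <- paste0("SSS", "PQPQLPYPQ", "SSS")
  h1 <- scan_protein(c(a = prot))
  h2 <- scan_protein(c(zzz = prot))
  expect_equal(h1$start, h2$start)
  padded <- paste0(strrep("G", 7), prot)
  h3 <- scan_protein(c(a = padded))
  expect_equal(h3$start, h1$start + 7)
  expect_equal(nrow(h3), nrow(h1))
})

test_that("the canonical 33-mer region yields one six-hit cluster", {
  region <- "LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF"
  expect_equal(nchar(region), 33)
  hits <- scan_protein(c(p = region), max_mismatch = 0)
  expect_equal(nrow(hits), 6)
  expect_equal(length(unique(hits$epitope_name)), 3)
  cl <- detect_clusters(hits)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_overlapping_hits, 6)
  expect_lte(cl$end - cl$start, 33)
})

test_that("an isolated hit never forms a cluster", {
  hits <- scan_protein(c(p = paste0("GGGG", "PFPQPQLPY", "GGGG")))
  expect_equal(nrow(detect_clusters(hits)), 0)
})

test_that("cluster calls agree with exhaustive sub-chain enumeration", {
  set_test_seed(12)
  oracle_clusters <- function(hits, window_len = 33, min_hits = 6,
                              min_distinct = 2) {
    hits <- hits[hits$mismatches == 0, , drop = FALSE]
    hits <- hits[order(hits$start, hits$epitope_name), , drop = FALSE]
    n <- nrow(hits)
    keep <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j < i) next
      sub <- hits[i:j, , drop = FALSE]
      ok_chain <- all(diff(sub$start) < 9)
      span <- max(sub$start + 9) - min(sub$start)
      if (ok_chain && span <= window_len && nrow(sub) >= min_hits &&
          length(unique(sub$epitope_name)) >= min_distinct)
        keep[[length(keep) + 1]] <- c(i, j)
    }
    # maximal only
    maximal <- Filter(function(a) !any(vapply(keep, function(b)
      (b[1] <= a[1] && b[2] >= a[2]) && !identical(a, b), logical(1))), keep)
    length(maximal)
  }
  proteins <- c(
    paste0("LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF"),
    paste0("SSS", "PFPQPQLPY", "SSS", "PFPQPQLPY", "SSS"),
    paste0(strrep("PQPQLPYPQ", 4), "GG"),
    paste0("PFPQPQLPYPQPQLPYPQ", strrep("S", 10), "PYPQPQLPYPQ"))
  for (p in proteins) {
    hits <- scan_protein(c(x = p), max_mismatch = 0)
    got <- nrow(detect_clusters(hits))
    expect_equal(got, oracle_clusters(hits), info = p)
  }
})

test_that("profiles aggregate per-protein hits and flag planted epitopes", {
  ch <- cached_cohort(301, 9, p_stop_gain = 0, p_frameshift = 0,
                      p_truncation_5 = 0, p_truncation_3 = 0,
                      p_te_insertion = 0, p_gap = 0)
  prots <- vapply(ch$genes, function(g) translate_cds(g, "truncate_at_stop"),
                  character(1))
  prof <- epitope_profile(prots)
  # A-genome-style planting: every protein carries a1a and a3 exactly once
  expect_true(all(prof$counts[, "DQ2.5-Glia-a1a"] == 1))
  expect_true(all(prof$counts[, "DQ2.5-Glia-a3"] == 1))
  # aggregation identity: counts equal scan_protein totals
  for (id in names(prots)) {
    hits <- scan_protein(prots[id], max_mismatch = 0)
    for (ep in default_epitopes()$name) {
      expect_equal(unname(prof$counts[id, ep]),
                   sum(hits$epitope_name == ep))
    }
  }
  # epitope-free protein profiles to zero
  prof0 <- epitope_profile(c(none = strrep("GA", 40)))
  expect_true(all(prof0$counts == 0))
})

test_that("epitope configs load from YAML and JSON", {
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("- name: DQ8-Glia-a1", "  class: DQ8",
               "  sequence: QGSVQPQQL"), y)
  eps <- read_epitope_config(y)
  expect_equal(nrow(eps), 1)
  expect_identical(eps$class, "DQ8")
  j <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"name":"E1","class":"DQ2.5","sequence":"PFPQPQLPY"}]', j)
  eps2 <- read_epitope_config(j)
  expect_identical(eps2$sequence, "PFPQPQLPY")
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("- name: short", "  sequence: PFP"), bad)
  expect_error(read_epitope_config(bad), "9 residues")
})
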