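## Synthetic alpha-gliadin data with full ground truth.
##
## Genes follow the canonical two-poly-Q prolamin architecture: signal
## peptide, repetitive domain (with optional planted CD epitopes), poly-Q I
## built from CAA/CAG codons, a short unique domain, poly-Q II, and a
## conserved C-terminal domain ending in GIFGTN. Mutation events emulate
## the catalogued pseudogenization mechanisms: C->T stop gains at glutamine
## codons, frameshift indels, terminal truncations, TE insertions and
## unassembled (N-run) gaps; per-gene event probabilities default to the
## frequencies observed in the wild emmer catalogue (28/40 genes with
## stops, 7/40 frameshifts, 8/40 5' deletions, 2/40 3' deletions, ~4/40 TE
## insertions, 2/40 gaps). Background divergence between family members is
## injected as synonymous third-position substitutions only, so every truth
## label (domain lengths, planted epitopes, poly-Q counts) survives it.

.SIG_PEPTIDE <- "MKTFLILALLAIVATTATTA"                      # 20 aa, starts M
.N_TERM <- "VRVP"
.FILLER_UNIT <- "PSNPGT"   # glutamine/tyrosine-free: cannot extend poly-Q runs
                           # or complete an epitope across a junction
.UNIQUE_I <- "NIQVDPSGEVQWPQELIPCMDVVLS"
.C_TERM <- "SFRPSQLNPQAQGSVQPQELPQFEEIRNLALETLPAMCNVYIPPHCSTTIAPFGIFGTN"

# fixed reverse-translation table (Q handled separately with CAA/CAG bias)
.AA2CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTC",
               G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
               M = "ATG", N = "AAT", P = "CCA", Q = "CAA", R = "AGA",
               S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

# codons whose third position is four-fold degenerate: safe targets for
# synonymous background substitutions
.FOURFOLD_PREFIX <- c("GC", "CC", "AC", "GT", "CT", "TC", "GG", "CG")

#' Simulation configuration
#'
#' Defaults are the package's standing study conditions; see the methods
#' vignette for the provenance of each value.
#'
#' @param seed Mandatory integer seed.
#' @param n_genes Cohort size.
#' @param polyq1_range,polyq2_range Integer ranges the poly-Q I / II lengths
#'   are drawn from.
#' @param q_caa_prob Probability that a glutamine codon is CAA (vs CAG).
#' @param planted_epitopes Epitope 9-mers embedded in the repetitive domain.
#' @param n_filler_range Range of filler repeat counts per spacer block.
#' @param syn_sub_rate Per-fourfold-codon probability of a synonymous
#'   third-position substitution. This sets the background divergence
#'   between family members (~90-95% pairwise nucleotide identity at the
#'   default), the regime in which stringent 99%-identity read mapping can
#'   separate paralogs; it never alters the encoded protein, so poly-Q
#'   counts, planted epitopes and domain truth survive it.
#' @param p_stop_gain,p_frameshift,p_truncation_5,p_truncation_3,p_te_insertion,p_gap
#'   Per-gene event probabilities.
#' @param stop_gain_extra_mean Poisson mean for stop gains beyond the first.
#' @param te_library Named TE sequences (default [default_te_library()]).
#' @param intact_baseline Relative transcript abundance of an intact gene.
#' @param delta Pseudogene abundance multiplier in `[0, 1]` (the
#'   NMD-depression factor).
#' @param read_length,n_reads,error_rate Read-simulation settings
#'   (single-end, substitution errors only).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genes = 40L,
                       polyq1_range = c(9L, 30L),
                       polyq2_range = c(6L, 16L),
                       q_caa_prob = 2 / 3,
                       planted_epitopes = c("PFPQPQLPY", "FRPQQPYPQ"),
                       n_filler_range = c(2L, 4L),
                       syn_sub_rate = 0.3,
                       p_stop_gain = 0.7,
                       stop_gain_extra_mean = 1.1,
                       p_frameshift = 0.175,
                       p_truncation_5 = 0.2,
                       p_truncation_3 = 0.05,
                       p_te_insertion = 0.1,
                       p_gap = 0.05,
                       te_library = default_te_library(),
                       intact_baseline = 1,
                       delta = 0.1,
                       read_length = 100L,
                       n_reads = 50000L,
                       error_rate = 0.005) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  rates <- c(p_stop_gain, p_frameshift, p_truncation_5, p_truncation_3,
             p_te_insertion, p_gap, syn_sub_rate, error_rate, delta)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]", call. = FALSE)
  if (polyq1_range[1L] < 1L || polyq2_range[1L] < 1L ||
      diff(polyq1_range) < 0L || diff(polyq2_range) < 0L)
    stop("infeasible poly-Q ranges", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

#' Default synthetic TE library
#'
#' Five synthetic elements of 150-600 bp with short terminal-repeat
#' decorations. The labels (Ada, Manor, Sabrina, Fatima, Inga) are
#' mnemonics for wheat TE families; the sequences themselves are synthetic
#' and deterministic.
#'
#' @return Named character vector of 5 elements.
#' @export
default_te_library <- function() {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(987654L)
  lens <- c(Ada = 420L, Manor = 300L, Sabrina = 600L, Fatima = 150L,
            Inga = 520L)
  out <- vapply(lens, function(n) {
    tir <- paste(sample(c("A", "C", "G", "T"), 12L, replace = TRUE),
                 collapse = "")
    body <- paste(sample(c("A", "C", "G", "T"), n - 24L, replace = TRUE),
                  collapse = "")
    paste0(tir, body, tir)
  }, character(1))
  out
}

.rev_translate <- function(protein, q_caa_prob, q_stream = NULL) {
  aa <- strsplit(protein, "")[[1L]]
  codons <- unname(.AA2CODON[aa])
  isQ <- aa == "Q"
  if (any(isQ)) {
    if (is.null(q_stream)) {
      codons[isQ] <- ifelse(stats::runif(sum(isQ)) < q_caa_prob, "CAA", "CAG")
    } else {
      # genes of one family share ancestral codon choices: the r-th Q run
      # reads the r-th row of the cohort stream from its start, so
      # homologous glutamine positions carry the same CAA/CAG codon
      r <- rle(isQ)
      run_id <- 0L
      pos <- 1L
      for (seg in seq_along(r$lengths)) {
        len <- r$lengths[seg]
        if (r$values[seg]) {
          run_id <- run_id + 1L
          take <- pmin(seq_len(len), ncol(q_stream))
          codons[pos:(pos + len - 1L)] <-
            q_stream[pmin(run_id, nrow(q_stream)), take]
        }
        pos <- pos + len
      }
    }
  }
  paste(codons, collapse = "")
}

# ancestral Q-codon choices for a cohort: one row per Q run, read from the
# run start
.make_q_stream <- function(q_caa_prob, n_runs = 64L, run_len = 64L) {
  matrix(ifelse(stats::runif(n_runs * run_len) < q_caa_prob, "CAA", "CAG"),
         nrow = n_runs)
}

.apply_synonymous_divergence <- function(cds, rate) {
  codons <- .split_codons(cds)
  pre <- substring(codons, 1L, 2L)
  eligible <- which(pre %in% .FOURFOLD_PREFIX)
  flip <- eligible[stats::runif(length(eligible)) < rate]
  if (length(flip)) {
    third <- substring(codons[flip], 3L, 3L)
    repl <- vapply(third, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    codons[flip] <- paste0(substring(codons[flip], 1L, 2L), repl)
  }
  paste(codons, collapse = "")
}

.sample1 <- function(x) x[sample.int(length(x), 1L)]

#' Simulate one intact alpha-gliadin gene
#'
#' Uses the current RNG stream (callers seed via their config). The CDS
#' starts with ATG, ends with a single terminal stop, and contains no
#' internal stop by construction.
#'
#' @param config A [sim_config()] list.
#' @return List with `cds`, `protein` (no terminal stop mark), and `truth`
#'   (`status = "intact"`, true poly-Q counts, planted epitopes, domain
#'   layout).
#' @export
simulate_intact_gene <- function(config) {
  nfill <- function() .sample1(seq(config$n_filler_range[1L],
                                   config$n_filler_range[2L]))
  rep_dom <- .N_TERM
  for (ep in config$planted_epitopes) {
    rep_dom <- paste0(rep_dom, strrep(.FILLER_UNIT, nfill()), ep)
  }
  rep_dom <- paste0(rep_dom, strrep(.FILLER_UNIT, nfill()))
  nq1 <- .sample1(seq(config$polyq1_range[1L], config$polyq1_range[2L]))
  nq2 <- .sample1(seq(config$polyq2_range[1L], config$polyq2_range[2L]))
  protein <- paste0(.SIG_PEPTIDE, rep_dom, strrep("Q", nq1), .UNIQUE_I,
                    strrep("Q", nq2), .C_TERM)
  cds <- paste0(.rev_translate(protein, config$q_caa_prob,
                               config$q_stream), "TGA")
  cds <- .apply_synonymous_divergence(cds, config$syn_sub_rate)
  truth <- list(status = "intact", events = .empty_events(),
                polyQ_I = nq1, polyQ_II = nq2,
                planted_epitopes = config$planted_epitopes,
                protein_length = nchar(protein))
  list(cds = cds, protein = protein, truth = truth)
}

#' Inject mutation events into an intact gene
#'
#' Event occurrence is Bernoulli per type with the configured per-gene
#' probabilities. Every stop gain targets base 1 of a CAA/CAG codon
#' (C->T, giving TAA/TAG); frameshifts are 1-2 bp indels; truncations cut
#' the 5'/3' ends; TE insertions splice in a library element; gaps replace
#' a run with `N`. Event sites are chosen inside the retained region and
#' mutually disjoint, so each injected event remains detectable.
#'
#' @param gene Result of [simulate_intact_gene()] (or a list with `cds`).
#' @param config A [sim_config()] list.
#' @return List with mutated `cds` and `truth` (status + injected events).
#' @export
apply_mutations <- function(gene, config) {
  cds <- gene$cds
  L <- nchar(cds)
  events <- .empty_events()
  occurs <- function(p) stats::runif(1L) < p
  t5 <- if (occurs(config$p_truncation_5)) sample(50:min(300L, L %/% 3L), 1L) else 0L
  t3 <- if (occurs(config$p_truncation_3)) sample(30:min(200L, L %/% 4L), 1L) else 0L
  lo <- t5 + 30L; hi <- L - t3 - 30L   # interior of the retained region
  used <- integer(0)                   # occupied base positions (1-based)
  claim <- function(from, to) used <<- c(used, from:to)
  free <- function(from, to) from >= lo && to <= hi &&
    !any(seq(from, to) %in% used)
  # stop gains at CAA/CAG codons
  stop_positions <- integer(0)
  if (occurs(config$p_stop_gain)) {
    codons <- .split_codons(cds)
    cand <- which(codons %in% .Q_CODONS)
    cand <- cand[3L * cand - 2L >= lo & 3L * cand <= hi]
    k <- min(1L + stats::rpois(1L, config$stop_gain_extra_mean), length(cand))
    if (k > 0L) {
      idx <- sort(cand[sample.int(length(cand), k)])
      for (i in idx) {
        b <- 3L * i - 2L
        claim(b, b + 2L)
        stop_positions <- c(stop_positions, b)
        events <- rbind(events, .event(
          "stop_codon", i, detail = "injected C->T stop gain",
          stop_codon_seq = sub("^C", "T", substring(cds, b, b + 2L)),
          next_to_Q = NA, q_to_stop_transition = TRUE))
      }
    }
  }
  pick_site <- function(width) {
    for (try in seq_len(200L)) {
      p <- sample(seq(lo, hi - width), 1L)
      if (free(p, p + width - 1L)) return(p)
    }
    NA_integer_
  }
  fs <- NULL
  if (occurs(config$p_frameshift)) {
    w <- sample(1:2, 1L)
    p <- pick_site(w + 2L)
    if (!is.na(p)) {
      fs <- list(pos = p, width = w, insert = occurs(0.5))
      claim(p, p + w + 1L)
      events <- rbind(events, .event(
        "frameshift", p - 1L,
        detail = sprintf("injected %d bp %s", w,
                         if (fs$insert) "insertion" else "deletion")))
    }
  }
  te <- NULL
  if (occurs(config$p_te_insertion) && length(config$te_library)) {
    p <- pick_site(4L)
    if (!is.na(p)) {
      nm <- sample(names(config$te_library), 1L)
      te <- list(pos = p, name = nm, seq = config$te_library[[nm]])
      claim(p, p + 3L)
      events <- rbind(events, .event("TE_insertion", p - 1L, detail = nm))
    }
  }
  gap <- NULL
  if (occurs(config$p_gap)) {
    w <- sample(15:40, 1L)
    p <- pick_site(w)
    if (!is.na(p)) {
      gap <- list(pos = p, width = w)
      claim(p, p + w - 1L)
      events <- rbind(events, .event("gap", p - 1L,
                                     detail = sprintf("%d bp N run", w)))
    }
  }
  if (t5 > 0L) events <- rbind(events, .event("deletion_5prime", 0L,
                                              detail = sprintf("%d bp", t5)))
  if (t3 > 0L) events <- rbind(events, .event("deletion_3prime", L - t3,
                                              detail = sprintf("%d bp", t3)))
  # apply edits from 3' to 5' so earlier coordinates stay valid
  seq <- cds
  if (t3 > 0L) seq <- substring(seq, 1L, nchar(seq) - t3)
  edit_at <- function(seq, pos, f) {
    paste0(substring(seq, 1L, pos - 1L), f(), substring(seq, pos, nchar(seq)))
  }
  ops <- list()
  if (!is.null(te)) ops[[length(ops) + 1L]] <- list(pos = te$pos, type = "te")
  if (!is.null(gap)) ops[[length(ops) + 1L]] <- list(pos = gap$pos, type = "gap")
  if (!is.null(fs)) ops[[length(ops) + 1L]] <- list(pos = fs$pos, type = "fs")
  for (sp in stop_positions)
    ops[[length(ops) + 1L]] <- list(pos = sp, type = "stop")
  if (length(ops)) {
    ord <- order(vapply(ops, `[[`, numeric(1), "pos"), decreasing = TRUE)
    for (op in ops[ord]) {
      if (op$type == "te") {
        seq <- edit_at(seq, op$pos, function() te$seq)
      } else if (op$type == "gap") {
        seq <- paste0(substring(seq, 1L, op$pos - 1L),
                      strrep("N", gap$width),
                      substring(seq, op$pos + gap$width, nchar(seq)))
      } else if (op$type == "fs") {
        if (fs$insert) {
          ins <- paste(sample(c("A", "C", "G", "T"), fs$width, replace = TRUE),
                       collapse = "")
          seq <- edit_at(seq, op$pos, function() ins)
        } else {
          seq <- paste0(substring(seq, 1L, op$pos - 1L),
                        substring(seq, op$pos + fs$width, nchar(seq)))
        }
      } else if (op$type == "stop") {
        codon <- substring(seq, op$pos, op$pos + 2L)
        seq <- paste0(substring(seq, 1L, op$pos - 1L), sub("^C", "T", codon),
                      substring(seq, op$pos + 3L, nchar(seq)))
      }
    }
  }
  if (t5 > 0L) seq <- substring(seq, t5 + 1L, nchar(seq))
  status <- if (nrow(events)) "pseudogene" else "intact"
  truth <- gene$truth
  truth$status <- status
  truth$events <- events
  list(cds = seq, truth = truth)
}

#' Simulate a cohort of genes with ground truth
#'
#' Seeds the RNG from `config$seed`, generates `n_genes` intact genes and
#' passes each through [apply_mutations()]. The first 60% of ids carry an
#' A-genome suffix, the rest a B-genome suffix.
#'
#' @param config A [sim_config()] list.
#' @return List with `genes` (named CDS vector), `truth` (per-gene truth
#'   list), and `config`.
#' @export
simulate_cohort <- function(config) {
  set.seed(as.integer(config$seed))
  if (is.null(config$q_stream))
    config$q_stream <- .make_q_stream(config$q_caa_prob)
  nA <- ceiling(config$n_genes * 0.6)
  ids <- c(paste0("Sim-A", seq_len(nA)),
           if (config$n_genes > nA) paste0("Sim-B", seq_len(config$n_genes - nA)))
  genes <- character(config$n_genes)
  truth <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    g <- simulate_intact_gene(config)
    m <- apply_mutations(g, config)
    genes[i] <- m$cds
    truth[[i]] <- m$truth
    truth[[i]]$intact_cds <- g$cds
    truth[[i]]$protein <- g$protein
  }
  names(genes) <- ids
  names(truth) <- ids
  list(genes = genes, truth = truth, config = config)
}

.random_bg <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Simulate a locus: genes separated by TE-bearing intergenic spacers
#'
#' @param config A [sim_config()] list.
#' @param locus_id Sequence id for the assembled locus.
#' @return List with `seq` (locus string), `features` (gene and TE
#'   intervals), `genes`, and `truth`.
#' @export
simulate_locus <- function(config, locus_id = "locus") {
  cohort <- simulate_cohort(config)
  parts <- character(0)
  feats <- NULL
  pos <- 0L
  add_spacer <- function(pos, feats, parts) {
    n_te <- sample(1:3, 1L)
    spacer <- .random_bg(sample(300:800, 1L))
    for (t in seq_len(n_te)) {
      nm <- sample(names(config$te_library), 1L)
      at <- sample(seq_len(nchar(spacer)), 1L)
      te <- config$te_library[[nm]]
      feats <- rbind(feats, data.frame(
        seq_id = locus_id, start = pos + at - 1L,
        end = pos + at - 1L + nchar(te), strand = "+", kind = "TE",
        label = nm, stringsAsFactors = FALSE))
      spacer <- paste0(substring(spacer, 1L, at - 1L), te,
                       substring(spacer, at, nchar(spacer)))
    }
    list(pos = pos + nchar(spacer), feats = feats,
         parts = c(parts, spacer))
  }
  for (i in seq_along(cohort$genes)) {
    sp <- add_spacer(pos, feats, parts)
    pos <- sp$pos; feats <- sp$feats; parts <- sp$parts
    g <- cohort$genes[[i]]
    feats <- rbind(feats, data.frame(
      seq_id = locus_id, start = pos, end = pos + nchar(g), strand = "+",
      kind = "gene", label = names(cohort$genes)[i], stringsAsFactors = FALSE))
    pos <- pos + nchar(g)
    parts <- c(parts, g)
  }
  sp <- add_spacer(pos, feats, parts)
  feats <- sp$feats; parts <- sp$parts
  seq <- paste(parts, collapse = "")
  features <- feature_interval(feats$seq_id, feats$start, feats$end,
                               feats$strand, feats$kind, feats$label)
  list(seq = setNames(seq, locus_id), features = features,
       genes = cohort$genes, truth = cohort$truth)
}

#' Simulate two homologous loci with shared and differential TEs
#'
#' Locus B reuses locus A's gene set under extra synonymous divergence;
#' one designated gene pair shares an identical intra-CDS TE at the same
#' gene-relative offset (the truth ortholog pair), and a configurable
#' number of intergenic intervals share ordered TE labels.
#'
#' @param config A [sim_config()] list (TE insertion/truncation rates are
#'   ignored here; genes stay intact so the shared TE is the only CDS
#'   lesion).
#' @param n_genes Number of genes per locus.
#' @param shared_gene Index of the gene pair carrying the shared intra-CDS
#'   TE.
#' @return List with `features_a`, `features_b`, `genes_a`, `genes_b`, and
#'   `truth` (the ortholog pair ids).
#' @export
simulate_homologous_loci <- function(config, n_genes = 6L, shared_gene = 3L) {
  set.seed(as.integer(config$seed))
  base <- replicate(n_genes, simulate_intact_gene(config)$cds)
  ids_a <- paste0("LA-g", seq_len(n_genes))
  ids_b <- paste0("LB-g", seq_len(n_genes))
  genes_a <- setNames(base, ids_a)
  genes_b <- setNames(vapply(base, .apply_synonymous_divergence, character(1),
                             rate = 0.05), ids_b)
  te_names <- names(config$te_library)
  shared_te <- te_names[1L]
  te_seq <- config$te_library[[shared_te]]
  offset <- 3L * (nchar(genes_a[[shared_gene]]) %/% 6L)  # same codon-aligned offset
  splice <- function(g, at, te) paste0(substring(g, 1L, at),
                                       te, substring(g, at + 1L, nchar(g)))
  genes_a[[shared_gene]] <- splice(genes_a[[shared_gene]], offset, te_seq)
  genes_b[[shared_gene]] <- splice(genes_b[[shared_gene]], offset, te_seq)
  build <- function(genes, locus_id, spacer_te_labels) {
    feats <- NULL; parts <- character(0); pos <- 0L
    for (i in seq_along(genes)) {
      spacer <- .random_bg(sample(200:400, 1L))
      for (nm in spacer_te_labels[[i]]) {
        at <- nchar(spacer) %/% 2L
        te <- config$te_library[[nm]]
        feats <- rbind(feats, data.frame(
          seq_id = locus_id, start = pos + at, end = pos + at + nchar(te),
          strand = "+", kind = "TE", label = nm, stringsAsFactors = FALSE))
        spacer <- paste0(substring(spacer, 1L, at), te,
                         substring(spacer, at + 1L, nchar(spacer)))
      }
      pos <- pos + nchar(spacer); parts <- c(parts, spacer)
      g <- genes[[i]]
      feats <- rbind(feats, data.frame(
        seq_id = locus_id, start = pos, end = pos + nchar(g), strand = "+",
        kind = "gene", label = names(genes)[i], stringsAsFactors = FALSE))
      # annotate the intra-CDS shared TE
      if (i == shared_gene) {
        feats <- rbind(feats, data.frame(
          seq_id = locus_id, start = pos + offset,
          end = pos + offset + nchar(te_seq), strand = "+", kind = "TE",
          label = shared_te, stringsAsFactors = FALSE))
      }
      pos <- pos + nchar(g); parts <- c(parts, g)
    }
    list(features = feature_interval(feats$seq_id, feats$start, feats$end,
                                     feats$strand, feats$kind, feats$label),
         seq = paste(parts, collapse = ""))
  }
  # differential intergenic TEs: distinct single labels per locus
  lab_a <- lapply(seq_len(n_genes), function(i) te_names[2L])
  lab_b <- lapply(seq_len(n_genes), function(i) te_names[3L])
  la <- build(genes_a, "locusA", lab_a)
  lb <- build(genes_b, "locusB", lab_b)
  list(features_a = la$features, features_b = lb$features,
       genes_a = genes_a, genes_b = genes_b,
       truth = list(ortholog_pair = c(ids_a[shared_gene], ids_b[shared_gene]),
                    shared_te = shared_te))
}

#' Simulate single-end reads with NMD-depressed pseudogene abundance
#'
#' Reads are drawn from genes with probability proportional to
#' `abundance * (length - read_length + 1)` where abundance is
#' `intact_baseline` for intact genes and `intact_baseline * delta` for
#' pseudogenes; start positions are uniform and substitution errors occur
#' independently per base.
#'
#' @param genes Named character vector of gene sequences.
#' @param truth Per-gene truth list (for `status`); genes absent from
#'   `truth` count as intact.
#' @param config A [sim_config()] list (uses `seed`, `read_length`,
#'   `n_reads`, `error_rate`, `delta`, `intact_baseline`).
#' @return Named character vector of reads with attributes
#'   `source` (true gene per read) and `expected_reads` (per-gene
#'   expectation).
#' @export
simulate_reads <- function(genes, truth, config) {
  set.seed(as.integer(config$seed) + 1L)
  L <- config$read_length
  usable <- nchar(genes) >= L
  if (any(!usable)) {
    warning("skipping gene(s) shorter than the read length: ",
            paste(names(genes)[!usable], collapse = ", "))
    genes <- genes[usable]
  }
  status <- vapply(names(genes), function(id) {
    t <- truth[[id]]
    if (is.null(t)) "intact" else t$status
  }, character(1))
  ab <- ifelse(status == "pseudogene",
               config$intact_baseline * config$delta, config$intact_baseline)
  w <- ab * (nchar(genes) - L + 1L)
  if (sum(w) == 0) stop("all abundances zero", call. = FALSE)
  prob <- w / sum(w)
  gi <- sample.int(length(genes), config$n_reads, replace = TRUE, prob = prob)
  starts <- floor(stats::runif(config$n_reads) *
                    (nchar(genes)[gi] - L + 1L)) + 1L
  reads <- substring(genes[gi], starts, starts + L - 1L)
  nerr <- stats::rbinom(config$n_reads, L, config$error_rate)
  for (r in which(nerr > 0L)) {
    pos <- sample.int(L, nerr[r])
    chars <- strsplit(reads[r], "")[[1L]]
    chars[pos] <- vapply(chars[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    reads[r] <- paste(chars, collapse = "")
  }
  names(reads) <- sprintf("read%06d", seq_along(reads))
  attr(reads, "source") <- names(genes)[gi]
  attr(reads, "expected_reads") <-
    setNames(config$n_reads * prob, names(genes))
  reads
}
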