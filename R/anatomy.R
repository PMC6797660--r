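## ORF finding, translation and alpha-gliadin domain segmentation.
##
## Alpha-gliadins follow a fixed anatomy: signal peptide, repetitive domain,
## poly-glutamine run I, a short unique (non-repetitive) domain, poly-Q run
## II, and a conserved C-terminal domain (A-genome proteins end in GIFGTN).
## Glutamine is encoded by CAA/CAG only, which is why the poly-Q runs behave
## like codon microsatellites and why a single C->T at the first codon base
## converts a glutamine codon into a TAA/TAG stop.

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.Q_CODONS <- c("CAA", "CAG")

#' Codon tables used throughout the package
#'
#' @return List with `stop_codons`, `glutamine_codons` and the standard
#'   genetic `code` (named character vector, codon -> amino acid, stops as
#'   `*`), taken from [Biostrings::GENETIC_CODE].
#' @export
codon_tables <- function() {
  code <- Biostrings::GENETIC_CODE
  list(stop_codons = .STOP_CODONS, glutamine_codons = .Q_CODONS, code = code)
}

.split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a coding sequence
#'
#' @param cds Nucleotide string (a single sequence; a name, if present, is
#'   carried over to the protein).
#' @param stop_policy `"read_through_mark"` renders every stop codon as
#'   `*` so pseudogene proteins remain alignable (requires length divisible
#'   by 3); `"truncate_at_stop"` stops at the first stop codon and returns
#'   the residues before it.
#' @return Protein string. Codons containing non-ACGT characters translate
#'   to `X` with a warning.
#' @export
translate_cds <- function(cds, stop_policy = c("read_through_mark",
                                               "truncate_at_stop")) {
  stop_policy <- match.arg(stop_policy)
  if (length(cds) != 1L || is.na(cds) || !nzchar(cds))
    stop("cds must be a single non-empty sequence", call. = FALSE)
  seq <- toupper(cds)
  if (stop_policy == "read_through_mark" && nchar(seq) %% 3L != 0L)
    stop("sequence length not divisible by 3 under read_through_mark",
         call. = FALSE)
  codons <- .split_codons(seq)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  if (anyNA(aa)) {
    warning("codon(s) with non-ACGT characters translated to X")
    aa[is.na(aa)] <- "X"
  }
  if (stop_policy == "truncate_at_stop") {
    first_stop <- which(codons %in% .STOP_CODONS)
    if (length(first_stop)) aa <- aa[seq_len(first_stop[1L] - 1L)]
  }
  protein <- paste(aa, collapse = "")
  if (!is.null(names(cds))) names(protein) <- names(cds)
  protein
}

#' Find the longest ORF on the + strand
#'
#' Scans all three frames for ATG-initiated, stop-terminated open reading
#' frames; the longest one wins (leftmost on ties). Input genes are assumed
#' pre-oriented, so only the + strand is examined.
#'
#' @param gene Nucleotide string (named or not).
#' @param min_orf_codons Minimum ORF size in codons (including the stop
#'   codon) below which `NULL` is returned.
#' @return A one-row `feature_interval` of kind `CDS` spanning start codon
#'   through stop codon (0-based half-open), or `NULL` when no qualifying
#'   ORF exists.
#' @export
find_orf <- function(gene, min_orf_codons = 50L) {
  seq <- toupper(gene[[1L]])
  id <- if (!is.null(names(gene))) names(gene)[1L] else "seq"
  n <- nchar(seq)
  best <- NULL
  for (frame in 0:2) {
    codons <- .split_codons(substring(seq, frame + 1L, n))
    if (!length(codons)) next
    stops <- which(codons %in% .STOP_CODONS)
    atgs <- which(codons == "ATG")
    prev_stop <- 0L
    for (st in stops) {
      cand <- atgs[atgs > prev_stop & atgs < st]
      if (length(cand)) {
        len <- st - cand[1L] + 1L  # codons incl. stop
        s0 <- frame + (cand[1L] - 1L) * 3L
        e0 <- frame + st * 3L
        if (is.null(best) || len > best$len) {
          best <- list(len = len, start = s0, end = e0)
        }
      }
      prev_stop <- st
    }
  }
  if (is.null(best) || best$len < min_orf_codons) return(NULL)
  feature_interval(seq_id = id, start = best$start, end = best$end,
                   strand = "+", kind = "CDS", label = paste0(id, "_CDS"))
}

#' Segmentation parameters for alpha-gliadin domain anatomy
#'
#' @param signal_len Signal-peptide length in residues (fixed-length model;
#'   the mature protein starts after it).
#' @param min_run Minimum number of glutamines for a run to qualify as a
#'   poly-Q region.
#' @param max_interruptions Maximum non-Q residues absorbed into a run.
#' @param min_flank Minimum Q count on each side of an absorbed interruption.
#' @return List of class `segmentation_params`.
#' @export
segmentation_params <- function(signal_len = 20L, min_run = 5L,
                                max_interruptions = 1L, min_flank = 3L) {
  structure(list(signal_len = as.integer(signal_len),
                 min_run = as.integer(min_run),
                 max_interruptions = as.integer(max_interruptions),
                 min_flank = as.integer(min_flank)),
            class = "segmentation_params")
}

# Maximal Q-runs with the merging rule: up to `max_interruptions` single
# non-Q residues are absorbed when flanked by >= min_flank Q on both sides.
# Returns data.frame(start, end, nQ) in 0-based half-open protein coords.
.find_q_runs <- function(protein, params) {
  chars <- strsplit(protein, "")[[1L]]
  isQ <- chars == "Q"
  r <- rle(isQ)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values] + 0L)
  if (!nrow(runs)) return(data.frame(start = integer(0), end = integer(0),
                                     nQ = integer(0)))
  # merge across single-residue interruptions
  merged <- runs[1L, , drop = FALSE]
  interruptions <- 0L
  for (i in seq_len(nrow(runs))[-1L]) {
    gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
    left_len <- merged$end[nrow(merged)] - merged$start[nrow(merged)] + 1L
    right_len <- runs$end[i] - runs$start[i] + 1L
    if (gap == 1L && interruptions < params$max_interruptions &&
        left_len >= params$min_flank && right_len >= params$min_flank) {
      merged$end[nrow(merged)] <- runs$end[i]
      interruptions <- interruptions + 1L
    } else {
      merged <- rbind(merged, runs[i, ])
      interruptions <- 0L
    }
  }
  nQ <- vapply(seq_len(nrow(merged)), function(i)
    sum(isQ[merged$start[i]:merged$end[i]]), integer(1))
  data.frame(start = merged$start - 1L, end = merged$end, nQ = nQ)
}

#' Segment an alpha-gliadin protein into its canonical domains
#'
#' Identifies the two poly-Q regions as the first two maximal glutamine runs
#' of at least `min_run` Q after the signal peptide (run merging may absorb
#' isolated non-Q residues, see [segmentation_params()]), and derives the
#' remaining domains from their positions.
#'
#' @param protein Protein string from an intact gene (no internal `*`).
#' @param params A [segmentation_params()] list.
#' @return List of class `domain_segmentation` with a `features` table
#'   (protein coordinates, 0-based half-open), `n_terminal_motif` (first 4
#'   mature residues), `c_terminal_motif` (last 7 residues), and
#'   `polyQ_II_absent` flag.
#' @export
segment_domains <- function(protein, params = segmentation_params()) {
  seq <- protein[[1L]]
  id <- if (!is.null(names(protein))) names(protein)[1L] else "protein"
  if (grepl("\\*", substring(seq, 1L, nchar(seq) - 1L)))
    stop("protein contains internal stop(s); segmentation requires an ",
         "intact gene product", call. = FALSE)
  seq <- sub("\\*$", "", seq)
  n <- nchar(seq)
  if (n <= params$signal_len + 11L)
    stop("protein too short to segment", call. = FALSE)
  runs <- .find_q_runs(seq, params)
  runs <- runs[runs$nQ >= params$min_run & runs$start >= params$signal_len, ,
               drop = FALSE]
  polyQ_II_absent <- nrow(runs) < 2L
  if (nrow(runs) == 0L)
    stop("no qualifying poly-Q run found", call. = FALSE)
  if (polyQ_II_absent)
    warning("fewer than two qualifying poly-Q runs; polyQ_II absent")
  q1 <- runs[1L, ]
  q2 <- if (!polyQ_II_absent) runs[2L, ] else NULL
  rows <- list(
    data.frame(kind = "signal_peptide", start = 0L, end = params$signal_len),
    data.frame(kind = "repetitive_domain", start = params$signal_len,
               end = q1$start),
    data.frame(kind = "polyQ_I", start = q1$start, end = q1$end))
  if (!is.null(q2)) {
    rows <- c(rows, list(
      data.frame(kind = "unique_I", start = q1$end, end = q2$start),
      data.frame(kind = "polyQ_II", start = q2$start, end = q2$end),
      data.frame(kind = "c_terminal", start = q2$end, end = n)))
  } else {
    rows <- c(rows, list(data.frame(kind = "c_terminal", start = q1$end,
                                    end = n)))
  }
  feats <- do.call(rbind, rows)
  feats <- feats[feats$start < feats$end, , drop = FALSE]
  feats$seq_id <- id
  mature <- substring(seq, params$signal_len + 1L, n)
  structure(list(
    features = feats[, c("seq_id", "kind", "start", "end")],
    n_terminal_motif = substring(mature, 1L, 4L),
    c_terminal_motif = substring(seq, n - 6L, n),
    polyQ_II_absent = polyQ_II_absent,
    params = params), class = "domain_segmentation")
}

.seg_interval <- function(seg, kind) {
  f <- seg$features[seg$features$kind == kind, , drop = FALSE]
  if (!nrow(f)) NULL else f
}

#' Poly-glutamine profile of a protein / CDS pair
#'
#' @param protein Protein string.
#' @param seg Its [segment_domains()] result.
#' @param cds The coding sequence the protein was translated from (used for
#'   the glutamine-codon fraction).
#' @return List with `nQ_polyQ_I`, `nQ_polyQ_II`, and `q_fraction_cds`
#'   (fraction of in-frame codons that are CAA/CAG, over all codons of the
#'   CDS including the terminal stop).
#' @export
polyq_profile <- function(protein, seg, cds) {
  seq <- sub("\\*$", "", protein[[1L]])
  np <- nchar(seq)
  ncod <- nchar(cds[[1L]]) %/% 3L
  if (nchar(cds[[1L]]) %% 3L != 0L || !(ncod %in% c(np, np + 1L)))
    stop("protein and CDS lengths are inconsistent", call. = FALSE)
  countQ <- function(kind) {
    f <- .seg_interval(seg, kind)
    if (is.null(f)) return(0L)
    sum(strsplit(substring(seq, f$start + 1L, f$end), "")[[1L]] == "Q")
  }
  codons <- .split_codons(toupper(cds[[1L]]))
  list(nQ_polyQ_I = countQ("polyQ_I"),
       nQ_polyQ_II = countQ("polyQ_II"),
       q_fraction_cds = sum(codons %in% .Q_CODONS) / length(codons))
}

#' Terminal motifs of a mature protein
#'
#' The first four and the last seven residues, the positions highlighted in
#' comparative analyses of mature alpha-gliadins (A-genome proteins end in
#' GIFGTN).
#'
#' @param protein Mature protein string (signal peptide already removed).
#' @return List with `first4` and `last7`.
#' @export
terminal_motifs <- function(protein) {
  seq <- sub("\\*$", "", protein[[1L]])
  n <- nchar(seq)
  if (n < 11L) stop("protein shorter than 11 residues", call. = FALSE)
  list(first4 = substring(seq, 1L, 4L), last7 = substring(seq, n - 6L, n))
}
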