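## Mutation-event detection and intact-vs-pseudogene classification.
##
## A gene is compared to intact full-ORF references by global alignment;
## transposable-element insertions are excised first (catalogue lengths are
## TE-excised lengths), then terminal truncations, internal frameshifts and
## premature stop codons are called. Stop codons are annotated with their
## glutamine context: whether an adjacent in-frame codon encodes Q, and
## whether the stop is explained by a single C->T change at base 1 of a
## CAA/CAG codon in the reference (TAA from CAA, TAG from CAG) -- the
## dominant pseudogenization mechanism in these glutamine-rich genes.

#' Alignment and event-calling parameters
#'
#' @param match,mismatch Per-base alignment scores (mismatch negative).
#' @param gap_open,gap_extend Affine gap penalties (negative).
#' @param frameshift_penalty Extra penalty (negative) charged when an
#'   internal gap run closes at a length that is not a multiple of 3; keeps
#'   in-frame poly-Q/repeat length variation represented as 3-periodic gaps.
#' @param te_min_identity Minimum local identity for a TE call.
#' @param te_min_length Minimum matched length (bp) for a TE call.
#' @param truncation_min_bp Minimum unaligned reference bp at an end to call
#'   a terminal deletion.
#' @param gap_min_n Minimum run of `N` called as an unassembled gap.
#' @param band Alignment band width: cells whose diagonal offset exceeds
#'   the sequence length difference by more than this are skipped (0
#'   disables banding). The default comfortably covers terminal
#'   truncations (absorbed by the length-difference term) plus internal
#'   poly-Q drift; set 0 when comparing sequences with huge unexcised
#'   insertions.
#' @return List of class `alignment_params`.
#' @export
alignment_params <- function(match = 2, mismatch = -3, gap_open = -5,
                             gap_extend = -2, frameshift_penalty = -30,
                             te_min_identity = 0.8,
                             te_min_length = 100L, truncation_min_bp = 15L,
                             gap_min_n = 10L, band = 200L) {
  if (gap_open >= 0 || gap_extend >= 0)
    stop("gap penalties must be negative", call. = FALSE)
  if (te_min_identity <= 0 || te_min_identity > 1)
    stop("te_min_identity must be in (0, 1]", call. = FALSE)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend,
                 frameshift_penalty = frameshift_penalty,
                 te_min_identity = te_min_identity,
                 te_min_length = as.integer(te_min_length),
                 truncation_min_bp = as.integer(truncation_min_bp),
                 gap_min_n = as.integer(gap_min_n),
                 band = as.integer(band)),
            class = "alignment_params")
}

.submat <- function(params) {
  Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                           mismatch = params$mismatch,
                                           baseOnly = FALSE)
}

.pairwise <- function(query, reference, params, type = "global") {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(reference),
    type = type, substitutionMatrix = .submat(params),
    gapOpening = abs(params$gap_open), gapExtension = abs(params$gap_extend))
}

#' Optimal global alignment of two nucleotide sequences
#'
#' Codon-aware Needleman-Wunsch with affine gaps and free end gaps: an
#' internal gap run whose length is not a multiple of 3 pays the extra
#' `frameshift_penalty`, so in-frame length variation (poly-Q and repeat
#' count differences between family members) aligns as 3-periodic gaps and
#' the reading-frame register survives across it; terminal overhangs
#' (truncations) are cost-free. The dynamic-programming tie-break is a
#' fixed state order, so repeated calls give identical alignments.
#'
#' @param query,reference Nucleotide strings.
#' @param params An [alignment_params()] list.
#' @return List of class `pairwise_alignment` with gapped `query` and
#'   `reference` strings and the alignment `score`.
#' @export
align_global <- function(query, reference, params = alignment_params()) {
  q <- toupper(query[[1L]]); r <- toupper(reference[[1L]])
  if (!nzchar(q) || !nzchar(r)) stop("empty sequence", call. = FALSE)
  aln <- .codon_align_cpp(q, r, params$match, params$mismatch,
                          params$gap_open, params$gap_extend,
                          params$frameshift_penalty, params$band)
  structure(list(query = aln$query, reference = aln$reference,
                 score = aln$score),
            class = "pairwise_alignment")
}

.kmer_set <- function(seq, k = 15L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

# shortlist references by shared 15-mers, then let the alignment score
# decide among the top candidates
.select_reference <- function(query, references, params, top = 2L) {
  if (length(references) == 1L) return(1L)
  qk <- .kmer_set(query)
  shared <- vapply(references, function(r) sum(.kmer_set(r) %in% qk),
                   numeric(1))
  cand <- order(shared, decreasing = TRUE)[seq_len(min(top, length(references)))]
  scores <- vapply(cand, function(i)
    .align_score(query, references[[i]], params), numeric(1))
  cand[which.max(scores)]
}

# score-only variant used for reference selection
.align_score <- function(query, reference, params) {
  .codon_align_score_cpp(toupper(query[[1L]]), toupper(reference[[1L]]),
                         params$match, params$mismatch, params$gap_open,
                         params$gap_extend, params$frameshift_penalty)
}

.empty_events <- function() {
  data.frame(kind = character(0), position = integer(0), detail = character(0),
              stop_codon_seq = character(0), next_to_Q = logical(0),
              q_to_stop_transition = logical(0), in_polyq_region = logical(0),
              stringsAsFactors = FALSE)
}

.event <- function(kind, position, detail = "", stop_codon_seq = NA_character_,
                   next_to_Q = NA, q_to_stop_transition = NA,
                   in_polyq_region = NA) {
  data.frame(kind = kind, position = as.integer(position), detail = detail,
             stop_codon_seq = stop_codon_seq, next_to_Q = next_to_Q,
             q_to_stop_transition = q_to_stop_transition,
             in_polyq_region = in_polyq_region, stringsAsFactors = FALSE)
}

#' Detect and excise transposable-element insertions
#'
#' Iterative best-hit excision: the strongest local alignment of any library
#' element covering at least `te_min_length` bp at `te_min_identity` or
#' better is excised, and the scan repeats on the excised sequence. This
#' makes nested insertions resolvable (excising an inner element restores
#' the outer one to contiguity). Overlapping calls collapse into single
#' events whose detail lists all contributing elements.
#'
#' @param gene Nucleotide string (named or not).
#' @param te_library Named character vector of TE sequences (`NULL` or
#'   empty means pass-through).
#' @param params An [alignment_params()] list.
#' @return List with `excised` (the TE-free sequence) and `events`
#'   (`TE_insertion` rows; `position` is the insertion offset in the excised
#'   sequence, 0-based).
#' @export
detect_te_insertions <- function(gene, te_library = NULL,
                                 params = alignment_params()) {
  seq <- toupper(gene[[1L]])
  events <- .empty_events()
  if (is.null(te_library) || !length(te_library))
    return(list(excised = seq, events = events))
  hits <- list()
  # cheap exact-probe screen: a qualifying hit (>= 100 bp at >= 80%
  # identity) almost surely contains one of these sampled 24-mers intact
  probes <- lapply(te_library, function(te) {
    at <- seq(1L, max(nchar(te) - 23L, 1L), by = 40L)
    unique(substring(te, at, at + 23L))
  })
  for (iter in seq_len(50L)) {
    best <- NULL
    for (te_name in names(te_library)) {
      if (!any(vapply(probes[[te_name]], function(p)
        grepl(p, seq, fixed = TRUE), logical(1)))) next
      aln <- .pairwise(te_library[[te_name]], seq, params, type = "local")
      rng <- Biostrings::subject(aln)
      w <- Biostrings::width(rng)
      if (w >= params$te_min_length &&
          Biostrings::pid(aln) / 100 >= params$te_min_identity) {
        sc <- Biostrings::score(aln)
        if (is.null(best) || sc > best$score) {
          best <- list(score = sc, name = te_name,
                       start = Biostrings::start(rng),
                       end = Biostrings::end(rng))
        }
      }
    }
    if (is.null(best)) break
    seq <- paste0(substring(seq, 1L, best$start - 1L),
                  substring(seq, best$end + 1L, nchar(seq)))
    hits[[length(hits) + 1L]] <- list(pos = best$start - 1L, name = best$name)
  }
  if (length(hits)) {
    pos <- vapply(hits, `[[`, numeric(1), "pos")
    nm <- vapply(hits, `[[`, character(1), "name")
    # collapse hits at (near-)identical excised offsets: nested/adjacent copies
    o <- order(pos)
    pos <- pos[o]; nm <- nm[o]
    grp <- cumsum(c(TRUE, diff(pos) > 0))
    for (g in unique(grp)) {
      events <- rbind(events, .event("TE_insertion", pos[grp == g][1L],
                                     detail = paste(nm[grp == g],
                                                    collapse = ",")))
    }
  }
  list(excised = seq, events = events)
}

#' Call terminal truncations from a global alignment
#'
#' At least `truncation_min_bp` of reference left unaligned at an alignment
#' end (a terminal gap run in the query) is called as a 5' or 3' deletion.
#'
#' @param aln A `pairwise_alignment` of a TE-excised gene against an intact
#'   reference.
#' @param params An [alignment_params()] list.
#' @return Event rows (possibly empty).
#' @export
detect_truncations <- function(aln, params = alignment_params()) {
  q <- strsplit(aln$query, "")[[1L]]
  r <- strsplit(aln$reference, "")[[1L]]
  nongap_q <- which(q != "-")
  events <- .empty_events()
  if (!length(nongap_q)) return(events)
  lead <- sum(r[seq_len(nongap_q[1L] - 1L)] != "-")
  trail_idx <- if (nongap_q[length(nongap_q)] < length(q))
    (nongap_q[length(nongap_q)] + 1L):length(q) else integer(0)
  trail <- sum(r[trail_idx] != "-")
  if (lead >= params$truncation_min_bp)
    events <- rbind(events, .event("deletion_5prime", 0L,
                                   detail = sprintf("%d bp of reference missing at 5' end", lead)))
  if (trail >= params$truncation_min_bp)
    events <- rbind(events, .event("deletion_3prime", length(nongap_q),
                                   detail = sprintf("%d bp of reference missing at 3' end", trail)))
  events
}

#' Call frameshifts from a global alignment
#'
#' Within the shared (non-truncated) region, every maximal internal indel
#' whose length is not a multiple of 3 yields one frameshift event; in-frame
#' indels (poly-Q length differences and repeat-count variation) do not.
#'
#' @param aln A `pairwise_alignment`.
#' @return Event rows; `position` is the 0-based query coordinate at the
#'   indel.
#' @export
detect_frameshifts <- function(aln) {
  q <- strsplit(aln$query, "")[[1L]]
  r <- strsplit(aln$reference, "")[[1L]]
  both <- which(q != "-" & r != "-")
  events <- .empty_events()
  if (length(both) < 2L) return(events)
  inner <- both[1L]:both[length(both)]
  qi <- cumsum(q != "-")  # query coordinate after each column
  gap_in <- function(chars) {
    isgap <- chars == "-"
    isgap[-inner] <- FALSE
    isgap
  }
  for (side in c("query", "reference")) {
    isgap <- if (side == "query") gap_in(q) else gap_in(r)
    rl <- rle(isgap)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (i in which(rl$values)) {
      len <- rl$lengths[i]
      if (len %% 3L != 0L) {
        pos <- if (side == "query") qi[starts[i]] else qi[starts[i]] - 1L
        detail <- sprintf("%d bp %s", len,
                          if (side == "query") "deletion" else "insertion")
        events <- rbind(events, .event("frameshift", max(pos, 0L),
                                       detail = detail))
      }
    }
  }
  events[order(events$position), , drop = FALSE]
}

# Project the query of a global alignment onto reference coordinates:
# a character vector of length nchar(reference), '-' where the query has
# no base aligned to that reference position (used by reference_align).
.project_on_reference <- function(aln) {
  q <- strsplit(aln$query, "")[[1L]]
  r <- strsplit(aln$reference, "")[[1L]]
  out <- q[r != "-"]
  out
}

.codon_at <- function(chars, i) paste(chars[(3L * i - 2L):(3L * i)], collapse = "")

#' Glutamine context of a stop codon
#'
#' @param cds In-frame nucleotide string carrying the stop.
#' @param stop_codon_index 1-based codon index of the stop.
#' @param reference Optional in-frame reference string laid out on the same
#'   codon grid (same length), used for the C->T transition call.
#' @return List with `next_to_Q` (an immediately adjacent in-frame codon is
#'   CAA/CAG) and `q_to_stop_transition` (stop is TAA with reference CAA, or
#'   TAG with reference CAG: one C->T at codon base 1).
#' @export
stop_context <- function(cds, stop_codon_index, reference = NULL) {
  chars <- strsplit(toupper(cds[[1L]]), "")[[1L]]
  ncod <- length(chars) %/% 3L
  i <- as.integer(stop_codon_index)
  if (i < 1L || i > ncod) stop("codon index out of range", call. = FALSE)
  codon <- .codon_at(chars, i)
  if (!codon %in% .STOP_CODONS)
    stop("codon at index ", i, " is ", codon, ", not a stop codon",
         call. = FALSE)
  neighbours <- c(if (i > 1L) .codon_at(chars, i - 1L),
                  if (i < ncod) .codon_at(chars, i + 1L))
  next_to_Q <- any(neighbours %in% .Q_CODONS)
  q_to_stop <- FALSE
  if (!is.null(reference)) {
    rchars <- strsplit(toupper(reference[[1L]]), "")[[1L]]
    if (length(rchars) >= 3L * i) {
      rcodon <- .codon_at(rchars, i)
      q_to_stop <- (codon == "TAA" && rcodon == "CAA") ||
        (codon == "TAG" && rcodon == "CAG")
    }
  }
  list(next_to_Q = next_to_Q, q_to_stop_transition = q_to_stop)
}

#' Detect premature (internal) stop codons
#'
#' With a reference alignment, every query base inherits the reference
#' reading-frame phase from the column it aligns to; bases inserted
#' relative to the reference continue the phase of the preceding aligned
#' base (the codon-aware aligner keeps such insertions 3-periodic), so
#' stops are found both downstream of frameshifting indels and inside
#' query-specific poly-Q extensions. Without a reference the TE-excised
#' sequence is read in frame 0. The codon aligned to the reference's
#' terminal stop is never counted.
#'
#' @param cds TE-excised nucleotide string.
#' @param frame_ref Optional `pairwise_alignment` of `cds` against an intact
#'   reference.
#' @return Event rows of kind `stop_codon`; `position` is the 1-based codon
#'   index on the reference grid where available, else the query codon
#'   ordinal.
#' @export
detect_premature_stops <- function(cds, frame_ref = NULL) {
  events <- .empty_events()
  if (is.null(frame_ref)) {
    chars <- strsplit(toupper(cds[[1L]]), "")[[1L]]
    ncod <- length(chars) %/% 3L
    if (ncod < 2L) return(events)
    seqstr <- paste(chars[seq_len(3L * ncod)], collapse = "")
    for (i in seq_len(ncod - 1L)) {
      codon <- .codon_at(chars, i)
      if (codon %in% .STOP_CODONS) {
        ctx <- stop_context(seqstr, i)
        events <- rbind(events, .event("stop_codon", i, detail = "frame 0",
                                       stop_codon_seq = codon,
                                       next_to_Q = ctx$next_to_Q,
                                       q_to_stop_transition = FALSE))
      }
    }
    return(events)
  }
  qc <- strsplit(frame_ref$query, "")[[1L]]
  rc <- strsplit(frame_ref$reference, "")[[1L]]
  refseq <- gsub("-", "", frame_ref$reference)
  ref_ncod <- nchar(refseq) %/% 3L
  ncol_aln <- length(qc)
  ref_pos <- cumsum(rc != "-")
  # reading-frame phase per column: from the reference where aligned,
  # continued through insertions
  phase <- integer(ncol_aln)
  prev <- -1L
  for (k in seq_len(ncol_aln)) {
    if (rc[k] != "-") {
      phase[k] <- (ref_pos[k] - 1L) %% 3L
    } else {
      phase[k] <- (prev + 1L) %% 3L
    }
    prev <- phase[k]
  }
  isq <- qc != "-"
  qb <- qc[isq]                 # query bases in order
  ph <- phase[isq]
  rcod <- ifelse(rc[isq] != "-", (ref_pos[isq] - 1L) %/% 3L + 1L, NA_integer_)
  nq <- length(qb)
  codon_start <- which(ph == 0L)
  codon_start <- codon_start[codon_start + 2L <= nq]
  keep <- ph[codon_start + 1L] == 1L & ph[codon_start + 2L] == 2L
  codon_start <- codon_start[keep]
  q_codon <- function(i) {
    # query codon starting at query-base index i, if phases are 0,1,2
    if (is.na(i) || i < 1L || i + 2L > nq) return(NA_character_)
    if (ph[i] != 0L || ph[i + 1L] != 1L || ph[i + 2L] != 2L)
      return(NA_character_)
    paste(qb[i:(i + 2L)], collapse = "")
  }
  for (i in codon_start) {
    codon <- paste(qb[i:(i + 2L)], collapse = "")
    if (!codon %in% .STOP_CODONS) next
    rci <- rcod[i]
    if (!is.na(rci) && rci >= ref_ncod) next  # reference terminal stop codon
    if (is.na(rci) && i + 5L > nq) next       # query end
    prev_cod <- q_codon(i - 3L)
    next_cod <- q_codon(i + 3L)
    next_to_Q <- any(c(prev_cod, next_cod) %in% .Q_CODONS, na.rm = TRUE)
    q_to_stop <- FALSE
    if (!is.na(rci) && !is.na(rcod[i + 1L]) && !is.na(rcod[i + 2L]) &&
        rcod[i + 1L] == rci && rcod[i + 2L] == rci) {
      ref_codon <- substring(refseq, 3L * rci - 2L, 3L * rci)
      q_to_stop <- (codon == "TAA" && ref_codon == "CAA") ||
        (codon == "TAG" && ref_codon == "CAG")
    }
    pos <- if (!is.na(rci)) rci else (i + 2L) %/% 3L
    events <- rbind(events, .event("stop_codon", pos,
                                   detail = if (is.na(rci))
                                     "query insertion" else "reference frame",
                                   stop_codon_seq = codon,
                                   next_to_Q = next_to_Q,
                                   q_to_stop_transition = q_to_stop))
  }
  events
}

.detect_assembly_gaps <- function(seq, params) {
  events <- .empty_events()
  m <- gregexpr(sprintf("N{%d,}", params$gap_min_n), seq)[[1L]]
  if (m[1L] != -1L) {
    for (k in seq_along(m)) {
      events <- rbind(events, .event("gap", m[k] - 1L,
                                     detail = sprintf("%d bp run of N",
                                                      attr(m, "match.length")[k])))
    }
  }
  events
}

# genes that look like complete, stop-free ORFs: usable as references
.is_full_orf <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L || n < 150L) return(FALSE)
  if (substring(seq, 1L, 3L) != "ATG") return(FALSE)
  codons <- .split_codons(seq)
  if (!codons[length(codons)] %in% .STOP_CODONS) return(FALSE)
  !any(codons[-length(codons)] %in% .STOP_CODONS) && !grepl("N", seq)
}

#' Pick intact full-ORF genes from a set to serve as references
#'
#' @param genes Named character vector of nucleotide sequences.
#' @return The subset that are complete ATG-to-stop ORFs with no internal
#'   stop and no ambiguous bases.
#' @export
find_intact_references <- function(genes) {
  genes[vapply(genes, .is_full_orf, logical(1))]
}

#' Classify one gene as intact or pseudogene
#'
#' Runs the full event-detection cascade: assembly-gap detection (runs of
#' `N`), TE excision, best-reference selection by global alignment score
#' (ties broken by input order), terminal truncations, frameshifts, and
#' premature stop codons with glutamine context. A gene is a pseudogene iff
#' at least one event is detected; the catalogue length is the TE-excised
#' length.
#'
#' @param gene Single named nucleotide sequence.
#' @param references Named character vector of intact reference CDS
#'   (empty/`NULL` switches to reference-free mode: frame-0 stop detection
#'   only).
#' @param te_library Optional named TE library.
#' @param params An [alignment_params()] list.
#' @param seg_params A [segmentation_params()] list (for flagging stops that
#'   fall inside the reference poly-Q regions).
#' @return List with `row` (one-row `gene_catalogue` data.frame) and
#'   `events` (all detected `MutationEvent` rows).
#' @export
classify_gene <- function(gene, references = NULL, te_library = NULL,
                          params = alignment_params(),
                          seg_params = segmentation_params()) {
  id <- if (!is.null(names(gene))) names(gene)[1L] else "gene"
  seq <- toupper(gene[[1L]])
  te <- detect_te_insertions(seq, te_library, params)
  excised <- te$excised
  events <- te$events
  events <- rbind(events, .detect_assembly_gaps(excised, params))
  if (!is.null(references) && length(references)) {
    ref <- references[[.select_reference(excised, references, params)]]
    aln <- align_global(excised, ref, params)
    events <- rbind(events, detect_truncations(aln, params))
    events <- rbind(events, detect_frameshifts(aln))
    stops <- detect_premature_stops(excised, frame_ref = aln)
    if (nrow(stops)) {
      stops$in_polyq_region <- .stops_in_polyq(stops$position, ref, seg_params)
    }
    events <- rbind(events, stops)
  } else {
    events <- rbind(events, detect_premature_stops(excised))
  }
  stops <- events[events$kind == "stop_codon", , drop = FALSE]
  row <- data.frame(gene_id = id, genome = .genome_from_id(id),
                    length_bp = nchar(excised),
                    n_stop = nrow(stops),
                    n_stop_next_to_Q = sum(stops$next_to_Q %in% TRUE),
                    status = if (nrow(events)) "pseudogene" else "intact",
                    stringsAsFactors = FALSE)
  row$mutation_types <- list(sort(unique(events$kind)))
  row <- row[, c("gene_id", "genome", "length_bp", "mutation_types",
                 "n_stop", "n_stop_next_to_Q", "status")]
  class(row) <- c("gene_catalogue", "data.frame")
  list(row = row, events = events)
}

# TRUE for stop codon indices whose residue lies in a reference poly-Q region
.stops_in_polyq <- function(codon_index, reference, seg_params) {
  prot <- translate_cds(reference, "read_through_mark")
  seg <- try(segment_domains(prot, seg_params), silent = TRUE)
  if (inherits(seg, "try-error")) return(rep(NA, length(codon_index)))
  pq <- seg$features[seg$features$kind %in% c("polyQ_I", "polyQ_II"), ,
                     drop = FALSE]
  res <- codon_index - 1L  # 0-based residue position
  vapply(res, function(p) any(p >= pq$start & p < pq$end), logical(1))
}

#' Classify a cohort of genes into a Table-1-style catalogue
#'
#' @param genes Named character vector of nucleotide sequences.
#' @param references Intact reference CDS; `NULL` auto-selects full-ORF
#'   members of `genes` via [find_intact_references()].
#' @param te_library Optional named TE library.
#' @param params,seg_params See [classify_gene()].
#' @param max_references Cap on the number of references scored per gene
#'   (first-come order; keeps cohort runs fast).
#' @return A `gene_catalogue` data.frame (one row per gene) with the
#'   per-gene event tables in `attr(, "events")`.
#' @export
classify_cohort <- function(genes, references = NULL, te_library = NULL,
                            params = alignment_params(),
                            seg_params = segmentation_params(),
                            max_references = 5L) {
  if (is.null(references)) references <- find_intact_references(genes)
  if (length(references) > max_references)
    references <- references[seq_len(max_references)]
  out <- vector("list", length(genes))
  ev <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    res <- classify_gene(genes[i], references = references,
                         te_library = te_library, params = params,
                         seg_params = seg_params)
    out[[i]] <- res$row
    ev[[i]] <- res$events
  }
  cat <- do.call(rbind, out)
  names(ev) <- cat$gene_id
  cat <- .validate_catalogue(cat)
  attr(cat, "events") <- ev
  cat
}
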