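## Celiac-disease T-cell epitope scanning on deduced prolamin proteins.
##
## The scanner slides a 9-residue window over each protein and reports
## windows within a Hamming distance of 0 or 1 of any configured epitope.
## Overlapping-epitope clusters emulate the 33-mer, a highly stimulatory
## region built from six overlapping copies of three epitopes.

#' The four canonical DQ2.5 alpha-gliadin 9-mer epitopes
#'
#' DQ2.5-Glia-a1a (PFPQPQLPY), DQ2.5-Glia-a1b (PYPQPQLPY), DQ2.5-Glia-a2
#' (PQPQLPYPQ) and DQ2.5-Glia-a3 (FRPQQPYPQ). Other epitopes (e.g. the DQ8
#' family) must be supplied via [read_epitope_config()]; no sequences beyond
#' these four are hard-coded.
#'
#' @return data.frame with columns `name`, `class`, `sequence`.
#' @export
default_epitopes <- function() {
  data.frame(
    name = c("DQ2.5-Glia-a1a", "DQ2.5-Glia-a1b", "DQ2.5-Glia-a2",
             "DQ2.5-Glia-a3"),
    class = "DQ2.5",
    sequence = c("PFPQPQLPY", "PYPQPQLPY", "PQPQLPYPQ", "FRPQQPYPQ"),
    stringsAsFactors = FALSE)
}

.validate_epitopes <- function(epitopes) {
  stopifnot(is.data.frame(epitopes),
            all(c("name", "sequence") %in% names(epitopes)))
  if (any(nchar(epitopes$sequence) != 9L))
    stop("epitope sequences must be 9 residues long", call. = FALSE)
  epitopes$sequence <- toupper(epitopes$sequence)
  if (!"class" %in% names(epitopes)) epitopes$class <- NA_character_
  epitopes
}

#' Read an epitope definition config (YAML or JSON)
#'
#' The file holds a list of records with fields `name`, `class`,
#' `sequence` (9 residues each).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return data.frame with columns `name`, `class`, `sequence`.
#' @export
read_epitope_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = FALSE)
         else stop("unsupported epitope config format: .", ext, call. = FALSE)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  df <- do.call(rbind, lapply(raw, function(e)
    data.frame(name = e$name,
               class = if (is.null(e$class)) NA_character_ else e$class,
               sequence = e$sequence, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  .validate_epitopes(df)
}

.empty_hits <- function() {
  data.frame(protein_id = character(0), epitope_name = character(0),
             start = integer(0), mismatches = integer(0),
             mutated_residues = character(0), stringsAsFactors = FALSE)
}

#' Scan one protein for epitope occurrences
#'
#' Every 9-residue window whose Hamming distance to any epitope is at most
#' `max_mismatch` yields one hit; exact matches report `mismatches = 0`.
#' Overlapping occurrences (including of the same epitope) are each
#' reported.
#'
#' @param protein Single named protein string.
#' @param epitopes Epitope table (see [default_epitopes()]).
#' @param max_mismatch 0 or 1 tolerated substitutions.
#' @return data.frame of hits: `protein_id`, `epitope_name`, `start`
#'   (0-based), `mismatches`, `mutated_residues` (semicolon-joined
#'   `pos:ref>obs` with `pos` the 0-based offset inside the epitope).
#' @export
scan_protein <- function(protein, epitopes = default_epitopes(),
                         max_mismatch = 0L) {
  if (!max_mismatch %in% c(0L, 1L))
    stop("max_mismatch must be 0 or 1", call. = FALSE)
  epitopes <- .validate_epitopes(epitopes)
  seq <- toupper(protein[[1L]])
  id <- if (!is.null(names(protein))) names(protein)[1L] else "protein"
  n <- nchar(seq)
  hits <- .empty_hits()
  if (n < 9L) return(hits)
  chars <- strsplit(seq, "")[[1L]]
  epi_chars <- lapply(epitopes$sequence, function(s) strsplit(s, "")[[1L]])
  for (s in 0:(n - 9L)) {
    win <- chars[(s + 1L):(s + 9L)]
    for (e in seq_len(nrow(epitopes))) {
      diff <- which(win != epi_chars[[e]])
      if (length(diff) <= max_mismatch) {
        mut <- if (length(diff))
          paste(sprintf("%d:%s>%s", diff - 1L, epi_chars[[e]][diff],
                        win[diff]), collapse = ";") else ""
        hits <- rbind(hits, data.frame(
          protein_id = id, epitope_name = epitopes$name[e], start = s,
          mismatches = length(diff), mutated_residues = mut,
          stringsAsFactors = FALSE))
      }
    }
  }
  hits
}

#' Detect overlapping-epitope clusters (33-mer-like regions)
#'
#' A cluster is a maximal set of exact hits on one protein such that,
#' sorted by start, consecutive hits overlap; the set spans at most
#' `window_len` residues, contains at least `cluster_min_hits` hits, and
#' involves at least `min_distinct` distinct epitopes. Maximality means no
#' reported set is contained in another.
#'
#' @param hits Exact hits (`mismatches == 0`) from one protein.
#' @param window_len Maximum cluster span in residues.
#' @param cluster_min_hits Minimum number of overlapping hits.
#' @param min_distinct Minimum number of distinct epitopes involved.
#' @return data.frame with `protein_id`, `start`, `end` (0-based half-open
#'   window), `n_overlapping_hits`, `distinct_epitopes` (comma-joined).
#' @export
detect_clusters <- function(hits, window_len = 33L, cluster_min_hits = 6L,
                            min_distinct = 2L) {
  empty <- data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), n_overlapping_hits = integer(0),
                      distinct_epitopes = character(0), stringsAsFactors = FALSE)
  hits <- hits[hits$mismatches == 0L, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  if (length(unique(hits$protein_id)) > 1L)
    stop("detect_clusters expects hits from a single protein", call. = FALSE)
  hits <- hits[order(hits$start, hits$epitope_name), , drop = FALSE]
  n <- nrow(hits)
  cand <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      sub <- hits[i:j, , drop = FALSE]
      if (j > i && any(diff(sub$start) >= 9L)) break  # chain broken
      span <- max(sub$start + 9L) - min(sub$start)
      if (span > window_len) break
      if (nrow(sub) >= cluster_min_hits &&
          length(unique(sub$epitope_name)) >= min_distinct) {
        cand[[length(cand) + 1L]] <- c(i = i, j = j)
      }
    }
  }
  if (!length(cand)) return(empty)
  keep <- rep(TRUE, length(cand))
  for (a in seq_along(cand)) {
    for (b in seq_along(cand)) {
      if (a != b && keep[b] &&
          cand[[b]]["i"] <= cand[[a]]["i"] && cand[[b]]["j"] >= cand[[a]]["j"] &&
          (cand[[b]]["i"] < cand[[a]]["i"] || cand[[b]]["j"] > cand[[a]]["j"])) {
        keep[a] <- FALSE
        break
      }
    }
  }
  do.call(rbind, lapply(cand[keep], function(ij) {
    sub <- hits[ij["i"]:ij["j"], , drop = FALSE]
    data.frame(protein_id = sub$protein_id[1L], start = min(sub$start),
               end = max(sub$start + 9L), n_overlapping_hits = nrow(sub),
               distinct_epitopes = paste(sort(unique(sub$epitope_name)),
                                         collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' Per-protein epitope profile
#'
#' @param proteins Named character vector of proteins.
#' @param epitopes Epitope table.
#' @param window_len,cluster_min_hits,min_distinct Cluster parameters, see
#'   [detect_clusters()].
#' @return List with `counts` (matrix of exact-hit counts, proteins x
#'   epitopes, plus an `n_clusters` column), `mismatch1_hits` (hits found
#'   only at one substitution), and `clusters`.
#' @export
epitope_profile <- function(proteins, epitopes = default_epitopes(),
                            window_len = 33L, cluster_min_hits = 6L,
                            min_distinct = 2L) {
  epitopes <- .validate_epitopes(epitopes)
  ids <- names(proteins)
  if (is.null(ids)) stop("proteins must be named", call. = FALSE)
  counts <- matrix(0L, nrow = length(proteins), ncol = nrow(epitopes),
                   dimnames = list(ids, epitopes$name))
  mm1 <- .empty_hits()
  clusters <- NULL
  ncl <- integer(length(proteins))
  for (i in seq_along(proteins)) {
    exact <- scan_protein(proteins[i], epitopes, max_mismatch = 0L)
    near <- scan_protein(proteins[i], epitopes, max_mismatch = 1L)
    mm1 <- rbind(mm1, near[near$mismatches == 1L, , drop = FALSE])
    if (nrow(exact)) {
      tab <- table(exact$epitope_name)
      counts[i, names(tab)] <- as.integer(tab)
      cl <- detect_clusters(exact, window_len, cluster_min_hits, min_distinct)
      ncl[i] <- nrow(cl)
      clusters <- rbind(clusters, cl)
    }
  }
  list(counts = cbind(counts, n_clusters = ncl), mismatch1_hits = mm1,
       clusters = clusters)
}
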