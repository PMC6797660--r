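## Readers/writers for the external representations shared across the
## pipeline, and the light record types every stage passes around.
##
## Conventions:
##  * sequence sets are named character vectors (names = ids, all upper case),
##    with an optional "descriptions" attribute;
##  * feature tables are data.frames with 0-based half-open [start, end)
##    coordinates; the 1-based inclusive convention appears only on the GFF3
##    boundary;
##  * gene catalogues are data.frames with one row per gene and a list-column
##    of mutation-type keywords.

.NUC_ALPHABET  <- c("A", "C", "G", "T", "N")
.PROT_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*", "X")

.FEATURE_KINDS <- c("gene", "CDS", "TE", "polyQ_I", "polyQ_II", "epitope", "GLR")

.MUTATION_KINDS <- c("stop_codon", "frameshift", "deletion_5prime",
                     "deletion_3prime", "TE_insertion", "gap")

.check_alphabet <- function(seqs, mode) {
  allowed <- if (mode == "nucleotide") .NUC_ALPHABET else .PROT_ALPHABET
  bad <- vapply(seqs, function(s) {
    chars <- unique(strsplit(s, "")[[1]])
    any(!chars %in% allowed)
  }, logical(1))
  if (any(bad)) {
    stop("sequence(s) with characters outside the ", mode, " alphabet: ",
         paste(names(seqs)[bad], collapse = ", "), call. = FALSE)
  }
  invisible(seqs)
}

#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that enforces the
#' pipeline's record invariants: unique non-empty identifiers, non-empty
#' sequences, upper-case letters, and an alphabet consistent with the
#' declared mode.
#'
#' @param path Path to a FASTA file.
#' @param mode `"nucleotide"` (alphabet `A,C,G,T,N`) or `"protein"`
#'   (the 20 amino acids plus `*` and `X`).
#' @return Named character vector of sequences, in file order, with the
#'   full header lines kept in the `"descriptions"` attribute.
#' @export
read_fasta <- function(path, mode = c("nucleotide", "protein")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) stop("FASTA record with empty identifier", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  }
  names(seqs) <- ids
  .check_alphabet(seqs, mode)
  attr(seqs, "descriptions") <- headers
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named", call. = FALSE)
  set <- Biostrings::BStringSet(unname(toupper(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Construct a feature-interval table
#'
#' Intervals use 0-based half-open coordinates; the GFF3 writer converts to
#' 1-based inclusive on output only.
#'
#' @param seq_id,start,end,strand,kind,label Parallel vectors describing the
#'   intervals. `kind` must come from the closed vocabulary
#'   `gene, CDS, TE, polyQ_I, polyQ_II, epitope, GLR`.
#' @return data.frame of class `feature_interval` with those six columns.
#' @export
feature_interval <- function(seq_id, start, end, strand = "+",
                             kind = "gene", label = kind) {
  df <- data.frame(seq_id = as.character(seq_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), kind = as.character(kind),
                   label = as.character(label), stringsAsFactors = FALSE)
  if (any(df$start < 0L) || any(df$start >= df$end))
    stop("intervals must satisfy 0 <= start < end", call. = FALSE)
  if (any(!df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  bad <- setdiff(unique(df$kind), .FEATURE_KINDS)
  if (length(bad))
    stop("unknown feature kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  class(df) <- c("feature_interval", "data.frame")
  df
}

#' Write features as GFF3
#'
#' Internal 0-based half-open intervals are converted to the 1-based
#' inclusive coordinates GFF3 requires; writing is delegated to
#' [rtracklayer::export.gff3()].
#'
#' @param features A `feature_interval` data.frame.
#' @param path Output path.
#' @param seq_lengths Optional named vector of sequence lengths used to
#'   reject out-of-bounds intervals.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(features, path, seq_lengths = NULL) {
  stopifnot(is.data.frame(features))
  if (!is.null(seq_lengths)) {
    len <- seq_lengths[features$seq_id]
    if (any(is.na(len)))
      stop("features reference unknown sequence(s): ",
           paste(unique(features$seq_id[is.na(len)]), collapse = ", "),
           call. = FALSE)
    if (any(features$end > len))
      stop("interval(s) extend beyond sequence bounds on: ",
           paste(unique(features$seq_id[features$end > len]), collapse = ", "),
           call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = features$seq_id,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$type <- features$kind
  S4Vectors::mcols(gr)$ID <- make.unique(features$label, sep = "_")
  S4Vectors::mcols(gr)$Name <- features$label
  S4Vectors::mcols(gr)$source <- "gliadinkit"
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read a GFF3 file back into a feature-interval table
#'
#' @param path Path to a GFF3 file.
#' @return A `feature_interval` data.frame (coordinates converted back to
#'   0-based half-open).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  label <- S4Vectors::mcols(gr)$Name
  if (is.null(label)) label <- as.character(S4Vectors::mcols(gr)$type)
  feature_interval(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    kind = as.character(S4Vectors::mcols(gr)$type),
    label = as.character(label))
}

## --- gene catalogue ---------------------------------------------------------

# Normalise a printed "Types of mutations" phrase to the fixed keyword set.
# Matching is case-insensitive and tolerant of typographic prime variants.
.parse_mutation_phrase <- function(phrase, row_label = "?") {
  raw <- phrase
  x <- tolower(phrase)
  x <- gsub("[′ʹ´`]", "'", x)   # prime variants -> ASCII '
  if (grepl("intact", x)) return(character(0))
  found <- character(0)
  eat <- function(pattern, kinds) {
    if (grepl(pattern, x)) {
      found <<- c(found, kinds)
      x <<- gsub(pattern, " ", x)
    }
  }
  eat("deletions? at both 5' and 3' ends?", c("deletion_5prime", "deletion_3prime"))
  eat("deletions? at (the )?5' ends?", "deletion_5prime")
  eat("deletions? at (the )?3' ends?", "deletion_3prime")
  eat("te insertions?", "TE_insertion")
  eat("frameshifts?", "frameshift")
  eat("stop codons?", "stop_codon")
  eat("gaps?", "gap")
  # direct keyword spellings (as written by write_catalogue_tsv)
  for (k in .MUTATION_KINDS) {
    eat(tolower(k), k)
  }
  leftover <- gsub("[[:space:],;]+|\\band\\b", "", x)
  if (nzchar(leftover))
    stop("unknown mutation keyword in row ", row_label, ": '", raw, "'",
         call. = FALSE)
  unique(found)
}

.genome_from_id <- function(gene_id) {
  g <- rep(NA_character_, length(gene_id))
  g[grepl("-A[0-9]*$", gene_id)] <- "A"
  g[grepl("-B[0-9]*$", gene_id)] <- "B"
  g
}

#' Read a Table-1-style gene catalogue TSV
#'
#' Expected columns: `gene_id`, `length_bp`, `mutation_types`, `n_stop`,
#' `n_stop_next_to_Q`, optionally preceded by an explicit `genome` column
#' (otherwise the genome is inferred from a `-A<k>` / `-B<k>` suffix of the
#' gene id). Blank numeric cells parse as 0; rows whose mutation phrase reads
#' "Intact full-length" get an empty mutation set and `status = "intact"`.
#'
#' @param path Path to the TSV.
#' @return data.frame of class `gene_catalogue` with columns `gene_id`,
#'   `genome`, `length_bp`, `mutation_types` (list-column of keyword
#'   vectors), `n_stop`, `n_stop_next_to_Q`, `status`.
#' @export
read_catalogue_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", fileEncoding = "UTF-8",
                          check.names = FALSE, na.strings = NULL)
  need <- c("gene_id", "length_bp", "mutation_types", "n_stop", "n_stop_next_to_Q")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("catalogue TSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) return(.empty_catalogue())
  num0 <- function(x) {
    x <- trimws(x)
    ifelse(nzchar(x), suppressWarnings(as.integer(x)), 0L)
  }
  types <- lapply(seq_len(nrow(df)), function(i)
    .parse_mutation_phrase(df$mutation_types[i], row_label = df$gene_id[i]))
  genome <- if ("genome" %in% names(df)) trimws(df$genome) else
    .genome_from_id(df$gene_id)
  out <- data.frame(gene_id = trimws(df$gene_id), genome = genome,
                    length_bp = num0(df$length_bp),
                    n_stop = num0(df$n_stop),
                    n_stop_next_to_Q = num0(df$n_stop_next_to_Q),
                    stringsAsFactors = FALSE)
  out$mutation_types <- types
  out$status <- ifelse(lengths(types) == 0L, "intact", "pseudogene")
  out <- out[, c("gene_id", "genome", "length_bp", "mutation_types",
                 "n_stop", "n_stop_next_to_Q", "status")]
  .validate_catalogue(out)
}

.empty_catalogue <- function() {
  out <- data.frame(gene_id = character(0), genome = character(0),
                    length_bp = integer(0), n_stop = integer(0),
                    n_stop_next_to_Q = integer(0), status = character(0),
                    stringsAsFactors = FALSE)
  out$mutation_types <- list()
  out <- out[, c("gene_id", "genome", "length_bp", "mutation_types",
                 "n_stop", "n_stop_next_to_Q", "status")]
  class(out) <- c("gene_catalogue", "data.frame")
  out
}

.validate_catalogue <- function(cat) {
  if (any(duplicated(cat$gene_id)))
    stop("duplicate gene_id in catalogue", call. = FALSE)
  if (any(cat$n_stop_next_to_Q > cat$n_stop))
    stop("n_stop_next_to_Q exceeds n_stop for: ",
         paste(cat$gene_id[cat$n_stop_next_to_Q > cat$n_stop], collapse = ", "),
         call. = FALSE)
  if (any(cat$length_bp <= 0L))
    stop("non-positive length_bp for: ",
         paste(cat$gene_id[cat$length_bp <= 0L], collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(unlist(cat$mutation_types)), .MUTATION_KINDS)
  if (length(bad))
    stop("unknown mutation type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  class(cat) <- unique(c("gene_catalogue", class(cat)))
  cat
}

#' Write a gene catalogue as TSV
#'
#' Mutation-type sets are serialised as comma-joined keywords, so the file
#' round-trips exactly through [read_catalogue_tsv()].
#'
#' @param catalogue A `gene_catalogue` data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_catalogue_tsv <- function(catalogue, path) {
  df <- data.frame(
    gene_id = catalogue$gene_id,
    genome = catalogue$genome,
    length_bp = catalogue$length_bp,
    mutation_types = vapply(catalogue$mutation_types, paste,
                            character(1), collapse = ","),
    n_stop = catalogue$n_stop,
    n_stop_next_to_Q = catalogue$n_stop_next_to_Q,
    stringsAsFactors = FALSE)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Path to the bundled Table-1-style wild emmer catalogue fixture
#'
#' A TSV transcription of the published per-gene mutation catalogue for the
#' wild emmer A- and B-genome alpha-gliadin genes (40 rows).
#'
#' @return File path inside the installed package.
#' @export
wild_emmer_catalogue_path <- function() {
  system.file("extdata", "wild_emmer_table1.tsv", package = "gliadinkit",
              mustWork = TRUE)
}
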