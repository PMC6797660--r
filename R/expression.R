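## Stringent-identity read assignment and FPKM quantification.
##
## The mapping contract: a read is assignable to a gene iff its best
## cost-optimal alignment (mismatch cost 2, indel cost 3 by default) covers
## at least `min_length_fraction` of the read at `min_similarity` identity
## or better; the lowest-cost gene wins and ties are resolved by the
## ambiguous-read policy. FPKM follows the standard definition with one
## single-end read counted as one fragment:
##   fpkm = assigned_reads * 1e9 / (total_assigned * gene_length_bp).

#' Read-mapping parameters
#'
#' @param min_similarity Minimum alignment identity (matches / alignment
#'   columns).
#' @param min_length_fraction Minimum fraction of the read that must be
#'   aligned.
#' @param mismatch_cost,indel_cost Positive alignment costs.
#' @param ambiguous_policy What to do with reads tied between genes:
#'   `"discard"` (default, conservative), `"split"` (fractional counts), or
#'   `"random"` (seeded draw among the tied genes).
#' @return List of class `mapping_params`.
#' @export
mapping_params <- function(min_similarity = 0.99, min_length_fraction = 0.9,
                           mismatch_cost = 2, indel_cost = 3,
                           ambiguous_policy = c("discard", "split", "random")) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  if (min_similarity <= 0 || min_similarity > 1 ||
      min_length_fraction <= 0 || min_length_fraction > 1)
    stop("fractions must be in (0, 1]", call. = FALSE)
  if (mismatch_cost <= 0 || indel_cost <= 0)
    stop("alignment costs must be positive", call. = FALSE)
  structure(list(min_similarity = min_similarity,
                 min_length_fraction = min_length_fraction,
                 mismatch_cost = mismatch_cost, indel_cost = indel_cost,
                 ambiguous_policy = ambiguous_policy),
            class = "mapping_params")
}

#' Assign reads to genes under the stringent mapping contract
#'
#' @param reads Named character vector of read sequences.
#' @param genes Named character vector of gene sequences.
#' @param params A [mapping_params()] list.
#' @param seed Seed for the `"random"` ambiguous policy.
#' @return List with `assignments` (data.frame `read_id`, `gene_id`, `cost`,
#'   `identity`, `weight`) and `counts` (named per-gene read counts;
#'   fractional under `"split"`).
#' @export
assign_reads <- function(reads, genes, params = mapping_params(), seed = 1L) {
  if (!length(genes)) stop("empty gene set", call. = FALSE)
  if (is.null(names(genes))) stop("genes must be named", call. = FALSE)
  read_ids <- if (!is.null(names(reads))) names(reads) else
    paste0("read", seq_along(reads))
  res <- .assign_reads_cpp(toupper(unname(reads)), toupper(unname(genes)),
                           params$min_similarity, params$min_length_fraction,
                           params$mismatch_cost, params$indel_cost, 15L)
  counts <- setNames(numeric(length(genes)), names(genes))
  gene <- res$gene                      # NA = unassignable
  weight <- rep(1, length(reads))
  tied_idx <- which(res$n_best > 1L)
  if (length(tied_idx)) {
    if (params$ambiguous_policy == "discard") {
      gene[tied_idx] <- NA_integer_
    } else if (params$ambiguous_policy == "random") {
      set.seed(as.integer(seed))
      gene[tied_idx] <- vapply(res$tied[tied_idx], function(tg)
        tg[sample.int(length(tg), 1L)], integer(1))
    } else { # split
      weight[tied_idx] <- 1 / res$n_best[tied_idx]
      for (r in tied_idx) {
        counts[res$tied[[r]]] <- counts[res$tied[[r]]] + weight[r]
      }
      gene[tied_idx] <- NA_integer_    # counted above, keep first for table
    }
  }
  hit <- which(!is.na(gene))
  add <- tapply(weight[hit], gene[hit], sum)
  counts[as.integer(names(add))] <- counts[as.integer(names(add))] + add
  table_idx <- if (params$ambiguous_policy == "split")
    sort(c(hit, tied_idx)) else hit
  assignments <- data.frame(
    read_id = read_ids[table_idx],
    gene_id = vapply(table_idx, function(r) {
      if (!is.na(gene[r])) names(genes)[gene[r]] else
        paste(names(genes)[res$tied[[r]]], collapse = ",")
    }, character(1)),
    cost = res$cost[table_idx], identity = res$identity[table_idx],
    weight = weight[table_idx], stringsAsFactors = FALSE)
  list(assignments = assignments, counts = counts,
       n_reads = length(reads), n_assigned = sum(counts))
}

#' FPKM from per-gene read counts
#'
#' @param assignments Result of [assign_reads()] (or any list with a named
#'   `counts` vector).
#' @param genes Named character vector of gene sequences (for lengths), or a
#'   named numeric vector of lengths.
#' @return data.frame of class `expression_table`: `gene_id`,
#'   `assigned_reads`, `length_bp`, `fpkm`.
#' @export
fpkm <- function(assignments, genes) {
  counts <- assignments$counts
  lens <- if (is.numeric(genes)) genes else
    setNames(nchar(genes), names(genes))
  lens <- lens[names(counts)]
  if (anyNA(lens))
    stop("missing gene length(s) for: ",
         paste(names(counts)[is.na(lens)], collapse = ", "), call. = FALSE)
  total <- sum(counts)
  if (total == 0) {
    warning("no assigned reads; all FPKM set to 0")
    vals <- rep(0, length(counts))
  } else {
    vals <- counts * 1e9 / (total * lens)
  }
  out <- data.frame(gene_id = names(counts),
                    assigned_reads = unname(counts),
                    length_bp = unname(lens), fpkm = unname(vals),
                    stringsAsFactors = FALSE)
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Expression report with intact/pseudogene aggregation
#'
#' Joins an expression table with a gene catalogue, flags pseudogene rows
#' (whose transcripts are expected to be depressed by nonsense-mediated
#' decay), and summarises read shares per class.
#'
#' @param records An `expression_table` from [fpkm()].
#' @param catalogue A `gene_catalogue` sharing the same gene ids.
#' @return List with `table` (per-gene, with `status`), and `summary`
#'   (assigned totals, per-class read counts and mean FPKM, pseudogene to
#'   intact mean-FPKM ratio).
#' @export
expression_report <- function(records, catalogue) {
  orphans <- setdiff(records$gene_id, catalogue$gene_id)
  if (length(orphans))
    stop("expression records without catalogue entry: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  tab <- merge(records, catalogue[, c("gene_id", "status")], by = "gene_id",
               sort = FALSE)
  tab$is_pseudogene <- tab$status == "pseudogene"
  total <- sum(tab$assigned_reads)
  share <- if (total > 0) tab$assigned_reads / total else
    rep(0, nrow(tab))
  tab$read_share <- share
  cls_mean <- function(flag) {
    v <- tab$fpkm[tab$is_pseudogene == flag]
    if (length(v)) mean(v) else NA_real_
  }
  summary <- list(
    total_assigned = total,
    reads_intact = sum(tab$assigned_reads[!tab$is_pseudogene]),
    reads_pseudogene = sum(tab$assigned_reads[tab$is_pseudogene]),
    mean_fpkm_intact = cls_mean(FALSE),
    mean_fpkm_pseudogene = cls_mean(TRUE),
    pseudogene_intact_fpkm_ratio =
      if (!is.na(cls_mean(FALSE)) && cls_mean(FALSE) > 0)
        cls_mean(TRUE) / cls_mean(FALSE) else NA_real_)
  list(table = tab, summary = summary)
}
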