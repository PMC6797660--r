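## Catalogue aggregation, locus gene-density metrics, and shared-TE
## orthology between two homologous loci.

#' Summarise a gene catalogue
#'
#' Pure aggregation of a Table-1-style catalogue: per-genome gene and
#' pseudogene counts, intact genes, total internal stop codons, stops next
#' to a glutamine codon (strict adjacency, the printed-column definition),
#' and pseudogenes carrying at least one stop.
#'
#' @param rows A `gene_catalogue` data.frame.
#' @return List of class `catalogue_summary`.
#' @export
summarize_catalogue <- function(rows) {
  genomes <- c("A", "B")
  per_genome <- lapply(genomes, function(g) {
    sub <- rows[rows$genome %in% g, , drop = FALSE]
    n <- nrow(sub)
    np <- sum(sub$status == "pseudogene")
    list(genes = n, pseudogenes = np,
         pseudogene_fraction = if (n) np / n else NA_real_)
  })
  names(per_genome) <- genomes
  pseudo <- rows[rows$status == "pseudogene", , drop = FALSE]
  out <- list(
    n_genes = nrow(rows),
    per_genome = per_genome,
    n_pseudogenes = nrow(pseudo),
    n_intact = sum(rows$status == "intact"),
    total_stops = sum(rows$n_stop),
    stops_next_to_Q = sum(rows$n_stop_next_to_Q),
    pseudogenes_with_stop = sum(pseudo$n_stop >= 1L))
  class(out) <- "catalogue_summary"
  out
}

#' @export
print.catalogue_summary <- function(x, ...) {
  cat("Gene catalogue summary\n")
  for (g in names(x$per_genome)) {
    pg <- x$per_genome[[g]]
    cat(sprintf("  genome %s: %d genes, %d pseudogenes (%.0f%%)\n", g,
                pg$genes, pg$pseudogenes, 100 * pg$pseudogene_fraction))
  }
  cat(sprintf("  intact genes: %d\n", x$n_intact))
  cat(sprintf("  internal stop codons: %d (%d next to Q)\n",
              x$total_stops, x$stops_next_to_Q))
  cat(sprintf("  pseudogenes with >= 1 stop: %d of %d\n",
              x$pseudogenes_with_stop, x$n_pseudogenes))
  invisible(x)
}

#' Gene density of a locus in kb per gene
#'
#' Defined as span / genes. Published per-locus figures derived from
#' first-to-last gene distances do not always match this division exactly
#' (the operational span is ambiguous in narrative descriptions); this
#' function is the explicit definition used throughout the package.
#'
#' @param span_bp Locus span in bp.
#' @param n_genes Number of genes in the span (>= 1).
#' @return kb per gene.
#' @export
gene_density <- function(span_bp, n_genes) {
  if (n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  if (span_bp <= 0) stop("span must be positive", call. = FALSE)
  span_bp / 1000 / n_genes
}

# gene-relative offset of an intra-CDS TE: TE start minus gene start
.intra_gene_tes <- function(features) {
  genes <- features[features$kind == "gene", , drop = FALSE]
  tes <- features[features$kind == "TE", , drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    inside <- tes$start >= g$start & tes$end <= g$end
    if (any(inside)) {
      sub <- tes[inside, , drop = FALSE]
      out <- rbind(out, data.frame(gene = g$label, te = sub$label,
                                   offset = sub$start - g$start,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

# ordered TE labels in the intergenic interval upstream of each gene
.flanking_tes <- function(features) {
  genes <- features[features$kind == "gene", , drop = FALSE]
  genes <- genes[order(genes$start), , drop = FALSE]
  tes <- features[features$kind == "TE", , drop = FALSE]
  bounds <- c(0L, genes$end)
  out <- vector("list", nrow(genes))
  names(out) <- genes$label
  for (i in seq_len(nrow(genes))) {
    lo <- bounds[i]; hi <- genes$start[i]
    sel <- tes$start >= lo & tes$end <= hi
    sub <- tes[sel, , drop = FALSE]
    out[[i]] <- sub$label[order(sub$start)]
  }
  out
}

# longest common ordered subsequence length of two label vectors
.lcs_len <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (!na || !nb) return(0L)
  dp <- matrix(0L, na + 1L, nb + 1L)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      dp[i + 1L, j + 1L] <- if (a[i] == b[j]) dp[i, j] + 1L else
        max(dp[i, j + 1L], dp[i + 1L, j])
    }
  }
  dp[na + 1L, nb + 1L]
}

#' Infer orthologous gene pairs from shared TE insertions
#'
#' A gene pair is called orthologous when (a) both carry an intra-CDS TE of
#' the same label at an equivalent gene-relative position (within
#' `position_tolerance` bp), or (b) their upstream intergenic intervals
#' share at least `min_shared_te` TE labels in the same order. Shared
#' insertions predate locus divergence, so they mark orthologous segments.
#'
#' @param features_a,features_b `feature_interval` tables of the two loci
#'   (must contain `gene` and `TE` rows).
#' @param position_tolerance Max gene-relative offset difference (bp) for an
#'   intra-CDS shared TE.
#' @param min_shared_te Minimum number of ordered shared flanking TE labels.
#' @return data.frame with `gene_a`, `gene_b`, `evidence`, `confidence`
#'   (`shared_te` for all calls made here).
#' @export
shared_te_orthology <- function(features_a, features_b,
                                position_tolerance = 30L,
                                min_shared_te = 2L) {
  calls <- data.frame(gene_a = character(0), gene_b = character(0),
                      evidence = character(0), confidence = character(0),
                      stringsAsFactors = FALSE)
  ia <- .intra_gene_tes(features_a)
  ib <- .intra_gene_tes(features_b)
  if (!is.null(ia) && !is.null(ib)) {
    for (i in seq_len(nrow(ia))) {
      m <- ib$te == ia$te[i] &
        abs(ib$offset - ia$offset[i]) <= position_tolerance
      for (j in which(m)) {
        calls <- rbind(calls, data.frame(
          gene_a = ia$gene[i], gene_b = ib$gene[j],
          evidence = sprintf("intra-CDS %s at offsets %d/%d", ia$te[i],
                             ia$offset[i], ib$offset[j]),
          confidence = "shared_te", stringsAsFactors = FALSE))
      }
    }
  }
  fa <- .flanking_tes(features_a)
  fb <- .flanking_tes(features_b)
  for (ga in names(fa)) {
    for (gb in names(fb)) {
      shared <- .lcs_len(fa[[ga]], fb[[gb]])
      if (shared >= min_shared_te) {
        calls <- rbind(calls, data.frame(
          gene_a = ga, gene_b = gb,
          evidence = sprintf("%d ordered shared flanking TE labels", shared),
          confidence = "shared_te", stringsAsFactors = FALSE))
      }
    }
  }
  unique(calls)
}
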