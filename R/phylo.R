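## Distance-based phylogeny for aligned coding sequences: p / Jukes-Cantor
## distances with pairwise deletion, Saitou-Nei neighbor-joining with a
## deterministic tie-break, and column-resampling bootstrap support.
## Trees are ape "phylo" objects; newick I/O is delegated to ape.

#' Pairwise distance matrix from an alignment
#'
#' Gap (`-`) and `N` columns are deleted pairwise; `p` is the fraction of
#' mismatching compared sites; the Jukes-Cantor distance is
#' `-(3/4) log(1 - 4p/3)`.
#'
#' @param alignment Named character vector of equal-length aligned
#'   nucleotide sequences (>= 2).
#' @param model `"p_distance"` (default) or `"jukes_cantor"`.
#' @return Symmetric numeric matrix with zero diagonal and the sequence
#'   names as dimnames.
#' @export
pairwise_distance <- function(alignment, model = c("p_distance",
                                                   "jukes_cantor")) {
  model <- match.arg(model)
  if (length(alignment) < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (length(unique(nchar(alignment))) != 1L)
    stop("aligned sequences must have equal length", call. = FALSE)
  labels <- names(alignment)
  if (is.null(labels)) stop("alignment rows must be named", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  ok <- !(mat == "-" | mat == "N")
  n <- length(alignment)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      ncomp <- sum(comp)
      if (ncomp == 0L)
        stop("zero comparable sites between ", labels[i], " and ", labels[j],
             call. = FALSE)
      p <- sum(mat[i, comp] != mat[j, comp]) / ncomp
      if (model == "jukes_cantor") {
        if (p >= 0.75)
          stop("Jukes-Cantor undefined at p >= 0.75 for pair ", labels[i],
               " / ", labels[j], call. = FALSE)
        p <- -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

.nwk_num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

#' Neighbor-joining tree (Saitou-Nei)
#'
#' In-package implementation of the canonical agglomeration: at each step
#' the pair minimising `Q(i,j) = (n-2) d(i,j) - R_i - R_j` is joined, with
#' ties broken by the first minimum in row-major order, making the result
#' deterministic. Negative branch-length estimates are clamped to zero and
#' flagged via the `"clamped"` attribute.
#'
#' @param dm Symmetric distance matrix with dimnames (>= 3 taxa).
#' @return Unrooted tree of class `phylo` (trifurcating root).
#' @export
nj_tree <- function(dm) {
  d <- as.matrix(dm)
  labels <- rownames(d)
  n <- nrow(d)
  if (is.null(labels) || n < 3L) stop("need >= 3 labelled taxa", call. = FALSE)
  clamped <- 0
  clamp <- function(x) {
    if (x < 0) clamped <<- clamped + abs(x)
    max(x, 0)
  }
  nodes <- labels  # newick fragment per active node
  while (length(nodes) > 3L) {
    m <- length(nodes)
    R <- rowSums(d)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * d[i, j] - R[i] - R[j]
        if (is.null(best) || q < best$q) best <- list(q = q, i = i, j = j)
      }
    }
    i <- best$i; j <- best$j
    li <- clamp(d[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2)))
    lj <- clamp(d[i, j] - (d[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))))
    newdist <- (d[i, ] + d[j, ] - d[i, j]) / 2
    merged <- sprintf("(%s:%s,%s:%s)", nodes[i], .nwk_num(li),
                      nodes[j], .nwk_num(lj))
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newdist[keep]),
               c(newdist[keep], 0))
    nodes <- c(nodes[keep], merged)
  }
  x <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  y <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  z <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], .nwk_num(x),
                 nodes[2], .nwk_num(y), nodes[3], .nwk_num(z))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

# Canonical bipartition keys of the internal edges of an unrooted tree:
# each non-root internal node's tip set, represented by whichever side does
# not contain the alphabetically first label.
.bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  out <- character(0)
  for (k in seq_along(pp)) {
    set <- sort(attr(pp, "labels")[pp[[k]]])
    if (length(set) <= 1L || length(set) >= length(tips) - 1L) {
      if (length(set) == length(tips)) next  # root
      if (length(set) <= 1L) next            # trivial
    }
    side <- if (tips[1L] %in% set) sort(setdiff(tips, set)) else set
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    out <- c(out, paste(side, collapse = "|"))
  }
  out
}

#' Bootstrap support for the neighbor-joining tree
#'
#' Resamples alignment columns with replacement `n_replicates` times,
#' rebuilds the NJ tree per replicate, and reports for each internal edge of
#' the point-estimate tree the percentage of replicates containing the same
#' bipartition. Supports are attached as `node.label` (root label empty).
#'
#' @param alignment Named character vector of aligned sequences.
#' @param model Distance model, see [pairwise_distance()].
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; fixed seed gives identical supports.
#' @return The point-estimate `phylo` tree with a `node.label` vector of
#'   supports in `[0, 100]` and a `"support"` attribute (named by
#'   bipartition key).
#' @export
bootstrap_support <- function(alignment, model = "p_distance",
                              n_replicates = 100L, seed = 1L) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  point <- nj_tree(pairwise_distance(alignment, model))
  target <- .bipartitions(point)
  hit <- setNames(numeric(length(target)), target)
  width <- nchar(alignment[[1L]])
  chars <- strsplit(toupper(alignment), "")
  set.seed(as.integer(seed))
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(width, width, replace = TRUE)
    boot <- vapply(chars, function(x) paste(x[cols], collapse = ""),
                   character(1))
    bt <- nj_tree(pairwise_distance(boot, model))
    bp <- .bipartitions(bt)
    hit[target %in% bp] <- hit[target %in% bp] + 1
  }
  support <- 100 * hit / n_replicates
  # map supports onto internal nodes of the point tree
  ntip <- length(point$tip.label)
  pp <- ape::prop.part(point)
  labs <- character(point$Nnode)
  tips <- sort(point$tip.label)
  for (k in seq_along(pp)) {
    set <- sort(attr(pp, "labels")[pp[[k]]])
    if (length(set) == ntip) { labs[k] <- ""; next }
    side <- if (tips[1L] %in% set) sort(setdiff(tips, set)) else set
    key <- paste(side, collapse = "|")
    labs[k] <- if (key %in% names(support))
      format(support[[key]], digits = 4) else ""
  }
  point$node.label <- labs
  attr(point, "support") <- support
  point
}

#' Write a tree to newick
#'
#' @param tree A `phylo` object (all leaves labelled).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("all leaves must be labelled", call. = FALSE)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree
#'
#' @param path Path to a newick file.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Drop alignment rows with poor coverage
#'
#' Pseudogenes carrying large deletions distort distance estimates; rows
#' whose non-gap site fraction falls below `min_coverage` of the alignment
#' width are removed before tree building.
#'
#' @param alignment Named character vector of aligned sequences.
#' @param min_coverage Minimum non-gap fraction (default 0.7).
#' @return The filtered alignment.
#' @export
filter_alignment_coverage <- function(alignment, min_coverage = 0.7) {
  width <- nchar(alignment[[1L]])
  cov <- vapply(alignment, function(s)
    sum(strsplit(s, "")[[1L]] != "-") / width, numeric(1))
  alignment[cov >= min_coverage]
}

#' Reference-guided pseudo-alignment of a gene set
#'
#' Projects every gene onto a common reference via global alignment,
#' producing equal-length rows on the reference coordinate grid (insertions
#' relative to the reference are dropped). A lightweight alternative to a
#' progressive multiple aligner for closely related gene families.
#'
#' @param genes Named character vector of nucleotide sequences.
#' @param reference Reference sequence (defaults to the longest full-ORF
#'   member of `genes`).
#' @param params An [alignment_params()] list.
#' @return Named character vector of equal-length rows.
#' @export
reference_align <- function(genes, reference = NULL,
                            params = alignment_params(band = 0L)) {
  if (is.null(reference)) {
    cand <- find_intact_references(genes)
    if (!length(cand)) cand <- genes
    reference <- cand[[which.max(nchar(cand))]]
  }
  out <- vapply(genes, function(g) {
    aln <- align_global(g, reference, params)
    paste(.project_on_reference(aln), collapse = "")
  }, character(1))
  names(out) <- names(genes)
  out
}
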