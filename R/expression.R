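#' Remove reads confounded by T7 transcription
#'
#' Drops every read whose alignment span intersects `position +/- flank`
#' of any canonical edit site, across all cells. Non-barcoded T7
#' transcripts (truncated by fragmentation) map near edit sites and would
#' otherwise inflate expression of edited genes.
#'
#' @param reads Tibble from [read_tagged_alignments()].
#' @param sites Tibble with `chrom`, `position` (typically confident
#'   canonical sites); zero rows makes this the identity filter.
#' @param flank Exclusion half-width in bp (default 1000).
#' @return Filtered read tibble.
#' @export
filter_confounded_reads <- function(reads, sites, flank = 1000L) {
  if (nrow(sites) == 0 || nrow(reads) == 0) return(reads)
  q <- GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(reads$ref_start + 1L, reads$ref_end)
  )
  s <- GenomicRanges::GRanges(
    sites$chrom,
    IRanges::IRanges(pmax(1L, sites$position + 1L - flank),
                     sites$position + 1L + flank)
  )
  reads[!IRanges::overlapsAny(q, s), , drop = FALSE]
}

# Number of connected components among UMIs where edges join pairs at
# Hamming distance <= 1 (unequal lengths: compared over the shorter length
# with the length difference added). Union-find.
umi_components <- function(umis) {
  n <- length(umis)
  if (n <= 1) return(n)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ints <- lapply(umis, utf8ToInt)
  lens <- lengths(ints)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      L <- min(lens[i], lens[j])
      d <- sum(ints[[i]][seq_len(L)] != ints[[j]][seq_len(L)]) +
        abs(lens[i] - lens[j])
      if (d <= 1) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, 0L)))
}

#' Count unique molecules per gene per cell
#'
#' Builds, per (cell, gene), a graph on the distinct UMIs with edges
#' between UMIs at Hamming distance <= 1 and counts connected components
#' as molecules: UMI sets linked by a single-edit path collapse to one
#' molecule, absorbing sequencing error.
#'
#' @param reads Tibble with `cell_barcode`, `gene_id`, `umi` (reads
#'   without a gene assignment are ignored).
#' @param cells,genes Optional orderings fixing the matrix dimensions.
#' @return Sparse genes x cells integer matrix of molecule counts.
#' @export
count_umis <- function(reads, cells = NULL, genes = NULL) {
  r <- reads[!is.na(reads$gene_id) & !is.na(reads$cell_barcode) &
               !is.na(reads$umi), , drop = FALSE]
  cells <- cells %||% sort(unique(r$cell_barcode))
  genes <- genes %||% sort(unique(r$gene_id))
  if (nrow(r) == 0) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = integer(0),
                                dims = c(length(genes), length(cells)),
                                dimnames = list(genes, cells)))
  }
  key <- paste(r$cell_barcode, r$gene_id, sep = "\r")
  grp <- split(r$umi, key)
  counts <- vapply(grp, function(u) umi_components(unique(u)), 0L)
  parts <- strsplit(names(grp), "\r", fixed = TRUE)
  cb <- vapply(parts, `[`, "", 1)
  gid <- vapply(parts, `[`, "", 2)
  keep <- cb %in% cells & gid %in% genes
  Matrix::sparseMatrix(
    i = match(gid[keep], genes), j = match(cb[keep], cells),
    x = counts[keep],
    dims = c(length(genes), length(cells)),
    dimnames = list(genes, cells)
  )
}

#' Median-library-size normalization
#'
#' Per cell: divide counts by the cell total, multiply by the median cell
#' total, then `log1p`. Zero entries stay zero; zero-total cells are
#' dropped with a warning.
#'
#' @param m Genes x cells count matrix (sparse or dense).
#' @return Normalized matrix of the same class and layout.
#' @export
normalize_counts <- function(m) {
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " zero-total cell(s) dropped")
    m <- m[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  med <- median(totals)
  scaled <- m %*% Matrix::Diagonal(x = med / totals)
  colnames(scaled) <- colnames(m)
  log1p(scaled)
}

#' Pearson residuals under a regularized negative-binomial model
#'
#' Variance-stabilizing transform in the style of regularized NB
#' residual normalization: the expected count is
#' `mu_gj = gene_total_g * cell_total_j / grand_total`, the variance is
#' `mu + mu^2 / theta_g` with a per-gene overdispersion `theta_g`
#' estimated by method of moments and regularized by a log-log linear
#' smooth against gene mean, and residuals `(x - mu) / sd` are clipped at
#' `+/- sqrt(n_cells)`. All-zero genes get residual 0. In the Poisson
#' limit (`theta -> Inf`) the residual is `(x - mu) / sqrt(mu)`.
#'
#' @param m Genes x cells integer count matrix.
#' @param theta Optional fixed overdispersion (scalar or per-gene vector)
#'   bypassing estimation; useful for closed-form checks.
#' @return Dense genes x cells residual matrix.
#' @export
pearson_residuals <- function(m, theta = NULL) {
  x <- as.matrix(m)
  n_cells <- ncol(x)
  gene_tot <- rowSums(x)
  cell_tot <- colSums(x)
  grand <- sum(gene_tot)
  mu <- outer(gene_tot, cell_tot) / grand
  if (is.null(theta)) {
    gm <- rowMeans(x)
    gv <- apply(x, 1, var)
    th <- ifelse(gv > gm, gm^2 / (gv - gm), Inf)
    ok <- is.finite(th) & th > 0 & gm > 0
    if (sum(ok) >= 3) {
      fit <- lm(log(th[ok]) ~ log(gm[ok]))
      th_s <- exp(cbind(1, log(pmax(gm, 1e-8))) %*% coef(fit))[, 1]
      theta <- pmin(pmax(th_s, 1e-3), 1e6)
    } else {
      theta <- rep(Inf, nrow(x))
    }
  }
  theta <- rep_len(theta, nrow(x))
  sdv <- sqrt(mu + mu^2 / theta)
  r <- (x - mu) / sdv
  r[!is.finite(r)] <- 0
  r[gene_tot == 0, ] <- 0
  clip <- sqrt(n_cells)
  pmin(pmax(r, -clip), clip)
}

#' Embed cells in two dimensions
#'
#' Cosine-metric nearest-neighbour UMAP of the normalized matrix,
#' deterministic for a given seed, plus per-cell QC: genes detected and
#' total molecules.
#'
#' @param norm Genes x cells normalized matrix (from
#'   [normalize_counts()]).
#' @param counts Genes x cells count matrix (for `genes_detected` /
#'   `total_umis`); defaults to thresholding `norm`.
#' @param sample_labels Optional named vector (cell -> sample label).
#' @param seed Random seed (default 42).
#' @param n_neighbors Neighbourhood size (default 15; reduced with a
#'   warning when there are fewer cells).
#' @return Tibble: `cell_barcode`, `umap1`, `umap2`, `genes_detected`,
#'   `total_umis`, `sample_label`.
#' @export
embed_cells <- function(norm, counts = NULL, sample_labels = NULL,
                        seed = 42L, n_neighbors = 15L) {
  x <- t(as.matrix(norm))
  counts <- counts %||% norm
  nn <- n_neighbors
  if (nrow(x) <= nn) {
    warning("fewer cells than n_neighbors; reducing")
    nn <- max(2L, nrow(x) - 1L)
  }
  emb <- withr::with_seed(seed, uwot::umap(
    x, n_neighbors = nn, metric = "cosine", n_threads = 1,
    n_sgd_threads = 0, ret_model = FALSE
  ))
  cb <- colnames(norm)
  lab <- if (is.null(sample_labels)) rep(NA_character_, length(cb))
         else unname(sample_labels[cb])
  tibble::tibble(
    cell_barcode = cb,
    umap1 = emb[, 1], umap2 = emb[, 2],
    genes_detected = as.integer(Matrix::colSums(counts > 0)[cb]),
    total_umis = as.integer(round(Matrix::colSums(counts)[cb])),
    sample_label = lab
  )
}
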