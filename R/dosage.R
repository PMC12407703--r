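#' Staged edit distance between two clip sequences
#'
#' Compares the donor-derived clip sequences of two particular edits while
#' tolerating the artifacts that make reads from the same allele look
#' different: 5' fragmentation, homopolymer sequencing error and 5'-end
#' base-call error. Three stages:
#'
#' 1. Local alignment (match +1, mismatch -1, gap -0.5, gap extension
#'    -0.5). The distance is the number of mismatch or gap columns in the
#'    best local alignment, plus any bases of the shorter sequence not
#'    covered by it (never "seen"). A sequence that is a subsequence of
#'    the other therefore scores 0, absorbing 5' fragmentation. A pair
#'    with no positively scoring local alignment shares nothing and is
#'    maximally distant (the longer sequence's length).
#' 2. If that distance is 2 or more, homopolymer runs of length >= 3 in
#'    both original sequences are collapsed to a single base and stage 1
#'    is recomputed on the collapsed strings.
#' 3. If the distance is still more than 2, mismatch/gap columns are
#'    recounted within the last 10 columns (the 3' end) of the stage-1
#'    alignment of the original strings, discounting 5'-end artifacts.
#'
#' Each stage replaces the previous distance; the final stage's count is
#' returned. Argument order is canonicalized internally (longer sequence
#' first, ties lexicographic), so the distance is symmetric.
#'
#' @param a,b Non-empty DNA strings.
#' @return Integer distance.
#' @export
clip_edit_distance <- function(a, b) {
  if (is.na(a) || is.na(b) || nchar(a) == 0 || nchar(b) == 0) {
    stop("clip_edit_distance requires non-empty sequences")
  }
  a <- toupper(a); b <- toupper(b)
  if (nchar(b) > nchar(a) || (nchar(b) == nchar(a) && b < a)) {
    tmp <- a; a <- b; b <- tmp
  }
  al1 <- align_local(a, b, gap_open = 0.5, gap_extend = 0.5)
  d <- stage_count(al1, a, b)
  if (d >= 2) {
    ah <- collapse_homopolymers(a)
    bh <- collapse_homopolymers(b)
    d <- stage_count(align_local(ah, bh, 0.5, 0.5), ah, bh)
    if (d > 2) {
      d <- tail_mismatches(al1, n = 10L)
    }
  }
  as.integer(d)
}

# Stage-1 count: mismatch/gap columns of the local alignment plus bases of
# the shorter input never covered by it. Sequences with no positively
# scoring local alignment share nothing and are maximally distant.
stage_count <- function(al, a, b) {
  shorter <- if (nchar(b) <= nchar(a)) "subject" else "pattern"
  p <- strsplit(al$pattern, "")[[1]]
  s <- strsplit(al$subject, "")[[1]]
  if (length(p) == 0 || al$score <= 0) {
    return(max(nchar(a), nchar(b)))
  }
  mism <- sum(p != s)
  seen <- if (shorter == "subject") sum(s != "-") else sum(p != "-")
  unseen <- min(nchar(a), nchar(b)) - seen
  mism + unseen
}

# Mismatch/gap columns within the last `n` columns of an alignment.
tail_mismatches <- function(al, n = 10L) {
  p <- strsplit(al$pattern, "")[[1]]
  s <- strsplit(al$subject, "")[[1]]
  L <- length(p)
  if (L == 0 || al$score <= 0) return(n)
  idx <- seq.int(max(1L, L - n + 1L), L)
  sum(p[idx] != s[idx])
}

# Collapse homopolymer runs of length >= 3 to a single base.
collapse_homopolymers <- function(s) {
  gsub("(.)\\1{2,}", "\\1", s)
}

#' Do two particular edits come from the same allele?
#'
#' Same-cell, same-site particular edits represent the same edited allele
#' only when they share the insertion orientation and the breakpoint and
#' their clip sequences are within staged edit distance 2.
#'
#' @param p1,p2 Single-row tibbles (or lists) with `orientation`,
#'   `breakpoint`, `clip_seq`.
#' @return Logical.
#' @export
same_allele <- function(p1, p2) {
  if (p1$orientation != p2$orientation) return(FALSE)
  if (p1$breakpoint != p2$breakpoint) return(FALSE)
  clip_edit_distance(p1$clip_seq, p2$clip_seq) <= 2
}

#' Count edited alleles for one cell at one site
#'
#' Maintains a candidate-longest-edit list: members are visited in a fixed
#' order (read support desc, clip length desc, clip lexicographic) and
#' compared pairwise against the current candidates; when a member matches
#' a candidate as the same allele the longer clip (ties: lexicographically
#' smaller) is kept, otherwise the member becomes a new candidate. The
#' allele count is the final list size.
#'
#' @param members Tibble of particular edits of one (cell, site):
#'   `orientation`, `breakpoint`, `clip_seq`, `n_reads`. Members with
#'   empty clips are dropped.
#' @return List with `allele_count` and `representative_clips`.
#' @export
count_cell_site_alleles <- function(members) {
  members <- members[!is.na(members$clip_seq) & nchar(members$clip_seq) > 0, ,
                     drop = FALSE]
  if (nrow(members) == 0) {
    return(list(allele_count = 0L, representative_clips = character(0)))
  }
  members <- members[order(-members$n_reads, -nchar(members$clip_seq),
                           members$clip_seq), , drop = FALSE]
  cand <- members[1, , drop = FALSE]
  for (i in seq_len(nrow(members))[-1]) {
    m <- members[i, , drop = FALSE]
    matched <- FALSE
    for (j in seq_len(nrow(cand))) {
      if (same_allele(m, cand[j, , drop = FALSE])) {
        # keep the longer clip as the candidate's representative
        a <- cand$clip_seq[j]; bseq <- m$clip_seq
        better <- nchar(bseq) > nchar(a) || (nchar(bseq) == nchar(a) && bseq < a)
        if (better) cand[j, ] <- m
        matched <- TRUE
        break
      }
    }
    if (!matched) cand <- dplyr::bind_rows(cand, m)
  }
  list(allele_count = nrow(cand),
       representative_clips = sort(cand$clip_seq))
}

#' Edit allele calls for all cells and sites
#'
#' @param particulars Tibble from [aggregate_particular_edits()].
#' @param clustering Result of [cluster_edit_sites()] (or whitelist
#'   membership wrapped as `list(membership = ...)`).
#' @return Tibble with `cell_barcode`, `site_id`, `allele_count`,
#'   `representative_clips` (list column).
#' @export
call_alleles <- function(particulars, clustering) {
  memb <- join_membership(particulars, clustering$membership)
  if (nrow(memb) == 0) {
    return(tibble::tibble(cell_barcode = character(0), site_id = character(0),
                          allele_count = integer(0),
                          representative_clips = list()))
  }
  groups <- split(memb, paste(memb$cell_barcode, memb$site_id, sep = "\r"))
  rows <- lapply(groups, function(g) {
    res <- count_cell_site_alleles(g)
    tibble::tibble(cell_barcode = g$cell_barcode[1], site_id = g$site_id[1],
                   allele_count = res$allele_count,
                   representative_clips = list(res$representative_clips))
  })
  out <- dplyr::bind_rows(rows)
  out <- out[out$allele_count > 0, , drop = FALSE]
  out[order(out$cell_barcode, out$site_id), , drop = FALSE]
}

#' Gene-level edit allele dosage
#'
#' Assigns each canonical site to every gene whose span intersects the
#' site position +/- `flank` bp, sums allele counts per (cell, gene) over
#' assigned sites, and caps the total at the gene's copy number. Sites
#' assigned to no gene are reported as intergenic and excluded from the
#' matrix.
#'
#' @param allele_calls Tibble from [call_alleles()].
#' @param sites Tibble with `site_id`, `chrom`, `position`.
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param copy_number Named integer vector (`gene_id` -> copies); genes
#'   absent from it default to `default_cap`.
#' @param flank Assignment flank in bp (default 140).
#' @param default_cap Copy-number cap when unknown (default 2).
#' @return List with `dosage` (sparse cells x genes matrix),
#'   `site_gene` (site-to-gene assignment tibble) and `intergenic_sites`
#'   (character vector).
#' @export
gene_edit_dosage <- function(allele_calls, sites, genes, copy_number = NULL,
                             flank = 140L, default_cap = 2L) {
  sgr <- GenomicRanges::GRanges(
    sites$chrom,
    IRanges::IRanges(pmax(1L, sites$position + 1L - flank),
                     sites$position + 1L + flank)
  )
  ggr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end)
  )
  ov <- IRanges::findOverlaps(sgr, ggr)
  site_gene <- tibble::tibble(
    site_id = sites$site_id[S4Vectors::queryHits(ov)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(ov)]
  )
  intergenic <- setdiff(sites$site_id, site_gene$site_id)
  joined <- dplyr::inner_join(allele_calls, site_gene, by = "site_id",
                              relationship = "many-to-many")
  cells <- sort(unique(allele_calls$cell_barcode))
  gids <- genes$gene_id
  caps <- setNames(rep(as.integer(default_cap), length(gids)), gids)
  if (!is.null(copy_number)) {
    caps[names(copy_number)[names(copy_number) %in% gids]] <-
      as.integer(copy_number[names(copy_number) %in% gids])
  }
  if (nrow(joined) == 0 || length(cells) == 0) {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = integer(0),
                              dims = c(length(cells), length(gids)),
                              dimnames = list(cells, gids))
    return(list(dosage = m, site_gene = site_gene,
                intergenic_sites = intergenic))
  }
  agg <- joined |>
    dplyr::group_by(.data$cell_barcode, .data$gene_id) |>
    dplyr::summarise(dosage = sum(.data$allele_count), .groups = "drop")
  agg$dosage <- pmin(agg$dosage, caps[agg$gene_id])
  m <- Matrix::sparseMatrix(
    i = match(agg$cell_barcode, cells),
    j = match(agg$gene_id, gids),
    x = agg$dosage,
    dims = c(length(cells), length(gids)),
    dimnames = list(cells, gids)
  )
  list(dosage = m, site_gene = site_gene, intergenic_sites = intergenic)
}
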