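#' Aggregate T7 read observations into particular edits
#'
#' A particular edit is one cell's observation of one edit version: the
#' group of T7-positive reads sharing (cell, chrom, breakpoint,
#' orientation, clip sequence), with its UMIs and read count accumulated.
#'
#' @param observations Tibble from `call_t7_reads()$observations`.
#' @return Tibble with `cell_barcode`, `chrom`, `breakpoint`,
#'   `orientation`, `clip_seq`, `umis` (list column of distinct UMIs),
#'   `n_umis`, `n_reads`.
#' @export
aggregate_particular_edits <- function(observations) {
  if (nrow(observations) == 0) {
    return(tibble::tibble(cell_barcode = character(0), chrom = character(0),
                          breakpoint = integer(0), orientation = character(0),
                          clip_seq = character(0), umis = list(),
                          n_umis = integer(0), n_reads = integer(0)))
  }
  observations |>
    dplyr::group_by(.data$cell_barcode, .data$chrom, .data$breakpoint,
                    .data$orientation, .data$clip_seq) |>
    dplyr::summarise(umis = list(unique(.data$umi)),
                     n_umis = length(unique(.data$umi)),
                     n_reads = dplyr::n(), .groups = "drop")
}

# Collapse particular edits over cells into particular SITES: unique
# (chrom, breakpoint, orientation, clip) classes with supporting-cell count.
particular_sites <- function(particulars) {
  particulars |>
    dplyr::group_by(.data$chrom, .data$breakpoint, .data$orientation,
                    .data$clip_seq) |>
    dplyr::summarise(n_cells = length(unique(.data$cell_barcode)),
                     n_reads = sum(.data$n_reads), .groups = "drop")
}

#' Greedy canonical clustering of particular edit sites
#'
#' Collapses particular edit sites into canonical edit sites, each
#' representing the most common version of an edit across cells.
#' Particular sites are ordered by descending supporting-cell count (ties
#' broken by chrom, breakpoint, orientation, then clip sequence, for
#' reproducibility); the top remaining site founds a new canonical site at
#' its breakpoint, every remaining particular site on the same chromosome
#' within `radius` bp (inclusive) of that breakpoint is assigned to it,
#' assigned sites are removed, and the procedure repeats until no
#' particular sites remain. Every particular site therefore belongs to
#' exactly one canonical site.
#'
#' @param particulars Tibble from [aggregate_particular_edits()].
#' @param radius Assignment radius in bp (default 140).
#' @return List with `sites` (tibble: `site_id`, `chrom`, `position` =
#'   founder breakpoint, `n_particular`) and `membership` (tibble mapping
#'   each particular site — `chrom`, `breakpoint`, `orientation`,
#'   `clip_seq` — to its `site_id`).
#' @export
cluster_edit_sites <- function(particulars, radius = 140L) {
  ps <- particular_sites(particulars)
  if (nrow(ps) == 0) {
    return(list(
      sites = tibble::tibble(site_id = character(0), chrom = character(0),
                             position = integer(0), n_particular = integer(0)),
      membership = tibble::tibble(chrom = character(0), breakpoint = integer(0),
                                  orientation = character(0),
                                  clip_seq = character(0),
                                  site_id = character(0))
    ))
  }
  ps <- ps[order(-ps$n_cells, ps$chrom, ps$breakpoint, ps$orientation,
                 ps$clip_seq), , drop = FALSE]
  remaining <- rep(TRUE, nrow(ps))
  site_id <- rep(NA_character_, nrow(ps))
  sites <- list()
  while (any(remaining)) {
    f <- which(remaining)[1]
    id <- sprintf("site_%s_%d", ps$chrom[f], ps$breakpoint[f])
    member <- remaining & ps$chrom == ps$chrom[f] &
      abs(ps$breakpoint - ps$breakpoint[f]) <= radius
    site_id[member] <- id
    sites[[length(sites) + 1]] <- tibble::tibble(
      site_id = id, chrom = ps$chrom[f], position = ps$breakpoint[f],
      n_particular = sum(member)
    )
    remaining <- remaining & !member
  }
  list(
    sites = dplyr::bind_rows(sites),
    membership = tibble::tibble(chrom = ps$chrom, breakpoint = ps$breakpoint,
                                orientation = ps$orientation,
                                clip_seq = ps$clip_seq, site_id = site_id)
  )
}

# Join particular edits to their canonical site via the membership table.
join_membership <- function(particulars, membership) {
  dplyr::inner_join(
    particulars, membership,
    by = c("chrom", "breakpoint", "orientation", "clip_seq")
  )
}

#' Per-site summary statistics
#'
#' Fills in the supporting-cell count, total distinct UMIs, orientation
#' presence and the minimum forward-reverse breakpoint gap (`Inf` when
#' either orientation is absent) for each canonical site.
#'
#' @param clustering Result of [cluster_edit_sites()].
#' @param particulars Tibble from [aggregate_particular_edits()].
#' @return The `sites` tibble with added `n_cells`, `n_umis`,
#'   `has_forward`, `has_reverse`, `min_fr_gap`.
#' @export
compute_site_stats <- function(clustering, particulars) {
  memb <- join_membership(particulars, clustering$membership)
  stats <- memb |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      n_cells = length(unique(.data$cell_barcode)),
      n_umis = sum(.data$n_umis),
      has_forward = any(.data$orientation == "forward"),
      has_reverse = any(.data$orientation == "reverse"),
      min_fr_gap = {
        f <- unique(.data$breakpoint[.data$orientation == "forward"])
        r <- unique(.data$breakpoint[.data$orientation == "reverse"])
        if (length(f) == 0 || length(r) == 0) Inf
        else min(abs(outer(f, r, "-")))
      },
      .groups = "drop"
    )
  dplyr::left_join(clustering$sites, stats, by = "site_id")
}

#' Build the genome-region blacklist
#'
#' Union of three interval classes on which canonical edit-site calls are
#' rejected: (a) user-supplied excessive-mapping peaks (BED), (b)
#' barcode-like regions — windows where barcode-similar sequence (sharing
#' at least one k-mer with the barcode or its reverse complement) occurs
#' on both strands within `proximity` bp, which combined with sequencing
#' error yields clip sequences resembling the barcode, and (c)
#' homopolymer (poly-N) runs longer than `polyN_min` bp.
#'
#' @param genome A [Biostrings::DNAStringSet] (named contigs).
#' @param spec A [barcode_spec()].
#' @param peaks_bed Optional BED path of excessive-mapping regions.
#' @param polyN_min Minimum homopolymer run length to blacklist
#'   (default 50; runs must exceed this).
#' @param proximity Maximum distance between opposite-strand barcode-like
#'   hits (default 200).
#' @return A [GenomicRanges::GRanges] with metadata column `label` in
#'   `excess_mapping`, `barcode_like`, `simple_repeat`.
#' @export
build_region_blacklist <- function(genome, spec, peaks_bed = NULL,
                                   polyN_min = 50L, proximity = 200L) {
  out <- GenomicRanges::GRanges()
  if (!is.null(peaks_bed)) {
    if (!file.exists(peaks_bed)) stop("cannot read BED: ", peaks_bed)
    pk <- rtracklayer::import(peaks_bed, format = "BED")
    if (length(pk) > 0) {
      S4Vectors::mcols(pk) <- NULL
      pk$label <- "excess_mapping"
      out <- suppressWarnings(c(out, pk))
    }
  }
  fwd_k <- spec$barcode_kmers
  rev_k <- kmer_set(revcomp(spec$barcode_seq), spec$k)
  match_pos <- function(subject, kmers) {
    # 1-based start positions of any k-mer occurrence
    sort(unique(unlist(lapply(kmers, function(km) {
      IRanges::start(Biostrings::matchPattern(km, subject))
    }))))
  }
  for (contig in names(genome)) {
    subject <- genome[[contig]]
    fp <- match_pos(subject, fwd_k)
    rp <- match_pos(subject, rev_k)
    if (length(fp) > 0 && length(rp) > 0) {
      fr <- IRanges::IRanges(fp, fp + spec$k - 1L)
      rr <- IRanges::IRanges(rp, rp + spec$k - 1L)
      ov <- IRanges::findOverlaps(fr, rr, maxgap = proximity)
      if (length(ov) > 0) {
        lo <- pmin(fp[S4Vectors::queryHits(ov)], rp[S4Vectors::subjectHits(ov)])
        hi <- pmax(fp[S4Vectors::queryHits(ov)] + spec$k - 1L,
                   rp[S4Vectors::subjectHits(ov)] + spec$k - 1L)
        gr <- GenomicRanges::reduce(
          GenomicRanges::GRanges(contig, IRanges::IRanges(lo, hi))
        )
        gr$label <- "barcode_like"
        out <- suppressWarnings(c(out, gr))
      }
    }
    # homopolymer runs
    r <- rle(strsplit(as.character(subject), "")[[1]])
    ends <- cumsum(r$lengths)
    long <- which(r$lengths > polyN_min)
    if (length(long) > 0) {
      gr <- GenomicRanges::GRanges(
        contig,
        IRanges::IRanges(ends[long] - r$lengths[long] + 1L, ends[long])
      )
      gr$label <- "simple_repeat"
      out <- suppressWarnings(c(out, gr))
    }
  }
  out
}

#' Filter canonical sites by confidence criteria
#'
#' A site is confident iff it is supported by at least `min_cells`
#' distinct cells, has particular edits in both orientations, its minimum
#' forward-reverse breakpoint gap is at most `max_fr_gap` bp, and its
#' position does not overlap the region blacklist. Rejected sites are
#' retained with the first failing reason (in that order) for reporting.
#' The filter is idempotent and order-independent.
#'
#' @param sites Tibble from [compute_site_stats()].
#' @param blacklist `GRanges` from [build_region_blacklist()], or `NULL`.
#' @param min_cells Minimum supporting cells (default 3).
#' @param max_fr_gap Maximum forward-reverse gap in bp (default 15).
#' @return `sites` with added `confident` and `reject_reason` columns.
#' @export
filter_canonical_sites <- function(sites, blacklist = NULL, min_cells = 3L,
                                   max_fr_gap = 15L) {
  in_bl <- rep(FALSE, nrow(sites))
  if (!is.null(blacklist) && length(blacklist) > 0 && nrow(sites) > 0) {
    pos <- GenomicRanges::GRanges(
      sites$chrom, IRanges::IRanges(sites$position + 1L, sites$position + 1L)
    )
    in_bl <- IRanges::overlapsAny(pos, blacklist)
  }
  reason <- rep(NA_character_, nrow(sites))
  reason[is.na(reason) & sites$n_cells < min_cells] <- "too_few_cells"
  reason[is.na(reason) & !(sites$has_forward & sites$has_reverse)] <-
    "unidirectional"
  reason[is.na(reason) & sites$min_fr_gap > max_fr_gap] <- "fr_gap"
  reason[is.na(reason) & in_bl] <- "blacklisted"
  sites$confident <- is.na(reason)
  sites$reject_reason <- reason
  sites
}

#' Whitelist-mode edit-site calling
#'
#' Small-library mode: accept any particular edit within `radius` bp of a
#' site on a whitelist (e.g. confident sites from a larger companion
#' library), regardless of the confidence filters.
#'
#' @param particulars Tibble from [aggregate_particular_edits()].
#' @param whitelist Tibble with `site_id`, `chrom`, `position`.
#' @param radius Matching radius in bp (default 140).
#' @return Membership tibble mapping particular sites to whitelist
#'   `site_id`s (nearest site on ties).
#' @export
match_whitelisted_sites <- function(particulars, whitelist, radius = 140L) {
  ps <- particular_sites(particulars)
  rows <- lapply(seq_len(nrow(ps)), function(i) {
    w <- whitelist[whitelist$chrom == ps$chrom[i], , drop = FALSE]
    if (nrow(w) == 0) return(NULL)
    d <- abs(w$position - ps$breakpoint[i])
    j <- which.min(d)
    if (d[j] > radius) return(NULL)
    cbind(ps[i, c("chrom", "breakpoint", "orientation", "clip_seq")],
          site_id = w$site_id[j])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(0), breakpoint = integer(0),
                          orientation = character(0), clip_seq = character(0),
                          site_id = character(0))
  }
  tibble::as_tibble(out)
}

#' Per-cell T7 UMI counts by canonical site
#'
#' @param clustering Result of [cluster_edit_sites()] (or a membership
#'   tibble in the same layout wrapped as `list(membership = ...)`).
#' @param particulars Tibble from [aggregate_particular_edits()].
#' @param site_ids Optional site ids fixing the column set/order.
#' @return Sparse [Matrix::sparseMatrix] of cells x sites, entries the
#'   number of distinct T7 UMIs of that cell among the site's particular
#'   edits.
#' @export
per_cell_site_umis <- function(clustering, particulars, site_ids = NULL) {
  memb <- join_membership(particulars, clustering$membership)
  cnt <- memb |>
    dplyr::group_by(.data$cell_barcode, .data$site_id) |>
    dplyr::summarise(n = length(unique(unlist(.data$umis))), .groups = "drop")
  cells <- sort(unique(cnt$cell_barcode))
  sids <- site_ids %||% sort(unique(cnt$site_id))
  cnt <- cnt[cnt$site_id %in% sids, , drop = FALSE]
  Matrix::sparseMatrix(
    i = match(cnt$cell_barcode, cells),
    j = match(cnt$site_id, sids),
    x = cnt$n,
    dims = c(length(cells), length(sids)),
    dimnames = list(cells, sids)
  )
}

#' Expected edited cells when downscaling a library
#'
#' Scales the edited-cell count observed in a large library to the size of
#' a smaller one: `edited_big / total_big * n_small`.
#'
#' @param edited_cells_big Edited cells at the site in the large library.
#' @param total_cells_big Total cells in the large library (> 0).
#' @param n_small Cell count of the small library.
#' @return Expected number of edited cells (real).
#' @export
expected_edited_cells <- function(edited_cells_big, total_cells_big, n_small) {
  if (any(total_cells_big <= 0)) stop("total_cells_big must be > 0")
  edited_cells_big / total_cells_big * n_small
}
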