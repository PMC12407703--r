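#' Barcode specification for T7 read classification
#'
#' Bundles the donor-derived clip barcode, the k-mer size and the
#' template-switch-oligo (TSO) variant set, and derives the blacklist of
#' barcode k-mers that also occur in a TSO variant. Clips whose only
#' barcode evidence is such a shared k-mer, with further TSO support, are
#' rejected as library-preparation artifacts rather than edit marks.
#'
#' @param barcode_seq Donor-derived barcode as it appears at the start of
#'   T7 transcripts (default `"GGGAGAGTAT"`).
#' @param k k-mer size for matching (default 6).
#' @param tso_variants Character vector of observed TSO sequence variants
#'   (may be empty).
#' @return A list of class `barcode_spec` with elements `barcode_seq`,
#'   `k`, `tso_variants`, `barcode_kmers`, `tso_kmers`, `blacklist_kmers`.
#' @export
barcode_spec <- function(barcode_seq = "GGGAGAGTAT", k = 6L,
                         tso_variants = character(0)) {
  barcode_seq <- toupper(barcode_seq)
  if (k > nchar(barcode_seq)) {
    stop("k (", k, ") exceeds barcode length (", nchar(barcode_seq), ")")
  }
  bk <- kmer_set(barcode_seq, k)
  tk <- unique(unlist(lapply(toupper(tso_variants), kmer_set, k = k)))
  tk <- tk %||% character(0)
  structure(
    list(barcode_seq = barcode_seq, k = as.integer(k),
         tso_variants = toupper(tso_variants),
         barcode_kmers = bk, tso_kmers = tk,
         blacklist_kmers = intersect(bk, tk)),
    class = "barcode_spec"
  )
}

#' Blacklisted barcode k-mers
#'
#' Every k-mer of the barcode that also occurs in a TSO variant.
#'
#' @param spec A [barcode_spec()].
#' @return Character vector of k-mers.
#' @export
build_blacklist_kmers <- function(spec) {
  intersect(spec$barcode_kmers,
            unique(unlist(lapply(spec$tso_variants, kmer_set, k = spec$k))))
}

#' Harvest TSO sequence variants from observed clips
#'
#' Collects distinct clip sequences within a Hamming neighbourhood of a
#' reference TSO (compared over the aligned suffix/prefix of equal
#' length), a conservative stand-in for cataloguing observed TSO
#' variation from data.
#'
#' @param clip_seqs Character vector of clip sequences.
#' @param tso_ref Reference TSO sequence.
#' @param max_mismatch Maximum Hamming distance (default 2).
#' @return Character vector of harvested variants (always includes
#'   `tso_ref`).
#' @export
harvest_tso_variants <- function(clip_seqs, tso_ref, max_mismatch = 2L) {
  tso_ref <- toupper(tso_ref)
  cand <- unique(toupper(clip_seqs))
  cand <- cand[!is.na(cand) & nchar(cand) >= 6]
  hit <- vapply(cand, function(s) {
    L <- min(nchar(s), nchar(tso_ref))
    # clips are 3' fragments of the TSO: compare suffixes
    a <- substr(s, nchar(s) - L + 1L, nchar(s))
    b <- substr(tso_ref, nchar(tso_ref) - L + 1L, nchar(tso_ref))
    sum(utf8ToInt(a) != utf8ToInt(b)) <= max_mismatch
  }, logical(1))
  unique(c(tso_ref, cand[hit]))
}

#' Classify clip sequences as T7-barcoded
#'
#' A clip is called T7 when it contains at least one barcode k-mer, unless
#' all of its barcode k-mer matches are blacklisted (shared with a TSO
#' variant) and the clip has at least one additional distinct k-mer match
#' to a TSO variant — the signature of a TSO artifact. Matching is
#' case-insensitive; k-mers containing N never match. "Additional" matches
#' are counted as distinct k-mer sequences, not positions.
#'
#' @param clip_seq Character vector of clip sequences (may be empty
#'   strings; those are never T7).
#' @param spec A [barcode_spec()].
#' @return Tibble with columns `clip_seq`, `is_t7`, `n_barcode_kmers`,
#'   `n_blacklist_kmers`, `n_nonblacklist_kmers`, `tso_support`.
#' @export
classify_clip <- function(clip_seq, spec) {
  stopifnot(inherits(spec, "barcode_spec"))
  res <- lapply(clip_seq, function(s) {
    ck <- kmer_set(s %||% "", spec$k)
    mb <- intersect(ck, spec$barcode_kmers)
    mbl <- intersect(mb, spec$blacklist_kmers)
    mnb <- setdiff(mb, spec$blacklist_kmers)
    extra_tso <- setdiff(intersect(ck, spec$tso_kmers), mbl)
    is_t7 <- length(mb) >= 1 &&
      !(length(mnb) == 0 && length(mbl) >= 1 && length(extra_tso) >= 1)
    c(length(mb), length(mbl), length(mnb), length(extra_tso), is_t7)
  })
  m <- do.call(rbind, res)
  tibble::tibble(
    clip_seq = clip_seq,
    is_t7 = as.logical(m[, 5]),
    n_barcode_kmers = as.integer(m[, 1]),
    n_blacklist_kmers = as.integer(m[, 2]),
    n_nonblacklist_kmers = as.integer(m[, 3]),
    tso_support = as.integer(m[, 4])
  )
}

#' Call T7-barcoded reads and emit particular-edit observations
#'
#' Extracts 5' clips from tagged alignments, classifies each against the
#' barcode spec, and returns one particular-edit observation per
#' T7-positive read: the cell it occurred in, the breakpoint (first
#' aligned base adjacent to the clip), the insertion orientation and the
#' clip sequence, with the UMI retained for per-site molecule counting.
#'
#' @param reads Tibble from [read_tagged_alignments()].
#' @param spec A [barcode_spec()].
#' @return List with `observations` (tibble of T7-positive clip
#'   observations) and `calls` (tibble of all clip-bearing reads with
#'   their classification).
#' @export
call_t7_reads <- function(reads, spec) {
  clips <- extract_five_prime_clips(reads)
  clips <- clips[!is.na(clips$cell_barcode) & clips$cell_barcode != "", ,
                 drop = FALSE]
  cls <- classify_clip(clips$clip_seq, spec)
  calls <- dplyr::bind_cols(clips, cls[, -1, drop = FALSE])
  list(
    observations = calls[calls$is_t7, c(
      "read_id", "cell_barcode", "umi", "gene_id", "gene_name",
      "chrom", "breakpoint", "orientation", "clip_seq"
    ), drop = FALSE],
    calls = calls
  )
}

#' Expected Cas9 cut coordinate from a PAM location
#'
#' Cas9 cuts bluntly 3 bp 5' of the PAM on the protospacer strand (between
#' protospacer positions 17 and 18). For a + strand PAM starting at
#' 0-based coordinate `p` the cut coordinate is `p - 3`; for a - strand
#' PAM occupying `[p, p + 3)` it is `p + 3`.
#'
#' @param pam_start 0-based genome coordinate of the first PAM base.
#' @param strand `"+"` or `"-"` (vectorized).
#' @return Integer vector of cut coordinates (0-based; the base
#'   immediately 3' of the cut on the forward genome strand).
#' @export
expected_cut_position <- function(pam_start, strand) {
  stopifnot(all(strand %in% c("+", "-")))
  if (any(pam_start < 20 & strand == "+")) {
    stop("PAM within 20 bp of contig start")
  }
  as.integer(ifelse(strand == "+", pam_start - 3L, pam_start + 3L))
}

#' Classification performance against labeled read sets
#'
#' Sensitivity is the fraction of positive-set reads called T7;
#' specificity is one minus the fraction of negative-set reads called T7;
#' FDR is the fraction of all positive calls (within the union of the two
#' sets) that come from the negative set.
#'
#' @param calls Tibble with `read_id` and `is_t7` (e.g.
#'   `call_t7_reads()$calls`); reads absent from it are counted as not
#'   called (clip-free reads are never T7).
#' @param positive_ids,negative_ids Character vectors of read ids forming
#'   the labeled positive / negative sets.
#' @return Tibble with `sensitivity`, `specificity`, `fdr`, `tp`, `fp`,
#'   `n_pos`, `n_neg`. Undefined ratios are `NA` (never coerced to 0).
#' @export
classification_metrics <- function(calls, positive_ids, negative_ids) {
  called <- calls$read_id[calls$is_t7]
  tp <- sum(positive_ids %in% called)
  fp <- sum(negative_ids %in% called)
  n_pos <- length(positive_ids)
  n_neg <- length(negative_ids)
  tibble::tibble(
    sensitivity = if (n_pos > 0) tp / n_pos else NA_real_,
    specificity = if (n_neg > 0) 1 - fp / n_neg else NA_real_,
    fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
    tp = tp, fp = fp, n_pos = n_pos, n_neg = n_neg
  )
}

#' Reads overlapping cut-site windows
#'
#' Helper for building a window-based positive set: ids of reads whose
#' alignment span intersects any `position +/- flank` window.
#'
#' @param reads Tibble from [read_tagged_alignments()].
#' @param windows Tibble with `chrom` and `position` (0-based).
#' @param flank Half-width in bp (default 100, a 200 bp window).
#' @return Character vector of read ids.
#' @export
reads_in_windows <- function(reads, windows, flank = 100L) {
  if (nrow(windows) == 0 || nrow(reads) == 0) return(character(0))
  q <- GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(reads$ref_start + 1L, reads$ref_end)
  )
  s <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(pmax(1L, windows$position + 1L - flank),
                     windows$position + 1L + flank)
  )
  hit <- IRanges::overlapsAny(q, s)
  unique(reads$read_id[hit])
}
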