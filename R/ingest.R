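#' Read tagged single-cell alignments
#'
#' Parses a coordinate-tagged SAM/BAM file (as produced by split-pool
#' single-cell pipelines) into a tibble of primary mapped alignments with
#' corrected cell barcode, UMI and gene-assignment tags. Coordinates are
#' converted to the package-wide 0-based half-open convention:
#' `ref_start` is the first aligned base, `ref_end` is one past the last.
#'
#' @param path Path to a SAM or BAM file. Text SAM input is converted on
#'   the fly with [Rsamtools::asBam()].
#' @param min_mapq Minimum mapping quality; alignments below it are dropped.
#'   Default 0 (upstream pipelines have usually filtered already).
#' @param tags Named list with elements `cb` (cell barcode tag), `umi`
#'   (UMI tags in preference order; the first present is used), `gene_id`,
#'   `gene_name`.
#' @param require_gene If `TRUE`, reads lacking a gene-id tag are skipped
#'   as if the tag were required. Default `FALSE`: edit-marking junction
#'   reads can fall outside annotated genes and must be retained.
#' @return A tibble with one row per retained alignment: `read_id`,
#'   `chrom`, `ref_start`, `ref_end`, `strand`, `cigar`, `seq` (stored in
#'   genome-forward orientation, as in BAM), `cell_barcode`, `umi`,
#'   `gene_id`, `gene_name`, `mapq`. The number of reads skipped for
#'   missing tags is attached as `attr(, "n_skipped_tags")`.
#' @export
read_tagged_alignments <- function(path,
                                   min_mapq = 0L,
                                   tags = list(cb = "CB",
                                               umi = c("UB", "UR"),
                                               gene_id = "GX",
                                               gene_name = "GN"),
                                   require_gene = FALSE) {
  if (!file.exists(path)) {
    stop("alignment file not found: ", path)
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, destination = tempfile(),
                            overwrite = TRUE, indexDestination = TRUE)
  }
  tag_names <- unique(c(tags$cb, tags$umi, tags$gene_id, tags$gene_name))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq",
             "strand"),
    tag = tag_names,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(res$qname)
  get_tag <- function(tg) {
    v <- res$tag[[tg]]
    if (is.null(v)) rep(NA_character_, n) else as.character(v)
  }
  umi <- rep(NA_character_, n)
  for (tg in tags$umi) {
    v <- get_tag(tg)
    umi <- ifelse(is.na(umi), v, umi)
  }
  cigar <- res$cigar
  # Record-level CIGAR sanity: must consume exactly the stored query bases.
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
  seqs <- as.character(res$seq)
  bad_cigar <- is.na(qw) | qw != nchar(seqs)
  rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  out <- tibble::tibble(
    read_id = res$qname,
    chrom = as.character(res$rname),
    ref_start = res$pos - 1L,
    ref_end = res$pos - 1L + rw,
    strand = as.character(res$strand),
    cigar = cigar,
    seq = seqs,
    cell_barcode = get_tag(tags$cb),
    umi = umi,
    gene_id = get_tag(tags$gene_id),
    gene_name = get_tag(tags$gene_name),
    mapq = res$mapq
  )
  keep <- !bad_cigar & out$mapq >= min_mapq &
    !is.na(out$cell_barcode) & out$cell_barcode != "" & !is.na(out$umi)
  if (require_gene) keep <- keep & !is.na(out$gene_id)
  n_skip <- sum((!keep) & !bad_cigar)
  if (n_skip > 0) {
    message(n_skip, " alignment(s) skipped (missing required tag or low MAPQ)")
  }
  out <- out[keep, , drop = FALSE]
  attr(out, "n_skipped_tags") <- n_skip
  attr(out, "n_bad_cigar") <- sum(bad_cigar)
  out
}

#' Extract 5' soft-clip observations
#'
#' For every read whose 5' (sequenced) end carries a soft clip, returns the
#' clip in sequenced orientation together with the junction breakpoint: the
#' first aligned base adjacent to the clip (`ref_start` for forward reads,
#' `ref_end - 1` for reverse reads). Reads with no 5' soft clip, or whose
#' 5' end is hard-clipped (sequence unavailable), contribute no row; their
#' counts are attached as attributes.
#'
#' @param reads Tibble from [read_tagged_alignments()].
#' @return Tibble with columns `read_id`, `cell_barcode`, `umi`, `gene_id`,
#'   `gene_name`, `chrom`, `breakpoint` (0-based), `orientation`
#'   (`"forward"` for + strand reads, clip at the genomic left; `"reverse"`
#'   for - strand reads, clip at the genomic right), `clip_seq` (5'->3' in
#'   sequenced orientation), `clip3_len` (length of any 3' clip, kept for
#'   QC). Attributes `n_no_clip` and `n_hard_clip` count excluded reads.
#' @export
extract_five_prime_clips <- function(reads) {
  n <- nrow(reads)
  ops <- GenomicAlignments::explodeCigarOps(reads$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(reads$cigar)
  first_op <- vapply(ops, function(x) x[1], "")
  last_op <- vapply(ops, function(x) x[length(x)], "")
  first_len <- vapply(lens, function(x) x[1], 0L)
  last_len <- vapply(lens, function(x) x[length(x)], 0L)
  left_s <- ifelse(first_op == "S", first_len, 0L)
  right_s <- ifelse(last_op == "S", last_len, 0L)
  fwd <- reads$strand == "+"
  five_s <- ifelse(fwd, left_s, right_s)
  three_s <- ifelse(fwd, right_s, left_s)
  five_hard <- ifelse(fwd, first_op == "H", last_op == "H")

  keep <- five_s > 0 & !five_hard
  r <- reads[keep, , drop = FALSE]
  fwd_k <- fwd[keep]
  cliplen <- five_s[keep]
  clip_raw <- ifelse(
    fwd_k,
    substr(r$seq, 1L, cliplen),
    substr(r$seq, nchar(r$seq) - cliplen + 1L, nchar(r$seq))
  )
  clip_seq <- clip_raw
  if (any(!fwd_k)) clip_seq[!fwd_k] <- revcomp(clip_raw[!fwd_k])

  out <- tibble::tibble(
    read_id = r$read_id,
    cell_barcode = r$cell_barcode,
    umi = r$umi,
    gene_id = r$gene_id,
    gene_name = r$gene_name,
    chrom = r$chrom,
    breakpoint = ifelse(fwd_k, r$ref_start, r$ref_end - 1L),
    orientation = ifelse(fwd_k, "forward", "reverse"),
    clip_seq = clip_seq,
    clip3_len = three_s[keep]
  )
  attr(out, "n_no_clip") <- sum(five_s == 0 & !five_hard)
  attr(out, "n_hard_clip") <- sum(five_hard)
  out
}

#' Write alignments back to SAM
#'
#' Re-emits a read tibble as a text SAM file (for debugging round trips or
#' for feeding simulated reads into the ingest path). Header `@SQ` lines
#' come from `seqlengths`.
#'
#' @param reads Tibble in the layout of [read_tagged_alignments()].
#' @param seqlengths Named integer vector of contig lengths.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, seqlengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  opt <- function(tag, v) ifelse(is.na(v), "", sprintf("\t%s:Z:%s", tag, v))
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s%s%s%s",
    reads$read_id, flag, reads$chrom, reads$ref_start + 1L,
    as.integer(reads$mapq), reads$cigar, reads$seq,
    strrep("F", nchar(reads$seq)),
    opt("CB", reads$cell_barcode), opt("UB", reads$umi),
    opt("GX", reads$gene_id), opt("GN", reads$gene_name)
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}
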