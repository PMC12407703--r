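#' Find candidate protospacer targets near an edit site
#'
#' Scans both strands for NGG / NAG PAMs whose first base lies within
#' `window` bp of the site position and returns, for each, the 20 bp of
#' reference sequence immediately 5' of the PAM in protospacer-strand
#' orientation, plus the predicted blunt-cut coordinate (3 bp 5' of the
#' PAM). PAMs whose protospacer would run off the contig are skipped (the
#' scan is truncated with a warning when the window itself is clipped).
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param chrom Contig name.
#' @param position 0-based site position.
#' @param window Scan half-width in bp (default 100).
#' @return Tibble: `chrom`, `strand`, `pam_start` (0-based), `pam_seq`,
#'   `target_seq` (20 nt), `predicted_cut` (0-based).
#' @export
find_candidate_targets <- function(genome, chrom, position, window = 100L) {
  if (!chrom %in% names(genome)) stop("unknown contig: ", chrom)
  gseq <- as.character(genome[[chrom]])
  L <- nchar(gseq)
  lo <- position - window
  hi <- position + window
  if (lo < 0 || hi > L - 3) {
    warning("scan window truncated at contig edge")
    lo <- max(0L, lo); hi <- min(L - 3L, hi)
  }
  ch <- function(i) substr(gseq, i + 1L, i + 1L)  # 0-based accessor
  rows <- list()
  for (p in seq.int(lo, hi)) {
    # + strand PAM N[GA]G at [p, p+3)
    if (p >= 20 && p + 3 <= L &&
        ch(p + 1) %in% c("G", "A") && ch(p + 2) == "G") {
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = chrom, strand = "+", pam_start = p,
        pam_seq = substr(gseq, p + 1L, p + 3L),
        target_seq = substr(gseq, p - 19L, p),
        predicted_cut = p - 3L
      )
    }
    # - strand PAM occupying [p, p+3): genome reads C[CT]N
    if (p + 3 + 20 <= L && ch(p) == "C" && ch(p + 1) %in% c("C", "T")) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = chrom, strand = "-", pam_start = p,
        pam_seq = revcomp(substr(gseq, p + 1L, p + 3L)),
        target_seq = revcomp(substr(gseq, p + 4L, p + 23L)),
        predicted_cut = p + 3L
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(chrom = character(0), strand = character(0),
                          pam_start = integer(0), pam_seq = character(0),
                          target_seq = character(0),
                          predicted_cut = integer(0)))
  }
  dplyr::bind_rows(rows)
}

#' Guide-to-target sequence similarity
#'
#' Local alignment of the 20-nt protospacer against a candidate target
#' (match +1, mismatch -1, gap -0.8, gap extension -0.5). The similarity
#' `h` is the number of aligned (non-gap in either sequence) columns of
#' the best local alignment; the raw alignment score is also returned.
#'
#' @param guide_seq 20-nt protospacer.
#' @param target_seq Candidate target sequence.
#' @return List with `h` (integer) and `score` (numeric).
#' @export
guide_target_similarity <- function(guide_seq, target_seq) {
  al <- align_local(toupper(guide_seq), toupper(target_seq),
                    gap_open = 0.8, gap_extend = 0.5)
  p <- strsplit(al$pattern, "")[[1]]
  s <- strsplit(al$subject, "")[[1]]
  list(h = sum(p != "-" & s != "-"), score = al$score)
}

#' Co-occurrence scores between sites and guide on-targets
#'
#' Cosine similarity between each site's per-cell T7 UMI column and each
#' guide's on-target column, scaled per site by the sum over all
#' on-targets so scores lie in `[0, 1]` and sum to 1 whenever any raw
#' cosine is positive. Zero-norm columns give raw cosine 0; an all-zero
#' denominator leaves all scores 0 for that site.
#'
#' @param umi_matrix Cells x sites sparse matrix from
#'   [per_cell_site_umis()].
#' @param on_target_map Named character vector: guide name -> on-target
#'   `site_id` (must be columns of `umi_matrix`).
#' @return Dense matrix sites x guides of scaled scores `c`.
#' @export
cooccurrence_scores <- function(umi_matrix, on_target_map) {
  m <- as.matrix(umi_matrix)
  sites <- colnames(m)
  guides <- names(on_target_map)
  norms <- sqrt(colSums(m^2))
  raw <- matrix(0, length(sites), length(guides),
                dimnames = list(sites, guides))
  for (g in guides) {
    ot <- on_target_map[[g]]
    if (!ot %in% sites) next
    v <- m[, ot]
    nv <- norms[ot]
    if (nv == 0) next
    num <- as.numeric(crossprod(m, v))
    denom <- norms * nv
    raw[, g] <- ifelse(denom > 0, num / denom, 0)
  }
  rs <- rowSums(raw)
  sc <- raw
  pos <- rs > 0
  sc[pos, ] <- raw[pos, , drop = FALSE] / rs[pos]
  sc[!pos, ] <- 0
  sc
}

#' Assign the causal guide for each canonical edit site
#'
#' For each site, each guide's best sequence similarity `h` is taken over
#' that guide's candidate targets within the scan window (ties resolved
#' toward the candidate whose predicted cut is nearest the site). If the
#' top guide by `h` and the top guide by co-occurrence `c` agree, that
#' guide is assigned (`method = "agree"`); if all `c` are zero the top
#' guide by `h` is assigned (`"sequence_only"`); otherwise the guide
#' maximizing the joint score `(h / hl)^q + c / cl` wins
#' (`"joint_score"`), ties broken by larger `h` then guide name.
#'
#' @param sites Tibble with `site_id`, `chrom`, `position`.
#' @param guides Tibble with `name`, `protospacer`, `on_target_site_id`.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param umi_matrix Cells x sites T7 UMI matrix (may be `NULL`: all `c`
#'   treated as zero).
#' @param window PAM scan half-width (default 100).
#' @param hl,cl Joint-score normalizing constants (defaults 15 and 0.7).
#' @param q Joint-score exponent on the similarity ratio (default 10).
#' @return Tibble: `site_id`, `guide_name`, `h`, `c`, `gscore`, `method`,
#'   `target_seq`, `pam_seq`, `strand`, `cut_distance` (|predicted cut -
#'   site position|).
#' @export
assign_causal_guides <- function(sites, guides, genome, umi_matrix = NULL,
                                 window = 100L, hl = 15, cl = 0.7, q = 10) {
  if (nrow(guides) == 0) stop("no guides supplied")
  cmat <- NULL
  if (!is.null(umi_matrix)) {
    otm <- setNames(guides$on_target_site_id, guides$name)
    otm <- otm[!is.na(otm)]
    if (length(otm) > 0) cmat <- cooccurrence_scores(umi_matrix, otm)
  }
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    cand <- find_candidate_targets(genome, sites$chrom[i], sites$position[i],
                                   window)
    per_guide <- lapply(seq_len(nrow(guides)), function(gi) {
      if (nrow(cand) == 0) {
        return(tibble::tibble(h = 0L, score = 0, target_seq = NA_character_,
                              pam_seq = NA_character_, strand = NA_character_,
                              cut_distance = NA_integer_))
      }
      sims <- lapply(cand$target_seq, guide_target_similarity,
                     guide_seq = guides$protospacer[gi])
      hs <- vapply(sims, function(x) as.integer(x$h), 0L)
      dist <- abs(cand$predicted_cut - sites$position[i])
      best <- order(-hs, dist)[1]
      tibble::tibble(h = hs[best], score = sims[[best]]$score,
                     target_seq = cand$target_seq[best],
                     pam_seq = cand$pam_seq[best],
                     strand = cand$strand[best],
                     cut_distance = dist[best])
    })
    pg <- dplyr::bind_rows(per_guide)
    pg$guide_name <- guides$name
    cc <- rep(0, nrow(guides))
    if (!is.null(cmat) && sites$site_id[i] %in% rownames(cmat)) {
      hit <- match(guides$name, colnames(cmat))
      cc <- ifelse(is.na(hit), 0, cmat[sites$site_id[i], hit])
    }
    pg$c <- cc
    pick_h <- order(-pg$h, pg$guide_name)[1]
    if (all(cc == 0)) {
      sel <- pick_h; method <- "sequence_only"
    } else {
      pick_c <- order(-cc, pg$guide_name)[1]
      if (pick_c == pick_h) {
        sel <- pick_h; method <- "agree"
      } else {
        pg$gscore <- (pg$h / hl)^q + cc / cl
        sel <- order(-pg$gscore, -pg$h, pg$guide_name)[1]
        method <- "joint_score"
      }
    }
    tibble::tibble(
      site_id = sites$site_id[i], guide_name = pg$guide_name[sel],
      h = pg$h[sel], c = pg$c[sel],
      gscore = (pg$h[sel] / hl)^q + pg$c[sel] / cl,
      method = method, target_seq = pg$target_seq[sel],
      pam_seq = pg$pam_seq[sel], strand = pg$strand[sel],
      cut_distance = pg$cut_distance[sel]
    )
  })
  dplyr::bind_rows(rows)
}
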