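#' Simulation configuration
#'
#' Bundles the generative assumptions for a synthetic tagged-alignment
#' experiment: a random genome with planted protospacer/PAM instances, a
#' population of barcoded cells split into an unedited control pool and
#' an edited pool, T7-promoter donor insertions at planted cut sites with
#' breakpoint jitter, clip fragmentation and substitution error,
#' TSO-artifact clips, and background per-cell/per-gene expression with
#' dosage-dependent knockdown.
#'
#' @param seed Integer seed; the whole simulation is deterministic in it.
#' @param n_cells Total cells across pools (default 500).
#' @param control_fraction Fraction of cells in the unedited pool
#'   (default 0.3).
#' @param n_contigs,contig_length,gc Genome shape (default 2 contigs of
#'   120 kb at 41% GC).
#' @param n_genes,gene_length Gene models tiled over the contigs
#'   (default 40 genes of 4 kb).
#' @param gene_mean_range Range of per-gene mean molecules per cell.
#' @param nb_size Negative-binomial size (common dispersion) for
#'   background counts.
#' @param cell_depth_sd SD of the log-normal per-cell depth factor.
#' @param n_guides Number of guide RNAs (default 4; pairwise protospacer
#'   Hamming distance at least 12 so off-targets are attributable).
#' @param on_target_probs Per-cell edit probability at each on-target
#'   site, conditional on guide activity.
#' @param off_targets Tibble with `guide_index`, `mismatches`, `pam`
#'   (`"NGG"`/`"NAG"`), `edit_prob` describing planted off-target sites.
#' @param guide_activity Probability a given edited-pool cell is active
#'   for a given guide (drives on/off-target co-occurrence).
#' @param p_two_alleles P(dosage 2 | edited), capped at gene copy number.
#' @param barcode,donor_clip_ref Transcribed barcode and the donor-derived
#'   clip reference carried by T7 reads (default both `GGGAGAGTAT`).
#' @param jitter_max Maximum |breakpoint - expected cut| in bp (default
#'   3).
#' @param clip_fragmentation Probability a T7 read's clip is truncated by
#'   library fragmentation (suffix retained).
#' @param min_frag_len Minimum retained clip length under fragmentation
#'   (default 6: shorter junction fragments do not retain a full k-mer
#'   and are not recognizable; set to 1 to model unrecoverable
#'   fragments).
#' @param substitution_error Per-base substitution rate applied to clip
#'   sequences.
#' @param tso_ref Template-switch oligo reference sequence.
#' @param tso_artifact_rate TSO-artifact clips per background molecule.
#' @param bg_clip_rate Fraction of background reads carrying a short
#'   random (non-barcode) soft clip.
#' @param t7_reads_mean Mean T7 reads per edited allele (min 1).
#' @param umi_length,umi_dup_rate UMI length and the rate of injecting a
#'   Hamming-1 duplicate UMI read per molecule.
#' @param reads_per_umi_extra Mean extra reads per background molecule.
#' @param read_length Read length in bp.
#' @param knockdown Multiplicative expression factor per edited allele of
#'   a gene (frameshift-mediated decay).
#' @param trans_effects Optional tibble (`gene_id`, `effect`) of
#'   expression multipliers applied in cells carrying any edit.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_cells = 500L,
                       control_fraction = 0.3,
                       n_contigs = 2L,
                       contig_length = 120000L,
                       gc = 0.41,
                       n_genes = 40L,
                       gene_length = 4000L,
                       gene_mean_range = c(0.5, 3),
                       nb_size = 2,
                       cell_depth_sd = 0.3,
                       n_guides = 4L,
                       on_target_probs = c(0.15, 0.20, 0.10, 0.12),
                       off_targets = tibble::tibble(
                         guide_index = c(1L, 2L, 4L),
                         mismatches = c(2L, 3L, 4L),
                         pam = c("NGG", "NAG", "NGG"),
                         edit_prob = c(0.08, 0.05, 0.10)
                       ),
                       guide_activity = 0.7,
                       p_two_alleles = 0.4,
                       barcode = "GGGAGAGTAT",
                       donor_clip_ref = "GGGAGAGTAT",
                       jitter_max = 3L,
                       clip_fragmentation = 0.4,
                       min_frag_len = 6L,
                       substitution_error = 0.01,
                       tso_ref = "AAGCAGTGGTATCAACGCAGAGTAC",
                       tso_artifact_rate = 0.01,
                       bg_clip_rate = 0.05,
                       t7_reads_mean = 4,
                       umi_length = 10L,
                       umi_dup_rate = 0.05,
                       reads_per_umi_extra = 0.2,
                       read_length = 90L,
                       knockdown = 0.5,
                       trans_effects = NULL) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$on_target_probs) == cfg$n_guides,
            all(cfg$off_targets$guide_index <= cfg$n_guides),
            cfg$control_fraction > 0, cfg$control_fraction < 1)
  structure(cfg, class = "sim_config")
}

rand_dna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

rand_umis <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), n, len)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

mutate_one_base <- function(s) {
  i <- sample(nchar(s), 1)
  b <- substr(s, i, i)
  substr(s, i, i) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
  s
}

# Apply per-base substitution errors to each sequence.
add_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    for (i in hit) {
      b <- substr(s, i, i)
      substr(s, i, i) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }
    s
  }, "", USE.NAMES = FALSE)
}

# Mutate `mm` distinct positions of a protospacer to different bases.
mutate_protospacer <- function(ps, mm) {
  pos <- sample(nchar(ps), mm)
  for (i in pos) {
    b <- substr(ps, i, i)
    substr(ps, i, i) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }
  ps
}

str_hamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

# Remove occurrences of any `kmers` within [lo, hi] (0-based) of a contig
# string by mutating the middle base; iterates in case a mutation creates
# a fresh occurrence.
scrub_kmers <- function(contig, kmers, lo, hi) {
  lo <- max(0L, lo); hi <- min(nchar(contig) - 1L, hi)
  pat <- paste(kmers, collapse = "|")
  for (iter in 1:20) {
    win <- substr(contig, lo + 1L, hi + 1L)
    m <- gregexpr(pat, win)[[1]]
    if (m[1] == -1) break
    for (st in as.integer(m)) {
      i <- lo + st + 2L  # 1-based middle-ish base of the k-mer
      b <- substr(contig, i, i)
      substr(contig, i, i) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }
  }
  contig
}

#' Simulate a genome with planted edit sites
#'
#' Generates random contigs, tiles gene models over them, draws guide
#' protospacers (pairwise Hamming distance >= 12) and plants
#' protospacer + PAM instances at on-target positions (exact match, NGG)
#' and off-target positions (the configured number of mismatches, NGG or
#' NAG), alternating strands. Planted sites sit inside distinct genes;
#' the expected Cas9 cut is 3 bp 5' of each planted PAM.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` ([Biostrings::DNAStringSet]), `seqlengths`,
#'   `genes` (tibble: `gene_id`, `gene_name`, `chrom`, `start`, `end`,
#'   `strand`, `mean_expr`, `copy_number`), `guides` (tibble: `name`,
#'   `protospacer`, `on_target_site`), `sites` (tibble: `site_name`,
#'   `guide`, `chrom`, `strand`, `pam_start`, `pam`, `cut`, `edit_prob`,
#'   `gene_id`, `is_on_target`, `mismatches`).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    contigs <- setNames(
      vapply(seq_len(cfg$n_contigs), function(i)
        rand_dna(cfg$contig_length, cfg$gc), ""),
      sprintf("chr%d", seq_len(cfg$n_contigs))
    )
    # genes tiled round-robin over contigs
    per_contig <- ceiling(cfg$n_genes / cfg$n_contigs)
    margin <- 2000L
    gap <- max(200L, (cfg$contig_length - 2L * margin -
                        per_contig * cfg$gene_length) %/% per_contig)
    genes <- tibble::tibble(
      gene_id = sprintf("G%03d", seq_len(cfg$n_genes)),
      gene_name = sprintf("Gene%03d", seq_len(cfg$n_genes)),
      chrom = sprintf("chr%d", ((seq_len(cfg$n_genes) - 1L) %%
                                  cfg$n_contigs) + 1L),
      slot = (seq_len(cfg$n_genes) - 1L) %/% cfg$n_contigs,
      strand = rep(c("+", "-"), length.out = cfg$n_genes),
      mean_expr = runif(cfg$n_genes, cfg$gene_mean_range[1],
                        cfg$gene_mean_range[2]),
      copy_number = 2L
    )
    genes$start <- margin + genes$slot * (cfg$gene_length + gap)
    genes$end <- genes$start + cfg$gene_length
    genes$slot <- NULL
    stopifnot(all(genes$end <= cfg$contig_length))

    # guide protospacers: pairwise far apart and free of barcode k-mers
    bc_kmers <- unique(c(kmer_set(cfg$barcode, 6L),
                         kmer_set(revcomp(cfg$barcode), 6L)))
    has_bc_kmer <- function(s) any(bc_kmers %in% kmer_set(s, 6L))
    draw_guides <- function() {
      repeat {
        ps <- vapply(seq_len(cfg$n_guides), function(i) rand_dna(20, 0.5), "")
        d <- outer(ps, ps, Vectorize(str_hamming))
        if (all(d[upper.tri(d)] >= 12) &&
            !any(vapply(ps, has_bc_kmer, TRUE))) return(ps)
      }
    }
    protospacers <- draw_guides()
    guides <- tibble::tibble(
      name = sprintf("guide%d", seq_len(cfg$n_guides)),
      protospacer = protospacers
    )

    # site plan: on-targets in genes 1..n_guides, off-targets in the next
    n_off <- nrow(cfg$off_targets)
    host <- c(seq_len(cfg$n_guides), cfg$n_guides + seq_len(n_off))
    stopifnot(max(host) <= cfg$n_genes)
    plan <- tibble::tibble(
      site_name = c(sprintf("on_%s", guides$name),
                    sprintf("off%d_%s", seq_len(n_off),
                            guides$name[cfg$off_targets$guide_index])),
      guide = c(guides$name, guides$name[cfg$off_targets$guide_index]),
      mismatches = c(rep(0L, cfg$n_guides), cfg$off_targets$mismatches),
      pam_class = c(rep("NGG", cfg$n_guides), cfg$off_targets$pam),
      edit_prob = c(cfg$on_target_probs, cfg$off_targets$edit_prob),
      gene_id = genes$gene_id[host],
      chrom = genes$chrom[host],
      is_on_target = c(rep(TRUE, cfg$n_guides), rep(FALSE, n_off)),
      strand = rep(c("+", "-"), length.out = cfg$n_guides + n_off)
    )
    # plant each site so its cut lands ~600 bp into the host gene
    plan$cut <- genes$start[host] + 600L
    plan$pam <- ifelse(plan$pam_class == "NGG", "TGG", "TAG")
    plan$pam_start <- ifelse(plan$strand == "+", plan$cut + 3L,
                             plan$cut - 3L)
    # Edit sites are planted in barcode-dissimilar sequence (guides are
    # chosen for specificity): scrub barcode k-mers near each cut so the
    # region blacklist reflects genuine barcode-like loci elsewhere.
    for (i in seq_len(nrow(plan))) {
      ctg <- plan$chrom[i]
      contigs[[ctg]] <- scrub_kmers(contigs[[ctg]], bc_kmers,
                                    lo = plan$cut[i] - 250L,
                                    hi = plan$cut[i] + 250L)
    }
    for (i in seq_len(nrow(plan))) {
      ps <- guides$protospacer[guides$name == plan$guide[i]]
      if (plan$mismatches[i] > 0) ps <- mutate_protospacer(ps, plan$mismatches[i])
      ctg <- plan$chrom[i]
      if (plan$strand[i] == "+") {
        # protospacer [pam_start-20, pam_start), PAM [pam_start, pam_start+3)
        s0 <- plan$pam_start[i] - 20L
        substr(contigs[[ctg]], s0 + 1L, s0 + 23L) <-
          paste0(ps, plan$pam[i])
      } else {
        # genome carries revcomp(PAM) at [pam_start, +3), revcomp(ps) after
        p <- plan$pam_start[i]
        substr(contigs[[ctg]], p + 1L, p + 23L) <-
          paste0(revcomp(plan$pam[i]), revcomp(ps))
      }
    }
    guides$on_target_site <- plan$site_name[match(guides$name, plan$guide)]
    list(
      genome = Biostrings::DNAStringSet(contigs),
      seqlengths = setNames(rep(cfg$contig_length, cfg$n_contigs),
                            names(contigs)),
      genes = genes,
      guides = guides,
      sites = plan[, c("site_name", "guide", "chrom", "strand", "pam_start",
                       "pam", "cut", "edit_prob", "gene_id", "is_on_target",
                       "mismatches")]
    )
  })
}

#' Simulate a tagged-alignment experiment
#'
#' Draws edits, T7 junction reads, background expression reads, UMI
#' duplicates and TSO artifacts per the configuration, against a genome
#' from [simulate_genome()]. Reads are emitted pre-aligned (the pipeline
#' consumes aligner output, so records are constructed directly), with
#' CB/UB/GX/GN tags.
#'
#' @param cfg A [sim_config()].
#' @param gen Result of [simulate_genome()].
#' @return List with `reads` (tibble accepted by [write_sam()]), `cells`
#'   (tibble: `cell_barcode`, `sample_label`), and `truth`: `read_class`
#'   (`read_id`, `class`), `cell_site_alleles` (`cell_barcode`,
#'   `site_name`, `gene_id`, `chrom`, `cut`, `n_alleles`),
#'   `cell_gene_dosage` (capped at copy number), `sites` (planted-site
#'   table), `expression_multiplier` (`cell_barcode`, `gene_id`,
#'   `multiplier`).
#' @export
simulate_experiment <- function(cfg, gen) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 1000003L, {
    gstr <- setNames(as.character(gen$genome), names(gen$genome))
    n_ctrl <- round(cfg$n_cells * cfg$control_fraction)
    cells <- tibble::tibble(
      cell_barcode = sprintf("CELL%04d", seq_len(cfg$n_cells)),
      sample_label = rep(c("control", "edited"),
                         c(n_ctrl, cfg$n_cells - n_ctrl))
    )
    edited_cells <- cells$cell_barcode[cells$sample_label == "edited"]
    activity <- matrix(
      runif(length(edited_cells) * nrow(gen$guides)) < cfg$guide_activity,
      length(edited_cells), nrow(gen$guides),
      dimnames = list(edited_cells, gen$guides$name)
    )
    caps <- setNames(gen$genes$copy_number, gen$genes$gene_id)

    # ---- edit truth: alleles per (cell, site) ----
    allele_rows <- list()
    for (si in seq_len(nrow(gen$sites))) {
      s <- gen$sites[si, ]
      act <- edited_cells[activity[, s$guide]]
      hit <- act[runif(length(act)) < s$edit_prob]
      if (length(hit) == 0) next
      n_all <- 1L + rbinom(length(hit), 1L, cfg$p_two_alleles)
      n_all <- pmin(n_all, caps[[s$gene_id]])
      allele_rows[[length(allele_rows) + 1]] <- tibble::tibble(
        cell_barcode = hit, site_name = s$site_name, gene_id = s$gene_id,
        chrom = s$chrom, cut = s$cut, n_alleles = n_all
      )
    }
    cell_site <- dplyr::bind_rows(allele_rows)
    if (nrow(cell_site) == 0) {
      cell_site <- tibble::tibble(cell_barcode = character(0),
                                  site_name = character(0),
                                  gene_id = character(0),
                                  chrom = character(0), cut = integer(0),
                                  n_alleles = integer(0))
    }

    # ---- T7 junction reads ----
    t7 <- list()
    rid <- 0L
    donor <- cfg$donor_clip_ref
    dl <- nchar(donor)
    for (i in seq_len(nrow(cell_site))) {
      row <- cell_site[i, ]
      ctg_len <- nchar(gstr[[row$chrom]])
      for (al in seq_len(row$n_alleles)) {
        orient <- sample(c("forward", "reverse"), 1)
        offset <- sample(0:cfg$jitter_max, 1) * sample(c(-1L, 1L), 1)
        bp <- row$cut + offset
        n_reads <- 1L + rpois(1, max(0, cfg$t7_reads_mean - 1))
        umis <- rand_umis(n_reads, cfg$umi_length)
        for (r in seq_len(n_reads)) {
          clip <- donor
          if (runif(1) < cfg$clip_fragmentation) {
            lo <- min(cfg$min_frag_len, dl - 1L)
            keep <- sample(lo:(dl - 1L), 1)
            clip <- substr(donor, dl - keep + 1L, dl)
          }
          clip <- add_substitutions(clip, cfg$substitution_error)
          cl <- nchar(clip)
          rid <- rid + 1L
          if (orient == "forward") {
            m <- min(cfg$read_length - cl, ctg_len - bp)
            t7[[length(t7) + 1]] <- tibble::tibble(
              read_id = sprintf("t7_%06d", rid), chrom = row$chrom,
              ref_start = bp, ref_end = bp + m, strand = "+",
              cigar = sprintf("%dS%dM", cl, m),
              seq = paste0(clip, substr(gstr[[row$chrom]], bp + 1L, bp + m)),
              cell_barcode = row$cell_barcode, umi = umis[r],
              gene_id = row$gene_id,
              gene_name = gen$genes$gene_name[match(row$gene_id,
                                                    gen$genes$gene_id)],
              mapq = 60L
            )
          } else {
            e <- bp + 1L
            m <- min(cfg$read_length - cl, e)
            t7[[length(t7) + 1]] <- tibble::tibble(
              read_id = sprintf("t7_%06d", rid), chrom = row$chrom,
              ref_start = e - m, ref_end = e, strand = "-",
              cigar = sprintf("%dM%dS", m, cl),
              seq = paste0(substr(gstr[[row$chrom]], e - m + 1L, e),
                           revcomp(clip)),
              cell_barcode = row$cell_barcode, umi = umis[r],
              gene_id = row$gene_id,
              gene_name = gen$genes$gene_name[match(row$gene_id,
                                                    gen$genes$gene_id)],
              mapq = 60L
            )
          }
        }
      }
    }
    t7 <- dplyr::bind_rows(t7)

    # ---- gene-level dosage truth and expression multipliers ----
    cell_gene <- cell_site |>
      dplyr::group_by(.data$cell_barcode, .data$gene_id) |>
      dplyr::summarise(dosage = sum(.data$n_alleles), .groups = "drop")
    if (nrow(cell_gene) > 0) {
      cell_gene$dosage <- pmin(cell_gene$dosage, caps[cell_gene$gene_id])
    }

    # ---- background expression reads ----
    depth <- setNames(exp(rnorm(cfg$n_cells, 0, cfg$cell_depth_sd)),
                      cells$cell_barcode)
    mu <- outer(gen$genes$mean_expr, depth[cells$cell_barcode])
    rownames(mu) <- gen$genes$gene_id
    if (nrow(cell_gene) > 0) {
      idx <- cbind(match(cell_gene$gene_id, gen$genes$gene_id),
                   match(cell_gene$cell_barcode, cells$cell_barcode))
      mu[idx] <- mu[idx] * cfg$knockdown^cell_gene$dosage
    }
    if (!is.null(cfg$trans_effects) && nrow(cell_site) > 0) {
      hit_cells <- unique(cell_site$cell_barcode)
      gi <- match(cfg$trans_effects$gene_id, gen$genes$gene_id)
      ci <- match(hit_cells, cells$cell_barcode)
      mu[gi, ci] <- mu[gi, ci] * cfg$trans_effects$effect
    }
    counts <- matrix(rnbinom(length(mu), mu = mu, size = cfg$nb_size),
                     nrow(mu), ncol(mu), dimnames = dimnames(mu))
    gene_idx <- rep(rep(seq_len(nrow(mu)), ncol(mu)), as.vector(counts))
    cell_idx <- rep(rep(seq_len(ncol(mu)), each = nrow(mu)),
                    as.vector(counts))
    n_mol <- length(gene_idx)
    g <- gen$genes[gene_idx, ]
    pos_max <- pmax(g$start + 1L, g$end - cfg$read_length)
    starts <- g$start + floor(runif(n_mol) * (pos_max - g$start))
    m_len <- pmin(cfg$read_length, nchar(gstr[g$chrom]) - starts)
    bg <- tibble::tibble(
      read_id = sprintf("bg_%07d", seq_len(n_mol)),
      chrom = g$chrom, ref_start = as.integer(starts),
      ref_end = as.integer(starts + m_len),
      strand = sample(c("+", "-"), n_mol, replace = TRUE),
      cigar = sprintf("%dM", m_len),
      seq = substring(gstr[g$chrom], starts + 1L, starts + m_len),
      cell_barcode = cells$cell_barcode[cell_idx],
      umi = rand_umis(n_mol, cfg$umi_length),
      gene_id = g$gene_id, gene_name = g$gene_name, mapq = 60L
    )
    # short random clips on a fraction of background reads
    if (cfg$bg_clip_rate > 0 && n_mol > 0) {
      clip_i <- which(runif(n_mol) < cfg$bg_clip_rate)
      for (i in clip_i) {
        cl <- sample(4:8, 1)
        rc <- rand_dna(cl, 0.5)
        if (bg$strand[i] == "+") {
          bg$cigar[i] <- sprintf("%dS%s", cl, bg$cigar[i])
          bg$seq[i] <- paste0(rc, bg$seq[i])
        } else {
          bg$cigar[i] <- sprintf("%s%dS", bg$cigar[i], cl)
          bg$seq[i] <- paste0(bg$seq[i], rc)
        }
      }
    }
    # extra reads per molecule and Hamming-1 UMI duplicates
    extra_n <- rpois(n_mol, cfg$reads_per_umi_extra)
    dup_rows <- bg[rep(seq_len(n_mol), extra_n), , drop = FALSE]
    umi_dup <- which(runif(n_mol) < cfg$umi_dup_rate)
    dup2 <- bg[umi_dup, , drop = FALSE]
    if (nrow(dup2) > 0) {
      dup2$umi <- vapply(dup2$umi, mutate_one_base, "")
    }
    extra <- dplyr::bind_rows(dup_rows, dup2)
    if (nrow(extra) > 0) {
      extra$read_id <- sprintf("bgx_%07d", seq_len(nrow(extra)))
    }
    bg <- dplyr::bind_rows(bg, extra)

    # ---- TSO artifact reads ----
    n_tso <- rpois(1, cfg$tso_artifact_rate * n_mol)
    tso <- NULL
    if (n_tso > 0) {
      gi <- sample(nrow(gen$genes), n_tso, replace = TRUE)
      gg <- gen$genes[gi, ]
      tlen <- nchar(cfg$tso_ref)
      keep <- sample(8:min(16, tlen), n_tso, replace = TRUE)
      clips <- add_substitutions(
        substr(rep(cfg$tso_ref, n_tso), tlen - keep + 1L, tlen),
        cfg$substitution_error
      )
      pos <- gg$start + floor(runif(n_tso) * (gg$end - gg$start - 100))
      strand <- sample(c("+", "-"), n_tso, replace = TRUE)
      cl <- nchar(clips)
      m <- cfg$read_length - cl
      tso <- tibble::tibble(
        read_id = sprintf("tso_%05d", seq_len(n_tso)),
        chrom = gg$chrom,
        ref_start = as.integer(ifelse(strand == "+", pos, pos - m + 1L)),
        ref_end = as.integer(ifelse(strand == "+", pos + m, pos + 1L)),
        strand = strand,
        cigar = ifelse(strand == "+", sprintf("%dS%dM", cl, m),
                       sprintf("%dM%dS", m, cl)),
        seq = ifelse(
          strand == "+",
          paste0(clips, substring(gstr[gg$chrom], pos + 1L, pos + m)),
          paste0(substring(gstr[gg$chrom], pos - m + 2L, pos + 1L),
                 revcomp(clips))
        ),
        cell_barcode = sample(cells$cell_barcode, n_tso, replace = TRUE),
        umi = rand_umis(n_tso, cfg$umi_length),
        gene_id = gg$gene_id, gene_name = gg$gene_name, mapq = 60L
      )
    }

    reads <- dplyr::bind_rows(t7, bg, tso)
    read_class <- tibble::tibble(
      read_id = reads$read_id,
      class = dplyr::case_when(
        grepl("^t7_", reads$read_id) ~ "t7",
        grepl("^tso_", reads$read_id) ~ "tso_artifact",
        TRUE ~ "background"
      )
    )
    mult <- cell_gene
    if (nrow(mult) > 0) mult$multiplier <- cfg$knockdown^mult$dosage
    list(
      reads = reads,
      cells = cells,
      truth = list(
        read_class = read_class,
        cell_site_alleles = cell_site,
        cell_gene_dosage = cell_gene,
        sites = gen$sites,
        expression_multiplier = mult
      )
    )
  })
}

#' Write ground-truth tables
#'
#' @param truth The `truth` element of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Paths of the written TSVs, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(truth)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write.table(truth[[nm]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
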