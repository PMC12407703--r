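#' Run the edit-calling pipeline on a tagged alignment file
#'
#' Convenience wrapper chaining the stages: ingest tagged alignments,
#' call T7-barcoded reads, aggregate particular edits, cluster into
#' canonical sites, apply confidence filters (with an optionally supplied
#' or genome-derived region blacklist), build the per-cell T7 UMI matrix,
#' call per-cell edit alleles at confident sites, roll dosage up to
#' genes, and (when guides are supplied) infer the causal guide per
#' confident site.
#'
#' @param alignments Path to a SAM/BAM file, or a read tibble from
#'   [read_tagged_alignments()].
#' @param genome Named [Biostrings::DNAStringSet].
#' @param genes Gene-model tibble (`gene_id`, `chrom`, `start`, `end`,
#'   optional `copy_number`).
#' @param spec A [barcode_spec()].
#' @param guides Optional tibble (`name`, `protospacer`); on-target site
#'   ids are resolved as the confident site nearest each guide's
#'   `on_target_position` (tibble columns `chrom`, `position`) when
#'   given, else by best sequence similarity.
#' @param blacklist Optional `GRanges`; by default built from the genome
#'   with [build_region_blacklist()].
#' @param min_cells,max_fr_gap,radius Site-calling parameters (defaults
#'   3, 15, 140).
#' @param dosage_flank Site-to-gene assignment flank (default 140).
#' @param min_mapq Passed to the reader.
#' @return List with `reads`, `calls`, `particulars`, `clustering`,
#'   `sites` (with confidence columns), `umi_matrix`, `alleles`,
#'   `dosage`, `guide_assignments` (or `NULL`).
#' @export
run_edit_calling <- function(alignments, genome, genes, spec,
                             guides = NULL, blacklist = NULL,
                             min_cells = 3L, max_fr_gap = 15L,
                             radius = 140L, dosage_flank = 140L,
                             min_mapq = 0L) {
  reads <- if (is.character(alignments)) {
    read_tagged_alignments(alignments, min_mapq = min_mapq)
  } else {
    alignments
  }
  t7 <- call_t7_reads(reads, spec)
  particulars <- aggregate_particular_edits(t7$observations)
  clustering <- cluster_edit_sites(particulars, radius = radius)
  if (is.null(blacklist)) {
    blacklist <- build_region_blacklist(genome, spec)
  }
  sites <- compute_site_stats(clustering, particulars)
  sites <- filter_canonical_sites(sites, blacklist, min_cells = min_cells,
                                  max_fr_gap = max_fr_gap)
  umi_matrix <- per_cell_site_umis(clustering, particulars)
  conf <- sites[sites$confident, , drop = FALSE]
  conf_membership <- clustering$membership[
    clustering$membership$site_id %in% conf$site_id, , drop = FALSE]
  alleles <- call_alleles(particulars, list(membership = conf_membership))
  copy_number <- NULL
  if ("copy_number" %in% names(genes)) {
    copy_number <- setNames(genes$copy_number, genes$gene_id)
  }
  dosage <- gene_edit_dosage(alleles, conf, genes, copy_number,
                             flank = dosage_flank)
  guide_assignments <- NULL
  if (!is.null(guides) && nrow(conf) > 0) {
    gdf <- guides
    if (!"on_target_site_id" %in% names(gdf)) {
      gdf$on_target_site_id <- NA_character_
      if (all(c("on_target_chrom", "on_target_position") %in% names(gdf))) {
        for (i in seq_len(nrow(gdf))) {
          cand <- conf[conf$chrom == gdf$on_target_chrom[i], , drop = FALSE]
          if (nrow(cand) == 0) next
          d <- abs(cand$position - gdf$on_target_position[i])
          if (min(d) <= radius) {
            gdf$on_target_site_id[i] <- cand$site_id[which.min(d)]
          }
        }
      }
    }
    guide_assignments <- assign_causal_guides(
      conf, gdf, genome,
      umi_matrix = umi_matrix[, conf$site_id[conf$site_id %in%
                                               colnames(umi_matrix)],
                              drop = FALSE]
    )
  }
  list(reads = reads, calls = t7$calls, particulars = particulars,
       clustering = clustering, sites = sites, umi_matrix = umi_matrix,
       alleles = alleles, dosage = dosage,
       guide_assignments = guide_assignments)
}
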