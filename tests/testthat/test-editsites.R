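obs_row <- function(cell, bp, orient = "forward", clip = "GGGAGAGTAT",
                    umi = NULL, chrom = "chr1") {
  tibble::tibble(read_id = paste0("r", cell, bp, orient, umi %||% "U"),
                 cell_barcode = cell, umi = umi %||% paste0("U", bp),
                 gene_id = NA_character_, gene_name = NA_character_,
                 chrom = chrom, breakpoint = bp, orientation = orient,
                 clip_seq = clip)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("particular edits aggregate by cell/position/orientation/clip", {
  obs <- dplyr::bind_rows(
    obs_row("c1", 100, umi = "A"), obs_row("c1", 100, umi = "B"),
    obs_row("c1", 100, umi = "B"),
    obs_row("c1", 100, orient = "reverse", umi = "C")
  )
  pe <- aggregate_particular_edits(obs)
  expect_equal(nrow(pe), 2)
  fwd <- pe[pe$orientation == "forward", ]
  expect_equal(fwd$n_reads, 3L)
  expect_equal(fwd$n_umis, 2L)
  expect_equal(nrow(aggregate_particular_edits(obs[0, ])), 0)
})

test_that("greedy clustering merges within 140 bp and splits beyond", {
  ps <- tibble::tibble(
    chrom = "chr1", breakpoint = c(1000L, 1100L),
    orientation = "forward", clip_seq = "GGGAGAGTAT",
    n_cells = c(5L, 2L)
  )
  cl <- cluster_edit_sites(sites_to_particulars(ps))
  expect_equal(nrow(cl$sites), 1)
  expect_equal(cl$sites$position, 1000L)
  expect_equal(sort(unique(cl$membership$site_id)), cl$sites$site_id)

  ps$breakpoint[2] <- 1250L
  ps$n_cells[2] <- 4L
  cl2 <- cluster_edit_sites(sites_to_particulars(ps))
  expect_equal(sort(cl2$sites$position), c(1000L, 1250L))
})

test_that("clustering matches the brute-force greedy oracle", {
  set.seed(101)
  for (i in 1:50) {
    ps <- random_particular_sites()
    part <- sites_to_particulars(ps)
    got <- cluster_edit_sites(part)$membership
    want <- oracle_cluster(ps)
    key <- function(d) paste(d$chrom, d$breakpoint, d$orientation, d$clip_seq)
    expect_equal(got$site_id[order(key(got))],
                 want$site_id[order(key(want))])
  }
})

test_that("clustering partitions the particular sites", {
  set.seed(102)
  for (i in 1:20) {
    ps <- random_particular_sites()
    cl <- cluster_edit_sites(sites_to_particulars(ps))
    expect_equal(nrow(cl$membership), nrow(ps))
    expect_false(any(is.na(cl$membership$site_id)))
    # every member within the radius of its founder
    pos <- setNames(cl$sites$position, cl$sites$site_id)
    expect_true(all(abs(cl$membership$breakpoint -
                          pos[cl$membership$site_id]) <= 140))
    # founder dominance: founder cell support is maximal within its site
    support <- dplyr::inner_join(
      cl$membership,
      ps, by = c("chrom", "breakpoint", "orientation", "clip_seq"))
    agg <- support |> dplyr::group_by(site_id) |>
      dplyr::summarise(
        founder_n = max(n_cells[breakpoint == pos[site_id[1]]]),
        max_n = max(n_cells))
    expect_true(all(agg$founder_n == agg$max_n))
  }
})

test_that("site stats report the minimum forward-reverse gap", {
  mk <- function(fwd, rev) {
    rows <- c(lapply(seq_along(fwd), function(i)
      obs_row(paste0("cf", i), fwd[i], "forward", umi = paste0("uf", i))),
      lapply(seq_along(rev), function(i)
        obs_row(paste0("cr", i), rev[i], "reverse", umi = paste0("ur", i))))
    pe <- aggregate_particular_edits(dplyr::bind_rows(rows))
    cl <- cluster_edit_sites(pe)
    compute_site_stats(cl, pe)
  }
  expect_equal(mk(100L, 103L)$min_fr_gap, 3)
  expect_equal(mk(c(100L, 120L), 112L)$min_fr_gap, 8)
  fonly <- mk(c(100L, 101L), integer(0))
  expect_equal(fonly$min_fr_gap, Inf)
  expect_false(fonly$has_reverse)
  expect_equal(mk(c(100L, 120L), 112L)$n_cells, 3L)
})

test_that("confidence filtering applies the four criteria with reasons", {
  base <- tibble::tibble(
    site_id = sprintf("s%d", 1:4), chrom = "chr1",
    position = c(500L, 2000L, 4000L, 6000L), n_particular = 1L,
    n_cells = c(5L, 10L, 3L, 4L), n_umis = 10L,
    has_forward = TRUE, has_reverse = c(TRUE, FALSE, TRUE, TRUE),
    min_fr_gap = c(4, Inf, 20, 2)
  )
  bl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5990, 6010),
                               label = "simple_repeat")
  out <- filter_canonical_sites(base, bl)
  expect_equal(out$confident, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$reject_reason,
               c(NA, "unidirectional", "fr_gap", "blacklisted"))
  low <- base; low$n_cells[1] <- 2L
  expect_equal(filter_canonical_sites(low, bl)$reject_reason[1],
               "too_few_cells")
  # idempotent and order-independent
  twice <- filter_canonical_sites(out, bl)
  expect_equal(twice$confident, out$confident)
  shuf <- filter_canonical_sites(base[c(3, 1, 4, 2), ], bl)
  expect_equal(shuf$confident[order(shuf$site_id)],
               out$confident[order(out$site_id)])
})

test_that("region blacklist finds planted repeats and barcode-like loci", {
  spec <- barcode_spec()
  clean <- strrep("ACGT", 1000)  # no barcode 6-mers, no homopolymers
  polyA <- paste0(substr(clean, 1, 1200), strrep("A", 60),
                  substr(clean, 1261, 4000))
  g1 <- Biostrings::DNAStringSet(c(c1 = polyA))
  bl <- build_region_blacklist(g1, spec)
  rep_iv <- bl[bl$label == "simple_repeat"]
  expect_equal(length(rep_iv), 1)
  expect_lte(IRanges::start(rep_iv), 1201)
  expect_gte(IRanges::end(rep_iv), 1260)

  bc <- spec$barcode_seq
  planted <- paste0(substr(clean, 1, 500), bc,
                    substr(clean, 511, 560), revcomp(bc),
                    substr(clean, 581, 4000))
  g2 <- Biostrings::DNAStringSet(c(c1 = planted))
  bl2 <- build_region_blacklist(g2, spec)
  like <- bl2[bl2$label == "barcode_like"]
  expect_gte(length(like), 1)
  expect_lte(min(IRanges::start(like)), 501 + 4)
  expect_gte(max(IRanges::end(like)), 561)

  expect_equal(length(build_region_blacklist(
    Biostrings::DNAStringSet(c(c1 = clean)), spec)), 0)
  expect_error(build_region_blacklist(g1, spec, peaks_bed = "absent.bed"),
               "BED")
})

test_that("per-cell site UMI matrix counts distinct UMIs", {
  obs <- dplyr::bind_rows(
    obs_row("c1", 100, umi = "A"), obs_row("c1", 100, umi = "B"),
    obs_row("c1", 102, umi = "B", orient = "reverse"),
    obs_row("c2", 100, umi = "Z")
  )
  pe <- aggregate_particular_edits(obs)
  cl <- cluster_edit_sites(pe)
  m <- per_cell_site_umis(cl, pe)
  expect_equal(dim(m), c(2L, 1L))
  expect_equal(as.numeric(m["c1", ]), 2)  # A, B (B shared across particulars)
  expect_equal(as.numeric(m["c2", ]), 1)
  expect_equal(Matrix::colSums(m)[[1]], 3)
})

test_that("whitelist mode recovers sites within 140 bp", {
  obs <- dplyr::bind_rows(obs_row("c1", 5100), obs_row("c2", 5260))
  pe <- aggregate_particular_edits(obs)
  wl <- tibble::tibble(site_id = "w1", chrom = "chr1", position = 5000L)
  memb <- match_whitelisted_sites(pe, wl)
  expect_equal(memb$site_id, "w1")       # 5100 within 140 of 5000
  expect_equal(memb$breakpoint, 5100L)   # 5260 is beyond the radius
})

test_that("expected edited cells scales by library size", {
  expect_equal(round(expected_edited_cells(1768, 9500, 500), 2), 93.05)
  expect_equal(expected_edited_cells(0, 9500, 500), 0)
  expect_equal(expected_edited_cells(9500, 9500, 500), 500)
  expect_error(expected_edited_cells(1, 0, 500), "total")
})
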