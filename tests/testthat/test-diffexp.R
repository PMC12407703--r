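test_that("testable edited genes need >30 edited cells and mean >0.2", {
  cells <- sprintf("c%03d", 1:120)
  dosage <- Matrix::Matrix(0, 120, 3,
                           dimnames = list(cells, c("g31", "g30", "glow")))
  dosage[1:31, "g31"] <- 1
  dosage[1:30, "g30"] <- 1
  dosage[1:31, "glow"] <- 1
  norm <- matrix(0.5, 3, 120, dimnames = list(c("g31", "g30", "glow"), cells))
  norm["glow", ] <- 0.1
  expect_equal(select_testable_edited_genes(dosage, norm), "g31")
})

test_that("pairing picks the nearest gene-compatible control", {
  states <- tibble::tibble(
    cell_barcode = c("e1", "k1", "k2"),
    umap1 = c(0, 0, 5), umap2 = c(0, 0, 5),
    genes_detected = c(5000L, 5000L, 5100L),
    total_umis = 1L, sample_label = c("edited", "control", "control")
  )
  p <- pair_control_cells(states, tibble::tibble(cell_barcode = "e1",
                                                 dosage = 1),
                          c("k1", "k2"), min_group = 0L)
  expect_equal(p$control_cell, "k1")
  expect_equal(p$allele_label, 1)
  # all controls too different in genes detected: unpaired
  states2 <- states
  states2$genes_detected[2:3] <- c(9000L, 9500L)
  p2 <- pair_control_cells(states2, tibble::tibble(cell_barcode = "e1",
                                                   dosage = 1),
                           c("k1", "k2"), min_group = 0L)
  expect_equal(nrow(p2), 0)
  expect_equal(attr(p2, "n_unpaired"), 1L)
})

test_that("sparse allele levels are dropped and twins are recovered", {
  set.seed(61)
  n <- 80
  ed <- tibble::tibble(
    cell_barcode = sprintf("e%03d", 1:n),
    dosage = rep(c(1, 1, 1, 2), length.out = n)
  )
  # each edited cell has a designed twin control at (almost) the same state
  x <- runif(n, -5, 5); y <- runif(n, -5, 5)
  gd <- sample(4000:8000, n)
  states <- tibble::tibble(
    cell_barcode = c(ed$cell_barcode, sprintf("k%03d", 1:n)),
    umap1 = c(x, x + 0.001), umap2 = c(y, y - 0.001),
    genes_detected = c(gd, gd + 5L),
    total_umis = 1L,
    sample_label = rep(c("edited", "control"), each = n)
  )
  p <- pair_control_cells(states, ed, sprintf("k%03d", 1:n), min_group = 10L)
  twin <- sub("^e", "k", p$edited_cell)
  expect_gte(mean(p$control_cell == twin), 0.95)
  # dosage-2 level has 20 <= min_group? 20 cells at level 2 vs min_group 10
  expect_setequal(unique(p$allele_label), c(1, 2))
  p2 <- pair_control_cells(states, ed, sprintf("k%03d", 1:n), min_group = 25L)
  expect_setequal(unique(p2$allele_label), 1)  # level 2 (20 pairs) dropped
})

test_that("the mixed model recovers a planted dosage effect", {
  set.seed(62)
  k <- 300
  a_e <- rep(c(1, 2), length.out = k)
  g <- rnorm(k, sd = 0.7)
  beta <- 0.5
  y <- c(beta * a_e + g + rnorm(k), g + rnorm(k))
  fit <- fit_allele_lmm(y, c(a_e, rep(0, k)),
                        rep(sprintf("g%03d", 1:k), 2))
  expect_true(is.na(fit$message))
  expect_lt(abs(fit$beta - beta), 3 * fit$se)
  expect_lt(fit$p, 0.001)
  # constant dosage: flagged, not fit
  fit0 <- fit_allele_lmm(rnorm(10), rep(1, 10), rep(1:5, 2))
  expect_true(is.na(fit0$beta))
  expect_match(fit0$message, "variation")
})

test_that("the allele-label fixed effect absorbs dosage-linked bias", {
  set.seed(63)
  k <- 200
  a_e <- rep(c(1, 2), length.out = k)
  g <- rnorm(k, sd = 0.5)
  # a group-level shift that follows the allele label (detection-rate bias)
  bias <- 0.8 * a_e
  y <- c(0 * a_e + g + bias + rnorm(k), g + bias + rnorm(k)) # beta = 0
  group <- rep(sprintf("g%03d", 1:k), 2)
  with_alpha <- fit_allele_lmm(y, c(a_e, rep(0, k)), group,
                               allele_label = c(a_e, a_e))
  expect_false(is.na(with_alpha$gamma))
  expect_lt(abs(with_alpha$beta), 3 * with_alpha$se)
})

test_that("DEG calling applies BH and the effect-size threshold", {
  fits <- tibble::tibble(
    gene = c("a", "b", "c"), beta = c(0.5, 0.1, -0.4),
    se = 0.1, wald = 1, p = c(0.001, 0.02, 0.9),
    gamma = NA_real_, n_groups = 10L, message = NA_character_
  )
  fits$p_adj <- p.adjust(fits$p, "BH")
  expect_equal(fits$p_adj, c(0.003, 0.03, 0.9))
  out <- call_degs(fits, alpha = 0.05, min_effect = 0.2)
  expect_equal(out$deg, c(TRUE, FALSE, FALSE))
  expect_equal(out$direction, c("up", NA, NA))
  # low effect size blocks a significant p
  out2 <- call_degs(tibble::tibble(gene = "x", beta = 0.1, se = 0.1,
                                   wald = 1, p = 0.001, p_adj = 0.005,
                                   gamma = NA_real_, n_groups = 5L,
                                   message = NA_character_))
  expect_false(out2$deg)
  expect_equal(deg_setdiff(out, out2), "a")
})

test_that("query-gene selection honours per-set overrides", {
  set.seed(64)
  n <- 50
  norm <- rbind(
    hv = pmax(0, rnorm(n, 1, 1.5)),      # variable, mid expression
    const = rep(0.5, n),                 # constant: never selected
    low = pmax(0, rnorm(n, 0.05, 0.25)), # below default min_mean
    high = rnorm(n, 8, 3)                # above max_mean
  )
  colnames(norm) <- sprintf("c%d", 1:n)
  sel <- select_test_genes(norm)
  expect_true("hv" %in% sel)
  expect_false(any(c("const", "low", "high") %in% sel))
  sel2 <- select_test_genes(norm, extra_sets = list(
    nurd = list(genes = c("low", "const"), min_mean = 0.03, min_disp = 0)))
  expect_true("low" %in% sel2)
  expect_false("const" %in% sel2)
})

test_that("Fisher enrichment reports CMLE odds ratios with CIs", {
  uni <- sprintf("g%02d", 1:20)
  # balanced table: no association
  out <- fisher_enrichment(uni[1:10], list(s = uni[c(1:5, 11:15)]), uni)
  expect_equal(out$a, 5); expect_equal(out$d, 5)
  expect_equal(out$odds_ratio, 1, tolerance = 1e-9)
  expect_equal(out$p, 1)
  # complete separation: infinite OR, finite lower bound
  out2 <- fisher_enrichment(uni[1:10], list(s = uni[1:10]), uni)
  expect_equal(out2$odds_ratio, Inf)
  expect_true(is.finite(out2$ci_low) && out2$ci_low > 0)
  expect_equal(fisher_enrichment(uni[1:10],
                                 list(s = uni[11:20]), uni)$odds_ratio, 0)
  expect_error(fisher_enrichment("a", list(s = "a"), character(0)), "universe")
  # agreement with fisher.test at its own precision
  set.seed(65)
  for (i in 1:10) {
    t <- matrix(rpois(4, 6) + 1, 2)
    ft <- stats::fisher.test(t, conf.int = TRUE)
    o <- cmle_odds_ratio(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
    expect_equal(o$or, unname(ft$estimate), tolerance = 1e-3)
    expect_equal(o$ci_low, ft$conf.int[1], tolerance = 1e-3)
    expect_equal(o$ci_high, ft$conf.int[2], tolerance = 1e-3)
  }
})
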