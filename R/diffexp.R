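#' Edited genes eligible for dosage testing
#'
#' An edited gene is testable when its edit is present in strictly more
#' than `min_cells` cells and its mean normalized expression exceeds
#' `min_mean`.
#'
#' @param dosage Cells x genes dosage matrix.
#' @param norm Genes x cells normalized expression matrix.
#' @param min_cells Minimum edited cells, strict (default 30).
#' @param min_mean Minimum mean expression, strict (default 0.2).
#' @return Character vector of gene ids.
#' @export
select_testable_edited_genes <- function(dosage, norm, min_cells = 30L,
                                         min_mean = 0.2) {
  edited_cells <- Matrix::colSums(dosage > 0)
  genes <- colnames(dosage)
  means <- Matrix::rowMeans(norm)
  m <- ifelse(genes %in% rownames(norm), means[genes], 0)
  genes[edited_cells > min_cells & m > min_mean]
}

#' Pair edited cells with matched unedited controls
#'
#' For each edited cell, controls are ranked by Manhattan distance over
#' the z-scored embedding coordinates and z-scored genes-detected; among
#' the `k_nn` nearest, the first (nearest-first) control whose
#' genes-detected differs by less than `max_gene_diff` is taken,
#' forming an allelic-pairing group that shares the edited cell's dosage
#' as its allele label. Dosage levels with no more than `min_group`
#' paired cells are dropped. Controls may be reused across groups; reuse
#' and unpaired counts are attached as attributes.
#'
#' @param states Tibble from [embed_cells()] covering both pools.
#' @param edited Tibble with `cell_barcode`, `dosage` (>= 1).
#' @param control_barcodes Character vector of control-pool cells.
#' @param k_nn Neighbourhood size (default 10).
#' @param max_gene_diff Genes-detected tolerance, strict (default 1000).
#' @param min_group Minimum paired cells per allele level, strict
#'   (default 25).
#' @return Tibble: `group_id`, `edited_cell`, `control_cell`,
#'   `allele_label`. Attributes `n_unpaired` and `control_reuse`.
#' @export
pair_control_cells <- function(states, edited, control_barcodes,
                               k_nn = 10L, max_gene_diff = 1000L,
                               min_group = 25L) {
  z <- function(v) {
    s <- sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  feat <- cbind(z(states$umap1), z(states$umap2), z(states$genes_detected))
  rownames(feat) <- states$cell_barcode
  gd <- setNames(states$genes_detected, states$cell_barcode)
  ctrl <- intersect(control_barcodes, states$cell_barcode)
  if (length(ctrl) == 0) stop("no control cells in states")
  cfeat <- feat[ctrl, , drop = FALSE]
  rows <- list()
  n_unpaired <- 0L
  for (i in seq_len(nrow(edited))) {
    cb <- edited$cell_barcode[i]
    if (!cb %in% rownames(feat)) { n_unpaired <- n_unpaired + 1L; next }
    d <- colSums(abs(t(cfeat) - feat[cb, ]))
    nn <- ctrl[order(d)][seq_len(min(k_nn, length(ctrl)))]
    ok <- nn[abs(gd[nn] - gd[cb]) < max_gene_diff]
    if (length(ok) == 0) { n_unpaired <- n_unpaired + 1L; next }
    rows[[length(rows) + 1]] <- tibble::tibble(
      edited_cell = cb, control_cell = ok[1],
      allele_label = edited$dosage[i]
    )
  }
  pairs <- dplyr::bind_rows(rows)
  if (nrow(pairs) > 0) {
    keep_lvls <- names(which(table(pairs$allele_label) > min_group))
    pairs <- pairs[pairs$allele_label %in% as.numeric(keep_lvls), ,
                   drop = FALSE]
    pairs$group_id <- sprintf("g%04d", seq_len(nrow(pairs)))
    pairs <- pairs[, c("group_id", "edited_cell", "control_cell",
                       "allele_label")]
  } else {
    pairs <- tibble::tibble(group_id = character(0),
                            edited_cell = character(0),
                            control_cell = character(0),
                            allele_label = numeric(0))
  }
  attr(pairs, "n_unpaired") <- n_unpaired
  attr(pairs, "control_reuse") <- table(pairs$control_cell)
  pairs
}

#' Fit the allele-dosage linear mixed model for one gene
#'
#' Fits `y ~ beta * a + (1 | group)` by REML, where `a` is the edit
#' allele count (0 for controls) and the random intercept absorbs the
#' shared state of each allelic pairing. When `allele_label` is supplied
#' (recommended when more than one positive dosage level is modeled) the
#' group's shared allele label enters as an additional fixed effect
#' `gamma`, adjusting for dosage-correlated detection-rate bias. The
#' p-value is a two-sided Wald test on `beta` against the normal
#' reference.
#'
#' @param y Response (residual expression) per cell.
#' @param a Edit allele count per cell (0 for controls).
#' @param group Group factor (one level per allelic pairing).
#' @param allele_label Optional numeric shared allele label per cell.
#' @return List: `beta`, `se`, `wald`, `p`, `gamma`, `n_groups`,
#'   `message` (`NA` on success).
#' @export
fit_allele_lmm <- function(y, a, group, allele_label = NULL) {
  if (length(unique(a)) < 2) {
    return(list(beta = NA_real_, se = NA_real_, wald = NA_real_,
                p = NA_real_, gamma = NA_real_,
                n_groups = length(unique(group)),
                message = "no dosage variation"))
  }
  df <- data.frame(y = y, a = a, group = factor(group))
  form <- y ~ a + (1 | group)
  if (!is.null(allele_label) && length(unique(allele_label)) > 1) {
    df$alpha <- allele_label
    form <- y ~ a + alpha + (1 | group)
  }
  fit <- tryCatch(
    suppressMessages(lme4::lmer(form, data = df, REML = TRUE)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(list(beta = NA_real_, se = NA_real_, wald = NA_real_,
                p = NA_real_, gamma = NA_real_,
                n_groups = length(unique(group)),
                message = conditionMessage(fit)))
  }
  co <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  w <- co[["a"]] / se[["a"]]
  list(beta = unname(co[["a"]]), se = unname(se[["a"]]),
       wald = unname(w), p = 2 * pnorm(-abs(w)),
       gamma = if ("alpha" %in% names(co)) unname(co[["alpha"]]) else NA_real_,
       n_groups = length(unique(group)), message = NA_character_)
}

#' Dosage differential expression across genes
#'
#' Builds the paired long data (each group contributes its edited cell
#' with `a = dosage` and its control with `a = 0`, both carrying the
#' group's allele label) and fits the mixed model per query gene. The
#' allele-label fixed effect is included when more than one positive
#' dosage level is present.
#'
#' @param resid Genes x cells residual matrix (from
#'   [pearson_residuals()]).
#' @param pairs Tibble from [pair_control_cells()].
#' @param test_genes Genes (rows of `resid`) to test.
#' @return Tibble: `gene`, `beta`, `se`, `wald`, `p`, `p_adj` (BH across
#'   tested genes), `gamma`, `n_groups`.
#' @export
fit_allele_de <- function(resid, pairs, test_genes) {
  if (nrow(pairs) == 0) stop("no paired groups")
  cells <- c(pairs$edited_cell, pairs$control_cell)
  a <- c(pairs$allele_label, rep(0, nrow(pairs)))
  alpha <- c(pairs$allele_label, pairs$allele_label)
  group <- factor(c(pairs$group_id, pairs$group_id))
  use_alpha <- length(unique(pairs$allele_label)) > 1
  test_genes <- intersect(test_genes, rownames(resid))
  keep <- cells %in% colnames(resid)
  cells <- cells[keep]; a <- a[keep]; alpha <- alpha[keep]
  group <- droplevels(group[keep])
  rows <- lapply(test_genes, function(g) {
    y <- resid[g, cells]
    f <- fit_allele_lmm(y, a, group,
                        allele_label = if (use_alpha) alpha else NULL)
    tibble::tibble(gene = g, beta = f$beta, se = f$se, wald = f$wald,
                   p = f$p, gamma = f$gamma, n_groups = f$n_groups,
                   message = f$message)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out[, c("gene", "beta", "se", "wald", "p", "p_adj", "gamma", "n_groups",
          "message")]
}

#' Call differentially expressed genes
#'
#' DEG iff BH-adjusted p-value is below `alpha` and the absolute dosage
#' effect exceeds `min_effect`; the sign of the effect is recorded as the
#' direction.
#'
#' @param fits Tibble from [fit_allele_de()].
#' @param alpha Adjusted-p threshold (default 0.01).
#' @param min_effect Absolute effect threshold (default 0.2).
#' @return `fits` with `deg` (logical) and `direction` (`"up"`, `"down"`,
#'   `NA`).
#' @export
call_degs <- function(fits, alpha = 0.01, min_effect = 0.2) {
  deg <- !is.na(fits$p_adj) & fits$p_adj < alpha &
    abs(fits$beta) > min_effect
  fits$deg <- deg
  fits$direction <- ifelse(deg, ifelse(fits$beta > 0, "up", "down"),
                           NA_character_)
  fits
}

#' DEGs specific to one analysis
#'
#' Set difference on DEG tables: DEGs of `fits_a` absent from the DEG set
#' of `fits_b`.
#'
#' @param fits_a,fits_b Tibbles from [call_degs()].
#' @return Character vector of gene ids.
#' @export
deg_setdiff <- function(fits_a, fits_b) {
  setdiff(fits_a$gene[fits_a$deg], fits_b$gene[fits_b$deg])
}

#' Select query genes for differential testing
#'
#' Highly variable genes by mean/dispersion thresholds on the normalized
#' matrix (dispersion = variance / mean), unioned with supplied target
#' gene sets filtered by their own per-set thresholds.
#'
#' @param norm Genes x cells normalized matrix.
#' @param min_mean,min_disp,max_mean HVG thresholds (defaults 0.2, 0.6,
#'   5).
#' @param extra_sets Optional named list; each element a list with
#'   `genes` plus optional `min_mean`, `min_disp` overrides.
#' @return Character vector of gene ids.
#' @export
select_test_genes <- function(norm, min_mean = 0.2, min_disp = 0.6,
                              max_mean = 5, extra_sets = NULL) {
  x <- as.matrix(norm)
  gm <- rowMeans(x)
  gv <- apply(x, 1, var)
  disp <- ifelse(gm > 0, gv / gm, 0)
  hvg <- rownames(x)[gm > min_mean & gm < max_mean & disp > min_disp]
  extra <- character(0)
  for (s in extra_sets %||% list()) {
    g <- intersect(s$genes, rownames(x))
    mm <- s$min_mean %||% min_mean
    md <- s$min_disp %||% min_disp
    extra <- c(extra, g[gm[g] > mm & disp[g] > md])
  }
  unique(c(hvg, extra))
}

#' Conditional-MLE odds ratio for a 2x2 table
#'
#' Maximizes the conditional (noncentral hypergeometric) likelihood of the
#' first cell given all margins, with a two-sided confidence interval from
#' the corresponding tail probabilities. Equivalent to the estimate
#' reported by [stats::fisher.test()] but solved to much tighter numerical
#' tolerance. Degenerate tables follow the usual conventions: an observed
#' count at the support minimum gives OR 0, at the maximum gives `Inf`.
#'
#' @param a,b,c,d Table counts (`a` = in-DEG and in-set).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `or`, `ci_low`, `ci_high`.
#' @export
cmle_odds_ratio <- function(a, b, c, d, conf_level = 0.95) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  support <- lo:hi
  logdc <- stats::dhyper(support, m, n, k, log = TRUE)
  dnch <- function(lpsi) {
    lw <- logdc + support * lpsi
    w <- exp(lw - max(lw))
    w / sum(w)
  }
  alpha <- (1 - conf_level) / 2
  or <- if (a == lo) 0 else if (a == hi) Inf else
    exp(stats::uniroot(function(lp) sum(support * dnch(lp)) - a,
                       c(-45, 45), tol = 1e-12)$root)
  ci_low <- if (a == lo) 0 else
    exp(stats::uniroot(function(lp) sum(dnch(lp)[support >= a]) - alpha,
                       c(-60, 60), tol = 1e-12)$root)
  ci_high <- if (a == hi) Inf else
    exp(stats::uniroot(function(lp) sum(dnch(lp)[support <= a]) - alpha,
                       c(-60, 60), tol = 1e-12)$root)
  list(or = or, ci_low = ci_low, ci_high = ci_high)
}

#' Gene-set enrichment of a DEG set by Fisher's exact test
#'
#' For each gene set, a 2x2 table of DEG membership against set
#' membership over the universe is tested with a two-sided Fisher exact
#' test; the odds ratio is the conditional maximum likelihood estimate
#' (see [cmle_odds_ratio()]) with a two-sided 95% confidence interval,
#' and p-values are BH-adjusted across the batch of sets.
#'
#' @param deg_genes Character vector of DEG gene ids.
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector (all genes tested in the
#'   corresponding DE analysis).
#' @param alpha Significance level on adjusted p (default 0.05).
#' @return Tibble: `gene_set`, `a`, `b`, `c`, `d` (table counts),
#'   `odds_ratio`, `ci_low`, `ci_high`, `p`, `p_adj`, `significant`.
#' @export
fisher_enrichment <- function(deg_genes, gene_sets, universe, alpha = 0.05) {
  if (length(universe) == 0) stop("empty universe")
  deg <- intersect(deg_genes, universe)
  rows <- lapply(names(gene_sets), function(nm) {
    gs <- intersect(gene_sets[[nm]], universe)
    a <- length(intersect(deg, gs))
    b <- length(setdiff(deg, gs))
    cc <- length(setdiff(gs, deg))
    d <- length(universe) - a - b - cc
    ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                             conf.int = FALSE)
    orr <- cmle_odds_ratio(a, b, cc, d)
    tibble::tibble(gene_set = nm, a = a, b = b, c = cc, d = d,
                   odds_ratio = orr$or,
                   ci_low = orr$ci_low, ci_high = orr$ci_high,
                   p = ft$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out
}
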