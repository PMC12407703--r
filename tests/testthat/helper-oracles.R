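# Independent reference implementations used as oracles. These share no
# code with the package paths they check.

# ---- greedy clustering: direct transcription of the iterative procedure,
# recomputing the ordering at every iteration ----
oracle_cluster <- function(ps, radius = 140L) {
  remaining <- ps
  out <- NULL
  while (nrow(remaining) > 0) {
    o <- order(-remaining$n_cells, remaining$chrom, remaining$breakpoint,
               remaining$orientation, remaining$clip_seq)
    f <- remaining[o[1], , drop = FALSE]
    sel <- remaining$chrom == f$chrom &
      abs(remaining$breakpoint - f$breakpoint) <= radius
    chunk <- remaining[sel, , drop = FALSE]
    chunk$site_id <- sprintf("site_%s_%d", f$chrom, f$breakpoint)
    chunk$position <- f$breakpoint
    out <- rbind(out, chunk)
    remaining <- remaining[!sel, , drop = FALSE]
  }
  out
}

random_particular_sites <- function(n_max = 30L, pos_max = 2000L) {
  n <- sample(1:n_max, 1)
  tibble::tibble(
    chrom = sample(c("cA", "cB"), n, replace = TRUE),
    breakpoint = sample(0:pos_max, n, replace = TRUE),
    orientation = sample(c("forward", "reverse"), n, replace = TRUE),
    clip_seq = replicate(n, paste(sample(c("A", "C", "G", "T"), 8,
                                         replace = TRUE), collapse = "")),
    n_cells = sample(1:20, n, replace = TRUE)
  ) |> dplyr::distinct(chrom, breakpoint, orientation, clip_seq,
                       .keep_all = TRUE)
}

# Expand particular sites into one single-cell particular edit per
# supporting cell, so the package path (which aggregates per cell) sees
# exactly these cell counts.
sites_to_particulars <- function(ps) {
  idx <- rep(seq_len(nrow(ps)), ps$n_cells)
  cell <- unlist(lapply(ps$n_cells, function(k) sprintf("c%03d", seq_len(k))))
  tibble::tibble(
    cell_barcode = cell,
    chrom = ps$chrom[idx], breakpoint = ps$breakpoint[idx],
    orientation = ps$orientation[idx], clip_seq = ps$clip_seq[idx],
    umis = as.list(sprintf("U%05d", seq_along(idx))),
    n_umis = 1L, n_reads = 1L
  )
}

# ---- hand-coded affine-gap Smith-Waterman (Gotoh), independent of
# Biostrings; gap of length L costs go + ge * (L - 1) ----
sw_align <- function(a, b, go = 0.5, ge = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(-Inf, n + 1, m + 1); M[1, ] <- 0; M[, 1] <- 0
  Ix <- matrix(-Inf, n + 1, m + 1); Iy <- matrix(-Inf, n + 1, m + 1)
  pM <- matrix(0L, n + 1, m + 1); pX <- matrix(0L, n + 1, m + 1)
  pY <- matrix(0L, n + 1, m + 1)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cx <- c(M[i, j + 1] - go, Ix[i, j + 1] - ge)
      Ix[i + 1, j + 1] <- max(cx); pX[i + 1, j + 1] <- which.max(cx)
      cy <- c(M[i + 1, j] - go, Iy[i + 1, j] - ge)
      Iy[i + 1, j + 1] <- max(cy); pY[i + 1, j + 1] <- which.max(cy)
      s <- if (A[i] == B[j]) 1 else -1
      cand <- c(0, M[i, j], Ix[i, j], Iy[i, j])
      w <- which.max(cand)
      M[i + 1, j + 1] <- cand[w] + s
      pM[i + 1, j + 1] <- w - 1L
      if (M[i + 1, j + 1] > best) {
        best <- M[i + 1, j + 1]; bi <- i + 1L; bj <- j + 1L
      }
    }
  }
  if (best <= 0) return(list(pattern = "", subject = "", score = 0))
  pa <- character(0); sb <- character(0)
  state <- "M"; i <- bi; j <- bj
  repeat {
    if (state == "M") {
      pa <- c(A[i - 1], pa); sb <- c(B[j - 1], sb)
      w <- pM[i, j]; i <- i - 1L; j <- j - 1L
      if (w == 0) break
      state <- c("M", "Ix", "Iy")[w]
    } else if (state == "Ix") {
      pa <- c(A[i - 1], pa); sb <- c("-", sb)
      w <- pX[i, j]; i <- i - 1L
      state <- c("M", "Ix")[w]
    } else {
      pa <- c("-", pa); sb <- c(B[j - 1], sb)
      w <- pY[i, j]; j <- j - 1L
      state <- c("M", "Iy")[w]
    }
  }
  list(pattern = paste(pa, collapse = ""), subject = paste(sb, collapse = ""),
       score = best)
}

# ---- literal transcription of the three-stage clip comparison ----
oracle_stage1 <- function(a, b) {
  al <- sw_align(a, b, 0.5, 0.5)
  p <- strsplit(al$pattern, "")[[1]]; s <- strsplit(al$subject, "")[[1]]
  short_is_subject <- nchar(b) <= nchar(a)
  if (length(p) == 0 || al$score <= 0) return(max(nchar(a), nchar(b)))
  mism <- sum(p != s)
  seen <- if (short_is_subject) sum(s != "-") else sum(p != "-")
  mism + (min(nchar(a), nchar(b)) - seen)
}

oracle_clip_distance <- function(a, b) {
  # canonical order: longer first, ties lexicographic
  if (nchar(b) > nchar(a) || (nchar(b) == nchar(a) && b < a)) {
    tmp <- a; a <- b; b <- tmp
  }
  d <- oracle_stage1(a, b)
  if (d >= 2) {
    ah <- gsub("(.)\\1{2,}", "\\1", a)
    bh <- gsub("(.)\\1{2,}", "\\1", b)
    d <- oracle_stage1(ah, bh)
    if (d > 2) {
      al <- sw_align(a, b, 0.5, 0.5)
      p <- strsplit(al$pattern, "")[[1]]; s <- strsplit(al$subject, "")[[1]]
      if (length(p) == 0) {
        d <- 10L
      } else {
        idx <- seq.int(max(1L, length(p) - 9L), length(p))
        d <- sum(p[idx] != s[idx])
      }
    }
  }
  as.integer(d)
}

# ---- UMI components via pairwise Hamming + igraph ----
oracle_umi_components <- function(umis) {
  umis <- unique(umis)
  n <- length(umis)
  if (n <= 1) return(n)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      x <- utf8ToInt(umis[i]); y <- utf8ToInt(umis[j])
      L <- min(length(x), length(y))
      d <- sum(x[seq_len(L)] != y[seq_len(L)]) + abs(length(x) - length(y))
      if (d <= 1) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::count_components(g)
}

# ---- conditional-MLE odds ratio, CI and two-sided Fisher p from the
# noncentral hypergeometric distribution, via direct enumeration ----
oracle_fisher <- function(a, b, cc, d) {
  m <- a + b; n <- cc + d; k <- a + cc
  lo <- max(0L, k - n); hi <- min(k, m)
  support <- lo:hi
  logdc <- lchoose(m, support) + lchoose(n, k - support)
  dnch <- function(psi) {
    w <- exp(logdc + support * log(psi) - max(logdc + support * log(psi)))
    w / sum(w)
  }
  mean_nch <- function(psi) sum(support * dnch(psi))
  # two-sided p at psi = 1
  p0 <- dnch(1)
  pval <- sum(p0[p0 <= p0[support == a] * (1 + 1e-7)])
  # CMLE
  if (a == lo) or <- 0
  else if (a == hi) or <- Inf
  else {
    or <- exp(stats::uniroot(function(lp) mean_nch(exp(lp)) - a,
                             c(-40, 40), tol = 1e-12)$root)
  }
  # 95% CI: psi_L solves P(X >= a) = .025, psi_U solves P(X <= a) = .025
  p_ge <- function(psi) sum(dnch(psi)[support >= a])
  p_le <- function(psi) sum(dnch(psi)[support <= a])
  ci_lo <- if (a == lo) 0 else
    exp(stats::uniroot(function(lp) p_ge(exp(lp)) - 0.025,
                       c(-60, 60), tol = 1e-12)$root)
  ci_hi <- if (a == hi) Inf else
    exp(stats::uniroot(function(lp) p_le(exp(lp)) - 0.025,
                       c(-60, 60), tol = 1e-12)$root)
  list(p = min(1, pval), or = or, ci_low = ci_lo, ci_high = ci_hi)
}

# ---- shared end-to-end simulation run, computed once per session ----
e2e_cache <- new.env(parent = emptyenv())
e2e_run <- function() {
  if (!is.null(e2e_cache$res)) return(e2e_cache$res)
  cfg <- sim_config(seed = 1)
  gen <- simulate_genome(cfg)
  sim <- simulate_experiment(cfg, gen)
  sam <- tempfile(fileext = ".sam")
  write_sam(sim$reads, gen$seqlengths, sam)
  spec <- barcode_spec(tso_variants = cfg$tso_ref)
  ot <- match(gen$guides$on_target_site, gen$sites$site_name)
  guides <- tibble::tibble(
    name = gen$guides$name, protospacer = gen$guides$protospacer,
    on_target_chrom = gen$sites$chrom[ot],
    on_target_position = gen$sites$cut[ot]
  )
  res <- run_edit_calling(sam, gen$genome, gen$genes, spec, guides = guides)
  e2e_cache$res <- list(cfg = cfg, gen = gen, sim = sim, res = res)
  e2e_cache$res
}
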