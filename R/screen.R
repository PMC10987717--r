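# Single-cell expression screen ------------------------------------------------
#
# The bespoke numeric rules applied on top of upstream tooling output:
# QC metrics and filters, fixed-size downsampling, cluster-aggregate log2
# sample ratios, fold-change gene selection, enrichment-score cutoff
# assignment, and a binomial overrepresentation test with Bonferroni
# correction. Clustering itself is an input (labels supplied).

#' Per-cell QC metrics
#'
#' `nFeature` = number of genes with count > 0, `nCount` = total counts,
#' `pct_mito` = 100 * mitochondrial counts / nCount (0 when nCount is 0).
#'
#' @param m A [count_matrix()].
#' @return Tibble: `cell`, `nFeature`, `nCount`, `pct_mito`, in input cell
#'   order.
#' @export
compute_cell_qc <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  x <- m$counts
  n_count <- Matrix::colSums(x)
  n_feat <- Matrix::colSums(x > 0)
  mito_counts <- if (length(m$mito_genes))
    Matrix::colSums(x[m$mito_genes, , drop = FALSE]) else 0
  tibble(
    cell = colnames(x),
    nFeature = as.integer(n_feat),
    nCount = as.integer(n_count),
    pct_mito = unname(ifelse(n_count > 0, 100 * mito_counts / n_count, 0))
  )
}

#' QC filter for cells
#'
#' A cell is removed iff `nFeature > max_nFeature` or `nFeature <
#' min_nFeature` or `nCount > max_nCount` or `pct_mito > max_pct_mito` — all
#' inequalities strict, so boundary cells (e.g. nFeature exactly 200) are
#' kept. Defaults are the screen's standard cutoffs (8000 / 200 / 50000 /
#' 20%).
#'
#' @param qc Tibble from [compute_cell_qc()].
#' @param max_nFeature,min_nFeature,max_nCount,max_pct_mito Cutoffs.
#' @return Character vector of surviving cell ids, preserving input order.
#' @export
qc_filter <- function(qc, max_nFeature = 8000, min_nFeature = 200,
                      max_nCount = 50000, max_pct_mito = 20) {
  stopifnot(all(c("cell", "nFeature", "nCount", "pct_mito") %in% names(qc)))
  if (any(c(max_nFeature, min_nFeature, max_nCount, max_pct_mito) <= 0))
    oq_abort("QC thresholds must be positive.", "parameter")
  removed <- qc$nFeature > max_nFeature | qc$nFeature < min_nFeature |
    qc$nCount > max_nCount | qc$pct_mito > max_pct_mito
  qc$cell[!removed]
}

#' Downsample a count matrix to a fixed number of cells
#'
#' Uniform sampling without replacement (the fixed-size subset used to make
#' samples comparable; default 6400 cells), seeded for reproducibility. The
#' gene axis is untouched.
#'
#' @param m A [count_matrix()].
#' @param n Target number of cells (default 6400).
#' @param seed Integer seed.
#' @param allow_smaller If the matrix has fewer than `n` cells, keep all with
#'   a warning instead of erroring.
#' @return A [count_matrix()] with `n` cells (original order preserved).
#' @export
downsample_cells <- function(m, n = 6400, seed = 1L, allow_smaller = FALSE) {
  stopifnot(inherits(m, "count_matrix"))
  if (n <= 0) oq_abort("`n` must be positive.", "parameter")
  total <- ncol(m$counts)
  if (total < n) {
    if (!allow_smaller)
      oq_abort(sprintf("matrix has %d cells, fewer than n = %d.", total, n),
               "parameter")
    warn(sprintf("keeping all %d cells (< n = %d).", total, n))
    return(m)
  }
  keep <- withr::with_seed(seed, sort(sample.int(total, n)))
  count_matrix(m$counts[, keep, drop = FALSE], m$sample,
               if (!is.null(m$clusters)) m$clusters[keep], m$mito_genes)
}

# library-size-normalized (counts per 10k) per-cluster gene means
cluster_means <- function(m, mode) {
  x <- m$counts
  tot <- Matrix::colSums(x)
  tot[tot == 0] <- 1
  xn <- x %*% Matrix::Diagonal(x = 1e4 / tot)
  cl <- if (mode == "pseudobulk" || is.null(m$clusters))
    rep("all", ncol(x)) else m$clusters
  groups <- sort(unique(cl))
  mm <- vapply(groups,
               function(g) Matrix::rowMeans(xn[, cl == g, drop = FALSE]),
               numeric(nrow(x)))
  matrix(mm, nrow = nrow(x), dimnames = list(rownames(x), groups))
}

#' Cluster-aggregate log2 sample ratios
#'
#' For every (gene, cluster): library-size-normalize each cell to 10,000
#' counts, average within the cluster per sample, and report
#' `log2((mean_A + pseudocount) / (mean_B + pseudocount))`. Clusters present
#' in only one sample are emitted with `shared = FALSE` and a missing ratio.
#' `mode = "pseudobulk"` pools all cells into a single pseudo-cluster.
#'
#' @param a,b [count_matrix()] objects sharing gene ids, with cluster labels
#'   from a common clustering.
#' @param pseudocount Ratio-stabilizing pseudocount (default 0.01, recorded
#'   in the output attribute `parameters`).
#' @param mode `"per_cluster"` (default) or `"pseudobulk"`.
#' @return Tibble: `gene`, `cluster`, `mean_a`, `mean_b`, `log2_ratio`,
#'   `shared`.
#' @export
cluster_aggregate_log2ratio <- function(a, b, pseudocount = 0.01,
                                        mode = c("per_cluster", "pseudobulk")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "count_matrix"), inherits(b, "count_matrix"))
  if (!identical(rownames(a$counts), rownames(b$counts)))
    oq_abort("samples must share the same gene ids in the same order.",
             "parameter")
  if (pseudocount < 0) oq_abort("`pseudocount` must be >= 0.", "parameter")
  ma <- cluster_means(a, mode)
  mb <- cluster_means(b, mode)
  cls <- sort(union(colnames(ma), colnames(mb)))
  out <- purrr::map_dfr(cls, function(cl) {
    shared <- cl %in% colnames(ma) && cl %in% colnames(mb)
    va <- if (cl %in% colnames(ma)) ma[, cl] else rep(NA_real_, nrow(ma))
    vb <- if (cl %in% colnames(mb)) mb[, cl] else rep(NA_real_, nrow(mb))
    tibble(
      gene = rownames(a$counts), cluster = cl,
      mean_a = unname(va), mean_b = unname(vb),
      log2_ratio = if (shared)
        unname(log2((va + pseudocount) / (vb + pseudocount))) else NA_real_,
      shared = shared
    )
  })
  attr(out, "parameters") <- list(normalization = "counts per 10k, arithmetic
 cluster mean", pseudocount = pseudocount, mode = mode)
  out
}

#' Select differential genes by absolute log2 ratio
#'
#' Keeps genes with `log2_ratio > threshold` or `< -threshold` (strict), per
#' cluster, in deterministic gene-id order.
#'
#' @param ratios Tibble from [cluster_aggregate_log2ratio()].
#' @param threshold Positive fold-change cutoff on the log2 scale (default 1).
#' @return Tibble: `cluster`, `gene`, `log2_ratio`, `direction`
#'   (`"up"`/`"down"`), ordered by cluster then gene id.
#' @export
select_de_genes <- function(ratios, threshold = 1) {
  if (threshold <= 0) oq_abort("`threshold` must be > 0.", "parameter")
  ratios |>
    dplyr::filter(!is.na(.data$log2_ratio),
                  abs(.data$log2_ratio) > threshold) |>
    dplyr::mutate(direction = ifelse(.data$log2_ratio > 0, "up", "down")) |>
    dplyr::select("cluster", "gene", "log2_ratio", "direction") |>
    dplyr::arrange(.data$cluster, .data$gene)
}

#' Assign cell types from an enrichment table by score cutoff
#'
#' Keeps per-cluster rows with `nes >= cutoff` (default 7.5; the boundary
#' score is kept) and assigns each cluster the arg-max surviving set.
#' Clusters with no surviving row are `"unassigned"`. Ties at the maximum go
#' to the lexicographically first set id and are flagged.
#'
#' @param enrichment Tibble with columns `cluster`, `set`, `nes` (one score
#'   per cluster x set; enrichment scores are consumed, not computed, here).
#' @param cutoff Significance cutoff on the normalized enrichment score.
#' @return Tibble: `cluster`, `assignment`, `nes`, `tie`.
#' @export
filter_enrichment <- function(enrichment, cutoff = 7.5) {
  stopifnot(all(c("cluster", "set", "nes") %in% names(enrichment)))
  enrichment |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_modify(function(d, key) {
      kept <- d[d$nes >= cutoff, , drop = FALSE]
      if (!nrow(kept))
        return(tibble(assignment = "unassigned", nes = NA_real_, tie = FALSE))
      top <- kept[kept$nes == max(kept$nes), , drop = FALSE]
      tibble(assignment = sort(top$set)[1], nes = max(kept$nes),
             tie = nrow(top) > 1)
    }) |>
    dplyr::ungroup()
}

#' Binomial overrepresentation test with Bonferroni correction
#'
#' For each gene set: background probability `p0 = |set n background| /
#' |background|`, overlap `k = |query n set|`, raw
#' `p = P(X >= k), X ~ Binomial(|query|, p0)`, and Bonferroni adjustment over
#' the number of sets tested.
#'
#' @param query Character vector of query gene ids (must be a subset of
#'   `background`).
#' @param background Character vector of background gene ids.
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]); each
#'   set is intersected with the background before testing.
#' @return Tibble: `set`, `k`, `n`, `p0`, `p_raw`, `p_adj`.
#' @export
overrepresentation_test <- function(query, background, sets) {
  background <- unique(background)
  query <- unique(query)
  if (!length(background)) oq_abort("background is empty.", "parameter")
  if (!all(query %in% background))
    oq_abort("query genes must be a subset of the background.", "parameter")
  if (!is.list(sets) || is.null(names(sets)))
    oq_abort("`sets` must be a named list.", "parameter")
  m <- length(sets)
  n <- length(query)
  purrr::imap_dfr(sets, function(s, id) {
    s <- intersect(unique(s), background)
    p0 <- length(s) / length(background)
    k <- length(intersect(query, s))
    p_raw <- if (n == 0 || k == 0) 1 else pbinom(k - 1, n, p0, lower.tail = FALSE)
    tibble(set = id, k = k, n = n, p0 = p0, p_raw = p_raw,
           p_adj = min(1, m * p_raw))
  })
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' member genes.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) oq_abort("malformed GMT line(s): need name, description, genes.",
                         "parameter")
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[[`, "", 1))
}
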