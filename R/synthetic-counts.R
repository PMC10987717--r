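# Synthetic single-cell count experiments --------------------------------------

#' Generate a paired-sample synthetic count experiment
#'
#' Draws a genes x cells count matrix for two samples ("A", "B") from a
#' negative-binomial model per gene x cluster (dispersion configurable,
#' default 0.1). Sample A's cluster means are scaled by `2^log2fc` for the
#' planted differential genes. A chosen fraction of genes is mitochondrial
#' (ids `MT-...`). Named cells can be planted to violate each QC rule relative
#' to the supplied thresholds; all other cells are kept comfortably inside
#' them.
#'
#' Gene base means are log-normal (meanlog `log(1)`, sdlog 1), giving per-cell
#' totals around 1.6 counts per gene on average — realistic for a moderately
#' expressed feature panel; per-cluster log-normal wobble (sd 0.3
#' on the log scale, shared between samples) makes clusters distinct without
#' introducing sample differences beyond the planted ones.
#'
#' @param n_genes Number of genes (planting an `nFeature_high` violator
#'   requires `n_genes > max_nFeature`).
#' @param n_cells_per_sample Cells per sample (split equally over clusters).
#' @param n_clusters Number of clusters (>= 1); every cluster gets >= 2 cells.
#' @param planted Tibble `gene`, `cluster`, `log2fc` of planted effects, or
#'   `NULL` for none. Gene ids must exist; by convention planted genes should
#'   be moderately expressed (the default base-mean draw guarantees a pool
#'   with mean >= 0.5 to plant into when `plant_n_up`/`plant_n_down` is used).
#' @param plant_n_up,plant_n_down,plant_log2fc Convenience alternative to
#'   `planted`: plant this many up/down genes at `+/- plant_log2fc` in every
#'   cluster, drawn from genes with base mean >= 0.5.
#' @param mito_fraction Fraction of genes that are mitochondrial.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param qc_violations Named list of cell counts to plant per violation type:
#'   `nFeature_high`, `nFeature_low`, `nCount_high`, `pct_mito_high`.
#' @param qc_thresholds QC cutoffs the violations are planted against
#'   (defaults: remove if nFeature > 8000 or < 200, nCount > 50000,
#'   pct_mito > 20).
#' @param seed Integer seed.
#' @return List with `sample_a`, `sample_b` ([count_matrix()]) and `truth`
#'   (`planted` fc table, `qc_violators` cell ids, seed).
#' @export
make_count_experiment <- function(n_genes = 1000, n_cells_per_sample = 1500,
                                  n_clusters = 3, planted = NULL,
                                  plant_n_up = 0, plant_n_down = 0,
                                  plant_log2fc = 2,
                                  mito_fraction = 0.02, dispersion = 0.1,
                                  qc_violations = list(),
                                  qc_thresholds = list(max_nFeature = 8000,
                                                       min_nFeature = 200,
                                                       max_nCount = 50000,
                                                       max_pct_mito = 20),
                                  seed = 1L) {
  if (n_cells_per_sample / n_clusters < 2)
    oq_abort("cluster sizes must be >= 2 cells.", "parameter")
  n_mito <- round(mito_fraction * n_genes)
  genes <- c(sprintf("MT-g%04d", seq_len(n_mito)),
             sprintf("g%04d", seq_len(n_genes - n_mito)))
  mito <- genes[seq_len(n_mito)]
  clusters <- rep_len(as.character(seq_len(n_clusters)), n_cells_per_sample)

  withr::with_seed(seed, {
    base_mean <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
    names(base_mean) <- genes
    # per-cluster wobble shared by the two samples
    clfac <- matrix(stats::rlnorm(n_genes * n_clusters, 0, 0.3),
                    n_genes, n_clusters, dimnames = list(genes, NULL))
    if (is.null(planted) && (plant_n_up > 0 || plant_n_down > 0)) {
      pool <- genes[base_mean >= 0.5]
      pick <- sample(pool, plant_n_up + plant_n_down)
      planted <- tidyr::expand_grid(
        tibble(gene = pick,
               log2fc = rep(c(plant_log2fc, -plant_log2fc),
                            c(plant_n_up, plant_n_down))),
        cluster = as.character(seq_len(n_clusters)))[, c("gene", "cluster", "log2fc")]
    }
    if (is.null(planted))
      planted <- tibble(gene = character(), cluster = character(),
                        log2fc = numeric())
    if (!all(planted$gene %in% genes))
      oq_abort("planted gene id(s) not in the gene universe.", "parameter")

    draw_sample <- function(label) {
      m <- matrix(0L, n_genes, n_cells_per_sample,
                  dimnames = list(genes, sprintf("%s_c%05d", label,
                                                 seq_len(n_cells_per_sample))))
      for (cl in seq_len(n_clusters)) {
        cells <- which(clusters == as.character(cl))
        mu <- base_mean * clfac[, cl]
        if (label == "A" && nrow(planted)) {
          rows <- planted$cluster == as.character(cl)
          if (any(rows)) {
            idx <- match(planted$gene[rows], genes)
            mu[idx] <- mu[idx] * 2^planted$log2fc[rows]
          }
        }
        m[, cells] <- rnbinom(n_genes * length(cells), size = 1 / dispersion,
                              mu = mu)
      }
      m
    }
    ma <- draw_sample("A")
    mb <- draw_sample("B")

    # plant QC violations into sample A's trailing cells
    violators <- character()
    thr <- qc_thresholds
    plant_types <- c("nFeature_high", "nFeature_low", "nCount_high",
                     "pct_mito_high")
    next_cell <- n_cells_per_sample
    for (type in intersect(plant_types, names(qc_violations))) {
      for (i in seq_len(qc_violations[[type]])) {
        cid <- colnames(ma)[next_cell]
        v <- ma[, next_cell]
        if (type == "nFeature_high") {
          if (n_genes <= thr$max_nFeature)
            oq_abort("cannot plant nFeature_high: n_genes <= max_nFeature.",
                     "parameter")
          v[] <- 0L; v[seq_len(thr$max_nFeature + 200)] <- 1L
        } else if (type == "nFeature_low") {
          keep <- sample(n_genes, max(1, thr$min_nFeature - 50))
          v[] <- 0L; v[keep] <- 1L
        } else if (type == "nCount_high") {
          v[which.max(v)] <- v[which.max(v)] + as.integer(thr$max_nCount + 5000)
        } else { # pct_mito_high
          need <- ceiling((thr$max_pct_mito / 100 * 1.8) * sum(v))
          if (!length(mito))
            oq_abort("cannot plant pct_mito_high without mitochondrial genes.",
                     "parameter")
          v[mito[1]] <- v[mito[1]] + as.integer(need)
        }
        ma[, next_cell] <- v
        violators <- c(violators, cid)
        next_cell <- next_cell - 1
      }
    }
  })

  list(
    sample_a = count_matrix(ma, "A", clusters, mito),
    sample_b = count_matrix(mb, "B", clusters, mito),
    truth = scene_truth(planted = planted, qc_violators = violators,
                        qc_thresholds = qc_thresholds, seed = seed)
  )
}
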