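#' Prepare expression input for module discovery
#'
#' Approximates a variance-stabilizing transform: counts are depth-
#' normalized to `scale_factor` per cell, log1p-transformed, centered and
#' scaled per gene, and negative values are clipped to zero so the result
#' is a valid non-negative input for [fit_gene_modules()].
#'
#' @param x a `spatial_counts`.
#' @param scale_factor per-cell depth target for normalization.
#' @return Dense genes x cells non-negative matrix.
#' @export
module_input <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "spatial_counts"))
  tot <- Matrix::rowSums(x$counts)
  norm <- log1p(x$counts / tot * scale_factor)
  m <- t(as.matrix(norm))  # genes x cells
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  sdv[sdv == 0] <- 1
  m <- (m - mu) / sdv
  m[m < 0] <- 0
  m
}

#' Non-negative matrix factorization into gene modules
#'
#' Factorizes a non-negative genes x cells expression matrix into
#' `basis %*% coef` (basis: genes x rank; coef: rank x cells) by Lee-Seung
#' multiplicative updates minimizing Frobenius reconstruction error, with
#' an optional nonsmooth interposition matrix
#' `S = (1 - smoothing) I + smoothing/rank * 11'` applied between the
#' factors during updates to encourage sparser modules. Initialization is
#' uniform random under `seed`, so runs are reproducible. Each NMF
#' component defines one gene module; genes within a module are ranked by
#' their basis coefficient in descending order.
#'
#' @param expression non-negative genes x cells matrix with rownames.
#' @param rank number of modules (default 20).
#' @param seed RNG seed for initialization.
#' @param max_iter,tol stopping rule on relative objective change.
#' @param smoothing nonsmooth parameter in `[0, 1)`; 0 = plain NMF.
#' @param tissue_tag label carried through to module names (e.g. "LM").
#' @return A `gene_module_set`: list with `basis`, `coef`, `sorted_genes`
#'   (list of per-module gene rankings), `objective` trace, `tissue_tag`.
#' @export
fit_gene_modules <- function(expression, rank = 20L, seed = 1L,
                             max_iter = 500L, tol = 1e-5, smoothing = 0,
                             tissue_tag = "M") {
  expression <- as.matrix(expression)
  if (any(expression < 0)) stop("expression must be non-negative")
  if (is.null(rownames(expression)))
    rownames(expression) <- paste0("g", seq_len(nrow(expression)))
  stopifnot(rank >= 1, smoothing >= 0, smoothing < 1)
  G <- nrow(expression); C <- ncol(expression)
  eps <- .Machine$double.eps
  init <- with_seed(seed, list(W = matrix(stats::runif(G * rank), G, rank),
                               H = matrix(stats::runif(rank * C), rank, C)))
  W <- init$W; H <- init$H
  S <- (1 - smoothing) * diag(rank) + smoothing / rank
  obj <- numeric(0)
  for (it in seq_len(max_iter)) {
    WS <- W %*% S
    H <- H * (crossprod(WS, expression)) / (crossprod(WS) %*% H + eps)
    SH <- S %*% H
    W <- W * (expression %*% t(SH)) / (W %*% tcrossprod(SH) + eps)
    obj <- c(obj, sqrt(sum((expression - W %*% S %*% H)^2)))
    if (it > 1L && (obj[it - 1L] - obj[it]) < tol * obj[it - 1L]) break
  }
  colnames(W) <- paste0(tissue_tag, seq_len(rank))
  rownames(H) <- colnames(W)
  sorted <- lapply(seq_len(rank), function(m)
    rownames(W)[order(W[, m], decreasing = TRUE)])
  names(sorted) <- colnames(W)
  structure(list(basis = W, coef = H, sorted_genes = sorted,
                 objective = obj, rank = as.integer(rank),
                 smoothing = smoothing, tissue_tag = tissue_tag),
            class = "gene_module_set")
}

#' @export
print.gene_module_set <- function(x, ...) {
  cat(sprintf("gene_module_set '%s': %d modules x %d genes (%d iterations)\n",
              x$tissue_tag, x$rank, nrow(x$basis), length(x$objective)))
  invisible(x)
}

#' Top contributing genes of a module
#'
#' Walking the module's descending coefficient ranking, genes are selected
#' as long as every gene so far has a strictly larger coefficient in this
#' module than in any other module; the scan stops at the first gene that
#' peaks elsewhere. The result is always a (possibly empty) prefix of the
#' sorted gene list.
#'
#' @param modules a `gene_module_set`.
#' @param m module index or name.
#' @return Character vector of gene ids.
#' @export
top_contributing_genes <- function(modules, m) {
  stopifnot(inherits(modules, "gene_module_set"))
  W <- modules$basis
  if (is.character(m)) m <- match(m, colnames(W))
  ord <- order(W[, m], decreasing = TRUE)
  other_max <- apply(W[, -m, drop = FALSE], 1L, max)
  dominated <- W[ord, m] > other_max[ord]
  k <- if (all(dominated)) length(ord) else which(!dominated)[1L] - 1L
  rownames(W)[ord[seq_len(k)]]
}

#' Match modules across tissues by top-gene overlap
#'
#' For every module of `set_a`, the `set_b` module sharing the largest
#' number of its top `top_n` ranked genes is matched (ties broken toward
#' the smaller `set_b` index); matched pairs sharing fewer than
#' `min_frac` of the `top_n` genes are dropped (the boundary is inclusive:
#' exactly 25% overlap is retained under the defaults).
#'
#' @param set_a,set_b `gene_module_set`s (e.g. liver/tumor vs spleen/tumor).
#' @param top_n genes per module entering the overlap (default 200); if a
#'   module ranks fewer genes, all are used with a warning.
#' @param min_frac minimum retained overlap fraction of `top_n`.
#' @return data.frame with columns `module_a`, `module_b`,
#'   `overlap_count`, `overlap_fraction`, sorted by `module_a`.
#' @export
match_modules <- function(set_a, set_b, top_n = 200L, min_frac = 0.25) {
  stopifnot(inherits(set_a, "gene_module_set"), inherits(set_b, "gene_module_set"))
  n_avail <- min(length(set_a$sorted_genes[[1]]), length(set_b$sorted_genes[[1]]))
  if (n_avail < top_n) {
    warning("fewer than ", top_n, " ranked genes; using ", n_avail)
    top_n <- n_avail
  }
  tops_a <- lapply(set_a$sorted_genes, utils::head, top_n)
  tops_b <- lapply(set_b$sorted_genes, utils::head, top_n)
  res <- lapply(seq_along(tops_a), function(i) {
    ov <- vapply(tops_b, function(tb) length(intersect(tops_a[[i]], tb)), integer(1))
    j <- which.max(ov)  # first maximum = smallest index on ties
    data.frame(module_a = names(tops_a)[i], module_b = names(tops_b)[j],
               overlap_count = ov[j], overlap_fraction = ov[j] / top_n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res[res$overlap_fraction >= min_frac, , drop = FALSE]
}

#' Cell-type fractions contributing to a gene set
#'
#' For each cell type, the mean expression of every gene across the cells
#' of that type is computed, the median over the gene set taken, and the
#' per-type medians normalized to fractions summing to 1 -- a summary of
#' which populations carry a module's expression.
#'
#' @param expression genes x cells matrix (log-normalized scale).
#' @param cell_types per-cell type labels.
#' @param genes gene ids of the module (must be present).
#' @return Named numeric vector of fractions summing to 1; all-zero
#'   medians yield NA with a warning.
#' @export
celltype_fractions <- function(expression, cell_types, genes) {
  miss <- setdiff(genes, rownames(expression))
  if (length(miss)) stop("genes absent from expression matrix: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  cell_types <- factor(cell_types)
  sub <- expression[genes, , drop = FALSE]
  med <- vapply(levels(cell_types), function(ct) {
    stats::median(rowMeans(sub[, cell_types == ct, drop = FALSE]))
  }, numeric(1))
  if (sum(med) == 0) {
    warning("all per-type medians are zero; fractions undefined")
    return(stats::setNames(rep(NA_real_, length(med)), names(med)))
  }
  med / sum(med)
}

#' Spatial projection of a gene module with high/low binarization
#'
#' Per well, the median expression over its cells is taken gene-wise and
#' averaged over the module genes; the global threshold is the
#' cells-per-well-weighted average of these per-well values. Wells strictly
#' above the threshold are labeled `high`, remaining wells with nonzero
#' module expression `low`, wells with zero expression `none`, and wells
#' without cells NA. Labels are invariant to a global positive rescaling
#' of the expression matrix.
#'
#' @param expression genes x cells matrix (log-normalized scale) with cells
#'   in columns named or ordered as `well_id`.
#' @param well_id per-cell well assignments (length = ncol(expression)).
#' @param genes module gene ids.
#' @param array a `well_array` (defines the well universe).
#' @return data.frame with columns `well_id`, `n_cells`, `mean_expr`,
#'   `label`.
#' @export
project_module <- function(expression, well_id, genes, array) {
  stopifnot(inherits(array, "well_array"), ncol(expression) == length(well_id))
  miss <- setdiff(genes, rownames(expression))
  if (length(miss)) stop("module genes absent from expression matrix")
  sub <- expression[genes, , drop = FALSE]
  wells <- array$wells$well_id
  wf <- factor(well_id, levels = wells)
  n_cells <- as.integer(table(wf))
  mean_expr <- rep(NA_real_, length(wells))
  for (i in which(n_cells > 0)) {
    cols <- which(wf == wells[i])
    med_per_gene <- apply(sub[, cols, drop = FALSE], 1L, stats::median)
    mean_expr[i] <- mean(med_per_gene)
  }
  occ <- n_cells > 0
  threshold <- sum(n_cells[occ] * mean_expr[occ]) / sum(n_cells[occ])
  label <- rep(NA_character_, length(wells))
  label[occ] <- ifelse(mean_expr[occ] > threshold, "high",
                       ifelse(mean_expr[occ] > 0, "low", "none"))
  data.frame(well_id = wells, n_cells = n_cells, mean_expr = mean_expr,
             label = label, stringsAsFactors = FALSE)
}
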