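#' Flag cross-species ambient outlier genes
#'
#' In a mixed-species run the human cell population acts as a control for
#' ambient contamination of the mouse transcriptome: mouse-aligned genes
#' with extremely high total expression inside human cells (natural
#' `log(total counts + 1)` above `log_threshold`, default 6) are flagged
#' for removal before model-based decontamination. Human genes are never
#' flagged.
#'
#' @param x a `spatial_counts` with species annotations on genes and cells.
#' @param human_cells optional cell ids to treat as the human population
#'   (default: cells called "human" in `cell_meta$species`).
#' @param log_threshold threshold on `log(counts + 1)`.
#' @return Character vector of flagged mouse gene ids (possibly empty; an
#'   empty human population warns and flags nothing).
#' @export
flag_cross_species_outliers <- function(x, human_cells = NULL, log_threshold = 6) {
  stopifnot(inherits(x, "spatial_counts"))
  if (is.null(human_cells))
    human_cells <- x$cell_meta$cell_id[x$cell_meta$species %in% "human"]
  if (!length(human_cells)) {
    warning("no human cells available; nothing flagged")
    return(character(0))
  }
  mouse_genes <- which(x$gene_meta$species %in% "mouse")
  if (!length(mouse_genes)) return(character(0))
  sub <- x$counts[match(human_cells, x$cell_meta$cell_id), mouse_genes, drop = FALSE]
  tot <- Matrix::colSums(sub)
  x$gene_meta$gene_id[mouse_genes][log(tot + 1) > log_threshold]
}

cluster_profiles <- function(tr, clusters, n_genes, pseudocount) {
  K <- nlevels(clusters)
  agg <- Matrix::sparseMatrix(i = as.integer(clusters)[tr$i], j = tr$j, x = tr$x,
                              dims = c(K, n_genes))
  m <- as.matrix(agg) + pseudocount
  m / rowSums(m)
}

#' Fit the ambient-contamination mixture by EM
#'
#' Observed counts of each cell are modeled as a two-component mixture:
#' each transcript carries a hidden Bernoulli state choosing between the
#' cell population's native expression distribution `phi_k` and a
#' contamination distribution `eta_k` aggregated from all other
#' populations, and each cell has a Beta-distributed proportion `theta_c`
#' of contaminating transcripts. The model is fitted by plain EM with MAP
#' updates for `theta` under a `Beta(alpha, beta)` prior (default
#' uninformative). `eta_k` is recomputed each M-step as the count-weighted
#' average of `phi_j` over clusters `j != k`.
#'
#' @param x a `spatial_counts`.
#' @param clusters per-cell cluster labels (>= 2 clusters; any clustering).
#' @param alpha,beta Beta prior hyperparameters for `theta`.
#' @param max_iter,tol EM stopping rule: stop when the objective improves
#'   by less than `tol` or after `max_iter` iterations.
#' @param seed RNG seed for the random initialization of `theta`.
#' @param pseudocount added to profile tallies to keep distributions
#'   strictly positive.
#' @return A `contamination_model`: list with per-cell `theta`, per-cluster
#'   gene distributions `phi` and `eta` (clusters x genes), `clusters`,
#'   `loglik_trace`, and `converged`.
#' @export
fit_decontamination <- function(x, clusters, alpha = 1, beta = 1,
                                max_iter = 200L, tol = 1e-4, seed = 1L,
                                pseudocount = 1e-12) {
  stopifnot(inherits(x, "spatial_counts"))
  clusters <- factor(clusters)
  if (length(clusters) != nrow(x$counts))
    stop("one cluster label per cell required")
  if (nlevels(clusters) < 2L)
    stop("need >= 2 clusters to define a contamination source")
  X <- x$counts
  tr <- Matrix::summary(X)
  n_cells <- nrow(X); n_genes <- ncol(X)
  kk <- as.integer(clusters)
  N <- Matrix::rowSums(X)
  if (any(N == 0)) stop("cells with zero counts cannot be modeled")
  w <- as.numeric(tapply(N, clusters, sum))  # cluster count mass, fixed

  phi <- cluster_profiles(tr, clusters, n_genes, pseudocount)
  theta <- with_seed(seed, stats::runif(n_cells, 0.05, 0.3))
  ki <- kk[tr$i]

  mix_eta <- function(phi) {
    total <- colSums(w * phi)
    eta <- -(w * phi) + rep(total, each = nrow(phi))
    eta / rowSums(eta)
  }

  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- mix_eta(phi)
    phi_e <- phi[cbind(ki, tr$j)]
    eta_e <- eta[cbind(ki, tr$j)]
    th_e <- theta[tr$i]
    dens <- (1 - th_e) * phi_e + th_e * eta_e
    ll <- sum(tr$x * log(dens)) +
      sum(stats::dbeta(theta, alpha, beta, log = TRUE))
    trace <- c(trace, ll)
    if (it > 1L && abs(trace[it] - trace[it - 1L]) < tol) {
      converged <- TRUE
      break
    }
    r <- th_e * eta_e / dens  # posterior P(transcript is contamination)
    contam <- as.numeric(rowsum(tr$x * r, tr$i, reorder = FALSE))
    contam_full <- numeric(n_cells)
    contam_full[unique(tr$i)] <- contam
    theta <- (contam_full + alpha - 1) / (N + alpha + beta - 2)
    theta <- pmin(pmax(theta, 1e-6), 1 - 1e-6)
    native <- Matrix::sparseMatrix(i = ki, j = tr$j, x = tr$x * (1 - r),
                                   dims = c(nlevels(clusters), n_genes))
    phi <- as.matrix(native) + pseudocount
    phi <- phi / rowSums(phi)
  }
  # generalized EM (eta is tied to phi), so allow tiny numerical dips only
  if (length(trace) > 1L) {
    dips <- diff(trace) < -1e-8 * (abs(trace[-length(trace)]) + 1)
    if (any(dips)) warning("EM objective decreased beyond numerical tolerance")
  }
  dimnames(phi) <- list(levels(clusters), colnames(X))
  eta <- mix_eta(phi)
  dimnames(eta) <- dimnames(phi)
  structure(list(theta = stats::setNames(theta, rownames(X)),
                 phi = phi, eta = eta,
                 clusters = stats::setNames(clusters, rownames(X)),
                 alpha = alpha, beta = beta,
                 loglik_trace = trace, converged = converged),
            class = "contamination_model")
}

#' @export
print.contamination_model <- function(x, ...) {
  cat(sprintf("contamination_model: %d cells, %d clusters, median theta %.3f (%s)\n",
              length(x$theta), nlevels(x$clusters), stats::median(x$theta),
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Subtract the estimated contamination from a count matrix
#'
#' Replaces every count by its expected native component under the fitted
#' mixture (the per-transcript posterior probability of being native times
#' the observed count), rounded toward zero. The corrected matrix is never
#' larger than the raw one in any entry, and per-cell totals shrink to
#' approximately `(1 - theta_c)` of the raw totals. Species tallies and
#' calls in the cell metadata are recomputed from the corrected counts.
#'
#' @param x the `spatial_counts` the model was fitted on.
#' @param model a `contamination_model` from [fit_decontamination()].
#' @param species_threshold threshold for re-calling species.
#' @return A corrected `spatial_counts` with integer counts; the
#'   unrounded expectation is attached as attribute `corrected_real`.
#' @export
decontaminate <- function(x, model, species_threshold = 0.66) {
  stopifnot(inherits(x, "spatial_counts"), inherits(model, "contamination_model"))
  if (nrow(x$counts) != length(model$theta) ||
      ncol(x$counts) != ncol(model$phi))
    stop("matrix dimensions do not match the fitted model")
  tr <- Matrix::summary(x$counts)
  ki <- as.integer(model$clusters)[tr$i]
  phi_e <- model$phi[cbind(ki, tr$j)]
  eta_e <- model$eta[cbind(ki, tr$j)]
  th_e <- model$theta[tr$i]
  dens <- (1 - th_e) * phi_e + th_e * eta_e
  native <- tr$x * (1 - th_e) * phi_e / dens
  real <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = native,
                               dims = dim(x$counts), dimnames = dimnames(x$counts))
  # snap before flooring so exact-integer expectations survive float noise
  rounded <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = floor(native + 1e-9),
                                  dims = dim(x$counts), dimnames = dimnames(x$counts))
  cm <- x$cell_meta
  if (all(c("human_umis", "mouse_umis") %in% names(cm))) {
    sp <- x$gene_meta$species
    cm$human_umis <- Matrix::rowSums(rounded[, which(sp %in% "human"), drop = FALSE])
    cm$mouse_umis <- Matrix::rowSums(rounded[, which(sp %in% "mouse"), drop = FALSE])
    cm$species <- call_species(cm$human_umis, cm$mouse_umis, species_threshold)
  }
  out <- spatial_counts(rounded, cm, x$gene_meta)
  attr(out, "corrected_real") <- real
  out
}

#' Per-cluster contamination summary
#'
#' Median estimated contamination proportion per cluster, reported as
#' percentages (the scale on which per-population ambient rates are
#' conventionally quoted).
#'
#' @param model a `contamination_model`.
#' @return data.frame with columns `cluster`, `n_cells`,
#'   `median_theta_pct`.
#' @export
contamination_summary <- function(model) {
  stopifnot(inherits(model, "contamination_model"))
  med <- tapply(model$theta, model$clusters, stats::median)
  data.frame(cluster = names(med),
             n_cells = as.integer(table(model$clusters)),
             median_theta_pct = 100 * as.numeric(med),
             stringsAsFactors = FALSE)
}
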