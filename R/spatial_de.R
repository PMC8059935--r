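#' Negative-binomial spline association with the proximity score
#'
#' Tests whether a gene's counts vary along the continuous proximity score:
#' counts are regressed on a cubic B-spline basis of the score under a
#' negative-binomial GLM with a library-size offset, and the spline
#' coefficients are tested jointly against zero by a Wald chi-square test.
#' The per-gene dispersion is estimated by method of moments from the
#' Poisson fit of the full model before refitting with the NB family.
#' Zero-variance genes are assigned `p = 1` and flagged; non-converging
#' fits are flagged and excluded downstream.
#'
#' @param y non-negative integer counts, one per cell.
#' @param score per-cell proximity score in `[0, 1]` (NAs excluded by the
#'   caller).
#' @param offset per-cell log library size (default `log(sum(y) ...)` must
#'   be supplied by the matrix-level wrapper; NULL = constant).
#' @param n_knots degrees of freedom of the B-spline basis (default 4).
#' @param grid score grid on which the fitted curve is evaluated.
#' @return list with `stat`, `df`, `p_value`, `dispersion`, `curve`
#'   (fitted mean at median offset over `grid`), `flag`.
#' @export
nb_spline_test <- function(y, score, offset = NULL, n_knots = 4L,
                           grid = seq(0, 1, length.out = 50L)) {
  stopifnot(length(y) == length(score))
  if (length(y) < 30L) stop("need >= 30 scored cells")
  if (is.null(offset)) offset <- rep(0, length(y))
  if (all(y == y[1L])) {
    return(list(stat = NA_real_, df = n_knots, p_value = 1, dispersion = NA_real_,
                curve = rep(mean(y), length(grid)), flag = "zero_variance"))
  }
  B <- splines::bs(score, df = n_knots,
                   Boundary.knots = range(c(0, 1, score)))
  fit <- tryCatch(suppressWarnings({
    pois <- stats::glm(y ~ B, family = stats::poisson(), offset = offset)
    mu <- stats::fitted(pois)
    excess <- sum((y - mu)^2 - mu)
    theta <- if (excess > 0) sum(mu^2) / excess else 1e8
    theta <- min(max(theta, 1e-3), 1e8)
    stats::glm(y ~ B, family = MASS::negative.binomial(theta), offset = offset)
  }), error = function(e) NULL)
  if (is.null(fit) || !fit$converged || anyNA(stats::coef(fit))) {
    return(list(stat = NA_real_, df = n_knots, p_value = NA_real_,
                dispersion = NA_real_, curve = rep(NA_real_, length(grid)),
                flag = "non_convergence"))
  }
  b <- stats::coef(fit)[-1L]
  V <- stats::vcov(fit)[-1L, -1L, drop = FALSE]
  stat <- tryCatch(as.numeric(t(b) %*% solve(V, b)), error = function(e) NA_real_)
  if (!is.finite(stat)) {
    return(list(stat = NA_real_, df = n_knots, p_value = NA_real_,
                dispersion = NA_real_, curve = rep(NA_real_, length(grid)),
                flag = "non_convergence"))
  }
  Bg <- stats::predict(B, grid)
  eta <- cbind(1, Bg) %*% stats::coef(fit) + stats::median(offset)
  list(stat = stat, df = length(b),
       p_value = stats::pchisq(stat, df = length(b), lower.tail = FALSE),
       dispersion = environment(fit$family$variance)$.Theta,
       curve = as.numeric(exp(eta)), flag = "ok")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH q-values controlling the false discovery rate (a thin,
#' validated wrapper around `p.adjust(method = "BH")`).
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify fitted curves into spatial regions
#'
#' Significant proximity-associated genes are broadly grouped by where
#' their fitted expression peaks along the score: argmax in the top third
#' of the score range (tumor-rich end) = `intratumor`, bottom third =
#' `intratissue`, middle = `boundary`. Flat curves are labeled `boundary`
#' and flagged.
#'
#' @param curves genes x grid matrix of fitted values.
#' @param grid the score grid the curves were evaluated on.
#' @param flat_tol relative range below which a curve counts as flat.
#' @return data.frame with columns `region` and `flat` (logical), one row
#'   per curve.
#' @export
classify_regions <- function(curves, grid = seq(0, 1, length.out = ncol(curves)),
                             flat_tol = 1e-8) {
  curves <- as.matrix(curves)
  peak <- grid[max.col(curves, ties.method = "first")]
  rng <- apply(curves, 1L, function(z) diff(range(z)))
  mid <- apply(curves, 1L, function(z) mean(abs(z)))
  flat <- rng <= flat_tol * pmax(mid, 1)
  region <- ifelse(peak >= 2 / 3, "intratumor",
                   ifelse(peak < 1 / 3, "intratissue", "boundary"))
  region[flat] <- "boundary"
  data.frame(region = region, flat = flat, row.names = rownames(curves))
}

#' Proximity-associated differential expression over a count matrix
#'
#' Applies [nb_spline_test()] to every gene of a (typically cell-type-
#' subsetted) count matrix against per-cell proximity scores, adjusts
#' p-values by Benjamini-Hochberg, and classifies significant genes into
#' intratumor / boundary / intratissue by the peak of their fitted curve.
#' Cells with NA scores are excluded before fitting.
#'
#' @param x a `spatial_counts` (cells x genes), or a counts matrix.
#' @param score per-cell proximity scores.
#' @param n_knots spline degrees of freedom.
#' @param fdr significance threshold on q-values for region assignment.
#' @param grid score grid for fitted curves.
#' @return list with `results` (data.frame: gene, stat, df, p_value,
#'   q_value, flag, region -- NA region for non-significant genes) and
#'   `curves` (genes x grid matrix).
#' @export
proximity_association <- function(x, score, n_knots = 4L, fdr = 0.05,
                                  grid = seq(0, 1, length.out = 50L)) {
  counts <- if (inherits(x, "spatial_counts")) x$counts else x
  stopifnot(nrow(counts) == length(score))
  keep <- !is.na(score)
  counts <- counts[keep, , drop = FALSE]
  score <- score[keep]
  off <- log(pmax(Matrix::rowSums(counts), 1))
  genes <- colnames(counts)
  res <- vector("list", length(genes))
  curves <- matrix(NA_real_, length(genes), length(grid),
                   dimnames = list(genes, NULL))
  for (g in seq_along(genes)) {
    out <- nb_spline_test(as.numeric(counts[, g]), score, offset = off,
                          n_knots = n_knots, grid = grid)
    res[[g]] <- data.frame(gene = genes[g], stat = out$stat, df = out$df,
                           p_value = out$p_value, flag = out$flag,
                           stringsAsFactors = FALSE)
    curves[g, ] <- out$curve
  }
  res <- do.call(rbind, res)
  res$q_value <- bh_adjust(res$p_value)
  res$region <- NA_character_
  sig <- which(!is.na(res$q_value) & res$q_value < fdr & res$flag == "ok")
  if (length(sig))
    res$region[sig] <- classify_regions(curves[sig, , drop = FALSE], grid)$region
  list(results = res[, c("gene", "stat", "df", "p_value", "q_value",
                         "flag", "region")],
       curves = curves)
}
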