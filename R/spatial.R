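#' Per-well cell-type composition
#'
#' Tallies cells of each type into their well of origin. Wells present on
#' the array but containing no cells are kept with zero counts, so totals
#' over wells always equal totals over cells.
#'
#' @param cells data.frame with columns `well_id` and `cell_type`; for a
#'   `spatial_counts` object pass
#'   `data.frame(well_id = x$cell_meta$well_id, cell_type = labels)`.
#' @param array the `well_array` the wells live on.
#' @return A `well_composition`: list with `counts` (wells x types integer
#'   matrix) and `wells` (data.frame well_id, row, col, n_cells).
#' @export
well_composition <- function(cells, array) {
  stopifnot(inherits(array, "well_array"),
            all(c("well_id", "cell_type") %in% names(cells)))
  bad <- setdiff(unique(cells$well_id), array$wells$well_id)
  if (length(bad)) stop("cells assigned to wells not on the array: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  types <- sort(unique(as.character(cells$cell_type)))
  tab <- table(factor(cells$well_id, levels = array$wells$well_id),
               factor(cells$cell_type, levels = types))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  wells <- data.frame(well_id = array$wells$well_id,
                      row = array$wells$row, col = array$wells$col,
                      n_cells = as.integer(rowSums(counts)),
                      stringsAsFactors = FALSE)
  structure(list(counts = counts, wells = wells), class = "well_composition")
}

#' Cell-type colocalization across wells
#'
#' Pearson correlation of per-well cell counts of two types, the standard
#' readout for spatial co-occurrence of cell populations on the array.
#'
#' @param comp a `well_composition`.
#' @param type_a,type_b cell-type names.
#' @param wells_with_cells if TRUE (default) restrict to wells containing
#'   at least one cell of any type.
#' @return list with `r`, `p_value`, `n_wells`; zero variance in either
#'   type yields `r = NA` with a warning.
#' @export
colocalization <- function(comp, type_a, type_b, wells_with_cells = TRUE) {
  stopifnot(inherits(comp, "well_composition"))
  a <- comp$counts[, type_a]
  b <- comp$counts[, type_b]
  if (wells_with_cells) {
    keep <- comp$wells$n_cells > 0
    a <- a[keep]; b <- b[keep]
  }
  if (length(a) < 3) stop("need >= 3 wells with cells")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in per-well counts; correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n_wells = length(a)))
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_wells = length(a))
}

#' Exponential-decay layer weights
#'
#' Distance weights for the concentric layers entering the proximity
#' score: `u_l = (1/d^l) / u_s` with normalizer `u_s = sum_{l=1..L} 1/d^l`,
#' so the weights sum to exactly 1 and decay geometrically with layer
#' index. The default decay factor `d = 1.05` over `L = 10` layers gives a
#' gently graded neighborhood; `d = 1` is the uniform limit.
#'
#' @param d decay factor (> 0).
#' @param L number of layers (>= 1).
#' @return list with `d`, `L`, `u` (length-L weight vector) and `u_s`.
#' @export
decay_weights <- function(d = 1.05, L = 10L) {
  if (d <= 0) stop("decay factor d must be positive")
  stopifnot(L >= 1)
  raw <- 1 / d^seq_len(L)
  u_s <- sum(raw)
  list(d = d, L = as.integer(L), u = raw / u_s, u_s = u_s)
}

#' Layered tumor-proximity score
#'
#' For every well the tumor/reference composition of its concentric layers
#' is summarized into a score `s` in `[0, 1]`. Writing `t_w` for the number
#' of tumor + reference cells in well `w`, `p_w` for the tumor fraction
#' (or, with `orientation = "reference"`, the reference fraction), the
#' layer-`l` summary is the cell-number-weighted mean of `p` over the wells
#' of layer `l` that contain scored cells, and
#' `s = (u_1 p_w + sum_l u_l p_{w,l}) / W` where `u` are the
#' [decay_weights()] (the well's own composition shares the layer-1
#' weight) and `W` is the realized total weight: terms whose well or layer
#' holds no tumor/reference cells are dropped and the remaining weights
#' renormalized, keeping `s` in `[0, 1]`. Scores near 1 mark tumor-rich
#' regions, near 0 reference-rich tissue, and wells straddling a straight
#' boundary take values around 0.5.
#'
#' @param comp a `well_composition`.
#' @param array the matching `well_array`.
#' @param weights layer weights from [decay_weights()].
#' @param tumor_label,ref_label cell-type names entering the composition.
#' @param orientation `"tumor"` (default; `p` = tumor fraction, score 1 =
#'   tumor-rich) or `"reference"` (the mirrored score `1 - s`).
#' @return A `proximity_field`: data.frame (well_id, row, col, score) with
#'   the scoring parameters in attributes; wells with no score (no scored
#'   cells anywhere in reach) carry NA.
#' @export
tumor_proximity <- function(comp, array, weights = decay_weights(),
                            tumor_label = "MC38", ref_label = "hepatocyte",
                            orientation = c("tumor", "reference")) {
  stopifnot(inherits(comp, "well_composition"), inherits(array, "well_array"))
  orientation <- match.arg(orientation)
  ids <- comp$wells$well_id
  if (!identical(ids, array$wells$well_id))
    stop("composition and array wells disagree")
  tum <- if (tumor_label %in% colnames(comp$counts)) comp$counts[, tumor_label] else numeric(length(ids))
  ref <- if (ref_label %in% colnames(comp$counts)) comp$counts[, ref_label] else numeric(length(ids))
  t_w <- tum + ref
  p_w <- rep(NA_real_, length(ids))
  p_w[t_w > 0] <- if (orientation == "tumor") {
    (tum / t_w)[t_w > 0]
  } else {
    (ref / t_w)[t_w > 0]
  }

  q <- array$wells$q; r <- array$wells$r
  D <- (abs(outer(q, q, "-")) + abs(outer(r, r, "-")) +
          abs(outer(q + r, q + r, "-"))) / 2
  u <- weights$u; L <- weights$L
  num <- ifelse(is.na(p_w), 0, u[1] * p_w)       # own-well term, layer-1 weight
  wsum <- ifelse(is.na(p_w), 0, u[1])
  for (l in seq_len(L)) {
    sel <- D == l
    tp <- ifelse(is.na(p_w), 0, t_w * p_w)
    lay_tp <- as.vector(sel %*% tp)
    lay_t <- as.vector(sel %*% t_w)
    has <- lay_t > 0
    num[has] <- num[has] + u[l] * lay_tp[has] / lay_t[has]
    wsum[has] <- wsum[has] + u[l]
  }
  score <- ifelse(wsum > 0, num / wsum, NA_real_)
  field <- data.frame(well_id = ids, row = array$wells$row,
                      col = array$wells$col, score = score,
                      stringsAsFactors = FALSE)
  structure(field, class = c("proximity_field", "data.frame"),
            variant = "layered", d = weights$d, L = L,
            orientation = orientation,
            tumor_label = tumor_label, ref_label = ref_label)
}

#' Seeded linear proximity score
#'
#' The unidirectional variant used when the tumor sits at one end of the
#' tissue: chosen seed wells on the far side of the tumor region are set to
#' score 1 and the score decreases linearly over `L` successive layers,
#' `s(w) = max(0, 1 - l / L)` with `l` the hexagonal distance to the
#' nearest seed; wells at layer `L` and beyond score 0.
#'
#' @param array a `well_array`.
#' @param seed_wells character vector of seed well ids (>= 1).
#' @param L number of layers over which the score decays.
#' @return A `proximity_field` data.frame (well_id, row, col, score).
#' @export
seeded_proximity <- function(array, seed_wells, L = 10L) {
  stopifnot(inherits(array, "well_array"))
  if (!length(seed_wells)) stop("at least one seed well is required")
  si <- well_index(array, seed_wells)
  q <- array$wells$q; r <- array$wells$r
  dmin <- rep(Inf, nrow(array$wells))
  for (i in si) {
    d <- (abs(q - q[i]) + abs(r - r[i]) + abs(q + r - q[i] - r[i])) / 2
    dmin <- pmin(dmin, d)
  }
  field <- data.frame(well_id = array$wells$well_id, row = array$wells$row,
                      col = array$wells$col,
                      score = pmax(0, 1 - dmin / L),
                      stringsAsFactors = FALSE)
  structure(field, class = c("proximity_field", "data.frame"),
            variant = "seeded_linear", L = as.integer(L))
}

#' Project well scores onto cells
#'
#' Each cell inherits the proximity score of its well; cells in unscored
#' wells get NA and are excluded from downstream association testing.
#'
#' @param field a `proximity_field`.
#' @param well_id per-cell well assignments (e.g. `x$cell_meta$well_id`).
#' @return Numeric vector of per-cell scores.
#' @export
cell_scores <- function(field, well_id) {
  stopifnot(inherits(field, "proximity_field"))
  field$score[match(well_id, field$well_id)]
}
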