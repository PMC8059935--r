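#' PCR index whitelist
#'
#' Generates `n` distinct i5 PCR well indices of `width` nt.
#'
#' @param n number of indices (default 384, two second-round plates).
#' @param width index length in nt.
#' @param seed RNG seed.
#' @return Character vector of distinct indices.
#' @export
make_pcr_whitelist <- function(n = 384L, width = 8L, seed = 1L) {
  with_seed(seed, {
    out <- unique(random_dna(2L * n, width))
    while (length(out) < n) out <- unique(c(out, random_dna(n, width)))
    out[seq_len(n)]
  })
}

#' Tissue-on-array simulation design
#'
#' Parameters of the synthetic tumor-bearing tissue: array geometry, the
#' tumor domain shape, per-domain cell-type mixtures, marker-gene programs
#' and negative-binomial expression noise. Defaults mirror the profiled
#' assay's conditions: a 24 x 32 (768-well) array at 500-um pitch, 13
#' cells expected per well, per-cell libraries of roughly a thousand UMIs,
#' NB dispersion 0.5, and a tumor/tissue split with MC38-dominated tumor
#' wells and hepatocyte-dominated liver wells, immune populations and MSCs
#' mixed through both.
#'
#' @param n_rows,n_cols array dimensions.
#' @param geometry `"half_plane"` (tumor = columns left of `boundary_col`)
#'   or `"disk"` (tumor = wells within `disk_radius` layers of the array
#'   center).
#' @param boundary_col first non-tumor column for the half-plane geometry.
#' @param disk_radius tumor radius in layers for the disk geometry.
#' @param cells_per_well Poisson mean of cells per well.
#' @param n_genes number of (mouse) genes.
#' @param n_markers marker genes per cell type.
#' @param marker_fc fold change of a marker in its own type.
#' @param base_meanlog,base_sdlog log-normal parameters of per-gene
#'   baseline means.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param tumor_mix,tissue_mix named cell-type probabilities per domain.
#' @param n_mito mitochondrial genes (symbol prefix `mt-`).
#' @param mito_mean baseline mean of each mitochondrial gene.
#' @param n_pcr PCR indices available for second-round indexing.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_rows = 24L, n_cols = 32L,
                              geometry = c("half_plane", "disk"),
                              boundary_col = n_cols %/% 2L, disk_radius = 6L,
                              cells_per_well = 13, n_genes = 400L,
                              n_markers = 25L, marker_fc = 8,
                              base_meanlog = log(1.5), base_sdlog = 1,
                              dispersion = 0.5,
                              tumor_mix = c(MC38 = 0.60, myeloid = 0.15,
                                            lymphocyte = 0.12, MSC = 0.08,
                                            Kupffer = 0.03, LSEC = 0.02),
                              tissue_mix = c(hepatocyte = 0.62, Kupffer = 0.13,
                                             LSEC = 0.10, MSC = 0.06,
                                             myeloid = 0.05, lymphocyte = 0.04),
                              n_mito = 5L, mito_mean = 1.0, n_pcr = 96L) {
  geometry <- match.arg(geometry)
  stopifnot(cells_per_well > 0, n_genes > 0, dispersion > 0,
            abs(sum(tumor_mix) - 1) < 1e-8, abs(sum(tissue_mix) - 1) < 1e-8)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 geometry = geometry, boundary_col = as.integer(boundary_col),
                 disk_radius = as.integer(disk_radius),
                 cells_per_well = cells_per_well, n_genes = as.integer(n_genes),
                 n_markers = as.integer(n_markers), marker_fc = marker_fc,
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 dispersion = dispersion, tumor_mix = tumor_mix,
                 tissue_mix = tissue_mix, n_mito = as.integer(n_mito),
                 mito_mean = mito_mean, n_pcr = as.integer(n_pcr)),
            class = "simulation_design")
}

recompute_species_meta <- function(counts, cell_meta, gene_meta, threshold = 0.66) {
  sp <- gene_meta$species
  cell_meta$human_umis <- Matrix::rowSums(counts[, which(sp %in% "human"), drop = FALSE])
  cell_meta$mouse_umis <- Matrix::rowSums(counts[, which(sp %in% "mouse"), drop = FALSE])
  cell_meta$species <- call_species(cell_meta$human_umis, cell_meta$mouse_umis, threshold)
  mito <- Matrix::rowSums(counts[, which(gene_meta$is_mito), drop = FALSE])
  tot <- Matrix::rowSums(counts)
  cell_meta$mito_frac <- ifelse(tot > 0, mito / tot, 0)
  cell_meta
}

nb_counts_by_type <- function(types, mu_by_type, dispersion) {
  n_genes <- nrow(mu_by_type)
  out <- matrix(0L, length(types), n_genes)
  for (ct in unique(types)) {
    rows <- which(types == ct)
    mu <- mu_by_type[, ct]
    out[rows, ] <- matrix(
      stats::rnbinom(length(rows) * n_genes, size = 1 / dispersion,
                     mu = rep(mu, times = length(rows))),
      nrow = length(rows), byrow = TRUE)
  }
  out
}

assign_cells_to_wells <- function(wells_df, n_cells_per_well, pcr_whitelist) {
  stopifnot(max(n_cells_per_well) <= length(pcr_whitelist))
  well_rep <- rep(seq_len(nrow(wells_df)), n_cells_per_well)
  pcr <- unlist(lapply(n_cells_per_well, function(n)
    sample(pcr_whitelist, n, replace = FALSE)), use.names = FALSE)
  data.frame(well_id = wells_df$well_id[well_rep],
             row = wells_df$row[well_rep], col = wells_df$col[well_rep],
             spatial_barcode = wells_df$spatial_barcode[well_rep],
             pcr_index = pcr, stringsAsFactors = FALSE)
}

#' Simulate a tumor-bearing tissue slice on the array
#'
#' Assigns every well to the tumor or tissue domain by the design's
#' geometry, draws Poisson cell numbers per well, samples cell types from
#' the domain mixture, and draws NB gene counts with marker fold-changes.
#' Fully reproducible given `(design, seed)`.
#'
#' @param design a [simulation_design()].
#' @param seed RNG seed.
#' @return list with `counts` (a `spatial_counts`), `truth` (lists of cell,
#'   gene and well ground truth), `array` (the `well_array`) and
#'   `pcr_whitelist`.
#' @export
simulate_tissue <- function(design = simulation_design(), seed = 1L) {
  stopifnot(inherits(design, "simulation_design"))
  array <- make_well_array(design$n_rows, design$n_cols, seed = seed)
  pcr <- make_pcr_whitelist(design$n_pcr, seed = seed)
  sim <- with_seed(seed + 1L, {
    w <- array$wells
    domain <- if (design$geometry == "half_plane") {
      ifelse(w$col < design$boundary_col, "tumor", "tissue")
    } else {
      center <- w$well_id[which.min(abs(w$row - design$n_rows %/% 2L) +
                                      abs(w$col - design$n_cols %/% 2L))]
      ifelse(hex_distance(array, w$well_id, center) <= design$disk_radius,
             "tumor", "tissue")
    }
    n_per_well <- stats::rpois(nrow(w), design$cells_per_well)
    n_per_well <- pmin(n_per_well, design$n_pcr)
    if (sum(n_per_well) == 0) stop("degenerate design: no cells drawn")
    cells <- assign_cells_to_wells(w, n_per_well, pcr)
    cells$domain <- rep(domain, n_per_well)
    mix <- list(tumor = design$tumor_mix, tissue = design$tissue_mix)
    cells$cell_type <- NA_character_
    for (dm in names(mix)) {
      rows <- which(cells$domain == dm)
      cells$cell_type[rows] <- sample(names(mix[[dm]]), length(rows),
                                      replace = TRUE, prob = mix[[dm]])
    }
    types <- sort(unique(c(names(design$tumor_mix), names(design$tissue_mix))))
    n_plain <- design$n_genes - design$n_mito
    gene_ids <- c(sprintf("mm10_G%04d", seq_len(n_plain)),
                  sprintf("mm10_mt-G%d", seq_len(design$n_mito)))
    base <- c(stats::rlnorm(n_plain, design$base_meanlog, design$base_sdlog),
              rep(design$mito_mean, design$n_mito))
    marker_of <- rep(NA_character_, design$n_genes)
    slots <- split(seq_len(min(n_plain, design$n_markers * length(types))),
                   rep(types, each = design$n_markers)[seq_len(min(n_plain, design$n_markers * length(types)))])
    for (ct in names(slots)) marker_of[slots[[ct]]] <- ct
    mu_by_type <- matrix(base, design$n_genes, length(types),
                         dimnames = list(gene_ids, types))
    for (ct in types) {
      sel <- which(marker_of == ct)
      mu_by_type[sel, ct] <- mu_by_type[sel, ct] * design$marker_fc
    }
    counts <- nb_counts_by_type(cells$cell_type, mu_by_type, design$dispersion)
    list(cells = cells, gene_ids = gene_ids, base = base,
         marker_of = marker_of, counts = counts, domain = domain)
  })
  cell_ids <- paste0(sim$cells$spatial_barcode, "-", sim$cells$pcr_index)
  gene_meta <- data.frame(gene_id = sim$gene_ids, species = "mouse",
                          is_mito = is_mito_gene(sim$gene_ids),
                          marker_of = sim$marker_of, base_mean = sim$base,
                          stringsAsFactors = FALSE)
  cell_meta <- data.frame(cell_id = cell_ids,
                          spatial_barcode = sim$cells$spatial_barcode,
                          pcr_index = sim$cells$pcr_index,
                          well_id = sim$cells$well_id,
                          row = sim$cells$row, col = sim$cells$col,
                          stringsAsFactors = FALSE)
  counts <- Matrix::Matrix(sim$counts, sparse = TRUE,
                           dimnames = list(cell_ids, sim$gene_ids))
  cell_meta <- recompute_species_meta(counts, cell_meta, gene_meta)
  x <- spatial_counts(counts, cell_meta, gene_meta)
  truth <- list(cells = data.frame(cell_id = cell_ids,
                                   well_id = sim$cells$well_id,
                                   cell_type = sim$cells$cell_type,
                                   domain = sim$cells$domain,
                                   species = "mouse", theta = 0,
                                   stringsAsFactors = FALSE),
                genes = gene_meta,
                wells = data.frame(well_id = array$wells$well_id,
                                   row = array$wells$row, col = array$wells$col,
                                   domain = sim$domain, stringsAsFactors = FALSE))
  list(counts = x, truth = truth, array = array, pcr_whitelist = pcr)
}

#' Simulate the mixed-species gradient experiment
#'
#' Human and mouse cells are deposited along the 21 array columns at the
#' gradient design's ratios (pure human flanks, pure mouse center, 11
#' distinct ratios). In `noiseless` mode each well holds exactly 10 cells
#' with the design composition realized exactly; otherwise cell numbers
#' are Poisson and species Bernoulli at the column ratio. An optional
#' planted co-encapsulation rate turns cells into human+mouse collisions
#' whose library mixes both transcriptomes.
#'
#' @param n_rows array rows (columns are fixed by the 21-column gradient).
#' @param cells_per_well Poisson mean (ignored in noiseless mode).
#' @param noiseless exact composition at 10 cells/well, no collisions.
#' @param collision_rate planted co-encapsulation probability per cell.
#' @param n_genes_per_species genes per species.
#' @param base_meanlog,base_sdlog,dispersion NB expression parameters.
#' @param n_pcr PCR indices.
#' @param seed RNG seed.
#' @return list with `counts`, `truth`, `array`, `pcr_whitelist`, `design`
#'   (the gradient design table).
#' @export
simulate_barnyard <- function(n_rows = 24L, cells_per_well = 8,
                              noiseless = FALSE, collision_rate = 0,
                              n_genes_per_species = 200L,
                              base_meanlog = log(1.5), base_sdlog = 1,
                              dispersion = 0.5, n_pcr = 96L, seed = 1L) {
  grad <- gradient_design()
  n_cols <- nrow(grad)
  array <- make_well_array(n_rows, n_cols, seed = seed)
  pcr <- make_pcr_whitelist(n_pcr, seed = seed)
  sim <- with_seed(seed + 1L, {
    w <- array$wells
    frac <- grad$human_frac[match(w$col, grad$col)]
    if (noiseless) {
      n_per_well <- rep(10L, nrow(w))
    } else {
      n_per_well <- pmin(stats::rpois(nrow(w), cells_per_well), n_pcr)
    }
    cells <- assign_cells_to_wells(w, n_per_well, pcr)
    well_frac <- rep(frac, n_per_well)
    if (noiseless) {
      species <- unlist(lapply(seq_along(n_per_well), function(i) {
        nh <- round(frac[i] * n_per_well[i])
        c(rep("human", nh), rep("mouse", n_per_well[i] - nh))
      }), use.names = FALSE)
    } else {
      species <- ifelse(stats::runif(nrow(cells)) < well_frac, "human", "mouse")
    }
    collided <- if (noiseless || collision_rate <= 0) {
      rep(FALSE, nrow(cells))
    } else {
      stats::runif(nrow(cells)) < collision_rate
    }
    truth_species <- ifelse(collided, "collision", species)
    gene_ids <- c(sprintf("GRCh38_H%04d", seq_len(n_genes_per_species)),
                  sprintf("mm10_M%04d", seq_len(n_genes_per_species)))
    base <- stats::rlnorm(2L * n_genes_per_species, base_meanlog, base_sdlog)
    mu_by_type <- matrix(0, 2L * n_genes_per_species, 3L,
                         dimnames = list(gene_ids, c("human", "mouse", "collision")))
    hsel <- seq_len(n_genes_per_species)
    msel <- n_genes_per_species + hsel
    mu_by_type[hsel, "human"] <- base[hsel]
    mu_by_type[msel, "mouse"] <- base[msel]
    mu_by_type[, "collision"] <- mu_by_type[, "human"] / 2 + mu_by_type[, "mouse"] / 2
    counts <- nb_counts_by_type(truth_species, mu_by_type, dispersion)
    list(cells = cells, gene_ids = gene_ids, base = base,
         truth_species = truth_species, counts = counts)
  })
  cell_ids <- paste0(sim$cells$spatial_barcode, "-", sim$cells$pcr_index)
  gene_meta <- data.frame(gene_id = sim$gene_ids,
                          species = gene_species(sim$gene_ids),
                          is_mito = FALSE, stringsAsFactors = FALSE)
  cell_meta <- data.frame(cell_id = cell_ids,
                          spatial_barcode = sim$cells$spatial_barcode,
                          pcr_index = sim$cells$pcr_index,
                          well_id = sim$cells$well_id,
                          row = sim$cells$row, col = sim$cells$col,
                          stringsAsFactors = FALSE)
  counts <- Matrix::Matrix(sim$counts, sparse = TRUE,
                           dimnames = list(cell_ids, sim$gene_ids))
  cell_meta <- recompute_species_meta(counts, cell_meta, gene_meta)
  x <- spatial_counts(counts, cell_meta, gene_meta)
  truth <- list(cells = data.frame(cell_id = cell_ids,
                                   well_id = sim$cells$well_id,
                                   species = sim$truth_species,
                                   stringsAsFactors = FALSE))
  list(counts = x, truth = truth, array = array, pcr_whitelist = pcr,
       design = grad)
}

#' Plant ambient contamination into a count matrix
#'
#' Emulates the generative model of [fit_decontamination()]: each cell
#' draws a contamination proportion `theta ~ Beta(alpha, beta)`, and that
#' fraction of its transcripts (rounded) is removed (uniformly over its
#' molecules) and replaced by draws from the pooled profile of the other
#' populations, preserving the cell's total counts.
#'
#' @param x a `spatial_counts`.
#' @param clusters per-cell population labels defining "other" profiles
#'   (default: the species call in `cell_meta`).
#' @param alpha,beta Beta parameters (default 2, 8: mean 0.2).
#' @param seed RNG seed.
#' @return list with `counts` (contaminated `spatial_counts`),
#'   `theta` (realized per-cell contamination fraction) and `theta_drawn`.
#' @export
inject_ambient <- function(x, clusters = NULL, alpha = 2, beta = 8, seed = 1L) {
  stopifnot(inherits(x, "spatial_counts"))
  if (is.null(clusters)) clusters <- x$cell_meta$species
  clusters <- factor(clusters)
  stopifnot(length(clusters) == nrow(x$counts), nlevels(clusters) >= 2L)
  M <- as.matrix(x$counts)
  n_cells <- nrow(M); n_genes <- ncol(M)
  cl_tot <- rowsum(M, clusters)          # clusters x genes
  cl_mass <- rowSums(cl_tot)
  out <- with_seed(seed, {
    theta_drawn <- stats::rbeta(n_cells, alpha, beta)
    theta_real <- numeric(n_cells)
    for (c in seq_len(n_cells)) {
      N <- sum(M[c, ])
      if (N == 0) next
      n_move <- round(theta_drawn[c] * N)
      if (n_move == 0) next
      k <- as.integer(clusters[c])
      pool <- colSums(cl_tot[-k, , drop = FALSE])
      if (sum(pool) == 0) next
      expanded <- rep.int(seq_len(n_genes), M[c, ])
      removed <- tabulate(sample(expanded, n_move, replace = FALSE), n_genes)
      added <- as.integer(stats::rmultinom(1L, n_move, pool))
      M[c, ] <- M[c, ] - removed + added
      theta_real[c] <- n_move / N
    }
    list(M = M, theta_drawn = theta_drawn, theta_real = theta_real)
  })
  counts <- Matrix::Matrix(out$M, sparse = TRUE, dimnames = dimnames(x$counts))
  cm <- x$cell_meta
  if ("species" %in% names(cm))
    cm <- recompute_species_meta(counts, cm, x$gene_meta)
  list(counts = spatial_counts(counts, cm, x$gene_meta),
       theta = stats::setNames(out$theta_real, rownames(M)),
       theta_drawn = stats::setNames(out$theta_drawn, rownames(M)))
}

mutate_seqs <- function(seqs, error_rate) {
  if (error_rate <= 0 || !length(seqs)) return(seqs)
  L <- nchar(seqs[1L])
  n_err <- stats::rbinom(length(seqs), L, error_rate)
  hit <- which(n_err > 0)
  if (!length(hit)) return(seqs)
  chars <- matrix(unlist(strsplit(seqs[hit], "", fixed = TRUE), use.names = FALSE),
                  nrow = length(hit), byrow = TRUE)
  rid <- rep(seq_along(hit), n_err[hit])
  pos <- sample.int(L, length(rid), replace = TRUE)
  idx <- cbind(rid, pos)
  old <- chars[idx]
  shift <- sample.int(3L, length(rid), replace = TRUE)
  chars[idx] <- DNA_BASES[(match(old, DNA_BASES) - 1L + shift) %% 4L + 1L]
  seqs[hit] <- apply(chars, 1L, paste0, collapse = "")
  seqs
}

write_fastq <- function(seqs, names, path, gzip = FALSE) {
  qual <- Biostrings::PhredQuality(strrep("I", nchar(seqs)))
  x <- Biostrings::QualityScaledDNAStringSet(Biostrings::DNAStringSet(seqs), qual)
  names(x) <- names
  Biostrings::writeQualityScaledXStringSet(x, path, compress = gzip)
  path
}

#' Emit synthetic FASTQ reads for a count matrix
#'
#' Serializes every molecule of a (simulated) count matrix into the
#' four-file library layout: read 1 (26 nt: 10-nt UMI + 16-nt spatial
#' barcode), read 2 (98 nt cDNA whose leading 12 nt carry the synthetic
#' gene tag, see [read_tagged_fastq()]), index read 1 (library index) and
#' index read 2 (i5 PCR index). Each molecule receives a distinct UMI
#' within its (cell, gene); the number of reads per molecule follows a
#' shifted geometric law parameterized by the sequencing `saturation`
#' (default 0.46, i.e. 1 - UMIs/reads = 0.46), and per-base substitution
#' errors at `error_rate` are applied to read 1 (gene assignment emulates
#' the delegated aligner and is emitted error-free).
#'
#' @param x a `spatial_counts` whose `cell_meta` carries `spatial_barcode`
#'   and `pcr_index`.
#' @param dir output directory.
#' @param error_rate per-base substitution probability on read 1.
#' @param saturation sequencing saturation in `[0, 1)`; 0 = one read per
#'   molecule.
#' @param r2_len read-2 length.
#' @param prefix file-name prefix.
#' @param gzip write gzip-compressed FASTQ.
#' @param seed RNG seed.
#' @return Named list of the four FASTQ paths (`r1`, `r2`, `i1`, `i2`),
#'   invisibly.
#' @export
emit_fastq <- function(x, dir, error_rate = 0, saturation = 0.46,
                       r2_len = 98L, prefix = "sim", gzip = FALSE, seed = 1L) {
  stopifnot(inherits(x, "spatial_counts"),
            all(c("spatial_barcode", "pcr_index") %in% names(x$cell_meta)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- Matrix::summary(x$counts)
  mol_cell <- rep.int(tr$i, tr$x)
  mol_gene <- rep.int(tr$j, tr$x)
  n_mol <- length(mol_cell)
  paths <- with_seed(seed, {
    umi <- random_dna(n_mol, 10L)
    key <- paste(mol_cell, mol_gene)
    repeat {
      dup <- duplicated(paste(key, umi))
      if (!any(dup)) break
      umi[dup] <- random_dna(sum(dup), 10L)
    }
    reads_per_mol <- if (saturation > 0) {
      1L + stats::rgeom(n_mol, prob = 1 - saturation)
    } else rep(1L, n_mol)
    ridx <- rep.int(seq_len(n_mol), reads_per_mol)
    n_reads <- length(ridx)
    perm <- sample.int(n_reads)  # shuffle reads as a sequencer would
    ridx <- ridx[perm]
    bc <- x$cell_meta$spatial_barcode[mol_cell[ridx]]
    r1 <- mutate_seqs(paste0(umi[ridx], bc), error_rate)
    tag <- encode_gene_tag(seq_len(ncol(x$counts)))
    tails <- random_dna(ncol(x$counts), r2_len - nchar(tag[1L]))
    r2 <- paste0(tag[mol_gene[ridx]], tails[mol_gene[ridx]])
    i1 <- rep(random_dna(1L, 8L), n_reads)
    i2 <- x$cell_meta$pcr_index[mol_cell[ridx]]
    ids <- sprintf("%s:%08d", prefix, seq_len(n_reads))
    ext <- if (gzip) ".fastq.gz" else ".fastq"
    list(r1 = write_fastq(r1, ids, file.path(dir, paste0(prefix, "_R1", ext)), gzip),
         r2 = write_fastq(r2, ids, file.path(dir, paste0(prefix, "_R2", ext)), gzip),
         i1 = write_fastq(i1, ids, file.path(dir, paste0(prefix, "_I1", ext)), gzip),
         i2 = write_fastq(i2, ids, file.path(dir, paste0(prefix, "_I2", ext)), gzip))
  })
  invisible(paths)
}
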