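#' Split read 1 into UMI and spatial barcode
#'
#' Read 1 of the library is sequenced for 26 cycles and is pure barcode
#' chemistry: positions 1-10 carry the UMI and positions 11-26 the 16-nt
#' spatial barcode of the microwell's RT primer. Longer reads are truncated;
#' reads shorter than `umi_len + barcode_len` are flagged and skipped by the
#' caller.
#'
#' @param seq character vector of read-1 sequences.
#' @param umi_len,barcode_len split lengths (defaults 10 and 16).
#' @return data.frame with columns `umi`, `spatial_barcode`, `ok` (logical,
#'   FALSE for too-short reads, whose umi/barcode are NA).
#' @export
parse_read1 <- function(seq, umi_len = 10L, barcode_len = 16L) {
  need <- umi_len + barcode_len
  ok <- !is.na(seq) & nchar(seq) >= need
  umi <- ifelse(ok, substr(seq, 1L, umi_len), NA_character_)
  bc <- ifelse(ok, substr(seq, umi_len + 1L, need), NA_character_)
  data.frame(umi = umi, spatial_barcode = bc, ok = ok, stringsAsFactors = FALSE)
}

dna_int_matrix <- function(x, width) {
  matrix(utf8ToInt(paste0(x, collapse = "")), ncol = width, byrow = TRUE)
}

#' Correct observed barcodes against a whitelist
#'
#' Exact matches are accepted; otherwise a barcode is corrected to the
#' unique whitelist entry within `max_hamming` substitutions. If no entry or
#' more than one entry lies within the tolerance the barcode is unassigned
#' (`NA`) -- ambiguity is never guessed. With whitelists at pairwise Hamming
#' distance >= 3 (as produced by [make_well_array()]), single-error
#' correction is always unambiguous.
#'
#' @param observed character vector of observed barcodes (all same width).
#' @param whitelist character vector of valid barcodes, pairwise distinct.
#' @param max_hamming maximum substitutions to correct (default 1; 0 =
#'   exact matching only).
#' @return Integer vector: index into `whitelist`, or NA if unassigned.
#' @export
correct_barcodes <- function(observed, whitelist, max_hamming = 1L) {
  if (anyDuplicated(whitelist)) stop("whitelist barcodes must be distinct")
  width <- unique(nchar(whitelist))
  stopifnot(length(width) == 1)
  idx <- match(observed, whitelist)
  if (max_hamming < 1L) return(idx)
  todo <- which(is.na(idx) & !is.na(observed) & nchar(observed) == width)
  if (!length(todo)) return(idx)
  uq <- unique(observed[todo])
  wl <- dna_int_matrix(whitelist, width)
  qm <- dna_int_matrix(uq, width)
  hit <- rep(NA_integer_, length(uq))
  chunk <- 512L
  for (s in seq(1L, length(uq), by = chunk)) {
    e <- min(s + chunk - 1L, length(uq))
    rows <- s:e
    D <- matrix(0L, length(rows), nrow(wl))
    for (j in seq_len(width))
      D <- D + outer(qm[rows, j], wl[, j], "!=")
    within <- D <= max_hamming
    nhit <- rowSums(within)
    one <- nhit == 1L
    hit[rows[one]] <- max.col(within[one, , drop = FALSE], ties.method = "first")
  }
  idx[todo] <- hit[match(observed[todo], uq)]
  idx
}

#' Combinatorial barcode capacity
#'
#' The number of distinct single-cell barcodes addressable by two rounds of
#' split-pool indexing: spatial RT barcodes times PCR well indices (e.g.
#' 768 x 384 = 294,912).
#'
#' @param spatial a `well_array` or the number of spatial barcodes.
#' @param pcr a character vector of PCR indices or their number.
#' @return Integer count of addressable cell barcodes.
#' @export
barcode_capacity <- function(spatial, pcr) {
  ns <- if (inherits(spatial, "well_array")) nrow(spatial$wells) else as.integer(spatial)
  np <- if (is.character(pcr)) length(pcr) else as.integer(pcr)
  ns * np
}

gene_species <- function(gene_id, species_prefixes = c(human = "GRCh38_", mouse = "mm10_")) {
  out <- rep(NA_character_, length(gene_id))
  for (sp in names(species_prefixes))
    out[startsWith(gene_id, species_prefixes[[sp]])] <- sp
  out
}

is_mito_gene <- function(gene_id, mito_prefixes = c("mt-", "MT-")) {
  sym <- sub("^[^_]*_", "", gene_id)
  Reduce(`|`, lapply(mito_prefixes, function(p) startsWith(sym, p)))
}

#' Build a spatially annotated count matrix from gene-tagged reads
#'
#' Consumes gene-tagged reads (alignment and gene assignment are delegated
#' upstream), demultiplexes the combinatorial barcode, UMI-deduplicates, and
#' tallies molecules into a sparse cells x genes matrix. A cell is a
#' distinct (spatial barcode, PCR index) pair; its well of origin follows
#' from the spatial barcode via the well map. One molecule is counted per
#' distinct (cell, gene, UMI) triple.
#'
#' @param reads data.frame with columns `read1_seq`, `pcr_index`, `gene_id`
#'   (NA for reads without a gene assignment).
#' @param array a `well_array` providing the spatial-barcode whitelist.
#' @param pcr_whitelist character vector of valid PCR (i5) indices.
#' @param max_hamming spatial-barcode correction tolerance (see
#'   [correct_barcodes()]).
#' @param genes optional gene universe for the output columns (defaults to
#'   the sorted genes observed).
#' @param species_prefixes named character vector mapping species to gene-id
#'   namespace prefixes of the joint reference.
#' @param mito_prefixes gene-symbol prefixes marking mitochondrial genes.
#' @param species_threshold majority fraction for the per-cell species call
#'   (see [call_species()]).
#' @return A `spatial_counts` with a `demux_report` attribute: a data.frame
#'   tallying reads in, too-short reads, barcode-corrected reads, discarded
#'   reads (by reason), UMIs out, and sequencing saturation
#'   (1 - UMIs / assigned reads).
#' @export
build_count_matrix <- function(reads, array, pcr_whitelist, max_hamming = 1L,
                               genes = NULL,
                               species_prefixes = c(human = "GRCh38_", mouse = "mm10_"),
                               mito_prefixes = c("mt-", "MT-"),
                               species_threshold = 0.66) {
  stopifnot(inherits(array, "well_array"),
            all(c("read1_seq", "pcr_index", "gene_id") %in% names(reads)))
  n_in <- nrow(reads)
  p <- parse_read1(reads$read1_seq)
  n_short <- sum(!p$ok)
  keep <- p$ok
  bc_idx <- rep(NA_integer_, n_in)
  bc_idx[keep] <- correct_barcodes(p$spatial_barcode[keep],
                                   array$wells$spatial_barcode, max_hamming)
  n_corrected <- sum(keep & !is.na(bc_idx) &
                       p$spatial_barcode != array$wells$spatial_barcode[bc_idx],
                     na.rm = TRUE)
  n_bc_fail <- sum(keep & is.na(bc_idx))
  keep <- keep & !is.na(bc_idx)
  pcr_ok <- reads$pcr_index %in% pcr_whitelist
  n_pcr_fail <- sum(keep & !pcr_ok)
  keep <- keep & pcr_ok
  has_gene <- !is.na(reads$gene_id) & nzchar(reads$gene_id)
  n_unassigned <- sum(keep & !has_gene)
  keep <- keep & has_gene

  n_assigned <- sum(keep)
  if (!n_assigned) stop("no reads survive demultiplexing")
  well <- array$wells$well_id[bc_idx[keep]]
  cell <- paste0(array$wells$spatial_barcode[bc_idx[keep]], "-", reads$pcr_index[keep])
  gene <- reads$gene_id[keep]
  umi <- p$umi[keep]

  mol_key <- paste(cell, gene, umi, sep = "\r")
  first <- !duplicated(mol_key)
  cell <- cell[first]; gene <- gene[first]; well <- well[first]
  n_umis <- sum(first)

  cell_ids <- sort(unique(cell))
  gene_ids <- if (is.null(genes)) sort(unique(gene)) else genes
  gi <- match(gene, gene_ids)
  if (anyNA(gi)) stop("reads carry gene ids outside the supplied gene universe")
  ci <- match(cell, cell_ids)
  counts <- Matrix::sparseMatrix(i = ci, j = gi, x = 1,
                                 dims = c(length(cell_ids), length(gene_ids)),
                                 dimnames = list(cell_ids, gene_ids))

  gene_meta <- data.frame(gene_id = gene_ids,
                          species = gene_species(gene_ids, species_prefixes),
                          is_mito = is_mito_gene(gene_ids, mito_prefixes),
                          stringsAsFactors = FALSE)
  cw <- well[match(cell_ids, cell)]
  wi <- well_index(array, cw)
  sp_counts <- cbind(
    human = Matrix::rowSums(counts[, which(gene_meta$species %in% "human"), drop = FALSE]),
    mouse = Matrix::rowSums(counts[, which(gene_meta$species %in% "mouse"), drop = FALSE]))
  mito <- Matrix::rowSums(counts[, which(gene_meta$is_mito), drop = FALSE])
  tot <- Matrix::rowSums(counts)
  cell_meta <- data.frame(
    cell_id = cell_ids,
    spatial_barcode = sub("-[^-]*$", "", cell_ids),
    pcr_index = sub("^.*-", "", cell_ids),
    well_id = cw, row = array$wells$row[wi], col = array$wells$col[wi],
    human_umis = sp_counts[, "human"], mouse_umis = sp_counts[, "mouse"],
    species = call_species(sp_counts[, "human"], sp_counts[, "mouse"],
                           threshold = species_threshold),
    mito_frac = ifelse(tot > 0, mito / tot, 0),
    stringsAsFactors = FALSE)

  x <- spatial_counts(counts, cell_meta, gene_meta)
  attr(x, "demux_report") <- data.frame(
    reads_in = n_in, reads_too_short = n_short,
    barcode_corrected = n_corrected, barcode_unassigned = n_bc_fail,
    pcr_unassigned = n_pcr_fail, gene_unassigned = n_unassigned,
    reads_assigned = n_assigned, umis = n_umis,
    saturation = 1 - n_umis / n_assigned)
  x
}

#' Cell-level quality filters
#'
#' Retains cells with `umi_min <= total UMIs <= umi_max`,
#' `gene_min <= genes detected <= gene_max` and mitochondrial UMI fraction
#' `<= mito_max`. Defaults are the microwell-assay thresholds (500-10,000
#' UMIs, 100-15,000 genes, 1% mitochondrial); droplet data conventionally
#' uses wider bounds, which can be passed explicitly.
#'
#' @param x a `spatial_counts` (from [build_count_matrix()] or a simulator).
#' @param umi_min,umi_max inclusive per-cell UMI bounds.
#' @param gene_min,gene_max inclusive detected-gene bounds.
#' @param mito_max maximum mitochondrial fraction (inclusive).
#' @return The filtered `spatial_counts`; warns (does not error) if no cell
#'   survives.
#' @export
filter_cells <- function(x, umi_min = 500, umi_max = 10000,
                         gene_min = 100, gene_max = 15000, mito_max = 0.01) {
  stopifnot(inherits(x, "spatial_counts"))
  cm <- x$cell_meta
  mito <- if ("mito_frac" %in% names(cm)) cm$mito_frac else 0
  keep <- cm$total_umis >= umi_min & cm$total_umis <= umi_max &
    cm$genes_detected >= gene_min & cm$genes_detected <= gene_max &
    mito <= mito_max
  if (!any(keep)) warning("no cells pass the quality filters")
  subset_counts(x, cells = which(keep))
}

# --- synthetic gene-tag codec -------------------------------------------------
# Gene identity for the aligner-free test path is carried in the first
# `width` nt of read 2 as a base-4 (A,C,G,T) big-endian encoding of the
# gene's index in the feature table.

encode_gene_tag <- function(idx, width = 12L) {
  stopifnot(all(idx >= 1), all(idx <= 4^width))
  v <- idx - 1
  digits <- matrix(0L, length(idx), width)
  for (k in width:1) {
    digits[, k] <- v %% 4
    v <- v %/% 4
  }
  apply(matrix(DNA_BASES[digits + 1L], ncol = width), 1L, paste0, collapse = "")
}

decode_gene_tag <- function(tag, n_genes, width = 12L) {
  m <- dna_int_matrix(tag, width)
  digit <- matrix(match(m, utf8ToInt(paste0(DNA_BASES, collapse = ""))) - 1L,
                  nrow = nrow(m))
  if (anyNA(digit)) digit[is.na(digit)] <- 99L  # non-ACGT -> out of range
  idx <- as.vector(digit %*% 4^((width - 1):0)) + 1
  idx[idx > n_genes | idx < 1] <- NA
  as.integer(idx)
}

#' Read synthetic FASTQ into gene-tagged reads
#'
#' Ingests the FASTQ files produced by [emit_fastq()]: read 1 (UMI +
#' spatial barcode), read 2 (whose leading bases encode the gene index under
#' the synthetic tag convention, standing in for alignment), and index read
#' 2 (the i5 PCR index). Returns the gene-tagged read table consumed by
#' [build_count_matrix()].
#'
#' @param r1,r2,i2 FASTQ paths (gzip allowed).
#' @param gene_ids the feature table defining gene indices.
#' @param tag_width width of the synthetic gene tag in read 2.
#' @return data.frame with columns `read1_seq`, `pcr_index`, `gene_id`.
#' @export
read_tagged_fastq <- function(r1, r2, i2, gene_ids, tag_width = 12L) {
  s1 <- as.character(Biostrings::readDNAStringSet(r1, format = "fastq"))
  s2 <- as.character(Biostrings::readDNAStringSet(r2, format = "fastq"))
  si <- as.character(Biostrings::readDNAStringSet(i2, format = "fastq"))
  stopifnot(length(s1) == length(s2), length(s1) == length(si))
  gi <- decode_gene_tag(substr(s2, 1L, tag_width), length(gene_ids), tag_width)
  data.frame(read1_seq = unname(s1), pcr_index = unname(si),
             gene_id = gene_ids[gi], stringsAsFactors = FALSE)
}
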