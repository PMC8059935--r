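write_manifest <- function(out_dir) {
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        c("manifest.tsv", "run.log")))  # log carries timestamps
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    bytes = file.size(file.path(out_dir, files)),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  manifest
}

persist_config <- function(config, out_dir) {
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))
  } else {
    dput(config, file.path(out_dir, "resolved_config.R"))
  }
}

log_msg <- function(con, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full synthetic-to-results pipeline
#'
#' End-to-end orchestration on simulated data: a mixed-species gradient
#' run (with planted collisions and ambient contamination) is
#' demultiplexed through the species QC and decontamination stages, and a
#' tumor-bearing tissue run flows through composition, proximity scoring,
#' gene-module discovery and proximity-associated differential expression.
#' Every stage writes its TSV/Matrix-Market artifacts under `out_dir`; the
#' run closes with a resolved-config copy, a `run.log`, and a
#' `manifest.tsv` of md5 checksums, so identical `(config, seed)` runs are
#' byte-reproducible.
#'
#' @param out_dir output directory (created).
#' @param seed master RNG seed.
#' @param design a [simulation_design()] for the tissue run.
#' @param barnyard_rows,barnyard_cells_per_well gradient-run size.
#' @param planted_collisions planted co-encapsulation rate.
#' @param ambient_alpha,ambient_beta Beta contamination parameters.
#' @param species_threshold majority rule for species calls.
#' @param nmf_rank,nmf_max_iter,top_n,min_frac gene-module parameters.
#' @param d,L proximity decay parameters.
#' @param fdr,n_knots differential-expression parameters.
#' @param de_cell_type cell type tested for proximity association.
#' @return Invisibly, a list of key results (collision rates, module set,
#'   association table, manifest).
#' @export
run_pipeline <- function(out_dir, seed = 1L, design = simulation_design(),
                         barnyard_rows = 24L, barnyard_cells_per_well = 8,
                         planted_collisions = 0.05, ambient_alpha = 2,
                         ambient_beta = 8, species_threshold = 0.66,
                         nmf_rank = 20L, nmf_max_iter = 100L,
                         top_n = 200L, min_frac = 0.25,
                         d = 1.05, L = 10L, fdr = 0.05, n_knots = 4L,
                         de_cell_type = "MSC") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)
  config <- list(seed = seed, design = unclass(design),
                 barnyard_rows = barnyard_rows,
                 barnyard_cells_per_well = barnyard_cells_per_well,
                 collision_rate = planted_collisions,
                 ambient_alpha = ambient_alpha, ambient_beta = ambient_beta,
                 species_threshold = species_threshold,
                 nmf_rank = nmf_rank, top_n = top_n, min_frac = min_frac,
                 d = d, L = L, fdr = fdr, n_knots = n_knots,
                 de_cell_type = de_cell_type,
                 version = as.character(utils::packageVersion("hexspat")))
  persist_config(config, out_dir)

  # --- mixed-species gradient: QC + decontamination ----------------------
  log_msg(logf, "simulating mixed-species gradient run")
  bn <- simulate_barnyard(n_rows = barnyard_rows,
                          cells_per_well = barnyard_cells_per_well,
                          collision_rate = planted_collisions, seed = seed)
  amb <- inject_ambient(bn$counts, clusters = bn$truth$cells$species,
                        alpha = ambient_alpha, beta = ambient_beta,
                        seed = seed + 1L)
  write_well_map(bn$array, file.path(out_dir, "barnyard_well_map.tsv"))
  write_counts(amb$counts, file.path(out_dir, "barnyard_raw"))
  rep_before <- barnyard_report(amb$counts, species_threshold)
  write_tsv(rep_before, file.path(out_dir, "barnyard_report.tsv"))
  rate_before <- collision_rate(rep_before$call)
  grad <- gradient_concordance(amb$counts)
  write_tsv(grad$columns, file.path(out_dir, "gradient_concordance.tsv"))
  log_msg(logf, sprintf("collision rate %.3f, gradient CCC %.3f",
                        rate_before, grad$ccc))
  majority <- ifelse(amb$counts$cell_meta$human_umis >=
                       amb$counts$cell_meta$mouse_umis, "human", "mouse")
  model <- fit_decontamination(amb$counts, majority, seed = seed)
  clean <- decontaminate(amb$counts, model, species_threshold)
  write_counts(clean, file.path(out_dir, "barnyard_decontaminated"))
  write_tsv(data.frame(cell_id = names(model$theta), theta = model$theta),
            file.path(out_dir, "contamination_theta.tsv"))
  write_tsv(contamination_summary(model),
            file.path(out_dir, "contamination_summary.tsv"))
  rate_after <- collision_rate(clean$cell_meta$species)
  log_msg(logf, sprintf("collision rate after decontamination %.3f", rate_after))

  # --- tissue run: spatial scores, modules, DE ---------------------------
  log_msg(logf, "simulating tissue run")
  ts <- simulate_tissue(design, seed = seed + 2L)
  write_well_map(ts$array, file.path(out_dir, "tissue_well_map.tsv"))
  tis <- filter_cells(ts$counts, umi_min = 0, umi_max = Inf,
                      gene_min = 0, gene_max = Inf, mito_max = 1)
  write_counts(tis, file.path(out_dir, "tissue_counts"))
  labels <- ts$truth$cells$cell_type
  comp <- well_composition(data.frame(well_id = tis$cell_meta$well_id,
                                      cell_type = labels), ts$array)
  comp_df <- cbind(comp$wells, as.data.frame(comp$counts))
  write_tsv(comp_df, file.path(out_dir, "composition.tsv"))
  field <- tumor_proximity(comp, ts$array, decay_weights(d, L))
  prox <- as.data.frame(field)
  prox$variant <- attr(field, "variant"); prox$d <- d; prox$L <- L
  write_tsv(prox, file.path(out_dir, "proximity.tsv"))
  sc <- cell_scores(field, tis$cell_meta$well_id)
  write_tsv(data.frame(cell_id = tis$cell_meta$cell_id,
                       well_id = tis$cell_meta$well_id, score = sc),
            file.path(out_dir, "cell_scores.tsv"))
  types <- colnames(comp$counts)
  pairs <- utils::combn(types, 2)
  coloc <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    cc <- colocalization(comp, pairs[1, i], pairs[2, i])
    data.frame(type_a = pairs[1, i], type_b = pairs[2, i],
               r = cc$r, p_value = cc$p_value, n_wells = cc$n_wells)
  }))
  write_tsv(coloc, file.path(out_dir, "colocalization.tsv"))

  log_msg(logf, "fitting gene modules")
  expr <- module_input(tis)
  mods <- fit_gene_modules(expr, rank = nmf_rank, seed = seed,
                           max_iter = nmf_max_iter, tissue_tag = "M")
  mod_rows <- do.call(rbind, lapply(seq_len(mods$rank), function(m) {
    top <- top_contributing_genes(mods, m)
    genes <- mods$sorted_genes[[m]]
    data.frame(gene = genes, module = colnames(mods$basis)[m],
               coefficient = mods$basis[genes, m],
               rank = seq_along(genes), is_top = genes %in% top,
               stringsAsFactors = FALSE)
  }))
  write_tsv(mod_rows, file.path(out_dir, "modules.tsv"))
  lognorm <- t(log1p(as.matrix(tis$counts) / pmax(tis$cell_meta$total_umis, 1) * 1e4))
  m1_top <- top_contributing_genes(mods, 1L)
  if (length(m1_top)) {
    proj <- project_module(lognorm, tis$cell_meta$well_id, m1_top, ts$array)
    proj$module <- colnames(mods$basis)[1L]
    write_tsv(proj, file.path(out_dir, "module_projection.tsv"))
  }

  log_msg(logf, "testing proximity-associated expression in ", de_cell_type)
  sel <- which(labels == de_cell_type & !is.na(sc))
  assoc <- NULL
  if (length(sel) >= 30L) {
    de <- proximity_association(subset_counts(tis, cells = sel),
                                sc[sel], n_knots = n_knots, fdr = fdr)
    assoc <- de$results
    write_tsv(assoc, file.path(out_dir, "association.tsv"))
    curves <- data.frame(gene = rownames(de$curves), de$curves,
                         check.names = FALSE)
    write_tsv(curves, file.path(out_dir, "fitted_curves.tsv"))
  } else {
    log_msg(logf, "too few scored ", de_cell_type, " cells; DE stage skipped")
  }
  manifest <- write_manifest(out_dir)
  log_msg(logf, "done: ", nrow(manifest), " artifacts")
  invisible(list(collision_before = rate_before, collision_after = rate_after,
                 gradient_ccc = grad$ccc, modules = mods,
                 association = assoc, manifest = manifest))
}
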