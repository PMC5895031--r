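# Stage orchestration: each run_* function chains one pipeline stage end
# to end and writes machine-readable reports (TSV + JSON) to an output
# directory. Reruns with the same inputs are byte-identical; the resolved
# configuration is re-emitted next to the reports.

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

emit_config <- function(config, out_dir) {
  jsonlite::write_json(config, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the variant-triage stage
#'
#' Loads a predictor-panel TSV (eight tool columns, optional printed
#' consensus), applies consensus classification, protein-variant mapping,
#' multi-allelic residue detection, region enrichment and (optionally) a
#' conservation overlay, and writes the reports.
#'
#' @param panel_path Predictor table TSV (defaults to the packaged
#'   fixture).
#' @param out_dir Output directory (created if needed).
#' @param ranges Residue intervals for the enrichment report (default the
#'   two transmembrane stretches aa 44-65 and 133-150).
#' @param conservation Optional per-residue conservation track (1..9).
#' @param min_score Conservation cutoff (default 8).
#' @return Invisibly, a list with `results`, `concordance`, `enrichment`,
#'   `multiallelic` and (if requested) `conservation`.
#' @export
run_triage <- function(panel_path = tspo_panel_path(), out_dir,
                       ranges = rbind(c(44, 65), c(133, 150)),
                       conservation = NULL, min_score = 8) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- utils::read.delim(panel_path, stringsAsFactors = FALSE)
  cls <- classify_table(rows)
  pvs <- map_protein_variants(cls$results$mutation, cls$results$id)
  enr <- region_enrichment(cls$results, ranges)
  multi <- multiallelic_residues(pvs)
  write_tsv(cls$results, file.path(out_dir, "consensus_results.tsv"))
  write_tsv(enr$per_range, file.path(out_dir, "enrichment.tsv"))
  report <- list(
    n_variants = nrow(cls$results),
    n_deleterious = sum(cls$results$label == "D"),
    n_distinct_residues = length(unique(pvs$position)),
    multiallelic_positions = as.integer(names(multi)),
    enrichment_total = enr$total,
    concordance = if (!is.null(cls$concordance))
      list(n = cls$concordance$n, n_match = cls$concordance$n_match,
           mismatches = cls$concordance$mismatches))
  cons <- NULL
  if (!is.null(conservation)) {
    cons <- conservation_overlay(cls$results, conservation, min_score)
    report$conserved_deleterious <- cons$n_conserved
  }
  jsonlite::write_json(report, file.path(out_dir, "triage_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  emit_config(list(stage = "triage", panel_path = panel_path,
                   ranges = apply(ranges, 1, paste, collapse = "-"),
                   min_score = min_score), out_dir)
  invisible(list(results = cls$results, concordance = cls$concordance,
                 enrichment = enr, multiallelic = multi,
                 conservation = cons))
}

#' Run the codon-usage stage
#'
#' Profiles a CDS with relative-adaptiveness values and detects rare-codon
#' clusters.
#'
#' @param cds A DNA string, or a FASTA path via `fasta`.
#' @param fasta Optional FASTA path (first record used).
#' @param out_dir Output directory.
#' @param usage Codon-usage table (default the embedded human table).
#' @param window,threshold Cluster detection parameters (defaults 15
#'   codons, 40%).
#' @return Invisibly, a list with `profile` and `clusters`.
#' @export
run_codons <- function(cds = NULL, fasta = NULL, out_dir,
                       usage = human_codon_usage(), window = 15,
                       threshold = 40) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cds)) {
    if (is.null(fasta)) stop_input("provide cds or fasta")
    cds <- read_cds_fasta(fasta)
  }
  adapt <- relative_adaptiveness(usage)
  prof <- profile_cds(cds, adapt)
  clusters <- detect_rare_clusters(prof, window = window,
                                   threshold = threshold)
  write_tsv(prof, file.path(out_dir, "cds_profile.tsv"))
  write_tsv(clusters, file.path(out_dir, "rare_codon_clusters.tsv"))
  emit_config(list(stage = "codons", window = window, threshold = threshold),
              out_dir)
  invisible(list(profile = prof, clusters = clusters))
}

#' Run the trajectory-analytics stage
#'
#' Computes backbone RMSD, C-alpha RMSD, per-residue C-alpha RMSF and the
#' radius-of-gyration series for one or more systems, with
#' post-equilibration means +/- SD and pairwise significance flags between
#' systems, laid out like a structural-properties summary table.
#'
#' @param trajectories Named list of [trajectory()] objects or multi-model
#'   PDB paths (names = system labels, e.g. wt / mutant).
#' @param out_dir Output directory.
#' @param equil_start_ns Equilibration window start in ns (default 12).
#' @return Invisibly, a list with `stats` (per-system summary data frame)
#'   and `comparisons` (pairwise test results on post-equilibration
#'   backbone RMSD).
#' @export
run_traj <- function(trajectories, out_dir, equil_start_ns = 12) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trajs <- lapply(trajectories, function(t)
    if (inherits(t, "trajectory")) t else read_multimodel_pdb(t))
  if (is.null(names(trajs)))
    names(trajs) <- sprintf("system%d", seq_along(trajs))
  per_system <- lapply(names(trajs), function(nm) {
    tr <- trajs[[nm]]
    has_bb <- length(tryCatch(select_atoms(tr, "backbone"),
                              error = function(e) integer(0))) >
      length(select_atoms(tr, "calpha"))
    bb_sel <- if (has_bb) "backbone" else "calpha"
    rmsd_bb <- rmsd_series(tr, bb_sel)
    rmsd_ca <- rmsd_series(tr, "calpha")
    rmsf <- rmsf_profile(tr, "calpha", equil_start_ns = equil_start_ns)
    rg <- rg_series(tr)
    st <- function(v) equilibrium_stats(v, tr$times_ps, equil_start_ns)
    s_bb <- st(rmsd_bb$rmsd); s_ca <- st(rmsd_ca$rmsd); s_rg <- st(rg$rg)
    write_tsv(rmsd_bb, file.path(out_dir, paste0(nm, "_rmsd_backbone.tsv")))
    write_tsv(rmsd_ca, file.path(out_dir, paste0(nm, "_rmsd_calpha.tsv")))
    write_tsv(rmsf, file.path(out_dir, paste0(nm, "_rmsf.tsv")))
    write_tsv(rg, file.path(out_dir, paste0(nm, "_rg.tsv")))
    list(system = nm,
         backbone_rmsd = s_bb, calpha_rmsd = s_ca,
         calpha_rmsf = list(mean = mean(rmsf$rmsf), sd = stats::sd(rmsf$rmsf)),
         rg = s_rg,
         post_equil_rmsd = rmsd_bb$rmsd[rmsd_bb$time_ps >=
                                          equil_start_ns * 1000])
  })
  names(per_system) <- names(trajs)
  stats_df <- do.call(rbind, lapply(per_system, function(s)
    data.frame(system = s$system,
               backbone_rmsd_mean = s$backbone_rmsd$mean,
               backbone_rmsd_sd = s$backbone_rmsd$sd,
               calpha_rmsd_mean = s$calpha_rmsd$mean,
               calpha_rmsd_sd = s$calpha_rmsd$sd,
               calpha_rmsf_mean = s$calpha_rmsf$mean,
               calpha_rmsf_sd = s$calpha_rmsf$sd,
               rg_mean = s$rg$mean, rg_sd = s$rg$sd)))
  comparisons <- list()
  nms <- names(per_system)
  if (length(nms) > 1) for (i in 1:(length(nms) - 1))
    for (j in (i + 1):length(nms)) {
      cmp <- compare_groups(per_system[[i]]$post_equil_rmsd,
                            per_system[[j]]$post_equil_rmsd)
      comparisons[[paste(nms[i], nms[j], sep = "_vs_")]] <- cmp
    }
  write_tsv(stats_df, file.path(out_dir, "traj_stats.tsv"))
  jsonlite::write_json(
    list(equil_start_ns = equil_start_ns,
         stats = stats_df, comparisons = comparisons),
    file.path(out_dir, "traj_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  emit_config(list(stage = "traj", equil_start_ns = equil_start_ns),
              out_dir)
  invisible(list(stats = stats_df, comparisons = comparisons))
}

#' Run the chase-kinetics stage
#'
#' Normalizes one or more cycloheximide-chase tables, fits first-order
#' decay per genotype, and reports percent half-life changes against a
#' designated reference genotype.
#'
#' @param tables Named list of chase data frames (or TSV paths) keyed by
#'   genotype; the first entry is the reference unless `reference` names
#'   another.
#' @param out_dir Output directory.
#' @param reference Name of the reference genotype.
#' @return Invisibly, a list with `fits`, `normalized` and `changes`.
#' @export
run_chase <- function(tables, out_dir, reference = names(tables)[1]) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- lapply(tables, function(t)
    if (is.data.frame(t)) t else utils::read.delim(t,
                                                   stringsAsFactors = FALSE))
  normalized <- lapply(tabs, normalize_chase)
  fits <- lapply(normalized, fit_decay)
  for (nm in names(tabs)) {
    write_tsv(normalized[[nm]]$points,
              file.path(out_dir, paste0(nm, "_normalized.tsv")))
  }
  changes <- lapply(setdiff(names(tabs), reference), function(nm)
    c(list(genotype = nm), compare_halflife(fits[[reference]], fits[[nm]])))
  names(changes) <- setdiff(names(tabs), reference)
  jsonlite::write_json(
    list(reference = reference,
         fits = lapply(fits, function(f)
           list(k_per_h = f$k, half_life_h = f$half_life,
                detectable = f$detectable,
                k_ci = as.list(f$k_ci), residual_sd = f$residual_sd)),
         percent_changes = changes),
    file.path(out_dir, "chase_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  emit_config(list(stage = "chase", reference = reference), out_dir)
  invisible(list(fits = fits, normalized = normalized, changes = changes))
}
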