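#' Pipeline configuration
#'
#' Defaults reproduce the standard settings of the analysis: 0.97/400
#' clustering, 999 ANOSIM and 5000 Mantel permutations, Euclidean-degree
#' geographic distances.
#'
#' @param cluster A [cluster_config()].
#' @param aligned Treat input residues as rows of one multiple alignment.
#' @param n_permutations_anosim,n_permutations_mantel Permutation counts.
#' @param geo_mode `"euclidean_degrees"` or `"haversine_km"`.
#' @param nmds_restarts Random restarts for the ordinations.
#' @param seed Seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cluster = cluster_config(), aligned = FALSE,
                            n_permutations_anosim = 999,
                            n_permutations_mantel = 5000,
                            geo_mode = "euclidean_degrees",
                            nmds_restarts = 20, seed = 1) {
  structure(list(cluster = cluster, aligned = aligned,
                 n_permutations_anosim = n_permutations_anosim,
                 n_permutations_mantel = n_permutations_mantel,
                 geo_mode = geo_mode, nmds_restarts = nmds_restarts,
                 seed = seed),
            class = "pipeline_config")
}

#' Run the full reverse-taxonomy analysis
#'
#' Per taxon group present in the records: pseudogene screen, greedy MOTU
#' clustering, station-by-MOTU abundance matrix and partition summary,
#' p-distance matrix and neighbor-joining tree, unweighted UniFrac and
#' cosine-similarity matrices over stations, nMDS ordinations, ANOSIM over
#' license areas, the Mantel battery (cosine and UniFrac vs geographic
#' distance, cosine vs UniFrac), richness estimators per license area, and
#' concordance against morpho-labels where available. Stations with no
#' sequences of a group are dropped from that group's community analyses
#' with a warning.
#'
#' @param records Sequence record table with `taxon_group` and `station_id`
#'   filled.
#' @param stations Station table ([read_station_table()] format).
#' @param config A [pipeline_config()].
#' @return A `revtax_results` list: one element per taxon group plus
#'   `pooled_richness` and a `manifest` recording configuration and seeds.
#' @export
run_pipeline <- function(records, stations, config = pipeline_config()) {
  stopifnot(nrow(records) > 0, nrow(stations) > 0)
  if (anyNA(records$station_id)) stop("records without station_id")
  unknown <- setdiff(records$station_id, stations$station_id)
  if (length(unknown)) stop("records at unknown station(s): ",
                            paste(unknown, collapse = ", "))
  area_map <- stats::setNames(stations$license_area, stations$station_id)
  geo <- geographic_distance_matrix(stations, config$geo_mode)
  groups <- unique(records$taxon_group)
  results <- list()
  pooled <- list()
  for (grp in groups) {
    rec <- records[records$taxon_group == grp, , drop = FALSE]
    screened <- screen_pseudogenes(rec)
    motus <- greedy_cluster(screened$pass, config$cluster,
                            aligned = config$aligned)
    sample_map <- stats::setNames(screened$pass$station_id,
                                  screened$pass$id)
    cm <- build_abundance_matrix(motus, sample_map)
    summary <- summarize_motus(motus, sample_map, area_map)

    pdm <- build_distance_matrix(screened$pass, metric = "p",
                                 aligned = config$aligned)
    tree <- neighbor_joining(pdm)
    incidence <- data.frame(tip_id = screened$pass$id,
                            sample_id = screened$pass$station_id,
                            stringsAsFactors = FALSE)
    uf <- unifrac_matrix(tree, incidence)
    cos <- cosine_similarity_matrix(cm[rowSums(cm) > 0, , drop = FALSE])
    common <- intersect(rownames(uf), rownames(cos))
    uf <- uf[common, common]
    cos <- cos[common, common]
    geo_g <- geo[common, common]

    nmds_uf <- nmds(uf, n_restarts = config$nmds_restarts,
                    seed = config$seed)
    nmds_cos <- nmds(sim_to_dist(cos), n_restarts = config$nmds_restarts,
                     seed = config$seed)
    anosim_uf <- anosim(uf, area_map,
                        n_permutations = config$n_permutations_anosim,
                        seed = config$seed)
    anosim_cos <- anosim(sim_to_dist(cos), area_map,
                         n_permutations = config$n_permutations_anosim,
                         seed = config$seed)
    np <- config$n_permutations_mantel
    mantel_tab <- list(
      cos_vs_geo = mantel(cos, geo_g, np, seed = config$seed),
      unifrac_vs_geo = mantel(uf, geo_g, np, seed = config$seed),
      cos_vs_unifrac = mantel(cos, uf, np, seed = config$seed))

    richness <- richness_table(cm, area_map)
    conc <- if (!all(is.na(screened$pass$morpho_label))) {
      labels <- stats::setNames(screened$pass$morpho_label,
                                screened$pass$id)
      suppressWarnings(compare_partitions(motus, labels))
    } else NULL

    results[[grp]] <- list(
      n_input = nrow(rec), n_screened_out = nrow(screened$fail),
      motus = motus, summary = summary, abundance = cm,
      p_distance_matrix = pdm, tree = tree,
      unifrac = uf, cosine = cos,
      nmds_unifrac = nmds_uf, nmds_cosine = nmds_cos,
      anosim_unifrac = anosim_uf, anosim_cosine = anosim_cos,
      mantel = mantel_tab, richness = richness, concordance = conc)
    pooled[[grp]] <- cm
  }
  pooled_cm <- pool_abundance_(pooled)
  structure(list(
    groups = results,
    pooled_richness = richness_table(pooled_cm, area_map),
    manifest = list(config = config, taxon_groups = groups,
                    n_records = nrow(records),
                    n_stations = nrow(stations),
                    timestamp = NA, package_version =
                      as.character(utils::packageVersion("revtax")))),
    class = "revtax_results")
}

# Bind per-group station-by-MOTU matrices column-wise on the union of stations.
pool_abundance_ <- function(cms) {
  stations <- sort(unique(unlist(lapply(cms, rownames))))
  blocks <- lapply(names(cms), function(g) {
    m <- matrix(0L, length(stations), ncol(cms[[g]]),
                dimnames = list(stations,
                                paste0(g, "_", colnames(cms[[g]]))))
    m[rownames(cms[[g]]), ] <- cms[[g]]
    m
  })
  do.call(cbind, blocks)
}

#' Write a results bundle to a directory
#'
#' Emits, per taxon group, the MOTU tables, distance/similarity matrices
#' (square TSV), the newick tree, ordination coordinates, a permutation
#' test summary, the richness table and the concordance report, plus a
#' `manifest.txt` recording the configuration and seed.
#'
#' @param results A `revtax_results` from [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results_bundle <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f) utils::write.table(
    cbind(id = rownames(m), as.data.frame(m)), file.path(dir, f),
    sep = "\t", quote = FALSE, row.names = FALSE)
  for (grp in names(results$groups)) {
    g <- results$groups[[grp]]
    write_motu_table(g$motus, file.path(dir, paste0(grp, "_motus")))
    wm(g$abundance, paste0(grp, "_abundance.tsv"))
    wm(g$unifrac, paste0(grp, "_unifrac.tsv"))
    wm(g$cosine, paste0(grp, "_cosine.tsv"))
    wm(g$nmds_unifrac$coordinates, paste0(grp, "_nmds_unifrac.tsv"))
    wm(g$nmds_cosine$coordinates, paste0(grp, "_nmds_cosine.tsv"))
    write_newick(g$tree, file.path(dir, paste0(grp, "_nj.nwk")))
    utils::write.table(g$richness, file.path(dir, paste0(grp, "_richness.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tests <- data.frame(
      test = c("anosim_unifrac", "anosim_cosine", names(g$mantel)),
      statistic = c(g$anosim_unifrac$statistic, g$anosim_cosine$statistic,
                    vapply(g$mantel, `[[`, 0, "statistic")),
      p_value = c(g$anosim_unifrac$p_value, g$anosim_cosine$p_value,
                  vapply(g$mantel, `[[`, 0, "p_value")))
    utils::write.table(tests, file.path(dir, paste0(grp, "_tests.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(g$concordance)) {
      utils::write.table(g$concordance$verdicts,
                         file.path(dir, paste0(grp, "_concordance.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  utils::write.table(results$pooled_richness,
                     file.path(dir, "pooled_richness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- results$manifest$config
  writeLines(c(
    paste0("revtax ", results$manifest$package_version),
    paste0("taxon_groups: ",
           paste(results$manifest$taxon_groups, collapse = ", ")),
    paste0("n_records: ", results$manifest$n_records),
    paste0("threshold: ", cfg$cluster$threshold),
    paste0("min_overlap: ", cfg$cluster$min_overlap),
    paste0("permutations_anosim: ", cfg$n_permutations_anosim),
    paste0("permutations_mantel: ", cfg$n_permutations_mantel),
    paste0("geo_mode: ", cfg$geo_mode),
    paste0("seed: ", cfg$seed)), file.path(dir, "manifest.txt"))
  invisible(dir)
}
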