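# Pipeline orchestration: one declarative configuration drives the stages
# quantify -> preprocess -> diffexpr -> network -> enrich -> traits ->
# overlap, each writing TSV outputs plus a JSON run manifest recording
# parameters, input hashes and the seed. Re-running an unchanged
# configuration reproduces byte-identical numeric outputs.

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed integer seed used by every stochastic stage.
#' @return nested configuration list; see [run_pipeline].
#' @export
default_config <- function(out_dir = "wpcna_out", seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    paths = list(peptides = NULL, protein_matrix = NULL, traits = NULL,
                 gene_sets = NULL, reference_partition = NULL),
    simulate = NULL,                     # a synthetic_spec to simulate inputs
    stages = list(quantify = TRUE, preprocess = TRUE, diffexpr = TRUE,
                  network = TRUE, enrich = TRUE, traits = TRUE,
                  overlap = TRUE),
    quantify = list(min_unique = 1L, min_spectra = 2L, log2 = TRUE),
    regression = list(covariates = c("age", "sex", "pmi"),
                      n_bootstrap = 1000L),
    diffexpr = list(alpha = 0.05),
    network = list(beta = 11.5, deep_split = 4L, min_module_size = 20L,
                   tom_denom = "mean", cor_method = "bicor", signed = TRUE,
                   merge_cut_height = 0.07, reassign_p = 0.05,
                   pam_respects_dendro = TRUE),
    traits = list(trait_columns = c("diagnosis", "casi", "cerad", "braak"),
                  diagnosis_coding = "ordinal")
  )
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [default_config].
#' @return configuration list merged over the defaults.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user)
}

# validate a configuration before any compute
validate_config <- function(config) {
  nw <- config$network
  # constructing the params object applies every bound check
  params <- network_params(beta = nw$beta, deep_split = nw$deep_split,
                           min_module_size = nw$min_module_size,
                           tom_denom = nw$tom_denom,
                           cor_method = nw$cor_method, signed = nw$signed,
                           merge_cut_height = nw$merge_cut_height,
                           reassign_p = nw$reassign_p,
                           pam_respects_dendro = nw$pam_respects_dendro)
  if (is.null(config$seed)) stopf("config must carry a seed")
  a <- config$diffexpr$alpha
  if (a <= 0 || a >= 1) stopf("diffexpr alpha must lie in (0, 1)")
  if (config$regression$n_bootstrap < 1) stopf("n_bootstrap must be >= 1")
  if (is.null(config$simulate)) {
    for (nm in c("peptides", "protein_matrix", "traits", "gene_sets",
                 "reference_partition")) {
      p <- config$paths[[nm]]
      if (!is.null(p) && !all(file.exists(p)))
        stopf("input file for '%s' does not exist: %s", nm,
              paste(p[!file.exists(p)], collapse = ", "))
    }
    if (is.null(config$paths$peptides) && is.null(config$paths$protein_matrix))
      stopf("either a peptide table or a protein matrix is required")
    if (is.null(config$paths$traits)) stopf("a trait table is required")
  }
  params
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the enabled stages in order (quantify, preprocess, diffexpr,
#' network, enrich, traits, overlap) and writes every stage output under
#' `config$out_dir`, together with `manifest.json` recording parameters,
#' input file hashes and the seed. With a `simulate` block (a
#' [synthetic_spec]), inputs are generated first and ground-truth sidecars
#' are written. A protein-matrix input bypasses the quantify stage.
#'
#' @param config configuration list (see [default_config]) or the path to
#'   a YAML file.
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  config <- modifyList(default_config(), config)
  params <- validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  failed_marker <- file.path(out, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)

  stage <- "setup"
  tryCatch({
    # ------------------------------------------------------------ inputs
    if (!is.null(config$simulate)) {
      stage <- "simulate"
      spec <- config$simulate
      sim <- generate_abundance(spec)
      traits <- sim$traits
      pm_raw <- sim$matrix
      write_tsv(data.frame(protein_id = names(sim$true_partition),
                           module = unname(sim$true_partition)),
                file.path(out, "truth_partition.tsv"))
      write_tsv(data.frame(module = rownames(sim$latents), sim$latents,
                           check.names = FALSE),
                file.path(out, "truth_latents.tsv"))
      utils::write.csv(traits, file.path(out, "traits.csv"),
                       row.names = FALSE, quote = FALSE)
      res$simulation <- sim
    } else {
      traits <- read_traits(config$paths$traits)
      if (!is.null(config$paths$peptides) &&
          isTRUE(config$stages$quantify)) {
        stage <- "quantify"
        peptides <- read_peptide_table(config$paths$peptides)
        keep <- filter_protein_groups(peptides,
                                      config$quantify$min_unique,
                                      config$quantify$min_spectra)
        pm_raw <- top3_protein_abundance(peptides, keep,
                                         log2_transform = config$quantify$log2)
        write_protein_matrix(pm_raw, file.path(out, "protein_matrix_raw.tsv"))
      } else {
        pm_raw <- read_protein_matrix(config$paths$protein_matrix)
      }
    }
    res$matrix_raw <- pm_raw

    # -------------------------------------------------------- preprocess
    pm <- pm_raw
    if (isTRUE(config$stages$preprocess)) {
      stage <- "preprocess"
      pm <- regress_covariates(pm_raw, traits,
                               covariates = config$regression$covariates,
                               n_bootstrap = config$regression$n_bootstrap,
                               seed = config$seed)
      write_protein_matrix(pm, file.path(out, "protein_matrix_regressed.tsv"))
    }
    res$matrix <- pm

    # ---------------------------------------------------------- diffexpr
    if (isTRUE(config$stages$diffexpr)) {
      stage <- "diffexpr"
      de <- anova_tukey(pm, traits)
      write_tsv(de, file.path(out, "diffexpr.tsv"))
      res$diffexpr <- de
      res$significant <- significant_sets(de, config$diffexpr$alpha)
    }

    # ----------------------------------------------------------- network
    if (isTRUE(config$stages$network)) {
      stage <- "network"
      net <- build_network(pm, params)
      write_network_tables(net, pm, out)
      res$network <- net
    }

    # ------------------------------------------------------------ enrich
    if (isTRUE(config$stages$enrich) && !is.null(config$paths$gene_sets) &&
        !is.null(res$network)) {
      stage <- "enrich"
      for (gpath in config$paths$gene_sets) {
        sets <- read_gmt(gpath)
        enr <- fisher_enrichment(res$network$partition, sets,
                                 gene_symbols = pm$gene_symbols)
        write_tsv(enr, file.path(out, paste0(
          "enrichment_", tools::file_path_sans_ext(basename(gpath)), ".tsv")))
        res$enrichment[[basename(gpath)]] <- enr
      }
    }

    # ------------------------------------------------------------ traits
    if (isTRUE(config$stages$traits) && !is.null(res$network)) {
      stage <- "traits"
      tc <- module_trait_bicor(res$network$eigenproteins, traits,
                               trait_columns = config$traits$trait_columns,
                               diagnosis_coding = config$traits$diagnosis_coding)
      kw <- eigenprotein_group_test(res$network$eigenproteins, traits)
      write_tsv(trait_cor_long(tc), file.path(out, "module_trait_bicor.tsv"))
      write_tsv(kw, file.path(out, "eigenprotein_kruskal.tsv"))
      res$trait_cor <- tc
      res$kruskal <- kw
    }

    # ----------------------------------------------------------- overlap
    if (isTRUE(config$stages$overlap) &&
        !is.null(config$paths$reference_partition) && !is.null(res$network)) {
      stage <- "overlap"
      ref <- read_partition_table(config$paths$reference_partition)
      ov <- cross_network_overlap(res$network$partition, ref,
                                  genes_a = pm$gene_symbols)
      write_tsv(ov$table, file.path(out, "cross_network_overlap.tsv"))
      write_tsv(data.frame(module = rownames(ov$signed_log10_fdr),
                           ov$signed_log10_fdr, check.names = FALSE),
                file.path(out, "cross_network_signed_log10_fdr.tsv"))
      res$overlap <- ov
    }

    stage <- "manifest"
    write_manifest(config, out)
  }, error = function(e) {
    writeLines(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
               failed_marker)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  invisible(res)
}

# long-form module x trait grid with stars at 0.05 / 0.01
trait_cor_long <- function(tc) {
  grid <- expand.grid(module = rownames(tc$r), trait = colnames(tc$r),
                      stringsAsFactors = FALSE)
  grid$bicor <- tc$r[cbind(grid$module, grid$trait)]
  grid$p <- tc$p[cbind(grid$module, grid$trait)]
  grid$fdr <- tc$fdr[cbind(grid$module, grid$trait)]
  grid$stars <- ifelse(is.na(grid$p), "",
                       ifelse(grid$p < 0.01, "**",
                              ifelse(grid$p < 0.05, "*", "")))
  grid
}

# manifest: parameters, input hashes, seed; no timestamps so reruns of an
# unchanged config are byte-identical
write_manifest <- function(config, out) {
  paths <- Filter(Negate(is.null), config$paths)
  hashes <- if (length(paths))
    as.list(tools::md5sum(unlist(paths))) else list()
  manifest <- list(
    package_version = as.character(utils::packageVersion("wpcna")),
    seed = config$seed,
    parameters = config[c("quantify", "regression", "diffexpr", "network",
                          "traits")],
    input_hashes = hashes)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
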