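# End-to-end orchestration: run every available stage from a single
# plain-text (YAML) configuration, write per-stage TSV reports, and
# capture a provenance manifest with input checksums and row counts.

.required_any <- c("inputs", "simulate")

validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) {
    stop("config missing required key: 'out_dir'")
  }
  if (!any(.required_any %in% names(config))) {
    stop("config missing required key: one of 'inputs' or 'simulate'")
  }
  if (!is.null(config$inputs)) {
    for (f in unlist(config$inputs)) {
      if (!file.exists(f)) stop("input file not found: ", f)
    }
    if (is.null(config$inputs$domtblout)) {
      stop("config missing required key: 'inputs.domtblout'")
    }
  }
  config
}

#' Run the whole tryptome pipeline from a configuration
#'
#' Executes every stage for which inputs are available, in dependency
#' order: architecture assembly from a domtblout table, tryptome census,
#' feature annotation (gene models, predictor tables, triad alignment),
#' co-expression summary, and phylostratigraphy. Stage reports are TSV
#' files in `out_dir`; a `manifest.json` records the configuration, input
#' checksums, per-stage row counts and output checksums. Stage outputs are
#' pure functions of the inputs and configuration, so re-running with
#' identical inputs reproduces identical files.
#'
#' @param config A list, or path to a YAML file, with keys: `out_dir`
#'   (required); either `simulate` (list of [sim_domain_hits()] arguments,
#'   plus optional `gff: true`, `matrix: true`) or `inputs` (paths:
#'   `domtblout` required; optional `gff`, `signalp`, `tmhmm`, `msa`,
#'   `triad_reference`, `matrix`, `genes`, `tree`, `presence`); optional
#'   `thresholds` (passed to [pipeline_config()]) and `min_reads`.
#' @param seed Seed forwarded to the simulation stage.
#' @return Invisibly, the manifest as a list.
#' @export
run_all <- function(config, seed = 1L) {
  config <- validate_run_config(config)
  cfg <- as_pipeline_config(config$thresholds)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  inputs <- config$inputs
  manifest <- list(config = config, stages = list())

  if (!is.null(config$simulate)) {
    simargs <- config$simulate
    sim_dir <- file.path(out_dir, "inputs")
    dir.create(sim_dir, showWarnings = FALSE)
    hits_args <- simargs[intersect(names(simargs),
                                   names(formals(sim_domain_hits)))]
    hits_args$seed <- hits_args$seed %||% seed
    sim <- do.call(sim_domain_hits, hits_args)
    dom_path <- file.path(sim_dir, "hits.domtblout")
    write_domtblout(sim$hits, dom_path)
    write_tsv(sim$truth, file.path(sim_dir, "architecture_truth.tsv"))
    inputs$domtblout <- dom_path
    if (isTRUE(simargs$gff)) {
      gff_path <- file.path(sim_dir, "models.gff3")
      simg <- sim_gff(path = gff_path, seed = hits_args$seed)
      dom_tsv <- file.path(sim_dir, "gff_domains.tsv")
      write_tsv(data.frame(protein_id = simg$truth$protein_id,
                           family = "planted",
                           start = simg$truth$domain_start,
                           end = simg$truth$domain_end), dom_tsv)
      inputs$gff <- gff_path
      inputs$domains <- dom_tsv
    }
    if (isTRUE(simargs$matrix)) {
      mtx_path <- file.path(sim_dir, "counts.mtx")
      simc <- sim_cell_matrix(seed = hits_args$seed)
      write_count_matrix(simc$counts, mtx_path)
      writeLines(simc$trypsin_genes, file.path(sim_dir, "trypsins.txt"))
      inputs$matrix <- mtx_path
      inputs$genes <- file.path(sim_dir, "trypsins.txt")
    }
    logf("simulate: wrote synthetic inputs to ", sim_dir)
  }

  logf("architect: parsing ", inputs$domtblout)
  hits <- parse_domtblout(inputs$domtblout,
                          program = config$program %||% "hmmscan")
  archs <- withCallingHandlers(
    build_architectures(hits, cfg),
    warning = function(w) {
      logf("warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  arch_path <- file.path(out_dir, "architectures.tsv")
  write_architectures(archs, arch_path)
  manifest$stages$architect <- list(n_hits = nrow(hits),
                                    n_proteins = length(archs))
  logf("architect: ", length(archs), " architectures")

  cls <- classify_tryptome(archs, cfg)
  bg <- proteome_domain_table(hits, cfg)
  abund <- domain_abundance(archs, bg, cfg)
  write_tsv(abund, file.path(out_dir, "domain_abundance.tsv"))
  census <- data.frame(metric = c("n_proteins", "n_trypsin_only",
                                  "n_multidomain", "n_associated_families"),
                       value = c(length(archs), cls$n_trypsin_only,
                                 cls$n_multidomain,
                                 attr(abund, "n_associated_families")))
  write_tsv(census, file.path(out_dir, "census.tsv"))
  manifest$stages$census <- as.list(stats::setNames(census$value,
                                                    census$metric))
  logf("census: ", cls$n_trypsin_only, " trypsin-only / ",
       cls$n_multidomain, " multi-domain")

  if (!is.null(inputs$gff)) {
    cds <- read_gene_models(inputs$gff)
    # an explicit domain table (e.g. from the generator's planted truth)
    # overrides the architecture-derived spans
    dom <- if (!is.null(inputs$domains)) {
      read_tsv(inputs$domains)
    } else {
      placed_domains(archs)
    }
    feats <- withCallingHandlers({
      mapped <- domain_exon_mapping(cds, dom)
      rep <- feature_report(archs, cds = cds)
      if (!is.null(inputs$signalp) && !is.null(inputs$tmhmm)) {
        pred <- read_predictor_tables(inputs$signalp, inputs$tmhmm,
                                      protein_ids = rep$protein_id)
        rep <- merge(rep, pred, by = "protein_id", all.x = TRUE)
      }
      if (!is.null(inputs$msa) && !is.null(inputs$triad_reference)) {
        tri <- triad_scan(inputs$msa, triad_spec(inputs$triad_reference))
        rep <- merge(rep, tri, by = "protein_id", all.x = TRUE)
      }
      list(mapped = mapped, rep = rep)
    }, warning = function(w) {
      logf("warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    write_tsv(feats$mapped, file.path(out_dir, "domain_exons.tsv"))
    write_tsv(feats$rep, file.path(out_dir, "features.tsv"))
    manifest$stages$features <- list(n_domains_mapped = nrow(feats$mapped),
                                     n_proteins = nrow(feats$rep))
    logf("features: mapped ", nrow(feats$mapped), " domains")
  }

  if (!is.null(inputs$matrix)) {
    counts <- read_count_matrix(inputs$matrix)
    genes <- if (!is.null(inputs$genes)) readLines(inputs$genes) else {
      colnames(counts)
    }
    cc <- cell_counts(counts, genes)
    cs <- coexpression_summary(cc, min_reads = config$min_reads %||% 1)
    write_tsv(cs$per_gene, file.path(out_dir, "coexpression_per_gene.tsv"))
    write_tsv(data.frame(trypsins_per_cell = names(cs$histogram),
                         n_cells = as.integer(cs$histogram)),
              file.path(out_dir, "coexpression_histogram.tsv"))
    manifest$stages$coexpress <- list(
      n_expressing_cells = cs$n_expressing_cells,
      pearson = cs$correlation$pearson$estimate)
    logf("coexpress: ", cs$n_expressing_cells, " expressing cells")
  }

  if (!is.null(inputs$tree) && !is.null(inputs$presence)) {
    tree <- ape::read.tree(inputs$tree)
    pm <- read_presence(inputs$presence)
    orig <- assign_origin(pm, tree)
    orig_out <- orig[, c("feature", "origin_label", "stratum", "n_losses")]
    write_tsv(orig_out, file.path(out_dir, "origins.tsv"))
    manifest$stages$phylostrat <- list(n_features = nrow(orig))
    logf("phylostrat: dated ", nrow(orig), " features")
  }

  outputs <- setdiff(list.files(out_dir, recursive = TRUE,
                                full.names = TRUE),
                     c(log_path, file.path(out_dir, "manifest.json")))
  manifest$input_checksums <- as.list(tools::md5sum(
    unlist(inputs, use.names = FALSE)))
  manifest$output_checksums <- as.list(tools::md5sum(sort(outputs)))
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  logf("done: manifest written")
  invisible(manifest)
}
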