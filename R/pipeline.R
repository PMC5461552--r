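#' Default pipeline configuration
#'
#' Returns the full configuration list with defaults filled in; `config`
#' entries override them. Paths are interpreted relative to the working
#' directory; stage outputs land under `outdir`.
#'
#' @param config named list of overrides (possibly from [load_config()]).
#' @return a complete configuration list.
#' @export
default_config <- function(config = list()) {
  defaults <- list(
    outdir = "kwlasso_out",
    expr = NULL, meth = NULL, labels = NULL, gmt = NULL, probe_map = NULL,
    orientation = "samples_in_rows",
    probe_rule = "most_negative",
    zero_threshold = 0.5,
    distance = "ks",             # or "ks_scaled"
    h = NULL,                    # fixed bandwidth; NULL = tune over h_grid
    h_grid = 10^seq(-2, 2, length.out = 10),
    nfolds = 5,
    seed = 1,
    intercept = TRUE,
    standardize = TRUE,
    include_self = TRUE,
    tolerance = 1e-8,
    methods = c("kernel_weighted", "separate", "pooled"),
    genes = NULL,                # NULL = all target genes
    top_k = 10,
    sim = list())                # sim_config() overrides for the simulate stage
  cfg <- utils::modifyList(defaults, config)
  # modifyList drops keys the caller sets to NULL; restore them so that $
  # lookups cannot partially match other keys (e.g. cfg$h vs cfg$h_grid)
  for (nm in setdiff(names(defaults), names(cfg))) cfg[nm] <- list(NULL)
  # YAML/JSON configs deliver sequences as lists; flatten scalars and vectors
  cfg$methods <- unlist(cfg$methods)
  cfg$h_grid <- as.numeric(unlist(cfg$h_grid))
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$genes)) cfg$genes <- unlist(cfg$genes)
  cfg
}

#' Read a pipeline configuration file (YAML or JSON)
#' @param path configuration file; format chosen by extension
#'   (`.json` = JSON, anything else YAML).
#' @return a complete configuration list with defaults filled in.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  default_config(raw)
}

.stage_file <- function(cfg, name) file.path(cfg$outdir, name)

.require_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    stop(sprintf("stage '%s' needs missing file %s (run the upstream stage first)",
                 stage, path))
  }
  path
}

#' Run the pipeline
#'
#' Orchestrates the stages: `simulate` (write a synthetic bundle into
#' `outdir/data`), `preprocess` (load, log-normalize, probe-collapse if a
#' probe map is given, zero-heavy and pathway-membership filters),
#' `distances` (between-subtype KS matrix), `fit` (bandwidth selection if
#' not fixed, then kernel-weighted fits for every gene and subtype),
#' `evaluate` (cross-validated three-method comparison plus gene and
#' pathway rankings) and `network` (edge lists, Venn partition, hubs,
#' GraphML). `"all"` chains every stage. Each stage reads its inputs from
#' `outdir`, so stages can be re-run individually; a missing upstream
#' artifact is an error naming the expected file. Every invocation writes
#' a `run_info.json` provenance record (config, seed, package version).
#'
#' @param stages character vector of stage names, or `"all"`.
#' @param config named list of configuration overrides (see
#'   [default_config()]).
#' @return invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(stages = "all", config = list()) {
  cfg <- default_config(config)
  all_stages <- c("simulate", "preprocess", "distances", "fit", "evaluate", "network")
  if (identical(stages, "all")) stages <- all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown)) stop(sprintf("unknown stage(s): %s", paste(unknown, collapse = ", ")))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  written <- list()

  if ("simulate" %in% stages) {
    sim_cfg <- do.call(sim_config, utils::modifyList(list(seed = cfg$seed), cfg$sim))
    bundle <- generate(sim_cfg)
    paths <- write_fixture(bundle, file.path(cfg$outdir, "data"))
    cfg$expr <- unname(paths["expr"])
    cfg$meth <- unname(paths["meth"])
    cfg$labels <- unname(paths["labels"])
    cfg$gmt <- unname(paths["gmt"])
    written$simulate <- paths
  }

  if ("preprocess" %in% stages) {
    for (f in c("expr", "meth", "labels", "gmt")) {
      if (is.null(cfg[[f]])) stop(sprintf("config entry '%s' is required", f))
      .require_artifact(cfg[[f]], "preprocess")
    }
    expr <- log_normalize(load_matrix(cfg$expr, cfg$orientation))
    meth_raw <- load_matrix(cfg$meth, cfg$orientation)
    pc <- load_gmt(cfg$gmt)
    sa <- load_labels(cfg$labels)
    if (!is.null(cfg$probe_map)) {
      pm <- load_probe_map(.require_artifact(cfg$probe_map, "preprocess"))
      meth_raw <- collapse_probes(log_normalize(meth_raw), expr, pm,
                                  rule = cfg$probe_rule)
      meth <- meth_raw
    } else {
      meth <- log_normalize(meth_raw)
    }
    expr <- filter_zero_heavy(expr, cfg$zero_threshold)
    meth <- filter_zero_heavy(meth, cfg$zero_threshold)
    expr <- filter_by_pathway_membership(expr, pc)
    meth <- filter_by_pathway_membership(meth, pc)
    written$preprocess <- c(
      expr = write_matrix(expr, .stage_file(cfg, "processed_expr.tsv")),
      meth = write_matrix(meth, .stage_file(cfg, "processed_meth.tsv")))
  }

  read_processed <- function(stage) {
    list(expr = omics_matrix(load_subtype_matrix(
           .require_artifact(.stage_file(cfg, "processed_expr.tsv"), stage))),
         meth = omics_matrix(load_subtype_matrix(
           .require_artifact(.stage_file(cfg, "processed_meth.tsv"), stage))),
         sa = load_labels(.require_artifact(cfg$labels, stage)),
         pc = load_gmt(.require_artifact(cfg$gmt, stage)))
  }

  if ("distances" %in% stages) {
    pr <- read_processed("distances")
    d <- subtype_distance_matrix(pr$meth, pr$sa,
                                 scaled = identical(cfg$distance, "ks_scaled"))
    written$distances <- write_subtype_matrix(d, .stage_file(cfg, "distances.tsv"))
  }

  get_kernel <- function(pr, stage) {
    d <- load_subtype_matrix(.require_artifact(.stage_file(cfg, "distances.tsv"), stage))
    h <- cfg$h
    if (is.null(h)) {
      genes <- if (is.null(cfg$genes)) colnames(pr$expr) else cfg$genes
      built <- build_all_designs(pr$expr, pr$meth, pr$pc, genes, cfg$include_self)
      h <- select_bandwidth(built$designs, pr$sa, d, h_grid = cfg$h_grid,
                            nfolds = cfg$nfolds, seed = cfg$seed,
                            intercept = cfg$intercept,
                            standardize = cfg$standardize)$h
    }
    subtype_kernel(d, h)
  }

  if ("fit" %in% stages) {
    pr <- read_processed("fit")
    sk <- get_kernel(pr, "fit")
    genes <- if (is.null(cfg$genes)) colnames(pr$expr) else cfg$genes
    fits <- fit_all(pr$expr, pr$meth, pr$pc, pr$sa, sk, genes,
                    nfolds = cfg$nfolds, seed = cfg$seed,
                    include_self = cfg$include_self,
                    intercept = cfg$intercept, standardize = cfg$standardize)
    tab <- as.data.frame(fits)
    path <- .stage_file(cfg, "coefficients.tsv")
    writeLines(c("target_gene\tsubtype\tfeature\tbeta\tlambda\th",
                 sprintf("%s\t%s\t%s\t%s\t%s\t%s", tab$target_gene, tab$subtype,
                         tab$feature, formatC(tab$beta, digits = 12, format = "g"),
                         formatC(tab$lambda, digits = 12, format = "g"),
                         formatC(tab$h, digits = 12, format = "g"))), path)
    written$fit <- path
  }

  if ("evaluate" %in% stages) {
    pr <- read_processed("evaluate")
    sk <- get_kernel(pr, "evaluate")
    genes <- if (is.null(cfg$genes)) colnames(pr$expr) else cfg$genes
    records <- evaluate_genes(pr$expr, pr$meth, pr$pc, pr$sa, sk, genes,
                              methods = cfg$methods, nfolds = cfg$nfolds,
                              seed = cfg$seed, include_self = cfg$include_self,
                              intercept = cfg$intercept,
                              standardize = cfg$standardize)
    rec_path <- .stage_file(cfg, "evaluation.tsv")
    utils::write.table(records, rec_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    rk <- rank_genes(records, top_k = cfg$top_k)
    rank_path <- .stage_file(cfg, "gene_rankings.tsv")
    rank_tab <- rbind(
      data.frame(list_name = "overall", gene = rk$overall$gene,
                 value = rk$overall$rmse, stringsAsFactors = FALSE),
      do.call(rbind, lapply(names(rk$by_subtype), function(s) {
        data.frame(list_name = s, gene = rk$by_subtype[[s]]$gene,
                   value = rk$by_subtype[[s]]$improvement,
                   stringsAsFactors = FALSE)
      })))
    utils::write.table(rank_tab, rank_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    pw <- pathway_error(records, pr$pc, statistic = "rmse")
    pw_path <- .stage_file(cfg, "pathway_scores.tsv")
    utils::write.table(pw, pw_path, sep = "\t", quote = FALSE, row.names = FALSE)
    written$evaluate <- c(records = rec_path, rankings = rank_path,
                          pathways = pw_path)
  }

  if ("network" %in% stages) {
    coef_path <- .require_artifact(.stage_file(cfg, "coefficients.tsv"), "network")
    tab <- utils::read.delim(coef_path, stringsAsFactors = FALSE)
    sa <- load_labels(.require_artifact(cfg$labels, "network"))
    net <- build_networks(
      data.frame(target_gene = tab$target_gene,
                 subtype = factor(tab$subtype, levels = sa$subtypes),
                 feature = tab$feature, beta = tab$beta,
                 stringsAsFactors = FALSE),
      tolerance = cfg$tolerance)
    net$subtypes <- sa$subtypes
    edge_path <- export_network(net, .stage_file(cfg, "network_edges.tsv"), "tsv")
    sif_path <- export_network(net, .stage_file(cfg, "network.sif"), "sif")
    gml_path <- export_network(net, .stage_file(cfg, "network.graphml"), "graphml")
    vp <- venn_partition(net)
    venn_path <- .stage_file(cfg, "venn_cells.tsv")
    utils::write.table(vp$cells, venn_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    hubs <- hub_degrees(net, "methylation", top_k = cfg$top_k)
    hub_path <- .stage_file(cfg, "hub_degrees.tsv")
    utils::write.table(hubs, hub_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written$network <- c(edges = edge_path, sif = sif_path, graphml = gml_path,
                         venn = venn_path, hubs = hub_path)
  }

  prov <- list(stages = stages,
               config = cfg[setdiff(names(cfg), "h_grid")],
               h_grid = as.numeric(cfg$h_grid),
               package_version = as.character(utils::packageVersion("kwlasso")))
  jsonlite::write_json(prov, .stage_file(cfg, "run_info.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(written)
}

#' Command-line entry point
#'
#' Thin wrapper used by the `inst/scripts/kwlasso` Rscript:
#' `kwlasso <stage|all> --config cfg.yaml [--seed N] [--outdir DIR]`.
#' Flags override config-file keys.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
kwl_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: kwlasso <simulate|preprocess|distances|fit|evaluate|network|all> [--config FILE] [--seed N] [--outdir DIR]")
    return(invisible(1L))
  }
  stage <- args[1]
  opt <- function(flag) {
    i <- which(args == flag)
    if (length(i) && i[1] < length(args)) args[i[1] + 1] else NULL
  }
  cfg <- if (!is.null(opt("--config"))) load_config(opt("--config")) else default_config()
  if (!is.null(opt("--seed"))) cfg$seed <- as.integer(opt("--seed"))
  if (!is.null(opt("--outdir"))) cfg$outdir <- opt("--outdir")
  status <- tryCatch({
    run_pipeline(stage, cfg)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
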