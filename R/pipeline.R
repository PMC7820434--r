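#' Pipeline configuration
#'
#' Collects the five inputs and every screening threshold of the end-to-end
#' analysis. Inputs may be file paths (read with the module readers) or
#' in-memory data frames. All defaults are the conventional screening
#' values: a 5 ppm fitting window, probability strictly above 0, combined
#' score at least 0.9, ten hubs, `P < 0.01`, top 20 pathways.
#'
#' @param predictions,disease,ppi,annotations Required inputs (path or
#'   data frame).
#' @param peaks Optional peak table (path or data frame).
#' @param background Optional background gene set for enrichment (path to a
#'   one-symbol-per-line file, or character vector).
#' @param out_dir Optional directory for intermediate artifacts.
#' @param tolerance_ppm Formula-fitting window (ppm).
#' @param min_probability Prediction screen; keeps probability strictly
#'   greater.
#' @param ppi_threshold Combined-score threshold (inclusive).
#' @param hub_k Number of hub genes.
#' @param alpha Enrichment screening threshold on the raw p-value.
#' @param top_pathways Number of pathways carried into the
#'   compound-target-pathway network.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(predictions, disease, ppi, annotations,
                            peaks = NULL, background = NULL, out_dir = NULL,
                            tolerance_ppm = 5, min_probability = 0,
                            ppi_threshold = 0.9, hub_k = 10, alpha = 0.01,
                            top_pathways = 20) {
  stopifnot(tolerance_ppm > 0, min_probability >= 0, min_probability <= 1,
            ppi_threshold >= 0, ppi_threshold <= 1, hub_k >= 1,
            alpha > 0, alpha <= 1, top_pathways >= 1)
  structure(list(
    peaks = peaks, predictions = predictions, disease = disease, ppi = ppi,
    annotations = annotations, background = background, out_dir = out_dir,
    tolerance_ppm = tolerance_ppm, min_probability = min_probability,
    ppi_threshold = ppi_threshold, hub_k = hub_k, alpha = alpha,
    top_pathways = top_pathways
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Expects top-level keys `inputs` (paths: `peaks`, `predictions`,
#' `disease`, `ppi`, `annotations`, optional `background`) and optional
#' `params` overriding the [pipeline_config()] defaults, plus `out_dir`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  inputs <- y$inputs %||% list()
  params <- y$params %||% list()
  do.call(pipeline_config, c(
    list(peaks = inputs$peaks, predictions = inputs$predictions,
         disease = inputs$disease, ppi = inputs$ppi,
         annotations = inputs$annotations, background = inputs$background,
         out_dir = y$out_dir),
    params
  ))
}

resolve_input <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) reader(x) else tibble::as_tibble(x)
}

#' Run the full network-pharmacology pipeline
#'
#' Executes peak annotation (when peaks are supplied), prediction and
#' disease-target screening, intersection into the therapeutic target set,
#' compound-target network construction with the main-ingredient screen,
#' protein-interaction filtering with hub ranking, over-representation
#' analysis, and the compound-target-pathway network. If `out_dir` is set,
#' every intermediate table is written (TSV/JSON, graphs additionally as
#' GraphML and SIF) along with a machine-readable `report.json`. The run is
#' fully deterministic: identical inputs give identical outputs.
#'
#' An empty therapeutic target set stops the pipeline after target assembly
#' with `status = "empty therapeutic set"` rather than an error.
#'
#' @param config A [pipeline_config()] (or a YAML path accepted by
#'   [read_pipeline_config()]).
#' @return A list of class `phytonet_run`: `status`, `report` (nested list
#'   of counts and screen reports) and the intermediate objects
#'   (`therapeutic`, `ct_graph`, `ingredients`, `ppi_graph`, `hubs`,
#'   `enrichment`, `top_terms`, `ctp_graph`, `candidates`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(params = config[c("tolerance_ppm", "min_probability",
                                   "ppi_threshold", "hub_k", "alpha",
                                   "top_pathways")])
  out <- list(status = "incomplete")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- mass annotation ------------------------------------------------------
  peaks <- resolve_input(config$peaks, read_peak_table)
  if (!is.null(peaks)) {
    out$candidates <- stage("mass_annotation",
      fit_peaks(peaks, tolerance_ppm = config$tolerance_ppm))
    top_hits <- out$candidates |> dplyr::filter(.data$rank == 1)
    report$mass_annotation <- list(
      n_peaks = nrow(peaks),
      n_with_candidates = length(unique(out$candidates$peak_id))
    )
    if ("known_formula" %in% names(peaks)) {
      truth <- peaks |>
        dplyr::select("peak_id", "known_formula") |>
        dplyr::left_join(top_hits, by = "peak_id")
      report$mass_annotation$n_recovered_rank1 <-
        sum(truth$known_formula == truth$formula, na.rm = TRUE)
    }
  }

  # -- target assembly ------------------------------------------------------
  predictions <- stage("target_assembly",
    resolve_input(config$predictions, read_predictions))
  disease <- stage("target_assembly",
    resolve_input(config$disease, read_disease_targets))
  pred_screen <- stage("target_assembly",
    screen_predictions(predictions, config$min_probability))
  dis_screen <- stage("target_assembly", screen_disease_targets(disease))
  therapeutic <- intersect_targets(pred_screen$union, dis_screen$union)
  out$pred_screen <- pred_screen
  out$dis_screen <- dis_screen
  out$therapeutic <- therapeutic
  report$target_assembly <- list(
    predictions = as.list(pred_screen$report),
    disease = dis_screen$report,
    n_compound_union = length(pred_screen$union),
    n_disease_union = length(dis_screen$union),
    n_therapeutic = length(therapeutic)
  )
  if (length(therapeutic) == 0) {
    out$status <- "empty therapeutic set"
    out$report <- report
    class(out) <- "phytonet_run"
    write_run_artifacts(out, config)
    return(out)
  }

  # -- compound-target network ---------------------------------------------
  out$ct_graph <- stage("network_core",
    build_compound_target_network(pred_screen$per_compound, therapeutic))
  out$ingredients <- stage("network_core", screen_main_ingredients(out$ct_graph))
  report$compound_target_network <- c(
    as.list(summarize_network(out$ct_graph)),
    list(main_ingredients = out$ingredients$ingredients,
         mean_degree_compounds = out$ingredients$mean_degree,
         mean_betweenness_compounds = out$ingredients$mean_betweenness)
  )

  # -- PPI network ----------------------------------------------------------
  ppi <- stage("ppi", resolve_input(config$ppi, read_ppi))
  out$ppi_graph <- stage("ppi",
    build_ppi_network(ppi, therapeutic, config$ppi_threshold))
  out$hubs <- stage("ppi", hub_genes(out$ppi_graph, config$hub_k))
  report$ppi_network <- c(
    as.list(summarize_network(out$ppi_graph)),
    list(hubs = out$hubs$hubs, tie_overflow = out$hubs$tie_overflow)
  )

  # -- enrichment -----------------------------------------------------------
  annotations <- stage("enrichment",
    resolve_input(config$annotations, read_annotations))
  background <- config$background
  if (is.character(background) && length(background) == 1 &&
      file.exists(background)) {
    background <- readLines(background)
  }
  out$enrichment <- stage("enrichment",
    ora(therapeutic, annotations, background = background,
        alpha = config$alpha))
  out$top_terms <- select_top(out$enrichment, config$top_pathways)
  report$enrichment <- list(
    n_significant = as.list(table(out$enrichment$category)),
    n_top = nrow(out$top_terms)
  )

  # -- compound-target-pathway network --------------------------------------
  kegg_top <- out$top_terms |> dplyr::filter(.data$category == "KEGG")
  membership <- annotations |>
    dplyr::filter(.data$term_id %in% kegg_top$term_id) |>
    dplyr::transmute(pathway = .data$term_id, gene = .data$gene)
  out$ctp_graph <- stage("ctp_network",
    build_ctp_network(out$ct_graph, membership, kegg_top$term_id))
  report$ctp_network <- as.list(summarize_network(out$ctp_graph))

  out$status <- "complete"
  out$report <- report
  class(out) <- "phytonet_run"
  write_run_artifacts(out, config)
  out
}

#' Read a protein-protein interaction edge table
#'
#' TSV/CSV with columns `gene_a`, `gene_b`, `combined_score`.
#' @param path File path.
#' @return A tibble.
#' @export
read_ppi <- function(path) {
  x <- read_delim_auto(path)
  need <- c("gene_a", "gene_b", "combined_score")
  if (!all(need %in% names(x))) {
    stop("PPI file needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  x
}

write_run_artifacts <- function(run, config) {
  dir <- config$out_dir
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  if (!is.null(run$candidates)) readr::write_tsv(run$candidates, p("candidates.tsv"))
  if (!is.null(run$therapeutic)) write_gene_set(run$therapeutic, p("therapeutic_targets.txt"))
  if (!is.null(run$ct_graph)) {
    readr::write_tsv(centrality(run$ct_graph), p("ct_centrality.tsv"))
    write_graphml(run$ct_graph, p("ct_network.graphml"))
    write_sif(run$ct_graph, p("ct_network.sif"))
  }
  if (!is.null(run$ppi_graph)) {
    readr::write_tsv(run$hubs$hubs, p("hub_genes.tsv"))
    write_graphml(run$ppi_graph, p("ppi_network.graphml"))
    write_sif(run$ppi_graph, p("ppi_network.sif"))
  }
  if (!is.null(run$enrichment)) {
    readr::write_tsv(tibble::as_tibble(run$enrichment), p("enrichment.tsv"))
    readr::write_tsv(bubble_export(run$top_terms), p("bubble.tsv"))
  }
  if (!is.null(run$ctp_graph)) {
    write_graphml(run$ctp_graph, p("ctp_network.graphml"))
    write_sif(run$ctp_graph, p("ctp_network.sif"))
  }
  jsonlite::write_json(run$report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.phytonet_run <- function(x, ...) {
  cat("<phytonet run> status:", x$status, "\n")
  if (!is.null(x$therapeutic)) {
    cat("therapeutic targets:", length(x$therapeutic), "\n")
  }
  if (!is.null(x$ct_graph)) {
    cat("compound-target network:", nrow(x$ct_graph$nodes), "nodes,",
        nrow(x$ct_graph$edges), "edges\n")
    cat("main ingredients:", paste(x$ingredients$ingredients, collapse = ", "), "\n")
  }
  if (!is.null(x$ppi_graph)) {
    cat("PPI network:", nrow(x$ppi_graph$nodes), "nodes,",
        nrow(x$ppi_graph$edges), "edges; hubs:",
        paste(x$hubs$hubs$gene, collapse = ", "), "\n")
  }
  if (!is.null(x$ctp_graph)) {
    cat("compound-target-pathway network:", nrow(x$ctp_graph$nodes), "nodes,",
        nrow(x$ctp_graph$edges), "edges\n")
  }
  invisible(x)
}

#' @export
glance.phytonet_run <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    n_therapeutic = length(x$therapeutic %||% character(0)),
    ct_nodes = if (is.null(x$ct_graph)) NA_integer_ else nrow(x$ct_graph$nodes),
    ct_edges = if (is.null(x$ct_graph)) NA_integer_ else nrow(x$ct_graph$edges),
    ppi_nodes = if (is.null(x$ppi_graph)) NA_integer_ else nrow(x$ppi_graph$nodes),
    ppi_edges = if (is.null(x$ppi_graph)) NA_integer_ else nrow(x$ppi_graph$edges),
    n_main_ingredients = if (is.null(x$ingredients)) NA_integer_ else length(x$ingredients$ingredients),
    ctp_nodes = if (is.null(x$ctp_graph)) NA_integer_ else nrow(x$ctp_graph$nodes)
  )
}
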