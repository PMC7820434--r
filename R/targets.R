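canonical_genes <- function(x) {
  unique(toupper(trimws(x[!is.na(x) & nzchar(trimws(x))])))
}

screen_report <- function(stage, ...) {
  tibble::tibble(stage = stage, ...)
}

#' Screen compound-target predictions
#'
#' Keeps predictions whose probability exceeds `min_probability` (strictly),
#' deduplicates genes per compound and across compounds, and records a
#' screening report. Gene symbols are canonicalized to uppercase with
#' surrounding whitespace stripped.
#'
#' @param predictions Data frame with columns `compound_id`, `gene`,
#'   `probability` (in `[0, 1]`).
#' @param min_probability Screening threshold; records with probability
#'   strictly greater are kept. Default 0.
#' @return An object of class `phytonet_screen` — a list with
#'   `per_compound` (tibble of `compound_id`, `gene`), `union` (character
#'   vector of unique genes) and `report` (tibble with raw, kept, and unique
#'   counts).
#' @examples
#' p <- tibble::tibble(compound_id = c("c1", "c1"), gene = c("G1", "G2"),
#'                     probability = c(0, 0.5))
#' screen_predictions(p)$union
#' @export
screen_predictions <- function(predictions, min_probability = 0) {
  predictions <- tibble::as_tibble(predictions)
  need <- c("compound_id", "gene", "probability")
  if (!all(need %in% names(predictions))) {
    stop("predictions need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(predictions$probability) |
                 predictions$probability < 0 | predictions$probability > 1)
  if (length(bad) > 0) {
    stop("probability outside [0,1] at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  kept <- predictions |>
    dplyr::filter(.data$probability > min_probability) |>
    dplyr::mutate(gene = toupper(trimws(.data$gene))) |>
    dplyr::filter(nzchar(.data$gene)) |>
    dplyr::distinct(.data$compound_id, .data$gene)
  res <- list(
    per_compound = kept,
    union = sort(unique(kept$gene)),
    report = screen_report(
      "predictions",
      n_raw = nrow(predictions),
      n_kept = nrow(kept),
      n_unique_genes = length(unique(kept$gene)),
      threshold = min_probability
    )
  )
  structure(res, class = "phytonet_screen")
}

#' Screen multi-source disease target lists
#'
#' Within each source independently, duplicate genes collapse to their
#' maximum score, then genes scoring at or above the source's arithmetic
#' mean score are kept. A source whose `score` column is entirely missing
#' (e.g. a curated database that publishes no score) keeps all its genes.
#'
#' @param disease Data frame with columns `source`, `gene`, `score`
#'   (`score` may be `NA` for score-less sources).
#' @param keep `"ge"` (default) keeps genes scoring at or above the source
#'   mean; `"gt"` requires strictly above.
#' @return A `phytonet_screen` list with `per_source` (named list of gene
#'   vectors), `union` (merged unique genes) and `report` (per-source tibble
#'   of raw/kept counts and the mean applied).
#' @examples
#' d <- tibble::tibble(source = "s", gene = c("A", "B", "C"), score = c(1, 2, 6))
#' screen_disease_targets(d)$per_source
#' @export
screen_disease_targets <- function(disease, keep = c("ge", "gt")) {
  keep <- match.arg(keep)
  disease <- tibble::as_tibble(disease)
  need <- c("source", "gene", "score")
  if (!all(need %in% names(disease))) {
    stop("disease table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(is.infinite(disease$score), na.rm = TRUE)) {
    stop("scores must be finite (or NA for score-less sources)", call. = FALSE)
  }
  disease <- disease |>
    dplyr::mutate(gene = toupper(trimws(.data$gene))) |>
    dplyr::filter(nzchar(.data$gene))
  per_source <- list()
  reports <- list()
  for (src in unique(disease$source)) {
    d <- disease[disease$source == src, ]
    n_raw <- nrow(d)
    if (all(is.na(d$score))) {
      genes <- sort(unique(d$gene))
      mu <- NA_real_
    } else {
      if (anyNA(d$score)) {
        stop("source '", src, "' mixes scored and unscored rows", call. = FALSE)
      }
      d <- d |>
        dplyr::summarise(score = max(.data$score), .by = "gene")
      mu <- mean(d$score)
      genes <- sort(d$gene[if (keep == "ge") d$score >= mu else d$score > mu])
    }
    per_source[[src]] <- genes
    reports[[src]] <- screen_report("disease", source = src, n_raw = n_raw,
                                    n_kept = length(genes), mean_score = mu)
  }
  structure(list(
    per_source = per_source,
    union = merge_sources(per_source),
    report = dplyr::bind_rows(reports)
  ), class = "phytonet_screen")
}

#' Merge gene sets from several sources
#'
#' @param per_source A list of character vectors (or a `phytonet_screen`
#'   from [screen_disease_targets()]).
#' @return Sorted character vector: the deduplicated union.
#' @export
merge_sources <- function(per_source) {
  if (inherits(per_source, "phytonet_screen")) per_source <- per_source$per_source
  sort(canonical_genes(unlist(per_source, use.names = FALSE)))
}

#' Intersect compound targets with disease targets
#'
#' The intersection is the therapeutic target set carried forward to network
#' construction, protein-protein interaction analysis and enrichment.
#'
#' @param compound_union,disease_union Character vectors of gene symbols.
#' @return Sorted character vector of common genes.
#' @export
intersect_targets <- function(compound_union, disease_union) {
  sort(intersect(canonical_genes(compound_union), canonical_genes(disease_union)))
}

#' @export
print.phytonet_screen <- function(x, ...) {
  cat("<phytonet screen>\n")
  print(x$report)
  invisible(x)
}

#' @export
tidy.phytonet_screen <- function(x, ...) x$report

#' Read a compound-target prediction table
#'
#' CSV/TSV with columns `compound_id`, `gene`, `probability`.
#' @param path File path.
#' @return A tibble.
#' @export
read_predictions <- function(path) {
  x <- read_delim_auto(path)
  need <- c("compound_id", "gene", "probability")
  if (!all(need %in% names(x))) {
    stop("prediction file needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  x
}

#' Read a multi-source disease target table
#'
#' CSV/TSV with columns `source`, `gene`, `score` (blank score allowed).
#' @param path File path.
#' @return A tibble.
#' @export
read_disease_targets <- function(path) {
  x <- read_delim_auto(path)
  need <- c("source", "gene", "score")
  if (!all(need %in% names(x))) {
    stop("disease file needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  x$score <- suppressWarnings(as.numeric(x$score))
  x
}

#' Write a gene set as one symbol per line
#' @param genes Character vector.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
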