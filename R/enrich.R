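#' Hypergeometric over-representation analysis
#'
#' For each annotation term, tests whether the query gene set overlaps the
#' term's gene set more than expected when drawing `n` genes at random from
#' the background of `N`. The p-value is the upper tail of the
#' hypergeometric distribution,
#' `p = sum_{i >= k} C(K, i) C(N - K, n - i) / C(N, n)`,
#' where `K` is the term size, `n` the query size and `k` the overlap.
#' Terms with no overlap are never reported; rows with `p < alpha` are
#' returned sorted by p-value.
#'
#' @param query Character vector of gene symbols.
#' @param annotations Data frame with columns `term_id`, `term_name`,
#'   `category` (one of `BP`, `CC`, `MF`, `KEGG`) and `gene`, one row per
#'   term-gene pair.
#' @param background Character vector; defaults to all genes in
#'   `annotations`. Query genes absent from the background are dropped from
#'   `n` (their count is attached as the `n_query_dropped` attribute, with a
#'   warning).
#' @param alpha Screening threshold on the raw p-value, default 0.01.
#' @param adjust If `TRUE`, adds a Benjamini-Hochberg `p_adjust` column
#'   (computed over all tested terms with overlap, before the `alpha`
#'   screen, which still applies to the raw p-value).
#' @return Tibble of class `phytonet_ora` with columns `term_id`,
#'   `term_name`, `category`, `k`, `K`, `n`, `N`, `p_value`, `genes`
#'   (comma-collapsed overlap), sorted by `p_value`.
#' @examples
#' db <- tibble::tibble(term_id = "t1", term_name = "term", category = "KEGG",
#'                      gene = paste0("G", 1:5))
#' bg <- paste0("G", 1:10)
#' ora(paste0("G", 1:5), db, background = bg, alpha = 1)
#' @export
ora <- function(query, annotations, background = NULL, alpha = 0.01,
                adjust = FALSE) {
  stopifnot(alpha > 0, alpha <= 1)
  annotations <- tibble::as_tibble(annotations)
  need <- c("term_id", "term_name", "category", "gene")
  if (!all(need %in% names(annotations))) {
    stop("annotation table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  annotations <- annotations |>
    dplyr::mutate(gene = toupper(trimws(.data$gene))) |>
    dplyr::distinct(.data$term_id, .data$term_name, .data$category, .data$gene)
  background <- if (is.null(background)) {
    unique(annotations$gene)
  } else {
    canonical_genes(background)
  }
  if (length(background) == 0) stop("background is empty", call. = FALSE)
  outside <- setdiff(unique(annotations$gene), background)
  if (length(outside) > 0) {
    stop("annotation term gene(s) outside the background: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  query <- canonical_genes(query)
  dropped <- sum(!query %in% background)
  if (dropped > 0) {
    warning(dropped, " query gene(s) absent from the background were dropped",
            call. = FALSE)
    query <- query[query %in% background]
  }
  N <- length(background)
  n <- length(query)
  rows <- annotations |>
    dplyr::summarise(
      term_name = dplyr::first(.data$term_name),
      category = dplyr::first(.data$category),
      K = dplyr::n_distinct(.data$gene),
      k = sum(.data$gene %in% query),
      genes = paste(sort(intersect(.data$gene, query)), collapse = ","),
      .by = "term_id"
    ) |>
    dplyr::filter(.data$k >= 1) |>
    dplyr::mutate(
      n = n, N = N,
      p_value = stats::phyper(.data$k - 1, .data$K, N - .data$K, n,
                              lower.tail = FALSE)
    )
  if (adjust) rows$p_adjust <- stats::p.adjust(rows$p_value, method = "BH")
  rows <- rows |>
    dplyr::filter(.data$p_value < alpha) |>
    dplyr::arrange(.data$p_value, .data$term_id) |>
    dplyr::select("term_id", "term_name", "category", "k", "K", "n", "N",
                  "p_value", dplyr::any_of("p_adjust"), "genes")
  attr(rows, "n_query_dropped") <- dropped
  class(rows) <- c("phytonet_ora", class(rows))
  rows
}

#' Select the top terms by enriched gene count
#'
#' Within each annotation category, terms are ordered by overlap count
#' descending, ties by p-value ascending, then term id; the first `k` per
#' category are returned.
#'
#' @param rows An [ora()] result (or any tibble with `category`, `k`,
#'   `p_value`, `term_id`).
#' @param k Terms per category, default 20.
#' @return The selected rows, same columns as the input.
#' @export
select_top <- function(rows, k = 20) {
  stopifnot(k >= 1)
  rows |>
    tibble::as_tibble() |>
    dplyr::arrange(dplyr::desc(.data$k), .data$p_value, .data$term_id) |>
    dplyr::slice_head(n = k, by = "category")
}

#' Bubble-plot export table
#'
#' The minimal table needed to redraw a standard enrichment bubble chart:
#' term, category, enriched gene count, gene ratio (`k / n`) and p-value.
#'
#' @param rows An [ora()] result.
#' @return Tibble with `term_name`, `category`, `count`, `gene_ratio`,
#'   `p_value`.
#' @export
bubble_export <- function(rows) {
  rows <- tibble::as_tibble(rows)
  if (nrow(rows) == 0) {
    return(tibble::tibble(term_name = character(), category = character(),
                          count = integer(), gene_ratio = numeric(),
                          p_value = numeric()))
  }
  dplyr::transmute(rows, term_name = .data$term_name,
                   category = .data$category, count = .data$k,
                   gene_ratio = .data$k / .data$n, p_value = .data$p_value)
}

#' Read an annotation table
#'
#' Two formats are accepted: a long TSV/CSV with columns `term_id`,
#' `term_name`, `category`, `gene` (one row per term-gene pair), or a
#' GMT-style file whose tab-separated fields are term id, term name,
#' category, then the member genes.
#'
#' @param path File path; `.gmt` selects the GMT-style parser.
#' @return A long-format annotation tibble.
#' @export
read_annotations <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    purrr::map_dfr(lines, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(f) < 4) stop("malformed GMT line: ", substr(l, 1, 40), call. = FALSE)
      tibble::tibble(term_id = f[1], term_name = f[2], category = f[3],
                     gene = f[-(1:3)])
    })
  } else {
    x <- read_delim_auto(path)
    need <- c("term_id", "term_name", "category", "gene")
    if (!all(need %in% names(x))) {
      stop("annotation file needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    x
  }
}
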