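HUB_SYMBOLS <- c("PIK3R1", "PIK3CA", "SRC", "MAPK1", "AKT1",
                 "HSP90AA1", "HRAS", "STAT3", "FYN", "RHOA")

sub_seed <- function(seed, stream) {
  offsets <- c(genes = 1L, peaks = 2L, predictions = 3L, disease = 4L,
               ppi = 5L, annotation = 6L)
  s <- (as.integer(seed) %% 100000L) * 7919L + offsets[[stream]] * 104729L
  (s %% 2147483629L) + 1L
}

#' Configuration for a synthetic network-pharmacology study
#'
#' Defaults emulate a study of a 41-compound herbal extract against a
#' well-annotated disease: four disease-gene sources on incomparable score
#' scales (two lognormal, one uniform, one small curated score-less list), a
#' 471-gene compound-target pool intersecting the disease genes in exactly
#' 262 therapeutic targets, a protein-interaction layer with exactly 222
#' connected genes and 1205 super-threshold edges around 10 planted hubs,
#' and an annotation base with planted enriched terms. All randomness is
#' driven by `seed` through per-table sub-streams, so adding one table type
#' never perturbs the draws of another.
#'
#' @param seed Integer master seed.
#' @param n_compounds Number of compounds (peaks).
#' @param targets_per_compound Length-2 range of per-compound prediction
#'   counts before boosting.
#' @param compound_pool_size Unique genes reachable by any compound.
#' @param n_planted_ingredients Compounds planted as main ingredients.
#' @param planted_degree_boost Multiplier on the planted compounds' number
#'   of therapeutic-target links.
#' @param zero_probability_fraction Fraction of extra prediction rows with
#'   probability exactly 0 (screen negatives).
#' @param intersection_size Planted size of the therapeutic target set.
#' @param universe_size Total gene universe.
#' @param disease_sources Named list of per-source settings: `n_genes` plus
#'   a score `family` (`"lognormal"`, `"uniform"` or `"constant"`, the last
#'   meaning a score-less curated source).
#' @param ppi List: `n_connected`, `n_edges` (super-threshold),
#'   `n_noise_edges` (sub-threshold), `n_planted_hubs`, `hub_degree_boost`,
#'   `threshold`.
#' @param annotation List: `n_terms` per category counts, `term_size_range`,
#'   `n_planted_terms`, `planted_overlap_fraction`,
#'   `enriched_fraction`/`enriched_overlap_fraction` for secondary mildly
#'   enriched terms.
#' @param peaks List: `noise_ppm` (max in-tolerance |error|),
#'   `outlier_fraction`, `outlier_ppm_range`.
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1L,
                         n_compounds = 41,
                         targets_per_compound = c(15, 40),
                         compound_pool_size = 471,
                         n_planted_ingredients = 7,
                         planted_degree_boost = 5,
                         zero_probability_fraction = 0.05,
                         intersection_size = 262,
                         universe_size = 8000,
                         disease_sources = list(
                           GeneCards = list(n_genes = 4000, family = "lognormal",
                                            meanlog = 1, sdlog = 1),
                           OMIM = list(n_genes = 900, family = "lognormal",
                                       meanlog = 0, sdlog = 0.8),
                           DisGeNET = list(n_genes = 1100, family = "uniform",
                                           min = 0, max = 1),
                           TTD = list(n_genes = 3, family = "constant")
                         ),
                         ppi = list(n_connected = 222, n_edges = 1205,
                                    n_noise_edges = 600, n_planted_hubs = 10,
                                    hub_degree_boost = 10, threshold = 0.9),
                         annotation = list(
                           n_terms = c(BP = 40, CC = 20, MF = 20, KEGG = 40),
                           term_size_range = c(10, 80),
                           n_planted_terms = c(BP = 1, CC = 1, MF = 1, KEGG = 1),
                           planted_overlap_fraction = 0.6,
                           enriched_fraction = 0.5,
                           enriched_overlap_fraction = 0.2
                         ),
                         peaks = list(noise_ppm = 4.5, outlier_fraction = 0.1,
                                      outlier_ppm_range = c(8, 20))) {
  cfg <- list(
    seed = as.integer(seed), n_compounds = n_compounds,
    targets_per_compound = targets_per_compound,
    compound_pool_size = compound_pool_size,
    n_planted_ingredients = n_planted_ingredients,
    planted_degree_boost = planted_degree_boost,
    zero_probability_fraction = zero_probability_fraction,
    intersection_size = intersection_size,
    universe_size = universe_size,
    disease_sources = disease_sources, ppi = ppi,
    annotation = annotation, peaks = peaks
  )
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  chk <- function(ok, what) if (!ok) stop("infeasible config: ", what, call. = FALSE)
  chk(cfg$n_compounds >= 1, "n_compounds must be >= 1")
  chk(cfg$intersection_size <= cfg$compound_pool_size,
      "intersection_size exceeds compound_pool_size")
  chk(cfg$compound_pool_size < cfg$universe_size,
      "compound pool must leave room for disease-only genes")
  chk(cfg$intersection_size >= cfg$ppi$n_planted_hubs,
      "intersection smaller than the planted hub count")
  chk(cfg$ppi$n_connected <= cfg$intersection_size,
      "ppi n_connected exceeds the therapeutic set")
  chk(cfg$ppi$n_edges <= choose(cfg$ppi$n_connected, 2),
      "ppi n_edges exceeds the number of available pairs")
  chk(cfg$n_planted_ingredients <= cfg$n_compounds,
      "more planted ingredients than compounds")
  chk(all(vapply(cfg$disease_sources, function(s) s$n_genes >= 1, logical(1))),
      "each disease source needs at least one gene")
  const_n <- sum(vapply(cfg$disease_sources,
                        function(s) if (s$family == "constant") s$n_genes else 0,
                        numeric(1)))
  chk(const_n <= cfg$intersection_size,
      "score-less sources cannot exceed the intersection")
  invisible(cfg)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(sub_seed(seed, stream))
  force(expr)
}

#' Molecular formula pool used by the peak generator
#'
#' The formulas of the bundled compound identification table.
#' @return Character vector of formula strings.
#' @export
formula_pool <- function() {
  path <- system.file("extdata", "sparganii_peaks.tsv", package = "phytonet")
  unique(read_peak_table(path)$known_formula)
}

#' Generate a synthetic peak table
#'
#' Formulas are drawn from [formula_pool()]; each observed m/z is the
#' theoretical adduct m/z perturbed by a uniform mass error within
#' `peaks$noise_ppm`, and a configurable fraction of peaks receives an
#' error beyond the fitting tolerance (planted negatives).
#'
#' @param config A [study_config()].
#' @return Tibble with `peak_id`, `rt_min`, `observed_mz`, `polarity`,
#'   `known_formula` plus truth columns `true_adduct` and
#'   `within_tolerance`.
#' @export
generate_peaks <- function(config) {
  with_stream(config$seed, "peaks", {
    n <- config$n_compounds
    pool <- formula_pool()
    formulas <- sample(pool, n, replace = n > length(pool))
    polarity <- sample(c("negative", "positive"), n, replace = TRUE,
                       prob = c(0.7, 0.3))
    adduct <- ifelse(polarity == "negative", "[M-H]-", "[M+H]+")
    theo <- vapply(seq_len(n), function(i) {
      adduct_mz(monoisotopic_mass(formulas[i]), adduct[i])
    }, numeric(1))
    outlier <- stats::runif(n) < config$peaks$outlier_fraction
    eps <- stats::runif(n, -config$peaks$noise_ppm, config$peaks$noise_ppm)
    out_mag <- stats::runif(n, config$peaks$outlier_ppm_range[1],
                            config$peaks$outlier_ppm_range[2])
    eps[outlier] <- (out_mag * sign(stats::runif(n, -1, 1)))[outlier]
    tibble::tibble(
      peak_id = sprintf("SYN%02d", seq_len(n)),
      rt_min = round(sort(stats::runif(n, 0.5, 42)), 2),
      observed_mz = round(theo * (1 + eps * 1e-6), 5),
      polarity = polarity,
      known_formula = formulas,
      true_adduct = adduct,
      within_tolerance = !outlier
    )
  })
}

#' Generate a complete synthetic study with planted ground truth
#'
#' Emits the five input tables of the pipeline (peaks, compound-target
#' predictions, multi-source disease targets, protein-interaction edges,
#' term annotations) together with the planted truth. Constructed
#' guarantees: the therapeutic intersection equals `planted_intersection`
#' exactly; planted ingredients carry `planted_degree_boost` times more
#' therapeutic links than baseline compounds; the interaction layer has
#' exactly `ppi$n_connected` nodes and `ppi$n_edges` edges at or above the
#' threshold, with hubs favoured by `hub_degree_boost`-weighted sampling;
#' planted terms overlap the therapeutic set at
#' `annotation$planted_overlap_fraction`.
#'
#' @param config A [study_config()].
#' @return A list of class `synthetic_study` with elements `peaks`,
#'   `predictions`, `disease`, `ppi`, `annotations` (tibbles), `background`
#'   (character) and `truth` (list).
#' @export
generate_study <- function(config = study_config()) {
  validate_study_config(config)

  universe <- c(HUB_SYMBOLS, sprintf("G%05d", seq_len(config$universe_size - length(HUB_SYMBOLS))))

  gene_sets <- with_stream(config$seed, "genes", {
    planted_hubs <- HUB_SYMBOLS[seq_len(config$ppi$n_planted_hubs)]
    others <- setdiff(universe, planted_hubs)
    intersection <- sort(c(planted_hubs,
                           sample(others, config$intersection_size - length(planted_hubs))))
    pool_extra <- sample(setdiff(universe, intersection),
                         config$compound_pool_size - config$intersection_size)
    list(intersection = intersection,
         compound_pool = sort(c(intersection, pool_extra)),
         planted_hubs = planted_hubs)
  })
  intersection <- gene_sets$intersection
  compound_pool <- gene_sets$compound_pool
  disease_only <- setdiff(universe, compound_pool)

  compounds <- sprintf("CMP%02d", seq_len(config$n_compounds))

  predictions <- with_stream(config$seed, "predictions", {
    planted <- sort(sample(compounds, config$n_planted_ingredients))
    rows <- purrr::map_dfr(compounds, function(cid) {
      t_base <- sample(seq(config$targets_per_compound[1],
                           config$targets_per_compound[2]), 1)
      if (cid %in% planted) {
        k <- min(round(t_base * config$planted_degree_boost), length(intersection))
        genes <- sample(intersection, k)
      } else {
        genes <- sample(compound_pool, min(t_base, length(compound_pool)))
      }
      tibble::tibble(compound_id = cid, gene = genes,
                     probability = round(stats::runif(length(genes), 0.05, 1), 3))
    })
    # guarantee every therapeutic gene is reachable from some compound
    uncovered <- setdiff(intersection, rows$gene)
    if (length(uncovered) > 0) {
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        compound_id = sample(compounds, length(uncovered), replace = TRUE),
        gene = uncovered,
        probability = round(stats::runif(length(uncovered), 0.05, 1), 3)
      ))
    }
    n_zero <- round(nrow(rows) * config$zero_probability_fraction)
    if (n_zero > 0) {
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        compound_id = sample(compounds, n_zero, replace = TRUE),
        gene = sample(compound_pool, n_zero, replace = TRUE),
        probability = 0
      ))
    }
    rows <- dplyr::distinct(rows, .data$compound_id, .data$gene, .keep_all = TRUE)
    list(rows = rows, planted = planted)
  })

  disease <- with_stream(config$seed, "disease", {
    srcs <- config$disease_sources
    # every therapeutic gene must survive screening in at least one scored
    # source (or sit in a score-less source); assign each to one source
    scored <- names(srcs)[vapply(srcs, function(s) s$family != "constant", logical(1))]
    constant <- setdiff(names(srcs), scored)
    const_genes <- character(0)
    assigned <- split(intersection,
                      sample(scored, length(intersection), replace = TRUE))
    if (length(constant) > 0) {
      # curated score-less sources draw their few genes from the intersection
      remaining <- intersection
      for (src in constant) {
        g <- sample(remaining, srcs[[src]]$n_genes)
        assigned[[src]] <- g
        const_genes <- c(const_genes, g)
      }
    }
    purrr::map_dfr(names(srcs), function(src) {
      s <- srcs[[src]]
      planted_genes <- assigned[[src]] %||% character(0)
      if (s$family == "constant") {
        return(tibble::tibble(source = src, gene = planted_genes, score = NA_real_))
      }
      n_bg <- max(s$n_genes - length(planted_genes), 0)
      bg_genes <- sample(disease_only, n_bg)
      bg_scores <- switch(s$family,
        lognormal = stats::rlnorm(n_bg, s$meanlog, s$sdlog),
        uniform = stats::runif(n_bg, s$min, s$max),
        stop("unknown score family: ", s$family, call. = FALSE)
      )
      # planted genes sit at twice the background maximum: always >= the
      # source mean, so the score screen provably keeps the whole stratum
      top <- if (n_bg > 0) max(bg_scores) else 1
      tibble::tibble(
        source = src,
        gene = c(planted_genes, bg_genes),
        score = round(c(rep(top * 2, length(planted_genes)), bg_scores), 4)
      )
    })
  })

  ppi <- with_stream(config$seed, "ppi", {
    p <- config$ppi
    hubs <- gene_sets$planted_hubs
    connected <- sort(c(hubs, sample(setdiff(intersection, hubs),
                                     p$n_connected - length(hubs))))
    w <- ifelse(connected %in% hubs, p$hub_degree_boost, 1)
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
    seen <- new.env(hash = TRUE, parent = emptyenv())
    ea <- character(p$n_edges); eb <- character(p$n_edges); n_e <- 0L
    add_edge <- function(a, b) {
      if (a == b) return(FALSE)
      k <- edge_key(a, b)
      if (!is.null(seen[[k]])) return(FALSE)
      seen[[k]] <- TRUE
      n_e <<- n_e + 1L
      ea[n_e] <<- a; eb[n_e] <<- b
      TRUE
    }
    # coverage pass: every connected gene gets at least one edge
    for (g in sample(connected)) {
      if (n_e >= p$n_edges) break
      if (g %in% c(ea[seq_len(n_e)], eb[seq_len(n_e)])) next
      repeat {
        partner <- sample(connected, 1, prob = w)
        if (add_edge(g, partner)) break
      }
    }
    while (n_e < p$n_edges) {
      pair <- sample(connected, 2, prob = w)
      add_edge(pair[1], pair[2])
    }
    super <- tibble::tibble(
      gene_a = ea, gene_b = eb,
      combined_score = round(stats::runif(p$n_edges, p$threshold, 1), 3)
    )
    noise <- NULL
    if (p$n_noise_edges > 0) {
      na <- sample(intersection, p$n_noise_edges * 2, replace = TRUE)
      nb <- sample(intersection, p$n_noise_edges * 2, replace = TRUE)
      ok <- na != nb & is.na(vapply(edge_key(na, nb),
                                    function(k) if (is.null(seen[[k]])) NA else 1,
                                    numeric(1)))
      keep <- which(ok)[seq_len(min(p$n_noise_edges, sum(ok)))]
      noise <- tibble::tibble(
        gene_a = na[keep], gene_b = nb[keep],
        combined_score = round(stats::runif(length(keep), 0.4,
                                            p$threshold - 0.001), 3)
      )
    }
    list(edges = dplyr::bind_rows(super, noise), connected = connected)
  })

  annotation <- with_stream(config$seed, "annotation", {
    a <- config$annotation
    rows <- list(); truth_terms <- character(0)
    for (cat in names(a$n_terms)) {
      n_cat <- a$n_terms[[cat]]
      n_planted <- a$n_planted_terms[[cat]] %||% 0
      for (i in seq_len(n_cat)) {
        tid <- sprintf("%s%03d", cat, i)
        if (i <= n_planted) {
          size <- a$term_size_range[2]
          k <- round(size * a$planted_overlap_fraction)
          genes <- c(sample(intersection, k),
                     sample(setdiff(universe, intersection), size - k))
          truth_terms <- c(truth_terms, tid)
        } else if (stats::runif(1) < a$enriched_fraction) {
          size <- sample(seq(a$term_size_range[1], a$term_size_range[2]), 1)
          k <- max(1, round(size * a$enriched_overlap_fraction))
          genes <- c(sample(intersection, min(k, length(intersection))),
                     sample(setdiff(universe, intersection), size - k))
        } else {
          size <- sample(seq(a$term_size_range[1], a$term_size_range[2]), 1)
          genes <- sample(universe, size)
        }
        rows[[tid]] <- tibble::tibble(
          term_id = tid, term_name = paste("synthetic term", tid),
          category = cat, gene = unique(genes)
        )
      }
    }
    list(rows = dplyr::bind_rows(rows), planted = truth_terms)
  })

  structure(list(
    peaks = generate_peaks(config),
    predictions = predictions$rows,
    disease = disease,
    ppi = ppi$edges,
    annotations = annotation$rows,
    background = universe,
    truth = list(
      planted_ingredients = predictions$planted,
      planted_hubs = gene_sets$planted_hubs,
      planted_terms = annotation$planted,
      planted_intersection = intersection,
      ppi_connected = ppi$connected
    ),
    config = config
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> seed ", x$config$seed, ": ",
      nrow(x$peaks), " peaks, ", nrow(x$predictions), " predictions, ",
      nrow(x$disease), " disease rows, ", nrow(x$ppi), " PPI rows, ",
      nrow(x$annotations), " annotation rows\n", sep = "")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits exactly the file formats the module readers accept, plus
#' `truth.json` and `background.txt`.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(study$peaks, p("peaks.tsv"))
  readr::write_tsv(study$predictions, p("predictions.tsv"))
  readr::write_tsv(study$disease, p("disease.tsv"))
  readr::write_tsv(study$ppi, p("ppi.tsv"))
  readr::write_tsv(study$annotations, p("annotations.tsv"))
  writeLines(study$background, p("background.txt"))
  jsonlite::write_json(study$truth, p("truth.json"), auto_unbox = FALSE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
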