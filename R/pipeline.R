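#' Build a validated pipeline configuration
#'
#' Accepts a list of settings or a path to a YAML file with the same
#' keys, fills in the documented defaults, and validates the result.
#'
#' Keys (all optional unless noted):
#' \describe{
#'   \item{`psm_path` / `quant_path` / `quant`}{input: a PSM TSV, a long
#'     protein quantification TSV, or an in-memory quantification
#'     data.frame. Exactly one is required.}
#'   \item{`out_dir`}{output directory (required for [run_pipeline()]).}
#'   \item{`channel_labels`, `temperatures_c`}{channel map; default the
#'     TMT10 37-67 gradient.}
#'   \item{`s2i_min`, `p2t_min`}{PSM filter thresholds; defaults 0.5, 4.}
#'   \item{`min_replicates`}{replicate-support requirement; default 2.}
#'   \item{`glog_percentile`}{normalization glog offset percentile;
#'     default 5.}
#'   \item{`form`}{melting-curve parameterization; default
#'     `"reciprocal"`.}
#'   \item{`comparisons`}{list of `list(name, treatment, reference)`;
#'     default: every non-reference condition against the first condition
#'     observed.}
#'   \item{`n_iter`, `seed`}{bootstrap iterations and RNG seed; defaults
#'     500 and 1.}
#'   \item{`criterion`}{hit criterion; default `"dual_fdr_001"`.}
#'   \item{`cluster_k`}{number of profile clusters; default 5.}
#'   \item{`complex_path`}{optional complex-membership TSV.}
#'   \item{`fit_curves`}{fit melting curves; default TRUE.}
#' }
#'
#' @param config list or YAML file path.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(psm_path = NULL, quant_path = NULL, quant = NULL,
                   out_dir = NULL,
                   channel_labels = NULL, temperatures_c = NULL,
                   s2i_min = 0.5, p2t_min = 4, min_replicates = 2,
                   glog_percentile = 5, form = "reciprocal",
                   comparisons = NULL, n_iter = 500, seed = 1,
                   criterion = "dual_fdr_001", cluster_k = 5,
                   complex_path = NULL, fit_curves = TRUE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$channel_labels) != is.null(cfg$temperatures_c)) {
    stop("channel_labels and temperatures_c must be given together")
  }
  cfg$channel_map <- if (is.null(cfg$channel_labels)) {
    default_channel_map()
  } else {
    channel_map(cfg$channel_labels, cfg$temperatures_c)
  }
  n_inputs <- sum(!is.null(cfg$psm_path), !is.null(cfg$quant_path),
                  !is.null(cfg$quant))
  if (n_inputs != 1) {
    stop("exactly one of psm_path, quant_path or quant must be given")
  }
  if (!cfg$criterion %in% c("dual_fdr_001", "z196_fdr005")) {
    stop("unknown hit criterion: ", cfg$criterion)
  }
  if (!cfg$form %in% c("reciprocal", "linear")) {
    stop("unknown curve form: ", cfg$form)
  }
  stopifnot(cfg$n_iter >= 1, cfg$cluster_k >= 2, cfg$min_replicates >= 1)
  if (!is.null(cfg$comparisons)) {
    for (cp in cfg$comparisons) {
      if (!all(c("name", "treatment", "reference") %in% names(cp))) {
        stop("each comparison needs name, treatment and reference")
      }
    }
  }
  structure(cfg, class = "pipeline_config")
}

.log_line <- function(lines, ...) c(lines, paste0(...))

#' Run the full TPP-TR analysis pipeline
#'
#' Executes filter -> aggregate -> replicate support -> normalize ->
#' batch removal -> melting-curve fits -> bootstrap/expression scoring ->
#' hit calling -> profile clustering -> complex co-melting, writing all
#' result tables plus a `run.log` (per-stage counts and the resolved
#' configuration) into `out_dir`.
#'
#' @param config a [pipeline_config()] (or a list/YAML path coercible to
#'   one).
#' @return Invisibly, a named list of written file paths (the manifest),
#'   with the in-memory results in the `"results"` attribute.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (is.null(config$out_dir)) stop("out_dir is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cm <- config$channel_map
  log_lines <- character(0)
  manifest <- list()
  out <- function(name) file.path(config$out_dir, name)

  # --- input stage -----------------------------------------------------
  if (!is.null(config$psm_path)) {
    psms <- read_psm_table(config$psm_path, cm)
    filtered <- filter_psms(psms, config$s2i_min, config$p2t_min)
    fc <- attr(filtered, "filter_counts")
    log_lines <- .log_line(log_lines, "filter_psms: input=", fc["input"],
                           " retained=", fc["retained"],
                           " discarded=", fc["discarded"])
    quant <- aggregate_psms_to_protein(filtered, cm)
    log_lines <- .log_line(log_lines, "aggregate: rows=", nrow(quant))
  } else if (!is.null(config$quant_path)) {
    quant <- read_protein_quant(config$quant_path)
    log_lines <- .log_line(log_lines, "read_quant: rows=", nrow(quant))
  } else {
    quant <- config$quant
    log_lines <- .log_line(log_lines, "in-memory quant: rows=", nrow(quant))
  }

  data_conds <- unique(quant$condition)
  comparisons <- if (is.null(config$comparisons)) {
    lapply(data_conds[-1], function(cond) {
      comparison_def(paste0(cond, "_vs_", data_conds[1]), cond,
                     data_conds[1])
    })
  } else {
    lapply(config$comparisons, function(cp) {
      comparison_def(cp$name, cp$treatment, cp$reference)
    })
  }
  for (cp in comparisons) {
    absent <- setdiff(c(cp$treatment, cp$reference), data_conds)
    if (length(absent) > 0) {
      stop("comparison '", cp$name, "' references condition(s) absent ",
           "from the data: ", paste(absent, collapse = ", "))
    }
  }

  n_before <- nrow(quant)
  quant <- require_replicate_support(quant, config$min_replicates)
  log_lines <- .log_line(log_lines, "replicate_support: rows ", n_before,
                         " -> ", nrow(quant))
  write_results_table(quant, out("quant_filtered.tsv"),
                      sort_by = c("protein_id", "condition", "replicate",
                                  "temperature_c"))
  manifest$quant_filtered <- out("quant_filtered.tsv")

  # --- normalization ---------------------------------------------------
  normalized <- normalize_per_temperature(quant, config$glog_percentile)
  normalized <- remove_batch_effects(normalized)
  n_unadj <- length(attr(normalized, "unadjusted"))
  log_lines <- .log_line(log_lines, "normalize: rows=", nrow(normalized),
                         " batch-unadjusted proteins=", n_unadj)
  write_results_table(normalized, out("normalized.tsv"),
                      sort_by = c("protein_id", "condition", "replicate",
                                  "temperature_c"))
  manifest$normalized <- out("normalized.tsv")

  # --- melting curves --------------------------------------------------
  if (isTRUE(config$fit_curves)) {
    curves <- fit_melting_curves(quant, cm, form = config$form)
    log_lines <- .log_line(log_lines, "curves: fitted=",
                           sum(curves$converged), "/", nrow(curves))
    write_results_table(curves, out("curves.tsv"),
                        sort_by = c("protein_id", "condition", "replicate"))
    manifest$curves <- out("curves.tsv")
  } else {
    curves <- NULL
  }

  # --- scoring ---------------------------------------------------------
  all_scores <- list()
  all_expr <- list()
  for (cp in comparisons) {
    sc <- score_comparison(normalized, cp, cm, n_iter = config$n_iter,
                           seed = config$seed)
    log_lines <- .log_line(log_lines, "score ", cp$name, ": proteins=",
                           length(unique(sc$scores$protein_id)),
                           " skipped=", length(attr(sc$scores, "skipped")))
    all_scores[[cp$name]] <- sc$scores
    all_expr[[cp$name]] <- sc$expression
  }
  scores <- do.call(rbind, all_scores)
  expr <- do.call(rbind, all_expr)
  rownames(scores) <- rownames(expr) <- NULL
  write_results_table(scores, out("scores.tsv"))
  write_results_table(expr, out("expression_scores.tsv"))
  manifest$scores <- out("scores.tsv")
  manifest$expression_scores <- out("expression_scores.tsv")

  hits <- rbind(call_hits(scores, config$criterion),
                call_hits(expr, config$criterion))
  log_lines <- .log_line(log_lines, "hits (", config$criterion, "): ",
                         nrow(hits))
  write_results_table(hits, out("hits.tsv"))
  manifest$hits <- out("hits.tsv")

  # --- clustering of hit ratio profiles --------------------------------
  clusters <- NULL
  hit_ids <- unique(hits$protein_id)
  if (length(hit_ids) >= config$cluster_k) {
    blocks <- lapply(comparisons, function(cp) {
      ratios <- compute_log2_ratios(normalized, cp)
      ratios <- ratios[ratios$protein_id %in% hit_ids, , drop = FALSE]
      if (nrow(ratios) == 0) return(NULL)
      agg <- stats::aggregate(ratio ~ protein_id + temperature_c, ratios,
                              mean, na.action = stats::na.omit)
      m <- matrix(NA_real_, length(hit_ids), length(cm$temperatures_c),
                  dimnames = list(hit_ids,
                                  paste0(cp$name, "_", cm$temperatures_c)))
      m[cbind(match(agg$protein_id, hit_ids),
              match(agg$temperature_c, cm$temperatures_c))] <- agg$ratio
      m
    })
    mat <- do.call(cbind, blocks)
    keep <- rowSums(is.finite(mat)) > 0
    mat <- mat[keep, , drop = FALSE]
    if (nrow(mat) >= config$cluster_k) {
      clusters <- cluster_profiles(mat, k = config$cluster_k)
      log_lines <- .log_line(log_lines, "clusters: ", config$cluster_k,
                             " over ", nrow(mat), " hit proteins")
      write_results_table(clusters, out("clusters.tsv"))
      manifest$clusters <- out("clusters.tsv")
    }
  }
  if (is.null(clusters)) {
    log_lines <- .log_line(log_lines,
                           "clusters: skipped (fewer hit proteins than k)")
  }

  # --- complex co-melting ----------------------------------------------
  comelt <- NULL
  if (!is.null(config$complex_path)) {
    complexes <- read_complex_table(config$complex_path)
    universe <- unique(scores$protein_id)
    comelt <- complex_comelt(intersect(hit_ids, universe), universe,
                             complexes)
    log_lines <- .log_line(log_lines, "comelt: complexes in universe=",
                           nrow(comelt))
    write_results_table(comelt, out("complex_summary.tsv"),
                        sort_by = "complex_id")
    manifest$complex_summary <- out("complex_summary.tsv")
  }

  # --- log + config echo ----------------------------------------------
  echo <- config
  echo$quant <- if (is.null(config$quant)) NULL else "<in-memory data.frame>"
  echo$channel_map <- NULL
  echo$channel_labels <- cm$channel_labels
  echo$temperatures_c <- cm$temperatures_c
  log_lines <- c(log_lines, "", "resolved config:",
                 yaml::as.yaml(echo[!vapply(echo, is.null, logical(1))]))
  writeLines(log_lines, out("run.log"))
  manifest$log <- out("run.log")

  attr(manifest, "results") <- list(quant = quant, normalized = normalized,
                                    curves = curves, scores = scores,
                                    expression = expr, hits = hits,
                                    clusters = clusters, comelt = comelt)
  invisible(manifest)
}
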