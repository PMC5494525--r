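#' Read an integration-site read table
#'
#' Parses the package's TSV dialect for IS read tables: a header line
#' \code{chrom pos strand tumor_id enzyme reads}, 1-based positions,
#' strands \code{+}/\code{-}. Malformed rows are rejected with
#' line-numbered errors.
#'
#' @param path Path to a tab-separated file.
#' @return Data frame of IS read records.
#' @export
read_is_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE, quote = "")
  need <- c("chrom", "pos", "strand", "tumor_id", "enzyme", "reads")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  if (nrow(df) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), tumor_id = character(0),
                      enzyme = character(0), reads = integer(0)))
  # normalize the unicode minus occasionally found in strand columns
  df$strand <- gsub("−", "-", df$strand)
  line <- seq_len(nrow(df)) + 1L         # header is line 1
  pos <- suppressWarnings(as.integer(df$pos))
  bad <- which(is.na(pos) | pos < 1)
  if (length(bad) > 0)
    stop("line ", bad[1] + 1L, ": position must be an integer >= 1 (got '",
         df$pos[bad[1]], "')")
  reads <- suppressWarnings(as.integer(df$reads))
  bad <- which(is.na(reads) | reads < 0)
  if (length(bad) > 0)
    stop("line ", bad[1] + 1L, ": read count must be a non-negative integer (got '",
         df$reads[bad[1]], "')")
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad) > 0)
    stop("line ", bad[1] + 1L, ": strand must be '+' or '-' (got '",
         df$strand[bad[1]], "')")
  data.frame(chrom = df$chrom, pos = pos, strand = df$strand,
             tumor_id = df$tumor_id, enzyme = df$enzyme, reads = reads,
             stringsAsFactors = FALSE)
}

#' Write an integration-site read table
#'
#' @param records IS read records (columns \code{chrom}, \code{pos},
#'   \code{strand}, \code{tumor_id}, \code{enzyme}, \code{reads}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_is_table <- function(records, path) {
  check_is_records(records)
  utils::write.table(records[, c("chrom", "pos", "strand", "tumor_id",
                                 "enzyme", "reads")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export integration sites as a BED file
#'
#' Converts 1-based IS positions to BED's 0-based half-open intervals
#' (start = pos - 1, end = pos) for genome-browser use.
#'
#' @param records IS read records.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_is_bed <- function(records, path) {
  check_is_records(records)
  u <- records[!duplicated(is_id_of(records$chrom, records$pos,
                                    records$strand)), , drop = FALSE]
  bed <- data.frame(chrom = u$chrom, start = u$pos - 1L, end = u$pos,
                    name = is_id_of(u$chrom, u$pos, u$strand),
                    score = 0L, strand = u$strand)
  utils::write.table(bed[order(chrom_rank(bed$chrom), bed$start), ],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read or write a transplant-design table
#'
#' TSV with one row per tumor: \code{tumor_id}, \code{patient},
#' \code{experiment}, \code{generation}, \code{parent_tumor} (empty for
#' roots), \code{site}, \code{n_cells_injected},
#' \code{transduction_efficiency}, \code{fraction_sampled_for_is},
#' \code{fraction_retransplanted}.
#'
#' @param path File path.
#' @return \code{read_transplant_design}: the design data frame.
#' @export
read_transplant_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  df$parent_tumor[df$parent_tumor %in% c("", "NA")] <- NA_character_
  df$generation <- as.integer(df$generation)
  generation_annotation(df[, c("tumor_id", "patient", "experiment",
                               "generation", "parent_tumor")])
  df
}

#' @param design Transplant-design data frame.
#' @rdname read_transplant_design
#' @export
write_transplant_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' JSON configuration with top-level sections \code{simulate},
#' \code{filter}, \code{metrics}, \code{infer} and \code{lda}; unknown
#' top-level keys are rejected.
#'
#' @param path Path to a JSON file.
#' @return Named list of configuration sections.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("simulate", "filter", "metrics", "infer", "lda", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "))
  cfg
}

config_from_list <- function(sim) {
  args <- sim[setdiff(names(sim), c("growth", "plan"))]
  if (!is.null(sim$growth))
    args$growth <- do.call(birth_params, as.list(sim$growth))
  if (!is.null(sim$plan))
    args$plan <- do.call(sampling_plan, as.list(sim$plan))
  do.call(simulation_config, args)
}

#' Run the analysis pipeline end to end
#'
#' Executes the stages in fixed order -- simulate (or load IS tables),
#' filter, metrics, infer, lda -- logging each stage to standard error and
#' writing JSON reports plus a provenance manifest (config hash and root
#' seed) to \code{out_dir}.
#'
#' @param config Configuration list (see [read_pipeline_config()]), or a
#'   path to a JSON configuration file.
#' @param out_dir Output directory, created if needed.
#' @param seed Root seed; overrides \code{config$seed} if given.
#' @return Invisible list with the stage outputs (experiment record,
#'   contribution matrix, succession summary, inference report, LDA
#'   report, manifest).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) config$seed <- 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...)
    message(sprintf("[%s] %s", stage, sprintf(...)))

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  # -- simulate ------------------------------------------------------------
  sim_cfg <- config$simulate
  if (is.null(sim_cfg)) sim_cfg <- list()
  sim_cfg$seed <- config$seed
  sconfig <- config_from_list(sim_cfg)
  log_stage("simulate", "scenario '%s', seed %d", sconfig$scenario,
            as.integer(config$seed))
  record <- simulate_serial_experiment(sconfig)
  write_is_table(record$is_tables, file.path(out_dir, "is_tables.tsv"))
  write_transplant_design(record$design, file.path(out_dir, "design.tsv"))
  log_stage("simulate", "%d tumors, %d IS read rows", nrow(record$design),
            nrow(record$is_tables))

  # -- filter --------------------------------------------------------------
  cutoff <- if (!is.null(config$filter$cutoff)) config$filter$cutoff else 6e-4
  grouping <- stats::setNames(record$design$experiment, record$design$tumor_id)
  cm <- process_is_records(record$is_tables, grouping, cutoff = cutoff,
                           tumor_order = record$design$tumor_id)
  log_stage("filter", "cutoff %.4g%%: %d IS x %d tumors", 100 * cutoff,
            length(cm$is_ids), length(cm$tumor_ids))

  # -- metrics -------------------------------------------------------------
  annotation <- generation_annotation(record$design)
  summary <- succession_summary(cm, annotation)
  jsonlite::write_json(
    list(total_is = summary$counts$total,
         per_tumor_is = as.list(summary$counts$per_tumor),
         generation_exclusive_fraction = summary$generation_exclusive_fraction,
         detected_once = summary$detected_once,
         dominant_nonpersistent_fraction = summary$dominant_nonpersistent_fraction,
         prior_generation_fraction = as.list(summary$prior_generation_fraction),
         pairwise_overlap = summary$pairwise_overlap),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    na = "null", pretty = TRUE)
  log_stage("metrics", "%d distinct IS, %.0f%% generation-exclusive",
            summary$counts$total, 100 * summary$generation_exclusive_fraction)

  # -- infer ---------------------------------------------------------------
  icfg <- config$infer
  q_true <- sconfig$growth$q
  rect <- nuisance_rectangle(
    q_interval = if (!is.null(icfg$q_interval)) icfg$q_interval
                 else pmin(1, pmax(1e-12, c(q_true / 3, q_true * 3))),
    f_interval = if (!is.null(icfg$f_interval)) icfg$f_interval
                 else c(0.03, 0.30))
  primary <- record$design$tumor_id[record$design$generation == 1L][1]
  k_obs <- sum(cm$detected[, primary])
  tumor_size <- record$truth[[primary]]$total_cells
  bound <- upper_bound_total_clones(k_obs, rect, sconfig$plan, tumor_size)
  n_marked <- nrow(record$founders)
  eff <- seeding_efficiency(bound, n_marked)
  shares <- cm$contribution[cm$detected[, primary], primary]
  total_sampled <- sum(record$truth[[primary]]$clones$sampled)
  mc <- if (!is.null(icfg$mc_replicates)) icfg$mc_replicates else 500
  h0p1 <- test_equal_proliferation(shares, total_sampled, rect,
                                   mc_replicates = mc, seed = config$seed)
  infer_report <- list(
    primary_tumor = primary, k_observed = k_obs,
    n_upper_99 = bound$n_upper,
    seeding_efficiency_pct = eff$interval_pct,
    equal_proliferation_p = h0p1$p_supremum)
  jsonlite::write_json(infer_report, file.path(out_dir, "inference.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("infer", "k=%d, n_upper=%d, H0,P1 sup-p=%.3f", k_obs,
            bound$n_upper, h0p1$p_supremum)

  # -- lda (optional) ------------------------------------------------------
  lda_report <- NULL
  if (!is.null(config$lda)) {
    tab <- config$lda
    fit <- fit_single_hit(lda_table(tab$dose, tab$tested, tab$positive))
    lda_report <- list(frequency_denominator = fit$frequency_denominator,
                       ci95_denominator = fit$ci95)
    jsonlite::write_json(lda_report, file.path(out_dir, "lda.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_stage("lda", "TIC frequency 1 in %s",
              format(fit$frequency_denominator, big.mark = ","))
  }

  manifest <- list(config_hash = cfg_hash, seed = config$seed,
                   stages = c("simulate", "filter", "metrics", "infer",
                              if (!is.null(lda_report)) "lda"),
                   outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(record = record, matrix = cm, summary = summary,
                 inference = infer_report, lda = lda_report,
                 manifest = manifest))
}
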