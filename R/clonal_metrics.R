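#' Generation annotation of xenograft tumors
#'
#' Validates and classes the per-tumor annotation used by all succession
#' metrics: patient, experiment lineage, serial generation, and the parent
#' tumor each inoculum came from.
#'
#' @param df Data frame with columns \code{tumor_id}, \code{patient},
#'   \code{experiment}, \code{generation}, \code{parent_tumor} (NA for
#'   roots). The transplant-design table of an
#'   [simulate_serial_experiment()] record qualifies directly.
#' @return The validated data frame with class \code{"generation_annotation"}.
#' @export
generation_annotation <- function(df) {
  need <- c("tumor_id", "patient", "experiment", "generation", "parent_tumor")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  if (anyDuplicated(df$tumor_id)) stop("duplicate tumor_id in annotation")
  roots <- is.na(df$parent_tumor)
  if (any(df$generation[roots] != 1L))
    stop("root tumors (no parent) must be generation 1")
  pg <- df$generation[match(df$parent_tumor[!roots], df$tumor_id)]
  if (any(is.na(pg)) || any(pg != df$generation[!roots] - 1L))
    stop("parent's generation must equal generation - 1")
  class(df) <- c("generation_annotation", "data.frame")
  df
}

check_annotation <- function(cm, annotation) {
  stopifnot(inherits(cm, "contribution_matrix"),
            inherits(annotation, "generation_annotation"))
  miss <- setdiff(cm$tumor_ids, annotation$tumor_id)
  if (length(miss) > 0)
    stop("annotation does not cover tumors: ", paste(miss, collapse = ", "))
  annotation[match(cm$tumor_ids, annotation$tumor_id), , drop = FALSE]
}

#' Count distinct integration sites
#'
#' Distinct IS counted once per scope: overall, per patient, and per tumor.
#'
#' @param cm A [build_contribution_matrix()] object.
#' @param annotation A [generation_annotation()].
#' @return List with \code{total}, \code{per_patient} (named vector) and
#'   \code{per_tumor} (named vector).
#' @export
is_counts <- function(cm, annotation) {
  ann <- check_annotation(cm, annotation)
  det <- cm$detected
  per_tumor <- colSums(det)
  per_patient <- vapply(split(seq_along(cm$tumor_ids), ann$patient),
                        function(j) sum(rowSums(det[, j, drop = FALSE]) > 0),
                        integer(1))
  list(total = sum(rowSums(det) > 0), per_patient = per_patient,
       per_tumor = per_tumor)
}

# generations in which each IS is detected (list of integer vectors)
detected_generations <- function(cm, ann) {
  apply(cm$detected, 1L, function(d) unique(ann$generation[d]),
        simplify = FALSE)
}

#' Fraction of IS detected exclusively in a single generation
#'
#' Fraction of distinct IS whose detections all fall in tumors of one
#' serial generation (the study's measure of clonal turnover between
#' generations).
#'
#' @inheritParams is_counts
#' @return A fraction in \[0, 1\].
#' @export
generation_exclusive_fraction <- function(cm, annotation) {
  ann <- check_annotation(cm, annotation)
  gens <- detected_generations(cm, ann)
  n_det <- vapply(gens, length, integer(1))
  if (sum(n_det > 0) == 0) stop("no detected IS")
  mean(n_det[n_det > 0] == 1L)
}

#' Fraction of IS detected in exactly one tumor
#'
#' Overall: fraction of distinct detected IS present in exactly one tumor.
#' Per generation g: among IS detected in generation-g tumors, the fraction
#' whose single overall detection lies in generation g.
#'
#' @inheritParams is_counts
#' @return List with \code{overall} and \code{per_generation} (named
#'   vector).
#' @export
detected_once_fraction <- function(cm, annotation) {
  ann <- check_annotation(cm, annotation)
  det <- cm$detected
  n_tumors <- rowSums(det)
  if (sum(n_tumors > 0) == 0) stop("no detected IS")
  overall <- mean(n_tumors[n_tumors > 0] == 1L)
  gens <- sort(unique(ann$generation))
  per_gen <- vapply(gens, function(g) {
    in_g <- rowSums(det[, ann$generation == g, drop = FALSE]) > 0
    if (!any(in_g)) return(NA_real_)
    mean(n_tumors[in_g] == 1L)
  }, numeric(1))
  names(per_gen) <- paste0("gen", gens)
  list(overall = overall, per_generation = per_gen)
}

#' Fraction of dominant clones confined to a single generation
#'
#' Among IS that reach a contribution of at least \code{dominance}
#' (default 50% of sequenced reads) in at least one tumor, the fraction
#' never detected outside the generation(s) where they were detected --
#' i.e. strongly contributing clones that did not persist across
#' generations.
#'
#' @inheritParams is_counts
#' @param dominance Contribution threshold in (0, 1\] defining a dominant
#'   clone.
#' @return A fraction, or \code{NA} if no IS reaches dominance.
#' @export
dominant_nonpersistent_fraction <- function(cm, annotation, dominance = 0.5) {
  stopifnot(dominance > 0, dominance <= 1)
  ann <- check_annotation(cm, annotation)
  dominant <- rowSums(cm$contribution >= dominance) > 0
  if (!any(dominant)) return(NA_real_)
  gens <- detected_generations(cm, ann)
  n_gens <- vapply(gens, length, integer(1))
  mean(n_gens[dominant] == 1L)
}

#' Fraction of serial-tumor clones already active in the primary tumor
#'
#' Per experiment lineage: among IS detected in its secondary or tertiary
#' tumors, the fraction also detected in that experiment's primary
#' tumor(s). Experiments without serial tumors are reported as \code{NA}.
#'
#' @inheritParams is_counts
#' @return Named numeric vector, one entry per experiment.
#' @export
prior_generation_fraction <- function(cm, annotation) {
  ann <- check_annotation(cm, annotation)
  det <- cm$detected
  exps <- sort(unique(ann$experiment))
  out <- vapply(exps, function(e) {
    sel <- ann$experiment == e
    if (max(ann$generation[sel]) < 2L) return(NA_real_)
    serial <- rowSums(det[, sel & ann$generation >= 2L, drop = FALSE]) > 0
    if (!any(serial)) return(NA_real_)
    primary <- rowSums(det[, sel & ann$generation == 1L, drop = FALSE]) > 0
    mean(primary[serial])
  }, numeric(1))
  names(out) <- exps
  out
}

#' Pairwise clone overlap between sibling tumors
#'
#' For tumors transplanted from the same donor tumor, the shared-IS
#' fraction per pair: |shared| / |union| (Jaccard, default) or
#' |shared| / |smaller set|.
#'
#' @inheritParams is_counts
#' @param denominator \code{"union"} (Jaccard) or \code{"smaller"}.
#' @return Data frame with columns \code{tumor_a}, \code{tumor_b},
#'   \code{parent}, \code{overlap}; zero rows if no sibling pairs exist.
#' @export
pairwise_overlap <- function(cm, annotation,
                             denominator = c("union", "smaller")) {
  denominator <- match.arg(denominator)
  ann <- check_annotation(cm, annotation)
  det <- cm$detected
  out <- list()
  for (p in unique(stats::na.omit(ann$parent_tumor))) {
    sibs <- which(!is.na(ann$parent_tumor) & ann$parent_tumor == p)
    if (length(sibs) < 2) next
    for (i in seq_along(sibs)[-length(sibs)]) for (j in seq((i + 1), length(sibs))) {
      a <- det[, sibs[i]]; b <- det[, sibs[j]]
      den <- if (denominator == "union") sum(a | b)
             else min(sum(a), sum(b))
      out[[length(out) + 1L]] <- data.frame(
        tumor_a = cm$tumor_ids[sibs[i]], tumor_b = cm$tumor_ids[sibs[j]],
        parent = p,
        overlap = if (den == 0) 0 else sum(a & b) / den,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(tumor_a = character(0), tumor_b = character(0),
                      parent = character(0), overlap = numeric(0)))
  do.call(rbind, out)
}

#' Summary of clonal-succession statistics
#'
#' Computes all succession metrics in one pass: IS counts, generation
#' exclusivity, detected-once fractions, dominant-clone persistence,
#' prior-generation fractions, and sibling-pair overlaps.
#'
#' @inheritParams dominant_nonpersistent_fraction
#' @param overlap_denominator Passed to [pairwise_overlap()].
#' @return Object of class \code{"succession_summary"}.
#' @export
succession_summary <- function(cm, annotation, dominance = 0.5,
                               overlap_denominator = "union") {
  structure(list(
    counts = is_counts(cm, annotation),
    generation_exclusive_fraction = generation_exclusive_fraction(cm, annotation),
    detected_once = detected_once_fraction(cm, annotation),
    dominant_nonpersistent_fraction =
      dominant_nonpersistent_fraction(cm, annotation, dominance),
    prior_generation_fraction = prior_generation_fraction(cm, annotation),
    pairwise_overlap = pairwise_overlap(cm, annotation, overlap_denominator),
    dominance = dominance), class = "succession_summary")
}

#' @export
print.succession_summary <- function(x, ...) {
  cat(sprintf("Distinct IS: %d\n", x$counts$total))
  cat(sprintf("Generation-exclusive IS: %.1f%%\n",
              100 * x$generation_exclusive_fraction))
  cat(sprintf("Detected once: %.1f%% overall (%s)\n",
              100 * x$detected_once$overall,
              paste(sprintf("%s: %.0f%%", names(x$detected_once$per_generation),
                            100 * x$detected_once$per_generation),
                    collapse = "; ")))
  if (!is.na(x$dominant_nonpersistent_fraction))
    cat(sprintf("Dominant (>=%.0f%%) clones confined to one generation: %.1f%%\n",
                100 * x$dominance, 100 * x$dominant_nonpersistent_fraction))
  pg <- x$prior_generation_fraction
  cat(sprintf("Serial-tumor clones already in primary: %s\n",
              paste(sprintf("%s: %.0f%%", names(pg), 100 * pg), collapse = "; ")))
  if (nrow(x$pairwise_overlap) > 0)
    cat(sprintf("Sibling overlap: %.0f-%.0f%%\n",
                100 * min(x$pairwise_overlap$overlap),
                100 * max(x$pairwise_overlap$overlap)))
  invisible(x)
}
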