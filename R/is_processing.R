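#' Merge the two restriction-enzyme replicates of an IS read table
#'
#' LAM-PCR is run twice per sample with different restriction enzymes
#' (TSP509I, MSEI) to enlarge genomic coverage. This step takes the union
#' of IS calls over enzymes per tumor and sums the replicate read counts;
#' relative abundances are recomputed per tumor over the merged totals.
#'
#' @param records Data frame of IS read records with columns \code{chrom},
#'   \code{pos}, \code{strand}, \code{tumor_id}, \code{enzyme},
#'   \code{reads}.
#' @return Data frame with columns \code{is_id}, \code{chrom}, \code{pos},
#'   \code{strand}, \code{tumor_id}, \code{reads} (merged) and \code{share}
#'   (merged read fraction within the tumor).
#' @export
merge_enzyme_replicates <- function(records) {
  check_is_records(records)
  is_id <- is_id_of(records$chrom, records$pos, records$strand)
  key <- paste(is_id, records$tumor_id, records$enzyme, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (IS, tumor, enzyme) rows; ambiguous input")
  grp <- paste(is_id, records$tumor_id, sep = "\r")
  agg <- rowsum(records$reads, grp)
  first <- !duplicated(grp)
  out <- data.frame(is_id = is_id[first], chrom = records$chrom[first],
                    pos = records$pos[first], strand = records$strand[first],
                    tumor_id = records$tumor_id[first],
                    reads = agg[match(grp[first], rownames(agg)), 1L],
                    stringsAsFactors = FALSE, row.names = NULL)
  tot <- tapply(out$reads, out$tumor_id, sum)
  out$share <- out$reads / as.numeric(tot[out$tumor_id])
  out[order(out$tumor_id, chrom_rank(out$chrom), out$pos, out$strand), ,
      drop = FALSE]
}

#' Remove IS calls below the relative-abundance cutoff
#'
#' IS whose read share within a tumor falls below the cutoff (default
#' 0.06% of total sequence counts) are removed from that tumor. Shares are
#' computed against the tumor's pre-filter read total, so the operation is
#' idempotent.
#'
#' @param merged Output of [merge_enzyme_replicates()] (or any table with
#'   \code{is_id}, \code{tumor_id}, \code{reads}).
#' @param cutoff Minimum read share in (0, 1); default 0.0006.
#' @return The filtered table, with \code{share} recomputed against the
#'   pre-filter per-tumor totals.
#' @export
apply_abundance_cutoff <- function(merged, cutoff = 6e-4) {
  stopifnot(is.data.frame(merged),
            all(c("is_id", "tumor_id", "reads") %in% names(merged)))
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 || cutoff >= 1)
    stop("cutoff must be a single number in (0, 1)")
  if (nrow(merged) == 0) return(merged)
  tot <- tapply(merged$reads, merged$tumor_id, sum)
  if (any(tot <= 0)) stop("per-tumor read totals must be positive")
  share <- merged$reads / as.numeric(tot[merged$tumor_id])
  out <- merged[share >= cutoff - 1e-12, , drop = FALSE]
  out$share <- out$reads / as.numeric(tot[out$tumor_id])
  rownames(out) <- NULL
  out
}

#' Remove cross-lineage collision IS occurrences
#'
#' The same genomic IS coordinate appearing in tumors from independent
#' experiment lineages (different patients/experiments) is a collision -- a
#' cross-contamination signature, since independent transductions cannot
#' share an exact integration coordinate. Collision occurrences below the
#' abundance cutoff are removed; occurrences at or above the cutoff in
#' their own lineage are retained. Within-lineage recurrence is the
#' biological signal and is never removed.
#'
#' @param counts Table with \code{is_id}, \code{tumor_id}, \code{reads}
#'   (typically merged counts; may contain below-cutoff rows).
#' @param grouping Named character vector mapping \code{tumor_id} to an
#'   experiment lineage.
#' @param cutoff Read-share threshold classifying an occurrence as
#'   below-cutoff; default 0.0006.
#' @return The cleaned table.
#' @export
remove_collisions <- function(counts, grouping, cutoff = 6e-4) {
  stopifnot(is.data.frame(counts),
            all(c("is_id", "tumor_id", "reads") %in% names(counts)))
  if (nrow(counts) == 0) return(counts)
  unmapped <- setdiff(unique(counts$tumor_id), names(grouping))
  if (length(unmapped) > 0)
    stop("tumors not mapped to an experiment lineage: ",
         paste(unmapped, collapse = ", "))
  lineage <- as.character(grouping[counts$tumor_id])
  n_lineages <- tapply(lineage, counts$is_id, function(z) length(unique(z)))
  collision <- as.numeric(n_lineages[counts$is_id]) > 1
  tot <- tapply(counts$reads, counts$tumor_id, sum)
  share <- counts$reads / as.numeric(tot[counts$tumor_id])
  drop <- collision & share < cutoff - 1e-12
  out <- counts[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the IS-by-tumor contribution matrix
#'
#' Converts a cleaned count table to the matrix representation used by all
#' succession metrics: rows are integration sites ordered by genomic
#' coordinate, columns are tumors, entries are relative read contributions
#' renormalized per tumor over the surviving IS, with a parallel logical
#' detection matrix.
#'
#' @param cleaned Cleaned count table with \code{is_id}, \code{chrom},
#'   \code{pos}, \code{strand}, \code{tumor_id}, \code{reads}.
#' @param tumor_order Optional explicit column order; defaults to sorted
#'   tumor ids (the transplant design's patient/generation/tumor ordering
#'   when ids encode it, as the generator's do).
#' @return An object of class \code{"contribution_matrix"}: list with
#'   \code{contribution} (numeric matrix), \code{detected} (logical
#'   matrix), \code{is_ids}, \code{tumor_ids}, and \code{empty_tumors}
#'   (tumors retained as all-undetected columns).
#' @export
build_contribution_matrix <- function(cleaned, tumor_order = NULL) {
  stopifnot(is.data.frame(cleaned),
            all(c("is_id", "chrom", "pos", "strand", "tumor_id", "reads")
                %in% names(cleaned)))
  if (nrow(cleaned) == 0) stop("cleaned count table is empty")
  first <- !duplicated(cleaned$is_id)
  ord <- order(chrom_rank(cleaned$chrom[first]), cleaned$pos[first],
               cleaned$strand[first])
  is_ids <- cleaned$is_id[first][ord]
  tumor_ids <- if (is.null(tumor_order)) sort(unique(cleaned$tumor_id))
               else tumor_order
  if (!all(cleaned$tumor_id %in% tumor_ids))
    stop("tumor_order does not cover all tumors in the table")
  contribution <- matrix(0, nrow = length(is_ids), ncol = length(tumor_ids),
                         dimnames = list(is_ids, tumor_ids))
  contribution[cbind(match(cleaned$is_id, is_ids),
                     match(cleaned$tumor_id, tumor_ids))] <- cleaned$reads
  tot <- colSums(contribution)
  empty <- tumor_ids[tot == 0]
  nz <- tot > 0
  contribution[, nz] <- sweep(contribution[, nz, drop = FALSE], 2L,
                              tot[nz], "/")
  structure(list(contribution = contribution, detected = contribution > 0,
                 is_ids = is_ids, tumor_ids = tumor_ids,
                 empty_tumors = empty),
            class = "contribution_matrix")
}

#' @export
print.contribution_matrix <- function(x, ...) {
  cat(sprintf("Contribution matrix: %d IS x %d tumors (%d detections)\n",
              length(x$is_ids), length(x$tumor_ids), sum(x$detected)))
  if (length(x$empty_tumors) > 0)
    cat("tumors with no surviving IS:", paste(x$empty_tumors, collapse = ", "), "\n")
  invisible(x)
}

#' Run the full IS-processing pipeline
#'
#' Fixed stage order (part of the contract, since permuting merging and
#' thresholding changes results): merge enzyme replicates, apply the
#' relative-abundance cutoff, remove cross-lineage collisions, build the
#' contribution matrix.
#'
#' @param records IS read records (see [merge_enzyme_replicates()]).
#' @param grouping Named vector mapping tumor_id to experiment lineage.
#' @param cutoff Relative-abundance cutoff, default 0.0006.
#' @param tumor_order Optional column order for the matrix.
#' @return A [build_contribution_matrix()] object.
#' @export
process_is_records <- function(records, grouping, cutoff = 6e-4,
                               tumor_order = NULL) {
  merged <- merge_enzyme_replicates(records)
  filtered <- apply_abundance_cutoff(merged, cutoff)
  cleaned <- remove_collisions(filtered, grouping, cutoff)
  build_contribution_matrix(cleaned, tumor_order)
}

check_is_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("chrom", "pos", "strand", "tumor_id", "enzyme", "reads")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop("missing IS record columns: ", paste(miss, collapse = ", "))
  if (nrow(records) > 0) {
    if (any(records$pos < 1)) stop("positions must be >= 1")
    if (any(records$reads < 0)) stop("read counts must be >= 0")
    if (!all(records$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
  }
  invisible(records)
}
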