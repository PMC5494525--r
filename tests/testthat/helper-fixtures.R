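# shared fixtures: built in code, no files

# one default-parameter succession experiment, computed once per test run
.fixture_env <- new.env(parent = emptyenv())

default_record <- function(seed = 42L) {
  key <- paste0("rec", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <-
      simulate_serial_experiment(simulation_config(seed = seed))
  }
  .fixture_env[[key]]
}

record_matrix <- function(record, cutoff = 6e-4) {
  grouping <- stats::setNames(record$design$experiment,
                              record$design$tumor_id)
  process_is_records(record$is_tables, grouping, cutoff = cutoff,
                     tumor_order = record$design$tumor_id)
}

# minimal hand-built IS record table
mk_records <- function(chrom, pos, strand, tumor_id, enzyme, reads) {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             tumor_id = tumor_id, enzyme = enzyme,
             reads = as.integer(reads), stringsAsFactors = FALSE)
}

# annotation for a hand-built three-generation, one-experiment design
toy_annotation <- function(tumors = c("T1", "T2", "T3"),
                           generations = c(1L, 2L, 3L),
                           parents = c(NA, "T1", "T2"),
                           experiment = "E1", patient = "P1") {
  generation_annotation(data.frame(
    tumor_id = tumors, patient = patient, experiment = experiment,
    generation = generations, parent_tumor = parents,
    stringsAsFactors = FALSE))
}

# build a contribution matrix directly from a detection/read layout:
# reads is an IS x tumor matrix of read counts
toy_matrix <- function(reads, tumors = colnames(reads)) {
  is_n <- nrow(reads)
  rec <- do.call(rbind, lapply(seq_len(ncol(reads)), function(j) {
    nz <- which(reads[, j] > 0)
    if (length(nz) == 0) return(NULL)
    data.frame(is_id = paste0("1:", nz * 100, ":+"), chrom = "1",
               pos = nz * 100, strand = "+", tumor_id = tumors[j],
               reads = reads[nz, j], stringsAsFactors = FALSE)
  }))
  build_contribution_matrix(rec, tumor_order = tumors)
}

# the eight printed limiting-dilution dose-response tables
lda_doses <- c(1e4, 1e3, 1e2, 10, 1)
lda_tables_printed <- list(
  list(label = "P2-a serum-free", positive = c(2, 0, 1, 0, 0),
       tested = c(4, 4, 4, 4, 4), denominator = 10965),
  list(label = "P2-a FBS", positive = c(4, 1, 0, 0, 0),
       tested = c(4, 3, 4, 4, 3), denominator = 2341),
  list(label = "P2-b serum-free", positive = c(3, 0, 0, 0, 0),
       tested = c(4, 2, 3, 4, 4), denominator = 8113),
  list(label = "P2-b FBS", positive = c(2, 0, 0, 0, 0),
       tested = c(4, 2, 4, 4, 3), denominator = 15694),
  list(label = "P3-a serum-free", positive = c(4, 4, 2, 1, 0),
       tested = c(4, 4, 4, 4, 4), denominator = 108),
  list(label = "P3-a FBS", positive = c(4, 3, 2, 0, 0),
       tested = c(4, 3, 4, 4, 4), denominator = 164),
  list(label = "P3-b serum-free", positive = c(4, 4, 3, 2, 0),
       tested = c(4, 4, 4, 4, 4), denominator = 47),
  list(label = "P3-b FBS", positive = c(4, 4, 4, 1, 0),
       tested = c(4, 4, 4, 4, 4), denominator = 28))
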