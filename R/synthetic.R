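#' Configuration of a synthetic serial-xenotransplantation experiment
#'
#' Bundles every knob of the generator that emulates the study design:
#' lentiviral marking of cultured cells, engraftment of a small fraction of
#' marked cells, clone growth by a Yule process, serial re-transplantation
#' over three mouse generations, and integration-site read tables from a
#' subsampled aliquot sequenced in two restriction-enzyme replicates.
#'
#' Clone activity is modeled as a clone-intrinsic state
#' (dormant / active / exhausted) advanced once per transplant epoch:
#' \itemize{
#'   \item \code{succession}: an active clone is exhausted with probability
#'     \code{p_inactivate} per epoch (its non-tumorigenic progeny die out in
#'     the recipient); a dormant clone activates with probability
#'     \code{p_activate} and then regrows from a single re-initiating cell.
#'     Exhausted clones never reactivate.
#'   \item \code{hierarchy}: only clones flagged as long-term TICs (fraction
#'     \code{ltic_fraction} of engrafted clones) drive growth; they stay
#'     active every generation (subject to \code{p_inactivate}).
#'   \item \code{stochastic}: every clone present is active in a given
#'     generation independently with probability \code{p_activate}.
#' }
#'
#' @param n_cells_transplanted Cells transplanted into the primary mouse.
#' @param transduction_efficiency Fraction of cells carrying a vector mark
#'   (study range 0.355--0.975).
#' @param seeding_prob Per-marked-cell probability of engrafting in the
#'   primary recipient.
#' @param growth [birth_params()] for active-clone growth per generation.
#' @param generations Number of serial generations (primary = 1).
#' @param mice_per_generation Recipient mice per transplanted tumor.
#' @param fraction_retransplanted Fraction of a tumor's cells injected into
#'   each daughter mouse (study range 0.33--0.50).
#' @param plan [sampling_plan()] for the IS-analysis aliquot (study sampled
#'   3--30% of cells; cutoff 0.06% of reads).
#' @param scenario One of \code{"succession"}, \code{"hierarchy"},
#'   \code{"stochastic"}.
#' @param p_inactivate Probability an active clone is exhausted after one
#'   epoch.
#' @param p_activate Probability a dormant clone activates at an epoch.
#' @param ltic_fraction Fraction of clones with persistent self-renewal
#'   (hierarchy scenario only).
#' @param enzyme_dropout Probability an IS is missed in one of the two
#'   enzyme replicates.
#' @param seed Integer seed; fixed seeds give byte-identical experiments.
#' @param size_guard Abort threshold on total tumor cell count.
#' @return An object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_cells_transplanted = 1e5,
                              transduction_efficiency = 0.6,
                              seeding_prob = 0.003,
                              growth = birth_params(1, 12),
                              generations = 3L,
                              mice_per_generation = 2L,
                              fraction_retransplanted = 0.4,
                              plan = sampling_plan(0.1, read_depth = 1e4, cutoff = 6e-4),
                              scenario = c("succession", "hierarchy", "stochastic"),
                              p_inactivate = 0.75,
                              p_activate = 0.06,
                              ltic_fraction = 0.05,
                              enzyme_dropout = 0.05,
                              seed = NULL,
                              size_guard = 1e9) {
  scenario <- match.arg(scenario)
  stopifnot(n_cells_transplanted >= 1,
            transduction_efficiency >= 0, transduction_efficiency <= 1,
            seeding_prob >= 0, seeding_prob <= 1,
            inherits(growth, "birth_params"),
            generations >= 1, mice_per_generation >= 1,
            fraction_retransplanted > 0, fraction_retransplanted <= 1,
            inherits(plan, "sampling_plan"),
            p_inactivate >= 0, p_inactivate <= 1,
            p_activate >= 0, p_activate <= 1,
            ltic_fraction >= 0, ltic_fraction <= 1,
            enzyme_dropout >= 0, enzyme_dropout <= 1)
  if (plan$fraction_sampled + mice_per_generation * fraction_retransplanted > 1)
    stop("fraction_sampled + mice_per_generation * fraction_retransplanted must not exceed 1 (cell conservation)")
  structure(list(n_cells_transplanted = n_cells_transplanted,
                 transduction_efficiency = transduction_efficiency,
                 seeding_prob = seeding_prob, growth = growth,
                 generations = as.integer(generations),
                 mice_per_generation = as.integer(mice_per_generation),
                 fraction_retransplanted = fraction_retransplanted,
                 plan = plan, scenario = scenario,
                 p_inactivate = p_inactivate, p_activate = p_activate,
                 ltic_fraction = ltic_fraction,
                 enzyme_dropout = enzyme_dropout, seed = seed,
                 size_guard = size_guard),
            class = "simulation_config")
}

#' Simulate lentiviral marking of transplanted cells
#'
#' Draws the marked founder cells: \code{floor(n_cells_transplanted *
#' transduction_efficiency)} cells, each with a unique integration site
#' encoded as (chromosome, 1-based position, strand) on hs37d5 chromosome
#' names, positions uniform over chromosome lengths.
#'
#' @param config A [simulation_config()].
#' @return Data frame with columns \code{clone_id}, \code{chrom},
#'   \code{pos}, \code{strand}, one row per marked founder cell.
#' @export
simulate_marking <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- floor(config$n_cells_transplanted * config$transduction_efficiency)
  if (n == 0)
    return(data.frame(clone_id = character(0), chrom = character(0),
                      pos = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  lens <- hs37d5_chrom_lengths
  chrom <- sample(names(lens), n, replace = TRUE, prob = lens)
  pos <- floor(stats::runif(n, min = 1, max = lens[chrom] + 1))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  id <- is_id_of(chrom, pos, strand)
  while (anyDuplicated(id)) {       # vanishingly rare; redraw clashes
    dup <- which(duplicated(id))
    chrom[dup] <- sample(names(lens), length(dup), replace = TRUE, prob = lens)
    pos[dup] <- floor(stats::runif(length(dup), 1, lens[chrom[dup]] + 1))
    id <- is_id_of(chrom, pos, strand)
  }
  data.frame(clone_id = id, chrom = chrom, pos = as.integer(pos),
             strand = strand, stringsAsFactors = FALSE, row.names = NULL)
}

# Advance clone-intrinsic activity states by one transplant epoch.
# States: "dormant" (never active), "active", "exhausted" (terminally
# inactive). Advanced once per epoch, shared across sibling recipients.
advance_clone_states <- function(state, ltic, config) {
  n <- length(state)
  if (n == 0) return(state)
  out <- state
  if (config$scenario == "succession") {
    act <- state == "active"
    out[act] <- ifelse(stats::runif(sum(act)) < config$p_inactivate,
                       "exhausted", "active")
    dorm <- state == "dormant"
    out[dorm] <- ifelse(stats::runif(sum(dorm)) < config$p_activate,
                        "active", "dormant")
  } else if (config$scenario == "hierarchy") {
    out[!ltic] <- ifelse(state[!ltic] == "exhausted", "exhausted", "dormant")
    lt <- ltic & state != "exhausted"
    out[lt] <- ifelse(stats::runif(sum(lt)) < config$p_inactivate,
                      "exhausted", "active")
  } else {                           # stochastic: memoryless activation
    out <- ifelse(stats::runif(n) < config$p_activate, "active", "dormant")
  }
  out
}

#' Simulate one tumor generation from an inoculum of clones
#'
#' Per clone: its transplanted cells engraft binomially with
#' \code{seeding_prob}; the scenario's activity rules are applied (unless
#' states were already advanced for this epoch); active clones regrow from a
#' single re-initiating founder cell by the Yule process, dormant clones
#' persist as quiescent non-growing cells, and exhausted clones' progeny die
#' out in the recipient.
#'
#' @param inoculum Data frame with columns \code{clone_id}, \code{cells},
#'   \code{state} (\code{"dormant"}, \code{"active"} or \code{"exhausted"})
#'   and \code{ltic} (logical).
#' @param config A [simulation_config()].
#' @param seeding_prob Per-cell engraftment probability for this
#'   transplantation (the primary transplant uses
#'   \code{config$seeding_prob}; tumor-derived serial transplants engraft
#'   their surviving lineages deterministically, i.e. 1).
#' @param update_activity If \code{FALSE}, inoculum states are taken as
#'   already advanced for this epoch.
#' @return Data frame of engrafted clones with columns \code{clone_id},
#'   \code{size}, \code{state}, \code{ltic}; only clones with
#'   \code{size > 0} are retained.
#' @export
simulate_generation <- function(inoculum, config, seeding_prob = 1,
                                update_activity = TRUE) {
  stopifnot(inherits(config, "simulation_config"),
            all(c("clone_id", "cells", "state") %in% names(inoculum)))
  if (nrow(inoculum) == 0) stop("inoculum must be nonempty")
  ltic <- if ("ltic" %in% names(inoculum)) inoculum$ltic else
    rep(FALSE, nrow(inoculum))
  engrafted <- stats::rbinom(nrow(inoculum), size = inoculum$cells,
                             prob = seeding_prob)
  keep <- engrafted > 0
  state <- inoculum$state[keep]
  ltic <- ltic[keep]
  if (update_activity) state <- advance_clone_states(state, ltic, config)
  n <- sum(keep)
  size <- numeric(n)
  act <- state == "active"
  size[act] <- yule_size_sample(config$growth, sum(act))
  size[state == "dormant"] <- engrafted[keep][state == "dormant"]
  # exhausted: size stays 0
  out <- data.frame(clone_id = inoculum$clone_id[keep], size = size,
                    state = state, ltic = ltic, stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[out$size > 0, , drop = FALSE]
  if (sum(out$size) > config$size_guard)
    stop("total tumor size exceeds size_guard")
  out
}

# Allocate a tumor's cells to the IS aliquot, daughter inocula, and the
# remainder by a per-clone multinomial draw; conserves cells exactly.
allocate_tumor_cells <- function(sizes, f, frac, n_daughters) {
  probs <- c(f, rep(frac, n_daughters), max(0, 1 - f - n_daughters * frac))
  out <- vapply(sizes, function(s) {
    drop(stats::rmultinom(1L, size = s, prob = probs))
  }, numeric(length(probs)))
  # rows: sampled, daughter 1..m, remainder; columns: clones
  matrix(out, nrow = length(probs))
}

# Convert per-clone sampled cell counts into two enzyme-replicate read
# tables via multinomial read draws with per-replicate IS dropout.
reads_from_sample <- function(tumor_id, clones, sampled, plan, dropout) {
  enzymes <- c("TSP509I", "MSEI")
  rows <- list()
  for (e in enzymes) {
    keep <- stats::runif(length(sampled)) >= dropout
    w <- sampled * keep
    if (sum(w) == 0) next
    reads <- drop(stats::rmultinom(1L, size = plan$read_depth, prob = w))
    nz <- reads > 0
    if (!any(nz)) next
    rows[[e]] <- data.frame(clone_id = clones[nz], tumor_id = tumor_id,
                            enzyme = e, reads = reads[nz],
                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

#' Simulate a complete serial xenotransplantation experiment
#'
#' Runs the full primary-to-tertiary design: lentiviral marking, binomial
#' engraftment in the primary recipient, per-epoch activity transitions,
#' Yule growth of active clones, exact multinomial allocation of each
#' tumor's cells to the IS-analysis aliquot, the daughter-mouse inocula and
#' the remainder, and conversion of sampled cells to two enzyme-replicate
#' read tables (multinomial reads, per-replicate IS dropout).
#'
#' @param config A [simulation_config()]; \code{config$seed} (if non-NULL)
#'   makes the whole experiment reproducible.
#' @param patient,experiment Labels recorded in the transplant design.
#' @return An object of class \code{"experiment_record"}: a list with
#'   \itemize{
#'     \item \code{design}: transplant-design data frame (one row per tumor),
#'     \item \code{is_tables}: IS read records (chrom, pos, strand,
#'       tumor_id, enzyme, reads),
#'     \item \code{truth}: per-tumor list of true clone sizes, states and
#'       sampled cell counts, plus \code{n_engrafted},
#'     \item \code{founders}: the marked founder table,
#'     \item \code{config}: the configuration used.
#'   }
#' @export
simulate_serial_experiment <- function(config, patient = "P1",
                                       experiment = "E1") {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    founders <- simulate_marking(config)
    if (nrow(founders) == 0) stop("no marked founder cells (transduction_efficiency = 0?)")
    founders$ltic <- stats::runif(nrow(founders)) < config$ltic_fraction
    coord <- founders[, c("clone_id", "chrom", "pos", "strand")]

    inoculum0 <- data.frame(clone_id = founders$clone_id, cells = 1L,
                            state = "dormant", ltic = founders$ltic,
                            stringsAsFactors = FALSE)
    m <- config$mice_per_generation
    f <- config$plan$fraction_sampled
    frac <- config$fraction_retransplanted

    design <- list(); truth <- list(); tables <- list()
    tumor_counter <- 0L
    queue <- list(list(inoculum = inoculum0, gen = 1L, parent = NA_character_,
                       pre_advanced = FALSE))
    while (length(queue) > 0) {
      job <- queue[[1]]; queue <- queue[-1]
      tumor_counter <- tumor_counter + 1L
      tid <- sprintf("%s-%s-T%02d", patient, experiment, tumor_counter)
      sp <- if (job$gen == 1L) config$seeding_prob else 1
      tumor <- simulate_generation(job$inoculum, config, seeding_prob = sp,
                                   update_activity = !job$pre_advanced)
      n_daughters <- if (job$gen < config$generations) m else 0L
      alloc <- allocate_tumor_cells(tumor$size, f, frac, n_daughters)
      sampled <- alloc[1L, ]
      tab <- reads_from_sample(tid, tumor$clone_id, sampled, config$plan,
                               config$enzyme_dropout)
      if (!is.null(tab)) tables[[tid]] <- tab
      design[[tid]] <- data.frame(
        tumor_id = tid, patient = patient, experiment = experiment,
        generation = job$gen, parent_tumor = job$parent, site = "s.c.",
        n_cells_injected = sum(job$inoculum$cells),
        transduction_efficiency = config$transduction_efficiency,
        fraction_sampled_for_is = f, fraction_retransplanted = frac,
        stringsAsFactors = FALSE)
      truth[[tid]] <- list(
        clones = data.frame(clone_id = tumor$clone_id, size = tumor$size,
                            state = tumor$state, sampled = sampled,
                            stringsAsFactors = FALSE),
        n_engrafted = nrow(tumor),
        total_cells = sum(tumor$size))
      if (n_daughters > 0L) {
        # activity is clone-intrinsic: advance once per epoch, before the
        # cells are split across sibling recipients
        next_state <- advance_clone_states(tumor$state, tumor$ltic, config)
        for (d in seq_len(n_daughters)) {
          cells_d <- alloc[1L + d, ]
          nz <- cells_d > 0
          if (!any(nz)) next
          inoc <- data.frame(clone_id = tumor$clone_id[nz],
                             cells = cells_d[nz], state = next_state[nz],
                             ltic = tumor$ltic[nz], stringsAsFactors = FALSE)
          queue[[length(queue) + 1L]] <-
            list(inoculum = inoc, gen = job$gen + 1L, parent = tid,
                 pre_advanced = TRUE)
        }
      }
    }

    is_tables <- if (length(tables) > 0)
      do.call(rbind, c(tables, list(make.row.names = FALSE)))
    else
      data.frame(clone_id = character(0), tumor_id = character(0),
                 enzyme = character(0), reads = integer(0))
    idx <- match(is_tables$clone_id, coord$clone_id)
    is_tables <- data.frame(chrom = coord$chrom[idx], pos = coord$pos[idx],
                            strand = coord$strand[idx],
                            tumor_id = is_tables$tumor_id,
                            enzyme = is_tables$enzyme,
                            reads = is_tables$reads,
                            stringsAsFactors = FALSE)
    structure(list(design = do.call(rbind, c(design, list(make.row.names = FALSE))),
                   is_tables = is_tables, truth = truth,
                   founders = founders, config = config),
              class = "experiment_record")
  })
}

#' @export
print.experiment_record <- function(x, ...) {
  cat(sprintf("Serial xenotransplantation experiment: %d tumors, %d generations, scenario '%s'\n",
              nrow(x$design), max(x$design$generation), x$config$scenario))
  det <- tapply(x$is_tables$chrom, x$is_tables$tumor_id,
                function(z) length(z))
  cat(sprintf("IS read rows: %d across %d tumors with reads\n",
              nrow(x$is_tables), length(det)))
  invisible(x)
}
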