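#' The seven lipid groups of the membrane model
#'
#' Cholesterol (CHO), sterol esters (SE), docosahexaenoic acid (DHA),
#' n-6 long-chain polyunsaturated fatty acids (N6LCPUFA), monounsaturated
#' fatty acids (MUFA), saturated fatty acids (SFA) and sphingolipids (SL).
#'
#' @return character vector of the seven group tokens, in canonical order.
#' @export
lipid_groups <- function() {
  c("CHO", "SE", "DHA", "N6LCPUFA", "MUFA", "SFA", "SL")
}

# raft-forming subset used by the local-order detector
RAFT_FORMERS <- c("CHO", "SFA", "SL")

#' Default lipid-lipid interaction matrix
#'
#' Encodes established raft physics in nearest-neighbour pair energies
#' (negative = attractive): cholesterol-sphingolipid and
#' cholesterol-saturate affinity drive raft condensation, cholesterol
#' avoids polyunsaturated chains, and sterol esters disrupt packing
#' against every neighbour. All entries are configuration-exposed.
#'
#' @return symmetric 7 x 7 numeric matrix, dimnames = [lipid_groups()].
#' @export
default_interaction <- function() {
  gs <- lipid_groups()
  J <- matrix(0, 7, 7, dimnames = list(gs, gs))
  J["CHO", "SL"] <- J["SL", "CHO"] <- -1
  J["SL", "SL"] <- -1
  J["CHO", "SFA"] <- J["SFA", "CHO"] <- -1
  J["CHO", "DHA"] <- J["DHA", "CHO"] <- 0.8
  J["CHO", "N6LCPUFA"] <- J["N6LCPUFA", "CHO"] <- 0.8
  J["SE", ] <- J[, "SE"] <- 0.4
  J
}

#' ABM configuration
#'
#' @param composition named fractions over [lipid_groups()], summing to 1.
#' @param lattice_size lattice side length L (periodic boundaries, >= 16).
#' @param interaction symmetric 7 x 7 energy matrix (negative =
#'   attractive), in units of `temperature`.
#' @param temperature thermal energy scale.
#' @param sweeps_burnin equilibration sweeps before measurement.
#' @param sweeps_measure sweeps of the mobility measurement window.
#' @param raft_theta local-order threshold in (0, 1] for raft sites
#'   (default 7/9: at least 7 of the 9 Moore-neighbourhood sites are
#'   raft-forming; lower thresholds put realistic brain-raft
#'   compositions in a percolating regime with one system-spanning
#'   cluster).
#' @param raft_min_size minimum connected-component size (sites) counted
#'   as a raft.
#' @param seed RNG seed.
#' @return an `abm_config` list.
#' @export
abm_config <- function(composition, lattice_size = 64,
                       interaction = default_interaction(),
                       temperature = 1.0,
                       sweeps_burnin = 2000, sweeps_measure = 100,
                       raft_theta = 7/9, raft_min_size = 5, seed = 1L) {
  gs <- lipid_groups()
  stopifnot(setequal(names(composition), gs),
            abs(sum(composition) - 1) < 1e-9,
            all(composition >= 0),
            lattice_size >= 16,
            isTRUE(all.equal(interaction, t(interaction))),
            temperature > 0, raft_theta > 0, raft_theta <= 1)
  structure(list(composition = composition[gs],
                 lattice_size = as.integer(lattice_size),
                 interaction = interaction[gs, gs],
                 temperature = temperature,
                 sweeps_burnin = as.integer(sweeps_burnin),
                 sweeps_measure = as.integer(sweeps_measure),
                 raft_theta = raft_theta,
                 raft_min_size = as.integer(raft_min_size),
                 seed = as.integer(seed)),
            class = "abm_config")
}

#' Map lipid profiles onto the seven model groups
#'
#' CHO, SE and the sphingolipid total come straight from the class
#' profile; the fatty-acid profile supplies DHA (22:6n-3), n-6 LCPUFA,
#' MUFA and SFA shares, scaled into the glycerophospholipid share of the
#' class table; the result is renormalized to sum to 1. DMAs and the few
#' fatty acids outside the four model groups are omitted before scaling.
#'
#' @param fa named fatty-acid profile (mol%).
#' @param lc named lipid-class profile (%).
#' @return named fractions over [lipid_groups()], summing to 1.
#' @export
composition_from_profiles <- function(fa, lc) {
  g <- function(tok) if (tok %in% names(lc)) as.numeric(lc[[tok]]) else 0
  cho <- g("CHO"); se <- g("SE")
  sl <- g("SM") + g("SULF") + g("OTHER_SL")
  pl <- g("PC") + g("PE") + g("PS") + g("PI") + g("PG")
  tot <- compute_totals(fa)
  dha <- if ("22:6n-3" %in% names(fa)) as.numeric(fa[["22:6n-3"]]) else 0
  w <- c(DHA = dha, N6LCPUFA = tot$total_n6_lcpufa,
         MUFA = tot$total_mufa, SFA = tot$total_saturates)
  comp <- c(CHO = cho, SE = se, SL = sl,
            if (sum(w) > 0) pl * w / sum(w) else w)
  comp <- comp[lipid_groups()]
  names(comp) <- lipid_groups()
  comp[is.na(comp)] <- 0
  if (sum(comp) <= 0) stop("all-zero composition", call. = FALSE)
  comp / sum(comp)
}

#' Default group compositions for the simulator
#'
#' The generator's NSL/ALS mean profiles mapped through
#' [composition_from_profiles()].
#'
#' @param group `"NSL"` or `"ALS"`.
#' @param config a `cohort_config`.
#' @return named fractions over [lipid_groups()].
#' @export
default_composition <- function(group = c("NSL", "ALS"),
                                config = default_cohort_config()) {
  group <- match.arg(group)
  g <- config$groups[[if (group == "NSL") 1 else 2]]
  mp <- g$mean_profile
  fa <- mp[setdiff(names(mp), LIPID_CLASSES)]
  lc <- mp[intersect(names(mp), LIPID_CLASSES)]
  composition_from_profiles(fa, lc)
}

#' Initialize a membrane lattice
#'
#' Deterministic largest-remainder rounding of fraction x L^2 per group,
#' then a seeded random shuffle onto the lattice. The state tracks agent
#' identities and periodically-unwrapped displacements for mobility
#' measurements.
#'
#' @param config an [abm_config()].
#' @return a `membrane_state` list: `groups` (L x L integer matrix,
#'   1-based group codes), `agents` (L x L agent ids), `dx`, `dy`
#'   (per-agent displacement accumulators), `agent_group`, `sweep`.
#' @export
init_membrane <- function(config) {
  L <- config$lattice_size
  n <- L * L
  counts <- largest_remainder(config$composition, n)
  set.seed(config$seed)
  codes <- sample(rep.int(seq_along(config$composition), counts))
  groups <- matrix(codes, L, L)
  agents <- matrix(seq_len(n), L, L)
  structure(list(groups = groups, agents = agents,
                 dx = numeric(n), dy = numeric(n),
                 agent_group = codes[order(as.vector(agents))],
                 sweep = 0L),
            class = "membrane_state")
}

# integer apportionment: floor, then distribute the remainder to the
# largest fractional parts (ties resolved by group order)
largest_remainder <- function(fractions, total) {
  raw <- fractions * total
  counts <- floor(raw)
  rem <- total - sum(counts)
  if (rem > 0) {
    idx <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[idx] <- counts[idx] + 1
  }
  as.integer(counts)
}

#' Advance the membrane with Kawasaki exchange dynamics
#'
#' Per sweep, L^2 attempted moves: a random site and a random
#' 4-neighbour are chosen and their occupants exchanged with Metropolis
#' probability min(1, exp(-dE/T)), dE from nearest-neighbour pair
#' energies. Exchanges conserve all per-group counts exactly.
#'
#' @param state a `membrane_state`.
#' @param config an [abm_config()].
#' @param n_sweeps sweeps to run.
#' @param record_energy also record the total lattice energy per sweep.
#' @return updated `membrane_state` with `acceptance` (per-group and
#'   overall acceptance rates) and optionally `energy_trace`.
#' @export
step_kawasaki <- function(state, config, n_sweeps,
                          record_energy = FALSE) {
  res <- cpp_abm_sweeps(state$groups - 1L, state$agents, state$dx, state$dy,
                        unname(config$interaction), config$temperature,
                        as.integer(n_sweeps), isTRUE(record_energy))
  state$groups <- res$groups + 1L
  state$agents <- res$agents
  state$dx <- res$dx
  state$dy <- res$dy
  state$sweep <- state$sweep + as.integer(n_sweeps)
  rate <- ifelse(res$attempted > 0, res$accepted / res$attempted, NA_real_)
  state$acceptance <- c(setNames(rate, lipid_groups()),
                        overall = sum(res$accepted) / sum(res$attempted))
  if (isTRUE(record_energy)) state$energy_trace <- res$energy_trace
  state
}

#' Detect lipid rafts and summarize the membrane
#'
#' A site's local order is the fraction of raft-forming lipids
#' (CHO, SFA, SL) among its 9-site Moore neighbourhood (centre
#' included); sites at or above `raft_theta` are raft sites, and rafts
#' are 4-connected components of at least `raft_min_size` sites.
#'
#' @param state a `membrane_state`.
#' @param config an [abm_config()].
#' @return a `raft_summary` list: `n_rafts`, `mean_size`,
#'   `size_distribution`, `area_fraction`, `raft_composition`,
#'   `whole_composition`, `raft_enrichment` (raft over whole, per
#'   group), `labels` (L x L raft label matrix).
#' @export
detect_rafts <- function(state, config) {
  gs <- lipid_groups()
  order_mat <- cpp_local_order(state$groups - 1L, gs %in% RAFT_FORMERS)
  raft_sites <- order_mat >= config$raft_theta
  lab <- cpp_label_rafts(raft_sites, config$raft_min_size)
  in_raft <- lab$labels > 0
  n_sites <- length(in_raft)
  whole <- tabulate(state$groups, nbins = 7) / n_sites
  raft_comp <- if (any(in_raft)) {
    tabulate(state$groups[in_raft], nbins = 7) / sum(in_raft)
  } else {
    rep(NA_real_, 7)
  }
  names(whole) <- names(raft_comp) <- gs
  structure(list(
    n_rafts = length(lab$sizes),
    mean_size = if (length(lab$sizes)) mean(lab$sizes) else 0,
    size_distribution = lab$sizes,
    area_fraction = sum(in_raft) / n_sites,
    raft_composition = raft_comp,
    whole_composition = whole,
    raft_enrichment = raft_comp / whole,
    labels = lab$labels
  ), class = "raft_summary")
}

#' Raft and non-raft mobility
#'
#' Tags every agent, classifies it by raft membership at the window
#' start, advances the dynamics `n_sweeps` sweeps and reports the mean
#' squared displacement per sweep (lattice units squared, periodically
#' unwrapped) separately for the raft and non-raft populations.
#'
#' @param state an equilibrated `membrane_state`.
#' @param config an [abm_config()].
#' @param n_sweeps measurement window (>= 10 sweeps).
#' @return list `mobility_raft`, `mobility_nonraft`, `state` (advanced).
#' @export
mobility_stats <- function(state, config, n_sweeps = config$sweeps_measure) {
  if (n_sweeps < 10) stop("mobility window must be >= 10 sweeps",
                          call. = FALSE)
  start_rafts <- detect_rafts(state, config)
  in_raft_site <- start_rafts$labels > 0
  agent_in_raft <- logical(length(state$dx))
  agent_in_raft[state$agents[in_raft_site]] <- TRUE
  state$dx[] <- 0
  state$dy[] <- 0
  state <- step_kawasaki(state, config, n_sweeps)
  sq <- state$dx^2 + state$dy^2
  list(
    mobility_raft = if (any(agent_in_raft)) {
      mean(sq[agent_in_raft]) / n_sweeps
    } else {
      NA_real_
    },
    mobility_nonraft = if (any(!agent_in_raft)) {
      mean(sq[!agent_in_raft]) / n_sweeps
    } else {
      NA_real_
    },
    state = state
  )
}

#' Replicated group simulation
#'
#' Runs `n_replicates` independently seeded simulations of one
#' composition (burn-in, raft detection, then a mobility window) and
#' aggregates every summary field. The master seed expands to
#' per-replicate streams by drawing `n_replicates` sub-seeds from the
#' master-seeded stream, so outputs are reproducible given
#' (`seed`, `n_replicates`).
#'
#' @param composition named fractions over [lipid_groups()].
#' @param config an [abm_config()] (its composition is replaced).
#' @param n_replicates replicate count.
#' @param seed master seed (defaults to `config$seed`).
#' @return list `replicates` (data.frame of per-replicate summaries),
#'   `mean`, `sd` (named vectors over the summary fields),
#'   `raft_composition` (mean over replicates, per group).
#' @export
simulate_group <- function(composition, config, n_replicates = 5,
                           seed = config$seed) {
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  comps <- vector("list", n_replicates)
  reps <- lapply(seq_len(n_replicates), function(k) {
    cfg <- config
    cfg$composition <- composition[lipid_groups()]
    cfg$seed <- sub_seeds[k]
    st <- init_membrane(cfg)
    st <- step_kawasaki(st, cfg, cfg$sweeps_burnin)
    det <- detect_rafts(st, cfg)
    mob <- mobility_stats(st, cfg, cfg$sweeps_measure)
    comps[[k]] <<- det$raft_composition
    data.frame(replicate = k, seed = sub_seeds[k],
               n_rafts = det$n_rafts, mean_size = det$mean_size,
               area_fraction = det$area_fraction,
               mobility_raft = mob$mobility_raft,
               mobility_nonraft = mob$mobility_nonraft)
  })
  reps <- do.call(rbind, reps)
  fields <- c("n_rafts", "mean_size", "area_fraction",
              "mobility_raft", "mobility_nonraft")
  list(
    replicates = reps,
    mean = vapply(reps[fields], mean, numeric(1), na.rm = TRUE),
    sd = vapply(reps[fields], sd, numeric(1), na.rm = TRUE),
    raft_composition = rowMeans(do.call(cbind, comps), na.rm = TRUE)
  )
}
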