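#' Ward system for the patient-flow model
#'
#' Describes the ICU ward layout: the number of wards, beds per ward, the
#' pathology each ward preferentially serves, and how many discharge
#' inspections happen per day. A ward's preferred pathology drives primary
#' hospitalization; arrivals finding the preferred ward full are oriented
#' to an alternative ward (secondary hospitalization) or overflow.
#'
#' @param beds Integer vector of bed counts, one per ward.
#' @param pathology_of_ward Integer vector mapping each ward to the index
#'   of the pathology it prefers (defaults to ward index).
#' @param n_pathologies Number of pathology types (defaults to the number
#'   of distinct preferred pathologies).
#' @param inspections_per_day Discharge-inspection epochs per day
#'   (default 3: the day is divided into fixed review intervals).
#' @return A `ward_system` object.
#' @export
ward_system <- function(beds, pathology_of_ward = seq_along(beds),
                        n_pathologies = max(pathology_of_ward),
                        inspections_per_day = 3L) {
  stopifnot(length(beds) >= 1, all(beds >= 0),
            length(pathology_of_ward) == length(beds),
            all(pathology_of_ward >= 1), n_pathologies >= 1)
  structure(list(M = length(beds), beds = as.integer(beds),
                 pathology_of_ward = as.integer(pathology_of_ward),
                 K = as.integer(n_pathologies),
                 inspections_per_day = as.integer(inspections_per_day)),
            class = "ward_system")
}

#' Initial (empty) flow state
#'
#' The state tracks a per-patient roster (ward, pathology, admission route,
#' sojourn clock in inspections), the FIFO overflow queue, the per-epoch
#' discharge counts (xi) with their running total (Gamma), and cumulative
#' arrivals for conservation checks.
#'
#' @param system A [ward_system()].
#' @return A `flow_state` object at epoch 0.
#' @export
flow_state <- function(system) {
  structure(list(
    roster = data.frame(pid = integer(0), ward = integer(0),
                        pathology = integer(0), route = character(0),
                        entered_epoch = integer(0), clock = integer(0)),
    overflow = data.frame(pathology = integer(0), route = character(0),
                          arrival_epoch = integer(0)),
    discharge_ledger = data.frame(pid = integer(0), ward = integer(0),
                                  pathology = integer(0), sojourn = integer(0),
                                  epoch = integer(0)),
    xi_last = integer(system$M),
    gamma = 0L,
    arrivals_total = 0L,
    next_pid = 1L,
    epoch = 0L
  ), class = "flow_state")
}

occupied_counts <- function(state, system) {
  Q <- matrix(0L, nrow = system$M, ncol = system$K)
  if (nrow(state$roster) > 0) {
    tab <- table(factor(state$roster$ward, levels = seq_len(system$M)),
                 factor(state$roster$pathology, levels = seq_len(system$K)))
    Q <- matrix(as.integer(tab), nrow = system$M, ncol = system$K)
  }
  Q
}

free_beds <- function(state, system) {
  system$beds - rowSums(occupied_counts(state, system))
}

#' Bed-occupancy matrix U
#'
#' `U[q, k]` is the number of patients of pathology `k` in ward `q` divided
#' by the ward's bed count. A zero-bed ward has occupancy defined as 0
#' (with a warning), since no patient can be allocated there.
#'
#' @param state A [flow_state()].
#' @param system A [ward_system()].
#' @return An `M x K` numeric matrix.
#' @export
occupancy <- function(state, system) {
  Q <- occupied_counts(state, system)
  beds <- system$beds
  zero <- beds == 0
  if (any(zero)) warning("ward(s) with zero beds: occupancy set to 0")
  U <- Q / ifelse(zero, 1, beds)
  U[zero, ] <- 0
  U
}

#' Primary and secondary hospitalization rates (alpha, beta)
#'
#' The distribution mass is the occupancy matrix together with the
#' free-bed vector. The primary rate `alpha[k]` is the occupancy of
#' pathology-`k` patients in their preferred ward(s) over the total mass;
#' the secondary rate is the remaining mass share, clamped to [0, 1]
#' (under the distribution-block reading the raw numerator is never
#' positive once free beds are counted; the `clamped` attribute records
#' when clamping fired). Errors when no patient occupies any bed.
#'
#' @param state A [flow_state()].
#' @param system A [ward_system()].
#' @return List with `alpha` (length-K vector), `beta` (`M x K` matrix with
#'   attribute `clamped`), and the total mass `D_total`.
#' @export
flow_rates <- function(state, system) {
  U <- suppressWarnings(occupancy(state, system))
  Fq <- free_beds(state, system)
  if (sum(U) == 0) stop("empty-system: no occupied beds, rates undefined",
                        call. = FALSE)
  D_total <- sum(U) + sum(Fq)
  alpha <- vapply(seq_len(system$K), function(k) {
    sum(U[system$pathology_of_ward == k, k]) / D_total
  }, 0)
  raw <- (D_total - sum(U) - sum(Fq)) / D_total
  clamped <- raw < 0 || raw > 1
  beta_val <- min(max(raw, 0), 1)
  beta <- matrix(beta_val, nrow = system$M, ncol = system$K)
  attr(beta, "clamped") <- clamped
  list(alpha = alpha, beta = beta, D_total = D_total)
}

# place `count` patients of pathology k given current free beds Fq:
# preferred ward first, then alternatives proportional to free capacity
# (largest remainder, ties by lowest ward index); returns the chosen
# wards and the number left unplaced.
place_pathology <- function(Fq, system, k, count) {
  placed <- integer(0)
  pref <- which(system$pathology_of_ward == k)
  for (q in pref) {
    take <- min(count - length(placed), Fq[q])
    if (take > 0) { placed <- c(placed, rep(q, take)); Fq[q] <- Fq[q] - take }
    if (length(placed) == count) return(list(wards = placed, unplaced = 0L))
  }
  rest <- count - length(placed)
  alt <- setdiff(which(Fq > 0), pref)
  if (rest > 0 && length(alt) > 0) {
    cap <- Fq[alt]
    alloc <- pmin(largest_remainder(cap, min(rest, sum(cap))), cap)
    # largest_remainder ties already break by lower index via order()
    short <- min(rest, sum(cap)) - sum(alloc)
    if (short > 0) {           # top up where capacity remains, lowest index
      for (i in seq_along(alt)) {
        add <- min(short, cap[i] - alloc[i]); alloc[i] <- alloc[i] + add
        short <- short - add
        if (short == 0) break
      }
    }
    placed <- c(placed, rep(alt, alloc))
  }
  list(wards = placed, unplaced = count - length(placed))
}

#' Allocate arrivals to wards (with FIFO overflow retry)
#'
#' The overflow queue is drained first (FIFO), then new arrivals are
#' placed: each patient of pathology `k` fills the preferred ward while it
#' has free beds; once full, remaining arrivals spread over alternative
#' wards with free capacity (proportional to free beds, largest-remainder,
#' ties to the lowest ward index); patients finding no bed anywhere join
#' the overflow queue. No ward ever exceeds its bed count and the
#' arrival/discharge/overflow conservation identity holds after the call.
#'
#' @param state A [flow_state()].
#' @param arrivals Data frame with columns `pathology` (integer index),
#'   `route` (character) and `n` (non-negative counts).
#' @param system A [ward_system()].
#' @return The updated `flow_state`.
#' @export
allocate <- function(state, arrivals, system) {
  stopifnot(inherits(state, "flow_state"))
  if (nrow(arrivals) > 0 && any(arrivals$n < 0))
    stop("negative arrival counts", call. = FALSE)

  queue <- state$overflow
  if (nrow(arrivals) > 0 && sum(arrivals$n) > 0) {
    new_rows <- arrivals[rep(seq_len(nrow(arrivals)), arrivals$n), , drop = FALSE]
    state$arrivals_total <- state$arrivals_total + sum(arrivals$n)
    queue <- rbind(queue, data.frame(pathology = new_rows$pathology,
                                     route = new_rows$route,
                                     arrival_epoch = state$epoch))
  }
  if (nrow(queue) == 0) { state$overflow <- queue; return(state) }

  kept <- logical(nrow(queue))
  Fq <- free_beds(state, system)
  new_ward <- integer(0); new_row <- integer(0)
  for (i in seq_len(nrow(queue))) {       # FIFO: queue rows are in order
    k <- queue$pathology[i]
    res <- place_pathology(Fq, system, k, 1L)
    if (res$unplaced == 0L) {
      q <- res$wards[1]
      Fq[q] <- Fq[q] - 1L
      new_ward <- c(new_ward, q); new_row <- c(new_row, i)
    } else kept[i] <- TRUE
  }
  if (length(new_row) > 0) {
    pids <- state$next_pid + seq_along(new_row) - 1L
    state$roster <- rbind(state$roster, data.frame(
      pid = pids, ward = new_ward, pathology = queue$pathology[new_row],
      route = queue$route[new_row], entered_epoch = state$epoch,
      clock = 0L))
    state$next_pid <- state$next_pid + length(new_row)
  }
  state$overflow <- queue[kept, , drop = FALSE]
  rownames(state$overflow) <- NULL
  state
}

#' One inspection epoch: Bernoulli discharges and clock advance
#'
#' At each inspection every in-bed patient is independently discharged with
#' their pathology's per-inspection probability. The per-ward discharge
#' count xi is recorded, the running total Gamma incremented, discharged
#' patients logged to the ledger with their sojourn (in inspections), and
#' the sojourn clocks of remaining patients advance by one. The epoch
#' counter advances with the inspection.
#'
#' @param state A [flow_state()].
#' @param system A [ward_system()].
#' @param discharge_prob Per-inspection discharge probability, scalar or
#'   length-K vector over pathologies, each in [0, 1].
#' @param seed Optional integer seed for the Bernoulli draws.
#' @return The updated `flow_state`.
#' @export
inspect_and_discharge <- function(state, system, discharge_prob, seed = NULL) {
  if (any(discharge_prob < 0 | discharge_prob > 1))
    stop("discharge_prob must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- rep_len(discharge_prob, system$K)
  r <- state$roster
  state$epoch <- state$epoch + 1L
  if (nrow(r) == 0) { state$xi_last <- integer(system$M); return(state) }
  go <- stats::runif(nrow(r)) < p[r$pathology]
  state$xi_last <- vapply(seq_len(system$M),
                          function(q) sum(go & r$ward == q), 1L)
  state$gamma <- state$gamma + sum(go)
  if (any(go)) {
    state$discharge_ledger <- rbind(state$discharge_ledger, data.frame(
      pid = r$pid[go], ward = r$ward[go], pathology = r$pathology[go],
      sojourn = r$clock[go] + 1L, epoch = state$epoch))
  }
  r <- r[!go, , drop = FALSE]
  r$clock <- r$clock + 1L
  rownames(r) <- NULL
  state$roster <- r
  state
}

#' Conservation identity check
#'
#' Cumulative arrivals must equal in-bed patients plus cumulative
#' discharges plus the overflow queue, exactly, at every epoch.
#'
#' @param state A [flow_state()].
#' @return `TRUE` if the identity holds.
#' @export
conservation_holds <- function(state) {
  state$arrivals_total == nrow(state$roster) + state$gamma + nrow(state$overflow)
}

#' Run the flow model over a horizon of inspection epochs
#'
#' Each epoch: overflow retry + new-arrival allocation, then one
#' inspection with Bernoulli discharges. Returns per-epoch summaries
#' (occupancy, rates, discharges, overflow) and the final state.
#'
#' @param system A [ward_system()].
#' @param arrival_schedule Either a list of arrival data frames (one per
#'   epoch, see [allocate()]) or a single data frame reused every epoch.
#' @param discharge_prob Per-inspection discharge probability (scalar or
#'   per-pathology vector).
#' @param horizon Number of inspection epochs (>= 1).
#' @param seed Integer seed; the whole trajectory is deterministic given it.
#' @return List with `epochs` (per-epoch data frame: epoch, occupied,
#'   free, xi, gamma, overflow, alpha_total, beta_clamped), `wards`
#'   (tidy per-epoch-per-ward occupancy and xi) and `state` (final
#'   [flow_state()]).
#' @export
run_flow <- function(system, arrival_schedule, discharge_prob, horizon,
                     seed = 1L) {
  stopifnot(horizon >= 1)
  set.seed(seed)
  state <- flow_state(system)
  per_epoch <- vector("list", horizon)
  per_ward <- vector("list", horizon)
  for (t in seq_len(horizon)) {
    arr <- if (is.data.frame(arrival_schedule)) arrival_schedule
           else arrival_schedule[[min(t, length(arrival_schedule))]]
    state <- allocate(state, arr, system)
    occ_before <- rowSums(occupied_counts(state, system))
    alpha_total <- if (sum(occ_before) > 0) {
      rt <- flow_rates(state, system); sum(rt$alpha)
    } else NA_real_
    state <- inspect_and_discharge(state, system, discharge_prob)
    occ <- rowSums(occupied_counts(state, system))
    per_epoch[[t]] <- data.frame(
      epoch = state$epoch, occupied = sum(occ),
      free = sum(system$beds) - sum(occ), xi = sum(state$xi_last),
      gamma = state$gamma, overflow = nrow(state$overflow),
      alpha_total = alpha_total,
      conserved = conservation_holds(state))
    per_ward[[t]] <- data.frame(
      epoch = state$epoch, ward = seq_len(system$M),
      occupied = occ, beds = system$beds, xi = state$xi_last)
  }
  list(epochs = do.call(rbind, per_epoch),
       wards = do.call(rbind, per_ward),
       state = state)
}

#' Per-inspection discharge probability from a mean length of stay
#'
#' Calibrates the Bernoulli inspection-discharge probability as
#' `1 / (mean LOS in days * inspections per day)`, i.e. the geometric
#' sojourn whose mean (in inspections) matches the mean stay.
#'
#' @param mean_los_days Mean length of stay in days.
#' @param inspections_per_day Inspection epochs per day.
#' @return Probability in (0, 1].
#' @export
discharge_prob_from_los <- function(mean_los_days, inspections_per_day = 3L) {
  p <- 1 / (mean_los_days * inspections_per_day)
  min(max(p, 0), 1)
}
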