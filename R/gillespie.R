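#' Exact individual-based simulation of the hierarchy
#'
#' Event-driven (Gillespie) simulation of the compartment model with one
#' record per cell. Waiting times are exponential with total rate
#' `sum_i r_i * (cells in i)`; the dividing compartment is drawn
#' proportionally to its aggregate rate and the cell uniformly within it
#' (distributionally identical to per-cell rates). The division outcome is
#' differentiation with probability `epsilon` (both daughters enter the
#' next compartment; cells differentiating out of the last compartment
#' leave the system), mutation with probability `u` (the cell is replaced
#' by one cell carrying one more mutation -- count-conserving, matching the
#' deterministic mutation flux), or self-renewal otherwise (two cells in
#' the same compartment). Every mutation event founds a new clone under the
#' infinite-sites assumption; the full clone genealogy is recorded.
#'
#' Mutations beyond the `k_max` truncation remove the cell from the tracked
#' system and are counted in `leaked`. Identical seeds give identical event
#' logs.
#'
#' @param params A [hierarchy_params()] object.
#' @param t_end Time horizon; `Inf` runs to extinction (wave regime only).
#' @param seed Integer seed for the run.
#' @param max_cells Population cap; runs that hit it are flagged
#'   `truncated` (mandatory guard in the accumulation regime).
#' @param snapshot_times Optional times at which full occupancy snapshots
#'   are stored.
#' @return Object of class `gillespie_run`: list with `events` (data frame:
#'   time, cell, outcome, compartment, k, clone), `clones` (data frame: id,
#'   parent, birth_time, origin_compartment, k), `snapshots` (array time x
#'   compartment x k, if requested), `entered` (clone ids ever present per
#'   compartment), and the flags `extinct`, `truncated`, `leaked`.
#' @examples
#' run <- gillespie_run(preset_params("test-small"), Inf, seed = 1)
#' nrow(run$events)
#' @export
gillespie_run <- function(params, t_end = Inf, seed = 1L, max_cells = 1e6,
                          snapshot_times = NULL) {
  stopifnot(inherits(params, "hierarchy_params"))
  if (params$regime != "wave" && (is.infinite(t_end) || is.infinite(max_cells)))
    stop("accumulation regime: supply finite t_end and max_cells")
  if (max_cells <= params$n0) stop("max_cells must exceed n0")
  set.seed(seed)
  n <- params$n_compartments; K <- params$k_max
  r <- params$rates; u <- params$u
  f <- params$founder_compartment

  ncell <- as.integer(params$n0)
  comp <- rep(f, ncell); kk <- rep(0L, ncell); cl <- rep(0L, ncell)
  alive <- rep(TRUE, ncell)
  by_comp <- vector("list", n)           # indices of alive cells per compartment
  by_comp[[f]] <- seq_len(ncell)
  counts <- integer(n); counts[f] <- ncell

  ev_cap <- 1024L
  ev <- matrix(0, ev_cap, 6L)            # time, cell, outcome, compartment, k, clone
  n_ev <- 0L
  cl_id <- integer(0); cl_par <- integer(0); cl_t <- numeric(0)
  cl_comp <- integer(0); cl_k <- integer(0)
  next_clone <- 1L
  # clone ids ever present per compartment (direct presence; ancestors are
  # implied and closed over in clone_census)
  entered <- vector("list", n)
  entered[[f]] <- 0L
  leaked <- 0L; truncated <- FALSE
  snaps <- NULL; snap_idx <- 1L
  if (!is.null(snapshot_times)) {
    snapshot_times <- sort(snapshot_times)
    snaps <- array(0L, c(length(snapshot_times), n, K + 1))
  }
  take_snaps <- function(now) {
    while (snap_idx <= length(snapshot_times) && snapshot_times[snap_idx] <= now) {
      for (i in which(counts > 0L))
        for (idx in by_comp[[i]])
          snaps[snap_idx, i, kk[idx] + 1L] <<- snaps[snap_idx, i, kk[idx] + 1L] + 1L
      snap_idx <<- snap_idx + 1L
    }
  }

  t_now <- 0
  while (sum(counts) > 0L) {
    rate_i <- r * counts
    total <- sum(rate_i)
    dt <- stats::rexp(1L, total)
    if (t_now + dt > t_end) { t_now <- t_end; break }
    t_now <- t_now + dt
    if (!is.null(snaps)) take_snaps(t_now)
    i <- sample.int(n, 1L, prob = rate_i)
    pos <- sample.int(counts[i], 1L)
    cell <- by_comp[[i]][pos]
    drawn <- stats::runif(1L)
    ek <- eps_at(params, i, kk[cell])
    outcome <- if (drawn < ek) 1L else if (drawn < ek + u) 3L else 2L

    if (outcome == 1L) {                 # differentiate: two daughters downstream
      by_comp[[i]] <- by_comp[[i]][-pos]; counts[i] <- counts[i] - 1L
      alive[cell] <- FALSE
      if (i < n) {
        for (d in 1:2) {
          comp <- c(comp, i + 1L); kk <- c(kk, kk[cell]); cl <- c(cl, cl[cell])
          alive <- c(alive, TRUE)
          by_comp[[i + 1L]] <- c(by_comp[[i + 1L]], length(comp))
        }
        counts[i + 1L] <- counts[i + 1L] + 2L
        if (!cl[cell] %in% entered[[i + 1L]])
          entered[[i + 1L]] <- c(entered[[i + 1L]], cl[cell])
      }
    } else if (outcome == 3L) {          # mutate: one cell, k + 1, new clone
      if (kk[cell] >= K) {
        by_comp[[i]] <- by_comp[[i]][-pos]; counts[i] <- counts[i] - 1L
        alive[cell] <- FALSE
        leaked <- leaked + 1L
      } else {
        cl_id <- c(cl_id, next_clone); cl_par <- c(cl_par, cl[cell])
        cl_t <- c(cl_t, t_now); cl_comp <- c(cl_comp, i)
        cl_k <- c(cl_k, kk[cell] + 1L)
        kk[cell] <- kk[cell] + 1L
        cl[cell] <- next_clone
        entered[[i]] <- c(entered[[i]], next_clone)
        next_clone <- next_clone + 1L
      }
    } else {                             # self-renew: one extra cell in place
      comp <- c(comp, i); kk <- c(kk, kk[cell]); cl <- c(cl, cl[cell])
      alive <- c(alive, TRUE)
      by_comp[[i]] <- c(by_comp[[i]], length(comp))
      counts[i] <- counts[i] + 1L
    }

    n_ev <- n_ev + 1L
    if (n_ev > nrow(ev)) ev <- rbind(ev, matrix(0, nrow(ev), 6L))
    ev[n_ev, ] <- c(t_now, cell, outcome, i, kk[cell], cl[cell])
    if (sum(counts) >= max_cells) { truncated <- TRUE; break }
  }
  if (!is.null(snaps)) { snap_idx_left <- snap_idx; take_snaps(Inf) }

  events <- data.frame(time = ev[seq_len(n_ev), 1],
                       cell = as.integer(ev[seq_len(n_ev), 2]),
                       outcome = c("differentiate", "self-renew",
                                   "mutate")[ev[seq_len(n_ev), 3]],
                       compartment = as.integer(ev[seq_len(n_ev), 4]),
                       k = as.integer(ev[seq_len(n_ev), 5]),
                       clone = as.integer(ev[seq_len(n_ev), 6]))
  clones <- data.frame(id = cl_id, parent = cl_par, birth_time = cl_t,
                       origin_compartment = cl_comp, k = cl_k)
  structure(list(events = events, clones = clones, snapshots = snaps,
                 snapshot_times = snapshot_times, entered = entered,
                 final_time = t_now, extinct = sum(counts) == 0L,
                 truncated = truncated, leaked = leaked,
                 seed = seed, params = params),
            class = "gillespie_run")
}

#' @export
print.gillespie_run <- function(x, ...) {
  cat(sprintf("gillespie_run: %d events, %d mutation clones, %s at t = %.4g%s\n",
              nrow(x$events), nrow(x$clones),
              if (x$extinct) "extinct" else "stopped", x$final_time,
              if (x$truncated) " [cap hit]" else ""))
  invisible(x)
}

#' Ensemble of independent stochastic runs
#'
#' Repeats [gillespie_run()] with independently derived seeds and
#' summarizes the occupancy snapshots as per-(compartment, mutation count,
#' time) means, standard deviations and standard errors. Runs that hit the
#' population cap are excluded from the summary (and counted).
#'
#' @inheritParams gillespie_run
#' @param n_runs Number of replicates (>= 2).
#' @param t_grid Snapshot times.
#' @param seed Master seed; per-replicate seeds are drawn from it.
#' @return Object of class `wave_ensemble`: list with arrays `mean`, `sd`,
#'   `se` (time x compartment x k), the replicate `census` list (distinct
#'   mutant clones per k at the last compartment), and bookkeeping fields.
#' @export
replicate_ensemble <- function(params, n_runs, t_grid, seed = 1L,
                               max_cells = 1e6) {
  stopifnot(n_runs >= 2)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  n <- params$n_compartments; K <- params$k_max
  acc <- array(0, c(length(t_grid), n, K + 1))
  acc2 <- acc
  census <- matrix(0L, n_runs, K)
  usable <- logical(n_runs)
  used <- 0L; dropped <- 0L
  for (b in seq_len(n_runs)) {
    run <- gillespie_run(params, t_end = Inf, seed = seeds[b],
                         max_cells = max_cells, snapshot_times = t_grid)
    if (run$truncated) { dropped <- dropped + 1L; next }
    usable[b] <- TRUE
    used <- used + 1L
    acc <- acc + run$snapshots
    acc2 <- acc2 + run$snapshots^2
    cen <- clone_census(run, n)
    census[b, ] <- cen$clones[match(seq_len(K), cen$k)]
  }
  census[is.na(census)] <- 0L
  census <- census[usable, , drop = FALSE]
  m <- acc / used
  v <- (acc2 / used - m^2) * used / max(1, used - 1)
  v[v < 0] <- 0
  structure(list(mean = m, sd = sqrt(v), se = sqrt(v / used),
                 t_grid = t_grid, census = census,
                 n_runs = n_runs, used = used, dropped = dropped,
                 seeds = seeds, params = params),
            class = "wave_ensemble")
}

#' @export
print.wave_ensemble <- function(x, ...) {
  cat(sprintf("wave_ensemble: %d/%d usable replicates (%d hit the cap)\n",
              x$used, x$n_runs, x$dropped))
  invisible(x)
}

#' Census of distinct mutant clones seen in a compartment
#'
#' Counts the distinct mutation events (clones) whose progeny ever entered
#' the queried compartment, grouped by the mutation count of the founding
#' event. A cell carrying clone `c` also carries every mutation on `c`'s
#' ancestral line, so ancestor clones are included.
#'
#' @param run A [gillespie_run()] result.
#' @param compartment Compartment index.
#' @return List with `k` (mutation count) and `clones` (distinct counts),
#'   plus the clone `ids` per k.
#' @export
clone_census <- function(run, compartment) {
  stopifnot(inherits(run, "gillespie_run"))
  ids <- setdiff(run$entered[[compartment]], 0L)
  # close over ancestors: every ancestor mutation is present in the progeny
  parent <- run$clones$parent[match(ids, run$clones$id)]
  repeat {
    new <- setdiff(setdiff(parent, 0L), ids)
    if (!length(new)) break
    ids <- c(ids, new)
    parent <- run$clones$parent[match(new, run$clones$id)]
  }
  kk <- run$clones$k[match(ids, run$clones$id)]
  if (!length(ids)) return(list(k = integer(0), clones = integer(0), ids = list()))
  tab <- table(kk)
  list(k = as.integer(names(tab)), clones = as.integer(tab),
       ids = split(ids, kk))
}

#' Export the clone genealogy as a Newick forest
#'
#' One Newick tree per founder-rooted component of the clone table. Node
#' labels are `c<id>_i<origin compartment>_t<birth time>`; branch lengths
#' are the waiting times between parent and child mutation events. An empty
#' clone table yields the founder-only tree `"(founder);"`.
#'
#' @param clones Clone data frame from [gillespie_run()] (`id`, `parent`,
#'   `birth_time`, `origin_compartment`, `k`).
#' @return Character vector of Newick strings (length 1 for a single tree).
#' @export
export_lineage_newick <- function(clones) {
  if (nrow(clones) == 0L) return("(founder);")
  if (anyDuplicated(clones$id)) stop("integrity error: duplicate clone ids")
  lab <- function(i) sprintf("c%d_i%d_t%g", clones$id[i],
                             clones$origin_compartment[i], clones$birth_time[i])
  kids <- split(seq_len(nrow(clones)), factor(clones$parent, exclude = NULL))
  seen <- integer(0)
  sub <- function(i, depth) {
    if (depth > nrow(clones)) stop("integrity error: cyclic parent links")
    ch <- kids[[as.character(clones$id[i])]]
    bl <- clones$birth_time[i] -
      if (clones$parent[i] == 0L) 0 else
        clones$birth_time[match(clones$parent[i], clones$id)]
    node <- if (is.null(ch)) lab(i) else
      sprintf("(%s)%s", paste(vapply(ch, sub, "", depth = depth + 1L),
                              collapse = ","), lab(i))
    sprintf("%s:%g", node, bl)
  }
  roots <- which(clones$parent == 0L)
  if (!length(roots))
    stop("integrity error: no founder-rooted component (cyclic parent links?)")
  sprintf("(%s)founder;", paste(vapply(roots, sub, "", depth = 1L),
                                collapse = ","))
}
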