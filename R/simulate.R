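#' Saturating Hill response
#'
#' `hill(u, h) = u^h / (1 + u^h)`: 0 at u = 0, half-saturated at u = 1,
#' approaching 1 for large u; `h` sets the cooperativity (steepness).
#'
#' @param u Nonnegative input (rate-scaled molecule count).
#' @param h Positive Hill coefficient.
#' @return Value in `[0, 1)`.
#' @export
hill <- function(u, h) {
  if (any(u < 0)) stop("hill() input must be nonnegative", call. = FALSE)
  uh <- u^h
  uh / (1 + uh)
}

#' Five-gene regulatory circuit as a reaction system
#'
#' Ten reactions over species x1..x5: first-order degradation of every
#' species (rate 0.005 for x1-x3, 0.01 for x4-x5) and Hill-regulated
#' production. Production propensities combine activating and repressing
#' Hill terms and can transiently evaluate below zero; they are clamped at
#' zero (the system counts clamps in the run statistics). Initial state:
#' x1..x3 drawn uniformly from `[x123_low, x123_high]` (rounded to integer
#' counts), x4 = x5 = 0.
#'
#' @param x123_low,x123_high Bounds of the uniform initial condition for
#'   x1..x3 (defaults 40 and 80).
#' @param seed Integer seed for the initial-condition draw.
#' @return A reaction system list: `stoichiometry` (10 x 5 integer matrix),
#'   `propensity(state)` returning 10 nonnegative rates, `state`, `time`.
#' @export
five_gene_circuit <- function(x123_low = 40, x123_high = 80, seed = 1) {
  stopifnot(x123_low <= x123_high)
  S <- matrix(0L, 10, 5,
              dimnames = list(paste0("R", 1:10), paste0("x", 1:5)))
  for (i in 1:5) S[i, i] <- -1L   # degradations
  for (i in 1:5) S[i + 5L, i] <- 1L # productions
  propensity <- function(x) {
    a <- c(
      0.005 * x[1],
      0.005 * x[2],
      0.005 * x[3],
      0.01  * x[4],
      0.01  * x[5],
      1 - hill(0.1   * x[3], 2) + hill(0.025 * x[4], 2) - hill(0.025 * x[5], 4),
      1 - hill(0.1   * x[1], 2) + hill(0.025 * x[5], 4),
      1 - hill(0.1   * x[2], 2) - hill(0.025 * x[4], 2),
      hill(0.013 * x[1], 8) + hill(0.025 * x[4], 2),
      hill(0.013 * x[2], 2) + hill(0.025 * x[5], 4)
    )
    a  # raw rates; gillespie_run() clamps negatives and counts the clamps
  }
  set.seed(seed)
  x0 <- c(round(stats::runif(3, x123_low, x123_high)), 0, 0)
  list(stoichiometry = S, propensity = propensity,
       state = as.numeric(x0), time = 0)
}

#' A generic reaction system
#'
#' @param stoichiometry Reactions x species integer matrix.
#' @param propensity Function of the state vector returning one nonnegative
#'   rate per reaction.
#' @param state Initial nonnegative state vector.
#' @return A reaction system list as consumed by [gillespie_run()].
#' @export
reaction_system <- function(stoichiometry, propensity, state) {
  stopifnot(is.function(propensity), ncol(stoichiometry) == length(state),
            all(state >= 0))
  list(stoichiometry = as.matrix(stoichiometry), propensity = propensity,
       state = as.numeric(state), time = 0)
}

#' Exact stochastic simulation (Gillespie SSA)
#'
#' Classic direct method: exponential waiting times at the total propensity,
#' reaction chosen with probability proportional to its propensity. The
#' full event log is recorded. If every propensity hits zero the system is
#' absorbed and the run stops early (flagged).
#'
#' @param sys Reaction system from [five_gene_circuit()] or
#'   [reaction_system()].
#' @param t_max End time.
#' @param seed Integer seed; the run is fully reproducible.
#' @return List with `times` (event times, starting at 0), `states`
#'   (events x species matrix of the state *after* each event), `absorbed`
#'   (logical), `n_clamped` (propensity evaluations clamped at 0).
#' @export
gillespie_run <- function(sys, t_max, seed = 1) {
  stopifnot(t_max > 0)
  set.seed(seed)
  S <- sys$stoichiometry
  x <- sys$state
  t <- sys$time
  cap <- 4096L
  times <- numeric(cap); states <- matrix(0, cap, length(x))
  times[1L] <- t; states[1L, ] <- x
  nev <- 1L
  absorbed <- FALSE
  n_clamped <- 0L
  repeat {
    a <- sys$propensity(x)
    neg <- a < 0
    n_clamped <- n_clamped + sum(neg)
    a[neg] <- 0
    a0 <- sum(a)
    if (a0 <= 0) { absorbed <- TRUE; break }
    t <- t + stats::rexp(1, rate = a0)
    if (t > t_max) break
    r <- sample.int(length(a), 1L, prob = a)
    x <- x + S[r, ]
    if (any(x < 0)) stop("negative state reached; bad stoichiometry",
                         call. = FALSE)
    nev <- nev + 1L
    if (nev > cap) {
      cap <- cap * 2L
      times <- c(times, numeric(cap / 2L))
      states <- rbind(states, matrix(0, cap / 2L, length(x)))
    }
    times[nev] <- t; states[nev, ] <- x
  }
  colnames(states) <- colnames(S)
  list(times = times[seq_len(nev)], states = states[seq_len(nev), , drop = FALSE],
       absorbed = absorbed, n_clamped = n_clamped,
       end_time = if (absorbed) t_max else min(t, t_max))
}

#' Sample synthetic cells from an SSA trajectory
#'
#' One cell per (replicate run, sampling time): the cell's expression is
#' the state holding at that time (the last event at or before it).
#'
#' @param runs A single run from [gillespie_run()] or a list of runs
#'   (replicates).
#' @param times Integer sampling times within each run.
#' @return List with `expression` (an [expression_matrix()], genes =
#'   species) and `meta` (tibble: `cell_id`, `replicate`, `time`).
#' @export
sample_cells <- function(runs, times) {
  if (!is.null(runs$times)) runs <- list(runs)
  rows <- list(); meta_rep <- integer(0); meta_t <- numeric(0)
  for (r in seq_along(runs)) {
    run <- runs[[r]]
    if (any(times > run$end_time + 1e-9))
      stop("sampling time beyond trajectory end (", run$end_time, ")",
           call. = FALSE)
    idx <- findInterval(times + 1e-12, run$times)
    if (any(idx == 0)) stop("sampling time before trajectory start",
                            call. = FALSE)
    rows[[r]] <- run$states[idx, , drop = FALSE]
    meta_rep <- c(meta_rep, rep.int(r, length(times)))
    meta_t <- c(meta_t, times)
  }
  vals <- do.call(rbind, rows)
  ids <- sprintf("rep%d_t%g", meta_rep, meta_t)
  rownames(vals) <- ids
  list(expression = expression_matrix(vals),
       meta = tibble::tibble(cell_id = ids, replicate = meta_rep,
                             time = meta_t))
}

#' Synthetic linear-lineage dataset
#'
#' Generates a chain of `n_clusters` cell states whose mean expression
#' programs drift monotonically along the chain, with multiplicative
#' lognormal noise — the minimal dataset on which a trajectory method must
#' recover a known linear lineage. Half the genes ramp up along the chain,
#' half ramp down, from baselines drawn once per gene; noise sd (on the log
#' scale) defaults to 0.15, a realistic per-gene dispersion for normalized
#' single-cell data.
#'
#' @param n_cells Total cells (split as evenly as possible over clusters).
#' @param n_clusters Chain length (>= 2).
#' @param n_genes Gene count (default 20).
#' @param noise_sd Lognormal sigma (default 0.15).
#' @param seed Integer seed.
#' @return List with `expression` ([expression_matrix()]), `labels` (named
#'   cluster label per cell, `"C1"..`), `truth_edges` (tibble `source`,
#'   `target`: the directed chain), `cluster_order` (labels in true order),
#'   `true_stage` (integer stage per cell).
#' @export
synthetic_linear_lineage <- function(n_cells = 300, n_clusters = 5,
                                     n_genes = 20, noise_sd = 0.15,
                                     seed = 1) {
  stopifnot(n_clusters >= 2)
  set.seed(seed)
  sizes <- rep(n_cells %/% n_clusters, n_clusters)
  sizes[seq_len(n_cells %% n_clusters)] <- sizes[seq_len(n_cells %% n_clusters)] + 1L
  stage <- rep(seq_len(n_clusters), sizes)
  up <- seq_len(n_genes) <= n_genes / 2
  base <- stats::runif(n_genes, 2, 6)
  slope <- stats::runif(n_genes, 0.8, 1.6) * ifelse(up, 1, -1)
  # mean program of gene g in stage s: base + slope * (s - 1), floored at 0.2
  mu <- vapply(seq_len(n_genes), function(g) {
    pmax(base[g] + slope[g] * (seq_len(n_clusters) - 1), 0.2)
  }, numeric(n_clusters))
  vals <- mu[stage, , drop = FALSE] *
    matrix(stats::rlnorm(n_cells * n_genes, 0, noise_sd), n_cells, n_genes)
  ids <- sprintf("cell%03d", seq_len(n_cells))
  dimnames(vals) <- list(ids, sprintf("g%02d", seq_len(n_genes)))
  labels <- stats::setNames(paste0("C", stage), ids)
  ord <- paste0("C", seq_len(n_clusters))
  list(
    expression = expression_matrix(vals),
    labels = labels,
    truth_edges = tibble::tibble(source = ord[-n_clusters], target = ord[-1]),
    cluster_order = ord,
    true_stage = stage
  )
}

#' Windowed network-change profile of a time-course dataset
#'
#' Splits the cells (ordered by sampling time) into consecutive windows,
#' fits one regulatory network per window, and returns the summed absolute
#' coefficient change between consecutive windows. Expression is z-scored
#' within each window before fitting so the profile reflects rewiring of
#' the regulatory structure rather than the growth of absolute molecule
#' counts along the time course. On the five-gene circuit this profile is
#' largest between the earliest windows — regulation changes drastically
#' while the circuit leaves its initial state — and decays as the dynamics
#' approach stationarity.
#'
#' @param expression Cells x genes matrix (cells in time order).
#' @param n_windows Number of consecutive windows (default 5).
#' @param lam Conservation penalty for the per-window fits.
#' @return Tibble with `window_pair` (index of the earlier window) and
#'   `change` (sum of `|A_{w+1} - A_w|`).
#' @export
grn_change_profile <- function(expression, n_windows = 5, lam = 0.1) {
  x <- unclass(expression)
  n <- nrow(x)
  stopifnot(n_windows >= 2, n >= 2 * n_windows)
  wins <- split(seq_len(n), cut(seq_len(n), n_windows, labels = FALSE))
  As <- lapply(wins, function(ix) {
    xi <- scale(x[ix, , drop = FALSE])
    xi[is.na(xi)] <- 0
    fit_cell_grn(xi, 1L, seq_len(nrow(xi)), lam = lam)$A
  })
  chg <- vapply(seq_len(n_windows - 1L),
                function(i) sum(abs(As[[i + 1L]] - As[[i]])), numeric(1))
  tibble::tibble(window_pair = seq_len(n_windows - 1L), change = chg)
}

#' Replicate-averaged change profile of the five-gene circuit
#'
#' Simulates `n_replicates` independent runs of [five_gene_circuit()] to
#' `t_max`, samples one cell per integer time point, computes each run's
#' [grn_change_profile()], and averages the profiles. Averaging over a few
#' replicate circuits smooths the run-to-run noise of single SSA paths so
#' the early-transient signature is visible.
#'
#' @param n_replicates Number of independent circuit runs (default 5).
#' @param t_max Simulation end time (default 1000).
#' @param n_windows Windows per profile (default 5).
#' @param seed Base seed; replicate r uses seeds derived from it.
#' @return Tibble with `window_pair` and mean `change`.
#' @export
circuit_change_profile <- function(n_replicates = 5, t_max = 1000,
                                   n_windows = 5, seed = 1) {
  profs <- vapply(seq_len(n_replicates), function(r) {
    sys <- five_gene_circuit(seed = seed * 101L + r)
    run <- gillespie_run(sys, t_max, seed = seed * 101L + r + 500L)
    cells <- sample_cells(run, 0:floor(t_max))
    grn_change_profile(cells$expression, n_windows = n_windows)$change
  }, numeric(n_windows - 1L))
  tibble::tibble(window_pair = seq_len(n_windows - 1L),
                 change = rowMeans(profs))
}
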