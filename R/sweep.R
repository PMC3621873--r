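#' Monte Carlo sweep specification
#'
#' Describes a full factorial sweep over cost ratio, conformity rate,
#' initial willingness and reproduction number, with independent decision
#' replicates per cell. Per-cell seeds are derived deterministically from
#' `base_seed` and the cell/replicate indices (see [cell_seed()]), so any
#' cell can be reproduced in isolation.
#'
#' @param r_grid cost ratios in `[0, 1]` (default `seq(0, 1, 0.1)`).
#' @param p_grid conformity rates in `[0, 1]` (default `seq(0, 1, 0.1)`).
#' @param w0_levels initial willingness levels (default `c(0.3, 0.5, 0.7)`).
#' @param R0_list reproduction numbers (default `1.4`; sensitivity set
#'   `c(1.2, 1.6, 2.0)`).
#' @param replicates decision replicates per cell (>= 1, default 50).
#' @param base_seed integer master seed.
#' @param network either a [contact_network()], a path to an edge list, or
#'   `NULL` to generate the `"highschool"` preset network.
#' @param gamma recovery rate for the epidemic coupling (default 0.312).
#' @param params_fn optional function `(r, p, w0, beta_perc) ->`
#'   [decision_params()] to override decision defaults (e.g. `max_iters`).
#' @return A list of class `sweep_spec`.
#' @export
sweep_spec <- function(r_grid = seq(0, 1, by = 0.1),
                       p_grid = seq(0, 1, by = 0.1),
                       w0_levels = c(0.3, 0.5, 0.7),
                       R0_list = 1.4,
                       replicates = 50L, base_seed = 1L,
                       network = NULL, gamma = 0.312,
                       params_fn = NULL) {
  stopifnot(length(r_grid) > 0, all(r_grid >= 0), all(r_grid <= 1),
            length(p_grid) > 0, all(p_grid >= 0), all(p_grid <= 1),
            length(w0_levels) > 0, all(w0_levels >= 0), all(w0_levels <= 1),
            length(R0_list) > 0, all(R0_list > 0),
            replicates >= 1L, gamma > 0)
  structure(list(r_grid = r_grid, p_grid = p_grid, w0_levels = w0_levels,
                 R0_list = R0_list, replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed), network = network,
                 gamma = gamma, params_fn = params_fn),
            class = "sweep_spec")
}

#' Deterministic per-cell replicate seed
#'
#' Stable integer hash of the master seed and the (r, p, w0) cell indices
#' plus the replicate number. Computed in double precision with
#' multiply-and-fold modulo 2^31 - 1, so identical inputs give identical
#' seeds on every platform and every seed stays inside the 32-bit integer
#' range.
#'
#' @param base_seed integer master seed.
#' @param ri,pi,wi 1-based indices of the cost-ratio, conformity and
#'   willingness grid points.
#' @param rep replicate number (1-based).
#' @return A positive integer seed.
#' @export
cell_seed <- function(base_seed, ri, pi, wi, rep) {
  m <- 2147483647  # 2^31 - 1
  h <- (as.numeric(base_seed) %% m)
  for (v in c(ri, pi, wi, rep)) {
    h <- (h * 69069 + as.numeric(v) * 2654435761) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

.sweep_network <- function(spec) {
  if (inherits(spec$network, "contact_network")) return(spec$network)
  if (is.character(spec$network)) return(read_edge_list(spec$network))
  generate_network(preset = "highschool", seed = spec$base_seed)
}

#' Run a Monte Carlo parameter sweep
#'
#' For every `(r, p, w0, R0)` cell, runs `replicates` independent decision
#' simulations on the shared network (the perceived transmission rate is set
#' equal to the actual one, `beta_perc = R0 * gamma`), records each
#' steady-state coverage, aggregates to a mean and standard error, and
#' couples the aggregated coverage to the SIR attack rate for that
#' reproduction number (`beta = R0 * gamma`). The attack rate is computed at
#' the cell's mean coverage, not per replicate. Replicate seeds depend only
#' on the `(r, p, w0)` indices and the replicate number, so runs at
#' different `R0` share seeds and differ only through the model. Results are
#' fully reproducible from the spec.
#'
#' @param spec a [sweep_spec()].
#' @param progress print one line per cell (default `FALSE`).
#' @return A list of class `sweep_result` with `raw` (one row per
#'   replicate: indices, parameters, seed, coverage, termination reason),
#'   `agg` (one row per cell and R0: mean coverage, its standard error,
#'   attack rate, and a tally of non-converged cost-only runs), `spec`, and
#'   `network_summary`.
#' @export
run_sweep <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  net <- .sweep_network(spec)
  raw <- list()
  agg <- list()
  for (R0 in spec$R0_list)
    for (wi in seq_along(spec$w0_levels)) for (pi in seq_along(spec$p_grid))
      for (ri in seq_along(spec$r_grid)) {
        r <- spec$r_grid[ri]; p <- spec$p_grid[pi]; w0 <- spec$w0_levels[wi]
        beta_perc <- min(1, R0 * spec$gamma)
        covs <- numeric(spec$replicates)
        reasons <- character(spec$replicates)
        seeds <- vapply(seq_len(spec$replicates), function(k)
          cell_seed(spec$base_seed, ri, pi, wi, k), integer(1))
        t_start <- proc.time()[["elapsed"]]
        for (rep in seq_len(spec$replicates)) {
          par <- if (is.null(spec$params_fn))
            decision_params(r = r, p = p, w0 = w0, beta_perc = beta_perc)
          else spec$params_fn(r, p, w0, beta_perc)
          res <- tryCatch(run_decision_dynamics(net, par, seed = seeds[rep]),
                          error = function(e) e)
          if (inherits(res, "error")) {
            covs[rep] <- NA_real_
            reasons[rep] <- paste("error:", conditionMessage(res))
          } else {
            covs[rep] <- res$coverage
            reasons[rep] <- res$termination_reason
          }
        }
        raw[[length(raw) + 1L]] <- data.frame(
          ri = ri, pi = pi, wi = wi, r = r, p = p, w0 = w0, R0 = R0,
          replicate = seq_len(spec$replicates), seed = seeds,
          coverage = covs, termination = reasons)
        mcov <- mean(covs, na.rm = TRUE)
        se <- stats::sd(covs, na.rm = TRUE) / sqrt(sum(!is.na(covs)))
        I0 <- 1e-4
        ar <- if (mcov >= 1 - I0) 0 else
          integrate_sir(sir_params(beta = R0 * spec$gamma,
                                   gamma = spec$gamma, N = 1, V = mcov,
                                   I0 = I0))$attack_rate
        agg[[length(agg) + 1L]] <- data.frame(
          r = r, p = p, w0 = w0, R0 = R0,
          mean_coverage = mcov, se_coverage = se, attack_rate = ar,
          n_replicates = sum(!is.na(covs)),
          n_failed = sum(is.na(covs)),
          n_nonconverged = sum(reasons == "max_iters" & p == 0))
        if (progress)
          message(sprintf(
            "cell R0=%.2f r=%.2f p=%.2f w0=%.2f: coverage %.3f (se %.3f) [%.1fs]",
            R0, r, p, w0, mcov, se, proc.time()[["elapsed"]] - t_start))
        if (any(is.na(covs)))
          warning(sprintf("cell r=%.2f p=%.2f w0=%.2f: %d replicate(s) failed",
                          r, p, w0, sum(is.na(covs))))
      }
  structure(list(raw = do.call(rbind, raw), agg = do.call(rbind, agg),
                 spec = spec, network_summary = summarize_network(net)),
            class = "sweep_result")
}

#' Coverage as a function of initial willingness among social followers
#'
#' Extracts the `w0 -> mean coverage` curve at a fixed conformity rate
#' (default `p = 1`, absolute social followers) and locates the steepest
#' change — the midpoint of the largest jump between adjacent willingness
#' levels — as an estimate of the critical willingness at which coverage
#' transitions between the low and high regimes.
#'
#' @param result a [run_sweep()] result (or its `agg` data.frame).
#' @param p_fixed conformity rate whose cells to use (default 1).
#' @return A list with `curve` (data.frame `w0, mean_coverage`) and
#'   `transition_w0` (`NA` when fewer than two levels).
#' @export
coverage_phase_profile <- function(result, p_fixed = 1.0) {
  agg <- if (inherits(result, "sweep_result")) result$agg else result
  rows <- agg[abs(agg$p - p_fixed) < 1e-12, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no cells with p = ", p_fixed, " in the sweep result")
  curve <- stats::aggregate(mean_coverage ~ w0, data = rows, FUN = mean)
  curve <- curve[order(curve$w0), ]
  transition <- NA_real_
  if (nrow(curve) >= 2L) {
    jumps <- diff(curve$mean_coverage)
    k <- which.max(abs(jumps))
    transition <- (curve$w0[k] + curve$w0[k + 1L]) / 2
  }
  list(curve = curve, transition_w0 = transition)
}

#' Write sweep results and a reproducibility manifest
#'
#' Writes `sweep_raw.csv` (per-replicate rows), `sweep_agg.csv` (per-cell
#' aggregates) and `manifest.json` (grids, seeds, network summary, package
#' version) into `out_dir`. Two runs of the same spec produce byte-identical
#' CSV files.
#'
#' @param result a [run_sweep()] result.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, out_dir) {
  stopifnot(inherits(result, "sweep_result"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir)
  raw_path <- file.path(out_dir, "sweep_raw.csv")
  agg_path <- file.path(out_dir, "sweep_agg.csv")
  man_path <- file.path(out_dir, "manifest.json")
  utils::write.csv(result$raw, raw_path, row.names = FALSE)
  utils::write.csv(result$agg, agg_path, row.names = FALSE)
  sp <- result$spec
  manifest <- list(
    package = "socvax",
    version = as.character(utils::packageVersion("socvax")),
    base_seed = sp$base_seed,
    r_grid = sp$r_grid, p_grid = sp$p_grid, w0_levels = sp$w0_levels,
    R0_list = sp$R0_list, replicates = sp$replicates, gamma = sp$gamma,
    network = unclass(result$network_summary))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  } else {
    dput(manifest, file = man_path)
  }
  invisible(c(raw = raw_path, agg = agg_path, manifest = man_path))
}
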