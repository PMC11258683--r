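## Rate-constant estimation. The objective is the weighted mean-squared error
## between predicted and observed concentrations over all traces and time
## points: weight w1 (default 1) before the per-trace plateau time t1, w2
## (default 0.2) from t1 onward (the boundary point t = t1 takes w2), and
## normalization by the sum of weights (which leaves the argmin unchanged).
## Unknown rates are searched in log10 space within finite bounds, multi-start.

#' Automatic plateau time
#'
#' The earliest time from which the trace stays within 2% (of its final
#' value's magnitude) of the final value. Automates the study's manually
#' chosen plateau time; overridable per trace.
#'
#' @param times,conc Trace vectors.
#' @return A time (seconds); the final time when the trace never plateaus.
#' @export
auto_t1 <- function(times, conc) {
  final <- conc[length(conc)]
  tol <- 0.02 * max(abs(final), 1e-9)
  dev <- rev(cummax(rev(abs(conc - final))))
  idx <- which(dev <= tol)
  if (length(idx)) times[idx[1]] else times[length(times)]
}

#' Build a fit trace from a dataset channel
#'
#' Converts the channel's signal to concentration-equivalent units via the
#' shared (maximum) calibration slope, and records the observation weights:
#' every fluorescent species' slope relative to the shared slope, so that
#' model predictions pass through the same linear map as the data (quenched
#' species contribute at their residual fraction).
#'
#' @param dataset A `kp_dataset`.
#' @param channel Channel name present in the dataset.
#' @param t1 Optional plateau time override.
#' @return A fit-trace list: `times`, `conc`, `weights` (named species
#'   weights), `initial`, `t1`, `name`.
#' @export
as_fit_trace <- function(dataset, channel, t1 = NULL) {
  cal <- dataset$calibrations[[channel]]
  if (is.null(cal)) stop("dataset has no channel '", channel, "'")
  tr <- dataset$traces[[channel]]
  smax <- max(cal$slopes)
  conc <- (tr$signal - cal$background) / smax
  init <- dataset$design$initial
  for (s in names(dataset$design$trigger))
    init[s] <- (if (s %in% names(init)) init[[s]] else 0) +
      dataset$design$trigger[[s]]
  list(times = tr$times, conc = conc, weights = cal$slopes / smax,
       initial = init,
       t1 = if (is.null(t1)) auto_t1(tr$times, conc) else t1,
       name = paste0(dataset$well_id, ":", channel))
}

#' Assemble a fit problem
#'
#' @param network The `kp_network` shared by all traces.
#' @param rates A `kp_rates` with the unknown names (and bounds) marked; the
#'   known values are held fixed.
#' @param traces List of fit traces (see [as_fit_trace()]); each may also be
#'   given as `list(times, conc, weights, initial)` with `weights` either a
#'   named numeric vector or a character vector of species (unit weights).
#' @param w1,w2 Weights for points before / from the plateau time t1.
#' @return A list of class `kp_fit_problem`.
#' @export
fit_problem <- function(network, rates, traces, w1 = 1, w2 = 0.2) {
  sp <- species_names(network)
  traces <- lapply(traces, function(tr) {
    if (is.character(tr$weights))
      tr$weights <- stats::setNames(rep(1, length(tr$weights)), tr$weights)
    bad <- setdiff(names(tr$weights), sp)
    if (length(bad)) stop("trace weights reference unknown species: ",
                          paste(bad, collapse = ", "))
    if (is.null(tr$t1)) tr$t1 <- auto_t1(tr$times, tr$conc)
    if (tr$t1 < tr$times[1] || tr$t1 > tr$times[length(tr$times)])
      stop("t1 outside the trace's time span")
    tr
  })
  for (nm in rates$unknown)
    if (is.null(rates$bounds[[nm]]) || !all(is.finite(rates$bounds[[nm]])))
      stop("unknown rate '", nm, "' needs finite positive bounds")
  structure(list(network = network, rates = rates, traces = traces,
                 w1 = w1, w2 = w2),
            class = "kp_fit_problem")
}

#' Weighted mean-squared error of a candidate rate vector
#'
#' MSE = sum over traces and points of w(t) (pred - obs)^2 / sum of w, with
#' w(t) = w1 for t < t1 and w2 for t >= t1. Predictions come from
#' [integrate_network()] with the known rates fixed and the unknowns set to
#' `k_un`. An integration failure yields +Inf with attribute `"failed"`.
#'
#' @param problem A `kp_fit_problem`.
#' @param k_un Named vector of values for every unknown rate (interface
#'   units). May be empty when the problem has no unknowns.
#' @return The scalar MSE (nM^2), with attribute `"per_trace"`.
#' @export
weighted_mse <- function(problem, k_un = numeric(0)) {
  miss <- setdiff(problem$rates$unknown, names(k_un))
  if (length(miss)) stop("values missing for unknowns: ",
                         paste(miss, collapse = ", "))
  rates <- if (length(k_un)) update_rates(problem$rates, k_un) else problem$rates
  total <- 0; wtot <- 0
  per <- numeric(length(problem$traces))
  for (j in seq_along(problem$traces)) {
    tr <- problem$traces[[j]]
    traj <- tryCatch(
      integrate_network(problem$network, rates, tr$initial, tr$times),
      error = function(e) e)
    if (inherits(traj, "error")) {
      out <- Inf
      attr(out, "failed") <- paste0(tr$name %||% j, ": ",
                                    conditionMessage(traj))
      return(out)
    }
    pred <- as.numeric(traj$conc[, names(tr$weights), drop = FALSE] %*%
                         tr$weights)
    w <- ifelse(tr$times < tr$t1, problem$w1, problem$w2)
    per[j] <- sum(w * (pred - tr$conc)^2)
    total <- total + per[j]
    wtot <- wtot + sum(w)
  }
  out <- total / wtot
  attr(out, "per_trace") <- per
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the unknown rate constants of a problem
#'
#' Bounded minimization of [weighted_mse()] over log10-transformed unknowns
#' (L-BFGS-B), multi-start: the first start is the log-midpoint of the bounds,
#' the rest are sampled log-uniformly within them from `seed`.
#'
#' @param problem A `kp_fit_problem` with at least one trace and unknown.
#' @param n_starts Number of starts (default 8).
#' @param seed Integer seed for the start sample.
#' @param init Optional named start vector (interface units) replacing the
#'   midpoint first start.
#' @param maxit Iteration cap per start.
#' @return A list of class `kp_fit`: `values` (fitted unknowns, interface
#'   units), `mse`, `per_trace`, `diagnostics` (per-start table),
#'   `history` (best-so-far objective over evaluations), `weak` (unknowns the
#'   data barely constrain), `converged`, `seed`.
#' @export
fit_rates <- function(problem, n_starts = 8, seed = 1, init = NULL,
                      maxit = 200) {
  un <- problem$rates$unknown
  if (!length(un)) stop("problem has no unknown rates")
  if (!length(problem$traces)) stop("problem has no traces")
  lb <- log10(vapply(problem$rates$bounds[un], `[`, 0, 1))
  ub <- log10(vapply(problem$rates$bounds[un], `[`, 0, 2))
  hist_env <- new.env()
  hist_env$v <- numeric(0)
  fn <- function(lp) {
    m <- weighted_mse(problem, stats::setNames(10^lp, un))
    m <- if (is.finite(m)) as.numeric(m) else 1e12
    hist_env$v <- c(hist_env$v, m)
    m
  }
  set.seed(as.integer(seed))
  starts <- matrix(stats::runif(n_starts * length(un)), nrow = n_starts)
  starts <- sweep(sweep(starts, 2, ub - lb, "*"), 2, lb, "+")
  starts[1, ] <- if (!is.null(init)) log10(init[un]) else (lb + ub) / 2
  best <- NULL
  diag <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    res <- stats::optim(starts[s, ], fn, method = "L-BFGS-B",
                        lower = lb, upper = ub,
                        control = list(maxit = maxit))
    diag[[s]] <- data.frame(start = s, value = res$value,
                            convergence = res$convergence,
                            evals = res$counts[1])
    if (is.null(best) || res$value < best$value) best <- res
  }
  diag <- do.call(rbind, diag)
  if (all(diag$convergence != 0) && !any(is.finite(diag$value)))
    stop("all starts failed to converge")
  values <- stats::setNames(10^best$par, un)
  mse <- weighted_mse(problem, values)
  # curvature probe: unknowns whose doubling/halving barely moves the MSE are
  # not constrained by the data (e.g. reverse proofreading at these designs)
  data_scale <- mean(vapply(problem$traces, function(tr) mean(tr$conc^2), 0))
  weak <- character(0)
  for (i in seq_along(un)) {
    probe <- vapply(c(-0.301, 0.301), function(d) {
      p <- best$par; p[i] <- min(max(p[i] + d, lb[i]), ub[i])
      fn(p)
    }, 0)
    if (max(probe) - best$value < 1e-4 * data_scale) weak <- c(weak, un[i])
  }
  structure(list(values = values, mse = as.numeric(mse),
                 per_trace = attr(mse, "per_trace"), diagnostics = diag,
                 history = hist_env$v, weak = weak,
                 converged = any(diag$convergence == 0),
                 seed = as.integer(seed)),
            class = "kp_fit")
}

#' @export
print.kp_fit <- function(x, ...) {
  cat("<kp_fit> MSE =", format(x$mse, digits = 6), "\n")
  for (nm in names(x$values))
    cat("  ", nm, "=", format(x$values[[nm]], digits = 6),
        if (nm %in% x$weak) "(weakly constrained)" else "", "\n")
  invisible(x)
}

## ---- staged protocol -------------------------------------------------------

stage3_bounds <- list(k_proof = c(1e2, 1e8), k_revproof = c(1e0, 1e6))

#' Select among candidate reporter rate sets
#'
#' For each candidate (a full-discard `kp_rates` whose known values carry that
#' candidate's reporter rate and whose stage-3 unknowns are marked), fits the
#' unknowns simultaneously on the template-recovery and full-discard traces,
#' and scores the candidate by the sum of the two experiment classes' weighted
#' MSEs at the optimum. Returns the argmin (1-based); exact ties are broken by
#' the lowest index and reported.
#'
#' @param candidates List of `kp_rates` on the full-discard network.
#' @param recovery,discard Lists of `kp_dataset`s (template-recovery and
#'   full-discard wells of one monomer variant).
#' @param seed Integer seed.
#' @param n_starts Starts per candidate fit.
#' @param w1,w2 Fitting weights.
#' @return A list of class `kp_selection`: `index`, `tie`, `errors` (one row
#'   per candidate: recovery/discard/total MSE), `fits`.
#' @export
select_reporter_set <- function(candidates, recovery, discard, seed = 1,
                                n_starts = 2, w1 = 1, w2 = 0.2) {
  if (!length(candidates)) stop("need at least one candidate")
  if (!length(recovery) || !length(discard))
    stop("stage 3: need both template-recovery and full-discard datasets")
  network <- discard[[1]]$network
  rec_tr <- lapply(recovery, as_fit_trace, channel = "af647_like")
  dis_tr <- lapply(discard, as_fit_trace, channel = "af647_like")
  fits <- vector("list", length(candidates))
  err <- data.frame(candidate = seq_along(candidates), recovery_mse = NA_real_,
                    discard_mse = NA_real_, total = NA_real_)
  for (k in seq_along(candidates)) {
    prob <- fit_problem(network, candidates[[k]], c(rec_tr, dis_tr), w1, w2)
    fit <- fit_rates(prob, n_starts = n_starts, seed = seed + k)
    p_rec <- fit_problem(network, candidates[[k]], rec_tr, w1, w2)
    p_dis <- fit_problem(network, candidates[[k]], dis_tr, w1, w2)
    err$recovery_mse[k] <- as.numeric(weighted_mse(p_rec, fit$values))
    err$discard_mse[k] <- as.numeric(weighted_mse(p_dis, fit$values))
    err$total[k] <- err$recovery_mse[k] + err$discard_mse[k]
    fits[[k]] <- fit
  }
  idx <- which.min(err$total)
  tie <- sum(err$total == err$total[idx]) > 1L
  structure(list(index = idx, tie = tie, errors = err, fits = fits),
            class = "kp_selection")
}

#' Staged rate-constant estimation
#'
#' The three-stage protocol: (1) template-binding wells identify the
#' blocker/template exchange rates, which become known rates downstream;
#' (2) reporter-triggering wells are fitted once per candidate total-monomer
#' concentration (a grid of `candidate_fracs` times the nominal, 8 candidates
#' by default, because the true monomer concentration in those wells is
#' uncertain), giving one reporter rate per candidate; (3) the remaining
#' unknowns (proofreading rates) are fitted simultaneously on the
#' template-recovery and full-discard wells once per candidate, and the
#' candidate minimizing the total stage-3 error is selected.
#'
#' @param study A `kp_study` containing `template_binding`, `reporter`,
#'   `template_recovery` and `full_discard` datasets (see
#'   [combine_studies()]).
#' @param variant Monomer variant the staged fit runs on.
#' @param candidate_fracs Candidate total-monomer fractions of nominal.
#' @param nominal_monomer Nominal total monomer concentration, nM.
#' @param seed Integer seed.
#' @param n_starts_stage1,n_starts_stage2,n_starts_stage3 Starts per stage.
#' @return A list of class `kp_staged_fit`: `rates` (final full-discard
#'   `kp_rates`), `stage1`, `stage2` (candidate table), `selection`.
#' @export
staged_fit <- function(study, variant = "M1",
                       candidate_fracs = seq(0.80, 1.15, by = 0.05),
                       nominal_monomer = 8, seed = 1,
                       n_starts_stage1 = 4, n_starts_stage2 = 3,
                       n_starts_stage3 = 2) {
  pick <- function(class) Filter(function(d)
    identical(d$class, class) &&
      (class == "reporter" || identical(d$variant, variant)),
    study$datasets)
  binding <- pick("template_binding")
  reporter <- pick("reporter")
  recovery <- pick("template_recovery")
  discard <- pick("full_discard")
  for (need in c("template_binding", "reporter", "template_recovery",
                 "full_discard")) {
    have <- switch(need, template_binding = binding, reporter = reporter,
                   template_recovery = recovery, full_discard = discard)
    stage <- switch(need, template_binding = "stage 1", reporter = "stage 2",
                    "stage 3")
    if (!length(have))
      stop(stage, ": study has no '", need, "' datasets",
           if (need != "reporter") paste0(" for variant ", variant))
  }

  # stage 1: blocker/template exchange rates from binding wells
  bnet <- binding[[1]]$network
  brates <- set_unknown(
    rate_set(bnet, c(k_bind = 1e4, k_unbind = 1e4)),
    c("k_bind", "k_unbind"),
    list(k_bind = c(1e2, 1e8), k_unbind = c(1e2, 1e8)))
  btr <- lapply(binding, as_fit_trace, channel = "cy3_like")
  stage1 <- fit_rates(fit_problem(bnet, brates, btr),
                      n_starts = n_starts_stage1, seed = seed)

  # stage 2: one reporter rate per candidate total-monomer concentration
  rnet <- reporter[[1]]$network
  rtr0 <- as_fit_trace(reporter[[1]], "af647_like")
  stage2 <- data.frame(candidate = seq_along(candidate_fracs),
                       frac = candidate_fracs, k_rep = NA_real_,
                       stage2_mse = NA_real_)
  base_vals <- c(k_proof = 1, k_revproof = 1, k_rep = 1e4)
  for (k in seq_along(candidate_fracs)) {
    tr <- rtr0
    tr$initial["MP"] <- candidate_fracs[k] * nominal_monomer
    rr <- set_unknown(rate_set(rnet, base_vals), "k_rep",
                      list(k_rep = c(1e2, 1e8)))
    f <- fit_rates(fit_problem(rnet, rr, list(tr)),
                   n_starts = n_starts_stage2, seed = seed + 100 + k)
    stage2$k_rep[k] <- f$values[["k_rep"]]
    stage2$stage2_mse[k] <- f$mse
  }

  # stage 3: proofreading rates per candidate on recovery + discard, select
  fnet <- discard[[1]]$network
  candidates <- lapply(seq_along(candidate_fracs), function(k) {
    vals <- c(k_bind = unname(stage1$values["k_bind"]),
              k_unbind = unname(stage1$values["k_unbind"]),
              k_proof = 1e4, k_revproof = 1e2,
              k_rep = stage2$k_rep[k])
    set_unknown(rate_set(fnet, vals), c("k_proof", "k_revproof"),
                stage3_bounds)
  })
  selection <- select_reporter_set(candidates, recovery, discard,
                                   seed = seed + 200,
                                   n_starts = n_starts_stage3)
  best <- selection$index
  final <- update_rates(candidates[[best]], selection$fits[[best]]$values)
  final$unknown <- character(0)
  final$known <- names(final$values)
  structure(list(rates = final, stage1 = stage1, stage2 = stage2,
                 selection = selection, variant = variant,
                 seed = as.integer(seed)),
            class = "kp_staged_fit")
}

#' @export
print.kp_staged_fit <- function(x, ...) {
  cat("<kp_staged_fit> variant", x$variant, "- selected candidate",
      x$selection$index,
      sprintf("(frac %.2f)", x$stage2$frac[x$selection$index]),
      if (x$selection$tie) "[tie]" else "", "\n")
  print(x$rates)
  invisible(x)
}
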