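# End-to-end analysis arcs: the solubility arc (diagram classification and
# stability constants per temperature) and the simulation arc (PMFs or a
# supplied free-energy table -> transition free energies -> Boltzmann
# ratios -> state ranking).

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[%s] %s", name, conditionMessage(e)))
  })
}

#' Run the phase-solubility analysis arc
#'
#' For each temperature present in the dataset: resolve the intrinsic
#' solubility, classify the diagram (A_L / A_p), estimate the effective
#' stoichiometry by log-log regression, and estimate stability constants by
#' every applicable method — the A_L slope formula, the linearized 1:1/1:2
#' regression, and the nonlinear least-squares fit — so the cross-method
#' agreement the diagrams support can be checked directly.
#'
#' @param data A phase-solubility tibble (`cd_total_M`, `s_total_M`, and
#'   optionally `temperature_K`; a single temperature is assumed when the
#'   column is absent).
#' @param s0 Optional intrinsic solubility, mol/L; default: per-temperature
#'   mean of the zero-cyclodextrin measurements.
#' @param alpha Significance level for diagram classification.
#' @return A `solubility_report`: list with `$summary` (one row per
#'   temperature: classification, `n_hat`, constants by method) and `$fits`
#'   (the underlying fit objects, keyed by temperature).
#' @export
run_solubility_arc <- function(data, s0 = NULL, alpha = 0.05) {
  .stage("input", .check_phase_data(data))
  if (!"temperature_K" %in% names(data)) data$temperature_K <- NA_real_
  temps <- unique(data$temperature_K)
  fits <- list()
  rows <- purrr::map(temps, function(tk) {
    d <- data[data$temperature_K %in% tk, , drop = FALSE]
    s0_t <- .stage("s0", .resolve_s0(d, s0, what = sprintf("%g K subset", tk)))
    cls <- .stage("classify", classify_profile(d, alpha = alpha))
    st <- .stage("loglog", fit_loglog_stoichiometry(d, s0 = s0_t))
    al <- if (cls$label == "A_L") {
      .stage("al_slope", fit_al_k11(d, s0 = s0_t))
    } else {
      tryCatch(fit_al_k11(d, s0 = s0_t), error = function(e) NULL)
    }
    lin <- .stage("ap_linearized", fit_ap_linearized(d, s0 = s0_t))
    nl <- .stage("ap_nonlinear", fit_ap_nonlinear(d, s0 = s0_t))
    fits[[as.character(tk)]] <<- list(classification = cls, loglog = st,
                                      al_slope = al, ap_linearized = lin,
                                      ap_nonlinear = nl)
    tibble(
      temperature_K = tk,
      s0_M = s0_t,
      profile = cls$label,
      curvature_pvalue = cls$curvature_pvalue,
      n_hat = st$n_hat,
      se_n = st$se_n,
      n_r_squared = st$r_squared,
      k11_al = if (is.null(al)) NA_real_ else al$k11,
      k11_ap_lin = lin$k11,
      k12_ap_lin = lin$k12,
      k11_ap_nl = nl$k11,
      k12_ap_nl = nl$k12
    )
  })
  structure(
    list(summary = dplyr::bind_rows(rows), fits = fits, alpha = alpha),
    class = "solubility_report"
  )
}

#' @export
print.solubility_report <- function(x, ...) {
  cat("Phase-solubility analysis\n")
  print(x$summary)
  invisible(x)
}

#' Run the complexation-thermodynamics arc
#'
#' Turns either reconstructed PMFs (from per-state pulling work ensembles)
#' or a supplied per-state free-energy table into transition free energies,
#' Boltzmann occupancy ratios and a stability ranking at each temperature.
#'
#' When `work` is given it must be a named list (names = state labels) of
#' work-ensemble tibbles; each state's binding free energy is the PMF value
#' at the bound end minus the unbound end, \eqn{\Delta G_{unbound \to s} =
#' F(\lambda_{first}) - F(\lambda_{last})}, with jackknife SDs. An element
#' may itself be a list of ensembles for a state reached by sequential
#' pulls; the endpoint differences then add and their SDs combine in
#' quadrature.
#'
#' @param work Named list of work ensembles (or `NULL` to use `states`).
#' @param states A free-energy table (`state`, `temperature_K`,
#'   `dg_kcal_mol`, `sd_kcal_mol`), e.g. [free_energy_states()]; ignored
#'   when `work` is given.
#' @param temperature Temperature(s), K, to analyse. With `work`, the single
#'   temperature of the ensembles.
#' @param transitions List of `c(from, to)` state pairs to report; default:
#'   every tabulated state versus every other, `to` more stable first.
#' @param estimator PMF estimator for `work` mode: `"jarzynski"` (default),
#'   `"cumulant2"` or `"mean_work"`.
#' @return A `simulation_report`: list with `$free_energies` (the per-state
#'   table used), `$transitions` (with `ratio` = [boltzmann_ratio()] of each
#'   transition) and `$ranking` (per temperature).
#' @export
run_simulation_arc <- function(work = NULL, states = NULL, temperature = NULL,
                               transitions = NULL,
                               estimator = c("jarzynski", "cumulant2",
                                             "mean_work")) {
  estimator <- match.arg(estimator)
  if (is.null(work) && is.null(states)) {
    abort("Provide either `work` ensembles or a `states` free-energy table.")
  }

  if (!is.null(work)) {
    if (is.null(names(work)) || any(!nzchar(names(work)))) {
      abort("`work` must be a named list: names are state labels.")
    }
    est_fn <- switch(estimator, jarzynski = jarzynski_pmf,
                     cumulant2 = cumulant_pmf, mean_work = mean_work_pmf)
    states <- dplyr::bind_rows(purrr::imap(work, function(w, state) {
      pieces <- if (is.data.frame(w)) list(w) else w
      deltas <- purrr::map(pieces, function(piece) {
        prof <- .stage(paste0("pmf:", state),
                       est_fn(piece, temperature = temperature))
        .stage(paste0("delta:", state),
               pmf_delta(prof, min(prof$lambda_A), max(prof$lambda_A)))
      })
      # pulls run bound -> unbound, so binding dG is minus the pull total
      tibble(
        state = state,
        temperature_K = temperature %||%
          attr(pieces[[1]], "temperature_K") %||% NA_real_,
        dg_kcal_mol = -sum(purrr::map_dbl(deltas, "dg_kcal_mol")),
        sd_kcal_mol = sqrt(sum(purrr::map_dbl(deltas, "sd_kcal_mol")^2))
      )
    }))
  }
  states <- .stage("states", .check_state_table(states))
  temps <- unique(states$temperature_K)

  trans_rows <- dplyr::bind_rows(purrr::map(temps, function(tk) {
    avail <- states$state[states$temperature_K == tk]
    pairs <- transitions %||% {
      all_states <- c(avail, "unbound")
      combs <- utils::combn(all_states, 2, simplify = FALSE)
      purrr::map(combs, function(p) {
        dgs <- purrr::map_dbl(p, function(s) .lookup_state(states, s, tk)$dg)
        p[order(dgs, decreasing = TRUE)] # to = the more stable state
      })
    }
    dplyr::bind_rows(purrr::map(pairs, function(p) {
      if (!all(p %in% c(avail, "unbound"))) return(NULL)
      .stage("transition", transition_dg(states, p[1], p[2], tk))
    }))
  }))
  trans_rows$ratio <- boltzmann_ratio(trans_rows$dg_kcal_mol,
                                      trans_rows$temperature_K)
  ranking <- purrr::map(setNames(temps, temps),
                        function(tk) .stage("ranking", rank_states(states, tk)))
  structure(
    list(free_energies = states, transitions = trans_rows, ranking = ranking,
         estimator = if (is.null(work)) NA_character_ else estimator),
    class = "simulation_report"
  )
}

#' @export
print.simulation_report <- function(x, ...) {
  cat("Complexation-state thermodynamics\n")
  print(x$transitions)
  for (tk in names(x$ranking)) {
    cat(sprintf("Ranking at %s K (least -> most stable): %s\n", tk,
                paste(x$ranking[[tk]]$state, collapse = " > ")))
  }
  invisible(x)
}
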