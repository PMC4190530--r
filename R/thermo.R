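# State free-energy bookkeeping, Boltzmann occupancy ratios and Arrhenius
# rate-ratio estimation between drug-cyclodextrin complexation states.

#' Free energies of celecoxib/HP-beta-CD complexation states
#'
#' Ships the free-energy differences (relative to the unbound state, with
#' repeat-based standard deviations) of the celecoxib/
#' hydroxypropyl-beta-cyclodextrin complexation states at 298 and 333 K,
#' obtained from steered-pulling free-energy reconstructions: two 1:1
#' inclusion complexes (I: F-ring enclosed; II: M-ring enclosed), the 1:2
#' inclusion complex (III) and the 1:1 surface-association complex (IV,
#' observed at 333 K only). The unbound state is the zero of each column and
#' is not stored.
#'
#' @return A tibble with columns `state`, `temperature_K`, `dg_kcal_mol`,
#'   `sd_kcal_mol`.
#' @seealso [transition_dg()], [rank_states()], [boltzmann_ratio()]
#' @export
#' @examples
#' free_energy_states()
free_energy_states <- function() {
  path <- system.file("extdata", "celecoxib_hpbcd_state_dg.csv",
                      package = "cdinclusion", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    state = readr::col_character(),
    temperature_K = readr::col_double(),
    dg_kcal_mol = readr::col_double(),
    sd_kcal_mol = readr::col_double()
  ))
}

.check_state_table <- function(table) {
  .require_columns(table, c("state", "temperature_K", "dg_kcal_mol"),
                   "a free-energy state table")
  if (!"sd_kcal_mol" %in% names(table)) table$sd_kcal_mol <- 0
  key <- paste(table$state, table$temperature_K)
  if (anyDuplicated(key)) {
    abort("Free-energy table has duplicated (state, temperature_K) pairs.")
  }
  if (any(table$sd_kcal_mol < 0, na.rm = TRUE)) {
    abort("`sd_kcal_mol` must be >= 0.")
  }
  table
}

.lookup_state <- function(table, state, temperature) {
  if (identical(state, "unbound")) {
    return(list(dg = 0, sd = 0))
  }
  row <- table[table$state == state & table$temperature_K == temperature, ]
  if (nrow(row) != 1) {
    abort(sprintf(
      "State `%s` at %g K is not in the free-energy table (available: %s).",
      state, temperature,
      paste(unique(paste0(table$state, "@", table$temperature_K, "K")),
            collapse = ", ")
    ))
  }
  list(dg = row$dg_kcal_mol, sd = row$sd_kcal_mol)
}

#' Free-energy difference between two complexation states
#'
#' Computes \eqn{\Delta G_{from \to to} = \Delta G_{unbound \to to} -
#' \Delta G_{unbound \to from}} at one temperature, propagating the
#' repeat-based standard deviations in quadrature (the per-state estimates
#' are treated as independent). The label `"unbound"` is always available
#' with \eqn{\Delta G = 0}.
#'
#' @param table A free-energy state table (columns `state`, `temperature_K`,
#'   `dg_kcal_mol`, `sd_kcal_mol`), e.g. [free_energy_states()].
#' @param from,to State labels.
#' @param temperature Temperature, K; both states must be tabulated at it.
#' @return A one-row tibble: `from`, `to`, `temperature_K`, `dg_kcal_mol`,
#'   `sd_kcal_mol`. Antisymmetric in `from`/`to`.
#' @export
#' @examples
#' transition_dg(free_energy_states(), "II", "I", 298)$dg_kcal_mol # -2.174
transition_dg <- function(table, from, to, temperature) {
  table <- .check_state_table(table)
  .check_scalar(temperature, "temperature", positive = TRUE)
  if (identical(from, to)) {
    return(tibble(from = from, to = to, temperature_K = temperature,
                  dg_kcal_mol = 0, sd_kcal_mol = 0))
  }
  a <- .lookup_state(table, from, temperature)
  b <- .lookup_state(table, to, temperature)
  tibble(
    from = from, to = to, temperature_K = temperature,
    dg_kcal_mol = b$dg - a$dg,
    sd_kcal_mol = sqrt(a$sd^2 + b$sd^2)
  )
}

#' Boltzmann occupancy ratio between two states
#'
#' For a system equilibrating from a common starting point, the relative
#' probability of ending in state B versus state A with
#' \eqn{\Delta G = G_B - G_A} is
#' \deqn{\frac{C_B}{C_A} = \exp\!\left(-\frac{\Delta G}{R T}\right),}
#' with \eqn{R = 1.987 \times 10^{-3}} kcal/(mol K). Vectorized over `dg`
#' and `temperature`.
#'
#' @param dg Free-energy difference(s) \eqn{G_{to} - G_{from}}, kcal/mol.
#' @param temperature Temperature(s), K (> 0).
#' @return Dimensionless probability ratio(s) \eqn{C_{to}/C_{from}}.
#' @export
#' @examples
#' boltzmann_ratio(-3.701, 333) # ~269
boltzmann_ratio <- function(dg, temperature) {
  .check_numeric(dg, "dg")
  .check_numeric(temperature, "temperature")
  if (any(temperature <= 0)) abort("`temperature` must be > 0 K.")
  exp(-dg / (.R_KCAL * temperature))
}

#' Arrhenius rate ratio upon a temperature change
#'
#' Under the Arrhenius law \eqn{k = A \exp(-E_a / RT)} with a
#' temperature-independent frequency factor \eqn{A}, the rate ratio between
#' two temperatures is
#' \deqn{\frac{k(T_2)}{k(T_1)} =
#'   \exp\!\left(-\frac{E_a}{R}\left(\frac{1}{T_2} -
#'   \frac{1}{T_1}\right)\right).}
#' The activation energy is a caller-supplied parameter: which barrier
#' governs a given interconversion is a modelling choice, not something this
#' function infers.
#'
#' @param ea Activation energy, kcal/mol.
#' @param t1,t2 Temperatures, K (> 0).
#' @return Dimensionless ratio \eqn{k(T_2)/k(T_1)}.
#' @export
#' @examples
#' arrhenius_rate_ratio(8.827, 298, 333)
arrhenius_rate_ratio <- function(ea, t1, t2) {
  .check_numeric(ea, "ea")
  .check_scalar(t1, "t1", positive = TRUE)
  .check_scalar(t2, "t2", positive = TRUE)
  exp(-(ea / .R_KCAL) * (1 / t2 - 1 / t1))
}

#' Rank complexation states by free energy at one temperature
#'
#' Orders the states tabulated at `temperature` (plus the implicit unbound
#' state at 0) from highest to lowest free energy, i.e. least to most
#' stable. Ties are broken alphabetically with a message.
#'
#' @inheritParams transition_dg
#' @return A tibble (`state`, `dg_kcal_mol`) ordered by decreasing free
#'   energy; `$state[1]` is the least stable state.
#' @export
#' @examples
#' rank_states(free_energy_states(), 333)$state
rank_states <- function(table, temperature) {
  table <- .check_state_table(table)
  .check_scalar(temperature, "temperature", positive = TRUE)
  rows <- table[table$temperature_K == temperature, c("state", "dg_kcal_mol")]
  if (nrow(rows) < 1) {
    abort(sprintf("No states tabulated at %g K.", temperature))
  }
  rows <- dplyr::bind_rows(tibble(state = "unbound", dg_kcal_mol = 0), rows)
  if (anyDuplicated(rows$dg_kcal_mol)) {
    inform("rank_states: tied free energies broken alphabetically.")
  }
  dplyr::arrange(rows, dplyr::desc(.data$dg_kcal_mol), .data$state)
}
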