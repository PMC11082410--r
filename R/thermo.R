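#' Specify a membrane transport step for free-energy evaluation
#'
#' @param charge signed integer ion charge Z.
#' @param potential transmembrane potential in volts, signed along the
#'   transport direction (the electrical work term is `Z F V`).
#' @param conc_origin,conc_dest ion concentrations (mmol/l or any common
#'   unit) at the origin and destination compartments; for protons pass
#'   `ph_origin`/`ph_dest` instead and activities `10^-pH` are used.
#' @param ph_origin,ph_dest origin/destination pH (alternative to the
#'   concentration pair).
#' @param temperature temperature in kelvin (default 310, body temperature).
#' @param gas_constant gas constant in J/(mol K).
#' @param faraday Faraday constant in C/mol.
#' @return an object of class `transport_spec`.
#' @export
transport_spec <- function(charge, potential, conc_origin = NULL,
                           conc_dest = NULL, ph_origin = NULL, ph_dest = NULL,
                           temperature = 310, gas_constant = 8.31,
                           faraday = 96485.3) {
  if (!is.null(ph_origin) || !is.null(ph_dest)) {
    if (is.null(ph_origin) || is.null(ph_dest)) {
      stop("provide both `ph_origin` and `ph_dest`", call. = FALSE)
    }
    conc_origin <- 10^(-ph_origin)
    conc_dest <- 10^(-ph_dest)
  }
  if (is.null(conc_origin) || is.null(conc_dest)) {
    stop("provide `conc_origin`/`conc_dest` or `ph_origin`/`ph_dest`",
         call. = FALSE)
  }
  if (conc_origin <= 0 || conc_dest <= 0) {
    stop("concentrations must be positive", call. = FALSE)
  }
  assert_scalar_number(temperature, "temperature", lower = 1e-12)
  structure(list(charge = charge, potential = potential,
                 conc_origin = conc_origin, conc_dest = conc_dest,
                 temperature = temperature, gas_constant = gas_constant,
                 faraday = faraday),
            class = "transport_spec")
}

#' Transport free energy of one ion movement
#'
#' `dG = Z F V + R T ln(conc_dest / conc_origin)` in J/mol. Negative values
#' mean the movement is downhill.
#'
#' @param spec a [transport_spec()].
#' @return free energy in J/mol.
#' @export
transport_deltaG <- function(spec) {
  stopifnot(inherits(spec, "transport_spec"))
  with(spec, charge * faraday * potential +
         gas_constant * temperature * log(conc_dest / conc_origin))
}

#' Free energy of an electroneutral coupled antiport
#'
#' For a 1:1 exchange across the same membrane the electrical terms of the
#' two legs cancel exactly, leaving
#' `dG = R T [ln(ratio_1) + ln(ratio_2)]`.
#'
#' @param spec_a,spec_b the two [transport_spec()] legs; their potentials
#'   must be opposite (antiport across one membrane) and their temperatures
#'   equal.
#' @return free energy in J/mol; independent of the membrane potential.
#' @export
coupled_exchange_deltaG <- function(spec_a, spec_b) {
  stopifnot(inherits(spec_a, "transport_spec"),
            inherits(spec_b, "transport_spec"))
  if (abs(spec_a$potential + spec_b$potential) > 1e-12) {
    stop("antiport legs must have opposite potentials", call. = FALSE)
  }
  if (abs(spec_a$temperature - spec_b$temperature) > 1e-9) {
    stop("antiport legs must share one temperature", call. = FALSE)
  }
  with(spec_a, gas_constant * temperature) *
    (log(spec_a$conc_dest / spec_a$conc_origin) +
       log(spec_b$conc_dest / spec_b$conc_origin))
}

#' Two-compartment tissue sodium model
#'
#' A unit of tissue splits into extracellular and intracellular volume
#' fractions; the volume-weighted total sodium concentration (TSC) of a
#' cancer tissue is `k` times the matching normal one, with the
#' extracellular concentration assumed stable.
#'
#' @param esc extracellular sodium concentration (mmol/l).
#' @param isc_n normal intracellular sodium concentration (mmol/l).
#' @param k cancer-to-normal TSC ratio; values outside \[2, 3\] warn.
#' @param vol_extracellular,vol_intracellular volume fractions summing to 1.
#' @return an object of class `sodium_model`.
#' @export
sodium_model <- function(esc = 140, isc_n = 12, k = 2,
                         vol_extracellular = 0.2, vol_intracellular = 0.8) {
  if (abs(vol_extracellular + vol_intracellular - 1) > 1e-9) {
    stop("volume fractions must sum to 1", call. = FALSE)
  }
  if (vol_intracellular == 0) stop("intracellular volume fraction is zero", call. = FALSE)
  if (k < 2 || k > 3) {
    warning("k outside the reported 2-3 fold range of total sodium in cancer")
  }
  structure(list(esc = esc, isc_n = isc_n, k = k,
                 vol_extracellular = vol_extracellular,
                 vol_intracellular = vol_intracellular),
            class = "sodium_model")
}

#' Cancer intracellular sodium concentration implied by the model
#'
#' `TSC_N = v_e ESC + v_i ISC_N`, and
#' `ISC_C = (k TSC_N - v_e ESC) / v_i`: affine and strictly increasing in `k`.
#'
#' @param model a [sodium_model()].
#' @return ISC in cancer, mmol/l.
#' @export
solve_cancer_isc <- function(model) {
  stopifnot(inherits(model, "sodium_model"))
  tsc_n <- normal_tsc(model)
  (model$k * tsc_n - model$vol_extracellular * model$esc) / model$vol_intracellular
}

#' Normal-tissue total sodium concentration
#'
#' @param model a [sodium_model()].
#' @return volume-weighted TSC of the normal tissue, mmol/l.
#' @export
normal_tsc <- function(model) {
  stopifnot(inherits(model, "sodium_model"))
  model$vol_extracellular * model$esc + model$vol_intracellular * model$isc_n
}

#' Thermodynamic feasibility verdict
#'
#' @param deltaG free energy in J/mol.
#' @return `"feasible"` (negative), `"infeasible"` (positive) or
#'   `"marginal"` (zero).
#' @export
feasibility <- function(deltaG) {
  if (!is.finite(deltaG)) stop("`deltaG` must be finite", call. = FALSE)
  if (deltaG > 0) "infeasible" else if (deltaG < 0) "feasible" else "marginal"
}

#' Net proton balance of an ATP production/consumption cycle
#'
#' ATP production by glucose fermentation (Warburg effect) is pH neutral per
#' ATP; production by respiration consumes one proton per ATP; every ATP
#' hydrolysis releases one proton. The cycle couples each hydrolysis event
#' with one production event of the chosen pathway.
#'
#' @param production `"warburg"`, `"respiration"` or `"none"` (no coupled
#'   production; hydrolysis of an existing pool).
#' @param hydrolysis_events nonnegative count of ATP hydrolysis events.
#' @return signed integer net protons.
#' @export
atp_pathway_balance <- function(production = c("warburg", "respiration", "none"),
                                hydrolysis_events = 1L) {
  production <- match.arg(production)
  assert_scalar_number(hydrolysis_events, "hydrolysis_events", lower = 0)
  per_atp <- switch(production, warburg = 0L, respiration = -1L, none = 0L)
  as.integer(hydrolysis_events) * (per_atp + 1L)
}

#' The bundled net-proton / CO2 ledger of Fenton-associated RMs
#'
#' Per reprogrammed metabolism positively associated with the cytosolic
#' Fenton reaction: the averaged contribution score and rate of contribution
#' from the cross-cancer L1 association, and the exact net protons and CO2
#' released per product unit. Conditional rows carry yields of "0 or +n".
#'
#' @return data.frame with columns `rm`, `contribution_score`,
#'   `rate_of_contribution`, `h_plus`, `co2`, `per_unit`, `conditional`.
#' @export
rm_proton_ledger <- function() {
  utils::read.delim(system.file("extdata", "proton_ledger.tsv",
                                package = "fentonflux", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Net proton / CO2 yield of one reprogrammed metabolism
#'
#' @param rm_name RM name as listed in the ledger ([rm_proton_ledger()]).
#' @return object of class `proton_yield`: integers `h_plus` and `co2` per
#'   product unit, the unit, and for conditional entries the `h_plus_range`
#'   (both admissible values).
#' @export
net_protons <- function(rm_name) {
  ledger <- rm_proton_ledger()
  i <- match(rm_name, ledger$rm)
  if (is.na(i)) {
    stop("unknown RM '", rm_name, "'; ledger entries: ",
         paste(ledger$rm, collapse = ", "), call. = FALSE)
  }
  row <- ledger[i, ]
  structure(list(rm = row$rm, h_plus = as.integer(row$h_plus),
                 co2 = as.integer(row$co2), per_unit = row$per_unit,
                 conditional = isTRUE(row$conditional),
                 h_plus_range = if (isTRUE(row$conditional)) {
                   c(0L, as.integer(row$h_plus))
                 } else {
                   rep(as.integer(row$h_plus), 2L)
                 }),
            class = "proton_yield")
}

#' @export
print.proton_yield <- function(x, ...) {
  hp <- if (x$conditional) paste0("0 or +", x$h_plus) else sprintf("%+d", x$h_plus)
  parts <- character()
  if (x$h_plus != 0L || x$co2 == 0L) parts <- c(parts, paste0(hp, " H+"))
  if (x$co2 != 0L) parts <- c(parts, sprintf("%+d CO2", x$co2))
  cat(sprintf("%s: %s per %s\n", x$rm, paste(parts, collapse = ", "), x$per_unit))
  invisible(x)
}
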