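# Empirical dose-response rules: leukocyte adhesion as a function of
# wall shear stress and cytokine exposure, and stiffness-dependent
# transmigration fractions. Each adhesion rule returns the regression
# value R/(rho t) in mm/s-equivalent units; conversion to a per-tick
# probability happens in adhesion_probability().

LEUK_TYPES <- c("NEUTROPHIL", "MONOCYTE", "LYMPHOCYTE")
AGENT_TYPES <- c("NEUTROPHIL", "MONOCYTE", "LYMPHOCYTE", "M1", "M2", "FOAM")

# sphere volumes from cell diameters (um): neutrophil/lymphocyte 12,
# monocyte-lineage 24, foam cell 25
AGENT_VOLUME_UM3 <- c(
  NEUTROPHIL = 4 / 3 * pi * 6^3,
  MONOCYTE   = 4 / 3 * pi * 12^3,
  LYMPHOCYTE = 4 / 3 * pi * 6^3,
  M1         = 4 / 3 * pi * 12^3,
  M2         = 4 / 3 * pi * 12^3,
  FOAM       = 4 / 3 * pi * 12.5^3
)

# wall lifespans in ticks (1 tick = 1 h): neutrophils 3 days,
# monocyte-lineage and lymphocytes 7 days, foam cells persistent
AGENT_LIFESPAN_TICKS <- c(NEUTROPHIL = 72, MONOCYTE = 168, LYMPHOCYTE = 168,
                          M1 = 168, M2 = 168, FOAM = Inf)

# shared sigmoid for TNF-alpha driven adhesion (all three leukocyte types)
.rule_tnfa <- function(x) {
  out <- numeric(length(x))
  lo <- x <= 1 & x > 0
  hi <- x > 1
  out[lo] <- 1180 * (0.0996 * x[lo])
  out[hi] <- 1180 * (0.80 - 0.68 * (1 - exp(-0.33 * log10(x[hi]) - 0.56)))
  pmax(out, 0)
}

.rule_il1b_neu <- function(x) {
  pmax(1900 * (0.10 + 0.19 * (1 - exp(-28.29 * x^1.46))), 0) * (x > 0)
}

.rule_il1b_mon <- function(x) {
  pmax(1600 * (0.14 + 0.80 * (1 - exp(-0.58 * x^1.19))), 0) * (x > 0)
}

.rule_wss_neu <- function(x) {
  v <- 1300 * (0.26 * x^2 - 0.8 * x + 0.63)
  pmax(v, 0) * (x > 0 & x < 1.2)
}

.rule_wss_mon <- function(x) {
  v <- 1600 * (-0.3295 * x^3 + 1.4 * x^2 - 1.8 * x + 0.79)
  pmax(v, 0) * (x > 0 & x < 1.0)
}

.rule_wss_lym <- function(x) {
  v <- 125 * (-9.93 * x^3 + 11 * x^2 - 4.1 * x + 0.55)
  pmax(v, 0) * (x > 0.04 & x < 0.41)
}

#' Registry of adhesion rules
#'
#' Returns the piecewise empirical functions mapping a stimulus (wall shear
#' stress in Pa, or TNF-alpha / IL-1beta concentration in U/ml) to the
#' leukocyte-adhesion regression value for each leukocyte type. Outside the
#' printed domain the shear-stress rules are identically zero.
#'
#' @return Nested list `rules[[type]][[stimulus]]`, stimuli `WSS`, `TNFA`,
#'   `IL1B`.
#' @export
adhesion_rules <- function() {
  list(
    NEUTROPHIL = list(WSS = .rule_wss_neu, TNFA = .rule_tnfa,
                      IL1B = .rule_il1b_neu),
    MONOCYTE   = list(WSS = .rule_wss_mon, TNFA = .rule_tnfa,
                      IL1B = .rule_il1b_mon),
    LYMPHOCYTE = list(WSS = .rule_wss_lym, TNFA = .rule_tnfa,
                      IL1B = .rule_il1b_neu)
  )
}

#' Evaluate one adhesion rule
#'
#' @param type Leukocyte type: `"NEUTROPHIL"`, `"MONOCYTE"` or
#'   `"LYMPHOCYTE"`.
#' @param stimulus `"WSS"`, `"TNFA"` or `"IL1B"`.
#' @param x Stimulus value(s): Pa for WSS, U/ml for cytokines. Must be
#'   non-negative.
#' @return Rule value(s), zero outside the rule's domain.
#' @export
eval_rule <- function(type, stimulus, x) {
  stopifnot(all(x >= 0))
  adhesion_rules()[[match.arg(type, LEUK_TYPES)]][[
    match.arg(stimulus, c("WSS", "TNFA", "IL1B"))]](x)
}

#' Stiffness-dependent transmigration percentage
#'
#' Fraction (in percent) of adherent leukocytes that cross the endothelium,
#' as a function of wall stiffness. Monocytes and lymphocytes share one
#' rule (quadratic on 1-5 kPa, 95% above 5 kPa); neutrophils follow a
#' linear rule on 0.42-5 kPa with 91% above. Below the rule domain the
#' lower-edge value is used.
#'
#' @param stiffness_kpa Wall stiffness in kPa (> 0).
#' @param type Leukocyte type.
#' @return Percent transmigrating, in `[0, 100]`.
#' @export
tem_fraction <- function(stiffness_kpa, type) {
  stopifnot(all(stiffness_kpa > 0))
  type <- match.arg(type, LEUK_TYPES)
  if (type == "NEUTROPHIL") {
    x <- pmax(stiffness_kpa, 0.42)
    ifelse(x > 5, 91, 9.18 * x + 46.96)
  } else {
    x <- pmax(stiffness_kpa, 1)
    ifelse(x > 5, 95, 0.78 * x^2 + 4.8 * x + 51.06)
  }
}

# cytokine production increments, U/ml per cell per tick (rules 13-15);
# M1 macrophages and foam cells produce at monocyte rates, M2 at the
# lymphocyte IL-10 rate (switchable via `extended`)
PROD_RATES <- list(
  TNFA = c(NEUTROPHIL = 5e-6, MONOCYTE = 6.7e-4),
  IL1B = c(NEUTROPHIL = 5e-7, MONOCYTE = 5e-5),
  IL10 = c(LYMPHOCYTE = 3.75e-5)
)

#' Cytokine production from per-voxel cell counts
#'
#' @param counts Named list of per-voxel count vectors (or arrays), one per
#'   agent type present; missing types contribute nothing.
#' @param extended If `TRUE` (default) M1 macrophages (the pro-inflammatory
#'   monocyte-derived phenotype) produce at the monocyte rates and M2
#'   macrophages produce IL-10 at the lymphocyte rate; foam cells are
#'   secretion-silent (lipid-laden macrophages with suppressed secretion).
#'   If `FALSE` only the three circulating types produce.
#' @return Named list of increments (same shape as the inputs) for `TNFA`,
#'   `IL1B`, `IL10` in U/ml per tick.
#' @export
produce_cytokines <- function(counts, extended = TRUE) {
  g <- function(t) if (!is.null(counts[[t]])) counts[[t]] else 0
  pro <- g("MONOCYTE")
  il10_src <- g("LYMPHOCYTE")
  if (extended) {
    pro <- pro + g("M1")
    il10_src <- il10_src + g("M2")
  }
  list(
    TNFA = PROD_RATES$TNFA[["NEUTROPHIL"]] * g("NEUTROPHIL") +
      PROD_RATES$TNFA[["MONOCYTE"]] * pro,
    IL1B = PROD_RATES$IL1B[["NEUTROPHIL"]] * g("NEUTROPHIL") +
      PROD_RATES$IL1B[["MONOCYTE"]] * pro,
    IL10 = PROD_RATES$IL10[["LYMPHOCYTE"]] * il10_src
  )
}

#' IL-10 mediated removal of pro-inflammatory cytokines
#'
#' Per tick, IL-1beta is multiplied by `max(0, 1 - 0.0096 IL10)` and
#' TNF-alpha by `max(0, 1 - 0.0095 IL10)`.
#'
#' @param tnfa,il1b,il10 Concentration vectors or arrays (U/ml, >= 0).
#' @return List with cleared `TNFA` and `IL1B`.
#' @export
il10_clearance <- function(tnfa, il1b, il10) {
  list(TNFA = tnfa * pmax(0, 1 - 0.0095 * il10),
       IL1B = il1b * pmax(0, 1 - 0.0096 * il10))
}

#' Shear-gated LDL wall-surface concentration and influx
#'
#' The wall-surface LDL concentration is `C_w = c0 * P(wss)` where `P` is
#' the empirical shear polynomial; 70% of `C_w` enters the wall per tick.
#' The printed polynomial carries two cubic terms; by default the second is
#' read as quadratic (degree sequence 6..0); `literal_cubic = TRUE` keeps
#' both cubic.
#'
#' @param wss Wall shear stress (Pa, >= 0).
#' @param c0_blood Luminal LDL concentration (ng/ul == ug/ml).
#' @param literal_cubic Use the literal duplicated-cubic reading.
#' @return List with `cw` (wall-surface concentration) and `influx`
#'   (concentration entering the adjacent wall voxel per tick), both >= 0.
#' @export
ldl_wall_influx <- function(wss, c0_blood = 960, literal_cubic = FALSE) {
  x <- wss
  stopifnot(all(x >= 0))
  p <- 2e-8 * x^6 - 2e-6 * x^5 + 6e-5 * x^4 - 1.1e-3 * x^3 - 0.05 * x + 1.15
  p <- p + if (literal_cubic) 1.04e-2 * x^3 else 1.04e-2 * x^2
  cw <- pmax(c0_blood * p, 0)
  list(cw = cw, influx = 0.70 * cw)
}

#' LDL oxidation step
#'
#' Each tick 1.2% of the local LDL concentration converts to oxidized LDL.
#'
#' @param ldl,oxldl Concentration vectors or arrays (ug/ml, >= 0).
#' @return List with updated `LDL` and `OXLDL`.
#' @export
oxidize_ldl <- function(ldl, oxldl) {
  d <- 0.012 * ldl
  list(LDL = ldl - d, OXLDL = oxldl + d)
}

# blood composition (Table 1): 7e9 leukocytes per litre = 7000 per mm^3
BLOOD_CONC_PER_MM3 <- c(NEUTROPHIL = 0.62, MONOCYTE = 0.053,
                        LYMPHOCYTE = 0.30) * 7000
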