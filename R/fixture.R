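#' Built-in reduced fixture network
#'
#' A 12-species, 14-reaction single-compartment network that reproduces, at
#' small scale, the structural features of the full ERK-activation model:
#'
#' * an **ultrasensitive kinase switch** — CaMKII is seeded by calcium
#'   (`K_CK1`), autophosphorylates (`K_CK2`) and is reset by a fixed PP1 pool
#'   (`K_PP1`); with `K_CK2 * CaMKII_total > K_PP1 * PP1` the phosphorylated
#'   state self-sustains once triggered, mimicking the CaMKII/PP1 switch;
#' * a **linear cAMP branch** — cAMP activates a GEF (`K_gef_on`/`K_gef_off`)
#'   which drives ERK phosphorylation (`K_erk_gef`), a graded, non-switch
#'   route standing in for the Epac arm;
#' * **competition for a shared substrate** — the GEF branch and a Gi
#'   beta-gamma/Src branch (`K_src_on`/`K_src_off`, `K_erk_src`) both draw on
#'   the same finite ERK pool, so co-stimulation saturates and sums
#'   sublinearly, the mechanism behind sublinear pathway combination.
#'
#' Inputs (`calcium`, `cAMP`, `Gibg`) start at zero and are cleared
#' first-order (`K_pump`, `K_pde`, `K_gibg_clear`); `K_mkp` dephosphorylates
#' ppERK. All rate constants are documented constants of the fixture, chosen
#' for minute-scale dynamics at nM concentrations; they are not fitted to any
#' published quantity.
#'
#' @param volume compartment volume in um^3 (default 4).
#' @return a `reaction_network` tagged as fixture parameterization.
#' @export
build_fixture_network <- function(volume = 4) {
  species <- data.frame(
    name = c("calcium", "CaMKII", "pCaMKII", "PP1", "cAMP", "GEF", "GEFa",
             "Gibg", "Src", "GibgSrc", "ERK", "ppERK"),
    initial_nM = c(0, 100, 0, 20, 0, 100, 0, 0, 100, 0, 200, 0),
    role = c("input", "kinase", "kinase", "phosphatase", "input", "gef", "gef",
             "input", "kinase", "kinase", "kinase", "kinase"),
    stringsAsFactors = FALSE)
  reactions <- data.frame(
    label = c("K_pump", "K_CK1", "K_CK2", "K_PP1", "K_pde", "K_gef_on",
              "K_gef_off", "K_erk_gef", "K_src_on", "K_src_off", "K_erk_src",
              "K_mkp", "K_erk_ck", "K_gibg_clear"),
    reactants = c("calcium", "calcium + CaMKII", "pCaMKII + CaMKII",
                  "pCaMKII + PP1", "cAMP", "cAMP + GEF", "GEFa",
                  "GEFa + ERK", "Gibg + Src", "GibgSrc", "GibgSrc + ERK",
                  "ppERK", "pCaMKII + ERK", "Gibg"),
    products = c("", "calcium + pCaMKII", "2 pCaMKII", "CaMKII + PP1", "",
                 "cAMP + GEFa", "GEF", "GEFa + ppERK", "GibgSrc",
                 "Gibg + Src", "GibgSrc + ppERK", "ERK",
                 "pCaMKII + ppERK", ""),
    kf = c(5, 0.002, 0.1, 0.05, 2, 0.001, 0.1, 0.001, 0.01, 0.1, 0.001,
           0.1, 0.0005, 0.1),
    kr = NA_real_,
    stringsAsFactors = FALSE)
  reaction_network(species, reactions, volume = volume,
                   parameterization = "fixture")
}

# Deterministic fixed point of the fixture's cAMP/Gibg output stage given
# steady effector levels; used by tests as an independent closed-form check.
# With GEFa, GibgSrc, pCaMKII held fixed, ppERK* = T * v / (v + k_mkp) where
# v = k_erk_gef*GEFa + k_erk_src*GibgSrc + k_erk_ck*pCaMKII.
.fixture_ppERK_fixed_point <- function(GEFa = 0, GibgSrc = 0, pCaMKII = 0,
                                       ERK_total = 200) {
  v <- 0.001 * GEFa + 0.001 * GibgSrc + 0.0005 * pCaMKII
  ERK_total * v / (v + 0.1)
}
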