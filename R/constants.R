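# Shared physical conventions. Integer atomic masses (C 12, H 1, O 16,
# N 14, S 32) and a molar gas volume of exactly 22.4 L/mol at STP are
# used for all stoichiometric quantities; oxygen *mass* conversions use
# the exact O2 molar mass 31.9988 g/mol. Mixing the two conventions is
# deliberate: it bit-matches the standard printed forms of the Buswell
# per-gram methane potential and of the theoretical-oxygen-demand
# formula, respectively.
ATOMIC_MASS <- c(C = 12, H = 1, O = 16, N = 14, S = 32)
O2_MOLAR_MASS <- 31.9988 # g/mol
MOLAR_VOLUME_STP <- 22.4 # L/mol at 0 degC, 1 atm
GAS_CONSTANT <- 8.314 # J/(mol K)
ATM_PRESSURE_PA <- 101325
AIR_O2_FRACTION <- 0.2095

RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")
UNASSIGNED <- "Unassigned"

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
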