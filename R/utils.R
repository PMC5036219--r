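# Shared physical constants and small helpers.

# Gas constant, kcal mol-1 K-1
.R_KCAL <- 1.987e-3

# Default experiment temperature (K) used when none is supplied.
.T_DEFAULT <- 298.15

#' Thermal energy RT in kcal/mol
#'
#' @param temperature Temperature in Kelvin.
#' @return RT in kcal mol-1.
#' @keywords internal
rt_kcal <- function(temperature = .T_DEFAULT) .R_KCAL * temperature

# The twenty standard amino-acid one-letter codes, alphabetical.
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.stop2 <- function(...) stop(..., call. = FALSE)

# Corrected Akaike information criterion from an nls-like fit residual
# sum of squares. k counts all estimated parameters plus the residual
# variance.
.aicc <- function(rss, n, n_par) {
  k <- n_par + 1
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Deterministic child seed streams: keep well below .Machine$integer.max.
.child_seed <- function(seed, i) (as.integer(seed) %% 1000000L) * 1000L + as.integer(i) %% 1000L
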