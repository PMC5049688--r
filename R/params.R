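#' Simulation parameters
#'
#' Bundles and validates the population-scaled parameters of the simulator.
#' Time is measured in coalescent units of N_e generations throughout, and
#' all rates are scaled by the effective population size: each site of each
#' lineage initiates a within-species conversion tract at rate `rho_int/2`
#' (and a between-species import at rate `rho_ext/2`) per unit time, the
#' rho/2-per-lineage convention of standard coalescent simulators.
#'
#' @param n Sample size (number of genomes), `>= 2`.
#' @param genome A [genome_map], or an integer length (taken as a whole
#'   circular genome).
#' @param theta Scaled per-site mutation rate; mutations fall at `theta/2`
#'   per site per unit time.
#' @param rho_int Scaled per-site within-species recombination initiation
#'   rate (the `R` of the model).
#' @param delta_int Mean within-species tract length in sites; tract lengths
#'   are geometric: `P(l) = (1/delta)(1 - 1/delta)^(l-1)`, `l >= 1`.
#' @param rho_ext Scaled per-site between-species initiation rate (`R_e`).
#' @param delta_ext Mean between-species tract length (`delta_e`).
#' @param div_min,div_max Bounds of the external divergence; each import
#'   draws `d ~ Uniform(div_min, div_max)`, the per-site probability that
#'   an imported base differs from the root homolog. Must satisfy
#'   `0 <= div_min <= div_max <= 0.75`.
#' @param seed Optional integer RNG seed; when present, [simulate_arg()]
#'   seeds the RNG so runs are byte-for-byte reproducible.
#'
#' @return An object of class `bacsim_params`.
#' @examples
#' sim_params(n = 10, genome = genome_map(1e4), theta = 0.01,
#'            rho_int = 0.005, delta_int = 500)
#' @export
sim_params <- function(n, genome, theta = 0, rho_int = 0, delta_int = 500,
                       rho_ext = 0, delta_ext = 500,
                       div_min = 0, div_max = 0, seed = NULL) {
  if (is.numeric(genome)) genome <- genome_map(genome)
  stopifnot(inherits(genome, "genome_map"))
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2")
  if (theta < 0) stop("`theta` must be >= 0")
  if (rho_int < 0 || rho_ext < 0) stop("recombination rates must be >= 0")
  if (delta_int < 1 || delta_ext < 1) stop("mean tract lengths must be >= 1")
  if (div_min < 0 || div_max > 0.75 || div_min > div_max)
    stop("divergence bounds must satisfy 0 <= div_min <= div_max <= 0.75")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(n = n, genome = genome, theta = as.numeric(theta),
         rho_int = as.numeric(rho_int), delta_int = as.numeric(delta_int),
         rho_ext = as.numeric(rho_ext), delta_ext = as.numeric(delta_ext),
         div_min = as.numeric(div_min), div_max = as.numeric(div_max),
         seed = seed),
    class = "bacsim_params")
}

#' @export
print.bacsim_params <- function(x, ...) {
  cat(sprintf(
    "bacsim parameters: n = %d, G = %d (%s), theta = %g\n", x$n,
    x$genome$total_length, x$genome$topology, x$theta))
  cat(sprintf("  within-species:  R = %g, delta = %g\n", x$rho_int, x$delta_int))
  cat(sprintf("  between-species: R_e = %g, delta_e = %g, d ~ U(%g, %g)\n",
              x$rho_ext, x$delta_ext, x$div_min, x$div_max))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

param_header <- function(params) {
  sprintf(paste0("bacsim n=%d G=%d topology=%s fragments=%s theta=%g ",
                 "R=%g delta=%g R_e=%g delta_e=%g D1=%g D2=%g seed=%s"),
          params$n, params$genome$total_length, params$genome$topology,
          paste(sprintf("%d:%d", params$genome$fragments$length,
                        params$genome$fragments$gap), collapse = ","),
          params$theta, params$rho_int, params$delta_int, params$rho_ext,
          params$delta_ext, params$div_min, params$div_max,
          if (is.null(params$seed)) "NA" else as.character(params$seed))
}
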