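#' Derive recombination parameters from map length and genome size
#'
#' The per-bp recombination rate is the genetic map length (Morgans) divided
#' by the genome size (bp); the population recombination parameter per site
#' is `theta_site * recomb_rate / mu_site`, with the per-site mutation rate
#' defaulting to 2.9e-9 per generation.
#'
#' @param map_length_morgans total genetic map length in Morgans.
#' @param genome_size_bp genome size in bp.
#' @param theta_site per-site population mutation parameter (nucleotide
#'   diversity).
#' @param mu_site per-site per-generation mutation rate.
#' @return list with `recomb_rate` (per bp per generation) and `rho_site`.
#' @export
derive_parameters <- function(map_length_morgans, genome_size_bp,
                              theta_site = 7.6e-3, mu_site = 2.9e-9) {
  if (any(c(map_length_morgans, genome_size_bp, theta_site, mu_site) <= 0))
    stop("config error: all inputs must be positive")
  recomb_rate <- map_length_morgans / genome_size_bp
  list(recomb_rate = recomb_rate,
       rho_site = theta_site * recomb_rate / mu_site)
}

#' Neutral null model for a sliding window
#'
#' Parameters for the neutral infinite-sites coalescent with recombination
#' used to generate null distributions of the sweep statistics.  `theta_site`
#' and `rho_site` are interpreted per site and multiplied by the window
#' length `L` (set `per_site = FALSE` to pass locus-wide values).
#'
#' @param n haplotypes sampled.
#' @param theta_site per-site population mutation rate.
#' @param rho_site per-site population recombination rate.
#' @param L window length in bp.
#' @param reps number of simulation replicates.
#' @param per_site logical; interpret theta/rho per site (default) or as
#'   locus totals.
#' @return list of class `null_model`.
#' @export
null_model <- function(n = 22L, theta_site = 7.6e-3, rho_site = 2.5e-1,
                       L = 2000L, reps = 10000L, per_site = TRUE) {
  if (theta_site < 0 || rho_site < 0) stop("config error: negative rate")
  if (reps < 1) stop("config error: reps must be >= 1")
  structure(list(n = as.integer(n), theta_site = theta_site,
                 rho_site = rho_site, L = as.integer(L),
                 reps = as.integer(reps), per_site = isTRUE(per_site)),
            class = "null_model")
}

locus_rates <- function(model) {
  mult <- if (model$per_site) model$L else 1
  list(theta = model$theta_site * mult, rho = model$rho_site * mult)
}

#' Simulate derived SFS replicates under the neutral null
#'
#' Runs the exact ancestral-recombination-graph coalescent (see
#' `src/coalescent.cpp`) and returns one polarized SFS per replicate.
#' Mutations follow the infinite-sites model and are polarized by
#' construction (the ancestral state is known on the simulated genealogy).
#' Uses R's RNG; call `set.seed()` first for reproducibility.
#'
#' @param model a [null_model()].
#' @return list of [derived_sfs()] objects, length `model$reps`.
#' @export
simulate_window <- function(model) {
  stopifnot(inherits(model, "null_model"))
  r <- locus_rates(model)
  raw <- .sim_arg_cpp(model$n, r$theta, r$rho, model$reps, detail = FALSE)
  lapply(raw, function(x) sfs_from_counts(model$n, x$count))
}

#' Null distributions of the sweep statistics
#'
#' Simulates `model$reps` neutral windows and computes Tajima's D,
#' standardized Fay-Wu H and Zeng's E for each; replicates with no
#' segregating sites (undefined statistics) are recorded but excluded from
#' the sorted value vectors.
#'
#' @param model a [null_model()].
#' @return object of class `null_distribution`: list with sorted numeric
#'   vectors `D`, `H`, `E`, integer `S` per replicate, `n_defined`, and the
#'   model.
#' @export
null_distribution <- function(model) {
  sims <- simulate_window(model)
  stats <- vapply(sims, function(sfs) {
    c(S = sfs$S, D = tajimas_d(sfs), H = fay_wu_h_std(sfs), E = zengs_e(sfs))
  }, numeric(4))
  def <- !is.na(stats["D", ])
  structure(list(
    D = sort(stats["D", def]),
    H = sort(stats["H", def]),
    E = sort(stats["E", def]),
    S = as.integer(stats["S", ]),
    n_defined = sum(def),
    model = model
  ), class = "null_distribution")
}

#' Empirical probability P(Sim <= Obs)
#'
#' Proportion of defined simulated values less than or equal to the observed
#' value (ties count).  This is the one-tailed empirical probability used to
#' judge observed sweep-statistic peaks.
#'
#' @param values numeric vector of simulated statistic values (undefined
#'   replicates already excluded).
#' @param observed observed statistic value.
#' @param pseudocount logical; if `TRUE` use `(k + 1) / (reps + 1)` instead
#'   of the raw proportion (off by default).
#' @return empirical probability in `[0, 1]`.
#' @export
empirical_p <- function(values, observed, pseudocount = FALSE) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no defined simulated values")
  k <- sum(values <= observed)
  if (pseudocount) (k + 1) / (length(values) + 1) else k / length(values)
}

#' Significance calls for the three sweep statistics
#'
#' An observed peak is significant when `P(Sim <= Obs) >= 0.95` for Zeng's E
#' (upper tail) and when `P(Sim <= Obs) < 0.05` for standardized Fay-Wu H
#' and Tajima's D (lower tail).
#'
#' @param p_E,p_H,p_D empirical probabilities from [empirical_p()].
#' @return list of class `sweep_call` with the probabilities and
#'   `significant_E`, `significant_H`, `significant_D`.
#' @export
call_significance <- function(p_E, p_H, p_D) {
  stopifnot(all(c(p_E, p_H, p_D) >= 0 & c(p_E, p_H, p_D) <= 1))
  structure(list(p_E = p_E, p_H = p_H, p_D = p_D,
                 significant_E = p_E >= 0.95,
                 significant_H = p_H < 0.05,
                 significant_D = p_D < 0.05),
            class = "sweep_call")
}

#' @export
print.sweep_call <- function(x, ...) {
  cat(sprintf(
    "sweep_call: P(Sim<=Obs) E = %.4f%s  H = %.4f%s  D = %.4f%s\n",
    x$p_E, if (x$significant_E) "*" else "",
    x$p_H, if (x$significant_H) "*" else "",
    x$p_D, if (x$significant_D) "*" else ""))
  invisible(x)
}
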