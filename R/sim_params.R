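#' Wright-Fisher simulation parameters
#'
#' Bundles the configuration of one simulation run.  Defaults follow the
#' study conditions: per-site mutation rate `mu = 1e-8` per generation,
#' baseline per-site recombination rate `r0` of `1e-6` or `1e-8`,
#' divergence coefficient `c = 0.03` per pairwise difference (the
#' recombination rate between homologs diverged at `d` sites is
#' `r0 * max(0, 1 - c * d)`), population size `2N` of 100 or 10,000
#' chromosomes, and 100,000 nonoverlapping generations.
#'
#' @param gene_model A [gene_model()]; defaults to the standard synthetic
#'   1,678-bp two-exon model ([generate_gene_model()] with seed 1).
#' @param mu Mutation rate per site per generation.
#' @param r0 Baseline recombination rate per site per meiosis.
#' @param c Recombination-divergence coefficient per pairwise difference,
#'   in `[0, 1]`.
#' @param pop_chromosomes Total chromosome count `2N`; even, at least 4.
#' @param generations Number of generations to simulate.
#' @param seed Integer RNG seed.
#' @param record_every Sampling interval (generations) for the trajectory;
#'   0 disables recording.
#' @param engine `"cpp"` (fast compiled engine, default) or `"r"` (naive
#'   per-individual reference implementation).
#' @param autosomal Ignore sex when drawing parents (both gametes from
#'   uniformly drawn individuals).  Used for neutral-drift sanity checks;
#'   default `FALSE`.
#' @param multi_crossover Allow a Poisson number of crossovers per meiosis
#'   instead of at most one.  At the study's rates multiple crossovers are
#'   negligible (probability below `(1.7e-3)^2` per meiosis); default
#'   `FALSE`.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(gene_model = NULL, mu = 1e-8, r0 = 1e-6, c = 0.03,
                       pop_chromosomes = 100L, generations = 100000L,
                       seed = 1L, record_every = 0L, engine = c("cpp", "r"),
                       autosomal = FALSE, multi_crossover = FALSE) {
  if (is.null(gene_model)) gene_model <- default_gene_model()
  stopifnot(inherits(gene_model, "gene_model"))
  pop_chromosomes <- as.integer(pop_chromosomes)
  generations <- as.integer(generations)
  if (pop_chromosomes < 4L || pop_chromosomes %% 2L != 0L) {
    stop("pop_chromosomes must be even and >= 4")
  }
  if (mu < 0 || r0 < 0) stop("mu and r0 must be non-negative")
  if (c < 0 || c > 1) stop("c must be in [0, 1]")
  if (generations < 0L) stop("generations must be >= 0")
  structure(
    list(
      gene_model = gene_model, mu = mu, r0 = r0, c = c,
      pop_chromosomes = pop_chromosomes, generations = generations,
      seed = as.integer(seed), record_every = as.integer(record_every),
      engine = match.arg(engine), autosomal = isTRUE(autosomal),
      multi_crossover = isTRUE(multi_crossover)
    ),
    class = "sim_params"
  )
}

## The standard locus used by default everywhere; built once per session.
default_gene_model <- local({
  gm <- NULL
  function() {
    if (is.null(gm)) gm <<- generate_gene_model()
    gm
  }
})

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "sim_params: mu = %g, r0 = %g, c = %g, 2N = %d, %d generations (engine %s)\n",
    x$mu, x$r0, x$c, x$pop_chromosomes, x$generations, x$engine))
  invisible(x)
}

#' Effective recombination rate under divergence suppression
#'
#' Recombination between two homologs that differ at `d` sites occurs at
#' `r0 * max(0, 1 - c * d)` per site per meiosis: each pairwise difference
#' removes a fraction `c` (default 3%) of the baseline rate, and the rate
#' clamps to zero once `c * d >= 1`.
#'
#' @param r0 Baseline rate per site per meiosis.
#' @param c Suppression coefficient per pairwise difference.
#' @param d Non-negative integer count of differing sites (vectorised).
#' @return Effective rate(s), same length as `d`.
#' @examples
#' effective_recombination_rate(1e-6, 0.03, 0)   # baseline
#' effective_recombination_rate(1e-6, 0.03, 10)  # 7e-7
#' effective_recombination_rate(1e-6, 0.03, 34)  # clamped to 0
#' @export
effective_recombination_rate <- function(r0, c, d) {
  if (any(d < 0)) stop("d must be non-negative")
  r0 * pmax(0, 1 - c * d)
}
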