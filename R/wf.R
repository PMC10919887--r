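#' Run one simulation replicate
#'
#' Initializes the population (one founding splice-donor mutation defining
#' the Z class), iterates Wright-Fisher generations with mutation and
#' divergence-suppressed recombination, then censuses the final state
#' ([census()]) and computes diversity statistics ([diversity_stats()]).
#' Fully reproducible: the same `(params, seed)` give bit-identical
#' results for a given engine.
#'
#' @param params A [sim_params()]; its `seed` and `engine` fields control
#'   the RNG and the implementation used.
#' @return Object of class `wf_replicate`: list with `params`, `seed`,
#'   `termination_status` (`"completed"` or `"extinct_single_sex"`),
#'   `generation` reached, the final `population`, `census`
#'   (a [census()] result), `diversity` (a [diversity_stats()] result) and
#'   the optional `trajectory`.
#' @examples
#' p <- sim_params(pop_chromosomes = 20L, generations = 200L, mu = 1e-5, seed = 7L)
#' r <- wf_simulate(p)
#' r
#' @export
wf_simulate <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  gm <- params$gene_model
  pop <- with_seed(params$seed, {
    if (params$engine == "cpp") {
      res <- .wf_run_cpp(
        gm$reference, unname(gm$lof),
        params$mu, params$r0, params$c,
        params$pop_chromosomes, params$generations, params$record_every,
        gm$initial_sd_site, gm$initial_sd_alt_base,
        params$autosomal, params$multi_crossover
      )
      haps <- mapply(function(p, b) haplotype(p, b, gm = gm),
                     res$hap_pos, res$hap_base, SIMPLIFY = FALSE)
      p <- new_population(res$generation, haps, as.logical(res$female),
                          if (res$status == 0L) "completed" else "extinct_single_sex")
      p$trajectory <- res$trajectory
      p
    } else {
      run_engine_r(params)
    }
  })

  cns <- census(pop, gm)
  div <- diversity_stats(pop, gm)
  structure(
    list(params = params, seed = params$seed,
         termination_status = pop$status, generation = pop$generation,
         population = pop, census = cns, diversity = div,
         trajectory = pop$trajectory),
    class = "wf_replicate"
  )
}

#' Run a batch of replicates and aggregate the results
#'
#' Replicate `i` runs with seed `base_seed + i - 1`.  The batch is
#' summarised into the standard table row ([aggregate_table1()]): turnover
#' percentage TS and histograms of replicates by their number of fixed and
#' nonfixed sex-determining mutations.
#'
#' @param params A [sim_params()] (its own `seed` is ignored).
#' @param n_replicates Number of replicates (study default 100).
#' @param base_seed Seed of the first replicate.
#' @param keep_populations Retain each replicate's final population
#'   (memory-heavy for large batches); default `FALSE` keeps only the
#'   census and diversity summaries.
#' @return Object of class `wf_batch`: list with `params`, `replicates`
#'   (each a [wf_simulate()] result, possibly stripped of its population),
#'   and `table` (the [aggregate_table1()] row).
#' @export
wf_batch <- function(params, n_replicates = 100L, base_seed = 1L,
                     keep_populations = FALSE) {
  stopifnot(n_replicates >= 1L)
  reps <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    p_i <- params
    p_i$seed <- as.integer(base_seed + i - 1L)
    r <- wf_simulate(p_i)
    if (!keep_populations) r$population <- NULL
    reps[[i]] <- r
  }
  structure(
    list(params = params, base_seed = as.integer(base_seed),
         replicates = reps, table = aggregate_table1(reps)),
    class = "wf_batch"
  )
}

#' @export
print.wf_replicate <- function(x, ...) {
  cat(sprintf("wf_replicate (seed %d): %s at generation %d\n",
              x$seed, x$termination_status, x$generation))
  print(x$census)
  cat(sprintf("  pi_all = %.4g, pi_w = %.4g, pi_z = %.4g, dxy = %.4g, fst = %.4g\n",
              x$diversity$pi_all, x$diversity$pi_w, x$diversity$pi_z,
              x$diversity$dxy, x$diversity$fst))
  invisible(x)
}

#' @export
summary.wf_replicate <- function(object, ...) {
  c(list(seed = object$seed, status = object$termination_status,
         generation = object$generation),
    census_row(object$census), unclass(object$diversity))
}

#' @export
print.wf_batch <- function(x, ...) {
  cat(sprintf("wf_batch: %d replicates (base seed %d)\n",
              length(x$replicates), x$base_seed))
  print(x$table)
  invisible(x)
}

#' @export
summary.wf_batch <- function(object, ...) {
  as.data.frame(do.call(rbind, lapply(object$replicates, function(r) {
    unlist(summary(r)[-2])  # drop character status for the numeric frame
  })))
}

#' Plot the distribution of fixed/nonfixed SD mutation counts in a batch
#'
#' Bar plot of the number of replicates by their count of fixed and of
#' nonfixed sex-determining mutations in the final state.
#'
#' @param x A [wf_batch()] result.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.wf_batch <- function(x, ...) {
  tab <- rbind(fixed = x$table$fixed_hist, nonfixed = x$table$nonfixed_hist[1:5])
  colnames(tab) <- c(0:3, "4+")
  graphics::barplot(tab, beside = TRUE, legend.text = TRUE,
                    xlab = "sex-determining mutations per replicate",
                    ylab = "replicates", ...)
  invisible(x)
}
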