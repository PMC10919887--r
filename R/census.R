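#' Census of sex-determining mutations in a final population
#'
#' Classifies every chromosome as W-class (functional) or Z-class
#' (loss-of-function), collects the LOF-classified differences carried by
#' Z-class haplotypes, and partitions their positions into *fixed* (carried
#' by every Z-class haplotype) and *nonfixed* (carried by at least one but
#' not all).  Two different alternative bases at the same position count as
#' one sex-determining position.  Fixation is defined among the Z class: by
#' construction no W-class haplotype carries a LOF change.
#'
#' @param population A population state (from [wf_simulate()]'s
#'   `$population`, [initialize_population()], or [step_generation()]).
#' @param gm The [gene_model()] the population evolved on.
#' @return Object of class `census_result`: list with `w_class_count`,
#'   `z_class_count`, `fixed_lof` (integer positions), `nonfixed_lof`
#'   (integer positions), `nonfixed_freq` (frequency of each nonfixed
#'   position among Z-class haplotypes) and `turnover` (logical, see
#'   [detect_turnover()]).
#' @export
census <- function(population, gm) {
  haps <- population$haplotypes
  functional <- vapply(haps, function(h) {
    if (!is.null(h$functional)) h$functional else is_functional(h, gm)
  }, logical(1))
  z_haps <- haps[!functional]
  n_z <- length(z_haps)

  lof_positions <- lapply(z_haps, function(h) {
    if (length(h$pos) == 0L) return(integer(0))
    h$pos[gm$lof[cbind(h$base, h$pos + 1L)]]
  })
  all_pos <- sort(unique(unlist(lof_positions, use.names = FALSE)))
  if (length(all_pos)) {
    counts <- table(factor(unlist(lof_positions, use.names = FALSE), levels = all_pos))
    counts <- as.integer(counts)
  } else {
    counts <- integer(0)
  }
  fixed <- all_pos[counts == n_z]
  nonfixed <- all_pos[counts < n_z]
  nonfixed_freq <- if (length(nonfixed)) {
    setNames(counts[counts < n_z] / n_z, nonfixed)
  } else {
    numeric(0)
  }

  out <- structure(
    list(
      w_class_count = sum(functional),
      z_class_count = n_z,
      fixed_lof = fixed,
      nonfixed_lof = nonfixed,
      nonfixed_freq = nonfixed_freq,
      initial_site = gm$initial_sd_site,
      turnover = NA
    ),
    class = "census_result"
  )
  out$turnover <- detect_turnover(out, gm$initial_sd_site)
  out
}

#' Did a turnover of the sex-determining mutation occur?
#'
#' A turnover is scored when the final state carries the sex-determining
#' function at a single *different* position: exactly one fixed LOF
#' position, not equal to the founding site, and no nonfixed LOF mutation
#' segregating.
#'
#' @param census A [census()] result (or any list with `fixed_lof` and
#'   `nonfixed_lof`).
#' @param initial_site 0-based position of the founding mutation.
#' @return Logical.
#' @export
detect_turnover <- function(census, initial_site) {
  length(census$fixed_lof) == 1L &&
    census$fixed_lof != initial_site &&
    length(census$nonfixed_lof) == 0L
}

#' @export
print.census_result <- function(x, ...) {
  cat(sprintf("census: %d W / %d Z chromosomes; fixed LOF at {%s}; %d nonfixed; turnover: %s\n",
              x$w_class_count, x$z_class_count,
              paste(x$fixed_lof, collapse = ","),
              length(x$nonfixed_lof), x$turnover))
  invisible(x)
}

census_row <- function(cns) {
  list(turnover = cns$turnover,
       n_fixed = length(cns$fixed_lof),
       n_nonfixed = length(cns$nonfixed_lof))
}

#' Aggregate a batch of replicates into a summary table row
#'
#' Produces the standard summary of a replicate batch: TS, the percentage
#' of replicates in which a turnover of the sex-determining position
#' occurred; the histogram of replicates by their number of fixed
#' sex-determining mutations (bins 0,1,2,3,4+); the histogram by their
#' number of nonfixed sex-determining mutations (bins 0..4,5+); and the
#' counts of replicates with at least two of each.
#'
#' @param batch A [wf_batch()] result or a list of [wf_simulate()] results.
#' @return Object of class `table1_row`.
#' @export
aggregate_table1 <- function(batch) {
  reps <- if (inherits(batch, "wf_batch")) batch$replicates else batch
  if (length(reps) == 0L) stop("empty batch")
  rows <- lapply(reps, function(r) {
    census_row(if (inherits(r, "wf_replicate")) r$census else r)
  })
  n <- length(rows)
  turn <- vapply(rows, `[[`, logical(1), "turnover")
  nf <- vapply(rows, `[[`, integer(1), "n_fixed")
  nn <- vapply(rows, `[[`, integer(1), "n_nonfixed")
  fixed_hist <- vapply(0:4, function(k) {
    if (k < 4) sum(nf == k) else sum(nf >= 4)
  }, integer(1))
  nonfixed_hist <- vapply(0:5, function(k) {
    if (k < 5) sum(nn == k) else sum(nn >= 5)
  }, integer(1))
  structure(
    list(
      n_replicates = n,
      ts_percent = 100 * sum(turn) / n,
      n_turnover = sum(turn),
      fixed_hist = setNames(fixed_hist, c(0:3, "4plus")),
      nonfixed_hist = setNames(nonfixed_hist, c(0:4, "5plus")),
      n_fixed_ge2 = sum(nf >= 2L),
      n_nonfixed_ge2 = sum(nn >= 2L)
    ),
    class = "table1_row"
  )
}

#' @export
print.table1_row <- function(x, ...) {
  cat(sprintf("  TS = %.1f%% (%d/%d turnovers)\n", x$ts_percent, x$n_turnover, x$n_replicates))
  cat("  replicates by # fixed SD mutations:    ",
      paste(sprintf("%s:%d", names(x$fixed_hist), x$fixed_hist), collapse = "  "), "\n")
  cat("  replicates by # nonfixed SD mutations: ",
      paste(sprintf("%s:%d", names(x$nonfixed_hist), x$nonfixed_hist), collapse = "  "), "\n")
  invisible(x)
}
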