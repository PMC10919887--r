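## Naive per-individual reference engine, written for auditability rather
## than speed.  The compiled engine must match it in distribution; the
## equivalence is asserted by the test suite on summary statistics.
##
## Internal population representation shared by both engines:
##   list(generation, haplotypes = list of 2N haplotype objects
##        (individual i owns elements 2i-1 and 2i), female = logical N,
##        status = "completed" | "extinct_single_sex")

#' Initial population state
#'
#' `ceiling(N/2)` females each carry one reference (W) haplotype and one Z
#' haplotype bearing exactly the founding splice-donor mutation; the
#' remaining individuals are males with two such Z haplotypes.  The initial
#' state therefore segregates a single sex-determining mutation and nothing
#' else.
#'
#' @param params A [sim_params()].
#' @return A population state (class `wf_population`).
#' @examples
#' p <- sim_params(pop_chromosomes = 4L, generations = 0L)
#' initialize_population(p)
#' @export
initialize_population <- function(params) {
  gm <- params$gene_model
  n_ind <- params$pop_chromosomes %/% 2L
  n_f <- (n_ind + 1L) %/% 2L
  w <- haplotype(gm = gm)
  z <- haplotype(gm$initial_sd_site, gm$initial_sd_alt_base, gm = gm)
  haps <- vector("list", 2L * n_ind)
  for (i in seq_len(n_ind)) {
    if (i <= n_f) {
      haps[[2L * i - 1L]] <- w
      haps[[2L * i]] <- z
    } else {
      haps[[2L * i - 1L]] <- z
      haps[[2L * i]] <- z
    }
  }
  new_population(0L, haps, c(rep(TRUE, n_f), rep(FALSE, n_ind - n_f)), "completed")
}

new_population <- function(generation, haplotypes, female, status) {
  structure(
    list(generation = as.integer(generation), haplotypes = haplotypes,
         female = female, status = status),
    class = "wf_population"
  )
}

#' @export
print.wf_population <- function(x, ...) {
  n_ind <- length(x$female)
  n_w <- sum(vapply(x$haplotypes, function(h) isTRUE(h$functional), logical(1)))
  cat(sprintf("wf_population: generation %d, %d individuals (%d F / %d M), %d W-class of %d chromosomes [%s]\n",
              x$generation, n_ind, sum(x$female), n_ind - sum(x$female),
              n_w, 2L * n_ind, x$status))
  invisible(x)
}

#' Produce one gamete from a parent (naive reference implementation)
#'
#' With probability `min(1, L * r0 * max(0, 1 - c*d))`, where `d` is the
#' divergence between the parent's homologs, a single crossover at a
#' uniformly chosen internal breakpoint joins the left part of one homolog
#' to the right part of the other; otherwise one homolog is copied (each
#' with probability 1/2).  A Poisson(`mu * L`) number of point mutations is
#' then applied at uniform positions, each to a uniformly chosen base among
#' the three alternatives to the current base; mutation back to the
#' reference base deletes the difference.  Uses the global RNG.
#'
#' @param h1,h2 The parent's two [haplotype()]s.
#' @param params A [sim_params()].
#' @return A [haplotype()] with its functional flag set.
#' @export
meiosis <- function(h1, h2, params) {
  gm <- params$gene_model
  L <- gm$total_length
  d <- pairwise_differences(h1, h2)
  pr <- min(1, L * effective_recombination_rate(params$r0, params$c, d))

  n_cross <- if (d > 0 && pr > 0) {
    if (params$multi_crossover) rpois(1L, pr) else as.integer(runif(1) < pr)
  } else 0L

  if (n_cross > 0L) {
    pair <- if (runif(1) < 0.5) list(h1, h2) else list(h2, h1)
    bps <- sort(sample.int(L - 1L, n_cross, replace = TRUE))
    ## walk segments, alternating the source homolog at each breakpoint
    bounds <- c(0L, bps, L)
    pos <- integer(0); base <- integer(0)
    src <- 1L
    for (s in seq_len(length(bounds) - 1L)) {
      h <- pair[[src]]
      keep <- h$pos >= bounds[s] & h$pos < bounds[s + 1L]
      pos <- c(pos, h$pos[keep]); base <- c(base, h$base[keep])
      src <- 3L - src
    }
    g <- list(pos = pos, base = base)
  } else {
    h <- if (runif(1) < 0.5) h1 else h2
    g <- list(pos = h$pos, base = h$base)
  }

  n_mut <- rpois(1L, params$mu * L)
  if (n_mut > 0L) {
    for (m in seq_len(n_mut)) {
      p <- sample.int(L, 1L) - 1L
      i <- match(p, g$pos)
      cur <- if (is.na(i)) gm$reference[p + 1L] else g$base[i]
      nb <- sample(setdiff(1:4, cur), 1L)
      if (nb == gm$reference[p + 1L]) {
        if (!is.na(i)) { g$pos <- g$pos[-i]; g$base <- g$base[-i] }
      } else if (!is.na(i)) {
        g$base[i] <- nb
      } else {
        g$pos <- c(g$pos, p); g$base <- c(g$base, nb)
      }
    }
  }
  haplotype(g$pos, g$base, gm = gm)
}

#' Advance the population one Wright-Fisher generation (reference engine)
#'
#' Each of the `N` offspring draws a mother uniformly from the females and
#' a father uniformly from the males (with replacement), receives one
#' gamete from each via [meiosis()], and its sex follows from haplotype
#' functionality.  If either sex is absent the replicate is marked
#' `extinct_single_sex` and the state is returned unchanged.
#'
#' @param state A population state from [initialize_population()] or a
#'   previous call.
#' @param params A [sim_params()].
#' @return The next population state.
#' @export
step_generation <- function(state, params) {
  n_ind <- length(state$female)
  mothers_pool <- which(if (params$autosomal) rep(TRUE, n_ind) else state$female)
  fathers_pool <- which(if (params$autosomal) rep(TRUE, n_ind) else !state$female)
  if (length(mothers_pool) == 0L || length(fathers_pool) == 0L) {
    state$status <- "extinct_single_sex"
    return(state)
  }
  haps <- vector("list", 2L * n_ind)
  female <- logical(n_ind)
  for (k in seq_len(n_ind)) {
    mi <- mothers_pool[sample.int(length(mothers_pool), 1L)]
    fi <- fathers_pool[sample.int(length(fathers_pool), 1L)]
    gm_h <- meiosis(state$haplotypes[[2L * mi - 1L]], state$haplotypes[[2L * mi]], params)
    gf_h <- meiosis(state$haplotypes[[2L * fi - 1L]], state$haplotypes[[2L * fi]], params)
    haps[[2L * k - 1L]] <- gm_h
    haps[[2L * k]] <- gf_h
    female[k] <- gm_h$functional || gf_h$functional
  }
  new_population(state$generation + 1L, haps, female, "completed")
}

## Run the naive engine for params$generations (or until extinction).
run_engine_r <- function(params) {
  state <- initialize_population(params)
  traj <- NULL
  if (params$record_every > 0L) {
    traj <- list(generation = integer(0), w_count = integer(0), lof_site_count = integer(0))
  }
  gen <- 0L
  while (gen < params$generations) {
    if (!is.null(traj) && gen %% params$record_every == 0L) {
      traj <- record_traj(traj, state, params$gene_model)
    }
    nxt <- step_generation(state, params)
    if (nxt$status == "extinct_single_sex") {
      state$status <- "extinct_single_sex"
      break
    }
    state <- nxt
    gen <- gen + 1L
  }
  state$trajectory <- traj
  state
}

record_traj <- function(traj, state, gm) {
  n_w <- 0L
  lofpos <- integer(0)
  for (h in state$haplotypes) {
    if (h$functional) n_w <- n_w + 1L
    if (length(h$pos)) {
      is_lof <- gm$lof[cbind(h$base, h$pos + 1L)]
      lofpos <- c(lofpos, h$pos[is_lof])
    }
  }
  traj$generation <- c(traj$generation, state$generation)
  traj$w_count <- c(traj$w_count, n_w)
  traj$lof_site_count <- c(traj$lof_site_count, length(unique(lofpos)))
  traj
}

#' Neutral-marker drift utilities
#'
#' Sanity-check mode for the reproduction machinery: a population of fully
#' functional (reference) haplotypes in which `round(freq * 2N)` uniformly
#' chosen chromosomes carry one neutral marker allele.  Because every
#' haplotype is functional, such a population is all-female under ZW
#' bookkeeping; it is meant to be evolved with `autosomal = TRUE`
#' (sex-blind parent draws), under which the marker's fixation probability
#' is its initial frequency.
#'
#' @param params A [sim_params()] (use `autosomal = TRUE`, `mu = 0`).
#' @param position 0-based marker position; must be neutral (non-LOF) for
#'   every alternative base.
#' @param base Marker allele (character or code), different from the
#'   reference base.
#' @param freq Initial marker frequency in (0, 1).
#' @return A population state carrying the marker.
#' @export
initialize_marker_population <- function(params, position, base, freq) {
  gm <- params$gene_model
  n_chrom <- params$pop_chromosomes
  n_carrier <- round(freq * n_chrom)
  stopifnot(n_carrier >= 1L, n_carrier < n_chrom)
  marker <- haplotype(position, base, gm = gm)
  if (!marker$functional) stop("marker must be neutral")
  carriers <- sample.int(n_chrom, n_carrier)
  haps <- vector("list", n_chrom)
  for (i in seq_len(n_chrom)) {
    haps[[i]] <- if (i %in% carriers) marker else haplotype(gm = gm)
  }
  new_population(0L, haps, rep(TRUE, n_chrom %/% 2L), "completed")
}

#' @rdname initialize_marker_population
#' @param state A population from [initialize_marker_population()].
#' @return `run_marker_drift`: `"fixed"`, `"lost"`, or `"segregating"`
#'   (still polymorphic after `params$generations`).
#' @export
run_marker_drift <- function(state, params, position) {
  for (g in seq_len(params$generations)) {
    carriers <- sum(vapply(state$haplotypes, function(h) position %in% h$pos, logical(1)))
    if (carriers == 0L) return("lost")
    if (carriers == length(state$haplotypes)) return("fixed")
    state <- step_generation(state, params)
  }
  "segregating"
}
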