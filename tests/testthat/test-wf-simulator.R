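test_that("the initial population has the prescribed ZW composition", {
  gm <- tiny_gene_model()
  # smallest valid case: 1 female W/Z + 1 male Z/Z
  p4 <- sim_params(gene_model = gm, pop_chromosomes = 4L, generations = 0L)
  pop <- initialize_population(p4)
  expect_identical(pop$female, c(TRUE, FALSE))
  expect_true(pop$haplotypes[[1]]$functional)
  expect_false(pop$haplotypes[[2]]$functional)

  # 2N = 100: 25 W-class and 75 Z-class chromosomes
  p100 <- sim_params(gene_model = gm, pop_chromosomes = 100L, generations = 0L)
  pop <- initialize_population(p100)
  functional <- vapply(pop$haplotypes, `[[`, logical(1), "functional")
  expect_identical(sum(functional), 25L)
  expect_identical(sum(!functional), 75L)
  expect_identical(sum(pop$female), 25L)

  # every Z haplotype carries exactly the founding splice-site diff
  for (h in pop$haplotypes[!functional]) {
    expect_identical(h$pos, gm$initial_sd_site)
    eff <- classify_site_change(gm, h$pos, h$base)
    expect_equal(as.character(eff$category), "splice_site")
  }
})

test_that("parameter validation rejects invalid configurations", {
  gm <- tiny_gene_model()
  expect_error(sim_params(gene_model = gm, pop_chromosomes = 3L), "even")
  expect_error(sim_params(gene_model = gm, pop_chromosomes = 2L), "even")
  expect_error(sim_params(gene_model = gm, mu = -1), "non-negative")
  expect_error(sim_params(gene_model = gm, c = 1.5), "c must")
  expect_error(sim_params(gene_model = gm, generations = -1L), "generations")
})

test_that("effective recombination rate is suppressed linearly and clamps at zero", {
  expect_equal(effective_recombination_rate(1e-6, 0.03, 0), 1e-6)
  expect_equal(effective_recombination_rate(1e-6, 0.03, 10), 7e-7)
  expect_equal(effective_recombination_rate(1e-6, 0.03, 34), 0)
  expect_equal(effective_recombination_rate(5e-7, 0.03, c(0, 1, 100)),
               c(5e-7, 5e-7 * 0.97, 0))
  expect_error(effective_recombination_rate(1e-6, 0.03, -1), "non-negative")
})

test_that("meiosis degenerates to faithful copying without mutation or recombination", {
  gm <- tiny_gene_model()
  p0 <- sim_params(gene_model = gm, mu = 0, r0 = 0, pop_chromosomes = 4L)
  h1 <- haplotype(c(3L, 20L), c("C", "A"), gm = gm)
  h2 <- haplotype(12L, "A", gm = gm)
  set.seed(1)
  picks <- replicate(200, {
    g <- meiosis(h1, h2, p0)
    identical(g$pos, h1$pos) && identical(g$base, h1$base)
  })
  # each parental haplotype chosen with probability ~1/2
  expect_gt(mean(picks), 0.35)
  expect_lt(mean(picks), 0.65)

  # homozygous parent: gamete equals the haplotype even with forced crossover
  p_rec <- sim_params(gene_model = gm, mu = 0, r0 = 1, c = 0, pop_chromosomes = 4L)
  g <- meiosis(h2, h2, p_rec)
  expect_identical(g$pos, h2$pos)
  expect_identical(g$base, h2$base)
})

test_that("a forced crossover joins left of one homolog to right of the other", {
  gm <- tiny_gene_model()
  # r0 = 1, c = 0 makes the per-meiosis crossover probability 1
  p_rec <- sim_params(gene_model = gm, mu = 0, r0 = 1, c = 0, pop_chromosomes = 4L)
  h_left <- haplotype(c(1L, 3L), c("C", "C"), gm = gm)   # diffs near the start
  h_right <- haplotype(c(55L, 58L), c("A", "C"), gm = gm) # diffs near the end
  is_single_crossover_product <- function(g, ha, hb, L) {
    any(vapply(1:(L - 1L), function(bp) {
      forward <- sort(c(ha$pos[ha$pos < bp], hb$pos[hb$pos >= bp]))
      backward <- sort(c(hb$pos[hb$pos < bp], ha$pos[ha$pos >= bp]))
      identical(sort(g$pos), forward) || identical(sort(g$pos), backward)
    }, logical(1)))
  }
  set.seed(2)
  for (i in 1:50) {
    g <- meiosis(h_left, h_right, p_rec)
    expect_true(is_single_crossover_product(g, h_left, h_right, 60L),
                info = paste(g$pos, collapse = ","))
  }
  # both mosaic products must occur
  mosaics <- replicate(200, length(meiosis(h_left, h_right, p_rec)$pos))
  expect_true(any(mosaics == 4L))
  expect_true(any(mosaics == 0L))
})

test_that("mutation counts per gamete are Poisson with mean mu * L", {
  gm <- tiny_gene_model()  # L = 60
  p <- sim_params(gene_model = gm, mu = 2e-4, r0 = 0, pop_chromosomes = 4L)
  h <- haplotype(gm = gm)
  set.seed(3)
  n <- 20000L
  counts <- vapply(seq_len(n), function(i) length(meiosis(h, h, p)$pos), integer(1))
  m <- p$mu * gm$total_length          # 0.012
  se <- sqrt(m / n)
  expect_lt(abs(mean(counts) - m), 3 * se)
})

test_that("one generation conserves population size and keeps sex consistent", {
  gm <- tiny_gene_model()
  p <- sim_params(gene_model = gm, mu = 1e-3, r0 = 1e-4, pop_chromosomes = 40L)
  set.seed(4)
  state <- initialize_population(p)
  for (g in 1:5) {
    state <- step_generation(state, p)
    expect_length(state$haplotypes, 40L)
    expect_length(state$female, 20L)
    for (i in seq_len(20L)) {
      h1 <- state$haplotypes[[2L * i - 1L]]
      h2 <- state$haplotypes[[2L * i]]
      expect_identical(state$female[i], h1$functional || h2$functional)
    }
  }

  # 1 female + 1 male, no mutation: offspring genotypes are W/Z or Z/Z only
  p2 <- sim_params(gene_model = gm, mu = 0, r0 = 0, pop_chromosomes = 4L)
  st <- initialize_population(p2)
  st <- step_generation(st, p2)
  for (i in 1:2) {
    n_w <- sum(st$haplotypes[[2L * i - 1L]]$functional, st$haplotypes[[2L * i]]$functional)
    expect_lte(n_w, 1L)  # never W/W: fathers only transmit Z
  }
})

test_that("with mu = 0 the offspring sex ratio is Binomial(N, 1/2)", {
  gm <- tiny_gene_model()
  p <- sim_params(gene_model = gm, mu = 0, r0 = 1e-6, pop_chromosomes = 100L)
  set.seed(5)
  state <- initialize_population(p)
  n_rep <- 200L
  females <- vapply(seq_len(n_rep), function(i) {
    sum(step_generation(state, p)$female)
  }, numeric(1))
  total <- 50 * n_rep
  p_hat <- sum(females) / total
  se <- sqrt(0.25 / total)
  expect_lt(abs(p_hat - 0.5), 3 * se)
})

test_that("replicates are bit-identical given (params, seed) for both engines", {
  gm <- tiny_gene_model()
  for (eng in c("cpp", "r")) {
    p <- sim_params(gene_model = gm, mu = 1e-4, r0 = 1e-4,
                    pop_chromosomes = 20L, generations = 200L,
                    seed = 99L, engine = eng)
    r1 <- wf_simulate(p)
    r2 <- wf_simulate(p)
    expect_identical(r1$population$haplotypes, r2$population$haplotypes)
    expect_identical(r1$census, r2$census)
    expect_identical(r1$diversity, r2$diversity)
  }
})

test_that("degenerate runs behave as forced by the model", {
  gm <- tiny_gene_model()
  # generations = 0: final state equals the initial state
  p0 <- sim_params(gene_model = gm, generations = 0L, pop_chromosomes = 20L, seed = 1L)
  r0 <- wf_simulate(p0)
  init <- initialize_population(p0)
  expect_identical(r0$generation, 0L)
  expect_identical(r0$population$haplotypes, init$haplotypes)

  # mu = 0: the founding mutation stays the single fixed SD mutation
  p_m0 <- sim_params(gene_model = gm, mu = 0, r0 = 1e-6,
                     pop_chromosomes = 50L, generations = 500L, seed = 17L)
  r <- wf_simulate(p_m0)
  expect_identical(r$termination_status, "completed")
  expect_identical(r$census$fixed_lof, gm$initial_sd_site)
  expect_length(r$census$nonfixed_lof, 0L)
  expect_false(r$census$turnover)
})

test_that("a single-sex generation terminates the replicate with a recorded status", {
  gm <- tiny_gene_model()
  # 2N = 4 and many generations: all-male offspring happens quickly
  # (probability 1/4 per generation)
  p <- sim_params(gene_model = gm, mu = 0, r0 = 0, pop_chromosomes = 4L,
                  generations = 500L, seed = 11L)
  r <- wf_simulate(p)
  expect_true(r$termination_status %in% c("completed", "extinct_single_sex"))
  expect_identical(r$termination_status, "extinct_single_sex")
  expect_lt(r$generation, 500L)
})

test_that("trajectory recording samples W counts and LOF site counts", {
  gm <- tiny_gene_model()
  for (eng in c("cpp", "r")) {
    p <- sim_params(gene_model = gm, mu = 1e-4, r0 = 1e-5,
                    pop_chromosomes = 20L, generations = 100L,
                    record_every = 10L, seed = 31L, engine = eng)
    r <- wf_simulate(p)
    tr <- r$trajectory
    expect_identical(as.integer(tr$generation), seq(0L, 90L, by = 10L))
    expect_identical(tr$w_count[1L], 5L)            # ceil(10/2) = 5 initial W
    expect_true(all(tr$w_count >= 0L & tr$w_count <= 20L))
    expect_identical(tr$lof_site_count[1L], 1L)     # founding site only
  }
})

test_that("mu = 0 batches never produce a turnover", {
  gm <- tiny_gene_model()
  p <- sim_params(gene_model = gm, mu = 0, r0 = 1e-6,
                  pop_chromosomes = 40L, generations = 300L)
  b <- wf_batch(p, n_replicates = 20L, base_seed = 7L)
  expect_identical(b$table$n_turnover, 0L)
  # and n_replicates = 1 reproduces run-with-same-seed exactly
  b1 <- wf_batch(p, n_replicates = 1L, base_seed = 123L)
  p1 <- p; p1$seed <- 123L
  r1 <- wf_simulate(p1)
  expect_identical(b1$replicates[[1L]]$census, r1$census)
})

test_that("neutral marker populations reject non-neutral markers and track drift endpoints", {
  gm <- tiny_gene_model()
  p <- sim_params(gene_model = gm, mu = 0, r0 = 0, pop_chromosomes = 20L,
                  generations = 2000L, autosomal = TRUE)
  expect_error(initialize_marker_population(p, 12L, "A", freq = 0.25), "neutral")
  set.seed(6)
  st <- initialize_marker_population(p, 30L, "A", freq = 0.25)
  carriers <- sum(vapply(st$haplotypes, function(h) 30L %in% h$pos, logical(1)))
  expect_identical(carriers, 5L)
  expect_true(run_marker_drift(st, p, 30L) %in% c("fixed", "lost"))
  # the full fixation-probability check (2,000 replicates) lives in the
  # end-to-end acceptance suite
})

test_that("optimized and naive engines agree in distribution", {
  gm <- tiny_gene_model()
  n_rep <- 200L
  run_set <- function(engine) {
    p <- sim_params(gene_model = gm, mu = 5e-5, r0 = 5e-5,
                    pop_chromosomes = 20L, generations = 500L, engine = engine)
    t(vapply(seq_len(n_rep), function(i) {
      p$seed <- 5000L + i
      r <- wf_simulate(p)
      c(sex_ratio = mean(r$population$female),
        pi_all = r$diversity$pi_all,
        n_seg = r$diversity$n_segregating)
    }, numeric(3)))
  }
  a <- run_set("cpp")
  b <- run_set("r")
  for (col in colnames(a)) {
    pv <- suppressWarnings(stats::ks.test(a[, col], b[, col]))$p.value
    expect_gt(pv, 0.01)
  }
})
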