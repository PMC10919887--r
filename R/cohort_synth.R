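#' Generate a sex-genotype cohort under female heterogamety
#'
#' Emulates a resequenced cohort segregating a perfectly sex-linked causal
#' variant on an otherwise undifferentiated chromosome: every female is
#' heterozygous and every male homozygous for the derived allele (the ZW
#' pattern), while background variants are drawn independently of sex in
#' Hardy-Weinberg proportions, so association tests on them are exactly
#' null.  Two presets mirror the validation cohorts: a 45-female /
#' 37-male SNP cohort and a 14-female / 7-male 4-bp-deletion cohort.
#'
#' @param n_females,n_males Cohort sizes.
#' @param n_background_snps Number of sex-independent background variants.
#' @param freq_range Background alternative-allele frequencies are drawn
#'   uniformly from this range (default `c(0.05, 0.5)`).
#' @param missingness Per-genotype missing probability (default 0).
#' @param causal_variant_kind `"snp"` (A>G) or `"deletion"` (GACC>-).
#' @param chrom_length Positions are drawn uniformly on
#'   `[0, chrom_length)`; the causal variant gets a dedicated position.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param preset `"golden-pompano"` (45 F / 37 M, SNP) or
#'   `"florida-pompano"` (14 F / 7 M, deletion); overrides the size and
#'   kind arguments.
#' @return Object of class `sex_cohort`: list with `genotypes` (integer
#'   dosage matrix, variants x individuals, NA = missing), `positions`
#'   (0-based), `ref`/`alt` alleles, `sex` (character "F"/"M"), and
#'   `truth` (list naming the causal variant's index, position and kind).
#' @export
generate_sex_genotype_cohort <- function(n_females = 45L, n_males = 37L,
                                         n_background_snps = 100L,
                                         freq_range = c(0.05, 0.5),
                                         missingness = 0,
                                         causal_variant_kind = c("snp", "deletion"),
                                         chrom_length = 1000000L,
                                         seed = 1L,
                                         preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("golden-pompano", "florida-pompano"))
    if (preset == "golden-pompano") {
      n_females <- 45L; n_males <- 37L; causal_variant_kind <- "snp"
    } else {
      n_females <- 14L; n_males <- 7L; causal_variant_kind <- "deletion"
    }
  }
  causal_variant_kind <- match.arg(causal_variant_kind)
  n <- n_females + n_males
  stopifnot(n_females >= 1L, n_males >= 1L, n_background_snps >= 0L)

  with_seed(seed, {
    n_var <- n_background_snps + 1L
    positions <- sort(sample.int(chrom_length, n_var)) - 1L
    causal_idx <- sample.int(n_var, 1L)

    sex <- c(rep("F", n_females), rep("M", n_males))
    geno <- matrix(NA_integer_, nrow = n_var, ncol = n)

    ## background: Hardy-Weinberg, independent of sex
    freqs <- runif(n_var, freq_range[1L], freq_range[2L])
    for (v in seq_len(n_var)) {
      geno[v, ] <- rbinom(n, 2L, freqs[v])
    }
    ## causal: females het, males homozygous derived
    geno[causal_idx, ] <- ifelse(sex == "F", 1L, 2L)

    ref <- rep(NA_character_, n_var)
    alt <- rep(NA_character_, n_var)
    for (v in seq_len(n_var)) {
      b <- sample(DNA_BASES, 2L)
      ref[v] <- b[1L]; alt[v] <- b[2L]
    }
    if (causal_variant_kind == "snp") {
      ref[causal_idx] <- "A"; alt[causal_idx] <- "G"
    } else {
      ref[causal_idx] <- "GACC"; alt[causal_idx] <- "G"  # 4-bp deletion, left-anchored
    }

    if (missingness > 0) {
      miss <- matrix(runif(n_var * n) < missingness, nrow = n_var)
      miss[causal_idx, ] <- FALSE  # the causal variant stays fully typed
      geno[miss] <- NA_integer_
    }

    structure(
      list(
        genotypes = geno,
        positions = positions,
        ref = ref, alt = alt,
        sex = sex,
        sample_ids = sprintf("%s%03d", sex, seq_len(n)),
        truth = list(causal_index = causal_idx,
                     causal_position = positions[causal_idx],
                     kind = causal_variant_kind)
      ),
      class = "sex_cohort"
    )
  })
}

#' @export
print.sex_cohort <- function(x, ...) {
  cat(sprintf("sex_cohort: %d females + %d males, %d variants (causal %s at 0-based pos %d)\n",
              sum(x$sex == "F"), sum(x$sex == "M"), nrow(x$genotypes),
              x$truth$kind, x$truth$causal_position))
  invisible(x)
}

#' Per-sex genotype count table for one variant
#'
#' @param genotypes Dosages (0/1/2, NA = missing) for one variant.
#' @param sex Character vector "F"/"M" aligned with `genotypes`.
#' @return 2 x 3 count matrix (rows female/male, columns hom_ref, het,
#'   hom_alt), suitable for [genotypic_sex_association()].
#' @export
genotype_count_table <- function(genotypes, sex) {
  sex <- toupper(substr(as.character(sex), 1L, 1L))
  keep <- !is.na(genotypes)
  tab <- table(factor(sex[keep], levels = c("F", "M")),
               factor(genotypes[keep], levels = 0:2))
  out <- matrix(as.integer(tab), nrow = 2L,
                dimnames = list(c("female", "male"), c("hom_ref", "het", "hom_alt")))
  out
}

#' Generate male/female coverage tracks with no sex difference
#'
#' Two independent per-window mean-depth tracks around a common mean,
#' emulating sequencing depth over an undifferentiated chromosome pair
#' scanned in nonoverlapping windows: the expected male/female depth
#' log-ratio is zero in every window.  Noise is Gaussian truncated at
#' zero.
#'
#' @param n_windows Number of windows (>= 1).
#' @param mean_depth Common mean depth (> 0).
#' @param noise_sd Standard deviation of the per-window noise; 0 gives
#'   exactly equal tracks.
#' @param seed Integer seed.
#' @return List with numeric `male` and `female` depth vectors.
#' @export
generate_coverage_tracks <- function(n_windows = 1000L, mean_depth = 30,
                                     noise_sd = 3, seed = 1L) {
  stopifnot(n_windows >= 1L, mean_depth > 0, noise_sd >= 0)
  with_seed(seed, {
    male <- pmax(0, rnorm(n_windows, mean_depth, noise_sd))
    female <- pmax(0, rnorm(n_windows, mean_depth, noise_sd))
    list(male = male, female = female)
  })
}
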