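#' Average number of pairwise nucleotide differences (pi)
#'
#' Mean of [pairwise_differences()] over all unordered pairs in the group,
#' reported as a count per segment (divide by the segment length for the
#' per-site value).
#'
#' @param group List of [haplotype()]s.
#' @param per_site Divide by `total_length` (requires `gm`); default FALSE.
#' @param gm Optional [gene_model()], needed for `per_site = TRUE`.
#' @return Numeric pi, or `NA` when the group has fewer than two members.
#' @export
nucleotide_diversity <- function(group, per_site = FALSE, gm = NULL) {
  n <- length(group)
  if (n < 2L) return(NA_real_)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      tot <- tot + pairwise_differences(group[[i]], group[[j]])
    }
  }
  out <- tot / choose(n, 2)
  if (per_site) {
    if (is.null(gm)) stop("per_site = TRUE requires gm")
    out <- out / gm$total_length
  }
  out
}

#' Average pairwise differences between two groups (dxy)
#'
#' Mean of [pairwise_differences()] over all cross pairs (one haplotype
#' from each group), as a count per segment.
#'
#' @param groupA,groupB Lists of [haplotype()]s.
#' @return Numeric dxy, or `NA` when either group is empty.
#' @export
dxy <- function(groupA, groupB) {
  if (length(groupA) == 0L || length(groupB) == 0L) return(NA_real_)
  tot <- 0
  for (a in groupA) for (b in groupB) tot <- tot + pairwise_differences(a, b)
  tot / (length(groupA) * length(groupB))
}

#' Fixation index from within- and between-class diversity
#'
#' `Fst = 1 - ((pi_w + pi_z)/2) / dxy`: the proportion of between-class
#' divergence not explained by mean within-class diversity.
#'
#' @param pi_w,pi_z Within-class diversities (counts per segment).
#' @param dxy Between-class divergence (count per segment).
#' @return Numeric in `(-Inf, 1]`, or `NA` when `dxy` is zero or any input
#'   is undefined.
#' @export
fst <- function(pi_w, pi_z, dxy) {
  if (any(is.na(c(pi_w, pi_z, dxy))) || dxy == 0) return(NA_real_)
  1 - ((pi_w + pi_z) / 2) / dxy
}

#' Diversity statistics of a population
#'
#' Computes pi over the whole population (`pi_all`), within the W class
#' (`pi_w`), within the Z class (`pi_z`), the between-class divergence
#' `dxy`, and `Fst`, all as difference counts per segment.  Uses allele
#' counts at segregating sites, which is exactly equivalent to averaging
#' [pairwise_differences()] over pairs (the equivalence is asserted by the
#' test suite).
#'
#' @param population A population state.
#' @param gm The [gene_model()].
#' @return Object of class `diversity_stats` with fields `pi_all`, `pi_w`,
#'   `pi_z`, `dxy`, `fst`, `n_w`, `n_z`, `n_segregating`.
#' @export
diversity_stats <- function(population, gm) {
  haps <- population$haplotypes
  functional <- vapply(haps, function(h) {
    if (!is.null(h$functional)) h$functional else is_functional(h, gm)
  }, logical(1))

  ## base matrix restricted to sites segregating anywhere
  sites <- sort(unique(unlist(lapply(haps, `[[`, "pos"), use.names = FALSE)))
  n <- length(haps)
  if (length(sites)) {
    mat <- matrix(rep(gm$reference[sites + 1L], each = n), nrow = n)
    site_index <- seq_along(sites)
    names(site_index) <- sites
    for (i in seq_len(n)) {
      h <- haps[[i]]
      if (length(h$pos)) mat[i, site_index[as.character(h$pos)]] <- h$base
    }
  } else {
    mat <- matrix(integer(0), nrow = n, ncol = 0L)
  }

  pi_from_counts <- function(rows) {
    k <- length(rows)
    if (k < 2L) return(NA_real_)
    if (ncol(mat) == 0L) return(0)
    tot <- 0
    for (s in seq_len(ncol(mat))) {
      cb <- tabulate(mat[rows, s], nbins = 4L)
      tot <- tot + (k^2 - sum(cb^2)) / 2
    }
    tot / choose(k, 2)
  }
  dxy_from_counts <- function(rowsA, rowsB) {
    ka <- length(rowsA); kb <- length(rowsB)
    if (ka == 0L || kb == 0L) return(NA_real_)
    if (ncol(mat) == 0L) return(0)
    tot <- 0
    for (s in seq_len(ncol(mat))) {
      ca <- tabulate(mat[rowsA, s], nbins = 4L)
      cb <- tabulate(mat[rowsB, s], nbins = 4L)
      tot <- tot + (ka * kb - sum(ca * cb))
    }
    tot / (ka * kb)
  }

  w_rows <- which(functional)
  z_rows <- which(!functional)
  pi_all <- pi_from_counts(seq_len(n))
  pi_w <- pi_from_counts(w_rows)
  pi_z <- pi_from_counts(z_rows)
  d_wz <- dxy_from_counts(w_rows, z_rows)

  structure(
    list(pi_all = pi_all, pi_w = pi_w, pi_z = pi_z, dxy = d_wz,
         fst = fst(pi_w, pi_z, d_wz),
         n_w = length(w_rows), n_z = length(z_rows),
         n_segregating = sum(vapply(seq_len(ncol(mat)), function(s) {
           length(unique(mat[, s])) > 1L
         }, logical(1)))),
    class = "diversity_stats"
  )
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("diversity: pi_all = %.4g, pi_w = %.4g, pi_z = %.4g, dxy = %.4g, fst = %.4g (%d W / %d Z, %d segregating sites)\n",
              x$pi_all, x$pi_w, x$pi_z, x$dxy, x$fst, x$n_w, x$n_z, x$n_segregating))
  invisible(x)
}

#' Genotypic test of association between sex and genotype
#'
#' Pearson chi-square (no continuity correction) on the sex x genotype
#' contingency table.  The default mode collapses genotypes into
#' heterozygous vs homozygous (2 x 2, df = 1), the pattern expected of a
#' perfectly sex-linked variant under female heterogamety: all females
#' heterozygous, all males homozygous.  `"full_df2"` keeps the three
#' genotype classes (df = 2).
#'
#' @param table Matrix of counts with one row per sex (rows `female`,
#'   `male`) and genotype-class columns.  With three columns they are taken
#'   as hom-ref, het, hom-alt (in any order if named `hom_ref`, `het`,
#'   `hom_alt`); with two columns as het and hom.
#' @param mode `"het_vs_hom_df1"` (default) or `"full_df2"`.
#' @return List with `chi2`, `df`, `p` (all `NA` when a margin of the
#'   collapsed table is zero).
#' @examples
#' ## a perfectly sex-linked SNP: 45 het females, 37 hom males
#' tab <- rbind(female = c(het = 45, hom = 0), male = c(het = 0, hom = 37))
#' genotypic_sex_association(tab)
#' @export
genotypic_sex_association <- function(table, mode = c("het_vs_hom_df1", "full_df2")) {
  mode <- match.arg(mode)
  table <- as.matrix(table)
  if (sum(table) < 1) stop("empty genotype table")

  if (mode == "het_vs_hom_df1" && ncol(table) > 2L) {
    het_col <- if (!is.null(colnames(table)) && "het" %in% colnames(table)) {
      match("het", colnames(table))
    } else {
      2L
    }
    table <- cbind(het = table[, het_col],
                   hom = rowSums(table[, -het_col, drop = FALSE]))
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_))
  }
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter), p = ct$p.value)
}

#' Classify the heterogamety pattern of a sex-linked variant
#'
#' `ZW_like` when every female is heterozygous and every male homozygous
#' for the same genotype; `XY_like` for the mirrored pattern; `none`
#' otherwise.  Missing genotypes (`NA`) are excluded.
#'
#' @param genotypes Integer dosages (0, 1, 2 copies of the alternative
#'   allele) per individual.
#' @param sex Character vector (`"F"`/`"M"` or `"female"`/`"male"`) aligned
#'   with `genotypes`.
#' @return One of `"ZW_like"`, `"XY_like"`, `"none"`.
#' @export
heterogamety_pattern <- function(genotypes, sex) {
  sex <- toupper(substr(as.character(sex), 1L, 1L))
  if (!all(sex %in% c("F", "M"))) stop("sex must be F/female or M/male")
  keep <- !is.na(genotypes)
  g <- genotypes[keep]; s <- sex[keep]
  gf <- g[s == "F"]; gmale <- g[s == "M"]
  if (length(gf) == 0L || length(gmale) == 0L) {
    stop("all genotypes missing in one sex")
  }
  hom_same <- function(x) all(x %in% c(0L, 2L)) && length(unique(x)) == 1L
  if (all(gf == 1L) && hom_same(gmale)) return("ZW_like")
  if (all(gmale == 1L) && hom_same(gf)) return("XY_like")
  "none"
}

#' Chi-square test of an equal sex ratio
#'
#' One-degree-of-freedom chi-square of observed female/male counts against
#' 1:1, without continuity correction.
#'
#' @param female_count,male_count Non-negative counts (total > 0).
#' @return List with `chi2` and `p`.
#' @examples
#' sex_ratio_chisq(502, 504)
#' @export
sex_ratio_chisq <- function(female_count, male_count) {
  n <- female_count + male_count
  if (n <= 0) stop("total count must be positive")
  e <- n / 2
  chi2 <- (female_count - e)^2 / e + (male_count - e)^2 / e
  list(chi2 = chi2, p = pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Windowed nucleotide diversity from allele frequencies
#'
#' Tiles `[0, sequence_length)` into nonoverlapping windows (default 10 kb)
#' and sums, over the variants in each window, the unbiased per-site
#' heterozygosity `2 p (1 - p) * n / (n - 1)` where `p` is the alternative
#' allele frequency and `n` the number of haplotypes.  This equals the mean
#' pairwise difference count per window for biallelic sites.
#'
#' @param positions 0-based variant positions.
#' @param dosages Matrix of genotype dosages (variants x individuals,
#'   values 0/1/2), or a numeric vector of alternative-allele frequencies
#'   (then `n_haplotypes` must be given).
#' @param sequence_length Total length tiled by windows.
#' @param window Window size in bp (default 10000).
#' @param n_haplotypes Number of haplotypes when `dosages` is a frequency
#'   vector.
#' @return Data frame with `start`, `end`, `pi` per window.
#' @export
windowed_pi <- function(positions, dosages, sequence_length, window = 10000L,
                        n_haplotypes = NULL) {
  positions <- as.integer(positions)
  if (any(positions < 0L | positions >= sequence_length)) {
    stop("positions must lie in [0, sequence_length)")
  }
  if (is.matrix(dosages)) {
    n <- 2L * ncol(dosages)
    p <- rowSums(dosages) / n
  } else {
    if (is.null(n_haplotypes)) stop("n_haplotypes required with a frequency vector")
    n <- n_haplotypes
    p <- as.numeric(dosages)
  }
  stopifnot(length(p) == length(positions))
  n_win <- as.integer(ceiling(sequence_length / window))
  starts <- (seq_len(n_win) - 1L) * as.integer(window)
  contrib <- 2 * p * (1 - p) * n / (n - 1)
  win_of <- positions %/% as.integer(window) + 1L
  pi_win <- vapply(seq_len(n_win), function(w) sum(contrib[win_of == w]), numeric(1))
  data.frame(start = starts,
             end = pmin(starts + as.integer(window), as.integer(sequence_length)),
             pi = pi_win)
}

#' Male/female depth log-ratio per window
#'
#' `log2((male + 0.1) / (female + 0.1))` elementwise; the 0.1 pseudocount
#' keeps empty windows defined and symmetric (both depths zero gives 0).
#' On undifferentiated sex chromosomes the expectation is 0 everywhere.
#'
#' @param male_depth,female_depth Non-negative per-window mean depths.
#' @return Numeric vector of log2 ratios.
#' @export
depth_log_ratio <- function(male_depth, female_depth) {
  if (any(male_depth < 0) || any(female_depth < 0)) stop("depths must be non-negative")
  log2((male_depth + 0.1) / (female_depth + 0.1))
}

#' Write per-window values as a BED-like TSV
#'
#' Four columns (chrom, start, end, value), 0-based half-open, suitable
#' for the outputs of [windowed_pi()] or [depth_log_ratio()] per window.
#'
#' @param windows Data frame with `start` and `end` columns and one value
#'   column (its name is taken from `value_col`).
#' @param path Output path.
#' @param chrom Chromosome name for the first column.
#' @param value_col Name of the value column (default: the third column).
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path, chrom = "locus",
                              value_col = setdiff(names(windows), c("start", "end"))[1L]) {
  df <- data.frame(chrom = chrom, start = windows$start, end = windows$end,
                   value = signif(windows[[value_col]], 6))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
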