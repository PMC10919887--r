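## File formats
##
## - Gene models: a JSON structure file (format-tagged) + a FASTA file for
##   the reference sequence (written/read with Biostrings).
## - Exons: BED (0-based, half-open).
## - Cohorts: a minimal VCF v4.2 subset (CHROM, POS 1-based, REF, ALT, GT)
##   and a native TSV with dosages; VCF reading goes through vcfR.
## - Batches: per-replicate TSV + aggregate table TSV + JSON metadata.
## All internal coordinates are 0-based half-open; 1-based coordinates
## appear only at the VCF boundary.

format_header <- function() sprintf("zwturnover_format=%s", ZW_FORMAT_VERSION)

check_format <- function(tag, file) {
  if (is.null(tag)) stop("missing format tag in ", file)
  major <- sub("\\..*$", "", sub("^zwturnover_format=", "", tag))
  if (major != sub("\\..*$", "", ZW_FORMAT_VERSION)) {
    stop("unsupported format version in ", file, ": ", tag)
  }
  invisible(TRUE)
}

#' Write / read a gene model
#'
#' The structure (exons, frame offset, founding mutation) goes to a JSON
#' file; the reference sequence goes to a sibling FASTA file
#' (`<path>.fasta` by default).
#'
#' @param gm A [gene_model()].
#' @param path Path of the JSON structure file.
#' @param fasta_path Path of the FASTA file (default `<path>.fasta`).
#' @return `write_gene_model`: `path`, invisibly.  `read_gene_model`: the
#'   reconstructed, validated [gene_model()].
#' @export
write_gene_model <- function(gm, path, fasta_path = paste0(path, ".fasta")) {
  seq_str <- paste0(code_to_base(gm$reference), collapse = "")
  dss <- Biostrings::DNAStringSet(seq_str)
  names(dss) <- "reference"
  Biostrings::writeXStringSet(dss, fasta_path)
  obj <- list(
    format = format_header(),
    total_length = gm$total_length,
    fasta = basename(fasta_path),
    exon_intervals = unname(apply(gm$exon_intervals, 1L, as.list)),
    coding_frame_offset = gm$coding_frame_offset,
    initial_sd_site = gm$initial_sd_site,
    initial_sd_alt_base = code_to_base(gm$initial_sd_alt_base)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_gene_model
#' @export
read_gene_model <- function(path, fasta_path = NULL) {
  obj <- jsonlite::read_json(path)
  check_format(obj$format, path)
  if (is.null(fasta_path)) fasta_path <- file.path(dirname(path), obj$fasta)
  dss <- Biostrings::readDNAStringSet(fasta_path)
  seq_chr <- as.character(dss[[1L]])
  ex <- do.call(rbind, lapply(obj$exon_intervals, function(e) {
    as.integer(c(e$start, e$end))
  }))
  gene_model(
    reference_sequence = seq_chr,
    exon_intervals = ex,
    initial_sd_site = obj$initial_sd_site,
    initial_sd_alt_base = obj$initial_sd_alt_base,
    coding_frame_offset = obj$coding_frame_offset
  )
}

#' Export exon intervals as BED
#'
#' @param gm A [gene_model()].
#' @param path Output path.
#' @param chrom Chromosome name used in the first column.
#' @return `path`, invisibly.
#' @export
write_exons_bed <- function(gm, path, chrom = "locus") {
  df <- data.frame(chrom = chrom,
                   start = gm$exon_intervals[, 1L],
                   end = gm$exon_intervals[, 2L],
                   name = sprintf("exon%d", seq_len(nrow(gm$exon_intervals))))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a cohort as a minimal VCF (v4.2 subset)
#'
#' Emits CHROM, POS (1-based), ID, REF, ALT, QUAL, FILTER, INFO, FORMAT=GT
#' and one diploid GT column per sample.  Missing genotypes become `./.`.
#'
#' @param cohort A [generate_sex_genotype_cohort()] result.
#' @param path Output path (plain text).
#' @param chrom Chromosome name.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path, chrom = "chr1") {
  gt_str <- function(d) {
    ifelse(is.na(d), "./.", c("0/0", "0/1", "1/1")[d + 1L])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##zwturnover_format=%s", ZW_FORMAT_VERSION),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$sample_ids), collapse = "\t")
  ), con)
  for (v in seq_len(nrow(cohort$genotypes))) {
    writeLines(paste(c(
      chrom, cohort$positions[v] + 1L, sprintf("var%d", v),
      cohort$ref[v], cohort$alt[v], ".", "PASS", ".", "GT",
      gt_str(cohort$genotypes[v, ])
    ), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotype dosages from a minimal VCF
#'
#' Parses a biallelic-variant VCF with vcfR and returns dosages of the
#' alternative allele.
#'
#' @param path VCF path.
#' @return List with `genotypes` (variants x samples dosage matrix),
#'   `positions` (0-based), `ref`, `alt`, `sample_ids`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean == "1/1"] <- 2L
  list(
    genotypes = dos,
    positions = as.integer(v@fix[, "POS"]) - 1L,
    ref = v@fix[, "REF"],
    alt = v@fix[, "ALT"],
    sample_ids = colnames(gt)
  )
}

#' Write a cohort as a native TSV (dosage matrix + truth record)
#'
#' @param cohort A [generate_sex_genotype_cohort()] result.
#' @param path Output TSV path; the truth record goes to `<path>.truth.tsv`.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  df <- data.frame(position = cohort$positions, ref = cohort$ref, alt = cohort$alt)
  dos <- as.data.frame(cohort$genotypes)
  names(dos) <- cohort$sample_ids
  con <- file(path, "w")
  writeLines(paste0("#", format_header()), con)
  writeLines(paste0("#sex\t", paste(cohort$sex, collapse = "\t")), con)
  close(con)
  suppressWarnings(write.table(cbind(df, dos), path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  tr <- cohort$truth
  write.table(data.frame(causal_index = tr$causal_index,
                         causal_position = tr$causal_position,
                         kind = tr$kind),
              paste0(path, ".truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a native cohort TSV
#'
#' @param path TSV written by [write_cohort_tsv()].
#' @return List with `genotypes`, `positions`, `ref`, `alt`, `sex`,
#'   `sample_ids`.
#' @export
read_cohort_tsv <- function(path) {
  header <- readLines(path, n = 2L)
  check_format(sub("^#", "", header[1L]), path)
  sex <- strsplit(sub("^#sex\t", "", header[2L]), "\t")[[1L]]
  df <- read.table(path, sep = "\t", header = TRUE, skip = 2L,
                   comment.char = "", check.names = FALSE)
  geno <- as.matrix(df[, -(1:3), drop = FALSE])
  storage.mode(geno) <- "integer"
  list(genotypes = geno, positions = as.integer(df$position),
       ref = df$ref, alt = df$alt, sex = sex, sample_ids = colnames(geno))
}

#' Write per-replicate results and the aggregate table of a batch
#'
#' `write_batch_tsv` emits one row per replicate (seed, status, turnover,
#' fixed/nonfixed counts, diversity statistics); `write_table1_tsv` emits
#' one aggregate row per batch in the standard layout (TS%, histogram of
#' replicates by number of fixed and nonfixed sex-determining mutations).
#'
#' @param batch A [wf_batch()] result (for `write_table1_tsv`, a named list
#'   of them, one per parameter set).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_batch_tsv <- function(batch, path) {
  rows <- lapply(seq_along(batch$replicates), function(i) {
    r <- batch$replicates[[i]]
    data.frame(
      replicate = i, seed = r$seed, status = r$termination_status,
      turnover = r$census$turnover,
      n_fixed = length(r$census$fixed_lof),
      n_nonfixed = length(r$census$nonfixed_lof),
      pi_all = signif(r$diversity$pi_all, 6), pi_w = signif(r$diversity$pi_w, 6),
      pi_z = signif(r$diversity$pi_z, 6), dxy = signif(r$diversity$dxy, 6),
      fst = signif(r$diversity$fst, 6)
    )
  })
  con <- file(path, "w")
  writeLines(paste0("#", format_header()), con)
  close(con)
  suppressWarnings(write.table(do.call(rbind, rows), path, sep = "\t",
                               quote = FALSE, row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_batch_tsv
#' @param params_by_set Named list of [sim_params()] matching `batch` when
#'   writing several sets.
#' @export
write_table1_tsv <- function(batch, path, params_by_set = NULL) {
  batches <- if (inherits(batch, "wf_batch")) list(batch = batch) else batch
  rows <- lapply(names(batches), function(nm) {
    b <- batches[[nm]]
    t1 <- b$table
    p <- if (!is.null(params_by_set)) params_by_set[[nm]] else b$params
    cbind(
      data.frame(set = nm, mu = p$mu, r0 = p$r0, pop_chromosomes = p$pop_chromosomes,
                 ts_percent = t1$ts_percent),
      as.data.frame(as.list(setNames(t1$fixed_hist,
                                     paste0("fixed_", names(t1$fixed_hist))))),
      as.data.frame(as.list(setNames(t1$nonfixed_hist,
                                     paste0("nonfixed_", names(t1$nonfixed_hist)))))
    )
  })
  con <- file(path, "w")
  writeLines(paste0("#", format_header()), con)
  close(con)
  suppressWarnings(write.table(do.call(rbind, rows), path, sep = "\t",
                               quote = FALSE, row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Read a run configuration file
#'
#' The configuration is a YAML file with fields `n_replicates`,
#' `base_seed`, optional `gene_model` (a LocusSpec: `total_length`,
#' `n_exons`, `exon_fraction`, `seed`) and a named map `sets`, each entry
#' giving `mu`, `r0`, `c` (optional), `pop_chromosomes` and `generations`.
#' A bundled configuration reproducing the four standard parameter sets is
#' at `system.file("extdata", "table1_config.yaml", package = "zwturnover")`.
#'
#' @param path YAML config path.
#' @return List with `n_replicates`, `base_seed`, `gene_model` (a built
#'   [gene_model()]) and `sets` (named list of [sim_params()]).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (field in c("sets", "n_replicates", "base_seed")) {
    if (is.null(cfg[[field]])) stop("config is missing required field '", field, "'")
  }
  gm_spec <- cfg$gene_model
  gm <- generate_gene_model(
    total_length = gm_spec$total_length %||% 1678L,
    n_exons = gm_spec$n_exons %||% 2L,
    exon_fraction = gm_spec$exon_fraction %||% 0.5,
    seed = gm_spec$seed %||% 1L
  )
  if (anyDuplicated(names(cfg$sets))) stop("duplicate set labels in config")
  sets <- lapply(cfg$sets, function(s) {
    sim_params(
      gene_model = gm,
      mu = s$mu %||% 1e-8,
      r0 = s$r0 %||% 1e-6,
      c = s$c %||% 0.03,
      pop_chromosomes = s$pop_chromosomes %||% 100L,
      generations = s$generations %||% 100000L
    )
  })
  list(n_replicates = as.integer(cfg$n_replicates),
       base_seed = as.integer(cfg$base_seed),
       gene_model = gm, sets = sets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the JSON metadata sidecar of a run
#'
#' Records parameters, seeds and the package version so a run can be
#' reproduced bit-identically.
#'
#' @param config A [read_run_config()] result.
#' @param set_labels Labels actually run.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(config, set_labels, path) {
  obj <- list(
    format = format_header(),
    package_version = as.character(utils::packageVersion("zwturnover")),
    n_replicates = config$n_replicates,
    base_seed = config$base_seed,
    sets = lapply(config$sets[set_labels], function(p) {
      list(mu = p$mu, r0 = p$r0, c = p$c,
           pop_chromosomes = p$pop_chromosomes, generations = p$generations)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Dump the final haplotypes of a replicate as FASTA
#'
#' One record per chromosome; the id encodes individual, sex and
#' functional class (`ind<i>_<F/M>_<W/Z>_<1/2>`).
#'
#' @param replicate A [wf_simulate()] result whose population was kept.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_population_fasta <- function(replicate, path) {
  pop <- replicate$population
  if (is.null(pop)) stop("replicate has no stored population")
  gm <- replicate$params$gene_model
  n_ind <- length(pop$female)
  seqs <- character(2L * n_ind)
  ids <- character(2L * n_ind)
  for (i in seq_len(n_ind)) {
    for (c in 1:2) {
      h <- pop$haplotypes[[2L * (i - 1L) + c]]
      seqs[2L * (i - 1L) + c] <- paste0(reconstruct_sequence(h, gm), collapse = "")
      ids[2L * (i - 1L) + c] <- sprintf("ind%d_%s_%s_%d", i,
                                        if (pop$female[i]) "F" else "M",
                                        if (h$functional) "W" else "Z", c)
    }
  }
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ids
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}
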