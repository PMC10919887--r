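#' Generate a synthetic sex-determining gene model
#'
#' Builds a gene segment with a valid exon/intron architecture: exons tiled
#' to meet the target coding fraction (within 5%), a coding sequence
#' assembled codon-by-codon from sense codons (so it contains no internal
#' stop) starting with ATG and ending with a stop codon, and introns opened
#' with the canonical donor `GT` and closed with the acceptor `AG`.  The
#' founding sex-determining mutation is placed on the first intron's donor
#' dinucleotide (the G of `GT` replaced by A), mirroring a splice-donor
#' disruption that abolishes gene function.
#'
#' The default emulates the simulated locus: a 1,678-bp segment with two
#' exons, one intron, and roughly half the segment coding.  The exact
#' architecture of the real segment is not published, so the exon count and
#' coding fraction are exposed as knobs; the loss-of-function target size
#' (and with it the supply of sex-determining mutations) depends on them.
#'
#' @param total_length Segment length in bp (default 1678).
#' @param n_exons Number of exons, at least 2 so there is an intron with a
#'   donor site (default 2).
#' @param exon_fraction Target fraction of the segment that is coding,
#'   in (0, 1) (default 0.5).
#' @param seed Integer seed; the model is deterministic given the seed.
#' @return A validated [gene_model()].
#' @examples
#' gm <- generate_gene_model()
#' gm
#' @export
generate_gene_model <- function(total_length = 1678L, n_exons = 2L,
                                exon_fraction = 0.5, seed = 1L) {
  total_length <- as.integer(total_length)
  n_exons <- as.integer(n_exons)
  if (n_exons < 2L) stop("n_exons must be >= 2 (need at least one intron)")
  if (!(exon_fraction > 0 && exon_fraction < 1)) stop("exon_fraction must be in (0, 1)")

  ## coding length: nearest multiple of 3 to the target, at least one codon
  ## per exon plus start and stop
  cds_len <- max(3L * (n_exons + 2L), 3L * as.integer(round(total_length * exon_fraction / 3)))
  n_introns <- n_exons - 1L
  intron_total <- total_length - cds_len
  if (intron_total < 4L * n_introns) {
    stop("infeasible spec: exon_fraction leaves an intron shorter than 4 bp")
  }
  if (abs(cds_len / total_length - exon_fraction) > 0.05) {
    stop("infeasible spec: cannot meet exon_fraction within 5% with whole codons")
  }

  ## split coding bases across exons and intronic bases across introns,
  ## as evenly as integer arithmetic allows
  split_even <- function(total, k) {
    out <- rep(total %/% k, k)
    extra <- total %% k
    if (extra > 0L) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
    out
  }
  exon_len <- split_even(cds_len, n_exons)
  intron_len <- split_even(intron_total, n_introns)

  pos <- 0L
  ex <- matrix(0L, nrow = n_exons, ncol = 2L)
  for (i in seq_len(n_exons)) {
    ex[i, ] <- c(pos, pos + exon_len[i])
    pos <- pos + exon_len[i]
    if (i <= n_introns) pos <- pos + intron_len[i]
  }

  with_seed(seed, {
    ## coding sequence from sense codons: ATG, random sense codons, stop
    gc_tab <- Biostrings::GENETIC_CODE
    sense <- names(gc_tab)[gc_tab != "*"]
    stops <- names(gc_tab)[gc_tab == "*"]
    n_codons <- cds_len %/% 3L
    codons <- c("ATG",
                sample(sense, n_codons - 2L, replace = TRUE),
                sample(stops, 1L))
    cds <- strsplit(paste0(codons, collapse = ""), "")[[1]]

    ## intron interiors are unconstrained
    seq_chr <- character(total_length)
    cds_cursor <- 1L
    for (i in seq_len(n_exons)) {
      idx <- seq.int(ex[i, 1L] + 1L, ex[i, 2L])
      seq_chr[idx] <- cds[seq.int(cds_cursor, cds_cursor + exon_len[i] - 1L)]
      cds_cursor <- cds_cursor + exon_len[i]
      if (i <= n_introns) {
        i_start <- ex[i, 2L]
        i_end <- ex[i + 1L, 1L]
        interior <- i_end - i_start - 4L
        seq_chr[seq.int(i_start + 1L, i_end)] <- c(
          "G", "T",
          if (interior > 0L) sample(DNA_BASES, interior, replace = TRUE),
          "A", "G"
        )
      }
    }

    gene_model(
      reference_sequence = seq_chr,
      exon_intervals = ex,
      initial_sd_site = ex[1L, 2L],   # the G of the first intron's GT
      initial_sd_alt_base = "A",
      coding_frame_offset = 0L
    )
  })
}
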