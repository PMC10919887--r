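#' Annotated gene model for a ZW sex-determining locus
#'
#' A `gene_model` describes the reference (ancestral, fully functional,
#' W-type) sequence of the sex-determining gene segment together with its
#' exon/intron structure.  It is the object against which every point
#' mutation in the simulator is classified as neutral or loss-of-function
#' (LOF): splice-site changes, missense changes and nonsense changes abolish
#' gene function and convert the chromosome carrying them from W to Z.
#'
#' All coordinates are 0-based, half-open.  Intron boundaries are derived
#' from the gaps between consecutive exons; each intron must begin with the
#' canonical donor dinucleotide `GT` and end with the acceptor `AG`.
#'
#' @param reference_sequence Character string (or vector of single bases, or
#'   integer codes 1-4 for A/C/G/T) giving the reference sequence.
#' @param exon_intervals Two-column matrix (start, end) of 0-based half-open
#'   exon intervals, sorted and non-overlapping.
#' @param initial_sd_site 0-based position of the founding sex-determining
#'   mutation.  Must fall inside the first intron's donor dinucleotide.
#' @param initial_sd_alt_base Derived base at `initial_sd_site` (single
#'   character or code 1-4); must differ from the reference base and be
#'   classified `splice_site`.
#' @param coding_frame_offset Offset (0-2) of the reading frame within the
#'   spliced exonic sequence.  The default layouts produced by
#'   [generate_gene_model()] use 0.
#' @param validate Check all structural invariants and fail on violation.
#'
#' @return An object of class `gene_model`: a list with fields
#'   `total_length`, `reference` (integer codes), `exon_intervals`,
#'   `coding_frame_offset`, `splice_donor_positions`,
#'   `splice_acceptor_positions`, `initial_sd_site`, `initial_sd_alt_base`,
#'   and the precomputed per-site effect table (`effect`, a 4 x L integer
#'   matrix over alternative bases, and `lof`, its logical LOF view).
#'
#' @seealso [classify_site_change()], [generate_gene_model()],
#'   [validate_gene_model()]
#' @export
gene_model <- function(reference_sequence, exon_intervals, initial_sd_site,
                       initial_sd_alt_base, coding_frame_offset = 0L,
                       validate = TRUE) {
  ref <- base_to_code(reference_sequence)
  L <- length(ref)
  exon_intervals <- matrix(as.integer(exon_intervals), ncol = 2L,
                           dimnames = list(NULL, c("start", "end")))
  ord <- order(exon_intervals[, 1L])
  exon_intervals <- exon_intervals[ord, , drop = FALSE]
  n_exons <- nrow(exon_intervals)
  if (n_exons < 1L) stop("at least one exon is required")

  ## introns are the gaps between consecutive exons
  if (n_exons >= 2L) {
    intron_start <- exon_intervals[-n_exons, 2L]
    intron_end <- exon_intervals[-1L, 1L]
  } else {
    intron_start <- integer(0)
    intron_end <- integer(0)
  }

  gm <- structure(
    list(
      total_length = L,
      reference = ref,
      exon_intervals = exon_intervals,
      coding_frame_offset = as.integer(coding_frame_offset),
      splice_donor_positions = intron_start,
      splice_acceptor_positions = intron_end - 2L,
      initial_sd_site = as.integer(initial_sd_site),
      initial_sd_alt_base = base_to_code(initial_sd_alt_base)
    ),
    class = "gene_model"
  )
  gm$effect <- build_effect_table(gm)
  gm$lof <- matrix(gm$effect %in% c(3L, 4L, 5L), nrow = 4L)

  if (validate) {
    bad <- validate_gene_model(gm)
    if (length(bad)) {
      stop("invalid gene model:\n  ", paste(bad, collapse = "\n  "))
    }
  }
  gm
}

#' Check every structural invariant of a gene model
#'
#' Returns a character vector of human-readable violations (empty when the
#' model is valid): exon ordering and bounds, canonical GT/AG intron ends,
#' reading frame a multiple of three with no internal stop and a terminal
#' stop codon, and a founding sex-determining mutation sitting in the first
#' intron's donor dinucleotide and classified as a splice-site LOF.
#'
#' @param gm A [gene_model()].
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
validate_gene_model <- function(gm) {
  bad <- character(0)
  L <- gm$total_length
  ex <- gm$exon_intervals
  n_exons <- nrow(ex)

  if (any(ex[, 1L] >= ex[, 2L])) bad <- c(bad, "empty or inverted exon interval")
  if (ex[1L, 1L] < 0L || ex[n_exons, 2L] > L) bad <- c(bad, "exon outside [0, total_length)")
  if (n_exons >= 2L && any(ex[-1L, 1L] < ex[-n_exons, 2L])) {
    bad <- c(bad, "exons overlap or are unsorted")
  }
  if (n_exons >= 2L && any(ex[-1L, 1L] - ex[-n_exons, 2L] < 4L)) {
    bad <- c(bad, "an intron is shorter than 4 bp (no room for GT..AG)")
  }

  ## canonical splice dinucleotides on the reference
  for (d in gm$splice_donor_positions) {
    if (!identical(code_to_base(gm$reference[d + 1:2]), c("G", "T"))) {
      bad <- c(bad, sprintf("intron at %d does not start with GT", d))
    }
  }
  for (a in gm$splice_acceptor_positions) {
    if (!identical(code_to_base(gm$reference[a + 1:2]), c("A", "G"))) {
      bad <- c(bad, sprintf("intron ending at %d does not end with AG", a + 2L))
    }
  }

  ## reading frame of the spliced coding sequence
  cds <- coding_sequence(gm)
  if (length(cds) %% 3L != 0L) {
    bad <- c(bad, "spliced coding sequence length not divisible by 3")
  } else if (length(cds) >= 3L) {
    aa <- translate_codes(cds)
    n_aa <- length(aa)
    if (aa[n_aa] != "*") bad <- c(bad, "coding sequence does not end with a stop codon")
    if (n_aa > 1L && any(aa[-n_aa] == "*")) bad <- c(bad, "internal stop codon in coding sequence")
  }

  ## founding sex-determining mutation
  if (length(gm$splice_donor_positions) == 0L) {
    bad <- c(bad, "no intron, so no donor site for the founding mutation")
  } else {
    donor1 <- gm$splice_donor_positions[1L]
    if (!(gm$initial_sd_site %in% (donor1 + 0:1))) {
      bad <- c(bad, "initial_sd_site is not in the first intron's donor dinucleotide")
    }
    if (gm$initial_sd_alt_base == gm$reference[gm$initial_sd_site + 1L]) {
      bad <- c(bad, "initial_sd_alt_base equals the reference base")
    } else {
      eff <- gm$effect[gm$initial_sd_alt_base, gm$initial_sd_site + 1L]
      if (is.na(eff) || eff != 5L) {
        bad <- c(bad, "founding mutation is not classified splice_site")
      }
    }
  }
  bad
}

## 0-based positions of exonic sites, in spliced order.
exonic_positions <- function(gm) {
  unlist(lapply(seq_len(nrow(gm$exon_intervals)), function(i) {
    seq.int(gm$exon_intervals[i, 1L], gm$exon_intervals[i, 2L] - 1L)
  }), use.names = FALSE)
}

## Spliced coding sequence (integer codes), after the frame offset.
coding_sequence <- function(gm) {
  sp <- gm$reference[exonic_positions(gm) + 1L]
  off <- gm$coding_frame_offset
  if (off > 0L) sp <- sp[-seq_len(off)]
  n <- 3L * (length(sp) %/% 3L)
  sp[seq_len(n)]
}

## Translate a vector of base codes (length divisible by 3) to amino acids,
## using the standard genetic code ("*" = stop).
translate_codes <- function(codes) {
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- apply(matrix(code_to_base(codes), nrow = 3L), 2L, paste0, collapse = "")
  unname(gc_tab[codons])
}

## Precompute the effect of every possible single-base change.
## Returns a 4 x L integer matrix (rows = alternative base A/C/G/T):
## NA where alt == reference; otherwise 1 intronic, 2 synonymous,
## 3 missense, 4 nonsense, 5 splice_site.
build_effect_table <- function(gm) {
  L <- gm$total_length
  eff <- matrix(1L, nrow = 4L, ncol = L)

  ## exonic coding positions: translate the substituted codon
  ex_pos <- exonic_positions(gm)
  off <- gm$coding_frame_offset
  n_cds <- 3L * ((length(ex_pos) - off) %/% 3L)
  if (n_cds > 0L) {
    cds_pos <- ex_pos[off + seq_len(n_cds)]        # genomic pos of each CDS base
    cds_ref <- gm$reference[cds_pos + 1L]
    gc_tab <- Biostrings::GENETIC_CODE
    ref_codons <- matrix(cds_ref, nrow = 3L)       # one column per codon
    ref_aa <- gc_tab[apply(matrix(code_to_base(cds_ref), nrow = 3L), 2L,
                           paste0, collapse = "")]
    for (i in seq_len(n_cds)) {
      codon_idx <- (i - 1L) %/% 3L + 1L
      within <- (i - 1L) %% 3L + 1L
      codon <- ref_codons[, codon_idx]
      for (alt in seq_len(4L)) {
        if (alt == cds_ref[i]) next
        mutated <- codon
        mutated[within] <- alt
        aa <- gc_tab[paste0(code_to_base(mutated), collapse = "")]
        eff[alt, cds_pos[i] + 1L] <- if (aa == ref_aa[codon_idx]) {
          2L
        } else if (aa == "*") {
          4L
        } else {
          3L   # includes stop-loss at the terminal codon: still disruptive
        }
      }
    }
    ## exonic but outside the reading frame (possible with a frame offset):
    ## treated as neutral noncoding, i.e. left at "intronic"
  }

  ## splice dinucleotides dominate everything else
  splice_sites <- c(outer(c(gm$splice_donor_positions, gm$splice_acceptor_positions), 0:1, "+"))
  eff[, splice_sites + 1L] <- 5L

  ## no "effect" where alt equals the reference base
  eff[cbind(gm$reference, seq_len(L))] <- NA_integer_
  eff
}

#' Classify a single-base change against the gene model
#'
#' A change inside any donor/acceptor dinucleotide is `splice_site`
#' regardless of other annotation.  Otherwise an exonic change is translated
#' in its reference codon (standard genetic code) and called `synonymous`,
#' `missense` or `nonsense`; everything else is `intronic`.  Missense,
#' nonsense and splice-site changes are loss-of-function (LOF): a chromosome
#' carrying any of them behaves as Z.  Classification is always relative to
#' the reference sequence, so the effect is a pure function of
#' `(position, new_base)`.
#'
#' @param gm A [gene_model()].
#' @param position 0-based site index (vectorised).
#' @param new_base Replacement base (character or code 1-4, vectorised);
#'   must differ from the reference base at `position`.
#' @return A `mutation_effect` object: list with `category` (factor with
#'   levels intronic, synonymous, missense, nonsense, splice_site) and `lof`
#'   (logical).
#' @examples
#' gm <- generate_gene_model()
#' classify_site_change(gm, gm$initial_sd_site, gm$initial_sd_alt_base)
#' @export
classify_site_change <- function(gm, position, new_base) {
  position <- as.integer(position)
  alt <- base_to_code(new_base)
  if (length(alt) == 1L && length(position) > 1L) alt <- rep(alt, length(position))
  if (any(position < 0L | position >= gm$total_length)) {
    stop("position out of range [0, total_length)")
  }
  if (any(alt == gm$reference[position + 1L])) {
    stop("new_base equals the reference base at that position")
  }
  codes <- gm$effect[cbind(alt, position + 1L)]
  category <- factor(EFFECT_LEVELS[codes], levels = EFFECT_LEVELS)
  structure(list(category = category, lof = codes >= 3L), class = "mutation_effect")
}

#' @export
print.mutation_effect <- function(x, ...) {
  cat(sprintf("%s (lof = %s)\n", as.character(x$category), x$lof), sep = "")
  invisible(x)
}

#' Is a haplotype functional (W-class)?
#'
#' A haplotype is represented by its differences from the reference.  It is
#' functional -- and so behaves as a W chromosome -- iff none of its
#' differences is loss-of-function.  A site whose base has reverted to the
#' reference carries no entry, so back-mutation restores function.
#'
#' @param diffs A [haplotype()] object, or a list with integer `pos`
#'   (0-based) and `base` (codes 1-4 or characters).
#' @param gm A [gene_model()].
#' @return `TRUE` (W-class) or `FALSE` (Z-class).
#' @export
is_functional <- function(diffs, gm) {
  h <- as_haplotype(diffs)
  if (length(h$pos) == 0L) return(TRUE)
  if (any(h$base == gm$reference[h$pos + 1L])) {
    stop("diffs entry equal to the reference base: representation invariant violated")
  }
  !any(gm$lof[cbind(h$base, h$pos + 1L)])
}

#' @export
print.gene_model <- function(x, ...) {
  n_in <- length(x$splice_donor_positions)
  cat(sprintf("gene_model: %d bp, %d exon(s), %d intron(s)\n",
              x$total_length, nrow(x$exon_intervals), n_in))
  cat(sprintf("  exon fraction: %.3f\n",
              sum(x$exon_intervals[, 2] - x$exon_intervals[, 1]) / x$total_length))
  cat(sprintf("  founding SD mutation: pos %d (0-based) %s>%s [splice donor]\n",
              x$initial_sd_site,
              code_to_base(x$reference[x$initial_sd_site + 1L]),
              code_to_base(x$initial_sd_alt_base)))
  n_lof <- sum(x$lof, na.rm = TRUE)
  cat(sprintf("  LOF target: %d of %d possible single-base changes (%.1f%%)\n",
              n_lof, 3L * x$total_length, 100 * n_lof / (3L * x$total_length)))
  invisible(x)
}
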