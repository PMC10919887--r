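#' Haplotype as differences from the reference
#'
#' A chromosome copy is stored sparsely as the set of positions where it
#' differs from the reference sequence, with the base it carries there.
#'
#' @param pos Integer vector of 0-based positions (need not be sorted).
#' @param base Bases carried at those positions (characters or codes 1-4).
#' @param gm Optional [gene_model()]; when supplied, the representation
#'   invariant (no entry equal to the reference base) is checked and the
#'   functional flag is cached.
#' @return Object of class `haplotype`: list with sorted integer `pos`,
#'   integer `base`, and (if `gm` given) logical `functional`.
#' @export
haplotype <- function(pos = integer(0), base = integer(0), gm = NULL) {
  pos <- as.integer(pos)
  base <- base_to_code(base)
  stopifnot(length(pos) == length(base))
  if (anyDuplicated(pos)) stop("duplicate positions in haplotype")
  o <- order(pos)
  h <- structure(list(pos = pos[o], base = base[o]), class = "haplotype")
  if (!is.null(gm)) {
    if (any(h$pos < 0L | h$pos >= gm$total_length)) stop("position out of range")
    h$functional <- is_functional(h, gm)
  }
  h
}

as_haplotype <- function(x) {
  if (inherits(x, "haplotype")) return(x)
  if (is.list(x) && !is.null(x$pos)) {
    return(haplotype(x$pos, x$base))
  }
  ## named vector convenience: names are 0-based positions
  if (length(x) == 0L) return(haplotype())
  if (!is.null(names(x))) {
    return(haplotype(as.integer(names(x)), x))
  }
  stop("cannot interpret object as a haplotype")
}

#' Reconstruct the full sequence of a haplotype
#'
#' @param h A [haplotype()].
#' @param gm A [gene_model()] providing the reference.
#' @param as_character Return bases as characters (default) or codes 1-4.
#' @return Vector of length `gm$total_length`.
#' @export
reconstruct_sequence <- function(h, gm, as_character = TRUE) {
  h <- as_haplotype(h)
  s <- gm$reference
  if (length(h$pos)) s[h$pos + 1L] <- h$base
  if (as_character) code_to_base(s) else s
}

#' Number of differing sites between two haplotypes
#'
#' Counts positions where the two chromosome copies carry different bases:
#' the symmetric difference of their diff sets, with positions present in
#' both but with different bases counted once.  This is the divergence `d`
#' that feeds the recombination-suppression formula, and the primitive
#' behind pi and dxy.
#'
#' @param h1,h2 [haplotype()] objects over the same gene model.
#' @return Non-negative integer count.
#' @export
pairwise_differences <- function(h1, h2) {
  h1 <- as_haplotype(h1); h2 <- as_haplotype(h2)
  if (length(h1$pos) == 0L) return(length(h2$pos))
  if (length(h2$pos) == 0L) return(length(h1$pos))
  common <- intersect(h1$pos, h2$pos)
  n_only <- (length(h1$pos) - length(common)) + (length(h2$pos) - length(common))
  if (length(common)) {
    b1 <- h1$base[match(common, h1$pos)]
    b2 <- h2$base[match(common, h2$pos)]
    n_only + sum(b1 != b2)
  } else {
    n_only
  }
}

#' @export
print.haplotype <- function(x, ...) {
  if (length(x$pos) == 0L) {
    cat("haplotype: identical to reference\n")
  } else {
    cat(sprintf("haplotype: %d diff(s): %s\n", length(x$pos),
                paste0(x$pos, ">", code_to_base(x$base), collapse = ", ")))
  }
  if (!is.null(x$functional)) {
    cat(sprintf("  class: %s\n", if (x$functional) "W (functional)" else "Z (loss-of-function)"))
  }
  invisible(x)
}
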