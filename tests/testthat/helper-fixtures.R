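# Small hand-built gene model with fully known structure, used wherever a
# test needs exact positional arithmetic.
#
# Layout (60 bp, 0-based half-open):
#   exon1  [0, 12):  ATG GGA TGG AAA            (M G W K)
#   intron [12, 48): GT ................ AG     (donor at 12-13, acceptor 46-47)
#   exon2  [48, 60): CAT GAT TGT TAA            (H D C *)
# Founding SD mutation: position 12 (the G of GT) -> A.
tiny_gene_model <- function() {
  ref <- paste0(
    "ATGGGATGGAAA",
    "GT", strrep("C", 32), "AG",
    "CATGATTGTTAA"
  )
  gene_model(
    reference_sequence = ref,
    exon_intervals = rbind(c(0L, 12L), c(48L, 60L)),
    initial_sd_site = 12L,
    initial_sd_alt_base = "A"
  )
}

# Random haplotype over a gene model (any bases different from reference).
random_haplotype <- function(gm, n_diffs) {
  pos <- sample.int(gm$total_length, n_diffs) - 1L
  base <- vapply(pos, function(p) {
    sample(setdiff(1:4, gm$reference[p + 1L]), 1L)
  }, integer(1))
  haplotype(pos, base, gm = gm)
}

# Brute-force oracles on fully reconstructed sequences.
oracle_pairwise <- function(h1, h2, gm) {
  sum(reconstruct_sequence(h1, gm) != reconstruct_sequence(h2, gm))
}
oracle_pi <- function(group, gm) {
  n <- length(group)
  if (n < 2) return(NA_real_)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    tot <- tot + oracle_pairwise(group[[i]], group[[j]], gm)
  }
  tot / choose(n, 2)
}
oracle_dxy <- function(ga, gb, gm) {
  tot <- 0
  for (a in ga) for (b in gb) tot <- tot + oracle_pairwise(a, b, gm)
  tot / (length(ga) * length(gb))
}

# Build a wf_population by hand from a list of haplotype objects
# (consecutive pairs form individuals).
manual_population <- function(haps, gm) {
  n_ind <- length(haps) %/% 2L
  female <- vapply(seq_len(n_ind), function(i) {
    haps[[2L * i - 1L]]$functional || haps[[2L * i]]$functional
  }, logical(1))
  structure(list(generation = 0L, haplotypes = haps, female = female,
                 status = "completed"),
            class = "wf_population")
}
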