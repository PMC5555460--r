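# Shared fixtures, built in code at test time.

# Exhaustive oracle for the maximum r^2 between two loci: search all valid
# two-locus haplotype frequency tables on a fine grid of D.
maxR2Oracle <- function(p1, p2, grid = 200001L) {
  D <- seq(-0.25, 0.25, length.out = grid)
  p11 <- p1 * p2 + D
  ok <- p11 >= 0 & (p1 - p11) >= 0 & (p2 - p11) >= 0 &
    (1 - p1 - p2 + p11) >= 0
  r <- D[ok] / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  max(r^2)
}

# Small deterministic panel: 6 samples x 3 variants
tinyPanel <- function() {
  GenotypePanel(
    matrix(c(0, 1, 2, 0, 1, 2,
             0, 1, 2, 0, 1, 2,
             2, 1, 0, 2, 1, 0), nrow = 6),
    positions = c(100, 200, 300),
    variantIds = c("v1", "v2", "v3"))
}

# Write a minimal diploid VCF with GT calls; genotypes is a variants x
# samples matrix of strings like "0/1".
writeTestVcf <- function(path, genotypes, ids, pos,
                         sampleIds = paste0("S", seq_len(ncol(genotypes)))) {
  con <- file(path, "w")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", sampleIds), collapse = "\t")), con)
  for (i in seq_len(nrow(genotypes))) {
    writeLines(paste(c("1", pos[i], ids[i], "A", "G", ".", "PASS", ".",
                       "GT", genotypes[i, ]), collapse = "\t"), con)
  }
  close(con)
  path
}
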