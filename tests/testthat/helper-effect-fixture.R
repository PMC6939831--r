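# -- effect-classification fixture ------------------------------------------
# chr c1, 30 kb. geneA (+): 10001-10900 with CDS 10001-10300 and
# 10601-10900 (intron between); geneB (-): 25001-25300, single CDS.
# Bases are pinned so the first codons are GGA on both strands.
make_effect_fixture <- function() {
  set.seed(101)
  s <- sample(c("A", "C", "G", "T"), 30000, replace = TRUE)
  s[10001:10003] <- c("G", "G", "A")
  s[25298:25300] <- c("T", "C", "C")  # revcomp -> GGA at the 5' end
  seqs <- c(c1 = paste(s, collapse = ""))
  ann <- gene_annotation(tibble::tibble(
    gene_id = c("geneA", "geneB"), chrom = "c1",
    start = c(10001L, 25001L), end = c(10900L, 25300L),
    strand = c("+", "-"),
    cds = list(tibble::tibble(start = c(10001L, 10601L),
                              end = c(10300L, 10900L)),
               tibble::tibble(start = 25001L, end = 25300L))
  ))
  list(seqs = seqs, ann = ann, s = s)
}
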