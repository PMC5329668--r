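# Shared fixture worlds (built once per test run) and hand-made toys.

withr_local_tempfile <- function(env = parent.frame()) {
  withr::local_tempfile(.local_envir = env)
}

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

world_small <- generate_world(101, alleles_per_locus = 3,
                              alleles_per_split = 2, n_haplotypes = 15,
                              protein_length = 21)

world_default <- generate_world(202)  # 4 alleles/locus, 40 haplotypes

# sparse study world: table small relative to the allele space, as for
# published tables; used by the end-to-end scenario checks
world_study <- generate_world(7, alleles_per_locus = 5,
                              alleles_per_split = 2, n_haplotypes = 60,
                              protein_length = 30)

# injective serology: split typing identifies the allele
world_injective <- generate_world(303, alleles_per_locus = 4,
                                  alleles_per_split = 1, n_haplotypes = 25,
                                  protein_length = 21)

# hand-made map: allele i at each locus -> split "<P>10i" -> broad
# "<P>ceil(i/2)", with injective allele->split
toy_map <- function(n_per_locus = 6L) {
  pre <- c(A = "A", B = "B", C = "Cw", DRB1 = "DR", DQB1 = "DQ")
  rows <- do.call(rbind, lapply(LOCI5, function(loc) {
    data.frame(
      allele = sprintf("%s*%02d:01", loc, seq_len(n_per_locus)),
      split = sprintf("%s%d", pre[[loc]], 100L + seq_len(n_per_locus)),
      broad = sprintf("%s%d", pre[[loc]], ceiling(seq_len(n_per_locus) / 2)),
      stringsAsFactors = FALSE)
  }))
  serology_map(rows$allele, rows$split, rows$broad)
}

# frequency table from a matrix of allele indices (rows = haplotypes,
# columns = the 5 loci)
toy_table <- function(idx, freq = NULL) {
  df <- as.data.frame(matrix(
    sprintf("%s*%02d:01", rep(LOCI5, each = nrow(idx)), as.vector(idx)),
    nrow = nrow(idx)), stringsAsFactors = FALSE)
  names(df) <- LOCI5
  df$freq <- if (is.null(freq)) rep(1 / nrow(idx), nrow(idx)) else freq
  hla_freq_table(df)
}

# split-level phenotype from per-locus allele index sets under toy_map
toy_split_phenotype <- function(...) {
  pre <- c(A = "A", B = "B", C = "Cw", DRB1 = "DR", DQB1 = "DQ")
  idx <- list(...)
  vals <- lapply(names(idx), function(loc) {
    sprintf("%s%d", pre[[loc]], 100L + idx[[loc]])
  })
  names(vals) <- names(idx)
  do.call(hla_phenotype, vals)
}

# random mixed-resolution phenotypes derived from table genotypes
random_phenotypes <- function(world, n, seed) {
  genos <- sample_genotypes(world$freq_table, n, seed = seed)
  set.seed(seed + 1L)
  lapply(genos, function(g) {
    lvl <- sample(c("split", "split", "twofield"), 1L)
    loci <- if (stats::runif(1) < 0.3) {
      sample(LOCI5, sample(3:4, 1L))
    } else LOCI5
    phenotype_of(g, world$sermap, lvl, loci = sort(loci))
  })
}
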