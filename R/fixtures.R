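## Deterministic synthetic HLA worlds: allele inventories, serology maps
## with configurable degeneracy, mutated protein sequences, eplet
## registries with controlled sharing, and Dirichlet-skewed haplotype
## frequency tables. Sized so exhaustive brute-force oracles stay
## feasible; stands in for published frequency tables and real typings.

.SEROTYPE_PREFIX <- c(A = "A", B = "B", C = "Cw", DRB1 = "DR", DQB1 = "DQ")
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Generate a synthetic HLA world
#'
#' Builds a complete, self-consistent set of inputs for the whole
#' pipeline from one seed: per-locus allele lists; a serology map in
#' which every `alleles_per_split` consecutive alleles share a split
#' antigen and every `splits_per_broad` splits share a broad antigen
#' (the serological degeneracy dial — the source of imputation
#' ambiguity); protein sequences derived from one base sequence per
#' locus by point substitutions (so alleles share most of their
#' sequence, as real HLA alleles do, exercising the PIRCHE self filter);
#' an eplet registry in which alleles of the same split share a core
#' eplet set plus a private eplet (controlled sharing); and a frequency
#' table over `n_haplotypes` distinct five-locus haplotypes with
#' Dirichlet-sampled frequencies, skewed (small concentration) so a few
#' haplotypes are common and many are rare, mimicking the truncation
#' behavior of published tables and exercising the fallback schemes.
#'
#' The world is regenerable bit-exactly from `(seed, params)`. Alleles
#' that end up in no sampled haplotype stay in the map/registry but are
#' recorded in `unused_alleles`.
#'
#' @param seed Integer seed.
#' @param alleles_per_locus Number of alleles at each locus.
#' @param alleles_per_split Alleles sharing one split antigen (1 makes
#'   serology injective: split typing identifies the allele).
#' @param splits_per_broad Splits sharing one broad antigen.
#' @param n_haplotypes Distinct haplotypes in the frequency table.
#' @param protein_length Length of the synthetic protein sequences.
#' @param eplets_per_allele Eplets annotated per allele.
#' @param eplet_pool Size of the eplet name pool.
#' @param dirichlet_conc Dirichlet concentration; small values give a
#'   skewed frequency profile.
#' @return A list of class `fixture_world` with elements `seed`,
#'   `params`, `alleles`, `sermap` (an `hla_serology_map`), `proteins`,
#'   `eplets`, `freq_table` (an `hla_freq_table`), `unused_alleles`.
#' @export
generate_world <- function(seed,
                           alleles_per_locus = 4L,
                           alleles_per_split = 2L,
                           splits_per_broad = 2L,
                           n_haplotypes = 40L,
                           protein_length = 40L,
                           eplets_per_allele = 6L,
                           eplet_pool = 60L,
                           dirichlet_conc = 0.5) {
  params <- list(alleles_per_locus = as.integer(alleles_per_locus),
                 alleles_per_split = as.integer(alleles_per_split),
                 splits_per_broad = as.integer(splits_per_broad),
                 n_haplotypes = as.integer(n_haplotypes),
                 protein_length = as.integer(protein_length),
                 eplets_per_allele = as.integer(eplets_per_allele),
                 eplet_pool = as.integer(eplet_pool),
                 dirichlet_conc = dirichlet_conc)
  if (any(unlist(params[1:7]) < 1L)) {
    stop("all world parameters must be >= 1", call. = FALSE)
  }
  max_h <- as.numeric(alleles_per_locus)^5
  if (n_haplotypes > max_h) {
    stop(sprintf("n_haplotypes = %d exceeds the %g possible haplotypes",
                 n_haplotypes, max_h), call. = FALSE)
  }
  if (protein_length < 9L) {
    stop("protein_length must be >= 9 for nonamer cores", call. = FALSE)
  }
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)

  alleles <- list(); ser_rows <- list()
  for (loc in HLA_LOCI) {
    a <- sprintf("%s*%02d:01", loc, seq_len(alleles_per_locus))
    alleles[[loc]] <- a
    split_idx <- ceiling(seq_len(alleles_per_locus) / alleles_per_split)
    broad_idx <- ceiling(split_idx / splits_per_broad)
    pre <- .SEROTYPE_PREFIX[[loc]]
    ser_rows[[loc]] <- data.frame(
      allele = a,
      split = sprintf("%s%d", pre, 100L + split_idx),
      broad = sprintf("%s%d", pre, broad_idx),
      stringsAsFactors = FALSE)
  }
  ser_df <- do.call(rbind, ser_rows)
  sermap <- serology_map(ser_df$allele, ser_df$split, ser_df$broad)

  ## proteins: per-locus base sequence, point substitutions per allele
  proteins <- character(0)
  n_mut <- max(2L, round(protein_length * 0.1))
  for (loc in HLA_LOCI) {
    base <- sample(.AA20, protein_length, replace = TRUE)
    for (a in alleles[[loc]]) {
      s <- base
      pos <- sample.int(protein_length, n_mut)
      for (p in pos) s[[p]] <- sample(setdiff(.AA20, s[[p]]), 1L)
      proteins[[a]] <- paste(s, collapse = "")
    }
  }

  ## eplets: alleles of one split share a core set plus a private eplet
  pool <- sprintf("ep%03d", seq_len(eplet_pool))
  eplets <- list()
  for (loc in HLA_LOCI) {
    splits <- unique(ser_rows[[loc]]$split)
    core <- stats::setNames(
      lapply(splits, function(s) {
        sample(pool, max(0L, eplets_per_allele - 1L))
      }), splits)
    for (i in seq_along(alleles[[loc]])) {
      a <- alleles[[loc]][[i]]
      sp <- ser_rows[[loc]]$split[[i]]
      eplets[[a]] <- unique(c(core[[sp]], sample(pool, 1L)))
    }
  }

  ## frequency table: distinct haplotypes, skewed Dirichlet frequencies
  seen <- character(0)
  rows <- vector("list", n_haplotypes)
  got <- 0L
  for (it in seq_len(1000L * n_haplotypes)) {
    h <- vapply(HLA_LOCI, function(loc) sample(alleles[[loc]], 1L),
                character(1L))
    key <- paste(h, collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    got <- got + 1L
    rows[[got]] <- h
    if (got == n_haplotypes) break
  }
  if (got < n_haplotypes) {
    stop("failed to sample the requested number of distinct haplotypes",
         call. = FALSE)
  }
  hap <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(hap) <- HLA_LOCI
  g <- stats::rgamma(n_haplotypes, shape = dirichlet_conc, rate = 1)
  g[g <= 0] <- min(g[g > 0])
  hap$freq <- g / sum(g)
  freq_table <- hla_freq_table(hap, source = "fixture",
                               population = sprintf("synthetic-seed%d", seed))

  unused <- lapply(alleles, function(a) {
    used <- unique(unlist(freq_table[HLA_LOCI], use.names = FALSE))
    setdiff(a, used)
  })

  structure(
    list(seed = seed, params = params, alleles = alleles, sermap = sermap,
         proteins = proteins, eplets = eplets, freq_table = freq_table,
         unused_alleles = unused),
    class = "fixture_world")
}

#' @export
print.fixture_world <- function(x, ...) {
  cat(sprintf(
    "<fixture_world> seed %d: %d alleles/locus, %d haplotypes, %d alleles/split\n",
    x$seed, x$params$alleles_per_locus, x$params$n_haplotypes,
    x$params$alleles_per_split))
  invisible(x)
}

#' Write a fixture world to disk
#'
#' Emits the file formats every other module reads: `freq.csv`,
#' `sermap.csv`, `proteins.fasta`, `eplets.csv` and a `manifest.json`
#' with the generator parameters.
#'
#' @param world A `fixture_world`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_haplotype_frequencies(world$freq_table, file.path(dir, "freq.csv"))
  write_serology_map(world$sermap, file.path(dir, "sermap.csv"))
  write_protein_fasta(world$proteins, file.path(dir, "proteins.fasta"))
  write_eplet_registry(world$eplets, file.path(dir, "eplets.csv"))
  jsonlite::write_json(c(list(seed = world$seed), world$params),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Degrade a true genotype to a scenario's input typing
#'
#' Projects a known two-field genotype down to what a given typing
#' scenario would provide as input: full split serology, split serology
#' with HLA-C or HLA-DQ omitted, or the two-field genotype passed
#' through unchanged.
#'
#' @param genotype An `hla_genotype`.
#' @param map An `hla_serology_map`.
#' @param scenario One of `"split"`, `"split_drop_C"`, `"split_drop_DQ"`,
#'   `"twofield"`.
#' @return An `hla_phenotype`.
#' @export
degrade <- function(genotype, map,
                    scenario = c("split", "split_drop_C", "split_drop_DQ",
                                 "twofield")) {
  scenario <- match.arg(scenario)
  switch(scenario,
    split = phenotype_of(genotype, map, "split"),
    split_drop_C = phenotype_of(genotype, map, "split",
                                loci = setdiff(HLA_LOCI, "C")),
    split_drop_DQ = phenotype_of(genotype, map, "split",
                                 loci = setdiff(HLA_LOCI, "DQB1")),
    twofield = phenotype_of(genotype, level = "twofield"))
}

#' Sample genotypes from a frequency table
#'
#' Draws `n` genotypes, each as two independent haplotypes with
#' probability proportional to frequency. A convenience for building
#' test couples.
#'
#' @param table An `hla_freq_table`.
#' @param n Number of genotypes.
#' @param seed Integer seed.
#' @return A list of `hla_genotype` objects.
#' @export
sample_genotypes <- function(table, n, seed = NULL) {
  pop <- sample_population(table, n, seed = seed, policy = "iid")
  lapply(seq_len(n), function(i) individual_genotype(pop, i))
}
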