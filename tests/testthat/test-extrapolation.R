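test_that("matches agrees with an allele-set-expansion matcher", {
  world <- world_small
  tab <- world$freq_table
  phenos <- random_phenotypes(world, 20, seed = 11)
  for (ph in phenos) {
    for (i in seq_len(nrow(tab))) {
      h <- setNames(unlist(tab[i, hla_loci()], use.names = FALSE), hla_loci())
      expect_identical(matches(h, ph, world$sermap),
                       oracle_matches(h, ph, world$sermap$df),
                       info = paste(unlist(ph), collapse = " "))
    }
  }
})

test_that("a single haplotype matching one phenotype value is not enough", {
  map <- toy_map()
  tab <- toy_table(rbind(rep(1, 5), rep(2, 5)))
  h1 <- setNames(sprintf("%s*01:01", hla_loci()), hla_loci())
  # A*01:01 maps to A101; membership in a two-valued phenotype holds
  expect_true(matches(h1, toy_split_phenotype(A = c(1, 2)), map))
  # but not when the phenotype names only the other antigen
  expect_false(matches(h1, toy_split_phenotype(A = 2), map))
  # the pair must jointly reproduce a heterozygous phenotype
  ph <- toy_split_phenotype(A = c(1, 2), B = c(1, 2), C = c(1, 2),
                            DRB1 = c(1, 2), DQB1 = c(1, 2))
  cand <- enumerate_candidates(ph, tab, map, scheme = 1)
  expect_equal(nrow(cand), 1L)  # only the het pair covers both antigens
  expect_false(cand$h1_A[[1]] == cand$h2_A[[1]])
})

test_that("forced single-haplotype table yields the homozygous candidate", {
  tab <- toy_table(matrix(rep(1, 5), nrow = 1), freq = 0.8)
  map <- toy_map()
  ph <- toy_split_phenotype(A = 1, B = 1, C = 1, DRB1 = 1, DQB1 = 1)
  cand <- enumerate_candidates(ph, tab, map, scheme = 1)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$freq, 0.8^2)
})

test_that("two haplotypes projecting to one phenotype give three pairs", {
  # both haplotypes share every split antigen (alleles 1 and 2 share a
  # split under toy serology with 2 alleles per split is not the case for
  # toy_map, so use the same indices at every locus)
  map <- serology_map(
    c(sprintf("%s*01:01", hla_loci()), sprintf("%s*02:01", hla_loci())),
    rep(sprintf("%s101", c("A", "B", "Cw", "DR", "DQ")), 2),
    rep(sprintf("%s1", c("A", "B", "Cw", "DR", "DQ")), 2))
  tab <- toy_table(rbind(rep(1, 5), rep(2, 5)), freq = c(0.6, 0.4))
  ph <- hla_phenotype(A = "A101", B = "B101", C = "Cw101",
                      DRB1 = "DR101", DQB1 = "DQ101")
  cand <- enumerate_candidates(ph, tab, map, scheme = 1)
  expect_equal(nrow(cand), 3L)  # (H1,H1), (H1,H2), (H2,H2)
  expect_equal(sort(cand$freq), sort(c(0.36, 0.24, 0.16)))
})

test_that("enumeration equals exhaustive brute force across all schemes", {
  for (world in list(world_small, world_default)) {
    phenos <- random_phenotypes(world, 6, seed = 23)
    for (ph in phenos) {
      for (s in 1:5) {
        got <- enumerate_candidates(ph, world$freq_table, world$sermap,
                                    scheme = s)
        want <- oracle_enumerate(ph, world$freq_table, world$sermap, s)
        keys <- candidate_keys(got)
        expect_setequal(keys, want$key)
        got_freq <- got$freq[order(keys)]
        expect_equal(got_freq, want$freq[order(want$key)], tolerance = 1e-9)
      }
    }
  }
})

test_that("hardy-weinberg flag doubles heterozygous pair frequencies", {
  world <- world_small
  ph <- random_phenotypes(world, 1, seed = 31)[[1]]
  plain <- enumerate_candidates(ph, world$freq_table, world$sermap, scheme = 5)
  hw <- enumerate_candidates(ph, world$freq_table, world$sermap, scheme = 5,
                             hw_factor = TRUE)
  het <- plain$h1_A != plain$h2_A |
    apply(plain[paste0("h1_", hla_loci())] != plain[paste0("h2_", hla_loci())],
          1, any)
  expect_equal(hw$freq, unname(plain$freq * ifelse(het, 2, 1)),
               tolerance = 1e-12)
})

test_that("extrapolate normalizes weights and stops at the first scheme", {
  world <- world_default
  phenos <- random_phenotypes(world, 10, seed = 41)
  for (ph in phenos) {
    imp <- extrapolate(ph, world$freq_table, world$sermap)
    expect_false(imp$unimputable)
    expect_equal(sum(imp$candidates$weight), 1, tolerance = 1e-9)
    # fallback monotonicity: all earlier schemes must be empty
    if (imp$scheme > 1L) {
      for (s in seq_len(imp$scheme - 1L)) {
        expect_equal(nrow(enumerate_candidates(ph, world$freq_table,
                                               world$sermap, scheme = s)), 0L)
      }
    }
    # consistency: every candidate re-projects into the phenotype
    for (i in seq_len(min(5L, imp$n_candidates))) {
      g <- candidate_genotype(imp, i)
      for (loc in names(ph)) {
        lvl <- if (grepl("*", ph[[loc]][[1]], fixed = TRUE)) "twofield"
               else "split"
        proj <- phenotype_of(g, world$sermap, lvl, loci = loc)[[loc]]
        expect_setequal(proj, ph[[loc]])
      }
    }
  }
})

test_that("under per-locus breakdown frequencies are products of allele frequencies", {
  world <- world_small
  tab <- world$freq_table
  # independent single-locus marginals
  marg <- lapply(hla_loci(), function(loc) tapply(tab$freq, tab[[loc]], sum))
  names(marg) <- hla_loci()
  phenos <- random_phenotypes(world, 6, seed = 53)
  for (ph in phenos) {
    cand <- enumerate_candidates(ph, tab, world$sermap, scheme = 5)
    for (i in seq_len(nrow(cand))) {
      prod10 <- prod(vapply(hla_loci(), function(loc) {
        marg[[loc]][[cand[[paste0("h1_", loc)]][[i]]]] *
          marg[[loc]][[cand[[paste0("h2_", loc)]][[i]]]]
      }, numeric(1L)))
      expect_equal(cand$freq[[i]], prod10, tolerance = 1e-12)
    }
  }
})

test_that("a serotype absent from the table is unimputable", {
  tab <- toy_table(rbind(rep(1, 5), rep(2, 5)))
  map <- toy_map()
  ph <- toy_split_phenotype(A = 5, B = 1, C = 1, DRB1 = 1, DQB1 = 1)
  imp <- extrapolate(ph, tab, map)
  expect_true(imp$unimputable)
  expect_true(is_unimputable(imp))
  expect_s3_class(imp, "hla_unimputable")
})

test_that("the candidate explosion guard raises a hard error", {
  world <- world_default
  ph <- random_phenotypes(world, 1, seed = 61)[[1]]
  expect_error(
    enumerate_candidates(ph, world$freq_table, world$sermap, scheme = 5,
                         max_candidates = 3),
    "candidate explosion")
})

test_that("single-as-unknown relaxes the homozygous reading", {
  map <- toy_map()
  tab <- toy_table(rbind(rep(1, 5), rep(2, 5)), freq = c(0.6, 0.4))
  ph <- toy_split_phenotype(A = 1, B = 1, C = 1, DRB1 = 1, DQB1 = 1)
  strict <- enumerate_candidates(ph, tab, map, scheme = 1)
  loose <- enumerate_candidates(ph, tab, map, scheme = 1,
                                single_as_unknown = TRUE)
  expect_equal(nrow(strict), 1L)           # homozygous H1 only
  expect_equal(nrow(loose), 2L)            # (H1,H1) and (H1,H2)
})
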